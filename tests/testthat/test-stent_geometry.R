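test_that("envelope surface map matches the toroidal parametrization", {
  env <- make_envelope(1.5, 1.5, R = 10, l = 20)
  expect_equal(envelope_radius(env, c(0, 7, 20)), rep(1.5, 3))
  expect_equal(unname(envelope_point(env, 0, 0)[1, ]), c(1.5 + 10, 0, 0))
  env2 <- make_envelope(1.4, 1.6, R = 10, l = 20)
  expect_equal(envelope_radius(env2, 10), 1.5)
  expect_error(make_envelope(-1, 1.5, 10, 20), "invalid geometry")
  expect_error(make_envelope(11, 11, 10, 20), "minor radii")
  expect_error(make_envelope(0.5, 1.6, 10, 20), "slowly varying")
})

test_that("wire generation yields 2*sum(n) wires on the envelope surface", {
  env <- make_envelope()
  cases <- list(list(n = c(5, 3, 5, 4), k = 25, total = 34),
                list(n = c(3, 3, 3, 3), k = 25, total = 24),
                list(n = c(5, 3, 4, 3), k = 25, total = 30))
  for (cs in cases) {
    ws <- generate_wires(stent_design(cs$n, cs$k), env)
    expect_length(ws$wires, cs$total)
    hands <- vapply(ws$wires, `[[`, character(1), "handedness")
    expect_equal(sum(hands == "cw"), cs$total / 2)
    expect_equal(sum(hands == "ccw"), cs$total / 2)
  }
  ws <- generate_wires(stent_design(c(3, 3, 3, 3), 25), env)
  for (w in ws$wires) {
    expect_lt(max(envelope_surface_error(env, w$points)), 1e-6 * 1.75)
    # chord error below 1 um: polyline midpoints stay on the surface
    mid <- (w$points[-1, ] + w$points[-nrow(w$points), ]) / 2
    expect_lt(max(envelope_surface_error(env, mid)), 1e-3)
  }
  # quadrant start positions are centered in equal azimuthal sub-intervals
  q1 <- Filter(function(w) w$quadrant == 1, ws$wires)
  expect_equal(sort(unique(vapply(q1, `[[`, numeric(1), "theta0"))),
               (c(1, 2, 3) - 0.5) * (pi / 2) / 3)
})

test_that("design vector validation and total wire-count range", {
  expect_error(stent_design(c(2, 3, 3, 3), 25), "3..7")
  expect_error(stent_design(c(3, 3, 3, 3), 22), "winding factor")
  counts <- vapply(seq_len(nrow(design_space())), function(i) {
    d <- design_space()[i, ]
    2L * sum(c(d$n1, d$n2, d$n3, d$n4))
  }, integer(1))
  expect_equal(range(counts), c(24L, 56L))
  expect_equal(nrow(design_space()), 2500L)
})

test_that("finite-difference braiding angle matches the closed form", {
  # slender constant-radius envelope: beta = 2 atan(r dtheta/ds)
  r <- 1.75
  env <- make_envelope(r, r, R = 1000, l = 20)
  for (k in c(20, 25, 35)) {
    ws <- generate_wires(stent_design(c(4, 4, 4, 4), k), env)
    closed <- 2 * atan(r * 2 * pi * k / env$reference_pitch_length) * 180 / pi
    expect_lt(abs(braiding_angle(ws) - closed), 0.1)
  }
  # default fixture calibration: winding factor 25 gives 75 degrees
  ws <- generate_wires(stent_design(c(5, 3, 5, 4), 25), make_envelope())
  expect_lt(abs(braiding_angle(ws) - 75), 1)
  # single handedness family has no crossing angle
  one <- structure(list(wires = Filter(function(w) w$handedness == "cw",
                                       ws$wires),
                        radius_um = 60, envelope = make_envelope()),
                   class = "wire_set")
  expect_error(braiding_angle(one), "undefined")
})

test_that("porosity matches a Monte-Carlo rasterization of wire coverage", {
  # worked configuration: 12 wires per family, beta = 75 deg, R_c = 1.75,
  # d = 120 um, on the unrolled cylinder
  Rc <- 1.75; d <- 0.12; Nfam <- 12
  beta <- 75 * pi / 180
  lref <- 2 * pi * 25 * Rc / tan(beta / 2)  # so that k = 25 gives 75 deg
  met <- porosity_pore_density(stent_design(c(3, 3, 3, 3), 25),
                               cylinder_radius = Rc,
                               reference_pitch_length = lref)
  psi <- beta / 2
  p <- (2 * pi * Rc / Nfam) * cos(psi)
  set.seed(42)
  n_mc <- 1.2e6
  x <- stats::runif(n_mc, 0, 2 * pi * Rc)
  y <- stats::runif(n_mc, 0, 40)
  m1 <- (x * cos(psi) - y * sin(psi)) %% p
  m2 <- (x * cos(psi) + y * sin(psi)) %% p
  covered <- pmin(m1, p - m1) < d / 2 | pmin(m2, p - m2) < d / 2
  por_mc <- 100 * (1 - mean(covered))
  expect_lt(abs(met$porosity - por_mc) / por_mc, 0.01)
})

test_that("porosity and pore density respond monotonically to the design", {
  base <- porosity_pore_density(stent_design(c(4, 4, 4, 4), 25))
  for (j in 1:4) {
    n <- c(4, 4, 4, 4); n[j] <- 5
    denser <- porosity_pore_density(stent_design(n, 25))
    expect_lt(denser$porosity, base$porosity)
    expect_gte(denser$pore_density, base$pore_density)
  }
  thick <- porosity_pore_density(stent_design(c(4, 4, 4, 4), 25,
                                              wire_radius_um = 80))
  expect_lt(thick$porosity, base$porosity)
  thin <- porosity_pore_density(stent_design(c(4, 4, 4, 4), 25,
                                             wire_radius_um = 1e-6))
  expect_gt(thin$porosity, 99.99)
  # swapping quadrant counts permutes the per-ROI metrics identically
  a <- porosity_pore_density(stent_design(c(3, 5, 4, 6), 25))
  b <- porosity_pore_density(stent_design(c(5, 3, 6, 4), 25))
  expect_equal(a$by_quadrant$porosity[c(2, 1, 4, 3)],
               b$by_quadrant$porosity)
  expect_equal(a$porosity, b$porosity)
})

test_that("plane sectioning produces equal-area elliptical discs", {
  # orthogonal crossing: circular section
  ws <- straight_wire_set(direction = c(0, 0, 1))
  pl <- plane_spec(c(0, 0, 5), c(0, 0, 1), c(1, 0, 0))
  sec <- section_obstacles(ws, pl)
  expect_equal(nrow(sec), 1L)
  expect_equal(sec$radius_um, 60, tolerance = 1e-9)
  # 45-degree incidence: radius * 2^(1/4)
  ws45 <- straight_wire_set(direction = c(1, 0, 1))
  sec45 <- section_obstacles(ws45, pl)
  expect_equal(sec45$radius_um, 60 * 2^0.25, tolerance = 1e-9)
  # plane beyond the wire extent: empty
  plfar <- plane_spec(c(0, 0, 50), c(0, 0, 1), c(1, 0, 0))
  expect_equal(nrow(section_obstacles(ws, plfar)), 0L)
  # grazing wires are skipped
  wsg <- straight_wire_set(direction = c(1, 0, 0.02))
  plg <- plane_spec(c(0, 0, 0.05), c(0, 0, 1), c(1, 0, 0))
  expect_message(secg <- section_obstacles(wsg, plg), "grazing")
  expect_equal(nrow(secg), 0L)
})

test_that("wire surface export is watertight-by-count and round-trips", {
  tmp <- tempfile(fileext = ".stl")
  ws <- straight_wire_set(length_mm = 10, radius_um = 60)
  counts <- export_wire_mesh(ws, tmp)
  area <- stl_area(tmp)
  expect_equal(area, 2 * pi * 0.06 * 10, tolerance = 0.02)
  # vtk round-trip: vertex and triangle counts survive
  tmp2 <- tempfile(fileext = ".vtk")
  env <- make_envelope()
  ws24 <- generate_wires(stent_design(c(3, 3, 3, 3), 25), env)
  c24 <- export_wire_mesh(ws24, tmp2)
  rt <- read_surface_counts(tmp2)
  expect_equal(rt$vertices, c24$vertices)
  expect_equal(rt$triangles, c24$triangles)
  # one connected component per wire: triangles reference disjoint
  # contiguous vertex blocks, one block per tube
  lines <- readLines(tmp2)
  ip <- grep("^POLYGONS", lines)
  tri <- matrix(as.integer(unlist(strsplit(
    lines[(ip + 1):(ip + rt$triangles)], " "))), ncol = 4, byrow = TRUE)[, -1]
  per_wire <- c24$vertices / 24
  blk <- tri %/% per_wire
  expect_true(all(blk[, 1] == blk[, 2] & blk[, 2] == blk[, 3]))
  expect_equal(length(unique(blk[, 1])), 24L)
  # a sharp kink self-intersects at the tube radius
  kink <- straight_wire_set()
  kink$wires[[1]]$points <- rbind(c(0, 0, 0), c(0.01, 0, 0),
                                  c(0.01, 0.0005, 0), c(0, 0.001, 0))
  expect_error(export_wire_mesh(kink, tempfile(fileext = ".stl")),
               "self-intersecting")
})

test_that("design vectors round-trip through JSON", {
  d <- stent_design(c(5, 3, 4, 3), 30, wire_radius_um = 60)
  tmp <- tempfile(fileext = ".json")
  write_design(d, tmp)
  d2 <- read_design(tmp)
  expect_equal(d2$n, d$n)
  expect_equal(d2$winding_factor, d$winding_factor)
  expect_equal(d2$wire_radius_um, d$wire_radius_um)
})
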