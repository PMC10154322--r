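test_that("meshes are conforming, positively oriented and fully tagged", {
  mesh <- coarse_mesh()
  nd <- mesh$nodes; tr <- mesh$tri
  a2 <- (nd[tr[, 2], 1] - nd[tr[, 1], 1]) * (nd[tr[, 3], 2] - nd[tr[, 1], 2]) -
        (nd[tr[, 3], 1] - nd[tr[, 1], 1]) * (nd[tr[, 2], 2] - nd[tr[, 1], 2])
  expect_true(all(a2 > 0))
  # every boundary edge tagged exactly once
  be <- mesh$boundary_edges
  key <- paste(pmin(be$n1, be$n2), pmax(be$n1, be$n2))
  expect_false(any(duplicated(key)))
  # boundary edges of the triangulation = tagged edges (no hanging nodes)
  ek <- c(paste(pmin(tr[, 1], tr[, 2]), pmax(tr[, 1], tr[, 2])),
          paste(pmin(tr[, 2], tr[, 3]), pmax(tr[, 2], tr[, 3])),
          paste(pmin(tr[, 3], tr[, 1]), pmax(tr[, 3], tr[, 1])))
  once <- names(which(table(ek) == 1))
  expect_setequal(once, key)
  expect_true(all(c("inlet", "outlet", "wall", "sac_wall") %in% be$tag))
  # sac_wall nodes lie strictly above the neck line
  expect_true(all(mesh$nodes[sac_wall_nodes(mesh), 2] >
                    mesh$geometry$parent_width))
  # geometry invariants
  expect_error(aneurysm_geometry(sac_radius = 2, neck_width = 4),
               "smaller than the sac diameter")
  # straight channel variant: rectangle with walls on two sides only
  g0 <- aneurysm_geometry(sac_radius = NULL, parent_width = 2,
                          parent_length = 8)
  m0 <- build_geometry(g0)
  expect_false("sac_wall" %in% m0$boundary_edges$tag)
  wall_y <- m0$nodes[unique(c(
    m0$boundary_edges$n1[m0$boundary_edges$tag == "wall"],
    m0$boundary_edges$n2[m0$boundary_edges$tag == "wall"])), 2]
  expect_setequal(round(range(wall_y), 9), c(0, 2))
})

test_that("parabolic inflow carries the exact flow rate", {
  mesh <- coarse_mesh()
  bc <- inflow_velocity(4, mesh)
  y <- mesh$nodes[bc$nodes, 2] * 1e-3
  dy <- diff(y)
  flux <- sum((bc$u1[-1] + bc$u1[-length(bc$u1)]) / 2 * dy)
  expect_equal(flux, 4e-6 / 4e-3, tolerance = 1e-10)
  expect_equal(max(bc$u1), 1.5 * bc$mean, tolerance = 0.01)
  expect_equal(bc$u1[which.min(y)], 0)
  expect_equal(bc$u1[which.max(y)], 0)
  expect_error(inflow_velocity(0, mesh), "positive")
})

test_that("obstacle immersion flags nodes and grows with disc radius", {
  mesh <- coarse_mesh()
  m0 <- immerse_obstacles(mesh, data.frame(x = numeric(0), y = numeric(0),
                                           radius_um = numeric(0)))
  expect_true(all(m0$chi == 0))
  # disc centered on an interior node with radius above the edge size
  node <- which.min((mesh$nodes[, 1] - 6)^2 + (mesh$nodes[, 2] - 2)^2)
  d1 <- data.frame(x = mesh$nodes[node, 1], y = mesh$nodes[node, 2],
                   radius_um = 600)
  m1 <- immerse_obstacles(mesh, d1)
  expect_equal(m1$obstacle[node], 1)
  expect_equal(m1$chi[node], 1)
  counts <- vapply(c(300, 600, 900, 1200), function(r) {
    sum(immerse_obstacles(mesh, transform(d1, radius_um = r))$obstacle)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(immerse_obstacles(mesh, data.frame(x = 0, y = 2,
                                                  radius_um = 500)),
               "inlet or outlet")
})

test_that("zero inflow from rest is a fixed point of the stepper", {
  mesh <- coarse_mesh()
  sv <- fdstent:::.make_solver(mesh, solver_settings(), cy_params())
  N <- nrow(mesh$nodes)
  state <- list(u1 = numeric(N), u2 = numeric(N), p = numeric(N), t = 0)
  bc <- inflow_velocity(1, mesh)
  bc$u1 <- bc$u1 * 0
  out <- fdstent:::.ns_step(sv, state, bc)
  expect_lt(max(abs(out$u1)), 1e-12)
  expect_lt(max(abs(out$u2)), 1e-12)
})

test_that("steady Newtonian channel flow recovers Poiseuille analytics", {
  pz <- poiseuille_run()
  y <- pz$mesh$nodes[, 2] * 1e-3
  uex <- 6 * pz$U * y * (pz$H - y) / pz$H^2
  l2 <- sqrt(sum((pz$res$u1 - uex)^2) / sum(uex^2))
  expect_lt(l2, 0.01)
  # wall WSS = 6 mu U / H from the first wall element layer
  sr <- fdstent:::element_shear_rate(pz$mesh$nodes * 1e-3, pz$mesh$tri,
                                     pz$res$u1, pz$res$u2)
  nd <- pz$mesh$nodes; tr <- pz$mesh$tri
  ym <- (nd[tr[, 1], 2] + nd[tr[, 2], 2] + nd[tr[, 3], 2]) / 3
  xm <- (nd[tr[, 1], 1] + nd[tr[, 2], 1] + nd[tr[, 3], 1]) / 3
  first_layer <- ym < sort(unique(nd[, 2]))[2] & xm > 4 & xm < 8
  wss <- mean(0.0456 * sr$gamma_dot[first_layer])
  expect_equal(wss, 6 * 0.0456 * pz$U / pz$H, tolerance = 0.01)
  expect_lt(pz$res$residual, 1e-6)
})

test_that("pulsatile cycles conserve mass and control the divergence", {
  h <- coarse_history3()
  expect_equal(h$steps_per_cycle, 40L)  # 0.8 s / 0.02 s
  # inlet flux balances outlet flux at every recorded step
  err <- abs(h$inlet_flux + h$outlet_flux) / max(abs(h$inlet_flux))
  expect_lt(max(err), 0.01)
  # continuity-row residual within the solver tolerance band
  expect_lt(max(h$div_residuals), 1e-6)
  expect_lt(max(h$residuals), 1e-6)
})

test_that("the solution settles into periodic oscillations after cycle 1", {
  h <- coarse_history3()
  rec <- compute_wss_record(h)
  spc <- h$steps_per_cycle
  s2 <- rec$sawss[(spc + 1):(2 * spc)]
  s3 <- rec$sawss[(2 * spc + 1):(3 * spc)]
  expect_lt(sqrt(mean((s2 - s3)^2)) / sqrt(mean(s2^2)), 0.02)
})

test_that("halving the time step changes second-cycle MWSS by under 2%", {
  mesh <- coarse_mesh()
  w <- make_synthetic_pulse()
  m1 <- compute_wss_record(
    solve_cycles(mesh, w, solver_settings(dt = 0.02), cy_params()))$mwss
  m2 <- compute_wss_record(
    solve_cycles(mesh, w, solver_settings(dt = 0.01), cy_params()))$mwss
  expect_lt(abs(m2 - m1) / m1, 0.02)
})

test_that("penalization suppresses the velocity inside solid obstacles", {
  mesh <- coarse_mesh()
  disc <- data.frame(x = 6, y = 2, radius_um = 800)
  m <- immerse_obstacles(mesh, disc)
  w <- make_synthetic_pulse()
  h <- solve_cycles(m, w, solver_settings(cycles = 1), cy_params())
  k <- nrow(h$u1)
  bc <- inflow_velocity(waveform_rate(w, h$times[k]), mesh)
  solid <- m$obstacle == 1
  expect_gt(sum(solid), 0)
  speed <- sqrt(h$u1[k, solid]^2 + h$u2[k, solid]^2)
  expect_lt(max(speed), 1e-3 * max(bc$u1))
})
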