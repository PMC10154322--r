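# memoized expensive fixtures shared across test files
.fix <- new.env(parent = emptyenv())

fix_cached <- function(key, maker) {
  if (is.null(.fix[[key]])) .fix[[key]] <- maker()
  .fix[[key]]
}

# coarse sidewall-aneurysm fixture for solver-level properties
coarse_geometry <- function() {
  aneurysm_geometry(target_edge_size = 0.5, neck_refine = 2,
                    wall_refine = 3)
}

coarse_mesh <- function() fix_cached("coarse_mesh", function()
  build_geometry(coarse_geometry()))

# 3-cycle pulsatile run on the coarse fixture (covers cycles 2 and 3)
coarse_history3 <- function() fix_cached("coarse_history3", function()
  solve_cycles(coarse_mesh(), make_synthetic_pulse(),
               solver_settings(cycles = 3), cy_params()))

# steady Newtonian Poiseuille channel
poiseuille_run <- function() fix_cached("poiseuille", function() {
  g <- aneurysm_geometry(parent_width = 2, parent_length = 12,
                         sac_radius = NULL, target_edge_size = 0.25,
                         wall_refine = 6)
  mesh <- build_geometry(g)
  rh <- cy_params(mu0 = 0.0456, mu_inf = 0.0456)
  res <- solve_steady(mesh, Q = 1.0, solver_settings(dt = 0.05), rh,
                      max_steps = 200, steady_tol = 1e-9)
  list(geometry = g, mesh = mesh, rheology = rh, res = res,
       H = 2e-3, U = 1e-6 / (2e-3)^2)
})

# straight single wire as a wire_set (for export / sectioning tests)
straight_wire_set <- function(length_mm = 10, radius_um = 60,
                              direction = c(0, 0, 1), npts = 51) {
  d <- direction / sqrt(sum(direction^2))
  pts <- outer(seq(0, length_mm, length.out = npts), d)
  colnames(pts) <- c("x", "y", "z")
  structure(list(wires = list(list(points = pts, handedness = "ccw",
                                   quadrant = 1L, theta0 = 0)),
                 radius_um = radius_um),
            class = "wire_set")
}

# parse an ASCII STL and return the total facet area
stl_area <- function(path) {
  lines <- readLines(path)
  v <- lines[grepl("^  vertex", lines)]
  m <- matrix(as.numeric(unlist(strsplit(trimws(v), "\\s+"))[
    c(FALSE, TRUE, TRUE, TRUE)]), ncol = 3, byrow = TRUE)
  p1 <- m[seq(1, nrow(m), 3), , drop = FALSE]
  p2 <- m[seq(2, nrow(m), 3), , drop = FALSE]
  p3 <- m[seq(3, nrow(m), 3), , drop = FALSE]
  u <- p2 - p1; w <- p3 - p1
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}
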