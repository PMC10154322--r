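#' Solver settings for the pulsatile flow environment
#'
#' @param dt Time step (s), default 0.02 (40 steps per 0.8 s cycle).
#' @param lin_tol Relative tolerance enforced on the linear solve.
#' @param c_supg Scaling of the SUPG/PSPG stabilization parameter tau_M.
#' @param c_lsic Scaling of the grad-div parameter tau_C.
#' @param penal_sigma Brinkman penalization rate mu/(rho kappa) (1/s);
#'   the default keeps the drag in obstacle nodes more than six orders
#'   of magnitude above the convective rate scale U/H of the fixture.
#' @param cycles Number of cardiac cycles to run (default 2; the first
#'   is transient burn-in, statistics use the second).
#' @param ramp_frac Fraction of the first cycle over which the inflow is
#'   ramped from zero to avoid an impulsive start.
#' @return An object of class \code{solver_settings}.
#' @export
solver_settings <- function(dt = 0.02, lin_tol = 1e-6, c_supg = 1,
                            c_lsic = 1, penal_sigma = 1e8,
                            cycles = 2L, ramp_frac = 0.1) {
  stopifnot(dt > 0, lin_tol > 0, lin_tol <= 1e-3, c_supg > 0, c_lsic >= 0,
            penal_sigma >= 0, cycles >= 1, ramp_frac >= 0, ramp_frac < 1)
  structure(list(dt = dt, lin_tol = lin_tol, c_supg = c_supg,
                 c_lsic = c_lsic, penal_sigma = penal_sigma,
                 cycles = as.integer(cycles), ramp_frac = ramp_frac),
            class = "solver_settings")
}

#' Parabolic inflow profile for a given flow rate
#'
#' The 2-D analogue of a pulsatile parabolic (Poiseuille) inflow: the
#' channel carries the volumetric rate Q through a unit-depth slab of
#' thickness equal to the channel width H, so the 2-D flux is
#' q = Q / H (m^2/s), the mean velocity U = q / H, and the profile
#' u(y) = 1.5 U (1 - (2(y - H/2)/H)^2), zero at the walls, with
#' centerline peak 1.5 U and exact integral q.
#'
#' @param Q Volumetric flow rate (ml/s), positive.
#' @param mesh A \code{mesh2d} (supplies the inlet node coordinates).
#' @return A list with \code{nodes} (inlet node indices), \code{u1}
#'   (axial velocity, m/s), \code{u2} (zeros), \code{flux} (m^2/s).
#' @export
inflow_velocity <- function(Q, mesh) {
  if (Q <= 0) stop("flow rate must be positive")
  H <- mesh$geometry$parent_width * 1e-3   # m
  q2 <- Q * 1e-6 / H                       # m^2/s
  U <- q2 / H
  inl <- unique(c(mesh$boundary_edges$n1[mesh$boundary_edges$tag == "inlet"],
                  mesh$boundary_edges$n2[mesh$boundary_edges$tag == "inlet"]))
  ord <- order(mesh$nodes[inl, 2])
  inl <- inl[ord]
  y <- mesh$nodes[inl, 2] * 1e-3
  u1 <- 1.5 * U * (1 - (2 * (y - H / 2) / H)^2)
  u1[abs(y) < 1e-12 | abs(y - H) < 1e-12] <- 0
  # rescale so the discrete (trapezoid) flux matches Q exactly
  dy <- diff(y)
  qtrap <- sum((u1[-1] + u1[-length(u1)]) / 2 * dy)
  u1 <- u1 * q2 / qtrap
  list(nodes = inl, u1 = u1, u2 = numeric(length(inl)), flux = q2,
       peak = max(u1), mean = U)
}

# Precompute what the stepper needs: SI node coordinates, Dirichlet dof
# lists, boundary edge tables.
.make_solver <- function(mesh, settings, rheology = cy_params()) {
  nodes_m <- mesh$nodes * 1e-3
  be <- mesh$boundary_edges
  wall_tags <- c("wall", "sac_wall")
  wall_nodes <- sort(unique(c(be$n1[be$tag %in% wall_tags],
                              be$n2[be$tag %in% wall_tags])))
  inlet_nodes <- sort(unique(c(be$n1[be$tag == "inlet"],
                               be$n2[be$tag == "inlet"])))
  # wall takes precedence at the inlet corners (no-slip)
  inlet_only <- setdiff(inlet_nodes, wall_nodes)
  N <- nrow(mesh$nodes)
  list(mesh = mesh, nodes_m = nodes_m, N = N,
       settings = settings, rheology = rheology,
       wall_nodes = wall_nodes, inlet_nodes = inlet_only,
       drag = .drag_field(mesh, settings, rheology))
}

# per-node drag rate (1/s): hard penalization on solid nodes, finite
# Ergun-type porous-screen drag ~ nu f^2 / ((1-f)^3 d^2) on partially
# covered nodes (f = indicator, d = wire diameter)
.drag_field <- function(mesh, settings, rheology) {
  chi <- mesh$chi
  raw <- if (is.null(mesh$obstacle)) numeric(length(chi)) else mesh$obstacle
  d_m <- (if (is.null(mesh$wire_d_mm)) 0.12 else mesh$wire_d_mm) * 1e-3
  nu_ref <- rheology$mu_inf / rheology$rho
  f <- pmin(chi, 0.95)
  drag <- 150 * nu_ref * f^2 / ((1 - f)^3 * d_m^2)
  drag <- pmin(drag, settings$penal_sigma)
  drag[raw >= 1] <- settings$penal_sigma
  drag[chi <= 0] <- 0
  drag
}

# One semi-implicit step.  state: list(u1, u2, p, t).  bc: inflow list as
# returned by inflow_velocity (already scaled to the target time).
.ns_step <- function(sv, state, bc) {
  s <- sv$settings
  p <- sv$rheology
  N <- sv$N
  sr <- element_shear_rate(sv$nodes_m, sv$mesh$tri, state$u1, state$u2)
  mu_e <- cy_viscosity(sr$gamma_dot, p)
  prj <- project_residual(sv$nodes_m, sv$mesh$tri, state$u1, state$u2,
                          state$p, p$rho)
  asm <- assemble_ns_step(sv$nodes_m, sv$mesh$tri, state$u1, state$u2,
                          mu_e, sv$drag, p$rho, s$dt,
                          s$c_supg, s$c_lsic, prj$pi1, prj$pi2)
  ii <- asm$i + 1L; jj <- asm$j + 1L; vv <- asm$v; rhs <- asm$rhs

  bc_dof <- c(sv$wall_nodes, N + sv$wall_nodes,
              bc$nodes, N + bc$nodes)
  bc_val <- c(numeric(2 * length(sv$wall_nodes)), bc$u1, bc$u2)
  # de-duplicate (inlet corner nodes appear as wall too)
  dup <- duplicated(bc_dof)
  bc_dof <- bc_dof[!dup]; bc_val <- bc_val[!dup]

  keep <- !(ii %in% bc_dof)
  A <- Matrix::sparseMatrix(i = c(ii[keep], bc_dof),
                            j = c(jj[keep], bc_dof),
                            x = c(vv[keep], rep(1, length(bc_dof))),
                            dims = c(3 * N, 3 * N))
  rhs[bc_dof] <- bc_val
  x <- as.numeric(Matrix::solve(A, rhs))
  resv <- as.numeric(A %*% x) - rhs
  res <- sqrt(sum(resv^2)) / max(1e-300, sqrt(sum(rhs^2)))
  if (!all(is.finite(x)))
    stop("flow solve produced non-finite fields")
  if (res > s$lin_tol)
    stop(sprintf("linear solve did not reach tolerance: residual %.3e", res))
  # continuity-row residual, normalized by the inflow flux scale
  flux_scale <- max(abs(bc$flux), 1e-300)
  res_div <- sqrt(sum(resv[2 * N + 1:N]^2)) / flux_scale
  list(u1 = x[1:N], u2 = x[N + 1:N], p = x[2 * N + 1:N],
       t = state$t + s$dt, residual = res, div_residual = res_div)
}

# net flux (m^2/s) through boundary edges of a tag, outward normal
.boundary_flux <- function(sv, state, tag) {
  be <- sv$mesh$boundary_edges
  e <- be[be$tag == tag, , drop = FALSE]
  if (nrow(e) == 0) return(0)
  p1 <- sv$nodes_m[e$n1, , drop = FALSE]
  p2 <- sv$nodes_m[e$n2, , drop = FALSE]
  dx <- p2[, 1] - p1[, 1]; dy <- p2[, 2] - p1[, 2]
  len <- sqrt(dx^2 + dy^2)
  # outward normal for the channel: inlet faces -x, outlet +x
  nx <- if (tag == "inlet") -1 else 1
  um <- (state$u1[e$n1] + state$u1[e$n2]) / 2
  sum(um * nx * len)
}

#' March the pulsatile environment over full cardiac cycles
#'
#' Starts from rest in the end-diastolic state, ramps the inflow over
#' the first \code{ramp_frac} of the first cycle, and records the state
#' at every step.  Viscosity is evaluated at the previous-step shear
#' rate and convection uses the previous-step advection velocity
#' (semi-implicit, first-order time stepping).
#'
#' @param mesh A \code{mesh2d}, optionally with immersed obstacles.
#' @param waveform A \code{pulse_waveform}.
#' @param settings A \code{solver_settings}.
#' @param rheology A \code{cy_params}.
#' @return An object of class \code{flow_history}: list with \code{times}
#'   (s), \code{u1}, \code{u2}, \code{p} (step x node matrices, SI),
#'   \code{inlet_flux}, \code{outlet_flux} (m^2/s per step), the mesh,
#'   waveform and settings.
#' @export
solve_cycles <- function(mesh, waveform, settings = solver_settings(),
                         rheology = cy_params()) {
  stopifnot(inherits(mesh, "mesh2d"), inherits(waveform, "pulse_waveform"))
  sv <- .make_solver(mesh, settings, rheology)
  nsteps_cycle <- as.integer(round(waveform$period / settings$dt))
  if (abs(nsteps_cycle * settings$dt - waveform$period) > 1e-9)
    warning("time step does not divide the period exactly")
  nsteps <- nsteps_cycle * settings$cycles
  N <- sv$N
  state <- list(u1 = numeric(N), u2 = numeric(N), p = numeric(N), t = 0)
  U1 <- matrix(0, nsteps, N); U2 <- matrix(0, nsteps, N)
  P <- matrix(0, nsteps, N)
  times <- numeric(nsteps); fin <- numeric(nsteps); fout <- numeric(nsteps)
  resid <- numeric(nsteps); dresid <- numeric(nsteps)
  ramp_T <- settings$ramp_frac * waveform$period
  for (k in seq_len(nsteps)) {
    tn <- k * settings$dt
    Q <- waveform_rate(waveform, tn)
    if (tn < ramp_T) Q <- Q * (tn / ramp_T)
    bc <- inflow_velocity(Q, mesh)
    state <- .ns_step(sv, state, bc)
    U1[k, ] <- state$u1; U2[k, ] <- state$u2; P[k, ] <- state$p
    times[k] <- tn
    fin[k] <- .boundary_flux(sv, state, "inlet")
    fout[k] <- .boundary_flux(sv, state, "outlet")
    resid[k] <- state$residual; dresid[k] <- state$div_residual
  }
  structure(list(times = times, u1 = U1, u2 = U2, p = P,
                 inlet_flux = fin, outlet_flux = fout,
                 residuals = resid, div_residuals = dresid,
                 steps_per_cycle = nsteps_cycle,
                 period = waveform$period,
                 mesh = mesh, settings = settings, rheology = rheology),
            class = "flow_history")
}

#' Solve a steady flow at a fixed inflow rate
#'
#' Pseudo-time marching with the same stepper until the velocity field
#' stops changing; used for the Poiseuille verification of the
#' discretization.
#'
#' @param mesh A \code{mesh2d}.
#' @param Q Constant flow rate (ml/s).
#' @param settings A \code{solver_settings}.
#' @param rheology A \code{cy_params} (set \code{mu0 = mu_inf} for a
#'   Newtonian fluid).
#' @param max_steps Iteration cap.
#' @param steady_tol Relative velocity change declaring steadiness.
#' @return A list with the final \code{u1}, \code{u2}, \code{p} fields,
#'   iteration count and the solver context.
#' @export
solve_steady <- function(mesh, Q, settings = solver_settings(),
                         rheology = cy_params(),
                         max_steps = 400L, steady_tol = 1e-8) {
  sv <- .make_solver(mesh, settings, rheology)
  bc <- inflow_velocity(Q, mesh)
  N <- sv$N
  state <- list(u1 = numeric(N), u2 = numeric(N), p = numeric(N), t = 0)
  for (k in seq_len(max_steps)) {
    prev <- state
    state <- .ns_step(sv, state, bc)
    du <- sqrt(sum((state$u1 - prev$u1)^2 + (state$u2 - prev$u2)^2))
    un <- sqrt(sum(state$u1^2 + state$u2^2))
    if (un > 0 && du / un < steady_tol) break
  }
  c(state, list(iterations = k, solver = sv, inflow = bc))
}

#' Export a flow state as legacy-ASCII VTK
#'
#' Writes the triangulation with point data (velocity, pressure,
#' viscosity, obstacle indicator) for inspection in ParaView.
#'
#' @param history A \code{flow_history}.
#' @param step Step index to export.
#' @param path Output .vtk path.
#' @return \code{path}, invisibly.
#' @export
export_flow_vtk <- function(history, step, path) {
  mesh <- history$mesh
  n <- nrow(mesh$nodes)
  u1 <- history$u1[step, ]; u2 <- history$u2[step, ]
  sr <- element_shear_rate(mesh$nodes * 1e-3, mesh$tri, u1, u2)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fdstent flow state", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], 0), con)
  m <- nrow(mesh$tri)
  writeLines(paste("CELLS", m, 4 * m), con)
  writeLines(paste(3, mesh$tri[, 1] - 1, mesh$tri[, 2] - 1,
                   mesh$tri[, 3] - 1), con)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(rep("5", m), con)
  writeLines(c(paste("POINT_DATA", n), "VECTORS velocity double"), con)
  writeLines(paste(u1, u2, 0), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(history$p[step, ]), con)
  writeLines(c("SCALARS obstacle double 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$chi), con)
  writeLines(c(paste("CELL_DATA", m), "SCALARS viscosity double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(cy_viscosity(sr$gamma_dot, history$rheology)), con)
  invisible(path)
}
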