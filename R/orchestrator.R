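#' Default run configuration
#'
#' A nested list mirroring the YAML run-configuration schema: geometry,
#' envelope, rheology, solver, waveform, reward and agent sections plus
#' a global seed and output directory.  \code{reward$mwss0 = "auto"}
#' requests a pre-stent simulation to measure the reference MWSS_0.
#'
#' @return A named list.
#' @export
default_run_config <- function() {
  list(
    geometry = list(parent_width = 4, parent_length = 24, sac_radius = 2.2,
                    neck_width = 3, sac_offset = 12,
                    target_edge_size = 0.35, neck_refine = 3,
                    wall_refine = 3),
    envelope = list(stent_margin = 2, wall_clearance_um = 60),
    waveform = list(period = 0.8, q_mean = 4.0, q_systole = 7.5,
                    q_diastole = 2.5),
    rheology = list(mu0 = 0.0456, mu_inf = 0.00320, tau = 10.03,
                    n_index = 0.344, a_param = 1.25, rho = 1050),
    solver = list(dt = 0.02, lin_tol = 1e-6, c_supg = 1, c_lsic = 1,
                  penal_sigma = 1e8, cycles = 2, ramp_frac = 0.1),
    reward = list(mwss0 = "auto"),
    agent = list(epochs = 32, n_envs = 8, minibatch_size = 2,
                 learning_rate = 5e-3, clip_range = 0.3,
                 n_episodes = 68, conv_window = 10),
    seed = 1, outdir = "fdstent-run")
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to the defaults.
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- default_run_config()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad) > 0)
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  for (sec in names(def)) {
    if (is.null(cfg[[sec]])) { cfg[[sec]] <- def[[sec]]; next }
    if (is.list(def[[sec]])) {
      badk <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
      if (length(badk) > 0)
        stop("unknown key(s) in '", sec, "': ", paste(badk, collapse = ", "))
      for (k in names(def[[sec]]))
        if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- def[[sec]][[k]]
    }
  }
  cfg
}

.cfg_objects <- function(cfg) {
  g <- do.call(aneurysm_geometry, cfg$geometry)
  w <- do.call(make_synthetic_pulse, cfg$waveform)
  rh <- do.call(cy_params, cfg$rheology)
  sv <- do.call(solver_settings, cfg$solver)
  list(geometry = g, waveform = w, rheology = rh, settings = sv)
}

#' Deploy a stent design into the 2-D environment
#'
#' Generates the braided wire set on a near-straight envelope inscribed
#' in the parent vessel (tube radius H/2 minus a wall clearance, axis on
#' the channel centerline, spanning the neck plus a margin on each
#' side).  The 2-D domain is a depth slab, so all wires within a
#' near-wall out-of-plane band obstruct the planar flow: at each axial
#' station the wires whose azimuth lies in the band facing the neck (or
#' the opposite wall) are counted and coarse-grained into one effective
#' wall-hugging disc per station whose diameter conserves the local
#' depth-averaged metal coverage.  The discs across the neck are the
#' flow-diverting obstruction; their total size grows with wire count
#' and winding factor exactly as the nominal metal coverage does.
#'
#' @param design A \code{stent_design}.
#' @param geometry An \code{aneurysm_geometry}.
#' @param stent_margin Stent overhang beyond the neck on each side (mm).
#' @param wall_clearance_um Gap between the wire centerline ring and the
#'   wall (micrometers); default = one wire radius (wires touch the
#'   wall).
#' @param band Half-width of the out-of-plane band as a fraction of the
#'   tube radius.
#' @param aggregate_mm Station spacing of the coarse-grained discs (mm).
#' @return A data frame of discs (x, y in mm, radius_um) for
#'   \code{immerse_obstacles}.
#' @export
deploy_stent_2d <- function(design, geometry, stent_margin = 2,
                            wall_clearance_um = design$wire_radius_um,
                            band = 0.4, aggregate_mm = 0.25) {
  stopifnot(inherits(design, "stent_design"),
            inherits(geometry, "aneurysm_geometry"))
  if (is.null(geometry$sac_radius))
    stop("deployment requires a geometry with an aneurysm sac")
  H <- geometry$parent_width
  l <- geometry$neck_width + 2 * stent_margin
  x_start <- geometry$sac_offset - l / 2
  if (x_start <= 0 || x_start + l >= geometry$parent_length)
    stop("stent does not fit inside the channel")
  r_env <- H / 2 - wall_clearance_um * 1e-3
  stopifnot(r_env > 0)
  # near-straight envelope: a very large major radius makes the torus
  # locally cylindrical over the stent length
  Re <- 100 * l
  env <- make_envelope(r_env, r_env, R = Re, l = l,
                       reference_pitch_length = calibrate_pitch())
  ws <- generate_wires(design, env)
  rate <- 2 * pi * design$winding_factor / env$reference_pitch_length
  beta <- 2 * atan(r_env * rate)
  d_mm <- 2 * design$wire_radius_um * 1e-3
  b_mm <- 2 * band * r_env                 # out-of-plane slab depth
  theta_b <- asin(min(1, band))            # band half-angle on the shell
  # band census: at each axial station, count wires whose azimuth lies in
  # the near-wall band facing the neck (top) or the opposite wall
  # (bottom); the local depth-averaged metal fraction is the wire count
  # times the oblique frontal width over the slab depth
  stations <- seq(x_start + aggregate_mm / 2, x_start + l - aggregate_mm / 4,
                  by = aggregate_mm)
  s <- stations - x_start
  th0 <- vapply(ws$wires, `[[`, numeric(1), "theta0")
  sgn <- ifelse(vapply(ws$wires, `[[`, character(1),
                       "handedness") == "ccw", 1, -1)
  th <- outer(sgn * rate, s) + th0         # wires x stations
  wrapped <- ((th + pi) %% (2 * pi)) - pi  # in (-pi, pi]
  n_top <- colSums(abs(wrapped) < theta_b)
  n_bot <- colSums(abs(abs(wrapped) - pi) < theta_b)
  frontal <- d_mm / cos(beta / 2)
  f_top <- pmin(0.95, n_top * frontal / b_mm)
  f_bot <- pmin(0.95, n_bot * frontal / b_mm)
  cap_um <- aggregate_mm / 2 * 1e3         # station capture radius
  out <- rbind(
    data.frame(x = stations, y = H, radius_um = cap_um, solidity = f_top),
    data.frame(x = stations, y = 0, radius_um = cap_um, solidity = f_bot))
  out <- out[out$solidity > 1e-6, , drop = FALSE]
  attr(out, "wire_d_mm") <- d_mm
  out
}

#' CFD reward environment over stent designs
#'
#' Returns a closure mapping a \code{stent_design} to the global
#' setpoint reward measured in the 2-D pulsatile environment: deploy the
#' design, immerse its section discs, run the configured number of
#' cardiac cycles, extract the second-cycle MWSS and score
#' \code{-|MWSS - MWSS_0/2|}.  Evaluations are memoized per design (the
#' environment is deterministic).
#'
#' @param cfg Run configuration (see \code{default_run_config}).
#' @param rspec A \code{reward_spec} (the pre-stent reference).
#' @return A function \code{design -> reward} with attribute
#'   \code{"details"} (an environment collecting per-design MWSS).
#' @export
make_cfd_environment <- function(cfg, rspec) {
  ob <- .cfg_objects(cfg)
  base_mesh <- build_geometry(ob$geometry)
  cache <- new.env(parent = emptyenv())
  f <- function(design) {
    key <- .design_key(design)
    if (!is.null(cache[[key]])) return(cache[[key]]$reward)
    discs <- deploy_stent_2d(design, ob$geometry,
                             stent_margin = cfg$envelope$stent_margin,
                             wall_clearance_um = cfg$envelope$wall_clearance_um)
    mesh <- immerse_obstacles(base_mesh, discs)
    hist <- solve_cycles(mesh, ob$waveform, ob$settings, ob$rheology)
    rec <- compute_wss_record(hist)
    r <- reward_global(rec$mwss, rspec)
    cache[[key]] <- list(reward = r, mwss = rec$mwss, n_discs = nrow(discs))
    r
  }
  attr(f, "details") <- cache
  f
}

#' Surrogate reward environment over stent designs
#'
#' A fast stand-in for the CFD environment used for agent validation and
#' brute-force enumeration.  At desk scale the flow diversion is set by
#' the stent's overall metal coverage, so the post-stent MWSS is
#' modelled as the pre-stent value damped by the global pre-deployment
#' porosity, \code{mwss_hat = mwss0 * (P/100)^exponent}, where P is the
#' unit-cell porosity of the uniform structure with the same total wire
#' count (per-family count = sum of the quadrant counts) and winding
#' factor.  The reward is the same global setpoint reward as the CFD
#' environment.  The default exponent reproduces the strong damping of
#' the 2-D slab environment, in which every design overshoots the
#' half-setpoint so the most porous design is optimal.
#'
#' @param rspec A \code{reward_spec}.
#' @param exponent Porosity-damping exponent.
#' @param cylinder_radius Reference cylinder radius (mm) for the
#'   porosity model.
#' @param reference_pitch_length Pitch calibration constant (mm).
#' @return A function \code{design -> reward}.
#' @export
make_surrogate_environment <- function(rspec, exponent = 2.5,
                                       cylinder_radius = 1.75,
                                       reference_pitch_length =
                                         calibrate_pitch()) {
  stopifnot(inherits(rspec, "reward_spec"))
  function(design) {
    d <- 2 * design$wire_radius_um * 1e-3
    rate <- 2 * pi * design$winding_factor / reference_pitch_length
    beta <- 2 * atan(cylinder_radius * rate)
    p <- (2 * pi * cylinder_radius / sum(design$n)) * cos(beta / 2)
    f <- min(1, d / p)
    P <- (1 - f)^2 * 100
    mwss_hat <- rspec$mwss0 * (P / 100)^exponent
    reward_global(mwss_hat, rspec)
  }
}

#' Enumerate the full design space
#' @param wire_radius_um Wire radius for all designs.
#' @return Data frame of all 2500 designs (n1..n4, winding_factor).
#' @export
design_space <- function(wire_radius_um = 60) {
  g <- expand.grid(n1 = 3:7, n2 = 3:7, n3 = 3:7, n4 = 3:7,
                   winding_factor = c(20L, 25L, 30L, 35L))
  g$wire_radius_um <- wire_radius_um
  g
}

#' Pre-stent reference simulation
#'
#' Runs the unstented fixture over the configured cycles and reports
#' MWSS_0 and the reward setpoint MWSS_0 / 2.  The simulation is
#' deterministic: re-runs at fixed settings reproduce MWSS_0 exactly.
#'
#' @param cfg Run configuration.
#' @return List with \code{mwss0}, \code{setpoint}, the \code{wss_record}
#'   and the \code{flow_history}.
#' @export
cmd_pre_stent <- function(cfg = default_run_config()) {
  ob <- .cfg_objects(cfg)
  mesh <- build_geometry(ob$geometry)
  hist <- solve_cycles(mesh, ob$waveform, ob$settings, ob$rheology)
  rec <- compute_wss_record(hist)
  list(mwss0 = rec$mwss, setpoint = rec$mwss / 2,
       record = rec, history = hist)
}

# resolve the reward reference: either a number in the config or "auto"
.resolve_rspec <- function(cfg) {
  m <- cfg$reward$mwss0
  if (identical(m, "auto")) {
    pre <- cmd_pre_stent(cfg)
    reward_spec(pre$mwss0)
  } else {
    reward_spec(as.numeric(m))
  }
}

#' Run the end-to-end design optimization
#'
#' Resolves the pre-stent reference, builds the requested environment
#' and trains the single-step PPO agent.  Environment evaluations are
#' batched per episode and the policy is only updated once the full
#' batch is available (barrier collection).
#'
#' @param cfg Run configuration.
#' @param environment "cfd" or "surrogate".
#' @param outdir Output directory (logs and artifacts); \code{NULL}
#'   writes nothing.
#' @return The \code{episode_log}, with the resolved \code{reward_spec}
#'   attached as attribute \code{"reward_spec"}.
#' @export
cmd_optimize <- function(cfg = default_run_config(),
                         environment = c("cfd", "surrogate"),
                         outdir = cfg$outdir) {
  environment <- match.arg(environment)
  rspec <- .resolve_rspec(cfg)
  env <- if (environment == "cfd") make_cfd_environment(cfg, rspec)
         else make_surrogate_environment(rspec)
  acfg <- sspo_config(epochs = cfg$agent$epochs, n_envs = cfg$agent$n_envs,
                      minibatch_size = cfg$agent$minibatch_size,
                      learning_rate = cfg$agent$learning_rate,
                      clip_range = cfg$agent$clip_range)
  log <- sspo_train(env, acfg, n_episodes = cfg$agent$n_episodes,
                    seed = cfg$seed, conv_window = cfg$agent$conv_window)
  attr(log, "reward_spec") <- rspec
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_episode_log(log, file.path(outdir, "episodes.jsonl"))
    best <- if (!is.null(log$converged_design)) log$converged_design
            else log$best$design
    if (!is.null(best)) {
      write_design(best, file.path(outdir, "best_design.json"))
      env3d <- make_envelope()
      export_wire_mesh(generate_wires(best, env3d),
                       file.path(outdir, "best_stent.stl"))
    }
  }
  log
}

#' Brute-force enumeration of the design space
#'
#' Evaluates every design (or a subset) in the given environment and
#' returns the ranked table.
#'
#' @param cfg Run configuration.
#' @param environment "surrogate" (full 2500-design sweep) or "cfd"
#'   (use \code{subset}).
#' @param subset Optional integer row indices of \code{design_space()}.
#' @return Data frame of designs with \code{reward}, sorted best-first,
#'   with a \code{rank} column.
#' @export
cmd_brute_force <- function(cfg = default_run_config(),
                            environment = c("surrogate", "cfd"),
                            subset = NULL) {
  environment <- match.arg(environment)
  rspec <- .resolve_rspec(cfg)
  env <- if (environment == "cfd") make_cfd_environment(cfg, rspec)
         else make_surrogate_environment(rspec)
  ds <- design_space()
  if (!is.null(subset)) ds <- ds[subset, , drop = FALSE]
  ds$reward <- vapply(seq_len(nrow(ds)), function(i)
    env(stent_design(c(ds$n1[i], ds$n2[i], ds$n3[i], ds$n4[i]),
                     ds$winding_factor[i], ds$wire_radius_um[i])),
    numeric(1))
  ds <- ds[order(-ds$reward), ]
  ds$rank <- seq_len(nrow(ds))
  rownames(ds) <- NULL
  ds
}
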