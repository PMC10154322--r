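test_that("run configurations validate against the schema", {
  cfg <- default_run_config()
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  cfg2 <- read_run_config(tmp)
  expect_equal(cfg2$rheology$mu0, 0.0456)
  expect_equal(cfg2$solver$dt, 0.02)
  # missing sections fall back to defaults
  yaml::write_yaml(list(solver = list(dt = 0.01)), tmp)
  cfg3 <- read_run_config(tmp)
  expect_equal(cfg3$solver$dt, 0.01)
  expect_equal(cfg3$geometry$parent_width, 4)
  yaml::write_yaml(list(funky = list(a = 1)), tmp)
  expect_error(read_run_config(tmp), "unknown configuration")
  yaml::write_yaml(list(solver = list(dx = 1)), tmp)
  expect_error(read_run_config(tmp), "unknown key")
})

test_that("2-D deployment produces wall-hugging monotone coverage", {
  g <- aneurysm_geometry()
  discs <- deploy_stent_2d(stent_design(c(3, 3, 3, 3), 25), g)
  expect_true(all(c("x", "y", "radius_um", "solidity") %in% names(discs)))
  expect_true(all(discs$solidity > 0 & discs$solidity <= 0.95))
  H <- g$parent_width
  expect_true(all(discs$y < 0.3 | discs$y > H - 0.3))
  cover <- function(d) sum(deploy_stent_2d(d, g)$solidity)
  base <- cover(stent_design(c(4, 4, 4, 4), 25))
  expect_gt(cover(stent_design(c(5, 5, 5, 5), 25)), base)
  expect_gt(cover(stent_design(c(4, 4, 4, 4), 35)), base)
  expect_error(deploy_stent_2d(stent_design(c(3, 3, 3, 3), 25),
                               aneurysm_geometry(sac_radius = NULL)),
               "sac")
})

test_that("brute-force enumeration ranks the full design space", {
  cfg <- default_run_config()
  cfg$reward$mwss0 <- 72.6
  bf <- cmd_brute_force(cfg, environment = "surrogate")
  expect_equal(nrow(bf), 2500L)
  expect_equal(sort(bf$rank), 1:2500)
  key <- paste(bf$n1, bf$n2, bf$n3, bf$n4, bf$winding_factor)
  expect_false(any(duplicated(key)))
  expect_true(all(diff(bf$reward) <= 0))
  # top-1 matches an independent re-evaluation
  env <- make_surrogate_environment(reward_spec(72.6))
  d1 <- stent_design(c(bf$n1[1], bf$n2[1], bf$n3[1], bf$n4[1]),
                     bf$winding_factor[1])
  expect_equal(env(d1), bf$reward[1])
})

test_that("the pre-stent stage reports MWSS_0 and its half setpoint", {
  cfg <- default_run_config()
  cfg$geometry$target_edge_size <- 0.5
  cfg$geometry$neck_refine <- 2
  cfg$geometry$wall_refine <- 3
  pre <- cmd_pre_stent(cfg)
  expect_gt(pre$mwss0, 0)
  expect_equal(pre$setpoint, pre$mwss0 / 2)
  expect_s3_class(pre$record, "wss_record")
  # the stepper itself is deterministic: two identical steps agree bitwise
  mesh <- coarse_mesh()
  sv <- fdstent:::.make_solver(mesh, solver_settings(), cy_params())
  N <- nrow(mesh$nodes)
  st0 <- list(u1 = numeric(N), u2 = numeric(N), p = numeric(N), t = 0)
  bc <- inflow_velocity(4, mesh)
  s1 <- fdstent:::.ns_step(sv, st0, bc)
  s2 <- fdstent:::.ns_step(sv, st0, bc)
  expect_identical(s1$u1, s2$u1)
  expect_identical(s1$p, s2$p)
})

test_that("surrogate optimization runs end-to-end and writes artifacts", {
  cfg <- default_run_config()
  cfg$reward$mwss0 <- 72.6
  cfg$agent$n_episodes <- 20
  outdir <- tempfile("fdrun")
  log <- cmd_optimize(cfg, environment = "surrogate", outdir = outdir)
  expect_equal(utils::tail(log$episodes$n_evaluations, 1), 160L)
  expect_equal(attr(log, "reward_spec")$setpoint, 36.3)
  expect_true(file.exists(file.path(outdir, "episodes.jsonl")))
  expect_true(file.exists(file.path(outdir, "best_design.json")))
  expect_true(file.exists(file.path(outdir, "best_stent.stl")))
  lines <- readLines(file.path(outdir, "episodes.jsonl"))
  expect_length(lines, 20L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("episode", "moving_avg", "n_evaluations") %in%
                    names(rec)))
})
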