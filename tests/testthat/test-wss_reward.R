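test_that("WSS statistics reduce correctly for a constant-in-time field", {
  h <- coarse_history3()
  spc <- h$steps_per_cycle
  # freeze the field at one instant over all steps
  hc <- h
  for (f in c("u1", "u2", "p")) {
    hc[[f]] <- matrix(h[[f]][60, ], nrow(h[[f]]), ncol(h[[f]]),
                      byrow = TRUE)
  }
  rec <- compute_wss_record(hc)
  expect_equal(stats::sd(rec$sawss), 0, tolerance = 1e-12)
  expect_equal(rec$mwss, rec$sawss[1])
  rec1 <- compute_wss_record(h)
  expect_setequal(rec1$tawss_nodes,
                  sort(unique(c(rec1$edges$n1, rec1$edges$n2))))
  # MWSS >= time-mean of SAWSS; area-weighted TAWSS mean = mean SAWSS
  ev <- rec1$eval_idx
  expect_gte(rec1$mwss, mean(rec1$sawss[ev]))
  wts <- sac_node_weights(rec1)
  expect_equal(sum(rec1$tawss * wts) / sum(wts), mean(rec1$sawss[ev]),
               tolerance = 1e-9)
})

test_that("SAWSS scales linearly with the inflow in the Stokes regime", {
  mesh <- coarse_mesh()
  rh <- cy_params(mu0 = 0.0456, mu_inf = 0.0456)  # Newtonian
  w1 <- make_synthetic_pulse(q_mean = 0.02, q_systole = 0.0375,
                             q_diastole = 0.0125)
  w2 <- make_synthetic_pulse(q_mean = 0.04, q_systole = 0.075,
                             q_diastole = 0.025)
  r1 <- compute_wss_record(solve_cycles(mesh, w1, solver_settings(), rh))
  r2 <- compute_wss_record(solve_cycles(mesh, w2, solver_settings(), rh))
  expect_equal(r2$mwss / r1$mwss, 2, tolerance = 0.01)
})

test_that("the global setpoint reward matches its definition", {
  spec <- reward_spec(72.6)
  expect_equal(spec$setpoint, 36.3)
  expect_equal(reward_global(36.3, spec), 0)
  expect_equal(reward_global(37.2, spec), -abs(37.2 - 36.3))
  # symmetry about the setpoint
  for (c in c(0.5, 3, 11)) {
    expect_equal(reward_global(36.3 + c, spec), reward_global(36.3 - c, spec))
  }
  expect_true(all(vapply(seq(0, 100, by = 2.5), reward_global,
                         numeric(1), spec = spec) <= 0))
  expect_error(reward_spec(-1))
})

test_that("the banded local reward integrates the piecewise deficit", {
  # entirely within band
  expect_equal(reward_local(rep(30, 10), rep(0.1, 10), 20, 40), 0)
  # uniform excess c above the band over area S gives -c*S
  S <- 2.4; c_exc <- 7
  n <- 100
  expect_equal(reward_local(rep(40 + c_exc, n), rep(S / n, n), 20, 40),
               -c_exc * S, tolerance = 1e-12)
  # mixed field: trapezoid sum matches adaptive quadrature within 0.1%
  f <- function(s) 30 + 25 * sin(3 * pi * s)
  r_loc <- function(v) ifelse(v < 20, v - 20, ifelse(v > 40, 40 - v, 0))
  s <- seq(0, 1, length.out = 20001)
  wts <- rep(1 / (length(s) - 1), length(s))
  wts[c(1, length(s))] <- wts[c(1, length(s))] / 2
  got <- reward_local(f(s), wts, 20, 40)
  oracle <- stats::integrate(function(x) r_loc(f(x)), 0, 1,
                             subdivisions = 2000L, rel.tol = 1e-10)$value
  expect_equal(got, oracle, tolerance = 1e-3)
  expect_lte(got, 0)
})
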