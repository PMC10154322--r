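test_that("action mapping covers exactly the 2500-design space", {
  expect_equal(map_action(rep(-1, 5))$n, rep(3L, 4))
  expect_equal(map_action(rep(-1, 5))$winding_factor, 20L)
  expect_equal(map_action(rep(1, 5))$n, rep(7L, 4))
  expect_equal(map_action(rep(1, 5))$winding_factor, 35L)
  # interior bin-edge ties round toward the lower bin
  expect_equal(map_action(c(-0.2, 0, 0, 0, 0))$n[1], 4L)  # edge of bins 2|3
  expect_equal(map_action(c(0, 0, 0, 0, 0))$winding_factor, 25L)
  expect_error(map_action(c(2, 0, 0, 0, 0)), "\\[-1, 1\\]")
  grid <- as.matrix(expand.grid(rep(list(seq(-0.99, 0.99,
                                             length.out = 11)), 5)))
  keys <- apply(grid, 1, function(a) {
    d <- map_action(a)
    paste(c(d$n, d$winding_factor), collapse = "-")
  })
  expect_equal(length(unique(keys)), 2500L)
})

test_that("whitening normalizes batches under the population convention", {
  set.seed(1)
  for (i in 1:10) {
    r <- stats::rnorm(8, sd = stats::runif(1, 0.1, 10))
    a <- whiten(r)
    expect_equal(mean(a), 0, tolerance = 1e-10)
    expect_equal(mean(a^2), 1, tolerance = 1e-10)
  }
  expect_equal(whiten(c(1, 3)), c(-1, 1))
  expect_equal(whiten(rep(4.2, 8)), rep(0, 8))
  expect_equal(whiten(5), 0)
})

test_that("the clipped surrogate loss has the ceiling and floor", {
  eps <- 0.3
  expect_equal(surrogate_loss(1, 2.5, eps), 2.5)        # identity ratio
  expect_equal(surrogate_loss(1 + 2 * eps, 1, eps), 1 + eps)   # ceiling
  expect_equal(surrogate_loss(1 - 2 * eps, -1, eps), -(1 - eps))  # floor
  expect_equal(surrogate_loss(c(1, 1 + 2 * eps), c(1, 1), eps),
               mean(c(1, 1 + eps)))
  expect_error(surrogate_loss(-0.1, 1, eps))
})

test_that("action sampling is reproducible and statistically unbiased", {
  ps <- policy_init(seed = 11)
  a1 <- sample_actions(ps, 8, seed = 99)
  a2 <- sample_actions(ps, 8, seed = 99)
  expect_identical(a1, a2)
  expect_true(all(a1 >= -1 & a1 <= 1))
  big <- sample_actions(ps, 1e5, seed = 7)
  raw <- attr(big, "raw")
  d <- policy_distribution(ps)
  for (j in 1:5) {
    expect_lt(abs(mean(raw[, j]) - d$mean[j]), 3 * d$sd[j] / sqrt(1e5))
  }
  # zero-variance limit: all actions equal the mean
  ps0 <- policy_init(seed = 11, init_std = 1e-12)
  a0 <- attr(sample_actions(ps0, 4, seed = 1), "raw")
  expect_equal(unname(a0[1, ]), policy_distribution(ps0)$mean,
               tolerance = 1e-9)
})

test_that("policy updates move density toward rewarded actions", {
  cfg <- sspo_config()
  expect_equal(cfg$gamma, 1)
  ps <- policy_init(seed = 5)
  set.seed(5)
  acts <- sample_actions(ps, 8)
  raw <- attr(acts, "raw")
  # degenerate batch: zero advantages leave the parameters unchanged
  ps_same <- sspo_update(ps, raw, rep(1.0, 8), cfg)
  expect_identical(ps_same$par, ps$par)
  # a single positive-advantage action gains density
  rewards <- c(1, rep(0, 7))
  ps2 <- sspo_update(ps, raw, rewards, cfg)
  lp_before <- fdstent:::.logp(policy_distribution(ps)$mean,
                               policy_distribution(ps)$sd,
                               raw[1, , drop = FALSE])
  lp_after <- fdstent:::.logp(policy_distribution(ps2)$mean,
                              policy_distribution(ps2)$sd,
                              raw[1, , drop = FALSE])
  expect_gt(lp_after, lp_before)
})

test_that("training is bit-reproducible and logs evaluation counts", {
  env <- make_surrogate_environment(reward_spec(72.6))
  log1 <- sspo_train(env, sspo_config(), n_episodes = 12, seed = 3)
  log2 <- sspo_train(env, sspo_config(), n_episodes = 12, seed = 3)
  expect_identical(log1$episodes, log2$episodes)
  expect_identical(log1$rewards, log2$rewards)
  expect_equal(log1$episodes$n_evaluations, seq_len(12) * 8)
  # 68 episodes with 8 environments = 544 evaluations
  log68 <- sspo_train(env, sspo_config(), n_episodes = 68, seed = 1)
  expect_equal(utils::tail(log68$episodes$n_evaluations, 1), 544L)
  # moving average window is capped at the 100 latest values
  expect_equal(log68$episodes$moving_avg[68],
               mean(utils::tail(log68$rewards, 100)))
  n_r <- length(log68$rewards)
  expect_equal(log68$episodes$moving_avg[13],
               mean(log68$rewards[(13 * 8 - 99):(13 * 8)]))
})

test_that("the agent solves a 1-D quadratic within one bin of the optimum", {
  # reward peaks at level 6 of the discrete set {3..7}
  map1 <- function(a) 2L + min(5L, max(1L, as.integer(ceiling((a + 1) / 2 * 5))))
  env <- function(n) -(n - 6)^2
  log <- sspo_train(env, sspo_config(), n_episodes = 100, seed = 2,
                    map = map1, conv_window = 10, dim = 1)
  final <- if (!is.null(log$converged_design)) log$converged_design
           else log$best$design
  expect_lte(abs(final - 6), 1)
})

test_that("failed environment evaluations are dropped from the batch", {
  calls <- 0
  env <- function(d) {
    calls <<- calls + 1
    if (calls %% 5 == 0) stop("solver failure")
    -abs(sum(d$n) - 18)
  }
  log <- sspo_train(env, sspo_config(), n_episodes = 6, seed = 4)
  expect_true(any(log$episodes$n_failed > 0))
  expect_equal(length(log$rewards),
               6 * 8 - sum(log$episodes$n_failed))
  expect_equal(utils::tail(log$episodes$n_evaluations, 1), 48L)
})

test_that("policy checkpoints round-trip through JSON", {
  ps <- policy_init(seed = 9)
  set.seed(1)
  ps <- sspo_update(ps, matrix(stats::rnorm(40), 8, 5), stats::rnorm(8),
                    sspo_config())
  tmp <- tempfile(fileext = ".json")
  write_policy(ps, tmp)
  ps2 <- read_policy(tmp)
  expect_equal(policy_distribution(ps2), policy_distribution(ps),
               tolerance = 1e-12)
  expect_equal(ps2$adam$t, ps$adam$t)
})
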