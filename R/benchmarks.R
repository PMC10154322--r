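#' Analytic benchmark objectives
#'
#' Standard minimization test functions used to validate the agent
#' against evolutionary baselines: the d-dimensional Rosenbrock valley
#' (global minimum 0 at the all-ones point) and the 2-D Branin function
#' (global minimum ~0.397887 at (pi, 2.275) among others).
#'
#' @param x Numeric vector within the task bounds.
#' @param dim Expected dimension (rosenbrock only).
#' @return Objective value (cost, to be minimized).
#' @export
rosenbrock <- function(x, dim = length(x)) {
  if (length(x) != dim || dim < 2)
    stop("rosenbrock: dimension mismatch")
  i <- seq_len(dim - 1)
  sum(100 * (x[i + 1] - x[i]^2)^2 + (1 - x[i])^2)
}

#' @rdname rosenbrock
#' @export
branin <- function(x) {
  if (length(x) != 2) stop("branin: dimension mismatch")
  a <- 1; b <- 5.1 / (4 * pi^2); cc <- 5 / pi
  r <- 6; s <- 10; t <- 1 / (8 * pi)
  a * (x[2] - b * x[1]^2 + cc * x[1] - r)^2 +
    s * (1 - t) * cos(x[1]) + s
}

#' Benchmark task definition
#'
#' @param objective One of "rosenbrock2", "rosenbrock5", "branin",
#'   "sphere2".
#' @param budget Total objective evaluations per run; must be a multiple
#'   of \code{n_parallel}.
#' @param n_parallel Environments (agent) / individuals per generation
#'   (evolution strategies).
#' @param n_runs Repetitions for averaged reporting.
#' @return An object of class \code{benchmark_task}.
#' @export
benchmark_task <- function(objective = c("rosenbrock2", "rosenbrock5",
                                         "branin", "sphere2"),
                           budget = 100L, n_parallel = 5L, n_runs = 10L) {
  objective <- match.arg(objective)
  stopifnot(budget >= 0, n_parallel >= 1, n_runs >= 1)
  if (budget %% n_parallel != 0)
    stop("budget must equal iterations x n_parallel")
  def <- switch(objective,
    rosenbrock2 = list(fn = function(x) rosenbrock(x, 2), dim = 2L,
                       lower = c(-2, -2), upper = c(2, 2)),
    rosenbrock5 = list(fn = function(x) rosenbrock(x, 5), dim = 5L,
                       lower = rep(-2, 5), upper = rep(2, 5)),
    branin = list(fn = branin, dim = 2L,
                  lower = c(-5, 0), upper = c(10, 15)),
    sphere2 = list(fn = function(x) sum(x^2), dim = 2L,
                   lower = c(-2, -2), upper = c(2, 2)))
  structure(c(def, list(name = objective, budget = as.integer(budget),
                        n_parallel = as.integer(n_parallel),
                        n_runs = as.integer(n_runs),
                        iterations = budget %/% n_parallel)),
            class = "benchmark_task")
}

.clamp_box <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# shared run-trace bookkeeping: best-so-far cost per evaluation,
# starting from the initial point's cost
.new_trace <- function(f0, budget) {
  tr <- numeric(budget + 1L)
  tr[1] <- f0
  tr
}

#' (mu, lambda) evolution strategy baseline
#'
#' Intermediate-recombination comma-selection ES with log-normal
#' self-adaptation of an isotropic step size, lambda = n_parallel
#' offspring per generation and mu = ceiling(lambda / 2) parents.
#' Offspring are clamped to the box before evaluation.
#'
#' @param task A \code{benchmark_task}.
#' @param seed RNG seed.
#' @param x0 Starting point (defaults to a uniform draw in the box).
#' @return A list with \code{trace} (best-so-far cost, length budget+1),
#'   \code{best_x}, \code{best_cost}, \code{evaluations}.
#' @export
mu_lambda_es <- function(task, seed = 1L, x0 = NULL) {
  set.seed(seed)
  d <- task$dim
  lo <- task$lower; hi <- task$upper
  if (is.null(x0)) x0 <- lo + stats::runif(d) * (hi - lo)
  lambda <- task$n_parallel
  mu <- max(1L, as.integer(ceiling(lambda / 2)))
  tau <- 1 / sqrt(2 * d)
  mean_x <- x0
  sigma <- 0.25 * mean(hi - lo)
  trace <- .new_trace(task$fn(.clamp_box(x0, lo, hi)), task$budget)
  best <- trace[1]; best_x <- x0
  ev <- 0L
  while (ev < task$budget) {
    sig_off <- sigma * exp(tau * stats::rnorm(lambda))
    off <- t(vapply(seq_len(lambda), function(i)
      mean_x + sig_off[i] * stats::rnorm(d), numeric(d)))
    cost <- numeric(lambda)
    for (i in seq_len(lambda)) {
      cost[i] <- task$fn(.clamp_box(off[i, ], lo, hi))
      ev <- ev + 1L
      if (cost[i] < best) { best <- cost[i]; best_x <- off[i, ] }
      trace[ev + 1L] <- best
    }
    sel <- order(cost)[seq_len(mu)]
    mean_x <- colMeans(off[sel, , drop = FALSE])
    sigma <- exp(mean(log(sig_off[sel])))
  }
  list(trace = trace, best_x = .clamp_box(best_x, lo, hi),
       best_cost = best, evaluations = ev)
}

#' CMA-ES baseline
#'
#' Covariance-matrix-adaptation evolution strategy (standard rank-mu /
#' rank-one update with cumulative step-size adaptation), population
#' lambda = n_parallel.
#'
#' @inheritParams mu_lambda_es
#' @return Same structure as \code{mu_lambda_es}.
#' @export
cma_es <- function(task, seed = 1L, x0 = NULL) {
  set.seed(seed)
  d <- task$dim
  lo <- task$lower; hi <- task$upper
  if (is.null(x0)) x0 <- lo + stats::runif(d) * (hi - lo)
  lambda <- task$n_parallel
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  csig <- (mueff + 2) / (d + mueff + 5)
  dsig <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + csig
  ccum <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))
  m <- x0
  sigma <- 0.25 * mean(hi - lo)
  C <- diag(d); ps <- numeric(d); pc <- numeric(d)
  trace <- .new_trace(task$fn(.clamp_box(x0, lo, hi)), task$budget)
  best <- trace[1]; best_x <- x0
  ev <- 0L; gen <- 0L
  while (ev < task$budget) {
    gen <- gen + 1L
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    Z <- matrix(stats::rnorm(lambda * d), lambda, d)
    Y <- Z %*% diag(D, d) %*% t(B)
    X <- sweep(sigma * Y, 2, m, `+`)
    cost <- numeric(lambda)
    for (i in seq_len(lambda)) {
      cost[i] <- task$fn(.clamp_box(X[i, ], lo, hi))
      ev <- ev + 1L
      if (cost[i] < best) { best <- cost[i]; best_x <- X[i, ] }
      trace[ev + 1L] <- best
    }
    sel <- order(cost)[seq_len(mu)]
    ybar <- as.numeric(w %*% Y[sel, , drop = FALSE])
    m <- m + sigma * ybar
    Cinvsq <- B %*% diag(1 / D, d) %*% t(B)
    ps <- (1 - csig) * ps +
      sqrt(csig * (2 - csig) * mueff) * as.numeric(Cinvsq %*% ybar)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - csig)^(2 * gen)) / chiN <
      1.4 + 2 / (d + 1)
    pc <- (1 - ccum) * pc + hsig * sqrt(ccum * (2 - ccum) * mueff) * ybar
    rank_mu <- matrix(0, d, d)
    for (i in seq_len(mu))
      rank_mu <- rank_mu + w[i] * tcrossprod(Y[sel[i], ])
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * ccum * (2 - ccum) * C) +
      cmu * rank_mu
    sigma <- sigma * exp(csig / dsig * (sqrt(sum(ps^2)) / chiN - 1))
  }
  list(trace = trace, best_x = .clamp_box(best_x, lo, hi),
       best_cost = best, evaluations = ev)
}

#' Run the single-step PPO agent on a benchmark task
#'
#' Minimization is implemented as maximization of the negative cost.
#' Raw actions in [-1, 1]^d map affinely onto the box; the initial
#' policy mean is set to the (shared) starting point.
#'
#' @inheritParams mu_lambda_es
#' @param cfg An \code{sspo_config}; \code{n_envs} is overridden by the
#'   task's \code{n_parallel}.
#' @return Same structure as \code{mu_lambda_es}.
#' @export
sspo_benchmark <- function(task, seed = 1L, x0 = NULL,
                           cfg = sspo_config()) {
  d <- task$dim
  lo <- task$lower; hi <- task$upper
  set.seed(seed)
  if (is.null(x0)) x0 <- lo + stats::runif(d) * (hi - lo)
  cfg$n_envs <- task$n_parallel
  to_box <- function(a) lo + (a + 1) / 2 * (hi - lo)
  raw0 <- 2 * (x0 - lo) / (hi - lo) - 1
  costs <- numeric(0)
  env <- function(x) {
    costs[length(costs) + 1L] <<- task$fn(x)
    -costs[length(costs)]
  }
  sspo_train(env, cfg, n_episodes = task$iterations, seed = seed,
             map = to_box, init_mean = raw0, conv_window = NULL, dim = d)
  trace <- .new_trace(task$fn(.clamp_box(x0, lo, hi)), task$budget)
  stopifnot(length(costs) == task$budget)
  trace[-1] <- cummin(pmin(costs, trace[1]))
  list(trace = trace, best_x = NULL, best_cost = min(trace),
       evaluations = length(costs))
}

#' Run a full benchmark comparison
#'
#' Executes \code{n_runs} seeded repetitions of every method with
#' identical starting points and budgets, and returns best-so-far
#' traces with mean/std summaries.
#'
#' @param task A \code{benchmark_task}.
#' @param methods Character subset of "sspo", "mu_lambda_es", "cma_es".
#' @param seed Base seed; run r uses seed + r - 1.
#' @return An object of class \code{benchmark_report}: per-method trace
#'   matrices (n_runs x budget+1), a summary data frame (mean and sd of
#'   the final best cost), the task, and the starting points.
#' @export
run_benchmark <- function(task,
                          methods = c("sspo", "mu_lambda_es", "cma_es"),
                          seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  runners <- list(sspo = sspo_benchmark, mu_lambda_es = mu_lambda_es,
                  cma_es = cma_es)
  traces <- lapply(methods, function(m)
    matrix(0, task$n_runs, task$budget + 1L))
  names(traces) <- methods
  starts <- matrix(0, task$n_runs, task$dim)
  for (r in seq_len(task$n_runs)) {
    sr <- seed + r - 1L
    set.seed(sr)
    x0 <- task$lower + stats::runif(task$dim) * (task$upper - task$lower)
    starts[r, ] <- x0
    for (m in methods) {
      res <- runners[[m]](task, seed = sr, x0 = x0)
      stopifnot(res$evaluations == task$budget)
      traces[[m]][r, ] <- res$trace
    }
  }
  finals <- lapply(traces, function(tr) tr[, ncol(tr)])
  summary <- data.frame(
    method = methods,
    final_mean = vapply(finals, mean, numeric(1)),
    final_sd = vapply(finals, stats::sd, numeric(1)))
  structure(list(task = task, traces = traces, summary = summary,
                 starts = starts),
            class = "benchmark_report")
}

#' Write benchmark traces as CSV
#' @param report A \code{benchmark_report}.
#' @param path Output CSV (long format: method, run, evaluation, best).
#' @return \code{path}, invisibly.
#' @export
write_benchmark_csv <- function(report, path) {
  rows <- do.call(rbind, lapply(names(report$traces), function(m) {
    tr <- report$traces[[m]]
    data.frame(method = m,
               run = rep(seq_len(nrow(tr)), each = ncol(tr)),
               evaluation = rep(0:(ncol(tr) - 1L), nrow(tr)),
               best_cost = as.numeric(t(tr)))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot mean +/- sd benchmark traces
#' @param report A \code{benchmark_report}.
#' @param path Output PNG path.
#' @return \code{path}, invisibly.
#' @export
plot_benchmark <- function(report, path) {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  cols <- c(sspo = "black", mu_lambda_es = "tomato", cma_es = "steelblue")
  ev <- 0:(report$task$budget)
  means <- lapply(report$traces, colMeans)
  ylim <- range(pmax(1e-16, unlist(means)))
  plot(NA, xlim = range(ev), ylim = ylim, log = "y",
       xlab = "objective evaluations", ylab = "best cost",
       main = report$task$name)
  for (m in names(report$traces)) {
    mu <- colMeans(report$traces[[m]])
    sdv <- apply(report$traces[[m]], 2, stats::sd)
    graphics::polygon(c(ev, rev(ev)),
                      pmax(1e-16, c(mu - sdv, rev(mu + sdv))),
                      col = grDevices::adjustcolor(cols[[m]], 0.2),
                      border = NA)
    graphics::lines(ev, pmax(1e-16, mu), col = cols[[m]], lwd = 2)
  }
  graphics::legend("topright", legend = names(report$traces),
                   col = cols[names(report$traces)], lwd = 2)
  invisible(path)
}
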