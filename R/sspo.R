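#' Single-step PPO configuration
#'
#' Hyperparameters of the single-step proximal-policy-optimization
#' agent.  The defaults are the standard set used throughout: 32 update
#' epochs, 8 parallel environments, minibatches of 2, learning rate
#' 5e-3, clipping range 0.3.  The discount is fixed at gamma = 1: each
#' episode is a single interaction, there is no bootstrapping and no
#' critic, and the advantage reduces to the whitened reward.
#'
#' @param epochs Update epochs per episode.
#' @param n_envs Parallel environment evaluations per episode.
#' @param minibatch_size Minibatch size for the shuffled updates.
#' @param learning_rate Adam step size.
#' @param clip_range PPO clipping parameter epsilon.
#' @return An object of class \code{sspo_config}.
#' @export
sspo_config <- function(epochs = 32L, n_envs = 8L, minibatch_size = 2L,
                        learning_rate = 5e-3, clip_range = 0.3) {
  stopifnot(epochs >= 1, n_envs >= 1, minibatch_size >= 1,
            learning_rate > 0, clip_range > 0)
  structure(list(epochs = as.integer(epochs), n_envs = as.integer(n_envs),
                 minibatch_size = as.integer(minibatch_size),
                 learning_rate = learning_rate, clip_range = clip_range,
                 gamma = 1),
            class = "sspo_config")
}

#' Initialize the policy network
#'
#' The policy is state-independent: a fixed input s0 = 0 is mapped
#' through two hidden layers of 4 tanh units to the mean of a 5-D
#' (or \code{dim}-D) normal distribution with diagonal covariance; the
#' per-dimension log standard deviations are free trainable parameters.
#' A large initial standard deviation (0.5 in raw [-1, 1] units) is used
#' for exploration.
#'
#' @param dim Action dimension.
#' @param seed RNG seed for the weight initialization.
#' @param init_mean Optional initial mean (raw units); implemented as
#'   the output-layer bias.
#' @param init_std Initial standard deviation (raw units).
#' @param hidden Hidden layer widths.
#' @return An object of class \code{policy_state}.
#' @export
policy_init <- function(dim = 5L, seed = NULL, init_mean = NULL,
                        init_std = 0.5, hidden = c(4L, 4L)) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(hidden) == 2L, init_std > 0)
  h1 <- hidden[1]; h2 <- hidden[2]
  par <- list(
    W1 = matrix(stats::rnorm(h1, 0, 0.3), h1, 1),
    b1 = stats::rnorm(h1, 0, 0.3),
    W2 = matrix(stats::rnorm(h2 * h1, 0, 0.3), h2, h1),
    b2 = stats::rnorm(h2, 0, 0.3),
    W3 = matrix(stats::rnorm(dim * h2, 0, 0.1), dim, h2),
    b3 = if (is.null(init_mean)) numeric(dim) else as.numeric(init_mean),
    log_std = rep(log(init_std), dim))
  adam <- list(m = lapply(par, function(x) x * 0),
               v = lapply(par, function(x) x * 0), t = 0L)
  structure(list(par = par, adam = adam, dim = dim, s0 = 0),
            class = "policy_state")
}

# forward pass: returns mean vector and hidden activations for backprop
.policy_forward <- function(ps) {
  p <- ps$par
  h1 <- tanh(p$W1 %*% ps$s0 + p$b1)
  h2 <- tanh(p$W2 %*% h1 + p$b2)
  list(mean = as.numeric(p$W3 %*% h2 + p$b3), h1 = h1, h2 = h2)
}

#' Current policy distribution
#' @param ps A \code{policy_state}.
#' @return List with \code{mean} and \code{sd} vectors (raw units).
#' @export
policy_distribution <- function(ps) {
  list(mean = .policy_forward(ps)$mean, sd = exp(ps$par$log_std))
}

#' Sample raw actions from the policy
#'
#' Draws \code{n_envs} actions from the current normal distribution and
#' clips them to the [-1, 1] hypercube.  The unclipped draws (used for
#' the probability ratios during updates) are attached as attribute
#' \code{"raw"}.  With a fixed seed the draw sequence is fully
#' reproducible.
#'
#' @param ps A \code{policy_state}.
#' @param n_envs Number of actions.
#' @param seed Optional RNG seed.
#' @return An \code{n_envs x dim} matrix of clipped actions.
#' @export
sample_actions <- function(ps, n_envs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- policy_distribution(ps)
  eps <- matrix(stats::rnorm(n_envs * ps$dim), n_envs, ps$dim)
  raw <- sweep(sweep(eps, 2, d$sd, `*`), 2, d$mean, `+`)
  out <- raw
  out[out > 1] <- 1
  out[out < -1] <- -1
  attr(out, "raw") <- raw
  out
}

#' Map a raw action to a stent design
#'
#' Each wire-count coordinate bins [-1, 1] into 5 equal sub-intervals
#' mapped to \{3..7\}; the fifth coordinate bins into 4 sub-intervals
#' mapped to winding factors \{20, 25, 30, 35\}.  Upper bins are
#' right-closed and interior bin-edge ties round toward the lower bin.
#' The image of the map is exactly the 2500-design space.
#'
#' @param a Numeric vector of length 5 in [-1, 1].
#' @param wire_radius_um Wire radius passed through to the design.
#' @return A \code{stent_design}.
#' @export
map_action <- function(a, wire_radius_um = 60) {
  if (length(a) != 5L || any(a < -1 - 1e-12) || any(a > 1 + 1e-12))
    stop("action must be a length-5 vector in [-1, 1]")
  bin <- function(x, K) {
    i <- ceiling((x + 1) / 2 * K)
    pmin(K, pmax(1L, i))
  }
  stent_design(2L + bin(a[1:4], 5L), 15L + 5L * bin(a[5], 4L),
               wire_radius_um = wire_radius_um)
}

#' Whiten a reward batch into advantages
#'
#' Normalizes to zero mean and unit variance under the population-
#' standard-deviation convention; a degenerate (zero-spread) batch
#' yields all-zero advantages.
#'
#' @param rewards Numeric vector (batch of episode rewards).
#' @return Advantages of the same length.
#' @export
whiten <- function(rewards) {
  stopifnot(length(rewards) >= 1)
  m <- mean(rewards)
  s <- sqrt(mean((rewards - m)^2))
  if (!is.finite(s) || s < 1e-12) return(numeric(length(rewards)))
  (rewards - m) / s
}

#' Clipped surrogate loss
#'
#' The PPO objective averaged over a minibatch:
#' mean(min(ratio * A, clip(ratio, 1 - eps, 1 + eps) * A)).  For a
#' positive advantage the ratio hits a ceiling of 1 + eps; for a
#' negative advantage a floor of 1 - eps.
#'
#' @param ratio Probability ratios pi_new / pi_old (> 0).
#' @param advantage Advantages, same length.
#' @param eps Clipping range.
#' @return Scalar loss (to be maximized).
#' @export
surrogate_loss <- function(ratio, advantage, eps = 0.3) {
  stopifnot(all(ratio > 0), length(ratio) == length(advantage))
  mean(pmin(ratio * advantage,
            pmax(pmin(ratio, 1 + eps), 1 - eps) * advantage))
}

# log-density of raw actions under the policy; returns n-vector
.logp <- function(mean, sd, raw) {
  z <- sweep(sweep(raw, 2, mean, `-`), 2, sd, `/`)
  -rowSums(sweep(0.5 * z^2, 2, log(sd), `+`)) -
    0.5 * ncol(raw) * log(2 * pi)
}

# one Adam ascent step on the parameter list
.adam_step <- function(ps, grad, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  ps$adam$t <- ps$adam$t + 1L
  t <- ps$adam$t
  for (nm in names(grad)) {
    g <- grad[[nm]]
    if (!all(is.finite(g))) stop("non-finite gradient in ", nm)
    ps$adam$m[[nm]] <- beta1 * ps$adam$m[[nm]] + (1 - beta1) * g
    ps$adam$v[[nm]] <- beta2 * ps$adam$v[[nm]] + (1 - beta2) * g^2
    mhat <- ps$adam$m[[nm]] / (1 - beta1^t)
    vhat <- ps$adam$v[[nm]] / (1 - beta2^t)
    ps$par[[nm]] <- ps$par[[nm]] + lr * mhat / (sqrt(vhat) + eps)
  }
  ps
}

#' Update the policy from one episode batch
#'
#' Whitens the rewards into advantages, then for each epoch shuffles the
#' batch, splits it into minibatches and performs one Adam ascent step
#' per minibatch on the clipped surrogate loss.  Probability ratios are
#' computed against the policy as it stood before the update began.
#'
#' @param ps A \code{policy_state}.
#' @param raw_actions Matrix (n x dim) of unclipped sampled actions.
#' @param rewards Numeric vector of length n.
#' @param cfg An \code{sspo_config}.
#' @return The updated \code{policy_state}.
#' @export
sspo_update <- function(ps, raw_actions, rewards, cfg = sspo_config()) {
  n <- length(rewards)
  stopifnot(nrow(raw_actions) == n)
  adv <- whiten(rewards)
  if (all(adv == 0)) return(ps)   # degenerate batch: zero gradient
  old <- policy_distribution(ps)
  logp_old <- .logp(old$mean, old$sd, raw_actions)
  eps <- cfg$clip_range
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$minibatch_size)
    for (s0 in starts) {
      mb <- perm[s0:min(n, s0 + cfg$minibatch_size - 1L)]
      fw <- .policy_forward(ps)
      sd <- exp(ps$par$log_std)
      a <- raw_actions[mb, , drop = FALSE]
      lp <- .logp(fw$mean, sd, a)
      ratio <- exp(lp - logp_old[mb])
      A <- adv[mb]
      unclipped <- ratio * A
      clipped <- pmax(pmin(ratio, 1 + eps), 1 - eps) * A
      active <- unclipped <= clipped   # min() selects the unclipped branch
      # d loss / d logp = ratio * A on active samples, 0 otherwise
      w <- ifelse(active, ratio * A, 0) / length(mb)
      z <- sweep(sweep(a, 2, fw$mean, `-`), 2, sd, `/`)
      gmean <- as.numeric(t(z / matrix(sd, length(mb), ps$dim,
                                       byrow = TRUE)) %*% w)
      glogstd <- as.numeric(t(z^2 - 1) %*% w)
      # backprop the mean gradient through the network
      gb3 <- gmean
      gW3 <- gmean %*% t(fw$h2)
      dh2 <- t(ps$par$W3) %*% gmean
      dz2 <- dh2 * (1 - fw$h2^2)
      gb2 <- as.numeric(dz2)
      gW2 <- dz2 %*% t(fw$h1)
      dh1 <- t(ps$par$W2) %*% dz2
      dz1 <- dh1 * (1 - fw$h1^2)
      gb1 <- as.numeric(dz1)
      gW1 <- dz1 %*% t(ps$s0)
      grad <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                   W3 = gW3, b3 = gb3, log_std = glogstd)
      ps <- .adam_step(ps, grad, cfg$learning_rate)
    }
  }
  ps
}

#' Train the agent against an environment
#'
#' Episode loop of the single-step agent: sample \code{n_envs} actions,
#' map them to candidate parameters, evaluate the environment for each,
#' whiten the rewards and update the policy.  Failed evaluations
#' (reward \code{NA}) are dropped from the batch.  Convergence is
#' declared when one mapped design is sampled by a majority of all
#' actions over a trailing window of episodes.
#'
#' @param env A function mapping the output of \code{map} to a scalar
#'   reward (or \code{NA} on failure).
#' @param cfg An \code{sspo_config}.
#' @param n_episodes Number of episodes.
#' @param seed RNG seed governing initialization, sampling and
#'   shuffling (fixed seed gives a bit-identical run).
#' @param map Action mapper; defaults to \code{map_action} (the
#'   2500-design stent space).  Use an affine map for continuous
#'   benchmark objectives.
#' @param init_mean Optional initial policy mean (raw units).
#' @param init_std Initial policy standard deviation.
#' @param conv_window Trailing window (episodes) for the convergence
#'   flag; set to \code{NULL} to disable design tracking (continuous
#'   spaces).
#' @param dim Action dimension.
#' @return An object of class \code{episode_log}: a list with
#'   \code{episodes} (data frame: episode, reward statistics, moving
#'   average over the 100 latest values, cumulative evaluation count),
#'   \code{actions}, \code{designs}, \code{rewards}, the final
#'   \code{policy}, \code{converged_design} (or NULL) and
#'   \code{best} (best design and reward seen).
#' @export
sspo_train <- function(env, cfg = sspo_config(), n_episodes = 100L,
                       seed = 1L, map = map_action, init_mean = NULL,
                       init_std = 0.5, conv_window = 10L, dim = 5L) {
  set.seed(seed)
  ps <- policy_init(dim = dim, init_mean = init_mean, init_std = init_std)
  rows <- vector("list", n_episodes)
  all_rewards <- numeric(0)
  actions_log <- vector("list", n_episodes)
  designs_log <- vector("list", n_episodes)
  keys_log <- vector("list", n_episodes)
  best_reward <- -Inf; best_design <- NULL
  converged <- NULL
  n_eval <- 0L
  for (epi in seq_len(n_episodes)) {
    acts <- sample_actions(ps, cfg$n_envs)
    raw <- attr(acts, "raw")
    designs <- lapply(seq_len(nrow(acts)), function(i) map(acts[i, ]))
    rewards <- vapply(designs, function(d) {
      r <- tryCatch(env(d), error = function(e) NA_real_)
      if (!is.finite(r)) NA_real_ else r
    }, numeric(1))
    n_eval <- n_eval + cfg$n_envs
    ok <- !is.na(rewards)
    if (any(ok)) {
      ps <- sspo_update(ps, raw[ok, , drop = FALSE], rewards[ok], cfg)
      ib <- which.max(ifelse(ok, rewards, -Inf))
      if (rewards[ib] > best_reward) {
        best_reward <- rewards[ib]; best_design <- designs[[ib]]
      }
    }
    all_rewards <- c(all_rewards, rewards[ok])
    mov <- mean(utils::tail(all_rewards, 100L))
    rows[[epi]] <- data.frame(
      episode = epi,
      reward_mean = if (any(ok)) mean(rewards[ok]) else NA_real_,
      reward_best = if (any(ok)) max(rewards[ok]) else NA_real_,
      moving_avg = mov, n_failed = sum(!ok), n_evaluations = n_eval)
    actions_log[[epi]] <- acts
    designs_log[[epi]] <- designs
    keys_log[[epi]] <- vapply(designs, .design_key, character(1))
    if (!is.null(conv_window) && epi >= conv_window && is.null(converged)) {
      recent <- unlist(keys_log[(epi - conv_window + 1L):epi])
      tab <- table(recent)
      if (max(tab) > length(recent) / 2) {
        kbest <- names(tab)[which.max(tab)]
        for (e in epi:(epi - conv_window + 1L)) {
          j <- which(keys_log[[e]] == kbest)
          if (length(j) > 0) {
            converged <- designs_log[[e]][[j[1]]]
            break
          }
        }
      }
    }
  }
  structure(list(episodes = do.call(rbind, rows),
                 actions = actions_log, designs = designs_log,
                 rewards = all_rewards, policy = ps,
                 converged_design = converged,
                 best = list(design = best_design, reward = best_reward)),
            class = "episode_log")
}

.design_key <- function(d) {
  if (inherits(d, "stent_design"))
    paste(c(d$n, d$winding_factor), collapse = "-")
  else paste(signif(unlist(d), 10), collapse = "-")
}

#' Save / load a policy checkpoint as JSON
#'
#' Self-describing parameter dump (network weights, log standard
#' deviations and Adam state).
#' @param ps A \code{policy_state}.
#' @param path JSON file path.
#' @return \code{read_policy} returns a \code{policy_state}.
#' @export
write_policy <- function(ps, path) {
  flat <- function(p) lapply(p, function(x)
    list(values = as.numeric(x), dim = dim(x)))
  jsonlite::write_json(
    list(dim = ps$dim,
         par = flat(ps$par),
         adam_m = flat(ps$adam$m), adam_v = flat(ps$adam$v),
         adam_t = ps$adam$t),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  unflat <- function(p) lapply(p, function(e) {
    v <- as.numeric(e$values)
    if (!is.null(e$dim) && length(e$dim) == 2) dim(v) <- e$dim
    v
  })
  structure(list(par = unflat(x$par),
                 adam = list(m = unflat(x$adam_m), v = unflat(x$adam_v),
                             t = x$adam_t),
                 dim = x$dim, s0 = 0),
            class = "policy_state")
}

#' Write an episode log as JSONL
#' @param log An \code{episode_log}.
#' @param path Output path (one JSON object per episode).
#' @return \code{path}, invisibly.
#' @export
write_episode_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log$episodes))) {
    rec <- as.list(log$episodes[i, ])
    rec$designs <- lapply(log$designs[[i]], function(d)
      if (inherits(d, "stent_design"))
        list(n = d$n, winding_factor = d$winding_factor) else d)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
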