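# adjacency of sac-wall boundary edges to their fluid triangle
.sac_edge_elements <- function(mesh) {
  be <- mesh$boundary_edges
  e <- be[be$tag == "sac_wall", , drop = FALSE]
  if (nrow(e) == 0) return(NULL)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tri <- mesh$tri
  ek <- c(key(tri[, 1], tri[, 2]), key(tri[, 2], tri[, 3]),
          key(tri[, 3], tri[, 1]))
  el <- rep(seq_len(nrow(tri)), 3)
  idx <- match(key(e$n1, e$n2), ek)
  stopifnot(!anyNA(idx))
  p1 <- mesh$nodes[e$n1, , drop = FALSE] * 1e-3
  p2 <- mesh$nodes[e$n2, , drop = FALSE] * 1e-3
  data.frame(n1 = e$n1, n2 = e$n2, elem = el[idx],
             len = sqrt(rowSums((p2 - p1)^2)))   # m
}

#' WSS statistics over the aneurysm sac
#'
#' Computes per-edge wall shear stress on the sac wall from the
#' element-wise shear rate (second invariant of the rate-of-deformation
#' tensor) with the Carreau-Yasuda viscosity and the
#' Weissenberg-Rabinowitsch prefactor, then the three summary
#' statistics: SAWSS(t), the instantaneous length-weighted spatial mean;
#' TAWSS, the per-node time mean over the evaluation cycle; and MWSS,
#' the maximum of SAWSS over the evaluation cycle.  The evaluation cycle
#' is the second cardiac cycle (the first is burn-in), so the history
#' must cover at least two cycles.
#'
#' @param history A \code{flow_history} spanning >= 2 cycles.
#' @param mesh The mesh (defaults to the one in the history).
#' @param rheology A \code{cy_params}.
#' @param eval_cycle Index of the cycle used for TAWSS/MWSS (default 2).
#' @return An object of class \code{wss_record}: \code{wss} (time x
#'   sac-edge matrix, dyne/cm^2), \code{sawss} (per recorded time),
#'   \code{tawss} (per sac node), \code{mwss} (scalar), \code{times},
#'   \code{eval_idx} (steps of the evaluation cycle), \code{edges}.
#' @export
compute_wss_record <- function(history, mesh = history$mesh,
                               rheology = history$rheology,
                               eval_cycle = 2L) {
  edges <- .sac_edge_elements(mesh)
  if (is.null(edges)) stop("mesh has no sac_wall boundary")
  spc <- history$steps_per_cycle
  nsteps <- length(history$times)
  if (nsteps < eval_cycle * spc)
    stop("history must cover at least ", eval_cycle, " cardiac cycles")
  nodes_m <- mesh$nodes * 1e-3
  wss <- matrix(0, nsteps, nrow(edges))
  for (k in seq_len(nsteps)) {
    sr <- element_shear_rate(nodes_m, mesh$tri,
                             history$u1[k, ], history$u2[k, ])
    gd <- sr$gamma_dot[edges$elem]
    mu <- cy_viscosity(gd, rheology)
    wss[k, ] <- wss_local(gd, mu, in_sac = TRUE, p = rheology)
  }
  sawss <- as.numeric(wss %*% edges$len) / sum(edges$len)
  eval_idx <- ((eval_cycle - 1L) * spc + 1L):(eval_cycle * spc)
  # per-node TAWSS: length-weighted average of adjacent edge values
  sac_nodes <- sort(unique(c(edges$n1, edges$n2)))
  tawss_edge <- colMeans(wss[eval_idx, , drop = FALSE])
  wnum <- numeric(length(sac_nodes)); wden <- numeric(length(sac_nodes))
  for (side in c("n1", "n2")) {
    id <- match(edges[[side]], sac_nodes)
    acc <- rowsum(cbind(tawss_edge * edges$len / 2, edges$len / 2), id)
    rows <- as.integer(rownames(acc))
    wnum[rows] <- wnum[rows] + acc[, 1]
    wden[rows] <- wden[rows] + acc[, 2]
  }
  structure(list(wss = wss, sawss = sawss,
                 tawss = wnum / wden, tawss_nodes = sac_nodes,
                 mwss = max(sawss[eval_idx]),
                 times = history$times, eval_idx = eval_idx,
                 edges = edges),
            class = "wss_record")
}

#' Reward specification from the pre-stent reference
#'
#' The optimization setpoint is half the pre-operative peak sac-averaged
#' WSS: MWSS_ref = MWSS_0 / 2.  Optional band limits configure the local
#' reward variant.
#'
#' @param mwss0 Pre-stent MWSS (dyne/cm^2), positive.
#' @param wss_inf,wss_sup Optional band limits (dyne/cm^2) for
#'   \code{reward_local}; \code{wss_inf < wss_sup}.
#' @return An object of class \code{reward_spec} with the derived
#'   \code{setpoint}.
#' @export
#' @examples
#' reward_spec(72.6)$setpoint  # 36.3
reward_spec <- function(mwss0, wss_inf = NULL, wss_sup = NULL) {
  stopifnot(is.numeric(mwss0), length(mwss0) == 1, mwss0 > 0)
  if (!is.null(wss_inf) || !is.null(wss_sup)) {
    stopifnot(!is.null(wss_inf), !is.null(wss_sup), wss_inf < wss_sup)
  }
  structure(list(mwss0 = mwss0, setpoint = mwss0 / 2,
                 wss_inf = wss_inf, wss_sup = wss_sup),
            class = "reward_spec")
}

#' Global setpoint reward
#'
#' r = -|MWSS - MWSS_0/2|: non-positive, maximal (zero) exactly at the
#' setpoint, symmetric about it.
#'
#' @param mwss Post-stent MWSS (dyne/cm^2).
#' @param spec A \code{reward_spec}.
#' @return Reward (dyne/cm^2, <= 0).
#' @export
reward_global <- function(mwss, spec) {
  stopifnot(inherits(spec, "reward_spec"), is.finite(mwss))
  -abs(mwss - spec$setpoint)
}

#' Banded local reward
#'
#' Surface integral of the piecewise integrand
#' r_loc(WSS) = WSS - WSS_inf below the band, 0 inside, WSS_sup - WSS
#' above; every off-band contribution is negative, so the reward is
#' maximal (zero) iff the field lies within the band almost everywhere.
#'
#' @param wss WSS values sampled along the sac wall (dyne/cm^2).
#' @param weights Quadrature weights (surface measure) per sample; for a
#'   polyline boundary, the lumped half-edge lengths.
#' @param wss_inf,wss_sup Band limits, \code{wss_inf < wss_sup}.
#' @return Reward (dyne/cm^2 times surface measure, <= 0).
#' @export
reward_local <- function(wss, weights, wss_inf, wss_sup) {
  stopifnot(wss_inf < wss_sup, length(wss) == length(weights))
  r <- numeric(length(wss))
  lo <- wss < wss_inf
  hi <- wss > wss_sup
  r[lo] <- wss[lo] - wss_inf
  r[hi] <- wss_sup - wss[hi]
  sum(r * weights)
}

#' Lumped boundary weights of the sac wall
#'
#' Half-edge lengths accumulated at each sac node, for use with
#' \code{reward_local} on nodal fields such as TAWSS.
#' @param rec A \code{wss_record}.
#' @return Named numeric vector of weights (m) per sac node.
#' @export
sac_node_weights <- function(rec) {
  nodes <- rec$tawss_nodes
  w <- numeric(length(nodes))
  for (side in c("n1", "n2")) {
    id <- match(rec$edges[[side]], nodes)
    acc <- rowsum(rec$edges$len / 2, id)
    rows <- as.integer(rownames(acc))
    w[rows] <- w[rows] + acc[, 1]
  }
  names(w) <- nodes
  w
}

#' Write the SAWSS time series as CSV
#' @param rec A \code{wss_record}.
#' @param path CSV path (columns t, sawss).
#' @return \code{path}, invisibly.
#' @export
write_sawss_csv <- function(rec, path) {
  utils::write.csv(data.frame(t = rec$times, sawss = rec$sawss), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
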