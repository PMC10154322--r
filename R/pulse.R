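#' Pulsatile volumetric flow-rate waveform
#'
#' Ordered (time, flow rate) samples over one cardiac period, linearly
#' interpolated and periodically extended when queried.
#'
#' @param t Sample times (s), strictly increasing, starting at 0.
#' @param q Flow rates (ml/s), all positive.
#' @param period Period (s); defaults to the last sample time.
#' @return An object of class \code{pulse_waveform}.
#' @export
pulse_waveform <- function(t, q, period = max(t)) {
  if (length(t) < 2L) stop("a waveform needs at least two samples")
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing")
  if (any(q <= 0)) stop("flow rates must be positive")
  stopifnot(period > 0, max(t) <= period + 1e-12)
  structure(list(t = t, q = q, period = period), class = "pulse_waveform")
}

#' Flow rate at an arbitrary time
#'
#' Linear interpolation between the two bracketing samples, exact at the
#' sample times, with periodic extension (the last sample wraps onto the
#' first when the samples do not cover the full period).
#'
#' @param w A \code{pulse_waveform}.
#' @param t Query time(s) (s), wrapped modulo the period.
#' @return Flow rate (ml/s).
#' @export
waveform_rate <- function(w, t) {
  tm <- t %% w$period
  ts <- w$t; qs <- w$q
  if (ts[1] > 0) { ts <- c(0, ts); qs <- c(qs[length(qs)], qs) }
  if (ts[length(ts)] < w$period) {
    ts <- c(ts, w$period); qs <- c(qs, qs[1])
  }
  stats::approx(ts, qs, xout = tm, rule = 2)$y
}

#' Synthetic one-period cardiac pulse
#'
#' Smooth waveform emulating a diastole-to-systole inflow pulse:
#' q(u) = q_dia + (q_sys - q_dia) * sin(pi u)^p on normalized phase
#' u in [0, 1].  It starts at the end-diastolic minimum, peaks at
#' mid-cycle systole, and the exponent p > 0 is solved so the cycle mean
#' matches \code{q_mean} (larger p gives a sharper systolic peak and a
#' longer diastolic plateau).  Extrema and mean are attained within the
#' sampling resolution (well under 1 percent at the default).
#'
#' @param period Period (s), default 0.8.
#' @param q_mean Cycle-mean flow rate (ml/s).
#' @param q_systole Peak (systolic) flow rate (ml/s).
#' @param q_diastole Minimum (end-diastolic) flow rate (ml/s).
#' @param n_samples Number of stored samples over one period.
#' @return A \code{pulse_waveform} whose first sample is the diastolic
#'   value.
#' @export
#' @examples
#' w <- make_synthetic_pulse()
#' waveform_rate(w, 0)       # end-diastolic start
make_synthetic_pulse <- function(period = 0.8, q_mean = 4.0,
                                 q_systole = 7.5, q_diastole = 2.5,
                                 n_samples = 161L) {
  if (!(q_diastole < q_mean && q_mean < q_systole))
    stop("flow rates must satisfy q_diastole < q_mean < q_systole")
  stopifnot(period > 0, q_diastole > 0, n_samples >= 9L)
  frac <- (q_mean - q_diastole) / (q_systole - q_diastole)
  ug <- seq(0, 1, length.out = 4001L)[-1]
  mean_shape <- function(p) mean(sin(pi * ug)^p)
  if (frac >= mean_shape(0.05) || frac <= mean_shape(80))
    stop("inconsistent pulse specification: mean too close to an extremum")
  p <- stats::uniroot(function(lp) mean_shape(exp(lp)) - frac,
                      c(log(0.05), log(80)), tol = 1e-12)$root
  p <- exp(p)
  u <- seq(0, 1, length.out = n_samples)
  qv <- q_diastole + (q_systole - q_diastole) * sin(pi * u)^p
  pulse_waveform(u * period, qv, period = period)
}

#' Read / write waveform CSV
#'
#' CSV interchange with header \code{t_s,q_ml_s}.
#' @param w A \code{pulse_waveform}.
#' @param path CSV path.
#' @return \code{read_waveform_csv} returns a \code{pulse_waveform}.
#' @export
write_waveform_csv <- function(w, path) {
  utils::write.csv(data.frame(t_s = w$t, q_ml_s = w$q), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param period Period (s); defaults to the last sample time.
#' @export
read_waveform_csv <- function(path, period = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("t_s", "q_ml_s") %in% names(d)))
  if (is.null(period)) period <- max(d$t_s)
  pulse_waveform(d$t_s, d$q_ml_s, period = period)
}
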