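#' Windowed average error between two trajectory channels
#'
#' The validation metric for trajectory shape agreement: the mean absolute
#' instantaneous difference between an experimental and a simulated channel
#' over a window (default 3 s) starting at perturbation onset, onset sample
#' included. Units follow the channel (degrees for sway, cm for COP).
#'
#' @param exp_t,exp_v experimental time (s) and channel values
#' @param sim_t,sim_v simulated time and channel values on the same grid
#' @param onset_s window start (s)
#' @param window_s window length (s), default 3
#' @return mean absolute error over the window
#' @export
average_error <- function(exp_t, exp_v, sim_t, sim_v, onset_s = 0,
                          window_s = 3) {
  idx <- .metric_window(exp_t, sim_t, onset_s, window_s)
  mean(abs(exp_v[idx] - sim_v[idx]))
}

#' Windowed normalised cross-correlation between two trajectory channels
#'
#' The zero-lag normalised cross-correlation
#' `sum(exp * sim) / sqrt(sum(exp^2) * sum(sim^2))` over the analysis
#' window. No mean subtraction is applied: the channels are deviations from
#' upright, where zero is physically meaningful. Values near 1 indicate
#' matching trajectory shape. Set `max_lag_s > 0` to search lags and return
#' the maximum (off by default).
#'
#' @inheritParams average_error
#' @param max_lag_s if positive, the maximum over lags in
#'   `[-max_lag_s, max_lag_s]` is returned instead of the zero-lag value
#' @return correlation value in `[-1, 1]`; errors when both windows are
#'   identically zero
#' @export
cross_correlation <- function(exp_t, exp_v, sim_t, sim_v, onset_s = 0,
                              window_s = 3, max_lag_s = 0) {
  idx <- .metric_window(exp_t, sim_t, onset_s, window_s)
  e <- exp_v[idx]
  s <- sim_v[idx]
  denom0 <- sqrt(sum(e^2) * sum(s^2))
  if (denom0 == 0) {
    stop("cross-correlation undefined: both channels are zero on the window",
         call. = FALSE)
  }
  cc0 <- sum(e * s) / denom0
  if (max_lag_s <= 0) return(cc0)
  dt <- exp_t[2] - exp_t[1]
  lags <- seq(-round(max_lag_s / dt), round(max_lag_s / dt))
  best <- -Inf
  n <- length(e)
  for (L in lags) {
    ii <- seq_len(n)
    jj <- ii + L
    keep <- jj >= 1 & jj <= n
    d <- sqrt(sum(e[ii[keep]]^2) * sum(s[jj[keep]]^2))
    if (d > 0) best <- max(best, sum(e[ii[keep]] * s[jj[keep]]) / d)
  }
  best
}

.metric_window <- function(exp_t, sim_t, onset_s, window_s) {
  if (length(exp_t) != length(sim_t) ||
      max(abs(exp_t - sim_t)) > 1e-9) {
    stop("experimental and simulated series must share the same time grid",
         call. = FALSE)
  }
  idx <- which(exp_t >= onset_s - 1e-9 & exp_t <= onset_s + window_s + 1e-9)
  if (length(idx) < 2) stop("window not covered by the series", call. = FALSE)
  idx
}

#' Packaged validation-metric table
#'
#' The printed table of average-error and cross-correlation validation
#' values across display configurations (off, 1x2, 3x4, 3x8, 3x16),
#' channels (AP, ML) and perturbation directions. Each of the four metric
#' blocks holds 15 cells; the gaps (1x2 at 90 degrees; 3x8/3x16 away from
#' 225 degrees) are structural.
#'
#' @return a data frame with columns `metric`, `config`, `channel`,
#'   `direction_deg`, `value`
#' @export
table1_values <- function() {
  path <- system.file("extdata", "table1_validation_metrics.csv",
                      package = "posturefb", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Summary means of the validation-metric table
#'
#' Arithmetic mean over all present cells of each metric block, rounded to
#' the printed precision (two decimals).
#'
#' @param tab table as returned by [table1_values()]
#' @return named numeric vector with elements `avg_err_sway` (deg),
#'   `avg_err_cop` (cm), `cc_sway`, `cc_cop`
#' @export
table1_summary <- function(tab = table1_values()) {
  need <- c("avg_err_sway", "cc_sway", "avg_err_cop", "cc_cop")
  counts <- table(factor(tab$metric, levels = need))
  if (any(counts != 15)) {
    stop("each metric block must contain exactly 15 cells", call. = FALSE)
  }
  if (any(!is.finite(tab$value))) stop("missing cells in the table", call. = FALSE)
  out <- vapply(need, function(m) round(mean(tab$value[tab$metric == m]), 2),
                numeric(1))
  out[c("avg_err_sway", "avg_err_cop", "cc_sway", "cc_cop")]
}

#' Validation metrics for one simulated trial against a reference
#'
#' Convenience wrapper computing both metrics for the standard channels of
#' two trajectories on a shared 100 Hz grid.
#'
#' @param ref,sim `stance_trajectory`-like data frames sharing a time grid
#' @param onset_s perturbation onset (s)
#' @param channels channel names to evaluate
#' @param window_s analysis window (s)
#' @return data frame with columns `channel`, `avg_err`, `cc`
#' @export
trajectory_metrics <- function(ref, sim, onset_s,
                               channels = c("sway_ap", "sway_ml",
                                            "cop_x", "cop_y"),
                               window_s = 3) {
  rows <- lapply(channels, function(ch) {
    cc <- tryCatch(cross_correlation(ref$t, ref[[ch]], sim$t, sim[[ch]],
                                     onset_s, window_s),
                   error = function(e) NA_real_)
    data.frame(channel = ch,
               avg_err = average_error(ref$t, ref[[ch]], sim$t, sim[[ch]],
                                       onset_s, window_s),
               cc = cc)
  })
  do.call(rbind, rows)
}
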