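#' Vibrotactile display configuration
#'
#' Geometry and coding of the tactor display: tactor columns around the
#' torso at azimuths drawn from the 16 positions at 22.5 degree intervals
#' starting at the navel, up to three rows per column coding feedback
#' magnitude stepwise, and a dead zone below which nothing is displayed.
#'
#' Named presets reproduce the configurations of interest: `"off"` (no
#' display), `"1x2"` (columns at 0 and 180 degrees, one row), `"3x4"`
#' (columns every 90 degrees), `"3x8"` (every 45), `"3x16"` (every 22.5).
#'
#' Row thresholds are the ascending feedback-magnitude boundaries (degrees)
#' at which successive rows activate; the first equals the dead zone. The
#' within-device row boundaries were not published, so the defaults
#' (1, 2, 3 degrees) are a documented reconstruction.
#'
#' @param preset preset name, or `NULL` when `columns_deg` is given
#' @param columns_deg active column azimuths (deg clockwise from navel)
#' @param n_rows number of rows (1-3)
#' @param dead_zone_deg dead zone (deg, default 1)
#' @param thresholds_deg ascending row thresholds (deg), first = dead zone
#' @return an object of class `display_config`
#' @export
display_config <- function(preset = NULL, columns_deg = NULL, n_rows = 3,
                           dead_zone_deg = 1,
                           thresholds_deg = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("off", "1x2", "3x4", "3x8", "3x16"))
    columns_deg <- switch(preset,
      off = numeric(0),
      "1x2" = c(0, 180),
      "3x4" = seq(0, 270, by = 90),
      "3x8" = seq(0, 315, by = 45),
      "3x16" = seq(0, 337.5, by = 22.5))
    n_rows <- if (preset == "1x2") 1L else if (preset == "off") 0L else 3L
  }
  columns_deg <- sort(columns_deg %% 360)
  if (anyDuplicated(columns_deg)) stop("column azimuths must be distinct", call. = FALSE)
  if (length(columns_deg) &&
      any(abs(columns_deg / 22.5 - round(columns_deg / 22.5)) > 1e-9)) {
    stop("columns must sit on the 22.5-degree grid", call. = FALSE)
  }
  n_rows <- as.integer(n_rows)
  if (length(columns_deg) && (n_rows < 1 || n_rows > 3)) {
    stop("`n_rows` must be 1-3 for an active display", call. = FALSE)
  }
  if (is.null(thresholds_deg)) {
    thresholds_deg <- dead_zone_deg + seq_len(max(n_rows, 0)) - 1
  }
  if (length(thresholds_deg) && thresholds_deg[1] != dead_zone_deg) {
    stop("first row threshold must equal the dead zone", call. = FALSE)
  }
  if (is.unsorted(thresholds_deg, strictly = TRUE)) {
    stop("row thresholds must be strictly ascending", call. = FALSE)
  }
  structure(list(preset = if (is.null(preset)) "custom" else preset,
                 columns_deg = columns_deg, n_rows = n_rows,
                 dead_zone_deg = dead_zone_deg,
                 thresholds_deg = as.numeric(thresholds_deg)),
            class = "display_config")
}

#' Biofeedback torque parameters
#'
#' The reaction time constant and the per-row steady-state torque magnitude
#' vectors of the additive biofeedback torque model. `k_s` and `k_c` are
#' 3x2 matrices (rows: display row 1-3; columns: ankle, hip) of sagittal and
#' coronal magnitudes (N m), constrained componentwise non-decreasing in the
#' row so that the displayed intensity maps monotonically to torque.
#'
#' @param tau_f reaction time constant (s, > 0)
#' @param k_s,k_c 3x2 magnitude matrices (N m)
#' @return an object of class `biofeedback_params`
#' @export
biofeedback_params <- function(tau_f = 0.3,
                               k_s = matrix(c(4, 6, 8, 0, 2, 3), 3, 2),
                               k_c = matrix(0, 3, 2)) {
  if (!is.numeric(tau_f) || length(tau_f) != 1 || tau_f <= 0) {
    stop("`tau_f` must be a single positive number", call. = FALSE)
  }
  k_s <- as.matrix(k_s)
  k_c <- as.matrix(k_c)
  if (!all(dim(k_s) == c(3, 2)) || !all(dim(k_c) == c(3, 2))) {
    stop("`k_s` and `k_c` must be 3x2 (rows x joints)", call. = FALSE)
  }
  for (km in list(k_s, k_c)) {
    if (any(diff(km[, 1]) < -1e-12) || any(diff(km[, 2]) < -1e-12)) {
      stop("row magnitudes must satisfy k1 <= k2 <= k3 componentwise",
           call. = FALSE)
    }
  }
  structure(list(tau_f = tau_f, k_s = unname(k_s), k_c = unname(k_c)),
            class = "biofeedback_params")
}

#' Sense torso tilt
#'
#' The device-sensed tilt signal: torso inclination (small-angle components
#' `ankle + hip` per plane, degrees), its rate, the tilt azimuth (degrees
#' clockwise from the navel; 0 by convention at zero inclination) and the
#' displayed feedback magnitude, inclination plus half its rate of change.
#'
#' @param state a [plant_state()] or 8-vector
#' @return named vector `c(phi, phidot, azimuth, magnitude)` (deg, deg/s,
#'   deg, deg)
#' @export
sense_tilt <- function(state) {
  .cpp_sense_tilt(.as_state8(state))
}

#' Select the active tactor column and row
#'
#' Nearest-neighbour column selection with stepwise row coding: the display
#' is off (`row = 0`) when the feedback magnitude is inside the dead zone or
#' no columns are configured; otherwise the highest row whose threshold the
#' magnitude reaches lights up in the configured column circularly closest
#' to the tilt azimuth (ties resolve to the lower azimuth).
#'
#' @param tilt output of [sense_tilt()]
#' @param config a [display_config()]
#' @return named vector `c(row, column)`; `column` is the displayed column
#'   azimuth in degrees, `NA` when the display is off
#' @export
select_activation <- function(tilt, config) {
  stopifnot(inherits(config, "display_config"))
  .cpp_select_activation(tilt[["magnitude"]], tilt[["azimuth"]],
                         config$columns_deg, config$n_rows,
                         config$dead_zone_deg, config$thresholds_deg)
}

#' Steady-state biofeedback torque targets
#'
#' Row- and direction-dependent torque targets: the displayed column azimuth
#' is decomposed into cardinal components, `K_F^S = k_r cos(theta)` and
#' `K_F^C = k_r sin(theta)` per joint. Row 0 (display off) yields zero
#' targets. Positive values are corrective: a positive sagittal target
#' opposes forward tilt.
#'
#' @param activation output of [select_activation()]
#' @param params a [biofeedback_params()]
#' @return list with `K_s` and `K_c`, each `c(ankle, hip)` in N m (device
#'   sign convention: positive = corrective)
#' @export
target_torque <- function(activation, params) {
  stopifnot(inherits(params, "biofeedback_params"))
  r <- as.integer(activation[["row"]])
  if (is.na(r) || r < 0 || r > 3) stop("row must be in 0..3", call. = FALSE)
  if (r == 0) {
    return(list(K_s = c(0, 0), K_c = c(0, 0)))
  }
  cs <- .azimuth_cos_sin(activation[["column"]])
  list(K_s = params$k_s[r, ] * cs[1], K_c = params$k_c[r, ] * cs[2])
}

#' Advance the biofeedback torque lag one step
#'
#' The biofeedback torque relaxes toward its target with first-order
#' dynamics, `tau_f dT_F/dt + T_F = K_F`. The step uses the exact
#' exponential solution over `dt`, so constant targets reproduce the
#' closed-form step response to machine precision.
#'
#' @param tf current torque list with `T_s`, `T_c` (each `c(ankle, hip)`)
#' @param targets list with `K_s`, `K_c` from [target_torque()]
#' @param tau_f time constant (s, > 0)
#' @param dt step (s, > 0)
#' @return updated torque list
#' @export
advance_feedback_torque <- function(tf, targets, tau_f, dt) {
  stopifnot(tau_f > 0, dt > 0)
  e <- exp(-dt / tau_f)
  list(T_s = targets$K_s + (tf$T_s - targets$K_s) * e,
       T_c = targets$K_c + (tf$T_c - targets$K_c) * e)
}
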