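#' Discrete support-surface perturbation specification
#'
#' A translational platform perturbation with a trapezoidal velocity profile:
#' constant acceleration, constant velocity, constant deceleration. Defaults
#' follow the experimental paradigm the model was built for: 100/200/100 ms
#' phases and 60 mm displacement (midpoint of the 50-70 mm range used across
#' subjects).
#'
#' @param direction_deg azimuth of platform motion, degrees clockwise from
#'   forward (the navel direction) viewed from above; in `[0, 360)`.
#'   180 degrees moves the platform backward (a sagittal perturbation),
#'   90 degrees moves it rightward (coronal).
#' @param displacement_m total platform travel (m, >= 0)
#' @param t_accel,t_const,t_decel phase durations (s, > 0)
#' @param onset_s perturbation onset time (s, >= 0)
#' @return an object of class `perturbation_spec`
#' @export
perturbation_spec <- function(direction_deg = 180, displacement_m = 0.060,
                              t_accel = 0.100, t_const = 0.200,
                              t_decel = 0.100, onset_s = 0.5) {
  if (displacement_m < 0) stop("`displacement_m` must be >= 0", call. = FALSE)
  if (any(c(t_accel, t_const, t_decel) <= 0)) {
    stop("phase durations must be positive", call. = FALSE)
  }
  if (onset_s < 0) stop("`onset_s` must be >= 0", call. = FALSE)
  direction_deg <- direction_deg %% 360
  structure(list(direction_deg = direction_deg,
                 displacement_m = displacement_m,
                 t_accel = t_accel, t_const = t_const, t_decel = t_decel,
                 onset_s = onset_s),
            class = "perturbation_spec")
}

# piecewise-constant platform acceleration magnitude at arbitrary times,
# relative to onset; returns the scalar acceleration along the motion axis
.trapezoid_accel_scalar <- function(t_rel, spec) {
  a <- spec$displacement_m /
    (spec$t_accel * (spec$t_accel / 2 + spec$t_const + spec$t_decel / 2))
  t1 <- spec$t_accel
  t2 <- t1 + spec$t_const
  t3 <- t2 + spec$t_decel
  out <- numeric(length(t_rel))
  out[t_rel >= 0 & t_rel < t1] <- a
  d <- a * spec$t_accel / spec$t_decel
  out[t_rel >= t2 & t_rel < t3] <- -d
  out
}

#' Trapezoidal platform motion profile
#'
#' Samples platform position, velocity and acceleration on a uniform grid for
#' a [perturbation_spec()]. The velocity profile is a trapezoid: constant
#' acceleration `+a` for `t_accel`, zero for `t_const`, constant deceleration
#' for `t_decel`; the integrated displacement equals the specified travel and
#' the platform ends at rest. Axes: `x` forward, `y` rightward.
#'
#' Phase boundaries are used exactly (not rounded); position and velocity are
#' evaluated from the closed-form piecewise polynomial, so the profile is
#' exact at every sample regardless of `dt`.
#'
#' @param spec a [perturbation_spec()]
#' @param dt sample interval (s)
#' @param horizon total duration (s); must cover onset + all phases
#' @return an object of class `platform_motion`: a data frame with columns
#'   `t, x, y, vx, vy, ax, ay` and attributes `dt` and `spec`
#' @export
trapezoid_profile <- function(spec, dt = 1e-3, horizon = 4) {
  stopifnot(inherits(spec, "perturbation_spec"))
  t_total <- spec$t_accel + spec$t_const + spec$t_decel
  if (horizon < spec$onset_s + t_total) {
    stop("`horizon` is shorter than onset + perturbation duration",
         call. = FALSE)
  }
  t <- seq(0, horizon, by = dt)
  tr <- t - spec$onset_s

  a <- spec$displacement_m /
    (spec$t_accel * (spec$t_accel / 2 + spec$t_const + spec$t_decel / 2))
  v_peak <- a * spec$t_accel
  d_dec <- v_peak / spec$t_decel
  t1 <- spec$t_accel
  t2 <- t1 + spec$t_const
  t3 <- t2 + spec$t_decel

  acc <- .trapezoid_accel_scalar(tr, spec)
  vel <- numeric(length(t))
  pos <- numeric(length(t))

  ph1 <- tr >= 0 & tr < t1
  ph2 <- tr >= t1 & tr < t2
  ph3 <- tr >= t2 & tr < t3
  ph4 <- tr >= t3
  vel[ph1] <- a * tr[ph1]
  pos[ph1] <- a * tr[ph1]^2 / 2
  vel[ph2] <- v_peak
  pos[ph2] <- a * t1^2 / 2 + v_peak * (tr[ph2] - t1)
  vel[ph3] <- v_peak - d_dec * (tr[ph3] - t2)
  pos[ph3] <- a * t1^2 / 2 + v_peak * spec$t_const +
    v_peak * (tr[ph3] - t2) - d_dec * (tr[ph3] - t2)^2 / 2
  vel[ph4] <- 0
  pos[ph4] <- spec$displacement_m

  cs <- .azimuth_cos_sin(spec$direction_deg)
  out <- data.frame(t = t,
                    x = pos * cs[1], y = pos * cs[2],
                    vx = vel * cs[1], vy = vel * cs[2],
                    ax = acc * cs[1], ay = acc * cs[2])
  structure(out, dt = dt, spec = spec,
            class = c("platform_motion", "data.frame"))
}

# cos/sin of a clockwise-from-forward azimuth in degrees for the user frame
# (x forward, y rightward); exact at multiples of 90 degrees so that
# single-plane perturbations stay exactly single-plane
.azimuth_cos_sin <- function(deg) {
  as.numeric(.cpp_cos_sin_deg(deg))
}

# platform acceleration (internal frame: y LEFT) at arbitrary times, used to
# build the integrator's stage-aligned acceleration arrays
.platform_accel_internal <- function(spec, times) {
  acc <- .trapezoid_accel_scalar(times - spec$onset_s, spec)
  cs <- .azimuth_cos_sin(spec$direction_deg)
  cbind(acc * cs[1], -acc * cs[2])
}
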