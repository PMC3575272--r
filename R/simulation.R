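#' Closed-loop simulation scenario
#'
#' Bundles everything a run needs: body parameters, controllers, biofeedback
#' parameters and display, the perturbation, and the integration settings.
#'
#' @param subject a [subject_spec()] (used when `body` is not given)
#' @param body a `body_params` object; derived from `subject` by default
#' @param controller a [controller_params()]; stabilising LQR defaults when
#'   omitted
#' @param biofeedback a [biofeedback_params()]
#' @param display a [display_config()]
#' @param perturbation a [perturbation_spec()]
#' @param dt integration step (s); default 1 ms
#' @param horizon total simulated time (s); must cover the perturbation end
#'   plus the 3 s analysis window
#' @param initial_state a [plant_state()]; upright at rest by default
#' @param seed integer seed recorded with the scenario (used only by fixture
#'   noise generation, never by the deterministic simulation itself)
#' @return an object of class `stance_scenario`
#' @export
scenario <- function(subject = subject_spec(), body = NULL, controller = NULL,
                     biofeedback = biofeedback_params(),
                     display = display_config("off"),
                     perturbation = perturbation_spec(),
                     dt = 1e-3, horizon = 4, initial_state = plant_state(),
                     seed = 1L) {
  if (is.null(body)) body <- derive_body_params(subject)
  validate_body_params(body)
  if (is.null(controller)) controller <- default_controller(body)
  stopifnot(inherits(controller, "controller_params"),
            inherits(biofeedback, "biofeedback_params"),
            inherits(display, "display_config"),
            inherits(perturbation, "perturbation_spec"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  pert_end <- perturbation$onset_s + perturbation$t_accel +
    perturbation$t_const + perturbation$t_decel
  if (horizon < pert_end + 3) {
    stop("`horizon` must cover the perturbation end plus 3 s", call. = FALSE)
  }
  structure(list(subject = subject, body = body, controller = controller,
                 biofeedback = biofeedback, display = display,
                 perturbation = perturbation, dt = dt, horizon = horizon,
                 initial_state = initial_state, seed = as.integer(seed)),
            class = "stance_scenario")
}

#' Simulate a closed-loop stance trial
#'
#' Fixed-step RK4 integration of the two-link plant with the delayed
#' postural controllers, the tactor display, and the first-order biofeedback
#' torque lag, all on one shared grid. Per step: the delayed state is read
#' and the controller torque formed; the current torso tilt drives the
#' display activation and the torque targets; the biofeedback lag is
#' advanced by its exact exponential solution; the summed torques drive the
#' plant. The feedback delay is rounded to the nearest integer number of
#' steps.
#'
#' @param scn a [scenario()]
#' @return an object of class `stance_trajectory`: a data frame (one row per
#'   grid point) with time `t` (s); torso sway `sway_ap`, `sway_ml` (deg,
#'   forward/rightward positive); joint angles (deg); COP relative to the
#'   ankle `cop_x`, `cop_y` (cm); controller (`tpc_*`), biofeedback
#'   (`tf_*`) and total (`tj_*`) generalized torques (N m, suffixes
#'   `ankle_s`, `hip_s`, `ankle_c`, `hip_c`); platform kinematics `plat_*`
#'   (m, m/s, m/s^2, user frame); display state `disp_row`, `disp_col`.
#'   Attributes: `dt`, `scenario`. Torque channels satisfy
#'   `tj = tpc + tf` exactly at every sample; biofeedback torques are
#'   reported in the generalized (joint) sign convention, so a corrective
#'   torque during forward sway is negative.
#' @export
simulate_stance <- function(scn) {
  stopifnot(inherits(scn, "stance_scenario"))
  dt <- scn$dt
  n <- round(scn$horizon / dt)
  tgrid <- seq(0, by = dt, length.out = n + 1)

  acc_grid <- .platform_accel_internal(scn$perturbation, tgrid)
  acc_half <- .platform_accel_internal(scn$perturbation, tgrid[-(n + 1)] + dt / 2)

  td_steps <- as.integer(round(scn$controller$t_d / dt))
  disp <- scn$display
  fb_on <- length(disp$columns_deg) > 0

  res <- .cpp_simulate(.as_state8(scn$initial_state), .pack_params(scn$body),
                       dt, n, acc_grid, acc_half,
                       scn$controller$K_s, scn$controller$K_c, td_steps,
                       fb_on, scn$biofeedback$tau_f,
                       scn$biofeedback$k_s, scn$biofeedback$k_c,
                       disp$columns_deg, disp$n_rows, disp$dead_zone_deg,
                       disp$thresholds_deg, pi / 2)
  if (res$fell_at >= 0) {
    stop(sprintf("fall detected at t = %.3f s (joint angle beyond pi/2)",
                 res$fell_at * dt), call. = FALSE)
  }

  st <- res$states
  r2d <- 180 / pi
  prof <- trapezoid_profile(scn$perturbation, dt = dt, horizon = scn$horizon)
  tpc <- res$tpc
  tf <- res$tf
  out <- data.frame(
    t = tgrid,
    sway_ap = (st[, 1] + st[, 2]) * r2d,
    sway_ml = (st[, 3] + st[, 4]) * r2d,
    ankle_s = st[, 1] * r2d, hip_s = st[, 2] * r2d,
    ankle_c = st[, 3] * r2d, hip_c = st[, 4] * r2d,
    d_ankle_s = st[, 5] * r2d, d_hip_s = st[, 6] * r2d,
    d_ankle_c = st[, 7] * r2d, d_hip_c = st[, 8] * r2d,
    cop_x = res$cop[, 1] * 100, cop_y = -res$cop[, 2] * 100,
    tpc_ankle_s = tpc[, 1], tpc_hip_s = tpc[, 2],
    tpc_ankle_c = tpc[, 3], tpc_hip_c = tpc[, 4],
    tf_ankle_s = tf[, 1], tf_hip_s = tf[, 2],
    tf_ankle_c = tf[, 3], tf_hip_c = tf[, 4],
    tj_ankle_s = tpc[, 1] + tf[, 1], tj_hip_s = tpc[, 2] + tf[, 2],
    tj_ankle_c = tpc[, 3] + tf[, 3], tj_hip_c = tpc[, 4] + tf[, 4],
    plat_x = prof$x, plat_y = prof$y, plat_vx = prof$vx, plat_vy = prof$vy,
    plat_ax = prof$ax, plat_ay = prof$ay,
    disp_row = res$row, disp_col = res$column
  )
  structure(out, dt = dt, scenario = scn,
            class = c("stance_trajectory", "data.frame"))
}

#' Resample a trajectory to the experimental rate
#'
#' Decimates a simulated trajectory to a lower uniform rate (default the
#' 100 Hz experimental acquisition rate). When the simulation rate is an
#' integer multiple of the target every k-th sample is kept unchanged;
#' otherwise channels are linearly interpolated onto the target grid.
#'
#' @param traj a `stance_trajectory`
#' @param rate_hz target rate (Hz); must not exceed the simulation rate
#' @return a `stance_trajectory` on the coarser grid
#' @export
resample_to_experiment <- function(traj, rate_hz = 100) {
  dt <- attr(traj, "dt")
  if (rate_hz > 1 / dt + 1e-9) {
    stop("target rate exceeds the simulation rate", call. = FALSE)
  }
  dt_out <- 1 / rate_hz
  k <- dt_out / dt
  if (abs(k - round(k)) < 1e-9) {
    idx <- seq(1, nrow(traj), by = round(k))
    out <- traj[idx, , drop = FALSE]
    rownames(out) <- NULL
  } else {
    t_new <- seq(0, traj$t[nrow(traj)], by = dt_out)
    out <- data.frame(lapply(traj, function(ch) {
      if (is.numeric(ch)) stats::approx(traj$t, ch, xout = t_new)$y else ch[1]
    }))
    out$t <- t_new
  }
  structure(out, dt = dt_out, scenario = attr(traj, "scenario"),
            class = c("stance_trajectory", "data.frame"))
}

#' @export
print.stance_scenario <- function(x, ...) {
  cat("Stance scenario\n")
  cat(sprintf("  subject: %.2f m, %.0f kg | display: %s | perturbation: %g deg, %g mm\n",
              x$subject$height_m, x$subject$mass_kg, x$display$preset,
              x$perturbation$direction_deg, 1000 * x$perturbation$displacement_m))
  cat(sprintf("  dt = %g s, horizon = %g s, delay = %g s, tau_F = %g s\n",
              x$dt, x$horizon, x$controller$t_d, x$biofeedback$tau_f))
  invisible(x)
}
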