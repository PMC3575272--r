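#' Synthetic reference-trajectory specification
#'
#' Defines a synthetic "experimental" reference set: a ground-truth scenario
#' simulated per perturbation direction, decimated to the experimental
#' 100 Hz rate, with optional smooth additive noise. The noise is low-pass
#' filtered Gaussian (2nd-order Butterworth, default 2 Hz cutoff) because
#' the references stand in for across-subject average trajectories, which
#' are smooth; its amplitude is the target sample standard deviation per
#' channel, in the channel's units (deg for sway, cm for COP).
#'
#' @param truth ground-truth [scenario()]
#' @param directions perturbation directions to generate (deg)
#' @param noise_sd named noise amplitudes for `sway_ap`, `sway_ml`,
#'   `cop_x`, `cop_y` (0 = noiseless)
#' @param cutoff_hz noise low-pass cutoff (Hz)
#' @param rate_hz output rate (Hz)
#' @param seed RNG seed for the noise
#' @return an object of class `fixture_spec`
#' @export
fixture_spec <- function(truth, directions = c(90, 180, 225),
                         noise_sd = c(sway_ap = 0, sway_ml = 0,
                                      cop_x = 0, cop_y = 0),
                         cutoff_hz = 2, rate_hz = 100, seed = 1L) {
  stopifnot(inherits(truth, "stance_scenario"), all(noise_sd >= 0))
  structure(list(truth = truth, directions = directions,
                 noise_sd = noise_sd, cutoff_hz = cutoff_hz,
                 rate_hz = rate_hz, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate synthetic reference trajectories
#'
#' Simulates the ground-truth scenario for every requested direction,
#' resamples to the experimental rate, and adds the specified smooth noise.
#' Ground truth is carried in the result so parameter-recovery experiments
#' can compare against it. With the same seed the output is reproducible
#' bit for bit.
#'
#' @param spec a [fixture_spec()]
#' @return named list (by direction) of reference data frames
#'   (`t`, `sway_ap`, `sway_ml`, `cop_x`, `cop_y`), with attributes `truth`
#'   (the scenario) and `clean` (the noiseless references)
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  channels <- c("sway_ap", "sway_ml", "cop_x", "cop_y")
  clean <- list()
  noisy <- list()
  for (dir in spec$directions) {
    scn <- spec$truth
    scn$perturbation$direction_deg <- dir
    sim <- resample_to_experiment(simulate_stance(scn), spec$rate_hz)
    ref <- sim[, c("t", channels)]
    rownames(ref) <- NULL
    clean[[as.character(dir)]] <- ref
    for (ch in channels) {
      sd_target <- spec$noise_sd[[ch]]
      if (!is.null(sd_target) && sd_target > 0) {
        ref[[ch]] <- ref[[ch]] +
          .smooth_noise(nrow(ref), spec$rate_hz, spec$cutoff_hz, sd_target)
      }
    }
    noisy[[as.character(dir)]] <- ref
  }
  structure(noisy, truth = spec$truth, clean = clean)
}

# low-pass filtered Gaussian noise rescaled to the target sample sd
.smooth_noise <- function(n, rate_hz, cutoff_hz, sd_target) {
  bf <- signal::butter(2, min(2 * cutoff_hz / rate_hz, 0.99))
  w <- stats::rnorm(n + 200)
  x <- signal::filtfilt(bf, w)[201:(n + 200)]
  x * sd_target / stats::sd(x)
}

#' Default study fixture
#'
#' The shipped demonstration ground truth, chosen to be qualitatively
#' plausible for the modelled paradigm: the study-mean subject (1.78 m,
#' 86 kg); stabilising LQR postural gains with 0.1 s delay yielding peak
#' ankle torques of tens of N m for the default 60 mm perturbation; a
#' 3x4 display; biofeedback magnitudes with zero coronal components and a
#' zero row-1 hip component (ankle-only response to the lowest row), peak
#' additional ankle torque of order 8 N m and hip torque of order 3 N m;
#' reaction time constant 0.3 s. These are illustrative values, not fitted
#' reproductions of any experiment.
#'
#' @param display display preset for the truth scenario
#' @param noise_sd passed to [fixture_spec()]
#' @param seed RNG seed
#' @return a [fixture_spec()]
#' @export
default_study_fixture <- function(display = "3x4",
                                  noise_sd = c(sway_ap = 0, sway_ml = 0,
                                               cop_x = 0, cop_y = 0),
                                  seed = 1L) {
  truth <- scenario(display = display_config(display),
                    biofeedback = biofeedback_params(
                      tau_f = 0.3,
                      k_s = matrix(c(4, 6, 8, 0, 2, 3), 3, 2),
                      k_c = matrix(0, 3, 2)))
  fixture_spec(truth, noise_sd = noise_sd, seed = seed)
}
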