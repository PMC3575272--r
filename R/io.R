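#' Load a scenario from a YAML configuration file
#'
#' The configuration has sections `subject`, `body` (optional overrides,
#' including an anthropometric `fractions` table), `controller`,
#' `biofeedback`, `display`, `perturbation` and `simulation`; every section
#' and key is optional, with the package defaults filling the gaps. Unknown
#' keys are rejected with their location. All scenario invariants
#' (k-ordering, positive time constants, horizon coverage) are re-validated
#' on load.
#'
#' @param path YAML file
#' @return a [scenario()]
#' @export
load_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  .check_keys(cfg, c("subject", "body", "controller", "biofeedback",
                     "display", "perturbation", "simulation"), "top level")

  subj <- cfg$subject
  .check_keys(subj, c("height_m", "mass_kg"), "subject")
  subject <- subject_spec(height_m = subj$height_m %||% 1.78,
                          mass_kg = subj$mass_kg %||% 86)

  body <- NULL
  if (!is.null(cfg$body)) {
    .check_keys(cfg$body, c("fractions", "ankle_offset_m"), "body")
    fr <- default_fraction_table()
    if (!is.null(cfg$body$fractions)) {
      .check_keys(cfg$body$fractions, c("legs", "torso"), "body.fractions")
      for (lk in names(cfg$body$fractions)) {
        .check_keys(cfg$body$fractions[[lk]],
                    c("mass_fraction", "length_fraction", "com_fraction",
                      "shape", "shape_dims"), paste0("body.fractions.", lk))
        fr[[lk]] <- utils::modifyList(fr[[lk]], cfg$body$fractions[[lk]])
        fr[[lk]]$shape_dims <- unlist(fr[[lk]]$shape_dims)
      }
    }
    body <- derive_body_params(subject, fr,
                               ankle_offset_m = cfg$body$ankle_offset_m %||% 0)
  }

  ctrl <- NULL
  if (!is.null(cfg$controller)) {
    .check_keys(cfg$controller, c("K_s", "K_c", "t_d"), "controller")
    if (is.null(body)) body <- derive_body_params(subject)
    base <- default_controller(body, t_d = cfg$controller$t_d %||% 0.1)
    Ks <- if (is.null(cfg$controller$K_s)) base$K_s else
      matrix(unlist(cfg$controller$K_s), 2, 4, byrow = TRUE)
    Kc <- if (is.null(cfg$controller$K_c)) base$K_c else
      matrix(unlist(cfg$controller$K_c), 2, 4, byrow = TRUE)
    ctrl <- controller_params(Ks, Kc, t_d = cfg$controller$t_d %||% 0.1)
  }

  bf <- cfg$biofeedback
  .check_keys(bf, c("tau_f", "k_s", "k_c"), "biofeedback")
  biofeedback <- biofeedback_params(
    tau_f = bf$tau_f %||% 0.3,
    k_s = if (is.null(bf$k_s)) matrix(c(4, 6, 8, 0, 2, 3), 3, 2) else
      matrix(unlist(bf$k_s), 3, 2, byrow = TRUE),
    k_c = if (is.null(bf$k_c)) matrix(0, 3, 2) else
      matrix(unlist(bf$k_c), 3, 2, byrow = TRUE))

  dc <- cfg$display
  .check_keys(dc, c("preset", "columns_deg", "n_rows", "dead_zone_deg",
                    "thresholds_deg"), "display")
  display <- if (is.null(dc) || !is.null(dc$preset)) {
    display_config(preset = dc$preset %||% "off")
  } else {
    display_config(columns_deg = unlist(dc$columns_deg),
                   n_rows = dc$n_rows %||% 3,
                   dead_zone_deg = dc$dead_zone_deg %||% 1,
                   thresholds_deg = if (is.null(dc$thresholds_deg)) NULL else
                     unlist(dc$thresholds_deg))
  }

  pt <- cfg$perturbation
  .check_keys(pt, c("direction_deg", "displacement_m", "t_accel", "t_const",
                    "t_decel", "onset_s"), "perturbation")
  perturbation <- perturbation_spec(
    direction_deg = pt$direction_deg %||% 180,
    displacement_m = pt$displacement_m %||% 0.060,
    t_accel = pt$t_accel %||% 0.100, t_const = pt$t_const %||% 0.200,
    t_decel = pt$t_decel %||% 0.100, onset_s = pt$onset_s %||% 0.5)

  sm <- cfg$simulation
  .check_keys(sm, c("dt", "horizon", "seed"), "simulation")
  scenario(subject = subject, body = body, controller = ctrl,
           biofeedback = biofeedback, display = display,
           perturbation = perturbation,
           dt = sm$dt %||% 1e-3, horizon = sm$horizon %||% 4,
           seed = sm$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible())
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible()
}

#' Serialise a scenario to a YAML configuration
#'
#' Writes the explicit, fully expanded configuration so that
#' `load_scenario(write_scenario(x))` reproduces the scenario.
#'
#' @param scn a [scenario()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "stance_scenario"))
  cfg <- list(
    subject = list(height_m = scn$subject$height_m,
                   mass_kg = scn$subject$mass_kg),
    controller = list(K_s = apply(scn$controller$K_s, 1, as.list,
                                  simplify = FALSE),
                      K_c = apply(scn$controller$K_c, 1, as.list,
                                  simplify = FALSE),
                      t_d = scn$controller$t_d),
    biofeedback = list(tau_f = scn$biofeedback$tau_f,
                       k_s = apply(scn$biofeedback$k_s, 1, as.list,
                                   simplify = FALSE),
                       k_c = apply(scn$biofeedback$k_c, 1, as.list,
                                   simplify = FALSE)),
    display = if (scn$display$preset != "custom") {
      list(preset = scn$display$preset)
    } else {
      list(columns_deg = as.list(scn$display$columns_deg),
           n_rows = scn$display$n_rows,
           dead_zone_deg = scn$display$dead_zone_deg,
           thresholds_deg = as.list(scn$display$thresholds_deg))
    },
    perturbation = scn$perturbation[c("direction_deg", "displacement_m",
                                      "t_accel", "t_const", "t_decel",
                                      "onset_s")],
    simulation = list(dt = scn$dt, horizon = scn$horizon, seed = scn$seed)
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' Comma-separated, one header row naming every channel; floats are written
#' with 17 significant digits so that [read_trajectory()] is the exact
#' inverse.
#'
#' @param traj a `stance_trajectory` (or compatible data frame)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  cols <- lapply(df, function(x) {
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path CSV written by [write_trajectory()] (or the same dialect)
#' @param require_channels channel names that must be present
#' @return data frame of class `stance_trajectory`
#' @export
read_trajectory <- function(path,
                            require_channels = c("t", "sway_ap", "sway_ml",
                                                 "cop_x", "cop_y")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  # columns that happen to hold only whole numbers parse as integer;
  # trajectories are double channels throughout
  df[] <- lapply(df, function(x) if (is.integer(x)) as.double(x) else x)
  missing <- setdiff(require_channels, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dt <- if (nrow(df) > 1) df$t[2] - df$t[1] else NA_real_
  structure(df, dt = dt, class = c("stance_trajectory", "data.frame"))
}
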