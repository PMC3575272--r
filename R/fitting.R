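#' Named free parameters of a fit
#'
#' Fits address scalar parameters of a scenario by name: controller gains
#' `Ks11..Ks24` and `Kc11..Kc24` (row 1 = ankle, row 2 = hip; columns =
#' ankle angle, hip angle, ankle rate, hip rate), the biofeedback time
#' constant `tauF`, and the biofeedback magnitudes `kS<r><j>` / `kC<r><j>`
#' with row `r` in 1..3 and joint `j` in `a` (ankle) or `h` (hip), e.g.
#' `kS2a`.
#'
#' @return character vector of all addressable parameter names
#' @export
fit_parameter_names <- function() {
  gains <- c(outer(1:2, 1:4, function(i, j) paste0("Ks", i, j)),
             outer(1:2, 1:4, function(i, j) paste0("Kc", i, j)))
  ks <- c(outer(1:3, c("a", "h"), function(r, j) paste0("kS", r, j)),
          outer(1:3, c("a", "h"), function(r, j) paste0("kC", r, j)))
  c(gains, "tauF", ks)
}

# inject named parameter values into a scenario; biofeedback row magnitudes
# are repaired to satisfy the k1 <= k2 <= k3 ordering by a running maximum
# (the constraint projection used by the search)
.apply_fit_params <- function(scn, values) {
  nm <- names(values)
  bad <- setdiff(nm, fit_parameter_names())
  if (length(bad)) stop("unknown fit parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  Ks <- scn$controller$K_s
  Kc <- scn$controller$K_c
  kS <- scn$biofeedback$k_s
  kC <- scn$biofeedback$k_c
  tauF <- scn$biofeedback$tau_f
  for (k in seq_along(values)) {
    n <- nm[k]
    v <- values[[k]]
    if (grepl("^Ks[12][1-4]$", n)) {
      Ks[as.integer(substr(n, 3, 3)), as.integer(substr(n, 4, 4))] <- v
    } else if (grepl("^Kc[12][1-4]$", n)) {
      Kc[as.integer(substr(n, 3, 3)), as.integer(substr(n, 4, 4))] <- v
    } else if (n == "tauF") {
      tauF <- max(v, 1e-3)
    } else if (grepl("^kS[123][ah]$", n)) {
      kS[as.integer(substr(n, 3, 3)), if (substr(n, 4, 4) == "a") 1 else 2] <- v
    } else if (grepl("^kC[123][ah]$", n)) {
      kC[as.integer(substr(n, 3, 3)), if (substr(n, 4, 4) == "a") 1 else 2] <- v
    }
  }
  kS <- apply(kS, 2, cummax)
  kC <- apply(kC, 2, cummax)
  scn$controller <- controller_params(Ks, Kc, t_d = scn$controller$t_d)
  scn$biofeedback <- biofeedback_params(tauF, kS, kC)
  scn
}

#' Define a trajectory-fitting problem
#'
#' Couples reference trajectories (one per perturbation direction) with a
#' scenario template and a set of free parameters. The objective follows the
#' printed form of the fitting criterion: the time integral over the fit
#' window of the square of the SUM of the per-channel normalised residuals
#' (cross terms included); `form = "sum_of_squares"` switches to the more
#' conventional per-channel sum of squared residuals.
#'
#' Channels: AP and ML sway plus COP x and y. Per direction, sway channels
#' to which the model responds unidirectionally are excluded (AP sway for
#' 90 degree perturbations, ML sway for 180 degrees), and any channel whose
#' reference peak is zero is dropped (its normaliser would vanish).
#' Normalisation uses the peak absolute reference value on the fit window.
#'
#' @param refs named list of reference trajectories; names are perturbation
#'   directions in degrees (`"90"`, `"180"`, `"225"`); each element a data
#'   frame with columns `t`, `sway_ap`, `sway_ml`, `cop_x`, `cop_y` on a
#'   uniform 100 Hz grid
#' @param template a [scenario()] supplying everything except the free
#'   parameters (its perturbation direction is overridden per reference)
#' @param free character vector of free parameter names
#'   (see [fit_parameter_names()])
#' @param lower,upper named bound vectors for the free parameters
#' @param window_s fit window after perturbation onset (s)
#' @param form objective form (see above)
#' @return an object of class `fit_problem`
#' @export
fit_problem <- function(refs, template, free, lower = NULL, upper = NULL,
                        window_s = 3,
                        form = c("squared_sum", "sum_of_squares")) {
  form <- match.arg(form)
  stopifnot(inherits(template, "stance_scenario"), length(free) >= 1)
  bad <- setdiff(free, fit_parameter_names())
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  onset <- template$perturbation$onset_s
  dirs <- as.numeric(names(refs))
  if (any(is.na(dirs))) stop("`refs` must be named by direction", call. = FALSE)

  channels <- c("sway_ap", "sway_ml", "cop_x", "cop_y")
  prep <- lapply(seq_along(refs), function(i) {
    ref <- refs[[i]]
    dir <- dirs[i]
    win <- ref$t >= onset - 1e-9 & ref$t <= onset + window_s + 1e-9
    incl <- channels
    if (dir == 90) incl <- setdiff(incl, "sway_ap")
    if (dir == 180) incl <- setdiff(incl, "sway_ml")
    peaks <- vapply(incl, function(ch) max(abs(ref[[ch]][win])), numeric(1))
    incl <- incl[peaks > 0]
    peaks <- peaks[peaks > 0]
    if (!length(incl)) stop("no usable channels for direction ", dir,
                            call. = FALSE)
    # platform acceleration arrays are identical for every candidate, so
    # they are precomputed once per direction
    scn_d <- template
    scn_d$perturbation$direction_deg <- dir
    n <- round(scn_d$horizon / scn_d$dt)
    tgrid <- seq(0, by = scn_d$dt, length.out = n + 1)
    list(direction = dir, ref = ref[win, c("t", channels)],
         include = incl, peaks = peaks,
         acc_grid = .platform_accel_internal(scn_d$perturbation, tgrid),
         acc_half = .platform_accel_internal(scn_d$perturbation,
                                             tgrid[-(n + 1)] + scn_d$dt / 2),
         n_steps = n)
  })
  structure(list(refs = prep, template = template, free = free,
                 lower = lower, upper = upper, window_s = window_s,
                 onset = onset, form = form),
            class = "fit_problem")
}

#' Fit objective
#'
#' Simulates the scenario under the candidate parameters for every reference
#' direction and evaluates the windowed, normalised residual functional
#' (trapezoidal quadrature on the 100 Hz grid). Simulation failures (falls)
#' return a large penalty rather than raising.
#'
#' @param problem a [fit_problem()]
#' @param values named numeric vector of candidate values for
#'   `problem$free`
#' @return the scalar objective `J` (>= 0, units s)
#' @export
fit_objective <- function(problem, values) {
  stopifnot(inherits(problem, "fit_problem"))
  values <- stats::setNames(as.numeric(values), names(values))
  if (is.null(names(values))) names(values) <- problem$free
  J <- 0
  for (pr in problem$refs) {
    scn <- problem$template
    scn$perturbation$direction_deg <- pr$direction
    scn <- tryCatch(.apply_fit_params(scn, values),
                    error = function(e) NULL)
    if (is.null(scn)) return(1e6)
    simw <- .simulate_fit_channels(scn, pr, problem$onset, problem$window_s)
    if (is.null(simw)) return(1e6)
    if (length(simw$t) != nrow(pr$ref)) return(1e6)
    res <- vapply(seq_along(pr$include), function(k) {
      ch <- pr$include[k]
      (pr$ref[[ch]] - simw[[ch]]) / pr$peaks[k]
    }, numeric(nrow(pr$ref)))
    integrand <- if (problem$form == "squared_sum") {
      rowSums(res)^2
    } else {
      rowSums(res^2)
    }
    dt <- pr$ref$t[2] - pr$ref$t[1]
    n <- length(integrand)
    J <- J + dt * (sum(integrand) - (integrand[1] + integrand[n]) / 2)
  }
  J
}

# lean simulation path for the fit loop: runs the compiled core with the
# cached platform arrays, decimates to the reference grid by index, and
# returns only the fitted channels; NULL on a fall
.simulate_fit_channels <- function(scn, pr, onset, window_s) {
  dt <- scn$dt
  stride <- 0.01 / dt
  if (abs(stride - round(stride)) > 1e-9) {
    # fall back to the general path when dt does not divide the 100 Hz grid
    sim <- tryCatch(resample_to_experiment(simulate_stance(scn), 100),
                    error = function(e) NULL)
    if (is.null(sim)) return(NULL)
    win <- sim$t >= onset - 1e-9 & sim$t <= onset + window_s + 1e-9
    return(as.list(sim[win, c("t", "sway_ap", "sway_ml", "cop_x", "cop_y")]))
  }
  disp <- scn$display
  fb_on <- length(disp$columns_deg) > 0
  td_steps <- as.integer(round(scn$controller$t_d / dt))
  res <- .cpp_simulate(.as_state8(scn$initial_state), .pack_params(scn$body),
                       dt, pr$n_steps, pr$acc_grid, pr$acc_half,
                       scn$controller$K_s, scn$controller$K_c, td_steps,
                       fb_on, scn$biofeedback$tau_f,
                       scn$biofeedback$k_s, scn$biofeedback$k_c,
                       disp$columns_deg, disp$n_rows, disp$dead_zone_deg,
                       disp$thresholds_deg, pi / 2, round(stride))
  if (res$fell_at >= 0) return(NULL)
  t_all <- seq(0, by = dt, length.out = pr$n_steps + 1)
  idx <- seq(1, pr$n_steps + 1, by = round(stride))
  keep <- t_all[idx] >= onset - 1e-9 & t_all[idx] <= onset + window_s + 1e-9
  idx <- idx[keep]
  r2d <- 180 / pi
  list(t = t_all[idx],
       sway_ap = (res$states[idx, 1] + res$states[idx, 2]) * r2d,
       sway_ml = (res$states[idx, 3] + res$states[idx, 4]) * r2d,
       cop_x = res$cop[idx, 1] * 100,
       cop_y = -res$cop[idx, 2] * 100)
}

#' Exhaustive grid sweep of the fit objective
#'
#' Evaluates the objective on the full Cartesian grid and returns the best
#' point (first encountered on ties). This is the first stage of the
#' two-stage fitting procedure; its winner seeds the perpendicular search.
#'
#' @param problem a [fit_problem()]
#' @param grid named list: one vector of levels per free parameter
#' @param objective objective function `(problem, values) -> J`; the
#'   packaged [fit_objective()] by default
#' @return list with `best` (named vector), `J` and the full evaluation
#'   `table`
#' @export
parameter_sweep <- function(problem, grid, objective = fit_objective) {
  if (!length(grid) || any(lengths(grid) == 0)) {
    stop("sweep grid is empty", call. = FALSE)
  }
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  Js <- vapply(seq_len(nrow(pts)), function(i) {
    objective(problem, stats::setNames(as.numeric(pts[i, ]), names(pts)))
  }, numeric(1))
  best <- which.min(Js) # ties: first encountered
  list(best = stats::setNames(as.numeric(pts[best, ]), names(pts)),
       J = Js[best],
       table = cbind(pts, J = Js))
}

#' Perpendicular (rotating-direction) search
#'
#' Derivative-free search over a set of mutually perpendicular probe
#' directions, initially the parameter axes. Each direction is probed at
#' its current signed step: a success is accepted and grows the step
#' (factor 3); a failure reverses and halves it. Once every direction has
#' both succeeded and subsequently failed, the direction set is
#' re-orthogonalized around the accumulated progress vector (Rosenbrock
#' rotation), so the leading direction tracks the valley floor -- this is
#' what lets the search follow the long curved valleys that axis-aligned
#' probing zigzags across. Terminates when every step falls below
#' `step_tol` relative to its initial size, when the objective falls below
#' `obj_tol`, or after `max_cycles` cycles. Bound constraints are enforced
#' by clipping; the biofeedback row-ordering constraint is enforced by
#' projection inside the parameter injection.
#'
#' @param problem a [fit_problem()]
#' @param start named start vector (e.g. the sweep winner)
#' @param step initial step sizes (named vector, or a single fraction of
#'   `max(|start|, 1)` per parameter; default 0.25)
#' @param step_tol terminal step size (relative to the initial step)
#' @param obj_tol stop when `J` falls below this
#' @param max_cycles cycle budget
#' @param objective objective function `(problem, values) -> J`; the
#'   packaged [fit_objective()] by default
#' @param stall_escape consecutive-failure count after which a direction
#'   that has not succeeded since the last rotation stops blocking the next
#'   rotation; `Inf` (default) requires every direction to make progress
#'   before the set rotates
#' @return an object of class `fit_result`: list with `par`, `J`, `trace`
#'   (data frame of accepted iterates), `evals`, `converged`
#' @export
perpendicular_search <- function(problem, start, step = 0.25,
                                 step_tol = 1e-4, obj_tol = 0,
                                 max_cycles = 200,
                                 objective = fit_objective,
                                 stall_escape = Inf) {
  x <- stats::setNames(as.numeric(start), names(start))
  p <- length(x)
  if (length(step) == 1) {
    step <- stats::setNames(pmax(abs(x), 1) * step, names(x))
  }
  step0 <- step
  clip <- function(v) {
    if (!is.null(problem$lower)) v <- pmax(v, problem$lower[names(v)])
    if (!is.null(problem$upper)) v <- pmin(v, problem$upper[names(v)])
    v
  }
  x <- clip(x)
  J <- objective(problem, x)
  evals <- 1L
  trace <- list(data.frame(cycle = 0L, J = J))
  cycle <- 0L

  D <- diag(p)                  # orthonormal probe directions (columns)
  s <- unname(step)             # signed step along each direction
  lambda <- numeric(p)          # accumulated successful travel per direction
  succ <- logical(p)            # direction has succeeded since last rotation
  fail_after <- logical(p)      # ... and failed after that success
  fail_run <- integer(p)        # consecutive failures since last success
  grow <- 3
  shrink <- -0.5

  while (cycle < max_cycles && J > obj_tol &&
         any(abs(s) / step0 > step_tol)) {
    cycle <- cycle + 1L
    for (i in seq_len(p)) {
      cand <- clip(x + s[i] * D[, i])
      if (all(cand == x)) {
        s[i] <- s[i] * shrink
        next
      }
      Jc <- objective(problem, cand)
      evals <- evals + 1L
      if (Jc < J) {
        x <- cand
        J <- Jc
        lambda[i] <- lambda[i] + s[i]
        succ[i] <- TRUE
        fail_run[i] <- 0L
        s[i] <- s[i] * grow
      } else {
        if (succ[i]) fail_after[i] <- TRUE
        fail_run[i] <- fail_run[i] + 1L
        s[i] <- s[i] * shrink
      }
    }
    # rotate when every direction is exhausted: productive directions have
    # succeeded and then failed; with a finite `stall_escape`, directions
    # that keep failing stop blocking the rotation after that many
    # consecutive failures (useful on piecewise-smooth objectives where
    # some axes are locally dead)
    if (p > 1 && any(succ) &&
        all((succ & fail_after) | (!succ & fail_run >= stall_escape))) {
      # Rosenbrock rotation: re-orthogonalize the probe set around the
      # accumulated progress direction so the first direction tracks the
      # valley floor
      Av <- sapply(seq_len(p), function(i) {
        rowSums(D[, i:p, drop = FALSE] *
                  rep(lambda[i:p], each = p))
      })
      Dn <- matrix(0, p, p)
      for (i in seq_len(p)) {
        v <- Av[, i]
        if (i > 1) {
          v <- v - Dn[, 1:(i - 1), drop = FALSE] %*%
            crossprod(Dn[, 1:(i - 1), drop = FALSE], Av[, i])
        }
        nv <- sqrt(sum(v^2))
        Dn[, i] <- if (nv > 1e-300) v / nv else D[, i]
      }
      travel <- sqrt(sum(lambda^2))
      D <- Dn
      s <- rep(travel / 2, p)
      lambda <- numeric(p)
      succ[] <- FALSE
      fail_after[] <- FALSE
      fail_run[] <- 0L
    }
    trace[[length(trace) + 1L]] <- data.frame(cycle = cycle, J = J)
  }
  structure(list(par = x, J = J, trace = do.call(rbind, trace),
                 evals = evals,
                 converged = (J <= obj_tol) ||
                   all(abs(s) / step0 <= step_tol)),
            class = "fit_result")
}

#' One-at-a-time sensitivity screen
#'
#' Perturbs each free parameter by `delta` about a base point and records
#' the larger absolute objective change of the two probes. Used to shrink
#' the sweep grids when sagittal and coronal controllers must be tuned
#' simultaneously (the 225 degree fits).
#'
#' @param problem a [fit_problem()]
#' @param base named base vector
#' @param delta absolute probe sizes: single number or named vector
#' @param objective objective function `(problem, values) -> J`; the
#'   packaged [fit_objective()] by default
#' @return data frame (`parameter`, `sensitivity`), sorted descending
#' @export
sensitivity_screen <- function(problem, base, delta = NULL,
                               objective = fit_objective) {
  x <- stats::setNames(as.numeric(base), names(base))
  if (is.null(delta)) delta <- pmax(abs(x), 1) * 0.05
  if (length(delta) == 1) delta <- stats::setNames(rep(delta, length(x)), names(x))
  J0 <- objective(problem, x)
  sens <- vapply(seq_along(x), function(i) {
    up <- x; up[i] <- up[i] + delta[[names(x)[i]]]
    dn <- x; dn[i] <- dn[i] - delta[[names(x)[i]]]
    max(abs(objective(problem, up) - J0),
        abs(objective(problem, dn) - J0))
  }, numeric(1))
  out <- data.frame(parameter = names(x), sensitivity = sens)
  out[order(-out$sensitivity), , drop = FALSE]
}

#' Two-stage fit: sweep then perpendicular search
#'
#' The fitting procedure used throughout: an exhaustive coarse sweep whose
#' winner seeds the perpendicular search.
#'
#' @param problem a [fit_problem()]
#' @param grid sweep grid (named list of levels)
#' @param ... passed to [perpendicular_search()]
#' @return a `fit_result` with the sweep stage attached as `sweep`
#' @export
fit_two_stage <- function(problem, grid, ...) {
  sw <- parameter_sweep(problem, grid)
  res <- perpendicular_search(problem, sw$best, ...)
  res$sweep <- sw[c("best", "J")]
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result: J = %.3g after %d evaluations (%s)\n", x$J,
              x$evals, if (x$converged) "converged" else "budget reached"))
  print(round(x$par, 4))
  invisible(x)
}
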