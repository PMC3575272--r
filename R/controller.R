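#' Delayed full-state-feedback controller parameters
#'
#' Two independent postural controllers, one per plane. Each is a 2x4 gain
#' matrix `K` (rows: ankle, hip torque; columns: ankle angle, hip angle,
#' ankle rate, hip rate) applied to the delayed plane state:
#' `T_PC(t) = -K x(t - t_d)`.
#'
#' @param K_s,K_c 2x4 sagittal and coronal gain matrices (N m/rad and
#'   N m s/rad)
#' @param t_d feedback delay (s, >= 0); rounded to an integer number of
#'   integration steps by the simulator. Default 0.1 s, a typical
#'   physiological sensorimotor latency.
#' @return an object of class `controller_params`
#' @export
controller_params <- function(K_s, K_c = K_s, t_d = 0.1) {
  K_s <- as.matrix(K_s)
  K_c <- as.matrix(K_c)
  if (!all(dim(K_s) == c(2, 4)) || !all(dim(K_c) == c(2, 4))) {
    stop("gain matrices must be 2x4", call. = FALSE)
  }
  if (!all(is.finite(K_s)) || !all(is.finite(K_c))) {
    stop("gains must be finite", call. = FALSE)
  }
  if (!is.numeric(t_d) || length(t_d) != 1 || t_d < 0) {
    stop("`t_d` must be a single non-negative number", call. = FALSE)
  }
  structure(list(K_s = unname(K_s), K_c = unname(K_c), t_d = t_d),
            class = "controller_params")
}

#' State history buffer
#'
#' Uniformly sampled plant states on the integration grid, used to evaluate
#' the delayed feedback. Lookups at `t - t_d` round the delay to the nearest
#' grid point; times before the start of the buffer return the initial state
#' (equilibrium padding).
#'
#' @param states matrix with 8 columns, one row per grid point (row 1 = t0)
#' @param dt grid spacing (s)
#' @param t0 time of the first sample (s)
#' @return an object of class `state_history`
#' @export
state_history <- function(states, dt, t0 = 0) {
  states <- as.matrix(states)
  if (ncol(states) != 8) stop("states must have 8 columns", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  structure(list(states = states, dt = dt, t0 = t0), class = "state_history")
}

#' Look up a (possibly delayed) state in a history buffer
#'
#' @param history a [state_history()]
#' @param t lookup time (s); rounded to the nearest grid point, clamped to
#'   the buffer start
#' @return the stored 8-state at that grid point
#' @export
history_lookup <- function(history, t) {
  i <- round((t - history$t0) / history$dt) + 1
  if (i > nrow(history$states)) {
    stop("history does not cover the requested time", call. = FALSE)
  }
  history$states[max(i, 1L), ]
}

#' Delayed postural control torque
#'
#' Evaluates `T_PC(t) = -K x(t - t_d)` independently per plane from a state
#' history buffer.
#'
#' @param history a [state_history()] covering `[t - t_d, t]`
#' @param t current time (s)
#' @param params a [controller_params()]
#' @return generalized torque vector `c(ankle_S, hip_S, ankle_C, hip_C)` (N m)
#' @export
control_torque <- function(history, t, params) {
  stopifnot(inherits(history, "state_history"),
            inherits(params, "controller_params"))
  x <- history_lookup(history, t - params$t_d)
  xS <- x[c(1, 2, 5, 6)]
  xC <- x[c(3, 4, 7, 8)]
  c(-params$K_s %*% xS, -params$K_c %*% xC)
}

#' Continuous-time LQR gains for the linearized plant
#'
#' Solves the continuous algebraic Riccati equation by the stable invariant
#' subspace of the Hamiltonian matrix and returns `K = R^-1 B' P`. Used to
#' construct stabilising demonstration gains on the 4-state per-plane
#' linearization; fitted gains replace these.
#'
#' @param A,B per-plane state-space matrices (4x4, 4x2)
#' @param Q,R state and input weight matrices
#' @return the 2x4 gain matrix
#' @export
lqr_gain <- function(A, B, Q, R) {
  n <- nrow(A)
  H <- rbind(cbind(A, -B %*% solve(R, t(B))),
             cbind(-Q, -t(A)))
  ei <- eigen(H)
  sel <- which(Re(ei$values) < 0)
  if (length(sel) != n) stop("Hamiltonian has no full stable subspace", call. = FALSE)
  V <- ei$vectors[, sel, drop = FALSE]
  X1 <- V[1:n, , drop = FALSE]
  X2 <- V[(n + 1):(2 * n), , drop = FALSE]
  P <- Re(X2 %*% solve(X1))
  P <- (P + t(P)) / 2
  solve(R, t(B) %*% P)
}

#' Spectral abscissa of a delayed per-plane closed loop
#'
#' Rightmost characteristic root of one plane of the linearized stance
#' model under delayed full-state feedback,
#' `M qdd + G q = -exp(-s t_d)(Kp q + Kd qd)` in the frequency domain.
#' The infinite-dimensional delay system is discretized by Chebyshev
#' spectral collocation on the delay interval (the standard numerical
#' treatment of such problems); the rightmost eigenvalues of the resulting
#' matrix approximate the rightmost characteristic roots to high accuracy
#' at moderate node counts.
#'
#' @param M,G per-plane 2x2 mass and gravity-stiffness matrices
#'   (see [linearize()])
#' @param K 2x4 gain matrix `(Kp | Kd)`, columns (angle_a, angle_h,
#'   rate_a, rate_h)
#' @param t_d feedback delay (s)
#' @param n_nodes Chebyshev nodes on the delay interval
#' @return the largest real part over the discretized spectrum (positive =
#'   unstable)
#' @export
delayed_spectral_abscissa <- function(M, G, K, t_d, n_nodes = 24) {
  Mi <- solve(M)
  A <- rbind(cbind(matrix(0, 2, 2), diag(2)),
             cbind(-Mi %*% G, matrix(0, 2, 2)))
  Ad <- rbind(matrix(0, 2, 4), -Mi %*% K)
  if (t_d == 0) return(max(Re(eigen(A + Ad, only.values = TRUE)$values)))
  # Chebyshev differentiation matrix on [-1, 1] (Trefethen), mapped to
  # [-t_d, 0]; node 1 is t = 0, node N+1 is t = -t_d
  N <- n_nodes
  x <- cos(pi * (0:N) / N)
  c_ <- c(2, rep(1, N - 1), 2) * (-1)^(0:N)
  X <- matrix(x, N + 1, N + 1)
  dX <- X - t(X)
  D <- (c_ %o% (1 / c_)) / (dX + diag(N + 1))
  D <- D - diag(rowSums(D))
  Dt <- D * (2 / t_d)
  d <- 4
  big <- kronecker(Dt, diag(d))
  big[1:d, ] <- 0
  big[1:d, 1:d] <- A
  big[1:d, (N * d + 1):((N + 1) * d)] <- big[1:d, (N * d + 1):((N + 1) * d)] + Ad
  ev <- eigen(big, only.values = TRUE)$values
  max(Re(ev))
}

# transient quality of one plane under delayed feedback: RK4 on the linear
# delayed system from a small ankle-rate initial condition; penalises both
# the sway excursion and what remains at the end of the window
.plane_transient_score <- function(plane, K, t_d, dt = 2e-3, horizon = 4) {
  Mi <- solve(plane$M)
  A <- rbind(cbind(matrix(0, 2, 2), diag(2)),
             cbind(-Mi %*% plane$G, matrix(0, 2, 2)))
  Ad <- rbind(matrix(0, 2, 4), -Mi %*% K)
  n <- round(horizon / dt)
  nd <- as.integer(round(t_d / dt))
  X <- matrix(0, 4, n + 1)
  X[, 1] <- c(0, 0, 0.2, 0)
  f <- function(x, xd) A %*% x + Ad %*% xd
  for (i in seq_len(n)) {
    xd0 <- X[, max(i - nd, 1)]
    xd1 <- X[, max(i + 1 - nd, 1)]
    xdh <- (xd0 + xd1) / 2
    x <- X[, i]
    k1 <- f(x, xd0)
    k2 <- f(x + dt / 2 * k1, xdh)
    k3 <- f(x + dt / 2 * k2, xdh)
    k4 <- f(x + dt * k3, xd1)
    X[, i + 1] <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(X[, i + 1])) || max(abs(X[1:2, i + 1])) > 10) {
      return(1e5)
    }
  }
  sway <- abs(X[1, ] + X[2, ])
  max(sway) + 10 * max(abs(X[, n + 1]))
}

.controller_cache <- new.env(parent = emptyenv())

#' Default stabilising postural gains
#'
#' Demonstration gains for the delayed full-state-feedback controllers.
#' For `t_d = 0` they are plain LQR gains on the per-plane linearization.
#' For a positive delay, LQR gains are generally too stiff (the delayed
#' loop goes unstable), so the gains are designed by minimising the
#' delayed closed loop's spectral abscissa
#' (see [delayed_spectral_abscissa()]) with a deterministic Nelder-Mead
#' search seeded from the LQR solution and from a literature-scale
#' proportional-derivative pattern. The result is cached per
#' (body, delay). These are demonstration values; model fitting replaces
#' them.
#'
#' @param params a `body_params` object
#' @param t_d feedback delay passed through to [controller_params()]
#' @return a [controller_params()]
#' @export
default_controller <- function(params, t_d = 0.1) {
  lin <- linearize(params)
  key <- paste(signif(c(unlist(lin$sagittal), unlist(lin$coronal), t_d), 10),
               collapse = ",")
  hit <- .controller_cache[[key]]
  if (!is.null(hit)) return(hit)

  Q <- diag(c(600, 250, 60, 25))
  R <- diag(c(1, 1)) / 450
  mk <- function(rows) {
    A <- matrix(0, 4, 4)
    A[1:2, 3:4] <- diag(2)
    A[3:4, 1:2] <- lin$A[rows, rows - 4]
    B <- matrix(0, 4, 2)
    B[3:4, ] <- lin$B[rows, if (rows[1] == 5) 1:2 else 3:4]
    list(A = A, B = B)
  }
  design <- function(plane, sys, extra_seed = NULL) {
    K_lqr <- lqr_gain(sys$A, sys$B, Q, R)
    if (t_d == 0) return(K_lqr)
    obj <- function(kv) delayed_spectral_abscissa(plane$M, plane$G,
                                                  matrix(kv, 2, 4), t_d,
                                                  n_nodes = 16)
    # PD pattern scaled to the gravitational stiffness of this body
    scale <- -plane$G[1, 1] / 810
    seeds <- list(as.numeric(K_lqr),
                  scale * c(950, 320, 320, 120, 300, 115, 110, 50))
    if (!is.null(extra_seed)) seeds <- c(seeds, list(as.numeric(extra_seed)))
    best <- NULL
    best_score <- Inf
    for (s0 in seeds) {
      r <- stats::optim(s0, obj, method = "Nelder-Mead",
                        control = list(maxit = 1200, reltol = 1e-7))
      r <- stats::optim(r$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 1200, reltol = 1e-7))
      K <- matrix(r$par, 2, 4)
      absc <- delayed_spectral_abscissa(plane$M, plane$G, K, t_d)
      # among stable candidates prefer the better-damped transient
      score <- if (absc < -0.5) .plane_transient_score(plane, K, t_d) else
        1e6 + absc
      if (score < best_score) {
        best_score <- score
        best <- K
      }
    }
    best
  }
  pS <- lin$sagittal
  pC <- lin$coronal
  K_s <- design(pS, mk(5:6))
  # the planes share geometry and most inertia, so the sagittal solution
  # seeds the coronal design as well
  K_c <- design(pC, mk(7:8), extra_seed = K_s)
  out <- controller_params(K_s, K_c, t_d = t_d)
  .controller_cache[[key]] <- out
  out
}
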