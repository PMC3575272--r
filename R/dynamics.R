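#' Plant state of the two-link pendulum
#'
#' The 8-dimensional state: ankle and hip joint angles in the sagittal (S)
#' and coronal (C) planes, and their angular velocities. Angles are measured
#' from vertical (ankle) and from the legs link (hip), positive forward (S)
#' and positive toward a rightward lean (C), in radians.
#'
#' @param ankle_s,hip_s,ankle_c,hip_c joint angles (rad)
#' @param d_ankle_s,d_hip_s,d_ankle_c,d_hip_c angular velocities (rad/s)
#' @return a named numeric vector of class `plant_state`
#' @export
plant_state <- function(ankle_s = 0, hip_s = 0, ankle_c = 0, hip_c = 0,
                        d_ankle_s = 0, d_hip_s = 0, d_ankle_c = 0,
                        d_hip_c = 0) {
  x <- c(ankle_s = ankle_s, hip_s = hip_s, ankle_c = ankle_c, hip_c = hip_c,
         d_ankle_s = d_ankle_s, d_hip_s = d_hip_s, d_ankle_c = d_ankle_c,
         d_hip_c = d_hip_c)
  if (!all(is.finite(x))) stop("plant state must be finite", call. = FALSE)
  structure(x, class = "plant_state")
}

.as_state8 <- function(state) {
  x <- as.numeric(state)
  if (length(x) != 8 || !all(is.finite(x))) {
    stop("state must be 8 finite numbers", call. = FALSE)
  }
  x
}

#' Equations of motion of the two-link inverted pendulum
#'
#' Full coupled nonlinear 4-DOF rigid-body dynamics (spherical ankle and hip
#' reduced to pitch + roll, yaw locked; no passive joint stiffness or
#' damping) of the legs + head-arms-trunk pendulum on a horizontally
#' accelerating base, evaluated by an exact Kane/Newton-Euler formulation.
#'
#' @param state a [plant_state()] or 8-vector
#' @param torques applied generalized joint torques, length 4 in order
#'   (ankle_S, hip_S, ankle_C, hip_C), N m. Positive sagittal torque
#'   accelerates the joint forward; positive coronal torque toward a
#'   rightward lean.
#' @param platform_accel horizontal platform acceleration `c(ax, ay)` in the
#'   user frame (x forward, y rightward), m/s^2
#' @param params a `body_params` object
#' @return the state time-derivative (length 8): velocities then
#'   generalized accelerations
#' @export
equations_of_motion <- function(state, torques = c(0, 0, 0, 0),
                                platform_accel = c(0, 0), params) {
  x <- .as_state8(state)
  stopifnot(length(torques) == 4, all(is.finite(torques)))
  acc_int <- c(platform_accel[1], -platform_accel[2]) # user y (right) -> internal y (left)
  qdd <- .cpp_forward_dynamics(x, as.numeric(torques), acc_int,
                               .pack_params(params))
  c(x[5:8], qdd)
}

#' Joint-space mass matrix
#'
#' @param state a [plant_state()] or 8-vector (only angles used)
#' @param params a `body_params` object
#' @return 4x4 symmetric positive-definite mass matrix
#' @export
mass_matrix <- function(state, params) {
  .cpp_mass_matrix(.as_state8(state), .pack_params(params))
}

#' Inverse dynamics
#'
#' Generalized joint torques required to realise the given accelerations at
#' the given state, including gravity and base excitation.
#'
#' @inheritParams equations_of_motion
#' @param qdd generalized accelerations, length 4
#' @return required generalized torques, length 4 (N m)
#' @export
inverse_dynamics <- function(state, qdd, platform_accel = c(0, 0), params) {
  x <- .as_state8(state)
  acc_int <- c(platform_accel[1], -platform_accel[2])
  .cpp_inverse_dynamics(x, as.numeric(qdd), acc_int, .pack_params(params))
}

#' Centre of pressure from the ground-reaction wrench
#'
#' The COP is the point on the support surface where the horizontal
#' components of the reaction moment vanish. It is computed from the
#' reaction wrench transmitted at the ankle: the accelerations implied by
#' the applied torques are solved first, then the reaction force and moment
#' follow from the Newton-Euler balance (so the vertical reaction includes
#' link accelerations).
#'
#' @inheritParams equations_of_motion
#' @return named vector `c(cop_x, cop_y, f_z)`: COP in metres relative to
#'   the ankle point, user frame (x forward, y rightward), and the vertical
#'   reaction force (N). Errors if `f_z <= 0` (contact lost, outside the
#'   model's validity).
#' @export
center_of_pressure <- function(state, torques = c(0, 0, 0, 0),
                               platform_accel = c(0, 0), params) {
  x <- .as_state8(state)
  acc_int <- c(platform_accel[1], -platform_accel[2])
  out <- .cpp_cop(x, as.numeric(torques), acc_int, .pack_params(params))
  if (!is.finite(out[3]) || out[3] <= 0) {
    stop("vertical reaction force is not positive: model validity violated",
         call. = FALSE)
  }
  c(cop_x = out[1], cop_y = -out[2], f_z = out[3])
}

#' Linearized state-space model about upright
#'
#' Closed-form linearization of the stance dynamics about the upright
#' equilibrium. At upright the sagittal and coronal planes decouple into two
#' planar double inverted pendulums that differ only in the link inertia
#' component about the respective tilt axis; the per-plane mass and gravity
#' stiffness matrices are assembled in closed form (no numerical
#' differentiation).
#'
#' State ordering: `(ankle_s, hip_s, ankle_c, hip_c, d_ankle_s, d_hip_s,
#' d_ankle_c, d_hip_c)`; inputs `(T_ankle_S, T_hip_S, T_ankle_C, T_hip_C)`.
#'
#' @param params a `body_params` object
#' @return list with `A` (8x8), `B` (8x4), `B_platform` (8x2, columns = user
#'   frame forward/rightward platform acceleration), and the per-plane
#'   `M`, `G` matrices
#' @export
linearize <- function(params) {
  m1 <- params$legs$mass_kg
  m2 <- params$torso$mass_kg
  L1 <- params$legs$length_m
  d1 <- params$legs$com_m
  d2 <- params$torso$com_m
  g <- params$g

  plane <- function(I1, I2) {
    M11 <- I1 + m1 * d1^2 + I2 + m2 * (L1 + d2)^2
    M12 <- I2 + m2 * d2 * (L1 + d2)
    M22 <- I2 + m2 * d2^2
    M <- matrix(c(M11, M12, M12, M22), 2, 2)
    # gravity stiffness (destabilising): d2V/dq2 at upright
    G11 <- -g * (m1 * d1 + m2 * (L1 + d2))
    G12 <- -g * m2 * d2
    G <- matrix(c(G11, G12, G12, -g * m2 * d2), 2, 2)
    # base-acceleration input: Q = -coef * a (forward accel tips body back)
    bcoef <- c(m1 * d1 + m2 * (L1 + d2), m2 * d2)
    list(M = M, G = G, bcoef = bcoef)
  }
  # sagittal tilts rotate about the pitch (y) axis, coronal about roll (x)
  pS <- plane(params$legs$inertia[2, 2], params$torso$inertia[2, 2])
  pC <- plane(params$legs$inertia[1, 1], params$torso$inertia[1, 1])

  A <- matrix(0, 8, 8)
  B <- matrix(0, 8, 4)
  Bp <- matrix(0, 8, 2)
  A[1:4, 5:8] <- diag(4)
  MSi <- solve(pS$M)
  MCi <- solve(pC$M)
  A[5:6, 1:2] <- -MSi %*% pS$G
  A[7:8, 3:4] <- -MCi %*% pC$G
  B[5:6, 1:2] <- MSi
  B[7:8, 3:4] <- MCi
  # user-frame rightward acceleration = internal leftward negated; a
  # rightward base acceleration tips the body leftward (negative coronal)
  Bp[5:6, 1] <- -MSi %*% pS$bcoef
  Bp[7:8, 2] <- -MCi %*% pC$bcoef
  list(A = A, B = B, B_platform = Bp,
       sagittal = pS[c("M", "G")], coronal = pC[c("M", "G")])
}
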