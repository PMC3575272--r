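# Shared physics helpers for the tests: mechanical energy of the two-link
# pendulum (for conservation oracles) and small scenario builders.

rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)

# total mechanical energy at a state, fixed platform (internal frame)
mech_energy <- function(state, bp) {
  q <- state[1:4]
  qd <- state[5:8]
  R1 <- rot_y(q[1]) %*% rot_x(q[3])
  R2 <- R1 %*% rot_y(q[2]) %*% rot_x(q[4])
  ey <- c(0, 1, 0)
  ex <- c(1, 0, 0)
  u1 <- ey
  u2 <- rot_y(q[1]) %*% ex
  u3 <- R1 %*% ey
  u4 <- R1 %*% rot_y(q[2]) %*% ex
  w1 <- qd[1] * u1 + qd[3] * as.numeric(u2)
  w2 <- w1 + qd[2] * as.numeric(u3) + qd[4] * as.numeric(u4)
  d1 <- bp$legs$com_m
  L1 <- bp$legs$length_m
  d2 <- bp$torso$com_m
  r1 <- d1 * R1[, 3]
  rL <- L1 * R1[, 3]
  r2 <- d2 * R2[, 3]
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  v1 <- cross3(w1, r1)
  v2 <- cross3(w1, rL) + cross3(w2, r2)
  w1b <- as.numeric(t(R1) %*% w1)
  w2b <- as.numeric(t(R2) %*% w2)
  I1 <- diag(bp$legs$inertia)
  I2 <- diag(bp$torso$inertia)
  ke <- 0.5 * bp$legs$mass_kg * sum(v1^2) + 0.5 * bp$torso$mass_kg * sum(v2^2) +
    0.5 * sum(I1 * w1b^2) + 0.5 * sum(I2 * w2b^2)
  pe <- bp$g * (bp$legs$mass_kg * r1[3] + bp$torso$mass_kg * (rL[3] + r2[3]))
  ke + pe
}

# canonical small scenarios used across test files
test_body <- function() derive_body_params()

zero_gain_controller <- function(t_d = 0) {
  controller_params(matrix(0, 2, 4), matrix(0, 2, 4), t_d = t_d)
}

passive_scenario <- function(bp = test_body(), tilt = 0.05, horizon = 5) {
  scenario(body = bp, controller = zero_gain_controller(),
           display = display_config("off"),
           perturbation = perturbation_spec(displacement_m = 0,
                                            onset_s = 0.5),
           horizon = horizon,
           initial_state = plant_state(ankle_s = tilt, hip_s = -tilt / 2))
}

# fast default controller for a given delay, memoised across tests
cached_controller <- local({
  cache <- list()
  function(bp = test_body(), t_d = 0.1) {
    key <- sprintf("%.6f", t_d)
    if (is.null(cache[[key]])) cache[[key]] <<- default_controller(bp, t_d)
    cache[[key]]
  }
})
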