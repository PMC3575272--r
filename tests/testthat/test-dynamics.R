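test_that("upright equilibrium has exactly zero accelerations", {
  bp <- test_body()
  expect_identical(equations_of_motion(rep(0, 8), params = bp), rep(0, 8))
})

test_that("equations of motion agree with the symbolic Lagrangian derivation", {
  bp <- test_body()
  par <- list(m1 = bp$legs$mass_kg, m2 = bp$torso$mass_kg,
              L1 = bp$legs$length_m, d1 = bp$legs$com_m, d2 = bp$torso$com_m,
              I1 = diag(bp$legs$inertia), I2 = diag(bp$torso$inertia),
              g = bp$g)
  set.seed(11)
  for (i in 1:100) {
    st <- c(runif(4, -0.4, 0.4), runif(4, -1.5, 1.5))
    tau <- runif(4, -60, 60)
    ap <- runif(2, -2, 2)
    qdd_kane <- equations_of_motion(st, tau, ap, bp)[5:8]
    qdd_lagr <- lagrangian_qdd(st, tau, c(ap[1], -ap[2]), par)
    expect_lt(max(abs(qdd_kane - qdd_lagr)) / max(1, max(abs(qdd_kane))),
              1e-11)
  }
})

test_that("mass matrix is symmetric positive definite and state dependent", {
  bp <- test_body()
  M0 <- mass_matrix(rep(0, 8), bp)
  expect_equal(M0, t(M0), tolerance = 1e-12)
  expect_true(all(eigen(M0, symmetric = TRUE)$values > 0))
  M1 <- mass_matrix(plant_state(hip_s = 0.5), bp)
  expect_gt(max(abs(M1 - M0)), 1e-3)
})

test_that("passive dynamics conserve mechanical energy", {
  bp <- test_body()
  # direct RK4 on the passive equations, fixed platform, 5 s at 1 ms
  st <- as.numeric(plant_state(ankle_s = 0.05, hip_s = -0.02))
  E0 <- mech_energy(st, bp)
  f <- function(x) equations_of_motion(x, params = bp)
  dt <- 1e-3
  drift <- 0
  for (i in 1:5000) {
    k1 <- f(st)
    k2 <- f(st + dt / 2 * k1)
    k3 <- f(st + dt / 2 * k2)
    k4 <- f(st + dt * k3)
    st <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% 500 == 0) drift <- max(drift, abs(mech_energy(st, bp) - E0))
  }
  drift <- max(drift, abs(mech_energy(st, bp) - E0))
  expect_lt(drift / abs(E0), 1e-6)
})

test_that("the closed-form linearization matches finite differences", {
  bp <- test_body()
  lin <- linearize(bp)
  eps <- 1e-7
  A_fd <- matrix(0, 8, 8)
  B_fd <- matrix(0, 8, 4)
  Bp_fd <- matrix(0, 8, 2)
  for (j in 1:8) {
    e <- rep(0, 8)
    e[j] <- eps
    A_fd[, j] <- (equations_of_motion(e, params = bp) -
                    equations_of_motion(-e, params = bp)) / (2 * eps)
  }
  for (j in 1:4) {
    tq <- rep(0, 4)
    tq[j] <- eps
    B_fd[, j] <- (equations_of_motion(rep(0, 8), tq, params = bp) -
                    equations_of_motion(rep(0, 8), -tq, params = bp)) / (2 * eps)
  }
  for (j in 1:2) {
    pa <- c(0, 0)
    pa[j] <- eps
    Bp_fd[, j] <- (equations_of_motion(rep(0, 8), platform_accel = pa,
                                       params = bp) -
                     equations_of_motion(rep(0, 8), platform_accel = -pa,
                                         params = bp)) / (2 * eps)
  }
  expect_lt(max(abs(A_fd - lin$A)) / max(abs(lin$A)), 1e-6)
  expect_lt(max(abs(B_fd - lin$B)) / max(abs(lin$B)), 1e-6)
  expect_lt(max(abs(Bp_fd - lin$B_platform)) / max(abs(lin$B_platform)), 1e-6)
})

test_that("the uncontrolled upright plant is unstable with a symmetric spectrum", {
  lin <- linearize(test_body())
  ev <- eigen(lin$A, only.values = TRUE)$values
  expect_gt(max(Re(ev)), 1)
  # eigenvalues come in +/- pairs about the imaginary axis
  expect_equal(sort(Re(ev)), sort(-Re(ev)), tolerance = 1e-9)
  # sagittal torque inputs do not enter coronal rows at upright
  expect_true(all(lin$B[7:8, 1:2] == 0))
  expect_true(all(lin$B[5:6, 3:4] == 0))
})

test_that("small sagittal motion follows the linearized model to first order", {
  bp <- test_body()
  lin <- linearize(bp)
  amp <- 1e-4
  x_nl <- as.numeric(plant_state(ankle_s = amp, hip_s = -amp / 3))
  x_li <- x_nl
  dt <- 1e-3
  f_nl <- function(x) equations_of_motion(x, params = bp)
  f_li <- function(x) as.numeric(lin$A %*% x)
  step <- function(f, x) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  for (i in 1:500) {
    x_nl <- step(f_nl, x_nl)
    x_li <- step(f_li, x_li)
  }
  # deviation is second order in amplitude
  expect_lt(max(abs(x_nl - x_li)) / max(abs(x_nl)), 100 * amp)
  # coronal states never leave zero in a pure sagittal motion
  expect_identical(x_nl[c(3, 4, 7, 8)], rep(0, 4))
})

test_that("centre of pressure reproduces static moment balance", {
  bp <- test_body()
  m_tot <- bp$legs$mass_kg + bp$torso$mass_kg
  cop0 <- center_of_pressure(rep(0, 8), params = bp)
  expect_equal(unname(cop0[1:2]), c(0, 0))
  expect_equal(unname(cop0[3]), m_tot * bp$g)

  # a held lean: COP magnitude = |T_ankle| / (m g), COP under the lean side
  for (lean in list(c(ch = "ankle_s", cop = "cop_x", sgn = 1),
                    c(ch = "ankle_c", cop = "cop_y", sgn = 1))) {
    st <- do.call(plant_state, stats::setNames(list(2 * pi / 180), lean[["ch"]]))
    tq <- inverse_dynamics(st, rep(0, 4), params = bp)
    cop <- center_of_pressure(st, tq, params = bp)
    i_t <- if (lean[["ch"]] == "ankle_s") 1 else 3
    expect_equal(unname(abs(cop[lean[["cop"]]])),
                 abs(tq[i_t]) / (m_tot * bp$g), tolerance = 1e-10)
    expect_gt(as.numeric(lean[["sgn"]]) * cop[lean[["cop"]]], 0)
  }
})

test_that("time-averaged COP tracks the horizontal centre of mass", {
  bp <- test_body()
  scn <- scenario(body = bp, controller = cached_controller(bp),
                  display = display_config("off"), horizon = 6)
  tr <- simulate_stance(scn)
  # post-transient window: COM acceleration averages to ~0, so mean COP
  # approaches the mean COM projection
  win <- tr$t >= 3
  com_x <- function(aS, hS) {
    # small-angle horizontal COM (m), forward positive
    (bp$legs$mass_kg * bp$legs$com_m * sin(aS * pi / 180) +
       bp$torso$mass_kg * (bp$legs$length_m * sin(aS * pi / 180) +
                             bp$torso$com_m * sin((aS + hS) * pi / 180))) /
      (bp$legs$mass_kg + bp$torso$mass_kg)
  }
  mean_com <- mean(com_x(tr$ankle_s[win], tr$hip_s[win]))
  mean_cop <- mean(tr$cop_x[win]) / 100
  expect_lt(abs(mean_com - mean_cop), 5e-4)
})

test_that("planes decouple exactly at the symmetric configuration", {
  bp <- test_body()
  set.seed(3)
  for (i in 1:20) {
    st <- c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3), 0, 0,
            runif(1, -1, 1), runif(1, -1, 1), 0, 0)
    tau <- c(runif(2, -40, 40), 0, 0)
    dx <- equations_of_motion(st, tau, c(runif(1, -2, 2), 0), bp)
    expect_identical(dx[c(3, 4, 7, 8)], rep(0, 4))
  }
  # but coupling exists away from symmetry
  dx <- equations_of_motion(c(0.1, 0, 0.2, 0, 0, 0, 0, 0), c(10, 0, 0, 0),
                            c(0, 0), bp)
  expect_gt(max(abs(dx[7:8])), 0)
})
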