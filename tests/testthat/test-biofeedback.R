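d2r <- pi / 180

test_that("tilt sensing combines inclination and half its rate", {
  # upright: zero magnitude, azimuth reported as 0 by convention
  up <- sense_tilt(rep(0, 8))
  expect_equal(unname(up), c(0, 0, 0, 0))

  # pure forward tilt of 2 deg growing at 1 deg/s: m = 2 + 0.5 * 1
  st <- plant_state(ankle_s = 2 * d2r, d_ankle_s = 1 * d2r)
  tl <- sense_tilt(st)
  expect_equal(tl[["phi"]], 2)
  expect_equal(tl[["phidot"]], 1)
  expect_equal(tl[["azimuth"]], 0)
  expect_equal(tl[["magnitude"]], 2.5)

  # pure rightward tilt: azimuth 90 (clockwise from navel)
  expect_equal(sense_tilt(plant_state(ankle_c = d2r))[["azimuth"]], 90)
  # backward and leftward
  expect_equal(sense_tilt(plant_state(ankle_s = -d2r))[["azimuth"]], 180)
  expect_equal(sense_tilt(plant_state(hip_c = -d2r))[["azimuth"]], 270)
  # the torso angle is the sum of ankle and hip contributions
  expect_equal(sense_tilt(plant_state(ankle_s = d2r, hip_s = d2r))[["phi"]], 2)
})

test_that("display activation follows dead zone, thresholds, and nearest column", {
  cfg4 <- display_config("3x4")
  # inside the 1 degree dead zone nothing is displayed
  for (az in c(0, 45, 200)) {
    act <- select_activation(c(magnitude = 0.5, azimuth = az), cfg4)
    expect_equal(act[["row"]], 0)
    expect_true(is.na(act[["column"]]))
  }
  # stepwise rows at the documented 1/2/3 degree defaults, capped at 3
  expect_equal(select_activation(c(magnitude = 1.2, azimuth = 0), cfg4)[["row"]], 1)
  expect_equal(select_activation(c(magnitude = 2.5, azimuth = 0), cfg4)[["row"]], 2)
  expect_equal(select_activation(c(magnitude = 7.0, azimuth = 0), cfg4)[["row"]], 3)
  # nearest neighbour: 10 degrees -> column 0
  expect_equal(select_activation(c(magnitude = 2, azimuth = 10), cfg4)[["column"]], 0)
  # 1x2 display: 100 degrees is circularly closer to 180 than to 0
  cfg2 <- display_config("1x2")
  expect_equal(select_activation(c(magnitude = 2, azimuth = 100), cfg2)[["column"]], 180)
  expect_equal(select_activation(c(magnitude = 2, azimuth = 80), cfg2)[["column"]], 0)
  # exact tie resolves to the lower azimuth
  expect_equal(select_activation(c(magnitude = 2, azimuth = 45), cfg4)[["column"]], 0)
  # empty display stays off regardless of magnitude
  off <- select_activation(c(magnitude = 10, azimuth = 10), display_config("off"))
  expect_equal(off[["row"]], 0)
})

test_that("torque targets decompose the displayed column into cardinal parts", {
  bf <- biofeedback_params(k_s = matrix(c(4, 6, 8, 1, 2, 3), 3, 2),
                           k_c = matrix(c(2, 3, 4, 0.5, 1, 1.5), 3, 2))
  off <- target_torque(c(row = 0, column = NA), bf)
  expect_equal(off$K_s, c(0, 0))
  expect_equal(off$K_c, c(0, 0))

  t1 <- target_torque(c(row = 1, column = 0), bf)
  expect_equal(t1$K_s, c(4, 1))
  expect_equal(t1$K_c, c(0, 0))

  t2 <- target_torque(c(row = 2, column = 270), bf)
  expect_equal(t2$K_s, c(0, 0))
  expect_equal(t2$K_c, -c(3, 1))

  expect_error(target_torque(c(row = 5, column = 0), bf), "row")
})

test_that("target magnitudes satisfy the decomposition identity and row monotonicity", {
  bf <- biofeedback_params(k_s = matrix(c(4, 6, 8, 1, 2, 3), 3, 2),
                           k_c = matrix(c(2, 3, 4, 0.5, 1, 1.5), 3, 2))
  for (az in c(22.5, 45, 112.5, 247.5, 315)) {
    for (r in 1:3) {
      tt <- target_torque(c(row = r, column = az), bf)
      ident <- (tt$K_s / bf$k_s[r, ])^2 + (tt$K_c / bf$k_c[r, ])^2
      expect_equal(unname(ident), c(1, 1))
    }
    mags <- sapply(1:3, function(r) {
      tt <- target_torque(c(row = r, column = az), bf)
      sqrt(sum(tt$K_s^2) + sum(tt$K_c^2))
    })
    expect_true(all(diff(mags) >= 0))
  }
})

test_that("feedback torque follows the first-order step response exactly", {
  tau_f <- 0.3
  dt <- 1e-3
  K <- list(K_s = c(5, 2), K_c = c(0, 0))
  tf <- list(T_s = c(0, 0), T_c = c(0, 0))
  n <- round(5 * tau_f / dt)
  traj <- matrix(0, n, 2)
  for (i in 1:n) {
    tf <- advance_feedback_torque(tf, K, tau_f, dt)
    traj[i, ] <- tf$T_s
  }
  for (mult in c(1, 2, 5)) {
    t_chk <- mult * tau_f
    want <- K$K_s * (1 - exp(-t_chk / tau_f))
    got <- traj[round(t_chk / dt), ]
    expect_lt(max(abs(got - want) / abs(want)), 1e-6)
  }
  # steady state equals the target
  expect_equal(traj[n, ], K$K_s * (1 - exp(-5)), tolerance = 1e-12)
  # fixed point: target equal to current torque leaves it unchanged
  fixed <- advance_feedback_torque(list(T_s = c(3, 1), T_c = c(0, 0)),
                                   list(K_s = c(3, 1), K_c = c(0, 0)),
                                   tau_f, dt)
  expect_equal(fixed$T_s, c(3, 1))
})

test_that("parameter invariants: k-ordering and positive time constant", {
  expect_error(biofeedback_params(k_s = matrix(c(4, 2, 8, 0, 1, 2), 3, 2)),
               "k1 <= k2")
  expect_error(biofeedback_params(tau_f = 0), "tau_f")
  expect_error(display_config(columns_deg = c(0, 0)), "distinct")
  expect_error(display_config(columns_deg = 10), "grid")
  expect_error(display_config(preset = "3x4", thresholds_deg = c(1, 0.5, 2)),
               "ascending")
})

test_that("3x4 and 3x16 displays are indistinguishable near a shared column", {
  cfg4 <- display_config("3x4")
  cfg16 <- display_config("3x16")
  bf <- biofeedback_params()
  # azimuths within +/- 11.25 degrees of the shared 0-degree column
  for (az in c(349, 355, 0, 5, 11)) {
    for (m in c(1.5, 2.5, 3.5)) {
      a4 <- select_activation(c(magnitude = m, azimuth = az), cfg4)
      a16 <- select_activation(c(magnitude = m, azimuth = az), cfg16)
      expect_equal(a4, a16)
      expect_equal(target_torque(a4, bf), target_torque(a16, bf))
    }
  }
})

test_that("display presets carry the documented geometry", {
  expect_equal(display_config("3x16")$columns_deg, seq(0, 337.5, by = 22.5))
  expect_equal(display_config("3x8")$columns_deg, seq(0, 315, by = 45))
  expect_equal(display_config("1x2")$n_rows, 1L)
  expect_equal(display_config("3x4")$thresholds_deg, c(1, 2, 3))
  expect_length(display_config("off")$columns_deg, 0)
})
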