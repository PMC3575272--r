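test_that("an unperturbed, unactuated upright run stays identically zero", {
  scn <- scenario(body = test_body(), controller = zero_gain_controller(),
                  biofeedback = biofeedback_params(k_s = matrix(0, 3, 2)),
                  display = display_config("off"),
                  perturbation = perturbation_spec(displacement_m = 0))
  tr <- simulate_stance(scn)
  num <- vapply(tr, is.numeric, logical(1))
  num["t"] <- FALSE
  expect_true(all(as.matrix(tr[, num]) == 0, na.rm = TRUE))
})

test_that("recorded joint torques satisfy the superposition bookkeeping exactly", {
  fx <- default_study_fixture()
  scn <- fx$truth
  scn$perturbation$direction_deg <- 225
  tr <- simulate_stance(scn)
  expect_identical(max(abs(tr$tj_ankle_s - (tr$tpc_ankle_s + tr$tf_ankle_s))), 0)
  expect_identical(max(abs(tr$tj_hip_s - (tr$tpc_hip_s + tr$tf_hip_s))), 0)
  expect_identical(max(abs(tr$tj_ankle_c - (tr$tpc_ankle_c + tr$tf_ankle_c))), 0)
  expect_identical(max(abs(tr$tj_hip_c - (tr$tpc_hip_c + tr$tf_hip_c))), 0)
  # biofeedback actually acted in this run
  expect_gt(max(abs(tr$tf_ankle_s)), 0.1)
})

test_that("sagittal perturbations leave the coronal plane exactly at rest", {
  bp <- test_body()
  for (disp in list(display_config("off"), display_config("3x4"))) {
    scn <- scenario(body = bp, controller = cached_controller(bp),
                    display = disp,
                    perturbation = perturbation_spec(direction_deg = 180))
    tr <- simulate_stance(scn)
    expect_lte(max(abs(tr$sway_ml)), 1e-12)
    expect_lte(max(abs(tr$cop_y)), 1e-12)
    expect_gt(max(abs(tr$sway_ap)), 1)
  }
})

test_that("coronal perturbations leave the sagittal plane exactly at rest", {
  bp <- test_body()
  scn <- scenario(body = bp, controller = cached_controller(bp),
                  display = display_config("3x4"),
                  perturbation = perturbation_spec(direction_deg = 90))
  tr <- simulate_stance(scn)
  expect_lte(max(abs(tr$sway_ap)), 1e-12)
  expect_lte(max(abs(tr$cop_x)), 1e-12)
  expect_gt(max(abs(tr$sway_ml)), 1)
})

test_that("identical scenarios give bit-identical trajectories", {
  fx <- default_study_fixture()
  scn <- fx$truth
  scn$perturbation$direction_deg <- 225
  tr1 <- simulate_stance(scn)
  tr2 <- simulate_stance(scn)
  expect_identical(tr1, tr2)
})

test_that("halving the step barely changes the post-perturbation sway", {
  bp <- test_body()
  scn1 <- scenario(body = bp, controller = cached_controller(bp),
                   display = display_config("off"), dt = 1e-3)
  scn2 <- scn1
  scn2$dt <- 5e-4
  s1 <- resample_to_experiment(simulate_stance(scn1), 100)
  s2 <- resample_to_experiment(simulate_stance(scn2), 100)
  win <- s1$t >= 0.5 & s1$t <= 3.5
  rms <- sqrt(mean((s1$sway_ap[win] - s2$sway_ap[win])^2))
  expect_lt(rms, 1e-4)

  # with the display on, the once-per-step activation update makes the
  # convergence first order in dt; the response still converges
  scn3 <- scn1
  scn3$display <- display_config("3x4")
  scn4 <- scn3
  scn4$dt <- 5e-4
  s3 <- resample_to_experiment(simulate_stance(scn3), 100)
  s4 <- resample_to_experiment(simulate_stance(scn4), 100)
  rms_on <- sqrt(mean((s3$sway_ap[win] - s4$sway_ap[win])^2))
  expect_lt(rms_on, 0.05)
})

test_that("corrective biofeedback does not worsen the sway peak", {
  fx <- default_study_fixture()
  on <- fx$truth
  off <- on
  off$display <- display_config("off")
  tr_on <- simulate_stance(on)
  tr_off <- simulate_stance(off)
  expect_lte(max(abs(tr_on$sway_ap)), max(abs(tr_off$sway_ap)))
})

test_that("resampling decimates exactly and reproduces band-limited signals", {
  fx <- default_study_fixture()
  tr <- simulate_stance(fx$truth)
  rs <- resample_to_experiment(tr, 100)
  expect_equal(nrow(rs), 401)
  idx <- seq(1, nrow(tr), by = 10)
  expect_identical(rs$sway_ap, tr$sway_ap[idx])
  expect_identical(rs$cop_x, tr$cop_x[idx])
  # constant channels survive round trips exactly
  const <- tr
  const$sway_ap <- rep(1.5, nrow(tr))
  expect_true(all(resample_to_experiment(const, 100)$sway_ap == 1.5))
  # a 2 Hz sine is far below Nyquist at 100 Hz: kept samples are analytic
  sine <- tr
  sine$sway_ap <- sin(2 * pi * 2 * tr$t)
  rs2 <- resample_to_experiment(sine, 100)
  expect_lt(max(abs(rs2$sway_ap - sin(2 * pi * 2 * rs2$t))), 1e-9)
  expect_error(resample_to_experiment(rs, 1000), "rate")
})

test_that("a fall aborts the run with a diagnostic", {
  scn <- scenario(body = test_body(), controller = zero_gain_controller(),
                  display = display_config("off"),
                  perturbation = perturbation_spec(displacement_m = 0),
                  initial_state = plant_state(ankle_s = 0.3),
                  horizon = 5)
  expect_error(simulate_stance(scn), "fall", ignore.case = TRUE)
})

test_that("the display state recorded in the trajectory matches the device rules", {
  fx <- default_study_fixture()
  scn <- fx$truth
  scn$perturbation$direction_deg <- 225
  tr <- simulate_stance(scn)
  cfg <- scn$display
  i <- which(tr$disp_row > 0)[1]
  tl <- sense_tilt(c(tr$ankle_s[i], tr$hip_s[i], tr$ankle_c[i], tr$hip_c[i],
                     tr$d_ankle_s[i], tr$d_hip_s[i], tr$d_ankle_c[i],
                     tr$d_hip_c[i]) * pi / 180)
  act <- select_activation(tl, cfg)
  expect_equal(act[["row"]], tr$disp_row[i])
  expect_equal(act[["column"]], tr$disp_col[i])
})
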