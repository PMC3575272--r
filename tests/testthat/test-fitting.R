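# shared small fixtures: coarse-step scenarios keep these tests quick
fit_truth_scenario <- function(display = "off", dt = 2e-3) {
  bp <- test_body()
  scenario(body = bp, controller = cached_controller(bp),
           display = display_config(display), dt = dt)
}

quad_objective <- function(center) {
  function(problem, values) sum((as.numeric(values) - center)^2)
}

test_that("the objective vanishes at the generating parameters", {
  truth <- fit_truth_scenario()
  refs <- generate_reference(fixture_spec(truth, directions = 180))
  prob <- fit_problem(refs["180"], truth, free = c("Ks11", "Ks13"))
  tv <- c(Ks11 = truth$controller$K_s[1, 1], Ks13 = truth$controller$K_s[1, 3])
  expect_lt(fit_objective(prob, tv), 1e-12)
  # and grows away from them
  expect_gt(fit_objective(prob, tv * 1.1), 1e-4)
})

test_that("a single triangular channel integrates to its closed form", {
  # reference: AP sway triangle peaking at 1 over the 3 s window; the
  # template simulates identically zero, so J = integral of (tri/max)^2
  t <- seq(0, 4, by = 0.01)
  tri <- pmax(0, 1 - abs(t - 2) / 1.5)
  refs <- list("180" = data.frame(t = t, sway_ap = tri, sway_ml = 0,
                                  cop_x = 0, cop_y = 0))
  tmpl <- scenario(body = test_body(), controller = zero_gain_controller(),
                   display = display_config("off"),
                   perturbation = perturbation_spec(displacement_m = 0),
                   dt = 2e-3)
  prob <- fit_problem(refs, tmpl, free = "Ks11")
  # only the sway channel survives (zero-peak channels are dropped)
  expect_equal(prob$refs[[1]]$include, "sway_ap")
  J <- fit_objective(prob, c(Ks11 = 0))
  expect_equal(J, 1, tolerance = 1e-3) # 2 * (1.5 / 3)
  # normalisation: doubling the reference channel leaves J unchanged
  refs2 <- refs
  refs2[["180"]]$sway_ap <- 2 * tri
  expect_equal(fit_objective(fit_problem(refs2, tmpl, free = "Ks11"),
                             c(Ks11 = 0)), J)
})

test_that("AP sway is excluded from the objective for coronal perturbations", {
  truth <- fit_truth_scenario()
  refs <- generate_reference(fixture_spec(truth, directions = 90))
  prob1 <- fit_problem(refs["90"], truth, free = "Kc11")
  expect_false("sway_ap" %in% prob1$refs[[1]]$include)
  # corrupting the AP reference does not change the objective
  refs2 <- refs
  refs2[["90"]]$sway_ap <- refs2[["90"]]$sway_ap + 5
  prob2 <- fit_problem(refs2["90"], truth, free = "Kc11")
  v <- c(Kc11 = truth$controller$K_c[1, 1] * 1.05)
  expect_equal(fit_objective(prob1, v), fit_objective(prob2, v))
})

test_that("the sweep returns the exact argmin, first encountered on ties", {
  truth <- fit_truth_scenario()
  refs <- generate_reference(fixture_spec(truth, directions = 180))
  prob <- fit_problem(refs["180"], truth, free = "Ks11")
  tv <- truth$controller$K_s[1, 1]
  # singleton grid
  one <- parameter_sweep(prob, list(Ks11 = tv * 1.1))
  expect_equal(unname(one$best), tv * 1.1)
  # a grid containing the truth returns the truth
  sw <- parameter_sweep(prob, list(Ks11 = tv * c(0.9, 0.97, 1, 1.05)))
  expect_equal(unname(sw$best), tv)
  expect_lt(sw$J, 1e-12)
  # convex slice: the winner is the grid point nearest the continuous minimum
  sw2 <- parameter_sweep(prob, list(Ks11 = tv * c(0.94, 0.98, 1.03, 1.09)))
  expect_equal(unname(sw2$best), tv * 0.98)
  expect_error(parameter_sweep(prob, list()), "empty")
  # deterministic tie-break on a flat analytic objective
  swt <- parameter_sweep(prob, list(Ks11 = c(3, 1, 2)),
                         objective = function(p, v) 0)
  expect_equal(unname(swt$best), 3)
})

test_that("perpendicular search solves separable quadratics", {
  center <- c(a = 1.5, b = -2, c = 0.25)
  prob <- structure(list(lower = NULL, upper = NULL), class = "fit_problem")
  # optimal start: no accepted moves, J stays put
  res0 <- perpendicular_search(prob, center, step = 0.5, step_tol = 1e-6,
                               objective = quad_objective(center))
  expect_equal(res0$par, center)
  expect_equal(res0$J, 0)
  expect_true(all(diff(res0$trace$J) == 0))
  # offset start converges to the analytic minimum
  res <- perpendicular_search(prob, center + c(2, -3, 1), step = 0.5,
                              step_tol = 1e-8,
                              objective = quad_objective(center))
  expect_equal(res$par, center, tolerance = 1e-4)
  expect_true(res$converged)
  # the trace never increases
  expect_true(all(diff(res$trace$J) <= 0))
})

test_that("search respects bounds and the k-ordering projection", {
  center <- c(a = 2, b = 2)
  prob <- structure(list(lower = c(a = 0, b = 3), upper = c(a = 1, b = 10)),
                    class = "fit_problem")
  res <- perpendicular_search(prob, c(a = 0.2, b = 5), step = 0.3,
                              step_tol = 1e-6,
                              objective = quad_objective(c(2, 2)))
  expect_equal(unname(res$par), c(1, 3), tolerance = 1e-6)

  # k-ordering: injecting k2 below k1 is repaired by the running maximum
  scn <- default_study_fixture()$truth
  scn2 <- posturefb:::.apply_fit_params(scn, c(kS2a = 1))
  expect_gte(scn2$biofeedback$k_s[2, 1], scn2$biofeedback$k_s[1, 1])
})

test_that("sensitivities vanish for decoupled parameters and scale linearly", {
  truth <- fit_truth_scenario()
  refs <- generate_reference(fixture_spec(truth, directions = 180))
  prob <- fit_problem(refs["180"], truth, free = c("Ks11", "Kc11"))
  base <- c(Ks11 = truth$controller$K_s[1, 1] * 1.05,
            Kc11 = truth$controller$K_c[1, 1])
  sens <- sensitivity_screen(prob, base, delta = c(Ks11 = 20, Kc11 = 20))
  # a coronal gain cannot influence a pure sagittal perturbation
  expect_equal(sens$sensitivity[sens$parameter == "Kc11"], 0)
  expect_gt(sens$sensitivity[sens$parameter == "Ks11"], 0)
  expect_equal(sens$parameter[1], "Ks11")

  # linear objective slice: sensitivity proportional to the probe size
  lin_obj <- function(p, v) 3 * as.numeric(v[["a"]]) - as.numeric(v[["b"]]) + 1
  probA <- structure(list(), class = "fit_problem")
  s_small <- sensitivity_screen(probA, c(a = 0, b = 0), delta = 0.1,
                                objective = lin_obj)
  s_large <- sensitivity_screen(probA, c(a = 0, b = 0), delta = 0.4,
                                objective = lin_obj)
  expect_equal(s_large$sensitivity / s_small$sensitivity, c(4, 4))
  # uniform probe scaling preserves the ranking
  expect_equal(s_large$parameter, s_small$parameter)
  expect_equal(s_small$parameter, c("a", "b"))
})

test_that("a detuned sagittal gain pair is recovered by the two-stage fit", {
  truth <- fit_truth_scenario()
  refs <- generate_reference(fixture_spec(truth, directions = 180))
  free <- c("Ks11", "Ks13")
  tv <- c(Ks11 = truth$controller$K_s[1, 1],
          Ks13 = truth$controller$K_s[1, 3])
  prob <- fit_problem(refs["180"], truth, free)
  res <- fit_two_stage(prob, grid = list(Ks11 = tv[["Ks11"]] * c(0.95, 1.02),
                                         Ks13 = tv[["Ks13"]] * c(0.94, 1.03)),
                       step = abs(tv) * 0.05, step_tol = 1e-6,
                       obj_tol = 1e-10, max_cycles = 60)
  expect_lt(max(abs(res$par - tv) / abs(tv)), 0.01)
  expect_lt(res$J, 1e-6)
})
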