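test_that("forward simulation matches the closed-form exponential", {
  # point-mass posterior r = -0.5, no antibiotics: N(t) = N0 exp(-0.5 t)
  pm <- point_mass_posterior(r = -0.5, patients = "A")
  density <- toy_density("A", 0:4, rep(1e10, 5))
  meta <- toy_meta("A", engraft = 0L)  # no phase window overlaps days 0..4
  sim <- forward_simulate_patient(pm, density, empty_exposures(), meta)
  expect_equal(sim$N_pred, 1e10 * exp(-0.5 * (0:4)), tolerance = 1e-9)
  # all-zero point mass: flat trajectory
  flat <- forward_simulate_patient(point_mass_posterior(patients = "A"),
                                   density, empty_exposures(), meta)
  expect_equal(flat$N_pred, rep(1e10, 5), tolerance = 1e-12)
})

test_that("forward simulation applies interval covariates and patient intercepts", {
  pm <- point_mass_posterior(beta_a = c("meropenem" = -1), r = 0.1,
                             p_int = c(A = 0.05), patients = "A")
  density <- toy_density("A", c(0, 1, 3), rep(1e9, 3))
  meta <- toy_meta("A"); meta$engraftment_day <- 0L
  exposures <- exposure_row("A", "meropenem", "iv", 1, 2)
  sim <- forward_simulate_patient(pm, density, exposures, meta)
  # step 0->1 exposed (interval [0,1] meets [1,2]); step 1->3 exposed
  expect_equal(sim$N_pred[2], 1e9 * exp(0.15 - 1), tolerance = 1e-9)
  expect_equal(sim$N_pred[3], sim$N_pred[2] * exp(2 * (0.15 - 1)),
               tolerance = 1e-9)
})

test_that("courses are maximal consecutive runs with day-by-day context", {
  metas <- toy_meta("A", cond = -7, engraft = 10, discharge = 20)
  exposures <- rbind(
    exposure_row("A", "piperacillin-tazobactam", "iv", 3, 9),
    exposure_row("A", "metronidazole", "iv", 5, 6))
  cs <- compile_courses(exposures, metas)
  pip <- Filter(function(x) x$label == "piperacillin-tazobactam", cs)
  expect_length(pip, 1)
  expect_equal(pip[[1]]$duration, 7)
  expect_equal(pip[[1]]$days, 3:9)
  ctx <- pip[[1]]$context
  expect_equal(ctx[["piperacillin-tazobactam"]], rep(1L, 7))
  expect_equal(ctx$metronidazole, as.integer(3:9 %in% 5:6))
  expect_equal(ctx$phase2, as.integer(3:9 < 10))

  # split administrations become separate courses
  two <- compile_courses(rbind(exposure_row("B", "cefepime", "iv", 1, 2),
                               exposure_row("B", "cefepime", "iv", 5, 6)),
                         toy_meta("B"))
  expect_length(two, 2)
  expect_equal(vapply(two, `[[`, numeric(1), "duration"), c(2, 2))
  expect_length(compile_courses(empty_exposures(), metas), 0)
})

test_that("course loss matches closed forms for point-mass posteriors", {
  metas <- toy_meta("A"); metas$engraftment_day <- 0L
  courses <- compile_courses(
    exposure_row("A", "piperacillin-tazobactam", "iv", 1, 7), metas)
  pm <- point_mass_posterior(beta_a = c("piperacillin-tazobactam" = -1.5),
                             patients = "A")
  loss <- predict_course_loss(pm, courses, "piperacillin-tazobactam",
                              n_resamples = 50)
  expect_equal(loss$residual_fraction, exp(-10.5), tolerance = 1e-9)
  expect_gt(loss$percent_loss, 99)
  # zero effect -> residual fraction exactly 1, zero loss
  null <- predict_course_loss(point_mass_posterior(patients = "A"), courses,
                              "piperacillin-tazobactam", n_resamples = 50)
  expect_equal(null$residual_fraction, 1, tolerance = 1e-12)
  expect_equal(null$percent_loss, 0, tolerance = 1e-10)
  expect_error(predict_course_loss(pm, courses, "linezolid"), "no compiled")
})

test_that("course resampling mixes courses uniformly with replacement", {
  metas <- toy_meta("A"); metas$engraftment_day <- 0L
  courses <- compile_courses(rbind(
    exposure_row("A", "meropenem", "iv", 1, 2),
    exposure_row("A", "meropenem", "iv", 5, 8)), metas)
  pm <- point_mass_posterior(beta_a = c("meropenem" = -1), patients = "A")
  loss <- predict_course_loss(pm, courses, "meropenem", n_resamples = 20000,
                              seed = 2)
  want <- (exp(-2) + exp(-4)) / 2
  mc_se <- stats::sd(c(exp(-2), exp(-4))) / sqrt(20000)
  expect_equal(loss$residual_fraction, want, tolerance = 5 * mc_se / want)

  # duplicating the course list leaves the estimator distribution unchanged
  dup <- predict_course_loss(pm, c(courses, courses), "meropenem",
                             n_resamples = 20000, seed = 3)
  expect_equal(dup$residual_fraction, want, tolerance = 5 * mc_se / want)
})

test_that("a more bactericidal effect never increases the residual fraction", {
  metas <- toy_meta("A"); metas$engraftment_day <- 0L
  courses <- compile_courses(
    exposure_row("A", "cefepime", "iv", 2, 6), metas)
  res <- vapply(c(0, -0.5, -1, -2), function(b) {
    pm <- point_mass_posterior(beta_a = c("cefepime" = b), patients = "A")
    predict_course_loss(pm, courses, "cefepime", n_resamples = 10,
                        seed = 1)$residual_fraction
  }, numeric(1))
  expect_true(all(diff(res) < 0))
})

test_that("capacity feedback enters through the running normalized density", {
  # one-day course, beta_c = -1: logN step = -1 * exp(0) = -1
  metas <- toy_meta("A"); metas$engraftment_day <- 0L
  courses <- compile_courses(exposure_row("A", "cefepime", "iv", 1, 2), metas)
  pm <- point_mass_posterior(beta_c = -1, patients = "A")
  loss <- predict_course_loss(pm, courses, "cefepime", n_resamples = 5)
  # day 1: mu = -1; day 2: mu = -exp(-1)
  expect_equal(loss$residual_fraction, exp(-1 - exp(-1)), tolerance = 1e-9)
})
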