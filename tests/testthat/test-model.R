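# fast sampler settings used throughout the model tests
fit_fast <- function(deltas, seed = 1, draws = 10000, warmup = 1000, ...)
  suppressMessages(fit_anaerobe_model(deltas, chains = 3, draws = draws,
                                      warmup = warmup, seed = seed, ...))

test_that("design matrix matches hand-written rows and flags constant covariates", {
  density <- toy_density("A", c(1, 2, 3), c(1e9, 1e8, 1e8))
  exposures <- rbind(exposure_row("A", "meropenem", "iv", 0, 1),
                     exposure_row("A", "ciprofloxacin", "po", -2, 10))
  deltas <- build_deltas(density, exposures, toy_meta("A"))
  expect_message(des <- build_design(deltas), "zero variance")
  expect_equal(des$y, c(-log(10), 0))
  expect_equal(unname(des$A[, "meropenem"]), c(1, 0))
  expect_equal(unname(des$Pr[, "fluoroquinolones"]), c(1, 1))
  expect_equal(des$patient, c(1L, 1L))
  expect_equal(des$n_scaled, c(1e9, 1e8) / 1e11)
  # cipro covers every interval -> constant, flagged
  expect_true("fluoroquinolones" %in% des$flagged)
  expect_true(all(c("piperacillin-tazobactam", "linezolid") %in% des$flagged))
})

test_that("model log-density matches an independently coded Gaussian likelihood", {
  set.seed(21)
  cohort <- generate_cohort(cohort_config(n_patients = 4L), seed = 3)
  deltas <- build_deltas(density_series(cohort$samples), cohort$exposures,
                         cohort$metas)
  emp <- empirical_labels(); pro <- prophylactic_labels()
  pats <- unique(deltas$patient_id)
  for (i in 1:50) {
    params <- list(r = rnorm(1), beta_p1 = rnorm(1), beta_p2 = rnorm(1),
                   beta_a = setNames(rnorm(7), emp), beta_o = rnorm(1),
                   o_dev = setNames(rnorm(4), pro),
                   p_int = setNames(rnorm(length(pats)), pats),
                   beta_c = rnorm(1), sigma_m = runif(1, 0.2, 2))
    # oracle: plain loop over observations, no shared code with the package
    ll <- 0
    for (j in seq_len(nrow(deltas))) {
      mu <- params$r + params$beta_p1 * deltas$phase1[j] +
        params$beta_p2 * deltas$phase2[j]
      for (e in emp) mu <- mu + params$beta_a[[e]] * deltas[[e]][j]
      for (g in pro) mu <- mu + (params$beta_o + params$o_dev[[g]]) * deltas[[g]][j]
      mu <- mu + params$p_int[[deltas$patient_id[j]]] +
        params$beta_c * deltas$N_start_scaled[j]
      ll <- ll - 0.5 * log(2 * pi * params$sigma_m^2) -
        (deltas$y[j] - mu)^2 / (2 * params$sigma_m^2)
    }
    expect_equal(suppressMessages(delta_loglik(deltas, params)), ll,
                 tolerance = 1e-8)
  }
})

test_that("with no data the posterior reproduces the prior", {
  empty <- build_deltas(toy_density("A", 1, 1e9), empty_exposures(),
                        toy_meta("A"))
  expect_equal(nrow(empty), 0)
  post <- fit_fast(empty, draws = 10000, warmup = 200)
  r <- post$draws[, "r"]
  ks <- suppressWarnings(stats::ks.test(r, "pnorm", 0, 100))
  expect_lt(unname(ks$statistic), 0.05)
  # regularized and positive-support priors land on their scales too
  expect_equal(stats::sd(post$draws[, "beta_o"]), sqrt(0.1), tolerance = 0.1)
  expect_true(all(post$draws[, "sigma_m"] > 0))
})

test_that("summaries have ordered intervals and are invariant to chain order", {
  cohort <- generate_cohort(cohort_config(n_patients = 6L), seed = 5)
  deltas <- build_deltas(density_series(cohort$samples), cohort$exposures,
                         cohort$metas)
  post <- fit_fast(deltas, draws = 1500, warmup = 500)
  s1 <- summary(post)
  expect_true(all(s1$lower <= s1$mean & s1$mean <= s1$upper))
  perm <- post
  idx <- order(match(perm$chain, c(2, 3, 1)))  # chains 2,3,1
  perm$draws <- perm$draws[idx, ]; perm$chain <- perm$chain[idx]
  expect_equal(summary(perm), s1)
})

test_that("point-mass and Monte-Carlo summaries match closed forms", {
  pm <- point_mass_posterior(r = 0.7, n_draws = 200)
  s <- summary(pm)
  expect_equal(s[s$parameter == "growth rate (r)", c("mean", "lower", "upper")],
               data.frame(mean = 0.7, lower = 0.7, upper = 0.7),
               ignore_attr = TRUE)
  # standard-normal draws: central 95% interval near +/- 1.96
  pm$draws <- cbind(pm$draws[rep(1, 30000), , drop = FALSE])
  set.seed(31)
  pm$draws[, "r"] <- rnorm(30000)
  pm$chain <- rep(1L, 30000)
  s <- summary(pm)
  expect_equal(s$lower[s$parameter == "growth rate (r)"], -1.96,
               tolerance = 0.05 / 1.96)
  expect_equal(s$upper[s$parameter == "growth rate (r)"], 1.96,
               tolerance = 0.05 / 1.96)
})

test_that("doubling every observation shrinks well-identified posterior sds", {
  cohort <- generate_cohort(cohort_config(), seed = 7)
  deltas <- build_deltas(density_series(cohort$samples), cohort$exposures,
                         cohort$metas)
  post1 <- fit_fast(deltas, seed = 7)
  post2 <- fit_fast(rbind(deltas, deltas), seed = 7)
  for (p in c("beta_a[piperacillin-tazobactam]", "sigma_m")) {
    ratio <- stats::sd(post2$draws[, p]) / stats::sd(post1$draws[, p])
    expect_equal(ratio, 1 / sqrt(2), tolerance = 0.25)
  }
})

test_that("the fit recovers generative antibiotic effects on one cohort", {
  cohort <- generate_cohort(cohort_config(), seed = 11)
  deltas <- build_deltas(density_series(cohort$samples), cohort$exposures,
                         cohort$metas)
  post <- fit_fast(deltas, seed = 11)
  s <- summary(post)
  truth <- cohort$truth$params
  row <- function(p) s[s$parameter == p, ]
  expect_gt(-1.5, row("piperacillin-tazobactam")$lower)
  expect_lt(-1.5, row("piperacillin-tazobactam")$upper)
  expect_gt(truth$sigma_m, row("sigma_m")$lower - 0.1)
  # convergence: split R-hat below 1.05 for all parameters
  expect_true(all(post$diagnostics$rhat < 1.05, na.rm = TRUE))
})
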