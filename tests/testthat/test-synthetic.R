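test_that("default cohort matches the emulated study conditions", {
  cohort <- generate_cohort(cohort_config(), seed = 2)
  m <- cohort$metas
  expect_equal(nrow(m), 18)
  expect_equal(sum(m$transplant_type == "allo"), 14)
  expect_true(all(m$conditioning_start_day %in% -(7:10)))
  expect_true(all(m$engraftment_day >= 10 & m$engraftment_day <= 20))
  hosp <- m$discharge_day - m$admit_day + 1
  expect_true(all(hosp >= 20 & hosp <= 38))
  # ~ 0.77 x 0.87 of inpatient days yield a sequenced sample
  n_days <- sum(hosp)
  n_samp <- length(unique(cohort$samples$sample_id))
  p <- 0.77 * 0.87
  expect_lt(abs(n_samp / n_days - p), 4 * sqrt(p * (1 - p) / n_days))
  # prophylaxis pattern: cipro for everyone, iv vancomycin for allo only
  cipro <- cohort$exposures[cohort$exposures$drug == "ciprofloxacin", ]
  expect_setequal(cipro$patient_id, m$patient_id)
  expect_true(all(cipro$start_day == -2))
  vanc <- cohort$exposures[cohort$exposures$covariate == "vancomycin-iv", ]
  expect_setequal(vanc$patient_id, m$patient_id[m$transplant_type == "allo"])
})

test_that("compositions are simplex-valued and track the latent anaerobe fraction", {
  cohort <- generate_cohort(cohort_config(), seed = 4)
  sums <- tapply(cohort$samples$rel_abundance, cohort$samples$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  s <- cohort$samples
  obs <- tapply(s$rel_abundance[is_obligate_anaerobe(s$lineage)],
                s$sample_id[is_obligate_anaerobe(s$lineage)], sum)
  lat <- cohort$truth$latent
  key <- paste(s$patient_id, s$day)[match(names(obs), s$sample_id)]
  latf <- (lat$N / (lat$N + lat$M))[match(key, paste(lat$patient_id, lat$day))]
  expect_lt(mean(abs(obs - latf)), 0.02)
})

test_that("with all noise off, observations sit exactly on the deterministic law", {
  cfg <- cohort_config(n_patients = 3L, qpcr_sd_log10 = 0,
                       dirichlet_conc = Inf, rel_detection = 0,
                       other_walk_sd_log10 = 0)
  cfg$params$sigma_m <- 0
  cfg$params$p_int_sd <- 0
  cohort <- generate_cohort(cfg, seed = 6)
  d <- density_series(cohort$samples)
  lat <- cohort$truth$latent
  latN <- lat$N[match(paste(d$patient_id, d$day),
                      paste(lat$patient_id, lat$day))]
  expect_equal(d$N, latN, tolerance = 1e-9)
  # independently recompute one patient's deterministic log increments
  p <- cfg$params
  pid <- cohort$metas$patient_id[1]
  meta <- cohort$metas[1, ]
  lat1 <- lat[lat$patient_id == pid, ]
  exp1 <- cohort$exposures[cohort$exposures$patient_id == pid, ]
  for (i in seq_len(nrow(lat1) - 1)) {
    t0 <- lat1$day[i]; t1 <- t0 + 1
    active <- exp1$covariate[exp1$start_day <= t1 & exp1$end_day >= t0]
    mu <- p$r +
      p$beta_p1 * (t0 < 0 && t1 >= meta$conditioning_start_day) +
      p$beta_p2 * (t0 < meta$engraftment_day && t1 >= 0) +
      sum(p$beta_a[intersect(names(p$beta_a), active)]) +
      sum((p$beta_o + p$o_dev)[intersect(names(p$o_dev), active)])
    expect_equal(log(lat1$N[i + 1]) - log(lat1$N[i]), mu, tolerance = 1e-9)
  }
})

test_that("observed log-declines on exposed days reflect the generative effect", {
  cohort <- generate_cohort(cohort_config(), seed = 8)
  deltas <- build_deltas(density_series(cohort$samples), cohort$exposures,
                         cohort$metas)
  keep <- c("phase1", "phase2", "piperacillin-tazobactam", "meropenem",
            "cefepime", "fluoroquinolones", "vancomycin-iv",
            "trimethoprim-sulfamethoxazole", "atovaquone")
  fit <- stats::lm(stats::reformulate(sprintf("`%s`", keep), "y"),
                   data = deltas)
  expect_equal(unname(stats::coef(fit)["`piperacillin-tazobactam`"]), -1.5,
               tolerance = 0.5 / 1.5)
})

test_that("fixtures regenerate byte-identically and round-trip through the reader", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 4L)
  p1 <- write_fixtures(generate_cohort(cfg, seed = 9), dir1)
  p2 <- write_fixtures(generate_cohort(cfg, seed = 9), dir2)
  for (f in names(p1))
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])), label = f)
  cohort <- generate_cohort(cfg, seed = 9)
  rt <- read_cohort(p1["taxa"], p1["qpcr"], p1["meds"], p1["meta"])
  expect_identical(rt$samples$sample_id, cohort$samples$sample_id)
  expect_equal(rt$samples$rel_abundance, cohort$samples$rel_abundance,
               tolerance = 1e-12)
  expect_equal(rt$samples$qpcr_total, cohort$samples$qpcr_total,
               tolerance = 1e-12)
  expect_identical(rt$metas$discharge_day, cohort$metas$discharge_day)
  expect_identical(rt$exposures$covariate, cohort$exposures$covariate)
})

test_that("an empty cohort writes headers-only sample tables", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 2L, retention_prob = 0)
  cohort <- generate_cohort(cfg, seed = 1)
  expect_null(cohort$samples)
  paths <- write_fixtures(cohort, dir)
  expect_equal(length(readLines(paths["taxa"])), 1)
  expect_equal(length(readLines(paths["qpcr"])), 1)
})

test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(retention_prob = 1.2))
  expect_error(cohort_config(n_patients = 0L))
  expect_error(cohort_config(hospitalization_range = c(0L, 0L)))
  expect_error(cohort_config(not_a_field = 1), "unknown config field")
})
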