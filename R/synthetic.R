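#' Taxon panel used by the synthetic cohort generator
#'
#' 27 gut taxa spanning the commensal obligate anaerobe groups (Clostridia,
#' Negativicutes, Bacteroidetes including a class-unassigned lineage,
#' Fusobacteria) and common facultative/aerotolerant groups (Bacilli,
#' Gammaproteobacteria, Actinobacteria), so taxonomic grouping, diversity
#' and volatility are all exercised.
#'
#' @return data.frame `lineage`, `anaerobe`.
#' @export
taxa_panel <- function() {
  L <- make_lineage
  an <- c(
    L("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Blautia"),
    L("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Roseburia"),
    L("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Coprococcus"),
    L("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Dorea"),
    L("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Anaerostipes"),
    L("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae",
      "Faecalibacterium", "prausnitzii"),
    L("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "Ruminococcus"),
    L("Firmicutes", "Clostridia", "Clostridiales", "Clostridiaceae", "Clostridium"),
    L("Firmicutes", "Clostridia", "Clostridiales", "Eubacteriaceae", "Eubacterium"),
    L("Firmicutes", "Negativicutes", "Veillonellales", "Veillonellaceae", "Veillonella"),
    L("Firmicutes", "Negativicutes", "Veillonellales", "Veillonellaceae", "Megasphaera"),
    L("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Bacteroidaceae", "Bacteroides"),
    L("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae", "Parabacteroides"),
    L("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae", "Prevotella"),
    L("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Rikenellaceae", "Alistipes"),
    L("Bacteroidetes"),  # class-unassigned: grouped as unclassified-Bacteroidetes
    L("Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Fusobacteriaceae", "Fusobacterium"))
  ot <- c(
    L("Firmicutes", "Bacilli", "Lactobacillales", "Enterococcaceae", "Enterococcus"),
    L("Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae", "Lactobacillus"),
    L("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae", "Streptococcus"),
    L("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae", "Lactococcus"),
    L("Firmicutes", "Bacilli", "Bacillales", "Staphylococcaceae", "Staphylococcus"),
    L("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
      "Enterobacteriaceae", "Escherichia", "coli"),
    L("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
      "Enterobacteriaceae", "Klebsiella"),
    L("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
      "Enterobacteriaceae", "Raoultella"),
    L("Actinobacteria", "Actinobacteria", "Bifidobacteriales",
      "Bifidobacteriaceae", "Bifidobacterium"),
    L("Actinobacteria", "Actinobacteria", "Actinomycetales",
      "Actinomycetaceae", "Actinomyces"))
  data.frame(lineage = c(an, ot),
             anaerobe = rep(c(TRUE, FALSE), c(length(an), length(ot))),
             stringsAsFactors = FALSE)
}

#' Synthetic cohort generator configuration
#'
#' Defaults emulate an 18-patient HCT inpatient cohort: 14/18 allogeneic,
#' conditioning starting 7-10 days before cell infusion (day 0),
#' engraftment on day 10-20, hospitalization of 20-38 days, a 0.77
#' probability that a given inpatient day yields a stool sample and a 0.87
#' probability that a collected sample amplifies. Prophylaxis follows HCT
#' service practice: oral ciprofloxacin from day -2 through engraftment for
#' everyone, i.v. vancomycin for allogeneic recipients, and
#' trimethoprim-sulfamethoxazole or atovaquone started either during
#' conditioning or after engraftment. A new fever during phase II
#' neutropenia triggers an empirical course (piperacillin-tazobactam,
#' cefepime or meropenem) of 5-10 days.
#'
#' The generative trajectory law is exactly the fitted model: daily
#' log-density increments equal the linear predictor plus Normal(0, sigma_m)
#' shocks. Observation noise is a log10-scale qPCR multiplier (sd
#' `qpcr_sd_log10`) and Dirichlet compositional noise (concentration
#' `dirichlet_conc`; `Inf` for exact compositions).
#'
#' @param ... overrides for any default field (see the function body).
#' @return config list of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_patients = 18L,
    frac_allo = 14 / 18,
    conditioning_days = c(7L, 10L),
    engraftment_range = c(10L, 20L),
    hospitalization_range = c(20L, 38L),
    retention_prob = 0.77,
    amplification_prob = 0.87,
    params = list(
      r = 0.2, beta_p1 = -0.1, beta_p2 = -0.3,
      beta_a = c("piperacillin-tazobactam" = -1.5, "meropenem" = -1.2,
                 "metronidazole" = -0.4, "cephalosporins-1-3" = -0.3,
                 "vancomycin-po" = -0.2, "cefepime" = -0.6,
                 "linezolid" = -0.1),
      beta_o = -0.05,
      o_dev = c("fluoroquinolones" = -0.02, "vancomycin-iv" = -0.03,
                "trimethoprim-sulfamethoxazole" = 0, "atovaquone" = 0.02),
      p_int_sd = 0.1, beta_c = 0, sigma_m = 0.5),
    N_ref = 1e11,
    fever_prob = 0.85,
    empirical_probs = c("piperacillin-tazobactam" = 0.5, "cefepime" = 0.25,
                        "meropenem" = 0.25),
    course_length_range = c(5L, 10L),
    pjp_probs = c("trimethoprim-sulfamethoxazole" = 0.45,
                  "atovaquone" = 0.25, "none" = 0.30),
    pjp_early_prob = 0.3,
    log10_N0 = c(mean = 10.5, sd = 0.4),
    log10_M0 = c(mean = 9.5, sd = 0.3),
    other_walk_sd_log10 = 0.1,
    dirichlet_conc = 5e4,
    rel_detection = 1e-4,
    qpcr_sd_log10 = 0.05,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  .validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

.validate_config <- function(cfg) {
  pr <- c(cfg$retention_prob, cfg$amplification_prob, cfg$frac_allo,
          cfg$fever_prob, cfg$pjp_early_prob)
  stopifnot(all(pr >= 0 & pr <= 1), cfg$n_patients >= 1,
            cfg$params$sigma_m >= 0, cfg$params$p_int_sd >= 0,
            cfg$dirichlet_conc > 0, cfg$N_ref > 0,
            cfg$rel_detection >= 0, cfg$rel_detection < 0.03,
            diff(cfg$hospitalization_range) >= 0,
            cfg$hospitalization_range[1] >= 1)
  invisible(cfg)
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

.sample_range <- function(rng) if (rng[1] == rng[2]) rng[1] else
  sample(seq(rng[1], rng[2]), 1)

#' Generate a synthetic cohort with known ground truth
#'
#' Per patient, a daily latent obligate anaerobe density evolves by the
#' model's mean law plus Normal(0, sigma_m) shocks in log space; an
#' independent non-anaerobe density follows a log10 random walk; observed
#' samples are produced on retained days as a Dirichlet composition around
#' the latent anaerobe/other split across [taxa_panel()], with a noisy qPCR
#' total.
#'
#' @param config from [cohort_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list of class `synthetic_cohort`: `samples` (long table as from
#'   [read_cohort()]), `exposures`, `metas`, `truth` (generative parameters,
#'   per-patient latent daily densities, patient intercepts).
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  .validate_config(config)
  set.seed(seed)
  p <- config$params
  panel <- taxa_panel()
  n_an <- sum(panel$anaerobe); n_ot <- sum(!panel$anaerobe)
  pids <- sprintf("P%02d", seq_len(config$n_patients))
  n_allo <- round(config$frac_allo * config$n_patients)
  allo <- pids %in% sample(pids, n_allo)

  metas <- exposures <- samples <- latent <- list()
  p_int <- stats::setNames(stats::rnorm(length(pids), 0, p$p_int_sd), pids)

  for (i in seq_along(pids)) {
    pid <- pids[i]
    cond_start <- -.sample_range(config$conditioning_days)
    engraft <- .sample_range(config$engraftment_range)
    admit <- cond_start
    lo <- max(config$hospitalization_range[1], engraft - admit + 3)
    hosp_len <- .sample_range(c(lo, max(lo, config$hospitalization_range[2])))
    discharge <- admit + hosp_len - 1
    metas[[pid]] <- data.frame(
      patient_id = pid, transplant_type = if (allo[i]) "allo" else "auto",
      conditioning_start_day = as.integer(cond_start),
      engraftment_day = as.integer(engraft), admit_day = as.integer(admit),
      discharge_day = as.integer(discharge), stringsAsFactors = FALSE)

    med <- list(list(pid, "ciprofloxacin", "po", -2L, engraft))
    if (allo[i]) med <- c(med, list(list(pid, "vancomycin", "iv", admit, engraft)))
    agent <- sample(names(config$pjp_probs), 1, prob = config$pjp_probs)
    if (agent != "none") {
      start <- if (stats::runif(1) < config$pjp_early_prob) admit else engraft + 1L
      if (start <= discharge)
        med <- c(med, list(list(pid, agent, "po", start, discharge)))
    }
    if (stats::runif(1) < config$fever_prob && engraft >= 2) {
      fever <- sample(seq(1L, engraft - 1L), 1)
      drug <- sample(names(config$empirical_probs), 1,
                     prob = config$empirical_probs)
      len <- .sample_range(config$course_length_range)
      med <- c(med, list(list(pid, drug, "iv", fever,
                              min(fever + len - 1L, discharge))))
    }
    med <- do.call(rbind, lapply(med, function(m)
      data.frame(patient_id = m[[1]], drug = m[[2]], route = m[[3]],
                 start_day = as.integer(m[[4]]), end_day = as.integer(m[[5]]),
                 stringsAsFactors = FALSE)))
    cls <- t(mapply(function(d, r) unlist(abx_class_map(d, r)),
                    med$drug, med$route))
    med$covariate <- unname(cls[, "covariate"]); med$category <- unname(cls[, "category"])
    exposures[[pid]] <- med

    days <- seq(admit, discharge)
    logN <- numeric(length(days))
    logN[1] <- log(10^stats::rnorm(1, config$log10_N0["mean"],
                                   config$log10_N0["sd"]))
    for (d in seq_len(length(days) - 1)) {
      t0 <- days[d]; t1 <- days[d] + 1L
      cov <- .interval_covariates(med, t0, t1)
      mu <- p$r +
        p$beta_p1 * .phase_flag(t0, t1, cond_start, 0) +
        p$beta_p2 * .phase_flag(t0, t1, 0, engraft) +
        sum(p$beta_a * cov[names(p$beta_a)]) +
        sum((p$beta_o + p$o_dev) * cov[names(p$o_dev)]) +
        p_int[pid] + p$beta_c * exp(logN[d]) / config$N_ref
      logN[d + 1] <- logN[d] + mu + stats::rnorm(1, 0, p$sigma_m)
    }
    log10M <- cumsum(c(stats::rnorm(1, config$log10_M0["mean"],
                                    config$log10_M0["sd"]),
                       stats::rnorm(length(days) - 1, 0,
                                    config$other_walk_sd_log10)))
    N <- exp(logN); M <- 10^log10M
    latent[[pid]] <- data.frame(patient_id = pid, day = days, N = N, M = M,
                                stringsAsFactors = FALSE)

    w_an <- .rdirichlet(rep(2, n_an)); w_ot <- .rdirichlet(rep(2, n_ot))
    keep <- stats::runif(length(days)) <
      config$retention_prob * config$amplification_prob
    for (d in which(keep)) {
      f <- N[d] / (N[d] + M[d])
      target <- numeric(nrow(panel))
      target[panel$anaerobe] <- f * w_an
      target[!panel$anaerobe] <- (1 - f) * w_ot
      rel <- if (is.finite(config$dirichlet_conc))
        .rdirichlet(config$dirichlet_conc * target + 1e-12) else target
      # finite read depth: fractions below the detection limit read as zero
      rel[rel < config$rel_detection] <- 0
      rel <- rel / sum(rel)
      qpcr <- (N[d] + M[d]) * 10^stats::rnorm(1, 0, config$qpcr_sd_log10)
      samples[[length(samples) + 1]] <- data.frame(
        sample_id = sprintf("%s_d%03d", pid, d), patient_id = pid,
        day = days[d], lineage = panel$lineage, rel_abundance = rel,
        qpcr_total = qpcr, stringsAsFactors = FALSE)
    }
  }
  rbind_all <- function(lst) if (length(lst) == 0) NULL else
    do.call(rbind, c(lst, list(make.row.names = FALSE)))
  structure(list(
    samples = rbind_all(samples),
    exposures = rbind_all(exposures),
    metas = rbind_all(metas),
    truth = list(params = p, p_int = p_int, latent = rbind_all(latent),
                 config = config, seed = seed)),
    class = c("synthetic_cohort", "anaerodyn_cohort"))
}

#' Write a cohort to its four on-disk tables (plus ground truth)
#'
#' Emits `cohort.taxa.tsv`, `cohort.qpcr.csv`, `cohort.meds.csv`,
#' `cohort.meta.csv` in the schema read by [read_cohort()], and, for
#' synthetic cohorts, `truth_params.json` and `truth_latent.csv`.
#' Regeneration with the same seed yields byte-identical files.
#'
#' @param cohort a cohort list (`samples`, `exposures`, `metas`, optionally
#'   `truth`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
write_fixtures <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  s <- cohort$samples
  paths <- c(taxa = file.path(out_dir, "cohort.taxa.tsv"),
             qpcr = file.path(out_dir, "cohort.qpcr.csv"),
             meds = file.path(out_dir, "cohort.meds.csv"),
             meta = file.path(out_dir, "cohort.meta.csv"))
  taxa_cols <- c("sample_id", "patient_id", "day", "lineage", "rel_abundance")
  if (is.null(s) || nrow(s) == 0) {
    s <- data.frame(sample_id = character(0), patient_id = character(0),
                    day = integer(0), lineage = character(0),
                    rel_abundance = numeric(0), qpcr_total = numeric(0))
  }
  utils::write.table(s[taxa_cols], paths["taxa"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  qpcr <- unique(s[c("sample_id", "qpcr_total")])
  names(qpcr) <- c("sample_id", "copies_per_g")
  utils::write.csv(qpcr, paths["qpcr"], row.names = FALSE, quote = FALSE)
  med_cols <- c("patient_id", "drug", "route", "start_day", "end_day")
  utils::write.csv(cohort$exposures[med_cols], paths["meds"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$metas, paths["meta"], row.names = FALSE,
                   quote = FALSE)
  if (!is.null(cohort$truth)) {
    paths <- c(paths,
               truth_params = file.path(out_dir, "truth_params.json"),
               truth_latent = file.path(out_dir, "truth_latent.csv"))
    tr <- cohort$truth
    jsonlite::write_json(list(params = tr$params, p_int = as.list(tr$p_int),
                              seed = tr$seed),
                         paths["truth_params"], auto_unbox = TRUE, digits = NA)
    utils::write.csv(tr$latent, paths["truth_latent"], row.names = FALSE,
                     quote = FALSE)
  }
  invisible(paths)
}
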