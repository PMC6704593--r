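# Small in-code fixtures shared across tests.

toy_meta <- function(pid, cond = -7L, engraft = 10L, admit = cond,
                     discharge = 20L, type = "allo") {
  data.frame(patient_id = pid, transplant_type = type,
             conditioning_start_day = cond, engraftment_day = engraft,
             admit_day = admit, discharge_day = discharge,
             stringsAsFactors = FALSE)
}

exposure_row <- function(pid, drug, route, start, end) {
  cls <- abx_class_map(drug, route)
  data.frame(patient_id = pid, drug = drug, route = route,
             start_day = as.integer(start), end_day = as.integer(end),
             covariate = cls$covariate, category = cls$category,
             stringsAsFactors = FALSE)
}

empty_exposures <- function() {
  data.frame(patient_id = character(0), drug = character(0),
             route = character(0), start_day = integer(0),
             end_day = integer(0), covariate = character(0),
             category = character(0), stringsAsFactors = FALSE)
}

# one long-format sample; rel is a named vector lineage -> fraction
toy_sample <- function(sample_id, pid, day, rel, qpcr) {
  data.frame(sample_id = sample_id, patient_id = pid, day = as.integer(day),
             lineage = names(rel), rel_abundance = unname(rel),
             qpcr_total = qpcr, stringsAsFactors = FALSE)
}

# density_series-shaped table from explicit values
toy_density <- function(pid, days, N, total = pmax(N, 1) * 2) {
  data.frame(patient_id = pid, day = as.integer(days), N = N, total = total,
             diversity = 1, stringsAsFactors = FALSE)
}

lin_clostridia <- make_lineage("Firmicutes", "Clostridia", "Clostridiales",
                               "Lachnospiraceae", "Blautia")
lin_bacteroides <- make_lineage("Bacteroidetes", "Bacteroidia",
                                "Bacteroidales", "Bacteroidaceae",
                                "Bacteroides")
lin_entero <- make_lineage("Proteobacteria", "Gammaproteobacteria",
                           "Enterobacterales", "Enterobacteriaceae",
                           "Escherichia", "coli")
lin_bacilli <- make_lineage("Firmicutes", "Bacilli", "Lactobacillales",
                            "Enterococcaceae", "Enterococcus")

# random composition over k named genera
random_comp <- function(k, labels = paste0("g", seq_len(k))) {
  x <- stats::rgamma(k, 1)
  stats::setNames(x / sum(x), labels)
}

# Hand-enumerated two-patient fixture used for the delta-construction oracle.
# Patient A (admit -7, conditioning -7, engraftment 10, discharge 20):
#   days -3, -2, 0, 3, 4, 5 with N = 1e9, 1e8, 1e7, 1e7, 0, 1e6
#   piperacillin-tazobactam days -3..-1; ciprofloxacin (po) days -2..10
# Admissible pairs: (-3,-2) dt 1, (-2,0) dt 2; (0,3) gap 3 dropped;
# (3,4) and (4,5) have a censored endpoint (N=0) and drop by default.
# Patient B (admit -5, engraftment 10, discharge 15):
#   days 11, 12, 14, 16 with N = 1e8, 1e8, 1e10, 1e9; meropenem days 12..13
# Admissible pairs: (11,12) dt 1, (12,14) dt 2; (14,16) leaves hospitalization.
delta_fixture <- function() {
  density <- rbind(toy_density("A", c(-3, -2, 0, 3, 4, 5),
                               c(1e9, 1e8, 1e7, 1e7, 0, 1e6)),
                   toy_density("B", c(11, 12, 14, 16),
                               c(1e8, 1e8, 1e10, 1e9)))
  exposures <- rbind(
    exposure_row("A", "piperacillin-tazobactam", "iv", -3, -1),
    exposure_row("A", "ciprofloxacin", "po", -2, 10),
    exposure_row("B", "meropenem", "iv", 12, 13))
  metas <- rbind(toy_meta("A", cond = -7, engraft = 10, discharge = 20),
                 toy_meta("B", cond = -5, engraft = 10, discharge = 15))
  list(density = density, exposures = exposures, metas = metas)
}

expected_deltas <- function() {
  z <- function(...) {
    cov <- stats::setNames(rep(0L, 11), covariate_labels())
    on <- c(...)
    cov[on] <- 1L
    cov
  }
  out <- data.frame(
    patient_id = c("A", "A", "B", "B"),
    t_start = c(-3L, -2L, 11L, 12L), t_end = c(-2L, 0L, 12L, 14L),
    delta_t = c(1L, 2L, 1L, 2L),
    y = c(log(1e8 / 1e9) / 1, log(1e7 / 1e8) / 2, 0, log(1e10 / 1e8) / 2),
    N_start_scaled = c(1e9, 1e8, 1e8, 1e8) / 1e11,
    phase1 = c(1L, 1L, 0L, 0L), phase2 = c(0L, 1L, 0L, 0L),
    stringsAsFactors = FALSE, check.names = FALSE)
  covs <- rbind(z("piperacillin-tazobactam", "fluoroquinolones"),
                z("piperacillin-tazobactam", "fluoroquinolones"),
                z("meropenem"), z("meropenem"))
  out[colnames(covs)] <- as.data.frame(covs)
  out
}
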