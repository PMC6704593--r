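#' Run the full analysis pipeline on a synthetic or on-disk cohort
#'
#' Orchestrates simulate (or load) -> density/diversity -> volatility ->
#' deltas -> model fit -> posterior summary -> course compilation -> course
#' loss, writing every stage's table plus a run manifest to `out_dir`:
#' `density.csv`, `volatility.csv`, `deltas.csv`, `posterior.csv` (one row
#' per draw with chain index), `summary.csv`, `loss.csv`, `manifest.json`.
#' Deterministic given `seed`. With `plots = TRUE`, headless-safe PDF
#' figure analogs (density/diversity timelines, volatility series, effect
#' forest, fold-change histograms) are also written.
#'
#' @param out_dir output directory.
#' @param config [cohort_config()] for the synthetic cohort, or `NULL` when
#'   `cohort_paths` is given.
#' @param cohort_paths optional named vector/list with `taxa`, `qpcr`,
#'   `meds`, `meta` paths of an on-disk cohort (stage "io").
#' @param seed integer master seed.
#' @param chains,draws,warmup sampler settings (see [fit_anaerobe_model()]).
#' @param n_resamples course-loss resamples per drug.
#' @param loss_drugs covariate labels to predict course loss for; labels
#'   with no compiled course are skipped with a message.
#' @param plots write PDF figure analogs.
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(out_dir, config = cohort_config(),
                         cohort_paths = NULL, seed = 1, chains = 3,
                         draws = 10000, warmup = 1000, n_resamples = 10000,
                         loss_drugs = c("piperacillin-tazobactam",
                                        "meropenem"),
                         plots = FALSE) {
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message("stage ", name, ": done")
    res
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (is.null(cohort_paths)) {
    stage("simulate", generate_cohort(config, seed = seed))
  } else {
    stage("io", read_cohort(cohort_paths[["taxa"]], cohort_paths[["qpcr"]],
                            cohort_paths[["meds"]], cohort_paths[["meta"]]))
  }
  density <- stage("densities", density_series(cohort$samples))
  vol <- stage("volatility", cohort_volatility(cohort$samples))
  deltas <- stage("deltas",
                  build_deltas(density, cohort$exposures, cohort$metas))
  post <- stage("fit", fit_anaerobe_model(deltas, chains = chains,
                                          draws = draws, warmup = warmup,
                                          seed = seed))
  summ <- stage("summarize", summary(post))
  courses <- stage("courses", compile_courses(cohort$exposures, cohort$metas))
  losses <- stage("predict", {
    have <- unique(vapply(courses, `[[`, character(1), "label"))
    out <- list()
    for (drug in loss_drugs) {
      if (!drug %in% have) { message("no courses for ", drug, "; skipped"); next }
      out[[drug]] <- predict_course_loss(post, courses, drug,
                                         n_resamples = n_resamples,
                                         seed = seed)
    }
    out
  })

  f <- function(x) file.path(out_dir, x)
  utils::write.csv(density, f("density.csv"), row.names = FALSE)
  utils::write.csv(vol, f("volatility.csv"), row.names = FALSE)
  utils::write.csv(deltas, f("deltas.csv"), row.names = FALSE)
  post_df <- data.frame(chain = post$chain, post$draws, check.names = FALSE)
  utils::write.csv(post_df, f("posterior.csv"), row.names = FALSE)
  utils::write.csv(summ, f("summary.csv"), row.names = FALSE)
  loss_df <- do.call(rbind, lapply(losses, function(l) data.frame(
    drug = l$label, residual_fraction = l$residual_fraction,
    percent_loss = l$percent_loss, fold_q2.5 = unname(l$fold_q[1]),
    fold_q97.5 = unname(l$fold_q[2]), stringsAsFactors = FALSE)))
  if (is.null(loss_df)) loss_df <- data.frame(drug = character(0))
  utils::write.csv(loss_df, f("loss.csv"), row.names = FALSE)
  if (plots) .pipeline_plots(out_dir, density, vol, summ, losses)
  .write_manifest(out_dir, config, seed,
                  list(chains = chains, draws = draws, warmup = warmup,
                       n_resamples = n_resamples))
  invisible(list(cohort = cohort, density = density, volatility = vol,
                 deltas = deltas, posterior = post, summary = summ,
                 courses = courses, losses = losses))
}

.write_manifest <- function(out_dir, config, seed, sampler) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  inv <- file.path(out_dir, outputs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("anaerodyn")),
    seed = seed, sampler = sampler,
    config_md5 = unname(tools::md5sum(tmp)),
    outputs = stats::setNames(as.list(unname(tools::md5sum(inv))), outputs))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.pipeline_plots <- function(out_dir, density, vol, summ, losses) {
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 8, height = 6)
  on.exit(grDevices::dev.off())
  plot(density$day, log10(pmax(density$total, 1)), col = "grey40", pch = 1,
       xlab = "day relative to infusion",
       ylab = "log10 16S copies/g", main = "Density during HCT")
  graphics::points(density$day, log10(pmax(density$N, 1)), col = "brown", pch = 16)
  graphics::legend("bottomleft", c("total", "obligate anaerobes"),
                   col = c("grey40", "brown"), pch = c(1, 16), bty = "n")
  plot(density$day, density$diversity, xlab = "day", ylab = "inverse Simpson",
       main = "Diversity during HCT")
  plot(vol$midpoint_time, vol$V, xlab = "day", ylab = "volatility V",
       ylim = c(0, 1), main = "Compositional volatility")
  k <- nrow(summ)
  plot(summ$mean, seq_len(k), xlim = range(c(summ$lower, summ$upper)),
       yaxt = "n", xlab = "effect on growth rate (1/day)", ylab = "",
       main = "Posterior effects (95% CI)", pch = 16)
  graphics::segments(summ$lower, seq_len(k), summ$upper, seq_len(k))
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(k), labels = summ$parameter, las = 2,
                 cex.axis = 0.6)
  for (l in losses)
    graphics::hist(log10(l$fold_changes), breaks = 40,
                   xlab = "log10 fold change of anaerobe density",
                   main = paste("Predicted course loss:", l$label))
}
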