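#' @title Posterior forward simulation and course-level loss prediction
#' @name anaerobe_predict
NULL

# Per-draw linear predictor for one covariate configuration.
# a, pr: named 0/1 vectors over the empirical/prophylactic labels;
# patient: id, contributing its random intercept when present in the
# posterior (new patients contribute 0, the intercept prior mean);
# n_scaled: capacity regressor value.
.mu_draws <- function(post, rows, phase1, phase2, a, pr, patient, n_scaled) {
  d <- post$draws[rows, , drop = FALSE]
  emp <- post$labels$empirical; pro <- post$labels$prophylactic
  mu <- d[, "r"] + d[, "beta_p1"] * phase1 + d[, "beta_p2"] * phase2 +
    as.numeric(d[, sprintf("beta_a[%s]", emp), drop = FALSE] %*% a[emp]) +
    sum(pr) * d[, "beta_o"] +
    as.numeric(d[, sprintf("o_dev[%s]", pro), drop = FALSE] %*% pr[pro]) +
    d[, "beta_c"] * n_scaled
  pcol <- sprintf("p_int[%s]", patient)
  if (pcol %in% colnames(d)) mu <- mu + d[, pcol]
  mu
}

.interval_covariates <- function(exp_p, t0, t1) {
  vapply(covariate_labels(), function(lab) {
    e <- exp_p[exp_p$covariate == lab, , drop = FALSE]
    as.numeric(any(e$start_day <= t1 & e$end_day >= t0))
  }, numeric(1))
}

#' Forward-simulate one patient's anaerobe trajectory
#'
#' Starts from the patient's first observed anaerobe density and advances
#' along the observed sampling days. For each step of length delta_t, the
#' predicted per-day log change mu is computed under `n_draws` parameter
#' vectors drawn jointly from the posterior (no observation noise: the
#' latent density is predicted, not a noisy measurement) and the density is
#' advanced by exp(mean(mu) * delta_t). The capacity term uses the running
#' simulated density scaled by `N_ref`.
#'
#' @param posterior an `anaerobe_posterior`.
#' @param density [density_series()] rows of a single patient (>= 1 row).
#' @param exposures resolved exposure table for the cohort.
#' @param meta metadata row(s); the patient's row is used for phase windows.
#' @param n_draws posterior draws per step.
#' @param N_ref capacity density scale, copies/g (match [build_deltas()]).
#' @param seed optional integer seed for the per-step posterior subsampling.
#' @return data.frame `patient_id, day, N_pred, N_obs` aligned to the
#'   observation days.
#' @export
forward_simulate_patient <- function(posterior, density, exposures, meta,
                                     n_draws = 100, N_ref = 1e11,
                                     seed = NULL) {
  stopifnot(nrow(density) >= 1, length(unique(density$patient_id)) == 1)
  if (!is.null(seed)) set.seed(seed)
  pid <- density$patient_id[1]
  meta <- meta[meta$patient_id == pid, , drop = FALSE]
  stopifnot(nrow(meta) == 1)
  exp_p <- exposures[exposures$patient_id == pid, , drop = FALSE]
  days <- density$day
  if (is.unsorted(days, strictly = TRUE)) stop("non-monotone sample days")

  N <- numeric(length(days))
  N[1] <- density$N[1]
  ndraw_tot <- nrow(posterior$draws)
  for (i in seq_len(length(days) - 1)) {
    t0 <- days[i]; t1 <- days[i + 1]; dt <- t1 - t0
    cov <- .interval_covariates(exp_p, t0, t1)
    rows <- sample.int(ndraw_tot, min(n_draws, ndraw_tot), replace = ndraw_tot < n_draws)
    mu <- .mu_draws(posterior, rows,
                    phase1 = .phase_flag(t0, t1, meta$conditioning_start_day, 0),
                    phase2 = .phase_flag(t0, t1, 0, meta$engraftment_day),
                    a = cov[empirical_labels()],
                    pr = cov[prophylactic_labels()],
                    patient = pid, n_scaled = N[i] / N_ref)
    N[i + 1] <- N[i] * exp(mean(mu) * dt)
  }
  data.frame(patient_id = pid, day = days, N_pred = N, N_obs = density$N,
             stringsAsFactors = FALSE)
}

#' Compile antibiotic courses as they occurred in a cohort
#'
#' A course is a maximal run of consecutive administration days of one
#' covariate (drug class) in one patient. Each course carries its day-by-day
#' context: the phase I/II flags of each day and the indicators of all
#' coadministered covariates on that day (its own indicator is 1 on every
#' day by construction).
#'
#' @param exposures resolved exposure table.
#' @param metas patient metadata table.
#' @return list of course records, each a list with `patient_id`, `label`,
#'   `days`, `duration` and `context` (data.frame: day, phase1, phase2, one
#'   column per covariate label).
#' @export
compile_courses <- function(exposures, metas) {
  labs <- covariate_labels()
  out <- list()
  for (pid in unique(exposures$patient_id)) {
    exp_p <- exposures[exposures$patient_id == pid, , drop = FALSE]
    meta <- metas[metas$patient_id == pid, , drop = FALSE]
    stopifnot(nrow(meta) == 1)
    for (lab in unique(exp_p$covariate)) {
      e <- exp_p[exp_p$covariate == lab, , drop = FALSE]
      days <- sort(unique(unlist(mapply(seq, e$start_day, e$end_day,
                                        SIMPLIFY = FALSE))))
      runs <- split(days, cumsum(c(1, diff(days) > 1)))
      for (run in runs) {
        ctx <- data.frame(day = run,
                          phase1 = as.integer(run >= meta$conditioning_start_day & run < 0),
                          phase2 = as.integer(run >= 0 & run < meta$engraftment_day),
                          check.names = FALSE)
        for (l2 in labs) {
          e2 <- exp_p[exp_p$covariate == l2, , drop = FALSE]
          ctx[[l2]] <- vapply(run, function(d)
            as.integer(any(e2$start_day <= d & e2$end_day >= d)), integer(1))
        }
        out[[length(out) + 1]] <- list(patient_id = pid, label = lab,
                                       days = run, duration = length(run),
                                       context = ctx)
      }
    }
  }
  out
}

#' Predict anaerobe loss over realistic courses of one antibiotic
#'
#' Monte-Carlo estimate of the residual fraction of obligate anaerobes after
#' a typical course of the given antibiotic. Each resample draws a course
#' uniformly with replacement from the compiled course list and one joint
#' parameter vector from the posterior, then integrates the mean model day
#' by day from a normalized starting density of 1 (interpreted as `N_ref`
#' on the capacity scale), recording the end-of-course fold change
#' exp(sum of daily mu). Coadministered antibiotics and the phase of each
#' course day contribute their fitted effects, as does the course patient's
#' random intercept.
#'
#' @param posterior an `anaerobe_posterior`.
#' @param courses list from [compile_courses()].
#' @param label covariate label of the antibiotic of interest.
#' @param n_resamples number of (course, draw) resamples.
#' @param seed integer seed.
#' @return object of class `loss_estimate`: list with `label`,
#'   `fold_changes`, `residual_fraction` (mean fold change), `percent_loss`
#'   = 100 (1 - residual_fraction), and 2.5/97.5% fold-change quantiles.
#' @export
predict_course_loss <- function(posterior, courses, label,
                                n_resamples = 10000, seed = 1) {
  stopifnot(n_resamples >= 1)
  cs <- Filter(function(x) x$label == label, courses)
  if (length(cs) == 0) stop("no compiled courses for '", label, "'")
  set.seed(seed)
  emp <- posterior$labels$empirical; pro <- posterior$labels$prophylactic
  ci <- sample.int(length(cs), n_resamples, replace = TRUE)
  di <- sample.int(nrow(posterior$draws), n_resamples, replace = TRUE)
  fold <- numeric(n_resamples)
  for (k in seq_along(cs)) {
    sel <- which(ci == k)
    if (!length(sel)) next
    crs <- cs[[k]]
    # daily linear effect excluding capacity: theta %*% context row
    pcol <- sprintf("p_int[%s]", crs$patient_id)
    cols <- c("r", "beta_p1", "beta_p2", sprintf("beta_a[%s]", emp),
              "beta_o", sprintf("o_dev[%s]", pro))
    C <- cbind(1, crs$context$phase1, crs$context$phase2,
               as.matrix(crs$context[emp]),
               rowSums(crs$context[pro]), as.matrix(crs$context[pro]))
    th <- posterior$draws[di[sel], cols, drop = FALSE]
    E <- th %*% t(C)                       # resample x day
    if (pcol %in% colnames(posterior$draws))
      E <- E + posterior$draws[di[sel], pcol]
    bc <- posterior$draws[di[sel], "beta_c"]
    logN <- numeric(length(sel))
    for (d in seq_len(crs$duration))
      logN <- logN + E[, d] + bc * exp(logN)
    fold[sel] <- exp(logN)
  }
  rf <- mean(fold)
  structure(list(label = label, fold_changes = fold,
                 residual_fraction = rf, percent_loss = 100 * (1 - rf),
                 fold_q = stats::quantile(fold, c(0.025, 0.975)),
                 n_resamples = n_resamples, n_courses = length(cs)),
            class = "loss_estimate")
}

#' @export
print.loss_estimate <- function(x, ...) {
  cat(sprintf(
    "course loss for %s: residual fraction %.4g (%.2f%% loss) over %d resamples of %d course(s)\n",
    x$label, x$residual_fraction, x$percent_loss, x$n_resamples, x$n_courses))
  invisible(x)
}
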