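#' Build the growth-regression dataset of per-day log changes
#'
#' Each observation (a "delta") is the per-day natural-log change in
#' obligate anaerobe density between two adjacent samples of one patient
#' that are at most 2 days apart and both within the first hospitalization:
#'
#'   y = (log N(t_end) - log N(t_start)) / delta_t      [1/day]
#'
#' A zero anaerobe density is a censored measurement: the population is
#' below the sequencing detection limit, which is a per-sample *fraction*
#' of the community, not a fixed density. `zero_policy` controls how such
#' pairs enter the regression:
#' \describe{
#'   \item{"drop" (default)}{pairs with any below-detection endpoint are
#'     excluded. The remaining deltas are fully observed, so growth-rate
#'     estimates are unbiased; the below-detection regime simply does not
#'     constrain the fit.}
#'   \item{"floor"}{zero densities are replaced by `floor` before logging
#'     (pairs with both endpoints censored are still dropped — they carry
#'     no rate information). This retains detection-crossing intervals but
#'     imputes the censored endpoint at a fixed density, which exaggerates
#'     the drop whenever the true density is above the global floor — e.g.
#'     when a bloom of other taxa pushes the anaerobe fraction below the
#'     detection limit — inflating both effect sizes and sigma_m.}
#' }
#' Covariates are binary indicators of exposure during the
#' interval: an antibiotic covariate is 1 iff any administration interval of
#' a drug mapping to that covariate intersects [t_start, t_end]; phase1 is 1
#' iff the interval intersects [conditioning_start_day, 0); phase2 iff it
#' intersects [0, engraftment_day). The capacity regressor is the
#' start-of-interval density scaled by `N_ref`.
#'
#' Only adjacent samples are paired (never all pairs within 2 days), so no
#' day contributes to two overlapping intervals.
#'
#' @param density density/diversity table from [density_series()].
#' @param exposures resolved exposure table (see [read_cohort()]).
#' @param metas patient metadata table.
#' @param N_ref density scale for the capacity regressor, copies/g. The
#'   default 1e11 is the order of magnitude of a healthy gut community, so
#'   the capacity coefficient is O(1) under its regularizing prior.
#' @param floor detection floor for zero densities under
#'   `zero_policy = "floor"`, copies/g. Default: half the smallest nonzero
#'   anaerobe density in `density`.
#' @param zero_policy handling of below-detection densities; see Details.
#' @return data.frame with columns patient_id, t_start, t_end, delta_t, y,
#'   N_start_scaled, phase1, phase2, and one 0/1 column per covariate label
#'   (see [covariate_labels()]).
#' @export
build_deltas <- function(density, exposures, metas, N_ref = 1e11,
                         floor = NULL, zero_policy = c("drop", "floor")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(N_ref > 0)
  if (is.null(floor)) {
    pos <- density$N[density$N > 0]
    if (length(pos) == 0) stop("no nonzero anaerobe densities; supply a floor")
    floor <- min(pos) / 2
  }
  stopifnot(floor > 0)
  labs <- covariate_labels()

  rows <- lapply(split(density, density$patient_id), function(d) {
    if (is.unsorted(d$day, strictly = TRUE)) stop("non-monotone sample days")
    meta <- metas[metas$patient_id == d$patient_id[1], ]
    stopifnot(nrow(meta) == 1)
    exp_p <- exposures[exposures$patient_id == d$patient_id[1], , drop = FALSE]

    out <- list()
    for (i in seq_len(nrow(d) - 1)) {
      t0 <- d$day[i]; t1 <- d$day[i + 1]; dt <- t1 - t0
      if (dt > 2) next
      if (t0 < meta$admit_day || t1 > meta$discharge_day) next
      censored <- c(d$N[i], d$N[i + 1]) <= 0
      if (all(censored)) next
      if (zero_policy == "drop" && any(censored)) next
      N0 <- max(d$N[i], floor); N1 <- max(d$N[i + 1], floor)
      cov <- vapply(labs, function(lab) {
        e <- exp_p[exp_p$covariate == lab, , drop = FALSE]
        as.integer(any(e$start_day <= t1 & e$end_day >= t0))
      }, integer(1))
      rec <- data.frame(patient_id = d$patient_id[1], t_start = t0,
                        t_end = t1, delta_t = dt,
                        y = (log(N1) - log(N0)) / dt,
                        N_start_scaled = N0 / N_ref,
                        phase1 = .phase_flag(t0, t1, meta$conditioning_start_day, 0),
                        phase2 = .phase_flag(t0, t1, 0, meta$engraftment_day),
                        stringsAsFactors = FALSE, check.names = FALSE)
      rec[labs] <- as.list(cov)
      out[[length(out) + 1]] <- rec
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), t_start = integer(0),
                      t_end = integer(0), delta_t = integer(0),
                      y = numeric(0), N_start_scaled = numeric(0),
                      phase1 = integer(0), phase2 = integer(0),
                      check.names = FALSE)
    out[labs] <- lapply(labs, function(l) integer(0))
  }
  rownames(out) <- NULL
  attr(out, "N_ref") <- N_ref
  attr(out, "floor") <- floor
  out
}

# 1 iff the closed interval [t0, t1] intersects the half-open window [w0, w1)
.phase_flag <- function(t0, t1, w0, w1) as.integer(t0 < w1 && t1 >= w0)
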