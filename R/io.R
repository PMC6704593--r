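#' Read a cohort from its four tables
#'
#' A cohort comprises four plain UTF-8 tables:
#' \describe{
#'   \item{taxa (TSV)}{`sample_id, patient_id, day, lineage, rel_abundance` —
#'     one row per taxon per stool sample; `lineage` is a 7-rank
#'     semicolon-joined taxonomy string; fractions sum to 1 per sample.}
#'   \item{qpcr (CSV)}{`sample_id, copies_per_g` — total 16S gene copies per
#'     gram wet stool by qPCR.}
#'   \item{meds (CSV)}{`patient_id, drug, route, start_day, end_day` — one
#'     administration interval per row, whole days, closed on both ends.}
#'   \item{meta (CSV)}{`patient_id, transplant_type, conditioning_start_day,
#'     engraftment_day, admit_day, discharge_day`.}
#' }
#' Days are integers relative to hematopoietic cell infusion (day 0);
#' negative days precede the infusion.
#'
#' Schema and units are enforced at this boundary: per-sample abundance
#' vectors are renormalized to sum to 1 when the raw sum is within
#' `renorm_tol` of 1 (and rejected otherwise); sequenced samples without a
#' qPCR measurement are dropped with a warning; every drug must resolve
#' through `map` (unresolvable names are a hard error); medication intervals
#' that do not intersect the patient's first hospitalization are dropped with
#' a warning.
#'
#' @param taxa_path,qpcr_path,meds_path,meta_path file paths.
#' @param renorm_tol tolerance on the raw per-sample abundance sum.
#' @param map drug mapping table, see [abx_drug_map()].
#' @return an object of class `anaerodyn_cohort`: a list with data.frames
#'   `samples` (long; sample_id, patient_id, day, lineage, rel_abundance,
#'   qpcr_total), `exposures` (meds plus resolved covariate/category) and
#'   `metas`.
#' @seealso [write_fixtures()] for the writer that round-trips this format.
#' @export
read_cohort <- function(taxa_path, qpcr_path, meds_path, meta_path,
                        renorm_tol = 0.05, map = abx_drug_map()) {
  for (p in c(taxa_path, qpcr_path, meds_path, meta_path))
    if (!file.exists(p)) stop("input table not found: ", p)
  taxa <- utils::read.delim(taxa_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  qpcr <- utils::read.csv(qpcr_path, stringsAsFactors = FALSE)
  meds <- utils::read.csv(meds_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)

  .require_cols(taxa, c("sample_id", "patient_id", "day", "lineage",
                        "rel_abundance"), taxa_path)
  .require_cols(qpcr, c("sample_id", "copies_per_g"), qpcr_path)
  .require_cols(meds, c("patient_id", "drug", "route", "start_day",
                        "end_day"), meds_path)
  .require_cols(meta, c("patient_id", "transplant_type",
                        "conditioning_start_day", "engraftment_day",
                        "admit_day", "discharge_day"), meta_path)

  metas <- .validate_metas(meta)
  samples <- .join_and_normalize(taxa, qpcr, renorm_tol)
  exposures <- .resolve_exposures(meds, metas, map)

  structure(list(samples = samples, exposures = exposures, metas = metas),
            class = "anaerodyn_cohort")
}

#' @export
print.anaerodyn_cohort <- function(x, ...) {
  cat("anaerodyn cohort:",
      length(unique(x$samples$sample_id)), "samples from",
      nrow(x$metas), "patients;",
      nrow(x$exposures), "medication intervals\n")
  invisible(x)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("table ", path, " is missing column(s): ", paste(miss, collapse = ", "))
}

.validate_metas <- function(meta) {
  stopifnot(!anyDuplicated(meta$patient_id))
  if (!all(meta$transplant_type %in% c("auto", "allo")))
    stop("transplant_type must be 'auto' or 'allo'")
  with(meta, {
    if (any(conditioning_start_day >= 0)) stop("conditioning must start before day 0")
    if (any(engraftment_day < 0)) stop("engraftment_day must be >= 0")
    if (any(admit_day > conditioning_start_day))
      stop("admit_day must not exceed conditioning_start_day")
    if (any(discharge_day < conditioning_start_day))
      stop("discharge_day before conditioning start")
  })
  meta
}

.join_and_normalize <- function(taxa, qpcr, renorm_tol) {
  .validate_lineage(unique(taxa$lineage))
  if (any(taxa$rel_abundance < 0)) stop("negative relative abundance")
  if (anyDuplicated(qpcr$sample_id)) stop("duplicated sample_id in qPCR table")
  if (any(!is.finite(qpcr$copies_per_g) | qpcr$copies_per_g <= 0))
    stop("qPCR copies_per_g must be positive and finite")

  no_qpcr <- setdiff(unique(taxa$sample_id), qpcr$sample_id)
  if (length(no_qpcr)) {
    warning("dropping ", length(no_qpcr),
            " sequenced sample(s) without a qPCR measurement: ",
            paste(utils::head(no_qpcr, 5), collapse = ", "))
    taxa <- taxa[!taxa$sample_id %in% no_qpcr, , drop = FALSE]
  }
  sums <- tapply(taxa$rel_abundance, taxa$sample_id, sum)
  off <- abs(sums - 1) > renorm_tol
  if (any(off))
    stop("abundance sum outside tolerance (", renorm_tol, ") for sample(s): ",
         paste(utils::head(names(sums)[off], 5), collapse = ", "))
  taxa$rel_abundance <- taxa$rel_abundance /
    as.numeric(sums[as.character(taxa$sample_id)])
  taxa$qpcr_total <- qpcr$copies_per_g[match(taxa$sample_id, qpcr$sample_id)]
  taxa$day <- as.integer(taxa$day)
  rownames(taxa) <- NULL
  taxa
}

.resolve_exposures <- function(meds, metas, map) {
  if (nrow(meds) == 0) {
    meds$covariate <- character(0); meds$category <- character(0)
    return(meds)
  }
  if (any(meds$start_day > meds$end_day))
    stop("medication interval with start_day > end_day")
  res <- mapply(function(d, r) unlist(abx_class_map(d, r, map = map)),
                meds$drug, meds$route)
  meds$covariate <- unname(res["covariate", ])
  meds$category <- unname(res["category", ])
  meds$start_day <- as.integer(meds$start_day)
  meds$end_day <- as.integer(meds$end_day)

  i <- match(meds$patient_id, metas$patient_id)
  if (anyNA(i)) stop("medication record for unknown patient")
  inside <- meds$start_day <= metas$discharge_day[i] &
    meds$end_day >= metas$admit_day[i]
  if (any(!inside)) {
    warning("dropping ", sum(!inside),
            " medication interval(s) outside the first hospitalization")
    meds <- meds[inside, , drop = FALSE]
  }
  rownames(meds) <- NULL
  meds
}
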