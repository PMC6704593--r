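#' Classify commensal obligate anaerobes
#'
#' The commensal obligate anaerobe community is defined taxonomically as the
#' classes Clostridia and Negativicutes plus the phyla Bacteroidetes and
#' Fusobacteria. Classification uses those four ranks only; there is no
#' species-level exception list.
#'
#' @param lineage character vector of lineage strings (see [make_lineage()]).
#' @return logical vector.
#' @examples
#' is_obligate_anaerobe(make_lineage("Firmicutes", "Clostridia"))   # TRUE
#' is_obligate_anaerobe(make_lineage("Bacteroidetes"))              # TRUE
#' is_obligate_anaerobe(
#'   make_lineage("Proteobacteria", "Gammaproteobacteria"))         # FALSE
#' @export
is_obligate_anaerobe <- function(lineage) {
  tab <- parse_lineage(lineage)
  if (any(!nzchar(tab$phylum))) stop("lineage with empty phylum")
  tab$class %in% c("Clostridia", "Negativicutes") |
    tab$phylum %in% c("Fusobacteria", "Bacteroidetes")
}

#' Absolute taxon densities for one sample
#'
#' Converts a sample's relative abundances to absolute densities by scaling
#' with the qPCR total: density_i = rel_abundance_i x copies_per_g. The
#' densities therefore sum to the sample's qPCR total (conservation).
#' 16S copies/g is used as the cell-density axis without per-taxon rRNA
#' copy-number correction.
#'
#' @param sample data.frame of one sample's rows with columns `lineage`,
#'   `rel_abundance`, `qpcr_total` (constant within the sample).
#' @return named numeric vector of copies/g, one entry per taxon row.
#' @export
absolute_abundances <- function(sample) {
  total <- unique(sample$qpcr_total)
  stopifnot(length(total) == 1, total > 0)
  stats::setNames(sample$rel_abundance * total, sample$lineage)
}

#' Total obligate anaerobe density of one sample
#'
#' N = copies_per_g x sum of relative abundances over taxa classified by
#' [is_obligate_anaerobe()].
#'
#' @inheritParams absolute_abundances
#' @return anaerobe density in 16S copies per gram (scalar).
#' @export
anaerobe_density <- function(sample) {
  total <- unique(sample$qpcr_total)
  stopifnot(length(total) == 1, total > 0)
  total * sum(sample$rel_abundance[is_obligate_anaerobe(sample$lineage)])
}

#' Inverse Simpson diversity
#'
#' 1 / sum(p_i^2), the effective number of equally abundant taxa; equals 1
#' for a monoculture and K for a uniform K-taxon composition.
#'
#' @param rel_abundances numeric vector of fractions summing to 1.
#' @return diversity >= 1.
#' @export
inverse_simpson <- function(rel_abundances) {
  if (all(rel_abundances == 0)) stop("all-zero abundance vector")
  if (abs(sum(rel_abundances) - 1) > 1e-6)
    stop("relative abundances must sum to 1")
  1 / sum(rel_abundances^2)
}

#' Per-patient density and diversity series
#'
#' For every sample: total 16S density (qPCR), obligate anaerobe density N,
#' and inverse Simpson diversity of the genus-level composition (the same
#' grain used by the volatility statistic).
#'
#' @param samples long sample table (see [read_cohort()]).
#' @return data.frame `patient_id, day, N, total, diversity`, ordered by
#'   patient then day.
#' @export
density_series <- function(samples) {
  key <- paste(samples$patient_id, samples$sample_id, sep = "\r")
  rows <- lapply(split(samples, key), function(s) {
    gen <- tapply(s$rel_abundance, genus_label(s$lineage), sum)
    data.frame(patient_id = s$patient_id[1], day = s$day[1],
               N = anaerobe_density(s), total = s$qpcr_total[1],
               diversity = inverse_simpson(as.numeric(gen)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  if (any(duplicated(out[c("patient_id", "day")])))
    stop("multiple samples on the same day for one patient")
  out
}
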