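#' Compositional volatility between two samples
#'
#' Volatility quantifies the per-day fraction of community turnover between
#' two compositions of one patient taken delta_t days apart:
#'
#'   V(t + delta_t/2) = 1/(2 delta_t) * sum_i |x_next_i - x_t_i|
#'
#' i.e. half the Manhattan (L1) distance between the genus-level
#' compositions, divided by the time gap. V = 0 for identical compositions;
#' V = 1 over one day corresponds to a complete replacement of the community
#' (disjoint genus support). The sum runs over the union of genera; a genus
#' absent from one composition contributes its full abundance in the other.
#'
#' @param x_t,x_next named numeric vectors (genus -> fraction, each summing
#'   to 1).
#' @param delta_t time gap in days (>= 1).
#' @return volatility V in [0, 1].
#' @examples
#' volatility(c(A = 1), c(B = 1), 1)            # 1: complete turnover
#' volatility(c(A = 1), c(A = 0.5, B = 0.5), 2) # 0.25
#' @export
volatility <- function(x_t, x_next, delta_t) {
  if (delta_t <= 0) stop("delta_t must be positive")
  genera <- union(names(x_t), names(x_next))
  a <- b <- stats::setNames(numeric(length(genera)), genera)
  a[names(x_t)] <- x_t
  b[names(x_next)] <- x_next
  sum(abs(b - a)) / (2 * delta_t)
}

#' Volatility series for one patient
#'
#' Groups each sample's composition at the genus level (see
#' [genus_label()]) and computes [volatility()] for every pair of
#' consecutive samples, regardless of gap length — the 1/delta_t factor
#' rescales long gaps. Each point is placed at the pair's midpoint time.
#'
#' @param samples long sample table rows for a single patient.
#' @return data.frame `patient_id, midpoint_time, delta_t, V`, ordered by
#'   midpoint_time; empty for fewer than 2 samples.
#' @export
volatility_series <- function(samples) {
  stopifnot(length(unique(samples$patient_id)) <= 1)
  empty <- data.frame(patient_id = character(0), midpoint_time = numeric(0),
                      delta_t = integer(0), V = numeric(0))
  if (nrow(samples) == 0) return(empty)
  comps <- lapply(split(samples, samples$day), function(s) {
    v <- tapply(s$rel_abundance, genus_label(s$lineage), sum)
    stats::setNames(as.numeric(v), names(v))
  })
  days <- sort(as.integer(names(comps)))
  if (length(days) < 2) return(empty)
  comps <- comps[as.character(days)]
  dt <- diff(days)
  V <- vapply(seq_along(dt), function(i)
    volatility(comps[[i]], comps[[i + 1]], dt[i]), numeric(1))
  data.frame(patient_id = samples$patient_id[1],
             midpoint_time = days[-length(days)] + dt / 2,
             delta_t = as.integer(dt), V = V, stringsAsFactors = FALSE)
}

#' Volatility for a whole cohort
#'
#' @param samples long sample table (any number of patients).
#' @return row-bound [volatility_series()] results for every patient.
#' @export
cohort_volatility <- function(samples) {
  out <- do.call(rbind, lapply(split(samples, samples$patient_id),
                               volatility_series))
  rownames(out) <- NULL
  out
}
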