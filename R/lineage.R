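#' @title Taxonomic lineage strings
#' @description Lineages are encoded as semicolon-joined 7-rank strings,
#'   `kingdom;phylum;class;order;family;genus;species`, with empty fields for
#'   unassigned lower ranks (e.g. `"Bacteria;Firmicutes;Clostridia;;;;"`).
#'   A rank may only be named if every rank above it is named.
#' @name lineage
NULL

.ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Build a lineage string from named ranks
#'
#' @param phylum,class,order,family,genus,species rank names; lower ranks may
#'   be empty (`""`). `kingdom` defaults to `"Bacteria"`.
#' @param kingdom kingdom name.
#' @return a 7-rank semicolon-joined lineage string.
#' @examples
#' make_lineage("Firmicutes", "Clostridia", genus = "Blautia")
#' @export
make_lineage <- function(phylum, class = "", order = "", family = "",
                         genus = "", species = "", kingdom = "Bacteria") {
  paste(kingdom, phylum, class, order, family, genus, species, sep = ";")
}

#' Parse lineage strings into a rank table
#'
#' @param lineage character vector of 7-rank lineage strings (fewer trailing
#'   ranks are tolerated and padded with empty fields).
#' @return data.frame with columns kingdom..species, one row per input.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- 7L
    p[is.na(p)] <- ""
    p
  }, character(7)))
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- .ranks
  out
}

#' Extract one rank from lineage strings
#'
#' @param lineage character vector of lineage strings.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return character vector of rank names ("" where unassigned).
#' @export
lineage_rank <- function(lineage, rank) {
  rank <- match.arg(rank, .ranks)
  parse_lineage(lineage)[[rank]]
}

#' Genus-level grouping label
#'
#' Taxa lacking a genus name are grouped under their lowest named rank,
#' prefixed `"unclassified-"`, so that no abundance mass is discarded when
#' compositions are grouped at the genus level.
#'
#' @param lineage character vector of lineage strings.
#' @return character vector of grouping labels.
#' @export
genus_label <- function(lineage) {
  tab <- parse_lineage(lineage)
  out <- tab$genus
  miss <- !nzchar(out)
  if (any(miss)) {
    lower <- apply(tab[miss, , drop = FALSE], 1, function(r) {
      named <- r[nzchar(r)]
      if (length(named) == 0) "unknown" else named[length(named)]
    })
    out[miss] <- paste0("unclassified-", lower)
  }
  out
}

.validate_lineage <- function(lineage) {
  tab <- parse_lineage(lineage)
  if (any(!nzchar(tab$phylum)))
    stop("lineage with empty phylum: ",
         paste(utils::head(lineage[!nzchar(tab$phylum)], 3), collapse = ", "))
  # ranks below a missing rank must be missing too
  m <- matrix(!nzchar(as.matrix(tab)), nrow = nrow(tab))
  bad <- apply(m, 1, function(r) any(diff(r) < 0))
  if (any(bad))
    stop("lineage with a named rank below a missing rank: ",
         paste(utils::head(lineage[bad], 3), collapse = ", "))
  invisible(TRUE)
}
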