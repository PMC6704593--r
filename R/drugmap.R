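#' Model covariate labels
#'
#' The growth model carries 11 binary antibiotic covariates: seven empirical
#' (fever-triggered, broad-spectrum) agents modeled without pooling, and four
#' prophylactic agents whose effects are partially pooled around a shared
#' prophylaxis effect. Routes matter for vancomycin only: oral vancomycin
#' stays in the gut lumen (empirical anti-anaerobe relevance), intravenous
#' vancomycin is systemic prophylaxis.
#'
#' @return character vector of covariate labels.
#' @export
empirical_labels <- function() {
  c("piperacillin-tazobactam", "meropenem", "metronidazole",
    "cephalosporins-1-3", "vancomycin-po", "cefepime", "linezolid")
}

#' @rdname empirical_labels
#' @export
prophylactic_labels <- function() {
  c("fluoroquinolones", "vancomycin-iv", "trimethoprim-sulfamethoxazole",
    "atovaquone")
}

#' @rdname empirical_labels
#' @export
covariate_labels <- function() c(empirical_labels(), prophylactic_labels())

#' Shipped drug-to-covariate mapping table
#'
#' Maps canonical drug names (and, where it matters, administration route) to
#' the model covariate they load on. `route = "any"` matches every route.
#' The table covers the agents used on HCT services; users may extend it and
#' pass the result to [read_cohort()].
#'
#' @return data.frame with columns drug, route, covariate, category.
#' @export
abx_drug_map <- function() {
  e <- "empirical"; p <- "prophylactic"
  m <- rbind(
    c("piperacillin-tazobactam", "any", "piperacillin-tazobactam", e),
    c("meropenem",               "any", "meropenem",               e),
    c("imipenem-cilastatin",     "any", "meropenem",               e),
    c("metronidazole",           "any", "metronidazole",           e),
    c("cefazolin",               "any", "cephalosporins-1-3",      e),
    c("cephalexin",              "any", "cephalosporins-1-3",      e),
    c("cefuroxime",              "any", "cephalosporins-1-3",      e),
    c("cefotaxime",              "any", "cephalosporins-1-3",      e),
    c("ceftriaxone",             "any", "cephalosporins-1-3",      e),
    c("ceftazidime",             "any", "cephalosporins-1-3",      e),
    c("cefepime",                "any", "cefepime",                e),
    c("linezolid",               "any", "linezolid",               e),
    c("vancomycin",              "po",  "vancomycin-po",           e),
    c("vancomycin",              "iv",  "vancomycin-iv",           p),
    c("ciprofloxacin",           "any", "fluoroquinolones",        p),
    c("levofloxacin",            "any", "fluoroquinolones",        p),
    c("moxifloxacin",            "any", "fluoroquinolones",        p),
    c("trimethoprim-sulfamethoxazole", "any",
      "trimethoprim-sulfamethoxazole", p),
    c("atovaquone",              "any", "atovaquone",              p)
  )
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- c("drug", "route", "covariate", "category")
  out
}

#' Resolve a drug administration to its model covariate
#'
#' @param drug canonical drug name (lower case).
#' @param route administration route: "iv", "po" or "aerosolized".
#' @param map mapping table, by default [abx_drug_map()].
#' @return list with elements `covariate` and `category`.
#' @examples
#' abx_class_map("ciprofloxacin", "po")   # fluoroquinolones, prophylactic
#' abx_class_map("vancomycin", "iv")      # vancomycin-iv,    prophylactic
#' abx_class_map("vancomycin", "po")      # vancomycin-po,    empirical
#' @export
abx_class_map <- function(drug, route = c("iv", "po", "aerosolized"),
                          map = abx_drug_map()) {
  route <- match.arg(route)
  hit <- map[map$drug == drug & (map$route == "any" | map$route == route), ,
             drop = FALSE]
  if (nrow(hit) == 0)
    stop("no covariate mapping for drug '", drug, "' (route ", route, ")")
  if (nrow(hit) > 1)
    stop("ambiguous mapping for drug '", drug, "'")
  list(covariate = hit$covariate, category = hit$category)
}
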