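#' Genetic prevalence from incidence, attribution and survival
#'
#' Genetic prevalence of a gene — the fraction of the birth population
#' carrying a disease-causing variant in it — is approximated as
#' `incidence x proportion_gene x mean_age_at_death`: new cases per
#' person-year, times the fraction of cases attributable to the gene, times
#' the average years lived by a case. When a direct literature estimate is
#' available it overrides the product.
#'
#' @param incidence Disease incidence, new cases per person-year.
#' @param proportion_gene Fraction of cases due to variants in the gene.
#' @param mean_age_at_death Mean age at death of cases, years.
#' @param direct_estimate Optional direct genetic-prevalence fraction;
#'   when supplied it is returned as-is.
#' @return Prevalence as a fraction (clipped to 1 with a warning if the
#'   product exceeds 1).
#' @export
#' @examples
#' estimate_genetic_prevalence(2e-6, 0.15, 67)  # ~1 in 50,000
estimate_genetic_prevalence <- function(incidence = NULL,
                                        proportion_gene = NULL,
                                        mean_age_at_death = NULL,
                                        direct_estimate = NULL) {
  if (!is.null(direct_estimate)) {
    if (direct_estimate < 0 || direct_estimate > 1) {
      stop("direct_estimate must be a fraction", call. = FALSE)
    }
    return(direct_estimate)
  }
  if (is.null(incidence) || is.null(proportion_gene) ||
      is.null(mean_age_at_death)) {
    stop(paste("need incidence, proportion_gene and mean_age_at_death",
               "(or a direct_estimate)"), call. = FALSE)
  }
  if (incidence < 0 || mean_age_at_death < 0 ||
      proportion_gene < 0 || proportion_gene > 1) {
    stop("components must be non-negative; proportion_gene a fraction",
         call. = FALSE)
  }
  prev <- incidence * proportion_gene * mean_age_at_death
  if (prev > 1) {
    warning("estimated prevalence exceeds 1; clipped")
    prev <- 1
  }
  prev
}

#' Format a fraction in "1 in N" style
#' @param p Fraction in (0, 1].
#' @return Character, e.g. `"1 in 49,751"`; `"0"` for `p = 0`.
#' @export
format_one_in <- function(p) {
  ifelse(p > 0, paste("1 in", format(round(1 / p), big.mark = ",",
                                     scientific = FALSE)), "0")
}

#' Genetic prevalence for a table of genes
#'
#' @param inputs Tibble with `gene_id` and columns `incidence`,
#'   `proportion_gene`, `mean_age_at_death`, `direct_estimate` (any of the
#'   last four may be `NA` row-wise as long as each row is computable).
#' @return Input tibble with `prevalence` and `one_in` columns appended.
#' @export
prevalence_table <- function(inputs) {
  stopifnot("gene_id" %in% names(inputs))
  prev <- purrr::pmap_dbl(
    list(inputs$incidence, inputs$proportion_gene,
         inputs$mean_age_at_death,
         if ("direct_estimate" %in% names(inputs)) inputs$direct_estimate
         else rep(NA_real_, nrow(inputs))),
    function(inc, prop, age, direct) {
      estimate_genetic_prevalence(
        incidence = if (is.na(inc)) NULL else inc,
        proportion_gene = if (is.na(prop)) NULL else prop,
        mean_age_at_death = if (is.na(age)) NULL else age,
        direct_estimate = if (is.na(direct)) NULL else direct)
    })
  dplyr::mutate(inputs, prevalence = prev, one_in = format_one_in(prev))
}
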