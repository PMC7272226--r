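#' Estimate cumulative pLoF allele frequency from carrier fractions
#'
#' Given per-gene carrier counts, computes the fraction of individuals
#' without any pLoF variant, `q = 1 - n_carriers / n_individuals`, and the
#' cumulative allele frequency `p = 1 - sqrt(q)`. The square-root form
#' conservatively assumes that an individual with two different pLoF
#' variants carries them in cis, i.e. as a single pLoF haplotype.
#'
#' A gene with a single carrier gets `p = 1 - sqrt(1 - 1/n)`, which agrees
#' with the singleton allele-frequency convention `1/(2n)` to first order
#' (the difference is O(1/n^2)). Genes with no carriers are reported with
#' `p = 0` and flagged `caf_censored = TRUE`: absence of observed pLoF at
#' the current sample size is censoring, not evidence of a zero frequency.
#'
#' @param summary Tibble with `gene_id`, `n_individuals`, `n_carriers`
#'   (e.g. from [carrier_summary()] or [read_carrier_summary()]).
#' @return Tibble `gene_id`, `n_individuals`, `n_carriers`, `q`, `p`,
#'   `caf_censored`.
#' @export
#' @examples
#' estimate_caf(tibble::tibble(gene_id = "G1", n_individuals = 10000,
#'                             n_carriers = 199))  # p = 0.01 exactly
estimate_caf <- function(summary) {
  req <- c("gene_id", "n_individuals", "n_carriers")
  if (!all(req %in% names(summary))) {
    stop("summary must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(summary$n_individuals < 1)) {
    stop("n_individuals must be >= 1", call. = FALSE)
  }
  if (any(summary$n_carriers < 0 |
          summary$n_carriers > summary$n_individuals)) {
    stop("n_carriers must lie in [0, n_individuals]", call. = FALSE)
  }
  q <- 1 - summary$n_carriers / summary$n_individuals
  tibble::tibble(
    gene_id = summary$gene_id,
    n_individuals = summary$n_individuals,
    n_carriers = summary$n_carriers,
    q = q,
    p = 1 - sqrt(q),
    caf_censored = summary$n_carriers == 0L
  )
}
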