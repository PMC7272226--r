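#' Point obs/exp constraint ratio
#'
#' The constraint score of a gene or region: observed pLoF variant count
#' divided by the count expected under a neutral mutation model. Low values
#' indicate purifying selection against loss of function.
#'
#' @param observed Observed variant count(s).
#' @param expected Expected count(s) under neutrality.
#' @return `observed / expected`; `NA` (with a warning) where
#'   `expected == 0`.
#' @export
oe_point <- function(observed, expected) {
  if (any(observed < 0) || any(expected < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  out <- ifelse(expected > 0, observed / expected, NA_real_)
  if (anyNA(out)) warning("obs/exp undefined where expected = 0")
  out
}

#' One-sided Poisson upper confidence bound on obs/exp
#'
#' Treats the observed count as Poisson and bounds the underlying rate from
#' above: `lambda_up` solves `P(Poisson(lambda_up) <= observed) = alpha`,
#' equivalently `lambda_up = qgamma(1 - alpha, observed + 1)` (the Garwood
#' construction). The bound on the ratio is `lambda_up / expected`. For zero
#' observed variants this is `-log(alpha) / expected`, e.g. a 95% upper
#' bound of `2.996 / E`: even a fully unobserved gene is only constrained
#' up to what its expected count can exclude.
#'
#' @param observed Observed count(s).
#' @param expected Expected count(s) (> 0).
#' @param alpha One-sided level, default 0.05 (a 95% upper bound).
#' @return Upper bound(s) on the obs/exp ratio.
#' @export
#' @examples
#' oe_upper_bound(0, 12.6)   # ~0.238: 0 observed of 12.6 expected
oe_upper_bound <- function(observed, expected, alpha = 0.05) {
  if (any(observed < 0)) stop("observed must be non-negative", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  out <- ifelse(expected > 0,
                stats::qgamma(1 - alpha, shape = observed + 1) / expected,
                NA_real_)
  if (anyNA(out)) warning("upper bound undefined where expected = 0")
  out
}

#' Map a whole-gene expected count onto a sub-region
#'
#' Rescales the gene-level expected pLoF count by the ratio of summed
#' per-site mutation frequencies in the region to those in the whole
#' transcript, so that region-restricted constraint uses an expectation
#' proportional to the region's mutational opportunity. Adjusted counts are
#' additive over any partition of the transcript.
#'
#' @param expected_gene Whole-transcript expected count (>= 0).
#' @param mu_region_sum Sum of mutation frequencies of all possible pLoF
#'   variants in the region.
#' @param mu_gene_sum Same sum over the entire transcript (> 0).
#' @return `expected_gene * mu_region_sum / mu_gene_sum`.
#' @export
region_adjusted_expected <- function(expected_gene, mu_region_sum,
                                     mu_gene_sum) {
  if (any(expected_gene < 0)) stop("expected_gene must be non-negative",
                                   call. = FALSE)
  if (any(mu_gene_sum <= 0)) stop("mu_gene_sum must be positive",
                                  call. = FALSE)
  if (any(mu_region_sum < 0)) stop("mu_region_sum must be non-negative",
                                   call. = FALSE)
  if (any(mu_region_sum > mu_gene_sum)) {
    stop("mu_region_sum exceeds mu_gene_sum (ratio > 1)", call. = FALSE)
  }
  expected_gene * mu_region_sum / mu_gene_sum
}

#' Constraint results for a table of genes
#'
#' @param genes Tibble with `gene_id` (or region id), `observed`,
#'   `expected`.
#' @param alpha One-sided level for the upper bound.
#' @return Tibble adding `oe`, `oe_upper`, `alpha`; `oe`/`oe_upper` are
#'   `NA` where `expected = 0`.
#' @export
constraint_table <- function(genes, alpha = 0.05) {
  stopifnot(all(c("gene_id", "observed", "expected") %in% names(genes)))
  suppressWarnings({
    oe <- oe_point(genes$observed, genes$expected)
    up <- oe_upper_bound(genes$observed, genes$expected, alpha)
  })
  if (anyNA(oe)) warning("obs/exp undefined for genes with expected = 0")
  dplyr::mutate(genes, oe = oe, oe_upper = up, alpha = alpha)
}

#' Compare obs/exp constraint between two gene sets
#'
#' Two-sample, two-sided Kolmogorov-Smirnov test on the obs/exp
#' distributions (asymptotic p-value), plus per-set means with
#' t-distribution 95% confidence intervals of the mean (omitted for sets
#' with fewer than two values).
#'
#' @param oe_a,oe_b Numeric vectors of obs/exp values (non-empty; `NA`
#'   dropped).
#' @param labels Length-2 character labels for the sets.
#' @param conf_level Confidence level for the CI of the mean.
#' @return List with `sets` (tibble: label, n, mean, ci_lower, ci_upper),
#'   `ks_D`, `ks_p`.
#' @export
compare_gene_sets <- function(oe_a, oe_b, labels = c("A", "B"),
                              conf_level = 0.95) {
  oe_a <- oe_a[!is.na(oe_a)]
  oe_b <- oe_b[!is.na(oe_b)]
  if (!length(oe_a) || !length(oe_b)) {
    stop("both gene sets must be non-empty", call. = FALSE)
  }
  # D from integer ECDF counts at the pooled points: max |i/n - j/m|
  pts <- sort(unique(c(oe_a, oe_b)))
  d_stat <- max(abs(findInterval(pts, sort(oe_a)) / length(oe_a) -
                      findInterval(pts, sort(oe_b)) / length(oe_b)))
  ks <- suppressWarnings(stats::ks.test(oe_a, oe_b,
                                        alternative = "two.sided",
                                        exact = FALSE))
  set_stats <- function(x, label) {
    n <- length(x)
    m <- mean(x)
    if (n >= 2) {
      half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
        stats::sd(x) / sqrt(n)
      ci <- c(m - half, m + half)
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    tibble::tibble(label = label, n = n, mean = m,
                   ci_lower = ci[1], ci_upper = ci[2])
  }
  list(sets = dplyr::bind_rows(set_stats(oe_a, labels[1]),
                               set_stats(oe_b, labels[2])),
       ks_D = d_stat,
       ks_p = unname(ks$p.value))
}
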