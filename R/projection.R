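#' Heterozygote and two-hit genotype frequencies under a population structure
#'
#' For cumulative pLoF allele frequency `p`, the heterozygote frequency is
#' `2p(1 - p)` under every structure. The two-hit (homozygote or compound
#' heterozygote) frequency is `p^2` for outbred and bottlenecked
#' populations (the bottleneck enters only through a population-specific
#' `p`), and `(1 - a)p^2 + a p` for consanguineous individuals with mean
#' autozygous genome fraction `a`: with probability `a` the locus is
#' identical by descent and one allele draw decides both haplotypes.
#'
#' @param p Cumulative allele frequency (vectorized, each in \[0, 1\]).
#' @param structure Population structure.
#' @param autozygosity_a Autozygous genome fraction `a` in \[0, 1)
#'   (consanguineous only; ignored otherwise).
#' @return Tibble `p`, `het_freq`, `two_hit_freq`.
#' @export
#' @examples
#' genotype_frequencies(0.01, "outbred")              # het 0.0198, two-hit 1e-4
#' genotype_frequencies(0.001, "consanguineous", 0.058)
genotype_frequencies <- function(p,
                                 structure = c("outbred", "bottlenecked",
                                               "consanguineous"),
                                 autozygosity_a = 0) {
  structure <- match.arg(structure)
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  if (autozygosity_a < 0 || autozygosity_a >= 1) {
    stop("autozygosity_a must be in [0, 1)", call. = FALSE)
  }
  a <- if (structure == "consanguineous") autozygosity_a else 0
  tibble::tibble(p = p,
                 het_freq = 2 * p * (1 - p),
                 two_hit_freq = (1 - a) * p^2 + a * p)
}

#' Sample size for expected discovery of a two-hit individual
#'
#' The smallest cohort size `N` whose expected number of two-hit individuals
#' `N * f` reaches 1, i.e. `ceiling(1 / f)`. The alternative definition via
#' `P(at least one) >= 50%` differs only by a factor `ln 2` and is exposed
#' through `method = "probability"`.
#'
#' @param f Two-hit genotype frequency (vectorized). `f = 0` yields `Inf`
#'   (discovery unattainable), not an error.
#' @param method `"expected"` (default) or `"probability"`.
#' @return Numeric vector of sample sizes (`Inf` where `f = 0`).
#' @export
discovery_sample_size <- function(f, method = c("expected", "probability")) {
  method <- match.arg(method)
  if (any(f < 0 | f > 1)) stop("f must be in [0, 1]", call. = FALSE)
  out <- rep(Inf, length(f))
  pos <- f > 0
  out[pos] <- switch(method,
    expected = ceiling(1 / f[pos]),
    probability = pmax(1, ceiling(log(0.5) / log1p(-f[pos])))
  )
  out
}

#' Sample size to infer lethality from absence of two-hit individuals
#'
#' If a two-hit genotype with frequency `f` is viable, the probability of
#' seeing none among `N` individuals is `(1 - f)^N`. The smallest `N` with
#' `(1 - f)^N <= alpha` is `ceiling(log(alpha) / log(1 - f))`; observing no
#' two-hit individual in such a cohort rejects viability at one-sided level
#' `alpha`. For small `f` this is about `-ln(alpha) / f`, i.e. roughly three
#' times the expected-discovery size at `alpha = 0.05`.
#'
#' @param f Two-hit genotype frequency (vectorized); `f = 0` yields `Inf`.
#' @param alpha One-sided significance level in (0, 1), default 0.05.
#' @return Numeric vector of sample sizes.
#' @export
lethality_sample_size <- function(f, alpha = 0.05) {
  if (any(f < 0 | f > 1)) stop("f must be in [0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  out <- rep(Inf, length(f))
  pos <- f > 0 & f < 1
  out[pos] <- ceiling(log(alpha) / log1p(-f[pos]))
  out[f == 1] <- 1
  out
}

#' Per-gene knockout projection under one population structure
#'
#' Assembles, for each gene's estimated cumulative allele frequency, the
#' genotype frequencies and the discovery and lethality sample sizes.
#'
#' @param caf Tibble from [estimate_caf()] (needs `gene_id`, `p`).
#' @param structure Population structure.
#' @param autozygosity_a Autozygous fraction for the consanguineous
#'   structure.
#' @param alpha One-sided level for the lethality projection.
#' @param method Discovery definition, see [discovery_sample_size()].
#' @return Tibble `gene_id`, `structure`, `p`, `het_freq`, `two_hit_freq`,
#'   `n_discovery`, `n_lethality`, `alpha`.
#' @export
project_genes <- function(caf, structure = c("outbred", "bottlenecked",
                                             "consanguineous"),
                          autozygosity_a = 0, alpha = 0.05,
                          method = "expected") {
  structure <- match.arg(structure)
  gf <- genotype_frequencies(caf$p, structure, autozygosity_a)
  tibble::tibble(
    gene_id = caf$gene_id,
    structure = structure,
    p = caf$p,
    het_freq = gf$het_freq,
    two_hit_freq = gf$two_hit_freq,
    n_discovery = discovery_sample_size(gf$two_hit_freq, method = method),
    n_lethality = lethality_sample_size(gf$two_hit_freq, alpha = alpha),
    alpha = alpha
  )
}

#' Histogram of projected genotype frequencies across genes
#'
#' Log10 histogram of per-gene heterozygote or two-hit frequencies, with
#' optional vertical reference lines at cohort sizes (drawn at frequency
#' `1 / N`, the frequency at which one expected individual appears in a
#' cohort of `N`).
#'
#' @param projections Tibble from [project_genes()] (one or more structures).
#' @param which `"two_hit_freq"` (default) or `"het_freq"`.
#' @param reference_n Optional named numeric vector of cohort sizes.
#' @return A ggplot object.
#' @export
plot_genotype_frequencies <- function(projections, which = "two_hit_freq",
                                      reference_n = NULL) {
  stopifnot(which %in% c("two_hit_freq", "het_freq"))
  dat <- dplyr::filter(projections, .data[[which]] > 0)
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = log10(.data[[which]]))) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~structure) +
    ggplot2::labs(x = paste0("log10 ", which), y = "genes")
  if (!is.null(reference_n)) {
    gg <- gg + ggplot2::geom_vline(xintercept = log10(1 / reference_n),
                                   linetype = "dashed")
  }
  gg
}
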