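# Independent oracles used across tests.

# Brute-force two-sample KS statistic: sup over pooled sample points of the
# absolute ECDF difference.
ks_D_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  ecdf_a <- vapply(pts, function(x) mean(a <= x), 1)
  ecdf_b <- vapply(pts, function(x) mean(b <= x), 1)
  max(abs(ecdf_a - ecdf_b))
}

# Poisson upper bound by bisection on P(X <= obs | lambda) = alpha.
poisson_upper_bisect <- function(obs, alpha, lo = 0, hi = 1e4,
                                 tol = 1e-12) {
  stats::uniroot(function(lam) stats::ppois(obs, lam) - alpha,
                 c(lo, hi), tol = tol)$root
}

# Tiny catalog with one gene at an exact CAF, for convergence checks.
single_gene_catalog <- function(caf, seed = 1L) {
  simulate_catalog(1, caf_range = c(caf, caf), seed = seed)
}

# Gene table + CAF pair for roadmap tests.
make_gene_caf <- function(omim = FALSE, twohit = FALSE, pli = 0.5, p = 0.01,
                          id = "G1") {
  list(
    genes = tibble::tibble(gene_id = id, expected_lof = 5, pli = pli,
                           omim_disease = omim, two_hit_reported = twohit,
                           drug_target = FALSE),
    caf = tibble::tibble(gene_id = id, p = p)
  )
}
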