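test_that("catalog draws log-uniform CAFs and ultra-rare-dominated spectra", {
  # degenerate range pins the CAF exactly
  cat1 <- simulate_catalog(1, caf_range = c(0.01, 0.01), seed = 7)
  expect_equal(cat1$genes$true_caf, 0.01)

  # log-uniform median ~ geometric mean of the bounds
  cat2 <- simulate_catalog(1000, caf_range = c(1e-6, 1e-2), seed = 1)
  expect_gt(stats::median(cat2$genes$true_caf), 1e-5)
  expect_lt(stats::median(cat2$genes$true_caf), 1e-3)

  # variant frequencies partition the CAF; spectrum dominated by rare alleles
  by_gene <- split(cat2$variants$freq, cat2$variants$gene_id)
  sums <- vapply(by_gene, sum, 1)
  expect_equal(unname(sums[cat2$genes$gene_id]), cat2$genes$true_caf,
               tolerance = 1e-12)
  frac_rare <- vapply(by_gene, function(f) mean(f < 10 * min(f)), 1)
  expect_true(all(frac_rare >= 0.8))
  expect_true(all(cat2$variants$freq > 0))
})

test_that("catalog and cohort simulation are seed-deterministic", {
  a <- simulate_catalog(50, seed = 42)
  b <- simulate_catalog(50, seed = 42)
  expect_identical(a, b)
  sp <- cohort_spec("outbred", 500, seed = 9)
  expect_identical(simulate_cohort(a, sp), simulate_cohort(a, sp))
})

test_that("catalog rejects invalid ranges and sizes", {
  expect_error(simulate_catalog(0), "n_genes")
  expect_error(simulate_catalog(5, caf_range = c(0.1, 0.01)), "caf_range")
  expect_error(simulate_catalog(5, caf_range = c(0, 0.5)), "caf_range")
})

test_that("empirical genotype fractions converge to the closed forms", {
  # outbred: two-hit fraction ~ p^2
  p <- 0.02
  co <- simulate_cohort(single_gene_catalog(p, seed = 21),
                        cohort_spec("outbred", 2e5, seed = 3))
  cs <- carrier_summary(co)
  f2 <- cs$n_two_hit / cs$n_individuals
  se <- sqrt(p^2 * (1 - p^2) / 2e5)
  expect_lt(abs(f2 - p^2), 3 * se)

  # heterozygote fraction ~ 2p(1-p)
  fhet <- (cs$n_carriers - cs$n_two_hit) / cs$n_individuals
  het <- 2 * p * (1 - p)
  expect_lt(abs(fhet - het), 3 * sqrt(het * (1 - het) / 2e5))

  # consanguineous: two-hit fraction ~ (1-a)p^2 + ap
  a <- 0.058
  co2 <- simulate_cohort(single_gene_catalog(0.001, seed = 22),
                         cohort_spec("consanguineous", 2e6,
                                     autozygosity_a = a, seed = 5))
  cs2 <- carrier_summary(co2)
  f_exp <- (1 - a) * 0.001^2 + a * 0.001
  se2 <- sqrt(f_exp * (1 - f_exp) / 2e6)
  expect_lt(abs(cs2$n_two_hit / cs2$n_individuals - f_exp), 3 * se2)
})

test_that("zero-frequency genes produce zero carriers", {
  cat1 <- simulate_catalog(1, caf_range = c(1e-12, 1e-12), seed = 2)
  # force an effectively zero frequency
  co <- simulate_cohort(cat1, cohort_spec("outbred", 1000, seed = 1))
  cs <- carrier_summary(co)
  expect_equal(cs$n_carriers, 0L)
  expect_equal(cs$n_two_hit, 0L)
})

test_that("bottleneck cohorts only carry founder alleles", {
  cat1 <- single_gene_catalog(0.02, seed = 5)
  co <- simulate_cohort(cat1, cohort_spec("bottlenecked", 5000,
                                          founder_haplotypes = 20,
                                          seed = 8))
  ac <- cohort_allele_counts(co)
  # with 20 founder haplotypes, some catalog variants missed the pool;
  # those must have cohort allele count exactly 0
  haps <- co$genes[[1]]$variant_haps
  absent <- lengths(haps) == 0
  expect_true(any(absent))
  expect_true(all(ac$allele_count[absent] == 0))
  # carried variants descend from few founders: allele counts are clumped,
  # roughly multiples of n/founders on average, never exceeding 2n
  expect_true(all(ac$allele_count <= 2 * 5000))
})

test_that("two-hit fraction is non-decreasing in autozygosity a", {
  cat1 <- single_gene_catalog(0.005, seed = 31)
  fracs <- vapply(c(0, 0.05, 0.2, 0.5), function(a) {
    f <- vapply(1:4, function(s) {
      co <- simulate_cohort(cat1, cohort_spec("consanguineous", 5e4,
                                              autozygosity_a = a,
                                              seed = 100 + s))
      cs <- carrier_summary(co)
      cs$n_two_hit / cs$n_individuals
    }, 1)
    mean(f)
  }, 1)
  expect_true(all(diff(fracs) >= 0))
})

test_that("cohort spec validation catches structural misuse", {
  expect_error(cohort_spec("bottlenecked", 100), "founder_haplotypes")
  expect_error(cohort_spec("consanguineous", 100, autozygosity_a = 1),
               "autozygosity_a")
  expect_warning(cohort_spec("outbred", 100, autozygosity_a = 0.1),
                 "consanguineous")
})

test_that("write_cohort round-trips through the readers", {
  cat1 <- simulate_catalog(5, caf_range = c(1e-3, 1e-2), seed = 13)
  co <- simulate_cohort(cat1, cohort_spec("outbred", 2000, seed = 6))
  pre <- file.path(withr::local_tempdir(), "cohort")
  write_cohort(co, cat1, pre)

  v <- read_variants(paste0(pre, ".vcf"))
  ac <- cohort_allele_counts(co)
  merged <- dplyr::inner_join(v, ac, by = c("gene_id", "variant_id"))
  expect_equal(nrow(merged), nrow(ac))
  expect_equal(merged$allele_count.x, merged$allele_count.y)
  expect_true(all(v$allele_number == 2 * 2000))

  cs_disk <- read_carrier_summary(paste0(pre, "_carriers.tsv"))
  expect_equal(as.data.frame(cs_disk), as.data.frame(carrier_summary(co)))
})

test_that("an empty cohort writes a valid header-only VCF", {
  cat0 <- simulate_catalog(1, caf_range = c(1e-3, 1e-3), seed = 3)
  co <- simulate_cohort(cat0, cohort_spec("outbred", 100, seed = 2))
  # drop the only gene to force an empty variant set
  co$genes <- list()
  cat0$variants <- cat0$variants[0, ]
  pre <- file.path(withr::local_tempdir(), "empty")
  write_cohort(co, cat0, pre)
  expect_equal(nrow(read_variants(paste0(pre, ".vcf"))), 0)
})
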