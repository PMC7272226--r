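mk_variants <- function(codons, ids = sprintf("v%02d", seq_along(codons))) {
  tibble::tibble(gene_id = "G1", variant_id = ids, codon_index = codons,
                 exon_id = paste0("E", pmin(3, (codons - 1) %/% 50 + 1)))
}

test_that("codon-interval masks are inclusive at both boundaries", {
  mask <- region_mask("G1", "codon_interval", codon_start = 1,
                      codon_end = 144)
  v <- mk_variants(c(1, 144, 145, 200))
  parts <- apply_region_mask(v, mask)
  expect_equal(parts$inside$codon_index, c(1, 144))
  expect_equal(parts$outside$codon_index, c(145, 200))
  expect_equal(nrow(parts$unassigned), 0)
})

test_that("mask partition conserves counts and routes missing coordinates", {
  mask <- region_mask("G1", "codon_interval", codon_start = 10,
                      codon_end = 20)
  v <- mk_variants(c(5, 15, NA, 25))
  expect_message(parts <- apply_region_mask(v, mask), "unassigned")
  expect_equal(nrow(parts$inside) + nrow(parts$outside) +
                 nrow(parts$unassigned), nrow(v))
  expect_equal(nrow(parts$unassigned), 1)

  empty <- apply_region_mask(mk_variants(numeric(0)), mask)
  expect_equal(nrow(empty$inside), 0)
  expect_equal(nrow(empty$outside), 0)
})

test_that("exon-set masks partition by exon membership", {
  mask <- region_mask("G1", "exon_set", included_exons = c("E1", "E3"))
  v <- mk_variants(c(10, 60, 120))   # exons E1, E2, E3
  parts <- apply_region_mask(v, mask)
  expect_equal(parts$inside$exon_id, c("E1", "E3"))
  expect_equal(parts$outside$exon_id, "E2")
})

test_that("constitutive exons must clear the threshold in every tissue", {
  expr <- tibble::tibble(
    exon_id = rep(c("E1", "E2", "E3"), each = 2),
    tissue = rep(c("cortex", "cerebellum"), 3),
    value = c(5, 4, 6, 0, 2, 3)
  )
  expect_equal(constitutive_exon_set(expr, threshold = 1), c("E1", "E3"))
  # threshold 0 keeps everything with nonzero rows everywhere... E2 is 0 in
  # cerebellum, and 0 >= 0, so all three qualify
  expect_equal(constitutive_exon_set(expr, threshold = 0),
               c("E1", "E2", "E3"))
  # restricting the required tissues changes the verdict
  expect_equal(constitutive_exon_set(expr, threshold = 1,
                                     tissues = "cortex"),
               c("E1", "E2", "E3"))
  expect_equal(constitutive_exon_set(expr[0, ], 1), character(0))
  # an exon missing a required tissue row is excluded
  expr2 <- expr[expr$exon_id != "E1" | expr$tissue != "cerebellum", ]
  expect_false("E1" %in% constitutive_exon_set(expr2, threshold = 1))
})

test_that("curated constraint composes masks, verdicts and Poisson bounds", {
  # nothing passes curation, adjusted E = 12.6: bound ~ 23.8%
  mask <- region_mask("G1", "codon_interval", codon_start = 1,
                      codon_end = 100, mu_region_sum = 12.6,
                      mu_gene_sum = 25.2)
  v <- mk_variants(c(10, 20, 30))
  verdicts <- tibble::tibble(variant_id = v$variant_id,
                             verdict = "artefact")
  res <- curated_constraint(v, mask, expected_gene = 25.2,
                            verdicts = verdicts)
  expect_equal(res$observed, 0)
  expect_equal(res$expected, 12.6)
  expect_equal(res$oe, 0)
  expect_equal(res$oe_upper, -log(0.05) / 12.6, tolerance = 1e-12)

  # PRNP-style: 6 passing inside the region, adjusted E = 6.06
  mask2 <- region_mask("G1", "codon_interval", codon_start = 1,
                       codon_end = 144, mu_region_sum = 6.06,
                       mu_gene_sum = 10.65)
  v2 <- mk_variants(c(5, 20, 50, 90, 120, 140, 180, 200))
  res2 <- curated_constraint(v2, mask2, expected_gene = 10.65)
  expect_equal(res2$observed, 6)
  expect_equal(res2$oe, 6 / 6.06)
  expect_equal(res2$oe, 0.990, tolerance = 1e-3)
})

test_that("a whole-gene mask reproduces the unadjusted constraint", {
  v <- mk_variants(c(3, 50, 99))
  mask <- region_mask("G1", "codon_interval", codon_start = 1,
                      codon_end = 150)
  res <- curated_constraint(v, mask, expected_gene = 4.2)
  expect_equal(res$observed, 3)
  expect_equal(res$expected, 4.2)
  expect_equal(res$oe, oe_point(3, 4.2))
  expect_equal(res$oe_upper, oe_upper_bound(3, 4.2))
})

test_that("mutation-weight masks compute region sums from the weights", {
  mu <- tibble::tibble(gene_id = "G1", codon = 1:100,
                       mu = rep(c(1, 2), 50))
  mask <- mask_from_mu_weights(mu, 1, 50)
  expect_equal(mask$mu_region_sum, sum(mu$mu[1:50]))
  expect_equal(mask$mu_gene_sum, sum(mu$mu))
  expect_equal(region_adjusted_expected(10, mask$mu_region_sum,
                                        mask$mu_gene_sum), 5)
})

test_that("positional distribution bins codons and measures gaps", {
  # all variants in the first bin: gap spans the remaining bins
  pd <- positional_distribution(mk_variants(c(2, 5, 9)), gene_length = 100,
                                n_bins = 10)
  expect_equal(pd$bins$count[1], 3)
  expect_equal(sum(pd$bins$count), 3)
  expect_equal(pd$max_gap, 90)

  expect_equal(positional_distribution(mk_variants(numeric(0)), 100,
                                       10)$max_gap, 100)

  # uniform positions look flat under a chi-square goodness-of-fit test
  set.seed(50)
  v <- mk_variants(sample.int(1000, 1000, replace = TRUE))
  pd2 <- positional_distribution(v, gene_length = 1000, n_bins = 10)
  gof <- stats::chisq.test(pd2$bins$count)
  expect_gt(gof$p.value, 0.001)
})

test_that("mask table readers round-trip codon-interval masks", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "masks.tsv")
  writeLines(c(
    "gene_id\tkind\tcodon_start\tcodon_end\tmu_region_sum\tmu_gene_sum",
    "G1\tcodon_interval\t1\t144\t6.06\t10.65"), path)
  masks <- read_region_masks(path)
  expect_length(masks, 1)
  expect_s3_class(masks[[1]], "region_mask")
  expect_equal(masks[[1]]$codon_end, 144)

  mu_path <- system.file("extdata", "prnp_mu_weights_synthetic.tsv",
                         package = "lofkit")
  mu <- read_mu_weights(mu_path)
  expect_equal(nrow(mu), 253)
  mask <- mask_from_mu_weights(mu, 1, 144)
  expect_equal(mask$mu_region_sum / mask$mu_gene_sum, 144 / 253)
})
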