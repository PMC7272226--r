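#' Simulate a gene catalog with a gnomAD-like pLoF frequency regime
#'
#' Generates `n_genes` synthetic genes, each with a true per-haplotype
#' cumulative pLoF allele frequency (CAF) drawn log-uniformly over
#' `caf_range`, a variant spectrum dominated by ultra-rare alleles, and the
#' per-gene metadata consumed downstream (expected pLoF count under a neutral
#' mutation model, pLI, gene-list membership flags, coding length).
#'
#' The per-gene CAF is split across variants so that at least 80% of a gene's
#' variants have frequencies within 2x of the rarest variant, mimicking
#' call sets in which cumulative LoF frequency is driven by singletons and
#' other ultra-rare alleles. The number of variants scales with coding
#' length.
#'
#' @param n_genes Number of genes to simulate (>= 1).
#' @param caf_range Length-2 numeric, the (inclusive) range of true CAF;
#'   both endpoints in (0, 1). A degenerate range (equal endpoints) gives
#'   every gene exactly that CAF.
#' @param seed Integer seed; identical calls with identical seeds return
#'   identical catalogs.
#' @param variant_density Expected pLoF variants per coding codon
#'   (default 1/100).
#' @param flag_probs Named list of probabilities for the gene-list membership
#'   flags `omim_disease`, `two_hit_reported`, `drug_target`.
#'
#' @return An object of class `lof_catalog`: a list with
#'   \describe{
#'     \item{genes}{tibble: `gene_id`, `true_caf`, `n_variants`,
#'       `expected_lof`, `pli`, `codon_length`, flag columns.}
#'     \item{variants}{tibble: one row per variant with `gene_id`,
#'       `variant_id`, `freq`, `chrom`, `pos`, `ref`, `alt`, `csq_class`,
#'       `lof_flag`, `codon_index`, `exon_id`.}
#'   }
#' @export
#' @examples
#' cat1 <- simulate_catalog(5, caf_range = c(1e-4, 1e-2), seed = 1)
#' cat1$genes
simulate_catalog <- function(n_genes, caf_range = c(1e-6, 1e-2), seed = 1L,
                             variant_density = 0.01,
                             flag_probs = list(omim_disease = 0.18,
                                               two_hit_reported = 0.18,
                                               drug_target = 0.02)) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1) {
    stop("`n_genes` must be a single count >= 1", call. = FALSE)
  }
  if (length(caf_range) != 2 || any(!is.finite(caf_range)) ||
      any(caf_range <= 0) || any(caf_range >= 1) ||
      caf_range[1] > caf_range[2]) {
    stop("`caf_range` must be an ordered pair within (0, 1)", call. = FALSE)
  }
  n_genes <- as.integer(n_genes)
  set.seed(as.integer(seed))

  gene_id <- sprintf("G%05d", seq_len(n_genes))
  codon_length <- pmax(50L, as.integer(round(stats::rlnorm(n_genes,
                                                           meanlog = log(450),
                                                           sdlog = 0.6))))
  true_caf <- exp(stats::runif(n_genes, log(caf_range[1]), log(caf_range[2])))
  n_variants <- pmax(1L, stats::rpois(n_genes, codon_length * variant_density))
  expected_lof <- round(codon_length * stats::runif(n_genes, 0.01, 0.04), 3)
  pli <- round(stats::rbeta(n_genes, 0.2, 0.2), 4)

  flags <- tibble::tibble(
    omim_disease = stats::runif(n_genes) < flag_probs$omim_disease,
    two_hit_reported = stats::runif(n_genes) < flag_probs$two_hit_reported,
    drug_target = stats::runif(n_genes) < flag_probs$drug_target
  )

  genes <- tibble::tibble(gene_id = gene_id, true_caf = true_caf,
                          n_variants = n_variants, expected_lof = expected_lof,
                          pli = pli, codon_length = codon_length)
  genes <- dplyr::bind_cols(genes, flags)

  variants <- purrr::pmap_dfr(
    list(gene_id, true_caf, n_variants, codon_length, seq_len(n_genes)),
    function(gid, caf, k, len, gi) {
      freqs <- .split_caf(caf, k)
      codon <- sort(sample.int(len, k, replace = TRUE))
      exon_width <- max(25L, len %/% 8L)
      tibble::tibble(
        gene_id = gid,
        variant_id = sprintf("%s_v%03d", gid, seq_len(k)),
        freq = freqs,
        chrom = "1",
        pos = gi * 100000L + 3L * (codon - 1L) + 1L,
        ref = sample(c("A", "C", "G", "T"), k, replace = TRUE),
        alt = "T",
        csq_class = sample(c("nonsense", "splice", "frameshift"), k,
                           replace = TRUE, prob = c(0.5, 0.2, 0.3)),
        lof_flag = sample(c("HC", "LC"), k, replace = TRUE,
                          prob = c(0.9, 0.1)),
        codon_index = codon,
        exon_id = sprintf("%s_E%d", gid, (codon - 1L) %/% exon_width + 1L)
      )
    }
  )
  # avoid ref == alt
  variants$alt[variants$ref == "T"] <- "G"

  structure(list(genes = genes, variants = variants), class = "lof_catalog")
}

# Partition a cumulative frequency across k variants so the spectrum is
# dominated by ultra-rare alleles: at most 10% of variants get "common"
# weights, the rest sit within 2x of the minimum.
.split_caf <- function(caf, k) {
  if (k == 1) return(caf)
  n_common <- k %/% 10L
  n_rare <- k - n_common
  w <- c(stats::runif(n_rare, 0.5, 1), stats::runif(n_common, 5, 50))
  f <- w / sum(w) * caf
  # keep deterministic association: rare first, common last
  f
}

#' Specify a cohort simulation recipe
#'
#' @param structure One of `"outbred"`, `"bottlenecked"`, `"consanguineous"`.
#' @param n_individuals Cohort size.
#' @param autozygosity_a For the consanguineous structure only: the expected
#'   fraction of the genome that is autozygous (identical by descent) within
#'   an individual; each gene is IBD with this probability, independently.
#' @param founder_haplotypes For the bottlenecked structure only: the number
#'   of founder haplotypes (>= 2) from which all cohort haplotypes descend.
#' @param inbreeding_threshold_F Inbreeding-coefficient cutoff used to label
#'   individuals as consanguineous in reports (default 0.05).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(structure = c("outbred", "bottlenecked",
                                      "consanguineous"),
                        n_individuals, autozygosity_a = 0,
                        founder_haplotypes = NULL,
                        inbreeding_threshold_F = 0.05, seed = 1L) {
  structure <- match.arg(structure)
  if (!is.numeric(n_individuals) || n_individuals < 0) {
    stop("`n_individuals` must be a non-negative count", call. = FALSE)
  }
  if (autozygosity_a < 0 || autozygosity_a >= 1) {
    stop("`autozygosity_a` must be in [0, 1)", call. = FALSE)
  }
  if (structure == "bottlenecked") {
    if (is.null(founder_haplotypes) || founder_haplotypes < 2) {
      stop("bottlenecked structure requires `founder_haplotypes` >= 2",
           call. = FALSE)
    }
  }
  if (structure != "consanguineous" && autozygosity_a != 0) {
    warning("`autozygosity_a` is only used for the consanguineous structure")
  }
  out <- list(structure = structure,
              n_individuals = as.integer(n_individuals),
              autozygosity_a = autozygosity_a,
              founder_haplotypes = if (is.null(founder_haplotypes)) NULL
                                   else as.integer(founder_haplotypes),
              inbreeding_threshold_F = inbreeding_threshold_F,
              seed = as.integer(seed))
  class(out) <- "cohort_spec"
  out
}

#' Simulate cohort genotypes for a gene catalog
#'
#' The stochastic counterpart of the closed-form genotype frequencies: each
#' haplotype of each individual carries each variant independently with its
#' allele frequency (outbred); all haplotypes are drawn with replacement from
#' a small founder pool whose haplotypes were drawn that way once
#' (bottlenecked); or, per individual and gene, the two haplotypes are
#' identical by descent with probability `autozygosity_a` (consanguineous).
#' Two different variants on the same haplotype still constitute a single
#' pLoF haplotype; a two-hit individual is one whose two haplotypes both
#' carry at least one pLoF variant.
#'
#' Carriage is stored sparsely (per variant, the indices of carrying
#' haplotype slots), so cohorts of millions of individuals are cheap when
#' allele frequencies are small.
#'
#' @param catalog A `lof_catalog` from [simulate_catalog()].
#' @param spec A [cohort_spec()].
#' @return An object of class `lof_cohort`: list with `spec`,
#'   `n_individuals`, and `genes`, a named list (per gene) holding
#'   `variant_id` and `variant_haps` (per variant, integer indices of
#'   carrying haplotype slots; individual `i` owns slots `2i - 1` and `2i`).
#' @export
simulate_cohort <- function(catalog, spec) {
  stopifnot(inherits(catalog, "lof_catalog"), inherits(spec, "cohort_spec"))
  n <- spec$n_individuals
  set.seed(spec$seed)
  var_split <- split(catalog$variants, catalog$variants$gene_id)
  # preserve catalog gene order
  var_split <- var_split[unique(catalog$variants$gene_id)]

  genes <- lapply(var_split, function(vt) {
    haps <- switch(spec$structure,
      outbred = .sim_gene_outbred(vt$freq, n),
      bottlenecked = .sim_gene_bottleneck(vt$freq, n,
                                          spec$founder_haplotypes),
      consanguineous = .sim_gene_consang(vt$freq, n, spec$autozygosity_a)
    )
    list(variant_id = vt$variant_id, variant_haps = haps)
  })

  structure(list(spec = spec, n_individuals = n, genes = genes),
            class = "lof_cohort")
}

# Each of the 2n haplotype slots carries variant j independently with
# frequency f_j: binomial count, then uniform choice of distinct slots.
.sim_gene_outbred <- function(freqs, n) {
  n_haps <- 2L * n
  lapply(freqs, function(f) {
    k <- stats::rbinom(1L, n_haps, f)
    if (k == 0L) integer(0) else sort(sample.int(n_haps, k))
  })
}

.sim_gene_bottleneck <- function(freqs, n, n_founders) {
  founder_carriers <- lapply(freqs, function(f) {
    k <- stats::rbinom(1L, n_founders, f)
    if (k == 0L) integer(0) else sample.int(n_founders, k)
  })
  hap_founder <- sample.int(n_founders, 2L * n, replace = TRUE)
  lapply(founder_carriers, function(fc) {
    if (length(fc) == 0L) integer(0) else which(hap_founder %in% fc)
  })
}

# Independent-haplotype pool: every individual contributes slot A; only
# non-IBD individuals contribute slot B. An IBD individual's single draw is
# copied to both haplotype slots (and so counts twice in allele counts).
.sim_gene_consang <- function(freqs, n, a) {
  ibd <- stats::runif(n) < a
  non_ibd_ids <- which(!ibd)
  pool_size <- n + length(non_ibd_ids)
  lapply(freqs, function(f) {
    k <- stats::rbinom(1L, pool_size, f)
    if (k == 0L) return(integer(0))
    pool <- sample.int(pool_size, k)
    first <- pool[pool <= n]                      # slot-A draws
    second <- non_ibd_ids[pool[pool > n] - n]     # slot-B draws (non-IBD only)
    haps <- c(2L * first - 1L, 2L * second)
    # IBD individuals: slot-A draw is copied to slot B
    dup <- first[ibd[first]]
    if (length(dup)) haps <- c(haps, 2L * dup)
    sort(haps)
  })
}

#' Tally per-gene carrier and two-hit counts from a simulated cohort
#'
#' An individual carrying any number of distinct pLoF variants contributes
#' exactly once to `n_carriers` (the conservative cis convention: multiple
#' variants in one individual are assumed to lie on one haplotype unless the
#' simulation placed them on both). A two-hit individual has at least one
#' pLoF variant on each haplotype.
#'
#' @param cohort An `lof_cohort`.
#' @param gene_id Optional single gene id; default all genes.
#' @param include_variants Optional character vector of variant ids to
#'   restrict the tally to (e.g. the ids surviving [filter_lof()]); default
#'   all simulated variants.
#' @return Tibble with `gene_id`, `n_individuals`, `n_carriers`,
#'   `n_two_hit`.
#' @export
carrier_summary <- function(cohort, gene_id = NULL,
                            include_variants = NULL) {
  stopifnot(inherits(cohort, "lof_cohort"))
  if (cohort$n_individuals == 0) {
    stop("cohort has zero individuals", call. = FALSE)
  }
  ids <- if (is.null(gene_id)) names(cohort$genes) else gene_id
  rows <- lapply(ids, function(g) {
    gh <- cohort$genes[[g]]
    if (is.null(gh)) stop("unknown gene_id: ", g, call. = FALSE)
    keep <- if (is.null(include_variants)) {
      seq_along(gh$variant_id)
    } else {
      which(gh$variant_id %in% include_variants)
    }
    haps <- unique(unlist(gh$variant_haps[keep], use.names = FALSE))
    ind <- (haps + 1L) %/% 2L
    carriers <- unique(ind)
    # an individual appears twice among the unique hap slots iff both
    # haplotypes carry a variant
    two_hit <- if (length(ind)) sum(tabulate(ind) == 2L) else 0L
    tibble::tibble(gene_id = g,
                   n_individuals = cohort$n_individuals,
                   n_carriers = length(carriers),
                   n_two_hit = two_hit)
  })
  dplyr::bind_rows(rows)
}

#' Per-variant cohort allele counts
#'
#' @param cohort An `lof_cohort`.
#' @return Tibble `gene_id`, `variant_id`, `allele_count`, `allele_number`.
#' @export
cohort_allele_counts <- function(cohort) {
  stopifnot(inherits(cohort, "lof_cohort"))
  an <- 2L * cohort$n_individuals
  if (length(cohort$genes) == 0) {
    return(tibble::tibble(gene_id = character(), variant_id = character(),
                          allele_count = integer(),
                          allele_number = integer()))
  }
  purrr::imap_dfr(cohort$genes, function(gh, g) {
    tibble::tibble(gene_id = g,
                   variant_id = gh$variant_id,
                   allele_count = vapply(gh$variant_haps, length, 1L),
                   allele_number = an)
  })
}

#' Write a simulated cohort as a sites VCF and carrier-summary TSV
#'
#' Emits `<out_prefix>.vcf` (VCF 4.2 sites file with INFO keys GENE, AC, AN,
#' LOF_FLAG, CSQ_CLASS, CODON, EXON) and `<out_prefix>_carriers.tsv`
#' (`gene_id`, `n_individuals`, `n_carriers`, `n_two_hit`). Round-trips
#' losslessly through [read_variants()] and [read_carrier_summary()].
#'
#' @param cohort An `lof_cohort`.
#' @param catalog The `lof_catalog` the cohort was simulated from.
#' @param out_prefix Path prefix for the two output files.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_cohort <- function(cohort, catalog, out_prefix) {
  stopifnot(inherits(cohort, "lof_cohort"), inherits(catalog, "lof_catalog"))
  vcf_path <- paste0(out_prefix, ".vcf")
  tsv_path <- paste0(out_prefix, "_carriers.tsv")

  ac <- cohort_allele_counts(cohort)
  v <- dplyr::inner_join(catalog$variants, ac,
                         by = c("gene_id", "variant_id"))
  v <- dplyr::arrange(v, .data$chrom, .data$pos)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lofkit_synthetic_cohort",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene identifier\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    "##INFO=<ID=LOF_FLAG,Number=1,Type=String,Description=\"LoF confidence (HC|LC)\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=CODON,Number=1,Type=Integer,Description=\"1-based affected codon\">",
    "##INFO=<ID=EXON,Number=1,Type=String,Description=\"Exon identifier\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(v) == 0) {
    writeLines(header, vcf_path)
  } else {
    info <- sprintf("GENE=%s;AC=%d;AN=%d;LOF_FLAG=%s;CSQ_CLASS=%s;CODON=%d;EXON=%s",
                    v$gene_id, v$allele_count, v$allele_number, v$lof_flag,
                    v$csq_class, v$codon_index, v$exon_id)
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                    v$chrom, v$pos, v$variant_id, v$ref, v$alt, info)
    writeLines(c(header, body), vcf_path)
  }

  cs <- carrier_summary(cohort)
  readr::write_tsv(cs, tsv_path)
  invisible(c(vcf = vcf_path, carriers = tsv_path))
}

#' Read a carrier-summary TSV written by [write_cohort()]
#' @param path TSV path.
#' @return Tibble `gene_id`, `n_individuals`, `n_carriers`, `n_two_hit`.
#' @export
read_carrier_summary <- function(path) {
  cs <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          gene_id = readr::col_character(),
                          n_individuals = readr::col_integer(),
                          n_carriers = readr::col_integer(),
                          n_two_hit = readr::col_integer()))
  bad <- cs$n_two_hit > cs$n_carriers | cs$n_carriers > cs$n_individuals
  if (any(bad)) stop("inconsistent carrier summary at row ", which(bad)[1],
                     call. = FALSE)
  cs
}
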