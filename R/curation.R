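#' Define a region mask over a transcript
#'
#' Either a 1-based inclusive codon interval (with optional summed per-site
#' mutation-frequency weights for expectation adjustment) or an explicit
#' set of included exons.
#'
#' @param gene_id Gene identifier.
#' @param kind `"codon_interval"` or `"exon_set"`.
#' @param codon_start,codon_end Inclusive codon bounds (codon interval).
#' @param included_exons Character vector of exon ids (exon set).
#' @param mu_region_sum,mu_gene_sum Mutation-frequency sums for the region
#'   and whole transcript (codon interval masks; used by
#'   [curated_constraint()]).
#' @return A `region_mask` list.
#' @export
region_mask <- function(gene_id, kind = c("codon_interval", "exon_set"),
                        codon_start = NULL, codon_end = NULL,
                        included_exons = NULL,
                        mu_region_sum = NULL, mu_gene_sum = NULL) {
  kind <- match.arg(kind)
  if (kind == "codon_interval") {
    if (is.null(codon_start) || is.null(codon_end) ||
        codon_start < 1 || codon_end < codon_start) {
      stop("codon interval requires 1 <= codon_start <= codon_end",
           call. = FALSE)
    }
    if (!is.null(mu_region_sum) && !is.null(mu_gene_sum) &&
        (mu_region_sum < 0 || mu_gene_sum <= 0 ||
         mu_region_sum > mu_gene_sum)) {
      stop("mutation-frequency sums must satisfy 0 <= region <= gene",
           call. = FALSE)
    }
  } else if (is.null(included_exons)) {
    stop("exon_set mask requires `included_exons`", call. = FALSE)
  }
  structure(list(gene_id = gene_id, kind = kind,
                 codon_start = codon_start, codon_end = codon_end,
                 included_exons = included_exons,
                 mu_region_sum = mu_region_sum, mu_gene_sum = mu_gene_sum),
            class = "region_mask")
}

#' Partition variants by a region mask
#'
#' Splits a variant table into the records inside the mask, outside it, and
#' an `unassigned` bucket for records lacking the coordinate the mask needs
#' (codon index or exon id). Both interval bounds are inside the region:
#' a mask over codons 1-144 includes codon 144 and excludes codon 145.
#'
#' @param variants Variant tibble (needs `codon_index` or `exon_id`).
#' @param mask A [region_mask()].
#' @return List of tibbles `inside`, `outside`, `unassigned`;
#'   their row counts always sum to `nrow(variants)`.
#' @export
apply_region_mask <- function(variants, mask) {
  stopifnot(inherits(mask, "region_mask"))
  if (mask$kind == "codon_interval") {
    coord <- variants$codon_index
    in_mask <- !is.na(coord) & coord >= mask$codon_start &
      coord <= mask$codon_end
  } else {
    coord <- variants$exon_id
    in_mask <- !is.na(coord) & coord %in% mask$included_exons
  }
  unassigned <- is.na(coord)
  if (any(unassigned)) {
    message(sum(unassigned),
            " variant(s) lack the coordinate required by the mask; ",
            "routed to `unassigned`")
  }
  list(inside = variants[in_mask & !unassigned, , drop = FALSE],
       outside = variants[!in_mask & !unassigned, , drop = FALSE],
       unassigned = variants[unassigned, , drop = FALSE])
}

#' Exons constitutively expressed across all required tissues
#'
#' An exon is constitutive when its expression value reaches `threshold`
#' in every required tissue; an exon with no row for a required tissue is
#' treated as not expressed there.
#'
#' @param expressions Tibble with `exon_id`, `tissue`, `value` (one row per
#'   exon x tissue).
#' @param threshold Minimum expression (inclusive), default 1 expression
#'   unit.
#' @param tissues Required tissues; default all tissues present in the
#'   table.
#' @return Character vector of constitutive exon ids.
#' @export
constitutive_exon_set <- function(expressions, threshold = 1,
                                  tissues = NULL) {
  stopifnot(all(c("exon_id", "tissue", "value") %in% names(expressions)))
  if (nrow(expressions) == 0) return(character(0))
  if (is.null(tissues)) tissues <- unique(expressions$tissue)
  per_exon <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(expressions, .data$tissue %in% tissues),
      .data$exon_id),
    ok = dplyr::n_distinct(.data$tissue[.data$value >= threshold]) ==
      length(tissues),
    .groups = "drop")
  sort(per_exon$exon_id[per_exon$ok])
}

#' Region-restricted, curation-aware constraint
#'
#' Counts variants that fall inside the mask (and, if curation verdicts are
#' supplied, whose verdict is `"pass"`), maps the whole-gene expected count
#' onto the region via [region_adjusted_expected()] when the mask carries
#' mutation-frequency sums, and returns the obs/exp point estimate with its
#' one-sided Poisson upper bound. With a whole-gene mask and no verdicts
#' this reduces exactly to the unadjusted constraint.
#'
#' @param variants Variant tibble (typically already pLoF-filtered).
#' @param mask A [region_mask()].
#' @param expected_gene Whole-transcript expected pLoF count.
#' @param verdicts Optional tibble `variant_id`, `verdict` (one of `pass`,
#'   `artefact`, `annotation_error`, `not_lof`); variants without a verdict
#'   row are assumed to pass.
#' @param alpha One-sided level for the upper bound.
#' @return One-row tibble `gene_id`, `observed`, `expected`, `oe`,
#'   `oe_upper`, `alpha`.
#' @export
curated_constraint <- function(variants, mask, expected_gene,
                               verdicts = NULL, alpha = 0.05) {
  stopifnot(inherits(mask, "region_mask"))
  if (!is.null(verdicts)) {
    stopifnot(all(c("variant_id", "verdict") %in% names(verdicts)))
    fails <- verdicts$variant_id[verdicts$verdict != "pass"]
    variants <- variants[!(variants$variant_id %in% fails), , drop = FALSE]
  }
  parts <- apply_region_mask(variants, mask)
  observed <- nrow(parts$inside)
  expected <- if (!is.null(mask$mu_region_sum) &&
                  !is.null(mask$mu_gene_sum)) {
    region_adjusted_expected(expected_gene, mask$mu_region_sum,
                             mask$mu_gene_sum)
  } else {
    expected_gene
  }
  tibble::tibble(gene_id = mask$gene_id,
                 observed = observed,
                 expected = expected,
                 oe = oe_point(observed, expected),
                 oe_upper = oe_upper_bound(observed, expected, alpha),
                 alpha = alpha)
}

#' Positional distribution of variants along a transcript
#'
#' Bins variant codon positions into `n_bins` equal-width bins over
#' codons 1..`gene_length` and reports the largest positional gap, defined
#' as the length (in codons) of the longest run of consecutive empty bins
#' — a descriptive statistic for spotting clustered, non-random variant
#' distributions (alignment artefacts, unexpressed exons, terminal-codon
#' effects).
#'
#' @param variants Variant tibble with `codon_index`.
#' @param gene_length Transcript length in codons.
#' @param n_bins Number of bins, default 10.
#' @return List with `bins` (tibble `bin`, `codon_start`, `codon_end`,
#'   `count`) and `max_gap` (codons).
#' @export
positional_distribution <- function(variants, gene_length, n_bins = 10) {
  stopifnot(gene_length >= 1, n_bins >= 1)
  width <- gene_length / n_bins
  codon <- variants$codon_index
  codon <- codon[!is.na(codon)]
  bin <- pmin(n_bins, floor((codon - 1) / width) + 1)
  counts <- tabulate(bin, nbins = n_bins)
  empty <- counts == 0
  runs <- rle(empty)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0
  tibble_bins <- tibble::tibble(
    bin = seq_len(n_bins),
    codon_start = floor((seq_len(n_bins) - 1) * width) + 1,
    codon_end = floor(seq_len(n_bins) * width),
    count = counts
  )
  list(bins = tibble_bins, max_gap = max_run * width)
}

#' Read a region-mask TSV
#'
#' Columns: `gene_id`, `kind`, `codon_start`, `codon_end`,
#' `mu_region_sum`, `mu_gene_sum` (exon-set masks use a `included_exons`
#' comma-separated column instead of the codon/mu columns).
#'
#' @param path TSV path.
#' @return List of [region_mask()] objects, one per row.
#' @export
read_region_masks <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"))
  stopifnot(all(c("gene_id", "kind") %in% names(tbl)))
  lapply(seq_len(nrow(tbl)), function(i) {
    r <- tbl[i, ]
    if (r$kind == "codon_interval") {
      region_mask(r$gene_id, "codon_interval",
                  codon_start = r$codon_start, codon_end = r$codon_end,
                  mu_region_sum = r$mu_region_sum,
                  mu_gene_sum = r$mu_gene_sum)
    } else {
      region_mask(r$gene_id, "exon_set",
                  included_exons = strsplit(r$included_exons, ",")[[1]])
    }
  })
}

#' Read per-codon mutation-frequency weights
#'
#' Columns: `gene_id`, `codon`, `mu` (relative mutation frequency of all
#' possible pLoF variants in that codon). Used to build codon-interval
#' masks with mutation-frequency-adjusted expectations.
#'
#' @param path TSV path.
#' @return Tibble `gene_id`, `codon`, `mu`.
#' @export
read_mu_weights <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           codon = readr::col_integer(),
                           mu = readr::col_double()))
  if (any(tbl$mu < 0)) stop("mutation frequencies must be non-negative",
                            call. = FALSE)
  tbl
}

#' Build a codon-interval mask from per-codon mutation weights
#'
#' @param mu_weights Tibble from [read_mu_weights()] (single gene).
#' @param codon_start,codon_end Inclusive codon bounds.
#' @return A [region_mask()] whose mutation-frequency sums are computed
#'   from the weights.
#' @export
mask_from_mu_weights <- function(mu_weights, codon_start, codon_end) {
  gid <- unique(mu_weights$gene_id)
  if (length(gid) != 1) stop("mu_weights must cover exactly one gene",
                             call. = FALSE)
  inside <- mu_weights$codon >= codon_start & mu_weights$codon <= codon_end
  region_mask(gid, "codon_interval",
              codon_start = codon_start, codon_end = codon_end,
              mu_region_sum = sum(mu_weights$mu[inside]),
              mu_gene_sum = sum(mu_weights$mu))
}
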