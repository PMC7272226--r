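#' Roadmap categories, in precedence order
#' @export
roadmap_categories <- c("mendelian_disease", "two_hit_reported",
                        "likely_haploinsufficient", "plof_not_observed",
                        "plof_observed")

#' Classify genes into the knockout-discovery roadmap
#'
#' Sequential classification by the current status of disease association
#' and pLoF ascertainment. The first matching rule wins:
#' \enumerate{
#'   \item known Mendelian disease association (`omim_disease` flag);
#'   \item a two-hit pLoF genotype already reported (`two_hit_reported`);
#'   \item likely haploinsufficient: `pli > pli_cutoff` (strict);
#'   \item no pLoF observed yet: estimated CAF `p = 0`;
#'   \item otherwise, pLoF observed.
#' }
#' Genes with missing pLI skip rule 3 (with a warning); a gene with missing
#' pLI and `p = 0` therefore falls to `plof_not_observed`.
#'
#' @param genes Gene tibble (from [read_gene_table()] or a catalog's
#'   `genes`) with `gene_id`, flags and `pli`.
#' @param caf CAF tibble from [estimate_caf()] (`gene_id`, `p`).
#' @param pli_cutoff Strict pLI threshold, default 0.9.
#' @return Tibble `gene_id`, `category` (factor over
#'   [roadmap_categories]).
#' @export
classify_genes <- function(genes, caf, pli_cutoff = 0.9) {
  stopifnot("gene_id" %in% names(genes))
  tbl <- dplyr::left_join(genes, caf[c("gene_id", "p")], by = "gene_id")
  if (anyNA(tbl$p)) {
    stop("missing CAF estimate for ", sum(is.na(tbl$p)), " gene(s)",
         call. = FALSE)
  }
  omim <- isTRUE_vec(tbl[["omim_disease"]], nrow(tbl))
  twohit <- isTRUE_vec(tbl[["two_hit_reported"]], nrow(tbl))
  if (anyNA(tbl$pli)) {
    warning(sum(is.na(tbl$pli)),
            " gene(s) with missing pLI skip the haploinsufficiency rule")
  }
  hi <- !is.na(tbl$pli) & tbl$pli > pli_cutoff
  category <- dplyr::case_when(
    omim ~ "mendelian_disease",
    twohit ~ "two_hit_reported",
    hi ~ "likely_haploinsufficient",
    tbl$p == 0 ~ "plof_not_observed",
    TRUE ~ "plof_observed"
  )
  tibble::tibble(gene_id = tbl$gene_id,
                 category = factor(category, levels = roadmap_categories))
}

# missing flag column or NA entries count as FALSE
isTRUE_vec <- function(x, n) {
  if (is.null(x)) return(rep(FALSE, n))
  !is.na(x) & as.logical(x)
}

#' Summarize a roadmap classification
#'
#' @param classified Tibble from [classify_genes()].
#' @return Tibble `category`, `n`, `fraction` covering all five categories
#'   (zero rows included); counts sum to the number of genes.
#' @export
summarize_roadmap <- function(classified) {
  counts <- table(factor(classified$category, levels = roadmap_categories))
  n_total <- sum(counts)
  tibble::tibble(
    category = factor(roadmap_categories, levels = roadmap_categories),
    n = as.integer(counts),
    fraction = if (n_total > 0) as.integer(counts) / n_total else 0
  )
}
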