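#' Read annotated pLoF variants from a sites VCF
#'
#' Parses a VCF 4.2 sites file carrying the INFO keys `GENE`, `AC`, `AN`,
#' `LOF_FLAG`, `CSQ_CLASS`, `CODON`, `EXON` (the layout written by
#' [write_cohort()]) into one record per gene x alt allele. Multi-allelic
#' sites are split into one row per alt allele (AC is Number=A). Missing
#' optional keys become `NA`; a missing LOF_FLAG is retained as
#' `lof_flag = "none"` so downstream high-confidence filters exclude it.
#' Minor allele frequency is `min(AC/AN, 1 - AC/AN)`.
#'
#' @param vcf_path Path to the VCF.
#' @return Tibble with columns `gene_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `csq_class`, `lof_flag`, `allele_count`, `allele_number`, `maf`,
#'   `codon_index`, `exon_id`.
#' @export
read_variants <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path, call. = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(tibble::tibble(gene_id = character(), variant_id = character(),
                          chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), csq_class = character(),
                          lof_flag = character(), allele_count = integer(),
                          allele_number = integer(), maf = double(),
                          codon_index = integer(), exon_id = character()))
  }
  info_get <- function(key) {
    unname(vcfR::extract.info(vcf, element = key, as.numeric = FALSE))
  }
  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                       fixed = TRUE)
  ac_list <- strsplit(ifelse(is.na(info_get("AC")), "", info_get("AC")), ",",
                      fixed = TRUE)
  n_alt <- lengths(alt_list)
  if (any(lengths(ac_list) != n_alt)) {
    stop("AC entries do not match ALT allele counts (AC must be Number=A)",
         call. = FALSE)
  }
  idx <- rep(seq_len(nrow(fix)), n_alt)
  an <- suppressWarnings(as.integer(info_get("AN")))
  lof <- info_get("LOF_FLAG")
  ac <- suppressWarnings(as.integer(unlist(ac_list, use.names = FALSE)))
  anx <- an[idx]
  out <- tibble::tibble(
    gene_id = info_get("GENE")[idx],
    variant_id = fix[idx, "ID"],
    chrom = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]),
    ref = fix[idx, "REF"],
    alt = unlist(alt_list, use.names = FALSE),
    csq_class = info_get("CSQ_CLASS")[idx],
    lof_flag = ifelse(is.na(lof[idx]), "none", lof[idx]),
    allele_count = ac,
    allele_number = anx,
    maf = pmin(ac / anx, 1 - ac / anx),
    codon_index = suppressWarnings(as.integer(info_get("CODON")))[idx],
    exon_id = info_get("EXON")[idx]
  )
  bad <- !is.na(out$allele_count) & !is.na(out$allele_number) &
    (out$allele_count < 0 | out$allele_count > out$allele_number)
  if (any(bad)) {
    stop("allele_count outside [0, allele_number] at record ", which(bad)[1],
         call. = FALSE)
  }
  out
}

#' Filter variants to a LoF-confidence flag and MAF ceiling
#'
#' Keeps records whose `lof_flag` equals `require_flag` and whose minor
#' allele frequency is strictly below `maf_max` (strict inequality, matching
#' the "<5%" and "<0.1%" conventions). Input order is preserved; the filter
#' is idempotent.
#'
#' @param variants Tibble from [read_variants()].
#' @param maf_max MAF ceiling in (0, 1].
#' @param require_flag Required LoF-confidence flag (default `"HC"`).
#' @return Filtered tibble.
#' @export
filter_lof <- function(variants, maf_max, require_flag = "HC") {
  if (!is.numeric(maf_max) || maf_max <= 0 || maf_max > 1) {
    stop("`maf_max` must be in (0, 1]", call. = FALSE)
  }
  dplyr::filter(variants, .data$lof_flag == require_flag,
                .data$maf < maf_max)
}

#' Read a per-gene metadata table
#'
#' Expects a TSV with mandatory columns `gene_id`, `expected_lof`, `pli`,
#' plus optional `symbol`, `coding_codons` and 0/1 (or logical) gene-list
#' flag columns `omim_disease`, `two_hit_reported`, `drug_target`. Unknown
#' columns are dropped with a warning. `pli` may be `NA` (the gene is then
#' skipped by pLI-based rules downstream).
#'
#' @param tsv_path Path to the TSV.
#' @return Tibble of gene records; flags coerced to logical.
#' @export
read_gene_table <- function(tsv_path) {
  tbl <- readr::read_tsv(tsv_path, show_col_types = FALSE,
                         na = c("", "NA"))
  mandatory <- c("gene_id", "expected_lof", "pli")
  missing <- setdiff(mandatory, names(tbl))
  if (length(missing)) {
    stop("gene table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tbl$gene_id)) {
    stop("duplicated gene_id in gene table: ",
         tbl$gene_id[duplicated(tbl$gene_id)][1], call. = FALSE)
  }
  known <- c(mandatory, "symbol", "coding_codons", "omim_disease",
             "two_hit_reported", "drug_target")
  unknown <- setdiff(names(tbl), known)
  if (length(unknown)) {
    warning("ignoring unknown gene-table column(s): ",
            paste(unknown, collapse = ", "))
    tbl <- tbl[known[known %in% names(tbl)]]
  }
  if (any(!is.na(tbl$pli) & (tbl$pli < 0 | tbl$pli > 1))) {
    stop("pli outside [0, 1]", call. = FALSE)
  }
  if (any(!is.na(tbl$expected_lof) & tbl$expected_lof < 0)) {
    stop("expected_lof must be non-negative", call. = FALSE)
  }
  for (fl in c("omim_disease", "two_hit_reported", "drug_target")) {
    if (fl %in% names(tbl)) tbl[[fl]] <- as.logical(tbl[[fl]])
  }
  tbl
}

#' Write a per-gene metadata table as TSV
#' @param genes Gene tibble (flags written as 0/1).
#' @param tsv_path Output path.
#' @export
write_gene_table <- function(genes, tsv_path) {
  out <- dplyr::mutate(genes, dplyr::across(dplyr::where(is.logical),
                                            as.integer))
  readr::write_tsv(out, tsv_path)
  invisible(tsv_path)
}
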