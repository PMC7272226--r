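#' Default pipeline configuration
#'
#' Thresholds and population constants used across the pipeline:
#' `maf_caf = 0.05` (MAF ceiling for the cumulative-allele-frequency
#' variant set), `maf_constraint = 0.001` (ceiling for the constraint set),
#' `pli_cutoff = 0.9`, `alpha = 0.05`, `autozygosity_a = 0.058` (mean
#' autozygous genome fraction of individuals with second-cousin-or-closer
#' parents), `consanguineous_world_fraction = 0.104` (fraction of the world
#' population with such parents), plus synthetic-cohort sizes and the seed.
#'
#' @return Named list of class `lof_config`.
#' @export
default_run_config <- function() {
  structure(list(
    n_genes = 1000L,
    caf_range = c(1e-6, 1e-2),
    n_individuals = 5000L,
    founder_haplotypes = 1000L,
    autozygosity_a = 0.058,
    inbreeding_threshold_F = 0.05,
    consanguineous_world_fraction = 0.104,
    maf_caf = 0.05,
    maf_constraint = 0.001,
    pli_cutoff = 0.9,
    alpha = 0.05,
    seed = 1L
  ), class = "lof_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' Plain-text YAML; unknown keys are rejected, absent keys fall back to
#' [default_run_config()]. Write-then-read round-trips to an identical
#' configuration.
#'
#' @param path YAML path.
#' @return `read_run_config`: an `lof_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(raw)) {
    cfg[[k]] <- if (is.integer(cfg[[k]])) as.integer(raw[[k]])
                else as.numeric(raw[[k]])
  }
  .validate_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param config An `lof_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.validate_config <- function(cfg) {
  frac_keys <- c("maf_caf", "maf_constraint", "pli_cutoff", "alpha")
  for (k in frac_keys) {
    if (cfg[[k]] <= 0 || cfg[[k]] > 1) {
      stop("config `", k, "` must be in (0, 1]", call. = FALSE)
    }
  }
  if (cfg$autozygosity_a < 0 || cfg$autozygosity_a >= 1) {
    stop("config `autozygosity_a` must be in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Run the full simulated-cohort analysis pipeline
#'
#' Simulates a gene catalog and one cohort per population structure,
#' estimates per-gene cumulative pLoF allele frequency from the outbred
#' cohort, projects knockout discovery/lethality sample sizes per
#' structure, classifies genes into the knockout roadmap, computes
#' constraint (observed = high-confidence variants below the constraint
#' MAF ceiling; expected from the catalog) with Poisson upper bounds, and
#' compares constraint between the drug-target set and all genes. Each
#' stage writes a TSV under `out_dir`; a `run_log.txt` records the package
#' version, seed and configuration hash. Outputs are deterministic given
#' the seed (re-running with the same config reproduces byte-identical
#' files).
#'
#' @param config An `lof_config` (default [default_run_config()]).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list of the output paths.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (config$n_genes == 0) {
    # valid empty reports
    empty <- tibble::tibble(gene_id = character())
    for (f in c("catalog_genes", "caf", "projections", "roadmap",
                "constraint")) {
      paths[[f]] <- file.path(out_dir, paste0(f, ".tsv"))
      readr::write_tsv(empty, paths[[f]])
    }
    .write_run_log(config, out_dir)
    return(invisible(paths))
  }

  catalog <- step("simulate", simulate_catalog(
    config$n_genes, caf_range = config$caf_range, seed = config$seed))
  paths$catalog_genes <- file.path(out_dir, "catalog_genes.tsv")
  write_gene_table(catalog$genes, paths$catalog_genes)

  structures <- c("outbred", "bottlenecked", "consanguineous")
  cohorts <- step("simulate", {
    specs <- list(
      outbred = cohort_spec("outbred", config$n_individuals,
                            seed = config$seed + 1L),
      bottlenecked = cohort_spec("bottlenecked", config$n_individuals,
                                 founder_haplotypes =
                                   config$founder_haplotypes,
                                 seed = config$seed + 2L),
      consanguineous = cohort_spec("consanguineous", config$n_individuals,
                                   autozygosity_a = config$autozygosity_a,
                                   seed = config$seed + 3L)
    )
    lapply(specs, function(s) simulate_cohort(catalog, s))
  })
  for (s in structures) {
    pre <- file.path(out_dir, paste0("cohort_", s))
    write_cohort(cohorts[[s]], catalog, pre)
    paths[[paste0("vcf_", s)]] <- paste0(pre, ".vcf")
  }

  # carrier counts come from the simulated genotypes (the VCF is sites-only);
  # the HC + MAF filter selects which variants enter the tally
  caf <- step("caf", {
    variants <- read_variants(paths$vcf_outbred)
    keep <- filter_lof(variants, maf_max = config$maf_caf,
                       require_flag = "HC")
    estimate_caf(carrier_summary(cohorts$outbred,
                                 include_variants = keep$variant_id))
  })
  paths$caf <- file.path(out_dir, "caf.tsv")
  readr::write_tsv(caf, paths$caf)

  projections <- step("project", dplyr::bind_rows(
    project_genes(caf, "outbred", alpha = config$alpha),
    project_genes(estimate_caf(carrier_summary(cohorts$bottlenecked)),
                  "bottlenecked", alpha = config$alpha),
    project_genes(caf, "consanguineous",
                  autozygosity_a = config$autozygosity_a,
                  alpha = config$alpha)
  ))
  paths$projections <- file.path(out_dir, "projections.tsv")
  readr::write_tsv(projections, paths$projections)

  roadmap <- step("roadmap", classify_genes(catalog$genes, caf,
                                            pli_cutoff = config$pli_cutoff))
  paths$roadmap <- file.path(out_dir, "roadmap.tsv")
  readr::write_tsv(roadmap, paths$roadmap)
  paths$roadmap_summary <- file.path(out_dir, "roadmap_summary.tsv")
  readr::write_tsv(summarize_roadmap(roadmap), paths$roadmap_summary)

  constraint <- step("constraint", {
    variants <- read_variants(paths$vcf_outbred)
    cvars <- filter_lof(variants, maf_max = config$maf_constraint,
                        require_flag = "HC")
    observed <- dplyr::count(dplyr::filter(cvars, .data$allele_count > 0),
                             .data$gene_id, name = "observed")
    tbl <- dplyr::left_join(catalog$genes[c("gene_id", "expected_lof",
                                            "drug_target")],
                            observed, by = "gene_id")
    tbl$observed[is.na(tbl$observed)] <- 0L
    constraint_table(dplyr::rename(tbl, expected = "expected_lof"),
                     alpha = config$alpha)
  })
  paths$constraint <- file.path(out_dir, "constraint.tsv")
  readr::write_tsv(constraint, paths$constraint)

  comparison <- step("compare", {
    oe_targets <- constraint$oe[constraint$drug_target & !is.na(constraint$oe)]
    oe_all <- constraint$oe[!is.na(constraint$oe)]
    if (length(oe_targets) == 0) {
      tibble::tibble(label = character(), n = integer(), mean = double(),
                     ci_lower = double(), ci_upper = double(),
                     ks_D = double(), ks_p = double())
    } else {
      cmp <- compare_gene_sets(oe_targets, oe_all,
                               labels = c("drug_targets", "all_genes"))
      dplyr::mutate(cmp$sets, ks_D = cmp$ks_D, ks_p = cmp$ks_p)
    }
  })
  paths$comparison <- file.path(out_dir, "gene_set_comparison.tsv")
  readr::write_tsv(comparison, paths$comparison)

  .write_run_log(config, out_dir)
  paths$log <- file.path(out_dir, "run_log.txt")
  invisible(paths)
}

.write_run_log <- function(config, out_dir) {
  cfg_str <- paste(names(config), vapply(config, paste, "",
                                         collapse = ","),
                   sep = "=", collapse = ";")
  hash <- sum(utf8ToInt(cfg_str) * seq_along(utf8ToInt(cfg_str))) %%
    .Machine$integer.max
  writeLines(c(
    paste0("lofkit_version=", as.character(utils::packageVersion("lofkit"))),
    paste0("seed=", config$seed),
    paste0("config_hash=", hash),
    paste0("config=", cfg_str)
  ), file.path(out_dir, "run_log.txt"))
}
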