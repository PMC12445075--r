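# End-to-end orchestration of the synthetic discovery pipeline:
# simulate -> shared differential peaks -> STAT-open regions -> signature
# derivation -> scoring -> survival stratification (-> single-cell stage),
# with a planted-truth recovery report and a reproducible run manifest.

truth_enhancer_peaks <- function(truth, ids) {
  e <- truth$enhancers[match(ids, truth$enhancers$enhancer_id), ]
  new_peaks(chrom = e$chrom, start = e$start, end = e$end,
            name = e$enhancer_id)
}

#' Run the full synthetic discovery pipeline
#'
#' Generates every input with planted ground truth under `config`, derives
#' shared differential binding regions from the two stimulation conditions,
#' intersects them with inducible-only accessibility to get STAT-open
#' regions, derives the stress-response signature on the synthetic tumor
#' cohort, scores and stratifies the cohort at the best survival cutoff,
#' derives and applies the cell-line inducibility signature, optionally runs
#' the single-cell stage (QC, extreme-decile stratification, treatment
#' enrichment), and reports how much of the planted truth was recovered.
#'
#' @param config A [sim_config()].
#' @param include_scrna Run the single-cell stage (default `TRUE`).
#' @param outdir Optional directory; when given, all primary artifacts are
#'   written there (BED, TSV, GMT, JSON) along with the manifest.
#' @return Object of class `stress_pipeline`: list with `report` (tibble of
#'   truth-recovery metrics), `signature`, `inducible_signature`,
#'   `stratification` (a [best_cutoff()] object), `scores`, `inducibility`
#'   (classified panel scores), `scrna` (list or `NULL`), `truth`, and
#'   `manifest`.
#' @export
run_full_synthetic <- function(config = sim_config(), include_scrna = TRUE,
                               outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ref <- simulate_reference(config)
  truth <- ref$truth

  chip_osm <- simulate_chip(config, truth, "OSM")
  chip_hyp <- simulate_chip(config, truth, "hypoxia")
  shared <- shared_differential_peaks(chip_osm, chip_hyp)
  atac_ind <- simulate_atac(config, truth, "inducible")
  atac_non <- simulate_atac(config, truth, "non-inducible")
  regions <- stat_open_regions(shared, atac_ind, atac_non)

  bulk <- simulate_bulk_cohort(config, truth)
  sig <- derive_stress_signature(shared, atac_ind, atac_non,
                                 ref$enhancer_map, ref$genes,
                                 bulk$expr, bulk$survival)

  logexpr <- normalize_counts(bulk$expr, "size_factors", log2 = TRUE)
  scores <- mean_signature_score(logexpr, sig)
  strat <- best_cutoff(scores, bulk$survival)

  panel <- simulate_cellline_panel(config, truth)
  known <- panel$labels$sample[panel$labels$known]
  ind_sig <- derive_inducible_signature(
    panel$counts[, known],
    panel$labels$sample[panel$labels$known &
                          panel$labels$group == "inducible"],
    panel$labels$sample[panel$labels$known &
                          panel$labels$group == "non-inducible"]
  )
  panel_log <- normalize_counts(panel$counts, "size_factors", log2 = TRUE)
  inducibility <- classify_inducibility(rank_score(panel_log, ind_sig))

  # --- truth recovery ---
  planted <- truth_enhancer_peaks(truth, truth$shared_enhancer_ids)
  hits <- if (nrow(regions) > 0) intersect_peaks(regions, planted) else NULL
  regions_hit <- if (is.null(hits)) 0L else length(unique(hits$b_name))
  regions_exact <- nrow(regions) == nrow(planted) &&
    regions_hit == nrow(planted)
  catalog <- sig$provenance$catalog %||% character(0)
  module <- c(truth$module_genes$hazardous, truth$module_genes$protective)
  dirs <- sig$provenance$directions
  truth_dir <- tibble(
    gene = module,
    truth_direction = rep(c("hazardous", "protective"),
                          c(length(truth$module_genes$hazardous),
                            length(truth$module_genes$protective)))
  )
  dir_check <- left_join(truth_dir, dirs, by = "gene")
  genes_correct <- sum(!is.na(dir_check$direction) &
                         dir_check$direction == dir_check$truth_direction)
  selected <- c(sig$up_genes, sig$down_genes)
  intruders <- length(setdiff(selected, module))

  class_truth <- panel$labels$group
  class_called <- inducibility$class[match(panel$labels$sample,
                                           inducibility$sample)]
  known_idx <- panel$labels$known
  class_acc <- mean(class_called[known_idx] == class_truth[known_idx])

  report <- tibble(
    metric = c("n_shared_regions", "n_stat_open_regions",
               "stat_open_regions_exact", "n_candidate_genes",
               "catalog_matches_truth", "n_selected_genes",
               "n_module_genes_correct_direction", "n_intruders",
               "hr_high_vs_low", "logrank_p",
               "n_inducible_signature_genes",
               "panel_classification_accuracy"),
    value = c(nrow(shared), nrow(regions), as.numeric(regions_exact),
              length(catalog), as.numeric(setequal(catalog,
                                                   truth$candidate_genes)),
              length(selected), genes_correct, intruders,
              strat$cox$hr, strat$p, length(ind_sig$up_genes), class_acc)
  )

  scrna <- NULL
  if (include_scrna) {
    sc <- simulate_scrna(config, truth)
    qc <- qc_filter(sc$counts, sc$meta, sc$genes,
                    min_genes = config$sc_min_genes)
    norm <- normalize_cells(qc$counts)
    malignant <- qc$meta$cell_type == "epithelial_malignant"
    meta_m <- mutate(qc$meta[malignant, ],
                     total_counts = colSums(qc$counts[, malignant,
                                                      drop = FALSE]))
    strata_meta <- stratify_extremes(norm[, malignant, drop = FALSE],
                                     meta_m, truth$candidate_genes[1])
    enr <- enrichment_fold(strata_meta$strata, strata_meta$treatment)
    scrna <- list(qc_report = qc$report, strata = strata_meta,
                  enrichment = enr,
                  cells_per_group = sum(strata_meta$strata == "High"))
  }

  manifest <- list(
    package = "stressig",
    version = as.character(utils::packageVersion("stressig")),
    config = unclass(config),
    stages = c("simulate", "shared-peaks", "stat-open", "derive-stress",
               "derive-inducible", "score", "survive",
               if (include_scrna) "scrna")
  )

  out <- structure(list(
    report = report, signature = sig, inducible_signature = ind_sig,
    stratification = strat, scores = scores, inducibility = inducibility,
    regions = regions, shared = shared, truth = truth, scrna = scrna,
    manifest = manifest
  ), class = "stress_pipeline")

  if (!is.null(outdir)) write_pipeline_outputs(out, ref, bulk, outdir)
  out
}

write_pipeline_outputs <- function(x, ref, bulk, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_bed(x$shared[, 1:8], p("shared_peaks.bed"))
  if (nrow(x$regions) > 0) write_bed(x$regions[, 1:8], p("stat_open.bed"))
  write_enhancer_map(ref$enhancer_map, p("enhancer_map.tsv"))
  write_expression(bulk$expr, p("tumor_expression.tsv"))
  write_survival(bulk$survival, p("survival.tsv"))
  write_gmt(x$signature, p("stress_signature.gmt"))
  readr::write_tsv(x$scores, p("signature_scores.tsv"))
  readr::write_tsv(x$report, p("truth_recovery.tsv"))
  jsonlite::write_json(
    list(shared_enhancers = x$truth$shared_enhancer_ids,
         candidate_genes = x$truth$candidate_genes,
         module_genes = x$truth$module_genes),
    p("truth.json"), auto_unbox = TRUE, pretty = TRUE
  )
  jsonlite::write_json(x$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(outdir)
}

#' @export
print.stress_pipeline <- function(x, ...) {
  cat("Synthetic discovery pipeline run\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' @export
glance.stress_pipeline <- function(x, ...) {
  tidyr::pivot_wider(x$report, names_from = "metric", values_from = "value")
}
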