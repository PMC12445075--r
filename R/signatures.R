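# Signature derivation: the cell-line inducibility signature (DE gates plus a
# within-group SD robustness filter) and the enhancer-driven STRESS-style
# signature (STAT-open regions -> candidate catalog -> correlation-frequency
# ranking -> top-half selection -> per-gene survival direction).

#' Construct a gene signature
#'
#' A signature is a named set of up-weighted genes, optionally paired with a
#' disjoint set of down-weighted genes, plus free-form provenance describing
#' how it was derived.
#'
#' @param name Signature name.
#' @param up_genes Character vector of up-weighted gene identifiers.
#' @param down_genes Character vector of down-weighted gene identifiers
#'   (disjoint from `up_genes`).
#' @param provenance Named list of derivation details.
#' @return Object of class `gene_signature`.
#' @export
new_gene_signature <- function(name, up_genes, down_genes = character(0),
                               provenance = list()) {
  if (length(intersect(up_genes, down_genes)) > 0) {
    abort("up and down gene lists must be disjoint")
  }
  structure(list(name = name, up_genes = up_genes, down_genes = down_genes,
                 provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature:", x$name, "\n")
  cat("  up  (", length(x$up_genes), "):",
      paste(head(x$up_genes, 8), collapse = ", "),
      if (length(x$up_genes) > 8) "..." else "", "\n")
  cat("  down(", length(x$down_genes), "):",
      paste(head(x$down_genes, 8), collapse = ", "),
      if (length(x$down_genes) > 8) "..." else "", "\n")
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1, x$provenance)
  if (length(scalars) > 0) {
    cat("  provenance:",
        paste(names(scalars), vapply(scalars, format, ""),
              sep = "=", collapse = ", "), "\n")
  }
  tables <- setdiff(names(x$provenance), names(scalars))
  if (length(tables) > 0) {
    cat("  provenance tables:", paste(tables, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.gene_signature <- function(x, ...) {
  bind_rows(
    tibble(gene = x$up_genes, direction = "up"),
    tibble(gene = x$down_genes, direction = "down")
  )
}

#' @export
glance.gene_signature <- function(x, ...) {
  tibble(name = x$name, n_up = length(x$up_genes),
         n_down = length(x$down_genes))
}

#' Derive an inducibility signature from a cell-line panel
#'
#' Pipeline: size-factor normalization; per-gene Welch t differential
#' expression between inducible and non-inducible lines; keep genes with
#' `|log2FC| > fc_gate` and FDR `< fdr_gate`; then drop any surviving gene
#' whose within-group SD of `log2(normalized + 1)` expression exceeds
#' `sd_gate` in either group (a robustness filter keeping only genes
#' consistent across all lines of a group). Up-regulated survivors form the
#' signature's up list; the down list is empty by construction.
#'
#' @param counts Count matrix, genes x samples.
#' @param inducible_samples,noninducible_samples Sample id vectors.
#' @param fc_gate,fdr_gate Differential-expression gates.
#' @param sd_gate Within-group SD ceiling on the log scale.
#' @return A `gene_signature` with stage-by-stage counts in `provenance`.
#' @export
derive_inducible_signature <- function(counts, inducible_samples,
                                       noninducible_samples,
                                       fc_gate = 1, fdr_gate = 0.05,
                                       sd_gate = 2) {
  if (length(inducible_samples) < 2 || length(noninducible_samples) < 2) {
    abort("need at least 2 samples per group")
  }
  de <- differential_expression(
    counts[, c(inducible_samples, noninducible_samples)],
    inducible_samples, noninducible_samples,
    fc_gate = fc_gate, fdr_gate = fdr_gate
  )
  degs <- filter(de, .data$significant)
  logn <- normalize_counts(counts[, c(inducible_samples, noninducible_samples)],
                           "size_factors", log2 = TRUE)
  sd_in <- apply(logn[degs$gene, inducible_samples, drop = FALSE], 1, sd)
  sd_non <- apply(logn[degs$gene, noninducible_samples, drop = FALSE], 1, sd)
  robust <- degs[sd_in <= sd_gate & sd_non <= sd_gate, ]
  up <- robust$gene[robust$log2fc > 0]
  new_gene_signature(
    "inducible", up_genes = sort(up),
    provenance = list(
      n_genes = nrow(de), n_degs = nrow(degs),
      n_after_sd_filter = nrow(robust), n_up = length(up),
      fc_gate = fc_gate, fdr_gate = fdr_gate, sd_gate = sd_gate
    )
  )
}

#' Rank genes by significant-pair frequency
#'
#' A pair is significant when its (adjusted, by default) p value is below
#' `alpha`. Each gene is scored by the number of significant pairs containing
#' it and ranked descending by that count with competition ranking (ties share
#' the better rank); tie order within a rank is alphabetical. Genes appearing
#' in the pair list but in no significant pair are kept with count 0.
#'
#' @param pairs Correlation-pair tibble from [pearson_pairs()].
#' @param alpha Significance level for a pair.
#' @param use_adjusted Use `p_adj` (default) or raw `p`.
#' @return Tibble with `gene`, `n_significant_pairs`, `rank`.
#' @export
rank_by_pair_frequency <- function(pairs, alpha = 0.05, use_adjusted = TRUE) {
  pcol <- if (use_adjusted) pairs$p_adj else pairs$p
  sig <- pairs[!is.na(pcol) & pcol < alpha, ]
  universe <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  counts <- table(factor(c(sig$gene_a, sig$gene_b), levels = universe))
  out <- tibble(gene = universe, n_significant_pairs = as.integer(counts))
  out <- arrange(out, desc(.data$n_significant_pairs), .data$gene)
  out$rank <- rank(-out$n_significant_pairs, ties.method = "min")
  out
}

#' Select the top half of a pair-frequency ranking
#'
#' Among genes with at least one significant pair, keeps those whose
#' competition rank is at most half (ceiling) of the number of distinct ranks.
#' The threshold and resulting size are attached as attributes so the
#' selection is auditable.
#'
#' @param ranking Tibble from [rank_by_pair_frequency()].
#' @return Character vector of selected genes with attributes
#'   `rank_threshold`, `n_distinct_ranks`, `n_selected`.
#' @export
select_top_half <- function(ranking) {
  if (nrow(ranking) == 0) abort("empty ranking")
  nz <- filter(ranking, .data$n_significant_pairs >= 1)
  if (nrow(nz) == 0) {
    return(structure(character(0), rank_threshold = 0L,
                     n_distinct_ranks = 0L, n_selected = 0L))
  }
  d <- length(unique(nz$rank))
  thr <- ceiling(d / 2)
  sel <- sort(nz$gene[nz$rank <= thr])
  structure(sel, rank_threshold = thr, n_distinct_ranks = d,
            n_selected = length(sel))
}

#' Call the survival direction of a gene
#'
#' Dichotomizes the gene's expression at the best log-rank cutoff (see
#' [best_cutoff()]) and fits a binary Cox model; hazard ratio above 1 calls
#' the gene hazardous, below 1 protective. The call is flagged unstable when
#' the Cox p exceeds 0.5, and undefined when the cohort has no events.
#' `mode = "continuous"` instead fits the expression values directly as a
#' continuous Cox covariate.
#'
#' @param expr Expression matrix, genes x samples (log scale recommended).
#' @param gene Gene id.
#' @param survival_table Tibble with `sample`, `time`, `event`.
#' @param mode `"best_cutoff"` (default) or `"continuous"`.
#' @param lower_q,upper_q Cutoff-scan band for the best-cutoff mode.
#' @return One-row tibble: `gene`, `direction` (`"hazardous"`,
#'   `"protective"`, or `NA`), `hr`, `p`, `flagged`.
#' @export
survival_direction <- function(expr, gene, survival_table,
                               mode = c("best_cutoff", "continuous"),
                               lower_q = 0.25, upper_q = 0.75) {
  mode <- match.arg(mode)
  if (!gene %in% rownames(expr)) abort(paste0("gene not in matrix: ", gene))
  common <- intersect(colnames(expr), survival_table$sample)
  st <- survival_table[match(common, survival_table$sample), ]
  if (sum(st$event) == 0) {
    return(tibble(gene = gene, direction = NA_character_, hr = NA_real_,
                  p = NA_real_, flagged = TRUE))
  }
  if (mode == "best_cutoff") {
    bc <- best_cutoff(setNames(expr[gene, common], common), st,
                      lower_q = lower_q, upper_q = upper_q)
    hr <- bc$cox$hr; p <- bc$cox$p
  } else {
    d <- data.frame(time = st$time, event = st$event,
                    x = as.numeric(expr[gene, common]))
    fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                           ties = "breslow")
    hr <- exp(unname(stats::coef(fit)))
    p <- 2 * pnorm(-abs(unname(stats::coef(fit)) /
                          sqrt(unname(stats::vcov(fit)[1, 1]))))
  }
  tibble(gene = gene,
         direction = if (hr > 1) "hazardous" else "protective",
         hr = hr, p = p, flagged = p > 0.5)
}

#' Derive an enhancer-driven stress-response signature
#'
#' The composed discovery pipeline: (1) [stat_open_regions()] finds binding
#' regions accessible only in inducible lines; (2) [annotate_peaks()] maps
#' them to enhancer target genes, giving the candidate catalog; (3)
#' [pearson_pairs()] on tumor expression with Holm adjustment; (4)
#' [rank_by_pair_frequency()] and [select_top_half()] keep the most
#' co-expressed genes; (5) [survival_direction()] splits the selection into
#' hazardous (up) and protective (down) lists. Every stage count is recorded
#' in the signature's provenance.
#'
#' @param chip_shared Shared differential binding regions
#'   ([shared_differential_peaks()]).
#' @param atac_ind,atac_non Accessibility peak sets for inducible and
#'   non-inducible lines.
#' @param enhancer_map,genes Reference tables (see [annotate_peaks()]).
#' @param tumor_expr Tumor expression count matrix, genes x samples.
#' @param survival_table Tibble with `sample`, `time`, `event`.
#' @param alpha Pair-significance level.
#' @param use_adjusted Gate pairs on Holm-adjusted p (default) or raw p.
#' @param name Signature name.
#' @return A `gene_signature` (hazardous genes up, protective genes down)
#'   with provenance, plus attributes-free access to the intermediate
#'   `regions`, `catalog`, `ranking`, and `directions` in `provenance`.
#' @export
derive_stress_signature <- function(chip_shared, atac_ind, atac_non,
                                    enhancer_map, genes, tumor_expr,
                                    survival_table, alpha = 0.05,
                                    use_adjusted = TRUE, name = "STRESS") {
  regions <- stat_open_regions(chip_shared, atac_ind, atac_non)
  if (nrow(regions) == 0) {
    warn("no STAT-open regions; returning empty signature")
    return(new_gene_signature(name, character(0),
                              provenance = list(n_regions = 0L)))
  }
  ann <- annotate_peaks(regions, enhancer_map, genes)
  catalog <- sort(unique(ann$gene[ann$type == "enhancer" & !is.na(ann$gene)]))
  catalog <- intersect(catalog, rownames(tumor_expr))
  if (length(catalog) < 2) {
    warn("fewer than 2 catalog genes present in expression; empty signature")
    return(new_gene_signature(name, character(0),
                              provenance = list(n_regions = nrow(regions),
                                                n_candidates = length(catalog))))
  }
  logexpr <- normalize_counts(tumor_expr, "size_factors", log2 = TRUE)
  pairs <- pearson_pairs(logexpr, catalog)
  ranking <- rank_by_pair_frequency(pairs, alpha = alpha,
                                    use_adjusted = use_adjusted)
  selected <- select_top_half(ranking)
  dirs <- map_dfr(selected, function(g) {
    survival_direction(logexpr, g, survival_table)
  })
  up <- if (nrow(dirs) > 0) dirs$gene[dirs$direction == "hazardous"]
        else character(0)
  down <- if (nrow(dirs) > 0) dirs$gene[dirs$direction == "protective"]
          else character(0)
  new_gene_signature(
    name, up_genes = sort(up[!is.na(up)]), down_genes = sort(down[!is.na(down)]),
    provenance = list(
      n_regions = nrow(regions),
      n_candidates = length(catalog),
      n_ranked = nrow(ranking),
      n_selected = length(selected),
      rank_threshold = attr(selected, "rank_threshold"),
      n_up = sum(dirs$direction == "hazardous", na.rm = TRUE),
      n_down = sum(dirs$direction == "protective", na.rm = TRUE),
      alpha = alpha, use_adjusted = use_adjusted,
      regions = regions, catalog = catalog, ranking = ranking,
      directions = dirs
    )
  )
}
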