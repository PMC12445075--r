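# Single-cell stage: QC gates, library-size normalization, extreme-decile
# stratification, extreme-group differential expression, treatment-enrichment
# fold, and a simplified sliding-window CNV score.

#' Quality-control filter for single-cell counts
#'
#' Gates applied in order: (1) cells with fewer than `min_genes` detected
#' genes removed; (2) genes detected in fewer than `min_cells` of the
#' remaining cells removed; (3) cells whose mitochondrial or ribosomal count
#' fraction exceeds `max_mt` / `max_ribo` removed (separate gates); (4) cells
#' whose detected-gene count is strictly above the `gene_pct` percentile
#' (type-7 quantile over the remaining cells) removed.
#'
#' @param counts Count matrix, genes x cells.
#' @param meta Tibble with a `cell` column aligned to `colnames(counts)`.
#' @param gene_meta Tibble with `gene`, `is_mt`, `is_ribo`.
#' @param min_genes Detected-gene floor per cell.
#' @param min_cells Detection floor per gene.
#' @param max_mt,max_ribo Count-fraction ceilings.
#' @param gene_pct Upper percentile gate on detected genes per cell.
#' @return List with `counts`, `meta` (filtered) and `report` (tibble: gate,
#'   removed, remaining).
#' @export
qc_filter <- function(counts, meta, gene_meta, min_genes = 200,
                      min_cells = 10, max_mt = 0.15, max_ribo = 0.15,
                      gene_pct = 98) {
  counts <- as.matrix(counts)
  if (!all(c("is_mt", "is_ribo") %in% names(gene_meta))) {
    abort("gene_meta must flag is_mt and is_ribo")
  }
  report <- list()
  note <- function(gate, removed, counts) {
    report[[length(report) + 1]] <<- tibble(
      gate = gate, removed = removed,
      remaining = paste0(nrow(counts), " genes x ", ncol(counts), " cells")
    )
  }
  detected <- colSums(counts > 0)
  keep_cells <- detected >= min_genes
  counts <- counts[, keep_cells, drop = FALSE]
  meta <- meta[keep_cells, ]
  note("cell_min_genes", sum(!keep_cells), counts)

  gene_cells <- rowSums(counts > 0)
  keep_genes <- gene_cells >= min_cells
  counts <- counts[keep_genes, , drop = FALSE]
  gm <- gene_meta[match(rownames(counts), gene_meta$gene), ]
  note("gene_min_cells", sum(!keep_genes), counts)

  totals <- colSums(counts)
  mt_frac <- colSums(counts[gm$is_mt, , drop = FALSE]) / totals
  ribo_frac <- colSums(counts[gm$is_ribo, , drop = FALSE]) / totals
  keep_cells <- mt_frac <= max_mt & ribo_frac <= max_ribo
  counts <- counts[, keep_cells, drop = FALSE]
  meta <- meta[keep_cells, ]
  note("mt_ribo_fraction", sum(!keep_cells), counts)

  detected <- colSums(counts > 0)
  thr <- quantile(detected, gene_pct / 100, type = 7)
  keep_cells <- detected <= thr
  counts <- counts[, keep_cells, drop = FALSE]
  meta <- meta[keep_cells, ]
  note("gene_count_percentile", sum(!keep_cells), counts)

  report <- bind_rows(report)
  if (ncol(counts) == 0 || nrow(counts) == 0) {
    print(report)
    abort("no cells or genes survive QC (per-gate report above)")
  }
  list(counts = counts, meta = meta, report = report)
}

#' Library-size normalization and log transform
#'
#' Scales each cell to the median total count across cells, then applies
#' `log1p`.
#'
#' @param counts Count matrix, genes x cells.
#' @return Log-normalized matrix of the same shape.
#' @export
normalize_cells <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) abort("cell with zero total counts")
  log1p(sweep(counts, 2, totals / median(totals), "/"))
}

#' Stratify cells by the expression extremes of one gene
#'
#' Ranks all cells by the gene's expression and labels exactly `floor(q * N)`
#' cells `High` (top) and the same number `Low` (bottom); everything else is
#' `neither`. Boundary ties are broken by total counts descending, then cell
#' id, so the stratification is deterministic. Stratification is intended to
#' run on the pooled target population (e.g., all malignant cells across
#' treatment groups).
#'
#' @param log_expr Expression matrix, genes x cells.
#' @param meta Tibble with `cell` aligned to columns; a `total_counts` column
#'   is used for tie-breaking (computed from `log_expr` if absent).
#' @param gene Gene id to stratify on.
#' @param q Extreme fraction per tail (default 0.10).
#' @return `meta` with an added `strata` column (`High`/`Low`/`neither`).
#' @export
stratify_extremes <- function(log_expr, meta, gene, q = 0.10) {
  if (!gene %in% rownames(log_expr)) abort(paste0("gene absent: ", gene))
  n <- ncol(log_expr)
  k <- floor(q * n)
  if (k < 10) abort("q * N < 10: extreme groups too small")
  totals <- if ("total_counts" %in% names(meta)) meta$total_counts
            else colSums(log_expr)
  x <- log_expr[gene, ]
  ids <- meta$cell
  ord_top <- order(-x, -totals, ids)
  ord_bot <- order(x, -totals, ids)
  strata <- rep("neither", n)
  strata[ord_top[seq_len(k)]] <- "High"
  strata[ord_bot[seq_len(k)]] <- "Low"
  mutate(meta, strata = strata)
}

#' Differential expression between extreme strata
#'
#' Per-gene Mann-Whitney test between the `High` and `Low` cells with BH
#' adjustment; the significance score is `-log10(p)` and the enrichment
#' score is the difference of group mean log expression.
#'
#' @param log_expr Expression matrix, genes x cells.
#' @param strata Character vector aligned to cells (`High`/`Low`/other).
#' @return Tibble with `gene`, `enrichment` (log FC), `p`, `p_adj`,
#'   `significance` (`-log10 p`).
#' @export
extreme_de <- function(log_expr, strata) {
  hi <- strata == "High"; lo <- strata == "Low"
  if (!any(hi) || !any(lo)) abort("both strata must be non-empty")
  x <- as.matrix(log_expr)
  n1 <- sum(hi); n2 <- sum(lo)
  sub <- x[, hi | lo, drop = FALSE]
  grp_hi <- strata[hi | lo] == "High"
  stats_by_gene <- apply(sub, 1, function(v) {
    r <- rank(v)
    u <- sum(r[grp_hi]) - n1 * (n1 + 1) / 2
    nt <- n1 + n2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (nt * (nt - 1))
    sigma2 <- n1 * n2 / 12 * (nt + 1 - tie_term)
    if (sigma2 == 0) return(c(u, 1))
    z <- (u - n1 * n2 / 2 - sign(u - n1 * n2 / 2) * 0.5) / sqrt(sigma2)
    c(u, min(1, 2 * pnorm(-abs(z))))
  })
  p <- stats_by_gene[2, ]
  enr <- rowMeans(sub[, grp_hi, drop = FALSE]) -
    rowMeans(sub[, !grp_hi, drop = FALSE])
  p_adj <- adjust_pvalues(p, "bh")
  tibble(gene = rownames(x), enrichment = unname(enr), p = unname(p),
         p_adj = unname(p_adj),
         significance = -log10(pmax(unname(p), 1e-300)))
}

#' Treatment enrichment of the High stratum
#'
#' Fold change of the proportion of High cells among treated cells over the
#' proportion among naive cells, with the 2x2 High/Low by treated/naive
#' contingency table. A Haldane correction (+0.5 to every cell of the
#' proportion ratio) is applied only when a zero cell occurs, and flagged.
#'
#' @param strata Character vector (`High`/`Low`/`neither`) per cell.
#' @param treatment Character vector (`naive`/`treated`) per cell.
#' @return List with `fold`, `table` (2x2), `haldane` flag.
#' @export
enrichment_fold <- function(strata, treatment) {
  if (!all(c("naive", "treated") %in% treatment)) {
    abort("both treatments must be represented")
  }
  n_treated <- sum(treatment == "treated")
  n_naive <- sum(treatment == "naive")
  hi_treated <- sum(strata == "High" & treatment == "treated")
  hi_naive <- sum(strata == "High" & treatment == "naive")
  tab <- matrix(c(hi_treated, hi_naive,
                  sum(strata == "Low" & treatment == "treated"),
                  sum(strata == "Low" & treatment == "naive")),
                nrow = 2, dimnames = list(c("treated", "naive"),
                                          c("High", "Low")))
  haldane <- hi_treated == 0 || hi_naive == 0
  if (haldane) {
    warn("zero cell in enrichment table; Haldane correction applied")
    fold <- ((hi_treated + 0.5) / (n_treated + 0.5)) /
      ((hi_naive + 0.5) / (n_naive + 0.5))
  } else {
    fold <- (hi_treated / n_treated) / (hi_naive / n_naive)
  }
  list(fold = fold, table = tab, haldane = haldane)
}

#' Sliding-window CNV score
#'
#' Relative expression per cell is the cell's log expression minus the
#' reference-cell mean per gene, clipped to three reference standard
#' deviations; the profile is a centered moving average over `window`
#' consecutive genes (truncated at the chromosome ends), and the burden is
#' the mean squared profile per cell. Genes must already be ordered by
#' genomic position. Identifying (and removing) the lowest-burden cluster is
#' left to the caller.
#'
#' @param log_expr Log-expression matrix, genes (position-ordered) x cells.
#' @param reference_cells Cell ids of the normal reference population.
#' @param window Moving-average width in genes (default 250).
#' @return List with `profile` (genes x cells matrix) and `burden` (named
#'   per-cell vector).
#' @export
cnv_window_score <- function(log_expr, reference_cells, window = 250) {
  x <- as.matrix(log_expr)
  if (window > nrow(x)) abort("window exceeds gene count")
  if (window < 1) abort("window must be >= 1")
  ref <- x[, reference_cells, drop = FALSE]
  ref_mean <- rowMeans(ref)
  ref_sd <- apply(ref, 1, sd)
  ref_sd[ref_sd == 0 | is.na(ref_sd)] <- mean(ref_sd[ref_sd > 0], na.rm = TRUE)
  rel <- sweep(x, 1, ref_mean)
  lim <- 3 * ref_sd
  rel <- pmin(pmax(rel, -lim), lim)
  # centered moving average, truncated at ends, via cumulative sums
  half_l <- floor((window - 1) / 2)
  half_r <- window - 1 - half_l
  G <- nrow(rel)
  cs <- apply(rel, 2, cumsum)
  cs <- rbind(0, cs)
  lo <- pmax(seq_len(G) - half_l, 1)
  hi <- pmin(seq_len(G) + half_r, G)
  profile <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1)
  dimnames(profile) <- dimnames(rel)
  list(profile = profile, burden = colMeans(profile^2))
}
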