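# Signature scoring: rank-based per-sample scores with closed-form
# normalization extremes, z-score inducibility classification, mean-expression
# scores with down-gene inversion (the survival-stratification score), subtype
# z scores, and bin-matched per-cell set scores.

check_coverage <- function(expr, signature) {
  sig_genes <- c(signature$up_genes, signature$down_genes)
  present <- intersect(sig_genes, rownames(expr))
  if (length(present) < length(sig_genes) / 2) {
    abort(paste0("signature coverage below 50%; missing: ",
                 paste(setdiff(sig_genes, rownames(expr)), collapse = ", ")))
  }
  list(up = intersect(signature$up_genes, rownames(expr)),
       down = intersect(signature$down_genes, rownames(expr)))
}

# theoretical extremes of the mean rank of a k-gene set among G ranks:
# min (k+1)/2 when the set occupies the bottom ranks, max (2G-k+1)/2 at the top
rank_set_score <- function(rank_mat, set_genes) {
  G <- nrow(rank_mat)
  k <- length(set_genes)
  mean_rank <- colMeans(rank_mat[set_genes, , drop = FALSE])
  lo <- (k + 1) / 2
  hi <- (2 * G - k + 1) / 2
  (mean_rank - lo) / (hi - lo)
}

#' Rank-based signature score
#'
#' Per sample, all G genes are ranked by expression (midrank ties). The up
#' score is the mean rank of the up genes, min-max normalized by its
#' closed-form extremes for a k-gene set ((k+1)/2 and (2G-k+1)/2); the down
#' score is computed the same way and subtracted. The normalized score lies in
#' \[-1, 1\] (in \[0, 1\] for up-only signatures) and is invariant to strictly
#' monotone per-sample transforms of the expression values. A constant sample
#' scores at the midpoint and is flagged.
#'
#' @param expr Expression matrix, genes x samples.
#' @param signature A `gene_signature` (>= 50% of its genes must be present).
#' @return Tibble with `sample`, `raw_score` (mean-rank difference),
#'   `normalized_score`, `flagged`.
#' @export
rank_score <- function(expr, signature) {
  sets <- check_coverage(expr, signature)
  expr <- as.matrix(expr)
  rank_mat <- apply(expr, 2, rank)
  rownames(rank_mat) <- rownames(expr)
  up_n <- rank_set_score(rank_mat, sets$up)
  raw <- colMeans(rank_mat[sets$up, , drop = FALSE])
  score <- up_n
  if (length(sets$down) > 0) {
    down_n <- rank_set_score(rank_mat, sets$down)
    score <- up_n - down_n
    raw <- raw - colMeans(rank_mat[sets$down, , drop = FALSE])
  }
  flagged <- apply(expr, 2, function(x) length(unique(x)) == 1)
  tibble(sample = colnames(expr) %||% as.character(seq_len(ncol(expr))),
         raw_score = unname(raw),
         normalized_score = unname(score),
         flagged = unname(flagged))
}

#' Classify inducibility from signature scores
#'
#' Standardizes the normalized scores to z scores across the cohort and calls
#' a sample inducible at `z >= z_band`, non-inducible at `z <= -z_band`, and
#' intermediate in between. Zero score variance yields all-intermediate with a
#' warning. The returned table is ranked by score, descending.
#'
#' @param scores Score tibble from [rank_score()].
#' @param z_band Half-width of the intermediate band in standard units.
#' @return `scores` with added `z` and `class` columns, ranked.
#' @export
classify_inducibility <- function(scores, z_band = 0.5) {
  if (nrow(scores) < 3) abort("need at least 3 samples")
  s <- sd(scores$normalized_score)
  if (s == 0) {
    warn("zero score variance; all samples classified intermediate")
    z <- rep(0, nrow(scores))
  } else {
    z <- (scores$normalized_score - mean(scores$normalized_score)) / s
  }
  out <- mutate(scores, z = z,
                class = dplyr::case_when(
                  z >= z_band ~ "inducible",
                  z <= -z_band ~ "non-inducible",
                  TRUE ~ "intermediate"
                ))
  arrange(out, desc(.data$z))
}

#' Plot ranked inducibility classification
#'
#' Ranked bar plot of z-scored signature values colored by class.
#'
#' @param scores Output of [classify_inducibility()].
#' @return A ggplot object.
#' @export
plot_inducibility <- function(scores) {
  d <- mutate(scores, sample = factor(.data$sample, levels = .data$sample))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$z,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Signature z score") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Mean-expression signature score with down-gene inversion
#'
#' The score fed to survival stratification: per-sample mean expression over
#' the up genes minus (when `invert_down`) the mean over the down genes, on
#' whatever scale `expr` is provided (log scale recommended). With
#' `invert_down = FALSE` the mean is taken over all signature genes.
#'
#' @param expr Expression matrix, genes x samples.
#' @param signature A `gene_signature`.
#' @param invert_down Invert the contribution of down genes (default `TRUE`).
#' @return Tibble with `sample` and `score`.
#' @export
mean_signature_score <- function(expr, signature, invert_down = TRUE) {
  sets <- check_coverage(expr, signature)
  expr <- as.matrix(expr)
  up_mean <- if (length(sets$up) > 0) {
    colMeans(expr[sets$up, , drop = FALSE])
  } else rep(0, ncol(expr))
  score <- if (invert_down && length(sets$down) > 0) {
    up_mean - colMeans(expr[sets$down, , drop = FALSE])
  } else if (!invert_down) {
    colMeans(expr[c(sets$up, sets$down), , drop = FALSE])
  } else {
    up_mean
  }
  tibble(sample = colnames(expr) %||% as.character(seq_len(ncol(expr))),
         score = unname(score))
}

#' Per-set z scores of log2 fold changes
#'
#' Z-scores each gene's log2 fold change across samples, then averages the z
#' scores over each set's genes per sample. Genes missing from the matrix are
#' dropped with a warning.
#'
#' @param log2fc_by_gene Matrix of log2 fold changes, genes x samples.
#' @param gene_sets Named list of gene id vectors (each with >= 2 genes
#'   present, or exactly the genes available).
#' @return Tibble with `sample`, `set`, `score`.
#' @export
subtype_zscore <- function(log2fc_by_gene, gene_sets) {
  z <- zscore(as.matrix(log2fc_by_gene), margin = 1)
  map_dfr(names(gene_sets), function(nm) {
    present <- intersect(gene_sets[[nm]], rownames(z))
    missing <- setdiff(gene_sets[[nm]], rownames(z))
    if (length(missing) > 0) {
      warn(paste0("set ", nm, ": dropping missing gene(s) ",
                  paste(missing, collapse = ", ")))
    }
    if (length(present) == 0) abort(paste0("set ", nm, ": no genes present"))
    tibble(sample = colnames(z), set = nm,
           score = unname(colMeans(z[present, , drop = FALSE])))
  })
}

#' Bin-matched per-cell gene-set score
#'
#' Scores each cell as the mean log expression of the set genes minus the
#' mean over a control set: genes are binned into `n_bins` equal-size bins of
#' mean expression across cells, and `n_ctrl` control genes are sampled
#' (seeded, with replacement when a bin is small) from the bin of each set
#' gene; the pooled unique controls form the reference.
#'
#' @param log_expr Log-expression matrix, genes x cells.
#' @param gene_set Character vector (must intersect the matrix genes).
#' @param n_bins Number of mean-expression bins.
#' @param n_ctrl Control genes sampled per set gene.
#' @param seed Integer seed for the control draw.
#' @return Tibble with `cell` and `score`.
#' @export
cell_set_score <- function(log_expr, gene_set, n_bins = 25, n_ctrl = 50,
                           seed = 1L) {
  log_expr <- as.matrix(log_expr)
  set_genes <- intersect(gene_set, rownames(log_expr))
  if (length(set_genes) == 0) abort("gene set entirely absent from matrix")
  means <- rowMeans(log_expr)
  bins <- dplyr::ntile(rank(means, ties.method = "first"), n_bins)
  names(bins) <- rownames(log_expr)
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(set_genes, function(g) {
      pool <- names(bins)[bins == bins[g]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    })))
  })
  score <- colMeans(log_expr[set_genes, , drop = FALSE]) -
    colMeans(log_expr[ctrl, , drop = FALSE])
  tibble(cell = colnames(log_expr) %||% as.character(seq_len(ncol(log_expr))),
         score = unname(score))
}
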