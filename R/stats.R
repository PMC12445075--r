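# Shared statistical primitives: normalization, differential expression,
# multiple-testing adjustment, correlation, rank tests, relative qPCR.

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed as the median ratio of a
#' sample's counts to the per-gene geometric-mean reference profile. Genes
#' with a zero geometric mean (any zero count) are excluded from the median.
#'
#' @param counts Non-negative count matrix, genes in rows, samples in columns.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0] %||% which(totals == 0)
    abort(paste0("all-zero sample(s): ", paste(bad, collapse = ", ")))
  }
  log_geo <- rowMeans(log(counts))       # -Inf for genes with any zero
  use <- is.finite(log_geo)
  if (!any(use)) abort("no gene has all-positive counts; cannot form reference")
  geo <- exp(log_geo[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(x) median(x / geo))
  setNames(sf, colnames(counts))
}

#' Normalize a count matrix
#'
#' `size_factors` divides each sample by its median-of-ratios size factor
#' (the standard bulk RNA-seq normalization); `cpm` scales each sample to one
#' million total counts. Optionally returns `log2(x + 1)` of the normalized
#' values, the variance-stabilized scale used throughout the signature
#' pipeline.
#'
#' @param counts Count matrix, genes x samples.
#' @param method `"size_factors"` or `"cpm"`.
#' @param log2 If `TRUE`, return `log2(normalized + 1)`.
#' @return Numeric matrix with the same dimnames as `counts`.
#' @export
normalize_counts <- function(counts, method = c("size_factors", "cpm"),
                             log2 = FALSE) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  norm <- switch(method,
    size_factors = sweep(counts, 2, size_factors(counts), "/"),
    cpm = sweep(counts, 2, colSums(counts) / 1e6, "/")
  )
  if (log2) norm <- log2(norm + 1)
  norm
}

#' Adjust p values for multiple testing
#'
#' Holm step-down or Benjamini-Hochberg step-up adjustment with enforced
#' monotonicity, preserving input order.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @param method `"holm"` or `"bh"`.
#' @return Adjusted p values in the order of `p`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p values must be finite and in [0, 1]")
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "holm")
}

#' Two-group differential expression on normalized log counts
#'
#' Normalizes by median-of-ratios size factors, transforms to
#' `log2(normalized + 1)`, and applies a per-gene Welch t-test between the
#' two sample groups with Benjamini-Hochberg adjustment. A gene is flagged
#' significant when `|log2FC| > fc_gate` and `p_adj < fdr_gate`. Genes with
#' zero variance in both groups get `p = 1` when the group means agree and
#' `p = 0` otherwise (flagged in `zero_variance`).
#'
#' @param counts Count matrix, genes x samples (column names are sample ids).
#' @param group_a,group_b Disjoint character vectors of sample ids;
#'   `log2fc` is mean(A) - mean(B) on the log scale.
#' @param fc_gate,fdr_gate Significance gates on `|log2fc|` and `p_adj`.
#' @param normalize If `FALSE`, `counts` is taken as already log-scale.
#' @return Tibble with columns `gene`, `log2fc`, `p`, `p_adj`,
#'   `significant`, `zero_variance`.
#' @export
differential_expression <- function(counts, group_a, group_b,
                                    fc_gate = 1, fdr_gate = 0.05,
                                    normalize = TRUE) {
  if (length(intersect(group_a, group_b)) > 0) abort("groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("need at least 2 samples per group")
  }
  missing <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(missing) > 0) {
    abort(paste0("samples not in matrix: ", paste(missing, collapse = ", ")))
  }
  x <- if (normalize) normalize_counts(counts, "size_factors", log2 = TRUE)
       else as.matrix(counts)
  a <- x[, group_a, drop = FALSE]
  b <- x[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  zerovar <- se2 == 0
  p[zerovar] <- ifelse(ma[zerovar] == mb[zerovar], 1, 0)
  res <- tibble(
    gene = rownames(x) %||% as.character(seq_len(nrow(x))),
    log2fc = unname(ma - mb),
    p = unname(p),
    p_adj = unname(adjust_pvalues(p, "bh")),
    zero_variance = unname(zerovar)
  )
  mutate(res, significant = abs(.data$log2fc) > fc_gate & .data$p_adj < fdr_gate)
}

#' All-pairs Pearson correlation with Holm adjustment
#'
#' Computes the Pearson correlation for every unordered pair of the requested
#' genes across samples, a two-sided p value from
#' `t = r * sqrt((n - 2) / (1 - r^2))`, and Holm-adjusted p values across all
#' pairs. Zero-variance genes yield `r = NA`, `p = 1`, flagged.
#'
#' @param expr Expression matrix, genes x samples.
#' @param genes Character vector of gene ids (default: all rows).
#' @return Tibble with `gene_a`, `gene_b` (a < b alphabetically), `r`, `p`,
#'   `p_adj`, `flagged`.
#' @export
pearson_pairs <- function(expr, genes = rownames(expr)) {
  expr <- as.matrix(expr)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    abort(paste0("genes not in matrix: ", paste(missing, collapse = ", ")))
  }
  n <- ncol(expr)
  if (n < 3) abort("need at least 3 samples")
  genes <- sort(unique(genes))
  x <- t(expr[genes, , drop = FALSE])
  sds <- apply(x, 2, sd)
  cmat <- suppressWarnings(cor(x))
  idx <- which(upper.tri(cmat), arr.ind = TRUE)
  r <- cmat[idx]
  flagged <- sds[idx[, 1]] == 0 | sds[idx[, 2]] == 0
  r[flagged] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  p[flagged] <- 1
  tibble(
    gene_a = genes[idx[, 1]],
    gene_b = genes[idx[, 2]],
    r = r,
    p = p,
    p_adj = adjust_pvalues(p, "holm"),
    flagged = flagged
  )
}

#' Mann-Whitney U test
#'
#' Computes U from rank sums with midrank ties. When `n1 * n2 <= 64` the
#' two-sided p value is exact, from full enumeration of group assignments of
#' the pooled values (doubled smaller tail, capped at 1); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors (non-empty).
#' @return List of class `rank_test` with elements `U` (for `x`), `p`,
#'   `method` (`"exact"` or `"normal"`), `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rks <- rank(pooled)
  u <- sum(rks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 * n2 <= 64) {
    ids <- combn(n1 + n2, n1)
    us <- apply(ids, 2, function(i) sum(rks[i])) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(us <= u + eps), mean(us >= u - eps))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nt * (nt - 1))
    sigma2 <- n1 * n2 / 12 * (nt + 1 - tie_term)
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    if (sigma2 == 0) z <- 0
    p <- 2 * pnorm(-abs(z))
    p <- min(1, p)
    method <- "normal"
  }
  structure(list(U = u, p = p, method = method, n1 = n1, n2 = n2),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat("  U =", x$U, " n1 =", x$n1, " n2 =", x$n2, " p =", format(x$p), "\n")
  invisible(x)
}

#' Relative qPCR quantification (2^-ddCT)
#'
#' Delta-CT is target minus housekeeping within each condition; delta-delta-CT
#' is experimental minus control; fold change is `2^(-ddCT)`.
#'
#' @param ct_target_exp,ct_housekeeping_exp Cycle thresholds, experimental.
#' @param ct_target_ctrl,ct_housekeeping_ctrl Cycle thresholds, control.
#' @return Tibble with `delta_ct_exp`, `delta_ct_ctrl`, `delta_delta_ct`,
#'   `fold_change`.
#' @export
ddct_fold_change <- function(ct_target_exp, ct_housekeeping_exp,
                             ct_target_ctrl, ct_housekeeping_ctrl) {
  vals <- c(ct_target_exp, ct_housekeeping_exp, ct_target_ctrl,
            ct_housekeeping_ctrl)
  if (any(!is.finite(vals))) abort("CT values must be finite")
  d_exp <- ct_target_exp - ct_housekeeping_exp
  d_ctrl <- ct_target_ctrl - ct_housekeeping_ctrl
  ddct <- d_exp - d_ctrl
  tibble(
    delta_ct_exp = d_exp,
    delta_ct_ctrl = d_ctrl,
    delta_delta_ct = ddct,
    fold_change = 2^(-ddct)
  )
}

#' Standardize values to z scores
#'
#' `(x - mean) / sd` with the sample (n - 1) standard deviation. For matrices,
#' `margin = 1` standardizes within rows, `margin = 2` within columns.
#' Zero-spread input returns all zeros with a warning.
#'
#' @param x Numeric vector or matrix.
#' @param margin For matrices: 1 = by row, 2 = by column.
#' @return Standardized object of the same shape.
#' @export
zscore <- function(x, margin = 1) {
  zs <- function(v) {
    if (length(v) < 2) abort("need at least 2 values")
    s <- sd(v)
    if (s == 0) {
      warn("zero standard deviation; returning zeros")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  if (is.matrix(x)) {
    out <- if (margin == 1) t(apply(x, 1, zs)) else apply(x, 2, zs)
    dimnames(out) <- dimnames(x)
    out
  } else {
    zs(x)
  }
}
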