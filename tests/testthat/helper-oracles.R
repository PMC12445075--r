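# Independent literal-definition oracles used to cross-check the package
# implementations. These are deliberately naive (loops, enumeration) and
# share no code with the package paths they verify.

# Holm step-down by its textbook definition
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- (m - i + 1) * p[ord[i]]
    running <- max(running, val)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# Benjamini-Hochberg step-up by its textbook definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  # tied p-values share the largest sort position: the step-up minimum over
  # j >= k then assigns every tie the same adjusted value
  ranks <- rank(p, ties.method = "max")
  for (i in ord) {
    running <- min(running, m / ranks[i] * p[i])
    adj[i] <- min(1, running)
  }
  adj
}

# All-pairs interval overlap (0-based half-open)
brute_intersect <- function(a, b, min_overlap_bp = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      lo <- max(a$start[i], b$start[j])
      hi <- min(a$end[i], b$end[j])
      if (hi - lo >= min_overlap_bp) {
        out[[length(out) + 1]] <- data.frame(
          a_name = a$name[i], b_name = b$name[j],
          shared_start = lo, shared_end = hi
        )
      }
    }
  }
  if (length(out) == 0) return(NULL)
  d <- do.call(rbind, out)
  d[order(d$a_name, d$b_name), ]
}

# Exhaustive nearest-TSS scan by peak midpoint
brute_nearest_tss <- function(peak, genes) {
  g <- genes[genes$chrom == peak$chrom, ]
  mid <- (peak$start + peak$end) / 2
  d <- abs(mid - g$tss)
  g$gene[order(d, g$gene)[1]]
}

# Exact two-sided Mann-Whitney p by pair counting over all group assignments
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  assignments <- combn(n1 + n2, n1)
  us <- apply(assignments, 2, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Median-of-ratios size factors, written directly from the definition
size_factor_oracle <- function(counts) {
  geo <- apply(counts, 1, function(x) exp(mean(log(x))))
  keep <- geo > 0 & is.finite(geo)
  sapply(seq_len(ncol(counts)), function(j) {
    median(counts[keep, j] / geo[keep])
  })
}

# Significant-pair tally per gene
pair_tally_oracle <- function(pairs, alpha, use_adjusted = TRUE) {
  pcol <- if (use_adjusted) pairs$p_adj else pairs$p
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  sapply(genes, function(g) {
    sum((pairs$gene_a == g | pairs$gene_b == g) & !is.na(pcol) &
          pcol < alpha)
  })
}
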