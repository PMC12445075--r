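# Small fixtures built in code.

toy_peaks <- function(starts, ends, chrom = "chr1",
                      names = paste0("p", seq_along(starts)),
                      score = seq_along(starts), p_adj = 0.01) {
  tibble::tibble(chrom = chrom, start = starts, end = ends, name = names,
                 score = score, strand = ".", log2fc = 1,
                 p_adj = p_adj)
}

random_peaks <- function(n, chrom = "chr1", max_pos = 10000,
                         prefix = "rp") {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(50, n, replace = TRUE)
  toy_peaks(start, start + width, chrom = chrom,
            names = sprintf("%s%04d", prefix, seq_len(n)),
            score = runif(n), p_adj = runif(n))
}

toy_survival <- function(time, event, samples = paste0("s", seq_along(time))) {
  tibble::tibble(sample = samples, time = time, event = as.integer(event))
}

# exponential two-group cohort for survival checks
exp_cohort <- function(n_per_group, hr, lambda0 = 0.05, censor_time = Inf) {
  t0 <- rexp(n_per_group, lambda0)
  t1 <- rexp(n_per_group, lambda0 * hr)
  time <- c(t0, t1)
  event <- rep(1L, 2 * n_per_group)
  if (is.finite(censor_time)) {
    cens <- runif(2 * n_per_group, 0, censor_time)
    event <- as.integer(time <= cens)
    time <- pmin(time, cens)
  }
  list(table = toy_survival(time, event),
       group = rep(c("low", "high"), each = n_per_group))
}

# constructed 100-cell QC toy: 7 cells under the gene floor, 5 cells over the
# MT fraction, 2 cells above the 98th percentile of detected genes (disjoint);
# 86 cells survive the four gates
make_qc_toy <- function() {
  set.seed(101)
  n_genes <- 400; n_cells <- 100
  counts <- matrix(rpois(n_genes * n_cells, 2), nrow = n_genes,
                   dimnames = list(
                     c(sprintf("MT-%d", 1:10), sprintf("RP-%d", 1:10),
                       sprintf("g%03d", 1:380)),
                     sprintf("c%03d", 1:n_cells)))
  counts[counts > 0] <- counts[counts > 0] + 1   # keep detection high
  low_cells <- 1:7
  counts[, low_cells] <- 0
  counts[1:150, low_cells] <- 1                  # 150 detected genes < 200
  mt_cells <- 8:12
  counts[1:10, mt_cells] <- 60                   # MT fraction > 0.15
  hi_cells <- 13:14
  counts[, hi_cells] <- pmax(counts[, hi_cells], 1)  # every gene detected
  gene_meta <- tibble::tibble(gene = rownames(counts),
                              is_mt = grepl("^MT-", rownames(counts)),
                              is_ribo = grepl("^RP-", rownames(counts)))
  meta <- tibble::tibble(cell = colnames(counts))
  list(counts = counts, meta = meta, gene_meta = gene_meta,
       expected_survivors = setdiff(colnames(counts)[-(1:14)], character(0)))
}
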