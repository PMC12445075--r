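cfg <- sim_config(seed = 3)
ref <- simulate_reference(cfg)
truth <- ref$truth

test_that("generators are deterministic under a fixed seed", {
  ref2 <- simulate_reference(cfg)
  expect_identical(ref, ref2)
  expect_identical(simulate_chip(cfg, truth, "OSM"),
                   simulate_chip(cfg, truth, "OSM"))
  expect_identical(simulate_atac(cfg, truth, "inducible"),
                   simulate_atac(cfg, truth, "inducible"))
  expect_identical(simulate_cellline_panel(cfg, truth)$counts,
                   simulate_cellline_panel(cfg, truth)$counts)
  expect_identical(simulate_bulk_cohort(cfg, truth),
                   simulate_bulk_cohort(cfg, truth))
  small <- sim_config(seed = 3, n_cells = 1500)
  expect_identical(simulate_scrna(small, truth)$counts,
                   simulate_scrna(small, truth)$counts)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_enhancers = 0), "configuration error")
  expect_error(sim_config(n_shared_responsive = 500), "configuration error")
  expect_error(sim_config(censor_frac = 1), "censor_frac")
  expect_error(sim_config(true_hr = 0), "true_hr")
  expect_error(sim_config(treated_enrichment = 0), "treated_enrichment")
  expect_error(sim_config(signature_size = 100, n_shared_responsive = 14),
               "5 targets")
})

test_that("every planted candidate gene is reachable from a shared enhancer", {
  # exhaustive traversal of the emitted map
  shared_rows <- ref$enhancer_map[
    ref$enhancer_map$enhancer_id %in% truth$shared_enhancer_ids, ]
  reachable <- unique(shared_rows$gene)
  expect_true(all(truth$candidate_genes %in% reachable))
  expect_setequal(reachable, truth$candidate_genes)
  # 1-5 targets per enhancer
  per_enh <- table(ref$enhancer_map$enhancer_id)
  expect_true(all(per_enh >= 1 & per_enh <= 5))
  # planted module genes are a subset of the candidates
  expect_true(all(unlist(truth$module_genes) %in% truth$candidate_genes))
  expect_length(intersect(truth$module_genes$hazardous,
                          truth$module_genes$protective), 0)
})

test_that("differential ChIP peaks cover planted enhancers below alpha", {
  chip <- simulate_chip(cfg, truth, "OSM")
  enh_peaks <- truth$enhancers[
    truth$enhancers$enhancer_id %in%
      c(truth$shared_enhancer_ids, truth$private_enhancer_ids$OSM), ]
  enh_tbl <- toy_peaks(enh_peaks$start, enh_peaks$end, chrom = "chrS",
                       names = enh_peaks$enhancer_id)
  sig_peaks <- chip[chip$p_adj < 0.05, ]
  hits <- intersect_peaks(enh_tbl, sig_peaks)
  expect_setequal(unique(hits$a_name), enh_peaks$enhancer_id)

  # zero background peaks: count equals planted count
  cfg0 <- sim_config(seed = 3, background_peaks = 0)
  chip0 <- simulate_chip(cfg0, truth, "OSM")
  expect_equal(nrow(chip0),
               length(truth$shared_enhancer_ids) +
                 length(truth$private_enhancer_ids$OSM))

  # shared enhancers hit in both conditions, private in exactly one
  hyp <- simulate_chip(cfg, truth, "hypoxia")
  shared_tbl <- toy_peaks(
    truth$enhancers$start[match(truth$shared_enhancer_ids,
                                truth$enhancers$enhancer_id)],
    truth$enhancers$end[match(truth$shared_enhancer_ids,
                              truth$enhancers$enhancer_id)],
    chrom = "chrS", names = truth$shared_enhancer_ids)
  expect_setequal(unique(intersect_peaks(shared_tbl, chip)$a_name),
                  truth$shared_enhancer_ids)
  expect_setequal(unique(intersect_peaks(shared_tbl, hyp)$a_name),
                  truth$shared_enhancer_ids)
  osm_priv <- truth$enhancers[match(truth$private_enhancer_ids$OSM,
                                    truth$enhancers$enhancer_id), ]
  priv_tbl <- toy_peaks(osm_priv$start, osm_priv$end, chrom = "chrS",
                        names = osm_priv$enhancer_id)
  expect_gt(nrow(intersect_peaks(priv_tbl, chip)), 0)
  expect_equal(nrow(intersect_peaks(priv_tbl, hyp)), 0)
})

test_that("accessibility tracks the planted line class", {
  shared_tbl <- toy_peaks(
    truth$enhancers$start[match(truth$shared_enhancer_ids,
                                truth$enhancers$enhancer_id)],
    truth$enhancers$end[match(truth$shared_enhancer_ids,
                              truth$enhancers$enhancer_id)],
    chrom = "chrS", names = truth$shared_enhancer_ids)
  ai <- simulate_atac(cfg, truth, "inducible")
  an <- simulate_atac(cfg, truth, "non-inducible")
  expect_setequal(unique(intersect_peaks(shared_tbl, ai)$a_name),
                  truth$shared_enhancer_ids)
  expect_equal(nrow(intersect_peaks(shared_tbl, an)), 0)
  # both classes share housekeeping background
  expect_gt(nrow(an), 0)
})

test_that("panel counts carry the planted fold change", {
  panel <- simulate_cellline_panel(cfg, truth)
  lab <- panel$labels
  logn <- normalize_counts(panel$counts, "size_factors", log2 = TRUE)
  ind <- lab$sample[lab$group == "inducible"]
  non <- lab$sample[lab$group == "non-inducible"]
  lfc <- rowMeans(logn[truth$inducible_genes, ind]) -
    rowMeans(logn[truth$inducible_genes, non])
  expect_true(all(abs(lfc - cfg$effect_log2fc) < 0.5))

  # no effect: the DE stage stays near its nominal false-positive rate
  cfg_null <- sim_config(seed = 9, effect_log2fc = 0)
  frac <- replicate(5, {
    cfg_null$seed <- cfg_null$seed + 1
    p <- simulate_cellline_panel(cfg_null, truth)
    known <- p$labels$known
    de <- differential_expression(
      p$counts[, p$labels$sample[known]],
      p$labels$sample[known & p$labels$group == "inducible"],
      p$labels$sample[known & p$labels$group == "non-inducible"])
    mean(de$significant)
  })
  expect_lt(mean(frac), 0.05)
})

test_that("bulk cohort encodes the survival and censoring model", {
  bulk <- simulate_bulk_cohort(cfg, truth)
  expect_equal(ncol(bulk$expr), cfg$n_tumors)
  expect_equal(mean(bulk$survival$event == 0), cfg$censor_frac,
               tolerance = 0.12)

  fit <- cox_binary(bulk$survival,
                    factor(ifelse(bulk$activation$activated == 1, "high",
                                  "low"), levels = c("low", "high")))
  expect_gt(fit$hr, 3.5)
  expect_lt(fit$hr, 10)

  cfg0 <- sim_config(seed = 3, censor_frac = 0)
  bulk0 <- simulate_bulk_cohort(cfg0, truth)
  expect_true(all(bulk0$survival$event == 1))

  # hazardous module genes up, protective down, in activated tumors
  logn <- normalize_counts(bulk$expr, "size_factors", log2 = TRUE)
  act <- bulk$activation$activated == 1
  dh <- rowMeans(logn[truth$module_genes$hazardous, act]) -
    rowMeans(logn[truth$module_genes$hazardous, !act])
  dp <- rowMeans(logn[truth$module_genes$protective, act]) -
    rowMeans(logn[truth$module_genes$protective, !act])
  expect_true(all(dh > 1))
  expect_true(all(dp < -1))
})

test_that("single-cell generator plants QC outliers exactly", {
  small <- sim_config(seed = 5, n_cells = 2000)
  sc <- simulate_scrna(small, truth)
  mt <- grepl("^MT-", rownames(sc$counts))
  mt_frac <- colSums(sc$counts[mt, ]) / colSums(sc$counts)
  expect_setequal(which(mt_frac > 0.15), which(sc$meta$forced_high_mt))

  qc <- qc_filter(sc$counts, sc$meta, sc$genes, min_genes = 100)
  expect_false(any(qc$meta$forced_high_mt))
  expect_false(any(qc$meta$forced_low_count))

  # enrichment prevalences respect the configured ratio
  m <- sc$meta
  mal <- m$cell_type == "epithelial_malignant"
  p_t <- mean(m$program[mal & m$treatment == "treated"])
  p_n <- mean(m$program[mal & m$treatment == "naive"])
  expect_gt(p_t / max(p_n, 1e-6), 5)
})
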