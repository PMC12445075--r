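test_that("QC gates remove exactly the constructed outliers", {
  toy <- make_qc_toy()
  res <- qc_filter(toy$counts, toy$meta, toy$gene_meta)
  expect_equal(ncol(res$counts), 86)
  expect_setequal(res$meta$cell, toy$expected_survivors)
  expect_equal(res$report$removed, c(7, 0, 5, 2))

  # all-pass input is untouched
  clean <- toy$counts[, -(1:14)]
  res2 <- qc_filter(clean, toy$meta[-(1:14), ], toy$gene_meta,
                    gene_pct = 100)
  expect_equal(dim(res2$counts), dim(clean))
})

test_that("QC matches an independent literal re-implementation", {
  set.seed(103)
  counts <- matrix(rnbinom(300 * 150, mu = 3, size = 2), nrow = 300,
                   dimnames = list(
                     c(sprintf("MT-%d", 1:8), sprintf("RP-%d", 1:8),
                       sprintf("g%03d", 1:284)),
                     sprintf("c%03d", 1:150)))
  gm <- tibble::tibble(gene = rownames(counts),
                       is_mt = grepl("^MT-", rownames(counts)),
                       is_ribo = grepl("^RP-", rownames(counts)))
  meta <- tibble::tibble(cell = colnames(counts))
  res <- qc_filter(counts, meta, gm, min_genes = 150, min_cells = 5,
                   max_mt = 0.1, max_ribo = 0.1, gene_pct = 95)

  # literal re-application of the gate definitions, in order
  m <- counts
  m <- m[, colSums(m > 0) >= 150, drop = FALSE]
  m <- m[rowSums(m > 0) >= 5, , drop = FALSE]
  mtf <- colSums(m[grepl("^MT-", rownames(m)), ]) / colSums(m)
  rbf <- colSums(m[grepl("^RP-", rownames(m)), ]) / colSums(m)
  m <- m[, mtf <= 0.1 & rbf <= 0.1, drop = FALSE]
  det <- colSums(m > 0)
  m <- m[, det <= quantile(det, 0.95), drop = FALSE]
  expect_identical(res$counts, m)
})

test_that("extreme stratification is exact-size and deterministic", {
  set.seed(107)
  n <- 500
  e <- matrix(rnorm(20 * n), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("c%04d", 1:n)))
  meta <- tibble::tibble(cell = colnames(e),
                         total_counts = runif(n, 500, 1500))
  sm <- stratify_extremes(e, meta, "g01", q = 0.1)
  expect_equal(sum(sm$strata == "High"), 50)
  expect_equal(sum(sm$strata == "Low"), 50)
  top <- sm$cell[sm$strata == "High"]
  expect_setequal(top, meta$cell[order(-e["g01", ])][1:50])

  # heavy zero inflation: Low group resolved by the documented tie-break
  e2 <- e
  e2["g01", ] <- abs(e2["g01", ]) + 1
  e2["g01", 1:400] <- 0
  sm2 <- stratify_extremes(e2, meta, "g01", q = 0.1)
  sm3 <- stratify_extremes(e2, meta, "g01", q = 0.1)
  expect_identical(sm2, sm3)
  low <- sm2$cell[sm2$strata == "Low"]
  expect_true(all(e2["g01", low] == 0))
  zero_cells <- meta[1:400, ]
  expected_low <- zero_cells$cell[order(-zero_cells$total_counts,
                                        zero_cells$cell)][1:50]
  expect_setequal(low, expected_low)

  expect_error(stratify_extremes(e[, 1:50], meta[1:50, ], "g01", q = 0.1),
               "too small")
  expect_error(stratify_extremes(e, meta, "nope"), "absent")
})

test_that("extreme-group DE flags planted shifts and nothing flat", {
  set.seed(109)
  n <- 400
  e <- matrix(rnorm(30 * n), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%03d", 1:n)))
  strata <- rep("neither", n)
  strata[1:80] <- "High"; strata[321:400] <- "Low"
  e[1:5, strata == "High"] <- e[1:5, strata == "High"] + 1
  e["g30", ] <- 3
  de <- extreme_de(e, strata)
  top <- de[de$gene %in% sprintf("g%02d", 1:5), ]
  expect_true(all(top$p_adj < 0.01))
  expect_true(all(top$enrichment > 0.5))
  flat <- de[de$gene == "g30", ]
  expect_equal(flat$enrichment, 0)
  expect_equal(flat$p, 1)

  # permuted strata stay near the nominal rate
  de_null <- extreme_de(e[6:29, ], sample(strata))
  expect_lt(mean(de_null$p_adj < 0.05), 0.2)
})

test_that("enrichment folds handle zero cells with a flagged correction", {
  strata <- c(rep("High", 10), rep("Low", 10), rep("neither", 180))
  treatment <- rep(c("treated", "naive"), 100)
  # balanced assignment: fold near 1
  ef <- enrichment_fold(strata, treatment)
  expect_equal(ef$fold, 1, tolerance = 0.01)
  expect_false(ef$haldane)
  expect_equal(sum(ef$table), 20)

  # all High cells treated: Haldane-corrected, flagged
  strata2 <- c(rep("High", 10), rep("Low", 10), rep("neither", 180))
  treatment2 <- c(rep("treated", 10), rep("naive", 10),
                  rep(c("treated", "naive"), 90))
  expect_warning(ef2 <- enrichment_fold(strata2, treatment2), "Haldane")
  expect_true(ef2$haldane)
  expect_gt(ef2$fold, 10)

  expect_error(enrichment_fold(strata, rep("treated", 200)), "represented")
})

test_that("window-1 CNV profiles equal clipped relative expression", {
  set.seed(113)
  e <- matrix(rnorm(100 * 40), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100),
                              sprintf("c%02d", 1:40)))
  ref_cells <- colnames(e)[1:15]
  cw <- cnv_window_score(e, ref_cells, window = 1)
  ref_mean <- rowMeans(e[, ref_cells])
  ref_sd <- apply(e[, ref_cells], 1, sd)
  rel <- sweep(e, 1, ref_mean)
  rel <- pmin(pmax(rel, -3 * ref_sd), 3 * ref_sd)
  expect_equal(cw$profile, rel)

  # a cell equal to the reference mean scores zero everywhere
  e2 <- cbind(e, flat = ref_mean)
  cw2 <- cnv_window_score(e2, ref_cells, window = 11)
  expect_equal(unname(cw2$profile[, "flat"]), rep(0, 100))
  expect_equal(unname(cw2$burden["flat"]), 0)

  expect_error(cnv_window_score(e, ref_cells, window = 500), "exceeds")
})

test_that("planted amplifications raise the CNV burden of carriers", {
  set.seed(127)
  n_genes <- 600; n_ref <- 40; n_car <- 20; n_non <- 20
  base <- matrix(rnorm(n_genes * (n_ref + n_car + n_non), 0, 0.4),
                 nrow = n_genes)
  colnames(base) <- c(sprintf("ref%02d", 1:n_ref),
                      sprintf("car%02d", 1:n_car),
                      sprintf("non%02d", 1:n_non))
  rownames(base) <- sprintf("g%03d", 1:n_genes)
  carriers <- grepl("^car", colnames(base))
  base[101:350, carriers] <- base[101:350, carriers] + 0.5
  cw <- cnv_window_score(base, colnames(base)[1:n_ref], window = 100)
  burden_car <- cw$burden[carriers]
  burden_non <- cw$burden[grepl("^non", colnames(base))]
  expect_gte(mean(outer(burden_car, burden_non, ">")), 0.95)
  # the planted span is elevated in the carrier profile
  span_mean <- mean(cw$profile[150:300, carriers])
  out_mean <- mean(cw$profile[451:600, carriers])
  expect_gt(span_mean, out_mean + 0.2)
})

test_that("MTX triplets round trip", {
  set.seed(131)
  m <- matrix(rpois(60, 1), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:6)))
  dir <- withr::local_tempdir()
  write_mtx(m, dir)
  back <- read_mtx(dir)
  expect_equal(back, m)
})
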