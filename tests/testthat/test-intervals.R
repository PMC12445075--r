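test_that("BED round trip preserves peaks and reports malformed lines", {
  peaks <- toy_peaks(c(10, 100), c(20, 200), p_adj = c(0.01, 0.5))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(peaks, path)
  back <- read_bed(path)
  expect_equal(back, peaks)

  p1 <- read_bed(path, "bed6+2")
  expect_equal(p1$start[1], 10)
  expect_equal(p1$p_adj[1], 0.01)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t20\t10\tp\t1\t.", bad)
  expect_error(read_bed(bad, "bed6"), "line 1")
  writeLines(c("chr1\t1\t10\tp\tX\t.", "chr1\t1\t5\tq\t2\t."), bad)
  expect_error(read_bed(bad, "bed6"), "non-numeric score")
})

test_that("peak intersection matches hand cases and the all-pairs oracle", {
  a <- toy_peaks(10, 20, names = "a1")
  b <- toy_peaks(15, 30, names = "b1")
  hit <- intersect_peaks(a, b)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$shared_start, 15)
  expect_equal(hit$shared_end, 20)

  # half-open adjacency does not overlap
  expect_equal(nrow(intersect_peaks(toy_peaks(10, 20), toy_peaks(20, 30))), 0)

  expect_error(intersect_peaks(a, b, min_overlap_bp = 0), ">= 1")

  set.seed(41)
  A <- random_peaks(200, prefix = "A")
  B <- random_peaks(200, prefix = "B")
  got <- intersect_peaks(A, B)
  oracle <- brute_intersect(A, B)
  got_sorted <- got[order(got$a_name, got$b_name), ]
  expect_equal(got_sorted$a_name, oracle$a_name)
  expect_equal(got_sorted$b_name, oracle$b_name)
  expect_equal(got_sorted$shared_start, oracle$shared_start)
  expect_equal(got_sorted$shared_end, oracle$shared_end)

  # symmetry up to pair ordering
  rev <- intersect_peaks(B, A)
  expect_setequal(paste(got$a_name, got$b_name),
                  paste(rev$b_name, rev$a_name))

  # minimum-overlap gate agrees with the oracle too
  got5 <- intersect_peaks(A, B, min_overlap_bp = 5)
  oracle5 <- brute_intersect(A, B, min_overlap_bp = 5)
  expect_equal(nrow(got5), nrow(oracle5))
})

test_that("top-peak selection is a deterministic sort head", {
  p <- toy_peaks(1:5 * 10, 1:5 * 10 + 5, score = c(3, 9, 1, 9, 5))
  top2 <- select_top_peaks(p, 2, "score")
  expect_setequal(top2$name, c("p2", "p4"))
  # ties broken by coordinate: p2 starts before p4
  expect_equal(top2$name[1], "p2")

  expect_equal(nrow(select_top_peaks(p, 200, "score")), 5)
  expect_equal(nrow(select_top_peaks(p[0, ], 3, "score")), 0)

  set.seed(43)
  q <- random_peaks(300)
  top <- select_top_peaks(q, 50, "p_adj")
  oracle <- q[order(q$p_adj, q$chrom, q$start, q$end, q$name), ][1:50, ]
  expect_equal(top, oracle)
})

test_that("annotation reports enhancer targets with signed TSS distances", {
  genes <- tibble::tibble(gene = c("ITGB3a", "OTHER"), chrom = "chr17",
                          tss = c(100000, 400000), strand = c("+", "+"))
  # enhancer centered 13.6 kb upstream, a second one 51.6 kb downstream
  emap <- tibble::tibble(
    enhancer_id = c("GH_up", "GH_down"),
    chrom = "chr17",
    start = c(100000 - 13600 - 500, 100000 + 51600 - 500),
    end = c(100000 - 13600 + 500, 100000 + 51600 + 500),
    gene = "ITGB3a", link_score = 1
  )
  peaks <- toy_peaks(c(emap$start[1], emap$start[2]),
                     c(emap$end[1], emap$end[2]),
                     chrom = "chr17", names = c("pk_up", "pk_down"))
  ann <- annotate_peaks(peaks, emap, genes)
  up <- ann[ann$name == "pk_up" & ann$type == "enhancer", ]
  expect_equal(up$gene, "ITGB3a")
  expect_equal(up$tss_distance, -13600)
  down <- ann[ann$name == "pk_down" & ann$type == "enhancer", ]
  expect_equal(down$tss_distance, 51600)

  # peak with no enhancer: nearest TSS only, against the exhaustive scan
  lone <- toy_peaks(390000, 390400, chrom = "chr17", names = "lone")
  ann2 <- annotate_peaks(lone, emap, genes)
  expect_equal(nrow(ann2), 1)
  expect_equal(ann2$type, "nearest_tss")
  expect_equal(ann2$gene, brute_nearest_tss(lone[1, ], genes))

  # minus-strand gene: downstream of TSS means negative coordinate direction
  genes_m <- tibble::tibble(gene = "MG", chrom = "chr1", tss = 5000,
                            strand = "-")
  pk <- toy_peaks(5995, 6005, names = "pm")   # midpoint 1000 bp after tss
  annm <- annotate_peaks(pk, emap[0, ], genes_m)
  expect_equal(annm$tss_distance, -1000)      # upstream in gene orientation

  expect_warning(
    annotate_peaks(toy_peaks(1, 10, chrom = "chrZ"), emap, genes),
    "absent")
})

test_that("nearest-TSS annotation equals the exhaustive scan on random data", {
  set.seed(47)
  genes <- tibble::tibble(gene = sprintf("g%03d", 1:50), chrom = "chr1",
                          tss = sort(sample.int(1e6, 50)), strand = "+")
  peaks <- random_peaks(100, max_pos = 1e6)
  emap <- tibble::tibble(enhancer_id = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         gene = character(), link_score = numeric())
  ann <- annotate_peaks(peaks, emap, genes)
  for (k in sample(nrow(peaks), 20)) {
    expect_equal(ann$gene[ann$name == peaks$name[k]],
                 brute_nearest_tss(peaks[k, ], genes))
  }
})

test_that("shared differential peaks honors its gates and identity case", {
  a <- toy_peaks(c(10, 100), c(50, 150), names = c("a1", "a2"),
                 p_adj = c(0.01, 0.5))
  b <- toy_peaks(c(30, 100), c(80, 150), names = c("b1", "b2"),
                 p_adj = c(0.01, 0.5))
  sh <- shared_differential_peaks(a, b, alpha = 0.05)
  expect_equal(nrow(sh), 1)       # only the p-passing pair overlaps
  expect_equal(sh$start, 30)
  expect_equal(sh$end, 50)
  expect_equal(sh$sources_1, "a1")

  # disjoint sets give nothing
  expect_equal(nrow(shared_differential_peaks(
    toy_peaks(10, 20), toy_peaks(1000, 1020))), 0)

  # alpha = 1, unlimited top-n on identical sets covers every peak
  set.seed(53)
  p <- random_peaks(100)
  sh2 <- shared_differential_peaks(p, p, alpha = 1, top_n = Inf)
  cover <- intersect_peaks(p, sh2)
  expect_setequal(cover$a_name, p$name)
})

test_that("STAT-open regions require inducible-only accessibility", {
  chip <- toy_peaks(c(10, 100, 200), c(50, 150, 260))
  ai <- toy_peaks(c(20, 110), c(40, 140), names = c("o1", "o2"))
  an <- toy_peaks(120, 130, names = "n1")
  so <- stat_open_regions(chip, ai, an)
  expect_equal(so$name, "p1")     # p2 blocked by non-inducible, p3 not open

  expect_equal(nrow(stat_open_regions(chip, ai, ai)), 0)
  expect_equal(nrow(stat_open_regions(chip[0, ], ai, an)), 0)
})
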