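# Genomic-interval algebra on BED-convention peak tables.
# All coordinates are 0-based half-open [start, end); IRanges (1-based closed)
# is used internally for overlap queries via start+1.

new_peaks <- function(chrom, start, end, name, score = 0, strand = ".",
                      log2fc = NA_real_, p_adj = NA_real_) {
  tibble(chrom = as.character(chrom), start = as.numeric(start),
         end = as.numeric(end), name = as.character(name),
         score = as.numeric(score), strand = as.character(strand),
         log2fc = as.numeric(log2fc), p_adj = as.numeric(p_adj))
}

validate_peaks <- function(peaks, what = "peaks") {
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(peaks))
  if (length(missing) > 0) {
    abort(paste0(what, " lacks column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- which(!(peaks$start >= 0 & peaks$start < peaks$end))
  if (length(bad) > 0) {
    abort(paste0(what, ": invalid interval (need 0 <= start < end) at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  invisible(peaks)
}

#' Read a BED peak file
#'
#' Supports dialects `"bed3"` (chrom, start, end), `"bed6"` (+ name, score,
#' strand), and `"bed6+2"` (+ log2fc, p_adj). Coordinates are 0-based
#' half-open. Malformed lines are reported with their line numbers.
#'
#' @param path File path.
#' @param dialect One of `"bed3"`, `"bed6"`, `"bed6+2"`.
#' @return Peak tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `log2fc`, `p_adj` (absent fields filled with defaults).
#' @export
read_bed <- function(path, dialect = c("bed6+2", "bed6", "bed3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ncols <- switch(dialect, bed3 = 3L, bed6 = 6L, `bed6+2` = 8L)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < ncols)) {
    abort(paste0("line ", which(nf < ncols)[1], ": expected ", ncols,
                 " fields, found ", nf[nf < ncols][1]))
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i, what, allow_na = FALSE) {
    raw <- get(i)
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v) & !(allow_na & raw == "NA")
    if (any(bad)) abort(paste0("line ", which(bad)[1],
                               ": non-numeric ", what))
    v
  }
  start <- num(2, "start")
  end <- num(3, "end")
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    abort(paste0("line ", bad[1], ": invalid interval (start >= end)"))
  }
  peaks <- new_peaks(
    chrom = get(1), start = start, end = end,
    name = if (ncols >= 6) get(4) else paste0("peak_", seq_along(lines)),
    score = if (ncols >= 6) num(5, "score") else 0,
    strand = if (ncols >= 6) get(6) else ".",
    log2fc = if (ncols >= 8) num(7, "log2fc", allow_na = TRUE) else NA_real_,
    p_adj = if (ncols >= 8) num(8, "p_adj", allow_na = TRUE) else NA_real_
  )
  if (ncols >= 8 && any(peaks$p_adj < 0 | peaks$p_adj > 1, na.rm = TRUE)) {
    abort(paste0("line ", which(peaks$p_adj < 0 | peaks$p_adj > 1)[1],
                 ": p_adj outside [0, 1]"))
  }
  peaks
}

#' Write peaks as BED
#'
#' @param peaks Peak tibble (see [read_bed()]).
#' @param path Output path.
#' @param dialect BED dialect to emit.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path, dialect = c("bed6+2", "bed6", "bed3")) {
  dialect <- match.arg(dialect)
  validate_peaks(peaks)
  cols <- switch(dialect,
    bed3 = c("chrom", "start", "end"),
    bed6 = c("chrom", "start", "end", "name", "score", "strand"),
    `bed6+2` = c("chrom", "start", "end", "name", "score", "strand",
                 "log2fc", "p_adj")
  )
  readr::write_tsv(peaks[, cols], path, col_names = FALSE)
  invisible(path)
}

peaks_to_iranges <- function(peaks) {
  IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
}

# findOverlaps split by chromosome; returns tibble of row indices (a_idx, b_idx)
overlap_pairs_idx <- function(a, b, min_overlap_bp = 1) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- map(chroms, function(ch) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    hits <- IRanges::findOverlaps(
      peaks_to_iranges(a[ai, ]), peaks_to_iranges(b[bi, ]),
      minoverlap = min_overlap_bp
    )
    tibble(a_idx = ai[S4Vectors::queryHits(hits)],
           b_idx = bi[S4Vectors::subjectHits(hits)])
  })
  bind_rows(out)
}

#' Intersect two peak sets
#'
#' Returns every pair of peaks from `a` and `b` overlapping by at least
#' `min_overlap_bp` bases, with the shared interval
#' `[max(starts), min(ends))`. Output order is deterministic: by `a`
#' coordinates, then `b` coordinates.
#'
#' @param a,b Peak tibbles.
#' @param min_overlap_bp Minimum overlap in bp (>= 1).
#' @return Tibble with `chrom`, `a_name`, `b_name`, `a_start`, `a_end`,
#'   `b_start`, `b_end`, `shared_start`, `shared_end`.
#' @export
intersect_peaks <- function(a, b, min_overlap_bp = 1) {
  if (min_overlap_bp < 1) abort("min_overlap_bp must be >= 1")
  validate_peaks(a, "a"); validate_peaks(b, "b")
  idx <- overlap_pairs_idx(a, b, min_overlap_bp)
  if (nrow(idx) == 0) {
    return(tibble(chrom = character(), a_name = character(),
                  b_name = character(), a_start = numeric(),
                  a_end = numeric(), b_start = numeric(), b_end = numeric(),
                  shared_start = numeric(), shared_end = numeric()))
  }
  out <- tibble(
    chrom = a$chrom[idx$a_idx],
    a_name = a$name[idx$a_idx] %||% NA_character_,
    b_name = b$name[idx$b_idx] %||% NA_character_,
    a_start = a$start[idx$a_idx], a_end = a$end[idx$a_idx],
    b_start = b$start[idx$b_idx], b_end = b$end[idx$b_idx],
    shared_start = pmax(a$start[idx$a_idx], b$start[idx$b_idx]),
    shared_end = pmin(a$end[idx$a_idx], b$end[idx$b_idx])
  )
  arrange(out, .data$chrom, .data$a_start, .data$a_end, .data$a_name,
          .data$b_start, .data$b_end, .data$b_name)
}

#' Select the top-ranked peaks
#'
#' Top `n` by descending `score` or ascending `p_adj`; ties broken by
#' (chrom, start, end, name) for determinism. Returns all peaks when fewer
#' than `n` are available.
#'
#' @param peaks Peak tibble.
#' @param n Number of peaks to keep (>= 1).
#' @param key `"score"` (descending) or `"p_adj"` (ascending).
#' @return Peak tibble with at most `n` rows.
#' @export
select_top_peaks <- function(peaks, n, key = c("score", "p_adj")) {
  key <- match.arg(key)
  if (n < 1) abort("n must be >= 1")
  if (nrow(peaks) == 0) return(peaks)
  ord <- if (key == "score") {
    order(-peaks$score, peaks$chrom, peaks$start, peaks$end, peaks$name)
  } else {
    order(peaks$p_adj, peaks$chrom, peaks$start, peaks$end, peaks$name)
  }
  peaks[ord[seq_len(min(n, nrow(peaks)))], ]
}

#' Annotate peaks with enhancers and nearest TSS
#'
#' For each peak: every enhancer record it overlaps by >= 1 bp (with that
#' enhancer's target genes and link scores) plus the gene whose TSS is nearest
#' the peak midpoint. Distances are signed by gene strand, negative meaning
#' upstream of the TSS. Peaks on chromosomes absent from the gene index get an
#' empty annotation with a warning.
#'
#' @param peaks Peak tibble.
#' @param enhancer_map Tibble with `enhancer_id`, `chrom`, `start`, `end`,
#'   `gene`, `link_score` (one row per enhancer-gene link).
#' @param genes Tibble with `gene`, `chrom`, `tss`, `strand`.
#' @return Tibble, one row per peak-gene link: `name` (peak), `gene`, `type`
#'   (`"enhancer"` or `"nearest_tss"`), `enhancer_id`, `link_score`,
#'   `tss_distance` (signed bp from peak midpoint to the gene TSS).
#' @export
annotate_peaks <- function(peaks, enhancer_map, genes) {
  validate_peaks(peaks)
  signed_dist <- function(mid, tss, strand) {
    ifelse(strand == "-", tss - mid, mid - tss)
  }
  mids <- (peaks$start + peaks$end) / 2
  # enhancer hits
  enh <- distinct(enhancer_map, .data$enhancer_id, .data$chrom, .data$start,
                  .data$end)
  hits <- overlap_pairs_idx(peaks, enh)
  enh_rows <- if (nrow(hits) > 0) {
    hit_tbl <- tibble(
      name = peaks$name[hits$a_idx],
      peak_mid = mids[hits$a_idx],
      enhancer_id = enh$enhancer_id[hits$b_idx]
    )
    hit_tbl <- left_join(hit_tbl,
                         select(enhancer_map, "enhancer_id", "gene",
                                "link_score"),
                         by = "enhancer_id", relationship = "many-to-many")
    hit_tbl <- left_join(hit_tbl, select(genes, "gene", "tss", "strand"),
                         by = "gene")
    mutate(hit_tbl,
           type = "enhancer",
           tss_distance = signed_dist(.data$peak_mid, .data$tss,
                                      .data$strand))
  } else {
    NULL
  }
  # nearest TSS per peak
  near_rows <- map_dfr(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0) {
      warn(paste0("peak ", peaks$name[i], ": chromosome ", peaks$chrom[i],
                  " absent from gene index"))
      return(tibble(name = peaks$name[i], gene = NA_character_,
                    type = "nearest_tss", enhancer_id = NA_character_,
                    link_score = NA_real_, tss_distance = NA_real_))
    }
    d <- abs(mids[i] - g$tss)
    j <- order(d, g$gene)[1]   # deterministic tie-break by gene id
    tibble(name = peaks$name[i], gene = g$gene[j], type = "nearest_tss",
           enhancer_id = NA_character_, link_score = NA_real_,
           tss_distance = signed_dist(mids[i], g$tss[j], g$strand[j]))
  })
  cols <- c("name", "gene", "type", "enhancer_id", "link_score",
            "tss_distance")
  out <- bind_rows(
    if (!is.null(enh_rows)) enh_rows[, cols],
    near_rows[, cols]
  )
  arrange(out, .data$name, desc(.data$type == "enhancer"), .data$enhancer_id,
          .data$gene)
}

#' Shared differential peaks between two conditions
#'
#' Implements the two-condition overlap gate: each peak set is filtered to
#' `p_adj <= alpha`, reduced to its `top_n` peaks by score, and intersected.
#' Overlapping intervals are merged into shared regions carrying the names of
#' the contributing peaks from each condition.
#'
#' @param cond1,cond2 Peak tibbles with `p_adj` and `score`.
#' @param alpha Adjusted-p gate (default 0.05).
#' @param top_n Number of top-scoring peaks to keep per condition
#'   (default 200; `Inf` disables the gate).
#' @return Peak tibble of merged shared regions with columns `chrom`, `start`,
#'   `end`, `name`, `score` (max contributing score), `strand`, `log2fc`,
#'   `p_adj` (min contributing), `sources_1`, `sources_2` (comma-separated
#'   contributing peak names).
#' @export
shared_differential_peaks <- function(cond1, cond2, alpha = 0.05,
                                      top_n = 200) {
  gate <- function(p) {
    p <- filter(p, .data$p_adj <= alpha)
    if (is.finite(top_n)) p <- select_top_peaks(p, top_n, "score") else p
  }
  a <- gate(cond1); b <- gate(cond2)
  empty <- new_peaks(character(), numeric(), numeric(), character())
  empty$sources_1 <- character(); empty$sources_2 <- character()
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  pairs <- intersect_peaks(a, b)
  if (nrow(pairs) == 0) return(empty)
  # merge shared intervals that themselves overlap or touch
  out <- map_dfr(unique(pairs$chrom), function(ch) {
    pc <- pairs[pairs$chrom == ch, ]
    ir <- IRanges::IRanges(pc$shared_start + 1L, pc$shared_end)
    red <- IRanges::reduce(ir)
    memb <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    map_dfr(seq_along(red), function(k) {
      rows <- pc[memb == k, ]
      a_rows <- a[a$name %in% rows$a_name, ]
      b_rows <- b[b$name %in% rows$b_name, ]
      tibble(
        chrom = ch,
        start = IRanges::start(red)[k] - 1,
        end = as.numeric(IRanges::end(red)[k]),
        score = max(c(a_rows$score, b_rows$score)),
        strand = ".",
        log2fc = NA_real_,
        p_adj = suppressWarnings(min(c(a_rows$p_adj, b_rows$p_adj))),
        sources_1 = paste(sort(unique(rows$a_name)), collapse = ","),
        sources_2 = paste(sort(unique(rows$b_name)), collapse = ",")
      )
    })
  })
  out <- arrange(out, .data$chrom, .data$start, .data$end)
  out$name <- paste0("shared_", seq_len(nrow(out)))
  out[, c("chrom", "start", "end", "name", "score", "strand", "log2fc",
          "p_adj", "sources_1", "sources_2")]
}

#' Derive STAT-open regions
#'
#' Regions where shared differential transcription-factor binding coincides
#' with chromatin that is accessible only in inducible cell lines: each
#' `chip_shared` region is kept when it overlaps at least one accessibility
#' peak from the inducible set and no peak from the non-inducible set.
#'
#' @param chip_shared Peak tibble of shared differential binding regions.
#' @param atac_inducible,atac_noninducible Accessibility peak tibbles.
#' @return Subset of `chip_shared` rows (same columns).
#' @export
stat_open_regions <- function(chip_shared, atac_inducible,
                              atac_noninducible) {
  if (nrow(chip_shared) == 0) return(chip_shared)
  has_ind <- rep(FALSE, nrow(chip_shared))
  has_non <- rep(FALSE, nrow(chip_shared))
  if (nrow(atac_inducible) > 0) {
    has_ind[unique(overlap_pairs_idx(chip_shared, atac_inducible)$a_idx)] <- TRUE
  }
  if (nrow(atac_noninducible) > 0) {
    has_non[unique(overlap_pairs_idx(chip_shared,
                                     atac_noninducible)$a_idx)] <- TRUE
  }
  chip_shared[has_ind & !has_non, ]
}
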