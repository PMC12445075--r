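# Readers and writers for the pipeline's plain-text interchange formats:
# expression TSV (genes x samples), survival TSV, enhancer-map TSV, GMT
# signatures, MTX triplets, and JSON truth/manifest files.

#' Read / write an expression matrix as TSV
#'
#' Genes in rows; the first column (`gene`) holds gene ids, remaining columns
#' are samples.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param expr Matrix, genes x samples.
#' @export
write_expression <- function(expr, path) {
  d <- bind_cols(tibble(gene = rownames(expr)),
                 as_tibble(as.data.frame(expr)))
  readr::write_tsv(d, path)
  invisible(path)
}

#' Read / write a survival table as TSV
#'
#' Columns: `sample`, `time`, `event`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_survival <- function(path) {
  d <- readr::read_tsv(path, col_types = "cdi")
  as_surv_table(d)
  d
}

#' @rdname read_survival
#' @param table Survival tibble.
#' @export
write_survival <- function(table, path) {
  readr::write_tsv(table[, c("sample", "time", "event")], path)
  invisible(path)
}

#' Read / write an enhancer-to-gene map as TSV
#'
#' Columns: `enhancer_id`, `chrom`, `start`, `end`, `gene`, `link_score`
#' (one row per enhancer-gene link; 0-based half-open coordinates).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_enhancer_map <- function(path) {
  readr::read_tsv(path, col_types = "ccddcd",
                  col_names = c("enhancer_id", "chrom", "start", "end",
                                "gene", "link_score"))
}

#' @rdname read_enhancer_map
#' @param map Enhancer-map tibble.
#' @export
write_enhancer_map <- function(map, path) {
  readr::write_tsv(map[, c("enhancer_id", "chrom", "start", "end", "gene",
                           "link_score")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read / write gene signatures as GMT
#'
#' One line per direction, named `<NAME>_UP` and `<NAME>_DN` (the `_DN` line
#' is omitted for up-only signatures).
#'
#' @param path File path.
#' @return A `gene_signature` (first signature in the file).
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readr::read_lines(path), "\t", fixed = TRUE)
  sets <- setNames(lapply(lines, function(f) f[-(1:2)]),
                   vapply(lines, `[[`, "", 1))
  base <- sub("_(UP|DN)$", "", names(sets)[1])
  new_gene_signature(
    base,
    up_genes = sets[[paste0(base, "_UP")]] %||% character(0),
    down_genes = sets[[paste0(base, "_DN")]] %||% character(0)
  )
}

#' @rdname read_gmt
#' @param signature A `gene_signature`.
#' @export
write_gmt <- function(signature, path) {
  lines <- paste(c(paste0(signature$name, "_UP"), "na",
                   signature$up_genes), collapse = "\t")
  if (length(signature$down_genes) > 0) {
    lines <- c(lines, paste(c(paste0(signature$name, "_DN"), "na",
                              signature$down_genes), collapse = "\t"))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read / write a single-cell count matrix as an MTX triplet
#'
#' `matrix.mtx` (genes x cells, MatrixMarket), `genes.tsv` and `barcodes.tsv`
#' in `dir`.
#'
#' @param dir Directory holding / receiving the triplet.
#' @return Dense integer matrix with dimnames.
#' @export
read_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readr::read_lines(file.path(dir, "genes.tsv"))
  colnames(m) <- readr::read_lines(file.path(dir, "barcodes.tsv"))
  m
}

#' @rdname read_mtx
#' @param counts Count matrix, genes x cells.
#' @export
write_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  readr::write_lines(rownames(counts), file.path(dir, "genes.tsv"))
  readr::write_lines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
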