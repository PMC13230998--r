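# Readers/writers for the 10x Genomics MTX triplet layout and simulated
# population export.

find_10x_file <- function(path, candidates) {
  for (nm in candidates) {
    fp <- file.path(path, nm)
    if (file.exists(fp)) return(fp)
  }
  NULL
}

read_tsv_plain <- function(path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read a 10x Genomics MTX matrix directory
#'
#' Reads the triplet layout `matrix.mtx[.gz]` + `features.tsv[.gz]` (or
#' `genes.tsv[.gz]`) + `barcodes.tsv[.gz]`. Row names of the returned matrix
#' are the gene symbols (features column 2, made unique); the raw feature ids
#' (column 1) are kept alongside.
#'
#' @param path directory containing the three files.
#' @return List with `counts` (sparse integer genes x cells matrix),
#'   `gene_ids`, `gene_names`, `barcodes`.
#' @export
read_10x_matrix <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  mtx <- find_10x_file(path, c("matrix.mtx", "matrix.mtx.gz"))
  if (is.null(mtx)) stop("missing matrix.mtx[.gz] in ", path)
  feats <- find_10x_file(path, c("features.tsv", "features.tsv.gz",
                                 "genes.tsv", "genes.tsv.gz"))
  if (is.null(feats)) stop("missing features.tsv[.gz] / genes.tsv[.gz] in ", path)
  bcs <- find_10x_file(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(bcs)) stop("missing barcodes.tsv[.gz] in ", path)

  counts <- if (endsWith(mtx, ".gz")) {
    con <- gzfile(mtx)
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    Matrix::readMM(con)
  } else {
    Matrix::readMM(mtx)
  }
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")

  ft <- read_tsv_plain(feats)
  bc <- read_tsv_plain(bcs)[[1L]]
  if (nrow(ft) != nrow(counts)) {
    stop(sprintf("dimension mismatch: %d features but %d matrix rows",
                 nrow(ft), nrow(counts)))
  }
  if (length(bc) != ncol(counts)) {
    stop(sprintf("dimension mismatch: %d barcodes but %d matrix columns",
                 length(bc), ncol(counts)))
  }
  if (length(counts@x) && any(counts@x != round(counts@x))) {
    stop("matrix contains non-integer values; expected raw UMI counts")
  }
  if (length(counts@x) && any(counts@x < 0)) {
    stop("matrix contains negative values")
  }
  gene_ids <- ft[[1L]]
  gene_names <- if (ncol(ft) >= 2L) ft[[2L]] else ft[[1L]]
  rownames(counts) <- make.unique(gene_names)
  colnames(counts) <- bc
  list(counts = counts, gene_ids = gene_ids, gene_names = gene_names,
       barcodes = bc)
}

#' Read a simulated population back from a 10x-style directory
#'
#' Like [read_10x_matrix()], but also reads the `labels.tsv` written by
#' [write_population_10x()] and reassembles a `cell_population` with its
#' ground-truth state labels.
#'
#' @param path directory written by [write_population_10x()].
#' @return A `cell_population`.
#' @export
read_population_10x <- function(path) {
  tx <- read_10x_matrix(path)
  lab_fp <- find_10x_file(path, c("labels.tsv", "labels.tsv.gz"))
  if (is.null(lab_fp)) stop("missing labels.tsv in ", path, " (not a population export?)")
  con <- if (endsWith(lab_fp, ".gz")) gzfile(lab_fp, "rt") else file(lab_fp, "rt")
  on.exit(close(con))
  lab <- utils::read.delim(con, stringsAsFactors = FALSE)
  if (!all(c("barcode", "state", "depth") %in% names(lab))) {
    stop("labels.tsv must have columns barcode, state, depth")
  }
  ord <- match(tx$barcodes, lab$barcode)
  if (any(is.na(ord))) stop("labels.tsv does not cover every barcode")
  new_cell_population(tx$counts, lab$state[ord],
                      provenance = list(name = "imported", path = path))
}

# integer-typed Matrix Market writer (the triplet body is plain text)
write_mtx_integer <- function(counts, path, gzip = FALSE) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  tm <- methods::as(counts, "TsparseMatrix")
  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(counts), ncol(counts), length(tm@x))),
             con)
  if (length(tm@x)) {
    writeLines(sprintf("%d %d %d", tm@i + 1L, tm@j + 1L, as.integer(tm@x)), con)
  }
  invisible(path)
}

#' Write a population as a 10x-style MTX directory
#'
#' Emits `matrix.mtx[.gz]` (integer Matrix Market triplets), `features.tsv[.gz]`
#' (id, symbol, "Gene Expression"), `barcodes.tsv[.gz]`, and `labels.tsv`
#' (barcode, state, depth). Round-trips exactly through
#' [read_population_10x()].
#'
#' @param pop a `cell_population`.
#' @param path output directory (created if needed).
#' @param gzip gzip the three 10x files (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_population_10x <- function(pop, path, gzip = FALSE) {
  validate_cell_population(pop)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sfx <- if (gzip) ".gz" else ""
  write_mtx_integer(pop$counts, file.path(path, paste0("matrix.mtx", sfx)),
                    gzip = gzip)
  genes <- rownames(pop$counts) %||% sprintf("G%05d", seq_len(nrow(pop$counts)))
  feat_con <- if (gzip) gzfile(file.path(path, "features.tsv.gz"), "wt") else
    file(file.path(path, "features.tsv"), "wt")
  writeLines(sprintf("%s\t%s\tGene Expression", genes, genes), feat_con)
  close(feat_con)
  bcs <- colnames(pop$counts) %||% sprintf("CELL_%04d", seq_len(ncol(pop$counts)))
  bc_con <- if (gzip) gzfile(file.path(path, "barcodes.tsv.gz"), "wt") else
    file(file.path(path, "barcodes.tsv"), "wt")
  writeLines(bcs, bc_con)
  close(bc_con)
  utils::write.table(
    data.frame(barcode = bcs, state = pop$labels, depth = pop$depths),
    file.path(path, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
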