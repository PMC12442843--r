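#' Read a CellRanger-style MatrixMarket count triplet
#'
#' Expects a directory holding `matrix.mtx` (genes as rows), `features.tsv`
#' (one or two tab-separated columns; the first is used as the gene id, a
#' second column is treated as a symbol and ignored) and `barcodes.tsv`.
#' Gzipped variants (`.mtx.gz`, `.tsv.gz`) are also accepted.
#'
#' @param dir_path directory containing the triplet.
#' @return sparse genes x cells count matrix with gene ids as rownames and
#'   cell barcodes as colnames.
#' @export
read_counts <- function(dir_path) {
  .assert(dir.exists(dir_path), sprintf("no such directory: %s", dir_path))
  pick <- function(stem) {
    for (f in file.path(dir_path, c(stem, paste0(stem, ".gz"))))
      if (file.exists(f)) return(f)
    stop(sprintf("missing %s in %s", stem, dir_path), call. = FALSE)
  }
  m <- tryCatch(Matrix::readMM(pick("matrix.mtx")),
                error = function(e) stop("malformed matrix.mtx: ",
                                         conditionMessage(e), call. = FALSE))
  feats <- utils::read.table(pick("features.tsv"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE,
                             quote = "", comment.char = "")
  bars <- utils::read.table(pick("barcodes.tsv"), sep = "\t",
                            header = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
  .assert(nrow(feats) == nrow(m),
          sprintf("features.tsv has %d rows but matrix has %d gene rows",
                  nrow(feats), nrow(m)))
  .assert(nrow(bars) == ncol(m),
          sprintf("barcodes.tsv has %d rows but matrix has %d cell columns",
                  nrow(bars), ncol(m)))
  .assert(!anyDuplicated(feats[[1]]), "duplicated gene ids in features.tsv")
  .assert(!anyDuplicated(bars[[1]]), "duplicated barcodes in barcodes.tsv")
  .assert(min(m) >= 0, "negative entries in count matrix")
  m <- .as_dgc(m)
  dimnames(m) <- list(feats[[1]], bars[[1]])
  m
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' Writes `matrix.mtx`, `features.tsv` (id and symbol columns, both the gene
#' id) and `barcodes.tsv` into `dir_path`, round-tripping bit-exactly with
#' [read_counts()].
#'
#' @param counts sparse or dense genes x cells count matrix with dimnames.
#' @param dir_path output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
write_counts <- function(counts, dir_path) {
  counts <- .values(counts)
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "counts must carry gene and cell ids as dimnames")
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir_path, "matrix.mtx"))
  utils::write.table(data.frame(rownames(counts), rownames(counts)),
                     file.path(dir_path, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(colnames(counts)),
                     file.path(dir_path, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir_path)
}

#' Write a simulated dataset to disk
#'
#' Writes the count triplet via [write_counts()] plus a `truth.tsv` cell
#' metadata table and a `gene_annotations.tsv` program-membership table.
#'
#' @param dataset a `sim_dataset`.
#' @param dir_path output directory.
#' @return `dir_path`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir_path) {
  .assert(inherits(dataset, "sim_dataset"), "dataset must be a sim_dataset")
  write_counts(dataset$counts, dir_path)
  utils::write.table(dataset$truth, file.path(dir_path, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$gene_annotations,
                     file.path(dir_path, "gene_annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir_path)
}
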