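#' Per-cell quality-control metrics
#'
#' Computes, for every cell: `n_genes` (genes with count > 0), `n_umi`
#' (column sum), `umi_gene_ratio` (`n_umi / n_genes`, 0 for empty cells so
#' that such cells always fail a minimum-ratio threshold) and `pct_mito`
#' (percent of UMI from genes whose id starts with `mito_prefix`,
#' case-insensitive — the mouse mitochondrial "mt-" convention).
#'
#' @param counts genes x cells count matrix with gene ids as rownames.
#' @param mito_prefix gene-id prefix identifying mitochondrial genes.
#' @return data.frame with one row per cell.
#' @export
compute_qc_metrics <- function(counts, mito_prefix = "mt-") {
  counts <- .values(counts)
  .assert(nzchar(mito_prefix), "mito_prefix must be nonempty")
  n_umi <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  ratio <- ifelse(n_genes > 0, n_umi / n_genes, 0)
  mito <- startsWith(tolower(rownames(counts)), tolower(mito_prefix))
  mito_umi <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
  pct_mito <- ifelse(n_umi > 0, 100 * mito_umi / n_umi, 0)
  data.frame(cell_id = colnames(counts), n_genes = as.integer(n_genes),
             n_umi = n_umi, umi_gene_ratio = ratio, pct_mito = pct_mito,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quality-control thresholds
#'
#' Builds a threshold set, either ad hoc or from a named preset reproducing a
#' published filtering rule, with the strict/inclusive comparison semantics
#' of each preset's wording:
#' \describe{
#'   \item{`"cd1"`}{more than 500 genes (strict), fewer than 30,000 UMI
#'     (strict), UMI/gene ratio above 1.2 (strict), mitochondrial percent
#'     below 2 (strict).}
#'   \item{`"reeler"`}{1000 genes and more (inclusive), UMI between 2500 and
#'     15,000 (inclusive both ends), mitochondrial percent below 1.}
#'   \item{`"vb"`}{more than 500 genes (strict), fewer than 20,000 UMI
#'     (strict), mitochondrial percent below 2.}
#' }
#' Unset thresholds (`NULL`/`NA`) are not applied. `max_umi`,
#' `min_umi_gene_ratio` and `max_pct_mito` comparisons are strict unless the
#' corresponding `*_inclusive` flag is set; `min_umi` is inclusive by
#' default (the "between" wording).
#'
#' @param preset one of `"cd1"`, `"reeler"`, `"vb"`, or `NULL` for ad hoc
#'   thresholds.
#' @param min_genes minimum genes detected.
#' @param min_genes_inclusive keep cells with exactly `min_genes`?
#' @param min_umi,max_umi UMI bounds.
#' @param min_umi_inclusive,max_umi_inclusive inclusivity of the UMI bounds.
#' @param min_umi_gene_ratio minimum UMI/gene ratio (strict).
#' @param max_pct_mito maximum mitochondrial percent (strict).
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(preset = NULL,
                          min_genes = NULL, min_genes_inclusive = FALSE,
                          min_umi = NULL, min_umi_inclusive = TRUE,
                          max_umi = NULL, max_umi_inclusive = FALSE,
                          min_umi_gene_ratio = NULL,
                          max_pct_mito = NULL) {
  if (!is.null(preset)) {
    th <- switch(preset,
      cd1 = qc_thresholds(min_genes = 500, min_genes_inclusive = FALSE,
                          max_umi = 30000, max_umi_inclusive = FALSE,
                          min_umi_gene_ratio = 1.2, max_pct_mito = 2),
      reeler = qc_thresholds(min_genes = 1000, min_genes_inclusive = TRUE,
                             min_umi = 2500, min_umi_inclusive = TRUE,
                             max_umi = 15000, max_umi_inclusive = TRUE,
                             max_pct_mito = 1),
      vb = qc_thresholds(min_genes = 500, min_genes_inclusive = FALSE,
                         max_umi = 20000, max_umi_inclusive = FALSE,
                         max_pct_mito = 2),
      stop(sprintf("unknown QC preset '%s'", preset), call. = FALSE))
    th$preset <- preset
    return(th)
  }
  if (!is.null(min_umi) && !is.null(max_umi))
    .assert(min_umi < max_umi, "min_umi must be below max_umi")
  structure(list(preset = NULL,
                 min_genes = min_genes,
                 min_genes_inclusive = isTRUE(min_genes_inclusive),
                 min_umi = min_umi, min_umi_inclusive = isTRUE(min_umi_inclusive),
                 max_umi = max_umi, max_umi_inclusive = isTRUE(max_umi_inclusive),
                 min_umi_gene_ratio = min_umi_gene_ratio,
                 max_pct_mito = max_pct_mito),
            class = "qc_thresholds")
}

#' Filter cells on quality-control metrics
#'
#' A cell is kept iff it satisfies every threshold that is set, with each
#' preset's strict/inclusive semantics; the input cell order is preserved.
#'
#' @param metrics data.frame from [compute_qc_metrics()].
#' @param thresholds a [qc_thresholds()] object or preset name.
#' @return character vector of kept cell ids.
#' @export
filter_cells <- function(metrics, thresholds) {
  if (is.character(thresholds)) thresholds <- qc_thresholds(preset = thresholds)
  .assert(inherits(thresholds, "qc_thresholds"),
          "thresholds must be a qc_thresholds object or preset name")
  th <- thresholds
  keep <- rep(TRUE, nrow(metrics))
  cmp <- function(x, bound, op_strict, op_incl, inclusive)
    if (inclusive) op_incl(x, bound) else op_strict(x, bound)
  if (!is.null(th$min_genes))
    keep <- keep & cmp(metrics$n_genes, th$min_genes, `>`, `>=`,
                       th$min_genes_inclusive)
  if (!is.null(th$min_umi))
    keep <- keep & cmp(metrics$n_umi, th$min_umi, `>`, `>=`,
                       th$min_umi_inclusive)
  if (!is.null(th$max_umi))
    keep <- keep & cmp(metrics$n_umi, th$max_umi, `<`, `<=`,
                       th$max_umi_inclusive)
  if (!is.null(th$min_umi_gene_ratio))
    keep <- keep & metrics$umi_gene_ratio > th$min_umi_gene_ratio
  if (!is.null(th$max_pct_mito))
    keep <- keep & metrics$pct_mito < th$max_pct_mito
  metrics$cell_id[keep]
}

#' Exclude cells with designated annotations
#'
#' Removes cells whose prior label is in an exclusion list (e.g. microglial,
#' endothelial and vascular-related identities excluded from neural
#' analyses). Labels absent from the data are ignored.
#'
#' @param cell_ids character vector of cell ids.
#' @param labels per-cell labels, same length/order as `cell_ids`.
#' @param exclude labels to remove.
#' @return kept cell ids, order preserved.
#' @export
exclude_annotated <- function(cell_ids, labels, exclude) {
  .assert(length(cell_ids) == length(labels),
          "labels must cover all cells")
  cell_ids[!(labels %in% exclude)]
}
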