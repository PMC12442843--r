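#' Differentially expressed genes between two conditions
#'
#' Per-gene Wilcoxon rank-sum test between two groups of cells on
#' log-normalized expression, with log2 fold change on de-logged means
#' (pseudocount 1) and percent-expressing difference. A gene is retained
#' when `|log2fc| > min_log2fc`, `p_adj < max_p_adj` (Bonferroni over the
#' gene universe) and `|pct_diff| > min_pct_diff` — both directions count.
#'
#' @param expr_a,expr_b genes x cells log-normalized matrices (same genes)
#'   for the two groups (>= 3 cells each).
#' @param min_log2fc fold-change threshold (default 0.6, strict).
#' @param max_p_adj adjusted-p threshold (default 0.05).
#' @param min_pct_diff percent-expressing difference threshold (default
#'   0.2, strict).
#' @return data.frame of retained DEG records: `gene`, `log2fc`, `p_adj`,
#'   `pct_diff`, `direction` (+1 up in a, -1 down in a).
#' @export
find_degs <- function(expr_a, expr_b, min_log2fc = 0.6, max_p_adj = 0.05,
                      min_pct_diff = 0.2) {
  a <- .values(expr_a)
  b <- .values(expr_b)
  .assert(ncol(a) >= 3 && ncol(b) >= 3, "each group needs at least 3 cells")
  .assert(identical(rownames(a), rownames(b)),
          "the two matrices must share the same gene rows")
  de <- .de_two_group(a, b, min_log2fc, min_pct_diff, max_p_adj,
                      pseudocount = 1, two_sided_fc = TRUE)
  de <- de[de$retained, , drop = FALSE]
  out <- data.frame(gene = de$gene, log2fc = de$log2fc, p_adj = de$p_adj,
                    pct_diff = de$pct_diff,
                    direction = sign(de$log2fc), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Partition DEGs into restored vs in-vivo-only
#'
#' A gene is "restored" when its organotypic mean expression is closer to
#' the in vivo mean than to the 2D-culture mean
#' (`|mean_organo - mean_invivo| < |mean_organo - mean_2d|`); ties count as
#' in-vivo-only. Means are on the log-normalized scale; the rule is
#' invariant to adding a constant to all three means of a gene. Genes with
#' any missing mean are dropped with a warning.
#'
#' @param genes gene ids.
#' @param mean_invivo,mean_2d,mean_organo per-gene condition means, aligned
#'   with `genes`.
#' @return named character vector: `"restored"` or `"in_vivo_only"` per
#'   gene.
#' @export
classify_restored <- function(genes, mean_invivo, mean_2d, mean_organo) {
  .assert(length(genes) == length(mean_invivo) &&
          length(genes) == length(mean_2d) &&
          length(genes) == length(mean_organo),
          "means must align with genes")
  ok <- is.finite(mean_invivo) & is.finite(mean_2d) & is.finite(mean_organo)
  if (any(!ok))
    warning(sprintf("%d genes dropped for missing condition means", sum(!ok)))
  cls <- ifelse(abs(mean_organo[ok] - mean_invivo[ok]) <
                abs(mean_organo[ok] - mean_2d[ok]),
                "restored", "in_vivo_only")
  stats::setNames(cls, genes[ok])
}

#' Summarize the restored-gene partition
#'
#' @param classes per-gene classes from [classify_restored()].
#' @return a `restoration_summary`: `n_deg`, `n_restored`,
#'   `percent_restored` (unrounded; round only at reporting).
#' @export
restoration_summary <- function(classes) {
  .assert(length(classes) >= 1, "no DEGs to summarize")
  n <- length(classes)
  r <- sum(classes == "restored")
  structure(list(n_deg = n, n_restored = r, percent_restored = 100 * r / n),
            class = "restoration_summary")
}

#' @export
print.restoration_summary <- function(x, ...) {
  cat(sprintf("restoration summary: %d / %d DEGs restored (%.0f%%)\n",
              x$n_restored, x$n_deg, x$percent_restored))
  invisible(x)
}

#' Condition-restoration analysis across three conditions
#'
#' Finds DEGs between the in vivo and 2D-culture matrices, then classifies
#' each DEG as restored or in-vivo-only from the three condition means.
#' With `groups` supplied (per-cell population labels for each condition),
#' DEG detection runs within each population present in all three
#' conditions and the union of the per-population DEG lists is classified —
#' appropriate when condition effects are population-specific and diluted
#' in pooled comparisons; condition means for the restored classification
#' are always computed across all cells of each condition.
#'
#' @param invivo,d2,organo genes x cells log-normalized matrices (shared
#'   gene rows).
#' @param groups optional list with per-cell population labels for
#'   `invivo`, `d2` and `organo` (same order as the matrix columns).
#' @param min_log2fc,max_p_adj,min_pct_diff see [find_degs()].
#' @return list with `degs` (gene ids), `classes`, `summary` (a
#'   `restoration_summary`) and the three per-gene condition `means`.
#' @export
restoration_analysis <- function(invivo, d2, organo, groups = NULL,
                                 min_log2fc = 0.6, max_p_adj = 0.05,
                                 min_pct_diff = 0.2) {
  vi <- .values(invivo); v2 <- .values(d2); vo <- .values(organo)
  if (is.null(groups)) {
    degs <- find_degs(vi, v2, min_log2fc, max_p_adj, min_pct_diff)$gene
  } else {
    shared <- intersect(intersect(unique(groups$invivo), unique(groups$d2)),
                        unique(groups$organo))
    shared <- shared[!is.na(shared)]
    degs <- character(0)
    for (p in shared) {
      a <- vi[, which(groups$invivo == p), drop = FALSE]
      b <- v2[, which(groups$d2 == p), drop = FALSE]
      if (ncol(a) < 3 || ncol(b) < 3) next
      degs <- union(degs, find_degs(a, b, min_log2fc, max_p_adj,
                                    min_pct_diff)$gene)
    }
  }
  .assert(length(degs) >= 1, "no differentially expressed genes detected")
  # condition means over the analyzed populations' cells (all cells when no
  # groups are given)
  keep_i <- if (is.null(groups)) seq_len(ncol(vi)) else which(!is.na(groups$invivo))
  keep_2 <- if (is.null(groups)) seq_len(ncol(v2)) else which(!is.na(groups$d2))
  keep_o <- if (is.null(groups)) seq_len(ncol(vo)) else which(!is.na(groups$organo))
  means <- data.frame(gene = degs,
                      invivo = Matrix::rowMeans(vi[degs, keep_i, drop = FALSE]),
                      d2 = Matrix::rowMeans(v2[degs, keep_2, drop = FALSE]),
                      organo = Matrix::rowMeans(vo[degs, keep_o, drop = FALSE]),
                      row.names = NULL, stringsAsFactors = FALSE)
  classes <- classify_restored(means$gene, means$invivo, means$d2,
                               means$organo)
  list(degs = degs, classes = classes, summary = restoration_summary(classes),
       means = means)
}
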