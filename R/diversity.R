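#' Shannon diversity of a cluster-count vector
#'
#' Natural-log Shannon index `H = -sum(p_i * log(p_i))` over nonzero
#' proportions `p_i = count_i / sum(counts)`, computed with
#' [vegan::diversity()]. `H` is 0 for a single nonempty cluster and at most
#' `log` of the number of nonempty clusters.
#'
#' @param cluster_counts non-negative integer vector with at least one
#'   positive entry.
#' @return the Shannon index (natural log).
#' @export
shannon_index <- function(cluster_counts) {
  .assert(all(cluster_counts >= 0), "cluster counts must be non-negative")
  .assert(sum(cluster_counts) > 0, "all-zero cluster counts")
  as.numeric(vegan::diversity(cluster_counts, index = "shannon"))
}

#' Cluster merged (unintegrated) datasets
#'
#' Concatenates cells from several count matrices over the shared gene
#' universe (intersection), without any batch integration, and clusters the
#' merged SNN graph at one resolution (default 1, the convention for
#' diversity assessment).
#'
#' @param count_list named list of genes x cells count matrices.
#' @param resolution clustering resolution (default 1).
#' @param seed integer seed.
#' @param n_components,k_neighbors see [build_neighbor_graph()].
#' @param scale_total,clip see [lognormalize()] and [scale_expression()].
#' @return list with `labels` (named integer cluster ids over all cells) and
#'   `dataset` (per-cell source-name vector).
#' @export
merged_cluster <- function(count_list, resolution = 1, seed = 0,
                           n_components = 30, k_neighbors = 20,
                           scale_total = 1e4, clip = 10) {
  .assert(length(count_list) >= 1, "need at least one dataset")
  mats <- lapply(count_list, .values)
  shared <- Reduce(intersect, lapply(mats, rownames))
  .assert(length(shared) > 0, "empty gene intersection across datasets")
  if (is.null(names(count_list)))
    names(count_list) <- paste0("dataset", seq_along(count_list))
  merged <- do.call(cbind, lapply(names(count_list), function(nm) {
    m <- mats[[nm]][shared, , drop = FALSE]
    colnames(m) <- paste(nm, colnames(m), sep = "|")
    m
  }))
  sc <- scale_expression(lognormalize(merged, scale_total), clip = clip)
  g <- build_neighbor_graph(sc, n_components, k_neighbors, seed = seed)
  labels <- cluster_graph(g, resolution, seed = seed)
  dataset <- rep(names(count_list), vapply(mats, ncol, integer(1)))
  names(dataset) <- colnames(merged)
  list(labels = labels, dataset = dataset)
}

#' Shannon diversity per group from merged-cluster composition
#'
#' For each group (e.g. a cell class within a condition), counts that
#' group's cells across the merged clusters and returns the Shannon index
#' of the composition (clusters without cells of the group contribute
#' nothing, per the `p_i > 0` convention).
#'
#' @param labels per-cell cluster ids (e.g. from [merged_cluster()]).
#' @param groups per-cell group labels, aligned with `labels`.
#' @return data.frame: `group`, `n_cells`, `n_clusters` (nonempty),
#'   `shannon`; log base recorded in the `log_base` attribute.
#' @export
diversity_by_group <- function(labels, groups) {
  .assert(length(labels) == length(groups),
          "labels and groups must align")
  out <- do.call(rbind, lapply(split(seq_along(labels), groups), function(idx) {
    tb <- table(labels[idx])
    data.frame(group = groups[idx[1]], n_cells = length(idx),
               n_clusters = sum(tb > 0), shannon = shannon_index(as.vector(tb)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "log_base") <- exp(1)
  out
}
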