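#' Build a shared-nearest-neighbour graph over cells
#'
#' Standard single-cell graph construction: PCA on the scaled matrix, exact
#' k-nearest neighbours in PC space, then shared-nearest-neighbour (SNN)
#' edge weights by the Jaccard overlap of neighbour sets, pruned below
#' `prune`.
#'
#' @param scaled a `scaled_matrix` (genes x cells) from [scale_expression()].
#' @param n_components number of principal components (>= 2).
#' @param k_neighbors neighbours per cell (>= 2).
#' @param seed integer seed (PCA and neighbour search are deterministic;
#'   the seed is fixed for strictness).
#' @param prune SNN Jaccard weights at or below this value are dropped
#'   (default 1/15, the conventional pruning).
#' @return an undirected weighted [igraph::graph] whose vertices are cells.
#' @export
build_neighbor_graph <- function(scaled, n_components = 30, k_neighbors = 20,
                                 seed = 0, prune = 1 / 15) {
  v <- .values(scaled)
  n <- ncol(v)
  .assert(n_components >= 2, "n_components must be >= 2")
  .assert(k_neighbors >= 2, "k_neighbors must be >= 2")
  .assert(n > k_neighbors, "fewer cells than k_neighbors")
  n_components <- min(n_components, n - 1L, nrow(v))
  pcs <- .with_seed(seed, stats::prcomp(t(as.matrix(v)), center = TRUE,
                                        scale. = FALSE, rank. = n_components)$x)
  nn <- RANN::nn2(pcs, k = k_neighbors)$nn.idx
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k_neighbors),
                              j = as.vector(nn), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  snn <- shared / (2 * k_neighbors - shared)
  snn@x[snn@x <= prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "max", weighted = TRUE)
  igraph::V(g)$name <- colnames(v)
  g
}

#' Cluster a cell graph by modularity community detection
#'
#' Leiden community detection with the modularity objective at a given
#' resolution; larger resolutions yield more, smaller communities. Cluster
#' ids are contiguous integers from 0, ordered by decreasing cluster size
#' (ties broken by the lexicographically smallest member cell id), which
#' makes the labelling equivariant under permutations of the cells.
#'
#' @param graph graph from [build_neighbor_graph()].
#' @param resolution resolution parameter (> 0).
#' @param seed integer seed for the (stochastic) refinement.
#' @return named integer vector of cluster ids (one per cell), with
#'   attribute `resolution`.
#' @export
cluster_graph <- function(graph, resolution, seed = 0) {
  .assert(igraph::vcount(graph) > 0, "empty graph")
  .assert(resolution > 0, "resolution must be > 0")
  mem <- .with_seed(seed, igraph::membership(igraph::cluster_leiden(
    graph, objective_function = "modularity",
    resolution = resolution, n_iterations = 10)))
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- as.character(seq_along(mem))
  sizes <- table(mem)
  firsts <- vapply(split(ids, mem), min, character(1))
  ord <- order(-as.vector(sizes), firsts)
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(ord) - 1L
  out <- relab[as.integer(factor(mem, levels = names(sizes)))]
  names(out) <- ids
  attr(out, "resolution") <- resolution
  out
}

#' Cluster at several resolutions
#'
#' @param graph graph from [build_neighbor_graph()].
#' @param resolutions numeric vector of resolutions.
#' @param seed integer seed.
#' @return named list of [cluster_graph()] labelings, one per resolution.
#' @export
sweep_resolutions <- function(graph, resolutions, seed = 0) {
  out <- lapply(resolutions, function(r) cluster_graph(graph, r, seed = seed))
  names(out) <- as.character(resolutions)
  out
}

#' Assemble a class/subclass/type tree from three labelings
#'
#' Each child population's parent is the parent-level cluster containing the
#' majority of its cells; the recorded purity is that majority fraction.
#' Ties are broken toward the lower parent id. Non-nested clusterings are
#' thus resolved by majority assignment with the violation made visible as
#' purity < 1 rather than by re-clustering.
#'
#' @param class_labels,subclass_labels,type_labels per-cell labelings
#'   covering the same cells (named vectors or plain vectors in the same
#'   cell order).
#' @return a `hierarchy_tree`: data.frame with columns `population`,
#'   `level`, `parent`, `purity`.
#' @export
assemble_tree <- function(class_labels, subclass_labels, type_labels) {
  .assert(length(class_labels) == length(subclass_labels) &&
          length(subclass_labels) == length(type_labels),
          "the three labelings must cover the same cells")
  majority <- function(child, parent) {
    do.call(rbind, lapply(sort(unique(as.character(child))), function(p) {
      tb <- table(as.character(parent)[as.character(child) == p])
      tb <- tb[order(-as.vector(tb), names(tb))]  # ties -> lower parent id
      data.frame(population = p, parent = names(tb)[1],
                 purity = as.vector(tb)[1] / sum(tb),
                 stringsAsFactors = FALSE)
    }))
  }
  cls <- data.frame(population = sort(unique(as.character(class_labels))),
                    parent = NA_character_, purity = 1,
                    stringsAsFactors = FALSE)
  sub <- majority(subclass_labels, class_labels)
  typ <- majority(type_labels, subclass_labels)
  tree <- rbind(cbind(level = "class", cls),
                cbind(level = "subclass", sub),
                cbind(level = "type", typ))
  tree <- tree[, c("population", "level", "parent", "purity")]
  rownames(tree) <- NULL
  class(tree) <- c("hierarchy_tree", "data.frame")
  tree
}

#' Three-level clustering of a reference dataset
#'
#' Runs the full taxonomy construction: SNN graph, community detection at
#' the class/subclass/type resolutions, and tree assembly with per-link
#' purity.
#'
#' @param scaled a `scaled_matrix` from [scale_expression()].
#' @param resolutions numeric length-3 vector of clustering resolutions,
#'   ordered class, subclass, type (defaults 0.0005, 0.001, 0.08).
#' @param n_components,k_neighbors,prune see [build_neighbor_graph()].
#' @param seed integer seed.
#' @return list with `labels` (data.frame cell_id/class/subclass/type of
#'   cluster ids), `tree` (a `hierarchy_tree`) and `graph`.
#' @export
cluster_hierarchy <- function(scaled, resolutions = c(0.0005, 0.001, 0.08),
                              n_components = 30, k_neighbors = 20,
                              prune = 1 / 15, seed = 0) {
  .assert(length(resolutions) == 3, "resolutions must have length 3")
  g <- build_neighbor_graph(scaled, n_components, k_neighbors,
                            seed = seed, prune = prune)
  labs <- sweep_resolutions(g, resolutions, seed = seed)
  labels <- data.frame(cell_id = colnames(.values(scaled)),
                       class = paste0("C", labs[[1]]),
                       subclass = paste0("S", labs[[2]]),
                       type = paste0("T", labs[[3]]),
                       stringsAsFactors = FALSE)
  tree <- assemble_tree(labels$class, labels$subclass, labels$type)
  list(labels = labels, tree = tree, graph = g)
}
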