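#' Identity-gene (marker) selection at one hierarchical level
#'
#' One-vs-rest marker test per population: Wilcoxon rank-sum p-values
#' (Bonferroni-adjusted over the gene universe), log2 fold change on
#' de-logged normalized means with a pseudocount, and percent-expressing
#' difference. A gene is retained for a population when
#' `log2fc >= min_log2fc`, `pct_in - pct_out >= min_pct_diff` and
#' `p_adj < alpha`. Populations with fewer than `min_cells` cells are
#' skipped with a warning.
#'
#' @param lognorm a `scaled_matrix` from [lognormalize()].
#' @param labels per-cell population labels (vector, one per column).
#' @param level level tag recorded in the output (`"class"`, `"subclass"`,
#'   `"type"`, or any label).
#' @param min_log2fc minimum log2 fold change (default 0.6).
#' @param min_pct_diff minimum percent-expressing difference (default 0.1).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param pseudocount pseudocount on de-logged means (default 1).
#' @param min_cells minimum population size tested (default 3).
#' @return data.frame of retained marker records: `gene`, `population`,
#'   `level`, `log2fc`, `pct_in`, `pct_out`, `p_adj`.
#' @export
find_level_markers <- function(lognorm, labels, level = "type",
                               min_log2fc = 0.6, min_pct_diff = 0.1,
                               alpha = 0.05, pseudocount = 1, min_cells = 3) {
  v <- .values(lognorm)
  labels <- as.character(labels)
  .assert(length(labels) == ncol(v), "labels must cover all cells")
  pops <- sort(unique(labels))
  .assert(length(pops) >= 2, "need at least two populations")
  out <- lapply(pops, function(p) {
    idx <- labels == p
    if (sum(idx) < min_cells) {
      warning(sprintf("population '%s' has fewer than %d cells; markers skipped",
                      p, min_cells))
      return(NULL)
    }
    de <- .de_two_group(v[, idx, drop = FALSE], v[, !idx, drop = FALSE],
                        min_log2fc, min_pct_diff, alpha, pseudocount)
    de <- de[de$retained, , drop = FALSE]
    if (!nrow(de)) return(NULL)
    data.frame(gene = de$gene, population = p, level = level,
               log2fc = de$log2fc, pct_in = de$pct_in, pct_out = de$pct_out,
               p_adj = de$p_adj, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(0), population = character(0),
                      level = character(0), log2fc = numeric(0),
                      pct_in = numeric(0), pct_out = numeric(0),
                      p_adj = numeric(0))
  rownames(res) <- NULL
  res
}

#' Collect per-level identity gene sets
#'
#' Groups marker records into per-(level, population) gene lists. A gene may
#' appear in several populations' lists; the per-level union size counts
#' each gene once.
#'
#' @param markers a marker data.frame, e.g. the row-bound results of
#'   [find_level_markers()] across levels.
#' @return an `identity_gene_sets` object: named list (level) of named lists
#'   (population) of gene vectors, with a `union_sizes` attribute.
#' @export
identity_gene_sets <- function(markers) {
  .assert(all(c("gene", "population", "level") %in% names(markers)),
          "markers must have gene, population and level columns")
  sets <- lapply(split(markers, markers$level), function(m)
    lapply(split(m$gene, m$population), unique))
  attr(sets, "union_sizes") <- vapply(sets, function(s)
    length(unique(unlist(s))), integer(1))
  class(sets) <- "identity_gene_sets"
  sets
}

#' Per-cell identity scores
#'
#' The identity score of a cell for a population is the arithmetic mean of
#' the scaled expression of that population's identity genes in the cell.
#' Genes missing from the matrix are dropped with a warning; a set left
#' empty is an error.
#'
#' @param scaled a `scaled_matrix` from [scale_expression()].
#' @param gene_sets an [identity_gene_sets()] object (or a plain named list
#'   of gene vectors).
#' @param level which level's sets to score; ignored when `gene_sets` is a
#'   plain list.
#' @return cells x populations score matrix with a `level` attribute.
#' @export
compute_identity_scores <- function(scaled, gene_sets, level = NULL) {
  v <- .values(scaled)
  sets <- if (inherits(gene_sets, "identity_gene_sets")) {
    .assert(!is.null(level) && level %in% names(gene_sets),
            "level must name an entry of gene_sets")
    gene_sets[[level]]
  } else gene_sets
  present <- lapply(sets, intersect, rownames(v))
  dropped <- sum(lengths(sets)) - sum(lengths(present))
  if (dropped > 0)
    warning(sprintf("%d identity genes absent from matrix were dropped", dropped))
  .assert(all(lengths(present) > 0),
          "an identity gene set is empty after dropping missing genes")
  s <- vapply(present, function(g)
    Matrix::colMeans(v[g, , drop = FALSE]), numeric(ncol(v)))
  if (ncol(v) == 1) s <- matrix(s, nrow = 1, dimnames = list(colnames(v), names(present)))
  rownames(s) <- colnames(v)
  attr(s, "level") <- level
  s
}

#' Fit the 2D identity embedding on reference scores
#'
#' UMAP of the reference cells' identity-score vectors (deterministic given
#' the seed; single-threaded optimization). The returned object supports
#' out-of-sample projection of query score vectors via [project_query()].
#'
#' @param ref_scores cells x populations score matrix (>= 10 cells, finite).
#' @param seed integer seed.
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @param min_dist UMAP minimum distance (default 0.01; tight clusters suit
#'   nearest-neighbour voting).
#' @return an `identity_embedding` with `coords` (reference 2D coordinates),
#'   `scores` (the reference score matrix) and the transform state.
#' @export
fit_identity_embedding <- function(ref_scores, seed = 0, n_neighbors = 15,
                                   min_dist = 0.01) {
  .assert(nrow(ref_scores) >= 10, "need at least 10 reference cells")
  .assert(all(is.finite(ref_scores)), "non-finite identity scores")
  model <- .with_seed(seed, uwot::umap(
    ref_scores, n_neighbors = min(n_neighbors, nrow(ref_scores) - 1),
    min_dist = min_dist, ret_model = TRUE,
    n_threads = 1, n_sgd_threads = 1))
  coords <- model$embedding
  rownames(coords) <- rownames(ref_scores)
  colnames(coords) <- c("UMAP1", "UMAP2")
  structure(list(coords = coords, scores = ref_scores, model = model,
                 seed = seed),
            class = "identity_embedding")
}

#' Project query score vectors into a fitted identity embedding
#'
#' @param embedding an [fit_identity_embedding()] result.
#' @param query_scores cells x populations score matrix; columns must match
#'   the reference score columns.
#' @return query 2D coordinates.
#' @export
project_query <- function(embedding, query_scores) {
  .assert(inherits(embedding, "identity_embedding"),
          "embedding must be an identity_embedding")
  .assert(identical(colnames(query_scores), colnames(embedding$scores)),
          "query score columns must match the reference score columns")
  if (nrow(query_scores) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("UMAP1", "UMAP2"))))
  xy <- .with_seed(embedding$seed,
                   uwot::umap_transform(query_scores, embedding$model,
                                        n_threads = 1, n_sgd_threads = 1))
  rownames(xy) <- rownames(query_scores)
  colnames(xy) <- c("UMAP1", "UMAP2")
  xy
}

#' k-nearest-neighbour consensus identity assignment
#'
#' For every query cell and every hierarchical level independently: find the
#' `k` nearest reference cells by Euclidean distance (distance ties broken
#' by reference index order), and assign the modal reference label if it is
#' carried by at least `consensus` of the `k` neighbours; otherwise the cell
#' is `"undefined"`. With the defaults this is the 9-of-10 consensus rule:
#' mixed neighbourhoods (8 or fewer agreeing) yield an undefined call.
#'
#' @param ref_coords reference coordinates (cells x d; 2D embedding
#'   coordinates or identity-score vectors).
#' @param ref_labels data.frame (or named list) of per-reference-cell labels,
#'   one column per level; a plain vector is treated as a single level.
#' @param query_coords query coordinates (cells x d, same space).
#' @param k neighbourhood size (default 10; must not exceed the reference).
#' @param consensus votes required for assignment (default 9; <= k).
#' @return an `identity_assignment` data.frame: for each level a label
#'   column and a `<level>_votes` column with the modal vote count.
#' @export
assign_identity <- function(ref_coords, ref_labels, query_coords,
                            k = 10, consensus = 9) {
  ref_coords <- as.matrix(ref_coords)
  query_coords <- as.matrix(query_coords)
  if (is.null(dim(ref_labels)) && !is.list(ref_labels))
    ref_labels <- data.frame(label = ref_labels, stringsAsFactors = FALSE)
  ref_labels <- as.data.frame(ref_labels, stringsAsFactors = FALSE)
  .assert(consensus <= k, "consensus must not exceed k")
  .assert(k <= nrow(ref_coords), "k exceeds the number of reference cells")
  .assert(nrow(ref_labels) == nrow(ref_coords),
          "ref_labels must cover all reference cells")
  .assert(ncol(query_coords) == ncol(ref_coords),
          "query and reference coordinate dimensions differ")
  n_q <- nrow(query_coords)
  out <- data.frame(cell_id = if (!is.null(rownames(query_coords)))
                      rownames(query_coords) else as.character(seq_len(n_q)),
                    stringsAsFactors = FALSE)
  # exact neighbour search with deterministic index tie-break
  rsq <- rowSums(ref_coords^2)
  nn_idx <- matrix(0L, n_q, k)
  if (n_q > 0) {
    cross <- query_coords %*% t(ref_coords)
    for (i in seq_len(n_q)) {
      d2 <- rsq - 2 * cross[i, ]
      nn_idx[i, ] <- order(d2, seq_along(d2))[seq_len(k)]
    }
  }
  for (lvl in names(ref_labels)) {
    labs <- as.character(ref_labels[[lvl]])
    call <- character(n_q)
    votes <- integer(n_q)
    for (i in seq_len(n_q)) {
      tb <- table(labs[nn_idx[i, ]])
      m <- which.max(tb)
      votes[i] <- as.integer(tb[m])
      call[i] <- if (tb[m] >= consensus) names(tb)[m] else "undefined"
    }
    out[[lvl]] <- call
    out[[paste0(lvl, "_votes")]] <- votes
  }
  attr(out, "k") <- k
  attr(out, "consensus") <- consensus
  class(out) <- c("identity_assignment", "data.frame")
  out
}

#' Population proportions per group and level
#'
#' Fraction of cells per label (including `"undefined"` as its own
#' category), per grouping value and per level; fractions sum to 1 within
#' each group and level.
#'
#' @param assignment an [assign_identity()] result (or any data.frame of
#'   per-cell labels).
#' @param grouping per-cell grouping vector (e.g. timepoint or condition);
#'   default a single group.
#' @param levels which label columns to tabulate; defaults to all non-vote,
#'   non-id columns.
#' @return long data.frame: `group`, `level`, `population`, `n`,
#'   `proportion`.
#' @export
population_proportions <- function(assignment, grouping = NULL,
                                   levels = NULL) {
  df <- as.data.frame(assignment)
  if (is.null(levels))
    levels <- setdiff(names(df), c("cell_id", grep("_votes$", names(df),
                                                   value = TRUE)))
  if (is.null(grouping)) grouping <- rep("all", nrow(df))
  out <- do.call(rbind, lapply(levels, function(lvl) {
    do.call(rbind, lapply(split(seq_len(nrow(df)), grouping), function(idx) {
      tb <- table(df[[lvl]][idx])
      data.frame(group = grouping[idx[1]], level = lvl,
                 population = names(tb), n = as.vector(tb),
                 proportion = as.vector(tb) / length(idx),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Reference-based classification of query cells
#'
#' End-to-end wrapper around the identity framework. A reference is built
#' from log-normalized counts, per-level labels and per-level identity gene
#' sets: reference cells are scored against every population at every level,
#' the per-level score matrices are concatenated into one identity-score
#' space, and (for `space = "embedding"`) a 2D UMAP is fitted on it. Query
#' cells are log-normalized, placed on the reference z-scale (reference
#' per-gene centers/scales), scored with the same gene sets, projected, and
#' assigned per level by the k-NN consensus rule.
#'
#' `space = "embedding"` reproduces the published procedure (neighbours in
#' the 2D identity UMAP) and is what the identity UMAP figures show;
#' `space = "score"` performs the consensus vote directly in the
#' identity-score space, which is the more stable choice for quantifying
#' identity degradation since the 2D out-of-sample transform necessarily
#' places every query inside some reference cluster.
#'
#' @param ref_counts,query_counts genes x cells count matrices.
#' @param ref_labels data.frame of per-reference-cell labels, one column per
#'   level (e.g. class/subclass/type).
#' @param gene_sets an [identity_gene_sets()] object covering those levels.
#' @param k,consensus consensus rule parameters (default 10 and 9).
#' @param space `"embedding"` (2D identity UMAP) or `"score"`
#'   (identity-score space).
#' @param scale_total,clip see [lognormalize()] and [scale_expression()].
#' @param seed integer seed (UMAP).
#' @return list with `assignment` (an `identity_assignment`), `ref_scores`,
#'   `query_scores`, and (embedding space) `embedding` and `query_coords`.
#' @export
classify_cells <- function(ref_counts, ref_labels, gene_sets, query_counts,
                           k = 10, consensus = 9,
                           space = c("embedding", "score"),
                           scale_total = 1e4, clip = 10, seed = 0) {
  space <- match.arg(space)
  lvls <- names(ref_labels)
  ref_ln <- lognormalize(ref_counts, scale_total)
  ref_sc <- scale_expression(ref_ln, clip = clip)
  q_ln <- lognormalize(query_counts, scale_total)
  q_sc <- scale_expression(q_ln, clip = clip, stats = ref_sc$meta)
  score_block <- function(sc) {
    blocks <- lapply(lvls, function(l)
      compute_identity_scores(sc, gene_sets, level = l))
    s <- do.call(cbind, blocks)
    colnames(s) <- unlist(lapply(lvls, function(l)
      paste(l, names(gene_sets[[l]]), sep = ":")))
    s
  }
  ref_scores <- score_block(ref_sc)
  query_scores <- score_block(q_sc)
  if (space == "embedding") {
    emb <- fit_identity_embedding(ref_scores, seed = seed)
    qxy <- project_query(emb, query_scores)
    asg <- assign_identity(emb$coords, ref_labels, qxy, k, consensus)
    list(assignment = asg, ref_scores = ref_scores,
         query_scores = query_scores, embedding = emb, query_coords = qxy)
  } else {
    asg <- assign_identity(ref_scores, ref_labels, query_scores, k, consensus)
    list(assignment = asg, ref_scores = ref_scores,
         query_scores = query_scores)
  }
}
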