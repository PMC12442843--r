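#' Train a regularized ordinal-regression staging model
#'
#' Fits the all-threshold hinge formulation of ordinal regression: with
#' ordered categories `1..T`, per-gene weights `w` and nondecreasing
#' cutpoints `theta[1..T-1]`, the objective is
#' `lambda * ||w||^2 + sum over cells i and thresholds t of
#' max(0, 1 - s * (w . x_i - theta[t]))`, where `s = +1` if cell `i`'s
#' category lies above threshold `t` and `-1` otherwise. The objective is
#' convex; it is minimized by L-BFGS on a quadratically smoothed hinge
#' (smoothing width `eps`), and the cutpoints are sorted afterwards (the
#' all-threshold loss admits a nondecreasing optimum).
#'
#' @param expr genes x cells matrix of scaled expression (a
#'   `scaled_matrix` or plain matrix).
#' @param labels ordered factor (or coercible) of timepoint categories, one
#'   per cell; every category must be populated.
#' @param lambda ridge penalty on `w` (> 0, default 1).
#' @param eps hinge smoothing width (default 0.05).
#' @param maxit optimizer iteration cap (default 500).
#' @return an `ordinal_model`: `genes`, `w`, `theta`, `lambda`.
#' @export
train_ordinal <- function(expr, labels, lambda = 1, eps = 0.05, maxit = 500) {
  v <- .values(expr)
  X <- t(as.matrix(v))              # cells x genes
  y <- as.integer(factor(labels, levels = if (is.factor(labels))
    levels(labels) else sort(unique(labels))))
  .assert(length(y) == nrow(X), "labels must cover all cells")
  n_t <- max(y)
  .assert(n_t >= 2, "need at least two ordered categories")
  .assert(all(seq_len(n_t) %in% y), "a category has no cells")
  .assert(lambda > 0, "lambda must be > 0")
  p <- ncol(X)
  sgn <- vapply(seq_len(n_t - 1), function(t) ifelse(y > t, 1, -1),
                numeric(length(y)))
  huber <- function(u) ifelse(u >= eps, u - eps / 2,
                              ifelse(u <= 0, 0, u^2 / (2 * eps)))
  dhuber <- function(u) ifelse(u >= eps, 1, ifelse(u <= 0, 0, u / eps))
  obj <- function(par) {
    w <- par[seq_len(p)]; th <- par[p + seq_len(n_t - 1)]
    f <- drop(X %*% w)
    lambda * sum(w^2) +
      sum(vapply(seq_len(n_t - 1), function(t)
        sum(huber(1 - sgn[, t] * (f - th[t]))), numeric(1)))
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; th <- par[p + seq_len(n_t - 1)]
    f <- drop(X %*% w)
    gw <- 2 * lambda * w
    gt <- numeric(n_t - 1)
    for (t in seq_len(n_t - 1)) {
      d <- dhuber(1 - sgn[, t] * (f - th[t]))
      gw <- gw - drop(crossprod(X, d * sgn[, t]))
      gt[t] <- sum(d * sgn[, t])
    }
    c(gw, gt)
  }
  fit <- stats::optim(rep(0, p + n_t - 1), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7))
  structure(list(genes = rownames(v), w = stats::setNames(fit$par[seq_len(p)],
                                                          rownames(v)),
                 theta = sort(fit$par[p + seq_len(n_t - 1)]),
                 lambda = lambda, value = fit$value),
            class = "ordinal_model")
}

#' Predict pseudo-age for query cells
#'
#' The pseudo-age of a cell is the linear score `w . x` over the model's
#' genes. Model genes missing from the query are dropped with a warning and
#' the score is renormalized by the fraction of genes available, keeping
#' scores comparable across matrices with different coverage.
#'
#' @param model an [train_ordinal()] model.
#' @param expr genes x cells matrix of scaled expression.
#' @return named numeric vector of per-cell pseudo-age scores.
#' @export
predict_pseudoage <- function(model, expr) {
  v <- .values(expr)
  avail <- intersect(model$genes, rownames(v))
  .assert(length(avail) > 0, "no model genes available in query matrix")
  if (length(avail) < length(model$genes))
    warning(sprintf("%d model genes missing from query; score renormalized",
                    length(model$genes) - length(avail)))
  s <- drop(crossprod(as.matrix(v[avail, , drop = FALSE]), model$w[avail]))
  s * length(model$genes) / length(avail)
}

# stratified fold assignment: each timepoint spread across folds
.strat_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  .with_seed(seed, for (lev in unique(y)) {
    idx <- which(y == lev)
    folds[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  })
  # a singleton category confined to one fold would leave some training set
  # without that category; train_ordinal reports it as an error downstream
  folds
}

#' Cross-validated pseudo-age scores
#'
#' Timepoint-stratified k-fold cross-validation: every cell's score comes
#' from a model trained without its fold. When `n_genes` is given, genes are
#' re-ranked by `|w|` from a full-gene model fitted on each fold's training
#' cells only, and the top `n_genes` genes of that ranking are used — the
#' ranking never sees the held-out cells.
#'
#' @param expr genes x cells scaled expression.
#' @param labels ordered timepoint categories.
#' @param n_folds number of folds (default 5; may equal the cell count for
#'   leave-one-out).
#' @param lambda ridge penalty.
#' @param seed integer seed for fold assignment.
#' @param n_genes optional gene-count restriction (nested per-fold ranking).
#' @return a `cv_result`: `scores` (per-cell out-of-fold score), `folds`,
#'   `labels`.
#' @export
cross_validate <- function(expr, labels, n_folds = 5, lambda = 1, seed = 0,
                           n_genes = NULL) {
  v <- as.matrix(.values(expr))
  y <- factor(labels, levels = if (is.factor(labels)) levels(labels)
              else sort(unique(labels)))
  .assert(n_folds >= 2, "n_folds must be >= 2")
  folds <- .strat_folds(as.integer(y), n_folds, seed)
  scores <- numeric(ncol(v))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    sub <- v
    if (!is.null(n_genes)) {
      .assert(n_genes <= nrow(v), "n_genes exceeds the gene universe")
      full <- train_ordinal(v[, tr, drop = FALSE], y[tr], lambda)
      top <- names(sort(abs(full$w), decreasing = TRUE))[seq_len(n_genes)]
      sub <- v[top, , drop = FALSE]
    }
    m <- train_ordinal(sub[, tr, drop = FALSE], y[tr], lambda)
    scores[!tr] <- drop(crossprod(sub[, !tr, drop = FALSE], m$w))
  }
  names(scores) <- colnames(v)
  structure(list(scores = scores, folds = folds, labels = y),
            class = "cv_result")
}

#' Overlap coefficient of two samples
#'
#' The integral of the pointwise minimum of two kernel density estimates
#' (Gaussian kernel, Silverman's rule bandwidth) over a shared 512-point
#' grid spanning the pooled range extended by three bandwidths; clipped to
#' \[0, 1\]. Identical distributions give ~1, disjoint ones ~0. Constant
#' samples fall back to a point-mass comparison (overlap 1 if the two
#' constants coincide, else 0 unless the other sample's density covers the
#' point).
#'
#' @param values_a,values_b numeric samples (>= 2 values each).
#' @param n_grid evaluation grid size (default 512).
#' @return overlap coefficient in \[0, 1\].
#' @export
overlap_coefficient <- function(values_a, values_b, n_grid = 512) {
  .assert(length(values_a) >= 2 && length(values_b) >= 2,
          "each sample needs at least 2 values")
  # degenerate (constant) samples: point-mass comparison
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0)
    return(as.numeric(stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
                        isTRUE(all.equal(values_a[1], values_b[1]))))
  bw_a <- stats::bw.nrd0(values_a)
  bw_b <- stats::bw.nrd0(values_b)
  lo <- min(values_a, values_b) - 3 * max(bw_a, bw_b)
  hi <- max(values_a, values_b) + 3 * max(bw_a, bw_b)
  da <- stats::density(values_a, bw = bw_a, from = lo, to = hi, n = n_grid)$y
  db <- stats::density(values_b, bw = bw_b, from = lo, to = hi, n = n_grid)$y
  step <- (hi - lo) / (n_grid - 1)
  min(1, max(0, sum(pmin(da, db)) * step))
}

# mean overlap between CV-score distributions of timepoint pairs
.mean_overlap <- function(scores, y, pairing) {
  lv <- levels(y)
  pairs <- if (pairing == "consecutive")
    lapply(seq_len(length(lv) - 1), function(i) c(i, i + 1))
  else utils::combn(length(lv), 2, simplify = FALSE)
  mean(vapply(pairs, function(pr)
    overlap_coefficient(scores[y == lv[pr[1]]], scores[y == lv[pr[2]]]),
    numeric(1)))
}

#' Select the pseudo-age gene count by cross-validated overlap
#'
#' For each candidate gene count, runs nested cross-validation
#' ([cross_validate()] with per-fold gene ranking) and records the mean
#' overlap coefficient between CV-score distributions of timepoint pairs
#' (consecutive pairs by default — the discriminative ones for ordering; all
#' pairs available as an option). The selected count is the smallest
#' candidate whose overlap is within `tol` of the minimum over candidates,
#' honouring "the minimal number of genes for which the overlap is minimal"
#' without chasing noise.
#'
#' @param expr genes x cells scaled expression.
#' @param labels ordered timepoint categories.
#' @param candidates ascending candidate gene counts.
#' @param lambda ridge penalty.
#' @param seed integer seed.
#' @param n_folds folds (default 5).
#' @param tol relative tolerance above the minimum (default 0.05).
#' @param pairing `"consecutive"` or `"all"` timepoint pairs.
#' @return an `overlap_curve`: data.frame `n_genes`/`overlap`, plus
#'   `selected`.
#' @export
select_gene_count <- function(expr, labels, candidates, lambda = 1, seed = 0,
                              n_folds = 5, tol = 0.05,
                              pairing = c("consecutive", "all")) {
  pairing <- match.arg(pairing)
  v <- .values(expr)
  .assert(all(diff(candidates) > 0), "candidates must be sorted ascending")
  .assert(max(candidates) <= nrow(v), "candidate exceeds the gene universe")
  curves <- vapply(candidates, function(nc) {
    cv <- cross_validate(v, labels, n_folds = n_folds, lambda = lambda,
                         seed = seed, n_genes = nc)
    .mean_overlap(cv$scores, cv$labels, pairing)
  }, numeric(1))
  sel <- candidates[which(curves <= (1 + tol) * min(curves))[1]]
  structure(list(curve = data.frame(n_genes = candidates, overlap = curves),
                 selected = sel, pairing = pairing),
            class = "overlap_curve")
}

#' @export
print.ordinal_model <- function(x, ...) {
  cat(sprintf("ordinal_model: %d genes, %d cutpoints, lambda %.3g\n",
              length(x$genes), length(x$theta), x$lambda))
  invisible(x)
}

#' @export
print.overlap_curve <- function(x, ...) {
  print(x$curve)
  cat(sprintf("selected gene count: %d (%s pairs)\n", x$selected, x$pairing))
  invisible(x)
}
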