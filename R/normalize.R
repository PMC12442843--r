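#' Library-size log-normalization
#'
#' Divides each cell's counts by its total, multiplies by `scale_total`
#' (default 1e4) and applies `log1p`. All-zero cells are returned as zeros.
#'
#' @param counts genes x cells count matrix.
#' @param scale_total per-cell target total before the log transform.
#' @return a `scaled_matrix` (method `"lognormalize"`) whose `values` are a
#'   sparse genes x cells matrix.
#' @export
lognormalize <- function(counts, scale_total = 1e4) {
  counts <- .values(counts)
  .assert(scale_total > 0, "scale_total must be > 0")
  cs <- Matrix::colSums(counts)
  sf <- ifelse(cs > 0, cs, 1)
  v <- .as_dgc(counts)
  v@x <- log1p(v@x * rep.int(scale_total / sf, diff(v@p)))
  structure(list(values = v,
                 meta = list(method = "lognormalize",
                             scale_total = scale_total, size_factors = cs)),
            class = "scaled_matrix")
}

#' Gene-wise z-scaling with clipping
#'
#' Centers and scales every gene across cells (population standard
#' deviation is not used; the sample SD is, matching common single-cell
#' practice of zero-variance genes mapping to 0), then clips to `±clip`.
#' When `stats` is supplied (a previous `scaled_matrix`'s scaling metadata),
#' its per-gene centers and scales are reused, which is how query datasets
#' are placed on the reference scale before identity scoring.
#'
#' @param lognorm a `scaled_matrix` from [lognormalize()] (or a plain
#'   genes x cells matrix of log-normalized values).
#' @param clip symmetric clip bound (default 10).
#' @param stats optional list with `center` and `scale` vectors named by
#'   gene, as found in the `meta` of a previous [scale_expression()] result.
#' @return a `scaled_matrix` (method `"zscore"`) with dense `values`; its
#'   `meta` records `clip`, `center` and `scale`.
#' @export
scale_expression <- function(lognorm, clip = 10, stats = NULL) {
  .assert(clip > 0, "clip must be > 0")
  v <- as.matrix(.values(lognorm))
  if (is.null(stats)) {
    center <- rowMeans(v)
    scl <- matrixStats::rowSds(v)
  } else {
    .assert(all(rownames(v) %in% names(stats$center)),
            "stats must cover every gene in the matrix")
    center <- stats$center[rownames(v)]
    scl <- stats$scale[rownames(v)]
  }
  names(center) <- names(scl) <- rownames(v)
  scl0 <- ifelse(scl > 0, scl, 1)
  z <- (v - center) / scl0
  z[] <- pmin(pmax(z, -clip), clip)
  structure(list(values = z,
                 meta = list(method = "zscore", clip = clip,
                             center = center, scale = scl)),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("scaled_matrix (%s): %d genes x %d cells\n",
              x$meta$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.scaled_matrix <- function(x) dim(x$values)
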