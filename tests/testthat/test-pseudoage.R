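test_that("a single monotone gene is perfectly ordered by the model", {
  set.seed(41)
  y <- factor(rep(paste0("T", 1:4), each = 15), levels = paste0("T", 1:4),
              ordered = TRUE)
  expr <- matrix(as.numeric(rep(1:4, each = 15)) * 2 +
                   rnorm(60, sd = 0.05), 1, 60,
                 dimnames = list("ramp", paste0("c", 1:60)))
  m <- train_ordinal(expr, y, lambda = 0.1)
  expect_gt(m$w["ramp"], 0)
  expect_true(all(diff(m$theta) >= 0))
  cv <- cross_validate(expr, y, n_folds = 5, lambda = 0.1, seed = 1)
  # zero ranking violations out of fold
  ranks <- split(cv$scores, y)
  expect_lt(max(ranks$T1), min(ranks$T2))
  expect_lt(max(ranks$T2), min(ranks$T3))
  expect_lt(max(ranks$T3), min(ranks$T4))
})

test_that("permuted labels leave consecutive-timepoint distributions overlapping", {
  d <- simulate_ramp(n_cells_per_timepoint = 60, n_genes = 40, n_signal = 5,
                     effect = 1, seed = 42)
  set.seed(43)
  y <- d$timepoint[sample(length(d$timepoint))]
  cv <- cross_validate(d$expr, y, lambda = 1, seed = 2)
  ovl <- mean(vapply(1:3, function(t)
    overlap_coefficient(cv$scores[y == paste0("T", t)],
                        cv$scores[y == paste0("T", t + 1)]), numeric(1)))
  expect_gt(ovl, 0.8)
})

test_that("heavy regularization shrinks weights and flattens scores", {
  d <- simulate_ramp(n_cells_per_timepoint = 20, n_genes = 30, n_signal = 5,
                     effect = 1, seed = 44)
  m <- train_ordinal(d$expr, d$timepoint, lambda = 1e7)
  expect_lt(max(abs(m$w)), 1e-3)
  s <- predict_pseudoage(m, d$expr)
  expect_lt(stats::sd(s), 0.05)
  expect_error(train_ordinal(d$expr, rep("T1", ncol(d$expr))),
               "two ordered categories")
  expect_error(train_ordinal(d$expr, d$timepoint, lambda = 0), "lambda")
})

test_that("cross-validation is stratified, reproducible, and supports leave-one-out", {
  d <- simulate_ramp(n_cells_per_timepoint = 10, n_genes = 10, n_signal = 3,
                     effect = 1.5, n_timepoints = 5, seed = 45)
  cv1 <- cross_validate(d$expr, d$timepoint, n_folds = 5, seed = 7)
  cv2 <- cross_validate(d$expr, d$timepoint, n_folds = 5, seed = 7)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$scores, cv2$scores)
  # stratification: every fold holds cells from every timepoint
  tab <- table(cv1$folds, d$timepoint)
  expect_true(all(tab == 2))
  # leave-one-out on a 50-cell fixture runs to completion
  cvl <- cross_validate(d$expr, d$timepoint, n_folds = 50, seed = 7)
  expect_length(cvl$scores, 50)
  expect_true(all(is.finite(cvl$scores)))
})

test_that("overlap coefficient matches its analytic anchors", {
  set.seed(46)
  a <- rnorm(500)
  expect_gte(overlap_coefficient(a, a), 0.99)
  expect_lte(overlap_coefficient(rnorm(500), rnorm(500, 100)), 0.01)
  x <- rnorm(2000); y <- rnorm(2000, 1)
  # closed form for unit-variance normals one SD apart: 2*pnorm(-1/2)
  expect_equal(overlap_coefficient(x, y), 2 * pnorm(-0.5), tolerance = 0.05)
  expect_equal(overlap_coefficient(x, y), overlap_coefficient(y, x),
               tolerance = 1e-6)
  # constant samples fall back to point-mass comparison
  expect_equal(overlap_coefficient(rep(1, 5), rep(1, 5)), 1)
  expect_equal(overlap_coefficient(rep(1, 5), rep(2, 5)), 0)
  expect_error(overlap_coefficient(1, 1:5), "at least 2")
})

test_that("gene-count selection prefers the smallest adequate candidate", {
  # all genes identical copies of one signal: every candidate performs the
  # same, so the tie rule must pick the smallest
  set.seed(47)
  sig <- rep(1:4, each = 20) + rnorm(80, sd = 0.3)
  expr <- matrix(rep(sig, each = 6), 6, 80,
                 dimnames = list(paste0("g", 1:6), paste0("c", 1:80)))
  y <- factor(rep(paste0("T", 1:4), each = 20), ordered = TRUE)
  sel <- select_gene_count(expr, y, candidates = c(1, 2, 4), seed = 3)
  expect_equal(sel$selected, 1)
  sel2 <- select_gene_count(expr, y, candidates = c(1, 2, 4), seed = 3)
  expect_identical(sel$curve, sel2$curve)
  expect_error(select_gene_count(expr, y, candidates = c(2, 50), seed = 3),
               "exceeds the gene universe")
  expect_error(select_gene_count(expr, y, candidates = c(4, 2), seed = 3),
               "ascending")
})

test_that("stronger temporal separation never increases mean consecutive overlap", {
  ovl <- vapply(c(0.5, 1, 2), function(eff) {
    d <- simulate_ramp(n_cells_per_timepoint = 25, n_genes = 30, n_signal = 5,
                       effect = eff, seed = 48)
    cv <- cross_validate(d$expr, d$timepoint, lambda = 1, seed = 4)
    mean(vapply(1:3, function(t)
      overlap_coefficient(cv$scores[d$timepoint == paste0("T", t)],
                          cv$scores[d$timepoint == paste0("T", t + 1)]),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ovl) <= 0.02))
})

test_that("prediction renormalizes for missing genes and flags delayed queries", {
  d <- simulate_ramp(n_cells_per_timepoint = 25, n_genes = 20, n_signal = 5,
                     effect = 1, seed = 49)
  m <- train_ordinal(d$expr, d$timepoint, lambda = 1)
  # a query identical to training data scores w.x
  expect_equal(predict_pseudoage(m, d$expr),
               drop(crossprod(d$expr, m$w)), ignore_attr = TRUE)
  # all-zero expression scores 0
  z <- matrix(0, 20, 3, dimnames = list(rownames(d$expr), paste0("q", 1:3)))
  expect_equal(unname(predict_pseudoage(m, z)), c(0, 0, 0))
  # dropping half the genes renormalizes by the available fraction
  half <- rownames(d$expr)[1:10]
  expect_warning(ph <- predict_pseudoage(m, d$expr[half, ]), "renormalized")
  expect_equal(unname(ph),
               unname(drop(crossprod(d$expr[half, ], m$w[half])) * 2))
  expect_error(predict_pseudoage(m, z[c(), , drop = FALSE]), "no model genes")
  # a "delayed" query (drawn at an earlier timepoint's profile) scores below
  # the final-timepoint cells
  delayed <- simulate_ramp(n_cells_per_timepoint = 200, n_genes = 20,
                           n_signal = 5, effect = 1, n_timepoints = 2,
                           seed = 50)
  q <- delayed$expr[, delayed$timepoint == "T2"]  # matches training T2
  sq <- predict_pseudoage(m, q)
  s4 <- predict_pseudoage(m, d$expr[, d$timepoint == "T4"])
  expect_lt(stats::wilcox.test(sq, s4, alternative = "less")$p.value, 0.01)
})
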