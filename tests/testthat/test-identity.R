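test_that("marker selection retains clean markers and honours thresholds", {
  # gene m1: high in population A only; gene flat: identical everywhere;
  # gene weak: fold change below 0.6 but large pct difference
  n <- 60
  labels <- rep(c("A", "B"), each = n)
  ln <- matrix(0, 4, 2 * n,
               dimnames = list(c("m1", "flat", "weak", "noise"),
                               paste0("c", seq_len(2 * n))))
  ln["m1", labels == "A"] <- 2
  ln["flat", ] <- 1.5
  # de-logged mean in A chosen so log2((mA+1)/(0+1)) ~ 0.45 < 0.6
  ln["weak", labels == "A"] <- log1p(0.37)
  set.seed(9)
  ln["noise", ] <- abs(rnorm(2 * n, 1, 0.1))
  mk <- find_level_markers(ln, labels, level = "type")
  a <- mk[mk$population == "A", ]
  expect_true("m1" %in% a$gene)
  expect_false("flat" %in% mk$gene)
  expect_false("weak" %in% mk$gene)
  expect_true(all(a$log2fc >= 0.6))
  expect_true(all(a$pct_in - a$pct_out >= 0.1))
  expect_true(all(a$p_adj < 0.05))
  # populations below the cell minimum are skipped with a warning
  labs2 <- c(rep("A", 2), rep("B", 2 * n - 2))
  expect_warning(find_level_markers(ln, labs2), "fewer than 3 cells")
  expect_error(find_level_markers(ln, rep("A", 2 * n)), "two populations")
})

test_that("planted simulator markers are recovered at every level", {
  ref <- ref_dataset()
  gs <- ref_gene_sets()
  ann <- ref$gene_annotations
  for (lvl in c("class", "subclass", "type")) {
    for (pop in names(gs[[lvl]])) {
      planted <- ann$gene[!is.na(ann$population) & ann$population == pop]
      expect_gte(mean(planted %in% gs[[lvl]][[pop]]), 0.9)
    }
  }
  # union sizes deduplicate genes shared between populations
  expect_true(all(attr(gs, "union_sizes") >= 2 * 20))
})

test_that("identity scores are means of scaled expression, order-invariant", {
  z <- matrix(c(1, 3, -2, 0.5, 2, 1), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  s <- compute_identity_scores(z, list(P = c("g1", "g2")))
  expect_equal(as.numeric(s[, "P"]), c(2, 1.25))
  s_rev <- compute_identity_scores(z, list(P = c("g2", "g1")))
  expect_equal(s, s_rev)
  one <- compute_identity_scores(z, list(P = "g3"))
  expect_equal(as.numeric(one[, "P"]), as.numeric(z["g3", ]))
  expect_equal(as.numeric(compute_identity_scores(z * 0, list(P = c("g1", "g2")))),
               c(0, 0))
  expect_warning(compute_identity_scores(z, list(P = c("g1", "missing"))),
                 "absent from matrix")
  expect_error(suppressWarnings(compute_identity_scores(z, list(P = "missing"))))
})

test_that("identity embedding is deterministic and respects blob geometry", {
  set.seed(4)
  scores <- rbind(matrix(rnorm(40 * 3), 40, 3),
                  matrix(rnorm(40 * 3, mean = 8), 40, 3))
  rownames(scores) <- paste0("r", 1:80)
  colnames(scores) <- paste0("P", 1:3)
  emb <- fit_identity_embedding(scores, seed = 1)
  emb2 <- fit_identity_embedding(scores, seed = 1)
  expect_identical(emb$coords, emb2$coords)
  blob <- rep(1:2, each = 40)
  sil <- cluster::silhouette(blob, stats::dist(emb$coords))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # a duplicated reference cell lands at (nearly) the same spot
  dup <- rbind(scores, scores[1, , drop = FALSE])
  rownames(dup) <- c(rownames(scores), "dup")
  e3 <- fit_identity_embedding(dup, seed = 1)
  scale <- max(dist(e3$coords[c(1, 41), ]))
  expect_lt(sqrt(sum((e3$coords["dup", ] - e3$coords[1, ])^2)), 0.05 * scale)
  expect_error(fit_identity_embedding(scores[1:5, ]), "at least 10")
  scores[1, 1] <- NA
  expect_error(fit_identity_embedding(scores), "non-finite")
})

test_that("query projection lands near matching reference cells", {
  set.seed(5)
  scores <- rbind(matrix(rnorm(40 * 3, sd = 0.5), 40, 3),
                  matrix(rnorm(40 * 3, mean = 8, sd = 0.5), 40, 3))
  rownames(scores) <- paste0("r", 1:80)
  colnames(scores) <- paste0("P", 1:3)
  emb <- fit_identity_embedding(scores, seed = 1)
  # queries identical to reference cells project onto them
  q <- scores[c(3, 55), , drop = FALSE]
  rownames(q) <- c("q1", "q2")
  xy <- project_query(emb, q)
  spread <- max(dist(emb$coords))
  expect_lt(sqrt(sum((xy["q1", ] - emb$coords[3, ])^2)), 0.05 * spread)
  expect_lt(sqrt(sum((xy["q2", ] - emb$coords[55, ])^2)), 0.05 * spread)
  # empty query gives an empty result
  expect_equal(nrow(project_query(emb, scores[0, , drop = FALSE])), 0)
  # column mismatch is an error
  qbad <- q
  colnames(qbad) <- c("P1", "P2", "X")
  expect_error(project_query(emb, qbad), "columns must match")
})

test_that("consensus assignment follows the 9-of-10 rule on constructed fixtures", {
  # 10 nearest neighbours at radius 1..10 with controlled labels, plus a
  # distant cloud of other labels
  make_ref <- function(labels10) {
    angles <- seq(0, 2 * pi, length.out = 11)[1:10]
    near <- cbind(cos(angles) * (1 + 0.01 * (1:10)),
                  sin(angles) * (1 + 0.01 * (1:10)))
    far <- cbind(50 + runif(30), 50 + runif(30))
    coords <- rbind(near, far)
    rownames(coords) <- paste0("r", 1:40)
    list(coords = coords, labels = c(labels10, rep("C", 30)))
  }
  q <- matrix(c(0, 0), 1, 2, dimnames = list("q", NULL))
  set.seed(11)
  unan <- make_ref(rep("A", 10))
  expect_equal(assign_identity(unan$coords, unan$labels, q)$label, "A")
  nine <- make_ref(c(rep("A", 9), "B"))
  a9 <- assign_identity(nine$coords, nine$labels, q)
  expect_equal(a9$label, "A")
  expect_equal(a9$label_votes, 9L)
  eight <- make_ref(c(rep("A", 8), "B", "B"))
  expect_equal(assign_identity(eight$coords, eight$labels, q)$label,
               "undefined")
  expect_error(assign_identity(unan$coords[1:5, ], unan$labels[1:5], q),
               "k exceeds")
  expect_error(assign_identity(unan$coords, unan$labels, q, k = 10,
                               consensus = 11), "consensus")
})

test_that("assignment matches the brute-force oracle on random fixtures", {
  set.seed(21)
  for (rep_i in 1:60) {
    n_ref <- sample(15:40, 1)
    ref_coords <- matrix(runif(n_ref * 2, 0, 10), n_ref, 2)
    labels <- sample(c("A", "B", "C"), n_ref, TRUE)
    q <- matrix(runif(10, 0, 10), 5, 2)
    got <- assign_identity(ref_coords, labels, q, k = 10, consensus = 9)
    want <- oracle_assign(ref_coords, labels, q, k = 10, consensus = 9)
    expect_identical(got$label, want)
  }
})

test_that("levels are assigned independently", {
  set.seed(22)
  ref_coords <- matrix(runif(60), 30, 2)
  labs <- data.frame(class = sample(c("X", "Y"), 30, TRUE),
                     type = sample(paste0("t", 1:4), 30, TRUE))
  q <- matrix(runif(12), 6, 2)
  a <- assign_identity(ref_coords, labs, q)
  labs2 <- labs
  labs2$type <- sample(labs$type)
  a2 <- assign_identity(ref_coords, labs2, q)
  expect_identical(a$class, a2$class)
  expect_identical(a$class_votes, a2$class_votes)
})

test_that("population proportions include undefined and sum to one", {
  asg <- data.frame(cell_id = as.character(1:100),
                    type = c(rep("L4_IT", 50), rep("undefined", 50)))
  pr <- population_proportions(asg)
  expect_equal(sort(pr$proportion), c(0.5, 0.5))
  expect_true("undefined" %in% pr$population)
  # grouped proportions each sum to 1 within 1e-12
  grp <- rep(c("g1", "g2"), 50)
  pr2 <- population_proportions(asg, grouping = grp)
  sums <- tapply(pr2$proportion, pr2$group, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  one <- population_proportions(data.frame(cell_id = "c", type = "A"))
  expect_equal(one$proportion, 1)
})

test_that("matured reference queries recover their true class via the embedding", {
  ref <- ref_dataset()
  gs <- ref_gene_sets()
  truth <- ref$truth
  query <- apply_condition(ref, "reference")
  # an independent count draw of the same cells, classified against the
  # reference through the full embedding path
  query_counts <- generate_reference(sim_config(seed = 0), seed = 123)$counts
  res <- classify_cells(ref$counts, truth[, c("class", "subclass", "type")],
                        gs, query_counts, space = "embedding", seed = 0)
  acc <- mean(res$assignment$class == truth$class)
  expect_gte(acc, 0.95)
})
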