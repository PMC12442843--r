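test_that("generated reference has exact nested bookkeeping", {
  ref <- ref_dataset()
  expect_equal(ncol(ref$counts), 8 * 50)  # 2 classes x 2 subs x 2 types
  expect_equal(nrow(ref$counts), 14 * 20 + 200 + 10)
  # each type carries exactly one subclass and one class, per the tree
  per_type <- split(ref$truth, ref$truth$type)
  for (tt in per_type) {
    expect_length(unique(tt$subclass), 1)
    expect_length(unique(tt$class), 1)
    expect_equal(nrow(tt), 50)
  }
  tr <- ref$tree
  expect_equal(tr$sub_parent[match(unique(ref$truth$subclass),
                                   tr$subclasses)],
               unname(vapply(split(ref$truth$class, ref$truth$subclass)[
                 unique(ref$truth$subclass)], function(x) x[1], "")))
  # every marker gene belongs to exactly one (level, population) program
  ann <- ref$gene_annotations
  expect_false(anyDuplicated(ann$gene) > 0)
  expect_true(all(table(ann$gene[!is.na(ann$population)]) == 1))
})

test_that("same config and seed reproduce bitwise-identical counts", {
  cfg <- sim_config(cells_per_type = 10)
  a <- generate_reference(cfg)
  b <- generate_reference(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth, b$truth)
})

test_that("zero marker effect leaves markers indistinguishable from background", {
  cfg <- sim_config(marker_log2_effect = 0, cells_per_type = 40, seed = 3)
  d <- generate_reference(cfg)
  ann <- d$gene_annotations
  # expected means: marker fold is exactly 1 everywhere
  for (lvl in c("class", "type")) {
    g <- which(!is.na(ann$level) & ann$level == lvl)[1:10]
    for (gi in g) {
      own <- d$truth[[lvl]] == ann$population[gi]
      ratio <- mean(d$means[gi, own]) / mean(d$means[gi, !own])
      expect_equal(ratio, 1, tolerance = 0.05)
    }
  }
})

test_that("marker elevation is monotone in the configured effect", {
  ratios <- vapply(c(0, 1, 2, 3), function(e) {
    d <- generate_reference(sim_config(marker_log2_effect = e,
                                       cells_per_type = 30, seed = 5))
    ann <- d$gene_annotations
    g <- which(!is.na(ann$level) & ann$level == "type")
    own_mean <- out_mean <- 0
    for (gi in g[1:20]) {
      own <- d$truth$type == ann$population[gi]
      own_mean <- own_mean + mean(d$counts[gi, own])
      out_mean <- out_mean + mean(d$counts[gi, !own])
    }
    own_mean / out_mean
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_equal(ratios[1], 1, tolerance = 0.15)
})

test_that("maturation ramps saturate at the final timepoint and start at background", {
  cfg <- sim_config(cells_per_type = 48)
  ref <- generate_reference(cfg)
  dev <- apply_maturation(ref)
  last <- dev$truth$timepoint == "P14"
  expect_equal(dev$means[, last], ref$means[, last])
  # first timepoint: type ramp is 0, so a type marker's expression rate in
  # its own type equals the rate in the sibling type of the same subclass
  first <- which(dev$truth$timepoint == "E17")
  ann <- dev$gene_annotations
  rate <- sweep(dev$means, 2, dev$truth$libsize, "/")
  tg <- which(!is.na(ann$level) & ann$level == "type")
  for (gi in tg[seq(1, length(tg), by = 23)]) {
    pop <- ann$population[gi]
    sub <- dev$tree$type_parent[match(pop, dev$tree$types)]
    own <- intersect(first, which(dev$truth$type == pop))
    sib <- intersect(first, which(dev$truth$subclass == sub &
                                    dev$truth$type != pop))
    expect_equal(mean(rate[gi, own]), mean(rate[gi, sib]), tolerance = 1e-10)
  }
})

test_that("mid-schedule empirical marker ratios match the configured ramp", {
  cfg <- sim_config(cells_per_type = 63)  # ~500 cells
  dev <- apply_maturation(generate_reference(cfg))
  # class ramp at P1 (index 2): r = 1 under schedule c(0, 2) -> fold 4;
  # subclass ramp at P1: r = 0.5 under c(1, 3) -> fold 2.5
  p1 <- dev$truth$timepoint == "P1"
  ann <- dev$gene_annotations
  for (case in list(list(level = "class", fold = 4),
                    list(level = "subclass", fold = 2.5))) {
    g <- which(!is.na(ann$level) & ann$level == case$level)
    own_tot <- out_tot <- 0
    for (gi in g) {
      own <- p1 & dev$truth[[case$level]] == ann$population[gi]
      out <- p1 & dev$truth[[case$level]] != ann$population[gi]
      own_tot <- own_tot + mean(dev$counts[gi, own])
      out_tot <- out_tot + mean(dev$counts[gi, out])
    }
    expect_equal(own_tot / out_tot, case$fold, tolerance = 0.15)
  }
})

test_that("condition attenuation scales designated type-marker means exactly", {
  cfg <- sim_config()
  ref <- generate_reference(cfg)
  d2 <- apply_condition(ref, "2D")
  ann <- d2$gene_annotations
  att <- which(ann$attenuated)
  expect_length(att, 4 * 20)  # 4 glutamatergic types x 20 markers
  for (gi in att[seq(1, length(att), by = 13)]) {
    own <- d2$truth$type == ann$population[gi]
    expect_equal(d2$means[gi, own] / ref$means[gi, own],
                 rep(0.3, sum(own)), ignore_attr = TRUE)
    expect_equal(d2$means[gi, !own], ref$means[gi, !own])
  }
  # alpha = 1 leaves the dataset unchanged
  cfg1 <- sim_config(condition_effects = list(
    "2D" = list(alpha = 1, rho = 0),
    "organotypic" = list(alpha = 0.3, rho = 0.4)))
  r1 <- generate_reference(cfg1)
  u <- apply_condition(r1, "2D")
  expect_identical(as.matrix(u$counts), as.matrix(r1$counts))
})

test_that("restored fraction is drawn exactly and recorded in truth", {
  ref <- ref_dataset()
  org <- apply_condition(ref, "organotypic")
  ann <- org$gene_annotations
  expect_equal(sum(ann$restored), round(0.4 * 80))
  expect_equal(sum(ann$attenuated), 80 - round(0.4 * 80))
  # restored genes keep reference means
  res <- which(ann$restored)
  expect_equal(org$means[res, ], ref$means[res, ])
  # the draw is reproducible
  org2 <- apply_condition(ref, "organotypic")
  expect_identical(ann$restored, org2$gene_annotations$restored)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(n_classes = 2, subclasses_per_class = c(2, 2, 2)),
               "one entry per class")
  expect_error(sim_config(types_per_subclass = c(2, 2)),
               "one entry per subclass")
  expect_error(sim_config(mito_fraction_mean = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(condition_effects = list(x = list(alpha = 2, rho = 0))),
               "alpha")
  ref <- ref_dataset()
  expect_error(apply_condition(ref, "no-such-condition"), "unknown condition")
  bad <- ref
  bad$truth$timepoint[1] <- "P99"
  expect_error(apply_maturation(bad), "timepoint")
})

test_that("ramp fixture carries the planted temporal signal", {
  d <- simulate_ramp(n_cells_per_timepoint = 20, n_genes = 50, n_signal = 5,
                     effect = 1, seed = 2)
  expect_equal(dim(d$expr), c(50, 80))
  sig_means <- vapply(levels(d$timepoint), function(tp)
    mean(d$expr[d$signal_genes, d$timepoint == tp]), numeric(1))
  expect_true(all(diff(sig_means) > 0.5))
  noise <- setdiff(rownames(d$expr), d$signal_genes)
  expect_lt(abs(mean(d$expr[noise, ])), 0.1)
  expect_identical(d$expr, simulate_ramp(20, 50, 5, 1, seed = 2)$expr)
})
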