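#' Configuration for the hierarchical count simulator
#'
#' Defines a nested class/subclass/type taxonomy of cell populations, a
#' negative-binomial count model with per-population marker-gene programs, a
#' maturation ramp over ordered timepoints, and culture-condition effects
#' (attenuation of glutamatergic type-marker programs, with partial
#' restoration). The defaults describe a desk-scale analogue of a developing
#' cortical dataset: two classes (glutamatergic / GABAergic analogues), four
#' subclasses, eight types, 50 cells per type, and snRNA-seq-like sparsity
#' (library sizes around 800 UMI over ~500 genes, so percent-expressing
#' statistics are informative).
#'
#' @param n_classes number of top-level classes.
#' @param subclasses_per_class integer vector, one entry per class.
#' @param types_per_subclass integer vector, one entry per subclass (in the
#'   order subclasses are generated, class by class).
#' @param cells_per_type cells simulated for every terminal type.
#' @param n_marker_genes_per_population marker genes exclusive to each
#'   population program (every class, subclass and type gets its own block).
#' @param n_background_genes genes with no program membership.
#' @param n_mito_genes mitochondrial genes, named with prefix `"mt-"`.
#' @param marker_log2_effect log2 fold elevation of a marker gene's mean in
#'   its own population (and all descendant populations for class/subclass
#'   programs).
#' @param dispersion negative-binomial overdispersion; the NB size parameter
#'   is `1/dispersion`.
#' @param libsize_logmean,libsize_logsd log-normal library-size parameters.
#' @param mito_fraction_mean expected mitochondrial fraction of each cell's
#'   library, in \[0, 1\].
#' @param timepoints ordered character vector of timepoint labels.
#' @param ramp_schedule named list with entries `class`, `subclass`, `type`,
#'   each `c(onset, full)` on the timepoint-index scale: the maturation ramp
#'   of that level rises linearly from 0 at `onset` to 1 at `full`. The class
#'   ramp must reach 1 no later than the subclass ramp, and subclass no later
#'   than type.
#' @param condition_effects named list of conditions; each entry is
#'   `list(alpha = , rho = )` with attenuation factor `alpha` in \[0, 1\]
#'   applied to designated type-marker programs and restored fraction `rho`
#'   in \[0, 1\].
#' @param affected_class class whose type-marker programs are attenuated by
#'   condition effects (index or name; default the first class).
#' @param seed integer root seed; base gene abundances and the restored-gene
#'   draw depend only on this seed, so all conditions share one gene universe.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_classes = 2,
                       subclasses_per_class = rep(2L, n_classes),
                       types_per_subclass = rep(2L, sum(subclasses_per_class)),
                       cells_per_type = 50,
                       n_marker_genes_per_population = 20,
                       n_background_genes = 200,
                       n_mito_genes = 10,
                       marker_log2_effect = 2,
                       dispersion = 0.5,
                       libsize_logmean = log(800),
                       libsize_logsd = 0.25,
                       mito_fraction_mean = 0.01,
                       timepoints = c("E17", "P1", "P7", "P14"),
                       ramp_schedule = list(class = c(0, 2),
                                            subclass = c(1, 3),
                                            type = c(2, 4)),
                       condition_effects = list(
                         "2D" = list(alpha = 0.3, rho = 0),
                         "organotypic" = list(alpha = 0.3, rho = 0.4)),
                       affected_class = 1,
                       seed = 0) {
  .assert(n_classes >= 1, "n_classes must be >= 1")
  .assert(length(subclasses_per_class) == n_classes,
          "subclasses_per_class must have one entry per class")
  .assert(length(types_per_subclass) == sum(subclasses_per_class),
          "types_per_subclass must have one entry per subclass")
  .assert(all(c(subclasses_per_class, types_per_subclass, cells_per_type,
                n_marker_genes_per_population, n_background_genes,
                n_mito_genes) >= 1), "all structure counts must be >= 1")
  .assert(dispersion > 0, "dispersion must be > 0")
  .assert(mito_fraction_mean >= 0 && mito_fraction_mean <= 1,
          "mito_fraction_mean must lie in [0, 1]")
  .assert(!anyDuplicated(timepoints) && length(timepoints) >= 1,
          "timepoints must be distinct labels in increasing order")
  for (ce in condition_effects) {
    .assert(ce$alpha >= 0 && ce$alpha <= 1, "alpha must lie in [0, 1]")
    .assert(ce$rho >= 0 && ce$rho <= 1, "rho must lie in [0, 1]")
  }
  for (l in c("class", "subclass", "type"))
    .assert(!is.null(ramp_schedule[[l]]) && length(ramp_schedule[[l]]) == 2,
            "ramp_schedule needs c(onset, full) for class, subclass and type")
  .assert(ramp_schedule$class[2] <= ramp_schedule$subclass[2] &&
          ramp_schedule$subclass[2] <= ramp_schedule$type[2],
          "class ramp must saturate no later than subclass, subclass no later than type")
  cfg <- list(n_classes = n_classes,
              subclasses_per_class = as.integer(subclasses_per_class),
              types_per_subclass = as.integer(types_per_subclass),
              cells_per_type = as.integer(cells_per_type),
              n_marker_genes_per_population = as.integer(n_marker_genes_per_population),
              n_background_genes = as.integer(n_background_genes),
              n_mito_genes = as.integer(n_mito_genes),
              marker_log2_effect = marker_log2_effect,
              dispersion = dispersion,
              libsize_logmean = libsize_logmean,
              libsize_logsd = libsize_logsd,
              mito_fraction_mean = mito_fraction_mean,
              timepoints = as.character(timepoints),
              ramp_schedule = ramp_schedule,
              condition_effects = condition_effects,
              affected_class = affected_class,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# population taxonomy implied by a sim_config
.sim_tree <- function(config) {
  class_names <- c("glut", "gaba", "astro", "olig")
  classes <- if (config$n_classes <= 4) class_names[seq_len(config$n_classes)]
             else paste0("class", seq_len(config$n_classes))
  subs <- unlist(lapply(seq_len(config$n_classes), function(i)
    paste0(classes[i], ".s", seq_len(config$subclasses_per_class[i]))))
  sub_parent <- rep(classes, config$subclasses_per_class)
  types <- unlist(lapply(seq_along(subs), function(j)
    paste0(subs[j], ".t", seq_len(config$types_per_subclass[j]))))
  type_parent <- rep(subs, config$types_per_subclass)
  aff <- if (is.numeric(config$affected_class)) classes[config$affected_class]
         else config$affected_class
  .assert(aff %in% classes, "affected_class not in configured classes")
  list(classes = classes, subclasses = subs, sub_parent = sub_parent,
       types = types, type_parent = type_parent, affected_class = aff)
}

# gene universe + base abundances, drawn from config$seed only so every
# condition and timepoint shares the same genes
.sim_genes <- function(config, tree) {
  pops <- c(tree$classes, tree$subclasses, tree$types)
  lev <- c(rep("class", length(tree$classes)),
           rep("subclass", length(tree$subclasses)),
           rep("type", length(tree$types)))
  nm <- config$n_marker_genes_per_population
  marker_genes <- unlist(lapply(pops, function(p) paste0(p, ".g", seq_len(nm))))
  genes <- c(marker_genes,
             paste0("bg.g", seq_len(config$n_background_genes)),
             paste0("mt-", seq_len(config$n_mito_genes)))
  ann <- data.frame(
    gene = genes,
    level = c(rep(lev, each = nm),
              rep(NA_character_, config$n_background_genes + config$n_mito_genes)),
    population = c(rep(pops, each = nm),
                   rep(NA_character_, config$n_background_genes + config$n_mito_genes)),
    is_mito = c(rep(FALSE, length(marker_genes) + config$n_background_genes),
                rep(TRUE, config$n_mito_genes)),
    stringsAsFactors = FALSE)
  base <- .with_seed(.derive_seed(config$seed, "base_rates"),
                     exp(stats::rnorm(length(genes), 0, 0.5)))
  names(base) <- genes
  list(annotations = ann, base = base)
}

# maturation ramp value r(level, timepoint index) in [0, 1]
.sim_ramp <- function(config, level, t_index) {
  sc <- config$ramp_schedule[[level]]
  pmin(1, pmax(0, (t_index - sc[1]) / (sc[2] - sc[1])))
}

# restored-gene draw: a fixed function of (config$seed, condition, rho)
.sim_restored <- function(config, tree, ann, condition) {
  eff <- config$condition_effects[[condition]]
  att <- which(!is.na(ann$level) & ann$level == "type" &
               ann$population %in% tree$types[
                 tree$type_parent %in% tree$subclasses[
                   tree$sub_parent == tree$affected_class]])
  restored <- integer(0)
  if (eff$rho > 0 && length(att) > 0) {
    n_res <- round(eff$rho * length(att))
    restored <- .with_seed(.derive_seed(config$seed, paste0("restored_", condition)),
                           sort(sample(att, n_res)))
  }
  list(attenuated = att, restored = restored)
}

# expected count matrix (genes x cells) for a given truth table and condition
.sim_means <- function(config, tree, genes, truth, mature = TRUE,
                       condition = "reference") {
  ann <- genes$annotations
  n_genes <- nrow(ann)
  n_cells <- nrow(truth)
  fold <- matrix(1, n_genes, n_cells)
  t_index <- match(truth$timepoint, config$timepoints)
  .assert(!anyNA(t_index), "unknown timepoint label in truth table")
  elev <- 2^config$marker_log2_effect - 1
  for (level in c("class", "subclass", "type")) {
    is_lvl <- !is.na(ann$level) & ann$level == level
    pops <- split(which(is_lvl), ann$population[is_lvl])
    cell_pop <- truth[[level]]
    r <- if (mature) rep(1, n_cells) else .sim_ramp(config, level, t_index)
    for (p in names(pops)) {
      cells <- which(cell_pop == p)
      if (!length(cells)) next
      fold[pops[[p]], cells] <- 1 + elev * rep(r[cells], each = length(pops[[p]]))
    }
  }
  base <- genes$base
  rates <- base * fold
  # mitochondrial block carries a fixed expected fraction of each library
  mito <- ann$is_mito
  if (any(mito) && config$mito_fraction_mean > 0) {
    f <- config$mito_fraction_mean
    w <- base[mito] / sum(base[mito])
    other <- colSums(rates[!mito, , drop = FALSE])
    rates[mito, ] <- outer(w, other * f / (1 - f))
  } else if (any(mito)) {
    rates[mito, ] <- 0
  }
  mu <- sweep(rates, 2, colSums(rates), "/")
  mu <- sweep(mu, 2, truth$libsize, "*")
  rownames(mu) <- ann$gene
  colnames(mu) <- truth$cell_id
  # condition attenuation acts on the expected counts directly: the lost
  # program expression shrinks the cell's library instead of being
  # redistributed, so the attenuated mean is exactly alpha x reference
  if (condition != "reference") {
    cond <- .sim_restored(config, tree, ann, condition)
    alpha <- config$condition_effects[[condition]]$alpha
    for (g in setdiff(cond$attenuated, cond$restored)) {
      cells <- which(truth$type == ann$population[g])
      if (length(cells)) mu[g, cells] <- mu[g, cells] * alpha
    }
  }
  mu
}

.sim_sample_counts <- function(mu, dispersion, seed) {
  cnt <- .with_seed(seed, matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion), nrow(mu)))
  dimnames(cnt) <- dimnames(mu)
  .as_dgc(cnt)
}

.sim_dataset <- function(counts, means, truth, gene_annotations, config,
                         tree, genes, mature, condition) {
  structure(list(counts = counts, means = means, truth = truth,
                 gene_annotations = gene_annotations, config = config,
                 tree = tree, genes = genes, mature = mature,
                 condition = condition),
            class = "sim_dataset")
}

#' Generate a mature hierarchical reference dataset
#'
#' Draws negative-binomial counts for `cells_per_type` cells of every terminal
#' type in the configured taxonomy, with every population's marker genes
#' elevated by `2^marker_log2_effect` in that population (class and subclass
#' programs are inherited by all descendant types). Cells are assigned
#' timepoints cycling through `config$timepoints` within each type, but the
#' reference is generated fully mature (all maturation ramps at 1);
#' [apply_maturation()] converts it into a developmental series.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for the count draw (library sizes and counts);
#'   the gene universe is governed by `config$seed`. Defaults to
#'   `config$seed`.
#' @return a `sim_dataset` with elements `counts` (sparse genes x cells),
#'   `means` (expected counts), `truth` (per-cell class/subclass/type,
#'   timepoint, condition), and `gene_annotations` (per-gene program
#'   membership, mitochondrial flag, attenuated/restored flags).
#' @export
generate_reference <- function(config, seed = config$seed) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  tree <- .sim_tree(config)
  genes <- .sim_genes(config, tree)
  n_types <- length(tree$types)
  truth <- data.frame(
    type = rep(tree$types, each = config$cells_per_type),
    stringsAsFactors = FALSE)
  truth$subclass <- tree$type_parent[match(truth$type, tree$types)]
  truth$class <- tree$sub_parent[match(truth$subclass, tree$subclasses)]
  truth$timepoint <- rep(rep(config$timepoints,
                             length.out = config$cells_per_type), n_types)
  truth$condition <- "reference"
  truth$cell_id <- sprintf("cell%04d", seq_len(nrow(truth)))
  truth$libsize <- .with_seed(.derive_seed(seed, "libsize"),
                              stats::rlnorm(nrow(truth), config$libsize_logmean,
                                            config$libsize_logsd))
  truth <- truth[, c("cell_id", "class", "subclass", "type", "timepoint",
                     "condition", "libsize")]
  mu <- .sim_means(config, tree, genes, truth, mature = TRUE)
  counts <- .sim_sample_counts(mu, config$dispersion,
                               .derive_seed(seed, "counts_reference"))
  ann <- genes$annotations
  ann$attenuated <- FALSE
  ann$restored <- FALSE
  .sim_dataset(counts, mu, truth, ann, config, tree, genes,
               mature = TRUE, condition = "reference")
}

#' Apply the maturation ramp to a simulated dataset
#'
#' Re-draws counts so that each marker program's elevation follows its level's
#' maturation ramp at the cell's timepoint: the fold change over background is
#' `1 + (2^marker_log2_effect - 1) * r(level, t)` with `r` nondecreasing in
#' `t`, class saturating no later than subclass and subclass no later than
#' type. At the final timepoint all ramps equal 1 and the data are
#' distributionally identical to [generate_reference()] output.
#'
#' @param dataset a `sim_dataset` with timepoint labels in `truth`.
#' @param config simulation configuration; defaults to the dataset's own.
#' @return a `sim_dataset` with ramped means and re-sampled counts.
#' @export
apply_maturation <- function(dataset, config = dataset$config) {
  .assert(inherits(dataset, "sim_dataset"), "dataset must be a sim_dataset")
  .assert(all(dataset$truth$timepoint %in% config$timepoints),
          "unknown timepoint label in dataset truth")
  mu <- .sim_means(config, dataset$tree, dataset$genes, dataset$truth,
                   mature = FALSE, condition = dataset$condition)
  counts <- .sim_sample_counts(mu, config$dispersion,
                               .derive_seed(config$seed, "counts_maturation"))
  out <- dataset
  out$means <- mu
  out$counts <- counts
  out$mature <- FALSE
  out
}

#' Apply a culture-condition effect to a simulated dataset
#'
#' For condition `"2D"`-style entries of `config$condition_effects`, each
#' designated type-marker gene (the type programs of the affected class) has
#' its mean multiplied by the attenuation factor `alpha` within its own
#' population's cells, emulating the loss of type-identity programs in
#' dissociated glutamatergic neurons. For `"organotypic"`-style entries a
#' seeded fraction `rho` of the designated genes is exempted ("restored"),
#' i.e. returned to reference means; the restored set is recorded in
#' `gene_annotations` and is identical across datasets generated from the
#' same configuration, so downstream restoration estimates have an exact
#' oracle.
#'
#' @param dataset a `sim_dataset`.
#' @param condition name of an entry of `config$condition_effects`, or
#'   `"reference"` (returns the dataset unchanged apart from the label).
#' @param config simulation configuration; defaults to the dataset's own.
#' @return a `sim_dataset` with condition-modified means and re-sampled
#'   counts.
#' @export
apply_condition <- function(dataset, condition, config = dataset$config) {
  .assert(inherits(dataset, "sim_dataset"), "dataset must be a sim_dataset")
  if (identical(condition, "reference")) {
    out <- dataset
    out$truth$condition <- "reference"
    return(out)
  }
  .assert(condition %in% names(config$condition_effects),
          sprintf("unknown condition '%s'", condition))
  eff <- config$condition_effects[[condition]]
  ann <- dataset$gene_annotations
  cond <- .sim_restored(config, dataset$tree, ann, condition)
  ann$attenuated <- seq_len(nrow(ann)) %in% setdiff(cond$attenuated,
                                                    cond$restored)
  ann$restored <- seq_len(nrow(ann)) %in% cond$restored
  out <- dataset
  out$gene_annotations <- ann
  out$truth$condition <- condition
  out$condition <- condition
  if (eff$alpha == 1) return(out)
  mu <- .sim_means(config, dataset$tree, dataset$genes, out$truth,
                   mature = dataset$mature, condition = condition)
  out$means <- mu
  out$counts <- .sim_sample_counts(mu, config$dispersion,
                                   .derive_seed(config$seed,
                                                paste0("counts_", condition)))
  out
}

#' Simulate a scaled-expression maturation ramp
#'
#' Produces a Gaussian scaled-expression matrix over ordered timepoints in
#' which a subset of signal genes increases linearly by `effect` standard
#' deviations per timepoint step, against unit-variance noise. This is the
#' fixture the pseudo-age module is calibrated and tested on.
#'
#' @param n_cells_per_timepoint cells per timepoint.
#' @param n_genes total genes.
#' @param n_signal number of temporally dynamic genes (the first `n_signal`).
#' @param effect per-step mean increase of signal genes, in noise SD units.
#' @param n_timepoints number of ordered timepoints.
#' @param seed integer seed.
#' @return list with `expr` (genes x cells), `timepoint` (ordered factor) and
#'   `signal_genes`.
#' @export
simulate_ramp <- function(n_cells_per_timepoint = 100, n_genes = 200,
                          n_signal = 20, effect = 1, n_timepoints = 4,
                          seed = 0) {
  .assert(n_signal <= n_genes, "n_signal must not exceed n_genes")
  n <- n_cells_per_timepoint * n_timepoints
  t_idx <- rep(seq_len(n_timepoints), each = n_cells_per_timepoint)
  expr <- .with_seed(seed, {
    x <- matrix(stats::rnorm(n_genes * n), n_genes, n)
    x[seq_len(n_signal), ] <- x[seq_len(n_signal), ] +
      rep((t_idx - 1) * effect, each = n_signal)
    x
  })
  rownames(expr) <- sprintf("gene%03d", seq_len(n_genes))
  colnames(expr) <- sprintf("cell%04d", seq_len(n))
  list(expr = expr,
       timepoint = factor(paste0("T", t_idx), levels = paste0("T", seq_len(n_timepoints)),
                          ordered = TRUE),
       signal_genes = rownames(expr)[seq_len(n_signal)])
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d genes x %d cells | condition: %s | %s\n",
              nrow(x$counts), ncol(x$counts), x$condition,
              if (x$mature) "mature" else "timepoint-ramped"))
  cat(sprintf("  taxonomy: %d classes / %d subclasses / %d types\n",
              length(x$tree$classes), length(x$tree$subclasses),
              length(x$tree$types)))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d classes, %d subclasses, %d types, %d cells/type, seed %d\n",
              x$n_classes, sum(x$subclasses_per_class),
              sum(x$types_per_subclass), x$cells_per_type, x$seed))
  invisible(x)
}
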