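#' Pipeline configuration
#'
#' Collects all stage parameters with the published defaults (clustering
#' resolutions 0.0005/0.001/0.08; marker thresholds log2FC 0.6 and percent
#' difference 0.1; 10-NN/9-consensus classification; diversity resolution 1;
#' DEG thresholds log2FC 0.6, adjusted p 0.05, percent difference 0.2) and
#' validates them before any stage runs. Every stochastic stage receives a
#' seed derived deterministically from the root seed.
#'
#' @param sim a [sim_config()] describing the simulated inputs.
#' @param qc a [qc_thresholds()] object or preset name; the default keeps
#'   cells with more than 100 genes and under 2 percent mitochondrial RNA,
#'   matched to the simulator's desk-scale library sizes.
#' @param resolutions class/subclass/type clustering resolutions.
#' @param min_log2fc,min_pct_diff,marker_alpha marker-selection thresholds.
#' @param k,consensus consensus-classification parameters.
#' @param diversity_resolution merged-clustering resolution.
#' @param pseudoage_n_genes number of most-variable genes fed to the
#'   ordinal model.
#' @param lambda ordinal-regression ridge penalty.
#' @param deg_min_log2fc,deg_max_p_adj,deg_min_pct_diff DEG thresholds.
#' @param seed root seed fanned out to every stage.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            qc = qc_thresholds(min_genes = 100,
                                               max_pct_mito = 2),
                            resolutions = c(0.0005, 0.001, 0.08),
                            min_log2fc = 0.6, min_pct_diff = 0.1,
                            marker_alpha = 0.05,
                            k = 10, consensus = 9,
                            diversity_resolution = 1,
                            pseudoage_n_genes = 100, lambda = 1,
                            deg_min_log2fc = 0.6, deg_max_p_adj = 0.05,
                            deg_min_pct_diff = 0.2,
                            seed = 0) {
  .assert(inherits(sim, "sim_config"), "sim must be a sim_config")
  if (is.character(qc)) qc <- qc_thresholds(preset = qc)
  .assert(inherits(qc, "qc_thresholds"), "qc must be qc_thresholds or preset")
  .assert(length(resolutions) == 3 && all(resolutions > 0),
          "resolutions must be three positive values")
  .assert(consensus <= k, "consensus must not exceed k")
  .assert(k >= 1 && consensus >= 1, "k and consensus must be positive")
  .assert(diversity_resolution > 0, "diversity_resolution must be > 0")
  .assert(lambda > 0, "lambda must be > 0")
  structure(list(sim = sim, qc = qc, resolutions = resolutions,
                 min_log2fc = min_log2fc, min_pct_diff = min_pct_diff,
                 marker_alpha = marker_alpha, k = k, consensus = consensus,
                 diversity_resolution = diversity_resolution,
                 pseudoage_n_genes = pseudoage_n_genes, lambda = lambda,
                 deg_min_log2fc = deg_min_log2fc,
                 deg_max_p_adj = deg_max_p_adj,
                 deg_min_pct_diff = deg_min_pct_diff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_tsv <- function(x, path)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate, QC, hierarchy, marker selection, consensus
#' classification (the 2D-culture dataset as query against the reference),
#' merged-cluster diversity, pseudo-age cross-validation on the
#' developmental series, and the restoration analysis, writing every stage
#' artifact as a TSV into `out_dir` together with an effective-config file
#' recording all parameters and seeds. Re-running with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; default a fresh tempdir).
#' @return invisibly, a list of stage results and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("cortid_run")) {
  .assert(inherits(config, "pipeline_config"),
          "config must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(tag) .derive_seed(config$seed, tag)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[cortid] ", fmt), ...))

  log_stage("simulate")
  ref <- generate_reference(config$sim, seed = stage_seed("simulate"))
  dev <- apply_maturation(ref)
  d2 <- apply_condition(ref, "2D")
  org <- apply_condition(ref, "organotypic")

  log_stage("qc")
  metrics <- compute_qc_metrics(ref$counts)
  kept <- filter_cells(metrics, config$qc)
  .assert(length(kept) >= 50, "QC removed too many cells to continue")
  .write_tsv(metrics, file.path(out_dir, "qc_metrics.tsv"))
  .write_tsv(data.frame(cell_id = kept), file.path(out_dir, "kept_cells.tsv"))
  ref_counts <- ref$counts[, kept, drop = FALSE]
  ref_truth <- ref$truth[match(kept, ref$truth$cell_id), ]

  log_stage("hierarchy")
  ref_ln <- lognormalize(ref_counts)
  ref_sc <- scale_expression(ref_ln)
  hier <- cluster_hierarchy(ref_sc, resolutions = config$resolutions,
                            seed = stage_seed("hierarchy"))
  .write_tsv(hier$labels, file.path(out_dir, "hierarchy_labels.tsv"))
  .write_tsv(as.data.frame(hier$tree), file.path(out_dir, "hierarchy_tree.tsv"))

  log_stage("markers")
  markers <- do.call(rbind, lapply(c("class", "subclass", "type"), function(l) {
    if (length(unique(hier$labels[[l]])) < 2) {
      warning(sprintf("only one %s-level cluster; markers skipped", l))
      return(NULL)
    }
    find_level_markers(ref_ln, hier$labels[[l]], level = l,
                       min_log2fc = config$min_log2fc,
                       min_pct_diff = config$min_pct_diff,
                       alpha = config$marker_alpha)
  }))
  .assert(nrow(markers) > 0, "no markers retained at any level")
  gsets <- identity_gene_sets(markers)
  .write_tsv(markers, file.path(out_dir, "markers.tsv"))

  log_stage("classify")
  lvls <- intersect(c("class", "subclass", "type"), names(gsets))
  cls <- classify_cells(ref_counts, hier$labels[lvls], gsets, d2$counts,
                        k = config$k, consensus = config$consensus,
                        seed = stage_seed("classify"))
  .write_tsv(as.data.frame(cls$assignment),
             file.path(out_dir, "assignment.tsv"))
  props <- population_proportions(cls$assignment,
                                  grouping = d2$truth$condition,
                                  levels = lvls)
  .write_tsv(props, file.path(out_dir, "proportions.tsv"))

  log_stage("diversity")
  mc <- merged_cluster(list(reference = ref$counts, d2 = d2$counts,
                            organotypic = org$counts),
                       resolution = config$diversity_resolution,
                       seed = stage_seed("diversity"))
  div <- diversity_by_group(mc$labels, mc$dataset)
  .write_tsv(div, file.path(out_dir, "diversity.tsv"))

  log_stage("pseudoage")
  dev_sc <- scale_expression(lognormalize(dev$counts))
  vars <- matrixStats::rowVars(dev_sc$values)
  top <- order(vars, decreasing = TRUE)[seq_len(
    min(config$pseudoage_n_genes, nrow(dev_sc$values)))]
  cv <- cross_validate(dev_sc$values[top, , drop = FALSE],
                       factor(dev$truth$timepoint,
                              levels = config$sim$timepoints),
                       lambda = config$lambda, seed = stage_seed("pseudoage"))
  pa <- data.frame(cell_id = dev$truth$cell_id,
                   timepoint = dev$truth$timepoint,
                   pseudoage = unname(cv$scores))
  .write_tsv(pa, file.path(out_dir, "pseudoage.tsv"))

  log_stage("restoration")
  aff <- ref$tree$affected_class
  groups <- list(invivo = ifelse(ref$truth$class == aff, ref$truth$type, NA),
                 d2 = ifelse(d2$truth$class == aff, d2$truth$type, NA),
                 organo = ifelse(org$truth$class == aff, org$truth$type, NA))
  rest <- restoration_analysis(lognormalize(ref$counts),
                               lognormalize(d2$counts),
                               lognormalize(org$counts), groups = groups,
                               min_log2fc = config$deg_min_log2fc,
                               max_p_adj = config$deg_max_p_adj,
                               min_pct_diff = config$deg_min_pct_diff)
  .write_tsv(data.frame(gene = names(rest$classes), class = rest$classes),
             file.path(out_dir, "restoration_degs.tsv"))
  .write_tsv(data.frame(n_deg = rest$summary$n_deg,
                        n_restored = rest$summary$n_restored,
                        percent_restored = rest$summary$percent_restored),
             file.path(out_dir, "restoration_summary.tsv"))

  eff <- c(sprintf("cortid_version\t%s",
                   as.character(utils::packageVersion("cortid"))),
           sprintf("seed\t%d", config$seed),
           sprintf("resolutions\t%s", paste(config$resolutions, collapse = ",")),
           sprintf("k\t%d", config$k), sprintf("consensus\t%d", config$consensus),
           sprintf("diversity_resolution\t%g", config$diversity_resolution),
           sprintf("lambda\t%g", config$lambda),
           sprintf("cells_per_type\t%d", config$sim$cells_per_type),
           sprintf("marker_log2_effect\t%g", config$sim$marker_log2_effect))
  writeLines(eff, file.path(out_dir, "effective_config.tsv"))
  invisible(list(out_dir = out_dir, hierarchy = hier, markers = markers,
                 classification = cls, diversity = div, pseudoage = pa,
                 restoration = rest))
}
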