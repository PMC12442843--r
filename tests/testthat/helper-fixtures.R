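# Shared fixtures, built once per test run and cached.

.fix_env <- new.env()

fixture <- function(name, expr) {
  if (is.null(.fix_env[[name]])) assign(name, force(expr), envir = .fix_env)
  .fix_env[[name]]
}

ref_dataset <- function() fixture("ref", generate_reference(sim_config()))

ref_lognorm <- function() fixture("ref_ln", lognormalize(ref_dataset()$counts))

ref_scaled <- function() fixture("ref_sc", scale_expression(ref_lognorm()))

ref_graph <- function() fixture("ref_graph",
  build_neighbor_graph(ref_scaled(), seed = 0))

# Reference markers from the simulation's true labels, as when reference
# annotations are supplied to the framework.
ref_gene_sets <- function() fixture("ref_gsets", {
  truth <- ref_dataset()$truth
  markers <- do.call(rbind, lapply(c("class", "subclass", "type"),
    function(l) find_level_markers(ref_lognorm(), truth[[l]], level = l)))
  identity_gene_sets(markers)
})

# two well-separated Gaussian blobs in gene space (genes x cells)
blob_matrix <- function(n_per = 40, n_genes = 20, sep = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per), n_genes, 2 * n_per)
  m[1:5, seq_len(n_per)] <- m[1:5, seq_len(n_per)] + sep
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("c", seq_len(2 * n_per)))
  structure(list(values = m, meta = list(method = "fixture")),
            class = "scaled_matrix")
}

# Independent brute-force consensus k-NN classifier used as the oracle for
# assign_identity: plain Euclidean distances, plain sort, same index
# tie-break contract.
oracle_assign <- function(ref_coords, labels, query_coords, k = 10,
                          consensus = 9) {
  n_r <- nrow(ref_coords)
  out <- character(nrow(query_coords))
  for (i in seq_len(nrow(query_coords))) {
    d <- numeric(n_r)
    for (j in seq_len(n_r))
      d[j] <- sqrt(sum((query_coords[i, ] - ref_coords[j, ])^2))
    nb <- order(d, seq_len(n_r))[seq_len(k)]
    counts <- table(labels[nb])
    top <- max(counts)
    out[i] <- if (top >= consensus) names(counts)[which.max(counts)]
              else "undefined"
  }
  out
}
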