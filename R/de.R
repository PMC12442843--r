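# Shared two-group differential-expression core.
#
# Means are taken on de-logged normalized values (expm1 of log-normalized),
# log2 fold change uses a pseudocount on both means, percent expressing is
# the fraction of cells with any count, and p-values come from the Wilcoxon
# rank-sum test with Bonferroni adjustment over all genes. Genes failing the
# fold-change or percent-difference thresholds are not tested (the adjustment
# denominator is nevertheless the full gene universe, keeping it
# conservative and threshold-independent).
.de_two_group <- function(v_in, v_out, min_log2fc, min_pct_diff, alpha,
                          pseudocount = 1, two_sided_fc = FALSE) {
  d_in <- expm1(v_in)
  d_out <- expm1(v_out)
  mean_in <- Matrix::rowMeans(d_in)
  mean_out <- Matrix::rowMeans(d_out)
  log2fc <- log2((mean_in + pseudocount) / (mean_out + pseudocount))
  pct_in <- Matrix::rowMeans(v_in > 0)
  pct_out <- Matrix::rowMeans(v_out > 0)
  pct_diff <- pct_in - pct_out
  fc_ok <- if (two_sided_fc) abs(log2fc) > min_log2fc else log2fc >= min_log2fc
  pct_ok <- if (two_sided_fc) abs(pct_diff) > min_pct_diff else pct_diff >= min_pct_diff
  cand <- which(fc_ok & pct_ok)
  p <- rep(NA_real_, nrow(v_in))
  if (length(cand)) {
    m_in <- as.matrix(v_in[cand, , drop = FALSE])
    m_out <- as.matrix(v_out[cand, , drop = FALSE])
    p[cand] <- vapply(seq_along(cand), function(i)
      stats::wilcox.test(m_in[i, ], m_out[i, ], exact = FALSE)$p.value,
      numeric(1))
  }
  p_adj <- pmin(p * nrow(v_in), 1)
  keep <- !is.na(p_adj) & p_adj < alpha
  data.frame(gene = rownames(v_in), log2fc = log2fc,
             pct_in = pct_in, pct_out = pct_out, pct_diff = pct_diff,
             p = p, p_adj = p_adj, retained = keep,
             row.names = NULL, stringsAsFactors = FALSE)
}
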