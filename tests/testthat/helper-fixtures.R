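# Fixture builders and independent oracles shared across the test files.

# SingleCellExperiment from a dense count matrix plus per-cell labels.
make_sce <- function(counts, condition = NULL, cluster = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  }
  cd <- S4Vectors::DataFrame(barcode = colnames(counts),
                             row.names = colnames(counts))
  if (!is.null(condition)) cd$condition <- condition
  if (!is.null(cluster)) cd$cluster <- cluster
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "CsparseMatrix")),
    colData = cd
  )
}

# Small simulated dataset used by several tests.
quick_sim <- function(seed = 1, n_genes = 300, n_cells = 100, n_clusters = 2,
                      effects = list()) {
  simulate_counts(sim_config(
    n_genes = n_genes, n_cells_per_condition = n_cells,
    n_clusters = n_clusters, planted_effects = effects, seed = seed
  ))
}

# --- independent oracles ---------------------------------------------------

# Two-sided Fisher exact p by exhaustive enumeration over all tables with the
# observed margins, summing point probabilities <= that of the observed table
# (with the standard 1 + 1e-7 relative tolerance for floating-point equality).
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lp <- function(x) {
    # P(X = x) for the hypergeometric with these margins, via lchoose
    lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  }
  support <- max(0L, r1 - (n - c1)):min(r1, c1)
  probs <- exp(vapply(support, lp, numeric(1)))
  p_obs <- exp(lp(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all group
# assignments (tie-free inputs only).
wilcox_enum_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Benjamini-Hochberg step-up computed directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
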