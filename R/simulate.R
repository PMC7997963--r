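#' Configure the two-condition scRNA-seq count simulator
#'
#' Builds the parameter set for [simulate_counts()]. The generative model is a
#' gamma-Poisson (negative binomial) count law per gene and cell: per-gene
#' baseline means are log-normal across genes, each cluster multiplies a
#' random subset of genes by a fold-change (giving marker structure), each
#' cell carries a log-normal library size factor, and planted signature
#' effects shift the means of chosen genes in one condition. A designated
#' block of mitochondrial genes (IDs prefixed `mt-`, the mouse convention)
#' takes up an expected share of each cell's counts equal to that cell's
#' drawn mitochondrial fraction.
#'
#' @param n_genes Number of genes, including the mitochondrial block.
#' @param n_cells_per_condition Cells drawn for each of the two conditions.
#' @param n_clusters Number of cell subpopulations (shared across conditions).
#' @param baseline_mean_log,baseline_sd_log Mean and sd (log scale) of the
#'   log-normal per-gene baseline expression.
#' @param dispersion Negative-binomial overdispersion; the NB size parameter
#'   is `1/dispersion`, so variance is `mu + dispersion * mu^2`.
#' @param libsize_sigma Log-normal sd of per-cell size factors (0 = equal
#'   library sizes).
#' @param mito_fraction_beta Length-2 positive vector: Beta shape parameters
#'   for the per-cell mitochondrial fraction.
#' @param n_mito_genes Number of `mt-` prefixed genes (13 protein-coding
#'   mitochondrial genes in mouse).
#' @param cluster_de_frac Fraction of genes each cluster (beyond the first)
#'   perturbs multiplicatively.
#' @param cluster_logfc_range Range (natural-log scale) the per-cluster
#'   fold-changes are drawn from, sign-flipped with probability 1/2.
#' @param conditions Length-2 character vector of condition labels.
#' @param planted_effects List of [planted_effect()] records.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `sim_config` object (a validated list).
#' @seealso [simulate_counts()], [planted_effect()], [sim_gene_universe()]
#' @export
sim_config <- function(n_genes = 5000L,
                       n_cells_per_condition = 4500L,
                       n_clusters = 6L,
                       baseline_mean_log = 0,
                       baseline_sd_log = 1,
                       dispersion = 0.4,
                       libsize_sigma = 0.35,
                       mito_fraction_beta = c(2.5, 50),
                       n_mito_genes = 13L,
                       cluster_de_frac = 0.05,
                       cluster_logfc_range = c(log(2), log(4)),
                       conditions = c("shSELP", "shNC"),
                       planted_effects = list(),
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_cells_per_condition <- as.integer(n_cells_per_condition)
  n_clusters <- as.integer(n_clusters)
  n_mito_genes <- as.integer(n_mito_genes)
  stopifnot(
    n_genes >= 1L, n_cells_per_condition >= 1L, n_clusters >= 1L,
    n_mito_genes >= 0L, n_mito_genes < n_genes,
    length(conditions) == 2L, !anyDuplicated(conditions)
  )
  .assert_scalar_number(dispersion, "dispersion", 0, strict = TRUE)
  .assert_scalar_number(libsize_sigma, "libsize_sigma", 0)
  .assert_scalar_number(baseline_sd_log, "baseline_sd_log", 0)
  if (length(mito_fraction_beta) != 2L || any(mito_fraction_beta <= 0)) {
    stop("'mito_fraction_beta' must be two positive Beta shape parameters",
         call. = FALSE)
  }
  if (cluster_de_frac < 0 || cluster_de_frac > 1) {
    stop("'cluster_de_frac' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.list(planted_effects) ||
      !all(vapply(planted_effects, inherits, logical(1), "planted_effect"))) {
    stop("'planted_effects' must be a list of planted_effect() records",
         call. = FALSE)
  }
  cfg <- list(
    n_genes = n_genes,
    n_cells_per_condition = n_cells_per_condition,
    n_clusters = n_clusters,
    baseline_mean_log = baseline_mean_log,
    baseline_sd_log = baseline_sd_log,
    dispersion = dispersion,
    libsize_sigma = libsize_sigma,
    mito_fraction_beta = as.numeric(mito_fraction_beta),
    n_mito_genes = n_mito_genes,
    cluster_de_frac = cluster_de_frac,
    cluster_logfc_range = as.numeric(cluster_logfc_range),
    conditions = as.character(conditions),
    planted_effects = planted_effects,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Declare a planted signature effect
#'
#' Describes a mean shift applied to a signature's member genes in one
#' condition: up-members are multiplied by `exp(up_log_fold)` and
#' down-members by `exp(down_log_fold)` (typically negative) in the target
#' condition only. The ground truth of every planted shift is emitted in the
#' simulator's `truth` record.
#'
#' @param signature_name Name tag carried through to the truth record.
#' @param target_condition Condition label receiving the shift.
#' @param up_genes,down_genes Gene IDs (must exist in the simulated universe;
#'   see [sim_gene_universe()]).
#' @param up_log_fold,down_log_fold Natural-log fold-changes applied to the
#'   up and down members.
#' @return A `planted_effect` object.
#' @export
planted_effect <- function(signature_name, target_condition,
                           up_genes, down_genes = character(),
                           up_log_fold = 1, down_log_fold = 0) {
  stopifnot(is.character(signature_name), length(signature_name) == 1L,
            is.character(target_condition), length(target_condition) == 1L)
  up_genes <- as.character(up_genes)
  down_genes <- as.character(down_genes)
  if (length(intersect(up_genes, down_genes)) > 0L) {
    stop("up and down gene lists overlap", call. = FALSE)
  }
  structure(
    list(signature_name = signature_name,
         target_condition = target_condition,
         up_genes = up_genes, down_genes = down_genes,
         up_log_fold = up_log_fold, down_log_fold = down_log_fold),
    class = "planted_effect"
  )
}

#' Gene IDs of the simulated universe
#'
#' Deterministic gene naming for a config: `n_mito_genes` IDs prefixed `mt-`
#' followed by `g1, g2, ...`. Use this to pick signature members for
#' [planted_effect()].
#'
#' @param config A [sim_config()].
#' @return Character vector of length `n_genes`.
#' @export
sim_gene_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_mt <- config$n_mito_genes
  c(if (n_mt > 0L) paste0("mt-", seq_len(n_mt)) else character(),
    paste0("g", seq_len(config$n_genes - n_mt)))
}

#' Simulate a two-condition, multi-cluster count matrix
#'
#' Draws counts from the negative-binomial model described in [sim_config()]
#' and returns both the data and the full ground truth. Output is a pure
#' function of the config (including its seed).
#'
#' @param config A [sim_config()].
#' @return A list with components:
#' \describe{
#'   \item{sce}{A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'     `counts` assay (genes x cells), `rowData` columns `baseline_mean` and
#'     `is_mito`, and `colData` columns `barcode`, `condition`, `cluster`,
#'     `size_factor`, `mito_fraction`.}
#'   \item{truth}{A list of two data frames: `gene` (baseline mean, every
#'     per-cluster and per-condition log-fold applied) and `cell` (condition,
#'     cluster, size factor, mito fraction per cell).}
#' }
#' @examples
#' cfg <- sim_config(n_genes = 200, n_cells_per_condition = 50,
#'                   n_clusters = 2, seed = 7)
#' sim <- simulate_counts(cfg)
#' dim(sim$sce)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_universe(config)
  universe_err <- function(g) {
    stop("planted signature gene '", g, "' is absent from the simulated ",
         "gene universe", call. = FALSE)
  }
  for (eff in config$planted_effects) {
    missing <- setdiff(c(eff$up_genes, eff$down_genes), genes)
    if (length(missing) > 0L) universe_err(missing[[1L]])
    if (!eff$target_condition %in% config$conditions) {
      stop("planted effect targets unknown condition '",
           eff$target_condition, "'", call. = FALSE)
    }
  }

  n_genes <- config$n_genes
  n_mt <- config$n_mito_genes
  is_mito <- startsWith(genes, "mt-")
  n_cells <- 2L * config$n_cells_per_condition

  .with_seed(config$seed, {
    baseline <- rlnorm(n_genes, config$baseline_mean_log, config$baseline_sd_log)

    # per-cluster multiplicative modifiers on a random gene subset
    cluster_lfc <- matrix(0, n_genes, config$n_clusters)
    n_de <- round(config$cluster_de_frac * n_genes)
    if (config$n_clusters > 1L && n_de > 0L) {
      for (k in 2:config$n_clusters) {
        idx <- sample.int(n_genes, n_de)
        mag <- runif(n_de, config$cluster_logfc_range[1],
                     config$cluster_logfc_range[2])
        cluster_lfc[idx, k] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
      }
    }

    # per-condition log-folds from planted effects
    cond_lfc <- matrix(0, n_genes, 2L,
                       dimnames = list(genes, config$conditions))
    for (eff in config$planted_effects) {
      j <- match(eff$target_condition, config$conditions)
      cond_lfc[match(eff$up_genes, genes), j] <-
        cond_lfc[match(eff$up_genes, genes), j] + eff$up_log_fold
      if (length(eff$down_genes) > 0L) {
        cond_lfc[match(eff$down_genes, genes), j] <-
          cond_lfc[match(eff$down_genes, genes), j] + eff$down_log_fold
      }
    }

    condition <- rep(config$conditions, each = config$n_cells_per_condition)
    cluster <- sample.int(config$n_clusters, n_cells, replace = TRUE)
    size_factor <- rlnorm(n_cells, 0, config$libsize_sigma)
    mito_fraction <- if (n_mt > 0L) {
      rbeta(n_cells, config$mito_fraction_beta[1], config$mito_fraction_beta[2])
    } else {
      rep(0, n_cells)
    }

    # expected counts: baseline x cluster modifier x condition shift x size
    # factor, then the mito block rescaled so its expected share per cell
    # equals the drawn mito fraction
    cond_idx <- match(condition, config$conditions)
    mu <- baseline * exp(cluster_lfc[, cluster, drop = FALSE] +
                           cond_lfc[, cond_idx, drop = FALSE])
    mu <- sweep(mu, 2L, size_factor, `*`)
    if (n_mt > 0L) {
      w_mt <- baseline[is_mito] / sum(baseline[is_mito])
      nonmito_total <- colSums(mu[!is_mito, , drop = FALSE])
      mu[is_mito, ] <- outer(w_mt, mito_fraction / (1 - mito_fraction) *
                               nonmito_total)
    }

    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
      nrow = n_genes
    )
    if (n_mt > 0L) {
      # mito genes are conditionally Poisson given the cell's drawn mito
      # fraction: their across-cell overdispersion is induced by the Beta
      # fraction itself, not doubled by the gene-level NB noise
      counts[is_mito, ] <- stats::rpois(sum(is_mito) * n_cells,
                                        mu[is_mito, ])
    }
    barcodes <- paste0(condition, "_cell", seq_len(n_cells))
    dimnames(counts) <- list(genes, barcodes)

    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(
        methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
        "dMatrix")),
      rowData = S4Vectors::DataFrame(
        gene = genes, baseline_mean = baseline, is_mito = is_mito,
        row.names = genes),
      colData = S4Vectors::DataFrame(
        barcode = barcodes,
        condition = condition,
        cluster = paste0("c", cluster),
        size_factor = size_factor,
        mito_fraction = mito_fraction,
        row.names = barcodes)
    )

    gene_truth <- data.frame(
      gene = genes, baseline_mean = baseline, is_mito = is_mito,
      cluster_lfc, check.names = FALSE
    )
    names(gene_truth)[3L + seq_len(config$n_clusters)] <-
      paste0("cluster_lfc_c", seq_len(config$n_clusters))
    gene_truth[[paste0("cond_lfc_", config$conditions[1])]] <- cond_lfc[, 1L]
    gene_truth[[paste0("cond_lfc_", config$conditions[2])]] <- cond_lfc[, 2L]

    cell_truth <- data.frame(
      barcode = barcodes, condition = condition,
      cluster = paste0("c", cluster),
      size_factor = size_factor, mito_fraction = mito_fraction
    )

    list(sce = sce, truth = list(gene = gene_truth, cell = cell_truth))
  })
}
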