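#' Quality-control and normalization parameters
#'
#' Defaults reproduce the droplet-workflow thresholds used throughout the
#' package: cells with more than 10% mitochondrial counts or fewer than 500
#' detected genes are removed (strict inequalities at both boundaries), genes
#' must be present in more than 3 cells, log-normalization uses a scale
#' factor of 10,000, and per-gene z-scores are clipped at +/-10.
#'
#' @param max_mito_fraction Cells with mito share strictly greater than this
#'   are excluded. Computed on raw counts, before any filtering.
#' @param min_genes_per_cell Cells detecting strictly fewer genes than this
#'   are excluded ("detected" = nonzero raw count).
#' @param min_cells_per_gene Genes must be nonzero in strictly more than this
#'   many cells.
#' @param scale_factor Per-cell counts are divided by the cell total and
#'   multiplied by this before `log1p`.
#' @param clip_value Z-scored expression is truncated to
#'   `[-clip_value, clip_value]`; `NULL` disables clipping.
#' @param mito_prefix Gene-ID prefix identifying mitochondrial genes.
#' @return A `qc_config` object.
#' @export
qc_config <- function(max_mito_fraction = 0.10,
                      min_genes_per_cell = 500L,
                      min_cells_per_gene = 3L,
                      scale_factor = 1e4,
                      clip_value = 10,
                      mito_prefix = "mt-") {
  stopifnot(max_mito_fraction >= 0, max_mito_fraction <= 1,
            min_genes_per_cell >= 0, min_cells_per_gene >= 0)
  .assert_scalar_number(scale_factor, "scale_factor", 0, strict = TRUE)
  if (!is.null(clip_value)) {
    .assert_scalar_number(clip_value, "clip_value", 0, strict = TRUE)
  }
  structure(
    list(max_mito_fraction = max_mito_fraction,
         min_genes_per_cell = as.integer(min_genes_per_cell),
         min_cells_per_gene = as.integer(min_cells_per_gene),
         scale_factor = scale_factor,
         clip_value = clip_value,
         mito_prefix = mito_prefix),
    class = "qc_config"
  )
}

#' Remove low-quality cells
#'
#' Excludes cells whose mitochondrial share of raw counts exceeds
#' `max_mito_fraction` or that detect fewer than `min_genes_per_cell` genes.
#' Both comparisons are strict, so a cell at exactly the boundary (10%
#' mito, 500 genes) is retained. The numbers removed under each criterion are
#' attached as the `"qc_log"` attribute and reported via `message()`.
#'
#' @param sce A SingleCellExperiment with a `counts` assay.
#' @param qc A [qc_config()].
#' @param verbose Emit a log message with removal counts.
#' @return The filtered SingleCellExperiment (metadata subset accordingly).
#' @export
filter_cells <- function(sce, qc = qc_config(), verbose = TRUE) {
  counts <- .get_matrix(sce, "counts")
  is_mito <- startsWith(rownames(counts), qc$mito_prefix)
  totals <- Matrix::colSums(counts)
  mito_share <- if (any(is_mito)) {
    Matrix::colSums(counts[is_mito, , drop = FALSE]) / pmax(totals, 1)
  } else {
    rep(0, ncol(counts))
  }
  n_detected <- Matrix::colSums(counts > 0)

  fail_mito <- mito_share > qc$max_mito_fraction
  fail_genes <- n_detected < qc$min_genes_per_cell
  keep <- !fail_mito & !fail_genes
  if (!any(keep)) {
    stop("no cells survive QC (", sum(fail_mito), " failed the mito filter, ",
         sum(fail_genes), " the detected-gene filter)", call. = FALSE)
  }
  if (verbose) {
    message("filter_cells: removed ", sum(!keep), "/", ncol(counts),
            " cells (", sum(fail_mito), " mito > ",
            qc$max_mito_fraction * 100, "%, ", sum(fail_genes),
            " detected genes < ", qc$min_genes_per_cell, ")")
  }
  out <- sce[, keep]
  attr(out, "qc_log") <- list(
    n_input = ncol(counts), n_kept = sum(keep),
    n_fail_mito = sum(fail_mito), n_fail_genes = sum(fail_genes)
  )
  out
}

#' Remove rarely detected genes
#'
#' Keeps genes with a nonzero count in strictly more than `min_cells_per_gene`
#' cells. Intended to run after [filter_cells()], so "cells" means the
#' retained cells.
#'
#' @inheritParams filter_cells
#' @return The gene-filtered SingleCellExperiment.
#' @export
filter_genes <- function(sce, qc = qc_config(), verbose = TRUE) {
  counts <- .get_matrix(sce, "counts")
  n_cells_expressing <- Matrix::rowSums(counts > 0)
  keep <- n_cells_expressing > qc$min_cells_per_gene
  if (verbose) {
    message("filter_genes: removed ", sum(!keep), "/", nrow(counts),
            " genes present in <= ", qc$min_cells_per_gene, " cells")
  }
  out <- sce[keep, ]
  attr(out, "qc_log") <- list(n_input = nrow(counts), n_kept = sum(keep))
  out
}

#' Log-normalize counts
#'
#' For each cell, counts are divided by the cell's total, multiplied by the
#' scale factor and `log1p`-transformed:
#' `log1p(count / total * scale_factor)`. Zeros map to zero exactly, so the
#' result stays sparse.
#'
#' @inheritParams filter_cells
#' @return The SingleCellExperiment with a `logcounts` assay added.
#' @export
normalize_log <- function(sce, qc = qc_config()) {
  counts <- .get_matrix(sce, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    stop("cells with zero total counts present; run filter_cells() first",
         call. = FALSE)
  }
  if (methods::is(counts, "CsparseMatrix")) {
    logc <- counts
    per_col <- diff(logc@p)
    logc@x <- log1p(logc@x / rep.int(totals, per_col) * qc$scale_factor)
  } else {
    dense <- as.matrix(counts)
    logc <- log1p(sweep(dense, 2L, totals, `/`) * qc$scale_factor)
  }
  if (methods::is(sce, "SingleCellExperiment")) {
    SummarizedExperiment::assay(sce, "logcounts") <- logc
    sce
  } else {
    logc
  }
}

#' Center and standardize each gene
#'
#' Per gene (row), subtracts the mean across cells and divides by the sample
#' standard deviation (n-1 denominator). Constant genes map to all zeros.
#' If `clip_value` is set, results are truncated to
#' `[-clip_value, clip_value]`. This z-scoring removes the bias toward highly
#' expressed genes before rank-based signature scoring.
#'
#' @param sce A SingleCellExperiment with a `logcounts` assay (or a plain
#'   matrix of normalized expression).
#' @inheritParams filter_cells
#' @return With SCE input, the object with a dense `scaled` assay added;
#'   with matrix input, the scaled matrix.
#' @export
scale_genes <- function(sce, qc = qc_config()) {
  m <- as.matrix(.get_matrix(sce, "logcounts"))
  if (ncol(m) < 2L) {
    stop("scaling needs at least 2 cells (standard deviation undefined)",
         call. = FALSE)
  }
  mu <- rowMeans(m)
  sd <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  scaled <- (m - mu) / ifelse(sd > 0, sd, 1)
  scaled[sd == 0, ] <- 0
  if (!is.null(qc$clip_value)) {
    scaled[scaled > qc$clip_value] <- qc$clip_value
    scaled[scaled < -qc$clip_value] <- -qc$clip_value
  }
  if (methods::is(sce, "SingleCellExperiment")) {
    SummarizedExperiment::assay(sce, "scaled") <- scaled
    sce
  } else {
    scaled
  }
}

#' Randomly downsample each group to equal size
#'
#' Draws `n_per_group` cells uniformly without replacement from every group
#' (e.g. 4580 from each condition), seeded for reproducibility.
#'
#' @param sce A SingleCellExperiment.
#' @param group_key Name of the `colData` column defining groups.
#' @param n_per_group Cells to keep per group.
#' @param seed Integer seed for the draw.
#' @return The downsampled SingleCellExperiment.
#' @export
downsample_equal <- function(sce, group_key = "condition", n_per_group,
                             seed = 1L) {
  groups <- .get_coldata(sce, group_key)
  n_per_group <- as.integer(n_per_group)
  stopifnot(n_per_group >= 1L)
  sizes <- table(groups)
  too_small <- names(sizes)[sizes < n_per_group]
  if (length(too_small) > 0L) {
    stop("group '", too_small[[1L]], "' has ", sizes[[too_small[[1L]]]],
         " cells, fewer than n_per_group = ", n_per_group, call. = FALSE)
  }
  keep <- .with_seed(seed, {
    unlist(lapply(names(sizes), function(g) {
      idx <- which(groups == g)
      sort(sample(idx, n_per_group))
    }), use.names = FALSE)
  })
  sce[, sort(keep)]
}
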