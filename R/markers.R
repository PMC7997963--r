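#' One-vs-rest marker detection
#'
#' For each cluster, compares its cells against all other cells. Genes are
#' pre-filtered before any testing: a gene is considered only if it is
#' detected (nonzero raw count) in at least `min_pct` of the cells on at
#' least one side, and its average log fold-change has magnitude at least
#' `logfc_min`. Surviving genes get a two-sided Wilcoxon rank-sum p-value on
#' log-normalized expression and a Bonferroni adjustment over the total
#' number of genes in the matrix.
#'
#' The fold-change is computed on the natural-log scale from mean
#' de-logged expression, `ln(mean(expm1(x_in)) + 1) - ln(mean(expm1(x_out)) + 1)`
#' (`fc_method = "expm1"`), or as the simple difference of mean log
#' expression (`fc_method = "logmean"`).
#'
#' @param sce A SingleCellExperiment with `logcounts` (and ideally `counts`
#'   for the detection fractions; `logcounts` nonzero is used otherwise).
#' @param cluster Cluster label per cell; taken from `colData` when absent.
#' @param logfc_min Minimum absolute log fold-change (default 0.25).
#' @param min_pct Minimum detection fraction in either population
#'   (default 0.25).
#' @param fc_method Fold-change formula, see Details.
#' @return A `de_result` data frame with columns `gene`, `cluster`,
#'   `avg_logFC`, `pct.1`, `pct.2`, `p_val`, `p_val_adj`, sorted by cluster
#'   then p-value. The number of Wilcoxon tests actually performed per
#'   cluster is attached as attribute `n_tests`.
#' @export
find_markers <- function(sce, cluster = NULL, logfc_min = 0.25,
                         min_pct = 0.25,
                         fc_method = c("expm1", "logmean")) {
  fc_method <- match.arg(fc_method)
  logc <- as.matrix(.get_matrix(sce, "logcounts"))
  detected <- if (methods::is(sce, "SingleCellExperiment") &&
                  "counts" %in% SummarizedExperiment::assayNames(sce)) {
    .get_matrix(sce, "counts") > 0
  } else {
    logc > 0
  }
  cluster <- as.character(.get_coldata(sce, "cluster", cluster))
  stopifnot(length(cluster) == ncol(logc))
  clusters <- sort(unique(cluster))
  if (length(clusters) < 2L) {
    stop("marker detection needs at least 2 clusters", call. = FALSE)
  }
  sizes <- table(cluster)
  if (any(sizes < 3L)) {
    small <- names(sizes)[sizes < 3L][1L]
    stop("cluster '", small, "' has fewer than 3 cells", call. = FALSE)
  }

  n_genes_total <- nrow(logc)
  n_tests <- integer(0)
  out <- lapply(clusters, function(cl) {
    in_cl <- cluster == cl
    pct1 <- Matrix::rowMeans(detected[, in_cl, drop = FALSE])
    pct2 <- Matrix::rowMeans(detected[, !in_cl, drop = FALSE])
    lfc <- if (fc_method == "expm1") {
      log(rowMeans(expm1(logc[, in_cl, drop = FALSE])) + 1) -
        log(rowMeans(expm1(logc[, !in_cl, drop = FALSE])) + 1)
    } else {
      rowMeans(logc[, in_cl, drop = FALSE]) -
        rowMeans(logc[, !in_cl, drop = FALSE])
    }
    test_idx <- which(pmax(pct1, pct2) >= min_pct & abs(lfc) >= logfc_min)
    n_tests[[cl]] <<- length(test_idx)
    if (length(test_idx) == 0L) return(NULL)
    p <- vapply(test_idx, function(g) {
      .rank_sum_test(logc[g, in_cl], logc[g, !in_cl])$p
    }, numeric(1))
    df <- data.frame(
      gene = rownames(logc)[test_idx], cluster = cl,
      avg_logFC = lfc[test_idx], pct.1 = pct1[test_idx],
      pct.2 = pct2[test_idx], p_val = p,
      p_val_adj = pmin(p * n_genes_total, 1),
      stringsAsFactors = FALSE
    )
    df[order(df$p_val), ]
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene = character(), cluster = character(),
                      avg_logFC = numeric(), pct.1 = numeric(),
                      pct.2 = numeric(), p_val = numeric(),
                      p_val_adj = numeric())
  }
  rownames(res) <- NULL
  structure(res, class = c("de_result", "data.frame"), n_tests = n_tests)
}

#' Cluster-composition shift between conditions
#'
#' For each cluster, tests whether its share of cells differs between the
#' two conditions: a 2x2 table of (in-cluster / out-of-cluster) by condition
#' is evaluated with Fisher's exact test (the same routine as
#' [fisher_condition_enrichment()]) and p-values are BH-adjusted across
#' clusters.
#'
#' @param cluster Cluster label per cell.
#' @param condition Condition label per cell (exactly two).
#' @param alternative Sidedness of the exact test.
#' @return A data frame with one row per cluster: the table cells
#'   `n_in_cond1`, `n_in_cond2`, `n_out_cond1`, `n_out_cond2`, `odds_ratio`,
#'   `p`, `p_adj`; condition order is recorded in attribute `conditions`.
#' @export
cluster_shift_fisher <- function(cluster, condition,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  cluster <- as.character(cluster)
  condition <- as.character(condition)
  stopifnot(length(cluster) == length(condition))
  conds <- unique(condition)
  if (length(conds) != 2L) {
    stop("exactly two conditions required (found ", length(conds), ")",
         call. = FALSE)
  }
  clusters <- sort(unique(cluster))
  rows <- lapply(clusters, function(cl) {
    a <- sum(cluster == cl & condition == conds[1])
    b <- sum(cluster == cl & condition == conds[2])
    c_ <- sum(cluster != cl & condition == conds[1])
    d <- sum(cluster != cl & condition == conds[2])
    ft <- .fisher_2x2(a, b, c_, d, alternative)
    data.frame(cluster = cl, n_in_cond1 = a, n_in_cond2 = b,
               n_out_cond1 = c_, n_out_cond2 = d,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  attr(res, "conditions") <- conds
  res
}
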