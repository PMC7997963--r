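#' Per-cell CERNO enrichment statistic
#'
#' For every cell, genes are ranked by normalized expression in descending
#' order (rank 1 = highest, ties get the average rank) and Fisher's
#' combination of the log relative ranks of the signature members is formed:
#' \deqn{F = -2 \sum_{i=1}^{N} \ln(r_i / N_{tot})}
#' where \eqn{r_i} is the rank of signature gene \eqn{i}, \eqn{N} the
#' signature size after resolution and \eqn{N_{tot}} the total number of
#' genes. Under the null of exchangeable ranks \eqn{F \sim \chi^2_{2N}}, so
#' the per-cell p-value is the chi-square upper-tail probability at F.
#' Highly expressed signature genes give small \eqn{r_i/N_{tot}} and large F.
#'
#' @param sce A SingleCellExperiment (or plain matrix). By default the
#'   statistic is computed on the log-normalized matrix; `matrix_use =
#'   "scaled"` switches to the z-scored matrix.
#' @param sig A [gene_signature()]; up and down members are pooled (the
#'   statistic is unsigned).
#' @param condition Condition label per cell; taken from `colData(sce)` when
#'   absent.
#' @param matrix_use Assay to rank: `"logcounts"` (default) or `"scaled"`.
#' @return A `cerno_result` data frame with columns `barcode`, `condition`,
#'   `F`, `p` and `q` (`NA` until [fdr_correct()]), and attributes
#'   `signature`, `N`, `N_tot`.
#' @export
cerno_cell <- function(sce, sig, condition = NULL,
                       matrix_use = c("logcounts", "scaled")) {
  matrix_use <- match.arg(matrix_use)
  m <- as.matrix(.get_matrix(sce, matrix_use))
  condition <- .get_coldata(sce, "condition", condition)
  stopifnot(length(condition) == ncol(m))
  sig <- .resolve_signature(sig, rownames(m))
  members <- c(sig$up_genes, sig$down_genes)
  n_tot <- nrow(m)
  n_sig <- length(members)
  idx <- match(members, rownames(m))

  # descending ranks with average ties; rank(-x) is O(G log G) per cell
  f_stat <- vapply(seq_len(ncol(m)), function(j) {
    r <- rank(-m[, j])[idx]
    -2 * sum(log(r / n_tot))
  }, numeric(1))
  p <- pchisq(f_stat, df = 2 * n_sig, lower.tail = FALSE)

  res <- data.frame(
    barcode = colnames(m) %||% paste0("cell", seq_len(ncol(m))),
    condition = as.character(condition),
    F = f_stat, p = p, q = NA_real_,
    stringsAsFactors = FALSE
  )
  structure(res, class = c("cerno_result", "data.frame"),
            signature = sig$name, N = n_sig, N_tot = n_tot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg correction within each condition
#'
#' Fills the `q` column of a [cerno_cell()] result by applying the BH
#' step-up procedure separately to the cells of each condition.
#'
#' @param result A `cerno_result`.
#' @return The same object with `q` filled (clipped to at most 1).
#' @export
fdr_correct <- function(result) {
  stopifnot(inherits(result, "cerno_result"))
  for (cond in unique(result$condition)) {
    sel <- result$condition == cond
    result$q[sel] <- p.adjust(result$p[sel], method = "BH")
  }
  result
}

# Shared Fisher 2x2 routine: table rows are groups, columns are outcomes.
# Odds ratio is the raw cross-product (a*d)/(b*c); zero cells give Inf, 0 or
# NaN per IEEE arithmetic, documented rather than continuity-corrected.
.fisher_2x2 <- function(a, b, c, d,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(p = min(p, 1), odds_ratio = (a * d) / (b * c))
}

#' Cross-condition enrichment by Fisher's exact test
#'
#' Dichotomizes cells into significantly enriched (`q < q_threshold`) versus
#' not, builds the 2x2 enriched-by-condition table and tests whether one
#' condition holds more CERNO-enriched cells than the other with Fisher's
#' exact test (two-sided by default; `alternative = "greater"` asks whether
#' the first condition is the enriched one).
#'
#' @param result A `cerno_result` with `q` filled (see [fdr_correct()]).
#' @param q_threshold FDR threshold declaring a cell enriched.
#' @param alternative Sidedness passed to the exact test.
#' @param conditions Optional length-2 vector fixing the order of the
#'   conditions (first = table row 1).
#' @return A `condition_enrichment` list: the 2x2 `table` (rows conditions,
#'   columns enriched/not), `odds_ratio` (raw cross-product, with zero cells
#'   propagating Inf/NaN), `p`, `alternative`, `q_threshold`, and
#'   `enriched_condition` (the condition with the larger enriched fraction).
#' @export
fisher_condition_enrichment <- function(result, q_threshold = 0.05,
                                        alternative = c("two.sided",
                                                        "greater", "less"),
                                        conditions = NULL) {
  stopifnot(inherits(result, "cerno_result"))
  alternative <- match.arg(alternative)
  if (any(is.na(result$q))) {
    stop("q-values missing; run fdr_correct() first", call. = FALSE)
  }
  conds <- conditions %||% unique(result$condition)
  if (length(conds) != 2L || !all(conds %in% result$condition)) {
    stop("exactly two conditions with cells are required (found: ",
         paste(unique(result$condition), collapse = ", "), ")", call. = FALSE)
  }
  enriched <- result$q < q_threshold
  a <- sum(enriched & result$condition == conds[1])
  b <- sum(!enriched & result$condition == conds[1])
  c_ <- sum(enriched & result$condition == conds[2])
  d <- sum(!enriched & result$condition == conds[2])
  ft <- .fisher_2x2(a, b, c_, d, alternative)
  tab <- matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE,
                dimnames = list(conds, c("enriched", "not_enriched")))
  frac <- c(a / (a + b), c_ / (c_ + d))
  structure(
    list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p,
         alternative = alternative, q_threshold = q_threshold,
         enriched_condition = conds[which.max(frac)]),
    class = "condition_enrichment"
  )
}

#' @export
print.condition_enrichment <- function(x, ...) {
  cat("Fisher exact test on CERNO-enriched cells (q < ", x$q_threshold,
      ", ", x$alternative, ")\n", sep = "")
  print(x$table)
  cat("odds ratio =", format(x$odds_ratio, digits = 4),
      "  p =", format(x$p, digits = 4),
      "  more enriched:", x$enriched_condition, "\n")
  invisible(x)
}

# Shared rank-sum routine: exact enumeration when both groups are small and
# tie-free, otherwise normal approximation with tie and continuity
# corrections (as implemented in stats::wilcox.test).
.rank_sum_test <- function(x, y, exact_max = 8L) {
  exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = min(wt$p.value, 1),
       exact = exact)
}

#' Two-sided Wilcoxon rank-sum test on signature scores
#'
#' Compares the per-cell signature scores of the two conditions with the
#' two-sided Mann-Whitney/Wilcoxon rank-sum test. The p-value is exact (full
#' enumeration) when both groups have at most 8 cells and no ties occur;
#' otherwise the normal approximation with tie and continuity corrections is
#' used.
#'
#' @param scores A `signature_scores` object or numeric vector.
#' @param condition Condition label per cell (exactly two distinct labels).
#' @return A list with `statistic` (the Mann-Whitney U of the first group),
#'   `p`, the two group labels, and whether the exact path was used.
#' @export
wilcoxon_score_test <- function(scores, condition) {
  x <- if (inherits(scores, "signature_scores")) scores$score else scores
  condition <- as.character(condition)
  stopifnot(length(x) == length(condition))
  groups <- unique(condition)
  if (length(groups) != 2L) {
    stop("exactly two conditions required (found ", length(groups), ")",
         call. = FALSE)
  }
  g1 <- x[condition == groups[1]]
  g2 <- x[condition == groups[2]]
  if (length(g1) == 0L || length(g2) == 0L) {
    stop("both conditions need at least one cell", call. = FALSE)
  }
  rs <- .rank_sum_test(g1, g2)
  c(rs, list(groups = groups))
}
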