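#' Define a gene signature
#'
#' A named gene set, optionally split into up-regulated and down-regulated
#' member lists. The two lists must be disjoint and at least one must be
#' nonempty.
#'
#' @param name Signature name.
#' @param up_genes,down_genes Character vectors of gene IDs.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(name, up_genes, down_genes = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  if (length(up_genes) + length(down_genes) == 0L) {
    stop("signature '", name, "' has no member genes", call. = FALSE)
  }
  if (length(intersect(up_genes, down_genes)) > 0L) {
    stop("signature '", name, "' has genes in both the up and down lists",
         call. = FALSE)
  }
  structure(list(name = name, up_genes = up_genes, down_genes = down_genes),
            class = "gene_signature")
}

# Resolve signature members against the matrix gene universe; unresolvable
# members are reported with a warning and dropped.
.resolve_signature <- function(sig, genes) {
  stopifnot(inherits(sig, "gene_signature"))
  missing <- setdiff(c(sig$up_genes, sig$down_genes), genes)
  if (length(missing) > 0L) {
    warning("signature '", sig$name, "': ", length(missing),
            " member gene(s) not in the matrix, dropped: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "", call. = FALSE)
  }
  up <- intersect(sig$up_genes, genes)
  down <- intersect(sig$down_genes, genes)
  if (length(up) + length(down) == 0L) {
    stop("signature '", sig$name, "': no member genes resolve against the ",
         "matrix", call. = FALSE)
  }
  gene_signature(sig$name, up_genes = if (length(up)) up else character(),
                 down_genes = down)
}

.new_scores <- function(score, s_up, s_down, method, sig, barcodes) {
  structure(
    list(score = stats::setNames(score, barcodes),
         s_up = s_up, s_down = s_down,
         method = method, signature = sig$name),
    class = "signature_scores"
  )
}

#' @export
print.signature_scores <- function(x, ...) {
  cat("signature_scores: '", x$signature, "' (", x$method, "), ",
      length(x$score), " cells\n", sep = "")
  print(summary(unname(x$score)))
  invisible(x)
}

#' Rank-index signature score
#'
#' For each cell, all genes are ranked by z-scored expression in ascending
#' order (rank 1 = lowest; ties get the average rank), and the ranks of the
#' signature members are summed. With a bidirectional signature the
#' down-member rank sum is subtracted from the up-member rank sum, so larger
#' scores always mean the signature is more expressed.
#'
#' @param sce A SingleCellExperiment with a `scaled` assay (see
#'   [scale_genes()]), or a plain gene-by-cell matrix of z-scored expression.
#' @param sig A [gene_signature()]; members missing from the matrix are
#'   dropped with a warning.
#' @return A `signature_scores` object with per-cell `score`, the separate
#'   `s_up`/`s_down` rank sums, and method tag `"rank"`.
#' @export
rank_score <- function(sce, sig) {
  m <- as.matrix(.get_matrix(sce, "scaled"))
  sig <- .resolve_signature(sig, rownames(m))
  ranks <- apply(m, 2L, rank)          # ascending, average ties
  up_idx <- match(sig$up_genes, rownames(m))
  down_idx <- match(sig$down_genes, rownames(m))
  s_up <- if (length(up_idx)) colSums(ranks[up_idx, , drop = FALSE]) else
    rep(0, ncol(m))
  s_down <- if (length(down_idx)) colSums(ranks[down_idx, , drop = FALSE]) else
    rep(0, ncol(m))
  .new_scores(s_up - s_down, s_up, s_down, "rank", sig, colnames(m))
}

#' Expression-sum signature score
#'
#' For each cell, sums the z-scored expression of the up-regulated members
#' and subtracts the sum over the down-regulated members. The up-minus-down
#' orientation keeps the sign convention of [rank_score()] (larger = more
#' expressed); set `direction = "down_minus_up"` for the reversed reading.
#'
#' @inheritParams rank_score
#' @param direction `"up_minus_down"` (default) or `"down_minus_up"`.
#' @return A `signature_scores` object with method tag `"expression_sum"`.
#' @export
expression_sum_score <- function(sce, sig,
                                 direction = c("up_minus_down",
                                               "down_minus_up")) {
  direction <- match.arg(direction)
  m <- as.matrix(.get_matrix(sce, "scaled"))
  sig <- .resolve_signature(sig, rownames(m))
  up_idx <- match(sig$up_genes, rownames(m))
  down_idx <- match(sig$down_genes, rownames(m))
  s_up <- if (length(up_idx)) colSums(m[up_idx, , drop = FALSE]) else
    rep(0, ncol(m))
  s_down <- if (length(down_idx)) colSums(m[down_idx, , drop = FALSE]) else
    rep(0, ncol(m))
  score <- if (direction == "up_minus_down") s_up - s_down else s_down - s_up
  .new_scores(score, s_up, s_down, "expression_sum", sig, colnames(m))
}

# z-score a vector across cells; constant vectors map to zero
.zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Combined signature score
#'
#' Z-scores the rank and expression-sum score vectors across cells and
#' averages them elementwise, giving the scaled-average score used for
#' per-cell signature projection.
#'
#' @param rank_scores,esum_scores `signature_scores` from [rank_score()] and
#'   [expression_sum_score()] over the same signature and cells.
#' @return A `signature_scores` object with method tag `"combined"`.
#' @export
combined_score <- function(rank_scores, esum_scores) {
  stopifnot(inherits(rank_scores, "signature_scores"),
            inherits(esum_scores, "signature_scores"))
  if (rank_scores$signature != esum_scores$signature) {
    stop("scores come from different signatures", call. = FALSE)
  }
  if (length(rank_scores$score) != length(esum_scores$score) ||
      !identical(names(rank_scores$score), names(esum_scores$score))) {
    stop("cell sets of the two score vectors do not match", call. = FALSE)
  }
  z <- (.zscore(rank_scores$score) + .zscore(esum_scores$score)) / 2
  .new_scores(z, s_up = NULL, s_down = NULL, "combined",
              list(name = rank_scores$signature), names(rank_scores$score))
}

#' High-score cell mask
#'
#' Flags cells whose score lies strictly above the given percentile of the
#' score distribution over all cells (linear-interpolation percentile). Used
#' to outline the region of highly scored cells.
#'
#' @param scores A `signature_scores` object or a numeric vector.
#' @param percentile Percentile threshold in `[0, 100]` (default 10).
#' @return A logical vector, one entry per cell.
#' @export
high_score_mask <- function(scores, percentile = 10) {
  x <- if (inherits(scores, "signature_scores")) scores$score else scores
  if (length(x) == 0L) stop("empty score vector", call. = FALSE)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile < 0 || percentile > 100) {
    stop("'percentile' must lie in [0, 100]", call. = FALSE)
  }
  x > quantile(x, percentile / 100, names = FALSE, type = 7)
}
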