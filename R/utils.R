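# shared internal helpers

#' @importFrom methods is
#' @importFrom stats rbeta rlnorm rnbinom rnorm runif quantile p.adjust
#'   pchisq fisher.test wilcox.test
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Pull a named assay out of an SCE, or pass a plain matrix through.
.get_matrix <- function(x, assay_name) {
  if (methods::is(x, "SingleCellExperiment")) {
    if (!assay_name %in% SummarizedExperiment::assayNames(x)) {
      stop("assay '", assay_name, "' not found; run the upstream step first",
           call. = FALSE)
    }
    SummarizedExperiment::assay(x, assay_name)
  } else if (is.matrix(x) || methods::is(x, "Matrix")) {
    x
  } else {
    stop("expected a SingleCellExperiment or a matrix", call. = FALSE)
  }
}

.get_coldata <- function(x, column, arg = NULL) {
  if (!is.null(arg)) return(arg)
  if (methods::is(x, "SingleCellExperiment") &&
      column %in% colnames(SummarizedExperiment::colData(x))) {
    return(SummarizedExperiment::colData(x)[[column]])
  }
  stop("no '", column, "' column available; pass it explicitly", call. = FALSE)
}

.assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  if (strict && x <= lower) stop("'", name, "' must be > ", lower, call. = FALSE)
  if (!strict && x < lower) stop("'", name, "' must be >= ", lower, call. = FALSE)
  invisible(x)
}
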