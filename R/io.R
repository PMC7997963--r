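#' Write a count matrix as a 10x-style MTX triplet
#'
#' Emits `matrix.mtx` (MatrixMarket sparse triplet, genes as rows),
#' `features.tsv`, `barcodes.tsv` and a `metadata.tsv` holding the cell
#' metadata (barcode, condition, cluster and any further `colData` columns).
#'
#' @param sce A nonempty SingleCellExperiment with a `counts` assay.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @seealso [read_10x_mtx()]
#' @export
write_10x <- function(sce, dir) {
  counts <- .get_matrix(sce, "counts")
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("refusing to write an empty matrix (", nrow(counts), " genes x ",
         ncol(counts), " cells)", call. = FALSE)
  }
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory '", dir, "'", call. = FALSE)
  }
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  meta <- if (methods::is(sce, "SingleCellExperiment")) {
    as.data.frame(SummarizedExperiment::colData(sce))
  } else {
    data.frame(barcode = colnames(counts))
  }
  if (!"barcode" %in% names(meta)) {
    meta <- cbind(barcode = colnames(counts), meta)
  }
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# first existing of path, path.gz
.find_file <- function(dir, name) {
  for (cand in c(file.path(dir, name), file.path(dir, paste0(name, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  NULL
}

.read_lines_maybe_gz <- function(path) {
  con <- if (endsWith(path, ".gz")) gzfile(path) else file(path)
  on.exit(close(con))
  readLines(con)
}

#' Read a 10x-style MTX triplet directory
#'
#' Reads the sparse matrix plus feature and barcode files (plain or
#' gzipped; `genes.tsv` accepted as an alias for `features.tsv`), orients
#' the matrix to genes-by-cells by matching dimensions against the two
#' tables, deduplicates repeated gene IDs by suffixing (with a warning) and
#' attaches `metadata.tsv` as `colData` when present.
#'
#' @param dir Directory holding `matrix.mtx[.gz]`, `features.tsv[.gz]` (or
#'   `genes.tsv[.gz]`) and `barcodes.tsv[.gz]`.
#' @return A SingleCellExperiment with an integer-valued sparse `counts`
#'   assay.
#' @export
read_10x_mtx <- function(dir) {
  mtx_path <- .find_file(dir, "matrix.mtx")
  feat_path <- .find_file(dir, "features.tsv") %||% .find_file(dir, "genes.tsv")
  bc_path <- .find_file(dir, "barcodes.tsv")
  if (is.null(mtx_path) || is.null(feat_path) || is.null(bc_path)) {
    stop("directory '", dir, "' must contain matrix.mtx, features.tsv (or ",
         "genes.tsv) and barcodes.tsv (optionally gzipped)", call. = FALSE)
  }
  m <- if (endsWith(mtx_path, ".gz")) {
    con <- gzfile(mtx_path)
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    Matrix::readMM(con)
  } else {
    Matrix::readMM(mtx_path)
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  feat_lines <- .read_lines_maybe_gz(feat_path)
  features <- vapply(strsplit(feat_lines, "\t"), `[[`, character(1), 1L)
  barcodes <- .read_lines_maybe_gz(bc_path)

  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    # genes x cells already
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
    m <- Matrix::t(m)
  } else {
    stop("matrix is ", nrow(m), " x ", ncol(m), " but there are ",
         length(features), " features and ", length(barcodes), " barcodes",
         call. = FALSE)
  }
  if (anyDuplicated(features)) {
    warning(sum(duplicated(features)), " duplicated gene ID(s) suffixed ",
            "to make them unique", call. = FALSE)
    features <- make.unique(features)
  }
  barcodes <- make.unique(barcodes)
  dimnames(m) <- list(features, barcodes)

  coldata <- S4Vectors::DataFrame(barcode = barcodes, row.names = barcodes)
  meta_path <- .find_file(dir, "metadata.tsv")
  if (!is.null(meta_path)) {
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, check.names = FALSE)
    if ("barcode" %in% names(meta)) {
      meta <- meta[match(barcodes, meta$barcode), , drop = FALSE]
      coldata <- S4Vectors::DataFrame(meta, row.names = barcodes)
    }
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = coldata
  )
}

#' Read gene signatures from a GMT file
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. A line
#' named `NAME_down` is merged as the down-regulated member list of the
#' signature `NAME` from the same file; an orphan `NAME_down` line becomes a
#' down-only signature. Input order is preserved.
#'
#' @param path Path to the GMT file.
#' @return A named list of [gene_signature()] objects (empty, with a
#'   warning, for an empty file).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file '", path, "' not found", call. = FALSE)
  lines <- .read_lines_maybe_gz(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("GMT file '", path, "' is empty", call. = FALSE)
    return(list())
  }
  raw <- vector("list", length(lines))
  names_raw <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields",
           call. = FALSE)
    }
    names_raw[i] <- fields[[1]]
    raw[[i]] <- fields[-(1:2)]
  }
  names(raw) <- names_raw

  sigs <- list()
  for (nm in names_raw) {
    if (endsWith(nm, "_down")) {
      base <- sub("_down$", "", nm)
      if (base %in% names_raw) next  # merged below into its base signature
      sigs[[nm]] <- gene_signature(nm, up_genes = character(),
                                   down_genes = raw[[nm]])
    } else {
      down_nm <- paste0(nm, "_down")
      down <- if (down_nm %in% names_raw) raw[[down_nm]] else character()
      sigs[[nm]] <- gene_signature(nm, up_genes = raw[[nm]], down_genes = down)
    }
  }
  sigs
}
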