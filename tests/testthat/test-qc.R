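# Toy matrix with controllable mito share and detected-gene counts: genes
# "mt-1" plus g2..g(n); each column is built to hit exact boundaries.
make_qc_fixture <- function() {
  n_genes <- 1000
  counts <- matrix(0L, nrow = n_genes, ncol = 4)
  rownames(counts) <- c("mt-1", paste0("g", 2:n_genes))
  colnames(counts) <- c("mito11", "mito10", "genes499", "genes500")
  # 11% mito, 600 detected genes
  counts["mt-1", "mito11"] <- 11L
  counts[2:600, "mito11"] <- 1L
  counts["mt-1", "mito11"] <- ceiling(0.11 * 599 / 0.89)  # share > 10%
  # exactly 10% mito: 90 non-mito counts over 599 genes + 10 mito
  counts[, "mito10"] <- 0L
  counts[2:600, "mito10"] <- 1L
  counts[2, "mito10"] <- 302L  # non-mito total 900
  counts["mt-1", "mito10"] <- 100L  # 100 / 1000 = 10% exactly
  # 499 and 500 detected genes, no mito
  counts[2:500, "genes499"] <- 1L
  counts[2:501, "genes500"] <- 1L
  counts
}

test_that("cell filter applies strict inequalities at both QC boundaries", {
  counts <- make_qc_fixture()
  m <- counts[, "mito10"]
  expect_equal(m[["mt-1"]] / sum(m), 0.10)        # fixture sanity
  expect_equal(sum(counts[, "genes500"] > 0), 500)
  qc <- qc_config()  # defaults: >10% mito excluded, <500 genes excluded
  kept <- suppressMessages(filter_cells(make_sce(counts), qc))
  expect_setequal(colnames(kept), c("mito10", "genes500"))
  log <- attr(kept, "qc_log")
  expect_equal(log$n_fail_mito, 1)
  expect_equal(log$n_fail_genes, 1)
})

test_that("gene filter keeps only genes present in strictly more than 3 cells", {
  counts <- matrix(0L, nrow = 4, ncol = 6)
  rownames(counts) <- c("in3", "in4", "allzero", "everywhere")
  counts["in3", 1:3] <- 1L
  counts["in4", 1:4] <- 1L
  counts["everywhere", ] <- 2L
  kept <- suppressMessages(filter_genes(make_sce(counts), qc_config()))
  expect_setequal(rownames(kept), c("in4", "everywhere"))
})

test_that("cell and gene filters are each idempotent and their order matters", {
  sim <- quick_sim(seed = 21, n_genes = 400, n_cells = 150)
  qc <- qc_config(min_genes_per_cell = 150, min_cells_per_gene = 170)
  cells_once <- suppressMessages(filter_cells(sim$sce, qc))
  cells_twice <- suppressMessages(filter_cells(cells_once, qc))
  expect_identical(colnames(cells_once), colnames(cells_twice))
  genes_once <- suppressMessages(filter_genes(cells_once, qc))
  genes_twice <- suppressMessages(filter_genes(genes_once, qc))
  expect_identical(rownames(genes_once), rownames(genes_twice))
  # the workflow fixes the cells-first order; the reverse order retains a
  # different gene set because removing cells lowers per-gene detection
  # counts (the threshold here sits in the bulk of the detection
  # distribution so boundary genes flip)
  reversed <- suppressMessages(filter_cells(filter_genes(sim$sce, qc), qc))
  expect_false(identical(sort(rownames(genes_once)),
                         sort(rownames(reversed))))
})

test_that("log-normalization matches log1p(count/total * s) and conserves totals", {
  counts <- matrix(c(1, 3), nrow = 2,
                   dimnames = list(c("a", "b"), "cell1"))
  counts <- cbind(counts, cell2 = c(0, 5))
  norm <- normalize_log(make_sce(counts), qc_config())
  logc <- as.matrix(SummarizedExperiment::assay(norm, "logcounts"))
  expect_equal(logc[, "cell1"], c(a = log1p(2500), b = log1p(7500)),
               tolerance = 1e-12)
  expect_identical(logc["a", "cell2"], 0)  # zero count stays exactly zero
  # doubling a cell's counts leaves its normalized vector unchanged
  norm2 <- normalize_log(make_sce(counts * 2), qc_config())
  expect_equal(as.matrix(SummarizedExperiment::assay(norm2, "logcounts")),
               logc, tolerance = 1e-12)
  # conservation on a random matrix: sum(expm1(normalized)) == scale factor
  sim <- quick_sim(seed = 22, n_genes = 200, n_cells = 40)
  norm3 <- normalize_log(sim$sce, qc_config())
  sums <- Matrix::colSums(expm1(
    SummarizedExperiment::assay(norm3, "logcounts")))
  expect_equal(sums, rep(1e4, ncol(norm3)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("normalization refuses zero-total cells", {
  counts <- matrix(c(1, 0, 0, 0), nrow = 2)
  expect_error(normalize_log(make_sce(counts), qc_config()), "filter_cells")
})

test_that("gene scaling centers, standardizes with n-1, zeroes constants, clips", {
  m <- rbind(lin = c(1, 2, 3), const = c(5, 5, 5))
  scaled <- scale_genes(m, qc_config())
  expect_equal(scaled["lin", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(scaled["const", ], c(0, 0, 0), ignore_attr = TRUE)
  # an extreme outlier is truncated at the clip value
  out <- c(rep(0, 50), 100)
  scaled_out <- scale_genes(rbind(out, seq_along(out)),
                            qc_config(clip_value = 3))
  expect_equal(max(scaled_out), 3)
  # contract on random data: per-gene mean 0, sd 1 before clipping
  set.seed(23)
  r <- matrix(rnorm(2000), nrow = 40)
  s <- scale_genes(r, qc_config(clip_value = NULL))
  expect_lt(max(abs(rowMeans(s))), 1e-10)
  expect_equal(apply(s, 1, sd), rep(1, 40), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(scale_genes(r[, 1, drop = FALSE], qc_config()), "2 cells")
})

test_that("equal-size downsampling is per-group, exact, seeded and validated", {
  sim <- quick_sim(seed = 24, n_genes = 100, n_cells = 60)
  down <- downsample_equal(sim$sce, "condition", 40, seed = 9)
  expect_equal(unname(table(down$condition)), c(40L, 40L), ignore_attr = TRUE)
  down2 <- downsample_equal(sim$sce, "condition", 40, seed = 9)
  expect_identical(colnames(down), colnames(down2))
  down3 <- downsample_equal(sim$sce, "condition", 40, seed = 10)
  expect_false(identical(colnames(down), colnames(down3)))
  # n equal to the group size returns the group intact
  full <- downsample_equal(sim$sce, "condition", 60, seed = 1)
  expect_setequal(colnames(full), colnames(sim$sce))
  expect_error(downsample_equal(sim$sce, "condition", 61, seed = 1),
               "shSELP|shNC")
})

test_that("an all-failing QC input raises an explicit empty-result error", {
  counts <- matrix(1L, nrow = 10, ncol = 3)
  rownames(counts) <- c("mt-1", paste0("g", 2:10))
  expect_error(
    suppressMessages(filter_cells(make_sce(counts), qc_config())),
    "no cells survive"
  )
})
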