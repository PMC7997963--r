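# One-cell expression matrix in which gene g_r holds descending rank r
# (g1 highest, g_ntot lowest), tie-free.
matrix_with_ranks <- function(n_tot) {
  matrix(rev(seq_len(n_tot)), ncol = 1,
         dimnames = list(paste0("g", 1:n_tot), "cell1"))
}

test_that("CERNO F matches the closed form and its chi-square p-value", {
  # signature at descending ranks {1, 2} of 10 genes
  m <- matrix_with_ranks(10)
  res <- cerno_cell(m, gene_signature("s", c("g1", "g2")),
                    condition = "A")
  f_expected <- -2 * (log(1 / 10) + log(2 / 10))
  expect_equal(res$F, f_expected, tolerance = 1e-12)
  expect_equal(res$F, 7.824046, tolerance = 1e-6)
  # independent upper-tail oracle: numeric integration of the chi^2_4 density
  dens <- function(x) stats::dchisq(x, df = 4)
  p_oracle <- stats::integrate(dens, f_expected, Inf,
                               rel.tol = 1e-12)$value
  expect_equal(res$p, p_oracle, tolerance = 1e-10)
})

test_that("signature genes ranked last give F = 0 and p = 1", {
  m <- matrix_with_ranks(10)
  res <- cerno_cell(m, gene_signature("s", "g10"), condition = "A")
  expect_equal(res$F, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("mean F over uniform random ranks approaches 2N", {
  # the chi-square law is asymptotic in the total gene count: discrete
  # ranks give E[F] = N * (2 - ln(2*pi*N_tot)/N_tot + O(1/N_tot)), so the
  # check runs at a study-scale N_tot where the bias is ~0.2%
  set.seed(41)
  n_tot <- 2000
  n_cells <- 10000
  m <- matrix(rnorm(n_tot * n_cells), nrow = n_tot,
              dimnames = list(paste0("g", 1:n_tot), NULL))
  res <- cerno_cell(m, gene_signature("s", paste0("g", 1:5)),
                    condition = rep("A", n_cells))
  expect_equal(mean(res$F), 10, tolerance = 0.02)
})

test_that("tied ranks from sparse counts shift F conservatively, never anticonservatively", {
  # small-integer counts tie large rank blocks; averaging a block's ranks
  # raises the mean log relative rank (Jensen), so F sits below its 2N
  # null mean and per-cell p-values lean conservative
  sim <- simulate_counts(sim_config(
    n_genes = 1000, n_cells_per_condition = 400, n_clusters = 1,
    baseline_sd_log = 0, seed = 44
  ))
  qc <- qc_config(min_genes_per_cell = 0)
  sce <- normalize_log(filter_genes(sim$sce, qc, verbose = FALSE), qc)
  res <- suppressWarnings(
    cerno_cell(sce, gene_signature("s", paste0("g", 1:50)))
  )
  expect_lt(mean(res$F), 100)
  expect_gt(mean(res$p), 0.5)
  # conservative means the FDR-filtered enrichment call stays controlled
  expect_equal(mean(fdr_correct(res)$q < 0.05), 0, tolerance = 0.005)
})

test_that("improving every signature gene's rank raises F and lowers p", {
  sig <- gene_signature("s", c("g3", "g7"))
  m1 <- matrix(as.numeric(10:1), ncol = 1,
               dimnames = list(paste0("g", 1:10), "c"))
  m2 <- m1
  m2[c("g3", "g7"), 1] <- c(11, 10.5)  # both members move to the top
  r1 <- cerno_cell(m1, sig, condition = "A")
  r2 <- cerno_cell(m2, sig, condition = "A")
  expect_gt(r2$F, r1$F)
  expect_lt(r2$p, r1$p)
})

test_that("CERNO uses average ranks for ties, independent of gene order", {
  m <- matrix(c(5, 0, 0, 0, 1), ncol = 1,
              dimnames = list(paste0("g", 1:5), "c"))
  res <- cerno_cell(m, gene_signature("s", "g3"), condition = "A")
  # zeros occupy descending ranks 3,4,5 -> average 4
  expect_equal(res$F, -2 * log(4 / 5), tolerance = 1e-12)
  perm <- m[c(3, 1, 5, 2, 4), , drop = FALSE]
  expect_equal(cerno_cell(perm, gene_signature("s", "g3"),
                          condition = "A")$F, res$F)
})

test_that("BH correction runs within condition and matches the step-up definition", {
  res <- structure(
    data.frame(barcode = paste0("c", 1:6),
               condition = c(rep("A", 4), "B", "B"),
               F = 0, p = c(0.01, 0.02, 0.03, 0.04, 0.5, 0.001),
               q = NA_real_),
    class = c("cerno_result", "data.frame")
  )
  out <- fdr_correct(res)
  expect_equal(out$q[1:4], rep(0.04, 4))          # direct BH computation
  expect_equal(out$q[5:6], bh_oracle(c(0.5, 0.001)))
  # condition B corrected separately from A
  expect_equal(out$q[6], 0.002)
  # all-ones and single-observation edge cases
  res$p <- rep(1, 6)
  expect_equal(fdr_correct(res)$q, rep(1, 6))
  single <- res[1, ]
  single$p <- 0.2
  class(single) <- c("cerno_result", "data.frame")
  expect_equal(fdr_correct(single)$q, 0.2)
})

test_that("BH q-values keyed by barcode are invariant to cell order", {
  set.seed(42)
  res <- structure(
    data.frame(barcode = paste0("c", 1:50),
               condition = rep(c("A", "B"), 25),
               F = 0, p = runif(50), q = NA_real_),
    class = c("cerno_result", "data.frame")
  )
  out1 <- fdr_correct(res)
  shuffled <- res[sample(50), ]
  class(shuffled) <- c("cerno_result", "data.frame")
  out2 <- fdr_correct(shuffled)
  expect_equal(setNames(out1$q, out1$barcode)[out2$barcode],
               setNames(out2$q, out2$barcode))
})

test_that("Fisher exact p matches exhaustive enumeration on all small tables", {
  max_margin <- 15
  checked <- 0
  for (a in 0:8) for (b in 0:8) for (c_ in 0:8) for (d in 0:8) {
    if (a + b == 0 || c_ + d == 0) next
    if (a + b > max_margin || c_ + d > max_margin ||
        a + c_ > max_margin || b + d > max_margin) next
    p_pkg <- cernoscore:::.fisher_2x2(a, b, c_, d)$p
    expect_equal(p_pkg, fisher_enum_oracle(a, b, c_, d), tolerance = 1e-12,
                 label = sprintf("table (%d,%d;%d,%d)", a, b, c_, d))
    checked <- checked + 1
  }
  expect_gt(checked, 5000)
})

test_that("Fisher p on reference tables matches hand enumeration", {
  expect_equal(cernoscore:::.fisher_2x2(5, 5, 5, 5)$p, 1)
  expect_equal(cernoscore:::.fisher_2x2(5, 5, 5, 5)$odds_ratio, 1)
  expect_equal(cernoscore:::.fisher_2x2(2, 8, 8, 2)$p, 4252 / 184756,
               tolerance = 1e-12)
  expect_equal(cernoscore:::.fisher_2x2(10, 0, 0, 10)$p, 2 / choose(20, 10),
               tolerance = 1e-12)
})

test_that("condition enrichment builds the 2x2 table from q-values and names the direction", {
  res <- structure(
    data.frame(barcode = paste0("c", 1:20),
               condition = rep(c("A", "B"), each = 10),
               F = 0,
               p = c(rep(0.001, 8), 0.9, 0.9, rep(0.9, 8), 0.001, 0.001),
               q = c(rep(0.001, 8), 0.9, 0.9, rep(0.9, 8), 0.001, 0.001)),
    class = c("cerno_result", "data.frame")
  )
  fe <- fisher_condition_enrichment(res, q_threshold = 0.05)
  expect_equal(unname(fe$table), matrix(c(8, 2, 2, 8), 2, byrow = TRUE))
  expect_equal(fe$p, 4252 / 184756, tolerance = 1e-12)
  expect_equal(fe$odds_ratio, 16)
  expect_identical(fe$enriched_condition, "A")
  # missing q or a single condition are refused
  res$q <- NA_real_
  expect_error(fisher_condition_enrichment(res), "fdr_correct")
  one <- res[res$condition == "A", ]
  one$q <- one$p
  class(one) <- c("cerno_result", "data.frame")
  expect_error(fisher_condition_enrichment(one), "two conditions")
})

test_that("Wilcoxon rank-sum: exact enumeration, ties, and approximation agreement", {
  w <- wilcoxon_score_test(c(1, 2, 3, 4, 5, 6),
                           rep(c("A", "B"), each = 3))
  expect_true(w$exact)
  expect_equal(w$p, 0.1)
  expect_equal(w$p, wilcox_enum_oracle(c(1, 2, 3), c(4, 5, 6)))
  # identical groups: no separation, p = 1
  same <- wilcoxon_score_test(rep(c(1, 2, 3), 2),
                              rep(c("A", "B"), each = 3))
  expect_false(same$exact)
  expect_equal(same$p, 1)
  # exact and approximate paths agree closely at n = 8 per group
  set.seed(43)
  x <- rnorm(8); y <- rnorm(8, 0.5)
  exact_p <- wilcox_enum_oracle(x, y)
  approx_p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  )
  pkg_p <- wilcoxon_score_test(c(x, y), rep(c("A", "B"), each = 8))$p
  expect_equal(pkg_p, exact_p, tolerance = 1e-12)
  expect_lt(abs(approx_p - exact_p), 0.01)
  expect_error(wilcoxon_score_test(1:4, rep("A", 4)), "two conditions")
})
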