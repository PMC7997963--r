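#!/usr/bin/env Rscript
# Stage 1: simulate a two-condition (shSELP vs shNC) droplet scRNA-seq study
# with multiple cell subpopulations and two planted signature programs:
#  - a 50-gene activation program up-regulated in shSELP, paired with a
#    20-gene homeostatic program down-regulated there (bidirectional), and
#  - a 40-gene antigen-presentation/chemokine-like program, also shSELP-up.
# Writes the 10x-style matrix, the ground truth, and the signatures as GMT.

suppressPackageStartupMessages(library(cernoscore))

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

activation_up <- paste0("g", 1:50)
homeostatic_down <- paste0("g", 51:70)
antigen_up <- paste0("g", 71:110)

cfg <- sim_config(
  n_genes = 3000,
  n_cells_per_condition = 1200,
  n_clusters = 4,
  planted_effects = list(
    planted_effect("activation", "shSELP",
                   up_genes = activation_up, down_genes = homeostatic_down,
                   up_log_fold = 1.0, down_log_fold = -1.0),
    planted_effect("antigen_presentation", "shSELP",
                   up_genes = antigen_up, up_log_fold = 0.5)
  ),
  seed = 20260928L
)

sim <- simulate_counts(cfg)
write_10x(sim$sce, file.path(outdir, "counts_10x"))
write.table(sim$truth$gene, file.path(outdir, "truth_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$cell, file.path(outdir, "truth_cells.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

gmt <- c(
  paste(c("activation", "planted shSELP-up program", activation_up),
        collapse = "\t"),
  paste(c("activation_down", "planted shSELP-down homeostatic program",
          homeostatic_down), collapse = "\t"),
  paste(c("antigen_presentation", "planted shSELP-up program", antigen_up),
        collapse = "\t")
)
writeLines(gmt, file.path(outdir, "signatures.gmt"))

message(sprintf("simulated %d genes x %d cells (%s)",
                nrow(sim$sce), ncol(sim$sce),
                paste(names(table(sim$sce$condition)),
                      table(sim$sce$condition), collapse = ", ")))
message("wrote ", outdir)
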