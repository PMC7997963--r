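#' Run the full signature-enrichment workflow
#'
#' Executes the analysis end-to-end: input (a 10x MTX directory with cell
#' metadata, or a simulation block), cell and gene QC, log-normalization,
#' per-gene scaling, optional equal-size downsampling, per-signature scoring
#' (rank, expression-sum, combined), the per-cell CERNO test with
#' per-condition FDR correction, the cross-condition Fisher and Wilcoxon
#' tests, and — when cluster labels are available — one-vs-rest marker
#' detection and cluster-composition shift tests. All result tables are
#' written as TSV under `outdir` together with a JSON run manifest (config
#' hash, seed, package version, per-stage entity counts) that suffices to
#' re-run the pipeline bit-identically.
#'
#' @param config A named list (see Details) or the path to a YAML file with
#'   the same structure. Exactly one of `input` (fields `mtx_dir`, optional
#'   `gmt`) or `simulation` (fields of [sim_config()], plus optional
#'   `signature_size`/`planted` shortcuts) must be present. Optional blocks:
#'   `qc` (fields of [qc_config()]), `downsample` (`n_per_group`),
#'   `enrichment` (`q_threshold`, `alternative`, `matrix_use`), `markers`
#'   (`logfc_min`, `min_pct`), `signatures` (named lists with `up`/`down`
#'   gene vectors, used when no GMT file is given).
#' @param outdir Output directory, created if needed.
#' @param seed Integer seed applied to simulation and downsampling.
#' @return Invisibly, a list with the final `sce`, the per-signature results
#'   and the manifest.
#' @export
run_pipeline <- function(config, outdir, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file '", config, "' not found", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim) {
    stop("config must contain exactly one of 'input' or 'simulation'",
         call. = FALSE)
  }
  # validate referenced files before any computation
  if (has_input) {
    if (is.null(config$input$mtx_dir) || !dir.exists(config$input$mtx_dir)) {
      stop("input$mtx_dir missing or not a directory", call. = FALSE)
    }
    if (!is.null(config$input$gmt) && !file.exists(config$input$gmt)) {
      stop("GMT file '", config$input$gmt, "' not found", call. = FALSE)
    }
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  qc <- do.call(qc_config, config$qc %||% list())
  counts_log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- input -----------------------------------------------------------
  truth <- NULL
  sce <- if (has_sim) {
    stage("simulate", {
      sim_args <- config$simulation
      sim_args$planted_effects <- lapply(
        sim_args$planted_effects %||% list(),
        function(pe) do.call(planted_effect, pe)
      )
      sim_args$seed <- seed
      sim <- simulate_counts(do.call(sim_config, sim_args))
      truth <- sim$truth
      write_10x(sim$sce, file.path(outdir, "simulated_counts"))
      utils::write.table(truth$gene,
                         file.path(outdir, "sim_truth_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(truth$cell,
                         file.path(outdir, "sim_truth_cells.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sim$sce
    })
  } else {
    stage("read_input", read_10x_mtx(config$input$mtx_dir))
  }
  counts_log$input <- dim(sce)

  sigs <- stage("signatures", {
    if (has_input && !is.null(config$input$gmt)) {
      read_gmt(config$input$gmt)
    } else if (!is.null(config$signatures)) {
      lapply(seq_along(config$signatures), function(i) {
        s <- config$signatures[[i]]
        gene_signature(names(config$signatures)[i],
                       up_genes = s$up %||% character(),
                       down_genes = s$down %||% character())
      })
    } else {
      list()
    }
  })

  # --- QC / normalization ---------------------------------------------
  sce <- stage("filter_cells", filter_cells(sce, qc, verbose = FALSE))
  counts_log$after_cell_filter <- dim(sce)
  sce <- stage("filter_genes", filter_genes(sce, qc, verbose = FALSE))
  counts_log$after_gene_filter <- dim(sce)
  if (!is.null(config$downsample$n_per_group)) {
    sce <- stage("downsample", downsample_equal(
      sce, config$downsample$group_key %||% "condition",
      config$downsample$n_per_group, seed = seed + 1L))
    counts_log$after_downsample <- dim(sce)
  }
  sce <- stage("normalize", normalize_log(sce, qc))
  sce <- stage("scale", scale_genes(sce, qc))

  # --- per-signature scoring and enrichment ----------------------------
  enr_cfg <- config$enrichment %||% list()
  q_thr <- enr_cfg$q_threshold %||% 0.05
  alternative <- enr_cfg$alternative %||% "two.sided"
  matrix_use <- enr_cfg$matrix_use %||% "logcounts"
  condition <- SummarizedExperiment::colData(sce)$condition
  two_conditions <- !is.null(condition) &&
    length(unique(condition)) == 2L

  score_rows <- list()
  summary_rows <- list()
  cerno_tables <- list()
  for (sig in sigs) {
    rs <- stage(paste0("score:", sig$name), rank_score(sce, sig))
    es <- stage(paste0("score:", sig$name), expression_sum_score(sce, sig))
    cs <- combined_score(rs, es)
    for (sc in list(rs, es, cs)) {
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        barcode = names(sc$score), signature = sig$name,
        method = sc$method, score = unname(sc$score),
        stringsAsFactors = FALSE
      )
    }
    if (two_conditions) {
      cr <- stage(paste0("cerno:", sig$name),
                  cerno_cell(sce, sig, matrix_use = matrix_use))
      cr <- fdr_correct(cr)
      fe <- fisher_condition_enrichment(cr, q_threshold = q_thr,
                                        alternative = alternative)
      wt <- wilcoxon_score_test(cs, condition)
      cr$enriched <- cr$q < q_thr
      cerno_tables[[sig$name]] <- cr
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        signature = sig$name,
        a = fe$table[1, 1], b = fe$table[1, 2],
        c = fe$table[2, 1], d = fe$table[2, 2],
        odds_ratio = fe$odds_ratio, fisher_p = fe$p,
        enriched_condition = fe$enriched_condition,
        wilcoxon_p = wt$p, stringsAsFactors = FALSE
      )
    }
  }
  if (length(score_rows) > 0L) {
    utils::write.table(do.call(rbind, score_rows),
                       file.path(outdir, "signature_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(cerno_tables) > 0L) {
    cerno_all <- do.call(rbind, lapply(names(cerno_tables), function(nm) {
      cbind(signature = nm, as.data.frame(cerno_tables[[nm]]))
    }))
    utils::write.table(cerno_all, file.path(outdir, "cerno_cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(summary_rows) > 0L) {
    utils::write.table(do.call(rbind, summary_rows),
                       file.path(outdir, "enrichment_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- markers and composition ----------------------------------------
  clusterv <- SummarizedExperiment::colData(sce)$cluster
  if (!is.null(clusterv) && length(unique(clusterv)) >= 2L) {
    mk_cfg <- config$markers %||% list()
    markers <- stage("markers", find_markers(
      sce, logfc_min = mk_cfg$logfc_min %||% 0.25,
      min_pct = mk_cfg$min_pct %||% 0.25))
    utils::write.table(as.data.frame(markers),
                       file.path(outdir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (two_conditions) {
      comp <- stage("composition", cluster_shift_fisher(clusterv, condition))
      utils::write.table(comp, file.path(outdir, "composition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- manifest --------------------------------------------------------
  cfg_path <- file.path(outdir, "config_used.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cernoscore")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stage_dimensions = counts_log,
    n_signatures = length(sigs)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(sce = sce, summary = if (length(summary_rows)) {
    do.call(rbind, summary_rows)
  } else NULL, cerno = cerno_tables, manifest = manifest, truth = truth))
}
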