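#' Full-pipeline configuration
#'
#' Bundles the synthetic-data configuration with every analysis threshold.
#' Defaults are the package's reference analysis settings: FDR 0.05, clumping at
#' r > 0.95 within a 500 kb window, the `r > 0.95` removal rule, prevalence
#' 1/300 for case-control liability conversion and 0.5 for site of onset, at
#' least 2 genes per tested drug, and at least 5 drugs per tested ATC group.
#'
#' @param synthetic a [synthetic_config()].
#' @param fdr FDR significance threshold (q < fdr).
#' @param r_thresh clumping correlation threshold.
#' @param window_bp proximity window for predicted-expression correlations.
#' @param thresholds PTS p-value threshold grid.
#' @param prevalence_case_control population prevalence K for case-control.
#' @param prevalence_site assumed prevalence K for spinal/bulbar onset.
#' @param min_genes_per_drug minimum target genes with statistics per drug.
#' @param min_drugs_per_atc minimum drugs per tested ATC group.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            fdr = 0.05,
                            r_thresh = 0.95,
                            window_bp = 5e5,
                            thresholds = c(1e-6, 1e-4, 1e-3, 0.01, 0.05,
                                           0.1, 0.5, 1),
                            prevalence_case_control = 1 / 300,
                            prevalence_site = 0.5,
                            min_genes_per_drug = 2,
                            min_drugs_per_atc = 5) {
  stop_if_not(inherits(synthetic, "synthetic_config"),
              "'synthetic' must be a synthetic_config()")
  check_fraction(fdr, "fdr")
  check_fraction(r_thresh, "r_thresh")
  check_positive(window_bp, "window_bp")
  stop_if_not(all(thresholds > 0 & thresholds <= 1),
              "thresholds must lie in (0, 1]")
  cfg <- list(synthetic = synthetic, fdr = fdr, r_thresh = r_thresh,
              window_bp = window_bp, thresholds = thresholds,
              prevalence_case_control = prevalence_case_control,
              prevalence_site = prevalence_site,
              min_genes_per_drug = min_genes_per_drug,
              min_drugs_per_atc = min_drugs_per_atc)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain a `synthetic:` block (passed to
#' [synthetic_config()]) and any top-level [pipeline_config()] field.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, y$synthetic %||% list())
  y$synthetic <- NULL
  do.call(pipeline_config, c(list(synthetic = syn), y))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes all stages in order -- simulate, gene discovery, clumping, PTS
#' scoring and association, drug enrichment, observed differential
#' expression and concordance -- writing every stage output as TSV under
#' `out_dir` plus a manifest of file checksums. Re-running with an identical
#' configuration reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stop_if_not(inherits(config, "pipeline_config"),
              "'config' must be a pipeline_config()")
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dir <- function(s) {
    d <- file.path(out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }

  # --- stage 1: simulate ----------------------------------------------
  say("stage simulate")
  sim <- simulate_all(config$synthetic)
  write_synthetic_data(sim, stage_dir("simulate"))

  # --- stage 2: gene discovery ----------------------------------------
  say("stage genes")
  assoc <- fdr_correct(sim$twas$associations)
  hc <- call_high_confidence(assoc, sim$credible_sets$credible_sets,
                             sim$gene_map, fdr_threshold = config$fdr)
  write_tsv(hc, file.path(stage_dir("genes"), "high_confidence.tsv"))

  # --- stage 3: clumping ----------------------------------------------
  say("stage clump")
  pred <- predict_expression(sim$twas$weights, sim$genotypes)
  corr <- pairwise_predicted_correlation(pred, sim$gene_map,
                                         window_bp = config$window_bp)
  cl <- clump(assoc, corr, r_thresh = config$r_thresh,
              known_units = colnames(pred))
  gene_weights <- average_duplicate_genes(cl)
  d <- stage_dir("clump")
  write_tsv(corr, file.path(d, "correlations.tsv"))
  write_tsv(cl$removed, file.path(d, "clump_removed.tsv"))
  write_tsv(cl$retained, file.path(d, "clump_retained.tsv"))
  write_tsv(gene_weights, file.path(d, "gene_weights.tsv"))

  # --- stage 4: PTS ----------------------------------------------------
  say("stage pts")
  weights_by_stratum <- build_pts_weights(cl)
  d <- stage_dir("pts")
  assoc_rows <- list()
  for (co in sim$expression$cohorts) {
    ez <- standardize_expression(co$expression)
    for (stratum in names(weights_by_stratum)) {
      w <- weights_by_stratum[[stratum]]
      if (nrow(w) == 0 || !any(w$gene_id %in% rownames(ez))) next
      pts <- suppressWarnings(compute_pts(ez, w, config$thresholds))
      if (stratum == "all.any") {
        write_tsv(matrix_to_df(pts$scores, "sample_id"),
                  file.path(d, sprintf("scores_%s.tsv", co$cohort_id)))
      }
      for (k in seq_along(config$thresholds)) {
        s <- pts$scores[, k]
        if (anyNA(s)) next
        for (outc in c("case_control", "site_of_onset", "age_at_onset",
                       "survival")) {
          K <- switch(outc, case_control = config$prevalence_case_control,
                      site_of_onset = config$prevalence_site, NULL)
          row <- tryCatch(
            associate(stats::setNames(s, rownames(pts$scores)),
                      co$phenotypes, outcome = outc, K = K),
            error = function(e) NULL)
          if (is.null(row)) next
          row$cohort <- co$cohort_id
          row$stratum <- stratum
          row$threshold <- config$thresholds[k]
          row$n_genes_used <- pts$n_genes_used[k]
          assoc_rows[[length(assoc_rows) + 1L]] <- row
        }
      }
    }
  }
  pts_assoc <- do.call(rbind, assoc_rows)
  write_tsv(pts_assoc, file.path(d, "associations.tsv"))
  pts_meta <- meta_pts(pts_assoc)
  write_tsv(pts_meta, file.path(d, "meta.tsv"))

  # --- stage 5: drug enrichment ---------------------------------------
  say("stage drugs")
  coded <- code_directions(sim$drugs$interactions)
  gcorr <- gene_correlation_from_units(corr)
  enr <- directional_enrichment(gene_weights, coded, gcorr,
                                min_genes = config$min_genes_per_drug)
  d <- stage_dir("drugs")
  if (nrow(enr)) {
    enr <- fdr_drugs(enr)
    atc <- atc_wilcoxon(enr, sim$drugs$atc_map,
                        min_drugs = config$min_drugs_per_atc)
  } else {
    atc <- data.frame()
  }
  write_tsv(enr, file.path(d, "drug_enrichment.tsv"))
  write_tsv(atc, file.path(d, "atc_enrichment.tsv"))

  # --- stage 6: observed DE and concordance ---------------------------
  say("stage de")
  de_by_cohort <- lapply(sim$expression$cohorts, function(co) {
    de_correlation(co$expression, co$phenotypes$status)
  })
  de_meta_tab <- meta_de(de_by_cohort)
  hc_z <- gene_weights[gene_weights$gene_id %in% hc$gene_id, , drop = FALSE]
  conc <- classify_concordance(hc_z[c("gene_id", "Z")], de_meta_tab,
                               fdr = config$fdr)
  d <- stage_dir("de")
  write_tsv(de_meta_tab, file.path(d, "de_meta.tsv"))
  write_tsv(conc, file.path(d, "concordance.tsv"))
  counts <- attr(conc, "counts")
  write_tsv(data.frame(call = names(counts), n = as.integer(counts)),
            file.path(d, "concordance_counts.tsv"))

  # --- manifest --------------------------------------------------------
  yaml::write_yaml(list(
    synthetic = unclass(config$synthetic),
    fdr = config$fdr, r_thresh = config$r_thresh,
    window_bp = config$window_bp, thresholds = config$thresholds,
    prevalence_case_control = config$prevalence_case_control,
    prevalence_site = config$prevalence_site,
    min_genes_per_drug = config$min_genes_per_drug,
    min_drugs_per_atc = config$min_drugs_per_atc
  ), file.path(out_dir, "config.yaml"))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(sim = sim, associations = assoc, high_confidence = hc,
                 clump = cl, gene_weights = gene_weights,
                 pts_associations = pts_assoc, pts_meta = pts_meta,
                 drug_enrichment = enr, atc_enrichment = atc,
                 de_meta = de_meta_tab, concordance = conc,
                 manifest = manifest))
}

#' Run a small end-to-end demonstration pipeline
#'
#' Executes [run_pipeline()] with a reduced synthetic configuration sized to
#' finish in seconds, so the whole analysis can be exercised (and its
#' determinism checked) with zero downloads.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param quiet suppress progress messages.
#' @return invisibly, the [run_pipeline()] result list.
#' @export
pipeline_demo <- function(out_dir, seed = 1L, quiet = TRUE) {
  cfg <- pipeline_config(
    synthetic = synthetic_config(
      n_genes = 120L, n_chromosomes = 3L, n_panels = 2L,
      n_ref_samples = 100L, snps_per_gene = 5L,
      n_cases = 80L, n_controls = 80L,
      n_drugs = 40L, n_atc_groups = 6L, seed = seed
    )
  )
  run_pipeline(cfg, out_dir, quiet = quiet)
}
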