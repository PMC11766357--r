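#' Pipeline run configuration
#'
#' Collects every stage parameter of a full synthetic-cohort run. A persisted
#' configuration plus the seed reproduces the run byte-identically.
#'
#' @param seed root integer seed; each stage consumes a sub-stream seed
#'   derived from it.
#' @param sim a [simulation_config()] (its own seed is overridden by the
#'   root seed's simulate sub-stream).
#' @param libsize_min_fraction QC library-size floor fraction.
#' @param auc_min,basemean_min,p_max candidate filter thresholds (strict).
#' @param C SVM soft-margin cost.
#' @param max_panel_candidates cap on candidates entering the pair search
#'   per contrast (top by AUC then p).
#' @param window reference-selection fold-change window.
#' @param ct_replicates,ct_noise_sd qPCR simulation parameters.
#' @param n_boot bootstrap resamples for AUC CIs.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = simulation_config(),
                            libsize_min_fraction = 0.1, auc_min = 0.75,
                            basemean_min = 10, p_max = 0.05, C = 1,
                            max_panel_candidates = 8, window = 1.2,
                            ct_replicates = 3, ct_noise_sd = 0.2,
                            n_boot = 2000) {
  cfg <- list(seed = as.integer(seed), sim = sim,
              libsize_min_fraction = libsize_min_fraction,
              auc_min = auc_min, basemean_min = basemean_min, p_max = p_max,
              C = C, max_panel_candidates = max_panel_candidates,
              window = window, ct_replicates = ct_replicates,
              ct_noise_sd = ct_noise_sd, n_boot = n_boot)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full discovery-to-validation pipeline on a synthetic cohort
#'
#' Stages: simulate counts -> QC exclusion -> differential expression
#' (unpaired basal-vs-control Wald, paired post-tx-vs-basal Wilcoxon) ->
#' diagnostic profiles and candidate filter -> pairwise SVM/LOOCV panel
#' search -> stability reference selection -> simulated qPCR validation with
#' delta-delta-Ct quantification, exact group tests and ROC. All stage
#' outputs, a machine-readable `summary.json`, and a `run_log.txt` with
#' seeds and parameters are written under `out_dir`. A stage failure writes
#' a `FAILED` marker with the message and stops; earlier outputs are kept.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("evsmallrna pipeline run",
                 paste0("package_version: ",
                        as.character(utils::packageVersion("evsmallrna"))),
                 paste0("r_version: ", R.version.string),
                 paste0("root_seed: ", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(paste0("stage: ", name),
                   paste0("error: ", conditionMessage(e))),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate -------------------------------------------------------------
  sim_seed <- sub_seed(config$seed, 1)
  config$sim$seed <- sim_seed
  log_lines <- c(log_lines, paste0("simulate_seed: ", sim_seed))
  sim <- stage("simulate", simulate_counts(config$sim))
  write_count_matrix(sim$counts, file.path(out_dir, "counts.tsv"))
  write_metadata(sim$metadata, file.path(out_dir, "metadata.csv"))
  write_table(sim$truth$features, file.path(out_dir, "truth_features.tsv"))

  # -- qc -------------------------------------------------------------------
  qc <- stage("qc", qc_report(sim$counts, sim$metadata,
                              config$libsize_min_fraction))
  write_table(qc, file.path(out_dir, "qc_report.tsv"))
  flt <- apply_qc(sim$counts, sim$metadata, qc)
  if (!any(flt$metadata$condition == "basal") ||
      !any(flt$metadata$condition == "control"))
    stage("qc", stop("a contrast group was emptied by QC"))

  # -- diffexp + diagnostics per contrast ----------------------------------
  contrasts <- list(basal_vs_control = c("basal", "control"),
                    post_tx_vs_basal = c("post_tx", "basal"))
  cand <- list(); de_tabs <- list(); prof_tabs <- list()
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    de <- stage(paste0("diffexp_", cn), {
      if (cn == "basal_vs_control") wald_test_unpaired(flt$counts,
                                                       flt$metadata, ct)
      else paired_test(flt$counts, flt$metadata, ct)
    })
    prof <- stage(paste0("diagnostics_", cn),
                  diagnostic_profiles(flt$counts, flt$metadata, ct))
    tab <- candidate_filter(de, prof, config$auc_min, config$basemean_min,
                            config$p_max)
    de_tabs[[cn]] <- de; prof_tabs[[cn]] <- prof; cand[[cn]] <- tab
    write_table(de, file.path(out_dir, paste0("diffexp_", cn, ".tsv")))
    write_table(tab, file.path(out_dir, paste0("candidates_", cn, ".tsv")))
  }

  # -- panel search ---------------------------------------------------------
  panel_seed <- sub_seed(config$seed, 2)
  log_lines <- c(log_lines, paste0("panel_seed: ", panel_seed))
  panels <- list()
  for (cn in names(contrasts)) {
    tab <- cand[[cn]]
    feats <- head(tab$feature[tab$candidate], config$max_panel_candidates)
    if (length(feats) >= 2) {
      M <- stage(paste0("panels_", cn),
                 all_pairs_matrix(flt$counts, flt$metadata, feats,
                                  contrasts[[cn]], config$C))
      best <- attr(M, "best_pair")
      bres <- loocv_pair_auc(flt$counts, flt$metadata, best,
                             contrasts[[cn]], config$C, ci = TRUE,
                             n_boot = config$n_boot, seed = panel_seed)
      rfe <- svm_rfe_rank(flt$counts, flt$metadata, feats,
                          contrasts[[cn]], config$C)
      panels[[cn]] <- list(matrix = M, best_pair = best,
                           best_auc = attr(M, "best_auc"),
                           best_ci = bres$cv_auc_ci, rfe = rfe)
      write_table(data.frame(feature = rownames(M), M, check.names = FALSE),
                  file.path(out_dir, paste0("pair_auc_", cn, ".tsv")))
    } else {
      panels[[cn]] <- list(matrix = NULL, best_pair = NULL, best_auc = NA,
                           best_ci = c(NA, NA), rfe = feats)
    }
  }

  # -- reference selection --------------------------------------------------
  stab <- stage("refselect",
                select_reference(flt$counts, flt$metadata,
                                 de_tabs$basal_vs_control, config$window))
  stability_report(stab, file.path(out_dir, "reference_stability.tsv"))
  reference <- stab$feature[1]

  # -- qPCR validation ------------------------------------------------------
  qpcr_seed <- sub_seed(config$seed, 3)
  log_lines <- c(log_lines, paste0("qpcr_seed: ", qpcr_seed))
  assays <- head(cand$basal_vs_control$feature[cand$basal_vs_control$candidate],
                 5)
  qpcr_summary <- NULL
  if (length(assays) >= 1) {
    ct_tab <- stage("qpcr", simulate_ct_table(
      sim$truth, flt$metadata, assays, reference,
      replicates = config$ct_replicates, ct_noise_sd = config$ct_noise_sd,
      seed = qpcr_seed))
    write_ct_table(ct_tab, file.path(out_dir, "ct_table.csv"))
    agg <- aggregate_triplicates(ct_tab)
    rq <- relative_expression(agg, reference, flt$metadata, "control")
    write_table(rq, file.path(out_dir, "relative_expression.tsv"))
    comp <- do.call(rbind, c(
      lapply(assays, function(a)
        compare_groups(rq, flt$metadata, a, c("basal", "control"))),
      lapply(assays, function(a)
        compare_groups(rq, flt$metadata, a, c("post_tx", "basal")))))
    write_table(comp, file.path(out_dir, "qpcr_group_tests.tsv"))
    rocs <- lapply(assays, function(a)
      validation_roc(rq, a, c("basal", "control"),
                     n_boot = config$n_boot, seed = qpcr_seed))
    # oriented AUC: the discovery contrast fixes each assay's direction, so
    # a down-regulated candidate is scored on the inverted axis
    disc_lfc <- cand$basal_vs_control$lfc[
      match(assays, cand$basal_vs_control$feature)]
    qpcr_summary <- list(
      assays = assays,
      group_tests = lapply(seq_len(nrow(comp)), function(i)
        list(assay = comp$assay[i], contrast = comp$contrast[i],
             test = comp$test[i], p = comp$p[i])),
      roc = lapply(seq_along(assays), function(i)
        list(assay = assays[i], auc = rocs[[i]]$auc,
             auc_oriented = if (disc_lfc[i] < 0) 1 - rocs[[i]]$auc else
               rocs[[i]]$auc,
             ci = as.numeric(rocs[[i]]$ci))))
  }

  summary <- list(
    seed = config$seed,
    n_samples_analyzed = nrow(flt$metadata),
    n_excluded = sum(qc$excluded),
    candidates = lapply(cand, function(tab) tab$feature[tab$candidate]),
    best_pair = lapply(panels, function(p)
      list(pair = p$best_pair, cv_auc = p$best_auc,
           ci = as.numeric(p$best_ci))),
    reference_feature = reference,
    true_reference_feature = sim$truth$reference_feature,
    qpcr = qpcr_summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(summary)
}

#' Render a plain-text report from a pipeline run directory
#'
#' Regenerates deterministic candidate tables (FC, p, AUC, SN, SP, PPV, NPV)
#' and a pair-AUC matrix per contrast from the stage outputs; states "no
#' candidates" for empty contrasts.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param path output file (default `report.md` inside `run_dir`).
#' @return path to the report, invisibly.
#' @export
make_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  fmt <- function(x) formatC(x, format = "fg", digits = 4)
  lines <- c("# Pipeline report", "")
  for (cn in c("basal_vs_control", "post_tx_vs_basal")) {
    lines <- c(lines, paste0("## Contrast ", cn), "")
    f <- file.path(run_dir, paste0("candidates_", cn, ".tsv"))
    if (!file.exists(f)) next
    tab <- read.delim(f, stringsAsFactors = FALSE)
    tab <- tab[tab$candidate, ]
    if (nrow(tab) == 0) {
      lines <- c(lines, "no candidates", "")
    } else {
      lines <- c(lines,
                 "feature\tFC\tp\tAUC\tSN\tSP\tPPV\tNPV",
                 vapply(seq_len(nrow(tab)), function(i)
                   paste(tab$feature[i], fmt(tab$fc_signed[i]),
                         fmt(tab$p[i]), round_half_up(tab$auc[i]),
                         round_half_up(tab$sn[i]), round_half_up(tab$sp[i]),
                         round_half_up(tab$ppv[i]), round_half_up(tab$npv[i]),
                         sep = "\t"), character(1)),
                 "")
    }
    pf <- file.path(run_dir, paste0("pair_auc_", cn, ".tsv"))
    if (file.exists(pf)) {
      lines <- c(lines, paste0("### Pair cross-validated AUC (", cn, ")"), "",
                 readLines(pf), "")
    }
  }
  sf <- file.path(run_dir, "reference_stability.tsv")
  if (file.exists(sf)) {
    stab <- read.delim(sf, stringsAsFactors = FALSE)
    lines <- c(lines, "## Selected qPCR reference", "",
               paste0("best: ", stab$feature[1], " (composite rank ",
                      fmt(stab$composite_rank[1]), ")"), "")
  }
  writeLines(lines, path)
  invisible(path)
}
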