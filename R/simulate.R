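#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the study
#' design the pipeline targets: 16 control subjects, 26 paired basal /
#' post-treatment subjects, 3 technical negative controls, and a few hundred
#' small-RNA features of which a small fraction carry planted fold changes.
#'
#' @param n_control number of unpaired control samples.
#' @param n_pairs number of subjects contributing one basal and one
#'   post-treatment sample each.
#' @param n_negative_controls number of technical negative-control samples
#'   (low-depth, no feature structure).
#' @param n_features number of small-RNA features (>= 10).
#' @param frac_de_vs_control fraction of features with a planted basal-vs-
#'   control log2 fold change.
#' @param frac_de_paired fraction of features with a planted post-treatment-
#'   vs-basal log2 fold change.
#' @param lfc_magnitude magnitude (log2 units) of planted fold changes; signs
#'   alternate up/down deterministically.
#' @param dispersion negative-binomial dispersion alpha (variance
#'   m + alpha * m^2).
#' @param mean_log_expression mean of log2 baseline feature means.
#' @param sd_log_expression SD of log2 baseline feature means.
#' @param libsize_log_sd SD (log2) of sample-specific size factors.
#' @param subject_effect_sd SD (log2) of the subject effect shared by a
#'   subject's basal/post-treatment pair.
#' @param negctrl_depth_factor negative-control library depth as a fraction of
#'   the median real-sample library size, in (0, 1].
#' @param seed integer seed; fully determines all generator output.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(n_control = 16, n_pairs = 26,
                              n_negative_controls = 3, n_features = 800,
                              frac_de_vs_control = 0.04, frac_de_paired = 0.04,
                              lfc_magnitude = 2, dispersion = 0.2,
                              mean_log_expression = 5, sd_log_expression = 2,
                              libsize_log_sd = 0.4, subject_effect_sd = 0.5,
                              negctrl_depth_factor = 0.02, seed = 1L) {
  cfg <- list(n_control = n_control, n_pairs = n_pairs,
              n_negative_controls = n_negative_controls,
              n_features = n_features,
              frac_de_vs_control = frac_de_vs_control,
              frac_de_paired = frac_de_paired,
              lfc_magnitude = lfc_magnitude, dispersion = dispersion,
              mean_log_expression = mean_log_expression,
              sd_log_expression = sd_log_expression,
              libsize_log_sd = libsize_log_sd,
              subject_effect_sd = subject_effect_sd,
              negctrl_depth_factor = negctrl_depth_factor,
              seed = seed)
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid simulation config: `", field, "` ", what,
                          call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(n_control) && n_control >= 1, "n_control", "must be >= 1")
  chk(num1(n_pairs) && n_pairs >= 1, "n_pairs", "must be >= 1")
  chk(num1(n_negative_controls) && n_negative_controls >= 0,
      "n_negative_controls", "must be >= 0")
  chk(num1(n_features) && n_features >= 10, "n_features", "must be >= 10")
  chk(num1(frac_de_vs_control) && frac_de_vs_control >= 0 &&
        frac_de_vs_control <= 1, "frac_de_vs_control", "must be in [0, 1]")
  chk(num1(frac_de_paired) && frac_de_paired >= 0 && frac_de_paired <= 1,
      "frac_de_paired", "must be in [0, 1]")
  chk(round(frac_de_vs_control * n_features) +
        round(frac_de_paired * n_features) < n_features,
      "frac_de_vs_control", "+ frac_de_paired plant more features than exist")
  chk(num1(lfc_magnitude) && lfc_magnitude > 0, "lfc_magnitude",
      "must be > 0")
  chk(num1(dispersion) && dispersion > 0, "dispersion", "must be > 0")
  chk(num1(mean_log_expression), "mean_log_expression", "must be finite")
  chk(num1(sd_log_expression) && sd_log_expression >= 0, "sd_log_expression",
      "must be >= 0")
  chk(num1(libsize_log_sd) && libsize_log_sd >= 0, "libsize_log_sd",
      "must be >= 0")
  chk(num1(subject_effect_sd) && subject_effect_sd >= 0, "subject_effect_sd",
      "must be >= 0")
  chk(num1(negctrl_depth_factor) && negctrl_depth_factor > 0 &&
        negctrl_depth_factor <= 1, "negctrl_depth_factor",
      "must be in (0, 1]")
  chk(num1(seed) && seed == round(seed), "seed", "must be an integer")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a small-RNA count matrix with cohort structure
#'
#' Counts are negative-binomial with mean
#' `baseline * 2^(condition LFC) * 2^(subject effect) * size factor` and
#' variance `m + alpha * m^2`. Planted fold changes are assigned to
#' deterministically chosen disjoint feature sets (signs alternating up/down).
#' One non-regulated feature is designated the stable reference: its baseline
#' abundance is set three SD above the mean and its dispersion to a tenth of the
#' global value, emulating a let-7a-like housekeeper. Negative-control samples
#' are drawn from a flat low-mean NB with no feature structure at a depth of
#' `negctrl_depth_factor` times the median real library size.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (integer feature-by-sample matrix), `metadata`
#'   (data.frame: sample_id, condition, subject_id, is_negative_control) and
#'   `truth` (`sim_truth`: per-feature baseline mean, true LFCs and
#'   dispersion, per-sample size factor, reference feature id).
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(simulation_config, config)
  set.seed(config$seed)
  nf <- config$n_features
  feature_ids <- sprintf("sRNA_%04d", seq_len(nf))

  base_log2 <- rnorm(nf, config$mean_log_expression, config$sd_log_expression)
  n_de_c <- round(config$frac_de_vs_control * nf)
  n_de_p <- round(config$frac_de_paired * nf)
  ord <- sample.int(nf)
  de_c <- ord[seq_len(n_de_c)]
  de_p <- ord[n_de_c + seq_len(n_de_p)]
  lfc_bc <- numeric(nf)
  lfc_pb <- numeric(nf)
  if (n_de_c > 0) lfc_bc[de_c] <- rep_len(c(1, -1), n_de_c) * config$lfc_magnitude
  if (n_de_p > 0) lfc_pb[de_p] <- rep_len(c(1, -1), n_de_p) * config$lfc_magnitude

  alpha <- rep(config$dispersion, nf)
  ref_idx <- setdiff(ord, c(de_c, de_p))[1]
  base_log2[ref_idx] <- config$mean_log_expression + 3 * config$sd_log_expression
  alpha[ref_idx] <- config$dispersion / 10

  ctrl_ids <- sprintf("CTRL_%02d", seq_len(config$n_control))
  subj_ids <- sprintf("SUBJ_%02d", seq_len(config$n_pairs))
  basal_ids <- sprintf("EOE_%02d_B", seq_len(config$n_pairs))
  post_ids <- sprintf("EOE_%02d_P", seq_len(config$n_pairs))
  nc_ids <- if (config$n_negative_controls > 0)
    sprintf("NEGCTRL_%02d", seq_len(config$n_negative_controls)) else character()

  real_ids <- c(ctrl_ids, basal_ids, post_ids)
  n_real <- length(real_ids)
  size_factors <- 2^rnorm(n_real, 0, config$libsize_log_sd)
  names(size_factors) <- real_ids
  subject_effect <- rnorm(config$n_pairs, 0, config$subject_effect_sd)

  cond_off <- cbind(control = numeric(nf), basal = lfc_bc,
                    post_tx = lfc_bc + lfc_pb)
  cond <- c(rep("control", config$n_control), rep("basal", config$n_pairs),
            rep("post_tx", config$n_pairs))
  subj_of <- c(rep(NA_integer_, config$n_control),
               seq_len(config$n_pairs), seq_len(config$n_pairs))

  counts <- matrix(0L, nf, n_real, dimnames = list(feature_ids, real_ids))
  for (j in seq_len(n_real)) {
    log2mu <- base_log2 + cond_off[, cond[j]] +
      if (is.na(subj_of[j])) 0 else subject_effect[subj_of[j]]
    mu <- 2^log2mu * size_factors[j]
    counts[, j] <- rnbinom(nf, mu = mu, size = 1 / alpha)
  }

  if (length(nc_ids) > 0) {
    med_lib <- median(colSums(counts))
    flat_mu <- config$negctrl_depth_factor * med_lib / nf
    nc <- matrix(rnbinom(nf * length(nc_ids), mu = flat_mu,
                         size = 1 / config$dispersion),
                 nf, length(nc_ids), dimnames = list(feature_ids, nc_ids))
    counts <- cbind(counts, nc)
  }

  metadata <- data.frame(
    sample_id = c(real_ids, nc_ids),
    condition = c(cond, rep("negative_control", length(nc_ids))),
    subject_id = c(ifelse(is.na(subj_of), "", subj_ids[subj_of]),
                   rep("", length(nc_ids))),
    is_negative_control = c(rep(FALSE, n_real), rep(TRUE, length(nc_ids))),
    stringsAsFactors = FALSE
  )

  truth <- list(
    features = data.frame(
      feature_id = feature_ids,
      base_mean = 2^base_log2,
      lfc_basal_vs_control = lfc_bc,
      lfc_post_vs_basal = lfc_pb,
      dispersion = alpha,
      stringsAsFactors = FALSE
    ),
    size_factors = size_factors,
    reference_feature = feature_ids[ref_idx]
  )
  class(truth) <- "sim_truth"

  validate_count_matrix(counts)
  validate_metadata(metadata, colnames(counts))
  list(counts = counts, metadata = metadata, truth = truth)
}

#' Simulate a long-format qPCR Ct table from simulation ground truth
#'
#' Each replicate Ct is `base Ct - log2(relative abundance) + N(0, ct_noise_sd)`
#' where the relative abundance of an assay in a sample is `2^(condition LFC)`
#' from the ground truth (1 for controls and for the reference assay in every
#' condition). The per-assay base Ct is `35 - log2(baseline mean + 1)` so that
#' abundant assays amplify earlier. Negative-control samples are not assayed.
#'
#' @param truth `sim_truth` from [simulate_counts()].
#' @param metadata sample metadata data.frame.
#' @param assays character vector of feature ids to assay.
#' @param reference reference feature id (always included).
#' @param replicates technical replicates per (sample, assay), >= 1.
#' @param ct_noise_sd SD (cycles) of Gaussian measurement noise, >= 0.
#' @param seed integer seed.
#' @return data.frame with columns sample_id, assay, replicate, ct.
#' @export
simulate_ct_table <- function(truth, metadata, assays, reference,
                              replicates = 3, ct_noise_sd = 0.2, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if (ct_noise_sd < 0) stop("`ct_noise_sd` must be >= 0", call. = FALSE)
  assays <- union(assays, reference)
  unknown <- setdiff(assays, truth$features$feature_id)
  if (length(unknown) > 0)
    stop("unknown assay id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  ft <- truth$features[match(assays, truth$features$feature_id), ]
  base_ct <- 35 - log2(ft$base_mean + 1)
  samp <- metadata[!metadata$is_negative_control, ]
  off <- function(cond) switch(cond,
    control = numeric(nrow(ft)),
    basal = ft$lfc_basal_vs_control,
    post_tx = ft$lfc_basal_vs_control + ft$lfc_post_vs_basal)
  rows <- vector("list", nrow(samp))
  for (i in seq_len(nrow(samp))) {
    la <- off(samp$condition[i])  # log2 relative abundance
    ct <- rep(base_ct - la, each = replicates) +
      rnorm(nrow(ft) * replicates, 0, ct_noise_sd)
    rows[[i]] <- data.frame(
      sample_id = samp$sample_id[i],
      assay = rep(assays, each = replicates),
      replicate = rep(seq_len(replicates), times = nrow(ft)),
      ct = ct, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
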