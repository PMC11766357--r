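#' Aggregate technical qPCR replicates
#'
#' Per (sample, assay): missing (undetermined) replicates are dropped, then
#' replicates farther than `outlier_window` cycles from the replicate median
#' are discarded, and the mean of the survivors is reported. Wells with no
#' usable replicate are skipped with a warning.
#'
#' @param ct validated Ct table (sample_id, assay, replicate, ct).
#' @param outlier_window maximum |Ct - median| in cycles (default 0.5).
#' @return data.frame: sample_id, assay, mean_ct, ct_sd, n_replicates_used.
#' @export
aggregate_triplicates <- function(ct, outlier_window = 0.5) {
  validate_ct_table(ct)
  if (outlier_window <= 0) stop("`outlier_window` must be > 0", call. = FALSE)
  key <- interaction(ct$sample_id, ct$assay, drop = TRUE, sep = "\r")
  groups <- split(ct, key)
  skipped <- 0L
  rows <- lapply(groups, function(g) {
    v <- g$ct[!is.na(g$ct)]
    if (length(v) == 0) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    v <- v[abs(v - median(v)) <= outlier_window]
    data.frame(sample_id = g$sample_id[1], assay = g$assay[1],
               mean_ct = mean(v), ct_sd = if (length(v) > 1) sd(v) else 0,
               n_replicates_used = length(v), stringsAsFactors = FALSE)
  })
  if (skipped > 0)
    warning(skipped, " (sample, assay) well(s) had no usable replicate")
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$assay), ]
  rownames(out) <- NULL
  out
}

#' Delta-delta-Ct relative quantification
#'
#' `delta_ct = mean_ct(assay) - mean_ct(reference)` within each sample,
#' `rel_expr = 2^-delta_ct`, and `rq = 2^-(delta_ct - mean calibrator
#' delta_ct)` with the calibrator the mean delta-Ct of the given metadata
#' condition. Samples missing the reference assay are excluded with a
#' warning.
#'
#' @param mean_ct data.frame from [aggregate_triplicates()].
#' @param reference_assay assay id used as normalizer.
#' @param metadata sample metadata (conditions for the calibrator group).
#' @param calibrator condition whose mean delta-Ct anchors rq (default
#'   "control").
#' @return data.frame: sample_id, assay, condition, mean_ct, delta_ct,
#'   rel_expr, rq.
#' @export
relative_expression <- function(mean_ct, reference_assay, metadata,
                                calibrator = "control") {
  if (!reference_assay %in% mean_ct$assay)
    stop("reference assay '", reference_assay, "' not in Ct table",
         call. = FALSE)
  ref <- mean_ct[mean_ct$assay == reference_assay, ]
  have_ref <- mean_ct$sample_id %in% ref$sample_id
  if (any(!have_ref)) {
    warning(length(unique(mean_ct$sample_id[!have_ref])),
            " sample(s) missing the reference assay were excluded")
    mean_ct <- mean_ct[have_ref, ]
  }
  out <- mean_ct[mean_ct$assay != reference_assay, ]
  out$delta_ct <- out$mean_ct -
    ref$mean_ct[match(out$sample_id, ref$sample_id)]
  out$condition <- metadata$condition[match(out$sample_id,
                                            metadata$sample_id)]
  out$rel_expr <- 2^(-out$delta_ct)
  cal <- vapply(split(out, out$assay), function(g)
    mean(g$delta_ct[g$condition == calibrator]), numeric(1))
  out$rq <- 2^(-(out$delta_ct - cal[out$assay]))
  out <- out[, c("sample_id", "assay", "condition", "mean_ct", "delta_ct",
                 "rel_expr", "rq")]
  rownames(out) <- NULL
  out
}

#' Nonparametric group comparison of relative expression
#'
#' Statistics are computed on `log2(rel_expr)` (= -delta-Ct); rank tests are
#' invariant to that monotone choice. Unpaired contrasts use the exact
#' Mann-Whitney U test, paired contrasts the exact Wilcoxon signed-rank on
#' complete within-subject pairs.
#'
#' @param relquant data.frame from [relative_expression()].
#' @param metadata sample metadata.
#' @param assay assay id to compare.
#' @param contrast length-2 character: case condition then reference
#'   condition. `c("basal", "control")` is unpaired; `c("post_tx", "basal")`
#'   (any contrast of two paired conditions) is paired via subject ids.
#' @return data.frame row: assay, contrast, test, statistic, p, direction
#'   (sign of the median case-vs-reference difference on log2 scale), n_case,
#'   n_ref.
#' @export
compare_groups <- function(relquant, metadata, assay,
                           contrast = c("basal", "control")) {
  rq <- relquant[relquant$assay == assay, ]
  if (nrow(rq) == 0) stop("assay '", assay, "' not found", call. = FALSE)
  rq$subject_id <- metadata$subject_id[match(rq$sample_id,
                                             metadata$sample_id)]
  x <- rq[rq$condition == contrast[1], ]
  y <- rq[rq$condition == contrast[2], ]
  paired <- all(contrast %in% c("basal", "post_tx"))
  lx <- -x$delta_ct
  ly <- -y$delta_ct
  if (paired) {
    subjects <- intersect(x$subject_id, y$subject_id)
    if (length(subjects) < 2)
      stop("need >= 2 complete pairs", call. = FALSE)
    d <- lx[match(subjects, x$subject_id)] - ly[match(subjects, y$subject_id)]
    tst <- wilcoxon_signed_rank_test(d)
    res <- data.frame(test = "wilcoxon_signed_rank",
                      statistic = tst$statistic, p = tst$p,
                      direction = sign(median(d)),
                      n_case = length(subjects), n_ref = length(subjects))
  } else {
    if (length(lx) == 0 || length(ly) == 0)
      stop("both groups must be non-empty", call. = FALSE)
    tst <- mann_whitney_u_test(lx, ly)
    res <- data.frame(test = "mann_whitney_u",
                      statistic = tst$statistic, p = tst$p,
                      direction = sign(median(lx) - median(ly)),
                      n_case = length(lx), n_ref = length(ly))
  }
  cbind(data.frame(assay = assay,
                   contrast = paste(contrast, collapse = "_vs_"),
                   stringsAsFactors = FALSE),
        res)
}

#' Validation-cohort ROC of a quantified assay
#'
#' Scores are `log2(rel_expr)` for the contrast samples (positive class
#' first in `contrast`); returns the raw rank AUC (not oriented) with a
#' seeded stratified-bootstrap 95 percent CI.
#'
#' @param relquant data.frame from [relative_expression()].
#' @param assay assay id (or precomputed `scores`/`labels`, see
#'   [loocv_pair_auc()] for panel scores).
#' @param contrast length-2 character contrast.
#' @param n_boot,seed bootstrap parameters.
#' @return list with `auc`, `ci` (length-2), `n_pos`, `n_neg`.
#' @export
validation_roc <- function(relquant, assay, contrast = c("basal", "control"),
                           n_boot = 2000, seed = 1L) {
  rq <- relquant[relquant$assay == assay, ]
  if (nrow(rq) == 0) stop("assay '", assay, "' not found", call. = FALSE)
  pos <- -rq$delta_ct[rq$condition == contrast[1]]
  neg <- -rq$delta_ct[rq$condition == contrast[2]]
  a <- auc_rank(pos, neg)
  list(auc = a,
       ci = auc_bootstrap_ci(pos, neg, n_boot = n_boot, seed = seed),
       n_pos = length(pos), n_neg = length(neg))
}
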