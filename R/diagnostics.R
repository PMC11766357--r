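#' Rank-based ROC AUC (Mann-Whitney form)
#'
#' `AUC = (# (pos, neg) pairs with pos > neg + 0.5 * ties) / (n_pos * n_neg)`,
#' computed via midranks. No orientation is applied: a score distribution
#' lower in positives gives an AUC below 0.5.
#'
#' @param scores_pos scores of the positive class (non-empty).
#' @param scores_neg scores of the negative class (non-empty).
#' @return AUC between 0 and 1.
#' @export
auc_rank <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0 || nn == 0) stop("both classes must be non-empty", call. = FALSE)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Youden-optimal operating threshold
#'
#' Scores must already be oriented so that higher means positive class.
#' Candidate thresholds are the midpoints between adjacent distinct sorted
#' scores plus one below the minimum and one above the maximum; a sample is
#' called positive when its score exceeds the threshold. The threshold
#' maximizing Youden's J = SN + SP - 1 is returned; ties are broken toward
#' higher sensitivity, then toward the lower threshold.
#'
#' @param scores numeric scores.
#' @param labels logical (TRUE = positive class).
#' @return list with `threshold`, `tp`, `fp`, `tn`, `fn`, `sn`, `sp`,
#'   `youden`.
#' @export
choose_threshold_youden <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) c(u - 1, u + 1) else
    c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  best <- NULL
  for (th in cand) {
    pred <- scores > th
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- npos - tp; tn <- nneg - fp
    sn <- tp / npos; sp <- tn / nneg
    j <- sn + sp - 1
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 &&
         (sn > best$sn + 1e-12 ||
          (abs(sn - best$sn) <= 1e-12 && th < best$threshold)))) {
      best <- list(threshold = th, tp = tp, fp = fp, tn = tn, fn = fn,
                   sn = sn, sp = sp, youden = j)
    }
  }
  best
}

#' Diagnostic metrics from a confusion matrix
#'
#' @param tp,fp,tn,fn non-negative integer counts; `tp + fn > 0` and
#'   `tn + fp > 0`.
#' @return list with exact `sn`, `sp`, `ppv`, `npv` (NA when the denominator
#'   is zero) and 2-decimal presentation values `sn2`, `sp2`, `ppv2`, `npv2`
#'   (round half away from zero).
#' @export
diagnostic_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0)
    stop("need at least one positive and one negative", call. = FALSE)
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  npv <- if (tn + fn == 0) NA_real_ else tn / (tn + fn)
  list(sn = sn, sp = sp, ppv = ppv, npv = npv,
       sn2 = round_half_up(sn), sp2 = round_half_up(sp),
       ppv2 = round_half_up(ppv), npv2 = round_half_up(npv))
}

#' Reconstruct an integer confusion matrix from reported SN/SP
#'
#' Inverts published sensitivity/specificity (given the group sizes) to the
#' underlying integer confusion matrix: `tp = round(sn * n_pos)`,
#' `tn = round(sp * n_neg)` (round half away from zero), from which the
#' predictive values follow exactly.
#'
#' @param sn,sp reported sensitivity and specificity.
#' @param n_pos,n_neg class sizes.
#' @return list with tp, fp, tn, fn and the [diagnostic_metrics()] of the
#'   reconstruction.
#' @export
reconstruct_confusion <- function(sn, sp, n_pos, n_neg) {
  tp <- as.integer(round_half_up(sn * n_pos, 0))
  tn <- as.integer(round_half_up(sp * n_neg, 0))
  fn <- n_pos - tp
  fp <- n_neg - tn
  c(list(tp = tp, fp = fp, tn = tn, fn = fn),
    diagnostic_metrics(tp, fp, tn, fn))
}

#' Per-feature diagnostic ROC profiles
#'
#' Scores each feature by `log2(normalized count + 0.5)` (size-factor
#' scaled), computes the rank AUC for the contrast, orients it to >= 0.5
#' (recording the direction), and derives the Youden operating point with
#' its confusion-matrix metrics.
#'
#' @param counts count matrix.
#' @param metadata sample metadata.
#' @param contrast length-2 character: positive class condition then
#'   negative class condition.
#' @param size_factors optional precomputed size factors.
#' @return data.frame: feature, auc, orientation, threshold, tp, fp, tn, fn,
#'   sn, sp, ppv, npv.
#' @export
diagnostic_profiles <- function(counts, metadata,
                                contrast = c("basal", "control"),
                                size_factors = NULL) {
  validate_metadata(metadata)
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  keep <- metadata$condition %in% contrast
  sub <- counts[, keep, drop = FALSE]
  meta <- metadata[keep, ]
  s <- if (is.null(size_factors)) size_factors_median_of_ratios(sub) else
    size_factors[colnames(sub)]
  scores_mat <- log2(sweep(sub, 2, s, "/") + 0.5)
  pos <- meta$condition == contrast[1]
  if (sum(pos) == 0 || sum(!pos) == 0)
    stop("both contrast groups must be non-empty", call. = FALSE)
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    sc <- scores_mat[i, ]
    a <- auc_rank(sc[pos], sc[!pos])
    orientation <- if (a >= 0.5) "positive-scores-up" else
      "positive-scores-down"
    oriented <- if (a >= 0.5) sc else -sc
    a_or <- max(a, 1 - a)
    op <- choose_threshold_youden(oriented, pos)
    dm <- diagnostic_metrics(op$tp, op$fp, op$tn, op$fn)
    data.frame(feature = rownames(sub)[i], auc = a_or,
               orientation = orientation, threshold = op$threshold,
               tp = op$tp, fp = op$fp, tn = op$tn, fn = op$fn,
               sn = dm$sn, sp = dm$sp, ppv = dm$ppv, npv = dm$npv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate biomarker filter
#'
#' A feature is a candidate iff `auc > 0.75` and `baseMean > 10` and
#' `p < 0.05` (all strict). Output is sorted by descending AUC then
#' ascending p. Features present in only one of the two tables are dropped
#' with a warning.
#'
#' @param diffexp data.frame from [wald_test_unpaired()] / [paired_test()].
#' @param profiles data.frame from [diagnostic_profiles()].
#' @param auc_min,basemean_min,p_max filter thresholds (strict).
#' @return merged data.frame with a logical `candidate` column, candidates
#'   first (descending AUC, ascending p).
#' @export
candidate_filter <- function(diffexp, profiles, auc_min = 0.75,
                             basemean_min = 10, p_max = 0.05) {
  common <- intersect(diffexp$feature, profiles$feature)
  lost <- length(union(diffexp$feature, profiles$feature)) - length(common)
  if (lost > 0)
    warning(lost, " feature(s) present in only one table were dropped")
  de <- diffexp[match(common, diffexp$feature), ]
  pr <- profiles[match(common, profiles$feature), ]
  merged <- cbind(de,
                  pr[, setdiff(names(pr), "feature"), drop = FALSE])
  merged$candidate <- merged$auc > auc_min & merged$baseMean > basemean_min &
    merged$p < p_max
  merged <- merged[order(-merged$candidate, -merged$auc, merged$p,
                         merged$feature), ]
  rownames(merged) <- NULL
  merged
}

#' Stratified bootstrap confidence interval for an AUC
#'
#' Resamples positive and negative scores independently with replacement and
#' returns the percentile interval of [auc_rank()] over the resamples.
#'
#' @param scores_pos,scores_neg class score vectors.
#' @param n_boot number of resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric length-2 vector (lower, upper).
#' @export
auc_bootstrap_ci <- function(scores_pos, scores_neg, n_boot = 2000,
                             conf = 0.95, seed = 1L) {
  set.seed(seed)
  np <- length(scores_pos); nn <- length(scores_neg)
  boots <- vapply(seq_len(n_boot), function(b) {
    auc_rank(scores_pos[sample.int(np, np, replace = TRUE)],
             scores_neg[sample.int(nn, nn, replace = TRUE)])
  }, numeric(1))
  a <- (1 - conf) / 2
  unname(quantile(boots, c(a, 1 - a)))
}
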