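#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over reference features (features
#' with nonzero counts in every sample) of `count_ij / geometric_mean_i`,
#' rescaled so the geometric mean of the size factors is exactly 1. If no
#' feature is expressed in every sample the function falls back to
#' library-size ratios and sets the `fallback` attribute with a warning.
#'
#' @param counts count matrix (features x samples).
#' @return named numeric vector of size factors (geometric mean 1), with
#'   attribute `fallback` = TRUE when library-size ratios were used.
#' @export
size_factors_median_of_ratios <- function(counts) {
  ref <- rowSums(counts > 0) == ncol(counts)
  if (any(ref)) {
    sub <- counts[ref, , drop = FALSE]
    loggeo <- rowMeans(log(sub))
    s <- apply(sub, 2, function(col) exp(median(log(col) - loggeo)))
    fallback <- FALSE
  } else {
    warning("no feature expressed in all samples; ",
            "falling back to library-size ratios")
    libs <- colSums(counts)
    s <- libs / exp(mean(log(libs)))
    fallback <- TRUE
  }
  s <- s / exp(mean(log(s)))
  names(s) <- colnames(counts)
  attr(s, "fallback") <- fallback
  s
}

#' Per-feature negative-binomial dispersion by shrunken method of moments
#'
#' Within-group method-of-moments estimate
#' `alpha_hat = max(0, (v - m) / m^2)` with `m` and `v` the across-group
#' means of the within-group mean and variance of normalized counts, shrunk
#' toward the across-feature mean `alpha_bar` with weight `w = 4 / (4 + n)`
#' (n = samples per feature): `alpha = (1 - w) * alpha_hat + w * alpha_bar`.
#' Features with zero mean are marked untestable (NA dispersion).
#'
#' @param normmat matrix of normalized counts (features x samples).
#' @param groups character/factor group label per sample; each group needs
#'   at least 2 samples.
#' @return numeric vector of shrunk dispersions (NA where untestable).
#' @export
estimate_dispersion <- function(normmat, groups) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (any(table(groups) < 2))
    stop("each group needs >= 2 samples for dispersion estimation",
         call. = FALSE)
  gm <- do.call(cbind, lapply(gl, function(g)
    rowMeans(normmat[, groups == g, drop = FALSE])))
  gv <- do.call(cbind, lapply(gl, function(g)
    apply(normmat[, groups == g, drop = FALSE], 1, var)))
  m <- rowMeans(gm)
  v <- rowMeans(gv)
  raw <- ifelse(m > 0, pmax(0, (v - m) / m^2), NA_real_)
  alpha_bar <- mean(raw, na.rm = TRUE)
  if (!is.finite(alpha_bar)) alpha_bar <- 0
  n <- length(groups)
  w <- 4 / (4 + n)
  ifelse(is.na(raw), NA_real_, (1 - w) * raw + w * alpha_bar)
}

#' Signed fold change from a log2 fold change
#'
#' `2^lfc` for `lfc >= 0`, `-2^(-lfc)` otherwise, so a positive value means
#' upregulation in the contrast's case group and `|fc| >= 1` always.
#'
#' @param lfc log2 fold change (finite).
#' @return signed fold change.
#' @export
signed_fc <- function(lfc) {
  ifelse(lfc >= 0, 2^lfc, -2^(-lfc))
}

# inverse of signed_fc, for |f| >= 1
lfc_of_signed_fc <- function(f) {
  ifelse(f >= 0, log2(f), -log2(-f))
}

#' Unpaired negative-binomial Wald screen (case vs control)
#'
#' For each feature, `lfc = log2((mean_norm_case + pc) / (mean_norm_ctrl +
#' pc))`. The standard error comes from the NB delta method, evaluated at
#' the same pseudocount-regularized means that enter the ratio: with
#' `m_g = mu_g + pc` (`mu_g` the mean normalized count) and dispersion
#' `alpha`, `Var(Xbar_g) = n_g^-2 * sum_j (m_g / s_j + alpha * m_g^2)`
#' (variance of a normalized NB count with mean `s_j * m_g`), so
#' `SE^2 = sum_g Var(Xbar_g) / (m_g * ln 2)^2` and
#' `p = 2 * Phi(-|lfc / SE|)`. Using `m_g` rather than the raw plug-in mean
#' keeps the ratio and its variance on one scale and avoids the mild
#' anticonservatism of evaluating the variance at a noisier smaller mean.
#' Features with zero counts everywhere are emitted with lfc 0, p 1 and
#' `testable = FALSE`.
#'
#' @param counts count matrix (all samples; the contrast subsets it).
#' @param metadata sample metadata.
#' @param contrast length-2 character: case condition then reference
#'   condition (default `c("basal", "control")`; positive lfc = up in case).
#' @param pseudocount offset inside the log-ratio (default 0.5).
#' @param size_factors optional precomputed size factors for the contrast
#'   samples; recomputed on the subset when NULL.
#' @return data.frame: feature, baseMean, lfc, fc_signed, p, p_adj (BH,
#'   informational), dispersion, testable.
#' @export
wald_test_unpaired <- function(counts, metadata,
                               contrast = c("basal", "control"),
                               pseudocount = 0.5, size_factors = NULL) {
  validate_metadata(metadata)
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  keep <- metadata$condition %in% contrast
  if (sum(metadata$condition == contrast[1]) == 0 ||
      sum(metadata$condition == contrast[2]) == 0)
    stop("both contrast groups must be non-empty", call. = FALSE)
  sub <- counts[, keep, drop = FALSE]
  meta <- metadata[keep, ]
  s <- if (is.null(size_factors)) size_factors_median_of_ratios(sub) else
    size_factors[colnames(sub)]
  norm <- sweep(sub, 2, s, "/")
  case <- meta$condition == contrast[1]
  alpha <- estimate_dispersion(norm, ifelse(case, "case", "ref"))

  mu1 <- rowMeans(norm[, case, drop = FALSE])
  mu0 <- rowMeans(norm[, !case, drop = FALSE])
  n1 <- sum(case); n0 <- sum(!case)
  m1 <- mu1 + pseudocount
  m0 <- mu0 + pseudocount
  lfc <- log2(m1 / m0)
  a <- ifelse(is.na(alpha), 0, alpha)
  var1 <- (rowSums(outer(m1, 1 / s[case])) + n1 * a * m1^2) / n1^2
  var0 <- (rowSums(outer(m0, 1 / s[!case])) + n0 * a * m0^2) / n0^2
  se2 <- var1 / (m1 * log(2))^2 + var0 / (m0 * log(2))^2
  z <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  p <- 2 * pnorm(-abs(z))
  testable <- mu1 + mu0 > 0
  lfc[!testable] <- 0
  p[!testable] <- 1
  baseMean <- rowMeans(norm)
  data.frame(
    feature = rownames(counts),
    baseMean = baseMean,
    lfc = lfc,
    fc_signed = signed_fc(lfc),
    p = pmin(1, p),
    p_adj = p.adjust(pmin(1, p), method = "BH"),
    dispersion = alpha,
    testable = testable,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Paired contrast by per-subject log-ratios and exact Wilcoxon signed-rank
#'
#' For each subject with both samples, `d_k = log2((norm_case + pc) /
#' (norm_ref + pc))`; `lfc = mean(d_k)` and the p-value is the exact
#' two-sided Wilcoxon signed-rank on the `d_k` (normal approximation with
#' continuity correction beyond 25 pairs). Subjects missing one side are
#' dropped (count in attribute `n_dropped_subjects`).
#'
#' @param counts count matrix.
#' @param metadata sample metadata.
#' @param contrast length-2 character: case condition then reference
#'   condition (default `c("post_tx", "basal")`; positive lfc = up in case).
#' @param pseudocount offset inside the log-ratio (default 0.5).
#' @return data.frame as in [wald_test_unpaired()].
#' @export
paired_test <- function(counts, metadata, contrast = c("post_tx", "basal"),
                        pseudocount = 0.5) {
  validate_metadata(metadata)
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  m_case <- metadata[metadata$condition == contrast[1], ]
  m_ref <- metadata[metadata$condition == contrast[2], ]
  subjects <- intersect(m_case$subject_id, m_ref$subject_id)
  n_dropped <- length(union(m_case$subject_id, m_ref$subject_id)) -
    length(subjects)
  if (length(subjects) < 2)
    stop("need >= 2 complete subject pairs", call. = FALSE)
  case_ids <- m_case$sample_id[match(subjects, m_case$subject_id)]
  ref_ids <- m_ref$sample_id[match(subjects, m_ref$subject_id)]
  sub <- counts[, c(case_ids, ref_ids), drop = FALSE]
  s <- size_factors_median_of_ratios(sub)
  norm <- sweep(sub, 2, s, "/")
  dmat <- log2((norm[, case_ids, drop = FALSE] + pseudocount) /
                 (norm[, ref_ids, drop = FALSE] + pseudocount))
  groups <- rep(c("case", "ref"), c(length(case_ids), length(ref_ids)))
  alpha <- estimate_dispersion(norm, groups)
  lfc <- rowMeans(dmat)
  p <- apply(dmat, 1, function(d) wilcoxon_signed_rank_test(d)$p)
  testable <- rowSums(sub) > 0
  lfc[!testable] <- 0
  p[!testable] <- 1
  out <- data.frame(
    feature = rownames(counts),
    baseMean = rowMeans(norm),
    lfc = lfc,
    fc_signed = signed_fc(lfc),
    p = p,
    p_adj = p.adjust(p, method = "BH"),
    dispersion = alpha,
    testable = testable,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped_subjects") <- n_dropped
  out
}
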