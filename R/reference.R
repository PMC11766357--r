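#' Stability-based qPCR reference selection
#'
#' Restricts to features whose differential-expression signed fold change
#' lies strictly inside the window (default 1.2-fold in either direction,
#' i.e. |lfc| < log2(1.2)), then ranks them by highest mean expression,
#' lowest SD, and lowest coefficient of variation across all non-excluded
#' samples (midranks for ties). The stability statistics are computed on
#' `log2(normalized count + 1)`, the variance-stabilized scale expression
#' stability tools operate on; on the raw count scale the SD criterion
#' mechanically favors low-abundance features (SD grows with the mean) and
#' no abundant housekeeper could rank well on it. The composite rank is the
#' unweighted mean of the three; the best (lowest composite, ties broken
#' lexicographically by feature id) is the suggested reference.
#'
#' @param counts count matrix (QC-filtered; real samples only).
#' @param metadata sample metadata.
#' @param diffexp data.frame from [wald_test_unpaired()] or [paired_test()]
#'   providing the fold changes used for the window.
#' @param window fold-change window half-width on the signed-FC scale
#'   (default 1.2; must be > 1).
#' @param size_factors optional precomputed size factors.
#' @return data.frame of stability records ordered by ascending composite
#'   rank: feature, mean_expr, sd_expr, cv, fc_signed, rank_mean, rank_sd,
#'   rank_cv, composite_rank.
#' @export
select_reference <- function(counts, metadata, diffexp, window = 1.2,
                             size_factors = NULL) {
  if (window <= 1) stop("`window` must be > 1", call. = FALSE)
  validate_metadata(metadata)
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  keep <- !metadata$is_negative_control
  sub <- counts[, keep, drop = FALSE]
  s <- if (is.null(size_factors)) size_factors_median_of_ratios(sub) else
    size_factors[colnames(sub)]
  norm <- sweep(sub, 2, s, "/")

  de <- diffexp[match(rownames(sub), diffexp$feature), ]
  in_window <- !is.na(de$lfc) & abs(de$lfc) < log2(window)
  if (!any(in_window))
    stop("no feature inside the fold-change window; widen `window`",
         call. = FALSE)
  nm <- log2(norm[in_window, , drop = FALSE] + 1)
  mean_expr <- rowMeans(nm)
  sd_expr <- apply(nm, 1, sd)
  cv <- ifelse(mean_expr > 0, sd_expr / mean_expr, NA_real_)
  rank_mean <- rank(-mean_expr)
  rank_sd <- rank(sd_expr)
  rank_cv <- rank(cv)
  composite <- (rank_mean + rank_sd + rank_cv) / 3
  out <- data.frame(
    feature = rownames(nm),
    mean_expr = mean_expr,
    sd_expr = sd_expr,
    cv = cv,
    fc_signed = de$fc_signed[in_window],
    rank_mean = rank_mean,
    rank_sd = rank_sd,
    rank_cv = rank_cv,
    composite_rank = composite,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$composite_rank, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Write the full stability ranking for audit
#'
#' @param records data.frame from [select_reference()].
#' @param path output TSV path.
#' @return the records, invisibly.
#' @export
stability_report <- function(records, path) {
  write_table(records, path)
  invisible(records)
}
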