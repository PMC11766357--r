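#' Log2 counts-per-million transform
#'
#' `log2(count / column_total * 1e6 + pseudocount)` with column totals taken
#' on the raw counts.
#'
#' @param counts count matrix (features x samples).
#' @param pseudocount positive offset added after CPM scaling (default 1).
#' @return real matrix of the same shape.
#' @export
log_cpm <- function(counts, pseudocount = 1) {
  if (pseudocount <= 0) stop("`pseudocount` must be > 0", call. = FALSE)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  log2(sweep(counts, 2, tot, "/") * 1e6 + pseudocount)
}

#' Pearson-correlation clustering of samples
#'
#' Average-linkage agglomerative clustering with distance `1 - Pearson r`
#' computed on a log-CPM matrix, plus the per-sample correlation summaries
#' used by the exclusion rule: the maximum correlation to any negative
#' control and to any other real (non-negative-control) sample. A constant
#' sample (zero variance) gets correlations 0 and a warning flag rather than
#' an error.
#'
#' @param logmat log-CPM matrix (features x samples).
#' @param metadata sample metadata matching the columns.
#' @return list with `hclust` (stats::hclust tree), `cor_matrix`, and
#'   `summary` data.frame (sample_id, max_cor_negctrl, max_cor_real,
#'   constant_flag).
#' @export
correlation_cluster <- function(logmat, metadata) {
  validate_metadata(metadata, colnames(logmat))
  metadata <- metadata[match(colnames(logmat), metadata$sample_id), ]
  n <- ncol(logmat)
  if (n < 3) stop("need >= 3 samples for clustering", call. = FALSE)
  sds <- apply(logmat, 2, sd)
  constant <- sds == 0
  cm <- suppressWarnings(cor(logmat))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  tree <- hclust(as.dist(1 - cm), method = "average")
  is_nc <- metadata$is_negative_control
  max_or_na <- function(x) if (length(x) == 0) NA_real_ else max(x)
  summ <- data.frame(
    sample_id = colnames(logmat),
    max_cor_negctrl = vapply(seq_len(n), function(j)
      max_or_na(cm[j, is_nc & seq_len(n) != j]), numeric(1)),
    max_cor_real = vapply(seq_len(n), function(j)
      max_or_na(cm[j, !is_nc & seq_len(n) != j]), numeric(1)),
    constant_flag = constant,
    stringsAsFactors = FALSE
  )
  list(hclust = tree, cor_matrix = cm, summary = summ)
}

#' Sample quality-control report
#'
#' Flags samples whose global expression profile clusters with the technical
#' negative controls. The study-style visual dendrogram/PCA exclusion is
#' replaced by a deterministic surrogate: a real sample is excluded iff its
#' maximum correlation to a negative control exceeds its maximum correlation
#' to any other real sample, or its library size falls below
#' `libsize_min_fraction` of the median real-sample library size. Negative
#' controls themselves are always excluded from downstream analysis. PCA
#' coordinates (first two components of centered, unscaled log-CPM) are
#' reported for plotting only and never enter the rule.
#'
#' @param counts count matrix.
#' @param metadata sample metadata.
#' @param libsize_min_fraction library-size floor as a fraction of the median
#'   real-sample library size (default 0.1).
#' @param pseudocount log-CPM pseudocount (default 1).
#' @return data.frame (one row per sample): sample_id, condition,
#'   library_size, max_cor_negctrl, max_cor_real, pc1, pc2, excluded, reason.
#' @export
qc_report <- function(counts, metadata, libsize_min_fraction = 0.1,
                      pseudocount = 1) {
  validate_metadata(metadata, colnames(counts))
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  lm <- log_cpm(counts, pseudocount)
  cl <- correlation_cluster(lm, metadata)
  libsize <- colSums(counts)
  is_nc <- metadata$is_negative_control
  med_real <- median(libsize[!is_nc])

  pcs <- matrix(NA_real_, ncol(counts), 2)
  if (ncol(counts) >= 3) {
    p <- prcomp(t(lm), center = TRUE, scale. = FALSE)
    k <- min(2, ncol(p$x))
    pcs[, seq_len(k)] <- p$x[, seq_len(k)]
  }

  excluded <- logical(ncol(counts))
  reason <- character(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (is_nc[j]) {
      excluded[j] <- TRUE
      reason[j] <- "negative_control"
    } else {
      why <- character()
      mcn <- cl$summary$max_cor_negctrl[j]
      mcr <- cl$summary$max_cor_real[j]
      if (!is.na(mcn) && !is.na(mcr) && mcn > mcr)
        why <- c(why, "clusters_with_negative_controls")
      if (libsize[j] < libsize_min_fraction * med_real)
        why <- c(why, "low_library_size")
      if (length(why) > 0) {
        excluded[j] <- TRUE
        reason[j] <- paste(why, collapse = ";")
      }
    }
  }
  data.frame(
    sample_id = colnames(counts),
    condition = metadata$condition,
    library_size = libsize,
    max_cor_negctrl = cl$summary$max_cor_negctrl,
    max_cor_real = cl$summary$max_cor_real,
    pc1 = pcs[, 1], pc2 = pcs[, 2],
    excluded = excluded,
    reason = reason,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Apply a QC report, returning the filtered count matrix and metadata
#'
#' @param counts count matrix.
#' @param metadata sample metadata.
#' @param report output of [qc_report()].
#' @return list with filtered `counts` and `metadata`.
#' @export
apply_qc <- function(counts, metadata, report) {
  keep <- report$sample_id[!report$excluded]
  list(counts = counts[, colnames(counts) %in% keep, drop = FALSE],
       metadata = metadata[metadata$sample_id %in% keep, , drop = FALSE])
}
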