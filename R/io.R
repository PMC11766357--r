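#' Validate a count matrix
#'
#' @param counts integer matrix, features x samples, with unique dimnames.
#' @return the matrix, invisibly; stops with an informative error otherwise.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) == 0 || ncol(counts) == 0)
    stop("count matrix must be a non-empty matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have feature and sample ids", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids in count matrix", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix", call. = FALSE)
  if (anyNA(counts)) {
    bad <- which(apply(counts, 1, anyNA))[1]
    stop("missing count in row ", bad, " (", rownames(counts)[bad], ")",
         call. = FALSE)
  }
  neg <- which(apply(counts < 0, 1, any))
  if (length(neg) > 0)
    stop("negative count in row ", neg[1], " (", rownames(counts)[neg[1]],
         ")", call. = FALSE)
  nonint <- which(apply(counts != round(counts), 1, any))
  if (length(nonint) > 0)
    stop("non-integer count in row ", nonint[1], " (",
         rownames(counts)[nonint[1]], ")", call. = FALSE)
  invisible(counts)
}

#' Read a feature-by-sample count matrix from TSV
#'
#' Expects a header row of sample ids; the first column holds feature ids.
#' Gzip-compressed files are handled transparently.
#'
#' @param path path to a TSV (optionally .gz).
#' @return validated integer matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- tryCatch(
    read.delim(path, header = TRUE, check.names = FALSE, sep = "\t",
               stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse count matrix at '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("count matrix at '", path, "' is empty or has no sample columns",
         call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(df[, -1, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric count in row ", if (length(bad)) bad[1] else "?",
         " of '", path, "'", call. = FALSE)
  }
  rownames(m) <- ids
  storage.mode(m) <- "double"
  validate_count_matrix(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as TSV
#'
#' @param counts validated count matrix.
#' @param path output path (gz suffix -> gzip).
#' @export
write_count_matrix <- function(counts, path) {
  validate_count_matrix(counts)
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Validate sample metadata
#'
#' Conditions must be exactly one of `control`, `basal`, `post_tx`,
#' `negative_control` (no case normalization). Every basal/post_tx sample
#' needs a subject id; a subject may contribute at most one basal and one
#' post_tx sample. When `sample_ids` is supplied, metadata must cover exactly
#' those samples.
#'
#' @param metadata data.frame with columns sample_id, condition, subject_id,
#'   is_negative_control.
#' @param sample_ids optional character vector to match against.
#' @return the metadata, invisibly.
#' @export
validate_metadata <- function(metadata, sample_ids = NULL) {
  need <- c("sample_id", "condition", "subject_id", "is_negative_control")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  bad <- setdiff(unique(metadata$condition), .condition_levels)
  if (length(bad) > 0)
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.condition_levels, collapse = ", "),
         call. = FALSE)
  paired <- metadata$condition %in% c("basal", "post_tx")
  if (any(paired & (is.na(metadata$subject_id) | metadata$subject_id == "")))
    stop("basal/post_tx samples must carry a subject_id", call. = FALSE)
  for (cond in c("basal", "post_tx")) {
    sj <- metadata$subject_id[metadata$condition == cond]
    if (anyDuplicated(sj))
      stop("subject ", sj[duplicated(sj)][1], " has more than one ", cond,
           " sample", call. = FALSE)
  }
  if (!is.logical(metadata$is_negative_control))
    stop("is_negative_control must be logical", call. = FALSE)
  if (any(metadata$is_negative_control !=
          (metadata$condition == "negative_control")))
    stop("is_negative_control flag inconsistent with condition", call. = FALSE)
  if (!is.null(sample_ids)) {
    if (!setequal(metadata$sample_id, sample_ids))
      stop("metadata sample ids do not match count matrix sample ids",
           call. = FALSE)
  }
  invisible(metadata)
}

#' Read sample metadata from CSV
#' @param path CSV path (columns sample_id, condition, subject_id,
#'   is_negative_control; optionally .gz).
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if ("is_negative_control" %in% names(df))
    df$is_negative_control <- df$is_negative_control %in% c("TRUE", "true", "1")
  if ("subject_id" %in% names(df)) df$subject_id[is.na(df$subject_id)] <- ""
  validate_metadata(df)
  df
}

#' Write sample metadata as CSV
#' @param metadata validated metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  cols <- c("sample_id", "condition", "subject_id", "is_negative_control")
  write.csv(metadata[, cols], path, row.names = FALSE, quote = FALSE)
}

#' Validate a long-format Ct table
#'
#' Missing Ct values (undetermined wells) are allowed and encoded as NA;
#' present values must lie in (0, 45]. (sample_id, assay, replicate) must be
#' unique.
#'
#' @param ct data.frame with columns sample_id, assay, replicate, ct.
#' @return the table, invisibly.
#' @export
validate_ct_table <- function(ct) {
  need <- c("sample_id", "assay", "replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0)
    stop("Ct table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(ct$sample_id, ct$assay, ct$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample_id, assay, replicate) in Ct table", call. = FALSE)
  if (any(ct$replicate < 1 | ct$replicate != round(ct$replicate)))
    stop("replicate must be a positive integer", call. = FALSE)
  bad <- !is.na(ct$ct) & (ct$ct <= 0 | ct$ct > 45)
  if (any(bad))
    stop("Ct value out of range (0, 45] in row ", which(bad)[1], call. = FALSE)
  invisible(ct)
}

#' Read a Ct table from CSV
#' @param path CSV path (columns sample_id, assay, replicate, ct; empty ct
#'   fields are read as undetermined).
#' @return validated Ct data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$ct <- suppressWarnings(as.numeric(df$ct))
  df$replicate <- as.integer(df$replicate)
  validate_ct_table(df)
  df
}

#' Write a Ct table as CSV
#' @param ct validated Ct data.frame.
#' @param path output path.
#' @export
write_ct_table <- function(ct, path) {
  validate_ct_table(ct)
  out <- ct[, c("sample_id", "assay", "replicate", "ct")]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write a generic result table as TSV with deterministic column order
#' @param records data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
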