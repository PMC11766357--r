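#' Train a linear max-margin classifier (L1-loss SVM)
#'
#' Minimizes `0.5 * (||w||^2 + b^2) + C * sum hinge` by deterministic dual
#' coordinate descent from a zero start (tolerance 1e-8), so repeated calls
#' give bit-identical solutions. The bias is regularized (augmented constant
#' feature). Features should be standardized by the caller.
#'
#' @param X numeric matrix, samples x features.
#' @param y labels: logical, or a two-level factor/character/±1 vector; the
#'   positive class is `TRUE`, the second level, or +1.
#' @param C soft-margin cost (> 0, default 1).
#' @return list with `weights`, `bias`, `decision` function of a new matrix.
#' @export
train_linear_svm <- function(X, y, C = 1) {
  X <- as.matrix(X)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  if (is.character(y) || is.factor(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2) stop("need exactly two classes", call. = FALSE)
    y <- ifelse(as.character(y) == lev[2], 1, -1)
  }
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  if (C <= 0) stop("`C` must be > 0", call. = FALSE)
  fit <- svm_linear_dcd(X, as.numeric(y), C, 1e-8, 20000L)
  if (!fit$converged && fit$final_violation > 1e-6)
    warning("SVM solver did not reach tolerance; result may be inexact")
  w <- as.numeric(fit$weights)
  b <- fit$bias
  list(weights = w, bias = b,
       decision = function(newX) as.numeric(as.matrix(newX) %*% w + b))
}

# standardize columns by training mean/SD; zero-SD columns get scale 1
.fold_standardize <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu, "-"), 2, sdv, "/"))
}

# Leave-one-out decision scores; standardization is fit within each training
# fold only, so the held-out sample never influences its own score. The
# pooled score is the linear component w.x of the fold's decision function,
# without the fold intercept: the intercept absorbs the one-sample class
# imbalance of each training fold and shifts every held-out score against
# its own class (the classic pessimistic bias of pooled LOOCV scores), while
# within a fold it is constant and carries no ranking information.
.loocv_scores <- function(X, y, C = 1) {
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr_y <- y[-i]
    if (length(unique(tr_y)) < 2)
      stop("a LOOCV training fold contains a single class", call. = FALSE)
    st <- .fold_standardize(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    fit <- train_linear_svm(st$train, tr_y, C)
    scores[i] <- fit$decision(st$test) - fit$bias
  }
  scores
}

# feature-score matrix for the classifier: log2(normalized count + 0.5),
# samples x features, restricted to the contrast groups
.panel_design <- function(counts, metadata, contrast, size_factors = NULL) {
  validate_metadata(metadata)
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  keep <- metadata$condition %in% contrast
  sub <- counts[, keep, drop = FALSE]
  meta <- metadata[keep, ]
  s <- if (is.null(size_factors)) size_factors_median_of_ratios(sub) else
    size_factors[colnames(sub)]
  X <- t(log2(sweep(sub, 2, s, "/") + 0.5))
  y <- meta$condition == contrast[1]
  if (sum(y) < 2 || sum(!y) < 2)
    stop("need >= 2 samples per class", call. = FALSE)
  list(X = X, y = y, meta = meta)
}

#' Leave-one-out cross-validated AUC of a feature pair
#'
#' For every sample, a linear SVM is trained on the remaining samples
#' (features standardized on the training fold only) and the held-out
#' decision value recorded; the pooled scores give one cross-validated ROC.
#'
#' @param counts count matrix.
#' @param metadata sample metadata.
#' @param pair character vector of 1 or 2 feature ids (a single id gives the
#'   single-feature LOOCV AUC).
#' @param contrast length-2 character: positive class condition then
#'   negative class condition.
#' @param C soft-margin cost (default 1).
#' @param ci compute a stratified-bootstrap 95 percent CI on the pooled scores.
#' @param n_boot,seed bootstrap parameters.
#' @return list with `pair`, `scores` (named, per analyzed sample), `labels`,
#'   `cv_auc`, and `cv_auc_ci` when requested.
#' @export
loocv_pair_auc <- function(counts, metadata, pair,
                           contrast = c("basal", "control"), C = 1,
                           ci = FALSE, n_boot = 2000, seed = 1L) {
  stopifnot(all(pair %in% rownames(counts)))
  des <- .panel_design(counts, metadata, contrast)
  X <- des$X[, pair, drop = FALSE]
  scores <- .loocv_scores(X, des$y, C)
  names(scores) <- rownames(des$X)
  out <- list(pair = pair, scores = scores, labels = des$y,
              cv_auc = auc_rank(scores[des$y], scores[!des$y]))
  if (ci)
    out$cv_auc_ci <- auc_bootstrap_ci(scores[des$y], scores[!des$y],
                                      n_boot = n_boot, seed = seed)
  out
}

#' Cross-validated AUC matrix over all candidate pairs
#'
#' Symmetric matrix of LOOCV AUCs for every unordered candidate pair; the
#' diagonal holds single-feature LOOCV AUCs. The best pair (ties broken by
#' lexicographic feature-id order) is attached as an attribute.
#'
#' @inheritParams loocv_pair_auc
#' @param candidates character vector of >= 2 feature ids.
#' @return numeric matrix with `best_pair` and `best_auc` attributes.
#' @export
all_pairs_matrix <- function(counts, metadata, candidates,
                             contrast = c("basal", "control"), C = 1) {
  candidates <- as.character(candidates)
  if (length(candidates) < 2) stop("need >= 2 candidates", call. = FALSE)
  k <- length(candidates)
  M <- matrix(NA_real_, k, k, dimnames = list(candidates, candidates))
  for (i in seq_len(k)) {
    M[i, i] <- loocv_pair_auc(counts, metadata, candidates[i], contrast,
                              C)$cv_auc
    for (j in if (i < k) seq.int(i + 1, k) else integer()) {
      a <- loocv_pair_auc(counts, metadata, candidates[c(i, j)], contrast,
                          C)$cv_auc
      M[i, j] <- a
      M[j, i] <- a
    }
  }
  off <- which(upper.tri(M), arr.ind = TRUE)
  pairs <- data.frame(a = candidates[off[, 1]], b = candidates[off[, 2]],
                      auc = M[off], stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$auc, pairs$a, pairs$b), ]
  attr(M, "best_pair") <- c(pairs$a[1], pairs$b[1])
  attr(M, "best_auc") <- pairs$auc[1]
  M
}

#' SVM-RFE feature ranking
#'
#' Recursive feature elimination: at each step a linear SVM is trained on the
#' surviving features (standardized over all contrast samples) and the
#' feature with the smallest |weight| is eliminated (ties: lexicographically
#' smaller id goes first). Returns the elimination order, first eliminated to
#' last survivor.
#'
#' @inheritParams loocv_pair_auc
#' @param features character vector of >= 2 feature ids.
#' @return character vector: elimination order (last element = top-ranked
#'   feature).
#' @export
svm_rfe_rank <- function(counts, metadata, features,
                         contrast = c("basal", "control"), C = 1) {
  features <- as.character(features)
  if (length(features) < 2) stop("need >= 2 features", call. = FALSE)
  des <- .panel_design(counts, metadata, contrast)
  surviving <- features
  eliminated <- character()
  while (length(surviving) > 1) {
    X <- des$X[, surviving, drop = FALSE]
    st <- .fold_standardize(X, X)
    fit <- train_linear_svm(st$train, des$y, C)
    aw <- abs(fit$weights)
    ord <- order(aw, surviving)  # smallest |w|, then lexicographic id
    drop_f <- surviving[ord[1]]
    eliminated <- c(eliminated, drop_f)
    surviving <- setdiff(surviving, drop_f)
  }
  c(eliminated, surviving)
}
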