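# shared fixture builders for the test suite

# tiny hand-built cohort: 2 controls, 2 basal/post pairs, optional neg control
tiny_metadata <- function(with_nc = FALSE) {
  md <- data.frame(
    sample_id = c("c1", "c2", "b1", "b2", "p1", "p2"),
    condition = c("control", "control", "basal", "basal", "post_tx",
                  "post_tx"),
    subject_id = c("", "", "s1", "s2", "s1", "s2"),
    is_negative_control = FALSE,
    stringsAsFactors = FALSE
  )
  if (with_nc) {
    md <- rbind(md, data.frame(sample_id = "nc1",
                               condition = "negative_control",
                               subject_id = "",
                               is_negative_control = TRUE))
  }
  md
}

tiny_counts <- function(with_nc = FALSE, seed = 1) {
  set.seed(seed)
  md <- tiny_metadata(with_nc)
  n <- nrow(md)
  m <- matrix(rpois(8 * n, lambda = 50), 8, n,
              dimnames = list(sprintf("f%02d", 1:8), md$sample_id))
  storage.mode(m) <- "integer"
  m
}

# brute-force AUC by exhaustive pair counting (independent oracle)
auc_brute <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mwu_enumerate <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  sets <- combn(length(pooled), nx)
  ws <- apply(sets, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided Wilcoxon signed-rank p by full 2^n sign enumeration
wsr_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exact QP oracle for the small-n linear SVM with regularized bias:
# brute-force enumeration of all active sets of the box-constrained dual
#   min 0.5 a' Q a - sum(a),  0 <= a <= C,  Q_ij = y_i y_j (x_i.x_j + 1),
# solving the interior block exactly and checking the KKT conditions;
# independent of the coordinate-descent path. Returns c(w, b).
svm_qp_oracle <- function(X, y, C) {
  n <- nrow(X)
  Xa <- cbind(X, 1)
  Q <- (Xa %*% t(Xa)) * tcrossprod(y)
  states <- expand.grid(rep(list(c("lo", "hi", "in")), n),
                        stringsAsFactors = FALSE)
  for (k in seq_len(nrow(states))) {
    st <- unlist(states[k, ])
    a <- numeric(n)
    a[st == "hi"] <- C
    int <- which(st == "in")
    if (length(int) > 0) {
      rhs <- 1 - Q[int, st == "hi", drop = FALSE] %*%
        rep(C, sum(st == "hi"))
      sol <- tryCatch(solve(Q[int, int, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(sol)) next
      if (any(sol <= 1e-10 | sol >= C - 1e-10)) next
      a[int] <- sol
    }
    g <- as.numeric(Q %*% a) - 1
    if (any(g[st == "lo"] < -1e-8)) next
    if (any(g[st == "hi"] > 1e-8)) next
    if (length(int) > 0 && any(abs(g[int]) > 1e-8)) next
    wb <- as.numeric(t(Xa) %*% (a * y))
    return(wb)
  }
  stop("QP oracle found no KKT point")
}

# exhaustive Youden threshold scan (independent of the implementation's
# candidate-midpoint construction): evaluates J on a dense threshold set
youden_scan <- function(scores, labels) {
  cand <- sort(unique(c(scores - 1e-6, scores + 1e-6,
                        min(scores) - 1, max(scores) + 1)))
  best_j <- -Inf
  for (th in cand) {
    sn <- mean(scores[labels] > th)
    sp <- mean(scores[!labels] <= th)
    best_j <- max(best_j, sn + sp - 1)
  }
  best_j
}
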