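# Exact nonparametric tests with documented tie/zero conventions.
#
# Both tests work on doubled midranks (2 * rank), which are integers even in
# the presence of ties, so the exact null distributions can be built by
# subset-sum dynamic programming without floating-point bins. Two-sided
# p-values are 2 * min(lower tail, upper tail), capped at 1; tails include
# the observed value.

# distribution of the sum over all subsets (each of the 2^n sign assignments)
# of integer values v; returns counts vector indexed by sum 0..sum(v)
.signed_rank_counts <- function(v) {
  counts <- numeric(sum(v) + 1)
  counts[1] <- 1
  for (val in v) {
    shifted <- c(numeric(val), counts[seq_len(length(counts) - val)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test
#'
#' Zeros are dropped before ranking (the classical convention); ties in
#' absolute value receive midranks. For n <= `exact_max` (default 25) the
#' exact conditional null distribution is built by dynamic programming over
#' doubled midranks (exact even with ties); above that a normal approximation
#' with tie correction and continuity correction is used. All paired
#' differences zero gives p = 1 by convention.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max largest n for which the exact distribution is computed.
#' @return list with `statistic` (W+, sum of positive-difference ranks), `p`
#'   (two-sided), `n_used`, `exact` flag.
#' @export
wilcoxon_signed_rank_test <- function(d, exact_max = 25) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p = 1, n_used = 0L, exact = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    v <- as.integer(round(2 * r))
    counts <- .signed_rank_counts(v)
    total <- 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[seq.int(w2 + 1, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = W, p = p, n_used = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    list(statistic = W, p = min(1, 2 * pnorm(-abs(z))), n_used = n,
         exact = FALSE)
  }
}

# distribution of the rank-sum of a size-nx subset drawn from integer values v
# (doubled midranks); returns matrix row = subset size 0..nx, col = sum 0..sum(v)
.ranksum_counts <- function(v, nx) {
  S <- sum(v)
  dp <- matrix(0, nx + 1, S + 1)
  dp[1, 1] <- 1
  for (val in v) {
    for (k in seq.int(nx, 1)) { # high to low so each value is used once

      shifted <- c(numeric(val), dp[k, seq_len(S + 1 - val)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  dp
}

#' Exact Mann-Whitney U test
#'
#' Combined-sample midranks; U = rank-sum of `x` minus nx(nx+1)/2. For
#' nx + ny <= `exact_max_total` (default 30) the exact conditional null
#' distribution (which accounts for ties through the observed midranks) is
#' built by subset-sum dynamic programming; otherwise a normal approximation
#' with tie and continuity correction is used.
#'
#' @param x,y numeric vectors (the two groups).
#' @param exact_max_total largest combined n for the exact distribution.
#' @return list with `statistic` (U for `x`), `p` (two-sided), `exact` flag.
#' @export
mann_whitney_u_test <- function(x, y, exact_max_total = 30) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  Wx <- sum(r[seq_len(nx)])
  U <- Wx - nx * (nx + 1) / 2
  N <- nx + ny
  if (N <= exact_max_total) {
    v <- as.integer(round(2 * r))
    dp <- .ranksum_counts(v, nx)
    dist <- dp[nx + 1, ]
    total <- choose(N, nx)
    w2 <- as.integer(round(2 * Wx))
    p_le <- sum(dist[seq_len(w2 + 1)]) / total
    p_ge <- sum(dist[seq.int(w2 + 1, length(dist))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = U, p = p, exact = TRUE)
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 *
      (N + 1 - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    list(statistic = U, p = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
  }
}
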