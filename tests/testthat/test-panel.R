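test_that("the linear SVM solves simple geometries and the QP oracle", {
  # 1-D separable pair
  fit <- train_linear_svm(matrix(c(0, 10), 2, 1), c(FALSE, TRUE))
  dv <- fit$decision(matrix(c(0, 10), 2, 1))
  expect_lt(dv[1], 0)
  expect_gt(dv[2], 0)
  expect_error(train_linear_svm(matrix(1:3, 3, 1), c(TRUE, TRUE, TRUE)),
               "class")
  # 4-point quadratic-program oracle (active-set enumeration), tolerance 1e-4
  X <- matrix(c(0, 0, 2, 0, 0, 2, 2, 2), 4, 2, byrow = TRUE)
  y <- c(-1, -1, 1, 1)
  fit2 <- train_linear_svm(X, y == 1, C = 1)
  oracle <- svm_qp_oracle(X, y, 1)
  expect_lt(max(abs(c(fit2$weights, fit2$bias) - oracle)), 1e-4)
  set.seed(71)
  for (rep in 1:5) {
    X <- matrix(rnorm(8), 4, 2)
    y <- c(-1, 1, -1, 1)
    fit3 <- train_linear_svm(X, y == 1, C = 1)
    oracle3 <- svm_qp_oracle(X, y, 1)
    expect_lt(max(abs(c(fit3$weights, fit3$bias) - oracle3)), 1e-4)
  }
})

test_that("duplicating every sample with halved cost leaves the solution fixed", {
  set.seed(72)
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(c(TRUE, FALSE), 5)
  f1 <- train_linear_svm(X, y, C = 1)
  f2 <- train_linear_svm(rbind(X, X), c(y, y), C = 0.5)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
  expect_equal(f1$bias, f2$bias, tolerance = 1e-6)
})

test_that("LOOCV scores never leak the held-out sample's label", {
  cfg <- simulation_config(n_control = 6, n_pairs = 6, n_features = 20,
                           n_negative_controls = 0, seed = 73)
  sim <- simulate_counts(cfg)
  des <- evsmallrna:::.panel_design(sim$counts, sim$metadata,
                                    c("basal", "control"))
  X <- des$X[, 1:2]
  sc <- evsmallrna:::.loocv_scores(X, des$y)
  # flipping sample i's label changes other folds' models but not score_i
  for (i in c(1, 5, 9)) {
    y2 <- des$y
    y2[i] <- !y2[i]
    sc2 <- evsmallrna:::.loocv_scores(X, y2)
    expect_equal(sc2[i], sc[i], tolerance = 1e-9)
  }
})

test_that("cv_auc is internally consistent with the stored pooled scores", {
  cfg <- simulation_config(n_control = 6, n_pairs = 6, n_features = 20,
                           n_negative_controls = 0, seed = 74)
  sim <- simulate_counts(cfg)
  f <- rownames(sim$counts)[1:2]
  r <- loocv_pair_auc(sim$counts, sim$metadata, f, ci = TRUE, n_boot = 200)
  expect_equal(r$cv_auc, auc_rank(r$scores[r$labels], r$scores[!r$labels]))
  expect_lte(r$cv_auc_ci[1], r$cv_auc)
  expect_gte(r$cv_auc_ci[2], r$cv_auc)
})

test_that("an all-zero feature does not perturb pair decision scores", {
  cfg <- simulation_config(n_control = 6, n_pairs = 6, n_features = 20,
                           n_negative_controls = 0, seed = 75)
  sim <- simulate_counts(cfg)
  m <- rbind(sim$counts, f_zero = 0L)
  f <- rownames(sim$counts)[3]
  r1 <- loocv_pair_auc(m, sim$metadata, f)
  r2 <- loocv_pair_auc(m, sim$metadata, c(f, "f_zero"))
  expect_equal(unname(r2$scores), unname(r1$scores), tolerance = 1e-6)
})

test_that("a feature paired with itself reproduces its single-feature AUC", {
  # within any fold the duplicated dimension gives a decision score that is
  # a positive multiple of the single-feature score, so fold-level rankings
  # are identical; the fold-specific scale can reorder scores *between*
  # folds, so the pooled AUCs agree closely but not bit-exactly
  for (s in c(76, 77, 78)) {
    cfg <- simulation_config(n_control = 6, n_pairs = 8, n_features = 30,
                             n_negative_controls = 0, seed = s)
    sim <- simulate_counts(cfg)
    f <- rownames(sim$counts)[5]
    r1 <- loocv_pair_auc(sim$counts, sim$metadata, f)
    r2 <- loocv_pair_auc(sim$counts, sim$metadata, c(f, f))
    expect_gt(cor(r1$scores, r2$scores), 0.99)
    expect_lt(abs(r2$cv_auc - r1$cv_auc), 0.06)
  }
})

test_that("the pair matrix is symmetric with single-feature diagonal", {
  cfg <- simulation_config(n_control = 5, n_pairs = 5, n_features = 20,
                           n_negative_controls = 0, seed = 79)
  sim <- simulate_counts(cfg)
  cands <- rownames(sim$counts)[1:3]
  M <- all_pairs_matrix(sim$counts, sim$metadata, cands)
  expect_identical(M, t(M))
  expect_equal(sum(!is.na(M[upper.tri(M)])), 3)
  for (f in cands)
    expect_equal(M[f, f], loocv_pair_auc(sim$counts, sim$metadata, f)$cv_auc)
  expect_length(attr(M, "best_pair"), 2)
})

test_that("SVM-RFE keeps informative features and drops noise first", {
  noise_first <- 0
  survivor_hits <- 0
  for (s in 1:20) {
    set.seed(s + 700)
    n <- 30
    md <- data.frame(
      sample_id = sprintf("s%02d", 1:n),
      condition = rep(c("basal", "control"), each = n / 2),
      subject_id = c(sprintf("u%02d", 1:(n / 2)), rep("", n / 2)),
      is_negative_control = FALSE, stringsAsFactors = FALSE)
    md$condition[md$condition == "basal"] <- "basal"
    base <- matrix(rpois(5 * n, 60), 5, n,
                   dimnames = list(paste0("f", 1:5), md$sample_id))
    # f1 informative: doubled in basal; f2-f5 noise
    base[1, md$condition == "basal"] <-
      base[1, md$condition == "basal"] * 2L
    storage.mode(base) <- "integer"
    rk2 <- svm_rfe_rank(base, md, c("f1", "f2"))
    noise_first <- noise_first + (rk2[1] == "f2")
    rk5 <- svm_rfe_rank(base, md, paste0("f", 1:5))
    survivor_hits <- survivor_hits + (rk5[5] == "f1")
  }
  expect_gte(noise_first, 18)
  expect_gte(survivor_hits, 17)
  # deterministic tie-break: ranking invariant to input feature order
  set.seed(720)
  md <- data.frame(sample_id = sprintf("s%02d", 1:12),
                   condition = rep(c("basal", "control"), each = 6),
                   subject_id = c(sprintf("u%d", 1:6), rep("", 6)),
                   is_negative_control = FALSE, stringsAsFactors = FALSE)
  m <- matrix(rpois(4 * 12, 40), 4, 12,
              dimnames = list(paste0("g", 1:4), md$sample_id))
  storage.mode(m) <- "integer"
  expect_equal(svm_rfe_rank(m, md, paste0("g", 1:4)),
               svm_rfe_rank(m, md, paste0("g", 4:1)))
})
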