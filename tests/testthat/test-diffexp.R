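test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(2L, 4L, 4L, 8L), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  s <- size_factors_median_of_ratios(m)
  expect_equal(as.numeric(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical samples give unit factors
  m2 <- cbind(s1 = c(a = 3L, b = 9L), s2 = c(3L, 9L), s3 = c(3L, 9L))
  expect_equal(as.numeric(size_factors_median_of_ratios(m2)), rep(1, 3))
  # geometric mean is exactly 1
  m3 <- tiny_counts()
  s3 <- size_factors_median_of_ratios(m3)
  expect_equal(exp(mean(log(s3))), 1, tolerance = 1e-9)
})

test_that("size factors are equivariant under permutation and scaling", {
  m <- tiny_counts(seed = 41)
  s <- size_factors_median_of_ratios(m)
  perm <- c(3, 1, 2, 6, 5, 4)
  s_perm <- size_factors_median_of_ratios(m[, perm])
  expect_equal(as.numeric(s_perm), as.numeric(s[perm]))
  # scaling one sample by c multiplies its factor by c (up to the global
  # geometric-mean rescale shared by all samples)
  m2 <- m
  m2[, 1] <- m2[, 1] * 4L
  s2 <- size_factors_median_of_ratios(m2)
  expect_equal(unname(s2[1] / s[1]) / unname(s2[2] / s[2]), 4,
               tolerance = 1e-9)
})

test_that("size factors agree with the DESeq2 implementation", {
  m <- tiny_counts(seed = 42) + 1L # all-positive reference set
  ours <- size_factors_median_of_ratios(m)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  theirs <- theirs / exp(mean(log(theirs)))
  expect_equal(as.numeric(ours), as.numeric(theirs), tolerance = 1e-10)
})

test_that("moment dispersion estimates follow the shrunken MoM formula", {
  # two groups engineered to mean 10, variance 30 -> raw alpha 0.2
  a <- sqrt(30)
  g <- c(10 - a, 10, 10 + a)
  normmat <- matrix(c(g, g), 1, 6)
  alpha <- estimate_dispersion(normmat, rep(c("x", "y"), each = 3))
  expect_equal(alpha, 0.2, tolerance = 1e-12) # single feature: no-op shrink
  # underdispersed data clamps to zero
  normmat2 <- matrix(rep(c(9, 10, 11, 9, 10, 11), 1), 1, 6)
  expect_equal(estimate_dispersion(normmat2, rep(c("x", "y"), each = 3)), 0)
  # zero-mean feature is marked untestable
  normmat3 <- rbind(normmat, 0)
  expect_true(is.na(estimate_dispersion(normmat3,
                                        rep(c("x", "y"), each = 3))[2]))
})

test_that("signed fold change and its inverse follow the table convention", {
  expect_equal(signed_fc(0), 1)
  expect_equal(signed_fc(1), 2)
  expect_equal(signed_fc(-1), -2)
  expect_equal(signed_fc(-log2(1.76)), -1.76, tolerance = 1e-12)
  # round trip for |f| >= 1
  for (f in c(1, 1.47, -1.76, 4.08, -13)) {
    lfc <- if (f >= 0) log2(f) else -log2(-f)
    expect_equal(signed_fc(lfc), f, tolerance = 1e-12)
  }
})

test_that("unpaired Wald screen handles identical and empty features", {
  md <- tiny_metadata()
  # every sample identical -> unit size factors -> identical normalized
  # counts in both groups
  m <- matrix(rep(c(50L, 10L, 200L, 0L, 7L), 6), 5, 6,
              dimnames = list(paste0("f0", 1:5), md$sample_id))
  de <- wald_test_unpaired(m, md)
  r1 <- de[de$feature == "f01", ]
  expect_equal(r1$lfc, 0)
  expect_equal(r1$p, 1)
  r2 <- de[de$feature == "f04", ]
  expect_false(r2$testable)
  expect_equal(r2$p, 1)
  expect_equal(r2$lfc, 0)
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_true(all(abs(de$fc_signed) >= 1))
})

test_that("paired test matches sign-enumeration and is antisymmetric", {
  cfg <- simulation_config(n_control = 2, n_pairs = 6, n_features = 30,
                           n_negative_controls = 0, seed = 44)
  sim <- simulate_counts(cfg)
  pt <- paired_test(sim$counts, sim$metadata)
  # oracle: recompute each feature's per-subject log-ratios and enumerate
  s <- size_factors_median_of_ratios(
    sim$counts[, sim$metadata$condition != "control"])
  norm <- sweep(sim$counts[, names(s)], 2, s, "/")
  md <- sim$metadata
  basal <- md$sample_id[md$condition == "basal"]
  post <- md$sample_id[md$condition == "post_tx"]
  for (i in seq_len(10)) {
    d <- log2((norm[i, post] + 0.5) / (norm[i, basal] + 0.5))
    expect_equal(pt$p[i], wsr_enumerate(d), tolerance = 1e-12)
  }
  # swapping contrast direction negates lfc, keeps p
  pt_rev <- paired_test(sim$counts, sim$metadata,
                        contrast = c("basal", "post_tx"))
  expect_equal(pt_rev$lfc, -pt$lfc, tolerance = 1e-12)
  expect_equal(pt_rev$p, pt$p, tolerance = 1e-12)
})

test_that("six concordant pairs give the exact two-sided p 0.03125", {
  md <- tiny_metadata()
  # six subjects, post always above basal
  md6 <- data.frame(
    sample_id = c(paste0("b", 1:6), paste0("p", 1:6)),
    condition = rep(c("basal", "post_tx"), each = 6),
    subject_id = rep(paste0("s", 1:6), 2),
    is_negative_control = FALSE, stringsAsFactors = FALSE)
  set.seed(45)
  base <- matrix(rpois(10 * 6, 100), 10, 6)
  post <- base
  post[1:5, ] <- post[1:5, ] * 2L  # five features doubled after treatment
  post <- post + matrix(rpois(10 * 6, 3), 10, 6)
  m <- cbind(base, post)
  dimnames(m) <- list(paste0("f", 1:10), md6$sample_id)
  storage.mode(m) <- "integer"
  pt <- paired_test(m, md6)
  # doubled features: every subject concordant up; flat features are pushed
  # down by normalization -> the exact two-sided p is 2/2^6 throughout
  expect_true(all(pt$p == 0.03125))
  expect_true(all(pt$lfc[1:5] > 0))
  expect_true(all(pt$lfc[6:10] < 0))
})
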