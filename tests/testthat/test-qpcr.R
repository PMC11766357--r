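mk_ct <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], assay = r[[2]],
               replicate = seq_along(r[[3]]), ct = r[[3]],
               stringsAsFactors = FALSE)))
}

test_that("replicate aggregation drops outliers and undetermined wells", {
  ct <- mk_ct(list("s1", "m1", c(25.0, 25.1, 28.0)),
              list("s2", "m1", c(25.0, 25.0, 25.0)),
              list("s3", "m1", 30.0),
              list("s4", "m1", c(NA, NA, NA)))
  expect_warning(agg <- aggregate_triplicates(ct), "no usable replicate")
  expect_equal(agg$mean_ct[agg$sample_id == "s1"], 25.05)
  expect_equal(agg$n_replicates_used[agg$sample_id == "s1"], 2)
  expect_equal(agg$mean_ct[agg$sample_id == "s2"], 25.0)
  expect_equal(agg$n_replicates_used[agg$sample_id == "s2"], 3)
  expect_equal(agg$mean_ct[agg$sample_id == "s3"], 30.0)
  expect_false("s4" %in% agg$sample_id)
})

test_that("delta-Ct quantification follows the 2^-ddCt identities", {
  md <- data.frame(sample_id = c("s1", "s2"),
                   condition = c("control", "basal"),
                   subject_id = c("", "u1"),
                   is_negative_control = FALSE, stringsAsFactors = FALSE)
  agg <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                    assay = rep(c("tgt", "ref"), 2),
                    mean_ct = c(25, 20, 24, 20),
                    ct_sd = 0, n_replicates_used = 3,
                    stringsAsFactors = FALSE)
  rq <- relative_expression(agg, "ref", md, calibrator = "control")
  s1 <- rq[rq$sample_id == "s1", ]
  expect_equal(s1$delta_ct, 5)
  expect_equal(s1$rel_expr, 2^-5)
  expect_equal(log2(s1$rel_expr), -s1$delta_ct, tolerance = 1e-12)
  # calibrator group mean dCt anchors rq at 1 for s1, 2 for s2 (dCt 4)
  expect_equal(s1$rq, 1)
  expect_equal(rq$rq[rq$sample_id == "s2"], 2)
  # reference against itself would be constant: rel_expr of a sample is
  # invariant to a constant shift of all its Ct values
  agg2 <- agg
  agg2$mean_ct[agg2$sample_id == "s1"] <-
    agg2$mean_ct[agg2$sample_id == "s1"] + 3
  rq2 <- relative_expression(agg2, "ref", md, calibrator = "control")
  expect_equal(rq2$rel_expr[rq2$sample_id == "s1"], s1$rel_expr)
  # missing reference excludes the sample with a warning
  agg3 <- agg[-2, ]
  expect_warning(rq3 <- relative_expression(agg3, "ref", md), "excluded")
  expect_false("s1" %in% rq3$sample_id)
})

test_that("group comparisons use the exact tests with correct pairing", {
  md <- data.frame(
    sample_id = c(paste0("c", 1:3), paste0("b", 1:6), paste0("p", 1:6)),
    condition = c(rep("control", 3), rep("basal", 6), rep("post_tx", 6)),
    subject_id = c(rep("", 3), rep(paste0("u", 1:6), 2)),
    is_negative_control = FALSE, stringsAsFactors = FALSE)
  rq <- data.frame(
    sample_id = md$sample_id, assay = "m1", condition = md$condition,
    mean_ct = 25, delta_ct = c(4, 5, 6, 1, 2, 3, 1, 2, 3, 2, 3, 4, 2, 3, 4),
    stringsAsFactors = FALSE)
  rq$rel_expr <- 2^-rq$delta_ct
  rq$rq <- rq$rel_expr
  # unpaired: -dCt separates completely at 3 v 6 -> exact MWU
  cmp <- compare_groups(rq, md, "m1", c("basal", "control"))
  expect_equal(cmp$test, "mann_whitney_u")
  expect_equal(cmp$p, mwu_enumerate(-rq$delta_ct[4:9], -rq$delta_ct[1:3]))
  expect_equal(cmp$direction, 1)
  # paired: post dCt exceeds basal by exactly 1 in every subject
  cmp2 <- compare_groups(rq, md, "m1", c("post_tx", "basal"))
  expect_equal(cmp2$test, "wilcoxon_signed_rank")
  expect_equal(cmp2$p, 0.03125)
  expect_equal(cmp2$direction, -1)
  # identical groups give p 1
  rq3 <- rq
  rq3$delta_ct <- 2
  expect_equal(compare_groups(rq3, md, "m1", c("basal", "control"))$p, 1)
  expect_equal(compare_groups(rq3, md, "m1", c("post_tx", "basal"))$p, 1)
})

test_that("validation ROC recovers planted dysregulation and stays null-calibrated", {
  aucs_alt <- c()
  for (s in 1:10) {
    cfg <- simulation_config(n_control = 33, n_pairs = 14, n_features = 60,
                             frac_de_vs_control = 0.1, lfc_magnitude = 1,
                             n_negative_controls = 0, seed = 900 + s)
    sim <- simulate_counts(cfg)
    tr <- sim$truth$features
    assay <- tr$feature_id[tr$lfc_basal_vs_control == 1][1]
    ct <- simulate_ct_table(sim$truth, sim$metadata, assay,
                            sim$truth$reference_feature,
                            ct_noise_sd = 0.1, seed = s)
    rq <- relative_expression(aggregate_triplicates(ct),
                              sim$truth$reference_feature, sim$metadata)
    roc <- validation_roc(rq, assay, c("basal", "control"), n_boot = 200,
                          seed = s)
    expect_lte(roc$ci[1], roc$auc)
    expect_gte(roc$ci[2], roc$auc)
    aucs_alt <- c(aucs_alt, roc$auc)
  }
  expect_true(all(aucs_alt > 0.9))
  # null assay: mean AUC near 0.5 across seeds
  aucs_null <- c()
  for (s in 1:40) {
    cfg <- simulation_config(n_control = 15, n_pairs = 15, n_features = 40,
                             frac_de_vs_control = 0, frac_de_paired = 0,
                             n_negative_controls = 0, seed = 940 + s)
    sim <- simulate_counts(cfg)
    tr <- sim$truth$features
    assay <- setdiff(tr$feature_id, sim$truth$reference_feature)[1]
    ct <- simulate_ct_table(sim$truth, sim$metadata, assay,
                            sim$truth$reference_feature,
                            ct_noise_sd = 0.3, seed = s)
    rq <- relative_expression(aggregate_triplicates(ct),
                              sim$truth$reference_feature, sim$metadata)
    aucs_null <- c(aucs_null, auc_rank(
      -rq$delta_ct[rq$condition == "basal"],
      -rq$delta_ct[rq$condition == "control"]))
  }
  expect_lt(abs(mean(aucs_null) - 0.5), 0.08)
})

test_that("a planted basal-up assay is detected with high power", {
  detected <- 0
  n_seeds <- 100
  for (s in 1:n_seeds) {
    cfg <- simulation_config(n_control = 15, n_pairs = 15, n_features = 40,
                             frac_de_vs_control = 0.1, lfc_magnitude = 1,
                             n_negative_controls = 0, seed = 2000 + s)
    sim <- simulate_counts(cfg)
    tr <- sim$truth$features
    assay <- tr$feature_id[tr$lfc_basal_vs_control == 1][1]
    ct <- simulate_ct_table(sim$truth, sim$metadata, assay,
                            sim$truth$reference_feature,
                            ct_noise_sd = 0.3, seed = s)
    rq <- relative_expression(aggregate_triplicates(ct),
                              sim$truth$reference_feature, sim$metadata)
    med_up <- median(rq$rel_expr[rq$condition == "basal"]) >
      median(rq$rel_expr[rq$condition == "control"])
    cmp <- compare_groups(rq, sim$metadata, assay, c("basal", "control"))
    detected <- detected + (med_up && cmp$p < 0.05)
  }
  expect_gte(detected / n_seeds, 0.8)
})
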