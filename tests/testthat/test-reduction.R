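toy_table <- function(X, labels) {
  colnames(X) <- paste0("glszm_F", seq_len(ncol(X)), "_t1w")
  feature_table(X, labels)
}

test_that("z-score standardization uses the sample SD and is idempotent", {
  t <- toy_table(cbind(c(1, 2, 3), c(10, 20, 60)), c(0, 1, 1))
  s <- zscore_standardize(t)
  expect_equal(unname(s$features[, 1]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(s$features))), 1e-10)
  expect_equal(unname(apply(s$features, 2, sd)), c(1, 1), tolerance = 1e-10)
  s2 <- zscore_standardize(s)
  expect_equal(s2$features, s$features, tolerance = 1e-12)
  # zero-variance columns are excluded with a recorded reason
  tz <- toy_table(cbind(c(1, 2, 3), c(5, 5, 5)), c(0, 1, 1))
  sz <- zscore_standardize(tz)
  expect_equal(ncol(sz$features), 1)
  expect_equal(attr(sz, "zero_variance_dropped"), "glszm_F2_t1w")
})

test_that("ICC(1,1) equals the one-way ANOVA closed form", {
  expect_equal(icc_1_1(cbind(1:4, 1:4)), 1)
  expect_equal(icc_1_1(cbind(1:4, 4:1)), -1)
  expect_equal(icc_1_1(cbind(1:4, 1:4 + 0.5)),
               (3.33333333333 - 0.125) / (3.33333333333 + 0.125),
               tolerance = 1e-8)
  # symmetric in rater order
  set.seed(11)
  x <- cbind(rnorm(20), rnorm(20))
  expect_equal(icc_1_1(x), icc_1_1(x[, 2:1]))
  # against R's own ANOVA decomposition on random data
  for (r in 1:5) {
    y <- cbind(rnorm(12), rnorm(12))
    df <- data.frame(v = c(y), subj = factor(rep(1:12, 2)))
    ms <- anova(aov(v ~ subj, df))$`Mean Sq`   # [1] between, [2] within
    expect_equal(icc_1_1(y), (ms[1] - ms[2]) / (ms[1] + ms[2]),
                 tolerance = 1e-10)
  }
  expect_warning(v <- icc_1_1(cbind(c(1, 1), c(1, 1))), "zero total variance")
  expect_equal(v, 1)
})

test_that("robustness filter drops features unstable under perturbation", {
  set.seed(12)
  n <- 80
  X <- cbind(rnorm(n), rnorm(n), rnorm(n))
  t0 <- toy_table(X, rbinom(n, 1, 0.5))
  # identical perturbation: all ICC = 1, nothing dropped
  r <- robustness_filter(t0, t0)
  expect_true(all(r$icc == 1))
  expect_length(r$dropped, 0)
  # a feature replaced by independent noise has ICC ~ 0 and is dropped
  Xp <- X; Xp[, 2] <- rnorm(n)
  r2 <- robustness_filter(t0, toy_table(Xp, t0$labels))
  expect_equal(r2$dropped, "glszm_F2_t1w")
  expect_lt(abs(mean(replicate(1000, {
    a <- rnorm(40); icc_1_1(cbind(a, rnorm(40)))
  }))), 0.05)
  # strict inequality at the threshold: ICC exactly at the cut is kept
  Xq <- X; Xq[, 3] <- X[, 3] * 0.3 + rnorm(n)
  icc3 <- icc_1_1(cbind(X[, 3], Xq[, 3]))
  r3 <- robustness_filter(t0, toy_table(Xq, t0$labels), threshold = icc3)
  expect_false("glszm_F3_t1w" %in% r3$dropped)
  r4 <- robustness_filter(t0, toy_table(Xq, t0$labels),
                          threshold = icc3 + 1e-12)
  expect_true("glszm_F3_t1w" %in% r4$dropped)
  # mismatched tables error
  expect_error(robustness_filter(t0, toy_table(X[1:10, ], t0$labels[1:10])),
               "do not match")
})

test_that("correlation filter prunes by label correlation, strictly above R", {
  set.seed(13)
  n <- 60
  lab <- rbinom(n, 1, 0.5)
  strong <- lab + rnorm(n, 0, 0.3)          # informative
  weak <- strong + rnorm(n, 0, 1e-8)        # duplicate, same label corr
  weak2 <- -strong + rnorm(n, 0, 1e-8)      # anticorrelated duplicate
  X <- cbind(strong, weak, weak2)
  t <- toy_table(X, lab)
  cf <- correlation_filter(t, 0.9)
  # three mutually collinear columns leave exactly one survivor
  expect_equal(ncol(cf$table$features), 1)
  expect_equal(nrow(cf$dropped), 2)
  # a pair at exactly the threshold is retained (strict >)
  set.seed(14)
  a <- rnorm(50); b <- 0.8 * a + rnorm(50)
  t2 <- toy_table(cbind(a, b), rbinom(50, 1, 0.5))
  r_ab <- abs(cor(a, b))
  keep <- correlation_filter(t2, r_threshold = r_ab)
  expect_equal(ncol(keep$table$features), 2)
  drop <- correlation_filter(t2, r_threshold = r_ab - 1e-12)
  expect_equal(ncol(drop$table$features), 1)
  # within a pair the less label-correlated member is dropped
  lab3 <- rbinom(80, 1, 0.5)
  f1 <- lab3 + rnorm(80, 0, 0.2)
  f2 <- f1 + rnorm(80, 0, 0.05)   # noisier copy: lower label correlation
  t3 <- toy_table(cbind(f1, f2), lab3)
  cf3 <- correlation_filter(t3, 0.9)
  kept_is_better <- abs(cor(t3$features[, cf3$dropped$kept], lab3)) >=
    abs(cor(t3$features[, cf3$dropped$feature], lab3))
  expect_true(kept_is_better)
  # constant features are dropped with a reason
  t4 <- toy_table(cbind(rnorm(30), rep(2, 30)), rbinom(30, 1, 0.5))
  cf4 <- correlation_filter(t4)
  expect_equal(cf4$constant_dropped, "glszm_F2_t1w")
})

test_that("backward selection keeps an informative feature and scores sanely", {
  # balanced accuracy of a constant classifier is 0.5
  expect_equal(marrowtex:::balanced_accuracy(c(0, 0, 1, 1, 1),
                                             rep(1, 5)), 0.5)
  # k_target = n_features: identity selection, single curve point
  set.seed(15)
  t <- toy_table(matrix(rnorm(40 * 3), 40, 3), rbinom(40, 1, 0.5))
  s <- sbs_select(t, "knn", k_target = 3, seed = 1)
  expect_setequal(s$selected, colnames(t$features))
  expect_length(s$curve, 1)
  # planted informative feature among 9 noise features survives RF selection
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 80
    lab <- rep(c(0, 1), each = n / 2)
    X <- cbind(lab * 2 + rnorm(n), matrix(rnorm(n * 9), n, 9))
    tt <- toy_table(X, lab)
    sel <- sbs_select(tt, "rf", k_target = 5, seed = seed)
    if ("glszm_F1_t1w" %in% sel$selected) hits <- hits + 1
  }
  expect_gte(hits, 19)
  # curve covers every feature count from |F| down to k_target
  expect_equal(as.integer(names(sbs_select(t, "knn", k_target = 1,
                                           seed = 2)$curve)), 3:1)
})

test_that("per-model selections aggregate into a ranked candidate set", {
  same <- list(m1 = letters[1:5], m2 = letters[1:5], m3 = letters[1:5])
  agg <- aggregate_top_features(same)
  expect_setequal(agg$candidates, letters[1:5])
  disjoint <- list(m1 = letters[1:5], m2 = letters[6:10], m3 = letters[11:15])
  agg2 <- aggregate_top_features(disjoint)
  expect_length(agg2$candidates, 15)
  expect_true(all(agg2$votes == 1))
  # a three-model membership pattern with one unanimous feature
  sets <- list(
    rf  = c("gldm_LargeDependenceHighGrayLevelEmphasis_t1w",
            "glszm_LargeAreaHighGrayLevelEmphasis_t1w",
            "glszm_SizeZoneNonUniformity_t1w",
            "glszm_ZonePercentage_t2w", "glszm_ZoneVariance_t2w"),
    knn = c("gldm_LargeDependenceHighGrayLevelEmphasis_t1w",
            "glszm_LargeAreaHighGrayLevelEmphasis_t1w",
            "glszm_SmallAreaLowGrayLevelEmphasis_t1w",
            "glszm_LargeAreaHighGrayLevelEmphasis_t2w", "ngtdm_Strength_t2w"),
    mlp = c("gldm_LargeDependenceHighGrayLevelEmphasis_t1w",
            "glszm_SizeZoneNonUniformity_t1w",
            "glszm_ZonePercentage_t2w", "glszm_ZoneVariance_t2w",
            "ngtdm_Coarseness_t2w"))
  agg3 <- aggregate_top_features(sets)
  expect_length(agg3$candidates, 9)
  expect_equal(unname(agg3$votes["gldm_LargeDependenceHighGrayLevelEmphasis_t1w"]), 3)
  expect_equal(agg3$candidates[1], "gldm_LargeDependenceHighGrayLevelEmphasis_t1w")
  expect_equal(dim(agg3$membership), c(9, 3))
})

test_that("backward-elimination logistic regression matches closed forms", {
  # single binary predictor, 2x2 table 30/10 vs 10/30: B = log OR = log 9
  x <- c(rep(1, 40), rep(0, 40))
  y <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  t <- feature_table(matrix(x, ncol = 1,
                            dimnames = list(NULL, "glszm_F1_t1w")), y)
  fit <- backward_eliminate_logistic(t)
  expect_equal(unname(fit$B["glszm_F1_t1w"]), log(9), tolerance = 1e-6)
  expect_equal(unname(fit$OR["glszm_F1_t1w"]), 9, tolerance = 1e-6)
  # schema: coefficients, Wald p, OR with ordered CI, intercept
  expect_true(all(c("B", "SE", "wald_p", "OR", "CI", "intercept") %in%
                  names(fit)))
  expect_true(all(fit$CI[, "lower"] <= fit$CI[, "upper"]))
  expect_equal(unname(fit$OR), unname(exp(fit$B)))
  # a pure-noise candidate is eliminated ~ (1 - alpha) of the time
  set.seed(16)
  kept <- replicate(1000, {
    yy <- rbinom(300, 1, 0.5)
    tt <- feature_table(matrix(rnorm(300), ncol = 1,
                               dimnames = list(NULL, "glszm_N_t1w")), yy)
    length(backward_eliminate_logistic(tt, alpha = 0.05)$features)
  })
  expect_equal(mean(kept == 0), 0.95, tolerance = 0.03)
})

test_that("the reduction ladder conserves every feature exactly once", {
  co <- small_cohort(n_patients = 4, seed = 55)
  cfg <- default_config(seed = 2)
  ex <- extract_cohort_features(co, cfg)
  r1 <- robustness_filter(ex$main, ex$contracted, cfg$icc_threshold)
  r2 <- robustness_filter(r1$table,
                          marrowtex:::subset_features(ex$voxel,
                                                      colnames(r1$table$features)),
                          cfg$icc_threshold)
  std <- zscore_standardize(r2$table)
  cf <- correlation_filter(std, cfg$r_threshold)
  all_out <- c(r1$dropped, r2$dropped, attr(std, "zero_variance_dropped"),
               cf$dropped$feature, cf$constant_dropped,
               colnames(cf$table$features))
  expect_setequal(all_out, colnames(ex$main$features))
  expect_equal(anyDuplicated(all_out), 0)
})
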