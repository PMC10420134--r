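make_fit <- function(B, intercept, features = names(B)) {
  structure(list(features = features, B = B,
                 SE = B * 0 + 0.1, wald_p = B * 0,
                 OR = exp(B), CI = cbind(lower = exp(B - 0.2),
                                         upper = exp(B + 0.2)),
                 intercept = intercept, intercept_p = 0,
                 eliminated = character(0), prediction_threshold = NULL),
            class = "logistic_fit")
}

test_that("predicted probabilities follow the logistic form", {
  fit <- make_fit(c(f1 = -0.98, f2 = -0.66), intercept = 1.63)
  X <- matrix(0, 2, 2, dimnames = list(NULL, c("f1", "f2")))
  # an all-zero feature row scores logistic(intercept)
  expect_equal(predict_proba(fit, X), rep(1 / (1 + exp(-1.63)), 2),
               tolerance = 1e-12)
  expect_equal(round(predict_proba(fit, X)[1], 3), 0.836)
  fit0 <- make_fit(c(f1 = 0), intercept = 0)
  expect_equal(predict_proba(fit0, matrix(5, 1, 1,
                                          dimnames = list(NULL, "f1"))), 0.5)
  # negative coefficients: score decreases as the feature grows
  xs <- matrix(seq(-2, 2, length.out = 9), ncol = 1,
               dimnames = list(NULL, "f1"))
  sc <- predict_proba(make_fit(c(f1 = -1), 0.5), xs)
  expect_true(all(diff(sc) < 0))
  expect_error(predict_proba(fit, matrix(0, 1, 1,
                                         dimnames = list(NULL, "f1"))), "f2")
})

test_that("the accuracy-maximizing threshold uses midpoints with low ties", {
  expect_equal(choose_threshold(c(0.2, 0.6, 0.9), c(0, 1, 1)), 0.4)
  expect_equal(mean((c(0.2, 0.6, 0.9) > 0.4) == c(0, 1, 1)), 1)
  # perfectly inverted scores: best rule is the majority class
  inv <- choose_threshold(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))
  acc <- mean((c(0.9, 0.8, 0.2, 0.1) > inv) == c(0, 0, 1, 1))
  expect_equal(acc, 0.5)
  # equals an exhaustive 1000-point grid on random data
  set.seed(17)
  for (r in 1:10) {
    sc <- runif(40); lb <- rbinom(40, 1, 0.6)
    th <- choose_threshold(sc, lb)
    grid <- seq(-0.01, 1.01, length.out = 1000)
    best_grid <- max(vapply(grid, function(g) mean((sc > g) == lb), numeric(1)))
    expect_equal(mean((sc > th) == lb), best_grid)
  }
})

test_that("confusion-matrix arithmetic reproduces the printed identities", {
  # 282 positives / 72 negatives; sens 96.5%, spec 27.8% => accuracy 82.5%
  lab <- c(rep(1, 282), rep(0, 72))
  pred <- c(rep(1, 272), rep(0, 10), rep(1, 52), rep(0, 20))
  ev <- evaluate(lab, pred)
  expect_equal(round(ev$sensitivity, 1), 96.5)
  expect_equal(round(ev$specificity, 1), 27.8)
  expect_equal(round(ev$accuracy, 1), 82.5)
  expect_equal(ev$tp + ev$fn, 282)
  expect_equal(ev$tn + ev$fp, 72)
  # spec 100%, accuracy 31.9% => sensitivity 14.5%
  pred2 <- c(rep(1, 41), rep(0, 241), rep(0, 72))
  ev2 <- evaluate(lab, pred2)
  expect_equal(round(ev2$specificity, 1), 100)
  expect_equal(round(ev2$accuracy, 1), 31.9)
  expect_equal(round(ev2$sensitivity, 1), 14.5)
  # perfect prediction
  ev3 <- evaluate(lab, lab)
  expect_equal(ev3$accuracy, 100)
  expect_equal(ev3$balanced_accuracy, 100)
  # single-class truth flags undefined specificity
  expect_warning(ev4 <- evaluate(rep(1, 5), rep(1, 5)), "single-class")
  expect_true(ev4$single_class)
  expect_true(is.na(ev4$specificity))
})

test_that("AUC matches concordant-pair counting and the curve sweep", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  # all-pairs oracle on 50 random points
  set.seed(18)
  sc <- runif(50); lb <- rbinom(50, 1, 0.5)
  r <- roc_auc(sc, lb)
  pos <- sc[lb == 1]; neg <- sc[lb == 0]
  conc <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(r$auc, conc, tolerance = 1e-12)
  # the two formulations agree to near machine precision
  expect_equal(r$auc, r$auc_trapezoid, tolerance = 1e-12)
  # independent scores give AUC ~ 0.5 on average
  set.seed(19)
  aucs <- replicate(1000, roc_auc(runif(60), rbinom(60, 1, 0.5))$auc)
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
  # cross-check against pROC on a fixed vector
  skip_if_not_installed("pROC")
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("the MC marker predicts fissures from any Modic change", {
  man <- data.frame(mc_type = c(0, 1, 2, 3, 0))
  expect_equal(mc_marker_predict(man), c(0L, 1L, 1L, 1L, 0L))
  expect_equal(mc_marker_predict(man, invert = TRUE), c(1L, 0L, 0L, 0L, 1L))
  expect_error(mc_marker_predict(data.frame(x = 1)), "mc_type")
  # in a cohort where MC arises only next to fissures, specificity is 100%
  co <- small_cohort(n_patients = 8, seed = 66)
  ev <- evaluate(co$manifest$fissure_label, mc_marker_predict(co$manifest))
  expect_equal(ev$specificity, 100)
})

test_that("mid-p McNemar equals exact binomial enumeration", {
  # b = 1, c = 5: 2 P(X <= 1) - P(X = 1) with X ~ Bin(6, 1/2) = 0.125
  a_ok <- c(rep(TRUE, 5), FALSE, rep(TRUE, 4))
  b_ok <- c(rep(FALSE, 5), TRUE, rep(TRUE, 4))
  m <- mcnemar_midp(b_ok, a_ok)   # b = 1 (first right only), c = 5
  expect_equal(m$p, 0.125)
  expect_equal(sort(c(m$b, m$c)), c(1, 5))
  # symmetric discordance: mid-p >= 0.5
  expect_gte(mcnemar_midp(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))$p, 0.5)
  # identical correctness: no discordant pairs, p = 1
  expect_equal(mcnemar_midp(c(TRUE, FALSE), c(TRUE, FALSE))$p, 1)
  # mid-p never exceeds the exact binomial p
  set.seed(20)
  for (r in 1:50) {
    x <- runif(30) < 0.6; y <- runif(30) < 0.6
    mm <- mcnemar_midp(x, y)
    expect_lte(mm$p, mm$p_exact)
    expect_lte(mm$p, 1)
  }
})
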