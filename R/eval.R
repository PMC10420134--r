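#' Predicted fissure probabilities from a logistic fit
#'
#' `logistic(intercept + x B)` per row. The feature table must carry the
#' model's features, standardized with the training transform.
#'
#' @param fit A `logistic_fit` from [backward_eliminate_logistic()].
#' @param t A [feature_table()] (or plain matrix with named columns).
#' @return Numeric vector of scores in (0, 1).
#' @export
predict_proba <- function(fit, t) {
  stopifnot(inherits(fit, "logistic_fit"))
  X <- if (inherits(t, "feature_table")) t$features else as.matrix(t)
  missing <- setdiff(fit$features, colnames(X))
  if (length(missing))
    stop("feature table lacks model feature(s): ",
         paste(missing, collapse = ", "))
  lin <- if (length(fit$features))
    as.numeric(X[, fit$features, drop = FALSE] %*% fit$B)
  else rep(0, nrow(X))   # intercept-only model scores every unit equally
  stats::plogis(fit$intercept + lin)
}

#' Choose a prediction threshold
#'
#' Scans the midpoints of consecutive sorted unique scores (plus a
#' threshold below the minimum, allowing the all-positive rule) and returns
#' the value maximizing accuracy of the rule `score > threshold`; ties go
#' to the lowest threshold.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary truth (0/1); both classes must be present.
#' @param criterion Only `"max_accuracy"` is implemented.
#' @return The selected threshold.
#' @export
choose_threshold <- function(scores, labels, criterion = "max_accuracy") {
  criterion <- match.arg(criterion)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  u <- sort(unique(scores))
  # midpoints of consecutive unique scores, plus sentinels below the
  # minimum (all-positive rule) and above the maximum (all-negative rule)
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 1)
  acc <- vapply(cand, function(th) mean((scores > th) == labels), numeric(1))
  cand[which.max(acc)]   # which.max takes the first (lowest) on ties
}

#' Confusion-matrix evaluation
#'
#' Counts TP/FN/FP/TN for binary predictions and derives sensitivity,
#' specificity, accuracy and balanced accuracy as percentages.
#'
#' @param labels Binary truth (0/1).
#' @param predictions Binary predictions (0/1).
#' @return An object of class `eval_report`.
#' @export
evaluate <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(labels) != length(predictions)) stop("length mismatch")
  if (!all(c(labels, predictions) %in% c(0L, 1L))) stop("inputs must be binary")
  tp <- sum(labels == 1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  pos <- tp + fn; neg <- tn + fp
  single_class <- pos == 0L || neg == 0L
  if (single_class)
    warning("single-class truth: sensitivity or specificity undefined")
  sens <- if (pos > 0) 100 * tp / pos else NA_real_
  spec <- if (neg > 0) 100 * tn / neg else NA_real_
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 sensitivity = sens, specificity = spec,
                 accuracy = 100 * (tp + tn) / (pos + neg),
                 balanced_accuracy = mean(c(sens, spec)),
                 single_class = single_class),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Confusion: TP=%d FN=%d FP=%d TN=%d\n", x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("Sensitivity %.1f%%  Specificity %.1f%%  Accuracy %.1f%%  Balanced %.1f%%\n",
              x$sensitivity, x$specificity, x$accuracy, x$balanced_accuracy))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) formulation with midranks for ties; the
#' curve by a sweep over unique score thresholds. The trapezoidal area
#' under that curve equals the rank AUC to floating-point accuracy and both
#' are returned.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary truth (0/1); both classes must be present.
#' @return List with `auc`, `auc_trapezoid` and `curve` (data.frame with
#'   threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)   # midranks
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, numeric(1))
  auc_trap <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, auc_trapezoid = auc_trap,
       curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

#' Predict fissures from the Modic-change marker
#'
#' The clinical comparator: a unit predicts an outer annular fissure in its
#' adjacent disc iff it shows any Modic change (`mc_type >= 1`). A flag
#' inverts the direction should a cohort encode the opposite association.
#'
#' @param manifest Manifest data.frame with an `mc_type` column.
#' @param invert If `TRUE`, predict fissure iff `mc_type == 0`.
#' @return Integer vector of 0/1 predictions, one per manifest row.
#' @export
mc_marker_predict <- function(manifest, invert = FALSE) {
  if (!"mc_type" %in% names(manifest)) stop("manifest lacks mc_type")
  if (any(is.na(manifest$mc_type))) stop("missing mc_type values")
  pred <- as.integer(manifest$mc_type >= 1)
  if (invert) pred <- 1L - pred
  pred
}

#' Mid-p McNemar test for paired classifiers
#'
#' Exact paired comparison on the discordant classifications: with
#' `b` units only classifier A got right and `c` only B, `n = b + c` and
#' `X ~ Binomial(n, 1/2)`, the two-sided mid-p-value is
#' `2 P(X <= min(b, c)) - P(X = min(b, c))`; `n = 0` gives p = 1.
#'
#' @param correct_a,correct_b Logical (or 0/1) vectors: was each paired
#'   classification correct under classifier A / B?
#' @return List with `p` (mid-p), `p_exact` (exact binomial two-sided),
#'   `b`, `c`.
#' @export
mcnemar_midp <- function(correct_a, correct_b) {
  a <- as.logical(correct_a); bb <- as.logical(correct_b)
  if (length(a) != length(bb)) stop("paired vectors must match in length")
  b <- sum(a & !bb)
  cc <- sum(!a & bb)
  n <- b + cc
  if (n == 0L) return(list(p = 1, p_exact = 1, b = b, c = cc))
  k <- min(b, cc)
  p_exact <- min(1, 2 * stats::pbinom(k, n, 0.5))
  p_mid <- min(1, 2 * stats::pbinom(k, n, 0.5) - stats::dbinom(k, n, 0.5))
  list(p = p_mid, p_exact = p_exact, b = b, c = cc)
}
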