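#' Construct a feature table
#'
#' Rows are vertebral units, columns named features
#' (`family_Feature_modality`); per-column modality and family metadata are
#' derived from the names.
#'
#' @param features Numeric matrix (units x features) with column names.
#' @param labels Binary fissure label per row (0/1).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, labels) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) stop("feature columns must be named")
  if (nrow(features) != length(labels)) stop("labels do not match rows")
  if (any(!is.finite(features))) stop("feature table contains missing values")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  nm <- colnames(features)
  meta <- data.frame(name = nm,
                     family = sub("_.*$", "", nm),
                     modality = sub("^.*_", "", nm),
                     stringsAsFactors = FALSE)
  structure(list(features = features, labels = labels, meta = meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d units x %d features, %.0f%% fissure-positive>\n",
              nrow(x$features), ncol(x$features), 100 * mean(x$labels)))
  invisible(x)
}

subset_features <- function(t, keep) {
  feature_table(t$features[, keep, drop = FALSE], t$labels)
}

#' Z-score standardize a feature table
#'
#' Transforms each column to mean 0 and variance 1 using the sample
#' standard deviation. Zero-variance columns cannot be standardized and are
#' excluded, with their names recorded in the `"zero_variance_dropped"`
#' attribute.
#'
#' @param t A [feature_table()].
#' @param center,scale Optional precomputed training means/SDs (used to
#'   apply a training transform to new data).
#' @return The standardized `feature_table`, with attributes `center` and
#'   `scale` carrying the transform.
#' @export
zscore_standardize <- function(t, center = NULL, scale = NULL) {
  stopifnot(inherits(t, "feature_table"))
  X <- t$features
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[scale == 0 | !is.finite(scale)]
  keep <- setdiff(colnames(X), dropped)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep], "-"),
              2, scale[keep], "/")
  out <- feature_table(Xs, t$labels)
  attr(out, "center") <- center[keep]
  attr(out, "scale") <- scale[keep]
  attr(out, "zero_variance_dropped") <- dropped
  out
}

#' Intraclass correlation ICC(1,1)
#'
#' One-way random-effects, single-rater, absolute-agreement intraclass
#' correlation: `(MSB - MSW) / (MSB + (k - 1) * MSW)` from the one-way
#' ANOVA decomposition over `n` subjects rated by `k` raters.
#'
#' @param x Numeric matrix, subjects in rows, raters in columns (`n >= 2`,
#'   `k >= 2`).
#' @return ICC value (in `[-1, 1]` for two raters). Zero total variance
#'   (identical raters on identical subjects) is defined as 1 with a
#'   warning.
#' @export
icc_1_1 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("ICC(1,1) needs >= 2 subjects and >= 2 raters")
  if (any(!is.finite(x))) stop("non-finite measurements")
  rm <- rowMeans(x)
  gm <- mean(x)
  msb <- k * sum((rm - gm)^2) / (n - 1)
  msw <- sum((x - rm)^2) / (n * (k - 1))
  if (msb + (k - 1) * msw == 0) {
    warning("zero total variance; ICC defined as 1")
    return(1)
  }
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Robustness filter: drop features unstable under an ROI perturbation
#'
#' For each feature, ICC(1,1) is computed with units as subjects and the
#' two perturbations (original vs. perturbed table) as raters, on raw
#' (pre-standardization) feature values. Features with `ICC < threshold`
#' are excluded (strict inequality: an ICC exactly at the threshold is
#' kept).
#'
#' @param t,t_perturbed Matched [feature_table()]s (same rows, same
#'   columns).
#' @param threshold Reliability cut-off (default 0.5).
#' @param pooled If `TRUE`, a single pooled ICC over all features is
#'   computed instead (values pooled as subjects) and applied to every
#'   feature; default `FALSE` (per-feature).
#' @return List with `table` (survivors), `icc` (named vector) and
#'   `dropped` (character).
#' @export
robustness_filter <- function(t, t_perturbed, threshold = 0.5,
                              pooled = FALSE) {
  stopifnot(inherits(t, "feature_table"), inherits(t_perturbed, "feature_table"))
  if (!identical(dim(t$features), dim(t_perturbed$features)) ||
      !identical(colnames(t$features), colnames(t_perturbed$features)))
    stop("original and perturbed tables do not match")
  nm <- colnames(t$features)
  if (pooled) {
    icc <- stats::setNames(rep(icc_1_1(cbind(as.vector(t$features),
                                             as.vector(t_perturbed$features))),
                               length(nm)), nm)
  } else {
    icc <- vapply(nm, function(f)
      icc_1_1(cbind(t$features[, f], t_perturbed$features[, f])), numeric(1))
  }
  dropped <- nm[icc < threshold]
  list(table = subset_features(t, setdiff(nm, dropped)),
       icc = icc, dropped = dropped)
}

#' Correlation filter: prune highly collinear feature pairs
#'
#' Feature pairs with `|Pearson R| > r_threshold` are processed in
#' descending `|R|`; within a pair, the feature with the lower absolute
#' point-biserial correlation to the fissure label is dropped. Pairs
#' containing an already-dropped feature are skipped; a pair at exactly the
#' threshold is retained (strict `>`). Constant columns, whose correlation
#' is undefined, are dropped first.
#'
#' @param t A [feature_table()] with labels.
#' @param r_threshold Absolute-correlation cut-off (default 0.9).
#' @return List with `table` (survivors), `dropped` (data.frame of feature,
#'   kept partner, |R|) and `constant_dropped`.
#' @export
correlation_filter <- function(t, r_threshold = 0.9) {
  stopifnot(inherits(t, "feature_table"))
  X <- t$features
  sds <- apply(X, 2, stats::sd)
  const <- colnames(X)[sds == 0]
  X <- X[, sds > 0, drop = FALSE]
  C <- suppressWarnings(stats::cor(X))
  lab_cor <- abs(suppressWarnings(stats::cor(X, t$labels)))[, 1]
  ut <- which(upper.tri(C) & abs(C) > r_threshold, arr.ind = TRUE)
  ord <- order(-abs(C[ut]))
  ut <- ut[ord, , drop = FALSE]
  alive <- stats::setNames(rep(TRUE, ncol(X)), colnames(X))
  dropped <- list()
  for (r in seq_len(nrow(ut))) {
    a <- colnames(X)[ut[r, 1]]; b <- colnames(X)[ut[r, 2]]
    if (!alive[a] || !alive[b]) next
    # drop the one less correlated with the fissure label; ties drop the
    # later column (deterministic)
    loser <- if (lab_cor[a] < lab_cor[b]) a else b
    winner <- setdiff(c(a, b), loser)
    alive[loser] <- FALSE
    dropped[[length(dropped) + 1L]] <- data.frame(
      feature = loser, kept = winner, r = abs(C[ut[r, 1], ut[r, 2]]),
      stringsAsFactors = FALSE)
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped)
             else data.frame(feature = character(), kept = character(),
                             r = numeric())
  list(table = subset_features(t, names(alive)[alive]),
       dropped = dropped, constant_dropped = const)
}

# ---- classifiers used inside sequential backward selection ---------------

make_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_predict <- function(spec, Xtr, ytr, Xte, seed, mlp_maxit = 18,
                        mlp_decay = 1e-4) {
  set.seed(seed)
  if (spec == "rf") {
    w <- length(ytr) / (2 * table(factor(ytr, levels = c(0, 1))))
    fit <- ranger::ranger(x = Xtr, y = factor(ytr, levels = c(0, 1)),
                          num.trees = 45, replace = TRUE,
                          class.weights = as.numeric(w),
                          num.threads = 1, seed = seed, oob.error = FALSE)
    as.integer(as.character(stats::predict(fit, data = Xte,
                                           num.threads = 1)$predictions))
  } else if (spec == "knn") {
    as.integer(as.character(class::knn(Xtr, Xte,
                                       factor(ytr, levels = c(0, 1)), k = 5)))
  } else if (spec == "mlp") {
    p <- cpp_mlp_predict(Xtr, as.numeric(ytr), Xte, 100L,
                         as.integer(mlp_maxit), 0.01, mlp_decay)
    as.integer(p >= 0.5)
  } else stop("unknown model spec: ", spec)
}

balanced_accuracy <- function(truth, pred) {
  sens <- if (any(truth == 1)) mean(pred[truth == 1] == 1) else NA_real_
  spec <- if (any(truth == 0)) mean(pred[truth == 0] == 0) else NA_real_
  mean(c(sens, spec))
}

cv_score <- function(spec, X, y, fold, seed, ...) {
  k <- max(fold)
  mean(vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      stop("a CV fold contains a single class; use stratified folds")
    pred <- fit_predict(spec, X[tr, , drop = FALSE], y[tr],
                        X[!tr, , drop = FALSE], seed = seed + f, ...)
    balanced_accuracy(y[!tr], pred)
  }, numeric(1)))
}

#' Sequential backward feature selection
#'
#' Starting from all columns, repeatedly removes the feature whose removal
#' maximizes the mean 5-fold cross-validated balanced accuracy of the given
#' classifier, until `k_target` features remain. Folds are stratified by
#' label and shared across calls with the same seed, so curves from
#' different model specs are comparable.
#'
#' Model specs: `"mlp"` (fully connected network with one hidden layer of
#' 100 ReLU nodes, trained by full-batch Adam on the cross-entropy loss),
#' `"rf"` (random forest, 45 trees, bootstrap samples, balanced class
#' weights), `"knn"` (5 nearest neighbours, uniform weights).
#'
#' @param t A standardized [feature_table()].
#' @param model_spec `"mlp"`, `"rf"` or `"knn"`.
#' @param k_target Number of features to keep (default 5).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed controlling folds and model randomness.
#' @param mlp_maxit,mlp_decay Training epochs and L2 penalty of the MLP.
#' @return List with `selected` (survivor names), `removal_order` (first
#'   removed first), `curve` (mean CV balanced accuracy indexed by feature
#'   count, from the full set down to `k_target`) and `model`.
#' @export
sbs_select <- function(t, model_spec, k_target = 5L, folds = 5L, seed = 1L,
                       mlp_maxit = 18L, mlp_decay = 1e-4) {
  stopifnot(inherits(t, "feature_table"))
  X <- t$features; y <- t$labels
  if (ncol(X) < k_target) stop("fewer features than k_target")
  fold <- make_folds(y, folds, seed)
  alive <- colnames(X)
  curve <- stats::setNames(numeric(0), character(0))
  curve[as.character(length(alive))] <-
    cv_score(model_spec, X[, alive, drop = FALSE], y, fold, seed,
             mlp_maxit = mlp_maxit, mlp_decay = mlp_decay)
  removal <- character(0)
  step <- 0L
  while (length(alive) > k_target) {
    step <- step + 1L
    scores <- vapply(seq_along(alive), function(ci) {
      keep <- alive[-ci]
      cv_score(model_spec, X[, keep, drop = FALSE], y, fold,
               seed + 1000L * step + ci,
               mlp_maxit = mlp_maxit, mlp_decay = mlp_decay)
    }, numeric(1))
    best <- which.max(scores)   # ties: first (column-order) candidate
    removal <- c(removal, alive[best])
    alive <- alive[-best]
    curve[as.character(length(alive))] <- scores[best]
  }
  list(selected = alive, removal_order = removal, curve = curve,
       model = model_spec)
}

#' Aggregate per-model top features into one candidate set
#'
#' Union of the per-model selections, ranked by model-vote count with mean
#' selection importance (how late each model removed the feature during
#' backward selection; survivors rank highest) as tie-break, then name. The
#' Table-style membership matrix records which model selected which
#' feature.
#'
#' @param selections Named list of [sbs_select()] results (or plain
#'   character vectors of selected features).
#' @param n_candidates Optional cap on the number of candidates passed on
#'   (default: the full union).
#' @return List with `candidates` (ordered character vector), `membership`
#'   (data.frame features x models) and `votes`.
#' @export
aggregate_top_features <- function(selections, n_candidates = NULL) {
  sel_sets <- lapply(selections, function(s)
    if (is.list(s)) s$selected else s)
  all_feats <- sort(unique(unlist(sel_sets)))
  membership <- as.data.frame(
    lapply(sel_sets, function(s) all_feats %in% s), row.names = all_feats)
  votes <- rowSums(membership)
  importance <- rep(0, length(all_feats))
  names(importance) <- all_feats
  for (s in selections) {
    if (!is.list(s)) next
    n_total <- length(s$removal_order) + length(s$selected)
    imp <- c(stats::setNames(seq_along(s$removal_order), s$removal_order),
             stats::setNames(rep(n_total, length(s$selected)), s$selected))
    common <- intersect(names(imp), all_feats)
    importance[common] <- importance[common] + imp[common] / n_total
  }
  ord <- order(-votes, -importance, all_feats)
  candidates <- all_feats[ord]
  if (!is.null(n_candidates)) candidates <- utils::head(candidates, n_candidates)
  list(candidates = candidates, membership = membership, votes = votes)
}

#' Backward-elimination logistic regression
#'
#' Fits a binomial logistic regression on the candidate features and
#' iteratively removes the feature with the largest Wald p-value while it
#' exceeds `alpha`. The returned fit reports, per retained feature, the
#' coefficient B, its Wald p-value, the odds ratio `exp(B)` and the 95%
#' Wald interval `exp(B +/- 1.96 SE)`.
#'
#' @param t A standardized [feature_table()] restricted to the candidates.
#' @param alpha Retention significance level (default 0.05).
#' @return An object of class `logistic_fit`.
#' @export
backward_eliminate_logistic <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "feature_table"))
  alive <- colnames(t$features)
  eliminated <- character(0)
  repeat {
    df <- data.frame(.y = t$labels, t$features[, alive, drop = FALSE],
                     check.names = FALSE)
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                      control = stats::glm.control(maxit = 100))
    if (!fit$converged)
      stop("logistic fit did not converge (possible separation); ",
           "consider a penalized fit outside this pipeline")
    sm <- summary(fit)$coefficients
    feat_rows <- setdiff(rownames(sm), "(Intercept)")
    if (!length(feat_rows)) break
    p <- sm[feat_rows, "Pr(>|z|)"]
    if (max(p) <= alpha) break
    worst <- feat_rows[which.max(p)]
    worst <- gsub("^`|`$", "", worst)
    eliminated <- c(eliminated, worst)
    alive <- setdiff(alive, worst)
  }
  sm <- summary(fit)$coefficients
  feat_rows <- setdiff(rownames(sm), "(Intercept)")
  nm <- gsub("^`|`$", "", feat_rows)
  B <- sm[feat_rows, "Estimate"]
  SE <- sm[feat_rows, "Std. Error"]
  structure(list(
    features = nm,
    B = stats::setNames(as.numeric(B), nm),
    SE = stats::setNames(as.numeric(SE), nm),
    wald_p = stats::setNames(as.numeric(sm[feat_rows, "Pr(>|z|)"]), nm),
    OR = stats::setNames(exp(as.numeric(B)), nm),
    CI = cbind(lower = exp(as.numeric(B) - 1.96 * as.numeric(SE)),
               upper = exp(as.numeric(B) + 1.96 * as.numeric(SE))),
    intercept = unname(sm["(Intercept)", "Estimate"]),
    intercept_p = unname(sm["(Intercept)", "Pr(>|z|)"]),
    eliminated = eliminated,
    prediction_threshold = NULL,
    glm = fit), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Backward-elimination logistic regression\n")
  if (length(x$features)) {
    tab <- data.frame(B = round(x$B, 3),
                      p = signif(x$wald_p, 3),
                      OR = round(x$OR, 3),
                      CI95 = sprintf("(%.2f %.2f)", x$CI[, 1], x$CI[, 2]))
    print(tab)
  } else cat("  (intercept-only model)\n")
  cat(sprintf("Intercept: %.3f (p = %.3g)\n", x$intercept, x$intercept_p))
  if (!is.null(x$prediction_threshold))
    cat(sprintf("Prediction threshold: %.3f\n", x$prediction_threshold))
  if (length(x$eliminated))
    cat("Eliminated:", paste(x$eliminated, collapse = ", "), "\n")
  invisible(x)
}
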