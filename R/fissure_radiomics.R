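#' Fit the vertebral-texture / annular-fissure association model
#'
#' End-to-end analysis on a cohort of paired T1W/T2W vertebral volumes:
#'
#' 1. preprocessing and extraction of the 186-feature catalog per vertebral
#'    unit (plus the two ICC perturbation conditions);
#' 2. robustness screening: features with ICC(1,1) < 0.5 under mask
#'    contraction, then under the 1.0 vs 1.1 mm voxel-size change, are
#'    excluded (on raw feature values);
#' 3. z-score standardization (zero-variance columns excluded);
#' 4. correlation pruning of pairs with |R| > 0.9, keeping the member more
#'    correlated with the fissure label;
#' 5. sequential backward selection under 5-fold CV balanced accuracy for
#'    the MLP, random-forest and kNN specs, aggregation of the per-model
#'    top-5 sets;
#' 6. backward-elimination logistic regression (Wald p > 0.05 dropped);
#' 7. evaluation: accuracy-maximizing threshold, confusion matrix, ROC/AUC,
#'    the Modic-change marker comparison and the mid-p McNemar test.
#'
#' @param cohort A `cohort_dataset`, or a directory path readable by
#'   [read_cohort()].
#' @param config A [default_config()] list.
#' @return An object of class `fissure_radiomics` with components
#'   `fit` (the `logistic_fit`), `reduction` (per-step exclusions, ICC
#'   values, correlation pairs, SBS curves, candidate membership),
#'   `scores`, `threshold`, `eval_radiomics`, `eval_mc`, `roc`, `mcnemar`,
#'   `standardization`, `manifest` and `config`.
#' @export
fissure_radiomics <- function(cohort, config = default_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "cohort_dataset"))

  ex <- extract_cohort_features(cohort, config)
  initial <- colnames(ex$main$features)

  r1 <- robustness_filter(ex$main, ex$contracted, config$icc_threshold)
  keep1 <- colnames(r1$table$features)
  r2 <- robustness_filter(r1$table, subset_features(ex$voxel, keep1),
                          config$icc_threshold)

  std <- zscore_standardize(r2$table)
  zv <- attr(std, "zero_variance_dropped")

  cf <- correlation_filter(std, config$r_threshold)

  sbs <- lapply(stats::setNames(config$models, config$models), function(mspec)
    sbs_select(cf$table, mspec, k_target = config$k_target,
               folds = config$folds, seed = config$seed,
               mlp_maxit = config$mlp_maxit, mlp_decay = config$mlp_decay))
  agg <- aggregate_top_features(sbs, n_candidates = config$n_candidates)
  sbs_dropped <- setdiff(colnames(cf$table$features), agg$candidates)

  fit <- backward_eliminate_logistic(subset_features(cf$table, agg$candidates),
                                     alpha = config$alpha)

  scores <- predict_proba(fit, cf$table)
  threshold <- choose_threshold(scores, cf$table$labels)
  fit$prediction_threshold <- threshold
  pred <- as.integer(scores > threshold)
  eval_radiomics <- evaluate(cf$table$labels, pred)
  roc <- roc_auc(scores, cf$table$labels)

  mc_pred <- mc_marker_predict(ex$manifest, invert = config$mc_invert)
  eval_mc <- evaluate(ex$manifest$fissure_label, mc_pred)
  mcn <- mcnemar_midp(pred == cf$table$labels,
                      mc_pred == ex$manifest$fissure_label)

  reduction <- list(
    initial = initial,
    icc_segmentation = list(icc = r1$icc, dropped = r1$dropped),
    icc_voxel = list(icc = r2$icc, dropped = r2$dropped),
    zero_variance = zv,
    correlation = cf$dropped,
    constant_after_icc = cf$constant_dropped,
    sbs = lapply(sbs, function(s) s[c("selected", "curve", "removal_order")]),
    sbs_dropped = sbs_dropped,
    candidates = agg$candidates,
    membership = agg$membership,
    votes = agg$votes,
    wald_eliminated = fit$eliminated,
    survivors = fit$features)

  structure(list(fit = fit, reduction = reduction, scores = scores,
                 threshold = threshold, eval_radiomics = eval_radiomics,
                 eval_mc = eval_mc, roc = roc, mcnemar = mcn,
                 standardization = list(center = attr(std, "center"),
                                        scale = attr(std, "scale")),
                 manifest = ex$manifest, config = config),
            class = "fissure_radiomics")
}

#' @export
print.fissure_radiomics <- function(x, ...) {
  cat("Vertebral-texture association with adjacent annular fissures\n")
  cat(sprintf("  %d units, %d initial features -> %d candidates -> %d in final model\n",
              nrow(x$manifest), length(x$reduction$initial),
              length(x$reduction$candidates), length(x$fit$features)))
  cat(sprintf("  AUC %.3f; radiomics accuracy %.1f%% vs MC marker %.1f%% (mid-p McNemar p = %.3g)\n",
              x$roc$auc, x$eval_radiomics$accuracy, x$eval_mc$accuracy,
              x$mcnemar$p))
  invisible(x)
}

#' @export
summary.fissure_radiomics <- function(object, ...) {
  x <- object
  cat("== Feature reduction ==\n")
  cat(sprintf("initial %d | ICC(segmentation) -%d | ICC(voxel) -%d | zero-variance -%d | correlation -%d | SBS -> %d candidates | Wald -> %d\n",
              length(x$reduction$initial),
              length(x$reduction$icc_segmentation$dropped),
              length(x$reduction$icc_voxel$dropped),
              length(x$reduction$zero_variance),
              nrow(x$reduction$correlation) +
                length(x$reduction$constant_after_icc),
              length(x$reduction$candidates),
              length(x$fit$features)))
  cat("\n== Candidate membership (per model) ==\n")
  print(x$reduction$membership)
  cat("\n== Final logistic model ==\n")
  print(x$fit)
  cat("\n== Classification (threshold ", sprintf("%.3f", x$threshold),
      ") ==\n", sep = "")
  print(x$eval_radiomics)
  cat(sprintf("AUC: %.3f\n", x$roc$auc))
  cat("\n== Modic-change marker ==\n")
  print(x$eval_mc)
  cat(sprintf("\nmid-p McNemar (radiomics vs MC): p = %.4g (b=%d, c=%d)\n",
              x$mcnemar$p, x$mcnemar$b, x$mcnemar$c))
  invisible(x)
}

#' @export
coef.fissure_radiomics <- function(object, ...) {
  c("(Intercept)" = object$fit$intercept, object$fit$B)
}

#' Predict fissure scores or classes for new units
#'
#' @param object A fitted `fissure_radiomics` model.
#' @param newdata A [feature_table()] or raw feature matrix on the original
#'   (unstandardized) scale with the catalog columns; defaults to the
#'   training scores.
#' @param type `"score"` (probability) or `"class"` (0/1 at the fitted
#'   threshold).
#' @param ... Unused.
#' @export
predict.fissure_radiomics <- function(object, newdata = NULL,
                                      type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    sc <- object$scores
  } else {
    X <- if (inherits(newdata, "feature_table")) newdata$features
         else as.matrix(newdata)
    ctr <- object$standardization$center
    scl <- object$standardization$scale
    need <- object$fit$features
    missing <- setdiff(need, colnames(X))
    if (length(missing))
      stop("newdata lacks model feature(s): ", paste(missing, collapse = ", "))
    Xs <- sweep(sweep(X[, need, drop = FALSE], 2, ctr[need], "-"),
                2, scl[need], "/")
    sc <- predict_proba(object$fit, Xs)
  }
  if (type == "score") sc else as.integer(sc > object$threshold)
}

#' Plot a fitted fissure-radiomics model
#'
#' Left: ROC curve of the final logistic model with the AUC. Right: the
#' backward-selection balanced-accuracy curves of the three classifiers
#' against the number of retained features.
#'
#' @param x A `fissure_radiomics` object.
#' @param which `"roc"`, `"sbs"` or `"both"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fissure_radiomics <- function(x, which = "both", ...) {
  which <- match.arg(which, c("both", "roc", "sbs"))
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "roc")) {
    graphics::plot(x$roc$curve$fpr, x$roc$curve$tpr, type = "l",
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = sprintf("ROC (AUC = %.3f)", x$roc$auc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  if (which %in% c("both", "sbs")) {
    curves <- lapply(x$reduction$sbs, `[[`, "curve")
    xs <- lapply(curves, function(cv) as.integer(names(cv)))
    rng <- range(unlist(curves))
    graphics::plot(NA, xlim = rev(range(unlist(xs))), ylim = rng,
                   xlab = "Number of features",
                   ylab = "CV balanced accuracy",
                   main = "Sequential backward selection")
    for (i in seq_along(curves))
      graphics::lines(xs[[i]], curves[[i]], col = i, lty = i)
    graphics::legend("bottomleft", legend = names(curves),
                     col = seq_along(curves), lty = seq_along(curves),
                     bty = "n")
  }
  invisible(x)
}

#' Write the report bundle of a fitted model
#'
#' JSON report (reduction counts, per-step exclusions, metrics, config,
#' seed) plus CSVs for the candidate membership matrix and the final
#' coefficient table.
#'
#' @param x A `fissure_radiomics` object.
#' @param dir Output directory.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "fissure_radiomics"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  red <- x$reduction
  report <- list(
    config = unclass(x$config),
    counts = list(
      units = nrow(x$manifest),
      initial = length(red$initial),
      icc_segmentation_dropped = length(red$icc_segmentation$dropped),
      icc_voxel_dropped = length(red$icc_voxel$dropped),
      zero_variance_dropped = length(red$zero_variance),
      correlation_dropped = nrow(red$correlation) +
        length(red$constant_after_icc),
      sbs_candidates = length(red$candidates),
      final_model = length(x$fit$features)),
    exclusions = list(
      icc_segmentation = red$icc_segmentation$dropped,
      icc_voxel = red$icc_voxel$dropped,
      zero_variance = red$zero_variance,
      correlation = red$correlation$feature,
      constant = red$constant_after_icc,
      sbs = red$sbs_dropped,
      wald = red$wald_eliminated),
    model = list(features = x$fit$features, B = x$fit$B, SE = x$fit$SE,
                 wald_p = x$fit$wald_p, OR = x$fit$OR,
                 intercept = x$fit$intercept,
                 threshold = x$threshold),
    metrics = list(
      radiomics = unclass(x$eval_radiomics),
      mc_marker = unclass(x$eval_mc),
      auc = x$roc$auc,
      mcnemar_midp = x$mcnemar$p))
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(cbind(feature = rownames(red$membership), red$membership),
                   file.path(dir, "candidate_membership.csv"),
                   row.names = FALSE)
  coefs <- data.frame(feature = c(x$fit$features, "(Intercept)"),
                      B = c(x$fit$B, x$fit$intercept),
                      p = c(x$fit$wald_p, x$fit$intercept_p),
                      OR = c(x$fit$OR, exp(x$fit$intercept)))
  utils::write.csv(coefs, file.path(dir, "model_coefficients.csv"),
                   row.names = FALSE)
  invisible(path)
}
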