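#' Binary classification metrics from confusion counts and scores
#'
#' TD is the negative class, DD the positive class. Balanced accuracy is
#' the unweighted mean of sensitivity (recall on DD) and specificity
#' (recall on TD). AUC uses the rank (Mann-Whitney) formulation with ties
#' counted one half. The quantity `TN / (TN + FN)` is the negative
#' predictive value; it is additionally reported under `for_reported`
#' because the reference analysis prints it under the label FOR, while the
#' conventional false omission rate `FN / (TN + FN)` is its complement
#' (`for_standard`). Undefined ratios (empty denominator) are reported as
#' `NA` rather than propagating `NaN`.
#'
#' @param tn,fp,fn,tp Confusion counts (TD negative, DD positive).
#' @param scores Optional per-subject decision scores (higher = more DD).
#' @param truth Optional 0/1 truth vector aligned with `scores`.
#' @return An object of class `"emf_metrics"`: list of `tn`, `fp`, `fn`,
#'   `tp`, `sensitivity`, `specificity`, `accuracy` (unbalanced),
#'   `balanced_accuracy`, `ppv`, `npv`, `for_reported`, `for_standard` and
#'   `auc` (fractions in \[0, 1\], `NA` when undefined).
#' @export
classification_metrics <- function(tn, fp, fn, tp, scores = NULL,
                                   truth = NULL) {
  if (any(c(tn, fp, fn, tp) < 0)) stop("confusion counts must be non-negative")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  acc <- safe_div(tp + tn, tn + fp + fn + tp)
  bacc <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(truth) || length(truth) != length(scores)) {
      stop("'truth' must align with 'scores'")
    }
    auc <- rank_auc(scores, truth)
  }
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp,
                 sensitivity = sens, specificity = spec,
                 accuracy = acc, balanced_accuracy = bacc,
                 ppv = ppv, npv = npv,
                 for_reported = npv,
                 for_standard = if (is.na(npv)) NA_real_ else 1 - npv,
                 auc = auc),
            class = "emf_metrics")
}

# Mann-Whitney AUC: ties between a positive and a negative score count 1/2.
rank_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.emf_metrics <- function(x, digits = 3, ...) {
  pct <- function(v) {
    if (is.na(v)) "NA" else paste0(format(round(100 * v, 1), nsmall = 1), "%")
  }
  cat("Confusion (TD negative / DD positive): TN=", x$tn, " FP=", x$fp,
      " FN=", x$fn, " TP=", x$tp, "\n", sep = "")
  cat("  sensitivity ", pct(x$sensitivity),
      "  specificity ", pct(x$specificity), "\n", sep = "")
  cat("  accuracy ", pct(x$accuracy),
      "  balanced accuracy ", pct(x$balanced_accuracy), "\n", sep = "")
  cat("  PPV ", pct(x$ppv), "  NPV ", pct(x$npv), sep = "")
  if (!is.na(x$auc)) cat("  AUC ", format(round(x$auc, 3), nsmall = 3), sep = "")
  cat("\n")
  invisible(x)
}

# Standardize columns with training-fold statistics only; constant columns
# pass through unscaled (sd -> 1) so they cannot produce NaN.
fold_standardizer <- function(X_train) {
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(apply = function(X) sweep(sweep(X, 2L, mu), 2L, sdv, "/"))
}

# Linear-margin classifier on standardized features; returns predicted 0/1
# label and a decision score oriented so that higher = DD.
fit_predict_svm <- function(X_train, y_train, X_test, cost = 1) {
  std <- fold_standardizer(X_train)
  yf <- factor(y_train, levels = c(0L, 1L))
  model <- e1071::svm(std$apply(X_train), yf, kernel = "linear",
                      cost = cost, scale = FALSE)
  pr <- stats::predict(model, std$apply(X_test), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # decision values are oriented toward the class named first in the column
  # label "A/B": positive favours A
  first <- strsplit(colnames(dv)[1L], "/")[[1L]][1L]
  score <- if (identical(first, "1")) as.numeric(dv) else -as.numeric(dv)
  list(pred = as.integer(as.character(pr)), score = score)
}

#' Leave-one-subject-out evaluation of the modulation model
#'
#' For each held-out subject the dynamic feature-selection cascade is run
#' on the remaining subjects' signature matrix against the held-out
#' signature, and a linear-margin classifier (margin penalty fixed at 1,
#' per-feature standardization fitted on the training fold only) is trained
#' on the selected coefficients. Predictions, signed decision scores and
#' per-fold selection masks are aggregated into an evaluation report.
#'
#' @param object An [emf()] fit.
#' @param thresholds A [dfs_thresholds()] object.
#' @param cost Margin penalty of the linear classifier.
#' @param use_dfs Set `FALSE` to skip the cascade and use all coefficients.
#' @return An object of class `"emf_eval"`: list with `metrics`
#'   (`emf_metrics` including AUC), `predictions` (per-subject data frame
#'   with truth, prediction, score, number of selected features, fallback
#'   level), `masks` (subjects x coefficients logical matrix),
#'   `selection_frequency` (see [selection_frequency()]),
#'   `subgroup_recall` and `thresholds`.
#' @export
loso <- function(object, thresholds = dfs_thresholds(), cost = 1,
                 use_dfs = TRUE) {
  stopifnot(inherits(object, "emf"))
  D <- object$D
  y <- object$y
  n <- nrow(D)
  if (min(table(y)) < 2L) stop("need at least 2 subjects per class")
  pred <- integer(n)
  score <- numeric(n)
  nsel <- integer(n)
  fallback <- integer(n)
  masks <- matrix(FALSE, n, ncol(D),
                  dimnames = list(rownames(D), colnames(D)))
  for (i in seq_len(n)) {
    Dtr <- D[-i, , drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      stop("training fold for subject ", rownames(D)[i],
           " lacks one of the classes")
    }
    if (use_dfs) {
      sel <- dfs_select(Dtr, ytr, D[i, ], thresholds)
      mask <- sel$mask
      fallback[i] <- sel$trace$fallback
    } else {
      mask <- rep(TRUE, ncol(D))
    }
    masks[i, ] <- mask
    nsel[i] <- sum(mask)
    fit <- fit_predict_svm(Dtr[, mask, drop = FALSE], ytr,
                           D[i, mask, drop = FALSE], cost = cost)
    pred[i] <- fit$pred
    score[i] <- fit$score
  }
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tp <- sum(pred == 1L & y == 1L)
  metrics <- classification_metrics(tn, fp, fn, tp, scores = score, truth = y)
  predictions <- data.frame(
    subject_id = rownames(D), diagnosis = as.character(object$diagnosis),
    truth = as.integer(y), prediction = pred, score = score,
    n_selected = nsel, fallback = fallback, stringsAsFactors = FALSE)
  structure(list(
    metrics = metrics,
    predictions = predictions,
    masks = masks,
    selection_frequency = selection_frequency(masks, object$diagnosis),
    subgroup_recall = subgroup_recall(predictions),
    thresholds = thresholds
  ), class = "emf_eval")
}

#' @export
print.emf_eval <- function(x, ...) {
  cat("Leave-one-subject-out evaluation (", nrow(x$predictions),
      " folds)\n", sep = "")
  print(x$metrics)
  if (nrow(x$subgroup_recall)) {
    cat("  subgroup recall: ",
        paste(x$subgroup_recall$diagnosis, " ",
              x$subgroup_recall$correct, "/", x$subgroup_recall$total,
              " (", round(100 * x$subgroup_recall$recall), "%)",
              sep = "", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.emf_eval <- function(object, ...) {
  object
}

#' ROC curve of an evaluation
#' @param x An `emf_eval` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.emf_eval <- function(x, ...) {
  sc <- x$predictions$score
  tr <- x$predictions$truth
  th <- c(Inf, sort(unique(sc), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(sc[tr == 1L] >= t), numeric(1L))
  fpr <- vapply(th, function(t) mean(sc[tr == 0L] >= t), numeric(1L))
  plot(fpr, tpr, type = "s", xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$metrics$auc), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Per-subgroup recall of the DD class
#'
#' For each disorder subgroup, the fraction of its subjects the evaluated
#' model assigned to the DD class.
#'
#' @param predictions Data frame with columns `diagnosis` and `prediction`
#'   (as produced by [loso()]).
#' @return Data frame with columns `diagnosis`, `correct`, `total`,
#'   `recall` and `percent`; empty subgroups are omitted.
#' @export
subgroup_recall <- function(predictions) {
  out <- lapply(setdiff(DIAGNOSES, "TD"), function(g) {
    rows <- predictions$diagnosis == g
    if (!any(rows)) return(NULL)
    correct <- sum(predictions$prediction[rows] == 1L)
    data.frame(diagnosis = g, correct = correct, total = sum(rows),
               recall = correct / sum(rows),
               percent = 100 * correct / sum(rows),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(diagnosis = character(0), correct = integer(0),
                      total = integer(0), recall = numeric(0),
                      percent = numeric(0), stringsAsFactors = FALSE)
  }
  out
}

#' Per-group feature-selection frequency
#'
#' For each diagnosis group and coefficient, the percentage of that group's
#' test folds in which the cascade selected the coefficient.
#'
#' @param masks Logical matrix (test subjects x coefficients).
#' @param diagnosis Named or aligned character vector of subject diagnoses.
#' @return Numeric matrix (groups x coefficients) of percentages in
#'   \[0, 100\]; only groups present in the cohort appear.
#' @export
selection_frequency <- function(masks, diagnosis) {
  diagnosis <- as.character(diagnosis)
  groups <- DIAGNOSES[DIAGNOSES %in% diagnosis]
  out <- t(vapply(groups, function(g) {
    100 * colMeans(masks[diagnosis == g, , drop = FALSE])
  }, numeric(ncol(masks))))
  rownames(out) <- groups
  colnames(out) <- colnames(masks)
  out
}
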