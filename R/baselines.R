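#' Rank features by a diagnosis t-test (FS1)
#'
#' Welch two-sided t statistics between DD and TD utterance values, per
#' feature, computed on the training rows; features are ranked by
#' descending absolute t (ties broken by column order) and the first
#' `top_k` are returned. A feature with zero pooled standard error has
#' `|t|` treated as 0 and ranks last.
#'
#' @param table An `emf_table`.
#' @param manifest An `emf_manifest`.
#' @param rows Integer indices of training rows (default: all rows).
#' @param top_k Number of features to retain.
#' @return Integer vector of feature column indices, best first.
#' @export
fs1_ttest_rank <- function(table, manifest, rows = seq_len(nrow(table)),
                           top_k = 100L) {
  stopifnot(inherits(table, "emf_table"), inherits(manifest, "emf_manifest"),
            top_k >= 1L)
  feats <- feature_names(table)
  diag_map <- stats::setNames(manifest$diagnosis, manifest$subject_id)
  y <- as.integer(diag_map[table$subject_id[rows]] != "TD")
  if (length(unique(y)) < 2L) {
    stop("training rows must contain both TD and DD utterances")
  }
  X <- as.matrix(table[rows, feats, drop = FALSE])
  tstat <- vapply(seq_len(ncol(X)), function(j) {
    x1 <- X[y == 1L, j]; x0 <- X[y == 0L, j]
    se2 <- stats::var(x1) / length(x1) + stats::var(x0) / length(x0)
    if (se2 == 0) 0 else abs(mean(x1) - mean(x0)) / sqrt(se2)
  }, numeric(1L))
  ord <- order(-tstat, seq_along(tstat))
  ord[seq_len(min(top_k, length(ord)))]
}

#' Valence-correlation feature selection on training rows (FS2)
#'
#' Re-uses the per-subject valence-correlation rule restricted to the
#' training partition: each training subject with at least two utterances
#' spanning at least two valence levels contributes its thresholded set,
#' and the sets are unioned.
#'
#' @param table An `emf_table`.
#' @param rows Integer indices of training rows (default: all rows).
#' @param threshold Correlation magnitude cutoff.
#' @return An `emf_features` set.
#' @export
fs2_valence_select <- function(table, rows = seq_len(nrow(table)),
                               threshold = 0.7) {
  stopifnot(inherits(table, "emf_table"))
  sub <- table[rows, , drop = FALSE]
  class(sub) <- class(table)
  usable <- Filter(function(s) {
    v <- sub$valence[sub$subject_id == s]
    length(v) >= 2L && length(unique(v)) >= 2L
  }, subject_ids(sub))
  sets <- lapply(usable, function(s) {
    select_subject_features(valence_correlation(sub, s), threshold)
  })
  names(sets) <- usable
  union_selected_features(sets, feature_names(table))
}

#' Cross-validated utterance-level baseline evaluation
#'
#' The standard paradigm: classify every *utterance* as TD or DD directly
#' from its acoustic features, with feature selection refit on each
#' training partition (FS1: diagnosis t-test ranking; FS2: valence
#' correlation) and a linear-margin classifier (margin penalty 1,
#' per-feature standardization fitted on the training partition). The
#' cross-validation unit is the subject by default — all of a subject's
#' utterances are held out together (leave-one-subject-out), so no subject
#' straddles train and test; `cv_unit = "utterance"` instead uses
#' `n_folds`-fold stratified folds over utterances.
#'
#' @param table An `emf_table`.
#' @param manifest An `emf_manifest`.
#' @param mode `"FS1"` or `"FS2"`.
#' @param top_k FS1 rank cut.
#' @param threshold FS2 correlation cutoff.
#' @param cv_unit `"subject"` or `"utterance"`.
#' @param n_folds Fold count for utterance-level folds.
#' @param cost Margin penalty.
#' @param seed Seed for utterance-level fold assignment.
#' @return An object of class `"emf_baseline_eval"`: list with `metrics`
#'   (utterance-level `emf_metrics`), `mode`, `cv_unit`, `predictions`
#'   (per utterance) and `n_selected` (per fold).
#' @export
baseline_evaluate <- function(table, manifest, mode = c("FS1", "FS2"),
                              top_k = 100L, threshold = 0.7,
                              cv_unit = c("subject", "utterance"),
                              n_folds = 10L, cost = 1, seed = 1L) {
  mode <- match.arg(mode)
  cv_unit <- match.arg(cv_unit)
  stopifnot(inherits(table, "emf_table"), inherits(manifest, "emf_manifest"))
  feats <- feature_names(table)
  diag_map <- stats::setNames(manifest$diagnosis, manifest$subject_id)
  y <- as.integer(diag_map[table$subject_id] != "TD")
  n <- nrow(table)

  if (cv_unit == "subject") {
    subs <- subject_ids(table)
    folds <- lapply(subs, function(s) which(table$subject_id == s))
  } else {
    set.seed(as.integer(seed))
    fold_id <- integer(n)
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      fold_id[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    folds <- split(seq_len(n), fold_id)
  }

  pred <- integer(n)
  score <- numeric(n)
  n_selected <- integer(length(folds))
  X <- as.matrix(table[, feats, drop = FALSE])
  for (fi in seq_along(folds)) {
    test <- folds[[fi]]
    train <- setdiff(seq_len(n), test)
    if (length(unique(y[train])) < 2L) {
      stop("training fold ", fi, " lacks one of the classes")
    }
    sel <- if (mode == "FS1") {
      fs1_ttest_rank(table, manifest, rows = train, top_k = top_k)
    } else {
      fs2_valence_select(table, rows = train, threshold = threshold)$indices
    }
    if (length(sel) == 0L) sel <- seq_along(feats)
    n_selected[fi] <- length(sel)
    fit <- fit_predict_svm(X[train, sel, drop = FALSE], y[train],
                           X[test, sel, drop = FALSE], cost = cost)
    pred[test] <- fit$pred
    score[test] <- fit$score
  }
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tp <- sum(pred == 1L & y == 1L)
  structure(list(
    metrics = classification_metrics(tn, fp, fn, tp, scores = score,
                                     truth = y),
    mode = mode, cv_unit = cv_unit,
    predictions = data.frame(subject_id = table$subject_id,
                             truth = y, prediction = pred, score = score,
                             stringsAsFactors = FALSE),
    n_selected = n_selected
  ), class = "emf_baseline_eval")
}

#' @export
print.emf_baseline_eval <- function(x, ...) {
  cat("Standard-paradigm baseline (", x$mode, ", utterance-level, ",
      x$cv_unit, " folds)\n", sep = "")
  print(x$metrics)
  invisible(x)
}

# Ridge-regularized linear discriminant fallback used when the pooled
# within-class scatter is singular.
ridge_lda_predict <- function(X_train, g_train, X_test, lambda = 1e-6) {
  classes <- sort(unique(g_train))
  p <- ncol(X_train)
  means <- lapply(classes, function(cl) colMeans(X_train[g_train == cl, ,
                                                         drop = FALSE]))
  W <- matrix(0, p, p)
  for (ci in seq_along(classes)) {
    Xc <- X_train[g_train == classes[ci], , drop = FALSE]
    Xc <- sweep(Xc, 2L, means[[ci]])
    W <- W + crossprod(Xc)
  }
  W <- W / max(1L, nrow(X_train) - length(classes))
  W <- W + lambda * (mean(diag(W)) + 1e-12) * diag(p)
  Winv <- solve(W)
  priors <- as.numeric(table(factor(g_train, levels = classes))) /
    length(g_train)
  disc <- vapply(seq_along(classes), function(ci) {
    d <- sweep(X_test, 2L, means[[ci]])
    -0.5 * rowSums((d %*% Winv) * d) + log(priors[ci])
  }, numeric(nrow(X_test)))
  disc <- matrix(disc, nrow = nrow(X_test))
  classes[max.col(disc, ties.method = "first")]
}

#' Per-subject valence recognition accuracy by linear discriminant analysis
#'
#' The appropriateness check of the acoustic features: for one subject, a
#' three-class linear discriminant classifier of utterance valence
#' (-1, 0, +1) is evaluated by leave-one-utterance-out cross-validation,
#' with the valence-correlation feature rule refit on each training split
#' (if the rule selects nothing, the single most correlated feature is
#' used). Singular within-class scatter triggers a ridge-regularized
#' fallback, flagged in the result.
#'
#' @param table An `emf_table`.
#' @param subject_id One subject with at least two utterances per valence
#'   class.
#' @param threshold Correlation magnitude cutoff.
#' @return A list with `balanced_accuracy` (mean per-class recall),
#'   `per_class_recall`, `n_utterances` and `ridge_folds` (number of folds
#'   that needed the regularized fallback).
#' @export
valence_lda_accuracy <- function(table, subject_id, threshold = 0.7) {
  stopifnot(inherits(table, "emf_table"))
  rows <- which(table$subject_id == subject_id)
  if (!length(rows)) stop("unknown subject: ", subject_id)
  v <- table$valence[rows]
  if (any(table(factor(v, levels = VALENCE_LEVELS)) < 2L)) {
    stop("subject ", subject_id,
         " needs at least 2 utterances per valence class")
  }
  feats <- feature_names(table)
  X <- as.matrix(table[rows, feats, drop = FALSE])
  n <- length(rows)
  pred <- integer(n)
  ridge_folds <- 0L
  for (u in seq_len(n)) {
    Xtr <- X[-u, , drop = FALSE]
    vtr <- v[-u]
    sds <- apply(Xtr, 2L, stats::sd)
    rho <- rep(0, length(feats))
    ok <- sds > 0
    if (any(ok)) rho[ok] <- abs(as.numeric(stats::cor(Xtr[, ok, drop = FALSE],
                                                      vtr)))
    sel <- which(rho > threshold)
    if (!length(sel)) sel <- which.max(rho)
    fit <- tryCatch({
      m <- suppressWarnings(MASS::lda(Xtr[, sel, drop = FALSE],
                                      grouping = factor(vtr)))
      p <- stats::predict(m, X[u, sel, drop = FALSE])$class
      as.integer(as.character(p))
    }, error = function(e) NULL)
    if (is.null(fit)) {
      ridge_folds <- ridge_folds + 1L
      fit <- ridge_lda_predict(Xtr[, sel, drop = FALSE], vtr,
                               X[u, sel, drop = FALSE])
    }
    pred[u] <- fit
  }
  recall <- vapply(VALENCE_LEVELS, function(cl) {
    mean(pred[v == cl] == cl)
  }, numeric(1L))
  names(recall) <- c("-1", "0", "+1")
  list(balanced_accuracy = mean(recall), per_class_recall = recall,
       n_utterances = n, ridge_folds = ridge_folds)
}
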