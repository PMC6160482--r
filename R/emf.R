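#' Per-valence moment matrix of one subject
#'
#' Collapses a subject's utterances into a 3 x 3*N_opt matrix of
#' distribution descriptors: for each selected feature and each valence
#' class (-1, 0, +1), the skewness, mean and kurtosis of the feature values
#' over the utterances of that class. Rows are valence classes; columns
#' come in three blocks `[skewness | mean | kurtosis]`, each block in
#' feature order. Moments use population central moments
#' `m_r = sum((x - mean)^r) / n`: skewness `m3 / m2^(3/2)` and non-excess
#' kurtosis `m4 / m2^2`, so both are scale-free. A zero-variance class
#' yields skewness 0 and kurtosis 0 and is flagged degenerate rather than
#' propagating non-finite values.
#'
#' @param table An `emf_table`.
#' @param subject_id One subject in `table`.
#' @param features An `emf_features` set (or integer indices / character
#'   names of feature columns).
#' @return An object of class `"emf_moments"`: list with `subject_id`,
#'   `matrix` (3 x 3*N_opt, rownames `-1`, `0`, `+1`), `degenerate`
#'   (logical matrix 3 x N_opt) and `feature_names`.
#' @export
per_valence_moments <- function(table, subject_id, features) {
  stopifnot(inherits(table, "emf_table"))
  fnames <- resolve_features(table, features)
  rows <- table$subject_id == subject_id
  if (!any(rows)) stop("unknown subject: ", subject_id)
  sub <- table[rows, , drop = FALSE]
  n_opt <- length(fnames)
  sk <- mu <- ku <- matrix(NA_real_, 3L, n_opt)
  degenerate <- matrix(FALSE, 3L, n_opt)
  for (vi in seq_along(VALENCE_LEVELS)) {
    v <- VALENCE_LEVELS[vi]
    cls <- sub[sub$valence == v, fnames, drop = FALSE]
    if (nrow(cls) == 0L) {
      stop("subject ", subject_id, " has no utterances in valence class ", v)
    }
    for (j in seq_len(n_opt)) {
      x <- cls[[j]]
      m <- mean(x)
      m2 <- mean((x - m)^2)
      mu[vi, j] <- m
      if (m2 == 0) {
        sk[vi, j] <- 0
        ku[vi, j] <- 0
        degenerate[vi, j] <- TRUE
      } else {
        sk[vi, j] <- mean((x - m)^3) / m2^1.5
        ku[vi, j] <- mean((x - m)^4) / m2^2
      }
    }
  }
  M <- cbind(sk, mu, ku)
  rownames(M) <- c("-1", "0", "+1")
  colnames(M) <- c(paste0("sk.", fnames), paste0("mu.", fnames),
                   paste0("ku.", fnames))
  rownames(degenerate) <- c("-1", "0", "+1")
  colnames(degenerate) <- fnames
  structure(list(subject_id = subject_id, matrix = M,
                 degenerate = degenerate, feature_names = fnames),
            class = "emf_moments")
}

resolve_features <- function(table, features) {
  feats <- feature_names(table)
  if (inherits(features, "emf_features")) {
    if (features$n_opt < 1L) stop("empty feature set (N_opt = 0)")
    return(features$names)
  }
  if (is.character(features)) {
    bad <- setdiff(features, feats)
    if (length(bad)) stop("unknown feature: ", bad[1L])
    return(features)
  }
  if (is.numeric(features)) return(feats[as.integer(features)])
  stop("cannot interpret 'features'")
}

# Minimum-norm least-squares solution of M b = v via the singular value
# decomposition; coincides with the normal-equation solution whenever
# t(M) %*% M is invertible, and is the Moore-Penrose pseudoinverse solution
# otherwise (the per-subject system has 3 rows and 3*N_opt unknowns, so the
# normal equations are singular for N_opt >= 2).
pinv_solve <- function(M, v) {
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  r <- sum(pos)
  if (r == 0L) {
    b <- numeric(ncol(M))
  } else {
    b <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], v)) / sv$d[pos])
    b <- as.numeric(b)
  }
  list(coefficients = b, rank = r,
       residual = sqrt(sum((as.numeric(M %*% b) - v)^2)))
}

#' Estimate a subject's emotional modulation function
#'
#' Fits the multilinear regression of the subject's moment matrix onto the
#' valence targets (-1, 0, +1): the coefficient vector is the subject's
#' modulation signature. The system has 3 observations and 3*N_opt unknowns,
#' so the minimum-norm least-squares solution (Moore-Penrose pseudoinverse)
#' is used; whenever the moment matrix has full row rank the fit interpolates
#' the targets exactly (zero residual).
#'
#' @param moments An `emf_moments` object (or a numeric matrix with 3 rows).
#' @param targets Valence target vector, fixed at `c(-1, 0, 1)`.
#' @return An object of class `"emf_coef"`: list with `subject_id`,
#'   `coefficients` (length 3*N_opt), `rank` and `residual`.
#' @export
estimate_emf <- function(moments, targets = c(-1, 0, 1)) {
  if (inherits(moments, "emf_moments")) {
    M <- moments$matrix
    sid <- moments$subject_id
  } else {
    M <- as.matrix(moments)
    sid <- NA_character_
  }
  if (nrow(M) != 3L) stop("moment matrix must have exactly 3 rows")
  if (any(!is.finite(M))) stop("non-finite entries in moment matrix")
  fit <- pinv_solve(M, as.numeric(targets))
  structure(list(subject_id = sid,
                 coefficients = stats::setNames(fit$coefficients,
                                                colnames(M)),
                 rank = fit$rank, residual = fit$residual),
            class = "emf_coef")
}

#' Fit the emotional modulation model over a cohort
#'
#' The central fitting function: validates the cohort, selects
#' valence-correlated features (unless a pre-computed set is supplied),
#' builds each included subject's per-valence moment matrix, estimates the
#' per-subject modulation coefficients, and stacks them into the cohort
#' signature matrix `D` (subjects x 3*N_opt) with binary labels
#' `y` (0 = TD, 1 = DD) and 4-class labels `L`
#' (0 = TD, 1 = PDD-NOS, 2 = SLI, 3 = AD).
#'
#' @param table An `emf_table` of utterance-level features.
#' @param manifest An `emf_manifest` of diagnoses.
#' @param features Optional `emf_features` set; computed with
#'   [select_features()] when `NULL`.
#' @param threshold Valence-correlation cutoff passed to [select_features()].
#' @param redundancy_threshold Optional mutual-correlation pruning cutoff.
#' @param min_per_valence Minimum utterances per valence class per subject.
#' @return An object of class `"emf"`: list with `D`, `y`, `L`,
#'   `subject_id`, `diagnosis`, `features`, `validation`, `diagnostics`
#'   (per-subject rank and residual) and `moments` (list of `emf_moments`).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_td = 6, n_nos = 2, n_sli = 2,
#'                                      n_ad = 2, n_signal = 3,
#'                                      n_nuisance = 2), seed = 7)
#' fit <- emf(coh$table, coh$manifest)
#' dim(coef(fit))
#' @export
emf <- function(table, manifest, features = NULL, threshold = 0.7,
                redundancy_threshold = NULL, min_per_valence = 3L) {
  stopifnot(inherits(table, "emf_table"), inherits(manifest, "emf_manifest"))
  validation <- validate_cohort(table, manifest, min_per_valence)
  if (length(validation$included) == 0L) {
    stop("empty cohort: every subject was excluded by validation")
  }
  if (is.null(features)) {
    features <- select_features(table, threshold = threshold,
                                redundancy_threshold = redundancy_threshold)
  }
  if (features$n_opt < 1L) {
    stop("no features selected (N_opt = 0); lower the threshold")
  }
  subs <- validation$included
  moments <- lapply(subs, function(s)
    per_valence_moments(table, s, features))
  fits <- lapply(moments, estimate_emf)
  D <- do.call(rbind, lapply(fits, function(f) f$coefficients))
  rownames(D) <- subs
  diag_map <- stats::setNames(manifest$diagnosis, manifest$subject_id)
  diagnosis <- diag_map[subs]
  L <- DIAGNOSIS_CODE[diagnosis]
  names(L) <- subs
  y <- as.integer(L > 0L)
  names(y) <- subs
  structure(list(
    D = D, y = y, L = L, subject_id = subs,
    diagnosis = stats::setNames(as.character(diagnosis), subs),
    features = features, validation = validation,
    diagnostics = data.frame(
      subject_id = subs,
      rank = vapply(fits, function(f) f$rank, integer(1L)),
      residual = vapply(fits, function(f) f$residual, numeric(1L)),
      stringsAsFactors = FALSE),
    moments = stats::setNames(moments, subs)
  ), class = "emf")
}

#' @export
print.emf <- function(x, ...) {
  cat("Emotional modulation model\n")
  cat("  subjects: ", nrow(x$D), " (TD = ", sum(x$y == 0L), ", DD = ",
      sum(x$y == 1L), ")\n", sep = "")
  cat("  selected features: N_opt = ", x$features$n_opt,
      " -> ", ncol(x$D), " modulation coefficients per subject\n", sep = "")
  if (nrow(x$validation$excluded)) {
    cat("  excluded subjects: ", nrow(x$validation$excluded), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.emf <- function(object, ...) {
  res <- object$diagnostics$residual
  structure(list(
    n_subjects = nrow(object$D),
    n_td = sum(object$y == 0L), n_dd = sum(object$y == 1L),
    by_group = table(factor(object$diagnosis, levels = DIAGNOSES)),
    n_opt = object$features$n_opt,
    feature_names = object$features$names,
    rank_table = table(object$diagnostics$rank),
    max_residual = max(res),
    n_excluded = nrow(object$validation$excluded)
  ), class = "summary.emf")
}

#' @export
print.summary.emf <- function(x, ...) {
  cat("Emotional modulation model summary\n")
  cat("  subjects: ", x$n_subjects, " (TD = ", x$n_td, ", DD = ", x$n_dd,
      "); excluded: ", x$n_excluded, "\n", sep = "")
  cat("  group sizes: ",
      paste(names(x$by_group), as.integer(x$by_group), sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  N_opt = ", x$n_opt, " features: ",
      paste(x$feature_names, collapse = ", "), "\n", sep = "")
  cat("  moment-matrix ranks: ",
      paste(names(x$rank_table), as.integer(x$rank_table), sep = ":",
            collapse = ", "),
      "; max fit residual = ", format(x$max_residual, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Extract the cohort signature matrix
#' @param object An `emf` fit.
#' @param ... Unused.
#' @return Numeric matrix, one row of modulation coefficients per subject.
#' @export
coef.emf <- function(object, ...) object$D

#' Per-subject regression residual norms
#' @param object An `emf` fit.
#' @param ... Unused.
#' @return Named numeric vector of residual norms of the per-subject fits
#'   (zero whenever the subject's moment matrix has full row rank).
#' @export
residuals.emf <- function(object, ...) {
  stats::setNames(object$diagnostics$residual, object$diagnostics$subject_id)
}

#' Heatmap of modulation signatures
#' @param x An `emf` fit.
#' @param ... Passed to [graphics::image()].
#' @export
plot.emf <- function(x, ...) {
  D <- x$D
  ord <- order(x$L)
  graphics::image(seq_len(ncol(D)), seq_len(nrow(D)), t(D[ord, , drop = FALSE]),
                  xlab = "modulation coefficient", ylab = "subject",
                  main = "EMF signatures (subjects sorted by group)", ...)
  graphics::abline(h = sum(x$y == 0L) + 0.5, lwd = 2)
  invisible(x)
}

#' Serialize an EMF dataset
#'
#' Writes the signature matrix as CSV (one row per subject) plus a JSON
#' sidecar with labels, selected-feature provenance and fit diagnostics.
#'
#' @param object An `emf` fit.
#' @param csv_path Output CSV path for the signature matrix.
#' @param json_path Output JSON path for the sidecar (default: `csv_path`
#'   with extension `.json`).
#' @return `csv_path`, invisibly.
#' @export
write_emf_dataset <- function(object, csv_path,
                              json_path = paste0(tools::file_path_sans_ext(csv_path), ".json")) {
  stopifnot(inherits(object, "emf"))
  df <- data.frame(subject_id = rownames(object$D),
                   as.data.frame(object$D, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE)
  side <- list(y = as.integer(object$y), L = as.integer(object$L),
               subject_id = object$subject_id,
               diagnosis = as.character(object$diagnosis),
               features = object$features$names,
               diagnostics = object$diagnostics)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
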