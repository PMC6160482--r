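#' Per-subject Pearson correlation of features with valence
#'
#' For one subject, correlates every feature column with the subject's
#' numeric valence sequence (-1, 0, +1 used arithmetically). Zero-variance
#' feature columns have no defined correlation; they are flagged and treated
#' as correlation 0 by the selection rule, so constant nuisance columns can
#' never be selected nor crash a run.
#'
#' @param table An `emf_table`.
#' @param subject_id One subject present in `table`.
#' @return An object of class `"emf_corr"`: list with `subject_id`, `rho`
#'   (named vector, `NA` where undefined) and `undefined` (logical vector).
#' @export
valence_correlation <- function(table, subject_id) {
  stopifnot(inherits(table, "emf_table"))
  rows <- table$subject_id == subject_id
  if (!any(rows)) stop("unknown subject: ", subject_id)
  e <- table$valence[rows]
  if (length(e) < 2L) stop("subject ", subject_id, " has fewer than 2 utterances")
  if (length(unique(e)) < 2L) {
    stop("degenerate valence sequence for subject ", subject_id,
         ": all utterances share valence ", e[1L])
  }
  feats <- feature_names(table)
  X <- as.matrix(table[rows, feats, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  rho <- rep(NA_real_, length(feats))
  ok <- sds > 0
  if (any(ok)) rho[ok] <- as.numeric(stats::cor(X[, ok, drop = FALSE], e))
  names(rho) <- feats
  structure(list(subject_id = subject_id, rho = rho, undefined = !ok),
            class = "emf_corr")
}

#' Threshold a correlation profile into a subject feature set
#'
#' Keeps features whose absolute valence correlation strictly exceeds the
#' threshold (0.7 in the reference analysis). Undefined correlations count
#' as 0.
#'
#' @param profile An `emf_corr` from [valence_correlation()].
#' @param threshold Correlation magnitude cutoff in \[0, 1\].
#' @return Integer vector of selected feature indices (table column order).
#' @export
select_subject_features <- function(profile, threshold = 0.7) {
  stopifnot(inherits(profile, "emf_corr"),
            threshold >= 0, threshold <= 1)
  rho <- profile$rho
  rho[is.na(rho)] <- 0
  unname(which(abs(rho) > threshold))
}

#' Union per-subject feature sets into the shared cohort set
#'
#' The same feature set is used for every subject downstream, so the
#' per-subject selections are unioned and returned in the original column
#' order.
#'
#' @param per_subject_sets List of integer index vectors (one per subject).
#' @param feature_names Character vector naming all feature columns, in
#'   table order.
#' @return An object of class `"emf_features"`: list with `indices`,
#'   `names`, `n_opt` and `provenance` (the per-subject sets).
#' @export
union_selected_features <- function(per_subject_sets, feature_names) {
  idx <- sort(unique(unlist(per_subject_sets)))
  if (length(idx) && (min(idx) < 1L || max(idx) > length(feature_names))) {
    stop("feature index out of range")
  }
  structure(list(indices = as.integer(idx),
                 names = feature_names[idx],
                 n_opt = length(idx),
                 provenance = per_subject_sets),
            class = "emf_features")
}

#' @export
print.emf_features <- function(x, ...) {
  cat("Selected feature set: N_opt = ", x$n_opt, "\n", sep = "")
  if (x$n_opt) cat("  ", paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Prune mutually redundant features
#'
#' Greedy redundancy pruning by mutual correlation: candidates are visited
#' in descending order of their strongest per-subject valence correlation
#' (ties broken by column order) and a candidate is dropped when its absolute
#' Pearson correlation over all utterances with an already-kept feature
#' reaches or exceeds `redundancy_threshold`. At threshold 1 only exactly
#' collinear duplicates are removed.
#'
#' @param table An `emf_table` (all utterances are pooled for the mutual
#'   correlations).
#' @param candidate An `emf_features` set to prune.
#' @param redundancy_threshold Mutual correlation cutoff in (0, 1].
#' @param strength Optional named numeric vector of per-feature selection
#'   strength (max over subjects of absolute valence correlation); computed
#'   from `table` when omitted.
#' @return A pruned `emf_features` set, in original column order.
#' @export
prune_redundant_features <- function(table, candidate,
                                     redundancy_threshold = 0.95,
                                     strength = NULL) {
  stopifnot(inherits(table, "emf_table"), inherits(candidate, "emf_features"),
            redundancy_threshold > 0, redundancy_threshold <= 1)
  if (candidate$n_opt <= 1L) return(candidate)
  feats <- feature_names(table)
  if (is.null(strength)) {
    profs <- lapply(subject_ids(table), function(s) {
      r <- valence_correlation(table, s)$rho
      r[is.na(r)] <- 0
      abs(r)
    })
    strength <- do.call(pmax, profs)
  }
  idx <- candidate$indices
  ord <- idx[order(-strength[idx], idx)]
  X <- as.matrix(table[, feats, drop = FALSE])
  kept <- integer(0)
  for (j in ord) {
    redundant <- FALSE
    for (k in kept) {
      xj <- X[, j]; xk <- X[, k]
      if (stats::sd(xj) == 0 || stats::sd(xk) == 0) next
      if (abs(stats::cor(xj, xk)) >= redundancy_threshold - 1e-12) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, j)
  }
  union_selected_features(list(sort(kept)), feats)
}

#' Cohort-level valence-correlated feature selection
#'
#' Runs [valence_correlation()] and [select_subject_features()] for each
#' subject, unions the per-subject sets, and optionally prunes mutually
#' redundant features. `subjects` restricts the selection to a training
#' subset (the "strict" leakage mode of a cross-validated run); by default
#' every subject contributes, which matches the reference protocol in which
#' selection uses valence annotations only and no diagnosis information.
#'
#' @param table An `emf_table`.
#' @param threshold Per-subject correlation magnitude cutoff (default 0.7).
#' @param redundancy_threshold Optional mutual-correlation cutoff in (0, 1];
#'   `NULL` (default) skips pruning.
#' @param subjects Optional character vector of contributing subjects.
#' @return An `emf_features` set.
#' @export
select_features <- function(table, threshold = 0.7,
                            redundancy_threshold = NULL, subjects = NULL) {
  stopifnot(inherits(table, "emf_table"))
  subs <- subjects %||% subject_ids(table)
  feats <- feature_names(table)
  sets <- lapply(subs, function(s) {
    select_subject_features(valence_correlation(table, s), threshold)
  })
  names(sets) <- subs
  out <- union_selected_features(sets, feats)
  if (!is.null(redundancy_threshold) && out$n_opt > 1L) {
    pruned <- prune_redundant_features(table, out, redundancy_threshold)
    pruned$provenance <- sets
    out <- pruned
  }
  out
}
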