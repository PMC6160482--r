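#' Thresholds for the dynamic feature-selection cascade
#'
#' The three gates of the cascade are governed by: `fds` for the
#' training-side Fisher-score gate (a feature is kept iff its Fisher score
#' strictly exceeds the threshold; by default the threshold is resolved per
#' training set as the `fds_percentile`-th percentile of the training Fisher
#' scores, a scale-free choice); `mr` for the Mahalanobis-ratio gate (kept
#' iff the ratio is strictly below `mr`); and `p` for the class-probability
#' gate. In `p_mode = "z"` (default) the probability gate keeps a feature
#' when the test value lies within `p` class standard deviations of the
#' nearest class mean, a per-feature scale-free reformulation of the density
#' threshold; `p_mode = "density"` applies the literal rule `P_k > p` on the
#' maximum Gaussian class density.
#'
#' @param fds Absolute Fisher-score threshold, or `NULL` to resolve from
#'   `fds_percentile` per training set.
#' @param fds_percentile Percentile (0-100) of the training Fisher scores
#'   used when `fds` is `NULL`.
#' @param mr Mahalanobis-ratio threshold (> 0).
#' @param mr_reference Reference class of the ratio, see
#'   [mahalanobis_ratio()]: `"nearest"` (default) or `"first"`.
#' @param p Probability-gate threshold: a z-score bound in `"z"` mode, a
#'   density bound in `"density"` mode.
#' @param p_mode `"z"` or `"density"`.
#' @return An object of class `"dfs_thresholds"`.
#' @export
dfs_thresholds <- function(fds = NULL, fds_percentile = 50, mr = 1,
                           mr_reference = c("nearest", "first"),
                           p = 2.5, p_mode = c("z", "density")) {
  p_mode <- match.arg(p_mode)
  mr_reference <- match.arg(mr_reference)
  if (!is.null(fds) && fds < 0) stop("fds threshold must be >= 0")
  if (mr <= 0) stop("mr threshold must be > 0")
  if (p < 0) stop("p threshold must be >= 0")
  structure(list(fds = fds, fds_percentile = fds_percentile, mr = mr,
                 mr_reference = mr_reference, p = p, p_mode = p_mode),
            class = "dfs_thresholds")
}

#' Fisher discriminant scores over features
#'
#' For each column of the training matrix, the ratio `SB / SW` where
#' `SB = sum_d (class-d mean - global mean)^2` over the two classes and
#' `SW = sum_d (1/L_d) * sum_i (x_id - class-d mean)^2`. Degenerate
#' conventions: `SW = 0` with `SB > 0` gives `+Inf` (the feature separates
#' the classes perfectly and is always kept); `SW = SB = 0` gives 0.
#'
#' @param D Numeric training matrix (subjects x features).
#' @param y Binary labels (0/1), one per row of `D`.
#' @return Numeric vector of Fisher scores, one per column.
#' @export
fisher_scores <- function(D, y) {
  D <- as.matrix(D)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("Fisher scores need both classes in the training set")
  }
  vapply(seq_len(ncol(D)), function(k) {
    x <- D[, k]
    gm <- mean(x)
    sb <- 0; sw <- 0
    for (d in c(0L, 1L)) {
      xd <- x[y == d]
      md <- mean(xd)
      sb <- sb + (md - gm)^2
      sw <- sw + mean((xd - md)^2)
    }
    if (sw == 0) {
      if (sb > 0) Inf else 0
    } else {
      sb / sw
    }
  }, numeric(1L))
}

#' Apply the Fisher-score gate
#' @param fds Vector of Fisher scores.
#' @param th_fds Numeric threshold (strict inequality `fds > th_fds`).
#' @return Logical mask over features.
#' @export
apply_c1 <- function(fds, th_fds) fds > th_fds

# Scalar per-feature Mahalanobis distance of s from class d with unbiased
# (n-1) class variance. Zero-variance convention: s at the constant -> 0,
# otherwise +Inf.
scalar_mahalanobis <- function(s, xd) {
  m <- mean(xd)
  v <- stats::var(xd)
  if (v == 0) {
    if (s == m) 0 else Inf
  } else {
    (s - m)^2 / v
  }
}

#' Mahalanobis ratio of a test value between the two classes
#'
#' `MR = M_ref * M_ref / M_other` where `M_d` is the squared per-feature
#' Mahalanobis distance of the test value from class `d` (unbiased class
#' variance). Low values mean the test value sits near the reference class
#' and far from the other — exactly the configuration in which the feature
#' is informative for this sample; high values flag outliers (far from
#' both classes). With `reference = "nearest"` (default, used by the
#' cascade) the reference is whichever class the test value is closer to,
#' so the gate treats both classes symmetrically; `reference = "first"`
#' fixes the reference to the lower label, the literal reading of the
#' printed ratio. Both agree whenever the test value is nearer class 1.
#' Conventions: a zero reference distance gives 0 (kept); in `"first"`
#' mode a zero class-2 distance with positive class-1 distance gives
#' `+Inf` (removed); distances infinite for both classes give `+Inf`.
#'
#' @param s Scalar test value for one feature.
#' @param x Training values for that feature.
#' @param y Binary labels (0/1) aligned with `x`.
#' @param reference `"nearest"` or `"first"`; see Details.
#' @return Scalar ratio (possibly `Inf`).
#' @export
mahalanobis_ratio <- function(s, x, y, reference = c("nearest", "first")) {
  reference <- match.arg(reference)
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("mahalanobis_ratio needs two classes")
  m1 <- scalar_mahalanobis(s, x[y == classes[1L]])
  m2 <- scalar_mahalanobis(s, x[y == classes[2L]])
  if (reference == "nearest") {
    mr <- min(m1, m2); mo <- max(m1, m2)
  } else {
    mr <- m1; mo <- m2
  }
  if (mr == 0) return(0)
  if (mo == 0) return(Inf)
  if (is.infinite(mr) && is.infinite(mo)) return(Inf)
  mr * mr / mo
}

#' Maximum Gaussian class density at a test value
#'
#' Fits a Normal distribution to each class's training values for one
#' feature (unbiased SD) and returns the larger density at the test value.
#' Densities are not probabilities and may exceed 1. A zero class SD gives
#' density `+Inf` at the constant and 0 elsewhere.
#'
#' @inheritParams mahalanobis_ratio
#' @return Scalar density (possibly `Inf`).
#' @export
max_class_probability <- function(s, x, y) {
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("max_class_probability needs two classes")
  dens <- vapply(classes, function(d) {
    xd <- x[y == d]
    m <- mean(xd)
    sdd <- stats::sd(xd)
    if (sdd == 0) {
      if (s == m) Inf else 0
    } else {
      stats::dnorm(s, m, sdd)
    }
  }, numeric(1L))
  max(dens)
}

# Minimum z-distance of s to the class means in class-SD units; the
# scale-free form of the density gate.
min_class_z <- function(s, x, y) {
  y <- as.integer(y)
  zs <- vapply(sort(unique(y)), function(d) {
    xd <- x[y == d]
    m <- mean(xd)
    sdd <- stats::sd(xd)
    if (sdd == 0) {
      if (s == m) 0 else Inf
    } else {
      abs(s - m) / sdd
    }
  }, numeric(1L))
  min(zs)
}

#' Dynamic feature selection for one test sample
#'
#' Applies the three-gate cascade to the training signature matrix and one
#' held-out signature vector: the training-side Fisher-score gate (C1),
#' then on its survivors the test-conditioned Mahalanobis-ratio gate (C2)
#' and the Gaussian class-probability gate (C3). If no feature survives C3
#' the C1 mask is used; if C1 itself is empty, all features are used (both
#' fallbacks flagged in the trace). Selection is stateless across test
#' samples: every feature is reconsidered afresh for the next sample.
#'
#' @param D Numeric training matrix (subjects x features).
#' @param y Binary labels (0/1) per training row.
#' @param s Test signature vector (length `ncol(D)`).
#' @param thresholds A [dfs_thresholds()] object.
#' @return A list with `mask` (logical over features) and `trace`
#'   (class `"dfs_trace"`): Fisher scores, per-feature `mr`, `p` and `z`
#'   values, the three cascade masks, the resolved thresholds and the
#'   fallback level (0 = none, 1 = C1 mask, 2 = all features).
#' @export
dfs_select <- function(D, y, s, thresholds = dfs_thresholds()) {
  D <- as.matrix(D)
  y <- as.integer(y)
  if (length(s) != ncol(D)) stop("test vector length does not match features")
  stopifnot(inherits(thresholds, "dfs_thresholds"))
  fds <- stats::setNames(fisher_scores(D, y), colnames(D))
  th_fds <- thresholds$fds
  if (is.null(th_fds)) {
    fin <- fds[is.finite(fds)]
    th_fds <- if (length(fin)) {
      as.numeric(stats::quantile(fin, thresholds$fds_percentile / 100))
    } else 0
  }
  mask1 <- apply_c1(fds, th_fds)

  nf <- ncol(D)
  mr <- stats::setNames(rep(NA_real_, nf), colnames(D))
  p <- stats::setNames(rep(NA_real_, nf), colnames(D))
  z <- stats::setNames(rep(NA_real_, nf), colnames(D))
  for (k in seq_len(nf)) {
    mr[k] <- mahalanobis_ratio(s[k], D[, k], y,
                               reference = thresholds$mr_reference)
    p[k] <- max_class_probability(s[k], D[, k], y)
    z[k] <- min_class_z(s[k], D[, k], y)
  }
  mask2 <- mask1 & (mr < thresholds$mr)
  c3 <- if (thresholds$p_mode == "z") z <= thresholds$p else p > thresholds$p
  mask3 <- mask2 & c3

  fallback <- 0L
  mask <- mask3
  if (!any(mask)) {
    mask <- mask1
    fallback <- 1L
    if (!any(mask)) {
      mask <- rep(TRUE, nf)
      fallback <- 2L
    }
  }
  trace <- structure(list(
    fds = fds, th_fds = th_fds, mr = mr, p = p, z = z,
    mask_c1 = mask1, mask_c2 = mask2, mask_c3 = mask3,
    fallback = fallback, thresholds = thresholds
  ), class = "dfs_trace")
  list(mask = mask, trace = trace)
}

#' @export
print.dfs_trace <- function(x, ...) {
  cat("DFS trace: ", length(x$fds), " features; th_FDS = ",
      format(x$th_fds, digits = 4), "\n", sep = "")
  cat("  survivors: C1 = ", sum(x$mask_c1), ", C2 = ", sum(x$mask_c2),
      ", C3 = ", sum(x$mask_c3), "; fallback level ", x$fallback, "\n",
      sep = "")
  invisible(x)
}
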