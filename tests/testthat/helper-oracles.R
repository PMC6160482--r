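# Independent brute-force oracles used to cross-check the implementation.
# Each is written directly from the defining formula, avoiding the package's
# own code paths.

# Pearson correlation from raw sums.
oracle_pearson <- function(x, e) {
  n <- length(x)
  num <- sum((x - mean(x)) * (e - mean(e))) / n
  den <- sqrt(sum((x - mean(x))^2) / n) * sqrt(sum((e - mean(e))^2) / n)
  num / den
}

# Population moments by explicit summation.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu,
       skewness = if (m2 == 0) 0 else m3 / m2^(3 / 2),
       kurtosis = if (m2 == 0) 0 else m4 / m2^2)
}

# Minimum-norm least squares through MASS::ginv, an implementation
# independent of the package's SVD route.
oracle_minnorm <- function(M, v) as.numeric(MASS::ginv(M) %*% v)

# Fisher score by direct two-class summation.
oracle_fds <- function(x, y) {
  gm <- mean(x)
  sb <- sw <- 0
  for (d in c(0, 1)) {
    xd <- x[y == d]
    sb <- sb + (mean(xd) - gm)^2
    sw <- sw + sum((xd - mean(xd))^2) / length(xd)
  }
  if (sw == 0) { if (sb > 0) Inf else 0 } else sb / sw
}

# Scalar Mahalanobis distance with unbiased class variance.
oracle_mdist <- function(s, xd) {
  v <- sum((xd - mean(xd))^2) / (length(xd) - 1)
  if (v == 0) { if (s == mean(xd)) 0 else Inf } else (s - mean(xd))^2 / v
}

# Mahalanobis ratio referenced to the nearest class (cascade convention).
oracle_mr <- function(s, x, y) {
  m0 <- oracle_mdist(s, x[y == 0])
  m1 <- oracle_mdist(s, x[y == 1])
  near <- min(m0, m1); far <- max(m0, m1)
  if (near == 0) return(0)
  if (far == 0) return(Inf)
  if (is.infinite(near)) return(Inf)
  near * near / far
}

# Maximum Gaussian class density, written from the density formula.
oracle_maxp <- function(s, x, y) {
  dens <- sapply(c(0, 1), function(d) {
    xd <- x[y == d]
    sdd <- sqrt(sum((xd - mean(xd))^2) / (length(xd) - 1))
    if (sdd == 0) { if (s == mean(xd)) Inf else 0 }
    else exp(-(s - mean(xd))^2 / (2 * sdd^2)) / (sqrt(2 * pi) * sdd)
  })
  max(dens)
}

# Full cascade by direct evaluation (z-mode probability gate).
oracle_dfs <- function(D, y, s, th_fds, th_mr, th_z) {
  nf <- ncol(D)
  fds <- sapply(seq_len(nf), function(k) oracle_fds(D[, k], y))
  m1 <- fds > th_fds
  mr <- sapply(seq_len(nf), function(k) oracle_mr(s[k], D[, k], y))
  z <- sapply(seq_len(nf), function(k) {
    zs <- sapply(c(0, 1), function(d) {
      xd <- D[y == d, k]
      sdd <- sd(xd)
      if (sdd == 0) { if (s[k] == mean(xd)) 0 else Inf }
      else abs(s[k] - mean(xd)) / sdd
    })
    min(zs)
  })
  m2 <- m1 & (mr < th_mr)
  m3 <- m2 & (z <= th_z)
  mask <- m3
  if (!any(mask)) mask <- m1
  if (!any(mask)) mask <- rep(TRUE, nf)
  mask
}

# AUC by exhaustive pair enumeration, ties counted one half.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Welch t statistic from first principles.
oracle_welch_t <- function(x1, x0) {
  se2 <- var(x1) / length(x1) + var(x0) / length(x0)
  if (se2 == 0) 0 else abs(mean(x1) - mean(x0)) / sqrt(se2)
}
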