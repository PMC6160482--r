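test_that("Fisher scores reproduce frozen two-class computations", {
  D <- cbind(c(0, 1, 2, 3),        # class means 0.5 / 2.5 -> SB 2, SW 0.5
             c(1, 2, 1, 2),        # identical multisets -> SB 0
             c(5, 5, 9, 9))        # zero within, positive between -> Inf
  y <- c(0L, 0L, 1L, 1L)
  fds <- fisher_scores(D, y)
  expect_equal(fds[1], 4)
  expect_equal(fds[2], 0)
  expect_equal(fds[3], Inf)
  expect_error(fisher_scores(D, c(0L, 0L, 0L, 0L)), "both classes")

  expect_equal(apply_c1(c(4, 0), 1), c(TRUE, FALSE))
  expect_equal(apply_c1(c(4, 0), 0), c(TRUE, FALSE))   # strict inequality
  expect_equal(apply_c1(c(4, Inf), Inf), c(FALSE, FALSE))
})

test_that("Mahalanobis ratio and class probability match frozen values", {
  x <- c(0, 2, 10, 12)
  y <- c(0L, 0L, 1L, 1L)
  # unbiased variances both 2: M1 = 0.5, M2 = 40.5
  expect_equal(mahalanobis_ratio(2, x, y), 0.5 * 0.5 / 40.5,
               tolerance = 1e-12)
  expect_equal(mahalanobis_ratio(1, x, y), 0)      # at class-1 mean
  # equidistant from both means with equal variances: ratio term 1 -> M1
  expect_equal(mahalanobis_ratio(6, x, y), (6 - 1)^2 / 2, tolerance = 1e-12)
  # literal first-class reference: zero class-2 distance removes the feature
  expect_equal(mahalanobis_ratio(11, c(0, 2, 11, 11), y,
                                 reference = "first"), Inf)

  # maximum class density
  xs <- c(-1, 1, 4, 6)  # class sds sqrt(2); means 0 and 5
  expect_equal(max_class_probability(0, xs, y), dnorm(0, 0, sqrt(2)),
               tolerance = 1e-12)
  expect_equal(max_class_probability(2.5, xs, y),
               dnorm(2.5, 0, sqrt(2)), tolerance = 1e-12)
  # densities can exceed 1 for tight classes
  tight <- c(0, 0.1, 5, 5.1)
  expect_gt(max_class_probability(0.05, tight, y), 1)
})

test_that("gate statistics agree with brute-force oracles on random data", {
  set.seed(41)
  for (rep in 1:100) {
    tr <- random_training(n0 = sample(3:8, 1), n1 = sample(3:8, 1), nf = 3)
    s <- rnorm(3)
    for (k in 1:3) {
      expect_equal(fisher_scores(tr$D, tr$y)[k],
                   oracle_fds(tr$D[, k], tr$y), tolerance = 1e-10)
      expect_equal(mahalanobis_ratio(s[k], tr$D[, k], tr$y),
                   oracle_mr(s[k], tr$D[, k], tr$y), tolerance = 1e-10)
      expect_equal(max_class_probability(s[k], tr$D[, k], tr$y),
                   oracle_maxp(s[k], tr$D[, k], tr$y), tolerance = 1e-10)
    }
  }
})

test_that("the cascade matches a brute-force evaluation on random instances", {
  set.seed(43)
  for (rep in 1:40) {
    tr <- random_training(n0 = 15, n1 = 15, nf = 12)
    s <- rnorm(12)
    th_fds <- as.numeric(quantile(sapply(1:12, function(k)
      oracle_fds(tr$D[, k], tr$y)), 0.5))
    sel <- dfs_select(tr$D, tr$y, s,
                      dfs_thresholds(fds = th_fds, mr = 1, p = 2.5))
    expect_identical(sel$mask, oracle_dfs(tr$D, tr$y, s, th_fds, 1, 2.5))
  }
})

test_that("constructed instances fail exactly one gate each", {
  # 30 training rows, 3 features engineered so that:
  #   A fails C1 (no class separation), B passes C1 but fails C2 (outlier
  #   test value), C passes all gates
  set.seed(47)
  n <- 15
  A <- c(rnorm(n, 0, 1), rnorm(n, 0, 1))
  B <- c(rnorm(n, 0, 0.5), rnorm(n, 4, 0.5))
  C <- c(rnorm(n, 0, 0.5), rnorm(n, 4, 0.5))
  D <- cbind(A = A, B = B, C = C)
  y <- rep(c(0L, 1L), each = n)
  s <- c(A = 0, B = 50, C = 4)   # B's value far from both classes
  th <- dfs_thresholds(fds = 1, mr = 1, p = 2.5)
  sel <- dfs_select(D, y, s, th)
  expect_equal(unname(sel$mask), c(FALSE, FALSE, TRUE))
  expect_false(sel$trace$mask_c1[["A"]])
  expect_true(sel$trace$mask_c1[["B"]])
  expect_false(sel$trace$mask_c2[["B"]])

  # a test value 2.6 class sds beyond the near class mean (far class much
  # further) passes C2 (ratio ~ 6.76^2 / M_far < 1) but fails the 2.5-sd
  # probability gate: C is removed by C3 alone
  m1 <- mean(C[y == 1L]); sd1 <- sd(C[y == 1L])
  s2 <- c(A = 0, B = 4, C = m1 + 2.6 * sd1)
  stopifnot(mahalanobis_ratio(s2[["C"]], C, y) < 1)
  sel2 <- dfs_select(D, y, s2, th)
  expect_true(sel2$trace$mask_c2[["C"]])
  expect_false(sel2$trace$mask_c3[["C"]])
})

test_that("cascade masks nest, fall back when empty, and are stateless", {
  set.seed(53)
  tr <- random_training(n0 = 12, n1 = 12, nf = 8)
  s <- rnorm(8)
  sel <- dfs_select(tr$D, tr$y, s)
  expect_true(all(sel$trace$mask_c3 <= sel$trace$mask_c2))
  expect_true(all(sel$trace$mask_c2 <= sel$trace$mask_c1))
  expect_true(any(sel$mask))

  # vacuous gates keep everything (all finite FDS > 0 here)
  vac <- dfs_select(tr$D, tr$y, s,
                    dfs_thresholds(fds = 0, mr = Inf, p = Inf))
  expect_true(all(vac$mask))

  # impossible C1 threshold triggers the all-features fallback
  none <- dfs_select(tr$D, tr$y, s, dfs_thresholds(fds = Inf))
  expect_true(all(none$mask))
  expect_equal(none$trace$fallback, 2L)

  # statelessness: evaluation order of two test samples is irrelevant
  s2 <- rnorm(8)
  m_a1 <- dfs_select(tr$D, tr$y, s)$mask
  m_b1 <- dfs_select(tr$D, tr$y, s2)$mask
  m_b2 <- dfs_select(tr$D, tr$y, s2)$mask
  m_a2 <- dfs_select(tr$D, tr$y, s)$mask
  expect_identical(m_a1, m_a2)
  expect_identical(m_b1, m_b2)
})

test_that("tightening any threshold never grows the pre-fallback selection", {
  set.seed(59)
  tr <- random_training(n0 = 15, n1 = 15, nf = 10)
  s <- rnorm(10)
  base <- dfs_thresholds(fds = 0.5, mr = 1, p = 2.5)
  b <- dfs_select(tr$D, tr$y, s, base)$trace$mask_c3
  for (rep in 1:100) {
    th2 <- dfs_thresholds(fds = 0.5 + runif(1, 0, 2),
                          mr = 1 / (1 + runif(1, 0, 3)),
                          p = 2.5 - runif(1, 0, 2))
    m2 <- dfs_select(tr$D, tr$y, s, th2)$trace$mask_c3
    expect_true(all(m2 <= b))
  }
})

test_that("scale equivariance: rescaling a feature leaves the gates unchanged", {
  set.seed(61)
  tr <- random_training(n0 = 10, n1 = 10, nf = 5)
  s <- rnorm(5)
  sel1 <- dfs_select(tr$D, tr$y, s)
  c <- 37.5
  D2 <- tr$D; D2[, 3] <- D2[, 3] * c
  s2 <- s; s2[3] <- s2[3] * c
  sel2 <- dfs_select(D2, tr$y, s2)
  expect_equal(sel1$trace$fds, sel2$trace$fds, tolerance = 1e-10)
  expect_equal(sel1$trace$mr, sel2$trace$mr, tolerance = 1e-10)
  expect_equal(sel1$trace$z, sel2$trace$z, tolerance = 1e-10)
  expect_identical(sel1$mask, sel2$mask)
})
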