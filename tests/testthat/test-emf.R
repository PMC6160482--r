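test_that("per-valence moments reproduce frozen hand computations", {
  tab <- make_table(list(
    s = list(valence = rep(c(-1L, 0L, 1L), times = c(3, 4, 3)),
             f = c(1, 2, 3,  1, 2, 3, 6,  5, 5, 5))
  ))
  mm <- per_valence_moments(tab, "s", "f")
  M <- mm$matrix
  # class -1: values (1,2,3): m2 = 2/3, m3 = 0, m4 = 2/3 -> ku = 1.5
  expect_equal(unname(M["-1", c("sk.f", "mu.f", "ku.f")]),
               c(0, 2, 1.5), tolerance = 1e-12)
  # class 0: values (1,2,3,6): m2 = 3.5, m3 = 4.5, m4 = 24.5
  expect_equal(unname(M["0", "mu.f"]), 3)
  expect_equal(unname(M["0", "sk.f"]), 4.5 / 3.5^1.5, tolerance = 1e-12)
  expect_equal(unname(M["0", "ku.f"]), 24.5 / 3.5^2, tolerance = 1e-12)
  # constant class: flagged degenerate, skewness/kurtosis forced to 0
  expect_equal(unname(M["+1", c("sk.f", "mu.f", "ku.f")]), c(0, 5, 0))
  expect_true(mm$degenerate["+1", "f"])
  expect_false(any(mm$degenerate[c("-1", "0"), ]))
})

test_that("moments agree with a summation oracle on random classes", {
  set.seed(17)
  for (rep in 1:100) {
    x <- rnorm(sample(3:12, 1))
    vals <- c(x, 0, 1)  # pad classes 0 and +1 with singletons
    tab <- make_table(list(s = list(
      valence = c(rep(-1L, length(x)), 0L, 1L), f = vals)))
    M <- per_valence_moments(tab, "s", "f")$matrix
    o <- oracle_moments(x)
    expect_equal(unname(M["-1", "mu.f"]), o$mean, tolerance = 1e-10)
    expect_equal(unname(M["-1", "sk.f"]), o$skewness, tolerance = 1e-10)
    expect_equal(unname(M["-1", "ku.f"]), o$kurtosis, tolerance = 1e-10)
  }
})

test_that("modulation estimation is minimum-norm least squares", {
  # all-zero moment matrix: minimum-norm solution is zero with full residual
  z <- estimate_emf(matrix(0, 3, 6))
  expect_equal(z$coefficients, setNames(rep(0, 6), rep("", 6)),
               ignore_attr = TRUE)
  expect_equal(z$residual, sqrt(2), tolerance = 1e-12)
  expect_equal(z$rank, 0L)

  # one column equal to the targets: exact sparse interpolation
  M <- matrix(0, 3, 5)
  M[, 3] <- c(-1, 0, 1)
  f <- estimate_emf(M)
  expect_equal(unname(f$coefficients), c(0, 0, 1, 0, 0), tolerance = 1e-12)
  expect_equal(f$residual, 0, tolerance = 1e-12)

  expect_error(estimate_emf(matrix(NA_real_, 3, 3)), "non-finite")
  expect_error(estimate_emf(matrix(0, 2, 3)), "3 rows")
})

test_that("estimation matches the pseudoinverse oracle on random systems", {
  set.seed(23)
  v <- c(-1, 0, 1)
  for (rep in 1:100) {
    M <- matrix(rnorm(3 * 6), 3, 6)
    f <- estimate_emf(M)
    expect_equal(unname(f$coefficients), oracle_minnorm(M, v),
                 tolerance = 1e-8)
    # full row rank: exact interpolation
    expect_equal(as.numeric(M %*% f$coefficients), v, tolerance = 1e-10)
    expect_equal(f$rank, 3L)
  }
  # rank-deficient systems keep the minimum-norm property
  for (rep in 1:50) {
    base <- matrix(rnorm(3 * 4), 3, 4)
    M <- cbind(base, base[, 1] * 2)      # collinear column
    M[3, ] <- M[1, ] + M[2, ]            # dependent row
    f <- estimate_emf(M)
    o <- oracle_minnorm(M, v)
    expect_equal(unname(f$coefficients), o, tolerance = 1e-8)
    expect_lte(sqrt(sum(f$coefficients^2)), sqrt(sum(o^2)) + 1e-8)
  }
})

test_that("permuting feature order permutes coefficients within blocks", {
  coh <- small_cohort(seed = 31)
  sel <- select_features(coh$table, 0.7)
  sid <- subject_ids(coh$table)[1]
  b1 <- estimate_emf(per_valence_moments(coh$table, sid, sel$names))
  perm <- rev(sel$names)
  b2 <- estimate_emf(per_valence_moments(coh$table, sid, perm))
  n <- length(sel$names)
  for (block in 0:2) {
    expect_equal(unname(b2$coefficients[block * n + seq_len(n)]),
                 unname(rev(b1$coefficients[block * n + seq_len(n)])),
                 tolerance = 1e-8)
  }
})

test_that("the cohort fit assembles labels, shapes and diagnostics", {
  coh <- small_cohort(seed = 2)
  fit <- emf(coh$table, coh$manifest)
  expect_s3_class(fit, "emf")
  expect_equal(ncol(fit$D), 3L * fit$features$n_opt)
  expect_equal(nrow(fit$D), 16L)
  expect_equal(unname(fit$y), as.integer(fit$L > 0))
  expect_equal(sum(fit$y == 0L), 8L)
  expect_equal(unname(fit$L[fit$diagnosis == "SLI"][1]), 2L)
  expect_equal(unname(fit$L[fit$diagnosis == "AD"][1]), 3L)
  expect_equal(coef(fit), fit$D)
  expect_equal(length(residuals(fit)), 16L)
  expect_output(print(fit), "modulation")
  expect_output(print(summary(fit)), "N_opt")

  # all-TD cohort has all-zero binary labels
  td <- simulate_cohort(cohort_config(n_td = 4, n_nos = 0, n_sli = 0,
                                      n_ad = 0, n_signal = 2,
                                      n_nuisance = 0), seed = 3)
  ftd <- emf(td$table, td$manifest)
  expect_true(all(ftd$y == 0L))
})

test_that("noiseless cohorts yield exact interpolation (zero residual)", {
  cfg <- cohort_config(n_td = 4, n_nos = 2, n_sli = 2, n_ad = 2,
                       n_signal = 3, n_nuisance = 0,
                       noise_sd = 0, within_group_sd = 0)
  coh <- simulate_cohort(cfg, seed = 19)
  fit <- emf(coh$table, coh$manifest)
  # noiseless classes are constant, so skew/kurt blocks vanish and the mean
  # rows lie on the line b + v*a: rank 2, but the valence targets remain in
  # the row-space image, so interpolation is still exact
  expect_true(all(fit$diagnostics$rank == 2L))
  expect_true(all(fit$diagnostics$residual <= 1e-10))
  # mean-block rows follow the planted linear law a*v + b
  sid <- fit$subject_id[1]
  mm <- per_valence_moments(coh$table, sid, fit$features)
  n <- fit$features$n_opt
  mu_block <- mm$matrix[, n + seq_len(n), drop = FALSE]
  a <- coh$truth$slopes[sid, fit$features$names]
  b <- coh$truth$offsets[sid, fit$features$names]
  for (vi in 1:3) {
    v <- c(-1, 0, 1)[vi]
    expect_equal(unname(mu_block[vi, ]), unname(a * v + b),
                 tolerance = 1e-10)
  }
})
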