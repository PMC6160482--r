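test_that("valence correlation matches the frozen hand computation", {
  tab <- make_table(list(
    s1 = list(valence = c(-1L, -1L, 0L, 0L, 1L, 1L),
              up = as.numeric(1:6),
              same = c(-1, -1, 0, 0, 1, 1),
              flat = rep(2, 6))
  ))
  prof <- valence_correlation(tab, "s1")
  # covariance 8, sum-of-squares 17.5 and 4 -> rho = 8 / sqrt(70)
  expect_equal(unname(prof$rho["up"]), 8 / sqrt(70), tolerance = 1e-12)
  expect_equal(unname(prof$rho["same"]), 1)
  expect_true(is.na(prof$rho["flat"]))
  expect_true(prof$undefined["flat"])

  expect_error(valence_correlation(tab, "nope"), "unknown subject")
  mono <- make_table(list(s1 = list(valence = c(1L, 1L), f1 = c(1, 2))))
  expect_error(valence_correlation(mono, "s1"), "degenerate")
})

test_that("correlation agrees with a raw-sum oracle on random subjects", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(4:20, 1)
    e <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    if (length(unique(e)) < 2L) e[1:2] <- c(-1L, 1L)
    x <- rnorm(n)
    tab <- make_table(list(s = list(valence = e, f = x)))
    expect_equal(unname(valence_correlation(tab, "s")$rho["f"]),
                 oracle_pearson(x, e), tolerance = 1e-10)
  }
})

test_that("selection thresholding is strict and invariant to affine rescaling", {
  prof <- structure(list(subject_id = "s",
                         rho = c(a = 0.9, b = -0.8, c = 0.3),
                         undefined = c(a = FALSE, b = FALSE, c = FALSE)),
                    class = "emf_corr")
  expect_equal(select_subject_features(prof, 0.7), c(1L, 2L))
  prof$rho <- c(a = 0.7, b = 0, c = 0)
  expect_equal(select_subject_features(prof, 0.7), integer(0))

  # affine rescaling of a feature leaves its selection unchanged
  set.seed(3)
  e <- rep(c(-1L, 0L, 1L), each = 4)
  x <- e + rnorm(12, sd = 0.3)
  t1 <- make_table(list(s = list(valence = e, f = x)))
  t2 <- make_table(list(s = list(valence = e, f = 5 + 2.5 * x)))
  r1 <- valence_correlation(t1, "s")$rho
  r2 <- valence_correlation(t2, "s")$rho
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("union keeps column order, deduplicates and is monotone", {
  fn <- c("f1", "f2", "f3", "f4")
  u <- union_selected_features(list(c(1L, 2L), c(2L, 3L)), fn)
  expect_equal(u$indices, 1:3)
  expect_equal(u$names, c("f1", "f2", "f3"))
  expect_equal(u$n_opt, 3L)

  expect_equal(union_selected_features(list(integer(0)), fn)$n_opt, 0L)
  one <- union_selected_features(list(c(3L, 1L)), fn)
  expect_equal(one$indices, c(1L, 3L))

  # adding a subject never shrinks the union
  base <- union_selected_features(list(c(1L)), fn)$indices
  more <- union_selected_features(list(c(1L), c(4L)), fn)$indices
  expect_true(all(base %in% more))
})

test_that("redundancy pruning keeps the stronger of correlated duplicates", {
  set.seed(7)
  e <- rep(c(-1L, 0L, 1L), each = 5)
  x <- e + rnorm(15, sd = 0.1)
  tab <- make_table(list(s = list(valence = e, A = x, B = x,
                                  C = rnorm(15))))
  cand <- union_selected_features(list(1:3), feature_names(tab))
  pruned <- prune_redundant_features(tab, cand, 0.95)
  expect_equal(pruned$names, c("A", "C"))  # duplicate B dropped, tie -> lower index

  # threshold 1 removes only exact collinearity
  kept_all <- prune_redundant_features(tab, cand, 1)
  expect_equal(kept_all$names, c("A", "C"))
  tabnc <- make_table(list(s = list(valence = e, A = x,
                                    B = x + rnorm(15, sd = 1e-3),
                                    C = rnorm(15))))
  expect_equal(prune_redundant_features(tabnc, cand, 1)$names,
               c("A", "B", "C"))
})

test_that("greedy pruning follows strength order on a constructed triple", {
  # A strongest; |cor|(A,B) high, (A,C) and (B,C) low -> keep {A, C}
  set.seed(21)
  e <- rep(c(-1L, 0L, 1L), each = 10)
  a <- e + rnorm(30, sd = 0.05)
  b <- a + rnorm(30, sd = 0.12)          # highly correlated with A, weaker
  cc <- rnorm(30)                        # near-independent
  tab <- make_table(list(s = list(valence = e, A = a, B = b, C = cc)))
  stopifnot(abs(cor(a, b)) > 0.95, abs(cor(a, cc)) < 0.5)
  cand <- union_selected_features(list(1:3), feature_names(tab))
  pruned <- prune_redundant_features(tab, cand, 0.95)
  expect_equal(pruned$names, c("A", "C"))
})

test_that("cohort selection recovers exactly the signal set on noiseless data", {
  cfg <- cohort_config(n_td = 5, n_nos = 2, n_sli = 2, n_ad = 2,
                       n_signal = 4, n_nuisance = 5,
                       noise_sd = 0, within_group_sd = 0)
  coh <- simulate_cohort(cfg, seed = 13)
  sel <- select_features(coh$table, threshold = 0.7)
  expect_equal(sel$names, sprintf("sig%02d", 1:4))
})
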