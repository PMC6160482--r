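# Programmatic fixtures shared across test files.

# A minimal hand-built table: `subjects` is a named list of lists with
# elements `valence` (vector) and one numeric vector per feature.
make_table <- function(subjects) {
  rows <- lapply(names(subjects), function(s) {
    sub <- subjects[[s]]
    df <- data.frame(subject_id = s, valence = sub$valence,
                     stringsAsFactors = FALSE)
    for (f in setdiff(names(sub), "valence")) df[[f]] <- sub[[f]]
    df
  })
  as_feature_table(do.call(rbind, rows))
}

make_manifest <- function(ids, diagnoses) {
  as_manifest(data.frame(subject_id = ids, diagnosis = diagnoses,
                         stringsAsFactors = FALSE))
}

# A small synthetic cohort for fast end-to-end tests.
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(cohort_config(n_td = 8, n_nos = 2, n_sli = 3, n_ad = 3,
                                utterances_per_valence = c(6, 5, 4),
                                n_signal = 4, n_nuisance = 3, ...),
                  seed = seed)
}

# Random binary-labelled training matrices for oracle-equivalence loops.
random_training <- function(n0 = 6, n1 = 5, nf = 4) {
  D <- matrix(rnorm((n0 + n1) * nf), n0 + n1, nf)
  y <- c(rep(0L, n0), rep(1L, n1))
  D[y == 1L, ] <- D[y == 1L, ] + rnorm(nf)
  list(D = D, y = y)
}
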