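#' Configuration for a synthetic child-speech cohort
#'
#' Defines a cohort whose utterance-level features carry the statistical
#' structure the modulation analysis assumes: each *signal* feature of
#' subject i follows `a_ij * e + b_ij + noise` in the utterance valence
#' `e` in \{-1, 0, +1\}, with subject slopes `a_ij` drawn around a
#' group-specific mean; *nuisance* features are valence-independent noise.
#' Defaults mirror the reference cohort shape: 68 typically developing
#' children and 34 with developmental disorders (10 PDD-NOS, 13 SLI, 11 AD),
#' with 15 negative, 6 neutral and 5 positive utterances per subject
#' (the emotional layout of the story-telling stimulus).
#'
#' Two group-separation modes are available:
#' \describe{
#'   \item{`"shift"`}{(default) the TD mean slope is `slope_mean` for every
#'     signal feature; each disorder subgroup's mean slope is shifted by
#'     `effect_size` with a subgroup-specific sign pattern over features, so
#'     four-class structure exists while binary separation is governed
#'     solely by `effect_size`.}
#'   \item{`"sign_flip"`}{TD slopes centre on `+slope_mean` and all DD slopes
#'     on `-slope_mean`. With a balanced number of utterances per valence
#'     class the per-utterance marginal distribution of every feature is
#'     identical across groups, so only the *modulation* carries the
#'     diagnosis — the construction behind the paradigm-contrast experiment.}
#' }
#'
#' @param n_td,n_nos,n_sli,n_ad Subject counts per diagnostic group.
#' @param utterances_per_valence Integer triple: utterances per subject with
#'   negative, neutral, positive valence.
#' @param n_signal Number of valence-modulated features.
#' @param n_nuisance Number of valence-independent features.
#' @param slope_mean Baseline modulation slope magnitude (signal scale).
#' @param effect_size Group separation of mean slopes (`"shift"` mode).
#' @param within_group_sd SD of subject slopes around their group mean.
#' @param noise_sd SD of additive utterance noise.
#' @param offset_sd SD of subject-specific feature offsets.
#' @param mode Group-separation mode, see Details.
#' @return An object of class `"emf_cohort_config"`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_td = 68L, n_nos = 10L, n_sli = 13L, n_ad = 11L,
                          utterances_per_valence = c(15L, 6L, 5L),
                          n_signal = 19L, n_nuisance = 21L,
                          slope_mean = 1, effect_size = 0.6,
                          within_group_sd = 0.2, noise_sd = 0.1,
                          offset_sd = 1, mode = c("shift", "sign_flip")) {
  mode <- match.arg(mode)
  counts <- c(n_td, n_nos, n_sli, n_ad)
  if (any(counts < 0L)) stop("subject counts must be non-negative")
  if (length(utterances_per_valence) != 3L ||
      any(utterances_per_valence < 1L)) {
    stop("utterances_per_valence must be three positive integers")
  }
  if (n_signal < 1L) stop("n_signal must be at least 1")
  if (n_nuisance < 0L) stop("n_nuisance must be non-negative")
  if (effect_size < 0 || within_group_sd < 0 || noise_sd < 0 || offset_sd < 0) {
    stop("effect_size and all standard deviations must be non-negative")
  }
  structure(list(
    n_td = as.integer(n_td), n_nos = as.integer(n_nos),
    n_sli = as.integer(n_sli), n_ad = as.integer(n_ad),
    utterances_per_valence = as.integer(utterances_per_valence),
    n_signal = as.integer(n_signal), n_nuisance = as.integer(n_nuisance),
    slope_mean = slope_mean, effect_size = effect_size,
    within_group_sd = within_group_sd, noise_sd = noise_sd,
    offset_sd = offset_sd, mode = mode
  ), class = "emf_cohort_config")
}

# Subgroup-specific slope-shift sign patterns over signal features; distinct
# patterns give the three disorder subgroups distinguishable modulation
# profiles while leaving TD unshifted. All three patterns have positive
# mutual correlation (majority +1), so the three disorder modes share a
# half-space around the TD centre and binary TD-vs-DD separation grows
# with the shift magnitude; antipodal patterns would instead place TD at
# the midpoint of two disorder modes and no linear rule could separate the
# classes however large the shift.
group_sign_patterns <- function(n_signal) {
  j <- seq_len(n_signal)
  nos <- rep(1, n_signal)
  sli <- ifelse(j %% 3 == 0, -1, 1)
  ad <- ifelse(j %% 4 == 0, -1, 1)
  list(`TD` = rep(0, n_signal), `PDD-NOS` = nos, `SLI` = sli, `AD` = ad)
}

#' Simulate a synthetic cohort with a planted modulation effect
#'
#' @param config An [cohort_config()] object.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `"emf_cohort"`: a list with `table`
#'   (`emf_table`), `manifest` (`emf_manifest`) and `truth`, the generating
#'   parameters per subject (`slopes`, `offsets` matrices over signal
#'   features) and per group (`group_mean_slopes`).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_td = 4, n_nos = 1, n_sli = 1,
#'                                      n_ad = 1), seed = 1)
#' dim(coh$table)
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "emf_cohort_config"))
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  cfg <- config
  n_sub <- cfg$n_td + cfg$n_nos + cfg$n_sli + cfg$n_ad
  if (n_sub < 1L) stop("cohort has no subjects")
  diagnosis <- rep(DIAGNOSES, times = c(cfg$n_td, cfg$n_nos, cfg$n_sli,
                                        cfg$n_ad))
  ids <- sprintf("s%03d", seq_len(n_sub))

  patterns <- group_sign_patterns(cfg$n_signal)
  group_means <- vapply(DIAGNOSES, function(g) {
    if (cfg$mode == "sign_flip") {
      if (g == "TD") rep(cfg$slope_mean, cfg$n_signal)
      else rep(-cfg$slope_mean, cfg$n_signal)
    } else {
      cfg$slope_mean + cfg$effect_size * patterns[[g]]
    }
  }, numeric(cfg$n_signal))
  # groups x signal features (vapply drops to a vector when n_signal = 1)
  group_means <- t(matrix(group_means, nrow = cfg$n_signal,
                          dimnames = list(NULL, DIAGNOSES)))

  slopes <- matrix(NA_real_, n_sub, cfg$n_signal)
  offsets <- matrix(NA_real_, n_sub, cfg$n_signal)
  for (i in seq_len(n_sub)) {
    m <- group_means[diagnosis[i], ]
    slopes[i, ] <- stats::rnorm(cfg$n_signal, m, cfg$within_group_sd)
    offsets[i, ] <- stats::rnorm(cfg$n_signal, 0, cfg$offset_sd)
  }
  rownames(slopes) <- rownames(offsets) <- ids

  upv <- cfg$utterances_per_valence
  e_subject <- rep(VALENCE_LEVELS, times = upv)
  n_utt <- length(e_subject)
  sig_names <- sprintf("sig%02d", seq_len(cfg$n_signal))
  nui_names <- if (cfg$n_nuisance > 0L) {
    sprintf("nui%02d", seq_len(cfg$n_nuisance))
  } else character(0)

  blocks <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    sig <- outer(e_subject, slopes[i, ]) +
      matrix(offsets[i, ], n_utt, cfg$n_signal, byrow = TRUE) +
      matrix(stats::rnorm(n_utt * cfg$n_signal, 0, cfg$noise_sd),
             n_utt, cfg$n_signal)
    block <- data.frame(subject_id = ids[i], valence = e_subject,
                        stringsAsFactors = FALSE)
    block[sig_names] <- as.data.frame(sig)
    if (cfg$n_nuisance > 0L) {
      block[nui_names] <- as.data.frame(
        matrix(stats::rnorm(n_utt * cfg$n_nuisance), n_utt, cfg$n_nuisance))
    }
    blocks[[i]] <- block
  }
  table <- as_feature_table(do.call(rbind, blocks))
  manifest <- as_manifest(data.frame(subject_id = ids, diagnosis = diagnosis,
                                     stringsAsFactors = FALSE))
  colnames(slopes) <- colnames(offsets) <- sig_names
  colnames(group_means) <- sig_names
  structure(list(
    table = table, manifest = manifest,
    truth = list(diagnosis = stats::setNames(diagnosis, ids),
                 slopes = slopes, offsets = offsets,
                 group_mean_slopes = group_means),
    config = cfg, seed = as.integer(seed)
  ), class = "emf_cohort")
}

#' @export
print.emf_cohort <- function(x, ...) {
  tab <- table(x$manifest$diagnosis)[DIAGNOSES]
  cat("Synthetic cohort: ", nrow(x$manifest), " subjects (",
      paste(DIAGNOSES, as.integer(tab), sep = "=", collapse = ", "), ")\n",
      sep = "")
  cat("  ", nrow(x$table), " utterances, ", x$config$n_signal,
      " signal + ", x$config$n_nuisance, " nuisance features, mode '",
      x$config$mode, "'\n", sep = "")
  invisible(x)
}

#' Randomly permute diagnoses across subjects
#'
#' Preserves the multiset of diagnosis labels; used to build permutation
#' null cohorts in which no subject-level signal can survive.
#'
#' @param manifest An `emf_manifest`.
#' @param seed Integer seed.
#' @return A new `emf_manifest` with permuted `diagnosis`.
#' @export
permute_labels <- function(manifest, seed) {
  stopifnot(inherits(manifest, "emf_manifest"))
  if (nrow(manifest) < 1L) stop("manifest is empty")
  set.seed(as.integer(seed))
  out <- manifest
  out$diagnosis <- sample(manifest$diagnosis)
  out
}
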