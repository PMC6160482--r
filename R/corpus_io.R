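#' Read an utterance-level feature table
#'
#' Reads a CSV file with one row per utterance. The mandatory leading columns
#' are `subject_id` and `valence` (coded -1 = negative, 0 = neutral,
#' +1 = positive); every remaining column is a numeric acoustic feature.
#' Column order of the features is preserved as read.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, `.` decimal,
#'   header mandatory).
#' @return A validated `data.frame` of class `"emf_table"` with columns
#'   `subject_id` (character), `valence` (integer) and one numeric column per
#'   feature.
#' @seealso [write_feature_table()], [read_manifest()], [validate_cohort()]
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_feature_table(df)
}

#' Coerce a data frame to a validated feature table
#'
#' @param df A data frame with columns `subject_id`, `valence`, then one
#'   numeric column per acoustic feature.
#' @return The validated table with class `"emf_table"` prepended.
#' @export
as_feature_table <- function(df) {
  if (!all(c("subject_id", "valence") %in% names(df))) {
    stop("feature table must contain columns 'subject_id' and 'valence'")
  }
  feat_cols <- setdiff(names(df), c("subject_id", "valence"))
  if (length(feat_cols) < 1L) stop("feature table has no feature columns")
  bad_val <- which(!(df$valence %in% VALENCE_LEVELS))
  if (length(bad_val)) {
    stop("invalid valence value '", df$valence[bad_val[1L]],
         "' in row ", bad_val[1L], " (must be -1, 0 or +1)")
  }
  for (fc in feat_cols) {
    v <- df[[fc]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v)) {
        stop("non-numeric value in feature column '", fc, "'")
      }
      v <- vn
      df[[fc]] <- v
    }
    if (!is.numeric(v)) stop("feature column '", fc, "' is not numeric")
    if (anyNA(v)) {
      stop("missing value in feature column '", fc, "', row ",
           which(is.na(v))[1L])
    }
  }
  df$subject_id <- as.character(df$subject_id)
  df$valence <- as.integer(df$valence)
  df <- df[, c("subject_id", "valence", feat_cols)]
  class(df) <- c("emf_table", "data.frame")
  df
}

#' Write an utterance-level feature table to CSV
#'
#' Inverse of [read_feature_table()]; a write/read round trip reproduces the
#' table exactly (numbers are serialized at full double precision).
#'
#' @param table An `emf_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "emf_table"))
  df <- as.data.frame(table)
  feat_cols <- feature_names(table)
  for (fc in feat_cols) df[[fc]] <- format(df[[fc]], digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Feature column names of a table
#' @param table An `emf_table`.
#' @return Character vector of feature column names, in table order.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("subject_id", "valence"))
}

#' Subject identifiers of a table, in order of first appearance
#' @param table An `emf_table`.
#' @return Character vector of unique subject ids.
#' @export
subject_ids <- function(table) unique(table$subject_id)

#' Read a cohort manifest
#'
#' A manifest maps each subject to a diagnosis in
#' `TD`, `PDD-NOS`, `SLI`, `AD`. CSV (columns `subject_id`, `diagnosis`,
#' optional `age`, `sex`) and JSON (object or records) are accepted.
#'
#' @param path Path to a CSV or JSON manifest.
#' @return A `data.frame` of class `"emf_manifest"` with columns
#'   `subject_id` and `diagnosis` (plus any optional columns present).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    if (is.data.frame(obj)) {
      df <- obj
    } else {
      df <- data.frame(subject_id = names(obj),
                       diagnosis = unlist(obj, use.names = FALSE),
                       stringsAsFactors = FALSE)
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  as_manifest(df)
}

#' Coerce a data frame to a validated cohort manifest
#' @param df Data frame with columns `subject_id` and `diagnosis`.
#' @return The manifest with class `"emf_manifest"` prepended.
#' @export
as_manifest <- function(df) {
  if (!all(c("subject_id", "diagnosis") %in% names(df))) {
    stop("manifest must contain columns 'subject_id' and 'diagnosis'")
  }
  df$subject_id <- as.character(df$subject_id)
  df$diagnosis <- as.character(df$diagnosis)
  dup <- duplicated(df$subject_id)
  if (any(dup)) {
    stop("duplicated subject id in manifest: ", df$subject_id[which(dup)[1L]])
  }
  bad <- setdiff(unique(df$diagnosis), DIAGNOSES)
  if (length(bad)) {
    stop("unknown diagnosis label: '", bad[1L], "' (allowed: ",
         paste(DIAGNOSES, collapse = ", "), ")")
  }
  class(df) <- c("emf_manifest", "data.frame")
  df
}

#' Write a cohort manifest to CSV
#' @param manifest An `emf_manifest`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "emf_manifest"))
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Validate a cohort against minimum per-valence utterance counts
#'
#' Skewness and kurtosis of a feature within one valence class are only
#' informative when that class holds enough utterances; subjects falling
#' below `min_per_valence` in any of the three classes are flagged for
#' exclusion from the modulation analysis.
#'
#' @param table An `emf_table`.
#' @param manifest An `emf_manifest` covering every subject in `table`.
#' @param min_per_valence Minimum utterance count required in each valence
#'   class (default 3, the smallest count for which within-class skewness and
#'   kurtosis are generically finite and non-trivial).
#' @return An object of class `"emf_validation"`: a list with `counts`
#'   (subjects x valence classes), `excluded` (data frame of subject id and
#'   reason), `included` (character vector) and `min_per_valence`.
#' @export
validate_cohort <- function(table, manifest, min_per_valence = 3L) {
  stopifnot(inherits(table, "emf_table"), inherits(manifest, "emf_manifest"))
  subs <- subject_ids(table)
  missing_man <- setdiff(subs, manifest$subject_id)
  if (length(missing_man)) {
    stop("subject '", missing_man[1L], "' in feature table is absent from ",
         "the manifest")
  }
  counts <- t(vapply(subs, function(s) {
    v <- table$valence[table$subject_id == s]
    vapply(VALENCE_LEVELS, function(lv) sum(v == lv), integer(1L))
  }, integer(3L)))
  colnames(counts) <- c("-1", "0", "+1")
  reasons <- character(0)
  excluded <- character(0)
  for (i in seq_along(subs)) {
    low <- which(counts[i, ] < min_per_valence)
    if (length(low)) {
      rs <- vapply(low, function(j) {
        if (counts[i, j] == 0L) {
          paste0("empty valence class ", colnames(counts)[j])
        } else {
          paste0("valence class ", colnames(counts)[j], " has ",
                 counts[i, j], " < ", min_per_valence, " utterances")
        }
      }, character(1L))
      excluded <- c(excluded, subs[i])
      reasons <- c(reasons, paste(rs, collapse = "; "))
    }
  }
  structure(list(
    counts = counts,
    excluded = data.frame(subject_id = excluded, reason = reasons,
                          stringsAsFactors = FALSE),
    included = setdiff(subs, excluded),
    min_per_valence = as.integer(min_per_valence)
  ), class = "emf_validation")
}

#' @export
print.emf_validation <- function(x, ...) {
  cat("Cohort validation: ", nrow(x$counts), " subjects, ",
      sum(x$counts), " utterances\n", sep = "")
  cat("  minimum per valence class: ", x$min_per_valence, "\n", sep = "")
  cat("  excluded subjects: ", nrow(x$excluded), "\n", sep = "")
  if (nrow(x$excluded)) {
    for (i in seq_len(nrow(x$excluded))) {
      cat("    ", x$excluded$subject_id[i], ": ", x$excluded$reason[i],
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report An `emf_validation` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "emf_validation"))
  obj <- list(
    min_per_valence = report$min_per_valence,
    counts = as.data.frame(cbind(subject_id = rownames(report$counts),
                                 as.data.frame(report$counts))),
    excluded = report$excluded,
    included = report$included
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
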