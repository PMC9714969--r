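# Data import/export, inclusion filters, packaged species-level summaries.

.SUBJECT_COLS <- c("subject_id", "species", "clade", "sex", "age_class",
                   "left_insertions", "right_insertions", "bouts")
.CLADES <- c("Platyrrhini", "Cercopithecoidea", "Hominoidea")

#' Read subject-level tube-task records
#'
#' Reads a CSV of individual tube-task results. Required columns are
#' `subject_id, species, clade, sex, age_class, left_insertions,
#' right_insertions, bouts`; a `genus` column is optional and is otherwise
#' derived from the first token of the species binomial. Age classes
#' `"infant"` and `"juvenile"` are pooled to `"subadult"` on read, matching
#' the two-category scheme (adult vs. subadult) used in comparative
#' laterality work. Unknown sex and missing age class are permitted but
#' counted in a warning.
#'
#' @param path path to a CSV file with a header row (UTF-8, comma-separated).
#' @return a `data.frame` of subject records, one row per input row, with a
#'   `row` column preserving input row numbers for error reporting.
#' @seealso [filter_subjects()], [write_subjects()]
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("subjects file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(.SUBJECT_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("subjects file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    warning("subjects file contains a header but no records: ", path)
  }
  raw$row <- seq_len(nrow(raw))
  for (col in c("subject_id", "species", "clade", "sex", "age_class")) {
    raw[[col]] <- as.character(raw[[col]])
  }
  for (col in c("left_insertions", "right_insertions", "bouts")) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num != round(num) | num < 0)
    if (length(bad) > 0) {
      stop("non-integer or negative value in column '", col, "' at row ",
           paste(raw$row[bad], collapse = ", "))
    }
    raw[[col]] <- as.integer(num)
  }
  if (any(raw$bouts < 1)) {
    stop("bouts must be >= 1; offending row(s): ",
         paste(raw$row[raw$bouts < 1], collapse = ", "))
  }
  bad_clade <- which(!raw$clade %in% .CLADES)
  if (length(bad_clade) > 0) {
    stop("unknown clade '", raw$clade[bad_clade[1]], "' at row ",
         raw$row[bad_clade[1]], "; expected one of ",
         paste(.CLADES, collapse = ", "))
  }
  # one clade per species
  cl <- unique(raw[, c("species", "clade")])
  dup <- cl$species[duplicated(cl$species)]
  if (length(dup) > 0) {
    stop("inconsistent clade assignment within species: ",
         paste(unique(dup), collapse = ", "))
  }
  raw$age_class <- ifelse(raw$age_class %in% c("infant", "juvenile"),
                          "subadult", raw$age_class)
  bad_age <- !raw$age_class %in% c("adult", "subadult") & nzchar(raw$age_class) &
    !is.na(raw$age_class)
  if (any(bad_age)) {
    stop("unknown age_class '", raw$age_class[which(bad_age)[1]], "' at row ",
         raw$row[which(bad_age)[1]])
  }
  raw$sex <- ifelse(is.na(raw$sex) | !nzchar(raw$sex), "unknown", raw$sex)
  raw$sex <- ifelse(raw$sex %in% c("F", "M"), raw$sex, "unknown")
  n_unk_sex <- sum(raw$sex == "unknown")
  n_na_age <- sum(is.na(raw$age_class) | !nzchar(raw$age_class))
  if (n_unk_sex > 0 || n_na_age > 0) {
    warning(n_unk_sex, " record(s) with unknown sex and ", n_na_age,
            " with missing age class were read (kept, flagged)")
  }
  if (!"genus" %in% names(raw) || all(!nzchar(raw$genus))) {
    raw$genus <- vapply(strsplit(raw$species, " "), `[[`, "", 1L)
  }
  raw[, c("row", "subject_id", "species", "genus", "clade", "sex",
          "age_class", "left_insertions", "right_insertions", "bouts")]
}

#' Write subject records to CSV
#'
#' Canonical dialect: UTF-8, comma separator, header row, no row names.
#' `write_subjects(read_subjects(f))` round-trips all analyzed fields.
#'
#' @param subjects data.frame as returned by [read_subjects()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  cols <- c("subject_id", "species", "genus", "clade", "sex", "age_class",
            "left_insertions", "right_insertions", "bouts")
  utils::write.csv(subjects[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read species-level predictor table
#'
#' Columns: `species, ecology (arboreal|terrestrial), tool_use (0/1 or
#' logical), brain_size_ml` (female endocranial volume in ml, stored raw; the
#' log10 transform is applied downstream, never at read time).
#'
#' @param path path to a CSV file.
#' @return data.frame with columns species, ecology, tool_use, brain_size_ml.
#' @export
read_predictors <- function(path) {
  if (!file.exists(path)) stop("predictor file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("species", "ecology", "tool_use", "brain_size_ml")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop("predictor file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(d$ecology %in% c("arboreal", "terrestrial"))) {
    stop("ecology must be 'arboreal' or 'terrestrial'")
  }
  d$tool_use <- as.logical(d$tool_use)
  if (anyNA(d$tool_use)) stop("tool_use must be coercible to logical")
  d$brain_size_ml <- as.numeric(d$brain_size_ml)
  if (any(!is.finite(d$brain_size_ml)) || any(d$brain_size_ml <= 0)) {
    stop("brain_size_ml must be positive")
  }
  d[, need]
}

#' Apply the tube-task inclusion filter
#'
#' Retains subjects with at least `min_insertions` bimanual insertions
#' (left + right) recorded in at least `min_bouts` bouts. Defaults are the
#' standard thresholds of 30 insertions in 6 bouts; both boundaries are
#' inclusive. The number of excluded records is reported via `message()` and
#' attached as attribute `"excluded"`.
#'
#' @param subjects data.frame of subject records.
#' @param min_insertions minimum total insertions (default 30).
#' @param min_bouts minimum number of bouts (default 6).
#' @return the filtered data.frame, with attribute `excluded` giving counts.
#' @export
filter_subjects <- function(subjects, min_insertions = 30, min_bouts = 6) {
  stopifnot(min_insertions >= 1, min_bouts >= 1)
  total <- subjects$left_insertions + subjects$right_insertions
  keep <- total >= min_insertions & subjects$bouts >= min_bouts
  out <- subjects[keep, , drop = FALSE]
  excl <- c(too_few_insertions = sum(total < min_insertions),
            too_few_bouts = sum(total >= min_insertions &
                                  subjects$bouts < min_bouts))
  message(sum(!keep), " of ", nrow(subjects),
          " subject(s) excluded by the inclusion filter (",
          excl[["too_few_insertions"]], " below ", min_insertions,
          " insertions, ", excl[["too_few_bouts"]], " below ", min_bouts,
          " bouts)")
  attr(out, "excluded") <- excl
  out
}

#' Filter group summaries by minimum sample size
#'
#' @param summaries data.frame of group summaries (from
#'   [summarize_laterality()] or [load_species_summaries()]).
#' @param min_n minimum number of sampled individuals per group (default 15).
#' @return the retained rows.
#' @export
filter_species_min_n <- function(summaries, min_n = 15) {
  stopifnot(min_n >= 1)
  summaries[summaries$n >= min_n, , drop = FALSE]
}

#' Packaged species-level tube-task summaries
#'
#' Loads the packaged transcription of published species-level tube-task
#' laterality summaries for 38 anthropoid species (1786 individuals):
#' category counts of left-handed, right-handed and ambipreferent subjects,
#' MeanHI (direction) and MeanAbsHI (strength), plus the percentage values
#' exactly as printed in the source table (`pct_*` columns; a handful of
#' printed percentages are internally inconsistent with the counts and are
#' kept verbatim for reference - recompute from counts for analysis).
#'
#' An integrity check verifies the packaged file on load: 38 rows, counts
#' summing to each row's n, and a total sample of 1786.
#'
#' @return data.frame with columns species, genus, clade, n, n_left, n_right,
#'   n_ambi, pct_left, pct_right, pct_ambi, mean_hi, mean_abs_hi.
#' @export
load_species_summaries <- function() {
  path <- system.file("extdata", "anthropoid_tube_task_summaries.csv",
                      package = "tubetask", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  ok <- nrow(d) == 38 &&
    all(d$n_left + d$n_right + d$n_ambi == d$n) &&
    sum(d$n) == 1786 &&
    all(d$clade %in% .CLADES)
  if (!ok) stop("packaged summary table failed its integrity check")
  d
}

#' Category percentages recomputed from counts
#'
#' Recomputes left/right/ambipreferent percentages from the category counts
#' of a summary table, rounded to one decimal (round-half-even, the
#' convention that reproduces the printed source values).
#'
#' @param summaries data.frame with n, n_left, n_right, n_ambi.
#' @return data.frame with group id and recomputed pct_left/right/ambi.
#' @export
recompute_percentages <- function(summaries) {
  id <- if ("species" %in% names(summaries)) summaries$species else
    summaries$group_id
  data.frame(group_id = id,
             pct_left = round(100 * summaries$n_left / summaries$n, 1),
             pct_right = round(100 * summaries$n_right / summaries$n, 1),
             pct_ambi = round(100 * summaries$n_ambi / summaries$n, 1),
             stringsAsFactors = FALSE)
}
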