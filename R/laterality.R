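# Individual handedness indices, z classification, group summaries.

#' Handedness index
#'
#' HI = (R - L) / (R + L) over bimanual insertions: -1 means all insertions
#' left-handed, +1 all right-handed. Vectorized.
#'
#' @param right,left non-negative insertion counts; `right + left >= 1`.
#' @return numeric in \[-1, 1\].
#' @export
handedness_index <- function(right, left) {
  if (any(right < 0 | left < 0)) stop("counts must be non-negative")
  n <- right + left
  if (any(n < 1)) stop("handedness index undefined: right + left must be >= 1")
  (right - left) / n
}

#' Binomial z score for individual hand preference
#'
#' Normal approximation to the binomial test of R successes in n = R + L
#' trials against p = 0.5, without continuity correction:
#' z = (R - n/2) / sqrt(n/4). The convention (no continuity correction, ties
#' at the +-1.96 boundary rated ambipreferent) is isolated here.
#'
#' @inheritParams handedness_index
#' @return numeric z score.
#' @export
binomial_z <- function(right, left) {
  if (any(right < 0 | left < 0)) stop("counts must be non-negative")
  n <- right + left
  if (any(n < 1)) stop("z score undefined: right + left must be >= 1")
  (right - n / 2) / sqrt(n / 4)
}

#' Classify hand preference from a z score
#'
#' Subjects with z > `cutoff` are right-handed, z < -`cutoff` left-handed,
#' and all others (boundary values included) ambipreferent.
#'
#' @param z numeric vector of finite z scores.
#' @param cutoff positive classification threshold (default 1.96).
#' @return character vector: "left", "right" or "ambipreferent".
#' @export
classify_handedness <- function(z, cutoff = 1.96) {
  if (any(!is.finite(z))) stop("z must be finite")
  ifelse(z > cutoff, "right", ifelse(z < -cutoff, "left", "ambipreferent"))
}

#' Per-subject laterality table
#'
#' Computes HI, |HI|, binomial z and the hand preference category for every
#' subject record.
#'
#' @param subjects data.frame of subject records (see [read_subjects()]).
#' @param cutoff z classification threshold (default 1.96).
#' @return data.frame with subject metadata plus hi, abs_hi, z, category.
#' @export
subject_laterality <- function(subjects, cutoff = 1.96) {
  hi <- handedness_index(subjects$right_insertions, subjects$left_insertions)
  z <- binomial_z(subjects$right_insertions, subjects$left_insertions)
  out <- subjects[, intersect(c("subject_id", "species", "genus", "clade",
                                "sex", "age_class"), names(subjects)),
                  drop = FALSE]
  out$hi <- hi
  out$abs_hi <- abs(hi)
  out$z <- z
  out$category <- classify_handedness(z, cutoff)
  out
}

#' Group-level laterality summaries
#'
#' Summarizes per-subject laterality at species or genus level: sample size,
#' category counts, MeanHI (unweighted mean of subject HIs; direction) and
#' MeanAbsHI (unweighted mean of |HI|; strength). Genus summaries pool
#' subjects across the genus's species rather than averaging species means.
#'
#' @param lat per-subject laterality table from [subject_laterality()].
#' @param by `"species"` or `"genus"`.
#' @return data.frame with group_id, clade, n, n_left, n_right, n_ambi,
#'   mean_hi, mean_abs_hi.
#' @export
summarize_laterality <- function(lat, by = c("species", "genus")) {
  by <- match.arg(by)
  if (nrow(lat) == 0) stop("no records to summarize")
  key <- lat[[by]]
  groups <- split(lat, key)
  rows <- lapply(groups, function(g) {
    data.frame(group_id = g[[by]][1],
               clade = g$clade[1],
               n = nrow(g),
               n_left = sum(g$category == "left"),
               n_right = sum(g$category == "right"),
               n_ambi = sum(g$category == "ambipreferent"),
               mean_hi = mean(g$hi),
               mean_abs_hi = mean(g$abs_hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group_id), , drop = FALSE]
}
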