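# Population-level tests: one-sample t on HIs, chi-square goodness-of-fit
# against clade-specific baselines, Bonferroni correction.

#' One-sample t-test of lateralization direction
#'
#' Two-sided t-test of whether the mean HI of a group differs from 0.
#'
#' @param his numeric vector of individual HI values (length >= 2, nonzero
#'   variance).
#' @return list with statistic, df, p.
#' @export
hi_t_test <- function(his) {
  if (length(his) < 2) stop("at least two HI values required")
  if (stats::sd(his) == 0) stop("degenerate sample: zero variance in HI")
  tt <- stats::t.test(his, mu = 0)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Clade-specific baseline distribution of hand preference categories
#'
#' Computes the expected proportions of left-handed, right-handed and
#' ambipreferent individuals for one clade from species summaries: the
#' ambipreferent proportion is estimated from the clade's data and the
#' remaining "handed" mass is split equally between left and right.
#' Humans are excluded from the baseline by default because their extreme
#' right-hand bias would skew it.
#'
#' With `weights = "individual"` (default) the ambipreferent proportion pools
#' individuals across the clade's species (this reproduces the published
#' goodness-of-fit p-values); `weights = "species"` takes an unweighted mean
#' of species-level proportions instead.
#'
#' @param summaries species-level summary data.frame (columns clade or
#'   group_id/species, n, n_ambi).
#' @param clade one of "Platyrrhini", "Cercopithecoidea", "Hominoidea".
#' @param exclude species excluded from the baseline (default Homo sapiens).
#' @param weights pooling rule, "individual" or "species".
#' @return list with clade, p_ambi, p_left, p_right, weights, n_species.
#' @export
clade_baseline <- function(summaries, clade,
                           exclude = "Homo sapiens",
                           weights = c("individual", "species")) {
  weights <- match.arg(weights)
  id <- if ("species" %in% names(summaries)) summaries$species else
    summaries$group_id
  s <- summaries[summaries$clade == clade & !(id %in% exclude), , drop = FALSE]
  if (nrow(s) == 0) stop("no species available for clade baseline: ", clade)
  p_ambi <- if (weights == "individual") {
    sum(s$n_ambi) / sum(s$n)
  } else {
    mean(s$n_ambi / s$n)
  }
  p_hand <- (1 - p_ambi) / 2
  list(clade = clade, p_ambi = p_ambi, p_left = p_hand, p_right = p_hand,
       weights = weights, n_species = nrow(s))
}

#' Chi-square goodness-of-fit test against a clade baseline
#'
#' Pearson chi-square of the observed (left, right, ambipreferent) counts
#' against expected counts N * (p_left, p_right, p_ambi), df = 2.
#'
#' @param n_left,n_right,n_ambi observed category counts.
#' @param baseline a baseline as returned by [clade_baseline()].
#' @return list with statistic, df, p, expected.
#' @export
gof_chi_square <- function(n_left, n_right, n_ambi, baseline) {
  obs <- c(left = n_left, right = n_right, ambi = n_ambi)
  n <- sum(obs)
  if (n < 1) stop("no observations")
  p <- c(baseline$p_left, baseline$p_right, baseline$p_ambi)
  if (any(p == 0 & obs > 0)) {
    stop("expected count of zero with positive observed count")
  }
  expd <- n * p
  keep <- expd > 0
  stat <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  list(statistic = stat, df = 2,
       p = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       expected = expd)
}

#' Bonferroni correction
#'
#' @param p raw p-value(s) in \[0, 1\].
#' @param m family size (number of tests), >= 1.
#' @return min(1, p * m), vectorized over p.
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1))
  pmin(1, p * m)
}

#' Population-level test battery
#'
#' For each species or genus, runs (a) the two-sided one-sample t-test of
#' MeanHI against zero (direction) and (b) the chi-square goodness-of-fit
#' test of the left/right/ambipreferent counts against the clade-specific
#' baseline (distribution). Raw p-values are Bonferroni-corrected with family
#' size equal to the number of groups at the chosen level. Groups below
#' `min_n` are flagged `below_min_n`; their t-test is still reported when
#' `include_below_min = TRUE` (the published table prints direction p even
#' for small samples) but can be restricted to qualifying groups.
#'
#' @param lat per-subject laterality table from [subject_laterality()].
#' @param level "species" or "genus".
#' @param min_n minimum group size for the direction test (default 15).
#' @param alpha significance level (default 0.05).
#' @param exclude_from_baseline species never used for baselines (default
#'   Homo sapiens).
#' @param baseline_weights pooling rule for [clade_baseline()].
#' @param include_below_min also run the t-test on groups with n < min_n,
#'   flagged (default TRUE).
#' @return data.frame, one row per group and test, with statistic, df, p,
#'   p_bonferroni, significance flags, family size and below_min_n flag.
#' @export
run_population_battery <- function(lat, level = c("species", "genus"),
                                   min_n = 15, alpha = 0.05,
                                   exclude_from_baseline = "Homo sapiens",
                                   baseline_weights = "individual",
                                   include_below_min = TRUE) {
  level <- match.arg(level)
  summ <- summarize_laterality(lat, by = level)
  species_summ <- summarize_laterality(lat, by = "species")
  baselines <- lapply(unique(summ$clade), function(cl) {
    clade_baseline(species_summ, cl, exclude = exclude_from_baseline,
                   weights = baseline_weights)
  })
  names(baselines) <- unique(summ$clade)
  m <- nrow(summ)
  groups <- split(lat, lat[[level]])
  rows <- list()
  for (i in seq_len(nrow(summ))) {
    g <- summ[i, ]
    if (g$n < min_n && !include_below_min) next
    his <- groups[[g$group_id]]$hi
    if (length(his) >= 2 && stats::sd(his) > 0) {
      tt <- hi_t_test(his)
      rows[[length(rows) + 1]] <- data.frame(
        group_id = g$group_id, level = level, test = "t_direction",
        statistic = tt$statistic, df = tt$df, p = tt$p,
        below_min_n = g$n < min_n, stringsAsFactors = FALSE)
    }
    gf <- gof_chi_square(g$n_left, g$n_right, g$n_ambi,
                         baselines[[g$clade]])
    rows[[length(rows) + 1]] <- data.frame(
      group_id = g$group_id, level = level, test = "gof_distribution",
      statistic = gf$statistic, df = gf$df, p = gf$p,
      below_min_n = g$n < min_n, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(group_id = character(0), level = character(0),
                      test = character(0), statistic = numeric(0),
                      df = numeric(0), p = numeric(0),
                      below_min_n = logical(0), family_size = numeric(0),
                      p_bonferroni = numeric(0), significant_raw = logical(0),
                      significant_corrected = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$family_size <- m
  out$p_bonferroni <- bonferroni_adjust(out$p, m)
  out$significant_raw <- out$p < alpha
  out$significant_corrected <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}

#' Goodness-of-fit battery on a summary table
#'
#' Variant of the distribution test that runs directly on species-level
#' category counts (e.g. the packaged summary table), without subject-level
#' records.
#'
#' @inheritParams run_population_battery
#' @param summaries summary data.frame with species, clade, n, n_left,
#'   n_right, n_ambi columns.
#' @return data.frame with one gof test per row.
#' @export
gof_battery <- function(summaries, alpha = 0.05,
                        exclude_from_baseline = "Homo sapiens",
                        baseline_weights = "individual") {
  id <- if ("species" %in% names(summaries)) summaries$species else
    summaries$group_id
  baselines <- lapply(unique(summaries$clade), function(cl) {
    clade_baseline(summaries, cl, exclude = exclude_from_baseline,
                   weights = baseline_weights)
  })
  names(baselines) <- unique(summaries$clade)
  m <- nrow(summaries)
  res <- lapply(seq_len(nrow(summaries)), function(i) {
    g <- summaries[i, ]
    gf <- gof_chi_square(g$n_left, g$n_right, g$n_ambi, baselines[[g$clade]])
    data.frame(group_id = id[i], test = "gof_distribution",
               statistic = gf$statistic, df = gf$df, p = gf$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$family_size <- m
  out$p_bonferroni <- bonferroni_adjust(out$p, m)
  out$significant_raw <- out$p < alpha
  out$significant_corrected <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}
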