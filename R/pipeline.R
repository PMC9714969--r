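# End-to-end orchestration: fixed stage order, plain CSV/JSON artifacts,
# manifest with config hash.

#' Pipeline configuration
#'
#' Bundles every analysis-relevant option with the standard defaults:
#' 30-insertion / 6-bout inclusion, 15-individual minimum for species-level
#' tests, alpha = 0.05, z cutoff 1.96, individual-pooled clade baselines
#' with humans excluded.
#'
#' @param min_insertions,min_bouts inclusion filter thresholds.
#' @param min_species_n minimum group size for direction tests and the
#'   direction PGLS analysis.
#' @param alpha significance level.
#' @param cutoff z classification threshold.
#' @param baseline_weights clade baseline pooling ("individual" or "species").
#' @param exclude_from_baseline species excluded from clade baselines.
#' @param run_bayes fit the Bayesian multilevel models (slowest stage).
#' @param mcmc an [mcmc_config()] for the Bayesian stage.
#' @param seed seed for any stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_insertions = 30, min_bouts = 6,
                       min_species_n = 15, alpha = 0.05, cutoff = 1.96,
                       baseline_weights = "individual",
                       exclude_from_baseline = "Homo sapiens",
                       run_bayes = FALSE, mcmc = mcmc_config(), seed = 1) {
  structure(list(min_insertions = min_insertions, min_bouts = min_bouts,
                 min_species_n = min_species_n, alpha = alpha,
                 cutoff = cutoff, baseline_weights = baseline_weights,
                 exclude_from_baseline = exclude_from_baseline,
                 run_bayes = run_bayes, mcmc = mcmc, seed = seed),
            class = "run_config")
}

.fmt_pct <- function(x) sub("\\.0$", "", formatC(round(x, 1), format = "f",
                                                 digits = 1))

#' Format a publication-style summary table
#'
#' Combines group summaries and test results into a display table: counts
#' with percentages, MeanHI, MeanAbsHI, direction and distribution p-values,
#' with significance marked ("." raw, "*" surviving Bonferroni). Genus
#' columns (pooled subject counts and genus-level p-values) are attached when
#' genus summaries and tests are supplied.
#'
#' @param summaries species-level summaries.
#' @param tests species-level battery results ([run_population_battery()] or
#'   [gof_battery()]).
#' @param genus_summaries,genus_tests optional genus-level counterparts.
#' @param genus_of named vector mapping species to genus (required for genus
#'   columns; defaults to the first token of the species name).
#' @return data.frame, one row per species.
#' @export
make_table1 <- function(summaries, tests, genus_summaries = NULL,
                        genus_tests = NULL, genus_of = NULL) {
  id <- if ("species" %in% names(summaries)) summaries$species else
    summaries$group_id
  if (nrow(summaries) > 0 && !all(id %in% tests$group_id)) {
    stop("summary and test tables cover different groups")
  }
  fmt_count <- function(k, n) {
    if (length(k) == 0) return(character(0))
    paste0(k, " (", .fmt_pct(100 * k / n), ")")
  }
  if (nrow(summaries) == 0) {
    return(data.frame(species = character(0), n = integer(0),
                      left = character(0), right = character(0),
                      ambipreferent = character(0), mean_hi = numeric(0),
                      mean_abs_hi = numeric(0), p_direction = numeric(0),
                      star_direction = character(0),
                      p_distribution = numeric(0),
                      star_distribution = character(0)))
  }
  pick <- function(tt, g, test) {
    r <- tt[tt$group_id == g & tt$test == test, ]
    if (nrow(r) == 0) return(c(NA, NA))
    c(r$p[1], r$significant_corrected[1])
  }
  out <- data.frame(species = id, n = summaries$n,
                    left = fmt_count(summaries$n_left, summaries$n),
                    right = fmt_count(summaries$n_right, summaries$n),
                    ambipreferent = fmt_count(summaries$n_ambi, summaries$n),
                    mean_hi = round(summaries$mean_hi, 3),
                    mean_abs_hi = round(summaries$mean_abs_hi, 3),
                    stringsAsFactors = FALSE)
  dirp <- t(vapply(id, pick, numeric(2), tt = tests, test = "t_direction"))
  gofp <- t(vapply(id, pick, numeric(2), tt = tests,
                   test = "gof_distribution"))
  out$p_direction <- round(dirp[, 1], 3)
  out$star_direction <- ifelse(is.na(dirp[, 2]), "", ifelse(dirp[, 2] == 1, "*", ""))
  out$p_distribution <- round(gofp[, 1], 3)
  out$star_distribution <- ifelse(is.na(gofp[, 2]), "", ifelse(gofp[, 2] == 1, "*", ""))
  if (!is.null(genus_summaries) && !is.null(genus_tests)) {
    if (is.null(genus_of)) {
      genus_of <- stats::setNames(vapply(strsplit(id, " "), `[[`, "", 1L), id)
    }
    gid <- genus_summaries$group_id
    gi <- match(unname(genus_of[id]), gid)
    out$genus <- unname(genus_of[id])
    out$n_genus <- genus_summaries$n[gi]
    gdir <- t(vapply(gid, pick, numeric(2), tt = genus_tests,
                     test = "t_direction"))
    ggof <- t(vapply(gid, pick, numeric(2), tt = genus_tests,
                     test = "gof_distribution"))
    out$p_direction_genus <- round(gdir[gi, 1], 3)
    out$p_distribution_genus <- round(ggof[gi, 1], 3)
  }
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: inclusion filtering, per-subject laterality,
#' species and genus summaries, the population test battery, the formatted
#' summary table, phylogenetic signal fits (lambda + LRT) and Brownian-motion
#' ancestral states for MeanHI and MeanAbsHI, the three PGLS multi-model
#' analyses and (optionally) the Bayesian multilevel models. Artifacts are
#' written as CSV/JSON under `out_dir` and linked in `manifest.json` together
#' with a hash of the configuration and the seed; the returned list carries
#' the same objects.
#'
#' Phylogenetic and regression stages are skipped (with a note in the
#' manifest) when `tree` or `predictors` is NULL.
#'
#' @param subjects subject records data.frame or path to a subjects CSV.
#' @param predictors optional predictor data.frame or CSV path.
#' @param tree optional `ape::phylo` tree or Newick file path.
#' @param out_dir output directory (created if missing).
#' @param config a [run_config()].
#' @return invisibly, a list with all stage results plus the manifest.
#' @export
run_all <- function(subjects, predictors = NULL, tree = NULL,
                    out_dir = tempfile("tubetask_run_"),
                    config = run_config()) {
  if (is.character(subjects)) subjects <- read_subjects(subjects)
  if (is.character(predictors)) predictors <- read_predictors(predictors)
  if (is.character(tree)) tree <- parse_newick(file = tree)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  artifacts <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    artifacts[[length(artifacts) + 1]] <<- name
    path
  }
  n_read <- nrow(subjects)
  kept <- filter_subjects(subjects, config$min_insertions, config$min_bouts)
  lat <- subject_laterality(kept, cutoff = config$cutoff)
  emit(lat, "subject_laterality.csv")
  species_summ <- summarize_laterality(lat, by = "species")
  genus_summ <- summarize_laterality(lat, by = "genus")
  emit(species_summ, "species_summary.csv")
  emit(genus_summ, "genus_summary.csv")
  battery_sp <- run_population_battery(
    lat, "species", min_n = config$min_species_n, alpha = config$alpha,
    exclude_from_baseline = config$exclude_from_baseline,
    baseline_weights = config$baseline_weights)
  battery_gen <- run_population_battery(
    lat, "genus", min_n = config$min_species_n, alpha = config$alpha,
    exclude_from_baseline = config$exclude_from_baseline,
    baseline_weights = config$baseline_weights)
  emit(rbind(battery_sp, battery_gen), "population_tests.csv")
  genus_of <- stats::setNames(kept$genus, kept$species)
  tab1 <- make_table1(species_summ, battery_sp, genus_summ, battery_gen,
                      genus_of = genus_of[!duplicated(names(genus_of))])
  emit(tab1, "summary_table.csv")
  out <- list(subjects_read = n_read, subjects_analyzed = nrow(kept),
              laterality = lat, species_summary = species_summ,
              genus_summary = genus_summ,
              tests = rbind(battery_sp, battery_gen), table1 = tab1)
  if (!is.null(tree)) {
    usable <- species_summ$group_id %in% tree$tip.label
    dir_trait <- stats::setNames(species_summ$mean_hi,
                                 species_summ$group_id)[usable]
    str_trait <- stats::setNames(species_summ$mean_abs_hi,
                                 species_summ$group_id)[usable]
    sig <- list(direction = fit_lambda(dir_trait, tree),
                strength = fit_lambda(str_trait, tree))
    out$signal <- sig
    sig_df <- data.frame(
      trait = names(sig),
      lambda = vapply(sig, function(f) f$lambda_hat, numeric(1)),
      loglik = vapply(sig, function(f) f$loglik, numeric(1)),
      lrt_stat = vapply(sig, function(f) f$lrt_stat, numeric(1)),
      p = vapply(sig, function(f) f$p, numeric(1)))
    emit(sig_df, "phylogenetic_signal.csv")
    asr_dir <- asr_bm(dir_trait, tree)
    asr_str <- asr_bm(str_trait, tree)
    asr_dir$trait <- "direction"
    asr_str$trait <- "strength"
    out$asr <- rbind(asr_dir, asr_str)
    emit(out$asr, "ancestral_states.csv")
    if (!is.null(predictors)) {
      suite <- run_model_suite(species_summ, predictors, tree,
                               min_n = config$min_species_n)
      out$pgls <- suite
      for (nm in names(suite)) {
        emit(suite[[nm]]$selection$table, paste0("pgls_", nm, "_models.csv"))
        emit(suite[[nm]]$average, paste0("pgls_", nm, "_coefficients.csv"))
      }
    }
    if (config$run_bayes) {
      bd <- build_bayes_dataset(lat, scope = "all")
      bayes <- list(
        direction = sample_posterior(bd, tree, "hi", config$mcmc),
        strength = sample_posterior(bd, tree, "abs_hi", config$mcmc))
      out$bayes <- bayes
      bs <- rbind(cbind(response = "hi", bayes$direction$summary),
                  cbind(response = "abs_hi", bayes$strength$summary))
      emit(bs, "bayes_summary.csv")
    }
  }
  manifest <- list(
    artifacts = artifacts,
    config_hash = rlang::hash(config),
    seed = config$seed,
    subjects_read = n_read,
    subjects_analyzed = nrow(kept),
    subjects_excluded = n_read - nrow(kept),
    stages_skipped = c(if (is.null(tree)) "phylogenetic",
                       if (is.null(predictors)) "pgls",
                       if (!config$run_bayes) "bayes"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  out$out_dir <- out_dir
  invisible(out)
}
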