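bayes_toy <- function(seed = 1, n_species = 12, n_ind = c(20, 20),
                      beta_age_strength = 0, beta_sex_strength = 0) {
  study <- generate_study(sim_config(
    seed = seed, n_species = n_species, n_ind = n_ind,
    beta_age_strength = beta_age_strength,
    beta_sex_strength = beta_sex_strength))
  lat <- subject_laterality(study$subjects)
  list(table = build_bayes_dataset(lat, exclude_species = character(0)),
       tree = study$tree)
}

test_that("model table applies the standard exclusions and scope", {
  lat <- data.frame(
    species = c("Homo sapiens", "Pan troglodytes", "Macaca tonkeana",
                "Pan paniscus", "Pan paniscus", "Ateles geoffroyi"),
    clade = c("Hominoidea", "Hominoidea", "Cercopithecoidea",
              "Hominoidea", "Hominoidea", "Platyrrhini"),
    sex = c("M", "F", "M", "unknown", "F", "M"),
    age_class = c("adult", "adult", "adult", "adult", "subadult", "adult"),
    hi = c(0.9, 0.2, -0.1, 0.3, -0.4, 0.1),
    abs_hi = c(0.9, 0.2, 0.1, 0.3, 0.4, 0.1))
  d <- build_bayes_dataset(lat, scope = "all")
  # humans, chimpanzees, Tonkean macaques and the unsexed bonobo are gone
  expect_setequal(d$species, c("Pan paniscus", "Ateles geoffroyi"))
  expect_equal(nrow(d), 2)
  expect_equal(d$age_subadult[d$species == "Pan paniscus"], 1)
  dh <- build_bayes_dataset(lat, scope = "Hominoidea")
  expect_equal(dh$species, "Pan paniscus")
  expect_error(build_bayes_dataset(lat[1, ], scope = "all"), "no subjects")
})

test_that("posterior sampling is deterministic under a fixed seed", {
  toy <- bayes_toy(seed = 7)
  cfg <- mcmc_config(chains = 2, iter = 400, warmup = 200, seed = 5)
  p1 <- sample_posterior(toy$table, toy$tree, "abs_hi", cfg)
  p2 <- sample_posterior(toy$table, toy$tree, "abs_hi", cfg)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$summary, p2$summary)
  # and summaries are invariant under chain relabeling
  perm <- p1$draws[, c(2, 1), , drop = FALSE]
  expect_equal(mean(perm[, , "b_age_subadult"]),
               mean(p1$draws[, , "b_age_subadult"]))
})

test_that("with the species effect disabled the posterior matches flat-prior regression", {
  toy <- bayes_toy(seed = 13)
  cfg <- mcmc_config(chains = 2, iter = 1500, warmup = 500, seed = 2)
  p0 <- sample_posterior(toy$table, toy$tree, "abs_hi", cfg,
                         fix_sigma_species = 0)
  X <- cbind(1, toy$table$age_subadult, toy$table$sex_male)
  ols <- qr.coef(qr(X), toy$table$abs_hi)
  post_means <- p0$summary$mean[match(
    c("b_Intercept", "b_age_subadult", "b_sex_male"), p0$summary$parameter)]
  # flat-prior posterior mean of slopes equals OLS up to Monte Carlo error
  se <- p0$summary$sd[1:3] / sqrt(p0$summary$ess[1:3])
  expect_true(all(abs(post_means - unname(ols)) < 5 * se + 1e-3))
})

test_that("species SD concentrates near zero for iid data on a star tree", {
  star <- ape::stree(15, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  set.seed(3)
  tab <- data.frame(species = rep(star$tip.label, each = 25),
                    hi = rnorm(375, 0, 0.3), abs_hi = abs(rnorm(375, 0, 0.3)),
                    age_subadult = rbinom(375, 1, 0.4),
                    sex_male = rbinom(375, 1, 0.5))
  p <- sample_posterior(tab, star, "hi",
                        mcmc_config(chains = 2, iter = 1200, warmup = 400,
                                    seed = 4))
  s <- p$summary
  expect_lt(s$mean[s$parameter == "sigma_species"],
            s$mean[s$parameter == "sigma_resid"] / 2)
})

test_that("effect summaries flag intervals that exclude zero", {
  toy <- bayes_toy(seed = 23, beta_age_strength = -0.15)
  cfg <- mcmc_config(chains = 2, iter = 1000, warmup = 400, seed = 6)
  p <- sample_posterior(toy$table, toy$tree, "abs_hi", cfg)
  eff <- summarize_effect(p, "b_age_subadult")
  expect_lt(eff$upper, 0)  # injected negative age effect is recovered
  expect_true(eff$notable)
  expect_identical(eff$notable, eff$lower > 0 || eff$upper < 0)
  sx <- summarize_effect(p, "b_sex_male")
  expect_identical(sx$notable, sx$lower > 0 || sx$upper < 0)
  expect_error(summarize_effect(p, "b_nonexistent"), "unknown parameter")
})
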