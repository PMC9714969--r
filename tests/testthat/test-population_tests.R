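test_that("one-sample t-test of direction matches the closed form", {
  sym <- hi_t_test(c(-0.4, 0.4, -0.2, 0.2))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p, 1)

  x <- c(0.2, 0.4, 0.6, 0.8)
  tt <- hi_t_test(x)
  t_oracle <- mean(x) / (sd(x) / sqrt(4))
  expect_equal(tt$statistic, t_oracle)
  expect_equal(tt$df, 3)
  expect_equal(tt$p, 2 * pt(-abs(t_oracle), 3))
  expect_equal(round(tt$statistic, 3), 3.873)
  expect_equal(round(tt$p, 4), 0.0305)

  expect_error(hi_t_test(c(0.5, 0.5, 0.5)), "degenerate")
  expect_error(hi_t_test(0.2), "two")
})

test_that("clade baseline splits the handed mass equally", {
  s <- data.frame(species = c("A a", "B b", "C c"), clade = "Platyrrhini",
                  n = c(10, 10, 10), n_left = c(4, 3, 3),
                  n_right = c(4, 4, 3), n_ambi = c(2, 3, 4))
  b <- clade_baseline(s, "Platyrrhini", exclude = character(0),
                      weights = "species")
  expect_equal(b$p_ambi, 0.3)
  expect_equal(b$p_left, 0.35)
  expect_equal(b$p_right, 0.35)
  # equal n: individual pooling coincides with the species mean
  bi <- clade_baseline(s, "Platyrrhini", exclude = character(0))
  expect_equal(bi$p_ambi, 0.3)
  # single-species clade returns its own frequencies
  b1 <- clade_baseline(s[1, ], "Platyrrhini", exclude = character(0))
  expect_equal(b1$p_ambi, 0.2)
  expect_error(clade_baseline(s, "Hominoidea"), "no species")
})

test_that("goodness-of-fit chi-square matches the Pearson formula", {
  uniform <- list(p_left = 1 / 3, p_right = 1 / 3, p_ambi = 1 / 3)
  g0 <- gof_chi_square(10, 10, 10, uniform)
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p, 1)
  expect_equal(g0$df, 2)

  b <- list(p_left = 0.45, p_right = 0.45, p_ambi = 0.10)
  g <- gof_chi_square(0, 0, 5, b)
  oracle <- sum((c(0, 0, 5) - 5 * c(0.45, 0.45, 0.10))^2 /
                  (5 * c(0.45, 0.45, 0.10)))
  expect_equal(g$statistic, oracle)
  expect_lt(g$p, 0.05)

  # swapping left and right leaves the statistic unchanged when p_l = p_r
  expect_equal(gof_chi_square(12, 4, 9, b)$statistic,
               gof_chi_square(4, 12, 9, b)$statistic)
  # relabeling categories together with the baseline is invariant
  b2 <- list(p_left = 0.10, p_right = 0.45, p_ambi = 0.45)
  expect_equal(gof_chi_square(9, 12, 4, b2)$statistic,
               gof_chi_square(12, 4, 9, b)$statistic)
  expect_error(gof_chi_square(1, 1, 1, list(p_left = 0.5, p_right = 0.5,
                                            p_ambi = 0)),
               "zero")
})

test_that("Bonferroni correction caps at one and reproduces the starring threshold", {
  expect_equal(bonferroni_adjust(0.001, 38), 0.038)
  expect_equal(bonferroni_adjust(0.04, 38), 1)
  # at alpha = 0.05 with 38 species: p = 0.001 stays significant, 0.006 does not
  expect_lt(bonferroni_adjust(0.001, 38), 0.05)
  expect_gt(bonferroni_adjust(0.006, 38), 0.05)
  expect_equal(bonferroni_adjust(c(0, 1), 5), c(0, 1))
})

test_that("population battery gates on group size and reports both tests", {
  set.seed(11)
  coh <- rbind(null_cohort(30, p = 0.5, species = "Testus unus"),
               null_cohort(10, p = 0.5, species = "Testus duo"))
  coh$subject_id <- sprintf("s%03d", seq_len(nrow(coh)))
  lat <- subject_laterality(coh)
  res <- run_population_battery(lat, "species", min_n = 15,
                                exclude_from_baseline = character(0))
  expect_setequal(res$test, c("t_direction", "gof_distribution"))
  expect_true(all(res$below_min_n[res$group_id == "Testus duo"]))
  expect_equal(unique(res$family_size), 2)
  expect_equal(res$p_bonferroni, pmin(1, res$p * 2))
  # a huge threshold without the below-minimum override empties the battery
  res0 <- run_population_battery(lat, "species", min_n = 1000,
                                 include_below_min = FALSE,
                                 exclude_from_baseline = character(0))
  expect_equal(nrow(res0), 0)
})

test_that("direction t-test holds its type-I error on null cohorts", {
  set.seed(19)
  n_rep <- 500
  p_vals <- replicate(n_rep, {
    r <- rbinom(20, 60, 0.5)
    hi_t_test(handedness_index(r, 60 - r))$p
  })
  hits <- sum(p_vals < 0.05)
  env <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(hits, env[1])
  expect_lte(hits, env[2])
})
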