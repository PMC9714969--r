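test_that("simulated trees are ultrametric, reproducible pure-birth trees", {
  tr <- simulate_tree(38, seed = 1)
  expect_length(tr$tip.label, 38)
  d <- ape::node.depth.edgelength(tr)[1:38]
  expect_lt(max(d) - min(d), 1e-9)
  expect_equal(max(d), 1)
  expect_identical(write_newick(simulate_tree(20, seed = 9)),
                   write_newick(simulate_tree(20, seed = 9)))
  t2 <- simulate_tree(2, seed = 3)
  expect_length(t2$tip.label, 2)
  expect_error(simulate_tree(1), "2 tips")
})

test_that("species effects honor the lambda / sigma2 contract", {
  tr <- simulate_tree(12, seed = 11)
  z <- simulate_species_effects(tr, 1, 0, seed = 12)
  expect_equal(unname(z), rep(0, 12))
  expect_error(simulate_species_effects(tr, 1.5, 1), "0, 1")
  expect_error(simulate_species_effects(tr, 0.5, -1), "non-negative")

  # under lambda = 1 closely related pairs correlate more than distant ones
  C <- phylo_vcv(tr)
  off <- which(upper.tri(C), arr.ind = TRUE)
  close_pair <- off[which.max(C[off]), ]
  far_pair <- off[which.min(C[off]), ]
  set.seed(13)
  draws <- replicate(400, unname(
    simulate_species_effects(tr, 1, 1)[c(close_pair, far_pair)]))
  r_close <- cor(draws[1, ], draws[2, ])
  r_far <- cor(draws[3, ], draws[4, ])
  expect_gt(r_close, r_far + 0.2)

  # under lambda = 0 cross-species correlation vanishes
  set.seed(14)
  draws0 <- replicate(400, unname(
    simulate_species_effects(tr, 0, 1)[close_pair]))
  expect_lt(abs(cor(draws0[1, ], draws0[2, ])), 0.15)
})

test_that("individual records respect the insertion range and the inclusion filter", {
  study <- generate_study(sim_config(seed = 21, n_species = 15))
  ins <- study$subjects$left_insertions + study$subjects$right_insertions
  expect_true(all(ins >= 30 & ins <= 155))
  expect_true(all(study$subjects$bouts >= 6))
  expect_message(kept <- filter_subjects(study$subjects), "0 of")
  expect_equal(nrow(kept), nrow(study$subjects))
  # the skewed insertion option stays within the configured range
  skew <- generate_study(sim_config(seed = 22, n_species = 8,
                                    insertion_dist = "nbinom"))
  ins2 <- skew$subjects$left_insertions + skew$subjects$right_insertions
  expect_true(all(ins2 >= 30 & ins2 <= 155))
})

test_that("neutral cohorts are unlateralized and strength maps to MeanAbsHI", {
  cfg0 <- sim_config(seed = 31, n_species = 20, n_ind = c(40, 40),
                     sigma_direction = 0, sigma_strength = 0)
  study <- generate_study(cfg0)
  lat <- subject_laterality(study$subjects)
  expect_lt(abs(mean(lat$hi)), 0.04)
  summ <- summarize_laterality(lat, "species")
  # strength_base = 0.6 should be recovered as the typical species MeanAbsHI
  expect_lt(abs(mean(summ$mean_abs_hi) - 0.6), 0.05)

  # expected strength increases monotonically with the latent strength level
  means <- vapply(c(0.25, 0.45, 0.65, 0.85), function(s) {
    st <- generate_study(sim_config(seed = 33, n_species = 10,
                                    n_ind = c(40, 40), sigma_direction = 0,
                                    sigma_strength = 0, strength_base = s))
    mean(subject_laterality(st$subjects)$abs_hi)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # highly heterogeneous species are strongly lateralized
  expect_gt(means[4], 0.8)
})

test_that("heritable strength and non-heritable direction separate in recovered lambda", {
  # default world: lambda = 0.9 on strength, 0 on direction. Subject-sampling
  # noise in the species means attenuates the strength estimate (median about
  # 0.7 rather than 0.9 at 38 species), but the two traits stay far apart.
  fits <- vapply(1:30, function(i) {
    study <- generate_study(sim_config(seed = 60000 + i))
    lat <- subject_laterality(study$subjects)
    summ <- summarize_laterality(lat, "species")
    c(strength = fit_lambda(setNames(summ$mean_abs_hi, summ$group_id),
                            study$tree)$lambda_hat,
      direction = fit_lambda(setNames(summ$mean_hi, summ$group_id),
                             study$tree)$lambda_hat)
  }, numeric(2))
  expect_gt(median(fits["strength", ]), 0.5)
  expect_lt(median(fits["direction", ]), 0.2)
  expect_gt(median(fits["strength", ]) - median(fits["direction", ]), 0.3)
})

test_that("studies regenerate exactly from their seed and expose ground truth", {
  cfg <- sim_config(seed = 41, n_species = 38, n_ind = c(25, 25))
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_equal(nrow(s1$subjects), 950)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$truth$direction, s2$truth$direction)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
  expect_setequal(names(s1$truth),
                  c("direction", "strength", "ecology", "subject_truth",
                    "config"))
  expect_true(all(s1$truth$subject_truth$p_right >= 0 &
                    s1$truth$subject_truth$p_right <= 1))
})
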