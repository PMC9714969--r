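make_predictors <- function(tree, seed = 1) {
  set.seed(seed)
  n <- length(tree$tip.label)
  data.frame(species = tree$tip.label,
             ecology = sample(c("arboreal", "terrestrial"), n, replace = TRUE),
             tool_use = as.logical(rbinom(n, 1, 0.3)),
             brain_size_ml = 10^rnorm(n, log10(70), 0.5),
             stringsAsFactors = FALSE)
}

test_that("AICc and Akaike weights follow the closed forms", {
  expect_equal(aicc(10, 2, 38), -16 + 12 / 35)
  expect_error(aicc(10, 37, 38), "exceed")
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)))
  expect_equal(round(w, 3), c(0.731, 0.269))
  expect_equal(akaike_weights(5), 1)
  expect_equal(sum(akaike_weights(rnorm(8))), 1)
})

test_that("model enumeration covers every subset including the null model", {
  m3 <- enumerate_models(c("ecology", "tool_use", "log_brain"))
  expect_length(m3, 8)
  expect_true(any(vapply(m3, length, integer(1)) == 0))
  expect_length(enumerate_models(character(0)), 1)
  expect_length(enumerate_models(c("a", "b")), 4)
})

test_that("PGLS at lambda 0 reduces to OLS and is scale-invariant in branch lengths", {
  tr <- simulate_tree(30, seed = 51)
  pred <- make_predictors(tr, seed = 52)
  y <- simulate_species_effects(tr, 1, 0.2, seed = 53) +
    0.3 * (pred$ecology == "terrestrial")
  f0 <- pgls_fit(y, c("ecology", "tool_use", "log_brain"), pred, tr,
                 lambda = 0)
  X <- cbind(1, pred$ecology == "terrestrial", pred$tool_use,
             log10(pred$brain_size_ml))
  ols <- qr.coef(qr(X), unname(y[pred$species]))
  expect_equal(unname(f0$coefficients), unname(ols), tolerance = 1e-8)

  f1 <- pgls_fit(y, "ecology", pred, tr)
  tr_big <- tr; tr_big$edge.length <- tr$edge.length * 7
  f1b <- pgls_fit(y, "ecology", pred, tr_big)
  expect_equal(f1b$coefficients, f1$coefficients, tolerance = 1e-6)
  expect_equal(f1b$lambda_hat, f1$lambda_hat, tolerance = 1e-4)
})

test_that("PGLS matches the nlme + corPagel oracle", {
  tr <- simulate_tree(40, seed = 61)
  pred <- make_predictors(tr, seed = 62)
  y <- simulate_species_effects(tr, 0.9, 0.3, seed = 63) -
    0.2 * (pred$ecology == "terrestrial")
  mine <- pgls_fit(y, c("ecology", "tool_use", "log_brain"), pred, tr)
  df <- data.frame(y = unname(y[pred$species]),
                   ecology = as.numeric(pred$ecology == "terrestrial"),
                   tool_use = as.numeric(pred$tool_use),
                   log_brain = log10(pred$brain_size_ml),
                   sp = pred$species)
  g <- nlme::gls(y ~ ecology + tool_use + log_brain, data = df,
                 correlation = ape::corPagel(0.5, tr, form = ~sp),
                 method = "ML", control = nlme::glsControl(opt = "optim"))
  expect_equal(mine$loglik, as.numeric(logLik(g)), tolerance = 1e-5)
  expect_equal(unname(mine$coefficients), unname(coef(g)), tolerance = 1e-4)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-3)
})

test_that("rank-deficient designs are rejected with the offending column named", {
  tr <- simulate_tree(20, seed = 71)
  pred <- make_predictors(tr, seed = 72)
  pred$tool_use <- pred$ecology == "terrestrial"  # duplicated information
  y <- simulate_species_effects(tr, 1, 0.2, seed = 73)
  expect_error(pgls_fit(y, c("ecology", "tool_use"), pred, tr),
               "rank-deficient")
  expect_error(vif(cbind(a = rnorm(10), b = 1:10, b2 = 2 * (1:10))),
               "collinearity")
})

test_that("conditional averaging renormalizes weights and adjusts the SE", {
  fake_fit <- function(terms, b, s) {
    list(terms = terms,
         coefficients = setNames(c(0, b), c("(Intercept)", terms)),
         se = setNames(c(1, s), c("(Intercept)", terms)))
  }
  sel <- list(table = data.frame(weight = c(0.6, 0.3, 0.1)),
              fits = list(fake_fit("ecology", 1, 0.5),
                          fake_fit("ecology", 2, 0.4),
                          fake_fit("tool_use", 5, 1)))
  avg <- conditional_average(sel)
  eco <- avg[avg$term == "ecology", ]
  w <- c(0.6, 0.3) / 0.9
  est <- sum(w * c(1, 2))
  expect_equal(eco$estimate, est)
  expect_equal(eco$se,
               sqrt(sum(w * (c(0.5, 0.4)^2 + (c(1, 2) - est)^2))))
  expect_equal(eco$p, 2 * pnorm(-abs(eco$estimate / eco$se)))
  # a term appearing in exactly one model keeps that model's estimate and SE
  tu <- avg[avg$term == "tool_use", ]
  expect_equal(tu$estimate, 5)
  expect_equal(tu$se, 1)
})

test_that("VIF follows 1 / (1 - R^2)", {
  set.seed(81)
  # construct two columns with exact sample correlation 0.8: unit-sd x1 and a
  # unit-sd residual e orthogonal to it (centered), then mix
  x1 <- drop(scale(rnorm(50)))
  e <- drop(scale(residuals(lm(rnorm(50) ~ x1))))
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * e
  v <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  expect_equal(unname(vif(cbind(a = x1, b = e))), c(1, 1), tolerance = 1e-10)
  expect_equal(unname(vif(matrix(rnorm(10), ncol = 1))), 1)
})

test_that("Shapiro-Wilk wrapper behaves at the contract boundaries", {
  q <- qnorm(ppoints(20))
  sw <- shapiro_wilk(q)
  expect_gt(sw$statistic, 0.99)
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
  set.seed(91)
  rejections <- sum(replicate(40, shapiro_wilk(rexp(50))$p < 0.05))
  expect_gte(rejections, 36)
})

test_that("the model suite runs its three analyses with the right species sets", {
  study <- generate_study(sim_config(seed = 101, n_species = 24,
                                     n_ind = c(10, 30)))
  # stand one species in as humans to exercise the exclusion path
  study$tree <- substitute_tips(study$tree, c(sp001 = "Homo sapiens"))
  study$predictors$species[study$predictors$species == "sp001"] <- "Homo sapiens"
  study$subjects$species[study$subjects$species == "sp001"] <- "Homo sapiens"
  lat <- subject_laterality(study$subjects)
  summ <- summarize_laterality(lat, "species")
  suite <- run_model_suite(summ, study$predictors, study$tree, min_n = 15)
  expect_s3_class(suite, "pgls_suite")
  expect_equal(suite$strength$n, 24)
  n_dir <- sum(summ$n >= 15)
  expect_equal(suite$direction$n, n_dir)
  has_human <- "Homo sapiens" %in%
    summ$group_id[summ$n >= 15]
  expect_equal(suite$direction_no_humans$n, n_dir - as.integer(has_human))
  for (an in suite) {
    expect_equal(nrow(an$selection$table), 8)
    expect_equal(sum(an$selection$table$weight), 1, tolerance = 1e-9)
    expect_equal(an$selection$table$delta_aicc[1], 0)
    expect_true(!is.unsorted(an$selection$table$aicc))
    expect_setequal(an$average$term, c("ecology", "tool_use", "log_brain"))
    expect_true(all(an$average$vif >= 1))
  }
})
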