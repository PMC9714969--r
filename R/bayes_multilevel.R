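# Bayesian phylogenetic multilevel models of age/sex effects on individual
# HI and AbsHI, fitted by a purpose-built Gibbs sampler with Metropolis
# updates for the two standard deviations.
#
# Model: y_i = b0 + b_age * subadult_i + b_sex * male_i + u_{s(i)} + e_i,
#        u ~ MVN(0, sigma_species^2 * A),  e_i ~ N(0, sigma_resid^2),
# where A is the phylogenetic correlation matrix (VCV scaled to unit
# diagonal). Priors: Student-t(3, 0, 2.5) on the intercept (implemented as an
# inverse-gamma scale mixture, keeping the coefficient update conjugate),
# improper flat on slopes, half-t(3, 0, 2.5) on both SDs (random-walk
# Metropolis on the log scale).

#' MCMC configuration
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iter iterations per chain (including warmup).
#' @param warmup warmup iterations discarded per chain (< iter).
#' @param seed integer seed; chain c uses seed + c.
#' @param prior_scale_intercept,prior_df_intercept Student-t prior on the
#'   intercept (default t(3, 0, 2.5)).
#' @param prior_scale_sd,prior_df_sd half-t prior on both SDs.
#' @param proposal_sd random-walk SD for the log-scale SD updates.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, iter = 2000, warmup = 1000, seed = 1,
                        prior_scale_intercept = 2.5, prior_df_intercept = 3,
                        prior_scale_sd = 2.5, prior_df_sd = 3,
                        proposal_sd = 0.2) {
  stopifnot(chains >= 2, warmup < iter, iter > 0, warmup >= 0)
  structure(list(chains = chains, iter = iter, warmup = warmup, seed = seed,
                 prior_scale_intercept = prior_scale_intercept,
                 prior_df_intercept = prior_df_intercept,
                 prior_scale_sd = prior_scale_sd, prior_df_sd = prior_df_sd,
                 proposal_sd = proposal_sd),
            class = "mcmc_config")
}

#' Assemble the model-ready table for the multilevel models
#'
#' Applies the standard exclusions: humans (extreme outlier), chimpanzees
#' (vastly overrepresented), Tonkean macaques (no age data) and unsexed
#' subjects, then restricts to a clade scope and attaches the HI and AbsHI
#' responses with 0/1 dummies for subadult age and male sex.
#'
#' @param lat per-subject laterality table from [subject_laterality()] (needs
#'   species, clade, sex, age_class, hi, abs_hi).
#' @param scope "all" or one clade name.
#' @param exclude_species species removed entirely.
#' @return data.frame with species, clade, hi, abs_hi, age_subadult,
#'   sex_male.
#' @export
build_bayes_dataset <- function(lat,
                                scope = c("all", "Hominoidea",
                                          "Cercopithecoidea", "Platyrrhini"),
                                exclude_species = c("Homo sapiens",
                                                    "Pan troglodytes",
                                                    "Macaca tonkeana")) {
  scope <- match.arg(scope)
  keep <- !(lat$species %in% exclude_species) & lat$sex %in% c("F", "M") &
    lat$age_class %in% c("adult", "subadult")
  d <- lat[keep, , drop = FALSE]
  if (scope != "all") d <- d[d$clade == scope, , drop = FALSE]
  if (nrow(d) == 0) stop("no subjects left after exclusions for scope ", scope)
  data.frame(species = d$species, clade = d$clade, hi = d$hi,
             abs_hi = d$abs_hi,
             age_subadult = as.numeric(d$age_class == "subadult"),
             sex_male = as.numeric(d$sex == "M"),
             stringsAsFactors = FALSE)
}

# log density of the half-t prior (unnormalized) plus log-scale Jacobian
.log_half_t <- function(sigma, df, scale) {
  -(df + 1) / 2 * log1p((sigma / scale)^2 / df)
}

.run_chain <- function(y, X, sp_idx, Ainv, n_sp, cfg, chain,
                       fix_sigma_species = NULL) {
  n <- length(y)
  p <- ncol(X)
  set.seed(cfg$seed + chain)
  nu_b <- cfg$prior_df_intercept
  s_b <- cfg$prior_scale_intercept
  no_ranef <- !is.null(fix_sigma_species) && fix_sigma_species == 0
  # W = [X, Z]; all cross-products are iteration-constant
  XtX <- crossprod(X)
  XtZ <- t(rowsum(X, sp_idx, reorder = TRUE))
  ns_count <- tabulate(sp_idx, n_sp)
  Wty <- c(crossprod(X, y), rowsum(y, sp_idx, reorder = TRUE)[, 1])
  WtW <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), diag(ns_count, n_sp)))
  q <- p + n_sp
  beta <- c(mean(y), rep(0, p - 1))
  u <- rep(0, n_sp)
  sigma_e <- max(stats::sd(y), 1e-3)
  sigma_s <- if (is.null(fix_sigma_species)) sigma_e / 2 else fix_sigma_species
  omega <- s_b^2
  kept <- cfg$iter - cfg$warmup
  out <- matrix(NA_real_, kept, p + 2)
  for (it in seq_len(cfg$iter)) {
    # joint conjugate draw of (beta, u); t intercept prior enters through the
    # inverse-gamma mixing scale omega
    if (no_ranef) {
      P <- XtX / sigma_e^2 + diag(c(1 / omega, rep(0, p - 1)), p)
      Rp <- chol(P)
      m <- backsolve(Rp, backsolve(Rp, crossprod(X, y) / sigma_e^2,
                                   transpose = TRUE))
      beta <- drop(m + backsolve(Rp, stats::rnorm(p)))
      u <- rep(0, n_sp)
    } else {
      P <- WtW / sigma_e^2
      P[seq_len(p), seq_len(p)] <- P[seq_len(p), seq_len(p)] +
        diag(c(1 / omega, rep(0, p - 1)), p)
      ui <- (p + 1):q
      P[ui, ui] <- P[ui, ui] + Ainv / sigma_s^2
      Rp <- chol(P)
      m <- backsolve(Rp, backsolve(Rp, Wty / sigma_e^2, transpose = TRUE))
      theta <- drop(m + backsolve(Rp, stats::rnorm(q)))
      beta <- theta[seq_len(p)]
      u <- theta[ui]
    }
    # mixing scale of the intercept's t prior
    omega <- 1 / stats::rgamma(1, (nu_b + 1) / 2,
                               (nu_b * s_b^2 + beta[1]^2) / 2)
    r <- y - drop(X %*% beta)
    # residual SD (Metropolis on log scale, half-t prior)
    ssr <- sum((r - u[sp_idx])^2)
    lp_e <- function(s) -n * log(s) - ssr / (2 * s^2) +
      .log_half_t(s, cfg$prior_df_sd, cfg$prior_scale_sd) + log(s)
    prop <- sigma_e * exp(cfg$proposal_sd * stats::rnorm(1))
    if (log(stats::runif(1)) < lp_e(prop) - lp_e(sigma_e)) sigma_e <- prop
    # species SD (Metropolis on log scale, half-t prior)
    if (is.null(fix_sigma_species)) {
      quad <- drop(crossprod(u, Ainv %*% u))
      lp_s <- function(s) -n_sp * log(s) - quad / (2 * s^2) +
        .log_half_t(s, cfg$prior_df_sd, cfg$prior_scale_sd) + log(s)
      prop <- sigma_s * exp(cfg$proposal_sd * stats::rnorm(1))
      if (log(stats::runif(1)) < lp_s(prop) - lp_s(sigma_s)) sigma_s <- prop
    }
    if (it > cfg$warmup) out[it - cfg$warmup, ] <- c(beta, sigma_s, sigma_e)
  }
  out
}

# split-chain potential scale reduction factor
.rhat <- function(mat) {
  half <- floor(nrow(mat) / 2)
  segs <- cbind(mat[seq_len(half), , drop = FALSE],
                mat[(nrow(mat) - half + 1):nrow(mat), , drop = FALSE])
  m <- ncol(segs)
  n <- nrow(segs)
  means <- colMeans(segs)
  B <- n * stats::var(means)
  W <- mean(apply(segs, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size with Geyer initial-positive-sequence truncation
.ess <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  centered <- sweep(mat, 2, colMeans(mat))
  varw <- mean(apply(mat, 2, stats::var))
  if (varw == 0) return(n * m)
  max_lag <- min(n - 1, 500)
  rho <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    acov <- mean(vapply(seq_len(m), function(j) {
      mean(centered[seq_len(n - lag), j] * centered[(lag + 1):n, j])
    }, numeric(1)))
    rho[lag] <- acov / varw
  }
  s <- 0
  lag <- 1
  while (lag + 1 <= max_lag) {
    pair <- rho[lag] + rho[lag + 1]
    if (pair < 0) break
    s <- s + pair
    lag <- lag + 2
  }
  max(1, n * m / (1 + 2 * s))
}

#' Sample the posterior of the phylogenetic multilevel model
#'
#' Gaussian response (HI or AbsHI) on age and sex dummies with a
#' species-level phylogenetic random effect. Coefficients and species
#' effects use conjugate Gibbs updates; the two SDs use random-walk
#' Metropolis on the log scale. Runs are reproducible: chain c is seeded with
#' `config$seed + c`.
#'
#' @param table model-ready table from [build_bayes_dataset()].
#' @param tree phylogeny containing all species of `table` as tips.
#' @param response "hi" (direction) or "abs_hi" (strength).
#' @param config an [mcmc_config()].
#' @param fix_sigma_species optionally fix the species SD (0 disables the
#'   random effect; used for validation against non-phylogenetic regression).
#' @param strict error when any split R-hat exceeds 1.01 (default FALSE;
#'   the result carries a `converged` flag either way).
#' @return object of class `posterior_draws`: `draws` (iterations x chains x
#'   parameters array) and `summary` (mean, sd, CI bounds, R-hat, ESS,
#'   notable flag per parameter).
#' @export
sample_posterior <- function(table, tree, response = c("hi", "abs_hi"),
                             config = mcmc_config(),
                             fix_sigma_species = NULL, strict = FALSE) {
  response <- match.arg(response)
  species <- sort(unique(table$species))
  missing_tips <- setdiff(species, tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("species not in tree: ", paste(missing_tips, collapse = ", "))
  }
  y <- table[[response]]
  Xlist <- list("b_Intercept" = rep(1, nrow(table)))
  for (col in c("age_subadult", "sex_male")) {
    if (length(unique(table[[col]])) > 1) {
      Xlist[[paste0("b_", col)]] <- table[[col]]
    } else {
      warning("dropping constant predictor: ", col)
    }
  }
  X <- do.call(cbind, Xlist)
  sp_idx <- match(table$species, species)
  C <- phylo_vcv(tree, species)
  A <- C / tcrossprod(sqrt(diag(C)))     # correlation: unit diagonal
  Ainv <- chol2inv(chol(A))
  pars <- c(colnames(X), "sigma_species", "sigma_resid")
  chains <- lapply(seq_len(config$chains), function(ch) {
    .run_chain(y, X, sp_idx, Ainv, length(species), config, ch,
               fix_sigma_species)
  })
  kept <- config$iter - config$warmup
  draws <- array(NA_real_, dim = c(kept, config$chains, length(pars)),
                 dimnames = list(NULL, paste0("chain", seq_len(config$chains)),
                                 pars))
  for (ch in seq_along(chains)) draws[, ch, ] <- chains[[ch]]
  summ <- do.call(rbind, lapply(pars, function(pp) {
    mat <- draws[, , pp]
    v <- as.vector(mat)
    ci <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = pp, mean = mean(v), sd = stats::sd(v),
               q2.5 = ci[1], q97.5 = ci[2],
               rhat = .rhat(mat), ess = .ess(mat),
               notable = ci[1] > 0 | ci[2] < 0,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  fixed_sd <- if (!is.null(fix_sigma_species)) "sigma_species" else character(0)
  converged <- all(summ$rhat[!summ$parameter %in% fixed_sd] <= 1.01,
                   na.rm = TRUE)
  if (strict && !converged) {
    stop("non-convergence: split R-hat > 1.01 for ",
         paste(summ$parameter[summ$rhat > 1.01], collapse = ", "))
  }
  structure(list(draws = draws, summary = summ, response = response,
                 converged = converged, config = config),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Phylogenetic multilevel model posterior (response:", x$response, ")\n")
  cat(" ", dim(x$draws)[2], "chains x", dim(x$draws)[1],
      "kept draws;", if (x$converged) "converged" else "NOT converged",
      "(split R-hat <= 1.01)\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Summarize one posterior effect
#'
#' Posterior mean and equal-tailed 95% credible interval; the effect is
#' "notable" when the interval excludes zero.
#'
#' @param draws a `posterior_draws` object.
#' @param parameter parameter name (e.g. "b_age_subadult").
#' @return list with mean, lower, upper, notable.
#' @export
summarize_effect <- function(draws, parameter) {
  s <- draws$summary
  row <- s[s$parameter == parameter, ]
  if (nrow(row) != 1) stop("unknown parameter: ", parameter)
  list(mean = row$mean, lower = row$q2.5, upper = row$q97.5,
       notable = row$notable)
}
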