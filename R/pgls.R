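# PGLS with Pagel's lambda correlation structure, all-subsets AICc model
# selection, Akaike weights, conditional model averaging, VIF, residual check.

.PGLS_TERMS <- c("ecology", "tool_use", "log_brain")

# Design matrix for a term subset. Coding: ecology 0 = arboreal (reference),
# 1 = terrestrial; tool_use 0 = absent, 1 = present; brain size log10.
.pgls_design <- function(species, terms, predictors) {
  idx <- match(species, predictors$species)
  if (anyNA(idx)) {
    stop("missing predictor row(s) for: ",
         paste(species[is.na(idx)], collapse = ", "))
  }
  p <- predictors[idx, , drop = FALSE]
  cols <- list("(Intercept)" = rep(1, length(species)))
  for (tm in terms) {
    cols[[tm]] <- switch(tm,
      ecology = as.numeric(p$ecology == "terrestrial"),
      tool_use = as.numeric(p$tool_use),
      log_brain = log10(p$brain_size_ml),
      stop("unknown term: ", tm))
  }
  X <- do.call(cbind, cols)
  rownames(X) <- species
  X
}

# Profile likelihood over lambda for fixed response/design; same eigen
# shortcut as the signal module on ultrametric trees.
.pgls_ll_factory <- function(C, y, X) {
  n <- length(y)
  h <- diag(C)
  eigen_route <- (max(h) - min(h)) / max(h) <= 1e-6
  if (eigen_route) {
    hbar <- mean(h)
    E <- eigen(C, symmetric = TRUE)
    Xt <- crossprod(E$vectors, X)
    yt <- crossprod(E$vectors, y)
    function(lambda) {
      d <- lambda * E$values + (1 - lambda) * hbar
      if (any(d <= 0)) return(list(ll = -Inf))
      w <- 1 / sqrt(d)
      Xw <- Xt * w
      yw <- yt * w
      qrX <- qr(Xw)
      if (qrX$rank < ncol(X)) return(list(ll = -Inf, rank_deficient = TRUE))
      beta <- qr.coef(qrX, yw)
      r <- yw - Xw %*% beta
      s2 <- sum(r^2) / n
      list(ll = -0.5 * (n * log(2 * pi * s2) + sum(log(d)) + n),
           beta = drop(beta), s2 = s2,
           xtxinv = chol2inv(qr.R(qrX)), resid_w = drop(r))
    }
  } else {
    function(lambda) {
      V <- lambda_transform(C, lambda)
      R <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(R)) return(list(ll = -Inf))
      Xw <- backsolve(R, X, transpose = TRUE)
      yw <- backsolve(R, y, transpose = TRUE)
      qrX <- qr(Xw)
      if (qrX$rank < ncol(X)) return(list(ll = -Inf, rank_deficient = TRUE))
      beta <- qr.coef(qrX, yw)
      r <- yw - Xw %*% beta
      s2 <- sum(r^2) / n
      list(ll = -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n),
           beta = drop(beta), s2 = s2,
           xtxinv = chol2inv(qr.R(qrX)), resid_w = drop(r))
    }
  }
}

#' Fit a PGLS regression with Pagel's lambda correlation structure
#'
#' Joint maximum likelihood: for each candidate lambda the coefficients and
#' residual variance are estimated in closed form by GLS (whitening with the
#' Cholesky factor of the lambda-transformed phylogenetic covariance), and
#' lambda is optimized on \[0, 1\]. Brain size enters as log10(ml). The
#' parameter count is k = number of coefficients (incl. intercept) + 1 for
#' the residual variance; the lambda of the correlation structure is not
#' counted, which reproduces the conventional df column of AICc tables.
#'
#' @param y named numeric response (species means), names = tip labels.
#' @param terms character subset of `c("ecology", "tool_use", "log_brain")`
#'   (may be empty for the NULL model).
#' @param predictors data.frame from [read_predictors()].
#' @param tree phylogeny containing all names of `y`.
#' @param lambda fix lambda at a value instead of optimizing (optional).
#' @return object of class `pgls_fit`.
#' @export
pgls_fit <- function(y, terms, predictors, tree, lambda = NULL) {
  if (is.null(names(y))) stop("response must be named by species")
  missing_tips <- setdiff(names(y), tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("species not in tree: ", paste(missing_tips, collapse = ", "))
  }
  tr <- if (length(y) < length(tree$tip.label)) {
    ape::drop.tip(tree, setdiff(tree$tip.label, names(y)))
  } else tree
  C <- phylo_vcv(tr)
  species <- rownames(C)
  yv <- unname(y[species])
  X <- .pgls_design(species, terms, predictors)
  qr0 <- qr(X)
  if (qr0$rank < ncol(X)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[qr0$pivot[(qr0$rank + 1):ncol(X)]], collapse = ", "))
  }
  ll_fun <- .pgls_ll_factory(C, yv, X)
  if (is.null(lambda)) {
    best <- .optimize_lambda(function(l) list(ll = ll_fun(l)$ll))
    lambda_hat <- best$lambda
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
    lambda_hat <- lambda
  }
  fit <- ll_fun(lambda_hat)
  n <- length(yv)
  p <- ncol(X)
  k <- p + 1
  se <- sqrt(diag(fit$xtxinv) * fit$s2 * n / (n - p))
  beta <- fit$beta
  names(beta) <- names(se) <- colnames(X)
  structure(list(terms = terms, coefficients = beta, se = se,
                 lambda_hat = lambda_hat, loglik = fit$ll, sigma2 = fit$s2,
                 n = n, k = k, aicc = aicc(fit$ll, k, n),
                 resid_normalized = fit$resid_w / sqrt(fit$s2 * n / (n - p)),
                 species = species),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (Pagel's lambda correlation), n =", x$n, "\n")
  cat("  terms:", if (length(x$terms)) paste(x$terms, collapse = " + ")
      else "(NULL)", "\n")
  cat(sprintf("  lambda = %.4g, logLik = %.4f, AICc = %.4f\n",
              x$lambda_hat, x$loglik, x$aicc))
  print(cbind(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' Second-order Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; requires n - k - 1 > 0.
#' @return numeric AICc.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' w_i proportional to exp(-delta_i / 2) with delta_i = AICc_i - min(AICc),
#' normalized to sum to one.
#'
#' @param aiccs vector of AICc values.
#' @return numeric weights summing to 1.
#' @export
akaike_weights <- function(aiccs) {
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Enumerate all predictor subsets
#'
#' All 2^p subsets of the term set, including the empty (NULL) model.
#'
#' @param terms character vector of candidate terms.
#' @return list of character vectors.
#' @export
enumerate_models <- function(terms = .PGLS_TERMS) {
  p <- length(terms)
  lapply(seq_len(2^p) - 1L, function(mask) {
    terms[bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) > 0]
  })
}

.model_label <- function(terms) {
  if (length(terms) == 0) "(NULL)" else paste(terms, collapse = " + ")
}

#' All-subsets PGLS model selection table
#'
#' Fits every subset of `terms` (lambda optimized per model), ranks by AICc
#' and attaches delta AICc and Akaike weights. Ties in AICc are broken by
#' fewer terms, then lexicographically.
#'
#' @inheritParams pgls_fit
#' @param terms candidate terms (default all three).
#' @return list with `table` (data.frame: model, df, aicc, delta_aicc,
#'   weight) and `fits` (list of `pgls_fit`, in table order).
#' @export
pgls_model_selection <- function(y, predictors, tree, terms = .PGLS_TERMS) {
  models <- enumerate_models(terms)
  fits <- lapply(models, function(tm) pgls_fit(y, tm, predictors, tree))
  tab <- data.frame(model = vapply(models, .model_label, character(1)),
                    df = vapply(fits, function(f) f$k, numeric(1)),
                    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
                    n_terms = vapply(models, length, integer(1)),
                    stringsAsFactors = FALSE)
  ord <- order(tab$aicc, tab$n_terms, tab$model)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  tab$weight <- akaike_weights(tab$aicc)
  tab$n_terms <- NULL
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Conditional model average of PGLS coefficients
#'
#' Each term is averaged only over the models that contain it, with Akaike
#' weights renormalized over that subset. The adjusted standard error uses
#' the revised model-averaging variance formula: the weighted combination of
#' each model's squared SE plus the squared deviation of its coefficient from
#' the average, square-rooted. Two-sided p-values use a normal (z) reference.
#'
#' @param selection result of [pgls_model_selection()].
#' @return data.frame with term, estimate, se, z, p, n_models.
#' @export
conditional_average <- function(selection) {
  fits <- selection$fits
  w <- selection$table$weight
  all_terms <- unique(unlist(lapply(fits, function(f) f$terms)))
  if (length(all_terms) == 0) stop("no term appears in any model")
  rows <- lapply(all_terms, function(tm) {
    idx <- which(vapply(fits, function(f) tm %in% f$terms, logical(1)))
    wt <- w[idx] / sum(w[idx])
    b <- vapply(fits[idx], function(f) f$coefficients[[tm]], numeric(1))
    s <- vapply(fits[idx], function(f) f$se[[tm]], numeric(1))
    est <- sum(wt * b)
    se <- sqrt(sum(wt * (s^2 + (b - est)^2)))
    z <- est / se
    data.frame(term = tm, estimate = est, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)), n_models = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j is from the OLS regression of
#' predictor j on all other predictors (with intercept).
#'
#' @param X numeric design matrix of predictors (no intercept column).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) return(stats::setNames(rep(1, p), colnames(X)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (1 - r2 < 1e-10) {
      stop("perfect collinearity: infinite VIF for column ",
           if (!is.null(colnames(X))) colnames(X)[j] else j)
    }
    out[j] <- 1 / (1 - r2)
  }
  stats::setNames(out, colnames(X))
}

#' Shapiro-Wilk normality test
#'
#' Standard W statistic and approximate p-value (3 <= n <= 5000), used to
#' check PGLS residual normality on the phylogenetically normalized
#' residuals.
#'
#' @param residuals numeric vector.
#' @return list with statistic (W) and p.
#' @export
shapiro_wilk <- function(residuals) {
  if (length(residuals) < 3) stop("Shapiro-Wilk requires n >= 3")
  sw <- stats::shapiro.test(residuals)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

#' The three PGLS multi-model analyses
#'
#' Runs the all-subsets PGLS analysis with predictors ecology, tool use and
#' log10 brain size for (1) direction (MeanHI) on species with at least
#' `min_n` individuals, (2) direction excluding humans, and (3) strength
#' (MeanAbsHI) on all species. Each analysis returns the model selection
#' table, the conditional model average (with VIFs from the full design),
#' and the Shapiro-Wilk check of the best model's normalized residuals.
#'
#' @param summaries species-level summary data.frame (species or group_id,
#'   n, mean_hi, mean_abs_hi).
#' @param predictors data.frame from [read_predictors()].
#' @param tree phylogeny covering the analyzed species.
#' @param min_n minimum sample size for the direction analyses (default 15).
#' @param human species label treated as human (default "Homo sapiens").
#' @return object of class `pgls_suite`: named list of three analyses, each
#'   with elements selection, average, shapiro, n.
#' @export
run_model_suite <- function(summaries, predictors, tree, min_n = 15,
                            human = "Homo sapiens") {
  id <- if ("species" %in% names(summaries)) summaries$species else
    summaries$group_id
  usable <- id %in% tree$tip.label & id %in% predictors$species
  if (!all(usable)) {
    warning("dropping species without tree tip or predictor row: ",
            paste(id[!usable], collapse = ", "))
  }
  s <- summaries[usable, , drop = FALSE]
  id <- id[usable]
  strength <- stats::setNames(s$mean_abs_hi, id)
  dir_keep <- s$n >= min_n
  direction <- stats::setNames(s$mean_hi[dir_keep], id[dir_keep])
  direction_nh <- direction[names(direction) != human]
  one <- function(y) {
    sel <- pgls_model_selection(y, predictors, tree)
    avg <- conditional_average(sel)
    Xfull <- .pgls_design(names(y), .PGLS_TERMS, predictors)[, -1, drop = FALSE]
    avg$vif <- unname(vif(Xfull)[avg$term])
    best <- sel$fits[[1]]
    list(selection = sel, average = avg,
         shapiro = shapiro_wilk(best$resid_normalized), n = length(y))
  }
  structure(list(direction = one(direction),
                 direction_no_humans = one(direction_nh),
                 strength = one(strength)),
            class = "pgls_suite")
}

#' @export
print.pgls_suite <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "(n =", x[[nm]]$n, "species) ==\n")
    print(x[[nm]]$selection$table, digits = 4)
    cat("conditional average:\n")
    print(x[[nm]]$average, digits = 3)
    cat("\n")
  }
  invisible(x)
}
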