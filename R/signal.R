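# Phylogenetic signal (Pagel's lambda, ML + LRT) and ancestral state
# reconstruction under Brownian motion.

# Profile log-likelihood machinery. For an ultrametric tree (equal root-to-tip
# depth h) the lambda-transformed covariance is lambda*C + (1-lambda)*h*I,
# which shares C's eigenvectors: one eigendecomposition gives the likelihood
# at any lambda in O(n). Non-ultrametric trees fall back to a Cholesky solve
# per evaluation.
.lambda_ll_factory <- function(C, y) {
  n <- length(y)
  h <- diag(C)
  rel_spread <- (max(h) - min(h)) / max(h)
  one <- rep(1, n)
  if (rel_spread <= 1e-6) {
    hbar <- mean(h)
    E <- eigen(C, symmetric = TRUE)
    u1 <- crossprod(E$vectors, one)
    uy <- crossprod(E$vectors, y)
    function(lambda) {
      d <- lambda * E$values + (1 - lambda) * hbar
      if (any(d <= 0)) return(list(ll = -Inf, mu = NA, s2 = NA))
      mu <- sum(u1 * uy / d) / sum(u1^2 / d)
      r <- uy - mu * u1
      s2 <- sum(r^2 / d) / n
      list(ll = -0.5 * (n * log(2 * pi * s2) + sum(log(d)) + n),
           mu = mu, s2 = s2)
    }
  } else {
    function(lambda) {
      V <- lambda_transform(C, lambda)
      R <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(R)) return(list(ll = -Inf, mu = NA, s2 = NA))
      wy <- backsolve(R, y, transpose = TRUE)
      w1 <- backsolve(R, one, transpose = TRUE)
      mu <- sum(w1 * wy) / sum(w1^2)
      r <- wy - mu * w1
      s2 <- sum(r^2) / n
      list(ll = -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n),
           mu = mu, s2 = s2)
    }
  }
}

# Bounded ML search for lambda on [0, 1]: Brent in each of `multistarts`
# subintervals plus explicit endpoint evaluation.
.optimize_lambda <- function(ll_fun, multistarts = 5, tol = 1e-8) {
  obj <- function(l) ll_fun(l)$ll
  breaks <- seq(0, 1, length.out = multistarts + 1)
  best <- list(lambda = 0, ll = obj(0))
  ll1 <- obj(1)
  if (ll1 > best$ll) best <- list(lambda = 1, ll = ll1)
  for (i in seq_len(multistarts)) {
    op <- stats::optimize(obj, lower = breaks[i], upper = breaks[i + 1],
                          maximum = TRUE, tol = tol)
    if (op$objective > best$ll) {
      best <- list(lambda = op$maximum, ll = op$objective)
    }
  }
  best
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Fits the multivariate normal model y ~ N(mu * 1, sigma2 * C_lambda), where
#' C_lambda multiplies the off-diagonal phylogenetic covariances by lambda.
#' mu and sigma2 are profiled in closed form; lambda is optimized on \[0, 1\]
#' by bounded Brent search with multiple starts. The null hypothesis of no
#' phylogenetic signal (lambda = 0) is tested with a likelihood-ratio test
#' against a chi-square with 1 df (the standard reference, conservative at
#' the lambda = 0 boundary).
#'
#' @param trait named numeric vector (names = tip labels), length >= 4,
#'   non-constant.
#' @param tree an `ape::phylo` tree containing all trait names as tips; tips
#'   without data are pruned.
#' @param multistarts number of Brent subintervals (default 5).
#' @param tol optimizer tolerance (default 1e-8).
#' @return object of class `lambda_fit`: lambda_hat, sigma2_hat, mu_hat,
#'   loglik, loglik_lambda0, lrt_stat, p, n, flat.
#' @export
fit_lambda <- function(trait, tree, multistarts = 5, tol = 1e-8) {
  if (is.null(names(trait))) stop("trait must be named by tip label")
  missing_tips <- setdiff(names(trait), tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("trait name(s) not in tree: ", paste(missing_tips, collapse = ", "))
  }
  if (length(trait) < 4) stop("at least 4 tips required")
  if (stats::var(trait) == 0) stop("degenerate trait: constant across tips")
  if (anyNA(trait)) stop("missing trait values")
  tr <- if (length(trait) < length(tree$tip.label)) {
    ape::drop.tip(tree, setdiff(tree$tip.label, names(trait)))
  } else tree
  if (.ultrametric_error(tr) > 1e-6) {
    warning("tree is not ultrametric; using the general (slower) likelihood")
  }
  C <- phylo_vcv(tr)
  y <- trait[rownames(C)]
  ll_fun <- .lambda_ll_factory(C, unname(y))
  grid <- vapply(seq(0, 1, length.out = 11), function(l) ll_fun(l)$ll,
                 numeric(1))
  flat <- (max(grid) - min(grid)) < 1e-8
  if (flat) {
    warning("log-likelihood is flat in lambda (unidentifiable, e.g. star phylogeny)")
  }
  best <- .optimize_lambda(ll_fun, multistarts = multistarts, tol = tol)
  at <- ll_fun(best$lambda)
  ll0 <- ll_fun(0)$ll
  lrt <- max(0, 2 * (best$ll - ll0))
  structure(list(lambda_hat = best$lambda, sigma2_hat = at$s2,
                 mu_hat = at$mu, loglik = best$ll, loglik_lambda0 = ll0,
                 lrt_stat = lrt,
                 p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 n = length(y), flat = flat),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda (ML)\n")
  cat(sprintf("  lambda = %.4g, sigma2 = %.4g, mu = %.4g (n = %d tips)\n",
              x$lambda_hat, x$sigma2_hat, x$mu_hat, x$n))
  cat(sprintf("  logLik = %.4f; logLik(lambda=0) = %.4f\n",
              x$loglik, x$loglik_lambda0))
  cat(sprintf("  LRT vs lambda = 0: stat = %.4g, p = %.4g\n", x$lrt_stat, x$p))
  invisible(x)
}

#' Ancestral state reconstruction under Brownian motion
#'
#' Maximum-likelihood (GLS) estimates of the trait value at every internal
#' node under Brownian motion on the untransformed tree. The root estimate
#' equals the GLS mean; reported variances include the uncertainty of the
#' root estimate. Estimates coincide with the mode of the joint likelihood
#' over all internal states.
#'
#' @inheritParams fit_lambda
#' @return data.frame with node (ape node id), estimate, variance; attributes
#'   `mu` (root/GLS mean) and `sigma2` (ML rate).
#' @export
asr_bm <- function(trait, tree) {
  if (is.null(names(trait))) stop("trait must be named by tip label")
  missing_tips <- setdiff(names(trait), tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("trait name(s) not in tree: ", paste(missing_tips, collapse = ", "))
  }
  tr <- if (length(trait) < length(tree$tip.label)) {
    ape::drop.tip(tree, setdiff(tree$tip.label, names(trait)))
  } else tree
  n <- length(tr$tip.label)
  depths <- ape::node.depth.edgelength(tr)
  M <- ape::mrca(tr, full = TRUE)
  tip_idx <- seq_len(n)
  node_idx <- (n + 1):(n + tr$Nnode)
  Cyy <- matrix(depths[M[tip_idx, tip_idx]], n, n)
  Cay <- matrix(depths[M[node_idx, tip_idx, drop = FALSE]], tr$Nnode, n)
  y <- unname(trait[tr$tip.label])
  Cinv <- solve(Cyy)
  one <- rep(1, n)
  denom <- sum(Cinv %*% one)
  mu <- sum(Cinv %*% y) / denom
  r <- y - mu
  sigma2 <- drop(crossprod(r, Cinv %*% r)) / n
  W <- Cay %*% Cinv                      # GLS weights of tips per node
  est <- mu + drop(W %*% r)
  # conditional variance plus propagation of root-mean uncertainty
  cond <- depths[node_idx] - rowSums(W * Cay)
  root_term <- (1 - drop(W %*% one))^2 / denom
  data.frame(node = node_idx, estimate = est,
             variance = sigma2 * (cond + root_term)) |>
    structure(mu = mu, sigma2 = sigma2)
}
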