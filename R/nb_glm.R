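# Negative-binomial GLM with log link and size-factor offsets, fitted by
# iteratively reweighted least squares. Variance model: V(mu) = mu + alpha*mu^2.

nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-10) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
}

#' Fit a negative-binomial GLM for one gene
#'
#' Maximizes the NB log-likelihood with mean `mu_j = s_j * exp((X beta)_j)`
#' at fixed dispersion `alpha`, by Fisher scoring (IRLS) with working
#' weights `mu / (1 + alpha * mu)`. Convergence when the largest
#' coefficient update falls below `tol` or after `max_iter` iterations.
#' An optional zero-centred normal prior on non-intercept coefficients
#' (variance `beta_prior_var`, natural-log scale) gives ridge-type LFC
#' shrinkage.
#'
#' @param y integer counts, one per sample.
#' @param X design matrix (full column rank).
#' @param s positive size factors.
#' @param alpha NB dispersion (> 0).
#' @param beta_prior_var optional prior variance for shrinkage; `Inf`
#'   (default) disables it.
#' @param tol,max_iter IRLS convergence controls.
#' @return List: `beta`, `se`, `loglik`, `mu`, `cov`, `converged`,
#'   `iterations`.
#' @export
fit_nb_glm <- function(y, X, s = rep(1, length(y)), alpha,
                       beta_prior_var = Inf, tol = 1e-6, max_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("length(y) != nrow(X)")
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stopf("design matrix is rank deficient; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }
  off <- log(s)
  # ridge penalty (0 on the intercept) implements the normal LFC prior
  lambda <- rep(0, p)
  if (is.finite(beta_prior_var)) {
    icpt <- apply(X, 2, function(cl) all(cl == cl[1]))
    lambda <- ifelse(icpt, 0, 1 / beta_prior_var)
  }
  beta <- qr.coef(qrX, log((y + 0.5) / s))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta) + off
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    xtwx <- crossprod(X, X * w) + diag(lambda, p)
    beta_new <- tryCatch(drop(solve(xtwx, crossprod(X, w * z))),
                         error = function(e) beta)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (is.na(delta)) break
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  eta <- drop(X %*% beta) + off
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X, X * w) + diag(lambda, p)
  covb <- tryCatch(solve(xtwx), error = function(e) matrix(NA_real_, p, p))
  names(beta) <- colnames(X)
  list(beta = beta, se = sqrt(pmax(diag(covb), 0)), loglik = nb_loglik(y, mu, alpha),
       mu = mu, cov = covb, converged = converged, iterations = iter)
}

#' Likelihood-ratio test between nested NB GLMs
#'
#' Fits both designs at the same fixed dispersion and compares
#' `2 * (l_full - l_reduced)` to a chi-squared reference with degrees of
#' freedom equal to the difference in column count. The reduced design
#' must span a subspace of the full design.
#'
#' @param y,s,alpha as in [fit_nb_glm()].
#' @param X_full,X_reduced nested design matrices.
#' @return List: `stat`, `df`, `p`, `fit_full`, `fit_reduced`.
#' @export
nb_lrt <- function(y, X_full, X_reduced, s = rep(1, length(y)), alpha) {
  X_full <- as.matrix(X_full); X_reduced <- as.matrix(X_reduced)
  if (ncol(X_reduced) > ncol(X_full))
    stopf("reduced design has more columns than the full design")
  # nesting check: every reduced column reproducible from the full columns
  resid <- qr.resid(qr(X_full), X_reduced)
  if (max(abs(resid)) > 1e-8)
    stopf("designs are not nested: reduced columns outside the full span")
  fit_full <- fit_nb_glm(y, X_full, s, alpha)
  fit_red <- fit_nb_glm(y, X_reduced, s, alpha)
  stat <- max(0, 2 * (fit_full$loglik - fit_red$loglik))
  df <- ncol(X_full) - ncol(X_reduced)
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(stat = stat, df = df, p = p,
       fit_full = fit_full, fit_reduced = fit_red)
}
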