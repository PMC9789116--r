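## Ridge-penalized negative binomial GLM with log link, fitted by IRLS
## (Fisher scoring) with step halving, plus profile-likelihood estimation of
## the dispersion.  Parameterization: Var(y) = mu + phi * mu^2, i.e. phi is
## the reciprocal of the NB "size".

nb_loglik <- function(y, mu, phi) {
  sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

## Profile ML for phi given a fixed mean vector; optimized on log(phi).
nb_profile_phi <- function(y, mu, lower = 1e-8, upper = 1e8) {
  f <- function(lp) -nb_loglik(y, mu, exp(lp))
  opt <- stats::optimize(f, interval = log(c(lower, upper)), tol = 1e-6)
  phi <- exp(opt$minimum)
  # Poisson limit: the profile is flat as phi -> 0; snap to the floor when
  # the boundary is at least as good.
  if (f(log(lower)) <= opt$objective + 1e-10) phi <- lower
  min(max(phi, lower), upper)
}

#' Fit a ridge-penalized negative binomial GLM by IRLS
#'
#' Maximizes `sum log NB(y; mu, phi) - 0.5 * sum(ridge * beta^2)` with
#' `log mu = X beta + offset` and `Var(y) = mu + phi mu^2`.  The dispersion
#' is either held fixed or profiled out by alternating coefficient and
#' dispersion updates.
#'
#' @param y non-negative integer response vector.
#' @param X design matrix (n x p).
#' @param offset optional log-scale offset (length n, default 0).
#' @param ridge non-negative penalty per coefficient (length p, recycled).
#' @param phi fixed dispersion (scalar or per-observation vector), or
#'   `"estimate"` for profile ML on `[1e-8, 1e8]`.
#' @param start optional starting coefficients.
#' @param max_iter maximum IRLS iterations per coefficient pass.
#' @param tol convergence tolerance on the penalized score norm.
#' @return list with `coefficients`, `phi`, `loglik` (unpenalized),
#'   `penalized_loglik`, `converged`, `iterations`.
#' @export
nb_irls_fit <- function(y, X, offset = NULL, ridge = 0, phi = "estimate",
                        start = NULL, max_iter = 100L, tol = 1e-6) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("dim mismatch between y and X")
  if (is.null(offset)) offset <- numeric(n)
  ridge <- rep_len(ridge, p)
  estimate_phi <- identical(phi, "estimate")
  if (estimate_phi && n <= p)
    stop("need n > p to estimate the dispersion")

  # all-zero response with an unpenalized intercept would diverge to -Inf;
  # clamp the fitted mean at 1e-8
  mu_floor <- 1e-8

  if (is.null(start)) {
    # moment start: intercept-like init via working response at mu = mean
    mu0 <- max(mean(y), mu_floor)
    z <- if (mean(y) > 0) log(mu0) + (y - mu0) / mu0 - offset
         else log(mu_floor) - offset
    beta <- tryCatch(stats::lm.fit(X, z)$coefficients,
                     error = function(e) numeric(p))
    beta[!is.finite(beta)] <- 0
  } else beta <- rep_len(start, p)

  # fixed phi may be a scalar or a per-observation vector
  phi_cur <- if (estimate_phi) 0.5 else rep_len(phi, n)
  if (any(phi_cur <= 0)) stop("phi must be positive")

  pen_ll <- function(beta, phi) {
    eta <- drop(X %*% beta) + offset
    mu <- pmax(exp(pmin(eta, 700)), mu_floor)
    nb_loglik(y, mu, phi) - 0.5 * sum(ridge * beta^2)
  }

  converged <- FALSE
  total_iter <- 0L
  n_outer <- if (estimate_phi) 8L else 1L
  for (outer in seq_len(n_outer)) {
    ll_old <- pen_ll(beta, phi_cur)
    for (it in seq_len(max_iter)) {
      total_iter <- total_iter + 1L
      eta <- drop(X %*% beta) + offset
      eta <- pmin(pmax(eta, log(mu_floor)), 700)
      mu <- exp(eta)
      w <- mu / (1 + phi_cur * mu)          # Fisher weights, log link
      score <- drop(crossprod(X, (y - mu) / (1 + phi_cur * mu))) - ridge * beta
      if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
      XtWX <- crossprod(X, X * w)
      diag(XtWX) <- diag(XtWX) + ridge
      step <- tryCatch(solve(XtWX, score), error = function(e) {
        solve(XtWX + diag(1e-8, p), score)
      })
      # step halving on the penalized log likelihood
      ll0 <- pen_ll(beta, phi_cur)
      fac <- 1
      for (h in 1:20) {
        cand <- beta + fac * step
        if (pen_ll(cand, phi_cur) >= ll0 - 1e-12) break
        fac <- fac / 2
      }
      beta <- beta + fac * step
    }
    if (!estimate_phi) break
    eta <- drop(X %*% beta) + offset
    mu <- pmax(exp(pmin(eta, 700)), mu_floor)
    phi_new <- nb_profile_phi(y, mu)
    ll_new <- pen_ll(beta, phi_new)
    phi_cur <- phi_new
    if (abs(ll_new - ll_old) < 1e-8 * (abs(ll_old) + 1)) break
  }

  eta <- drop(X %*% beta) + offset
  mu <- pmax(exp(pmin(eta, 700)), mu_floor)
  list(coefficients = beta,
       phi = phi_cur,
       loglik = nb_loglik(y, mu, phi_cur),
       penalized_loglik = pen_ll(beta, phi_cur),
       fitted = mu,
       converged = converged,
       iterations = total_iter)
}
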