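## Alternating estimation of the NB log-linear unwanted-variation model
##
##   y_ij ~ NB(mu_ij, phi_i),  log mu_ij = zeta_i + (M beta_i)_j + (W alpha_i)_j
##
## The replicate matrix M identifies the biological part; the latent sample
## scores W are estimated from negative-control taxa only.  The alternation:
## a taxon step updates (beta_i, alpha_i, phi_i) given W by a ridge NB fit
## on design [M | W] (ridge lambda_a on the alpha block); a sample step
## updates each row W_j given (beta, alpha, phi) by a ridge NB fit of the
## control-taxa counts on design t(alpha_C) with offset zeta_C + (M beta)_Cj
## (ridge lambda_b).  Identifiability: W columns centered (absorbed into
## beta), SVD-orthogonalized (W <- UD, alpha <- V' alpha; this preserves the
## likelihood and both penalty norms exactly), signs fixed against the
## initialization.  The control-taxa penalized likelihood
##   sum_{i in C} loglik_i - lambda_a/2 ||alpha_C||^2 - lambda_b/2 ||W||^2
## is non-decreasing over these steps and is recorded as the trace.

## Vectorized taxon step: all taxa share the design X = [M | W], so the
## per-taxon ridge IRLS updates can be computed with dense matrix algebra.
## Per inner iteration: Fisher weights and scores for every taxon at once,
## then T small p x p solves; candidate steps are accepted per taxon only if
## they do not decrease that taxon's penalized log likelihood (vectorized
## step halving), which keeps the alternation monotone.
taxon_step <- function(Y, X, B, phi, ridge, n_inner = 4L) {
  Tn <- nrow(Y); N <- ncol(Y); p <- ncol(X)
  pair_i <- rep(seq_len(p), times = p)
  pair_j <- rep(seq_len(p), each = p)
  Xpair <- X[, pair_i, drop = FALSE] * X[, pair_j, drop = FALSE]  # N x p^2

  pen_ll_rows <- function(B) {
    eta <- pmin(pmax(tcrossprod(t(B), X), log(1e-8)), 700)  # T x N
    mu <- exp(eta)
    ll <- stats::dnbinom(Y, size = 1 / phi, mu = mu, log = TRUE)
    rowSums(ll) - 0.5 * colSums(ridge * B^2)
  }

  ll_cur <- pen_ll_rows(B)
  for (it in seq_len(n_inner)) {
    eta <- pmin(pmax(tcrossprod(t(B), X), log(1e-8)), 700)
    mu <- exp(eta)
    denom <- 1 + phi * mu
    R <- (Y - mu) / denom                       # T x N working residuals
    score <- R %*% X - t(ridge * B)             # T x p
    CP <- (mu / denom) %*% Xpair                # T x p^2 : X'W_i X rows
    step <- matrix(0, Tn, p)
    jit <- ridge + 1e-10
    for (i in seq_len(Tn)) {
      H <- matrix(CP[i, ], p, p)
      diag(H) <- diag(H) + jit
      s <- try(solve(H, score[i, ]), silent = TRUE)
      if (inherits(s, "try-error"))
        s <- solve(H + diag(1e-6, p), score[i, ])
      step[i, ] <- s
    }
    fac <- rep(1, Tn)
    active <- rep(TRUE, Tn)
    for (h in 1:15) {
      cand <- B
      cand[, active] <- B[, active] + t(step[active, , drop = FALSE] *
                                          fac[active])
      ll_new <- pen_ll_rows(cand)
      ok <- ll_new >= ll_cur - 1e-10
      take <- active & ok
      B[, take] <- cand[, take]
      ll_cur[take] <- ll_new[take]
      active <- active & !ok
      if (!any(active)) break
      fac[active] <- fac[active] / 2
    }
    if (max(abs(score)) < 1e-6) break
  }
  list(B = B, pen_ll = ll_cur)
}

## Vectorized profile ML for per-taxon dispersion: bisection on the sign of
## the profile score in u = log(size), warm-started around the current phi
## and bounded to phi in [1e-8, 1e8]; falls back to the old phi for any
## taxon the update does not improve.
phi_step <- function(Y, mu, phi) {
  u_min <- log(1e-8); u_max <- log(1e8)
  score_u <- function(u) {                      # d loglik / d log(r), per taxon
    r <- exp(u)                                 # vector, recycles down rows
    g <- digamma(Y + r) - digamma(r) + log(r / (r + mu)) +
      (mu - Y) / (r + mu)
    rowSums(g) * r
  }
  u0 <- pmin(pmax(-log(phi), u_min), u_max)
  lo <- pmax(u0 - 2, u_min); hi <- pmin(u0 + 2, u_max)
  # expand brackets (doubling) until the score changes sign or hits bounds
  for (e in 1:6) {
    s_lo <- score_u(lo); s_hi <- score_u(hi)
    need_lo <- s_lo < 0 & lo > u_min
    need_hi <- s_hi > 0 & hi < u_max
    if (!any(need_lo | need_hi)) break
    w <- hi - lo
    lo[need_lo] <- pmax(lo[need_lo] - w[need_lo], u_min)
    hi[need_hi] <- pmin(hi[need_hi] + w[need_hi], u_max)
  }
  at_hi <- score_u(hi) >= 0   # likelihood still rising at r = 1e8 (Poisson)
  at_lo <- score_u(lo) <= 0
  for (b in 1:22) {
    mid <- (lo + hi) / 2
    up <- score_u(mid) > 0
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
  }
  r <- exp((lo + hi) / 2)
  r[at_hi] <- 1e8; r[at_lo] <- 1e-8
  phi_new <- pmin(pmax(1 / r, 1e-8), 1e8)
  ll_old <- rowSums(stats::dnbinom(Y, size = 1 / phi, mu = mu, log = TRUE))
  ll_new <- rowSums(stats::dnbinom(Y, size = 1 / phi_new, mu = mu, log = TRUE))
  ifelse(ll_new >= ll_old, phi_new, phi)
}

#' Fit the negative binomial unwanted-variation factor model
#'
#' @param counts taxa x samples integer matrix (validated).
#' @param M N x m binary replicate matrix ([build_replicate_matrix()]).
#' @param controls a [control_set()] naming the negative-control taxa.
#' @param k number of unwanted factors. If `|controls| <= k` it is lowered
#'   to `|controls| - 1` with a warning.
#' @param lambda_a ridge penalty on the taxon loadings alpha (default 0.01).
#' @param lambda_b ridge penalty on the sample scores W (default 5).
#' @param tol relative W-change convergence tolerance (default 1e-4).
#' @param max_iter maximum outer alternation cycles (default 50).
#' @param seed integer seed (recorded; the fit itself is deterministic).
#' @return object of class `ruv_fit`: `W` (N x k, columns centered and
#'   orthogonal), `alpha` (k x T), `beta` (m x T), `zeta` (T), `phi` (T),
#'   `M`, `control_taxa`, `k`, `lambda_a`, `lambda_b`, `converged`,
#'   `n_iter`, `penalized_loglik_trace`.
#' @export
fit_ruv3nb <- function(counts, M, controls, k = 7, lambda_a = 0.01,
                       lambda_b = 5, tol = 1e-4, max_iter = 50L,
                       seed = 1L) {
  validate_counts(counts)
  taxa <- rownames(counts); samples <- colnames(counts)
  N <- ncol(counts); Tn <- nrow(counts); m <- ncol(M)
  if (nrow(M) != N) stop("replicate matrix rows must match samples")
  ctrl <- intersect(controls$taxa_ids, taxa)
  drop_zero <- ctrl[rowSums(counts[ctrl, , drop = FALSE]) == 0]
  if (length(drop_zero)) {
    warning("dropping all-zero control taxa: ",
            paste(drop_zero, collapse = ", "))
    ctrl <- setdiff(ctrl, drop_zero)
  }
  if (length(ctrl) < 1) stop("no usable control taxa")
  if (length(ctrl) <= k) {
    warning(sprintf("only %d control taxa; lowering k from %d to %d",
                    length(ctrl), k, length(ctrl) - 1L))
    k <- length(ctrl) - 1L
  }
  if (k < 1) stop("k must be >= 1 (need |controls| >= 2)")
  if (any(colSums(counts) <= 0)) stop("every sample needs total count > 0")
  cidx <- match(ctrl, taxa)

  ## --- initialization -----------------------------------------------------
  lgm <- colMeans(log(counts + 1))            # per-sample log geometric mean
  W <- matrix(0, N, k, dimnames = list(samples, paste0("W", seq_len(k))))
  W[, 1L] <- if (stats::sd(lgm) > 0) (lgm - mean(lgm)) / stats::sd(lgm) else 0
  if (k > 1) {
    clr <- clr_transform(counts)[cidx, , drop = FALSE]
    ## remove biology: center within replicate groups
    gsize <- colSums(M)
    gmean <- clr %*% M %*% diag(1 / gsize, m)   # Tc x m group means
    resid <- clr - gmean %*% t(M)
    ## remove the depth direction already captured by W1
    w1 <- W[, 1L]
    if (sum(w1^2) > 0)
      resid <- resid - (resid %*% w1) %*% t(w1) / sum(w1^2)
    sv <- svd(resid, nu = 0, nv = k - 1L)
    W[, -1L] <- sv$v[, seq_len(k - 1L), drop = FALSE] *
      rep(sv$d[seq_len(k - 1L)] / sqrt(N), each = N)
  }
  W <- sweep(W, 2L, colMeans(W), "-")
  W_init <- W

  beta <- matrix(0, m, Tn, dimnames = list(colnames(M), taxa))
  alpha <- matrix(0, k, Tn, dimnames = list(colnames(W), taxa))
  phi <- rep(0.5, Tn)
  ridge_taxon <- c(rep(0, m), rep(lambda_a, k))
  group_of <- max.col(M)                      # sample -> group index

  pen_trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  y_ctrl <- counts[cidx, , drop = FALSE]

  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    W_old <- W

    ## --- taxon step: (beta_i, alpha_i, phi_i) | W -------------------------
    X <- cbind(M, W)
    B <- rbind(beta, alpha)
    ts <- taxon_step(counts, X, B, phi, ridge_taxon, n_inner = 4L)
    B <- ts$B
    eta <- pmin(pmax(tcrossprod(t(B), X), log(1e-8)), 700)
    phi <- phi_step(counts, exp(eta), phi)
    ts <- taxon_step(counts, X, B, phi, ridge_taxon, n_inner = 2L)
    B <- ts$B
    beta <- B[seq_len(m), , drop = FALSE]
    alpha <- B[m + seq_len(k), , drop = FALSE]

    ## --- sample step: W_j | (beta, alpha, phi) ----------------------------
    A <- t(alpha[, cidx, drop = FALSE])       # Tc x k design
    phi_c <- phi[cidx]
    for (j in seq_len(N)) {
      off <- beta[group_of[j], cidx]
      fit <- nb_irls_fit(y_ctrl[, j], A, offset = off,
                         ridge = lambda_b, phi = phi_c,
                         start = W[j, ], max_iter = 25L, tol = 1e-6)
      W[j, ] <- fit$coefficients
    }

    ## --- identifiability --------------------------------------------------
    cm <- colMeans(W)
    W <- sweep(W, 2L, cm, "-")
    beta <- beta + matrix(1, m, 1) %*% (t(cm) %*% alpha)  # absorb shift
    if (k > 1) {
      sv <- svd(W)
      W <- sv$u %*% diag(sv$d, k)
      alpha <- t(sv$v) %*% alpha
    }
    ## penalty-optimal scale allocation per column: s minimizing
    ## lambda_a s^2 ||alpha_c||^2 + lambda_b ||W_c||^2 / s^2 with the
    ## product W alpha unchanged.  Without it the alternation drifts into
    ## an alpha-heavy allocation that evades the ridge on W.
    for (c. in seq_len(k)) {
      na <- sum(alpha[c., ]^2); nw <- sum(W[, c.]^2)
      if (na > 0 && nw > 0) {
        s <- (lambda_b * nw / (lambda_a * na))^0.25
        W[, c.] <- W[, c.] / s
        alpha[c., ] <- alpha[c., ] * s
      }
    }
    sgn <- sapply(seq_len(k), function(c.) {
      s <- sum(W[, c.] * W_init[, c.])
      if (s < 0) -1 else 1
    })
    W <- sweep(W, 2L, sgn, "*")
    alpha <- sweep(alpha, 1L, sgn, "*")
    dimnames(W) <- list(samples, paste0("W", seq_len(k)))
    rownames(alpha) <- colnames(W)

    ## --- control-taxa penalized log likelihood ----------------------------
    eta_c <- t(beta[group_of, cidx, drop = FALSE]) + t(W %*% alpha[, cidx, drop = FALSE])
    mu_c <- exp(pmin(eta_c, 700))
    ll <- sum(stats::dnbinom(y_ctrl, size = rep(1 / phi_c, N),
                             mu = pmax(mu_c, 1e-8), log = TRUE)) -
      0.5 * lambda_a * sum(alpha[, cidx]^2) - 0.5 * lambda_b * sum(W^2)
    pen_trace <- c(pen_trace, ll)

    dW <- max(abs(W - W_old)) / (1 + max(abs(W)))
    if (dW < tol) { converged <- TRUE; break }
  }

  ## split intercept out of beta for reporting: zeta_i = mean_g beta_gi
  zeta <- colMeans(beta)
  beta <- sweep(beta, 2L, zeta, "-")

  structure(list(W = W, alpha = alpha, beta = beta,
                 zeta = stats::setNames(zeta, taxa),
                 phi = stats::setNames(phi, taxa),
                 M = M, control_taxa = ctrl,
                 k = k, lambda_a = lambda_a, lambda_b = lambda_b,
                 converged = converged, n_iter = n_iter,
                 penalized_loglik_trace = pen_trace,
                 seed = seed),
            class = "ruv_fit")
}

#' @export
print.ruv_fit <- function(x, ...) {
  cat(sprintf(
    "ruv_fit: %d taxa x %d samples, k = %d (lambda_a = %g, lambda_b = %g)\n",
    ncol(x$alpha), nrow(x$W), x$k, x$lambda_a, x$lambda_b))
  cat(sprintf("  %d control taxa; %s after %d iterations\n",
              length(x$control_taxa),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Fitted means of a ruv_fit
#'
#' @param fit a `ruv_fit`.
#' @param W_ref optional replacement sample scores (e.g. the zero matrix for
#'   the unwanted-variation-free reference model).
#' @return taxa x samples matrix of fitted NB means.
#' @export
ruv_fitted_mean <- function(fit, W_ref = NULL) {
  W <- if (is.null(W_ref)) fit$W else W_ref
  group_of <- max.col(fit$M)
  eta <- fit$zeta + t(fit$beta[group_of, , drop = FALSE]) +
    t(W %*% fit$alpha)
  exp(pmin(eta, 700))
}

#' Percentile-invariant adjusted counts
#'
#' Maps each observed count to the count with the same percentile under the
#' model with unwanted factors set to their reference value (the column
#' means of `W`, i.e. zero after centering).  For cell (i, j), with `F` the
#' NB CDF at the fitted mean and `F~` the CDF at the reference mean, the
#' percentile is the midpoint of `(F(y-1), F(y)]` (`mode = "mid"`,
#' deterministic) or a seeded uniform draw from that interval
#' (`mode = "randomized"`), and the adjusted count is the smallest
#' non-negative integer q with `F~(q) >= p`.
#'
#' @param fit a `ruv_fit`.
#' @param counts the count matrix the fit was estimated on.
#' @param mode `"mid"` (default, deterministic) or `"randomized"`.
#' @param seed required for `mode = "randomized"`.
#' @param w_ref optional 1 x k reference row for "adjust to sample s"
#'   semantics; default the column means of `W`.
#' @return list of class `adjusted_counts`: `pac` (integer matrix),
#'   `log_pac` (`log(pac + 1)`), `mode`, `seed`.
#' @export
percentile_adjusted_counts <- function(fit, counts, mode = c("mid", "randomized"),
                                       seed = NULL, w_ref = NULL) {
  mode <- match.arg(mode)
  if (mode == "randomized" && is.null(seed))
    stop("randomized mode requires an explicit seed")
  if (ncol(fit$alpha) != nrow(counts) || nrow(fit$W) != ncol(counts))
    stop("fit dimensions do not match the count matrix")
  mu_hat <- ruv_fitted_mean(fit)
  if (is.null(w_ref)) w_ref <- colMeans(fit$W)
  W_ref <- matrix(rep(w_ref, each = nrow(fit$W)), nrow(fit$W), fit$k)
  mu_ref <- ruv_fitted_mean(fit, W_ref = W_ref)

  Tn <- nrow(counts); N <- ncol(counts)
  size <- rep(1 / fit$phi, N)
  y <- as.vector(counts)
  mh <- as.vector(mu_hat); mr <- as.vector(mu_ref)
  Fy  <- stats::pnbinom(y, size = size, mu = mh)
  Fy1 <- ifelse(y > 0, stats::pnbinom(y - 1, size = size, mu = mh), 0)
  # upper-tail complements for precision deep in the right tail
  Sy  <- stats::pnbinom(y, size = size, mu = mh, lower.tail = FALSE)
  Sy1 <- ifelse(y > 0,
                stats::pnbinom(y - 1, size = size, mu = mh,
                               lower.tail = FALSE), 1)
  if (mode == "mid") {
    p <- (Fy1 + Fy) / 2
    ps <- (Sy1 + Sy) / 2
  } else {
    set.seed(seed)
    u <- stats::runif(length(y))
    p <- Fy1 + u * (Fy - Fy1)
    ps <- Sy1 - u * (Sy1 - Sy)
  }
  hi <- ps <= 1e-300
  if (any(hi)) {
    warning(sum(hi), " cells at the upper CDF boundary; capped")
    ps[hi] <- 1e-300
  }
  upper <- p > 0.5
  pac <- numeric(length(y))
  pac[!upper] <- stats::qnbinom(p[!upper], size = size[!upper],
                                mu = mr[!upper])
  pac[upper] <- stats::qnbinom(ps[upper], size = size[upper],
                               mu = mr[upper], lower.tail = FALSE)
  # identical fitted and reference distributions invert to the observation
  same <- abs(mr - mh) <= 1e-12 * (mh + 1e-12)
  pac[same] <- y[same]
  pac <- matrix(as.integer(pac), Tn, N, dimnames = dimnames(counts))
  structure(list(pac = pac, log_pac = log(pac + 1), mode = mode,
                 seed = seed),
            class = "adjusted_counts")
}

#' Serialize a ruv_fit to a directory of TSV files plus fit.json
#' @param fit a `ruv_fit`.
#' @param outdir output directory (created).
#' @export
write_ruv_fit <- function(fit, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(fit$W, file.path(outdir, "W.tsv"), id_col = "sample_id")
  write_matrix_tsv(fit$alpha, file.path(outdir, "alpha.tsv"), id_col = "factor")
  write_matrix_tsv(fit$beta, file.path(outdir, "beta.tsv"), id_col = "group")
  utils::write.table(
    data.frame(taxon_id = names(fit$zeta), zeta = fit$zeta, phi = fit$phi),
    file.path(outdir, "zeta_phi.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(k = fit$k, lambda_a = fit$lambda_a, lambda_b = fit$lambda_b,
         seed = fit$seed, n_iter = fit$n_iter, converged = fit$converged,
         control_taxa = fit$control_taxa),
    file.path(outdir, "fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Write adjusted counts as pac.tsv / log_pac.tsv
#' @param adj an `adjusted_counts` object.
#' @param outdir output directory (created).
#' @export
write_adjusted_counts <- function(adj, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(adj$pac, file.path(outdir, "pac.tsv"))
  write_matrix_tsv(adj$log_pac, file.path(outdir, "log_pac.tsv"))
  invisible(outdir)
}
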