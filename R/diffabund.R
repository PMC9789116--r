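## NB differential abundance testing with optional unwanted-factor
## covariates, TMM effective library sizes, BH correction and Storey pi0.

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors that multiply raw library sizes into
#' effective sizes (delegates to edgeR's implementation; the reference
#' sample is the one whose 75th-percentile CPM is closest to the mean, and
#' the returned factors have geometric mean 1).
#'
#' @param counts taxa x samples matrix.
#' @param logratio_trim trim fraction on log ratios (default 0.3).
#' @param abs_trim trim fraction on absolute intensities (default 0.05).
#' @return named positive per-sample factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(colSums(counts) <= 0)) stop("samples with zero totals")
  f <- edgeR::calcNormFactors(as.matrix(counts), method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  stats::setNames(f, colnames(counts))
}

#' Per-taxon NB likelihood-ratio test for a two-group contrast
#'
#' For every taxon, fits the full model
#' `log mu = intercept + gamma * group + covariates + log(effective library
#' size)` and the reduced model without the group term, and tests
#' `gamma = 0` by a likelihood-ratio test against chi-squared(1).  The
#' dispersion is profiled under the full model and held fixed for the
#' reduced fit.  Unwanted-factor scores estimated by [fit_ruv3nb()] are the
#' intended `covariates`.
#'
#' @param counts taxa x samples matrix.
#' @param group binary labels (factor/character/logical), length N.
#' @param covariates optional N x c numeric matrix.
#' @param use_tmm use TMM effective library sizes (default TRUE).
#' @param moderate_dispersion shrink each taxon's ML dispersion toward a
#'   lowess mean-dispersion trend (prior weight `prior_df`) before the LRT
#'   (default TRUE).  Moderation keeps taxa whose counts are inflated by
#'   structure from absorbing that structure into their own dispersion,
#'   which would otherwise mask real differences.
#' @param prior_df prior degrees of freedom for the dispersion shrinkage;
#'   `Inf` uses the trended dispersion alone (appropriate for screening and
#'   ranking applications, where per-taxon dispersion freedom lets
#'   structure-inflated taxa evade detection).
#' @return object of class `da_result` with `table` (taxon_id, log2fc,
#'   lrt_stat, pvalue, qvalue, flagged), `pi0`, `design_description`.
#' @export
nb_da_test <- function(counts, group, covariates = NULL, use_tmm = TRUE,
                       moderate_dispersion = TRUE, prior_df = 10) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  if (any(table(group) == 0)) stop("both groups must be non-empty")
  N <- ncol(counts)
  if (length(group) != N) stop("group length must match samples")
  lib <- colSums(counts)
  if (use_tmm) lib <- lib * tmm_factors(counts)
  off <- log(lib)
  g <- as.numeric(group == levels(group)[2])
  Xr <- matrix(1, N, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (any(!is.finite(covariates))) stop("covariates must be finite")
    Xr <- cbind(Xr, covariates)
  }
  Xf <- cbind(Xr[, 1, drop = FALSE], group = g,
              if (!is.null(covariates)) covariates)

  Tn <- nrow(counts)
  log2fc <- lrt <- pv <- numeric(Tn)
  flagged <- logical(Tn)
  nonzero <- rowSums(counts) > 0

  # pass 1: per-taxon ML dispersion under the full model
  full_fits <- vector("list", Tn)
  phi_ml <- rep(NA_real_, Tn)
  for (i in which(nonzero)) {
    full_fits[[i]] <- nb_irls_fit(counts[i, ], Xf, offset = off, ridge = 0,
                                  phi = "estimate")
    phi_ml[i] <- full_fits[[i]]$phi
  }

  phi_use <- phi_ml
  if (moderate_dispersion && sum(nonzero) >= 10) {
    # lowess trend of log dispersion on log mean CPM, then weighted
    # geometric shrinkage with prior_df pseudo-observations.  The
    # trended-only screening mode (prior_df = Inf) refits the trend through
    # the taxa at or below the first fit, so taxa whose dispersion is
    # inflated by structure cannot drag the trend up; the finite-prior mode
    # keeps the plain trend, which preserves type-I calibration.
    amean <- log(rowMeans(sweep(counts, 2, lib, "/") * 1e6)[nonzero] + 0.5)
    lphi <- log(pmin(pmax(phi_ml[nonzero], 1e-6), 1e4))
    tr <- stats::lowess(amean, lphi, f = 0.5)
    ltrend <- stats::approx(tr$x, tr$y, xout = amean, rule = 2,
                            ties = mean)$y
    if (is.infinite(prior_df)) {
      low <- lphi <= ltrend
      if (sum(low) >= 10) {
        tr2 <- stats::lowess(amean[low], lphi[low], f = 0.5)
        ltrend <- stats::approx(tr2$x, tr2$y, xout = amean, rule = 2,
                                ties = mean)$y
      }
      phi_use[nonzero] <- exp(ltrend)
    } else {
      w_obs <- N - ncol(Xf)
      phi_use[nonzero] <- exp((w_obs * lphi + prior_df * ltrend) /
                                (w_obs + prior_df))
    }
  }

  # pass 2: LRT at the (possibly moderated) dispersion
  for (i in seq_len(Tn)) {
    y <- counts[i, ]
    if (!nonzero[i]) {
      log2fc[i] <- 0; lrt[i] <- 0; pv[i] <- 1; flagged[i] <- TRUE
      next
    }
    full <- if (phi_use[i] == phi_ml[i]) full_fits[[i]] else
      nb_irls_fit(y, Xf, offset = off, ridge = 0, phi = phi_use[i],
                  start = full_fits[[i]]$coefficients)
    red <- nb_irls_fit(y, Xr, offset = off, ridge = 0, phi = phi_use[i])
    stat <- max(0, 2 * (full$loglik - red$loglik))
    lrt[i] <- stat
    pv[i] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    log2fc[i] <- full$coefficients[2] / log(2)
    flagged[i] <- !(full$converged && red$converged)
  }
  qv <- stats::p.adjust(pv, method = "BH")
  pi0 <- storey_pi0(pv)
  desc <- sprintf("NB-LRT: ~ group%s, offset log(%s library size)%s",
                  if (is.null(covariates)) ""
                  else sprintf(" + %d covariates", ncol(covariates)),
                  if (use_tmm) "TMM-effective" else "raw",
                  if (moderate_dispersion) ", trend-moderated dispersion"
                  else "")
  structure(list(table = data.frame(taxon_id = rownames(counts),
                                    log2fc = log2fc, lrt_stat = lrt,
                                    pvalue = pv, qvalue = qv,
                                    flagged = flagged,
                                    stringsAsFactors = FALSE),
                 pi0 = pi0, design_description = desc),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat("da_result:", nrow(x$table), "taxa;", x$design_description, "\n")
  cat(sprintf("  pi0 = %.3f; %d taxa at q < 0.05 & |log2FC| > 1\n", x$pi0,
              length(significant_taxa(x))))
  invisible(x)
}

#' Significant taxa at FDR and fold-change thresholds
#'
#' @param res a `da_result`.
#' @param q_threshold FDR cutoff (default 0.05).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @return character vector of taxon ids.
#' @export
significant_taxa <- function(res, q_threshold = 0.05, lfc_threshold = 1) {
  tab <- res$table
  tab$taxon_id[!tab$flagged & tab$qvalue < q_threshold &
                 abs(tab$log2fc) > lfc_threshold]
}

#' Storey estimate of the proportion of null hypotheses
#'
#' Computes `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` on a grid,
#' fits a 3-df cubic smoothing spline in lambda, and evaluates it at the
#' largest lambda, clamped to `[0, 1]`.
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @param lambda_grid evaluation grid (default `seq(0.05, 0.95, 0.05)`).
#' @return scalar in `[0, 1]`.
#' @export
storey_pi0 <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  pvalues <- pvalues[!is.na(pvalues)]
  m <- length(pvalues)
  if (m < 20) {
    warning("fewer than 20 p-values; falling back to lambda = 0.5")
    return(min(1, max(0, sum(pvalues > 0.5) / (m * 0.5))))
  }
  pi0_l <- vapply(lambda_grid,
                  function(l) sum(pvalues > l) / (m * (1 - l)), 0)
  sp <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
  min(1, max(0, stats::predict(sp, x = max(lambda_grid))$y))
}

#' Write a da_result as TSV plus a JSON sidecar
#' @param res `da_result`.
#' @param path output TSV path; sidecar at `<path>.json`.
#' @export
write_da_result <- function(res, path) {
  utils::write.table(res$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(pi0 = res$pi0,
                            design = res$design_description),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
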