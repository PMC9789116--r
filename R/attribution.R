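## Attribution of unwanted factors to taxa via cumulative NB GLM
## pseudo-R-squared: for each taxon, models with W1, W1+W2, ... are fitted
## and each factor's contribution is the increment in Veall-Zimmermann
## pseudo-R2 over the previous model.

#' Veall-Zimmermann pseudo-R-squared
#'
#' `G2 = 2 (llik_model - llik_null)`; the Aldrich-Nelson ratio
#' `G2 / (G2 + n)` is rescaled by its Veall-Zimmermann upper bound
#' `(2 llik_null - n) / (2 llik_null)` and clamped to `[0, 1]`.
#'
#' @param loglik_model log likelihood of the fitted model.
#' @param loglik_null log likelihood of the intercept-only null (< 0).
#' @param n number of observations.
#' @return scalar in `[0, 1]`.
#' @export
veall_zimmermann_r2 <- function(loglik_model, loglik_null, n) {
  if (loglik_null >= 0) stop("degenerate null log likelihood (>= 0)")
  if (loglik_model < loglik_null - 1e-8)
    stop("model log likelihood below the null")
  g2 <- 2 * (loglik_model - loglik_null)
  r2_an <- g2 / (g2 + n)
  r2 <- r2_an * (2 * loglik_null - n) / (2 * loglik_null)
  min(1, max(0, r2))
}

## NB fit of y ~ X (intercept included in X), no offset; returns loglik.
## MASS::glm.nb is the primary route, with the package IRLS as fallback
## for fits glm.nb fails to converge on.
nb_fit_loglik <- function(y, X) {
  ll <- tryCatch({
    df <- as.data.frame(X[, -1, drop = FALSE])
    fit <- if (ncol(df) == 0)
      suppressWarnings(MASS::glm.nb(y ~ 1,
                                    control = stats::glm.control(maxit = 50)))
    else
      suppressWarnings(MASS::glm.nb(y ~ ., data = df,
                                    control = stats::glm.control(maxit = 50)))
    as.numeric(stats::logLik(fit))
  }, error = function(e) NA_real_)
  if (!is.finite(ll)) {
    f <- nb_irls_fit(y, X, ridge = 0, phi = "estimate")
    if (!f$converged) return(list(loglik = f$loglik, ok = FALSE))
    ll <- f$loglik
  }
  list(loglik = ll, ok = TRUE)
}

#' Cumulative pseudo-R2 attribution of unwanted factors to taxa
#'
#' For each taxon i and each n in 1..k, fits an NB GLM of the raw counts on
#' intercept + W columns 1..n (no library-size offset: the first factor is
#' expected to carry sequencing depth) and computes the Veall-Zimmermann
#' pseudo-R2 against the intercept-only null.  `delta_r2[i, n]` is the
#' increment over the model with n-1 factors, floored at 0 (raw values kept
#' in `delta_r2_raw`).
#'
#' @param counts taxa x samples matrix.
#' @param W N x k matrix of unwanted factor scores.
#' @return list of class `attribution_result`: `delta_r2`, `delta_r2_raw`,
#'   `cumulative_r2` (T x k), `converged` (per taxon).
#' @export
cumulative_pseudo_r2 <- function(counts, W) {
  W <- as.matrix(W)
  if (any(!is.finite(W))) stop("W must be finite")
  N <- ncol(counts); k <- ncol(W)
  if (nrow(W) != N) stop("W rows must match samples")
  Tn <- nrow(counts)
  fn <- colnames(W) %||% paste0("W", seq_len(k))
  cum <- matrix(NA_real_, Tn, k, dimnames = list(rownames(counts), fn))
  ok <- rep(TRUE, Tn)
  for (i in seq_len(Tn)) {
    y <- counts[i, ]
    if (all(y == 0)) { ok[i] <- FALSE; next }
    null <- nb_fit_loglik(y, matrix(1, N, 1))
    if (!null$ok || null$loglik >= 0) { ok[i] <- FALSE; next }
    prev <- null$loglik
    for (n in seq_len(k)) {
      f <- nb_fit_loglik(y, cbind(1, W[, seq_len(n), drop = FALSE]))
      ll <- max(f$loglik, prev)   # nested models cannot lose likelihood
      if (!f$ok) ok[i] <- FALSE
      cum[i, n] <- veall_zimmermann_r2(ll, null$loglik, N)
      prev <- ll
    }
    cum[i, ] <- cummax(cum[i, ])
  }
  raw <- cbind(cum[, 1, drop = FALSE],
               cum[, -1, drop = FALSE] - cum[, -k, drop = FALSE])
  colnames(raw) <- fn
  structure(list(delta_r2 = pmax(raw, 0), delta_r2_raw = raw,
                 cumulative_r2 = cum, converged = ok),
            class = "attribution_result")
}

#' Top taxa most affected by one unwanted factor
#'
#' Ranks taxa by `delta_r2[, factor]` descending (ties by taxon id),
#' excluding non-convergent fits, and tabulates the class composition of
#' the top set; classes with fewer than 2 members in the top set are merged
#' into `"others"`.
#'
#' @param attr an `attribution_result`.
#' @param factor factor index or name.
#' @param n_top number of taxa (default 100).
#' @param classes optional named map taxon -> class label.
#' @return list `taxa` (ranked data.frame taxon_id, delta_r2, class),
#'   `class_counts` (table with "others" merging).
#' @export
top_affected <- function(attr, factor = 1, n_top = 100, classes = NULL) {
  d <- attr$delta_r2[, factor]
  ids <- rownames(attr$delta_r2)
  keep <- attr$converged
  ord <- order(-d[keep], ids[keep])
  sel <- ids[keep][ord][seq_len(min(n_top, sum(keep)))]
  out <- data.frame(taxon_id = sel, delta_r2 = d[sel],
                    class = if (is.null(classes)) NA_character_
                            else as.character(classes[sel]),
                    stringsAsFactors = FALSE)
  cc <- NULL
  if (!is.null(classes)) {
    tab <- table(out$class)
    small <- names(tab)[tab < 2]
    merged <- out$class
    merged[merged %in% small] <- "others"
    cc <- sort(table(merged), decreasing = TRUE)
  }
  list(taxa = out, class_counts = cc)
}

#' Mean per-sample abundance proportion of a taxon set
#'
#' Per sample, the fraction of the library belonging to `top_taxa`; the
#' mean over samples is returned.
#'
#' @param counts taxa x samples matrix.
#' @param top_taxa character vector of taxon ids (subset of the matrix).
#' @return scalar in `[0, 1]`.
#' @export
affected_abundance_proportion <- function(counts, top_taxa) {
  if (length(top_taxa) == 0) return(0)
  if (!all(top_taxa %in% rownames(counts)))
    stop("top_taxa must be a subset of the matrix taxa")
  mean(colSums(counts[top_taxa, , drop = FALSE]) / colSums(counts))
}

#' Write an attribution result as TSV plus JSON summary
#' @param attr `attribution_result`.
#' @param path output TSV path (per-taxon delta-R2); JSON summary with top
#'   sets and abundance proportions at `<path>.json`.
#' @param counts count matrix for the abundance proportions.
#' @param classes optional taxon -> class map.
#' @param n_top size of the per-factor top sets (default 100).
#' @export
write_attribution <- function(attr, path, counts, classes = NULL,
                              n_top = 100) {
  df <- data.frame(taxon_id = rownames(attr$delta_r2), attr$delta_r2,
                   converged = attr$converged, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tops <- lapply(seq_len(ncol(attr$delta_r2)), function(f) {
    tp <- top_affected(attr, f, n_top, classes)
    list(factor = colnames(attr$delta_r2)[f],
         taxa = tp$taxa$taxon_id,
         abundance_proportion =
           affected_abundance_proportion(counts, tp$taxa$taxon_id))
  })
  jsonlite::write_json(tops, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
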