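## Factor-analytic baselines operating on log-scale (CLR) matrices:
## control-taxa SVD (RUVg-style) and replicate-centered control-taxa SVD
## (RUVs-style).  Both estimate sample scores W from the controls and
## remove the least-squares projection of every taxon on W.

ruv_log_adjust <- function(logm, W, M = NULL) {
  ## alpha-hat = taxa x k regression on W; rows are centered first (within
  ## replicate groups when M is given, so biology cannot leak into alpha)
  if (is.null(M)) {
    Xc <- logm - rowMeans(logm)
    Wc <- W
  } else {
    gsize <- colSums(M)
    Xc <- logm - (logm %*% M %*% diag(1 / gsize, ncol(M))) %*% t(M)
    Wc <- W - M %*% diag(1 / gsize, ncol(M)) %*% (t(M) %*% W)
  }
  A <- Xc %*% Wc %*% solve(crossprod(Wc))
  adjusted <- logm - A %*% t(W)
  list(adjusted = adjusted, alpha = A)
}

#' RUVg-style correction: control-taxa SVD on a log-scale matrix
#'
#' `W` is the first `k` right-singular directions (sample scores, scaled by
#' the singular values) of the row-centered control submatrix; the adjusted
#' matrix removes each taxon's least-squares projection on `W`.
#'
#' @param logm taxa x samples log-scale matrix (CLR recommended).
#' @param controls a [control_set()] (or character vector) of control taxa.
#' @param k number of unwanted factors, `1 <= k <= rank of the control
#'   submatrix`.
#' @return list `W` (N x k), `adjusted` (same shape as `logm`), `alpha`.
#' @export
ruvg <- function(logm, controls, k) {
  ids <- if (inherits(controls, "control_set")) controls$taxa_ids
         else as.character(controls)
  ids <- intersect(ids, rownames(logm))
  if (length(ids) < k) stop("need |controls| >= k")
  if (k < 1) stop("k must be >= 1")
  C <- logm[ids, , drop = FALSE]
  C <- C - rowMeans(C)
  sv <- svd(C)
  if (sum(sv$d > 1e-10) < k) stop("k exceeds the rank of the control submatrix")
  W <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(W) <- colnames(logm); colnames(W) <- paste0("W", seq_len(k))
  adj <- ruv_log_adjust(logm, W)
  list(W = W, adjusted = adj$adjusted, alpha = adj$alpha)
}

#' RUVs-style correction: replicate-centered control-taxa SVD
#'
#' As [ruvg()], but the control rows are centered within each replicate
#' group before the SVD, so biological differences between groups cannot
#' leak into `W`.
#'
#' @inheritParams ruvg
#' @param M N x m binary replicate matrix; at least one group of size >= 2.
#' @export
ruvs <- function(logm, controls, M, k) {
  if (all(colSums(M) < 2)) stop("all replicate groups are singletons")
  ids <- if (inherits(controls, "control_set")) controls$taxa_ids
         else as.character(controls)
  ids <- intersect(ids, rownames(logm))
  if (length(ids) < k) stop("need |controls| >= k")
  if (k < 1) stop("k must be >= 1")
  C <- logm[ids, , drop = FALSE]
  gsize <- colSums(M)
  gmean <- C %*% M %*% diag(1 / gsize, ncol(M))
  Cc <- C - gmean %*% t(M)
  sv <- svd(Cc)
  if (sum(sv$d > 1e-10) < k) stop("k exceeds the rank of the control submatrix")
  W <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(W) <- colnames(logm); colnames(W) <- paste0("W", seq_len(k))
  adj <- ruv_log_adjust(logm, W, M)
  list(W = W, adjusted = adj$adjusted, alpha = adj$alpha)
}
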