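## Correction-quality metrics: RLE summaries with Omega_RLE and NCC_RLE,
## PCA + silhouette by biology and by batch, correlation of estimated
## unwanted factors with known experimental factors, spike-in CPM ratios.

#' Relative log expression matrix
#'
#' `RLE_ij = logm_ij - median_j(logm_i.)`: each taxon row is centered on its
#' cross-sample median.
#'
#' @param logm taxa x samples real matrix (log scale).
#' @return matrix of the same shape, row medians 0.
#' @export
rle_matrix <- function(logm) {
  if (any(!is.finite(logm))) stop("log matrix must be finite")
  med <- apply(logm, 1L, stats::median)
  sweep(logm, 1L, med, "-")
}

## dummy-code metadata factors, dropping each factor's reference level and
## any collinear columns
dummy_code <- function(md, factors) {
  cols <- lapply(factors, function(f) {
    v <- as.factor(md[[f]])
    if (nlevels(v) < 2) return(NULL)
    m <- stats::model.matrix(~ v)[, -1, drop = FALSE]
    colnames(m) <- paste0(f, "_", levels(v)[-1])
    m
  })
  D <- do.call(cbind, cols)
  if (is.null(D) || ncol(D) == 0) stop("no usable factor columns")
  q <- qr(scale(D, scale = FALSE))
  if (q$rank < ncol(D)) {
    warning("dropping collinear factor columns")
    D <- D[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  D
}

#' Per-sample RLE summary and the Omega_RLE quality score
#'
#' Summarizes an RLE matrix by the per-sample median and IQR over taxa,
#' then scores how tightly these summaries agree within biological groups:
#' `V_med` and `V_iqr` are the means over groups (of size >= 2) of the
#' within-group variances of the medians and IQRs, and
#' `omega = -log(V_med + V_iqr)` (natural log).  Perfect replicates give an
#' infinite omega, reported as the sentinel 1e9 with `capped = TRUE`.
#'
#' @param rle RLE matrix ([rle_matrix()]).
#' @param groups per-sample biological grouping (length N).
#' @return list of class `rle_summary`: `sample_median`, `sample_iqr`,
#'   `groups`, `V_med`, `V_iqr`, `omega`, `capped`.
#' @export
rle_quality <- function(rle, groups) {
  N <- ncol(rle)
  if (length(groups) != N) stop("groups must match samples")
  med <- apply(rle, 2L, stats::median)
  iqr <- apply(rle, 2L, stats::IQR, type = 7)
  sz <- table(groups)
  use <- names(sz)[sz >= 2]
  if (length(use) == 0) stop("all groups are singletons")
  vm <- mean(vapply(use, function(g) stats::var(med[groups == g]), 0))
  vi <- mean(vapply(use, function(g) stats::var(iqr[groups == g]), 0))
  tot <- vm + vi
  capped <- tot <= 0
  omega <- if (capped) 1e9 else -log(tot)
  structure(list(sample_median = med, sample_iqr = iqr, groups = groups,
                 V_med = vm, V_iqr = vi, omega = omega, capped = capped),
            class = "rle_summary")
}

#' @export
print.rle_summary <- function(x, ...) {
  cat(sprintf("rle_summary: V_med = %.4g, V_iqr = %.4g, omega = %.4g%s\n",
              x$V_med, x$V_iqr, x$omega, if (x$capped) " (capped)" else ""))
  invisible(x)
}

## canonical correlations between two centered matrices; returns the vector
## of correlations (possibly empty when either side has no variance)
canonical_cors <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  keep_x <- apply(X, 2L, stats::sd) > 0
  keep_y <- apply(Y, 2L, stats::sd) > 0
  if (!any(keep_x) || !any(keep_y)) return(numeric(0))
  cc <- stats::cancor(X[, keep_x, drop = FALSE], Y[, keep_y, drop = FALSE])
  pmin(pmax(cc$cor, 0), 1)
}

#' NCC_RLE: residual association of RLE summaries with known factors
#'
#' Computes the canonical correlations between the N x 2 matrix of
#' per-sample RLE medians and IQRs and the dummy-coded known unwanted
#' factors, aggregates them as the total canonical correlation
#' `sqrt(1 - prod(1 - rho_i^2))` (the Wilks-lambda complement), and returns
#' `1 - total`.  Values near 1 mean the RLE summaries carry no detectable
#' batch signal.
#'
#' @param rs an `rle_summary`, or an N x 2 matrix of (median, IQR).
#' @param md sample metadata.
#' @param factors metadata factor names regarded as known unwanted factors.
#' @return scalar in `[0, 1]`.
#' @export
rle_ncc <- function(rs, md, factors = metadata_factor_names(md)) {
  S <- if (inherits(rs, "rle_summary"))
    cbind(median = rs$sample_median, iqr = rs$sample_iqr) else as.matrix(rs)
  D <- dummy_code(md[match(rownames(S) %||% md$sample_id, md$sample_id), ],
                  factors)
  if (nrow(S) <= ncol(D) + ncol(S)) stop("too few samples for NCC")
  rho <- canonical_cors(S, D)
  if (length(rho) == 0) return(1)
  total <- sqrt(1 - prod(1 - rho^2))
  1 - total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal-component sample scores
#'
#' Samples are observations and taxa are variables; variables are centered,
#' not scaled.  Scores come from the SVD, with each component's sign fixed
#' so its largest-magnitude loading is positive.
#'
#' @param m taxa x samples real matrix.
#' @param n_components number of PCs (default 4).
#' @return list `scores` (N x n), `explained` (variance fractions).
#' @export
pca_scores <- function(m, n_components = 4) {
  N <- ncol(m)
  if (N <= n_components) stop("need more samples than components")
  X <- t(m)                                   # samples x taxa
  X <- sweep(X, 2L, colMeans(X), "-")
  if (all(abs(X) < 1e-12)) {
    warning("constant matrix; zero scores")
    return(list(scores = matrix(0, N, n_components,
                                dimnames = list(colnames(m),
                                                paste0("PC", 1:n_components))),
                explained = rep(0, n_components)))
  }
  sv <- svd(X, nu = n_components, nv = n_components)
  sgn <- vapply(seq_len(n_components), function(c.) {
    v <- sv$v[, c.]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_components)], n_components),
                  2L, sgn, "*")
  dimnames(scores) <- list(colnames(m), paste0("PC", seq_len(n_components)))
  list(scores = scores,
       explained = sv$d[seq_len(n_components)]^2 / sum(svd(X)$d^2))
}

#' Average silhouette width of samples under a labelling
#'
#' Standard silhouette on Euclidean distances (via the cluster package):
#' `s(i) = (b - a) / max(a, b)` with `a` the mean intra-label distance and
#' `b` the smallest mean distance to another label; singleton labels score 0.
#'
#' @param scores N x d score matrix (e.g. first four PCs).
#' @param labels per-sample labels, >= 2 distinct.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_by_label <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need >= 2 labels")
  sil <- cluster::silhouette(as.integer(droplevels(labels)),
                             dist = stats::dist(scores))
  mean(sil[, "sil_width"])
}

#' Correlate estimated unwanted factors with known sample covariates
#'
#' For each column of `W`: numeric covariates give |Pearson r| (sign kept in
#' `signed`); categorical metadata factors give the canonical correlation
#' with the dummy-coded factor.
#'
#' @param W N x k matrix of estimated factor scores.
#' @param md sample metadata.
#' @param factors metadata factor names (default all).
#' @param numeric_covariates optional named list/data.frame of numeric
#'   per-sample covariates (e.g. log library size, log geometric mean).
#' @return data.frame (w_column, covariate, correlation, signed).
#' @export
factor_correlation <- function(W, md, factors = metadata_factor_names(md),
                               numeric_covariates = NULL) {
  W <- as.matrix(W)
  md <- md[match(rownames(W) %||% md$sample_id, md$sample_id), ]
  out <- list()
  for (c. in seq_len(ncol(W))) {
    w <- W[, c.]
    wn <- colnames(W)[c.] %||% paste0("W", c.)
    if (stats::sd(w) == 0) {
      for (f in factors)
        out[[length(out) + 1L]] <- data.frame(
          w_column = wn, covariate = f, correlation = 0, signed = NA_real_)
      next
    }
    for (f in factors) {
      rho <- canonical_cors(matrix(w), dummy_code(md, f))
      total <- if (length(rho)) sqrt(1 - prod(1 - rho^2)) else 0
      out[[length(out) + 1L]] <- data.frame(
        w_column = wn, covariate = f, correlation = total,
        signed = NA_real_)
    }
    if (!is.null(numeric_covariates)) {
      for (nm in names(numeric_covariates)) {
        r <- stats::cor(w, numeric_covariates[[nm]])
        out[[length(out) + 1L]] <- data.frame(
          w_column = wn, covariate = nm, correlation = abs(r), signed = r)
      }
    }
  }
  do.call(rbind, out)
}

#' Spiked vs unspiked mean-CPM ratio for selected taxa
#'
#' @param counts taxa x samples matrix.
#' @param md metadata with a logical `spiked` column partitioning samples.
#' @param taxa a [control_set()] (or character vector) of taxa to score.
#' @return data.frame (taxon_id, cpm_spiked, cpm_unspiked, ratio, flagged);
#'   `ratio` is `Inf` when the unspiked mean is 0 and `NaN` (flagged) when
#'   both means are 0.
#' @export
control_cpm_ratio <- function(counts, md, taxa) {
  md <- validate_metadata(md)
  if (!"spiked" %in% colnames(md)) stop("metadata lacks a spiked flag")
  md <- md[match(colnames(counts), md$sample_id), ]
  if (!any(md$spiked) || !all(is.finite(md$spiked)) || all(md$spiked))
    stop("spiked flag must partition samples into two non-empty sets")
  ids <- if (inherits(taxa, "control_set")) taxa$taxa_ids else as.character(taxa)
  cpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  sp <- rowMeans(cpm[ids, md$spiked, drop = FALSE])
  un <- rowMeans(cpm[ids, !md$spiked, drop = FALSE])
  ratio <- sp / un
  data.frame(taxon_id = ids, cpm_spiked = sp, cpm_unspiked = un,
             ratio = ratio, flagged = sp == 0 & un == 0)
}

#' Full evaluation report for a corrected log-scale matrix
#'
#' Bundles the RLE summary (Omega_RLE), NCC_RLE against the known unwanted
#' factors, and first-four-PC silhouette widths by each requested labelling.
#'
#' @param logm corrected taxa x samples log-scale matrix (e.g. CLR or
#'   log-PAC).
#' @param md sample metadata.
#' @param bio_groups per-sample biological grouping for the RLE variances
#'   (default `replicate_group`).
#' @param silhouette_labels named list of per-sample label vectors.
#' @param unwanted_factors metadata factor names for NCC_RLE.
#' @return list of class `evaluation_report`.
#' @export
evaluate_correction <- function(logm, md,
                                bio_groups = NULL,
                                silhouette_labels = NULL,
                                unwanted_factors = metadata_factor_names(md)) {
  md <- md[match(colnames(logm), md$sample_id), ]
  if (is.null(bio_groups)) bio_groups <- md$replicate_group
  rle <- rle_matrix(logm)
  rs <- rle_quality(rle, bio_groups)
  ncc <- rle_ncc(rs, md, unwanted_factors)
  pcs <- pca_scores(logm, 4)
  sil <- if (is.null(silhouette_labels)) list() else
    lapply(silhouette_labels, function(l) silhouette_by_label(pcs$scores, l))
  structure(list(rle = rs, ncc = ncc, silhouette = sil,
                 pca_explained = pcs$explained),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: omega = %.3f, NCC_RLE = %.3f\n",
              x$rle$omega, x$ncc))
  for (nm in names(x$silhouette))
    cat(sprintf("  silhouette[%s] = %.3f\n", nm, x$silhouette[[nm]]))
  invisible(x)
}

#' Serialize an evaluation report as JSON
#' @param report `evaluation_report`.
#' @param path output path.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(
    list(V_med = report$rle$V_med, V_iqr = report$rle$V_iqr,
         omega = report$rle$omega, capped = report$rle$capped,
         ncc_rle = report$ncc,
         silhouette = report$silhouette,
         pca_explained = report$pca_explained),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
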