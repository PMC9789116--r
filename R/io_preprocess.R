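## Count matrices are plain integer matrices, taxa in rows, samples in
## columns, with mandatory unique dimnames.  validate_counts() is the single
## gatekeeper every entry point funnels through.

#' Validate a taxon-by-sample count matrix
#'
#' Checks the invariants every downstream function assumes: a numeric matrix
#' with unique taxon rownames and sample colnames, all entries finite,
#' non-negative and integral, at least one taxon and two samples.
#'
#' @param counts matrix to validate.
#' @return The matrix, invisibly, with integer storage mode.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stop("need at least 1 taxon and 2 samples")
  if (any(!is.finite(counts)))
    stop("non-numeric or missing cells in count matrix")
  if (any(counts < 0))
    stop("negative counts are not allowed")
  if (any(counts != round(counts)))
    stop("non-integer counts are not allowed")
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read a count matrix from a delimited file
#'
#' Expects a header row of sample ids and taxon ids in the first column
#' (the canonical taxa-in-rows layout); `orientation = "samples_in_rows"`
#' accepts the transpose.
#'
#' @param path path to a TSV/CSV file.
#' @param orientation `"taxa_in_rows"` (default) or `"samples_in_rows"`.
#' @param sep field separator; default tab.
#' @return Validated integer matrix, taxa in rows.
#' @export
read_counts <- function(path, orientation = c("taxa_in_rows", "samples_in_rows"),
                        sep = "\t") {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate ids in first column of ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric cells in ", path)
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix (or any numeric matrix) as TSV
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_col name for the first (row id) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "taxon_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' A TSV with mandatory columns `sample_id` and `replicate_group`; any other
#' column is treated as a named experimental factor.  A column named
#' `spiked` (TRUE/FALSE) flags samples that received spike-in taxa.
#'
#' @param path TSV path.
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' @rdname read_sample_metadata
#' @param md metadata data.frame to validate.
#' @export
validate_metadata <- function(md) {
  if (!all(c("sample_id", "replicate_group") %in% colnames(md)))
    stop("metadata needs sample_id and replicate_group columns")
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata")
  if ("spiked" %in% colnames(md)) md$spiked <- as.logical(md$spiked)
  fac <- metadata_factor_names(md)
  for (f in fac) {
    v <- md[[f]]
    if (is.character(v) && any(!nzchar(v)))
      stop("empty level in factor ", f)
  }
  md
}

#' Names of the experimental-factor columns in a metadata table
#' @param md metadata data.frame.
#' @export
metadata_factor_names <- function(md) {
  setdiff(colnames(md), c("sample_id", "replicate_group", "spiked"))
}

#' Negative-control taxa sets
#'
#' A `control_set` is a character vector of taxon ids plus a provenance tag
#' (`spike_in`, `empirical` or `combined`).
#'
#' @param taxa_ids character vector of taxon ids.
#' @param provenance one of `"spike_in"`, `"empirical"`, `"combined"`.
#' @return object of class `control_set`.
#' @export
control_set <- function(taxa_ids, provenance = c("spike_in", "empirical", "combined")) {
  provenance <- match.arg(provenance)
  taxa_ids <- unique(as.character(taxa_ids))
  if (length(taxa_ids) == 0L) stop("empty control set")
  structure(list(taxa_ids = taxa_ids, provenance = provenance),
            class = "control_set")
}

#' @export
print.control_set <- function(x, ...) {
  cat(sprintf("control_set: %d taxa (%s)\n", length(x$taxa_ids), x$provenance))
  invisible(x)
}

#' Read a plain-text control list (one taxon id per line, '#' comments)
#' @param path file path.
#' @param provenance provenance tag for the resulting set.
#' @export
read_control_list <- function(path, provenance = "spike_in") {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  control_set(ln[nzchar(ln)], provenance)
}

#' Write a control set as a plain-text list with a JSON sidecar
#' @param cs control_set.
#' @param path output path for the id list; sidecar written to `<path>.json`.
#' @param params optional list of parameters recorded in the sidecar.
#' @export
write_control_set <- function(cs, path, params = list()) {
  writeLines(cs$taxa_ids, path)
  side <- c(list(provenance = cs$provenance, n_taxa = length(cs$taxa_ids)),
            params)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Filter taxa on a counts-per-million prevalence rule
#'
#' Keeps taxon i iff its CPM exceeds `cpm_threshold` (strict `>`) in at
#' least `ceiling(min_fraction * N)` samples.  Library sizes are column sums
#' of the matrix as given, so the filter should be applied before any other
#' taxa subsetting if CPM is to reflect sequencing depth.
#'
#' @param counts taxa x samples integer matrix.
#' @param cpm_threshold CPM cutoff, default 4.
#' @param min_fraction minimum fraction of samples above the cutoff, default 0.15.
#' @param lib_size optional library sizes to use instead of column sums
#'   (e.g. those of the unfiltered matrix).
#' @return The filtered count matrix; samples unchanged.
#' @export
filter_by_cpm <- function(counts, cpm_threshold = 4, min_fraction = 0.15,
                          lib_size = NULL) {
  validate_counts(counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) stop("every sample must have total count > 0")
  cpm <- sweep(counts, 2L, lib_size, "/") * 1e6
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(cpm > cpm_threshold) >= need
  if (!any(keep))
    stop(sprintf("CPM filter removed all %d taxa (threshold %g, >=%d samples)",
                 nrow(counts), cpm_threshold, need))
  counts[keep, , drop = FALSE]
}

#' Centered log-ratio transform
#'
#' Per sample j, `x_ij = log(y_ij + pseudocount) - mean_i log(y_ij +
#' pseudocount)`; every column of the result sums to zero.
#'
#' @param counts taxa x samples matrix.
#' @param pseudocount positive offset added before the log; default 1.
#' @return real matrix, same shape as `counts`.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  lx <- log(counts + pseudocount)
  sweep(lx, 2L, colMeans(lx), "-")
}

#' Total-sum scaling to per-sample proportions
#' @param counts taxa x samples matrix with positive column sums.
#' @return matrix of per-sample proportions (columns sum to 1).
#' @export
tss_normalize <- function(counts) {
  ls <- colSums(counts)
  bad <- ls <= 0
  if (any(bad))
    stop("zero-total sample(s): ", paste(colnames(counts)[bad], collapse = ", "))
  sweep(counts, 2L, ls, "/")
}

#' Build the binary sample-to-biological-source replicate matrix
#'
#' Row p carries a single 1 in the column of sample p's replicate group;
#' groups are ordered by first appearance in `samples`.
#'
#' @param md sample metadata (needs `sample_id`, `replicate_group`).
#' @param samples ordered sample ids (typically `colnames(counts)`).
#' @return N x m binary matrix, rownames samples, colnames group ids.
#' @export
build_replicate_matrix <- function(md, samples) {
  idx <- match(samples, md$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(samples[is.na(idx)], collapse = ", "))
  grp <- as.character(md$replicate_group[idx])
  groups <- unique(grp)
  M <- matrix(0L, nrow = length(samples), ncol = length(groups),
              dimnames = list(samples, groups))
  M[cbind(seq_along(samples), match(grp, groups))] <- 1L
  M
}
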