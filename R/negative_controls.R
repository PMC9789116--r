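## Empirical negative-control identification.
##
## Two procedures: (1) a biological-contrast procedure for replicated
## designs with few biological sources — taxa least differentially abundant
## between the sources, optionally refined by a spiked-vs-unspiked contrast
## within each source; (2) a permutation procedure for designs with many
## sources and declared factors of interest — repeated random splits
## balanced on each factor in turn, keeping taxa that are consistently
## non-significant and intersecting across permutations and factors.

## stable ordering by decreasing p, ties by taxon id
order_by_p_desc <- function(tab) {
  tab$taxon_id[order(-tab$pvalue, tab$taxon_id)]
}

#' Empirical negative controls from a biological contrast
#'
#' Runs an unadjusted two-group NB test between the biological replicate
#' groups and keeps the `n_keep` taxa with the highest p-values.  When the
#' metadata flags spiked and unspiked samples within each group, the list
#' is refined: per group, a spiked-vs-unspiked test is run and the top
#' `spike_exclude_fraction` of taxa by smallest p-value are dropped; the
#' kept sets are intersected across groups and with the unrefined list.
#'
#' @param counts taxa x samples matrix.
#' @param md sample metadata.
#' @param n_keep number of highest-p taxa to keep (default 1000).
#' @param spike_exclude_fraction fraction of smallest-p taxa dropped in the
#'   spike refinement (default 0.15).
#' @param use_tmm passed to [nb_da_test()].
#' @return a [control_set()] with provenance `"empirical"`.
#' @export
empirical_controls_biological <- function(counts, md, n_keep = 1000,
                                          spike_exclude_fraction = 0.15,
                                          use_tmm = TRUE) {
  md <- validate_metadata(md)
  md <- md[match(colnames(counts), md$sample_id), ]
  groups <- unique(md$replicate_group)
  if (length(groups) < 2)
    stop("need >= 2 replicate groups for the biological contrast")
  if (length(groups) > 2) {
    # contrast the two largest groups
    sz <- sort(table(md$replicate_group), decreasing = TRUE)
    groups <- names(sz)[1:2]
  }
  in_contrast <- md$replicate_group %in% groups
  res <- nb_da_test(counts[, in_contrast, drop = FALSE],
                    md$replicate_group[in_contrast], use_tmm = use_tmm)
  n_keep <- min(n_keep, nrow(res$table))
  keep_bio <- order_by_p_desc(res$table)[seq_len(n_keep)]

  refine <- "spiked" %in% colnames(md) && !anyNA(md$spiked) &&
    all(vapply(split(md$spiked, md$replicate_group),
               function(s) any(s) && any(!s), TRUE))
  if (!refine) {
    message("no spiked/unspiked partition within every group; ",
            "skipping spike refinement")
    return(control_set(sort(keep_bio), "empirical"))
  }
  kept_per_group <- lapply(unique(md$replicate_group), function(g) {
    ix <- md$replicate_group == g
    r <- nb_da_test(counts[, ix, drop = FALSE], md$spiked[ix],
                    use_tmm = use_tmm)
    n_drop <- floor(spike_exclude_fraction * nrow(r$table))
    ord <- order_by_p_desc(r$table)          # decreasing p
    if (n_drop > 0) ord <- ord[seq_len(length(ord) - n_drop)]
    ord
  })
  kept <- Reduce(intersect, kept_per_group)
  final <- intersect(keep_bio, kept)
  if (length(final) == 0)
    stop("empty control set after refinement; increase n_keep")
  control_set(sort(final), "empirical")
}

## balanced random split: within each level of `balance`, samples are
## shuffled and halved; odd leftovers alternate between the two groups
balanced_split <- function(balance) {
  N <- length(balance)
  g <- integer(N)
  side <- 0L
  for (lev in unique(balance)) {
    ix <- sample(which(balance == lev))
    h <- floor(length(ix) / 2)
    g[ix[seq_len(h)]] <- 1L
    if (length(ix) > 2 * h) {                # odd leftover
      g[ix[length(ix)]] <- side
      side <- 1L - side
    }
  }
  g
}

#' Empirical negative controls by balanced random-split permutations
#'
#' For each named factor of interest: repeat `n_perm` times — randomly
#' split the samples into two hypothetical groups balanced on that factor's
#' levels, test all taxa between the hypothetical groups, and keep the
#' `ceiling(keep_fraction * T)` taxa with the highest p-values; intersect
#' the kept sets over the permutations.  The per-factor sets are then
#' intersected over all factors.  Taxa structured by anything (a factor of
#' interest, biology, a batch) acquire real abundance differences under
#' random unbalanced-in-that-respect splits and are eliminated.
#'
#' @param counts taxa x samples matrix.
#' @param md sample metadata.
#' @param factors names of metadata factor columns to balance on.
#' @param n_perm permutations per factor (default 10).
#' @param keep_fraction fraction of taxa kept per permutation (default 0.75).
#' @param seed integer seed for the random splits.
#' @param use_tmm passed to [nb_da_test()].
#' @return a [control_set()] with provenance `"empirical"`.
#' @export
empirical_controls_permutation <- function(counts, md, factors,
                                           n_perm = 10, keep_fraction = 0.75,
                                           seed = 1L, use_tmm = TRUE) {
  md <- validate_metadata(md)
  md <- md[match(colnames(counts), md$sample_id), ]
  if (ncol(counts) < 4) stop("need at least 4 samples")
  missing_f <- setdiff(factors, colnames(md))
  if (length(missing_f))
    stop("factors not in metadata: ", paste(missing_f, collapse = ", "))
  set.seed(seed)
  n_keep <- ceiling(keep_fraction * nrow(counts))
  per_factor <- lapply(factors, function(f) {
    lv <- as.character(md[[f]])
    if (length(unique(lv)) < 2)
      stop("factor ", f, " has fewer than 2 levels")
    sets <- lapply(seq_len(n_perm), function(p) {
      repeat {                               # both halves must be non-empty
        g <- balanced_split(lv)
        if (length(unique(g)) == 2) break
      }
      # trended-only dispersion: ranking must not let structure-inflated
      # dispersions mask real differences between the hypothetical groups
      res <- nb_da_test(counts, g, use_tmm = use_tmm, prior_df = Inf)
      order_by_p_desc(res$table)[seq_len(n_keep)]
    })
    Reduce(intersect, sets)
  })
  final <- Reduce(intersect, per_factor)
  if (length(final) == 0)
    stop("empty intersection; increase keep_fraction or lower n_perm")
  control_set(sort(final), "empirical")
}

#' Combine spike-in and empirical control sets
#'
#' Set union, restricted to the taxa of the analysis matrix when given.
#'
#' @param spikes `control_set` of spike-in taxa, or NULL.
#' @param empirical `control_set` of empirical controls, or NULL.
#' @param counts optional count matrix; controls absent from it are dropped
#'   with a warning.
#' @return a `control_set`; provenance `"combined"` when both inputs given.
#' @export
combine_controls <- function(spikes = NULL, empirical = NULL, counts = NULL) {
  if (is.null(spikes) && is.null(empirical))
    stop("at least one control set is required")
  ids <- union(if (!is.null(spikes)) spikes$taxa_ids else character(),
               if (!is.null(empirical)) empirical$taxa_ids else character())
  if (length(ids) == 0) stop("both control sets are empty")
  if (!is.null(counts)) {
    absent <- setdiff(ids, rownames(counts))
    if (length(absent)) {
      warning("dropping controls absent from the matrix: ",
              paste(absent, collapse = ", "))
      ids <- setdiff(ids, absent)
    }
  }
  prov <- if (!is.null(spikes) && !is.null(empirical)) "combined"
          else if (!is.null(spikes)) "spike_in" else "empirical"
  control_set(sort(ids), prov)
}
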