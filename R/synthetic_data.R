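## Synthetic taxon-count experiments with known unwanted-variation structure.
##
## The generator mirrors the statistical assumptions of the correction model:
## counts are NB with taxon-specific dispersion; samples form a few
## biological sources each observed through many technical replicates; a
## dominant per-sample depth factor plus batch-like factors act on counts
## through taxon loadings; designated control taxa carry no biological
## signal; spike-in-like taxa are present only at elevated level in "spiked"
## samples.  Everything is returned as ground truth so recovery can be
## scored exactly.

#' Simulate a replicated microbiome experiment with known unwanted factors
#'
#' Counts are drawn as `y_ij ~ NB(mu_ij, phi_i)` with
#' `log mu_ij = zeta_i + (M beta)_ij + (W alpha)_ij`.  Column 1 of the true
#' `W` is the standardized log sequencing depth; each remaining column is a
#' standardized batch dummy (two-level factors assigned at random within
#' replicate groups), optionally followed by standard-normal noise factors
#' when `k` exceeds `1 + length(batch_factors)`.  Taxon loadings on each
#' batch factor are class-structured: one taxon class is predominantly
#' affected by each factor.  The abundance intercepts `zeta_i` are drawn
#' from a log-normal spectrum whose location is calibrated (on the analytic
#' NB zero probability) so the expected zero fraction matches
#' `sparsity_target`.
#'
#' @param n_groups number of biological sources (replicate groups).
#' @param reps_per_group technical replicates per source.
#' @param n_taxa number of taxa.
#' @param k total number of unwanted factors (depth + batch + noise).
#' @param n_controls number of designated negative-control taxa (beta = 0).
#' @param n_spikes number of spike-in-like taxa (beta = 0, elevated
#'   abundance, reduced `spike_ratio`-fold in unspiked samples).
#' @param batch_factors named numeric vector of per-factor loading scales
#'   (log scale), e.g. `c(storage = 0.8, kit = 0.6)`; each factor gets two
#'   levels.
#' @param depth_sd standard deviation of log library depth.
#' @param depth_loading_scale mean absolute taxon loading on the depth
#'   factor (per unit of standardized log depth).
#' @param bio_sd standard deviation of the biological group effects
#'   (log scale) for non-control taxa.
#' @param bio_min minimum between-group contrast (log scale) enforced for
#'   non-control taxa; 0 (default) leaves the Gaussian draws untouched.
#'   Use it to construct scenarios where every biological taxon is
#'   unambiguously non-null.
#' @param sparsity_target desired overall zero fraction.
#' @param phi_range range of the uniform taxon dispersion distribution.
#' @param n_classes number of taxon classes used for the structured loading
#'   masks.
#' @param spike_ratio target spiked/unspiked mean CPM ratio for spike taxa.
#' @param spike_fraction fraction of samples flagged as spiked (balanced
#'   within replicate groups).  The default 1 mirrors an analysis matrix of
#'   spiked samples only; lower it to emulate paired spiked/unspiked designs
#'   (note the spiking contrast then acts as an additional latent technical
#'   factor on the spike taxa).
#' @param seed integer seed; the generator is fully reproducible.
#' @return list with `counts` (taxa x samples integer matrix), `metadata`
#'   (sample_id, replicate_group, batch factors, spiked), and `truth`
#'   (W_true, alpha_true, beta_true, zeta_true, phi_true, control/spike
#'   flags, class labels, seed).
#' @export
simulate_experiment <- function(n_groups = 2, reps_per_group = 20,
                                n_taxa = 400, k = 3,
                                n_controls = 80, n_spikes = 8,
                                batch_factors = c(storage = 0.8, kit = 0.6),
                                depth_sd = 0.5,
                                depth_loading_scale = 1,
                                bio_sd = 1,
                                bio_min = 0,
                                sparsity_target = 0.6,
                                phi_range = c(0.05, 1),
                                n_classes = 4,
                                spike_ratio = 50,
                                spike_fraction = 1,
                                seed = 1L) {
  if (n_controls + n_spikes > n_taxa)
    stop("n_controls + n_spikes must not exceed n_taxa")
  n_batch <- length(batch_factors)
  if (k < 1 + n_batch)
    stop("k must be at least 1 + number of batch factors")
  set.seed(seed)

  N <- n_groups * reps_per_group
  m <- n_groups
  sample_ids <- sprintf("S%03d", seq_len(N))
  group_ids <- sprintf("G%d", seq_len(n_groups))
  grp <- rep(group_ids, each = reps_per_group)
  taxa_ids <- sprintf("taxon_%04d", seq_len(n_taxa))

  ## sample roles: spikes / controls / biological taxa, class labels
  is_spike <- c(rep(TRUE, n_spikes), rep(FALSE, n_taxa - n_spikes))
  is_control <- c(rep(TRUE, n_spikes + n_controls),
                  rep(FALSE, n_taxa - n_spikes - n_controls))
  class_labels <- paste0("class_",
                         sample.int(n_classes, n_taxa, replace = TRUE))
  class_labels[is_spike] <- "spike"

  ## replicate matrix and biological effects (zero for controls/spikes)
  M <- matrix(0L, N, m, dimnames = list(sample_ids, group_ids))
  M[cbind(seq_len(N), match(grp, group_ids))] <- 1L
  beta <- matrix(0, m, n_taxa, dimnames = list(group_ids, taxa_ids))
  n_bio <- sum(!is_control)
  beta[, !is_control] <- stats::rnorm(m * n_bio, sd = bio_sd)
  beta <- sweep(beta, 2L, colMeans(beta), "-")   # center over groups
  if (bio_min > 0 && n_bio > 0) {
    # enforce a minimum between-group contrast for non-control taxa
    rng <- apply(beta[, !is_control, drop = FALSE], 2L,
                 function(b) diff(range(b)))
    scl <- pmax(1, bio_min / pmax(rng, 1e-12))
    beta[, !is_control] <- sweep(beta[, !is_control, drop = FALSE], 2L,
                                 scl, "*")
  }

  ## unwanted factors: depth, batch dummies, optional noise factors
  W <- matrix(0, N, k, dimnames = list(sample_ids, paste0("W", seq_len(k))))
  log_depth <- stats::rnorm(N, 0, max(depth_sd, 1e-12))
  W[, 1L] <- if (stats::sd(log_depth) > 0)
    (log_depth - mean(log_depth)) / stats::sd(log_depth) else 0
  md <- data.frame(sample_id = sample_ids, replicate_group = grp,
                   stringsAsFactors = FALSE)
  if (n_batch > 0) {
    for (f in seq_len(n_batch)) {
      nm <- names(batch_factors)[f]
      lv <- character(N)                     # balanced levels within group
      for (g in group_ids) {
        ix <- which(grp == g)
        half <- sample(ix, floor(length(ix) / 2))
        lv[ix] <- "A"; lv[half] <- "B"
      }
      md[[nm]] <- lv
      d <- as.numeric(lv == "B")
      W[, 1L + f] <- if (stats::sd(d) > 0) (d - mean(d)) / stats::sd(d) else 0
    }
  }
  if (k > 1 + n_batch)
    W[, (2 + n_batch):k] <- stats::rnorm(N * (k - 1 - n_batch))

  ## class-structured loadings
  alpha <- matrix(0, k, n_taxa, dimnames = list(colnames(W), taxa_ids))
  alpha[1L, ] <- depth_sd * depth_loading_scale *
    stats::runif(n_taxa, 0.7, 1.3)
  if (n_batch > 0) {
    classes <- paste0("class_", seq_len(n_classes))
    for (f in seq_len(n_batch)) {
      dominant <- classes[((f - 1L) %% n_classes) + 1L]
      p_hit <- ifelse(class_labels == dominant, 0.9, 0.2)
      p_hit[is_spike] <- 0.9                 # spikes feel technical effects
      mask <- stats::rbinom(n_taxa, 1L, p_hit)
      alpha[1L + f, ] <- mask * stats::rnorm(n_taxa, 0, batch_factors[f])
    }
  }
  if (k > 1 + n_batch)
    alpha[(2 + n_batch):k, ] <- stats::rnorm((k - 1 - n_batch) * n_taxa,
                                             0, 0.1)

  phi <- stats::runif(n_taxa, phi_range[1], phi_range[2])

  ## spiked flag: balanced within each replicate group
  spiked <- rep(FALSE, N)
  if (n_spikes > 0 && spike_fraction > 0) {
    for (g in group_ids) {
      ix <- which(grp == g)
      spiked[sample(ix, round(spike_fraction * length(ix)))] <- TRUE
    }
  }
  md$spiked <- spiked

  ## abundance spectrum, calibrated to the sparsity target via the analytic
  ## NB zero probability P(y=0) = (1 + phi mu)^(-1/phi)
  zeta_shape <- stats::rnorm(n_taxa, 0, 2)   # log-normal spectrum, sd 2
  if (n_spikes > 0)                          # spikes added at high (not
    zeta_shape[is_spike] <-                  # dominant) known abundance
      stats::quantile(zeta_shape[!is_spike], 0.9) +
      stats::rnorm(n_spikes, 0, 0.25)
  eta_core <- t(M %*% beta) + t(W %*% alpha)   # taxa x samples, no intercept
  unspiked_pen <- matrix(0, n_taxa, N)
  if (n_spikes > 0)
    unspiked_pen[is_spike, !spiked] <- -log(spike_ratio)

  zero_frac <- function(loc) {
    mu <- exp(pmin(zeta_shape + loc + eta_core + unspiked_pen, 700))
    mean((1 + phi * mu)^(-1 / phi))
  }
  lo <- -20; hi <- 20
  if (zero_frac(lo) < sparsity_target || zero_frac(hi) > sparsity_target) {
    stop("sparsity target infeasible for this configuration")
  }
  for (round in 1:40) {                       # monotone decreasing in loc
    mid <- (lo + hi) / 2
    if (zero_frac(mid) > sparsity_target) lo <- mid else hi <- mid
  }
  loc <- (lo + hi) / 2
  zeta <- zeta_shape + loc

  mu <- exp(pmin(zeta + eta_core + unspiked_pen, 700))
  counts <- matrix(stats::rnbinom(n_taxa * N, size = rep(1 / phi, N),
                                  mu = as.vector(mu)),
                   n_taxa, N, dimnames = list(taxa_ids, sample_ids))
  storage.mode(counts) <- "integer"

  truth <- list(W_true = W, alpha_true = alpha, beta_true = beta,
                zeta_true = stats::setNames(zeta, taxa_ids),
                phi_true = stats::setNames(phi, taxa_ids),
                control_flags = stats::setNames(is_control, taxa_ids),
                spike_flags = stats::setNames(is_spike, taxa_ids),
                class_labels = stats::setNames(class_labels, taxa_ids),
                replicate_matrix = M,
                seed = seed)
  list(counts = counts, metadata = md, truth = truth)
}

#' Write a simulated scenario to disk
#'
#' Emits `counts.tsv`, `metadata.tsv`, `controls_true.txt` (designated
#' control + spike taxa), a `truth/` directory with the generating
#' parameters, and `scenario.json` recording the seed.
#'
#' @param sim result of [simulate_experiment()].
#' @param outdir output directory.
#' @param force overwrite an existing directory.
#' @export
write_scenario <- function(sim, outdir, force = FALSE) {
  if (dir.exists(outdir) && !force)
    stop("output directory exists (use force = TRUE): ", outdir)
  dir.create(file.path(outdir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  write_matrix_tsv(sim$counts, file.path(outdir, "counts.tsv"))
  utils::write.table(sim$metadata, file.path(outdir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  writeLines(names(which(tr$control_flags)),
             file.path(outdir, "controls_true.txt"))
  write_matrix_tsv(tr$W_true, file.path(outdir, "truth", "W_true.tsv"),
                   id_col = "sample_id")
  write_matrix_tsv(tr$alpha_true, file.path(outdir, "truth", "alpha.tsv"),
                   id_col = "factor")
  write_matrix_tsv(tr$beta_true, file.path(outdir, "truth", "beta.tsv"),
                   id_col = "group")
  utils::write.table(
    data.frame(taxon_id = names(tr$zeta_true), zeta = tr$zeta_true,
               phi = tr$phi_true, control = tr$control_flags,
               spike = tr$spike_flags, class = tr$class_labels),
    file.path(outdir, "truth", "taxa.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = tr$seed,
                            n_taxa = nrow(sim$counts),
                            n_samples = ncol(sim$counts)),
                       file.path(outdir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
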