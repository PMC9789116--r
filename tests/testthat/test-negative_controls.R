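# Labeled scenario for control identification: nulls have beta = 0, the
# rest carry strong group effects (contrast floor 2 log units), at
# moderate sparsity so biological taxa are testable.
controls_scenario <- function(seed = 19, n_taxa = 500, n_null = 200, ...) {
  simulate_experiment(n_groups = 2, reps_per_group = 12, n_taxa = n_taxa,
                      k = 3, n_controls = n_null, n_spikes = 0,
                      bio_sd = 2, bio_min = 2, sparsity_target = 0.3,
                      spike_fraction = 0, seed = seed, ...)
}

test_that("biological procedure enriches for beta = 0 taxa", {
  sim <- controls_scenario()
  # analysis operates on the prevalence-filtered matrix, as the identification
  # procedure assumes testable taxa
  counts <- filter_by_cpm(sim$counts)
  n_null_kept <- sum(sim$truth$control_flags[rownames(counts)])
  n_keep <- round(1.2 * n_null_kept)         # kept set a bit above the nulls
  cs <- empirical_controls_biological(counts, sim$metadata, n_keep = n_keep)
  expect_s3_class(cs, "control_set")
  expect_equal(length(cs$taxa_ids), n_keep)
  prec <- mean(sim$truth$control_flags[cs$taxa_ids])
  expect_gte(prec, 0.8)
  # strongly biological taxa (top decile |beta| contrast) rarely kept
  bdiff <- abs(sim$truth$beta_true[1, rownames(counts)] -
                 sim$truth$beta_true[2, rownames(counts)])
  strong <- names(sort(bdiff, decreasing = TRUE))[seq_len(round(0.1 * nrow(counts)))]
  expect_lte(mean(strong %in% cs$taxa_ids), 0.05)
})

test_that("refinement is skipped without a spiked partition and applied with one", {
  sim <- controls_scenario(seed = 20)
  expect_message(
    cs <- empirical_controls_biological(sim$counts, sim$metadata,
                                        n_keep = 100),
    "skipping spike refinement")
  expect_equal(length(cs$taxa_ids), 100)

  sim2 <- simulate_experiment(n_groups = 2, reps_per_group = 10,
                              n_taxa = 300, k = 3, n_controls = 80,
                              n_spikes = 6, bio_sd = 2,
                              spike_fraction = 0.5, seed = 21)
  cs2 <- empirical_controls_biological(sim2$counts, sim2$metadata,
                                       n_keep = 150,
                                       spike_exclude_fraction = 0.15)
  # refinement intersects, so the result cannot exceed n_keep
  expect_lte(length(cs2$taxa_ids), 150)
  # spike taxa are strongly affected by spiking and should be excluded
  spikes <- names(which(sim2$truth$spike_flags))
  expect_lte(length(intersect(cs2$taxa_ids, spikes)), 1)
})

test_that("permutation size bounds and reproducibility hold on null data", {
  # no factor effects at all: retention is governed by p-value dependence
  # across permutations, between 0.05 T and 0.75 T
  sim <- simulate_experiment(n_groups = 2, reps_per_group = 12, n_taxa = 400,
                             k = 3, n_controls = 100, n_spikes = 0,
                             batch_factors = c(storage = 0, kit = 0),
                             bio_sd = 0, sparsity_target = 0.6,
                             spike_fraction = 0, seed = 22)
  cs <- empirical_controls_permutation(sim$counts, sim$metadata,
                                       factors = c("storage", "kit"),
                                       n_perm = 10, keep_fraction = 0.75,
                                       seed = 1)
  T_ <- nrow(sim$counts)
  expect_gte(length(cs$taxa_ids), 0.05 * T_)
  expect_lte(length(cs$taxa_ids), 0.75 * T_)
  cs2 <- empirical_controls_permutation(sim$counts, sim$metadata,
                                        factors = c("storage", "kit"),
                                        n_perm = 10, keep_fraction = 0.75,
                                        seed = 1)
  expect_identical(cs$taxa_ids, cs2$taxa_ids)
})

test_that("permutation procedure keeps beta = 0 taxa and drops biological ones", {
  sim <- controls_scenario(seed = 19,
                           batch_factors = c(storage = 0, kit = 0))
  counts <- filter_by_cpm(sim$counts)
  cs <- empirical_controls_permutation(counts, sim$metadata,
                                       factors = c("storage", "kit"),
                                       n_perm = 10, keep_fraction = 0.75,
                                       seed = 1)
  prec <- mean(sim$truth$control_flags[cs$taxa_ids])
  expect_gte(prec, 0.8)
  # strongly biological taxa (top decile |beta| contrast) rarely survive
  bdiff <- abs(sim$truth$beta_true[1, rownames(counts)] -
                 sim$truth$beta_true[2, rownames(counts)])
  strong <- names(sort(bdiff, decreasing = TRUE))[seq_len(round(0.1 * nrow(counts)))]
  expect_lte(mean(strong %in% cs$taxa_ids), 0.05)
})

test_that("keep_fraction = 1 keeps every taxon", {
  sim <- controls_scenario(seed = 23, n_taxa = 80, n_null = 30)
  cs <- empirical_controls_permutation(sim$counts, sim$metadata,
                                       factors = "storage", n_perm = 3,
                                       keep_fraction = 1, seed = 2)
  expect_setequal(cs$taxa_ids, rownames(sim$counts))
})

test_that("permutation result shrinks (weakly) as permutations accumulate", {
  sim <- controls_scenario(seed = 24, n_taxa = 150, n_null = 60)
  sizes <- sapply(c(2, 4, 8), function(np)
    length(empirical_controls_permutation(sim$counts, sim$metadata,
                                          factors = "storage",
                                          n_perm = np, keep_fraction = 0.75,
                                          seed = 3)$taxa_ids))
  expect_true(all(diff(sizes) <= 0))
})

test_that("combine_controls unions, restricts and tags provenance", {
  sp <- control_set(paste0("spike_", 1:8), "spike_in")
  em <- control_set(paste0("taxon_", 1:471), "empirical")
  comb <- combine_controls(sp, em)
  expect_equal(length(comb$taxa_ids), 479)
  expect_identical(comb$provenance, "combined")

  # idempotent union
  same <- combine_controls(sp, sp)
  expect_setequal(same$taxa_ids, sp$taxa_ids)

  # restriction to the matrix taxa drops absent spikes with a warning
  m <- matrix(1L, 4, 2, dimnames = list(paste0("taxon_", 1:4), c("a", "b")))
  expect_warning(r <- combine_controls(sp, control_set("taxon_1", "empirical"),
                                       counts = m),
                 "absent")
  expect_identical(r$taxa_ids, "taxon_1")

  expect_error(combine_controls(NULL, NULL), "required")
})
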