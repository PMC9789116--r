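#!/usr/bin/env Rscript
# Generate the benchmark scenario: 2 biological sources x 20 technical
# replicates, 400 taxa, a dominant depth factor plus storage and kit batch
# factors, 80 designated control taxa (8 of them spike-in-like), ~60% zeros.
# Writes counts, metadata and full ground truth under results/scenario/.

suppressMessages(library(ruvtax))
library(optparse)

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--outdir", type = "character", default = "results/scenario"),
  make_option("--force", action = "store_true", default = FALSE))))

sim <- simulate_experiment(n_groups = 2, reps_per_group = 20, n_taxa = 400,
                           k = 3, n_controls = 72, n_spikes = 8,
                           seed = opts$seed)
write_scenario(sim, opts$outdir, force = opts$force)

zero_frac <- mean(sim$counts == 0)
message(sprintf("scenario written to %s: %d taxa x %d samples, %.1f%% zeros",
                opts$outdir, nrow(sim$counts), ncol(sim$counts),
                100 * zero_frac))
message(sprintf("  %d control taxa (%d spike-like), groups: %s",
                sum(sim$truth$control_flags), sum(sim$truth$spike_flags),
                paste(unique(sim$metadata$replicate_group), collapse = ", ")))
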