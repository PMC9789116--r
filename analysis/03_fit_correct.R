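#!/usr/bin/env Rscript
# Fit the NB unwanted-variation model on the scenario using the designated
# control taxa, write the fitted factors and percentile-invariant adjusted
# counts, and correlate what was estimated (W) with the known experimental
# factors and depth covariates.  Reads results/scenario/ (+ controls),
# writes results/fit/.

suppressMessages(library(ruvtax))
library(optparse)

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--scenario", type = "character", default = "results/scenario"),
  make_option("--k", type = "integer", default = 3L),
  make_option("--outdir", type = "character", default = "results/fit"))))

counts_raw <- read_counts(file.path(opts$scenario, "counts.tsv"))
md <- read_sample_metadata(file.path(opts$scenario, "metadata.tsv"))
counts <- filter_by_cpm(counts_raw)
ctrl_all <- read_control_list(file.path(opts$scenario, "controls_true.txt"),
                              "empirical")
ctrl <- control_set(intersect(ctrl_all$taxa_ids, rownames(counts)),
                    "empirical")
M <- build_replicate_matrix(md, colnames(counts))

fit <- fit_ruv3nb(counts, M, ctrl, k = opts$k, seed = opts$seed)
print(fit)
write_ruv_fit(fit, opts$outdir)

adj <- percentile_adjusted_counts(fit, counts, mode = "mid")
write_adjusted_counts(adj, opts$outdir)

num <- list(log_lib_size = log(colSums(counts)),
            log_geom_mean = colMeans(log(counts + 1)))
fc <- factor_correlation(fit$W, md, numeric_covariates = num)
write.table(fc, file.path(opts$outdir, "factor_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("W correlations with known factors and depth covariates:")
for (r in seq_len(nrow(fc)))
  if (fc$correlation[r] > 0.5)
    message(sprintf("  %s ~ %-14s r = %.3f", fc$w_column[r],
                    fc$covariate[r], fc$correlation[r]))
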