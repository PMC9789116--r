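#!/usr/bin/env Rscript
# Attribute unwanted variation to taxa: cumulative NB GLM pseudo-R2 per
# estimated factor, top-100 most affected taxa per factor with taxon-class
# composition, and the share of an average sample's reads they carry.
# Reads results/scenario/ and results/fit/, writes results/attribution/.

suppressMessages(library(ruvtax))
library(optparse)

opts <- parse_args(OptionParser(option_list = list(
  make_option("--scenario", type = "character", default = "results/scenario"),
  make_option("--fit", type = "character", default = "results/fit"),
  make_option("--n_top", type = "integer", default = 100L),
  make_option("--outdir", type = "character",
              default = "results/attribution"))))

dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
counts_raw <- read_counts(file.path(opts$scenario, "counts.tsv"))
counts <- filter_by_cpm(counts_raw)
W <- as.matrix(read.table(file.path(opts$fit, "W.tsv"), header = TRUE,
                          sep = "\t", row.names = 1, check.names = FALSE))
tx <- read.table(file.path(opts$scenario, "truth", "taxa.tsv"),
                 header = TRUE, sep = "\t")
classes <- setNames(tx$class, tx$taxon_id)

attr <- cumulative_pseudo_r2(counts, W)
write_attribution(attr, file.path(opts$outdir, "attribution.tsv"),
                  counts, classes = classes, n_top = opts$n_top)

n_top <- min(opts$n_top, nrow(counts))
for (f in seq_len(ncol(W))) {
  top <- top_affected(attr, f, n_top = n_top, classes = classes)
  prop <- affected_abundance_proportion(counts, top$taxa$taxon_id)
  message(sprintf(
    "%s: top %d taxa carry %.1f%% of an average sample; leading classes: %s",
    colnames(W)[f], n_top, 100 * prop,
    paste(names(top$class_counts)[seq_len(min(2, length(top$class_counts)))],
          collapse = ", ")))
}
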