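# ruvtax

Removing unknown unwanted variation from microbiome taxon count matrices.

Metagenomic count data mix the biology of interest with technical
variation — sequencing depth, storage condition, freeze–thaw cycles,
library kits — that is often larger than the biology and only partially
recorded. `ruvtax` is for analysts of replicated microbiome studies who
want to estimate that unwanted variation directly from the data, remove it
at the count level, verify that removal worked, and find out which taxa
each technical factor distorts most.

## The model

Counts are negative binomial, `y_ij ~ NB(mu_ij, phi_i)` with
`Var = mu + phi mu^2`, and

```
log mu_ij = zeta_i + (M beta_i)_j + (W alpha_i)_j
```

where `M` (samples × sources) encodes known technical replicates, `W`
(samples × k) holds *unknown* unwanted-factor scores and `alpha_i` the
taxon loadings. Replicates identify the biology (`beta`), negative-control
taxa — spike-ins or empirically selected — identify `W`. Estimation
alternates ridge-penalized IRLS over taxa and samples
(`lambda_a = 0.01` on loadings, `lambda_b = 5` on scores); corrected
counts come from percentile-invariant quantile mapping onto the model with
unwanted factors at their reference value. Correction quality is scored by
RLE summaries (`Omega_RLE = -log(V_med + V_iqr)`, and `NCC_RLE`, one minus
the total canonical correlation between RLE summaries and known technical
factors), first-four-PC silhouettes by biology and by batch, and Storey's
`pi0` in null contrasts; per-factor impact is quantified by cumulative NB
GLM fits and Veall–Zimmermann pseudo-R² increments.

## Worked example

```r
library(ruvtax)

sim    <- simulate_experiment(seed = 1)       # 2 sources x 20 replicates,
counts <- filter_by_cpm(sim$counts)           # 400 taxa, depth+storage+kit
md     <- sim$metadata
ctrl   <- control_set(intersect(names(which(sim$truth$control_flags)),
                                rownames(counts)), "empirical")
M      <- build_replicate_matrix(md, colnames(counts))

fit <- fit_ruv3nb(counts, M, ctrl, k = 3, seed = 1)
fit
#> ruv_fit: 294 taxa x 40 samples, k = 3 (lambda_a = 0.01, lambda_b = 5)
#>   65 control taxa; NOT converged after 50 iterations

adj  <- percentile_adjusted_counts(fit, counts, mode = "mid")
labs <- list(biology = md$replicate_group, batch = md$storage)
evaluate_correction(clr_transform(counts), md, silhouette_labels = labs)
#> evaluation_report: omega = 2.591, NCC_RLE = 0.558
#>   silhouette[biology] = 0.388
#>   silhouette[batch] = 0.242
evaluate_correction(adj$log_pac, md, silhouette_labels = labs)
#> evaluation_report: omega = 3.553, NCC_RLE = 0.892
#>   silhouette[biology] = 0.615
#>   silhouette[batch] = -0.029
```

Read: after correction the RLE summaries vary less within replicate groups
(`omega` 2.59 → 3.55) and carry less batch association (`NCC_RLE` 0.56 →
0.89, larger is cleaner), storage-batch separation collapses (silhouette
0.24 → −0.03) while the biological separation is preserved (0.39 → 0.62).
The convergence note is expected at the default 50-cycle cap: factor
recovery saturates long before the scores stop drifting at the fourth
decimal (see the methods vignette).

The numbered scripts under `analysis/` run the full study on a generated
scenario — simulate, identify empirical negative controls, fit and
correct, benchmark against CLR/RUVg/RUVs, attribute factors to taxa — each
writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1 --force
Rscript analysis/02_identify_controls.R --seed 1
Rscript analysis/03_fit_correct.R --seed 1
Rscript analysis/04_benchmark.R --seed 1
Rscript analysis/05_attribution.R
```

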