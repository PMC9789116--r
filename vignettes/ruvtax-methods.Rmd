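---
title: "Removing unwanted variation from taxon count matrices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing unwanted variation from taxon count matrices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Shotgun metagenomic and amplicon count matrices mix the biological signal of
interest with systematic technical effects: sequencing depth, storage
condition, freeze–thaw cycles, extraction and library kits, run batches.
These unwanted effects are often larger than the biology, they are usually
only partially recorded, and they do not act uniformly — different taxa are
distorted to different degrees. `ruvtax` estimates such unknown unwanted
variation from the data itself, removes it, scores how well removal worked,
and attributes each unwanted factor to the taxa it affects most.

## The model

The count for taxon $i$ in sample $j$ is modelled as negative binomial with
mean $\mu_{ij}$ and taxon-specific dispersion $\phi_i$
($\mathrm{Var} = \mu + \phi\mu^2$), with log-linear mean

$$\log \mu_{ij} = \zeta_i + (M\beta_i)_j + (W\alpha_i)_j,$$

where

* $M$ ($N \times m$) is the known binary replicate matrix assigning each
  sample to its biological source (e.g. animal, subject, treatment plant);
  $\beta_i$ carries the biological differences between sources,
* $W$ ($N \times k$) holds the *unknown* per-sample scores of $k$ unwanted
  factors and $\alpha_i$ the per-taxon loadings on them,
* $\zeta_i$ is the abundance intercept.

Two pieces of side information make $W$ identifiable: technical replicates
(rows of $M$) separate biology from everything else, and negative-control
taxa — spike-ins or empirically selected taxa with no biological signal —
anchor the estimation of $W$.

## Estimation

`fit_ruv3nb()` alternates two ridge-penalized IRLS steps:

1. **Taxon step.** For each taxon, a NB regression of $y_i$ on the design
   $[M \mid W]$ with ridge `lambda_a` on the $\alpha$ block only updates
   $(\beta_i, \alpha_i)$; the dispersion $\phi_i$ is profiled by maximum
   likelihood (bisection on the profile score, clamped to
   $[10^{-8}, 10^8]$). Because every taxon shares the design, the updates
   are computed for all taxa simultaneously with dense matrix algebra, with
   per-taxon step halving so no taxon's penalized likelihood decreases.
2. **Sample step.** For each sample, a NB regression of the control-taxa
   counts on $\hat\alpha_C^\top$ with offset $(\,\hat\zeta + M\hat\beta)_C$
   and ridge `lambda_b` on every coordinate updates the row $W_j$. Only
   control taxa inform $W$.

After each cycle $W$ is centered (the shift is absorbed into $\beta$),
orthogonalized, and sign-anchored to its initialization. Orthogonalization
uses the SVD, $W = UDV^\top \mapsto W \leftarrow UD$,
$\alpha \leftarrow V^\top\alpha$: unlike a QR step this preserves both the
likelihood and the two ridge penalty norms exactly, so the recorded
objective — the control-taxa log likelihood minus both penalties — is
non-decreasing over cycles (up to the $10^{-6}$ relative slack of inexact
inner solves). This monotone trace is asserted in the test suite.

Initialization: $W_1$ is the standardized per-sample log geometric mean of
counts (sequencing depth); remaining columns come from a truncated SVD of
the within-replicate-centered CLR residuals of the control taxa after
projecting out $W_1$.

Defaults follow the benchmark settings of the approach this package
implements: `lambda_a = 0.01`, `lambda_b = 5`, `k = 7` lowered with a
warning to $|C|-1$ when the control set is small. Convergence is declared
when $\max|\Delta W| / (1 + \max|W|) < 10^{-4}$; the cap of 50 alternation
cycles is usually the binding constraint, which matters little in practice
because factor recovery plateaus well before the scores stop drifting at
the fourth decimal.

### Adjusted counts

`percentile_adjusted_counts()` maps each observation to the count with the
same percentile under the model with unwanted factors at their reference
value (the column means of $W$, i.e. zero): with $F$ the NB CDF at the
fitted mean and $\tilde F$ at the reference mean, the cell's percentile is
the midpoint of $(F(y-1), F(y)]$ (deterministic `mid` mode; `randomized`
mode draws uniformly from the interval under an explicit seed) and the
adjusted count is the smallest integer $q$ with $\tilde F(q) \ge p$. Cells
deep in the right tail are computed on the survival scale so the inversion
stays exact where $F$ saturates at 1 in double precision; when fitted and
reference distributions coincide the observation is returned unchanged.
`log_pac` applies `log(pac + 1)`.

## Negative-control identification

Two procedures return empirical control sets:

* `empirical_controls_biological()`: test between the biological sources
  (unadjusted), keep the `n_keep` taxa with the highest p-values; when
  spiked and unspiked samples exist within every source, additionally drop
  the 15% of taxa most affected by spiking in any source and intersect.
* `empirical_controls_permutation()`: for each declared factor of interest,
  repeatedly split samples into two hypothetical groups *balanced* on that
  factor (within-level random halving, odd leftovers alternating), keep the
  `keep_fraction` of taxa with the highest p-values, and intersect across
  permutations, then across factors. Taxa structured by *anything* — the
  other factors, biology, batches — acquire real differences under splits
  that are unbalanced in that respect, and are eliminated.

Both use strict set intersection, break p-value ties by taxon id, and are
deterministic given a seed.

## Differential abundance and specificity

`nb_da_test()` is a per-taxon NB likelihood-ratio test of a two-group
contrast with optional covariates (typically the estimated $\hat W$) and an
offset of log TMM-effective library size. The dispersion is estimated by
profile ML under the full model and, by default, shrunk toward a lowess
mean–dispersion trend with 10 prior degrees of freedom before the LRT.
This moderation matters: with purely per-taxon ML dispersion, a taxon whose
counts are inflated by latent structure absorbs that structure into its own
dispersion and becomes untestable — its p-values turn conservative, which
both masks real effects and (in the permutation procedure above) inverts
the selection toward exactly the structured taxa one wants to exclude.
The reduced model reuses the full-model dispersion, the standard nested-GLM
choice that keeps the null distribution of the statistic calibrated; null
simulations in the test suite hold the type-I error at the 5% level within
[0.03, 0.08].

`storey_pi0()` estimates the null proportion from
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on the grid
$\lambda = 0.05, \dots, 0.95$, smoothed by a 3-df cubic spline and read off
at $\lambda = 0.95$, clamped to $[0, 1]$. In a contrast with no biological
difference (e.g. frozen vs unfrozen aliquots of the same source), a
$\hat\pi_0$ near 1 after adjustment is the specificity signature of
successful correction.

## Correction-quality metrics

* **RLE.** `rle_matrix()` centers each taxon's log values on its
  cross-sample median; `rle_quality()` summarizes samples by median and IQR
  and scores $\Omega_{RLE} = -\log(V_{med} + V_{iqr})$, the natural-log
  transform of the mean within-source variances of those summaries (groups
  of size 1 are excluded; a perfect-replicate zero sum is reported as the
  sentinel $10^9$ with a flag).
* **NCC.** `rle_ncc()` returns one minus the total canonical correlation
  between the per-sample (median, IQR) pairs and the dummy-coded known
  unwanted factors, with total defined through Wilks' lambda as
  $\sqrt{1 - \prod_i(1-\rho_i^2)}$ — equivalent to $\rho_1$ when only one
  canonical pair exists. Larger values mean less residual batch signal.
* **Silhouettes.** `pca_scores()` (samples as observations, taxa centered
  but not scaled, deterministic sign convention) feeds
  `silhouette_by_label()` on the first four PCs: separation by biology
  should survive correction, separation by batch should vanish.
* `factor_correlation()` links each estimated factor to interpretable
  covariates (|Pearson r| for numeric ones such as log library size,
  canonical correlation for categorical factors); `control_cpm_ratio()`
  checks spike-in behavior between spiked and unspiked samples.

## Attribution

`cumulative_pseudo_r2()` fits, per taxon, NB GLMs on intercept plus
$W_1, \dots, W_n$ cumulatively ($n = 1..k$, no library-size offset — the
first factor carries depth) via `MASS::glm.nb` with the package's IRLS as
fallback, and converts likelihoods to Veall–Zimmermann pseudo-$R^2$
($G^2/(G^2+n)$ rescaled by its attainable maximum). Each factor's
contribution is the increment over the previous model, floored at zero
with raw values retained; dispersion is re-estimated per nested model, so
small negative raw increments are possible and are the reason for the
floor. `top_affected()` ranks taxa per factor (ties by id), merging classes
with fewer than two members into "others", and
`affected_abundance_proportion()` reports the average library share of a
top set.

## Baselines

`ruvg()` and `ruvs()` are contract-level factor-analytic baselines on
log-scale (CLR) input: sample scores from the SVD of the (row-centered,
respectively within-replicate-centered) control submatrix, followed by
removal of each taxon's least-squares projection on those scores. In
`ruvs()` the projection coefficients are also estimated on
replicate-centered data so biological contrasts cannot leak into the
adjustment. Exact numerical agreement with any published package is not a
goal; their role is benchmarking the NB model on equal inputs. Externally
corrected matrices (e.g. from location/scale batch methods) can enter the
same evaluation through the TSV interfaces.

## The synthetic generator

`simulate_experiment()` draws the study conditions the analysis assumes:

* design: `n_groups` biological sources × `reps_per_group` technical
  replicates (default 2 × 20, a reduced form of a replicated pig-faeces
  style design);
* abundance: $\zeta_i$ from a log-normal spectrum (sd 2 on the log scale),
  its location calibrated by bisection on the *analytic* NB zero
  probability so the expected zero fraction matches `sparsity_target`
  (default 0.6, typical of species-level shotgun profiles);
* unwanted factors: $W_1$ = standardized log depth (`depth_sd` 0.5);
  one standardized two-level dummy per named batch factor (defaults:
  storage 0.8, kit 0.6 on the log scale — batch effects comparable to or
  larger than typical biological contrasts, as storage experiments show),
  balanced within sources; loadings are class-structured (each factor
  predominantly hits one taxon class, Bernoulli masks 0.9 vs 0.2);
* biology: group effects $\mathcal{N}(0, \texttt{bio\_sd})$ for non-control
  taxa, exactly zero for the `n_controls` designated controls;
  `bio_min` optionally enforces a minimum between-group contrast for
  scenarios whose point is that every biological taxon is unambiguously
  non-null;
* spike-ins: `n_spikes` taxa with zero biology, abundance pinned near the
  90th percentile of the spectrum, and counts reduced `spike_ratio`-fold in
  unspiked samples. The default `spike_fraction = 1` mirrors an analysis
  matrix of spiked samples only; partial spiking turns the spiking contrast
  itself into an additional latent technical factor, which is exactly what
  the spiked/unspiked refinement and CPM-ratio checks need, but what a
  factor-recovery benchmark must avoid conflating with its declared `k`.

What the generator does **not** emulate: taxon–taxon ecological
correlations, compositional closure beyond what NB sampling induces,
classifier misassignment noise, or continuous gradients in the unwanted
factors. Passing tests therefore demonstrate correctness of the estimation
machinery under the model's own assumptions, not robustness to every way
real metagenomes deviate from them.

## Numerical choices and degenerate inputs

* IRLS: Fisher scoring with step halving on the penalized likelihood;
  convergence at penalized-score norm $<10^{-6}$; linear systems get a
  $10^{-10}$ ridge jitter and a $10^{-6}$ fallback on singularity.
* All-zero responses clamp the fitted mean at $10^{-8}$ (intercept
  $\log 10^{-8}$); all-zero control taxa are dropped with a warning;
  all-zero taxa in testing are flagged with $p = 1$.
* Dispersion bounds $[10^{-8}, 10^8]$ everywhere; the Poisson limit snaps
  to the lower bound when the profile is still rising there.
* Ties at the CPM filter threshold use strict `>`; the CLR pseudocount
  defaults to 1 and is configurable (scale-invariance holds only in the
  pseudocount $\to 0$ limit).
* Problem sizes in the tests and the acceptance script — $N = 40$,
  $T = 400$, $k = 3$, 10 simulation replicates — were chosen as the
  smallest sizes at which factor recovery, specificity and metric
  directions stabilize across seeds.

## Known limitations

* The alternation converges geometrically and slowly in its tail; the
  50-cycle default typically stops on `max_iter` with factor recovery
  already saturated. Raise `max_iter` for publication-grade fits.
* Dispersion moderation uses a fixed 10 prior df rather than estimating the
  prior from the data; extremely heterogeneous dispersion landscapes may
  prefer a heavier or lighter prior.
* `pi0` estimation inherits Storey's sensitivity to discrete p-value
  spikes near 1; it is reliable only on prevalence-filtered matrices where
  most taxa are genuinely testable, which is how the workflow applies it.
* Percentile adjustment treats the fitted model as exact; counts from taxa
  whose NB fit is poor (e.g. zero-inflated beyond NB) move accordingly.
* At the benchmark penalty settings the scale-invariant penalty on the
  product $W\alpha$ is only $\sqrt{\lambda_a\lambda_b}$, which is weak: on
  data with *no* unwanted variation the maximum-penalized-likelihood fit
  still absorbs some sampling noise into small spurious unwanted effects
  (a property of the objective, not the optimizer — a direct joint
  maximization lands on the same solution), so adjusted counts for
  abundant taxa can differ slightly from the raw counts. The identifiability
  step therefore includes a product-preserving, penalty-optimal rescaling
  of each factor so at least the reported $W$/$\alpha$ split is
  well-defined. When the data may truly lack unwanted structure, inspect
  the factor correlations and the size of the fitted loadings before
  adjusting.
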