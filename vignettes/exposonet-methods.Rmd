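---
title: "Methods: shrinkage Gaussian graphical models for exposome-metabolome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shrinkage Gaussian graphical models for exposome-metabolome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposonet)
```

## The model

A feature table holds intensities of $p$ molecules (environmental
chemicals and endogenous metabolites) in $n$ samples. Under a multivariate
normal model for the (transformed) intensities, the conditional dependence
structure is encoded by the precision matrix $\Omega = \Sigma^{-1}$: the
partial correlation

$$\rho_{ij} = -\frac{\Omega_{ij}}{\sqrt{\Omega_{ii}\,\Omega_{jj}}}$$

is the Pearson correlation of molecules $i$ and $j$ after conditioning on
all remaining molecules, and $\rho_{ij} \ne 0$ defines an edge of the
Gaussian graphical model. Partial correlations suppress the indirect
associations that dominate marginal correlations in omics data, which is
why GGM edges between metabolites tend to coincide with known biochemical
reactions, and why an edge between a chemical and a metabolite is a
candidate *direct* exposure effect worth follow-up.

Because metabolomics tables routinely have $p$ near or above $n$, the
empirical correlation matrix $R$ is ill-conditioned or singular and cannot
be inverted. `fit_ggm()` therefore uses the analytic shrinkage estimator

$$R^\ast = \lambda I + (1-\lambda) R, \qquad
\hat\lambda = \min\!\left(1, \frac{\sum_{i<j}\widehat{\mathrm{Var}}(r_{ij})}
{\sum_{i<j} r_{ij}^2}\right),$$

with $\widehat{\mathrm{Var}}(r_{ij})$ the unbiased estimate of the
sampling variance of each empirical correlation computed from the
standardized data products. $R^\ast$ is positive definite for any $n, p$
whenever $\lambda > 0$, and $\lambda$ adapts to the data: near 1 when the
off-diagonal signal is indistinguishable from sampling noise, near 0 when
$n \gg p$ and correlations are strong. Columns are standardized before
estimation, so the identity target is the natural null.

## Edge significance

Under the null of no conditional dependence, a partial correlation $r$ has
density

$$f_0(r;\kappa) = \frac{(1-r^2)^{(\kappa-3)/2}}{B(1/2,(\kappa-1)/2)},
\qquad r^2 \sim \mathrm{Beta}\!\left(\tfrac12, \tfrac{\kappa-1}{2}\right),$$

where $\kappa$ acts as an effective degrees of freedom (for the classical
sample partial correlation, $\kappa = n - p + 1$; shrinkage changes the
effective value, so $\kappa$ is estimated from the data). We fit $\kappa$
by maximum likelihood on the lower 90% of the $|r|$ distribution —
genuine edges live in the upper tail, so the bulk is null-dominated — using
the truncated density $f_0(r)/P(|R| \le q_{0.9})$ so that trimming does not
bias the fit. Two-sided p-values are the tail areas
$P(|R| \ge |r|) = 1 - I_{r^2}(1/2, (\kappa-1)/2)$ via the regularized
incomplete beta function.

Multiple testing over the $p(p-1)/2$ unique pairs uses Benjamini–Hochberg
at FDR $q = 0.1$ by default. The procedure implies a realized p-value
cutoff (the largest rejected p-value), which `fit_ggm()` reports so a run
can be summarized as "edges significant at FDR < 10% (p < cutoff)". BH is a
step-up rule on tail-area p-values; empirical-Bayes local-fdr machinery is
deliberately out of scope, so realized cutoffs from other tooling are
comparable only qualitatively.

## Preprocessing

The chain is fixed as filter → impute → normalize → transform → merge:

* **Missingness filter** (`max_missing_fraction = 0.5`): molecules with
  *strictly more than* 50% missing cells are removed; exactly half missing
  is retained. Samples are never dropped.
* **KNN imputation** (`k = 10`): a missing cell is the mean of the
  molecule's $k$ nearest molecules' observed values in that sample.
  Nearness is Euclidean distance between molecule profiles over mutually
  observed samples, normalized by the overlap count (an RMS distance) so
  pairs with different overlaps are comparable; molecule pairs sharing no
  sample get infinite distance. Imputing molecules from molecules (not
  samples from samples) is the standard choice when $p \approx n$ and the
  inter-molecule correlation is the signal. $k = 10$ is the conventional
  default of the KNN-imputation literature. Imputation runs on raw
  intensities, before normalization, matching the usual order of
  metabolomics pipelines. A cell whose $k$ neighbours are all missing in
  that sample falls back to the molecule's observed mean and is listed in
  the report.
* **Sum normalization**: each sample's values are divided by that sample's
  total, *separately* within the chemical and metabolite blocks, cancelling
  per-sample dilution and injection-volume variation exactly (the
  simulator's dilution factors are multiplicative per sample, so block
  totals carry them entirely).
* **Generalized log transform**: $\mathrm{glog}(x; a) =
  \log_2\!\big((x + \sqrt{x^2+a^2})/2\big)$, strictly increasing, equal to
  $\log_2 x$ for $x \gg a$ and defined at 0. The offset $a$ defaults to
  each block's smallest positive normalized value — data-adaptive, always
  valid, and recorded in the preprocessing report for reproducibility; it
  can be fixed in configuration when comparability across runs matters.
* **Merge**: chemical columns first, then metabolites, with annotations
  preserved.

## The synthetic cohort generator

No public cohort accompanies this class of serum exposome+metabolome
studies, so validation uses simulated cohorts with known truth. The
generator's defaults emulate the structure such a study reports:
140 samples and 140 molecules (50 chemicals + 90 metabolites), metabolites
organized in 15 pathway blocks, sparse chemical→metabolite partial
correlations of magnitude 0.12–0.3, left-censored missingness (10% per
molecule) and log-normal per-sample dilution (sd 0.25 on the log scale).

Ground truth is a sparse precision matrix: unit diagonal, off-diagonal
entries $-\rho_{ij}$ at the planted edges. Metabolite blocks are *chains*
(consecutive within-block edges), mimicking biosynthesis sequences such as
fatty-acid elongation/desaturation or bile-acid conversion; chemicals get
1–3 edges each, mirroring the sparse chemical–metabolite association
pattern such studies report. Positive definiteness is enforced by diagonal
loading (add $\epsilon I$ until the smallest eigenvalue reaches $10^{-3}$)
followed by rescaling the off-diagonals to restore the target partial
correlation magnitudes, iterated a bounded number of times; an infeasible
combination raises an error rather than silently changing magnitudes.
Latent concentrations are drawn from $N(0, \Omega^{-1})$ through a
Cholesky factor (keeping the random stream platform-reproducible),
exponentiated around per-molecule log-normal baselines, scaled per sample
by the dilution factor, and left-censored: values below the molecule's
configured latent quantile become missing, a limit-of-detection mechanism
rather than missing-completely-at-random. Censoring acts on the latent
(pre-dilution) scale — the detection limit is treated as a property of the
molecule — which also makes the normalization's dilution-invariance exact.

What the generator does *not* emulate: batch effects and drift, QC-sample
structure, retention-time/adduct artifacts, non-normal marginal
distributions beyond log-normality, and the dense strong marginal
correlation structure of real metabolomes. Passing recovery tests
therefore demonstrates correctness of the estimator and pipeline, not
performance guarantees on any real cohort.

## What recovery does and does not show

On the recovery benchmark (30 molecules, planted $|\rho| = 0.3$, 300
samples), the fitted GGM attains sensitivity ~1 and precision ~0.9 at
FDR 0.1 — the regime where the method is demonstrably sound. Two honest
caveats, both visible in the package's own outputs:

* **Small-sample, weak-signal regimes find few edges.** At the generator's
  default study-scale conditions (n = 140, p = 140, sparse $|\rho| \in
  [0.12, 0.3]$), the analytic $\lambda$ is large (the sparse weak signal is
  barely distinguishable from noise at this $n/p$), shrunken partial
  correlations are small, and BH typically declares zero to a handful of
  edges. Real cohorts that report dozens of edges at similar sizes have
  much denser and stronger correlation structure than this deliberately
  sparse simulation; edge counts are not comparable between the two.
* **Sum normalization induces compositional closure.** Dividing by block
  totals makes each block's columns sum to 1, creating spurious negative
  dependence that is strongest for small blocks; with few chemicals the
  chemical–chemical partial correlations acquire a closure component. The
  recovery benchmark therefore measures the estimator on the glog scale
  where the generative model lives; the full-pipeline run reports its own
  recovery separately.

## Numerical choices and degenerate inputs

* Shrinkage $\lambda$ is clamped to $[0,1]$; $p = 1$ defines $\lambda = 0$.
  A zero-variance molecule is an error naming the molecule, not a silent
  drop.
* $\kappa$ is optimized over $\log(\kappa - 3)$ on a wide bracket, keeping
  the $\kappa > 3$ constraint implicit and the optimization scale-free. An
  all-zero partial correlation matrix (total shrinkage, $\lambda = 1$)
  yields the sentinel $\kappa = \infty$ with a warning; p-values then
  degenerate to 1 at $r = 0$ and no edges are declared.
* BH ties are broken by the stable canonical pair order (lexicographic
  molecule ids), so edge tables are byte-reproducible.
* `partial_correlations()` refuses non-positive-definite input (Cholesky
  failure) rather than pseudo-inverting.
* Matrix inversion goes through `chol2inv(chol(.))`; symmetry is enforced
  by averaging with the transpose to remove rounding asymmetry.
* The missingness filter errors when *no* molecule survives; the overlay
  errors when *no* reference reaction resolves, and reports (never drops)
  partially unresolved names.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on simulated
data chosen to finish in seconds while keeping Monte-Carlo margins
meaningful: oracle equivalence at $n = 200, p = 10$; the closed-form
equicorrelated check at $n = 50{,}000, p = 3$ (drawn with exact empirical
moments so the $10^{-3}$ band tests the estimator, not sampling noise);
FDR control over 200 global-null datasets at $n = 100, p = 20$; edge
recovery over 20 cohorts at $n = 300, p = 30$; $\kappa$ recovery from
5,000 null draws; and one end-to-end run at the default study-scale
conditions.

## Known limitations

* Gaussianity after glog is an approximation; heavy-tailed or strongly
  zero-inflated molecules violate it and inflate the null tail (partly
  absorbed by the fitted $\kappa$).
* The estimator assumes samples are exchangeable; confounding by group
  structure should be handled by stratified runs (`run_stratified()`),
  which re-filter molecules per stratum, rather than by pooling.
* Alternative GGM estimators (graphical lasso, nodewise regression) and
  local-fdr edge selection are intentionally not provided.
* Overlay matching is case-insensitive *exact* name matching plus an
  explicit synonym map; fuzzy matching is refused by design, since silent
  mismatches would corrupt the comparison.
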