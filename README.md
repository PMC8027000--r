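# exposonet

Exposome–metabolome association networks from Gaussian graphical models.

Non-targeted LC-HRMS metabolomics measures environmental chemicals (the
serum exposome) and endogenous metabolites (the metabolome) in the same
biospecimens. Marginal Pearson correlations between such molecules are
dominated by indirect associations; the quantity of biological interest is
the **partial correlation** — the correlation of two molecules conditioned
on all remaining molecules — whose nonzero entries define a Gaussian
graphical model (GGM) and tend to track direct biochemical relationships.

`exposonet` provides, for R users analysing annotated feature tables:

* **Preprocessing** in the standard metabolomics order: exclusion of
  molecules with more than 50% missing values, k-nearest-molecule
  imputation, per-sample sum normalization applied separately to the
  chemical and metabolite blocks, and the generalized log transform
  `glog(x; a) = log2((x + sqrt(x^2 + a^2))/2)`.
* **GGM estimation**: the Schäfer–Strimmer analytic shrinkage correlation
  estimator `R* = λI + (1−λ)R` (positive definite for any n, p), partial
  correlations from its inverse,
  `ρ_ij = −Ω_ij / sqrt(Ω_ii Ω_jj)` with `Ω = (R*)^{-1}`, a null
  distribution `f0(r; κ) ∝ (1−r²)^((κ−3)/2)` fitted to the bulk of the
  observed partial correlations by truncated maximum likelihood, two-sided
  tail-area p-values, and Benjamini–Hochberg edge selection at FDR `q`
  (default 0.1) with the realized p-value cutoff reported.
* **Network construction**: typed chemical/metabolite graphs with signed
  partial-correlation edge weights, sub-network extraction, and GraphML /
  SIF / tidy edge-table export for Cytoscape-style viewers.
* **Validation**: overlay scoring of inferred edges against a curated
  reference of known biochemical reactions (a polyunsaturated fatty-acid
  and bile-acid reaction fixture ships with the package), and
  sensitivity/precision/MCC scoring against simulated ground truth.
* **A synthetic-cohort generator** with known sparse precision matrices —
  pathway-block metabolite chains plus sparse chemical→metabolite edges,
  left-censored missingness and per-sample dilution — so every stage is
  testable without cohort data.

## Worked example

```r
library(exposonet)

cfg <- sim_config(n_samples = 300, n_chemicals = 10, n_metabolites = 20,
                  n_blocks = 4, chemical_edge_count = 10,
                  pcor_magnitude_range = c(0.3, 0.3),
                  censoring_quantile = 0, dilution_sd = 0, seed = 1)
cohort <- simulate_cohort(cfg)
fit <- fit_ggm(glog_transform(cohort$table, offset = 1), q = 0.1)
fit
#> Gaussian graphical model (shrinkage partial correlations)
#>   data: 300 samples x 30 molecules
#>   shrinkage lambda: 0.2825   null kappa: 627.75
#>   significant edges at FDR 0.1: 30 (p < 0.00453)

net <- build_network(fit, cohort = "demo")
net
#> exposure_network: 30 nodes, 30 edges (cohort: demo)
#>   nodes: 10 chemicals, 20 metabolites
#>   edges: metabolite-metabolite=17, chemical-metabolite=11, chemical-chemical=2

head(edge_table(fit), 5)
#>   molecule_a molecule_b       pcor       pvalue significant
#> 1     met_13     met_14  0.2950060 4.313118e-14        TRUE
#> 2     met_07     met_08  0.2823758 5.443507e-13        TRUE
#> 3     met_19     met_20  0.2601178 3.501401e-11        TRUE
#> 4    chem_06     met_14 -0.2579942 5.106892e-11        TRUE
#> 5    chem_10     met_10  0.2536805 1.087915e-10        TRUE

evaluate_recovery(net, cohort$model)[c("sensitivity", "precision", "mcc")]
#> $sensitivity [1] 1     $precision [1] 0.867     $mcc [1] 0.926
```

The fit reports the shrinkage intensity λ (how far the empirical
correlation matrix was pulled toward the identity), the fitted null
effective degrees of freedom κ, and the realized p-value cutoff implied by
BH at the chosen FDR. Here all 26 planted edges are recovered
(sensitivity 1) with 4 false edges among 30 declared (precision 0.87),
consistent with the FDR target. `run_pipeline()` executes the same analysis
end-to-end from a single YAML configuration, including preprocessing,
exports and a run manifest; `run_stratified()` repeats it per sample
stratum plus pooled.

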