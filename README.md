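# plasmad

Tools for large-scale aptamer-based **plasma proteomic studies of Alzheimer
disease** (AD), written for biostatisticians and computational biologists who
need the full analysis chain of a modern case-control proteomics study as
reusable, tested components rather than a one-off script pile.

Cohort-scale plasma proteomics (thousands of analytes measured as relative
fluorescence units, RFU) asks a recurring set of questions: which proteins
differ between AD cases and cognitively normal controls after rigorous assay
QC; do the associations replicate across stages and external studies; do
they track biomarker-defined (amyloid/tau) rather than merely clinical
status; do they predict conversion from cognitively normal to symptomatic
AD and the rate of memory decline; and can a small frozen panel of proteins
carry the predictive signal to new cohorts? `plasmad` implements each step:

* **QC cascade** — LOD, scale-factor and CV analyte filters; Tukey-fence
  outlier masking on log10 values; two-pass (65% / 85%) call-rate
  filtering; per-cluster z-score normalization.
* **Three-stage differential abundance** — per-analyte OLS of normalized
  levels on status (CO = 0, AD = 1) with age/sex (+ cohort) covariates; a
  discovery/replication gate (nominal p, concordant direction);
  sample-size-weighted Stouffer meta-analysis
  `Z = sum(sqrt(n_i) z_i)/sqrt(sum n_i)`; Benjamini–Hochberg FDR over the
  full assayed universe; tertile odds ratios with the transformed OR
  `max(OR, 1/OR)`.
* **Cross-study concordance** — sign concordance with exact (log-space)
  binomial enrichment against the 0.5 null, effect-size correlations,
  overlap patterns.
* **Biomarker dichotomization** — two-component Gaussian-mixture EM on
  z-scores with a posterior-equality cutoff, mapped back to the raw scale;
  joint AT status.
* **Progression & decline** — time-to-event construction for CDR = 0
  participants, Cox models (Efron ties), Kaplan–Meier summaries, CDR-SB
  slopes per year and Wilcoxon group comparisons.
* **Frozen predictive panel** — stratified 70/30 split, 5-fold CV Lasso
  (age/sex unpenalized), the 90%-of-best-performance λ rule, logistic
  refit with a frozen cutoff and standardization constants, undersampled
  matched evaluation, conversion-horizon AUCs.
* **Enrichment** — exact hypergeometric over-representation over GMT gene
  sets and aggregated-Cauchy (ACAT) module ranking.
* **Synthetic cohorts** — a generator with ground truth (planted SD-unit
  effects, LOD censoring, plate scale factors, bimodal biomarkers,
  protein-dependent conversion hazards, CDR-SB trajectories) so the whole
  pipeline is testable without access-controlled data.

## Worked example

```r
library(plasmad)

# a synthetic discovery + replication pair sharing ground truth
eff <- 0.4 * c(1, 1, -1, 1, -1)   # five planted analytes, SD units
sims <- lapply(1:2, function(s) {
  cf <- sim_config(n_co = 600, n_ad = 400, n_analytes = 200,
                   fraction_nonnull = 0.025, effect_size_sd = eff,
                   cohort = c("KADRC", "STANF")[s],
                   dataset_cluster = c("cA", "cB")[s], seed = s)
  sim <- simulate_cohort(cf)
  sim$z <- zscore_normalize(sim$matrix,
                            setNames(sim$samples$dataset_cluster,
                                     sim$samples$sample_id))
  sim
})
out <- run_daa(sims[[1]]$z, sims[[1]]$samples,
               sims[[2]]$z, sims[[2]]$samples, m = 200)
subset(out$meta, significant)
#>   analyte_id    z_meta       p_meta direction n_total selected        fdr_q significant
#> 1   seq.0001  6.138633 8.323478e-10         1    1978     TRUE 3.329391e-08        TRUE
#> 2   seq.0002  9.305732 1.330724e-20         1    1975     TRUE 2.661447e-18        TRUE
#> 3   seq.0003 -7.538122 4.767891e-14        -1    1968     TRUE 3.178594e-12        TRUE
#> 4   seq.0004  8.580447 9.450538e-18         1    1980     TRUE 9.450538e-16        TRUE
#> 5   seq.0005 -6.910603 4.825986e-12        -1    1940     TRUE 2.412993e-10        TRUE
```

All five planted analytes (and nothing else) pass the gate and FDR: the
`z_meta`/`p_meta` columns are the Stouffer-combined evidence over the two
stages, `fdr_q` the BH q-value against the full 200-analyte universe.
The printed concordance headline numbers reproduce exactly:

```r
binomial_enrichment(354, 456)                     # GNPC external replication
#> $fold 1.552632          $p 6.185368e-34
```

## Command line

```sh
plasmad simulate   --config cfg.yaml --out sim/
plasmad qc         --config cfg.yaml --out qc/
plasmad daa        --config cfg.yaml --out daa/
plasmad model-train --config cfg.yaml --out model/
```

(after installation the script lives in `exec/`; see the vignette for the
config schema).

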