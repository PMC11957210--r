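---
title: "Models and methods behind plasmad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plasmad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plasmad` re-implements, as reusable and tested components, the analysis
pattern of large aptamer-based plasma proteomic case-control studies of
Alzheimer disease (AD): assay quality control, a three-stage differential
abundance analysis, cross-study concordance statistics, Gaussian-mixture
biomarker dichotomization, progression and memory-decline models, a sparse
predictive panel with frozen-weight transfer, and enrichment ranking. Real
cohort data of this kind are access-controlled, so the package ships a
synthetic cohort generator with ground truth; every pipeline stage is
exercised and judged against that stated world.

## Quality control

Aptamer assays report relative fluorescence units (RFU): positive,
right-skewed intensities with per-plate scale factors and limits of
detection (LOD). The QC cascade applies, in order:

1. **Analyte filters.** An analyte is removed when at least 85% of its
   measurements fall below the LOD, when its scale factor deviates by more
   than 0.5 from the plate-median scale factor on any plate, or when its
   coefficient of variation (CV = sd/mean on raw RFU) exceeds 0.15. The CV
   reference population is configurable (`cv_scope`): the default computes
   CV per plate across all samples on that plate, the only population
   computable from the stated inputs (vendor replicate CVs are not part of
   the data model).
2. **Outlier masking.** Per analyte, log10 values outside the standard
   Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` become missing. Quartiles
   use the linear-interpolation convention (`type = 7`), exposed as a
   parameter because boundary cells can flip under other conventions. The
   masking is single-pass: fences are computed once on the incoming data,
   and a second application masks nothing new on its own output.
3. **Call-rate filtering, two passes.** Pass 1 removes analytes *and*
   subjects below a 65% call rate, judged simultaneously on the incoming
   matrix; call rates are recomputed on the reduced matrix; pass 2 removes
   those below 85%. The simultaneous-then-recompute order is the minimal
   reading of a two-pass description; the order is not otherwise
   identifiable from outputs.
4. **Per-cluster z-normalization.** Within each dataset cluster (e.g. a
   blood-draw-era batch), each analyte's log10 values are centered and
   scaled to unit variance. Normalizing on the log scale matches the
   outlier step and stabilizes the variance of intensity data; analytes
   with zero within-cluster variance are dropped with a warning rather
   than producing infinities.

Filters only remove or mask: no retained value is altered before
normalization.

## Three-stage differential abundance

Per analyte, ordinary least squares of the z-normalized protein level on
clinical status (CO = 0, AD = 1) with age at draw and sex as covariates
(replication adds a cohort indicator); effects are therefore in SD units
with positive meaning higher in AD. The gate keeps analytes nominally
significant (p < 0.05) in both discovery and replication with concordant
direction. Gated analytes are meta-analyzed by the sample-size-weighted
Stouffer combination of signed z-scores,

$$Z = \frac{\sum_i \sqrt{n_i}\, \mathrm{sign}(\beta_i)\,\Phi^{-1}(1-p_i/2)}{\sqrt{\sum_i n_i}},$$

with two-sided $p = 2\Phi(-|Z|)$. The combination method inside the
meta-analysis package used by such studies is rarely stated; the
direction-aware Stouffer form is the natural choice when the inputs are
"effect sizes and p-values", and a weighted-Fisher alternative is kept
behind a flag for sensitivity. Benjamini-Hochberg correction is applied to
the meta p-values with the universe size `m` fixed at the *total* number of
assayed aptamers (6,905 at full scale), not the gated subset - conservative
and matching how such studies report FDR.

Effect sizes in SD units are hard to read clinically, so `tertile_odds_ratio`
contrasts the top and bottom tertiles of an analyte's pooled distribution by
logistic regression (middle tertile excluded, rank-based tertiles with ties
broken by sample id for determinism) and reports the transformed odds ratio
`max(OR, 1/OR)` - the fold change in risk regardless of direction.

## Cross-study concordance

Replication against external summary statistics uses the sign of the effect
(log hazard ratios share the sign convention for survival-based studies).
Exactly-zero external effects carry no sign and are excluded from the
evaluable count. The enrichment of concordant directions over the 50% null
is `fold = k/(0.5 n)` with an exact binomial tail p-value computed in log
space (log-gamma terms and log-sum-exp), because the headline values sit at
p ~ 1e-34 where naive summation underflows relative accuracy. Both the
one-sided upper tail (matching the "probability of observing the given
number or larger" description) and the symmetric two-sided version are
provided; published comparisons are not all reproducible under a single
sidedness convention, so neither is guessed as intended - both are exposed.

## Biomarker dichotomization

Continuous AD biomarkers (CSF A-beta-42 and ptau181, amyloid-PET composite,
plasma ptau217) are bimodal in mixed cohorts. `fit_gmm_cutoff` z-scores the
values, fits a two-component univariate Gaussian mixture with unequal
variances by EM (k-means initialization, fixed seed, relative log-likelihood
tolerance 1e-6), and places the cutoff where the posterior membership
probabilities are equal - the unique solution between the component means,
which is standard practice and well-defined even with unequal variances,
unlike the outer density intersections. The raw-scale cutoff is recovered by
inverting the z-transform, so assigned statuses are invariant to increasing
affine transforms of the input. Positivity direction (A-beta low-is-positive,
ptau/PET high-is-positive) is metadata supplied by the caller, never
inferred. A BIC comparison against 1- and 3-component fits warns when
bimodality is questionable, and a component weight under 0.01 raises a
degenerate flag. The joint amyloid/tau (AT) contrast keeps A+T+ versus
A-T-; discordant profiles are excluded from that contrast.

## Progression and memory decline

Time-to-event inputs are built for participants who were cognitively normal
(CDR = 0) at draw: duration is age at AD onset (converters) or at the last
CDR visit, minus age at draw; non-positive durations (onset recorded before
draw) are excluded with a warning, never clamped. When no explicit onset age
is available, onset is taken as the midpoint between the last CDR = 0 visit
and the first CDR > 0 visit - symptom onset between two annual visits is
otherwise unobservable, and the midpoint is unbiased under a uniform onset
position. Cox models use the Efron tie approximation (visit-derived ages are
coarse, where Breslow degrades). Monotone-likelihood fits are flagged, not
silently reported.

CDR sum-of-boxes slopes take as initial record the visit closest to the
draw within a 180-day window on either side (nearest wins; ties break toward
the pre-draw record) and the latest visit as the last record; the slope is
the difference divided by years spanned. Group comparisons use the
two-sided Wilcoxon rank-sum test, exact for combined n <= 25 without ties,
tie-corrected normal approximation otherwise.

## The predictive panel

The panel procedure mirrors a frozen-biomarker workflow:

1. Stratified 70/30 split by status with nearest-integer allocation per
   stratum (1,381 CO / 750 AD reproduces 967/525 training participants).
2. Five-fold cross-validated L1-penalized logistic regression over the
   candidate analytes with age and sex *unpenalized*; folds stratified by
   label; analyte predictors standardized on training data only, constants
   retained. The lambda grid is glmnet's: 100 log-spaced values spanning
   four orders of magnitude below the smallest all-zero lambda.
3. **The 90%-of-best rule.** The chosen lambda is the largest one whose CV
   performance retains 90% of the best model's. With mean validation AUC as
   the metric (the metric such studies report throughout), retention is
   measured on discrimination above chance, `AUC - 0.5` (the Gini
   coefficient). This choice was forced by analysis: AUC of a k-protein
   panel grows like $\Phi(c\sqrt{k})$ and is concave above the 0.5 chance
   level, so an *absolute* AUC ratio of 0.9 is attainable by a 3-protein
   model for any equal effect size, and the rule would never retain a
   7-protein panel. The absolute-ratio reading remains available
   (`baseline = "absolute"`), as does a deviance-based metric.
4. Unpenalized logistic refit of the selected analytes plus age and sex;
   the probability cutoff is fixed on the training ROC by Youden's J
   (probability 0.5 by option - the original rule is unstated, and Youden
   is the common default when a single operating point must be frozen).
   The weights, cutoff and standardization constants are then *frozen* and
   applied to any later dataset without re-estimation; serialization is a
   flat JSON file.
5. Evaluation reports AUC, accuracy, sensitivity, specificity, NPV and PPV
   at the frozen cutoff; the undersampled mode draws, per iteration,
   equal-size case/control subsets with exactly matched sex (optionally
   draw-year cluster) composition and reports mean/min/max over 100
   iterations. Horizon AUCs classify conversion within 5/10/15 years,
   excluding non-converters censored before the horizon.

Missing normalized values are imputed at 0 (the within-cluster mean) for
panel fitting and scoring: sporadic LOD censoring would otherwise discard
nearly every sample under complete-case logic across hundreds of analytes.

## Enrichment and module ranking

Over-representation uses the exact hypergeometric upper tail
`P(X >= k)` with BH adjustment across the tested sets; the universe is
caller-supplied (at full scale, the unique genes covered by the assay).
Network modules (user-supplied; network construction itself is out of
scope) are ranked by combining the module's enrichment p-values for the
up-regulated and down-regulated signature subsets with the aggregated
Cauchy test,

$$T = \frac{\sum_i w_i \tan((0.5 - p_i)\pi)}{\sum_i w_i}, \qquad
p = \frac{1}{2} - \frac{\arctan T}{\pi},$$

with inputs clamped to `[1e-15, 1 - 1e-15]` (the tangent diverges at the
boundary). Only the ACAT combination plus rank-by-combined-p is
implemented; the fuller ensemble-ranking machinery of network pipelines
lives in its own external method.

## The synthetic cohort and what a green test establishes

`simulate_cohort` generates, under one seed: log-scale abundances
`10^(baseline + plate effect + status effect + age/sex nuisance + noise)`
with per-(analyte, plate) scale factors and LOD floors at a configured
null quantile (below-LOD cells become missing); a planted fraction of
analytes with case/control shifts expressed in units of the residual SD;
bimodal biomarkers driven by a latent pathology group (prevalence 0.85 in
cases, 0.25 in controls - clinical control groups are known to harbour
preclinical pathology); exponential conversion times whose log-hazard is
linear in designated analytes, with uniform administrative censoring; and
linear CDR-SB trajectories with slopes depending on status and latent
group (defaults 0.09/0.46 for controls and 1.67/2.02 points/year for
cases, negative/positive, with 0.25 between-subject SD - the magnitudes
reported for predicted-negative/positive groups in large cohorts).

Deliberate calibrations of this stated world, fixed before any acceptance
measurement:

* Residual SD is 0.05 on log10 (about 12% raw-scale CV) and age/sex
  nuisance slopes are small (SD 0.001/year and 0.01 log10 units), so that
  a *clean* cohort passes the CV <= 0.15 filter with zero removals - the
  filter's threshold is part of the stated world, and planted effects are
  defined in SD units, so all downstream inference is invariant to the
  dispersion chosen.
* Default desk scale is 1,000 analytes and 600 + 400 subjects per stage;
  the full 6,905-analyte scale is reachable by configuration.

The generator deliberately does **not** emulate assay chemistry, plate
spatial effects, non-linear batch distortions, or realistic protein-protein
correlation. A green pipeline test therefore establishes statistical
correctness of the implemented procedures under the stated generative
model - calibrated null p-values, FDR control, planted-effect and hazard
recovery, panel support recovery - but not robustness to the correlated,
heavy-tailed structure of real assay data. One consequence worth knowing:
down-regulated analytes push case values toward the LOD, and the resulting
asymmetric censoring attenuates negative effect estimates - a real property
of LOD-censored data that the tests document rather than hide.

## Numerical choices

* Exact binomial and ACAT computations are done in log space / with
  clamping as described; BH uses the step-up `cummin` form with an external
  universe size.
* The GMM-EM stops when the relative log-likelihood change falls below
  1e-6 (up to 1,000 iterations); component SDs are floored at 1e-6 to
  avoid variance collapse.
* Logistic separation (in the tertile OR and the panel refit) is flagged;
  the panel refit falls back to a lightly ridged fit (lambda = 1e-4) with
  a warning rather than returning divergent weights.
* The 90%-of-best lambda comparison uses a 1e-9 relative tolerance so that
  grid values sitting exactly at the threshold are retained.
* p-values of exactly 0 entering the meta-analysis are clamped to the
  smallest positive double with a warning.

## Known limitations

* CV filtering across biological samples is stricter than the vendor's
  replicate-based CV; on real data the `cv_scope` and threshold should be
  reviewed jointly.
* The meta-analysis variant and the training-cutoff rule are documented
  assumptions where the field's reports are silent; both are configurable.
* Per-gene rollup of multi-aptamer proteins is limited to best-p selection
  when mapping to external per-gene studies.
* No mixed-effects or robust regression; no competing risks or
  time-varying covariates; proportional-hazards diagnostics are limited to
  flagging monotone likelihoods.
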