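---
title: "Methods: MSI scoring, clonality estimation and outcome modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSI scoring, clonality estimation and outcome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiclone)
```

This vignette documents the models behind `msiclone`, the parameters that
matter, the decisions taken where the methodology is genuinely open, and
what the synthetic-data generator does and does not emulate.

## MSI scoring from STR length histograms

The unit of data is a per-locus read-length histogram: counts of reads by
total STR tract length in bp. Lengths are tract lengths, not repeat-unit
counts, because the alteration rule below is expressed in bp.

**Alteration rule.** A read at a locus with reference tract length
$L_\mathrm{ref}$ is altered when $L \le L_\mathrm{ref} - 2$ or
$L > L_\mathrm{ref}$. This is the single largest interpretive decision in
the scorer, isolated in `is_altered_length()`:

* "shortened by 2 bp" is read as *at least* 2 bp. One-bp shortenings are
  excluded deliberately: single-slip PCR stutter at mononucleotide repeats
  is overwhelmingly a ±1 bp phenomenon, and counting it would put stutter
  noise directly into the score. An `"exact2"` variant is provided for the
  stricter reading.
* Any lengthening counts. Insertions are rarer than deletions in MSI but
  are unambiguous evidence of instability.

**Score.** The MSI score is the cumulative altered-read prevalence over
evaluable loci, $S = \sum_j p_j \in [0, n_\mathrm{loci}]$. Loci with zero
depth are excluded rather than imputed, and `n_loci_evaluated` is
reported together with a normalized score $S / n_\mathrm{loci}$ so samples
with failed loci remain comparable; the raw sum is the primary quantity.

**Positivity threshold.** No universal numeric cutoff exists for this
score; platforms calibrate it internally. The default rule is
mean + 3 SD of the scores of microsatellite-stable reference samples
(≥ 20 required; 400 is the intended scale), with an upper-percentile rule
as the alternative. Positivity is *strict* ($S > t$); a score exactly at
the threshold is called MSS, the conservative choice. Calls with fewer
than `min_loci = 10` evaluable loci are indeterminate.

## Clonality estimation

Clonality quantifies the fraction of tumor cells (FFPE) or ctDNA (LB)
carrying the MSI phenotype.

**Reference envelope.** Stable samples define, per locus and length bin,
an upper prevalence bound. The default rule is the per-bin **maximum**
across references: "area above the reference distributions" then means
mass where no stable sample ever put any. Alternatives (`mean`,
`mean_2sd`) are selectable because a pooled reading of the reference set
is also defensible; the maximum is the most conservative against
false-positive excess and makes in-sample references score exactly 0.

**Statistic.** For each locus, the area above the envelope is
$\sum_\ell \max(0, \hat p(\ell) - e(\ell))$; the sample statistic $s$ is
the mean over evaluable loci, so $s \in [0, 1]$.

**Transform.** Clonality in percent is the linear calibration
$88.81\,s - 11.42$, clamped to $[0, 100]$. The negative intercept absorbs
the small excess areas that pure noise produces: a perfectly stable
sample has $s$ slightly above 0 and maps below 0, hence to 0. The root of
the transform is $s = 11.42/88.81 \approx 0.1286$.

**Classification.** FFPE: high at clonality ≥ 18%; LB: high at ≥ 7%
(boundary inclusive; LB thresholds are lower because ctDNA dilutes the
tumor signal). Clonality is computed only for MSI-positive samples;
MSS and reference samples get `not_applicable`.

**The 15% vs 18% tissue cutoff.** The low/high dichotomization of FFPE
clonality is 18%. The composite non-responder score, however, uses
"tissue clonality ≤ 15%" as its predictor. These are deliberately
distinct named constants (`classify_clonality()` thresholds vs
`composite_score()`'s `ffpe_low_max`): the dichotomization describes the
biology, while the composite predictor is a screening cutoff, and both
are kept exactly as specified rather than silently unified.

## Concordance

dMMR by IHC and MSI by PCR/NGS are treated as one binary phenotype.
Missing results are handled complete-case *per computation*: pairwise
deletion for concordance rates and Cohen's κ, listwise deletion for
Fleiss's κ and all-method agreement. This reproduces the situation where
each method has its own denominator. Cohen's κ uses marginal-product
chance agreement and is reported as undefined when both raters are
constant ($p_e = 1$). The IHC-vs-genomic discordance flag is TRUE when
the IHC call differs from **any** available genomic call (PCR, NGS-FFPE,
NGS-LB); the stricter all-methods rule is available via
`require = "all"`. Patients without an IHC result or without any genomic
result are not evaluable (NA) and drop out of models using the flag.

## Exact response statistics

Clopper–Pearson intervals come from Beta quantiles,
$\mathrm{lo} = B_{\alpha/2}(x, n-x+1)$,
$\mathrm{hi} = B_{1-\alpha/2}(x+1, n-x)$, with the conventional closed
boundaries at $x = 0$ and $x = n$. Rates use the intention-to-treat
denominator: not-evaluable patients count in $n$ but never in the
numerator. Reported percentages follow standard rounding (23/30 prints
as 76.7%).

Barnard's unconditional exact test uses the pooled score statistic
$Z = (\hat p_1 - \hat p_2)/\sqrt{\bar p(1-\bar p)(1/n_1 + 1/n_2)}$, a
two-sided rejection region by $|Z|$, and maximizes the exact binomial
tail probability over a fixed grid of 1001 equally spaced nuisance values
$\pi_g = g/1002$, $g = 1..1001$. The grid is an explicit convention
(config-visible): a fixed grid keeps the test deterministic and
reproducible, at the cost of a p-value that is a lower bound on the
supremum over $\pi \in (0,1)$ — with 1001 points the discrepancy is far
below any decision threshold. Degenerate tables (an empty group, or a
statistic of 0) return p = 1. Fisher's test is the standard two-sided
hypergeometric sum (via `stats::fisher.test`).

## Survival modelling

Progression-free survival is modelled with Weibull AFT regression:
$\log T = b_0 + x'\beta + \sigma W$, $W$ standard minimum-Gumbel, shape
$k = 1/\sigma$. The fit maximizes the log-likelihood with an L2 penalty
$\lambda \lVert \beta \rVert^2$ on covariate coefficients (intercept and
shape unpenalized), by BFGS with the analytic gradient. Reported
log-likelihoods include the $\mathrm{d}\log t$ Jacobian for events,
matching the usual parametric-survival convention.

* **Scaling.** Continuous covariates are z-scored before fitting; binary
  covariates stay 0/1 for interpretability (a flag scales everything for
  the strict reading of "scaled beforehand"). Zero-variance covariates
  are dropped with a warning; patients missing any model covariate are
  dropped listwise.
* **Penalizer selection.** $\lambda$ is chosen from the grid
  {0, 0.001, 0.01, 0.1, 1} by minimizing
  $\mathrm{AIC} = 2(p + 2) - 2\,\ell_\mathrm{unpen}(\hat\theta_\lambda)$,
  the unpenalized log-likelihood evaluated at the penalized estimates
  (the common heuristic when the effective degrees of freedom are not
  tracked). Ties break to the smallest $\lambda$; grid order is
  irrelevant.
* **Hazard ratios.** Although the model is AFT, effects are reported as
  hazard ratios through the Weibull AFT↔PH equivalence
  $\mathrm{HR}_j = \exp(-k \beta_j)$, with Wald intervals transformed the
  same way (the shape is treated as fixed in the transformation — the
  usual first-order reporting convention). Acceleration factors
  $\exp(\beta_j)$ are available via `report = "time_ratio"`.
* Kaplan–Meier estimation wraps `survival::survfit`; the median is the
  first time the curve reaches 0.5 or below.

## The synthetic-data generator

The generator exists so every stage has a testable input with known
truth. Its defaults describe the study conditions the pipeline targets:
39 mononucleotide STR loci (A/T homopolymers of 15–27 bp — the clinical
archetype of MSI markers), 5000× depth per locus, and 400 stable
reference samples.

* **Stutter**: each read shifts with probability 0.02 by ±1 repeat unit
  per step, step count 1 + Geometric(0.8), signs equiprobable. This is
  the standard first-order PCR stutter approximation; real stutter is
  deletion-biased and length-dependent, which is *not* modelled.
* **MSI clone**: per locus and sample, the clone allele deletes
  $d \ge 2$ repeat units, $d \sim 2 + \mathrm{Geom}(1/2)$ (mean 3), so
  the 2-bp detector can always see mononucleotide clones. Reads are a
  binomial mixture of clone and stable alleles at the configured clone
  fraction; per-locus depth is exact by construction (multinomial
  sampling is distributionally identical to iid per-read simulation).
* **Cohorts**: every patient is truly MSI-positive (trial inclusion).
  FFPE clone fractions are Beta(2,2), with an 8% chance of no detectable
  clone; LB fractions are the FFPE fraction times a lognormal ctDNA
  factor (meanlog −1.2, sdlog 0.8, capped at 1), zeroed with probability
  0.25 to emulate ctDNA-free plasma. These mixing weights reproduce the
  observed platform positivity scale (~91% FFPE, ~71% LB). IHC/PCR calls
  flip from truth with method-specific false-negative rates (10%/5%) and
  go missing with per-method probabilities (0.27/0.03/0.23/0.07),
  mirroring the per-method denominators such cohorts show. NGS calls are
  produced by actually running the scorer and clonality estimator on the
  generated profiles — they are not drawn from an error model.
* **Response** is logistic on the four composite-score predictors
  (intercept 0.4, weights −1.5/−1.5/−1.0/−1.5): a testing scaffold, not
  an estimated clinical model.
* **Survival** follows the Weibull AFT model with shape 1.5, intercept
  log(250) days, and configured true hazard ratios matching the
  multivariate structure the pipeline fits (0.63 FFPE clonality, 3.05 LB
  clonality, 2.16 discordance, 3.69 age, 1.12 female sex, 0.76
  metastatic, 1.08 IHC-first), with administrative censoring at the
  empirical 80% quantile of latent times.
* **Reproducibility**: one seed drives everything; per-stage substreams
  are spawned up front so changing one stage's internals does not
  perturb the draws of another.

What passing tests on this generator show — and what they do not: the
pipeline recovers clone fractions, thresholds separate clean mixtures,
and the survival machinery recovers configured hazard ratios at n = 1000.
Real FFPE/LB data add locus-specific stutter spectra, sequencing error,
capture bias, subclonal structure and non-Weibull hazards, none of which
the generator claims to reproduce; positivity percentages and kappas from
synthetic cohorts are structural analogues, not reproductions of any
clinical dataset.

## Numerical choices and degenerate inputs

* Clonality clamp to [0, 100]; transform rejects $s \notin [0,1]$.
* MSI tie at threshold → MSS; classification boundaries inclusive
  (18 → high FFPE, 7 → high LB).
* Barnard grid 1001 points; extremeness comparison uses a $10^{-10}$
  slack so ties in $|Z|$ are included despite floating-point noise.
* Zero-depth loci: excluded everywhere, never imputed.
* Missing event flags default to censored, with a warning.
* Composite score with no evaluable predictor is missing, not FALSE.
* Problem sizes in the shipped checks are chosen to give the statistics
  room to concentrate while keeping a laptop run comfortable: 8 × 50
  samples for clonality recovery, 100 replicates × n = 1000 for hazard
  ratio recovery, 200 + 200 samples for sensitivity/specificity, and a
  150-patient end-to-end cohort in the acceptance script.

## Known limitations

* The envelope rule and the alteration rule each admit alternative
  readings; both alternatives ship behind switches, and conclusions
  should be checked under both when the choice could matter.
* Hazard-ratio confidence intervals ignore the sampling variability of
  the Weibull shape in the AFT→PH transformation.
* Fleiss's κ is computed on listwise-complete rows only; with heavy,
  non-random missingness this subset can be unrepresentative.
* The multivariate survival fit drops patients missing any covariate —
  in particular LB clonality is undefined for LB-MSS patients, so the
  fitted subset is MSI-positive-in-plasma by construction, exactly as in
  the clinical analyses this mirrors. Interpret accordingly.
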