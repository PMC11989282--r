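# msiclone

Microsatellite instability (MSI) scoring, MSI-clonality estimation and
treatment-outcome modelling from short-tandem-repeat (STR) read-length
profiles.

## The problem

Colorectal tumors with deficient mismatch repair accumulate
insertion/deletion mutations in microsatellites. MSI/dMMR status selects
patients for immune checkpoint inhibition, but the determination can be made
by several methods — MMR-protein immunohistochemistry (IHC), fragment-length
PCR, and NGS of tumor tissue (FFPE) or plasma cell-free DNA (liquid biopsy,
LB) — and these do not always agree. Beyond the binary call, the *fraction*
of tumor cells (or ctDNA) carrying the MSI phenotype — its clonality — is a
quantitative axis of baseline tumor heterogeneity that may predict who will
not respond to immunotherapy.

`msiclone` implements the full analytical chain for studies of this
question, for biostatisticians and translational researchers working with
amplicon STR panels:

1. **MSI scoring.** For each STR locus the assay yields a read-length
   histogram. A read is *altered* when its tract length L satisfies
   L ≤ L_ref − 2 or L > L_ref (1-bp shortenings are excluded as PCR
   stutter). The MSI score of a sample is the cumulative prevalence of
   altered reads across the panel, S = Σ_j p_j, and a sample is
   MSI-positive when S exceeds a threshold calibrated on
   microsatellite-stable reference samples (default mean + 3 SD of
   reference scores).
2. **Clonality.** Sample length distributions are compared to a
   stable-reference envelope (per-bin maximum prevalence over the
   reference set). With s the mean per-locus area above the envelope,
   clonality (%) = clamp(88.81·s − 11.42, 0, 100). FFPE samples are
   high-clonality at ≥ 18%, LB at ≥ 7%.
3. **Concordance.** Pairwise concordance rates and Cohen's κ, Fleiss's κ
   across all four methods, all-method agreement, and a per-patient
   IHC-vs-genomic discordance flag.
4. **Outcomes.** Exact binomial (Clopper–Pearson) confidence intervals for
   ORR/DCR/pCR, Barnard's unconditional and Fisher's exact 2×2 tests, and
   a composite non-responder score: flagged when ≥ 2 of {discordance,
   LB-MSS, FFPE clonality ≤ 15%, LB clonality ≥ 7%} are present, or on LB
   clonality ≥ 10% alone.
5. **Survival.** Kaplan–Meier curves and penalized Weibull accelerated
   failure time (AFT) regression of progression-free survival, with
   covariates scaled beforehand, the L2 penalizer selected automatically
   by AIC, and hazard ratios obtained via the Weibull AFT↔PH equivalence
   HR_j = exp(−k·β_j).
6. **Synthetic data.** A generator producing stable reference profiles,
   FFPE/LB mixtures of a stable background and a deletion-shifted MSI
   clone with PCR stutter, and complete cohorts (method calls with error
   and missingness, logistic response, Weibull AFT survival), so the
   whole pipeline is testable end to end without patient-level data.

## Worked example

```r
library(msiclone)

cfg   <- sim_config(seed = 7)                    # 39 loci, 5000x, 400 refs
panel <- generate_panel(cfg)
refs  <- generate_reference_profiles(cfg, panel)
thr   <- calibrate_threshold(refs, panel = panel)
env   <- build_envelope(refs, panel)

cfg$seed <- NULL
samp <- generate_sample_profile(cfg, panel, clone_fraction = 0.35,
                                sample_type = "FFPE",
                                sample_id = "TUMOR01")$profile
(call <- call_msi(samp, panel, thr))
#> <msi_result> TUMOR01: score 13.8420 (threshold 0.4961, 39 loci) -> MSI_positive
estimate_clonality(samp, env, call$status)
#> <clonality_result> TUMOR01 (FFPE): s = 0.3437, clonality = 19.1% -> high
round(clopper_pearson(15, 30), 1)    # exact 95% CI for a 15/30 response rate
#>   lo   hi
#> 31.3 68.7
```

A sample with 35% of reads from the MSI clone scores 13.8 cumulative
altered-read prevalence over 39 loci — far above the 0.50 threshold
calibrated on the stable references — and its estimated clonality of 19.1%
is classified high for tumor tissue (FFPE cutoff 18%). The exact
Clopper–Pearson interval for an observed 15/30 objective response rate is
31.3–68.7%.

`run_pipeline(sim_config(seed = 1), n_patients = 150)` executes the whole
chain (simulate → MSI calls → clonality → concordance → response and
composite score → penalized AFT) and `write_pipeline_outputs()` writes the
CSV/JSON result set.

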