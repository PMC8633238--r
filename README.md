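# mrdseq

Tumor-informed molecular-residual-disease (MRD) analysis for resected
non-small-cell lung cancer from longitudinal plasma cell-free DNA.

After surgery with curative intent, residual tumor cells shed trace DNA
into plasma months before imaging can see a relapse. `mrdseq` implements
both arms of a plasma surveillance pipeline for researchers analysing
targeted bisulfite (methylation-block) and deep targeted mutation
sequencing of serial blood draws:

* **Methylation MRD.** Patient-specific cancer methylation blocks are
  selected by ranking the resected tumor's per-block methylation rate
  within a healthy-donor plasma panel (empirical rank p < 0.05, effect
  size ≥ 0.1; patients with tumor content < 30% are excluded). The ctDNA
  fraction α of a plasma sample — the **MD ratio** — is then estimated by
  maximum likelihood under a per-block binomial mixture,

  ```
  k_j ~ Binomial(n_j, α·p_T_j + (1 − α)·p_N_j)
  ```

  with `k_j/n_j` the methylated/total plasma reads, `p_T_j` the tumor
  rate and `p_N_j` the donor background. The **MRD score** is the Wald
  statistic `W = α̂·√I(α̂)` with the closed-form Fisher information
  `I(α) = Σ n_j (p_T_j − p_N_j)² / (θ_j(1−θ_j))`; a sample is MRD
  positive when `W > 1.96`.

* **Mutation tracking.** Per-sample maxAF (highest mutant allelic
  fraction), tissue–plasma concordance classes (Match / Tis_only /
  Pla_only), and ctDNA clearance (loss of all detectable plasma
  mutations in a baseline-positive patient).

* **Cohort summaries.** Per-timepoint detection-rate tables over
  assayed patients, two-sided Fisher exact comparisons, exact Wilcoxon
  rank-sum tests, Spearman correlation of maxAF vs MD ratio, and
  recurrence lead times (earliest postoperative MRD-positive call to
  radiologic recurrence, in months).

* **Synthetic cohorts.** A fully seeded generator
  (`simulate_cohort()`) producing panels, tumor profiles, plasma block
  counts, mutation calls and the generating ground truth, used by the
  validation suite for parameter-recovery and type-I-error experiments.

## Worked example

```r
library(mrdseq)

cfg    <- sim_config(seed = 1, n_patients = 12)
cohort <- simulate_cohort(cfg)
scored <- score_cohort(cohort)     # select blocks, fit, call, track

detection_rate_table(scored$trajectories, "methylation", "baseline")
#>   timepoint_label       assay n_positive n_assayed rate
#> 1        baseline methylation         10        10  100

summary(scored$mrd_calls[["P01_B"]]$estimate)
#> Tumor-informed methylation MRD fit (sample P01_B)
#>   MD ratio (alpha_hat): 0.0148
#>   SE: 0.002815   Wald MRD score: 5.257
#>   blocks used: 153  reads used: 15298
#> 95% Wald CI: [0.009283, 0.02032]
#>   MRD POSITIVE at Wald threshold 1.96

scored$trajectories[[1]]
#> Trajectory of patient P01 - 4 plasma timepoint(s)
#>   timepoint_label days_from_surgery      wald mrd_positive max_af
#> 1        baseline                -7 5.2573013         TRUE 0.0043
#> 2      followup_1                90 0.6088658        FALSE 0.0010
#> 3      followup_2               180 0.8133653        FALSE 0.0019
#> 4      followup_3               270 4.1839529         TRUE 0.0022
```

Reading the output: before surgery 1.48% of this patient's cfDNA is
tumor-derived (Wald 5.3, MRD positive). Resection clears the signal at
the first two follow-ups; the score rises again at day 270, consistent
with this simulated patient's recurrence (ground-truth recurrence day
207). The `rate` column of the detection table is the percent of
*assayed* patients positive at that timepoint — patients without
sufficient cfDNA for an assay are excluded from that denominator, so
denominators vary across timepoints. Two of the twelve simulated
patients fall below 30% tumor content and receive no methylation
scoring at all.

File-based workflows use `read_block_table()`, `read_manifest()` and
`read_mutation_table()` on tab-separated tables (BED-like coordinates
for blocks, 1-based positions for variants); `write_cohort()` emits a
complete simulated file set in those formats.

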