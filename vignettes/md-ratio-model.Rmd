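---
title: "The tumor-informed MD-ratio model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tumor-informed MD-ratio model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdseq)
```

## The problem

After curative-intent resection of non-small-cell lung cancer, residual
tumor cells shed trace amounts of DNA into plasma long before imaging can
see a relapse. `mrdseq` quantifies that molecular residual disease (MRD)
from two parallel plasma assays:

* **methylation arm** — targeted bisulfite sequencing of methylation
  blocks (genomic regions whose reads are aggregated into
  methylated/total count pairs), interpreted through a *tumor-informed*
  model that only looks at blocks the patient's own resected tumor marked
  as aberrant;
* **mutation arm** — deep targeted sequencing of somatic variants first
  identified in the resected tissue, summarised per plasma sample as the
  maximum mutant allelic fraction (maxAF).

## Block selection

For each patient, the tumor tissue methylation rate of every block is
ranked within a panel of healthy-donor plasma samples. With a single
tumor observation per patient no two-sample test is possible, so we use
the one-sided empirical rank p-value

$$p = \frac{1 + \#\{\text{donors at least as extreme}\}}{N + 1},$$

distribution-free and exact under exchangeability. A block is selected
when `p < 0.05` (strict) *and* the tumor rate differs from the
donor-panel mean by at least `min_delta = 0.1`. The effect-size floor is
our own guard against small-but-consistent technical shifts; the rank
test alone would admit them. With $N$ donors the smallest attainable p
is $1/(N+1)$, so at least 20 donors are needed for selection at 0.05;
the simulator defaults to 30. The default direction is `hyper`
(tumor-gained methylation), the signal plasma MRD panels conventionally
track; `hypo` is available by argument. Patients whose tissue has tumor
content below 30% are excluded up front (`check_tumor_content()`): a
low-purity tissue profile mostly reflects normal cells and would define
a diluted, unreliable signature. The 30% boundary is inclusive.

## The mixture likelihood

Let $\alpha \in [0,1]$ be the fraction of cell-free DNA derived from the
tumor (the *MD ratio*). For selected block $j$ with plasma counts
$k_j / n_j$, tumor rate $p_{T,j}$ and donor background $p_{N,j}$ (the
panel mean, clamped to $[10^{-6}, 1-10^{-6}]$):

$$k_j \sim \mathrm{Binomial}\!\left(n_j,\;
  \theta_j(\alpha)\right), \qquad
  \theta_j(\alpha) = \alpha\, p_{T,j} + (1-\alpha)\, p_{N,j}.$$

$\theta_j$ is linear in $\alpha$ and the binomial log-likelihood is
concave in $\theta$, so $\ell(\alpha)$ is concave with a unique maximum
(or a flat stretch when $p_T \approx p_N$ everywhere). `fit_md_ratio()`
maximises $\ell$ on $[0,1]$ with `stats::optimize()`, compares the
interior optimum against both boundaries, and breaks numerical ties
toward the *smallest* maximiser — a flat likelihood therefore returns
$\hat\alpha = 0$, conservative toward the null. The test suite holds the
optimizer to a $10^{-4}$-step grid-search oracle within $10^{-3}$.

The expected Fisher information is available in closed form,

$$I(\alpha) = \sum_j \frac{n_j (p_{T,j} - p_{N,j})^2}
  {\theta_j(\alpha)\,(1-\theta_j(\alpha))},$$

and the **MRD score** is the Wald statistic for $H_0: \alpha = 0$,

$$W = \hat\alpha \sqrt{I(\hat\alpha)} = \hat\alpha / \mathrm{SE}(\hat\alpha),$$

with $W = 0$ whenever $\hat\alpha = 0$ or $I = 0$. We evaluate the
information at $\hat\alpha$ (the conventional Wald plug-in) rather than
at 0; the two differ little at the small $\alpha$ typical of MRD but the
plug-in matches the definition of the estimator's variance. Positivity
is called at $W > 1.96$ (strictly), the standard-normal upper-2.5%
quantile. Because $\alpha$ lives on $[0,1]$ and $\hat\alpha$ piles up on
the boundary under the null, $W$ follows a half-normal-like boundary
null and the realised type-I rate is about 2.5%, not 5% — the suite
asserts it stays below 5% over 5,000 null replicates.

Numerical details worth knowing: rates are clamped at
$\varepsilon = 10^{-6}$ so fully (un)methylated blocks cannot produce
`log(0)`; blocks with zero plasma reads are dropped before fitting and
counted separately; a sample whose selected blocks carry no reads at all
is an error ("no informative reads"), not a silent zero.

## Mutation arm

`summarize_plasma()` reduces a sample's calls to a detection flag and
maxAF, the highest mutant allelic fraction observed. An undetected
sample has maxAF *absent* (`NA`), never 0 — non-detection and a zero AF
are different observations, and conflating them would distort rank
statistics and detection-rate denominators. Variants are matched across
tissue and plasma by `(chrom, pos, ref, alt)`; coordinate-less events
(fusions, rearrangements) fall back to a `(gene, label)` key. Each
variant in the tissue/plasma union receives exactly one concordance
class (`Match`, `Tis_only`, `Pla_only`); a patient counts as concordant
when plasma shares at least one tissue variant. ctDNA *clearance* is
the loss of all detectable plasma mutations at follow-up in a patient
who was mutation-positive at baseline; baseline-negative patients are
`not_applicable`, never "cleared". Clonal-hematopoiesis removal by
paired-lymphocyte sequencing happens upstream; the pipeline only records
the fact per call (`chip_filtered`) and refuses unfiltered calls unless
explicitly overridden.

## Cohort statistics

Per-timepoint detection rates count only patients assayed at that
timepoint — cfDNA yield limits which samples get methylation profiling,
so denominators legitimately vary across timepoints. Rate contrasts use
the two-sided Fisher exact test (`stats::fisher.test`, checked in the
suite against a full hypergeometric enumeration oracle on all tables
with cells up to 12; a zero margin returns p = 1 by convention). Group
comparisons of maxAF / MD ratio use the Wilcoxon rank-sum test, exact
when the smaller group has at most 10 observations and no ties, normal
approximation with tie correction otherwise. The maxAF–MD-ratio
association uses Spearman's rank correlation: both quantities are
heavily right-skewed and the relationship is monotone, not linear, so a
rank measure is the defensible default.

The recurrence *lead time* is the interval from the earliest
postoperative MRD-positive methylation call to the radiologic recurrence
date, in months at 30.4375 days/month (the calendar average; the
convention matters at the 0.1-month reporting precision). "Elevated MRD"
is operationalised as the Wald positivity rule — it is the only crisply
defined criterion; an alternative "increase versus the prior timepoint"
reading exists in the field but is ambiguous about baselines and is not
the default.

## What the simulator emulates

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, plus the generating truth for scoring:

* donor panel and tumor rates from beta distributions — background
  Beta(1, 19) (mean 0.05) on tumor-hyper blocks, tumor Beta(18, 2)
  (mean 0.9), uninformative blocks Beta(5, 5). The shapes are our
  choice: they give a clear hypermethylation margin (about 0.85) while
  leaving genuinely overlapping blocks for the selection step to reject;
* per-block plasma coverage Poisson with mean 100 and tissue observation
  at 1,000 reads. Panel-wide sequencing runs at roughly 10,000x, but the
  likelihood only ever sees per-block counts, and 100 reads/block keeps
  500-replicate recovery experiments in seconds while preserving the
  regime where a 0.5–1% ctDNA fraction is detectable but not trivial;
* known spiked $\alpha$ per sample: baseline fractions log-normal around
  1%, post-operative $\alpha = 0$ for non-recurring patients, and for
  recurring patients a geometric ramp (default start 0.002, doubling per
  follow-up) beginning one to two follow-ups before the recurrence day —
  this reproduces the "molecular elevation precedes imaging"
  phenomenology without claiming real growth kinetics;
* plasma mutation AFs $\alpha \cdot \mathrm{AF}_{tissue}/\mathrm{purity}$
  observed binomially at 10,000x behind a caller floor (AF ≥ 0.05% and
  ≥ 3 alt reads), mimicking the detection limit of UMI-corrected deep
  sequencing.

One deliberate simplification: the block-level "true" background rate is
defined as the donor-panel mean — the same plug-in the estimator uses —
so recovery experiments test the estimator under a well-specified model.
Real plasma background varies between individuals beyond the panel mean;
the simulator expresses that variability only across donors in the
selection stage. Consequently, passing recovery and type-I tests shows
the inference machinery is correct, not that real-world backgrounds are
this clean; batch effects, inter-individual background shifts,
fragmentation biases and copy-number distortion of AFs are all outside
the generator. Everything is driven by a single integer seed through
fixed per-stream sub-seeds, so a cohort is byte-identical across runs.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_patients = 12)
cohort <- simulate_cohort(cfg)
scored <- score_cohort(cohort)
detection_rate_table(scored$trajectories, "methylation", "baseline")
fit <- scored$mrd_calls[["P01_B"]]$estimate
summary(fit)
```

## Problem sizes used in validation

The suite's simulation experiments run at: 200 random instances for the
grid-search oracle; 500 replicates x 1,000 informative blocks x depth
100 for recovery at $\alpha \in \{0.005, 0.01, 0.05\}$; 5,000 null
replicates x 300 blocks for boundary type-I control; a 15-patient,
2,000-block cohort for the end-to-end recurrence check. These sizes give
Monte-Carlo error comfortably inside the asserted tolerances (e.g. the
recovery SE at $\alpha = 0.01$ is about $8\times10^{-4}/\sqrt{500}$,
two orders below the 20% band).

## Known limitations

* The likelihood works on per-block counts; read-level methylation
  haplotype patterns, which can sharpen tumor/normal discrimination, are
  not modelled.
* A single $\alpha$ is fitted per sample; no joint multi-timepoint
  estimation or per-block error-rate learning.
* Confidence statements are Wald-based; near the boundary a profile or
  bootstrap interval would be more honest at very low depth.
* The concordance rate counts patients sharing at least one tissue
  variant; stricter definitions (full set recovery) would give lower
  rates.
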