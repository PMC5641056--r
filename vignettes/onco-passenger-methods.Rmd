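---
title: "Onco-passenger dosage coupling: models, parameters and design choices"
author: "oncopassenger package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Onco-passenger dosage coupling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncopassenger)
```

# The scientific problem

Chromosomal instability produces amplifications and deletions of large
segments. The driver oncogene inside such a segment is under selection;
the hundreds of neighbours that ride along — onco-passenger genes — are
not, yet their dosage changes perturb the transcriptome. Tumors can
tolerate or exploit a passenger's dosage change (its expression then
tracks copy number), or they can neutralize it, notably through DNA
methylation of the amplified copies or demethylation of a remaining
allele. This package implements the statistical machinery to separate
the two regimes and follow their consequences into survival and pathway
space.

# Data model

`OncoCohort` holds up to four aligned layers over one ordered sample
set: gene-level CNV log-ratios, expression (normalized counts),
methylation betas (probe-level, with a probe→gene map) and clinical
follow-up, with gene bodies as a `GRanges`. Layers other than CNV may be
absent; validity enforces sample alignment, betas in [0,1], positive
times and 0/1 events. Missing CNV entries (no segment coverage) are
propagated and handled pairwise-complete in every correlation, which
avoids casewise loss of samples.

## Segment-to-gene mapping

SEG input is 1-based inclusive and converted internally to 0-based
half-open intervals. A gene's value in a sample is the length-weighted
mean of segment means over the covered bases of the gene body; zero
coverage yields `NA`. The gene body, not the promoter, defines the
interval, because segment means measure dosage rather than regulation.
How a segmentation tool should resolve genes spanning several segments
is genuinely open; length-weighting is this package's normative choice
and is pinned by a per-base brute-force oracle in the tests.
Overlapping segments within one sample are rejected rather than
averaged — they indicate an upstream error.

## Thresholds

All stage defaults live in `defaultThresholds()` and are recorded in the
run manifest when overridden:

* gain: 90th percentile of a gene's log-ratios strictly `> 0.50`;
  loss: 10th percentile strictly `< -0.50`. Percentiles use linear
  interpolation between order statistics (`quantile` type 7), the most
  common convention, stated here because the boundary cases in the test
  suite depend on it.
* expression filter: count strictly `> 30` in at least
  `ceiling(0.10 * n)` samples.
* CR pivot and fallback cutoff: `r = 0.4`.
* overexpression alpha `0.001`; Cox z band `|z| <= 2`; walk restart
  `0.05`.

# CR classification

The dosage correlation is Pearson's r between a gene's CNV row and its
own `log2(count + 1)` expression. The log transform is a deliberate
choice: normalized counts are heavy-tailed and a linear-scale Pearson
correlation would be dominated by a few samples.

The CR cutoff is fitted from the density of these correlations: Gaussian
KDE with the Silverman rule-of-thumb bandwidth (`bw.nrd0`) on a 512-point
grid over [-1, 1]; the two highest local maxima are taken as the hills
and the cutoff is the grid location of the minimum strictly between
them. Three guards make this robust and deterministic:

* if fewer than two local maxima exist, the fallback 0.4 is returned;
* the lesser hill must rise at least 1.1-fold above the valley density
  (`min_prominence`), otherwise sampling wiggles on a unimodal density
  would masquerade as bimodality;
* the valley must lie in the admissible window [0.0, 0.8]; minima in
  the tails are artefacts of sparse data.

Ties at the cutoff are assigned to CR-low: the strict rule
(`r > cutoff` is CR-high) is required for determinism and is asserted by
the class validity method. Whether a per-cohort valley or the fixed 0.4
should be used is exposed as an argument; the pathway stage always
pivots at the fixed 0.4.

# Profiles and enrichment

An index oncogene's co-amplification profile correlates its CNV with
every gene's CNV; its co-expression profile correlates the same CNV with
every gene's log2 expression. Profile concordance is the Pearson
correlation of the two vectors across genes with the index gene
excluded (Spearman is available; Pearson is the default because profile
values are already bounded correlations). For enrichment, samples are
split at index CNV > 0.5, genes overexpressed in the gain group are
detected by a Welch two-sample t-test on log2 counts — the simplest test
of a difference in means under unequal variances — and the overlap with
the co-amplified set (profile r > 0.4 by default) is evaluated with the
upper-tail hypergeometric distribution. A `trans_only` scope drops the
index gene's chromosome, separating physical co-amplification from
downstream effects.

# Methylation compensation

Per-gene CNV–methylation correlations use one of three explicit probe
policies (`best_abs`, `mean_beta`, `per_probe`) — the summarization of
multi-probe genes is ambiguous in principle, so the policy is an
argument and is echoed in the output. Coherence is the Spearman rank
correlation (and OLS slope) of CNV–methylation against CNV–mRNA
correlations: compensation manifests as negative coherence. Group
comparisons of beta values split samples into copy-gain (CNV > 0.5),
2N (|CNV| <= 0.5) and, for the deletion side, loss (CNV < -0.5) — the
symmetric scale of the gain call. Betas are bounded and non-normal, so
the comparison uses a two-sided Mann–Whitney test; for small groups the
p-value is computed by full enumeration of group assignments with
average ranks, which stays exact under ties.

# Survival screening

Each gene is screened with a univariate Cox proportional-hazards model
on standardized log2 expression, so coefficients are log hazard ratios
per expression SD and comparable genome-wide. The partial likelihood is
maximized by Newton–Raphson with Efron's approximation for ties (the
default of the standard survival software); the z-score uses the
observed information. Non-convergence after 50 iterations is flagged,
never silently accepted. The NS band is inclusive (`|z| <= 2`), so the
three strata partition the tested genes. Kaplan–Meier curves use a
median expression split by default (tertiles offered), and group
comparison uses the standard log-rank chi-square.

# Pathway flux

The per-gene correlations are transformed by `2^(r - 0.4)`: positive,
centered at 1, CR-high above 1 and CR-low below. The walk moves from
node i to neighbour j with probability proportional to
`edge_weight(i, j) * value(j)` and restarts with probability 0.05 (a
conventional propagation default, exposed as an argument) into the
value-proportional distribution; the stationary law is found by power
iteration to an L1 change below 1e-10. Edge flux is the symmetric sum
`pi(i) P(i->j) + pi(j) P(j->i)`. Disconnected graphs are walked per
component with component mass proportional to summed node values. A
pathway's score sums member node flux and pathway-internal edge flux;
its null permutes node labels within degree bins (exact bins up to
degree 10, doubling bins above), which controls for hub effects without
rewiring the graph. With `exact = TRUE` every bin-consistent placement
is enumerated and the null SD is the population value, which the test
suite checks against full enumeration on a degree-regular toy graph.
These walk mechanics are this package's normative definition of the
statistic, validated against closed-form linear solves rather than any
external implementation.

# The synthetic cohort generator

`simulateCohort()` emulates the joint structure the analysis assumes,
with ground truth returned alongside:

* **Copy number.** Each driver is amplified in a sample with its
  configured frequency; the amplified segment extends geometrically
  (mean `segment_decay` genes per side), giving the distance-decaying
  co-amplification the analysis expects. Segment means are
  Normal(0.8, 0.1) — a typical single-copy-gain log-ratio — over a
  per-chromosome background of Normal(0, `cnv_noise_sd`).
* **Expression.** `log2(count + 1) = baseline + slope * CNV +
  Normal(0, 0.3)`, with slope `dosage_slope` for dosage-coupled genes
  and 0 for CR-low genes. Genes outside amplicons are labelled
  `neutral` and keep the dosage slope: coupling is the genome-wide
  default; planted uncoupling is the exception. Baselines are uniform
  on 6–12 log2 counts so genes clear the expression filter.
* **Methylation.** One probe per gene (multi-probe behaviour is tested
  with dedicated fixtures);
  `beta = plogis(qlogis(b0) + methyl_compensation * k * CNV + noise)`
  with `k = +2` for CR-low (hypermethylate on gain) and `k = -2` for
  amplicon CR-high genes (hypomethylate on gain).
* **Survival.** Exponential proportional hazards: the baseline is
  exponential because Cox estimation is baseline-free, so any monotone
  baseline would do and the simplest is preferred. Five CR-high and
  five CR-low amplicon genes carry coefficients
  `hazard_coef_crhigh` / `hazard_coef_crlow` on standardized
  expression. Censoring times are exponential with rate
  `lambda0 * censor_rate / (1 - censor_rate)`, giving a marginal
  censoring probability of about `censor_rate` for baseline-hazard
  subjects — the simplest independent-censoring mechanism.
* **Ground truth.** Amplicon membership is defined as lying within
  `segment_decay` genes of a driver; the CR-low set is an exact
  `round(cr_low_fraction * n_amplicon)`-sized random subset, so the
  planted fraction is not itself binomially noisy.

Defaults (200 samples, 2000 genes, 3 drivers, amplification frequency
0.4, decay 30 genes, dosage slope 1, CR-low fraction 0.3, compensation
1, hazards ±0.5, censoring 0.3) describe a mid-sized cohort with strong
but not caricatural effects. Everything is deterministic given `seed`,
and the generator restores the caller's RNG state.

What the generator does **not** emulate: real breakpoint processes,
tumor purity and ploidy, subclonality, batch effects, probe-level
chemistry, or correlated clinical covariates. Passing parameter-recovery
tests therefore demonstrates that the estimators do what they claim
under the stated generative model — not that real cohorts satisfy that
model.

# Problem sizes and numerical choices in the validation suite

The test and acceptance workloads use cohorts of 100–300 samples and
100–300 genes with 1–2 drivers — large enough that planted effects are
identifiable (≥ 100 amplicon genes where fraction recovery is asserted)
and small enough to iterate quickly. Null calibration of the Cox z uses
1000 permutations at 200 subjects; pathway nulls use 300 permutations
over 40 pathways of 15 genes. In validation fixtures the planted
pathway is wired as an interacting module (a ring with chords) over a
random background network, because a pathway is a set of interacting
genes and the flux statistic is designed to reward coherent modules; the
39 competing pathways are random gene sets. Power iteration tolerance
is 1e-10; Newton–Raphson tolerance 1e-9 on the score; correlation
oracles agree to ~1e-12 (the limit of the naive sum formula's floating
point stability).

# Known limitations

* The valley detector assumes at most two meaningful modes; heavily
  multi-modal correlation landscapes fall back to 0.4.
* Univariate Cox screening marginalizes over co-expressed outcome
  genes, attenuating coefficient magnitudes (signs are preserved —
  this is visible in the README example).
* The exact pathway-null enumeration is only practical on small graphs;
  large graphs use the sampled null.
* Deletion-side analyses reuse the gain machinery with mirrored
  thresholds; no special handling of homozygous deletion exists.
* `mapSegmentsToGenes` materializes a dense gene × sample matrix and a
  dense transition matrix is used for the walk; both are sized for
  desk-scale cohorts and curated networks, not genome-scale interactomes.
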