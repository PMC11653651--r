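---
title: "Models and methods behind mirlame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirlame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlame)
```

`mirlame` analyzes blood miRNA profiles of feedlot cattle with different
lameness phenotypes (digital dermatitis DD, foot rot FR, toe tip necrosis
TTN, the FR+DD combination FRDD, and healthy controls HC), sampled at
diagnosis (W0) and one and two weeks after treatment (W1, W2). This
vignette records the models the package implements, the defaults it
chooses where the procedure leaves a choice open, and what its simulation
based tests do and do not demonstrate.

## Expression calling and specificity rules

Counts are normalized to reads per million mapped reads with the count
matrix's own column totals as the denominator — after alignment to a
miRNA reference, the miRNA-assigned reads are the only mapped reads
available, so no external library-size file is needed. A miRNA is
*expressed* in a sample when RPM is strictly greater than 1; a value of
exactly 1 is not expressed. Ties at the threshold are vanishingly rare in
real data, but the strict reading keeps the rule unambiguous.

A miRNA is *phenotype-specific* when it is expressed in at least 60% of
one phenotype's samples while being expressed in **no** sample of any
other group. The "no sample" part is the strictest defensible reading of
"not in other groups"; it is exposed as `max_other_prevalence` (default
0) so a tolerant variant (e.g. ≤ 10% elsewhere) is one argument away.
When permissive settings let a miRNA qualify in several groups, it is
assigned to the group where it is most prevalent, and dropped on ties, so
the reported sets are always disjoint. *Time-point-specific* miRNAs reuse
the same ≥ 60% group-expression rule per (phenotype, week) stratum: the
miRNA must pass it at exactly one of the sampled weeks. Using a single
prevalence rule for both cross-sectional and temporal specificity keeps
the two definitions coherent; nothing in the procedure's source defines
group-level expression any more precisely.

## Differential expression

Testing uses a deliberately simplified negative-binomial Wald scheme
rather than a full GLM framework, because the scientific content here is
the *call rule* (|log2FC| > 1 and Benjamini–Hochberg FDR < 0.05) and the
downstream procedures, not dispersion-estimation machinery:

* **Size factors** are plain median-of-ratios: each sample's median ratio
  to the per-miRNA geometric mean across samples, over miRNAs with
  nonzero counts everywhere, rescaled to geometric mean 1. When no miRNA
  is positive in all samples (sparse simulated matrices), a
  "poscounts"-style fallback takes each miRNA's geometric mean over its
  positive counts only.
* **Dispersion** is a per-miRNA method-of-moments estimate pooled within
  groups, solving `Var = mu + alpha * mu^2`, clamped at zero and shrunk
  50/50 toward a `alpha(mu) = a0 + a1/mu` trend fitted across miRNAs.
  The shrinkage stabilizes small-sample estimates enough for calibrated
  Wald tests without introducing iterative fitting.
* **The two-group fit is closed-form**: with a log link and size-factor
  offsets, the fitted group abundances are the group means of normalized
  counts, so `log2fc = log2(q_B/q_A)`, and the standard error follows
  from the delta method with `Var(y) = mu + alpha*mu^2`. A group whose
  mean is exactly zero is replaced by a pseudo-mean of 0.5 normalized
  counts, preserving direction while keeping fold changes finite.
  miRNAs with zero counts in every tested sample are excluded.

The suite verifies the consequences rather than the internals: on
simulated null data (2000 miRNAs, 20 animals per group, dispersion 0.2)
the empirical type-I error at p < 0.05 stays within [0.03, 0.07], and a
planted log2 fold change of 2 at high abundance is recovered with bias
below 0.3. Swapping the groups negates every fold change and leaves
p-values untouched.

Direction-wise summaries round half away from zero, the convention that
reproduces printed two-decimal averages from tables of per-miRNA fold
changes (base R's `round()` rounds half to even and would disagree on
exact halves). The package ships the published per-contrast fold-change
tables of the cattle cohort it models (`reported_de_log2fc()`), and
feeding them through `summarize_directions()` reproduces the cohort's
reported per-direction averages; the one published average that
disagrees with its own per-miRNA table (the FR upregulated mean) is
reported as computed from the table, not as printed.

## Temporal patterns

Within each (phenotype, recovery) stratum, time courses are the
arithmetic mean RPM per week. Profiles are standardized to mean 0,
standard deviation 1 across the three weeks — population (1/T)
denominator, since the three points are the complete series — and
constant profiles are excluded with a flag rather than silently dropped.

Fuzzy C-means uses the classical alternating updates with memberships
initialized from a seeded uniform generator. Defaults are `c = 9` (one
cluster per nominal pattern category) and fuzzifier `m = 2`, both
configurable; convergence is declared when the largest centroid shift
falls below `1e-6`. A profile exactly on a centroid receives membership
split evenly among coinciding centroids. Signature miRNAs are argmax
cluster members with membership strictly above 0.7 (ties in the argmax go
to the lowest cluster index, for reproducibility). Correctness is checked
against an independent plain-loop implementation started from the same
initial memberships: converged objectives agree within 1e-6.

Trend calling is the one place the procedure's source is genuinely
silent: no rule is stated for labeling an interval up/none/down. The
package applies the only thresholds the procedure defines anywhere — the
DE call rule — to each consecutive-week contrast (W0→W1, W1→W2), treating
animals as independent per week because no pairing model is given. The
two interval calls concatenate into the nine-category pattern set
`{U,N,D}²`; the mapping is total and injective by construction. The
clustering and the trend classification are therefore deliberately
decoupled: they share only the stratum definition, and either can be used
without the other.

## Marker evaluation

AUC is computed through the Mann–Whitney identity on midranks, so ties
count one half; this equals exhaustive concordant-pair counting, which
the tests verify on a thousand random instances. `direction = "auto"`
orients each marker so the reported AUC is at least 0.5 — the convention
of standard ROC tooling, and the orientation is reported (`">"`: higher
values indicate the case class) so the choice is auditable. Predictiveness
bands are lower-inclusive half-open intervals (0.8 is "good", 0.9 is
"excellent"), resolving the shared endpoints in the conventional band
wording in the direction consistent with 0.8 being called good. No
confidence intervals are computed; the evaluation reports point AUCs.

## qPCR validation

ΔΔCt uses the arithmetic mean Ct of the two reference assays (the
geometric mean of their linear quantities) per sample, centers on the
mean ΔCt of the calibrator group, and assumes perfect doubling per cycle
(`fold = 2^-ΔΔCt`) with no efficiency correction. Two invariances pin the
implementation: any per-sample Ct offset shared by all assays cancels
exactly, and the calibrator group's geometric mean fold change is 1 by
construction. Concordance with sequencing compares only the *sign* of the
group-level log2 ratio against the sequencing fold change — the published
validation claims directional consistency, not numerical agreement.
One-way ANOVA on the relative expressions is deliberately omitted as
routine; group differences are reported descriptively.

## The synthetic-data generator

The generator is the package's stand-in for the archived cohort and
defines the conditions under which the pipeline is tested:

* **Design**: the cross-sectional default reproduces the pre-treatment
  arm — HC 12, DD 24, FR 40, TTN 13, FRDD 17, i.e. 106 W0 samples. The
  longitudinal generator samples each animal at W0/W1/W2; its default
  stratum sizes (on the order of 10–20 animals per phenotype) match the
  scale of the cohort's recovery arm.
* **Counts** are negative-binomial, `Var = mu + alpha*mu^2`, with one
  global dispersion (default 0.2, a typical biological CV for bulk
  RNA-seq) and log-normal library sizes (mean 6.7 million reads — the
  cohort's 709 million reads over 106 libraries — CV 0.3; the source
  reports no per-sample depth distribution, so these are stated defaults,
  not inferred ones).
* **Abundance structure**: a deterministic baseline profile whose top ten
  miRNAs carry 85% of reads (geometric decay within the head, emulating
  the miR-486/let-7 dominance of bovine blood), with the tail decaying to
  a few RPM so that near-threshold miRNAs exist.
* **Planted truth**: differential effects multiply one group's mean by
  `2^log2fc`; group-specific miRNAs get a target RPM in their group and
  zero mean elsewhere (the strictest reading of specificity); temporal
  patterns shift a stratum's mean per interval by ±2 log2 units for U/D
  letters (0 for N). Everything planted is recorded in truth tables, and
  nothing else in the generative model is differential — so sensitivity
  and precision against truth are well-defined.
* **Recovery** follows the gait-score rule: recovered animals start at
  gait 2–3 and drop one point per week; unrecovered animals never
  improve. The label is derived from the trajectory (final < initial),
  with ties labeled unrecovered.
* Identical configurations (including the seed) give byte-identical
  studies.

What passing tests on this generator shows: the rules and estimators are
implemented correctly, are calibrated at the stated design sizes, and
recover planted effects of the stated magnitudes. What it does not show:
performance on real blood miRNAomes, which have correlated miRNAs,
per-miRNA dispersions, batch structure and imperfect group labels, none
of which the generator emulates. Published real-data results that depend
on the archived cohort (the 321 expressed miRNAs, per-group Venn counts,
specific marker identities, real AUC values) are consequently outside
what this package can reproduce.

## Test problem sizes and numerical choices

The simulation-based checks use the smallest sizes at which the claims
are meaningful: 2000 null miRNAs at 20 animals per group for Wald
calibration, ten seeded replicates for the specificity and concordance
rates, five for the generator's distributional checks, and N = 6
instances for the clustering oracle. These sizes keep the full suite
around ten seconds while leaving the Monte-Carlo bands comfortably wider
than the observed variation.

Degenerate inputs are handled explicitly rather than by convention:
all-zero sample columns are errors naming the sample; constant profiles
are excluded from clustering with a flag; single-class ROC contrasts are
errors (or skipped with a warning inside the orchestration wrappers);
missing reference Ct values are errors naming the sample and assay.
Validation never silently drops rows — inconsistencies like a recovered
label with a non-decreasing gait trajectory produce warnings and keep the
data.

## Known limitations

* One global dispersion in the generator and a moment-based estimator in
  the test; real data would warrant per-miRNA maximum-likelihood
  dispersions.
* Trend calls treat weeks as independent groups; a paired model would
  gain power on true longitudinal data.
* The Benjamini–Hochberg step is the only multiple-testing option.
* No multi-marker panels or cross-validation in the ROC module; the
  evaluation is per-miRNA by design.
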