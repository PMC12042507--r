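---
title: "Methods: the nc886 genotype-by-epigenotype proxy pipeline"
author: "nc886proxy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nc886 genotype-by-epigenotype proxy pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nc886proxy)
```

## The biological model

nc886 (vtRNA2-1) sits in a 1.9 kb differentially methylated region on
chromosome 5q31.1 and is the clearest human example of *polymorphic*
imprinting: roughly three quarters of individuals carry a methylated,
transcriptionally silenced maternal allele and an active paternal allele
("imprinted"), most of the rest are unmethylated on both alleles
("non-methylated"), and a small minority (a few percent) show intermediate
methylation. The epigenotype is established around conception and is stable
across the lifespan and most somatic tissues, so it can be read from a
single adult blood sample.

A second, genetic layer acts in cis through a downstream regulatory
variant, represented by the SNP rs1799962 (major allele T, minor allele C).
The minor allele raises expression of the two processed RNAs (nc886-3p and
nc886-5p) — but only when it sits on a transcriptionally *active* copy of
the gene. On the silenced maternal allele of an imprinted individual it
does nothing. This cis-action is demonstrable with family trios: among
imprinted heterozygotes, those who inherited C from the father are
upregulated about twofold, those who inherited it from the mother are
indistinguishable from non-carriers.

Because both regulators are lifelong-stable, their combination — the
epigenotype crossed with the genotype — is a *proxy for lifelong nc886 RNA
levels* that is available in any cohort with methylation and genotype
arrays, even when RNA was never measured. The pipeline classifies that
proxy, and then asks whether predicted-elevated individuals differ from
controls in cardiometabolic phenotypes, per cohort and pooled by
meta-analysis.

## Pipeline stages and their parameters

### Epigenotype classification

Per individual we take the median beta value over 11 DMR CpG probes
(`nc886Probes()`) and cut at two thresholds:

* median >= 0.4 — imprinted (monoallelic methylation),
* median < 0.2 — non-methylated,
* otherwise — intermediate.

The published thresholds are strict inequalities, which leave the boundary
points 0.2 and 0.4 unassigned; we close the intervals as `[0.4, 1]`,
`[0.2, 0.4)`, `[0, 0.2)` so that the rule is total, and expose both cut
points as arguments. The source description mentions both "median" and
"mean" summaries; we use the median throughout, which is what the
reference figure plots, and is robust to a single aberrant probe. Three
further bimodal probes with a documented hypomethylation bias
(`biasedProbes()`) are rejected from probe lists by default. A call
requires at least `minProbes = 6` of the 11 probes (a majority); samples
below that are labelled `unknown`, excluded from downstream analysis with
a recorded reason, and never silently dropped.

### Parent of origin from trios

For a heterozygous child the minor allele's parental origin is deduced by
enumeration of transmissions: a parent genotype can only contribute alleles
it carries, and a missing parent is unconstrained. The call is `paternal`
or `maternal` when exactly one transmission pattern is consistent (a single
observed homozygous parent can suffice), `ambiguous` for fully observed
double-heterozygous trios (we do not phase probabilistically — the study
design restricts to families where the origin is *known*), `unknown` when
a missing parent leaves it undetermined, and `mendelian_error` whenever an
observed parent cannot have transmitted an obligate allele. Errors are
reported, never dropped.

### The proxy and its usage labels

The nine epigenotype-by-genotype groups collapse to three usage labels:

| usage    | groups                                              |
|----------|-----------------------------------------------------|
| control  | imprinted T/T                                       |
| elevated | non-methylated T/T, T/C, C/C; imprinted C/C         |
| excluded | all intermediate; imprinted T/C                     |

Imprinted heterozygotes are excluded because without parental genotypes the
minor allele is equally likely to sit on the silenced or the active copy —
the group's expression is bimodal. A `pofoRescue` flag (default off)
optionally reassigns known-paternal carriers to elevated and
known-maternal carriers to control for sensitivity analyses; it is off by
default because the published analysis discards the whole group. Display
percentages use half-up rounding to two decimals, matching the published
tables; all raw fractions are retained.

### Expression and fold changes

Relative expression follows the delta-delta-Cq convention with the median
of imprinted individuals as the reference. Group fold changes are ratios
of medians by default (means by flag), consistent with that reference
convention; the accompanying test is Welch's t on log2 values
(Mann-Whitney by flag). The bimodality check fits one- and two-component
equal-variance Gaussian mixtures to log2 expression via `mclust` and flags
bimodality when the two-component fit wins on BIC *and* the component
means are at least 0.5 log2 units apart — a pure BIC comparison
over-detects on heavy-tailed unimodal data, and 0.5 log2 units is well
below the ~1.1 log2 separation expected between carrier and non-carrier
components, so the guard costs no sensitivity. Exact two-point data are a
degenerate zero-variance mixture and are handled directly.

### Association models

Continuous outcomes are rank-based inverse-normal transformed (Blom
offset c = 3/8, average ranks for ties — the standard convention in
quantitative-trait association work) within the analysis subset, then fit
by OLS on the elevated-vs-control indicator adjusted for age, sex and
fasting. Binary outcomes use a maximum-likelihood logistic model adjusted
for age and sex, with the odds ratio and a 1.96-normal Wald CI; an outcome
is only analysed when the cohort has more than 10 cases. Sex-stratified
fits drop the sex covariate. All fits are complete-case, with dropped and
skipped analyses recorded. Rank-deficient designs raise an error naming
the aliased columns; separation (fitted probabilities numerically 0 or 1)
is an explicit error, never a silently huge estimate. FDR adjustment is
Benjamini-Hochberg within each cohort x stratum x model-type family,
matching per-cohort adjustment.

### Meta-analysis

Continuous outcomes pool by inverse-variance fixed effects; binary
outcomes by DerSimonian-Laird random effects on the log-OR scale, with
Cochran's Q and the method-of-moments tau-squared truncated at zero. The
DL estimator was chosen over REML as the default because it is a closed
form that can be verified against a hand computation to machine precision;
`metafor` serves as an independent cross-check in the test suite. CIs use
the 1.96 normal multiplier (no small-sample adjustment), matching the
reported intervals. A single-study pooling passes the study through,
flagged. For longitudinal cohorts the pooling layer expects exactly one
timepoint per cohort; timepoint selection is a configuration concern.

## The synthetic cohort generator

Real cohort data for this locus are access-restricted, so the generator is
a first-class module: it encodes the regulatory model above and makes
every downstream stage testable at known truth.

Per individual: epigenotype ~ categorical(0.732, 0.032, 0.236); eleven
beta values from per-epigenotype Beta distributions; maternal and paternal
alleles independently Bernoulli(MAF = 0.097); expression per species =
(maternal activity + paternal activity) x 2^N(0, sd), where a T allele
contributes 1, a C allele contributes the species' fold effect, and the
maternal contribution is scaled by 0 (imprinted), 0.5 (intermediate) or 1
(non-methylated). Parental genotypes, when emitted, are drawn conditional
on the transmitted allele, so simulated trios are always Mendelian
consistent. Phenotypes are standard normal plus the configured
standardized shift for latent-elevated individuals (continuous), or
logistic with a configured baseline prevalence and log OR (binary).

Default choices, made once:

* **Mixture and MAF** — the largest reference cohort column: epigenotype
  (73.2 / 3.2 / 23.6)% and genotypes (81.6 / 17.4 / 1.0)%, which give
  MAF = (0.174 + 2 x 0.010)/2 = 0.097.
* **Beta distributions** — means 0.50 / 0.30 / 0.05 with concentration
  180, putting 0.34% of single-probe imprinted draws below 0.4; the
  11-probe median then essentially never misclassifies, reproducing the
  clean trimodal separation seen on real arrays.
* **Expression effects** — 2.18 (nc886-3p) and 1.76 (nc886-5p), the
  imprinted-heterozygote parent-of-origin contrasts, rather than the
  overall carrier fold changes (2.3 / 3.5), which mix methylation strata.
  An exact joint calibration to all published fold changes is
  over-determined; these defaults reproduce the parent-of-origin contrasts
  exactly and the others approximately.
* **Expression noise** — sd 0.6 on the log2 scale, back-computed from the
  magnitude of the published n = 33 trio contrast (FC 2.18 at
  p = 9e-6 implies a per-group log2 spread of roughly 0.6).
* **Intermediate silencing** — 0.5. No quantitative expression model is
  published for this group; it is excluded downstream, so the value only
  affects the excluded stratum.
* **Phenotype effects** — diastolic BP +0.067 SD and HDL cholesterol
  -0.066 SD (the published pooled estimates); type 2 diabetes
  log(1.260), stroke log(1.581), death log(1.290); hypertension 0 (the
  published per-cohort directions conflict and no pooled value is
  printed). Baseline prevalences 0.10 (T2D, death), 0.05 (stroke), 0.25
  (hypertension). Covariates (age, sex, fasting) are drawn but carry no
  phenotype effect by default, so configured effects are recovered on the
  inverse-normal scale without attenuation; the adjustment machinery is
  still exercised.
* **Seeds** — one seed per cohort; `simulateMultiCohort(..., seed =)`
  derives per-cohort streams by a fixed splitting rule, so adding a cohort
  never perturbs the others, and identical configuration reproduces a
  cohort exactly.

What the generator deliberately does **not** emulate: array technical
structure (probe bias, batch effects, cross-array 450K/EPIC differences),
the three discarded hypomethylation-biased probes, genotyping or
imputation error, covariate-phenotype confounding, and ancestry variation
in group frequencies. Passing tests therefore demonstrate that the
*pipeline logic* is correct at the published effect sizes and sample
sizes — not that real data are free of the preprocessing artifacts the
generator omits.

## Numerical choices and degenerate inputs

* Classification boundaries are half-open (above); thresholds are
  validated as `0 < lower < upper < 1`.
* The logistic IRLS declares convergence when the deviance change falls
  below 1e-8 (at most 50 iterations); tests that compare against closed
  forms tighten this to 1e-14.
* DL tau-squared truncates at zero, where the random-effects result
  coincides with fixed effects exactly.
* A zero-residual linear fit is flagged (`perfect_fit`) rather than
  reported with a meaningless p-value.
* Fold changes of constant noise-free groups return exact ratios with an
  NA p-value (no test information in constant data).
* Percentage tables conserve counts exactly; rounded percentages sum to
  100 within 0.02 by construction of half-up rounding.

## Problem sizes used in the packaged analyses

The test-suite and acceptance computations run at sizes chosen to make
Monte-Carlo error small relative to the tolerances they check: population
fraction checks use one cohort of 20,000; Hardy-Weinberg goodness-of-fit
uses 50,000; the parent-of-origin contrast uses ~25,000 individuals with
parents, yielding 2,000+ informative trios (the published analysis had 33
— the packaged check verifies the estimator, not that small-sample
p-value); effect-recovery pooling uses the six published cohort sizes
(1497, 504, 2183, 1653, 658, 792) averaged over 20 seeds, giving a
standard error near 0.007 on the pooled continuous estimate against a
0.03 tolerance; null calibration uses 1000 replicates of n = 500 with
~100 cases per logistic replicate, inside the Wald test's calibrated
regime.

## Known limitations

* The proxy is a two-level contrast; dose effects (minor-allele
  homozygotes, non-methylated carriers) are collapsed into "elevated".
* The intermediate epigenotype is excluded, as in the source analysis; no
  phenotype model is offered for it.
* Binary case definitions are taken as given; no medication adjustment,
  no survival modelling.
* The VCF helper extracts a single biallelic variant; no phasing or
  multi-variant haplotypes.
* Meta-analysis assumes one independent estimate per cohort; overlapping
  samples between cohort waves must be resolved upstream.
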