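# nc886proxy

Classify the polymorphically imprinted **nc886 (vtRNA2-1)** locus from
DNA-methylation beta values, combine the epigenotype with the **rs1799962**
genotype into a proxy for lifelong nc886 RNA levels, and associate that
proxy with cardiometabolic phenotypes per cohort and by meta-analysis.

## The problem

nc886 is the only known human gene whose genomic imprinting is
*polymorphic* and independent of genotype: ~75% of people silence the
maternal allele by DNA methylation ("imprinted"), ~25% express both
alleles ("non-methylated"), and a few percent are intermediate. A
cis-acting downstream variant (rs1799962, major T / minor C) further
raises expression of the processed RNAs nc886-3p and nc886-5p — but only
when the minor allele sits on a transcriptionally active copy. Both
regulators are fixed around conception and stable for life, so the
combination

```
epigenotype (imprinted / intermediate / non-methylated)
  x  genotype (T/T, T/C, C/C)
```

predicts an individual's lifelong nc886 RNA level from two standard array
measurements, with no RNA assay. The package implements the full analysis
around that idea:

* **Epigenotype classification** — per-sample median beta over 11 DMR CpG
  probes, cut at 0.4 (imprinted) and 0.2 (non-methylated).
* **Trio genetics** — genotype frequencies and parent-of-origin inference
  for the minor allele (`paternal` / `maternal` / `ambiguous` / `unknown`
  / `mendelian_error`), demonstrating cis-action.
* **Proxy groups** — the 9 epigenotype-x-genotype groups with usage labels:
  imprinted T/T = *control*; non-methylated or imprinted C/C = *elevated*;
  intermediate and imprinted T/C = *excluded*.
* **Expression** — delta-delta-Cq relative expression, ratio-of-medians
  fold changes, and a mixture-model bimodality check.
* **Association** — inverse-normal transformed linear models (age, sex,
  fasting adjusted) and logistic models (age, sex adjusted; >10-case
  rule), with per-cohort Benjamini-Hochberg FDR.
* **Meta-analysis** — inverse-variance fixed effects (continuous) and
  DerSimonian-Laird random effects (binary), with Q, tau², weights and
  forest-plot tables.
* **Synthetic cohorts** — a generator encoding the regulatory model
  (maternal-allele silencing, cis-acting minor-allele effect, additive
  allele activities) so the whole pipeline is testable without the
  access-restricted cohort data.

## Worked example

```r
library(nc886proxy)

cfg    <- simulationConfig(nIndividuals = 5000L, seed = 42L,
                           emitParents = TRUE)
cohort <- simulateCohort(cfg)

calls <- classifyCohort(cohort)
round(attr(calls, "proportions"), 3)
#>      imprinted   intermediate non_methylated
#>          0.724          0.031          0.245

proxy <- buildProxy(calls$status, genotypes(cohort)$genotype,
                    sampleId = calls$sample_id)
attr(proxyFrequencyTable(proxy), "usage")
#>      usage count fraction percent
#> 1  control  2947   0.5894   58.94
#> 2 elevated  1252   0.2504   25.04
#> 3 excluded   801   0.1602   16.02

pofo <- callPofoCohort(genotypes(cohort))
pofoExpressionContrast(expressionData(cohort), pofo,
                       data.frame(sample_id = calls$sample_id,
                                  status = calls$status))$nc886_3p
#> FoldChange: FC = 2.238 (log2 1.162), p = 3.01e-83, n = 314 vs 266 (median/welch)

res <- runCohortAssociations(cohort, continuousOutcomes = "dbp",
                             binaryOutcomes = "t2d", strata = "all")
res[, c("outcome", "type", "estimate", "se", "p", "n", "n_cases", "or")]
#>   outcome       type estimate     se       p    n n_cases   or
#> 1     dbp continuous   0.1068 0.0337 0.00156 4199      NA   NA
#> 2     t2d     binary   0.0874 0.1108 0.42996 4199     422 1.09
```

Reading the output: about 59% of simulated individuals are imprinted
major-allele homozygotes (controls) and 25% are predicted-elevated,
matching the population tables the generator is calibrated to. Among
imprinted heterozygotes with informative trios, paternal-origin minor
alleles give a 2.24-fold nc886-3p upregulation over maternal-origin ones
(the cis-action signature; the generator's true effect is 2.18). The
association scan then recovers the configured diastolic-BP shift on the
inverse-normal scale, while this particular cohort's type-2-diabetes odds
ratio is positive but not significant at n = 5000 — detecting an OR of
1.26 reliably needs the pooled six-cohort design, which is what
`poolAll()` provides.

Per-cohort results from several cohorts pool with:

```r
pooled <- poolAll(allCohortRows)   # fixed FX for continuous, DL for binary
pooled$meta ; pooled$forest
```

A thin command-line dispatcher over these functions (subcommands
`simulate`, `classify`, `pofo`, `proxy`, `expression-fc`, `assoc`,
`meta`, `validate`, `run`) is installed at
`inst/scripts/nc886proxy-cli.R`, and `runPipeline()` executes the whole
chain from TSV sheets to pooled results with a reproducibility manifest.

## Package layout

* `R/` — S4 classes (`SimulationConfig`, `Nc886Cohort`) and the stage
  functions listed above.
* `tests/testthat/` — unit, property and oracle-equivalence tests,
  including brute-force enumerations of the trio logic and hand-rolled
  meta-analysis oracles.
* `vignettes/nc886-proxy-methods.Rmd` — the model, parameter defaults and
  their rationale, numerical choices, and limitations.
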