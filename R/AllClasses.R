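#' Simulation configuration for a synthetic nc886 cohort
#'
#' Holds every tunable parameter of the cohort generator: cohort size, the
#' epigenotype mixture, the rs1799962 minor-allele frequency, beta-value
#' distribution parameters, the allele-level expression model, phenotype
#' effect sizes and the covariate model. Construct with [simulationConfig()],
#' which supplies defaults calibrated to the published cohort tables.
#'
#' @slot nIndividuals Integer cohort size (>= 1).
#' @slot epistatusProbs Named probability triple over
#'   `c("imprinted", "intermediate", "non_methylated")`; sums to 1.
#' @slot minorAlleleFreq Probability that a transmitted allele is the minor
#'   (C) allele.
#' @slot betaMeans Named means of the per-epigenotype beta-value
#'   distributions.
#' @slot betaConcentration Concentration (shape1 + shape2) of the Beta
#'   distributions; larger values give tighter, better-separated clusters.
#' @slot paternalMinorFC Named positive ratios (`nc886_3p`, `nc886_5p`):
#'   multiplicative expression effect of a C allele on a transcriptionally
#'   active allele.
#' @slot intermediateSilencing Fraction in \[0, 1\] of maternal-allele
#'   activity retained under the intermediate epigenotype.
#' @slot expressionNoiseSd Standard deviation of log2-scale expression noise.
#' @slot continuousEffects Named standardized mean differences
#'   (elevated vs control) for continuous outcomes.
#' @slot binaryEffects Named log odds ratios (elevated vs control) for
#'   binary outcomes.
#' @slot binaryBaselinePrev Named baseline prevalences for the binary
#'   outcomes (same names as `binaryEffects`).
#' @slot ageRange Numeric length-2 age range in years.
#' @slot femaleProb Probability an individual is female (sex coded 1).
#' @slot fastingProb Probability an individual was fasting at sampling.
#' @slot emitParents Logical; draw and emit mother/father genotypes
#'   (consistent with the transmitted alleles) for every individual.
#' @slot seed Integer random seed for this cohort.
#'
#' @seealso [simulateCohort()], [simulateMultiCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    nIndividuals = "integer",
    epistatusProbs = "numeric",
    minorAlleleFreq = "numeric",
    betaMeans = "numeric",
    betaConcentration = "numeric",
    paternalMinorFC = "numeric",
    intermediateSilencing = "numeric",
    expressionNoiseSd = "numeric",
    continuousEffects = "numeric",
    binaryEffects = "numeric",
    binaryBaselinePrev = "numeric",
    ageRange = "numeric",
    femaleProb = "numeric",
    fastingProb = "numeric",
    emitParents = "logical",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (length(object@nIndividuals) != 1L || is.na(object@nIndividuals) ||
      object@nIndividuals < 1L)
    msg <- c(msg, "nIndividuals must be a single integer >= 1")
  p <- object@epistatusProbs
  if (length(p) != 3L || !identical(names(p), .EPISTATUS))
    msg <- c(msg, sprintf("epistatusProbs must be named (%s)",
                          paste(.EPISTATUS, collapse = ", ")))
  else {
    if (any(p < 0 | p > 1)) msg <- c(msg, "epistatusProbs must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9) msg <- c(msg, "epistatusProbs must sum to 1")
  }
  if (object@minorAlleleFreq < 0 || object@minorAlleleFreq > 1)
    msg <- c(msg, "minorAlleleFreq must lie in [0, 1]")
  if (!identical(names(object@betaMeans), .EPISTATUS) ||
      any(object@betaMeans <= 0 | object@betaMeans >= 1))
    msg <- c(msg, "betaMeans must be named per epigenotype and lie in (0, 1)")
  if (object@betaConcentration <= 0)
    msg <- c(msg, "betaConcentration must be positive")
  if (!identical(names(object@paternalMinorFC), .SPECIES) ||
      any(object@paternalMinorFC <= 0))
    msg <- c(msg, "paternalMinorFC must be positive, named nc886_3p/nc886_5p")
  if (object@intermediateSilencing < 0 || object@intermediateSilencing > 1)
    msg <- c(msg, "intermediateSilencing must lie in [0, 1]")
  if (object@expressionNoiseSd < 0)
    msg <- c(msg, "expressionNoiseSd must be non-negative")
  if (!identical(names(object@binaryBaselinePrev), names(object@binaryEffects)))
    msg <- c(msg, "binaryBaselinePrev must carry the same names as binaryEffects")
  if (any(object@binaryBaselinePrev <= 0 | object@binaryBaselinePrev >= 1))
    msg <- c(msg, "binaryBaselinePrev must lie in (0, 1)")
  if (length(object@ageRange) != 2L || diff(object@ageRange) < 0 ||
      any(object@ageRange < 0))
    msg <- c(msg, "ageRange must be non-decreasing and non-negative")
  if (object@femaleProb < 0 || object@femaleProb > 1)
    msg <- c(msg, "femaleProb must lie in [0, 1]")
  if (object@fastingProb < 0 || object@fastingProb > 1)
    msg <- c(msg, "fastingProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic (or assembled) nc886 cohort container
#'
#' Bundles the four per-cohort sheets — methylation beta matrix, rs1799962
#' genotypes (optionally with parental genotypes), nc886-3p/-5p relative
#' expression, and phenotypes — keyed by a shared set of sample identifiers.
#' Cohorts built by [simulateCohort()] additionally carry the generating
#' configuration and per-sample latent truth in `truth`.
#'
#' @slot methylation Numeric matrix of beta values in \[0, 1\]
#'   (samples x probes), rownames = sample ids, colnames = probe ids.
#' @slot genotypes data.frame with columns `sample_id`, `genotype`
#'   (TT/TC/CC), `maternal_allele`, `paternal_allele`, `mother_genotype`,
#'   `father_genotype` (NA where unknown).
#' @slot expression data.frame with columns `sample_id`, `nc886_3p`,
#'   `nc886_5p` (strictly positive relative expression).
#' @slot phenotypes data.frame with `sample_id`, `age`, `sex` (0 = male,
#'   1 = female), `fasting` (0/1), plus outcome columns.
#' @slot truth list; for simulated cohorts: `config` plus per-sample latent
#'   states (`epistatus`, `usage`). Empty for cohorts read from disk.
#'
#' @seealso [simulateCohort()], [readCohortSheets()], [methylationSE()]
#' @export
setClass("Nc886Cohort",
  representation(
    methylation = "matrix",
    genotypes = "data.frame",
    expression = "data.frame",
    phenotypes = "data.frame",
    truth = "list"
  )
)

setValidity("Nc886Cohort", function(object) {
  msg <- character(0)
  ids <- rownames(object@methylation)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "methylation rownames must be unique sample ids")
  if (anyDuplicated(colnames(object@methylation)))
    msg <- c(msg, "methylation colnames (probe ids) must be unique")
  b <- object@methylation
  if (any(b < 0 | b > 1, na.rm = TRUE))
    msg <- c(msg, "beta values must lie in [0, 1]")
  for (nm in c("genotypes", "expression", "phenotypes")) {
    df <- slot(object, nm)
    if (!"sample_id" %in% names(df)) {
      msg <- c(msg, sprintf("%s must have a sample_id column", nm))
      next
    }
    if (!setequal(df$sample_id, ids) || nrow(df) != length(ids))
      msg <- c(msg, sprintf("%s sample ids must match the methylation matrix", nm))
  }
  ex <- object@expression
  if (all(c("nc886_3p", "nc886_5p") %in% names(ex))) {
    if (any(ex$nc886_3p <= 0 | ex$nc886_5p <= 0, na.rm = TRUE))
      msg <- c(msg, "expression values must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Nc886Cohort Compact summary of the cohort contents.
#' @param object An `Nc886Cohort`.
#' @export
setMethod("show", "Nc886Cohort", function(object) {
  cat(sprintf("Nc886Cohort with %d samples, %d methylation probes\n",
              nrow(object@methylation), ncol(object@methylation)))
  outc <- setdiff(names(object@phenotypes),
                  c("sample_id", "age", "sex", "fasting"))
  cat(sprintf("  outcomes: %s\n", paste(outc, collapse = ", ")))
  hasParents <- any(!is.na(object@genotypes$mother_genotype))
  cat(sprintf("  parental genotypes: %s; simulated truth: %s\n",
              if (hasParents) "present" else "absent",
              if (length(object@truth)) "present" else "absent"))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: n = %d, seed = %d\n",
              object@nIndividuals, object@seed))
  cat(sprintf("  epistatus probs: %s; MAF = %.4f\n",
              paste(sprintf("%s %.3f", names(object@epistatusProbs),
                            object@epistatusProbs), collapse = ", "),
              object@minorAlleleFreq))
  cat(sprintf("  paternal minor-allele FC: 3p %.2f, 5p %.2f; log2 noise sd %.2f\n",
              object@paternalMinorFC[["nc886_3p"]],
              object@paternalMinorFC[["nc886_5p"]],
              object@expressionNoiseSd))
})

#' @rdname Nc886Cohort
#' @param x An `Nc886Cohort`.
#' @export
setGeneric("methylation", function(x) standardGeneric("methylation"))
#' @rdname Nc886Cohort
#' @export
setMethod("methylation", "Nc886Cohort", function(x) x@methylation)

#' @rdname Nc886Cohort
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname Nc886Cohort
#' @export
setMethod("genotypes", "Nc886Cohort", function(x) x@genotypes)

#' @rdname Nc886Cohort
#' @export
setGeneric("expressionData", function(x) standardGeneric("expressionData"))
#' @rdname Nc886Cohort
#' @export
setMethod("expressionData", "Nc886Cohort", function(x) x@expression)

#' @rdname Nc886Cohort
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname Nc886Cohort
#' @export
setMethod("phenotypes", "Nc886Cohort", function(x) x@phenotypes)

#' @rdname Nc886Cohort
#' @export
setGeneric("truthInfo", function(x) standardGeneric("truthInfo"))
#' @rdname Nc886Cohort
#' @export
setMethod("truthInfo", "Nc886Cohort", function(x) x@truth)

#' @rdname Nc886Cohort
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))
#' @rdname Nc886Cohort
#' @export
setMethod("cohortSize", "Nc886Cohort", function(x) nrow(x@methylation))

#' Methylation view of a cohort as a SummarizedExperiment
#'
#' Returns the beta-value matrix as a `SummarizedExperiment` (probes as rows,
#' samples as columns, the standard Bioconductor orientation) with genotype
#' and phenotype sheets merged into `colData`, for interoperability with
#' methylation tooling.
#'
#' @param cohort An [Nc886Cohort].
#' @return A [SummarizedExperiment::SummarizedExperiment] with one assay
#'   `"beta"`.
#' @export
methylationSE <- function(cohort) {
  stopifnot(is(cohort, "Nc886Cohort"))
  cd <- merge(cohort@genotypes, cohort@phenotypes, by = "sample_id")
  cd <- cd[match(rownames(cohort@methylation), cd$sample_id), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = t(cohort@methylation)),
    colData = S4Vectors::DataFrame(cd, row.names = cd$sample_id)
  )
}
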