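#' Build a simulation configuration
#'
#' Defaults encode the regulatory model the pipeline is designed to detect,
#' calibrated to the published population tables for the locus: the
#' epigenotype mixture and genotype frequencies of the largest reference
#' cohort column (imprinted 73.2%, intermediate 3.2%, non-methylated 23.6%;
#' minor-allele frequency 0.097), maternal-allele silencing under the
#' imprinted epigenotype, a cis-acting multiplicative minor-allele effect on
#' transcriptionally active alleles (2.18 for nc886-3p, 1.76 for nc886-5p,
#' the imprinted-heterozygote parent-of-origin contrasts), and small
#' phenotype effects for elevated-proxy individuals (standardized mean
#' differences for continuous outcomes, log odds ratios for binary ones).
#'
#' @param nIndividuals Cohort size.
#' @param epistatusProbs Probability triple (imprinted, intermediate,
#'   non-methylated); recycled names if unnamed.
#' @param minorAlleleFreq Minor (C) allele frequency of rs1799962.
#' @param betaMeans Means of the per-epigenotype beta-value Beta
#'   distributions.
#' @param betaConcentration Shared Beta concentration; the default 180 puts
#'   under 0.5% of single-probe imprinted draws below the 0.4 threshold.
#' @param paternalMinorFC Expression fold effect of an active C allele,
#'   per RNA species.
#' @param intermediateSilencing Maternal-allele activity fraction under the
#'   intermediate epigenotype.
#' @param expressionNoiseSd Log2-scale expression noise SD.
#' @param continuousEffects,binaryEffects,binaryBaselinePrev Named phenotype
#'   effect maps (see [SimulationConfig]).
#' @param ageRange,femaleProb,fastingProb Covariate model.
#' @param emitParents Emit parental genotypes consistent with the
#'   transmitted alleles.
#' @param seed Integer seed for this cohort's random stream.
#' @return A validated [SimulationConfig].
#' @examples
#' cfg <- simulationConfig(nIndividuals = 100, seed = 7)
#' cohort <- simulateCohort(cfg)
#' @export
simulationConfig <- function(nIndividuals = 1497L,
                             epistatusProbs = c(imprinted = 0.732,
                                                intermediate = 0.032,
                                                non_methylated = 0.236),
                             minorAlleleFreq = 0.097,
                             betaMeans = c(imprinted = 0.50,
                                           intermediate = 0.30,
                                           non_methylated = 0.05),
                             betaConcentration = 180,
                             paternalMinorFC = c(nc886_3p = 2.18,
                                                 nc886_5p = 1.76),
                             intermediateSilencing = 0.5,
                             expressionNoiseSd = 0.6,
                             continuousEffects = c(sbp = 0, dbp = 0.067,
                                                   total_chol = 0,
                                                   hdl_chol = -0.066,
                                                   nonhdl_chol = 0,
                                                   ldl_chol = 0,
                                                   glucose = 0, insulin = 0),
                             binaryEffects = c(hypertension = 0,
                                               t2d = log(1.260),
                                               stroke = log(1.581),
                                               death = log(1.290)),
                             binaryBaselinePrev = c(hypertension = 0.25,
                                                    t2d = 0.10,
                                                    stroke = 0.05,
                                                    death = 0.10),
                             ageRange = c(30, 45),
                             femaleProb = 0.5,
                             fastingProb = 0.9,
                             emitParents = FALSE,
                             seed = 1L) {
  if (is.null(names(epistatusProbs))) names(epistatusProbs) <- .EPISTATUS
  if (is.null(names(betaMeans))) names(betaMeans) <- .EPISTATUS
  if (is.null(names(paternalMinorFC))) names(paternalMinorFC) <- .SPECIES
  new("SimulationConfig",
      nIndividuals = as.integer(nIndividuals),
      epistatusProbs = epistatusProbs,
      minorAlleleFreq = minorAlleleFreq,
      betaMeans = betaMeans,
      betaConcentration = betaConcentration,
      paternalMinorFC = paternalMinorFC,
      intermediateSilencing = intermediateSilencing,
      expressionNoiseSd = expressionNoiseSd,
      continuousEffects = continuousEffects,
      binaryEffects = binaryEffects,
      binaryBaselinePrev = binaryBaselinePrev,
      ageRange = as.numeric(ageRange),
      femaleProb = femaleProb,
      fastingProb = fastingProb,
      emitParents = emitParents,
      seed = as.integer(seed))
}

## Deterministic child-seed derivation: a fixed mixing rule so that stream i
## is a pure function of (master, i) and adding streams never perturbs
## existing ones. Stays below 2^31 - 1.
deriveSeed <- function(master, stream) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 +
                as.numeric(stream) * 1046527) %% 2147483647)
}

.alleleActivity <- function(allele, fc) ifelse(allele == "C", fc, 1)

.allelesToGenotype <- function(a1, a2) {
  .GENOTYPES[(a1 == "C") + (a2 == "C") + 1L]
}

## Draw the non-transmitted parental allele and return the parent genotype.
.parentGenotype <- function(transmitted, maf, n) {
  other <- ifelse(rbinom(n, 1L, maf) == 1L, "C", "T")
  .allelesToGenotype(transmitted, other)
}

#' Simulate one cohort under the nc886 regulatory model
#'
#' Per individual: an epigenotype is drawn from the configured mixture;
#' eleven CpG beta values are drawn from that epigenotype's Beta
#' distribution; maternal and paternal rs1799962 alleles are drawn
#' independently (Bernoulli on the minor-allele frequency); expression of
#' each RNA species is the sum of the two allele activities times log-normal
#' noise, where an active T allele contributes 1, an active C allele
#' contributes the configured fold effect, and the maternal allele's
#' activity is scaled 0 (imprinted), `intermediateSilencing` (intermediate)
#' or 1 (non-methylated). Continuous phenotypes are standard normal plus the
#' configured shift for samples whose latent proxy label is elevated; binary
#' outcomes follow a logistic model with the configured baseline and log
#' odds ratio. Parental genotypes, when emitted, are always Mendelian
#' consistent with the transmitted alleles. Identical configuration (seed
#' included) reproduces the cohort exactly.
#'
#' @param config A [SimulationConfig].
#' @return An [Nc886Cohort] whose `truth` records the configuration and the
#'   per-sample latent epigenotype and usage label.
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nIndividuals
  withr::with_seed(config@seed, {
    id <- sprintf("S%05d", seq_len(n))
    epistatus <- sample(.EPISTATUS, n, replace = TRUE,
                        prob = config@epistatusProbs)

    k <- config@betaConcentration
    mu <- config@betaMeans[epistatus]
    betas <- matrix(rbeta(n * 11L, rep(mu * k, 11L), rep((1 - mu) * k, 11L)),
                    nrow = n, ncol = 11L,
                    dimnames = list(id, nc886Probes()))

    maf <- config@minorAlleleFreq
    matAllele <- ifelse(rbinom(n, 1L, maf) == 1L, "C", "T")
    patAllele <- ifelse(rbinom(n, 1L, maf) == 1L, "C", "T")
    genotype <- .allelesToGenotype(matAllele, patAllele)
    if (config@emitParents) {
      motherGeno <- .parentGenotype(matAllele, maf, n)
      fatherGeno <- .parentGenotype(patAllele, maf, n)
    } else {
      motherGeno <- fatherGeno <- rep(NA_character_, n)
    }

    silencing <- c(imprinted = 0,
                   intermediate = config@intermediateSilencing,
                   non_methylated = 1)[epistatus]
    expr <- sapply(.SPECIES, function(sp) {
      fc <- config@paternalMinorFC[[sp]]
      act <- silencing * .alleleActivity(matAllele, fc) +
        .alleleActivity(patAllele, fc)
      act * 2^rnorm(n, 0, config@expressionNoiseSd)
    })

    usage <- buildProxy(epistatus, genotype)$usage
    elevated <- as.numeric(usage == "elevated")

    pheno <- data.frame(
      sample_id = id,
      age = runif(n, config@ageRange[1], config@ageRange[2]),
      sex = rbinom(n, 1L, config@femaleProb),
      fasting = rbinom(n, 1L, config@fastingProb),
      stringsAsFactors = FALSE
    )
    for (oc in names(config@continuousEffects))
      pheno[[oc]] <- rnorm(n) + config@continuousEffects[[oc]] * elevated
    for (oc in names(config@binaryEffects)) {
      eta <- qlogis(config@binaryBaselinePrev[[oc]]) +
        config@binaryEffects[[oc]] * elevated
      pheno[[oc]] <- rbinom(n, 1L, plogis(eta))
    }

    new("Nc886Cohort",
        methylation = betas,
        genotypes = data.frame(sample_id = id, genotype = genotype,
                               maternal_allele = matAllele,
                               paternal_allele = patAllele,
                               mother_genotype = motherGeno,
                               father_genotype = fatherGeno,
                               stringsAsFactors = FALSE),
        expression = data.frame(sample_id = id,
                                nc886_3p = expr[, "nc886_3p"],
                                nc886_5p = expr[, "nc886_5p"],
                                stringsAsFactors = FALSE),
        phenotypes = pheno,
        truth = list(config = config, epistatus = setNames(epistatus, id),
                     usage = setNames(usage, id)))
  })
}

#' Simulate several independent cohorts
#'
#' Each cohort is generated by [simulateCohort()]. When `seed` is given,
#' per-cohort seeds are derived from it by a fixed splitting rule
#' (cohort i always receives the same stream regardless of how many cohorts
#' are requested); otherwise each configuration's own seed is used.
#'
#' @param configs Non-empty list of [SimulationConfig] objects.
#' @param seed Optional master seed overriding the per-config seeds.
#' @return List of [Nc886Cohort] objects, named after `configs`.
#' @export
simulateMultiCohort <- function(configs, seed = NULL) {
  if (!is.list(configs) || length(configs) == 0L)
    stop("configs must be a non-empty list of SimulationConfig objects")
  lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    stopifnot(is(cfg, "SimulationConfig"))
    if (!is.null(seed)) cfg@seed <- deriveSeed(seed, i)
    simulateCohort(cfg)
  }) |> setNames(names(configs))
}
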