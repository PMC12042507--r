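## rs1799962 genotypes and trio-based parent-of-origin inference.
## Major allele T, minor allele C throughout (configurable symbols).

#' Normalize genotype strings
#'
#' Accepts `"TT"`, `"T/C"`, `"ct"` and the like; returns canonical
#' `"TT"`/`"TC"`/`"CC"` ordered major-then-minor. Unrecognized non-missing
#' strings raise an error.
#'
#' @param g Character vector of genotypes (NA allowed).
#' @param alleles Length-2 character: major then minor allele symbol.
#' @return Character vector of canonical genotypes.
#' @export
normalizeGenotype <- function(g, alleles = c("T", "C")) {
  stopifnot(length(alleles) == 2L)
  g2 <- toupper(gsub("[/|]", "", as.character(g)))
  major <- alleles[1]; minor <- alleles[2]
  canon <- c(paste0(major, major), paste0(major, minor), paste0(minor, minor))
  g2[g2 == paste0(minor, major)] <- paste0(major, minor)
  bad <- !is.na(g2) & !(g2 %in% canon)
  if (any(bad))
    stop(sprintf("unrecognized genotype string(s): %s",
                 paste(unique(g[bad]), collapse = ", ")))
  ## report in T/C canonical symbols
  map <- setNames(.GENOTYPES, canon)
  ifelse(is.na(g2), NA_character_, map[g2])
}

.minorCount <- function(g) c(TT = 0L, TC = 1L, CC = 2L)[g]

#' Genotype frequencies and minor allele frequency
#'
#' @param g Character vector of genotypes (any format accepted by
#'   [normalizeGenotype()]); missing values are dropped with a count kept.
#' @param alleles Major/minor allele symbols.
#' @return List with `freq` (named triple TT/TC/CC summing to 1), `maf`
#'   (= (n_TC + 2 n_CC) / 2n), `counts` and `n`.
#' @export
genotypeFrequencies <- function(g, alleles = c("T", "C")) {
  g <- normalizeGenotype(g, alleles)
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("no non-missing genotypes")
  counts <- table(factor(g, levels = .GENOTYPES))
  n <- length(g)
  list(freq = setNames(as.numeric(counts) / n, .GENOTYPES),
       maf = sum(.minorCount(g)) / (2 * n),
       counts = setNames(as.integer(counts), .GENOTYPES),
       n = n)
}

## Can this (possibly missing) parent genotype transmit the given allele?
## A missing parent is unconstrained. Vectorized over both arguments.
.canTransmit <- function(parent, allele) {
  allele <- rep_len(allele, length(parent))
  is.na(parent) |
    mapply(function(p, a) !is.na(p) && grepl(a, p, fixed = TRUE),
           parent, allele, USE.NAMES = FALSE)
}

#' Parental origin of the minor allele from a genotype trio
#'
#' For a heterozygous child the call is `paternal` or `maternal` when the
#' observed parent genotypes admit exactly one transmission pattern (a
#' missing parent is unconstrained, so e.g. father T/T alone suffices to
#' call `maternal`), `ambiguous` when both parents are observed
#' heterozygotes, and `unknown` when a missing parent leaves the origin
#' undetermined. Homozygous children are `not_applicable`. Any observed
#' parent that cannot have transmitted the child's obligate allele yields
#' `mendelian_error` (checked for homozygous children too, and never
#' silently dropped).
#'
#' @param child,mother,father Genotype vectors (mother/father may be NA).
#'   Recycled to a common length.
#' @param alleles Major/minor allele symbols.
#' @return Character vector over
#'   `c("maternal", "paternal", "ambiguous", "unknown", "mendelian_error",
#'   "not_applicable")`.
#' @export
assignParentOfOrigin <- function(child, mother = NA, father = NA,
                                 alleles = c("T", "C")) {
  child <- normalizeGenotype(child, alleles)
  if (any(is.na(child))) stop("child genotype must be present")
  nLen <- max(length(child), length(mother), length(father))
  child <- rep_len(child, nLen)
  mother <- rep_len(normalizeGenotype(mother, alleles), nLen)
  father <- rep_len(normalizeGenotype(father, alleles), nLen)

  out <- character(nLen)
  het <- child == "TC"

  ## homozygous children: Mendelian check on the obligate allele
  homAllele <- ifelse(child == "TT", "T", "C")
  homErr <- !het & (!.canTransmit(mother, homAllele) |
                      !.canTransmit(father, homAllele))
  out[!het] <- ifelse(homErr[!het], "mendelian_error", "not_applicable")

  ## heterozygous children: which parent supplied the C allele?
  canPat <- .canTransmit(mother, "T") & .canTransmit(father, "C")
  canMat <- .canTransmit(mother, "C") & .canTransmit(father, "T")
  bothObserved <- !is.na(mother) & !is.na(father)
  hetCall <- ifelse(!canPat & !canMat, "mendelian_error",
             ifelse(canPat & !canMat, "paternal",
             ifelse(canMat & !canPat, "maternal",
             ifelse(bothObserved, "ambiguous", "unknown"))))
  out[het] <- hetCall[het]
  out
}

#' Parent-of-origin calls for a cohort of trios
#'
#' @param trios data.frame with columns `genotype` (child),
#'   `mother_genotype`, `father_genotype` and optionally `sample_id`.
#' @param alleles Major/minor allele symbols.
#' @return data.frame with `sample_id` and `origin`; attribute `"tally"`
#'   counts every category and sums to `nrow(trios)`.
#' @export
callPofoCohort <- function(trios, alleles = c("T", "C")) {
  stopifnot(nrow(trios) > 0L,
            all(c("genotype", "mother_genotype", "father_genotype") %in%
                  names(trios)))
  origin <- assignParentOfOrigin(trios$genotype, trios$mother_genotype,
                                 trios$father_genotype, alleles)
  out <- data.frame(
    sample_id = if ("sample_id" %in% names(trios)) trios$sample_id
                else seq_len(nrow(trios)),
    origin = origin, stringsAsFactors = FALSE)
  attr(out, "tally") <- table(factor(origin, levels = .POFO))
  out
}

#' Extract one biallelic variant's genotypes from a VCF
#'
#' Thin helper over `vcfR` turning a single named variant into the genotype
#' sheet format used by the pipeline. The REF allele is treated as major
#' and the first ALT allele as minor.
#'
#' @param vcfPath Path to a VCF file.
#' @param variantId Variant ID to extract (e.g. `"rs1799962"`).
#' @return data.frame with `sample_id` and `genotype` (canonical TT/TC/CC).
#' @export
extractVariantGenotypes <- function(vcfPath, variantId) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required for VCF extraction")
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  idx <- which(vcf@fix[, "ID"] == variantId)
  if (length(idx) != 1L)
    stop(sprintf("variant %s not found exactly once in %s", variantId, vcfPath))
  gt <- vcfR::extract.gt(vcf, element = "GT")[idx, ]
  code <- vapply(strsplit(gt, "[/|]"), function(a)
    sum(as.integer(a) > 0L), integer(1))
  data.frame(sample_id = names(gt),
             genotype = .GENOTYPES[code + 1L],
             stringsAsFactors = FALSE, row.names = NULL)
}
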