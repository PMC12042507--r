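## The genotype-by-epigenotype proxy for lifelong nc886 RNA levels.
## Usage rule: imprinted T/T individuals express one unmodified allele and
## serve as controls; any configuration predicted to raise expression
## (non-methylated locus, or a minor allele on an active copy) is elevated;
## intermediately methylated individuals and imprinted heterozygotes (whose
## minor allele sits on either the silenced or the active copy, unknowable
## without parents) are excluded.

.GROUP_ORDER <- c("imprinted_TT", "intermediate_TT", "non_methylated_TT",
                  "imprinted_TC", "intermediate_TC", "non_methylated_TC",
                  "imprinted_CC", "intermediate_CC", "non_methylated_CC")

## half-up rounding, the display convention of the published tables
roundHalfUp <- function(x, digits = 2L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Assign proxy groups and usage labels
#'
#' Combines the epigenotype with the rs1799962 genotype into the nine-level
#' proxy group and labels each sample `control` (imprinted T/T), `elevated`
#' (non-methylated any genotype, or imprinted C/C) or `excluded`
#' (intermediate epigenotype, imprinted T/C, unknown epigenotype or missing
#' genotype — each with a recorded reason, never silently dropped).
#'
#' With `pofoRescue = TRUE` (a sensitivity analysis, off by default)
#' imprinted heterozygotes with a known parental origin are reassigned:
#' paternal-origin minor alleles sit on the active copy (elevated),
#' maternal-origin ones on the silenced copy (control).
#'
#' @param status Epigenotype labels (from [classifyCohort()]); `"unknown"`
#'   and NA allowed.
#' @param genotype Genotypes (any format accepted by [normalizeGenotype()]).
#' @param sampleId Optional sample identifiers.
#' @param pofo Optional parent-of-origin calls (from
#'   [assignParentOfOrigin()]); used only when `pofoRescue = TRUE`.
#' @param pofoRescue Reassign imprinted heterozygotes of known origin.
#' @return data.frame with `sample_id`, `epistatus`, `genotype`, `group`,
#'   `usage`, `reason` (NA unless excluded).
#' @export
buildProxy <- function(status, genotype, sampleId = NULL, pofo = NULL,
                       pofoRescue = FALSE) {
  n <- max(length(status), length(genotype))
  status <- rep_len(as.character(status), n)
  genotype <- rep_len(normalizeGenotype(genotype), n)
  if (is.null(sampleId)) sampleId <- seq_len(n)
  status[is.na(status)] <- "unknown"

  usage <- rep("excluded", n)
  reason <- rep(NA_character_, n)
  known <- status %in% .EPISTATUS & !is.na(genotype)
  reason[status == "unknown"] <- "unknown_epistatus"
  reason[is.na(genotype)] <- "missing_genotype"
  reason[known & status == "intermediate"] <- "intermediate_methylation"

  ctrl <- known & status == "imprinted" & genotype == "TT"
  elev <- known & (status == "non_methylated" |
                     (status == "imprinted" & genotype == "CC"))
  impHet <- known & status == "imprinted" & genotype == "TC"
  usage[ctrl] <- "control"
  usage[elev] <- "elevated"
  reason[impHet] <- "imprinted_heterozygote_pofo_unknown"

  if (pofoRescue && !is.null(pofo)) {
    pofo <- rep_len(as.character(pofo), n)
    resc <- impHet & pofo %in% c("maternal", "paternal")
    usage[resc] <- ifelse(pofo[resc] == "paternal", "elevated", "control")
    reason[resc] <- NA_character_
  }

  data.frame(sample_id = sampleId, epistatus = status, genotype = genotype,
             group = ifelse(known, paste(status, genotype, sep = "_"),
                            NA_character_),
             usage = usage, reason = reason, stringsAsFactors = FALSE)
}

#' Nine-group and usage frequency tables
#'
#' Tabulates proxy assignments into the nine (epigenotype x genotype)
#' groups, with raw fractions and display percentages (half-up, two
#' decimals). Samples without a group (unknown epigenotype or missing
#' genotype) are counted separately under attribute `"ungrouped"`. The
#' three-level usage tally is attached as attribute `"usage"`.
#'
#' @param assignments data.frame from [buildProxy()].
#' @return data.frame with one row per group (`group`, `count`,
#'   `fraction`, `percent`), attributes `"usage"` and `"ungrouped"`.
#' @export
proxyFrequencyTable <- function(assignments) {
  if (nrow(assignments) == 0L) stop("assignments must be non-empty")
  grouped <- assignments[!is.na(assignments$group), ]
  n <- nrow(assignments)
  tab <- table(factor(grouped$group, levels = .GROUP_ORDER))
  out <- data.frame(group = .GROUP_ORDER,
                    count = as.integer(tab),
                    fraction = as.numeric(tab) / n,
                    stringsAsFactors = FALSE)
  out$percent <- roundHalfUp(100 * out$fraction, 2L)
  utab <- table(factor(assignments$usage, levels = .USAGE))
  usage <- data.frame(usage = .USAGE, count = as.integer(utab),
                      fraction = as.numeric(utab) / n,
                      stringsAsFactors = FALSE)
  usage$percent <- roundHalfUp(100 * usage$fraction, 2L)
  attr(out, "usage") <- usage
  attr(out, "ungrouped") <- sum(is.na(assignments$group))
  out
}

#' Usage percentages from the nine group percentages
#'
#' Pure arithmetic consequence of the assignment rules, applicable directly
#' to published group-frequency rows: control = imprinted T/T; elevated =
#' the three non-methylated groups plus imprinted C/C; excluded = the three
#' intermediate groups plus imprinted T/C.
#'
#' @param groupPercent Nine non-negative values, ordered as
#'   `.GROUP_ORDER` (imprinted/intermediate/non-methylated within TT, TC,
#'   CC) or named by those group labels.
#' @return Named triple (control, elevated, excluded) on the same scale.
#' @export
usageFromGroupPercentages <- function(groupPercent) {
  if (length(groupPercent) != 9L)
    stop("groupPercent must have exactly 9 values")
  if (any(groupPercent < 0)) stop("groupPercent must be non-negative")
  p <- if (!is.null(names(groupPercent))) groupPercent[.GROUP_ORDER]
       else setNames(groupPercent, .GROUP_ORDER)
  c(control = unname(p["imprinted_TT"]),
    elevated = unname(p["non_methylated_TT"] + p["non_methylated_TC"] +
                        p["non_methylated_CC"] + p["imprinted_CC"]),
    excluded = unname(p["intermediate_TT"] + p["intermediate_TC"] +
                        p["intermediate_CC"] + p["imprinted_TC"]))
}
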