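#' CpG probes classifying the nc886 differentially methylated region
#'
#' `nc886Probes()` returns the 11 array probes whose bimodal methylation
#' pattern indexes the polymorphic imprint at the locus; per-sample
#' classification uses their median beta value. `biasedProbes()` returns
#' three further bimodal probes that are hypomethylation-biased and are
#' rejected from classification by default.
#'
#' @return Character vector of probe ids.
#' @export
nc886Probes <- function() {
  c("cg07158503", "cg11608150", "cg06478886", "cg04481923", "cg18678645",
    "cg06536614", "cg25340688", "cg26896946", "cg00124993", "cg08745965",
    "cg18797653")
}

#' @rdname nc886Probes
#' @export
biasedProbes <- function() c("cg04515200", "cg13581155", "cg11978884")

#' Per-sample median methylation over the DMR probes
#'
#' Computes, for every sample, the median of its non-missing beta values
#' over the listed probes, together with the number of probes used.
#' Hypomethylation-biased probes present in `probes` are dropped with a
#' warning unless `allowBiased = TRUE`.
#'
#' @param beta Numeric samples x probes matrix of beta values in \[0, 1\]
#'   (missing allowed), rownames = sample ids.
#' @param probes Probe ids to summarize over; defaults to [nc886Probes()].
#' @param allowBiased Keep probes listed by [biasedProbes()].
#' @return data.frame with columns `sample_id`, `median_beta`
#'   (NA when no probe is observed) and `n_probes_used`.
#' @export
summarizeDmr <- function(beta, probes = nc886Probes(), allowBiased = FALSE) {
  stopifnot(is.matrix(beta))
  if (length(probes) == 0L) stop("probes must be non-empty")
  if (!allowBiased && any(probes %in% biasedProbes())) {
    bad <- intersect(probes, biasedProbes())
    warning(sprintf("rejecting hypomethylation-biased probe(s): %s",
                    paste(bad, collapse = ", ")))
    probes <- setdiff(probes, biasedProbes())
  }
  present <- intersect(probes, colnames(beta))
  if (length(present) == 0L)
    stop("none of the listed probes are present in the beta matrix")
  if (any(beta[, present] < 0 | beta[, present] > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  sub <- beta[, present, drop = FALSE]
  data.frame(
    sample_id = rownames(sub),
    median_beta = apply(sub, 1L, median, na.rm = TRUE),
    n_probes_used = rowSums(!is.na(sub)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Three-group epigenotype from a median beta value
#'
#' Thresholds follow the locus' trimodal clustering: imprinted
#' (monoallelic methylation) for beta >= `upper`, non-methylated (both
#' alleles unmethylated) for beta < `lower`, intermediate otherwise. The
#' published thresholds use strict inequalities that leave the boundary
#' points unassigned; here the intervals are half-open — `[upper, 1]`
#' imprinted, `[lower, upper)` intermediate, `[0, lower)` non-methylated —
#' so 0.4 classifies as imprinted and 0.2 as intermediate. `NA` input maps
#' to `"unknown"`.
#'
#' @param medianBeta Numeric vector of values in \[0, 1\] (NA allowed).
#' @param lower,upper Classification thresholds, `0 < lower < upper < 1`.
#' @return Character vector in
#'   `c("imprinted", "intermediate", "non_methylated", "unknown")`.
#' @export
classifyEpistatus <- function(medianBeta, lower = 0.2, upper = 0.4) {
  stopifnot(lower > 0, upper < 1, lower < upper)
  if (any(medianBeta < 0 | medianBeta > 1, na.rm = TRUE))
    stop("medianBeta must lie in [0, 1]")
  out <- ifelse(is.na(medianBeta), "unknown",
         ifelse(medianBeta >= upper, "imprinted",
         ifelse(medianBeta < lower, "non_methylated", "intermediate")))
  as.character(out)
}

#' Classify a whole cohort's epigenotypes
#'
#' Runs [summarizeDmr()] then [classifyEpistatus()] per sample; samples with
#' fewer than `minProbes` observed probes are called `"unknown"` and omitted
#' from the proportion summary (attribute `"proportions"`, which sums to 1
#' over the three known statuses).
#'
#' @param x Beta matrix (samples x probes) or an [Nc886Cohort].
#' @param probes,allowBiased Passed to [summarizeDmr()].
#' @param minProbes Minimum observed probes for a call (default 6 of 11).
#' @param lower,upper Passed to [classifyEpistatus()].
#' @return data.frame of per-sample calls (`sample_id`, `median_beta`,
#'   `n_probes_used`, `status`) with attribute `"proportions"`.
#' @export
setGeneric("classifyCohort",
  function(x, probes = nc886Probes(), minProbes = 6L, lower = 0.2,
           upper = 0.4, allowBiased = FALSE) standardGeneric("classifyCohort"))

#' @rdname classifyCohort
#' @export
setMethod("classifyCohort", "matrix",
  function(x, probes, minProbes, lower, upper, allowBiased) {
    calls <- summarizeDmr(x, probes, allowBiased)
    calls$status <- classifyEpistatus(calls$median_beta, lower, upper)
    calls$status[calls$n_probes_used < minProbes] <- "unknown"
    attr(calls, "proportions") <- epistatusProportions(calls)
    calls
  })

#' @rdname classifyCohort
#' @export
setMethod("classifyCohort", "Nc886Cohort",
  function(x, probes, minProbes, lower, upper, allowBiased) {
    classifyCohort(methylation(x), probes, minProbes, lower, upper,
                   allowBiased)
  })

#' Epigenotype proportions over classified samples
#'
#' @param calls data.frame from [classifyCohort()] (needs a `status` column).
#' @return Named proportions over the three known statuses (unknown samples
#'   excluded); sums to 1.
#' @export
epistatusProportions <- function(calls) {
  known <- calls$status[calls$status != "unknown"]
  if (length(known) == 0L)
    return(setNames(rep(NA_real_, 3L), .EPISTATUS))
  tab <- table(factor(known, levels = .EPISTATUS))
  prop <- as.numeric(tab) / length(known)
  setNames(prop, .EPISTATUS)
}
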