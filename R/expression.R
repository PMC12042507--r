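#' Relative expression from qPCR quantification cycles
#'
#' Standard delta-delta-Cq quantification against a reference group:
#' each sample's relative expression is `2^-(Cq - median reference Cq)`,
#' so the reference group's median relative expression is exactly 1. The
#' customary reference here is the imprinted-epigenotype group.
#'
#' @param cq Named numeric vector of Cq values (names = sample ids).
#' @param referenceSamples Sample ids forming the reference group.
#' @return Named numeric vector of relative expression values.
#' @export
relativeExpression <- function(cq, referenceSamples) {
  if (length(referenceSamples) == 0L) stop("reference set must be non-empty")
  refCq <- cq[names(cq) %in% referenceSamples]
  refCq <- refCq[!is.na(refCq)]
  if (length(refCq) == 0L) stop("no non-missing Cq in the reference set")
  2^(-(cq - median(refCq)))
}

#' Fold change between two expression groups
#'
#' Fold change is the ratio of group summaries of relative expression
#' (medians by default — robust, and consistent with the median-of-imprinted
#' reference convention; means by flag), with a two-group test on log2
#' values (Welch's t by default, Mann-Whitney by flag).
#'
#' @param a,b Positive numeric expression vectors; `b` is the reference
#'   (denominator).
#' @param summary `"median"` or `"mean"` group summary.
#' @param test `"welch"` or `"wilcoxon"` two-group test on log2 values.
#' @return List of class `"FoldChange"`: `fc`, `log2fc` (= log2(fc)), `p`,
#'   `nA`, `nB`, `summary`, `test`.
#' @export
groupFoldChange <- function(a, b, summary = c("median", "mean"),
                            test = c("welch", "wilcoxon")) {
  summary <- match.arg(summary)
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty")
  if (any(a <= 0) || any(b <= 0))
    stop("expression values must be strictly positive")
  s <- if (summary == "median") median else mean
  fc <- s(a) / s(b)
  ## degenerate groups (constant data) carry no test information
  p <- if (length(a) > 1L && length(b) > 1L) {
    tryCatch(
      if (test == "welch") t.test(log2(a), log2(b))$p.value
      else wilcox.test(log2(a), log2(b), exact = FALSE)$p.value,
      error = function(e) NA_real_)
  } else NA_real_
  structure(list(fc = fc, log2fc = log2(fc), p = p,
                 nA = length(a), nB = length(b),
                 summary = summary, test = test),
            class = "FoldChange")
}

#' @export
print.FoldChange <- function(x, ...) {
  cat(sprintf("FoldChange: FC = %.3f (log2 %.3f), p = %.3g, n = %d vs %d (%s/%s)\n",
              x$fc, x$log2fc, x$p, x$nA, x$nB, x$summary, x$test))
  invisible(x)
}

#' Parent-of-origin expression contrast
#'
#' Among imprinted heterozygotes with an unambiguous parental-origin call,
#' contrasts expression of paternal-origin minor-allele carriers (minor
#' allele on the transcriptionally active copy) against maternal-origin
#' carriers (minor allele on the silenced copy). Under cis-action the
#' paternal group is upregulated and the maternal group matches imprinted
#' non-carriers.
#'
#' @param expression data.frame with `sample_id` and the species columns.
#' @param pofo data.frame with `sample_id`, `origin` (from
#'   [callPofoCohort()]).
#' @param epistatus data.frame with `sample_id`, `status` (from
#'   [classifyCohort()]).
#' @param species RNA species column(s) to contrast.
#' @param ... Passed to [groupFoldChange()].
#' @return Named list of `FoldChange` objects, one per species.
#' @export
pofoExpressionContrast <- function(expression, pofo, epistatus,
                                   species = .SPECIES, ...) {
  d <- merge(merge(expression, pofo, by = "sample_id"),
             epistatus[, c("sample_id", "status")], by = "sample_id")
  d <- d[d$status == "imprinted" & d$origin %in% c("maternal", "paternal"), ]
  pat <- d[d$origin == "paternal", ]
  mat <- d[d$origin == "maternal", ]
  if (nrow(pat) == 0L) stop("paternal-origin group is empty")
  if (nrow(mat) == 0L) stop("maternal-origin group is empty")
  out <- lapply(species, function(sp) groupFoldChange(pat[[sp]], mat[[sp]], ...))
  setNames(out, species)
}

#' One- versus two-component mixture check for bimodal expression
#'
#' Fits equal-variance Gaussian mixtures with one and two components to
#' log2 expression (via `mclust`) and flags bimodality when the
#' two-component fit is preferred by BIC and the component means are at
#' least `minSeparation` log2 units apart. Imprinted-heterozygote
#' expression at this locus is expected bimodal (minor allele on the active
#' vs the silenced copy); other proxy groups unimodal.
#'
#' @param values Positive expression values, length >= 10.
#' @param minSeparation Minimum log2 mean separation to call bimodality.
#' @return List: `bimodal`, `means` (log2), `weights`, `deltaBic`
#'   (two-component BIC minus one-component; positive favours two), `n`.
#' @export
bimodalityReport <- function(values, minSeparation = 0.5) {
  values <- values[!is.na(values)]
  if (length(values) < 10L) stop("need at least 10 values")
  if (any(values <= 0)) stop("expression values must be strictly positive")
  x <- log2(values)
  if (sd(x) == 0)
    return(list(bimodal = FALSE, means = mean(x), weights = 1,
                deltaBic = -Inf, n = length(x)))
  ux <- sort(unique(x))
  if (length(ux) == 2L) {
    ## two point masses: a degenerate two-component mixture fits exactly
    return(list(bimodal = diff(ux) >= minSeparation, means = ux,
                weights = as.numeric(table(x)) / length(x),
                deltaBic = Inf, n = length(x)))
  }
  fit1 <- mclust::Mclust(x, G = 1, modelNames = "E", verbose = FALSE)
  fit2 <- mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE)
  if (is.null(fit2))
    return(list(bimodal = FALSE, means = fit1$parameters$mean,
                weights = 1, deltaBic = -Inf, n = length(x)))
  deltaBic <- as.numeric(fit2$bic - fit1$bic)  # mclust BIC: larger is better
  sep <- abs(diff(fit2$parameters$mean))
  list(bimodal = deltaBic > 0 && sep >= minSeparation,
       means = fit2$parameters$mean,
       weights = fit2$parameters$pro,
       deltaBic = deltaBic, n = length(x))
}
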