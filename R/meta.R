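## Inverse-variance pooling of per-cohort association estimates.
## Fixed effects for continuous outcomes, DerSimonian-Laird random effects
## for binary outcomes (pooled on the log-OR scale), per the study design.

.metaResult <- function(model, estimate, se, k, Q, tau2, weights, labels,
                        passThrough = FALSE) {
  z <- estimate / se
  structure(list(model = model, k = k,
                 estimate = estimate, se = se,
                 ci_low = estimate - 1.96 * se,
                 ci_high = estimate + 1.96 * se,
                 z = z, p = 2 * pnorm(-abs(z)),
                 Q = Q, tau2 = tau2,
                 weights = setNames(weights / sum(weights), labels),
                 passThrough = passThrough),
            class = "MetaResult")
}

#' @export
print.MetaResult <- function(x, ...) {
  cat(sprintf("%s-effects meta-analysis of k = %d: estimate %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$model, x$k, x$estimate, x$se, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  Q = %.3f, tau2 = %.4f%s\n", x$Q, x$tau2,
              if (x$passThrough) " (single-study pass-through)" else ""))
  invisible(x)
}

.checkMetaInput <- function(estimate, se) {
  if (length(estimate) != length(se) || length(estimate) == 0L)
    stop("estimate and se must be non-empty and of equal length")
  if (any(is.na(estimate)) || any(is.na(se)) || any(se <= 0))
    stop("all standard errors must be positive and estimates non-missing")
}

#' Fixed-effects (inverse-variance) pooling
#'
#' Weights `w_i = 1/se_i^2`; pooled estimate `sum(w b) / sum(w)`; pooled
#' standard error `1/sqrt(sum(w))`; Cochran heterogeneity
#' `Q = sum(w (b - pooled)^2)`. A single study is returned as-is, flagged
#' as pass-through.
#'
#' @param estimate Per-cohort estimates (regression coefficients or log
#'   odds ratios).
#' @param se Per-cohort standard errors (> 0).
#' @param labels Optional cohort labels for the weight vector.
#' @return A `MetaResult` list: estimate, se, 95% CI, z, p, Q, tau2 (0),
#'   normalized weights, model.
#' @export
fixedEffects <- function(estimate, se, labels = NULL) {
  .checkMetaInput(estimate, se)
  w <- 1 / se^2
  pooled <- sum(w * estimate) / sum(w)
  .metaResult("fixed",
              estimate = pooled, se = 1 / sqrt(sum(w)),
              k = length(estimate),
              Q = sum(w * (estimate - pooled)^2), tau2 = 0,
              weights = w, labels = labels,
              passThrough = length(estimate) == 1L)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-cohort variance
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effects weights `w = 1/se^2`, then inverse-variance pooling with
#' weights `1/(se^2 + tau2)`. When `Q <= k - 1`, tau2 truncates to 0 and
#' the result equals [fixedEffects()]. For binary outcomes pooling is on
#' the log-OR scale; exponentiate the estimate and CI to report odds
#' ratios.
#'
#' @inheritParams fixedEffects
#' @return A `MetaResult` list (model `"random"`).
#' @export
randomEffects <- function(estimate, se, labels = NULL) {
  .checkMetaInput(estimate, se)
  k <- length(estimate)
  if (k == 1L) {
    out <- fixedEffects(estimate, se, labels)
    out$model <- "random"
    return(out)
  }
  w <- 1 / se^2
  fixed <- sum(w * estimate) / sum(w)
  Q <- sum(w * (estimate - fixed)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wStar <- 1 / (se^2 + tau2)
  pooled <- sum(wStar * estimate) / sum(wStar)
  .metaResult("random",
              estimate = pooled, se = 1 / sqrt(sum(wStar)),
              k = k, Q = Q, tau2 = tau2, weights = wStar, labels = labels)
}

#' Pool per-cohort association results across cohorts
#'
#' For every outcome x stratum present: continuous outcomes are pooled by
#' [fixedEffects()], binary outcomes by [randomEffects()] on the log-OR
#' scale. Cohorts with missing estimates for an outcome (e.g. skipped
#' case-count rule) are dropped from that pooling with the count recorded.
#' Also emits a forest-plot table: one row per contributing cohort
#' (estimate, CI, normalized weight) followed by the pooled row.
#'
#' @param results data.frame of per-cohort rows: `cohort`, `outcome`,
#'   `stratum`, `type` (`"continuous"`/`"binary"`), `estimate`, `se`
#'   (the format produced by [runCohortAssociations()] plus a `cohort`
#'   column).
#' @return List with `meta` (one row per outcome x stratum: model, k,
#'   k_total, estimate, se, ci, z, p, Q, tau2, and or/or_ci for binary)
#'   and `forest` (long table for plotting).
#' @export
poolAll <- function(results) {
  need <- c("cohort", "outcome", "stratum", "type", "estimate", "se")
  stopifnot(all(need %in% names(results)))
  keys <- unique(results[, c("outcome", "stratum", "type")])
  metaRows <- list(); forestRows <- list()
  for (i in seq_len(nrow(keys))) {
    oc <- keys$outcome[i]; st <- keys$stratum[i]; ty <- keys$type[i]
    sub <- results[results$outcome == oc & results$stratum == st &
                     results$type == ty, ]
    ok <- !is.na(sub$estimate) & !is.na(sub$se) & sub$se > 0
    used <- sub[ok, ]
    if (nrow(used) == 0L) next
    pool <- if (ty == "continuous")
      fixedEffects(used$estimate, used$se, used$cohort)
    else
      randomEffects(used$estimate, used$se, used$cohort)
    isBin <- ty == "binary"
    metaRows[[length(metaRows) + 1L]] <- data.frame(
      outcome = oc, stratum = st, type = ty, model = pool$model,
      k = pool$k, k_total = nrow(sub),
      estimate = pool$estimate, se = pool$se,
      ci_low = pool$ci_low, ci_high = pool$ci_high,
      z = pool$z, p = pool$p, Q = pool$Q, tau2 = pool$tau2,
      or = if (isBin) exp(pool$estimate) else NA_real_,
      or_ci_low = if (isBin) exp(pool$ci_low) else NA_real_,
      or_ci_high = if (isBin) exp(pool$ci_high) else NA_real_,
      stringsAsFactors = FALSE)
    forestRows[[length(forestRows) + 1L]] <- data.frame(
      outcome = oc, stratum = st, row = c(used$cohort, "pooled"),
      estimate = c(used$estimate, pool$estimate),
      ci_low = c(used$estimate - 1.96 * used$se, pool$ci_low),
      ci_high = c(used$estimate + 1.96 * used$se, pool$ci_high),
      weight = c(unname(pool$weights), 1),
      stringsAsFactors = FALSE)
  }
  list(meta = do.call(rbind, metaRows), forest = do.call(rbind, forestRows))
}
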