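#' Rank-based inverse normal transform
#'
#' Maps non-missing values to normal quantiles via the Blom variant used
#' throughout quantitative-trait association work:
#' `qnorm((r - c) / (m - 2c + 1))` with average ranks `r` for ties,
#' non-missing count `m` and offset `c = 3/8`. Missing values stay missing.
#'
#' @param x Numeric vector (NA allowed); needs >= 2 non-missing values.
#' @param offset Rank offset `c` (default 3/8).
#' @return Numeric vector of transformed scores, same length as `x`.
#' @export
inverseNormalTransform <- function(x, offset = 3 / 8) {
  obs <- !is.na(x)
  m <- sum(obs)
  if (m < 2L) stop("need at least 2 non-missing values")
  r <- rank(x[obs], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[obs] <- qnorm((r - offset) / (m - 2 * offset + 1))
  out
}

.checkFullRank <- function(mm) {
  qrd <- qr(mm)
  if (qrd$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrd$pivot[(qrd$rank + 1L):ncol(mm)]]
    stop(sprintf("collinear design: column(s) %s are aliased",
                 paste(dropped, collapse = ", ")))
  }
  qrd$rank
}

.assocRow <- function(outcome = NA_character_, stratum = NA_character_,
                      type = NA_character_, estimate = NA_real_,
                      se = NA_real_, p = NA_real_, q = NA_real_,
                      n = NA_integer_, n_cases = NA_integer_,
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      perfect_fit = FALSE, reason = NA_character_) {
  data.frame(outcome = outcome, stratum = stratum, type = type,
             estimate = estimate, se = se, p = p, q = q,
             n = n, n_cases = n_cases, or = or,
             ci_low = ci_low, ci_high = ci_high,
             perfect_fit = perfect_fit, reason = reason,
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of a (typically inverse-normal transformed)
#' outcome on an elevated-vs-control indicator plus covariates, on complete
#' cases. The reported estimate is the group coefficient; the standard
#' error uses the unbiased residual variance and p comes from the t
#' distribution on `n - rank` degrees of freedom. A rank-deficient design
#' raises a collinearity error naming the aliased columns; a zero-residual
#' fit is flagged (`perfect_fit`), not an error.
#'
#' @param y Numeric outcome.
#' @param group 0/1 indicator (1 = elevated).
#' @param covariates Optional data.frame of numeric covariates.
#' @return One-row data.frame (estimate, se, p, n, ...).
#' @export
fitLinear <- function(y, group, covariates = NULL) {
  d <- data.frame(.y = y, .group = group)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  d <- d[complete.cases(d), , drop = FALSE]
  mm <- model.matrix(~ ., data = d[, -1L, drop = FALSE])
  rank <- .checkFullRank(mm)
  if (nrow(d) <= rank) stop("insufficient data: n <= model rank")
  fit <- lm(.y ~ ., data = d)
  ## a zero-residual fit is reported via the perfect_fit flag, not a warning
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients[".group", ]
  perfect <- sm$sigma < 1e-12
  .assocRow(type = "continuous",
            estimate = unname(co["Estimate"]),
            se = unname(co["Std. Error"]),
            p = if (perfect) NA_real_ else unname(co["Pr(>|t|)"]),
            n = nrow(d), perfect_fit = perfect)
}

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logit fit (IRLS via `stats::glm`) of a binary outcome
#' on the elevated-vs-control indicator plus covariates, on complete cases.
#' Reports the log odds ratio with Wald standard error, the odds ratio and
#' its 95% CI (`exp(estimate +/- 1.96 se)`). Cohorts with `minCases` cases
#' or fewer are skipped with a recorded reason (not an error); separation
#' or non-convergence raises an explicit error rather than returning a
#' silent result.
#'
#' @param y Binary 0/1 outcome.
#' @param group 0/1 indicator (1 = elevated).
#' @param covariates Optional data.frame of numeric covariates.
#' @param minCases Analyze only when the case count exceeds this (default
#'   10).
#' @param epsilon,maxit IRLS convergence tolerance and iteration cap.
#' @return One-row data.frame (estimate = log OR, se, p, or, ci_low,
#'   ci_high, n, n_cases) or a skipped row carrying `reason`.
#' @export
fitLogistic <- function(y, group, covariates = NULL, minCases = 10L,
                        epsilon = 1e-8, maxit = 50L) {
  d <- data.frame(.y = y, .group = group)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  d <- d[complete.cases(d), , drop = FALSE]
  nCases <- sum(d$.y == 1)
  if (nCases == 0L || nCases == nrow(d))
    stop("both outcome classes must be present")
  if (nCases <= minCases)
    return(.assocRow(type = "binary", n = nrow(d), n_cases = nCases,
                     reason = sprintf("skipped: %d cases <= minCases (%d)",
                                      nCases, minCases)))
  mm <- model.matrix(~ ., data = d[, -1L, drop = FALSE])
  .checkFullRank(mm)
  fit <- withCallingHandlers(
    glm(.y ~ ., data = d, family = binomial(),
        control = glm.control(epsilon = epsilon, maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("separation detected: fitted probabilities numerically 0 or 1")
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop(sprintf("logistic fit did not converge in %d iterations", maxit))
  mu <- fit$fitted.values
  if (any(mu < 1e-10 | mu > 1 - 1e-10))
    stop("separation detected: fitted probabilities numerically 0 or 1")
  co <- summary(fit)$coefficients[".group", ]
  est <- unname(co["Estimate"]); se <- unname(co["Std. Error"])
  .assocRow(type = "binary", estimate = est, se = se,
            p = unname(co["Pr(>|z|)"]), n = nrow(d), n_cases = nCases,
            or = exp(est), ci_low = exp(est - 1.96 * se),
            ci_high = exp(est + 1.96 * se))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Validating wrapper over `stats::p.adjust(method = "BH")`: step-up
#' adjustment with monotonicity enforcement, preserving input order.
#'
#' @param p Numeric p-values in \[0, 1\] (NA allowed and propagated).
#' @return Adjusted values, same length and order.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-cohort association scan
#'
#' For every outcome and stratum (`all`, `women`, `men`): continuous
#' outcomes are inverse-normal transformed within the analysis subset and
#' fit by [fitLinear()] adjusted for age, sex and fasting; binary outcomes
#' are fit by [fitLogistic()] adjusted for age and sex, subject to the
#' case-count rule. Sex-stratified fits drop the sex covariate. The sample
#' is restricted to control and elevated proxy labels (the group indicator
#' is elevated = 1). FDR adjustment (q) is applied within each
#' (stratum x outcome-type) family, matching per-cohort adjustment.
#' Per-outcome failures are recorded in `reason` and the scan continues.
#'
#' @param x An [Nc886Cohort] or a phenotype data.frame (with `sample_id`,
#'   `age`, `sex`, `fasting` and outcome columns).
#' @param proxy data.frame from [buildProxy()]. When `x` is a cohort and
#'   `proxy` is NULL, it is built from the cohort's methylation and
#'   genotypes with default settings.
#' @param continuousOutcomes,binaryOutcomes Outcome column names.
#' @param strata Subset of `c("all", "women", "men")`.
#' @param minCases Passed to [fitLogistic()].
#' @return data.frame with one row per outcome x stratum.
#' @export
runCohortAssociations <- function(x, proxy = NULL,
                                  continuousOutcomes = NULL,
                                  binaryOutcomes = NULL,
                                  strata = c("all", "women", "men"),
                                  minCases = 10L) {
  if (is(x, "Nc886Cohort")) {
    pheno <- phenotypes(x)
    if (is.null(proxy)) {
      calls <- classifyCohort(x)
      proxy <- buildProxy(calls$status, genotypes(x)$genotype,
                          sampleId = calls$sample_id)
    }
  } else pheno <- x
  if (is.null(proxy)) stop("proxy assignments are required")
  strata <- match.arg(strata, several.ok = TRUE)

  d <- merge(pheno, proxy[, c("sample_id", "usage")], by = "sample_id")
  d <- d[d$usage %in% c("control", "elevated"), , drop = FALSE]
  d$.group <- as.numeric(d$usage == "elevated")

  fitOne <- function(sub, oc, type, stratum) {
    covs <- if (stratum == "all") {
      if (type == "continuous") sub[, c("age", "sex", "fasting")]
      else sub[, c("age", "sex")]
    } else {
      if (type == "continuous") sub[, c("age", "fasting")]
      else sub[, c("age"), drop = FALSE]
    }
    row <- tryCatch({
      if (type == "continuous")
        fitLinear(inverseNormalTransform(sub[[oc]]), sub$.group, covs)
      else
        fitLogistic(sub[[oc]], sub$.group, covs, minCases = minCases)
    }, error = function(e) .assocRow(type = type,
                                     reason = conditionMessage(e)))
    row$outcome <- oc
    row$stratum <- stratum
    row
  }

  out <- list()
  for (stratum in strata) {
    sub <- switch(stratum, all = d,
                  women = d[!is.na(d$sex) & d$sex == 1, , drop = FALSE],
                  men = d[!is.na(d$sex) & d$sex == 0, , drop = FALSE])
    for (oc in continuousOutcomes)
      out[[length(out) + 1L]] <- fitOne(sub, oc, "continuous", stratum)
    for (oc in binaryOutcomes)
      out[[length(out) + 1L]] <- fitOne(sub, oc, "binary", stratum)
  }
  res <- do.call(rbind, out)
  ## FDR families: stratum x model type, within this cohort
  for (stratum in unique(res$stratum)) for (type in unique(res$type)) {
    sel <- res$stratum == stratum & res$type == type & !is.na(res$p)
    if (any(sel)) res$q[sel] <- bhFdr(res$p[sel])
  }
  rownames(res) <- NULL
  res
}
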