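test_that("inverse normal transform follows the Blom convention", {
  got <- inverseNormalTransform(c(5, 1, 9))
  expected <- qnorm((c(2, 1, 3) - 0.375) / (3 + 0.25))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got, c(0, -0.8694, 0.8694), tolerance = 1e-4)

  # ties collapse to the average-rank score; all tied -> all zero
  expect_equal(inverseNormalTransform(rep(3, 5)), rep(0, 5))
  # symmetric input sums to zero
  expect_lt(abs(sum(inverseNormalTransform(c(-2, -1, 0, 1, 2)))), 1e-9)
  # missing values stay missing, ranks use non-missing count
  got2 <- inverseNormalTransform(c(1, NA, 2))
  expect_true(is.na(got2[2]))
  expect_equal(got2[c(1, 3)],
               qnorm((c(1, 2) - 0.375) / (2 + 0.25)))
  expect_error(inverseNormalTransform(c(1, NA, NA)), "at least 2")

  # monotone and rank preserving; large-m scores standardize
  withr::with_seed(3, x <- rexp(5000))
  z <- inverseNormalTransform(x)
  expect_identical(order(z), order(x))
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(sd(z) - 1), 0.01)
  # invariant to monotone transforms of the raw outcome
  expect_equal(inverseNormalTransform(log(x)), z)
})

test_that("linear fit matches an independent normal-equations solve", {
  d <- data.frame(y = c(1.2, 0.8, 1.9, 2.4, 3.1, 2.2, 4.0, 3.6),
                  g = c(0, 0, 0, 0, 1, 1, 1, 1),
                  age = c(31, 45, 52, 38, 47, 33, 59, 41),
                  sex = c(0, 1, 0, 1, 0, 1, 0, 1))
  fit <- fitLinear(d$y, d$g, d[, c("age", "sex")])
  X <- cbind(1, d$g, d$age, d$sex)
  betaHat <- solve(t(X) %*% X, t(X) %*% d$y)
  resid <- d$y - X %*% betaHat
  s2 <- sum(resid^2) / (8 - 4)
  seHat <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(fit$estimate, betaHat[2], tolerance = 1e-10)
  expect_equal(fit$se, seHat[2], tolerance = 1e-10)
  expect_equal(fit$p, 2 * pt(-abs(betaHat[2] / seHat[2]), df = 4),
               tolerance = 1e-10)
  expect_equal(fit$n, 8L)
})

test_that("linear fit flags perfect fits and names collinear columns", {
  g <- rep(c(0, 1), 5)
  perfect <- fitLinear(g, g)
  expect_equal(perfect$estimate, 1)
  expect_true(perfect$perfect_fit)
  covs <- data.frame(age = 1:10, age2 = 2 * (1:10))
  expect_error(fitLinear(rnorm(10), g, covs), "age2")
  expect_error(fitLinear(rnorm(3)[c(1, 2)], c(0, 1)), "insufficient|aliased")
})

test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  y <- c(rep(1, 30), rep(0, 70), rep(1, 20), rep(0, 80))
  g <- c(rep(1, 100), rep(0, 100))
  fit <- fitLogistic(y, g, epsilon = 1e-14)
  expect_equal(fit$or, (30 * 80) / (70 * 20), tolerance = 1e-10)
  expect_equal(fit$se, sqrt(1 / 30 + 1 / 70 + 1 / 20 + 1 / 80),
               tolerance = 1e-8)
  expect_equal(fit$n_cases, 50L)
  expect_equal(fit$ci_low, exp(fit$estimate - 1.96 * fit$se))
})

test_that("logistic fit enforces case rules and detects separation", {
  expect_error(fitLogistic(rep(1, 20), rep(c(0, 1), 10)), "both outcome")
  skipped <- fitLogistic(c(rep(1, 9), rep(0, 191)), rep(c(0, 1), 100))
  expect_match(skipped$reason, "9 cases")
  expect_true(is.na(skipped$estimate))
  # group perfectly predicts outcome -> separation error, not a result
  expect_error(fitLogistic(rep(c(0, 1), each = 20), rep(c(0, 1), each = 20)),
               "separation")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bhFdr(0.01), 0.01)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(rep(1, 4)), rep(1, 4))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(5, {
    for (rep in 1:20) {
      p <- runif(sample(1:10, 1))
      expect_equal(bhFdr(p), oracleBH(p), tolerance = 1e-12)
    }
  })
})

test_that("cohort association scan recovers configured effects and skips sparse outcomes", {
  cfg <- simulationConfig(
    nIndividuals = 1500L, seed = 23L,
    continuousEffects = c(dbp = 0.4),
    binaryEffects = c(t2d = log(2), stroke = 0),
    binaryBaselinePrev = c(t2d = 0.15, stroke = 0.004))
  co <- simulateCohort(cfg)
  res <- runCohortAssociations(co, continuousOutcomes = "dbp",
                               binaryOutcomes = c("t2d", "stroke"))
  all <- res[res$stratum == "all", ]
  expect_gt(all$estimate[all$outcome == "dbp"], 0)
  expect_lt(all$p[all$outcome == "dbp"], 0.01)
  expect_gt(all$or[all$outcome == "t2d"], 1)
  # ~4 stroke cases in 1500: skipped with a recorded reason
  expect_match(all$reason[all$outcome == "stroke"], "minCases")
  # sex strata exclude the sex covariate yet still fit
  expect_equal(nrow(res), 9L)
  expect_false(any(is.na(res$estimate[res$outcome == "dbp"])))
  # q-values within each stratum/type family dominate p-values
  ok <- !is.na(res$p)
  expect_true(all(res$q[ok] >= res$p[ok] - 1e-12))
})

test_that("an empty contrast group fails loudly for every outcome", {
  co <- simulateCohort(simulationConfig(nIndividuals = 300L, seed = 29L))
  pheno <- phenotypes(co)
  proxy <- data.frame(sample_id = pheno$sample_id, usage = "control")
  res <- runCohortAssociations(pheno, proxy, continuousOutcomes = "dbp",
                               binaryOutcomes = "t2d", strata = "all")
  expect_true(all(is.na(res$estimate)))
  expect_true(all(!is.na(res$reason)))
})
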