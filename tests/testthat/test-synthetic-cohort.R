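test_that("degenerate configurations force exact expression values", {
  # all imprinted, no minor allele, no noise: only the paternal T is active
  cfg <- simulationConfig(nIndividuals = 50L,
                          epistatusProbs = c(1, 0, 0),
                          minorAlleleFreq = 0,
                          expressionNoiseSd = 0, seed = 3L)
  co <- simulateCohort(cfg)
  expect_true(all(truthInfo(co)$epistatus == "imprinted"))
  expect_true(all(genotypes(co)$genotype == "TT"))
  expect_equal(expressionData(co)$nc886_3p, rep(1, 50))
  expect_equal(expressionData(co)$nc886_5p, rep(1, 50))

  # all non-methylated: both T alleles active
  cfg2 <- simulationConfig(nIndividuals = 50L,
                           epistatusProbs = c(0, 0, 1),
                           minorAlleleFreq = 0,
                           expressionNoiseSd = 0, seed = 3L)
  expect_equal(expressionData(simulateCohort(cfg2))$nc886_3p, rep(2, 50))
})

test_that("noise-free expression matches brute-force allele-activity enumeration", {
  s <- 0.5; fc3 <- 2.18; fc5 <- 1.76
  cfg <- simulationConfig(nIndividuals = 600L,
                          epistatusProbs = c(1, 1, 1) / 3,
                          minorAlleleFreq = 0.5,
                          intermediateSilencing = s,
                          expressionNoiseSd = 0, seed = 8L)
  co <- simulateCohort(cfg)
  # oracle: activity = silencing(epistatus) * allele(mat) + allele(pat)
  oracleExpr <- function(epi, mat, pat, fc) {
    sil <- c(imprinted = 0, intermediate = s, non_methylated = 1)[[epi]]
    af <- function(a) if (a == "C") fc else 1
    sil * af(mat) + af(pat)
  }
  g <- genotypes(co); epi <- truthInfo(co)$epistatus
  exp3 <- mapply(oracleExpr, epi, g$maternal_allele, g$paternal_allele, fc3)
  exp5 <- mapply(oracleExpr, epi, g$maternal_allele, g$paternal_allele, fc5)
  expect_equal(expressionData(co)$nc886_3p, unname(exp3), tolerance = 1e-12)
  expect_equal(expressionData(co)$nc886_5p, unname(exp5), tolerance = 1e-12)
  # noise-free expression is confined to the enumerable activity levels:
  # {1, fc} (imprinted) + {2, 1 + fc, 2fc} (non-methylated) +
  # {1.5, 0.5 + fc, 1 + fc/2, 1.5fc} (half-silenced intermediate)
  levels3 <- unique(c(1, fc3, 2, 1 + fc3, 2 * fc3,
                      1.5, 0.5 + fc3, 1 + fc3 / 2, 1.5 * fc3))
  expect_true(all(vapply(expressionData(co)$nc886_3p,
                         function(v) any(abs(v - levels3) < 1e-12),
                         logical(1))))
  expect_lte(length(unique(round(expressionData(co)$nc886_3p, 12))),
             length(levels3))
})

test_that("default cohort reproduces the reference population fractions", {
  co <- simulateCohort(simulationConfig(nIndividuals = 20000L, seed = 11L))
  epi <- table(truthInfo(co)$epistatus) / 20000
  expect_equal(unname(epi[["imprinted"]]), 0.732, tolerance = 0.015)
  expect_lt(abs(epi[["imprinted"]] - 0.732), 0.01)
  expect_lt(abs(epi[["non_methylated"]] - 0.236), 0.01)
  gf <- genotypeFrequencies(genotypes(co)$genotype)
  expect_lt(abs(gf$freq[["TT"]] - 0.816), 0.01)
  expect_lt(abs(gf$maf - 0.097), 0.005)
})

test_that("identical seeds reproduce cohorts exactly; seeds split deterministically", {
  cfg <- simulationConfig(nIndividuals = 200L, seed = 5L, emitParents = TRUE)
  a <- simulateCohort(cfg); b <- simulateCohort(cfg)
  expect_identical(methylation(a), methylation(b))
  expect_identical(expressionData(a), expressionData(b))
  expect_identical(genotypes(a), genotypes(b))

  # multi-cohort: singleton equals the direct call; master seed reruns match
  expect_identical(methylation(simulateMultiCohort(list(cfg))[[1]]),
                   methylation(a))
  cfgs <- list(simulationConfig(nIndividuals = 100L),
               simulationConfig(nIndividuals = 100L))
  r1 <- simulateMultiCohort(cfgs, seed = 99L)
  r2 <- simulateMultiCohort(cfgs, seed = 99L)
  expect_identical(methylation(r1[[1]]), methylation(r2[[1]]))
  expect_identical(methylation(r1[[2]]), methylation(r2[[2]]))
  expect_false(identical(methylation(r1[[1]]), methylation(r1[[2]])))
})

test_that("multi-cohort simulation honours the requested sizes", {
  sizes <- c(1497L, 504L, 2183L, 1653L, 658L, 792L)
  cohorts <- simulateMultiCohort(
    lapply(sizes, function(n) simulationConfig(nIndividuals = n)), seed = 2L)
  expect_identical(vapply(cohorts, cohortSize, integer(1)), sizes)
  expect_error(simulateMultiCohort(list()), "non-empty")
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(nIndividuals = 0L), "nIndividuals")
  expect_error(simulationConfig(epistatusProbs = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(simulationConfig(minorAlleleFreq = 1.2), "\\[0, 1\\]")
  expect_error(simulationConfig(paternalMinorFC = c(nc886_3p = -1,
                                                    nc886_5p = 1)),
               "positive")
})

test_that("genotypes converge to Hardy-Weinberg proportions", {
  q <- 0.097; expected <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  for (s in 1:3) {
    co <- simulateCohort(simulationConfig(nIndividuals = 50000L, seed = s))
    counts <- genotypeFrequencies(genotypes(co)$genotype)$counts
    gof <- suppressWarnings(chisq.test(counts, p = expected))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("emitted parental genotypes are Mendelian consistent", {
  co <- simulateCohort(simulationConfig(nIndividuals = 3000L, seed = 21L,
                                        emitParents = TRUE))
  g <- genotypes(co)
  expect_true(all(mapply(grepl, g$maternal_allele, g$mother_genotype,
                         MoreArgs = list(fixed = TRUE))))
  expect_true(all(mapply(grepl, g$paternal_allele, g$father_genotype,
                         MoreArgs = list(fixed = TRUE))))
  expect_identical(attr(callPofoCohort(g), "tally")[["mendelian_error"]], 0L)
})
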