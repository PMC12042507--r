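test_that("genotype frequencies and MAF are simple counts", {
  gf <- genotypeFrequencies(c("TT", "TT", "TC", "CC"))
  expect_equal(unname(gf$freq), c(0.5, 0.25, 0.25))
  expect_equal(gf$maf, 0.375)
  expect_equal(sum(gf$freq), 1, tolerance = 1e-9)

  gf2 <- genotypeFrequencies(c("TT", "TT", "TT"))
  expect_equal(unname(gf2$freq), c(1, 0, 0))
  expect_equal(gf2$maf, 0)

  # counts consistent with the reference cohort column (n = 1497):
  # display-rounds to 81.6 / 17.4 / 1.0 percent
  g <- rep(c("TT", "TC", "CC"), c(1221, 261, 15))
  gf3 <- genotypeFrequencies(g)
  expect_equal(round(100 * unname(gf3$freq), 1), c(81.6, 17.4, 1.0))
  expect_error(genotypeFrequencies(c(NA, NA)), "no non-missing")
  expect_error(genotypeFrequencies("TG"), "unrecognized")
})

test_that("genotype strings normalize across separators and case", {
  expect_identical(normalizeGenotype(c("T/T", "t/c", "CT", "C|C", NA)),
                   c("TT", "TC", "TC", "CC", NA))
})

test_that("parent-of-origin logic handles the canonical trios", {
  expect_identical(assignParentOfOrigin("TC", "TT", "TC"), "paternal")
  expect_identical(assignParentOfOrigin("TC", "TC", "TT"), "maternal")
  expect_identical(assignParentOfOrigin("TC", "TC", "TC"), "ambiguous")
  expect_identical(assignParentOfOrigin("CC", "TT", "CC"), "mendelian_error")
  expect_identical(assignParentOfOrigin("TT", "TT", "TT"), "not_applicable")
  # deducible from a single observed parent
  expect_identical(assignParentOfOrigin("TC", NA, "TT"), "maternal")
  expect_identical(assignParentOfOrigin("TC", NA, "CC"), "paternal")
  # undetermined with a missing, unconstraining parent
  expect_identical(assignParentOfOrigin("TC", NA, "TC"), "unknown")
  expect_identical(assignParentOfOrigin("TC", NA, NA), "unknown")
  expect_error(assignParentOfOrigin(NA, "TT", "TT"), "must be present")
})

test_that("all 48 trio configurations match the enumeration oracle exactly", {
  genos <- c("TT", "TC", "CC")
  parents <- c(genos, NA)
  for (child in genos) for (mother in parents) for (father in parents) {
    got <- assignParentOfOrigin(child, mother, father)
    expect_identical(got, oraclePofo(child, mother, father),
                     info = sprintf("child=%s mother=%s father=%s",
                                    child, mother, father))
    # exactly one category, always
    expect_length(got, 1L)
    # swapping parents maps maternal <-> paternal, fixes the rest
    swapped <- assignParentOfOrigin(child, father, mother)
    expected <- c(maternal = "paternal", paternal = "maternal")
    expect_identical(swapped,
                     if (got %in% names(expected)) expected[[got]] else got)
  }
})

test_that("cohort-level calls tally to the list length and match recounts", {
  trios <- data.frame(
    sample_id = 1:6,
    genotype = c("TT", "TT", "TT", "TC", "TC", "CC"),
    mother_genotype = c("TT", "TT", "TT", "TT", "TC", "TT"),
    father_genotype = c("TT", "TT", "TT", "TC", "TC", "CC"))
  calls <- callPofoCohort(trios)
  tally <- attr(calls, "tally")
  expect_equal(sum(tally), nrow(trios))
  expect_identical(unname(tally[["not_applicable"]]), 3L)
  brute <- table(factor(vapply(1:6, function(i)
    oraclePofo(trios$genotype[i], trios$mother_genotype[i],
               trios$father_genotype[i]), character(1)),
    levels = names(tally)))
  expect_equal(as.integer(tally), as.integer(brute))
})

test_that("inferred origin equals the simulated transmitted-allele truth", {
  co <- simulateCohort(simulationConfig(nIndividuals = 5000L, seed = 13L,
                                        emitParents = TRUE))
  g <- genotypes(co)
  calls <- callPofoCohort(g)
  called <- calls$origin %in% c("maternal", "paternal")
  truthOrigin <- ifelse(g$paternal_allele == "C", "paternal", "maternal")
  expect_gt(sum(called), 100)
  expect_identical(calls$origin[called], truthOrigin[called])
})

test_that("single-variant genotypes can be pulled from a VCF", {
  skip_if_not_installed("vcfR")
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
           "5\t135416204\trs1799962\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
           "5\t135417000\trs0000001\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- extractVariantGenotypes(path, "rs1799962")
  expect_identical(g$genotype, c("TT", "TC", "CC"))
  expect_identical(g$sample_id, c("S1", "S2", "S3"))
  expect_error(extractVariantGenotypes(path, "rs_missing"), "not found")
})
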