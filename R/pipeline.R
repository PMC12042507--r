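#' Assemble a pipeline configuration
#'
#' Either pass a YAML file path or a list. Recognized fields: `cohorts`
#' (named map of cohort name to the four sheet paths, or to a directory),
#' `probes`, `minProbes`, `thresholds` (`lower`, `upper`), `pofoRescue`,
#' `continuousOutcomes`, `binaryOutcomes`, `strata`, `minCases`, `seed`.
#' Missing fields take the package defaults.
#'
#' @param config YAML path or list.
#' @return Normalized configuration list.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$cohorts))
  defaults <- list(probes = nc886Probes(), minProbes = 6L,
                   thresholds = list(lower = 0.2, upper = 0.4),
                   pofoRescue = FALSE,
                   continuousOutcomes = c("sbp", "dbp", "total_chol",
                                          "hdl_chol", "nonhdl_chol",
                                          "ldl_chol", "glucose", "insulin"),
                   binaryOutcomes = c("hypertension", "t2d", "stroke",
                                      "death"),
                   strata = c("all", "women", "men"),
                   minCases = 10L, seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  lo <- config$thresholds$lower; hi <- config$thresholds$upper
  if (!(lo > 0 && lo < hi && hi < 1))
    stop("thresholds must satisfy 0 < lower < upper < 1")
  config
}

.cohortPaths <- function(entry) {
  if (is.character(entry) && length(entry) == 1L)
    c(methylation = file.path(entry, "methylation.tsv"),
      genotypes = file.path(entry, "genotypes.tsv"),
      expression = file.path(entry, "expression.tsv"),
      phenotypes = file.path(entry, "phenotypes.tsv"))
  else unlist(entry)
}

#' Run the full per-cohort and meta-analysis pipeline
#'
#' Per cohort: validate inputs, classify epigenotypes, call parent of
#' origin (when parental genotypes are present), assign proxy groups, run
#' the association scan; then pool all cohorts' results by outcome and
#' stratum. Every stage's TSV output is written under
#' `outDir/<cohort>/`, the pooled tables at the top level, and a
#' `manifest.json` records input checksums, the configuration, seed and
#' package version, so a rerun with identical inputs is byte-identical
#' (manifest timestamp aside). A stage failure halts with a stage-named
#' error after writing a partial manifest.
#'
#' @param config Configuration list or YAML path (see [pipelineConfig()]).
#' @param outDir Output directory.
#' @return Invisibly, a list with `assoc` (all per-cohort rows), `meta`,
#'   `forest` and `manifest`.
#' @export
runPipeline <- function(config, outDir) {
  config <- pipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "nc886proxy",
                   version = as.character(packageVersion("nc886proxy")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "cohorts")],
                   created = format(Sys.time(), tz = "UTC"),
                   inputs = list(), stages = list(), status = "running")
  writeManifest <- function()
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
  fail <- function(stage, cohort, e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- paste(stage, cohort, sep = ":")
    writeManifest()
    stop(sprintf("[%s] stage failed for cohort '%s': %s", stage, cohort,
                 conditionMessage(e)), call. = FALSE)
  }
  stage <- function(name, cohort, expr) {
    res <- tryCatch(expr, error = function(e) fail(name, cohort, e))
    manifest$stages[[paste(name, cohort, sep = ":")]] <<- "ok"
    res
  }

  allAssoc <- list()
  for (cname in names(config$cohorts)) {
    paths <- .cohortPaths(config$cohorts[[cname]])
    for (p in paths) if (!file.exists(p))
      fail("inputs", cname, simpleError(sprintf("missing input file: %s", p)))
    manifest$inputs[[cname]] <- as.list(md5sum(paths))
    cdir <- file.path(outDir, cname)
    dir.create(cdir, showWarnings = FALSE)

    sheets <- stage("read", cname, lapply(paths, .readTsv))
    stage("validate", cname, validateInputs(sheets, strict = TRUE))
    cohort <- stage("read", cname, readCohortSheets(as.list(paths)))

    calls <- stage("classify", cname,
                   classifyCohort(methylation(cohort), config$probes,
                                  config$minProbes,
                                  config$thresholds$lower,
                                  config$thresholds$upper))
    .writeTsv(calls, file.path(cdir, "epistatus.tsv"))

    geno <- genotypes(cohort)
    pofo <- NULL
    if (any(!is.na(geno$mother_genotype) | !is.na(geno$father_genotype))) {
      pofo <- stage("pofo", cname, callPofoCohort(geno))
      .writeTsv(pofo, file.path(cdir, "pofo.tsv"))
    }

    proxy <- stage("proxy", cname,
                   buildProxy(calls$status, geno$genotype,
                              sampleId = calls$sample_id,
                              pofo = if (!is.null(pofo)) pofo$origin,
                              pofoRescue = config$pofoRescue))
    .writeTsv(proxy, file.path(cdir, "proxy.tsv"))
    freq <- proxyFrequencyTable(proxy)
    .writeTsv(freq, file.path(cdir, "proxy_freq.tsv"))
    .writeTsv(attr(freq, "usage"), file.path(cdir, "proxy_usage.tsv"))

    assoc <- stage("assoc", cname,
                   runCohortAssociations(
                     phenotypes(cohort), proxy,
                     continuousOutcomes = intersect(config$continuousOutcomes,
                                                    names(phenotypes(cohort))),
                     binaryOutcomes = intersect(config$binaryOutcomes,
                                                names(phenotypes(cohort))),
                     strata = config$strata, minCases = config$minCases))
    assoc$cohort <- cname
    .writeTsv(assoc, file.path(cdir, "assoc.tsv"))
    allAssoc[[cname]] <- assoc
  }

  assoc <- do.call(rbind, allAssoc)
  pooled <- stage("meta", "all", poolAll(assoc))
  .writeTsv(pooled$meta, file.path(outDir, "meta.tsv"))
  .writeTsv(pooled$forest, file.path(outDir, "forest.tsv"))
  manifest$status <- "ok"
  writeManifest()
  invisible(list(assoc = assoc, meta = pooled$meta, forest = pooled$forest,
                 manifest = manifest))
}
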