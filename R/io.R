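## TSV plumbing: the four per-cohort sheets, written and read losslessly.
## UTF-8, tab-separated, header row, "NA" for missing.

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

.readTsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  read.delim(path, sep = "\t", na.strings = "NA", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a cohort's four sheets to a directory
#'
#' Emits `methylation.tsv` (sample_id + one column per probe),
#' `genotypes.tsv`, `expression.tsv` and `phenotypes.tsv`.
#'
#' @param cohort An [Nc886Cohort].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeCohortSheets <- function(cohort, dir) {
  stopifnot(is(cohort, "Nc886Cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meth <- data.frame(sample_id = rownames(methylation(cohort)),
                     methylation(cohort), check.names = FALSE,
                     stringsAsFactors = FALSE)
  paths <- c(
    methylation = .writeTsv(meth, file.path(dir, "methylation.tsv")),
    genotypes = .writeTsv(genotypes(cohort), file.path(dir, "genotypes.tsv")),
    expression = .writeTsv(expressionData(cohort),
                           file.path(dir, "expression.tsv")),
    phenotypes = .writeTsv(phenotypes(cohort),
                           file.path(dir, "phenotypes.tsv")))
  invisible(paths)
}

#' Read a cohort back from its sheets
#'
#' @param dir Directory containing the four sheets written by
#'   [writeCohortSheets()], or a named list/vector of the four paths
#'   (`methylation`, `genotypes`, `expression`, `phenotypes`).
#' @return An [Nc886Cohort] (with empty `truth`).
#' @export
readCohortSheets <- function(dir) {
  paths <- if (is.character(dir) && length(dir) == 1L && dir.exists(dir))
    c(methylation = file.path(dir, "methylation.tsv"),
      genotypes = file.path(dir, "genotypes.tsv"),
      expression = file.path(dir, "expression.tsv"),
      phenotypes = file.path(dir, "phenotypes.tsv"))
  else unlist(dir)
  meth <- .readTsv(paths[["methylation"]])
  beta <- as.matrix(meth[, setdiff(names(meth), "sample_id"), drop = FALSE])
  rownames(beta) <- meth$sample_id
  geno <- .readTsv(paths[["genotypes"]])
  for (col in c("maternal_allele", "paternal_allele", "mother_genotype",
                "father_genotype"))
    if (!col %in% names(geno)) geno[[col]] <- NA_character_
  new("Nc886Cohort", methylation = beta, genotypes = geno,
      expression = .readTsv(paths[["expression"]]),
      phenotypes = .readTsv(paths[["phenotypes"]]),
      truth = list())
}

.finding <- function(sheet, check, severity, message, n = NA_integer_) {
  data.frame(sheet = sheet, check = check, severity = severity,
             message = message, n = as.integer(n), stringsAsFactors = FALSE)
}

#' Validate cohort input sheets
#'
#' Checks for duplicated sample ids, out-of-range beta values, unknown
#' genotype strings, sex/fasting coding problems, non-positive expression
#' and join coverage across sheets. Findings carry a severity; with
#' `strict = TRUE` any fatal finding raises an error listing the problems,
#' otherwise the full report is returned for inspection.
#'
#' @param sheets Named list of data.frames (`methylation` in sheet form with
#'   a `sample_id` column, `genotypes`, `expression`, `phenotypes`), as read
#'   from TSV before any object construction.
#' @param strict Raise on fatal findings.
#' @return data.frame report (zero rows when clean), invisibly when
#'   `strict = TRUE`.
#' @export
validateInputs <- function(sheets, strict = FALSE) {
  findings <- list()
  add <- function(f) findings[[length(findings) + 1L]] <<- f

  ids <- list()
  for (nm in names(sheets)) {
    df <- sheets[[nm]]
    if (!"sample_id" %in% names(df)) {
      add(.finding(nm, "sample_id", "fatal", "missing sample_id column"))
      next
    }
    ids[[nm]] <- df$sample_id
    dup <- sum(duplicated(df$sample_id))
    if (dup > 0)
      add(.finding(nm, "duplicate_ids", "fatal",
                   sprintf("%d duplicated sample ids", dup), dup))
  }

  if (!is.null(sheets$methylation)) {
    b <- as.matrix(sheets$methylation[,
           setdiff(names(sheets$methylation), "sample_id"), drop = FALSE])
    bad <- sum(b < 0 | b > 1, na.rm = TRUE)
    if (bad > 0)
      add(.finding("methylation", "beta_range", "fatal",
                   sprintf("%d beta values outside [0, 1]", bad), bad))
  }
  if (!is.null(sheets$genotypes)) {
    g <- sheets$genotypes$genotype
    ok <- tryCatch({normalizeGenotype(g); TRUE}, error = function(e) FALSE)
    if (!ok) {
      bad <- g[!is.na(g) &
                 !toupper(gsub("[/|]", "", g)) %in% c("TT", "TC", "CT", "CC")]
      add(.finding("genotypes", "genotype_strings", "fatal",
                   sprintf("unknown genotype string(s): %s",
                           paste(unique(bad), collapse = ", ")), length(bad)))
    }
  }
  if (!is.null(sheets$phenotypes)) {
    for (col in c("sex", "fasting")) {
      v <- sheets$phenotypes[[col]]
      if (is.null(v)) next
      bad <- sum(!is.na(v) & !v %in% c(0, 1))
      if (bad > 0)
        add(.finding("phenotypes", paste0(col, "_coding"), "fatal",
                     sprintf("%d %s values outside {0, 1}", bad, col), bad))
    }
  }
  if (!is.null(sheets$expression)) {
    for (col in intersect(.SPECIES, names(sheets$expression))) {
      v <- sheets$expression[[col]]
      bad <- sum(!is.na(v) & v <= 0)
      if (bad > 0)
        add(.finding("expression", paste0(col, "_positive"), "fatal",
                     sprintf("%d non-positive %s values", bad, col), bad))
    }
  }
  if (length(ids) > 1L) {
    common <- Reduce(intersect, ids)
    for (nm in names(ids)) {
      extra <- length(setdiff(ids[[nm]], common))
      if (extra > 0)
        add(.finding(nm, "join_coverage", "info",
                     sprintf("%d sample ids absent from other sheets", extra),
                     extra))
    }
  }

  report <- if (length(findings)) do.call(rbind, findings)
            else .finding(character(0), character(0), character(0),
                          character(0), integer(0))
  if (strict && any(report$severity == "fatal"))
    stop(paste(c("fatal input problems:",
                 sprintf("  [%s] %s", report$sheet[report$severity == "fatal"],
                         report$message[report$severity == "fatal"])),
               collapse = "\n"))
  if (strict) invisible(report) else report
}
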