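# Cohort container and CSV round-trip.
#
# A cohort is a data.frame of patient records plus the disease codebook it
# was coded against. Demographic columns come first, then the 26 disease
# indicator columns named by codebook id, in codebook order.

.demo_cols <- c("patient_id", "age", "sex", "sep", "smoking",
                "n_teeth", "n_pockets_ge6", "bop_pct", "pisa_mm2")

#' Construct a cohort object
#'
#' Validates patient records against the codebook and the domain invariants:
#' adults only (age >= 18), sex in {female, male}, SEP in [-1, 1] or missing,
#' teeth 0-32, non-negative pocket counts, BOP 0-100, non-negative PISA, and
#' complete binary disease indicators.
#'
#' @param records data.frame with columns `patient_id`, `age`, `sex`, `sep`,
#'   `smoking`, `n_teeth`, `n_pockets_ge6`, `bop_pct`, `pisa_mm2` and one
#'   0/1 column per codebook disease id.
#' @param codebook a `disease_codebook`, default [load_codebook()].
#' @return An object of class `comorbidity_cohort`: a list with elements
#'   `records` (validated data.frame) and `codebook`.
#' @export
cohort <- function(records, codebook = load_codebook()) {
  required <- c(.demo_cols, codebook$id)
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("cohort must contain at least one record")
  records <- records[, required, drop = FALSE]
  records$patient_id <- as.character(records$patient_id)
  records$sex <- as.character(records$sex)
  records$smoking <- as.integer(records$smoking)

  flags <- as.matrix(records[, codebook$id, drop = FALSE])
  if (anyNA(flags) || !all(flags %in% c(0, 1))) {
    bad <- which(is.na(flags) | !(flags %in% c(0, 1)), arr.ind = TRUE)
    stop(sprintf("non-binary disease indicator at row %d, column '%s'",
                 bad[1, 1], codebook$id[bad[1, 2]]))
  }
  storage.mode(flags) <- "integer"
  records[, codebook$id] <- flags

  problems <- character(0)
  chk <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      problems <<- c(problems, sprintf("row %d: %s", idx[1], msg))
    }
  }
  chk(is.na(records$age) | records$age < 18, "age below 18 or missing")
  chk(!records$sex %in% c("female", "male"), "sex must be 'female' or 'male'")
  chk(!is.na(records$sep) & abs(records$sep) > 1, "SEP outside [-1, 1]")
  chk(is.na(records$smoking) | !records$smoking %in% c(0L, 1L),
      "smoking must be 0/1")
  chk(is.na(records$n_teeth) | records$n_teeth < 0 | records$n_teeth > 32,
      "number of teeth outside 0-32")
  chk(is.na(records$n_pockets_ge6) | records$n_pockets_ge6 < 0,
      "negative pocket count")
  chk(is.na(records$bop_pct) | records$bop_pct < 0 | records$bop_pct > 100,
      "BOP percentage outside 0-100")
  chk(is.na(records$pisa_mm2) | records$pisa_mm2 < 0, "negative PISA")
  if (length(problems) > 0L) {
    stop("invalid patient record(s):\n  ", paste(problems, collapse = "\n  "))
  }

  structure(list(records = records, codebook = codebook),
            class = "comorbidity_cohort")
}

#' @export
print.comorbidity_cohort <- function(x, ...) {
  n <- nrow(x$records)
  nc <- sum(disease_counts(x) >= 1)
  cat(sprintf("A periodontitis cohort: %d patients, %d disease indicators\n",
              n, nrow(x$codebook)))
  cat(sprintf("  with comorbidity (>=1 disease): %d (%.1f%%)\n",
              nc, 100 * nc / n))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort_obj a `comorbidity_cohort`.
#' @return integer.
#' @export
n_patients <- function(cohort_obj) nrow(cohort_obj$records)

#' Disease indicator matrix of a cohort
#' @param cohort_obj a `comorbidity_cohort`.
#' @return integer matrix, patients x diseases, columns in codebook order.
#' @export
disease_matrix <- function(cohort_obj) {
  m <- as.matrix(cohort_obj$records[, cohort_obj$codebook$id, drop = FALSE])
  rownames(m) <- cohort_obj$records$patient_id
  m
}

#' Read a cohort from CSV
#'
#' Expects one row per patient with the demographic columns and one 0/1
#' column per codebook disease. Rows below 18 years of age and rows with any
#' missing disease indicator are excluded (the questionnaire-completeness
#' rule) and counted in the `exclusions` attribute; a non-binary disease
#' value other than an empty cell is an error.
#'
#' @param path CSV path (UTF-8, comma-separated, "." decimal).
#' @param codebook a `disease_codebook`.
#' @return a `comorbidity_cohort` with attribute `exclusions`, a list with
#'   counts `n_rows`, `n_included`, `n_excluded_age`, `n_excluded_incomplete`.
#' @export
read_cohort <- function(path, codebook = load_codebook()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c(.demo_cols, codebook$id)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  flags <- as.matrix(raw[, codebook$id, drop = FALSE])
  bad <- which(!is.na(flags) & !(flags %in% c(0, 1)), arr.ind = TRUE)
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-binary disease value '%s' at row %d, column '%s' of %s",
      flags[bad[1, 1], bad[1, 2]], bad[1, 1], codebook$id[bad[1, 2]], path))
  }
  underage <- !is.na(raw$age) & raw$age < 18
  incomplete <- apply(is.na(flags), 1L, any) & !underage
  keep <- !underage & !incomplete
  if (!any(keep)) stop("no valid records in ", path)
  out <- cohort(raw[keep, , drop = FALSE], codebook)
  attr(out, "exclusions") <- list(
    n_rows = nrow(raw),
    n_included = sum(keep),
    n_excluded_age = sum(underage),
    n_excluded_incomplete = sum(incomplete)
  )
  out
}

#' Write a cohort to CSV
#'
#' Round-trip safe with [read_cohort()]: missing SEP is serialised as an
#' empty cell and read back as missing.
#'
#' @param cohort_obj a `comorbidity_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort_obj, path) {
  stopifnot(inherits(cohort_obj, "comorbidity_cohort"))
  utils::write.csv(cohort_obj$records, path, row.names = FALSE, na = "")
  invisible(path)
}
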