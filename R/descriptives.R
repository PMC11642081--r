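# Descriptive accounting: disease-count distribution, comorbidity and
# multimorbidity prevalence, per-disease prevalence tables by stratum, and
# the t-test / chi-square comparisons between patient groups.

#' Number of systemic diseases per patient
#'
#' Comorbidity is defined as >= 1 systemic disease alongside periodontitis,
#' multimorbidity as >= 2; both derive from this count.
#'
#' @param cohort_obj a `comorbidity_cohort`.
#' @return integer vector, one count (0-26) per patient.
#' @export
disease_counts <- function(cohort_obj) {
  as.integer(rowSums(disease_matrix(cohort_obj)))
}

#' Disease-count distribution and comorbidity prevalence
#'
#' Bins patients by number of systemic diseases (0, 1, 2, 3, 4, >= 5) and
#' reports comorbidity prevalence (share with >= 1 disease), multimorbidity
#' prevalence (share with >= 2), and the mean +/- SD number of diseases.
#' The mean is reported both over comorbid patients only (the convention in
#' the reference tables, where the range starts at 1) and over everyone.
#'
#' @param cohort_obj a `comorbidity_cohort`.
#' @return A list of class `count_distribution`: `bins` (named integer
#'   vector for 0,1,2,3,4,>=5), `n_total`, `comorbidity_pct`,
#'   `multimorbidity_pct` (exact percentages, unrounded),
#'   `mean_diseases_comorbid`, `sd_diseases_comorbid` (NA when no patient is
#'   comorbid), `mean_diseases_all`, `max_diseases`.
#' @export
count_distribution <- function(cohort_obj) {
  counts <- disease_counts(cohort_obj)
  n <- length(counts)
  bins <- c(
    `0` = sum(counts == 0L), `1` = sum(counts == 1L),
    `2` = sum(counts == 2L), `3` = sum(counts == 3L),
    `4` = sum(counts == 4L), `>=5` = sum(counts >= 5L)
  )
  comorbid <- counts[counts >= 1L]
  structure(list(
    bins = bins,
    n_total = n,
    comorbidity_pct = 100 * sum(counts >= 1L) / n,
    multimorbidity_pct = 100 * sum(counts >= 2L) / n,
    mean_diseases_comorbid = if (length(comorbid)) mean(comorbid) else NA_real_,
    sd_diseases_comorbid = if (length(comorbid) > 1L) stats::sd(comorbid)
                           else NA_real_,
    mean_diseases_all = mean(counts),
    max_diseases = max(counts)
  ), class = "count_distribution")
}

#' Per-disease prevalence by stratum
#'
#' For each disease and each stratum, the number of carriers and the
#' percentage of the stratum (half-up rounded to 1 decimal, the reporting
#' convention of the reference tables). An empty stratum yields NA
#' percentages.
#'
#' @param cohort_obj a `comorbidity_cohort`.
#' @param strata named list of logical or integer index vectors selecting
#'   patients, e.g. `list(total = TRUE, comorbid = disease_counts(x) >= 1)`.
#'   A logical scalar `TRUE` selects everyone. Strata may overlap.
#' @return A data.frame of class `prevalence_table` with columns `disease`,
#'   `label`, then `<stratum>_n` and `<stratum>_pct` per stratum. The
#'   stratum sizes are in attribute `stratum_n`.
#' @export
prevalence_table <- function(cohort_obj,
                             strata = list(total = TRUE)) {
  if (is.null(names(strata)) || any(names(strata) == "")) {
    stop("strata must be a named list")
  }
  m <- disease_matrix(cohort_obj)
  cb <- cohort_obj$codebook
  out <- data.frame(disease = cb$id, label = cb$label,
                    stringsAsFactors = FALSE)
  sizes <- integer(0)
  for (s in names(strata)) {
    sel <- strata[[s]]
    if (isTRUE(sel)) sel <- rep(TRUE, nrow(m))
    sub <- m[sel, , drop = FALSE]
    ns <- nrow(sub)
    sizes[s] <- ns
    cnt <- colSums(sub)
    out[[paste0(s, "_n")]] <- as.integer(cnt)
    out[[paste0(s, "_pct")]] <-
      if (ns == 0L) NA_real_ else round_half_up(100 * cnt / ns, 1)
  }
  attr(out, "stratum_n") <- sizes
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Compare two patient groups variable by variable
#'
#' Continuous variables (age, SEP, pockets >= 6 mm, BOP, teeth, PISA) are
#' compared with the two-sample Student t-test (pooled variance; Welch
#' available via `welch = TRUE`); categorical variables (sex, smoking) with
#' the Pearson chi-square test without continuity correction. Two-sided
#' p-values throughout; missing values (SEP) dropped per variable.
#'
#' @param cohort_obj a `comorbidity_cohort`.
#' @param grouping logical vector, one per patient (`TRUE` = group B).
#' @param variables character vector of record columns to compare.
#' @param welch use Welch's unequal-variance t-test instead of pooled.
#' @return data.frame with one row per variable: `variable`, `test`
#'   ("t" or "chi2"), `statistic`, `p_value`, group summaries (`mean_a`,
#'   `sd_a`, `mean_b`, `sd_b` for continuous; `n_a`, `pct_a`, `n_b`, `pct_b`
#'   for categorical), and `note` flagging degenerate cases.
#' @export
compare_groups <- function(cohort_obj, grouping,
                           variables = c("age", "sex", "sep", "smoking",
                                         "n_pockets_ge6", "bop_pct",
                                         "n_teeth", "pisa_mm2"),
                           welch = FALSE) {
  rec <- cohort_obj$records
  stopifnot(length(grouping) == nrow(rec), is.logical(grouping))
  if (!any(grouping) || all(grouping)) stop("both groups must be non-empty")
  categorical <- c("sex", "smoking")
  rows <- lapply(variables, function(v) {
    x <- rec[[v]]
    if (is.null(x)) stop("unknown variable: ", v)
    if (v %in% categorical) {
      pos <- if (v == "sex") as.integer(x == "female") else as.integer(x)
      tab <- rbind(a = c(sum(pos[!grouping]), sum(1 - pos[!grouping])),
                   b = c(sum(pos[grouping]), sum(1 - pos[grouping])))
      deg <- any(colSums(tab) == 0L)
      if (deg) {
        stat <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        stat <- unname(ct$statistic); p <- ct$p.value
      }
      data.frame(variable = v, test = "chi2", statistic = stat, p_value = p,
                 mean_a = NA_real_, sd_a = NA_real_,
                 mean_b = NA_real_, sd_b = NA_real_,
                 n_a = tab["a", 1], pct_a = 100 * tab["a", 1] / sum(tab["a", ]),
                 n_b = tab["b", 1], pct_b = 100 * tab["b", 1] / sum(tab["b", ]),
                 note = if (deg) "degenerate table" else "",
                 stringsAsFactors = FALSE)
    } else {
      xa <- x[!grouping & !is.na(x)]
      xb <- x[grouping & !is.na(x)]
      note <- ""
      if (length(xa) < 2L || length(xb) < 2L) {
        stat <- NA_real_; p <- NA_real_; note <- "too few observations"
      } else if (stats::var(xa) == 0 && stats::var(xb) == 0) {
        note <- "zero variance in both groups"
        if (mean(xa) == mean(xb)) { stat <- 0; p <- 1 }
        else { stat <- NA_real_; p <- NA_real_ }
      } else {
        tt <- stats::t.test(xa, xb, var.equal = !welch)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
      data.frame(variable = v, test = "t", statistic = stat, p_value = p,
                 mean_a = mean(xa), sd_a = stats::sd(xa),
                 mean_b = mean(xb), sd_b = stats::sd(xb),
                 n_a = NA_integer_, pct_a = NA_real_,
                 n_b = NA_integer_, pct_b = NA_real_,
                 note = note, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Closed-form Pearson chi-square for a 2x2 table
#'
#' n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), the uncorrected Pearson statistic.
#' Used as an arithmetic cross-check of the contingency-table comparisons.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return list with `statistic` and two-sided `p_value` (1 df).
#' @export
chisq2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(list(statistic = NA_real_, p_value = NA_real_))
  stat <- n * (a * d - b * c)^2 / denom
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
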