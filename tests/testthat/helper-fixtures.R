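# Fixture builders shared across the test files. Fixtures are constructed
# in code; nothing is read from disk except files the tests write first.

CB <- load_codebook()

# Records data.frame from a flags matrix (patients x 26, codebook order),
# with sane demographic defaults that can be overridden per column.
make_records <- function(flags, age = 50, sex = "female", sep = 0.1,
                         smoking = 0L, n_teeth = 28L, n_pockets_ge6 = 10L,
                         bop_pct = 40, pisa_mm2 = 900) {
  n <- nrow(flags)
  colnames(flags) <- CB$id
  rec <- data.frame(
    patient_id = sprintf("T%04d", seq_len(n)),
    age = rep_len(age, n), sex = rep_len(sex, n), sep = rep_len(sep, n),
    smoking = rep_len(smoking, n), n_teeth = rep_len(n_teeth, n),
    n_pockets_ge6 = rep_len(n_pockets_ge6, n),
    bop_pct = rep_len(bop_pct, n), pisa_mm2 = rep_len(pisa_mm2, n),
    stringsAsFactors = FALSE
  )
  cbind(rec, as.data.frame(flags))
}

# Flags matrix with given diseases set per patient; `sets` is a list of
# character vectors of codebook ids.
flags_from_sets <- function(sets) {
  m <- matrix(0L, nrow = length(sets), ncol = 26L,
              dimnames = list(NULL, CB$id))
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  m
}

toy_cohort <- function(sets, ...) {
  cohort(make_records(flags_from_sets(sets), ...))
}

# Random valid cohort for round-trip property tests.
random_cohort <- function(n, seed, p_flag = 0.15, p_sep_missing = 0.2) {
  set.seed(seed)
  flags <- matrix(rbinom(n * 26L, 1L, p_flag), nrow = n,
                  dimnames = list(NULL, CB$id))
  rec <- make_records(
    flags,
    age = round(runif(n, 18, 90), 1),
    sex = sample(c("female", "male"), n, replace = TRUE),
    sep = ifelse(runif(n) < p_sep_missing, NA_real_,
                 round(runif(n, -1, 1), 3)),
    smoking = rbinom(n, 1L, 0.25),
    n_teeth = sample(0:32, n, replace = TRUE),
    n_pockets_ge6 = rpois(n, 15),
    bop_pct = round(runif(n, 0, 100), 2),
    pisa_mm2 = round(runif(n, 0, 3000), 2)
  )
  cohort(rec)
}

# Comorbid subset of a generated cohort plus the matching true labels.
comorbid_subset <- function(gen) {
  counts <- disease_counts(gen$cohort)
  idx <- counts >= 1L
  list(cohort = cohort(gen$cohort$records[idx, , drop = FALSE],
                       gen$cohort$codebook),
       labels = gen$labels[idx])
}

# Adjusted Rand index (chance-corrected partition agreement); small
# self-contained implementation used when mclust is unavailable.
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
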