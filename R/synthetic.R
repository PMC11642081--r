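# Synthetic periodontitis cohorts.
#
# The generator emulates the statistical structure the downstream analyses
# assume: a latent three-class mixture over patients — a disease-free class,
# a respiratory/allergy class, and a cardiometabolic class — with
# class-conditional Bernoulli disease indicators (independent within class)
# and class-conditional demographic and periodontal distributions. The
# default calibration reproduces the marginal and per-cluster prevalences of
# the reference periodontitis cohort (n = 3171).

.synth_classes <- c("none", "respiratory", "cardiometabolic")

# Solve for the raw Bernoulli rates q that, after conditioning on >= 1
# disease, reproduce the target conditional prevalences p: q = c * p with
# c = 1 - prod(1 - q) (the acceptance probability). A positive solution
# exists iff sum(p) > 1, i.e. the target conditional mean disease count
# exceeds 1 -- automatic for prevalences reported within a comorbid class.
.deflate_rates <- function(p, tol = 1e-12, max_iter = 1000L) {
  if (sum(p) <= 1) {
    stop("conditional disease prevalences must sum to > 1 for a class ",
         "restricted to >= 1 disease (got ", signif(sum(p), 4), ")")
  }
  c_acc <- 1
  for (i in seq_len(max_iter)) {
    c_new <- 1 - prod(1 - c_acc * p)
    if (abs(c_new - c_acc) < tol) break
    c_acc <- c_new
  }
  c_acc * p
}

#' Default synthetic-cohort specification
#'
#' Mixture weights: 52.9% disease-free; the comorbid 47.1% split 45.8/54.2
#' between the respiratory/allergy class and the cardiometabolic class.
#' Per-class disease rates are the per-cluster prevalences of the reference
#' cohort (e.g. allergic rhinitis 47.5% in the respiratory class,
#' hypertension 43.6% in the cardiometabolic class); demographics and
#' periodontal metrics are class-conditional (truncated) normals and
#' Bernoullis with the reference means/SDs (e.g. cardiometabolic-class age
#' 57.4 +/- 11.8 years). PISA is carried in mm^2.
#'
#' @param n cohort size (default 3171, the reference cohort size).
#' @param seed integer seed driving all draws.
#' @return An object of class `synthetic_spec`.
#' @export
default_spec <- function(n = 3171, seed = 1L) {
  cb <- load_codebook()
  p_resp <- c(
    angina_pectoris = 0.001, myocardial_infarction = 0.000,
    heart_murmur_valve_defect = 0.000, artificial_valve_pacemaker_hip = 0.003,
    heart_vascular_surgery = 0.000, cardiac_arrhythmia = 0.015,
    heart_weakness = 0.000, hyperventilation = 0.012, hypertension = 0.003,
    cerebrovascular_disease = 0.000, epilepsy = 0.000, asthma = 0.151,
    lung_disease = 0.095, allergic_rhinitis = 0.475, allergy = 0.478,
    diabetes_mellitus = 0.004, hyperthyroidism = 0.004, hypothyroidism = 0.139,
    liver_disease = 0.000, chronic_kidney_disease = 0.001,
    chronic_gastrointestinal_disease = 0.000, anemia = 0.004,
    malignant_lymph_blood_disease = 0.000, bleeding_diathesis = 0.001,
    radiation = 0.001, contagious_disease = 0.001
  )
  p_cardio <- c(
    angina_pectoris = 0.059, myocardial_infarction = 0.085,
    heart_murmur_valve_defect = 0.073, artificial_valve_pacemaker_hip = 0.074,
    heart_vascular_surgery = 0.014, cardiac_arrhythmia = 0.138,
    heart_weakness = 0.058, hyperventilation = 0.127, hypertension = 0.436,
    cerebrovascular_disease = 0.068, epilepsy = 0.026, asthma = 0.049,
    lung_disease = 0.058, allergic_rhinitis = 0.120, allergy = 0.233,
    diabetes_mellitus = 0.137, hyperthyroidism = 0.042, hypothyroidism = 0.033,
    liver_disease = 0.015, chronic_kidney_disease = 0.018,
    chronic_gastrointestinal_disease = 0.031, anemia = 0.043,
    malignant_lymph_blood_disease = 0.018, bleeding_diathesis = 0.020,
    radiation = 0.025, contagious_disease = 0.005
  )
  stopifnot(identical(names(p_resp), cb$id), identical(names(p_cardio), cb$id))
  p_none <- stats::setNames(rep(0, nrow(cb)), cb$id)

  demo <- list(
    none = list(age_mean = 51.3, age_sd = 12.3, female = 0.507,
                sep_mean = 0.07, sep_sd = 0.20, sep_missing = 0.008,
                smoking = 0.260),
    respiratory = list(age_mean = 51.7, age_sd = 12.4, female = 0.680,
                       sep_mean = 0.08, sep_sd = 0.18, sep_missing = 0.012,
                       smoking = 0.221),
    cardiometabolic = list(age_mean = 57.4, age_sd = 11.8, female = 0.567,
                           sep_mean = 0.05, sep_sd = 0.19, sep_missing = 0.007,
                           smoking = 0.252)
  )
  perio <- list(
    none = list(pockets_mean = 20.9, pockets_sd = 21.9,
                bop_mean = 51.5, bop_sd = 25.8,
                teeth_mean = 26.0, teeth_sd = 3.4,
                pisa_mean = 1360, pisa_sd = 880),
    respiratory = list(pockets_mean = 18.1, pockets_sd = 19.8,
                       bop_mean = 48.9, bop_sd = 25.9,
                       teeth_mean = 25.9, teeth_sd = 3.5,
                       pisa_mean = 1270, pisa_sd = 850),
    cardiometabolic = list(pockets_mean = 21.1, pockets_sd = 21.6,
                           bop_mean = 53.6, bop_sd = 26.0,
                           teeth_mean = 24.9, teeth_sd = 3.8,
                           pisa_mean = 1370, pisa_sd = 860)
  )

  spec <- list(
    n = as.integer(n),
    mix = c(none = 0.529,
            respiratory = 0.471 * 0.458,
            cardiometabolic = 0.471 * 0.542),
    disease_probs = list(none = p_none, respiratory = p_resp,
                         cardiometabolic = p_cardio),
    demo = demo,
    perio = perio,
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_spec(spec)
  spec
}

#' Validate a synthetic-cohort specification
#'
#' @param spec a `synthetic_spec`.
#' @return `spec`, invisibly; errors on violation.
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n < 1L) stop("cohort size n must be >= 1")
  if (abs(sum(spec$mix) - 1) > 1e-12) stop("mixture weights must sum to 1")
  if (any(spec$mix < 0)) stop("mixture weights must be non-negative")
  for (cl in .synth_classes) {
    p <- spec$disease_probs[[cl]]
    if (any(p < 0 | p > 1)) {
      stop("disease probabilities for class '", cl, "' outside [0, 1]")
    }
  }
  if (any(spec$disease_probs$none != 0)) {
    stop("the disease-free class must have all disease probabilities 0")
  }
  for (cl in .synth_classes) {
    for (f in c("female", "smoking", "sep_missing")) {
      v <- spec$demo[[cl]][[f]]
      if (v < 0 || v > 1) stop("probability '", f, "' outside [0, 1]")
    }
  }
  invisible(spec)
}

#' Modify a synthetic specification
#'
#' Returns a copy of `spec` with the given fields replaced; the original is
#' untouched. Overrides are addressed by path, e.g.
#' `perturb_spec(spec, disease_probs.respiratory.asthma = 0.2, seed = 7)`.
#'
#' @param spec a `synthetic_spec`.
#' @param ... named overrides; names are `.`-separated field paths.
#' @return a validated `synthetic_spec`.
#' @export
perturb_spec <- function(spec, ...) {
  overrides <- list(...)
  if (length(overrides) > 0L && is.null(names(overrides))) {
    stop("overrides must be named")
  }
  for (key in names(overrides)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- spec
    for (i in seq_along(path)) {
      if (is.null(node[[path[i]]])) stop("unknown spec field: ", key)
      node <- node[[path[i]]]
    }
    spec[[path]] <- overrides[[key]]
  }
  validate_spec(spec)
  spec
}

#' Generate a synthetic cohort
#'
#' Each patient is drawn by sampling a latent class, then independent
#' Bernoulli disease indicators and class-conditional demographics and
#' periodontal metrics. Disease-free-class patients carry exactly 0
#' diseases; patients in the two comorbid classes are rejection-sampled to
#' carry at least 1 (those classes model the comorbid subpopulation). The
#' class disease probabilities are interpreted as prevalences *within the
#' drawn class*: the raw Bernoulli rates are deflated by the
#' self-consistent acceptance probability so that, after the >= 1-disease
#' rejection step, each within-class prevalence matches its specified value
#' in expectation. All randomness derives from `spec$seed`, so a given
#' spec always yields the same cohort.
#'
#' @param spec a `synthetic_spec`, e.g. [default_spec()].
#' @return A list with elements `cohort` (a `comorbidity_cohort`) and
#'   `labels` (character vector of true latent classes, one per patient).
#' @export
generate_cohort <- function(spec) {
  validate_spec(spec)
  n <- spec$n
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  labels <- sample(.synth_classes, n, replace = TRUE, prob = spec$mix)
  flags <- matrix(0L, nrow = n, ncol = 26L,
                  dimnames = list(NULL, names(spec$disease_probs$none)))
  for (cl in c("respiratory", "cardiometabolic")) {
    idx <- which(labels == cl)
    if (length(idx) == 0L) next
    # disease_probs are prevalences *within the drawn class* (which is
    # conditioned on >= 1 disease); deflate to the raw Bernoulli rates so
    # rejection sampling reproduces them in expectation
    p <- .deflate_rates(spec$disease_probs[[cl]])
    draw <- matrix(stats::rbinom(length(idx) * 26L, 1L, rep(p, each = length(idx))),
                   nrow = length(idx))
    # rejection-sample the >=1-disease constraint, preserving relative rates
    empty <- which(rowSums(draw) == 0L)
    while (length(empty) > 0L) {
      draw[empty, ] <- stats::rbinom(length(empty) * 26L, 1L,
                                     rep(p, each = length(empty)))
      empty <- empty[rowSums(draw[empty, , drop = FALSE]) == 0L]
    }
    flags[idx, ] <- draw
  }

  age <- sep <- bop <- pisa <- numeric(n)
  teeth <- pockets <- integer(n)
  sex <- character(n)
  smoking <- integer(n)
  for (cl in .synth_classes) {
    idx <- which(labels == cl)
    if (length(idx) == 0L) next
    d <- spec$demo[[cl]]
    p <- spec$perio[[cl]]
    k <- length(idx)
    age[idx] <- rtrunc_norm(k, d$age_mean, d$age_sd, lo = 18)
    sex[idx] <- ifelse(stats::rbinom(k, 1L, d$female) == 1L, "female", "male")
    sep[idx] <- rtrunc_norm(k, d$sep_mean, d$sep_sd, lo = -1, hi = 1)
    sep[idx][stats::rbinom(k, 1L, d$sep_missing) == 1L] <- NA_real_
    smoking[idx] <- stats::rbinom(k, 1L, d$smoking)
    pockets[idx] <- as.integer(round(rtrunc_norm(k, p$pockets_mean,
                                                 p$pockets_sd, lo = 0)))
    bop[idx] <- rtrunc_norm(k, p$bop_mean, p$bop_sd, lo = 0, hi = 100)
    teeth[idx] <- as.integer(round(rtrunc_norm(k, p$teeth_mean, p$teeth_sd,
                                               lo = 0, hi = 32)))
    pisa[idx] <- rtrunc_norm(k, p$pisa_mean, p$pisa_sd, lo = 0)
  }

  records <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = age, sex = sex, sep = sep, smoking = smoking,
    n_teeth = teeth, n_pockets_ge6 = pockets,
    bop_pct = bop, pisa_mm2 = pisa,
    stringsAsFactors = FALSE
  )
  records <- cbind(records, as.data.frame(flags))
  list(cohort = cohort(records), labels = labels)
}
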