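# Covariate-adjusted between-cluster prevalence comparison.
#
# Each disease (or ICD-11-adapted disease group) is regressed on cluster
# membership with binomial logistic regression, adjusting for age, sex,
# SEP, and smoking; the cluster effect is reported as an odds ratio with a
# Wald 95% CI and two-sided p-value. Records with missing SEP are dropped
# listwise per model.

#' Maximum-likelihood logistic regression via IRLS
#'
#' Newton scoring (iteratively reweighted least squares) for
#' `logit P(y = 1) = X beta`. Converges when the largest coefficient change
#' drops below `tol`; quasi-separated fits (a standardised coefficient
#' exceeding `sep_limit`) are flagged rather than silently returned.
#'
#' @param y 0/1 response vector.
#' @param X design matrix including the intercept column.
#' @param tol convergence tolerance on `max |delta beta|` (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @param sep_limit |beta| (on predictors scaled to unit SD) beyond which
#'   separation is flagged (default 15).
#' @return list of class `logistic_fit`: `coefficients`, `vcov`,
#'   `converged`, `separation`, `iterations`, `n_used`, `loglik`.
#' @export
fit_logistic <- function(y, X, tol = 1e-8, max_iter = 100L, sep_limit = 15) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  n <- length(y)
  if (nrow(X) != n) stop("X and y sizes differ")
  if (n <= ncol(X)) stop("more coefficients than observations")
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate outcome: y is constant")
  }
  if (qr(X)$rank < ncol(X)) stop("singular design: collinear columns")

  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    delta <- fit$coefficients - beta
    beta <- fit$coefficients
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  # flag separation on the standardised-predictor scale
  sds <- apply(X, 2L, stats::sd)
  scale_fac <- ifelse(sds > 0, sds, 1)
  separation <- any(abs(beta * scale_fac)[sds > 0] > sep_limit) ||
    (!converged && max(abs(beta)) > sep_limit)
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    vcov = vcov, converged = converged, separation = separation,
    iterations = iter, n_used = n, loglik = ll
  ), class = "logistic_fit")
}

# Build the adjusted design for a cluster comparison. Returns list(y, X,
# n_dropped) or a character reason when the model is untestable.
.cluster_design <- function(cohort_obj, assignments, outcome) {
  rec <- cohort_obj$records
  stopifnot(length(assignments) == nrow(rec))
  cl <- sort(unique(assignments))
  if (length(cl) != 2L) stop("exactly two clusters are required")
  keep <- !is.na(rec$sep)
  y <- outcome[keep]
  if (all(y == 0) || all(y == 1)) return("degenerate outcome")
  X <- cbind(
    intercept = 1,
    cluster2 = as.numeric(assignments[keep] == cl[2]),
    age = rec$age[keep],
    sex_male = as.numeric(rec$sex[keep] == "male"),
    sep = rec$sep[keep],
    smoking = as.numeric(rec$smoking[keep])
  )
  list(y = y, X = X, n_dropped = sum(!keep))
}

.adjusted_result <- function(outcome_name, level, design) {
  if (is.character(design)) {
    return(data.frame(
      outcome = outcome_name, level = level, or = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
      significant = NA, direction = NA_character_, n_used = NA_integer_,
      note = design, stringsAsFactors = FALSE
    ))
  }
  fit <- fit_logistic(design$y, design$X)
  b <- fit$coefficients["cluster2"]
  se <- sqrt(fit$vcov["cluster2", "cluster2"])
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  note <- if (fit$separation) "separation flagged" else ""
  data.frame(
    outcome = outcome_name, level = level,
    or = exp(b), ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
    p_value = p, significant = is.finite(p) && p < 0.05,
    direction = if (b > 0) "cluster2" else "cluster1",
    n_used = fit$n_used, note = note,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Adjusted between-cluster comparison for one disease
#'
#' Fits `disease ~ cluster + age + sex + SEP + smoking` and reports the
#' cluster-2 odds ratio, Wald 95% CI and p-value. A disease absent (or
#' universal) among the compared patients is marked untestable.
#'
#' @param cohort_obj a `comorbidity_cohort` (typically the comorbid subset).
#' @param assignments cluster id per record (exactly two distinct values).
#' @param disease codebook disease id.
#' @return one-row data.frame: `outcome`, `level`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `significant`, `direction` (which cluster is
#'   enriched), `n_used`, `note`.
#' @export
disease_cluster_comparison <- function(cohort_obj, assignments, disease) {
  if (!disease %in% cohort_obj$codebook$id) stop("unknown disease: ", disease)
  outcome <- cohort_obj$records[[disease]]
  design <- .cluster_design(cohort_obj, assignments, outcome)
  .adjusted_result(disease, "disease", design)
}

#' Adjusted between-cluster comparison for a disease group
#'
#' Outcome is the indicator of carrying at least one disease of the
#' ICD-11-adapted group; model and reporting as in
#' [disease_cluster_comparison()].
#'
#' @param cohort_obj a `comorbidity_cohort`.
#' @param assignments cluster id per record (two clusters).
#' @param group group label from the codebook.
#' @return one-row data.frame as in [disease_cluster_comparison()].
#' @export
group_cluster_comparison <- function(cohort_obj, assignments, group) {
  ids <- group_members(cohort_obj$codebook, group)
  m <- disease_matrix(cohort_obj)
  outcome <- as.integer(rowSums(m[, ids, drop = FALSE]) >= 1L)
  design <- .cluster_design(cohort_obj, assignments, outcome)
  .adjusted_result(group, "group", design)
}

#' Adjusted comparisons for all diseases and all groups
#'
#' @param cohort_obj a `comorbidity_cohort`.
#' @param assignments cluster id per record (two clusters).
#' @return data.frame with one row per disease (26) and per group (6).
#' @export
all_cluster_comparisons <- function(cohort_obj, assignments) {
  cb <- cohort_obj$codebook
  dis <- lapply(cb$id, function(d)
    disease_cluster_comparison(cohort_obj, assignments, d))
  grp <- lapply(sort(unique(stats::na.omit(cb$group))), function(g)
    group_cluster_comparison(cohort_obj, assignments, g))
  out <- do.call(rbind, c(dis, grp))
  rownames(out) <- NULL
  out
}
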