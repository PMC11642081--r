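# Two-step clustering of patients by binary disease indicators.
#
# The procedure mirrors the classic two-stage design for categorical data:
# a sequential leader pass condenses records into homogeneous leaves, then
# hierarchical agglomeration merges leaves under the log-likelihood
# (entropy) distance, and the cluster count is chosen by a BIC-based coarse
# search refined by the ratio of closest-pair merge distances.
#
# For a cluster v with N_v members and per-attribute one-counts N_vk1, the
# cluster cost is
#   xi_v = N_v * sum_k H_vk,   H_vk = entropy of attribute k within v,
# and the distance between clusters a, b is the entropy increase on pooling
#   d(a, b) = xi_{a+b} - xi_a - xi_b  >=  0.
# BIC(J) = 2 * sum_v xi_v + J * K * ln N for K binary attributes.

# a*log(b) with the 0*log(0) := 0 convention; preserves dim
.xlogy <- function(a, b) {
  out <- numeric(length(a))
  pos <- which(a > 0)
  out[pos] <- a[pos] * log(b[pos])
  dim(out) <- dim(a)
  out
}

# xi for each row of a (sizes n, one-counts ones[L x K]) summary block
.xi_rows <- function(n, ones) {
  zeros <- n - ones
  -rowSums(.xlogy(ones, ones / n) + .xlogy(zeros, zeros / n))
}

.as_flag_matrix <- function(x) {
  if (inherits(x, "comorbidity_cohort")) return(disease_matrix(x))
  m <- as.matrix(x)
  if (anyNA(m) || !all(m %in% c(0, 1))) stop("flags must be binary 0/1")
  storage.mode(m) <- "integer"
  m
}

#' Summarise a block of records as one cluster
#'
#' @param flags binary matrix (records x attributes) or a
#'   `comorbidity_cohort` (its disease indicators are used).
#' @return An object of class `cluster_summary`: list with `n` (member
#'   count) and `ones` (named one-count per attribute).
#' @export
cluster_summary <- function(flags) {
  m <- .as_flag_matrix(flags)
  if (nrow(m) < 1L) stop("empty cluster")
  structure(list(n = nrow(m), ones = colSums(m)), class = "cluster_summary")
}

#' Log-likelihood cost of a cluster
#'
#' `N_v` times the summed per-attribute entropy (natural log); 0 for a pure
#' cluster, increasing with within-cluster heterogeneity.
#'
#' @param summary a `cluster_summary`.
#' @return non-negative scalar.
#' @export
cluster_cost <- function(summary) {
  stopifnot(inherits(summary, "cluster_summary"))
  if (summary$n < 1L) stop("empty cluster")
  .xi_rows(summary$n, matrix(summary$ones, nrow = 1L))
}

#' Pool two cluster summaries
#'
#' @param a,b `cluster_summary` objects over the same attribute set.
#' @return the `cluster_summary` of the union.
#' @export
pool_summaries <- function(a, b) {
  if (!identical(names(a$ones), names(b$ones))) {
    stop("cluster summaries cover different attribute sets")
  }
  structure(list(n = a$n + b$n, ones = a$ones + b$ones),
            class = "cluster_summary")
}

#' Log-likelihood distance between two clusters
#'
#' The increase in total entropy cost caused by pooling:
#' `d(a, b) = xi_pooled - xi_a - xi_b`. Symmetric and non-negative; 0 iff
#' pooling adds no heterogeneity.
#'
#' @param a,b `cluster_summary` objects over the same attribute set.
#' @return non-negative scalar.
#' @export
ll_distance <- function(a, b) {
  cluster_cost(pool_summaries(a, b)) - cluster_cost(a) - cluster_cost(b)
}

# Single leader pass at a fixed threshold. Returns NULL if max_leaves would
# be exceeded, else list(n, ones, leaf_of).
.leader_pass <- function(m, threshold, max_leaves) {
  nrec <- nrow(m)
  K <- ncol(m)
  n <- numeric(0)
  ones <- matrix(0, nrow = 0L, ncol = K)
  leaf_of <- integer(nrec)
  xi <- numeric(0)
  for (i in seq_len(nrec)) {
    x <- m[i, ]
    if (length(n) > 0L) {
      pn <- n + 1
      pones <- ones + rep(x, each = length(n))
      d <- .xi_rows(pn, pones) - xi            # xi of a singleton is 0
      j <- which.min(d)
      if (d[j] <= threshold) {
        n[j] <- pn[j]
        ones[j, ] <- pones[j, ]
        xi[j] <- d[j] + xi[j]
        leaf_of[i] <- j
        next
      }
    }
    if (length(n) >= max_leaves) return(NULL)
    n <- c(n, 1)
    ones <- rbind(ones, x)
    xi <- c(xi, 0)
    leaf_of[i] <- length(n)
  }
  list(n = n, ones = ones, leaf_of = leaf_of, threshold = threshold)
}

#' Pre-cluster records into homogeneous leaves
#'
#' Sequential leader pass: each record joins the nearest existing leaf if
#' the log-likelihood distance increase is at most `threshold`, else starts
#' a new leaf. If the number of leaves would exceed `max_leaves`, the
#' threshold is raised (0 is bumped to `ln 2 / 4`, then doubled) and the
#' pass rebuilt. With the default `threshold = 0`, leaves are exactly the
#' distinct disease profiles.
#'
#' @param x binary matrix (records x attributes) or `comorbidity_cohort`.
#' @param threshold admission distance threshold (>= 0).
#' @param max_leaves leaf cap (>= 2).
#' @return list with `n` (leaf sizes), `ones` (leaf one-count matrix),
#'   `leaf_of` (leaf index per record, input order), `threshold` (the
#'   threshold actually used).
#' @export
precluster <- function(x, threshold = 0, max_leaves = 1000L) {
  m <- .as_flag_matrix(x)
  if (max_leaves < 2L) stop("max_leaves must be >= 2")
  if (threshold < 0) stop("threshold must be >= 0")
  if (threshold == 0) {
    # leaves are the distinct rows; equivalent to the leader pass but O(n)
    key <- apply(m, 1L, paste, collapse = "")
    first <- !duplicated(key)
    if (sum(first) <= max_leaves) {
      leaf_of <- match(key, key[first])
      ones <- rowsum(m, leaf_of)
      return(list(n = as.numeric(tabulate(leaf_of, sum(first))),
                  ones = unname(ones), leaf_of = leaf_of, threshold = 0))
    }
    threshold <- log(2) / 4
  }
  repeat {
    res <- .leader_pass(m, threshold, max_leaves)
    if (!is.null(res)) return(res)
    threshold <- threshold * 2
  }
}

#' Hierarchical agglomeration of leaves with BIC trace
#'
#' Greedily merges the closest pair of clusters under the log-likelihood
#' distance until one cluster remains, recording the merge history, the
#' closest-pair distance of every intermediate solution, and
#' `BIC(J) = 2 * sum xi_v + J * K * ln N` for `J <= J_max`.
#'
#' @param leaves a [precluster()] result (or list with `n` and `ones`).
#' @param J_max largest cluster count reported in the BIC trace.
#' @return list with `merges` (data.frame: step, i, j, dist, J_after; i/j are
#'   leaf representative indices, j absorbed into i), `bic_trace` (J = 1..
#'   min(J_max, L)), `dmin` (closest-pair distance of each J-cluster
#'   solution, J = 2..L), `xi_total` (per J), `n_leaves`, `N`, `K`.
#' @export
agglomerate <- function(leaves, J_max = 15L) {
  n <- leaves$n
  ones <- leaves$ones
  L <- length(n)
  if (L < 2L) stop("agglomeration needs at least 2 leaves")
  K <- ncol(ones)
  N <- sum(n)
  xi <- .xi_rows(n, ones)
  xi_total <- sum(xi)

  # full pairwise distance matrix
  S <- matrix(0, L, L)
  for (k in seq_len(K)) {
    On <- outer(n, n, "+")
    O1 <- outer(ones[, k], ones[, k], "+")
    O0 <- On - O1
    S <- S - (.xlogy(O1, O1 / On) + .xlogy(O0, O0 / On))
  }
  D <- S - outer(xi, xi, "+")
  diag(D) <- Inf

  active <- rep(TRUE, L)
  merges <- data.frame(step = integer(L - 1L), i = integer(L - 1L),
                       j = integer(L - 1L), dist = numeric(L - 1L),
                       J_after = integer(L - 1L))
  dmin <- numeric(L)          # dmin[J]: closest-pair distance at J clusters
  xi_by_J <- numeric(L)       # total cost at J clusters
  xi_by_J[L] <- xi_total

  for (step in seq_len(L - 1L)) {
    J <- L - step + 1L
    idx <- which(D == min(D[active, active]), arr.ind = TRUE)
    # deterministic tie-break: lowest row index, then lowest column
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    d <- D[i, j]
    dmin[J] <- d
    n[i] <- n[i] + n[j]
    ones[i, ] <- ones[i, ] + ones[j, ]
    xi[i] <- xi[i] + xi[j] + d
    xi_total <- xi_total + d
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    merges[step, ] <- list(step, i, j, d, J - 1L)
    xi_by_J[J - 1L] <- xi_total
    others <- which(active); others <- others[others != i]
    if (length(others) > 0L) {
      pn <- n[others] + n[i]
      pones <- ones[others, , drop = FALSE] + rep(ones[i, ], each = length(others))
      dnew <- .xi_rows(pn, pones) - xi[others] - xi[i]
      D[i, others] <- dnew
      D[others, i] <- dnew
    }
  }

  Js <- seq_len(min(J_max, L))
  bic <- 2 * xi_by_J[Js] + Js * K * log(N)
  list(merges = merges, bic_trace = bic, dmin = dmin[2:L],
       xi_total = xi_by_J, n_leaves = L, N = N, K = K)
}

# Replay merges until `k` clusters remain; returns cluster id per leaf.
.cut_merges <- function(merges, n_leaves, k) {
  stopifnot(k >= 1L, k <= n_leaves)
  parent <- seq_len(n_leaves)
  n_steps <- n_leaves - k
  for (s in seq_len(n_steps)) {
    parent[parent == merges$j[s]] <- merges$i[s]
  }
  match(parent, sort(unique(parent)))
}

#' Select the cluster count from the BIC trace and merge distances
#'
#' Two-stage rule. Stage 1 (coarse): the smallest `J >= 2` at which the
#' ratio of successive BIC improvements
#' `R1(J) = [BIC(J-1) - BIC(J)] / [BIC(1) - BIC(2)]` falls below
#' `bic_ratio`; if BIC does not improve at all from 1 to 2 clusters the
#' result is 1. Stage 2 (refine): among candidate counts `2..k_coarse`,
#' compare `R2(J) = dmin(J) / dmin(J + 1)` — a large value marks a solution
#' whose own closest pair is far apart relative to the solution one step
#' finer. The largest-`R2` candidate wins if it beats the runner-up by a
#' factor of at least `dist_ratio`; otherwise the larger of the two counts
#' is taken.
#'
#' @param agg an [agglomerate()] result.
#' @param bic_ratio stage-1 threshold (default 0.04).
#' @param dist_ratio stage-2 dominance factor (default 1.15).
#' @return integer cluster count `k`.
#' @export
select_k <- function(agg, bic_ratio = 0.04, dist_ratio = 1.15) {
  bic <- agg$bic_trace
  Jmax <- length(bic)
  if (Jmax < 2L) return(1L)
  base <- bic[1] - bic[2]
  if (!is.finite(base) || base <= 0) return(1L)
  r1 <- c(NA, (bic[-Jmax] - bic[-1]) / base)   # r1[J] for J >= 2; r1[2] = 1
  below <- which(!is.na(r1) & r1 < bic_ratio)
  k_coarse <- if (length(below) > 0L) min(below) else Jmax
  if (k_coarse < 2L) return(1L)
  cands <- 2:k_coarse
  # dmin is indexed J = 2..L
  dm <- function(J) agg$dmin[J - 1L]
  r2 <- vapply(cands, function(J) {
    dJ1 <- dm(J + 1L)
    if (is.na(dJ1) || dJ1 <= 0) Inf else dm(J) / dJ1
  }, numeric(1))
  if (length(cands) == 1L) return(cands)
  ord <- order(r2, decreasing = TRUE)
  top <- ord[1]; second <- ord[2]
  if (r2[second] == 0 || r2[top] / r2[second] >= dist_ratio) {
    cands[top]
  } else {
    max(cands[top], cands[second])
  }
}

#' Fit a two-step clustering of a cohort's disease indicators
#'
#' Runs the full two-step procedure on the 26 binary disease indicators:
#' seeded shuffle (the leader pass is order-dependent for positive
#' thresholds), pre-clustering, agglomeration, automatic or fixed cluster
#' count, and assignment of every record to its leaf's cluster. Clusters
#' are labelled 1..k by increasing size (ties by first appearance), so with
#' two clusters, cluster 1 is the smaller.
#'
#' @param x a `comorbidity_cohort` or binary record matrix.
#' @param comorbid_only drop records with 0 diseases before clustering
#'   (the configuration used for pattern discovery in the comorbid
#'   subpopulation). Default FALSE.
#' @param k fixed cluster count, or NULL (default) for automatic selection.
#' @param threshold,max_leaves leader-pass controls, see [precluster()].
#' @param J_max largest cluster count considered.
#' @param shuffle_seed seed for the record shuffle; NULL keeps input order.
#' @param bic_ratio,dist_ratio selection thresholds, see [select_k()].
#' @return An object of class `twostep_model`: list with `k`, `assignments`
#'   (cluster id per clustered record, input order), `record_index` (row
#'   indices of the clustered records in the input), `profiles` (k x K
#'   per-cluster prevalence matrix), `sizes`, `bic_trace`, `dmin`,
#'   `merges`, `n_leaves`, `threshold`.
#' @export
fit_twostep <- function(x, comorbid_only = FALSE, k = NULL,
                        threshold = 0, max_leaves = 1000L, J_max = 15L,
                        shuffle_seed = 1L,
                        bic_ratio = 0.04, dist_ratio = 1.15) {
  m <- .as_flag_matrix(x)
  record_index <- seq_len(nrow(m))
  if (comorbid_only) {
    record_index <- unname(which(rowSums(m) >= 1L))
    if (length(record_index) == 0L) stop("no comorbid records to cluster")
    m <- m[record_index, , drop = FALSE]
  }
  ord <- seq_len(nrow(m))
  if (!is.null(shuffle_seed)) {
    ord <- local({
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(shuffle_seed)
      sample.int(nrow(m))
    })
  }
  leaves <- precluster(m[ord, , drop = FALSE], threshold, max_leaves)
  L <- length(leaves$n)
  if (L == 1L) {
    prof <- matrix(leaves$ones / leaves$n, nrow = 1L,
                   dimnames = list(NULL, colnames(m)))
    return(structure(list(
      k = 1L, assignments = rep(1L, nrow(m)), record_index = record_index,
      profiles = prof, sizes = nrow(m), bic_trace = NA_real_,
      dmin = numeric(0), merges = NULL, n_leaves = 1L,
      threshold = leaves$threshold
    ), class = "twostep_model"))
  }
  agg <- agglomerate(leaves, J_max = J_max)
  if (is.null(k)) k <- select_k(agg, bic_ratio, dist_ratio)
  leaf_cluster <- .cut_merges(agg$merges, L, k)
  assign_shuffled <- leaf_cluster[leaves$leaf_of]
  assignments <- integer(length(assign_shuffled))
  assignments[ord] <- assign_shuffled
  # relabel by increasing size, ties by first occurrence
  sizes <- tabulate(assignments, k)
  relabel <- order(order(sizes, seq_len(k)))
  assignments <- relabel[assignments]
  sizes <- tabulate(assignments, k)
  prof <- rowsum(m, assignments) / sizes
  structure(list(
    k = as.integer(k), assignments = assignments,
    record_index = record_index, profiles = prof, sizes = sizes,
    bic_trace = agg$bic_trace, dmin = agg$dmin, merges = agg$merges,
    n_leaves = L, threshold = leaves$threshold
  ), class = "twostep_model")
}

#' @export
print.twostep_model <- function(x, ...) {
  cat(sprintf("Two-step clustering: %d cluster(s) over %d records (%d leaves)\n",
              x$k, length(x$assignments), x$n_leaves))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}
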