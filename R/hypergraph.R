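# Hypergraph co-occurrence analysis over multimorbid patients.
#
# Patients with >= 2 systemic diseases define a hypergraph H = (V, E):
# nodes V are the diseases, and each patient contributes the hyperedge of
# diseases they carry. The incidence matrix M (diseases x patients) gives
# the co-occurrence adjacency A = M M^T - D_n, where D_n = diag(M M^T)
# holds the per-disease occurrence counts, so A has zero diagonal and
# A_ij = number of patients carrying both i and j. Disease centrality is
# the principal (Perron) eigenvector of A.

#' Build the disease-by-patient incidence matrix
#'
#' Columns are restricted to multimorbid patients (disease count >=
#' `min_diseases`); rows are the 26 diseases in codebook order.
#'
#' @param cohort_obj a `comorbidity_cohort`.
#' @param min_diseases minimum disease count for inclusion (default 2).
#' @return binary integer matrix, diseases x patients, with codebook ids as
#'   row names and patient ids as column names.
#' @export
build_incidence <- function(cohort_obj, min_diseases = 2L) {
  m <- disease_matrix(cohort_obj)
  keep <- rowSums(m) >= min_diseases
  if (!any(keep)) {
    stop("no patient carries >= ", min_diseases,
         " diseases; incidence matrix would be empty")
  }
  t(m[keep, , drop = FALSE])
}

#' Catalogue the unique hyperedges of an incidence matrix
#'
#' Groups identical patient columns: each unique combination of >= 2
#' diseases is one hyperedge with an occurrence count. Counts sum to the
#' number of patients (columns).
#'
#' @param M incidence matrix from [build_incidence()].
#' @return data.frame of class `hyperedge_catalog`, one row per unique
#'   combination: `diseases` (comma-joined sorted ids), `size` (number of
#'   diseases), `count` (occurrences), ordered by decreasing count.
#' @export
catalog_hyperedges <- function(M) {
  keys <- apply(M, 2L, function(col) {
    paste(rownames(M)[col == 1L], collapse = ",")
  })
  tab <- table(keys)
  out <- data.frame(
    diseases = names(tab),
    size = lengths(strsplit(names(tab), ",", fixed = TRUE)),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$diseases), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hyperedge_catalog", "data.frame")
  out
}

#' Filter a hyperedge catalogue by occurrence count
#'
#' Keeps combinations occurring at least `min_count` times (default 8, the
#' noise threshold used for visualisation; centrality is computed on the
#' unfiltered hypergraph).
#'
#' @param catalog a `hyperedge_catalog`.
#' @param min_count minimum occurrence count (>= 1).
#' @return the filtered `hyperedge_catalog` (possibly zero rows).
#' @export
filter_catalog <- function(catalog, min_count = 8L) {
  if (min_count < 1L) stop("min_count must be >= 1")
  out <- catalog[catalog$count >= min_count, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hyperedge_catalog", "data.frame")
  out
}

#' Co-occurrence adjacency matrix A = M M^T - D_n
#'
#' `D_n = diag(M M^T)` are the per-disease occurrence counts among the
#' multimorbid patients, so the subtraction zeroes the diagonal and leaves
#' `A_ij` = number of patients carrying both diseases i and j. With
#' `dn = "proportions"`, `D_n` instead holds occurrence proportions
#' (counts / patients), leaving a mixed-scale diagonal; provided for
#' completeness, the counts reading is the default.
#'
#' @param M incidence matrix from [build_incidence()].
#' @param dn `"counts"` (default) or `"proportions"`.
#' @return list of class `cooccurrence_adjacency`: `A` (symmetric disease x
#'   disease matrix), `Dn` (the diagonal entries subtracted), `n_patients`.
#' @export
cooccurrence_adjacency <- function(M, dn = c("counts", "proportions")) {
  dn <- match.arg(dn)
  MMt <- M %*% t(M)
  d <- diag(MMt)
  Dn <- if (dn == "counts") d else d / ncol(M)
  A <- MMt - diag(Dn, nrow = nrow(MMt))
  list2 <- list(A = A, Dn = Dn, n_patients = ncol(M))
  class(list2) <- "cooccurrence_adjacency"
  list2
}

#' Principal-eigenvector disease centrality
#'
#' Power iteration from the uniform vector on the symmetric non-negative
#' adjacency matrix; the Perron eigenvector (unit Euclidean norm, sign
#' fixed so the largest-magnitude entry is positive) scores each disease by
#' how centrally it co-occurs with others. Diseases with an all-zero row
#' score 0. If the two leading eigenvalues are (near-)degenerate the
#' result is flagged non-unique.
#'
#' @param adj a `cooccurrence_adjacency` or a symmetric non-negative matrix.
#' @param tol max-norm convergence tolerance (default 1e-12).
#' @param max_iter iteration cap (default 1e5).
#' @return list of class `centrality_scores`: `scores` (named, unit 2-norm),
#'   `eigenvalue`, `iterations`, `converged`, `unique` (FALSE when the top
#'   eigenpair is degenerate), `ranking` (disease ids, most central first).
#' @export
centrality <- function(adj, tol = 1e-12, max_iter = 1e5L) {
  A <- if (inherits(adj, "cooccurrence_adjacency")) adj$A else as.matrix(adj)
  if (any(A < 0)) stop("adjacency must be non-negative")
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency must be symmetric")
  if (all(A == 0)) stop("all-zero adjacency: centrality undefined")
  n <- nrow(A)
  v <- rep(1 / sqrt(n), n)
  # positive diagonal shift: leaves the Perron vector unchanged but makes
  # the leading eigenvalue strictly dominant in magnitude, so iteration
  # cannot oscillate on bipartite-like structures (eigenvalues +/- lambda)
  sigma <- 0.05 * max(rowSums(A))
  lambda <- 0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- drop(A %*% v) + sigma * v
    nw <- sqrt(sum(w^2))
    if (nw == 0) break     # uniform start annihilated; fall through flagged
    w <- w / nw
    if (max(abs(w - v)) < tol) { v <- w; lambda <- nw - sigma; converged <- TRUE; break }
    v <- w
    lambda <- nw - sigma
  }
  # sign convention: largest-magnitude entry positive
  if (v[which.max(abs(v))] < 0) v <- -v
  v[abs(v) < 1e-14] <- 0
  # degeneracy check on the deflated matrix
  lambda2 <- tryCatch({
    B <- A - lambda * tcrossprod(v)
    max(abs(eigen(B, symmetric = TRUE, only.values = TRUE)$values))
  }, error = function(e) NA_real_)
  uniq <- !(is.finite(lambda2) && lambda > 0 &&
              abs(lambda - lambda2) / lambda < 1e-9)
  scores <- stats::setNames(v, rownames(A))
  structure(list(
    scores = scores, eigenvalue = lambda, iterations = iter,
    converged = converged, unique = uniq,
    ranking = if (is.null(names(scores))) order(-scores)
              else names(sort(scores, decreasing = TRUE))
  ), class = "centrality_scores")
}

#' Export hypergraph tables
#'
#' Writes `nodes.tsv` (disease, centrality, degree = number of distinct
#' partner diseases), `hyperedges.tsv` (edge id, member diseases, count),
#' and `hypergraph.json` bundling both, into `dir`.
#'
#' @param catalog a `hyperedge_catalog` (typically [filter_catalog()]
#'   output).
#' @param scores a `centrality_scores` over the same diseases.
#' @param adj the `cooccurrence_adjacency` (for node degrees).
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
export_hypergraph <- function(catalog, scores, adj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  degree <- rowSums(adj$A > 0)
  nodes <- data.frame(
    disease = names(scores$scores),
    centrality = unname(scores$scores),
    degree = as.integer(degree[names(scores$scores)]),
    stringsAsFactors = FALSE
  )
  nodes_path <- file.path(dir, "nodes.tsv")
  utils::write.table(nodes, nodes_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files <- nodes_path
  if (nrow(catalog) > 0L) {
    edges <- data.frame(edge_id = sprintf("e%03d", seq_len(nrow(catalog))),
                        catalog, stringsAsFactors = FALSE)
    edges_path <- file.path(dir, "hyperedges.tsv")
    utils::write.table(edges, edges_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, edges_path)
  } else {
    warning("hyperedge catalogue is empty after filtering; ",
            "writing node table only")
    edges <- NULL
  }
  json_path <- file.path(dir, "hypergraph.json")
  jsonlite::write_json(list(nodes = nodes, hyperedges = edges), json_path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(files, json_path))
}
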