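# Brute-force co-occurrence oracle: loop over patients and disease pairs.
brute_cooccurrence <- function(M) {
  n <- nrow(M)
  A <- matrix(0L, n, n, dimnames = dimnames(M)[c(1, 1)])
  for (p in seq_len(ncol(M))) {
    carried <- which(M[, p] == 1L)
    for (i in carried) for (j in carried) {
      if (i != j) A[i, j] <- A[i, j] + 1L
    }
  }
  A
}

# Random multimorbid incidence matrix (diseases x patients), every patient
# carrying >= 2 diseases.
random_incidence <- function(n_dis, n_pat, p = 0.3) {
  M <- matrix(0L, n_dis, n_pat,
              dimnames = list(paste0("d", seq_len(n_dis)),
                              paste0("p", seq_len(n_pat))))
  for (j in seq_len(n_pat)) {
    repeat {
      col <- rbinom(n_dis, 1L, p)
      if (sum(col) >= 2L) break
    }
    M[, j] <- col
  }
  M
}

test_that("incidence matrix keeps multimorbid patients in codebook order", {
  ch <- toy_cohort(list(
    c("allergy", "asthma"), c("allergy", "asthma"),
    c("allergy", "hypertension"), "hypertension", character(0)
  ))
  M <- build_incidence(ch, min_diseases = 2)
  expect_equal(dim(M), c(26L, 3L))
  expect_equal(rownames(M), CB$id)
  expect_true(all(colSums(M) >= 2))
  expect_equal(unname(colSums(M)), c(2, 2, 2))
  expect_equal(unname(M["allergy", ]), c(1L, 1L, 1L))
  singles <- toy_cohort(list("allergy", "hypertension"))
  expect_error(build_incidence(singles), "empty")
})

test_that("hyperedge catalogue groups identical disease combinations", {
  ch <- toy_cohort(list(
    c("allergy", "asthma"), c("allergy", "asthma"),
    c("allergy", "hypertension")
  ))
  M <- build_incidence(ch)
  cat_ <- catalog_hyperedges(M)
  expect_equal(nrow(cat_), 2L)
  expect_equal(cat_$count[cat_$diseases == "asthma,allergy" |
                          cat_$diseases == "allergy,asthma"], 2L)
  expect_equal(sum(cat_$count), ncol(M))
  expect_true(all(cat_$size >= 2))

  # all columns identical -> one entry with count m
  ch_same <- toy_cohort(rep(list(c("allergy", "asthma")), 7))
  cat_same <- catalog_hyperedges(build_incidence(ch_same))
  expect_equal(nrow(cat_same), 1L)
  expect_equal(cat_same$count, 7L)
})

test_that("catalogue filtering keeps combinations at the occurrence threshold", {
  cat_ <- structure(data.frame(
    diseases = c("a,b", "a,c", "b,c"), size = c(2L, 2L, 2L),
    count = c(9L, 8L, 7L), stringsAsFactors = FALSE
  ), class = c("hyperedge_catalog", "data.frame"))
  kept <- filter_catalog(cat_, min_count = 8)
  expect_equal(kept$diseases, c("a,b", "a,c"))
  expect_equal(filter_catalog(cat_, 1), cat_, ignore_attr = TRUE)
  none <- filter_catalog(cat_, 100)
  expect_equal(nrow(none), 0L)
  expect_error(filter_catalog(cat_, 0), "min_count")
})

test_that("adjacency equals brute-force pairwise co-occurrence with zero diagonal", {
  ch <- toy_cohort(list(
    c("allergy", "asthma"), c("allergy", "asthma"),
    c("allergy", "hypertension"), c("asthma", "hypertension")
  ))
  M <- build_incidence(ch)
  adj <- cooccurrence_adjacency(M)
  expect_equal(adj$A["allergy", "asthma"], 2)
  expect_equal(adj$A["allergy", "hypertension"], 1)
  expect_equal(adj$A["asthma", "hypertension"], 1)
  expect_true(all(diag(adj$A) == 0))
  expect_equal(unname(adj$Dn[c("allergy", "asthma", "hypertension")]),
               c(3, 3, 2))

  set.seed(19)
  for (i in 1:20) {
    M <- random_incidence(sample(4:10, 1), sample(5:50, 1))
    adj <- cooccurrence_adjacency(M)
    expect_identical(unname(adj$A), unname(brute_cooccurrence(M)) + 0)
    expect_identical(adj$A, t(adj$A))
    # handshake identity: sum over pairs = sum over patients of C(d_p, 2)
    expect_equal(sum(adj$A[upper.tri(adj$A)]),
                 sum(choose(colSums(M), 2)))
  }

  # proportions reading of the diagonal is available behind the flag
  M <- random_incidence(5, 12)
  adj_p <- cooccurrence_adjacency(M, dn = "proportions")
  expect_equal(unname(adj_p$Dn), unname(diag(M %*% t(M))) / ncol(M))
})

test_that("power-iteration centrality matches closed forms and the eigen oracle", {
  # symmetric two-disease case: exactly (1/sqrt(2), 1/sqrt(2))
  for (c_ in c(1, 4, 117)) {
    A <- matrix(c(0, c_, c_, 0), 2)
    sc <- centrality(A)
    expect_equal(unname(sc$scores), rep(1 / sqrt(2), 2), tolerance = 1e-14)
    expect_equal(sc$eigenvalue, c_, tolerance = 1e-12)
  }
  # star: the hub carries the unique maximum
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  sc <- centrality(star)
  expect_equal(which.max(sc$scores), 1L)
  expect_equal(unname(sc$scores), c(1 / sqrt(2), rep(1 / (2 * sqrt(2)), 4)),
               tolerance = 1e-10)

  set.seed(23)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    A <- matrix(rpois(n * n, 2), n)
    A <- A + t(A)
    diag(A) <- 0
    if (all(A == 0)) next
    sc <- centrality(A)
    e <- eigen(A, symmetric = TRUE)
    v <- e$vectors[, 1]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_lt(max(abs(sc$scores - v)), 1e-8)
    expect_equal(sc$eigenvalue, e$values[1], tolerance = 1e-8)
    expect_equal(sqrt(sum(sc$scores^2)), 1, tolerance = 1e-12)
    expect_true(all(sc$scores >= -1e-12))
  }

  expect_error(centrality(matrix(0, 3, 3)), "all-zero")
  expect_error(centrality(matrix(c(0, -1, -1, 0), 2)), "non-negative")
})

test_that("centrality is invariant under relabelling and zero rows score 0", {
  set.seed(29)
  A <- matrix(rpois(49, 3), 7); A <- A + t(A); diag(A) <- 0
  A[3, ] <- A[, 3] <- 0                     # isolated disease
  rownames(A) <- colnames(A) <- paste0("d", 1:7)
  sc <- centrality(A)
  expect_equal(unname(sc$scores["d3"]), 0)
  perm <- sample(7)
  sc_p <- centrality(A[perm, perm])
  expect_equal(sc_p$scores[rownames(A)], sc$scores, tolerance = 1e-9)
})

test_that("hypergraph export writes re-readable node and edge tables", {
  ch <- toy_cohort(c(rep(list(c("allergy", "asthma")), 9),
                     list(c("hypertension", "diabetes_mellitus"))))
  M <- build_incidence(ch)
  catal <- catalog_hyperedges(M)
  adj <- cooccurrence_adjacency(M)
  sc <- centrality(adj)
  dir <- withr::local_tempdir()
  files <- export_hypergraph(filter_catalog(catal, 8), sc, adj, dir)
  nodes <- read.delim(file.path(dir, "nodes.tsv"))
  expect_equal(nrow(nodes), 26L)
  expect_equal(nodes$disease, CB$id)
  edges <- read.delim(file.path(dir, "hyperedges.tsv"))
  expect_equal(edges$count, 9L)             # only the frequent pair survives
  bundle <- jsonlite::read_json(file.path(dir, "hypergraph.json"))
  expect_equal(length(bundle$nodes), 26L)
  expect_equal(bundle$hyperedges[[1]]$count, 9L)

  # nothing passes the filter: node table only, with a warning
  dir2 <- withr::local_tempdir()
  expect_warning(export_hypergraph(filter_catalog(catal, 100), sc, adj, dir2),
                 "empty")
  expect_false(file.exists(file.path(dir2, "hyperedges.tsv")))
})
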