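# Small binary matrices for distance-level tests use few attributes; the
# entropy formulas are attribute-count agnostic.

test_that("cluster cost is N times the summed attribute entropy", {
  pure <- cluster_summary(matrix(c(1, 0, 1, 1, 0, 1), 2, byrow = TRUE))
  expect_equal(cluster_cost(pure), 0)
  # N = 2, one attribute split {0, 1}: cost = 2 * ln 2
  mixed <- cluster_summary(matrix(c(0, 1), ncol = 1))
  expect_equal(cluster_cost(mixed), 2 * log(2))
  # merging two identical pure clusters stays pure
  a <- cluster_summary(matrix(c(1, 0, 1, 0), 2, byrow = TRUE))
  b <- cluster_summary(matrix(c(1, 0, 1, 0), 2, byrow = TRUE))
  expect_equal(cluster_cost(pool_summaries(a, b)), 0)
})

test_that("log-likelihood distance is the pooled-entropy increase", {
  one <- cluster_summary(matrix(1, 1, 1))
  zero <- cluster_summary(matrix(0, 1, 1))
  expect_equal(ll_distance(one, one), 0)
  expect_equal(ll_distance(one, zero), 2 * log(2))
  # symmetry and superadditivity of cost under pooling, random summaries
  set.seed(4)
  for (i in 1:25) {
    a <- cluster_summary(matrix(rbinom(40, 1, runif(1, 0.2, 0.8)), 8))
    b <- cluster_summary(matrix(rbinom(25, 1, runif(1, 0.2, 0.8)), 5))
    d_ab <- ll_distance(a, b)
    expect_equal(d_ab, ll_distance(b, a))
    expect_gte(d_ab, -1e-12)
    expect_gte(cluster_cost(pool_summaries(a, b)),
               cluster_cost(a) + cluster_cost(b) - 1e-12)
  }
  bad <- cluster_summary(matrix(rbinom(12, 1, 0.5), 4,
                                dimnames = list(NULL, c("x", "y", "z"))))
  expect_error(ll_distance(one, bad), "different attribute sets")
})

test_that("preclustering partitions records; extreme thresholds behave", {
  set.seed(9)
  m <- matrix(rbinom(200 * 6, 1, 0.3), 200)
  res0 <- precluster(m, threshold = 0)
  # every distinct profile its own leaf
  expect_equal(length(res0$n), nrow(unique(m)))
  expect_equal(sum(res0$n), nrow(m))
  expect_true(all(tabulate(res0$leaf_of, length(res0$n)) == res0$n))
  # leaves are pure at threshold 0
  for (leaf in seq_along(res0$n)) {
    rows <- m[res0$leaf_of == leaf, , drop = FALSE]
    expect_equal(nrow(unique(rows)), 1L)
  }
  resInf <- precluster(m, threshold = Inf)
  expect_equal(length(resInf$n), 1L)
  expect_equal(resInf$n, nrow(m))
  expect_error(precluster(m, max_leaves = 1), "max_leaves")

  # the leaf cap triggers threshold escalation but still partitions
  res_cap <- precluster(m, threshold = 0, max_leaves = 10)
  expect_lte(length(res_cap$n), 10)
  expect_equal(sum(res_cap$n), nrow(m))
  expect_gt(res_cap$threshold, 0)
})

test_that("planted two-class cohorts precluster within the leaf cap", {
  gen <- generate_cohort(default_spec(n = 600, seed = 21))
  sub <- comorbid_subset(gen)
  res <- precluster(disease_matrix(sub$cohort), threshold = 0,
                    max_leaves = 1000)
  expect_lte(length(res$n), 1000)
  expect_equal(sum(res$n), n_patients(sub$cohort))
})

test_that("agglomeration merges one pair per step and separates pure blocks", {
  # two well-separated pure blocks (disjoint single diseases)
  m <- rbind(matrix(rep(c(1, 0), each = 10), 10),
             matrix(rep(c(0, 1), each = 10), 10))
  leaves <- precluster(m, threshold = 0)
  agg <- agglomerate(leaves, J_max = 5)
  expect_equal(agg$merges$J_after, 1L)          # 2 leaves -> single merge
  expect_equal(agg$n_leaves, 2L)
  # the only merge distance equals the pooled cost of the two blocks
  expect_equal(agg$dmin[1], 20 * 2 * log(2))

  set.seed(13)
  m2 <- matrix(rbinom(50 * 4, 1, 0.4), 50)
  leaves2 <- precluster(m2, threshold = 0)
  agg2 <- agglomerate(leaves2, J_max = 15)
  expect_equal(agg2$merges$J_after,
               seq(length(leaves2$n) - 1L, 1L))  # one fewer cluster per step
  expect_equal(length(agg2$bic_trace), min(15L, length(leaves2$n)))
})

test_that("leader-pass + agglomeration equals all-singleton agglomeration", {
  # oracle equivalence at threshold 0 on small cohorts
  for (seed in c(2, 5)) {
    set.seed(seed)
    m <- matrix(rbinom(120 * 5, 1, 0.35), 120)
    via_leaves <- fit_twostep(m, k = 3, shuffle_seed = NULL)
    singletons <- list(n = rep(1, nrow(m)),
                       ones = m + 0)
    agg <- agglomerate(singletons, J_max = 15)
    leaf_cluster <- comorbinet:::.cut_merges(agg$merges, nrow(m), 3L)
    expect_equal(ari(via_leaves$assignments, leaf_cluster), 1)
  }
})

test_that("cluster-count selection: planted structure vs none", {
  # three blocks with disjoint disease sets -> k = 3
  blocks <- c(rep(list(c("asthma", "allergic_rhinitis")), 40),
              rep(list(c("hypertension", "diabetes_mellitus")), 40),
              rep(list(c("anemia", "radiation")), 40))
  ch3 <- toy_cohort(blocks)
  fit3 <- fit_twostep(ch3)
  expect_equal(fit3$k, 3L)

  # identical records -> a single leaf -> k = 1
  ch1 <- toy_cohort(rep(list(c("allergy")), 30))
  fit1 <- fit_twostep(ch1)
  expect_equal(fit1$k, 1L)

  # pi-identical classes (no real structure): any partition found must be
  # uninformative about the planted labels (chance-level ARI)
  for (seed in 1:3) {
    spec <- default_spec(n = 1200, seed = 400 + seed)
    spec <- perturb_spec(spec,
                         disease_probs.respiratory = spec$disease_probs$cardiometabolic)
    gen <- generate_cohort(spec)
    sub <- comorbid_subset(gen)
    fit0 <- fit_twostep(sub$cohort, shuffle_seed = seed)
    if (fit0$k > 1L) {
      expect_lt(abs(ari(fit0$assignments, sub$labels)), 0.05)
    }
  }
})

test_that("two-step fit recovers the planted two-cluster pattern", {
  gen <- generate_cohort(default_spec(n = 2500, seed = 3))
  sub <- comorbid_subset(gen)
  fit <- fit_twostep(sub$cohort, shuffle_seed = 3)
  expect_equal(fit$k, 2L)
  expect_equal(length(fit$assignments), n_patients(sub$cohort))
  expect_equal(unname(fit$sizes), unname(tabulate(fit$assignments, fit$k)))
  # profiles average to cluster prevalence
  m <- disease_matrix(sub$cohort)
  expect_equal(unname(fit$profiles[1, ]),
               unname(colMeans(m[fit$assignments == 1L, , drop = FALSE])))
  # the hypertension-rich cluster is also the diabetes-rich cluster
  hyp_cl <- unname(which.max(fit$profiles[, "hypertension"]))
  expect_equal(unname(which.max(fit$profiles[, "diabetes_mellitus"])), hyp_cl)
  # and the other cluster carries the respiratory/allergy pattern
  expect_equal(unname(which.max(fit$profiles[, "allergic_rhinitis"])),
               setdiff(1:2, hyp_cl))
  # recovered partition tracks the planted one well above chance
  expect_gt(ari(fit$assignments, sub$labels), 0.4)
})

test_that("fixed k and comorbid_only subsetting behave", {
  gen <- generate_cohort(default_spec(n = 500, seed = 8))
  fit_all <- fit_twostep(gen$cohort, comorbid_only = TRUE, k = 2)
  counts <- disease_counts(gen$cohort)
  expect_equal(fit_all$record_index, which(counts >= 1L))
  expect_equal(fit_all$k, 2L)
  expect_error(fit_twostep(matrix(0L, 5, 3), comorbid_only = TRUE),
               "no comorbid records")
})
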