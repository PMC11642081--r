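# End-to-end orchestration: descriptives -> comorbid-subset clustering ->
# adjusted comparisons -> hypergraph analysis, from a CSV cohort or the
# synthetic generator, with a single reproducibility seed and a run
# manifest. The R functions are the interface; `pipeline_config()` +
# `run_pipeline()` replace a shell wrapper.

#' Assemble a pipeline configuration
#'
#' Defaults reproduce the reference analysis settings: multimorbidity is
#' >= 2 diseases and hyperedges with >= 8 occurrences are kept for the
#' visual export.
#'
#' @param input `"synthetic"` (default) or `"csv"`.
#' @param csv_path cohort CSV path when `input = "csv"`.
#' @param spec a `synthetic_spec`; default [default_spec()] re-seeded from
#'   `seed` when `input = "synthetic"`.
#' @param min_diseases multimorbidity threshold (default 2).
#' @param hyperedge_min_count hyperedge occurrence filter (default 8).
#' @param seed root seed; drives generation and the clustering shuffle.
#' @param out_dir output directory.
#' @param total_population_cluster also run the sanity clustering of the
#'   full population (comorbid vs not), off by default.
#' @param bh_correct add Benjamini-Hochberg adjusted p-values to the
#'   comparison table, off by default.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = c("synthetic", "csv"), csv_path = NULL,
                            spec = NULL, min_diseases = 2L,
                            hyperedge_min_count = 8L, seed = 1L,
                            out_dir = tempfile("comorbinet_run_"),
                            total_population_cluster = FALSE,
                            bh_correct = FALSE) {
  input <- match.arg(input)
  if (input == "csv" && is.null(csv_path)) stop("csv input needs csv_path")
  structure(list(
    input = input, csv_path = csv_path, spec = spec,
    min_diseases = as.integer(min_diseases),
    hyperedge_min_count = as.integer(hyperedge_min_count),
    seed = as.integer(seed), out_dir = out_dir,
    total_population_cluster = total_population_cluster,
    bh_correct = bh_correct
  ), class = "pipeline_config")
}

#' Run the full comorbidity-pattern pipeline
#'
#' Stages: load or generate the cohort; disease-count distribution and
#' characteristics comparison (comorbid vs not); two-step clustering of the
#' comorbid subset; per-cluster prevalence table; covariate-adjusted
#' disease and group comparisons between the two largest clusters; and the
#' multimorbidity hypergraph with centrality. Writes `table1.csv`,
#' `table2.csv`, `figure2.csv`, `clusters.csv`, `bic.csv`,
#' `adjusted_comparisons.csv`, the hypergraph exports, and
#' `manifest.json`; identical config + seed yields identical outputs.
#'
#' @param config a `pipeline_config`.
#' @return list of class `pipeline_result` with elements `cohort`,
#'   `distribution`, `table1`, `model`, `table2`, `adjusted`, `hypergraph`
#'   (list: incidence, catalog, filtered, adjacency, centrality),
#'   `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[comorbinet] %-12s %s", stage, sprintf(...)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  exclusions <- NULL
  if (config$input == "synthetic") {
    spec <- config$spec %||% default_spec(seed = config$seed)
    gen <- generate_cohort(spec)
    ch <- gen$cohort
    labels <- gen$labels
    log_stage("generate", "synthetic cohort of %d patients (seed %d)",
              n_patients(ch), spec$seed)
  } else {
    ch <- read_cohort(config$csv_path)
    labels <- NULL
    exclusions <- attr(ch, "exclusions")
    log_stage("read", "cohort of %d patients from %s (excluded: %d underage, %d incomplete)",
              n_patients(ch), config$csv_path,
              exclusions$n_excluded_age, exclusions$n_excluded_incomplete)
  }

  counts <- disease_counts(ch)
  dist <- count_distribution(ch)
  comorbid <- counts >= 1L
  table1 <- compare_groups(ch, comorbid)
  log_stage("descriptives", "comorbidity %.1f%%, multimorbidity %.1f%%",
            dist$comorbidity_pct, dist$multimorbidity_pct)

  if (config$total_population_cluster) {
    total_model <- fit_twostep(ch, comorbid_only = FALSE,
                               shuffle_seed = config$seed)
    log_stage("cluster-all", "total-population run selected k = %d",
              total_model$k)
  } else {
    total_model <- NULL
  }

  sub <- cohort(ch$records[comorbid, , drop = FALSE], ch$codebook)
  model <- fit_twostep(sub, shuffle_seed = config$seed)
  log_stage("cluster", "comorbid subset n = %d -> k = %d (sizes: %s)",
            n_patients(sub), model$k, paste(model$sizes, collapse = ", "))

  strata <- list(total = TRUE, comorbid = comorbid)
  assign_full <- rep(NA_integer_, n_patients(ch))
  assign_full[which(comorbid)] <- model$assignments
  for (cl in seq_len(model$k)) {
    strata[[paste0("cluster", cl)]] <- !is.na(assign_full) & assign_full == cl
  }
  table2 <- prevalence_table(ch, strata)

  adjusted <- NULL
  if (model$k >= 2L) {
    # compare the two largest clusters
    top2 <- order(model$sizes, decreasing = TRUE)[1:2]
    sel <- model$assignments %in% top2
    sub2 <- cohort(sub$records[sel, , drop = FALSE], sub$codebook)
    adjusted <- all_cluster_comparisons(sub2, model$assignments[sel])
    if (config$bh_correct) {
      adjusted$p_bh <- stats::p.adjust(adjusted$p_value, method = "BH")
    }
    log_stage("adjusted", "%d outcomes compared, %d significant at 0.05",
              nrow(adjusted), sum(adjusted$significant, na.rm = TRUE))
  }

  hyper <- NULL
  if (any(counts >= config$min_diseases)) {
    M <- build_incidence(ch, config$min_diseases)
    catalog <- catalog_hyperedges(M)
    filtered <- filter_catalog(catalog, config$hyperedge_min_count)
    adj <- cooccurrence_adjacency(M)
    cent <- centrality(adj)
    hyper <- list(incidence = M, catalog = catalog, filtered = filtered,
                  adjacency = adj, centrality = cent)
    log_stage("hypergraph", "%d multimorbid patients, %d unique hyperedges (%d kept), top: %s",
              ncol(M), nrow(catalog), nrow(filtered), cent$ranking[1])
  }

  # ---- write outputs -------------------------------------------------
  od <- config$out_dir
  utils::write.csv(table1, file.path(od, "table1.csv"), row.names = FALSE)
  utils::write.csv(table2, file.path(od, "table2.csv"), row.names = FALSE)
  fig2 <- data.frame(n_diseases = names(dist$bins),
                     n_patients = as.integer(dist$bins),
                     pct = 100 * as.integer(dist$bins) / dist$n_total)
  utils::write.csv(fig2, file.path(od, "figure2.csv"), row.names = FALSE)
  clusters_df <- data.frame(patient_id = sub$records$patient_id,
                            cluster = model$assignments)
  utils::write.csv(clusters_df, file.path(od, "clusters.csv"),
                   row.names = FALSE)
  if (!all(is.na(model$bic_trace))) {
    utils::write.csv(data.frame(J = seq_along(model$bic_trace),
                                BIC = model$bic_trace),
                     file.path(od, "bic.csv"), row.names = FALSE)
  }
  if (!is.null(adjusted)) {
    utils::write.csv(adjusted, file.path(od, "adjusted_comparisons.csv"),
                     row.names = FALSE)
  }
  if (!is.null(hyper)) {
    export_hypergraph(hyper$filtered, hyper$centrality, hyper$adjacency,
                      od)
    utils::write.table(hyper$adjacency$A, file.path(od, "adjacency.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(
      data.frame(disease = names(hyper$centrality$scores),
                 centrality = unname(hyper$centrality$scores)),
      file.path(od, "centrality.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    input = config$input,
    n = n_patients(ch),
    n_comorbid = sum(comorbid),
    n_multimorbid = sum(counts >= config$min_diseases),
    k = model$k,
    cluster_sizes = model$sizes,
    min_diseases = config$min_diseases,
    hyperedge_min_count = config$hyperedge_min_count,
    exclusions = exclusions,
    package_version = as.character(utils::packageVersion("comorbinet")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  structure(list(
    cohort = ch, labels = labels, distribution = dist, table1 = table1,
    model = model, total_model = total_model, table2 = table2,
    adjusted = adjusted, hypergraph = hyper, manifest = manifest,
    out_dir = od
  ), class = "pipeline_result")
}

#' Monte-Carlo reproduction of the reference tables
#'
#' Runs the synthetic pipeline at the default calibration (n = 3171) across
#' several seeds and averages the headline quantities, with Monte-Carlo
#' intervals: comorbidity and multimorbidity prevalence, selected cluster
#' count, cluster shares, and the per-disease cluster prevalences.
#'
#' @param n_seeds number of replicate cohorts (default 20).
#' @param base_seed seeds used are `base_seed + 0:(n_seeds-1)`.
#' @param n cohort size per replicate (default 3171).
#' @return list with `summary` (named means), `per_seed` (data.frame, one
#'   row per replicate), `profile_mean` (mean cluster-prevalence matrix of
#'   the two-cluster fits).
#' @export
reproduce_reference_tables <- function(n_seeds = 20L, base_seed = 1L,
                                       n = 3171L) {
  seeds <- base_seed + seq_len(n_seeds) - 1L
  rows <- vector("list", n_seeds)
  profiles <- NULL
  for (i in seq_along(seeds)) {
    spec <- default_spec(n = n, seed = seeds[i])
    gen <- generate_cohort(spec)
    counts <- disease_counts(gen$cohort)
    sub <- cohort(gen$cohort$records[counts >= 1L, , drop = FALSE],
                  gen$cohort$codebook)
    model <- fit_twostep(sub, shuffle_seed = seeds[i])
    share2 <- if (model$k == 2L) 100 * model$sizes[2] / sum(model$sizes)
              else NA_real_
    if (model$k == 2L) {
      profiles <- if (is.null(profiles)) model$profiles
                  else profiles + model$profiles
    }
    rows[[i]] <- data.frame(
      seed = seeds[i],
      comorbidity_pct = 100 * mean(counts >= 1L),
      multimorbidity_pct = 100 * mean(counts >= 2L),
      k = model$k,
      cluster2_share_pct = share2
    )
  }
  per_seed <- do.call(rbind, rows)
  k2 <- sum(per_seed$k == 2L)
  summary <- c(
    comorbidity_pct = mean(per_seed$comorbidity_pct),
    multimorbidity_pct = mean(per_seed$multimorbidity_pct),
    k2_fraction = k2 / n_seeds,
    cluster2_share_pct = mean(per_seed$cluster2_share_pct, na.rm = TRUE)
  )
  list(summary = summary, per_seed = per_seed,
       profile_mean = if (!is.null(profiles)) profiles / k2 else NULL)
}
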