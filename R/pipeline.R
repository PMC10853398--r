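#' Pipeline configuration
#'
#' Assembles the end-to-end configuration: cohort generator settings,
#' preprocessing thresholds, prediction tasks, knowledge-graph source
#' (either a generator config or a path to an edge-list TSV — exactly one),
#' and interpretation settings. The global seed propagates to every stage.
#'
#' @param cohort A [cohort_config()] or a list of its arguments.
#' @param preprocessing List: `missing_feature_threshold`,
#'   `missing_subject_threshold`, `outlier_limits`, `impute_max_iter`,
#'   `impute_n_trees`.
#' @param targets Clinical targets to model.
#' @param horizons Horizons to model (`"6mo"`, `"1yr"`).
#' @param mode `"classification"` or `"regression"`.
#' @param feature_sets Names of feature sets to compare (default all seven).
#' @param n_folds Outer CV folds.
#' @param kg A [kg_config()] (or argument list), or `NULL` when `kg_path`
#'   is given.
#' @param kg_path Path to an existing edge-list TSV, or `NULL`.
#' @param interpret List: `target` (which task's predictors seed the graph
#'   stage; default the first target), `horizon`, `top_k`.
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            preprocessing = list(),
                            targets = clinical_target_names(),
                            horizons = "6mo",
                            mode = "classification",
                            feature_sets = NULL,
                            n_folds = 10L,
                            kg = kg_config(),
                            kg_path = NULL,
                            interpret = list(),
                            seed = 1L) {
  if (is.list(cohort) && !inherits(cohort, "cohort_config"))
    cohort <- do.call(cohort_config, cohort)
  if (!is.null(kg) && is.list(kg) && !inherits(kg, "kg_config"))
    kg <- do.call(kg_config, kg)
  if (is.null(kg) && is.null(kg_path))
    stop("configuration error: provide either a KG generator config (kg) ",
         "or an edge-list path (kg_path)")
  if (!is.null(kg_path) && !file.exists(kg_path))
    stop("configuration error: kg_path does not exist: ", kg_path)
  stopifnot(all(targets %in% clinical_target_names()),
            all(horizons %in% c("6mo", "1yr")),
            mode %in% c("classification", "regression"))
  pp <- utils::modifyList(list(missing_feature_threshold = 0.10,
                               missing_subject_threshold = 0.10,
                               outlier_limits = c(HbA1c = 12, glucose = 200,
                                                  insulin = 60),
                               impute_max_iter = 10L,
                               impute_n_trees = 100L), preprocessing)
  it <- utils::modifyList(list(target = targets[1], horizon = horizons[1],
                               top_k = 10L), interpret)
  seed <- as.integer(seed)
  cohort$seed <- seed
  if (!is.null(kg)) kg$seed <- seed + 104729L
  structure(list(cohort = cohort, preprocessing = pp, targets = targets,
                 horizons = horizons, mode = mode,
                 feature_sets = feature_sets, n_folds = n_folds,
                 kg = kg, kg_path = kg_path, interpret = it, seed = seed),
            class = "pipeline_config")
}

#' Small demonstration configuration
#'
#' A scaled-down cohort (200 subjects, 40 proteins, 60 metabolites) and
#' knowledge graph (about 400 nodes) that exercises every pipeline stage in
#' well under a minute, with the same planted-effect structure as the
#' full-size defaults.
#'
#' @param seed Global seed.
#' @return A `pipeline_config`.
#' @export
demo_pipeline_config <- function(seed = 1L) {
  pipeline_config(
    cohort = cohort_config(n_subjects = 200L, n_proteins = 40L,
                           n_metabolites = 60L, n_clinical = 12L,
                           missing_rates = c(clinical = 0.005,
                                             protein = 0.002,
                                             metabolite = 0.03),
                           seed = seed),
    preprocessing = list(impute_max_iter = 2L, impute_n_trees = 15L),
    targets = c("HbA1c", "insulin"),
    horizons = "6mo",
    feature_sets = c("baseline", "demographics_only", "proteomics"),
    kg = kg_config(n_proteins = 150L, n_genes = 80L, n_compounds = 120L,
                   n_diseases = 50L, seed_proteins = NULL, n_seeds = 8L,
                   n_hidden = 4L),
    interpret = list(target = "HbA1c", horizon = "6mo", top_k = 8L),
    seed = seed)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]: top-level keys
#' `cohort`, `preprocessing`, `targets`, `horizons`, `mode`, `feature_sets`,
#' `n_folds`, `kg` (or `kg_path`), `interpret`, `seed`; `cohort` and `kg`
#' are argument maps for [cohort_config()] and [kg_config()]. Mappings such
#' as `outlier_limits`, `missing_rates` and `effect_map` entries become
#' named vectors.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) {
    for (f in c("missing_rates", "baseline_params"))
      if (!is.null(y$cohort[[f]]) && f == "missing_rates")
        y$cohort[[f]] <- unlist(y$cohort[[f]])
    if (!is.null(y$cohort$effect_map))
      y$cohort$effect_map <- lapply(y$cohort$effect_map, unlist)
    if (!is.null(y$cohort$baseline_params))
      y$cohort$baseline_params <- lapply(y$cohort$baseline_params, unlist)
  }
  if (!is.null(y$preprocessing$outlier_limits))
    y$preprocessing$outlier_limits <- unlist(y$preprocessing$outlier_limits)
  args <- y[intersect(names(y),
                      c("cohort", "preprocessing", "targets", "horizons",
                        "mode", "feature_sets", "n_folds", "kg", "kg_path",
                        "interpret", "seed"))]
  do.call(pipeline_config, args)
}

write_json_artifact <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

#' Run the full simulate / preprocess / train / interpret pipeline
#'
#' Executes all stages in order, each reading only the previous stage's
#' serialized artifacts, and writes a machine-readable manifest with an MD5
#' checksum per output file — two runs of the same configuration produce
#' bit-identical artifacts. Stage boundaries are plain files, so any stage's
#' input can be replaced by real data (a measured cohort CSV, a curated
#' edge-list TSV) without code changes.
#'
#' Stages and artifacts: `simulate` (cohort.csv, cohort_registry.tsv,
#' truth.json), `preprocess` (cohort_processed.csv, filter_report.json),
#' `deltas` (deltas.tsv), `train` (scores.tsv, model_report.json,
#' predictor_rankings.tsv), `kg` (kg_edges.tsv, kg_planted.json), and
#' `interpret` (steiner_tree.tsv, steiner_expanded.tsv, pagerank_top.tsv,
#' recovery.json), plus manifest.json.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly; on failure the error names the failing
#'   stage and partial outputs are retained.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, files) {
    manifest$stages[[length(manifest$stages) + 1]] <<- list(
      stage = stage,
      outputs = lapply(files, function(f) list(
        file = basename(f),
        md5 = unname(tools::md5sum(f)))))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  pth <- function(f) file.path(out_dir, f)

  # -- simulate ------------------------------------------------------------
  run_stage("simulate", function() {
    gen <- generate_cohort(config$cohort)
    cohort <- inject_missingness(gen$cohort, config$cohort)
    write_cohort(cohort, pth("cohort.csv"))
    write_json_artifact(list(
      effects = lapply(gen$truth$effects, as.list),
      insulin_reversion_rate = gen$truth$insulin_reversion_rate),
      pth("truth.json"))
    note("simulate", c(pth("cohort.csv"), pth("cohort_registry.tsv"),
                       pth("truth.json")))
  })

  # -- preprocess ----------------------------------------------------------
  run_stage("preprocess", function() {
    cohort <- read_cohort(pth("cohort.csv"))
    pp <- config$preprocessing
    res <- run_preprocessing(cohort,
      missing_feature_threshold = pp$missing_feature_threshold,
      missing_subject_threshold = pp$missing_subject_threshold,
      outlier_limits = pp$outlier_limits,
      impute_max_iter = pp$impute_max_iter,
      impute_n_trees = pp$impute_n_trees,
      seed = config$seed + 11L)
    write_cohort(res$cohort, pth("cohort_processed.csv"))
    write_filter_report(res$report, pth("filter_report.json"))
    note("preprocess", c(pth("cohort_processed.csv"),
                         pth("cohort_processed_registry.tsv"),
                         pth("filter_report.json")))
  })

  # -- deltas --------------------------------------------------------------
  run_stage("deltas", function() {
    cohort <- read_cohort(pth("cohort_processed.csv"))
    deltas <- binarize_deltas(compute_deltas(cohort,
                                             targets = config$targets))
    write_deltas(deltas, pth("deltas.tsv"))
    note("deltas", pth("deltas.tsv"))
  })

  # -- train ---------------------------------------------------------------
  run_stage("train", function() {
    cohort <- read_cohort(pth("cohort_processed.csv"))
    deltas <- utils::read.delim(pth("deltas.tsv"),
                                stringsAsFactors = FALSE)
    class(deltas) <- c("delta_table", "data.frame")
    all_scores <- list()
    report_json <- list()
    rankings <- list()
    for (tg in config$targets) for (h in config$horizons) {
      sets <- build_feature_sets(cohort$features, tg)
      if (!is.null(config$feature_sets))
        sets <- sets[config$feature_sets]
      ev <- evaluate_feature_sets(cohort, deltas, tg, horizon = h,
                                  feature_sets = sets, mode = config$mode,
                                  n_folds = config$n_folds,
                                  seed = config$seed + 23L)
      sc <- ev$scores
      sc$target <- tg; sc$horizon <- h
      all_scores[[paste(tg, h)]] <- sc
      for (fs in names(ev$reports)) {
        r <- ev$reports[[fs]]
        report_json[[paste(tg, h, fs, sep = "|")]] <- list(
          target = tg, horizon = h, feature_set = fs, mode = config$mode,
          fold_scores = r$scores, score_mean = r$score_mean,
          score_sd = r$score_sd)
      }
      widest <- names(sets)[which.max(vapply(sets, length, 0L))]
      rk <- suppressWarnings(
        rank_features(ev$reports[[widest]], k = config$interpret$top_k,
                      restrict_kind = "protein"))
      if (nrow(rk)) {
        rk$target <- tg; rk$horizon <- h; rk$feature_set <- widest
        rankings[[paste(tg, h)]] <- rk
      }
    }
    utils::write.table(
      format_numeric_df(do.call(rbind, c(all_scores,
                                         list(make.row.names = FALSE)))),
      pth("scores.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    write_json_artifact(report_json, pth("model_report.json"))
    utils::write.table(
      format_numeric_df(do.call(rbind, c(rankings,
                                         list(make.row.names = FALSE)))),
      pth("predictor_rankings.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    note("train", c(pth("scores.tsv"), pth("model_report.json"),
                    pth("predictor_rankings.tsv")))
  })

  # -- kg ------------------------------------------------------------------
  run_stage("kg", function() {
    if (!is.null(config$kg_path)) {
      g <- load_graph(config$kg_path)
      planted <- list(disease_node = config$kg$disease_node)
      write_graph_tsv(g, pth("kg_edges.tsv"))
      write_json_artifact(planted, pth("kg_planted.json"))
    } else {
      gen <- generate_synthetic_kg(config$kg)
      write_graph_tsv(gen$graph, pth("kg_edges.tsv"))
      write_json_artifact(gen$planted, pth("kg_planted.json"))
    }
    note("kg", c(pth("kg_edges.tsv"), pth("kg_planted.json")))
  })

  # -- interpret -----------------------------------------------------------
  run_stage("interpret", function() {
    g <- load_graph(pth("kg_edges.tsv"))
    planted <- jsonlite::read_json(pth("kg_planted.json"),
                                   simplifyVector = TRUE)
    rankings <- utils::read.delim(pth("predictor_rankings.tsv"),
                                  stringsAsFactors = FALSE)
    it <- config$interpret
    rk <- rankings[rankings$target == it$target &
                     rankings$horizon == it$horizon, , drop = FALSE]
    seeds0 <- utils::head(rk$feature, it$top_k)
    seeds <- intersect(seeds0, g$nodes$id)
    if (!length(seeds))
      stop("none of the top predictors map to graph nodes")
    st <- suppressWarnings(
      steiner_takahashi(g, c(seeds, planted$disease_node)))
    utils::write.table(st$tree_edges, pth("steiner_tree.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(st$expanded_edges, pth("steiner_expanded.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    pr <- topic_pagerank(g, seeds)
    top <- prioritize_nodes(pr, node_type = "Protein",
                            exclude_seeds = TRUE, k = 20L)
    utils::write.table(format_numeric_df(top), pth("pagerank_top.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    rec <- if (!is.null(planted$hidden_proteins))
      recovery_metrics(top, planted$hidden_proteins) else
      list(note = "no planted truth available")
    write_json_artifact(rec, pth("recovery.json"))
    note("interpret", c(pth("steiner_tree.tsv"), pth("steiner_expanded.tsv"),
                        pth("pagerank_top.tsv"), pth("recovery.json")))
  })

  write_json_artifact(manifest, pth("manifest.json"))
  invisible(out_dir)
}

#' Summarize a pipeline run directory
#'
#' Reads the manifest and artifacts of a [run_pipeline()] output directory
#' and prints a human-readable report: filtering counts, the per-task
#' feature-set score table, the top predictor table with cross-fold
#' coefficient ranges, the PageRank-prioritized proteins, and — when the
#' run had planted truth — recovery metrics recomputed from the artifacts.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return The report, as a character vector of lines, invisibly (also
#'   printed).
#' @export
summarize_run <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path))
    stop("no manifest.json in ", run_dir, "; not a pipeline run directory")
  manifest <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  listed <- unlist(lapply(manifest$stages, function(s)
    vapply(s$outputs, `[[`, "", "file")))
  missing <- listed[!file.exists(file.path(run_dir, listed))]
  if (length(missing))
    stop("manifest lists missing artifact(s): ",
         paste(missing, collapse = ", "))
  stages <- vapply(manifest$stages, `[[`, "", "stage")
  out <- c(sprintf("Pipeline run: %s (seed %s)", run_dir, manifest$seed),
           sprintf("Stages completed: %s", paste(stages, collapse = ", ")))

  if (file.exists(file.path(run_dir, "filter_report.json"))) {
    fr <- jsonlite::read_json(file.path(run_dir, "filter_report.json"),
                              simplifyVector = TRUE)
    out <- c(out, "", "Filtering cascade:")
    for (i in seq_len(nrow(fr)))
      out <- c(out, sprintf("  %-28s -%d subjects, -%d features",
                            fr$step[i], length(fr$subjects_removed[[i]]),
                            length(fr$features_removed[[i]])))
  }
  if (file.exists(file.path(run_dir, "scores.tsv"))) {
    sc <- utils::read.delim(file.path(run_dir, "scores.tsv"),
                            stringsAsFactors = FALSE)
    agg <- stats::aggregate(score ~ target + horizon + feature_set, sc,
                            function(s) mean(s, na.rm = TRUE))
    out <- c(out, "", "Mean held-out score by task and feature set:")
    for (i in order(agg$target, agg$horizon, -agg$score))
      out <- c(out, sprintf("  %-8s %-4s %-18s %.3f", agg$target[i],
                            agg$horizon[i], agg$feature_set[i],
                            agg$score[i]))
  }
  if (file.exists(file.path(run_dir, "predictor_rankings.tsv"))) {
    rk <- utils::read.delim(file.path(run_dir, "predictor_rankings.tsv"),
                            stringsAsFactors = FALSE)
    out <- c(out, "", "Top-weighted protein predictors (coef range over folds):")
    for (i in seq_len(nrow(rk)))
      out <- c(out, sprintf("  %-8s %-4s #%d %-10s |coef|=%.3f [%.3f, %.3f] (%d folds)",
                            rk$target[i], rk$horizon[i], rk$rank[i],
                            rk$feature[i], rk$mean_abs_coef[i],
                            rk$coef_min[i], rk$coef_max[i],
                            rk$nonzero_folds[i]))
  }
  if (file.exists(file.path(run_dir, "pagerank_top.tsv"))) {
    pr <- utils::read.delim(file.path(run_dir, "pagerank_top.tsv"),
                            stringsAsFactors = FALSE)
    out <- c(out, "", "Topic-PageRank prioritized proteins (non-seed):")
    for (i in seq_len(min(10, nrow(pr))))
      out <- c(out, sprintf("  #%-3d %-10s score=%.5f seed_neighbors=%d",
                            pr$rank[i], pr$node[i], pr$score[i],
                            pr$seed_adjacency[i]))
    if (file.exists(file.path(run_dir, "recovery.json"))) {
      rec <- jsonlite::read_json(file.path(run_dir, "recovery.json"),
                                 simplifyVector = TRUE)
      if (!is.null(rec$recall)) {
        planted <- jsonlite::read_json(file.path(run_dir, "kg_planted.json"),
                                       simplifyVector = TRUE)
        check <- recovery_metrics(pr, planted$hidden_proteins)
        out <- c(out, "", sprintf(
          "Hidden-protein recovery: %s; MRR=%.3f (recomputed: MRR=%.3f)",
          paste(names(rec$recall), sprintf("%.2f", unlist(rec$recall)),
                sep = "=", collapse = ", "),
          rec$mrr, check$mrr))
      }
    }
  } else {
    out <- c(out, "", "Note: no knowledge-graph interpretation stage in this run.")
  }
  cat(out, sep = "\n")
  invisible(out)
}
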