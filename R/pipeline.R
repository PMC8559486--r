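#' Pipeline run configuration
#'
#' Everything one end-to-end run needs. Every stage derives its own
#' seed deterministically from the global seed plus a stage tag, so a
#' stage rerun in isolation reproduces its in-pipeline draws.
#' @param out_dir output directory for all tables and the manifest.
#' @param sim a [simulation_config()] (its seed is overridden by the
#'   global seed).
#' @param mean_threshold feature-space mean-connectivity threshold.
#' @param spls an [spls_config()].
#' @param boot a [bootstrap_config()].
#' @param train_fraction train share of the cohort split.
#' @param nested_sizes nested model sizes (`NULL` = all/10/2).
#' @param linkage,n_clusters feature-clustering settings.
#' @param seed global integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       sim = benchmark_config(seed),
                       mean_threshold = 1,
                       spls = spls_config(seed = seed),
                       boot = bootstrap_config(n_boot = 500L, seed = seed),
                       train_fraction = 0.7,
                       nested_sizes = NULL,
                       linkage = "average", n_clusters = 4L,
                       seed = 1L) {
  structure(list(out_dir = out_dir, sim = sim,
                 mean_threshold = mean_threshold, spls = spls, boot = boot,
                 train_fraction = train_fraction, nested_sizes = nested_sizes,
                 linkage = linkage, n_clusters = n_clusters,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full lesion-symptom mapping pipeline
#'
#' Simulate (or accept) a cohort, build and threshold the edge feature
#' space, score and covariate-adjust behaviour, split the cohort, tune
#' keepX, run bootstrap-VIP stability selection, evaluate nested models
#' on the held-out test set, refit on the full cohort, cluster the
#' candidate features, and summarise connectivity by severity group.
#' All tables are written under `config$out_dir` together with a
#' `manifest.json` recording parameters, seeds and output digests.
#' @param config a [run_config()].
#' @param cohort optional pre-built `cohort_bundle`; by default the
#'   configured simulation is run.
#' @return list of class `run_result` with each stage's object plus the
#'   manifest.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name) stage_seed(config$seed, name)
  manifest <- list(seed = config$seed, stages = list())
  note <- function(name, ...) {
    manifest$stages[[name]] <<- list(seed = stage(name), ...)
  }

  # --- simulate -------------------------------------------------------
  if (is.null(cohort)) {
    sim <- config$sim; sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
    note("cohort", n_subjects = sim$n_subjects,
         n_regions = length(sim$atlas$region_ids),
         planted_edges = sim$planted_edges)
  } else {
    note("cohort", n_subjects = length(cohort$matrices), source = "supplied")
  }

  # --- features -------------------------------------------------------
  fm_full <- build_feature_matrix(cohort$matrices)
  forced <- slf_edge_set(cohort$atlas)
  fm <- threshold_and_force(fm_full, config$mean_threshold, forced)
  write_feature_matrix(fm, config$out_dir)
  note("features", universe = ncol(fm_full$values), kept = ncol(fm$values),
       forced = length(forced), mean_threshold = config$mean_threshold)

  # --- behaviour ------------------------------------------------------
  beh <- score_behavior(cohort)
  utils::write.table(
    data.frame(subject_id = names(beh$composite),
               composite = as.numeric(beh$composite),
               adjusted = as.numeric(beh$adjusted)),
    file.path(config$out_dir, "behavior.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  note("behavior", intertest_r = beh$intertest_r,
       r_squared = beh$model$r_squared, f = beh$model$f_statistic)

  X <- fm$values
  y <- as.numeric(beh$adjusted)
  n <- nrow(X)

  # --- split + tune ---------------------------------------------------
  split <- split_cohort(n, config$train_fraction, seed = config$seed)
  Xtr <- X[split$train_indices, , drop = FALSE]
  ytr <- y[split$train_indices]
  tuning <- tune_keepX(Xtr, ytr, config$spls)
  note("tune", keepX = tuning$keepX)

  # --- bootstrap-VIP selection ---------------------------------------
  bv <- bootstrap_vip(Xtr, ytr, config$spls, config$boot, keepX = tuning$keepX)
  cand <- select_candidates(bv, config$boot)
  utils::write.table(cbind(bv$table,
                           selected = bv$table$edge %in% cand$edge),
                     file.path(config$out_dir, "bootstrap_vip.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("bootstrap", n_boot = config$boot$n_boot, n_candidates = nrow(cand),
       n_redraws = bv$n_redraws)

  # --- nested evaluation ---------------------------------------------
  eval_res <- NULL
  refit <- NULL
  clus <- NULL
  if (nrow(cand) >= 1) {
    subsets <- nested_models(cand, config$nested_sizes)
    eval_res <- evaluate_nested_models(X, y, split, subsets,
                                       config$spls$n_components)
    utils::write.table(eval_res$table,
                       file.path(config$out_dir, "nested_models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tier_sizes <- vapply(subsets, length, 1L)
    refit_subset <- subsets[[which(tier_sizes == min(10L, max(tier_sizes)))[1]]]
    refit <- final_refit_report(X, y, refit_subset,
                                config$spls$n_components)
    utils::write.table(refit, file.path(config$out_dir, "final_refit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(cand) >= 2) {
      clus <- cluster_features(X[, cand$edge, drop = FALSE],
                               config$linkage, config$n_clusters)
      utils::write.table(
        data.frame(edge = names(clus$labels), cluster = clus$labels),
        file.path(config$out_dir, "feature_clusters.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    # severity grouping for the connectivity barplot table
    sev <- cut(beh$composite, stats::quantile(beh$composite, c(0, 1/3, 2/3, 1)),
               labels = c("severe", "moderate", "mild"), include.lowest = TRUE)
    gs <- group_summary(X, as.character(sev), cand$edge,
                        group_order = c("mild", "moderate", "severe"))
    utils::write.table(gs, file.path(config$out_dir, "group_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  note("evaluate",
       models = if (is.null(eval_res)) character(0) else eval_res$table$model)

  files <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$outputs <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(cohort = cohort, features = fm, behavior = beh,
                 split = split, tuning = tuning, bootstrap = bv,
                 candidates = cand, evaluation = eval_res, refit = refit,
                 clusters = clus, manifest = manifest),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("run_result: %d subjects, %d edges kept, keepX = %d, %d candidate edge(s)\n",
              nrow(x$features$values), ncol(x$features$values),
              x$tuning$keepX, nrow(x$candidates)))
  if (!is.null(x$evaluation)) print(x$evaluation$table, row.names = FALSE)
  invisible(x)
}
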