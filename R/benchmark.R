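#' Run the reference benchmark experiment end to end
#'
#' One complete replicate of the package's planted-edge recovery
#' experiment on the [benchmark_config()] cohort (70 subjects, 300
#' candidate edges, 8 planted edges, planted-signal R-squared 0.6):
#' simulate, build the edge feature space, score and adjust behaviour,
#' split 70/30, run bootstrap-VIP stability selection on the training
#' set, select candidates at the conventional thresholds (mean VIP > 1,
#' frequency > 0.5), and evaluate the 10-feature nested model (or all
#' candidates when fewer than 10) on the held-out test set.
#'
#' The bootstrap replicates the whole tuning procedure inside each
#' resample (`retune_each_iteration = TRUE`), with a light
#' cross-validation (3 repeats of 5 folds) per resample; this mirrors
#' the replicated-tuning protocol and lets the effective sparsity adapt
#' to each resample.
#'
#' @param seed integer replicate seed; drives the cohort, the split and
#'   the bootstrap.
#' @param n_boot bootstrap iterations (default 300).
#' @param permute permute the adjusted outcome before analysis (the
#'   null-calibration mode: breaks every X-y association while keeping
#'   both marginals).
#' @param cv_repeats CV repeats for the per-resample tuning.
#' @param retune replicate tuning inside each resample (default TRUE).
#' @return list: `n_candidates`, `true_positives`, `false_positives`,
#'   `candidates` (the `candidate_set`), `r_test`, `p_test` (10-feature
#'   nested model; NA when fewer than 2 candidates), `planted_edges`,
#'   `keepX` (tuned once; NULL in retune mode), `seed`.
#' @export
run_benchmark <- function(seed, n_boot = 300L, permute = FALSE,
                          cv_repeats = 3L, retune = TRUE) {
  cfg <- benchmark_config(seed = seed)
  cohort <- simulate_cohort(cfg)
  beh <- score_behavior(cohort)
  X <- build_feature_matrix(cohort$matrices)$values
  y <- as.numeric(beh$adjusted)
  if (permute) {
    set.seed(stage_seed(seed, "null_permutation"))
    y <- sample(y)
  }
  split <- split_cohort(nrow(X), 0.7, seed = seed)
  Xtr <- X[split$train_indices, , drop = FALSE]
  ytr <- y[split$train_indices]
  scfg <- spls_config(cv_repeats = cv_repeats, seed = seed)
  bcfg <- bootstrap_config(n_boot = n_boot, retune_each_iteration = retune,
                           seed = seed)
  bv <- bootstrap_vip(Xtr, ytr, scfg, bcfg)
  cand <- select_candidates(bv, bcfg)
  tp <- sum(cand$edge %in% cfg$planted_edges)
  r_test <- p_test <- NA_real_
  if (nrow(cand) >= 2) {
    subsets <- nested_models(cand)
    sizes <- vapply(subsets, length, 1L)
    model10 <- subsets[[which(sizes == min(10L, max(sizes)))[1]]]
    ev <- fit_and_evaluate(X, y, split, model10)
    r_test <- ev$r_test
    p_test <- ev$p_test
  }
  list(n_candidates = nrow(cand), true_positives = tp,
       false_positives = nrow(cand) - tp, candidates = cand,
       r_test = r_test, p_test = p_test,
       planted_edges = cfg$planted_edges, keepX = bv$keepX, seed = seed)
}
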