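#' Random train/test split
#'
#' Uniformly random partition of `n` subjects with
#' `round(train_fraction * n)` training subjects (no stratification).
#' @param n cohort size (>= 4).
#' @param train_fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return list of class `split_spec`: `train_indices`, `test_indices`,
#'   `train_fraction`, `seed`.
#' @export
split_cohort <- function(n, train_fraction = 0.7, seed = 1L) {
  if (n < 4) stopf("need at least 4 subjects")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  n_train <- as.integer(round(train_fraction * n))
  set.seed(stage_seed(seed, "split"))
  tr <- sort(sample.int(n, n_train))
  structure(list(train_indices = tr, test_indices = setdiff(seq_len(n), tr),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Nested feature subsets from a ranked candidate set
#'
#' Prefixes of the mean-VIP-ranked candidate list at the requested
#' sizes (default: all candidates, the top 10, and the top 2). Sizes
#' exceeding the candidate count are clipped with a warning.
#' @param candidates a `candidate_set` (or data.frame with `edge`
#'   ranked best-first).
#' @param sizes nonincreasing model sizes.
#' @return named list of character vectors of edge labels.
#' @export
nested_models <- function(candidates, sizes = NULL) {
  edges <- candidates$edge
  if (!length(edges)) stopf("empty candidate set")
  if (is.null(sizes)) sizes <- unique(pmin(c(length(edges), 10L, 2L),
                                           length(edges)))
  if (is.unsorted(rev(sizes))) stopf("sizes must be nonincreasing")
  if (any(sizes > length(edges))) {
    warning(sprintf("clipping model sizes to the %d available candidates",
                    length(edges)))
    sizes <- unique(pmin(sizes, length(edges)))
  }
  stats::setNames(lapply(sizes, function(s) edges[seq_len(s)]),
                  paste0("top", sizes))
}

#' One-tailed Pearson correlation test (positive direction)
#'
#' Pearson r with the one-tailed p-value for positive association via
#' the t transform `t = r * sqrt((n-2)/(1-r^2))` against Student's t
#' with n-2 degrees of freedom. The direction is fixed a priori:
#' greater connectivity predicting better performance.
#' @param a,b numeric vectors, length >= 3, nonzero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_one_tailed <- function(a, b) {
  n <- length(a)
  if (n < 3 || length(b) != n) stopf("need two equal-length vectors, n >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stopf("zero-variance input")
  r <- stats::cor(a, b)
  p <- if (r >= 1) 0 else if (r <= -1) 1 else
    stats::pt(r * sqrt((n - 2) / (1 - r^2)), n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

#' Choose the number of PLS components by repeated cross-validation
#'
#' Dense PLS1 fits with H = 1..`h_max`, scored by held-out mean
#' absolute error over repeated k-fold CV (seeded folds shared across
#' H). The smallest H within one standard error of the minimising H is
#' returned — small feature subsets rarely support many components.
#' @param X,y training data (X restricted to the candidate subset).
#' @param h_max largest H considered.
#' @param cv_folds,cv_repeats CV shape.
#' @param seed fold-assignment seed.
#' @return chosen H (integer).
#' @export
choose_n_components <- function(X, y, h_max = 5L, cv_folds = 5L,
                                cv_repeats = 50L, seed = 1L) {
  n <- nrow(X)
  h_max <- max(1L, min(h_max, ncol(X), n - 2L))
  if (h_max == 1L) return(1L)
  set.seed(stage_seed(seed, "choose_h"))
  mae <- matrix(NA_real_, h_max, cv_repeats * cv_folds)
  col <- 0L
  for (r in seq_len(cv_repeats)) {
    folds <- sample(rep(seq_len(cv_folds), length.out = n))
    for (f in seq_len(cv_folds)) {
      col <- col + 1L
      trr <- folds != f
      fit <- fit_spls(X[trr, , drop = FALSE], y[trr], keepX = ncol(X),
                      n_components = h_max, allow_constant = TRUE)
      # predictions for every truncation of the component sequence
      Xs <- sweep(sweep(X[!trr, , drop = FALSE], 2, fit$x_center),
                  2, fit$x_scale, "/")
      for (h in seq_len(min(h_max, fit$n_components_fitted))) {
        Wh <- fit$W[, 1:h, drop = FALSE]
        Ph <- fit$P[, 1:h, drop = FALSE]
        bh <- drop(Wh %*% solve(crossprod(Ph, Wh), fit$q[1:h]))
        pred <- fit$y_center + fit$y_scale * drop(Xs %*% bh)
        mae[h, col] <- mean(abs(pred - y[!trr]))
      }
    }
  }
  ok <- rowSums(!is.na(mae)) > 0
  mean_mae <- rowMeans(mae, na.rm = TRUE)
  se <- apply(mae, 1, stats::sd, na.rm = TRUE) / sqrt(ncol(mae))
  i_min <- which.min(mean_mae[ok])
  as.integer(which(mean_mae <= mean_mae[i_min] + se[i_min])[1])
}

#' Train and evaluate one nested model on a held-out split
#'
#' Fits a dense PLS model (keepX equal to the subset size) on the
#' training rows restricted to `subset`, then scores both fitted values
#' on the training set and predictions on the test set by one-tailed
#' Pearson correlation with the actual outcome. The number of
#' components is chosen by repeated CV on the training set, capped at
#' `min(n_components, |subset|, n_train - 2)`.
#' @param X full subjects-by-edges matrix with edge-label columns.
#' @param y full outcome vector (the adjusted composite).
#' @param split a `split_spec`.
#' @param subset nonempty character vector of edge labels.
#' @param n_components largest H considered.
#' @param choose_h select H by repeated CV (default) rather than using
#'   the cap directly.
#' @return list: `subset`, `n_components`, `r_train`, `p_train`,
#'   `r_test`, `p_test`, `fitted_train`, `pred_test`, `model`.
#' @export
fit_and_evaluate <- function(X, y, split, subset, n_components = 5L,
                             choose_h = TRUE) {
  if (!length(subset)) stopf("feature subset is empty")
  miss <- setdiff(subset, colnames(X))
  if (length(miss)) stopf("unknown features: %s", paste(miss, collapse = ", "))
  tr <- split$train_indices; te <- split$test_indices
  H <- min(n_components, length(subset), length(tr) - 2L)
  if (choose_h && H > 1L)
    H <- choose_n_components(X[tr, subset, drop = FALSE], y[tr], h_max = H,
                             seed = split$seed %||% 1L)
  fit <- fit_spls(X[tr, subset, drop = FALSE], y[tr],
                  keepX = length(subset), n_components = H)
  fitted_train <- fit$fitted_values
  pred_test <- predict(fit, X[te, subset, drop = FALSE])
  ct_tr <- pearson_one_tailed(fitted_train, y[tr])
  ct_te <- pearson_one_tailed(pred_test, y[te])
  list(subset = subset, n_components = fit$n_components_fitted,
       r_train = ct_tr$r, p_train = ct_tr$p,
       r_test = ct_te$r, p_test = ct_te$p,
       fitted_train = fitted_train, pred_test = pred_test, model = fit)
}

#' Evaluate a family of nested models
#'
#' Runs [fit_and_evaluate()] for each subset and tabulates train/test
#' correlations and one-tailed p-values.
#' @param X,y,split as in [fit_and_evaluate()].
#' @param subsets named list of edge-label vectors (see [nested_models()]).
#' @param n_components requested H per model.
#' @return list with `table` (data.frame: model, n_features, r_train,
#'   p_train, r_test, p_test) and `fits` (per-model detail).
#' @export
evaluate_nested_models <- function(X, y, split, subsets, n_components = 5L) {
  fits <- lapply(subsets, function(s)
    fit_and_evaluate(X, y, split, s, n_components))
  tab <- data.frame(
    model = names(subsets),
    n_features = vapply(subsets, length, 1L),
    r_train = vapply(fits, `[[`, 1, "r_train"),
    p_train = vapply(fits, `[[`, 1, "p_train"),
    r_test = vapply(fits, `[[`, 1, "r_test"),
    p_test = vapply(fits, `[[`, 1, "p_test"),
    row.names = NULL)
  list(table = tab, fits = fits)
}

#' Full-cohort refit report
#'
#' Dense PLS on all subjects restricted to `subset`; reports, per
#' feature and ranked by descending component-1 weight: the component-1
#' unit-norm weight (labelled "loading"), the VIP over the fitted
#' components, and raw-scale descriptive statistics (mean, SD, range).
#' @param X_full,y_full full-cohort data.
#' @param subset edge labels to refit on.
#' @param n_components requested H, capped as in [fit_and_evaluate()].
#' @return data.frame: edge, loading, vip, mean, sd, min, max.
#' @export
final_refit_report <- function(X_full, y_full, subset, n_components = 5L) {
  if (!length(subset)) stopf("feature subset is empty")
  H <- min(n_components, length(subset), nrow(X_full) - 2L)
  fit <- fit_spls(X_full[, subset, drop = FALSE], y_full,
                  keepX = length(subset), n_components = H)
  vip <- compute_vip(fit)$vip
  Xs <- X_full[, subset, drop = FALSE]
  out <- data.frame(edge = subset,
                    loading = fit$W[, 1],
                    vip = as.numeric(vip),
                    mean = colMeans(Xs),
                    sd = apply(Xs, 2, stats::sd),
                    min = apply(Xs, 2, min),
                    max = apply(Xs, 2, max),
                    row.names = NULL)
  out[order(-out$loading), , drop = FALSE]
}

#' Hierarchically cluster candidate features by correlation
#'
#' Pairwise Pearson correlations across subjects; distance `1 - r`;
#' agglomerative clustering with the chosen linkage, labels from a cut
#' at `n_clusters`.
#' @param X_subset subjects x features matrix (>= 2 features, none
#'   constant).
#' @param linkage hclust method (default "average").
#' @param n_clusters where to cut the dendrogram (default 4).
#' @return list of class `cluster_report`: `correlation` matrix,
#'   `hclust`, `labels`.
#' @export
cluster_features <- function(X_subset, linkage = "average", n_clusters = 4L) {
  if (ncol(X_subset) < 2) stopf("need at least 2 features")
  sds <- apply(X_subset, 2, stats::sd)
  if (any(sds == 0)) stopf("zero-variance feature(s): %s",
                           paste(colnames(X_subset)[sds == 0], collapse = ", "))
  cm <- stats::cor(X_subset)
  hc <- stats::hclust(stats::as.dist(1 - cm), method = linkage)
  k <- min(n_clusters, ncol(X_subset))
  structure(list(correlation = cm, hclust = hc,
                 labels = stats::cutree(hc, k = k)),
            class = "cluster_report")
}

#' Group-wise feature summaries
#'
#' Mean and standard error of each feature within each subject group
#' (e.g. aphasia subtype), ordered by the supplied group ordering.
#' @param X subjects x features matrix.
#' @param group_labels one label per subject.
#' @param subset feature columns to summarise.
#' @param group_order optional explicit ordering of group names.
#' @return data.frame: group, edge, mean, se, n.
#' @export
group_summary <- function(X, group_labels, subset = colnames(X),
                          group_order = unique(group_labels)) {
  if (length(group_labels) != nrow(X)) stopf("one group label per subject")
  unknown <- setdiff(group_order, unique(group_labels))
  if (length(unknown)) stopf("unknown group label(s): %s",
                             paste(unknown, collapse = ", "))
  out <- do.call(rbind, lapply(group_order, function(g) {
    rows <- which(group_labels == g)
    Xi <- X[rows, subset, drop = FALSE]
    data.frame(group = g, edge = subset,
               mean = colMeans(Xi),
               se = apply(Xi, 2, stats::sd) / sqrt(length(rows)),
               n = length(rows), row.names = NULL)
  }))
  out
}
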