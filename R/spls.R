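#' sPLS configuration
#'
#' Hyperparameters for sparse PLS1 fitting and tuning. Defaults follow
#' the package's standard protocol: five latent components, a shared
#' sparsity level `keepX` across components tuned on a grid with
#' maximum 100 by repeated 5-fold cross-validation (50 repeats) under
#' mean absolute error.
#' @param n_components number of latent components H (default 5).
#' @param keepX maximum nonzero weights per component (default 100;
#'   capped at the number of features at fit time).
#' @param keepX_grid ascending candidate grid for tuning.
#' @param cv_folds,cv_repeats repeated k-fold CV shape (5, 50).
#' @param seed integer seed for fold assignment.
#' @return list of class `spls_config`.
#' @export
spls_config <- function(n_components = 5L, keepX = 100L,
                        keepX_grid = c(5L, 10L, 20L, 35L, 50L, 75L, 100L),
                        cv_folds = 5L, cv_repeats = 50L, seed = 1L) {
  if (n_components < 1) stopf("n_components must be >= 1")
  if (cv_folds < 2) stopf("cv_folds must be >= 2")
  if (any(keepX_grid < 1)) stopf("keepX_grid values must be >= 1")
  structure(list(n_components = as.integer(n_components),
                 keepX = as.integer(keepX),
                 keepX_grid = sort(unique(as.integer(keepX_grid))),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 seed = as.integer(seed)),
            class = "spls_config")
}

#' Centre and scale a feature matrix and outcome
#'
#' Columns of `X` are centred to mean zero and scaled to unit standard
#' deviation (denominator n-1); `y` likewise. The parameters are
#' returned for the inverse transform. Zero-variance columns are an
#' error unless `allow_constant = TRUE`, in which case they are centred
#' and given scale 1 (they then carry no weight in any fit — their
#' covariance with any outcome is exactly zero).
#' @param X numeric matrix (subjects x features).
#' @param y numeric outcome vector.
#' @param allow_constant tolerate zero-variance columns.
#' @return list with `X`, `y`, `x_center`, `x_scale`, `y_center`, `y_scale`.
#' @export
standardize <- function(X, y, allow_constant = FALSE) {
  n <- nrow(X)
  xc <- colMeans(X)
  xs <- sqrt(pmax(colSums(X^2) - n * xc^2, 0) / (n - 1))
  zero <- xs < 1e-12
  if (any(zero)) {
    if (!allow_constant)
      stopf("zero-variance feature column(s): %s",
            paste(utils::head(colnames(X)[zero] %||% which(zero), 5),
                  collapse = ", "))
    xs[zero] <- 1
  }
  ys <- stats::sd(y)
  if (ys < .Machine$double.eps) stopf("outcome has zero variance")
  list(X = sweep(sweep(X, 2, xc), 2, xs, "/"),
       y = (y - mean(y)) / ys,
       x_center = xc, x_scale = xs, y_center = mean(y), y_scale = ys)
}

#' Soft-thresholded unit-norm weight vector
#'
#' The sparsity primitive of sPLS: with `lambda` the (keepX+1)-th
#' largest absolute entry of `z` (0 when `keepX = length(z)`), returns
#' `sign(z) * max(|z| - lambda, 0)` normalised to unit Euclidean norm.
#' Entries tied with the cutoff magnitude shrink to zero together, so
#' fewer than `keepX` nonzeros are possible under ties.
#' @param z nonzero numeric vector (typically `X'y`).
#' @param keepX target support size, `1 <= keepX <= length(z)`.
#' @return unit-norm vector with at most `keepX` nonzeros.
#' @export
sparse_weight <- function(z, keepX) {
  p <- length(z)
  if (keepX < 1 || keepX > p) stopf("keepX must be in [1, %d]", p)
  az <- abs(z)
  if (all(az == 0)) stopf("cannot sparsify an all-zero vector")
  lambda <- if (keepX == p) 0 else sort(az, decreasing = TRUE)[keepX + 1L]
  w <- sign(z) * pmax(az - lambda, 0)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0)
    stopf("all entries tied at the sparsity cutoff; no weight survives")
  w / nrm
}

# NIPALS-style sequential extraction on already-standardised data.
# Returns weights, loadings, scores, y-loadings, score sums of squares
# and the standardised-scale coefficient vector.
spls_nipals <- function(Xh, yh, keepX, H) {
  n <- nrow(Xh); p <- ncol(Xh)
  W <- matrix(0, p, H); P <- matrix(0, p, H)
  Tm <- matrix(0, n, H); q <- numeric(H); tt <- numeric(H)
  early <- FALSE
  h_done <- 0L
  for (h in seq_len(H)) {
    z <- drop(crossprod(Xh, yh))
    if (all(abs(z) < 1e-14)) { early <- TRUE; break }
    w <- sparse_weight(z, keepX)
    th <- drop(Xh %*% w)
    ss <- sum(th^2)
    if (ss < 1e-12) { early <- TRUE; break }
    ph <- drop(crossprod(Xh, th)) / ss
    qh <- sum(yh * th) / ss
    W[, h] <- w; P[, h] <- ph; Tm[, h] <- th; q[h] <- qh; tt[h] <- ss
    Xh <- Xh - tcrossprod(th, ph)
    yh <- yh - qh * th
    h_done <- h
  }
  if (h_done == 0L) stopf("no usable component could be extracted")
  keep_h <- seq_len(h_done)
  W <- W[, keep_h, drop = FALSE]; P <- P[, keep_h, drop = FALSE]
  Tm <- Tm[, keep_h, drop = FALSE]; q <- q[keep_h]; tt <- tt[keep_h]
  b_std <- drop(W %*% solve(crossprod(P, W), q))
  list(W = W, P = P, T = Tm, q = q, tt = tt, b_std = b_std,
       h_done = h_done, early = early)
}

#' Fit a sparse PLS1 regression model
#'
#' Sequential (NIPALS-style) extraction of `n_components` latent
#' components on internally standardised data. Per component `h`:
#' weight `w_h = sparse_weight(X'y, keepX)`, score `t_h = X w_h`,
#' X-loading `p_h = X't_h / t_h't_h`, y-loading `q_h = y't_h / t_h't_h`,
#' then deflation of both `X` and `y`. Regression coefficients are
#' `b = W (P'W)^{-1} q`, mapped back to the original scale. Component
#' extraction stops early (with a record) if a score's sum of squares
#' falls below 1e-12.
#' @param X subjects-by-features matrix with column names.
#' @param y outcome vector.
#' @param keepX sparsity per component (default: dense, `ncol(X)`).
#' @param n_components number of components H.
#' @param allow_constant passed to [standardize()] (used on bootstrap
#'   resamples where a column may be constant by chance).
#' @return object of class `spls_model`: weights `W` (p x H, unit-norm
#'   columns), scores `T`, X-loadings `P`, y-loadings `q`, score sums of
#'   squares `tt`, standardised and original-scale coefficients,
#'   centring/scaling parameters, `n_components_fitted`, `early_stop`.
#' @export
fit_spls <- function(X, y, keepX = ncol(X), n_components = 5L,
                     allow_constant = FALSE) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stopf("need at least 3 subjects")
  keepX <- min(as.integer(keepX), p)
  H <- min(as.integer(n_components), p, n - 1L)
  std <- standardize(X, y, allow_constant = allow_constant)
  core <- spls_nipals(std$X, std$y, keepX, H)
  W <- core$W; P <- core$P; Tm <- core$T; q <- core$q; tt <- core$tt
  b_std <- core$b_std
  coef_orig <- std$y_scale * b_std / std$x_scale
  intercept <- std$y_center - sum(coef_orig * std$x_center)

  structure(list(
    W = W, P = P, T = Tm, q = q, tt = tt,
    b_std = b_std, coefficients = stats::setNames(coef_orig, colnames(X)),
    intercept = intercept,
    x_center = std$x_center, x_scale = std$x_scale,
    y_center = std$y_center, y_scale = std$y_scale,
    keepX = keepX, n_components_fitted = core$h_done,
    early_stop = core$early, feature_names = colnames(X),
    fitted_values = intercept + drop(X %*% coef_orig)),
    class = "spls_model")
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf("spls_model: %d features, %d component(s), keepX = %d%s\n",
              length(x$coefficients), x$n_components_fitted, x$keepX,
              if (x$early_stop) " (early stop)" else ""))
  invisible(x)
}

#' Predict from a fitted sPLS model
#'
#' `yhat = intercept + X_new %*% coefficients` on the original scale,
#' which equals the standardised coefficient route and the sequential
#' component recursion.
#' @param object an `spls_model`.
#' @param newdata matrix with the training feature columns (matched by
#'   name when both are named).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.spls_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names)) {
    if (!setequal(colnames(newdata), object$feature_names))
      stopf("feature columns do not match the training features")
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) != length(object$coefficients)) {
    stopf("newdata has %d columns; model expects %d",
          ncol(newdata), length(object$coefficients))
  }
  object$intercept + drop(newdata %*% object$coefficients)
}

#' Variable importance in projection
#'
#' Per-feature VIP over the first `n_components_used` components:
#' `vip_j = sqrt( p * sum_h ss_h w_jh^2 / sum_h ss_h )` with
#' `ss_h = q_h^2 t_h't_h`, the outcome variance explained by component
#' h. With unit-norm weight columns, `sum_j vip_j^2 = p`; for a single
#' component the formula collapses to `sqrt(p) * |w_j1|`.
#' @param model an `spls_model`.
#' @param n_components_used how many leading components to aggregate
#'   (default: all fitted).
#' @return list of class `vip_vector`: named `vip` and `n_components_used`.
#' @export
compute_vip <- function(model, n_components_used = model$n_components_fitted) {
  stopifnot(inherits(model, "spls_model"))
  nc <- as.integer(n_components_used)
  if (nc < 1 || nc > model$n_components_fitted)
    stopf("n_components_used must be in [1, %d]", model$n_components_fitted)
  p <- nrow(model$W)
  ss <- model$q[seq_len(nc)]^2 * model$tt[seq_len(nc)]
  vip <- sqrt(p * drop(model$W[, seq_len(nc), drop = FALSE]^2 %*% ss) / sum(ss))
  structure(list(vip = stats::setNames(vip, model$feature_names),
                 n_components_used = nc),
            class = "vip_vector")
}

#' Tune keepX by repeated k-fold cross-validation
#'
#' For every grid value, fits on each training fold and scores held-out
#' predictions by mean absolute error; fold assignments are drawn once
#' per repeat (seeded) and shared across the grid. Under the default
#' `"1se"` rule the chosen keepX is the smallest grid value whose mean
#' MAE is within one standard error of the minimum — the standard
#' parsimony-favouring cross-validation rule, in keeping with the aim
#' of a sparse, interpretable model; `rule = "min"` takes the plain
#' minimiser. Exact ties always go to the smaller (sparser) keepX.
#'
#' By default held-out predictions are scored at component depth 1
#' (`eval_components = 1`), mirroring the reference ecosystem's
#' per-component tuning: the sparsity penalty acts per component and
#' downstream stability selection operates on component 1, and
#' full-depth scoring is degenerate under weak signal (denser models
#' always shrink noise predictions harder, so the loss curve slopes
#' toward dense keepX regardless of the data). Set
#' `eval_components = NULL` to score the full fitted model instead.
#' @param X,y training data.
#' @param config an `spls_config`.
#' @param rule `"1se"` (default) or `"min"`.
#' @param eval_components component depth at which held-out predictions
#'   are scored (default 1; `NULL` for all fitted components).
#' @return list of class `keepx_tuning`: `keepX` (chosen), `cv_table`
#'   (data.frame keepX / mean_mae / se_mae), `config`.
#' @export
tune_keepX <- function(X, y, config = spls_config(), rule = c("1se", "min"),
                       eval_components = 1L) {
  stopifnot(inherits(config, "spls_config"))
  rule <- match.arg(rule)
  n <- nrow(X)
  k <- config$cv_folds
  if (n < 2 * k)
    stopf("n = %d too small for %d-fold CV; use smaller cv_folds", n, k)
  grid <- pmin(config$keepX_grid, ncol(X))
  grid <- sort(unique(grid))
  set.seed(stage_seed(config$seed, "tune_keepX"))
  fold_mae <- matrix(NA_real_, length(grid), config$cv_repeats * k)
  col <- 0L
  for (r in seq_len(config$cv_repeats)) {
    folds <- sample(rep(seq_len(k), length.out = n))
    for (f in seq_len(k)) {
      col <- col + 1L
      tr <- folds != f
      std <- standardize(X[tr, , drop = FALSE], y[tr], allow_constant = TRUE)
      H <- min(config$n_components, ncol(X), sum(tr) - 1L)
      Xs_new <- sweep(sweep(X[!tr, , drop = FALSE], 2, std$x_center),
                      2, std$x_scale, "/")
      for (gi in seq_along(grid)) {
        core <- spls_nipals(std$X, std$y, grid[gi], H)
        d <- if (is.null(eval_components)) core$h_done else
          min(eval_components, core$h_done)
        b_d <- if (d == core$h_done) core$b_std else
          drop(core$W[, 1:d, drop = FALSE] %*%
                 solve(crossprod(core$P[, 1:d, drop = FALSE],
                                 core$W[, 1:d, drop = FALSE]),
                       core$q[1:d]))
        pred <- std$y_center + std$y_scale * drop(Xs_new %*% b_d)
        fold_mae[gi, col] <- mean(abs(pred - y[!tr]))
      }
    }
  }
  mean_mae <- rowMeans(fold_mae)
  # SE from repeat-level means: folds within a repeat share one
  # assignment, so fold-level SEs would be too small
  rep_id <- rep(seq_len(config$cv_repeats), each = k)
  rep_means <- t(apply(fold_mae, 1, function(v) tapply(v, rep_id, mean)))
  se_mae <- apply(rep_means, 1, stats::sd) / sqrt(config$cv_repeats)
  i_min <- which.min(mean_mae)        # grid ascending: ties go sparse
  best <- if (rule == "1se") {
    grid[which(mean_mae <= mean_mae[i_min] + se_mae[i_min])[1]]
  } else {
    grid[i_min]
  }
  structure(list(keepX = best, rule = rule,
                 cv_table = data.frame(keepX = grid, mean_mae = mean_mae,
                                       se_mae = se_mae),
                 config = config),
            class = "keepx_tuning")
}

#' @export
print.keepx_tuning <- function(x, ...) {
  cat(sprintf("keepX tuning (k = %d, repeats = %d): chose keepX = %d\n",
              x$config$cv_folds, x$config$cv_repeats, x$keepX))
  print(x$cv_table, row.names = FALSE)
  invisible(x)
}
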