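make_xy <- function(seed, n = 12, p = 6, signal = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("e", 1:p)))
  y <- if (signal) drop(X[, 1:2] %*% c(1, -0.5)) + rnorm(n, 0, 0.3) else rnorm(n)
  list(X = X, y = y)
}

test_that("standardize centres and scales, and is idempotent", {
  d <- make_xy(1)
  s <- standardize(d$X, d$y)
  expect_equal(unname(colMeans(s$X)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(s$X, 2, sd)), rep(1, 6), tolerance = 1e-10)
  expect_equal(mean(s$y), 0, tolerance = 1e-12)
  s2 <- standardize(s$X, s$y)
  expect_equal(s2$X, s$X, tolerance = 1e-12)
  Xc <- d$X; Xc[, 3] <- 2
  expect_error(standardize(Xc, d$y), "zero-variance")
  # tolerated (and neutralised) under allow_constant
  sc <- standardize(Xc, d$y, allow_constant = TRUE)
  expect_equal(unname(sc$X[, 3]), rep(0, 12))
})

test_that("sparse_weight soft-thresholds at the (keepX+1)-th magnitude", {
  w <- sparse_weight(c(3, -2, 1), 2)
  expect_equal(w, c(2, -1, 0) / sqrt(5))
  # keepX = p: plain normalisation
  z <- c(1.5, -2, 0.5)
  expect_equal(sparse_weight(z, 3), z / sqrt(sum(z^2)))
  # ties at the cutoff shrink together: brute-force ranking oracle
  z <- c(2, 1, 1, 1, 0.5)
  w <- sparse_weight(z, 3)
  lambda <- sort(abs(z), decreasing = TRUE)[4]   # == 1, ties with ranks 2:4
  oracle <- sign(z) * pmax(abs(z) - lambda, 0)
  expect_equal(w, oracle / sqrt(sum(oracle^2)))
  expect_equal(sum(w != 0), 1L)   # fewer than keepX survivors under ties
  expect_error(sparse_weight(rep(0, 4), 2), "all-zero")
  expect_error(sparse_weight(c(1, 1), 3), "keepX")
})

test_that("dense fit matches the independent PLS1 reference", {
  for (seed in 1:4) {
    d <- make_xy(seed, n = 10, p = 6)
    fit <- fit_spls(d$X, d$y, keepX = 6, n_components = 3)
    ref <- ref_pls1(d$X, d$y, 3)
    expect_equal(fit$fitted_values, ref$fitted, tolerance = 1e-8)
    newX <- matrix(rnorm(30), 5, 6, dimnames = list(NULL, colnames(d$X)))
    expect_equal(predict(fit, newX), ref$predict(newX), tolerance = 1e-8)
  }
})

test_that("single-column fit collapses to simple least squares", {
  set.seed(2)
  x <- rnorm(15); y <- 2 + 3 * x + rnorm(15, 0, 0.1)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "e1"))
  fit <- fit_spls(X, y, keepX = 1, n_components = 1)
  ls <- lm(y ~ x)
  expect_equal(fit$fitted_values, unname(fitted(ls)), tolerance = 1e-10)
})

test_that("first dense component weight is proportional to X'y", {
  d <- make_xy(3)
  fit <- fit_spls(d$X, d$y, keepX = 6, n_components = 1)
  s <- standardize(d$X, d$y)
  z <- drop(crossprod(s$X, s$y))
  expect_equal(fit$W[, 1], unname(z / sqrt(sum(z^2))), tolerance = 1e-12)
})

test_that("model invariants: unit-norm sparse weights, orthogonal scores, route equivalence", {
  for (seed in 1:3) {
    d <- make_xy(seed, n = 14, p = 10)
    fit <- fit_spls(d$X, d$y, keepX = 4, n_components = 4)
    # unit norm, support size
    expect_equal(unname(sqrt(colSums(fit$W^2))),
                 rep(1, fit$n_components_fitted), tolerance = 1e-12)
    expect_true(all(colSums(fit$W != 0) <= 4))
    # score orthogonality
    G <- crossprod(fit$T)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    # coefficient route equals sequential component route
    s <- standardize(d$X, d$y)
    Xh <- s$X; acc <- numeric(nrow(Xh))
    for (h in seq_len(fit$n_components_fitted)) {
      th <- drop(Xh %*% fit$W[, h])
      acc <- acc + fit$q[h] * th
      Xh <- Xh - th %*% t(fit$P[, h])
    }
    route2 <- s$y_center + s$y_scale * acc
    expect_equal(fit$fitted_values, route2, tolerance = 1e-10)
    # sparse with keepX = p identical to dense
    f1 <- fit_spls(d$X, d$y, keepX = 10, n_components = 3)
    ref <- ref_pls1(d$X, d$y, 3)
    expect_equal(f1$W, unname(ref$W), tolerance = 1e-10)
  }
})

test_that("prediction handles centring and label matching", {
  d <- make_xy(5)
  fit <- fit_spls(d$X, d$y, keepX = 6, n_components = 2)
  expect_equal(predict(fit, d$X), fit$fitted_values, tolerance = 1e-12)
  # a row at the training column means predicts mean(y)
  mu <- matrix(colMeans(d$X), 1, dimnames = list(NULL, colnames(d$X)))
  expect_equal(predict(fit, mu), mean(d$y), tolerance = 1e-10)
  bad <- d$X; colnames(bad)[1] <- "other"
  expect_error(predict(fit, bad), "match")
})

test_that("compute_vip satisfies the closed forms and the formula oracle", {
  # H = 1 closed forms
  d <- make_xy(6, n = 16, p = 4)
  fit <- fit_spls(d$X, d$y, keepX = 4, n_components = 1)
  v <- compute_vip(fit)
  expect_equal(unname(v$vip), 2 * abs(fit$W[, 1]), tolerance = 1e-10)
  # H = 2: direct formula evaluation
  fit2 <- fit_spls(d$X, d$y, keepX = 4, n_components = 2)
  v2 <- compute_vip(fit2)
  expect_equal(unname(v2$vip), ref_vip(fit2$W, fit2$q, fit2$tt, 2),
               tolerance = 1e-10)
  # sum of squares equals p, sparse or dense
  for (kx in c(2, 4)) {
    f <- fit_spls(d$X, d$y, keepX = kx, n_components = 2)
    expect_equal(sum(compute_vip(f)$vip^2), 4, tolerance = 1e-6)
  }
  expect_error(compute_vip(fit, 5), "n_components_used")
})

test_that("tune_keepX: trivial grid, planted-signal recovery, flat-noise parsimony", {
  d <- make_xy(7, n = 20, p = 8)
  one <- tune_keepX(d$X, d$y, spls_config(keepX_grid = 4L, cv_repeats = 2L,
                                          seed = 1))
  expect_equal(one$keepX, 4L)
  expect_error(tune_keepX(d$X[1:8, ], d$y[1:8],
                          spls_config(cv_folds = 5L)), "folds")
  # strong orthogonal 5-feature signal: sparse grid value wins
  wins <- sapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(100 * 120), 100, 120,
                dimnames = list(NULL, sprintf("e%03d", 1:120)))
    sig <- rowSums(X[, 1:5])
    y <- sig + rnorm(100, 0, sd(sig) * 0.5)
    tune_keepX(X, y, spls_config(keepX_grid = c(5L, 50L), cv_repeats = 10L,
                                 seed = s))$keepX
  })
  expect_gte(mean(wins == 5L), 0.9)
  # pure-noise outcome: the loss curve is nearly flat (no grid value is
  # meaningfully better than any other)
  spreads <- sapply(1:10, function(s) {
    set.seed(s + 100)
    X <- matrix(rnorm(50 * 100), 50, 100,
                dimnames = list(NULL, sprintf("e%03d", 1:100)))
    tb <- tune_keepX(X, rnorm(50),
                     spls_config(keepX_grid = c(5L, 20L, 50L, 100L),
                                 cv_repeats = 10L, seed = s))$cv_table
    (max(tb$mean_mae) - min(tb$mean_mae)) / min(tb$mean_mae)
  })
  expect_true(all(spreads < 0.25))
  expect_lt(median(spreads), 0.12)
})

test_that("degenerate deflation stops early with a record", {
  # one informative direction only: later components collapse
  set.seed(8)
  x <- rnorm(10)
  X <- cbind(e1 = x, e2 = x, e3 = x)
  y <- x + rnorm(10, 0, 1e-8)
  fit <- fit_spls(X, y, keepX = 3, n_components = 3)
  expect_lt(fit$n_components_fitted, 3L)
  expect_true(fit$early_stop)
})
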