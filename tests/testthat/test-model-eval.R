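test_that("split_cohort sizes, disjointness and determinism", {
  s <- split_cohort(71, 0.7, seed = 1)
  expect_length(s$train_indices, 50L)
  expect_length(s$test_indices, 21L)
  expect_length(intersect(s$train_indices, s$test_indices), 0L)
  expect_setequal(c(s$train_indices, s$test_indices), 1:71)
  expect_length(split_cohort(10, 0.7, seed = 2)$train_indices, 7L)
  expect_identical(split_cohort(40, 0.7, seed = 9),
                   split_cohort(40, 0.7, seed = 9))
  expect_error(split_cohort(40, 1.2), "train_fraction")
  # sizes/disjointness over assorted n and fractions
  for (n in c(11, 23, 64)) for (fr in c(0.5, 0.7, 0.8)) {
    sp <- split_cohort(n, fr, seed = n)
    expect_length(sp$train_indices, round(fr * n))
    expect_setequal(c(sp$train_indices, sp$test_indices), seq_len(n))
  }
})

test_that("nested_models takes ranked prefixes and clips with a warning", {
  cand <- data.frame(edge = paste0("e", 1:16),
                     mean_vip = seq(16, 1), frequency = rep(0.9, 16))
  subs <- nested_models(cand, c(16L, 10L, 2L))
  expect_named(subs, c("top16", "top10", "top2"))
  expect_equal(subs$top2, c("e1", "e2"))
  expect_equal(subs$top10, paste0("e", 1:10))
  # brute-force sort-and-slice oracle
  expect_equal(subs$top16, cand$edge[order(-cand$mean_vip)][1:16])
  expect_equal(nested_models(cand, 16L)[[1]], cand$edge)
  expect_warning(nested_models(cand[1:4, ], c(10L, 2L)), "clipping")
})

test_that("pearson_one_tailed matches a numerically integrated t tail", {
  a <- c(0.3, 1.2, 0.8, 2.0, 1.5, 0.1)
  b <- c(0.5, 1.0, 1.1, 1.8, 1.9, 0.4)
  res <- pearson_one_tailed(a, b)
  r <- cor(a, b)
  expect_equal(res$r, r)
  tval <- r * sqrt((length(a) - 2) / (1 - r^2))
  expect_equal(res$p, ref_t_tail(tval, length(a) - 2), tolerance = 1e-8)
  # identity: one-tailed p is half the two-tailed p when r > 0
  expect_equal(res$p, cor.test(a, b)$p.value / 2, tolerance = 1e-10)
  # degenerate directions
  expect_equal(pearson_one_tailed(a, a)$p, 0)
  expect_equal(pearson_one_tailed(a, -a)$p, 1)
  expect_error(pearson_one_tailed(rep(1, 5), a[1:5]), "variance")
})

test_that("fit_and_evaluate: perfect training signal and permutation null", {
  set.seed(3)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("e", 1:6)))
  y <- drop(X[, 1:3] %*% c(1, 0.5, -0.7))     # noiseless in the subset
  sp <- split_cohort(n, 0.7, seed = 1)
  ev <- fit_and_evaluate(X, y, sp, paste0("e", 1:3), n_components = 3,
                         choose_h = FALSE)
  expect_gt(ev$r_train, 1 - 1e-8)
  expect_lt(ev$p_test, 1e-6)
  # permuted outcome: test correlations centre on zero
  rs <- sapply(1:20, function(s) {
    set.seed(s)
    fit_and_evaluate(X, sample(y), sp, paste0("e", 1:3), n_components = 2,
                     choose_h = FALSE)$r_test
  })
  expect_lt(abs(mean(rs)), 2 * sd(rs) / sqrt(20) + 0.15)
  expect_error(fit_and_evaluate(X, y, sp, character(0)), "empty")
  expect_error(fit_and_evaluate(X, y, sp, "unknown"), "unknown")
})

test_that("r_train does not increase when signal-free features are dropped", {
  set.seed(6)
  n <- 30
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("e", 1:5)))
  y <- drop(X[, 1:2] %*% c(1, 1))   # e3..e5 carry no signal
  sp <- split_cohort(n, 0.7, seed = 2)
  r5 <- fit_and_evaluate(X, y, sp, paste0("e", 1:5), 5, choose_h = FALSE)$r_train
  r2 <- fit_and_evaluate(X, y, sp, paste0("e", 1:2), 5, choose_h = FALSE)$r_train
  expect_lte(r2, r5 + 1e-8)
})

test_that("final_refit_report ranks by loading and reports raw statistics", {
  set.seed(4)
  X <- matrix(rlnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("e", 1:4)))
  y <- X[, 2] + rnorm(50, 0, 0.5)
  rep4 <- final_refit_report(X, y, paste0("e", 1:4), n_components = 2)
  expect_equal(rep4$loading, sort(rep4$loading, decreasing = TRUE))
  # descriptive statistics recomputed independently
  i <- match("e3", rep4$edge)
  expect_equal(rep4$mean[i], mean(X[, "e3"]))
  expect_equal(rep4$sd[i], sd(X[, "e3"]))
  expect_equal(rep4$min[i], min(X[, "e3"]))
  expect_equal(rep4$max[i], max(X[, "e3"]))
  # single feature: unit loading, unit VIP
  rep1 <- final_refit_report(X, y, "e2", n_components = 1)
  expect_equal(abs(rep1$loading), 1)
  expect_equal(rep1$vip, 1)
})

test_that("cluster_features recovers designed blocks and honours linkage", {
  set.seed(7)
  n <- 60
  u <- rnorm(n); v <- rnorm(n)
  X <- cbind(a1 = u + rnorm(n, 0, 0.3), a2 = u + rnorm(n, 0, 0.3),
             b1 = v + rnorm(n, 0, 0.3), b2 = v + rnorm(n, 0, 0.3))
  cr <- cluster_features(X, n_clusters = 2)
  expect_equal(unname(cr$labels["a1"]), unname(cr$labels["a2"]))
  expect_equal(unname(cr$labels["b1"]), unname(cr$labels["b2"]))
  expect_false(cr$labels["a1"] == cr$labels["b1"])
  expect_equal(cr$correlation, t(cr$correlation))
  expect_equal(unname(diag(cr$correlation)), rep(1, 4))
  # perfectly correlated pair merges at height ~0
  Xp <- cbind(x = u, y = 2 * u + 3, z = v)
  crp <- cluster_features(Xp, n_clusters = 2)
  expect_lt(min(crp$hclust$height), 1e-12)
  # single vs average linkage differ on a designed chain
  set.seed(8)
  base <- rnorm(n)
  chain <- sapply(0:4, function(k) base + rnorm(n, 0, 0.15 * (1 + k)))
  colnames(chain) <- paste0("c", 1:5)
  h_avg <- cluster_features(chain, "average")$hclust$merge
  h_sgl <- cluster_features(chain, "single")$hclust$height
  expect_false(identical(h_avg, cluster_features(chain, "single")$hclust$merge) &&
                 identical(cluster_features(chain, "average")$hclust$height, h_sgl))
  expect_error(cluster_features(cbind(a = u, b = rep(1, n))), "zero-variance")
})

test_that("group_summary matches hand arithmetic", {
  X <- matrix(c(1, 2, 3, 4,
                10, 20, 30, 40), ncol = 2,
              dimnames = list(NULL, c("e1", "e2")))
  g <- c("a", "a", "b", "b")
  gs <- group_summary(X, g, c("e1", "e2"), group_order = c("b", "a"))
  expect_equal(gs$mean[gs$group == "a" & gs$edge == "e1"], 1.5)
  expect_equal(gs$se[gs$group == "a" & gs$edge == "e1"],
               sd(c(1, 2)) / sqrt(2))
  expect_equal(gs$mean[gs$group == "b" & gs$edge == "e2"], 35)
  expect_equal(gs$group[1], "b")   # supplied ordering respected
  # single group: overall column means; constant column: zero SE
  one <- group_summary(cbind(k = c(5, 5, 5)), rep("g", 3), "k")
  expect_equal(one$mean, 5)
  expect_equal(one$se, 0)
  expect_error(group_summary(X, g, "e1", group_order = "zz"), "unknown")
})
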