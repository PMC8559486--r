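test_that("symmetrize_normalize implements the volume-normalised average", {
  expect_equal(symmetrize_normalize(4, 6, 2, 3), 1.0)
  expect_equal(symmetrize_normalize(0, 0, 2, 3), 0)
  # symmetric closed form c/(2v)
  expect_equal(symmetrize_normalize(7, 7, 5, 5), 7 / 10)
  expect_error(symmetrize_normalize(1, 1, 0, 2), "volumes")
})

test_that("normalize_raw_counts symmetrises a directed count matrix", {
  raw <- matrix(c(0, 4, 2,
                  6, 0, 8,
                  4, 10, 0), 3, 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  vols <- c(A = 2, B = 3, C = 1)
  m <- normalize_raw_counts(raw, vols)
  expect_equal(m, t(m))
  expect_equal(m["A", "B"], ((4 + 6) / 2) / (2 + 3))
  expect_equal(m["B", "C"], ((8 + 10) / 2) / (3 + 1))
  expect_equal(diag(m), c(A = 0, B = 0, C = 0))
})

test_that("vectorize_lower_triangle uses canonical row-major order", {
  m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m[2, 1] <- m[1, 2] <- 5
  m[3, 1] <- m[1, 3] <- 7
  m[3, 2] <- m[2, 3] <- 11
  v <- vectorize_lower_triangle(m)
  expect_equal(v$edge_values, c(5, 7, 11))
  expect_equal(v$edge_labels, c("A<->B", "A<->C", "B<->C"))
  # zeros stay zeros
  z <- diag(3); dimnames(z) <- dimnames(m)
  expect_equal(vectorize_lower_triangle(z)$edge_values, c(0, 0, 0))
  # a 192-region matrix vectorises to n(n-1)/2 = 18,336 edges
  expect_equal(nrow(edge_pairs(192L)), 18336L)
  # asymmetry beyond tolerance is an error
  bad <- m; bad[2, 1] <- 5 + 1e-6
  expect_error(vectorize_lower_triangle(bad), "asymmetric")
})

test_that("build_feature_matrix matches per-subject vectorisation (round trip)", {
  ch <- small_cohort(seed = 3, n_subjects = 6, n_regions = 9)
  fm <- build_feature_matrix(ch$matrices)
  expect_equal(nrow(fm$values), 6L)
  expect_equal(ncol(fm$values), 9 * 8 / 2)
  for (s in c(1, 4)) {
    v <- vectorize_lower_triangle(ch$matrices[[s]])
    expect_equal(unname(fm$values[s, ]), v$edge_values)
    expect_equal(fm$edge_labels, v$edge_labels)
  }
  # rebuild a matrix from the edge vector and re-vectorise: exact round trip
  pr <- edge_pairs(9L)
  m2 <- matrix(0, 9, 9,
               dimnames = list(rownames(ch$matrices[[1]]),
                               rownames(ch$matrices[[1]])))
  m2[pr] <- fm$values[2, ]
  m2[pr[, c(2, 1)]] <- fm$values[2, ]
  expect_equal(vectorize_lower_triangle(m2)$edge_values,
               unname(fm$values[2, ]))
  # label mismatch across subjects errors
  mats <- ch$matrices
  rownames(mats[[2]])[1] <- colnames(mats[[2]])[1] <- "XXX"
  expect_error(build_feature_matrix(mats), "labels differ")
})

test_that("slf_edge_set enumerates cross-group pairs", {
  atlas <- structure(list(
    region_ids = sprintf("R%03d", 1:7),
    region_coords = matrix(runif(21), 7, 3,
                           dimnames = list(sprintf("R%03d", 1:7), NULL)),
    region_volumes = setNames(rep(1, 7), sprintf("R%03d", 1:7)),
    region_groups = list(inferior_frontal = c("R001", "R002"),
                         lateral_temporal = c("R003", "R004", "R005"),
                         supramarginal = c("R006", "R007"))),
    class = "atlas_spec")
  slf <- slf_edge_set(atlas)
  # 2*3 + 2*2 + 2*3 = 16 edges, verified by brute-force enumeration
  expect_length(slf, 16L)
  brute <- unique(c(
    outer(c("R001", "R002"), c("R003", "R004", "R005"),
          function(a, b) paste0(a, "<->", b)),
    outer(c("R001", "R002"), c("R006", "R007"),
          function(a, b) paste0(a, "<->", b)),
    outer(c("R006", "R007"), c("R003", "R004", "R005"),
          function(a, b) paste0(pmin(a, b), "<->", pmax(a, b)))))
  expect_setequal(slf, brute)
  # overlapping groups never produce self-pairs
  atlas$region_groups$lateral_temporal <- c("R001", "R003")
  expect_false(any(grepl("^(R\\d+)<->\\1$", slf_edge_set(atlas))))
  # missing group errors with its name
  atlas$region_groups$supramarginal <- NULL
  expect_error(slf_edge_set(atlas), "supramarginal")
})

test_that("threshold keeps the boundary and forced edges, and is monotone", {
  vals <- rbind(c(0.1, 1.0, 3.5, 0.99, 1.02),
                c(0.3, 1.0, 3.9, 0.99, 1.00))
  fm <- feature_matrix(vals, c("s1", "s2"),
                       c("e1", "e2", "e3", "e4", "e5"))
  kept <- threshold_and_force(fm, 1)
  # mean exactly 1 is retained (only strictly-below is removed)
  expect_equal(kept$edge_labels, c("e2", "e3", "e5"))
  # forced edge below threshold is retained and flagged
  kf <- threshold_and_force(fm, 1, forced = "e1")
  expect_true("e1" %in% kf$edge_labels)
  expect_true(kf$forced_slf[kf$edge_labels == "e1"])
  expect_false(kf$survived_threshold[kf$edge_labels == "e1"])
  # all-zero column goes unless forced
  fm0 <- feature_matrix(cbind(vals, 0), c("s1", "s2"),
                        c("e1", "e2", "e3", "e4", "e5", "zero"))
  expect_false("zero" %in% threshold_and_force(fm0, 1)$edge_labels)
  # raising the threshold never enlarges the non-forced survivor set
  keep_at <- function(th) tryCatch(threshold_and_force(fm, th)$edge_labels,
                                   error = function(e) character(0))
  for (th in c(0, 0.5, 1, 2, 4)) {
    expect_true(all(keep_at(th + 0.5) %in% keep_at(th)))
  }
  # column count equals |survivors union forced|
  expect_equal(ncol(kf$values),
               length(union(c("e2", "e3", "e5"), "e1")))
  expect_error(threshold_and_force(fm, 1, forced = "nope"), "absent")
})

test_that("feature matrix IO round-trips", {
  ch <- small_cohort(seed = 2, n_subjects = 4, n_regions = 8)
  fm <- build_feature_matrix(ch$matrices)
  dir <- withr::local_tempdir()
  write_feature_matrix(fm, dir)
  back <- as.matrix(utils::read.table(file.path(dir, "features.tsv"),
                                      sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(fm$values), tolerance = 1e-12)
  expect_identical(colnames(back), fm$edge_labels)
})
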