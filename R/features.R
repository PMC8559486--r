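SYM_TOL <- 1e-9
EDGE_SEP <- "<->"

#' Canonical edge index pairs
#'
#' Row-major lower-triangle enumeration: for each row `i = 2..n`, all
#' columns `j < i`. This is the canonical edge order used everywhere in
#' the package (it is deterministic and defined purely by the atlas's
#' region ordering).
#' @param n number of regions.
#' @return integer matrix with columns `i`, `j` (`i > j`), `n(n-1)/2` rows.
#' @export
edge_pairs <- function(n) {
  i <- rep.int(2:n, times = 1:(n - 1L))
  j <- sequence(1:(n - 1L))
  cbind(i = i, j = j)
}

#' Canonical edge label
#'
#' `"A<->B"` with the two labels in atlas order (the lower-index region
#' first). Self-pairs are rejected.
#' @param a,b region labels.
#' @param region_ids the atlas's ordered region labels.
#' @return character vector of canonical labels.
#' @export
edge_label <- function(a, b, region_ids) {
  ia <- match(a, region_ids); ib <- match(b, region_ids)
  if (anyNA(ia) || anyNA(ib)) stopf("unknown region label")
  if (any(ia == ib)) stopf("an edge cannot join a region to itself")
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  paste0(region_ids[lo], EDGE_SEP, region_ids[hi])
}

edge_labels_for <- function(atlas) {
  pr <- edge_pairs(length(atlas$region_ids))
  # pairs are (i, j) with i > j; canonical label puts the lower index first
  paste0(atlas$region_ids[pr[, 2]], EDGE_SEP, atlas$region_ids[pr[, 1]])
}

#' Volume-normalised symmetric edge weight
#'
#' Combines the two directed streamline counts of a region pair and
#' normalises by the regions' total volume:
#' `((raw_ij + raw_ji) / 2) / (vol_i + vol_j)`. Vectorised.
#' @param raw_ij,raw_ji nonnegative directed counts.
#' @param vol_i,vol_j strictly positive region volumes.
#' @return the normalised weight(s).
#' @export
symmetrize_normalize <- function(raw_ij, raw_ji, vol_i, vol_j) {
  if (any(vol_i <= 0) || any(vol_j <= 0)) stopf("region volumes must be > 0")
  if (any(raw_ij < 0) || any(raw_ji < 0)) stopf("streamline counts must be >= 0")
  ((raw_ij + raw_ji) / 2) / (vol_i + vol_j)
}

#' Build a connectivity matrix from raw directed counts
#'
#' Applies [symmetrize_normalize()] elementwise to a possibly asymmetric
#' raw count matrix, producing a symmetric volume-normalised matrix with
#' zero diagonal.
#' @param raw square nonnegative matrix of directed counts with region
#'   labels as dimnames.
#' @param volumes named positive volumes covering all regions.
#' @return symmetric connectivity matrix.
#' @export
normalize_raw_counts <- function(raw, volumes) {
  stopifnot(is.matrix(raw), nrow(raw) == ncol(raw))
  ids <- rownames(raw)
  v <- volumes[ids]
  if (anyNA(v)) stopf("volumes missing for some regions")
  vs <- outer(v, v, "+")
  m <- ((raw + t(raw)) / 2) / vs
  if (any(v <= 0)) stopf("region volumes must be > 0")
  diag(m) <- 0
  m
}

as_connectivity_matrix <- function(m, tol = SYM_TOL) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  asym <- max(abs(m - t(m)))
  if (asym > tol)
    stopf("matrix asymmetric beyond tolerance (max |m - t(m)| = %.3g)", asym)
  m <- (m + t(m)) / 2        # absorb file-precision noise
  if (any(m[row(m) != col(m)] < 0)) stopf("negative connectivity values")
  diag(m) <- 0
  m
}

#' Vectorise the lower triangle of a connectivity matrix
#'
#' Extracts all unordered off-diagonal pairs in canonical row-major
#' lower-triangle order (length `n(n-1)/2`). Errors if the matrix is
#' asymmetric beyond 1e-9; asymmetry within tolerance is averaged away.
#' @param m symmetric connectivity matrix with region-label dimnames.
#' @return list with `edge_labels` and `edge_values`.
#' @export
vectorize_lower_triangle <- function(m) {
  m <- as_connectivity_matrix(m)
  ids <- rownames(m) %||% sprintf("R%03d", seq_len(nrow(m)))
  pr <- edge_pairs(nrow(m))
  list(edge_labels = paste0(ids[pr[, 2]], EDGE_SEP, ids[pr[, 1]]),
       edge_values = m[pr])
}

#' Construct a feature matrix object
#'
#' A subjects-by-edges matrix with canonical edge labels and per-edge
#' provenance flags recording whether each edge survived the mean
#' threshold and/or was force-included.
#' @param values numeric matrix, subjects in rows.
#' @param subject_ids row identifiers.
#' @param edge_labels column identifiers (canonical edge labels).
#' @param survived_threshold,forced_slf logical per-edge flags.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, subject_ids, edge_labels,
                           survived_threshold = rep(TRUE, ncol(values)),
                           forced_slf = rep(FALSE, ncol(values))) {
  stopifnot(is.matrix(values), length(subject_ids) == nrow(values),
            length(edge_labels) == ncol(values),
            length(survived_threshold) == ncol(values),
            length(forced_slf) == ncol(values))
  if (anyDuplicated(edge_labels)) stopf("duplicate edge labels")
  dimnames(values) <- list(subject_ids, edge_labels)
  structure(list(values = values, subject_ids = subject_ids,
                 edge_labels = edge_labels,
                 survived_threshold = survived_threshold,
                 forced_slf = forced_slf),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d subjects x %d edges (%d threshold survivors, %d forced)\n",
              nrow(x$values), ncol(x$values), sum(x$survived_threshold),
              sum(x$forced_slf)))
  invisible(x)
}

#' Vectorise a cohort of connectivity matrices into a feature matrix
#'
#' One row per subject, one column per canonical edge; all subjects must
#' share the same region labels in the same order.
#' @param matrices named list of symmetric connectivity matrices.
#' @return a `feature_matrix` over the full edge universe.
#' @export
build_feature_matrix <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  ref <- rownames(matrices[[1]])
  rows <- lapply(matrices, function(m) {
    if (!identical(rownames(m), ref))
      stopf("region labels differ across subjects")
    vectorize_lower_triangle(m)
  })
  vals <- do.call(rbind, lapply(rows, `[[`, "edge_values"))
  ids <- names(matrices) %||% sprintf("S%03d", seq_along(matrices))
  feature_matrix(vals, ids, rows[[1]]$edge_labels)
}

#' Cross-group SLF-like edge set
#'
#' The union of all region pairs crossing the three group pairings
#' inferior_frontal-lateral_temporal, inferior_frontal-supramarginal and
#' supramarginal-lateral_temporal, deduplicated, as canonical edge
#' labels. These are the edges force-included in the feature space
#' regardless of the mean-connectivity threshold.
#' @param atlas an `atlas_spec` defining the three groups.
#' @return character vector of canonical edge labels (atlas edge order).
#' @export
slf_edge_set <- function(atlas) {
  validate_atlas(atlas)
  need <- c("inferior_frontal", "lateral_temporal", "supramarginal")
  miss <- setdiff(need, names(atlas$region_groups))
  if (length(miss)) stopf("atlas is missing region group(s): %s",
                          paste(miss, collapse = ", "))
  g <- atlas$region_groups
  pairs <- rbind(
    expand.grid(a = g$inferior_frontal, b = g$lateral_temporal,
                stringsAsFactors = FALSE),
    expand.grid(a = g$inferior_frontal, b = g$supramarginal,
                stringsAsFactors = FALSE),
    expand.grid(a = g$supramarginal, b = g$lateral_temporal,
                stringsAsFactors = FALSE))
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  labs <- unique(edge_label(pairs$a, pairs$b, atlas$region_ids))
  labs[order(match(labs, edge_labels_for(atlas)))]
}

#' Threshold the feature space and force-include an edge set
#'
#' Retains every edge whose cohort mean weight is at least
#' `mean_threshold` (the boundary is kept: only strictly smaller means
#' are removed), plus every `forced` edge regardless of its mean.
#' Provenance flags record which rule admitted each edge.
#' @param fm a `feature_matrix` over the candidate edge universe.
#' @param mean_threshold nonnegative scalar, default 1.
#' @param forced character vector of canonical edge labels to keep
#'   unconditionally; must exist in `fm`.
#' @return a reduced `feature_matrix`.
#' @export
threshold_and_force <- function(fm, mean_threshold = 1, forced = character(0)) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (mean_threshold < 0) stopf("mean_threshold must be >= 0")
  missing_f <- setdiff(forced, fm$edge_labels)
  if (length(missing_f))
    stopf("forced edges absent from the edge universe: %s",
          paste(utils::head(missing_f, 5), collapse = ", "))
  mu <- colMeans(fm$values)
  survived <- mu >= mean_threshold
  is_forced <- fm$edge_labels %in% forced
  keep <- survived | is_forced
  if (!any(keep)) stopf("thresholding removed every edge")
  feature_matrix(fm$values[, keep, drop = FALSE],
                 fm$subject_ids, fm$edge_labels[keep],
                 survived_threshold = survived[keep],
                 forced_slf = is_forced[keep])
}

#' Write a feature matrix and its provenance sidecar
#'
#' `features.tsv` holds the subjects-by-edges table (edge labels as
#' column headers); `features_provenance.tsv` records per-edge flags.
#' @param fm a `feature_matrix`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_feature_matrix <- function(fm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(fm$values, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  prov <- data.frame(edge = fm$edge_labels,
                     survived_threshold = fm$survived_threshold,
                     forced_slf = fm$forced_slf)
  utils::write.table(prov, file.path(dir, "features_provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
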