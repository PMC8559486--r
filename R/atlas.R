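#' Generate a synthetic brain atlas
#'
#' Builds an atlas of labelled regions with spatial coordinates, positive
#' volumes and three named region groups. The groups play the role of the
#' perisylvian cortical territories whose cross-group connections define
#' the forced-inclusion superior-longitudinal-fasciculus (SLF) edge set:
#' `inferior_frontal`, `lateral_temporal` and `supramarginal`.
#'
#' Coordinates are uniform on a 100-unit cube; volumes are log-normal
#' (meanlog `log(1500)`, sdlog 0.35), right-skewed like parcel volumes in
#' fine-grained parcellations. Each group collects the `max(2, round(n/20))`
#' regions nearest to one of three mutually distant anchor regions, so
#' groups are spatially coherent and disjoint.
#'
#' @param n_regions number of regions (>= 4); 192 mirrors fine-grained
#'   parcellations such as AICHA.
#' @param seed integer seed; identical seeds give identical atlases.
#' @return An object of class `atlas_spec`: list with `region_ids`,
#'   `region_coords` (n x 3 matrix), `region_volumes`, `region_groups`
#'   (named list of region-label vectors).
#' @export
generate_atlas <- function(n_regions = 192L, seed = 1L) {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 4)
    stopf("n_regions must be a single number >= 4 (got %s)", format(n_regions))
  n_regions <- as.integer(n_regions)

  rs <- local({
    set.seed(stage_seed(seed, "atlas"))
    coords <- matrix(stats::runif(n_regions * 3, 0, 100), ncol = 3)
    vols <- stats::rlnorm(n_regions, meanlog = log(1500), sdlog = 0.35)
    list(coords = coords, vols = vols)
  })
  ids <- sprintf("R%03d", seq_len(n_regions))
  rownames(rs$coords) <- ids
  names(rs$vols) <- ids

  group_size <- max(2L, as.integer(round(n_regions / 20)))
  # three anchors chosen greedily to be far apart (first region, then the
  # farthest from chosen anchors); groups are nearest-neighbour balls
  d <- as.matrix(stats::dist(rs$coords))
  anchors <- 1L
  for (k in 2:3) {
    mind <- apply(d[, anchors, drop = FALSE], 1, min)
    anchors <- c(anchors, which.max(mind))
  }
  group_names <- c("inferior_frontal", "lateral_temporal", "supramarginal")
  taken <- integer(0)
  groups <- stats::setNames(vector("list", 3), group_names)
  for (k in 1:3) {
    ord <- order(d[, anchors[k]])
    pick <- setdiff(ord, taken)[seq_len(group_size)]
    taken <- c(taken, pick)
    groups[[k]] <- ids[sort(pick)]
  }

  structure(
    list(region_ids = ids, region_coords = rs$coords,
         region_volumes = rs$vols, region_groups = groups),
    class = "atlas_spec")
}

validate_atlas <- function(atlas) {
  if (!inherits(atlas, "atlas_spec")) stopf("not an atlas_spec")
  if (anyDuplicated(atlas$region_ids)) stopf("atlas region labels must be unique")
  if (any(atlas$region_volumes <= 0)) stopf("atlas volumes must be strictly positive")
  bad <- setdiff(unlist(atlas$region_groups), atlas$region_ids)
  if (length(bad)) stopf("atlas groups reference unknown regions: %s",
                         paste(bad, collapse = ", "))
  invisible(atlas)
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat(sprintf("atlas_spec: %d regions, groups: %s\n",
              length(x$region_ids),
              paste(sprintf("%s (%d)", names(x$region_groups),
                            lengths(x$region_groups)), collapse = ", ")))
  invisible(x)
}
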