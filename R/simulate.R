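#' Per-edge lesion attenuation factors
#'
#' Models a contiguous (spherical) lesion in atlas coordinate space. Each
#' region at distance `d` from the lesion centre gets a retention factor
#' that ramps linearly from 0 at the centre to 1 at the lesion radius;
#' an edge retains the factor of its *nearer* endpoint. Because every
#' edge incident to a damaged region shares that endpoint's factor, edges
#' sharing lesion geometry receive correlated attenuation across subjects
#' — the collinearity that makes lesioned-cohort feature spaces hard.
#'
#' @param lesion_center numeric coordinate (same dimension as the atlas).
#' @param lesion_radius scalar >= 0; radius 0 means no lesion (all 1).
#' @param atlas an `atlas_spec`.
#' @return named numeric vector of factors in `[0, 1]`, one per edge in
#'   canonical (row-major lower-triangle) order.
#' @export
lesion_attenuation <- function(lesion_center, lesion_radius, atlas) {
  validate_atlas(atlas)
  if (lesion_radius < 0) stopf("lesion_radius must be >= 0")
  n <- length(atlas$region_ids)
  pr <- edge_pairs(n)
  labs <- edge_labels_for(atlas)
  if (lesion_radius == 0) {
    return(stats::setNames(rep(1, nrow(pr)), labs))
  }
  d <- sqrt(colSums((t(atlas$region_coords) - as.numeric(lesion_center))^2))
  g <- clamp01(d / lesion_radius)           # per-region retention
  f <- pmin(g[pr[, 1]], g[pr[, 2]])         # nearer endpoint governs the edge
  stats::setNames(as.numeric(f), labs)
}

#' Simulation configuration for a synthetic lesioned cohort
#'
#' Bundles the generative parameters for [simulate_cohort()]. Defaults
#' describe the package's reference cohort: log-normal baseline edge
#' weights around a shared template, one spherical lesion per subject,
#' and a behavioural outcome that is a noisy monotone function of the
#' retained integrity of a small planted edge set plus age and
#' months-post-stroke effects.
#'
#' @param n_subjects cohort size (>= 4).
#' @param atlas an `atlas_spec`.
#' @param planted_edges character vector of canonical edge labels whose
#'   integrity drives behaviour; `NULL` picks 8 edges spread over the
#'   atlas's cross-group (SLF-like) pairs.
#' @param baseline_weight_scale multiplies the shared weight template.
#' @param lesion_radius_range length-2 interval for the uniform lesion
#'   radius draw, in coordinate units (atlas cube is 100 units wide).
#' @param effect_size slope from planted-edge mean integrity to the
#'   latent behavioural score (0-1 scale).
#' @param subject_noise_sdlog SD (log scale) of the per-subject,
#'   per-edge multiplicative weight noise around the template.
#' @param pathway_noise_sdlog SD (log scale) of per-subject integrity
#'   factors on the planted edges, modelling coherent degradation of
#'   the critical pathway as a tract system (predictive edge sets in
#'   lesioned cohorts are strongly positively inter-correlated). The
#'   pathway is modelled as three branches (the planted edges split
#'   into three consecutive canonical-order segments, like the three
#'   segments of the SLF): each branch has its own integrity factor,
#'   correlated across branches through a shared trunk factor.
#' @param pathway_branch_cor correlation of the branch factors induced
#'   by the shared trunk (fraction of pathway variance that is common;
#'   default 0.4).
#' @param region_noise_sdlog SD (log scale) of per-subject, per-region
#'   measurement factors (probabilistic-tractography seeding
#'   efficiency): every edge's *observed* weight is multiplied by the
#'   factors of its two endpoint regions, correlating edges that share
#'   a region. These are measurement artifacts — behaviour depends on
#'   the true retained integrity, not on them.
#' @param noise_sd SD of the Gaussian noise on the latent score; the two
#'   test instruments additionally get independent noise of half this SD.
#' @param target_r2 if non-`NULL`, `noise_sd` is recalibrated so the
#'   planted signal explains this fraction of signal-plus-noise variance
#'   in the composite score.
#' @param covariate_effects c(age slope, months slope) on the latent scale.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 70L,
                              atlas = generate_atlas(192L, seed = seed),
                              planted_edges = NULL,
                              baseline_weight_scale = 1,
                              lesion_radius_range = c(15, 40),
                              effect_size = 0.55,
                              subject_noise_sdlog = 0.4,
                              pathway_noise_sdlog = 0.45,
                              pathway_branch_cor = 0.4,
                              region_noise_sdlog = 0.15,
                              noise_sd = 0.08,
                              target_r2 = NULL,
                              covariate_effects = c(age = 9e-4, months = -4e-4),
                              seed = 1L) {
  if (n_subjects < 4) stopf("n_subjects must be >= 4")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(lesion_radius_range) != 2L || any(lesion_radius_range < 0) ||
      diff(lesion_radius_range) < 0)
    stopf("lesion_radius_range must be a nondecreasing nonnegative interval")
  validate_atlas(atlas)
  if (is.null(planted_edges)) planted_edges <- default_planted_edges(atlas)
  universe <- edge_labels_for(atlas)
  missing_e <- setdiff(planted_edges, universe)
  if (length(missing_e))
    stopf("planted edges absent from atlas: %s", paste(missing_e, collapse = ", "))
  if (anyDuplicated(planted_edges)) stopf("planted edges must be distinct")
  structure(list(
    n_subjects = as.integer(n_subjects), atlas = atlas,
    planted_edges = planted_edges,
    baseline_weight_scale = baseline_weight_scale,
    lesion_radius_range = lesion_radius_range,
    effect_size = effect_size, subject_noise_sdlog = subject_noise_sdlog,
    pathway_noise_sdlog = pathway_noise_sdlog,
    pathway_branch_cor = pathway_branch_cor,
    region_noise_sdlog = region_noise_sdlog,
    noise_sd = noise_sd, target_r2 = target_r2,
    covariate_effects = covariate_effects, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Default planted edge set
#'
#' Picks `n_planted` edges evenly spaced along the canonical ordering of
#' the atlas's cross-group (SLF-like) edge set, so the planted signal is
#' spread over several distinct region pairs rather than one hub.
#' @param atlas an `atlas_spec`.
#' @param n_planted how many edges to plant.
#' @return character vector of canonical edge labels.
#' @export
default_planted_edges <- function(atlas, n_planted = 8L) {
  slf <- slf_edge_set(atlas)
  if (length(slf) <= n_planted) return(slf)
  idx <- unique(round(seq(1, length(slf), length.out = n_planted)))
  slf[idx]
}

#' Simulate a synthetic stroke cohort
#'
#' Each subject receives a baseline connectivity matrix (a shared
#' log-normal edge template times subject-level log-normal noise), one
#' spherical lesion with uniform centre and radius, and multiplicative
#' per-edge attenuation from [lesion_attenuation()]. Behaviour is
#' generated on a latent 0-1 scale as
#' `0.05 + effect_size * integrity + covariate effects + noise`, where
#' `integrity` is the mean, over the planted edges, of the fraction of
#' the template weight the subject retains on that edge (mean-one
#' individual and pathway variation times lesion attenuation) —
#' behaviour tracks the streamline weight actually remaining in the
#' critical pathway, not just lesion geometry;
#' the two instrument scores are clamped affine transforms of the latent
#' onto 0-10 and 0-175 scales (mirroring WAB-R repetition and PRT
#' maxima). Ages are uniform 30-80 years, months post-stroke uniform
#' 12-240.
#'
#' @param config a `simulation_config`.
#' @return list of class `cohort_bundle` with `matrices` (list of
#'   symmetric nonnegative matrices, zero diagonal), `covariates`
#'   (data.frame: subject_id, age, months_post), `behavior_raw`
#'   (data.frame: subject_id, score_a 0-10, score_b 0-175), and `truth`
#'   (planted edges, lesion centres/radii, per-subject integrity, the
#'   noise SD actually used).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  atlas <- config$atlas
  n <- config$n_subjects
  nr <- length(atlas$region_ids)
  pr <- edge_pairs(nr)
  labs <- edge_labels_for(atlas)
  p <- nrow(pr)
  planted_idx <- match(config$planted_edges, labs)

  set.seed(stage_seed(config$seed, "cohort"))
  # shared template: median 1 so the downstream mean-connectivity
  # threshold at 1 removes roughly half the edge universe
  template <- config$baseline_weight_scale *
    stats::rlnorm(p, meanlog = 0, sdlog = 1.1)
  age <- stats::runif(n, 30, 80)
  months <- stats::runif(n, 12, 240)
  centers <- matrix(stats::runif(n * ncol(atlas$region_coords), 0, 100),
                    nrow = n)
  radii <- stats::runif(n, config$lesion_radius_range[1],
                        config$lesion_radius_range[2])

  # per-subject branch integrity factors for the planted pathway: three
  # branches (consecutive canonical-order segments of the planted set)
  # degrade semi-independently around a shared trunk factor, so the
  # critical edges are mutually correlated but not rank-one
  n_br <- min(3L, length(planted_idx))
  branch_of <- rep(seq_len(n_br), length.out = length(planted_idx))
  branch_of <- sort(branch_of)
  kappa <- config$pathway_branch_cor
  trunk <- stats::rnorm(n)
  branch <- matrix(stats::rnorm(n * n_br), n, n_br)
  u <- config$pathway_noise_sdlog *
    (sqrt(kappa) * trunk + sqrt(1 - kappa) * branch)
  pathway_mult <- matrix(1, n, p)
  pathway_mult[, planted_idx] <- exp(u[, branch_of])

  factors <- matrix(NA_real_, n, p)
  weights <- matrix(NA_real_, n, p)
  true_retained <- matrix(NA_real_, n, p)
  # mean-one normaliser for the biological noise on each edge
  noise_mean <- exp((config$subject_noise_sdlog^2 +
                       ifelse(seq_len(p) %in% planted_idx,
                              config$pathway_noise_sdlog^2, 0)) / 2)
  for (s in seq_len(n)) {
    f <- lesion_attenuation(centers[s, ], radii[s], atlas)
    subj_noise <- stats::rlnorm(p, meanlog = 0,
                                sdlog = config$subject_noise_sdlog)
    region_fac <- stats::rnorm(nr, 0, config$region_noise_sdlog)
    edge_meas <- exp(region_fac[pr[, 1]] + region_fac[pr[, 2]])
    factors[s, ] <- f
    true_retained[s, ] <- subj_noise * pathway_mult[s, ] * f / noise_mean
    weights[s, ] <- template * subj_noise * pathway_mult[s, ] *
      edge_meas * f
  }
  integrity <- rowMeans(true_retained[, planted_idx, drop = FALSE])

  signal <- config$effect_size * integrity
  cov_part <- config$covariate_effects[[1]] * age +
    config$covariate_effects[[2]] * months
  eps_latent <- stats::rnorm(n)
  eps_a <- stats::rnorm(n)
  eps_b <- stats::rnorm(n)
  make_scores <- function(noise_sd) {
    latent <- 0.05 + signal + cov_part + noise_sd * eps_latent
    list(a = 10 * clamp01(latent + noise_sd / 2 * eps_a),
         b = 175 * clamp01(latent + noise_sd / 2 * eps_b))
  }
  noise_sd <- config$noise_sd
  if (!is.null(config$target_r2)) {
    # calibrate the noise scale so the REALISED squared correlation
    # between planted integrity and the covariate-adjusted composite
    # equals target_r2 (clamping and instrument noise both eat signal,
    # so a closed-form noise variance would overshoot)
    realized <- function(s) {
      sc <- make_scores(s)
      comp <- (sc$a / 10 + sc$b / 175) / 2
      adj <- stats::lm.fit(cbind(1, age, months), comp)$residuals
      stats::cor(integrity, adj)^2 - config$target_r2
    }
    hi <- stats::sd(signal) * 5 + 1e-6
    noise_sd <- if (realized(0) < 0) 0 else
      stats::uniroot(realized, c(1e-9, hi), extendInt = "downX")$root
  }
  sc <- make_scores(noise_sd)
  score_a <- sc$a
  score_b <- sc$b

  ids <- sprintf("S%03d", seq_len(n))
  matrices <- lapply(seq_len(n), function(s) {
    m <- matrix(0, nr, nr, dimnames = list(atlas$region_ids, atlas$region_ids))
    m[pr] <- weights[s, ]
    m[pr[, c(2, 1)]] <- weights[s, ]
    m
  })
  names(matrices) <- ids

  structure(list(
    matrices = matrices,
    covariates = data.frame(subject_id = ids, age = age, months_post = months),
    behavior_raw = data.frame(subject_id = ids, score_a = score_a,
                              score_b = score_b),
    truth = list(planted_edges = config$planted_edges,
                 lesion_centers = centers, lesion_radii = radii,
                 integrity = stats::setNames(integrity, ids),
                 noise_sd_used = noise_sd),
    atlas = atlas),
    class = "cohort_bundle")
}

#' Reference synthetic benchmark configuration
#'
#' The cohort on which the package's recovery and calibration properties
#' are assessed: 70 subjects, a 25-region atlas (300 candidate edges),
#' 8 planted edges, and noise calibrated so the planted signal explains
#' about 60% of the composite's signal-plus-noise variance.
#' @param seed integer seed.
#' @return a `simulation_config`.
#' @export
benchmark_config <- function(seed = 1L) {
  atlas <- generate_atlas(25L, seed = seed)
  simulation_config(
    n_subjects = 70L, atlas = atlas,
    planted_edges = default_planted_edges(atlas, 8L),
    lesion_radius_range = c(8, 18),
    effect_size = 0.55, target_r2 = 0.6,
    subject_noise_sdlog = 0.25, pathway_noise_sdlog = 0.55,
    pathway_branch_cor = 0.45, region_noise_sdlog = 0.12, seed = seed)
}

#' Write a cohort bundle as plain-text tables
#'
#' One tab-delimited matrix per subject (`matrix_<id>.tsv`, region labels
#' as header row and first column), a `subjects.tsv` with covariates and
#' raw behaviour, and `truth.json`.
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(bundle$matrices)) {
    utils::write.table(bundle$matrices[[id]],
                       file.path(dir, sprintf("matrix_%s.tsv", id)),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  subj <- merge(bundle$covariates, bundle$behavior_raw, by = "subject_id")
  utils::write.table(subj, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(planted_edges = bundle$truth$planted_edges,
         lesion_radii = bundle$truth$lesion_radii,
         integrity = as.numeric(bundle$truth$integrity),
         noise_sd_used = bundle$truth$noise_sd_used),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read per-subject connectivity matrices from a directory
#'
#' Reads every `matrix_*.tsv` written by [write_cohort()] and validates
#' symmetry and nonnegativity.
#' @param dir directory containing the matrices.
#' @return named list of matrices, in subject-id order.
#' @export
read_cohort_matrices <- function(dir) {
  files <- sort(list.files(dir, pattern = "^matrix_.*\\.tsv$", full.names = TRUE))
  if (!length(files)) stopf("no matrix_*.tsv files in %s", dir)
  out <- lapply(files, function(f) {
    m <- as.matrix(utils::read.table(f, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    as_connectivity_matrix(m)
  })
  names(out) <- sub("^matrix_(.*)\\.tsv$", "\\1", basename(files))
  out
}
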