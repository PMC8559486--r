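# Independent reference implementations used as oracles. These are
# deliberately literal and share no code with the package internals.

# Dense PLS1: classical NIPALS recursion, standardised in/out, with
# sequential-component prediction for new data.
ref_pls1 <- function(X, y, H) {
  n <- nrow(X)
  xc <- colMeans(X); xs <- apply(X, 2, sd)
  yc <- mean(y); ys <- sd(y)
  Xh <- sweep(sweep(X, 2, xc), 2, xs, "/")
  yh <- (y - yc) / ys
  Ws <- list(); Ps <- list(); qs <- c(); Ts <- list()
  for (h in seq_len(H)) {
    z <- t(Xh) %*% yh
    w <- z / sqrt(sum(z^2))
    t_ <- Xh %*% w
    ss <- sum(t_^2)
    p_ <- t(Xh) %*% t_ / ss
    q_ <- sum(yh * t_) / ss
    Ws[[h]] <- w; Ps[[h]] <- p_; qs[h] <- q_; Ts[[h]] <- t_
    Xh <- Xh - t_ %*% t(p_)
    yh <- yh - q_ * t_
  }
  fitted_std <- Reduce(`+`, Map(function(t_, q_) q_ * t_, Ts, qs))
  predict_ref <- function(Xnew) {
    Xn <- sweep(sweep(Xnew, 2, xc), 2, xs, "/")
    acc <- numeric(nrow(Xnew))
    for (h in seq_len(H)) {
      t_ <- Xn %*% Ws[[h]]
      acc <- acc + qs[h] * drop(t_)
      Xn <- Xn - t_ %*% t(Ps[[h]])
    }
    yc + ys * acc
  }
  list(fitted = yc + ys * drop(fitted_std),
       W = do.call(cbind, Ws), q = qs, predict = predict_ref)
}

# VIP by direct formula evaluation from a fitted model's pieces.
ref_vip <- function(W, q, tt, ncomp) {
  p <- nrow(W)
  ss <- q[1:ncomp]^2 * tt[1:ncomp]
  sapply(seq_len(p), function(j) {
    sqrt(p * sum(ss * W[j, 1:ncomp]^2) / sum(ss))
  })
}

# One-tailed upper tail probability of Student's t by numerical
# integration of the density.
ref_t_tail <- function(tval, df) {
  integrate(function(x) dt(x, df), lower = tval, upper = Inf,
            rel.tol = 1e-10)$value
}

# Tiny deterministic cohort for IO/pipeline tests.
small_cohort <- function(seed = 1, n_subjects = 24, n_regions = 12) {
  atlas <- generate_atlas(n_regions, seed = seed)
  cfg <- simulation_config(
    n_subjects = n_subjects, atlas = atlas,
    planted_edges = default_planted_edges(atlas, 4L),
    lesion_radius_range = c(10, 25), target_r2 = 0.6, seed = seed)
  simulate_cohort(cfg)
}
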