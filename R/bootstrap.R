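#' Bootstrap-VIP configuration
#'
#' @param n_boot number of bootstrap resamples B (the reference
#'   protocol uses 8,000; smaller values are adequate for desk-scale
#'   cohorts — selection frequencies stabilise well before that).
#' @param vip_threshold candidate edges need mean component-1 VIP
#'   strictly greater than this (default 1, the conventional relevance
#'   cutoff).
#' @param freq_threshold candidate edges need selection frequency
#'   strictly greater than this (default 0.5: survive the penalty on a
#'   majority of resamples).
#' @param retune_each_iteration re-run the full keepX cross-validation
#'   grid inside every resample (`TRUE` mirrors replicating the whole
#'   tuning procedure; `FALSE`, the default, reuses the keepX tuned once
#'   on the full training set).
#' @param seed integer seed.
#' @return list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 8000L, vip_threshold = 1,
                             freq_threshold = 0.5,
                             retune_each_iteration = FALSE, seed = 1L) {
  if (n_boot < 1) stopf("n_boot must be >= 1")
  if (vip_threshold < 0) stopf("vip_threshold must be >= 0")
  if (freq_threshold < 0 || freq_threshold > 1)
    stopf("freq_threshold must be in [0, 1]")
  structure(list(n_boot = as.integer(n_boot), vip_threshold = vip_threshold,
                 freq_threshold = freq_threshold,
                 retune_each_iteration = isTRUE(retune_each_iteration),
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Bootstrap-VIP stability selection
#'
#' Replicates the tuned sPLS fit over `n_boot` bootstrap resamples
#' (subjects drawn with replacement at full training size) and records,
#' per edge, the component-1 VIP (`sqrt(p) * |w_1|`) and an indicator of
#' surviving the sparsity penalty (nonzero component-1 weight). Edges
#' not selected in an iteration contribute VIP 0 to the mean, so the
#' mean VIP jointly reflects magnitude and stability. Resamples with
#' zero outcome variance are redrawn (counted in the result).
#' @param X_train,y_train training data (>= 10 subjects).
#' @param spls_config an [spls_config()].
#' @param boot_config a [bootstrap_config()].
#' @param keepX optional pre-tuned keepX; if `NULL` and
#'   `retune_each_iteration` is `FALSE`, keepX is tuned once on the full
#'   training set first.
#' @param tune_rule cross-validation selection rule passed to
#'   [tune_keepX()] wherever tuning happens.
#' @return list of class `bootstrap_vip_result`: `table` (data.frame
#'   edge / mean_vip / frequency), `n_boot`, `keepX`, `n_redraws`.
#' @export
bootstrap_vip <- function(X_train, y_train, spls_config = spls_config(),
                          boot_config = bootstrap_config(), keepX = NULL,
                          tune_rule = c("1se", "min")) {
  tune_rule <- match.arg(tune_rule)
  stopifnot(is.matrix(X_train), length(y_train) == nrow(X_train))
  n <- nrow(X_train); p <- ncol(X_train)
  if (n < 10) stopf("need at least 10 training subjects")
  if (is.null(keepX) && !boot_config$retune_each_iteration) {
    keepX <- tune_keepX(X_train, y_train, spls_config, rule = tune_rule)$keepX
  }
  set.seed(stage_seed(boot_config$seed, "bootstrap_vip"))
  vip_sum <- numeric(p)
  sel_sum <- numeric(p)
  n_redraws <- 0L
  sqp <- sqrt(p)
  for (b in seq_len(boot_config$n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(y_train[idx]) > 0) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 1000L) stopf("outcome degenerate under resampling")
    }
    kx <- keepX
    if (boot_config$retune_each_iteration) {
      cfg_b <- spls_config
      cfg_b$seed <- stage_seed(boot_config$seed, paste0("retune", b))
      kx <- tune_keepX(X_train[idx, , drop = FALSE], y_train[idx], cfg_b,
                       rule = tune_rule)$keepX
    }
    fit <- fit_spls(X_train[idx, , drop = FALSE], y_train[idx], keepX = kx,
                    n_components = spls_config$n_components,
                    allow_constant = TRUE)
    w1 <- fit$W[, 1]
    vip_sum <- vip_sum + sqp * abs(w1)   # component-1 VIP; 0 when unselected
    sel_sum <- sel_sum + (w1 != 0)
  }
  structure(list(
    table = data.frame(edge = colnames(X_train) %||% sprintf("E%05d", seq_len(p)),
                       mean_vip = vip_sum / boot_config$n_boot,
                       frequency = sel_sum / boot_config$n_boot,
                       stringsAsFactors = FALSE),
    n_boot = boot_config$n_boot, keepX = keepX, n_redraws = n_redraws),
    class = "bootstrap_vip_result")
}

#' @export
print.bootstrap_vip_result <- function(x, ...) {
  top <- x$table[order(-x$table$mean_vip), ][1:min(5, nrow(x$table)), ]
  cat(sprintf("bootstrap_vip_result: B = %d, keepX = %s; top edges:\n",
              x$n_boot, x$keepX %||% "per-iteration"))
  print(top, row.names = FALSE)
  invisible(x)
}

#' Select candidate edges from a bootstrap-VIP result
#'
#' Keeps edges whose bootstrap mean component-1 VIP exceeds
#' `vip_threshold` *and* whose selection frequency exceeds
#' `freq_threshold`, ranked by mean VIP descending (ties broken by edge
#' label). An empty candidate set is a valid outcome.
#' @param result a `bootstrap_vip_result`.
#' @param boot_config the thresholds to apply.
#' @return data.frame of class `candidate_set` (edge, mean_vip,
#'   frequency), with thresholds in attributes.
#' @export
select_candidates <- function(result, boot_config = bootstrap_config()) {
  stopifnot(inherits(result, "bootstrap_vip_result"))
  tb <- result$table
  keep <- tb$mean_vip > boot_config$vip_threshold &
    tb$frequency > boot_config$freq_threshold
  out <- tb[keep, , drop = FALSE]
  out <- out[order(-out$mean_vip, out$edge), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("candidate_set", "data.frame"),
            vip_threshold = boot_config$vip_threshold,
            freq_threshold = boot_config$freq_threshold)
}
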