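#' @keywords internal
"_PACKAGE"

# Deterministic per-stage seed derived from a global seed and a stage tag,
# so a stage rerun in isolation reproduces its in-pipeline draws.
# Kept below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 1000003L
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483647)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
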