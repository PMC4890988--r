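# Internal helpers shared across modules.

# Floor below which p-values are clamped before taking logs. Keeps Fisher
# scores finite while preserving the ordering of extremely small p-values.
P_FLOOR <- 1e-300

pi_abort <- function(msg, class = "pathintegrate_error", ...) {
  abort(msg, class = c(class, "pathintegrate_error"), ...)
}

#' Deterministic RNG substream seed
#'
#' Derives a 31-bit seed from a base seed and a character label, so that each
#' pathway (or simulation stage) draws from its own reproducible substream.
#' Results are then invariant to evaluation order.
#'
#' @param seed Integer base seed.
#' @param id Character label (e.g. a pathway id).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, id) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(id))) {
    h <- (h * 31 + ch) %% m
  }
  s <- ((as.double(seed) %% m) * 48271) %% m
  as.integer(((h * 65537) %% m + s) %% m)
}

# Clamp p-values into (0, 1] for log transforms; errors on values outside
# [0, 1].
clamp_pvalues <- function(p, what = "p-value") {
  p <- as.double(p)
  if (anyNA(p)) {
    pi_abort(paste0(what, "s must not be NA"), class = "pathintegrate_error_domain")
  }
  if (any(p < 0 | p > 1)) {
    pi_abort(
      paste0(what, "s must lie in [0, 1]; offending value: ",
             format(p[which(p < 0 | p > 1)[1]])),
      class = "pathintegrate_error_domain"
    )
  }
  pmax(p, P_FLOOR)
}

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || is.na(x) || x < min || x != as.integer(x)) {
    pi_abort(
      sprintf("`%s` must be a single integer >= %d", name, min),
      class = "pathintegrate_error_config"
    )
  }
  invisible(as.integer(x))
}

assert_proportion <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    pi_abort(
      sprintf("`%s` must be a single value in [0, 1]", name),
      class = "pathintegrate_error_config"
    )
  }
  invisible(as.double(x))
}

assert_range <- function(x, name, lo = -Inf, hi = Inf) {
  if (length(x) != 2 || anyNA(x) || x[1] > x[2] || x[1] < lo || x[2] > hi) {
    pi_abort(
      sprintf("`%s` must be a non-empty range within [%s, %s]", name,
              format(lo), format(hi)),
      class = "pathintegrate_error_config"
    )
  }
  invisible(x)
}
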