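# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a classed condition
#'
#' All user-facing errors raised by the package carry a condition class of the
#' form `brewtrace_<what>` so callers and tests can distinguish failure modes.
#' @noRd
bt_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("brewtrace_", class), "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

bt_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

#' Derive a child RNG seed from a base seed
#'
#' Keeps derived seeds strictly below 2^31 so they remain valid R integers.
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 + 97 * as.numeric(k)) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Linear-interpolated percentile (type 7), exposed for reproducibility
#' @noRd
pct_linear <- function(x, p) {
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    bt_stop("config", "'%s' must be a scalar in [%g, %g]", name, lo, hi)
  invisible(x)
}
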