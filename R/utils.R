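#' @keywords internal
"_PACKAGE"

# Small shared helpers. Validation errors are thrown with informative
# messages; all user-facing checks funnel through these.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nf <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_nf("'%s' must be TRUE or FALSE", name)
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_nf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_nf("'%s' must be a single number in [%s, %s]", name,
            format(min), format(max))
  as.numeric(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
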