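#' @keywords internal
"_PACKAGE"

#' @useDynLib orientspim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils write.csv read.csv
NULL

## Classed error helpers: every user-facing failure carries a condition class
## so callers (and the CLI exit-code mapping) can dispatch on it.
stop_orientspim <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "orientspim_error"), call = call))
}

stop_invalid_parameter <- function(msg) {
  stop_orientspim(msg, "orientspim_invalid_parameter")
}

stop_invalid_input <- function(msg) {
  stop_orientspim(msg, "orientspim_invalid_input")
}

## Deterministic substream seeds: all randomness in the package flows from one
## master seed through this map.  Kept strictly below 2^31 - 1.
derive_seed <- function(master, stream) {
  s <- (as.double(master) %% 2147483647) * 48271 + as.double(stream) * 1009
  as.integer(s %% 2147483629) + 1L
}

## Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards so package internals never clobber a user's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

check_positive_scalar <- function(x, name, allow_inf = FALSE) {
  if (!is_scalar_number(x) || x <= 0 || (!allow_inf && !is.finite(x))) {
    stop_invalid_parameter(sprintf("`%s` must be a positive finite scalar", name))
  }
  invisible(x)
}
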