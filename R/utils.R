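# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Classed errors so callers can distinguish failure modes programmatically.
sw_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "sw_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All stochastic package code funnels through
# this so a single master seed makes runs bit-reproducible.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic child seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  x <- as.numeric(seed)
  for (o in offs) x <- (x * 69069 + as.numeric(o) + 1) %% 2147483399
  as.integer(x) + 1L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(x, what) {
  if (!is_scalar_number(x))
    sw_abort(sprintf("%s must be a single finite number", what), "sw_validation_error")
  invisible(x)
}
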