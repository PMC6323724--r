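# Shared internal helpers: error signalling, seeded evaluation, small checks.

#' Signal a classed septinevo error
#'
#' All user-facing validation failures carry a specific condition class
#' (e.g. "septinevo_invalid_input") plus the umbrella class
#' "septinevo_error", so callers can distinguish failure modes.
#' @noRd
abort <- function(message, class = "septinevo_invalid_input") {
  stop(errorCondition(message, class = c(class, "septinevo_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores (or removes) the global .Random.seed afterwards so generators
#' never leak random state; this is what makes every simulate_* call a
#' pure function of (arguments, seed).
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer", "septinevo_invalid_parameter")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name),
          "septinevo_invalid_parameter")
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    abort(sprintf("`%s` must be %s %s", name,
                  if (strict) ">" else ">=", lower),
          "septinevo_invalid_parameter")
  }
  invisible(x)
}

#' The 20 standard amino acids (alphabetical one-letter codes)
#' @noRd
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Derive a stream-specific seed from a master seed.
#' Keeps derived seeds well inside 32-bit integer range.
#' @noRd
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}
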