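## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a fraction that may carry a percent suffix
#'
#' Fractions are stored on the `[0, 1]` scale throughout the package; percent
#' notation is accepted only at input boundaries. A character value ending in
#' `"%"` is divided by 100; any other character value is parsed as a plain
#' number.
#'
#' @param x Numeric, or character such as `"38%"` or `"0.38"`.
#' @param what Field name used in error messages.
#' @return A numeric vector of fractions.
#' @examples
#' parse_fraction("38%")  # 0.38
#' parse_fraction(0.38)
#' @export
parse_fraction <- function(x, what = "value") {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  out <- suppressWarnings(as.numeric(sub("%$", "", x)))
  if (anyNA(out)) {
    stop(sprintf("%s: cannot parse '%s' as a number", what,
                 paste(x[is.na(out)], collapse = "', '")), call. = FALSE)
  }
  out[pct] <- out[pct] / 100
  out
}

# Domain check naming the offending field, as the model operations require.
check_range <- function(x, what, lo = 0, hi = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi)) {
    stop(sprintf("%s must be in [%g, %g] (got %s)", what, lo, hi,
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb user scripts.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed derivation: n sub-streams from one master seed.
# Documented so that panels and paired generators are reproducible.
derive_subseeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
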