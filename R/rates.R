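#' Per-generation conversion coefficients
#'
#' Bundle the two coefficients of the two-state variegation model:
#' `c_sa`, the probability per generation that a silenced locus converts to
#' the active state (S->A), and `c_as`, the probability of the reverse
#' conversion (A->S). Both are probabilities and must lie in `[0, 1]`; the
#' model places no other constraint on them and they are independent of each
#' other and of the current population composition.
#'
#' Values may be given as fractions or as percent strings (`"8%"`), which are
#' divided by 100 on input. When `c_sa + c_as > 1` the deterministic approach
#' to equilibrium is oscillatory (the retention factor `1 - c_sa - c_as` is
#' negative); this is mathematically admissible and accepted with a warning.
#'
#' @param c_sa Silent-to-active conversion probability per generation.
#' @param c_as Active-to-silent conversion probability per generation.
#' @return An object of class `conversion_rates`: a list with fields `c_sa`
#'   and `c_as` stored as fractions.
#' @examples
#' conversion_rates(0.08, 0.063)
#' conversion_rates("8%", "6.3%")
#' @export
conversion_rates <- function(c_sa, c_as) {
  c_sa <- parse_fraction(c_sa, "c_sa")
  c_as <- parse_fraction(c_as, "c_as")
  stopifnot(length(c_sa) == 1L, length(c_as) == 1L)
  check_range(c_sa, "c_sa")
  check_range(c_as, "c_as")
  if (c_sa + c_as > 1) {
    warning("c_sa + c_as > 1: the approach to equilibrium is oscillatory",
            call. = FALSE)
  }
  structure(list(c_sa = c_sa, c_as = c_as), class = "conversion_rates")
}

# Accept a conversion_rates object, a length-2 numeric, or a 2-element list.
as_conversion_rates <- function(x) {
  if (inherits(x, "conversion_rates")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(conversion_rates(x[1], x[2]))
  if (is.list(x) && all(c("c_sa", "c_as") %in% names(x))) {
    return(conversion_rates(x$c_sa, x$c_as))
  }
  stop("cannot interpret input as conversion rates", call. = FALSE)
}

#' @export
print.conversion_rates <- function(x, ...) {
  cat(sprintf("Conversion rates: c_sa (S->A) = %g%%, c_as (A->S) = %g%% per generation\n",
              100 * x$c_sa, 100 * x$c_as))
  invisible(x)
}

#' @export
format.conversion_rates <- function(x, ...) {
  sprintf("c_sa=%g c_as=%g", x$c_sa, x$c_as)
}
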