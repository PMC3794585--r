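#' One generation of the two-state conversion recurrence
#'
#' Advance the active-cell fraction by one generation:
#' `y' = y - y * c_as + (1 - y) * c_sa`. The update maps `[0, 1]` into
#' `[0, 1]` for any valid rates, and the coefficients do not depend on the
#' current composition of the population.
#'
#' @param y_a Fraction of cells with the active gene, in `[0, 1]`. Vectorised.
#' @param rates A [conversion_rates()] object (or length-2 numeric).
#' @return The active fraction after one generation.
#' @examples
#' pev_step(0, conversion_rates(0.15, 0.06))  # 0.15
#' @export
pev_step <- function(y_a, rates) {
  rates <- as_conversion_rates(rates)
  check_range(y_a, "y_a")
  y_a - y_a * rates$c_as + (1 - y_a) * rates$c_sa
}

#' Deterministic trajectory of the active fraction
#'
#' Iterate [pev_step()] from an initial active fraction `y0` for `n_gens`
#' generations. `y0 = 1` corresponds to prior selection for the active state
#' (e.g. uracil dropout for a URA3 reporter) and `y0 = 0` to selection for the
#' silenced state (5-FOA).
#'
#' @param y0 Initial active fraction in `[0, 1]`.
#' @param rates A [conversion_rates()] object.
#' @param n_gens Number of generations (non-negative integer).
#' @return An object of class `pev_trajectory`: a list with `y0`, `rates`, and
#'   a data frame `values` with columns `generation` (0..n_gens) and `y_a`.
#' @examples
#' tr <- pev_trajectory(0, conversion_rates(0.15, 0.06), 20)
#' tail(as.data.frame(tr), 1)  # y_a approx 0.7079
#' @export
pev_trajectory <- function(y0, rates, n_gens) {
  rates <- as_conversion_rates(rates)
  check_range(y0, "y0")
  if (length(n_gens) != 1L || is.na(n_gens) || n_gens < 0 ||
      n_gens != floor(n_gens)) {
    stop("n_gens must be a non-negative integer", call. = FALSE)
  }
  y <- numeric(n_gens + 1L)
  y[1L] <- y0
  if (n_gens > 0) {
    for (i in seq_len(n_gens)) {
      y[i + 1L] <- y[i] - y[i] * rates$c_as + (1 - y[i]) * rates$c_sa
    }
  }
  structure(list(y0 = y0, rates = rates,
                 values = data.frame(generation = 0:n_gens, y_a = y)),
            class = "pev_trajectory")
}

#' @export
as.data.frame.pev_trajectory <- function(x, ...) x$values

#' @export
print.pev_trajectory <- function(x, ...) {
  cat(sprintf("Two-state conversion trajectory: y0 = %g, %s, %d generations\n",
              x$y0, format(x$rates), nrow(x$values) - 1L))
  cat(sprintf("final active fraction: %.6f\n", x$values$y_a[nrow(x$values)]))
  invisible(x)
}

#' Closed-form solution of the conversion recurrence
#'
#' The recurrence is linear; its solution is
#' `Y_n = Y* + (y0 - Y*) * lambda^n` with equilibrium
#' `Y* = c_sa / (c_sa + c_as)` and retention factor
#' `lambda = 1 - c_sa - c_as`. When both rates are zero the state is frozen
#' and `y0` is returned for every `n`. Non-integer `n` is accepted and
#' answered by the same expression, i.e. as a smooth interpolation between
#' generations (only meaningful when `lambda >= 0`).
#'
#' @inheritParams pev_trajectory
#' @param n Generation number(s), real and non-negative. Vectorised.
#' @return The active fraction(s) at generation `n`.
#' @examples
#' pev_closed_form(1, conversion_rates(0.01, 0.01), 15)  # 0.8693
#' @export
pev_closed_form <- function(y0, rates, n) {
  rates <- as_conversion_rates(rates)
  check_range(y0, "y0")
  if (any(n < 0)) stop("n must be non-negative", call. = FALSE)
  s <- rates$c_sa + rates$c_as
  if (s == 0) return(rep(y0, length(n)))
  y_star <- rates$c_sa / s
  lam <- 1 - s
  if (lam < 0 && any(n != floor(n))) {
    stop("non-integer generations are undefined when c_sa + c_as > 1",
         call. = FALSE)
  }
  y_star + (y0 - y_star) * lam^n
}

#' Equilibrium of the two-state conversion model
#'
#' The fixed point of the recurrence is `Y* = c_sa / (c_sa + c_as)`,
#' independent of the initial condition, and deviations from it shrink by the
#' retention factor `lambda = 1 - c_sa - c_as` each generation. No unique
#' equilibrium exists when both rates are zero (every state is frozen).
#'
#' @param rates A [conversion_rates()] object.
#' @return An object of class `pev_equilibrium`: list with `y_star` (active
#'   fraction at equilibrium, `NA` if none), `retention` (lambda), and
#'   `exists` (logical).
#' @seealso [equilibrium_fraction()] for direct access with an error when no
#'   equilibrium exists.
#' @examples
#' pev_equilibrium(conversion_rates(0.15, 0.06))  # y_star = 5/7
#' @export
pev_equilibrium <- function(rates) {
  rates <- as_conversion_rates(rates)
  s <- rates$c_sa + rates$c_as
  structure(list(
    y_star = if (s > 0) rates$c_sa / s else NA_real_,
    retention = 1 - s,
    exists = s > 0
  ), class = "pev_equilibrium")
}

#' @export
print.pev_equilibrium <- function(x, ...) {
  if (x$exists) {
    cat(sprintf("Equilibrium active fraction Y* = %.6f (silenced %.1f%%), retention factor lambda = %.4f\n",
                x$y_star, 100 * (1 - x$y_star), x$retention))
  } else {
    cat("No unique equilibrium: both conversion rates are zero (states frozen)\n")
  }
  invisible(x)
}

#' @rdname pev_equilibrium
#' @export
equilibrium_fraction <- function(rates) {
  eq <- pev_equilibrium(rates)
  if (!eq$exists) {
    stop("no unique equilibrium: both conversion rates are zero", call. = FALSE)
  }
  eq$y_star
}

#' Generations needed to reach equilibrium
#'
#' Smallest integer generation `n` at which the deterministic trajectory is
#' within `tol` of the equilibrium active fraction from every starting point
#' in `y0_set`. The default convention ("within 2 percentage points from both
#' a fully silenced and a fully active start") mirrors the dual-selection
#' design, where cultures are established from both prior FOA selection
#' (`y0 = 0`) and prior uracil-dropout selection (`y0 = 1`).
#'
#' Computed by inverting the closed form,
#' `n = ceiling(log(tol / |y0 - Y*|) / log(lambda))`, with an exact
#' first-passage adjustment against the geometric deviation decay and an
#' iterative fallback when the retention factor is non-positive.
#'
#' @param rates A [conversion_rates()] object.
#' @param tol Absolute tolerance on the active fraction (default 0.02).
#' @param y0_set Starting active fractions (default `c(0, 1)`).
#' @return Integer number of generations.
#' @examples
#' generations_to_equilibrium(conversion_rates(0.15, 0.06))  # 16
#' generations_to_equilibrium(conversion_rates(0.01, 0.01))  # 160
#' @export
generations_to_equilibrium <- function(rates, tol = 0.02, y0_set = c(0, 1)) {
  rates <- as_conversion_rates(rates)
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    stop("tol must be a positive fraction", call. = FALSE)
  }
  check_range(y0_set, "y0_set")
  eq <- pev_equilibrium(rates)
  if (!eq$exists) {
    stop("no unique equilibrium: both conversion rates are zero", call. = FALSE)
  }
  lam <- eq$retention
  first_passage <- function(y0) {
    d0 <- abs(y0 - eq$y_star)
    if (d0 <= tol) return(0L)
    if (abs(lam) >= 1) {
      stop("never converges: |retention factor| = 1 with a start outside the tolerance band",
           call. = FALSE)
    }
    if (lam <= 0) {
      # oscillatory (or single-jump) regime: deviations still shrink
      # geometrically in |lambda|; iterate the decay directly
      n <- 0L
      d <- d0
      while (d > tol) {
        d <- d * abs(lam)
        n <- n + 1L
      }
      return(n)
    }
    n <- max(0, ceiling(log(tol / d0) / log(lam)))
    # floating-point guard: pin down the true first passage
    while (n > 0 && d0 * lam^(n - 1) <= tol) n <- n - 1
    while (d0 * lam^n > tol) n <- n + 1
    as.integer(n)
  }
  max(vapply(y0_set, first_passage, integer(1)))
}

#' Generation number from optical density readings
#'
#' Number of population doublings between two OD600 readings of the same
#' culture: `log2(od_final / od_initial)`. A 1000-fold regrowth corresponds to
#' just under 10 doublings.
#'
#' @param od_initial,od_final Positive OD600 readings, `od_final >= od_initial`.
#' @return Real number of generations.
#' @examples
#' od_to_generations(0.001, 1.024)  # 10
#' @export
od_to_generations <- function(od_initial, od_final) {
  if (any(od_initial <= 0) || any(od_final <= 0)) {
    stop("OD600 readings must be positive", call. = FALSE)
  }
  if (any(od_final < od_initial)) {
    stop("od_final must be >= od_initial (no growth decline modelled)",
         call. = FALSE)
  }
  log2(od_final / od_initial)
}

#' Export a trajectory as a tab-separated table
#'
#' Writes `generation`, `frac_active`, `frac_silent` columns with 6-decimal
#' fractions, preceded by `#`-prefixed metadata lines carrying the rates and
#' initial condition.
#'
#' @param trajectory A [pev_trajectory()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "pev_trajectory"))
  v <- trajectory$values
  lines <- c(
    "# pevconv trajectory",
    sprintf("# %s y0=%g", format(trajectory$rates), trajectory$y0),
    "generation\tfrac_active\tfrac_silent",
    sprintf("%d\t%.6f\t%.6f", v$generation, v$y_a, 1 - v$y_a)
  )
  writeLines(lines, path)
  invisible(path)
}
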