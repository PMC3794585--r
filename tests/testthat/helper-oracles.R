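# Independent oracles, kept deliberately naive: literal recurrence iteration,
# brute-force first-passage counting, and a per-cell agent simulation of the
# branching mini-culture. These never call the implementation paths they
# check.

# Literal iteration of the printed recurrence.
iterate_recurrence <- function(y0, c_sa, c_as, n) {
  y <- y0
  for (i in seq_len(n)) y <- y - y * c_as + (1 - y) * c_sa
  y
}

iterate_recurrence_series <- function(y0, c_sa, c_as, n) {
  y <- numeric(n + 1)
  y[1] <- y0
  for (i in seq_len(n)) y[i + 1] <- y[i] - y[i] * c_as + (1 - y[i]) * c_sa
  y
}

# Brute-force first passage into the tolerance band around the fixed point,
# from every start in y0_set.
brute_force_gens_to_eq <- function(c_sa, c_as, tol = 0.02, y0_set = c(0, 1)) {
  y_star <- c_sa / (c_sa + c_as)
  max(vapply(y0_set, function(y0) {
    y <- y0
    n <- 0
    while (abs(y - y_star) > tol) {
      y <- y - y * c_as + (1 - y) * c_sa
      n <- n + 1
      if (n > 1e6) stop("oracle did not converge")
    }
    n
  }, numeric(1)))
}

# Literal agent-based mini-culture: one logical per cell (TRUE = active).
# Every cell divides; each daughter independently converts.
per_cell_clone <- function(founder_active, c_sa, c_as, n_gens) {
  cells <- founder_active
  for (g in seq_len(n_gens)) {
    cells <- rep(cells, each = 2)
    u <- runif(length(cells))
    flip <- ifelse(cells, u < c_as, u < c_sa)
    cells <- xor(cells, flip)
  }
  mean(cells)
}

# Deterministically derived small seed sets for parameterised cases.
expand_rate_cases <- function(n, seed = 20260) {
  set.seed(seed)
  data.frame(y0 = runif(n),
             c_sa = runif(n),
             c_as = runif(n))
}
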