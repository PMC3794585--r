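## Estimation of conversion coefficients from dual-selection time courses.
##
## The observable is the FOA-resistant fraction, identified with the silenced
## fraction 1 - Y_A (perfect selection, no plating-efficiency correction).
## The fitted model is the closed-form solution of the conversion recurrence,
## and the objective is unweighted least squares over all points of all
## courses, both selection origins jointly.

# Fast internal SSE on flattened data; rates passed as plain numerics.
sse_flat <- function(c_sa, c_as, y0, gen, obs) {
  s <- c_sa + c_as
  ya <- if (s == 0) y0 else {
    y_star <- c_sa / s
    y_star + (y0 - y_star) * (1 - s)^gen
  }
  sum((1 - ya - obs)^2)
}

#' Least-squares objective for conversion-rate fitting
#'
#' Sum of squared differences between observed FOA-resistant fractions and
#' the model prediction `1 - Y_A(n)` from the closed form, over every point of
#' every course. Observed fractions are clamped to `[0, 1]` before comparison.
#' The value is invariant to the ordering of courses and points.
#'
#' @param rates A [conversion_rates()] object.
#' @param courses A [time_course()] or list of them.
#' @return Non-negative sum of squared errors.
#' @export
sse_objective <- function(rates, courses) {
  rates <- as_conversion_rates(rates)
  dat <- flatten_courses(courses)
  if (nrow(dat) == 0L) stop("no data points", call. = FALSE)
  sse_flat(rates$c_sa, rates$c_as, dat$y0, dat$generation, dat$obs)
}

#' Best-fit conversion coefficients from time courses
#'
#' Minimises [sse_objective()] over the rate box by a log-spaced grid scan
#' followed by bounded quasi-Newton refinement (on log10 scale, so small rates
#' are resolved with relative precision) from the best `n_starts` grid cells.
#' Ties between equally good optima are broken toward smaller `c_as`.
#'
#' Both selection origins should be present: a single origin leaves the pair
#' poorly constrained away from equilibrium and is recorded as a warning flag
#' in the result (not an error). Data in which every observation sits within
#' 2 percentage points of a single value carry equilibrium information only
#' (they determine the ratio `c_sa / (c_sa + c_as)`, not the individual
#' rates); such fits are flagged `identifiable = FALSE`.
#'
#' @param courses A [time_course()] or list of them, spanning at least two
#'   distinct generations.
#' @param bounds Length-2 search box applied to each rate (default
#'   `c(1e-5, 0.5)`, covering reported conversion rates from 0.06% to 15% per
#'   generation while excluding the degenerate boundary).
#' @param n_starts Number of grid cells used to seed local refinement.
#' @param grid_n Grid resolution per axis (default 24).
#' @return An object of class `pev_fit`: list with `rates_hat`
#'   ([conversion_rates()]), `sse`, `n_points`, `converged`, `identifiable`,
#'   `single_origin`, `bounds`, and (after [bootstrap_ci()]) `ci_c_sa`,
#'   `ci_c_as`, `n_boot`, `ci_unstable`.
#' @examples
#' rates <- conversion_rates(0.08, 0.063)
#' gens <- c(0, 5, 10, 15, 20, 30, 40)
#' courses <- ideal_dual_selection(rates, gens)
#' fit_rates(courses)$rates_hat
#' @export
fit_rates <- function(courses, bounds = c(1e-5, 0.5), n_starts = 5,
                      grid_n = 24) {
  dat <- flatten_courses(courses)
  if (length(unique(dat$generation)) < 2) {
    stop("insufficient time resolution: need observations at >= 2 distinct generations",
         call. = FALSE)
  }
  stopifnot(length(bounds) == 2L, bounds[1] > 0, bounds[2] > bounds[1],
            bounds[2] <= 1)
  single_origin <- length(unique(dat$origin)) < 2
  lo <- log10(bounds[1])
  hi <- log10(bounds[2])

  lg <- seq(lo, hi, length.out = grid_n)
  grid <- expand.grid(lsa = lg, las = lg)
  grid$sse <- vapply(seq_len(nrow(grid)), function(i) {
    sse_flat(10^grid$lsa[i], 10^grid$las[i], dat$y0, dat$generation, dat$obs)
  }, numeric(1))
  ord <- order(grid$sse, grid$las)
  starts <- grid[ord[seq_len(min(n_starts, nrow(grid)))], , drop = FALSE]

  fn <- function(p) sse_flat(10^p[1], 10^p[2], dat$y0, dat$generation, dat$obs)
  cands <- lapply(seq_len(nrow(starts)), function(i) {
    optim(c(starts$lsa[i], starts$las[i]), fn, method = "L-BFGS-B",
          lower = c(lo, lo), upper = c(hi, hi),
          control = list(factr = 1e4))
  })
  vals <- vapply(cands, `[[`, numeric(1), "value")
  csas <- vapply(cands, function(x) 10^x$par[2], numeric(1))
  best <- cands[[order(vals, csas)[1]]]

  structure(list(
    rates_hat = conversion_rates(10^best$par[1], 10^best$par[2]),
    sse = best$value,
    n_points = nrow(dat),
    converged = best$convergence == 0,
    identifiable = diff(range(dat$obs)) > 0.04,
    single_origin = single_origin,
    bounds = bounds,
    ci_c_sa = NULL, ci_c_as = NULL, n_boot = NULL, ci_unstable = NA
  ), class = "pev_fit")
}

#' @export
print.pev_fit <- function(x, ...) {
  cat(sprintf("Best-fit conversion rates: c_sa = %.4g%% , c_as = %.4g%% per generation\n",
              100 * x$rates_hat$c_sa, 100 * x$rates_hat$c_as))
  cat(sprintf("SSE = %.4g over %d points; converged: %s; identifiable: %s%s\n",
              x$sse, x$n_points, x$converged, x$identifiable,
              if (x$single_origin) "; note: single selection origin" else ""))
  if (!is.null(x$ci_c_sa)) {
    cat(sprintf("95%% bootstrap CI: c_sa [%.4g, %.4g], c_as [%.4g, %.4g] (B = %d)\n",
                x$ci_c_sa[1], x$ci_c_sa[2], x$ci_c_as[1], x$ci_c_as[2],
                x$n_boot))
  }
  invisible(x)
}

#' Case-resampling bootstrap intervals for fitted rates
#'
#' Resamples time points with replacement within each course, refits by local
#' optimisation warm-started at the full-data estimate, and returns 2.5-97.5
#' percentile intervals (widened, if necessary, to contain the point
#' estimate). Deterministic given `seed`.
#'
#' @param fit A [fit_rates()] result.
#' @param courses The courses the fit was computed from.
#' @param B Number of bootstrap resamples (default 200; fewer than 20 marks
#'   the intervals unstable with a warning).
#' @param seed Integer seed.
#' @return `fit` with `ci_c_sa`, `ci_c_as`, `n_boot`, `ci_unstable` filled in.
#' @export
bootstrap_ci <- function(fit, courses, B = 200, seed = 1L) {
  stopifnot(inherits(fit, "pev_fit"), B >= 1)
  unstable <- B < 20
  if (unstable) {
    warning("B < 20: bootstrap intervals are unstable", call. = FALSE)
  }
  if (inherits(courses, "time_course")) courses <- list(courses)
  parts <- lapply(courses, function(tc) flatten_courses(tc))
  start <- log10(c(fit$rates_hat$c_sa, fit$rates_hat$c_as))
  lo <- log10(fit$bounds[1])
  hi <- log10(fit$bounds[2])
  draws <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      dat <- do.call(rbind, lapply(parts, function(p) {
        p[sample.int(nrow(p), replace = TRUE), , drop = FALSE]
      }))
      fn <- function(q) sse_flat(10^q[1], 10^q[2], dat$y0, dat$generation,
                                 dat$obs)
      opt <- optim(start, fn, method = "L-BFGS-B", lower = c(lo, lo),
                   upper = c(hi, hi), control = list(factr = 1e4))
      10^opt$par
    }, numeric(2))
  })
  q_sa <- quantile(draws[1, ], c(0.025, 0.975), names = FALSE)
  q_as <- quantile(draws[2, ], c(0.025, 0.975), names = FALSE)
  fit$ci_c_sa <- c(min(q_sa[1], fit$rates_hat$c_sa),
                   max(q_sa[2], fit$rates_hat$c_sa))
  fit$ci_c_as <- c(min(q_as[1], fit$rates_hat$c_as),
                   max(q_as[2], fit$rates_hat$c_as))
  fit$n_boot <- as.integer(B)
  fit$ci_unstable <- unstable
  fit
}

#' Diagnose dynamic equilibrium versus selection dependence
#'
#' A single paired measurement of the FOA-resistant fraction after prior FOA
#' selection and after prior uracil-dropout selection, both taken at the same
#' generation (typically the 20th), diagnoses whether the culture has reached
#' its dynamic equilibrium: at equilibrium the two values agree regardless of
#' the starting state, whereas a large difference (hysteresis) indicates slow
#' conversions and persistent memory of the initial selection.
#'
#' @param foa_r_after_foa_selection,foa_r_after_ura_selection FOA-resistant
#'   fractions (percent strings accepted), each in `[0, 1.2]`.
#' @param threshold Absolute difference above which the culture is called
#'   selection-dependent (default 0.15).
#' @return List with `status` (`"at_equilibrium"` or `"selection_dependent"`)
#'   and `delta` (absolute difference). Symmetric in its two inputs.
#' @examples
#' diagnose_equilibrium("38%", "41%")  # at_equilibrium, wild-type-like
#' diagnose_equilibrium("93%", "1%")   # selection_dependent, hysteretic
#' @export
diagnose_equilibrium <- function(foa_r_after_foa_selection,
                                 foa_r_after_ura_selection,
                                 threshold = 0.15) {
  a <- parse_fraction(foa_r_after_foa_selection, "foa_r_after_foa_selection")
  b <- parse_fraction(foa_r_after_ura_selection, "foa_r_after_ura_selection")
  check_range(a, "foa_r_after_foa_selection", 0, 1.2)
  check_range(b, "foa_r_after_ura_selection", 0, 1.2)
  delta <- abs(a - b)
  list(status = if (delta <= threshold) "at_equilibrium" else "selection_dependent",
       delta = delta)
}

# Fold change test/reference with explicit zero handling: 0 -> 0 is no
# change (fold 1); growth from 0 is an infinite increase.
fold_change <- function(ref, test) {
  if (ref == 0 && test == 0) return(1)
  if (ref == 0) return(Inf)
  test / ref
}

#' Classify a change in conversion rates
#'
#' Compares a test rate pair against a reference pair and names the scenario:
#' both rates decreased by at least `fold` is a gain of epigenetic stability,
#' both increased a loss of stability; an isolated `c_sa` increase is a loss
#' of silencing (the equilibrium shifts toward the active state) and an
#' isolated `c_as` increase a gain of silencing. Anything weaker than `fold`
#' in both directions is reported unchanged. The stability terms are distinct
#' from silencing terms: stability changes move both coefficients together
#' and can leave the equilibrium untouched, which is why endpoint-only assays
#' confuse a gain of stability with a loss of silencing.
#'
#' @param reference,test [conversion_rates()] objects.
#' @param fold Fold-change threshold (default 3).
#' @return An object of class `pev_scenario`: list with `label` (one of
#'   `loss_of_silencing`, `gain_of_silencing`, `loss_of_stability`,
#'   `gain_of_stability`, `unchanged`) and per-rate fold changes.
#' @examples
#' classify_scenario(conversion_rates(0.080, 0.063),
#'                   conversion_rates(0.0044, 0.0006))  # gain_of_stability
#' @export
classify_scenario <- function(reference, test, fold = 3) {
  reference <- as_conversion_rates(reference)
  test <- as_conversion_rates(test)
  stopifnot(fold > 1)
  f_sa <- fold_change(reference$c_sa, test$c_sa)
  f_as <- fold_change(reference$c_as, test$c_as)
  sa_up <- f_sa >= fold
  as_up <- f_as >= fold
  sa_down <- f_sa <= 1 / fold
  as_down <- f_as <= 1 / fold
  label <- if (sa_down && as_down) "gain_of_stability"
  else if (sa_up && as_up) "loss_of_stability"
  else if (sa_up && !as_up) "loss_of_silencing"
  else if (as_up && !sa_up) "gain_of_silencing"
  else "unchanged"
  structure(list(label = label, fold_c_sa = f_sa, fold_c_as = f_as,
                 fold_threshold = fold),
            class = "pev_scenario")
}

#' @export
print.pev_scenario <- function(x, ...) {
  cat(sprintf("Scenario: %s (fold change c_sa %.3g, c_as %.3g; threshold %g)\n",
              x$label, x$fold_c_sa, x$fold_c_as, x$fold_threshold))
  invisible(x)
}

#' Flat JSON report of a fit
#'
#' Serialises a [fit_rates()] result (rates as fractions and percent, SSE,
#' flags, intervals, optional scenario label) as a flat JSON document.
#'
#' @param fit A [fit_rates()] result.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @param scenario Optional [classify_scenario()] result to embed.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_fit_report <- function(fit, path = NULL, scenario = NULL) {
  stopifnot(inherits(fit, "pev_fit"))
  rep <- list(
    c_sa = fit$rates_hat$c_sa,
    c_as = fit$rates_hat$c_as,
    c_sa_percent = 100 * fit$rates_hat$c_sa,
    c_as_percent = 100 * fit$rates_hat$c_as,
    sse = fit$sse,
    n_points = fit$n_points,
    converged = fit$converged,
    identifiable = fit$identifiable,
    single_origin = fit$single_origin
  )
  if (!is.null(fit$ci_c_sa)) {
    rep$ci_c_sa_low <- fit$ci_c_sa[1]
    rep$ci_c_sa_high <- fit$ci_c_sa[2]
    rep$ci_c_as_low <- fit$ci_c_as[1]
    rep$ci_c_as_high <- fit$ci_c_as[2]
    rep$n_boot <- fit$n_boot
  }
  if (!is.null(scenario)) rep$scenario <- scenario$label
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
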