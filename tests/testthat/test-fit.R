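wt_gens <- c(0, 5, 10, 15, 20, 30, 40)

test_that("the least-squares objective scores FOA-resistant fractions", {
  rates <- conversion_rates(0.08, 0.063)
  courses <- ideal_dual_selection(rates, wt_gens)
  expect_lt(sse_objective(rates, courses), 1e-20)

  # single hand-evaluated point: origin URA, generation 1, observed 0
  one <- time_course("URA", 1, 0)
  expect_equal(sse_objective(conversion_rates(0.15, 0.06), one), 0.06^2)

  # summation commutes over courses and points
  noisy <- synth_dual_selection(rates, wt_gens, seed = 9)
  probe <- conversion_rates(0.05, 0.02)
  expect_equal(sse_objective(probe, noisy),
               sse_objective(probe, rev(noisy)))
  expect_equal(sse_objective(probe, list(noisy$ura, noisy$foa, noisy$ura)),
               sse_objective(probe, noisy$ura) * 2 +
                 sse_objective(probe, noisy$foa))
})

test_that("noiseless dual-origin courses return the generating rates", {
  wt <- conversion_rates(0.080, 0.063)
  fit <- fit_rates(ideal_dual_selection(wt, wt_gens))
  expect_lt(abs(fit$rates_hat$c_sa - 0.080), 0.001)
  expect_lt(abs(fit$rates_hat$c_as - 0.063), 0.001)
  expect_true(fit$converged)
  expect_true(fit$identifiable)
  expect_false(fit$single_origin)

  slow <- conversion_rates(0.0044, 0.0006)
  fit2 <- fit_rates(ideal_dual_selection(slow, seq(0, 50, 10)))
  expect_lt(abs(fit2$rates_hat$c_sa / 0.0044 - 1), 0.10)
  expect_lt(abs(fit2$rates_hat$c_as / 0.0006 - 1), 0.10)

  # all points at one generation: no kinetics to fit
  flat <- time_course("URA", c(10, 10, 10), c(0.2, 0.25, 0.22))
  expect_error(fit_rates(flat), "insufficient time resolution")
})

test_that("a single selection origin is flagged, not fatal", {
  wt <- conversion_rates(0.080, 0.063)
  fit <- fit_rates(ideal_timecourse(wt, 1, wt_gens))
  expect_true(fit$single_origin)
})

test_that("equilibrium-only data pin down only the rate ratio", {
  wt <- conversion_rates(0.080, 0.063)
  plateau_gens <- c(200, 220, 240, 260)
  fit <- fit_rates(ideal_dual_selection(wt, plateau_gens))
  expect_false(fit$identifiable)
  ratio <- fit$rates_hat$c_sa / (fit$rates_hat$c_sa + fit$rates_hat$c_as)
  plateau <- 1 - equilibrium_fraction(wt)  # observed FOA-resistant plateau
  expect_lt(abs((1 - ratio) - plateau), 0.02)
})

test_that("the optimum is never worse than an exhaustive grid scan", {
  wt <- conversion_rates(0.080, 0.063)
  lg <- seq(log10(1e-5), log10(0.5), length.out = 50)
  grid <- expand.grid(c_sa = 10^lg, c_as = 10^lg)
  for (s in 1:3) {
    d <- synth_dual_selection(wt, wt_gens, mean_colonies = 200, seed = s)
    fit <- fit_rates(d)
    grid_min <- min(vapply(seq_len(nrow(grid)), function(i) {
      sse_objective(conversion_rates(grid$c_sa[i], grid$c_as[i]), d)
    }, numeric(1)))
    expect_lte(fit$sse, grid_min)
  }
})

test_that("mean recovery from noisy plating data stays within 20%", {
  pairs <- list(c(0.08, 0.063), c(0.0044, 0.0006), c(0.0566, 0.0017))
  for (p in pairs) {
    truth <- conversion_rates(p[1], p[2])
    est <- vapply(1:25, function(s) {
      d <- synth_dual_selection(truth, seq(0, 50, 5), mean_colonies = 200,
                                seed = 1000 + s)
      f <- fit_rates(d)$rates_hat
      c(f$c_sa, f$c_as)
    }, numeric(2))
    expect_lt(abs(mean(est[1, ]) / p[1] - 1), 0.20)
    expect_lt(abs(mean(est[2, ]) / p[2] - 1), 0.20)
  }
})

test_that("bootstrap intervals are deterministic and collapse on clean data", {
  wt <- conversion_rates(0.080, 0.063)
  clean <- ideal_dual_selection(wt, wt_gens)
  fit <- fit_rates(clean)
  fit <- bootstrap_ci(fit, clean, B = 50, seed = 4)
  expect_lt(diff(fit$ci_c_sa), 1e-3)
  expect_lt(diff(fit$ci_c_as), 1e-3)

  noisy <- synth_dual_selection(wt, wt_gens, seed = 21)
  f1 <- bootstrap_ci(fit_rates(noisy), noisy, B = 60, seed = 9)
  f2 <- bootstrap_ci(fit_rates(noisy), noisy, B = 60, seed = 9)
  expect_identical(f1$ci_c_sa, f2$ci_c_sa)
  expect_identical(f1$ci_c_as, f2$ci_c_as)
  # intervals contain the point estimates
  expect_true(f1$ci_c_sa[1] <= f1$rates_hat$c_sa &&
                f1$rates_hat$c_sa <= f1$ci_c_sa[2])
  expect_true(f1$ci_c_as[1] <= f1$rates_hat$c_as &&
                f1$rates_hat$c_as <= f1$ci_c_as[2])

  expect_warning(bootstrap_ci(fit_rates(noisy), noisy, B = 10, seed = 1),
                 "unstable")
})

test_that("the equilibrium diagnostic separates hysteresis from equilibrium", {
  # worked examples: paired FOA-resistant fractions at the 20th generation
  wt <- diagnose_equilibrium("38%", "41%")
  expect_equal(wt$status, "at_equilibrium")
  expect_equal(wt$delta, 0.03)

  hysteretic <- diagnose_equilibrium("93%", "1%")
  expect_equal(hysteretic$status, "selection_dependent")
  expect_equal(hysteretic$delta, 0.92)

  same <- diagnose_equilibrium(0.3, 0.3)
  expect_equal(same$status, "at_equilibrium")
  expect_equal(same$delta, 0)

  # symmetric in its two inputs
  expect_equal(diagnose_equilibrium(0.93, 0.01)$delta,
               diagnose_equilibrium(0.01, 0.93)$delta)
  expect_error(diagnose_equilibrium(1.5, 0.3), "foa_r_after_foa_selection")
})

test_that("scenario classification follows the fold-change rule table", {
  ref_wt <- conversion_rates(0.080, 0.063)
  expect_equal(classify_scenario(ref_wt, conversion_rates(0.0044, 0.0006))$label,
               "gain_of_stability")
  expect_equal(classify_scenario(conversion_rates(0.03, 0.03),
                                 conversion_rates(0.15, 0.0001))$label,
               "loss_of_silencing")
  expect_equal(classify_scenario(ref_wt, ref_wt)$label, "unchanged")
  expect_equal(classify_scenario(conversion_rates(0.03, 0.03),
                                 conversion_rates(0.09, 0.09))$label,
               "loss_of_stability")
  expect_equal(classify_scenario(conversion_rates(0.03, 0.03),
                                 conversion_rates(0.03, 0.09))$label,
               "gain_of_silencing")
  # below threshold in both directions
  expect_equal(classify_scenario(ref_wt, conversion_rates(0.1, 0.05))$label,
               "unchanged")
  # zero reference rates count as infinite increases
  z <- classify_scenario(conversion_rates(0, 0.03), conversion_rates(0.05, 0.03))
  expect_equal(z$label, "loss_of_silencing")
  expect_equal(z$fold_c_sa, Inf)
})

test_that("fit reports serialise to flat JSON", {
  wt <- conversion_rates(0.080, 0.063)
  clean <- ideal_dual_selection(wt, wt_gens)
  fit <- bootstrap_ci(fit_rates(clean), clean, B = 25, seed = 2)
  js <- jsonlite::fromJSON(write_fit_report(fit))
  expect_equal(js$c_sa_percent, 100 * js$c_sa)
  expect_equal(js$c_sa, fit$rates_hat$c_sa)
  expect_true(js$converged)
  expect_equal(js$n_boot, 25)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, path, scenario = classify_scenario(wt, wt))
  expect_equal(jsonlite::fromJSON(path)$scenario, "unchanged")
})
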