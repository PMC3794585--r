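test_that("single-generation update follows the conversion recurrence", {
  expect_equal(pev_step(0.5, conversion_rates(0, 0)), 0.5)
  expect_equal(pev_step(0.0, conversion_rates(0.15, 0.06)), 0.15)
  expect_equal(pev_step(1.0, conversion_rates(0.15, 0.06)), 0.94)

  # hand-substitution oracle on randomized valid inputs
  cases <- expand_rate_cases(50)
  for (i in seq_len(nrow(cases))) {
    r <- suppressWarnings(conversion_rates(cases$c_sa[i], cases$c_as[i]))
    expect_equal(pev_step(cases$y0[i], r),
                 iterate_recurrence(cases$y0[i], cases$c_sa[i], cases$c_as[i], 1))
  }

  expect_error(pev_step(1.5, conversion_rates(0.1, 0.1)), "y_a")
  expect_error(conversion_rates(-0.1, 0.1), "c_sa")
  expect_error(conversion_rates(0.1, 1.7), "c_as")
  expect_warning(conversion_rates(0.6, 0.6), "oscillatory")
})

test_that("step maps the unit interval into itself for all valid rates", {
  cases <- expand_rate_cases(200)
  r <- suppressWarnings(mapply(function(a, b) conversion_rates(a, b),
                               cases$c_sa, cases$c_as, SIMPLIFY = FALSE))
  out <- mapply(function(y, rr) pev_step(y, rr), cases$y0, r)
  expect_true(all(out >= 0 & out <= 1))
  # boundary starts too
  out01 <- unlist(lapply(r, function(rr) pev_step(c(0, 1), rr)))
  expect_true(all(out01 >= 0 & out01 <= 1))
})

test_that("trajectories iterate the recurrence and respect edge cases", {
  r <- conversion_rates(0.15, 0.06)

  tr0 <- pev_trajectory(0.3, r, 0)
  expect_equal(tr0$values, data.frame(generation = 0L, y_a = 0.3))

  # symmetric rates: 0.5 is the fixed point
  flat <- pev_trajectory(0.5, conversion_rates(0.07, 0.07), 40)
  expect_equal(flat$values$y_a, rep(0.5, 41))

  tr <- pev_trajectory(0, r, 20)
  expect_equal(nrow(tr$values), 21L)
  expect_equal(tr$values$y_a[21], 0.7079, tolerance = 1e-4 / 0.7079)
  expect_equal(tr$values$y_a, iterate_recurrence_series(0, 0.15, 0.06, 20))
  # consecutive entries satisfy the recurrence
  y <- tr$values$y_a
  expect_equal(y[-1], y[-21] - y[-21] * 0.06 + (1 - y[-21]) * 0.15)
  expect_true(all(y >= 0 & y <= 1))

  expect_error(pev_trajectory(0, r, -1), "non-negative")
  expect_error(pev_trajectory(-0.2, r, 5), "y0")
})

test_that("closed form solves the recurrence exactly", {
  expect_equal(pev_closed_form(0.37, conversion_rates(0.2, 0.1), 0), 0.37)
  expect_equal(pev_closed_form(1, conversion_rates(0.01, 0.01), 15),
               0.8693, tolerance = 1e-4 / 0.8693)
  # frozen states when both rates are zero
  expect_equal(pev_closed_form(0.42, conversion_rates(0, 0), c(0, 7, 500)),
               rep(0.42, 3))

  # n = 1 is algebraically one step
  cases <- expand_rate_cases(50)
  for (i in seq_len(nrow(cases))) {
    r <- suppressWarnings(conversion_rates(cases$c_sa[i], cases$c_as[i]))
    expect_equal(pev_closed_form(cases$y0[i], r, 1),
                 pev_step(cases$y0[i], r), tolerance = 1e-14)
  }
})

test_that("closed form agrees with iteration to 1e-12 over 500 generations", {
  cases <- expand_rate_cases(1000)
  worst <- 0
  for (i in seq_len(nrow(cases))) {
    r <- suppressWarnings(conversion_rates(cases$c_sa[i], cases$c_as[i]))
    n <- 0:500
    cf <- pev_closed_form(cases$y0[i], r, n)
    it <- iterate_recurrence_series(cases$y0[i], r$c_sa, r$c_as, 500)
    worst <- max(worst, max(abs(cf - it)))
  }
  expect_lt(worst, 1e-12)
})

test_that("equilibrium is the rate ratio and a fixed point of the update", {
  expect_equal(pev_equilibrium(conversion_rates(0.07, 0.07))$y_star, 0.5)
  expect_equal(pev_equilibrium(conversion_rates(0, 0.10))$y_star, 0)
  eq <- pev_equilibrium(conversion_rates(0.15, 0.06))
  expect_equal(eq$y_star, 0.714286, tolerance = 1e-6 / 0.714286)
  expect_equal(eq$retention, 0.79)

  # independent oracle: fixed-point iteration of the bare recurrence
  y <- 0.123
  for (i in 1:2000) y <- y - y * 0.06 + (1 - y) * 0.15
  expect_equal(eq$y_star, y, tolerance = 1e-12)

  # fixed point identity, across random rates
  cases <- expand_rate_cases(100)
  for (i in seq_len(nrow(cases))) {
    r <- suppressWarnings(conversion_rates(cases$c_sa[i], cases$c_as[i]))
    if (!pev_equilibrium(r)$exists) next
    ys <- equilibrium_fraction(r)
    expect_equal(pev_step(ys, r), ys, tolerance = 1e-12)
  }

  none <- pev_equilibrium(conversion_rates(0, 0))
  expect_false(none$exists)
  expect_error(equilibrium_fraction(conversion_rates(0, 0)),
               "no unique equilibrium")
})

test_that("geometric contraction: deviations shrink by the retention factor", {
  r <- conversion_rates(0.08, 0.063)
  eq <- pev_equilibrium(r)
  tr <- pev_trajectory(1, r, 100)$values$y_a
  dev <- abs(tr - eq$y_star)
  expect_equal(dev, dev[1] * eq$retention^(0:100), tolerance = 1e-10)
  expect_true(all(diff(dev) < 0))
})

test_that("relabeling active and silent states mirrors the trajectory", {
  cases <- expand_rate_cases(50)
  for (i in seq_len(nrow(cases))) {
    a <- suppressWarnings(conversion_rates(cases$c_sa[i], cases$c_as[i]))
    b <- suppressWarnings(conversion_rates(cases$c_as[i], cases$c_sa[i]))
    ya <- pev_trajectory(cases$y0[i], a, 60)$values$y_a
    yb <- pev_trajectory(1 - cases$y0[i], b, 60)$values$y_a
    expect_equal(ya, 1 - yb, tolerance = 1e-12)
  }
})

test_that("generations to equilibrium matches brute-force first passage", {
  pairs <- list(c(0.15, 0.06), c(0.07, 0.03), c(0.15, 0.0001),
                c(0.15, 0.15), c(0.01, 0.01))
  frozen <- c(16L, 34L, 25L, 10L, 160L)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    got <- generations_to_equilibrium(conversion_rates(p[1], p[2]))
    expect_identical(got, frozen[i])
    expect_equal(got, brute_force_gens_to_eq(p[1], p[2]))
  }

  # randomized agreement with the brute-force oracle, including the
  # oscillatory regime c_sa + c_as > 1
  cases <- expand_rate_cases(60)
  for (i in seq_len(nrow(cases))) {
    c_sa <- cases$c_sa[i]
    c_as <- cases$c_as[i]
    if (c_sa + c_as == 0 || abs(1 - c_sa - c_as) >= 1 - 1e-9) next
    r <- suppressWarnings(conversion_rates(c_sa, c_as))
    expect_equal(generations_to_equilibrium(r),
                 brute_force_gens_to_eq(c_sa, c_as))
  }

  # already at equilibrium
  r <- conversion_rates(0.15, 0.06)
  expect_identical(generations_to_equilibrium(r, y0_set = 5 / 7), 0L)
  expect_error(generations_to_equilibrium(conversion_rates(0, 0)),
               "no unique equilibrium")
  expect_error(
    suppressWarnings(generations_to_equilibrium(conversion_rates(1, 1))),
    "never converges")
  expect_error(generations_to_equilibrium(r, tol = 0), "tol")
})

test_that("OD600 ratios convert to doubling counts", {
  expect_equal(od_to_generations(0.001, 1.024), 10)
  expect_equal(od_to_generations(0.35, 0.35), 0)
  expect_equal(od_to_generations(0.003, 3), 9.966, tolerance = 1e-3 / 9.966)
  expect_error(od_to_generations(0, 1), "positive")
  expect_error(od_to_generations(1, 0.5), "od_final")
})

test_that("trajectory TSV export carries metadata and 6-decimal fractions", {
  tr <- pev_trajectory(0, conversion_rates(0.15, 0.06), 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# c_sa=0.15 c_as=0.06 y0=0", lines)))
  expect_identical(lines[3], "generation\tfrac_active\tfrac_silent")
  last <- strsplit(lines[length(lines)], "\t")[[1]]
  expect_identical(last[2], "0.707882")
  expect_equal(as.numeric(last[2]) + as.numeric(last[3]), 1)
})
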