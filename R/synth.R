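## Synthetic assay-data generators. These emulate the statistical structure
## of the wet-lab measurements the analysis consumes: colony-count plating
## assays with counting noise, dual-selection designs, and per-clone FACS
## fractions of mini-culture panels. Every generator is a pure function of
## its parameters and seed.

#' Noise-free expected time course
#'
#' The expectation of the plating assay: FOA-resistant and URA+ fractions set
#' exactly to the closed-form silenced and active fractions at each
#' generation. Useful as the noiseless limit of [synth_timecourse()] and for
#' self-consistency checks of the fitting routine.
#'
#' @param rates A [conversion_rates()] object.
#' @param y0 Initial active fraction (0 after FOA selection, 1 after uracil
#'   dropout).
#' @param generations Sorted non-negative generation numbers.
#' @param replicate Replicate label.
#' @return A [time_course()].
#' @export
ideal_timecourse <- function(rates, y0, generations, replicate = 1L) {
  rates <- as_conversion_rates(rates)
  y <- pev_closed_form(y0, rates, generations)
  time_course(if (y0 >= 0.5) "URA" else "FOA", generations,
              frac_foa_r = 1 - y, frac_ura = y, replicate = replicate,
              y0 = y0)
}

#' @rdname ideal_timecourse
#' @return `ideal_dual_selection()`: list of two courses, FOA origin
#'   (`y0 = 0`) and URA origin (`y0 = 1`).
#' @export
ideal_dual_selection <- function(rates, generations) {
  list(foa = ideal_timecourse(rates, 0, generations),
       ura = ideal_timecourse(rates, 1, generations))
}

#' Synthetic plating time course with Poisson counting noise
#'
#' For each requested generation the true active fraction `y` is taken from
#' the closed form; colony counts are then drawn independently per plate, as
#' in a serial-dilution protocol where the selective and non-selective plates
#' receive independent aliquots: `Poisson(mean_colonies)` on the
#' non-selective plate (redrawn until positive), `Poisson(mean_colonies * y)`
#' on uracil dropout and `Poisson(mean_colonies * (1 - y))` on FOA. Observed
#' fractions are the plate ratios, so they occasionally exceed 100% exactly
#' as real colony-count tables do (entries of 103-109% are realistic, not a
#' bug).
#'
#' @param rates A [conversion_rates()] object.
#' @param y0 Initial active fraction.
#' @param generations Sorted non-negative generation numbers.
#' @param mean_colonies Expected colonies per plate (default 200, a typical
#'   countable density).
#' @param seed Integer seed; same seed, same course.
#' @param replicate Replicate label.
#' @return A [time_course()] with counts attached.
#' @examples
#' synth_timecourse(conversion_rates(0.15, 0.06), 0, seq(0, 40, 5), seed = 1)
#' @export
synth_timecourse <- function(rates, y0, generations, mean_colonies = 200,
                             seed = 1L, replicate = 1L) {
  rates <- as_conversion_rates(rates)
  if (any(generations < 0) || is.unsorted(generations)) {
    stop("generations must be sorted and non-negative", call. = FALSE)
  }
  stopifnot(mean_colonies >= 1)
  y <- pev_closed_form(y0, rates, generations)
  m <- length(generations)
  with_seed(seed, {
    n_ns <- numeric(m)
    n_ura <- numeric(m)
    n_foa <- numeric(m)
    for (i in seq_len(m)) {
      repeat {
        n_ns[i] <- rpois(1L, mean_colonies)
        if (n_ns[i] > 0) break
      }
      n_ura[i] <- rpois(1L, mean_colonies * y[i])
      n_foa[i] <- rpois(1L, mean_colonies * (1 - y[i]))
    }
  })
  # clamp the rare extreme ratio to the dialect's 1.2 ceiling
  time_course(if (y0 >= 0.5) "URA" else "FOA", generations,
              frac_foa_r = pmin(n_foa / n_ns, 1.2),
              frac_ura = pmin(n_ura / n_ns, 1.2),
              counts = data.frame(n_nonselective = n_ns, n_ura = n_ura,
                                  n_foa = n_foa),
              replicate = replicate, y0 = y0)
}

#' Synthetic dual-selection experiment
#'
#' Generates the paired design: one course established from FOA selection
#' (`y0 = 0`) and one from uracil-dropout selection (`y0 = 1`), with
#' independent sub-seeds derived from `seed`.
#'
#' @inheritParams synth_timecourse
#' @return List with elements `foa` and `ura`, each a [time_course()].
#' @export
synth_dual_selection <- function(rates, generations, mean_colonies = 200,
                                 seed = 1L) {
  ss <- derive_subseeds(seed, 2L)
  list(foa = synth_timecourse(rates, 0, generations, mean_colonies,
                              seed = ss[1]),
       ura = synth_timecourse(rates, 1, generations, mean_colonies,
                              seed = ss[2]))
}

#' Synthetic FACS readout of a mini-culture panel
#'
#' Simulates the panel with [simulate_panel()] and then the flow-cytometry
#' measurement of each well: the observed GFP+ fraction is
#' `Binomial(n_events, true fraction) / n_events`. With the default 10,000
#' events the measurement error has standard deviation at most 0.005, far
#' below the clone-to-clone spread produced by early stochastic switching.
#'
#' @inheritParams simulate_panel
#' @param n_events FACS events acquired per well (default 10000).
#' @return An object of class `facs_panel`: data frame with columns
#'   `clone_index`, `true_frac_gfp`, `observed_frac_gfp`, `n_events`; the
#'   underlying `clone_panel` is attached as attribute `panel`.
#' @export
synth_facs_panel <- function(rates, n_clones, n_gens = 15,
                             founder_prob_active = NULL, n_events = 10000,
                             seed = 1L) {
  stopifnot(n_events >= 1)
  ss <- derive_subseeds(seed, 2L)
  panel <- simulate_panel(n_clones, rates, n_gens, founder_prob_active,
                          seed = ss[1])
  truth <- panel$clones$frac_active
  obs <- with_seed(ss[2], rbinom(length(truth), n_events, truth) / n_events)
  structure(data.frame(clone_index = panel$clones$clone_index,
                       true_frac_gfp = truth,
                       observed_frac_gfp = obs,
                       n_events = as.integer(n_events)),
            panel = panel, class = c("facs_panel", "data.frame"))
}

#' Write a FACS panel as a tab-separated table
#'
#' @param facs A [synth_facs_panel()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_facs_panel <- function(facs, path) {
  stopifnot(inherits(facs, "facs_panel"))
  panel <- attr(facs, "panel")
  lines <- c("# pevconv FACS panel",
             sprintf("# %s n_gens=%d founder_prob_active=%g seed=%d n_events=%d",
                     format(panel$rates), panel$n_gens,
                     panel$founder_prob_active, panel$seed, facs$n_events[1]),
             "clone_index\tobserved_frac_gfp",
             sprintf("%d\t%.6f", facs$clone_index, facs$observed_frac_gfp))
  writeLines(lines, path)
  invisible(path)
}

# Named rate-pair fixtures for the scenarios and strains the model is
# exercised on. Provenance strings describe the scenario each pair encodes.
fixture_table <- function() {
  list(
    wt_tel_VIIL = list(rates = c(0.080, 0.063),
                       provenance = "best-fit rates, wild-type (W303) URA3 at the VIIL telomere"),
    cac1_tel_VIIL_first50 = list(rates = c(0.0044, 0.0006),
                                 provenance = "best-fit rates, cac1-null URA3 at the VIIL telomere, first 50 generations"),
    sir1_hmr = list(rates = c(0.0566, 0.0017),
                    provenance = "best-fit rates, sir1-null hmr-a1::URA3"),
    fig2A_fast = list(rates = c(0.15, 0.06),
                      provenance = "simulation scenario: equilibrium near 30% FOA-resistant reached in about 20 generations"),
    fig2A_slow = list(rates = c(0.07, 0.03),
                      provenance = "simulation scenario: same equilibrium reached in about 40 generations"),
    fig2C_loss = list(rates = c(0.15, 0.0001),
                      provenance = "simulation scenario: loss of silencing, fast"),
    fig2C_loss_slow = list(rates = c(0.07, 0.0001),
                           provenance = "simulation scenario: loss of silencing, slow"),
    fig2D_gain = list(rates = c(0.03, 0.15),
                      provenance = "simulation scenario: gain of silencing, fast"),
    fig2D_gain_slow = list(rates = c(0.03, 0.07),
                           provenance = "simulation scenario: gain of silencing, slow"),
    fig3A_unstable = list(rates = c(0.15, 0.15),
                          provenance = "simulation scenario: loss of epigenetic stability"),
    fig3B_stable = list(rates = c(0.01, 0.01),
                        provenance = "simulation scenario: gain of epigenetic stability")
  )
}

#' Named conversion-rate fixtures
#'
#' A catalogue of the rate pairs used throughout the package: the three
#' empirically fitted strain estimates (wild-type telomere, cac1-null
#' telomere over the first 50 generations, sir1-null silent mating locus) and
#' the eight canonical simulation scenarios (fast/slow equilibration,
#' loss/gain of silencing, loss/gain of stability).
#'
#' @param name Optional fixture name; if given, that single fixture is
#'   returned and an unknown name is an error listing the catalogue.
#' @return A named list of fixtures (each with `name`, `rates` as
#'   [conversion_rates()], and a `provenance` string), or one fixture.
#' @examples
#' pev_fixtures("wt_tel_VIIL")$rates
#' names(pev_fixtures())
#' @export
pev_fixtures <- function(name = NULL) {
  tab <- fixture_table()
  out <- lapply(names(tab), function(nm) {
    list(name = nm,
         rates = conversion_rates(tab[[nm]]$rates[1], tab[[nm]]$rates[2]),
         provenance = tab[[nm]]$provenance)
  })
  names(out) <- names(tab)
  if (is.null(name)) return(out)
  if (!name %in% names(out)) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(out), collapse = ", ")), call. = FALSE)
  }
  out[[name]]
}
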