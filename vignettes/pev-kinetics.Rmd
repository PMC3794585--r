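---
title: "Quantifying epigenetic conversion rates at variegating loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epigenetic conversion rates at variegating loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pevconv)
```

## The model

Position-effect variegation (PEV) produces mixed populations in which a
reporter gene near heterochromatin — a telomeric `URA3` insertion or a GFP
cassette at a silent mating locus in budding yeast — is silenced in some
cells and active in others, with each state heritable for many divisions.
`pevconv` models the population kinetics with two per-generation conversion
probabilities: $C_{S \to A}$ (`c_sa`), the chance that a silenced locus
becomes active during one division, and $C_{A \to S}$ (`c_as`), the reverse.
The fraction of cells with the active gene, $Y_A$, obeys the linear
recurrence

$$Y_{A,n} \;=\; Y_{A,n-1} \;-\; Y_{A,n-1}\,C_{A\to S} \;+\; (1 - Y_{A,n-1})\,C_{S\to A},$$

whose closed-form solution is

$$Y_{A,n} \;=\; Y^{*} + (Y_{A,0} - Y^{*})\,\lambda^{n}, \qquad
Y^{*} = \frac{C_{S\to A}}{C_{S\to A}+C_{A\to S}}, \qquad
\lambda = 1 - C_{S\to A} - C_{A\to S}.$$

Both coefficients are probabilities (each in $[0,1]$), independent of each
other and of the current population composition. Every population converges
geometrically to the same dynamic equilibrium $Y^*$ regardless of where it
starts; the retention factor $\lambda$ sets the speed. This separation is the
scientific point of the framework: the *position* of the equilibrium and the
*speed* of approach are independent observables. Endpoint assays measure only
the first; the conversion rates are only accessible from the approach.

```{r closed-form}
rates <- conversion_rates(0.15, 0.06)   # 15% and 6% per generation
pev_equilibrium(rates)
generations_to_equilibrium(rates)       # from both y0 = 0 and y0 = 1
```

The model deliberately does not distinguish whether one or both daughter loci
convert at a division, nor replication-coupled from replication-independent
conversion; it has exactly two states, and the rates are constant across
generations (no replicative-aging effects).

## Dual-selection time courses and rate estimation

The measurement design that exposes the kinetics is dual selection: grow the
strain under selection for the *active* reporter (uracil dropout,
$Y_{A,0}=1$) and, in parallel, for the *silenced* reporter (5-FOA,
$Y_{A,0}=0$); release both into non-selective medium; and plate aliquots at
known generation numbers (obtained from optical density as
$\log_2(\mathrm{OD_{final}}/\mathrm{OD_{initial}})$, see
`od_to_generations()`). The FOA-resistant fraction is identified with the
silenced fraction $1 - Y_A$, the URA+ fraction with $Y_A$ — perfect
selection, no plating-efficiency correction.

`fit_rates()` estimates the pair by unweighted least squares of
$1 - Y_A(n)$ against the observed FOA-resistant fractions, jointly over both
origins. Design choices worth knowing:

* **Search box** $[10^{-5}, 0.5]$ per rate. This spans every rate the assays
  plausibly produce (from well below 0.1% to 15% per generation) while
  excluding the degenerate boundary; the optimisation runs on the log10
  scale so that rates of a few times $10^{-4}$ are resolved with relative,
  not absolute, precision.
* **Global-then-local search**: a 24×24 log-spaced grid scan followed by
  L-BFGS-B refinement from the best five cells; ties prefer smaller `c_as`.
  The objective is smooth and two-dimensional, so this is reliably global (a
  50×50 exhaustive grid never beats it in the test suite).
* **Identifiability**: data whose observations all sit within 2 percentage
  points of one value carry only equilibrium information — they fix the
  ratio $C_{S\to A}/(C_{S\to A}+C_{A\to S})$, not the two rates — and the
  fit is flagged `identifiable = FALSE`. A single selection origin is
  flagged (`single_origin`) but not refused.
* **Observed values above 100%** (plating-ratio noise) are accepted up to
  120% and clamped to 100% for fitting only.

`bootstrap_ci()` adds case-resampling percentile intervals (resampling time
points within each course, refitting from the full-data estimate,
2.5–97.5 percentiles, widened if needed to contain the point estimate).
At typical design sizes — about eleven time points per course — percentile
intervals of this kind are mildly anti-conservative: in the package's own
coverage simulations at 95% nominal level they cover the generating rates in
roughly 85–90% of datasets, a shortfall that full-grid refits, reversed
("basic") intervals, and bias-corrected variants do not repair. Treat the
intervals as honest summaries of estimation spread rather than exact 95%
statements; denser sampling designs tighten them toward nominal.

## Interpreting rate changes

Two vocabularies are kept distinct. A **loss or gain of silencing** is a
shift of the equilibrium driven by one coefficient: an isolated rise of
$C_{S\to A}$ derepresses the locus, an isolated rise of $C_{A\to S}$
silences it. A **loss or gain of epigenetic stability** moves *both*
coefficients together — up for instability, down for stability — and can
leave the equilibrium almost untouched, which is precisely why endpoint-only
assays misread a gain of stability as a loss of silencing when cultures are
only ever established from one selection. `classify_scenario()` encodes this
as a fold-change rule table (default threshold 3×, configurable; rates of
zero are treated as infinite fold changes in the direction of change).
`diagnose_equilibrium()` applies the cheap single-time-point screen: paired
FOA-resistance after both selections at the same generation, called
selection-dependent when they differ by more than 0.15 (a threshold that
cleanly separates hysteretic strains, e.g. 93% vs 1%, from equilibrated
ones, e.g. 38% vs 41%, in published plating tables).

## Mini-culture branching simulation

At loci with no counter-selectable marker (a GFP reporter at *HMR*a), rates
are probed by seeding single cells in 96-well plates, growing ~15
generations, and reading the per-well GFP+ fraction by FACS. Because each
culture starts from one cell, the first conversion falls in the earliest
generations (2, 4, 8… cells at risk) and leaves a large, heritable imprint
on the final fraction; the sorted per-clone profile is therefore a
fingerprint of the rates. `simulate_clone()` implements the branching
process exactly: every cell divides, and each daughter converts
independently with its state's rate. Per-daughter independence is the
minimal mechanism whose expectation reproduces the population recurrence;
the population is propagated by paired binomial counts
($A' = 2A - \mathrm{Bin}(2A, c_{as}) + \mathrm{Bin}(2S, c_{sa})$), which is
distributionally identical to per-cell simulation (verified against a
literal agent-based oracle in the tests) but constant-time per generation.

```{r clones}
summarize_panel(simulate_panel(50, conversion_rates(0.07, 0.07), 15,
                               founder_prob_active = 0.5, seed = 1))
summarize_panel(simulate_panel(500, conversion_rates(0.01, 0.01), 15,
                               founder_prob_active = 0.5, seed = 1))
```

Symmetric 7% rates scatter 50 clones through a narrow mid band
(roughly 35–65% active); 1% rates produce a two-phase profile piled near the
closed-form endpoints 0.13 and 0.87, with almost no mid-band clones. The
founder mixture defaults to the equilibrium composition of the supplied
rates (0.5 for symmetric rates) because the seeding culture is grown without
selection; it is overridable. No cell death, no state-dependent growth-rate
difference, and no well cross-contamination are modelled. Per-clone sub-seeds
are derived deterministically from the master seed, so panels are exactly
reproducible.

## The synthetic assay generator

There are no deposited datasets for assays of this kind, so the package
generates its own with the statistical structure the analysis assumes:

* **Plating counts**: independent Poisson counts per plate
  (`Poisson(mean_colonies)` non-selective, `Poisson(mean_colonies * y)`
  uracil dropout, `Poisson(mean_colonies * (1-y))` FOA), matching a
  serial-dilution protocol in which each plate receives an independent
  aliquot. Ratios of independent Poissons occasionally exceed 100% — real
  colony-count tables contain 103–109% entries — so this is reproduced, not
  suppressed (capped at the dialect's 120% ceiling). The default 200
  expected colonies per plate is a typical countable density; tests that
  depend on the noise magnitude state their own counts.
* **FACS wells**: `Binomial(n_events, true fraction)/n_events` with 10,000
  events by default and no autofluorescence floor.
* **No mutational FOA resistance**: forward-mutation rates (~1e-6) are three
  to four orders of magnitude below epigenetic switching (1e-2 to 1e-3) and
  are omitted.

What the generator does *not* emulate: plating-efficiency differences
between media, aging-related rate drift (real CAF-I-deficient cultures show
a collapse of FOA resistance after ~60 generations that this constant-rate
model deliberately excludes), cell death, and day-to-day batch effects. A
passing recovery test therefore demonstrates that the estimator inverts the
assumed noise model at realistic signal sizes — not that every laboratory
complication is handled.

## Numerical conventions

* Rates and fractions are stored in $[0,1]$; `"%"`-suffixed strings are
  accepted at all input boundaries and divided by 100. Output is in
  fractions, with percent alongside in fit reports.
* Generations are integer steps (one division = one generation); the closed
  form answers fractional generations as smooth interpolation, which is the
  natural reading of OD-derived real-valued generation numbers.
* "Equilibrium reached" means within 2 percentage points (0.02 absolute) of
  $Y^*$ from both $y_0 = 0$ and $y_0 = 1$. This convention reproduces, as
  bounds, every published generation-to-equilibrium count the model is
  checked against; it is computed by closed-form inversion with an exact
  first-passage guard, and by direct iteration when $\lambda \le 0$.
* `c_sa + c_as > 1` (oscillatory approach, $\lambda < 0$) is admitted with a
  warning; both coefficients are probabilities, so their sum may legally
  reach 2 even though measured assays live well below 0.3.
* Both rates zero: trajectories are frozen at $y_0$; `equilibrium` queries
  raise an explicit "no unique equilibrium" error.
* Problem sizes used by the verification suite: 1000 random rate pairs over
  500 generations for closed-form/recurrence agreement (tolerance 1e-12);
  2000-clone panels for the law-of-large-numbers check; 25 replicate
  datasets per rate pair for noisy recovery; 50 datasets × 200 resamples
  for bootstrap coverage.

## Limitations

* Exactly two epigenetic states; no intermediate or short-lived silencing
  states, which short-term single-cell experiments suggest exist. Rates
  estimated over tens of generations are long-run effective rates.
* Constant rates: replicative aging and its late collapse of silencing are
  out of scope, so fits to long cultures of aging-sensitive mutants should
  be restricted to the early window (the catalogued CAF-I-deficient
  estimate is explicitly a first-50-generations fit).
* Bootstrap intervals are mildly anti-conservative at small designs (see
  above).
* The branching simulator's exact-count propagation relies on binomial
  draws whose size doubles each generation; it is instantaneous to ~30
  generations, far beyond the 15–18 a mini-culture experiment uses.
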