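---
title: "Methods: simulating misclassification of disease status at death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating misclassification of disease status at death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micdad)
```

## The problem

Linking one-time cross-sectional surveys to death registries is a common way
to estimate mortality rates by disease status. The design has a blind spot:
disease status is frozen at the survey date. A participant who is
disease-free at interview and develops the chronic disease afterwards dies
*diagnosed* but is recorded as *non-diseased* — misclassification of disease
status at death (MicDaD). Deaths and person-time that belong to the diseased
group are booked to the non-diseased group, so the diseased mortality rate
`m1` is under-sampled among its sickest (post-survey-onset) members while the
non-diseased rate `m0` is inflated, and the mortality rate ratio
`MRR(a) = m1(a) / m0(a)` is pulled towards 1. This package measures that
pull by simulation.

## The illness-death model and its simulation

Individuals move through three states — healthy, diseased (chronic, no
remission), dead — with age as the only timescale. The transition
intensities are:

| Quantity | Form | Default (high) | Default (low) | Units |
| --- | --- | --- | --- | --- |
| `m0(a)` | `exp(b0 + b1 a)` | `b0 = -10.3832`, `b1 = 0.1` | `b0 = -9.7215`, `b1 = 0.1` | per year |
| `MRR(a)` | `exp(c0 - c1 a)` | `c0 = 2`, `c1 = 0.02` | `c0 = 2.2526`, `c1 = 0.02301` | ratio |
| `i(a)` | `exp(d0 + d1 a)` above onset, else 0 | onset 30 y, `d0 = -6.6461`, `d1 = 0.03792` | onset 18 y, `d0 = -8.6817`, `d1 = -0.03672` | per year |

`m1(a) = m0(a) · MRR(a)` is again Gompertz. All rates live on ages 0–110;
the estimation window (ages 40–80) is a property of the analysis, not of the
rates, because observed diagnosis and death ages fall outside it.

The cohort is simulated at birth by discrete-event simulation. The age of
leaving the healthy state solves the inverse-cumulative-hazard equation
$\Lambda_{m_0+i}(0, a^\*) = -\log U$, solved by 50 steps of monotone
bisection on the closed-form cumulative hazard (bracket width
$< 10^{-13}$ y, far below the 1e-8 y documented tolerance); the event is a
diagnosis with probability $i(a^\*)/(i(a^\*)+m_0(a^\*))$ — the standard
thinning-equivalent split for competing risks — otherwise a death. Diagnosed
individuals draw a death age from $m_1$ starting at diagnosis. A draw whose
total hazard to 110 cannot reach $-\log U$ is assigned death at exactly 110,
so every life ends in the death state; with the shipped rates this touches
fewer than $10^{-4}$ of lives. The whole sampler is vectorised, so a
100 000-person cohort takes about a second.

## What the generator emulates, and what it does not

The two shipped settings emulate a common late-onset disease (≈40% lifetime
diagnosis risk, median onset 60.75 y, modelled on type 2 diabetes) and a
rare early-onset disease (≈0.2%, median onset 32.55 y, modelled on lupus
erythematosus). The exact rate formulas behind those published summaries are
not available, so the defaults are *calibrated surrogates*: smooth
two-parameter forms matched to the printed lifetime risk, median onset age,
median death age and MRR anchors. Consequences worth keeping in mind:

* Passing tests show the pipeline recovers the behaviour of *this* family of
  rates; real incidence and mortality curves are not exactly Gompertz or
  log-linear, and reproduction of the published medians is expected only to
  stochastic tolerance, not bit-for-bit.
* The generator omits calendar-time effects, duration-in-state dependence of
  `m1`, covariates (sex, socioeconomic position), repeated surveys, and
  migration — real data have all of these.
* Survey ages are uniform on [18, 110]; real participation ages are not
  uniform, and the amount of masking (here ≈45% of diagnoses in the high
  setting) is an emergent quantity, neither controlled nor varied.

## Calibration

`calibrate_m0()` solves the Gompertz level in closed form so the `m0`-only
cumulative hazard to the target median death age equals `log 2`; the slope
is fixed at 0.1 per year, a typical adult value, leaving one free parameter
per target. `calibrate_incidence()` solves the incidence level and slope so
that the competing-risk lifetime diagnosis probability
$\int_0^{110} i\,e^{-\Lambda_i-\Lambda_{m_0}}\,da$ and the median onset age
among the diagnosed hit their targets (nested monotone root finds; risk
residual below 1e-6). That integral is evaluated after integration by parts
so the integrand is bounded by `m0`: the naive form develops a boundary
layer just above the onset age at the extreme incidence levels the root
search passes through, which adaptive quadrature silently misses.

One design choice was genuinely open: which death-age summary `m0` should be
calibrated against. The published median death age of the *non-diseased*
refers to individuals who actually died without a diagnosis — a selected
group, because dying early is what prevented their diagnosis. In a
high-incidence setting the selection is strong: matching the target with the
no-competition closed form alone leaves the simulated non-diseased median at
70.3 y against a 74.0 y target and the overall median near 72.1 y against
74.8 y. `calibrate_rate_set()` therefore alternates the incidence
calibration with a re-solve of the `m0` level against the median of the
*selected* non-diseased death-age distribution
($\propto m_0 e^{-\Lambda_{m_0}-\Lambda_i}$) until the fixed point
converges. With that choice the simulated high-incidence cohort reproduces
the non-diseased median (74.0), the overall median (75.2 vs 74.8) and the
diagnosed share within Monte-Carlo error; in the low-incidence setting
selection is negligible and the fixed point collapses to the closed form
(`log_level` −9.7215, i.e. the classic ≈ −9.72 for a 70.53-y median). The
onset ages (30 y high, 18 y low) are assumptions: published summaries do not
state whether incidence was zero in childhood, only that no early diagnoses
are reported in the high setting and that onset is early in the low one.

`default_rates()` returns these calibrations frozen at full precision;
`recalibrate = TRUE` re-derives them, and the test suite checks the two
agree to 1e-6.

## Estimation

`split_person_time()` allocates each life's time in the 40–80 window to
one-year age bands by disease group, following the time split rather than
the status at death: a person diagnosed at 60 contributes non-diseased
person-time in 40–60 and diseased person-time afterwards. Under masking the
observed diagnosis age replaces the true one, so masked individuals
contribute everything — including their death — to the non-diseased group.
This reallocates person-time and events but conserves their totals, an
invariant the tests exercise. Deaths at or past the window edge are censored
at the edge; deaths before 40 contribute nothing.

`fit_poisson_loglinear()` maximises the Poisson likelihood of the banded
counts with log person-years offset and band midpoint as the age covariate,
by Newton–Raphson from the intercept-only start, convergence at parameter
changes below 1e-10 (typically 4–6 iterations), with steps capped at length
5 to keep the exponential finite on wild small-sample tables. One-year bands
make the banded and individual-level fits indistinguishable at this
smoothness. Groups are fitted separately, which is equivalent to one fully
interacted joint model. The estimated ratio is `m1/m0` — reported MRRs
exceed 1 and are read as diseased-versus-non-diseased excess mortality.

Degenerate inputs are defined behaviour: a single informative band fixes the
slope at 0 and returns the closed-form rate; zero events raise an error,
which the resampling study catches and counts as a failed fit (in the rare-
disease setting a 5000-person sample can contain no diseased death).

## The bias study

200 sub-populations of 5000 are drawn without replacement within a draw and
independently across draws; survey ages are assigned once on the parent
cohort and inherited, so the same individuals are compared with and without
masking (paired design). Per sub-population and evaluation age (40/60/80)
the study records the masked and unmasked MRR and their difference; the bias
is the median difference, flanked by type-7 (linear-interpolation) 2.5% and
97.5% quantiles. Ties (`diff == 0`, common in the low setting where many
samples contain no masked diagnosis) and failed fits are reported
separately, which is why over- and under-estimation counts need not sum to
the number of sub-populations. Kernel densities of the estimates use a
Gaussian kernel with Silverman's bandwidth, floored at a small positive
value for constant samples.

## Numerical and reproducibility choices

* Quadrature fallback: relative tolerance 1e-10; calibration residual 1e-6;
  event-age bisection ≈ 1e-13 y; Newton convergence 1e-10.
* Boundary ties: a survey exactly at the diagnosis age counts as observed; a
  death exactly at a band edge belongs to the upper band; deaths at exactly
  80 are censored.
* Surveys after death follow the literal masking rule (masked iff
  survey < diagnosis); no special handling, matching the design where the
  110-y upper bound guarantees death before the latest possible survey.
* One top-level seed expands into named sub-streams (simulation, survey,
  sampling) so stages can be re-run independently; pipeline CSVs are rounded
  to 10 significant digits for byte-stable output, and the YAML rate config
  stores doubles as `%.17g` strings so it round-trips bit-exactly.

## Problem sizes

The shipped defaults follow the study design: 100 000-person cohorts, 200
sub-populations of 5000, evaluation at ages 40/60/80. A full paired study
runs in well under a minute on one core; the test suite uses the full sizes
for the headline checks and smaller cohorts (3000–50 000) for structural
properties, with one 10^6 cohort to pin the low-setting onset median.

## Known limitations

Everything listed under what the generator does not emulate, plus: the
surrogate rates make published-value comparisons stochastic by construction
(the shipped high-setting masking effect is slightly weaker than the
published one, median bias ≈ −0.15 to −0.20 at age 60); confidence intervals
for a single fit are not provided (uncertainty comes from the resampling);
and the estimation model is intentionally the simple log-linear one — if the
true rates were not log-linear in age, part of any observed bias would be
model misspecification rather than MicDaD, which is why the simulation keeps
the model correctly specified.
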