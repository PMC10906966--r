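---
title: "Simulating from sufficient-component-cause models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating from sufficient-component-cause models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccsim)
```

## The model

`sccsim` simulates from *sufficient-component-cause* (SCC) models over
binary variables. The stated world is:

- **Exogenous components** are mutually independent Bernoulli variables
  with declared prevalences. Independence is enforced by construction —
  independent binomial draws when simulating, product-form weights when
  enumerating — and is an assumption of the framework, not an option.
- **Endogenous variables** are deterministic boolean functions of their
  causes: a variable equals 1 exactly when at least one of its sufficient
  causes (a conjunction of literals) is completed. A literal may require a
  component's presence or absence; absence literals are how mechanisms such
  as "high education causes study participation" are expressed.
- The dependency graph is acyclic; data generation assigns values
  hierarchically, from the exogenous components toward the outcome.

Because every component of every individual is known, each individual's
*risk-set type* (their components other than the exposure) and hence
*response type* is known: clamp the exposure to 1 and to 0, re-evaluate the
cascade, and classify the potential-outcome pair as doomed, causal,
preventive or immune. Clamping never resamples a component — the response
type is a property of the individual's other causes — and when the exposure
is itself endogenous (confounding scenario) clamping severs its causes,
which is ordinary do-operator semantics on a boolean structural model.

Two consequences anchor the test suite: the sample average treatment effect
equals the proportion of causal minus preventive types, identically, in
every sample; and when no sufficient cause contains the exposure's absence
(monotonicity), preventive types are structurally impossible.

## The exact oracle

With `k` independent components the joint distribution has `2^k` weighted
patterns (capped at `k = 20`; the shipped scenarios use at most 8). Every
population quantity is a weighted sum over patterns and therefore exact:
true effects under `do(exposure)`, crude (observational) contrasts,
response-type probabilities, and all of these within sub-populations.
Conditioning — on a modifier stratum or on realized study participation —
always uses *factual* variable values while the potential outcomes use the
clamped cascade; this matches how response types are reported within an
analytic sample of realized participants.

Monte Carlo results are validated against this oracle (binomial bound at
`n = 10^6`, α = 0.001), and the oracle itself is cross-checked against the
closed form available for the two-cause causation model.

## Calibration: prevalences are the effect sizes

In SCC simulation there are no regression coefficients; effect sizes emerge
from component prevalences. Where a target effect is wanted,
`calibrate_prevalences()` solves for selected prevalences so that exact
oracle statistics equal the targets. The solver is deliberately boring and
deterministic: the i-th free parameter is bisected on `[0, 1]` against the
i-th target statistic while the others are held fixed, with an outer
fixed-point sweep (tolerance `1e-6`, at most 200 sweeps). For the shipped
scenarios the paired statistics are monotone in their parameters, and the
sweep converges in a handful of iterations; infeasible targets raise an
error carrying the best residuals rather than returning a near miss.

## The scenarios and their defaults

All scenarios default to 1,000 samples of 10,000 individuals. The exposure
(low education) prevalence defaults to 0.5; it has no bearing on risk
ratios, risk differences or within-group response-type proportions, all of
which are the quantities of interest. The unexposed dementia risk is
anchored at `P(Z2) = 0.10` (a plausible dementia risk in older adults
without low education), and crude associations are calibrated to ≈ 1.55,
inside the range reported for education and dementia.

- **Causation** — `Dementia <- (LowEdu & Z1) | Z2`, `P(Z1) = 0.06` is
  back-calculated from the 0.10 anchor and the target ratio, giving true
  RR 1.54 / RD 0.054.
- **Confounding (sharp null)** — low education is endogenous
  (`(LowSES & Q1) | Q2`) and the education mechanism is switched off
  (`P(Z1) = 0`). Defaults `P(LowSES) = 0.4`, `P(Q1) = 0.6`, `P(Q2) = 0.2`
  produce a strong SES–education link; `P(Z3)` and `P(Z4)` are calibrated so
  the exact crude association is RR 1.55 / RD 0.079 while the true effect is
  exactly null. Those two targets pin the doomed prevalence among the
  exposed at `RD·RR/(RR−1) ≈ 22.3%`.
- **Collider** — participation `<- (!LowEdu & X1) | X2 | (APOE & X3)`,
  dementia `<- Z5 | (APOE & Z6)` (`P(Z1) = 0`). Defaults `P(APOE) = 0.25`,
  `P(X1) = 0.28`, `P(X2) = 0.05`, `P(X3) = 0.7` give a participation
  probability of ≈ 0.326 (mean analytic sample ≈ 3,260 of 10,000) and leave
  `P(Z5)`, `P(Z6)` to calibration against the analytic-sample crude
  RR 1.55 / RD 0.117. Education and APOE are independent in the full
  population, so full-sample contrasts are exactly null; restriction to
  participants induces the bias, and APOE-standardization removes it exactly
  on the oracle.
- **Effect modification** — the education cause is split into
  `(LowEdu & Z1a)` and `(LowEdu & APOE & Z1b)`. Both stratum prevalences are
  closed-form back-calculations from the stratum targets (carriers
  RR 2.22 / RD 0.122, non-carriers RR 1.36 / RD 0.036):
  `P(Z1a) = p2(rr_nc − 1)/(1 − p2) = 0.04` and
  `P(Z1b) = 1 − (1 − p2·rr_c)/((1 − P(Z1a))(1 − p2)) ≈ 0.0995`. With
  `P(APOE) = 0.25` the implied overall truth is RR 1.575 / RD 0.0575
  (reported rounded as 1.58 / 0.058), which is why 0.25 is the default
  carrier prevalence rather than an arbitrary choice.
- **Confounding, non-sharp-null** — same structure with `P(Z1) = 0.06`; the
  sharp-null calibration is reused for the other components. On the oracle
  the crude association exceeds the SES-standardized one, which equals the
  (now non-null) true effect exactly.

Where the published account fixes a number (the 0.06/0.10 causation pair,
the crude targets, the stratum effects) it is a default here; the remaining
degrees of freedom (`P(LowSES)`, `P(Q1)`, `P(Q2)`, the participation
prevalences) are under-determined by those constraints, so they were chosen
once in plausible epidemiologic ranges, are documented above, and are
ordinary arguments for instructors who want different worlds.

## Summaries and intervals

Across iterations each statistic is summarized by its arithmetic mean and
empirical 2.5th/97.5th percentiles. Percentiles were chosen over a normal
approximation because ratio estimates have asymmetric sampling
distributions at these event rates; the arithmetic (not geometric) mean of
per-iteration RRs is reported, consistent with slight upward shifts of mean
stratified RRs relative to their true values (e.g. 2.26 vs 2.22 among
carriers). Iterations where an estimate is undefined — an empty exposure
group, an empty standardization cell, a zero unexposed risk — are flagged,
excluded from that statistic's summary and counted in `n_excluded`; at the
default scale and these prevalences this effectively never occurs.

## Numerical choices and degenerate inputs

- Exact identities (ATE = causal − preventive; weights summing to 1;
  null effects in sharp-null structures) are asserted at `1e-12`.
- Calibration tolerance is `1e-6` on each statistic; bisection runs to an
  interval of `1e-13`, so results are reproducible to more digits than the
  tolerance guarantees.
- Degenerate models are flagged, not guessed at: a zero-probability
  sub-population stops an oracle computation; an all-exposed sample yields a
  flagged estimate; a scenario whose exposure prevalence is 0 fails
  calibration with residual diagnostics.
- A weaker form of monotonicity (a preventive mechanism existing but no
  individual completing only that cause) is described in the literature; the
  engine supports absent-state exposure literals, so such models can be
  declared, but no canned scenario uses one.

## What a green test establishes — and what it does not

The generator emulates the stated teaching world: binary variables,
independent components, deterministic boolean causation, cumulative risks
over an implicit fixed timeframe. Real cohort data violate most of this —
correlated causes, time-varying exposure, censoring, measurement error,
non-binary variables — so agreement between the simulations and the exact
oracle validates the engine and the pedagogy, not any empirical claim about
education and dementia. Within scope, limitations worth naming: no
interaction response types for joint exposures, no automated translation
from a DAG to an SCC model (an analyst step), no dependence among exogenous
components, and enumeration is exponential in the number of components
(fine at the teaching scale this package targets).
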