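---
title: "Simulating virtual human populations for PBPK priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating virtual human populations for PBPK priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physpop)
```

## Why a hierarchical prior

PBPK models describe chemical disposition through compartments that are
real organs connected by blood flow.  Population-level inference — forward
dosimetry, reverse dosimetry from biomarkers, or QIVIVE — needs a prior
over the organ masses and regional flows of the target population.
Specifying that prior organ-by-organ (independent lognormals, or normal
fractions of body weight and cardiac output) ignores the correlations that
anatomy imposes: tall people have heavier livers, adipose and muscle trade
off against each other, and all fifteen masses must sum to the body weight
that the skeleton and skin were generated for.  A piecemeal prior therefore
spends most of its probability on physiologies that cannot occur, and in a
weakly identified inverse problem that prior mass does not wash out.

`physpop` instead generates whole individuals hierarchically, so that every
emitted physiology is internally consistent, and exposes the contextual
handles (gender, ethnicity, age, height, body mass — exact or bounded) that
shrink the prior when partial information about a subject is available.

## The generative model

### Phase 1: age, height, body mass, cardiac output

* **Age** is uniform on [16, 65] years.  A census-derived piecewise fit
  would add precision the downstream models cannot use; the uniform is an
  adequate approximation for the working-age population and is trivially
  replaced by an exact value or interval through `constraints()`.
* **Height (cm) and log body mass (log kg)** are bivariate normal with
  quadratic-in-age means and an ethnicity/gender-specific residual
  correlation ρ (0.28–0.46 across the twelve sub-populations).  Sampling
  uses the marginal/conditional factorisation: one variable from its
  truncated marginal, the other from the conditional normal
  N(μ_Y + (σ_Y/σ_X) ρ (X − μ_X), (1 − ρ²) σ_Y²), truncated to its own
  bounds.  Default bounds are location ± 3σ; a constraint interval
  overrides them (body-mass intervals are mapped to the log scale).  The
  variable with the smaller standardised width σ⁻¹(upper − lower) is drawn
  first — the more tightly constrained variable carries more information,
  so it is treated as the marginal; with no constraints both widths are 6
  and the tie resolves to height.  Exact constraints bypass sampling
  entirely and drive the conditional of the other variable.
* **BMI filter.** The coefficient tables were fitted to populations
  restricted to BMI 17.5–32.5 kg/m², so the same window is the default at
  simulation time, enforced by rejection of (height, mass) pairs.
  Rejection reproduces the fitting-time truncation without distorting the
  conditional structure.  The cap is 10,000 redraw rounds, after which the
  constraints are reported as incompatible rather than silently relaxed.
* **Cardiac output (L/min)** is normal about a gender-specific regression:
  males `α + h1·H + a1·A + a2/(1 + exp(−a3(A − 18)))` (the logistic term
  captures late male maturation), females `α + h1·H + a1·A + a2·A² +
  a3·A³`.  The coefficient magnitudes and the simulated medians (≈ 5–6)
  identify the unit as L/min even though one table header in the source
  material reads ml/min; the package adopts L/min throughout.  Draws are
  truncated below at zero, which with σ ≈ 0.1 around a location of 5–7 is
  never binding.

### Phase 2: organ masses and flows

Fifteen organs and tissues are modelled: lung, brain, heart, kidneys,
liver, pancreas, spleen, stomach, small and large intestine, sexual organs,
skin, bone (total skeleton), adipose, skeletal muscle.

* **Masses** follow the printed mean forms (constant; linear in height or
  age; quadratic in body mass for skin; a logistic-ramp height form for
  male bone; age/height/BMI forms for adipose and muscle).  Lung, spleen,
  adipose and muscle are lognormal — the form is the mean of the natural
  log and σ is the log-scale SD, the only reading that yields plausible
  organ sizes (e.g. spleen e^−1.44 ≈ 0.24 kg).  Each draw is truncated to
  its central 90% (±1.6449σ) so masses are never unrealistically extreme.
  Log adipose and log muscle are drawn jointly with their strong negative
  correlation (−0.86 to −0.90): surplus body mass is fat *or* muscle, not
  both.  The joint draw is truncated to the rectangle of the two marginal
  bands by rejection from the bivariate normal; whether that truncation
  should be marginal or fully joint is not prescribed, and the rectangle
  reading keeps both marginals inside their printed bands (the test suite
  checks the resulting correlation against a quadrature oracle for the
  rectangle-truncated bivariate normal).
* **Flows** are normal fractions of cardiac output truncated at ±2σ
  (intra-individual flow variability is poorly known and the printed σ are
  generous).  The fractions are gender-specific and shared across
  ethnicities and countries; their sum is ≈ 1.03 (male) / 1.02 (female)
  before rescaling.
* **Balancing.** All flows are rescaled by a common factor so they sum to
  cardiac output.  For mass, rescaling everything would push small organs
  below realistic sizes whenever adipose or muscle came out large, so only
  adipose and muscle are rescaled, by the common factor
  λ = (BM − Σ other 13)/(adipose + muscle); the common factor is the
  minimal intervention that preserves the adipose:muscle ratio and hence
  their sampled correlation.  Individuals with λ outside [0.2, 5]
  (including λ ≤ 0, where the other organs already exceed body mass) are
  rejected and fully redrawn; the count is recorded in the population
  attributes, and 100 fruitless rounds raise an error — constraints that
  routinely force λ ≤ 0 (say, a 25 kg body mass at 190 cm) are treated as
  infeasible rather than papered over.

Masses and flows are mutually independent given the phase-1 state; no
organ-level mass–flow correlation is modelled.

### Reproducibility and numerics

Truncated normals are drawn by inverse CDF (`qnorm` of a uniform between
the bound CDF values), which is exact, vectorised and respects the seed; a
constraint interval lying beyond ±8σ of its marginal raises an error since
no double-precision probability mass remains.  Zero-σ parameter sets
degenerate cleanly to the location functions (the conditional shift is
defined as 0 when the conditioning σ is 0), which is what the closed-form
pipeline oracle in the test suite exploits.  The RNG stream is consumed in
a fixed documented order (age; first anthropometry variable; second;
cardiac output; organ masses; adipose/muscle pair; flow fractions), so a
seed fully determines a population.

## Parameter data

All coefficients ship as two plain-text CSVs under
`inst/extdata/parameters/` (one anthropometry/cardiac-output record per
population; one record per population × organ), loaded and validated by
`load_parameters()` and frozen by checksum tests.  Transcription is
verbatim, including three oddities kept as printed rather than "fixed": the
UK Caucasian female stomach mass σ of 0.022 (the male value is 0.055); the
US Caucasian male adipose BMI coefficient of 0.0105 (other male populations
print ≈ 0.105); and a muscle-mass form that nominally includes a BMI² term
for which no population prints a coefficient (transcribed as 0).  One name
collision in the US Caucasian male bone row (two coefficients labelled h₂)
is resolved by pattern with every other male bone row (h₁ ≈ 0.04,
h₂ ≈ 0.009); the values are unchanged.  `validate_parameters()` returns
violations as data so hand-edited parameter sets can be checked the same
way.

## Aggregation, blood, and the sink update

`aggregate()` lumps organs under a user scheme; `default_scheme()` is the
conventional pairing (rapidly perfused = heart, lung, spleen, pancreas,
sexual organs; slowly perfused = skin, muscle).  `sohn_scheme()` is the
four-compartment partition used for the prior comparison: fat, liver, all
remaining viscera as rapidly perfused, and muscle + skin + bone as slowly
perfused — the standard mapping for four-compartment volatile-organic PBPK
models.  `subtract_blood()` removes a stated blood mass via per-organ
reference fractions; those fractions are reference-document values that are
deliberately *not* shipped — they must be supplied explicitly, and the
subtracted blood is reported as its own entry so total mass is conserved.
`sink_rebalance()` implements the single-component update needed inside an
MCMC sampler: set one organ's mass and flow, let skeletal muscle (or a
chosen sink) absorb the difference, and fail loudly if the sink would go
non-positive — the caller should reject such proposals.

No closed-form distribution is offered for aggregated compartments (a sum
of normals and lognormals has none); inverse problems should either keep
organs separate or approximate the compartment distribution per
application.

## Literature priors and the plausibility screen

`sample_sohn()` draws the four-compartment prior in which every mass and
flow is an independent lognormal; the printed pairs are read as geometric
mean and geometric SD (dispersions near 2.1 are only sensible as GSDs), and
cardiac output is the sum of the four flows.  `sample_allen()` draws the
body-weight/fraction prior: bounded lognormal body weight, cardiac output
as a bounded-normal coefficient (L/hr) scaled by BW^0.75 and converted to
L/min — the only reading consistent with its reported central cardiac
output — and truncated-normal tissue and flow fractions, including the
gut/intestine double counting of the original specification, reproduced as
printed.  `reference_bounds()` takes the absolute min/max of every
aggregated quantity over a simulated reference population (n ≥ 10⁴
recommended), and `screen_physiologies()` classes a draw as plausible only
if every quantity falls inside its bounds.  The screen is deliberately
generous — absolute bounds, not percentiles — which makes sub-1% pass rates
for the literature priors the more telling.

## What the simulator does and does not emulate

It emulates: survey-consistent anthropometry by country, gender, ethnicity
and age; age trends in cardiac output, bone, muscle and adipose; the
adipose–muscle trade-off; hard mass and flow balance; honest truncation of
every marginal.  It does not emulate: children or adults over 65; severe
obesity (BMI > 32.5 — the skeletal-muscle and skin models would need
different forms there); biochemical/metabolic variability; organ-level
mass–flow correlation; intra-individual change over time.  Tests passing
on simulated data therefore certify the internal consistency of the
generative model and its agreement with the published summary statistics,
not fidelity to any particular external cohort.

## Problem sizes

The package's own checks run populations of 10,000 (matching the scale at
which the reference summary statistics were produced) for the acceptance
checks, and 2,000–50,000 draws for moment-recovery tests; a 10,000-member
population simulates in well under a second on one CPU core.
`scripts/acceptance.R` regenerates every headline number from scratch at
n = 10,000 per population.

## Known limitations

* The twelve parameter sets are transcriptions; the three printed oddities
  noted above are preserved, so the US Caucasian male adipose model in
  particular should be treated with caution at high BMI.
* Bounds-based screening depends on the reference population size; min/max
  bounds widen slowly with n, so fractions near the 1% boundary should be
  read with that in mind.
* Ethnicity is a coarse survey label, not a biological covariate; the
  stratification reflects the underlying survey databases.
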