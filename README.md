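# physpop

Virtual human populations for physiologically based pharmacokinetic (PBPK)
modelling.

## The problem

Reverse dosimetry and quantitative in vitro-to-in vivo extrapolation
(QIVIVE) invert a PBPK model: from a biomarker or an in vitro
concentration-response they infer the external dose a human population
could have received.  That inversion needs a prior distribution over human
physiology — organ masses and regional blood flows — and the priors
historically used for this purpose (independent lognormals per compartment,
or normal fractions of body weight and cardiac output) admit far more
variation than real human anatomy does: most of the parameter space they
cover corresponds to people who cannot exist.

`physpop` provides a concise, hierarchical, fully probabilistic alternative:
a generative model of the adult (16–65 years) working-age population,
stratified by country (UK, US), gender, and ethnicity (White/Caucasian,
Asian, Black for the UK; White/Caucasian, Non-Black Hispanic, Black for the
US), whose coefficient tables derive from national survey databases (HSE,
NHANES III) and cadaver-informed organ algorithms.  It is aimed at PBPK
modellers who need realistic population priors, and at anyone who wants to
screen a proposed prior for physiological plausibility.

## The model

Each virtual individual is built in two phases.

**Phase 1 — the "shell".** Age A ~ U(16, 65) (or fixed/bounded by
contextual information).  Height and log body mass are bivariate normal
with age-dependent means,

    H       ~ N(α_H + a1·A + a2·A², σ_H²)
    log BM  ~ N(α_B + b1·A + b2·A², σ_B²),   cor(H, log BM) = ρ

sampled as a truncated marginal followed by the conditional
N(μ_Y + (σ_Y/σ_X)·ρ·(X − μ_X), (1 − ρ²)·σ_Y²); which variable goes first is
decided by the smaller standardised interval width σ⁻¹(upper − lower)
(defaults ±3σ, overridden by any known interval).  BMI is restricted to
17.5–32.5 by rejection, matching the populations the coefficients were
fitted to.  Cardiac output follows a gender-specific regression on age and
height (logistic late-maturation term for males, cubic in age for
females).

**Phase 2 — the organs.** Fifteen organ/tissue masses follow normal
(lognormal for lung, spleen, adipose, muscle) distributions whose means are
the printed functions of age, height, body mass and BMI, truncated at the
5th–95th percentiles; log adipose and log muscle are drawn jointly with a
strong negative correlation (ρ ≈ −0.9).  Flows are normal fractions of
cardiac output truncated at ±2σ.  Flow balance rescales all flows so they
sum to cardiac output; mass balance rescales *only* adipose and muscle by a
common factor λ so that the fifteen masses sum to body mass.

Downstream: organs can be lumped into rapidly/slowly perfused compartments,
blood mass can be subtracted given reference organ-blood fractions, a
"sink" update keeps balance under single-component MCMC proposals, and two
published literature prior styles can be sampled and screened against the
absolute bounds of a simulated reference population.

## Worked example

A 16-year-old US Non-Black Hispanic female population:

```r
library(physpop)
m <- physiology_model("US", "female", "Hispanic", constr = constraints(age = 16))
pop <- simulate(m, nsim = 10000, seed = 1)
pop
#> virtual population: 10000 individuals (US Hispanic female)
#>   body mass 58.4 kg, cardiac output 5.90 L/min (medians)
summary(pop, scheme = default_scheme())
#> population summary (US Hispanic female, n = 10000)
#>  quantity                    median   95% interval
#>  body_mass_kg                 58.4000 (42.8, 80.5)
#>  cardiac_output_l_min          5.9000 (5.55, 6.25)
#>  flow_rapidly_perfused_l_min   0.6770 (0.493, 0.877)
#>  flow_slowly_perfused_l_min    0.9970 (0.684, 1.31)
#>  mass_adipose_kg              19.3000 (7.78, 42.3)
#>  flow_kidneys_l_min            1.1700 (0.778, 1.56)
#>  flow_liver_l_min              0.4100 (0.231, 0.596)
#>  ...
```

The median body mass (58.4 kg), cardiac output (5.90 L/min) and regional
flows (kidneys 1.17, liver 0.41 L/min) are the central physiology of that
sub-population; the 95% intervals quantify inter-individual variability
with all masses summing to each individual's body weight and all flows to
their cardiac output.

Contextual information tightens the prior.  For a UK Caucasian male known
only from tick-box survey answers — aged 50–55, 1.71–1.75 m, 75–80 kg:

```r
m2 <- physiology_model("UK", "male", "White",
                       constraints(age = c(50, 55), height = c(171, 175),
                                   body_mass = c(75, 80)))
pop2 <- simulate(m2, nsim = 10000, seed = 2)
```

The conditioned adipose, muscle and cardiac-output distributions are
substantially narrower than the unconditioned ones.

Plausibility screening of a published four-compartment lognormal prior
against a simulated US Caucasian male reference population:

```r
bounds <- reference_bounds(physiology_model("US", "male", "White"),
                           n = 10000, scheme = sohn_scheme(), seed = 3)
screen_physiologies(sample_sohn(10000, seed = 4), bounds)
#> [1] 0.001
```

— about 0.1% of draws from that prior are consistent with human
physiology.

A thin command-line wrapper ships in `inst/scripts/physpop-cli.R`
(subcommands `simulate`, `summarize`, `compare`, `validate-params`; all
accept `--seed` and `--config`).

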