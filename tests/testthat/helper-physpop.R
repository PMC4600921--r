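## Shared fixtures and independent oracles.

uk_male_white <- load_parameters("UK", "male", "White")
us_female_hisp <- load_parameters("US", "female", "Hispanic")
us_female_white <- load_parameters("US", "female", "White")

## Closed-form moments of N(mean, sd^2) truncated symmetrically at +- z*sd:
## the mean is unchanged; the variance shrinks by the standard factor.
trunc_sd_oracle <- function(sd, z) {
  shrink <- 1 - 2 * z * dnorm(z) / (2 * pnorm(z) - 1)
  sd * sqrt(shrink)
}

## Post-truncation correlation of a standard bivariate normal restricted to
## the rectangle [-z, z]^2, by 2-D quadrature (independent of the sampler).
bivar_trunc_cor_oracle <- function(rho, z) {
  dens <- function(x, y)
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
  Z <- pracma::quad2d(dens, -z, z, -z, z, n = 64)
  Exy <- pracma::quad2d(function(x, y) x * y * dens(x, y),
                        -z, z, -z, z, n = 64) / Z
  Ex2 <- pracma::quad2d(function(x, y) x^2 * dens(x, y),
                        -z, z, -z, z, n = 64) / Z
  ## means are zero by symmetry; marginal variances equal by exchangeability
  Exy / Ex2
}

## Closed-form deterministic physiology: every sigma forced to zero, so the
## whole pipeline collapses to evaluating the table formulas plus the two
## rebalances.  Used as the brute-force oracle for the simulator.
zero_sigma_params <- function(params) {
  params$anthro$height_sigma <- 0
  params$anthro$logbm_sigma <- 0
  params$co$sigma <- 0
  for (o in organ_names()) {
    params$organs[[o]]$mass_sigma <- 0
    params$organs[[o]]$flow_sigma <- 0
  }
  params
}

deterministic_oracle <- function(params, age) {
  H <- height_location(age, params)
  BM <- exp(logbm_location(age, params))
  BMI <- BM / (H / 100)^2
  CO <- cardiac_output_location(age, H, params)
  ind <- list(age = age, height = H, body_mass = BM, bmi = BMI)
  masses <- sapply(organ_names(), function(o) {
    m <- params$organs[[o]]
    loc <- organ_mass_location(m, ind)
    if (m$family == "lognormal") exp(loc) else loc
  })
  others <- sum(masses[setdiff(organ_names(), c("adipose", "muscle"))])
  lam <- (BM - others) / (masses["adipose"] + masses["muscle"])
  masses["adipose"] <- masses["adipose"] * lam
  masses["muscle"] <- masses["muscle"] * lam
  c1 <- sapply(organ_names(), function(o) params$organs[[o]]$flow_c1)
  flows <- CO * c1 / sum(c1)
  list(age = age, height = H, body_mass = BM, bmi = BMI,
       cardiac_output = CO, masses = masses, flows = flows)
}

## phase-1 states with the BMI filter off (for recovery checks)
phase1_unfiltered <- function(n, params, constr = constraints()) {
  age <- sample_age(n, constr)
  hm <- sample_height_mass(n, age, constr, params, bmi_limits = NULL)
  data.frame(age = age, height = hm$height, body_mass = hm$body_mass,
             bmi = hm$body_mass / (hm$height / 100)^2)
}
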