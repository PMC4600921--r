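## Phase 1: age, height, body mass (jointly) and cardiac output.

#' Contextual constraints on age, height and body mass
#'
#' Partial knowledge about an individual can be fed into the simulation:
#' each of age, height and body mass may be left unspecified (the population
#' default), fixed at an exact value, or bounded within an interval.
#' Interval knowledge is honoured by sampling from correspondingly truncated
#' normal distributions; an exact value is passed through unchanged.
#'
#' @param age `NULL` (uniform on 16-65 years), a single value in years, or
#'   a length-2 interval `c(lo, hi)` within \[16, 65\].
#' @param height `NULL`, an exact height in cm, or an interval in cm.
#' @param body_mass `NULL`, an exact body mass in kg, or an interval in kg.
#' @return An object of class `"physpop_constraints"`.
#' @examples
#' constraints(age = 49)
#' constraints(age = c(50, 55), height = c(171, 175), body_mass = c(75, 80))
#' @export
constraints <- function(age = NULL, height = NULL, body_mass = NULL) {
  chk <- function(x, name, lo = -Inf, hi = Inf) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (!length(x) %in% 1:2 || anyNA(x))
      stop(name, " constraint must be an exact value or a c(lo, hi) interval")
    if (length(x) == 2L && x[1L] >= x[2L])
      stop(name, " interval must have lo < hi")
    if (any(x < lo) || any(x > hi))
      stop(name, " constraint must lie within [", lo, ", ", hi, "]")
    x
  }
  structure(list(age = chk(age, "age", 16, 65),
                 height = chk(height, "height", 0),
                 body_mass = chk(body_mass, "body_mass", 0)),
            class = "physpop_constraints")
}

#' @export
print.physpop_constraints <- function(x, ...) {
  show <- function(v, unit) {
    if (is.null(v)) "population default"
    else if (length(v) == 1L) paste0("= ", v, " ", unit)
    else paste0("in [", v[1L], ", ", v[2L], "] ", unit)
  }
  cat("contextual constraints:\n")
  cat("  age       ", show(x$age, "yr"), "\n")
  cat("  height    ", show(x$height, "cm"), "\n")
  cat("  body mass ", show(x$body_mass, "kg"), "\n")
  invisible(x)
}

## Inverse-CDF draw from N(mean, sd^2) truncated to (lower, upper).
## Vectorised over all arguments; sd = 0 degenerates to the clamped mean.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  out <- numeric(n)
  degen <- sd <= 0
  if (any(degen))
    out[degen] <- pmin(pmax(mean[degen], lower[degen]), upper[degen])
  if (any(!degen)) {
    i <- which(!degen)
    a <- (lower[i] - mean[i]) / sd[i]
    b <- (upper[i] - mean[i]) / sd[i]
    if (any(a > 8 | b < -8))
      stop("truncation interval has essentially zero probability mass ",
           "(beyond 8 sigma)")
    p <- stats::runif(length(i), stats::pnorm(a), stats::pnorm(b))
    out[i] <- mean[i] + sd[i] * stats::qnorm(p)
  }
  out
}

#' Sample age
#'
#' Unconstrained ages are uniform on 16-65 years, the working-age
#' approximation used throughout the model; an interval constraint gives a
#' uniform draw on the interval and an exact constraint is returned as is.
#'
#' @param n Number of draws.
#' @param constr A [constraints()] object (only its `age` field is used).
#' @return Numeric vector of ages in years.
#' @export
sample_age <- function(n, constr = constraints()) {
  a <- constr$age
  if (is.null(a)) stats::runif(n, 16, 65)
  else if (length(a) == 1L) rep_len(a, n)
  else stats::runif(n, a[1L], a[2L])
}

#' Location (mean) functions of the anthropometry marginals
#'
#' `height_location()` returns the age-dependent mean height in cm;
#' `logbm_location()` the mean of log body mass in log(kg).  Both are the
#' quadratic-in-age forms `alpha + a1*A + a2*A^2` with population-specific
#' coefficients.
#'
#' @param age Age in years (vectorised).
#' @param params A `"physpop_params"` object from [load_parameters()].
#' @return Numeric vector.
#' @examples
#' p <- load_parameters("UK", "male", "White")
#' height_location(30, p)  # 177.8 cm
#' @export
height_location <- function(age, params) {
  a <- params$anthro
  a$height_alpha + a$height_a1 * age + a$height_a2 * age^2
}

#' @rdname height_location
#' @export
logbm_location <- function(age, params) {
  a <- params$anthro
  a$logbm_alpha + a$logbm_a1 * age + a$logbm_a2 * age^2
}

## Decide which anthropometry variable is simulated marginally: the one
## whose standardised constraint width sigma^-1 (upper - lower) is smaller
## (defaults +-3 sigma, i.e. width 6); ties go to height.
.anthro_order <- function(constr, params) {
  a <- params$anthro
  w <- function(con, sigma) {
    if (is.null(con) || length(con) == 1L) 6
    else (con[2L] - con[1L]) / sigma
  }
  wh <- w(constr$height, a$height_sigma)
  con_m <- constr$body_mass
  if (!is.null(con_m) && length(con_m) == 2L) con_m <- log(con_m)
  wm <- if (is.null(con_m) || length(con_m) == 1L) 6
        else (con_m[2L] - con_m[1L]) / a$logbm_sigma
  if (wm < wh) "mass_first" else "height_first"
}

#' Sample height and body mass jointly
#'
#' Height and log body mass follow a bivariate normal distribution around
#' their age-dependent locations.  One variable is drawn from its truncated
#' marginal and the other from the conditional normal given the first;
#' which is drawn first depends on the constraints: the variable with the
#' smaller standardised interval width (default bounds are location +- 3
#' standard deviations, overwritten by any constraint interval) is drawn
#' marginally.  Exact constraints pass through unchanged.  When BMI limits
#' are supplied the pair is rejection-sampled until BMI falls inside them.
#'
#' @param n Number of individuals.
#' @param age Age(s) in years, recycled to length `n`.
#' @param constr A [constraints()] object (height/body-mass fields used).
#' @param params A `"physpop_params"` object.
#' @param bmi_limits `NULL` to disable the BMI filter, or `c(lo, hi)` in
#'   kg/m^2 (the population default is `c(17.5, 32.5)`).
#' @param max_tries Rejection cap for the BMI filter.
#' @return A list with numeric vectors `height` (cm) and `body_mass` (kg).
#' @export
sample_height_mass <- function(n, age, constr = constraints(), params,
                               bmi_limits = NULL, max_tries = 10000L) {
  age <- rep_len(age, n)
  a <- params$anthro
  draw_pair <- function(idx_age) {
    m <- length(idx_age)
    mu_h <- height_location(idx_age, params)
    mu_l <- logbm_location(idx_age, params)
    ch <- constr$height
    cm <- constr$body_mass
    ## exact constraints short-circuit the bivariate machinery
    h_exact <- !is.null(ch) && length(ch) == 1L
    m_exact <- !is.null(cm) && length(cm) == 1L
    bnd <- function(con, mu, sigma, logscale = FALSE) {
      if (is.null(con) || length(con) == 1L)
        cbind(mu - 3 * sigma, mu + 3 * sigma)
      else {
        con <- if (logscale) log(con) else con
        cbind(rep_len(con[1L], length(mu)), rep_len(con[2L], length(mu)))
      }
    }
    bh <- bnd(ch, mu_h, a$height_sigma)
    bl <- bnd(cm, mu_l, a$logbm_sigma, logscale = TRUE)
    rho <- a$rho_height_logbm
    cond <- function(x, mu_x, s_x, mu_y, s_y) { # E, SD of Y | X = x
      shift <- if (s_x > 0) (s_y / s_x) * rho * (x - mu_x) else 0
      list(mean = mu_y + shift, sd = s_y * sqrt(1 - rho^2))
    }
    if (h_exact && m_exact) {
      list(height = rep_len(ch, m), body_mass = rep_len(cm, m))
    } else if (h_exact) {
      h <- rep_len(ch, m)
      cl <- cond(h, mu_h, a$height_sigma, mu_l, a$logbm_sigma)
      l <- rtruncnorm(m, cl$mean, cl$sd, bl[, 1L], bl[, 2L])
      list(height = h, body_mass = exp(l))
    } else if (m_exact) {
      l <- rep_len(log(cm), m)
      chm <- cond(l, mu_l, a$logbm_sigma, mu_h, a$height_sigma)
      h <- rtruncnorm(m, chm$mean, chm$sd, bh[, 1L], bh[, 2L])
      list(height = h, body_mass = rep_len(cm, m))
    } else if (.anthro_order(constr, params) == "height_first") {
      h <- rtruncnorm(m, mu_h, a$height_sigma, bh[, 1L], bh[, 2L])
      cl <- cond(h, mu_h, a$height_sigma, mu_l, a$logbm_sigma)
      l <- rtruncnorm(m, cl$mean, cl$sd, bl[, 1L], bl[, 2L])
      list(height = h, body_mass = exp(l))
    } else {
      l <- rtruncnorm(m, mu_l, a$logbm_sigma, bl[, 1L], bl[, 2L])
      chm <- cond(l, mu_l, a$logbm_sigma, mu_h, a$height_sigma)
      h <- rtruncnorm(m, chm$mean, chm$sd, bh[, 1L], bh[, 2L])
      list(height = h, body_mass = exp(l))
    }
  }

  res <- draw_pair(age)
  if (!is.null(bmi_limits)) {
    bmi <- res$body_mass / (res$height / 100)^2
    bad <- which(bmi < bmi_limits[1L] | bmi > bmi_limits[2L])
    tries <- 0L
    while (length(bad)) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("constraints are incompatible with the BMI limits [",
             bmi_limits[1L], ", ", bmi_limits[2L], "] (rejection cap hit)")
      rr <- draw_pair(age[bad])
      res$height[bad] <- rr$height
      res$body_mass[bad] <- rr$body_mass
      bmi_bad <- rr$body_mass / (rr$height / 100)^2
      bad <- bad[bmi_bad < bmi_limits[1L] | bmi_bad > bmi_limits[2L]]
    }
  }
  res
}

#' Cardiac output location and sampling
#'
#' The mean cardiac output (L/min) is a gender-specific regression on age
#' and height: for males `alpha + h1*H + a1*A + a2/(1 + exp(-a3*(A - 18)))`
#' (a logistic ramp describing late male maturation), for females
#' `alpha + h1*H + a1*A + a2*A^2 + a3*A^3`.  `sample_cardiac_output()` adds
#' normal intra-individual variability (truncated below at zero, which is
#' never binding in practice).
#'
#' @param age Age in years (vectorised).
#' @param height Height in cm (vectorised).
#' @param params A `"physpop_params"` object.
#' @param n Number of draws.
#' @return Numeric vector of cardiac outputs in L/min.
#' @examples
#' p <- load_parameters("US", "female", "White")
#' cardiac_output_location(49, 163.06, p)  # about 5.095
#' @export
cardiac_output_location <- function(age, height, params) {
  co <- params$co
  base <- co$alpha + co$h1 * height + co$a1 * age
  if (co$form == "male_logistic")
    base + co$a2 / (1 + exp(-co$a3 * (age - 18)))
  else
    base + co$a2 * age^2 + co$a3 * age^3
}

#' @rdname cardiac_output_location
#' @export
sample_cardiac_output <- function(n, age, height, params) {
  loc <- cardiac_output_location(age, height, params)
  rtruncnorm(n, loc, params$co$sigma, lower = 0)
}

## Full phase 1: age, (height, body mass), BMI, cardiac output.
## Draws consume the RNG stream in that fixed order.
sample_phase1 <- function(n, params, constr = constraints(),
                          bmi_limits = c(17.5, 32.5)) {
  age <- sample_age(n, constr)
  hm <- sample_height_mass(n, age, constr, params, bmi_limits = bmi_limits)
  bmi <- hm$body_mass / (hm$height / 100)^2
  co <- sample_cardiac_output(n, age, hm$height, params)
  data.frame(age = age, height = hm$height, body_mass = hm$body_mass,
             bmi = bmi, cardiac_output = co)
}
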