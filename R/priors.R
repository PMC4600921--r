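## Literature prior specifications and the plausibility screen.
##
## Two published prior styles are reproduced for comparison: a direct
## four-compartment lognormal specification (an adult male inhalation
## model), and a body-weight/fraction specification with truncated normal
## fractions (a female population of child-bearing age).  Both are screened
## against min/max bounds from a reference population simulated with this
## package.

## Four-compartment lognormal priors: geometric mean and geometric SD per
## compartment, volumes (L) treated as masses (kg) 1:1.
.sohn_spec <- list(
  mass = list(fat              = c(gm = 12.87, gsd = 2.10),
              slowly_perfused  = c(gm = 42.30, gsd = 2.06),
              rapidly_perfused = c(gm = 12.94, gsd = 2.18),
              liver            = c(gm = 2.18,  gsd = 2.08)),
  flow = list(fat              = c(gm = 0.30, gsd = 2.30),
              slowly_perfused  = c(gm = 0.81, gsd = 2.22),
              rapidly_perfused = c(gm = 3.98, gsd = 2.22),
              liver            = c(gm = 1.12, gsd = 2.30)))

#' Sample the four-compartment lognormal prior
#'
#' Draws independent lognormal masses (kg) and flows (L/min) for fat,
#' slowly perfused, rapidly perfused and liver compartments, each
#' parameterised by geometric mean and geometric standard deviation.
#' Cardiac output is the sum of the four flows.
#'
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Data frame with columns `mass_<compartment>_kg`,
#'   `flow_<compartment>_l_min` and `cardiac_output_l_min`.
#' @export
sample_sohn <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(row.names = seq_len(n))
  for (cmp in names(.sohn_spec$mass)) {
    s <- .sohn_spec$mass[[cmp]]
    out[[paste0("mass_", cmp, "_kg")]] <-
      stats::rlnorm(n, log(s[["gm"]]), log(s[["gsd"]]))
  }
  for (cmp in names(.sohn_spec$flow)) {
    s <- .sohn_spec$flow[[cmp]]
    out[[paste0("flow_", cmp, "_l_min")]] <-
      stats::rlnorm(n, log(s[["gm"]]), log(s[["gsd"]]))
  }
  out$cardiac_output_l_min <-
    rowSums(out[, paste0("flow_", names(.sohn_spec$flow), "_l_min")])
  out
}

## Body-weight + fraction prior: BW lognormal (log-scale mean/sd with
## bounds), cardiac output scaled to BW^0.75, truncated-normal fractions.
.allen_spec <- list(
  bw = list(meanlog = log(67.77), sdlog = log(1.603),
            bounds = c(30.81, 139.9)),
  ## L/hr per kg^0.75; converted to L/min after scaling by BW^0.75
  co = list(mean = 20, sd = 10, bounds = c(6.8, 33.2)),
  volume = list(   # fractions of body weight
    liver            = list(mean = 0.026, sd = 0.013,  bounds = c(0.006, 0.046)),
    kidney           = list(mean = 0.004, sd = 0.002,  bounds = c(0.0004, 0.008)),
    brain            = list(mean = 0.02,  sd = 0.01,   bounds = c(0.002, 0.038)),
    intestine        = list(mean = 0.014, sd = 0.007,  bounds = c(0.001, 0.027)),
    gut              = list(mean = 0.017, sd = 0.0085, bounds = c(0.009, 0.025)),
    rapidly_perfused = list(mean = 0.10,  sd = 0.05,   bounds = c(0.01, 0.190)),
    slowly_perfused  = list(mean = 0.35,  sd = 0.175,  bounds = c(0.18, 0.52)),
    adipose          = list(mean = 0.273, sd = 0.14,   bounds = c(0.076, 0.47)),
    remainder        = list(mean = 0.122, sd = 0.061,  bounds = c(0.012, 0.23))),
  flow = list(     # fractions of cardiac output
    liver            = list(mean = 0.046, sd = 0.023,  bounds = c(0.01, 0.090)),
    kidney           = list(mean = 0.175, sd = 0.0875, bounds = c(0.018, 0.333)),
    brain            = list(mean = 0.114, sd = 0.057,  bounds = c(0.011, 0.217)),
    gut              = list(mean = 0.181, sd = 0.0905, bounds = c(0.002, 0.360)),
    rapidly_perfused = list(mean = 0.183, sd = 0.0915, bounds = c(0.018, 0.348)),
    slowly_perfused  = list(mean = 0.249, sd = 0.1245, bounds = c(0.025, 0.473)),
    adipose          = list(mean = 0.052, sd = 0.0256, bounds = c(0.0052, 0.099))))

#' Sample the body-weight/fraction prior
#'
#' Body weight is lognormal (bounded); cardiac output is a truncated-normal
#' coefficient scaled by body weight to the 0.75 power and converted from
#' L/hr to L/min; tissue volumes are truncated-normal fractions of body
#' weight and regional flows truncated-normal fractions of cardiac output,
#' each restricted to its printed bounding interval.  Volumes (L) are
#' treated as masses (kg) 1:1.
#'
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Data frame with `body_mass_kg`, `cardiac_output_l_min`,
#'   `mass_<tissue>_kg` and `flow_<tissue>_l_min` columns.
#' @export
sample_allen <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- .allen_spec$bw
  lb <- log(s$bounds)
  bw <- exp(rtruncnorm(n, s$meanlog, s$sdlog, lb[1L], lb[2L]))
  s <- .allen_spec$co
  qcc <- rtruncnorm(n, s$mean, s$sd, s$bounds[1L], s$bounds[2L])
  co <- qcc * bw^0.75 / 60
  out <- data.frame(body_mass_kg = bw, cardiac_output_l_min = co)
  for (tis in names(.allen_spec$volume)) {
    s <- .allen_spec$volume[[tis]]
    fr <- rtruncnorm(n, s$mean, s$sd, s$bounds[1L], s$bounds[2L])
    out[[paste0("mass_", tis, "_kg")]] <- fr * bw
  }
  for (tis in names(.allen_spec$flow)) {
    s <- .allen_spec$flow[[tis]]
    fr <- rtruncnorm(n, s$mean, s$sd, s$bounds[1L], s$bounds[2L])
    out[[paste0("flow_", tis, "_l_min")]] <- fr * co
  }
  out
}

#' Plausibility bounds from a reference population
#'
#' Simulates (or accepts) a reference population, aggregates it under a
#' scheme, and records the minimum and maximum of every mass, flow and
#' cardiac output.  A physiology is later classed as plausible if every
#' quantity falls inside these absolute bounds.
#'
#' @param x A `"physiology_model"`, `"physpop_params"` or an already
#'   simulated `"physiology_population"`.
#' @param n Reference population size (ignored if `x` is already a
#'   population); at least 10^4 is recommended.
#' @param scheme Aggregation scheme applied before taking bounds.
#' @param seed Optional integer seed.
#' @return An object of class `"plausibility_bounds"`: a data frame with
#'   columns `quantity`, `min`, `max`.
#' @export
reference_bounds <- function(x, n = 10000, scheme = sohn_scheme(),
                             seed = NULL) {
  pop <- if (inherits(x, "physiology_population")) x
         else simulate_population(x, n = n, seed = seed)
  agg <- stats::aggregate(pop, scheme = scheme)
  qcols <- c(grep("^(mass|flow)_", names(agg), value = TRUE),
             "cardiac_output_l_min")
  out <- data.frame(quantity = qcols,
                    min = vapply(agg[qcols], min, numeric(1)),
                    max = vapply(agg[qcols], max, numeric(1)),
                    row.names = NULL)
  class(out) <- c("plausibility_bounds", "data.frame")
  out
}

#' Screen physiologies against plausibility bounds
#'
#' A sampled physiology is plausible if and only if every screened quantity
#' lies within the reference minimum and maximum.  Only quantities present
#' in both the samples and the bounds are screened; by default every bound
#' quantity must be present.
#'
#' @param samples Data frame of sampled physiologies (e.g. from
#'   [sample_sohn()] or an aggregated population).
#' @param bounds A [reference_bounds()] object.
#' @param quantities Character vector of quantities to screen; defaults to
#'   every quantity in `bounds`, and it is an error if any is missing from
#'   `samples`.
#' @return The fraction of samples classed as plausible, in \[0, 1\].
#' @export
screen_physiologies <- function(samples, bounds,
                                quantities = bounds$quantity) {
  missing <- setdiff(quantities, names(samples))
  if (length(missing))
    stop("samples lack screened quantities: ",
         paste(missing, collapse = ", "))
  missing_b <- setdiff(quantities, bounds$quantity)
  if (length(missing_b))
    stop("bounds lack screened quantities: ",
         paste(missing_b, collapse = ", "))
  ok <- rep(TRUE, nrow(samples))
  for (q in quantities) {
    b <- bounds[bounds$quantity == q, ]
    ok <- ok & samples[[q]] >= b$min & samples[[q]] <= b$max
  }
  mean(ok)
}
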