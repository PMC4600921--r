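## The user-facing model object: a population prior for human physiology.

#' A probabilistic model of adult human physiology
#'
#' Bundles the parameter set of one sub-population with optional contextual
#' constraints and the BMI window into a model object.  The object is a
#' generative prior: `simulate()` draws virtual individuals whose age,
#' height, body mass, cardiac output and fifteen organ masses and flows are
#' mutually consistent (masses sum to body weight, flows to cardiac
#' output).
#'
#' @param country,gender,ethnicity Population selectors, see
#'   [population_key()].
#' @param constr A [constraints()] object with contextual information.
#' @param bmi_limits BMI window `c(lo, hi)` in kg/m^2; the populations the
#'   parameters were fitted to were restricted to 17.5-32.5, so that is the
#'   default.  `NULL` disables the filter.
#' @return An object of class `"physiology_model"` with elements `params`,
#'   `constraints`, `bmi_limits`.
#' @examples
#' m <- physiology_model("US", "female", "Hispanic", constraints(age = 16))
#' pop <- simulate(m, nsim = 200, seed = 1)
#' summary(pop)
#' @seealso [simulate_population()], [summary.physiology_population()]
#' @export
physiology_model <- function(country, gender = NULL, ethnicity = NULL,
                             constr = constraints(),
                             bmi_limits = c(17.5, 32.5)) {
  params <- if (inherits(country, "physpop_params")) country
            else load_parameters(country, gender, ethnicity)
  stopifnot(inherits(constr, "physpop_constraints"))
  if (!is.null(bmi_limits)) {
    bmi_limits <- as.numeric(bmi_limits)
    if (length(bmi_limits) != 2L || bmi_limits[1L] >= bmi_limits[2L])
      stop("bmi_limits must be c(lo, hi) with lo < hi, or NULL")
  }
  structure(list(params = params, constraints = constr,
                 bmi_limits = bmi_limits),
            class = "physiology_model")
}

#' Simulate virtual individuals from a physiology model
#'
#' @param object A `"physiology_model"`.
#' @param nsim Number of individuals.
#' @param seed Optional integer seed; with a fixed seed the output is
#'   reproducible bit for bit.
#' @param ... Unused.
#' @return A `"physiology_population"` data frame; see
#'   [simulate_population()].
#' @export
simulate.physiology_model <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_population(object, n = nsim, seed = seed)
}

#' @export
print.physiology_model <- function(x, ...) {
  k <- x$params$key
  cat(sprintf("physiology model: %s %s %s population\n",
              k$country, k$ethnicity, k$gender))
  print(x$constraints)
  if (is.null(x$bmi_limits)) cat("  BMI filter off\n")
  else cat(sprintf("  BMI restricted to [%g, %g] kg/m^2\n",
                   x$bmi_limits[1L], x$bmi_limits[2L]))
  invisible(x)
}

#' @export
coef.physiology_model <- function(object, ...) {
  p <- object$params
  org <- lapply(p$organs, function(m)
    c(unlist(Filter(Negate(is.na), m$coeffs)),
      mass_sigma = m$mass_sigma, flow_c1 = m$flow_c1,
      flow_sigma = m$flow_sigma))
  list(anthropometry = unlist(p$anthro),
       cardiac_output = unlist(p$co[-1L]),
       organs = org,
       rho_adipose_muscle = p$rho_adipose_muscle)
}

#' @export
summary.physiology_model <- function(object, ...) {
  print(object)
  print(object$params)
  invisible(object)
}

#' @export
print.physiology_population <- function(x, ...) {
  k <- attr(x, "key")
  cat(sprintf("virtual population: %d individuals (%s %s %s)\n",
              nrow(x), k$country, k$ethnicity, k$gender))
  rej <- attr(x, "rejections")
  if (!is.null(rej) && rej > 0)
    cat(sprintf("  %d mass-balance rejections during simulation\n", rej))
  cat(sprintf("  body mass %.1f kg, cardiac output %.2f L/min (medians)\n",
              stats::median(x$body_mass_kg),
              stats::median(x$cardiac_output_l_min)))
  invisible(x)
}

#' Diagnostic plots for a simulated population
#'
#' Histograms of body mass, cardiac output and the two dominant tissue
#' masses (adipose and skeletal muscle).
#'
#' @param x A `"physiology_population"`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.physiology_population <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::hist(x$body_mass_kg, main = "Body mass",
                 xlab = "kg", col = "grey85", ...)
  graphics::hist(x$cardiac_output_l_min, main = "Cardiac output",
                 xlab = "L/min", col = "grey85", ...)
  graphics::hist(x$mass_adipose_kg, main = "Adipose mass",
                 xlab = "kg", col = "grey85", ...)
  graphics::hist(x$mass_muscle_kg, main = "Skeletal muscle mass",
                 xlab = "kg", col = "grey85", ...)
  invisible(x)
}
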