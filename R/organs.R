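## Phase 2: organ/tissue masses and regional blood flows, with mass balance
## to body weight and flow balance to cardiac output.

#' Location of an organ mass model
#'
#' Evaluates the mean form of one organ's mass model at the given phase-1
#' state.  For normally distributed organs the value is the mean mass in
#' kg; for log-normally distributed organs (lung, spleen, adipose, muscle)
#' it is the mean of the natural log of mass, so the median mass is its
#' exponential.
#'
#' @param model One element of `params$organs`, e.g.
#'   `load_parameters(...)$organs$liver`.
#' @param individual A data frame (or list) with fields `age`, `height`,
#'   `body_mass`, `bmi`; vectorised over rows.
#' @return Numeric vector of locations (kg, or log kg).
#' @examples
#' p <- load_parameters("UK", "male", "White")
#' organ_mass_location(p$organs$liver, list(age = 30, height = 176,
#'                     body_mass = 76, bmi = 24.5))  # 2.449 kg
#' @export
organ_mass_location <- function(model, individual) {
  A <- individual$age; H <- individual$height
  BM <- individual$body_mass; BMI <- individual$bmi
  k <- model$coeffs
  switch(model$form,
    const         = rep_len(k$alpha, max(length(A), 1L)),
    height_linear = k$alpha + k$h1 * H,
    age_linear    = k$alpha + k$a1 * A,
    bm_quadratic  = k$alpha + k$m1 * BM + k$m2 * BM^2,
    bone_male     = k$alpha + k$h1 * H +
                    k$h2 * H / (1 + exp(-k$a1 * (A - 18))),
    bone_female   = k$alpha + k$a1 * A + k$a2 * A^2 + k$h1 * H,
    adipose_form  = k$alpha + k$a1 * A + k$a2 * A^2 + k$h1 * H +
                    k$b1 * BMI,
    muscle_form   = k$alpha + k$a1 * A + k$a2 * A^2 + k$h1 * H +
                    k$b1 * BMI + k$b2 * BMI^2,
    stop("unknown mass form: ", model$form))
}

## Joint draw of (log adipose, log muscle): bivariate normal with the
## population correlation, truncated to the rectangle of the two central-90%
## marginal bands (rejection from the joint).
.sample_adipose_muscle <- function(mu_a, sd_a, mu_m, sd_m, rho) {
  n <- length(mu_a)
  la <- numeric(n); lm <- numeric(n)
  todo <- seq_len(n)
  lo_a <- mu_a - .z90 * sd_a; hi_a <- mu_a + .z90 * sd_a
  lo_m <- mu_m - .z90 * sd_m; hi_m <- mu_m + .z90 * sd_m
  guard <- 0L
  while (length(todo)) {
    guard <- guard + 1L
    if (guard > 10000L) stop("adipose-muscle joint sampler failed to accept")
    z1 <- stats::rnorm(length(todo))
    z2 <- stats::rnorm(length(todo))
    x <- mu_a[todo] + sd_a * z1
    y <- mu_m[todo] + sd_m * (rho * z1 + sqrt(1 - rho^2) * z2)
    ok <- x >= lo_a[todo] & x <= hi_a[todo] &
          y >= lo_m[todo] & y <= hi_m[todo]
    la[todo[ok]] <- x[ok]
    lm[todo[ok]] <- y[ok]
    todo <- todo[!ok]
  }
  list(log_adipose = la, log_muscle = lm)
}

#' Sample raw (pre-balance) organ masses
#'
#' Each organ mass is drawn around its model location, truncated to its
#' central 90% (5th to 95th percentile) so that masses are not
#' unrealistically small or large.  Normal organs are drawn on the kg
#' scale, log-normal organs on the log scale.  The logs of adipose and
#' muscle mass are drawn jointly from a bivariate normal with the
#' population's (strongly negative) correlation, truncated to the rectangle
#' of their marginal bands.  Should a normal organ's 5th percentile fall at
#' or below zero the lower truncation is clamped to a small positive floor
#' and a warning is issued.
#'
#' @param individual Data frame of phase-1 states (`age`, `height`,
#'   `body_mass`, `bmi`), one row per individual.
#' @param params A `"physpop_params"` object.
#' @return Numeric matrix, one row per individual, one named column per
#'   organ; all entries strictly positive.  These are raw masses, before
#'   [rebalance_masses()].
#' @export
sample_organ_masses <- function(individual, params) {
  n <- length(individual$age)
  out <- matrix(NA_real_, n, length(.organs),
                dimnames = list(NULL, .organs))
  clamped <- character(0)
  for (o in setdiff(.organs, c("adipose", "muscle"))) {
    m <- params$organs[[o]]
    loc <- organ_mass_location(m, individual)
    lo <- loc - .z90 * m$mass_sigma
    hi <- loc + .z90 * m$mass_sigma
    if (m$family == "normal" && any(lo <= 0)) {
      lo <- pmax(lo, 1e-4)
      clamped <- c(clamped, o)
    }
    x <- rtruncnorm(n, loc, m$mass_sigma, lo, hi)
    out[, o] <- if (m$family == "lognormal") exp(x) else x
  }
  if (length(clamped))
    warning("5th percentile at or below zero for ",
            paste(unique(clamped), collapse = ", "),
            "; lower truncation clamped to 1e-4 kg")
  ma <- params$organs$adipose; mm <- params$organs$muscle
  am <- .sample_adipose_muscle(
    organ_mass_location(ma, individual), ma$mass_sigma,
    organ_mass_location(mm, individual), mm$mass_sigma,
    params$rho_adipose_muscle)
  out[, "adipose"] <- exp(am$log_adipose)
  out[, "muscle"] <- exp(am$log_muscle)
  out
}

#' Sample regional flow fractions
#'
#' Each organ's share of cardiac output is drawn from a normal distribution
#' around its reference fraction `c1`, truncated at two standard deviations
#' (intra-individual variability in regional flows is not well known and
#' the printed ranges are generous).  A positive floor of 1e-6 guards
#' organs whose `c1 - 2*sigma` would be non-positive.
#'
#' @param n Number of individuals.
#' @param params A `"physpop_params"` object.
#' @return Numeric matrix, one row per individual, one named column per
#'   organ; dimensionless fractions of cardiac output (they need not sum
#'   to one until [rebalance_flows()] is applied).
#' @export
sample_flow_fractions <- function(n, params) {
  out <- matrix(NA_real_, n, length(.organs),
                dimnames = list(NULL, .organs))
  for (o in .organs) {
    m <- params$organs[[o]]
    lo <- max(m$flow_c1 - 2 * m$flow_sigma, 1e-6)
    hi <- m$flow_c1 + 2 * m$flow_sigma
    out[, o] <- rtruncnorm(n, m$flow_c1, m$flow_sigma, lo, hi)
  }
  out
}

#' Rescale flows to cardiac output
#'
#' Flow balance is achieved by rescaling all regional flows by a common
#' factor so that their sum equals cardiac output exactly.
#'
#' @param fractions Matrix of flow fractions (rows = individuals, columns =
#'   organs), all positive.
#' @param cardiac_output Cardiac output in L/min, one value per row.
#' @return Matrix of flows in L/min whose rows sum to `cardiac_output`.
#' @export
rebalance_flows <- function(fractions, cardiac_output) {
  fractions <- rbind(fractions)           # tolerate a bare vector
  tot <- rowSums(fractions)
  if (any(tot <= 0)) stop("flow fractions must have a positive sum")
  fractions * (cardiac_output / tot)
}

#' Rescale adipose and muscle mass to achieve mass balance
#'
#' All organ masses except adipose and skeletal muscle are treated as
#' correct; adipose and muscle are multiplied by the common factor
#' `lambda = (body_mass - sum of the other 13) / (adipose + muscle)` so the
#' fifteen masses sum exactly to body mass.  The common factor preserves
#' the adipose:muscle ratio and hence their sampled correlation structure.
#'
#' @param raw_masses Matrix of raw organ masses from
#'   [sample_organ_masses()].
#' @param body_mass Body mass in kg, one value per row.
#' @return A list with `masses` (the balanced matrix) and `lambda` (the
#'   per-individual scale factor; non-positive values mean the other organs
#'   already exceed body mass and the individual should be rejected).
#' @export
rebalance_masses <- function(raw_masses, body_mass) {
  raw_masses <- rbind(raw_masses)
  others <- setdiff(colnames(raw_masses), c("adipose", "muscle"))
  s <- rowSums(raw_masses[, others, drop = FALSE])
  lambda <- (body_mass - s) /
    (raw_masses[, "adipose"] + raw_masses[, "muscle"])
  out <- raw_masses
  out[, "adipose"] <- raw_masses[, "adipose"] * lambda
  out[, "muscle"] <- raw_masses[, "muscle"] * lambda
  list(masses = out, lambda = lambda)
}

## lambda acceptance window: reject pathological draws where the adipose +
## muscle rescaling would be extreme.
.lambda_window <- c(0.2, 5)

#' Simulate a virtual population
#'
#' Composes the full hierarchy: age, then height and body mass jointly,
#' then cardiac output (phase 1); then organ masses and flow fractions
#' (phase 2); then the flow rescaling to cardiac output and the
#' adipose/muscle-only mass rescaling to body weight.  Individuals whose
#' mass-balance factor falls outside a sanity window are rejected and
#' redrawn transparently; the count is recorded in the result attributes.
#'
#' @param params A `"physpop_params"` object, a `"physpop_key"`, or a
#'   `"physiology_model"`.
#' @param n Number of individuals.
#' @param constr A [constraints()] object.
#' @param bmi_limits `c(lo, hi)` BMI window (default 17.5-32.5 kg/m^2), or
#'   `NULL` to disable the filter.
#' @param seed Optional integer seed for reproducibility.
#' @return A `"physiology_population"`: a data frame with columns `id`,
#'   `age`, `height_cm`, `body_mass_kg`, `bmi`, `cardiac_output_l_min`, and
#'   `mass_<organ>_kg` / `flow_<organ>_l_min` for the fifteen organs.
#'   Attributes `key`, `constraints`, `bmi_limits`, `seed` and `rejections`
#'   record the provenance.
#' @examples
#' pop <- simulate_population(load_parameters("UK", "male", "White"),
#'                            n = 100, seed = 1)
#' summary(pop)
#' @export
simulate_population <- function(params, n, constr = constraints(),
                                bmi_limits = c(17.5, 32.5), seed = NULL) {
  if (inherits(params, "physiology_model")) {
    constr <- params$constraints
    bmi_limits <- params$bmi_limits
    params <- params$params
  } else if (inherits(params, "physpop_key")) {
    params <- load_parameters(params)
  }
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)

  got <- 0L
  rejections <- 0L
  rounds <- 0L
  ph1_all <- NULL; mass_all <- NULL; flow_all <- NULL
  while (got < n) {
    rounds <- rounds + 1L
    if (rounds > 100L)
      stop("mass balance failed repeatedly (", rejections,
           " rejections); constraints may force an infeasible physiology")
    need <- n - got
    ph1 <- sample_phase1(need, params, constr, bmi_limits)
    raw <- sample_organ_masses(ph1, params)
    bal <- rebalance_masses(raw, ph1$body_mass)
    fr <- sample_flow_fractions(need, params)
    fl <- rebalance_flows(fr, ph1$cardiac_output)
    ok <- bal$lambda >= .lambda_window[1L] & bal$lambda <= .lambda_window[2L]
    rejections <- rejections + sum(!ok)
    if (any(ok)) {
      ph1_all <- rbind(ph1_all, ph1[ok, , drop = FALSE])
      mass_all <- rbind(mass_all, bal$masses[ok, , drop = FALSE])
      flow_all <- rbind(flow_all, fl[ok, , drop = FALSE])
      got <- got + sum(ok)
    }
  }

  colnames(mass_all) <- paste0("mass_", .organs, "_kg")
  colnames(flow_all) <- paste0("flow_", .organs, "_l_min")
  out <- data.frame(id = seq_len(n),
                    age = ph1_all$age,
                    height_cm = ph1_all$height,
                    body_mass_kg = ph1_all$body_mass,
                    bmi = ph1_all$bmi,
                    cardiac_output_l_min = ph1_all$cardiac_output,
                    mass_all, flow_all,
                    row.names = NULL)
  structure(out,
            key = params$key,
            constraints = constr,
            bmi_limits = bmi_limits,
            seed = seed,
            rejections = rejections,
            class = c("physiology_population", "data.frame"))
}

#' @rdname simulate_population
#' @export
simulate_individual <- function(params, constr = constraints(),
                                bmi_limits = c(17.5, 32.5), seed = NULL) {
  simulate_population(params, n = 1L, constr = constr,
                      bmi_limits = bmi_limits, seed = seed)
}

## column helpers shared by aggregation / summaries
.mass_cols <- function(pop) grep("^mass_.*_kg$", names(pop), value = TRUE)
.flow_cols <- function(pop) grep("^flow_.*_l_min$", names(pop), value = TRUE)
.col_organ <- function(cols) sub("^(mass|flow)_(.*)_(kg|l_min)$", "\\2", cols)
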