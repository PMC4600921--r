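## Parameter registry: coefficient tables for the 12 sub-populations,
## loaded from plain-text CSV so the transcription is auditable.

#' Organ and tissue names used throughout the package
#'
#' The fifteen organs and tissues whose masses (kg) and regional blood flows
#' (L/min) are simulated.  The masses of the lung, spleen, adipose and
#' skeletal muscle are log-normally distributed; all other organ masses are
#' normally distributed.
#'
#' @return Character vector of length 15.
#' @export
organ_names <- function() .organs

.organs <- c("lung", "brain", "heart", "kidneys", "liver", "pancreas",
             "spleen", "stomach", "small_intestine", "large_intestine",
             "sexual_organs", "skin", "bone", "adipose", "muscle")

.lognormal_organs <- c("lung", "spleen", "adipose", "muscle")

.uk_ethnicities <- c("White", "Asian", "Black")
.us_ethnicities <- c("White", "Hispanic", "Black")

## z for the central 90% band (5th/95th percentile truncation of masses)
.z90 <- stats::qnorm(0.95)

.param_file <- function(name) {
  f <- system.file("extdata", "parameters", name, package = "physpop",
                   mustWork = FALSE)
  if (!nzchar(f) || !file.exists(f))
    stop("parameter file not found: ", name)
  f
}

#' Construct a population key
#'
#' A population key identifies one of the twelve sub-populations (two
#' countries by two genders by three ethnicities each) for which parameter
#' sets are shipped.  "Caucasian" is accepted as a synonym for "White", and
#' "Non-Black Hispanic" for "Hispanic".
#'
#' @param country "UK" or "US".
#' @param gender "male" or "female".
#' @param ethnicity For the UK: "White" (or "Caucasian"), "Asian", "Black".
#'   For the US: "White" (or "Caucasian"), "Hispanic" (or
#'   "Non-Black Hispanic"), "Black".
#' @return An object of class `"physpop_key"`: a list with elements
#'   `country`, `gender`, `ethnicity` (normalised labels).
#' @examples
#' population_key("UK", "male", "Caucasian")
#' @export
population_key <- function(country, gender, ethnicity) {
  country <- toupper(as.character(country)[1L])
  if (!country %in% c("UK", "US"))
    stop("unknown country '", country, "'; legal values: UK, US")
  gender <- tolower(as.character(gender)[1L])
  if (!gender %in% c("male", "female"))
    stop("unknown gender '", gender, "'; legal values: male, female")
  ethnicity <- .normalise_ethnicity(ethnicity)
  legal <- if (country == "UK") .uk_ethnicities else .us_ethnicities
  if (!ethnicity %in% legal)
    stop("ethnicity '", ethnicity, "' is not defined for ", country,
         "; legal values: ", paste(legal, collapse = ", "))
  structure(list(country = country, gender = gender, ethnicity = ethnicity),
            class = "physpop_key")
}

.normalise_ethnicity <- function(x) {
  x <- gsub("[ _-]", "", tolower(as.character(x)[1L]))
  switch(x,
         white = , caucasian = "White",
         asian = "Asian",
         black = "Black",
         hispanic = , nonblackhispanic = "Hispanic",
         ## return as given so the caller's error message shows the input
         as.character(x))
}

#' @export
print.physpop_key <- function(x, ...) {
  cat(sprintf("<population: %s %s %s>\n", x$country, x$ethnicity, x$gender))
  invisible(x)
}

#' List the available sub-populations
#'
#' @return A data frame with columns `country`, `gender`, `ethnicity`;
#'   one row per shipped parameter set (12 in all).
#' @export
list_populations <- function() {
  d <- utils::read.csv(.param_file("anthropometry.csv"),
                       stringsAsFactors = FALSE)
  d[, c("country", "gender", "ethnicity")]
}

#' Load the parameter set for one sub-population
#'
#' Reads the shipped coefficient tables: the age/height/log(body mass)
#' marginals and height-log(body mass) correlation, the cardiac output
#' regression, and the fifteen organ mass and flow models (including the
#' adipose-muscle log-scale correlation).
#'
#' @param country,gender,ethnicity Passed to [population_key()].  The first
#'   argument may instead be a `"physpop_key"` object.
#' @return An object of class `"physpop_params"`: a list with elements
#'   `key`, `anthro`, `co` (cardiac output), `organs` (a named list of 15
#'   organ models) and `rho_adipose_muscle`.
#' @examples
#' p <- load_parameters("UK", "male", "White")
#' p$anthro$height_alpha   # 176.0
#' @export
load_parameters <- function(country, gender = NULL, ethnicity = NULL) {
  key <- if (inherits(country, "physpop_key")) country
         else population_key(country, gender, ethnicity)

  anth <- utils::read.csv(.param_file("anthropometry.csv"),
                          stringsAsFactors = FALSE)
  row <- anth[anth$country == key$country & anth$gender == key$gender &
              anth$ethnicity == key$ethnicity, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("anthropometry record missing for ",
         paste(key$country, key$gender, key$ethnicity))
  anthro <- list(
    height_alpha = row$height_alpha, height_a1 = row$height_a1,
    height_a2 = row$height_a2, height_sigma = row$height_sigma,
    logbm_alpha = row$logbm_alpha, logbm_a1 = row$logbm_a1,
    logbm_a2 = row$logbm_a2, logbm_sigma = row$logbm_sigma,
    rho_height_logbm = row$rho_height_logbm)
  co <- list(
    form = if (key$gender == "male") "male_logistic" else "female_cubic",
    alpha = row$co_alpha, h1 = row$co_h1, a1 = row$co_a1,
    a2 = row$co_a2, a3 = row$co_a3, sigma = row$co_sigma)

  org <- utils::read.csv(.param_file("organs.csv"), stringsAsFactors = FALSE)
  org <- org[org$country == key$country & org$gender == key$gender &
             org$ethnicity == key$ethnicity, , drop = FALSE]
  organs <- list()
  for (o in .organs) {
    r <- org[org$organ == o, , drop = FALSE]
    if (nrow(r) != 1L)
      stop("organ record missing for ", o, " (",
           paste(key$country, key$gender, key$ethnicity), ")")
    organs[[o]] <- list(
      organ = o, family = r$family, form = r$form,
      coeffs = list(alpha = r$alpha, a1 = r$a1, a2 = r$a2, h1 = r$h1,
                    h2 = r$h2, m1 = r$m1, m2 = r$m2, b1 = r$b1, b2 = r$b2),
      mass_sigma = r$mass_sigma,
      flow_c1 = r$c1, flow_sigma = r$flow_sigma)
  }
  rho_am <- org$rho[org$organ == "adipose"]

  params <- structure(
    list(key = key, anthro = anthro, co = co, organs = organs,
         rho_adipose_muscle = rho_am),
    class = "physpop_params")
  bad <- validate_parameters(params)
  if (length(bad))
    stop("invalid parameter set for ",
         paste(key$country, key$gender, key$ethnicity), ":\n  ",
         paste(bad, collapse = "\n  "))
  params
}

## coefficients each mass form requires (beyond alpha)
.form_coeffs <- list(
  const          = character(0),
  height_linear  = "h1",
  age_linear     = "a1",
  bm_quadratic   = c("m1", "m2"),
  bone_male      = c("a1", "h1", "h2"),
  bone_female    = c("a1", "a2", "h1"),
  adipose_form   = c("a1", "a2", "h1", "b1"),
  muscle_form    = c("a1", "a2", "h1", "b1", "b2"))

#' Validate a parameter set
#'
#' Checks the structural invariants of a parameter set: 15 organs, the
#' correct distribution family per organ, positive standard deviations,
#' correlations inside (-1, 1), coefficients present for each mass form.
#' Violations are returned as data rather than raised as errors.
#'
#' @param params A `"physpop_params"` object (possibly hand-modified).
#' @return Character vector of violations; empty if the set is valid.
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  a <- params$anthro
  for (f in c("height_sigma", "logbm_sigma"))
    if (!is.numeric(a[[f]]) || is.na(a[[f]]) || a[[f]] <= 0)
      v <- c(v, paste0("anthro$", f, ": must be > 0"))
  if (is.na(a$rho_height_logbm) || abs(a$rho_height_logbm) >= 1)
    v <- c(v, "anthro$rho_height_logbm: must lie in (-1, 1)")
  if (is.na(params$co$sigma) || params$co$sigma <= 0)
    v <- c(v, "co$sigma: must be > 0")
  expected_form <- if (params$key$gender == "male") "male_logistic"
                   else "female_cubic"
  if (!identical(params$co$form, expected_form))
    v <- c(v, paste0("co$form: expected ", expected_form))

  orgs <- params$organs
  if (length(orgs) != 15L)
    v <- c(v, paste0("organs: expected 15, got ", length(orgs)))
  missing <- setdiff(.organs, names(orgs))
  if (length(missing))
    v <- c(v, paste0("organs: missing ", paste(missing, collapse = ", ")))
  for (o in intersect(.organs, names(orgs))) {
    m <- orgs[[o]]
    fam_expected <- if (o %in% .lognormal_organs) "lognormal" else "normal"
    if (!identical(m$family, fam_expected))
      v <- c(v, paste0("organs$", o, "$family: expected ", fam_expected))
    if (is.na(m$mass_sigma) || m$mass_sigma <= 0)
      v <- c(v, paste0("organs$", o, "$mass_sigma: must be > 0"))
    if (is.na(m$flow_c1) || m$flow_c1 <= 0)
      v <- c(v, paste0("organs$", o, "$flow_c1: must be > 0"))
    if (is.na(m$flow_sigma) || m$flow_sigma <= 0)
      v <- c(v, paste0("organs$", o, "$flow_sigma: must be > 0"))
    if (is.na(m$coeffs$alpha))
      v <- c(v, paste0("organs$", o, "$coeffs$alpha: missing"))
    need <- .form_coeffs[[m$form]]
    if (is.null(need)) {
      v <- c(v, paste0("organs$", o, "$form: unknown form '", m$form, "'"))
    } else {
      for (cf in need)
        if (is.na(m$coeffs[[cf]]))
          v <- c(v, paste0("organs$", o, "$coeffs$", cf,
                           ": required by form ", m$form))
    }
  }
  if (is.na(params$rho_adipose_muscle) ||
      params$rho_adipose_muscle > 0 || params$rho_adipose_muscle <= -1)
    v <- c(v, "rho_adipose_muscle: must lie in (-1, 0]")
  v
}

#' @export
print.physpop_params <- function(x, ...) {
  k <- x$key
  cat(sprintf("physpop parameter set: %s %s %s\n",
              k$country, k$ethnicity, k$gender))
  cat(sprintf("  height  ~ N(%g %+g A %+g A^2, %g^2) cm\n",
              x$anthro$height_alpha, x$anthro$height_a1, x$anthro$height_a2,
              x$anthro$height_sigma))
  cat(sprintf("  log(BM) ~ N(%g %+g A %+g A^2, %g^2), rho(H, logBM) = %g\n",
              x$anthro$logbm_alpha, x$anthro$logbm_a1, x$anthro$logbm_a2,
              x$anthro$logbm_sigma, x$anthro$rho_height_logbm))
  cat(sprintf("  cardiac output: %s form, sigma = %g L/min\n",
              x$co$form, x$co$sigma))
  cat(sprintf("  15 organ models; rho(log adipose, log muscle) = %g\n",
              x$rho_adipose_muscle))
  invisible(x)
}
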