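## Population summary tables and CSV/JSON input-output.

#' Summary statistics for a simulated population
#'
#' Per-quantity empirical median and 2.5/97.5 percentiles (the conventional
#' 95% population interval), computed with the linear-interpolation
#' quantile definition (`stats::quantile()` type 7).  At the population
#' sizes used here (10^4) the choice of quantile definition is immaterial
#' at the printed precision.
#'
#' @param object A `"physiology_population"`.
#' @param scheme Optional [aggregation_scheme()]; if supplied the
#'   population is aggregated before summarising.
#' @param probs Lower/upper interval probabilities, default
#'   `c(0.025, 0.975)`.
#' @param ... Unused.
#' @return An object of class `"physpop_summary"`: a data frame with
#'   columns `quantity`, `median`, `lower`, `upper`, plus attributes `n`,
#'   `key`, `probs`.
#' @export
summary.physiology_population <- function(object, scheme = NULL,
                                          probs = c(0.025, 0.975), ...) {
  if (nrow(object) == 0L) stop("population is empty")
  d <- if (is.null(scheme)) as.data.frame(object)
       else stats::aggregate(object, scheme = scheme)
  qcols <- setdiff(names(d)[vapply(d, is.numeric, logical(1))], "id")
  out <- data.frame(
    quantity = qcols,
    median = vapply(d[qcols], stats::median, numeric(1)),
    lower = vapply(d[qcols], stats::quantile, numeric(1),
                   probs = probs[1L], type = 7, names = FALSE),
    upper = vapply(d[qcols], stats::quantile, numeric(1),
                   probs = probs[2L], type = 7, names = FALSE),
    row.names = NULL)
  structure(out, n = nrow(d), key = attr(object, "key"), probs = probs,
            class = c("physpop_summary", "data.frame"))
}

#' @rdname summary.physiology_population
#' @param pop A `"physiology_population"`.
#' @export
summarize_population <- function(pop, scheme = NULL,
                                 probs = c(0.025, 0.975)) {
  summary(pop, scheme = scheme, probs = probs)
}

#' @export
print.physpop_summary <- function(x, digits = 3, ...) {
  k <- attr(x, "key")
  if (!is.null(k))
    cat(sprintf("population summary (%s %s %s, n = %d)\n",
                k$country, k$ethnicity, k$gender, attr(x, "n")))
  p <- attr(x, "probs")
  d <- data.frame(quantity = x$quantity,
                  median = signif(x$median, digits),
                  interval = sprintf("(%s, %s)", signif(x$lower, digits),
                                     signif(x$upper, digits)))
  names(d)[3L] <- sprintf("%g%% interval", 100 * diff(p))
  print(d, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Write / read a simulated population
#'
#' The population is written as plain CSV at full double precision, with a
#' JSON sidecar (`<file>.json`) recording provenance: population key,
#' constraints, BMI limits, seed, rejection count and package version.
#' `read_population()` restores the data frame, its class and—when the
#' sidecar is present—its attributes, so written and re-read populations
#' summarise identically.
#'
#' @param pop A `"physiology_population"`.
#' @param file Path of the CSV file.
#' @param sidecar Write the JSON sidecar? Default `TRUE`.
#' @return `write_population()` returns `file` invisibly;
#'   `read_population()` returns a `"physiology_population"`.
#' @export
write_population <- function(pop, file, sidecar = TRUE) {
  df <- as.data.frame(pop)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   file, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    k <- attr(pop, "key")
    con <- attr(pop, "constraints")
    meta <- list(
      key = if (is.null(k)) NULL else unclass(k),
      constraints = if (is.null(con)) NULL else
        Filter(Negate(is.null), unclass(con)),
      bmi_limits = attr(pop, "bmi_limits"),
      seed = attr(pop, "seed"),
      rejections = attr(pop, "rejections"),
      n = nrow(pop),
      package_version = as.character(utils::packageVersion("physpop")))
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(file)
}

#' @rdname write_population
#' @export
read_population <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  side <- paste0(file, ".json")
  key <- NULL; constr <- NULL; bmi <- NULL; seed <- NULL; rej <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$key))
      key <- structure(as.list(meta$key), class = "physpop_key")
    if (!is.null(meta$constraints))
      constr <- do.call(constraints, lapply(meta$constraints, as.numeric))
    bmi <- meta$bmi_limits
    seed <- meta$seed
    rej <- meta$rejections
  }
  structure(df, key = key, constraints = constr, bmi_limits = bmi,
            seed = seed, rejections = rej,
            class = c("physiology_population", "data.frame"))
}
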