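## Lumping organs into perfusion compartments, blood-mass subtraction, and
## the balance-restoring sink update for single-component MCMC proposals.

#' Define an aggregation scheme
#'
#' An aggregation scheme maps named compartments to disjoint sets of
#' organs.  Organs not assigned to any compartment pass through unchanged.
#'
#' @param compartments Named list, each element a character vector of organ
#'   names (see [organ_names()]).
#' @param sink Name of the organ or compartment used as the balance sink by
#'   [sink_rebalance()]; defaults to `"muscle"`.
#' @return An object of class `"aggregation_scheme"`.
#' @examples
#' default_scheme()
#' @export
aggregation_scheme <- function(compartments = list(), sink = "muscle") {
  stopifnot(is.list(compartments))
  all_members <- unlist(compartments, use.names = FALSE)
  unknown <- setdiff(all_members, .organs)
  if (length(unknown))
    stop("unknown organ(s) in scheme: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(all_members))
    stop("organ assigned to more than one compartment: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  if (length(compartments) &&
      (is.null(names(compartments)) || any(!nzchar(names(compartments)))))
    stop("every compartment must be named")
  if (!sink %in% c(.organs, names(compartments)))
    stop("sink '", sink, "' is neither an organ nor a compartment")
  structure(list(compartments = compartments, sink = sink),
            class = "aggregation_scheme")
}

#' @export
print.aggregation_scheme <- function(x, ...) {
  cat("aggregation scheme:\n")
  for (nm in names(x$compartments))
    cat("  ", nm, ": ", paste(x$compartments[[nm]], collapse = " + "), "\n",
        sep = "")
  cat("  sink:", x$sink, "\n")
  invisible(x)
}

#' Standard aggregation schemes
#'
#' `default_scheme()` is the conventional two-compartment lumping: the
#' rapidly perfused compartment comprises heart, lung, spleen, pancreas and
#' sexual organs; the slowly perfused compartment comprises skin and
#' skeletal muscle.  `sohn_scheme()` is the four-compartment partition used
#' for comparison against direct lognormal prior specifications of
#' trichloroethylene-type PBPK models: fat (adipose), liver, a rapidly
#' perfused compartment holding all remaining viscera, and a slowly
#' perfused compartment of muscle, skin and bone.
#'
#' @return An `"aggregation_scheme"`.
#' @export
default_scheme <- function() {
  aggregation_scheme(
    compartments = list(
      rapidly_perfused = c("heart", "lung", "spleen", "pancreas",
                           "sexual_organs"),
      slowly_perfused = c("skin", "muscle")),
    sink = "slowly_perfused")
}

#' @rdname default_scheme
#' @export
sohn_scheme <- function() {
  aggregation_scheme(
    compartments = list(
      fat = "adipose",
      liver = "liver",
      rapidly_perfused = c("lung", "brain", "heart", "kidneys", "pancreas",
                           "spleen", "stomach", "small_intestine",
                           "large_intestine", "sexual_organs"),
      slowly_perfused = c("muscle", "skin", "bone")),
    sink = "slowly_perfused")
}

#' Aggregate organs into compartments
#'
#' Sums the member organs' masses and flows for every compartment of the
#' scheme; unassigned organs pass through unchanged, so totals are
#' conserved exactly.
#'
#' @param x A `"physiology_population"`.
#' @param scheme An [aggregation_scheme()]; defaults to [default_scheme()].
#' @param ... Unused.
#' @return A data frame with the phase-1 columns of `x` followed by
#'   `mass_*_kg` / `flow_*_l_min` columns for each compartment and each
#'   unassigned organ.
#' @export
aggregate.physiology_population <- function(x, scheme = default_scheme(),
                                            ...) {
  stopifnot(inherits(scheme, "aggregation_scheme"))
  assigned <- unlist(scheme$compartments, use.names = FALSE)
  keep <- setdiff(.organs, assigned)
  head_cols <- intersect(c("id", "age", "height_cm", "body_mass_kg", "bmi",
                           "cardiac_output_l_min"), names(x))
  out <- as.data.frame(x)[, head_cols, drop = FALSE]
  for (nm in names(scheme$compartments)) {
    mem <- scheme$compartments[[nm]]
    out[[paste0("mass_", nm, "_kg")]] <-
      rowSums(as.data.frame(x)[, paste0("mass_", mem, "_kg"), drop = FALSE])
    out[[paste0("flow_", nm, "_l_min")]] <-
      rowSums(as.data.frame(x)[, paste0("flow_", mem, "_l_min"),
                               drop = FALSE])
  }
  for (o in keep) {
    out[[paste0("mass_", o, "_kg")]] <- x[[paste0("mass_", o, "_kg")]]
    out[[paste0("flow_", o, "_l_min")]] <- x[[paste0("flow_", o, "_l_min")]]
  }
  out
}

#' Subtract blood mass from organ masses
#'
#' The simulated organ masses include the blood resident in each organ.
#' For comparison with models that treat blood as a separate compartment
#' the blood can be removed: each organ loses `blood_mass * fraction[organ]`
#' and a `mass_blood_kg` column reports the total subtracted, so overall
#' mass is conserved.  Organ blood fractions are reference values (e.g.
#' ICRP) and must be supplied explicitly; there is no default.
#'
#' @param pop A `"physiology_population"`.
#' @param blood_mass Total blood mass in kg (e.g. 4.1).
#' @param fractions Named numeric vector of organ blood-weight fractions,
#'   names in [organ_names()], summing to at most 1.
#' @return The population with reduced organ masses and a `mass_blood_kg`
#'   column.
#' @export
subtract_blood <- function(pop, blood_mass, fractions) {
  stopifnot(is.numeric(blood_mass), length(blood_mass) == 1L,
            blood_mass >= 0)
  if (is.null(names(fractions)) ||
      length(setdiff(names(fractions), .organs)))
    stop("fractions must be named with organ names; unknown: ",
         paste(setdiff(names(fractions), .organs), collapse = ", "))
  if (any(fractions < 0) || sum(fractions) > 1 + 1e-12)
    stop("fractions must be non-negative and sum to at most 1")
  out <- pop
  for (o in names(fractions)) {
    col <- paste0("mass_", o, "_kg")
    newmass <- out[[col]] - blood_mass * fractions[[o]]
    if (any(newmass <= 0))
      stop("blood subtraction drives ", o, " mass non-positive")
    out[[col]] <- newmass
  }
  out$mass_blood_kg <- rep_len(blood_mass * sum(fractions), nrow(pop))
  out
}

#' Balance-restoring sink update
#'
#' For single-component updates (as in an MCMC sampler around a PBPK
#' model), setting one organ's mass and flow to proposed values breaks the
#' mass and flow balance.  The sink organ — skeletal muscle by default —
#' absorbs the difference: its mass and flow are adjusted by the negative
#' of the change so that totals still equal body mass and cardiac output.
#'
#' @param pop A `"physiology_population"` (vectorised over rows).
#' @param organ The organ being updated (not the sink).
#' @param new_mass,new_flow Proposed values (kg, L/min), recycled over rows.
#' @param sink Sink organ name; default `"muscle"`.
#' @return The updated population.  An error is raised if the sink would be
#'   driven non-positive — the caller should treat that as an invalid
#'   proposal.
#' @export
sink_rebalance <- function(pop, organ, new_mass, new_flow, sink = "muscle") {
  stopifnot(organ %in% .organs, sink %in% .organs)
  if (identical(organ, sink)) stop("sink must differ from the updated organ")
  mc <- paste0("mass_", organ, "_kg"); fc <- paste0("flow_", organ, "_l_min")
  ms <- paste0("mass_", sink, "_kg"); fs <- paste0("flow_", sink, "_l_min")
  d_mass <- new_mass - pop[[mc]]
  d_flow <- new_flow - pop[[fc]]
  sink_mass <- pop[[ms]] - d_mass
  sink_flow <- pop[[fs]] - d_flow
  if (any(sink_mass <= 0) || any(sink_flow <= 0))
    stop("sink '", sink, "' cannot absorb the proposed change ",
         "(mass or flow would become non-positive)")
  out <- pop
  out[[mc]] <- rep_len(new_mass, nrow(pop))
  out[[fc]] <- rep_len(new_flow, nrow(pop))
  out[[ms]] <- sink_mass
  out[[fs]] <- sink_flow
  out
}
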