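#' Full-time-equivalent (FTE) convention
#'
#' Defines what one FTE means in hours. The default working year is 52
#' weeks of 5 days of 8 hours (2080 hours), the convention under which the
#' per-procedure minutes of the default profile reproduce the headline FTE
#' requirements for a 114-patient caseload.
#'
#' @param days_per_week Working days per week (default 5).
#' @param hours_per_day Working hours per day (default 8).
#' @param hours_per_year Working hours per year; defaults to
#'   `52 * days_per_week * hours_per_day`.
#' @return An object of class `fte_convention`.
#' @export
fte_convention <- function(days_per_week = 5, hours_per_day = 8,
                           hours_per_year = 52 * days_per_week * hours_per_day) {
  stopifnot(days_per_week > 0, hours_per_day > 0, hours_per_year > 0)
  structure(list(hours_per_year = hours_per_year,
                 days_per_week = days_per_week,
                 hours_per_day = hours_per_day),
            class = "fte_convention")
}

#' Convert days per week of availability to an FTE fraction
#'
#' Interviewees report availability as clinic days per week (for example a
#' neurologist allocating 1.25 days per week to the HD clinic works at 0.25
#' FTE under a 5-day week).
#'
#' @param days Days per week (non-negative).
#' @param convention An [fte_convention()].
#' @return FTE fraction `days / convention$days_per_week`. Days exceeding
#'   the working week give a warning (over-allocation), not an error.
#' @examples
#' days_per_week_to_fte(1.25) # 0.25
#' @export
days_per_week_to_fte <- function(days, convention = fte_convention()) {
  stopifnot(inherits(convention, "fte_convention"))
  if (any(!is.finite(days)) || any(days < 0)) {
    stop("days must be non-negative", call. = FALSE)
  }
  if (any(days > convention$days_per_week)) {
    warning("days exceed the working week (", convention$days_per_week,
            " days): FTE fraction > 1", call. = FALSE)
  }
  days / convention$days_per_week
}

#' FTEs needed to serve a caseload, per resource class
#'
#' Converts annual person-minutes of procedure demand into FTEs of the
#' given class: `annual_resource_minutes / 60 / hours_per_year`. The raw
#' (unrounded) value is returned; reports round to 2 decimals.
#'
#' @inheritParams annual_resource_minutes
#' @inheritParams days_per_week_to_fte
#' @return Needed FTE (raw).
#' @examples
#' # 114 patients/year needs 0.36 proceduralist FTE and 0.92 nurse FTE
#' round(needed_fte(114, default_generation_hd1_profile(), "proceduralist"), 2)
#' round(needed_fte(114, default_generation_hd1_profile(), "nurse"), 2)
#' @export
needed_fte <- function(patients_per_year, profile, resource,
                       convention = fte_convention()) {
  stopifnot(inherits(convention, "fte_convention"))
  annual_resource_minutes(patients_per_year, profile, resource) / 60 /
    convention$hours_per_year
}

as_centre_row <- function(centre) {
  if (inherits(centre, "survey_collection")) centre <- centre$centres
  centre <- tibble::as_tibble(as.list(centre)[survey_columns()])
  if (nrow(centre) != 1L) stop("expected a single centre record", call. = FALSE)
  centre
}

#' FTE a centre currently makes available for the procedure
#'
#' The interview-reported FTE allocation of the class, optionally discounted
#' by the fraction of that staff class willing to perform/assist the
#' procedure (a multiplicative haircut, applied by default).
#'
#' @param centre A one-row centre record (as in
#'   [survey_collection()]`$centres`) or a single-centre collection.
#' @param resource One of [resource_classes()].
#' @param apply_willingness Discount availability by willingness?
#' @return Available FTE.
#' @export
available_fte <- function(centre, resource, apply_willingness = TRUE) {
  centre <- as_centre_row(centre)
  resource <- match_resource(resource)
  fte <- centre[[paste0(resource, "_fte")]]
  if (apply_willingness) fte <- fte * centre[[paste0(resource, "_willingness")]]
  fte
}

# Vectorised engine behind gap_for_centre()/aggregate_gap(): computes the
# per-centre gap table columnwise over a centres tibble.
compute_gaps <- function(centres, profile, convention, apply_willingness) {
  classes <- resource_classes()
  n <- nrow(centres)
  demand_proc <- annual_procedures(centres$anticipated_patients_per_year,
                                   profile)
  ppm <- vapply(classes, per_procedure_minutes, numeric(1), profile = profile)

  needed <- avail <- thru <- matrix(NA_real_, nrow = n, ncol = length(classes),
                                    dimnames = list(NULL, classes))
  for (r in classes) {
    needed[, r] <- demand_proc * ppm[[r]] / 60 / convention$hours_per_year
    a <- centres[[paste0(r, "_fte")]]
    if (apply_willingness) a <- a * centres[[paste0(r, "_willingness")]]
    avail[, r] <- a
    # per-class procedure throughput; a class the profile never uses is not
    # limiting
    thru[, r] <- if (ppm[[r]] > 0) {
      a * convention$hours_per_year * 60 / ppm[[r]]
    } else {
      rep(Inf, n)
    }
  }
  capacity <- do.call(pmin, as.data.frame(thru))
  bottleneck <- classes[apply(thru, 1L, which.min)] # ties -> first class
  coverage <- ifelse(demand_proc == 0, 1, pmin(1, capacity / demand_proc))
  # full coverage up to floating-point noise from back-solved availabilities
  coverage <- ifelse(coverage >= 1 - 1e-9, 1, coverage)

  has <- sapply(classes, function(r) centres[[paste0("has_", r)]])
  if (n == 1L) has <- matrix(has, nrow = 1L, dimnames = list(NULL, classes))
  component_class <- unname(classify_components(
    has[, "proceduralist"], has[, "nurse"], has[, "facility"]))

  out <- tibble::tibble(centre_id = centres$centre_id)
  for (r in classes) out[[paste0("needed_", r, "_fte")]] <- needed[, r]
  for (r in classes) out[[paste0("available_", r, "_fte")]] <- avail[, r]
  for (r in classes) {
    out[[paste0("gap_", r, "_fte")]] <- pmax(0, needed[, r] - avail[, r])
  }
  out$bottleneck <- bottleneck
  out$capacity_procedures_per_year <- ifelse(is.finite(capacity), capacity,
                                             Inf)
  out$coverage_fraction <- coverage
  out$component_class <- component_class
  out
}

classify_components <- function(has_proceduralist, has_nurse, has_facility) {
  n_absent <- (!has_nurse) + (!has_facility)
  ifelse(has_proceduralist & has_nurse & has_facility, "all_three",
    ifelse(n_absent == 1, "lacks_one_of_nurse_or_facility",
      ifelse(n_absent == 2, "lacks_both", "other")))
}

#' Annual procedure throughput a centre can sustain
#'
#' The minimum over resource classes of the procedures per year each class's
#' available FTE supports: `available_fte * hours_per_year * 60 /
#' per_procedure_minutes`. A centre with zero availability in any class the
#' profile requires has capacity 0.
#'
#' @inheritParams available_fte
#' @inheritParams needed_fte
#' @return Procedures per year.
#' @export
capacity_procedures <- function(centre, profile,
                                convention = fte_convention(),
                                apply_willingness = TRUE) {
  g <- compute_gaps(as_centre_row(centre), profile, convention,
                    apply_willingness)
  g$capacity_procedures_per_year
}

#' Capacity gap analysis for a single centre
#'
#' Combines the needed-FTE calculation (caseload times per-procedure
#' minutes), the available-FTE estimate (allocation times willingness) and
#' their difference into one record: per-class needed/available/gap FTEs
#' (gaps floored at 0 for reporting; the signed value is `needed -
#' available`), the bottleneck class (ties broken in the fixed order
#' proceduralist, nurse, facility), annual procedure capacity, coverage
#' fraction `min(1, capacity / demand)` (1 when demand is 0), and the
#' interview-reported component classification.
#'
#' @inheritParams capacity_procedures
#' @return A one-row tibble (see [aggregate_gap()] for the multi-centre
#'   version).
#' @export
gap_for_centre <- function(centre, profile, convention = fte_convention(),
                           apply_willingness = TRUE) {
  compute_gaps(as_centre_row(centre), profile, convention, apply_willingness)
}

#' Capacity gap analysis across a survey collection
#'
#' Runs [gap_for_centre()] for every centre and aggregates: the share of
#' centres per component class, the count at full coverage, cumulative
#' counts below 50% and 30% coverage, and mean needed/available/gap FTEs per
#' resource class. The per-centre table is sorted by coverage, descending.
#'
#' @inheritParams capacity_procedures
#' @param collection A non-empty [survey_collection()].
#' @return An object of class `gap_report`: a list with `per_centre`
#'   (tibble), `n_centres`, `component_split` (named fractions),
#'   `component_pct` (named, rounded to whole percent), `n_full_coverage`,
#'   `pct_full_coverage`, `n_below_half`, `n_below_third`, and `mean_fte`
#'   (tibble with needed/available/gap means per class).
#' @export
aggregate_gap <- function(collection, profile, convention = fte_convention(),
                          apply_willingness = TRUE) {
  validate_survey(collection)
  centres <- collection$centres
  if (nrow(centres) == 0L) {
    stop("cannot aggregate an empty survey collection", call. = FALSE)
  }
  per_centre <- compute_gaps(centres, profile, convention, apply_willingness)
  per_centre <- per_centre[order(-per_centre$coverage_fraction,
                                 per_centre$centre_id), ]
  n <- nrow(per_centre)
  levels <- c("all_three", "lacks_one_of_nurse_or_facility", "lacks_both",
              "other")
  split <- vapply(levels, function(l) mean(per_centre$component_class == l),
                  numeric(1))
  classes <- resource_classes()
  mean_fte <- tibble::tibble(
    resource = classes,
    needed_fte = vapply(classes, function(r)
      mean(per_centre[[paste0("needed_", r, "_fte")]]), numeric(1)),
    available_fte = vapply(classes, function(r)
      mean(per_centre[[paste0("available_", r, "_fte")]]), numeric(1)),
    gap_fte = vapply(classes, function(r)
      mean(per_centre[[paste0("gap_", r, "_fte")]]), numeric(1))
  )
  structure(list(
    per_centre = per_centre,
    n_centres = n,
    component_split = split,
    component_pct = round(100 * split),
    n_full_coverage = sum(per_centre$coverage_fraction == 1),
    pct_full_coverage = round(100 * mean(per_centre$coverage_fraction == 1)),
    n_below_half = sum(per_centre$coverage_fraction < 0.5),
    n_below_third = sum(per_centre$coverage_fraction < 0.3),
    mean_fte = mean_fte
  ), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report> ", x$n_centres, " centres\n", sep = "")
  cat("  full coverage: ", x$n_full_coverage, " (", x$pct_full_coverage,
      "%)\n", sep = "")
  cat("  coverage < 50%: ", x$n_below_half, "; coverage < 30%: ",
      x$n_below_third, "\n", sep = "")
  cat("  component split (%): ",
      paste(sprintf("%s=%d", names(x$component_pct), x$component_pct),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
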