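#' Construct a procedure profile
#'
#' A procedure profile describes one intrathecal administration in terms of
#' its steps: how many minutes each resource class is occupied, and by how
#' many persons simultaneously. Together with the dosing cadence
#' (`admins_per_patient_per_year`) it converts an annual patient caseload
#' into annual person-minutes of demand per resource class.
#'
#' @param steps A data frame with columns `name` (character),
#'   `resource` (one of [resource_classes()]), `minutes` (positive, per
#'   person) and `persons` (positive integer).
#' @param admins_per_patient_per_year Procedures each treated patient
#'   receives per year. The default dosing cadence of one administration
#'   every 8 weeks gives 52/8 = 6.5.
#' @param name Free-text label for the profile.
#' @return An object of class `procedure_profile`.
#' @seealso [default_generation_hd1_profile()] for the packaged default.
#' @export
procedure_profile <- function(steps, admins_per_patient_per_year = 6.5,
                              name = "custom") {
  steps <- tibble::as_tibble(steps)
  required <- c("name", "resource", "minutes", "persons")
  missing_cols <- setdiff(required, names(steps))
  if (length(missing_cols) > 0L) {
    stop("profile steps lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- !steps$resource %in% resource_classes()
  if (any(bad)) {
    stop("unknown resource class in steps: ",
         paste(unique(steps$resource[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(steps$minutes <= 0)) stop("step minutes must be > 0", call. = FALSE)
  if (any(steps$persons < 1)) stop("step persons must be >= 1", call. = FALSE)
  if (!is.numeric(admins_per_patient_per_year) ||
      length(admins_per_patient_per_year) != 1L ||
      admins_per_patient_per_year <= 0) {
    stop("admins_per_patient_per_year must be a positive number", call. = FALSE)
  }
  structure(
    list(name = name, steps = steps,
         admins_per_patient_per_year = admins_per_patient_per_year),
    class = "procedure_profile"
  )
}

#' @export
print.procedure_profile <- function(x, ...) {
  cat("<procedure_profile> ", x$name, "\n", sep = "")
  cat("  admins/patient/year: ", x$admins_per_patient_per_year, "\n", sep = "")
  totals <- vapply(resource_classes(), per_procedure_minutes, numeric(1),
                   profile = x)
  cat("  person-minutes/procedure: ",
      paste(sprintf("%s=%g", names(totals), totals), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Load a procedure profile from a YAML file
#'
#' The file carries a `steps` list (each with `name`, `resource`, `minutes`,
#' `persons`), an `admins_per_patient_per_year` dosing frequency, and an
#' optional `name`, so alternative protocols (for example ultrasound-guided
#' variants) can be modelled without code changes.
#'
#' @param path Path to a YAML profile file.
#' @return A [procedure_profile()].
#' @export
load_procedure_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  steps <- tibble::tibble(
    name = vapply(raw$steps, function(s) as.character(s$name), character(1)),
    resource = vapply(raw$steps, function(s) as.character(s$resource), character(1)),
    minutes = vapply(raw$steps, function(s) as.numeric(s$minutes), numeric(1)),
    persons = vapply(raw$steps, function(s) as.integer(s$persons), integer(1))
  )
  procedure_profile(steps, as.numeric(raw$admins_per_patient_per_year),
                    name = raw$name %||% basename(path))
}

#' Default intrathecal administration profile (GENERATION HD1 protocol)
#'
#' The packaged default profile: 60 person-minutes of proceduralist time,
#' 155 person-minutes of nurse time (two nurses during CSF collection and
#' bolus injection) and 70 minutes of chair/bed occupancy per procedure,
#' with 6.5 administrations per patient per year (every-8-week dosing).
#'
#' @return A [procedure_profile()].
#' @examples
#' prof <- default_generation_hd1_profile()
#' per_procedure_minutes(prof, "nurse")
#' @export
default_generation_hd1_profile <- function() {
  path <- system.file("extdata", "generation_hd1_profile.yaml",
                      package = "hdcapacity", mustWork = TRUE)
  load_procedure_profile(path)
}

#' Person-minutes one procedure demands from a resource class
#'
#' Sums `minutes * persons` over the profile steps of the given class, so
#' overlapping staff time is counted as person-minutes (two nurses for 40
#' minutes contribute 80).
#'
#' @param profile A [procedure_profile()].
#' @param resource One of [resource_classes()].
#' @return Person-minutes per procedure (0 if the profile has no steps for
#'   the class).
#' @export
per_procedure_minutes <- function(profile, resource) {
  stopifnot(inherits(profile, "procedure_profile"))
  resource <- match_resource(resource)
  sel <- profile$steps$resource == resource
  sum(profile$steps$minutes[sel] * profile$steps$persons[sel])
}

#' Annual procedures implied by a patient caseload
#'
#' @param patients_per_year Patients treated per year (non-negative; not
#'   rounded).
#' @param profile A [procedure_profile()] supplying the dosing cadence.
#' @return Procedures per year: `patients_per_year *
#'   admins_per_patient_per_year`.
#' @examples
#' annual_procedures(114, default_generation_hd1_profile()) # 741
#' @export
annual_procedures <- function(patients_per_year, profile) {
  stopifnot(inherits(profile, "procedure_profile"))
  if (any(!is.finite(patients_per_year)) || any(patients_per_year < 0)) {
    stop("patients_per_year must be non-negative", call. = FALSE)
  }
  patients_per_year * profile$admins_per_patient_per_year
}

#' Annual person-minutes a caseload demands from a resource class
#'
#' @inheritParams annual_procedures
#' @inheritParams per_procedure_minutes
#' @return Person-minutes per year:
#'   `annual_procedures(...) * per_procedure_minutes(...)`.
#' @examples
#' annual_resource_minutes(114, default_generation_hd1_profile(), "nurse")
#' @export
annual_resource_minutes <- function(patients_per_year, profile, resource) {
  annual_procedures(patients_per_year, profile) *
    per_procedure_minutes(profile, resource)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
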