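#' Construct a centre survey collection
#'
#' A survey collection holds one record per HD centre, as elicited in
#' structured interviews: the anticipated annual caseload for an
#' intrathecally administered therapy, the full-time-equivalent (FTE) time
#' each resource class currently makes available, the fraction of each staff
#' class willing to take part in the procedure, and interview-reported flags
#' for whether the centre has each component (proceduralist, nurses,
#' facility) in place for the procedure.
#'
#' The component flags are a survey item in their own right, distinct from
#' the FTE figures: a centre may report that it lacks a dedicated nursing
#' component while still naming nursing time it could draw on, and vice
#' versa. When flags are absent from an input file they default to
#' `availability > 0`.
#'
#' @param centres A data frame with columns `centre_id`, `country`,
#'   `anticipated_patients_per_year`, `<class>_fte`, `<class>_willingness`
#'   and `has_<class>` for each of [resource_classes()].
#' @param metadata Named list of free-text provenance fields (source, seed,
#'   generator parameters).
#' @return An object of class `survey_collection` with elements `centres`
#'   (tibble, file/order preserved) and `metadata` (list).
#' @export
survey_collection <- function(centres, metadata = list()) {
  centres <- tibble::as_tibble(centres)
  out <- structure(list(centres = centres, metadata = metadata),
                   class = "survey_collection")
  validate_survey(out)
  out
}

#' @rdname survey_collection
#' @param centre_id,country Identifier and country label for one centre.
#' @param anticipated_patients_per_year Patients per year anticipated to
#'   receive the therapy at this centre.
#' @param resource_availability Named numeric: available FTE fraction per
#'   resource class.
#' @param willingness Named numeric in `[0, 1]`: fraction of each class
#'   willing to perform/assist; classes not measured default to 1.
#' @param has_component Named logical per class; defaults to
#'   `resource_availability > 0`.
#' @return `centre_survey()`: a one-row centres tibble suitable for
#'   [survey_collection()].
#' @export
centre_survey <- function(centre_id, country = "unknown",
                          anticipated_patients_per_year = 0,
                          resource_availability = c(proceduralist = 0,
                                                    nurse = 0, facility = 0),
                          willingness = c(proceduralist = 1, nurse = 1,
                                          facility = 1),
                          has_component = NULL) {
  classes <- resource_classes()
  avail <- vapply(classes, function(r) {
    if (!r %in% names(resource_availability)) return(0)
    as.numeric(resource_availability[[r]])
  }, numeric(1))
  will <- vapply(classes, function(r) {
    v <- if (r %in% names(willingness)) willingness[[r]] else NULL
    if (is.null(v)) 1 else as.numeric(v)
  }, numeric(1))
  if (is.null(has_component)) has_component <- avail > 0
  has <- vapply(classes, function(r) {
    v <- if (r %in% names(has_component)) has_component[[r]] else NULL
    if (is.null(v)) avail[[r]] > 0 else as.logical(v)
  }, logical(1))
  row <- tibble::tibble(
    centre_id = as.character(centre_id),
    country = as.character(country),
    anticipated_patients_per_year = as.numeric(anticipated_patients_per_year)
  )
  for (r in classes) row[[paste0(r, "_fte")]] <- avail[[r]]
  for (r in classes) row[[paste0(r, "_willingness")]] <- will[[r]]
  for (r in classes) row[[paste0("has_", r)]] <- has[[r]]
  row
}

survey_columns <- function() {
  classes <- resource_classes()
  c("centre_id", "country", "anticipated_patients_per_year",
    paste0(classes, "_fte"), paste0(classes, "_willingness"),
    paste0("has_", classes))
}

empty_centres <- function() {
  cols <- survey_columns()
  out <- tibble::as_tibble(setNames(
    lapply(cols, function(nm) {
      if (nm %in% c("centre_id", "country")) character(0)
      else if (startsWith(nm, "has_")) logical(0)
      else numeric(0)
    }), cols))
  out
}

#' Validate a survey collection
#'
#' Checks the structural invariants of the survey record format: required
#' columns present, `centre_id` unique, caseloads and FTE availabilities
#' non-negative and finite, willingness fractions in `[0, 1]`. Errors name
#' the offending centre and field.
#'
#' @param collection A [survey_collection()].
#' @return The collection, invisibly, if valid; otherwise an error.
#' @export
validate_survey <- function(collection) {
  if (!inherits(collection, "survey_collection")) {
    stop("not a survey_collection", call. = FALSE)
  }
  centres <- collection$centres
  missing_cols <- setdiff(survey_columns(), names(centres))
  if (length(missing_cols) > 0L) {
    stop("survey lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(centres$centre_id)) {
    dup <- unique(centres$centre_id[duplicated(centres$centre_id)])
    stop("duplicate centre_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  fail <- function(bad, field, why) {
    if (any(bad)) {
      stop("centre '", centres$centre_id[which(bad)[1]], "': field '", field,
           "' ", why, call. = FALSE)
    }
  }
  d <- centres$anticipated_patients_per_year
  fail(!is.finite(d) | d < 0, "anticipated_patients_per_year",
       "must be a non-negative number")
  for (r in resource_classes()) {
    a <- centres[[paste0(r, "_fte")]]
    fail(!is.finite(a) | a < 0, paste0(r, "_fte"),
         "must be a non-negative FTE fraction")
    w <- centres[[paste0(r, "_willingness")]]
    fail(!is.finite(w) | w < 0 | w > 1, paste0(r, "_willingness"),
         "must be a willingness in [0, 1]")
    fail(is.na(centres[[paste0("has_", r)]]), paste0("has_", r),
         "must be TRUE or FALSE")
  }
  invisible(collection)
}

#' @export
print.survey_collection <- function(x, ...) {
  cat("<survey_collection> ", nrow(x$centres), " centres\n", sep = "")
  if (length(x$metadata) > 0L) {
    cat("  metadata: ", paste(names(x$metadata), collapse = ", "), "\n",
        sep = "")
  }
  print(x$centres, ...)
  invisible(x)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "csv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) return(ext)
  stop("cannot infer survey format from extension '", ext,
       "'; pass format = \"json\" or \"csv\"", call. = FALSE)
}

#' Read a centre survey file
#'
#' JSON is the canonical format (nested per-class maps plus a metadata
#' block); CSV is a flat convenience view with one row per centre and
#' columns `<class>_fte`, `<class>_willingness`, `has_<class>` (metadata is
#' not carried in CSV). Records with missing willingness values are
#' defaulted to 1 with a warning, because interviews measured willingness
#' only for some staff classes.
#'
#' @param path Path to a survey file.
#' @param format `"json"` or `"csv"`; inferred from the file extension when
#'   omitted.
#' @return A validated [survey_collection()]; centre order is preserved from
#'   the file.
#' @export
load_survey <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  collection <- switch(format,
    json = load_survey_json(path),
    csv = load_survey_csv(path)
  )
  validate_survey(collection)
  message("Read ", nrow(collection$centres), " centre record(s) from ", path)
  collection
}

load_survey_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  centres <- raw$centres %||% list()
  if (length(centres) == 0L) {
    return(structure(list(centres = empty_centres(),
                          metadata = raw$metadata %||% list()),
                     class = "survey_collection"))
  }
  rows <- lapply(centres, function(ct) {
    will <- ct$willingness %||% list()
    miss <- setdiff(resource_classes(), names(will))
    if (length(miss) > 0L) {
      warning("centre '", ct$centre_id, "': willingness missing for ",
              paste(miss, collapse = ", "), "; defaulting to 1",
              call. = FALSE)
    }
    centre_survey(
      centre_id = ct$centre_id %||% stop("centre without centre_id",
                                         call. = FALSE),
      country = ct$country %||% "unknown",
      anticipated_patients_per_year =
        as.numeric(ct$anticipated_patients_per_year %||% NA_real_),
      resource_availability = unlist(ct$resource_availability %||% list()),
      willingness = unlist(will),
      has_component = if (is.null(ct$has_component)) NULL
                      else unlist(ct$has_component)
    )
  })
  structure(list(centres = do.call(rbind, rows),
                 metadata = raw$metadata %||% list()),
            class = "survey_collection")
}

load_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(centre_id = "character"))
  if (nrow(df) == 0L) {
    return(structure(list(centres = empty_centres(), metadata = list()),
                     class = "survey_collection"))
  }
  for (r in resource_classes()) {
    wcol <- paste0(r, "_willingness")
    if (!wcol %in% names(df) || anyNA(df[[wcol]])) {
      warning("column '", wcol, "' missing or incomplete; defaulting to 1",
              call. = FALSE)
      if (!wcol %in% names(df)) df[[wcol]] <- 1
      df[[wcol]][is.na(df[[wcol]])] <- 1
    }
    hcol <- paste0("has_", r)
    if (!hcol %in% names(df)) df[[hcol]] <- df[[paste0(r, "_fte")]] > 0
    df[[hcol]] <- as.logical(df[[hcol]])
  }
  if (!"country" %in% names(df)) df$country <- "unknown"
  numeric_cols <- grep("_fte$|_willingness$|anticipated", names(df),
                       value = TRUE)
  for (col in numeric_cols) df[[col]] <- as.numeric(df[[col]])
  structure(list(centres = tibble::as_tibble(df[, survey_columns()]),
                 metadata = list()),
            class = "survey_collection")
}

#' Write a centre survey file
#'
#' Writes a [survey_collection()] so that [load_survey()] recovers an equal
#' collection (JSON round-trips metadata too; CSV drops it). Numeric fields
#' are serialized at full precision.
#'
#' @inheritParams load_survey
#' @param collection A valid [survey_collection()].
#' @return The path, invisibly.
#' @export
write_survey <- function(collection, path, format = NULL) {
  validate_survey(collection)
  format <- infer_format(path, format)
  if (format == "json") {
    centres <- collection$centres
    recs <- lapply(seq_len(nrow(centres)), function(i) {
      list(
        centre_id = centres$centre_id[[i]],
        country = centres$country[[i]],
        anticipated_patients_per_year =
          centres$anticipated_patients_per_year[[i]],
        resource_availability = as.list(setNames(
          lapply(resource_classes(),
                 function(r) centres[[paste0(r, "_fte")]][[i]]),
          resource_classes())),
        willingness = as.list(setNames(
          lapply(resource_classes(),
                 function(r) centres[[paste0(r, "_willingness")]][[i]]),
          resource_classes())),
        has_component = as.list(setNames(
          lapply(resource_classes(),
                 function(r) centres[[paste0("has_", r)]][[i]]),
          resource_classes()))
      )
    })
    jsonlite::write_json(list(metadata = collection$metadata, centres = recs),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    utils::write.csv(as.data.frame(collection$centres), path,
                     row.names = FALSE)
  }
  message("Wrote ", nrow(collection$centres), " centre record(s) to ", path)
  invisible(path)
}
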