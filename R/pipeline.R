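#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `survey_path` (load an existing survey file) or
#' `generator` (a [generator_params()] to synthesise one) must be supplied.
#'
#' @param survey_path Path to a survey JSON/CSV file, or `NULL`.
#' @param generator A [generator_params()] object, or `NULL`.
#' @param profile_path Path to a YAML procedure profile; `NULL` uses the
#'   packaged default protocol.
#' @param hours_per_year,days_per_week,hours_per_day FTE convention
#'   overrides (see [fte_convention()]).
#' @param apply_willingness Discount available FTEs by willingness?
#' @param horizon_months Waiting-list projection horizon.
#' @param waitlist_mode `"fluid"` or `"des"`.
#' @param replicates Replicates per centre in `"des"` mode.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the DES (generator seeds live in `generator`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(survey_path = NULL, generator = NULL,
                       profile_path = NULL,
                       days_per_week = 5, hours_per_day = 8,
                       hours_per_year = 52 * days_per_week * hours_per_day,
                       apply_willingness = TRUE,
                       horizon_months = 24, waitlist_mode = c("fluid", "des"),
                       replicates = 1, out_dir = tempfile("hdcapacity-run-"),
                       seed = 1) {
  if (is.null(survey_path) == is.null(generator)) {
    stop("supply exactly one of survey_path or generator", call. = FALSE)
  }
  if (!is.null(generator)) stopifnot(inherits(generator, "generator_params"))
  structure(list(
    survey_path = survey_path, generator = generator,
    profile_path = profile_path,
    convention = fte_convention(days_per_week, hours_per_day, hours_per_year),
    apply_willingness = apply_willingness,
    horizon_months = horizon_months,
    waitlist_mode = match.arg(waitlist_mode),
    replicates = replicates, out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full capacity pipeline
#'
#' Survey in (loaded or generated), then the three modelling steps: needed
#' resources per centre, available resources per centre, and the capacity
#' gap with coverage classification; finally a waiting-list projection.
#' Writes, under `config$out_dir`:
#' \describe{
#'   \item{`gap_per_centre.csv`}{per-centre needed/available/gap FTEs,
#'     bottleneck, capacity, coverage, component class (sorted by coverage
#'     descending).}
#'   \item{`summary.json`}{aggregate report: component-class percentages,
#'     full-coverage count, coverage-band counts, mean FTEs per class,
#'     average waiting time at the horizon.}
#'   \item{`waitlist.csv`}{tidy trajectory (centre_id, month, backlog,
#'     wait months).}
#'   \item{`manifest.json`}{all parameters, seed, package version.}
#' }
#' Identical config and seed give byte-identical machine-readable outputs.
#' The input survey file is never modified.
#'
#' @param config A [run_config()].
#' @return The aggregate `gap_report`, invisibly, with attribute `files`
#'   naming the written outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  survey <- if (!is.null(config$survey_path)) {
    load_survey(config$survey_path)
  } else {
    generate_reference_survey(config$generator)
  }
  if (nrow(survey$centres) == 0L) {
    stop("pipeline stage 'survey': survey contains no centres", call. = FALSE)
  }
  profile <- if (is.null(config$profile_path)) {
    default_generation_hd1_profile()
  } else {
    load_procedure_profile(config$profile_path)
  }

  report <- aggregate_gap(survey, profile, config$convention,
                          config$apply_willingness)

  trajectories <- lapply(seq_len(nrow(survey$centres)), function(i) {
    centre <- survey$centres[i, ]
    if (config$waitlist_mode == "fluid") {
      fluid_trajectory(
        annual_procedures(centre$anticipated_patients_per_year, profile),
        capacity_procedures(centre, profile, config$convention,
                            config$apply_willingness),
        config$horizon_months, centre_id = centre$centre_id)
    } else {
      simulate_des(centre, profile, config$convention,
                   config$horizon_months, seed = config$seed + i,
                   apply_willingness = config$apply_willingness)
    }
  })
  waitlist <- do.call(rbind, trajectories)

  avg_wait <- tryCatch(
    average_waiting_time(survey, profile, config$convention,
                         month = config$horizon_months,
                         apply_willingness = config$apply_willingness),
    error = function(e) NA_real_)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    gap = file.path(config$out_dir, "gap_per_centre.csv"),
    summary = file.path(config$out_dir, "summary.json"),
    waitlist = file.path(config$out_dir, "waitlist.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  utils::write.csv(as.data.frame(report$per_centre), files[["gap"]],
                   row.names = FALSE)
  summary <- list(
    n_centres = report$n_centres,
    component_split_pct = as.list(report$component_pct),
    n_full_coverage = report$n_full_coverage,
    pct_full_coverage = report$pct_full_coverage,
    n_below_half_coverage = report$n_below_half,
    n_below_third_coverage = report$n_below_third,
    mean_fte = lapply(seq_len(nrow(report$mean_fte)), function(i)
      as.list(report$mean_fte[i, ])),
    average_waiting_time_months = if (is.na(avg_wait)) NULL
                                  else as.numeric(avg_wait),
    waiting_time_month = config$horizon_months,
    n_zero_capacity_excluded = if (is.na(avg_wait)) NULL
                               else attr(avg_wait, "n_excluded")
  )
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  utils::write.csv(as.data.frame(waitlist), files[["waitlist"]],
                   row.names = FALSE)
  manifest <- list(
    package = "hdcapacity",
    version = as.character(utils::packageVersion("hdcapacity")),
    survey_path = config$survey_path,
    survey_metadata = survey$metadata,
    profile = profile$name,
    convention = unclass(config$convention),
    apply_willingness = config$apply_willingness,
    horizon_months = config$horizon_months,
    waitlist_mode = config$waitlist_mode,
    seed = config$seed
  )
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  message("Pipeline wrote ", length(files), " file(s) to ", config$out_dir)
  attr(report, "files") <- files
  invisible(report)
}

#' Render an aggregate gap report as a fixed-width text table
#'
#' Two blocks: per resource class, the mean needed vs. available vs.
#' additional (gap) FTEs; then one row per centre with its coverage
#' percentage, sorted descending. Percentages are whole numbers and FTEs are
#' rounded to 2 decimals, matching the reporting precision used throughout.
#'
#' @param report A `gap_report` from [aggregate_gap()].
#' @return Character vector of table lines (one element per line).
#' @export
render_summary_table <- function(report) {
  stopifnot(inherits(report, "gap_report"))
  lines <- c(
    sprintf("%-14s %10s %12s %12s", "resource", "needed_fte", "available_fte",
            "additional_fte"),
    sprintf("%-14s %10.2f %12.2f %12.2f", report$mean_fte$resource,
            report$mean_fte$needed_fte, report$mean_fte$available_fte,
            report$mean_fte$gap_fte),
    "",
    sprintf("%-10s %10s %-30s", "centre_id", "coverage", "component_class"),
    sprintf("%-10s %9.0f%% %-30s", report$per_centre$centre_id,
            100 * report$per_centre$coverage_fraction,
            report$per_centre$component_class)
  )
  lines
}
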