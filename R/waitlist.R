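#' Fluid-approximation waiting-list trajectory
#'
#' Deterministic backlog projection for a centre after therapy launch, under
#' constant demand and capacity rates and zero initial backlog. Procedures
#' accumulate at the demand rate and are worked off at the capacity rate, so
#' the backlog after `t` months is `max(0, demand - capacity) * t / 12` and
#' the waiting time — the backlog divided by monthly throughput, in the
#' spirit of Little's law — has the closed form
#' `max(0, demand / capacity - 1) * t` months.
#'
#' @param demand_rate Procedures demanded per year (non-negative).
#' @param capacity_rate Procedures deliverable per year (non-negative). A
#'   centre with zero capacity and positive demand gets an infinite waiting
#'   time (`Inf` sentinel), not an error.
#' @param horizon_months Number of months to project (>= 1).
#' @param centre_id Label carried into the output.
#' @return A `waitlist_trajectory` tibble with columns `centre_id`, `month`
#'   (0..horizon), `backlog` (procedures) and `waiting_time_months`.
#' @examples
#' # a centre able to deliver 2/7 of its demand waits 60 months by month 24
#' tr <- fluid_trajectory(7, 2, 24)
#' tr$waiting_time_months[tr$month == 24]
#' @export
fluid_trajectory <- function(demand_rate, capacity_rate, horizon_months,
                             centre_id = "centre") {
  stopifnot(is.finite(demand_rate), demand_rate >= 0,
            is.finite(capacity_rate), capacity_rate >= 0,
            horizon_months >= 1)
  months <- 0:as.integer(horizon_months)
  backlog <- max(0, demand_rate - capacity_rate) * months / 12
  waiting <- if (capacity_rate > 0) {
    backlog / (capacity_rate / 12)
  } else {
    ifelse(backlog > 0, Inf, 0)
  }
  out <- tibble::tibble(centre_id = centre_id, month = months,
                        backlog = backlog, waiting_time_months = waiting)
  class(out) <- c("waitlist_trajectory", class(out))
  out
}

#' Discrete-event simulation of a centre's waiting list
#'
#' Stochastic cross-check of [fluid_trajectory()]. Patient procedures arrive
#' as a Poisson process at the centre's annual procedure demand rate.
#' Service-start tokens are released at the centre's capacity rate (derived
#' from its available FTEs and the profile's per-procedure step minutes via
#' [capacity_procedures()]); patients start in FIFO order at the later of
#' their arrival and their token time, and then occupy the chair/bed for the
#' profile's facility minutes. The backlog sampled at each month is the
#' number of arrivals not yet started, and the reported waiting time is
#' backlog over monthly capacity, mirroring the fluid definition.
#'
#' @inheritParams capacity_procedures
#' @param horizon_months Months to simulate.
#' @param seed Integer seed; the same seed reproduces the trajectory
#'   exactly.
#' @return A `waitlist_trajectory` tibble (as [fluid_trajectory()]) with
#'   attributes `arrivals`, `completed`, `in_service`, `queued` (counts at
#'   the horizon) and `mean_sojourn_months` (mean arrival-to-completion time
#'   of patients completed within the horizon, `NA` if none).
#' @export
simulate_des <- function(centre, profile, convention = fte_convention(),
                         horizon_months = 24, seed = 1,
                         apply_willingness = TRUE) {
  centre <- as_centre_row(centre)
  demand_rate <- annual_procedures(centre$anticipated_patients_per_year,
                                   profile)
  capacity_rate <- capacity_procedures(centre, profile, convention,
                                       apply_willingness)
  # chair/bed wall-clock occupancy, in months of working time
  dur_months <- per_procedure_minutes(profile, "facility") / 60 /
    (convention$hours_per_year / 12)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  monthly_demand <- demand_rate / 12
  arrivals <- numeric(0)
  if (monthly_demand > 0) {
    # oversample exponential gaps, then truncate at the horizon
    n_guess <- max(10, ceiling(monthly_demand * horizon_months +
                                 6 * sqrt(monthly_demand * horizon_months)))
    gaps <- stats::rexp(n_guess, rate = monthly_demand)
    while (sum(gaps) < horizon_months) {
      gaps <- c(gaps, stats::rexp(n_guess, rate = monthly_demand))
    }
    arrivals <- cumsum(gaps)
    arrivals <- arrivals[arrivals <= horizon_months]
  }
  n_arr <- length(arrivals)
  if (capacity_rate > 0 && n_arr > 0) {
    token_gap <- 12 / capacity_rate
    tokens <- seq_len(n_arr) * token_gap
    starts <- pmax(arrivals, tokens)
    completions <- starts + dur_months
  } else {
    starts <- rep(Inf, n_arr)
    completions <- rep(Inf, n_arr)
  }

  months <- 0:as.integer(horizon_months)
  n_arrived <- vapply(months, function(m) sum(arrivals <= m), numeric(1))
  n_started <- vapply(months, function(m) sum(starts <= m), numeric(1))
  n_done <- vapply(months, function(m) sum(completions <= m), numeric(1))
  backlog <- n_arrived - n_started
  waiting <- if (capacity_rate > 0) {
    backlog / (capacity_rate / 12)
  } else {
    ifelse(backlog > 0, Inf, 0)
  }
  out <- tibble::tibble(centre_id = centre$centre_id, month = months,
                        backlog = backlog, waiting_time_months = waiting)
  class(out) <- c("waitlist_trajectory", class(out))
  done <- completions <= horizon_months
  attr(out, "arrivals") <- n_arr
  attr(out, "completed") <- sum(done)
  attr(out, "in_service") <- sum(starts <= horizon_months & !done)
  attr(out, "queued") <- sum(starts > horizon_months)
  attr(out, "mean_sojourn_months") <-
    if (any(done)) mean(completions[done] - arrivals[done]) else NA_real_
  out
}

#' Average fluid waiting time across a survey collection
#'
#' The arithmetic mean of per-centre fluid waiting times at a given month.
#' By default, centres with zero procedure capacity (and positive demand)
#' are excluded — their waiting time is unbounded — and their count is
#' reported in the `n_excluded` attribute.
#'
#' @inheritParams aggregate_gap
#' @param month Month after launch at which to evaluate waiting times.
#' @param exclusion_rule `"exclude_zero_capacity"` (default) or `"none"`
#'   (zero-capacity centres enter the mean as `Inf`).
#' @return Mean waiting time in months, with attributes `n_included` and
#'   `n_excluded`.
#' @export
average_waiting_time <- function(collection, profile,
                                 convention = fte_convention(),
                                 month = 24,
                                 exclusion_rule = c("exclude_zero_capacity",
                                                    "none"),
                                 apply_willingness = TRUE) {
  validate_survey(collection)
  exclusion_rule <- match.arg(exclusion_rule)
  centres <- collection$centres
  if (nrow(centres) == 0L) stop("empty survey collection", call. = FALSE)
  gaps <- compute_gaps(centres, profile, convention, apply_willingness)
  demand <- annual_procedures(centres$anticipated_patients_per_year, profile)
  capacity <- gaps$capacity_procedures_per_year
  waits <- ifelse(capacity > 0, pmax(0, demand / capacity - 1) * month,
                  ifelse(demand > 0, Inf, 0))
  excluded <- capacity <= 0 & demand > 0
  if (exclusion_rule == "exclude_zero_capacity") {
    waits <- waits[!excluded]
    if (length(waits) == 0L) {
      stop("all centres excluded (zero capacity with positive demand)",
           call. = FALSE)
    }
  }
  out <- mean(waits)
  attr(out, "n_included") <- length(waits)
  attr(out, "n_excluded") <- if (exclusion_rule == "exclude_zero_capacity") {
    sum(excluded)
  } else {
    0L
  }
  out
}
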