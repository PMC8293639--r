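# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Integer apportionment of n among fractions (largest remainder), so strata
# counts are exact and reproducible across platforms.
apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Parameters for the synthetic survey generators
#'
#' Defaults encode the aggregate structure of the 40-centre interview
#' sample the capacity model was built on: a mean anticipated caseload of
#' 114 patients/centre/year; mean current allocations of 0.25 FTE
#' (neurologist/proceduralist), 0.15 FTE (nurse) and 0.20 FTE (facility, one
#' day per week); willingness of 0.65 for proceduralists (the midpoint of
#' the reported 60--70% range) and 0.80 for nurses; a component split of 25%
#' of centres with all three components, 50% lacking one of nurses or
#' facilities and 25% lacking both; and cumulative coverage strata of 6
#' centres at full coverage, 25 below 50% and 18 below 30% (the <30% band is
#' a subset of the <50% band).
#'
#' @param n_centres Number of centres (default 40).
#' @param mean_demand Mean anticipated patients/centre/year (default 114).
#' @param demand_dispersion Coefficient of variation of the demand
#'   distribution; 0 makes every centre's demand equal to the mean.
#' @param mean_neurologist_fte,mean_nurse_fte,mean_facility_fte Mean current
#'   FTE allocation per class, among centres with the component.
#' @param willingness_proceduralist,willingness_nurse Willingness fractions
#'   applied to those classes (facility willingness is 1).
#' @param component_split Fractions (summing to 1) of centres with all three
#'   components / lacking one of nurse-or-facility / lacking both.
#' @param coverage_strata Named counts `full_coverage`, `below_half`,
#'   `below_third`; cumulative bands, so `below_third <= below_half`. The
#'   default is the sample pattern (6, 25, 18 out of 40) scaled to
#'   `n_centres`.
#' @param seed Integer seed for all draws.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_centres = 40,
                             mean_demand = 114,
                             demand_dispersion = 0.5,
                             mean_neurologist_fte = 0.25,
                             mean_nurse_fte = 0.15,
                             mean_facility_fte = 0.20,
                             willingness_proceduralist = 0.65,
                             willingness_nurse = 0.80,
                             component_split = c(
                               all_three = 0.25,
                               lacks_one_of_nurse_or_facility = 0.50,
                               lacks_both = 0.25),
                             coverage_strata = NULL,
                             seed = 0) {
  stopifnot(n_centres >= 1, mean_demand >= 0, demand_dispersion >= 0,
            mean_neurologist_fte >= 0, mean_nurse_fte >= 0,
            mean_facility_fte >= 0,
            willingness_proceduralist >= 0, willingness_proceduralist <= 1,
            willingness_nurse >= 0, willingness_nurse <= 1,
            length(component_split) == 3)
  if (abs(sum(component_split) - 1) > 1e-9) {
    stop("component_split must sum to 1", call. = FALSE)
  }
  if (any(component_split < 0)) {
    stop("component_split fractions must be non-negative", call. = FALSE)
  }
  if (is.null(coverage_strata)) {
    # the sample pattern 6/25/18 out of 40, scaled to n_centres
    coverage_strata <- c(full_coverage = round(n_centres * 6 / 40),
                         below_half = round(n_centres * 25 / 40),
                         below_third = round(n_centres * 18 / 40))
  }
  cs <- coverage_strata
  required <- c("full_coverage", "below_half", "below_third")
  if (!all(required %in% names(cs))) {
    stop("coverage_strata needs counts: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (any(cs < 0) || any(cs > n_centres)) {
    stop("coverage_strata counts must lie in [0, n_centres]", call. = FALSE)
  }
  if (cs[["below_third"]] > cs[["below_half"]]) {
    stop("coverage_strata: the <30% band is a subset of the <50% band",
         call. = FALSE)
  }
  if (cs[["full_coverage"]] + cs[["below_half"]] > n_centres) {
    stop("coverage_strata: full-coverage and below-half bands overlap",
         call. = FALSE)
  }
  structure(list(
    n_centres = as.integer(n_centres), mean_demand = mean_demand,
    demand_dispersion = demand_dispersion,
    mean_neurologist_fte = mean_neurologist_fte,
    mean_nurse_fte = mean_nurse_fte, mean_facility_fte = mean_facility_fte,
    willingness_proceduralist = willingness_proceduralist,
    willingness_nurse = willingness_nurse,
    component_split = component_split,
    coverage_strata = c(full_coverage = as.integer(cs[["full_coverage"]]),
                        below_half = as.integer(cs[["below_half"]]),
                        below_third = as.integer(cs[["below_third"]])),
    seed = as.integer(seed)
  ), class = "generator_params")
}

# Country labels matching the study sample's recruitment counts (40 centres
# across 12 countries); recycled for other n.
reference_countries <- function(n) {
  counts <- c(Germany = 8, `United Kingdom` = 6, Italy = 6, France = 5,
              Canada = 5, Brazil = 4, Sweden = 1, Spain = 1, Australia = 1,
              Egypt = 1, Colombia = 1, Mexico = 1)
  rep(rep(names(counts), counts), length.out = n)
}

# Gamma draws with a given mean and coefficient of variation; cv = 0
# degenerates to the mean.
rgamma_cv <- function(n, mean, cv) {
  if (cv == 0 || mean == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

#' Generate the deterministic reference survey
#'
#' Builds a synthetic survey collection whose aggregate structure matches
#' the interview sample by construction (exact stratification, not rejection
#' sampling): component-availability flags assigned exactly to the
#' `component_split` strata, and per-centre FTE availabilities back-solved
#' from target coverage fractions through the capacity-gap equations so that
#' exactly `full_coverage` centres cover their whole caseload, exactly
#' `below_half` fall under 50% coverage and exactly `below_third` under 30%.
#' Demand values are drawn around `mean_demand` and rescaled so the sample
#' mean equals `mean_demand` exactly. Component flags correlate with
#' coverage: the best-covered centres are those reporting all three
#' components.
#'
#' Because the component flags are an interview item distinct from the
#' modelled FTE availabilities, a centre may be flagged as lacking a
#' dedicated component while carrying a positive back-solved availability;
#' this mirrors the source data, in which 30 of 40 centres lack a component
#' yet only 18 fall below 30% coverage.
#'
#' @param params A [generator_params()] (its `seed` drives all draws).
#' @param profile,convention The procedure profile and FTE convention whose
#'   equations the availabilities are back-solved through.
#' @return A [survey_collection()] with generator provenance in `metadata`.
#' @examples
#' ref <- generate_reference_survey()
#' mean(ref$centres$anticipated_patients_per_year) # exactly 114
#' @export
generate_reference_survey <- function(params = generator_params(),
                                      profile = default_generation_hd1_profile(),
                                      convention = fte_convention()) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_centres
  comp_counts <- apportion(n, params$component_split)
  cs <- params$coverage_strata
  if (cs[["full_coverage"]] > comp_counts[[1]]) {
    stop("infeasible strata: more full-coverage centres (",
         cs[["full_coverage"]], ") than all-three centres (",
         comp_counts[[1]], ")", call. = FALSE)
  }
  n_full <- cs[["full_coverage"]]
  n_upper <- n - n_full - cs[["below_half"]]
  n_mid <- cs[["below_half"]] - cs[["below_third"]]
  n_low <- cs[["below_third"]]
  # target coverage fractions, descending; interior points keep each centre
  # strictly inside its band
  coverage <- c(
    rep(1, n_full),
    if (n_upper > 0) seq(0.95, 0.55, length.out = n_upper),
    if (n_mid > 0) seq(0.48, 0.32, length.out = n_mid),
    if (n_low > 0) seq(0.28, 0, length.out = n_low)
  )

  # component strata in the same (coverage-descending) order
  comp_class <- rep(c("all_three", "lacks_one_of_nurse_or_facility",
                      "lacks_both"), comp_counts)
  lacks_one_idx <- which(comp_class == "lacks_one_of_nurse_or_facility")
  miss_nurse <- lacks_one_idx[seq_along(lacks_one_idx) %% 2 == 1]
  has_n <- comp_class == "all_three"
  has_f <- comp_class == "all_three"
  has_n[setdiff(lacks_one_idx, miss_nurse)] <- TRUE
  has_f[miss_nurse] <- TRUE

  demand <- with_local_seed(params$seed, {
    rgamma_cv(n, params$mean_demand, params$demand_dispersion)
  })
  if (params$mean_demand > 0) {
    demand <- demand * params$mean_demand / mean(demand)
  }

  will <- c(proceduralist = params$willingness_proceduralist,
            nurse = params$willingness_nurse, facility = 1)
  centres <- do.call(rbind, lapply(seq_len(n), function(i) {
    avail <- vapply(resource_classes(), function(r) {
      coverage[[i]] * needed_fte(demand[[i]], profile, r, convention) /
        will[[r]]
    }, numeric(1))
    centre_survey(
      centre_id = sprintf("C%02d", i),
      country = reference_countries(n)[[i]],
      anticipated_patients_per_year = demand[[i]],
      resource_availability = avail,
      willingness = will,
      has_component = c(proceduralist = TRUE, nurse = has_n[[i]],
                        facility = has_f[[i]])
    )
  }))
  survey_collection(centres, metadata = list(
    source = "synthetic reference survey (exact stratified construction)",
    generator = "generate_reference_survey",
    seed = params$seed,
    n_centres = n,
    mean_demand = params$mean_demand,
    demand_dispersion = params$demand_dispersion,
    component_split = as.list(params$component_split),
    coverage_strata = as.list(params$coverage_strata)
  ))
}

#' Generate a fully stochastic survey
#'
#' Unlike [generate_reference_survey()], nothing is back-solved: demand is
#' drawn from an over-dispersed count-like distribution (rounded gamma) with
#' the stated mean and coefficient of variation; per-class availabilities
#' come from right-skewed gamma distributions with the stated means;
#' component presence is thinned independently per centre at the marginal
#' rates implied by `component_split` (nurse and facility each present with
#' probability `1 - lacks_one/2 - lacks_both`), and availability is zeroed
#' where a component is absent. Intended as a property-testing input source.
#'
#' @inheritParams generate_reference_survey
#' @param seed Overrides `params$seed` when given.
#' @return A [survey_collection()].
#' @export
generate_random_survey <- function(params = generator_params(), seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  seed <- if (is.null(seed)) params$seed else as.integer(seed)
  n <- params$n_centres
  p_absent <- params$component_split[["lacks_one_of_nurse_or_facility"]] / 2 +
    params$component_split[["lacks_both"]]
  dat <- with_local_seed(seed, {
    demand <- round(rgamma_cv(n, params$mean_demand,
                              params$demand_dispersion))
    avail_p <- rgamma_cv(n, params$mean_neurologist_fte, 0.6)
    avail_n <- rgamma_cv(n, params$mean_nurse_fte, 0.6)
    avail_f <- rgamma_cv(n, params$mean_facility_fte, 0.6)
    has_n <- stats::runif(n) >= p_absent
    has_f <- stats::runif(n) >= p_absent
    list(demand = demand, avail_p = avail_p,
         avail_n = ifelse(has_n, avail_n, 0),
         avail_f = ifelse(has_f, avail_f, 0),
         has_n = has_n, has_f = has_f)
  })
  centres <- tibble::tibble(
    centre_id = sprintf("R%05d", seq_len(n)),
    country = reference_countries(n),
    anticipated_patients_per_year = as.numeric(dat$demand),
    proceduralist_fte = dat$avail_p,
    nurse_fte = dat$avail_n,
    facility_fte = dat$avail_f,
    proceduralist_willingness = rep(params$willingness_proceduralist, n),
    nurse_willingness = rep(params$willingness_nurse, n),
    facility_willingness = rep(1, n),
    has_proceduralist = rep(TRUE, n),
    has_nurse = dat$has_n,
    has_facility = dat$has_f
  )
  survey_collection(centres, metadata = list(
    source = "synthetic random survey (independent draws)",
    generator = "generate_random_survey",
    seed = seed,
    n_centres = n
  ))
}
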