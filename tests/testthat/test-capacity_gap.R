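test_that("days per week convert to FTE fractions", {
  expect_equal(days_per_week_to_fte(1.25), 0.25)
  expect_equal(days_per_week_to_fte(0), 0)
  expect_equal(days_per_week_to_fte(5), 1.0)
  expect_warning(over <- days_per_week_to_fte(6), "exceed")
  expect_equal(over, 1.2)
  # convention invariant: 52 x 5 x 8 = 2080 under defaults
  expect_equal(default_convention$hours_per_year,
               52 * default_convention$days_per_week *
                 default_convention$hours_per_day)
})

test_that("needed FTEs for the average caseload match the headline figures", {
  expect_equal(round(needed_fte(114, default_profile, "proceduralist"), 2),
               0.36)
  expect_equal(round(needed_fte(114, default_profile, "nurse"), 2), 0.92)
  expect_equal(needed_fte(0, default_profile, "facility"), 0)
  # raw values: 741 procedures x minutes / 60 / 2080
  expect_equal(needed_fte(114, default_profile, "proceduralist"),
               741 * 60 / 60 / 2080)
})

test_that("available FTE applies the willingness haircut multiplicatively", {
  c1 <- centre_survey("A", resource_availability = c(nurse = 0.15),
                      willingness = c(nurse = 1))
  expect_equal(available_fte(c1, "nurse"), 0.15)
  c2 <- centre_survey("B", resource_availability = c(proceduralist = 0.20),
                      willingness = c(proceduralist = 0.65))
  expect_equal(available_fte(c2, "proceduralist"), 0.13)
  expect_equal(available_fte(c2, "proceduralist", apply_willingness = FALSE),
               0.20)
  c3 <- centre_survey("C", resource_availability = c(nurse = 0.5),
                      willingness = c(nurse = 0))
  expect_equal(available_fte(c3, "nurse"), 0)
})

test_that("centre capacity is the bottleneck class throughput", {
  no_nurse <- centre_survey("N0", anticipated_patients_per_year = 10,
                            resource_availability = c(proceduralist = 1,
                                                      nurse = 0,
                                                      facility = 1))
  expect_equal(capacity_procedures(no_nurse, default_profile), 0)

  fig2 <- centre_survey("F", anticipated_patients_per_year = 114,
                        resource_availability = c(proceduralist = 0.36,
                                                  nurse = 0.92,
                                                  facility = 0.42))
  cap <- capacity_procedures(fig2, default_profile)
  oracle <- brute_force_capacity(fig2, default_profile, default_convention)
  expect_equal(cap, oracle$capacity)
  expect_gte(cap, 741 * 0.99) # each class individually supports ~741

  # homogeneity: doubling every availability doubles capacity
  doubled <- fig2
  for (r in resource_classes()) {
    doubled[[paste0(r, "_fte")]] <- 2 * doubled[[paste0(r, "_fte")]]
  }
  expect_equal(capacity_procedures(doubled, default_profile), 2 * cap)
})

test_that("gap_for_centre populates coverage, gaps and classification", {
  exact <- centre_at_coverage(1)
  g <- gap_for_centre(exact, default_profile)
  expect_equal(g$coverage_fraction, 1)
  for (r in resource_classes()) {
    expect_equal(g[[paste0("gap_", r, "_fte")]], 0, tolerance = 1e-12)
  }
  expect_identical(g$component_class, "all_three")

  idle <- centre_survey("I", anticipated_patients_per_year = 0)
  expect_equal(gap_for_centre(idle, default_profile)$coverage_fraction, 1)

  two_sevenths <- centre_at_coverage(2 / 7)
  expect_equal(gap_for_centre(two_sevenths, default_profile)$coverage_fraction,
               2 / 7, tolerance = 1e-9)
})

test_that("component classification follows the interview flags", {
  flags <- list(
    list(h = c(TRUE, TRUE, TRUE), want = "all_three"),
    list(h = c(TRUE, FALSE, TRUE), want = "lacks_one_of_nurse_or_facility"),
    list(h = c(TRUE, TRUE, FALSE), want = "lacks_one_of_nurse_or_facility"),
    list(h = c(TRUE, FALSE, FALSE), want = "lacks_both"),
    list(h = c(FALSE, TRUE, TRUE), want = "other")
  )
  for (f in flags) {
    ct <- centre_survey("X", anticipated_patients_per_year = 1,
                        resource_availability = c(proceduralist = 1,
                                                  nurse = 1, facility = 1),
                        has_component = setNames(f$h, resource_classes()))
    expect_identical(gap_for_centre(ct, default_profile)$component_class,
                     f$want)
  }
})

test_that("aggregate_gap summarises a collection and rejects an empty one", {
  one <- make_collection(centre_at_coverage(1))
  rep1 <- aggregate_gap(one, default_profile)
  expect_equal(rep1$component_pct[["all_three"]], 100)
  expect_equal(rep1$n_full_coverage, 1)
  expect_equal(rep1$pct_full_coverage, 100)

  empty <- suppressMessages(survey_collection(one$centres[0, ]))
  expect_error(aggregate_gap(empty, default_profile), "empty")
})

test_that("bottleneck matches a brute-force oracle on random centres", {
  params <- generator_params(n_centres = 200, seed = 11)
  coll <- generate_random_survey(params, seed = 11)
  gaps <- aggregate_gap(coll, default_profile)$per_centre
  for (i in seq_len(nrow(gaps))) {
    ct <- coll$centres[coll$centres$centre_id == gaps$centre_id[i], ]
    oracle <- brute_force_capacity(ct, default_profile, default_convention)
    expect_equal(gaps$capacity_procedures_per_year[i], oracle$capacity)
    expect_identical(gaps$bottleneck[i], oracle$bottleneck)
  }
})

test_that("coverage is bounded, monotone in availability, and consistent", {
  set.seed(23)
  coll <- generate_random_survey(generator_params(n_centres = 100), seed = 5)
  gaps <- aggregate_gap(coll, default_profile)$per_centre
  expect_true(all(gaps$coverage_fraction >= 0 & gaps$coverage_fraction <= 1))
  gap_cols <- paste0("gap_", resource_classes(), "_fte")
  expect_true(all(as.matrix(gaps[, gap_cols]) >= 0))

  # coverage = 1 iff capacity covers the annual procedure demand
  demand <- annual_procedures(
    coll$centres$anticipated_patients_per_year[
      match(gaps$centre_id, coll$centres$centre_id)], default_profile)
  expect_identical(gaps$coverage_fraction == 1,
                   gaps$capacity_procedures_per_year >= demand * (1 - 1e-9))

  # raising any availability never lowers coverage
  for (i in sample(nrow(coll$centres), 20)) {
    ct <- coll$centres[i, ]
    before <- gap_for_centre(ct, default_profile)$coverage_fraction
    r <- sample(resource_classes(), 1)
    ct[[paste0(r, "_fte")]] <- ct[[paste0(r, "_fte")]] + runif(1, 0, 0.5)
    after <- gap_for_centre(ct, default_profile)$coverage_fraction
    expect_gte(after, before)
  }
})
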