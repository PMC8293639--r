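test_that("JSON and CSV surveys round-trip field-by-field", {
  params <- generator_params(n_centres = 12, seed = 42)
  for (fmt in c("json", "csv")) {
    for (s in 1:3) {
      coll <- generate_random_survey(params, seed = s)
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      suppressMessages(write_survey(coll, path))
      got <- suppressMessages(load_survey(path))
      expect_equal(got$centres, coll$centres, tolerance = 1e-9)
    }
  }
  # metadata survives the canonical (JSON) format
  coll <- generate_random_survey(params, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  suppressMessages(write_survey(coll, path))
  got <- suppressMessages(load_survey(path))
  expect_equal(got$metadata$seed, 9)
})

test_that("an empty survey file loads as an empty collection", {
  coll <- suppressMessages(survey_collection(
    generate_random_survey(generator_params(n_centres = 2))$centres[0, ]))
  for (fmt in c("json", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    suppressMessages(write_survey(coll, path))
    got <- suppressMessages(load_survey(path))
    expect_s3_class(got, "survey_collection")
    expect_identical(nrow(got$centres), 0L)
  }
})

test_that("validation names the offending centre and field", {
  bad_will <- centre_survey("C7", anticipated_patients_per_year = 10,
                            resource_availability = c(proceduralist = 0.2,
                                                      nurse = 0.1,
                                                      facility = 0.1))
  bad_will$nurse_willingness <- 1.2
  expect_error(survey_collection(bad_will), "C7.*willingness")

  bad_fte <- centre_survey("C8")
  bad_fte$facility_fte <- -0.1
  expect_error(survey_collection(bad_fte), "C8.*facility_fte")

  bad_demand <- centre_survey("C9")
  bad_demand$anticipated_patients_per_year <- -5
  expect_error(survey_collection(bad_demand), "C9.*anticipated_patients")
})

test_that("duplicate centre ids are rejected on construction and write", {
  rows <- rbind(centre_survey("DUP"), centre_survey("DUP"))
  expect_error(survey_collection(rows), "duplicate centre_id")
  coll <- make_collection(centre_survey("A"), centre_survey("B"))
  coll$centres$centre_id <- c("A", "A") # corrupt after construction
  path <- withr::local_tempfile(fileext = ".json")
  expect_error(suppressMessages(write_survey(coll, path)), "duplicate")
})

test_that("validation rejects exactly the invalid records among random ones", {
  set.seed(101)
  for (rep in 1:20) {
    coll <- generate_random_survey(generator_params(n_centres = 5), seed = rep)
    expect_silent(validate_survey(coll)) # valid records always pass
    # corrupt one field of one centre and expect rejection naming it
    i <- sample(5, 1)
    field <- sample(c("proceduralist_willingness", "nurse_fte",
                      "anticipated_patients_per_year"), 1)
    coll$centres[[field]][i] <- if (grepl("willingness", field)) 1.5 else -1
    expect_error(validate_survey(coll),
                 regexp = coll$centres$centre_id[i], fixed = TRUE)
  }
})

test_that("missing willingness defaults to 1 with a warning", {
  coll <- make_collection(centre_survey(
    "W1", anticipated_patients_per_year = 5,
    resource_availability = c(proceduralist = 0.3, nurse = 0.3,
                              facility = 0.3)))
  path <- withr::local_tempfile(fileext = ".json")
  suppressMessages(write_survey(coll, path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  raw$centres[[1]]$willingness$nurse <- NULL
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  expect_warning(got <- suppressMessages(load_survey(path)),
                 "willingness.*nurse")
  expect_identical(got$centres$nurse_willingness, 1)

  # CSV: drop the willingness columns entirely
  path2 <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(write_survey(coll, path2))
  df <- utils::read.csv(path2)
  df <- df[, !grepl("willingness", names(df))]
  utils::write.csv(df, path2, row.names = FALSE)
  suppressWarnings(expect_warning(
    got2 <- suppressMessages(load_survey(path2)), "willingness"))
  expect_identical(got2$centres$proceduralist_willingness, 1)
})

test_that("centre order is preserved from file", {
  coll <- make_collection(centre_survey("Z"), centre_survey("A"),
                          centre_survey("M"))
  path <- withr::local_tempfile(fileext = ".json")
  suppressMessages(write_survey(coll, path))
  got <- suppressMessages(load_survey(path))
  expect_identical(got$centres$centre_id, c("Z", "A", "M"))
})
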