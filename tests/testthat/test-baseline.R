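make_demo_cohort <- function(db) {
  data.frame(person_id = db$persons$person_id,
             index_date = as.Date("2015-06-01"))
}

# 10-person database with a fixed gender split and one HbA1c value each
demo_db <- function(hba1c = NULL) {
  voc <- toy_vocabulary()
  persons <- data.frame(
    person_id = sprintf("D%02d", 1:10),
    birth_year = 1950L,
    gender_concept = c(rep("G_FEMALE", 4), rep("G_MALE", 5), "G_UNKNOWN"),
    race_concept = "R_WHITE", ethnicity_concept = "R_UNKNOWN",
    observation_start = as.Date("2010-01-01"),
    observation_end = as.Date("2019-12-31"))
  events <- if (is.null(hba1c)) {
    data.frame(person_id = character(0), concept_id = character(0),
               event_date = as.Date(character(0)), value = numeric(0))
  } else {
    data.frame(person_id = persons$person_id[seq_along(hba1c)],
               concept_id = "M_HBA1C",
               event_date = as.Date("2015-05-01"), value = hba1c)
  }
  patient_db(persons, events, voc)
}

test_that("demographic levels report percents that sum to 100", {
  db <- demo_db()
  cohort <- make_demo_cohort(db)
  specs <- list(
    characteristic_spec("female", "demographic_level", concept = "G_FEMALE",
                        field = "gender", group = "sex"),
    characteristic_spec("male", "demographic_level", concept = "G_MALE",
                        field = "gender", group = "sex"),
    characteristic_spec("unknown", "demographic_level", concept = "G_UNKNOWN",
                        field = "gender", group = "sex"))
  s <- summarize_cohort(cohort, db, specs)
  expect_equal(s$value, c(40, 50, 10))
  expect_equal(sum(s$value), 100, tolerance = 0.001)
})

test_that("derived flags dichotomize the per-person baseline value", {
  db <- demo_db(hba1c = c(6.0, 7.0, 8.0, 9.5))
  cohort <- make_demo_cohort(db)[1:4, ]   # the four with a value
  spec <- characteristic_spec("hba1c_ge8", "derived_flag", source = "M_HBA1C",
                              comparator = ">=", bound = 8.0)
  s <- summarize_cohort(cohort, db, list(spec), ned_threshold = 1)
  expect_equal(s$value, 50)               # 8.0 and 9.5 of four
  expect_equal(s$n_recorded, 4L)
  # brute-force count oracle
  vals <- sapply(cohort$person_id, function(p)
    baseline_value(db, spec, p, cohort$index_date[1]))
  expect_equal(s$value, 100 * sum(vals) / nrow(cohort))
})

test_that("characteristics without enough recorded data are NED", {
  db <- demo_db()                         # no measurements at all
  cohort <- make_demo_cohort(db)
  s <- summarize_cohort(cohort, db, list(
    characteristic_spec("hba1c", "measurement", concept = "M_HBA1C")))
  expect_true(s$ned)
  expect_true(is.na(s$value))
  # threshold is configurable: 4 recorded of 10 is NED at 5, not at 4
  db2 <- demo_db(hba1c = c(6, 7, 8, 9))
  s5 <- summarize_cohort(make_demo_cohort(db2), db2, list(
    characteristic_spec("hba1c", "measurement", concept = "M_HBA1C")),
    ned_threshold = 5)
  expect_true(s5$ned)
  s4 <- summarize_cohort(make_demo_cohort(db2), db2, list(
    characteristic_spec("hba1c", "measurement", concept = "M_HBA1C")),
    ned_threshold = 4)
  expect_false(s4$ned)
  expect_equal(s4$value, 7.5)
})

test_that("the per-person baseline value follows the window and tie rules", {
  voc <- toy_vocabulary()
  idx <- as.Date("2016-01-01")
  persons <- data.frame(person_id = "W1", birth_year = 1960L,
                        gender_concept = "G_MALE", race_concept = "R_WHITE",
                        ethnicity_concept = "R_UNKNOWN",
                        observation_start = as.Date("2010-01-01"),
                        observation_end = as.Date("2019-12-31"))
  events <- data.frame(
    person_id = "W1", concept_id = "M_TC",
    event_date = idx - c(10, 100, 365, 366),
    value = c(110, 120, 130, 140))
  db <- patient_db(persons, events, voc)
  spec <- characteristic_spec("tc", "measurement", concept = "M_TC",
                              window = c(365, 0))
  expect_equal(baseline_value(db, spec, "W1", idx), 110)  # closest to index
  # exact boundary value is included; one day further out is not
  db$events <- events[3:4, ]
  expect_equal(baseline_value(db, spec, "W1", idx), 130)
  db$events <- events[4, , drop = FALSE]
  expect_true(is.na(baseline_value(db, spec, "W1", idx)))
  # enumeration oracle over all sub-windows
  db$events <- events
  for (w in c(5, 10, 100, 365, 400)) {
    sp <- characteristic_spec("tc", "measurement", concept = "M_TC",
                              window = c(w, 0))
    keep <- as.numeric(idx - events$event_date) <= w
    want <- if (any(keep)) events$value[keep][which.min(idx - events$event_date[keep])]
            else NA_real_
    expect_equal(baseline_value(db, sp, "W1", idx), want)
  }
})

test_that("summarizing the whole database equals direct whole-database statistics", {
  db <- random_db(80, 77)
  cohort <- data.frame(person_id = db$persons$person_id,
                       index_date = as.Date("2019-12-31"))
  specs <- list(
    characteristic_spec("white", "demographic_level", concept = "R_WHITE",
                        field = "race"),
    characteristic_spec("any_dm", "event_presence", concept = "C_DM",
                        window = c(36500, 0)),
    characteristic_spec("tc", "measurement", concept = "M_TC",
                        window = c(36500, 0)))
  s <- summarize_cohort(cohort, db, specs, ned_threshold = 1)
  expect_equal(s$value[1], 100 * mean(db$persons$race_concept == "R_WHITE"))
  expect_equal(s$value[2],
               100 * mean(db$persons$person_id %in%
                            db$events$person_id[db$events$concept_id == "C_DM"]))
  # direct per-person latest-TC mean
  tc <- db$events[db$events$concept_id == "M_TC", ]
  latest <- sapply(split(tc, tc$person_id), function(d)
    d$value[order(d$event_date, decreasing = TRUE)[1]])
  expect_equal(s$value[3], mean(latest))
})

test_that("emulated populations recover the printed cohort column (link test)", {
  trial <- load_trial("sitagliptin_glimepiride")
  db <- generate_population(trial_emulation_config(trial, n_persons = 4000),
                            seed = 101)
  ind <- build_cohort(db, load_definition("sitagliptin_glimepiride"),
                      mode = "indication_only")
  s <- summarize_cohort(ind, db, trial_characteristic_specs(trial))
  col <- cohort_column(trial, "indication_only")
  n <- nrow(ind$members)
  for (nm in c("male", "female", "race_unknown")) {
    p <- col$value[col$characteristic == nm] / 100
    expect_lt(abs(s$value[s$characteristic == nm] / 100 - p),
              4 * sqrt(p * (1 - p) / n))
  }
  hb <- s[s$characteristic == "hba1c_mean", ]
  expect_lt(abs(hb$value - col$value[col$characteristic == "hba1c_mean"]),
            4 * 0.7 / sqrt(hb$n_recorded))
})
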