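test_that("event criteria honour the closed temporal window", {
  db <- tiny_db()
  index <- as.Date("2015-06-01")   # T01's diabetes code is exactly at index
  dm <- concept_set("C_DM")
  has <- criterion("has_event", concept_set = dm, window = c(365, 0))
  expect_true(evaluate_criterion(db, has, "T01", index + 30))  # 30 d post-code
  expect_false(evaluate_criterion(
    db, criterion("absent_event", concept_set = dm, window = c(365, 0)),
    "T01", index + 30))
  # window boundary is inclusive on both sides
  expect_true(evaluate_criterion(db, has, "T01", index + 365))
  expect_false(evaluate_criterion(db, has, "T01", index + 366))
})

test_that("measurement criteria use the closest-not-after rule and fail on missing", {
  db <- tiny_db()
  crit <- function(cmp, b) criterion("measurement_threshold",
                                     concept_set = concept_set("M_HBA1C"),
                                     window = c(365, 0), comparator = cmp,
                                     bound = b)
  # T01 has HbA1c 9.1 (2015-02-21) and 7.5 (2015-05-02): later one qualifies
  idx <- as.Date("2015-06-01")
  expect_true(evaluate_criterion(db, crit("<", 8), "T01", idx))
  expect_false(evaluate_criterion(db, crit(">=", 8), "T01", idx))
  # no in-window measurement: excluded by default, admitted under "pass"
  expect_false(evaluate_criterion(db, crit("<", 8), "T04", idx))
  expect_true(evaluate_criterion(db, crit("<", 8), "T04", idx,
                                 missing_measurement = "pass"))
  expect_error(criterion("measurement_threshold",
                         concept_set = concept_set("M_HBA1C"),
                         comparator = "between", bounds = c(9, 2)),
               "low <= high")
})

test_that("age and demographic criteria evaluate at the index date", {
  db <- tiny_db()
  idx <- as.Date("2015-06-01")
  expect_true(evaluate_criterion(   # T01 born 1950 -> 65 at 2015 index
    db, criterion("age_range", min = 65), "T01", idx))
  expect_false(evaluate_criterion(
    db, criterion("age_range", min = 66), "T01", idx))
  expect_true(evaluate_criterion(
    db, criterion("demographic_equals", field = "gender",
                  values = c("G_MALE", "G_UNKNOWN")), "T01", idx))
})

test_that("vacuous conjunction reduces to the indication-only cohort", {
  db <- random_db(60, 21)
  def <- cohort_definition(concept_set("C_DM"), list())
  a <- build_cohort(db, def, mode = "indication_only")
  b <- build_cohort(db, def, mode = "indication_plus_criteria")
  expect_equal(a$members, b$members)
})

test_that("unoperationalizable criteria are skipped with a warning", {
  db <- random_db(40, 31)
  def <- cohort_definition(
    concept_set("C_DM"),
    list(criterion("unoperationalizable", description = "expected survival")))
  expect_warning(co <- build_cohort(db, def), "unoperationalizable")
  expect_equal(co$members,
               build_cohort(db, def, mode = "indication_only")$members)
})

test_that("cohort construction matches the brute-force scan on random inputs", {
  for (i in 1:12) {
    db <- random_db(50, 100 + i)
    def <- random_definition(200 + i)
    for (mode in c("indication_only", "indication_plus_criteria")) {
      got <- build_cohort(db, def, mode = mode)$members
      want <- oracle_build_cohort(db, def, mode)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, info = paste("defn", i, mode))
    }
  }
})

test_that("eligibility shrinks monotonically, is order-invariant, and subsets indication", {
  db <- random_db(120, 55)
  crits <- list(
    criterion("age_range", min = 40, max = 80),
    criterion("has_event", concept_set = concept_set("C_HTN"),
              window = c(3650, 0)),
    criterion("measurement_threshold", concept_set = concept_set("M_TC"),
              window = c(3650, 0), comparator = "<", bound = 70))
  ind <- build_cohort(db, cohort_definition(concept_set("C_DM")),
                      mode = "indication_only")$members$person_id
  sizes <- sapply(0:3, function(k)
    nrow(build_cohort(db, cohort_definition(concept_set("C_DM"), crits[seq_len(k)]))$members))
  expect_true(all(diff(sizes) <= 0))
  full <- build_cohort(db, cohort_definition(concept_set("C_DM"), crits))
  expect_true(all(full$members$person_id %in% ind))
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    alt <- build_cohort(db, cohort_definition(concept_set("C_DM"), crits[perm]))
    expect_equal(alt$members, full$members)
  }
  # brute-force intersection of single-criterion cohorts
  singletons <- lapply(crits, function(cr)
    build_cohort(db, cohort_definition(concept_set("C_DM"), list(cr)))$members$person_id)
  expect_setequal(full$members$person_id, Reduce(intersect, singletons))
})

test_that("packaged cohort definitions parse and build on emulated data", {
  for (trial in packaged_trials()) {
    def <- load_definition(trial)
    expect_s3_class(def, "cohort_definition")
    db <- generate_population(trial_emulation_config(trial, n_persons = 400),
                              seed = 9)
    ind <- build_cohort(db, def, mode = "indication_only")
    ec <- suppressWarnings(build_cohort(db, def, mode = "indication_plus_criteria"))
    expect_true(all(ec$members$person_id %in% ind$members$person_id))
    expect_lte(nrow(ec$members), nrow(ind$members))
    att <- attr(ec, "attrition")
    expect_true(all(diff(att$n) <= 0))
  }
})
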