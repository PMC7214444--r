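# In-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 3-level, 7-node toy hierarchy: A -> (B, C); B -> (D, E); C -> (F, G)
seven_node_vocab <- function() {
  concept_vocabulary(
    data.frame(concept_id = LETTERS[1:7], domain = "condition",
               label = paste("node", LETTERS[1:7])),
    data.frame(parent_id = c("A", "A", "B", "B", "C", "C"),
               child_id = c("B", "C", "D", "E", "F", "G")))
}

# deliberately small hand-built database over the packaged vocabulary
tiny_db <- function() {
  voc <- toy_vocabulary()
  persons <- data.frame(
    person_id = sprintf("T%02d", 1:4),
    birth_year = c(1950L, 1960L, 1980L, 1940L),
    gender_concept = c("G_MALE", "G_FEMALE", "G_FEMALE", "G_UNKNOWN"),
    race_concept = c("R_WHITE", "R_BLACK", "R_UNKNOWN", "R_WHITE"),
    ethnicity_concept = "R_UNKNOWN",
    observation_start = as.Date("2010-01-01"),
    observation_end = as.Date("2019-12-31"))
  events <- data.frame(
    person_id = c("T01", "T01", "T01", "T02", "T02", "T03", "T04"),
    concept_id = c("C_T2DM", "M_HBA1C", "M_HBA1C", "C_T2DM", "M_HBA1C",
                   "C_T1DM", "C_T2DM"),
    event_date = as.Date(c("2015-06-01", "2015-05-02", "2015-02-21",
                           "2016-01-10", "2015-12-30", "2017-03-05",
                           "2012-08-19")),
    value = c(NA, 7.5, 9.1, NA, 8.4, NA, NA))
  patient_db(persons, events, voc)
}

# random database over the packaged vocabulary for property tests
random_db <- function(n_persons, rng_seed) {
  set.seed(rng_seed)
  voc <- toy_vocabulary()
  conc <- voc$concepts
  event_concepts <- conc$concept_id[conc$domain %in%
                                      c("condition", "drug", "procedure")]
  meas_concepts <- conc$concept_id[conc$domain == "measurement"]
  genders <- conc$concept_id[startsWith(conc$concept_id, "G_")]
  races <- conc$concept_id[startsWith(conc$concept_id, "R_")]
  obs_start <- as.Date("2010-01-01"); obs_end <- as.Date("2019-12-31")
  persons <- data.frame(
    person_id = sprintf("R%04d", seq_len(n_persons)),
    birth_year = sample(1930:1995, n_persons, replace = TRUE),
    gender_concept = sample(genders, n_persons, replace = TRUE),
    race_concept = sample(races, n_persons, replace = TRUE),
    ethnicity_concept = "R_UNKNOWN",
    observation_start = obs_start, observation_end = obs_end)
  n_ev <- n_persons * 6L
  dom_pick <- stats::runif(n_ev) < 0.6
  concept_id <- ifelse(dom_pick,
                       sample(event_concepts, n_ev, replace = TRUE),
                       sample(meas_concepts, n_ev, replace = TRUE))
  events <- data.frame(
    person_id = sample(persons$person_id, n_ev, replace = TRUE),
    concept_id = concept_id,
    event_date = obs_start + sample.int(as.integer(obs_end - obs_start) + 1L,
                                        n_ev, replace = TRUE) - 1L,
    value = ifelse(dom_pick, NA_real_, round(stats::rnorm(n_ev, 50, 20), 1)))
  patient_db(persons, events, voc)
}

# random cohort definition over the packaged vocabulary
random_definition <- function(rng_seed) {
  set.seed(rng_seed)
  voc <- toy_vocabulary()
  conc <- voc$concepts
  cond <- conc$concept_id[conc$domain %in% c("condition", "drug", "procedure")]
  meas <- conc$concept_id[conc$domain == "measurement"]
  rand_cs <- function(pool) {
    inc <- sample(pool, sample(1:2, 1))
    exc <- if (stats::runif(1) < 0.3) sample(pool, 1) else character(0)
    concept_set(inc, exc,
                include_descendants = stats::runif(length(inc)) < 0.7,
                exclude_descendants = stats::runif(length(exc)) < 0.7)
  }
  rand_window <- function() c(sample(c(30, 365, 3650), 1), sample(c(0, 30), 1))
  rand_crit <- function() {
    switch(sample(4, 1),
      criterion("has_event", concept_set = rand_cs(cond), window = rand_window()),
      criterion("absent_event", concept_set = rand_cs(cond), window = rand_window()),
      criterion("measurement_threshold", concept_set = concept_set(sample(meas, 1)),
                window = rand_window(),
                comparator = sample(c(">", ">=", "<", "<=", "between"), 1),
                bound = round(stats::runif(1, 20, 80), 1),
                bounds = sort(round(stats::runif(2, 20, 80), 1))),
      criterion("age_range", min = sample(c(18, 40, 65), 1),
                max = sample(c(70, 80, NULL), 1)))
  }
  cohort_definition(rand_cs(cond),
                    replicate(sample(0:3, 1), rand_crit(), simplify = FALSE),
                    trial_id = paste0("random_", rng_seed))
}
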