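#' Characteristic specifications aligned to a packaged trial
#'
#' Translates a trial transcription's annotated rows into the
#' [characteristic_spec()] list that [summarize_cohort()] needs to produce a
#' table aligned row-for-row with the trial's baseline characteristics.
#' Rows annotated `excluded` in the transcription (cohort extremes, the
#' ordinal prior-antihypertensive counts) have no defined cohort mapping
#' and are skipped.
#'
#' @param trial a `trial_summary` (see [load_trial()]) or a trial id.
#' @return List of [characteristic_spec()] objects.
#' @export
trial_characteristic_specs <- function(trial) {
  if (is.character(trial)) trial <- load_trial(trial)
  stopifnot(inherits(trial, "trial_summary"))
  specs <- lapply(trial$characteristics, function(r) {
    w <- if (!is.null(r$window)) c(r$window$days_before, r$window$days_after)
    switch(r$kind,
      age = characteristic_spec(r$name, "age"),
      demographic = characteristic_spec(
        r$name, "demographic_level", concept = r$concept,
        field = if (identical(r$group, "sex")) "gender" else "race",
        group = r$group),
      event_presence = characteristic_spec(
        r$name, "event_presence", concept = r$concept, window = w,
        group = r$group),
      index_event = characteristic_spec(
        r$name, "event_presence", concept = r$concept, window = c(0, 0),
        group = r$group),
      measurement = characteristic_spec(
        r$name, "measurement", concept = r$concept,
        aggregate = if (isTRUE(r$median)) "median" else "mean",
        group = r$group),
      derived_flag = characteristic_spec(
        r$name, "derived_flag", source = r$derived$source,
        comparator = r$derived$comparator, bound = r$derived$bound,
        group = r$group),
      derived_missing = characteristic_spec(
        r$name, "derived_missing", source = r$derived$source,
        group = r$group),
      excluded = NULL,
      stop("unknown characteristic kind in trial spec: ", r$kind))
  })
  specs[!vapply(specs, is.null, logical(1))]
}

# indication emitted by the generator for each packaged trial; prevalences
# are package choices (the source reports cohort sizes, not base rates)
emulation_indications <- list(
  sitagliptin_glimepiride = list(concepts = "C_T2DM", probs = 1,
                                 prevalence = 0.25),
  prove_it = list(concepts = NULL, probs = NULL, prevalence = 0.20),
  renaal = list(concepts = "C_DIABETIC_NEPHROPATHY", probs = 1,
                prevalence = 0.15),
  accomplish = list(concepts = "C_SYS_HTN", probs = 1, prevalence = 0.50))

#' Generator configuration emulating a packaged trial's real-world cohort
#'
#' Builds a [population_config()] whose marginals are set, field by field,
#' to the trial transcription's printed Indication-Only cohort column:
#' demographic level probabilities (including the Unknown mass), condition,
#' drug and procedure prevalences, and measurement means. Measurement SDs
#' use the trial's printed pooled sigma where one exists and a documented
#' package assumption otherwise (`sd_assumed` in the transcription); rows
#' printed NED get recording probability zero. Where a trial reports age
#' only as band percentages, the age mean/SD are solved from the two normal
#' band equations.
#'
#' @param trial_id one of [packaged_trials()], or a `trial_summary`.
#' @param n_persons population size (default 5000).
#' @param seed default seed stored in the config.
#' @return A [population_config()].
#' @export
trial_emulation_config <- function(trial_id, n_persons = 5000, seed = 1L) {
  trial <- if (inherits(trial_id, "trial_summary")) trial_id
  else load_trial(match.arg(trial_id, packaged_trials()))
  rows <- trial$characteristics
  ind_val <- function(r) {
    v <- r$indication_only$value
    if (is.numeric(v)) v else NA_real_
  }
  pick <- function(kind, domain = NULL, timing = NULL) {
    Filter(function(r) {
      r$kind == kind &&
        (is.null(domain) || identical(r$domain, domain)) &&
        (if (is.null(timing)) is.null(r$timing) else identical(r$timing, timing))
    }, rows)
  }
  marginals <- function(group) {
    sel <- Filter(function(r) r$kind == "demographic" &&
                    identical(r$group, group), rows)
    levels <- vapply(sel, `[[`, "", "concept")
    p <- vapply(sel, ind_val, numeric(1))
    list(levels = levels, probs = p / sum(p))
  }
  prev_spec <- function(sel) {
    if (!length(sel)) return(empty_prevalence_spec())
    data.frame(concept = vapply(sel, `[[`, "", "concept"),
               prevalence = vapply(sel, ind_val, numeric(1)) / 100)
  }

  age_rows <- pick("age")
  if (length(age_rows) && is.finite(ind_val(age_rows[[1]]))) {
    r <- age_rows[[1]]
    age <- list(mean = ind_val(r), sd = as.numeric(r$sigma), min = 18, max = 100)
  } else {
    # solve N(mu, sd) from two printed age-band tail percents
    bands <- Filter(function(r) r$kind == "derived_flag" &&
                      identical(r$derived$source, "age"), rows)
    stopifnot(length(bands) >= 2)
    b <- vapply(bands[1:2], function(r) r$derived$bound, numeric(1))
    p <- vapply(bands[1:2], ind_val, numeric(1)) / 100
    z <- stats::qnorm(1 - p)
    sdv <- (b[2] - b[1]) / (z[2] - z[1])
    age <- list(mean = b[1] - z[1] * sdv, sd = sdv, min = 18, max = 100)
  }

  ind <- emulation_indications[[trial$trial_id]]
  if (is.null(ind)) stop("no packaged emulation for trial ", trial$trial_id)
  if (is.null(ind$concepts)) {   # categorical indication from index-event rows
    idx <- pick("index_event")
    ind$concepts <- vapply(idx, `[[`, "", "concept")
    ind$probs <- vapply(idx, ind_val, numeric(1))
    ind$probs <- ind$probs / sum(ind$probs)
  }

  ms_rows <- Filter(function(r) r$kind == "measurement", rows)
  measurements <- if (length(ms_rows)) {
    do.call(rbind, lapply(ms_rows, function(r) {
      m <- ind_val(r)
      if (!is.finite(m)) m <- as.numeric(r$pooled_printed)  # NED rows
      sdv <- if (!is.null(r$sigma)) as.numeric(r$sigma) else r$sd_assumed
      if (is.null(sdv)) stop("no sigma or sd_assumed for ", r$name)
      data.frame(concept = r$concept, mean = m, sd = sdv,
                 record_prob = r$record_prob %||% 0.95)
    }))
  } else empty_measurement_spec()

  population_config(
    n_persons = n_persons, seed = seed,
    demographics = list(gender = marginals("sex"), race = marginals("race")),
    age = age,
    indication = ind,
    conditions = prev_spec(pick("event_presence", "condition")),
    drugs = prev_spec(pick("event_presence", "drug")),
    procedures = prev_spec(pick("event_presence", "procedure")),
    post_index = prev_spec(Filter(function(r)
      r$kind == "event_presence" && identical(r$timing, "after_index"), rows)),
    measurements = measurements)
}
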