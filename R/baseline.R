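#' Specification of one baseline characteristic
#'
#' Describes how one row of a trial's baseline table is computed from
#' patient records at each cohort member's index date. Exactly one source
#' mode applies per kind:
#' \describe{
#'   \item{demographic_level}{percent of the cohort whose `gender`/`race`
#'     concept equals `concept` ("Unknown" is a first-class level).}
#'   \item{event_presence}{percent of the cohort with >= 1 event in the
#'     resolved concept set within `window` around the index date.}
#'   \item{measurement}{mean (or median, `aggregate = "median"`) of the
#'     per-person baseline measurement closest to the index date within
#'     `window`.}
#'   \item{derived_flag}{percent of the cohort whose per-person baseline
#'     value of `source` (a measurement concept, or `"age"`) satisfies
#'     `comparator bound` (e.g. HbA1c >= 8).}
#'   \item{derived_missing}{percent of the cohort with no in-window value
#'     of `source` (the "Unknown" row of a dichotomized measurement).}
#'   \item{age}{mean age at index (index year minus birth year).}
#' }
#'
#' @param name characteristic name (must match the trial spec row to be
#'   comparable).
#' @param kind one of the kinds above.
#' @param concept concept id (event/measurement/demographic-level kinds).
#' @param concept_descendants include the concept's descendant closure?
#'   Default `FALSE`: trial rows name a specific coded characteristic.
#' @param field `"gender"` or `"race"` for `demographic_level`.
#' @param window `c(days_before, days_after)`; defaults: 365 days lookback
#'   for measurements, 3650 for event history.
#' @param aggregate `"mean"` or `"median"` for measurements.
#' @param source,comparator,bound for derived kinds.
#' @param group optional grouping label (levels of one categorical row
#'   block share a group; their percents sum to ~100).
#' @return An object of class `characteristic_spec`.
#' @export
characteristic_spec <- function(name, kind, concept = NULL,
                                concept_descendants = FALSE, field = NULL,
                                window = NULL, aggregate = "mean",
                                source = NULL, comparator = NULL,
                                bound = NULL, group = NULL) {
  kinds <- c("demographic_level", "event_presence", "measurement",
             "derived_flag", "derived_missing", "age")
  kind <- match.arg(kind, kinds)
  if (is.null(window))
    window <- switch(kind, event_presence = c(3650, 0), c(365, 0))
  if (kind %in% c("demographic_level", "event_presence", "measurement") &&
      is.null(concept))
    stop("characteristic_spec `", name, "`: kind ", kind, " requires a concept")
  if (kind == "demographic_level") {
    field <- match.arg(field, c("gender", "race"))
  }
  if (kind %in% c("derived_flag", "derived_missing") && is.null(source))
    stop("characteristic_spec `", name, "`: derived kinds require a source")
  if (kind == "derived_flag" && (is.null(comparator) || is.null(bound)))
    stop("characteristic_spec `", name, "`: derived_flag requires comparator and bound")
  aggregate <- match.arg(aggregate, c("mean", "median"))
  data_type <- if (kind %in% c("measurement", "age")) "continuous" else "discrete"
  structure(list(name = name, kind = kind, data_type = data_type,
                 concept = concept, concept_descendants = concept_descendants,
                 field = field, window = as.numeric(window),
                 aggregate = aggregate, source = source,
                 comparator = comparator, bound = bound, group = group),
            class = "characteristic_spec")
}

apply_comparator <- function(v, comparator, bound) {
  switch(comparator,
         ">" = v > bound, ">=" = v >= bound,
         "<" = v < bound, "<=" = v <= bound)
}

#' Per-person baseline value of a characteristic
#'
#' The per-person reduction behind [summarize_cohort()]: the demographic
#' category, the event-presence indicator, the qualifying measurement value
#' (closest to and not after the index date within the window, same tie
#' rule as the criteria engine), the derived flag, or the age at index.
#'
#' @param db a [patient_db()].
#' @param spec a [characteristic_spec()].
#' @param person_id a person in the database.
#' @param index_date the member's index date.
#' @return A category string, logical, or numeric; `NA` when the value is
#'   missing (no in-window measurement).
#' @export
baseline_value <- function(db, spec, person_id, index_date) {
  stopifnot(inherits(db, "patient_db"), inherits(spec, "characteristic_spec"))
  index_date <- as.Date(index_date)
  prow <- db$persons[db$persons$person_id == person_id, , drop = FALSE]
  if (!nrow(prow)) stop("unknown person_id: ", person_id)
  pev <- db$events[db$events$person_id == person_id, , drop = FALSE]
  measure_at <- function(concept, window) {
    ids <- spec_concepts(spec, concept, db$vocabulary)
    sub <- pev[pev$concept_id %in% ids & !is.na(pev$value), , drop = FALSE]
    select_baseline_measurement(sub$event_date, sub$value,
                                seq_len(nrow(sub)), index_date, window)
  }
  switch(spec$kind,
    demographic_level = if (spec$field == "gender") prow$gender_concept
                        else prow$race_concept,
    event_presence = {
      ids <- spec_concepts(spec, spec$concept, db$vocabulary)
      lo <- index_date - spec$window[1]; hi <- index_date + spec$window[2]
      any(pev$concept_id %in% ids &
            pev$event_date >= lo & pev$event_date <= hi)
    },
    measurement = measure_at(spec$concept, spec$window),
    derived_flag = {
      v <- if (identical(spec$source, "age"))
        as.integer(format(index_date, "%Y")) - prow$birth_year
      else measure_at(spec$source, spec$window)
      if (is.na(v)) NA else apply_comparator(v, spec$comparator, spec$bound)
    },
    derived_missing = is.na(measure_at(spec$source, spec$window)),
    age = as.integer(format(index_date, "%Y")) - prow$birth_year)
}

spec_concepts <- function(spec, concept, vocabulary) {
  if (isTRUE(spec$concept_descendants)) descendants(vocabulary, concept)
  else {
    assert_known_concepts(vocabulary, concept)
    concept
  }
}

#' Baseline characteristics of a cohort
#'
#' Computes, for each [characteristic_spec()], the cohort-level summary
#' aligned to a trial's baseline table: percents for discrete
#' characteristics (levels of a categorical block sum to ~100 including the
#' explicit Unknown level; persons missing a dichotomized measurement fall
#' in its `derived_missing` level, not in the flag percents' denominator
#' complement), means/medians with SD for continuous ones. A characteristic
#' with fewer than `ned_threshold` recorded persons is reported as NED
#' ("not enough data"): its value is `NA` and the `ned` flag is set.
#'
#' @param cohort a [build_cohort()] result (or a data.frame of `person_id`,
#'   `index_date`).
#' @param db the [patient_db()] the cohort was built from.
#' @param specs list of [characteristic_spec()].
#' @param ned_threshold minimum number of recorded persons for a value to
#'   be reported (default 10).
#' @return A `cohort_summary` data.frame with columns `characteristic`,
#'   `group`, `kind`, `data_type`, `value`, `sd`, `n_recorded`, `ned`;
#'   attribute `n` is the cohort size.
#' @export
summarize_cohort <- function(cohort, db, specs, ned_threshold = 10) {
  members <- if (inherits(cohort, "cohort")) cohort$members else cohort
  stopifnot(is.data.frame(members), inherits(db, "patient_db"))
  if (inherits(specs, "characteristic_spec")) specs <- list(specs)
  n <- nrow(members)
  ev <- db$events
  pidx <- match(members$person_id, db$persons$person_id)
  if (anyNA(pidx)) stop("cohort members missing from the database")
  index_year <- as.integer(format(as.Date(members$index_date), "%Y"))

  # qualifying measurement per member for one concept set (closest-to-index
  # rule, vectorized over the cohort)
  member_measurements <- function(ids, window) {
    sub <- ev[ev$concept_id %in% ids & !is.na(ev$value), , drop = FALSE]
    sub <- sub[sub$person_id %in% members$person_id, , drop = FALSE]
    out <- rep(NA_real_, n)
    if (!nrow(sub)) return(out)
    mm <- match(sub$person_id, members$person_id)
    idx_date <- as.Date(members$index_date)[mm]
    keep <- sub$event_date >= idx_date - window[1] &
      sub$event_date <= idx_date + window[2]
    sub <- sub[keep, , drop = FALSE]; mm <- mm[keep]; idx_date <- idx_date[keep]
    if (!nrow(sub)) return(out)
    before <- sub$event_date <= idx_date
    closeness <- abs(as.numeric(sub$event_date - idx_date))
    ord <- order(mm, !before, closeness, seq_len(nrow(sub)))
    first <- ord[!duplicated(mm[ord])]
    out[mm[first]] <- sub$value[first]
    out
  }

  rows <- lapply(specs, function(spec) {
    value <- NA_real_; sdv <- NA_real_
    if (spec$kind == "demographic_level") {
      col <- if (spec$field == "gender") "gender_concept" else "race_concept"
      vals <- db$persons[[col]][pidx]
      n_rec <- n
      value <- 100 * sum(vals == spec$concept) / n
    } else if (spec$kind == "event_presence") {
      ids <- spec_concepts(spec, spec$concept, db$vocabulary)
      sub <- ev[ev$concept_id %in% ids, , drop = FALSE]
      sub <- sub[sub$person_id %in% members$person_id, , drop = FALSE]
      hit <- rep(FALSE, n)
      if (nrow(sub)) {
        mm <- match(sub$person_id, members$person_id)
        idx_date <- as.Date(members$index_date)[mm]
        ok <- sub$event_date >= idx_date - spec$window[1] &
          sub$event_date <= idx_date + spec$window[2]
        hit[unique(mm[ok])] <- TRUE
      }
      n_rec <- n
      value <- 100 * sum(hit) / n
    } else if (spec$kind == "measurement") {
      ids <- spec_concepts(spec, spec$concept, db$vocabulary)
      v <- member_measurements(ids, spec$window)
      n_rec <- sum(!is.na(v))
      if (n_rec >= 1) {
        value <- if (spec$aggregate == "median") stats::median(v, na.rm = TRUE)
        else mean(v, na.rm = TRUE)
        sdv <- stats::sd(v[!is.na(v)])
      }
    } else if (spec$kind %in% c("derived_flag", "derived_missing")) {
      if (identical(spec$source, "age")) {
        v <- as.numeric(index_year - db$persons$birth_year[pidx])
      } else {
        ids <- spec_concepts(spec, spec$source, db$vocabulary)
        v <- member_measurements(ids, spec$window)
      }
      if (spec$kind == "derived_missing") {
        n_rec <- n
        value <- 100 * sum(is.na(v)) / n
      } else {
        n_rec <- sum(!is.na(v))
        flag <- apply_comparator(v, spec$comparator, spec$bound)
        value <- 100 * sum(flag, na.rm = TRUE) / n   # whole-cohort denominator
      }
    } else if (spec$kind == "age") {
      v <- as.numeric(index_year - db$persons$birth_year[pidx])
      n_rec <- n
      value <- mean(v)
      sdv <- stats::sd(v)
    }
    ned <- n_rec < ned_threshold
    if (ned) { value <- NA_real_; sdv <- NA_real_ }
    data.frame(characteristic = spec$name, group = spec$group %||% NA_character_,
               kind = spec$kind, data_type = spec$data_type, value = value,
               sd = sdv, n_recorded = n_rec, ned = ned)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "ned_threshold") <- ned_threshold
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, digits = 2, ...) {
  cat(sprintf("<cohort_summary> n = %d\n", attr(x, "n")))
  y <- as.data.frame(x)
  y$value <- round(y$value, digits)
  y$sd <- round(y$sd, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
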