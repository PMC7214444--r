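#' Declarative eligibility criterion
#'
#' One operationalized trial criterion. Supported kinds:
#' \describe{
#'   \item{has_event}{at least one event whose concept is in the resolved
#'     concept set and whose date lies in the closed window
#'     `[index - days_before, index + days_after]`.}
#'   \item{absent_event}{the negation of `has_event`.}
#'   \item{measurement_threshold}{the qualifying in-window measurement
#'     (closest to and not after the index date; see Details) satisfies the
#'     comparator (`">"`, `">="`, `"<"`, `"<="`, `"between"`).}
#'   \item{age_range}{age at the index date, computed as index year minus
#'     birth year, lies in the closed range `[min, max]`.}
#'   \item{demographic_equals}{the person's `gender` or `race` concept is
#'     one of `values`.}
#'   \item{unoperationalizable}{a soft criterion (e.g. expected survival)
#'     that cannot be represented with coded data; the engine skips it with
#'     a warning, mirroring how such criteria are excluded when published
#'     criteria are operationalized.}
#' }
#'
#' @details When several measurements fall inside the window, the one
#' closest to the index date among those on or before it is used; ties are
#' broken by the later date, then by record order. If no in-window
#' measurement is on or before the index date, the earliest one after it is
#' used. A person with no in-window measurement fails the criterion by
#' default (trials verify labs at screening); pass
#' `missing_measurement = "pass"` to [build_cohort()] to flip that.
#'
#' @param kind criterion kind, see above.
#' @param concept_set a [concept_set()] (event and measurement kinds).
#' @param window numeric `c(days_before, days_after)`, both `>= 0`; the
#'   window is a closed interval in days around the index date.
#' @param comparator,bound,bounds for `measurement_threshold`: comparator
#'   and a single `bound`, or `bounds = c(low, high)` with `low <= high` for
#'   `"between"`.
#' @param min,max for `age_range` (either may be `NULL` for one-sided).
#' @param field,values for `demographic_equals`: `"gender"` or `"race"` and
#'   the admissible demographic concept ids.
#' @param description free text for `unoperationalizable`.
#' @return An object of class `criterion`.
#' @export
criterion <- function(kind, concept_set = NULL, window = c(365, 0),
                      comparator = NULL, bound = NULL, bounds = NULL,
                      min = NULL, max = NULL, field = NULL, values = NULL,
                      description = NULL) {
  kinds <- c("has_event", "absent_event", "measurement_threshold",
             "age_range", "demographic_equals", "unoperationalizable")
  kind <- match.arg(kind, kinds)
  window <- as.numeric(window)
  if (length(window) != 2L || any(is.na(window)) || any(window < 0))
    stop("window must be c(days_before, days_after) with both >= 0")
  if (kind %in% c("has_event", "absent_event", "measurement_threshold")) {
    if (!inherits(concept_set, "concept_set"))
      stop(kind, " criterion requires a concept_set")
  }
  if (kind == "measurement_threshold") {
    comparator <- match.arg(comparator, c(">", ">=", "<", "<=", "between"))
    if (comparator == "between") {
      if (is.null(bounds) && !is.null(bound) && length(bound) == 2L)
        bounds <- bound
      if (length(bounds) != 2L || bounds[1] > bounds[2])
        stop("between requires bounds = c(low, high) with low <= high")
    } else if (is.null(bound) || length(bound) != 1L) {
      stop("comparator ", comparator, " requires a single bound")
    }
  }
  if (kind == "age_range" && is.null(min) && is.null(max))
    stop("age_range requires min and/or max")
  if (kind == "demographic_equals") {
    field <- match.arg(field, c("gender", "race"))
    if (!length(values)) stop("demographic_equals requires values")
  }
  structure(list(kind = kind, concept_set = concept_set, window = window,
                 comparator = comparator, bound = bound, bounds = bounds,
                 min = min, max = max, field = field, values = values,
                 description = description),
            class = "criterion")
}

#' @export
print.criterion <- function(x, ...) {
  cat("<criterion>", x$kind)
  if (!is.null(x$comparator))
    cat(" ", x$comparator, " ",
        paste(c(x$bound, x$bounds), collapse = ".."), sep = "")
  if (x$kind == "age_range")
    cat(sprintf(" [%s, %s]", x$min %||% "-Inf", x$max %||% "Inf"))
  if (x$kind %in% c("has_event", "absent_event", "measurement_threshold"))
    cat(sprintf(" window [-%g, +%g]d", x$window[1], x$window[2]))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort definition: indication plus ordered eligibility criteria
#'
#' The indication concept set defines cohort entry: every person with at
#' least one indication event enters, anchored at the earliest such event
#' (the index date). In `"indication_plus_criteria"` mode all eligibility
#' criteria are additionally applied conjunctively at that index date.
#'
#' @param indication a [concept_set()] for the drug's indication.
#' @param eligibility list of [criterion()] objects (may be empty).
#' @param mode `"indication_only"` or `"indication_plus_criteria"`.
#' @param trial_id optional label.
#' @return An object of class `cohort_definition`.
#' @export
cohort_definition <- function(indication, eligibility = list(),
                              mode = c("indication_plus_criteria",
                                       "indication_only"),
                              trial_id = NULL) {
  stopifnot(inherits(indication, "concept_set"))
  mode <- match.arg(mode)
  if (!all(vapply(eligibility, inherits, logical(1), "criterion")))
    stop("eligibility must be a list of criterion objects")
  structure(list(indication = indication, eligibility = eligibility,
                 mode = mode, trial_id = trial_id),
            class = "cohort_definition")
}

#' @export
print.cohort_definition <- function(x, ...) {
  cat(sprintf("<cohort_definition> %s: indication + %d criteria (mode %s)\n",
              x$trial_id %||% "(unnamed)", length(x$eligibility), x$mode))
  invisible(x)
}

#' Read a cohort definition from YAML
#'
#' See the packaged files under `extdata/definitions/` for the schema:
#' `indication: {concept_set: ...}` and a list of `eligibility` entries,
#' each with a `kind` and kind-specific fields.
#'
#' @param path YAML file.
#' @return A [cohort_definition()].
#' @export
read_cohort_definition <- function(path) {
  doc <- yaml::read_yaml(path)
  parse_cs <- function(node) {
    stopifnot(!is.null(node))
    mk <- function(entries) {
      ids <- vapply(entries, `[[`, "", "id")
      desc <- vapply(entries, function(e) isTRUE(e$descendants), logical(1))
      list(ids = ids, desc = desc)
    }
    inc <- mk(node$include %||% list())
    exc <- mk(node$exclude %||% list())
    concept_set(inc$ids, exc$ids, inc$desc, exc$desc)
  }
  parse_window <- function(w) {
    if (is.null(w)) c(365, 0) else c(w$days_before %||% 365, w$days_after %||% 0)
  }
  elig <- lapply(doc$eligibility %||% list(), function(e) {
    switch(e$kind,
      age_range = criterion("age_range", min = e$min, max = e$max),
      has_event = criterion("has_event", concept_set = parse_cs(e$concept_set),
                            window = parse_window(e$window)),
      absent_event = criterion("absent_event",
                               concept_set = parse_cs(e$concept_set),
                               window = parse_window(e$window)),
      measurement_threshold = criterion(
        "measurement_threshold", concept_set = parse_cs(e$concept_set),
        window = parse_window(e$window), comparator = e$comparator,
        bound = if (e$comparator != "between") e$bound,
        bounds = if (e$comparator == "between") unlist(e$bounds)),
      demographic_equals = criterion("demographic_equals", field = e$field,
                                     values = unlist(e$values)),
      unoperationalizable = criterion("unoperationalizable",
                                      description = e$description),
      stop("unknown criterion kind in ", path, ": ", e$kind))
  })
  cohort_definition(parse_cs(doc$indication$concept_set), elig,
                    trial_id = doc$trial_id)
}

# qualifying measurement under the closest-to-index tie rule; NA if none
select_baseline_measurement <- function(dates, values, order_idx, index_date,
                                        window) {
  lo <- index_date - window[1]; hi <- index_date + window[2]
  keep <- dates >= lo & dates <= hi
  if (!any(keep)) return(NA_real_)
  dates <- dates[keep]; values <- values[keep]; order_idx <- order_idx[keep]
  before <- dates <= index_date
  if (any(before)) {
    dates <- dates[before]; values <- values[before]; order_idx <- order_idx[before]
    pick <- order(as.numeric(index_date - dates), order_idx)[1L]
  } else {
    pick <- order(as.numeric(dates - index_date), order_idx)[1L]
  }
  values[pick]
}

#' Evaluate one criterion for one person at an index date
#'
#' @param db a [patient_db()].
#' @param crit a [criterion()].
#' @param person_id single person id present in the database.
#' @param index_date the anchoring date.
#' @param missing_measurement `"fail"` (default) or `"pass"`: verdict for a
#'   `measurement_threshold` criterion when no in-window measurement exists.
#' @return `TRUE` or `FALSE` (`unoperationalizable` criteria warn and
#'   return `TRUE`, i.e. they are ignored).
#' @export
evaluate_criterion <- function(db, crit, person_id, index_date,
                               missing_measurement = c("fail", "pass")) {
  stopifnot(inherits(db, "patient_db"), inherits(crit, "criterion"))
  missing_measurement <- match.arg(missing_measurement)
  index_date <- as.Date(index_date)
  prow <- db$persons[db$persons$person_id == person_id, , drop = FALSE]
  if (!nrow(prow)) stop("unknown person_id: ", person_id)
  pev <- db$events[db$events$person_id == person_id, , drop = FALSE]
  eval_criterion_one(db, crit, prow, pev, index_date, missing_measurement)
}

eval_criterion_one <- function(db, crit, prow, pev, index_date,
                               missing_measurement) {
  switch(crit$kind,
    has_event = ,
    absent_event = {
      set <- resolve_concept_set(crit$concept_set, db$vocabulary)
      lo <- index_date - crit$window[1]; hi <- index_date + crit$window[2]
      hit <- any(pev$concept_id %in% set &
                   pev$event_date >= lo & pev$event_date <= hi)
      if (crit$kind == "has_event") hit else !hit
    },
    measurement_threshold = {
      set <- resolve_concept_set(crit$concept_set, db$vocabulary)
      sub <- pev[pev$concept_id %in% set & !is.na(pev$value), , drop = FALSE]
      v <- select_baseline_measurement(sub$event_date, sub$value,
                                       seq_len(nrow(sub)), index_date,
                                       crit$window)
      if (is.na(v)) return(missing_measurement == "pass")
      switch(crit$comparator,
             ">" = v > crit$bound, ">=" = v >= crit$bound,
             "<" = v < crit$bound, "<=" = v <= crit$bound,
             between = v >= crit$bounds[1] & v <= crit$bounds[2])
    },
    age_range = {
      age <- as.integer(format(index_date, "%Y")) - prow$birth_year
      (is.null(crit$min) || age >= crit$min) &&
        (is.null(crit$max) || age <= crit$max)
    },
    demographic_equals = {
      val <- if (crit$field == "gender") prow$gender_concept else prow$race_concept
      val %in% crit$values
    },
    unoperationalizable = {
      warning("ignoring unoperationalizable criterion: ",
              crit$description %||% "(no description)", call. = FALSE)
      TRUE
    })
}

#' Materialize a cohort from a patient database
#'
#' Entry is defined by the indication: every person with at least one event
#' in the resolved indication concept set (within their observation period)
#' enters, with index date equal to the earliest such event. In
#' `"indication_plus_criteria"` mode the ordered eligibility criteria are
#' then applied conjunctively at that index date; the member set is
#' invariant to the ordering of the criteria, and adding criteria can only
#' shrink the cohort. Per-criterion attrition counts are attached as the
#' `"attrition"` attribute.
#'
#' @param db a [patient_db()].
#' @param definition a [cohort_definition()].
#' @param mode overrides `definition$mode` if given.
#' @inheritParams evaluate_criterion
#' @return An object of class `cohort`: list with `members` (data.frame of
#'   `person_id`, `index_date`), the definition and the mode.
#' @export
build_cohort <- function(db, definition, mode = NULL,
                         missing_measurement = c("fail", "pass")) {
  stopifnot(inherits(db, "patient_db"), inherits(definition, "cohort_definition"))
  missing_measurement <- match.arg(missing_measurement)
  mode <- match.arg(mode %||% definition$mode,
                    c("indication_only", "indication_plus_criteria"))
  ind_set <- resolve_concept_set(definition$indication, db$vocabulary)
  ev <- db$events
  cand <- ev[ev$concept_id %in% ind_set, c("person_id", "event_date")]
  m <- match(cand$person_id, db$persons$person_id)
  in_obs <- cand$event_date >= db$persons$observation_start[m] &
    cand$event_date <= db$persons$observation_end[m]
  cand <- cand[in_obs, , drop = FALSE]
  if (nrow(cand)) {
    cand <- cand[order(cand$person_id, cand$event_date), , drop = FALSE]
    cand <- cand[!duplicated(cand$person_id), , drop = FALSE]
  }
  members <- data.frame(person_id = cand$person_id,
                        index_date = cand$event_date)
  rownames(members) <- NULL
  attrition <- data.frame(step = "indication", n = nrow(members))

  if (mode == "indication_plus_criteria" && nrow(members)) {
    ev_by_person <- split(seq_len(nrow(ev)), ev$person_id)
    pidx <- match(members$person_id, db$persons$person_id)
    for (j in seq_along(definition$eligibility)) {
      crit <- definition$eligibility[[j]]
      if (crit$kind == "unoperationalizable") {
        warning("ignoring unoperationalizable criterion: ",
                crit$description %||% "(no description)", call. = FALSE)
        attrition <- rbind(attrition,
                           data.frame(step = paste0("criterion_", j,
                                                    "_unoperationalizable"),
                                      n = nrow(members)))
        next
      }
      keep <- vapply(seq_len(nrow(members)), function(i) {
        rows <- ev_by_person[[members$person_id[i]]]
        pev <- ev[rows %||% integer(0), , drop = FALSE]
        prow <- db$persons[pidx[i], , drop = FALSE]
        eval_criterion_one(db, crit, prow, pev, members$index_date[i],
                           missing_measurement)
      }, logical(1))
      members <- members[keep, , drop = FALSE]
      pidx <- pidx[keep]
      attrition <- rbind(attrition,
                         data.frame(step = paste0("criterion_", j, "_", crit$kind),
                                    n = nrow(members)))
    }
    rownames(members) <- NULL
  }
  structure(list(members = members, definition = definition, mode = mode),
            attrition = attrition, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s, mode %s: %d members\n",
              x$definition$trial_id %||% "(unnamed)", x$mode,
              nrow(x$members)))
  att <- attr(x, "attrition")
  if (!is.null(att)) {
    cat("attrition:\n")
    print(att, row.names = FALSE)
  }
  invisible(x)
}
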