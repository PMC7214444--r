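#' Longitudinal patient database
#'
#' Container for a synthetic longitudinal patient population in a minimal
#' OMOP-like layout: one row per person (demographics and a single
#' observation window) and one row per clinical event (condition, drug,
#' procedure or valued measurement), plus the concept vocabulary the events
#' are coded against.
#'
#' @param persons data.frame with columns `person_id`, `birth_year`,
#'   `gender_concept`, `race_concept`, `ethnicity_concept`,
#'   `observation_start`, `observation_end` (Dates).
#' @param events data.frame with columns `person_id`, `concept_id`,
#'   `event_date` (Date) and `value` (numeric; `NA` except for measurement
#'   events).
#' @param vocabulary a [concept_vocabulary()].
#' @return An object of class `patient_db`.
#' @seealso [validate_database()], [write_patient_db()], [generate_population()]
#' @export
patient_db <- function(persons, events, vocabulary) {
  stopifnot(is.data.frame(persons), is.data.frame(events),
            inherits(vocabulary, "concept_vocabulary"))
  need_p <- c("person_id", "birth_year", "gender_concept", "race_concept",
              "ethnicity_concept", "observation_start", "observation_end")
  if (!all(need_p %in% names(persons)))
    stop("persons must have columns: ", paste(need_p, collapse = ", "))
  need_e <- c("person_id", "concept_id", "event_date", "value")
  if (!all(need_e %in% names(events)))
    stop("events must have columns: ", paste(need_e, collapse = ", "))
  persons$observation_start <- as.Date(persons$observation_start)
  persons$observation_end <- as.Date(persons$observation_end)
  events$event_date <- as.Date(events$event_date)
  rownames(persons) <- NULL
  rownames(events) <- NULL
  structure(list(persons = persons, events = events, vocabulary = vocabulary),
            class = "patient_db")
}

#' @export
print.patient_db <- function(x, ...) {
  cat(sprintf("<patient_db> %d persons, %d events\n",
              nrow(x$persons), nrow(x$events)))
  dom <- concept_domain(x$vocabulary, x$events$concept_id)
  if (length(dom)) print(table(dom, useNA = "ifany"))
  invisible(x)
}

#' Check referential integrity and record invariants of a patient database
#'
#' Violations are returned as report rows, never raised as conditions, so a
#' database can be audited wholesale. An empty report means the database is
#' valid.
#'
#' Checks: unique person ids; observation_start <= observation_end; every
#' event resolves to a known person and concept; event dates fall inside the
#' person's observation window; measurement events carry a value and
#' non-measurement events do not; person demographic codes exist in the
#' vocabulary.
#'
#' @param db a [patient_db()].
#' @return data.frame with columns `rule`, `id`, `message`; zero rows iff
#'   the database is valid.
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "patient_db"))
  per <- db$persons; ev <- db$events; voc <- db$vocabulary
  out <- list()
  add <- function(rule, id, message) {
    out[[length(out) + 1L]] <<- data.frame(rule = rule, id = as.character(id),
                                           message = message)
  }
  dup <- per$person_id[duplicated(per$person_id)]
  for (d in unique(dup)) add("person_unique", d, "duplicated person_id")
  bad <- per$person_id[per$observation_start > per$observation_end]
  for (d in bad) add("observation_window", d,
                     "observation_start after observation_end")
  for (col in c("gender_concept", "race_concept", "ethnicity_concept")) {
    unknown <- setdiff(unique(per[[col]]), voc$concepts$concept_id)
    for (d in unknown) add("person_concept", d,
                           paste0("unknown ", col, " value"))
  }
  if (nrow(ev)) {
    dangling <- !(ev$person_id %in% per$person_id)
    for (i in which(dangling))
      add("event_person", ev$person_id[i], "event person_id not in persons")
    unknown_c <- !(ev$concept_id %in% voc$concepts$concept_id)
    for (i in which(unknown_c))
      add("event_concept", ev$concept_id[i], "event concept_id not in vocabulary")
    ok <- !dangling & !unknown_c
    if (any(ok)) {
      idx <- which(ok)
      m <- match(ev$person_id[idx], per$person_id)
      out_win <- ev$event_date[idx] < per$observation_start[m] |
        ev$event_date[idx] > per$observation_end[m]
      for (i in idx[out_win])
        add("event_date", ev$person_id[i],
            "event_date outside person's observation period")
      dom <- concept_domain(voc, ev$concept_id[idx])
      miss_val <- dom == "measurement" & is.na(ev$value[idx])
      for (i in idx[miss_val])
        add("measurement_value", ev$person_id[i],
            "measurement event lacking a value")
      extra_val <- dom != "measurement" & !is.na(ev$value[idx])
      for (i in idx[extra_val])
        add("measurement_value", ev$person_id[i],
            "non-measurement event carrying a value")
    }
  }
  if (!length(out))
    return(data.frame(rule = character(0), id = character(0),
                      message = character(0)))
  do.call(rbind, out)
}

# On-disk layout: one delimited table per domain plus the vocabulary.
db_event_tables <- c(condition = "condition_occurrence.csv",
                     drug = "drug_exposure.csv",
                     measurement = "measurement.csv",
                     procedure = "procedure_occurrence.csv")

#' Write a patient database to a directory of delimited text tables
#'
#' One UTF-8 CSV per domain (`persons.csv`, `condition_occurrence.csv`,
#' `drug_exposure.csv`, `measurement.csv`, `procedure_occurrence.csv`) plus
#' `vocabulary.csv` and `hierarchy.csv`. Dates are ISO-8601. Only the
#' measurement table carries a `value` column. The layout round-trips:
#' [read_patient_db()] on the directory reconstructs an identical database.
#'
#' @param db a [patient_db()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_patient_db <- function(db, dir) {
  stopifnot(inherits(db, "patient_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per <- db$persons
  per$observation_start <- format(per$observation_start)
  per$observation_end <- format(per$observation_end)
  utils::write.csv(per, file.path(dir, "persons.csv"), row.names = FALSE)
  ev <- db$events
  dom <- concept_domain(db$vocabulary, ev$concept_id)
  for (d in names(db_event_tables)) {
    sub <- ev[which(dom == d), c("person_id", "concept_id", "event_date", "value")]
    sub$event_date <- format(sub$event_date)
    if (d != "measurement") sub$value <- NULL
    utils::write.csv(sub, file.path(dir, db_event_tables[[d]]),
                     row.names = FALSE)
  }
  utils::write.csv(db$vocabulary$concepts, file.path(dir, "vocabulary.csv"),
                   row.names = FALSE)
  utils::write.csv(db$vocabulary$edges, file.path(dir, "hierarchy.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a patient database written by [write_patient_db()]
#'
#' @param dir directory containing the domain tables.
#' @return A [patient_db()].
#' @export
read_patient_db <- function(dir) {
  voc <- read_vocabulary_dir(dir)
  per <- utils::read.csv(file.path(dir, "persons.csv"),
                         stringsAsFactors = FALSE)
  evs <- lapply(names(db_event_tables), function(d) {
    sub <- utils::read.csv(file.path(dir, db_event_tables[[d]]),
                           stringsAsFactors = FALSE)
    if (!"value" %in% names(sub)) sub$value <- rep(NA_real_, nrow(sub))
    sub$value <- as.numeric(sub$value)
    sub
  })
  ev <- do.call(rbind, evs)
  patient_db(per, ev, voc)
}
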