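# Independent oracles: plain re-implementations used only to cross-check the
# package. They share no code with the package internals — descendant closure
# by breadth-first search over the raw edge table, cohort construction by a
# naive per-person, per-event scan without concept-set precomputation.

oracle_descendants <- function(voc, id) {
  edges <- voc$edges
  found <- id
  frontier <- id
  while (length(frontier)) {
    kids <- edges$child_id[edges$parent_id %in% frontier]
    frontier <- setdiff(kids, found)
    found <- union(found, frontier)
  }
  sort(found)
}

oracle_resolve <- function(voc, cs) {
  expand <- function(tab) {
    out <- character(0)
    for (i in seq_len(nrow(tab))) {
      out <- union(out, if (tab$descendants[i])
        oracle_descendants(voc, tab$concept_id[i]) else tab$concept_id[i])
    }
    out
  }
  sort(setdiff(expand(cs$include), expand(cs$exclude)))
}

# criterion verdict by direct scan of one person's records
oracle_criterion <- function(db, crit, pid, index_date,
                             missing_measurement = "fail") {
  per <- db$persons[db$persons$person_id == pid, ]
  evs <- db$events[db$events$person_id == pid, ]
  if (crit$kind == "age_range") {
    age <- as.integer(format(index_date, "%Y")) - per$birth_year
    lo_ok <- is.null(crit$min) || age >= crit$min
    hi_ok <- is.null(crit$max) || age <= crit$max
    return(lo_ok && hi_ok)
  }
  if (crit$kind == "demographic_equals") {
    v <- if (crit$field == "gender") per$gender_concept else per$race_concept
    return(v %in% crit$values)
  }
  set <- oracle_resolve(db$vocabulary, crit$concept_set)
  lo <- index_date - crit$window[1]
  hi <- index_date + crit$window[2]
  if (crit$kind %in% c("has_event", "absent_event")) {
    hit <- FALSE
    for (i in seq_len(nrow(evs))) {
      if (evs$concept_id[i] %in% set &&
          evs$event_date[i] >= lo && evs$event_date[i] <= hi) hit <- TRUE
    }
    return(if (crit$kind == "has_event") hit else !hit)
  }
  # measurement_threshold: enumerate candidates, apply the tie rule by hand
  best <- NULL; best_key <- NULL
  for (i in seq_len(nrow(evs))) {
    if (!(evs$concept_id[i] %in% set) || is.na(evs$value[i])) next
    d <- evs$event_date[i]
    if (d < lo || d > hi) next
    key <- c(as.numeric(d > index_date),          # prefer on-or-before
             abs(as.numeric(d - index_date)), i)  # closest, then record order
    if (is.null(best_key) ||
        key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2]) ||
        (key[1] == best_key[1] && key[2] == best_key[2] && key[3] < best_key[3])) {
      best <- evs$value[i]; best_key <- key
    }
  }
  if (is.null(best)) return(missing_measurement == "pass")
  switch(crit$comparator,
         ">" = best > crit$bound, ">=" = best >= crit$bound,
         "<" = best < crit$bound, "<=" = best <= crit$bound,
         between = best >= crit$bounds[1] && best <= crit$bounds[2])
}

oracle_build_cohort <- function(db, definition, mode,
                                missing_measurement = "fail") {
  set <- oracle_resolve(db$vocabulary, definition$indication)
  members <- list()
  for (pid in db$persons$person_id) {
    per <- db$persons[db$persons$person_id == pid, ]
    evs <- db$events[db$events$person_id == pid, ]
    dates <- evs$event_date[evs$concept_id %in% set &
                              evs$event_date >= per$observation_start &
                              evs$event_date <= per$observation_end]
    if (!length(dates)) next
    index <- min(dates)
    ok <- TRUE
    if (mode == "indication_plus_criteria") {
      for (crit in definition$eligibility) {
        if (crit$kind == "unoperationalizable") next
        if (!oracle_criterion(db, crit, pid, index, missing_measurement)) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) members[[length(members) + 1L]] <-
        data.frame(person_id = pid, index_date = index)
  }
  if (!length(members))
    return(data.frame(person_id = character(0),
                      index_date = as.Date(character(0))))
  out <- do.call(rbind, members)
  out[order(out$person_id), ]
}

# two-sided normal tail probability without pnorm
oracle_normal_p <- function(z) {
  2 * stats::integrate(stats::dnorm, -Inf, -abs(z))$value
}
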