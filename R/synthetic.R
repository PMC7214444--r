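#' Configuration for the synthetic population generator
#'
#' Describes the statistical structure of a synthetic longitudinal patient
#' population: demographic marginals (with explicit "unknown" mass),
#' per-measurement distributions with a recording probability
#' (missingness), condition/drug/procedure prevalences for history events,
#' and an indication specification whose events anchor each indicated
#' person's index date. All characteristics are sampled independently per
#' person by default; an optional Gaussian-copula correlation over the
#' continuous measurements can be supplied but packaged configurations leave
#' it off, because published baseline tables report only marginals.
#'
#' @param n_persons number of persons to simulate (>= 1).
#' @param seed default random seed used by [generate_population()].
#' @param observation list with `start` and `end` dates bounding every
#'   person's observation window.
#' @param demographics list with `gender` and `race`, each a list of
#'   `levels` (demographic concept ids) and `probs` (summing to 1).
#' @param age list with `mean`, `sd` and optional truncation `min`, `max`
#'   for the age (in years) at the person's index/reference date.
#' @param indication list with `concepts` (ids emitted as the indication
#'   event), `probs` (sampling weights over those concepts) and `prevalence`
#'   (fraction of persons carrying the indication).
#' @param conditions,drugs,procedures data.frames with columns `concept`,
#'   `prevalence`: history events placed strictly before the reference date.
#' @param post_index data.frame with columns `concept`, `prevalence`:
#'   events placed strictly after the reference date.
#' @param measurements data.frame with columns `concept`, `mean`, `sd`,
#'   `record_prob` and optional `lower`, `upper` truncation bounds
#'   (default mean +/- 6 sd, i.e. effectively untruncated).
#' @param correlation optional correlation matrix (dimension = rows of
#'   `measurements`) for the Gaussian copula hook; `NULL` (default) samples
#'   measurements independently.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_persons,
                              seed = 1L,
                              observation = list(start = "2010-01-01",
                                                 end = "2019-12-31"),
                              demographics = list(
                                gender = list(levels = c("G_MALE", "G_FEMALE", "G_UNKNOWN"),
                                              probs = c(0.49, 0.50, 0.01)),
                                race = list(levels = c("R_WHITE", "R_BLACK", "R_UNKNOWN"),
                                            probs = c(0.5, 0.3, 0.2))),
                              age = list(mean = 60, sd = 12, min = 18, max = 100),
                              indication = list(concepts = "C_T2DM", probs = 1,
                                                prevalence = 0.25),
                              conditions = empty_prevalence_spec(),
                              drugs = empty_prevalence_spec(),
                              procedures = empty_prevalence_spec(),
                              post_index = empty_prevalence_spec(),
                              measurements = empty_measurement_spec(),
                              correlation = NULL) {
  cfg <- structure(
    list(n_persons = n_persons, seed = seed, observation = observation,
         demographics = demographics, age = age, indication = indication,
         conditions = as_prevalence_spec(conditions, "conditions"),
         drugs = as_prevalence_spec(drugs, "drugs"),
         procedures = as_prevalence_spec(procedures, "procedures"),
         post_index = as_prevalence_spec(post_index, "post_index"),
         measurements = as_measurement_spec(measurements),
         correlation = correlation),
    class = "population_config")
  validate_population_config(cfg)
  cfg
}

empty_prevalence_spec <- function() {
  data.frame(concept = character(0), prevalence = numeric(0))
}

empty_measurement_spec <- function() {
  data.frame(concept = character(0), mean = numeric(0), sd = numeric(0),
             record_prob = numeric(0))
}

as_prevalence_spec <- function(x, what) {
  x <- as.data.frame(x)
  if (!all(c("concept", "prevalence") %in% names(x)))
    stop("invalid config: ", what, " needs columns concept, prevalence")
  x
}

as_measurement_spec <- function(x) {
  x <- as.data.frame(x)
  if (!nrow(x)) return(cbind(empty_measurement_spec(),
                             lower = numeric(0), upper = numeric(0)))
  if (!all(c("concept", "mean", "sd", "record_prob") %in% names(x)))
    stop("invalid config: measurements needs columns concept, mean, sd, record_prob")
  if (is.null(x$lower)) x$lower <- x$mean - 6 * x$sd
  if (is.null(x$upper)) x$upper <- x$mean + 6 * x$sd
  x$lower <- ifelse(is.na(x$lower), x$mean - 6 * x$sd, x$lower)
  x$upper <- ifelse(is.na(x$upper), x$mean + 6 * x$sd, x$upper)
  x
}

validate_population_config <- function(cfg) {
  fail <- function(field, why) stop("invalid config field `", field, "`: ", why)
  if (!is.numeric(cfg$n_persons) || length(cfg$n_persons) != 1L ||
      is.na(cfg$n_persons) || cfg$n_persons < 1)
    fail("n_persons", "must be a single number >= 1")
  for (dim in c("gender", "race")) {
    d <- cfg$demographics[[dim]]
    if (is.null(d$levels) || is.null(d$probs) ||
        length(d$levels) != length(d$probs))
      fail(paste0("demographics$", dim), "levels and probs must align")
    if (any(d$probs < 0) || abs(sum(d$probs) - 1) > 1e-6)
      fail(paste0("demographics$", dim, "$probs"),
           "must be non-negative and sum to 1")
  }
  if (!is.finite(cfg$age$mean) || !is.finite(cfg$age$sd) || cfg$age$sd < 0)
    fail("age", "mean/sd must be finite with sd >= 0")
  ind <- cfg$indication
  if (length(ind$concepts) < 1L) fail("indication$concepts", "must be non-empty")
  if (length(ind$probs) != length(ind$concepts) || any(ind$probs < 0))
    fail("indication$probs", "must be non-negative and align with concepts")
  if (!is.finite(ind$prevalence) || ind$prevalence < 0 || ind$prevalence > 1)
    fail("indication$prevalence", "must be in [0, 1]")
  for (nm in c("conditions", "drugs", "procedures", "post_index")) {
    p <- cfg[[nm]]$prevalence
    if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > 1)))
      fail(paste0(nm, "$prevalence"), "must be in [0, 1]")
  }
  ms <- cfg$measurements
  if (nrow(ms)) {
    if (any(!is.finite(ms$mean)) || any(!is.finite(ms$sd)) || any(ms$sd < 0))
      fail("measurements$sd", "mean/sd must be finite with sd >= 0")
    if (any(ms$record_prob < 0) || any(ms$record_prob > 1))
      fail("measurements$record_prob", "must be in [0, 1]")
  }
  if (!is.null(cfg$correlation)) {
    k <- nrow(ms)
    if (!is.matrix(cfg$correlation) || !all(dim(cfg$correlation) == k))
      fail("correlation", "must be a square matrix matching measurements")
  }
  invisible(cfg)
}

# Inverse-CDF truncated normal; z is N(0,1) (possibly copula-correlated).
rtruncnorm_from_z <- function(z, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, length(z)))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::pnorm(z)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Generate a synthetic patient database
#'
#' Simulates persons and their longitudinal records from a
#' [population_config()]. For each indicated person a single indication
#' event is placed at the index/reference date (drawn uniformly so that at
#' least a year of lookback exists inside the observation window); history
#' events fall strictly before that date, post-index events strictly after,
#' and each recorded measurement is taken within the year before it.
#' Measurement values are truncated normal, rounded to two decimals.
#'
#' Output is deterministic given `(config, seed)` down to the written text
#' tables, and passes [validate_database()] by construction. The global
#' random-number state is left untouched.
#'
#' @param config a [population_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param vocabulary vocabulary to embed; defaults to [toy_vocabulary()].
#' @return A [patient_db()].
#' @export
generate_population <- function(config, seed = config$seed,
                                vocabulary = toy_vocabulary()) {
  stopifnot(inherits(config, "population_config"))
  validate_population_config(config)
  all_concepts <- c(config$indication$concepts, config$conditions$concept,
                    config$drugs$concept, config$procedures$concept,
                    config$post_index$concept, config$measurements$concept,
                    config$demographics$gender$levels,
                    config$demographics$race$levels)
  assert_known_concepts(vocabulary, all_concepts)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  n <- as.integer(config$n_persons)
  obs_start <- as.Date(config$observation$start)
  obs_end <- as.Date(config$observation$end)
  if (obs_end - obs_start < 730)
    stop("invalid config field `observation`: window must span >= 730 days")

  person_id <- sprintf("P%06d", seq_len(n))
  gender <- sample(config$demographics$gender$levels, n, replace = TRUE,
                   prob = config$demographics$gender$probs)
  race <- sample(config$demographics$race$levels, n, replace = TRUE,
                 prob = config$demographics$race$probs)
  has_ind <- stats::runif(n) < config$indication$prevalence
  ind_concept <- sample(rep(config$indication$concepts, 2), n, replace = TRUE,
                        prob = rep(config$indication$probs, 2))

  # reference date: index for indicated persons; same construction for the
  # rest so their history events and birth years are anchored identically
  span <- as.integer(obs_end - obs_start) - 395L
  ref <- obs_start + 365L + floor(stats::runif(n) * (span + 1L))

  amin <- if (is.null(config$age$min)) -Inf else config$age$min
  amax <- if (is.null(config$age$max)) Inf else config$age$max
  age <- round(rtruncnorm_from_z(stats::rnorm(n), config$age$mean,
                                 config$age$sd, amin, amax))
  birth_year <- as.integer(format(ref, "%Y")) - as.integer(age)

  persons <- data.frame(person_id = person_id, birth_year = birth_year,
                        gender_concept = gender, race_concept = race,
                        ethnicity_concept = "R_UNKNOWN",
                        observation_start = obs_start,
                        observation_end = obs_end)

  ev <- list()
  emit <- function(pid, concept, date, value = NA_real_) {
    ev[[length(ev) + 1L]] <<- data.frame(
      person_id = pid, concept_id = concept, event_date = date, value = value)
  }
  if (any(has_ind))
    emit(person_id[has_ind], ind_concept[has_ind], ref[has_ind])

  history <- rbind(config$conditions, config$drugs, config$procedures)
  for (i in seq_len(nrow(history))) {
    sel <- stats::runif(n) < history$prevalence[i]
    if (!any(sel)) next
    back <- as.integer(ref[sel] - obs_start)      # >= 365 by construction
    offset <- 1L + floor(stats::runif(sum(sel)) * (back - 1L))
    emit(person_id[sel], history$concept[i], ref[sel] - offset)
  }
  for (i in seq_len(nrow(config$post_index))) {
    sel <- stats::runif(n) < config$post_index$prevalence[i]
    if (!any(sel)) next
    fwd <- as.integer(obs_end - ref[sel])
    offset <- 1L + floor(stats::runif(sum(sel)) * (fwd - 1L))
    emit(person_id[sel], config$post_index$concept[i], ref[sel] + offset)
  }

  ms <- config$measurements
  k <- nrow(ms)
  if (k) {
    z <- matrix(stats::rnorm(n * k), n, k)
    if (!is.null(config$correlation)) {
      z <- z %*% chol(config$correlation)
    }
    for (i in seq_len(k)) {
      sel <- stats::runif(n) < ms$record_prob[i]
      if (!any(sel)) next
      val <- round(rtruncnorm_from_z(z[sel, i], ms$mean[i], ms$sd[i],
                                     ms$lower[i], ms$upper[i]), 2)
      lag <- floor(stats::runif(sum(sel)) * 366L)   # within a year pre-index
      emit(person_id[sel], ms$concept[i], ref[sel] - lag, val)
    }
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(person_id = character(0), concept_id = character(0),
               event_date = as.Date(character(0)), value = numeric(0))
  events <- events[order(events$person_id, events$event_date,
                         events$concept_id), , drop = FALSE]
  patient_db(persons, events, vocabulary)
}
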