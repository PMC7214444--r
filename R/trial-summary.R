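#' Pool a discrete baseline characteristic across two trial arms
#'
#' Counts are summed across the arms and expressed as a percent of the
#' combined arm sizes.
#'
#' @param count_arm1,count_arm2 event counts in each arm.
#' @param n_arm1,n_arm2 arm sizes.
#' @return Pooled percent in `[0, 100]`, at full precision (display rounding
#'   is left to the caller).
#' @examples
#' pool_discrete(93, 77, 197, 191)    # 43.81 % male
#' @export
pool_discrete <- function(count_arm1, count_arm2, n_arm1, n_arm2) {
  if ((n_arm1 + n_arm2) == 0) stop("undefined: combined arm size is zero")
  if (any(c(count_arm1, count_arm2) < 0) ||
      count_arm1 > n_arm1 || count_arm2 > n_arm2)
    stop("counts must be non-negative and no larger than the arm sizes")
  100 * (count_arm1 + count_arm2) / (n_arm1 + n_arm2)
}

#' Pool a continuous baseline characteristic across two trial arms
#'
#' The arm means (or medians, see note) are averaged with weights equal to
#' the proportion of patients in each arm. When the arm statistics are
#' medians the result is a weighted average of medians, not a median; it is
#' still the pooled value the comparison uses, flagged `median_average`
#' downstream.
#'
#' @param mean_arm1,mean_arm2 per-arm means (or medians).
#' @param n_arm1,n_arm2 arm sizes (>= 1).
#' @return Weighted mean `(n1*m1 + n2*m2) / (n1 + n2)`.
#' @examples
#' pool_continuous(70.6, 70.8, 197, 191)  # 70.70 years
#' @export
pool_continuous <- function(mean_arm1, mean_arm2, n_arm1, n_arm2) {
  if (n_arm1 < 1 || n_arm2 < 1) stop("arm sizes must be >= 1")
  (n_arm1 * mean_arm1 + n_arm2 * mean_arm2) / (n_arm1 + n_arm2)
}

#' Load a trial baseline-characteristics transcription
#'
#' Reads a JSON trial specification (two arms with sizes; per-characteristic
#' per-arm counts or means; the printed pooled column and sigma column as
#' strings preserving their decimal places; the printed observational-cohort
#' columns) and validates its invariants: exactly two arms, counts within
#' arm sizes, sigma non-negative, percents within `[0, 100]`.
#'
#' @param path path to a trial JSON file; see [packaged_trials()] for the
#'   four shipped transcriptions.
#' @return An object of class `trial_summary`.
#' @export
load_trial_spec <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  perr <- function(field, why) stop("trial spec parse error at ", field, ": ",
                                    why, " [", path, "]")
  if (is.null(doc$trial_id)) perr("trial_id", "missing")
  if (length(doc$arms) != 2L)
    perr("arms", paste0("expected exactly 2 arms, found ", length(doc$arms)))
  for (i in 1:2) {
    if (is.null(doc$arms[[i]]$n) || doc$arms[[i]]$n < 1)
      perr(paste0("arms[", i, "]$n"), "missing or < 1")
  }
  n1 <- doc$arms[[1]]$n; n2 <- doc$arms[[2]]$n
  for (r in doc$characteristics) {
    at <- paste0("characteristics[", r$name, "]")
    if (is.null(r$name) || is.null(r$data_type) || is.null(r$value_type))
      perr(at, "name, data_type and value_type are required")
    if (!is.null(r$sigma) && as.numeric(r$sigma) < 0)
      perr(paste0(at, "$sigma"), "sigma must be >= 0")
    if (r$value_type == "count" && !is.null(r$arm_values)) {
      a <- unlist(r$arm_values)
      if (length(a) != 2L) perr(paste0(at, "$arm_values"), "need one count per arm")
      if (a[1] > n1 || a[2] > n2 || any(a < 0))
        perr(paste0(at, "$arm_values"), "counts must lie in [0, arm n]")
    }
    for (side in c("indication_only", "with_criteria")) {
      v <- r[[side]]$value
      if (is.numeric(v) && r$data_type == "discrete" && (v < 0 || v > 100))
        perr(paste0(at, "$", side), "percent outside [0, 100]")
    }
  }
  structure(list(trial_id = doc$trial_id, label = doc$label,
                 arms = doc$arms, cohorts = doc$cohorts,
                 characteristics = doc$characteristics),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("<trial_summary> %s\n  arms: %s (n=%d) vs %s (n=%d); %d characteristics\n",
              x$trial_id, x$arms[[1]]$name, x$arms[[1]]$n,
              x$arms[[2]]$name, x$arms[[2]]$n, length(x$characteristics)))
  invisible(x)
}

#' Pooled trial values for every characteristic
#'
#' Recomputes the trial's pooled column from the per-arm transcription:
#' discrete rows via [pool_discrete()] on the arm counts (rows transcribed
#' as arm percents are converted to implied counts by rounding, with a
#' lossy-input warning; rows with no per-arm data fall back to the printed
#' pooled value), continuous rows via [pool_continuous()] on the arm means.
#'
#' @param trial a `trial_summary`.
#' @return data.frame with columns `characteristic`, `group`, `kind`,
#'   `data_type`, `value` (full precision), `value_kind` (`percent`,
#'   `mean` or `median_average`), `sigma`, `pooled_printed`.
#' @export
pooled_values <- function(trial) {
  stopifnot(inherits(trial, "trial_summary"))
  n1 <- trial$arms[[1]]$n; n2 <- trial$arms[[2]]$n
  rows <- lapply(trial$characteristics, function(r) {
    a <- if (is.null(r$arm_values)) NULL else unlist(r$arm_values)
    if (r$data_type == "discrete") {
      if (is.null(a)) {
        value <- as.numeric(r$pooled_printed)
      } else if (r$value_type == "percent") {
        warning("arm percents converted to implied counts for ", r$name,
                " (lossy input)", call. = FALSE)
        value <- pool_discrete(round(a[1] * n1 / 100), round(a[2] * n2 / 100),
                               n1, n2)
      } else {
        value <- pool_discrete(a[1], a[2], n1, n2)
      }
      kind_v <- "percent"
    } else {
      value <- if (is.null(a)) as.numeric(r$pooled_printed)
      else pool_continuous(a[1], a[2], n1, n2)
      kind_v <- if (isTRUE(r$median)) "median_average" else "mean"
    }
    data.frame(characteristic = r$name, group = r$group %||% NA_character_,
               kind = r$kind, data_type = r$data_type, value = value,
               value_kind = kind_v,
               sigma = if (is.null(r$sigma)) NA_real_ else as.numeric(r$sigma),
               pooled_printed = r$pooled_printed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Printed observational-cohort column of a trial transcription
#'
#' Convenience accessor for the cohort values and discrepancy cells printed
#' alongside each trial table, used to reproduce the discrete-delta cells
#' and to parameterize the synthetic generator.
#'
#' @param trial a `trial_summary`.
#' @param cohort `"indication_only"` or `"with_criteria"`.
#' @return data.frame with columns `characteristic`, `kind`, `data_type`,
#'   `value` (NA where the table prints NED or leaves the cell blank),
#'   `ned`, `delta_printed`, `delta_consistent` (FALSE where the printed
#'   delta cell cannot be reproduced from the row's own printed values).
#' @export
cohort_column <- function(trial, cohort = c("indication_only", "with_criteria")) {
  stopifnot(inherits(trial, "trial_summary"))
  cohort <- match.arg(cohort)
  flag <- paste0("delta_", cohort, "_consistent")
  rows <- lapply(trial$characteristics, function(r) {
    cell <- r[[cohort]]
    ned <- identical(cell$value, "NED")
    val <- if (is.numeric(cell$value)) cell$value else NA_real_
    data.frame(characteristic = r$name, kind = r$kind,
               data_type = r$data_type, value = val, ned = ned,
               delta_printed = if (is.numeric(cell$delta)) cell$delta else NA_real_,
               delta_consistent = r[[flag]] %||% NA)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged trial transcriptions
#'
#' @return Character vector of the four packaged trial identifiers.
#' @export
packaged_trials <- function() {
  c("sitagliptin_glimepiride", "prove_it", "renaal", "accomplish")
}

#' Load a packaged trial transcription or cohort definition
#'
#' @param trial_id one of [packaged_trials()].
#' @return `load_trial()` returns a `trial_summary`;
#'   `load_definition()` a [cohort_definition()].
#' @export
load_trial <- function(trial_id) {
  trial_id <- match.arg(trial_id, packaged_trials())
  load_trial_spec(system.file("extdata", "trials",
                              paste0(trial_id, ".json"),
                              package = "trialconcord", mustWork = TRUE))
}

#' @rdname load_trial
#' @export
load_definition <- function(trial_id) {
  trial_id <- match.arg(trial_id, packaged_trials())
  read_cohort_definition(system.file("extdata", "definitions",
                                     paste0(trial_id, ".yaml"),
                                     package = "trialconcord", mustWork = TRUE))
}
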