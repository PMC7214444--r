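#' Percentage-point discrepancy for a discrete characteristic
#'
#' The cohort-minus-trial difference in percentage points, expressed as a
#' signed proportion (percentage points / 100). Zero means the
#' observational cohort does not differ from the pooled trial value;
#' antisymmetric in its arguments.
#'
#' @param cohort_percent,rct_pooled_percent percents in `[0, 100]`.
#' @return Signed proportion (full precision; tables display 3 decimals).
#' @examples
#' delta_discrete(35.87, 43.8)   # -0.0793: cohort has fewer males
#' @export
delta_discrete <- function(cohort_percent, rct_pooled_percent) {
  if (any(c(cohort_percent, rct_pooled_percent) < 0) ||
      any(c(cohort_percent, rct_pooled_percent) > 100))
    stop("percents must lie in [0, 100]")
  (cohort_percent - rct_pooled_percent) / 100
}

#' Standardized mean discrepancy for a continuous characteristic
#'
#' The cohort-minus-trial difference in means divided by a scale. The
#' default scale is the symmetric two-sample form
#' `sqrt((sigma_rct^2 + cohort_sd^2) / 2)`; `denominator = "rct"` divides
#' by the trial's pooled sigma alone. The statistic is antisymmetric in the
#' two means and invariant under a common affine rescaling of means and
#' SDs.
#'
#' @param cohort_mean,cohort_sd observational cohort mean and SD.
#' @param rct_pooled_mean,sigma_rct pooled trial mean and printed sigma.
#' @param denominator `"pooled"` (default) or `"rct"`.
#' @return Signed standardized difference.
#' @export
delta_continuous <- function(cohort_mean, cohort_sd, rct_pooled_mean,
                             sigma_rct, denominator = c("pooled", "rct")) {
  denominator <- match.arg(denominator)
  scale <- if (denominator == "pooled") {
    if (is.na(cohort_sd) || is.na(sigma_rct))
      stop("pooled denominator requires both cohort_sd and sigma_rct")
    sqrt((sigma_rct^2 + cohort_sd^2) / 2)
  } else {
    if (is.na(sigma_rct)) stop("rct denominator requires sigma_rct")
    sigma_rct
  }
  if (!is.finite(scale) || scale <= 0)
    stop("undefined standardized difference: zero or invalid denominator")
  (cohort_mean - rct_pooled_mean) / scale
}

#' Reconstructed significance test for one comparison row
#'
#' The source analysis reports p-values without naming a test; this is a
#' labeled reconstruction, not a reproduction. Continuous characteristics
#' use a two-sided one-sample z-test of the cohort mean against the pooled
#' trial mean with scale `sigma_rct / sqrt(n)`; discrete ones a two-sided
#' one-proportion z-test against the pooled trial proportion.
#'
#' @param data_type `"continuous"` or `"discrete"`.
#' @param cohort_value cohort mean or percent.
#' @param rct_pooled pooled trial mean or percent.
#' @param sigma_rct pooled trial SD (continuous only).
#' @param cohort_n cohort size.
#' @return p-value, or `NA` for degenerate inputs (n < 2, sigma <= 0,
#'   boundary proportions).
#' @export
significance_test <- function(data_type, cohort_value, rct_pooled,
                              sigma_rct = NA, cohort_n) {
  if (is.na(cohort_value) || is.na(rct_pooled) || is.na(cohort_n) ||
      cohort_n < 2)
    return(NA_real_)
  if (data_type == "continuous") {
    if (is.na(sigma_rct) || sigma_rct <= 0) return(NA_real_)
    z <- (cohort_value - rct_pooled) / (sigma_rct / sqrt(cohort_n))
  } else {
    p0 <- rct_pooled / 100
    if (p0 <= 0 || p0 >= 1) return(NA_real_)
    z <- (cohort_value / 100 - p0) / sqrt(p0 * (1 - p0) / cohort_n)
  }
  2 * stats::pnorm(-abs(z))
}

#' Compare a cohort summary against a trial's pooled baseline table
#'
#' Produces one comparison row per characteristic shared between the trial
#' transcription and the cohort summary, in the trial's row order: the
#' pooled trial value, the cohort value, and the discrepancy
#' (percentage-point difference / 100 for discrete rows, standardized mean
#' difference for continuous rows). NED cohort entries yield rows with the
#' delta absent. Characteristics present on only one side are reported in a
#' warning (use `strict = TRUE` to make that an error).
#'
#' @param trial a `trial_summary` (or trial id).
#' @param cohort_summary a [summarize_cohort()] result. Continuous rows
#'   use its `sd` column for the default symmetric denominator.
#' @param cohort_label label recorded on the result.
#' @param denominator passed to [delta_continuous()].
#' @param significance add reconstructed p-values?
#' @param cohort_n cohort size for the significance reconstruction
#'   (defaults to the summary's `n` attribute).
#' @param strict error (rather than warn) on unmatched characteristics.
#' @return A `trial_concordance` data.frame: `characteristic`, `group`,
#'   `data_type`, `value_kind`, `rct_pooled`, `sigma_rct`, `cohort_value`,
#'   `cohort_sd`, `delta`, `ned`, and with `significance = TRUE`
#'   `p_value` + `method`.
#' @export
compare_trial <- function(trial, cohort_summary, cohort_label = "cohort",
                          denominator = c("pooled", "rct"),
                          significance = FALSE,
                          cohort_n = attr(cohort_summary, "n"),
                          strict = FALSE) {
  if (is.character(trial)) trial <- load_trial(trial)
  stopifnot(inherits(trial, "trial_summary"), is.data.frame(cohort_summary))
  denominator <- match.arg(denominator)
  pooled <- pooled_values(trial)
  pooled <- pooled[pooled$kind != "excluded", , drop = FALSE]
  shared <- intersect(pooled$characteristic, cohort_summary$characteristic)
  offenders <- c(setdiff(pooled$characteristic, shared),
                 setdiff(cohort_summary$characteristic, shared))
  if (length(offenders)) {
    msg <- paste("unmatched characteristic names:",
                 paste(offenders, collapse = ", "))
    if (strict) stop("alignment error: ", msg) else warning(msg, call. = FALSE)
  }
  if (!length(shared)) stop("alignment error: no shared characteristics")
  pooled <- pooled[match(shared, pooled$characteristic), , drop = FALSE]
  cs <- cohort_summary[match(shared, cohort_summary$characteristic), , drop = FALSE]

  delta <- mapply(function(dt, cv, csd, rv, sig, ned) {
    if (ned || is.na(cv)) return(NA_real_)
    if (dt == "discrete") return(delta_discrete(cv, rv))
    # rows with no printed trial sigma fall back to the cohort SD alone;
    # rows with no computable scale at all get no delta rather than an error
    if (denominator == "pooled" && is.na(sig) && !is.na(csd))
      return((cv - rv) / csd)
    if (is.na(sig) || (denominator == "pooled" && is.na(csd)))
      return(NA_real_)
    delta_continuous(cv, csd, rv, sig, denominator)
  }, pooled$data_type, cs$value, cs$sd, pooled$value, pooled$sigma, cs$ned)

  out <- data.frame(characteristic = shared, group = pooled$group,
                    data_type = pooled$data_type,
                    value_kind = pooled$value_kind,
                    rct_pooled = pooled$value, sigma_rct = pooled$sigma,
                    cohort_value = cs$value, cohort_sd = cs$sd,
                    delta = as.numeric(delta), ned = cs$ned)
  if (significance) {
    out$p_value <- mapply(significance_test, out$data_type, out$cohort_value,
                          out$rct_pooled, out$sigma_rct,
                          MoreArgs = list(cohort_n = cohort_n))
    out$method <- ifelse(is.na(out$p_value), NA_character_,
                         ifelse(out$data_type == "continuous",
                                "reconstructed one-sample z-test",
                                "reconstructed one-proportion z-test"))
  }
  rownames(out) <- NULL
  attr(out, "trial_id") <- trial$trial_id
  attr(out, "cohort_label") <- cohort_label
  attr(out, "denominator") <- denominator
  class(out) <- c("trial_concordance", "data.frame")
  out
}

#' @export
print.trial_concordance <- function(x, ...) {
  cat(sprintf("<trial_concordance> %s vs %s (continuous denominator: %s)\n",
              attr(x, "trial_id"), attr(x, "cohort_label"),
              attr(x, "denominator")))
  y <- as.data.frame(x)
  y$rct_pooled <- round(y$rct_pooled, 2)
  y$cohort_value <- round(y$cohort_value, 2)
  y$cohort_sd <- round(y$cohort_sd, 2)
  y$delta <- round(y$delta, 3)     # tables print deltas to 3 decimals
  if (!is.null(y$p_value)) y$p_value <- signif(y$p_value, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Paired discrepancies with and without eligibility criteria
#'
#' Inner-joins two comparison tables from the same trial (typically the
#' Indication-Only and Indication + Eligibility-Criteria cohorts) on
#' characteristic, yielding one point per characteristic for the paired
#' discrepancy plot. Rows whose delta is absent on either side (NED or
#' excluded characteristics) are dropped with a message.
#'
#' @param rows_indication,rows_with_criteria two [compare_trial()] results
#'   for the same trial.
#' @return A `paired_deltas` data.frame: `characteristic`, `data_type`,
#'   `marker` (`circle_continuous` / `plus_discrete`),
#'   `delta_indication_only`, `delta_with_criteria`.
#' @seealso [plot.paired_deltas()]
#' @export
figure1_pairs <- function(rows_indication, rows_with_criteria) {
  stopifnot(is.data.frame(rows_indication), is.data.frame(rows_with_criteria))
  shared <- intersect(rows_indication$characteristic,
                      rows_with_criteria$characteristic)
  only <- c(setdiff(rows_indication$characteristic, shared),
            setdiff(rows_with_criteria$characteristic, shared))
  if (length(only))
    message("dropped (present in one cohort only): ",
            paste(only, collapse = ", "))
  a <- rows_indication[match(shared, rows_indication$characteristic), ]
  b <- rows_with_criteria[match(shared, rows_with_criteria$characteristic), ]
  keep <- !is.na(a$delta) & !is.na(b$delta)
  if (any(!keep))
    message("dropped (no computable delta): ",
            paste(shared[!keep], collapse = ", "))
  out <- data.frame(characteristic = shared[keep],
                    data_type = a$data_type[keep],
                    marker = ifelse(a$data_type[keep] == "continuous",
                                    "circle_continuous", "plus_discrete"),
                    delta_indication_only = a$delta[keep],
                    delta_with_criteria = b$delta[keep])
  rownames(out) <- NULL
  attr(out, "trial_id") <- attr(rows_indication, "trial_id")
  class(out) <- c("paired_deltas", "data.frame")
  out
}

#' Paired discrepancy plot
#'
#' One point per baseline characteristic: the discrepancy of the
#' Indication-Only cohort from the trial (x) against the discrepancy of the
#' Indication + Eligibility-Criteria cohort (y). Circles mark standardized
#' mean differences of continuous characteristics, pluses percentage-point
#' differences of discrete ones. Points near the origin indicate cohorts
#' close to the trial; points on the 45-degree line indicate
#' characteristics unaffected by the eligibility criteria.
#'
#' @param x a [figure1_pairs()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.paired_deltas <- function(x, ...) {
  lim <- range(0, x$delta_indication_only, x$delta_with_criteria)
  lim <- lim + 0.05 * c(-1, 1) * diff(lim)
  graphics::plot(x$delta_indication_only, x$delta_with_criteria,
                 pch = ifelse(x$data_type == "continuous", 1L, 3L),
                 xlim = lim, ylim = lim, asp = 1,
                 xlab = "delta, indication only",
                 ylab = "delta, with eligibility criteria",
                 main = attr(x, "trial_id") %||% "", ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  graphics::abline(h = 0, v = 0, col = "grey85")
  graphics::legend("topleft", pch = c(1L, 3L), bty = "n",
                   legend = c("continuous (standardized)",
                              "discrete (percentage points / 100)"))
  invisible(x)
}
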