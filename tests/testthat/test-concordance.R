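test_that("discrete delta is the signed percentage-point difference over 100", {
  expect_equal(round(delta_discrete(35.87, 43.8), 3), -0.079)   # male
  expect_equal(round(delta_discrete(5.40, 63.71), 3), -0.583)   # retinopathy
  expect_equal(delta_discrete(12.34, 12.34), 0)
  expect_error(delta_discrete(101, 50), "\\[0, 100\\]")
  # antisymmetry over random pairs
  set.seed(2)
  for (i in 1:20) {
    a <- stats::runif(1, 0, 100); b <- stats::runif(1, 0, 100)
    expect_equal(delta_discrete(a, b), -delta_discrete(b, a))
  }
})

test_that("continuous delta is standardized, antisymmetric and affine-invariant", {
  expect_equal(delta_continuous(10, 2, 10, 2), 0)
  expect_equal(delta_continuous(12, 3, 10, 3), 2 / 3)   # (m+d, s, m, s) = d/s
  set.seed(3)
  for (i in 1:20) {
    m1 <- stats::rnorm(1, 50, 10); m2 <- stats::rnorm(1, 50, 10)
    s1 <- stats::runif(1, 1, 5); s2 <- stats::runif(1, 1, 5)
    d <- delta_continuous(m1, s1, m2, s2)
    expect_equal(d, -delta_continuous(m2, s2, m1, s1))
    a <- stats::rnorm(1); b <- stats::runif(1, 0.1, 4)
    expect_equal(delta_continuous(a + b * m1, b * s1, a + b * m2, b * s2), d)
  }
  expect_error(delta_continuous(1, 0, 2, 0), "zero")
  expect_equal(delta_continuous(12, 99, 10, 4, denominator = "rct"), 0.5)
})

test_that("reconstructed significance matches an independent normal-tail computation", {
  # cohort mean equal to the trial mean: p = 1
  expect_equal(significance_test("continuous", 70, 70, 5, 100), 1.0)
  # one-sigma shift at n = 100: z = 10
  p <- significance_test("continuous", 71, 70, 1, 100)
  expect_equal(p, oracle_normal_p(10), tolerance = 1e-12)
  p2 <- significance_test("discrete", 55, 50, NA, 100)
  expect_equal(p2, oracle_normal_p(0.05 / sqrt(0.5 * 0.5 / 100)),
               tolerance = 1e-9)
  expect_true(is.na(significance_test("continuous", 70, 71, 5, 1)))
  expect_true(is.na(significance_test("discrete", 1, 0, NA, 50)))
})

test_that("comparison rows align to the trial, flag NED, and zero out at equality", {
  trial <- load_trial("accomplish")
  pv <- pooled_values(trial)
  pv <- pv[pv$kind != "excluded", ]
  # a cohort summary numerically equal to the pooled trial values
  cs <- data.frame(characteristic = pv$characteristic, group = pv$group,
                   kind = pv$kind, data_type = pv$data_type,
                   value = pv$value, sd = ifelse(is.na(pv$sigma), 1, pv$sigma),
                   n_recorded = 500L, ned = FALSE)
  attr(cs, "n") <- 500L
  conc <- compare_trial(trial, cs)
  expect_equal(nrow(conc), nrow(pv))
  expect_true(all(abs(conc$delta) < 1e-12))
  # NED rows keep their place but carry no delta
  cs$ned[cs$characteristic == "weight"] <- TRUE
  cs$value[cs$characteristic == "weight"] <- NA
  conc2 <- compare_trial(trial, cs)
  expect_true(is.na(conc2$delta[conc2$characteristic == "weight"]))
  # unmatched names warn (and error when strict)
  expect_warning(compare_trial(trial, cs[-1, ]), "unmatched")
  expect_error(suppressWarnings(compare_trial(trial, cs[-1, ], strict = TRUE)),
               "alignment")
})

test_that("paired deltas join on characteristic and drop non-computable rows", {
  trial <- load_trial("accomplish")
  specs_names <- sapply(pooled_values(trial)$characteristic, identity)
  col_ind <- cohort_column(trial, "indication_only")
  col_ec <- cohort_column(trial, "with_criteria")
  mk <- function(col, label) {
    pv <- pooled_values(trial); pv <- pv[pv$kind != "excluded", ]
    col <- col[match(pv$characteristic, col$characteristic), ]
    cs <- data.frame(characteristic = pv$characteristic, group = pv$group,
                     kind = pv$kind, data_type = pv$data_type,
                     value = col$value, sd = NA_real_, n_recorded = 100L,
                     ned = col$ned)
    attr(cs, "n") <- 100L
    compare_trial(trial, cs, cohort_label = label)
  }
  ci <- mk(col_ind, "ind"); ce <- mk(col_ec, "ec")
  expect_message(pairs <- figure1_pairs(ci, ce), "no computable delta")
  # the printed female cell pair for this trial
  f <- pairs[pairs$characteristic == "female", ]
  expect_equal(round(f$delta_indication_only, 3), 0.283)
  expect_equal(round(f$delta_with_criteria, 3), 0.309)
  expect_equal(f$marker, "plus_discrete")
  # NED rows (waist, eGFR) are excluded from the pairing
  expect_false(any(pairs$characteristic %in% c("waist_circumference", "egfr")))
  # identical inputs land on the 45-degree line
  on_line <- figure1_pairs(ci, ci)
  expect_equal(on_line$delta_indication_only, on_line$delta_with_criteria)
  # a characteristic present on one side only is dropped with a message
  expect_message(p2 <- figure1_pairs(ci[-1, ], ce), "one cohort only")
  expect_false(ci$characteristic[1] %in% p2$characteristic)
  # plotting works headlessly
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(pairs))
})
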