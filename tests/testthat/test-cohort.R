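meds <- c("risperidone", "olanzapine")

test_that("eligibility filters apply in a fixed order with audit counts", {
  res <- apply_eligibility(toy_records(), meds, rare_min = 1)
  # ages 75 and 15 go first, then clozapine, then the inpatient start
  expect_equal(unname(res$exclusions),
               c(2L, 1L, 1L, 0L))
  expect_equal(names(res$exclusions),
               c("age", "second_line", "inpatient_rx", "rare_drug"))
  expect_setequal(res$records$patient_id, c(1L, 6L))

  # idempotence
  res2 <- apply_eligibility(res$records, meds, rare_min = 1)
  expect_identical(res2$records, res$records)
  expect_true(all(res2$exclusions == 0L))

  # rare-drug minimum: both surviving drugs have a single recipient
  res3 <- apply_eligibility(toy_records(), meds, rare_min = 2)
  expect_equal(unname(res3$exclusions["rare_drug"]), 2L)
  expect_equal(nrow(res3$records), 0)

  # empty input and empty medication list
  empty <- apply_eligibility(toy_records()[0, ], meds, rare_min = 1)
  expect_equal(nrow(empty$records), 0)
  expect_true(all(empty$exclusions == 0L))
  expect_error(apply_eligibility(toy_records(), character()), "empty")
})

test_that("outcome labeling follows the primary definition", {
  ev <- function(type, month) data.frame(patient_id = 1L, type = type,
                                         month = month)
  lab <- function(events, def = outcome_definition()) {
    unname(label_outcome(events, 1L, def))
  }
  expect_equal(lab(ev("hospitalization_other", 6)), 0L)
  expect_equal(lab(ev("hospitalization_psychiatric", 1)), 0L)
  expect_equal(lab(ev("med_switch", 11.9)), 0L)
  expect_equal(lab(ev("inpatient_death", 3)), 0L)
  # discontinuation is not a failure under the primary definition
  expect_equal(lab(ev("discontinuation", 4)), 1L)
  # events at month 0 are pre-index, window is half-open (0, 12]
  expect_equal(lab(ev("med_switch", 0)), 1L)
  expect_equal(lab(ev("med_switch", 12)), 0L)
  # empty stream succeeds under every variant
  none <- data.frame(patient_id = integer(), type = character(),
                     month = numeric())
  for (v in c("primary", "psych_hosp_or_change", "psych_hosp_only",
              "change_only", "primary_plus_discontinuation")) {
    expect_equal(lab(none, outcome_definition(v)), 1L)
  }
  expect_error(lab(ev("transplant", 3)), "unknown event type")
})

test_that("sensitivity variants widen or narrow the failure set as documented", {
  ev <- function(type, month) data.frame(patient_id = 1L, type = type,
                                         month = month)
  lab <- function(events, v, w = c(3, 9)) {
    unname(label_outcome(events, 1L, outcome_definition(v, w)))
  }
  # non-psychiatric hospitalization ignored by the narrower variants
  expect_equal(lab(ev("hospitalization_other", 5), "psych_hosp_or_change"), 1L)
  expect_equal(lab(ev("hospitalization_other", 5), "psych_hosp_only"), 1L)
  expect_equal(lab(ev("med_switch", 5), "psych_hosp_only"), 1L)
  expect_equal(lab(ev("med_switch", 5), "change_only"), 0L)
  expect_equal(lab(ev("hospitalization_psychiatric", 5), "change_only"), 1L)
  # discontinuation window variant
  expect_equal(lab(ev("discontinuation", 4), "primary_plus_discontinuation"), 0L)
  expect_equal(lab(ev("discontinuation", 10), "primary_plus_discontinuation"), 1L)
  expect_error(outcome_definition("primary_plus_discontinuation",
                                  c(9, 3)), "start < end")
})

test_that("variant failure sets obey the documented subset relations", {
  coh <- simulate_cohort(default_sim_config(n_patients = 2000, seed = 21))
  ids <- coh$data$patient_id
  y <- list()
  for (v in c("primary", "psych_hosp_or_change", "psych_hosp_only",
              "change_only", "primary_plus_discontinuation")) {
    y[[v]] <- label_outcome(coh$events, ids, outcome_definition(v))
  }
  # failing a narrow variant implies failing the primary
  expect_true(all(y$primary[y$psych_hosp_only == 0] == 0))
  expect_true(all(y$primary[y$change_only == 0] == 0))
  expect_true(all(y$primary[y$psych_hosp_or_change == 0] == 0))
  # primary failures are a subset of primary-plus-discontinuation failures
  expect_true(all(y$primary_plus_discontinuation[y$primary == 0] == 0))
  # round trip against the generator's labels
  expect_equal(unname(y$primary), coh$data$y)
})

test_that("train/holdout split has the right sizes and balance", {
  s <- split_sample(10, 0.7, seed = 1)
  expect_equal(sum(s == "train"), 7)
  expect_equal(sum(s == "holdout"), 3)
  expect_identical(s, split_sample(10, 0.7, seed = 1))
  expect_false(identical(s, split_sample(10, 0.7, seed = 2)))
  expect_error(split_sample(1, 0.7), "at least 2")
  expect_error(split_sample(10, 1.0), "train_fraction")

  # covariate balance at n = 10^4
  x <- generate_covariates(default_sim_config(n_patients = 1e4, seed = 22))
  s <- split_sample(1e4, 0.7, seed = 23)
  tr <- s == "train"
  for (v in names(x)) {
    se <- stats::sd(x[[v]]) * sqrt(1 / sum(tr) + 1 / sum(!tr))
    expect_lt(abs(mean(x[[v]][tr]) - mean(x[[v]][!tr])), 4 * se)
  }
})
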