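test_that("covariate generation is deterministic, typed, and handles n = 0", {
  cfg <- default_sim_config(n_patients = 50, seed = 9)
  x1 <- generate_covariates(cfg)
  x2 <- generate_covariates(cfg)
  expect_identical(x1, x2)
  expect_equal(nrow(x1), 50)
  expect_true(all(c("age", "ed_visits", "benzodiazepine") %in% names(x1)))
  expect_true(all(x1$age >= 16 & x1$age <= 74))
  expect_true(all(x1$benzodiazepine %in% 0:1))
  expect_true(all(x1$ed_visits == floor(x1$ed_visits)))

  x0 <- generate_covariates(cfg, n = 0)
  expect_equal(nrow(x0), 0)
  expect_identical(names(x0), names(x1))
})

test_that("uniform age covariate has the closed-form mean", {
  cfg <- default_sim_config(n_patients = 1e5, seed = 2)
  x <- generate_covariates(cfg)
  # age ~ U(16, 74): mean 45, sd (74-16)/sqrt(12)
  se <- (74 - 16) / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(x$age) - 45), 3 * se)
})

test_that("configuration validation rejects bad inputs", {
  cfg <- default_sim_config(n_patients = 10)
  expect_error(sim_config(10, 1, cfg$covariate_spec,
                          cfg$propensity_coefficients,
                          cfg$outcome_coefficients), "n_arms")
  expect_error(default_sim_config(decoy_fraction = 2), "decoy_fraction")
  bad_spec <- cfg$covariate_spec
  bad_spec[[1]]$min <- 100 # uniform with min > max
  expect_error(sim_config(10, 5, bad_spec, cfg$propensity_coefficients,
                          cfg$outcome_coefficients), "min < max")
})

test_that("treatment assignment follows the softmax of linear scores", {
  cfg <- default_sim_config(n_patients = 2000, seed = 3)
  # all-zero coefficients: uniform propensities
  cfg0 <- cfg
  cfg0$propensity_coefficients[] <- 0
  x <- generate_covariates(cfg0)
  tr <- assign_treatments(cfg0, x)
  expect_true(all(abs(tr$true_propensities - 0.2) < 1e-12))

  # Monte-Carlo: empirical arm frequencies match mean true propensities
  cfg2 <- default_sim_config(n_patients = 1e5, seed = 4)
  x2 <- generate_covariates(cfg2)
  tr2 <- assign_treatments(cfg2, x2)
  expect_true(all(abs(rowSums(tr2$true_propensities) - 1) < 1e-10))
  pbar <- colMeans(tr2$true_propensities)
  freq <- tabulate(tr2$arms, 5) / 1e5
  tol <- 3 * sqrt(pbar * (1 - pbar) / 1e5)
  expect_true(all(abs(freq - pbar) < tol))
})

test_that("simulated outcomes match their true success probabilities", {
  cfg <- default_sim_config(n_patients = 1e5, seed = 5)
  x <- generate_covariates(cfg)
  tr <- assign_treatments(cfg, x)
  out <- simulate_outcomes(cfg, x, tr$arms)
  expect_true(all(out$true_success_probs > 0 & out$true_success_probs < 1))
  for (a in 1:5) {
    ia <- tr$arms == a
    pa <- mean(out$true_success_probs[ia, a])
    se <- sqrt(pa * (1 - pa) / sum(ia))
    expect_lt(abs(mean(out$y[ia]) - pa), 3 * se)
  }
})

test_that("event streams are consistent with the simulated labels", {
  cfg <- default_sim_config(n_patients = 500, seed = 6)
  coh <- simulate_cohort(cfg)
  ev <- coh$events
  fail_types <- c("hospitalization_psychiatric", "hospitalization_other",
                  "med_switch", "med_addition", "inpatient_death")
  succ <- coh$data$patient_id[coh$data$y == 1]
  ev_succ <- ev[ev$patient_id %in% succ, ]
  expect_false(any(ev_succ$type %in% fail_types &
                     ev_succ$month > 0 & ev_succ$month <= 12))
  fails <- coh$data$patient_id[coh$data$y == 0]
  has_fail_event <- tapply(ev$type %in% fail_types & ev$month > 0 &
                             ev$month <= 12, ev$patient_id, any)
  expect_true(all(unlist(has_fail_event[as.character(fails)])))
})

test_that("homogeneous scenario collapses the success surface", {
  cfg <- default_sim_config(n_patients = 100, seed = 7, heterogeneity = 0)
  cfg$outcome_coefficients$arm_intercepts[] <- -0.2
  coh <- simulate_cohort(cfg)
  mu <- coh$truth$true_success_probs
  expect_true(all(abs(mu - mu[, 1]) < 1e-12))
})

test_that("decoy records carry exclusion labels of every class", {
  cfg <- default_sim_config(n_patients = 400, seed = 8, decoy_fraction = 0.2)
  raw <- generate_raw_records(cfg)
  rec <- raw$records
  expect_equal(sum(!rec$eligible), 80)
  expect_setequal(unique(rec$exclusion_class[!rec$eligible]),
                  c("age", "second_line", "inpatient_rx", "rare_drug"))
  age_decoys <- rec[!rec$eligible & rec$exclusion_class == "age", ]
  expect_true(all(age_decoys$age < 16 | age_decoys$age > 74))
  sl <- rec[!rec$eligible & rec$exclusion_class == "second_line", ]
  expect_true(all(sl$first_regimen %in%
                    c("clozapine", "polypharmacy", "long_acting_injectable")))
  # decoy_fraction = 0 emits only eligible records
  raw0 <- generate_raw_records(default_sim_config(n_patients = 50, seed = 8))
  expect_true(all(raw0$records$eligible))
})

test_that("oracle value dominates every other rule", {
  cfg <- default_sim_config(n_patients = 300, seed = 10)
  coh <- simulate_cohort(cfg)
  truth <- coh$truth
  expect_equal(oracle_rule_value(truth, truth$oracle_arm),
               truth$oracle_value)
  # uniform stochastic rule equals the grand mean of the surface
  unif <- make_rule("stochastic", weights = rep(0.2, 5))
  expect_equal(oracle_rule_value(truth, unif),
               mean(truth$true_success_probs))
  set.seed(11)
  for (r in 1:100) {
    rnd <- sample(1:5, 300, replace = TRUE)
    expect_lte(oracle_rule_value(truth, rnd), truth$oracle_value)
  }
  expect_error(oracle_rule_value(truth, rep(9L, 300)), "outside")
})

test_that("cohort simulation is seed-deterministic end to end", {
  cfg <- default_sim_config(n_patients = 200, seed = 12, decoy_fraction = 0.1)
  a <- generate_raw_records(cfg)
  b <- generate_raw_records(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
})
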