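# small helper: hand-built rule_value objects for arithmetic tests
rv <- function(value, ic) {
  structure(list(value = value, se = stats::sd(ic) / sqrt(length(ic)),
                 ci95 = c(NA, NA), influence_values = ic,
                 n = length(ic)), class = "rule_value")
}

test_that("TMLE solves the score equation and recovers exact identities", {
  set.seed(51)
  n <- 400
  y <- rbinom(n, 1, 0.45)
  # everyone received arm 1, rule = static(1), g = 1: value is the
  # sample mean exactly
  g <- matrix(1, n, 1)
  Q <- matrix(0.3, n, 1)
  est <- tmle_rule_value(y, rep(1L, n), rep(1L, n), g, Q)
  expect_equal(est$value, mean(y), tolerance = 1e-9)
  expect_lt(abs(est$score_residual), 1e-6)
  expect_lt(abs(mean(est$influence_values)), 1e-8)

  # if Q already solves the score equation the fluctuation is zero
  Q2 <- matrix(mean(y), n, 1)
  est2 <- tmle_rule_value(y, rep(1L, n), rep(1L, n), g, Q2)
  expect_equal(est2$epsilon, 0, tolerance = 1e-6)
  expect_equal(est2$value, mean(y), tolerance = 1e-9)
})

test_that("TMLE covers the oracle static-arm value on synthetic data", {
  coh <- simulate_cohort(default_sim_config(n_patients = 6000, seed = 52))
  d <- coh$data
  nuis <- holdout_nuisances(default_formula(), d, roster = light_roster(),
                            n_folds = 5, seed = 52)
  a <- 2L
  est <- tmle_rule_value(d$y, d$arm, rep(a, nrow(d)), nuis$g, nuis$Q)
  oracle <- mean(coh$truth$true_success_probs[, a])
  expect_lt(abs(est$value - oracle), 3 * est$se)
  expect_lt(abs(est$score_residual), 1e-6)
  expect_lt(abs(mean(est$influence_values)), 1e-8)
})

test_that("stochastic rule values combine linearly with their weights", {
  ic1 <- c(-0.1, 0.1, -0.2, 0.2)
  ic2 <- c(0.3, -0.3, 0.1, -0.1)
  e1 <- rv(0.4, ic1); e2 <- rv(0.6, ic2)
  comb <- stochastic_rule_value(list(e1, e2), c(0.5, 0.5))
  expect_equal(comb$value, 0.5)
  expect_equal(comb$influence_values, 0.5 * ic1 + 0.5 * ic2)
  # weight concentrated on one arm reproduces that arm's estimate
  solo <- stochastic_rule_value(list(e1, e2), c(1, 0))
  expect_equal(solo$value, e1$value)
  expect_equal(solo$se, e1$se)
  expect_error(stochastic_rule_value(list(e1, NULL), c(0.5, 0.5)),
               "no estimate")
})

test_that("uniform randomisation matches the oracle surface mean", {
  coh <- simulate_cohort(default_sim_config(n_patients = 6000, seed = 53))
  d <- coh$data
  nuis <- holdout_nuisances(default_formula(), d, roster = light_roster(),
                            n_folds = 5, seed = 53)
  unif <- evaluate_rule(make_rule("stochastic", weights = rep(0.2, 5)),
                        nuis)
  oracle <- mean(coh$truth$true_success_probs)
  expect_lt(abs(unif$value - oracle), 3 * unif$se)
})

test_that("observed success rate has the binomial standard error", {
  est <- observed_success_rate(c(1, 0, 1, 0))
  expect_equal(est$value, 0.5)
  expect_equal(est$se, sqrt(0.25 / 4))
  all1 <- observed_success_rate(rep(1, 10))
  expect_equal(all1$value, 1)
  expect_equal(all1$se, 0)
  # large synthetic holdout tracks the factual oracle value
  coh <- simulate_cohort(default_sim_config(n_patients = 20000, seed = 54))
  d <- coh$data
  est2 <- observed_success_rate(d$y)
  oracle <- mean(coh$truth$true_success_probs[cbind(seq_len(nrow(d)),
                                                    d$arm)])
  expect_lt(abs(est2$value - oracle), 3 * est2$se)
})

test_that("rule comparisons use the influence-curve contrast", {
  set.seed(55)
  ic <- rnorm(500, sd = 0.5)
  e1 <- rv(0.5, ic + rnorm(500, sd = 0.1))
  e2 <- rv(0.5, ic)
  cmp <- compare_rules(e1, e2)
  expect_equal(cmp$z, 0, tolerance = 1e-9)
  expect_equal(cmp$p_one_sided, 0.5, tolerance = 1e-9)
  # z = 1.645 gives one-sided p = 0.05
  dic <- rnorm(400)
  dic <- (dic - mean(dic)) / stats::sd(dic) # exact unit sd
  se <- 1 / sqrt(400)
  e3 <- rv(0.5 + 1.645 * se, dic * 0.5)
  e4 <- rv(0.5, dic * -0.5)
  cmp2 <- compare_rules(e3, e4)
  expect_equal(cmp2$z, 1.645, tolerance = 1e-9)
  expect_equal(cmp2$p_one_sided, 0.05, tolerance = 1e-3)
  # zero contrast variance is an error
  expect_error(compare_rules(e2, e2), "zero contrast variance")
  # uncorrelated fallback combines variances independently
  cmp3 <- compare_rules(e1, e2, correlated = FALSE)
  expect_equal(cmp3$se, sqrt(e1$se^2 + e2$se^2))
})

test_that("NNT reproduces printed arithmetic including sign", {
  expect_equal(nnt(51.7, 44.5), 13.9)
  expect_equal(nnt(100, 50), 2.0)
  expect_equal(nnt(44.5, 51.7), -13.9)
  expect_error(nnt(44.5, 44.5), "undefined")
})

test_that("proportional ratio reproduces printed arithmetic", {
  expect_equal(proportional_ratio(51.7, 44.5), 1.16)
  expect_equal(proportional_ratio(86.9, 81.7), 1.06)
  expect_equal(proportional_ratio(44.5, 44.5), 1.00)
  expect_error(proportional_ratio(51.7, 0), "positive")
})

test_that("concordance ratio handles zeros per the reporting convention", {
  expect_equal(concordance_ratio(26.2, 9.7), 2.7)
  expect_equal(concordance_ratio(7.6, 5.8), 1.3)
  expect_equal(concordance_ratio(0, 1.1), 0)
  expect_equal(concordance_ratio(0, 0), 0)
  expect_error(concordance_ratio(3, 0), "zero denominator")
})

test_that("contribution decomposition sums to 100 and allows negatives", {
  d <- c(2, -1, 3); n <- c(10, 20, 5)
  contrib <- contribution_decomposition(d, n)
  expect_equal(sum(contrib), 100, tolerance = 1e-8)
  expect_lt(contrib[2], 0)
  eq <- contribution_decomposition(rep(2, 13), rep(100, 13))
  expect_equal(eq, rep(100 / 13, 13))
  expect_error(contribution_decomposition(c(1, -1), c(5, 5)), "zero total")
})

test_that("distribution tables count, percentage, and test homogeneity", {
  meds <- paste0("m", 1:3)
  tab <- distribution_table(c(1, 1, 2, 3), meds)
  expect_equal(tab$n, c(2L, 1L, 1L))
  expect_equal(tab$pct, c(50, 25, 25))
  expect_equal(nrow(distribution_table(integer(), meds)), 0)
  same <- distribution_table(c(1, 2, 3), meds, compare = c(1, 2, 3))
  expect_equal(attr(same, "chisq"), 0)
})

test_that("medication summary coincides with observed under the factual rule", {
  coh <- simulate_cohort(default_sim_config(n_patients = 4000, seed = 56))
  d <- coh$data
  nuis <- holdout_nuisances(default_formula(), d, roster = light_roster(),
                            n_folds = 5, seed = 56)
  static <- lapply(1:5, function(a) {
    tmle_rule_value(d$y, d$arm, rep(a, nrow(d)), nuis$g, nuis$Q)
  })
  itr_est <- observed_success_rate(d$y)
  tab <- medication_specific_summary(d$y, d$arm, rec_arms = d$arm,
                                     static_estimates = static,
                                     itr_estimate = itr_est,
                                     medications = paste0("m", 1:5))
  expect_equal(tab$obs_success_pct, tab$rec_subset_success_pct)
  expect_equal(tab$n_received, tab$n_recommended)
})
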