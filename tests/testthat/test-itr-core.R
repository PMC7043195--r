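test_that("propensity estimates are calibrated on randomized data", {
  set.seed(31)
  n <- 5000
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  arms <- sample(1:2, n, replace = TRUE) # true propensity 0.5
  g <- estimate_propensities(x, arms, roster = light_roster(),
                             n_folds = 5, seed = 31)
  expect_true(all(g$raw >= 0.45 & g$raw <= 0.55))
  expect_true(all(abs(rowSums(g$raw) - 1) < 1e-8))
})

test_that("propensity truncation clips cells at delta and counts them", {
  set.seed(32)
  n <- 2000
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "z"))
  # strong separation pushes some fitted propensities below delta
  arms <- ifelse(x[, 1] + rnorm(n, sd = 0.3) > 0, 1L, 2L)
  g <- estimate_propensities(x, arms, roster = list(lrn_glm()),
                             n_folds = 5, seed = 32, delta = 0.05)
  expect_true(all(g$values >= 0.05))
  expect_gt(g$truncated_count, 0)
  expect_equal(g$truncated_count, sum(g$raw < 0.05))
  expect_error(estimate_propensities(x, arms, roster = list(lrn_glm()),
                                     delta = 0.6), "delta")
  expect_error(estimate_propensities(x, rep(1L, n),
                                     roster = list(lrn_glm())), ">= 2 arms")
})

test_that("degenerate outcomes give constant surfaces with a warning", {
  x <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  arms <- rep(1:2, 25)
  expect_warning(s <- estimate_outcome_surfaces(x, arms, rep(1, 50),
                                                roster = light_roster(),
                                                n_folds = 5, seed = 33),
                 "degenerate")
  expect_true(all(s$Q == 1))
  expect_true(all(s$m == 1))
})

test_that("outcome surfaces track the true success probabilities", {
  coh <- simulate_cohort(default_sim_config(n_patients = 8000, seed = 34))
  d <- coh$data
  x <- as.matrix(d[, coh$covariate_names])
  s <- estimate_outcome_surfaces(x, d$arm, d$y,
                                 roster = list(lrn_glm()),
                                 n_folds = 5, seed = 34)
  expect_lte(mean(abs(s$Q - coh$truth$true_success_probs)), 0.05)
  # the m regression agrees with the propensity-weighted Q combination
  g <- estimate_propensities(x, d$arm, roster = list(lrn_glm()),
                             n_folds = 5, seed = 34)
  expect_lte(mean(abs(s$m - rowSums(g$raw * s$Q))), 0.05)
})

test_that("difference scores satisfy the plug-in identities", {
  # exact cancellation when Y, Q and m coincide
  n <- 10; K <- 3
  g <- matrix(1 / K, n, K)
  surf <- list(Q = matrix(0.3, n, K), m = rep(0.3, n))
  D <- compute_difference_scores(rep(0.3, n), rep(1L, n), g, surf)
  expect_true(all(D == 0))
  # single-patient plug-in value
  D1 <- compute_difference_scores(1, 1L, matrix(1, 1, 1),
                                  list(Q = matrix(0, 1, 1), m = 0))
  expect_equal(drop(D1), 1)
})

test_that("difference-score column means are doubly robust", {
  coh <- simulate_cohort(default_sim_config(n_patients = 50000, seed = 35))
  d <- coh$data
  mu <- coh$truth$true_success_probs
  g <- coh$truth$true_propensities
  m <- rowSums(g * mu)
  n <- nrow(d)
  target <- colMeans(mu) - mean(m)
  check <- function(D) {
    se <- apply(D, 2, stats::sd) / sqrt(n)
    expect_true(all(abs(colMeans(D) - target) <= 3 * se))
  }
  # true g, corrupted Q
  badQ <- pmin(pmax(mu * 0.6 + 0.25, 0), 1)
  check(compute_difference_scores(d$y, d$arm, pmax(g, 0.01),
                                  list(Q = badQ, m = m)))
  # corrupted g, true Q
  badg <- (g + 0.25) / rowSums(g + 0.25)
  check(compute_difference_scores(d$y, d$arm, pmax(badg, 0.01),
                                  list(Q = mu, m = m)))
})

test_that("second-stage fits recover constant and monotone signals", {
  set.seed(36)
  n <- 500
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("x1", "x2")))
  D <- cbind(rep(0.25, n), 0.5 * x[, 1] + rnorm(n, sd = 0.5))
  fits <- fit_cate_models(x, D, roster = light_roster(), n_folds = 5,
                          seed = 36)
  expect_equal(predict(fits[[1]], x), rep(0.25, n), tolerance = 1e-8)
  # fitted difference increases in the driving covariate over its
  # central 80% range
  grid <- cbind(x1 = seq(quantile(x[, 1], 0.1), quantile(x[, 1], 0.9),
                         length.out = 25), x2 = 0)
  pred <- predict(fits[[2]], grid)
  expect_true(all(diff(pred) > 0))
})

test_that("antisymmetric two-arm effects yield antisymmetric fits", {
  set.seed(37)
  n <- 8000
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x1"))
  tau <- 0.3 * x[, 1] # mu_1 - m = -(mu_2 - m)
  D <- cbind(tau + rnorm(n), -tau + rnorm(n))
  fits <- fit_cate_models(x, D, roster = list(lrn_glm()), n_folds = 5,
                          seed = 37)
  f1 <- predict(fits[[1]], x)
  f2 <- predict(fits[[2]], x)
  expect_gte(stats::cor(f1, -f2), 0.8)
})

test_that("rules respect kinds, simplex weights, and tie-breaking", {
  r <- make_rule("static", arm = 3)
  expect_equal(rule_arms(r, n = 4), rep(3L, 4))
  expect_error(make_rule("static", arm = 7, n_arms = 5), "outside")

  w <- make_rule("stochastic", weights = rep(1 / 15, 15))
  expect_equal(w$weights, rep(1 / 15, 15))
  expect_error(make_rule("stochastic", weights = c(0.5, 0.6)), "sum to 1")
  expect_error(make_rule("stochastic", weights = c(-0.5, 1.5)),
               "nonnegative")

  f <- make_rule("factual")
  expect_equal(rule_arms(f, arms = c(2L, 5L)), c(2L, 5L))

  # exact tie between arms 2 and 5 resolves to arm 2
  const <- function(v) {
    structure(list(v = v), class = "const_fit")
  }
  fits <- list(NULL, const(0.7), NULL, NULL, const(0.7))
  registerS3method("predict", "const_fit",
                   function(object, newdata, ...) rep(object$v, nrow(newdata)),
                   envir = environment())
  lr <- itrlearn:::new_learned_rule(fits, c(2L, 5L), paste0("m", 1:5))
  expect_equal(rule_arms(lr, newdata = matrix(0, 3, 1)), rep(2L, 3))
})

test_that("the fitted ITR stays inside the eligible arm set", {
  coh <- simulate_cohort(default_sim_config(n_patients = 3000, seed = 38))
  d <- coh$data
  # make arm 5 too rare to be eligible
  d$arm[d$arm == 5] <- 1L
  d$arm[1:10] <- 5L
  expect_warning(
    fit <- itr(default_formula(), data = d, treatment = "arm",
               roster = light_roster(), n_folds = 5, min_arm_n = 25,
               seed = 38),
    "below min_arm_n")
  expect_false(5L %in% fit$eligible_arms)
  rec <- predict(fit, d)
  expect_true(all(rec %in% fit$eligible_arms))
})

test_that("the fit is deterministic given the seed tuple", {
  coh <- simulate_cohort(default_sim_config(n_patients = 1500, seed = 39))
  d <- coh$data
  f <- function() itr(y ~ age + benzodiazepine + mood_stabilizer +
                        antidepressant + urban,
                      data = d, treatment = "arm",
                      roster = light_roster(), n_folds = 5, seed = 40)
  a <- f(); b <- f()
  expect_identical(a$difference_scores, b$difference_scores)
  expect_identical(predict(a, d), predict(b, d))
})
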