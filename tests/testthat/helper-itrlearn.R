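# shared test fixtures, all generated in code

# fast roster for simulation-heavy tests
light_roster <- function() list(lrn_mean(), lrn_glm())

# the default scenario's covariate formula
default_formula <- function() {
  y ~ age + male + ed_visits + prior_hosp + outpatient_visits +
    benzodiazepine + mood_stabilizer + antidepressant + anticholinergic +
    comorbidity_count + severity_score + urban
}

# a small eligible-record table with known fields
toy_records <- function() {
  data.frame(
    patient_id = 1:6,
    age = c(30, 75, 15, 40, 50, 60),
    first_regimen = c("risperidone", "risperidone", "olanzapine",
                      "clozapine", "risperidone", "olanzapine"),
    first_rx_inpatient = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    arm = c(1L, 1L, 2L, 1L, 1L, 2L))
}

# linear-response regression task for Super Learner tests
toy_regression <- function(n = 200, p = 4, sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- c(1, -0.5, 0.25, 0)[seq_len(p)]
  list(x = x, y = drop(x %*% beta) + rnorm(n, sd = sd), beta = beta)
}

# independent brute-force CV risk for a single learner (oracle for
# fit_super_learner's internals)
brute_force_cv_risk <- function(learner, x, y, folds) {
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    m <- learner$fit(x[tr, , drop = FALSE], y[tr])
    pred[!tr] <- as.numeric(learner$predict(m, x[!tr, , drop = FALSE]))
  }
  mean((pred - y)^2)
}
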