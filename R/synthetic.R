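#' Simulation configuration for synthetic claims-like cohorts
#'
#' Defines a multi-arm observational scenario with known ground truth:
#' covariate distributions, covariate-dependent multinomial treatment
#' assignment (softmax of per-arm linear scores), and arm-specific
#' success probabilities on the logit scale with arm-by-covariate
#' interactions (true heterogeneous effects). Coefficients act on
#' internally standardised covariates, so a unit coefficient is a
#' per-standard-deviation log-odds shift.
#'
#' @param n_patients number of eligible patients to generate.
#' @param n_arms number of treatment arms, between 2 and 15.
#' @param covariate_spec list of `list(name, kind, ...)` entries with
#'   `kind` one of `"continuous"` (`dist = "uniform"` with `min`,`max`,
#'   or `dist = "normal"` with `mean`,`sd`), `"binary"` (`prob`), or
#'   `"count"` (`lambda`).
#' @param propensity_coefficients `n_arms x (p + 1)` matrix (intercept
#'   first) of per-arm scores; the first arm is the reference and its row
#'   is forced to zero.
#' @param outcome_coefficients list with `arm_intercepts` (length
#'   `n_arms`), `main` (length `p`), and `interactions`
#'   (`n_arms x p` matrix) on the logit-success scale.
#' @param decoy_fraction fraction (of `n_patients`) of additional
#'   ineligible "decoy" records emitted by [generate_raw_records()].
#' @param medications character vector of arm (medication) names,
#'   length `n_arms`.
#' @param seed integer master seed.
#' @return a validated object of class `"sim_config"`.
#' @seealso [default_sim_config()] for the package's reference scenario.
#' @export
sim_config <- function(n_patients, n_arms, covariate_spec,
                       propensity_coefficients, outcome_coefficients,
                       decoy_fraction = 0, medications = NULL, seed = 1) {
  if (n_arms < 2 || n_arms > 15) stop_config("n_arms must be in [2, 15]")
  if (n_patients < 0) stop_config("n_patients must be nonnegative")
  if (decoy_fraction < 0 || decoy_fraction > 1)
    stop_config("decoy_fraction must be in [0, 1]")
  p <- length(covariate_spec)
  if (!p) stop_config("covariate_spec is empty")
  nms <- vapply(covariate_spec, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_config("covariate names must be unique")
  for (cv in covariate_spec) {
    switch(cv$kind,
      continuous = {
        if (identical(cv$dist %||% "normal", "uniform")) {
          if (!(cv$min < cv$max)) stop_config("uniform covariate '%s': need min < max", cv$name)
        } else if (!((cv$sd %||% 1) > 0)) stop_config("normal covariate '%s': sd must be > 0", cv$name)
      },
      binary = if (cv$prob < 0 || cv$prob > 1)
        stop_config("binary covariate '%s': prob outside [0,1]", cv$name),
      count = if (cv$lambda <= 0)
        stop_config("count covariate '%s': lambda must be > 0", cv$name),
      stop_config("unknown covariate kind '%s'", cv$kind))
  }
  pc <- as.matrix(propensity_coefficients)
  if (!all(dim(pc) == c(n_arms, p + 1)))
    stop_config("propensity_coefficients must be %d x %d (intercept first)", n_arms, p + 1)
  pc[1, ] <- 0 # reference arm
  oc <- outcome_coefficients
  if (length(oc$arm_intercepts) != n_arms || length(oc$main) != p ||
      !all(dim(as.matrix(oc$interactions)) == c(n_arms, p)))
    stop_config("outcome_coefficients have inconsistent dimensions")
  if (is.null(medications)) medications <- antipsychotic_names(n_arms)
  if (length(medications) != n_arms) stop_config("need one medication name per arm")
  structure(list(
    n_patients = as.integer(n_patients), n_arms = as.integer(n_arms),
    covariate_spec = covariate_spec, covariate_names = nms,
    propensity_coefficients = pc, outcome_coefficients = oc,
    decoy_fraction = decoy_fraction, medications = medications,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# the antipsychotic arm labels used by the reference scenario
antipsychotic_names <- function(k) {
  all15 <- c("amisulpride", "aripiprazole", "risperidone", "olanzapine",
             "quetiapine", "haloperidol", "sulpiride", "paliperidone",
             "flupentixol", "zotepine", "chlorpromazine", "trifluoperazine",
             "ziprasidone", "clothiapine", "thioridazine")
  all15[seq_len(k)]
}

#' The package's reference simulation scenario
#'
#' A desk-scale analogue of a 15-arm, 121-predictor claims problem:
#' 5 arms, 12 covariates (an age-like uniform(16, 74) variable, visit and
#' hospitalisation counts, prior-medication indicators, a continuous
#' severity score, and noise covariates), moderate confounding (per-SD
#' propensity odds ratios at most 3), and arm-by-covariate interactions
#' calibrated so that the oracle rule's value exceeds the best single
#' arm's value by about five percentage points at a mean success rate
#' near 45%.
#'
#' @param n_patients cohort size (default 20000).
#' @param seed master seed.
#' @param decoy_fraction ineligible-decoy fraction for raw-record output.
#' @param heterogeneity multiplier on the arm-specific effect structure
#'   (arm-by-covariate interactions and the spread of the arm
#'   intercepts); `0` gives a null scenario in which every arm shares
#'   one success surface.
#' @param confounding multiplier on the propensity coefficients; `0`
#'   gives randomised assignment.
#' @return a `"sim_config"`.
#' @export
default_sim_config <- function(n_patients = 20000, seed = 1,
                               decoy_fraction = 0, heterogeneity = 1,
                               confounding = 1) {
  spec <- list(
    list(name = "age", kind = "continuous", dist = "uniform", min = 16, max = 74),
    list(name = "male", kind = "binary", prob = 0.49),
    list(name = "ed_visits", kind = "count", lambda = 0.8),
    list(name = "prior_hosp", kind = "count", lambda = 0.4),
    list(name = "outpatient_visits", kind = "count", lambda = 6),
    list(name = "benzodiazepine", kind = "binary", prob = 0.45),
    list(name = "mood_stabilizer", kind = "binary", prob = 0.20),
    list(name = "antidepressant", kind = "binary", prob = 0.30),
    list(name = "anticholinergic", kind = "binary", prob = 0.15),
    list(name = "comorbidity_count", kind = "count", lambda = 0.7),
    list(name = "severity_score", kind = "continuous", dist = "normal", mean = 0, sd = 1),
    list(name = "urban", kind = "binary", prob = 0.60))
  p <- length(spec)
  K <- 5
  # per-SD log-odds of assignment. Individual coefficients stay well
  # under log(3) and are kept small enough jointly that assignment
  # probabilities retain overlap (inverse weights in the single digits
  # for almost all patients): confounding is moderate by design
  pc <- matrix(0, K, p + 1)
  #                      int   age  male    ed  hosp  outp benzo  mood antid antich comorb sever urban
  pc[2, ] <- confounding * c(0.10, -0.25, 0, 0.15, 0, 0, 0.20, 0, 0, 0, 0, 0.10, 0)
  pc[3, ] <- confounding * c(0.20, 0.20, 0, -0.15, 0.15, 0, -0.20, 0.15, 0, 0, 0, 0, 0)
  pc[4, ] <- confounding * c(0.00, 0.10, 0, 0, -0.15, 0.10, 0.15, -0.20, 0, 0, 0, -0.10, 0)
  pc[5, ] <- confounding * c(-0.10, -0.15, 0, -0.20, 0, 0, -0.15, 0.20, 0, 0, 0, 0.15, 0)
  # common prognostic main effects (per SD, logit scale)
  main <- c(-0.30, 0, -0.40, -0.50, -0.10, -0.30, -0.15, -0.10, 0, -0.20, 0.20, 0)
  # arm-specific interactions on the prior-medication and residence
  # indicators (benzodiazepine, mood stabilizer, antidepressant, urban).
  # The pattern gives every covariate cell a clearly best arm (cell
  # margins mostly 4-7 percentage points) while keeping the arms' marginal
  # success rates close, so the oracle rule beats the best single arm by
  # about five percentage points
  gam <- matrix(0, K, p)
  gam[, c(6, 7, 8, 12)] <- c(
    0.198, 0.221, -0.176, -0.140, -0.143,   # benzodiazepine
    -0.105, 0.263, 0.051, -0.140, 0.109,    # mood stabilizer
    0.173, 0.150, -0.134, -0.159, -0.227,   # antidepressant
    0.139, 0.015, -0.112, 0.470, 0.160)     # urban
  gam <- heterogeneity * gam
  alpha <- c(0.111, -0.276, -0.262, -0.318, -0.303) * heterogeneity -
    0.27 * (1 - heterogeneity)
  sim_config(
    n_patients = n_patients, n_arms = K, covariate_spec = spec,
    propensity_coefficients = pc,
    outcome_coefficients = list(arm_intercepts = alpha, main = main,
                                interactions = gam),
    decoy_fraction = decoy_fraction, seed = seed)
}

# closed-form mean/sd of each declared covariate, for standardisation
covariate_moments <- function(config) {
  t(vapply(config$covariate_spec, function(cv) {
    switch(cv$kind,
      continuous = if (identical(cv$dist %||% "normal", "uniform")) {
        c((cv$min + cv$max) / 2, (cv$max - cv$min) / sqrt(12))
      } else c(cv$mean %||% 0, cv$sd %||% 1),
      binary = c(cv$prob, max(sqrt(cv$prob * (1 - cv$prob)), 1e-6)),
      count = c(cv$lambda, sqrt(cv$lambda)))
  }, numeric(2)))
}

standardise_covariates <- function(config, x) {
  m <- covariate_moments(config)
  sweep(sweep(as.matrix(x), 2, m[, 1]), 2, m[, 2], "/")
}

#' Generate baseline covariates
#'
#' Draws the covariate table declared in the configuration. Deterministic
#' given the configuration seed; `n_patients = 0` yields an empty table
#' with the declared columns.
#'
#' @param config a [sim_config()].
#' @param n override for the number of rows (defaults to
#'   `config$n_patients`).
#' @param seed override for the seed.
#' @return data frame with one numeric column per declared covariate.
#' @export
generate_covariates <- function(config, n = config$n_patients,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cols <- lapply(config$covariate_spec, function(cv) {
    switch(cv$kind,
      continuous = if (identical(cv$dist %||% "normal", "uniform")) {
        stats::runif(n, cv$min, cv$max)
      } else stats::rnorm(n, cv$mean %||% 0, cv$sd %||% 1),
      binary = stats::rbinom(n, 1, cv$prob),
      count = stats::rpois(n, cv$lambda))
  })
  names(cols) <- config$covariate_names
  as.data.frame(cols)[seq_len(n), , drop = FALSE]
}

#' Assign treatments by covariate-dependent multinomial sampling
#'
#' Each patient's arm is drawn from the softmax of per-arm linear scores
#' on the standardised covariates; the exact softmax probabilities are
#' returned as the true propensities.
#'
#' @param config a [sim_config()] (supplies coefficients and
#'   standardisation).
#' @param covariates covariate table from [generate_covariates()].
#' @param seed seed for the draw.
#' @return list with `arms` (integer in `1:K`) and `true_propensities`
#'   (`n x K`, rows summing to one).
#' @export
assign_treatments <- function(config, covariates, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  z <- standardise_covariates(config, covariates)
  K <- config$n_arms
  scores <- cbind(1, z) %*% t(config$propensity_coefficients)
  scores <- scores - apply(scores, 1, max)
  g <- exp(scores)
  g <- g / rowSums(g)
  set.seed(seed)
  u <- stats::runif(nrow(g))
  cum <- t(apply(g, 1, cumsum))
  arms <- as.integer(rowSums(u > cum) + 1L)
  arms[arms > K] <- K
  list(arms = arms, true_propensities = g)
}

# true success-probability surface mu_a(x) for every arm
true_success_surface <- function(config, covariates) {
  z <- standardise_covariates(config, covariates)
  oc <- config$outcome_coefficients
  eta_main <- drop(z %*% oc$main)
  mu <- sapply(seq_len(config$n_arms), function(a) {
    stats::plogis(oc$arm_intercepts[a] + eta_main +
                    drop(z %*% as.matrix(oc$interactions)[a, ]))
  })
  matrix(mu, nrow = nrow(z))
}

#' Simulate outcomes and 12-month event streams
#'
#' Draws the binary 12-month treatment-success label from the true
#' arm-specific success probability, then constructs an event stream
#' consistent with it: every failure carries at least one
#' failure-triggering event (hospitalization, medication switch or
#' addition, or inpatient death) at a uniform time in the 12-month
#' window, and successes carry none. Discontinuation events, which the
#' primary success definition ignores, are sprinkled into both groups.
#'
#' @param config a [sim_config()].
#' @param covariates covariate table.
#' @param arms integer arm assignments.
#' @param seed seed for the draws.
#' @return list with `y` (0/1 success), `true_success_probs` (`n x K`),
#'   and `events` (data frame `patient_id`, `type`, `month`).
#' @export
simulate_outcomes <- function(config, covariates, arms,
                              seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  mu <- true_success_surface(config, covariates)
  n <- nrow(mu)
  set.seed(seed)
  pa <- mu[cbind(seq_len(n), arms)]
  y <- stats::rbinom(n, 1, pa)

  fail_types <- c("hospitalization_psychiatric", "hospitalization_other",
                  "med_switch", "med_addition", "inpatient_death")
  fail_prob <- c(0.25, 0.25, 0.30, 0.15, 0.05)
  ev <- list()
  fidx <- which(y == 0)
  if (length(fidx)) {
    t1 <- sample(fail_types, length(fidx), replace = TRUE, prob = fail_prob)
    m1 <- stats::runif(length(fidx), 1e-6, 12)
    ev[[1]] <- data.frame(patient_id = fidx, type = t1, month = m1)
    extra <- fidx[stats::runif(length(fidx)) < 0.30]
    if (length(extra)) {
      t2 <- sample(fail_types, length(extra), replace = TRUE, prob = fail_prob)
      m2 <- stats::runif(length(extra), 1e-6, 12)
      ev[[2]] <- data.frame(patient_id = extra, type = t2, month = m2)
    }
  }
  disc <- which(stats::runif(n) < 0.25)
  if (length(disc)) {
    ev[[3]] <- data.frame(patient_id = disc, type = "discontinuation",
                          month = stats::runif(length(disc), 1e-6, 12))
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(patient_id = integer(), type = character(), month = numeric())
  events <- events[order(events$patient_id, events$month), , drop = FALSE]
  rownames(events) <- NULL
  list(y = y, true_success_probs = mu, events = events)
}

#' Simulate a complete eligible cohort with ground truth
#'
#' Runs covariate generation, treatment assignment and outcome
#' simulation, and packages the ground truth (true propensities, true
#' success surface, the oracle argmax arm, and the oracle rule value).
#'
#' @param config a [sim_config()].
#' @return list of class `"synthetic_cohort"` with `data` (patient
#'   table: id, eligibility fields, covariates, `arm`, `y`), `events`
#'   (event-stream table), `truth` (a `"ground_truth"` list), and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  x <- generate_covariates(config)
  tr <- assign_treatments(config, x)
  out <- simulate_outcomes(config, x, tr$arms)
  mu <- out$true_success_probs
  oracle_arm <- max.col(mu, ties.method = "first")
  truth <- structure(list(
    true_propensities = tr$true_propensities,
    true_success_probs = mu,
    oracle_arm = oracle_arm,
    oracle_value = mean(mu[cbind(seq_len(nrow(mu)), oracle_arm)])
  ), class = "ground_truth")
  data <- data.frame(
    patient_id = seq_len(nrow(x)),
    age = if ("age" %in% names(x)) x$age else NA_real_,
    first_regimen = config$medications[tr$arms],
    first_rx_inpatient = FALSE,
    x,
    arm = tr$arms,
    y = out$y)
  structure(list(data = data, events = out$events, truth = truth,
                 config = config, covariate_names = config$covariate_names),
            class = "synthetic_cohort")
}

#' Generate raw records including ineligible decoys
#'
#' Emits the eligible cohort plus labelled decoy records, one of each
#' exclusion class in rotation: out-of-range age, second-line first
#' regimen (clozapine, polypharmacy, long-acting injectable), first
#' prescription during hospitalization, and a rarely-prescribed drug.
#' The ground-truth `eligible` flag and `exclusion_class` label are
#' retained so filter tests can be exact.
#'
#' @param config a [sim_config()] with `decoy_fraction` set.
#' @return list with `records` (patient table with `eligible` and
#'   `exclusion_class` columns), `events`, `truth`, `config`.
#' @export
generate_raw_records <- function(config) {
  coh <- simulate_cohort(config)
  rec <- coh$data
  rec$eligible <- TRUE
  rec$exclusion_class <- NA_character_
  n_decoy <- round(config$decoy_fraction * config$n_patients)
  if (n_decoy > 0) {
    set.seed(child_seed(config$seed, 77L))
    classes <- rep_len(c("age", "second_line", "inpatient_rx", "rare_drug"),
                       n_decoy)
    idx <- sample(nrow(rec), n_decoy, replace = TRUE)
    dec <- rec[idx, , drop = FALSE]
    dec$patient_id <- max(rec$patient_id) + seq_len(n_decoy)
    dec$eligible <- FALSE
    dec$exclusion_class <- classes
    low <- stats::runif(n_decoy) < 0.5
    dec$age[classes == "age"] <- ifelse(low[classes == "age"],
                                        stats::runif(sum(classes == "age"), 5, 15.5),
                                        stats::runif(sum(classes == "age"), 74.5, 90))
    sl <- c("clozapine", "polypharmacy", "long_acting_injectable")
    dec$first_regimen[classes == "second_line"] <-
      sample(sl, sum(classes == "second_line"), replace = TRUE)
    dec$first_rx_inpatient[classes == "inpatient_rx"] <- TRUE
    dec$first_regimen[classes == "rare_drug"] <- "pimozide"
    rec <- rbind(rec, dec)
    rownames(rec) <- NULL
  }
  list(records = rec, events = coh$events, truth = coh$truth, config = config)
}

#' True mean success under a treatment rule
#'
#' The ground-truth value of a rule: the mean over patients of the true
#' success probability under the arm the rule assigns (or the
#' weight-averaged mean for a stochastic rule).
#'
#' @param truth a `"ground_truth"` object from [simulate_cohort()].
#' @param rule one of: an integer vector of per-patient arms; a
#'   [make_rule()] object (`static`, `stochastic`, or `learned` — the
#'   latter requires `newdata`); or a single arm index.
#' @param newdata covariates for predicting a learned rule's arms.
#' @return scalar true mean success probability.
#' @export
oracle_rule_value <- function(truth, rule, newdata = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  mu <- truth$true_success_probs
  n <- nrow(mu); K <- ncol(mu)
  if (inherits(rule, "treatment_rule")) {
    if (rule$kind == "stochastic") {
      return(sum(rule$weights * colMeans(mu)))
    }
    arms <- rule_arms(rule, newdata = newdata, n = n)
  } else if (length(rule) == 1) {
    arms <- rep(as.integer(rule), n)
  } else {
    arms <- as.integer(rule)
    if (length(arms) != n) stop_config("rule assigns %d arms for %d patients",
                                       length(arms), n)
  }
  if (any(arms < 1 | arms > K)) stop_config("rule emits an arm outside [1, %d]", K)
  mean(mu[cbind(seq_len(n), arms)])
}
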