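#' Run the full synthetic ITR pipeline
#'
#' Orchestrates every stage from one configuration: simulate raw
#' records, apply the eligibility filters, derive the success outcome
#' from the event streams, split 70/30, fit the two-stage ITR on the
#' training sample, value it against the comparator allocations on the
#' holdout, and (optionally) compute prescriptive-predictor importance.
#' Per-stage seeds are derived from the configuration's master seed by
#' fixed offsets, so a rerun with an identical configuration reproduces
#' identical numerical output.
#'
#' @param config a [sim_config()] (e.g. [default_sim_config()]).
#' @param train_fraction training share in (0, 1); default 0.7.
#' @param roster candidate learners for all Super Learner stages.
#' @param n_folds,delta,min_arm_n see [itr()].
#' @param rare_min rare-drug eligibility minimum; default scales the
#'   conventional full-size threshold of 100 to the configured cohort
#'   (`max(5, round(100 * n / 32000))`).
#' @param outcome an [outcome_definition()] used to label success from
#'   the event streams.
#' @param importance compute permutation importance (default `FALSE`;
#'   it dominates runtime on large rosters).
#' @param n_repetitions permutation repetitions when `importance` is on.
#' @param out_dir optional directory: delimited artifact tables and a
#'   JSON manifest are written there.
#' @return object of class `"itr_pipeline"`: `fit`, `evaluation`,
#'   `cohort` (filtered records + labels + split), `truth`,
#'   `importance`, `tables` (the five report tables), and `manifest`.
#' @export
run_pipeline <- function(config = default_sim_config(),
                         train_fraction = 0.7,
                         roster = default_roster(heavy = FALSE),
                         n_folds = 10, delta = 0.01, min_arm_n = 25,
                         rare_min = NULL,
                         outcome = outcome_definition("primary"),
                         importance = FALSE, n_repetitions = 10,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must be in (0, 1): a nonempty holdout is required")
  rare_min <- rare_min %||% max(5, round(100 * config$n_patients / 32000))

  raw <- generate_raw_records(config)
  elig <- apply_eligibility(raw$records, config$medications,
                            rare_min = rare_min)
  rec <- elig$records
  y <- label_outcome(raw$events, rec$patient_id, outcome)
  rec$y <- as.integer(y)
  split <- split_sample(nrow(rec), train_fraction,
                        seed = child_seed(config$seed, 5L))
  rec$split <- split
  covs <- raw$truth # ground truth rows align with eligible patient ids
  form <- stats::as.formula(paste("y ~",
                                  paste(config$covariate_names,
                                        collapse = " + ")))
  train <- rec[split == "train", , drop = FALSE]
  holdout <- rec[split == "holdout", , drop = FALSE]

  fit <- itr(form, data = train, treatment = "arm", roster = roster,
             n_folds = n_folds, delta = delta, min_arm_n = min_arm_n,
             seed = child_seed(config$seed, 6L),
             medications = config$medications)
  ev <- evaluate_itr(fit, holdout, roster = roster, n_folds = n_folds,
                     seed = child_seed(config$seed, 7L), delta = delta,
                     min_arm_n = min_arm_n)
  imp <- if (importance) {
    itr_importance(fit, train, n_repetitions = n_repetitions,
                   seed = child_seed(config$seed, 8L))
  }
  tables <- render_tables(ev, train_arms = train$arm,
                          medications = config$medications)
  manifest <- build_manifest(config, stages = list(
    raw_records = nrow(raw$records), eligible = nrow(rec),
    excluded = elig$exclusions, train = nrow(train),
    holdout = nrow(holdout)))

  res <- structure(list(fit = fit, evaluation = ev,
                        cohort = list(records = rec,
                                      events = raw$events,
                                      exclusions = elig$exclusions),
                        truth = raw$truth, importance = imp,
                        tables = tables, manifest = manifest,
                        config = config),
                   class = "itr_pipeline")
  if (!is.null(out_dir)) res$manifest <- write_artifacts(res, out_dir)
  res
}

#' @export
print.itr_pipeline <- function(x, ...) {
  cat("ITR pipeline run (seed", x$config$seed, ")\n")
  cat(sprintf("  raw %d -> eligible %d (excl: %s)\n",
              x$manifest$stages$raw_records, x$manifest$stages$eligible,
              paste(names(x$manifest$stages$excluded),
                    x$manifest$stages$excluded, collapse = ", ")))
  print(x$evaluation)
  invisible(x)
}

# deterministic digest of the configuration (md5 of its JSON form)
config_digest <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

build_manifest <- function(config, stages, files = character()) {
  list(config_digest = config_digest(config),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("itrlearn")),
       stages = stages, files = files)
}

#' Render the five report tables from a holdout evaluation
#'
#' Analogues of the standard comparative-effectiveness report tables:
#' (1) observed vs recommended medication distributions; (2) prescribing
#' proportions given recommendation with concordance ratios; (3)
#' medication-specific success summary; (4) recommended-medication
#' outcomes among discordantly treated patients; (5) the contribution
#' decomposition of the rule's aggregate improvement.
#'
#' @param ev an `"itr_evaluation"`.
#' @param train_arms training-sample arm vector (for table 1's first
#'   column); optional.
#' @param medications arm names.
#' @return named list of data frames `t1`..`t5`.
#' @export
render_tables <- function(ev, train_arms = NULL, medications) {
  K <- length(medications)
  arms <- ev$nuisances$arms
  y <- ev$nuisances$y
  rec <- ev$recommended

  t1 <- distribution_table(arms, medications, compare = rec)
  names(t1) <- c("medication", "holdout_n", "holdout_pct", "holdout_se")
  r <- distribution_table(rec, medications)
  t1$recommended_n <- r$n
  t1$recommended_pct <- r$pct
  if (!is.null(train_arms)) {
    tr <- distribution_table(train_arms, medications)
    t1$train_n <- tr$n
    t1$train_pct <- tr$pct
  }

  t2 <- do.call(rbind, lapply(seq_len(K), function(a) {
    rec_a <- rec == a
    p1 <- if (any(rec_a)) 100 * mean(arms[rec_a] == a) else 0
    p0 <- if (any(!rec_a)) 100 * mean(arms[!rec_a] == a) else 0
    ratio <- if (p1 == 0) 0 else if (p0 == 0) NA_real_ else
      concordance_ratio(p1, p0)
    data.frame(medication = medications[a],
               pct_when_recommended = round_half_up(p1, 1),
               pct_when_not = round_half_up(p0, 1),
               concordance_ratio = ratio)
  }))

  t3 <- medication_specific_summary(y, arms, rec, ev$estimates$static,
                                    ev$estimates$itr, medications)

  Q <- ev$nuisances$Q
  i <- seq_along(y)
  q_rec <- Q[cbind(i, rec)]
  t4 <- do.call(rbind, lapply(seq_len(K), function(a) {
    sub <- which(rec == a & arms != a)
    data.frame(medication = medications[a],
               n_without = length(sub),
               obs_success_pct = round_half_up(
                 100 * if (length(sub)) mean(y[sub]) else NA_real_, 1),
               est_if_recommended_pct = round_half_up(
                 100 * if (length(sub)) mean(q_rec[sub]) else NA_real_, 1))
  }))

  t5_rows <- lapply(seq_len(K), function(a) {
    sub <- which(arms == a & rec != a)
    if (!length(sub)) return(NULL)
    obs <- mean(y[sub])
    est <- mean(q_rec[sub])
    data.frame(medication = medications[a], n_without = length(sub),
               obs_success_pct = 100 * obs,
               est_if_recommended_pct = 100 * est,
               diff_pct = 100 * (est - obs))
  })
  t5 <- do.call(rbind, t5_rows)
  if (!is.null(t5) && nrow(t5) && abs(sum(t5$diff_pct * t5$n_without)) > 1e-12) {
    t5$contribution_pct <- round_half_up(
      contribution_decomposition(t5$diff_pct, t5$n_without), 1)
  }
  if (!is.null(t5)) {
    t5$obs_success_pct <- round_half_up(t5$obs_success_pct, 1)
    t5$est_if_recommended_pct <- round_half_up(t5$est_if_recommended_pct, 1)
    t5$diff_pct <- round_half_up(t5$diff_pct, 1)
  }
  list(t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5)
}

# write delimited artifacts plus a JSON manifest; returns the manifest
write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    f <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    f
  }
  ev <- res$evaluation
  files <- c(
    wr(res$cohort$records, "patients"),
    wr(res$cohort$events, "events"),
    wr(as.data.frame(res$truth$true_success_probs), "true_success_probs"),
    wr(as.data.frame(res$fit$propensities$values), "propensities"),
    wr(as.data.frame(res$fit$difference_scores), "difference_scores"),
    wr(data.frame(patient = seq_along(ev$recommended),
                  recommended_arm = ev$recommended), "recommendations"),
    wr(do.call(rbind, lapply(names(ev$estimates)[names(ev$estimates) != "static"],
                             function(nm) {
      e <- ev$estimates[[nm]]
      data.frame(rule = nm, value = e$value, se = e$se,
                 ci_lo = e$ci95[1], ci_hi = e$ci95[2], n = e$n)
    })), "evaluation"))
  for (nm in names(res$tables)) {
    if (!is.null(res$tables[[nm]])) files <- c(files, wr(res$tables[[nm]], nm))
  }
  if (!is.null(res$importance)) files <- c(files, wr(res$importance, "importance"))
  manifest <- res$manifest
  manifest$files <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
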