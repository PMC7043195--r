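#' Outcome definition
#'
#' The primary 12-month treatment-success definition and its sensitivity
#' variants. A patient succeeds under the primary definition when the
#' window (0, 12] months after the index date contains no inpatient
#' death, no hospitalization of any kind, and no antipsychotic switch or
#' addition; treatment discontinuation is deliberately not a failure
#' (a well-responding patient may still discontinue). Variants narrow or
#' widen the failure set:
#' \describe{
#'   \item{primary}{death, any hospitalization, switch, or addition.}
#'   \item{psych_hosp_or_change}{as primary but non-psychiatric
#'     hospitalizations are ignored.}
#'   \item{psych_hosp_only}{fails only on psychiatric hospitalization or
#'     inpatient death.}
#'   \item{change_only}{fails only on switch or addition.}
#'   \item{primary_plus_discontinuation}{the primary failure set plus
#'     any discontinuation inside `discontinuation_window`.}
#' }
#'
#' @param variant one of the five names above.
#' @param discontinuation_window numeric `(start, end)` months, used only
#'   by `primary_plus_discontinuation` (default `c(3, 9)`).
#' @return object of class `"outcome_definition"`.
#' @export
outcome_definition <- function(variant = c("primary", "psych_hosp_or_change",
                                           "psych_hosp_only", "change_only",
                                           "primary_plus_discontinuation"),
                               discontinuation_window = c(3, 9)) {
  variant <- match.arg(variant)
  w <- as.numeric(discontinuation_window)
  if (length(w) != 2 || w[1] >= w[2] || w[1] < 0 || w[2] > 12)
    stop_config("discontinuation_window must be within [0, 12] with start < end")
  structure(list(variant = variant, discontinuation_window = w),
            class = "outcome_definition")
}

event_types <- c("hospitalization_psychiatric", "hospitalization_other",
                 "med_switch", "med_addition", "discontinuation",
                 "inpatient_death")

#' Label the binary success outcome from an event stream
#'
#' Applies an [outcome_definition()] to an event-stream table. Events at
#' exactly month 0 are pre-index and ignored; the window is half-open
#' (0, 12].
#'
#' @param events data frame with columns `patient_id`, `type`, `month`.
#' @param patient_ids the ids to label (patients absent from `events`
#'   have empty streams and succeed under every variant).
#' @param definition an [outcome_definition()]; defaults to the primary
#'   definition.
#' @return named integer vector of 0/1 success labels, one per
#'   `patient_ids` entry.
#' @export
label_outcome <- function(events, patient_ids,
                          definition = outcome_definition()) {
  stopifnot(inherits(definition, "outcome_definition"))
  if (nrow(events)) {
    bad <- setdiff(unique(events$type), event_types)
    if (length(bad)) stop_config("unknown event type(s): %s",
                                 paste(bad, collapse = ", "))
  }
  fail_set <- switch(definition$variant,
    primary = ,
    primary_plus_discontinuation = c("hospitalization_psychiatric",
                                     "hospitalization_other", "med_switch",
                                     "med_addition", "inpatient_death"),
    psych_hosp_or_change = c("hospitalization_psychiatric", "med_switch",
                             "med_addition", "inpatient_death"),
    psych_hosp_only = c("hospitalization_psychiatric", "inpatient_death"),
    change_only = c("med_switch", "med_addition"))
  in_window <- events$month > 0 & events$month <= 12
  fail <- events$type %in% fail_set & in_window
  if (definition$variant == "primary_plus_discontinuation") {
    w <- definition$discontinuation_window
    fail <- fail | (events$type == "discontinuation" &
                      events$month > w[1] & events$month < w[2])
  }
  failed_ids <- unique(events$patient_id[fail])
  stats::setNames(as.integer(!(patient_ids %in% failed_ids)), patient_ids)
}

#' Apply cohort eligibility filters
#'
#' Filters raw records in a fixed order so per-class exclusion counts are
#' reproducible: (1) age outside the allowed range; (2) first regimen a
#' second-line treatment (clozapine, polypharmacy, long-acting
#' injectable) or otherwise outside the allowed single-agent medication
#' list; (3) first prescription issued during hospitalization; (4) first
#' regimen prescribed to fewer than `rare_min` patients among the records
#' surviving filters 1–3. The operation is idempotent.
#'
#' @param records data frame with columns `age`, `first_regimen`,
#'   `first_rx_inpatient` (plus anything else, carried through).
#' @param medications allowed single-agent medication names.
#' @param age_range inclusive allowed age range (default `c(16, 74)`).
#' @param rare_min minimum cohort-wide patient count per first-regimen
#'   medication.
#' @return list with `records` (eligible rows) and `exclusions` (named
#'   integer counts per filter class, in application order).
#' @export
apply_eligibility <- function(records, medications, age_range = c(16, 74),
                              rare_min = 100) {
  if (!length(medications)) stop_config("medication list is empty")
  counts <- c(age = 0L, second_line = 0L, inpatient_rx = 0L, rare_drug = 0L)
  keep <- records$age >= age_range[1] & records$age <= age_range[2]
  counts["age"] <- sum(!keep, na.rm = TRUE) + sum(is.na(keep))
  keep[is.na(keep)] <- FALSE
  r <- records[keep, , drop = FALSE]

  ok <- r$first_regimen %in% medications
  counts["second_line"] <- sum(!ok)
  r <- r[ok, , drop = FALSE]

  ok <- !r$first_rx_inpatient
  counts["inpatient_rx"] <- sum(!ok)
  r <- r[ok, , drop = FALSE]

  tab <- table(r$first_regimen)
  rare <- names(tab)[tab < rare_min]
  ok <- !(r$first_regimen %in% rare)
  counts["rare_drug"] <- sum(!ok)
  r <- r[ok, , drop = FALSE]
  rownames(r) <- NULL
  list(records = r, exclusions = counts)
}

#' Random train/holdout split
#'
#' Honest evaluation requires the rule to be learned and valued on
#' disjoint samples: a simple random split without replacement, with
#' train size `round(n * train_fraction)`.
#'
#' @param n number of patients.
#' @param train_fraction fraction assigned to training, in (0, 1);
#'   default 0.7.
#' @param seed integer seed.
#' @return character vector of `"train"`/`"holdout"` labels.
#' @export
split_sample <- function(n, train_fraction = 0.7, seed = 1) {
  if (n < 2) stop_config("need at least 2 patients to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must be in (0, 1)")
  set.seed(seed)
  n_train <- round(n * train_fraction)
  lab <- rep("holdout", n)
  lab[sample(n, n_train)] <- "train"
  lab
}
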