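#' Fit evaluation-sample nuisance models
#'
#' TMLE evaluation of a rule needs the propensity matrix and outcome
#' surface on the evaluation (holdout) sample. Following common TMLE
#' practice these are refit on that sample; alternatively the fits from
#' a training-sample [itr()] object can be transported and merely
#' evaluated on the holdout covariates.
#'
#' @param formula outcome formula (as in [itr()]).
#' @param data evaluation-sample data frame.
#' @param treatment treatment column name.
#' @param roster,n_folds,seed,delta Super Learner and truncation
#'   controls.
#' @param transport_from optional fitted [itr()] object whose nuisance
#'   fits are evaluated on this sample instead of refitting.
#' @return list of class `"itr_nuisances"` with `x`, `y`, `arms`, `K`,
#'   `g` (truncated `n x K`), `Q` (`n x K`), `m`.
#' @export
holdout_nuisances <- function(formula, data, treatment = "arm",
                              roster = default_roster(heavy = FALSE),
                              n_folds = 10, seed = 1, delta = 0.01,
                              transport_from = NULL) {
  arms_raw <- data[[treatment]]
  arms <- if (is.factor(arms_raw)) as.integer(arms_raw) else as.integer(arms_raw)
  mf_data <- data[setdiff(names(data), treatment)]
  mf <- stats::model.frame(formula, data = mf_data)
  y <- as.numeric(stats::model.response(mf))
  x <- stats::model.matrix(stats::delete.response(stats::terms(mf)), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  if (!is.null(transport_from)) {
    stopifnot(inherits(transport_from, "itr"))
    K <- transport_from$K
    gp <- predict_propensities(transport_from$propensities, x)
    qs <- predict_outcome_surfaces(transport_from$surfaces, x)
    return(structure(list(x = x, y = y, arms = arms, K = K,
                          g = gp$values, Q = qs$Q, m = qs$m),
                     class = "itr_nuisances"))
  }
  K <- max(arms)
  g <- estimate_propensities(x, arms, K = K, roster = roster,
                             n_folds = n_folds,
                             seed = child_seed(seed, 11L), delta = delta)
  surf <- estimate_outcome_surfaces(x, arms, y, K = K, roster = roster,
                                    n_folds = n_folds,
                                    seed = child_seed(seed, 12L))
  structure(list(x = x, y = y, arms = arms, K = K,
                 g = g$values, Q = surf$Q, m = surf$m),
            class = "itr_nuisances")
}

#' Evaluate a treatment rule on a holdout sample
#'
#' Dispatches on the rule kind: learned and static rules are valued by
#' [tmle_rule_value()]; stochastic rules combine the static single-arm
#' TMLE estimates linearly; the factual rule is reported as the raw
#' observed success rate (the conventional observed-allocation
#' comparator).
#'
#' @param rule a `"treatment_rule"` or a fitted [itr()] object (its
#'   learned rule is used).
#' @param nuisances an `"itr_nuisances"` object from
#'   [holdout_nuisances()].
#' @param itr_fit when `rule` is learned and was built by [itr()], the
#'   fit used to map covariates to recommendations (defaults to `rule`
#'   itself when an `itr` object is passed).
#' @return a `"rule_value"`.
#' @export
evaluate_rule <- function(rule, nuisances, itr_fit = NULL) {
  stopifnot(inherits(nuisances, "itr_nuisances"))
  if (inherits(rule, "itr")) {
    itr_fit <- rule
    rule <- rule$rule
  }
  stopifnot(inherits(rule, "treatment_rule"))
  y <- nuisances$y; arms <- nuisances$arms
  switch(rule$kind,
    factual = observed_success_rate(y),
    static = tmle_rule_value(y, arms, rep(rule$arm, length(y)),
                             nuisances$g, nuisances$Q),
    learned = {
      d <- rule_arms(rule, newdata = nuisances$x)
      tmle_rule_value(y, arms, d, nuisances$g, nuisances$Q)
    },
    stochastic = {
      ests <- vector("list", nuisances$K)
      for (a in which(rule$weights > 0)) {
        ests[[a]] <- tmle_rule_value(y, arms, rep(a, length(y)),
                                     nuisances$g, nuisances$Q)
      }
      stochastic_rule_value(ests, rule$weights)
    })
}

#' Full holdout evaluation of a fitted ITR
#'
#' Values the learned rule and the standard comparator allocations on a
#' holdout sample: the observed allocation, uniform randomisation
#' across arms, randomisation in the observed prescription proportions,
#' and every single-arm scheme with enough recipients. One-sided
#' influence-curve contrasts of the learned rule against each comparator
#' are included.
#'
#' @param fit a fitted [itr()] object.
#' @param data holdout data frame.
#' @param roster,n_folds,seed,delta controls for the holdout nuisance
#'   refits (defaults mirror the fit).
#' @param min_arm_n single-arm schemes are skipped for arms with fewer
#'   holdout recipients.
#' @param transport if `TRUE`, transport the training nuisance fits
#'   instead of refitting on the holdout.
#' @return object of class `"itr_evaluation"`: `estimates` (named list
#'   of `"rule_value"`), `comparisons` (named list of
#'   `"rule_comparison"` vs the learned rule), `recommended`
#'   (per-patient arms), and `nuisances`.
#' @export
evaluate_itr <- function(fit, data, roster = fit$roster,
                         n_folds = fit$n_folds, seed = fit$seed + 1000L,
                         delta = fit$delta, min_arm_n = 25,
                         transport = FALSE) {
  stopifnot(inherits(fit, "itr"))
  nuis <- holdout_nuisances(fit$formula, data, fit$treatment, roster,
                            n_folds, seed, delta,
                            transport_from = if (transport) fit else NULL)
  K <- fit$K
  n <- length(nuis$y)
  rec <- rule_arms(fit$rule, newdata = nuis$x)

  est <- list()
  est$itr <- evaluate_rule(fit, nuis)
  est$observed <- observed_success_rate(nuis$y)
  shares <- tabulate(nuis$arms, K) / n
  static <- vector("list", K)
  for (a in seq_len(K)) {
    if (sum(nuis$arms == a) >= min_arm_n) {
      static[[a]] <- tmle_rule_value(nuis$y, nuis$arms, rep(a, n),
                                     nuis$g, nuis$Q)
    }
  }
  have_all <- !vapply(static, is.null, logical(1))
  if (all(have_all)) {
    est$uniform <- stochastic_rule_value(static, rep(1 / K, K))
    est$proportional <- stochastic_rule_value(static, shares)
  } else if (any(have_all)) {
    # restrict stochastic comparators to arms with estimable values
    w_u <- ifelse(have_all, 1, 0); w_u <- w_u / sum(w_u)
    w_p <- ifelse(have_all, shares, 0)
    if (sum(w_p) > 0) w_p <- w_p / sum(w_p)
    est$uniform <- stochastic_rule_value(static, w_u)
    est$proportional <- stochastic_rule_value(static, w_p)
  }
  names(static) <- fit$medications
  est$static <- static

  comp <- list()
  safe_compare <- function(a, b) {
    # a degenerate contrast (e.g. the learned rule coincides with a
    # single-arm scheme) has no variance; report nothing rather than fail
    tryCatch(compare_rules(a, b), error = function(e) NULL)
  }
  for (nm in c("observed", "uniform", "proportional")) {
    if (!is.null(est[[nm]]))
      comp[[paste0("itr_vs_", nm)]] <- safe_compare(est$itr, est[[nm]])
  }
  for (a in which(have_all)) {
    comp[[paste0("itr_vs_", fit$medications[a])]] <-
      safe_compare(est$itr, static[[a]])
  }
  structure(list(estimates = est, comparisons = comp, recommended = rec,
                 nuisances = nuis, medications = fit$medications,
                 observed_shares = shares, n = n),
            class = "itr_evaluation")
}

#' @export
print.itr_evaluation <- function(x, ...) {
  cat("Holdout evaluation (n =", x$n, ")\n")
  show <- function(nm, e) {
    if (is.null(e)) return()
    cat(sprintf("  %-13s %5.1f%% (SE %.1f%%)\n", nm, 100 * e$value,
                100 * e$se))
  }
  show("ITR", x$estimates$itr)
  show("observed", x$estimates$observed)
  show("uniform", x$estimates$uniform)
  show("proportional", x$estimates$proportional)
  cmp <- x$comparisons$itr_vs_observed
  if (!is.null(cmp))
    cat(sprintf("  ITR vs observed: z = %.2f, one-sided p = %.3g, NNT %.1f\n",
                cmp$z, cmp$p_one_sided, cmp$nnt))
  invisible(x)
}
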