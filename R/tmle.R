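#' TMLE of the mean outcome under a deterministic rule
#'
#' Targeted minimum loss-based estimation of the value of a rule (the
#' mean success probability if everyone were treated by it). Starting
#' from the outcome-surface plug-in, a one-dimensional logistic
#' fluctuation along the clever covariate
#' \eqn{H_i = 1\{A_i = d(X_i)\}/\hat g_{d(X_i)}(X_i)} is fit by maximum
#' likelihood (Newton iterations) until the efficient-influence-curve
#' score equation \eqn{\sum_i H_i (Y_i - Q^*_i) = 0} is solved, which is
#' what makes the influence-curve standard error valid.
#'
#' @param y binary outcome on the evaluation sample.
#' @param arms observed arm per patient.
#' @param d_arms arm the rule assigns each patient.
#' @param g `n x K` truncated propensity matrix (or
#'   `"propensity_matrix"`).
#' @param Q `n x K` outcome-surface matrix (or `"outcome_surfaces"`,
#'   whose `Q` is used).
#' @param max_iter,tol fluctuation controls.
#' @return object of class `"rule_value"`: `value`, `se`, `ci95`,
#'   `influence_values`, `n`, plus `epsilon` and `score_residual`
#'   diagnostics.
#' @export
tmle_rule_value <- function(y, arms, d_arms, g, Q, max_iter = 100,
                            tol = 1e-8) {
  gv <- if (inherits(g, "propensity_matrix")) g$values else as.matrix(g)
  Qm <- if (inherits(Q, "outcome_surfaces")) Q$Q else as.matrix(Q)
  y <- as.numeric(y)
  n <- length(y)
  i <- seq_len(n)
  stopifnot(length(arms) == n, length(d_arms) == n,
            nrow(gv) == n, nrow(Qm) == n)
  bound <- 1e-4
  l_obs <- stats::qlogis(clip(Qm[cbind(i, arms)], bound, 1 - bound))
  l_d <- stats::qlogis(clip(Qm[cbind(i, d_arms)], bound, 1 - bound))
  H_d <- 1 / gv[cbind(i, d_arms)]
  H <- as.numeric(arms == d_arms) * H_d

  eps <- 0
  if (any(H > 0)) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      q <- stats::plogis(l_obs + eps * H)
      score <- sum(H * (y - q))
      if (abs(score) < tol) { converged <- TRUE; break }
      info <- sum(H^2 * q * (1 - q))
      if (info < 1e-12) break
      step <- score / info
      # step-halving keeps the one-dimensional Newton update stable
      step <- clip(step, -4, 4)
      eps <- eps + step
    }
    if (!converged) {
      q <- stats::plogis(l_obs + eps * H)
      score <- sum(H * (y - q))
      if (abs(score) > 1e-6) {
        stop(sprintf(paste0("TMLE fluctuation did not converge: score ",
                            "residual %.3g after %d iterations (epsilon = %.3g)"),
                     score, max_iter, eps), call. = FALSE)
      }
    }
  }
  q_obs <- stats::plogis(l_obs + eps * H)
  q_d <- stats::plogis(l_d + eps * H_d)
  value <- mean(q_d)
  ic <- H * (y - q_obs) + q_d - value
  se <- stats::sd(ic) / sqrt(n)
  structure(list(value = value, se = se,
                 ci95 = value + c(-1, 1) * stats::qnorm(0.975) * se,
                 influence_values = ic, n = n,
                 epsilon = eps, score_residual = sum(H * (y - q_obs))),
            class = "rule_value")
}

#' Value of a stochastic allocation from static-arm estimates
#'
#' The mean outcome under "randomise patients across arms with weights
#' w" is the w-combination of the single-arm values; the influence
#' values combine with the same weights, giving the standard error of
#' the combined estimate.
#'
#' @param estimates list of `"rule_value"` objects, one per arm (indexed
#'   by arm; arms with zero weight may be `NULL`).
#' @param weights nonnegative weights summing to one.
#' @return a `"rule_value"`.
#' @export
stochastic_rule_value <- function(estimates, weights) {
  w <- as.numeric(weights)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop_config("weights must be nonnegative and sum to 1")
  sup <- which(w > 0)
  for (a in sup) if (is.null(estimates[[a]]))
    stop_config("weight on arm %d but no estimate supplied for it", a)
  n <- estimates[[sup[1]]]$n
  ic <- numeric(n)
  value <- 0
  for (a in sup) {
    stopifnot(estimates[[a]]$n == n)
    value <- value + w[a] * estimates[[a]]$value
    ic <- ic + w[a] * estimates[[a]]$influence_values
  }
  se <- stats::sd(ic) / sqrt(n)
  structure(list(value = value, se = se,
                 ci95 = value + c(-1, 1) * stats::qnorm(0.975) * se,
                 influence_values = ic, n = n),
            class = "rule_value")
}

#' Observed success rate
#'
#' The factual-allocation comparator: the raw empirical success rate
#' with a binomial standard error. Its influence values (`y - p`) allow
#' correlated contrasts against TMLE estimates on the same sample.
#'
#' @param y binary outcomes.
#' @return a `"rule_value"`.
#' @export
observed_success_rate <- function(y) {
  y <- as.numeric(y)
  n <- length(y)
  p <- mean(y)
  se <- sqrt(p * (1 - p) / n)
  structure(list(value = p, se = se,
                 ci95 = p + c(-1, 1) * stats::qnorm(0.975) * se,
                 influence_values = y - p, n = n),
            class = "rule_value")
}

#' @export
print.rule_value <- function(x, ...) {
  cat(sprintf("Rule value: %.1f%% (SE %.1f%%), 95%% CI [%.1f, %.1f], n = %d\n",
              100 * x$value, 100 * x$se, 100 * x$ci95[1], 100 * x$ci95[2],
              x$n))
  invisible(x)
}

#' Compare two rule-value estimates
#'
#' One-sided test that the first rule's value exceeds the second's,
#' using the normal reference (at evaluation-sample sizes in the
#' thousands this is indistinguishable from the t reference). When both
#' estimates carry influence values on the same sample, the contrast
#' standard error comes from the per-patient difference of influence
#' values (the correlated form); otherwise variances combine
#' independently.
#'
#' @param est_rule,est_reference `"rule_value"` objects.
#' @param correlated use the influence-curve contrast (default `TRUE`).
#' @return object of class `"rule_comparison"` with the two values, the
#'   contrast `z`, `p_one_sided`, `nnt`, and `proportional_ratio`.
#' @export
compare_rules <- function(est_rule, est_reference, correlated = TRUE) {
  v1 <- est_rule$value; v2 <- est_reference$value
  if (correlated) {
    stopifnot(est_rule$n == est_reference$n)
    dic <- est_rule$influence_values - est_reference$influence_values
    se <- stats::sd(dic) / sqrt(est_rule$n)
  } else {
    se <- sqrt(est_rule$se^2 + est_reference$se^2)
  }
  if (se < 1e-12) stop_config("zero contrast variance")
  z <- (v1 - v2) / se
  structure(list(
    value_rule = v1, value_reference = v2, se = se, z = z,
    p_one_sided = 1 - stats::pnorm(z),
    nnt = if (abs(v1 - v2) > 1e-12) nnt(100 * v1, 100 * v2) else NA_real_,
    proportional_ratio = if (v2 > 0) proportional_ratio(100 * v1, 100 * v2)
                         else NA_real_
  ), class = "rule_comparison")
}

#' @export
print.rule_comparison <- function(x, ...) {
  cat(sprintf("Rule comparison: %.1f%% vs %.1f%% (z = %.2f, one-sided p = %.3g)\n",
              100 * x$value_rule, 100 * x$value_reference, x$z, x$p_one_sided))
  if (!is.na(x$nnt))
    cat(sprintf("  NNT %.1f, proportional ratio %.2f\n", x$nnt,
                x$proportional_ratio))
  invisible(x)
}

#' Number needed to treat
#'
#' Reciprocal of the absolute risk difference: `100 / (p_rule -
#' p_reference)` with both rates in percent, reported to one decimal.
#' The sign is preserved, so a harmful contrast yields a negative NNT.
#'
#' @param p_rule,p_reference success rates in percent (e.g. 51.7).
#' @return NNT rounded half-up to one decimal.
#' @export
#' @examples
#' nnt(51.7, 44.5) # 13.9
nnt <- function(p_rule, p_reference) {
  if (abs(p_rule - p_reference) < 1e-12)
    stop_config("NNT undefined for equal success rates")
  round_half_up(100 / (p_rule - p_reference), 1)
}

#' Proportional success ratio
#'
#' `p_rule / p_reference` (equivalently one plus the relative increase),
#' reported to two decimals.
#'
#' @param p_rule,p_reference success rates in percent.
#' @return ratio rounded half-up to two decimals.
#' @export
#' @examples
#' proportional_ratio(51.7, 44.5) # 1.16
proportional_ratio <- function(p_rule, p_reference) {
  if (p_reference <= 0) stop_config("reference rate must be positive")
  round_half_up(p_rule / p_reference, 2)
}

#' Concordance ratio of prescribing given recommendation
#'
#' The proportion of times a medication was prescribed to patients for
#' whom it was rule-recommended divided by the same proportion among
#' patients for whom it was not. A ratio of 0 is reported whenever the
#' numerator proportion is 0 (including the 0/0 case, matching printed
#' report convention); a positive numerator over a zero denominator is
#' an error.
#'
#' @param pct_when_recommended,pct_when_not proportions in percent.
#' @return ratio rounded half-up to one decimal.
#' @export
#' @examples
#' concordance_ratio(26.2, 9.7) # 2.7
concordance_ratio <- function(pct_when_recommended, pct_when_not) {
  stopifnot(pct_when_recommended >= 0, pct_when_recommended <= 100,
            pct_when_not >= 0, pct_when_not <= 100)
  if (pct_when_recommended == 0) return(0)
  if (pct_when_not == 0)
    stop_config("ratio undefined: zero denominator with positive numerator")
  round_half_up(pct_when_recommended / pct_when_not, 1)
}

#' Per-medication contribution decomposition
#'
#' Decomposes the rule's aggregate improvement across the nonrecommended
#' medications: each medication's contribution is the product of its
#' success-rate difference and its count of patients without their
#' recommended medication, as a percentage of the sum of those products.
#' Contributions sum to 100% and may be negative.
#'
#' @param diffs per-medication success-rate differences (percentage
#'   points).
#' @param counts per-medication counts of patients without their
#'   recommended medication.
#' @return numeric vector of percentage contributions.
#' @export
contribution_decomposition <- function(diffs, counts) {
  stopifnot(length(diffs) == length(counts))
  prod <- diffs * counts
  tot <- sum(prod)
  if (abs(tot) < 1e-12) stop_config("zero total product; decomposition undefined")
  100 * prod / tot
}

#' Per-arm distribution table
#'
#' Counts and percentages (with binomial standard errors) of an arm
#' vector, optionally with a chi-square homogeneity test against a
#' second distribution over the same arms.
#'
#' @param arms integer or factor arm labels.
#' @param medications arm names defining the row order.
#' @param compare optional second arm vector to test homogeneity
#'   against.
#' @return data frame `medication`, `n`, `pct`, `se_pct`; when `compare`
#'   is given, attributes `chisq` and `p_value` carry the test.
#' @export
distribution_table <- function(arms, medications, compare = NULL) {
  if (!length(arms)) {
    out <- data.frame(medication = character(), n = integer(),
                      pct = numeric(), se_pct = numeric())
    return(out)
  }
  f <- factor(medications[as.integer(arms)], levels = medications)
  n <- as.integer(table(f))
  N <- length(arms)
  p <- n / N
  out <- data.frame(medication = medications, n = n,
                    pct = round_half_up(100 * p, 1),
                    se_pct = round_half_up(100 * sqrt(p * (1 - p) / N), 1))
  if (!is.null(compare)) {
    f2 <- factor(medications[as.integer(compare)], levels = medications)
    tab <- rbind(table(f), table(f2))
    keep <- colSums(tab) > 0
    if (identical(as.integer(table(f)), as.integer(table(f2)))) {
      attr(out, "chisq") <- 0
      attr(out, "p_value") <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab[, keep, drop = FALSE]))
      attr(out, "chisq") <- unname(ct$statistic)
      attr(out, "p_value") <- ct$p.value
    }
  }
  out
}

#' Medication-specific success summary
#'
#' For each medication: the observed success rate among its recipients,
#' the estimated success rate if the whole sample received it (static
#' single-arm TMLE), the contrast between the rule's value and that
#' single-arm value, and the observed success rate among patients for
#' whom the rule recommends it. Arms below the support threshold are
#' marked unavailable.
#'
#' @param y,arms outcome and observed arms on the evaluation sample.
#' @param rec_arms the rule's recommended arm per patient.
#' @param static_estimates list of `"rule_value"` per arm (NULL where
#'   unavailable).
#' @param itr_estimate `"rule_value"` of the learned rule.
#' @param medications arm names.
#' @param min_support arms with fewer recipients than this are marked
#'   `NA` (default 0 = no masking beyond missing estimates).
#' @return data frame, one row per medication.
#' @export
medication_specific_summary <- function(y, arms, rec_arms, static_estimates,
                                        itr_estimate, medications,
                                        min_support = 0) {
  K <- length(medications)
  rows <- lapply(seq_len(K), function(a) {
    ra <- which(arms == a)
    n_a <- length(ra)
    obs <- if (n_a) mean(y[ra]) else NA_real_
    obs_se <- if (n_a > 1) sqrt(obs * (1 - obs) / n_a) else NA_real_
    est <- static_estimates[[a]]
    avail <- !is.null(est) && n_a >= min_support
    rec <- which(rec_arms == a)
    rec_obs <- if (length(rec)) mean(y[rec]) else NA_real_
    diff <- diff_se <- NA_real_
    if (avail && !is.null(itr_estimate)) {
      # degenerate contrasts (rule identical to this arm) have no variance
      cmp <- tryCatch(compare_rules(itr_estimate, est, correlated = TRUE),
                      error = function(e) NULL)
      if (!is.null(cmp)) {
        diff <- 100 * (cmp$value_rule - cmp$value_reference)
        diff_se <- 100 * cmp$se
      }
    }
    data.frame(
      medication = medications[a],
      n_received = n_a,
      obs_success_pct = round_half_up(100 * obs, 1),
      obs_success_se = round_half_up(100 * obs_se, 1),
      est_if_all_pct = if (avail) round_half_up(100 * est$value, 1) else NA_real_,
      est_if_all_se = if (avail) round_half_up(100 * est$se, 1) else NA_real_,
      itr_minus_arm_pct = round_half_up(diff, 1),
      itr_minus_arm_se = round_half_up(diff_se, 1),
      n_recommended = length(rec),
      rec_subset_success_pct = round_half_up(100 * rec_obs, 1))
  })
  do.call(rbind, rows)
}
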