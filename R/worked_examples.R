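#' Worked-example arithmetic from packaged report tables
#'
#' The package ships, as plain-text fixtures, the printed inputs of the
#' published report tables for a 15-medication first-episode
#' schizophrenia ITR analysis: headline success rates under the rule and
#' its comparators, per-medication prescribing proportions given
#' recommendation, per-medication success-rate differences with counts
#' of discordantly treated patients, and the observed/recommended
#' medication distributions. This function recomputes every derived
#' quantity — number needed to treat, proportional success ratios,
#' concordance ratios, the contribution decomposition, and
#' count-derived percentages — with the package's own arithmetic so the
#' derivations can be checked against the printed values. Cells whose
#' printed inputs are internally inconsistent are flagged
#' (`consistent = 0`) and carried through unasserted.
#'
#' @return list of data frames: `headline` (with `computed_ratio`,
#'   `computed_nnt`), `concordance` (with `computed_ratio`),
#'   `contributions` (with `computed_contribution_pct`),
#'   `distribution` (with computed percentage columns), and
#'   `observed_success` (with `computed_success_pct`).
#' @export
worked_examples <- function() {
  path <- function(f) system.file("extdata", f, package = "itrlearn",
                                  mustWork = TRUE)
  headline <- utils::read.csv(path("headline_rates.csv"))
  headline$computed_ratio <- mapply(proportional_ratio,
                                    headline$rate_rule_pct,
                                    headline$rate_reference_pct)
  headline$computed_nnt <- mapply(nnt, headline$rate_rule_pct,
                                  headline$rate_reference_pct)

  conc <- utils::read.csv(path("table2_concordance.csv"))
  conc$computed_ratio <- mapply(concordance_ratio, conc$pct_recommended,
                                conc$pct_not_recommended)

  contrib <- utils::read.csv(path("table5_contributions.csv"))
  contrib$computed_contribution_pct <- round_half_up(
    contribution_decomposition(contrib$diff_pct,
                               contrib$count_without_recommended), 1)

  dist <- utils::read.csv(path("table1_distribution.csv"))
  dist$computed_train_pct <- round_half_up(100 * dist$train_n /
                                             sum(dist$train_n), 1)
  dist$computed_valid_pct <- round_half_up(100 * dist$valid_n /
                                             sum(dist$valid_n), 1)
  dist$computed_rec_pct <- round_half_up(100 * dist$rec_n /
                                           sum(dist$rec_n), 1)

  obs <- utils::read.csv(path("table3_observed_success.csv"))
  obs$computed_success_pct <- round_half_up(100 * obs$n_success /
                                              obs$n_received, 1)

  list(headline = headline, concordance = conc, contributions = contrib,
       distribution = dist, observed_success = obs)
}
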