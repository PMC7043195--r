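#' Construct a treatment rule
#'
#' Rules come in four kinds: `static` (everyone gets one arm),
#' `stochastic` (patients are randomised across arms with fixed weights,
#' e.g. uniform 1/K or the observed prescription shares), `factual` (the
#' arm each patient actually received), and `learned` (the argmax of
#' fitted per-arm difference scores; built internally by [itr()]).
#'
#' @param kind one of `"static"`, `"stochastic"`, `"factual"`.
#' @param arm the single arm index, for static rules.
#' @param weights nonnegative weights over arms summing to one, for
#'   stochastic rules.
#' @param n_arms number of arms (used for validation).
#' @return an object of class `"treatment_rule"`.
#' @export
make_rule <- function(kind = c("static", "stochastic", "factual"),
                      arm = NULL, weights = NULL, n_arms = NULL) {
  kind <- match.arg(kind)
  if (kind == "static") {
    if (is.null(arm)) stop_config("static rule needs an arm")
    if (!is.null(n_arms) && (arm < 1 || arm > n_arms))
      stop_config("static arm %d outside [1, %d]", arm, n_arms)
    return(structure(list(kind = "static", arm = as.integer(arm)),
                     class = "treatment_rule"))
  }
  if (kind == "stochastic") {
    if (is.null(weights)) stop_config("stochastic rule needs weights")
    w <- as.numeric(weights)
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
      stop_config("stochastic weights must be nonnegative and sum to 1")
    if (!is.null(n_arms) && length(w) != n_arms)
      stop_config("need one weight per arm")
    return(structure(list(kind = "stochastic", weights = w),
                     class = "treatment_rule"))
  }
  structure(list(kind = "factual"), class = "treatment_rule")
}

# learned rule: carries the fitted second-stage models and eligible arms
new_learned_rule <- function(cate_fits, eligible_arms, medications) {
  if (!length(eligible_arms)) stop_config("eligible-arm set is empty")
  structure(list(kind = "learned", cate_fits = cate_fits,
                 eligible_arms = as.integer(eligible_arms),
                 medications = medications),
            class = "treatment_rule")
}

#' Per-patient arms selected by a rule
#'
#' @param rule a `"treatment_rule"`.
#' @param newdata covariates (needed for learned rules).
#' @param arms observed arms (needed for factual rules).
#' @param n number of patients (needed for static rules when `newdata`
#'   is absent).
#' @return integer vector of arm indices; stochastic rules have no
#'   deterministic arm and raise an error.
#' @export
rule_arms <- function(rule, newdata = NULL, arms = NULL, n = NULL) {
  stopifnot(inherits(rule, "treatment_rule"))
  switch(rule$kind,
    static = rep(rule$arm, n %||% nrow(newdata)),
    factual = {
      if (is.null(arms)) stop_config("factual rule needs the observed arms")
      as.integer(arms)
    },
    learned = {
      if (is.null(newdata)) stop_config("learned rule needs covariates")
      scores <- predict_cate(rule$cate_fits, newdata, rule$eligible_arms)
      # argmax over eligible arms; ties go to the lowest arm index in
      # the configured medication order
      rule$eligible_arms[max.col(scores, ties.method = "first")]
    },
    stochastic = stop_config("a stochastic rule has no per-patient arm"))
}

# n x |eligible| matrix of fitted difference scores
predict_cate <- function(cate_fits, newdata, eligible_arms) {
  sapply(eligible_arms, function(a) predict(cate_fits[[a]], newdata))
}

#' @export
print.treatment_rule <- function(x, ...) {
  switch(x$kind,
    static = cat("Static rule: arm", x$arm, "\n"),
    stochastic = cat("Stochastic rule: weights",
                     paste(signif(x$weights, 3), collapse = " "), "\n"),
    factual = cat("Factual rule (observed assignment)\n"),
    learned = cat("Learned ITR over arms {",
                  paste(x$eligible_arms, collapse = ", "), "}\n"))
  invisible(x)
}
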