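#' Estimate per-arm propensity scores
#'
#' One-vs-rest Super Learner probability fit per arm, so every roster
#' member (including binary-only learners) can participate. Rows are
#' renormalised to sum to one and then clipped below at the truncation
#' bound `delta`; clipped cells are intended for inverse-weighting
#' denominators only, so no renormalisation follows the clipping.
#'
#' @param x covariate matrix/data frame.
#' @param arms integer arm assignments in `1:K`.
#' @param K number of arms.
#' @param roster candidate learners.
#' @param n_folds,seed,folds cross-validation controls (see
#'   [fit_super_learner()]).
#' @param delta truncation bound in `(0, 1/K)` (default 0.01).
#' @return object of class `"propensity_matrix"`: `values` (truncated),
#'   `raw` (renormalised, pre-truncation), `delta`, `truncated_count`,
#'   and the per-arm fits.
#' @export
estimate_propensities <- function(x, arms, K = max(arms),
                                  roster = default_roster(heavy = FALSE),
                                  n_folds = 10, seed = 1, folds = NULL,
                                  delta = 0.01) {
  arms <- as.integer(arms)
  if (length(unique(arms)) < 2) stop_config("need >= 2 arms present to fit propensities")
  if (delta <= 0 || delta >= 1 / K)
    stop_config("delta must lie in (0, 1/K)")
  xm <- covariate_matrix(x)
  if (is.null(folds)) folds <- make_cv_folds(nrow(xm), n_folds, seed,
                                             stratify_labels = arms)
  fits <- vector("list", K)
  g <- matrix(NA_real_, nrow(xm), K)
  for (a in seq_len(K)) {
    if (!any(arms == a)) next
    fits[[a]] <- fit_super_learner(xm, as.numeric(arms == a), roster,
                                   seed = seed, task = "bounded",
                                   folds = folds)
    g[, a] <- predict(fits[[a]], xm)
  }
  present <- which(!vapply(fits, is.null, logical(1)))
  g[, setdiff(seq_len(K), present)] <- 0
  rs <- rowSums(g)
  rs[rs < 1e-12] <- 1
  raw <- g / rs
  values <- raw
  clipped <- values < delta
  clipped[, setdiff(seq_len(K), present)] <- FALSE
  values[values < delta] <- delta
  structure(list(values = values, raw = raw, delta = delta,
                 truncated_count = sum(clipped), fits = fits,
                 arms_present = present, folds = folds),
            class = "propensity_matrix")
}

# evaluate fitted propensity models on new covariates
predict_propensities <- function(g, newdata) {
  stopifnot(inherits(g, "propensity_matrix"))
  xm <- covariate_matrix(newdata)
  K <- length(g$fits)
  out <- matrix(0, nrow(xm), K)
  for (a in g$arms_present) out[, a] <- predict(g$fits[[a]], xm)
  rs <- rowSums(out)
  rs[rs < 1e-12] <- 1
  raw <- out / rs
  val <- raw
  val[val < g$delta] <- g$delta
  list(values = val, raw = raw)
}

#' Estimate outcome surfaces
#'
#' Two Super Learner regressions: `Q`, the probability of success given
#' covariates and arm (one fit on covariates plus arm indicators,
#' evaluated at each counterfactual arm), and `m`, the population
#' success probability given covariates alone. `m` is fit directly on
#' the covariates rather than assembled as the propensity-weighted
#' combination of the `Q` columns; the identity between the two holds at
#' the true parameters and is available as a diagnostic.
#'
#' @inheritParams estimate_propensities
#' @param y binary success outcome.
#' @param interactions include arm-by-covariate product columns in the
#'   design (default `TRUE`), letting linear learners express
#'   heterogeneous effects.
#' @return object of class `"outcome_surfaces"` with `Q` (`n x K`), `m`
#'   (length-`n`), and the underlying fits.
#' @export
estimate_outcome_surfaces <- function(x, arms, y, K = max(arms),
                                      roster = default_roster(heavy = FALSE),
                                      n_folds = 10, seed = 1, folds = NULL,
                                      interactions = TRUE) {
  xm <- covariate_matrix(x)
  y <- as.numeric(y)
  arms <- as.integer(arms)
  n <- nrow(xm)
  if (is.null(folds)) folds <- make_cv_folds(n, n_folds, seed,
                                             stratify_labels = y)
  if (stats::var(y) < 1e-12) {
    warning("degenerate outcome (all ", y[1], "); surfaces are constant",
            call. = FALSE)
    return(structure(list(Q = matrix(y[1], n, K), m = rep(y[1], n),
                          fit_q = NULL, fit_m = NULL, K = K),
                     class = "outcome_surfaces"))
  }
  fit_q <- fit_super_learner(q_design(xm, arms, K, interactions), y,
                             roster, seed = seed, task = "bounded",
                             folds = folds)
  Q <- sapply(seq_len(K), function(a) {
    predict(fit_q, q_design(xm, rep(a, n), K, interactions))
  })
  fit_m <- fit_super_learner(xm, y, roster, seed = seed, task = "bounded",
                             folds = folds)
  structure(list(Q = matrix(Q, n), m = predict(fit_m, xm),
                 fit_q = fit_q, fit_m = fit_m, K = K,
                 interactions = interactions),
            class = "outcome_surfaces")
}

# K-1 dummy columns (arm 1 = reference cell)
arm_dummies <- function(arms, K) {
  d <- matrix(0, length(arms), K - 1,
              dimnames = list(NULL, paste0("arm", 2:K)))
  for (a in 2:K) d[arms == a, a - 1] <- 1
  d
}

# outcome-stage design: covariates, arm dummies, optional products
q_design <- function(xm, arms, K, interactions) {
  ad <- arm_dummies(arms, K)
  if (!interactions) return(cbind(xm, ad))
  inter <- do.call(cbind, lapply(seq_len(ncol(ad)), function(j) {
    out <- xm * ad[, j]
    colnames(out) <- paste0(colnames(ad)[j], "_x_", colnames(xm))
    out
  }))
  cbind(xm, ad, inter)
}

# evaluate Q at counterfactual arms on new covariates
predict_outcome_surfaces <- function(surfaces, newdata) {
  stopifnot(inherits(surfaces, "outcome_surfaces"))
  xm <- covariate_matrix(newdata)
  K <- surfaces$K
  n <- nrow(xm)
  if (is.null(surfaces$fit_q)) {
    return(list(Q = matrix(surfaces$Q[1], n, K), m = rep(surfaces$m[1], n)))
  }
  Q <- sapply(seq_len(K), function(a) {
    predict(surfaces$fit_q, q_design(xm, rep(a, n), K, surfaces$interactions))
  })
  list(Q = matrix(Q, n), m = predict(surfaces$fit_m, xm))
}

#' Doubly robust difference scores
#'
#' The AIPW pseudo-outcome contrasting each arm with the observed
#' population:
#' \deqn{D_{ia} = \frac{1\{A_i = a\}}{\hat g_a(X_i)}\,(Y_i - \hat Q_a(X_i))
#'   + \hat Q_a(X_i) - \hat m(X_i),}
#' with the truncated propensity in the denominator. Column `a` is an
#' approximately unbiased estimate of \eqn{\mu_a(X) - m(X)}: consistent
#' when either the propensity model or the outcome model is correct.
#'
#' @param y binary outcome.
#' @param arms integer arm assignments.
#' @param g a `"propensity_matrix"` (or a bare `n x K` probability
#'   matrix, taken as already truncated).
#' @param surfaces an `"outcome_surfaces"` object (or a list with `Q`
#'   and `m`).
#' @return `n x K` numeric matrix of difference scores.
#' @export
compute_difference_scores <- function(y, arms, g, surfaces) {
  gv <- if (inherits(g, "propensity_matrix")) g$values else as.matrix(g)
  Q <- surfaces$Q
  m <- surfaces$m
  y <- as.numeric(y)
  n <- length(y); K <- ncol(gv)
  stopifnot(nrow(gv) == n, all(dim(Q) == c(n, K)), length(m) == n)
  if (inherits(g, "propensity_matrix") &&
      any(gv[, g$arms_present, drop = FALSE] < g$delta - 1e-12))
    stop("internal error: propensity cell below the truncation bound")
  ind <- matrix(0, n, K)
  ind[cbind(seq_len(n), arms)] <- 1
  D <- ind / gv * (y - Q) + Q - m
  if (any(!is.finite(D))) stop("difference scores contain non-finite values")
  D
}

#' Second-stage models for per-arm difference scores
#'
#' One Super Learner regression of each arm's difference-score column on
#' the covariates (unbounded target, no clipping). These fitted surfaces
#' estimate the arm-vs-population treatment-effect heterogeneity
#' directly; their argmax defines the learned rule.
#'
#' @inheritParams estimate_propensities
#' @param D difference-score matrix from [compute_difference_scores()].
#' @param eligible_arms arms to fit (others are skipped).
#' @return list of `super_learner` fits indexed by arm.
#' @export
fit_cate_models <- function(x, D, eligible_arms = seq_len(ncol(D)),
                            roster = default_roster(heavy = FALSE),
                            n_folds = 10, seed = 1, folds = NULL) {
  xm <- covariate_matrix(x)
  if (any(!is.finite(D))) stop_config("difference scores must be finite")
  if (is.null(folds)) folds <- make_cv_folds(nrow(xm), n_folds, seed)
  fits <- vector("list", ncol(D))
  for (a in eligible_arms) {
    fits[[a]] <- fit_super_learner(xm, D[, a], roster, seed = seed,
                                   task = "unbounded", folds = folds)
  }
  fits
}

#' Fit an individualized treatment rule
#'
#' The two-stage doubly robust ITR estimator. Stage one fits, by
#' cross-validated Super Learner: per-arm propensity scores (one-vs-rest,
#' truncated at `delta`), the success probability given covariates and
#' arm, and the population success probability given covariates; these
#' are combined into AIPW difference scores contrasting each arm with
#' the observed population. Stage two regresses each arm's difference
#' scores on the covariates, and the rule assigns each patient the
#' eligible arm with the highest fitted score (ties to the lowest arm
#' index in the configured medication order).
#'
#' @param formula model formula `outcome ~ covariates` (use `.` for all
#'   columns other than the outcome and treatment).
#' @param data data frame holding the outcome, covariates and treatment.
#' @param treatment name of the treatment-arm column (integer codes
#'   `1:K` or a factor).
#' @param roster candidate learners for every Super Learner stage.
#' @param n_folds cross-validation folds (default 10).
#' @param delta propensity truncation bound (default 0.01).
#' @param min_arm_n arms observed fewer than this many times are dropped
#'   from the eligible set (default 25).
#' @param seed master seed; stage seeds are derived from it.
#' @param shared_folds if `TRUE` (default) the propensity and outcome
#'   stages share one fold assignment.
#' @param pseudo_outcome `"aipw"` (default) for the augmented difference
#'   score, or `"plugin"` for the unaugmented `Q - m` contrast.
#' @param medications optional arm names for reporting.
#' @return an object of class `"itr"` with the fitted nuisances
#'   (`propensities`, `surfaces`), `difference_scores`, second-stage
#'   `cate_fits`, the learned `rule`, `eligible_arms`, and bookkeeping.
#' @examples
#' coh <- simulate_cohort(default_sim_config(n_patients = 600, seed = 7))
#' d <- coh$data
#' fit <- itr(y ~ age + ed_visits + benzodiazepine + mood_stabilizer,
#'            data = d, treatment = "arm",
#'            roster = list(lrn_mean(), lrn_glm()), n_folds = 5, seed = 7)
#' table(predict(fit, d))
#' @export
itr <- function(formula, data, treatment = "arm",
                roster = default_roster(heavy = FALSE),
                n_folds = 10, delta = 0.01, min_arm_n = 25, seed = 1,
                shared_folds = TRUE,
                pseudo_outcome = c("aipw", "plugin"),
                medications = NULL) {
  pseudo_outcome <- match.arg(pseudo_outcome)
  cl <- match.call()
  stopifnot(is.data.frame(data), treatment %in% names(data))
  arms_raw <- data[[treatment]]
  arms <- if (is.factor(arms_raw)) as.integer(arms_raw) else as.integer(arms_raw)
  K <- if (is.factor(arms_raw)) nlevels(arms_raw) else max(arms)
  if (is.null(medications)) {
    medications <- if (is.factor(arms_raw)) levels(arms_raw) else
      paste0("arm", seq_len(K))
  }
  mf_data <- data[setdiff(names(data), treatment)]
  mf <- stats::model.frame(formula, data = mf_data)
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1))) stop_config("outcome must be binary 0/1")
  x <- stats::model.matrix(stats::delete.response(stats::terms(mf)), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  n <- nrow(x)

  tab <- tabulate(arms, K)
  eligible <- which(tab >= max(1L, min_arm_n))
  if (!length(eligible)) stop_config("no arm meets min_arm_n = %d", min_arm_n)
  if (length(eligible) < K)
    warning(sprintf("arm(s) %s below min_arm_n; dropped from the eligible set",
                    paste(setdiff(seq_len(K), eligible), collapse = ", ")),
            call. = FALSE)

  seed_g <- child_seed(seed, 1L)
  seed_q <- if (shared_folds) seed_g else child_seed(seed, 2L)
  seed_d <- child_seed(seed, 3L)

  g <- estimate_propensities(x, arms, K = K, roster = roster,
                             n_folds = n_folds, seed = seed_g, delta = delta)
  surf <- estimate_outcome_surfaces(x, arms, y, K = K, roster = roster,
                                    n_folds = n_folds, seed = seed_q)
  D <- if (pseudo_outcome == "aipw") {
    compute_difference_scores(y, arms, g, surf)
  } else {
    surf$Q - surf$m
  }
  cate <- fit_cate_models(x, D, eligible_arms = eligible, roster = roster,
                          n_folds = n_folds, seed = seed_d)
  rule <- new_learned_rule(cate, eligible, medications)

  structure(list(
    call = cl, formula = formula, treatment = treatment,
    medications = medications, n = n, K = K,
    arms = arms, y = y, x_names = colnames(x),
    propensities = g, surfaces = surf, difference_scores = D,
    cate_fits = cate, rule = rule, eligible_arms = eligible,
    delta = delta, n_folds = n_folds, seed = seed, roster = roster,
    pseudo_outcome = pseudo_outcome
  ), class = "itr")
}

# rebuild the stage-one covariate matrix from new data
itr_design <- function(object, newdata) {
  tt <- stats::delete.response(stats::terms(object$formula,
                                            data = newdata[setdiff(names(newdata),
                                                                   object$treatment)]))
  mf <- stats::model.frame(tt, newdata)
  x <- stats::model.matrix(tt, mf)
  x[, colnames(x) != "(Intercept)", drop = FALSE]
}

#' Predict treatment recommendations or difference scores
#'
#' @param object a fitted [itr()] object.
#' @param newdata data frame of patients to score.
#' @param type `"arm"` for the recommended arm index, `"medication"` for
#'   its name, or `"score"` for the `n x |eligible|` matrix of fitted
#'   difference scores.
#' @param ... unused.
#' @return integer vector, character vector, or score matrix.
#' @export
predict.itr <- function(object, newdata,
                        type = c("arm", "medication", "score"), ...) {
  type <- match.arg(type)
  x <- itr_design(object, newdata)
  if (type == "score") {
    s <- predict_cate(object$cate_fits, x, object$eligible_arms)
    colnames(s) <- object$medications[object$eligible_arms]
    return(s)
  }
  arms <- rule_arms(object$rule, newdata = x)
  if (type == "medication") object$medications[arms] else arms
}

#' @export
print.itr <- function(x, ...) {
  cat("Individualized treatment rule (two-stage doubly robust estimator)\n")
  cat(sprintf("  n = %d patients, K = %d arms (%d eligible), %d-fold CV\n",
              x$n, x$K, length(x$eligible_arms), x$n_folds))
  cat(sprintf("  propensity truncation delta = %g (%d cells clipped)\n",
              x$delta, x$propensities$truncated_count))
  s_arm <- max.col(x$difference_scores[, x$eligible_arms, drop = FALSE],
                   ties.method = "first")
  tb <- table(factor(x$medications[x$eligible_arms][s_arm],
                     levels = x$medications))
  cat("  argmax of raw training difference scores:\n")
  print(tb)
  invisible(x)
}

#' @export
summary.itr <- function(object, ...) {
  s_arm <- max.col(object$difference_scores[, object$eligible_arms,
                                            drop = FALSE],
                   ties.method = "first")
  out <- list(
    n = object$n, K = object$K, eligible = object$eligible_arms,
    medications = object$medications,
    truncated = object$propensities$truncated_count,
    delta = object$delta,
    weights = lapply(object$cate_fits[object$eligible_arms],
                     function(f) f$weights),
    observed_arms = table(factor(object$medications[object$arms],
                                 levels = object$medications)),
    score_argmax = table(factor(object$medications[object$eligible_arms][s_arm],
                                levels = object$medications)),
    success_rate = mean(object$y))
  class(out) <- "summary.itr"
  out
}

#' @export
print.summary.itr <- function(x, ...) {
  cat("Two-stage ITR fit\n")
  cat(sprintf("  n = %d, K = %d arms, training success rate %.1f%%\n",
              x$n, x$K, 100 * x$success_rate))
  cat(sprintf("  propensity truncation at %g: %d cells clipped\n",
              x$delta, x$truncated))
  cat("  observed arm distribution:\n")
  print(x$observed_arms)
  cat("  argmax of raw difference scores (training):\n")
  print(x$score_argmax)
  cat("  second-stage ensemble weights per eligible arm:\n")
  for (i in seq_along(x$weights)) {
    cat(sprintf("   %s: ", x$medications[x$eligible[i]]))
    w <- x$weights[[i]]
    cat(paste(sprintf("%s %.2f", names(w), w), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot fitted difference scores by recommended arm
#'
#' Boxplots of each eligible arm's fitted difference score (its
#' estimated success-probability advantage over the observed
#' population), computed on new data.
#'
#' @param x a fitted [itr()] object.
#' @param newdata data frame to score (e.g. the training or holdout
#'   sample).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.itr <- function(x, newdata, ...) {
  s <- predict(x, newdata, type = "score")
  graphics::boxplot(as.data.frame(s),
                    ylab = "fitted difference score (arm vs population)",
                    las = 2, ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
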