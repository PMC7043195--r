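#' Permutation importance of prescriptive predictors
#'
#' Random-forest-style permutation importance applied to a second-stage
#' difference-score model: for each predictor, its column is shuffled
#' (several repetitions with distinct sub-seeds), the model's prediction
#' mean squared error against the arm's difference-score targets is
#' recomputed, and the mean increase over the baseline MSE is reported.
#' Predictors whose permutation does not degrade prediction are
#' prescriptively unimportant for that arm; small negative increases are
#' possible by chance.
#'
#' @param fit a fitted model with a `predict(fit, x)` method (e.g. a
#'   second-stage `super_learner` from an [itr()] object's
#'   `cate_fits`).
#' @param x covariate matrix the model was trained on.
#' @param d_column that arm's difference-score targets.
#' @param n_repetitions permutations per predictor (default 20).
#' @param seed integer seed.
#' @return data frame of class `"importance_report"` with one row per
#'   predictor: `predictor`, `baseline_mse`, `permuted_mse`, `increase`,
#'   `rank` (1 = most important, ties broken by predictor order).
#' @export
permutation_importance <- function(fit, x, d_column, n_repetitions = 20,
                                   seed = 1) {
  if (n_repetitions < 1) stop_config("n_repetitions must be >= 1")
  x <- covariate_matrix(x)
  d <- as.numeric(d_column)
  n <- nrow(x)
  stopifnot(length(d) == n)
  base <- mean((predict(fit, x) - d)^2)
  p <- ncol(x)
  perm_mse <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (r in seq_len(n_repetitions)) {
      set.seed(child_seed(seed, j * 1000L + r))
      xp <- x
      xp[, j] <- xp[sample(n), j]
      acc <- acc + mean((predict(fit, xp) - d)^2)
    }
    perm_mse[j] <- acc / n_repetitions
  }
  inc <- perm_mse - base
  out <- data.frame(
    predictor = colnames(x) %||% paste0("V", seq_len(p)),
    baseline_mse = base, permuted_mse = perm_mse, increase = inc,
    rank = rank(-inc, ties.method = "first"))
  class(out) <- c("importance_report", class(out))
  out
}

#' Importance reports for every arm of a fitted ITR
#'
#' @param fit a fitted [itr()] object.
#' @param data the sample to permute within (by default the training
#'   design is rebuilt from `data`).
#' @param n_repetitions,seed see [permutation_importance()].
#' @return long data frame: `arm`, `medication`, `predictor`,
#'   `increase`, `rank`.
#' @export
itr_importance <- function(fit, data, n_repetitions = 20, seed = 1) {
  stopifnot(inherits(fit, "itr"))
  x <- itr_design(fit, data)
  out <- lapply(fit$eligible_arms, function(a) {
    rep_a <- permutation_importance(fit$cate_fits[[a]], x,
                                    fit$difference_scores[, a],
                                    n_repetitions,
                                    seed = child_seed(seed, a))
    cbind(arm = a, medication = fit$medications[a], rep_a)
  })
  do.call(rbind, out)
}

#' Top-k predictors per arm
#'
#' @param reports one or more importance reports (an
#'   `"importance_report"` or the long table from [itr_importance()]).
#' @param k how many predictors to keep per arm.
#' @return data frame of the `k` largest mean MSE increases per arm,
#'   ties broken by predictor order.
#' @export
top_k_table <- function(reports, k) {
  if (!nrow(reports)) return(reports)
  if (!"arm" %in% names(reports)) reports <- cbind(arm = 1L, reports)
  out <- lapply(split(reports, reports$arm), function(r) {
    r[order(r$rank), , drop = FALSE][seq_len(min(k, nrow(r))), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
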