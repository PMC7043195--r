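#' Cross-validation fold assignment
#'
#' Assigns each of `n` observations to one of `n_folds` folds so fold
#' sizes differ by at most one. With `stratify_labels`, the assignment is
#' done within each label so per-fold label proportions match the sample
#' within one observation.
#'
#' @param n number of observations.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed; the assignment is deterministic given it.
#' @param stratify_labels optional length-`n` vector of labels to
#'   stratify on.
#' @return integer vector of fold ids in `1:n_folds`.
#' @export
make_cv_folds <- function(n, n_folds = 10, seed = 1, stratify_labels = NULL) {
  if (n_folds < 2) stop_config("n_folds must be >= 2")
  if (n < n_folds) stop_config("need n >= n_folds (n = %d, n_folds = %d)", n, n_folds)
  set.seed(seed)
  if (is.null(stratify_labels)) {
    return(sample(rep_len(seq_len(n_folds), n)))
  }
  stopifnot(length(stratify_labels) == n)
  folds <- integer(n)
  # offset the fold cycle across strata so remainders spread evenly
  start <- 0L
  for (lev in unique(stratify_labels)) {
    idx <- which(stratify_labels == lev)
    cyc <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
    folds[idx] <- sample(cyc)
    start <- start + length(idx)
  }
  folds
}

#' Fit a Super Learner stacking ensemble
#'
#' Combines a roster of candidate learners with convex weights chosen to
#' minimise the cross-validated mean squared error of the weighted
#' out-of-fold predictions. Weights are obtained by non-negative least
#' squares of the target on the out-of-fold prediction matrix, then
#' normalised to the simplex; if the normalised solution would have a
#' larger CV risk than the best single learner, all weight moves to that
#' learner, so the ensemble's CV risk never exceeds the best candidate's
#' (the meta-level oracle guarantee). All learners are then refit on the
#' full data for prediction.
#'
#' A learner that fails on any fold (or on the full-data refit) receives
#' weight zero with a warning rather than aborting the fit.
#'
#' @param x numeric covariate matrix (or data frame coercible to one).
#' @param y numeric target; for `task = "bounded"` it should lie in
#'   `[0, 1]` and predictions are clipped to that range.
#' @param roster nonempty list of learners, e.g. [default_roster()].
#' @param n_folds cross-validation folds (default 10).
#' @param seed integer seed controlling the fold split.
#' @param task `"bounded"` for probability regression (predictions
#'   clipped to `[0, 1]`) or `"unbounded"`.
#' @param folds optional precomputed fold assignment (overrides
#'   `n_folds`/`seed`); lets several nuisance fits share folds.
#' @return an object of class `"super_learner"` with components
#'   `weights`, `cv_risks` (per learner), `cv_risk_ensemble`, `cv_pred`
#'   (per-learner out-of-fold predictions), `folds`, `fits` (full-data
#'   refits) and `learner_ok`.
#' @export
fit_super_learner <- function(x, y, roster = default_roster(heavy = FALSE),
                              n_folds = 10, seed = 1,
                              task = c("bounded", "unbounded"),
                              folds = NULL) {
  task <- match.arg(task)
  x <- covariate_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(length(y) == n)
  if (!length(roster)) stop_config("learner roster is empty")
  if (any(!is.finite(y))) stop_config("target contains non-finite values")
  nm <- vapply(roster, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_config("learner names must be unique")
  if (is.null(folds)) folds <- make_cv_folds(n, n_folds, seed)
  J <- length(roster)
  Z <- matrix(NA_real_, n, J, dimnames = list(NULL, nm))
  ok <- rep(TRUE, J)

  for (j in seq_len(J)) {
    lr <- roster[[j]]
    for (f in sort(unique(folds))) {
      tr <- folds != f
      pred <- tryCatch({
        m <- lr$fit(x[tr, , drop = FALSE], y[tr])
        as.numeric(lr$predict(m, x[!tr, , drop = FALSE]))
      }, error = function(e) e)
      if (inherits(pred, "error")) {
        warning(sprintf("learner '%s' failed on fold %d (%s); weight set to 0",
                        lr$name, f, conditionMessage(pred)), call. = FALSE)
        ok[j] <- FALSE
        break
      }
      Z[!tr, j] <- pred
    }
  }
  if (!any(ok)) stop_config("every learner failed; cannot stack")
  if (task == "bounded") Z[, ok] <- clip(Z[, ok, drop = FALSE], 0, 1)

  w <- numeric(J)
  Zok <- Z[, ok, drop = FALSE]
  nn <- tryCatch(pracma::lsqnonneg(Zok, y)$x, error = function(e) NULL)
  if (is.null(nn) || sum(nn) <= 0) nn <- rep(1, ncol(Zok))
  w[ok] <- nn / sum(nn)

  cv_risks <- colMeans((Z - y)^2)
  cv_risks[!ok] <- NA_real_
  ens_pred <- drop(Zok %*% w[ok])
  if (task == "bounded") ens_pred <- clip(ens_pred, 0, 1)
  risk_ens <- mean((ens_pred - y)^2)
  best <- which.min(ifelse(ok, cv_risks, Inf))
  if (risk_ens > cv_risks[best]) {
    w[] <- 0; w[best] <- 1
    risk_ens <- cv_risks[best]
  }

  fits <- vector("list", J)
  for (j in which(ok & w > 0)) {
    fits[[j]] <- tryCatch(roster[[j]]$fit(x, y), error = function(e) e)
    if (inherits(fits[[j]], "error")) {
      warning(sprintf("learner '%s' failed on the full-data refit; weight set to 0",
                      roster[[j]]$name), call. = FALSE)
      ok[j] <- FALSE
      w[j] <- 0
    }
  }
  if (sum(w) <= 0) stop_config("no learner survived the refit")
  w <- w / sum(w)

  structure(list(
    roster = roster, weights = stats::setNames(w, nm),
    cv_risks = stats::setNames(cv_risks, nm), cv_risk_ensemble = risk_ens,
    cv_pred = Z, folds = folds, fits = fits, learner_ok = ok,
    task = task, p = ncol(x), colnames = colnames(x)
  ), class = "super_learner")
}

#' Predict from a Super Learner fit
#'
#' The ensemble prediction is the weight-vector combination of the
#' full-data learner refits; probability-task predictions are clipped to
#' `[0, 1]`.
#'
#' @param object a [fit_super_learner()] fit.
#' @param newdata covariate matrix/data frame with the training schema.
#' @param ... unused.
#' @return numeric prediction vector.
#' @export
predict.super_learner <- function(object, newdata, ...) {
  x <- covariate_matrix(newdata)
  if (ncol(x) != object$p)
    stop_config("newdata has %d columns; the fit expects %d", ncol(x), object$p)
  out <- numeric(nrow(x))
  for (j in which(object$weights > 0)) {
    out <- out + object$weights[j] *
      as.numeric(object$roster[[j]]$predict(object$fits[[j]], x))
  }
  if (object$task == "bounded") out <- clip(out, 0, 1)
  out
}

#' @export
print.super_learner <- function(x, ...) {
  cat("Super Learner (", x$task, " target, ",
      length(unique(x$folds)), "-fold CV)\n", sep = "")
  print(cv_risk_table(x), digits = 4)
  invisible(x)
}

#' Cross-validated risk table
#'
#' Per-learner and ensemble cross-validated mean squared errors. By
#' construction the ensemble risk is no larger than the best single
#' learner's.
#'
#' @param fit a [fit_super_learner()] fit.
#' @return data frame with columns `learner`, `weight`, `cv_mse`.
#' @export
cv_risk_table <- function(fit) {
  stopifnot(inherits(fit, "super_learner"))
  data.frame(
    learner = c(names(fit$weights), "ensemble"),
    weight = c(unname(fit$weights), 1),
    cv_mse = c(unname(fit$cv_risks), fit$cv_risk_ensemble),
    row.names = NULL
  )
}
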