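#' Candidate learners for the stacking ensemble
#'
#' A learner is a small list with a unique `name`, a `fit(x, y)` closure
#' returning a fitted model, and a `predict(model, x)` closure returning a
#' numeric vector. All learners regress a numeric target on a numeric
#' covariate matrix; binary outcomes are treated as probability
#' regressions so that the ensemble can be stacked under squared-error
#' loss. Internal randomness (e.g. the tree ensemble's bootstrap) is fixed
#' so that fits are deterministic given the data.
#'
#' @param name learner name, unique within a roster.
#' @return an object of class `"itr_learner"`.
#' @name learners
NULL

new_learner <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "itr_learner")
}

#' @rdname learners
#' @export
lrn_mean <- function(name = "mean") {
  new_learner(name,
    fit = function(x, y) mean(y),
    predict = function(model, x) rep(model, nrow(x)))
}

#' @rdname learners
#' @param family `"gaussian"` for a linear fit or `"binomial"` for a
#'   logistic fit (the latter only makes sense for targets in `[0, 1]`).
#' @export
lrn_glm <- function(name = "glm", family = "gaussian") {
  new_learner(name,
    fit = function(x, y) {
      xf <- cbind(1, x)
      if (family == "binomial" && all(y >= 0 & y <= 1)) {
        f <- suppressWarnings(stats::glm.fit(xf, y, family = stats::quasibinomial()))
        list(coef = f$coefficients, link = "logit")
      } else {
        list(coef = stats::lm.fit(xf, y)$coefficients, link = "identity")
      }
    },
    predict = function(model, x) {
      b <- model$coef
      b[is.na(b)] <- 0
      eta <- drop(cbind(1, x) %*% b)
      if (model$link == "logit") stats::plogis(eta) else eta
    })
}

#' @rdname learners
#' @param alpha glmnet elastic-net mixing parameter: 1 = lasso, 0 = ridge.
#' @param nfolds_internal folds for glmnet's internal lambda selection
#'   (deterministic fold ids).
#' @export
lrn_glmnet <- function(name = if (alpha == 1) "lasso" else "ridge",
                       alpha = 1, nfolds_internal = 5) {
  force(alpha); force(nfolds_internal)
  new_learner(name,
    fit = function(x, y) {
      if (stats::var(y) < 1e-12 || ncol(x) < 2) {
        return(list(const = mean(y)))
      }
      foldid <- rep_len(seq_len(nfolds_internal), nrow(x))
      glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                        standardize = TRUE)
    },
    predict = function(model, x) {
      if (!is.null(model$const)) return(rep(model$const, nrow(x)))
      drop(stats::predict(model, newx = x, s = "lambda.min"))
    })
}

#' @rdname learners
#' @param num.trees,mtry,min.node.size forwarded to [ranger::ranger()].
#' @export
lrn_ranger <- function(name = "ranger", num.trees = 200, mtry = NULL,
                       min.node.size = 20) {
  force(num.trees); force(mtry); force(min.node.size)
  new_learner(name,
    fit = function(x, y) {
      d <- as.data.frame(x)
      d$.y <- y
      ranger::ranger(
        dependent.variable.name = ".y", data = d,
        num.trees = num.trees, mtry = mtry, min.node.size = min.node.size,
        seed = 20260101L, num.threads = 1, respect.unordered.factors = TRUE)
    },
    predict = function(model, x) {
      stats::predict(model, data = as.data.frame(x), num.threads = 1)$predictions
    })
}

#' @rdname learners
#' @param k number of neighbours.
#' @export
lrn_knn <- function(name = "knn", k = 25) {
  force(k)
  new_learner(name,
    fit = function(x, y) {
      # scale columns so distances are not dominated by wide-range covariates
      mu <- colMeans(x)
      sdv <- apply(x, 2, stats::sd)
      sdv[sdv < 1e-12] <- 1
      xs <- scale(x, center = mu, scale = sdv)
      list(m = caret::knnreg(as.data.frame(xs), y, k = min(k, nrow(x))),
           mu = mu, sdv = sdv)
    },
    predict = function(model, x) {
      xs <- scale(x, center = model$mu, scale = model$sdv)
      stats::predict(model$m, as.data.frame(xs))
    })
}

#' @rdname learners
#' @param max_smooth maximum number of continuous covariates given a
#'   spline term; the rest enter linearly (keeps the fit tractable on
#'   wide designs).
#' @export
lrn_gam <- function(name = "gam", max_smooth = 6) {
  force(max_smooth)
  new_learner(name,
    fit = function(x, y) {
      d <- as.data.frame(x)
      names(d) <- paste0("V", seq_len(ncol(d)))
      nu <- vapply(d, function(v) length(unique(v)), integer(1))
      # spline terms only where there is enough distinct support
      smooth_ok <- which(nu >= 10)
      if (length(smooth_ok) > max_smooth) {
        v <- vapply(d[smooth_ok], stats::var, numeric(1))
        smooth_ok <- smooth_ok[order(-v)][seq_len(max_smooth)]
      }
      terms <- ifelse(seq_along(d) %in% smooth_ok,
                      paste0("s(", names(d), ", k = 5)"), names(d))
      d$.y <- y
      f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
      mgcv::gam(f, data = d, method = "REML")
    },
    predict = function(model, x) {
      d <- as.data.frame(x)
      names(d) <- paste0("V", seq_len(ncol(d)))
      as.numeric(stats::predict(model, newdata = d))
    })
}

#' Default candidate-learner roster
#'
#' A deliberately diverse roster: an intercept-only reference, L1- and
#' L2-penalised generalized linear models, a random-forest tree ensemble,
#' a k-nearest-neighbour smoother, and a spline-based additive model.
#' Diversity across bias/variance profiles is what gives the stacking
#' ensemble its cross-validated guarantee any practical bite.
#'
#' @param heavy if `FALSE`, drop the kNN and GAM learners — a faster
#'   roster appropriate for repeated simulation studies.
#' @return list of learners (see [lrn_mean()]).
#' @export
default_roster <- function(heavy = TRUE) {
  r <- list(lrn_mean(), lrn_glm(), lrn_glmnet(alpha = 1),
            lrn_glmnet(alpha = 0), lrn_ranger())
  if (heavy) r <- c(r, list(lrn_knn(), lrn_gam()))
  r
}
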