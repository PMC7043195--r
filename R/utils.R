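#' Round half away from zero
#'
#' Report tables in comparative-effectiveness papers conventionally round
#' 5 upward (half-up), whereas [base::round()] rounds half to even. This
#' helper reproduces printed-table rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(13.888, 1) # 13.9
#' round_half_up(-14.206, 1) # -14.2
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# clip to a closed interval; used for probabilities and TMLE offsets
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a reproducible child seed from a master seed and a stage offset,
# staying inside the 32-bit integer range
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# coerce a data.frame of covariates to a plain numeric matrix; factors and
# characters become dummy columns via model.matrix
covariate_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x))
  if (all(vapply(x, is.numeric, logical(1)))) {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    return(m)
  }
  stats::model.matrix(~ . - 1, data = x)
}
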