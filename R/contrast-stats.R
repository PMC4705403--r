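## SMCV contrast statistics. The standardized mean of a contrast variable
## is an effect-size statistic: for groups with means Ybar_i and variances
## s_i, and zero-sum contrast coefficients c_i, the method-of-moments
## estimate is
##   lambda-hat = sum(c_i * Ybar_i) / sqrt(sum(c_i^2 * s_i)).
## Under a normal model of the contrast variable, the c+-probability (the
## probability that the contrast variable is positive) is Phi(lambda-hat),
## and the one-sided p-value for the null "SMCV <= 0" is 1 - c+.
## Note the denominator uses the group variances themselves, not variances
## of the group means: lambda is a property of the populations, not of the
## sample size, so this is an effect size and the derived test is
## conservative relative to a t-test at equal nominal level.

#' Validate SMCV contrast coefficients
#'
#' @param coefficients numeric vector of length t >= 2, summing to zero
#'   (within 1e-12), not all zero.
#' @return the coefficients, invisibly validated.
#' @export
contrastSpec <- function(coefficients) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 2L) stop("a contrast needs at least 2 groups")
  if (abs(sum(coefficients)) > 1e-12)
    stop("contrast coefficients must sum to zero")
  if (all(coefficients == 0)) stop("contrast coefficients must not all be zero")
  coefficients
}

#' Summarize samples into SMCV group summaries
#'
#' @param samples list of numeric vectors, one per group.
#' @return data.frame with columns \code{mean}, \code{variance}, \code{n}.
#' @export
groupSummaries <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  do.call(rbind, lapply(samples, function(x) {
    data.frame(mean = mean(x),
               variance = if (length(x) > 1L) stats::var(x) else 0,
               n = length(x))
  }))
}

#' Method-of-moments SMCV estimate for a contrast across groups
#'
#' @param groups data.frame with columns \code{mean} and \code{variance}
#'   (one row per group), e.g. from [groupSummaries()].
#' @param coefficients zero-sum contrast coefficients, one per group.
#' @param s_reading \code{"variance"} (default: denominator
#'   \eqn{\sqrt{\sum c_i^2 s_i}} with s_i a variance) or \code{"sd"}
#'   (denominator \eqn{\sqrt{\sum c_i^2 s_i^2}} with the \code{variance}
#'   column read as standard deviations), provided for sensitivity
#'   analysis.
#' @return the dimensionless SMCV estimate.
#' @examples
#' g <- data.frame(mean = c(3, 1), variance = c(1, 1))
#' smcvEstimate(g, c(1, -1))  # 2/sqrt(2) = 1.4142
#' @export
smcvEstimate <- function(groups, coefficients,
                         s_reading = c("variance", "sd")) {
  s_reading <- match.arg(s_reading)
  coefficients <- contrastSpec(coefficients)
  stopifnot(is.data.frame(groups),
            all(c("mean", "variance") %in% colnames(groups)))
  if (nrow(groups) != length(coefficients))
    stop("one coefficient per group required")
  if (any(groups$variance < 0)) stop("group variances must be >= 0")
  s2 <- if (s_reading == "variance") groups$variance else groups$variance^2
  denom2 <- sum(coefficients^2 * s2)
  if (denom2 <= 0) stop("contrast variance is zero; SMCV undefined")
  sum(coefficients * groups$mean) / sqrt(denom2)
}

#' c+-probability of an SMCV value
#'
#' The probability that the contrast variable is positive under a normal
#' model: \eqn{\Phi(\hat\lambda)}; 0.5 at zero, strictly increasing.
#'
#' @param smcv finite SMCV estimate.
#' @return probability in [0, 1].
#' @export
cplusProbability <- function(smcv) {
  if (!all(is.finite(smcv))) stop("smcv must be finite")
  stats::pnorm(smcv)
}

#' One-sided p-value from a c+-probability
#'
#' \eqn{p = 1 - c^+}: the probability of an SMCV value as extreme as
#' observed under the null hypothesis that the SMCV is <= 0. Values with
#' an upper boundary below 0.050 are flagged significant (strictly:
#' p = 0.05 is not significant).
#'
#' @param cplus probability in [0, 1].
#' @return data.frame with columns \code{p} and \code{significant}.
#' @export
smcvPvalue <- function(cplus) {
  if (any(cplus < 0 | cplus > 1)) stop("cplus must lie in [0, 1]")
  p <- 1 - cplus
  data.frame(p = p, significant = p < 0.050)
}

#' Full SMCV contrast: estimate, c+-probability and p-value
#'
#' @inheritParams smcvEstimate
#' @return a [ContrastResult-class].
#' @export
smcvContrast <- function(groups, coefficients,
                         s_reading = c("variance", "sd")) {
  lam <- smcvEstimate(groups, coefficients, s_reading)
  cp <- cplusProbability(lam)
  pv <- smcvPvalue(cp)
  new("ContrastResult", smcv = lam, cplus = cp, pValue = pv$p,
      significant = pv$significant)
}

#' @rdname ContrastResult-class
#' @export
setMethod("smcv", "ContrastResult", function(x) x@smcv)

#' @rdname ContrastResult-class
#' @export
setMethod("cplusProb", "ContrastResult", function(x) x@cplus)

#' @rdname ContrastResult-class
#' @export
setMethod("pValue", "ContrastResult", function(x) x@pValue)

#' @rdname ContrastResult-class
#' @export
setMethod("isSignificant", "ContrastResult", function(x) x@significant)

setMethod("show", "ContrastResult", function(object) {
  cat(sprintf("ContrastResult: SMCV = %.4f, c+ = %.4f, p = %.4g%s\n",
              object@smcv, object@cplus, object@pValue,
              if (object@significant) " (significant)" else ""))
})
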