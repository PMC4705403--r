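## Cy0-based quantification. The amplification curve is fitted by nonlinear
## least squares to a Richards sigmoid; Cy0 is the cycle where the tangent
## at the inflection point crosses zero fluorescence; the per-reaction
## efficiency is 2^slope of log2(fluorescence) over the 5 cycles nearest
## Cy0; expression is Eff^(-Cy0) with the per-plate mean amplicon
## efficiency. Expression values are relative quantities: with perfect
## doubling, one fewer Cy0 cycle means twice the starting material.

#' Fit a Richards sigmoid to an amplification curve
#'
#' Least-squares fit of \eqn{F(x) = F_{max}/(1 + e^{-(x-c)/b})^d} via
#' Levenberg-Marquardt with multi-start initialization from curve landmarks
#' (plateau estimate, half-max crossing) and a fixed-d = 1 logistic
#' fallback. A curve the optimizer cannot fit, or that does not amplify,
#' yields \code{converged = FALSE}; malformed input is an error.
#'
#' @param curve an [AmplificationCurve-class].
#' @param fix_d if TRUE, fit the logistic (d = 1) only.
#' @return a [RichardsFit-class] with \code{cy0} already computed when the
#'   fit converged.
#' @export
fitAmplificationModel <- function(curve, fix_d = FALSE) {
  stopifnot(is(curve, "AmplificationCurve"))
  validObject(curve)
  x <- as.numeric(curve@cycles)
  f <- curve@fluorescence
  fail <- new("RichardsFit", wellId = curve@wellId, amplicon = curve@amplicon,
              fmax = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
              rmse = NA_real_, converged = FALSE, cy0 = NA_real_)
  ## non-amplifying guard: needs a real rise above early-cycle noise
  rng <- max(f) - min(f)
  early_sd <- stats::sd(f[seq_len(5L)])
  if (!(max(f) > 0) || rng <= 0 || rng < 8 * max(early_sd, 1e-12))
    return(fail)

  fmax0 <- max(f)
  half <- which(f >= fmax0 / 2)
  c0 <- if (length(half)) x[half[1]] else stats::median(x)
  starts <- list()
  for (b0 in c(0.5, 1.5, 3)) for (d0 in c(0.25, 1)) {
    s <- list(fmax = fmax0, b = b0, c = c0, d = d0)
    if (fix_d) s$d <- NULL
    starts[[length(starts) + 1L]] <- s
  }
  form <- if (fix_d) f ~ fmax / (1 + exp(-(x - c) / b)) else
    f ~ fmax / (1 + exp(-(x - c) / b))^d
  lower <- if (fix_d) c(fmax = 1e-8, b = 1e-3, c = min(x) - 10) else
    c(fmax = 1e-8, b = 1e-3, c = min(x) - 10, d = 1e-3)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, start = s, lower = lower,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    ## landmarks start most curves close enough that the first converged
    ## tight fit is the global optimum; skip the remaining starts then
    if (sqrt(rss / length(f)) < 0.01 * fmax0) break
  }
  if (is.null(best) && !fix_d)
    return(fitAmplificationModel(curve, fix_d = TRUE))
  if (is.null(best)) return(fail)
  cf <- stats::coef(best$fit)
  if (fix_d) cf["d"] <- 1
  rmse <- sqrt(best$rss / length(f))
  ## sanity: parameters positive, center within reach of the run, fit not
  ## wildly extrapolating the plateau
  ok <- all(is.finite(cf)) && cf["fmax"] > 0 && cf["b"] > 0 && cf["d"] > 0 &&
    cf["c"] > min(x) - 10 && cf["c"] < max(x) + 10 &&
    cf["fmax"] < 5 * max(f) && rmse < 0.2 * max(f)
  if (!ok) {
    if (!fix_d) return(fitAmplificationModel(curve, fix_d = TRUE))
    return(fail)
  }
  fit <- new("RichardsFit", wellId = curve@wellId, amplicon = curve@amplicon,
             fmax = unname(cf["fmax"]), b = unname(cf["b"]),
             c = unname(cf["c"]), d = unname(cf["d"]),
             rmse = rmse, converged = TRUE, cy0 = NA_real_)
  cy <- tryCatch(computeCy0(fit), error = function(e) NA_real_)
  if (!is.finite(cy) || cy <= 0) {
    if (!fix_d) return(fitAmplificationModel(curve, fix_d = TRUE))
    return(fail)
  }
  fit@cy0 <- cy
  fit
}

#' Tangent-intercept quantification cycle Cy0
#'
#' The abscissa where the tangent to the fitted curve at its inflection
#' point crosses zero fluorescence. For the Richards model the inflection
#' lies at \eqn{x = c + b\ln d}, giving the closed form
#' \deqn{Cy0 = c + b \ln d - b (1 + 1/d),}
#' which reduces to \eqn{c - 2b} for the logistic (d = 1).
#'
#' @param fit a converged [RichardsFit-class].
#' @return Cy0 in cycles; also stored back when called via
#'   [fitAmplificationModel()].
#' @export
computeCy0 <- function(fit) {
  stopifnot(is(fit, "RichardsFit"))
  if (!isTRUE(fit@converged)) stop("Cy0 requires a converged fit")
  fit@c + fit@b * log(fit@d) - fit@b * (1 + 1 / fit@d)
}

#' Per-reaction amplification efficiency from the Cy0 window
#'
#' Least-squares slope m of log2(fluorescence) against cycle over the five
#' cycles centred on the cycle nearest Cy0 (that cycle, the two prior and
#' the two latter); the efficiency is \eqn{2^m} fold per cycle, so perfect
#' doubling gives exactly 2.
#'
#' @param curve the [AmplificationCurve-class] the fit came from.
#' @param cy0 the reaction's Cy0 (cycles).
#' @return efficiency, fold per cycle.
#' @export
estimateReactionEfficiency <- function(curve, cy0) {
  stopifnot(is(curve, "AmplificationCurve"))
  if (!is.finite(cy0)) stop("cy0 must be finite")
  idx <- which.min(abs(curve@cycles - cy0))
  win <- (idx - 2L):(idx + 2L)
  if (win[1] < 1L || win[5] > length(curve@cycles))
    stop("efficiency window (Cy0 +/- 2 cycles) falls outside the curve")
  fw <- curve@fluorescence[win]
  if (any(fw <= 0))
    stop("non-positive fluorescence in the efficiency window")
  xw <- as.numeric(curve@cycles[win])
  m <- unname(stats::coef(stats::lm(log2(fw) ~ xw))[2])
  2^m
}

#' Expression value from efficiency and Cy0
#'
#' \eqn{Eff^{-Cy0}}: the relative starting quantity implied by reaching the
#' tangent-intercept cycle Cy0 under per-cycle fold increase Eff.
#'
#' @param eff amplification efficiency (fold per cycle), > 1.
#' @param cy0 quantification cycle.
#' @return positive relative quantity.
#' @export
expressionValue <- function(eff, cy0) {
  if (any(eff <= 1)) stop("efficiency must exceed 1")
  eff^(-cy0)
}

#' Quantify a plate of amplification curves
#'
#' Fits every curve, computes Cy0 and the per-reaction efficiency, averages
#' efficiencies per amplicon over the plate (the per-plate mean efficiency
#' correction), and computes each well's expression value
#' \eqn{Eff_{amplicon}^{-Cy0}}. Non-converged wells, and wells whose
#' efficiency window is unusable, are excluded from the efficiency mean and
#' listed in the result; a non-converged well has no expression value.
#'
#' @param plate an [AmplificationPlate-class] or list of
#'   [AmplificationCurve-class].
#' @param fix_d passed to [fitAmplificationModel()].
#' @return a [PlateQuant-class].
#' @export
quantifyPlate <- function(plate, fix_d = FALSE) {
  curve_list <- if (is(plate, "AmplificationPlate")) plate@curves else plate
  stopifnot(length(curve_list) >= 1L)
  fits <- lapply(curve_list, fitAmplificationModel, fix_d = fix_d)
  rows <- list()
  excluded <- list()
  for (i in seq_along(fits)) {
    ft <- fits[[i]]
    if (!ft@converged) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        well = ft@wellId, amplicon = ft@amplicon,
        reason = "fit did not converge", stringsAsFactors = FALSE)
      next
    }
    eff_i <- tryCatch(
      estimateReactionEfficiency(curve_list[[i]], ft@cy0),
      error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      well = ft@wellId, amplicon = ft@amplicon, cy0 = ft@cy0,
      efficiency = eff_i, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no curve on the plate could be fitted")
  wells <- do.call(rbind, rows)
  amplicons <- unique(vapply(curve_list, function(cv) cv@amplicon, character(1)))
  missing <- setdiff(amplicons, wells$amplicon)
  if (length(missing))
    stop("no converged curve for amplicon(s): ", paste(missing, collapse = ", "))
  eff <- tapply(wells$efficiency, wells$amplicon,
                function(v) mean(v[is.finite(v) & v > 1]), default = NA_real_)
  bad <- names(eff)[!is.finite(eff)]
  if (length(bad))
    stop("no usable efficiency window for amplicon(s): ",
         paste(bad, collapse = ", "))
  wells$expression <- expressionValue(unname(eff[wells$amplicon]), wells$cy0)
  new("PlateQuant", wells = wells,
      amplicon_efficiency = stats::setNames(as.numeric(eff), names(eff)),
      excluded = if (length(excluded)) do.call(rbind, excluded) else
        data.frame(well = character(), amplicon = character(),
                   reason = character(), stringsAsFactors = FALSE))
}

#' @rdname RichardsFit-class
#' @export
setMethod("cy0", "RichardsFit", function(x) x@cy0)

setMethod("show", "RichardsFit", function(object) {
  if (object@converged)
    cat(sprintf(
      "RichardsFit %s [%s]: Fmax=%.1f b=%.3f c=%.2f d=%.3f Cy0=%.2f rmse=%.2f\n",
      object@wellId, object@amplicon, object@fmax, object@b, object@c,
      object@d, object@cy0, object@rmse))
  else
    cat(sprintf("RichardsFit %s [%s]: not converged\n",
                object@wellId, object@amplicon))
})

#' @rdname PlateQuant-class
#' @export
setMethod("wellData", "PlateQuant", function(x) x@wells)

#' @rdname PlateQuant-class
#' @export
setMethod("ampliconEfficiency", "PlateQuant", function(x) x@amplicon_efficiency)

#' @rdname PlateQuant-class
#' @export
setMethod("excludedWells", "PlateQuant", function(x) x@excluded)

setMethod("show", "PlateQuant", function(object) {
  cat("PlateQuant:", nrow(object@wells), "quantified wells;",
      nrow(object@excluded), "excluded\n")
  eff <- object@amplicon_efficiency
  cat("  mean efficiency:",
      paste(sprintf("%s=%.3f", names(eff), eff), collapse = ", "), "\n")
})
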