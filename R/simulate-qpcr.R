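## Synthetic qPCR plates. The noiseless curve is a Richards sigmoid whose
## exponential phase multiplies fluorescence by the true efficiency each
## cycle; that pins the slope-scale at b = d / ln(Eff), so the user chooses
## the plateau Fmax and the asymmetry d and the generator derives b.

#' Evaluate a Richards amplification curve
#'
#' \eqn{F(x) = F_{max} / (1 + e^{-(x - c)/b})^d}. With \eqn{b = d/\ln E} the
#' deep exponential phase satisfies \eqn{F(x) \approx F_{max} E^{x - c}},
#' i.e. a per-cycle fold increase of exactly \eqn{E}.
#'
#' @param x cycle (numeric vector).
#' @param fmax plateau fluorescence.
#' @param b slope scale in cycles.
#' @param c center in cycles.
#' @param d asymmetry (d = 1 recovers the logistic).
#' @return numeric vector of fluorescence values.
#' @export
richardsCurve <- function(x, fmax, b, c, d) {
  fmax / (1 + exp(-(x - c) / b))^d
}

## Run code under a fixed seed, restoring the caller's RNG state after.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration for a simulated qPCR plate
#'
#' @param wells data.frame with columns \code{well}, \code{amplicon},
#'   \code{quantity} (true initial quantity, > 0, in the same arbitrary
#'   units as fluorescence: a quantity Q crosses the exponential phase at
#'   cycle \eqn{\ln(F_{max}/Q)/\ln E}).
#' @param efficiency true per-cycle fold increase in (1, 2].
#' @param fmax plateau fluorescence (default 1000).
#' @param d Richards asymmetry (default 0.25; see the methods vignette for
#'   why sub-logistic asymmetry reproduces the long log-linear exponential
#'   stretch of baseline-subtracted probe data).
#' @param noise_sd additive Gaussian fluorescence noise, >= 0 (default 5).
#' @param n_cycles number of cycles, >= 10 (default 45).
#' @param seed integer seed; simulation is a pure function of the config.
#' @return a validated list of class \code{qpcr_sim_config}.
#' @export
qpcrSimConfig <- function(wells, efficiency, fmax = 1000, d = 0.25,
                          noise_sd = 5, n_cycles = 45, seed = 1) {
  stopifnot(is.data.frame(wells),
            all(c("well", "amplicon", "quantity") %in% colnames(wells)))
  if (nrow(wells) < 1L) stop("at least one well required")
  if (any(wells$quantity <= 0)) stop("all initial quantities must be > 0")
  if (!(efficiency > 1 && efficiency <= 2))
    stop("efficiency must lie in (1, 2]")
  if (!(fmax > 0 && d > 0)) stop("fmax and d must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_cycles < 10L) stop("n_cycles must be >= 10 (too short for a sigmoid)")
  structure(
    list(wells = wells, efficiency = efficiency, fmax = fmax, d = d,
         b = d / log(efficiency), noise_sd = noise_sd,
         n_cycles = as.integer(n_cycles), seed = as.integer(seed)),
    class = "qpcr_sim_config"
  )
}

#' Simulate a qPCR plate of amplification curves
#'
#' Each well's noiseless trace is a Richards sigmoid positioned so that the
#' exponential phase extrapolates to the well's true initial quantity at
#' cycle zero; independent Gaussian noise of sd \code{noise_sd} is added.
#' The returned plate carries a ground-truth record of each well's quantity
#' and the common true efficiency. Identical configs (including seed) give
#' identical plates.
#'
#' @param config a [qpcrSimConfig()] object.
#' @return an [AmplificationPlate-class] object.
#' @examples
#' cfg <- qpcrSimConfig(
#'   wells = data.frame(well = c("A1", "A2"), amplicon = "RFP",
#'                      quantity = c(1e-4, 5e-5)),
#'   efficiency = 2, noise_sd = 0)
#' plate <- simulateQpcrPlate(cfg)
#' length(curves(plate))
#' @export
simulateQpcrPlate <- function(config) {
  if (!inherits(config, "qpcr_sim_config"))
    config <- do.call(qpcrSimConfig, config)
  x <- seq_len(config$n_cycles)
  withSeed(config$seed, {
    curves <- lapply(seq_len(nrow(config$wells)), function(i) {
      w <- config$wells[i, ]
      ## center so that F ~ Q * Eff^x in the exponential phase
      cc <- log(config$fmax / w$quantity) / log(config$efficiency)
      f <- richardsCurve(x, config$fmax, config$b, cc, config$d)
      if (config$noise_sd > 0)
        f <- f + stats::rnorm(length(x), sd = config$noise_sd)
      new("AmplificationCurve", wellId = as.character(w$well),
          amplicon = as.character(w$amplicon),
          cycles = x, fluorescence = f)
    })
    truth <- data.frame(
      well = as.character(config$wells$well),
      amplicon = as.character(config$wells$amplicon),
      quantity = config$wells$quantity,
      efficiency = config$efficiency,
      stringsAsFactors = FALSE
    )
    new("AmplificationPlate", curves = curves, groundTruth = truth)
  })
}

#' @rdname AmplificationPlate-class
#' @export
setMethod("curves", "AmplificationPlate", function(x) x@curves)

#' @rdname AmplificationPlate-class
#' @export
setMethod("groundTruth", "AmplificationPlate", function(x) x@groundTruth)

#' @describeIn AmplificationPlate-class number of curves on the plate.
#' @export
setMethod("length", "AmplificationPlate", function(x) length(x@curves))

setMethod("show", "AmplificationPlate", function(object) {
  cat("AmplificationPlate with", length(object@curves), "curves;",
      "amplicons:", paste(unique(vapply(object@curves,
        function(cv) cv@amplicon, character(1))), collapse = ", "), "\n")
  if (nrow(object@groundTruth))
    cat("  simulated (ground truth attached)\n")
})

setMethod("show", "AmplificationCurve", function(object) {
  cat(sprintf("AmplificationCurve %s [%s], %d cycles, max fluorescence %.1f\n",
              object@wellId, object@amplicon, length(object@cycles),
              max(object@fluorescence)))
})
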