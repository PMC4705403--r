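## Synthetic flow-cytometry events: a bimodal (induced / non-induced)
## population on the log(RFP/GFP) scale, pushed through a linear spillover
## matrix to emulate spectral overlap between detectors.

#' Configuration for simulated flow-cytometry events
#'
#' @param n_events number of events.
#' @param induced_fraction fraction of doxycycline-responsive cells in
#'   [0, 1].
#' @param induced_mean,induced_sd normal parameters of log(RFP/GFP) for the
#'   induced component (defaults 1 and 0.5).
#' @param noninduced_mean,noninduced_sd parameters for the non-induced
#'   component (defaults -2 and 0.5).
#' @param gfp_meanlog,gfp_sdlog log-normal parameters of the GFP channel
#'   (defaults log(500), 0.6).
#' @param apc_meanlog,apc_sdlog log-normal parameters of the APC
#'   autofluorescence channel (defaults log(50), 0.4).
#' @param spillover 3x3 spillover matrix (rows = fluorophores RFP, GFP,
#'   APC; columns = detectors; unit diagonal). Default identity.
#' @param seed integer seed.
#' @return a validated list of class \code{flow_sim_config}.
#' @export
flowSimConfig <- function(n_events, induced_fraction,
                          induced_mean = 1, induced_sd = 0.5,
                          noninduced_mean = -2, noninduced_sd = 0.5,
                          gfp_meanlog = log(500), gfp_sdlog = 0.6,
                          apc_meanlog = log(50), apc_sdlog = 0.4,
                          spillover = diag(3), seed = 1) {
  if (n_events < 1L) stop("n_events must be >= 1")
  if (induced_fraction < 0 || induced_fraction > 1)
    stop("induced_fraction must lie in [0, 1]")
  if (induced_sd <= 0 || noninduced_sd <= 0)
    stop("component standard deviations must be positive")
  spillover <- validateSpillover(spillover)
  structure(
    list(n_events = as.integer(n_events), induced_fraction = induced_fraction,
         induced_mean = induced_mean, induced_sd = induced_sd,
         noninduced_mean = noninduced_mean, noninduced_sd = noninduced_sd,
         gfp_meanlog = gfp_meanlog, gfp_sdlog = gfp_sdlog,
         apc_meanlog = apc_meanlog, apc_sdlog = apc_sdlog,
         spillover = spillover, seed = as.integer(seed)),
    class = "flow_sim_config"
  )
}

#' Validate a spillover matrix
#'
#' Square, non-negative entries, unit diagonal, invertible.
#'
#' @param m numeric matrix.
#' @return the matrix with channel dimnames attached.
#' @export
validateSpillover <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("spillover matrix must be square")
  if (any(m < 0)) stop("spillover entries must be >= 0")
  if (any(abs(diag(m) - 1) > 1e-12)) stop("spillover diagonal must be 1")
  if (rcondSafe(m) < 1e-12) stop("spillover matrix is singular")
  if (is.null(rownames(m)) && nrow(m) == 3L)
    dimnames(m) <- list(c("RFP", "GFP", "APC"), c("RFP", "GFP", "APC"))
  m
}

rcondSafe <- function(m) tryCatch(rcond(m), error = function(e) 0)

#' Simulate flow-cytometry events with spectral spillover
#'
#' Each event carries a true RFP/GFP/APC fluorophore signal; induced events
#' draw their log-ratio from the induced component, the rest from the
#' non-induced component. The observed detector intensities are the true
#' signals multiplied by the spillover matrix. Ground-truth labels and the
#' true signals are attached.
#'
#' @param config a [flowSimConfig()] object.
#' @return a [FlowEventSet-class]; \code{truth} holds \code{induced}
#'   (logical), \code{trueSignals} and \code{spillover}.
#' @export
simulateFlowEvents <- function(config) {
  if (!inherits(config, "flow_sim_config"))
    config <- do.call(flowSimConfig, config)
  withSeed(config$seed, {
    n <- config$n_events
    induced <- stats::runif(n) < config$induced_fraction
    lr <- ifelse(induced,
                 stats::rnorm(n, config$induced_mean, config$induced_sd),
                 stats::rnorm(n, config$noninduced_mean, config$noninduced_sd))
    gfp <- stats::rlnorm(n, config$gfp_meanlog, config$gfp_sdlog)
    rfp <- gfp * exp(lr)
    apc <- stats::rlnorm(n, config$apc_meanlog, config$apc_sdlog)
    true_sig <- cbind(RFP = rfp, GFP = gfp, APC = apc)
    observed <- true_sig %*% config$spillover
    events <- as.data.frame(observed)
    colnames(events) <- colnames(config$spillover)
    new("FlowEventSet", events = events,
        truth = list(induced = induced, trueSignals = true_sig,
                     spillover = config$spillover),
        compensated = FALSE)
  })
}

#' @rdname FlowEventSet-class
#' @export
setMethod("eventData", "FlowEventSet", function(x) x@events)

#' @rdname FlowEventSet-class
#' @export
setMethod("groundTruth", "FlowEventSet", function(x) x@truth)

#' @describeIn FlowEventSet-class number of events.
#' @export
setMethod("length", "FlowEventSet", function(x) nrow(x@events))

setMethod("show", "FlowEventSet", function(object) {
  cat(sprintf("FlowEventSet: %d events, channels %s%s\n",
              nrow(object@events),
              paste(colnames(object@events), collapse = "/"),
              if (object@compensated) " (compensated)" else ""))
})
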