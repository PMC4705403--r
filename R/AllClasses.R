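## Central S4 classes. Validity functions enforce the structural invariants
## the downstream algebra relies on; numerical sanity (e.g. the efficiency
## band) is checked where the quantity is produced.

#' AmplificationCurve: one well's baseline-subtracted qPCR trace
#'
#' Holds the fluorescence readings of a single qPCR reaction, already
#' baseline-subtracted by the instrument software. Cycles are 1-based and
#' strictly increasing; at least 10 cycles are required for a sigmoid fit to
#' be meaningful.
#'
#' @slot wellId character(1), plate well identifier.
#' @slot amplicon character(1), amplicon label (e.g. \code{"RFP"}, \code{"GFP"}).
#' @slot cycles integer vector of cycle indices.
#' @slot fluorescence numeric vector, same length as \code{cycles}, arbitrary
#'   units.
#' @export
setClass("AmplificationCurve",
  representation(
    wellId = "character",
    amplicon = "character",
    cycles = "integer",
    fluorescence = "numeric"
  )
)

setValidity("AmplificationCurve", function(object) {
  msg <- character()
  if (length(object@wellId) != 1L || is.na(object@wellId))
    msg <- c(msg, "wellId must be a single non-missing string")
  if (length(object@amplicon) != 1L || is.na(object@amplicon))
    msg <- c(msg, "amplicon must be a single non-missing string")
  if (length(object@cycles) != length(object@fluorescence))
    msg <- c(msg, "cycles and fluorescence must have equal length")
  if (length(object@cycles) < 10L)
    msg <- c(msg, "at least 10 cycles are required")
  if (length(object@cycles) > 1L && any(diff(object@cycles) <= 0L))
    msg <- c(msg, "cycles must be strictly increasing")
  if (anyNA(object@fluorescence))
    msg <- c(msg, "fluorescence must not contain NA")
  if (length(msg)) msg else TRUE
})

#' AmplificationPlate: a set of amplification curves plus simulation truth
#'
#' @slot curves list of [AmplificationCurve] objects.
#' @slot groundTruth data.frame of per-well simulation truth (columns
#'   \code{well}, \code{amplicon}, \code{quantity}, \code{efficiency});
#'   zero rows for plates read from instrument files.
#' @export
setClass("AmplificationPlate",
  representation(curves = "list", groundTruth = "data.frame")
)

setValidity("AmplificationPlate", function(object) {
  ok <- vapply(object@curves, is, logical(1), class2 = "AmplificationCurve")
  if (!all(ok)) return("all elements of curves must be AmplificationCurve")
  TRUE
})

#' RichardsFit: least-squares sigmoid fit of one amplification curve
#'
#' Parameters of the Richards model
#' \eqn{F(x) = F_{max} / (1 + e^{-(x - c)/b})^d} fitted to a curve, with the
#' tangent-intercept cycle Cy0 once computed. When the optimizer fails or the
#' curve does not amplify, \code{converged} is \code{FALSE} and parameters are
#' \code{NA} -- never an exception.
#'
#' @slot wellId,amplicon labels carried over from the curve.
#' @slot fmax,b,c,d numeric(1) model parameters (fluorescence units, cycles,
#'   cycles, dimensionless).
#' @slot rmse numeric(1), root-mean-square residual in fluorescence units.
#' @slot converged logical(1).
#' @slot cy0 numeric(1), tangent-intercept cycle (NA until computed).
#' @export
setClass("RichardsFit",
  representation(
    wellId = "character", amplicon = "character",
    fmax = "numeric", b = "numeric", c = "numeric", d = "numeric",
    rmse = "numeric", converged = "logical", cy0 = "numeric"
  ),
  prototype(cy0 = NA_real_)
)

setValidity("RichardsFit", function(object) {
  msg <- character()
  if (length(object@converged) != 1L)
    msg <- c(msg, "converged must be logical(1)")
  if (isTRUE(object@converged)) {
    if (!(object@fmax > 0)) msg <- c(msg, "Fmax must be > 0 when converged")
    if (!(object@b > 0)) msg <- c(msg, "b must be > 0 when converged")
    if (!(object@d > 0)) msg <- c(msg, "d must be > 0 when converged")
    if (!is.na(object@cy0) && !(is.finite(object@cy0) && object@cy0 > 0))
      msg <- c(msg, "cy0 must be finite and > 0 when converged")
  }
  if (length(msg)) msg else TRUE
})

#' PlateQuant: per-plate quantification results
#'
#' Per-well Cy0, per-reaction efficiency, per-amplicon mean efficiency, and
#' the expression value \eqn{Eff^{-Cy0}} for every converged well. Excluded
#' (non-converged) wells are retained with a reason code.
#'
#' @slot wells data.frame with columns \code{well}, \code{amplicon},
#'   \code{cy0}, \code{efficiency} (per-reaction), \code{expression}.
#' @slot amplicon_efficiency named numeric, mean per-amplicon efficiency
#'   (fold per cycle) used in the expression values.
#' @slot excluded data.frame of wells dropped from quantification, with a
#'   \code{reason} column.
#' @export
setClass("PlateQuant",
  representation(
    wells = "data.frame",
    amplicon_efficiency = "numeric",
    excluded = "data.frame"
  )
)

setValidity("PlateQuant", function(object) {
  msg <- character()
  eff <- object@amplicon_efficiency
  if (length(eff) && (any(eff <= 1) || any(eff > 2.2)))
    msg <- c(msg, "amplicon efficiencies outside the sanity band (1, 2.2]")
  if (nrow(object@wells) && any(object@wells$expression <= 0, na.rm = TRUE))
    msg <- c(msg, "expression values must be positive")
  if (length(msg)) msg else TRUE
})

#' ConditionGroup: replicate (RFP, GFP) expression pairs for one condition
#'
#' One experimental condition is a unique cell line x vector x time point.
#' Each of the n measurements contributes one RFP and one GFP expression
#' value.
#'
#' @slot cellLine,vectorLabel character(1) condition labels.
#' @slot timeH numeric(1), hours post induction.
#' @slot rfp,gfp positive numeric vectors of equal length n.
#' @export
setClass("ConditionGroup",
  representation(
    cellLine = "character", vectorLabel = "character", timeH = "numeric",
    rfp = "numeric", gfp = "numeric"
  )
)

setValidity("ConditionGroup", function(object) {
  msg <- character()
  if (length(object@rfp) != length(object@gfp))
    msg <- c(msg, "rfp and gfp must have equal length")
  if (length(object@rfp) < 1L) msg <- c(msg, "at least one measurement required")
  if (any(object@rfp <= 0) || any(object@gfp <= 0))
    msg <- c(msg, "expression values must be positive")
  if (length(msg)) msg else TRUE
})

#' CombinationRatios: pairwise-combination normalized ratios for a condition
#'
#' For a group of n (RFP, GFP) pairs, the choose(n, 2) values
#' \eqn{(R_i + R_j) / (G_i + G_j)} over all unordered pairs, in lexicographic
#' (i, j) order.
#'
#' @slot ratios positive numeric vector of length choose(n, 2).
#' @slot n integer(1), number of source measurements.
#' @slot cellLine,vectorLabel,timeH source condition reference.
#' @export
setClass("CombinationRatios",
  representation(
    ratios = "numeric", n = "integer",
    cellLine = "character", vectorLabel = "character", timeH = "numeric"
  )
)

setValidity("CombinationRatios", function(object) {
  msg <- character()
  if (object@n >= 2L && length(object@ratios) != choose(object@n, 2))
    msg <- c(msg, "length(ratios) must equal choose(n, 2)")
  if (any(object@ratios <= 0)) msg <- c(msg, "ratios must be positive")
  if (length(msg)) msg else TRUE
})

#' ScaledTimecourse: combination ratios scaled to the undamaged control max
#'
#' All ratios of one cell line expressed as percent of the reference value:
#' the maximum over time points of the control vector's per-time mean
#' combination ratio. By construction the control series attains 100% at its
#' maximal time point.
#'
#' @slot cellLine character(1).
#' @slot reference numeric(1), the combination-ratio value defining 100%.
#' @slot controlVector character(1), label of the undamaged control.
#' @slot values data.frame with columns \code{vector_label}, \code{time_h},
#'   \code{value_pct} (one row per scaled combination ratio).
#' @export
setClass("ScaledTimecourse",
  representation(
    cellLine = "character", reference = "numeric",
    controlVector = "character", values = "data.frame"
  )
)

setValidity("ScaledTimecourse", function(object) {
  if (!(length(object@reference) == 1L && object@reference > 0))
    return("reference must be a single positive value")
  TRUE
})

#' ContrastResult: SMCV estimate with c+-probability and one-sided p-value
#'
#' @slot smcv numeric(1), the standardized mean of the contrast variable.
#' @slot cplus numeric(1) in [0, 1], probability that the contrast variable
#'   is positive under a normal model.
#' @slot pValue numeric(1), \code{1 - cplus}; one-sided p for the null that
#'   the SMCV is <= 0.
#' @slot significant logical(1), \code{pValue < 0.05} (strict).
#' @export
setClass("ContrastResult",
  representation(
    smcv = "numeric", cplus = "numeric", pValue = "numeric",
    significant = "logical"
  )
)

setValidity("ContrastResult", function(object) {
  msg <- character()
  if (abs(object@cplus + object@pValue - 1) > 1e-12)
    msg <- c(msg, "cplus + pValue must equal 1")
  if (object@cplus < 0 || object@cplus > 1)
    msg <- c(msg, "cplus must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' FlowEventSet: per-event channel intensities with optional simulation truth
#'
#' @slot events data.frame with one row per event and numeric channel
#'   columns (at least \code{RFP} and \code{GFP}; typically also \code{APC}).
#' @slot truth list of simulation ground truth (\code{induced} labels,
#'   \code{trueSignals} matrix, \code{spillover}); empty for real data.
#' @slot compensated logical(1), whether spillover compensation was applied.
#' @export
setClass("FlowEventSet",
  representation(events = "data.frame", truth = "list",
                 compensated = "logical"),
  prototype(compensated = FALSE)
)

setValidity("FlowEventSet", function(object) {
  if (nrow(object@events) < 1L) return("at least one event required")
  if (!all(c("RFP", "GFP") %in% colnames(object@events)))
    return("events must contain RFP and GFP columns")
  TRUE
})

#' MixtureFit: two-component normal mixture of log-ratio fluorescence
#'
#' Fit of log(RFP/GFP) values by a two-component normal mixture via EM; the
#' induced (doxycycline-responsive) component is the one with the larger
#' mean. Degenerate data (effectively one component) are flagged rather than
#' forced into two components.
#'
#' @slot weights numeric(2) mixing proportions, summing to 1.
#' @slot means,variances numeric(2) component parameters.
#' @slot responsibilities numeric matrix, events x components.
#' @slot assignment integer vector, maximum-responsibility component per event.
#' @slot induced integer(1), index of the induced component.
#' @slot logLik numeric(1) final log-likelihood.
#' @slot converged,degenerate logical(1) flags.
#' @export
setClass("MixtureFit",
  representation(
    weights = "numeric", means = "numeric", variances = "numeric",
    responsibilities = "matrix", assignment = "integer",
    induced = "integer", logLik = "numeric",
    converged = "logical", degenerate = "logical"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must sum to 1")
  if (any(object@weights < 0 | object@weights > 1))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (any(object@variances <= 0))
    msg <- c(msg, "variances must be positive")
  if (length(msg)) msg else TRUE
})

#' VariantTally: lesion-site variant classes with the background-rate filter
#'
#' Counts and frequencies of lesion-opposite-position classes over classified
#' reads, and the retained flag from the frequency >= fold_threshold x
#' background_rate rule (inclusive boundary).
#'
#' @slot table data.frame with columns \code{class}, \code{count},
#'   \code{frequency}, \code{retained}.
#' @slot nClassified,nUnclassifiable integer(1) read counts.
#' @slot backgroundRate numeric(1) per-base background misincorporation rate.
#' @slot foldThreshold numeric(1) retention multiplier.
#' @export
setClass("VariantTally",
  representation(
    table = "data.frame",
    nClassified = "integer", nUnclassifiable = "integer",
    backgroundRate = "numeric", foldThreshold = "numeric"
  )
)

setValidity("VariantTally", function(object) {
  msg <- character()
  if (nrow(object@table) && sum(object@table$frequency) > 1 + 1e-9)
    msg <- c(msg, "class frequencies must sum to <= 1")
  if (object@backgroundRate <= 0) msg <- c(msg, "backgroundRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' FlowConditionSummary: condition-level flow summaries with ANOVA/contrasts
#'
#' @slot conditions data.frame with columns \code{condition},
#'   \code{mean_pct}, \code{se}, \code{n} (independent populations).
#' @slot anovaF,anovaP numeric(1) one-way ANOVA across conditions.
#' @slot contrasts data.frame with columns \code{contrast}, \code{estimate},
#'   \code{t}, \code{p}.
#' @slot controlCondition character(1).
#' @export
setClass("FlowConditionSummary",
  representation(
    conditions = "data.frame", anovaF = "numeric", anovaP = "numeric",
    contrasts = "data.frame", controlCondition = "character"
  )
)
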