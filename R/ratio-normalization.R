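## Pairwise-combination ratio normalization. GFP (transfection control)
## expression follows a gamma distribution with shape < 2, so 1/GFP is
## heavy-tailed and simple per-measurement RFP/GFP ratios have an extended,
## multimodal error tail at small n. Summing pairs before dividing doubles
## the gamma shape of the denominator (> 2), giving the inverse a finite
## variance and a unimodal error distribution.

#' Pairwise combination ratios for one condition group
#'
#' For n (RFP, GFP) measurement pairs, returns the choose(n, 2) values
#' \eqn{(R_i + R_j)/(G_i + G_j)} over all unordered pairs \{i, j\}, in
#' lexicographic (i, j) order. These combination ratios are the unit of all
#' downstream statistics.
#'
#' @param group a [ConditionGroup-class] with n >= 2.
#' @return a [CombinationRatios-class].
#' @examples
#' g <- new("ConditionGroup", cellLine = "NHF", vectorLabel = "control",
#'          timeH = 18, rfp = c(4, 6), gfp = c(2, 2))
#' ratios(combinationRatios(g))  # (4+6)/(2+2) = 2.5
#' @export
combinationRatios <- function(group) {
  stopifnot(is(group, "ConditionGroup"))
  validObject(group)
  n <- length(group@rfp)
  if (n < 2L) stop("need at least 2 measurements to form combinations")
  idx <- utils::combn(n, 2L)
  r <- (group@rfp[idx[1, ]] + group@rfp[idx[2, ]]) /
       (group@gfp[idx[1, ]] + group@gfp[idx[2, ]])
  new("CombinationRatios", ratios = r, n = n,
      cellLine = group@cellLine, vectorLabel = group@vectorLabel,
      timeH = group@timeH)
}

#' @rdname CombinationRatios-class
#' @export
setMethod("ratios", "CombinationRatios", function(x) x@ratios)

#' @describeIn CombinationRatios-class number of combination ratios.
#' @export
setMethod("length", "CombinationRatios", function(x) length(x@ratios))

setMethod("show", "CombinationRatios", function(object) {
  cat(sprintf("CombinationRatios %s / %s / %g h: %d ratios from n = %d\n",
              object@cellLine, object@vectorLabel, object@timeH,
              length(object@ratios), object@n))
})

#' Scale a cell line's combination ratios to the control maximum
#'
#' The reference defining 100% is the maximum over time points of the
#' control vector's per-time mean combination ratio; every condition's
#' ratios are divided by it and multiplied by 100, so the control series
#' peaks at exactly 100% and all conditions within the cell line share one
#' scale. Scaling within each cell type removes absolute expression
#' differences so time courses can be compared across cell types.
#'
#' @param combo_list list of [CombinationRatios-class], all from one cell
#'   line, covering the control vector at >= 1 time point.
#' @param control label of the undamaged control vector (default
#'   \code{"control"}).
#' @return a [ScaledTimecourse-class].
#' @export
scaleToControlMax <- function(combo_list, control = "control") {
  stopifnot(length(combo_list) >= 1L,
            all(vapply(combo_list, is, logical(1), "CombinationRatios")))
  cl <- unique(vapply(combo_list, function(x) x@cellLine, character(1)))
  if (length(cl) != 1L)
    stop("scaleToControlMax expects combination ratios from a single cell line")
  is_ctrl <- vapply(combo_list, function(x) x@vectorLabel == control, logical(1))
  if (!any(is_ctrl)) stop("control vector '", control, "' not present")
  ctrl_means <- vapply(combo_list[is_ctrl],
                       function(x) mean(x@ratios), numeric(1))
  reference <- max(ctrl_means)
  if (!is.finite(reference) || reference <= 0)
    stop("control reference is zero or undefined; cannot scale")
  values <- do.call(rbind, lapply(combo_list, function(x)
    data.frame(vector_label = x@vectorLabel, time_h = x@timeH,
               value_pct = 100 * x@ratios / reference,
               stringsAsFactors = FALSE)))
  new("ScaledTimecourse", cellLine = cl, reference = reference,
      controlVector = control, values = values)
}

#' Per-time summary of a scaled time course
#'
#' Mean percent of control maximum, standard error and number of
#' combination ratios at each vector x time point. The SE for a single
#' ratio is reported as NA (not zero).
#'
#' @param scaled a [ScaledTimecourse-class].
#' @return data.frame with columns \code{cell_line}, \code{vector_label},
#'   \code{time_h}, \code{mean_pct}, \code{se}, \code{n}.
#' @export
summarizeTimecourse <- function(scaled) {
  stopifnot(is(scaled, "ScaledTimecourse"))
  v <- scaled@values
  keys <- unique(v[c("vector_label", "time_h")])
  keys <- keys[order(keys$vector_label, keys$time_h), , drop = FALSE]
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- v$vector_label == keys$vector_label[i] & v$time_h == keys$time_h[i]
    x <- v$value_pct[sel]
    data.frame(cell_line = scaled@cellLine,
               vector_label = keys$vector_label[i],
               time_h = keys$time_h[i],
               mean_pct = mean(x),
               se = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

setMethod("show", "ScaledTimecourse", function(object) {
  cat(sprintf(
    "ScaledTimecourse %s: %d scaled ratios, reference = %.4g (control '%s')\n",
    object@cellLine, nrow(object@values), object@reference,
    object@controlVector))
})
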