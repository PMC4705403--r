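## Flow-cytometry processing: linear spillover compensation, log-ratio
## normalization of RFP by GFP, a two-component normal mixture on the log
## ratio to isolate the doxycycline-induced population, and condition-level
## summaries with one-way ANOVA and contrasts.

#' Compensate flow events for spectral spillover
#'
#' Detector intensities are modelled as true fluorophore signals multiplied
#' by a spillover matrix (rows = fluorophores, columns = detectors, unit
#' diagonal); compensation right-multiplies by its inverse. Negative
#' compensated values are preserved -- the ratio stage's positivity filter
#' handles them -- because clipping would bias low signals upward.
#'
#' @param events a [FlowEventSet-class] or data.frame of channel columns.
#' @param spillover square spillover matrix matching the channel columns.
#' @return a compensated [FlowEventSet-class].
#' @export
compensateEvents <- function(events, spillover) {
  es <- if (is(events, "FlowEventSet")) events else
    new("FlowEventSet", events = as.data.frame(events), truth = list())
  spillover <- validateSpillover(spillover)
  chans <- colnames(spillover)
  if (is.null(chans)) chans <- colnames(es@events)[seq_len(ncol(spillover))]
  if (!all(chans %in% colnames(es@events)))
    stop("spillover channels not all present in the event table")
  obs <- as.matrix(es@events[chans])
  comp <- obs %*% solve(spillover)
  out <- es@events
  out[chans] <- comp
  new("FlowEventSet", events = out, truth = es@truth, compensated = TRUE)
}

#' Per-event log-ratio normalization
#'
#' Maps each event to \eqn{\log_e(RFP/GFP)}, the transfection-normalized
#' RFP signal. Events with non-positive RFP or GFP (possible after
#' compensation) are excluded and counted.
#'
#' @param events a [FlowEventSet-class] or data.frame with RFP and GFP
#'   columns.
#' @return list with \code{log_ratio} (numeric), \code{kept} (row indices)
#'   and \code{n_excluded}.
#' @export
logRatioNormalize <- function(events) {
  ev <- if (is(events, "FlowEventSet")) events@events else as.data.frame(events)
  stopifnot(all(c("RFP", "GFP") %in% colnames(ev)))
  ok <- ev$RFP > 0 & ev$GFP > 0
  if (!any(ok)) stop("no events with positive RFP and GFP")
  list(log_ratio = log(ev$RFP[ok] / ev$GFP[ok]),
       kept = which(ok), n_excluded = sum(!ok))
}

#' Programmatic autofluorescence gate
#'
#' Replaces hand-drawn significant-fluorescence gates with a reproducible
#' rule: events pass when their GFP intensity exceeds the q-th quantile of
#' an unstained-control event table (cells carrying no reporter, so their
#' GFP channel reads autofluorescence only). With no unstained control
#' supplied, all events pass to the mixture stage.
#'
#' @param events a [FlowEventSet-class] or data.frame with a GFP column.
#' @param unstained optional unstained-control [FlowEventSet-class] or
#'   data.frame with a GFP column.
#' @param q quantile of the unstained GFP distribution defining the
#'   threshold (default 0.99).
#' @return list with \code{kept} (row indices), \code{threshold} and
#'   \code{n_excluded}.
#' @export
autofluorescenceGate <- function(events, unstained = NULL, q = 0.99) {
  ev <- if (is(events, "FlowEventSet")) events@events else as.data.frame(events)
  stopifnot("GFP" %in% colnames(ev))
  if (is.null(unstained))
    return(list(kept = seq_len(nrow(ev)), threshold = -Inf, n_excluded = 0L))
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  un <- if (is(unstained, "FlowEventSet")) unstained@events else
    as.data.frame(unstained)
  stopifnot("GFP" %in% colnames(un))
  thr <- stats::quantile(un$GFP, q, names = FALSE)
  kept <- which(ev$GFP > thr)
  if (!length(kept)) stop("no events above the autofluorescence threshold")
  list(kept = kept, threshold = thr, n_excluded = nrow(ev) - length(kept))
}

## One EM run from given initial parameters; returns NULL on failure.
emNormal2 <- function(x, w0, mu0, var0, tol, max_iter) {
  n <- length(x)
  w <- w0; mu <- mu0; v <- pmax(var0, 1e-12)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dens <- cbind(w[1] * stats::dnorm(x, mu[1], sqrt(v[1])),
                  w[2] * stats::dnorm(x, mu[2], sqrt(v[2])))
    rs <- rowSums(dens)
    if (any(rs <= 0) || any(!is.finite(rs))) return(NULL)
    ll <- sum(log(rs))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / rs
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk,
              1e-10 * stats::var(x))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ## EM guarantees a non-decreasing likelihood; a drop beyond numerical
  ## noise means the update is wrong, so fail loudly
  if (length(ll_trace) > 1L && any(diff(ll_trace) < -1e-6))
    stop("internal error: EM log-likelihood decreased")
  list(w = w, mu = mu, v = v, resp = resp, logLik = ll,
       converged = it < max_iter)
}

#' Two-component mixture gate for the induced population
#'
#' Fits a two-component normal mixture to log(RFP/GFP) values by
#' expectation-maximization, initialized from k-means and 10 seeded random
#' restarts; the component with the larger mean is the induced
#' (doxycycline-responsive) population and events are assigned by maximum
#' responsibility. Effectively unimodal data -- a component weight below
#' 0.01, mean separation under 0.1 pooled SD, or a BIC preferring a single
#' normal -- are flagged degenerate and all events assigned to the single
#' component rather than forcing a spurious split.
#'
#' @param log_ratios numeric vector of per-event log(RFP/GFP), >= 50
#'   events.
#' @param n_restarts random restarts in addition to the k-means start
#'   (default 10).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap per start (default 1000).
#' @param seed seed for the restarts.
#' @return a [MixtureFit-class].
#' @export
fitInducedMixture <- function(log_ratios, n_restarts = 10, tol = 1e-8,
                              max_iter = 1000, seed = 1) {
  x <- as.numeric(log_ratios)
  if (length(x) < 50L) stop("mixture gating needs at least 50 events")
  if (anyNA(x) || any(!is.finite(x))) stop("log ratios must be finite")
  sx <- stats::sd(x)
  if (sx == 0) {
    n <- length(x)
    return(new("MixtureFit", weights = c(1, 0), means = c(x[1], x[1]),
               variances = c(1e-12, 1e-12),
               responsibilities = cbind(rep(1, n), rep(0, n)),
               assignment = rep(1L, n), induced = 1L,
               logLik = NA_real_, converged = TRUE, degenerate = TRUE))
  }
  best <- NULL
  withSeed(seed, {
    km <- tryCatch(stats::kmeans(x, centers = 2L, nstart = 3L),
                   error = function(e) NULL)
    inits <- list()
    if (!is.null(km)) {
      vk <- vapply(1:2, function(k) {
        xk <- x[km$cluster == k]
        if (length(xk) > 1L) stats::var(xk) else sx^2 / 4
      }, numeric(1))
      inits[[1]] <- list(w = pmax(km$size / length(x), 0.01),
                         mu = as.numeric(km$centers), v = vk)
    }
    for (r in seq_len(n_restarts)) {
      q <- sort(stats::runif(2, 0.05, 0.95))
      inits[[length(inits) + 1L]] <- list(
        w = c(0.5, 0.5),
        mu = as.numeric(stats::quantile(x, q)),
        v = c(sx^2 / 4, sx^2 / 4))
    }
    for (ini in inits) {
      fit <- emNormal2(x, ini$w / sum(ini$w), ini$mu, ini$v, tol, max_iter)
      if (is.null(fit)) next
      if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
  })
  if (is.null(best))
    stop("mixture fit failed to converge from any start (n = ",
         length(x), ", sd = ", signif(sx, 3), ")")
  pooled_sd <- sqrt(sum(best$w * best$v))
  ## three degeneracy signals: a vanishing component, coincident means, or
  ## a BIC that prefers a single normal (EM happily splits unimodal data
  ## into two overlapping halves, which the first two checks cannot see)
  n <- length(x)
  ll1 <- sum(stats::dnorm(x, mean(x), sqrt(stats::var(x) * (n - 1) / n),
                          log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * best$logLik + 5 * log(n)
  degenerate <- min(best$w) < 0.01 ||
    abs(diff(best$mu)) < 0.1 * pooled_sd ||
    bic1 <= bic2
  if (degenerate) {
    major <- which.max(best$w)
    n <- length(x)
    resp <- matrix(0, n, 2); resp[, major] <- 1
    return(new("MixtureFit", weights = best$w, means = best$mu,
               variances = best$v, responsibilities = resp,
               assignment = rep(as.integer(major), n),
               induced = as.integer(major), logLik = best$logLik,
               converged = best$converged, degenerate = TRUE))
  }
  assignment <- max.col(best$resp)
  new("MixtureFit", weights = best$w, means = best$mu, variances = best$v,
      responsibilities = best$resp, assignment = as.integer(assignment),
      induced = as.integer(which.max(best$mu)), logLik = best$logLik,
      converged = best$converged, degenerate = FALSE)
}

#' @rdname MixtureFit-class
#' @export
setMethod("componentWeights", "MixtureFit", function(x) x@weights)

#' @rdname MixtureFit-class
#' @export
setMethod("componentMeans", "MixtureFit", function(x) x@means)

#' @rdname MixtureFit-class
#' @export
setMethod("componentVariances", "MixtureFit", function(x) x@variances)

#' @rdname MixtureFit-class
#' @export
setMethod("inducedComponent", "MixtureFit", function(x) x@induced)

#' @rdname MixtureFit-class
#' @export
setMethod("inducedAssignment", "MixtureFit",
          function(x) which(x@assignment == x@induced))

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf(
    "MixtureFit: weights %.3f/%.3f, means %.3f/%.3f, induced = component %d%s\n",
    object@weights[1], object@weights[2], object@means[1], object@means[2],
    object@induced, if (object@degenerate) " [degenerate]" else ""))
})

#' Condition-level flow summary with one-way ANOVA and contrasts
#'
#' Each independent cell population contributes one normalized RFP value:
#' the back-transformed (geometric-mean scale) mean induced-cell log-ratio,
#' or an already back-transformed \code{value} column. Values are expressed
#' as percent of the control condition's mean (control = 100% by
#' construction), compared across conditions by one-way ANOVA, and tested
#' with user-defined zero-sum contrasts on the condition means.
#'
#' @param populations data.frame with columns \code{population},
#'   \code{condition}, and either \code{log_ratio_mean} (mean induced-cell
#'   log(RFP/GFP)) or \code{value} (back-transformed).
#' @param control control condition label (default \code{"control"}).
#' @param contrasts named list of contrast coefficient vectors; each must
#'   be named by condition and sum to zero.
#' @param scale \code{"geometric"} (default; back-transform
#'   \code{exp(log_ratio_mean)}) or \code{"arithmetic"} (use \code{value}).
#' @return a [FlowConditionSummary-class].
#' @export
conditionSummaryAnova <- function(populations, control = "control",
                                  contrasts = NULL,
                                  scale = c("geometric", "arithmetic")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(populations),
            all(c("population", "condition") %in% colnames(populations)))
  pop <- populations
  if (scale == "geometric") {
    if (!"log_ratio_mean" %in% colnames(pop))
      stop("geometric scale requires a log_ratio_mean column")
    pop$value <- exp(pop$log_ratio_mean)
  } else if (!"value" %in% colnames(pop))
    stop("arithmetic scale requires a value column")
  counts <- table(pop$condition)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("excluding condition(s) with < 2 populations: ",
            paste(small, collapse = ", "))
    pop <- pop[!pop$condition %in% small, , drop = FALSE]
  }
  if (length(unique(pop$condition)) < 2L)
    stop("need at least 2 conditions with >= 2 populations each")
  if (!control %in% pop$condition) stop("control condition not present")
  ctrl_mean <- mean(pop$value[pop$condition == control])
  pop$pct <- 100 * pop$value / ctrl_mean
  pop$condition <- factor(pop$condition)
  ## identical populations: between- and within-condition mean squares are
  ## both numerical zero, so report F = 0 rather than a 0/0 artifact
  flat <- stats::var(pop$pct) < 1e-12 * (mean(pop$pct)^2 + 1)
  fit <- stats::aov(pct ~ condition, data = pop)
  an <- summary(fit)[[1]]
  cond_tab <- do.call(rbind, lapply(levels(pop$condition), function(cd) {
    x <- pop$pct[pop$condition == cd]
    data.frame(condition = cd, mean_pct = mean(x),
               se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  }))
  ctr_tab <- data.frame(contrast = character(), estimate = numeric(),
                        t = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (!is.null(contrasts)) {
    mse <- if (flat) 0 else an[["Mean Sq"]][2]
    df <- an[["Df"]][2]
    for (nm in names(contrasts)) {
      cf <- contrasts[[nm]]
      if (is.null(names(cf)) || !all(names(cf) %in% levels(pop$condition)))
        stop("contrast '", nm, "' must be named by condition")
      if (abs(sum(cf)) > 1e-12)
        stop("contrast '", nm, "' coefficients must sum to zero")
      mns <- vapply(names(cf), function(cd) mean(pop$pct[pop$condition == cd]),
                    numeric(1))
      ns <- vapply(names(cf), function(cd) sum(pop$condition == cd), numeric(1))
      est <- sum(cf * mns)
      se <- sqrt(mse * sum(cf^2 / ns))
      tval <- if (se > 0) est / se else 0
      pval <- if (se > 0) 2 * stats::pt(-abs(tval), df) else 1
      ctr_tab <- rbind(ctr_tab, data.frame(
        contrast = nm, estimate = est, t = tval, p = pval,
        stringsAsFactors = FALSE))
    }
  }
  Fv <- an[["F value"]][1]
  Pv <- an[["Pr(>F)"]][1]
  if (flat || !is.finite(Fv)) { Fv <- 0; Pv <- 1 }
  new("FlowConditionSummary", conditions = cond_tab,
      anovaF = Fv, anovaP = Pv, contrasts = ctr_tab,
      controlCondition = control)
}

setMethod("show", "FlowConditionSummary", function(object) {
  cat("FlowConditionSummary (control =", object@controlCondition, ")\n")
  print(object@conditions, row.names = FALSE)
  cat(sprintf("  one-way ANOVA: F = %.3f, p = %.4g\n",
              object@anovaF, object@anovaP))
  if (nrow(object@contrasts)) print(object@contrasts, row.names = FALSE)
})
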