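## End-to-end orchestration. The mRNA pipeline chains
## plates -> PlateQuant -> condition groups -> combination ratios ->
## control-max scaling -> SMCV contrasts; the flow pipeline chains
## events -> compensation -> log-ratio -> mixture gating -> ANOVA/contrast
## summaries. Both are pure functions of a config (list or JSON path) whose
## simulation blocks carry explicit seeds, so re-running a config
## reproduces outputs exactly.

readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON path")
  config
}

subSeed <- function(seed, k) (as.integer(seed) + 1009L * as.integer(k)) %% 2147483587L

## jsonlite simplifies a list of contrast specs to a data.frame with a
## nested coefficients column; normalize either form to a list of lists
## with a named numeric coefficients vector.
normalizeContrastSpecs <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    return(lapply(seq_len(nrow(x)), function(i) {
      co <- x$coefficients
      co <- if (is.data.frame(co)) unlist(co[i, , drop = FALSE]) else
        unlist(co[[i]])
      list(name = x$name[i], cell_line = x$cell_line[i], coefficients = co)
    }))
  }
  lapply(x, function(cs) {
    cs[["coefficients"]] <- unlist(cs[["coefficients"]])
    cs
  })
}

#' Run the mRNA quantification pipeline
#'
#' From a simulation block (or plate CSVs plus well metadata), quantifies
#' every plate (Cy0 + per-plate efficiency), averages duplicate reactions
#' into one RFP and one GFP expression value per measurement, forms
#' pairwise combination ratios per condition, scales each cell line to its
#' undamaged control's maximum, and evaluates the configured SMCV
#' contrasts per time point.
#'
#' Config fields (simulated mode): \code{simulation$design} (arguments of
#' [experimentDesign()]), \code{simulation$qpcr} (optional: efficiency,
#' fmax, d, noise_sd, n_cycles, duplicates), \code{contrasts} (list of
#' \code{list(name =, cell_line =, coefficients = list(vector = weight,
#' ...))}; a named list, not a named vector, so the names survive JSON),
#' \code{control} (control vector label). Real-data mode instead takes
#' \code{plates} (CSV paths) and \code{metadata} (CSV path mapping well to
#' cell_line, vector, time_h, replicate); exactly one of the two modes must
#' be configured.
#'
#' @param config list or JSON path.
#' @param out_dir optional output directory; intermediates and result
#'   tables are written there as CSV/JSON.
#' @return a \code{mrna_run_report} list: \code{timecourse},
#'   \code{contrasts}, \code{plate_efficiencies}, \code{exclusions},
#'   \code{counts}, \code{config_echo}.
#' @export
runMrnaPipeline <- function(config, out_dir = NULL) {
  t0 <- Sys.time()
  config <- readRunConfig(config)
  has_sim <- !is.null(config$simulation)
  has_real <- !is.null(config$plates)
  if (has_sim == has_real)
    stop("configure exactly one of simulation or plates")
  control <- if (!is.null(config$control)) config$control else "control"
  exclusions <- list()
  note <- function(stage, record, reason)
    exclusions[[length(exclusions) + 1L]] <<- data.frame(
      stage = stage, record = record, reason = reason,
      stringsAsFactors = FALSE)

  if (has_sim) {
    design <- config$simulation$design
    if (is.null(design)) stop("simulation block requires a design")
    if (!inherits(design, "experiment_design"))
      design <- do.call(experimentDesign, design)
    expr <- simulateExpressionExperiment(design)
    qp <- config$simulation$qpcr
    if (is.null(qp)) qp <- list()
    ## [[ ]] access throughout: $ would partial-match (e.g. qp$d against
    ## a "duplicates" field)
    dup <- if (is.null(qp[["duplicates"]])) 2L else as.integer(qp[["duplicates"]])
    eff_true <- if (is.null(qp[["efficiency"]])) 1.9 else qp[["efficiency"]]
    ## one simulated plate holding every reaction of the run; quantities
    ## are the simulated expression values
    wells <- list()
    meta <- list()
    for (gi in seq_along(expr$groups)) {
      g <- expr$groups[[gi]]
      for (r in seq_len(length(g))) {
        for (amp in c("RFP", "GFP")) {
          q <- if (amp == "RFP") g@rfp[r] else g@gfp[r]
          for (dd in seq_len(dup)) {
            wid <- sprintf("g%02dr%02d%s%d", gi, r, amp, dd)
            wells[[length(wells) + 1L]] <- data.frame(
              well = wid, amplicon = amp, quantity = q,
              stringsAsFactors = FALSE)
            meta[[length(meta) + 1L]] <- data.frame(
              well = wid, cell_line = g@cellLine, vector = g@vectorLabel,
              time_h = g@timeH, replicate = r, stringsAsFactors = FALSE)
          }
        }
      }
    }
    seed_q <- if (is.null(config$simulation$seed)) design$seed + 1L else
      config$simulation$seed
    cfg <- qpcrSimConfig(
      wells = do.call(rbind, wells), efficiency = eff_true,
      fmax = if (is.null(qp[["fmax"]])) 1000 else qp[["fmax"]],
      d = if (is.null(qp[["d"]])) 0.25 else qp[["d"]],
      noise_sd = if (is.null(qp[["noise_sd"]])) 5 else qp[["noise_sd"]],
      n_cycles = if (is.null(qp[["n_cycles"]])) 45 else qp[["n_cycles"]],
      seed = subSeed(seed_q, 1L))
    plates <- list(simulateQpcrPlate(cfg))
    metadata <- do.call(rbind, meta)
  } else {
    if (is.null(config$metadata)) stop("real-data mode requires metadata")
    if (!file.exists(config$metadata))
      stop("metadata file not found: ", config$metadata)
    missing_p <- config$plates[!file.exists(unlist(config$plates))]
    if (length(missing_p))
      stop("plate file(s) not found: ", paste(missing_p, collapse = ", "))
    metadata <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)
    plates <- lapply(unlist(config$plates), readPlateCsv)
  }

  ## stage: plate quantification (per-plate efficiency correction)
  quants <- lapply(plates, quantifyPlate)
  welltab <- do.call(rbind, lapply(seq_along(quants), function(i) {
    w <- wellData(quants[[i]]); w$plate <- i; w
  }))
  for (q in quants) {
    ex <- excludedWells(q)
    for (i in seq_len(nrow(ex)))
      note("qpcr_quant", ex$well[i], ex$reason[i])
  }

  ## stage: pair RFP/GFP per measurement, averaging duplicate reactions
  welltab <- merge(welltab, metadata, by = "well")
  keys <- unique(welltab[c("cell_line", "vector", "time_h", "replicate")])
  pairs <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- welltab$cell_line == keys$cell_line[i] &
      welltab$vector == keys$vector[i] &
      welltab$time_h == keys$time_h[i] &
      welltab$replicate == keys$replicate[i]
    sub <- welltab[sel, , drop = FALSE]
    rv <- sub$expression[sub$amplicon == "RFP"]
    gv <- sub$expression[sub$amplicon == "GFP"]
    if (!length(rv) || !length(gv)) {
      note("pairing", sprintf("%s/%s/%g/rep%s", keys$cell_line[i],
                              keys$vector[i], keys$time_h[i],
                              keys$replicate[i]),
           "measurement lost: no converged reaction for one amplicon")
      next
    }
    pairs[[length(pairs) + 1L]] <- cbind(keys[i, , drop = FALSE],
                                         rfp = mean(rv), gfp = mean(gv))
  }
  if (!length(pairs)) stop("pairing: no usable measurements")
  pairtab <- do.call(rbind, pairs)

  ## stage: condition groups -> combination ratios
  gkeys <- unique(pairtab[c("cell_line", "vector", "time_h")])
  combos <- list()
  for (i in seq_len(nrow(gkeys))) {
    sel <- pairtab$cell_line == gkeys$cell_line[i] &
      pairtab$vector == gkeys$vector[i] &
      pairtab$time_h == gkeys$time_h[i]
    sub <- pairtab[sel, , drop = FALSE]
    if (nrow(sub) < 2L) {
      note("combination", sprintf("%s/%s/%g", gkeys$cell_line[i],
                                  gkeys$vector[i], gkeys$time_h[i]),
           "fewer than 2 measurements; no combinations")
      next
    }
    grp <- new("ConditionGroup", cellLine = gkeys$cell_line[i],
               vectorLabel = gkeys$vector[i], timeH = gkeys$time_h[i],
               rfp = sub$rfp, gfp = sub$gfp)
    combos[[length(combos) + 1L]] <- combinationRatios(grp)
  }
  if (!length(combos)) stop("combination: no condition with >= 2 measurements")

  ## stage: scale to control max within each cell line, summarize
  cls <- unique(vapply(combos, function(x) x@cellLine, character(1)))
  scaled <- lapply(cls, function(cl) {
    scaleToControlMax(combos[vapply(combos, function(x)
      x@cellLine == cl, logical(1))], control = control)
  })
  names(scaled) <- cls
  timecourse <- do.call(rbind, lapply(scaled, summarizeTimecourse))
  rownames(timecourse) <- NULL

  ## stage: SMCV contrasts per time point on the scaled ratios
  contrast_rows <- list()
  for (cspec in normalizeContrastSpecs(config$contrasts)) {
    cl <- cspec[["cell_line"]]
    co <- cspec[["coefficients"]]
    if (is.null(names(co)) || any(!nzchar(names(co))))
      stop("contrast '", cspec$name, "': coefficients must be named by ",
           "vector label (use a named list so JSON keeps the names)")
    st <- scaled[[cl]]
    if (is.null(st)) stop("contrast '", cspec$name,
                          "': unknown cell line ", cl)
    v <- st@values
    for (tp in sort(unique(v$time_h))) {
      samples <- lapply(names(co), function(vec)
        v$value_pct[v$vector_label == vec & v$time_h == tp])
      if (any(vapply(samples, length, integer(1)) < 2L)) {
        note("contrast", sprintf("%s/%s/%g h", cspec$name, cl, tp),
             "a contrasted group has < 2 combination ratios")
        next
      }
      res <- smcvContrast(groupSummaries(samples), unname(co))
      contrast_rows[[length(contrast_rows) + 1L]] <- data.frame(
        contrast = cspec$name, cell_line = cl, time_h = tp,
        smcv = smcv(res), cplus = cplusProb(res), p = pValue(res),
        significant = isSignificant(res), stringsAsFactors = FALSE)
    }
  }
  contrast_tab <- if (length(contrast_rows)) do.call(rbind, contrast_rows)
    else data.frame()

  exclusions_tab <- if (length(exclusions)) do.call(rbind, exclusions)
    else data.frame(stage = character(), record = character(),
                    reason = character(), stringsAsFactors = FALSE)
  report <- structure(list(
    timecourse = timecourse,
    contrasts = contrast_tab,
    plate_efficiencies = lapply(quants, ampliconEfficiency),
    exclusions = exclusions_tab,
    counts = list(n_plates = length(plates),
                  n_wells = nrow(welltab),
                  n_measurements = nrow(pairtab),
                  n_conditions = length(combos),
                  n_excluded = nrow(exclusions_tab)),
    config_echo = config[setdiff(names(config), "simulation")],
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "mrna_run_report")
  if (!is.null(out_dir)) writeMrnaReport(report, out_dir)
  report
}

writeMrnaReport <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$timecourse, file.path(out_dir, "timecourse.csv"),
                   row.names = FALSE)
  if (nrow(report$contrasts))
    utils::write.csv(report$contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$counts, file.path(out_dir, "counts.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the flow-cytometry pipeline
#'
#' events -> spillover compensation -> log-ratio normalization -> mixture
#' gating of the induced population -> per-population summaries ->
#' condition-level ANOVA and contrasts.
#'
#' Config fields (simulated mode): \code{simulation$conditions} (list of
#' \code{list(name =, effect =, n_populations =)}; \code{effect} is the
#' RFP fraction of control, shifting the induced component's log-ratio mean
#' by \code{log(effect)}), \code{simulation$flow} (optional arguments of
#' [flowSimConfig()] shared by all populations), \code{simulation$seed}.
#' Real mode: \code{events} (list of \code{list(path =, condition =)}),
#' optional \code{spillover} (CSV path). A config with neither block
#' returns a skipped-stage report. \code{contrasts} as in
#' [conditionSummaryAnova()].
#'
#' @param config list or JSON path.
#' @param out_dir optional output directory.
#' @return a \code{flow_run_report} list.
#' @export
runFlowPipeline <- function(config, out_dir = NULL) {
  t0 <- Sys.time()
  config <- readRunConfig(config)
  if (is.null(config$simulation) && is.null(config$events))
    return(structure(list(stage = "skipped",
                          reason = "no flow inputs configured"),
                     class = "flow_run_report"))
  control <- if (!is.null(config$control)) config$control else "control"
  pops <- list()
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    if (is.null(sim$conditions)) stop("flow simulation requires conditions")
    base <- sim$flow
    if (is.null(base)) base <- list()
    seed0 <- if (is.null(sim$seed)) 1L else sim$seed
    k <- 0L
    for (cond in sim$conditions) {
      npop <- if (is.null(cond$n_populations)) 3L else cond$n_populations
      eff <- if (is.null(cond$effect)) 1 else cond$effect
      for (pi in seq_len(npop)) {
        k <- k + 1L
        args <- utils::modifyList(list(
          n_events = 2000L, induced_fraction = 0.6,
          induced_mean = 1, spillover = diag(3)), base)
        args$induced_mean <- args$induced_mean + log(eff)
        args$seed <- subSeed(seed0, k)
        fc <- do.call(flowSimConfig, args)
        ev <- simulateFlowEvents(fc)
        comp <- compensateEvents(ev, fc$spillover)
        lr <- logRatioNormalize(comp)
        mf <- fitInducedMixture(lr$log_ratio, seed = subSeed(seed0, 10000L + k))
        ind <- lr$log_ratio[inducedAssignment(mf)]
        pops[[k]] <- data.frame(
          population = sprintf("%s_pop%d", cond$name, pi),
          condition = cond$name, log_ratio_mean = mean(ind),
          n_events = length(lr$log_ratio), n_induced = length(ind),
          n_excluded = lr$n_excluded, degenerate = mf@degenerate,
          stringsAsFactors = FALSE)
      }
    }
  } else {
    spill <- if (!is.null(config$spillover))
      validateSpillover(as.matrix(utils::read.csv(config$spillover,
                                                  row.names = 1))) else NULL
    for (k in seq_along(config$events)) {
      e <- config$events[[k]]
      if (!file.exists(e$path)) stop("events file not found: ", e$path)
      ev <- readFlowCsv(e$path)
      if (!is.null(spill)) ev <- compensateEvents(ev, spill)
      lr <- logRatioNormalize(ev)
      mf <- fitInducedMixture(lr$log_ratio, seed = k)
      ind <- lr$log_ratio[inducedAssignment(mf)]
      pops[[k]] <- data.frame(
        population = if (!is.null(e$name)) e$name else basename(e$path),
        condition = e$condition, log_ratio_mean = mean(ind),
        n_events = length(lr$log_ratio), n_induced = length(ind),
        n_excluded = lr$n_excluded, degenerate = mf@degenerate,
        stringsAsFactors = FALSE)
    }
  }
  poptab <- do.call(rbind, pops)
  contrasts <- lapply(config$contrasts, function(co) unlist(co))
  names(contrasts) <- vapply(seq_along(config$contrasts), function(i) {
    nm <- names(config$contrasts)[i]
    if (!is.null(nm) && nzchar(nm)) nm else paste0("contrast", i)
  }, character(1))
  if (!length(contrasts)) contrasts <- NULL
  summ <- conditionSummaryAnova(poptab, control = control,
                                contrasts = contrasts)
  report <- structure(list(
    populations = poptab,
    summary = summ,
    counts = list(n_populations = nrow(poptab),
                  n_conditions = length(unique(poptab$condition)),
                  n_events = sum(poptab$n_events),
                  n_excluded = sum(poptab$n_excluded)),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "flow_run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(poptab, file.path(out_dir, "flow_populations.csv"),
                     row.names = FALSE)
    utils::write.csv(summ@conditions,
                     file.path(out_dir, "flow_conditions.csv"),
                     row.names = FALSE)
    if (nrow(summ@contrasts))
      utils::write.csv(summ@contrasts,
                       file.path(out_dir, "flow_contrasts.csv"),
                       row.names = FALSE)
  }
  report
}
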