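## Plain-text interchange formats: long-format plate CSV
## (well,amplicon,cycle,fluorescence), flow CSV (event,RFP,GFP,APC),
## tidy result CSVs, and JSON ground truth / summaries.

#' Read a long-format plate CSV into amplification curves
#'
#' Expects columns \code{well}, \code{amplicon}, \code{cycle},
#' \code{fluorescence} (header required, UTF-8).
#'
#' @param path CSV file.
#' @return an [AmplificationPlate-class] (no ground truth).
#' @export
readPlateCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "amplicon", "cycle", "fluorescence")
  if (!all(need %in% colnames(tab)))
    stop("plate CSV must have columns: ", paste(need, collapse = ", "))
  keys <- unique(tab[c("well", "amplicon")])
  curves <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- tab$well == keys$well[i] & tab$amplicon == keys$amplicon[i]
    sub <- tab[sel, , drop = FALSE]
    sub <- sub[order(sub$cycle), , drop = FALSE]
    new("AmplificationCurve", wellId = as.character(keys$well[i]),
        amplicon = as.character(keys$amplicon[i]),
        cycles = as.integer(sub$cycle), fluorescence = sub$fluorescence)
  })
  new("AmplificationPlate", curves = curves,
      groundTruth = data.frame())
}

#' Write an amplification plate as long-format CSV
#'
#' @param plate an [AmplificationPlate-class].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writePlateCsv <- function(plate, path) {
  stopifnot(is(plate, "AmplificationPlate"))
  tab <- do.call(rbind, lapply(plate@curves, function(cv)
    data.frame(well = cv@wellId, amplicon = cv@amplicon,
               cycle = cv@cycles, fluorescence = cv@fluorescence,
               stringsAsFactors = FALSE)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write plate quantification results as CSV plus a JSON summary
#'
#' @param pq a [PlateQuant-class].
#' @param path output CSV (well,amplicon,cy0,efficiency,expression);
#'   a \code{.json} summary with the per-amplicon efficiencies and the
#'   exclusion list is written next to it.
#' @return invisibly, the CSV path.
#' @export
writePlateQuant <- function(pq, path) {
  stopifnot(is(pq, "PlateQuant"))
  utils::write.csv(pq@wells, path, row.names = FALSE)
  summary_path <- sub("\\.csv$", ".json", path)
  if (identical(summary_path, path)) summary_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(amplicon_efficiency = as.list(pq@amplicon_efficiency),
         n_wells = nrow(pq@wells),
         excluded = pq@excluded),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a flow-event CSV
#'
#' Expects columns \code{event}, \code{RFP}, \code{GFP} and optionally
#' further channels such as \code{APC}.
#'
#' @param path CSV file.
#' @return a [FlowEventSet-class].
#' @export
readFlowCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("RFP", "GFP") %in% colnames(tab)))
    stop("flow CSV must have RFP and GFP columns")
  new("FlowEventSet", events = tab[setdiff(colnames(tab), "event")],
      truth = list())
}

#' Write a flow-event set as CSV
#'
#' @param events a [FlowEventSet-class].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeFlowCsv <- function(events, path) {
  stopifnot(is(events, "FlowEventSet"))
  tab <- cbind(event = seq_len(nrow(events@events)), events@events)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON beside a dataset
#'
#' @param truth a list or data.frame of ground-truth values.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeGroundTruthJson <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
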