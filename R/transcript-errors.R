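## Transcription-error calling. Reads are globally aligned to the expected
## transcript with a banded affine-gap aligner (match +1, mismatch -1, gap
## open -2 for the first gapped position, -1 per additional position, band
## +/- 5 around the diagonal); the aligned column at the lesion-opposite
## position determines the variant class. Off-site substitutions count
## toward the edit budget (> 3 differences = unclassifiable) but are not
## reported as lesion events: abnormal transcripts are read out only in the
## vicinity of the adduct.

NEG_INF <- -1e9

#' Banded global alignment of a read against the reference transcript
#'
#' Needleman-Wunsch with affine gaps restricted to a diagonal band. Returns
#' per-reference-position aligned read characters (gap = \code{"-"}) and
#' any inserted read bases with the reference position they follow.
#'
#' @param read RNA/DNA sequence (converted to RNA internally).
#' @param reference RNA/DNA reference sequence.
#' @param band half-width of the diagonal band (default 5).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; a gap of
#'   length L scores \code{gap_open + (L - 1) * gap_extend}.
#' @return list with \code{score}, \code{ref_align} (character vector,
#'   length nchar(reference)), \code{insertions} (data.frame
#'   \code{after_ref_pos}, \code{base}).
#' @export
alignReadBanded <- function(read, reference, band = 5,
                            match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  read <- asRnaSequence(read)
  reference <- asRnaSequence(reference)
  a <- strsplit(reference, "")[[1]]   # rows: reference
  b <- strsplit(read, "")[[1]]        # cols: read
  n <- length(a); m <- length(b)
  if (abs(n - m) > band)
    stop("read length differs from the reference by more than the band")
  ## state matrices: M diagonal, X ref-vs-gap (deletion), Y gap-vs-read
  ## (insertion); pointer matrices hold the predecessor state (1=M,2=X,3=Y)
  M <- matrix(NEG_INF, n + 1, m + 1)
  X <- matrix(NEG_INF, n + 1, m + 1)
  Y <- matrix(NEG_INF, n + 1, m + 1)
  pM <- matrix(0L, n + 1, m + 1)
  pX <- matrix(0L, n + 1, m + 1)
  pY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(min(n, band))) {
    X[i + 1, 1] <- gap_open + (i - 1) * gap_extend
    pX[i + 1, 1] <- if (i == 1) 1L else 2L
  }
  for (j in seq_len(min(m, band))) {
    Y[1, j + 1] <- gap_open + (j - 1) * gap_extend
    pY[1, j + 1] <- if (j == 1) 1L else 3L
  }
  for (i in seq_len(n)) {
    jlo <- max(1L, i - band); jhi <- min(m, i + band)
    for (j in jlo:jhi) {
      s <- if (a[i] == b[j]) match else mismatch
      prev <- c(M[i, j], X[i, j], Y[i, j])
      k <- which.max(prev)
      if (prev[k] > NEG_INF / 2) {
        M[i + 1, j + 1] <- prev[k] + s
        pM[i + 1, j + 1] <- k
      }
      ## deletion: ref[i] against a gap
      cand <- c(M[i, j + 1] + gap_open, X[i, j + 1] + gap_extend,
                Y[i, j + 1] + gap_open)
      k <- which.max(cand)
      if (cand[k] > NEG_INF / 2) {
        X[i + 1, j + 1] <- cand[k]
        pX[i + 1, j + 1] <- k
      }
      ## insertion: read[j] against a gap
      cand <- c(M[i + 1, j] + gap_open, Y[i + 1, j] + gap_extend,
                X[i + 1, j] + gap_open)
      k <- which.max(cand)
      if (cand[k] > NEG_INF / 2) {
        Y[i + 1, j + 1] <- cand[k]
        pY[i + 1, j + 1] <- if (k == 1L) 1L else if (k == 2L) 3L else 2L
      }
    }
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(fin)
  if (fin[state] <= NEG_INF / 2) stop("no alignment within the band")
  ## traceback
  ref_align <- character(n)
  ins <- list()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (state == 1L) {
      ref_align[i] <- b[j]
      state <- pM[i + 1, j + 1]
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      ref_align[i] <- "-"
      state <- pX[i + 1, j + 1]
      i <- i - 1
    } else {
      ins[[length(ins) + 1L]] <- data.frame(after_ref_pos = i, base = b[j],
                                            stringsAsFactors = FALSE)
      state <- pY[i + 1, j + 1]
      j <- j - 1
    }
  }
  insertions <- if (length(ins)) do.call(rbind, rev(ins)) else
    data.frame(after_ref_pos = integer(), base = character(),
               stringsAsFactors = FALSE)
  list(score = fin[which.max(fin)], ref_align = ref_align,
       insertions = insertions)
}

#' Classify one read at the lesion-opposite position
#'
#' Aligns the read to the reference and reads off the class of the column
#' at \code{lesion_opposite_pos}: \code{match},
#' \code{misincorporation:<base>}, \code{deletion}, or (for an inserted
#' read base adjacent to the lesion column) \code{insertion:<base>}. Reads
#' with more than \code{max_diffs} total differences (mismatches plus
#' gapped positions anywhere) are \code{unclassifiable}.
#'
#' @param read sequence (RNA or DNA letters); must be non-empty and within
#'   the alignment band of the reference length.
#' @param reference expected transcript.
#' @param lesion_opposite_pos 1-based lesion-opposite position in the
#'   reference.
#' @param max_diffs edit budget before a read is set aside (default 3).
#' @param band alignment band half-width (default 5).
#' @return character(1) class label.
#' @export
alignAndClassify <- function(read, reference, lesion_opposite_pos,
                             max_diffs = 3, band = 5) {
  if (!nzchar(read)) stop("empty read")
  reference <- asRnaSequence(reference)
  if (lesion_opposite_pos < 1 || lesion_opposite_pos > nchar(reference))
    stop("lesion position outside the reference")
  al <- alignReadBanded(read, reference, band = band)
  ref_chars <- strsplit(reference, "")[[1]]
  n_mm <- sum(al$ref_align != "-" & al$ref_align != ref_chars)
  n_del <- sum(al$ref_align == "-")
  n_ins <- nrow(al$insertions)
  if (n_mm + n_del + n_ins > max_diffs) return("unclassifiable")
  p <- lesion_opposite_pos
  col <- al$ref_align[p]
  if (col == "-") return("deletion")
  if (col != ref_chars[p])
    return(paste0("misincorporation:", col))
  near <- al$insertions$after_ref_pos %in% c(p - 1L, p)
  if (any(near))
    return(paste0("insertion:", al$insertions$base[which(near)[1]]))
  "match"
}

#' Classify a set of reads
#'
#' @param reads character vector of read sequences (named or not).
#' @inheritParams alignAndClassify
#' @return data.frame with columns \code{read_id} and \code{class}.
#' @export
classifyReads <- function(reads, reference, lesion_opposite_pos,
                          max_diffs = 3, band = 5) {
  ids <- if (!is.null(names(reads))) names(reads) else
    sprintf("read_%05d", seq_along(reads))
  cls <- vapply(reads, alignAndClassify, character(1),
                reference = reference,
                lesion_opposite_pos = lesion_opposite_pos,
                max_diffs = max_diffs, band = band, USE.NAMES = FALSE)
  data.frame(read_id = ids, class = cls, stringsAsFactors = FALSE)
}

#' Tally variant classes and apply the background-rate filter
#'
#' Counts lesion-site classes over classified reads; frequencies are counts
#' divided by the number of classified (not unclassifiable) reads. The
#' retained flag is set by [filterByBackground()]: a class is reported only
#' when its frequency is at least \code{fold_threshold} times the
#' background misincorporation rate (inclusive boundary).
#'
#' @param calls data.frame from [classifyReads()], or a character vector of
#'   classes.
#' @param background_rate per-base background misincorporation rate
#'   (default 0.001).
#' @param fold_threshold retention multiplier (default 10).
#' @return a [VariantTally-class].
#' @export
tallyVariants <- function(calls, background_rate = 0.001,
                          fold_threshold = 10) {
  cls <- if (is.data.frame(calls)) calls$class else as.character(calls)
  uncls <- sum(cls == "unclassifiable")
  cls <- cls[cls != "unclassifiable"]
  if (!length(cls)) stop("zero classified reads")
  tab <- table(cls)
  tally <- data.frame(class = names(tab), count = as.integer(tab),
                      frequency = as.numeric(tab) / length(cls),
                      stringsAsFactors = FALSE)
  tally <- tally[order(-tally$count, tally$class), , drop = FALSE]
  rownames(tally) <- NULL
  tally$retained <- NA
  out <- new("VariantTally", table = tally,
             nClassified = length(cls), nUnclassifiable = as.integer(uncls),
             backgroundRate = background_rate,
             foldThreshold = fold_threshold)
  filterByBackground(out)
}

#' Apply (or re-apply) the background-rate retention filter
#'
#' A variant class is retained exactly when
#' \code{frequency >= fold_threshold * background_rate}; the boundary is
#' inclusive. The \code{match} class is never flagged as an abnormal
#' transcript and is reported with \code{retained = NA}.
#'
#' @param tally a [VariantTally-class].
#' @param background_rate,fold_threshold optional overrides.
#' @return the tally with the \code{retained} column updated.
#' @export
filterByBackground <- function(tally, background_rate = NULL,
                               fold_threshold = NULL) {
  stopifnot(is(tally, "VariantTally"))
  if (!is.null(background_rate)) tally@backgroundRate <- background_rate
  if (!is.null(fold_threshold)) tally@foldThreshold <- fold_threshold
  if (tally@backgroundRate <= 0) stop("background_rate must be > 0")
  tab <- tally@table
  thr <- tally@foldThreshold * tally@backgroundRate
  tab$retained <- ifelse(tab$class == "match", NA, tab$frequency >= thr)
  tally@table <- tab
  validObject(tally)
  tally
}

#' @rdname VariantTally-class
#' @export
setMethod("tallyTable", "VariantTally", function(x) x@table)

setMethod("show", "VariantTally", function(object) {
  cat(sprintf(
    "VariantTally: %d classified, %d unclassifiable; filter >= %g x %g\n",
    object@nClassified, object@nUnclassifiable, object@foldThreshold,
    object@backgroundRate))
  print(object@table, row.names = FALSE)
})
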