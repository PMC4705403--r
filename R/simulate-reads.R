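## Synthetic amplicon reads: the expected transcript plus independent
## background substitutions and at most one lesion-site event per read.
## Internal representation is RNA; DNA input (T) is converted on ingestion.

RNA_BASES <- c("A", "C", "G", "U")

#' Convert a sequence to the internal RNA representation
#'
#' @param x character(1) sequence over A/C/G/T/U (case-insensitive).
#' @return uppercase RNA character string (T mapped to U).
#' @export
asRnaSequence <- function(x) {
  x <- toupper(as.character(x))
  x <- chartr("T", "U", x)
  if (!grepl("^[ACGU]+$", x)) stop("sequence must be over A/C/G/T/U")
  x
}

#' Configuration for simulated amplicon reads
#'
#' Lesion events are named like \code{"misincorporation:A"},
#' \code{"deletion"}, or \code{"insertion:G"}. Their probabilities must sum
#' to at most 1; the remainder is error-free copying at the lesion-opposite
#' position.
#'
#' @param reference expected transcript sequence (RNA or DNA letters),
#'   length >= 21 so the lesion-opposite position has usable flanks.
#' @param lesion_opposite_pos 1-based position opposite the adducted
#'   template base.
#' @param background_error_rate per-base substitution probability away from
#'   the lesion site (default 0.001, i.e. 0.1%).
#' @param lesion_event_profile named numeric vector of event probabilities
#'   (may be empty).
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @return a validated list of class \code{read_sim_config}.
#' @export
readSimConfig <- function(reference, lesion_opposite_pos,
                          background_error_rate = 0.001,
                          lesion_event_profile = numeric(0),
                          n_reads, seed = 1) {
  reference <- asRnaSequence(reference)
  if (nchar(reference) < 21L)
    stop("reference must be at least 21 nt (>= 10 nt flank each side)")
  if (lesion_opposite_pos < 1L || lesion_opposite_pos > nchar(reference))
    stop("lesion_opposite_pos outside the reference")
  if (background_error_rate < 0 || background_error_rate > 1)
    stop("background_error_rate must lie in [0, 1]")
  p <- lesion_event_profile
  if (length(p)) {
    if (is.null(names(p)) || any(!nzchar(names(p))))
      stop("lesion_event_profile must be named")
    if (any(p < 0 | p > 1) || sum(p) > 1)
      stop("lesion event probabilities must lie in [0, 1] and sum to <= 1")
    refbase <- substr(reference, lesion_opposite_pos, lesion_opposite_pos)
    for (nm in names(p)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      kind <- parts[1]
      if (!kind %in% c("misincorporation", "deletion", "insertion"))
        stop("unknown lesion event class: ", nm)
      if (kind != "deletion") {
        if (length(parts) != 2L || !parts[2] %in% RNA_BASES)
          stop("event ", nm, " must name a base, e.g. misincorporation:A")
        if (kind == "misincorporation" && parts[2] == refbase)
          stop("misincorporation base must differ from the reference base")
      }
    }
  }
  if (n_reads < 1L) stop("n_reads must be >= 1")
  structure(
    list(reference = reference,
         lesion_opposite_pos = as.integer(lesion_opposite_pos),
         background_error_rate = background_error_rate,
         lesion_event_profile = p, n_reads = as.integer(n_reads),
         seed = as.integer(seed)),
    class = "read_sim_config"
  )
}

#' Simulate amplicon reads over the expected transcript
#'
#' Each read is the reference with (i) independent background substitutions
#' at every position except the lesion-opposite one, at
#' \code{background_error_rate} per base, and (ii) at most one lesion-site
#' event drawn from \code{lesion_event_profile} (misincorporation replaces
#' the lesion-opposite base; deletion removes it; insertion adds a base
#' immediately 3' of it).
#'
#' @param config a [readSimConfig()] object.
#' @return list with \code{reads} (named character vector of RNA
#'   sequences), \code{truth} (data.frame: \code{read_id},
#'   \code{lesion_event}, \code{n_background}), and \code{reference}.
#' @export
simulateAmpliconReads <- function(config) {
  if (!inherits(config, "read_sim_config"))
    config <- do.call(readSimConfig, config)
  ref_chars <- strsplit(config$reference, "")[[1]]
  L <- length(ref_chars)
  pos <- config$lesion_opposite_pos
  off_lesion <- setdiff(seq_len(L), pos)
  p <- config$lesion_event_profile
  event_names <- c(names(p), "none")
  event_probs <- c(unname(p), 1 - sum(p))
  withSeed(config$seed, {
    reads <- character(config$n_reads)
    events <- character(config$n_reads)
    nbg <- integer(config$n_reads)
    for (i in seq_len(config$n_reads)) {
      chars <- ref_chars
      sub_at <- off_lesion[stats::runif(length(off_lesion)) <
                             config$background_error_rate]
      for (j in sub_at)
        chars[j] <- sample(setdiff(RNA_BASES, chars[j]), 1L)
      nbg[i] <- length(sub_at)
      ev <- sample(event_names, 1L, prob = event_probs)
      events[i] <- ev
      if (ev != "none") {
        parts <- strsplit(ev, ":", fixed = TRUE)[[1]]
        chars <- switch(parts[1],
          misincorporation = { chars[pos] <- parts[2]; chars },
          deletion = chars[-pos],
          insertion = append(chars, parts[2], after = pos)
        )
      }
      reads[i] <- paste(chars, collapse = "")
    }
    names(reads) <- sprintf("read_%05d", seq_len(config$n_reads))
    list(reads = reads,
         truth = data.frame(read_id = names(reads), lesion_event = events,
                            n_background = nbg, stringsAsFactors = FALSE),
         reference = config$reference)
  })
}

#' Write simulated reads as FASTQ (Phred+33, constant quality)
#'
#' RNA sequences are written with T in place of U, as sequencers report.
#'
#' @param reads named character vector of RNA sequences.
#' @param path output FASTQ path.
#' @param quality_char constant per-base quality character (default "I",
#'   Q40).
#' @return invisibly, the path.
#' @export
writeReadsFastq <- function(reads, path, quality_char = "I") {
  dna <- Biostrings::DNAStringSet(chartr("U", "T", reads))
  qual <- Biostrings::BStringSet(vapply(nchar(chartr("U", "T", reads)),
    function(w) strrep(quality_char, w), character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read amplicon reads from FASTQ into the internal RNA representation
#'
#' @param path FASTQ file.
#' @return named character vector of RNA sequences.
#' @export
readReadsFastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- chartr("T", "U", as.character(dna))
  names(out) <- names(dna)
  out
}

#' Write / read the expected transcript reference as FASTA
#'
#' @param sequence RNA/DNA sequence (written as DNA letters).
#' @param path FASTA path.
#' @param name sequence header.
#' @return invisibly, the path (writer); RNA character (reader).
#' @export
writeReferenceFasta <- function(sequence, path, name = "reference") {
  dna <- Biostrings::DNAStringSet(chartr("U", "T", asRnaSequence(sequence)))
  names(dna) <- name
  Biostrings::writeXStringSet(dna, path, format = "fasta")
  invisible(path)
}

#' @rdname writeReferenceFasta
#' @export
readReferenceFasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fasta")
  asRnaSequence(as.character(dna[[1]]))
}
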