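## Independent oracles used by the tests. These are deliberately separate
## implementations from the package code paths they check.

## Numeric Cy0 oracle: locate the inflection of the Richards curve by
## maximizing the first difference on a fine grid, then intersect the
## numeric tangent with zero fluorescence.
cy0NumericOracle <- function(fmax, b, c, d, step = 1e-3) {
  xinf <- c + b * log(d)
  xs <- seq(xinf - 8 * b - 2, xinf + 8 * b + 2, by = step)
  f <- fmax / (1 + exp(-(xs - c) / b))^d
  df <- diff(f)
  k <- which.max(df)
  x0 <- (xs[k] + xs[k + 1]) / 2
  slope <- df[k] / step
  f0 <- fmax / (1 + exp(-(x0 - c) / b))^d
  x0 - f0 / slope
}

## Full (unbanded) dynamic-programming global aligner with affine gaps,
## same scoring convention as the package (open -2 for the first gapped
## position, -1 per extension), written as a single 3-state recursion over
## a dense array with its own traceback. Returns the lesion-site class.
fullDpClassify <- function(read, ref, lesion_pos, max_diffs = 3) {
  a <- strsplit(toupper(chartr("T", "U", ref)), "")[[1]]
  b <- strsplit(toupper(chartr("T", "U", read)), "")[[1]]
  n <- length(a); m <- length(b)
  INF <- -1e9
  ## S[i+1, j+1, s]: best score of aligning a[1..i] vs b[1..j] ending in
  ## state s (1 = diagonal, 2 = gap in read/deletion, 3 = inserted base)
  S <- array(INF, c(n + 1, m + 1, 3))
  P <- array(0L, c(n + 1, m + 1, 3))
  S[1, 1, 1] <- 0
  for (i in seq_len(n)) {
    S[i + 1, 1, 2] <- -2 - (i - 1)
    P[i + 1, 1, 2] <- if (i == 1) 1L else 2L
  }
  for (j in seq_len(m)) {
    S[1, j + 1, 3] <- -2 - (j - 1)
    P[1, j + 1, 3] <- if (j == 1) 1L else 3L
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc <- if (a[i] == b[j]) 1 else -1
    v <- S[i, j, ] + sc
    S[i + 1, j + 1, 1] <- max(v); P[i + 1, j + 1, 1] <- which.max(v)
    v <- S[i, j + 1, ] + c(-2, -1, -2)
    S[i + 1, j + 1, 2] <- max(v); P[i + 1, j + 1, 2] <- which.max(v)
    v <- S[i + 1, j, ] + c(-2, -2, -1)
    S[i + 1, j + 1, 3] <- max(v); P[i + 1, j + 1, 3] <- which.max(v)
  }
  s <- which.max(S[n + 1, m + 1, ])
  ref_align <- character(n)
  ins_after <- integer(0); ins_base <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    s_prev <- P[i + 1, j + 1, s]
    if (s == 1) { ref_align[i] <- b[j]; i <- i - 1; j <- j - 1 }
    else if (s == 2) { ref_align[i] <- "-"; i <- i - 1 }
    else { ins_after <- c(ins_after, i); ins_base <- c(ins_base, b[j]); j <- j - 1 }
    s <- s_prev
  }
  n_diff <- sum(ref_align == "-") +
    sum(ref_align != "-" & ref_align != a) + length(ins_after)
  if (n_diff > max_diffs) return("unclassifiable")
  col <- ref_align[lesion_pos]
  if (col == "-") return("deletion")
  if (col != a[lesion_pos]) return(paste0("misincorporation:", col))
  near <- ins_after %in% c(lesion_pos - 1L, lesion_pos)
  if (any(near)) return(paste0("insertion:", ins_base[which(near)[1]]))
  "match"
}

## Fixture: expected transcript around the lesion. The damaged template
## 11-mer reverse-complements to GAGCGUACGAG with the lesion-opposite U at
## its center; synthetic 10-nt flanks complete a 31-nt reference.
lesionReference <- function() {
  list(sequence = paste0("ACGGAUUCCA", "GAGCGUACGAG", "UCCGGAAGGA"),
       lesion_pos = 16L)
}

## Noise-free Richards amplification curve as an AmplificationCurve.
makeRichardsCurve <- function(fmax = 1000, b = 1.5, c = 20, d = 1,
                              n_cycles = 40, well = "W1", amplicon = "RFP") {
  x <- seq_len(n_cycles)
  new("AmplificationCurve", wellId = well, amplicon = amplicon,
      cycles = x, fluorescence = richardsCurve(x, fmax, b, c, d))
}
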