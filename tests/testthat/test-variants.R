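test_that("reference-identical and lesion-edited reads classify correctly", {
  ref <- lesionReference()
  p <- ref$lesion_pos
  expect_equal(alignAndClassify(ref$sequence, ref$sequence, p), "match")
  ## U -> A at the lesion-opposite position
  mut <- ref$sequence
  substr(mut, p, p) <- "A"
  expect_equal(alignAndClassify(mut, ref$sequence, p), "misincorporation:A")
  ## lesion-opposite base missing, flanks intact
  del <- paste0(substr(ref$sequence, 1, p - 1),
                substr(ref$sequence, p + 1, nchar(ref$sequence)))
  expect_equal(alignAndClassify(del, ref$sequence, p), "deletion")
  ## base inserted right after the lesion column
  ins <- paste0(substr(ref$sequence, 1, p), "G",
                substr(ref$sequence, p + 1, nchar(ref$sequence)))
  expect_equal(alignAndClassify(ins, ref$sequence, p), "insertion:G")
  expect_error(alignAndClassify("", ref$sequence, p), "empty")
})

test_that("off-lesion edits count toward the budget but not the class", {
  ref <- lesionReference()
  p <- ref$lesion_pos
  ## three substitutions away from the lesion: still classified as match
  mut <- ref$sequence
  for (i in c(2, 5, 25)) {
    old <- substr(mut, i, i)
    substr(mut, i, i) <- setdiff(c("A", "C", "G", "U"), old)[1]
  }
  expect_equal(alignAndClassify(mut, ref$sequence, p), "match")
  ## a fourth pushes it over the budget
  substr(mut, 28, 28) <- setdiff(c("A", "C", "G", "U"),
                                 substr(mut, 28, 28))[1]
  expect_equal(alignAndClassify(mut, ref$sequence, p), "unclassifiable")
})

test_that("banded classification equals full dynamic programming on single-edit reads", {
  ref <- lesionReference()
  seqc <- strsplit(ref$sequence, "")[[1]]
  L <- length(seqc)
  p <- ref$lesion_pos
  reads <- character(0)
  ## every single substitution
  for (i in seq_len(L)) for (bb in setdiff(c("A", "C", "G", "U"), seqc[i])) {
    r <- seqc; r[i] <- bb
    reads <- c(reads, paste(r, collapse = ""))
  }
  ## every single deletion and every single insertion
  for (i in seq_len(L)) reads <- c(reads, paste(seqc[-i], collapse = ""))
  for (i in 0:L) for (bb in c("A", "C", "G", "U"))
    reads <- c(reads, paste(append(seqc, bb, after = i), collapse = ""))
  banded <- vapply(reads, alignAndClassify, character(1),
                   reference = ref$sequence, lesion_opposite_pos = p,
                   USE.NAMES = FALSE)
  oracle <- vapply(reads, fullDpClassify, character(1),
                   ref = ref$sequence, lesion_pos = p, USE.NAMES = FALSE)
  expect_identical(banded, oracle)
  ## single-edit reads are never unclassifiable
  expect_false(any(banded == "unclassifiable"))
})

test_that("classified plus unclassifiable reads always total the input", {
  ref <- lesionReference()
  rs <- simulateAmpliconReads(readSimConfig(
    ref$sequence, ref$lesion_pos, 0.02,
    c("misincorporation:C" = 0.1, "deletion" = 0.05),
    n_reads = 300, seed = 161))
  calls <- classifyReads(rs$reads, ref$sequence, ref$lesion_pos)
  tal <- tallyVariants(calls)
  expect_equal(tal@nClassified + tal@nUnclassifiable, 300)
})

test_that("variant frequencies recover the simulated lesion profile", {
  ref <- lesionReference()
  rs <- simulateAmpliconReads(readSimConfig(
    ref$sequence, ref$lesion_pos, 0, c("deletion" = 0.1),
    n_reads = 5000, seed = 162))
  calls <- classifyReads(rs$reads, ref$sequence, ref$lesion_pos)
  tal <- tallyVariants(calls)
  tab <- tallyTable(tal)
  expect_equal(tab$frequency[tab$class == "deletion"], 0.1,
               tolerance = 0.01 / 0.1)
})

test_that("tally arithmetic and the zero-classified error", {
  tal <- tallyVariants(rep("match", 100))
  tab <- tallyTable(tal)
  expect_equal(tab$frequency[tab$class == "match"], 1.0)
  expect_equal(nrow(tab), 1)
  tal2 <- tallyVariants(c(rep("match", 95), rep("misincorporation:C", 5)))
  tab2 <- tallyTable(tal2)
  expect_equal(tab2$frequency[tab2$class == "misincorporation:C"], 0.05)
  expect_error(tallyVariants(rep("unclassifiable", 5)), "zero classified")
})

test_that("the 10x background filter has an inclusive boundary", {
  calls <- c(rep("match", 990), rep("misincorporation:A", 10))
  tab <- tallyTable(tallyVariants(calls))  # frequency exactly 0.010
  expect_true(tab$retained[tab$class == "misincorporation:A"])
  calls2 <- c(rep("match", 9901), rep("misincorporation:A", 99))
  tab2 <- tallyTable(tallyVariants(calls2))  # 0.0099: just below
  expect_false(tab2$retained[tab2$class == "misincorporation:A"])
  ## absent class: frequency 0 is never retained (by construction absent
  ## classes are not listed)
  expect_false("deletion" %in% tab2$class)
})

test_that("raising the fold threshold never retains a dropped class", {
  calls <- c(rep("match", 930), rep("misincorporation:A", 50),
             rep("deletion", 15), rep("insertion:G", 5))
  tal <- tallyVariants(calls)
  prev <- NULL
  for (fold in c(5, 10, 20, 60)) {
    tab <- tallyTable(filterByBackground(tal, fold_threshold = fold))
    kept <- tab$class[which(tab$retained)]
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})
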