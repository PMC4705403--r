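test_that("all four generators are deterministic under a fixed seed", {
  qcfg <- qpcrSimConfig(
    wells = data.frame(well = c("A1", "B1"), amplicon = c("RFP", "GFP"),
                       quantity = c(1e-4, 2e-4)),
    efficiency = 1.9, seed = 11)
  p1 <- simulateQpcrPlate(qcfg); p2 <- simulateQpcrPlate(qcfg)
  expect_identical(
    lapply(curves(p1), function(cv) cv@fluorescence),
    lapply(curves(p2), function(cv) cv@fluorescence))

  des <- experimentDesign("NHF", c("control", "BaP"), c(6, 18),
                          n_replicates = 3, seed = 12)
  e1 <- simulateExpressionExperiment(des)
  e2 <- simulateExpressionExperiment(des)
  expect_identical(lapply(e1$groups, rfp), lapply(e2$groups, rfp))

  fcfg <- flowSimConfig(n_events = 500, induced_fraction = 0.5, seed = 13)
  f1 <- simulateFlowEvents(fcfg); f2 <- simulateFlowEvents(fcfg)
  expect_identical(eventData(f1), eventData(f2))

  ref <- lesionReference()
  rcfg <- readSimConfig(ref$sequence, ref$lesion_pos, 0.001,
                        c("deletion" = 0.1), n_reads = 100, seed = 14)
  r1 <- simulateAmpliconReads(rcfg); r2 <- simulateAmpliconReads(rcfg)
  expect_identical(r1$reads, r2$reads)
})

test_that("invalid generator configs are rejected", {
  w <- data.frame(well = "A1", amplicon = "RFP", quantity = 1e-4)
  expect_error(qpcrSimConfig(w, efficiency = 2.3), "efficiency")
  expect_error(qpcrSimConfig(w, efficiency = 1.0), "efficiency")
  expect_error(qpcrSimConfig(w, efficiency = 2, n_cycles = 5), "n_cycles")
  expect_error(
    qpcrSimConfig(data.frame(well = "A1", amplicon = "RFP", quantity = -1),
                  efficiency = 2), "quantities")
  expect_error(experimentDesign("NHF", "control", 18, n_replicates = 0),
               "n_replicates")
  expect_error(experimentDesign(character(), "control", 18), "at least one")
  expect_error(flowSimConfig(100, induced_fraction = 1.3), "induced_fraction")
  sing <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  expect_error(flowSimConfig(100, 0.5, spillover = sing))
  ref <- lesionReference()
  expect_error(readSimConfig(ref$sequence, 99, n_reads = 10), "outside")
  expect_error(readSimConfig(ref$sequence, ref$lesion_pos,
                             lesion_event_profile = c("deletion" = 0.7,
                                                      "insertion:A" = 0.5),
                             n_reads = 10), "sum")
})

test_that("simulated GFP is gamma with the designed shape and positive skew", {
  des <- experimentDesign("NHF", "control", 18, n_replicates = 10000,
                          gfp_shape = 1.5, seed = 21)
  g <- gfp(simulateExpressionExperiment(des)$groups[[1]])
  expect_equal(gammaShapeMoM(g), 1.5, tolerance = 0.1 / 1.5)
  skew <- mean((g - mean(g))^3) / stats::sd(g)^3
  expect_gt(skew, 0)
})

test_that("control conditions have unit RFP/GFP ratio up to noise", {
  des <- experimentDesign("NHF", "control", 18, n_replicates = 2000,
                          noise_cv = 0.1, seed = 22)
  g <- simulateExpressionExperiment(des)$groups[[1]]
  expect_equal(mean(rfp(g) / gfp(g)), 1, tolerance = 0.02)
})

test_that("the condition-effect surface is applied to RFP only", {
  eff <- data.frame(cell_line = "NHF", vector = "BaP", time_h = 18,
                    effect = 0.3)
  des <- experimentDesign("NHF", c("control", "BaP"), 18,
                          n_replicates = 500, condition_effect = eff,
                          noise_cv = 0.05, seed = 23)
  sim <- simulateExpressionExperiment(des)
  lab <- vapply(sim$groups, function(g) g@vectorLabel, character(1))
  bap <- sim$groups[[which(lab == "BaP")]]
  ctl <- sim$groups[[which(lab == "control")]]
  expect_equal(mean(rfp(bap) / gfp(bap)), 0.3, tolerance = 0.02)
  expect_equal(mean(rfp(ctl) / gfp(ctl)), 1, tolerance = 0.02)
})

test_that("flow labels match the induced fraction; identity spillover preserves signals", {
  cfg <- flowSimConfig(n_events = 10000, induced_fraction = 0.7, seed = 31)
  ev <- simulateFlowEvents(cfg)
  expect_equal(mean(groundTruth(ev)$induced), 0.7, tolerance = 0.02 / 0.7)
  ## identity spillover: observed equals true, per-event sums conserved
  expect_equal(as.matrix(eventData(ev)), groundTruth(ev)$trueSignals,
               ignore_attr = TRUE)
  cfg0 <- flowSimConfig(n_events = 200, induced_fraction = 0, seed = 32)
  expect_false(any(groundTruth(simulateFlowEvents(cfg0))$induced))
})

test_that("read simulation respects its event and background rates", {
  ref <- lesionReference()
  ## all rates zero: every read is the reference
  r0 <- simulateAmpliconReads(readSimConfig(ref$sequence, ref$lesion_pos,
                                            0, n_reads = 50, seed = 41))
  expect_true(all(r0$reads == ref$sequence))
  ## lesion event rate recovered
  rc <- readSimConfig(ref$sequence, ref$lesion_pos, 0,
                      c("misincorporation:A" = 0.2), n_reads = 5000,
                      seed = 42)
  rs <- simulateAmpliconReads(rc)
  expect_equal(mean(rs$truth$lesion_event == "misincorporation:A"), 0.2,
               tolerance = 0.02 / 0.2)
  ## background substitutions per read ~ rate * (L - 1) off-lesion
  rb <- simulateAmpliconReads(readSimConfig(
    strrep("ACGU", 25), 50, 0.001, n_reads = 5000, seed = 43))
  expect_equal(mean(rb$truth$n_background), 0.001 * 99, tolerance = 0.2)
})

test_that("reads and references roundtrip through FASTQ/FASTA", {
  ref <- lesionReference()
  rs <- simulateAmpliconReads(readSimConfig(ref$sequence, ref$lesion_pos,
                                            0.01, n_reads = 20, seed = 44))
  fq <- tempfile(fileext = ".fastq")
  writeReadsFastq(rs$reads, fq)
  back <- readReadsFastq(fq)
  expect_equal(unname(back), unname(rs$reads))
  fa <- tempfile(fileext = ".fasta")
  writeReferenceFasta(ref$sequence, fa)
  expect_equal(readReferenceFasta(fa), ref$sequence)
  unlink(c(fq, fa))
})
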