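spill3 <- function(rfp_gfp = 0.1, gfp_rfp = 0.05) {
  m <- diag(3)
  dimnames(m) <- list(c("RFP", "GFP", "APC"), c("RFP", "GFP", "APC"))
  m["GFP", "RFP"] <- gfp_rfp  # GFP fluorophore bleeding into RFP detector
  m["RFP", "GFP"] <- rfp_gfp
  m
}

test_that("compensation inverts the simulator's spillover exactly", {
  sp <- spill3()
  ev <- simulateFlowEvents(flowSimConfig(n_events = 2000,
                                         induced_fraction = 0.5,
                                         spillover = sp, seed = 121))
  comp <- compensateEvents(ev, sp)
  err <- max(abs(as.matrix(eventData(comp)[, c("RFP", "GFP", "APC")]) -
                   groundTruth(ev)$trueSignals))
  expect_lt(err / max(groundTruth(ev)$trueSignals), 1e-9)
  ## identity spillover: output equals input
  id <- compensateEvents(ev, diag(3))
  expect_equal(as.matrix(eventData(id)[, 1:3]),
               as.matrix(eventData(ev)[, 1:3]), ignore_attr = TRUE)
})

test_that("singular or malformed spillover matrices are rejected", {
  bad <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  expect_error(validateSpillover(bad))
  nonunit <- diag(3); nonunit[1, 1] <- 0.9
  expect_error(validateSpillover(nonunit), "diagonal")
  expect_error(validateSpillover(matrix(1, 2, 3)), "square")
})

test_that("log-ratio normalization maps and filters as specified", {
  ev <- data.frame(RFP = c(5, exp(1) * 3, 2, -1),
                   GFP = c(5, 3, 0, 4), APC = 1)
  lr <- logRatioNormalize(ev)
  expect_equal(lr$log_ratio, c(0, 1))
  expect_equal(lr$n_excluded, 2)
  expect_error(logRatioNormalize(data.frame(RFP = -1, GFP = 2)), "positive")
})

test_that("the mixture gate recovers simulated components", {
  set.seed(131)
  x <- c(rnorm(3000, -2, 0.5), rnorm(7000, 1, 0.5))
  mf <- fitInducedMixture(x, seed = 132)
  expect_false(mf@degenerate)
  ind <- inducedComponent(mf)
  expect_equal(componentWeights(mf)[ind], 0.7, tolerance = 0.05 / 0.7)
  expect_equal(componentMeans(mf)[ind], 1, tolerance = 0.1)
  expect_equal(componentMeans(mf)[3 - ind], -2, tolerance = 0.1 / 2)
  ## induced component is always the one with the larger mean
  expect_equal(componentMeans(mf)[ind], max(componentMeans(mf)))
})

test_that("mixture recovery agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  set.seed(133)
  x <- c(rnorm(2000, -1.5, 0.6), rnorm(3000, 0.8, 0.5))
  mf <- fitInducedMixture(x, seed = 134)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  ours <- sort(componentMeans(mf))
  theirs <- sort(mc$parameters$mean)
  expect_equal(ours, theirs, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("degenerate and boundary mixtures are flagged, not forced", {
  expect_true(fitInducedMixture(rep(1.3, 100))@degenerate)
  set.seed(135)
  one <- fitInducedMixture(rnorm(2000, 0, 0.4), seed = 136)
  if (!one@degenerate) {
    ## if two components are kept on unimodal data they must be nearly
    ## coincident or one must carry almost no weight -- never a confident
    ## split
    sep <- abs(diff(componentMeans(one))) /
      sqrt(sum(componentWeights(one) * componentVariances(one)))
    expect_lt(min(min(componentWeights(one)), sep), 0.5)
  }
  expect_error(fitInducedMixture(rnorm(10)), "50")
})

test_that("fully induced simulations assign nearly all events as induced", {
  ev <- simulateFlowEvents(flowSimConfig(n_events = 4000,
                                         induced_fraction = 1, seed = 137))
  lr <- logRatioNormalize(ev)
  mf <- fitInducedMixture(lr$log_ratio, seed = 138)
  expect_gte(length(inducedAssignment(mf)) / length(lr$log_ratio), 0.99)
})

test_that("condition summaries normalize to control and test contrasts", {
  set.seed(141)
  pops <- data.frame(
    population = sprintf("p%d", 1:9),
    condition = rep(c("control", "BaP", "BcPh"), each = 3),
    log_ratio_mean = c(rnorm(3, 1, 0.03), rnorm(3, 1 + log(0.5), 0.03),
                       rnorm(3, 1 + log(0.33), 0.03)))
  summ <- conditionSummaryAnova(
    pops, control = "control",
    contrasts = list(BaP_vs_control = c(control = 1, BaP = -1)))
  cond <- summ@conditions
  expect_equal(cond$mean_pct[cond$condition == "control"], 100,
               tolerance = 1e-6)
  expect_equal(cond$mean_pct[cond$condition == "BaP"], 50, tolerance = 5 / 50)
  expect_equal(cond$mean_pct[cond$condition == "BcPh"], 33, tolerance = 5 / 33)
  expect_lt(summ@anovaP, 0.01)
  expect_lt(summ@contrasts$p[1], 0.05)
})

test_that("identical populations give F = 0 and zero contrasts", {
  pops <- data.frame(population = sprintf("p%d", 1:6),
                     condition = rep(c("control", "BaP"), each = 3),
                     log_ratio_mean = rep(0.7, 6))
  summ <- conditionSummaryAnova(
    pops, contrasts = list(null = c(control = 1, BaP = -1)))
  expect_equal(summ@anovaF, 0)
  expect_equal(summ@contrasts$t[1], 0)
})

test_that("contrast and population validation in condition summaries", {
  pops <- data.frame(population = sprintf("p%d", 1:7),
                     condition = c(rep("control", 3), rep("BaP", 3), "solo"),
                     log_ratio_mean = rnorm(7))
  expect_warning(conditionSummaryAnova(pops), "solo")
  expect_error(
    suppressWarnings(conditionSummaryAnova(
      pops, contrasts = list(bad = c(control = 1, BaP = -0.5)))),
    "sum to zero")
})

test_that("the autofluorescence gate thresholds on the unstained control", {
  set.seed(145)
  ev <- data.frame(RFP = rlnorm(500, 5), GFP = rlnorm(500, 5), APC = 1)
  ## no unstained control: everything passes
  g0 <- autofluorescenceGate(ev)
  expect_length(g0$kept, 500)
  un <- data.frame(GFP = runif(1000, 0, 40))
  g1 <- autofluorescenceGate(ev, un, q = 0.99)
  expect_equal(g1$threshold, quantile(un$GFP, 0.99), ignore_attr = TRUE)
  expect_true(all(ev$GFP[g1$kept] > g1$threshold))
  expect_equal(length(g1$kept) + g1$n_excluded, 500)
  ## unstained brighter than every event: nothing survives
  expect_error(autofluorescenceGate(ev, data.frame(GFP = 1e9), q = 0),
               "threshold")
})

test_that("flow CSV roundtrips", {
  ev <- simulateFlowEvents(flowSimConfig(n_events = 50,
                                         induced_fraction = 0.5, seed = 151))
  path <- tempfile(fileext = ".csv")
  writeFlowCsv(ev, path)
  back <- readFlowCsv(path)
  expect_equal(eventData(back)$RFP, eventData(ev)$RFP, tolerance = 1e-12)
  unlink(path)
})
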