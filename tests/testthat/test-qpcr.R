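test_that("noiseless Richards parameters are recovered by the fitter", {
  cv <- makeRichardsCurve(fmax = 1000, b = 1.5, c = 20, d = 1)
  ft <- fitAmplificationModel(cv)
  expect_true(ft@converged)
  expect_equal(ft@fmax, 1000, tolerance = 1e-3)
  expect_equal(ft@b, 1.5, tolerance = 1e-3)
  expect_equal(ft@c, 20, tolerance = 1e-3)
  expect_equal(ft@d, 1, tolerance = 1e-3)
})

test_that("flat and malformed curves are handled as specified", {
  flat <- new("AmplificationCurve", wellId = "F1", amplicon = "RFP",
              cycles = 1:40, fluorescence = rep(0, 40))
  expect_false(fitAmplificationModel(flat)@converged)
  expect_error(new("AmplificationCurve", wellId = "X", amplicon = "RFP",
                   cycles = 1:9, fluorescence = rnorm(9)), "10 cycles")
  expect_error(new("AmplificationCurve", wellId = "X", amplicon = "RFP",
                   cycles = 1:12, fluorescence = rnorm(11)), "equal length")
})

test_that("fit residual scale tracks the injected noise", {
  cfg <- qpcrSimConfig(
    wells = data.frame(well = "A1", amplicon = "RFP", quantity = 1e-4),
    efficiency = 1.9, noise_sd = 5, seed = 51)
  ft <- fitAmplificationModel(curves(simulateQpcrPlate(cfg))[[1]])
  expect_true(ft@converged)
  expect_lte(ft@rmse, 3 * 5)
})

test_that("Cy0 has the logistic closed form and the steep-curve limit", {
  ft <- new("RichardsFit", wellId = "w", amplicon = "RFP", fmax = 1000,
            b = 2, c = 20, d = 1, rmse = 0, converged = TRUE)
  expect_identical(computeCy0(ft), 20 - 2 * 2)  # c - 2b = 16 exactly
  ft@b <- 1e-4
  expect_equal(computeCy0(ft), 20, tolerance = 1e-3)
  ft@converged <- FALSE
  expect_error(computeCy0(ft), "converged")
})

test_that("Cy0 matches the numeric tangent oracle over a parameter sweep", {
  set.seed(61)
  for (i in 1:40) {
    b <- runif(1, 0.3, 3); c <- runif(1, 15, 30)
    d <- runif(1, 0.1, 4); fmax <- runif(1, 500, 2000)
    ft <- new("RichardsFit", wellId = "w", amplicon = "RFP", fmax = fmax,
              b = b, c = c, d = d, rmse = 0, converged = TRUE)
    expect_equal(computeCy0(ft), cy0NumericOracle(fmax, b, c, d),
                 tolerance = 0.05, ignore_attr = TRUE)
  }
})

test_that("efficiency is exact on pure exponentials and guarded at boundaries", {
  x <- 1:30
  pow2 <- new("AmplificationCurve", wellId = "w", amplicon = "RFP",
              cycles = x, fluorescence = 0.01 * 2^x)
  expect_equal(estimateReactionEfficiency(pow2, 15), 2, tolerance = 1e-9)
  pow19 <- new("AmplificationCurve", wellId = "w", amplicon = "RFP",
               cycles = x, fluorescence = 0.01 * 1.9^x)
  expect_equal(estimateReactionEfficiency(pow19, 15), 1.9, tolerance = 1e-6)
  ## window incomplete near the start of the run
  expect_error(estimateReactionEfficiency(pow2, 1.4), "window")
  ## non-positive fluorescence in the window
  neg <- new("AmplificationCurve", wellId = "w", amplicon = "RFP",
             cycles = x, fluorescence = c(-1, 0.01 * 2^(2:30)))
  expect_error(estimateReactionEfficiency(neg, 3), "non-positive")
})

test_that("expression values follow Eff^(-Cy0)", {
  expect_identical(expressionValue(2, 0), 1)
  expect_equal(expressionValue(2, 10), 2^-10)
  expect_error(expressionValue(0.9, 5), "exceed 1")
  ## monotonicity: expression strictly decreasing in Cy0 for fixed Eff > 1
  cys <- seq(0, 30, by = 0.5)
  expect_true(all(diff(expressionValue(1.9, cys)) < 0))
})

test_that("plate quantification recovers known input ratios", {
  ## 8-fold true input difference, perfect doubling, noiseless
  cfg <- qpcrSimConfig(
    wells = data.frame(well = c("A1", "A2"), amplicon = "RFP",
                       quantity = c(8e-5, 1e-5)),
    efficiency = 2, noise_sd = 0, seed = 71)
  pq <- quantifyPlate(simulateQpcrPlate(cfg))
  w <- wellData(pq)
  ## delta-Cy0 is exactly log2(8) = 3 cycles
  expect_equal(abs(diff(w$cy0)), 3, tolerance = 1e-3)
  expect_equal(w$expression[w$well == "A1"] / w$expression[w$well == "A2"],
               8, tolerance = 0.10)
})

test_that("non-converged wells are excluded and empty amplicons are an error", {
  cfg <- qpcrSimConfig(
    wells = data.frame(well = c("A1", "A2"), amplicon = c("RFP", "GFP"),
                       quantity = c(1e-4, 1e-4)),
    efficiency = 1.9, noise_sd = 0, seed = 81)
  plate <- simulateQpcrPlate(cfg)
  flat <- new("AmplificationCurve", wellId = "Z9", amplicon = "RFP",
              cycles = 1:45, fluorescence = rep(0, 45))
  pq <- quantifyPlate(c(curves(plate), list(flat)))
  expect_equal(excludedWells(pq)$well, "Z9")
  expect_equal(nrow(wellData(pq)), 2)
  ## an amplicon whose only curve fails must be named in the error
  expect_error(quantifyPlate(list(curves(plate)[[2]], flat)), "RFP")
})

test_that("simulated plates recover efficiency and pairwise ratios", {
  ## low noise (0.25% of Fmax), quantities spread over ~4 log2 units
  q <- 1e-4 * 2^seq(0, 4, length.out = 8)
  cfg <- qpcrSimConfig(
    wells = data.frame(well = sprintf("W%d", 1:8), amplicon = "GFP",
                       quantity = q),
    efficiency = 1.9, noise_sd = 2.5, seed = 91)
  pq <- quantifyPlate(simulateQpcrPlate(cfg))
  expect_equal(unname(ampliconEfficiency(pq)["GFP"]), 1.9,
               tolerance = 0.05 / 1.9)
  w <- wellData(pq)
  w <- w[match(sprintf("W%d", 1:8), w$well), ]
  true_ratio <- q / q[1]
  expect_equal(w$expression / w$expression[1], true_ratio,
               tolerance = 0.10, ignore_attr = TRUE)
})

test_that("plate CSV roundtrips through the reader and writer", {
  cfg <- qpcrSimConfig(
    wells = data.frame(well = c("A1", "B1"), amplicon = c("RFP", "GFP"),
                       quantity = c(1e-4, 2e-4)),
    efficiency = 1.9, seed = 95)
  plate <- simulateQpcrPlate(cfg)
  path <- tempfile(fileext = ".csv")
  writePlateCsv(plate, path)
  back <- readPlateCsv(path)
  expect_equal(length(back), length(plate))
  expect_equal(curves(back)[[1]]@fluorescence,
               curves(plate)[[1]]@fluorescence)
  unlink(path)
})
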