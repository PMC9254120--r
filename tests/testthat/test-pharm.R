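test_that("noiseless logistic data recover all three parameters", {
  cc <- 10^seq(-13, -7, length.out = 8)
  dat <- data.frame(concentration_M = cc,
                    response = 100 / (1 + 1e-10 / cc))
  fit <- fitLogistic3(dat)
  expect_lt(abs(fit@basal), 1e-6)
  expect_lt(abs(fit@emax - 100), 1e-6)
  expect_lt(abs(fit@ec50 - 1e-10) / 1e-10, 1e-6)
  # midpoint identity: R(EC50) = (basal + Emax)/2
  expect_equal(predictResponse(fit, fit@ec50),
               (fit@basal + fit@emax) / 2)
  expect_error(fitLogistic3(dat[1:3, ]), "distinct")
})

test_that("noiseless bell data with 10x separated potencies recover within 1%", {
  tru <- list(basal = 5, spanS = 100, ec50S = 1e-10, spanI = 80,
              ec50I = 1e-9)
  gd <- generateDoseResponse(tru, noiseSD = 0, nRep = 1, seed = 1)
  fit <- fitBell(gd$total)
  expect_equal(fit@flag, "ok")
  expect_lt(abs(fit@spanS - 100) / 100, 0.01)
  expect_lt(abs(fit@spanI - 80) / 80, 0.01)
  expect_lt(abs(fit@ec50S - 1e-10) / 1e-10, 0.01)
  expect_lt(abs(fit@ec50I / fit@ec50S - 10) / 10, 0.01)
})

test_that("the bell fit nests the logistic fit", {
  cc <- 10^seq(-13, -7, length.out = 8)
  dat <- data.frame(concentration_M = cc,
                    response = 10 + 90 / (1 + 1e-10 / cc))
  l3 <- fitLogistic3(dat)
  nested <- fitBell(dat, fixSpanI = 0)
  expect_equal(nested@flag, "collapsed_to_logistic3")
  expect_equal(nested@emax, l3@emax, tolerance = 1e-6)
  expect_equal(nested@ec50, l3@ec50, tolerance = 1e-6)
  # span_i = 0 data collapse on their own too
  free <- fitBell(dat)
  expect_lt(free@spanI, 1)
  expect_equal(free@emax, l3@emax, tolerance = 0.02)
})

test_that("the fitted bell maximum lies between the two EC50s", {
  tru <- list(basal = 0, spanS = 100, ec50S = 1e-10, spanI = 90,
              ec50I = 2e-9)
  gd <- generateDoseResponse(tru, noiseSD = 0, nRep = 1, seed = 2)
  fit <- fitBell(gd$total)
  grid <- 10^seq(-13, -5, length.out = 4000)
  peak <- grid[which.max(predictResponse(fit, grid))]
  expect_gt(peak, fit@ec50S)
  expect_lt(peak, fit@ec50I)
})

test_that("PTX subtraction recovers the generated inhibitory component", {
  tru <- list(basal = 0, spanS = 100, ec50S = 1e-10, spanI = 80,
              ec50I = 1e-9)
  gd <- generateDoseResponse(tru, noiseSD = 2, nRep = 6, seed = 3)
  gi <- giComponent(gd$total, gd$ptx)
  cc <- gi$curve$concentration_M
  trueInhib <- tru$spanI / (1 + tru$ec50I / cc)
  trueAuc <- lipidsites:::trapz(log10(cc), trueInhib)
  expect_lt(abs(gi$auc - trueAuc) / trueAuc, 0.05)
  # identical datasets give a zero component
  z <- giComponent(gd$total, gd$total)
  expect_true(all(z$curve$gi_suppression == 0))
  # mismatched grids are rejected
  shifted <- gd$ptx
  shifted$concentration_M[1] <- shifted$concentration_M[1] * 1.5
  expect_error(giComponent(gd$total, shifted), "identical concentration")
})

test_that("the agonism index behaves like a normalised log ratio", {
  cc <- 10^seq(-13, -7, length.out = 8)
  veh <- fitLogistic3(data.frame(concentration_M = cc,
                                 response = 100 / (1 + 1e-10 / cc)))
  expect_equal(agonismIndex(veh, veh), 0)
  treat <- fitLogistic3(data.frame(concentration_M = cc,
                                   response = 200 / (1 + 5e-11 / cc)))
  expect_equal(agonismIndex(treat, veh), log10(4), tolerance = 1e-6)
  # invariant to a common response rescaling
  veh2 <- fitLogistic3(data.frame(concentration_M = cc,
                                  response = 100 * 3 / (1 + 1e-10 / cc)))
  treat2 <- fitLogistic3(data.frame(concentration_M = cc,
                                    response = 200 * 3 / (1 + 5e-11 / cc)))
  expect_equal(agonismIndex(treat2, veh2), agonismIndex(treat, veh),
               tolerance = 1e-6)
  bad <- veh; bad@ec50 <- -1
  expect_error(agonismIndex(bad, veh), "positive")
})

test_that("cholesterol-response regression reports slope, fit and CI", {
  # collinear points
  r <- suppressWarnings(cholesterolResponseRegression(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(r$slope, -1)
  expect_equal(r$r2, 1)
  expect_error(cholesterolResponseRegression(c(1, 2), c(1, 2)), "3 points")
  expect_error(cholesterolResponseRegression(c(1, 1, 1), c(1, 2, 3)),
               "variance")

  # CI covers the true slope in most seeded simulations
  cover <- vapply(1:100, function(i) {
    set.seed(i)
    x <- seq(0.5, 2, length.out = 10)
    y <- 1 - 0.8 * x + rnorm(10, 0, 0.2)
    ci <- cholesterolResponseRegression(x, y)$ci["cholesterol", ]
    ci[1] <= -0.8 && ci[2] >= -0.8
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("the glucagon-alanine index is the plain product", {
  expect_equal(glucagonAlanineIndex(9.2, 1.0), 9.2)
  expect_equal(glucagonAlanineIndex(0, 5), 0)
  expect_equal(glucagonAlanineIndex(12.0, 2.0), 24.0)
  expect_equal(glucagonAlanineIndex(c(9.2, 12), c(1, 2)), c(9.2, 24))
  expect_error(glucagonAlanineIndex(-1, 1), ">= 0")
})
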