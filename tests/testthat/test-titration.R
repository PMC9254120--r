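test_that("free cholesterol percentage counts unbound molecules over all lipids", {
  # 25 CHOL / 100 lipids, none ever bound -> 25%
  empty <- makeContactSet(list(), 10,
                          census = c(cholesterol = 25L, phospholipid = 75L))
  expect_equal(freeCholesterolPercent(empty), 25)

  # exactly 5 bound in every frame -> 20%
  bound <- lapply(1:5, function(i)
    matrix(TRUE, 1, 10, dimnames = list("F1", NULL)))
  names(bound) <- paste0("CHOL_", 1:5)
  cs <- makeContactSet(bound, 10,
                       census = c(cholesterol = 25L, phospholipid = 75L))
  expect_equal(freeCholesterolPercent(cs), 20)

  # no cholesterol at all -> 0%
  none <- makeContactSet(list(), 10, census = c(phospholipid = 100L))
  expect_equal(freeCholesterolPercent(none), 0)

  zero <- makeContactSet(list(), 10, census = integer())
  expect_error(freeCholesterolPercent(zero), "no lipids")
})

test_that("noiseless saturation data recover Kd and Occ_max exactly", {
  x <- c(2, 5, 10, 20, 40)
  pts <- data.frame(x = x, occupancy_pct = 90 * x / (6.6 + x))
  fit <- fitSaturation(pts)
  expect_equal(fit@flag, "ok")
  expect_lt(abs(fit@kd - 6.6), 1e-6)
  expect_lt(abs(fit@occMax - 90), 1e-6)
  # half-saturation identity: Occ(Kd) = Occ_max / 2
  expect_equal(fit@occMax * fit@kd / (fit@kd + fit@kd), fit@occMax / 2)
})

test_that("saturation fitting validates and flags degenerate inputs", {
  expect_error(fitSaturation(data.frame(x = c(1, 1, 2),
                                        occupancy_pct = c(1, 2, 3))),
               "distinct")
  zero <- fitSaturation(data.frame(x = c(2, 5, 10),
                                   occupancy_pct = c(0, 0, 0)))
  expect_equal(zero@flag, "no_binding")
  expect_true(is.na(zero@kd))

  # pure non-specific line: flagged non-saturable
  x <- c(2, 5, 10, 20, 40)
  lin <- fitSaturation(data.frame(x = x, occupancy_pct = 0.8 * x))
  expect_equal(lin@flag, "non_saturable")
})

test_that("rescaling occupancies rescales Occ_max but not Kd", {
  x <- c(2, 5, 10, 20, 40)
  occ <- 40 * x / (10 + x)
  f1 <- fitSaturation(data.frame(x = x, occupancy_pct = occ))
  f2 <- fitSaturation(data.frame(x = x, occupancy_pct = 2 * occ))
  expect_equal(f2@occMax / f1@occMax, 2, tolerance = 1e-6)
  expect_equal(f2@kd, f1@kd, tolerance = 1e-6)
})

test_that("weighted fits honour a 1/SE^2 weighting when SEs are present", {
  x <- c(2, 5, 10, 20, 40)
  occ <- 90 * x / (6.6 + x)
  occ[5] <- occ[5] + 20                     # corrupt one point
  se <- c(1, 1, 1, 1, 100)                  # ...which carries no weight
  fw <- fitSaturation(data.frame(x = x, occupancy_pct = pmin(occ, 100),
                                 se = se))
  expect_lt(abs(fw@kd - 6.6), 0.05)
})

test_that("generated titration points follow x / (x + Kd) occupancy", {
  # fast exchange (tau = 40/20 ns) so the time average converges quickly
  sites <- defaultSyntheticSites()
  sites$k_off <- c(25, 50)
  sites$k_on_scale <- c(25 / 8, 50 / 16)   # Kd = 8 and 16 mole %
  spec <- syntheticSpec(nLipids = 100, cholPct = 25, nFrames = 20000,
                        seed = 31, sites = sites)
  td <- generateTitrationDataset(spec, compositions = c(7, 15, 30),
                                 replicates = 4, seed = 77, mode = "points")
  pts <- td$points
  for (sid in unique(pts$site_id)) {
    kd <- td$truth$kd_pct[td$truth$site_id == sid]
    sub <- pts[pts$site_id == sid, ]
    agg <- aggregateTitration(sub)
    expected <- 100 * agg$x / (agg$x + kd)
    expect_lt(max(abs(agg$occupancy_pct - expected)), 5)
  }
  expect_error(generateTitrationDataset(spec, compositions = 10, seed = 1),
               ">= 3 compositions")
  expect_error(generateTitrationDataset(spec, compositions = c(0, 10, 20),
                                        seed = 1), "invalid composition")
})

test_that("the full trajectory titration pipeline recovers the planted Kd", {
  dir <- tempfile("titr_")
  site <- defaultSyntheticSites()[1, ]
  site$k_off <- 12.5                     # tau 80 ns: ample events per run
  site$k_on_scale <- 12.5 / 6.6          # Kd stays at 6.6 mole %
  spec <- syntheticSpec(nLipids = 50, cholPct = 25, nFrames = 2000,
                        seed = 5, sites = site)
  td <- generateTitrationDataset(spec, compositions = c(4, 8, 16, 32),
                                 replicates = 2, seed = 9,
                                 mode = "trajectory", dir = dir,
                                 nFramesPerReplicate = 2000)
  expect_true(file.exists(td$manifestPath))
  man <- readTitrationManifest(td$manifestPath)
  expect_equal(nrow(man), 8L)
  residues <- td$replicateTruths[[1]]$residues[[1]]
  pts <- titrationFromManifest(man, residues)
  expect_equal(nrow(pts), 8L)
  expect_true(all(pts$x <= 33 & pts$x >= 2))
  fit <- fitSaturation(pts)
  expect_equal(fit@flag, "ok")
  # desk-scale sampling: accept the truth inside the fit's 95% CI
  expect_true(fit@kdCI[1] <= 6.6 && fit@kdCI[2] >= 6.6)
})

test_that("manifests validate their required columns", {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(composition_label = "a", structure = "s"),
                   p, row.names = FALSE)
  expect_error(readTitrationManifest(p), "lacks columns")
  y <- tempfile(fileext = ".yaml")
  writeLines(c("- composition_label: chol10", "  structure: s.gro",
               "  trajectory: t.gro", "  replicate: 1"), y)
  m <- readTitrationManifest(y)
  expect_equal(m$replicate, 1L)
})
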