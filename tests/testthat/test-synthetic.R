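test_that("the generator is deterministic under its seed", {
  spec <- syntheticSpec(nLipids = 30, cholPct = 20, nFrames = 500, seed = 8)
  g1 <- generateMembraneTrajectory(spec)
  g2 <- generateMembraneTrajectory(spec)
  expect_identical(g1$trajectory@coords, g2$trajectory@coords)
  expect_identical(g1$truth$events, g2$truth$events)
  g3 <- generateMembraneTrajectory(syntheticSpec(nLipids = 30, cholPct = 20,
                                                 nFrames = 500, seed = 9))
  expect_false(identical(g1$trajectory@coords, g3$trajectory@coords))
})

test_that("zero on-rate plants no events and the pipeline finds no sites", {
  sites <- defaultSyntheticSites()
  sites$k_on_scale <- 0
  spec <- syntheticSpec(nLipids = 40, cholPct = 25, nFrames = 1000,
                        seed = 3, sites = sites)
  g <- generateMembraneTrajectory(spec)
  expect_equal(nrow(g$truth$events), 0L)
  ct <- detectContacts(g$trajectory, g$topology)
  sl <- detectSites(buildCoContactGraph(ct), seed = 1)
  expect_length(sl, 0L)
})

test_that("spec validity rejects impossible kinetics and requires a seed", {
  expect_error(syntheticSpec(nLipids = 10, nFrames = 10), "seed")
  sites <- defaultSyntheticSites()
  sites$k_off <- 2000   # k_off * dt > 1 at 1 ns/frame
  expect_error(syntheticSpec(seed = 1, sites = sites), "probability")
  overlap <- defaultSyntheticSites()
  overlap$residue_start <- c(387L, 390L)
  expect_error(syntheticSpec(seed = 1, sites = overlap), "disjoint")
})

test_that("bound durations are exponential with mean 1/k_off", {
  sites <- defaultSyntheticSites()
  sites$k_off <- c(25, 25)             # tau = 40 ns: many events
  sites$k_on_scale <- c(2.5, 2.5)      # Kd = 10%
  spec <- syntheticSpec(nLipids = 40, cholPct = 30, nFrames = 40000,
                        seed = 17, sites = sites)
  g <- generateMembraneTrajectory(spec)
  d <- g$truth$events$duration_ns[!g$truth$events$censored]
  expect_gt(length(d), 600)
  expect_lt(abs(mean(d) - 40) / 40, 0.1)
  ks <- suppressWarnings(stats::ks.test(d, "pexp", rate = 1 / 40))
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical occupancy converges to x / (x + Kd)", {
  spec <- syntheticSpec(nLipids = 80, cholPct = 25, nFrames = 30000,
                        seed = 23)
  g <- generateMembraneTrajectory(spec)
  x <- mean(g$truth$freeCholPct)
  for (i in seq_len(nrow(g$truth$sites))) {
    kd <- g$truth$sites$kd_pct[i]
    expect_lt(abs(g$truth$sites$occupancy_pct[i] - 100 * x / (x + kd)), 8)
  }
})

test_that("emitted files round-trip through the reader unchanged", {
  dir <- tempfile("gen_")
  spec <- syntheticSpec(nLipids = 24, cholPct = 25, nFrames = 40, seed = 4)
  g <- generateMembraneTrajectory(spec, dir = dir)
  expect_true(all(file.exists(unlist(g$paths))))
  top2 <- readStructure(g$paths$structure)
  expect_equal(lipidCensus(top2), lipidCensus(g$topology))
  tr2 <- readTrajectory(g$paths$trajectory, top2)
  expect_equal(nFrames(tr2), 40L)
  expect_lt(max(abs(tr2@coords - g$trajectory@coords)), 6e-4)
  truth <- jsonlite::read_json(g$paths$truth)
  expect_equal(truth$sites[[1]]$tau_ns, 800)
})

test_that("ground-truth bound assignments match the emitted geometry", {
  run <- smallSyntheticRun()
  g <- run$gen
  # whenever the truth says a cholesterol is bound, its hydroxyl bead sits
  # within the lower contact cutoff of a site residue
  bm <- g$truth$boundMol
  sA <- which(!is.na(bm[, 1]))[1:20]
  resIdx <- residueIndices(g$topology, g$truth$residues$siteA[1])
  for (f in sA) {
    mol <- bm[f, 1]
    head <- lipidIndices(g$topology, mol, headOnly = TRUE)
    dd <- sqrt(sum((g$trajectory@coords[head, , f] -
                    g$trajectory@coords[resIdx, , f])^2))
    expect_lt(dd, 0.475)
  }
})

test_that("dose-response generation is exact at zero noise and seeded", {
  tru <- list(basal = 2, spanS = 50, ec50S = 1e-10, spanI = 30,
              ec50I = 1e-9)
  g0 <- generateDoseResponse(tru, noiseSD = 0, nRep = 2, seed = 6)
  cc <- g0$total$concentration_M
  expect_equal(g0$total$response,
               2 + 50 / (1 + 1e-10 / cc) - 30 / (1 + 1e-9 / cc))
  expect_equal(g0$ptx$response, 2 + 50 / (1 + 1e-10 / cc))
  gA <- generateDoseResponse(tru, noiseSD = 1, nRep = 2, seed = 6)
  gB <- generateDoseResponse(tru, noiseSD = 1, nRep = 2, seed = 6)
  expect_identical(gA$total$response, gB$total$response)
  expect_error(generateDoseResponse(list(basal = 0, spanS = 1, ec50S = 1e-9,
                                         spanI = 1, ec50I = 1e-10)),
               "inhibitory EC50")
})
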