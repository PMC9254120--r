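test_that("the dual-cutoff hand trace yields the expected two events", {
  d <- c(0.50, 0.45, 0.60, 0.70, 0.80, 0.40)
  b <- lipidsites:::hysteresisBound(d, 0.475, 0.70)
  # 0.50 > lower starts nothing; 0.45 opens; 0.70 >= upper closes;
  # 0.40 reopens at the final frame
  expect_equal(b, c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE))
  ev <- lipidsites:::boundRunsToEvents(b, 6L, 1.0)
  expect_equal(ev$start_frame, c(2L, 6L))
  expect_equal(ev$duration_frames, c(2L, 1L))
  expect_equal(ev$censored, c(FALSE, TRUE))
})

test_that("hysteresis equals the brute-force state machine on random series", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(5:80, 1)
    d <- runif(n, 0.2, 1.2)
    lower <- runif(1, 0.3, 0.6)
    upper <- lower + runif(1, 0, 0.4)
    expect_identical(lipidsites:::hysteresisBound(d, lower, upper),
                     oracleDualCutoff(d, lower, upper))
  }
})

test_that("equal cutoffs degenerate to simple thresholding", {
  set.seed(3)
  d <- runif(200, 0.2, 1.2)
  expect_identical(lipidsites:::hysteresisBound(d, 0.5, 0.5), d < 0.5)
})

test_that("cutoff monotonicity holds", {
  set.seed(21)
  for (i in 1:50) {
    d <- runif(60, 0.2, 1.2)
    b1 <- lipidsites:::hysteresisBound(d, 0.45, 0.6)
    b2 <- lipidsites:::hysteresisBound(d, 0.45, 0.8)
    # raising the upper cutoff never shortens any event
    expect_true(all(b2[b1]))
    b3 <- lipidsites:::hysteresisBound(d, 0.35, 0.6)
    # lowering the lower cutoff never creates frames absent at the higher one
    expect_true(all(b1[b3]))
  }
})

test_that("detectContacts finds planted events and flags censoring", {
  run <- smallSyntheticRun()
  ct <- run$contacts
  ev <- contactEvents(ct)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$duration_frames >= 1))
  expect_true(all(ev$start_frame + ev$duration_frames - 1L <= nFrames(ct)))
  # censored events are exactly those touching the final frame
  atEnd <- ev$start_frame + ev$duration_frames - 1L == nFrames(ct)
  expect_equal(ev$censored, atEnd)
  # detected site-level bound intervals agree with the generator's record
  truth <- run$gen$truth
  sA <- truth$residues$siteA
  detA <- lipidsites:::siteEvents(ct, sA)
  truA <- truth$events[truth$events$site_id == "siteA", ]
  expect_equal(sum(detA$duration_frames), sum(truA$duration_frames))
})

test_that("extreme distance series give no events or one censored event", {
  coords <- array(0, dim = c(2, 3, 4))
  coords[1, , ] <- c(1, 1, 1)      # static protein particle
  far <- coords; far[2, 1, ] <- 5  # always > upper
  top <- lipidsites:::buildTopology(
    data.frame(index = 1:2, name = c("CA", "ROH"),
               resname = c("PHE", "CHOL"), resid = c(1L, 10L),
               chain = c("A", "")),
    box = c(10, 10, 10), defaultLipidMap(), lipidsites:::defaultHeadNames(),
    strict = TRUE)
  ctFar <- detectContacts(makeTrajectory(far), top)
  expect_equal(nrow(contactEvents(ctFar)), 0L)

  near <- coords; near[2, , ] <- c(1.1, 1, 1)  # always < lower
  ctNear <- detectContacts(makeTrajectory(near), top)
  ev <- contactEvents(ctNear)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_frames, 4L)
  expect_true(ev$censored)

  expect_error(detectContacts(makeTrajectory(near), top, "ceramide"),
               "ceramide")
  expect_error(contactParameters(lower = 0.7, upper = 0.4), "upperCutoff")
})

test_that("dissociation classification reports first stable departure", {
  always <- rep(0.4, 50)
  r <- classifyDissociation(always, 0.7)
  expect_equal(r$bound_fraction, 1.0)
  expect_true(is.na(r$dissociation_time))

  d <- c(rep(0.4, 100), rep(2.0, 50))
  r2 <- classifyDissociation(d, 0.7, dwell = 10, timestep = 1)
  expect_equal(r2$dissociation_time, 100)
  expect_equal(r2$bound_fraction, 100 / 150)

  # a brief excursion shorter than the dwell does not count
  d3 <- c(rep(0.4, 20), rep(1.0, 5), rep(0.4, 20), rep(1.0, 30))
  r3 <- classifyDissociation(d3, 0.7, dwell = 10)
  expect_equal(r3$dissociation_time, 45)

  expect_error(classifyDissociation(numeric(), 0.7), "empty")
  expect_error(classifyDissociation(d, 0.7, dwell = 0), "dwell")
})
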