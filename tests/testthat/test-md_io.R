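test_that("a minimal 3-atom PDB parses into one protein residue", {
  top <- readStructure(writeTinyPdb())
  expect_s4_class(top, "Topology")
  expect_equal(nrow(particles(top)), 3L)
  expect_equal(proteinResidues(top), "F387")
  expect_equal(boxDims(top), c(10, 10, 6))
  expect_length(lipidCensus(top), 0L)
})

test_that("lipid molecules are grouped and counted by type", {
  top <- readStructure(writeMixedPdb())
  expect_equal(lipidCensus(top),
               c(cholesterol = 5L, phospholipid = 10L))
  expect_equal(proteinResidues(top), c("F387", "S388", "Q389"))
  expect_length(lipidIds(top, "cholesterol"), 5L)
  # cholesterol head particle is the hydroxyl bead
  mol <- lipidIds(top, "cholesterol")[1]
  headName <- particles(top)$name[lipidIndices(top, mol, headOnly = TRUE)]
  expect_equal(headName, "ROH")
})

test_that("unknown residue names are rejected in strict mode, flagged otherwise", {
  path <- writeMixedPdb(badResidue = TRUE)
  expect_error(readStructure(path), "XXX")
  expect_warning(top <- readStructure(path, strict = FALSE), "XXX")
  cen <- lipidCensus(top)
  expect_equal(cen[["unmapped"]], 1L)
})

test_that("triclinic boxes are rejected with a clear message", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1  100.000  100.000   60.000  90.00  90.00 120.00 P 1           1",
    "ATOM      1  CA  PHE A   1      10.000  20.000  30.000  1.00  0.00",
    "END"), path)
  expect_error(readStructure(path), "orthorhombic")
})

test_that("structure and trajectory files round-trip within format precision", {
  run <- smallSyntheticRun()
  top <- run$gen$topology
  traj <- run$gen$trajectory
  small <- makeTrajectory(traj@coords[, , 1:3, drop = FALSE],
                          box = boxDims(traj), timestep = timeStep(traj))

  for (ext in c(".gro", ".pdb")) {
    sp <- tempfile(fileext = ext)
    tp <- tempfile(fileext = ext)
    writeStructure(top, small@coords[, , 1], sp)
    writeTrajectory(top, small, tp)
    top2 <- readStructure(sp)
    expect_equal(lipidCensus(top2), lipidCensus(top))
    expect_equal(boxDims(top2), boxDims(top), tolerance = 1e-6)
    tr2 <- readTrajectory(tp, top2, timestep = timeStep(small))
    expect_equal(nFrames(tr2), 3L)
    # GRO stores nm at 1e-3, PDB Angstroms at 1e-3 (-> 1e-4 nm)
    tol <- if (ext == ".gro") 6e-4 else 6e-5
    expect_lt(max(abs(tr2@coords - small@coords)), tol)
  }
})

test_that("trajectory reading validates particle counts and frame counts", {
  run <- smallSyntheticRun()
  top <- run$gen$topology
  tiny <- readStructure(writeTinyPdb())
  tp <- tempfile(fileext = ".gro")
  small <- makeTrajectory(run$gen$trajectory@coords[, , 1, drop = FALSE],
                          box = boxDims(run$gen$trajectory))
  writeTrajectory(top, small, tp)
  expect_equal(nFrames(readTrajectory(tp, top)), 1L)
  expect_error(readTrajectory(tp, tiny), "mismatch")
  expect_error(readTrajectory(tp, top, timestep = 0), "timestep")
})

test_that("minimum-image distances match a brute-force double loop", {
  set.seed(7)
  box <- c(4, 5, 6)
  coords <- array(runif(3 * 3 * 5, -2, 8), dim = c(3, 3, 5))
  traj <- makeTrajectory(coords, box = box)
  d <- minDistanceSeries(traj, c(1, 2), 3)
  expect_equal(d, oracleMinDist(coords, box, c(1, 2), 3))
  # symmetry
  expect_equal(d, minDistanceSeries(traj, 3, c(1, 2)))
  # bounds: non-negative and at most half the box diagonal
  expect_true(all(d >= 0))
  expect_true(all(d <= sqrt(sum((box / 2)^2))))
})

test_that("minimum image wraps across the periodic boundary", {
  coords <- array(0, dim = c(2, 3, 1))
  coords[1, , 1] <- c(0.5, 5, 5)
  coords[2, , 1] <- c(9.5, 5, 5)
  traj <- makeTrajectory(coords, box = c(10, 10, 10))
  expect_equal(minDistanceSeries(traj, 1, 2), 1.0)
  coords[2, , 1] <- coords[1, , 1]
  traj0 <- makeTrajectory(coords, box = c(10, 10, 10))
  expect_equal(minDistanceSeries(traj0, 1, 2), 0.0)
  expect_error(minDistanceSeries(traj, integer(), 2), "empty")
})
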