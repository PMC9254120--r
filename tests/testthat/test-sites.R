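test_that("co-contact edge weights count simultaneous binding", {
  m <- matrix(FALSE, 2, 100, dimnames = list(c("F1", "L2"), NULL))
  m[, 1:50] <- TRUE
  g <- buildCoContactGraph(makeContactSet(list(CHOL_1 = m), 100))
  w <- igraph::E(g@graph)$weight
  expect_equal(w, 0.5)

  # two lipids on disjoint residue pairs -> two connected components
  m2 <- matrix(TRUE, 2, 100, dimnames = list(c("V3", "I4"), NULL))
  g2 <- buildCoContactGraph(makeContactSet(list(CHOL_1 = m, CHOL_2 = m2), 100))
  expect_equal(igraph::count_components(g2@graph), 2)

  # no simultaneous contacts -> edgeless graph
  m3 <- matrix(FALSE, 2, 10, dimnames = list(c("F1", "L2"), NULL))
  m3[1, 1:5] <- TRUE; m3[2, 6:10] <- TRUE
  g3 <- buildCoContactGraph(makeContactSet(list(CHOL_1 = m3), 10))
  expect_equal(igraph::ecount(g3@graph), 0)
})

test_that("planted cliques are recovered exactly; degenerate graphs give none", {
  resA <- paste0("A", 1:6); resB <- paste0("B", 1:6)
  mkClique <- function(res, frames, nF) {
    m <- matrix(FALSE, length(res), nF, dimnames = list(res, NULL))
    m[, frames] <- TRUE
    m
  }
  cs <- makeContactSet(list(CHOL_1 = mkClique(resA, 1:40, 100),
                            CHOL_2 = mkClique(resB, 50:90, 100)), 100)
  g <- buildCoContactGraph(cs)
  sites <- detectSites(g, minResidues = 4, weightFloor = 0.05, seed = 3)
  expect_length(sites, 2L)
  best <- sapply(sites, function(s)
    max(jaccard(s, resA), jaccard(s, resB)))
  expect_equal(unname(best), c(1, 1))

  # one clique -> one site with all its nodes
  one <- buildCoContactGraph(
    makeContactSet(list(CHOL_1 = mkClique(resA, 1:40, 100)), 100))
  s1 <- detectSites(one, seed = 3)
  expect_length(s1, 1L)
  expect_setequal(s1[[1]], resA)

  # edgeless graph -> no sites
  m3 <- matrix(FALSE, 2, 10, dimnames = list(c("F1", "L2"), NULL))
  m3[1, 1:5] <- TRUE
  empty <- buildCoContactGraph(makeContactSet(list(CHOL_1 = m3), 10))
  expect_length(detectSites(empty, seed = 3), 0L)
})

test_that("site detection and ranking are deterministic under a fixed seed", {
  run <- smallSyntheticRun()
  g <- buildCoContactGraph(run$contacts)
  s1 <- detectSites(g, seed = 5)
  s2 <- detectSites(g, seed = 5)
  expect_identical(s1, s2)
  ss1 <- scoreSites(s1, run$contacts, nBoot = 20, seed = 4)
  ss2 <- scoreSites(s2, run$contacts, nBoot = 20, seed = 4)
  expect_identical(siteTable(ss1), siteTable(ss2))
})

test_that("site occupancy counts frames with any lipid on any site residue", {
  # one lipid bound to a site residue every frame -> 100%
  m <- matrix(TRUE, 1, 50, dimnames = list("F1", NULL))
  cs <- makeContactSet(list(CHOL_1 = m), 50)
  ss <- scoreSites(list("F1"), cs, nBoot = 0, seed = 1)
  expect_equal(siteTable(ss)$occupancy_pct, 100)

  # OR true on 60 of 100 frames -> 60%
  m2 <- matrix(FALSE, 2, 100, dimnames = list(c("F1", "L2"), NULL))
  m2[1, 1:40] <- TRUE; m2[2, 31:60] <- TRUE
  cs2 <- makeContactSet(list(CHOL_1 = m2), 100)
  ss2 <- scoreSites(list(c("F1", "L2")), cs2, nBoot = 0, seed = 1)
  expect_equal(siteTable(ss2)$occupancy_pct, 60)

  # a single-residue site's tau equals that residue's own tau
  expect_equal(siteTable(ss)$tau_ns, ss@perResidue$tau_ns)
})

test_that("site occupancy is at least the max per-residue occupancy", {
  run <- smallSyntheticRun()
  g <- buildCoContactGraph(run$contacts)
  sl <- detectSites(g, seed = 5)
  ss <- scoreSites(sl, run$contacts, nBoot = 0, seed = 1)
  tab <- siteTable(ss)
  for (sid in tab$site_id) {
    pr <- ss@perResidue[ss@perResidue$site_id == sid, ]
    expect_gte(tab$occupancy_pct[tab$site_id == sid] + 1e-9,
               max(pr$occupancy_pct))
  }
})

test_that("pose clustering ranks the planted major cluster first", {
  run <- smallSyntheticRun()
  ct <- run$contacts
  g <- buildCoContactGraph(ct)
  sl <- detectSites(g, seed = 5)
  ss <- scoreSites(sl, ct, nBoot = 0, seed = 1)
  topId <- siteTable(ss)$site_id[1]
  ps <- representativePose(ss, topId, ct, run$gen$trajectory,
                           run$gen$topology, rmsdCutoff = 0.2,
                           maxPoses = 200)
  expect_s4_class(ps, "BoundPoseSet")
  expect_true(all(ps@poses$rank >= 1))
  # bound poses are planted with < 0.05 nm jitter: one dominant cluster
  top <- ps@poses[ps@poses$rank == 1, ]
  expect_gt(nrow(top) / nrow(ps@poses), 0.9)
  med <- top[top$is_medoid, ]
  expect_equal(nrow(med), 1L)
  # medoid of identical poses is one of them with minimal spread
  expect_true(med$frame %in% top$frame)
  pp <- tempfile(fileext = ".pdb")
  writePoses(ps, pp, nTop = 2)
  expect_true(file.exists(pp))
  expect_error(representativePose(ss, "site-99", ct, run$gen$trajectory,
                                  run$gen$topology), "unknown site")
})

test_that("orientation classification follows the midplane rule", {
  expect_equal(as.character(classifyOrientation(0.1, 1.0, 0)), "flipped")
  expect_equal(as.character(classifyOrientation(1.9, 1.2, 0)), "canonical")
  o <- classifyOrientation(c(0.1, -1.9), c(1.0, -1.2), 0)
  expect_equal(attr(o, "leaflet"), c(1L, -1L))
})

test_that("planted flipped and canonical sites classify as such every frame", {
  run <- smallSyntheticRun()
  ct <- run$contacts
  g <- buildCoContactGraph(ct)
  sl <- detectSites(g, seed = 5)
  ss <- scoreSites(sl, ct, nBoot = 0, seed = 1)
  truth <- run$gen$truth
  flippedRes <- truth$residues$siteA   # planted flipped site
  canonRes <- truth$residues$siteB
  for (sid in siteTable(ss)$site_id) {
    ors <- siteOrientations(ss, sid, ct, run$gen$trajectory,
                            run$gen$topology)
    memb <- siteResidues(ss)[[sid]]
    if (jaccard(memb, flippedRes) > 0.8)
      expect_true(all(ors$orientation == "flipped"))
    else if (jaccard(memb, canonRes) > 0.8)
      expect_true(all(ors$orientation == "canonical"))
  }
})

test_that("midplane and head-group planes sit where the bilayer was built", {
  run <- smallSyntheticRun()
  traj <- run$gen$trajectory
  top <- run$gen$topology
  mid <- bilayerMidplane(traj, top)
  expect_lt(max(abs(mid - 5)), 0.25)
  ph <- phosphatePlanes(traj, top)
  expect_lt(max(abs(ph$upper - 6.75)), 0.35)
  expect_lt(max(abs(ph$lower - 3.25)), 0.35)
})
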