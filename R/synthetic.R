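## Ground-truthed synthetic data: bilayer trajectories with planted binding
## sites and Markovian on/off kinetics, titration datasets with known Kd,
## and hormetic dose-response datasets.
##
## Binding is a site-level continuous-time Markov chain made spatially
## consistent afterwards, not force-field physics: a free site binds a
## cholesterol with per-frame probability c * x * dt (x = instantaneous free
## cholesterol mole %), and unbinds with probability k_off * dt, so the
## equilibrium site occupancy is exactly x / (x + Kd) with Kd = k_off / c
## (mole %) and the mean bound duration is 1 / k_off.

#' Default planted binding sites
#'
#' Two six-residue sites in the upper leaflet of the synthetic bilayer: a
#' deep "flipped-pose" site with residence time 0.8 us and Kd 6.6 mole %
#' (the strong-site regime reported for cholesterol on several membrane
#' proteins), and a shallower canonical-pose site with residence time
#' 0.25 us and Kd 15 mole %.
#'
#' @param midplaneZ bilayer midplane z (nm).
#' @return sites data.frame for [syntheticSpec()]
#' @export
defaultSyntheticSites <- function(midplaneZ = 5) {
  data.frame(
    site_id = c("siteA", "siteB"),
    x = c(3.5, 8.5), y = c(6, 6),
    leaflet = c(1, 1),
    z_anchor = c(midplaneZ + 0.3, midplaneZ + 1.6),
    n_residues = c(6L, 6L),
    k_on_scale = c(1.25 / 6.6, 4.0 / 15.0),   # -> Kd 6.6 and 15.0 mole %
    k_off = c(1.25, 4.0),                     # -> tau 800 and 250 ns
    flipped = c(TRUE, FALSE),
    residue_start = c(387L, 420L),
    stringsAsFactors = FALSE)
}

#' Construct a synthetic-trajectory specification
#'
#' Defaults describe the desk-scale study system: 100 lipids at 25 mole %
#' cholesterol around a static protein with two planted sites, 20,000
#' frames at 1 ns/frame (20 us).
#'
#' @param nLipids total lipid molecules (default 100).
#' @param cholPct cholesterol mole % (default 25).
#' @param nFrames frames (default 20000).
#' @param timestep ns per frame (default 1).
#' @param seed mandatory RNG seed.
#' @param sites sites data.frame (see [defaultSyntheticSites()]).
#' @param box box lengths nm (default `c(12, 12, 10)`).
#' @param midplaneZ bilayer midplane (default `box[3]/2`).
#' @param leafletOffset midplane-to-head-plane distance (default 1.75 nm).
#' @param captureRadius site exclusion/capture disc radius (default 1 nm).
#' @param diffStep per-frame Brownian step SD (default 0.1 nm).
#' @param extraResidues decoy protein beads away from the sites (default 4).
#' @return a [SyntheticSpec-class]
#' @export
syntheticSpec <- function(nLipids = 100L, cholPct = 25, nFrames = 20000L,
                          timestep = 1.0, seed, sites = NULL,
                          box = c(12, 12, 10), midplaneZ = box[3] / 2,
                          leafletOffset = 1.75, captureRadius = 1.0,
                          diffStep = 0.1, extraResidues = 4L) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(sites)) sites <- defaultSyntheticSites(midplaneZ)
  new("SyntheticSpec", box = as.numeric(box), midplaneZ = midplaneZ,
      leafletOffset = leafletOffset, sites = sites,
      extraResidues = as.integer(extraResidues),
      nLipids = as.integer(nLipids), cholPct = cholPct,
      captureRadius = captureRadius, diffStep = diffStep,
      timestep = timestep, nFrames = as.integer(nFrames),
      seed = as.integer(seed))
}

## residue-bead layout: n beads on a 0.3 nm circle around each site anchor,
## plus decoy beads near the box corners at the midplane
syntheticProtein <- function(spec) {
  resnames <- c("PHE", "SER", "GLN", "LEU", "VAL", "ILE", "THR", "MET")
  rows <- list(); xyz <- list()
  s <- spec@sites
  for (i in seq_len(nrow(s))) {
    n <- s$n_residues[i]
    ang <- 2 * pi * (seq_len(n) - 1) / n
    xyz[[i]] <- cbind(s$x[i] + 0.3 * cos(ang), s$y[i] + 0.3 * sin(ang),
                      s$z_anchor[i])
    rows[[i]] <- data.frame(
      name = "BB", resname = resnames[((seq_len(n) - 1) %% 8) + 1],
      resid = s$residue_start[i] + seq_len(n) - 1L, chain = "A")
  }
  if (spec@extraResidues > 0L) {
    fr <- c(0.12, 0.88)
    corners <- as.matrix(expand.grid(fr * spec@box[1], fr * spec@box[2]))
    k <- spec@extraResidues
    idx <- ((seq_len(k) - 1) %% 4) + 1
    xyz[[length(xyz) + 1L]] <- cbind(corners[idx, 1], corners[idx, 2],
                                     spec@midplaneZ)
    rows[[length(rows) + 1L]] <- data.frame(
      name = "BB", resname = "GLY", resid = 900L + seq_len(k), chain = "A")
  }
  list(atoms = do.call(rbind, rows), xyz = do.call(rbind, xyz))
}

## ground-truth residue ids per site
syntheticSiteResidues <- function(spec) {
  resnames <- c("PHE", "SER", "GLN", "LEU", "VAL", "ILE", "THR", "MET")
  s <- spec@sites
  out <- lapply(seq_len(nrow(s)), function(i) {
    n <- s$n_residues[i]
    unname(residueId(resnames[((seq_len(n) - 1) %% 8) + 1],
                     s$residue_start[i] + seq_len(n) - 1L))
  })
  stats::setNames(out, s$site_id)
}

## cholesterol bead z coordinates; free lipids are always canonical
cholBeadZ <- function(spec, leaflet, boundSite = 0L) {
  mid <- spec@midplaneZ
  if (boundSite == 0L) {
    mid + leaflet * c(1.55, 0.95, 0.35)
  } else {
    za <- spec@sites$z_anchor[boundSite]
    dir <- if (spec@sites$flipped[boundSite]) spec@sites$leaflet[boundSite]
           else -spec@sites$leaflet[boundSite]
    c(za, za + dir * 0.6, za + dir * 1.2)
  }
}

#' Generate a synthetic bilayer trajectory with planted binding sites
#'
#' Unbound lipids perform 2D Brownian motion within their leaflet
#' (periodic in x/y, excluded from a disc of `captureRadius` around each
#' site axis); each site is a single-occupancy Markov chain that binds a
#' free cholesterol with per-frame probability `k_on_scale * x * dt`
#' (x = instantaneous free cholesterol mole %) and releases it with
#' probability `k_off * dt`. A bound cholesterol sits at the site anchor
#' with small jitter, inside the lower contact cutoff of all site residues;
#' at a flipped site it is written hydroxyl-toward-midplane. Deterministic
#' under the spec seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir optional output directory; when given, `structure.gro`,
#'   `trajectory.gro` and `ground_truth.json` are written there.
#' @return list with `topology` ([Topology-class]), `trajectory`
#'   ([Trajectory-class]), `truth` (ground-truth list: `sites` table with
#'   true tau/Kd, `residues`, `events`, `boundMol` frame-by-site matrix,
#'   `freeCholPct`), and, when `dir` is given, `paths`.
#' @export
generateMembraneTrajectory <- function(spec, dir = NULL) {
  validObject(spec)
  set.seed(spec@seed)
  box <- spec@box
  mid <- spec@midplaneZ
  nS <- nrow(spec@sites)
  dtus <- spec@timestep / 1000
  pOff <- spec@sites$k_off * dtus

  prot <- syntheticProtein(spec)
  nProt <- nrow(prot$atoms)
  nChol <- round(spec@nLipids * spec@cholPct / 100)
  nPopc <- spec@nLipids - nChol
  atoms <- rbind(
    prot$atoms,
    if (nChol) data.frame(name = rep(c("ROH", "R1", "C2"), nChol),
                          resname = "CHOL",
                          resid = rep(1000L + seq_len(nChol), each = 3L),
                          chain = ""),
    if (nPopc) data.frame(name = "PO4", resname = "POPC",
                          resid = 2000L + seq_len(nPopc), chain = ""))
  atoms$index <- seq_len(nrow(atoms))
  topology <- buildTopology(atoms[, c("index", "name", "resname", "resid",
                                      "chain")],
                            box, defaultLipidMap(), defaultHeadNames(),
                            strict = TRUE)

  anchors <- cbind(spec@sites$x, spec@sites$y)
  ## initial molecule xy: uniform outside the exclusion discs
  nL <- spec@nLipids
  xy <- matrix(NA_real_, nL, 2)
  filled <- 0L
  while (filled < nL) {
    cand <- cbind(stats::runif(nL, 0, box[1]), stats::runif(nL, 0, box[2]))
    ok <- rep(TRUE, nL)
    for (s in seq_len(nS)) {
      dx <- minImage(cand[, 1] - anchors[s, 1], box[1])
      dy <- minImage(cand[, 2] - anchors[s, 2], box[2])
      ok <- ok & (dx * dx + dy * dy >= spec@captureRadius^2)
    }
    take <- which(ok)[seq_len(min(sum(ok), nL - filled))]
    if (length(take)) {
      xy[(filled + 1L):(filled + length(take)), ] <- cand[take, , drop = FALSE]
      filled <- filled + length(take)
    }
  }
  ## alternate leaflets within each lipid type so both leaflets carry the
  ## same composition (keeps the mean-z midplane estimator unbiased)
  leaflet <- c(rep_len(c(1, -1), nChol), rep_len(c(1, -1), nPopc))
  homeLeaflet <- leaflet       # restored on unbinding: no net leaflet drift
  cholBound <- rep(0L, nChol)        # site index, 0 = free
  siteMol <- rep(0L, nS)             # cholesterol index, 0 = empty
  eventStart <- rep(NA_integer_, nS)

  ## particle index bookkeeping
  rohIdx <- nProt + (seq_len(nChol) - 1L) * 3L + 1L
  r1Idx <- rohIdx + 1L
  c2Idx <- rohIdx + 2L
  po4Idx <- nProt + 3L * nChol + seq_len(nPopc)

  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, spec@nFrames))
  boundMolMat <- matrix(NA_character_, spec@nFrames, nS)
  freeCount <- integer(spec@nFrames)
  events <- list()
  cholIds <- lipidIds(topology, "cholesterol")
  freeZ <- vapply(c(1, -1), function(s) cholBeadZ(spec, s), numeric(3))

  pushOut <- function(xy, movable) {
    for (s in seq_len(nS)) {
      dx <- minImage(xy[movable, 1] - anchors[s, 1], box[1])
      dy <- minImage(xy[movable, 2] - anchors[s, 2], box[2])
      r <- sqrt(dx * dx + dy * dy)
      bad <- r < spec@captureRadius
      if (any(bad)) {
        r0 <- pmax(r[bad], 1e-9)
        f <- (spec@captureRadius + 1e-3) / r0
        i <- movable[bad]
        xy[i, 1] <- (anchors[s, 1] + dx[bad] * f) %% box[1]
        xy[i, 2] <- (anchors[s, 2] + dy[bad] * f) %% box[2]
      }
    }
    xy
  }
  xy <- pushOut(xy, seq_len(nL))

  for (t in seq_len(spec@nFrames)) {
    if (t > 1L) {
      ## unbinding
      for (s in seq_len(nS)) {
        if (siteMol[s] != 0L && stats::runif(1) < pOff[s]) {
          m <- siteMol[s]
          events[[length(events) + 1L]] <- data.frame(
            site_id = spec@sites$site_id[s], lipid_id = cholIds[m],
            start_frame = eventStart[s], end_frame = t - 1L)
          ang <- stats::runif(1, 0, 2 * pi)
          rr <- spec@captureRadius + 0.3
          xy[m, ] <- c((anchors[s, 1] + rr * cos(ang)) %% box[1],
                       (anchors[s, 2] + rr * sin(ang)) %% box[2])
          leaflet[m] <- homeLeaflet[m]
          cholBound[m] <- 0L
          siteMol[s] <- 0L
          eventStart[s] <- NA_integer_
        }
      }
      ## binding
      for (s in seq_len(nS)) {
        if (siteMol[s] == 0L) {
          freeChol <- which(cholBound == 0L)
          x <- 100 * length(freeChol) / nL
          if (length(freeChol) &&
              stats::runif(1) < spec@sites$k_on_scale[s] * x * dtus) {
            dx <- minImage(xy[freeChol, 1] - anchors[s, 1], box[1])
            dy <- minImage(xy[freeChol, 2] - anchors[s, 2], box[2])
            d2 <- dx * dx + dy * dy
            near <- d2 <= spec@captureRadius^2
            pick <- if (any(near)) freeChol[near][which.min(d2[near])]
                    else freeChol[which.min(d2)]
            cholBound[pick] <- s
            siteMol[s] <- pick
            eventStart[s] <- t
            leaflet[pick] <- spec@sites$leaflet[s]
          }
        }
      }
      ## diffusion of free molecules
      boundLip <- rep(FALSE, nL)
      if (nChol) boundLip[seq_len(nChol)] <- cholBound != 0L
      free <- which(!boundLip)
      nf <- length(free)
      if (nf) {
        xy[free, ] <- xy[free, , drop = FALSE] +
          matrix(stats::rnorm(2L * nf, 0, spec@diffStep), nf, 2L)
        xy[free, 1] <- xy[free, 1] %% box[1]
        xy[free, 2] <- xy[free, 2] %% box[2]
        xy <- pushOut(xy, free)
      }
    }

    ## record state
    boundMolMat[t, ] <- ifelse(siteMol > 0L, cholIds[pmax(siteMol, 1L)],
                               NA_character_)
    freeCount[t] <- sum(cholBound == 0L)

    frame <- matrix(NA_real_, nrow(atoms), 3L)
    frame[seq_len(nProt), ] <- prot$xyz
    if (nChol) {
      cxy <- xy[seq_len(nChol), , drop = FALSE]
      b <- which(cholBound != 0L)
      if (length(b)) {
        jit <- matrix(stats::runif(2L * length(b), -0.035, 0.035),
                      length(b), 2L)
        cxy[b, ] <- anchors[cholBound[b], , drop = FALSE] + jit
      }
      zz <- t(freeZ)[(3 - leaflet[seq_len(nChol)]) / 2, , drop = FALSE]
      for (i in b) zz[i, ] <- cholBeadZ(spec, leaflet[i], cholBound[i])
      frame[rohIdx, ] <- cbind(cxy, zz[, 1])
      frame[r1Idx, ] <- cbind(cxy, zz[, 2])
      frame[c2Idx, ] <- cbind(cxy, zz[, 3])
    }
    if (nPopc) {
      pxy <- xy[nChol + seq_len(nPopc), , drop = FALSE]
      frame[po4Idx, ] <- cbind(
        pxy, mid + leaflet[nChol + seq_len(nPopc)] * spec@leafletOffset)
    }
    coords[, , t] <- frame
  }

  ## close open events as censored
  for (s in seq_len(nS)) {
    if (siteMol[s] != 0L)
      events[[length(events) + 1L]] <- data.frame(
        site_id = spec@sites$site_id[s], lipid_id = cholIds[siteMol[s]],
        start_frame = eventStart[s], end_frame = spec@nFrames)
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(site_id = character(), lipid_id = character(),
               start_frame = integer(), end_frame = integer())
  if (nrow(ev)) {
    ev$duration_frames <- ev$end_frame - ev$start_frame + 1L
    ev$duration_ns <- ev$duration_frames * spec@timestep
    ev$censored <- ev$end_frame == spec@nFrames
    ev <- ev[order(ev$site_id, ev$start_frame), ]
    rownames(ev) <- NULL
  }

  truth <- list(
    sites = data.frame(
      site_id = spec@sites$site_id,
      tau_ns = 1000 / spec@sites$k_off,
      kd_pct = spec@sites$k_off / spec@sites$k_on_scale,
      flipped = spec@sites$flipped,
      occupancy_pct = vapply(spec@sites$site_id, function(sid)
        100 * mean(!is.na(boundMolMat[, match(sid, spec@sites$site_id)])),
        numeric(1))),
    residues = syntheticSiteResidues(spec),
    events = ev,
    boundMol = boundMolMat,
    freeCholPct = 100 * freeCount / nL)

  trajectory <- new("Trajectory", coords = coords, timestep = spec@timestep,
                    box = box)
  out <- list(topology = topology, trajectory = trajectory, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(structure = file.path(dir, "structure.gro"),
                  trajectory = file.path(dir, "trajectory.gro"),
                  truth = file.path(dir, "ground_truth.json"))
    writeStructure(topology, coords[, , 1], paths$structure)
    writeTrajectory(topology, trajectory, paths$trajectory)
    writeGroundTruth(truth, paths$truth)
    out$paths <- paths
  }
  out
}

#' Write a ground-truth record as JSON
#'
#' @param truth ground-truth list from [generateMembraneTrajectory()].
#' @param path output JSON path.
#' @return `path`, invisibly
#' @export
writeGroundTruth <- function(truth, path) {
  truth$boundMol <- NULL      # frame-level matrix: bulky, derivable
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Generate a titration dataset over bilayer compositions
#'
#' One simulation per (composition, replicate). `mode = "points"` runs the
#' site-level Markov chains with occupancy bookkeeping only and returns
#' per-replicate titration points directly; `mode = "trajectory"`
#' additionally emits full coordinate trajectories plus a manifest, to be
#' consumed by [titrationFromManifest()]. In both modes the expected site
#' occupancy is `x / (x + Kd)` with `Kd = k_off / k_on_scale`.
#'
#' @param spec template [SyntheticSpec-class] (its `cholPct` is overridden
#'   per composition).
#' @param compositions cholesterol mole % values (need >= 3).
#' @param replicates replicates per composition (default 3).
#' @param seed RNG seed.
#' @param mode `"points"` or `"trajectory"`.
#' @param dir output directory (required for `"trajectory"`).
#' @param nFramesPerReplicate frames per replicate simulation (default
#'   5000, i.e. 5 us at 1 ns/frame).
#' @return for `"points"`: list with `points` (data.frame `site_id`,
#'   `composition_label`, `replicate`, `x`, `occupancy_pct`) and `truth`;
#'   for `"trajectory"`: list with `manifest`, `manifestPath`, `truth`.
#' @export
generateTitrationDataset <- function(spec, compositions, replicates = 3L,
                                     seed, mode = c("points", "trajectory"),
                                     dir = NULL,
                                     nFramesPerReplicate = 5000L) {
  mode <- match.arg(mode)
  if (length(compositions) < 3L) stop("need >= 3 compositions")
  if (any(compositions <= 0 | compositions > 100))
    stop("invalid composition(s): ",
         paste(compositions[compositions <= 0 | compositions > 100],
               collapse = ", "))
  if (missing(seed)) stop("seed is mandatory")
  s <- spec@sites
  truth <- data.frame(site_id = s$site_id,
                      tau_ns = 1000 / s$k_off,
                      kd_pct = s$k_off / s$k_on_scale)

  if (mode == "points") {
    set.seed(as.integer(seed))
    runs <- expand.grid(replicate = seq_len(replicates),
                        composition = compositions)
    nR <- nrow(runs)
    nS <- nrow(s)
    nL <- spec@nLipids
    nCholRun <- round(nL * runs$composition / 100)
    dtus <- spec@timestep / 1000
    bound <- matrix(FALSE, nR, nS)
    boundSum <- matrix(0, nR, nS)
    freeSum <- nCholRun            # frame 1: everything free
    freeNow <- nCholRun
    nF <- as.integer(nFramesPerReplicate)
    for (t in seq_len(nF - 1L)) {
      for (j in seq_len(nS)) {
        off <- bound[, j] & stats::runif(nR) < s$k_off[j] * dtus
        bound[off, j] <- FALSE
      }
      freeNow <- nCholRun - rowSums(bound)
      for (j in seq_len(nS)) {
        x <- 100 * freeNow / nL
        on <- !bound[, j] & freeNow > 0 &
          stats::runif(nR) < s$k_on_scale[j] * x * dtus
        bound[on, j] <- TRUE
        freeNow <- nCholRun - rowSums(bound)
      }
      boundSum <- boundSum + bound
      freeSum <- freeSum + freeNow
    }
    pts <- do.call(rbind, lapply(seq_len(nS), function(j) data.frame(
      site_id = s$site_id[j],
      composition_label = sprintf("chol%g", runs$composition),
      replicate = runs$replicate,
      x = 100 * (freeSum / nF) / nL,
      occupancy_pct = 100 * boundSum[, j] / nF)))
    rownames(pts) <- NULL
    return(list(points = pts, truth = truth))
  }

  ## trajectory mode
  if (is.null(dir)) stop("dir is required for mode = 'trajectory'")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list(); truths <- list()
  for (ci in seq_along(compositions)) for (r in seq_len(replicates)) {
    sp <- spec
    sp@cholPct <- compositions[ci]
    sp@nFrames <- as.integer(nFramesPerReplicate)
    sp@seed <- deriveSeed(seed, ci * 1000L + r)
    g <- generateMembraneTrajectory(sp)
    base <- sprintf("chol%g_rep%d", compositions[ci], r)
    st <- file.path(dir, paste0(base, "_structure.gro"))
    tr <- file.path(dir, paste0(base, "_trajectory.gro"))
    writeStructure(g$topology, g$trajectory@coords[, , 1], st)
    writeTrajectory(g$topology, g$trajectory, tr)
    rows[[length(rows) + 1L]] <- data.frame(
      composition_label = sprintf("chol%g", compositions[ci]),
      structure = st, trajectory = tr, replicate = r)
    truths[[length(truths) + 1L]] <- g$truth
  }
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifestPath, row.names = FALSE)
  list(manifest = manifest, manifestPath = manifestPath, truth = truth,
       replicateTruths = truths)
}

#' Generate a synthetic hormetic dose-response dataset pair
#'
#' Total responses follow the superposed stimulatory/inhibitory model; the
#' paired "PTX" dataset omits the inhibitory term, emulating pertussis-toxin
#' blockade of Gi so that only the Gs-specific response remains. Gaussian
#' noise of `noiseSD` response units is added to both.
#'
#' @param truth list with `basal`, `spanS`, `ec50S` (mol/L), `spanI`,
#'   `ec50I` (mol/L). The default separates the inhibitory potency from the
#'   stimulatory one by 10-fold.
#' @param concentrations agonist concentrations (mol/L).
#' @param noiseSD Gaussian noise SD (response units, >= 0).
#' @param nRep replicates per concentration (default 3).
#' @param seed RNG seed.
#' @return list with `total` and `ptx` data.frames (`concentration_M`,
#'   `response`, `condition`, `replicate`) and `truth`
#' @export
generateDoseResponse <- function(truth = list(basal = 0, spanS = 100,
                                              ec50S = 1e-10, spanI = 80,
                                              ec50I = 1e-9),
                                 concentrations = 10^seq(-13, -6.5,
                                                         length.out = 10),
                                 noiseSD = 0, nRep = 3L, seed = 1L) {
  if (noiseSD < 0) stop("noiseSD must be >= 0")
  if (truth$ec50I < truth$ec50S)
    stop("inhibitory EC50 must be >= stimulatory EC50")
  set.seed(as.integer(seed))
  stim <- function(c) truth$basal + truth$spanS / (1 + truth$ec50S / c)
  inhib <- function(c) truth$spanI / (1 + truth$ec50I / c)
  grid <- rep(concentrations, times = nRep)
  repl <- rep(seq_len(nRep), each = length(concentrations))
  total <- data.frame(
    concentration_M = grid,
    response = stim(grid) - inhib(grid) +
      stats::rnorm(length(grid), 0, noiseSD),
    condition = "total", replicate = repl)
  ptx <- data.frame(
    concentration_M = grid,
    response = stim(grid) + stats::rnorm(length(grid), 0, noiseSD),
    condition = "ptx", replicate = repl)
  list(total = total, ptx = ptx, truth = truth)
}
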