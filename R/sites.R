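## Binding-site identification: residue co-contact graph, community
## detection, site scoring (occupancy + residence time), representative
## bound poses and cholesterol orientation classification.

#' Build the residue co-contact graph
#'
#' Nodes are residues; the weight of edge (r1, r2) is the fraction of frames
#' in which at least one single lipid molecule is simultaneously bound to
#' both residues (frame-wise AND per lipid, summed over lipids, divided by
#' the frame count and clipped to `[0, 1]`).
#'
#' @param contacts a [ContactSet-class].
#' @return a [CoContactGraph-class]
#' @export
buildCoContactGraph <- function(contacts) {
  res <- sort(unique(unlist(lapply(contacts@bound, rownames))))
  n <- length(res)
  counts <- matrix(0, n, n, dimnames = list(res, res))
  for (m in contacts@bound) {
    idx <- match(rownames(m), res)
    counts[idx, idx] <- counts[idx, idx] + tcrossprod(m * 1)
  }
  w <- pmin(counts / contacts@nFrames, 1)
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  new("CoContactGraph", graph = g, nFrames = contacts@nFrames)
}

#' Detect binding sites as residue communities
#'
#' Prunes edges below `weightFloor`, runs seeded Louvain modularity
#' maximisation, and discards communities smaller than `minResidues`.
#'
#' @param graph a [CoContactGraph-class].
#' @param minResidues minimum residues per site (default 4).
#' @param weightFloor minimum co-contact weight for an edge to count
#'   (default 0.05).
#' @param seed RNG seed for the community detection (default 1).
#' @param resolution Louvain resolution parameter (default 1).
#' @return list of residue character vectors, one per detected site
#' @export
detectSites <- function(graph, minResidues = 4L, weightFloor = 0.05,
                        seed = 1L, resolution = 1) {
  g <- graph@graph
  if (igraph::ecount(g))
    g <- igraph::delete_edges(
      g, igraph::E(g)[igraph::E(g)$weight < weightFloor])
  if (!igraph::vcount(g)) return(list())
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  groups <- igraph::communities(comm)
  groups <- lapply(groups, as.character)
  ## a community with no internal edge is noise, whatever its nominal size
  keep <- vapply(groups, function(memb) {
    length(memb) >= minResidues &&
      igraph::ecount(igraph::induced_subgraph(g, memb)) > 0
  }, logical(1))
  unname(groups[keep])
}

## per-lipid bound series OR'ed over a residue set
siteBoundByLipid <- function(contacts, residues) {
  lapply(contacts@bound, function(m) {
    rows <- intersect(rownames(m), residues)
    if (!length(rows)) return(NULL)
    colSums(m[rows, , drop = FALSE]) > 0
  })
}

## site-level occupancy: % frames with >= 1 lipid bound to >= 1 site residue
siteOccupancy <- function(contacts, residues) {
  per <- siteBoundByLipid(contacts, residues)
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) return(0)
  100 * mean(Reduce("|", per))
}

## site-level events: maximal runs of each lipid's OR'ed bound series
siteEvents <- function(contacts, residues) {
  per <- siteBoundByLipid(contacts, residues)
  out <- list()
  for (mol in names(per)) {
    b <- per[[mol]]
    if (is.null(b) || !any(b)) next
    ev <- boundRunsToEvents(b, contacts@nFrames, contacts@timestep)
    ev$lipid_id <- mol
    out[[length(out) + 1L]] <- ev
  }
  if (!length(out))
    return(data.frame(lipid_id = character(), start_frame = integer(),
                      duration_frames = integer(), duration_ns = numeric(),
                      censored = logical()))
  e <- do.call(rbind, out)
  e <- e[order(e$start_frame, e$lipid_id),
         c("lipid_id", "start_frame", "duration_frames", "duration_ns",
           "censored")]
  rownames(e) <- NULL
  e
}

#' Score residue communities as binding sites
#'
#' For each residue community: site-level occupancy (percentage of frames in
#' which at least one lipid is bound to at least one site residue), a
#' residence-time [KineticFit-class] on the site-level event durations, and
#' per-residue residence times from each residue's own events. Sites are
#' ranked by descending residence time with occupancy as tie-break.
#'
#' @param siteList list of residue character vectors (from [detectSites()]).
#' @param contacts a [ContactSet-class].
#' @param nBoot bootstrap resamples for site-level fits (default 200).
#' @param seed RNG seed for the bootstraps.
#' @param minEvents minimum event count for an unflagged fit (default 20).
#' @param censorPolicy censoring policy for kinetic fits (see
#'   [survivalFunction()]); censored events always count towards occupancy.
#' @return a [BindingSiteSet-class]
#' @export
scoreSites <- function(siteList, contacts, nBoot = 200L, seed = 1L,
                       minEvents = 20L, censorPolicy = "drop") {
  if (!length(siteList))
    return(new("BindingSiteSet",
               sites = data.frame(site_id = character(),
                                  n_residues = integer(),
                                  occupancy_pct = numeric(),
                                  tau_ns = numeric(), ci_low_ns = numeric(),
                                  ci_high_ns = numeric(),
                                  n_events = integer(), flag = character()),
               residues = list(), perResidue = data.frame(), fits = list(),
               siteEvents = list()))
  allEv <- contactEvents(contacts)
  rows <- list(); fits <- list(); resList <- list(); evList <- list()
  prRows <- list()
  for (i in seq_along(siteList)) {
    residues <- siteList[[i]]
    ev <- siteEvents(contacts, residues)
    occ <- siteOccupancy(contacts, residues)
    fit <- kineticFitFromEvents(ev$duration_ns, ev$censored, nBoot,
                                deriveSeed(seed, i), minEvents, censorPolicy)
    rows[[i]] <- data.frame(
      n_residues = length(residues), occupancy_pct = occ,
      tau_ns = fit@tau, ci_low_ns = fit@ciLow, ci_high_ns = fit@ciHigh,
      n_events = nrow(ev), flag = fit@flag)
    fits[[i]] <- fit
    resList[[i]] <- residues
    evList[[i]] <- ev
    for (r in residues) {
      re <- allEv[allEv$residue == r, , drop = FALSE]
      rf <- kineticFitFromEvents(re$duration_ns, re$censored, 0L, NULL,
                                 minEvents, censorPolicy)
      prRows[[length(prRows) + 1L]] <- data.frame(
        site = i, residue = r, tau_ns = rf@tau, n_events = nrow(re),
        occupancy_pct = siteOccupancy(contacts, r))
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(-ifelse(is.finite(tab$tau_ns), tab$tau_ns, -Inf),
               -tab$occupancy_pct)
  ids <- paste0("site-", seq_along(ord))
  tab <- tab[ord, ]
  tab <- cbind(site_id = ids, tab)
  rownames(tab) <- NULL
  pr <- do.call(rbind, prRows)
  pr$site_id <- ids[match(pr$site, ord)]
  pr <- pr[order(match(pr$site_id, ids)),
           c("site_id", "residue", "tau_ns", "n_events", "occupancy_pct")]
  rownames(pr) <- NULL
  new("BindingSiteSet", sites = tab,
      residues = stats::setNames(resList[ord], ids),
      perResidue = pr, fits = stats::setNames(fits[ord], ids),
      siteEvents = stats::setNames(evList[ord], ids))
}

kineticFitFromEvents <- function(durations, censored, nBoot, seed,
                                 minEvents, censorPolicy) {
  d <- tryCatch(survivalFunction(durations, censored, policy = censorPolicy),
                error = function(e) NULL)
  if (is.null(d))
    return(new("KineticFit", model = "mono", k1 = NA_real_, k2 = NA_real_,
               A = 1, tau = NA_real_, r2 = NA_real_, ciLow = NA_real_,
               ciHigh = NA_real_, nEvents = 0L, nBoot = 0L, flag = "no_fit"))
  fitResidenceTime(d, nBoot = nBoot, seed = seed, minEvents = minEvents)
}

#' Export a binding-site set as CSV
#'
#' Writes the ranked site table and (optionally) the per-residue table.
#'
#' @param sites a [BindingSiteSet-class].
#' @param path site-table CSV path.
#' @param perResiduePath optional per-residue CSV path.
#' @return `path`, invisibly
#' @export
writeSiteTables <- function(sites, path, perResiduePath = NULL) {
  tab <- siteTable(sites)
  tab$residues <- vapply(sites@residues[tab$site_id],
                         paste, character(1), collapse = ";")
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(perResiduePath))
    utils::write.csv(sites@perResidue, perResiduePath, row.names = FALSE)
  invisible(path)
}

## ---- representative poses ----

## map contact-set (strided) frame index to trajectory frame index
contactFrameToTrajFrame <- function(contacts, f) {
  (f - 1L) * contacts@params@stride + 1L
}

## unwrap coordinates around a reference point under PBC
unwrapAround <- function(X, ref, box) {
  for (k in 1:3)
    X[, k] <- X[, k] - box[k] * round((X[, k] - ref[k]) / box[k])
  X
}

#' Extract and rank representative bound poses at a site
#'
#' Collects every (lipid, frame) pair in which a lipid of the contact set's
#' type is bound to the site, expresses the lipid coordinates in the
#' site-local frame (Kabsch superposition on the site residue particles,
#' with PBC unwrapping around the site), clusters the poses by RMSD over the
#' lipid particles (average-linkage agglomerative clustering cut at
#' `rmsdCutoff`), and ranks clusters by size. Each cluster's representative
#' is its medoid; ties break towards the earliest frame.
#'
#' @param sites a [BindingSiteSet-class].
#' @param siteId site identifier (e.g. `"site-1"`).
#' @param contacts the [ContactSet-class] behind the sites.
#' @param trajectory,topology the underlying data.
#' @param rmsdCutoff cluster cut height in nm (default 0.2).
#' @param maxPoses poses are subsampled evenly to at most this many
#'   (default 500) before the O(n^2) RMSD matrix is built.
#' @return a [BoundPoseSet-class]
#' @export
representativePose <- function(sites, siteId, contacts, trajectory, topology,
                               rmsdCutoff = 0.2, maxPoses = 500L) {
  residues <- sites@residues[[siteId]]
  if (is.null(residues)) stop("unknown site: ", siteId)
  per <- siteBoundByLipid(contacts, residues)
  pairs <- list()
  for (mol in names(per)) {
    b <- per[[mol]]
    if (is.null(b)) next
    f <- which(b)
    if (length(f))
      pairs[[mol]] <- data.frame(lipid_id = mol, frame = f)
  }
  if (!length(pairs)) stop("site has no occupied frames: ", siteId)
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(pairs$frame, pairs$lipid_id), ]
  if (nrow(pairs) > maxPoses) {
    keep <- unique(round(seq(1, nrow(pairs), length.out = maxPoses)))
    pairs <- pairs[keep, , drop = FALSE]
  }

  box <- boxDims(trajectory)
  siteIdx <- unlist(lapply(residues, residueIndices, x = topology))
  refFrame <- contactFrameToTrajFrame(contacts, pairs$frame[1])
  refSite <- trajectory@coords[siteIdx, , refFrame, drop = FALSE][, , 1]
  refCentroid <- colMeans(refSite)
  refSite <- unwrapAround(refSite, refCentroid, box)

  lipIdx <- lapply(unique(pairs$lipid_id), lipidIndices, x = topology)
  names(lipIdx) <- unique(pairs$lipid_id)
  npart <- length(lipIdx[[1]])
  poseCoords <- array(NA_real_, dim = c(nrow(pairs), npart, 3))
  for (p in seq_len(nrow(pairs))) {
    tf <- contactFrameToTrajFrame(contacts, pairs$frame[p])
    site <- trajectory@coords[siteIdx, , tf, drop = FALSE][, , 1]
    cen <- site[1, ]
    site <- unwrapAround(site, cen, box)
    fit <- kabsch(site, refSite)
    lip <- trajectory@coords[lipIdx[[pairs$lipid_id[p]]], , tf,
                             drop = FALSE][, , 1]
    lip <- unwrapAround(lip, cen, box)
    poseCoords[p, , ] <- applyKabsch(fit, lip)
  }

  n <- nrow(pairs)
  if (n > 1L) {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      di <- poseCoords[(i + 1L):n, , , drop = FALSE]
      ref <- poseCoords[i, , ]
      rms <- sqrt(apply(sweep(di, c(2, 3), ref), 1,
                        function(m) mean(rowSums(m^2))))
      D[i, (i + 1L):n] <- rms
      D[(i + 1L):n, i] <- rms
    }
    cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "average"),
                        h = rmsdCutoff)
  } else {
    D <- matrix(0, 1, 1)
    cl <- 1L
  }

  sizes <- table(cl)
  firstFrame <- tapply(pairs$frame, cl, min)
  ord <- order(-as.integer(sizes), as.integer(firstFrame))
  rankOf <- integer(length(sizes))
  rankOf[ord] <- seq_along(ord)
  medoid <- logical(n)
  for (c in seq_along(sizes)) {
    memb <- which(cl == as.integer(names(sizes))[c])
    tot <- if (length(memb) > 1L) rowSums(D[memb, memb, drop = FALSE])
           else 0
    best <- memb[order(tot, pairs$frame[memb])][1]
    medoid[best] <- TRUE
  }
  poses <- data.frame(
    pose = seq_len(n), frame = pairs$frame, lipid_id = pairs$lipid_id,
    cluster = as.integer(cl), rank = rankOf[match(cl, as.integer(names(sizes)))],
    is_medoid = medoid)
  pnames <- topology@particles$name[lipIdx[[1]]]
  new("BoundPoseSet", poses = poses, coords = poseCoords,
      particleNames = pnames, rmsdCutoff = rmsdCutoff)
}

#' Write top-ranked poses as a multi-model PDB
#'
#' One MODEL per cluster representative (medoid), in rank order.
#'
#' @param poseSet a [BoundPoseSet-class].
#' @param path output PDB path.
#' @param nTop number of top clusters to write (default all).
#' @return `path`, invisibly
#' @export
writePoses <- function(poseSet, path, nTop = Inf) {
  p <- poseSet@poses
  med <- p[p$is_medoid, ]
  med <- med[order(med$rank), ]
  med <- med[seq_len(min(nrow(med), nTop)), , drop = FALSE]
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(med))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    xyz <- poseSet@coords[med$pose[i], , , drop = FALSE][1, , ]
    xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(xyz)), poseSet@particleNames, "LIG", i,
      xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- orientation ----

#' Per-frame bilayer midplane estimate
#'
#' Mean z coordinate of all lipid particles, per frame — robust to bilayer
#' drift.
#'
#' @param trajectory a [Trajectory-class].
#' @param topology the matching [Topology-class].
#' @return numeric vector, one z (nm) per frame
#' @export
bilayerMidplane <- function(trajectory, topology) {
  idx <- topology@particles$index[topology@particles$role == "lipid"]
  colMeans(trajectory@coords[idx, 3, , drop = FALSE][, 1, , drop = TRUE],
           na.rm = TRUE)
}

#' Per-frame head-group (phosphate) plane estimates
#'
#' Mean z of designated head particles in each leaflet (split at the
#' midplane).
#'
#' @inheritParams bilayerMidplane
#' @return list with numeric vectors `upper` and `lower` (nm per frame)
#' @export
phosphatePlanes <- function(trajectory, topology) {
  p <- topology@particles
  idx <- p$index[p$role == "lipid" & p$head]
  z <- trajectory@coords[idx, 3, , drop = FALSE][, 1, , drop = TRUE]
  z <- matrix(z, nrow = length(idx))
  mid <- bilayerMidplane(trajectory, topology)
  up <- lo <- numeric(ncol(z))
  for (f in seq_len(ncol(z))) {
    up[f] <- mean(z[z[, f] >= mid[f], f])
    lo[f] <- mean(z[z[, f] < mid[f], f])
  }
  list(upper = up, lower = lo)
}

#' Classify a cholesterol orientation from bead heights
#'
#' A pose is `"flipped"` when its hydroxyl (head) particle lies closer to
#' the bilayer midplane than its ring centre does — i.e. the beta3-hydroxyl
#' points at the membrane core instead of the lipid/water interface —
#' and `"canonical"` otherwise. The leaflet is assigned from the sign of
#' the ring-centre height relative to the midplane.
#'
#' @param headZ,ringZ z coordinates (nm) of the hydroxyl/head particle and
#'   the ring centre (vectorised).
#' @param midplaneZ bilayer midplane z (nm), scalar or vector.
#' @return character vector (`"flipped"`/`"canonical"`) with attribute
#'   `leaflet` (+1 upper / -1 lower)
#' @export
classifyOrientation <- function(headZ, ringZ, midplaneZ) {
  flip <- abs(headZ - midplaneZ) < abs(ringZ - midplaneZ)
  out <- ifelse(flip, "flipped", "canonical")
  attr(out, "leaflet") <- ifelse(ringZ - midplaneZ >= 0, 1L, -1L)
  out
}

#' Orientation of every bound cholesterol frame at a site
#'
#' For each (lipid, frame) pair bound to the site, classifies the lipid
#' orientation from its designated head particle and the centroid of its
#' remaining (ring/tail) particles against the per-frame bilayer midplane.
#'
#' @param sites a [BindingSiteSet-class].
#' @param siteId site identifier.
#' @param contacts the [ContactSet-class] behind the sites.
#' @param trajectory,topology the underlying data.
#' @return data.frame: `frame`, `lipid_id`, `orientation`, `leaflet`
#' @export
siteOrientations <- function(sites, siteId, contacts, trajectory, topology) {
  residues <- sites@residues[[siteId]]
  if (is.null(residues)) stop("unknown site: ", siteId)
  per <- siteBoundByLipid(contacts, residues)
  mid <- bilayerMidplane(trajectory, topology)
  out <- list()
  for (mol in names(per)) {
    b <- per[[mol]]
    if (is.null(b) || !any(b)) next
    headIdx <- lipidIndices(topology, mol, headOnly = TRUE)
    allIdx <- lipidIndices(topology, mol)
    ringIdx <- setdiff(allIdx, headIdx)
    if (!length(headIdx))
      stop("lipid ", mol, " has no designated head particle")
    if (!length(ringIdx))
      stop("lipid ", mol, " has no ring particles besides the head")
    f <- which(b)
    tf <- contactFrameToTrajFrame(contacts, f)
    hz <- trajectory@coords[headIdx[1], 3, tf]
    rz <- colMeans(matrix(trajectory@coords[ringIdx, 3, tf],
                          nrow = length(ringIdx)))
    o <- classifyOrientation(hz, rz, mid[tf])
    out[[mol]] <- data.frame(frame = f, lipid_id = mol,
                             orientation = as.character(o),
                             leaflet = attr(o, "leaflet"))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$frame, res$lipid_id), ]
  rownames(res) <- NULL
  res
}
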