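# Fixtures are built in code; no binary data ships with the package.

# minimal 3-atom PDB (one phenylalanine backbone fragment) with a box
writeTinyPdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "CRYST1  100.000  100.000   60.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   PHE A 387      10.000  20.000  30.000  1.00  0.00",
    "ATOM      2  CA  PHE A 387      11.000  21.000  31.000  1.00  0.00",
    "ATOM      3  C   PHE A 387      12.000  22.000  32.000  1.00  0.00",
    "END"), path)
  path
}

# one protein chain (3 residues) + 10 POPC + 5 CHOL molecules
writeMixedPdb <- function(path = tempfile(fileext = ".pdb"),
                          badResidue = FALSE) {
  lines <- c(
    "CRYST1  120.000  120.000  100.000  90.00  90.00  90.00 P 1           1")
  ser <- 0L
  atom <- function(name, resname, chain, resid, x, y, z) {
    ser <<- ser + 1L
    sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            ser, name, resname, chain, resid, x, y, z)
  }
  for (i in 1:3)
    lines <- c(lines, atom("CA", c("PHE", "SER", "GLN")[i], "A", 386L + i,
                           10 * i, 10, 50))
  for (i in 1:10)
    lines <- c(lines, atom("PO4", "POPC", " ", 600L + i, 5 * i, 40, 67.5))
  for (i in 1:5)
    lines <- c(lines,
               atom("ROH", "CHOL", " ", 500L + i, 8 * i, 80, 66),
               atom("R1", "CHOL", " ", 500L + i, 8 * i, 80, 60))
  if (badResidue)
    lines <- c(lines, atom("X1", "XXX", " ", 999L, 1, 1, 50))
  writeLines(c(lines, "END"), path)
  path
}

# trajectory object from an [n_particles, 3, n_frames] array
makeTrajectory <- function(coords, box = c(10, 10, 10), timestep = 1) {
  new("Trajectory", coords = coords, timestep = timestep, box = box)
}

# independently written brute-force oracle for the dual-cutoff rule:
# explicit per-frame state machine, no vectorisation tricks
oracleDualCutoff <- function(d, lower, upper) {
  bound <- logical(length(d))
  state <- FALSE
  for (i in seq_along(d)) {
    if (!state && d[i] < lower) state <- TRUE
    else if (state && d[i] >= upper) state <- FALSE
    bound[i] <- state
  }
  bound
}

# brute-force per-frame minimum-image distance over all pairs
oracleMinDist <- function(coords, box, setA, setB) {
  nf <- dim(coords)[3]
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    best <- Inf
    for (i in setA) for (j in setB) {
      dd <- coords[i, , f] - coords[j, , f]
      dd <- dd - box * round(dd / box)
      best <- min(best, sqrt(sum(dd^2)))
    }
    out[f] <- best
  }
  out
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# hand-built ContactSet from per-lipid bound matrices (residues x frames)
makeContactSet <- function(boundList, nFrames, timestep = 1,
                           census = c(cholesterol = 5L, phospholipid = 10L),
                           lipidType = "cholesterol") {
  events <- list()
  for (mol in names(boundList)) {
    m <- boundList[[mol]]
    for (r in rownames(m)) {
      runs <- rle(m[r, ])
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      keep <- which(runs$values)
      if (length(keep))
        events[[length(events) + 1L]] <- data.frame(
          lipid_id = mol, residue = r, start_frame = starts[keep],
          duration_frames = runs$lengths[keep],
          duration_ns = runs$lengths[keep] * timestep,
          censored = ends[keep] == nFrames)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(lipid_id = character(), residue = character(),
               start_frame = integer(), duration_frames = integer(),
               duration_ns = numeric(), censored = logical())
  new("ContactSet", events = events, bound = boundList,
      nFrames = as.integer(nFrames), timestep = timestep,
      params = contactParameters(), lipidType = lipidType,
      census = census)
}

# small synthetic system shared by several tests (cached per session)
smallSyntheticRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- syntheticSpec(nLipids = 60, cholPct = 25, nFrames = 4000,
                            seed = 2024)
      gen <- generateMembraneTrajectory(spec)
      ct <- detectContacts(gen$trajectory, gen$topology)
      cache <<- list(spec = spec, gen = gen, contacts = ct)
    }
    cache
  }
})
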