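## Structure / trajectory I/O and periodic-boundary distance computation.
## Internal units are nm and ns everywhere; PDB/DCD Angstroms are converted
## at the boundary.

#' Read a structure file into a Topology
#'
#' Parses a PDB (via bio3d) or GRO file, groups particles into protein
#' residues and lipid molecules using a residue-name to lipid-type mapping,
#' and designates each lipid molecule's head particle (e.g. the cholesterol
#' hydroxyl bead).
#'
#' Standard amino-acid residue names become protein residues; names present
#' in `lipidMap` become lipid molecules. Any other residue name is an error
#' in strict mode, otherwise the molecule is kept with lipid type
#' `"unmapped"` and a warning.
#'
#' @param path PDB (`.pdb`) or GRO (`.gro`) file.
#' @param lipidMap named character, residue name -> lipid type; see
#'   [defaultLipidMap()].
#' @param headNames named list of head-particle name preferences per lipid
#'   type.
#' @param strict error on unmapped residue names (default `TRUE`).
#' @param box numeric(3) box lengths in nm, overriding / supplying the box
#'   when the file lacks one (PDB `CRYST1` and the GRO box line are used when
#'   present). Triclinic boxes are rejected.
#' @return a [Topology-class]
#' @export
readStructure <- function(path, lipidMap = defaultLipidMap(),
                          headNames = defaultHeadNames(),
                          strict = TRUE, box = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- fileFormat(path)
  if (fmt == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    atoms <- data.frame(
      index = seq_len(nrow(pdb$atom)),
      name = trimws(pdb$atom$elety),
      resname = trimws(pdb$atom$resid),
      resid = pdb$atom$resno,
      chain = ifelse(is.na(pdb$atom$chain), "", pdb$atom$chain),
      stringsAsFactors = FALSE
    )
    fileBox <- pdbBox(path)
  } else if (fmt == "gro") {
    g <- parseGro(path)
    atoms <- g$atoms
    fileBox <- g$box
  } else {
    stop("unsupported structure format: ", fmt, " (need .pdb or .gro)")
  }
  if (is.null(box)) box <- fileBox
  if (is.null(box))
    stop("no box in ", path, "; supply box = c(x, y, z) in nm")
  buildTopology(atoms, box, lipidMap, headNames, strict)
}

## classify atoms, group lipid molecules, designate heads
buildTopology <- function(atoms, box, lipidMap, headNames, strict) {
  resname <- atoms$resname
  isProt <- isAminoAcid(resname)
  isLip <- !isProt & resname %in% names(lipidMap)
  bad <- !isProt & !isLip
  if (any(bad)) {
    offenders <- unique(resname[bad])
    if (strict)
      stop("unknown residue name(s): ", paste(offenders, collapse = ", "),
           " - extend lipidMap or set strict = FALSE")
    warning("unmapped residue name(s) kept as lipid type 'unmapped': ",
            paste(offenders, collapse = ", "))
  }
  role <- ifelse(isProt, "protein", "lipid")
  ltype <- rep(NA_character_, nrow(atoms))
  ltype[isLip] <- lipidMap[resname[isLip]]
  ltype[bad] <- "unmapped"

  ## consecutive runs of the same (resname, resid, chain) form one molecule
  key <- paste(resname, atoms$resid, atoms$chain, sep = "|")
  grp <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  molId <- rep(NA_character_, nrow(atoms))
  lipGrp <- unique(grp[role == "lipid"])
  if (length(lipGrp)) {
    first <- match(lipGrp, grp)
    base <- paste0(resname[first], "_", atoms$resid[first])
    base <- make.unique(base, sep = ".")
    molId[role == "lipid"] <- base[match(grp[role == "lipid"], lipGrp)]
  }

  head <- rep(FALSE, nrow(atoms))
  for (g in lipGrp) {
    idx <- which(grp == g)
    ty <- ltype[idx[1]]
    pref <- headNames[[ty]]
    hit <- idx[match(pref, atoms$name[idx])]
    hit <- hit[!is.na(hit)]
    head[if (length(hit)) hit[1] else idx[1]] <- TRUE
  }

  particles <- data.frame(
    index = atoms$index, name = atoms$name, resname = resname,
    resid = atoms$resid, chain = atoms$chain, role = role,
    mol_id = molId, lipid_type = ltype, head = head,
    stringsAsFactors = FALSE
  )
  new("Topology", particles = particles, box = as.numeric(box),
      lipidMap = lipidMap)
}

fileFormat <- function(path) tolower(tools::file_ext(path))

## CRYST1 -> nm box; triclinic rejected
pdbBox <- function(path) {
  lines <- readLines(path, n = 200L, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  f <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                    substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                    substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
  if (any(abs(f[4:6] - 90) > 1e-3))
    stop("triclinic box in ", path, ": only orthorhombic boxes are supported")
  f[1:3] / 10
}

## GRO file (one or more frames); returns atoms of frame 1, box, and all
## frame coordinate matrices
parseGro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); atoms <- NULL; box <- NULL
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(paste(lines[i], collapse = "")))) {
    if (i + 1L > length(lines)) break
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("cannot parse GRO atom count at line ", i + 1L)
    body <- lines[(i + 2L):(i + 1L + nat)]
    boxLine <- strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]]
    bx <- as.numeric(boxLine)
    if (length(bx) > 3 && any(abs(bx[-(1:3)]) > 1e-9))
      stop("triclinic box in ", path, ": only orthorhombic boxes are supported")
    box <- bx[1:3]
    xyz <- cbind(as.numeric(substr(body, 21, 28)),
                 as.numeric(substr(body, 29, 36)),
                 as.numeric(substr(body, 37, 44)))
    if (is.null(atoms)) {
      atoms <- data.frame(
        index = seq_len(nat),
        name = trimws(substr(body, 11, 15)),
        resname = trimws(substr(body, 6, 10)),
        resid = as.integer(substr(body, 1, 5)),
        chain = "",
        stringsAsFactors = FALSE
      )
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 3L + nat
    if (i > length(lines)) break
  }
  if (is.null(atoms)) stop("no frames in GRO file ", path)
  list(atoms = atoms, box = box, frames = frames)
}

#' Read a trajectory into memory
#'
#' Supported formats: multi-model PDB (`.pdb`), multi-frame GRO (`.gro`) and
#' DCD (`.dcd`, via bio3d). The particle count must match the topology.
#'
#' @param path trajectory file.
#' @param topology the matching [Topology-class].
#' @param timestep ns per frame; none of the supported formats records a
#'   reliable frame time, so this is a required piece of configuration
#'   (default 1 ns).
#' @param box override box lengths (nm); defaults to the topology's box.
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(path, topology, timestep = 1.0, box = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (timestep <= 0) stop("timestep must be > 0")
  np <- nrow(topology@particles)
  fmt <- fileFormat(path)
  if (fmt == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz / 10
    if (is.null(box)) box <- pdbBox(path)
  } else if (fmt == "gro") {
    g <- parseGro(path)
    xyz <- do.call(rbind, lapply(g$frames, function(m) as.numeric(t(m))))
    if (is.null(box)) box <- g$box
  } else if (fmt == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE) / 10
  } else {
    stop("unsupported trajectory format: ", fmt, " (need .pdb, .gro or .dcd)")
  }
  if (is.null(box)) box <- boxDims(topology)
  xyz <- matrix(xyz, ncol = ncol(as.matrix(xyz)))
  nf <- nrow(xyz)
  if (nf < 1L) stop("trajectory has zero frames: ", path)
  if (ncol(xyz) != 3L * np)
    stop("particle count mismatch: trajectory has ", ncol(xyz) / 3,
         " particles, topology has ", np)
  coords <- array(NA_real_, dim = c(np, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  new("Trajectory", coords = coords, timestep = timestep,
      box = as.numeric(box))
}

#' Write a structure file
#'
#' Writes one frame as PDB (Angstroms, with `CRYST1`) or GRO (nm).
#'
#' @param topology a [Topology-class].
#' @param coords numeric matrix `[n_particles, 3]` in nm.
#' @param path output file; format chosen by extension (`.pdb` / `.gro`).
#' @return `path`, invisibly
#' @export
writeStructure <- function(topology, coords, path) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(topology@particles) || ncol(coords) != 3L)
    stop("coords must be [n_particles, 3]")
  fmt <- fileFormat(path)
  if (fmt == "pdb") {
    writeLines(c(pdbCryst(boxDims(topology)),
                 pdbAtomLines(topology, coords), "END"), path)
  } else if (fmt == "gro") {
    writeLines(groFrameLines(topology, coords, "generated by lipidsites"),
               path)
  } else stop("unsupported structure format: ", fmt)
  invisible(path)
}

#' Write a trajectory file
#'
#' Writes all frames as a multi-model PDB or a multi-frame GRO file.
#'
#' @param topology a [Topology-class].
#' @param trajectory a [Trajectory-class].
#' @param path output file (`.pdb` or `.gro`).
#' @return `path`, invisibly
#' @export
writeTrajectory <- function(topology, trajectory, path) {
  nf <- nFrames(trajectory)
  fmt <- fileFormat(path)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (fmt == "pdb") {
    writeLines(pdbCryst(boxDims(trajectory)), con)
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(pdbAtomLines(topology, trajectory@coords[, , f]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else if (fmt == "gro") {
    for (f in seq_len(nf))
      writeLines(groFrameLines(topology, trajectory@coords[, , f],
                               sprintf("frame %d, t= %.4f ns",
                                       f, (f - 1) * timeStep(trajectory)),
                               boxDims(trajectory)), con)
  } else stop("unsupported trajectory format: ", fmt)
  invisible(path)
}

pdbCryst <- function(box) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90)
}

pdbAtomLines <- function(topology, coords) {
  p <- topology@particles
  sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          p$index %% 100000L, p$name, p$resname,
          ifelse(p$chain == "", " ", substr(p$chain, 1, 1)),
          p$resid %% 10000L,
          coords[, 1] * 10, coords[, 2] * 10, coords[, 3] * 10)
}

groFrameLines <- function(topology, coords, title, box = boxDims(topology)) {
  p <- topology@particles
  c(title,
    sprintf("%5d", nrow(p)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            p$resid %% 100000L, p$resname, p$name, p$index %% 100000L,
            coords[, 1], coords[, 2], coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
}

#' Per-frame minimum distance between two particle sets
#'
#' For each frame, the minimum over all pairs of the periodic minimum-image
#' distance in the orthorhombic box. Symmetric in its two arguments.
#'
#' @param trajectory a [Trajectory-class].
#' @param setA,setB non-empty integer particle index vectors.
#' @return numeric vector, one distance (nm) per frame
#' @export
minDistanceSeries <- function(trajectory, setA, setB) {
  setA <- as.integer(setA); setB <- as.integer(setB)
  if (!length(setA) || !length(setB)) stop("empty particle selection")
  np <- dim(trajectory@coords)[1]
  if (any(c(setA, setB) < 1L) || any(c(setA, setB) > np))
    stop("particle index out of range")
  pairSetMinDist(trajectory@coords, boxDims(trajectory), setA, setB)
}
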