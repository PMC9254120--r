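## Dual-cutoff (hysteresis) lipid-residue contact detection and
## dissociation classification of distance traces.

#' Construct contact-detection parameters
#'
#' The dual-cutoff scheme opens a contact when the lipid-residue minimum
#' distance drops strictly below `lower` and keeps it open until the distance
#' first reaches or exceeds `upper`, suppressing boundary rattling.
#' Conventional defaults are 0.475/0.70 nm for coarse-grained and
#' 0.35/0.55 nm for atomistic systems.
#'
#' @param lower,upper cutoffs in nm, `0 < lower <= upper`.
#' @param stride analyse every `stride`-th frame (default 1).
#' @param resolution `"coarse"` or `"atomistic"`; sets default cutoffs when
#'   `lower`/`upper` are not given.
#' @return a [ContactParameters-class]
#' @export
contactParameters <- function(lower = NULL, upper = NULL, stride = 1L,
                              resolution = c("coarse", "atomistic")) {
  resolution <- match.arg(resolution)
  def <- if (resolution == "coarse") c(0.475, 0.70) else c(0.35, 0.55)
  if (is.null(lower)) lower <- def[1]
  if (is.null(upper)) upper <- def[2]
  new("ContactParameters", lowerCutoff = lower, upperCutoff = upper,
      stride = as.integer(stride))
}

## Hysteresis state machine, vectorised: state flips to bound where
## d < lower, to unbound where d >= upper, and is carried forward elsewhere;
## the initial state is unbound. With lower == upper this degenerates to
## simple thresholding.
hysteresisBound <- function(d, lower, upper) {
  n <- length(d)
  code <- integer(n)
  code[d >= upper] <- -1L
  code[d < lower] <- 1L          # lower < upper always wins the open rule
  idx <- seq_len(n)
  lastDecisive <- cummax(ifelse(code != 0L, idx, 0L))
  out <- rep(FALSE, n)
  has <- lastDecisive > 0L
  out[has] <- code[lastDecisive[has]] == 1L
  out
}

## maximal runs of a bound series -> event data.frame
boundRunsToEvents <- function(bound, nf, tstep) {
  runs <- trueRuns(bound)
  if (!nrow(runs)) return(NULL)
  data.frame(
    start_frame = runs$start,
    duration_frames = runs$length,
    duration_ns = runs$length * tstep,
    censored = runs$start + runs$length - 1L == nf
  )
}

#' Detect lipid-residue contacts with the dual-cutoff scheme
#'
#' For every (lipid molecule of `lipidType`, protein residue) pair, computes
#' the per-frame minimum-image minimum distance and applies the hysteresis
#' rule: a contact opens when the distance drops strictly below the lower
#' cutoff and persists until it reaches or exceeds the upper cutoff. Maximal
#' runs of the bound state become contact events; an event still open at the
#' final frame is closed there and flagged censored.
#'
#' @param trajectory a [Trajectory-class].
#' @param topology the matching [Topology-class].
#' @param lipidType lipid type to analyse (default `"cholesterol"`).
#' @param params a [ContactParameters-class].
#' @return a [ContactSet-class]
#' @export
detectContacts <- function(trajectory, topology,
                           lipidType = "cholesterol",
                           params = contactParameters()) {
  validObject(params)
  census <- lipidCensus(topology)
  if (!lipidType %in% names(census))
    stop("lipid type not present in topology: ", lipidType)
  residues <- proteinResidues(topology)
  if (!length(residues)) stop("topology has no protein residues")

  stride <- params@stride
  frames <- seq(1L, nFrames(trajectory), by = stride)
  coords <- trajectory@coords[, , frames, drop = FALSE]
  nf <- length(frames)
  tstep <- timeStep(trajectory) * stride
  box <- boxDims(trajectory)

  resIdx <- lapply(residues, function(r) residueIndices(topology, r))
  mols <- lipidIds(topology, lipidType)

  boundList <- list()
  eventList <- list()
  for (mol in mols) {
    lidx <- lipidIndices(topology, mol)
    mat <- NULL
    evs <- list()
    for (ri in seq_along(residues)) {
      d <- pairSetMinDist(coords, box, lidx, resIdx[[ri]])
      b <- hysteresisBound(d, params@lowerCutoff, params@upperCutoff)
      if (any(b)) {
        if (is.null(mat))
          mat <- matrix(FALSE, nrow = 0, ncol = nf)
        mat <- rbind(mat, b)
        rownames(mat)[nrow(mat)] <- residues[ri]
        ev <- boundRunsToEvents(b, nf, tstep)
        ev$residue <- residues[ri]
        evs[[length(evs) + 1L]] <- ev
      }
    }
    if (!is.null(mat)) {
      boundList[[mol]] <- mat
      ev <- do.call(rbind, evs)
      ev$lipid_id <- mol
      eventList[[length(eventList) + 1L]] <- ev
    }
  }

  events <- if (length(eventList)) {
    e <- do.call(rbind, eventList)
    e <- e[, c("lipid_id", "residue", "start_frame", "duration_frames",
               "duration_ns", "censored")]
    e <- e[order(e$lipid_id, e$residue, e$start_frame), ]
    rownames(e) <- NULL
    e
  } else {
    data.frame(lipid_id = character(), residue = character(),
               start_frame = integer(), duration_frames = integer(),
               duration_ns = numeric(), censored = logical())
  }
  new("ContactSet", events = events, bound = boundList,
      nFrames = as.integer(nf), timestep = tstep, params = params,
      lipidType = lipidType, census = census)
}

#' Export contact events as CSV
#'
#' @param contacts a [ContactSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly
#' @export
writeContactEvents <- function(contacts, path) {
  utils::write.csv(contactEvents(contacts), path, row.names = FALSE)
  invisible(path)
}

#' Classify a distance trace as stably bound or dissociating
#'
#' The dissociation time is the time of the first frame from which the
#' distance stays at or above `threshold` for at least `dwell` consecutive
#' frames (`NA` if the lipid never leaves); the bound fraction is the
#' fraction of frames below `threshold`. Used to distinguish stably bound
#' poses from rapidly dissociating ones in minimum-distance traces.
#'
#' @param distances per-frame distances (nm).
#' @param threshold nm.
#' @param dwell minimum consecutive frames at or above threshold (>= 1).
#' @param timestep ns per frame.
#' @return list with `bound_fraction` (in `[0, 1]`) and `dissociation_time`
#'   (ns, `NA` when the trace never dissociates)
#' @export
classifyDissociation <- function(distances, threshold, dwell = 1L,
                                 timestep = 1.0) {
  if (!length(distances)) stop("empty distance series")
  if (dwell < 1L) stop("dwell must be >= 1")
  above <- distances >= threshold
  runs <- trueRuns(above)
  runs <- runs[runs$length >= dwell, , drop = FALSE]
  tdiss <- if (nrow(runs)) (runs$start[1] - 1L) * timestep else NA_real_
  list(bound_fraction = mean(!above), dissociation_time = tdiss)
}
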