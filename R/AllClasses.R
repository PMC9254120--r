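#' @import methods
NULL

#' Topology of a membrane-protein / bilayer system
#'
#' Particle-level description of a simulation system: protein particles
#' grouped into residues and lipid particles grouped into molecules, plus the
#' orthorhombic box. All lengths are nm.
#'
#' @slot particles data.frame with one row per particle: `index` (1-based),
#'   `name`, `resname`, `resid`, `chain`, `role` ("protein" or "lipid"),
#'   `mol_id` (lipid molecule id, `NA` for protein), `lipid_type`
#'   (mapped type, `NA` for protein), `head` (logical, designated head
#'   particle of its lipid molecule).
#' @slot box numeric(3), orthorhombic box lengths (nm).
#' @slot lipidMap named character, residue-name to lipid-type mapping used
#'   when the object was built.
#'
#' @seealso [readStructure()], [proteinResidues()], [lipidCensus()]
#' @export
setClass("Topology", representation(
  particles = "data.frame",
  box = "numeric",
  lipidMap = "character"
))

setValidity("Topology", function(object) {
  p <- object@particles
  need <- c("index", "name", "resname", "resid", "chain", "role",
            "mol_id", "lipid_type", "head")
  if (!all(need %in% names(p)))
    return(paste("particles lacks columns:",
                 paste(setdiff(need, names(p)), collapse = ", ")))
  if (length(object@box) != 3L || any(!is.finite(object@box)) ||
      any(object@box <= 0))
    return("box must be three positive lengths (nm)")
  if (!all(p$role %in% c("protein", "lipid")))
    return("particle role must be 'protein' or 'lipid'")
  if (anyNA(p$mol_id[p$role == "lipid"]))
    return("every lipid particle must belong to a lipid molecule")
  if (!anyNA(p$mol_id[p$role == "protein"]) && any(p$role == "protein"))
    return("protein particles must not carry a lipid molecule id")
  TRUE
})

#' Trajectory of particle coordinates
#'
#' Coordinates (nm) for every particle of a [Topology-class] over frames, with
#' a constant orthorhombic box and a frame spacing in ns.
#'
#' @slot coords numeric array `[n_particles, 3, n_frames]`, nm.
#' @slot timestep numeric(1), ns between stored frames.
#' @slot box numeric(3), box lengths (nm).
#'
#' @seealso [readTrajectory()], [minDistanceSeries()]
#' @export
setClass("Trajectory", representation(
  coords = "array",
  timestep = "numeric",
  box = "numeric"
))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an [n_particles, 3, n_frames] array")
  if (d[3] < 1L) return("trajectory must contain at least one frame")
  if (length(object@timestep) != 1L || object@timestep <= 0)
    return("timestep must be a single positive number (ns)")
  if (length(object@box) != 3L || any(object@box <= 0))
    return("box must be three positive lengths (nm)")
  TRUE
})

#' Dual-cutoff contact detection parameters
#'
#' @slot lowerCutoff numeric(1), nm; a contact opens when the lipid-residue
#'   minimum distance drops strictly below this value.
#' @slot upperCutoff numeric(1), nm; an open contact closes at the first frame
#'   whose distance is greater than or equal to this value.
#' @slot stride integer(1), analyse every `stride`-th frame.
#' @export
setClass("ContactParameters", representation(
  lowerCutoff = "numeric",
  upperCutoff = "numeric",
  stride = "integer"
))

setValidity("ContactParameters", function(object) {
  if (object@lowerCutoff <= 0) return("lowerCutoff must be > 0")
  if (object@upperCutoff < object@lowerCutoff)
    return("upperCutoff must be >= lowerCutoff")
  if (object@stride < 1L) return("stride must be >= 1")
  TRUE
})

#' Set of lipid-residue contact records
#'
#' Result of [detectContacts()]: per (lipid molecule, residue) bound-state
#' series and the contact events they imply.
#'
#' @slot events data.frame: `lipid_id`, `residue`, `start_frame` (1-based,
#'   strided frame units), `duration_frames`, `duration_ns`, `censored`
#'   (event still open at the final frame).
#' @slot bound named list (by lipid molecule id) of logical matrices
#'   `[residues x frames]`; only lipids with at least one event appear, and
#'   only residues that were ever bound are kept as rows.
#' @slot nFrames integer(1), number of analysed (strided) frames.
#' @slot timestep numeric(1), ns per analysed frame (trajectory timestep
#'   times stride).
#' @slot params the [ContactParameters-class] used.
#' @slot lipidType character(1), lipid type analysed.
#' @slot census named integer, lipid-type census of the topology (all types).
#' @export
setClass("ContactSet", representation(
  events = "data.frame",
  bound = "list",
  nFrames = "integer",
  timestep = "numeric",
  params = "ContactParameters",
  lipidType = "character",
  census = "integer"
))

setValidity("ContactSet", function(object) {
  e <- object@events
  need <- c("lipid_id", "residue", "start_frame", "duration_frames",
            "duration_ns", "censored")
  if (!all(need %in% names(e)))
    return(paste("events lacks columns:",
                 paste(setdiff(need, names(e)), collapse = ", ")))
  if (nrow(e) && any(e$duration_frames < 1L))
    return("event durations must be >= 1 frame")
  if (nrow(e) && any(e$start_frame + e$duration_frames - 1L > object@nFrames))
    return("events must lie within the trajectory")
  TRUE
})

#' Empirical survival curve of contact-event durations
#'
#' \eqn{S(t)} is the fraction of events with duration \eqn{\ge t}:
#' `S(0) = 1`, non-increasing.
#'
#' @slot durations numeric, event durations (ns) entering the curve.
#' @slot censored logical, censoring flag per duration (as supplied; whether
#'   censored events enter the curve depends on the policy used to build it).
#' @slot times numeric, evaluation grid (ns), starts at 0.
#' @slot surv numeric, `S(times)`.
#' @slot nEvents integer(1), number of events in the curve.
#' @export
setClass("SurvivalCurve", representation(
  durations = "numeric",
  censored = "logical",
  times = "numeric",
  surv = "numeric",
  nEvents = "integer"
))

setValidity("SurvivalCurve", function(object) {
  if (object@nEvents < 1L) return("survival curve needs >= 1 event")
  if (length(object@times) != length(object@surv))
    return("times and surv must have equal length")
  if (abs(object@surv[1] - 1) > 1e-12 || object@times[1] != 0)
    return("S(0) must equal 1")
  if (any(diff(object@surv) > 1e-12)) return("S must be non-increasing")
  TRUE
})

#' Exponential residence-time fit of a survival curve
#'
#' Mono- or biexponential fit \eqn{S(t) = A e^{-k_1 t} + (1-A) e^{-k_2 t}}
#' with \eqn{k_1 \ge k_2}; the residence time is \eqn{\tau = 1/k_2}.
#'
#' @slot model character(1), "mono" or "bi".
#' @slot k1,k2 numeric(1), rates in 1/ns, `k1 >= k2`.
#' @slot A numeric(1), fast-component amplitude (1 for mono).
#' @slot tau numeric(1), residence time in ns (`1/k2`).
#' @slot r2 numeric(1), coefficient of determination in log-survival space.
#' @slot ciLow,ciHigh numeric(1), bootstrap percentile CI (2.5/97.5%) for tau.
#' @slot nEvents integer(1), events behind the fit.
#' @slot nBoot integer(1), bootstrap resamples used (0 = no CI).
#' @slot flag character(1), "ok", "low_n" (below the minimum event count) or
#'   "no_fit".
#' @export
setClass("KineticFit", representation(
  model = "character", k1 = "numeric", k2 = "numeric", A = "numeric",
  tau = "numeric", r2 = "numeric", ciLow = "numeric", ciHigh = "numeric",
  nEvents = "integer", nBoot = "integer", flag = "character"
))

setValidity("KineticFit", function(object) {
  if (!object@model %in% c("mono", "bi")) return("model must be mono or bi")
  if (object@flag == "ok") {
    if (!is.finite(object@tau) || object@tau <= 0) return("tau must be > 0")
    if (object@k1 < object@k2 - 1e-12) return("k1 must be >= k2")
    if (object@model == "mono" &&
        (abs(object@A - 1) > 1e-12 || abs(object@k1 - object@k2) > 1e-12))
      return("mono model requires A = 1 and k1 = k2")
    if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
        (object@ciLow > object@tau + 1e-9 || object@ciHigh < object@tau - 1e-9))
      return("CI must bracket the point estimate")
  }
  TRUE
})

#' Residue co-contact graph
#'
#' Undirected weighted graph whose nodes are residues; the weight of edge
#' (r1, r2) is the fraction of frames in which at least one single lipid
#' molecule is simultaneously bound to both residues (clipped to `[0, 1]`).
#'
#' @slot graph an [igraph::igraph] object with edge attribute `weight`.
#' @slot nFrames integer(1), frames behind the weights.
#' @export
setClass("CoContactGraph", representation(
  graph = "ANY",
  nFrames = "integer"
))

setValidity("CoContactGraph", function(object) {
  if (!igraph::is_igraph(object@graph)) return("graph must be an igraph")
  w <- igraph::E(object@graph)$weight
  if (length(w) && (any(w < -1e-12) || any(w > 1 + 1e-12)))
    return("edge weights must lie in [0, 1]")
  TRUE
})

#' Ranked set of lipid binding sites
#'
#' Result of site detection and scoring: one row per site, ranked by
#' descending residence time (occupancy breaks ties).
#'
#' @slot sites data.frame: `site_id`, `n_residues`, `occupancy_pct`,
#'   `tau_ns`, `ci_low_ns`, `ci_high_ns`, `n_events`, `flag`.
#' @slot residues named list (by site id) of residue character vectors.
#' @slot perResidue data.frame: `site_id`, `residue`, `tau_ns`, `n_events`,
#'   `occupancy_pct`.
#' @slot fits named list (by site id) of [KineticFit-class] objects.
#' @slot siteEvents named list (by site id) of data.frames of site-level
#'   events (`lipid_id`, `start_frame`, `duration_frames`, `duration_ns`,
#'   `censored`).
#' @export
setClass("BindingSiteSet", representation(
  sites = "data.frame",
  residues = "list",
  perResidue = "data.frame",
  fits = "list",
  siteEvents = "list"
))

setValidity("BindingSiteSet", function(object) {
  s <- object@sites
  if (nrow(s)) {
    if (any(s$occupancy_pct < -1e-9 | s$occupancy_pct > 100 + 1e-9))
      return("site occupancy must lie in [0, 100]")
    if (!all(s$site_id %in% names(object@residues)))
      return("every site needs a residue set")
  }
  TRUE
})

#' Clustered bound poses at a binding site
#'
#' Bound-lipid poses expressed in the site-local frame (after superposition
#' on the site residues), clustered by RMSD; clusters ranked by size.
#'
#' @slot poses data.frame: `pose` (index into `coords`), `frame`, `lipid_id`,
#'   `cluster`, `rank` (cluster rank, 1 = largest), `is_medoid`.
#' @slot coords numeric array `[n_poses, n_lipid_particles, 3]`, nm,
#'   site-local frame.
#' @slot particleNames character, names of the lipid particles.
#' @slot rmsdCutoff numeric(1), nm.
#' @export
setClass("BoundPoseSet", representation(
  poses = "data.frame",
  coords = "array",
  particleNames = "character",
  rmsdCutoff = "numeric"
))

#' Saturation-binding fit of site occupancy vs free cholesterol
#'
#' Fit of \eqn{Occ(x) = Occ_{max} x / (K_d^{app} + x)} (optionally plus a
#' non-specific linear term \eqn{m x}) to titration points.
#'
#' @slot kd numeric(1), apparent dissociation constant (mole % free
#'   cholesterol).
#' @slot kdSE numeric(1), standard error of `kd`.
#' @slot occMax,occMaxSE numeric(1), saturating occupancy (%) and its SE.
#' @slot slope numeric(1), non-specific slope (%/%, `NA` if not fitted).
#' @slot r2 numeric(1), coefficient of determination.
#' @slot kdCI numeric(2), t-based 95% CI for `kd`.
#' @slot n integer(1), number of points fitted.
#' @slot flag character(1), "ok", "non_saturable" (a pure line describes the
#'   data at least as well) or "no_binding" (all occupancies zero).
#' @export
setClass("SaturationFit", representation(
  kd = "numeric", kdSE = "numeric", occMax = "numeric", occMaxSE = "numeric",
  slope = "numeric", r2 = "numeric", kdCI = "numeric", n = "integer",
  flag = "character"
))

setValidity("SaturationFit", function(object) {
  if (object@flag == "ok") {
    if (!is.finite(object@kd) || object@kd <= 0) return("Kd must be > 0")
    if (!is.finite(object@occMax) || object@occMax <= 0 ||
        object@occMax > 100 + 1e-6)
      return("Occ_max must lie in (0, 100]")
  }
  TRUE
})

#' Dose-response curve fit
#'
#' Three-parameter logistic (`model = "logistic3"`, Hill slope fixed at 1):
#' \eqn{R(c) = basal + (E_{max} - basal) / (1 + EC_{50}/c)}; or superposed
#' stimulatory/inhibitory ("bell") model:
#' \eqn{R(c) = basal + span_s/(1 + EC_{50,s}/c) - span_i/(1 + EC_{50,i}/c)}
#' with \eqn{EC_{50,i} = EC_{50,s} 10^{\delta}}, \eqn{\delta \ge 0}.
#'
#' @slot model character(1), "logistic3" or "bell".
#' @slot basal numeric(1).
#' @slot emax numeric(1); for "bell" this is `basal + span_s`, the plateau of
#'   the stimulatory component.
#' @slot ec50 numeric(1), mol/L; for "bell" the stimulatory `EC50_s`.
#' @slot spanS,ec50S,spanI,ec50I numeric(1), bell components (`NA` for
#'   logistic3).
#' @slot r2 numeric(1).
#' @slot flag character(1), "ok" or "collapsed_to_logistic3" (bell fit whose
#'   inhibitory span vanished).
#' @export
setClass("DoseResponseFit", representation(
  model = "character", basal = "numeric", emax = "numeric", ec50 = "numeric",
  spanS = "numeric", ec50S = "numeric", spanI = "numeric", ec50I = "numeric",
  r2 = "numeric", flag = "character"
))

setValidity("DoseResponseFit", function(object) {
  if (!object@model %in% c("logistic3", "bell"))
    return("model must be logistic3 or bell")
  if (!is.finite(object@ec50) || object@ec50 <= 0) return("EC50 must be > 0")
  if (object@model == "bell" && is.finite(object@ec50I) &&
      object@ec50I < object@ec50S - 1e-15)
    return("EC50_i must be >= EC50_s")
  TRUE
})

#' Specification of a synthetic bilayer trajectory
#'
#' Defines the geometry, composition and site-level Markov kinetics of the
#' synthetic membrane generator. The implied equilibrium dissociation
#' constant of each site is `k_off / c` in mole % free cholesterol.
#'
#' @slot box numeric(3), nm.
#' @slot midplaneZ numeric(1), bilayer midplane z (nm).
#' @slot leafletOffset numeric(1), distance from midplane to the head-group
#'   plane of each leaflet (nm).
#' @slot sites data.frame: `site_id`, `x`, `y` (anchor, nm), `leaflet`
#'   (+1/-1), `z_anchor` (residue-bead z, nm), `n_residues`, `k_on_scale`
#'   (c, 1/(us * mole%)), `k_off` (1/us), `flipped` (logical),
#'   `residue_start` (first residue number for labelling).
#' @slot extraResidues integer(1), decoy protein beads placed away from the
#'   sites.
#' @slot nLipids integer(1), total lipid molecules.
#' @slot cholPct numeric(1), cholesterol mole %.
#' @slot captureRadius numeric(1), nm; free lipids are excluded from discs of
#'   this radius around each site axis, and a binding event preferentially
#'   recruits a free cholesterol inside it (else the nearest one).
#' @slot diffStep numeric(1), per-frame Brownian step SD (nm).
#' @slot timestep numeric(1), ns per frame.
#' @slot nFrames integer(1).
#' @slot seed integer(1), mandatory RNG seed.
#' @export
setClass("SyntheticSpec", representation(
  box = "numeric", midplaneZ = "numeric", leafletOffset = "numeric",
  sites = "data.frame", extraResidues = "integer", nLipids = "integer",
  cholPct = "numeric", captureRadius = "numeric", diffStep = "numeric",
  timestep = "numeric", nFrames = "integer", seed = "integer"
))

setValidity("SyntheticSpec", function(object) {
  s <- object@sites
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  if (object@nLipids < 1L) return("need >= 1 lipid")
  if (object@cholPct < 0 || object@cholPct > 100)
    return("cholPct must lie in [0, 100]")
  if (nrow(s)) {
    if (any(s$k_off <= 0)) return("k_off must be > 0")
    if (any(s$k_on_scale < 0)) return("k_on_scale must be >= 0")
    if (any(s$k_off * object@timestep / 1000 > 1))
      return("k_off * timestep exceeds 1: unbinding probability > 1")
    starts <- s$residue_start
    ends <- s$residue_start + s$n_residues - 1L
    for (i in seq_len(nrow(s) - 1L))
      for (j in seq(i + 1L, nrow(s)))
        if (starts[i] <= ends[j] && starts[j] <= ends[i])
          return("site residue ranges must be disjoint")
  }
  if (object@timestep <= 0) return("timestep must be > 0")
  if (object@nFrames < 1L) return("need >= 1 frame")
  TRUE
})
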