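#' @include AllClasses.R
NULL

#' Number of frames
#' @param x a [Trajectory-class] or [ContactSet-class]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame spacing in ns
#' @param x a [Trajectory-class] or [ContactSet-class]
#' @return numeric, ns per frame
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))

#' Box lengths in nm
#' @param x a [Topology-class] or [Trajectory-class]
#' @return numeric(3)
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' Residence time in ns
#' @param x a [KineticFit-class]
#' @return numeric(1), ns
#' @export
setGeneric("residenceTime", function(x) standardGeneric("residenceTime"))

#' Maximal response of a dose-response fit
#' @param x a [DoseResponseFit-class]
#' @return numeric(1)
#' @export
setGeneric("Emax", function(x) standardGeneric("Emax"))

#' Half-maximal concentration of a dose-response fit (mol/L)
#' @param x a [DoseResponseFit-class]
#' @return numeric(1), mol/L
#' @export
setGeneric("EC50", function(x) standardGeneric("EC50"))

#' Apparent dissociation constant (mole % free cholesterol)
#' @param x a [SaturationFit-class]
#' @return numeric(1), mole %
#' @export
setGeneric("kdApp", function(x) standardGeneric("kdApp"))

## ---- Topology accessors ----

#' Particle table of a topology
#' @param x a [Topology-class]
#' @return the particle data.frame
#' @export
particles <- function(x) {
  stopifnot(is(x, "Topology"))
  x@particles
}

#' Ordered protein residue identifiers
#'
#' Residue ids are `"<one-letter-code><resid>"` (e.g. `"F387"`) when the
#' residue name is a standard amino acid, otherwise `"<resname><resid>"`.
#'
#' @param x a [Topology-class]
#' @return character vector in residue order
#' @export
proteinResidues <- function(x) {
  stopifnot(is(x, "Topology"))
  p <- x@particles[x@particles$role == "protein", , drop = FALSE]
  if (!nrow(p)) return(character())
  ids <- residueId(p$resname, p$resid)
  ids[!duplicated(ids)]
}

#' Particle indices of a protein residue
#' @param x a [Topology-class]
#' @param residue residue id as returned by [proteinResidues()]
#' @return integer particle indices
#' @export
residueIndices <- function(x, residue) {
  stopifnot(is(x, "Topology"))
  p <- x@particles
  sel <- p$role == "protein" & residueId(p$resname, p$resid) == residue
  if (!any(sel)) stop("unknown protein residue: ", residue)
  p$index[sel]
}

#' Lipid-type census
#' @param x a [Topology-class]
#' @return named integer, molecules per lipid type
#' @export
lipidCensus <- function(x) {
  stopifnot(is(x, "Topology"))
  p <- x@particles[x@particles$role == "lipid", , drop = FALSE]
  if (!nrow(p)) return(integer())
  m <- p[!duplicated(p$mol_id), ]
  tab <- table(m$lipid_type)
  stats::setNames(as.integer(tab), names(tab))
}

#' Lipid molecule ids of a given type
#' @param x a [Topology-class]
#' @param type lipid type (e.g. `"cholesterol"`); `NULL` for all
#' @return character molecule ids
#' @export
lipidIds <- function(x, type = NULL) {
  stopifnot(is(x, "Topology"))
  p <- x@particles[x@particles$role == "lipid", , drop = FALSE]
  if (!is.null(type)) p <- p[p$lipid_type == type, , drop = FALSE]
  unique(p$mol_id)
}

#' Particle indices of a lipid molecule
#' @param x a [Topology-class]
#' @param mol lipid molecule id
#' @param headOnly return only the designated head particle
#' @return integer particle indices
#' @export
lipidIndices <- function(x, mol, headOnly = FALSE) {
  stopifnot(is(x, "Topology"))
  p <- x@particles
  sel <- !is.na(p$mol_id) & p$mol_id == mol
  if (!any(sel)) stop("unknown lipid molecule: ", mol)
  if (headOnly) sel <- sel & p$head
  p$index[sel]
}

## ---- simple S4 accessors ----

#' @describeIn nFrames frames of a trajectory
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @describeIn nFrames analysed frames of a contact set
#' @export
setMethod("nFrames", "ContactSet", function(x) x@nFrames)

#' @describeIn timeStep ns per trajectory frame
#' @export
setMethod("timeStep", "Trajectory", function(x) x@timestep)

#' @describeIn timeStep ns per analysed frame
#' @export
setMethod("timeStep", "ContactSet", function(x) x@timestep)

#' @describeIn boxDims box of a topology
#' @export
setMethod("boxDims", "Topology", function(x) x@box)

#' @describeIn boxDims box of a trajectory
#' @export
setMethod("boxDims", "Trajectory", function(x) x@box)

#' @describeIn residenceTime tau (ns) of a kinetic fit
#' @export
setMethod("residenceTime", "KineticFit", function(x) x@tau)

#' @describeIn Emax logistic3 plateau, or stimulatory plateau of a bell fit
#' @export
setMethod("Emax", "DoseResponseFit", function(x) x@emax)

#' @describeIn EC50 logistic3 EC50, or stimulatory EC50 of a bell fit
#' @export
setMethod("EC50", "DoseResponseFit", function(x) x@ec50)

#' @describeIn kdApp fitted apparent Kd
#' @export
setMethod("kdApp", "SaturationFit", function(x) x@kd)

#' Contact events of a contact set
#' @param x a [ContactSet-class]
#' @return data.frame of events (lipid_id, residue, start_frame,
#'   duration_frames, duration_ns, censored)
#' @export
contactEvents <- function(x) {
  stopifnot(is(x, "ContactSet"))
  x@events
}

#' Site table of a binding-site set
#' @param x a [BindingSiteSet-class]
#' @return data.frame of ranked sites
#' @export
siteTable <- function(x) {
  stopifnot(is(x, "BindingSiteSet"))
  x@sites
}

#' Residue membership of detected sites
#' @param x a [BindingSiteSet-class]
#' @return named list of residue character vectors
#' @export
siteResidues <- function(x) {
  stopifnot(is(x, "BindingSiteSet"))
  x@residues
}

## ---- show methods ----

setMethod("show", "Topology", function(object) {
  cen <- lipidCensus(object)
  cat("Topology:", nrow(object@particles), "particles,",
      length(proteinResidues(object)), "protein residues,",
      sum(cen), "lipid molecules\n")
  if (length(cen))
    cat("  lipids:", paste(names(cen), cen, sep = ":", collapse = ", "), "\n")
  cat(sprintf("  box: %.3f x %.3f x %.3f nm\n",
              object@box[1], object@box[2], object@box[3]))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d particles, %d frames, %.4g ns/frame (%.4g ns total)\n",
              d[1], d[3], object@timestep, d[3] * object@timestep))
})

setMethod("show", "ContactSet", function(object) {
  cat(sprintf("ContactSet (%s): %d events, %d lipid molecules, %d frames\n",
              object@lipidType, nrow(object@events), length(object@bound),
              object@nFrames))
  cat(sprintf("  cutoffs %.3f/%.3f nm, stride %d\n",
              object@params@lowerCutoff, object@params@upperCutoff,
              object@params@stride))
})

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve: %d events, durations %.4g-%.4g ns\n",
              object@nEvents, min(object@durations), max(object@durations)))
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit [%s, %s]: tau = %.4g ns", object@flag,
              object@model, object@tau))
  if (is.finite(object@ciLow))
    cat(sprintf(" (95%% CI %.4g-%.4g)", object@ciLow, object@ciHigh))
  cat(sprintf(", n = %d events\n", object@nEvents))
})

setMethod("show", "CoContactGraph", function(object) {
  cat(sprintf("CoContactGraph: %d residues, %d edges (%d frames)\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              object@nFrames))
})

setMethod("show", "BindingSiteSet", function(object) {
  cat("BindingSiteSet:", nrow(object@sites), "sites\n")
  if (nrow(object@sites)) print(object@sites, row.names = FALSE)
})

setMethod("show", "BoundPoseSet", function(object) {
  cat(sprintf("BoundPoseSet: %d poses in %d clusters (RMSD cutoff %.3g nm)\n",
              nrow(object@poses), length(unique(object@poses$cluster)),
              object@rmsdCutoff))
})

setMethod("show", "SaturationFit", function(object) {
  if (object@flag == "ok") {
    cat(sprintf(
      "SaturationFit: Kd_app = %.3g +/- %.2g mole%%, Occ_max = %.3g +/- %.2g%%, R2 = %.3f\n",
      object@kd, object@kdSE, object@occMax, object@occMaxSE, object@r2))
  } else {
    cat("SaturationFit: flagged", object@flag, "\n")
  }
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf("DoseResponseFit [%s]: basal = %.4g, Emax = %.4g, EC50 = %.4g M",
              object@model, object@basal, object@emax, object@ec50))
  if (object@model == "bell" && is.finite(object@ec50I))
    cat(sprintf("; inhibitory span = %.4g, EC50_i = %.4g M",
                object@spanI, object@ec50I))
  cat(sprintf(", R2 = %.4f\n", object@r2))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d lipids (%.3g%% cholesterol), %d sites, %d frames @ %.4g ns, seed %d\n",
    object@nLipids, object@cholPct, nrow(object@sites), object@nFrames,
    object@timestep, object@seed))
  if (nrow(object@sites)) {
    kd <- object@sites$k_off / object@sites$k_on_scale
    cat("  implied Kd (mole %):",
        paste(sprintf("%s=%.3g", object@sites$site_id, kd), collapse = ", "),
        "\n")
  }
})
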