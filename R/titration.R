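## Occupancy titration: free-cholesterol percentage, titration points across
## bilayer compositions, saturation-binding fit of the apparent Kd.

#' Time-averaged free cholesterol percentage
#'
#' The independent variable of the binding saturation curve:
#' `100 * <cholesterol molecules not in dual-cutoff contact with any protein
#' residue> / <total lipid molecules>`, averaged over frames. Normalising to
#' all lipids (rather than the cholesterol pool) keeps x on the mole-%
#' composition scale while correcting for protein-sequestered cholesterol.
#'
#' @param contacts a [ContactSet-class] computed for the cholesterol type.
#' @return numeric(1), mole % free cholesterol
#' @export
freeCholesterolPercent <- function(contacts) {
  census <- contacts@census
  total <- sum(census)
  if (total < 1L) stop("topology contains no lipids")
  nChol <- if (contacts@lipidType %in% names(census))
    census[[contacts@lipidType]] else 0L
  if (nChol == 0L) return(0)
  boundPerFrame <- rep(0L, contacts@nFrames)
  for (m in contacts@bound) {
    anyBound <- colSums(m) > 0
    boundPerFrame <- boundPerFrame + anyBound
  }
  100 * mean(nChol - boundPerFrame) / total
}

#' Measure one titration point from a contact set
#'
#' @param contacts a [ContactSet-class].
#' @param residues site residue ids.
#' @return list with `x` (mole % free cholesterol) and `occupancy` (%)
#' @export
titrationPoint <- function(contacts, residues) {
  list(x = freeCholesterolPercent(contacts),
       occupancy = siteOccupancy(contacts, residues))
}

#' Read a titration manifest
#'
#' A manifest lists one row per (composition, replicate) trajectory:
#' columns `composition_label`, `structure`, `trajectory`, `replicate`.
#' CSV or YAML (a list of row records). Compositions are never inferred
#' from file names.
#'
#' @param path CSV or YAML manifest.
#' @return data.frame
#' @export
readTitrationManifest <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("yml", "yaml")) {
    do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("composition_label", "structure", "trajectory", "replicate")
  if (!all(need %in% names(m)))
    stop("manifest lacks columns: ",
         paste(setdiff(need, names(m)), collapse = ", "))
  m
}

#' Compute titration points for a site across a manifest
#'
#' Runs structure/trajectory reading and dual-cutoff contact detection for
#' every manifest row and measures (free cholesterol %, site occupancy %).
#'
#' @param manifest data.frame from [readTitrationManifest()] (or a path).
#' @param residues site residue ids.
#' @param params a [ContactParameters-class].
#' @param lipidType lipid type (default `"cholesterol"`).
#' @param timestep ns per frame for the trajectories.
#' @param ... passed to [readStructure()].
#' @return data.frame: `composition_label`, `replicate`, `x`,
#'   `occupancy_pct`
#' @export
titrationFromManifest <- function(manifest, residues,
                                  params = contactParameters(),
                                  lipidType = "cholesterol", timestep = 1.0,
                                  ...) {
  if (is.character(manifest)) manifest <- readTitrationManifest(manifest)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    top <- readStructure(manifest$structure[i], ...)
    trj <- readTrajectory(manifest$trajectory[i], top, timestep = timestep)
    ct <- detectContacts(trj, top, lipidType, params)
    pt <- titrationPoint(ct, residues)
    data.frame(composition_label = manifest$composition_label[i],
               replicate = manifest$replicate[i],
               x = pt$x, occupancy_pct = pt$occupancy)
  })
  do.call(rbind, rows)
}

#' Aggregate per-replicate titration points per composition
#'
#' @param points data.frame with `composition_label`, `x`, `occupancy_pct`.
#' @return data.frame with mean `x`, mean `occupancy_pct`, `se` (across
#'   replicates) and `n_rep` per composition
#' @export
aggregateTitration <- function(points) {
  sp <- split(points, points$composition_label)
  out <- lapply(sp, function(d) data.frame(
    composition_label = d$composition_label[1],
    x = mean(d$x),
    occupancy_pct = mean(d$occupancy_pct),
    se = stats::sd(d$occupancy_pct) / sqrt(nrow(d)),
    n_rep = nrow(d)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$x), ]
}

#' Fit a binding saturation curve
#'
#' Fits \eqn{Occ(x) = Occ_{max} \, x / (K_d^{app} + x)} — optionally plus a
#' non-specific linear term \eqn{m x} — to occupancy-vs-free-cholesterol
#' points, weighted by \eqn{1/SE^2} when an `se` column is present.
#' Parameter standard errors come from the fit covariance; the 95% CI for
#' \eqn{K_d^{app}} is t-based. Data that a pure line describes at least as
#' well (corrected AIC) are flagged `"non_saturable"`; all-zero occupancies
#' are flagged `"no_binding"` and carry no Kd.
#'
#' @param points data.frame with columns `x` (mole % free cholesterol,
#'   in `[0, 100]`) and `occupancy_pct` (`[0, 100]`), optionally `se`.
#' @param includeNonspecific add the linear background term (default
#'   `FALSE`; the conventional alternative is fitting the background as its
#'   own curve and reporting it alongside).
#' @return a [SaturationFit-class]
#' @export
fitSaturation <- function(points, includeNonspecific = FALSE) {
  x <- points$x
  occ <- points$occupancy_pct
  if (any(x < 0 | x > 100)) stop("x must lie in [0, 100] mole %")
  if (any(occ < -1e-9 | occ > 100 + 1e-9))
    stop("occupancy must lie in [0, 100] %")
  if (length(unique(x)) < 3L)
    stop("need >= 3 distinct free-cholesterol values")
  noFit <- function(flag) new(
    "SaturationFit", kd = NA_real_, kdSE = NA_real_, occMax = NA_real_,
    occMaxSE = NA_real_, slope = NA_real_, r2 = NA_real_,
    kdCI = c(NA_real_, NA_real_), n = length(x), flag = flag)
  if (all(occ == 0)) return(noFit("no_binding"))

  w <- if (!is.null(points$se) && all(is.finite(points$se)) &&
           all(points$se > 0)) 1 / points$se^2 else rep(1, length(x))

  occmax0 <- min(max(occ) * 1.1, 99)  # keep the start off the upper bound
  kd0 <- x[which.min(abs(occ - occmax0 / 2))]
  kd0 <- min(max(kd0, 0.5), 100)
  fml <- if (includeNonspecific)
    occupancy_pct ~ occmax * x / (kd + x) + m * x
  else occupancy_pct ~ occmax * x / (kd + x)
  st <- list(occmax = occmax0, kd = kd0)
  lo <- c(occmax = 1e-6, kd = 1e-6)
  up <- c(occmax = 100, kd = Inf)
  if (includeNonspecific) {
    st$m <- 0; lo <- c(lo, m = -Inf); up <- c(up, m = Inf)
  }
  dat <- data.frame(x = x, occupancy_pct = occ)
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(fml, data = dat, start = st, weights = w,
                      lower = lo, upper = up,
                      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) return(noFit("non_saturable"))

  p <- length(st)
  rss <- sum(w * stats::residuals(fit)^2)
  lin <- stats::lm(occ ~ 0 + x, weights = w)
  rssLin <- sum(w * stats::residuals(lin)^2)
  n <- length(x)

  co <- summary(fit)$coefficients
  kd <- co["kd", "Estimate"]; kdSE <- co["kd", "Std. Error"]
  om <- co["occmax", "Estimate"]; omSE <- co["occmax", "Std. Error"]
  ## non-saturable background: a pure line carries at least as much AICc
  ## support as the hyperbola AND half-saturation lies beyond the sampled
  ## composition range, i.e. no saturation was observed at all
  if (aicc(max(rssLin, 1e-300), n, 1) < aicc(max(rss, 1e-300), n, p) &&
      kd > max(x))
    return(noFit("non_saturable"))
  m <- if (includeNonspecific) co["m", "Estimate"] else NA_real_
  mw <- sum(w * occ) / sum(w)
  tss <- sum(w * (occ - mw)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  ## profile-likelihood 95% CI for Kd (the Wald interval undercovers for
  ## this strongly curved parameter); Wald as fallback where the profile
  ## fails or runs into a bound
  tq <- stats::qt(0.975, df = max(n - p, 1))
  wald <- c(kd - tq * kdSE, kd + tq * kdSE)
  ci <- tryCatch(
    as.numeric(suppressWarnings(suppressMessages(
      stats::confint(fit, "kd", level = 0.95)))),
    error = function(e) wald)
  ci[is.na(ci)] <- wald[is.na(ci)]
  new("SaturationFit", kd = kd, kdSE = kdSE, occMax = om, occMaxSE = omSE,
      slope = m, r2 = r2, kdCI = ci,
      n = as.integer(n), flag = "ok")
}

#' Export a saturation fit as a JSON report
#'
#' The report records the fitted parameters together with the definitions
#' used (free cholesterol normalised to all lipids; per-replicate points).
#'
#' @param fit a [SaturationFit-class].
#' @param path output JSON path.
#' @param points optional points data.frame to embed.
#' @return `path`, invisibly
#' @export
writeSaturationReport <- function(fit, path, points = NULL) {
  rep <- list(
    kd_app_pct = fit@kd, kd_se = fit@kdSE,
    kd_ci95 = fit@kdCI,
    occ_max_pct = fit@occMax, occ_max_se = fit@occMaxSE,
    nonspecific_slope = fit@slope, r2 = fit@r2, n_points = fit@n,
    flag = fit@flag,
    definitions = list(
      free_cholesterol = "unbound cholesterol / all lipid molecules, time-averaged",
      replicates = "per-replicate points unless aggregated upstream"))
  if (!is.null(points)) rep$points <- points
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
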