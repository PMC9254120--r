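## Dose-response statistics: 3-parameter logistic and bell-shaped
## (superposed stimulatory/inhibitory) fits, pertussis-toxin subtraction of
## the Gi component, Emax/EC50 agonism index and its regression against
## cellular cholesterol, and the glucagon-alanine index.

checkDose <- function(data, minConc) {
  need <- c("concentration_M", "response")
  if (!all(need %in% names(data)))
    stop("dose-response data needs columns: ", paste(need, collapse = ", "))
  if (any(data$concentration_M <= 0)) stop("concentrations must be > 0")
  if (length(unique(data$concentration_M)) < minConc)
    stop("need >= ", minConc, " distinct concentrations")
  invisible(data)
}

## deterministic multi-start nlsLM; returns the converged fit with least RSS
multiStartNls <- function(formula, data, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("nonlinear fit failed to converge from any start")
  best$fit
}

rSquared <- function(y, rss) {
  tss <- sum((y - mean(y))^2)
  if (tss > 0) 1 - rss / tss else 1
}

#' Fit a 3-parameter logistic concentration-response curve
#'
#' \eqn{R(c) = basal + (E_{max} - basal)/(1 + EC_{50}/c)} with the Hill
#' slope fixed at 1, by least squares on the supplied response scale with
#' deterministic multi-start in \eqn{\log_{10} EC_{50}}.
#'
#' @param data data.frame with `concentration_M` (mol/L) and `response`.
#' @return a [DoseResponseFit-class] with `model = "logistic3"`
#' @export
fitLogistic3 <- function(data) {
  checkDose(data, 4L)
  lc <- log10(data$concentration_M)
  starts <- lapply(stats::quantile(lc, c(0.25, 0.5, 0.75), names = FALSE),
                   function(le) list(basal = min(data$response),
                                     emax = max(data$response),
                                     logec50 = le))
  fit <- multiStartNls(
    response ~ basal + (emax - basal) / (1 + 10^logec50 / concentration_M),
    data, starts,
    lower = c(basal = -Inf, emax = -Inf, logec50 = -30),
    upper = c(basal = Inf, emax = Inf, logec50 = 5))
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  new("DoseResponseFit", model = "logistic3",
      basal = co[["basal"]], emax = co[["emax"]],
      ec50 = 10^co[["logec50"]],
      spanS = NA_real_, ec50S = NA_real_, spanI = NA_real_,
      ec50I = NA_real_, r2 = rSquared(data$response, rss), flag = "ok")
}

#' Fit a hormetic (bell-shaped) concentration-response curve
#'
#' Superposed stimulatory and inhibitory logistic components with Hill
#' slopes fixed at 1:
#' \deqn{R(c) = basal + span_s/(1 + EC_{50,s}/c) - span_i/(1 + EC_{50,i}/c)}
#' The inhibitory potency is parameterised as
#' \eqn{EC_{50,i} = EC_{50,s} \cdot 10^{\delta}} with \eqn{\delta \ge 0}, so
#' the inhibitory component always engages at higher agonist concentrations
#' than the stimulatory one. A fit whose inhibitory span vanishes is
#' reported as collapsed to the 3-parameter logistic.
#'
#' @param data data.frame with `concentration_M` (mol/L) and `response`.
#' @param fixSpanI optionally constrain the inhibitory span (e.g. `0` for
#'   the nested logistic fit).
#' @return a [DoseResponseFit-class] with `model = "bell"`; slot `emax` is
#'   the stimulatory plateau `basal + span_s` and slot `ec50` is `EC50_s`.
#' @export
fitBell <- function(data, fixSpanI = NULL) {
  checkDose(data, 6L)
  if (!is.null(fixSpanI) && fixSpanI == 0) {
    l3 <- fitLogistic3(data)
    return(new("DoseResponseFit", model = "bell", basal = l3@basal,
               emax = l3@emax, ec50 = l3@ec50,
               spanS = l3@emax - l3@basal, ec50S = l3@ec50,
               spanI = 0, ec50I = l3@ec50, r2 = l3@r2,
               flag = "collapsed_to_logistic3"))
  }
  agg <- tapply(data$response, data$concentration_M, mean)
  peak <- max(agg)
  tail <- agg[[length(agg)]]
  b0 <- min(agg)
  lc <- log10(sort(unique(data$concentration_M)))
  starts <- list()
  for (le in stats::quantile(lc, c(0.2, 0.4, 0.6), names = FALSE))
    for (d0 in c(0.5, 1, 2))
      starts[[length(starts) + 1L]] <- list(
        basal = b0, spans = peak - b0,
        spani = max(peak - tail, 0.05 * (peak - b0)),
        logec50s = le, delta = d0)
  fit <- multiStartNls(
    response ~ basal + spans / (1 + 10^logec50s / concentration_M) -
      spani / (1 + 10^(logec50s + delta) / concentration_M),
    data, starts,
    lower = c(basal = -Inf, spans = 0, spani = 0, logec50s = -30, delta = 0),
    upper = c(basal = Inf, spans = Inf, spani = Inf, logec50s = 5,
              delta = 15))
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  spanI <- co[["spani"]]
  ## data without a genuine descending phase are over-parameterised by the
  ## bell model (stimulatory/inhibitory spans can cancel): report the fit
  ## as collapsed when the nested logistic describes it as well (AICc)
  l3 <- tryCatch(fitLogistic3(data), error = function(e) NULL)
  if (!is.null(l3)) {
    rssL3 <- sum((data$response -
                    predictResponse(l3, data$concentration_M))^2)
    n <- nrow(data)
    if (aicc(max(rssL3, 1e-300), n, 3) <= aicc(max(rss, 1e-300), n, 5)) {
      return(new("DoseResponseFit", model = "bell", basal = l3@basal,
                 emax = l3@emax, ec50 = l3@ec50,
                 spanS = l3@emax - l3@basal, ec50S = l3@ec50,
                 spanI = 0, ec50I = l3@ec50, r2 = l3@r2,
                 flag = "collapsed_to_logistic3"))
    }
  }
  collapsed <- spanI <= 1e-6 * max(co[["spans"]], 1)
  new("DoseResponseFit", model = "bell", basal = co[["basal"]],
      emax = co[["basal"]] + co[["spans"]], ec50 = 10^co[["logec50s"]],
      spanS = co[["spans"]], ec50S = 10^co[["logec50s"]],
      spanI = spanI, ec50I = 10^(co[["logec50s"]] + co[["delta"]]),
      r2 = rSquared(data$response, rss),
      flag = if (collapsed) "collapsed_to_logistic3" else "ok")
}

#' Predicted response of a dose-response fit
#'
#' @param fit a [DoseResponseFit-class].
#' @param concentration concentrations (mol/L).
#' @return numeric responses
#' @export
predictResponse <- function(fit, concentration) {
  if (fit@model == "logistic3")
    fit@basal + (fit@emax - fit@basal) / (1 + fit@ec50 / concentration)
  else
    fit@basal + fit@spanS / (1 + fit@ec50S / concentration) -
      fit@spanI / (1 + fit@ec50I / concentration)
}

#' Gi component of a bell-shaped response by pertussis-toxin subtraction
#'
#' Pertussis toxin blocks Gi signalling, so the response measured with PTX
#' is the Gs-specific response; subtracting the total response from it
#' (pointwise, per concentration) yields the positive-signed Gi suppression
#' of cAMP. Replicates are averaged per concentration; the two datasets must
#' share an identical concentration grid.
#'
#' @param total dose-response data.frame (total response).
#' @param ptx dose-response data.frame measured with pertussis toxin.
#' @return list with `curve` (data.frame `concentration_M`,
#'   `gi_suppression`) and `auc` (trapezoidal area over
#'   \eqn{\log_{10}} concentration)
#' @export
giComponent <- function(total, ptx) {
  checkDose(total, 1L); checkDose(ptx, 1L)
  gT <- sort(unique(total$concentration_M))
  gP <- sort(unique(ptx$concentration_M))
  if (length(gT) != length(gP) || any(abs(gT - gP) > 1e-12 * pmax(gT, gP)))
    stop("total and PTX datasets must share an identical concentration grid")
  mT <- tapply(total$response, total$concentration_M, mean)
  mP <- tapply(ptx$response, ptx$concentration_M, mean)
  diff <- as.numeric(mP) - as.numeric(mT)
  curve <- data.frame(concentration_M = gT, gi_suppression = diff)
  list(curve = curve, auc = trapz(log10(gT), diff))
}

#' Combined Emax/EC50 agonism index
#'
#' \eqn{\log_{10}\left[(E_{max}/EC_{50})_{treatment} /
#' (E_{max}/EC_{50})_{vehicle}\right]}: a combined measure of efficacy and
#' potency normalised to vehicle control, so the vehicle's own index is 0.
#' Invariant to rescaling both curves' response units by a common factor.
#'
#' @param treatmentFit,vehicleFit [DoseResponseFit-class] objects.
#' @return numeric(1)
#' @export
agonismIndex <- function(treatmentFit, vehicleFit) {
  vals <- c(Emax(treatmentFit), Emax(vehicleFit),
            EC50(treatmentFit), EC50(vehicleFit))
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("agonism index requires positive Emax and EC50 in both fits")
  log10((Emax(treatmentFit) / EC50(treatmentFit)) /
          (Emax(vehicleFit) / EC50(vehicleFit)))
}

#' Linear regression of agonism index on cellular cholesterol
#'
#' Ordinary least squares of the log-transformed Emax/EC50 index against
#' relative cellular cholesterol content, with goodness of fit and 95%
#' confidence intervals.
#'
#' @param cholesterol relative cellular cholesterol (numeric).
#' @param index agonism indices (numeric, same length).
#' @return list: `slope`, `intercept`, `r2`, `ci` (2x2 matrix of 95% CIs),
#'   `n`
#' @export
cholesterolResponseRegression <- function(cholesterol, index) {
  if (length(cholesterol) != length(index))
    stop("cholesterol and index must have equal length")
  if (length(cholesterol) < 3L) stop("need >= 3 points")
  if (stats::sd(cholesterol) == 0) stop("zero variance in cholesterol")
  fit <- stats::lm(index ~ cholesterol)
  s <- summary(fit)
  list(slope = stats::coef(fit)[["cholesterol"]],
       intercept = stats::coef(fit)[["(Intercept)"]],
       r2 = s$r.squared,
       ci = stats::confint(fit),
       n = length(index))
}

#' Glucagon-alanine index
#'
#' Fasting glucagon (pmol/L) multiplied by fasting alanine (mmol/L), a
#' surrogate marker of glucagon resistance.
#'
#' @param glucagon pmol/L, >= 0 (vectorised).
#' @param alanine mmol/L, >= 0 (vectorised).
#' @return numeric, pmol x mmol / L^2
#' @export
glucagonAlanineIndex <- function(glucagon, alanine) {
  if (any(glucagon < 0) || any(alanine < 0))
    stop("glucagon and alanine must be >= 0")
  glucagon * alanine
}
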