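#' @import methods
NULL

## Site classes recognised throughout the package. "side" events sit on the
## filament lattice, "branch" events at mother/daughter junctions.
.SITE_CLASSES <- c("background", "side", "branch")

#' Kinetic model for one site class
#'
#' Couples a homogeneous Poisson arrival rate (events per second per site)
#' with a dwell-time model: either a single exponential with mean `tau`, or
#' a two-component exponential mixture with means `tShort < tLong` and
#' long-component weight `fracLong`.
#'
#' @slot arrivalRate events per second per site (>= 0).
#' @slot dwell named list: either `list(tau = )` or
#'   `list(tShort = , tLong = , fracLong = )`, all times in seconds.
#' @export
setClass("KineticModel",
  representation(arrivalRate = "numeric", dwell = "list"))

setValidity("KineticModel", function(object) {
  msg <- character()
  if (length(object@arrivalRate) != 1 || is.na(object@arrivalRate) ||
      object@arrivalRate < 0)
    msg <- c(msg, "arrivalRate must be a single nonnegative number")
  d <- object@dwell
  if (!is.null(d$tau)) {
    if (!is.finite(d$tau) || d$tau <= 0)
      msg <- c(msg, "tau must be > 0")
  } else if (!is.null(d$tShort)) {
    if (!is.finite(d$tShort) || !is.finite(d$tLong) ||
        d$tShort <= 0 || d$tLong <= d$tShort)
      msg <- c(msg, "need 0 < tShort < tLong")
    if (is.null(d$fracLong) || d$fracLong < 0 || d$fracLong > 1)
      msg <- c(msg, "fracLong must lie in [0, 1]")
  } else {
    msg <- c(msg, "dwell must specify tau or (tShort, tLong, fracLong)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a KineticModel
#'
#' @param arrivalRate Poisson arrival rate, events/s per site.
#' @param tau single-exponential mean dwell (s). Mutually exclusive with
#'   the mixture parameters.
#' @param tShort,tLong,fracLong two-exponential mixture: component means (s)
#'   with `tShort < tLong`, and the weight of the long component.
#' @return A [KineticModel-class] object.
#' @examples
#' KineticModel(arrivalRate = 0.5, tau = 0.46)
#' KineticModel(arrivalRate = 0.1, tShort = 2, tLong = 28, fracLong = 0.1)
#' @export
KineticModel <- function(arrivalRate = 0, tau = NULL,
                         tShort = NULL, tLong = NULL, fracLong = NULL) {
  if (!is.null(tau) && !is.null(tShort))
    stop("give either tau or (tShort, tLong, fracLong), not both")
  dwell <- if (!is.null(tau)) list(tau = tau)
           else list(tShort = tShort, tLong = tLong, fracLong = fracLong)
  new("KineticModel", arrivalRate = arrivalRate, dwell = dwell)
}

setMethod("show", "KineticModel", function(object) {
  d <- object@dwell
  dw <- if (!is.null(d$tau)) sprintf("Exp(tau = %g s)", d$tau)
        else sprintf("Mix(tShort = %g s, tLong = %g s, fracLong = %g)",
                     d$tShort, d$tLong, d$fracLong)
  cat(sprintf("KineticModel: arrival %g /s/site, dwell %s\n",
              object@arrivalRate, dw))
})

#' Geometry of filaments and branch junctions
#'
#' Filaments are polylines in micrometres (origin at the image corner);
#' branch junctions are points. Total filament length feeds the 370
#' sites/um side-site count, branch points count 1 site each.
#'
#' @slot filaments list of two-column matrices (x_um, y_um), one per
#'   filament polyline.
#' @slot branches two-column matrix of branch junction coordinates (um).
#' @export
setClass("SiteMap",
  representation(filaments = "list", branches = "matrix"))

setValidity("SiteMap", function(object) {
  ok <- vapply(object@filaments, function(f)
    is.matrix(f) && ncol(f) == 2 && nrow(f) >= 2 && all(is.finite(f)),
    logical(1))
  if (!all(ok)) return("each filament must be a finite n x 2 matrix, n >= 2")
  if (ncol(object@branches) != 2 && nrow(object@branches) > 0)
    return("branches must be a two-column matrix")
  TRUE
})

#' Construct a SiteMap
#'
#' @param filaments list of n x 2 matrices of polyline vertices (um).
#' @param branches two-column matrix (or NULL) of branch points (um).
#' @return A [SiteMap-class] object.
#' @examples
#' sm <- SiteMap(filaments = list(cbind(c(0, 10), c(5, 5))),
#'               branches = cbind(4, 5))
#' filamentLength(sm)
#' @export
SiteMap <- function(filaments = list(), branches = NULL) {
  if (is.null(branches)) branches <- matrix(numeric(0), ncol = 2)
  if (!is.matrix(branches)) branches <- matrix(branches, ncol = 2)
  new("SiteMap", filaments = filaments, branches = branches)
}

#' @describeIn SiteMap total polyline length in micrometres.
#' @param siteMap a [SiteMap-class] object.
#' @export
filamentLength <- function(siteMap) {
  sum(vapply(siteMap@filaments, function(f) {
    sum(sqrt(rowSums((f[-1, , drop = FALSE] -
                      f[-nrow(f), , drop = FALSE])^2)))
  }, numeric(1)))
}

#' @describeIn SiteMap number of branch junction points.
#' @export
nBranches <- function(siteMap) nrow(siteMap@branches)

setMethod("show", "SiteMap", function(object) {
  cat(sprintf("SiteMap: %d filaments (%.2f um total), %d branch junctions\n",
              length(object@filaments), filamentLength(object),
              nBranches(object)))
})

#' Simulation scenario
#'
#' Bundles everything a reproducible ground-truth simulation needs: the
#' random seed, recording duration and frame interval, site geometry, and
#' a kinetic model per site class.
#'
#' @slot seed integer RNG seed; identical (seed, scenario) pairs reproduce
#'   identical outputs.
#' @slot durationS recording duration in seconds.
#' @slot frameIntervalS acquisition interval dt in seconds (typical values
#'   0.15, 0.25 or 1).
#' @slot siteMap a [SiteMap-class].
#' @slot kinetics named list of [KineticModel-class] objects keyed by site
#'   class (`background`, `side`, `branch`).
#' @slot labeledFraction fraction of molecules carrying a visible label.
#' @export
setClass("SimScenario",
  representation(seed = "numeric", durationS = "numeric",
                 frameIntervalS = "numeric", siteMap = "SiteMap",
                 kinetics = "list", labeledFraction = "numeric"))

setValidity("SimScenario", function(object) {
  msg <- character()
  if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be > 0")
  if (object@labeledFraction < 0 || object@labeledFraction > 1)
    msg <- c(msg, "labeledFraction must lie in [0, 1]")
  if (length(object@kinetics) == 0 ||
      !all(names(object@kinetics) %in% .SITE_CLASSES))
    msg <- c(msg, "kinetics must be named by site class")
  if (!all(vapply(object@kinetics, is, logical(1), "KineticModel")))
    msg <- c(msg, "kinetics entries must be KineticModel objects")
  if (length(msg)) msg else TRUE
})

#' Construct a SimScenario
#'
#' @param seed integer RNG seed.
#' @param durationS recording duration (s).
#' @param frameIntervalS frame interval dt (s).
#' @param siteMap a [SiteMap-class].
#' @param kinetics named list of [KineticModel-class] per site class.
#' @param labeledFraction fraction of molecules labeled, in [0, 1].
#' @return A [SimScenario-class] object.
#' @export
SimScenario <- function(seed, durationS, frameIntervalS, siteMap = SiteMap(),
                        kinetics = list(), labeledFraction = 1) {
  new("SimScenario", seed = seed, durationS = durationS,
      frameIntervalS = frameIntervalS, siteMap = siteMap,
      kinetics = kinetics, labeledFraction = labeledFraction)
}

setMethod("show", "SimScenario", function(object) {
  cat(sprintf(
    "SimScenario: %g s at dt = %g s, seed %d, %d site classes\n",
    object@durationS, object@frameIntervalS, as.integer(object@seed),
    length(object@kinetics)))
})

#' Rendering parameters for synthetic movies
#'
#' @slot pixelSizeUm um per pixel (microscope setups here use 0.27 or 0.18).
#' @slot imageShape c(height, width) in pixels.
#' @slot psfSigmaPx Gaussian point-spread sigma in pixels.
#' @slot photonsPerSpot expected integrated photons per bound molecule.
#' @slot backgroundLevel constant background counts per pixel.
#' @slot noiseModel one of "none", "poisson", "gaussian".
#' @slot noiseSd Gaussian noise SD (used when noiseModel == "gaussian").
#' @export
setClass("MovieParams",
  representation(pixelSizeUm = "numeric", imageShape = "numeric",
                 psfSigmaPx = "numeric", photonsPerSpot = "numeric",
                 backgroundLevel = "numeric", noiseModel = "character",
                 noiseSd = "numeric"))

setValidity("MovieParams", function(object) {
  msg <- character()
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@psfSigmaPx <= 0) msg <- c(msg, "psfSigmaPx must be > 0")
  if (length(object@imageShape) != 2 || any(object@imageShape < 1))
    msg <- c(msg, "imageShape must be c(height, width)")
  if (!object@noiseModel %in% c("none", "poisson", "gaussian"))
    msg <- c(msg, "noiseModel must be none, poisson or gaussian")
  if (length(msg)) msg else TRUE
})

#' Construct MovieParams
#'
#' @param pixelSizeUm um/pixel.
#' @param imageShape c(height, width) pixels.
#' @param psfSigmaPx PSF sigma (pixels).
#' @param photonsPerSpot photons per spot.
#' @param backgroundLevel background counts/pixel.
#' @param noiseModel "none", "poisson" or "gaussian".
#' @param noiseSd SD for Gaussian noise.
#' @return A [MovieParams-class] object.
#' @export
MovieParams <- function(pixelSizeUm = 0.27, imageShape = c(64, 64),
                        psfSigmaPx = 1.2, photonsPerSpot = 500,
                        backgroundLevel = 0, noiseModel = "none",
                        noiseSd = 0) {
  new("MovieParams", pixelSizeUm = pixelSizeUm, imageShape = imageShape,
      psfSigmaPx = psfSigmaPx, photonsPerSpot = photonsPerSpot,
      backgroundLevel = backgroundLevel, noiseModel = noiseModel,
      noiseSd = noiseSd)
}

#' A sample of frame-quantized dwell times
#'
#' The unit of all survival fitting: integer frame counts k >= 1 with the
#' frame interval dt and per-event right-censoring flags. Observed dwell
#' time is k * dt.
#'
#' @slot frameCounts integer vector, each >= 1.
#' @slot frameIntervalS acquisition interval dt (s).
#' @slot censored logical vector parallel to frameCounts; TRUE means the
#'   molecule was still bound at the last acquisition instant.
#' @export
setClass("DwellSample",
  representation(frameCounts = "integer", frameIntervalS = "numeric",
                 censored = "logical"))

setValidity("DwellSample", function(object) {
  msg <- character()
  if (length(object@frameCounts) < 1) msg <- c(msg, "need at least 1 event")
  if (any(object@frameCounts < 1L)) msg <- c(msg, "all frame counts must be >= 1")
  if (length(object@censored) != length(object@frameCounts))
    msg <- c(msg, "censored must parallel frameCounts")
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DwellSample
#'
#' @param frameCounts integer frame counts (>= 1).
#' @param frameIntervalS frame interval dt (s).
#' @param censored logical right-censoring flags (default all FALSE).
#' @return A [DwellSample-class] object.
#' @examples
#' DwellSample(c(1, 1, 2, 3), frameIntervalS = 0.25)
#' @export
DwellSample <- function(frameCounts, frameIntervalS,
                        censored = rep(FALSE, length(frameCounts))) {
  new("DwellSample", frameCounts = as.integer(frameCounts),
      frameIntervalS = frameIntervalS, censored = as.logical(censored))
}

#' @describeIn DwellSample number of events in the sample.
#' @param sample a [DwellSample-class].
#' @export
nEvents <- function(sample) length(sample@frameCounts)

#' @describeIn DwellSample frame counts accessor.
#' @export
frameCounts <- function(sample) sample@frameCounts

#' @describeIn DwellSample frame interval accessor (s).
#' @export
frameInterval <- function(sample) sample@frameIntervalS

#' @describeIn DwellSample censoring flags accessor.
#' @export
isCensored <- function(sample) sample@censored

#' @describeIn DwellSample observed dwell times k * dt (s).
#' @export
dwellTimes <- function(sample) sample@frameCounts * sample@frameIntervalS

setMethod("show", "DwellSample", function(object) {
  cat(sprintf(
    "DwellSample: n = %d events at dt = %g s (%d censored), mean dwell %.3g s\n",
    nEvents(object), object@frameIntervalS, sum(object@censored),
    mean(dwellTimes(object))))
})

#' Single-exponential dwell fit
#'
#' @slot tau fitted mean dwell time (s).
#' @slot loglik maximized log-likelihood.
#' @slot seTau bootstrap standard error of tau (NA until bootstrapped).
#' @slot estimator "naive" or "phase_marginalized".
#' @slot n number of events fitted.
#' @export
setClass("ExpFit",
  representation(tau = "numeric", loglik = "numeric", seTau = "numeric",
                 estimator = "character", n = "integer"))

setValidity("ExpFit", function(object)
  if (object@tau <= 0) "tau must be > 0" else TRUE)

setMethod("show", "ExpFit", function(object) {
  cat(sprintf("ExpFit (%s): tau = %.4g s%s, logLik = %.3f, n = %d\n",
              object@estimator, object@tau,
              if (is.na(object@seTau)) "" else
                sprintf(" +/- %.3g", object@seTau),
              object@loglik, object@n))
})

#' Two-exponential mixture dwell fit
#'
#' Canonical ordering `tShort < tLong` is enforced. `fracLong` is the
#' mixture weight of the long-lived component.
#'
#' @slot tShort,tLong component mean dwell times (s).
#' @slot fracLong weight of the long component, in [0, 1].
#' @slot loglik maximized log-likelihood.
#' @slot se named numeric: bootstrap SEs for tShort, tLong, fracLong.
#' @slot estimator "naive" or "phase_marginalized".
#' @slot n number of events fitted.
#' @slot converged logical optimizer status.
#' @export
setClass("Exp2Fit",
  representation(tShort = "numeric", tLong = "numeric", fracLong = "numeric",
                 loglik = "numeric", se = "numeric", estimator = "character",
                 n = "integer", converged = "logical"))

setValidity("Exp2Fit", function(object) {
  msg <- character()
  if (object@tShort <= 0) msg <- c(msg, "tShort must be > 0")
  if (object@tLong < object@tShort)
    msg <- c(msg, "canonical ordering tShort <= tLong violated")
  if (object@fracLong < 0 || object@fracLong > 1)
    msg <- c(msg, "fracLong must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Exp2Fit", function(object) {
  fmt <- function(v, s) if (is.na(s)) sprintf("%.4g", v) else
    sprintf("%.4g +/- %.3g", v, s)
  cat(sprintf(
    "Exp2Fit (%s): tShort = %s s, tLong = %s s, fracLong = %s, logLik = %.3f, n = %d\n",
    object@estimator, fmt(object@tShort, object@se[["tShort"]]),
    fmt(object@tLong, object@se[["tLong"]]),
    fmt(object@fracLong, object@se[["fracLong"]]), object@loglik, object@n))
})

#' Empirical cumulative survival curve
#'
#' S(t) is the fraction of events with dwell (or lifetime) >= t; it starts
#' at 1 and is non-increasing. With right-censored observations the
#' product-limit (Kaplan-Meier) estimator is used.
#'
#' @slot times evaluation times (s).
#' @slot survival survival fractions in [0, 1].
#' @export
setClass("SurvivalCurve",
  representation(times = "numeric", survival = "numeric"))

setValidity("SurvivalCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@survival))
    msg <- c(msg, "times and survival must have equal length")
  if (any(diff(object@survival) > 1e-12))
    msg <- c(msg, "survival must be non-increasing")
  if (any(object@survival < -1e-12 | object@survival > 1 + 1e-12))
    msg <- c(msg, "survival must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SurvivalCurve evaluation times accessor.
#' @param curve a [SurvivalCurve-class].
#' @export
curveTimes <- function(curve) curve@times

#' @describeIn SurvivalCurve survival fraction accessor.
#' @export
curveSurvival <- function(curve) curve@survival

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve on [%g, %g] s (%d points)\n",
              min(object@times), max(object@times), length(object@times)))
})

#' Piecewise-constant photobleaching step fit
#'
#' @slot nSteps number of downward intensity steps.
#' @slot changePoints 1-based frame indices of the first frame after each
#'   retained change point (downward changes only).
#' @slot levelMeans fitted segment means, in time order.
#' @slot score BIC of the selected segmentation.
#' @export
setClass("StepFit",
  representation(nSteps = "integer", changePoints = "integer",
                 levelMeans = "numeric", score = "numeric"))

setMethod("show", "StepFit", function(object) {
  cat(sprintf("StepFit: %d downward step(s) at frame(s) %s\n",
              object@nSteps,
              if (length(object@changePoints))
                paste(object@changePoints, collapse = ", ") else "-"))
})

#' Gel densitometry standard curve
#'
#' Intensity = b1 * c + b2 * c^2, forced through the origin.
#'
#' @slot species species label.
#' @slot b1,b2 polynomial coefficients.
#' @slot residual residual standard error of the fit.
#' @slot concRange range of fitted concentrations.
#' @export
setClass("StandardCurve",
  representation(species = "character", b1 = "numeric", b2 = "numeric",
                 residual = "numeric", concRange = "numeric"))

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve [%s]: I = %.4g c + %.4g c^2 (through zero), range [%g, %g]\n",
    object@species, object@b1, object@b2,
    object@concRange[1], object@concRange[2]))
})
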