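#' Simulate ground-truth binding events for a scenario
#'
#' Arrivals at each site are homogeneous Poisson with the class arrival
#' rate; dwell durations are i.i.d. draws from the class dwell model.
#' Sites are: one per branch junction point (`branch`), one per filament
#' polyline (`side`, positions uniform along the polyline), and a single
#' diffuse site (`background`, positions uniform over the non-filament
#' area of the bounding box). Output is the latent truth in continuous
#' time; see [quantizeToFrames()] for the observation process.
#'
#' @param scenario a [SimScenario-class].
#' @return data.frame with columns `event_id`, `site_id`, `site_class`,
#'   `x_um`, `y_um`, `t_start` (s, continuous), `duration` (s, continuous).
#' @examples
#' sc <- SimScenario(seed = 1, durationS = 100, frameIntervalS = 0.25,
#'   siteMap = SiteMap(branches = cbind(2, 2)),
#'   kinetics = list(branch = KineticModel(arrivalRate = 0.2, tau = 1)))
#' head(simulateBindingEvents(sc))
#' @export
simulateBindingEvents <- function(scenario) {
  validObject(scenario)
  sm <- scenario@siteMap
  D <- scenario@durationS
  out <- list()
  withSeed(scenario@seed, {
    for (cls in names(scenario@kinetics)) {
      km <- scenario@kinetics[[cls]]
      validObject(km)
      sites <- switch(cls,
        branch = if (nBranches(sm) > 0)
          lapply(seq_len(nBranches(sm)), function(i)
            list(id = paste0("branch_", i), xy = sm@branches[i, ])) else list(),
        side = if (length(sm@filaments) > 0)
          lapply(seq_along(sm@filaments), function(i)
            list(id = paste0("filament_", i), poly = sm@filaments[[i]])) else list(),
        background = list(list(id = "background_1")))
      for (s in sites) {
        nEv <- stats::rpois(1, km@arrivalRate * D)
        if (nEv == 0) next
        tStart <- sort(stats::runif(nEv, 0, D))
        dur <- drawDwells(nEv, km@dwell)
        pos <- sitePositions(cls, s, nEv, sm)
        out[[length(out) + 1]] <- data.frame(
          site_id = s$id, site_class = cls,
          x_um = pos[, 1], y_um = pos[, 2],
          t_start = tStart, duration = dur,
          stringsAsFactors = FALSE)
      }
    }
  })
  if (length(out) == 0) {
    ev <- data.frame(event_id = integer(0), site_id = character(0),
                     site_class = character(0), x_um = numeric(0),
                     y_um = numeric(0), t_start = numeric(0),
                     duration = numeric(0), stringsAsFactors = FALSE)
    return(ev)
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$t_start), , drop = FALSE]
  ev <- cbind(event_id = seq_len(nrow(ev)), ev)
  rownames(ev) <- NULL
  ev
}

## Draw event positions for a site, class-dependent.
sitePositions <- function(cls, site, n, siteMap) {
  if (cls == "branch") {
    matrix(rep(site$xy, each = n), ncol = 2)
  } else if (cls == "side") {
    poly <- site$poly
    seg <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                         poly[-nrow(poly), , drop = FALSE])^2))
    cum <- c(0, cumsum(seg))
    u <- stats::runif(n, 0, cum[length(cum)])
    i <- findInterval(u, cum, rightmost.closed = TRUE)
    i[i >= nrow(poly)] <- nrow(poly) - 1
    frac <- (u - cum[i]) / pmax(seg[i], .Machine$double.eps)
    poly[i, , drop = FALSE] +
      (poly[i + 1, , drop = FALSE] - poly[i, , drop = FALSE]) * frac
  } else {
    bb <- backgroundBox(siteMap)
    keep <- matrix(NA_real_, 0, 2)
    guard <- 0
    while (nrow(keep) < n && guard < 1000) {
      m <- max(2 * n, 16)
      x <- stats::runif(m, bb[1], bb[2]); y <- stats::runif(m, bb[3], bb[4])
      far <- if (length(siteMap@filaments)) {
        d <- rep(Inf, m)
        for (f in siteMap@filaments) d <- pmin(d, distToPolyline(x, y, f))
        d > sqrt(1.14) / 2
      } else rep(TRUE, m)
      keep <- rbind(keep, cbind(x[far], y[far]))
      guard <- guard + 1
    }
    keep[seq_len(n), , drop = FALSE]
  }
}

backgroundBox <- function(siteMap) {
  pts <- do.call(rbind, c(siteMap@filaments,
                          list(siteMap@branches)))
  if (is.null(pts) || nrow(pts) == 0) return(c(0, 10, 0, 10))
  c(min(pts[, 1]) - 2, max(pts[, 1]) + 2,
    min(pts[, 2]) - 2, max(pts[, 2]) + 2)
}

#' Quantize continuous events onto the acquisition frame grid
#'
#' A molecule is observed in frame k iff it is bound at the instantaneous
#' acquisition time k * dt (exposure is short relative to dt). The
#' observed frame count of an event is the number of acquisition instants
#' falling in `[t_start, t_start + duration)`; events spanning fewer than
#' `minFrames` instants go undetected (detection censoring). Events still
#' bound at the final acquisition instant of a finite recording are
#' right-censored (or dropped when `endHandling = "drop"`).
#'
#' @param events data.frame with `t_start` and `duration` (s); other
#'   columns are carried through.
#' @param frameIntervalS acquisition interval dt (s).
#' @param minFrames minimum number of frames for detection (>= 1).
#' @param durationS recording length (s) defining the final acquisition
#'   instant, or `NULL` for an unbounded recording.
#' @param endHandling `"censor"` (default) flags events running past the
#'   final instant; `"drop"` removes them.
#' @return data.frame of detected events with added columns `start_frame`
#'   (0-based), `n_frames`, `dwell_s = n_frames * dt`, `censored`.
#' @examples
#' ev <- data.frame(t_start = c(0.10, 0.9), duration = c(0.05, 3.0))
#' quantizeToFrames(ev, frameIntervalS = 0.25)
#' @export
quantizeToFrames <- function(events, frameIntervalS, minFrames = 1,
                             durationS = NULL,
                             endHandling = c("censor", "drop")) {
  endHandling <- match.arg(endHandling)
  stopIfNot(minFrames >= 1, "minFrames must be >= 1")
  stopIfNot(frameIntervalS > 0, "frameIntervalS must be > 0")
  if (nrow(events) == 0) {
    events$start_frame <- integer(0); events$n_frames <- integer(0)
    events$dwell_s <- numeric(0); events$censored <- logical(0)
    return(events)
  }
  dt <- frameIntervalS
  k0 <- ceiling(events$t_start / dt)
  ## first instant strictly before the event start is excluded; interval is
  ## half open so an instant exactly at t_start counts, one at the end does not
  kEnd <- ceiling((events$t_start + events$duration) / dt) - 1
  censored <- rep(FALSE, nrow(events))
  if (!is.null(durationS)) {
    kMax <- floor(durationS / dt)
    over <- kEnd >= kMax
    kEnd[over] <- kMax
    censored[over & k0 <= kMax] <- TRUE
  }
  n <- kEnd - k0 + 1
  keep <- n >= minFrames
  out <- events[keep, , drop = FALSE]
  out$start_frame <- as.integer(k0[keep])
  out$n_frames <- as.integer(n[keep])
  out$dwell_s <- out$n_frames * dt
  out$censored <- if (endHandling == "censor") censored[keep] else FALSE
  if (endHandling == "drop") {
    dropMask <- censored[keep]
    out <- out[!dropMask, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Simulate a fixed-size sample of frame-quantized dwell times
#'
#' Convenience generator for parameter-recovery experiments at the event
#' counts a study reports: draws continuous dwells from a single- or
#' two-exponential model with binding start phase uniform on [0, dt),
#' quantizes to frames, and keeps drawing until exactly `n` events are
#' detected (>= `minFrames` frames). No recording-end censoring is applied.
#'
#' @param n number of detected events to return.
#' @param dwell dwell model list: `list(tau = )` or
#'   `list(tShort = , tLong = , fracLong = )` (seconds).
#' @param frameIntervalS acquisition interval dt (s).
#' @param seed RNG seed.
#' @param minFrames detection threshold in frames.
#' @return A [DwellSample-class] of exactly `n` uncensored events.
#' @examples
#' simulateDwells(100, list(tau = 0.46), frameIntervalS = 0.25, seed = 1)
#' @export
simulateDwells <- function(n, dwell, frameIntervalS, seed, minFrames = 1) {
  stopIfNot(n >= 1, "n must be >= 1")
  dt <- frameIntervalS
  counts <- integer(0)
  withSeed(seed, {
    while (length(counts) < n) {
      m <- max(ceiling((n - length(counts)) * 1.6), 64)
      d <- drawDwells(m, dwell)
      u <- stats::runif(m, 0, dt)
      k <- ifelse(d > u, floor((d - u) / dt) + 1, 0)
      counts <- c(counts, k[k >= minFrames])
    }
  })
  DwellSample(counts[seq_len(n)], frameIntervalS = dt)
}

#' Render a synthetic fluorescence movie from quantized events
#'
#' Each bound molecule contributes an integrated-photon Gaussian of sigma
#' `psfSigmaPx` centred at its position for every frame it occupies;
#' constant background and per-pixel noise are applied per the noise model.
#'
#' @param events data.frame with `x_um`, `y_um`, `start_frame`, `n_frames`.
#' @param movieParams a [MovieParams-class].
#' @param nFrames number of frames to render.
#' @return list with `stack` (array height x width x nFrames) and `truth`
#'   (the input events with pixel coordinates `x_px`, `y_px` appended).
#' @export
renderMovie <- function(events, movieParams, nFrames) {
  validObject(movieParams)
  h <- movieParams@imageShape[1]; w <- movieParams@imageShape[2]
  xpx <- events$x_um / movieParams@pixelSizeUm
  ypx <- events$y_um / movieParams@pixelSizeUm
  if (nrow(events) > 0 &&
      (any(xpx < 0 | xpx > w - 1) || any(ypx < 0 | ypx > h - 1)))
    stop("event positions fall outside the image bounds")
  stack <- array(movieParams@backgroundLevel, dim = c(h, w, nFrames))
  sig <- movieParams@psfSigmaPx
  amp <- movieParams@photonsPerSpot / (2 * pi * sig^2)
  r <- ceiling(4 * sig)
  for (i in seq_len(nrow(events))) {
    f0 <- events$start_frame[i]
    f1 <- min(f0 + events$n_frames[i] - 1, nFrames - 1)
    if (f1 < f0 || f0 > nFrames - 1) next
    cx <- xpx[i]; cy <- ypx[i]
    xs <- max(0, floor(cx) - r):min(w - 1, ceiling(cx) + r)
    ys <- max(0, floor(cy) - r):min(h - 1, ceiling(cy) + r)
    g <- amp * outer(exp(-(ys - cy)^2 / (2 * sig^2)),
                     exp(-(xs - cx)^2 / (2 * sig^2)))
    for (f in f0:f1)
      stack[ys + 1, xs + 1, f + 1] <- stack[ys + 1, xs + 1, f + 1] + g
  }
  if (movieParams@noiseModel == "poisson") {
    stack[] <- stats::rpois(length(stack), lambda = pmax(stack, 0))
  } else if (movieParams@noiseModel == "gaussian") {
    stack[] <- stack + stats::rnorm(length(stack), 0, movieParams@noiseSd)
  }
  truth <- events
  truth$x_px <- xpx; truth$y_px <- ypx
  list(stack = stack, truth = truth)
}

#' Simulate stepwise photobleaching intensity traces
#'
#' A fraction of spots carry two fluorophores (the rest one). Each
#' fluorophore bleaches at an independent geometric frame with per-frame
#' probability `bleachRatePerFrame`, dropping the trace intensity by
#' `stepAmplitude`; i.i.d. Gaussian noise is added. Blinking and upward
#' recovery are not modelled.
#'
#' @param nTraces number of traces.
#' @param multiStepFraction fraction of spots with two fluorophores, [0, 1].
#' @param stepAmplitude intensity drop per fluorophore (a.u.).
#' @param bleachRatePerFrame per-frame bleaching probability.
#' @param noiseSd Gaussian noise SD (a.u., >= 0).
#' @param nFrames trace length in frames.
#' @param seed RNG seed.
#' @param frameIntervalS frame interval for the time column (s).
#' @return list with `traces` (data.frame `trace_id`, `frame`, `time_s`,
#'   `intensity`), `trueSteps` (integer fluorophore count per trace), and
#'   `bleachFrames` (list of per-trace bleaching frames; values past the
#'   trace end mean the fluorophore survived the recording).
#' @examples
#' sim <- simulatePhotobleachTraces(5, multiStepFraction = 0.2,
#'   stepAmplitude = 100, bleachRatePerFrame = 0.05, noiseSd = 0,
#'   nFrames = 50, seed = 1)
#' table(sim$trueSteps)
#' @export
simulatePhotobleachTraces <- function(nTraces, multiStepFraction,
                                      stepAmplitude = 100,
                                      bleachRatePerFrame = 0.03,
                                      noiseSd = 0, nFrames = 300, seed = 1,
                                      frameIntervalS = 1) {
  stopIfNot(multiStepFraction >= 0 && multiStepFraction <= 1,
            "multiStepFraction must lie in [0, 1]")
  stopIfNot(noiseSd >= 0, "noiseSd must be >= 0")
  withSeed(seed, {
    nFluor <- ifelse(stats::runif(nTraces) < multiStepFraction, 2L, 1L)
    frames <- 0:(nFrames - 1)
    traces <- vector("list", nTraces)
    bleachFrames <- vector("list", nTraces)
    for (i in seq_len(nTraces)) {
      intensity <- numeric(nFrames)
      bf <- integer(nFluor[i])
      for (j in seq_len(nFluor[i])) {
        bf[j] <- stats::rgeom(1, bleachRatePerFrame) + 1L
        intensity <- intensity + stepAmplitude * (frames < bf[j])
      }
      if (noiseSd > 0)
        intensity <- intensity + stats::rnorm(nFrames, 0, noiseSd)
      traces[[i]] <- data.frame(trace_id = i, frame = frames,
                                time_s = frames * frameIntervalS,
                                intensity = intensity)
      bleachFrames[[i]] <- sort(bf)
    }
    list(traces = do.call(rbind, traces), trueSteps = nFluor,
         bleachFrames = bleachFrames)
  })
}

#' Simulate branch lifetimes with window censoring
#'
#' Lifetimes are drawn from the dwell model (or a point mass via
#' `list(fixed = )`); lifetimes exceeding the observation window are
#' right-censored at the window end.
#'
#' @param nBranches number of branches (>= 1).
#' @param lifetimeModel dwell list: `list(tau = )`,
#'   `list(tShort = , tLong = , fracLong = )`, or `list(fixed = )`.
#' @param observationWindowS observation window (s).
#' @param seed RNG seed.
#' @return data.frame `branch_id`, `lifetime_s`, `censored`.
#' @export
simulateDebranching <- function(nBranches, lifetimeModel,
                                observationWindowS, seed = 1) {
  stopIfNot(nBranches >= 1, "nBranches must be >= 1")
  withSeed(seed, {
    lt <- if (!is.null(lifetimeModel$fixed))
      rep(lifetimeModel$fixed, nBranches)
    else drawDwells(nBranches, lifetimeModel)
    cens <- lt > observationWindowS
    lt[cens] <- observationWindowS
    data.frame(branch_id = seq_len(nBranches), lifetime_s = lt,
               censored = cens)
  })
}

#' Simulate gel standard-curve and sample-band intensities
#'
#' Band intensity follows `b1 * c + b2 * c^2` scaled by multiplicative
#' Gaussian noise of coefficient of variation `noiseCv`; a zero
#' concentration always yields zero intensity (the curve is forced through
#' the origin). Intensities are clipped at zero.
#'
#' @param trueCoeffs numeric c(b1, b2) with b1 >= 0.
#' @param standardConcs concentrations of the standard lanes (>= 0).
#' @param sampleConcs true concentrations of the unknown lanes (>= 0).
#' @param noiseCv coefficient of variation of multiplicative noise.
#' @param seed RNG seed.
#' @return list with `standards` and `samples`, each a data.frame
#'   `conc`, `intensity`.
#' @export
simulateGelStandards <- function(trueCoeffs, standardConcs, sampleConcs,
                                 noiseCv = 0, seed = 1) {
  stopIfNot(trueCoeffs[1] >= 0, "b1 must be >= 0")
  stopIfNot(all(standardConcs >= 0) && all(sampleConcs >= 0),
            "concentrations must be >= 0")
  band <- function(c, noise) {
    y <- (trueCoeffs[1] * c + trueCoeffs[2] * c^2) * noise
    pmax(y, 0)
  }
  withSeed(seed, {
    nz1 <- 1 + stats::rnorm(length(standardConcs), 0, noiseCv)
    nz2 <- 1 + stats::rnorm(length(sampleConcs), 0, noiseCv)
    list(standards = data.frame(conc = standardConcs,
                                intensity = band(standardConcs, nz1)),
         samples = data.frame(conc = sampleConcs,
                              intensity = band(sampleConcs, nz2)))
  })
}

#' Simulate a stationary two-state (bound/unbound) site process
#'
#' Each site alternates between exponentially distributed bound and unbound
#' sojourns with stationary bound fraction (duty ratio)
#' `dutyRatio = meanBoundS / (meanBoundS + meanUnboundS)`. The process is
#' started in its stationary distribution. Bound intervals are emitted as
#' events for [quantizeToFrames()] and [occupancy()].
#'
#' @param nSites number of independent sites.
#' @param dutyRatio stationary bound fraction, in (0, 1).
#' @param meanBoundS mean bound sojourn (s).
#' @param durationS recording length (s).
#' @param seed RNG seed.
#' @return data.frame `site_id`, `t_start`, `duration` of bound intervals
#'   clipped to `[0, durationS)`.
#' @export
simulateOccupancyTrace <- function(nSites, dutyRatio, meanBoundS,
                                   durationS, seed = 1) {
  stopIfNot(dutyRatio > 0 && dutyRatio < 1, "dutyRatio must be in (0, 1)")
  meanUnboundS <- meanBoundS * (1 - dutyRatio) / dutyRatio
  out <- list()
  withSeed(seed, {
    for (s in seq_len(nSites)) {
      t <- 0
      bound <- stats::runif(1) < dutyRatio
      while (t < durationS) {
        if (bound) {
          d <- stats::rexp(1, 1 / meanBoundS)
          out[[length(out) + 1]] <- c(s, t, min(d, durationS - t))
          t <- t + d
        } else {
          t <- t + stats::rexp(1, 1 / meanUnboundS)
        }
        bound <- !bound
      }
    }
  })
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("site_id", "t_start", "duration")
  df
}
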