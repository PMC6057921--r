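# Independent oracles used across the suite. These re-derive expected
# values by brute force or closed form, independently of the package's
# fitting code paths.

# Dense grid-search maximizer of the phase-marginalized single-exponential
# (geometric) likelihood, written from the model definition.
gridSearchTau <- function(frameCounts, dt, censored = NULL,
                          tauRange = c(dt / 20, dt * 200), nGrid = 8000) {
  if (is.null(censored)) censored <- rep(FALSE, length(frameCounts))
  ll <- function(tau) {
    q <- exp(-dt / tau)
    sum(ifelse(censored,
               (frameCounts - 1) * log(q),
               log(1 - q) + (frameCounts - 1) * log(q)))
  }
  lo <- log(tauRange[1]); hi <- log(tauRange[2])
  for (stage in 1:3) {   # successive grid refinement around the maximum
    taus <- exp(seq(lo, hi, length.out = nGrid))
    lls <- vapply(taus, ll, numeric(1))
    i <- which.max(lls)
    step <- (hi - lo) / (nGrid - 1)
    lo <- log(taus[i]) - 2 * step
    hi <- log(taus[i]) + 2 * step
  }
  taus[i]
}

# Conditional-on-detection mixture likelihood of frame counts, written out
# from the sampling model (uniform phase + geometric given detection),
# evaluated on a grid. Returns the maximum log-likelihood found.
gridSearchMixLoglik <- function(frameCounts, dt, tsGrid, tlGrid, aGrid) {
  best <- -Inf
  for (ts in tsGrid) for (tl in tlGrid) for (a in aGrid) {
    if (tl <= ts) next
    qs <- exp(-dt / ts); ql <- exp(-dt / tl)
    ps <- ts / dt * (1 - qs); pl <- tl / dt * (1 - ql)
    wl <- a * pl / ((1 - a) * ps + a * pl)
    pk <- (1 - wl) * (1 - qs) * qs^(frameCounts - 1) +
      wl * (1 - ql) * ql^(frameCounts - 1)
    ll <- sum(log(pk))
    if (ll > best) best <- ll
  }
  best
}

# Brute-force frame-by-frame colocalization oracle: for one anchor,
# mark every frame with a detection within radius, then read off the
# maximal runs.
bruteForceColocRuns <- function(detections, ax, ay, radius) {
  frames <- sort(unique(detections$frame))
  hit <- vapply(frames, function(f) {
    d <- detections[detections$frame == f, ]
    any(sqrt((d$x_px - ax)^2 + (d$y_px - ay)^2) <= radius)
  }, logical(1))
  hf <- frames[hit]
  if (!length(hf)) return(data.frame(start = integer(0), len = integer(0)))
  st <- hf[c(TRUE, diff(hf) > 1)]
  en <- hf[c(diff(hf) > 1, TRUE)]
  data.frame(start = st, len = en - st + 1)
}

# Merged per-site occupancy runs of quantized ground-truth events:
# the observable truth a detector can recover when events at one site
# overlap in time.
mergedTruthRuns <- function(quantized) {
  out <- list()
  for (sid in unique(quantized$site_id)) {
    q <- quantized[quantized$site_id == sid, ]
    frames <- sort(unique(unlist(Map(function(s, n) s:(s + n - 1),
                                     q$start_frame, q$n_frames))))
    st <- frames[c(TRUE, diff(frames) > 1)]
    en <- frames[c(diff(frames) > 1, TRUE)]
    out[[length(out) + 1]] <- data.frame(site_id = sid, start_frame = st,
                                         n_frames = en - st + 1)
  }
  do.call(rbind, out)
}

# A clean sigmoid for pyrene normalization tests.
sigmoidCurve <- function(times, t50 = 300, slope = 60, lo = 5, hi = 25) {
  data.frame(time_s = times,
             value = lo + (hi - lo) / (1 + exp(-(times - t50) / slope)))
}
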