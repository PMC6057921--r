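## Minimal spot detection, greedy nearest-neighbour track linking,
## two-channel colocalization, and geometric event classification.
## Pixel coordinates are 0-based with pixel centres at integer coordinates;
## an image matrix element [y + 1, x + 1] holds pixel (x, y).

#' Detect fluorescent spots in a single frame
#'
#' Local maxima exceeding the robust background level (median) by
#' `thresholdSd` robust SDs (MAD) are accepted, brightest first, with no
#' two detections closer than `spotRadiusPx`; each is refined to a
#' sub-pixel centroid by the intensity-weighted mean of the
#' background-subtracted neighbourhood.
#'
#' @param frameImage numeric matrix (grayscale, one frame).
#' @param thresholdSd detection threshold in robust SDs above background.
#' @param spotRadiusPx neighbourhood radius (pixels) for exclusion and
#'   centroid refinement.
#' @return data.frame `x_px`, `y_px`, `intensity` (background-subtracted
#'   sum over the neighbourhood).
#' @export
detectSpots <- function(frameImage, thresholdSd = 5, spotRadiusPx = 3) {
  stopIfNot(is.matrix(frameImage) && length(frameImage) > 0,
            "frameImage must be a non-empty matrix")
  bg <- stats::median(frameImage)
  bgSd <- stats::mad(frameImage)
  thr <- bg + thresholdSd * bgSd
  h <- nrow(frameImage); w <- ncol(frameImage)
  cand <- which(frameImage > thr, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0)))
  ## keep 3x3 local maxima only
  isMax <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- frameImage[max(1, r - 1):min(h, r + 1),
                     max(1, c - 1):min(w, c + 1)]
    frameImage[r, c] >= max(nb)
  }, logical(1))
  cand <- cand[isMax, , drop = FALSE]
  ord <- order(frameImage[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  acc <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(acc) == 0 ||
        all((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2 >= spotRadiusPx^2))
      acc <- rbind(acc, p)
  }
  out <- lapply(seq_len(nrow(acc)), function(i) {
    r0 <- acc[i, 1]; c0 <- acc[i, 2]
    rs <- max(1, r0 - spotRadiusPx):min(h, r0 + spotRadiusPx)
    cs <- max(1, c0 - spotRadiusPx):min(w, c0 + spotRadiusPx)
    patch <- pmax(frameImage[rs, cs, drop = FALSE] - bg, 0)
    tot <- sum(patch)
    if (tot <= 0) return(NULL)
    yc <- sum((rs - 1) * rowSums(patch)) / tot
    xc <- sum((cs - 1) * colSums(patch)) / tot
    data.frame(x_px = xc, y_px = yc, intensity = tot)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(x_px = numeric(0), y_px = numeric(0),
                               intensity = numeric(0)) else out
}

#' Detect spots in every frame of a stack
#'
#' @param stack array height x width x frames.
#' @inheritParams detectSpots
#' @return data.frame with `frame` (0-based), `x_px`, `y_px`, `intensity`.
#' @export
detectSpotsStack <- function(stack, thresholdSd = 5, spotRadiusPx = 3) {
  out <- lapply(seq_len(dim(stack)[3]), function(f) {
    d <- detectSpots(stack[, , f], thresholdSd, spotRadiusPx)
    if (nrow(d)) cbind(frame = f - 1L, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
               intensity = numeric(0))
  else out
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour linking frame to frame: at each frame, open
#' tracks claim the closest detection within `linkRadiusPx`, smallest
#' distance first (ties broken by lowest spot index); unclaimed detections
#' start new tracks; a track closes after `maxGapFrames` consecutive
#' frames without a match. Greedy linking is adequate for the sparse
#' fields simulated here; it is not a global assignment.
#'
#' @param detections data.frame `frame`, `x_px`, `y_px` (sorted by frame).
#' @param linkRadiusPx maximum inter-frame displacement (pixels).
#' @param maxGapFrames tolerated consecutive missed frames (default 0).
#' @return list of data.frames, one per track, each with the detection
#'   rows of that track in frame order.
#' @export
linkTracks <- function(detections, linkRadiusPx, maxGapFrames = 0) {
  if (nrow(detections) == 0) return(list())
  detections <- detections[order(detections$frame), , drop = FALSE]
  tracks <- list()        # closed tracks
  open <- list()          # each: list(rows = df, lastFrame)
  for (f in sort(unique(detections$frame))) {
    det <- detections[detections$frame == f, , drop = FALSE]
    ## close stale tracks
    if (length(open)) {
      stale <- vapply(open, function(tr) f - tr$lastFrame > maxGapFrames + 1,
                      logical(1))
      tracks <- c(tracks, lapply(open[stale], `[[`, "rows"))
      open <- open[!stale]
    }
    assignedDet <- rep(FALSE, nrow(det))
    assignedTr <- rep(FALSE, length(open))
    if (length(open) && nrow(det)) {
      dmat <- outer(seq_along(open), seq_len(nrow(det)),
                    Vectorize(function(i, j) {
                      last <- open[[i]]$rows[nrow(open[[i]]$rows), ]
                      sqrt((last$x_px - det$x_px[j])^2 +
                           (last$y_px - det$y_px[j])^2)
                    }))
      repeat {
        dmat2 <- dmat
        dmat2[assignedTr, ] <- Inf
        dmat2[, assignedDet] <- Inf
        if (all(!is.finite(dmat2)) || min(dmat2) > linkRadiusPx) break
        idx <- which(dmat2 == min(dmat2), arr.ind = TRUE)
        ## ties: lowest spot index, then lowest track index
        idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE][1, ]
        open[[idx[1]]]$rows <- rbind(open[[idx[1]]]$rows, det[idx[2], ])
        open[[idx[1]]]$lastFrame <- f
        assignedTr[idx[1]] <- TRUE
        assignedDet[idx[2]] <- TRUE
      }
    }
    for (j in which(!assignedDet))
      open[[length(open) + 1]] <- list(rows = det[j, , drop = FALSE],
                                       lastFrame = f)
  }
  tracks <- c(tracks, lapply(open, `[[`, "rows"))
  lapply(tracks, function(tr) { rownames(tr) <- NULL; tr })
}

#' Colocalization events between tracks and anchored partners
#'
#' An event is a maximal run of consecutive frames in which a track
#' centroid lies within `colocRadiusPx` of an anchor; its dwell is the run
#' length times the acquisition interval. Runs still in contact at the
#' final recorded frame are flagged right-censored.
#'
#' @param tracks list of track data.frames (from [linkTracks()]).
#' @param anchors data.frame `anchor_id`, `x_px`, `y_px` of static partner
#'   positions.
#' @param colocRadiusPx spatial overlap radius (pixels; default 1, the
#'   package's convention for "overlapping" centroids).
#' @param frameIntervalS acquisition interval dt (s).
#' @param nFrames total frames in the recording (for end censoring), or
#'   NULL to infer from the data.
#' @return data.frame `event_id`, `anchor_id`, `start_frame`, `n_frames`,
#'   `dwell_s`, `censored`.
#' @export
colocalize <- function(tracks, anchors, colocRadiusPx = 1,
                       frameIntervalS = 1, nFrames = NULL) {
  allDet <- do.call(rbind, tracks)
  if (is.null(allDet) || nrow(allDet) == 0)
    return(data.frame(event_id = integer(0), anchor_id = integer(0),
                      start_frame = integer(0), n_frames = integer(0),
                      dwell_s = numeric(0), censored = logical(0)))
  lastFrame <- if (is.null(nFrames)) max(allDet$frame) else nFrames - 1
  out <- list()
  for (i in seq_len(nrow(anchors))) {
    d <- sqrt((allDet$x_px - anchors$x_px[i])^2 +
              (allDet$y_px - anchors$y_px[i])^2)
    frames <- sort(unique(allDet$frame[d <= colocRadiusPx]))
    if (!length(frames)) next
    runStart <- frames[c(TRUE, diff(frames) > 1)]
    runEnd <- frames[c(diff(frames) > 1, TRUE)]
    out[[length(out) + 1]] <- data.frame(
      anchor_id = anchors$anchor_id[i],
      start_frame = as.integer(runStart),
      n_frames = as.integer(runEnd - runStart + 1),
      censored = runEnd == lastFrame)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    return(data.frame(event_id = integer(0), anchor_id = integer(0),
                      start_frame = integer(0), n_frames = integer(0),
                      dwell_s = numeric(0), censored = logical(0)))
  ev$dwell_s <- ev$n_frames * frameIntervalS
  ev <- cbind(event_id = seq_len(nrow(ev)),
              ev[, c("anchor_id", "start_frame", "n_frames", "dwell_s",
                     "censored")])
  rownames(ev) <- NULL
  ev
}

#' Classify event locations against a site map
#'
#' An event inside the square detection box (area `boxAreaUm2`, default
#' 1.14 um^2) centred on a branch junction is `branch`; otherwise, within
#' half a box side of a filament polyline it is `side`; otherwise
#' `background`. Branch boxes take priority where boxes overlap, so every
#' event receives exactly one class.
#'
#' @param x,y event coordinates (um).
#' @param siteMap a [SiteMap-class].
#' @param boxAreaUm2 detection box area (um^2).
#' @param branchPriority if TRUE (default) branch boxes win over filament
#'   proximity.
#' @return character vector of site classes.
#' @export
classifyLocation <- function(x, y, siteMap, boxAreaUm2 = 1.14,
                             branchPriority = TRUE) {
  half <- sqrt(boxAreaUm2) / 2
  cls <- rep("background", length(x))
  if (length(siteMap@filaments)) {
    d <- rep(Inf, length(x))
    for (f in siteMap@filaments) d <- pmin(d, distToPolyline(x, y, f))
    cls[d <= half] <- "side"
  }
  if (nBranches(siteMap) > 0) {
    inBranch <- rep(FALSE, length(x))
    for (i in seq_len(nBranches(siteMap))) {
      b <- siteMap@branches[i, ]
      inBranch <- inBranch | (abs(x - b[1]) <= half & abs(y - b[2]) <= half)
    }
    if (branchPriority) cls[inBranch] <- "branch"
    else cls[inBranch & cls == "background"] <- "branch"
  }
  cls
}

#' Background-subtracted intensity along a filament
#'
#' Integrates image intensity over a band `widthPx` pixels wide along the
#' polyline, subtracts an equal band displaced `offsetPx` pixels along the
#' perpendicular, and optionally normalizes by filament length.
#'
#' @param image numeric matrix.
#' @param polylinePx n x 2 matrix of polyline vertices in pixels.
#' @param widthPx band width in pixels (default 3).
#' @param offsetPx perpendicular displacement of the background band.
#' @param perPosition if TRUE also return the per-position profile.
#' @return list with `total` (background-subtracted integral),
#'   `perLength` (total / polyline length in px), and, when requested,
#'   `profile` (per-position net intensity) and `position` (px along the
#'   filament).
#' @export
filamentIntensityProfile <- function(image, polylinePx, widthPx = 3,
                                     offsetPx = 5, perPosition = FALSE) {
  h <- nrow(image); w <- ncol(image)
  if (any(polylinePx[, 1] < 0 | polylinePx[, 1] > w - 1 |
          polylinePx[, 2] < 0 | polylinePx[, 2] > h - 1))
    stop("polyline falls outside the image")
  interp <- function(x, y) {
    x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
    x0 <- floor(x); y0 <- floor(y)
    x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
    fx <- x - x0; fy <- y - y0
    image[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
      image[cbind(y0 + 1, x1 + 1)] * fx * (1 - fy) +
      image[cbind(y1 + 1, x0 + 1)] * (1 - fx) * fy +
      image[cbind(y1 + 1, x1 + 1)] * fx * fy
  }
  ## sample the polyline at ~1 px spacing
  pts <- list(); nrm <- list()
  for (i in seq_len(nrow(polylinePx) - 1)) {
    p <- polylinePx[i, ]; q <- polylinePx[i + 1, ]
    len <- sqrt(sum((q - p)^2))
    nSamp <- max(2, ceiling(len))
    tt <- seq(0, 1, length.out = nSamp)
    if (i > 1) tt <- tt[-1]
    seg <- cbind(p[1] + tt * (q[1] - p[1]), p[2] + tt * (q[2] - p[2]))
    u <- (q - p) / len
    pts[[i]] <- seg
    nrm[[i]] <- matrix(rep(c(-u[2], u[1]), each = nrow(seg)), ncol = 2)
  }
  pts <- do.call(rbind, pts); nrm <- do.call(rbind, nrm)
  offs <- seq(-(widthPx - 1) / 2, (widthPx - 1) / 2, by = 1)
  onBand <- rowSums(vapply(offs, function(o)
    interp(pts[, 1] + o * nrm[, 1], pts[, 2] + o * nrm[, 2]),
    numeric(nrow(pts))))
  offBand <- rowSums(vapply(offs + offsetPx, function(o)
    interp(pts[, 1] + o * nrm[, 1], pts[, 2] + o * nrm[, 2]),
    numeric(nrow(pts))))
  net <- onBand - offBand
  lenPx <- sum(sqrt(rowSums(diff(polylinePx)^2)))
  res <- list(total = sum(net), perLength = sum(net) / lenPx)
  if (perPosition) {
    res$profile <- net
    res$position <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  }
  res
}
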