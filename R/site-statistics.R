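## Binding-frequency and occupancy statistics per site class.

#' Binding frequency per detection box
#'
#' For each detection box, the frequency is the number of event starts
#' inside the box divided by the time the box was available, i.e. the
#' total observation time minus the union of intervals during which the
#' box was occupied by any detected event. Boxes whose available time is
#' not positive are excluded with a warning.
#'
#' @param events data.frame with event positions `x_um`, `y_um`, start
#'   times (`t_start` in seconds, or `start_frame` with `frameIntervalS`)
#'   and durations (`duration` or `dwell_s`).
#' @param boxes data.frame `box_id`, `x_um`, `y_um` of box centres.
#' @param totalTimeS total observation time (s).
#' @param boxAreaUm2 box area (um^2, default 1.14).
#' @param frameIntervalS frame interval, needed when times come as frames.
#' @return list with `perBox` (data.frame `box_id`, `nStarts`,
#'   `availableS`, `frequency`), `mean` and `sd` of the per-box
#'   frequencies, and `nBoxes`.
#' @export
bindingFrequency <- function(events, boxes, totalTimeS, boxAreaUm2 = 1.14,
                             frameIntervalS = NULL) {
  stopIfNot(nrow(boxes) >= 1, "boxes must be non-empty")
  stopIfNot(totalTimeS > 0, "totalTimeS must be > 0")
  half <- sqrt(boxAreaUm2) / 2
  tStart <- if ("t_start" %in% names(events)) events$t_start
            else events$start_frame * frameIntervalS
  dur <- if ("duration" %in% names(events)) events$duration
         else events$dwell_s
  per <- lapply(seq_len(nrow(boxes)), function(i) {
    inBox <- abs(events$x_um - boxes$x_um[i]) <= half &
             abs(events$y_um - boxes$y_um[i]) <= half
    ts <- tStart[inBox]; de <- pmin(ts + dur[inBox], totalTimeS)
    occupied <- 0
    if (length(ts)) {
      o <- order(ts); ts <- ts[o]; de <- de[o]
      curS <- ts[1]; curE <- de[1]
      for (j in seq_along(ts)[-1]) {
        if (ts[j] <= curE) curE <- max(curE, de[j])
        else { occupied <- occupied + (curE - curS); curS <- ts[j]; curE <- de[j] }
      }
      occupied <- occupied + (curE - curS)
    }
    avail <- totalTimeS - occupied
    data.frame(box_id = boxes$box_id[i], nStarts = sum(inBox),
               availableS = avail,
               frequency = if (avail > 0) sum(inBox) / avail else NA_real_)
  })
  per <- do.call(rbind, per)
  bad <- !is.finite(per$frequency)
  if (any(bad)) {
    warning(sprintf("%d box(es) with no available time excluded", sum(bad)))
    per <- per[!bad, , drop = FALSE]
  }
  list(perBox = per, mean = mean(per$frequency), sd = stats::sd(per$frequency),
       nBoxes = nrow(per))
}

#' Count candidate binding sites of a class
#'
#' Filament-side sites are counted at a linear density (370 sites per um
#' of F-actin by default); each branch junction counts as one site.
#'
#' @param siteMap a [SiteMap-class].
#' @param siteClass `"side"` or `"branch"`.
#' @param densityPerUm side-site linear density (sites/um).
#' @return integer site count.
#' @examples
#' sm <- SiteMap(filaments = list(cbind(c(0, 1), c(0, 0))))
#' countSites(sm, "side")   # 370
#' @export
countSites <- function(siteMap, siteClass = c("side", "branch"),
                       densityPerUm = 370) {
  siteClass <- match.arg(siteClass)
  if (siteClass == "side") as.integer(round(filamentLength(siteMap) *
                                            densityPerUm))
  else nBranches(siteMap)
}

#' Time-averaged binding-site occupancy
#'
#' Occupancy is the total bound time summed over events divided by
#' `nSites * observationS`, clipped at 1. Bound time per event is
#' `n_frames * frameIntervalS` (or `dwell_s`/`duration` when present).
#' The estimate refers to labeled molecules; an optional scaling by
#' `1 / labeledFraction` is available but off by default.
#'
#' @param events data.frame of detected events.
#' @param nSites number of candidate sites (>= 1).
#' @param observationS observation time (s).
#' @param frameIntervalS frame interval (s), used with `n_frames`.
#' @param labeledFraction if supplied (in (0, 1]), occupancy is scaled by
#'   its reciprocal to estimate total (labeled + unlabeled) occupancy.
#' @return list with `occupancy` (fraction), `boundTimeS`, `nSites`,
#'   `observationS`.
#' @export
occupancy <- function(events, nSites, observationS, frameIntervalS = NULL,
                      labeledFraction = NULL) {
  stopIfNot(nSites >= 1, "nSites must be >= 1")
  stopIfNot(observationS > 0, "observationS must be > 0")
  bound <- if (nrow(events) == 0) 0
    else if ("n_frames" %in% names(events) && !is.null(frameIntervalS))
      sum(events$n_frames * frameIntervalS)
    else if ("dwell_s" %in% names(events)) sum(events$dwell_s)
    else sum(events$duration)
  occ <- bound / (nSites * observationS)
  if (!is.null(labeledFraction)) occ <- occ / labeledFraction
  list(occupancy = min(occ, 1), boundTimeS = bound, nSites = nSites,
       observationS = observationS)
}

#' Fold difference between two occupancies
#'
#' Given per-trial occupancy values for two site classes, returns the
#' per-trial ratios and their mean and SD; with scalar inputs, the plain
#' ratio.
#'
#' @param occA,occB numeric vectors of (per-trial) occupancies, or the
#'   lists returned by [occupancy()].
#' @return list with `ratio` (mean of per-trial ratios), `sd`,
#'   `perTrial`.
#' @export
occupancyRatio <- function(occA, occB) {
  a <- if (is.list(occA)) occA$occupancy else occA
  b <- if (is.list(occB)) occB$occupancy else occB
  bad <- b == 0
  if (all(bad)) stop("denominator occupancy is zero; ratio undefined")
  if (any(bad)) warning(sprintf("%d trial(s) with zero denominator dropped",
                                sum(bad)))
  r <- a[!bad] / b[!bad]
  list(ratio = mean(r), sd = if (length(r) > 1) stats::sd(r) else NA_real_,
       perTrial = r)
}
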