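## Branch nucleation curves, debranching survival, elongation rates,
## and pyrene-curve normalization.

#' Cumulative branch nucleation curves
#'
#' Counts, per field of view, the branches that have appeared by each
#' evaluation time, and averages across FOVs with the standard error of
#' the mean.
#'
#' @param appearances data.frame with `appearance_time_s` and `fov`
#'   (FOV/trial identifier).
#' @param times evaluation time grid (s).
#' @param fovAreaUm2 FOV area (um^2), recorded alongside the curve
#'   (default 18000).
#' @return list with `times`, `perFov` (matrix times x FOVs), `mean`,
#'   `sem`, `fovAreaUm2`.
#' @export
cumulativeBranching <- function(appearances, times, fovAreaUm2 = 18000) {
  fovs <- if (nrow(appearances)) sort(unique(appearances$fov)) else "fov1"
  perFov <- vapply(fovs, function(f) {
    at <- appearances$appearance_time_s[appearances$fov == f]
    vapply(times, function(t) sum(at <= t), numeric(1))
  }, numeric(length(times)))
  perFov <- matrix(perFov, nrow = length(times),
                   dimnames = list(NULL, fovs))
  list(times = times, perFov = perFov, mean = rowMeans(perFov),
       sem = apply(perFov, 1, stats::sd) / sqrt(ncol(perFov)),
       fovAreaUm2 = fovAreaUm2)
}

#' Cumulative branch survival curves
#'
#' Per trial, S(t) is the fraction of initially present branches
#' persisting beyond t; right-censored branches (still present at the end
#' of the observation window) survive through the window. The condition
#' curve is the mean across trials with SEM. On uncensored data the
#' per-trial curve equals 1 minus the empirical CDF of lifetimes.
#'
#' @param branches data.frame with `lifetime_s`, `censored`, and
#'   optionally `trial`.
#' @param times evaluation time grid (s).
#' @return list with `times`, `perTrial` (matrix times x trials), `mean`,
#'   `sem`.
#' @export
branchSurvival <- function(branches, times) {
  stopIfNot(nrow(branches) >= 1, "need at least one branch")
  if (!"trial" %in% names(branches)) branches$trial <- 1
  trials <- sort(unique(branches$trial))
  perTrial <- vapply(trials, function(tr) {
    b <- branches[branches$trial == tr, ]
    vapply(times, function(t)
      mean(ifelse(b$censored, b$lifetime_s >= t, b$lifetime_s > t)),
      numeric(1))
  }, numeric(length(times)))
  perTrial <- matrix(perTrial, nrow = length(times),
                     dimnames = list(NULL, trials))
  list(times = times, perTrial = perTrial, mean = rowMeans(perTrial),
       sem = apply(perTrial, 1, stats::sd) / sqrt(ncol(perTrial)))
}

#' Filament elongation rate by linear fit
#'
#' Ordinary least-squares slope of filament length over time, optionally
#' converted to subunits/s at 370 subunits per um.
#'
#' @param lengths data.frame with `time_s` and `length_um` (>= 3 rows).
#' @param subunitsPerUm conversion constant (monomers per um of F-actin).
#' @return list with `rate` (um/s), `intercept`, `r2`, `subunitsPerS`.
#' @examples
#' elongationRate(data.frame(time_s = c(0, 10, 20),
#'                           length_um = c(0, 1, 2)))$rate   # 0.1
#' @export
elongationRate <- function(lengths, subunitsPerUm = 370) {
  stopIfNot(nrow(lengths) >= 3, "need at least 3 time points")
  fit <- stats::lm(length_um ~ time_s, data = lengths)
  rate <- unname(stats::coef(fit)[2])
  tss <- sum((lengths$length_um - mean(lengths$length_um))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  list(rate = rate, intercept = unname(stats::coef(fit)[1]),
       r2 = r2, subunitsPerS = rate * subunitsPerUm)
}

#' Normalize pyrene assembly curves to [0, 1]
#'
#' Each curve is shifted so its baseline (minimum) is 0. Curves that
#' reach a plateau — final-window least-squares slope below
#' `slopeFracPer100s` of the curve's range per 100 s — are scaled so the
#' plateau is 1. Curves that do not plateau are scaled by the mean
#' baseline-to-plateau span of the curves that did, so their final values
#' stay below 1 in proportion to how far they got.
#'
#' @param curves named list of data.frames, each with `time_s` and
#'   `value`.
#' @param plateauWindowFrac fraction of final points used for plateau
#'   detection (default 0.1).
#' @param slopeFracPer100s plateau slope threshold, as a fraction of the
#'   curve range per 100 s (default 0.01).
#' @return named list of data.frames with normalized `value`; attribute
#'   `plateaued` records which curves reached plateau.
#' @export
normalizePyrene <- function(curves, plateauWindowFrac = 0.1,
                            slopeFracPer100s = 0.01) {
  stopIfNot(length(curves) >= 1, "need at least one curve")
  info <- lapply(curves, function(cv) {
    nW <- max(3, ceiling(nrow(cv) * plateauWindowFrac))
    tail <- cv[(nrow(cv) - nW + 1):nrow(cv), ]
    slope <- unname(stats::coef(stats::lm(value ~ time_s, data = tail))[2])
    rng <- diff(range(cv$value))
    list(base = min(cv$value),
         plateau = mean(tail$value),
         plateaued = rng > 0 && abs(slope) < slopeFracPer100s * rng / 100)
  })
  plateaued <- vapply(info, `[[`, logical(1), "plateaued")
  if (!any(plateaued))
    stop(paste("no curve reaches a plateau; the shared-plateau fallback",
               "for truncated curves is inapplicable"))
  meanSpan <- mean(vapply(info[plateaued], function(x)
    x$plateau - x$base, numeric(1)))
  out <- Map(function(cv, inf) {
    span <- if (inf$plateaued) inf$plateau - inf$base else meanSpan
    cv$value <- (cv$value - inf$base) / span
    cv
  }, curves, info)
  attr(out, "plateaued") <- plateaued
  out
}
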