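## Gel densitometry: standard curves forced through the origin,
## concentration inference, and molar-ratio estimation.

#' Fit a second-order standard curve forced through zero
#'
#' Least squares of `intensity = b1 * c + b2 * c^2` with no intercept,
#' the standard calibration for stain-free gel band quantification.
#'
#' @param concs known concentrations (>= 3 distinct values).
#' @param intensities integrated band intensities.
#' @param species species label carried on the result.
#' @return A [StandardCurve-class].
#' @examples
#' cv <- fitStandardCurve(1:4, 2 * (1:4) + (1:4)^2)
#' c(cv@b1, cv@b2)   # 2 1
#' @export
fitStandardCurve <- function(concs, intensities, species = "") {
  stopIfNot(length(unique(concs)) >= 3,
            "need at least 3 distinct concentrations")
  X <- cbind(concs, concs^2)
  if (qr(X)$rank < 2) stop("rank-deficient design; cannot fit b1 and b2")
  fit <- stats::lm.fit(X, intensities)
  new("StandardCurve", species = species,
      b1 = unname(fit$coefficients[1]), b2 = unname(fit$coefficients[2]),
      residual = sqrt(sum(fit$residuals^2) / max(1, length(concs) - 2)),
      concRange = range(concs))
}

#' Evaluate a standard curve
#'
#' @param curve a [StandardCurve-class].
#' @param conc concentrations.
#' @return predicted intensities `b1 * c + b2 * c^2`.
#' @export
predictIntensity <- function(curve, conc) {
  curve@b1 * conc + curve@b2 * conc^2
}

#' Invert a standard curve to a concentration
#'
#' Returns the unique nonnegative root of `b2 c^2 + b1 c - y = 0` by the
#' quadratic formula, with a linear fallback when `|b2|` is negligible.
#'
#' @param netIntensity background-subtracted band intensity (>= 0).
#' @param curve a [StandardCurve-class].
#' @return inferred concentration(s).
#' @examples
#' cv <- fitStandardCurve(1:4, 2 * (1:4) + (1:4)^2)
#' inferConcentration(3, cv)   # 1
#' @export
inferConcentration <- function(netIntensity, curve) {
  stopIfNot(all(netIntensity >= 0), "net intensity must be >= 0")
  b1 <- curve@b1; b2 <- curve@b2
  if (abs(b2) < 1e-12 * max(abs(b1), 1)) return(netIntensity / b1)
  disc <- b1^2 + 4 * b2 * netIntensity
  if (any(disc < 0)) stop("no nonnegative root; pathological coefficients")
  c1 <- (-b1 + sqrt(disc)) / (2 * b2)
  if (any(c1 < -1e-9)) stop("no nonnegative root; pathological coefficients")
  pmax(c1, 0)
}

#' Background-subtract a band intensity
#'
#' Net intensity is raw minus background (from an adjacent empty lane);
#' negative values are clipped to zero with a warning.
#'
#' @param raw raw integrated intensity.
#' @param background background intensity.
#' @return net intensity (>= 0).
#' @export
netIntensity <- function(raw, background) {
  net <- raw - background
  if (any(net < 0)) {
    warning("negative net intensity clipped to 0")
    net <- pmax(net, 0)
  }
  net
}

#' Molar ratio of two species across replicates
#'
#' Per replicate, the ratio of inferred concentrations `cA / cB`;
#' replicates with a zero denominator are flagged and excluded from the
#' summary.
#'
#' @param concA,concB concentration vectors (one entry per replicate).
#' @return list with `ratio` (mean), `sd`, `perReplicate`, `excluded`.
#' @examples
#' molarRatio(c(2.1, 1.9, 2.0), c(1, 1, 1))$ratio
#' @export
molarRatio <- function(concA, concB) {
  stopIfNot(length(concA) == length(concB) && length(concA) >= 1,
            "need paired replicate concentrations")
  bad <- concB == 0
  if (all(bad)) stop("all replicates have zero denominator")
  if (any(bad)) warning(sprintf("%d replicate(s) with zero denominator excluded",
                                sum(bad)))
  r <- concA[!bad] / concB[!bad]
  list(ratio = mean(r), sd = if (length(r) > 1) stats::sd(r) else NA_real_,
       perReplicate = r, excluded = which(bad))
}
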