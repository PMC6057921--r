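## Internal helpers shared across modules.

## Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
## All stochastic entry points funnel through this so that a (seed, inputs)
## pair fully determines the output and never perturbs global randomness.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Draw n dwell durations from a KineticModel dwell spec (list with tau or
## tShort/tLong/fracLong). Uses the current RNG stream.
drawDwells <- function(n, dwell) {
  if (!is.null(dwell$tau)) {
    stats::rexp(n, rate = 1 / dwell$tau)
  } else {
    long <- stats::runif(n) < dwell$fracLong
    ifelse(long,
           stats::rexp(n, rate = 1 / dwell$tLong),
           stats::rexp(n, rate = 1 / dwell$tShort))
  }
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## Squared distance from points (x, y) to a polyline (n x 2 matrix).
distToPolyline <- function(x, y, poly) {
  d2 <- rep(Inf, length(x))
  for (i in seq_len(nrow(poly) - 1)) {
    p <- poly[i, ]; q <- poly[i + 1, ]
    vx <- q[1] - p[1]; vy <- q[2] - p[2]
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - p[1]) * vx + (y - p[2]) * vy) / len2))
    dx <- x - (p[1] + t * vx); dy <- y - (p[2] + t * vy)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}
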