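## Dwell-time survival analysis and censored exponential-mixture MLE.
##
## The observation process: a molecule binding at a uniformly random phase
## relative to the frame clock and dwelling Exp(tau) is seen in
## K = floor((d - u)/dt) + 1 frames given detection (d > u). By
## memorylessness K | detected is geometric with success 1 - q,
## q = exp(-dt/tau), and the unconditional detection probability is
## p(tau) = (tau/dt) * (1 - q). The phase-marginalized estimators below
## maximize these discrete likelihoods; the naive estimators treat k * dt
## as a continuous exponential observation.

#' Empirical cumulative survival curve of a dwell sample
#'
#' S(t) is the fraction of events with dwell >= t, evaluated on the frame
#' grid 0, dt, 2 dt, ... one step past the longest observed dwell. With
#' right-censored events the product-limit (Kaplan-Meier) estimator is
#' used; censored events contribute to the risk set up to their censoring
#' time. Without censoring the curve equals 1 minus the empirical CDF
#' (with the >= convention) exactly.
#'
#' @param sample a [DwellSample-class].
#' @return A [SurvivalCurve-class].
#' @examples
#' s <- DwellSample(c(2, 2), frameIntervalS = 1)
#' curveSurvival(survivalCurve(s))   # 1 1 1 0
#' @export
survivalCurve <- function(sample) {
  validObject(sample)
  dt <- sample@frameIntervalS
  t <- dwellTimes(sample)
  cens <- sample@censored
  grid <- seq(0, (max(sample@frameCounts) + 1) * dt, by = dt)
  deathTimes <- sort(unique(t[!cens]))
  surv <- numeric(length(grid))
  for (i in seq_along(grid)) {
    g <- grid[i]
    s <- 1
    for (tj in deathTimes) {
      if (tj >= g - 1e-12) break
      nRisk <- sum(t >= tj - 1e-12)
      dj <- sum(!cens & abs(t - tj) < 1e-12)
      s <- s * (1 - dj / nRisk)
    }
    surv[i] <- s
  }
  new("SurvivalCurve", times = grid, survival = surv)
}

## Tabulate a sample into unique frame counts with weights, split by
## censoring status. All likelihoods work on this compressed form.
tabulateSample <- function(frameCounts, censored) {
  ku <- frameCounts[!censored]; kc <- frameCounts[censored]
  tu <- if (length(ku)) table(ku) else NULL
  tc <- if (length(kc)) table(kc) else NULL
  list(ku = as.integer(names(tu)), wu = as.numeric(tu),
       kc = as.integer(names(tc)), wc = as.numeric(tc),
       nUnc = length(ku), nCens = length(kc))
}

## Single-exponential log-likelihoods on tabulated data.
loglik1Geom <- function(tau, tab, dt) {
  q <- exp(-dt / tau)
  ll <- 0
  if (tab$nUnc)
    ll <- ll + sum(tab$wu * (log1p(-q) + (tab$ku - 1) * log(q)))
  if (tab$nCens)
    ll <- ll + sum(tab$wc * (tab$kc - 1) * log(q))
  ll
}

loglik1Cont <- function(tau, tab, dt) {
  ll <- 0
  if (tab$nUnc)
    ll <- ll + sum(tab$wu * (-log(tau) - tab$ku * dt / tau))
  if (tab$nCens)
    ll <- ll + sum(tab$wc * (-tab$kc * dt / tau))
  ll
}

#' Maximum-likelihood single-exponential dwell fit
#'
#' The `phase_marginalized` estimator (default) maximizes the discrete
#' likelihood of the observed frame counts obtained by marginalizing a
#' uniform binding phase and conditioning on detection; for a single
#' exponential this is geometric, giving the closed form
#' `tau = dt / log(kbar / (kbar - 1))` on uncensored data. The `naive`
#' estimator maximizes the continuous exponential likelihood of
#' `k * dt` (closed form: the mean), which overestimates `tau` when dwells
#' are comparable to the frame interval. Right-censored events enter both
#' likelihoods as survival terms (or are dropped with
#' `censoring = "drop"`).
#'
#' @param sample a [DwellSample-class] with n >= 2.
#' @param estimator `"phase_marginalized"` or `"naive"`.
#' @param censoring `"survival"` (default) or `"drop"`.
#' @return An [ExpFit-class].
#' @examples
#' s <- DwellSample(c(1, 1, 2, 3), frameIntervalS = 0.25)
#' fitExponential(s)                      # 0.25 / log(1.75 / 0.75)
#' fitExponential(DwellSample(c(1, 2, 3), 1), estimator = "naive")  # tau = 2
#' @export
fitExponential <- function(sample,
                           estimator = c("phase_marginalized", "naive"),
                           censoring = c("survival", "drop")) {
  estimator <- match.arg(estimator)
  censoring <- match.arg(censoring)
  validObject(sample)
  stopIfNot(nEvents(sample) >= 2, "need at least 2 events")
  k <- sample@frameCounts; cens <- sample@censored
  if (censoring == "drop") { k <- k[!cens]; cens <- rep(FALSE, length(k)) }
  dt <- sample@frameIntervalS
  tab <- tabulateSample(k, cens)
  if (estimator == "naive") {
    stopIfNot(tab$nUnc >= 1, "all events censored; naive fit undefined")
    tau <- sum(k) * dt / tab$nUnc
    ll <- loglik1Cont(tau, tab, dt)
  } else {
    S <- sum(k - 1)
    if (S == 0) {
      warning("all dwells are single-frame; tau at its lower bound")
      tau <- dt / log(4 * length(k) + 4)
    } else {
      q <- S / (tab$nUnc + S)
      tau <- -dt / log(q)
    }
    ll <- loglik1Geom(tau, tab, dt)
  }
  new("ExpFit", tau = tau, loglik = ll, seTau = NA_real_,
      estimator = estimator, n = length(k))
}

## Two-exponential mixture log-likelihoods on tabulated data.
## theta = c(log tShort, log tLong, logit fracLong); a is the latent
## (continuous-time) mixture weight. Conditioning on detection re-weights
## the components by their detection probabilities p(tau).
loglik2Geom <- function(theta, tab, dt) {
  ts <- exp(theta[1]); tl <- exp(theta[2])
  a <- stats::plogis(theta[3])
  qs <- exp(-dt / ts); ql <- exp(-dt / tl)
  ps <- ts / dt * (1 - qs); pl <- tl / dt * (1 - ql)
  wl <- a * pl / ((1 - a) * ps + a * pl)
  ws <- 1 - wl
  ll <- 0
  if (tab$nUnc) {
    pk <- ws * (1 - qs) * qs^(tab$ku - 1) + wl * (1 - ql) * ql^(tab$ku - 1)
    ll <- ll + sum(tab$wu * log(pmax(pk, 1e-300)))
  }
  if (tab$nCens) {
    sk <- ws * qs^(tab$kc - 1) + wl * ql^(tab$kc - 1)
    ll <- ll + sum(tab$wc * log(pmax(sk, 1e-300)))
  }
  ll
}

loglik2Cont <- function(theta, tab, dt) {
  ts <- exp(theta[1]); tl <- exp(theta[2])
  a <- stats::plogis(theta[3])
  ll <- 0
  if (tab$nUnc) {
    t <- tab$ku * dt
    f <- (1 - a) / ts * exp(-t / ts) + a / tl * exp(-t / tl)
    ll <- ll + sum(tab$wu * log(pmax(f, 1e-300)))
  }
  if (tab$nCens) {
    t <- tab$kc * dt
    s <- (1 - a) * exp(-t / ts) + a * exp(-t / tl)
    ll <- ll + sum(tab$wc * log(pmax(s, 1e-300)))
  }
  ll
}

#' Maximum-likelihood two-exponential mixture dwell fit
#'
#' Fits the mixture `(1 - a) Exp(tShort) + a Exp(tLong)` to frame-quantized
#' dwells by bounded quasi-Newton optimization of log-transformed component
#' means and logit-transformed weight, with multi-start initialization
#' (single-exponential solution, quantile split, and jittered variants).
#' Under `estimator = "phase_marginalized"` the likelihood marginalizes the
#' binding phase and conditions on detection, so `fracLong` estimates the
#' latent continuous-time mixture weight (the weight before short events
#' are lost to detection censoring). Canonical ordering `tShort < tLong` is
#' enforced on output. The maximized log-likelihood is never below the
#' nested single-exponential fit's.
#'
#' @param sample a [DwellSample-class] with n >= 10.
#' @param estimator `"phase_marginalized"` or `"naive"`.
#' @param nStarts number of optimizer starts.
#' @param init optional [Exp2Fit-class] supplying an extra start (used to
#'   speed up bootstrap refits).
#' @param censoring `"survival"` or `"drop"`.
#' @return An [Exp2Fit-class].
#' @export
fitTwoExponential <- function(sample,
                              estimator = c("phase_marginalized", "naive"),
                              nStarts = 10, init = NULL,
                              censoring = c("survival", "drop")) {
  estimator <- match.arg(estimator)
  censoring <- match.arg(censoring)
  validObject(sample)
  stopIfNot(nEvents(sample) >= 10, "need at least 10 events")
  k <- sample@frameCounts; cens <- sample@censored
  if (censoring == "drop") { k <- k[!cens]; cens <- rep(FALSE, length(k)) }
  dt <- sample@frameIntervalS
  tab <- tabulateSample(k, cens)
  negll <- if (estimator == "phase_marginalized")
    function(th) -loglik2Geom(th, tab, dt)
  else
    function(th) -loglik2Cont(th, tab, dt)

  fit1 <- fitExponential(sample, estimator = estimator,
                         censoring = censoring)
  tau1 <- fit1@tau
  t <- k * dt
  med <- stats::median(t)
  lo <- mean(t[t <= med]); hi <- max(mean(t[t > med]), med + dt)
  starts <- list(
    c(log(tau1 * 0.5), log(tau1 * 3), stats::qlogis(0.3)),
    c(log(max(lo, dt / 10)), log(hi), stats::qlogis(mean(t > med))),
    c(log(tau1), log(tau1 * 5), stats::qlogis(0.05)),
    ## near-degenerate start: reproduces the nested 1-exp solution
    c(log(tau1), log(tau1 * 1.5), -9))
  if (!is.null(init))
    starts <- c(list(c(log(init@tShort), log(init@tLong),
                       stats::qlogis(min(max(init@fracLong, 1e-4),
                                         1 - 1e-4)))), starts)
  i <- 0
  while (length(starts) < nStarts) {
    i <- i + 1
    starts[[length(starts) + 1]] <-
      c(log(tau1 * 0.5 * 1.5^(i %% 3)), log(tau1 * (2 + 3 * i)),
        stats::qlogis(0.1 + 0.2 * (i %% 4)))
  }
  starts <- starts[seq_len(min(length(starts), max(nStarts, 1)))]
  lower <- c(log(dt / 50), log(dt / 50), -9)
  upper <- c(log(dt * 1e5), log(dt * 1e5), 9)
  best <- NULL
  anyConv <- FALSE
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    res <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    anyConv <- anyConv || res$convergence == 0
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("two-exponential fit failed to converge from any start")
  ts <- exp(best$par[1]); tl <- exp(best$par[2])
  a <- stats::plogis(best$par[3])
  if (ts > tl) { tmp <- ts; ts <- tl; tl <- tmp; a <- 1 - a }
  new("Exp2Fit", tShort = ts, tLong = max(tl, ts), fracLong = a,
      loglik = -best$value,
      se = c(tShort = NA_real_, tLong = NA_real_, fracLong = NA_real_),
      estimator = estimator, n = length(k), converged = anyConv)
}

#' Nonparametric bootstrap standard errors for dwell fits
#'
#' Resamples events with replacement, refits with `fitFunction`, and
#' returns the standard deviation of each fitted parameter over the
#' replicates. For mixture fits the canonical ordering `tShort < tLong`
#' resolves label switching before aggregation. Replicates whose fit
#' fails are counted; more than 5% failures triggers a warning.
#'
#' @param sample a [DwellSample-class].
#' @param fitFunction function taking a DwellSample and returning an
#'   [ExpFit-class] or [Exp2Fit-class].
#' @param nBoot number of bootstrap replicates (study convention: 10000).
#' @param seed RNG seed.
#' @return list with `se` (named numeric), `nFail`, and `replicates`
#'   (matrix of per-replicate parameters).
#' @examples
#' s <- simulateDwells(200, list(tau = 1), 0.25, seed = 2)
#' bootstrapSE(s, fitExponential, nBoot = 200, seed = 3)$se
#' @export
bootstrapSE <- function(sample, fitFunction, nBoot = 10000, seed = 1) {
  validObject(sample)
  n <- nEvents(sample)
  stopIfNot(n >= 2, "need at least 2 events")
  k <- sample@frameCounts; cens <- sample@censored
  dt <- sample@frameIntervalS
  reps <- list(); nFail <- 0
  withSeed(seed, {
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bs <- new("DwellSample", frameCounts = k[idx],
                frameIntervalS = dt, censored = cens[idx])
      fit <- tryCatch(fitFunction(bs), error = function(e) NULL,
                      warning = function(w) NULL)
      if (is.null(fit)) { nFail <- nFail + 1; next }
      reps[[length(reps) + 1]] <- paramVector(fit)
    }
  })
  if (nFail > 0.05 * nBoot)
    warning(sprintf("%d of %d bootstrap refits failed", nFail, nBoot))
  m <- do.call(rbind, reps)
  list(se = apply(m, 2, stats::sd), nFail = nFail, replicates = m)
}

#' @describeIn bootstrapSE extract the fitted parameter vector of a dwell
#'   fit (used to aggregate bootstrap replicates).
#' @param fit an [ExpFit-class] or [Exp2Fit-class].
#' @export
paramVector <- function(fit) {
  if (is(fit, "ExpFit")) c(tau = fit@tau)
  else c(tShort = fit@tShort, tLong = fit@tLong, fracLong = fit@fracLong)
}

#' Compare single- and two-exponential fits by AIC
#'
#' AIC = 2p - 2 logLik with p = 1 and 3. The two-exponential model nests
#' the single, so its log-likelihood is never lower; the extra parameters
#' must buy enough likelihood to be preferred.
#'
#' @param fit1 an [ExpFit-class].
#' @param fit2 an [Exp2Fit-class] on the same sample.
#' @return list with `dLogLik`, `aic1`, `aic2`, `preferred`.
#' @export
compareModels <- function(fit1, fit2) {
  stopIfNot(fit1@n == fit2@n, "fits must be on the same sample")
  aic1 <- 2 * 1 - 2 * fit1@loglik
  aic2 <- 2 * 3 - 2 * fit2@loglik
  list(dLogLik = fit2@loglik - fit1@loglik, aic1 = aic1, aic2 = aic2,
       preferred = if (aic2 < aic1) "two_exponential" else
         "single_exponential")
}

#' Mean lifetime of a fitted dwell model
#'
#' For a single exponential this is `tau`; for a mixture,
#' `(1 - fracLong) * tShort + fracLong * tLong`.
#'
#' @param fit an [ExpFit-class] or [Exp2Fit-class].
#' @return mean lifetime in seconds.
#' @export
setGeneric("meanLifetime", function(fit) standardGeneric("meanLifetime"))

#' @rdname meanLifetime
#' @export
setMethod("meanLifetime", "ExpFit", function(fit) fit@tau)

#' @rdname meanLifetime
#' @export
setMethod("meanLifetime", "Exp2Fit", function(fit)
  (1 - fit@fracLong) * fit@tShort + fit@fracLong * fit@tLong)
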