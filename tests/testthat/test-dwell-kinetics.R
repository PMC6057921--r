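# Survival curves and censored exponential(-mixture) maximum likelihood.

test_that("survival curves reproduce the product-limit table and survfit", {
  # two uncensored 2-s dwells: S = 1 up to and including t = 2, 0 after
  sc <- survivalCurve(DwellSample(c(2, 2), frameIntervalS = 1))
  expect_equal(curveSurvival(sc), c(1, 1, 1, 0))
  # single event: one drop
  sc1 <- survivalCurve(DwellSample(4, frameIntervalS = 0.5))
  expect_equal(curveSurvival(sc1), c(1, 1, 1, 1, 1, 0))
  # mixed censoring, hand-computed Kaplan-Meier on 5 events:
  # times 1,2,2+,3,5+ -> S(>=1)=1, S(>=2)=4/5, S(>=3)=3/5, S(>=4)=0.3
  s <- DwellSample(c(1, 2, 2, 3, 5), 1,
                   censored = c(FALSE, TRUE, FALSE, FALSE, TRUE))
  km <- survivalCurve(s)
  expect_equal(curveSurvival(km)[1:5], c(1, 1, 4/5, 3/5, 0.3))
  # cross-check against survival::survfit (right-continuous S(t) equals
  # our left-continuous curve evaluated just above each event time)
  skip_if_not_installed("survival")
  sf <- survival::survfit(survival::Surv(dwellTimes(s), !isCensored(s)) ~ 1)
  expect_equal(curveSurvival(km)[c(3, 4, 5)],
               summary(sf, times = c(1, 2, 3))$surv)
})

test_that("survival curves are monotone and start at one", {
  for (seed in 1:5) {
    s <- simulateDwells(200, list(tau = runif(1, 0.2, 5)), 0.25,
                        seed = seed)
    sc <- survivalCurve(s)
    expect_equal(curveSurvival(sc)[1], 1)
    expect_true(all(diff(curveSurvival(sc)) <= 1e-12))
  }
})

test_that("single-exponential MLEs match their closed forms", {
  # naive estimator is the mean of the observed dwells
  expect_equal(fitExponential(DwellSample(c(1, 2, 3), 1),
                              estimator = "naive")@tau, 2)
  # phase-marginalized geometric closed form
  f <- fitExponential(DwellSample(c(1, 1, 2, 3), 0.25))
  expect_equal(f@tau, 0.25 / log(1.75 / 0.75), tolerance = 1e-10)
  # all-single-frame boundary
  expect_warning(fitExponential(DwellSample(c(1, 1, 1), 0.25)),
                 "lower bound")
})

test_that("phase-marginalized MLE equals the dense grid-search maximizer", {
  set.seed(501)
  for (i in 1:8) {
    n <- sample(5:50, 1)
    dt <- sample(c(0.15, 0.25, 1), 1)
    s <- simulateDwells(n, list(tau = runif(1, 0.3, 8) * dt), dt,
                        seed = 500 + i)
    if (all(frameCounts(s) == 1)) next
    fit <- fitExponential(s)
    oracle <- gridSearchTau(frameCounts(s), dt)
    expect_equal(fit@tau, oracle, tolerance = 1e-4)
  }
})

test_that("censored events enter the likelihood as survival terms", {
  k <- c(2, 3, 5, 7, 4); cens <- c(FALSE, FALSE, TRUE, FALSE, TRUE)
  s <- DwellSample(k, 1, censored = cens)
  fit <- fitExponential(s)
  oracle <- gridSearchTau(k, 1, censored = cens)
  expect_equal(fit@tau, oracle, tolerance = 1e-4)
  # censoring raises the estimate relative to treating all as complete
  expect_gt(fit@tau, fitExponential(DwellSample(k, 1))@tau)
})

test_that("generating lifetimes are recovered without bias across the interval grid", {
  for (cfg in list(c(0.37, 0.15), c(0.2, 0.15), c(2, 1), c(40, 1))) {
    tau <- cfg[1]; dt <- cfg[2]
    s <- simulateDwells(10000, list(tau = tau), dt,
                        seed = round(1000 * tau + 100 * dt))
    expect_lt(abs(fitExponential(s)@tau - tau) / tau, 0.05)
  }
})

test_that("the naive estimator overestimates short dwells, worse at coarser intervals", {
  tau <- 0.46
  biases <- vapply(c(0.25, 0.5, 1), function(dt) {
    s <- simulateDwells(20000, list(tau = tau), dt, seed = 600 + dt * 100)
    fitExponential(s, estimator = "naive")@tau - tau
  }, numeric(1))
  expect_true(all(biases > 0))
  expect_true(all(diff(biases) > 0))
})

test_that("the two-exponential fit nests the single and matches a grid oracle", {
  # single-exponential data: mixture fit collapses onto the same loglik
  s <- simulateDwells(400, list(tau = 1.5), 0.25, seed = 701)
  f1 <- fitExponential(s)
  f2 <- fitTwoExponential(s)
  expect_gte(f2@loglik, f1@loglik - 1e-6)
  expect_lt(f2@loglik - f1@loglik, 2)
  # small-sample mixture: loglik within 1e-3 of brute-force grid search
  sm <- simulateDwells(20, list(tShort = 1, tLong = 10, fracLong = 0.4),
                       0.5, seed = 702)
  fm <- fitTwoExponential(sm)
  grd <- gridSearchMixLoglik(frameCounts(sm), 0.5,
                             tsGrid = exp(seq(log(0.1), log(20), length.out = 60)),
                             tlGrid = exp(seq(log(0.1), log(60), length.out = 60)),
                             aGrid = seq(0.02, 0.98, by = 0.02))
  expect_gte(fm@loglik, grd - 1e-3)
  expect_lte(fm@tShort, fm@tLong)
})

test_that("mixture parameters are recovered within bootstrap error", {
  s <- simulateDwells(1080, list(tShort = 2, tLong = 28, fracLong = 0.10),
                      1, seed = 703)
  fit <- fitTwoExponential(s)
  bs <- bootstrapSE(s, function(x) fitTwoExponential(x, nStarts = 1,
                                                     init = fit),
                    nBoot = 300, seed = 704)
  expect_lt(abs(fit@tShort - 2), 2 * bs$se[["tShort"]])
  expect_lt(abs(fit@tLong - 28), 2 * bs$se[["tLong"]])
  expect_lt(abs(fit@fracLong - 0.10), 2 * bs$se[["fracLong"]])
})

test_that("bootstrap SEs behave like sampling error", {
  # degenerate sample: zero spread
  s0 <- DwellSample(rep(5, 30), 0.25)
  expect_equal(unname(bootstrapSE(s0, fitExponential, nBoot = 50,
                                  seed = 1)$se), 0)
  # uncensored exponential at fine sampling: SE close to tau/sqrt(n)
  s <- simulateDwells(400, list(tau = 1), 0.01, seed = 801)
  bs <- bootstrapSE(s, function(x) fitExponential(x, estimator = "naive"),
                    nBoot = 400, seed = 802)
  expect_lt(abs(bs$se[["tau"]] - 0.05) / 0.05, 0.15)
  # same seed, same answer
  bs2 <- bootstrapSE(s, function(x) fitExponential(x, estimator = "naive"),
                     nBoot = 400, seed = 802)
  expect_identical(bs$se, bs2$se)
})

test_that("model comparison prefers the true generating model", {
  s1 <- simulateDwells(400, list(tau = 1.5), 0.25, seed = 901)
  cmp1 <- compareModels(fitExponential(s1), fitTwoExponential(s1))
  expect_equal(cmp1$preferred, "single_exponential")
  expect_gte(cmp1$dLogLik, -1e-6)
  s2 <- simulateDwells(2000, list(tShort = 0.5, tLong = 20, fracLong = 0.3),
                       0.25, seed = 902)
  cmp2 <- compareModels(fitExponential(s2), fitTwoExponential(s2))
  expect_equal(cmp2$preferred, "two_exponential")
})

test_that("mean lifetime combines mixture components by weight", {
  f1 <- new("ExpFit", tau = 0.46, loglik = 0, seTau = NA_real_,
            estimator = "naive", n = 10L)
  expect_equal(meanLifetime(f1), 0.46)
  mk <- function(a) new("Exp2Fit", tShort = 2, tLong = 28, fracLong = a,
                        loglik = 0,
                        se = c(tShort = NA_real_, tLong = NA_real_,
                               fracLong = NA_real_),
                        estimator = "naive", n = 10L, converged = TRUE)
  expect_equal(meanLifetime(mk(0)), 2)
  expect_equal(meanLifetime(mk(0.5)), 15)
})
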