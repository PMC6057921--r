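# Ground-truth generators: determinism, analytic moments, and the
# frame-quantization observation model.

branchScenario <- function(seed, rate, tau = 1, duration = 1000) {
  SimScenario(seed = seed, durationS = duration, frameIntervalS = 0.25,
              siteMap = SiteMap(branches = cbind(5, 5)),
              kinetics = list(branch = KineticModel(arrivalRate = rate,
                                                    tau = tau)))
}

test_that("zero arrival rate gives no events and a seed fully determines the output", {
  expect_equal(nrow(simulateBindingEvents(branchScenario(1, 0))), 0)
  sc <- branchScenario(42, 0.3, tau = 2, duration = 200)
  expect_identical(simulateBindingEvents(sc), simulateBindingEvents(sc))
  sc2 <- branchScenario(43, 0.3, tau = 2, duration = 200)
  expect_false(identical(simulateBindingEvents(sc),
                         simulateBindingEvents(sc2)))
})

test_that("arrival counts and dwell means match Poisson/exponential moments", {
  ev <- simulateBindingEvents(branchScenario(7, 0.5, tau = 2))
  expect_lt(abs(nrow(ev) - 500), 3 * sqrt(500))
  expect_lt(abs(mean(ev$duration) - 2), 3 * 2 / sqrt(nrow(ev)))
  expect_true(all(ev$duration > 0))
  expect_true(all(ev$t_start >= 0 & ev$t_start < 1000))
})

test_that("malformed kinetic models are rejected", {
  expect_error(KineticModel(arrivalRate = -1, tau = 1), "nonnegative")
  expect_error(KineticModel(arrivalRate = 1, tau = -2), "tau")
  expect_error(KineticModel(arrivalRate = 1, tShort = 3, tLong = 2,
                            fracLong = 0.5), "tShort")
})

test_that("frame quantization follows the frames-times-interval convention", {
  # sub-frame event spanning no acquisition instant goes undetected
  ev <- data.frame(t_start = 0.10, duration = 0.05)
  expect_equal(nrow(quantizeToFrames(ev, 0.25)), 0)
  # an event observed at 3 consecutive 1-s instants has dwell 3 s
  ev <- data.frame(t_start = 0.5, duration = 2.7)
  q <- quantizeToFrames(ev, 1)
  expect_equal(q$n_frames, 3L)
  expect_equal(q$dwell_s, 3)
  # events running past the final instant are right-censored by default,
  # dropped on request
  ev <- data.frame(t_start = c(1.2, 8.6), duration = c(2, 50))
  q <- quantizeToFrames(ev, 1, durationS = 10)
  expect_equal(q$censored, c(FALSE, TRUE))
  expect_equal(q$n_frames[2], 10L - 9L + 1L)
  expect_equal(nrow(quantizeToFrames(ev, 1, durationS = 10,
                                     endHandling = "drop")), 1)
})

test_that("detected fraction under uniform phase matches the closed form", {
  tau <- 0.46; dt <- 0.25; n <- 50000
  set.seed(301)
  ev <- data.frame(t_start = runif(n, 0, dt),
                   duration = rexp(n, 1 / tau))
  pDet <- nrow(quantizeToFrames(ev, dt)) / n
  pTheory <- (tau / dt) * (1 - exp(-dt / tau))
  expect_lt(abs(pDet - pTheory), 3 * sqrt(pTheory * (1 - pTheory) / n))
})

test_that("coarser frame intervals never detect more events", {
  set.seed(302)
  ev <- data.frame(t_start = runif(2000, 0, 50),
                   duration = rexp(2000, 1 / 0.5))
  counts <- vapply(c(0.15, 0.25, 0.5, 1, 2),
                   function(dt) nrow(quantizeToFrames(ev, dt)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fixed-size dwell sampling returns exactly n detected events, reproducibly", {
  s <- simulateDwells(500, list(tau = 0.37), 0.15, seed = 9)
  expect_equal(nEvents(s), 500)
  expect_true(all(frameCounts(s) >= 1))
  s2 <- simulateDwells(500, list(tau = 0.37), 0.15, seed = 9)
  expect_identical(frameCounts(s), frameCounts(s2))
})

test_that("photobleaching traces carry the designed step structure", {
  # no noise, all monomers: exactly one downward step to baseline
  sim <- simulatePhotobleachTraces(20, multiStepFraction = 0,
                                   stepAmplitude = 100, noiseSd = 0,
                                   nFrames = 60, seed = 11)
  expect_true(all(sim$trueSteps == 1))
  for (y in split(sim$traces$intensity, sim$traces$trace_id)) {
    drops <- which(diff(y) != 0)
    expect_true(length(drops) <= 1)          # at most one transition
    expect_true(all(diff(y)[drops] < 0))     # and it goes down
    expect_equal(y[length(y)] %in% c(0, 100), TRUE)
  }
  # all dimers
  sim2 <- simulatePhotobleachTraces(50, multiStepFraction = 1, seed = 12)
  expect_true(all(sim2$trueSteps == 2))
  # binomial share of dimers
  sim3 <- simulatePhotobleachTraces(1000, multiStepFraction = 0.2, seed = 13)
  expect_lt(abs(mean(sim3$trueSteps == 2) - 0.2),
            3 * sqrt(0.2 * 0.8 / 1000))
  expect_error(simulatePhotobleachTraces(5, 0.5, noiseSd = -1), "noiseSd")
})

test_that("debranching lifetimes are censored at the observation window", {
  d <- simulateDebranching(200, list(tau = 10), observationWindowS = 1e9,
                           seed = 21)
  expect_equal(sum(d$censored), 0)
  d2 <- simulateDebranching(50, list(fixed = 10), observationWindowS = 5,
                            seed = 22)
  expect_true(all(d2$censored))
  expect_true(all(d2$lifetime_s == 5))
  d3 <- simulateDebranching(10000, list(tau = 100),
                            observationWindowS = 900, seed = 23)
  p <- exp(-9)
  expect_lt(abs(mean(d3$censored) - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("gel standards follow the through-zero quadratic with multiplicative noise", {
  g <- simulateGelStandards(c(2, 1), standardConcs = c(0, 1),
                            sampleConcs = numeric(0), noiseCv = 0, seed = 31)
  expect_equal(g$standards$intensity, c(0, 3))
  # zero concentration stays exactly zero even with noise
  gn <- simulateGelStandards(c(2, 1), standardConcs = rep(0, 20),
                             sampleConcs = numeric(0), noiseCv = 0.5,
                             seed = 32)
  expect_true(all(gn$standards$intensity == 0))
  g100 <- simulateGelStandards(c(2, 1), standardConcs = rep(1, 100),
                               sampleConcs = numeric(0), noiseCv = 0.05,
                               seed = 33)
  expect_lt(abs(mean(g100$standards$intensity) - 3),
            3 * 3 * 0.05 / sqrt(100))
  expect_error(simulateGelStandards(c(2, 1), standardConcs = -1,
                                    sampleConcs = 1), "concentrations")
})

test_that("the two-state occupancy process has the requested duty ratio", {
  ev <- simulateOccupancyTrace(40, dutyRatio = 0.6, meanBoundS = 20,
                               durationS = 2000, seed = 41)
  frac <- sum(ev$duration) / (40 * 2000)
  expect_lt(abs(frac - 0.6), 0.05)
  expect_identical(ev, simulateOccupancyTrace(40, 0.6, 20, 2000, seed = 41))
})
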