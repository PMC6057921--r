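# Spot detection, track linking, colocalization, classification, and the
# end-to-end recovery of simulated ground truth from rendered movies.

renderSpots <- function(xy_px, photons = 800, shape = c(64, 64),
                        background = 0, noise = "none", sigma = 1.2,
                        pixelUm = 0.27) {
  ev <- data.frame(x_um = xy_px[, 1] * pixelUm, y_um = xy_px[, 2] * pixelUm,
                   start_frame = 0L, n_frames = 1L)
  mp <- MovieParams(pixelSizeUm = pixelUm, imageShape = shape,
                    psfSigmaPx = sigma, photonsPerSpot = photons,
                    backgroundLevel = background, noiseModel = noise)
  renderMovie(ev, mp, nFrames = 1)$stack[, , 1]
}

test_that("rendering honours bounds, noiselessness, and Poisson mean preservation", {
  mp <- MovieParams(imageShape = c(32, 32), backgroundLevel = 0)
  empty <- renderMovie(data.frame(x_um = numeric(0), y_um = numeric(0),
                                  start_frame = integer(0),
                                  n_frames = integer(0)), mp, 5)
  expect_true(all(empty$stack == 0))
  img <- renderSpots(cbind(20, 12))
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(13, 21))  # row = y + 1, col = x + 1
  expect_error(renderSpots(cbind(100, 5)), "bounds")
  # Poisson noise preserves the summed intensity on average
  ev <- data.frame(x_um = 20 * 0.27, y_um = 12 * 0.27, start_frame = 0L,
                   n_frames = 100L)
  mp2 <- MovieParams(imageShape = c(32, 32), photonsPerSpot = 500,
                     backgroundLevel = 0, noiseModel = "poisson")
  set.seed(61)
  noisy <- renderMovie(ev, mp2, 100)$stack
  clean <- renderMovie(ev, MovieParams(imageShape = c(32, 32),
                                       photonsPerSpot = 500), 100)$stack
  expect_lt(abs(sum(noisy) - sum(clean)), 5 * sqrt(sum(clean)))
})

test_that("spot detection finds isolated Gaussians at sub-pixel accuracy", {
  expect_equal(nrow(detectSpots(matrix(0, 32, 32))), 0)
  expect_error(detectSpots(matrix(numeric(0), 0, 0)), "non-empty")
  img <- renderSpots(cbind(20.0, 30.0))
  d <- detectSpots(img, thresholdSd = 5, spotRadiusPx = 3)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x_px - 20.0), 0.1)
  expect_lt(abs(d$y_px - 30.0), 0.1)
  # sub-pixel ground truth
  img2 <- renderSpots(cbind(20.4, 30.7))
  d2 <- detectSpots(img2)
  expect_lt(abs(d2$x_px - 20.4), 0.1)
  expect_lt(abs(d2$y_px - 30.7), 0.1)
  # two spots 10 px apart stay separate
  img3 <- renderSpots(cbind(c(20, 30), c(15, 15)))
  expect_equal(nrow(detectSpots(img3)), 2)
})

test_that("greedy linking respects radius, identity, and gap tolerance", {
  det <- data.frame(frame = 0:4, x_px = 10, y_px = 10, intensity = 1)
  tr <- linkTracks(det, linkRadiusPx = 2)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 5)
  # two well-separated stationary spots never merge
  det2 <- rbind(det, transform(det, x_px = 60))
  det2 <- det2[order(det2$frame), ]
  tr2 <- linkTracks(det2, linkRadiusPx = 2)
  expect_length(tr2, 2)
  expect_true(all(vapply(tr2, function(t) length(unique(t$x_px)) == 1,
                         logical(1))))
  # one missing frame: split without gap tolerance, joined with it
  det3 <- det[det$frame != 2, ]
  expect_length(linkTracks(det3, linkRadiusPx = 2, maxGapFrames = 0), 2)
  expect_length(linkTracks(det3, linkRadiusPx = 2, maxGapFrames = 1), 1)
})

test_that("colocalization runs match the frame-by-frame oracle", {
  mkTrack <- function(frames, x, y)
    data.frame(frame = frames, x_px = x, y_px = y, intensity = 1)
  anchors <- data.frame(anchor_id = 1, x_px = 10, y_px = 10)
  # coincident for 3 frames at dt = 1 s -> one 3 s event
  ev <- colocalize(list(mkTrack(0:2, 10, 10)), anchors, colocRadiusPx = 1,
                   frameIntervalS = 1, nFrames = 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$dwell_s, 3)
  expect_false(ev$censored)
  # always out of range -> nothing
  expect_equal(nrow(colocalize(list(mkTrack(0:5, 30, 30)), anchors,
                               colocRadiusPx = 1, nFrames = 10)), 0)
  # split occupancy: frames 2-4 and 8-9 -> two events of 3 and 2 frames
  trk <- mkTrack(c(2:4, 8:9), 10, 10)
  ev2 <- colocalize(list(trk), anchors, colocRadiusPx = 1,
                    frameIntervalS = 1, nFrames = 10)
  oracle <- bruteForceColocRuns(trk, 10, 10, 1)
  expect_equal(ev2$start_frame, oracle$start)
  expect_equal(ev2$n_frames, oracle$len)
  # contact at the final recorded frame is right-censored
  ev3 <- colocalize(list(mkTrack(7:9, 10, 10)), anchors, colocRadiusPx = 1,
                    frameIntervalS = 1, nFrames = 10)
  expect_true(ev3$censored)
})

test_that("location classification is exhaustive, exclusive, and box-geometric", {
  sm <- SiteMap(filaments = list(cbind(c(0, 10), c(5, 5))),
                branches = cbind(4, 5))
  expect_equal(classifyLocation(4, 5, sm), "branch")
  expect_equal(classifyLocation(9, 11, sm), "background")
  # 0.3 um from the branch point is inside the 1.068-um box
  expect_equal(classifyLocation(4.3, 5, sm), "branch")
  # just beyond the half box side but near the filament: side
  expect_equal(classifyLocation(4, 5.6, sm), "background")
  expect_equal(classifyLocation(8, 5.3, sm), "side")
  # every random event gets exactly one of the three classes
  set.seed(71)
  cls <- classifyLocation(runif(500, -2, 12), runif(500, -2, 12), sm)
  expect_true(all(cls %in% c("background", "side", "branch")))
  expect_true(all(c("background", "side", "branch") %in% cls))
})

test_that("filament intensity profiles are background-subtracted and ordered", {
  # uniform image nets to zero
  uni <- matrix(7, 48, 48)
  poly <- cbind(c(10, 35), c(20, 20))
  expect_equal(filamentIntensityProfile(uni, poly)$total, 0)
  expect_error(filamentIntensityProfile(uni, cbind(c(-5, 10), c(2, 2))),
               "outside")
  # a rendered line of spots scales with the photon budget
  lineImg <- function(photons) {
    ev <- data.frame(x_um = seq(10, 35, by = 1) * 0.27, y_um = 20 * 0.27,
                     start_frame = 0L, n_frames = 1L)
    mp <- MovieParams(imageShape = c(48, 48), photonsPerSpot = photons)
    renderMovie(ev, mp, 1)$stack[, , 1]
  }
  p1 <- filamentIntensityProfile(lineImg(300), poly)$total
  p2 <- filamentIntensityProfile(lineImg(600), poly)$total
  expect_gt(p1, 0)
  expect_equal(p2 / p1, 2, tolerance = 0.02)
  # an end-decorated filament profiles higher at the decorated end
  ev <- data.frame(x_um = c(seq(10, 35, 1), seq(30, 35, 0.5)) * 0.27,
                   y_um = 20 * 0.27, start_frame = 0L, n_frames = 1L)
  img <- renderMovie(ev, MovieParams(imageShape = c(48, 48),
                                     photonsPerSpot = 300), 1)$stack[, , 1]
  pr <- filamentIntensityProfile(img, poly, perPosition = TRUE)
  nP <- length(pr$profile)
  expect_gt(mean(pr$profile[(nP - 5):nP]), mean(pr$profile[1:6]))
})

test_that("simulated movies round-trip through detect/link/colocalize", {
  sm <- SiteMap(branches = cbind(c(3, 8, 12, 3, 8, 12), c(3, 3, 3, 9, 9, 9)))
  sc <- SimScenario(seed = 7, durationS = 60, frameIntervalS = 0.25,
                    siteMap = sm,
                    kinetics = list(branch = KineticModel(arrivalRate = 0.05,
                                                          tau = 2)))
  ev <- simulateBindingEvents(sc)
  q <- quantizeToFrames(ev, 0.25, durationS = 60)
  mp <- MovieParams(pixelSizeUm = 0.27, imageShape = c(64, 64),
                    psfSigmaPx = 1.2, photonsPerSpot = 800,
                    backgroundLevel = 20, noiseModel = "poisson")
  set.seed(81)
  mv <- renderMovie(q, mp, 241)
  det <- detectSpotsStack(mv$stack, thresholdSd = 6, spotRadiusPx = 3)
  tracks <- linkTracks(det, linkRadiusPx = 2)
  anchors <- data.frame(anchor_id = seq_len(nBranches(sm)),
                        x_px = sm@branches[, 1] / 0.27,
                        y_px = sm@branches[, 2] / 0.27)
  found <- colocalize(tracks, anchors, colocRadiusPx = 2,
                      frameIntervalS = 0.25, nFrames = 241)
  # observable truth: overlapping same-site events merge into one run
  truth <- mergedTruthRuns(q)
  truth <- truth[truth$n_frames >= 2, ]
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(found$start_frame == truth$start_frame[i] &
        found$n_frames == truth$n_frames[i]), logical(1))
  expect_gte(mean(hit), 0.95)
  # spurious: recovered >= 2-frame events absent from the merged truth
  f2 <- found[found$n_frames >= 2, ]
  spur <- vapply(seq_len(nrow(f2)), function(i)
    !any(truth$start_frame == f2$start_frame[i] &
         truth$n_frames == f2$n_frames[i]), logical(1))
  expect_lt(mean(spur), 0.05)
  # recovered dwells are exact multiples of the frame interval
  expect_true(all(abs(found$dwell_s / 0.25 -
                      round(found$dwell_s / 0.25)) < 1e-12))
})
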