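# Brute-force structure tensor for the oracle comparisons: per-pixel window
# sums of gradient products with explicit loops.
bruteShiTomasi <- function(frame, half) {
  nr <- nrow(frame); nc <- ncol(frame)
  gx <- gy <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    gx[r, cc] <- (frame[r, min(cc + 1, nc)] - frame[r, max(cc - 1, 1)]) / 2
    gy[r, cc] <- (frame[min(r + 1, nr), cc] - frame[max(r - 1, 1), cc]) / 2
  }
  R <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    rs <- pmin(pmax((r - half):(r + half), 1), nr)
    cs <- pmin(pmax((cc - half):(cc + half), 1), nc)
    a <- sum(gx[rs, cs]^2); d <- sum(gy[rs, cs]^2); b <- sum(gx[rs, cs] * gy[rs, cs])
    R[r, cc] <- min(eigen(matrix(c(a, b, b, d), 2), symmetric = TRUE,
                          only.values = TRUE)$values)
  }
  pmax(R, 0)
}

test_that("Shi-Tomasi scores match a brute-force eigen-decomposition oracle", {
  img <- matrix(0, 24, 24); img[9:16, 9:16] <- 1
  cfg <- cornerConfig(tensorWindow = 3)
  R <- structureTensorScores(img, cfg)
  expect_lt(max(abs(R - bruteShiTomasi(img, 1))), 1e-10)
  # constant frame: identically zero
  expect_identical(unique(as.vector(
    structureTensorScores(matrix(0.4, 20, 20), cfg))), 0)
  # interior of an ideal vertical step edge: rank-1 tensor, R ~ 0
  edge <- matrix(0, 32, 32); edge[, 17:32] <- 1
  Re <- structureTensorScores(edge, cfg)
  expect_lt(max(Re[10:22, ]), 1e-10)
})

test_that("corners of a white square are localised within 2 px", {
  img <- matrix(0, 64, 64); img[25:40, 25:40] <- 1
  cc <- detectCorners(img, cornerConfig(nCorners = 10, qualityLevel = 0.2,
                                        minDistance = 7, tensorWindow = 3))
  expect_identical(nrow(cc), 4L)
  truth <- rbind(c(24, 24), c(24, 39), c(39, 24), c(39, 39))
  for (i in seq_len(4)) {
    d <- sqrt((cc$x - truth[i, 2])^2 + (cc$y - truth[i, 1])^2)
    expect_lte(min(d), 2)
  }
})

test_that("corner detection respects quality, suppression and count contracts", {
  f <- getFrame(genFlatVideo(synthConfig(imageSize = 96, nFrames = 1,
                                         seed = 8)), 1)
  # no pixel can beat the top scorer at quality level 1 + eps scenario:
  # an impossible threshold returns the single best pixel only
  cc1 <- detectCorners(f, cornerConfig(nCorners = 300, qualityLevel = 1))
  expect_lte(nrow(cc1), 2L)
  # count decreases monotonically with the quality level
  n02 <- nrow(detectCorners(f, cornerConfig(qualityLevel = 0.2)))
  n04 <- nrow(detectCorners(f, cornerConfig(qualityLevel = 0.4)))
  expect_lte(n04, n02)
  # no two returned corners closer than the suppression distance
  cc <- detectCorners(f, cornerConfig(nCorners = 100, minDistance = 7))
  if (nrow(cc) > 1) {
    dm <- as.matrix(dist(cc[, c("x", "y")]))
    expect_true(all(dm[upper.tri(dm)] >= 7))
  }
  expect_lte(nrow(cc), 100L)
  # scores come back sorted
  expect_true(all(diff(cc$score) <= 0))
})

test_that("Lucas-Kanade recovers integer and subpixel shifts", {
  base <- getFrame(genFlatVideo(synthConfig(imageSize = 96, nFrames = 1,
                                            seed = 8, noiseSigma = 0)), 1)
  pts <- detectCorners(base, cornerConfig(nCorners = 20))
  keep <- pts$x > 25 & pts$x < 70 & pts$y > 25 & pts$y < 70
  pts <- pts[keep, ]
  for (d in list(c(1, 0), c(-2, 3), c(4, -4))) {
    fl <- lkFlow(base, circShift(base, d[1], d[2]), pts, lkConfig())
    ok <- fl$status == 1
    expect_gt(mean(ok), 0.8)
    err <- cbind(fl$points$x - pts$x - d[1],
                 fl$points$y - pts$y - d[2])[ok, , drop = FALSE]
    expect_lt(max(abs(err)), 0.1)
  }
  # identical frames: zero displacement, everything alive
  fl0 <- lkFlow(base, base, pts, lkConfig())
  expect_true(all(fl0$status == 1))
  expect_lt(max(abs(cbind(fl0$points$x - pts$x, fl0$points$y - pts$y))), 1e-6)
  # smooth subpixel shift recovered within 0.2 px
  S <- 96
  sm <- 0.5 + 0.2 * sin(2 * pi * outer(rep(1, S), 0:(S - 1)) / 17) *
    cos(2 * pi * outer(0:(S - 1), rep(1, S)) / 23) +
    0.15 * cos(2 * pi * outer(0:(S - 1), rep(1, S)) / 13)
  ptsm <- data.frame(x = c(30, 48, 60), y = c(40, 50, 30))
  fl <- lkFlow(sm, spectralShift(sm, 0.5, 0.5), ptsm, lkConfig())
  expect_true(all(fl$status == 1))
  expect_lt(max(abs(c(fl$points$x - ptsm$x - 0.5,
                      fl$points$y - ptsm$y - 0.5))), 0.2)
})

test_that("pyramids allow larger shifts than a single window", {
  base <- getFrame(genFlatVideo(synthConfig(imageSize = 128, nFrames = 1,
                                            seed = 12, noiseSigma = 0)), 1)
  pts <- detectCorners(base, cornerConfig(nCorners = 15))
  keep <- pts$x > 45 & pts$x < 85 & pts$y > 45 & pts$y < 85
  pts <- pts[keep, ]
  fl <- lkFlow(base, circShift(base, 16, 0), pts,
               lkConfig(pyramidLevels = 3))
  ok <- fl$status == 1
  expect_gt(sum(ok), 0)
  err <- cbind(fl$points$x - pts$x - 16, fl$points$y - pts$y)[ok, , drop = FALSE]
  expect_lt(max(abs(err)), 0.3)
})

test_that("whole-video tracking honours its lifecycle contracts", {
  cfg <- synthConfig(imageSize = 96, nFrames = 20, seed = 3, wanderSigma = 0,
                     noiseSigma = 0, waveAmp = 0, ringSpeed = 0)
  v <- genFlatVideo(cfg)
  expect_error(trackVideo(waveVideo(getFrame(v, 1))), "insufficient frames")
  # corners seeded away from the border so every tracking window fits
  ts <- trackVideo(v, testCornerCfg(), lkConfig(), margin = 18L)
  # static video: all trajectories survive with ~ zero net displacement
  perTrack <- split(ts@tracks, ts@tracks$track)
  expect_gt(length(perTrack), 3L)
  expect_true(all(vapply(perTrack, nrow, integer(1)) == 20L))
  net <- vapply(perTrack, function(d)
    max(abs(c(d$x[20] - d$x[1], d$y[20] - d$y[1]))), numeric(1))
  expect_lt(max(net), 0.1)
  # alive counts never increase over frames
  vd <- genRidgedVideo(synthConfig(imageSize = 96, nFrames = 40, seed = 5,
                                   driftVelocity = c(-0.5, 0)))
  tsd <- trackVideo(vd, testCornerCfg(), lkConfig())
  alive <- table(factor(tsd@tracks$frame, levels = 0:39))
  expect_true(all(diff(as.integer(alive)) <= 0))
  # imposed drift shows up in the tracked steps
  steps <- unlist(lapply(split(tsd@tracks, tsd@tracks$track),
                         function(d) diff(d$x)), use.names = FALSE)
  expect_lt(abs(median(steps) - (-0.5)), 0.1)
})

test_that("flow summaries equal a brute-force mean over the step list", {
  tr <- data.frame(
    track = rep(1:3, times = c(5, 4, 2)),
    frame = c(0:4, 0:3, 0:1),
    x = c(cumsum(c(10, -0.5, -0.5, -0.5, -0.5)),
          cumsum(c(20, 0.3, -0.1, 0.2)), c(30, 30.7)),
    y = c(cumsum(c(10, 0, 0, 0, 0)),
          cumsum(c(20, -0.2, 0.4, 0.1)), c(30, 29.1)))
  ts <- new("TrackSet", tracks = tr, nFrames = 5L, videoId = "toy")
  fs <- flowSummary(ts)
  allDx <- c(rep(-0.5, 4), 0.3, -0.1, 0.2, 0.7)
  allDy <- c(rep(0, 4), -0.2, 0.4, 0.1, -0.9)
  expect_lt(abs(fs@vx - mean(allDx)), 1e-12)
  expect_lt(abs(fs@vy - mean(allDy)), 1e-12)
  expect_lt(abs(fs@v - sqrt(mean(allDx)^2 + mean(allDy)^2)), 1e-12)
  expect_identical(fs@nSteps, 8L)
  # per-trajectory weighting option
  fsw <- flowSummary(ts, perTrajectory = TRUE)
  expect_lt(abs(fsw@vx - mean(c(-0.5, mean(c(0.3, -0.1, 0.2)), 0.7))), 1e-12)
  # uniform steps give the exact constant summary
  uni <- new("TrackSet", nFrames = 3L, videoId = "u",
             tracks = data.frame(track = rep(1:2, each = 3), frame = rep(0:2, 2),
                                 x = c(10, 9.5, 9, 20, 19.5, 19),
                                 y = rep(c(5, 5, 5, 8, 8, 8))))
  fu <- flowSummary(uni)
  expect_equal(c(fu@vx, fu@vy, fu@v), c(-0.5, 0, 0.5), tolerance = 1e-12)
  # no steps at all is an error
  empty <- new("TrackSet", nFrames = 2L, videoId = "e",
               tracks = data.frame(track = 1L, frame = 0L, x = 1, y = 1))
  expect_error(flowSummary(empty), "undefined summary")
})

test_that("zero-mean wandering yields near-zero mean velocity but nonzero speed", {
  set.seed(11)
  n <- 4000
  dx <- rnorm(n); dy <- rnorm(n)
  tr <- data.frame(track = 1L, frame = 0:n,
                   x = cumsum(c(0, dx)), y = cumsum(c(0, dy)))
  fs <- flowSummary(new("TrackSet", tracks = tr,
                        nFrames = as.integer(n + 1), videoId = "walk"))
  meanSpeed <- mean(sqrt(dx^2 + dy^2))
  expect_lt(fs@v, 0.1 * meanSpeed)
})

test_that("velocity magnitude is invariant under video rotation", {
  v <- genRidgedVideo(synthConfig(imageSize = 96, nFrames = 30, seed = 2,
                                  driftVelocity = c(-0.5, 0)))
  fs <- flowSummary(trackVideo(v, testCornerCfg(), lkConfig()), v)
  vr <- rotateVideo(v, 90)
  fsr <- flowSummary(trackVideo(vr, testCornerCfg(), lkConfig()), vr)
  # y-down CCW rotation maps (vx, vy) -> (vy, -vx); |v| is unchanged
  expect_lt(abs(fsr@vx - fs@vy), 0.05)
  expect_lt(abs(fsr@vy - (-fs@vx)), 0.05)
  expect_lt(abs(fsr@v - fs@v), 0.05)
  expect_gte(fs@v, max(abs(fs@vx), abs(fs@vy)) / sqrt(2))
  # physical conversion: px/frame to um/s
  expect_equal(unname(fs@umPerS["v"]), fs@v * v@umPerPx / v@sPerFrame,
               tolerance = 1e-12)
})

test_that("sub-video segmentation follows the stated tail rule", {
  mk <- function(n) waveVideo(array(0.5, c(8, 8, n)), videoId = "v")
  s95 <- subdivideVideo(mk(95), 60)
  expect_length(s95, 2L)
  expect_identical(vapply(s95, nFrames, integer(1)), c(60L, 60L))
  expect_identical(vapply(s95, videoId, character(1)), c("v_s0", "v_s35"))
  expect_length(subdivideVideo(mk(120), 60), 2L)
  expect_length(subdivideVideo(mk(30), 60), 1L)
  expect_identical(nFrames(subdivideVideo(mk(30), 60)[[1]]), 30L)
  expect_length(subdivideVideo(mk(200), 60), 4L)  # 0, 60, 120 + tail 140
  expect_error(subdivideVideo(mk(10), 1), "invalid config")
})
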