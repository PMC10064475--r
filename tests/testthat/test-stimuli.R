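test_that("drifting grating honours zero-contrast, static and parameter contracts", {
  s <- genDriftingGrating(c(16, 20), 8, 30, 1, 0, 5, meanLuminance = 0.4)
  expect_true(all(frames(s) == 0.4))

  s0 <- genDriftingGrating(c(16, 20), 8, 30, 0, 1, 5)
  f <- frames(s0)
  for (t in 2:5) expect_identical(f[, , t], f[, , 1])

  expect_error(genDriftingGrating(c(16, 16), 1.5, 0, 1, 1, 4), "wavelength")
  expect_error(genDriftingGrating(c(16, 16), 8, 0, 1, 1.4, 4), "contrast")
  expect_error(genDriftingGrating(c(16, 16), 8, 0, 1, 0.5, 4,
                                  meanLuminance = 0.9), "stay inside")
})

test_that("drifting grating has its 3D spectral peak at the stated frequencies", {
  # wavelength 16 px rightward at 2 px/frame: spatial peak 1/16 cyc/px along
  # x, temporal peak 2/16 cyc/frame (conjugate-symmetric bins allowed)
  s <- genDriftingGrating(c(32, 32), 16, 0, 2, 1, 32)
  A <- abs(fft(frames(s) - mean(frames(s))))
  idx <- which(A == max(A), arr.ind = TRUE) - 1L  # 0-based bins
  for (row in seq_len(nrow(idx))) {
    b <- idx[row, ]
    expect_equal(b[[1]], 0)                              # no y frequency
    expect_equal(min(b[[2]], 32 - b[[2]]) / 32, 1 / 16)  # spatial freq
    expect_equal(min(b[[3]], 32 - b[[3]]) / 32, 2 / 16)  # temporal freq
  }
})

test_that("counterphase grating is the sum of two opposite drifting gratings", {
  size <- c(24, 24)
  cp <- genCounterphaseGrating(size, 8, 30, 0.125, 0.8, 16)
  g1 <- genDriftingGrating(size, 8, 30, 0.125 * 8, 0.4, 16)
  g2 <- genDriftingGrating(size, 8, 30 + 180, 0.125 * 8, 0.4, 16)
  # sum of the two half-contrast components, re-centered on one mean level
  recon <- frames(g1) + frames(g2) - 0.5
  expect_lt(max(abs(frames(cp) - recon)), 1e-6)

  z <- genCounterphaseGrating(size, 8, 0, 0.125, 0, 8)
  expect_true(all(frames(z) == 0.5))

  # temporal spectrum at a pixel peaks at the reversal frequency
  v <- frames(cp)[5, 3, ]
  sp <- abs(fft(v - mean(v)))
  peak <- which.max(sp[2:8])  # positive-frequency bins 1..7
  expect_equal(peak / 16, 0.125)
})

test_that("generator outputs satisfy frame-sequence invariants over random draws", {
  set.seed(11)
  for (i in 1:8) {
    wl <- runif(1, 3, 20)
    s <- genDriftingGrating(c(20, 24), wl, runif(1, -180, 180),
                            runif(1, -2, 2), runif(1), sample(3:10, 1))
    expect_true(validObject(s))
    expect_gte(min(frames(s)), 0)
    expect_lte(max(frames(s)), 1)
  }
})

test_that("stepping feet translate rigidly and respect their contracts", {
  spec <- steppingFeetSpec(backgroundContrast = 0)
  size <- c(48L, 96L)
  s <- genSteppingFeet(spec, size, 12, startX = 6)
  f <- frames(s)
  cents <- sapply(seq_len(12), function(t)
    motionEnergy:::feetCentroids(f[, , t], spec, size))
  # both centroids advance exactly speed px/frame, every frame
  expect_equal(as.vector(diff(cents["bright", ])), rep(spec@speed, 11),
               tolerance = 1e-9)
  expect_equal(as.vector(diff(cents["dark", ])), rep(spec@speed, 11),
               tolerance = 1e-9)

  # zero background contrast: uniform background, feet still visible
  border <- f[1:4, , 1]
  expect_true(all(border == 0.5))
  expect_setequal(round(range(f[, , 1]), 3), round(range(c(0.5, spec@footLuminances)), 3))

  expect_error(genSteppingFeet(spec, c(48L, 40L), 12, startX = 6), "leave")
})

test_that("luminance ahead of the leading foot edge is periodic in the grating period", {
  spec <- steppingFeetSpec()  # full-contrast grating, period 16
  size <- c(48L, 112L)
  s <- genSteppingFeet(spec, size, 64, startX = 4)
  f <- frames(s)
  midRow <- 24L
  lead <- sapply(seq_len(64), function(t) {
    x <- 4 + spec@speed * (t - 1) + spec@footSize[1] + 2  # just ahead
    f[midRow, round(x), t]
  })
  period <- spec@gratingPeriod / spec@speed
  expect_equal(lead[seq_len(64 - period)], lead[seq_len(64 - period) + period])
  expect_gt(stats::sd(lead), 0.1)  # it actually alternates
})

test_that("ring stimuli honour symmetry, expansion and bounds contracts", {
  ctr <- c(32.5, 32.5)
  static <- genRingStimulus(
    ringStimulusSpec(center = ctr, baseRadius = 16,
                     elementKind = "solid_texture", nElements = 12L,
                     elementSigma = 3), c(64, 64), 4)
  f <- frames(static)
  for (t in 2:4) expect_identical(f[, , t], f[, , 1])

  # n-fold angular symmetry: one rotation step of 360/n is the identity
  sym <- genRingStimulus(
    ringStimulusSpec(center = ctr, baseRadius = 16, rotationRate = 30,
                     elementKind = "solid_texture", nElements = 12L,
                     elementSigma = 3), c(64, 64), 3)
  expect_lt(max(abs(frames(sym)[, , 2] - frames(sym)[, , 1])), 1e-12)

  # expanding ring: fitted radius tracks base_radius + t within 0.5 px
  g <- expand.grid(y = 1:64, x = 1:64)
  r <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2)
  fitRadius <- function(fr) {
    w <- as.vector((fr - 0.5)^2) / pmax(r, 1)  # area-corrected weights
    sum(w * r) / sum(w)
  }
  for (kind in c("solid_texture", "gabor_elements")) {
    ex <- genRingStimulus(
      ringStimulusSpec(center = ctr, baseRadius = 12, expansionRate = 1,
                       elementKind = kind, nElements = 12L,
                       elementWavelength = 6, elementSigma = 3),
      c(64, 64), 7)
    for (t in c(1, 4, 7))
      expect_lt(abs(fitRadius(frames(ex)[, , t]) - (12 + t - 1)), 0.5)
  }

  # bounds: error when the ring leaves the frame unless clipping is allowed
  spec <- ringStimulusSpec(center = ctr, baseRadius = 24, expansionRate = 2,
                           elementKind = "solid_texture", nElements = 8L,
                           elementSigma = 4)
  expect_error(genRingStimulus(spec, c(64, 64), 10), "leaves the frame")
  clipped <- genRingStimulus(spec, c(64, 64), 10, allowClipping = TRUE)
  expect_true(validObject(clipped))
  expect_error(genRingStimulus(
    ringStimulusSpec(center = ctr, baseRadius = 4, expansionRate = -1,
                     elementKind = "solid_texture", nElements = 8L,
                     elementSigma = 1), c(64, 64), 8), "nonpositive")
})

test_that("camera jitter is an identity at zero amplitude and reproducible", {
  s <- genDriftingGrating(c(24, 24), 8, 20, 1, 1, 6)
  expect_identical(applyCameraJitter(s, 0), s)
  j1 <- applyCameraJitter(s, 0.5, seed = 9)
  j2 <- applyCameraJitter(s, 0.5, seed = 9)
  expect_identical(frames(j1), frames(j2))
  expect_gt(max(abs(frames(j1) - frames(s))), 1e-3)
  expect_identical(dim(frames(j1)), dim(frames(s)))
})

test_that("jitter increments are zero-mean with the requested RMS", {
  walk <- motionEnergy:::jitterWalk(1000, 0.8, seed = 3)
  inc <- apply(walk, 2, diff)
  inc <- rbind(walk[1, ], inc)  # first displacement is the first increment
  expect_lt(max(abs(colMeans(inc))), 0.1 * 0.8)
  rms <- sqrt(mean(rowSums(inc^2)))
  expect_lt(abs(rms - 0.8) / 0.8, 0.1)
})

test_that("PNG round trips preserve shape, count and 8-bit values", {
  dir <- withr::local_tempdir()
  s <- genDriftingGrating(c(17, 23), 8, 75, 1.3, 0.9, 3)
  writeFrames(s, dir)
  back <- readFrames(dir)
  expect_identical(dim(frames(back)), dim(frames(s)))
  expect_equal(length(back), 3L)
  expect_lt(max(abs(frames(back) - frames(s))), 1 / 255)

  empty <- withr::local_tempdir()
  expect_error(readFrames(empty), "no PNG frames")
  expect_error(readFrames(file.path(empty, "nope")), "no such directory")
})

test_that("color PNG input is converted to Rec.601 luminance", {
  dir <- withr::local_tempdir()
  rgb <- array(0, c(8, 8, 3))
  rgb[, , 1] <- 1; rgb[, , 2] <- 1  # yellow
  png::writePNG(rgb, file.path(dir, "frame_0001.png"))
  lum <- frames(readFrames(dir))[, , 1]
  expect_equal(max(abs(lum - (0.299 + 0.587))), 0, tolerance = 1 / 255)
})
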