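test_that("spatial quadrature pair has the required symmetries and normalization", {
  sp <- makeSpatialQuadrature(8, 4, 30, 15)
  rot180 <- function(m) m[nrow(m):1, ncol(m):1]
  expect_identical(sp@even, rot180(sp@even))
  expect_equal(max(abs(sp@odd + rot180(sp@odd))), 0)
  expect_lt(abs(sum(sp@even)), 1e-6)
  expect_lt(abs(sum(sp@odd)), 1e-6)
  expect_equal(sum(sp@even^2), 1, tolerance = 1e-12)
  expect_equal(sum(sp@odd^2), 1, tolerance = 1e-12)
  expect_true(validObject(sp))

  expect_error(makeSpatialQuadrature(8, 4, 0, 14), "odd")
  expect_error(makeSpatialQuadrature(8, -1, 0, 15), "sigma")
})

test_that("squared quadrature response is invariant to stimulus spatial phase", {
  sp <- makeSpatialQuadrature(8, 4, 30, 15)
  resp <- sapply(seq(0, 360 - 22.5, by = 22.5), function(ph) {
    g <- frames(genDriftingGrating(c(33, 33), 8, 30, 0, 1, 1,
                                   phaseDeg = ph))[, , 1]
    ctr <- g[10:24, 10:24]
    sum(sp@even * ctr)^2 + sum(sp@odd * ctr)^2
  })
  expect_lt((max(resp) - min(resp)) / mean(resp), 0.01)
})

test_that("temporal pair is biphasic with fast peaking before slow", {
  tp <- makeTemporalPair(0.5, 11)
  expect_lt(which.max(tp@fast), which.max(tp@slow))
  for (f in list(tp@fast, tp@slow)) {
    sg <- sign(f[f != 0])
    expect_equal(sum(diff(sg) != 0), 1L)
    expect_lt(abs(f[length(f)]), 0.01 * max(abs(f)))
  }
  expect_true(validObject(tp))
})

test_that("doubling tau with doubled support scales the peak location by two", {
  t1 <- makeTemporalPair(0.5, 11)
  t2 <- makeTemporalPair(1.0, 21)
  # peak lags in frames (tap index is lag + 1)
  for (nm in c("fast", "slow")) {
    p1 <- which.max(slot(t1, nm)) - 1L
    p2 <- which.max(slot(t2, nm)) - 1L
    expect_lte(abs(p2 - 2L * p1), 1L)
  }
})

test_that("too-short temporal support raises the parameter error", {
  # 9 taps at tau = 1.5 truncate the slow lobe before its sign change
  expect_error(makeTemporalPair(1.5, 9), "support too short")
  expect_error(makeTemporalPair(0.5, 4), "nTaps")
  expect_error(makeTemporalPair(0, 11), "tau")
})

test_that("bank directions are exact and opposite channels agree on static input", {
  bank <- smallBank()
  expect_identical(channelDirections(bank), 360 * (0:7) / 8)
  expect_error(buildFilterBank(K = 6L + 1L), "even")
  expect_error(buildFilterBank(K = 2L), ">= 4")

  img <- frames(genDriftingGrating(c(24, 24), 8, 20, 0, 1, 1))[, , 1]
  Tn <- temporalDepth(bank)
  vol <- motionEnergy:::frameVolume(Tn, 24, 24)
  for (t in seq_len(Tn)) vol <- pushFrame(vol, img)
  E <- computeEnergy(vol, bank)@E
  for (k in 1:4) expect_equal(E[, , k], E[, , k + 4], tolerance = 1e-10)
})

test_that("the argmax channel matches the nearest direction for a 16-direction sweep", {
  bank <- smallBank()
  Tn <- temporalDepth(bank)
  dirs <- seq(0, 360 - 22.5, by = 22.5)
  th <- channelDirections(bank)
  for (d in dirs) {
    s <- genDriftingGrating(c(32, 32), 8, d, 1, 1, Tn)
    res <- processStream(s, bank, keepEnergy = TRUE)
    m <- apply(res$energy[[1]]@E[9:24, 9:24, ], 3, mean)
    best <- th[which.max(m)]
    nearest <- min(abs(wrapAngle(th - d)))
    expect_lte(abs(wrapAngle(best - d)), nearest + 1e-9)
  }
})

test_that("energy peaks at a finite nonzero speed and falls at zero and 4x", {
  bank <- buildFilterBank()
  Tn <- temporalDepth(bank)
  speeds <- c(0, 0.5, 1, 1.5, 2)
  en <- sapply(speeds, function(v) {
    s <- genDriftingGrating(c(48, 48), 8, 0, v, 1, Tn)
    E <- processStream(s, bank, keepEnergy = TRUE)$energy[[1]]@E
    mean(E[17:32, 17:32, 1])
  })
  vStar <- speeds[which.max(en)]
  expect_gt(vStar, 0)
  e4 <- {
    s <- genDriftingGrating(c(48, 48), 8, 0, 4 * vStar, 1, Tn)
    E <- processStream(s, bank, keepEnergy = TRUE)$energy[[1]]@E
    mean(E[17:32, 17:32, 1])
  }
  expect_lt(en[1], max(en))        # static is weaker than the peak
  expect_lt(e4, max(en))           # so is 4x the preferred speed
})

test_that("filter banks serialize and restore faithfully", {
  path <- withr::local_tempfile(fileext = ".rds")
  bank <- smallBank()
  writeFilterBank(bank, path)
  back <- readFilterBank(path)
  expect_identical(back@params, bank@params)
  expect_equal(back@channels[[3]]@kernelEven, bank@channels[[3]]@kernelEven)
})
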