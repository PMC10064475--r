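test_that("frame volume behaves as a FIFO buffer", {
  vol <- motionEnergy:::frameVolume(4, 6, 6)
  expect_false(isWarm(vol))
  f1 <- matrix(0.2, 6, 6)
  for (i in 1:4) vol <- pushFrame(vol, f1)
  expect_true(isWarm(vol))
  expect_true(all(vol@buffer == 0.2))

  f2 <- matrix(0.9, 6, 6)
  vol <- pushFrame(vol, f2)
  expect_true(isWarm(vol))
  expect_identical(vol@buffer[, , 4], f2)   # newest frame is last

  # pushing T + 5 frames retains exactly the last T
  vol <- motionEnergy:::frameVolume(4, 6, 6)
  for (i in 1:9) vol <- pushFrame(vol, matrix(i / 10, 6, 6))
  expect_identical(dim(vol@buffer)[3], 4L)
  expect_equal(vol@buffer[1, 1, ], c(0.6, 0.7, 0.8, 0.9))

  expect_error(pushFrame(vol, matrix(0, 5, 6)), "shape")
})

test_that("a cold buffer raises the not-ready condition", {
  bank <- smallBank()
  vol <- motionEnergy:::frameVolume(temporalDepth(bank), 16, 16)
  vol <- pushFrame(vol, matrix(0.5, 16, 16))
  expect_error(computeEnergy(vol, bank), class = "motionEnergyNotReady")
})

test_that("static volumes carry no opponent energy and contrast scales quadratically", {
  bank <- smallBank()
  Tn <- temporalDepth(bank)
  img <- frames(genDriftingGrating(c(24, 24), 8, 63, 0, 0.8, 1))[, , 1]
  vol <- motionEnergy:::frameVolume(Tn, 24, 24)
  for (t in seq_len(Tn)) vol <- pushFrame(vol, img)
  E <- computeEnergy(vol, bank)
  O <- computeOpponent(E)
  expect_lt(max(abs(O@O)), 1e-6 * max(E@E))

  # contrast scaling about the mean: E is quadratic in contrast
  sA <- genDriftingGrating(c(24, 24), 8, 45, 1, 0.8, Tn)
  sB <- genDriftingGrating(c(24, 24), 8, 45, 1, 0.4, Tn)
  EA <- processStream(sA, bank, keepEnergy = TRUE)$energy[[1]]@E
  EB <- processStream(sB, bank, keepEnergy = TRUE)$energy[[1]]@E
  expect_lt(max(abs(EA - 4 * EB)) / max(EA), 1e-5)
})

test_that("streaming equals the brute-force 3D convolution oracle", {
  bank <- smallBank()
  set.seed(7)
  N <- 32
  f <- array(runif(18 * 20 * N), c(18, 20, N))
  seq <- frameSequence(f)
  res <- processStream(seq, bank, keepEnergy = TRUE)
  expect_length(res$opponent, N - temporalDepth(bank) + 1L)
  for (i in c(1L, 7L, length(res$opponent))) {
    E <- oracleEnergy(f, bank, res$frameIndex[i])
    expect_lt(max(abs(E - res$energy[[i]]@E)), 1e-5)
    expect_lt(max(abs(oracleOpponent(E) - res$opponent[[i]]@O)), 1e-5)
  }
})

test_that("single-shot energy matches the stream and the oracle on a grating", {
  bank <- smallBank()
  Tn <- temporalDepth(bank)
  s <- genDriftingGrating(c(24, 24), 8, 0, 1, 1, Tn)
  f <- frames(s)
  vol <- motionEnergy:::frameVolume(Tn, 24, 24)
  for (t in seq_len(Tn)) vol <- pushFrame(vol, f[, , t])
  E1 <- computeEnergy(vol, bank)@E
  E2 <- processStream(s, bank, keepEnergy = TRUE)$energy[[1]]@E
  expect_equal(E1, E2, tolerance = 1e-12)
  Eo <- oracleEnergy(f, bank, Tn)
  expect_lt(max(abs(E1 - Eo)), 1e-5)
  # rightward grating drives the rightward channel hardest, and its
  # opponent energy is positive at grating pixels
  O <- computeOpponent(new("EnergyMap", E = E1,
                           thetaDeg = channelDirections(bank)))
  expect_equal(which.max(apply(E1[9:16, 9:16, ], 3, mean)), 1L)
  expect_true(all(O@O[9:16, 9:16, 1] > 0))
})

test_that("opponent maps are exactly antisymmetric and vanish for counterphase input", {
  bank <- smallBank()
  Tn <- temporalDepth(bank)
  cp <- genCounterphaseGrating(c(24, 24), 8, 0, 0.125, 1, Tn + 6)
  res <- processStream(cp, bank, keepEnergy = TRUE)
  for (i in seq_along(res$opponent)) {
    O <- res$opponent[[i]]@O
    expect_identical(max(abs(O + O[, , c(5:8, 1:4)])), 0)
    expect_lt(max(abs(O)), 0.05 * max(res$energy[[i]]@E))
  }
})

test_that("stream output count and constant-sequence behaviour match the contracts", {
  bank <- smallBank()
  Tn <- temporalDepth(bank)
  const <- frameSequence(array(0.37, c(12, 12, Tn + 3)))
  res <- processStream(const, bank)
  expect_length(res$opponent, 4L)
  for (o in res$opponent) expect_lt(max(abs(o@O)), 1e-12)
  expect_error(processStream(frameSequence(array(0.4, c(8, 8, Tn - 1))), bank),
               "shorter")
})

test_that("time reversal swaps opposite channels on steady drifting input", {
  bank <- smallBank()
  Tn <- temporalDepth(bank)
  N <- Tn + 8
  s <- genDriftingGrating(c(40, 40), 8, 60, 1.2, 1, N)
  rev <- frameSequence(frames(s)[, , N:1])
  o1 <- processStream(s, bank)$opponent
  o2 <- processStream(rev, bank)$opponent
  L <- length(o1)
  mx <- max(abs(o1[[1]]@O))
  ctr <- 13:28  # interior, clear of the reflecting border
  for (i in c(1L, L)) for (k in 1:8) {
    k2 <- ((k - 1 + 4) %% 8) + 1
    expect_lt(max(abs(o2[[i]]@O[ctr, ctr, k2] - o1[[L + 1 - i]]@O[ctr, ctr, k])),
              1e-5 * mx)
  }
})

test_that("a 90-degree frame rotation permutes channels by K/4", {
  bank <- smallBank()
  Tn <- temporalDepth(bank)
  s <- genDriftingGrating(c(32, 32), 8, 30, 1, 1, Tn)
  f <- frames(s)
  fr <- array(0, dim(f))
  for (t in seq_len(Tn)) fr[, , t] <- rot90cw(f[, , t])
  E1 <- processStream(s, bank, keepEnergy = TRUE)$energy[[1]]@E
  E2 <- processStream(frameSequence(fr), bank, keepEnergy = TRUE)$energy[[1]]@E
  for (k in 1:8) {
    k2 <- ((k - 1 + 2) %% 8) + 1
    expect_lt(max(abs(E2[, , k2] - rot90cw(E1[, , k]))), 1e-5 * max(E1))
  }
})

test_that("divisive normalization rescales opponent maps without changing sign structure", {
  bank <- smallBank()
  Tn <- temporalDepth(bank)
  s <- genDriftingGrating(c(24, 24), 8, 0, 1, 0.6, Tn)
  raw <- processStream(s, bank)$opponent[[1]]@O
  nrm <- processStream(s, bank, normalize = TRUE)$opponent[[1]]@O
  expect_identical(max(abs(nrm + nrm[, , c(5:8, 1:4)])), 0)
  expect_true(all(sign(nrm) == sign(raw)))
  expect_false(isTRUE(all.equal(raw, nrm)))
})
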