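# Shared fixtures and independent oracles for the test suite.
# Everything is built in code; no stored data.

# a compact bank for fast tests (same temporal defaults as the full bank)
smallBank <- function(kernelSize = 9L) buildFilterBank(kernelSize = kernelSize)

# Independent brute-force oracle: full 3D correlation of the stored
# space-time kernels with the reflect-padded volume (causal in time,
# evaluated at frame tOut), by direct summation over every kernel entry.
# Deliberately shares no code path with the streaming engine.
oracleEnergy <- function(f, bank, tOut) {
  d <- dim(f)
  Tn <- temporalDepth(bank)
  ks <- bank@params$kernelSize
  hw <- (ks - 1L) %/% 2L
  P <- array(0, c(d[1] + 2 * hw, d[2] + 2 * hw, d[3]))
  ridx <- c(hw:1, 1:d[1], d[1]:(d[1] - hw + 1))
  cidx <- c(hw:1, 1:d[2], d[2]:(d[2] - hw + 1))
  for (t in seq_len(d[3])) P[, , t] <- f[ridx, cidx, t]
  K <- nChannels(bank)
  E <- array(0, c(d[1], d[2], K))
  for (k in seq_len(K)) {
    ch <- bank@channels[[k]]
    re <- matrix(0, d[1], d[2])
    ro <- matrix(0, d[1], d[2])
    for (l in seq_len(Tn)) {
      fr <- P[, , tOut - (l - 1L)]
      for (i in seq_len(ks)) for (j in seq_len(ks)) {
        blk <- fr[i:(i + d[1] - 1L), j:(j + d[2] - 1L)]
        re <- re + ch@kernelEven[i, j, l] * blk
        ro <- ro + ch@kernelOdd[i, j, l] * blk
      }
    }
    E[, , k] <- re^2 + ro^2
  }
  E
}

oracleOpponent <- function(E) {
  K <- dim(E)[3]
  E - E[, , ((seq_len(K) - 1L + K %/% 2L) %% K) + 1L]
}

# circular mean over a matrix region (weights = magnitudes)
flowMeanAngle <- function(flow, rows, cols) {
  a <- flow@angleDeg[rows, cols]
  m <- flow@magnitude[rows, cols]
  keep <- !is.na(a)
  cm <- motionEnergy:::circularMean(as.vector(a[keep]), as.vector(m[keep]))
  cm$meanDeg
}

# a synthetic FlowField from angle/magnitude matrices
makeFlow <- function(angleDeg, magnitude) {
  angleDeg[magnitude == 0] <- NA_real_
  new("FlowField", angleDeg = motionEnergy:::wrapAngle(angleDeg),
      magnitude = magnitude)
}

# synthetic ring flow: every annulus pixel moves at the local radial
# direction + phase offset (deg, clockwise +); background magnitude 0
ringFlow <- function(size, center, rMin, rMax, phaseOffsetDeg, mag = 1) {
  g <- expand.grid(y = seq_len(size[1]), x = seq_len(size[2]))
  dx <- g$x - center[1]; dy <- g$y - center[2]
  r <- sqrt(dx^2 + dy^2)
  ann <- r >= rMin & r <= rMax
  ang <- matrix(screenAngle(dx, dy) + phaseOffsetDeg, size[1], size[2])
  m <- matrix(ifelse(ann, mag, 0), size[1], size[2])
  makeFlow(ang, m)
}

# 90-degree clockwise (as displayed) rotation of a matrix; direction
# theta maps to theta + 90 and channels shift by K/4
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
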