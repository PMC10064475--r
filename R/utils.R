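# Internal geometry / numerics helpers.
#
# Angle convention used throughout the package ("screen convention"):
# x increases rightward (columns), y increases downward (rows), angles are
# measured in degrees from the +x axis, increasing clockwise as displayed.
# With y pointing down, atan2(dy, dx) already yields this convention, so a
# single helper (screenAngle) is the only place direction vectors are turned
# into angles.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Wrap angles to (-180, 180]
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @examples
#' wrapAngle(c(190, -270, 180, 360))
#' @export
wrapAngle <- function(deg) {
  w <- deg %% 360
  hi <- !is.na(w) & w > 180
  w[hi] <- w[hi] - 360
  w
}

#' Screen-convention angle of a displacement vector
#'
#' Converts displacement components (dx rightward, dy downward) into an angle
#' in degrees, clockwise-positive as displayed, in (-180, 180].
#'
#' @param dx,dy displacement components in pixels (x rightward, y downward).
#' @return angle in degrees.
#' @export
screenAngle <- function(dx, dy) {
  wrapAngle(rad2deg(atan2(dy, dx)))
}

# circular mean of angles (deg) with nonnegative weights; returns
# list(meanDeg, resultantLength, sumWeight); NA mean if total weight is 0
circularMean <- function(deg, w = rep(1, length(deg))) {
  sw <- sum(w)
  if (length(deg) == 0L || sw <= 0) {
    return(list(meanDeg = NA_real_, resultantLength = NA_real_, sumWeight = 0))
  }
  a <- deg2rad(deg)
  cx <- sum(w * cos(a)) / sw
  sx <- sum(w * sin(a)) / sw
  list(meanDeg = wrapAngle(rad2deg(atan2(sx, cx))),
       resultantLength = sqrt(cx^2 + sx^2),
       sumWeight = sw)
}

# symmetric (edge-duplicating) reflection index for padding
reflectIndex <- function(n, pad) {
  stopifnot(pad >= 0, pad <= n)
  if (pad == 0) return(seq_len(n))
  c(pad:1, 1:n, n:(n - pad + 1))
}

padReflect <- function(m, pad) {
  m[reflectIndex(nrow(m), pad), reflectIndex(ncol(m), pad), drop = FALSE]
}

# smallest 5-smooth integer >= n (keeps R's mixed-radix FFT fast)
nextFastSize <- function(n) {
  repeat {
    k <- n
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(n)
    n <- n + 1
  }
}

# Plan for repeated same-size "same" correlation with reflect borders.
# Kernels are applied as correlation (no flip), matching the way oriented
# kernels are specified. Returns a closure applying all kernels to one frame.
makeConvPlan <- function(H, W, kernels) {
  ks <- unique(vapply(kernels, function(k) nrow(k), 1L))
  stopifnot(length(ks) == 1L, ks %% 2 == 1L,
            all(vapply(kernels, function(k) ncol(k) == ks, TRUE)))
  hw <- (ks - 1L) %/% 2L
  N1 <- nextFastSize(H + 2L * hw)
  N2 <- nextFastSize(W + 2L * hw)
  kfft <- lapply(kernels, function(k) {
    kp <- matrix(0, N1, N2)
    kp[1:ks, 1:ks] <- k
    Conj(stats::fft(kp))
  })
  function(frame) {
    P <- matrix(0, N1, N2)
    P[seq_len(H + 2L * hw), seq_len(W + 2L * hw)] <- padReflect(frame, hw)
    Ff <- stats::fft(P)
    lapply(kfft, function(kf) {
      Re(stats::fft(Ff * kf, inverse = TRUE))[seq_len(H), seq_len(W)] / (N1 * N2)
    })
  }
}

# single-kernel convenience (used by tests/oracles sparingly)
convSameReflect <- function(img, kernel) {
  makeConvPlan(nrow(img), ncol(img), list(kernel))(img)[[1L]]
}

# Evaluate code with a temporarily seeded RNG, restoring global RNG state.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# reflect a continuous coordinate into [0.5, n + 0.5] (symmetric borders)
reflectCoord <- function(x, n) {
  p <- (x - 0.5) %% (2 * n)
  p <- pmin(p, 2 * n - p)
  p + 0.5
}

# bilinear sampling of matrix m at continuous (row, col) coordinates with
# symmetric reflection outside the support
bilinearSampleReflect <- function(m, rows, cols) {
  H <- nrow(m); W <- ncol(m)
  r <- reflectCoord(rows, H)
  c <- reflectCoord(cols, W)
  r0 <- pmax(1L, pmin(H, floor(r))); r1 <- pmin(H, r0 + 1L)
  c0 <- pmax(1L, pmin(W, floor(c))); c1 <- pmin(W, c0 + 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- m[cbind(r0, c0)]; v01 <- m[cbind(r0, c1)]
  v10 <- m[cbind(r1, c0)]; v11 <- m[cbind(r1, c1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# vectorized HSV -> RGB on numeric vectors in [0,1]; returns cbind(r,g,b)
hsv2rgbNum <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h6))
  sel <- i == 0; r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- i == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- i == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- i == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- i == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- i == 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  cbind(r = r, g = g, b = b)
}
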