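# Synthetic stimulus generators.
#
# All generators render the analytic pattern at continuous coordinates per
# frame (no rasterized-template shifting), so sub-pixel motion is exact and
# free of interpolation artifacts. Pixel (r, c) has position x = c, y = r;
# see utils.R for the screen angle convention.

pixelGrid <- function(size) {
  H <- size[1]; W <- size[2]
  list(X = matrix(rep(seq_len(W), each = H), H, W),
       Y = matrix(rep(seq_len(H), times = W), H, W))
}

#' Drifting sinusoidal grating
#'
#' Luminance `mean + (contrast/2) * cos(2*pi*(u - speed*t)/wavelength)` with
#' u the coordinate along `orientationDeg` (the motion direction, screen
#' convention): a rigid translation perpendicular to the stripes at `speed`
#' px/frame. The canonical probe stimulus for the energy model.
#'
#' @param size c(height, width) in px.
#' @param wavelengthPx spatial wavelength, >= 2 px.
#' @param orientationDeg drift direction in degrees (screen convention:
#'   0 = rightward, 90 = downward as displayed).
#' @param speedPxPerFrame drift speed in px/frame (signed; negative drifts
#'   opposite to `orientationDeg`).
#' @param contrast peak-to-peak luminance contrast in [0, 1].
#' @param nFrames number of frames.
#' @param meanLuminance mean level; `meanLuminance +/- contrast/2` must stay
#'   inside [0, 1].
#' @param phaseDeg carrier phase offset at the origin, degrees.
#' @return a [FrameSequence-class].
#' @export
genDriftingGrating <- function(size, wavelengthPx, orientationDeg,
                               speedPxPerFrame, contrast, nFrames,
                               meanLuminance = 0.5, phaseDeg = 0) {
  checkGratingParams(wavelengthPx, contrast, meanLuminance)
  g <- pixelGrid(size)
  th <- deg2rad(orientationDeg)
  u <- g$X * cos(th) + g$Y * sin(th)
  out <- array(0, c(size[1], size[2], nFrames))
  for (t in seq_len(nFrames)) {
    ph <- 2 * pi * (u - speedPxPerFrame * (t - 1)) / wavelengthPx + deg2rad(phaseDeg)
    out[, , t] <- meanLuminance + (contrast / 2) * cos(ph)
  }
  frameSequence(out)
}

#' Counterphase (contrast-reversing) grating
#'
#' A standing grating whose contrast reverses sinusoidally in time:
#' `mean + (contrast/2) * cos(2*pi*u/wavelength) * cos(2*pi*f*t)`. By the
#' product-to-sum identity this equals the superposition of two
#' opposite-drifting gratings at half contrast, which is why a balanced
#' opponent stage cancels on it.
#'
#' @inheritParams genDriftingGrating
#' @param temporalFreq contrast-reversal frequency in cycles/frame.
#' @return a [FrameSequence-class].
#' @export
genCounterphaseGrating <- function(size, wavelengthPx, orientationDeg,
                                   temporalFreq, contrast, nFrames,
                                   meanLuminance = 0.5, phaseDeg = 0) {
  checkGratingParams(wavelengthPx, contrast, meanLuminance)
  g <- pixelGrid(size)
  th <- deg2rad(orientationDeg)
  u <- g$X * cos(th) + g$Y * sin(th)
  carrier <- cos(2 * pi * u / wavelengthPx + deg2rad(phaseDeg))
  out <- array(0, c(size[1], size[2], nFrames))
  for (t in seq_len(nFrames)) {
    out[, , t] <- meanLuminance +
      (contrast / 2) * carrier * cos(2 * pi * temporalFreq * (t - 1))
  }
  frameSequence(out)
}

checkGratingParams <- function(wavelengthPx, contrast, meanLuminance) {
  if (wavelengthPx < 2) stop("wavelengthPx must be >= 2 px")
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0, 1]")
  if (meanLuminance - contrast / 2 < -1e-12 ||
      meanLuminance + contrast / 2 > 1 + 1e-12)
    stop("meanLuminance +/- contrast/2 must stay inside [0, 1]")
  invisible(TRUE)
}

# partial-coverage (antialiased) indicator of [lo, hi] sampled at centers v
coverage1d <- function(v, lo, hi) {
  pmax(0, pmin(v + 0.5, hi) - pmax(v - 0.5, lo))
}

#' Stepping-feet stimulus
#'
#' Renders the classical stepping-feet display: a bright and a dark foot,
#' vertically aligned, translating rightward at identical constant speed
#' over a vertical square-wave grating. The colored feet of the original
#' display are rendered as their luminances (the model is luminance-driven).
#' Foot edges are antialiased by exact pixel coverage so sub-pixel speeds
#' translate rigidly.
#'
#' @param spec a [SteppingFeetSpec-class].
#' @param size c(height, width) in px.
#' @param nFrames number of frames.
#' @param startX left edge of the feet at frame 1 (px). The feet must stay
#'   inside the frame for all frames, otherwise an error is raised.
#' @return a [FrameSequence-class].
#' @export
genSteppingFeet <- function(spec, size, nFrames, startX = 4) {
  validObject(spec)
  H <- size[1]; W <- size[2]
  fw <- spec@footSize[1]; fh <- spec@footSize[2]
  endX <- startX + spec@speed * (nFrames - 1) + fw
  if (startX < 0 || endX > W)
    stop("feet leave the frame: reduce speed/nFrames or widen the frame")
  totalH <- 2 * fh + spec@verticalGap
  if (totalH > H) stop("feet do not fit vertically in the frame")
  y1 <- (H - totalH) / 2          # top of bright foot
  y2 <- y1 + fh + spec@verticalGap  # top of dark foot

  # background: vertical square-wave grating about mid-gray
  xs <- seq_len(W)
  stripe <- ifelse(((xs - 1) %% spec@gratingPeriod) < spec@gratingPeriod / 2,
                   0.5 + spec@backgroundContrast / 2,
                   0.5 - spec@backgroundContrast / 2)
  bg <- matrix(rep(stripe, each = H), H, W)

  ys <- seq_len(H)
  covY1 <- coverage1d(ys, y1, y1 + fh)
  covY2 <- coverage1d(ys, y2, y2 + fh)
  out <- array(0, c(H, W, nFrames))
  for (t in seq_len(nFrames)) {
    left <- startX + spec@speed * (t - 1)
    covX <- coverage1d(xs, left, left + fw)
    f <- bg
    a1 <- outer(covY1, covX)   # coverage of bright foot
    a2 <- outer(covY2, covX)   # coverage of dark foot
    f <- f * (1 - a1) + spec@footLuminances[1] * a1
    f <- f * (1 - a2) + spec@footLuminances[2] * a2
    out[, , t] <- f
  }
  frameSequence(out)
}

# centroid x-positions of the two feet in one rendered frame (used by tests)
feetCentroids <- function(frame, spec, size) {
  H <- size[1]
  fh <- spec@footSize[2]
  totalH <- 2 * fh + spec@verticalGap
  y1 <- (H - totalH) / 2
  rows1 <- which(seq_len(H) > y1 & seq_len(H) <= y1 + fh)
  rows2 <- rows1 + fh + spec@verticalGap
  cx <- function(rows, lum) {
    w <- abs(colMeans(frame[rows, , drop = FALSE]) - 0.5)
    # deviation from mid-gray isolates the foot against any stripe phase
    sum(w * seq_len(ncol(frame))) / sum(w)
  }
  c(bright = cx(rows1), dark = cx(rows2))
}

#' Ring stimulus (textured annulus or Gabor-element ring)
#'
#' For `solid_texture`, an annulus with a Gaussian radial profile
#' (s.d. `elementSigma`) carrying an `nElements`-fold angular luminance
#' modulation. For `gabor_elements`, `nElements` Gabor micropatterns on the
#' circle, each carrier wave vector tilted `elementOrientationOffsetDeg`
#' clockwise from its local outward radial direction; elements are rendered
#' additively on a mid-gray background and clipped to [0, 1]. Per frame the
#' radius grows by `expansionRate` and the pattern rotates by
#' `rotationRate` (clockwise positive as displayed).
#'
#' @param spec a [RingStimulusSpec-class].
#' @param size c(height, width) in px.
#' @param nFrames number of frames.
#' @param allowClipping if FALSE (default) an error is raised when the ring
#'   (radius + 3 element sigma) leaves the frame or the radius becomes
#'   nonpositive; TRUE permits looming rings to outgrow the frame, as in
#'   the expanding Pinna-Brelstaff demonstration, rendering only the
#'   visible part.
#' @return a [FrameSequence-class].
#' @export
genRingStimulus <- function(spec, size, nFrames, allowClipping = FALSE) {
  validObject(spec)
  H <- size[1]; W <- size[2]
  cx <- spec@center[1]; cy <- spec@center[2]
  radii <- spec@baseRadius + spec@expansionRate * (seq_len(nFrames) - 1)
  if (min(radii) <= 0) stop("ring radius becomes nonpositive")
  margin <- 3 * spec@elementSigma
  maxInside <- min(cx - 1, cy - 1, W - cx, H - cy)
  if (!allowClipping && max(radii) + margin > maxInside)
    stop("ring leaves the frame; enlarge the frame or set allowClipping = TRUE")

  g <- pixelGrid(size)
  dx <- g$X - cx; dy <- g$Y - cy
  out <- array(0.5, c(H, W, nFrames))
  if (spec@elementKind == "solid_texture") {
    r <- sqrt(dx^2 + dy^2)
    alpha <- atan2(dy, dx)  # position angle, clockwise + as displayed
    for (t in seq_len(nFrames)) {
      rot <- deg2rad(spec@rotationRate) * (t - 1)
      env <- exp(-(r - radii[t])^2 / (2 * spec@elementSigma^2))
      tex <- cos(spec@nElements * (alpha - rot))
      out[, , t] <- 0.5 + (spec@contrast / 2) * env * tex
    }
  } else {
    lam <- spec@elementWavelength
    sig <- spec@elementSigma
    half <- ceiling(4 * sig)
    baseAng <- 2 * pi * (seq_len(spec@nElements) - 1) / spec@nElements
    for (t in seq_len(nFrames)) {
      rot <- deg2rad(spec@rotationRate) * (t - 1)
      f <- matrix(0, H, W)
      for (j in seq_len(spec@nElements)) {
        aj <- baseAng[j] + rot
        ex <- cx + radii[t] * cos(aj)
        ey <- cy + radii[t] * sin(aj)
        c0 <- max(1L, floor(ex - half)); c1 <- min(W, ceiling(ex + half))
        r0 <- max(1L, floor(ey - half)); r1 <- min(H, ceiling(ey + half))
        if (c0 > c1 || r0 > r1) next
        # carrier wave vector: local radial direction + clockwise tilt
        psi <- aj + deg2rad(spec@elementOrientationOffsetDeg)
        xs <- seq(c0, c1); ys <- seq(r0, r1)
        lx <- matrix(rep(xs - ex, each = length(ys)), length(ys))
        ly <- matrix(rep(ys - ey, times = length(xs)), length(ys))
        d2 <- lx^2 + ly^2
        patch <- exp(-d2 / (2 * sig^2)) *
          cos(2 * pi * (lx * cos(psi) + ly * sin(psi)) / lam)
        f[r0:r1, c0:c1] <- f[r0:r1, c0:c1] + patch
      }
      out[, , t] <- pmin(1, pmax(0, 0.5 + (spec@contrast / 2) * f))
    }
  }
  frameSequence(out)
}

# seeded zero-mean random-walk displacement (n x 2 matrix of cumulative
# dx, dy); increment vectors have RMS length rmsAmplitudePx
jitterWalk <- function(n, rmsAmplitudePx, seed = NULL) {
  if (rmsAmplitudePx < 0) stop("rmsAmplitudePx must be >= 0")
  inc <- withSeed(seed, matrix(stats::rnorm(2 * n, sd = rmsAmplitudePx / sqrt(2)),
                               ncol = 2))
  apply(inc, 2, cumsum)
}

#' Camera jitter (fixational eye-movement simulation)
#'
#' Globally translates each frame by a seeded random-walk displacement with
#' zero-mean Gaussian increments (per-frame increment vectors have RMS
#' length `rmsAmplitudePx`), emulating fixational eye movements by camera
#' motion. Frames are resampled bilinearly with symmetric border reflection
#' so the frame size is constant and no dark border sweeps in.
#'
#' @param seq a [FrameSequence-class].
#' @param rmsAmplitudePx RMS per-frame displacement increment in px (>= 0;
#'   0 returns the input unchanged).
#' @param seed integer seed making the walk reproducible.
#' @return a [FrameSequence-class] of the same shape.
#' @export
applyCameraJitter <- function(seq, rmsAmplitudePx, seed = 1L) {
  if (rmsAmplitudePx < 0) stop("rmsAmplitudePx must be >= 0")
  if (rmsAmplitudePx == 0) return(seq)
  f <- frames(seq)
  d <- dim(f)
  disp <- jitterWalk(d[3], rmsAmplitudePx, seed)
  g <- pixelGrid(d[1:2])
  out <- array(0, d)
  for (t in seq_len(d[3])) {
    # content shifted by (dx, dy): sample source at (x - dx, y - dy)
    out[, , t] <- matrix(
      bilinearSampleReflect(f[, , t],
                            as.vector(g$Y) - disp[t, 2],
                            as.vector(g$X) - disp[t, 1]),
      d[1], d[2])
  }
  frameSequence(out, frameRate(seq))
}
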