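#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core containers
## ---------------------------------------------------------------------------

#' FrameSequence: an ordered stack of luminance frames
#'
#' A spatiotemporal volume: `frames` is an H x W x T array of luminance
#' values in [0, 1] (rows = y downward, columns = x rightward), plus a
#' nominal frame rate carried as metadata only.
#'
#' @slot frames numeric array, H x W x T, values in [0, 1].
#' @slot frameRate frames per second (metadata; does not affect computation).
#' @exportClass FrameSequence
setClass("FrameSequence",
  representation(frames = "array", frameRate = "numeric"),
  prototype(frames = array(0, c(1, 1, 1)), frameRate = 30))

setValidity("FrameSequence", function(object) {
  f <- object@frames
  if (length(dim(f)) != 3L) return("frames must be an H x W x T array")
  if (dim(f)[3] < 1L) return("sequence must contain at least one frame")
  if (anyNA(f) || !all(is.finite(f))) return("frames contain non-finite values")
  if (min(f) < -1e-9 || max(f) > 1 + 1e-9) return("frame values must lie in [0, 1]")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("frameRate must be a single positive number")
  TRUE
})

#' Construct a FrameSequence
#'
#' @param frames H x W x T numeric array (or a list of equal-shaped H x W
#'   matrices) with values in [0, 1].
#' @param frameRate nominal frames per second (metadata only).
#' @return a [FrameSequence-class] object.
#' @export
frameSequence <- function(frames, frameRate = 30) {
  if (is.list(frames)) {
    d <- dim(frames[[1L]])
    if (!all(vapply(frames, function(m) identical(dim(m), d), TRUE)))
      stop("all frames must have the same shape")
    frames <- array(unlist(frames, use.names = FALSE), c(d, length(frames)))
  }
  frames <- pmin(pmax(frames, 0), 1)  # clip tiny numeric excursions
  new("FrameSequence", frames = frames, frameRate = frameRate)
}

#' @describeIn frameSequence number of frames
#' @param x a FrameSequence.
#' @export
setMethod("length", "FrameSequence", function(x) dim(x@frames)[3])

#' Accessors for FrameSequence
#'
#' `frames()` returns the underlying H x W x T array, `frameRate()` the
#' nominal frame rate.
#'
#' @param x a [FrameSequence-class].
#' @return `frames()`: numeric array; `frameRate()`: a number.
#' @aliases frames frameRate
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)

#' @rdname frames
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname frames
#' @export
setMethod("frameRate", "FrameSequence", function(x) x@frameRate)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frame(s) of %d x %d px, %.4g fps\n",
              d[3], d[1], d[2], object@frameRate))
  cat(sprintf("  luminance range [%.3f, %.3f]\n",
              min(object@frames), max(object@frames)))
})

## ---------------------------------------------------------------------------
## Filter bank components
## ---------------------------------------------------------------------------

#' Spatial quadrature pair (Gabor cosine/sine kernels)
#'
#' @slot even,odd square 2D kernels; even is cosine-phase (symmetric under
#'   180 degree rotation), odd sine-phase (antisymmetric). Both are
#'   DC-corrected and unit L2 norm.
#' @slot orientationDeg carrier wave-vector direction, screen convention.
#' @slot wavelengthPx carrier wavelength in pixels.
#' @slot sigmaPx Gaussian envelope s.d. in pixels.
#' @exportClass SpatialQuadPair
setClass("SpatialQuadPair",
  representation(even = "matrix", odd = "matrix", orientationDeg = "numeric",
                 wavelengthPx = "numeric", sigmaPx = "numeric"))

setValidity("SpatialQuadPair", function(object) {
  e <- object@even; o <- object@odd
  if (!identical(dim(e), dim(o)) || nrow(e) != ncol(e) || nrow(e) %% 2 == 0)
    return("kernels must be square, odd-sized and equally shaped")
  rot180 <- function(m) m[nrow(m):1, ncol(m):1]
  if (abs(sum(e)) > 1e-6 || abs(sum(o)) > 1e-6)
    return("kernels must have (near) zero DC")
  if (max(abs(e - rot180(e))) > 1e-12) return("even kernel must be 180-degree symmetric")
  if (max(abs(o + rot180(o))) > 1e-12) return("odd kernel must be 180-degree antisymmetric")
  if (abs(sum(e^2) - 1) > 1e-9 || abs(sum(o^2) - 1) > 1e-9)
    return("kernels must have unit L2 norm")
  TRUE
})

#' Temporal biphasic filter pair
#'
#' Sampled impulse responses f_n(t) = (t/tau)^n exp(-t/tau)
#' [1/n! - (t/tau)^2/(n+2)!] with n = 3 ("fast") and n = 5 ("slow"),
#' each unit L2 normalized. Both are biphasic: a positive lobe followed by a
#' single sign change into a negative lobe.
#'
#' @slot fast,slow numeric vectors of length nTaps (tap j is lag j-1 frames).
#' @slot tauFrames time constant in frames.
#' @exportClass TemporalFilterPair
setClass("TemporalFilterPair",
  representation(fast = "numeric", slow = "numeric", tauFrames = "numeric"))

setValidity("TemporalFilterPair", function(object) {
  for (nm in c("fast", "slow")) {
    f <- slot(object, nm)
    if (length(f) < 5L) return("temporal filters need at least 5 taps")
    sg <- sign(f[f != 0])
    if (sum(diff(sg) != 0) != 1L)
      return(sprintf("%s filter must change sign exactly once", nm))
    if (abs(f[length(f)]) >= 0.01 * max(abs(f)))
      return(sprintf("%s filter is truncated: last tap >= 1%% of peak", nm))
  }
  if (object@tauFrames <= 0) return("tauFrames must be positive")
  TRUE
})

#' A direction-selective spatiotemporal channel
#'
#' Holds the full 3D (y, x, t) quadrature kernel pair for one preferred
#' direction. Kernel slice `[, , l]` applies to the frame l-1 steps in the
#' past (causal correlation).
#'
#' @slot thetaDeg preferred direction, screen convention.
#' @slot kernelEven,kernelOdd 3D arrays (ks x ks x nTaps).
#' @exportClass DirectionChannel
setClass("DirectionChannel",
  representation(thetaDeg = "numeric", kernelEven = "array", kernelOdd = "array"))

setValidity("DirectionChannel", function(object) {
  ke <- object@kernelEven; ko <- object@kernelOdd
  if (!identical(dim(ke), dim(ko)) || length(dim(ke)) != 3L)
    return("kernels must be equally shaped 3D arrays")
  if (!all(is.finite(ke)) || !all(is.finite(ko))) return("kernels must be finite")
  if (abs(sum(ke)) > 1e-4 || abs(sum(ko)) > 1e-4)
    return("kernels must be (near) zero DC")
  TRUE
})

#' Direction-selective spatiotemporal filter bank
#'
#' K channels with preferred directions theta_k = 360 (k-1)/K (screen
#' convention, clockwise as displayed). Channels k and k + K/2 are
#' opposite-direction counterparts and share a spatial quadrature pair (the
#' odd kernel changes sign).
#'
#' @slot channels list of K [DirectionChannel-class] objects.
#' @slot spatial list of K/2 [SpatialQuadPair-class] (orientations 0..180).
#' @slot temporal a [TemporalFilterPair-class] shared by all channels.
#' @slot params list of the construction parameters.
#' @exportClass FilterBank
setClass("FilterBank",
  representation(channels = "list", spatial = "list",
                 temporal = "TemporalFilterPair", params = "list"))

setValidity("FilterBank", function(object) {
  K <- length(object@channels)
  if (K < 4L || K %% 2 != 0L) return("K must be even and >= 4")
  th <- vapply(object@channels, function(ch) ch@thetaDeg, 1)
  want <- 360 * (seq_len(K) - 1) / K
  if (max(abs(wrapAngle(th - want))) > 1e-9)
    return("channel directions must be 360*k/K")
  if (length(object@spatial) != K %/% 2L)
    return("one spatial pair per orientation (K/2) is required")
  TRUE
})

setMethod("show", "FilterBank", function(object) {
  p <- object@params
  cat("FilterBank (spatiotemporal quadrature energy front end)\n")
  cat(sprintf("  K = %d channels at: %s degrees\n", length(object@channels),
              paste(vapply(object@channels, function(ch) format(ch@thetaDeg),
                           ""), collapse = ", ")))
  cat(sprintf("  spatial : Gabor wavelength %.3g px, sigma %.3g px, kernel %d x %d\n",
              p$wavelengthPx, p$sigmaPx, p$kernelSize, p$kernelSize))
  cat(sprintf("  temporal: biphasic pair (n = 3 fast / n = 5 slow), tau %.3g frames, %d taps\n",
              p$tauFrames, p$nTaps))
})

## ---------------------------------------------------------------------------
## Streaming buffer and result maps
## ---------------------------------------------------------------------------

#' Rolling spatiotemporal frame buffer
#'
#' FIFO buffer of the T most recent frames (oldest first); T is the temporal
#' kernel length of the bank it feeds. Energy can be computed once the
#' buffer is warm (holds exactly T frames).
#'
#' @slot buffer H x W x n array, n <= capacity, oldest frame first.
#' @slot capacity required temporal depth T.
#' @exportClass FrameVolume
setClass("FrameVolume",
  representation(buffer = "array", capacity = "integer"))

setValidity("FrameVolume", function(object) {
  d <- dim(object@buffer)
  if (length(d) != 3L) return("buffer must be a 3D array")
  if (d[3] > object@capacity) return("buffer holds more frames than capacity")
  if (object@capacity < 1L) return("capacity must be >= 1")
  v <- object@buffer
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    return("buffered values must lie in [0, 1]")
  TRUE
})

setMethod("show", "FrameVolume", function(object) {
  d <- dim(object@buffer)
  cat(sprintf("FrameVolume: %d/%d frame(s) of %d x %d px (%s)\n",
              d[3], object@capacity, d[1], d[2],
              if (d[3] == object@capacity) "warm" else "filling"))
})

#' Per-pixel, per-direction motion energy
#'
#' @slot E H x W x K array of nonnegative energies.
#' @slot thetaDeg the K channel directions.
#' @exportClass EnergyMap
setClass("EnergyMap", representation(E = "array", thetaDeg = "numeric"))

setValidity("EnergyMap", function(object) {
  if (length(dim(object@E)) != 3L) return("E must be H x W x K")
  if (dim(object@E)[3] != length(object@thetaDeg))
    return("one direction label per channel required")
  if (!all(is.finite(object@E))) return("energies must be finite")
  if (min(object@E) < -1e-12) return("energies must be nonnegative")
  TRUE
})

#' Per-pixel signed opponent motion energy
#'
#' O_k = E_k - E_{k + K/2 mod K}: positive where motion along theta_k
#' dominates motion along the opposite direction.
#'
#' @slot O H x W x K array of signed energies; O_k = -O_{k+K/2} exactly.
#' @slot thetaDeg the K channel directions.
#' @exportClass OpponentMap
setClass("OpponentMap", representation(O = "array", thetaDeg = "numeric"))

setValidity("OpponentMap", function(object) {
  K <- dim(object@O)[3]
  if (K %% 2 != 0L) return("K must be even")
  if (length(object@thetaDeg) != K) return("one direction label per channel")
  if (!all(is.finite(object@O))) return("opponent energies must be finite")
  half <- K %/% 2L
  flip <- ((seq_len(K) - 1L + half) %% K) + 1L
  if (max(abs(object@O + object@O[, , flip, drop = FALSE])) > 0)
    return("O_k must equal -O_{k+K/2} exactly")
  TRUE
})

#' Decoded per-pixel flow field
#'
#' @slot angleDeg H x W matrix of motion directions (screen convention,
#'   (-180, 180]); NA where the magnitude is zero (direction undefined).
#' @slot magnitude H x W matrix of nonnegative readout magnitudes.
#' @exportClass FlowField
setClass("FlowField", representation(angleDeg = "matrix", magnitude = "matrix"))

setValidity("FlowField", function(object) {
  if (!identical(dim(object@angleDeg), dim(object@magnitude)))
    return("angle and magnitude must share a shape")
  if (min(object@magnitude) < 0) return("magnitude must be nonnegative")
  bad <- object@magnitude == 0 & !is.na(object@angleDeg)
  if (any(bad)) return("angle must be NA (undefined) wherever magnitude is 0")
  TRUE
})

setMethod("show", "FlowField", function(object) {
  cat(sprintf("FlowField: %d x %d px, magnitude range [%.3g, %.3g], %d undefined px\n",
              nrow(object@magnitude), ncol(object@magnitude),
              min(object@magnitude), max(object@magnitude),
              sum(is.na(object@angleDeg))))
})

## ---------------------------------------------------------------------------
## Stimulus specifications
## ---------------------------------------------------------------------------

#' Ring stimulus specification
#'
#' Describes an annular stimulus: either a solid annulus carrying an angular
#' luminance texture, or a ring of Gabor micropatterns whose carrier wave
#' vector is tilted `elementOrientationOffsetDeg` clockwise from the local
#' outward radial direction (0 = radial wave vector, i.e. tangential
#' stripes; +45 = the classic Pinna-Brelstaff oblique).
#'
#' @slot center (x, y) center in pixels.
#' @slot baseRadius starting radius in pixels.
#' @slot expansionRate px/frame, positive = expanding.
#' @slot rotationRate deg/frame, positive = clockwise on screen.
#' @slot elementKind "solid_texture" or "gabor_elements".
#' @slot nElements texture cycles (solid) or micropattern count (gabor).
#' @slot elementOrientationOffsetDeg carrier tilt from radial, clockwise +.
#' @slot elementWavelength,elementSigma Gabor carrier wavelength / envelope
#'   s.d. in px (elementSigma also sets the radial width of solid annuli).
#' @slot contrast peak-to-peak luminance contrast in [0, 1].
#' @exportClass RingStimulusSpec
setClass("RingStimulusSpec",
  representation(center = "numeric", baseRadius = "numeric",
                 expansionRate = "numeric", rotationRate = "numeric",
                 elementKind = "character", nElements = "integer",
                 elementOrientationOffsetDeg = "numeric",
                 elementWavelength = "numeric", elementSigma = "numeric",
                 contrast = "numeric"))

setValidity("RingStimulusSpec", function(object) {
  if (length(object@center) != 2L) return("center must be (x, y)")
  if (object@baseRadius <= 0) return("baseRadius must be positive")
  if (!object@elementKind %in% c("solid_texture", "gabor_elements"))
    return("elementKind must be 'solid_texture' or 'gabor_elements'")
  if (object@elementKind == "gabor_elements" && object@nElements < 4L)
    return("gabor_elements requires at least 4 elements")
  if (object@nElements < 1L) return("nElements must be >= 1")
  if (object@contrast < 0 || object@contrast > 1) return("contrast must be in [0, 1]")
  if (object@elementWavelength < 2) return("elementWavelength must be >= 2 px")
  if (object@elementSigma <= 0) return("elementSigma must be positive")
  TRUE
})

#' @rdname RingStimulusSpec-class
#' @param center,baseRadius,expansionRate,rotationRate,elementKind,nElements
#'   see slots.
#' @param elementOrientationOffsetDeg,elementWavelength,elementSigma,contrast
#'   see slots.
#' @return a validated RingStimulusSpec.
#' @export
ringStimulusSpec <- function(center, baseRadius, expansionRate = 0,
                             rotationRate = 0,
                             elementKind = c("solid_texture", "gabor_elements"),
                             nElements = 12L,
                             elementOrientationOffsetDeg = 0,
                             elementWavelength = 8, elementSigma = 4,
                             contrast = 1) {
  new("RingStimulusSpec", center = as.numeric(center),
      baseRadius = baseRadius, expansionRate = expansionRate,
      rotationRate = rotationRate, elementKind = match.arg(elementKind),
      nElements = as.integer(nElements),
      elementOrientationOffsetDeg = elementOrientationOffsetDeg,
      elementWavelength = elementWavelength, elementSigma = elementSigma,
      contrast = contrast)
}

#' Stepping-feet stimulus specification
#'
#' Two vertically aligned rectangles ("feet") of distinct luminances
#' translating horizontally at the same constant speed over a vertical
#' square-wave grating. Default foot luminances are the Rec.601 luminances
#' of the classic yellow and blue feet.
#'
#' @slot gratingPeriod full period (one dark + one bright stripe) in px.
#' @slot footLuminances c(bright, dark) in [0, 1], distinct.
#' @slot footSize c(width, height) in px.
#' @slot speed horizontal speed in px/frame (> 0, rightward).
#' @slot backgroundContrast grating contrast in [0, 1] about mid-gray.
#' @slot verticalGap gap between the two feet in px.
#' @exportClass SteppingFeetSpec
setClass("SteppingFeetSpec",
  representation(gratingPeriod = "numeric", footLuminances = "numeric",
                 footSize = "numeric", speed = "numeric",
                 backgroundContrast = "numeric", verticalGap = "numeric"))

setValidity("SteppingFeetSpec", function(object) {
  if (object@gratingPeriod < 2) return("gratingPeriod must be >= 2 px")
  if (length(object@footLuminances) != 2L ||
      object@footLuminances[1] == object@footLuminances[2])
    return("footLuminances must be two distinct values")
  if (any(object@footLuminances < 0 | object@footLuminances > 1))
    return("footLuminances must lie in [0, 1]")
  if (object@speed <= 0) return("speed must be positive")
  if (object@backgroundContrast < 0 || object@backgroundContrast > 1)
    return("backgroundContrast must be in [0, 1]")
  if (length(object@footSize) != 2L || any(object@footSize < 1))
    return("footSize must be c(width, height), both >= 1 px")
  TRUE
})

#' @rdname SteppingFeetSpec-class
#' @param gratingPeriod,footLuminances,footSize,speed,backgroundContrast,verticalGap
#'   see slots.
#' @return a validated SteppingFeetSpec.
#' @export
steppingFeetSpec <- function(gratingPeriod = 16,
                             footLuminances = c(0.886, 0.114),
                             footSize = c(32, 12), speed = 1,
                             backgroundContrast = 1, verticalGap = 8) {
  new("SteppingFeetSpec", gratingPeriod = gratingPeriod,
      footLuminances = footLuminances, footSize = footSize, speed = speed,
      backgroundContrast = backgroundContrast, verticalGap = verticalGap)
}

## ---------------------------------------------------------------------------
## Readout configuration and measurements
## ---------------------------------------------------------------------------

#' Color-wheel rendering configuration
#'
#' @slot hueAtZeroDeg hue (degrees on the color wheel) assigned to motion
#'   direction 0 (rightward).
#' @slot directionOfIncrease "cw" or "ccw": sense in which hue advances with
#'   motion angle, as displayed.
#' @slot magnitudePercentile robust-max percentile used for per-frame
#'   brightness normalization, in (50, 100].
#' @slot gamma display gamma (> 0) applied to normalized magnitude.
#' @slot fixedScale absolute magnitude scale; NA = per-frame robust max.
#'   Set a number for quantitative cross-condition comparisons.
#' @exportClass ColorWheelConfig
setClass("ColorWheelConfig",
  representation(hueAtZeroDeg = "numeric", directionOfIncrease = "character",
                 magnitudePercentile = "numeric", gamma = "numeric",
                 fixedScale = "numeric"))

setValidity("ColorWheelConfig", function(object) {
  if (object@magnitudePercentile <= 50 || object@magnitudePercentile > 100)
    return("magnitudePercentile must be in (50, 100]")
  if (object@gamma <= 0) return("gamma must be positive")
  if (!object@directionOfIncrease %in% c("cw", "ccw"))
    return("directionOfIncrease must be 'cw' or 'ccw'")
  TRUE
})

#' @rdname ColorWheelConfig-class
#' @param hueAtZeroDeg,directionOfIncrease,magnitudePercentile,gamma,fixedScale
#'   see slots.
#' @return a validated ColorWheelConfig.
#' @export
colorWheelConfig <- function(hueAtZeroDeg = 0, directionOfIncrease = "cw",
                             magnitudePercentile = 99, gamma = 1,
                             fixedScale = NA_real_) {
  new("ColorWheelConfig", hueAtZeroDeg = hueAtZeroDeg,
      directionOfIncrease = directionOfIncrease,
      magnitudePercentile = magnitudePercentile, gamma = gamma,
      fixedScale = as.numeric(fixedScale))
}

#' Ring-phase measurement
#'
#' Magnitude-weighted circular mean of decoded motion direction relative to
#' the local outward radial direction over an annulus. 0 = pure expansion,
#' +90 = clockwise rotation, -90 = counter-clockwise rotation, +/-45 = equal
#' mixture. `phaseDeg` is NA when no pixel exceeded the magnitude floor.
#'
#' @slot phaseDeg circular mean phase, degrees in (-180, 180], clockwise +.
#' @slot resultantLength circular concentration in [0, 1].
#' @slot nPixels number of annulus pixels used.
#' @slot weight total magnitude weight (used when pooling across frames).
#' @exportClass PhaseMeasurement
setClass("PhaseMeasurement",
  representation(phaseDeg = "numeric", resultantLength = "numeric",
                 nPixels = "integer", weight = "numeric"))

setValidity("PhaseMeasurement", function(object) {
  if (!is.na(object@resultantLength) &&
      (object@resultantLength < 0 || object@resultantLength > 1 + 1e-12))
    return("resultantLength must lie in [0, 1]")
  if (!is.na(object@phaseDeg) && object@nPixels <= 0L)
    return("a defined phase requires nPixels > 0")
  TRUE
})

setMethod("show", "PhaseMeasurement", function(object) {
  if (is.na(object@phaseDeg)) {
    cat("PhaseMeasurement: undefined (no pixels above magnitude floor)\n")
  } else {
    cat(sprintf("PhaseMeasurement: phase %+.2f deg (cw+), resultant %.3f, n = %d px\n",
                object@phaseDeg, object@resultantLength, object@nPixels))
  }
})

#' @rdname PhaseMeasurement-class
#' @param object a PhaseMeasurement.
#' @aliases phaseDeg resultantLength
#' @export
setGeneric("phaseDeg", function(object) standardGeneric("phaseDeg"))

#' @rdname PhaseMeasurement-class
#' @export
setMethod("phaseDeg", "PhaseMeasurement", function(object) object@phaseDeg)

#' @rdname PhaseMeasurement-class
#' @export
setGeneric("resultantLength", function(object) standardGeneric("resultantLength"))

#' @rdname PhaseMeasurement-class
#' @export
setMethod("resultantLength", "PhaseMeasurement", function(object) object@resultantLength)
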