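# Ring-phase analysis: collapse a flow field over an annulus into a single
# circular-mean phase relative to the local outward radial direction.
# 0 degrees = pure expansion, +90 = clockwise rotation (as displayed),
# -90 = counter-clockwise, +/-45 = equal mixture of expansion and rotation.

#' Measure the motion phase of a ring stimulus
#'
#' For every annulus pixel whose decoded magnitude reaches
#' `magnitudeFloorFrac` times the annulus maximum, takes the signed angular
#' difference between the decoded motion direction and the local outward
#' radial direction (clockwise positive as displayed) and returns the
#' magnitude-weighted circular mean and resultant length. Low-energy
#' background pixels are excluded by the floor so they cannot dilute the
#' measurement.
#'
#' @param flow a [FlowField-class].
#' @param center c(x, y) ring center in px.
#' @param rMin,rMax annulus radii in px (inclusive).
#' @param magnitudeFloorFrac fraction of the annulus maximum magnitude
#'   below which pixels are ignored; in [0, 1).
#' @return a [PhaseMeasurement-class]; `phaseDeg` is NA (the
#'   undefined-phase signal) when no pixel passes the floor.
#' @export
setGeneric("measureRingPhase",
  function(flow, center, rMin, rMax, magnitudeFloorFrac = 0.1)
    standardGeneric("measureRingPhase"))

#' @rdname measureRingPhase
#' @export
setMethod("measureRingPhase", "FlowField",
  function(flow, center, rMin, rMax, magnitudeFloorFrac = 0.1) {
    if (magnitudeFloorFrac < 0 || magnitudeFloorFrac >= 1)
      stop("magnitudeFloorFrac must be in [0, 1)")
    d <- dim(flow@magnitude)
    g <- pixelGrid(d)
    dx <- g$X - center[1]; dy <- g$Y - center[2]
    r <- sqrt(dx^2 + dy^2)
    ann <- r >= rMin & r <= rMax
    if (!any(ann)) stop("annulus contains no pixels")
    mag <- flow@magnitude
    floorAbs <- magnitudeFloorFrac * max(mag[ann])
    sel <- ann & mag >= floorAbs & mag > 0 & !is.na(flow@angleDeg)
    if (!any(sel)) {
      return(new("PhaseMeasurement", phaseDeg = NA_real_,
                 resultantLength = NA_real_, nPixels = 0L, weight = 0))
    }
    radial <- screenAngle(dx[sel], dy[sel])
    delta <- wrapAngle(flow@angleDeg[sel] - radial)
    cm <- circularMean(delta, mag[sel])
    new("PhaseMeasurement", phaseDeg = cm$meanDeg,
        resultantLength = cm$resultantLength,
        nPixels = sum(sel), weight = cm$sumWeight)
  })

#' Per-frame ring-phase timecourse
#'
#' Applies [measureRingPhase()] to each flow field; annulus radii may be
#' scalars or per-frame vectors (for looming rings whose radius grows).
#'
#' @param flows list of [FlowField-class] objects.
#' @param center c(x, y) ring center in px.
#' @param rMin,rMax scalar or per-frame annulus radii.
#' @param magnitudeFloorFrac see [measureRingPhase()].
#' @return a list of [PhaseMeasurement-class], one per flow field (entries
#'   with no pixel above the floor have an NA phase).
#' @export
phaseTimecourse <- function(flows, center, rMin, rMax,
                            magnitudeFloorFrac = 0.1) {
  n <- length(flows)
  rMin <- rep_len(rMin, n); rMax <- rep_len(rMax, n)
  lapply(seq_len(n), function(i)
    measureRingPhase(flows[[i]], center, rMin[i], rMax[i],
                     magnitudeFloorFrac))
}

#' Pool phase measurements across frames
#'
#' Combines per-frame measurements into one phase by summing the
#' per-frame mean resultant vectors, each weighted by that frame's total
#' magnitude weight, so frames with little visible motion energy (for
#' example a looming ring mostly outside the frame) contribute little.
#'
#' @param measurements list of [PhaseMeasurement-class].
#' @return a pooled [PhaseMeasurement-class] (NA phase if no frame had a
#'   defined phase).
#' @export
aggregateRingPhase <- function(measurements) {
  ok <- vapply(measurements, function(m) !is.na(m@phaseDeg), TRUE)
  if (!any(ok)) {
    return(new("PhaseMeasurement", phaseDeg = NA_real_,
               resultantLength = NA_real_, nPixels = 0L, weight = 0))
  }
  ms <- measurements[ok]
  w <- vapply(ms, function(m) m@weight, 1)
  rl <- vapply(ms, function(m) m@resultantLength, 1)
  ph <- deg2rad(vapply(ms, function(m) m@phaseDeg, 1))
  cx <- sum(w * rl * cos(ph)) / sum(w)
  sx <- sum(w * rl * sin(ph)) / sum(w)
  new("PhaseMeasurement",
      phaseDeg = wrapAngle(rad2deg(atan2(sx, cx))),
      resultantLength = min(1, sqrt(cx^2 + sx^2)),
      nPixels = sum(vapply(ms, function(m) m@nPixels, 1L)),
      weight = sum(w))
}
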