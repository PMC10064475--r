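# Population readout and color-wheel rendering. The decoder is a rectified
# vector sum over opponent channels; because O_k = -O_{k+K/2}, each opposed
# pair contributes once, along whichever of its two directions dominates.

#' Decode a per-pixel flow field from opponent energy
#'
#' Per pixel, `v = sum_k max(O_k, 0) * (cos theta_k, sin theta_k)` (screen
#' convention); the flow angle is `atan2` of v and the magnitude its norm.
#' Where the magnitude is exactly zero the direction is undefined and the
#' angle is NA, never a fabricated direction.
#'
#' @param O an [OpponentMap-class].
#' @return a [FlowField-class].
#' @export
setGeneric("decodeFlow", function(O) standardGeneric("decodeFlow"))

#' @rdname decodeFlow
#' @export
setMethod("decodeFlow", "OpponentMap", function(O) {
  th <- deg2rad(O@thetaDeg)
  d <- dim(O@O)
  vx <- matrix(0, d[1], d[2]); vy <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) {
    r <- pmax(O@O[, , k], 0)
    vx <- vx + r * cos(th[k])
    vy <- vy + r * sin(th[k])
  }
  mag <- sqrt(vx^2 + vy^2)
  ang <- screenAngle(vx, vy)
  ang[mag == 0] <- NA_real_
  new("FlowField", angleDeg = ang, magnitude = mag)
})

# shared hue mapping (degrees on the wheel, in [0, 360))
angleToHue <- function(angleDeg, cfg) {
  s <- if (cfg@directionOfIncrease == "cw") 1 else -1
  (cfg@hueAtZeroDeg + s * angleDeg) %% 360
}

#' Render a flow field on the color wheel
#'
#' Hue encodes motion direction (see [colorWheelConfig()] for the anchor
#' and sense); brightness encodes magnitude, normalized by the per-frame
#' robust maximum (`magnitudePercentile`) or by `fixedScale` when set, then
#' gamma-corrected. Pixels with undefined direction render neutral
#' (achromatic, brightness from magnitude, i.e. black where motion energy
#' vanishes).
#'
#' @param flow a [FlowField-class].
#' @param cfg a [ColorWheelConfig-class].
#' @return an H x W x 3 RGB array in [0, 1].
#' @export
setGeneric("flowToRGB", function(flow, cfg = colorWheelConfig())
  standardGeneric("flowToRGB"))

#' @rdname flowToRGB
#' @export
setMethod("flowToRGB", "FlowField", function(flow, cfg = colorWheelConfig()) {
  mag <- flow@magnitude
  scale <- if (!is.na(cfg@fixedScale)) cfg@fixedScale else
    stats::quantile(mag, cfg@magnitudePercentile / 100, names = FALSE)
  v <- if (scale > 0) pmin(1, mag / scale)^(1 / cfg@gamma) else mag * 0
  h <- angleToHue(flow@angleDeg, cfg) / 360
  s <- ifelse(is.na(flow@angleDeg), 0, 1)
  h[is.na(h)] <- 0
  rgb <- hsv2rgbNum(as.vector(h), as.vector(s), as.vector(v))
  array(rgb, c(dim(mag), 3))
})

#' Render the color-wheel legend
#'
#' A square RGBA image of the direction wheel: hue follows the same mapping
#' as [flowToRGB()], brightness ramps with radius, and the corners outside
#' the wheel are transparent. Tick marks at 0/90/180/270 degrees label the
#' cardinal motion directions.
#'
#' @param cfg a [ColorWheelConfig-class].
#' @param size side length in px.
#' @return a size x size x 4 RGBA array in [0, 1].
#' @export
renderLegend <- function(cfg = colorWheelConfig(), size = 128L) {
  ctr <- (size + 1) / 2
  rmax <- size / 2 - 1
  g <- pixelGrid(c(size, size))
  dx <- g$X - ctr; dy <- g$Y - ctr
  r <- sqrt(dx^2 + dy^2)
  ang <- screenAngle(dx, dy)
  h <- angleToHue(ang, cfg) / 360
  v <- pmin(1, r / rmax)^(1 / cfg@gamma)
  inside <- r <= rmax
  rgb <- hsv2rgbNum(as.vector(h), rep(1, length(h)), as.vector(v))
  out <- array(0, c(size, size, 4))
  for (ch in 1:3) out[, , ch] <- matrix(rgb[, ch], size, size) * inside
  # cardinal tick marks: darken a thin radial segment every 90 degrees
  tick <- inside & r > 0.85 * rmax & (abs(dx) < 1 | abs(dy) < 1)
  for (ch in 1:3) out[, , ch][tick] <- 0
  out[, , 4] <- inside * 1
  out
}
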