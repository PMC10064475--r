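# Construction of the direction-selective spatiotemporal filter bank: the
# linear front end of the energy model. Spatial selectivity comes from
# oriented Gabor quadrature pairs, temporal structure from a fast/slow pair
# of biphasic causal filters, and direction selectivity from the classical
# sum/difference combinations of their separable products.

#' Oriented spatial Gabor quadrature pair
#'
#' Builds cosine-phase (even) and sine-phase (odd) Gabor kernels with an
#' isotropic Gaussian envelope. The even kernel is DC-corrected by
#' subtracting an envelope-shaped offset (which preserves its 180-degree
#' symmetry); both kernels are normalized to unit L2 norm. Squaring and
#' summing the two filtered outputs gives a response invariant to the
#' spatial phase of a matched stimulus (quadrature).
#'
#' @param wavelengthPx carrier wavelength in px (>= 2).
#' @param sigmaPx envelope standard deviation in px (> 0).
#' @param orientationDeg carrier wave-vector direction, screen convention.
#' @param kernelSize odd kernel side length in px.
#' @return a [SpatialQuadPair-class].
#' @export
makeSpatialQuadrature <- function(wavelengthPx, sigmaPx, orientationDeg,
                                  kernelSize) {
  if (kernelSize %% 2 == 0) stop("kernelSize must be odd")
  if (sigmaPx <= 0) stop("sigmaPx must be positive")
  if (wavelengthPx < 2) stop("wavelengthPx must be >= 2 px")
  hw <- (kernelSize - 1) / 2
  d <- seq(-hw, hw)
  DX <- matrix(rep(d, each = kernelSize), kernelSize)   # column offset (x)
  DY <- matrix(rep(d, times = kernelSize), kernelSize)  # row offset (y, down)
  th <- deg2rad(orientationDeg)
  u <- DX * cos(th) + DY * sin(th)
  env <- exp(-(DX^2 + DY^2) / (2 * sigmaPx^2))
  even <- env * cos(2 * pi * u / wavelengthPx)
  odd <- env * sin(2 * pi * u / wavelengthPx)
  even <- even - sum(even) * env / sum(env)  # DC removal, symmetry preserved
  odd <- odd - sum(odd) * env / sum(env)     # exact zero already; keeps form
  even <- even / sqrt(sum(even^2))
  odd <- odd / sqrt(sum(odd^2))
  new("SpatialQuadPair", even = even, odd = odd,
      orientationDeg = orientationDeg, wavelengthPx = wavelengthPx,
      sigmaPx = sigmaPx)
}

# closed-form biphasic temporal impulse response, s = t / tau
temporalForm <- function(s, n) {
  s^n * exp(-s) * (1 / factorial(n) - s^2 / factorial(n + 2))
}

#' Fast/slow biphasic temporal filter pair
#'
#' Samples the classical biphasic impulse responses
#' `f_n(t) = (t/tau)^n exp(-t/tau) [1/n! - (t/tau)^2/(n+2)!]` at integer
#' frame lags t = 0, ..., nTaps-1, with n = 3 (fast) and n = 5 (slow); each
#' is unit L2 normalized. The support must be long enough to contain both
#' lobes of each filter and let the response decay (last tap below 1% of
#' the peak), otherwise an error is raised.
#'
#' @param tauFrames time constant in frames (> 0).
#' @param nTaps number of taps (>= 5).
#' @return a [TemporalFilterPair-class].
#' @export
makeTemporalPair <- function(tauFrames, nTaps) {
  if (tauFrames <= 0) stop("tauFrames must be positive")
  if (nTaps < 5) stop("nTaps must be >= 5")
  s <- (seq_len(nTaps) - 1) / tauFrames
  fast <- temporalForm(s, 3)
  slow <- temporalForm(s, 5)
  for (f in list(fast = fast, slow = slow)) {
    sg <- sign(f[f != 0])
    if (sum(diff(sg) != 0) != 1L || abs(f[length(f)]) >= 0.01 * max(abs(f)))
      stop("temporal support too short to contain the biphasic lobes; ",
           "increase nTaps (roughly 20 * tauFrames + 1)")
  }
  new("TemporalFilterPair", fast = fast / sqrt(sum(fast^2)),
      slow = slow / sqrt(sum(slow^2)), tauFrames = tauFrames)
}

#' Build the direction-selective spatiotemporal filter bank
#'
#' Constructs K channels with preferred directions theta_k = 360 (k-1)/K.
#' Each channel's quadrature 3D kernels are the classical combinations of
#' the four separable products of the oriented spatial pair (even, odd at
#' theta_k) and the temporal pair (fast, slow):
#' `kernelEven = even x fast - odd x slow` and
#' `kernelOdd  = odd x fast + even x slow`.
#' Squaring and summing the two kernel responses yields energy tuned to
#' motion along theta_k; channels k and k+K/2 are opposite-direction
#' counterparts (the sine spatial kernel changes sign under a 180-degree
#' orientation change, which flips the temporal pairing).
#'
#' @param K number of direction channels (even, >= 4).
#' @param wavelengthPx,sigmaPx,kernelSize spatial Gabor parameters
#'   (see [makeSpatialQuadrature()]).
#' @param tauFrames,nTaps temporal parameters (see [makeTemporalPair()]).
#' @return a [FilterBank-class].
#' @export
buildFilterBank <- function(K = 8L, wavelengthPx = 8, sigmaPx = 4,
                            tauFrames = 0.5, kernelSize = 15L, nTaps = 11L) {
  K <- as.integer(K)
  if (K < 4L || K %% 2L != 0L) stop("K must be even and >= 4")
  temporal <- makeTemporalPair(tauFrames, nTaps)
  half <- K %/% 2L
  spatial <- lapply(seq_len(half) - 1L, function(k)
    makeSpatialQuadrature(wavelengthPx, sigmaPx, 360 * k / K, kernelSize))
  fast <- temporal@fast; slow <- temporal@slow
  channels <- vector("list", K)
  for (k in seq_len(K)) {
    o <- ((k - 1L) %% half) + 1L
    sp <- spatial[[o]]
    oddK <- if (k <= half) sp@odd else -sp@odd  # sin flips across 180 deg
    ke <- outer(sp@even, fast) - outer(oddK, slow)
    ko <- outer(oddK, fast) + outer(sp@even, slow)
    channels[[k]] <- new("DirectionChannel", thetaDeg = 360 * (k - 1) / K,
                         kernelEven = ke, kernelOdd = ko)
  }
  new("FilterBank", channels = channels, spatial = spatial,
      temporal = temporal,
      params = list(K = K, wavelengthPx = wavelengthPx, sigmaPx = sigmaPx,
                    tauFrames = tauFrames, kernelSize = as.integer(kernelSize),
                    nTaps = as.integer(nTaps)))
}

#' Number of direction channels / channel directions / temporal depth
#'
#' @param bank a [FilterBank-class].
#' @return `nChannels()`: integer K; `channelDirections()`: numeric vector
#'   of preferred directions in degrees; `temporalDepth()`: integer number
#'   of temporal taps (the warm-up length of the streaming buffer).
#' @aliases nChannels channelDirections temporalDepth
#' @export
nChannels <- function(bank) length(bank@channels)

#' @rdname nChannels
#' @export
channelDirections <- function(bank) vapply(bank@channels, function(ch) ch@thetaDeg, 1)

#' @rdname nChannels
#' @export
temporalDepth <- function(bank) bank@params$nTaps

#' Serialize / restore a filter bank
#'
#' Writes all kernels and parameters to an RDS container (a plain R list of
#' numeric arrays, documented in the value section) for external
#' inspection, or restores a bank from one.
#'
#' @param bank a [FilterBank-class].
#' @param path file path.
#' @return `writeFilterBank()` invisibly returns `path`; `readFilterBank()`
#'   returns a [FilterBank-class]. The container is a list with elements
#'   `params` (construction parameters) and `channels` (per channel:
#'   `thetaDeg`, `kernelEven`, `kernelOdd` arrays).
#' @export
writeFilterBank <- function(bank, path) {
  obj <- list(params = bank@params,
              channels = lapply(bank@channels, function(ch)
                list(thetaDeg = ch@thetaDeg, kernelEven = ch@kernelEven,
                     kernelOdd = ch@kernelOdd)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeFilterBank
#' @export
readFilterBank <- function(path) {
  obj <- readRDS(path)
  do.call(buildFilterBank, obj$params)
}
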