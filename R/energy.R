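# Streaming energy engine: push frames through the bank, square quadrature
# responses into per-direction energy, difference opposite channels into
# opponent energy. Spatial filtering uses "same" correlation with symmetric
# reflect borders (FFT-based); temporal filtering is causal and valid (an
# output exists only once the buffer is warm), so no future frame ever
# leaks into an output. All accumulation is in double precision.

notReady <- function(msg) {
  stop(structure(class = c("motionEnergyNotReady", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Create an empty rolling frame buffer
#'
#' @param capacity temporal depth T (usually `temporalDepth(bank)`).
#' @param height,width frame shape in px.
#' @return a [FrameVolume-class] holding no frames yet.
#' @export
frameVolume <- function(capacity, height, width) {
  new("FrameVolume", buffer = array(0, c(height, width, 0)),
      capacity = as.integer(capacity))
}

#' Push a frame into a rolling buffer
#'
#' Appends `frame` as the newest entry, dropping the oldest frame if the
#' buffer is full. No other state is touched (the returned object shares
#' nothing mutable with the input).
#'
#' @param vol a [FrameVolume-class].
#' @param frame H x W numeric matrix matching the buffer shape.
#' @return the updated [FrameVolume-class].
#' @export
pushFrame <- function(vol, frame) {
  d <- dim(vol@buffer)
  if (!identical(as.integer(dim(frame)), as.integer(d[1:2])))
    stop("frame shape does not match buffer")
  keep <- if (d[3] >= vol@capacity) seq.int(d[3] - vol@capacity + 2L, d[3]) else seq_len(d[3])
  buf <- array(0, c(dim(frame), length(keep) + 1L))
  if (length(keep)) buf[, , seq_along(keep)] <- vol@buffer[, , keep]
  buf[, , length(keep) + 1L] <- frame
  initialize(vol, buffer = buf)
}

#' Is the buffer warmed up?
#'
#' @param vol a [FrameVolume-class].
#' @return TRUE once the buffer holds exactly its capacity of frames.
#' @export
isWarm <- function(vol) dim(vol@buffer)[3] == vol@capacity

# spatial responses of one frame for all K/2 orientations:
# list(even = list per orientation, odd = list per orientation)
spatialResponses <- function(frame, bank, plan = NULL) {
  if (is.null(plan)) plan <- spatialPlan(nrow(frame), ncol(frame), bank)
  res <- plan(frame)
  half <- length(res) %/% 2L
  list(even = res[seq_len(half)], odd = res[half + seq_len(half)])
}

spatialPlan <- function(H, W, bank) {
  makeConvPlan(H, W, c(lapply(bank@spatial, function(s) s@even),
                       lapply(bank@spatial, function(s) s@odd)))
}

# combine buffered spatial responses (lists of length T, oldest first) into
# the K-channel energy array at the newest time sample
temporalCombine <- function(evenBuf, oddBuf, bank) {
  fast <- rev(bank@temporal@fast)  # weight for oldest..newest buffer slot
  slow <- rev(bank@temporal@slow)
  K <- nChannels(bank)
  half <- K %/% 2L
  d <- dim(evenBuf[[1L]][[1L]])
  E <- array(0, c(d, K))
  Tn <- length(evenBuf)
  for (o in seq_len(half)) {
    Ef <- Es <- Of <- Os <- matrix(0, d[1], d[2])
    for (i in seq_len(Tn)) {
      e <- evenBuf[[i]][[o]]; od <- oddBuf[[i]][[o]]
      Ef <- Ef + fast[i] * e;  Es <- Es + slow[i] * e
      Of <- Of + fast[i] * od; Os <- Os + slow[i] * od
    }
    E[, , o] <- (Ef - Os)^2 + (Of + Es)^2            # motion along theta_o
    E[, , o + half] <- (Ef + Os)^2 + (Of - Es)^2     # opposite direction
  }
  E
}

#' Per-pixel, per-direction motion energy of a warm volume
#'
#' For each channel, filters the buffered volume with the channel's even
#' and odd space-time kernels (spatial same-correlation with reflect
#' borders; temporal causal correlation evaluated at the newest frame) and
#' returns the sum of the two squared responses.
#'
#' @param vol a warm [FrameVolume-class] whose depth equals the bank's
#'   temporal depth. A cold buffer raises a not-ready condition (class
#'   `motionEnergyNotReady`).
#' @param bank a [FilterBank-class].
#' @return an [EnergyMap-class] (H x W x K).
#' @export
setGeneric("computeEnergy", function(vol, bank) standardGeneric("computeEnergy"))

#' @rdname computeEnergy
#' @export
setMethod("computeEnergy", signature("FrameVolume", "FilterBank"),
  function(vol, bank) {
    if (!isWarm(vol) || vol@capacity != temporalDepth(bank))
      notReady("frame buffer is not warmed up to the bank's temporal depth")
    d <- dim(vol@buffer)
    plan <- spatialPlan(d[1], d[2], bank)
    evenBuf <- vector("list", d[3]); oddBuf <- vector("list", d[3])
    for (t in seq_len(d[3])) {
      sr <- spatialResponses(vol@buffer[, , t], bank, plan)
      evenBuf[[t]] <- sr$even; oddBuf[[t]] <- sr$odd
    }
    new("EnergyMap", E = temporalCombine(evenBuf, oddBuf, bank),
        thetaDeg = channelDirections(bank))
  })

#' Opponent motion energy
#'
#' Differences opposite-direction channels: `O_k = E_k - E_{k+K/2 mod K}`.
#' Static and counterphase stimuli, which excite opposite channels equally,
#' cancel here.
#'
#' @param E an [EnergyMap-class] with an even number of channels.
#' @return an [OpponentMap-class].
#' @export
setGeneric("computeOpponent", function(E) standardGeneric("computeOpponent"))

#' @rdname computeOpponent
#' @export
setMethod("computeOpponent", "EnergyMap", function(E) {
  K <- dim(E@E)[3]
  if (K %% 2L != 0L) stop("opponent stage requires an even channel count")
  half <- K %/% 2L
  flip <- ((seq_len(K) - 1L + half) %% K) + 1L
  O <- E@E - E@E[, , flip, drop = FALSE]
  # enforce exact antisymmetry (floating differences are already exact,
  # since both entries are computed from the same pair of numbers)
  new("OpponentMap", O = O, thetaDeg = E@thetaDeg)
})

#' Stream a frame sequence through the filter bank
#'
#' Produces one opponent map per warmed-up frame (`length(seq) - T + 1`
#' outputs for temporal depth T), identical to computing each output from
#' the full volume in one batch. Spatial responses are computed once per
#' frame and reused across output times.
#'
#' @param seq a [FrameSequence-class] with at least T frames.
#' @param bank a [FilterBank-class].
#' @param keepEnergy also return the per-frame [EnergyMap-class] objects.
#' @param normalize apply divisive contrast normalization: each opponent
#'   map is divided pixelwise by `normalizeEpsilon + mean_k E_k`. Off by
#'   default, so stimulus contrast modulates output strength.
#' @param normalizeEpsilon saturation constant of the normalization.
#' @return a list with elements `opponent` (list of [OpponentMap-class]),
#'   `frameIndex` (the 1-based index of the newest frame entering each
#'   output) and, if requested, `energy`.
#' @export
setGeneric("processStream", function(seq, bank, keepEnergy = FALSE,
                                      normalize = FALSE,
                                      normalizeEpsilon = 1e-6)
  standardGeneric("processStream"))

#' @rdname processStream
#' @export
setMethod("processStream", signature("FrameSequence", "FilterBank"),
  function(seq, bank, keepEnergy = FALSE, normalize = FALSE,
           normalizeEpsilon = 1e-6) {
    f <- frames(seq)
    Tn <- temporalDepth(bank)
    N <- dim(f)[3]
    if (N < Tn) stop("sequence shorter than the bank's temporal depth")
    plan <- spatialPlan(dim(f)[1], dim(f)[2], bank)
    evenBuf <- list(); oddBuf <- list()
    thetas <- channelDirections(bank)
    opp <- vector("list", N - Tn + 1L)
    en <- if (keepEnergy) vector("list", N - Tn + 1L) else NULL
    for (t in seq_len(N)) {
      sr <- spatialResponses(f[, , t], bank, plan)
      evenBuf <- c(evenBuf, list(sr$even))
      oddBuf <- c(oddBuf, list(sr$odd))
      if (length(evenBuf) > Tn) {
        evenBuf <- evenBuf[-1L]; oddBuf <- oddBuf[-1L]
      }
      if (length(evenBuf) == Tn) {
        i <- t - Tn + 1L
        Earr <- temporalCombine(evenBuf, oddBuf, bank)
        Emap <- new("EnergyMap", E = Earr, thetaDeg = thetas)
        if (keepEnergy) en[[i]] <- Emap
        om <- computeOpponent(Emap)
        if (normalize) {
          denom <- normalizeEpsilon + apply(Earr, c(1, 2), mean)
          om <- new("OpponentMap", O = om@O / as.vector(denom),
                    thetaDeg = om@thetaDeg)
        }
        opp[[i]] <- om
      }
    }
    out <- list(opponent = opp, frameIndex = seq.int(Tn, N))
    if (keepEnergy) out$energy <- en
    out
  })
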