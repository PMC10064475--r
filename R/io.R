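# Frame-sequence I/O: PNG frame directories with zero-padded numeric
# filenames. Color PNGs are converted to luminance with Rec.601 weights at
# ingest (the model is luminance-driven). A small plain-text sidecar file
# (framerate.txt) carries the nominal frame rate.

rec601 <- c(0.299, 0.587, 0.114)

#' Read a frame sequence from a PNG directory
#'
#' Reads all `*.png` files in `path` in lexicographic order (write with
#' zero-padded numeric names, as [writeFrames()] does). Color frames are
#' converted to luminance with Rec.601 weights; an alpha channel, if
#' present, is ignored.
#'
#' @param path directory containing PNG frames.
#' @return a [FrameSequence-class].
#' @export
readFrames <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG frames found in ", path)
  mats <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) {
      nch <- dim(img)[3]
      w <- if (nch >= 3L) rec601 else rep(1 / nch, nch)
      if (nch > 3L) w <- c(w[1:3], rep(0, nch - 3L))
      apply(sweep(img, 3, w, `*`), c(1, 2), sum)
    } else img
  })
  d <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), TRUE)))
    stop("frames in ", path, " have inconsistent shapes")
  fr <- 30
  meta <- file.path(path, "framerate.txt")
  if (file.exists(meta)) fr <- as.numeric(readLines(meta, n = 1L))
  frameSequence(mats, frameRate = fr)
}

#' Write a frame sequence as 8-bit grayscale PNGs
#'
#' @param seq a [FrameSequence-class].
#' @param path output directory (created if needed). Frames are written as
#'   `frame_0001.png`, `frame_0002.png`, ... plus a `framerate.txt` sidecar.
#' @return invisibly, the vector of file paths written.
#' @export
writeFrames <- function(seq, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  f <- frames(seq)
  n <- dim(f)[3]
  fmt <- sprintf("frame_%%0%dd.png", max(4L, nchar(n)))
  out <- character(n)
  for (t in seq_len(n)) {
    out[t] <- file.path(path, sprintf(fmt, t))
    png::writePNG(f[, , t], out[t])
  }
  writeLines(format(frameRate(seq)), file.path(path, "framerate.txt"))
  invisible(out)
}
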