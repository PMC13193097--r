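# Calibrated image stacks and TIFF input/output.

#' Calibrated time-lapse image stack
#'
#' Container for a grayscale time-lapse: a list of equally sized intensity
#' matrices plus the physical calibration every downstream measurement uses.
#'
#' @param frames list of numeric/integer matrices (H x W), one per frame.
#' @param pixel_size_um microns per pixel (> 0); default 0.13, the
#'   calibration at which 60 px = 7.8 um and 40 px = 5.2 um.
#' @param frame_interval_s seconds per frame (> 0).
#' @return a `frame_stack` object.
#' @export
frame_stack <- function(frames, pixel_size_um = 0.13, frame_interval_s = 1) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3L]), function(i) frames[, , i])
  if (!is.list(frames) || !length(frames))
    stop("'frames' must be a non-empty list of matrices", call. = FALSE)
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1L))))
    stop("all frames must have the same shape", call. = FALSE)
  if (pixel_size_um <= 0 || frame_interval_s <= 0)
    stop("calibration values must be positive", call. = FALSE)
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat("Frame stack: ", length(x$frames), " frame(s) of ", d[1L], "x", d[2L],
      " px; ", x$pixel_size_um, " um/px, ", x$frame_interval_s, " s/frame\n",
      sep = "")
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Read a multi-page TIFF as a frame stack
#'
#' @param path TIFF file path.
#' @param pixel_size_um,frame_interval_s calibration (TIFF tags are not
#'   relied upon).
#' @return a [frame_stack()]; 16-bit and RGB pages are converted to 8-bit
#'   grayscale via [to_grayscale_8bit()].
#' @export
read_frame_stack <- function(path, pixel_size_um = 0.13, frame_interval_s = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, to_grayscale_8bit)
  frame_stack(frames, pixel_size_um, frame_interval_s)
}

#' Write a frame stack as a multi-page 8-bit grayscale TIFF
#'
#' @param stack a [frame_stack()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  imgs <- lapply(stack$frames, function(f) {
    f <- to_grayscale_8bit(f)
    matrix(f / 255, nrow(f), ncol(f))
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  invisible(path)
}

#' Convert a frame to 8-bit grayscale
#'
#' RGB input (H x W x 3) is combined with the standard luminance weights
#' (0.299, 0.587, 0.114) and rounded. Single-channel 16-bit input is
#' rescaled by full-range division (/257, mapping 65535 to 255) and
#' rounded; 8-bit input passes through unchanged. Bit depth is taken from
#' `bit_depth`, or inferred (`"auto"`): values above 255 imply 16-bit.
#'
#' @param frame 2D matrix or H x W x 3 array.
#' @param bit_depth `"auto"`, `"8"` or `"16"` (single-channel input only).
#' @return integer matrix with values in 0..255.
#' @examples
#' to_grayscale_8bit(matrix(65535L, 2, 2))   # all 255
#' @export
to_grayscale_8bit <- function(frame, bit_depth = c("auto", "8", "16")) {
  bit_depth <- match.arg(bit_depth)
  if (is.array(frame) && length(dim(frame)) == 3L) {
    if (dim(frame)[3L] != 3L)
      stop("unsupported channel count: ", dim(frame)[3L], call. = FALSE)
    ch <- frame
    if (max(ch) > 255) ch <- ch / 257
    g <- 0.299 * ch[, , 1L] + 0.587 * ch[, , 2L] + 0.114 * ch[, , 3L]
    return(matrix(as.integer(round(g)), dim(frame)[1L], dim(frame)[2L]))
  }
  if (!is.matrix(frame)) stop("'frame' must be a matrix or H x W x 3 array",
                              call. = FALSE)
  is16 <- switch(bit_depth, auto = max(frame) > 255, `8` = FALSE, `16` = TRUE)
  v <- if (is16) round(frame / 257) else round(frame)
  matrix(as.integer(pmin(255L, pmax(0L, v))), nrow(frame), ncol(frame))
}
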