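# Punctum detection: global thresholding, 8-connected component labeling,
# and per-object centroid/area/intensity extraction.

#' Label 8-connected foreground components
#'
#' Iterative minimum-label propagation: every foreground pixel starts with
#' its own label (its linear index) and repeatedly adopts the smallest label
#' among itself and its 8 neighbors until a fixed point. Labels are then
#' renumbered 1..k in raster-scan order (row by row, left to right) of each
#' component's first pixel.
#'
#' @param bw logical matrix of foreground pixels.
#' @return integer matrix of component labels (0 = background).
#' @keywords internal
#' @noRd
label_components <- function(bw) {
  H <- nrow(bw); W <- ncol(bw)
  lab <- matrix(Inf, H, W)
  lab[bw] <- which(bw)
  shift <- function(M, dr, dc) {
    out <- matrix(Inf, H, W)
    rs <- max(1L, 1L + dr):min(H, H + dr)
    cs <- max(1L, 1L + dc):min(W, W + dc)
    out[rs, cs] <- M[rs - dr, cs - dc]
    out
  }
  repeat {
    nxt <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nxt <- pmin(nxt, shift(lab, dr, dc))
    }
    nxt[!bw] <- Inf
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  out <- matrix(0L, H, W)
  if (any(bw)) {
    vals <- lab[bw]
    # raster order of each component's first pixel: rank by min(y*W + x)
    rows <- row(bw)[bw] - 1L; cols <- col(bw)[bw] - 1L
    raster <- rows * W + cols
    first <- tapply(raster, vals, min)
    ord <- rank(first)
    out[bw] <- as.integer(ord[match(vals, as.numeric(names(first)))])
  }
  out
}

#' Segment one frame into punctate objects
#'
#' Binarizes the frame by a global intensity threshold (foreground is
#' strictly greater than the threshold by default), labels 8-connected
#' components, and measures each object: pixel area, binary-moment centroid
#' (unweighted mean of member pixel coordinates, 0-based), and summed
#' intensity. Objects are returned in raster-scan order.
#'
#' @param frame 2D 8-bit matrix (use [to_grayscale_8bit()] first if needed).
#' @param threshold global intensity threshold; default 100.
#' @param frame_index value for the `frame` column (0-based).
#' @param min_area drop objects smaller than this many pixels (default 1,
#'   i.e. no filtering).
#' @param strict if `TRUE` (default) foreground is `> threshold`; if
#'   `FALSE`, `>= threshold`.
#' @return a `detection_table` data frame with columns
#'   `frame`, `x`, `y`, `area_px2`, `intensity_sum`, `region`.
#' @examples
#' fr <- matrix(0L, 30, 40); fr[11:15, 21:25] <- 200L
#' segment_frame(fr)   # one object, area 25, centroid (22, 12)
#' @export
segment_frame <- function(frame, threshold = 100, frame_index = 0L,
                          min_area = 1L, strict = TRUE) {
  if (!is.matrix(frame)) stop("'frame' must be a 2D matrix", call. = FALSE)
  bw <- if (strict) frame > threshold else frame >= threshold
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      area_px2 = integer(0), intensity_sum = numeric(0),
                      region = character(0))
  if (!any(bw)) {
    class(empty) <- c("detection_table", "data.frame")
    return(empty)
  }
  lab <- label_components(bw)
  ids <- lab[bw]
  xs <- col(bw)[bw] - 1L
  ys <- row(bw)[bw] - 1L
  ints <- frame[bw]
  area <- tabulate(ids)
  cx <- as.vector(rowsum(xs, ids)) / area
  cy <- as.vector(rowsum(ys, ids)) / area
  isum <- as.vector(rowsum(as.numeric(ints), ids))
  out <- data.frame(frame = as.integer(frame_index), x = cx, y = cy,
                    area_px2 = area, intensity_sum = isum, region = "none")
  out <- out[out$area_px2 >= min_area, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("detection_table", "data.frame")
  out
}

#' Detect objects across a stack
#'
#' Applies [segment_frame()] to the first `max_frames` frames (all frames by
#' default; the spatial analysis uses the first 50) and concatenates the
#' per-frame detection tables.
#'
#' @param stack a [frame_stack()].
#' @param threshold global intensity threshold; default 100.
#' @param max_frames number of leading frames to analyze, or `NULL` for all.
#' @param min_area,strict passed to [segment_frame()].
#' @return a `detection_table` with a populated 0-based `frame` column and
#'   attributes `n_frames` (frames analyzed), `pixel_size_um`,
#'   `frame_interval_s`, `image_shape`.
#' @export
detect_stack <- function(stack, threshold = 100, max_frames = NULL,
                         min_area = 1L, strict = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  nT <- length(stack$frames)
  if (nT < 1L) stop("empty stack", call. = FALSE)
  nuse <- if (is.null(max_frames)) nT else min(nT, max_frames)
  rows <- lapply(seq_len(nuse), function(i)
    segment_frame(to_grayscale_8bit(stack$frames[[i]]), threshold,
                  frame_index = i - 1L, min_area = min_area, strict = strict))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("detection_table", "data.frame")
  attr(out, "n_frames") <- nuse
  attr(out, "pixel_size_um") <- stack$pixel_size_um
  attr(out, "frame_interval_s") <- stack$frame_interval_s
  attr(out, "image_shape") <- dim(stack$frames[[1L]])
  out
}

#' Per-frame object counts and their mean
#'
#' @param detections a `detection_table`.
#' @param n_frames number of frames analyzed (frames with zero objects count
#'   as zero); defaults to the table's `n_frames` attribute, else the
#'   largest frame index + 1.
#' @return list with `counts` (data frame `frame`, `n`) and `mean_count`.
#' @examples
#' d <- data.frame(frame = c(0, 0, 1), x = 1, y = 1,
#'                 area_px2 = 1, intensity_sum = 1, region = "none")
#' summarize_counts(d, n_frames = 2)$mean_count   # 1.5
#' @export
summarize_counts <- function(detections, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- attr(detections, "n_frames")
  if (is.null(n_frames))
    n_frames <- if (nrow(detections)) max(detections$frame) + 1L else 0L
  frames <- seq_len(n_frames) - 1L
  n <- vapply(frames, function(f) sum(detections$frame == f), integer(1L))
  list(counts = data.frame(frame = frames, n = n),
       mean_count = if (n_frames) mean(n) else NA_real_)
}

#' Write / read a detection table as CSV
#'
#' @param detections a `detection_table`.
#' @param path CSV file path.
#' @return `write_detections()` returns `path` invisibly;
#'   `read_detections()` returns a `detection_table`.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(as.data.frame(detections)[, c("frame", "x", "y", "area_px2",
                                                 "intensity_sum", "region")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("detection_table", "data.frame")
  out
}
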