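# Ripley's K function: per-frame estimates, the CSR baseline, and
# frame/video aggregation with confidence intervals.

#' Ripley's K function of a planar point pattern
#'
#' The uncorrected (no edge correction) estimator
#' \deqn{K(r) = \frac{A}{n(n-1)} \#\{(i,j): i \ne j,\ d_{ij} \le r\}}
#' over ordered pairs — an area-normalized count of point pairs within each
#' distance threshold. Under complete spatial randomness K(r) equals
#' \eqn{\pi r^2}; values above/below indicate clustering/dispersion at
#' scale r. Without edge correction the estimator is biased downward as r
#' approaches the window size, which is acceptable for comparing groups
#' analyzed identically.
#'
#' @param points 2-column matrix (or data frame with `x`, `y`) of
#'   coordinates, px; at least 2 points.
#' @param radii ascending positive radius grid, px; default `1:250`.
#' @param window_area normalizing area A, px^2 (typically the alpha-shape
#'   cell-mask pixel count).
#' @return a `k_curve` data frame (`r_px`, `k`) with attributes `n_points`,
#'   `window_area`, `frame`.
#' @examples
#' ripley_k(rbind(c(0, 0), c(3, 4)), radii = c(4, 5, 6), window_area = 100)
#' @export
ripley_k <- function(points, radii = 1:250, window_area) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  n <- nrow(points)
  if (is.null(n) || n < 2L) stop("insufficient points (need n >= 2)", call. = FALSE)
  if (window_area <= 0) stop("'window_area' must be positive", call. = FALSE)
  if (is.unsorted(radii) || any(radii <= 0))
    stop("'radii' must be ascending and positive", call. = FALSE)
  d <- sort(stats::dist(points))
  pairs <- findInterval(radii, d)            # unordered pairs with d <= r
  k <- window_area * 2 * pairs / (n * (n - 1))
  structure(data.frame(r_px = radii, k = k),
            class = c("k_curve", "data.frame"),
            n_points = n, window_area = window_area, frame = NA_integer_)
}

#' Theoretical K under complete spatial randomness
#'
#' @param radii radius grid, px.
#' @return numeric vector \eqn{\pi r^2}.
#' @export
csr_baseline <- function(radii) {
  if (any(radii < 0)) stop("'radii' must be non-negative", call. = FALSE)
  pi * radii^2
}

#' Per-frame K curves for a detection table
#'
#' Runs [ripley_k()] on the centroids of every frame; frames with fewer
#' than 2 detections are skipped with a message reporting how many.
#'
#' @param detections a `detection_table` (optionally region-filtered).
#' @param radii radius grid, px.
#' @param window_area normalizing area, px^2.
#' @return list of `k_curve`s (one per usable frame), with attribute
#'   `n_skipped`.
#' @export
ripley_k_stack <- function(detections, radii = 1:250, window_area) {
  frames <- sort(unique(detections$frame))
  curves <- list()
  skipped <- 0L
  for (f in frames) {
    pf <- detections[detections$frame == f, c("x", "y")]
    if (nrow(pf) < 2L) { skipped <- skipped + 1L; next }
    cv <- ripley_k(pf, radii, window_area)
    attr(cv, "frame") <- f
    curves[[length(curves) + 1L]] <- cv
  }
  if (skipped) message(skipped, " frame(s) with < 2 detections skipped")
  attr(curves, "n_skipped") <- skipped
  curves
}

#' Average K curves over the frames of a video
#'
#' Pointwise arithmetic mean of per-frame K(r) curves sharing one radius
#' grid; the video-level spatial-organization summary.
#'
#' @param curves list of `k_curve`s (e.g. from [ripley_k_stack()]).
#' @return a `k_curve` data frame (`r_px`, `k`) with attribute `n_frames`.
#' @export
mean_k_over_frames <- function(curves) {
  if (!length(curves)) stop("empty curve list", call. = FALSE)
  r <- curves[[1L]]$r_px
  for (cv in curves) if (!identical(cv$r_px, r))
    stop("curves have mismatched radius grids", call. = FALSE)
  km <- rowMeans(vapply(curves, function(cv) cv$k, numeric(length(r))))
  structure(data.frame(r_px = r, k = km),
            class = c("k_curve", "data.frame"), n_frames = length(curves))
}

#' Group-level K summary with confidence intervals
#'
#' Pointwise mean of per-video mean K curves with a normal-approximation
#' confidence band, mean +/- z * SD / sqrt(n_videos) (z = 1.96 for 95%).
#' With a single video the band collapses to the mean (with a warning).
#'
#' @param video_means list of per-video mean `k_curve`s.
#' @param group_label text label for the group.
#' @param z normal quantile (default 1.96); set
#'   `z = qt(0.975, n - 1)` for a t-based band.
#' @return a `group_k_summary` data frame (`r_px`, `mean_k`, `ci_low`,
#'   `ci_high`) with attributes `n_videos`, `group_label`.
#' @export
group_k_summary <- function(video_means, group_label = "", z = 1.96) {
  if (!length(video_means)) stop("empty curve list", call. = FALSE)
  r <- video_means[[1L]]$r_px
  for (cv in video_means) if (!identical(cv$r_px, r))
    stop("curves have mismatched radius grids", call. = FALSE)
  m <- vapply(video_means, function(cv) cv$k, numeric(length(r)))
  m <- matrix(m, nrow = length(r))
  n <- ncol(m)
  mean_k <- rowMeans(m)
  if (n == 1L) {
    warning("single video: confidence interval collapses to the mean")
    half <- rep(0, length(r))
  } else {
    half <- z * apply(m, 1L, stats::sd) / sqrt(n)
  }
  structure(data.frame(r_px = r, mean_k = mean_k,
                       ci_low = mean_k - half, ci_high = mean_k + half),
            class = c("group_k_summary", "data.frame"),
            n_videos = n, group_label = group_label)
}

#' Plot a K curve or group summary against the CSR baseline
#'
#' @param x a `k_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.k_curve <- function(x, ...) {
  graphics::plot(x$r_px, x$k, type = "l", xlab = "r (px)",
                 ylab = expression(K(r) ~ (px^2)), ...)
  graphics::lines(x$r_px, csr_baseline(x$r_px), lty = 2, col = "grey40")
  graphics::legend("topleft", c("K(r)", expression(pi * r^2 ~ "(CSR)")),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(x)
}

#' @export
plot.group_k_summary <- function(x, ...) {
  graphics::plot(x$r_px, x$mean_k, type = "n", xlab = "r (px)",
                 ylab = expression(bar(K)(r) ~ (px^2)), ...)
  graphics::polygon(c(x$r_px, rev(x$r_px)), c(x$ci_low, rev(x$ci_high)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$r_px, x$mean_k, col = "steelblue")
  graphics::lines(x$r_px, csr_baseline(x$r_px), lty = 2, col = "grey40")
  invisible(x)
}

#' Write a K curve (with CSR baseline) or group summary as CSV
#'
#' @param curve a `k_curve` or `group_k_summary`.
#' @param path CSV file path.
#' @export
write_k_curve <- function(curve, path) {
  if (inherits(curve, "group_k_summary")) {
    out <- data.frame(r_px = curve$r_px, mean_k = curve$mean_k,
                      ci_low = curve$ci_low, ci_high = curve$ci_high,
                      n_videos = attr(curve, "n_videos"))
  } else {
    out <- data.frame(r_px = curve$r_px, k = curve$k,
                      csr_baseline = csr_baseline(curve$r_px))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
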