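# Ensemble mean-squared displacement and the power-law diffusion fit
# EMSD(tau) = 4 * D * tau^alpha.

#' Ensemble mean-squared displacement
#'
#' For each lag tau, pools every displacement pair
#' `(x(t+tau) - x(t), y(t+tau) - y(t))` across all tracks and all
#' overlapping start times t at which both frames are detected (frames
#' missing inside a gap contribute no pairs), and averages the squared
#' displacements with equal weight per pair. Lags with zero pairs are
#' omitted. `per_track = TRUE` instead averages per-track MSD curves with
#' equal weight per track.
#'
#' @param tracks a `track_table` (`particle_id`, `frame`, `x`, `y`).
#' @param max_lag largest lag in frames; defaults to the longest track span
#'   minus one.
#' @param pixel_size_um,frame_interval_s calibration used for the um^2 and
#'   seconds columns (defaults 1: pixel/frame units).
#' @param per_track average per-track MSDs instead of pooling pairs.
#' @return an `emsd_curve` data frame: `lag_frames`, `lag_s`, `emsd_px2`,
#'   `emsd_um2`, `n_pairs`.
#' @examples
#' tr <- data.frame(particle_id = 1, frame = 0:9, x = 0:9, y = 0)
#' emsd(tr)   # ballistic: EMSD(tau) = tau^2
#' @export
emsd <- function(tracks, max_lag = NULL, pixel_size_um = 1,
                 frame_interval_s = 1, per_track = FALSE) {
  if (!nrow(tracks)) stop("no tracks", call. = FALSE)
  by_id <- split(tracks[, c("frame", "x", "y")], tracks$particle_id)
  spans <- vapply(by_id, function(tr) diff(range(tr$frame)), numeric(1L))
  if (is.null(max_lag)) max_lag <- max(spans)
  if (max_lag < 1L) stop("'max_lag' must be at least 1", call. = FALSE)
  nlag <- as.integer(max_lag)
  sums <- counts <- matrix(0, nlag, length(by_id))
  for (j in seq_along(by_id)) {
    tr <- by_id[[j]]
    tr <- tr[order(tr$frame), ]
    f0 <- tr$frame[1L]
    L <- tr$frame[nrow(tr)] - f0 + 1L
    px <- py <- rep(NA_real_, L)
    px[tr$frame - f0 + 1L] <- tr$x
    py[tr$frame - f0 + 1L] <- tr$y
    for (tau in seq_len(min(nlag, L - 1L))) {
      dx <- px[(1L + tau):L] - px[1L:(L - tau)]
      dy <- py[(1L + tau):L] - py[1L:(L - tau)]
      sq <- dx * dx + dy * dy
      ok <- !is.na(sq)
      sums[tau, j] <- sum(sq[ok])
      counts[tau, j] <- sum(ok)
    }
  }
  if (per_track) {
    with_pairs <- counts > 0
    msd_tr <- ifelse(with_pairs, sums / pmax(counts, 1L), NA_real_)
    val <- rowMeans(msd_tr, na.rm = TRUE)
    npair <- rowSums(with_pairs)
  } else {
    val <- rowSums(sums) / pmax(rowSums(counts), 1L)
    npair <- rowSums(counts)
  }
  keep <- npair > 0
  if (!any(keep)) stop("no usable displacement pairs at any lag", call. = FALSE)
  lags <- seq_len(nlag)[keep]
  structure(data.frame(lag_frames = lags,
                       lag_s = lags * frame_interval_s,
                       emsd_px2 = val[keep],
                       emsd_um2 = val[keep] * pixel_size_um^2,
                       n_pairs = npair[keep]),
            class = c("emsd_curve", "data.frame"),
            pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s)
}

#' Fit the power law EMSD(tau) = 4 D tau^alpha
#'
#' Ordinary least squares of `ln(EMSD)` on `ln(tau)` over the chosen lag
#' range. The slope is the diffusion exponent alpha; the generalized
#' diffusion coefficient is `D = exp(intercept) / 4` (px^2/frame^alpha).
#' The motion regime is classified against a tolerance band `delta` around
#' alpha = 1: subdiffusive below `1 - delta`, Brownian within, and
#' superdiffusive above `1 + delta`.
#'
#' @param curve an [emsd()] curve.
#' @param fit_lags lags (frames) to fit over; default
#'   `1:min(20, floor(max_lag / 2))` — long-lag EMSD values rest on few
#'   pairs and are noisy.
#' @param delta half-width of the Brownian classification band
#'   (default 0.1).
#' @return a `diffusion_fit` object with elements `alpha`, `d_apparent`,
#'   `intercept_log`, `r_squared`, `alpha_se`, `fit_lag_range`, `regime`,
#'   plus the fitted `lm` model and the input curve.
#' @examples
#' tr <- data.frame(particle_id = 1, frame = 0:20, x = 0:20, y = 0)
#' fit_power_law(emsd(tr))   # ballistic: alpha = 2, D = 0.25
#' @export
fit_power_law <- function(curve, fit_lags = NULL, delta = 0.1) {
  if (is.null(fit_lags)) {
    ml <- max(curve$lag_frames)
    fit_lags <- seq_len(max(2L, min(20L, floor(ml / 2))))
  }
  sub <- curve[curve$lag_frames %in% fit_lags, , drop = FALSE]
  bad <- sub$lag_frames[sub$emsd_px2 <= 0]
  if (length(bad))
    stop("non-positive EMSD at lag(s) ", paste(bad, collapse = ", "),
         ": cannot fit in log-log space", call. = FALSE)
  if (nrow(sub) < 2L)
    stop("need at least 2 positive EMSD points in the fit range", call. = FALSE)
  model <- stats::lm(log(emsd_px2) ~ log(lag_frames), data = sub)
  cf <- stats::coef(model)
  alpha <- unname(cf[2L])
  intercept <- unname(cf[1L])
  smry <- suppressWarnings(summary(model))  # exact power laws fit perfectly
  se <- tryCatch(smry$coefficients[2L, 2L], error = function(e) NA_real_)
  regime <- if (alpha < 1 - delta) "subdiffusive"
            else if (alpha > 1 + delta) "superdiffusive"
            else "brownian"
  structure(list(alpha = alpha,
                 d_apparent = exp(intercept) / 4,
                 intercept_log = intercept,
                 r_squared = smry$r.squared,
                 alpha_se = se,
                 fit_lag_range = range(sub$lag_frames),
                 regime = regime,
                 delta = delta,
                 model = model,
                 curve = curve),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, digits = 4L, ...) {
  cat("Power-law diffusion fit: EMSD(tau) = 4 D tau^alpha\n")
  cat("  alpha = ", format(x$alpha, digits = digits),
      " (SE ", format(x$alpha_se, digits = 3L), ")",
      "   D = ", format(x$d_apparent, digits = digits),
      " px^2/frame^alpha\n", sep = "")
  cat("  R^2 = ", format(x$r_squared, digits = digits),
      "   lags ", x$fit_lag_range[1L], "-", x$fit_lag_range[2L],
      "   regime: ", x$regime, " (|alpha - 1| band ", x$delta, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.diffusion_fit <- function(object, ...) {
  print(object)
  cat("\nLog-log regression:\n")
  print(summary(object$model)$coefficients)
  invisible(object)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(alpha = object$alpha, D = object$d_apparent)
}

#' @export
predict.diffusion_fit <- function(object, lags = NULL, ...) {
  if (is.null(lags)) lags <- object$curve$lag_frames
  4 * object$d_apparent * lags^object$alpha
}

#' @export
residuals.diffusion_fit <- function(object, ...) stats::residuals(object$model)

#' @export
plot.diffusion_fit <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$lag_frames, cv$emsd_px2, log = "xy",
                 xlab = expression(tau ~ "(frames)"),
                 ylab = expression(EMSD ~ (px^2)), ...)
  graphics::lines(cv$lag_frames, predict(x), col = "firebrick")
  graphics::legend("topleft",
                   sprintf("alpha = %.3f, D = %.3g (%s)", x$alpha,
                           x$d_apparent, x$regime),
                   bty = "n")
  invisible(x)
}

#' Region-resolved diffusion analysis
#'
#' Partitions detections by region label (whole cell = every detection
#' inside the cell, plus the perinuclear and peripheral subsets), then
#' independently links, length-filters, computes the pooled EMSD, and fits
#' the power law for each region. Regions with no track surviving the
#' length filter are reported absent (`NULL`) with a message, not an error.
#'
#' @param detections a `detection_table` with regions assigned
#'   ([assign_regions()]).
#' @param masks the [region_mask_set()] used for assignment (kept for the
#'   result's provenance; may be `NULL` if regions are pre-assigned).
#' @param params a [link_params()] list.
#' @param max_lag,fit_lags,delta passed to [emsd()] / [fit_power_law()].
#' @param pixel_size_um,frame_interval_s calibration for the EMSD curve.
#' @return named list (`whole`, `perinuclear`, `peripheral`); each element
#'   is `NULL` or a list with `fit` (a `diffusion_fit`), `curve`, `tracks`,
#'   `n_tracks`.
#' @export
regional_diffusion <- function(detections, masks = NULL,
                               params = link_params(), max_lag = NULL,
                               fit_lags = NULL, delta = 0.1,
                               pixel_size_um = 1, frame_interval_s = 1) {
  sel <- list(
    whole = detections$region != "none",
    perinuclear = if ("in_perinuclear" %in% names(detections))
      detections$in_perinuclear else detections$region == "perinuclear",
    peripheral = if ("in_peripheral" %in% names(detections))
      detections$in_peripheral else detections$region == "peripheral")
  out <- vector("list", 3L)
  names(out) <- names(sel)
  for (rg in names(sel)) {
    d <- detections[sel[[rg]], , drop = FALSE]
    if (!nrow(d)) { message("region '", rg, "': no detections"); next }
    tr <- filter_tracks(link_trajectories(d, params), params$min_length)
    if (!nrow(tr)) {
      message("region '", rg, "': no track survived the minimum-length ",
              "filter (min_length = ", params$min_length, ")")
      next
    }
    cv <- emsd(tr, max_lag = max_lag, pixel_size_um = pixel_size_um,
               frame_interval_s = frame_interval_s)
    out[[rg]] <- list(fit = fit_power_law(cv, fit_lags, delta), curve = cv,
                      tracks = tr, n_tracks = length(unique(tr$particle_id)))
  }
  out
}

#' Write an EMSD curve / diffusion fit to disk
#'
#' @param curve an `emsd_curve`.
#' @param path output path (CSV for curves, JSON for fits).
#' @export
write_emsd <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emsd
#' @param fit a `diffusion_fit`.
#' @param region optional region label recorded in the JSON.
#' @export
write_diffusion_fit <- function(fit, path, region = NULL) {
  jsonlite::write_json(list(alpha = fit$alpha, D = fit$d_apparent,
                            intercept_log = fit$intercept_log,
                            r_squared = fit$r_squared,
                            alpha_se = fit$alpha_se,
                            fit_lag_range = fit$fit_lag_range,
                            regime = fit$regime, delta = fit$delta,
                            region = region),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
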