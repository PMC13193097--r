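# Intensity-distribution metrics: perinuclear index, corrected total cell
# fluorescence, and region-resolved object areas.

#' Perinuclear index from an intensity image
#'
#' Quantifies whether signal sits near the nucleus or at the cell
#' periphery. A Euclidean distance-from-nucleus field is built inside the
#' cell mask; the perinuclear fraction `I<5` is the summed intensity within
#' 0-5 um of the nuclear boundary divided by the whole-cell total, and the
#' peripheral fraction `I>10` is the summed intensity beyond 10 um, also
#' normalized. The index is `(I<5 - I>10) * 100`: +100 when all signal is
#' perinuclear, -100 when all is peripheral. The 5-10 um zone is reported
#' but does not enter the index; the whole-cell total includes the nuclear
#' interior (set `include_nucleus_in_total = FALSE` to exclude it).
#'
#' @param image 2D intensity matrix.
#' @param geometry a `cell_geometry` (cell and nucleus masks), or a list
#'   with `cell_mask` and `nucleus_mask`.
#' @param zone_width_um perinuclear band width, um (default 5).
#' @param peripheral_cutoff_um distance beyond which signal counts as
#'   peripheral, um (default 10).
#' @param pixel_size_um calibration; defaults to the geometry's.
#' @param include_nucleus_in_total include nuclear signal in the total
#'   (default `TRUE`).
#' @return a `perinuclear_profile` list: `i_nucleus`, `i_zone_0_5`,
#'   `i_zone_5_10`, `i_periphery_gt10`, `i_total`, `i_lt5_frac`,
#'   `i_gt10_frac`, `perinuclear_index`, `zone_width_um`.
#' @export
perinuclear_index <- function(image, geometry, zone_width_um = 5,
                              peripheral_cutoff_um = 10,
                              pixel_size_um = NULL,
                              include_nucleus_in_total = TRUE) {
  cell <- geometry$cell_mask > 0
  nuc <- geometry$nucleus_mask > 0
  if (is.null(pixel_size_um)) pixel_size_um <- geometry$pixel_size_um
  if (is.null(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be positive", call. = FALSE)
  if (!identical(dim(image), dim(cell)))
    stop("image and mask shapes differ", call. = FALSE)
  if (any(nuc & !cell)) stop("nucleus not contained in the cell mask", call. = FALSE)
  d_um <- dist_to_mask(nuc) * pixel_size_um
  i_total <- sum(image[if (include_nucleus_in_total) cell else (cell & !nuc)])
  if (i_total == 0) stop("zero total intensity in the cell", call. = FALSE)
  inzone <- cell & !nuc & d_um > 0 & d_um <= zone_width_um
  midzone <- cell & !nuc & d_um > zone_width_um & d_um <= peripheral_cutoff_um
  outer <- cell & d_um > peripheral_cutoff_um
  i_zone <- sum(image[inzone])
  i_out <- sum(image[outer])
  lt5 <- i_zone / i_total
  gt10 <- i_out / i_total
  structure(list(i_nucleus = sum(image[nuc]),
                 i_zone_0_5 = i_zone,
                 i_zone_5_10 = sum(image[midzone]),
                 i_periphery_gt10 = i_out,
                 i_total = i_total,
                 i_lt5_frac = lt5,
                 i_gt10_frac = gt10,
                 perinuclear_index = (lt5 - gt10) * 100,
                 zone_width_um = zone_width_um,
                 peripheral_cutoff_um = peripheral_cutoff_um,
                 pixel_size_um = pixel_size_um),
            class = "perinuclear_profile")
}

#' @export
print.perinuclear_profile <- function(x, ...) {
  cat("Perinuclear profile: index ", round(x$perinuclear_index, 2),
      "  (I<", x$zone_width_um, "um = ", round(x$i_lt5_frac, 4),
      ", I>", x$peripheral_cutoff_um, "um = ", round(x$i_gt10_frac, 4),
      ")\n", sep = "")
  invisible(x)
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated density - (cell area x mean background fluorescence)`:
#' the summed intensity over the cell ROI minus the background expected
#' over the same area, estimated from a user-supplied background ROI.
#' Negative values are passed through.
#'
#' @param image 2D intensity matrix.
#' @param cell_roi logical mask (or polygon vertex matrix) of the cell.
#' @param background_roi logical mask (or polygon) of a cell-free
#'   background region; must be disjoint from the cell ROI.
#' @return a `ctcf_result` list: `integrated_density`, `cell_area_px2`,
#'   `mean_background`, `ctcf`.
#' @examples
#' img <- matrix(10, 20, 20); img[5:8, 5:8] <- 50
#' cell <- matrix(FALSE, 20, 20); cell[4:9, 4:9] <- TRUE
#' bg <- matrix(FALSE, 20, 20); bg[15:18, 15:18] <- TRUE
#' ctcf(img, cell, bg)
#' @export
ctcf <- function(image, cell_roi, background_roi) {
  as_mask <- function(roi) {
    if (is.matrix(roi) && ncol(roi) == 2L && !is.logical(roi) &&
        nrow(roi) >= 3L && !identical(dim(roi), dim(image)))
      polygon_mask(roi, dim(image))
    else roi > 0
  }
  cm <- as_mask(cell_roi)
  bm <- as_mask(background_roi)
  if (!any(cm) || !any(bm)) stop("empty ROI", call. = FALSE)
  if (any(cm & bm)) stop("cell and background ROIs overlap", call. = FALSE)
  integrated <- sum(image[cm])
  area <- sum(cm)
  mbg <- mean(image[bm])
  structure(list(integrated_density = integrated, cell_area_px2 = area,
                 mean_background = mbg, ctcf = integrated - area * mbg),
            class = "ctcf_result")
}

#' @export
print.ctcf_result <- function(x, ...) {
  cat("CTCF = ", x$ctcf, "  (integrated ", x$integrated_density,
      ", area ", x$cell_area_px2, " px^2, background ",
      round(x$mean_background, 4), ")\n", sep = "")
  invisible(x)
}

#' Mean object area per frame and region
#'
#' @param detections a region-labeled `detection_table`.
#' @param pixel_size_um optional calibration; adds a `mean_area_um2`
#'   column (um^2 = px^2 * pixel_size^2).
#' @param regions region labels to summarize.
#' @return data frame (`frame`, `region`, `n_objects`, `mean_area_px2`,
#'   and `mean_area_um2` when calibrated); frame/region combinations with
#'   zero objects are absent.
#' @export
region_area_summary <- function(detections, pixel_size_um = NULL,
                                regions = c("peripheral", "perinuclear",
                                            "whole")) {
  sel <- detections[detections$region %in% regions, , drop = FALSE]
  if (!nrow(sel))
    return(data.frame(frame = integer(0), region = character(0),
                      n_objects = integer(0), mean_area_px2 = numeric(0)))
  agg <- stats::aggregate(area_px2 ~ frame + region, data = sel,
                          FUN = function(a) c(n = length(a), m = mean(a)))
  out <- data.frame(frame = agg$frame, region = agg$region,
                    n_objects = as.integer(agg$area_px2[, "n"]),
                    mean_area_px2 = agg$area_px2[, "m"])
  if (!is.null(pixel_size_um))
    out$mean_area_um2 <- out$mean_area_px2 * pixel_size_um^2
  out <- out[order(out$frame, out$region), ]
  rownames(out) <- NULL
  out
}
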