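# End-to-end pipelines: spatial organization (counts, regions, Ripley's K)
# and motility (linking, EMSD, diffusion exponents), with a serializable
# configuration and self-documenting output manifests.

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the two pipelines with the defaults
#' of the published analysis: detection threshold 100 on 8-bit images over
#' the first 50 frames; alpha-shape parameter 0.02 (circumradius < 50 px);
#' 60 px (7.8 um) peripheral rim and 40 px (5.2 um) perinuclear annulus;
#' Ripley radii 1-250 px; linking search range 9 px, memory 5 frames,
#' minimum track length 20; Brownian classification band 0.1; calibration
#' 0.13 um/px.
#'
#' @param pixel_size_um,frame_interval_s calibration.
#' @param threshold,max_frames detection parameters.
#' @param alpha,rim_px,annulus_px,boundary_frame region parameters; the
#'   cell boundary is reconstructed from the centroids of
#'   `boundary_frame` (0-based, default 0, the first frame).
#' @param radii,window_area_mode Ripley's K radius grid and normalizing
#'   area (`"cell_mask"` or `"image"`).
#' @param search_range_px,memory_frames,min_length,fit_lags,delta tracking
#'   and fitting parameters (`fit_lags = NULL`: lags 1..min(20, max/2)).
#' @param seed integer seed for any stochastic step.
#' @param verbose logical.
#' @return a `pipeline_config` list that round-trips through
#'   [write_config()] / [read_config()] unchanged.
#' @export
pipeline_config <- function(pixel_size_um = 0.13, frame_interval_s = 1,
                            threshold = 100, max_frames = 50L,
                            alpha = 0.02, rim_px = 60L, annulus_px = 40L,
                            boundary_frame = 0L,
                            radii = 1:250,
                            window_area_mode = c("cell_mask", "image"),
                            search_range_px = 9, memory_frames = 5L,
                            min_length = 20L, fit_lags = NULL, delta = 0.1,
                            seed = 1L, verbose = FALSE) {
  window_area_mode <- match.arg(window_area_mode)
  cfg <- list(pixel_size_um = as.numeric(pixel_size_um),
              frame_interval_s = as.numeric(frame_interval_s),
              threshold = as.numeric(threshold),
              max_frames = as.integer(max_frames),
              alpha = as.numeric(alpha), rim_px = as.integer(rim_px),
              annulus_px = as.integer(annulus_px),
              boundary_frame = as.integer(boundary_frame),
              radii = as.integer(radii),
              window_area_mode = window_area_mode,
              search_range_px = as.numeric(search_range_px),
              memory_frames = as.integer(memory_frames),
              min_length = as.integer(min_length),
              fit_lags = if (!is.null(fit_lags)) as.integer(fit_lags),
              delta = as.numeric(delta), seed = as.integer(seed),
              verbose = isTRUE(verbose))
  if (cfg$threshold < 0 || cfg$max_frames < 1L || cfg$rim_px < 1L ||
      cfg$annulus_px < 1L || cfg$min_length < 2L)
    stop("invalid pipeline configuration", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration as JSON
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

pipeline_log <- function(config, ...) {
  if (isTRUE(config$verbose)) message(...)
}

write_manifest <- function(path, config, extra = list()) {
  jsonlite::write_json(c(list(package = "lysoquant",
                              version = as.character(utils::packageVersion("lysoquant")),
                              config = unclass(config)), extra),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

resolve_geometry <- function(detections, config, nucleus = NULL,
                             image_shape = NULL) {
  if (is.null(image_shape)) image_shape <- attr(detections, "image_shape")
  pts <- detections[detections$frame == config$boundary_frame, c("x", "y")]
  shape <- alpha_shape_boundary(pts, alpha = config$alpha,
                                image_shape = image_shape)
  nuc_mask <- NULL
  if (!is.null(nucleus)) {
    nuc_mask <- if (is.matrix(nucleus) && identical(dim(nucleus),
                                                    dim(shape$mask)))
      nucleus > 0
    else if (is.character(nucleus))
      polygon_mask(read_polygon(nucleus), dim(shape$mask))
    else polygon_mask(nucleus, dim(shape$mask))
  }
  list(shape = shape,
       masks = region_mask_set(shape$mask, nuc_mask, config$rim_px,
                               config$annulus_px, config$pixel_size_um))
}

#' Run the spatial-organization pipeline on one video
#'
#' Detects puncta on the first `max_frames` frames, reconstructs the cell
#' boundary from the boundary frame's centroids by alpha shape, builds the
#' region masks, labels detections, computes per-frame Ripley's K
#' normalized by the cell-mask area, averages K over frames, and summarizes
#' counts and region-resolved object areas. All tables plus a JSON manifest
#' of the exact parameters are written when `out_dir` is given.
#'
#' @param stack a [frame_stack()] or TIFF path.
#' @param config a [pipeline_config()].
#' @param nucleus optional nucleus annotation: logical mask, polygon
#'   matrix, or CSV path of vertices.
#' @param out_dir optional output directory.
#' @return list: `detections`, `geometry` (alpha-shape result), `masks`,
#'   `k_curves`, `mean_k`, `counts`, `areas`, `window_area`.
#' @export
run_spatial_pipeline <- function(stack, config = pipeline_config(),
                                 nucleus = NULL, out_dir = NULL) {
  if (is.character(stack))
    stack <- read_frame_stack(stack, config$pixel_size_um,
                              config$frame_interval_s)
  pipeline_log(config, "detecting objects on ",
               min(length(stack$frames), config$max_frames), " frame(s)")
  det <- detect_stack(stack, threshold = config$threshold,
                      max_frames = config$max_frames)
  if (!nrow(det)) stop("no detections in any frame", call. = FALSE)
  geo <- resolve_geometry(det, config)
  det <- assign_regions(det, geo$masks)
  A <- if (config$window_area_mode == "cell_mask") sum(geo$masks$whole)
       else prod(dim(stack$frames[[1L]]))
  curves <- ripley_k_stack(det[det$region != "none", , drop = FALSE],
                           radii = config$radii, window_area = A)
  if (!length(curves))
    stop("fewer than 2 detections in every frame: cannot compute K",
         call. = FALSE)
  kmean <- mean_k_over_frames(curves)
  counts <- summarize_counts(det)
  areas <- region_area_summary(det, pixel_size_um = config$pixel_size_um)
  res <- list(detections = det, geometry = geo$shape, masks = geo$masks,
              k_curves = curves, mean_k = kmean, counts = counts,
              areas = areas, window_area = A)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_detections(det, file.path(out_dir, "detections.csv"))
    write_k_curve(kmean, file.path(out_dir, "mean_k.csv"))
    utils::write.csv(counts$counts, file.path(out_dir, "counts.csv"),
                     row.names = FALSE)
    utils::write.csv(areas, file.path(out_dir, "region_areas.csv"),
                     row.names = FALSE)
    write_polygon(res$geometry$polygon, file.path(out_dir, "cell_boundary.csv"))
    write_manifest(file.path(out_dir, "manifest.json"), config,
                   list(analysis = "spatial", window_area_px2 = A,
                        mean_count = counts$mean_count,
                        n_frames_k = attr(kmean, "n_frames")))
  }
  res
}

#' Run the motility pipeline on one video
#'
#' Detects puncta on all frames, builds the region masks, and runs the
#' region-resolved diffusion analysis (link, length-filter, pooled EMSD,
#' power-law fit) for the whole cell, the perinuclear region, and the
#' peripheral region. EMSD CSVs and diffusion-fit JSONs per region plus a
#' manifest are written when `out_dir` is given.
#'
#' @inheritParams run_spatial_pipeline
#' @return list: `detections`, `masks`, `regional` (per-region fit
#'   bundles from [regional_diffusion()]).
#' @export
run_motility_pipeline <- function(stack, config = pipeline_config(),
                                  nucleus = NULL, out_dir = NULL) {
  if (is.character(stack))
    stack <- read_frame_stack(stack, config$pixel_size_um,
                              config$frame_interval_s)
  if (length(stack$frames) < config$min_length)
    warning("stack has fewer frames (", length(stack$frames),
            ") than min_length (", config$min_length,
            "): no track can survive the length filter")
  det <- detect_stack(stack, threshold = config$threshold)
  if (!nrow(det)) stop("no detections in any frame", call. = FALSE)
  geo <- resolve_geometry(det, config, nucleus = nucleus)
  det <- assign_regions(det, geo$masks)
  lp <- link_params(config$search_range_px, config$memory_frames,
                    config$min_length)
  regional <- regional_diffusion(det, geo$masks, lp,
                                 fit_lags = config$fit_lags,
                                 delta = config$delta,
                                 pixel_size_um = config$pixel_size_um,
                                 frame_interval_s = config$frame_interval_s)
  if (all(vapply(regional, is.null, logical(1L))))
    stop("no track survived the minimum-length filter (min_length = ",
         config$min_length, ") in any region", call. = FALSE)
  res <- list(detections = det, masks = geo$masks, geometry = geo$shape,
              regional = regional)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_detections(det, file.path(out_dir, "detections.csv"))
    for (rg in names(regional)) {
      if (is.null(regional[[rg]])) next
      write_emsd(regional[[rg]]$curve,
                 file.path(out_dir, paste0("emsd_", rg, ".csv")))
      write_diffusion_fit(regional[[rg]]$fit,
                          file.path(out_dir, paste0("fit_", rg, ".json")),
                          region = rg)
      write_tracks(regional[[rg]]$tracks,
                   file.path(out_dir, paste0("tracks_", rg, ".csv")))
    }
    write_manifest(file.path(out_dir, "manifest.json"), config,
                   list(analysis = "motility",
                        alphas = lapply(regional, function(r)
                          if (!is.null(r)) r$fit$alpha)))
  }
  res
}
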