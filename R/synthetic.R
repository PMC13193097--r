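# Ground-truthed synthetic data: cell geometries, point patterns,
# trajectories, and rendered image stacks.
#
# The generator emulates the imaging conditions of dextran/LAMP1-labeled
# HeLa cells: cell footprints of 500-1400 um^2, a calibration of 0.13 um/px,
# 50-frame videos, and punctate signals. Point patterns span
# clustered -> CSR -> dispersed; trajectories span sub-/normal/super-diffusive
# regimes so every downstream estimator can be validated against truth.

#' Construct a ground-truth scene
#' @noRd
new_scene <- function(positions, regime, true_params, window, geometry = NULL,
                      pixel_size_um = 0.13, frame_interval_s = 1, seed = NA_integer_,
                      n_frames = NA_integer_) {
  structure(list(
    positions = positions,          # data.frame(frame, particle_id, x, y)
    regime = regime,
    true_params = true_params,
    window = window,
    geometry = geometry,
    pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s,
    seed = as.integer(seed),
    n_frames = as.integer(n_frames)
  ), class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat("Ground-truth scene: regime '", x$regime, "', ", x$n_frames,
      " frame(s), ", length(unique(x$positions$particle_id)),
      " particle id(s)\n", sep = "")
  cat("  calibration: ", x$pixel_size_um, " um/px, ", x$frame_interval_s,
      " s/frame, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Synthetic cell and nucleus geometry
#'
#' Builds a closed cell polygon of a requested physical area with a
#' concentric nucleus, plus the corresponding binary raster masks. `disk`
#' gives a circle; `blob` perturbs the disk radius with a low-order Fourier
#' series (modes 3-6) and rescales so the polygon area matches the request,
#' emulating the irregular but star-shaped outline of an adherent HeLa cell.
#'
#' @param cell_area_um2 target cell footprint, um^2 (HeLa cells: 500-1400).
#' @param nucleus_fraction nucleus area as a fraction of cell area, in (0, 1).
#' @param pixel_size_um calibration, um per pixel.
#' @param shape `"disk"` or `"blob"`.
#' @param seed integer seed (blob perturbation only; disks are deterministic).
#' @param margin_px clear margin between the cell and the image border.
#' @return a `cell_geometry`: closed `cell_polygon` and `nucleus_polygon`
#'   (2-column x, y matrices, px), logical `cell_mask` and `nucleus_mask`,
#'   `shape` (H, W of the rasters), `pixel_size_um`, and `source`.
#' @examples
#' g <- make_cell_geometry(900, 0.2, 0.13, "disk", seed = 1)
#' sum(g$cell_mask) * 0.13^2   # ~900 um^2
#' @export
make_cell_geometry <- function(cell_area_um2 = 900, nucleus_fraction = 0.2,
                               pixel_size_um = 0.13,
                               shape = c("disk", "blob"), seed = 1L,
                               margin_px = 20L) {
  shape <- match.arg(shape)
  if (cell_area_um2 <= 0) stop("'cell_area_um2' must be positive", call. = FALSE)
  if (nucleus_fraction <= 0 || nucleus_fraction >= 1)
    stop("'nucleus_fraction' must be strictly between 0 and 1", call. = FALSE)
  target_px2 <- cell_area_um2 / pixel_size_um^2
  r0 <- sqrt(target_px2 / pi)
  theta <- seq(0, 2 * pi, length.out = 257L)[-257L]
  r <- with_seed(seed, {
    if (shape == "disk") rep(r0, length(theta))
    else {
      amp <- rnorm(4L, 0, 0.04)
      phase <- runif(4L, 0, 2 * pi)
      pert <- rep(0, length(theta))
      for (k in seq_along(amp)) pert <- pert + amp[k] * cos((k + 2L) * theta + phase[k])
      r0 * pmax(1 + pert, 0.2)
    }
  })
  poly <- cbind(x = r * cos(theta), y = r * sin(theta))
  poly <- scale_polygon(poly, sqrt(target_px2 / abs(poly_area(poly))))
  rmax <- max(sqrt(poly[, 1L]^2 + poly[, 2L]^2))
  half <- ceiling(rmax + margin_px)
  ctr <- half  # integer center; image is (2*half + 1)^2
  poly[, 1L] <- poly[, 1L] + ctr
  poly[, 2L] <- poly[, 2L] + ctr
  nuc <- scale_polygon(poly, sqrt(nucleus_fraction))
  shp <- c(2L * half + 1L, 2L * half + 1L)
  close_poly <- function(p) rbind(p, p[1L, , drop = FALSE])
  structure(list(
    cell_polygon = close_poly(poly),
    nucleus_polygon = close_poly(nuc),
    cell_mask = polygon_mask(poly, shp),
    nucleus_mask = polygon_mask(nuc, shp),
    shape = shp,
    pixel_size_um = pixel_size_um,
    source = "synthetic"
  ), class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("Cell geometry (", x$source, "): raster ", x$shape[1L], "x", x$shape[2L],
      " px, cell ", sum(x$cell_mask), " px^2",
      if (!is.null(x$nucleus_mask)) paste0(", nucleus ", sum(x$nucleus_mask), " px^2"),
      ", ", x$pixel_size_um, " um/px\n", sep = "")
  invisible(x)
}

#' Simulate static point patterns (CSR, clustered, dispersed)
#'
#' Draws `n_frames` independent point patterns inside a window, providing
#' the three canonical regimes of spatial organization against which
#' Ripley's K is validated: complete spatial randomness (uniform), a
#' Thomas-type parent-offspring cluster process, and a hard-core (minimum
#' spacing) inhibition process.
#'
#' @param kind `"csr"`, `"clustered"` or `"dispersed"`.
#' @param n points per frame. Under `poisson_counts = TRUE` the per-frame
#'   count is Poisson with this mean; the default fixed-n mode removes count
#'   variance (convenient for estimator tests).
#' @param window `c(width, height)` rectangle, a polygon matrix, or a
#'   `cell_geometry`.
#' @param n_frames number of independent frames.
#' @param seed integer seed; fully determines the scene.
#' @param n_parents,cluster_sd cluster process: number of uniformly placed
#'   parents and the Gaussian scatter (px) of offspring about their parent.
#'   Offspring falling outside the window are redrawn (bounded retries).
#' @param hardcore_radius dispersed: minimum pairwise distance (px),
#'   enforced by sequential inhibition; infeasible packings error out after
#'   bounded retries.
#' @param poisson_counts logical; Poisson per-frame counts for `"csr"`.
#' @param pixel_size_um,frame_interval_s calibration carried by the scene.
#' @return a `ground_truth_scene`; `$positions` has columns
#'   `frame` (0-based), `particle_id`, `x`, `y`.
#' @examples
#' sc <- simulate_point_pattern("csr", n = 50, window = c(200, 200), seed = 1)
#' head(sc$positions)
#' @export
simulate_point_pattern <- function(kind = c("csr", "clustered", "dispersed"),
                                   n, window, n_frames = 1L, seed = 1L,
                                   n_parents = max(1L, round(n / 10)),
                                   cluster_sd = 5, hardcore_radius = 5,
                                   poisson_counts = FALSE,
                                   pixel_size_um = 0.13, frame_interval_s = 1) {
  kind <- match.arg(kind)
  w <- as_window(window)
  A <- window_area(w)
  if (A <= 0) stop("window area must be positive", call. = FALSE)
  if (n < 0) stop("'n' must be non-negative", call. = FALSE)
  positions <- with_seed(seed, {
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      nf <- if (poisson_counts && kind == "csr") rpois(1L, n) else n
      pts <- switch(kind,
        csr = sample_in_window(nf, w),
        clustered = rthomas_frame(nf, n_parents, cluster_sd, w),
        dispersed = rhardcore_frame(nf, hardcore_radius, w))
      frames[[f]] <- if (nrow(pts)) data.frame(frame = f - 1L,
                                               particle_id = seq_len(nrow(pts)),
                                               x = pts[, 1L], y = pts[, 2L])
                     else data.frame(frame = integer(0), particle_id = integer(0),
                                     x = numeric(0), y = numeric(0))
    }
    do.call(rbind, frames)
  })
  params <- list(n = n, poisson_counts = poisson_counts)
  if (kind == "clustered") params <- c(params, list(n_parents = n_parents,
                                                    cluster_sd = cluster_sd))
  if (kind == "dispersed") params <- c(params, list(hardcore_radius = hardcore_radius))
  new_scene(positions, kind, params, w,
            geometry = if (inherits(window, "cell_geometry")) window else NULL,
            pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
            seed = seed, n_frames = n_frames)
}

# Thomas-type cluster frame with a fixed total count: parents uniform in the
# window, offspring split round-robin over parents and Gaussian-scattered;
# offspring outside the window are redrawn from the same parent.
rthomas_frame <- function(n, n_parents, cluster_sd, w, max_tries = 1000L) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  parents <- sample_in_window(n_parents, w)
  assign <- sample(rep(seq_len(n_parents), length.out = n))
  x <- y <- numeric(n)
  need <- seq_len(n)
  for (k in seq_len(max_tries)) {
    m <- length(need)
    xx <- parents[assign[need], 1L] + rnorm(m, 0, cluster_sd)
    yy <- parents[assign[need], 2L] + rnorm(m, 0, cluster_sd)
    ok <- in_window(xx, yy, w)
    x[need[ok]] <- xx[ok]; y[need[ok]] <- yy[ok]
    need <- need[!ok]
    if (!length(need)) break
  }
  if (length(need)) stop("failed to place cluster offspring inside the window",
                         call. = FALSE)
  cbind(x = x, y = y)
}

# Sequential (RSA) hard-core frame: uniform proposals, rejected when closer
# than the hard-core radius to an accepted point.
rhardcore_frame <- function(n, h, w, max_proposals_per_point = 200L) {
  if (h <= 0) stop("'hardcore_radius' must be positive", call. = FALSE)
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  x <- y <- numeric(n)
  placed <- 0L
  budget <- max_proposals_per_point * n
  while (placed < n && budget > 0L) {
    p <- sample_in_window(1L, w)
    budget <- budget - 1L
    if (placed == 0L ||
        min((x[seq_len(placed)] - p[1L])^2 + (y[seq_len(placed)] - p[2L])^2) >= h^2) {
      placed <- placed + 1L
      x[placed] <- p[1L]; y[placed] <- p[2L]
    }
  }
  if (placed < n)
    stop("hard-core radius ", h, " infeasible for n = ", n,
         " in this window (packing failed after bounded retries)", call. = FALSE)
  cbind(x = x, y = y)
}

#' Simulate particle trajectories (Brownian, confined, directed)
#'
#' Generates ground-truth trajectories of the three motion regimes the
#' diffusion-exponent fit distinguishes: free 2D Brownian motion
#' (per-axis increments Normal(0, 2*D*dt), dt = 1 frame), Brownian motion
#' reflected inside a circular corral centered on each particle's start
#' (subdiffusive at long lags), and constant-velocity drift plus Brownian
#' noise (superdiffusive). Rectangular windows use specular reflection at
#' the boundary (directed motion reflects billiard-style, flipping the
#' velocity component); polygon windows redraw boundary-crossing steps.
#'
#' @param regime `"brownian"`, `"confined"` or `"directed"`.
#' @param n_particles,n_frames counts; `n_frames >= 2`.
#' @param window `c(width, height)`, polygon matrix, or `cell_geometry`.
#' @param D diffusion coefficient, px^2/frame (>= 0).
#' @param velocity directed: scalar speed (px/frame, direction drawn
#'   uniformly per particle) or a fixed `c(vx, vy)` vector for all particles.
#' @param corral_radius confined: corral radius, px (> 0).
#' @param seed integer seed.
#' @param pixel_size_um,frame_interval_s calibration carried by the scene.
#' @return a `ground_truth_scene` with per-frame true positions and stable
#'   `particle_id`s.
#' @examples
#' sc <- simulate_trajectories("brownian", n_particles = 10, n_frames = 50,
#'                             window = c(200, 200), D = 0.25, seed = 1)
#' @export
simulate_trajectories <- function(regime = c("brownian", "confined", "directed"),
                                  n_particles, n_frames, window,
                                  D = 0.25, velocity = 0, corral_radius = 10,
                                  seed = 1L,
                                  pixel_size_um = 0.13, frame_interval_s = 1) {
  regime <- match.arg(regime)
  if (n_frames < 2L) stop("'n_frames' must be at least 2", call. = FALSE)
  if (D < 0) stop("'D' must be non-negative", call. = FALSE)
  w <- as_window(window)
  speed <- if (length(velocity) == 2L) sqrt(sum(velocity^2)) else abs(velocity)
  if (w$type == "rect" && speed > min(w$width, w$height))
    stop("velocity magnitude exceeds the window size per frame", call. = FALSE)
  if (regime == "confined" && corral_radius <= 0)
    stop("'corral_radius' must be positive", call. = FALSE)
  sd_step <- sqrt(2 * D)
  positions <- with_seed(seed, {
    if (regime == "confined" && w$type == "rect") {
      # keep whole corrals inside the rectangle
      r <- min(corral_radius, min(w$width, w$height) / 2 - 1e-9)
      cx <- runif(n_particles, r, w$width - r)
      cy <- runif(n_particles, r, w$height - r)
      start <- cbind(cx, cy)
    } else start <- sample_in_window(n_particles, w)
    if (regime == "directed") {
      if (length(velocity) == 2L) {
        vx <- rep(velocity[1L], n_particles); vy <- rep(velocity[2L], n_particles)
      } else {
        ang <- runif(n_particles, 0, 2 * pi)
        vx <- speed * cos(ang); vy <- speed * sin(ang)
      }
    } else vx <- vy <- numeric(n_particles)
    x <- matrix(NA_real_, n_frames, n_particles)
    y <- matrix(NA_real_, n_frames, n_particles)
    x[1L, ] <- start[, 1L]; y[1L, ] <- start[, 2L]
    for (f in 2L:n_frames) {
      nx <- x[f - 1L, ] + vx + rnorm(n_particles, 0, sd_step)
      ny <- y[f - 1L, ] + vy + rnorm(n_particles, 0, sd_step)
      if (regime == "confined") {
        dx <- nx - start[, 1L]; dy <- ny - start[, 2L]
        r <- sqrt(dx^2 + dy^2)
        out <- r > corral_radius & r > 0
        if (any(out)) {
          rr <- reflect_into(r[out], corral_radius)
          nx[out] <- start[out, 1L] + dx[out] * rr / r[out]
          ny[out] <- start[out, 2L] + dy[out] * rr / r[out]
        }
      }
      if (w$type == "rect") {
        # specular reflection; directed motion also flips its velocity
        flipx <- nx < 0 | nx > w$width
        flipy <- ny < 0 | ny > w$height
        nx <- reflect_into(nx, w$width)
        ny <- reflect_into(ny, w$height)
        if (regime == "directed") {
          vx[flipx] <- -vx[flipx]; vy[flipy] <- -vy[flipy]
        }
      } else {
        bad <- !in_window(nx, ny, w)
        tries <- 0L
        while (any(bad) && tries < 1000L) {
          nx[bad] <- x[f - 1L, bad] + vx[bad] + rnorm(sum(bad), 0, sd_step)
          ny[bad] <- y[f - 1L, bad] + vy[bad] + rnorm(sum(bad), 0, sd_step)
          bad <- !in_window(nx, ny, w)
          tries <- tries + 1L
        }
        if (any(bad)) { nx[bad] <- x[f - 1L, bad]; ny[bad] <- y[f - 1L, bad] }
      }
      x[f, ] <- nx; y[f, ] <- ny
    }
    data.frame(frame = rep(0L:(n_frames - 1L), times = n_particles),
               particle_id = rep(seq_len(n_particles), each = n_frames),
               x = as.vector(x), y = as.vector(y))
  })
  params <- list(D = D)
  if (regime == "directed") params$velocity <- velocity
  if (regime == "confined") params$corral_radius <- corral_radius
  new_scene(positions, regime, params, w,
            geometry = if (inherits(window, "cell_geometry")) window else NULL,
            pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
            seed = seed, n_frames = n_frames)
}

#' Rendering parameters for synthetic image stacks
#'
#' @param spot_sigma_px Gaussian spot radius (SD), px.
#' @param peak_intensity spot peak, 8-bit units; must exceed the detection
#'   threshold for rendered spots to be recoverable.
#' @param background_level constant background offset, 8-bit units.
#' @param noise_sd additive Gaussian noise SD, 8-bit units.
#' @param image_shape optional `c(H, W)`; defaults to the scene's window.
#' @param threshold detection threshold the recoverability warnings refer to.
#' @export
render_params <- function(spot_sigma_px = 1.5, peak_intensity = 200,
                          background_level = 20, noise_sd = 5,
                          image_shape = NULL, threshold = 100) {
  if (peak_intensity <= threshold)
    warning("peak_intensity <= threshold: rendered spots will not be detectable")
  if (background_level + 3 * noise_sd >= threshold)
    warning("background_level + 3*noise_sd >= threshold: ",
            "background may cross the detection threshold")
  structure(list(spot_sigma_px = spot_sigma_px, peak_intensity = peak_intensity,
                 background_level = background_level, noise_sd = noise_sd,
                 image_shape = image_shape, threshold = threshold),
            class = "render_params")
}

#' Render a ground-truth scene to an 8-bit image stack
#'
#' Each frame is `background + sum of Gaussian spots at the true positions
#' + optional Gaussian noise`, clipped and quantized to 8-bit. Noise is
#' seeded from the scene's seed so rendering is deterministic.
#'
#' @param scene a `ground_truth_scene`.
#' @param render a [render_params()] list.
#' @return a [frame_stack()] carrying the scene's calibration.
#' @examples
#' sc <- simulate_point_pattern("csr", n = 20, window = c(100, 100), seed = 1)
#' st <- render_stack(sc, render_params(noise_sd = 0))
#' @export
render_stack <- function(scene, render = render_params()) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  shp <- render$image_shape
  if (is.null(shp)) {
    bb <- scene$window$bbox
    shp <- c(ceiling(bb[4L]) + 1L, ceiling(bb[2L]) + 1L)
    if (!is.null(scene$geometry)) shp <- pmax(shp, scene$geometry$shape)
  }
  H <- shp[1L]; W <- shp[2L]
  pos <- scene$positions
  if (nrow(pos) && (max(pos$x) > W - 1 || max(pos$y) > H - 1 ||
                    min(pos$x) < 0 || min(pos$y) < 0))
    stop("image_shape too small to contain the scene positions", call. = FALSE)
  sigma <- render$spot_sigma_px
  ext <- ceiling(4 * sigma)
  frames <- with_seed(scene$seed + 10^6, {
    lapply(seq_len(scene$n_frames) - 1L, function(f) {
      img <- matrix(render$background_level, H, W)
      pf <- pos[pos$frame == f, , drop = FALSE]
      for (i in seq_len(nrow(pf))) {
        x0 <- pf$x[i]; y0 <- pf$y[i]
        cs <- max(0L, floor(x0) - ext):min(W - 1L, ceiling(x0) + ext)
        rs <- max(0L, floor(y0) - ext):min(H - 1L, ceiling(y0) + ext)
        spot <- render$peak_intensity *
          exp(-(outer((rs - y0)^2, (cs - x0)^2, "+")) / (2 * sigma^2))
        img[rs + 1L, cs + 1L] <- img[rs + 1L, cs + 1L] + spot
      }
      if (render$noise_sd > 0) img <- img + rnorm(length(img), 0, render$noise_sd)
      matrix(as.integer(pmin(255, pmax(0, round(img)))), H, W)
    })
  })
  frame_stack(frames, pixel_size_um = scene$pixel_size_um,
              frame_interval_s = scene$frame_interval_s)
}

#' Write a scene's ground truth to disk
#'
#' Writes `truth.csv` (frame, particle_id, x, y) and `scene.json`
#' (regime, true parameters, calibration, seed) into `dir`.
#'
#' @param scene a `ground_truth_scene`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- file.path(dir, "truth.csv")
  meta <- file.path(dir, "scene.json")
  utils::write.csv(scene$positions, truth, row.names = FALSE)
  jsonlite::write_json(list(regime = scene$regime,
                            true_params = scene$true_params,
                            pixel_size_um = scene$pixel_size_um,
                            frame_interval_s = scene$frame_interval_s,
                            n_frames = scene$n_frames,
                            seed = scene$seed),
                       meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(truth = truth, meta = meta))
}

#' Ground-truth positions as a track table
#'
#' Convenience accessor returning the scene's positions in the
#' `(particle_id, frame, x, y)` layout used by [emsd()] and the linker,
#' for validating tracking against truth.
#' @param scene a `ground_truth_scene`.
#' @export
scene_tracks <- function(scene) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  out <- scene$positions[, c("particle_id", "frame", "x", "y")]
  out <- out[order(out$particle_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("track_table", "data.frame")
  out
}

#' Ground-truth positions as a detection table
#'
#' Returns the scene's true positions formatted like [detect_stack()]
#' output (without areas/intensities), so linking and spatial statistics
#' can run directly on noise-free coordinates.
#' @param scene a `ground_truth_scene`.
#' @export
scene_detections <- function(scene) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  pos <- scene$positions
  out <- data.frame(frame = pos$frame, x = pos$x, y = pos$y,
                    area_px2 = 1L, intensity_sum = NA_real_,
                    region = "whole")
  out <- out[order(out$frame, out$y, out$x), ]
  rownames(out) <- NULL
  class(out) <- c("detection_table", "data.frame")
  attr(out, "n_frames") <- scene$n_frames
  out
}
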