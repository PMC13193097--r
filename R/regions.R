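# Cell-region reconstruction: alpha-shape cell boundary from punctum
# centroids, and peripheral-rim / perinuclear-annulus masks by Euclidean
# distance bands.

triangle_circumradius <- function(ax, ay, bx, by, cx, cy) {
  a <- sqrt((bx - cx)^2 + (by - cy)^2)
  b <- sqrt((ax - cx)^2 + (ay - cy)^2)
  cc <- sqrt((ax - bx)^2 + (ay - by)^2)
  area2 <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))  # 2*area
  ifelse(area2 <= .Machine$double.eps * (a + b + cc)^2, Inf,
         a * b * cc / (2 * area2))
}

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Delaunay triangulation as an index matrix (one row per triangle).
# tri.mesh may fall back to internal jittering on degenerate (cocircular)
# inputs; pin the RNG so the triangulation is deterministic either way.
delaunay_triangles <- function(x, y) {
  tm <- with_seed(0L, suppressWarnings(interp::tri.mesh(x, y)))
  tri <- interp::triangles(tm)[, c("node1", "node2", "node3"), drop = FALSE]
  matrix(as.integer(tri), ncol = 3L)
}

#' Concave cell boundary by the alpha-shape algorithm
#'
#' Delaunay-triangulates the punctum centroids and keeps every triangle
#' whose circumradius is below `1/alpha` (the inverse-radius convention;
#' the default `alpha = 0.02` keeps triangles with circumradius < 50 px).
#' The cell outline is the outer boundary of the union of kept triangles —
#' a concave hull that follows the outermost puncta. If no triangle
#' survives, or the kept triangles are disconnected, the convex hull is
#' returned instead with a warning. Points belonging to no kept triangle
#' are reported via the `excluded` element.
#'
#' @param points 2-column matrix (or data frame with `x`, `y`) of centroids,
#'   px; at least 3 non-collinear points.
#' @param alpha shape parameter (inverse circumradius cutoff); `alpha <= 0`
#'   means no cutoff, i.e. the convex hull.
#' @param image_shape optional `c(H, W)` for the rasterized mask; defaults
#'   to the point bounding box (plus 1 px).
#' @return a list: `polygon` (closed vertex matrix, px), `mask` (logical
#'   raster of the kept-triangle union), `excluded` (indices of input
#'   points in no kept triangle), `triangles`, `kept`, `source`
#'   (`"alpha_shape"` or `"convex_hull"`).
#' @examples
#' pts <- cbind(x = c(0, 40, 20), y = c(0, 0, 30))
#' alpha_shape_boundary(pts, alpha = 0.02)$polygon
#' @export
alpha_shape_boundary <- function(points, alpha = 0.02, image_shape = NULL) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- unique(points[stats::complete.cases(points), , drop = FALSE])
  if (nrow(points) < 3L) stop("need at least 3 distinct points", call. = FALSE)
  x <- points[, 1L]; y <- points[, 2L]
  cross <- abs((x[2L] - x[1L]) * (y - y[1L]) - (y[2L] - y[1L]) * (x - x[1L]))
  if (max(cross) < 1e-12) stop("points are collinear", call. = FALSE)
  if (is.null(image_shape))
    image_shape <- c(ceiling(max(y)) + 1L, ceiling(max(x)) + 1L)
  tri <- delaunay_triangles(x, y)
  cutoff <- if (alpha <= 0) Inf else 1 / alpha
  cr <- triangle_circumradius(x[tri[, 1L]], y[tri[, 1L]], x[tri[, 2L]],
                              y[tri[, 2L]], x[tri[, 3L]], y[tri[, 3L]])
  kept <- cr < cutoff
  fallback <- FALSE
  if (!any(kept)) {
    warning("no Delaunay triangle has circumradius < 1/alpha; ",
            "falling back to the convex hull")
    fallback <- TRUE
  } else {
    # connectivity of the kept-triangle union (shared edges), by union-find
    kt <- tri[kept, , drop = FALSE]
    edges <- rbind(kt[, c(1L, 2L)], kt[, c(2L, 3L)], kt[, c(1L, 3L)])
    ekey <- paste(pmin(edges[, 1L], edges[, 2L]),
                  pmax(edges[, 1L], edges[, 2L]))
    etri <- rep(seq_len(nrow(kt)), 3L)
    parent <- seq_len(nrow(kt))
    for (k in split(etri, ekey)) {
      if (length(k) > 1L) {
        r <- uf_find(parent, k[1L])
        for (j in k[-1L]) parent[uf_find(parent, j)] <- r
      }
    }
    roots <- vapply(seq_len(nrow(kt)), function(i) uf_find(parent, i), integer(1L))
    if (length(unique(roots)) > 1L) {
      warning("kept alpha-shape triangles are disconnected; ",
              "falling back to the convex hull")
      fallback <- TRUE
    }
  }
  if (fallback) {
    h <- grDevices::chull(x, y)
    poly <- cbind(x = x[c(h, h[1L])], y = y[c(h, h[1L])])
    mask <- polygon_mask(poly, image_shape)
    out <- list(polygon = poly, mask = mask, excluded = integer(0),
                triangles = tri, kept = kept, source = "convex_hull")
    return(out)
  }
  kt <- tri[kept, , drop = FALSE]
  # boundary = edges used by exactly one kept triangle
  edges <- rbind(kt[, c(1L, 2L)], kt[, c(2L, 3L)], kt[, c(1L, 3L)])
  e1 <- pmin(edges[, 1L], edges[, 2L]); e2 <- pmax(edges[, 1L], edges[, 2L])
  ekey <- paste(e1, e2)
  once <- names(which(table(ekey) == 1L))
  be <- unique(cbind(e1, e2)[ekey %in% once, , drop = FALSE])
  poly <- trace_boundary_loop(be, x, y)
  mask <- matrix(FALSE, image_shape[1L], image_shape[2L])
  for (i in seq_len(nrow(kt))) {
    tp <- cbind(x[kt[i, ]], y[kt[i, ]])
    mask <- mask | polygon_mask(rbind(tp, tp[1L, ]), image_shape)
  }
  excluded <- setdiff(seq_len(nrow(points)), unique(as.vector(kt)))
  if (length(excluded))
    warning(length(excluded), " point(s) lie outside the alpha shape")
  list(polygon = poly, mask = mask, excluded = excluded,
       triangles = tri, kept = kept, source = "alpha_shape")
}

# Order once-used boundary edges into loops and return the largest-area
# loop as a closed polygon.
trace_boundary_loop <- function(be, x, y) {
  adj <- split(c(be[, 2L], be[, 1L]), c(be[, 1L], be[, 2L]))
  used <- rep(FALSE, nrow(be))
  ekey <- paste(be[, 1L], be[, 2L])
  loops <- list()
  for (s in seq_len(nrow(be))) {
    if (used[s]) next
    loop <- c(be[s, 1L], be[s, 2L]); used[s] <- TRUE
    repeat {
      v <- loop[length(loop)]
      nbrs <- adj[[as.character(v)]]
      nxt <- NA_integer_
      for (u in nbrs) {
        k <- which(ekey == paste(min(v, u), max(v, u)))
        if (length(k) && !all(used[k])) { nxt <- u; used[k[!used[k]][1L]] <- TRUE; break }
      }
      if (is.na(nxt) || nxt == loop[1L]) break
      loop <- c(loop, nxt)
    }
    loops[[length(loops) + 1L]] <- loop
  }
  areas <- vapply(loops, function(l) abs(poly_area(cbind(x[l], y[l]))), numeric(1L))
  l <- loops[[which.max(areas)]]
  cbind(x = x[c(l, l[1L])], y = y[c(l, l[1L])])
}

#' Peripheral rim mask
#'
#' The peripheral cytoplasm band: pixels of the cell mask within
#' `thickness_px` (Euclidean) of the mask's exterior — equivalently the
#' cell mask minus its Euclidean erosion by `thickness_px`. The default 60
#' px equals 7.8 um at 0.13 um/px. `method = "dilate"` instead erodes
#' iteratively with a 3x3 structuring element (`thickness_px` iterations,
#' Chebyshev bands), matching plain iterative morphology.
#'
#' @param cell_mask logical raster of the cell.
#' @param thickness_px band thickness, px (> 0).
#' @param method `"edt"` (Euclidean distance transform, default) or
#'   `"dilate"`.
#' @return logical raster, a subset of `cell_mask`.
#' @export
peripheral_rim <- function(cell_mask, thickness_px = 60,
                           method = c("edt", "dilate")) {
  method <- match.arg(method)
  stopifnot_mask(cell_mask, "cell_mask")
  if (thickness_px <= 0) stop("'thickness_px' must be positive", call. = FALSE)
  cell_mask <- cell_mask > 0
  if (method == "edt") {
    cell_mask & dist_to_exterior(cell_mask) <= thickness_px
  } else {
    kern <- matrix(1, 3L, 3L)
    er <- matrix(as.numeric(cell_mask), nrow(cell_mask), ncol(cell_mask))
    for (i in seq_len(thickness_px)) er <- EBImage::erode(er, kern)
    cell_mask & !(er > 0)
  }
}

#' Perinuclear annulus mask
#'
#' The concentric band around the nucleus: the nucleus mask dilated outward
#' by `thickness_px` (Euclidean by default), minus the nucleus itself,
#' optionally clipped to the cell mask. The default 40 px equals 5.2 um at
#' 0.13 um/px.
#'
#' @param nucleus_mask logical raster of the nucleus.
#' @param thickness_px band thickness, px (> 0).
#' @param clip_to optional cell mask to intersect with.
#' @param method `"edt"` or `"dilate"` (iterative 3x3 dilation).
#' @return logical raster, disjoint from `nucleus_mask`.
#' @export
perinuclear_annulus <- function(nucleus_mask, thickness_px = 40,
                                clip_to = NULL, method = c("edt", "dilate")) {
  method <- match.arg(method)
  stopifnot_mask(nucleus_mask, "nucleus_mask")
  if (thickness_px <= 0) stop("'thickness_px' must be positive", call. = FALSE)
  nucleus_mask <- nucleus_mask > 0
  ann <- if (method == "edt") {
    d <- dist_to_mask(nucleus_mask)
    d > 0 & d <= thickness_px
  } else {
    kern <- matrix(1, 3L, 3L)
    di <- matrix(as.numeric(nucleus_mask), nrow(nucleus_mask), ncol(nucleus_mask))
    for (i in seq_len(thickness_px)) di <- EBImage::dilate(di, kern)
    (di > 0) & !nucleus_mask
  }
  if (!is.null(clip_to)) ann <- ann & (clip_to > 0)
  ann
}

#' Build the whole / peripheral / perinuclear mask set
#'
#' @param cell_mask logical raster of the cell (whole-cell region).
#' @param nucleus_mask optional logical raster of the nucleus; without it
#'   the perinuclear mask is absent.
#' @param rim_px peripheral rim thickness, px (default 60 = 7.8 um).
#' @param annulus_px perinuclear annulus thickness, px (default 40 = 5.2 um).
#' @param pixel_size_um calibration carried for unit conversions.
#' @param method band construction, `"edt"` or `"dilate"`.
#' @param clip_annulus clip the perinuclear annulus to the cell mask
#'   (default `TRUE`).
#' @return a `region_mask_set`: `whole`, `peripheral`, `perinuclear`
#'   (logical rasters; `perinuclear` may be `NULL`), `nucleus`, thicknesses
#'   and calibration. A warning is emitted if the peripheral and
#'   perinuclear bands overlap.
#' @export
region_mask_set <- function(cell_mask, nucleus_mask = NULL, rim_px = 60,
                            annulus_px = 40, pixel_size_um = 0.13,
                            method = c("edt", "dilate"), clip_annulus = TRUE) {
  method <- match.arg(method)
  stopifnot_mask(cell_mask, "cell_mask")
  cell_mask <- cell_mask > 0
  peri <- peripheral_rim(cell_mask, rim_px, method)
  ann <- NULL
  if (!is.null(nucleus_mask)) {
    nucleus_mask <- nucleus_mask > 0
    if (!identical(dim(nucleus_mask), dim(cell_mask)))
      stop("mask shapes differ", call. = FALSE)
    ann <- perinuclear_annulus(nucleus_mask, annulus_px,
                               clip_to = if (clip_annulus) cell_mask else NULL,
                               method = method)
    if (any(peri & ann))
      warning("peripheral and perinuclear masks overlap (",
              sum(peri & ann), " px); overlapping detections get both labels")
  }
  structure(list(whole = cell_mask, peripheral = peri, perinuclear = ann,
                 nucleus = nucleus_mask, rim_thickness_px = rim_px,
                 annulus_thickness_px = annulus_px,
                 pixel_size_um = pixel_size_um),
            class = "region_mask_set")
}

#' @export
print.region_mask_set <- function(x, ...) {
  cat("Region masks: whole ", sum(x$whole), " px, peripheral ",
      sum(x$peripheral), " px (", x$rim_thickness_px, " px rim)",
      if (!is.null(x$perinuclear)) paste0(", perinuclear ", sum(x$perinuclear),
                                          " px (", x$annulus_thickness_px,
                                          " px annulus)"),
      "\n", sep = "")
  invisible(x)
}

#' Label detections by region membership
#'
#' Each detection is assigned by the mask membership of its rounded
#' centroid pixel: `"none"` inside the nucleus or outside the cell,
#' `"peripheral"` / `"perinuclear"` inside the respective band, `"whole"`
#' for the remaining cell interior. Logical columns `in_peripheral` /
#' `in_perinuclear` record membership independently, so overlapping bands
#' (geometrically possible in small cells; a warning is emitted at mask
#' construction) keep both labels.
#'
#' @param detections a `detection_table`.
#' @param masks a [region_mask_set()].
#' @return the detection table with `region`, `in_peripheral`,
#'   `in_perinuclear` columns filled.
#' @export
assign_regions <- function(detections, masks) {
  stopifnot(inherits(masks, "region_mask_set"))
  d <- dim(masks$whole)
  px <- round(detections$x) + 1L
  py <- round(detections$y) + 1L
  if (nrow(detections) &&
      (min(px) < 1L || max(px) > d[2L] || min(py) < 1L || max(py) > d[1L]))
    stop("detection coordinates outside the mask raster", call. = FALSE)
  idx <- cbind(py, px)
  in_cell <- masks$whole[idx]
  in_nuc <- if (!is.null(masks$nucleus)) masks$nucleus[idx] else rep(FALSE, nrow(detections))
  in_per <- masks$peripheral[idx]
  in_ann <- if (!is.null(masks$perinuclear)) masks$perinuclear[idx] else rep(FALSE, nrow(detections))
  region <- rep("none", nrow(detections))
  region[in_cell] <- "whole"
  region[in_ann] <- "perinuclear"
  region[in_per] <- "peripheral"
  region[in_nuc] <- "none"
  detections$region <- region
  detections$in_peripheral <- in_per & !in_nuc
  detections$in_perinuclear <- in_ann & !in_nuc
  detections
}

#' Read / write polygons as CSV vertex lists
#'
#' @param path CSV with columns `x`, `y` (px, 0-based).
#' @return `read_polygon()` returns a 2-column matrix;
#'   `write_polygon()` returns `path` invisibly.
#' @export
read_polygon <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[, c("x", "y")])
}

#' @rdname read_polygon
#' @param poly 2-column vertex matrix.
#' @export
write_polygon <- function(poly, path) {
  utils::write.csv(data.frame(x = poly[, 1L], y = poly[, 2L]), path,
                   row.names = FALSE)
  invisible(path)
}

#' Rasterize a polygon to a logical mask
#'
#' Pixel centers at integer 0-based (x, y); even-odd fill.
#' @param poly closed or open 2-column vertex matrix.
#' @param shape `c(H, W)` of the raster.
#' @export
rasterize_polygon <- function(poly, shape) polygon_mask(poly, shape)
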