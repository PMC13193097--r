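# Internal geometry, RNG and raster helpers shared across modules.
#
# Coordinate convention (package-wide): 0-based pixel coordinates, origin at
# the top-left corner, x = column index, y = row index. Continuous positions
# are allowed; pixel (x, y) of a mask or image matrix `m` is m[y + 1, x + 1].

#' Evaluate an expression with a local RNG seed
#'
#' Runs `expr` under `set.seed(seed)` while preserving (and afterwards
#' restoring) the caller's global RNG state, so every simulation is fully
#' determined by its own `seed` argument and never perturbs user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## ---- windows -------------------------------------------------------------
## A simulation window is either a rectangle `c(width, height)` spanning
## [0, width] x [0, height], a closed polygon (2-column matrix of x, y), or a
## cell_geometry (its cell polygon is used).

as_window <- function(window) {
  if (inherits(window, "cell_geometry"))
    return(list(type = "polygon", poly = window$cell_polygon,
                bbox = poly_bbox(window$cell_polygon)))
  if (is.matrix(window) && ncol(window) == 2L) {
    if (nrow(window) < 3L) stop("polygon window needs >= 3 vertices", call. = FALSE)
    return(list(type = "polygon", poly = window, bbox = poly_bbox(window)))
  }
  if (is.numeric(window) && length(window) == 2L) {
    if (any(window <= 0)) stop("window dimensions must be positive", call. = FALSE)
    return(list(type = "rect", width = window[1L], height = window[2L],
                bbox = c(0, window[1L], 0, window[2L])))
  }
  stop("'window' must be c(width, height), a 2-column polygon matrix, ",
       "or a cell_geometry", call. = FALSE)
}

poly_bbox <- function(poly) c(min(poly[, 1L]), max(poly[, 1L]),
                              min(poly[, 2L]), max(poly[, 2L]))

#' Signed polygon area by the shoelace formula
#' @noRd
poly_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x)
  if (x[1L] == x[n] && y[1L] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

window_area <- function(w) {
  if (w$type == "rect") w$width * w$height else abs(poly_area(w$poly))
}

#' Even-odd point-in-polygon test, vectorized over query points
#' @noRd
points_in_polygon <- function(x, y, poly) {
  px <- poly[, 1L]; py <- poly[, 2L]
  n <- length(px)
  if (px[1L] == px[n] && py[1L] == py[n]) { px <- px[-n]; py <- py[-n]; n <- n - 1L }
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

in_window <- function(x, y, w) {
  if (w$type == "rect") x >= 0 & x <= w$width & y >= 0 & y <= w$height
  else points_in_polygon(x, y, w$poly)
}

#' Uniform sampling inside a window (rejection from the bounding box)
#' @noRd
sample_in_window <- function(n, w, max_tries = 1000L) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  bb <- w$bbox
  out <- matrix(NA_real_, n, 2L)
  need <- seq_len(n)
  for (k in seq_len(max_tries)) {
    m <- length(need)
    x <- runif(m, bb[1L], bb[2L]); y <- runif(m, bb[3L], bb[4L])
    ok <- in_window(x, y, w)
    out[need[ok], 1L] <- x[ok]; out[need[ok], 2L] <- y[ok]
    need <- need[!ok]
    if (!length(need)) break
  }
  if (length(need)) stop("failed to sample points inside the window", call. = FALSE)
  colnames(out) <- c("x", "y")
  out
}

#' Reflect coordinates into [0, upper] by repeated folding
#' @noRd
reflect_into <- function(v, upper) {
  period <- 2 * upper
  v <- v %% period
  ifelse(v > upper, period - v, v)
}

## ---- raster helpers ------------------------------------------------------

#' Rasterize a closed polygon to a logical mask by scanline fill
#'
#' Pixel centers at integer (x, y); a pixel is set when its center lies
#' inside the polygon under the even-odd rule.
#' @noRd
polygon_mask <- function(poly, shape) {
  H <- shape[1L]; W <- shape[2L]
  mask <- matrix(FALSE, H, W)
  px <- poly[, 1L]; py <- poly[, 2L]
  n <- length(px)
  if (px[1L] == px[n] && py[1L] == py[n]) { px <- px[-n]; py <- py[-n]; n <- n - 1L }
  y0 <- max(0L, floor(min(py))); y1 <- min(H - 1L, ceiling(max(py)))
  jdx <- c(n, seq_len(n - 1L))
  for (yy in y0:y1) {
    crosses <- which((py > yy) != (py[jdx] > yy))
    if (!length(crosses)) next
    xs <- px[crosses] + (yy - py[crosses]) *
      (px[jdx][crosses] - px[crosses]) / (py[jdx][crosses] - py[crosses])
    xs <- sort(xs)
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      a <- ceiling(xs[k] - 1e-9); b <- floor(xs[k + 1L] + 1e-9)
      a <- max(a, 0L); b <- min(b, W - 1L)
      if (a <= b) mask[yy + 1L, (a:b) + 1L] <- TRUE
    }
  }
  mask
}

#' Scale a polygon about its centroid
#' @noRd
scale_polygon <- function(poly, factor) {
  cx <- mean(poly[, 1L]); cy <- mean(poly[, 2L])
  cbind(x = cx + (poly[, 1L] - cx) * factor,
        y = cy + (poly[, 2L] - cy) * factor)
}

#' Euclidean distance (in px) of every pixel to the nearest pixel outside
#' `mask` (0 on pixels outside the mask). Thin wrapper over EBImage's
#' distance transform, kept in one place so the band operations share it.
#' @noRd
dist_to_exterior <- function(mask) {
  EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
}

#' Distance of every pixel to the nearest pixel of `mask` (0 inside mask)
#' @noRd
dist_to_mask <- function(mask) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  dist_to_exterior(!mask)
}

stopifnot_mask <- function(m, arg) {
  if (!is.matrix(m) || !(is.logical(m) || all(m %in% c(0, 1))))
    stop("'", arg, "' must be a logical (binary) matrix", call. = FALSE)
  if (!any(m)) stop("'", arg, "' is empty", call. = FALSE)
  invisible(NULL)
}
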