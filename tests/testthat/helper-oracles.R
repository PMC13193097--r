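# Independent brute-force oracles used to pin the implementations.
# Each is written as the most literal computation possible and shares no
# code with the package internals it checks.

# Explicit stack-based flood fill with 8-connectivity.
floodfill_labels <- function(bw) {
  H <- nrow(bw); W <- ncol(bw)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  # raster scan (row, then col) so labels appear in raster order
  for (rr in seq_len(H)) for (cc in seq_len(W)) {
    if (!bw[rr, cc] || lab[rr, cc] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(rr, cc))
    lab[rr, cc] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1L] + dr; c2 <- p[2L] + dc
        if (r2 >= 1L && r2 <= H && c2 >= 1L && c2 <= W &&
            bw[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# O(n^2) double-loop Ripley's K estimator (ordered pairs).
ripley_k_bruteforce <- function(points, radii, A) {
  n <- nrow(points)
  k <- numeric(length(radii))
  for (ri in seq_along(radii)) {
    cnt <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((points[i, 1] - points[j, 1])^2 +
                (points[i, 2] - points[j, 2])^2)
      if (d <= radii[ri]) cnt <- cnt + 1L
    }
    k[ri] <- A * cnt / (n * (n - 1))
  }
  k
}

# Triple-loop pooled-pair EMSD (track x start time x lag).
emsd_bruteforce <- function(tracks, max_lag) {
  out <- numeric(max_lag)
  npairs <- integer(max_lag)
  for (tau in seq_len(max_lag)) {
    s <- 0; m <- 0L
    for (id in unique(tracks$particle_id)) {
      tr <- tracks[tracks$particle_id == id, ]
      for (i in seq_len(nrow(tr))) {
        j <- which(tr$frame == tr$frame[i] + tau)
        if (length(j) == 1L) {
          s <- s + (tr$x[j] - tr$x[i])^2 + (tr$y[j] - tr$y[i])^2
          m <- m + 1L
        }
      }
    }
    out[tau] <- if (m) s / m else NA_real_
    npairs[tau] <- m
  }
  list(emsd = out, n_pairs = npairs)
}

# Per-pixel Euclidean distance band masks.
rim_bruteforce <- function(mask, thickness) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(FALSE, H, W)
  for (rr in seq_len(H)) for (cc in seq_len(W)) {
    if (!mask[rr, cc]) next
    d <- sqrt(min((bg[, 1] - rr)^2 + (bg[, 2] - cc)^2))
    out[rr, cc] <- d <= thickness
  }
  out
}

annulus_bruteforce <- function(nucleus, thickness) {
  H <- nrow(nucleus); W <- ncol(nucleus)
  fg <- which(nucleus, arr.ind = TRUE)
  out <- matrix(FALSE, H, W)
  for (rr in seq_len(H)) for (cc in seq_len(W)) {
    if (nucleus[rr, cc]) next
    d <- sqrt(min((fg[, 1] - rr)^2 + (fg[, 2] - cc)^2))
    out[rr, cc] <- d <= thickness
  }
  out
}

# Per-pixel perinuclear index on mask geometry.
perinuclear_index_bruteforce <- function(image, cell, nucleus, px_um,
                                         zone = 5, cutoff = 10) {
  fg <- which(nucleus, arr.ind = TRUE)
  iz <- io <- 0
  itot <- sum(image[cell])
  H <- nrow(image); W <- ncol(image)
  for (rr in seq_len(H)) for (cc in seq_len(W)) {
    if (!cell[rr, cc] || nucleus[rr, cc]) next
    d <- sqrt(min((fg[, 1] - rr)^2 + (fg[, 2] - cc)^2)) * px_um
    if (d > 0 && d <= zone) iz <- iz + image[rr, cc]
    if (d > cutoff) io <- io + image[rr, cc]
  }
  (iz / itot - io / itot) * 100
}

# Shoelace polygon area (independent of the package's internal version).
poly_area_for_test <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Per-pixel distance to the nearest TRUE pixel of `mask` (0 inside it).
dist_band_for_test <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (rr in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (mask[rr, cc]) next
    out[rr, cc] <- sqrt(min((fg[, 1] - rr)^2 + (fg[, 2] - cc)^2))
  }
  out
}

# Single-particle scene at (x, y) in a (side x side) image, built by
# overriding an empty generated scene's positions.
new_scene_for_test <- function(x, y, side) {
  sc <- simulate_point_pattern("csr", n = 0, window = c(side - 1, side - 1),
                               seed = 1)
  sc$positions <- data.frame(frame = 0L, particle_id = 1L, x = x, y = y)
  sc
}

# Disk mask with 0-based center (cx, cy) in a H x W raster.
disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(0:(W - 1L), each = H), H, W)
  ys <- matrix(rep(0:(H - 1L), times = W), H, W)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}
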