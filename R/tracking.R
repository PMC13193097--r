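# Trajectory linking: frame-to-frame optimal assignment with a gap memory
# (Crocker-Grier style), plus the minimum-length stub filter.

#' Linking parameters
#'
#' @param search_range_px maximum displacement per linking step, px
#'   (default 9).
#' @param memory_frames maximum number of consecutive frames a particle may
#'   be missing and still be reconnected (default 5).
#' @param min_length minimum number of detections for a track to be
#'   retained by [filter_tracks()] (default 20, inclusive).
#' @return a `link_params` list.
#' @export
link_params <- function(search_range_px = 9, memory_frames = 5L,
                        min_length = 20L) {
  if (search_range_px < 0 || memory_frames < 0)
    stop("linking parameters must be non-negative", call. = FALSE)
  if (min_length < 2L) stop("'min_length' must be at least 2", call. = FALSE)
  structure(list(search_range_px = search_range_px,
                 memory_frames = as.integer(memory_frames),
                 min_length = as.integer(min_length)),
            class = "link_params")
}

#' Link detections into trajectories
#'
#' Builds trajectories by globally optimal frame-to-frame assignment:
#' candidate links are detection/track pairs within `search_range_px` of
#' the track's last known position; each frame's candidates are decomposed
#' into independent subnetworks (connected components of the bipartite
#' candidate graph) and each subnetwork is solved as a linear assignment
#' problem minimizing total squared displacement, with a fixed cost of
#' `search_range_px^2` for leaving a track or detection unmatched. Tracks
#' that go unmatched persist as "lost" for up to `memory_frames` frames and
#' remain linkable against their last known position (gap closing, same
#' distance cutoff); unmatched detections start new tracks, numbered in
#' raster order. Subnetworks larger than 64 nodes fall back to greedy
#' nearest-pair linking with a warning.
#'
#' @param detections a `detection_table` (columns `frame`, `x`, `y`).
#' @param params a [link_params()] list.
#' @return a `track_table` data frame (`particle_id`, `frame`, `x`, `y`)
#'   ordered by particle then frame.
#' @examples
#' d <- data.frame(frame = rep(0:4, each = 2),
#'                 x = rep(c(0, 50), 5) + rep(0:4, each = 2),
#'                 y = rep(c(0, 0), 5))
#' link_trajectories(d, link_params(min_length = 2))
#' @export
link_trajectories <- function(detections, params = link_params()) {
  stopifnot(inherits(params, "link_params"))
  out_empty <- structure(data.frame(particle_id = integer(0), frame = integer(0),
                                    x = numeric(0), y = numeric(0)),
                         class = c("track_table", "data.frame"))
  if (!nrow(detections)) return(out_empty)
  ord <- order(detections$frame, detections$y, detections$x)
  det <- detections[ord, c("frame", "x", "y")]
  sr <- params$search_range_px
  sr2 <- sr^2
  mem <- params$memory_frames
  n <- nrow(det)
  assigned <- integer(n)
  # track state
  tr_x <- tr_y <- numeric(0)
  tr_last <- integer(0)
  next_id <- 1L
  rows_by_frame <- split(seq_len(n), det$frame)
  frame_vals <- as.integer(names(rows_by_frame))
  for (fi in seq_along(frame_vals)) {
    f <- frame_vals[fi]
    cur <- rows_by_frame[[fi]]
    nd <- length(cur)
    alive <- which(tr_last < f & (f - tr_last) <= mem + 1L)
    nt <- length(alive)
    linked_det <- rep(FALSE, nd)
    if (nt && nd) {
      dx <- outer(tr_x[alive], det$x[cur], "-")
      dy <- outer(tr_y[alive], det$y[cur], "-")
      d2 <- dx * dx + dy * dy
      allowed <- d2 <= sr2
      pr <- which(allowed, arr.ind = TRUE)
      if (nrow(pr)) {
        # connected components of the bipartite candidate graph
        parent <- seq_len(nt + nd)
        for (k in seq_len(nrow(pr))) {
          a <- uf_find(parent, pr[k, 1L])
          b <- uf_find(parent, nt + pr[k, 2L])
          if (a != b) parent[b] <- a
        }
        roots <- vapply(seq_len(nt + nd), function(i) uf_find(parent, i),
                        integer(1L))
        involved <- unique(c(pr[, 1L], nt + pr[, 2L]))
        for (rt in unique(roots[involved])) {
          nodes <- which(roots == rt)
          tt <- nodes[nodes <= nt]
          dd <- nodes[nodes > nt] - nt
          t_ <- length(tt); d_ <- length(dd)
          if (t_ + d_ > 64L) {
            warning("linking subnetwork of ", t_ + d_,
                    " nodes: using greedy fallback")
            sub <- d2[tt, dd, drop = FALSE]
            sub[sub > sr2] <- Inf
            while (any(is.finite(sub))) {
              ij <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
              ti <- tt[ij[1L]]; di <- dd[ij[2L]]
              tr_x[alive[ti]] <- det$x[cur[di]]
              tr_y[alive[ti]] <- det$y[cur[di]]
              tr_last[alive[ti]] <- f
              assigned[cur[di]] <- alive[ti]
              linked_det[di] <- TRUE
              sub[ij[1L], ] <- Inf; sub[, ij[2L]] <- Inf
            }
            next
          }
          big <- sr2 * (t_ + d_ + 1L) + 1
          C <- d2[tt, dd, drop = FALSE]
          C[C > sr2] <- big
          Dt <- matrix(big, t_, t_); diag(Dt) <- sr2
          Dd <- matrix(big, d_, d_); diag(Dd) <- sr2
          M <- rbind(cbind(C, Dt), cbind(Dd, matrix(0, d_, t_)))
          sol <- as.integer(clue::solve_LSAP(M))
          for (i in seq_len(t_)) {
            j <- sol[i]
            if (j <= d_ && d2[tt[i], dd[j]] <= sr2) {
              ti <- alive[tt[i]]; di <- dd[j]
              tr_x[ti] <- det$x[cur[di]]
              tr_y[ti] <- det$y[cur[di]]
              tr_last[ti] <- f
              assigned[cur[di]] <- ti
              linked_det[di] <- TRUE
            }
          }
        }
      }
    }
    # unmatched detections start new tracks, in raster order
    for (di in which(!linked_det)) {
      tr_x <- c(tr_x, det$x[cur[di]])
      tr_y <- c(tr_y, det$y[cur[di]])
      tr_last <- c(tr_last, f)
      assigned[cur[di]] <- next_id
      next_id <- next_id + 1L
    }
  }
  out <- data.frame(particle_id = assigned, frame = det$frame,
                    x = det$x, y = det$y)
  out <- out[order(out$particle_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("track_table", "data.frame")
  out
}

#' Drop tracks shorter than a minimum number of detections
#'
#' Length counts detections (not frames spanned); the boundary is
#' inclusive, so a 20-detection track survives `min_length = 20`.
#'
#' @param tracks a `track_table`.
#' @param min_length minimum detections per retained track (default 20).
#' @return the filtered `track_table`.
#' @export
filter_tracks <- function(tracks, min_length = 20L) {
  if (!nrow(tracks)) return(tracks)
  len <- table(tracks$particle_id)
  keep <- names(len)[len >= min_length]
  out <- tracks[tracks$particle_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_table", "data.frame")
  out
}

#' Write / read a track table as CSV
#'
#' @param tracks a `track_table`.
#' @param path CSV file path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks)[, c("particle_id", "frame", "x", "y")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("track_table", "data.frame")
  out
}
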