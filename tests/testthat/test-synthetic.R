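# Synthetic-data generator: determinism, closed-form moments, and the
# statistical structure each regime promises.

test_that("identical parameters and seed give bit-identical scenes and stacks", {
  a <- simulate_point_pattern("clustered", n = 40, window = c(120, 120),
                              n_frames = 3, seed = 11)
  b <- simulate_point_pattern("clustered", n = 40, window = c(120, 120),
                              n_frames = 3, seed = 11)
  expect_identical(a$positions, b$positions)
  expect_false(identical(
    a$positions,
    simulate_point_pattern("clustered", n = 40, window = c(120, 120),
                           n_frames = 3, seed = 12)$positions))
  sa <- render_stack(a, render_params(noise_sd = 3))
  sb <- render_stack(b, render_params(noise_sd = 3))
  expect_identical(sa$frames, sb$frames)

  ta <- simulate_trajectories("brownian", 20, 30, c(100, 100), D = 0.3, seed = 5)
  tb <- simulate_trajectories("brownian", 20, 30, c(100, 100), D = 0.3, seed = 5)
  expect_identical(ta$positions, tb$positions)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_point_pattern("csr", n = 10, window = c(50, 50), seed = 3))
  expect_identical(runif(1), before)
})

test_that("CSR pattern matches Poisson nearest-neighbor theory and stays in-window", {
  # E[NN distance] = 1/(2*sqrt(lambda)) for a Poisson process
  n <- 500; side <- 250; reps <- 60
  lambda <- n / side^2
  nn <- numeric(reps)
  for (i in seq_len(reps)) {
    sc <- simulate_point_pattern("csr", n = n, window = c(side, side), seed = i)
    p <- sc$positions
    expect_true(all(p$x >= 0 & p$x <= side & p$y >= 0 & p$y <= side))
    dm <- as.matrix(dist(cbind(p$x, p$y)))
    diag(dm) <- Inf
    nn[i] <- mean(apply(dm, 1, min))
  }
  expect_equal(mean(nn), 1 / (2 * sqrt(lambda)), tolerance = 0.05)
})

test_that("Poisson-count mode has per-frame counts with mean ~ lambda*A", {
  sc <- simulate_point_pattern("csr", n = 40, window = c(100, 100),
                               n_frames = 200, poisson_counts = TRUE, seed = 8)
  counts <- tabulate(sc$positions$frame + 1L, nbins = 200)
  se <- sqrt(40 / 200)
  expect_lt(abs(mean(counts) - 40), 3 * se)
})

test_that("empty and hard-core patterns honor their construction", {
  e <- simulate_point_pattern("csr", n = 0, window = c(50, 50),
                              n_frames = 2, seed = 1)
  expect_identical(nrow(e$positions), 0L)
  h <- 8
  sc <- simulate_point_pattern("dispersed", n = 40, window = c(200, 200),
                               hardcore_radius = h, n_frames = 5, seed = 2)
  for (f in 0:4) {
    p <- sc$positions[sc$positions$frame == f, ]
    expect_gte(min(dist(cbind(p$x, p$y))), h)
  }
  expect_error(
    simulate_point_pattern("dispersed", n = 200, window = c(20, 20),
                           hardcore_radius = 10, seed = 3),
    "infeasible")
})

test_that("Brownian increments have mean zero and variance 2*D*tau", {
  D <- 0.25
  sc <- simulate_trajectories("brownian", 1000, 100, c(4000, 4000),
                              D = D, seed = 7)
  p <- sc$positions
  x <- matrix(p$x, nrow = 100)
  y <- matrix(p$y, nrow = 100)
  dx1 <- diff(x, lag = 1)
  expect_equal(var(as.vector(dx1)), 2 * D, tolerance = 0.05)
  for (tau in c(5, 25)) {   # up to n_frames/4
    idx <- seq(1, 100, by = tau)            # non-overlapping, independent
    dxt <- as.vector(diff(x[idx, ]))
    dyt <- as.vector(diff(y[idx, ]))
    se <- sqrt(2 * D * tau) / sqrt(length(dxt))
    expect_lt(abs(mean(dxt)), 3 * se)
    expect_lt(abs(mean(dyt)), 3 * se)
    expect_equal(var(dxt), 2 * D * tau, tolerance = 0.1)
  }
})

test_that("degenerate and deterministic motions are exact", {
  st <- simulate_trajectories("brownian", 5, 20, c(50, 50), D = 0, seed = 1)
  p <- st$positions
  expect_true(all(tapply(p$x, p$particle_id, function(v) max(v) - min(v)) == 0))
  dirs <- simulate_trajectories("directed", 3, 11, c(100, 100), D = 0,
                                velocity = c(1, 0), seed = 2)
  p <- dirs$positions
  for (id in 1:3) {
    tr <- p[p$particle_id == id, ]
    expect_equal(diff(tr$x), rep(1, 10), tolerance = 1e-12)
    expect_equal(diff(tr$y), rep(0, 10), tolerance = 1e-12)
  }
})

test_that("confined motion plateaus below the corral bound", {
  R <- 6
  sc <- simulate_trajectories("confined", 200, 120, c(400, 400),
                              D = 0.5, corral_radius = R, seed = 9)
  cv <- emsd(scene_tracks(sc))
  expect_true(all(cv$emsd_px2 <= 4 * R^2))
  # long-lag EMSD approaches the uniform-disk limit 2R^2, clearly below 4DT
  expect_lt(cv$emsd_px2[nrow(cv)], 2.5 * R^2)
})

test_that("cell geometry hits requested areas and is reproducible", {
  px <- 0.13
  g <- make_cell_geometry(900, 0.2, px, "disk", seed = 1)
  expect_equal(sum(g$cell_mask) * px^2, 900, tolerance = 0.02)
  r_px <- sqrt(900 / pi) / px
  d <- dim(g$cell_mask)
  expect_equal(max(rowSums(g$cell_mask)) / 2, r_px, tolerance = 0.02)
  expect_equal(sum(g$nucleus_mask) / sum(g$cell_mask), 0.2, tolerance = 0.02)
  expect_true(all(g$cell_mask[g$nucleus_mask]))   # nucleus inside cell

  b1 <- make_cell_geometry(1400, 0.15, px, "blob", seed = 42)
  b2 <- make_cell_geometry(1400, 0.15, px, "blob", seed = 42)
  expect_identical(b1$cell_polygon, b2$cell_polygon)
  expect_equal(sum(b1$cell_mask) * px^2, 1400, tolerance = 0.02)
  gg <- make_cell_geometry(900, 0.01, px, "disk", seed = 1)
  expect_equal(sum(gg$nucleus_mask) / sum(gg$cell_mask), 0.01, tolerance = 0.15)
  expect_error(make_cell_geometry(900, 1.2), "nucleus_fraction")
})

test_that("rendered stacks reproduce background and spot positions", {
  sc0 <- simulate_point_pattern("csr", n = 0, window = c(40, 40), seed = 1)
  st0 <- render_stack(sc0, render_params(noise_sd = 0, background_level = 20))
  expect_true(all(st0$frames[[1]] == 20L))

  one <- new_scene_for_test(50, 50, 101)
  st1 <- render_stack(one, render_params(noise_sd = 0))
  am <- which(st1$frames[[1]] == max(st1$frames[[1]]), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(51, 51))  # row y+1, col x+1
})

test_that("scene files round-trip through disk", {
  sc <- simulate_point_pattern("csr", n = 15, window = c(60, 60),
                               n_frames = 2, seed = 3)
  d <- withr::local_tempdir()
  write_scene(sc, d)
  tr <- read.csv(file.path(d, "truth.csv"))
  expect_equal(nrow(tr), nrow(sc$positions))
  meta <- jsonlite::read_json(file.path(d, "scene.json"))
  expect_identical(meta$regime, "csr")
  expect_identical(meta$seed, 3L)

  st <- render_stack(sc, render_params(noise_sd = 2))
  f <- withr::local_tempfile(fileext = ".tif")
  write_frame_stack(st, f)
  back <- read_frame_stack(f, sc$pixel_size_um, sc$frame_interval_s)
  expect_identical(back$frames, st$frames)
})
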