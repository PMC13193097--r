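# EMSD and the power-law diffusion fit.

test_that("EMSD closed forms: stationary zero and ballistic tau^2", {
  still <- data.frame(particle_id = 1, frame = 0:19, x = 3, y = 7)
  expect_true(all(emsd(still)$emsd_px2 == 0))
  ball <- data.frame(particle_id = 1, frame = 0:19, x = 0:19, y = 0)
  cv <- emsd(ball)
  expect_equal(cv$emsd_px2, cv$lag_frames^2)
  # translation invariance
  shifted <- transform(ball, x = x + 123.4, y = y - 77)
  expect_equal(emsd(shifted)$emsd_px2, cv$emsd_px2)
})

test_that("pooled-pair EMSD equals the brute-force triple loop, gaps included", {
  set.seed(5)
  tracks <- do.call(rbind, lapply(1:4, function(id) {
    frames <- sort(sample(0:14, 10))   # ragged, gappy tracks
    data.frame(particle_id = id, frame = frames,
               x = cumsum(rnorm(10)), y = cumsum(rnorm(10)))
  }))
  cv <- emsd(tracks, max_lag = 10)
  oracle <- emsd_bruteforce(tracks, 10)
  keep <- oracle$n_pairs > 0
  expect_equal(cv$emsd_px2, oracle$emsd[keep], tolerance = 1e-12)
  expect_identical(cv$n_pairs, as.numeric(oracle$n_pairs[keep]))
  expect_identical(cv$lag_frames, which(keep))
})

test_that("Brownian EMSD matches 4*D*tau within Monte-Carlo error", {
  D <- 0.25
  sc <- simulate_trajectories("brownian", 500, 60, c(2000, 2000), D = D,
                              seed = 17)
  cv <- emsd(scene_tracks(sc), max_lag = 20)
  for (tau in c(1, 5, 10, 20)) {
    v <- cv$emsd_px2[cv$lag_frames == tau]
    n <- cv$n_pairs[cv$lag_frames == tau]
    # SE of a mean of chi^2-like squared displacements ~ EMSD * sqrt(2/n)
    se <- 4 * D * tau * sqrt(2 / n) * 2   # pairs overlap; inflate
    expect_lt(abs(v - 4 * D * tau), 3 * se)
  }
})

test_that("log-log regression recovers exact power laws exactly", {
  lag <- 1:10
  mk <- function(v) structure(
    data.frame(lag_frames = lag, lag_s = lag, emsd_px2 = v, emsd_um2 = v,
               n_pairs = 100), class = c("emsd_curve", "data.frame"))
  f1 <- fit_power_law(mk(2 * lag))
  expect_equal(f1$alpha, 1, tolerance = 1e-10)
  expect_equal(f1$d_apparent, 0.5, tolerance = 1e-10)
  expect_identical(f1$regime, "brownian")
  f2 <- fit_power_law(mk(2 * lag^1.5))
  expect_equal(f2$alpha, 1.5, tolerance = 1e-10)
  expect_equal(f2$d_apparent, 0.5, tolerance = 1e-10)
  expect_identical(f2$regime, "superdiffusive")
  f3 <- fit_power_law(mk(0.8 * lag^0.6))
  expect_identical(f3$regime, "subdiffusive")
  expect_error(fit_power_law(mk(c(0, 2:10))), "lag")
  expect_equal(unname(coef(f1)), c(1, 0.5), tolerance = 1e-10)
  expect_equal(predict(f2, lags = 4), 4 * 0.5 * 8, tolerance = 1e-9)
})

test_that("fitted alpha and D are calibrated on simulated Brownian scenes", {
  alphas <- ds <- numeric(10)
  for (i in seq_len(10)) {
    sc <- simulate_trajectories("brownian", 150, 60, c(1200, 1200),
                                D = 0.25, seed = 100 + i)
    fit <- fit_power_law(emsd(scene_tracks(sc), max_lag = 40))
    alphas[i] <- fit$alpha
    ds[i] <- fit$d_apparent
  }
  expect_gt(mean(alphas), 0.95)
  expect_lt(mean(alphas), 1.05)
  expect_equal(mean(ds), 0.25, tolerance = 0.1)
})

test_that("fitted exponents order confined < brownian < directed", {
  reps <- 6
  a <- matrix(NA_real_, reps, 3,
              dimnames = list(NULL, c("confined", "brownian", "directed")))
  for (i in seq_len(reps)) {
    s1 <- simulate_trajectories("confined", 150, 100, c(600, 600), D = 0.5,
                                corral_radius = 5, seed = 200 + i)
    s2 <- simulate_trajectories("brownian", 150, 100, c(600, 600), D = 0.5,
                                seed = 300 + i)
    s3 <- simulate_trajectories("directed", 150, 100, c(2000, 2000), D = 0.05,
                                velocity = 0.5, seed = 400 + i)
    a[i, 1] <- fit_power_law(emsd(scene_tracks(s1), max_lag = 40))$alpha
    a[i, 2] <- fit_power_law(emsd(scene_tracks(s2), max_lag = 40))$alpha
    a[i, 3] <- fit_power_law(emsd(scene_tracks(s3), max_lag = 40))$alpha
  }
  gap1 <- mean(a[, 2]) - mean(a[, 1])
  gap2 <- mean(a[, 3]) - mean(a[, 2])
  expect_gt(gap1, 3 * sd(a[, 2] - a[, 1]) / sqrt(reps))
  expect_gt(gap2, 3 * sd(a[, 3] - a[, 2]) / sqrt(reps))
})

test_that("regional diffusion separates regimes placed in different regions", {
  cell <- disk_mask(301, 301, 150, 150, 140)
  nuc <- disk_mask(301, 301, 150, 150, 40)
  masks <- region_mask_set(cell, nuc, rim_px = 40, annulus_px = 30)
  # confined particles near the nucleus, directed particles in the periphery
  conf <- simulate_trajectories("confined", 60, 60, c(40, 40), D = 0.5,
                                corral_radius = 4, seed = 31)
  pc <- conf$positions
  rad <- 40 + 12; cx <- 150
  th0 <- 2 * pi * (as.numeric(factor(pc$particle_id)) - 1) / 60
  pc$x <- cx + (rad) * cos(th0) + (pc$x - 20) / 4
  pc$y <- cx + (rad) * sin(th0) + (pc$y - 20) / 4
  dirs <- simulate_trajectories("directed", 60, 60, c(3000, 3000), D = 0.02,
                                velocity = 0.8, seed = 32)
  pd <- dirs$positions
  th1 <- 2 * pi * (as.numeric(factor(pd$particle_id)) - 1) / 60
  prad <- 120
  pd$x <- cx + prad * cos(th1) + (pd$x - ave(pd$x, pd$particle_id,
                                             FUN = function(v) v[1])) / 12
  pd$y <- cx + prad * sin(th1) + (pd$y - ave(pd$y, pd$particle_id,
                                             FUN = function(v) v[1])) / 12
  pd$particle_id <- pd$particle_id + 100
  det <- rbind(
    data.frame(frame = pc$frame, x = pc$x, y = pc$y, area_px2 = 1L,
               intensity_sum = 1, region = "none"),
    data.frame(frame = pd$frame, x = pd$x, y = pd$y, area_px2 = 1L,
               intensity_sum = 1, region = "none"))
  det <- assign_regions(det, masks)
  res <- regional_diffusion(det, masks, link_params(), max_lag = 30)
  expect_false(is.null(res$perinuclear))
  expect_false(is.null(res$peripheral))
  expect_false(is.null(res$whole))
  expect_gt(res$peripheral$fit$alpha, 1)
  expect_lt(res$perinuclear$fit$alpha, 1)
  expect_gt(res$peripheral$fit$alpha, res$perinuclear$fit$alpha)
})

test_that("regions without surviving tracks are reported absent", {
  cell <- disk_mask(101, 101, 50, 50, 45)
  nuc <- disk_mask(101, 101, 50, 50, 10)
  masks <- region_mask_set(cell, nuc, rim_px = 10, annulus_px = 8)
  # short tracks only: nothing survives min_length = 20
  det <- data.frame(frame = rep(0:9, 2),
                    x = c(rep(50, 10), rep(88, 10)),
                    y = 50, area_px2 = 1L, intensity_sum = 1, region = "none")
  det <- assign_regions(det, masks)
  expect_message(res <- regional_diffusion(det, masks, link_params()),
                 "minimum-length")
  expect_true(all(vapply(res, is.null, logical(1))))
})
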