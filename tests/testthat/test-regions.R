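# Region geometry: alpha-shape boundary, distance-band masks, and region
# assignment.

test_that("alpha shape of a small triangle is the triangle itself", {
  pts <- cbind(x = c(10, 50, 30), y = c(10, 10, 40))  # circumradius ~ 21 < 50
  res <- alpha_shape_boundary(pts, alpha = 0.02)
  expect_identical(res$source, "alpha_shape")
  verts <- unique(res$polygon[-nrow(res$polygon), , drop = FALSE])
  expect_identical(nrow(verts), 3L)
  expect_true(all(apply(pts, 1, function(p)
    any(abs(verts[, 1] - p[1]) < 1e-9 & abs(verts[, 2] - p[2]) < 1e-9))))
  expect_identical(length(res$excluded), 0L)
})

test_that("alpha -> 0 recovers the convex hull; keeping is monotone in alpha", {
  set.seed(2)
  pc <- cbind(runif(150, 0, 120), runif(150, 0, 120))
  a0 <- alpha_shape_boundary(pc, alpha = 0)
  h <- chull(pc)
  expect_equal(abs(poly_area_for_test(a0$polygon)),
               abs(poly_area_for_test(pc[c(h, h[1]), ])), tolerance = 1e-9)
  # lowering alpha (raising the cutoff) never drops triangles
  k1 <- alpha_shape_boundary(pc, alpha = 0.05)$kept
  k2 <- alpha_shape_boundary(pc, alpha = 0.02)$kept
  k3 <- alpha_shape_boundary(pc, alpha = 0.005)$kept
  expect_true(all(k2 >= k1))
  expect_true(all(k3 >= k2))
})

test_that("alpha shape of a C-shaped cloud is concave and matches the
           brute-force triangle filter", {
  th <- seq(0.4 * pi, 1.6 * pi, length.out = 100)
  pts <- rbind(cbind(100 + 80 * cos(th), 100 + 80 * sin(th)),
               cbind(100 + 40 * cos(rev(th)), 100 + 40 * sin(rev(th))))
  res <- alpha_shape_boundary(pts, alpha = 0.02)
  expect_identical(res$source, "alpha_shape")
  hull_area <- abs(poly_area_for_test(pts[c(chull(pts), chull(pts)[1]), ]))
  expect_lt(abs(poly_area_for_test(res$polygon)), hull_area)
  # brute-force filter: circumradius of every Delaunay triangle vs 1/alpha
  tri <- res$triangles
  circum <- function(p1, p2, p3) {
    a <- sqrt(sum((p2 - p3)^2)); b <- sqrt(sum((p1 - p3)^2))
    cc <- sqrt(sum((p1 - p2)^2))
    ar <- abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
              (p3[1] - p1[1]) * (p2[2] - p1[2])) / 2
    if (ar == 0) Inf else a * b * cc / (4 * ar)
  }
  expected_kept <- vapply(seq_len(nrow(tri)), function(i)
    circum(pts[tri[i, 1], ], pts[tri[i, 2], ], pts[tri[i, 3], ]) < 50,
    logical(1))
  expect_identical(res$kept, expected_kept)
  # all kept-triangle vertices lie inside (or on) the mask
  vids <- unique(as.vector(tri[res$kept, ]))
  px <- round(pts[vids, 1]) + 1L; py <- round(pts[vids, 2]) + 1L
  near_mask <- vapply(seq_along(px), function(i) {
    rs <- max(1, py[i] - 1):min(nrow(res$mask), py[i] + 1)
    cs <- max(1, px[i] - 1):min(ncol(res$mask), px[i] + 1)
    any(res$mask[rs, cs])
  }, logical(1))
  expect_true(all(near_mask))
  expect_error(alpha_shape_boundary(cbind(c(0, 1), c(0, 1))), "3")
  expect_error(alpha_shape_boundary(cbind(0:5, 0:5)), "collinear")
})

test_that("rim and annulus masks match analytic annuli on disks", {
  disk <- disk_mask(221, 221, 110, 110, 100)
  rim <- peripheral_rim(disk, 60)
  expect_equal(sum(rim), pi * (100^2 - 40^2), tolerance = 0.02)
  expect_true(all(disk[rim]))                     # rim subset of mask
  full <- peripheral_rim(disk, 120)               # thickness > radius
  expect_identical(full, disk)
  # rim + interior remainder = cell, exactly (pixel counts)
  expect_identical(sum(rim) + sum(disk & !rim), sum(disk))

  nuc <- disk_mask(221, 221, 110, 110, 30)
  ann <- perinuclear_annulus(nuc, 40)
  expect_equal(sum(ann), pi * (70^2 - 30^2), tolerance = 0.02)
  expect_identical(sum(ann & nuc), 0L)            # disjoint from nucleus
  shell <- perinuclear_annulus(nuc, 1)
  expect_true(all(shell[!nuc] == (dist_band_for_test(nuc) <= 1)[!nuc]))
  expect_error(peripheral_rim(matrix(FALSE, 5, 5), 2), "empty")
})

test_that("EDT band masks equal brute-force per-pixel distance bands", {
  set.seed(7)
  # irregular small mask: union of two disks
  m <- disk_mask(60, 60, 20, 25, 12) | disk_mask(60, 60, 38, 30, 9)
  expect_identical(peripheral_rim(m, 5), rim_bruteforce(m, 5))
  nuc <- disk_mask(60, 60, 28, 28, 6)
  expect_identical(perinuclear_annulus(nuc, 7),
                   annulus_bruteforce(nuc, 7) & !nuc)
})

test_that("dilate-mode bands are Chebyshev (square) versions of the EDT bands", {
  disk <- disk_mask(101, 101, 50, 50, 35)
  rim_e <- peripheral_rim(disk, 10, method = "edt")
  rim_d <- peripheral_rim(disk, 10, method = "dilate")
  expect_true(all(disk[rim_d]))
  expect_gte(sum(rim_d), sum(rim_e))   # square element erodes no less
})

test_that("detections are assigned to the regions they sit in", {
  cell <- disk_mask(201, 201, 100, 100, 90)
  nuc <- disk_mask(201, 201, 100, 100, 25)
  masks <- region_mask_set(cell, nuc, rim_px = 20, annulus_px = 15)
  det <- data.frame(
    frame = 0L,
    x = c(100, 100 + 89, 100 + 30, 100 + 50),  # nucleus, boundary, annulus, interior
    y = 100,
    area_px2 = 1L, intensity_sum = 1, region = "none")
  out <- assign_regions(det, masks)
  expect_identical(out$region, c("none", "peripheral", "perinuclear", "whole"))
  # construction oracle: particles placed only in the analytic annulus
  ang <- seq(0, 2 * pi, length.out = 41)[-41]
  r <- 25 + 7
  det2 <- data.frame(frame = 0L, x = 100 + r * cos(ang), y = 100 + r * sin(ang),
                     area_px2 = 1L, intensity_sum = 1, region = "none")
  out2 <- assign_regions(det2, masks)
  expect_true(all(out2$region == "perinuclear"))
  expect_error(assign_regions(data.frame(frame = 0L, x = 500, y = 0,
                                         area_px2 = 1L, intensity_sum = 1,
                                         region = "none"), masks),
               "outside")
})

test_that("polygons and masks round-trip through disk", {
  g <- make_cell_geometry(600, 0.2, 0.13, "blob", seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_polygon(g$cell_polygon, f)
  back <- read_polygon(f)
  expect_equal(back[, 1], unname(g$cell_polygon[, 1]))
  m <- rasterize_polygon(g$cell_polygon, g$shape)
  expect_identical(m, g$cell_mask)
})
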