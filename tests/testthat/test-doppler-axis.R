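test_that("intermeans threshold reproduces hand-iterated fixed points", {
  expect_equal(as.numeric(intermeans_threshold(matrix(c(0, 0, 0, 10, 10), 1))), 5.0)
  expect_equal(as.numeric(intermeans_threshold(matrix(c(1, 2, 9, 10), 1))), 5.5)
  z <- intermeans_threshold(matrix(0, 4, 4))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  k <- intermeans_threshold(matrix(7, 3, 3))
  expect_equal(as.numeric(k), 7)
  expect_true(attr(k, "degenerate"))
})

test_that("preprocessing zeroes strictly sub-threshold pixels and nothing else", {
  img <- image_grid(matrix(c(4, 5, 6), 1), 1)
  out <- preprocess_doppler(img, threshold = 5)
  expect_equal(as.vector(out$intensities), c(0, 5, 6))

  img2 <- image_grid(matrix(c(0, 0, 0, 10, 10), 1), 1)
  out2 <- preprocess_doppler(img2)
  expect_equal(as.vector(out2$intensities), c(0, 0, 0, 10, 10))
  expect_equal(attr(out2, "threshold"), 5)

  zero <- preprocess_doppler(image_grid(matrix(0, 3, 3), 1))
  expect_true(all(zero$intensities == 0))

  # no surviving pixel may sit strictly between 0 and the threshold
  set.seed(42)
  img3 <- image_grid(matrix(runif(400), 20), 1)
  out3 <- preprocess_doppler(img3)
  v <- out3$intensities
  expect_true(all(v == 0 | v >= attr(out3, "threshold")))
  expect_equal(dim(out3$intensities), dim(img3$intensities))
})

test_that("DBSCAN matches brute-force density connectivity on block fixtures", {
  m <- matrix(0, 64, 90)
  m[10:21, 10:21] <- 1      # 12x12 block
  m[10:21, 72:83] <- 1      # second block, > 50 px away
  img <- image_grid(m, 1)
  cl <- cluster_doppler(img, R = 6, M = 100)
  expect_length(cl, 2L)
  # exact density connectivity: the 4 corners of a 12x12 block are farther
  # than R from every core pixel, so each cluster has 140 members
  expect_equal(sort(vapply(cl, function(x) nrow(x$pixels), integer(1))), c(140L, 140L))

  pts <- which(m == 1, arr.ind = TRUE)
  oc <- oracle_dbscan(pts, 6, 100)
  got <- canon_clusters(cluster_pixel_sets(cl, nrow(m)))
  want <- canon_clusters(lapply(oc, function(ix) {
    sort((pts[ix, 2] - 1L) * nrow(m) + pts[ix, 1])
  }))
  expect_equal(got, want)
})

test_that("DBSCAN discards sub-minimum point sets and keeps solid blocks whole", {
  m <- matrix(0, 64, 64)
  m[cbind(sample(1:64, 50, TRUE), sample(1:64, 50, TRUE))] <- 1
  m[m > 0] <- 1
  img <- image_grid(m, 1)
  expect_length(cluster_doppler(img, R = 6, M = 100), 0L)

  m2 <- matrix(0, 40, 40)
  m2[11:30, 11:30] <- 1     # 20x20 block
  cl2 <- cluster_doppler(image_grid(m2, 1), R = 6, M = 100)
  expect_length(cl2, 1L)
  # exact density connectivity again excludes the 4 block corners (> R from
  # every core pixel); brute force agrees
  expect_equal(nrow(cl2[[1]]$pixels), 396L)
  pts2 <- which(m2 == 1, arr.ind = TRUE)
  oc2 <- oracle_dbscan(pts2, 6, 100)
  expect_length(oc2, 1L)
  expect_length(oc2[[1]], 396L)

  expect_length(cluster_doppler(image_grid(matrix(0, 8, 8), 1)), 0L)
})

test_that("DBSCAN equals the brute-force oracle on random small fixtures", {
  for (seed in 1:4) {
    set.seed(seed)
    m <- matrix(0, 48, 48)
    # a few dense patches plus scattered noise
    for (k in 1:3) {
      r <- sample(8:40, 1); c <- sample(8:40, 1); s <- sample(3:6, 1)
      m[max(1, r - s):min(48, r + s), max(1, c - s):min(48, c + s)] <- 1
    }
    m[cbind(sample(1:48, 30, TRUE), sample(1:48, 30, TRUE))] <- 1
    R <- sample(2:4, 1); M <- sample(c(12, 20, 30), 1)
    cl <- cluster_doppler(image_grid(m, 1), R = R, M = M)
    pts <- which(m == 1, arr.ind = TRUE)
    oc <- oracle_dbscan(pts, R, M)
    got <- canon_clusters(cluster_pixel_sets(cl, 48))
    want <- canon_clusters(lapply(oc, function(ix) sort((pts[ix, 2] - 1L) * 48L + pts[ix, 1])))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("Radon line detection finds the dominant straight structure", {
  # single horizontal row of ones
  m <- matrix(0, 21, 21); m[8, ] <- 1
  est <- radon_line_detect(image_grid(m, 1))
  expect_equal(est$angle, 0)
  expect_equal(unname(est$direction), c(0, 1))
  expect_lt(point_line_distance(est, c(8, 11)), 1e-9)

  # a 30 px line beats a 10 px line of equal intensity
  m2 <- draw_segment(64, 64, c(5, 5), 35, 30)
  m2 <- pmax(m2, draw_segment(64, 64, c(50, 10), 100, 10))
  est2 <- radon_line_detect(m2)
  expect_lt(angle_error(35, est2$angle), 3)

  # rotating the input by 90 degrees rotates the detected line by 90 degrees
  m3 <- draw_segment(41, 41, c(8, 6), 20, 28)
  e3 <- radon_line_detect(m3)
  m3r <- t(m3[nrow(m3):1, ])   # 90 degree rotation
  e3r <- radon_line_detect(m3r)
  expect_lt(angle_error(e3$angle + 90, e3r$angle), 1.5)

  expect_error(radon_line_detect(matrix(0, 8, 8)), "no line")
})

test_that("Radon transform equals the literal per-pixel oracle", {
  angles <- seq(0, 175, by = 5)
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(0, 32, 32)
    m[sample(length(m), 60)] <- runif(60)
    rt <- radon_transform(m, angles)
    or <- oracle_radon(m, angles)
    # the oracle integrates the shadow numerically; its only error is the
    # quadrature resolution at profile breakpoints
    expect_lt(max(abs(rt$sinogram - or$sinogram)), 0.01)
    expect_equal(rt$rho, or$rho)
  }
  # argmax agreement on a structured image over the full 1-degree grid
  m <- draw_segment(48, 48, c(6, 4), 40, 38, value = 0.8)
  rt <- radon_transform(m, 0:179)
  or <- oracle_radon(m, 0:179)
  expect_equal(which(rt$sinogram == max(rt$sinogram)),
               which(or$sinogram == max(or$sinogram)))
})

test_that("initial axis tracks the dominant cluster orientation", {
  # one cluster forming a 45 degree strip
  m <- matrix(0, 64, 64)
  for (t in 0:49) {
    r <- 6 + t; c <- 6 + t
    m[max(1, r - 2):min(64, r + 2), c] <- 1
  }
  img <- image_grid(m, 1)
  cl <- cluster_doppler(img, R = 3, M = 20)
  expect_gte(length(cl), 1L)
  ax <- initial_axis(cl, img)
  expect_lte(angle_error(45, ax$angle), 1 + 1e-9)

  # two disjoint collinear clusters: the line passes through both
  m2 <- matrix(0, 64, 64)
  m2[10:15, 5:20] <- 1
  m2[10:15, 45:60] <- 1
  img2 <- image_grid(m2, 1)
  cl2 <- cluster_doppler(img2, R = 3, M = 20)
  expect_length(cl2, 2L)
  ax2 <- initial_axis(cl2, img2)
  # the returned line passes through both clusters (the flat projection of a
  # uniform block ties over several offsets, so only membership is asserted)
  # (a line slightly tilted within the 6-px band is slightly longer, so the
  # angle itself may be a few degrees off horizontal)
  expect_lt(min(point_line_distance(ax2, cl2[[1]]$pixels)), 0.75)
  expect_lt(min(point_line_distance(ax2, cl2[[2]]$pixels)), 0.75)

  expect_error(initial_axis(list(), img2), "no Doppler evidence")
})

test_that("moment ellipses have the regionprops convention and equivariances", {
  # filled disc of radius 10
  g <- expand.grid(r = 1:41, c = 1:41)
  disc <- as.matrix(g[(g$r - 21)^2 + (g$c - 21)^2 <= 100, ])
  e <- fit_ellipse(disc)
  expect_equal(e$center, c(21, 21), tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(abs(e$major - 20) / 20, 0.05)
  expect_lt(abs(e$minor - 20) / 20, 0.05)

  # 1 x 41 horizontal strip: discrete variance 140, major = 4*sqrt(140)
  strip <- cbind(rep(5, 41), 1:41)
  es <- fit_ellipse(strip)
  expect_equal(es$orientation, 0)
  expect_equal(es$major, 4 * sqrt(140), tolerance = 1e-9)
  expect_equal(es$minor, 1)  # collinear floor

  # translation equivariance
  et <- fit_ellipse(strip + matrix(rep(c(5, 7), each = 41), ncol = 2))
  expect_equal(et$center, es$center + c(5, 7), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(et$major, es$major, tolerance = 1e-12)

  # rotation equivariance within discretization tolerance
  set.seed(7)
  blob <- cbind(round(rnorm(300, 0, 8)), round(rnorm(300, 0, 3)))
  e0 <- fit_ellipse(blob + 50)
  ang <- 30 * pi / 180
  rot <- cbind(round(blob[, 1] * cos(ang) + blob[, 2] * sin(ang)),
               round(-blob[, 1] * sin(ang) + blob[, 2] * cos(ang)))
  e1 <- fit_ellipse(rot + 50)
  expect_lt(abs(e0$major - e1$major) / e0$major, 0.05)
  expect_lt(abs(e0$minor - e1$minor) / e0$minor, 0.05)
})

test_that("ROI elimination keeps exactly the ellipses meeting the axis", {
  shape <- c(100, 100)
  axis <- line_from_angle_point(0, c(50, 1), shape)  # horizontal, row 50
  on_line <- ellipse_roi(c(50, 30), 10, 10, 0)        # radius-5 circle on line
  away <- ellipse_roi(c(70, 30), 10, 10, 0)           # 20 px off
  tangent <- ellipse_roi(c(55, 60), 10, 10, 0)        # exactly 5 px off
  kept <- filter_rois(list(on_line, away, tangent), axis)
  expect_length(kept, 2L)
  expect_equal(kept[[1]]$center, c(50, 30), ignore_attr = TRUE)
  expect_equal(kept[[2]]$center, c(55, 60), ignore_attr = TRUE)

  # anisotropic case: a thin ellipse aligned with the line is reachable only
  # along its major axis
  thin <- ellipse_roi(c(58, 30), 30, 4, 0)  # semi-minor 2 across the line
  expect_length(filter_rois(list(thin), axis), 0L)
  thin2 <- ellipse_roi(c(52, 30), 30, 4, 0)
  expect_length(filter_rois(list(thin2), axis), 1L)
  expect_length(filter_rois(list(), axis), 0L)
})
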