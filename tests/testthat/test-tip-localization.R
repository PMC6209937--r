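test_that("entry point is the shallowest boundary intersection", {
  shape <- c(100, 100)
  # horizontal axis at row 11: enters at the left edge (smallest column tie)
  h <- line_from_angle_point(0, c(11, 50), shape)
  expect_equal(unname(entry_point(h)), c(11, 1))

  # 45-degree axis through (1, 21): top-edge intersection
  d45 <- line_from_angle_point(45, c(1, 21), shape)
  expect_equal(unname(entry_point(d45)), c(1, 21), tolerance = 1e-9)

  # axis entirely outside the image
  far <- line_from_angle_point(0, c(-50, 1), shape)
  expect_error(entry_point(far, shape), "does not intersect")
})

test_that("window-averaged profiles obey constancy, linearity and symmetry", {
  shape <- c(80, 80)
  axis <- line_from_angle_point(60, c(1, 10), shape)
  const <- image_grid(matrix(0.37, 80, 80), 1)
  zero <- image_grid(matrix(0, 80, 80), 1)
  p <- compute_axis_profiles(const, zero, axis, 4)
  expect_true(all(abs(p$ipd - 0.37) < 1e-12))
  expect_true(all(p$ibm == 0))
  expect_equal(p$window_length, 8)
  expect_equal(p$window_width, 4)
  expect_gte(length(p$ipd), 2)

  set.seed(5)
  img <- image_grid(matrix(runif(6400), 80, 80), 1)
  img2 <- image_grid(2 * img$intensities, 1)
  p1 <- compute_axis_profiles(img, img, axis, 4)
  p2 <- compute_axis_profiles(img2, img2, axis, 4)
  expect_equal(p2$ipd, 2 * p1$ipd, tolerance = 1e-12)
  # both profiles come from the same windower: swapping image roles swaps them
  ps <- compute_axis_profiles(img, img2, axis, 4)
  expect_equal(ps$ipd, p1$ipd, tolerance = 1e-12)
  expect_equal(ps$ibm, p2$ipd, tolerance = 1e-12)
})

test_that("a step image produces a window-length ramp centered on the step", {
  # value 1 on rows 1-50 (i.e. l = 0..49 along a vertical axis), 0 below;
  # the box average of a unit step ramps linearly over the window length,
  # centered at the boundary l = 49.5
  m <- matrix(0, 100, 100)
  m[1:50, ] <- 1
  img <- image_grid(m, 1)
  axis <- line_from_angle_point(90, c(1, 40), c(100, 100))
  d <- 4
  p <- compute_axis_profiles(img, img, axis, d)
  l <- p$l
  expected <- pmin(pmax((49.5 + d - l) / (2 * d), 0), 1)
  expect_equal(p$ibm, expected, tolerance = 0.08)
  # exact plateaus away from the ramp
  expect_true(all(p$ibm[l <= 49.5 - d - 1] == 1))
  expect_true(all(p$ibm[l >= 49.5 + d + 1] == 0))
  # midpoint of the ramp at the step
  mid <- which.min(abs(p$ibm - 0.5)) - 1
  expect_lte(abs(mid - 49.5), 1)
})

test_that("the Doppler separation score matches its definition and tie rules", {
  tip <- doppler_tip_estimate(c(1, 1, 1, 0, 0) * 10)  # ipd with mean 6
  # B = [1,1,1,0,0] under the mean threshold
  expect_equal(attr(tip, "spd"), c(0.6, 0.8, 1.0, 0.8, 0.6))
  expect_equal(as.integer(tip), 2L)

  # all strong: tip at the deepest sample, flagged
  tip2 <- doppler_tip_estimate(rep(3, 6))
  expect_equal(as.integer(tip2), 5L)
  expect_equal(max(attr(tip2, "spd")), 1.0)
  expect_true(attr(tip2, "low_confidence"))

  # alternating: tie between l = 0 and l = 2 resolved to the deeper 2
  tip3 <- doppler_tip_estimate(c(10, 0, 10, 0))
  expect_equal(attr(tip3, "spd"), c(0.75, 0.5, 0.75, 0.5))
  expect_equal(as.integer(tip3), 2L)
})

test_that("the separation score equals brute force and peaks at step boundaries", {
  # random binary vectors against the literal double-loop oracle
  set.seed(11)
  for (k in 1:25) {
    L <- sample(2:14, 1)
    b <- sample(0:1, L, replace = TRUE)
    expect_equal(needleloc:::spd_score(b), oracle_spd(b), tolerance = 1e-12)
  }
  # perfect steps 1^k 0^(L-k): argmax at the boundary k-1
  for (L in c(5, 9, 12)) {
    for (k in 1:L) {
      s <- needleloc:::spd_score(c(rep(1, k), rep(0, L - k)))
      expect_equal(max(which(s == max(s))) - 1L, k - 1L)
    }
  }
})

test_that("B-mode refinement finds the strongest drop near the Doppler tip", {
  mk_profile <- function(ibm) {
    L <- length(ibm)
    structure(list(l = 0:(L - 1), positions = cbind(seq_len(L), 1),
                   ipd = rep(1, L), ibm = ibm, entry = c(1, 1), axis = NULL,
                   window_length = 4, window_width = 2),
              class = "axis_profile")
  }
  r <- bmode_tip_refine(mk_profile(c(5, 5, 5, 1, 1)), 2, 2)
  expect_equal(r$refined_tip_index, 2L)
  expect_false(r$low_confidence)
  expect_equal(unname(r$tip_pixel), c(3, 1))
  expect_lte(abs(r$refined_tip_index - r$doppler_tip_index), r$search_radius)

  # constant profile: no drop exists, fall back to the Doppler estimate
  rc <- bmode_tip_refine(mk_profile(rep(2, 8)), 4, 2)
  expect_equal(rc$refined_tip_index, 4L)
  expect_true(rc$low_confidence)

  # two equal drops at l = 3 and l = 6: deepest wins
  ibm <- c(9, 9, 9, 9, 5, 5, 5, 1, 1, 1)
  rt <- bmode_tip_refine(mk_profile(ibm), 5, 3)
  expect_equal(rt$refined_tip_index, 6L)
})

test_that("tips are recovered within two needle diameters on the phantom batch", {
  b <- phantom_batch()
  tab <- b$table
  expect_true(all(!tab$failed_hard))
  within2d <- tab$tip_err <= 2 * b$needle_diameter
  expect_gte(mean(within2d), 0.9)
})
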