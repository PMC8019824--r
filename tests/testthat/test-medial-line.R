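test_that("order_skeleton walks simple curves and rejects branches", {
  occ <- array(FALSE, c(7, 3, 3)); occ[2:6, 2, 2] <- TRUE
  poly <- order_skeleton(binary_volume(occ, c(2, 2, 2)))
  expect_equal(nrow(poly), 5)
  expect_equal(poly[, 1], c(2, 4, 6, 8, 10))  # world x of voxels 1..5
  expect_true(all(poly[, 2] == 2) && all(poly[, 3] == 2))

  # L-shape: path runs through the corner, covering every voxel once
  occ <- array(FALSE, c(6, 6, 3))
  occ[1:4, 2, 2] <- TRUE; occ[4, 3:5, 2] <- TRUE
  polyL <- order_skeleton(binary_volume(occ))
  expect_equal(nrow(polyL), sum(occ))
  steps <- sqrt(rowSums(diff(polyL)^2))
  expect_true(all(steps <= sqrt(3) + 1e-12))  # consecutive 26-neighbours

  # Y-shape has three endpoints
  occ <- array(FALSE, c(7, 7, 3))
  occ[1:4, 4, 2] <- TRUE; occ[5, 5, 2] <- TRUE; occ[5, 3, 2] <- TRUE
  occ[6, 6, 2] <- TRUE; occ[6, 2, 2] <- TRUE
  expect_error(order_skeleton(binary_volume(occ)), "not a simple curve")
})

test_that("skeleton_to_polyline recovers the diameter path with spurs", {
  occ <- array(FALSE, c(10, 5, 3))
  occ[1:9, 2, 2] <- TRUE
  occ[5, 3, 2] <- TRUE  # one-voxel spur
  poly <- skeleton_to_polyline(binary_volume(occ))
  expect_equal(nrow(poly), 9)  # spur dropped, main run kept
})

test_that("least-squares B-spline matches a dense pseudo-inverse solve", {
  # collinear data are reproduced exactly
  t0 <- seq(0, 1, length.out = 20)
  line <- cbind(1 + 3 * t0, 2 - t0, t0)
  cv <- fit_bspline(line, n_ctrl = 6, degree = 3)
  resid <- eval_bspline(cv, tractdir:::chord_params(line)) - line
  expect_lt(max(abs(resid)), 1e-9)

  set.seed(7)
  pts <- matrix(rnorm(40 * 3), ncol = 3)
  pts <- pts[c(TRUE, sqrt(rowSums(diff(pts)^2)) > 0), , drop = FALSE]
  cv <- fit_bspline(pts, n_ctrl = 8, degree = 3)
  # oracle: generic pseudo-inverse least squares on the same design
  tk <- tractdir:::chord_params(pts)
  A <- splines::splineDesign(cv$knots, tk, ord = 4)
  Q_oracle <- MASS::ginv(A) %*% pts
  expect_lt(max(abs(cv$control - Q_oracle)), 1e-8)

  # points on a cubic polynomial are exactly representable with enough
  # control points
  tc <- seq(0, 1, length.out = 12)
  cub <- cbind(tc^3, tc^2 - tc, 2 * tc)
  cvc <- fit_bspline(cub, n_ctrl = 12, degree = 3)
  expect_lt(max(abs(eval_bspline(cvc, tractdir:::chord_params(cub)) - cub)),
            1e-9)

  expect_error(fit_bspline(line, n_ctrl = 3, degree = 3), "degree")
})

test_that("B-spline residual is non-increasing in the control count", {
  set.seed(8)
  t0 <- seq(0, 1, length.out = 60)
  pts <- cbind(sin(2 * t0), cos(3 * t0), t0) + 0.01 * matrix(rnorm(180), ncol = 3)
  tk <- tractdir:::chord_params(pts)
  res <- vapply(c(5, 8, 12, 20), function(nc) {
    cv <- fit_bspline(pts, n_ctrl = nc, degree = 3)
    sum((eval_bspline(cv, tk) - pts)^2)
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-10))
})

test_that("derivative curve equals finite differences of the original", {
  t0 <- seq(0, 1, length.out = 20)
  line <- cbind(3 * t0, -t0, 0.5 * t0)
  dcv <- derivative_curve(fit_bspline(line, n_ctrl = 5, degree = 3))
  d <- eval_bspline(dcv, runif(5))
  expect_lt(max(abs(sweep(d, 2, c(3, -1, 0.5)))), 1e-8)

  set.seed(9)
  pts <- matrix(rnorm(60), ncol = 3)
  cv <- fit_bspline(pts, n_ctrl = 7, degree = 3)
  dcv <- derivative_curve(cv)
  tt <- seq(0.02, 0.98, length.out = 200)
  h <- 1e-6
  fd <- (eval_bspline(cv, tt + h) - eval_bspline(cv, tt - h)) / (2 * h)
  an <- eval_bspline(dcv, tt)
  expect_lt(max(abs(an - fd)) / max(abs(an)), 1e-4)

  # second application matches finite differences of the first derivative
  d2cv <- derivative_curve(dcv)
  fd2 <- (eval_bspline(dcv, tt + h) - eval_bspline(dcv, tt - h)) / (2 * h)
  an2 <- eval_bspline(d2cv, tt)
  expect_lt(max(abs(an2 - fd2)) / max(abs(an2)), 1e-4)
  expect_error(derivative_curve(derivative_curve(d2cv)), "degree-0")
})

test_that("slices fall at regular arc lengths with unit tangents", {
  t0 <- seq(0, 1, length.out = 30)
  line <- cbind(10 * t0, 0 * t0, 0 * t0)
  fr <- sample_slices(fit_bspline(line, n_ctrl = 5), spacing_mm = 2)
  expect_equal(fr$s_mm, c(0, 2, 4, 6, 8, 10))
  expect_equal(fr$x, fr$s_mm, tolerance = 1e-6)
  expect_equal(sqrt(fr$tx^2 + fr$ty^2 + fr$tz^2), rep(1, 6),
               tolerance = 1e-9)

  # quarter circle of radius 10: length pi r / 2
  th <- seq(0, pi / 2, length.out = 200)
  arcpts <- cbind(10 * cos(th), 10 * sin(th), 0 * th)
  cva <- fit_bspline(arcpts, n_ctrl = 40, degree = 3)
  expect_equal(arc_length(cva), pi * 10 / 2, tolerance = 1e-4)
  fra <- sample_slices(cva, 2)
  # consecutive frames are spacing +- 5 percent apart in space
  gaps <- sqrt(rowSums(diff(as.matrix(fra[, c("x", "y", "z")]))^2))
  expect_true(all(abs(gaps - 2) < 0.1))

  expect_warning(sample_slices(fit_bspline(line, n_ctrl = 5), 50),
                 "shorter")
})

test_that("cross-section slabs collect the in-plane connected voxels", {
  tube <- tube_volume(40, r = 3)
  t0 <- seq(0, 1, length.out = 30)
  axis_line <- cbind(39 * t0, 0 * t0 + 3, 0 * t0 + 3)
  cv <- fit_bspline(axis_line, n_ctrl = 5)
  fr <- sample_slices(cv, 2)
  mid <- fr[10, ]
  cs <- cut_cross_section(tube, mid)
  expect_equal(nrow(cs), 29)              # ~ pi 3^2 disc
  expect_equal(length(unique(cs[, 1])), 1) # one axial index: slab = 1 voxel
  # union of all slabs stays inside the bundle
  all_vox <- do.call(rbind, lapply(seq_len(nrow(fr)), function(i)
    cut_cross_section(tube, fr[i, ])))
  expect_true(all(tube$occupancy[all_vox + 1L]))
  # a frame far outside the bundle collects nothing
  off <- mid; off$y <- 40; off$z <- 40
  expect_equal(nrow(cut_cross_section(tube, off)), 0)
})

test_that("curves serialize to JSON and back", {
  set.seed(10)
  cv <- fit_bspline(matrix(rnorm(45), ncol = 3), n_ctrl = 5)
  cv2 <- bspline_from_json(bspline_to_json(cv))
  expect_equal(cv2$control, cv$control, tolerance = 1e-12)
  expect_equal(cv2$knots, cv$knots)
  expect_identical(cv2$degree, cv$degree)
})
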