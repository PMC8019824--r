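test_that("axial canonicalization fixes the hemisphere and normalises", {
  expect_equal(as.numeric(axial_sample(c(0, 0, -1))), c(0, 0, 1))
  expect_equal(as.numeric(axial_sample(c(0, -2, 0))), c(0, 1, 0))
  set.seed(1)
  X <- uniform_axes(50)
  Xc <- axial_sample(X)
  expect_identical(unclass(axial_sample(unclass(Xc))), unclass(Xc))
  expect_equal(scatter_matrix(axial_sample(X))$T,
               scatter_matrix(axial_sample(-X))$T, tolerance = 1e-12)
  expect_error(axial_sample(c(0, 0, 0)), "zero")
})

test_that("scatter matrix has unit trace and recovers concentration axes", {
  z <- matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)
  sc <- scatter_matrix(axial_sample(z))
  expect_equal(sc$values, c(1, 0, 0), tolerance = 1e-12)
  set.seed(2)
  scu <- scatter_matrix(axial_sample(uniform_axes(1e4)))
  expect_true(all(abs(scu$values - 1 / 3) < 0.02))
  expect_equal(sum(diag(scu$T)), 1, tolerance = 1e-9)
})

test_that("Kummer series matches closed forms and a direct-sum oracle", {
  expect_equal(kummer_M(0.7, 1.9, 0), 1)
  expect_equal(kummer_M(1, 2, 1), exp(1) - 1, tolerance = 1e-12)
  # independent oracle: plain cumulative sum of the defining series
  oracle_M <- function(a, b, x, terms = 200) {
    tot <- 1; term <- 1
    for (n in 0:(terms - 1)) {
      term <- term * (a + n) / (b + n) * x / (n + 1)
      tot <- tot + term
    }
    tot
  }
  for (k in c(1, 5, 20))
    expect_equal(kummer_M(0.5, 1.5, k), oracle_M(0.5, 1.5, k),
                 tolerance = 1e-10)
  expect_error(kummer_M(0.5, 1.5, 800), "overflow")
  expect_error(kummer_M(1, -2, 1), "nonpositive")
})

test_that("the Watson moment function is increasing and invertible", {
  ks <- c(-50, -5, -1, 0, 1, 5, 50)
  d <- watson_D3(ks)
  expect_true(all(diff(d) > 0))
  expect_equal(watson_D3(0), 1 / 3, tolerance = 1e-12)
  for (k in c(-30, -2, 0.5, 8, 90))
    expect_equal(watson_kappa_solve(watson_D3(k)), k, tolerance = 1e-5)
  # numeric derivative check of D3'
  h <- 1e-5
  for (k in c(-4, 0, 6))
    expect_equal(tractdir:::watson_D3_prime(k),
                 (watson_D3(k + h) - watson_D3(k - h)) / (2 * h),
                 tolerance = 1e-6)
})

test_that("Watson MLE recovers axis and concentration on both branches", {
  same <- matrix(rep(c(0, 0, 1), 50), ncol = 3, byrow = TRUE)
  expect_warning(f <- watson_mle(axial_sample(same)), "capped")
  expect_equal(f$kappa, 700)

  set.seed(3)
  fi <- watson_mle(axial_sample(uniform_axes(1e4)))
  expect_lt(abs(fi$kappa), 0.5)

  wg <- structure(list(mu = c(0, 1, 0), kappa = -12),
                  class = "watson_model")
  fg <- watson_mle(sample_model(wg, 4000, seed = 4))
  expect_lt(abs(fg$kappa - (-12)) / 12, 0.2)
  expect_gt(abs(sum(fg$mu * c(0, 1, 0))), 0.99)
})

test_that("Watson density integrates to one and is antipodal", {
  m0 <- structure(list(mu = c(0, 0, 1), kappa = 0), class = "watson_model")
  expect_equal(watson_logpdf(c(1, 0, 0), m0), log(1 / (4 * pi)),
               tolerance = 1e-12)
  grid <- sphere_grid(60)
  for (k in c(-10, 5, 50)) {
    m <- structure(list(mu = c(1, 1, 1) / sqrt(3), kappa = k),
                   class = "watson_model")
    expect_equal(sum(grid$w * exp(watson_logpdf(grid$X, m))), 1,
                 tolerance = 1e-6)
    x <- axial_sample(c(0.3, -0.5, 1))
    expect_equal(watson_logpdf(x, m), watson_logpdf(-x, m))
  }
})

test_that("Bingham MLE recovers symmetric, asymmetric and isotropic cases", {
  U <- diag(3)
  # rotationally symmetric bipolar: fitted minor concentrations agree
  fs <- bingham_mle(sample_model(bingham_model(U, c(0, -8, -8)), 5000,
                                 seed = 5))
  expect_lt(abs(fs$kappas[2] - fs$kappas[3]), 0.2 * abs(fs$kappas[3]))
  # isotropic: everything near zero
  set.seed(6)
  fi <- bingham_mle(axial_sample(uniform_axes(1e4)))
  expect_true(all(abs(fi$kappas) < 1))
  # gauge always holds
  for (kp in list(c(0, -3, -9), c(0, 0, -15), c(0, -1, -1))) {
    f <- bingham_mle(sample_model(bingham_model(U, kp), 3000, seed = 7))
    expect_equal(f$kappas[1], 0)
    expect_true(f$kappas[2] >= f$kappas[3])
    expect_lte(f$kappas[2], 1e-9)
    expect_equal(max(abs(crossprod(f$U) - diag(3))), 0, tolerance = 1e-9)
  }
})

test_that("Bingham density integrates to one and reduces to Watson", {
  U <- diag(3)
  m0 <- bingham_model(U, c(0, 0, 0))
  expect_equal(bingham_logpdf(c(0, 1, 0), m0), log(1 / (4 * pi)),
               tolerance = 1e-8)
  grid <- sphere_grid(60)
  m <- bingham_model(U, c(0, -1, -10))
  expect_equal(sum(grid$w * exp(bingham_logpdf(grid$X, m))), 1,
               tolerance = 1e-6)
  # kappa_2 = 0, kappa_3 = kappa: Watson girdle about the third axis
  mw <- bingham_model(U, c(0, 0, -6))
  watson_equiv <- structure(list(mu = c(0, 0, 1), kappa = -6),
                            class = "watson_model")
  x <- axial_sample(matrix(rnorm(30), ncol = 3))
  expect_equal(bingham_logpdf(x, mw), watson_logpdf(x, watson_equiv),
               tolerance = 1e-7)
})

test_that("model sampling is seeded, moment-matched and uniform at kappa 0", {
  bm <- bingham_model(diag(3), c(0, -5, -20))
  s1 <- sample_model(bm, 500, seed = 8)
  s2 <- sample_model(bm, 500, seed = 8)
  expect_identical(unclass(s1), unclass(s2))
  # scatter eigenvalues converge to the model moments
  big <- sample_model(bm, 1e5, seed = 9)
  got <- scatter_matrix(big)$values
  grid <- sphere_grid(80)
  dens <- exp(bingham_logpdf(grid$X, bm))
  want <- vapply(1:3, function(j)
    sum(grid$w * dens * grid$X[, j]^2), numeric(1))
  expect_true(all(abs(got - sort(want, decreasing = TRUE)) < 0.02))
  # uniform: |z| has mean 1/2 on the sphere
  u <- sample_model(bingham_model(diag(3), c(0, 0, 0)), 2e4, seed = 10)
  expect_equal(mean(abs(u[, 3])), 0.5, tolerance = 0.02)
})

test_that("fits are rotation equivariant", {
  R <- tractdir:::rotation_about(c(1, 2, 2) / 3, 0.9)
  bm <- bingham_model(diag(3), c(0, -4, -15))
  s <- sample_model(bm, 3000, seed = 11)
  f1 <- bingham_mle(s)
  f2 <- bingham_mle(axial_sample(unclass(s) %*% t(R)))
  expect_equal(f2$kappas, f1$kappas, tolerance = 1e-6)
  for (j in 1:3)
    expect_equal(abs(sum((R %*% f1$U[, j]) * f2$U[, j])), 1,
                 tolerance = 1e-6)
  w1 <- watson_mle(s)
  w2 <- watson_mle(axial_sample(unclass(s) %*% t(R)))
  expect_equal(w2$kappa, w1$kappa, tolerance = 1e-6)
  expect_equal(abs(sum((R %*% w1$mu) * w2$mu)), 1, tolerance = 1e-6)
})

test_that("kappa-hat bias shrinks with sample size", {
  wm <- structure(list(mu = c(0, 0, 1), kappa = 10), class = "watson_model")
  bias <- vapply(c(250, 1000, 4000), function(n) {
    k <- vapply(1:30, function(i)
      watson_mle(sample_model(wm, n, seed = 1000 * n + i))$kappa, numeric(1))
    abs(mean(k) - 10)
  }, numeric(1))
  expect_lt(bias[3], bias[1])
})

test_that("confidence ellipses scale as 1/sqrt(N) and with concentration", {
  bm <- bingham_mle(sample_model(bingham_model(diag(3), c(0, -5, -20)),
                                 2000, seed = 12))
  ci <- confidence_ellipse(bm, alpha = 0.01)
  bm2 <- bm; bm2$n_fit <- 2L * bm$n_fit
  ci2 <- confidence_ellipse(bm2, alpha = 0.01)
  expect_equal(ci2$e2 * sqrt(2), ci$e2, tolerance = 1e-9)
  expect_equal(ci2$e3 * sqrt(2), ci$e3, tolerance = 1e-9)
  # stronger minor concentration tightens the matching semi-axis
  bm3 <- bm; bm3$kappas[3] <- 2 * bm$kappas[3]
  expect_lt(confidence_ellipse(bm3, 0.01)$e3, ci$e3)
  # degenerate spectrum is refused
  bad <- bm; bad$kappas <- c(0, 0, bm$kappas[3])
  expect_error(confidence_ellipse(bad, 0.01), "ellipse undefined")
  # containment is exact at the boundary directions
  probe <- ci$mean_axis * cos(ci$e2 * 0.99) +
    ci$semi_axis_dirs[, 1] * sin(ci$e2 * 0.99)
  expect_true(ellipse_contains(ci, probe))
  probe_out <- ci$mean_axis * cos(ci$e2 * 1.05) +
    ci$semi_axis_dirs[, 1] * sin(ci$e2 * 1.05)
  expect_false(ellipse_contains(ci, probe_out))
})

test_that("separated-cones test distinguishes identical from orthogonal axes", {
  fit_ci <- function(U, n, seed)
    confidence_ellipse(bingham_mle(
      sample_model(bingham_model(U, c(0, -10, -40)), n, seed = seed)),
      alpha = 0.005)
  a <- fit_ci(diag(3), 4000, 13)
  expect_false(groups_differ(a, a))
  Uy <- cbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
  b <- fit_ci(Uy, 4000, 14)
  expect_true(groups_differ(a, b))
  expect_error(groups_differ(a, confidence_ellipse(
    bingham_mle(sample_model(bingham_model(diag(3), c(0, -10, -40)),
                             500, seed = 15)), alpha = 0.01)),
    "alpha")
})
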