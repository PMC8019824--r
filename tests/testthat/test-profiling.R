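# small shared cohort fixtures (built once per test file)
spec40 <- bundle_spec("straight", length_mm = 40, radius_mm = 5,
                      spacing_mm = 2.2)

test_that("profiles of a clean tube have the expected slice structure", {
  coh <- make_cohort(2, spec40, kappas = c(0, -5, -40), effect = NULL,
                     seed = 1, jitter_prob = 0)
  prof <- build_profile(coh, c(1, 2))
  expect_s3_class(prof, "tract_profile")
  expect_equal(length(prof$slices), floor(prof$length_mm / 2) + 1)
  expect_true(all(vapply(prof$slices, `[[`, TRUE, "testable")))
  # slice samples are bounded by subjects x slab voxels
  for (sl in prof$slices) {
    bound <- 2 * nrow(sl$voxels)
    expect_true(all(vapply(sl$samples, nrow, 0L) <= bound))
  }
  # arc-length ordering
  s <- vapply(prof$slices, `[[`, 0, "s_mm")
  expect_true(all(diff(s) > 0))
})

test_that("an empty-mask subject contributes no axes but does not abort", {
  coh <- make_cohort(2, spec40, kappas = c(0, -5, -40), seed = 2,
                     jitter_prob = 0)
  empty <- binary_volume(array(FALSE, coh$bundle_masks[["1-2"]][[1]]$shape),
                         coh$spacing_mm)
  coh$bundle_masks[["1-2"]][[2]] <- empty
  prof <- build_profile(coh, c(1, 2))
  expect_equal(length(prof$slices), 0)  # intersection empty
  expect_match(prof$reason, "empty overlap")
  flags <- test_profile(prof)
  expect_length(flags, 0)
  expect_equal(count_clusters(flags), 0)
})

test_that("identical groups never separate; untestable slices never flag", {
  coh <- make_cohort(3, spec40, kappas = c(0, -5, -40), seed = 3,
                     jitter_prob = 0)
  # make group B's fields literally identical to group A's
  idx_a <- which(coh$group == "A")
  idx_b <- which(coh$group == "B")
  for (k in seq_along(idx_b)) {
    coh$pdd_fields[[idx_b[k]]] <- coh$pdd_fields[[idx_a[k]]]
    coh$bundle_masks[["1-2"]][[idx_b[k]]] <-
      coh$bundle_masks[["1-2"]][[idx_a[k]]]
  }
  prof <- build_profile(coh, c(1, 2))
  flags <- test_profile(prof)
  expect_true(all(flags == "not"))

  # starved slices become untestable, never significant
  prof2 <- build_profile(coh, c(1, 2), min_axes = 10000)
  flags2 <- test_profile(prof2)
  expect_true(all(flags2 == "untestable"))
  expect_equal(count_clusters(flags2), 0)
})

test_that("cluster counting equals a brute-force run-length scan", {
  expect_equal(count_clusters(rep("not", 10)), 0)
  expect_equal(count_clusters(
    c("significant", "significant", "significant", "significant", "not",
      rep("significant", 5)), n_min = 4), 2)
  # untestable breaks contiguity
  expect_equal(count_clusters(
    c(rep("significant", 3), "untestable", rep("significant", 3)),
    n_min = 4), 0)

  oracle_clusters <- function(flags, n_min) {
    run <- 0L; total <- 0L
    for (f in c(flags, "stop")) {
      if (f == "significant") run <- run + 1L
      else {
        if (run >= n_min) total <- total + 1L
        run <- 0L
      }
    }
    total
  }
  set.seed(5)
  for (i in 1:1000) {
    flags <- sample(c("significant", "not", "untestable"),
                    sample(1:40, 1), replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
    nm <- sample(2:5, 1)
    expect_identical(count_clusters(flags, nm),
                     oracle_clusters(flags, nm),
                     label = paste("case", i))
  }
})

test_that("slice significance is monotone in the error rate", {
  eff <- group_effect(10, c(10, 30), "B")
  coh <- make_cohort(6, spec40, kappas = c(0, -5, -40), effect = eff,
                     seed = 6)
  prof <- build_profile(coh, c(1, 2))
  f_strict <- test_profile(prof, alpha = 0.0005)
  f_mid <- test_profile(prof, alpha = 0.005)
  f_loose <- test_profile(prof, alpha = 0.05)
  expect_true(all(!(f_strict == "significant") | (f_mid == "significant")))
  expect_true(all(!(f_mid == "significant") | (f_loose == "significant")))
  expect_lte(count_clusters(f_strict), count_clusters(f_mid))
  expect_lte(count_clusters(f_mid), count_clusters(f_loose))
})

test_that("the difference matrix is symmetric and pinpoints the planted pair", {
  eff <- group_effect(45, c(12, 28), "B")
  coh <- make_cohort(6, spec40, kappas = c(0, -5, -40), effect = eff,
                     seed = 7)
  dm <- difference_matrix(coh)
  expect_identical(dm$weights, t(dm$weights))
  expect_true(all(diag(dm$weights) == 0))
  expect_gte(dm$weights["1", "2"], 1)
  # determinism: same cohort gives a bitwise-identical matrix
  dm2 <- difference_matrix(coh)
  expect_identical(dm$weights, dm2$weights)
})

test_that("length regression matches the closed-form OLS oracle", {
  expect_error(length_cluster_regression(rep(2, 5), c(20, 40, 60, 80, 100)),
               "zero variance")
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- length_cluster_regression(y, abs(x) + 1)
    xs <- abs(x) + 1
    zx <- (xs - mean(xs)) / sd(xs); zy <- (y - mean(y)) / sd(y)
    beta <- sum(zx * zy) / sum(zx^2)
    expect_equal(got$slope, beta, tolerance = 1e-10)
    r2 <- beta^2
    expect_equal(got$adj_r2, 1 - (1 - r2) * (n - 1) / (n - 2),
                 tolerance = 1e-10)
  }
})

test_that("aggregation modes nest and select plausible models", {
  coh <- make_cohort(3, spec40, kappas = c(0, -5, -40), seed = 9,
                     jitter_prob = 0)
  mask <- largest_component(
    intersect_subject_masks(coh$bundle_masks[["1-2"]]))
  rv <- aggregate_mode_fit(coh, mask, mode = "voxels", seed = 10)
  rs <- aggregate_mode_fit(coh, mask, mode = "skeleton", seed = 10)
  rp <- aggregate_mode_fit(coh, mask, mode = "profile", seed = 10)
  expect_lte(rs$n_axes, rv$n_axes)  # skeleton voxels are a subset
  # strongly anisotropic dispersion: structure found, Bingham preferred
  expect_false(rv$selected == "no fit")
  expect_identical(rv$selected, "Bingham")
  expect_false(rp$selected == "no fit")
  # uniform axes carry no structure
  cohu <- make_cohort(3, spec40, kappas = c(0, 0, 0), seed = 11,
                      jitter_prob = 0)
  ru <- aggregate_mode_fit(cohu, mask, mode = "voxels", seed = 12)
  expect_identical(ru$selected, "no fit")
  # tiny regions refuse to fit
  tiny <- binary_volume(array(FALSE, mask$shape), coh$spacing_mm)
  tiny$occupancy[5, 5, 5] <- TRUE
  rt <- aggregate_mode_fit(coh, tiny, mode = "voxels", seed = 13)
  expect_identical(rt$selected, "no fit")
})
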