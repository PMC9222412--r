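test_that("spec validation rejects bad weights and parameters", {
  cl <- cluster_spec(-72, -76, 5, 0.5)
  expect_error(synthetic_spec(list(cl), 0.4, n_linkages = 2, n_frames = 10),
               "sum to 1")
  expect_error(cluster_spec(-181, 0, 1, 0.1), "-180, 180")
  expect_error(cluster_spec(0, 0, -1, 0.1), "kappa")
  expect_error(cluster_spec(0, 0, 1, 1.5), "weight")
  expect_s3_class(synthetic_spec(list(cl), 0.5, 2, 10, seed = 1),
                  "synthetic_spec")
})

test_that("identical spec and seed give bit-identical series", {
  cl <- list(cluster_spec(-72, -76, 8, 0.7), cluster_spec(60, 120, 4, 0.3))
  spec <- synthetic_spec(cl, 0, n_linkages = 5, n_frames = 50, seed = 123)
  s1 <- sample_angle_series(spec)
  s2 <- sample_angle_series(spec)
  expect_identical(s1$phi, s2$phi)
  expect_identical(s1$psi, s2$psi)
})

test_that("zero-dispersion cluster collapses every sample onto its mean", {
  spec <- synthetic_spec(list(cluster_spec(-72, -76, Inf, 1)), 0,
                         n_linkages = 4, n_frames = 25, seed = 2)
  s <- sample_angle_series(spec)
  expect_true(all(s$phi == -72))
  expect_true(all(s$psi == -76))
})

test_that("empirical cluster weights match the spec within 3-sigma binomial error", {
  w1 <- 0.3
  spec <- synthetic_spec(list(cluster_spec(-90, -90, Inf, w1),
                              cluster_spec(90, 90, Inf, 1 - w1)),
                         0, n_linkages = 100, n_frames = 1000, seed = 31)
  s <- sample_angle_series(spec)
  n <- length(s$phi)
  frac <- mean(s$phi < 0)
  expect_lt(abs(frac - w1), 3 * sqrt(w1 * (1 - w1) / n))
})

test_that("von Mises deviates concentrate around the mean and wrap at +/-180", {
  set.seed(4)
  x <- rvonmises(20000, 175, 20)
  expect_true(all(x > -180 & x <= 180))
  # circular mean back near +175 despite wrapping
  rad <- x * pi / 180
  cm <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  expect_lt(abs(wrap_angle(cm - 175)), 2)
  # mass stays within a wrapped neighborhood: nothing near the antipode
  d <- abs(wrap_angle(x - 175))
  expect_lt(quantile(d, 0.999), 90)
  # both signs of the wrapped edge are populated
  expect_gt(sum(x > 170), 0)
  expect_gt(sum(x < -170), 0)
})

test_that("uniform background sampling approaches the closed-form entropy", {
  spec <- synthetic_spec(list(), uniform_background_weight = 1,
                         n_linkages = 23, n_frames = 1000, seed = 17)
  s <- sample_angle_series(spec, "one_three")
  bins <- 12L
  h <- angle_histogram2d(s, bins_per_axis = bins)
  S <- conformational_entropy(h)$S
  # plug-in estimate is biased low by ~R0 (B - 1) / (2 n); compare to the
  # bias-corrected closed form for a uniform source over all B bins
  B <- bins^2
  expected <- R0_GAS * log(B)
  bias <- R0_GAS * (B - 1) / (2 * h$n)
  expect_lt(abs(S + bias - expected), 0.05)
  # Miller-Madow estimator applies that correction internally
  S_mm <- conformational_entropy(h, miller_madow = TRUE)$S
  expect_lt(abs(S_mm - expected), 0.06)
})

test_that("two equal zero-dispersion clusters give entropy R0 ln 2", {
  spec <- synthetic_spec(list(cluster_spec(-90, -90, Inf, 0.5),
                              cluster_spec(90, 90, Inf, 0.5)),
                         0, n_linkages = 24, n_frames = 1000, seed = 8)
  s <- sample_angle_series(spec)
  S <- conformational_entropy(angle_histogram2d(s, 72))$S
  # closed form: -R0 (w1 ln w1 + w2 ln w2) at the sampled weights
  w <- mean(s$phi < 0)
  expect_equal(S, -R0_GAS * (w * log(w) + (1 - w) * log(1 - w)),
               tolerance = 1e-12)
  # and the ideal-weight value R0 ln 2 ~ 5.763 up to sampling error
  expect_equal(S, R0_GAS * log(2), tolerance = 2e-4)
})

test_that("sticky component switching preserves the marginal mixture", {
  cl <- list(cluster_spec(-90, -90, Inf, 0.25), cluster_spec(90, 90, Inf, 0.75))
  spec <- synthetic_spec(cl, 0, n_linkages = 50, n_frames = 2000,
                         seed = 21, ar1 = 0.9)
  s <- sample_angle_series(spec)
  n <- length(s$phi)
  # effective sample size shrinks by (1+ar1)/(1-ar1) under sticky switching
  ess <- n * (1 - 0.9) / (1 + 0.9)
  expect_lt(abs(mean(s$phi < 0) - 0.25), 4 * sqrt(0.25 * 0.75 / ess))
})

test_that("all-zero torsions embed as planar cis quadruples", {
  top <- build_chain("HA", 2)
  s14 <- make_series(rep(0, 2 * 3), rep(0, 2 * 3), 3, 2, "one_four")
  s13 <- make_series(rep(0, 1 * 3), rep(0, 1 * 3), 3, 1, "one_three")
  traj <- embed_torsions_as_coordinates(top, list(s14, s13))
  e14 <- extract_torsion_series(traj, top, "one_four")
  e13 <- extract_torsion_series(traj, top, "one_three")
  expect_equal(max(abs(e14$phi), abs(e14$psi)), 0, tolerance = 1e-9)
  expect_equal(max(abs(e13$phi), abs(e13$psi)), 0, tolerance = 1e-9)
})

test_that("embedding round-trips random torsions below 1e-6 degrees", {
  top <- build_chain("CS6", 3)
  set.seed(7)
  s14 <- make_series(runif(30, -179.9, 180), runif(30, -179.9, 180),
                     10, 3, "one_four")
  s13 <- make_series(runif(20, -179.9, 180), runif(20, -179.9, 180),
                     10, 2, "one_three")
  traj <- embed_torsions_as_coordinates(top, list(s14, s13))
  e14 <- extract_torsion_series(traj, top, "one_four")
  e13 <- extract_torsion_series(traj, top, "one_three")
  expect_lt(max(abs(e14$phi - s14$phi), abs(e14$psi - s14$psi)), 1e-6)
  expect_lt(max(abs(e13$phi - s13$phi), abs(e13$psi - s13$psi)), 1e-6)
})

test_that("a full-size random series embeds and extracts at study scale", {
  top <- build_chain("HA", 24)
  set.seed(12)
  nf <- 50  # frame count reduced; per-frame arithmetic is frame-independent
  s14 <- make_series(runif(24 * nf, -179.9, 180), runif(24 * nf, -179.9, 180),
                     nf, 24, "one_four")
  traj <- embed_torsions_as_coordinates(top, s14)
  expect_equal(dim(extract_torsion_series(traj, top, "one_four")$phi),
               c(nf, 24L))
  expect_equal(dim(extract_torsion_series(traj, top, "one_three")$phi),
               c(nf, 23L))
})

test_that("embedding rejects shape mismatches", {
  top <- build_chain("HA", 3)
  s_bad <- make_series(runif(10 * 2, -179, 180), runif(10 * 2, -179, 180),
                       10, 2, "one_four")  # 3 repeats need 3 columns
  expect_error(embed_torsions_as_coordinates(top, s_bad), "spec error")
})
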