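test_that("pooling combines all linkages and frames into one histogram", {
  set.seed(1)
  s <- make_series(runif(24 * 1000, -179, 180), runif(24 * 1000, -179, 180),
                   1000, 24, "one_four")
  h <- angle_histogram2d(s, 72)
  expect_equal(h$n, 24L * 1000L)
  expect_equal(sum(h$counts), h$n)
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_equal(h$p, h$counts / h$n)
})

test_that("identical samples occupy a single bin; +180 lands in the last bin", {
  s <- make_series(rep(-72, 4), rep(-76, 4), 4, 1)
  h <- angle_histogram2d(s, 72)
  expect_equal(max(h$counts), 4)
  expect_equal(sum(h$counts > 0), 1)

  s180 <- make_series(c(180, 180), c(180, -179.99), 2, 1)
  h2 <- angle_histogram2d(s180, 72)
  expect_equal(sum(h2$counts), 2)
  expect_equal(sum(h2$counts[72, ]), 2)       # +180 in last phi bin
  expect_equal(h2$counts[72, 72], 1)          # (+180, +180) in the corner
  expect_equal(h2$counts[72, 1], 1)           # psi just above -180 in first bin
})

test_that("entropy matches hand-computed and closed-form values", {
  # delta distribution
  h <- angle_histogram2d(make_series(rep(10, 5), rep(20, 5), 5, 1), 36)
  expect_equal(conformational_entropy(h)$S, 0)

  # uniform over the full 72 x 72 grid: S = R0 ln 5184
  bins <- 72L
  centers <- seq(-180 + 2.5, 180 - 2.5, by = 5)
  grid <- expand.grid(phi = centers, psi = centers)
  hu <- angle_histogram2d(phi = grid$phi, psi = grid$psi, bins_per_axis = bins)
  expect_equal(conformational_entropy(hu)$S, 8.314 * log(5184),
               tolerance = 1e-12)
  expect_equal(conformational_entropy(hu)$S, 71.13, tolerance = 1e-3)

  # counts [[2,1],[1,0]]: p = (0.5, 0.25, 0.25)
  s <- make_series(c(-90, -90, 90, -90), c(-90, -90, -90, 90), 4, 1)
  h2 <- angle_histogram2d(s, 2)
  expect_equal(sort(as.vector(h2$counts)), c(0, 1, 1, 2))
  expect_equal(conformational_entropy(h2)$S,
               -8.314 * (0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(conformational_entropy(h2)$S, 8.644, tolerance = 1e-4)
})

test_that("entropy equals the brute-force summation on small random histograms", {
  set.seed(33)
  for (bins in c(2L, 3L, 4L)) {
    for (rep in 1:10) {
      n <- sample(5:200, 1)
      s <- make_series(runif(n, -179, 180), runif(n, -179, 180), n, 1)
      h <- angle_histogram2d(s, bins)
      expect_equal(conformational_entropy(h)$S, oracle_entropy(h$counts),
                   tolerance = 1e-12)
    }
  }
})

test_that("entropy is permutation-invariant, shuffle-invariant and bounded", {
  set.seed(14)
  for (rep in 1:20) {
    n <- 500
    s <- make_series(rvonmises(n, -72, 3), rvonmises(n, -76, 3), 100, 5)
    h <- angle_histogram2d(s, 24)
    S <- conformational_entropy(h)$S
    expect_gte(S, 0)
    expect_lte(S, 8.314 * log(24^2) + 1e-12)

    # permuting histogram bins leaves S unchanged
    hp <- h
    hp$p <- matrix(sample(as.vector(h$p)), nrow(h$p), ncol(h$p))
    hp$counts <- matrix(sample(as.vector(h$counts)), nrow(h$p), ncol(h$p))
    expect_equal(conformational_entropy(hp)$S, S, tolerance = 1e-12)

    # shuffling the underlying frames leaves S unchanged exactly
    ord <- sample(nrow(s$phi))
    s2 <- torsion_series(s$phi[ord, ], s$psi[ord, ], s$angle_pair_type)
    expect_identical(conformational_entropy(angle_histogram2d(s2, 24))$S, S)
  }
})

test_that("merging two occupied bins never increases entropy", {
  set.seed(77)
  for (rep in 1:25) {
    counts <- matrix(rpois(16, 3), 4, 4)
    if (sum(counts) == 0 || sum(counts > 0) < 2) next
    occ <- which(counts > 0)
    pick <- sample(occ, 2)
    merged <- counts
    merged[pick[1]] <- merged[pick[1]] + merged[pick[2]]
    merged[pick[2]] <- 0
    expect_lte(oracle_entropy(merged), oracle_entropy(counts) + 1e-12)
  }
})

test_that("the modal bin center is recovered, with lexicographic tie-breaking", {
  # single occupied bin
  s <- make_series(rep(-72, 3), rep(-76, 3), 3, 1)
  m <- most_frequent_angles(angle_histogram2d(s, 72))
  expect_equal(unname(m), c(-72.5, -77.5))

  # two tied bins -> lexicographically smaller (phi, psi) center
  s2 <- make_series(c(-72, 61), c(-76, 64), 2, 1)
  m2 <- most_frequent_angles(angle_histogram2d(s2, 72))
  expect_equal(unname(m2), c(-72.5, -77.5))
  s3 <- make_series(c(-72, -72), c(64, -76), 2, 1)
  m3 <- most_frequent_angles(angle_histogram2d(s3, 72))
  expect_equal(unname(m3), c(-72.5, -77.5))

  # sampled single tight cluster at (-72, -76): mode within one bin width
  spec <- synthetic_spec(list(cluster_spec(-72, -76, 400, 1)), 0,
                         n_linkages = 24, n_frames = 1000, seed = 6)
  hm <- angle_histogram2d(sample_angle_series(spec), 72)
  m4 <- most_frequent_angles(hm)
  expect_lt(abs(m4["phi"] - (-72)), 5)
  expect_lt(abs(m4["psi"] - (-76)), 5)
})

test_that("region occupancy sums the right probability mass", {
  s <- make_series(rep(-72, 10), rep(-76, 10), 10, 1)
  h <- angle_histogram2d(s, 72)
  expect_equal(region_occupancy(h, c(-180, 180), c(-180, 180)), 1)
  expect_equal(region_occupancy(h, c(50, 150), c(50, 150)), 0)

  # 50/50 two-cluster data: mass near one cluster ~ 0.5 within MC error
  spec <- synthetic_spec(list(cluster_spec(-72, -76, 50, 0.5),
                              cluster_spec(100, 120, 50, 0.5)),
                         0, n_linkages = 24, n_frames = 1000, seed = 19)
  h2 <- angle_histogram2d(sample_angle_series(spec), 72)
  occ <- region_occupancy(h2, c(-130, -20), c(-130, -20))
  n <- 24 * 1000
  expect_lt(abs(occ - 0.5), 4 * sqrt(0.25 / n) + 0.01)

  expect_error(region_occupancy(h, c(10, 10), c(0, 50)), "degenerate")
  expect_error(region_occupancy(h, c(-190, 0), c(0, 50)), "degenerate")
})

test_that("histograms reject empty or out-of-range input", {
  expect_error(angle_histogram2d(phi = numeric(0), psi = numeric(0)),
               "empty")
  expect_error(angle_histogram2d(phi = 190, psi = 0, bins_per_axis = 10),
               "-180, 180")
  expect_error(angle_histogram2d(phi = 0, psi = 0, bins_per_axis = 1),
               "bins_per_axis")
})

test_that("histogram CSV export round-trips counts and edges", {
  set.seed(2)
  s <- make_series(runif(50, -179, 180), runif(50, -179, 180), 50, 1)
  h <- angle_histogram2d(s, 12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(h, f)
  back <- as.matrix(utils::read.csv(f, row.names = 1))
  expect_equal(unname(back), unname(h$counts))
  edges <- utils::read.csv(sub("\\.csv$", "_edges.csv", f))
  expect_equal(edges$phi_edge, h$phi_edges)
})
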