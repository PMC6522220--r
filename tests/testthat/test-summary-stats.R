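test_that("k-NN density matches its closed form", {
  # 6 neighbors on the unit circle plus farther points: d_6 = 1
  th <- 2 * pi * (0:5) / 6
  pts <- rbind(c(0, 0), cbind(cos(th), sin(th)), cbind(3 + cos(th), sin(th)))
  expect_equal(knn_density(pts, k = 6, focal_index = 1), 6 / pi)
  # k = 1, two points at distance 2
  expect_equal(knn_density(rbind(c(0, 0), c(2, 0)), k = 1, focal_index = 1),
               1 / (4 * pi))
  expect_error(knn_density(matrix(runif(10), 5), k = 6), "insufficient")
})

test_that("k-NN density is invariant under rigid motion", {
  set.seed(10)
  pts <- matrix(runif(60, 0, 5), ncol = 2)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(pts %*% R, 2, c(11, -3), `+`)
  expect_equal(knn_density(pts, 6), knn_density(moved, 6), tolerance = 1e-12)
})

test_that("pair correlation matches brute-force counting and is 1 under CSR", {
  set.seed(2)
  edges <- seq(0, 4, by = 0.5)
  pts <- matrix(runif(80, 0, 8), ncol = 2)
  obs <- oracle_pair_counts(pts, edges, side = 8)
  s1 <- pair_correlation(list(pts), edges, list(type = "periodic", side = 8))
  expected <- (nrow(pts) * (nrow(pts) - 1) / 2) *
    diff(wormswarm:::torus_disc_area(edges, 8)) / 64
  expect_equal(s1$value, obs / expected, tolerance = 1e-12)

  # complete spatial randomness: every bin near 1 with many points
  set.seed(3)
  frames <- replicate(8, matrix(runif(2000, 0, 8), ncol = 2), simplify = FALSE)
  s1c <- pair_correlation(frames, seq(0, 4, by = 0.25),
                          list(type = "periodic", side = 8))
  expect_true(all(abs(s1c$value - 1) < 0.1))
})

test_that("two isolated points put all S1 mass in their distance bin", {
  pts <- rbind(c(1, 1), c(1, 2.25))
  edges <- seq(0, 4, by = 0.5)
  s1 <- pair_correlation(list(pts), edges, list(type = "periodic", side = 8))
  expect_true(all(s1$value[-3] == 0))
  expect_gt(s1$value[3], 0)
})

test_that("coincident points are flagged", {
  pts <- rbind(c(1, 1), c(1, 1), c(3, 3))
  expect_warning(
    pair_correlation(list(pts), seq(0, 4, 0.5),
                     list(type = "periodic", side = 8)),
    "coincident")
})

test_that("bounded-domain S1 uses a Monte-Carlo uniform reference", {
  set.seed(5)
  pts <- matrix(runif(600, 0, 10), ncol = 2)
  s1 <- pair_correlation(list(pts), seq(0, 5, 0.5),
                         list(type = "bounded", bbox = c(0, 10, 0, 10),
                              mc_seed = 2))
  expect_true(all(abs(s1$value - 1) < 0.35))
})

test_that("single-linkage branch lengths match hand computation and the cubic oracle", {
  # 1-D points {0, 1, 3}: merges at 1 then 2
  h <- wormswarm:::single_linkage_heights(cbind(c(0, 1, 3), 0))
  expect_equal(sort(h), c(1, 2))
  # n points give n - 1 merge distances
  set.seed(6)
  pts <- matrix(runif(60, 0, 5), ncol = 2)
  expect_length(wormswarm:::single_linkage_heights(pts), 29)
  # agreement with the O(n^3) agglomeration oracle
  for (rep in 1:3) {
    pts <- matrix(runif(2 * sample(10:40, 1), 0, 6), ncol = 2)
    expect_equal(sort(wormswarm:::single_linkage_heights(pts)),
                 oracle_single_linkage(pts), tolerance = 1e-12)
  }
  # periodic metric agrees with the oracle too
  pts <- matrix(runif(50, 0, 8), ncol = 2)
  expect_equal(sort(wormswarm:::single_linkage_heights(pts, 8)),
               oracle_single_linkage(pts, 8), tolerance = 1e-12)
})

test_that("two tight clusters give one large merge distance", {
  set.seed(7)
  a <- matrix(runif(20, 0, 0.1), ncol = 2)
  b <- matrix(runif(20, 5, 5.1), ncol = 2)
  h <- wormswarm:::single_linkage_heights(rbind(a, b))
  expect_equal(sum(h > 1), 1)
  expect_gt(max(h), 4.8)
  expect_true(all(h[h < 1] <= 0.15))
})

test_that("S2 histogram is a distribution over the bins", {
  set.seed(8)
  frames <- replicate(4, matrix(runif(60, 0, 6), ncol = 2), simplify = FALSE)
  s2 <- branch_length_distribution(frames, seq(0, 8, 0.2))
  expect_equal(sum(s2$value), 1)
  expect_true(all(s2$value >= 0))
})

test_that("dispersion and kurtosis recover Gaussian and uniform moments", {
  set.seed(9)
  g <- matrix(rnorm(2 * 40000), ncol = 2)
  dk <- dispersion_and_kurtosis(list(g))
  expect_equal(dk$S3, 1, tolerance = 0.05)
  expect_equal(dk$S4, 3, tolerance = 0.05)
  u <- matrix(runif(2 * 40000, -1, 1), ncol = 2)
  dku <- dispersion_and_kurtosis(list(u))
  expect_equal(dku$S4, 1.8, tolerance = 0.03 * 1.8)
  # heavy-tailed (clustered plus outliers) exceeds uniform kurtosis
  h <- rbind(matrix(rnorm(2000, 0, 0.1), ncol = 2),
             matrix(runif(200, -3, 3), ncol = 2))
  expect_gt(dispersion_and_kurtosis(list(h))$S4, dku$S4)
})

test_that("velocity-neighbor correlation is signed and vanishes for isotropic motion", {
  # mover heading straight at a neighbor 0.6 mm away: +1 in that bin
  d <- worm_tracks(times = 0:1, x = cbind(c(0, 0.1), c(0.6, 0.6)),
                   y = cbind(c(0, 0), c(0, 0)), arena_side = 0,
                   provenance = "fixture")
  vc <- velocity_neighbor_correlation(d, seq(0, 2, 0.5))
  expect_equal(vc$value[2], 1)
  # heading directly away: -1
  d2 <- worm_tracks(times = 0:1, x = cbind(c(0, -0.1), c(0.6, 0.6)),
                    y = cbind(c(0, 0), c(0, 0)), arena_side = 0,
                    provenance = "fixture")
  expect_equal(velocity_neighbor_correlation(d2, seq(0, 2, 0.5))$value[2], -1)
  # random walkers (independent step directions), uniform positions:
  # near 0 in every well-sampled bin
  set.seed(12)
  nf <- 60; nw <- 80
  x0 <- runif(nw, 0, 20); y0 <- runif(nw, 0, 20)
  tt <- seq_len(nf)
  ph <- matrix(runif(nf * nw, 0, 2 * pi), nf, nw)
  x <- apply(0.02 * cos(ph), 2, cumsum) + matrix(x0, nf, nw, byrow = TRUE)
  y <- apply(0.02 * sin(ph), 2, cumsum) + matrix(y0, nf, nw, byrow = TRUE)
  d3 <- worm_tracks(times = tt, x = x, y = y, arena_side = 0,
                    provenance = "fixture")
  vc3 <- velocity_neighbor_correlation(d3, seq(0, 2, 0.5))
  expect_true(all(abs(vc3$value[vc3$n > 1000]) < 0.05))
})

test_that("summary sets are deterministic and order clustered above uniform", {
  cl <- generate_fixtures("clustered", seed = 31)
  un <- generate_fixtures("uniform", seed = 31)
  s_cl <- summarize_dataset(cl, sample_every = 1)
  s_un <- summarize_dataset(un, sample_every = 1)
  expect_identical(s_cl, summarize_dataset(cl, sample_every = 1))
  expect_gt(s1_small(s_cl), s1_small(s_un))
  expect_lt(s_cl$S3, s_un$S3)
})

test_that("statistics use head positions only, ignoring skeletons", {
  p <- worm_params(N = 12, M = 6, seed = 13)
  d <- run_simulation(p, 30, record_every = 2, record_skeletons = TRUE)
  d_nosk <- d
  d_nosk$skeletons <- NULL
  expect_identical(summarize_dataset(d, sample_every = 5, last_fraction = 1),
                   summarize_dataset(d_nosk, sample_every = 5, last_fraction = 1))
})
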