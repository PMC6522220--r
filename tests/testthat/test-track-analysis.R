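test_that("signed speed is positive along the skeleton and negative against it", {
  fr <- 9
  centroid <- cbind(seq(0, 0.01 * 19, by = 0.01), 0)  # mm, forward in +x
  skel <- matrix(c(1, 0), 20, 2, byrow = TRUE)
  sp <- signed_speed(centroid, skel, fr)
  expect_true(all(sp[1:18] > 0))
  # moving against the skeleton direction
  sp_back <- signed_speed(centroid[20:1, ], skel, fr)
  expect_true(all(sp_back[1:18] < 0))
  # constant velocity: smoothing leaves the series unchanged
  expect_equal(sp[2:17], rep(0.01 * fr * 1000, 16), tolerance = 1e-9)
})

test_that("missing frames are linearly interpolated before differencing", {
  centroid <- cbind(c(0, NA, NA, 0.3, 0.4), c(0, NA, NA, 0, 0))
  skel <- matrix(c(1, 0), 5, 2, byrow = TRUE)
  sp <- signed_speed(centroid, skel, 1)
  expect_true(all(is.finite(sp[1:4])))
  expect_equal(sp[2], 100, tolerance = 1e-6)  # 0.1 mm/frame at 1 Hz
})

test_that("reversal detection applies the path-length and displacement filters", {
  fx <- generate_fixtures("scripted_reversal",
                          params = list(lengths_um = c(100, 60, 55, 40)),
                          seed = 1)
  tr <- attr(fx, "truth")
  sp <- signed_speed(cbind(fx$x, fx$y), tr$skeleton, tr$frame_rate)
  ev <- detect_reversals(sp, cbind(fx$x, fx$y), tr$frame_rate)
  # the 40 um excursion fails the 50 um minimum length
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$path_length_um >= 50))
  expect_error(detect_reversals(sp, cbind(fx$x, fx$y), tr$frame_rate,
                                um_per_px = NULL), "calibration")
})

test_that("sub-threshold jitter produces no reversal events", {
  set.seed(21)
  n <- 200
  pos <- cbind(cumsum(rnorm(n, 0, 1e-4)), cumsum(rnorm(n, 0, 1e-4)))  # mm
  skel <- matrix(c(1, 0), n, 2, byrow = TRUE)
  sp <- signed_speed(pos, skel, 9)
  ev <- detect_reversals(sp, pos, 9)
  expect_equal(nrow(ev), 0)
})

test_that("reversal rates are events over forward time with bootstrap dispersion", {
  # 2 events over 100 s of forward time in one bin
  fr <- 1
  dens <- c(rep(0.5, 100), rep(5, 100))
  fwd <- rep(TRUE, 200)
  ev <- rep(FALSE, 200)
  ev[c(150, 180)] <- TRUE
  rr <- reversal_rate_by_density(dens, fwd, ev, fr, bins = c(0, 1, 10))
  expect_equal(rr$rate, c(0, 0.02))
  expect_equal(rr$n_events, c(0, 2))
  expect_equal(rr$forward_time, c(100, 100))
  # no events anywhere: all rates and bootstrap dispersion zero
  rr0 <- reversal_rate_by_density(dens, fwd, rep(FALSE, 200), fr,
                                  bins = c(0, 1, 10))
  expect_equal(rr0$rate, c(0, 0))
  expect_equal(rr0$boot_sd, c(0, 0))
})

test_that("the rate estimator recovers a linear density dependence", {
  # synthetic worm-frames with Poisson reversals at rate c * rho
  set.seed(22)
  cc <- 0.02; fr <- 2
  rho <- runif(60000, 0, 10)
  ev <- runif(60000) < (cc * rho) / fr
  bins <- seq(0, 10, by = 2)
  rr <- reversal_rate_by_density(rho, rep(TRUE, 60000), ev, fr, bins,
                                 n_boot = 100)
  mids <- (bins[-1] + bins[-length(bins)]) / 2
  inside <- abs(rr$rate - cc * mids) <= 3 * rr$boot_sd
  expect_gte(mean(inside), 0.9)
  # estimator bias below 5% overall
  expect_equal(sum(rr$n_events) / sum(rr$forward_time),
               cc * mean(rho), tolerance = 0.05)
})

test_that("speed profiles separate the fast and slow density regimes", {
  fx <- generate_fixtures("two_state_speed", seed = 23)
  tr <- attr(fx, "truth")
  nf <- nrow(fx$x)
  # per worm-frame speeds and densities
  sp <- matrix(NA_real_, nf, ncol(fx$x))
  for (w in seq_len(ncol(fx$x))) {
    dx <- diff(fx$x[, w]); dy <- diff(fx$y[, w])
    side <- fx$arena_side
    dx <- dx - side * round(dx / side); dy <- dy - side * round(dy / side)
    sp[, w] <- c(sqrt(dx^2 + dy^2) * 9 * 1000, NA)
  }
  dens <- matrix(rep(knn_density(cbind(fx$x[1, ], fx$y[1, ]), 6,
                                 arena_side = fx$arena_side), each = nf),
                 nf)
  prof <- speed_profiles_by_density(sp, dens, density_bins = c(0, 2, 100),
                                    speed_bins = seq(0, 500, 50),
                                    frame_rate = 9)
  expect_equal(unname(rowSums(prof)), c(1, 1), tolerance = 1e-9)
  # low-density worms occupy the high-speed mode and vice versa
  expect_gt(which.max(prof[1, ]), which.max(prof[2, ]))
})

test_that("cluster tracking recovers a rigid blob's speed and is translation invariant", {
  fx <- generate_fixtures("rigid_blob", params = list(speed_um_min = 150),
                          seed = 24)
  ct <- cluster_tracks(fx, sample_every = 30, smooth_window = 600)
  expect_gte(length(ct), 1)
  v <- median_cluster_speed(ct)
  expect_equal(v, 150, tolerance = 10 / 150)
  # global translation leaves the speed unchanged
  fx2 <- fx
  fx2$x <- (fx2$x + 3) %% fx2$arena_side
  fx2$y <- (fx2$y + 1) %% fx2$arena_side
  ct2 <- cluster_tracks(fx2, sample_every = 30, smooth_window = 600)
  expect_equal(median_cluster_speed(ct2), v, tolerance = 1e-6)
})

test_that("stationary blobs have near-zero speed and small blobs are excluded", {
  fx <- generate_fixtures("rigid_blob", params = list(speed_um_min = 0),
                          seed = 25)
  ct <- cluster_tracks(fx, sample_every = 30, smooth_window = 600)
  expect_lt(abs(median_cluster_speed(ct)), 1e-6)
  # a lone pair of points is below the 3-worm footprint threshold
  fx3 <- generate_fixtures("rigid_blob",
                           params = list(n_worms = 2, radius = 0.05,
                                         speed_um_min = 0), seed = 26)
  ct3 <- cluster_tracks(fx3, sample_every = 30, smooth_window = 600,
                        area_threshold = 0.5)
  expect_equal(length(ct3), 0)
})
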