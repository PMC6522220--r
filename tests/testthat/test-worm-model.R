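test_that("initialization builds N chains of M nodes with total length L", {
  p <- worm_params(N = 40, M = 18, L = 1.0, seed = 1)
  st <- initialize_state(p)
  expect_length(st$worms, 40)
  lens <- vapply(st$worms, function(w) {
    d <- diff(w$nodes)
    d <- d - p$arena_side * round(d / p$arena_side)
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
  expect_true(all(abs(lens - 1.0) < 1e-9))
  expect_true(all(vapply(st$worms, function(w)
    all(w$nodes >= 0 & w$nodes < p$arena_side), logical(1))))
})

test_that("initialization is deterministic given the seed", {
  p <- worm_params(seed = 42)
  expect_identical(initialize_state(p), initialize_state(p))
})

test_that("default geometry gives the experimental occupied-area fraction", {
  # 40 worms x 1 mm x 0.08 mm width in an 8 mm box: 5%, inside 4-6%
  p <- worm_params()
  frac <- p$N * p$L * 0.08 / p$arena_side^2
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("initialization rejects an arena smaller than a worm", {
  expect_error(worm_params(arena_side = 0.9, L = 1), "arena")
})

test_that("taxis drive sums 1/r-weighted unit vectors within the cutoff", {
  v <- taxis_drive(c(0, 0), rbind(c(0.5, 0), c(0, 0.25)), f_t = 1, cutoff = 1)
  expect_equal(v, c(2, 4))
  # beyond one worm length: no contribution
  expect_equal(taxis_drive(c(0, 0), rbind(c(1.5, 0)), 1, cutoff = 1), c(0, 0))
  expect_equal(taxis_drive(c(0, 0), rbind(c(0.5, 0)), 0, cutoff = 1), c(0, 0))
  # minimum-image convention: a neighbor across the boundary attracts
  v <- taxis_drive(c(0.1, 0), rbind(c(7.9, 0)), 1, cutoff = 1, arena_side = 8)
  expect_equal(v, c(-1 / 0.2, 0))
  expect_warning(taxis_drive(c(1, 1), rbind(c(1, 1)), 1, cutoff = 1),
                 "coincident")
})

test_that("heading is unchanged without noise or taxis, and turns to a dominant taxis vector", {
  p <- worm_params(D_theta = 0)
  w <- list(heading = 0.7)
  expect_equal(update_heading(w, c(0, 0), p), 0.7)
  # overwhelming pull due north
  expect_equal(update_heading(w, c(0, 1e6), p), pi / 2, tolerance = 1e-3)
})

test_that("heading increments have variance 2 * D_theta * dt", {
  p <- worm_params(D_theta = 0.2, dt = 0.05)
  set.seed(7)
  w <- list(heading = 0)
  inc <- replicate(10000, update_heading(w, c(0, 0), p))
  expect_equal(var(inc), 2 * 0.2 * 0.05, tolerance = 0.05)
})

test_that("body advance is follow-the-leader with conserved chain length", {
  p <- worm_params(M = 18, L = 1, dt = 0.05)
  spacing <- p$L / (p$M - 1)
  nodes <- cbind(4 - (0:17) * spacing, rep(4, 18))
  w <- list(nodes = nodes, heading = 0, reversing = FALSE)
  # zero speed: nothing moves
  expect_equal(advance_body(w, 0, p)$nodes, nodes)
  # straight worm moving along +x
  w2 <- advance_body(w, 0.35, p)
  expect_equal(w2$nodes[1, 1], 4 + 0.35 * 0.05, tolerance = 1e-9)
  d <- diff(w2$nodes)
  expect_equal(sum(sqrt(rowSums(d^2))), 1, tolerance = 0.05)
})

test_that("spring relaxation pulls a stretched segment back towards rest", {
  p <- worm_params(M = 5, L = 1, dt = 0.05)
  spacing <- p$L / 4
  nodes <- cbind(c(0, spacing, 2 * spacing, 3 * spacing, 3 * spacing + 2 * spacing),
                 rep(2, 5))
  w <- list(nodes = nodes, heading = 0, reversing = FALSE)
  out <- advance_body(w, 0, p)$nodes
  gap <- abs(out[5, 1] - out[4, 1])
  expect_lt(abs(gap - spacing), abs(2 * spacing - spacing))
})

test_that("worms wrap across the periodic boundary", {
  p <- worm_params(M = 5, L = 0.4, dt = 1, arena_side = 8)
  spacing <- 0.1
  nodes <- cbind(7.95 - (0:4) * spacing, rep(1, 5))
  w <- list(nodes = nodes, heading = 0, reversing = FALSE)
  out <- advance_body(w, 0.35, p)$nodes
  expect_true(all(out >= 0 & out < 8))
  expect_lt(out[1, 1], 1)  # reappeared near x = 0
})

test_that("zero reversal slope means no reversals regardless of contact", {
  p <- worm_params(M = 10, L = 1, r_prime = 0)
  spacing <- p$L / 9
  w <- list(nodes = cbind(4 + (0:9) * -spacing, rep(4, 10)), heading = 0,
            motility_state = "fast", reversing = FALSE, reversal_time_left = 0)
  other <- list(nodes = cbind(rep(4.05, 10), 4 + (0:9) * spacing))
  expect_true(wormswarm:::end_contacts(w, list(other), p)[["head"]])
  set.seed(1)
  for (i in 1:100)
    expect_false(reversal_update(w, list(other), rho = 10, params = p)$reversing)
})

test_that("one-end contact starts reversals at the closed-form Poisson frequency", {
  # head-only contact, r' * rho * dt = 0.2
  p <- worm_params(M = 10, L = 1, r_prime = 0.4, dt = 0.05,
                   reversal_duration_mean = 2)
  rho <- 10  # r' rho dt = 0.2
  spacing <- p$L / 9
  w <- list(nodes = cbind(4 + (0:9) * -spacing, rep(4, 10)), heading = 0,
            motility_state = "fast", reversing = FALSE, reversal_time_left = 0)
  other <- list(nodes = cbind(rep(4.05, 10), 4 + (0:9) * spacing),
                heading = 0, motility_state = "fast", reversing = FALSE,
                reversal_time_left = 0)
  ec <- wormswarm:::end_contacts(w, list(other), p)
  expect_true(ec[["head"]] && !ec[["tail"]])
  set.seed(99)
  n <- 100000
  hits <- sum(vapply(seq_len(n), function(i)
    reversal_update(w, list(other), rho, p)$reversing, logical(1)))
  expect_equal(hits / n, 1 - exp(-0.2), tolerance = 0.005 / (1 - exp(-0.2)))
})

test_that("contact at both ends (inside a cluster) never initiates a reversal", {
  p <- worm_params(M = 10, L = 1, r_prime = 5)
  spacing <- p$L / 9
  w <- list(nodes = cbind(4 + (0:9) * spacing, rep(4, 10)), heading = 0,
            motility_state = "fast", reversing = FALSE, reversal_time_left = 0)
  # a parallel worm alongside: every node within r_contact
  other <- w
  other$nodes[, 2] <- 4.05
  ec <- wormswarm:::end_contacts(w, list(other), p)
  expect_true(ec[["head"]] && ec[["tail"]])
  set.seed(3)
  for (i in 1:200)
    expect_false(reversal_update(w, list(other), rho = 50, params = p)$reversing)
})

test_that("speed switching rates follow the stated density dependence", {
  # at rho = 0 the rates are exactly (k_s0, k_f0); the exponential halves
  # k_fast when k_f' * rho = ln 2
  p <- worm_params(k_s0 = 0.3, k_f0 = 1, k_s_prime = 2, k_f_prime = log(2),
                   dt = 0.1)
  w_fast <- list(motility_state = "fast")
  w_slow <- list(motility_state = "slow")
  est <- function(w, rho, food = TRUE, n = 150000) {
    set.seed(11)
    mean(vapply(seq_len(n), function(i)
      speed_state_update(w, rho, food, p)$motility_state, character(1)) !=
        w$motility_state)
  }
  expect_equal(est(w_fast, 0), 1 - exp(-0.3 * 0.1), tolerance = 0.04)
  expect_equal(est(w_slow, 0), 1 - exp(-1 * 0.1), tolerance = 0.04)
  # k_fast = k_f0 exp(-k_f' rho) = 0.5 at rho = 1
  expect_equal(est(w_slow, 1), 1 - exp(-0.5 * 0.1), tolerance = 0.04)
  # absence of food suppresses slowing entirely
  expect_equal(est(w_fast, 5, food = FALSE), 0)
})

test_that("simulation runs are reproducible and coordinates stay wrapped", {
  p <- worm_params(N = 10, M = 8, seed = 5, D_theta = 0.2)
  d1 <- run_simulation(p, duration = 30, record_every = 1)
  d2 <- run_simulation(p, duration = 30, record_every = 1)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  expect_true(all(d1$x >= 0 & d1$x < p$arena_side))
  expect_true(all(d1$y >= 0 & d1$y < p$arena_side))
  expect_equal(ncol(d1$x), 10)
  expect_equal(d1$times, 0:30)
})

test_that("chain length is conserved within 5% at every recorded frame", {
  p <- worm_params(N = 8, M = 18, seed = 2, D_theta = 0.3,
                   r_prime = 0.3, k_s_prime = 0.05, k_f_prime = 0.3, f_t = 0.01)
  d <- run_simulation(p, duration = 60, record_every = 5,
                      record_skeletons = TRUE)
  for (f in seq_along(d$times)) {
    for (w in seq_len(p$N)) {
      sk <- d$skeletons[f, w, , ]
      dd <- diff(sk)
      dd <- dd - p$arena_side * round(dd / p$arena_side)
      len <- sum(sqrt(rowSums(dd^2)))
      expect_gte(len, 0.95 * p$L)
      expect_lte(len, 1.05 * p$L)
    }
  }
})

test_that("non-interacting walkers stay spatially uniform (S1 near 1)", {
  p <- worm_params(N = 40, r_prime = 0, k_s_prime = 0, k_f_prime = 0,
                   f_t = 0, seed = 8, D_theta = 0.2)
  d <- run_simulation(p, duration = 600, record_every = 5)
  st <- summarize_dataset(d, sample_every = 10, last_fraction = 0.5)
  mid <- (st$s1_edges[-1] + st$s1_edges[-length(st$s1_edges)]) / 2
  # average over a broad range of r to beat counting noise
  expect_equal(mean(st$s1[mid > 0.5 & mid < 4]), 1, tolerance = 0.15)
})

test_that("aggregating parameters raise small-r pair correlation over the null", {
  d_npr1 <- run_simulation(npr1_ref(seed = 21), 900, record_every = 5)
  d_null <- run_simulation(worm_params(seed = 21), 900, record_every = 5)
  s_npr1 <- summarize_dataset(d_npr1, sample_every = 15)
  s_null <- summarize_dataset(d_null, sample_every = 15)
  expect_gt(s1_small(s_npr1), s1_small(s_null))
})
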