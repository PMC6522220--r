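#' Initialize the simulation state
#'
#' Places `N` straight worm chains of `M` nodes and total length `L` at
#' uniformly random positions and orientations in the periodic square arena,
#' assigns each worm a random heading equal to its body orientation, and
#' draws the initial slow/fast motility state from its zero-density
#' stationary distribution `k_f0 / (k_f0 + k_s0)`.
#'
#' @param params a [worm_params()] object.
#' @param seed optional seed; defaults to `params$seed`.  When `NULL` the
#'   current RNG stream is used.
#' @return an object of class `worm_state`: a list with `time`, a list of
#'   `N` worm states (`nodes` an `M x 2` matrix in mm, `heading`,
#'   `motility_state`, `reversing`, `reversal_time_left`), and `params`.
#' @export
initialize_state <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "worm_params"))
  if (!is.null(seed)) set.seed(seed)
  spacing <- params$L / (params$M - 1)
  p_fast <- params$k_f0 / (params$k_f0 + params$k_s0)
  worms <- lapply(seq_len(params$N), function(i) {
    head <- stats::runif(2, 0, params$arena_side)
    th <- stats::runif(1, 0, 2 * pi)
    idx <- seq_len(params$M) - 1
    nodes <- cbind(head[1] - idx * spacing * cos(th),
                   head[2] - idx * spacing * sin(th))
    nodes <- nodes %% params$arena_side
    list(nodes = nodes, heading = th,
         motility_state = if (stats::runif(1) < p_fast) "fast" else "slow",
         reversing = FALSE, reversal_time_left = 0)
  })
  structure(list(time = 0, worms = worms, params = params),
            class = "worm_state")
}

#' Taxis drive towards neighboring worms
#'
#' Cumulative attraction towards neighbor head positions, each contribution
#' the unit vector towards the neighbor weighted by the inverse distance
#' `1/r`.  Neighbors beyond the cutoff (one worm length by default) do not
#' contribute; neighbors coincident with the head are skipped with a
#' warning.  Distances use the minimum-image convention when `arena_side`
#' is positive.
#'
#' @param head_pos length-2 position of the focal head, mm.
#' @param neighbor_heads matrix (rows = neighbors) of head positions, mm.
#' @param f_t taxis strength (dimensionless).
#' @param cutoff interaction cutoff, mm.
#' @param arena_side side of the periodic arena, mm; `0` for a
#'   non-periodic domain.
#' @return length-2 taxis vector `f_t * sum_j u_j / r_j`.
#' @export
taxis_drive <- function(head_pos, neighbor_heads, f_t, cutoff,
                        arena_side = 0) {
  stopifnot(cutoff > 0)
  neighbor_heads <- matrix(as.numeric(neighbor_heads), ncol = 2)
  v <- cpp_taxis_drive(as.numeric(head_pos), neighbor_heads,
                       f_t, cutoff, arena_side)
  if (isTRUE(attr(v, "n_skipped") > 0))
    warning("skipped ", attr(v, "n_skipped"),
            " neighbor(s) coincident with the focal head")
  as.numeric(v)
}

#' Update the head heading of one worm
#'
#' The heading turns towards the combined motile-force direction (the unit
#' persistence vector along the current heading plus the taxis vector) and
#' then receives a rotational-diffusion increment, Gaussian with variance
#' `2 * D_theta * dt`.  With `D_theta = 0` and zero taxis the heading is
#' unchanged.
#'
#' @param worm a worm state (see [initialize_state()]).
#' @param taxis_vec length-2 taxis vector from [taxis_drive()].
#' @param params a [worm_params()] object.
#' @return the new heading, rad.
#' @export
update_heading <- function(worm, taxis_vec, params) {
  h <- worm$heading
  v <- c(cos(h), sin(h)) + taxis_vec
  if (any(v != 0)) h <- atan2(v[2], v[1])
  sig <- sqrt(2 * params$D_theta * params$dt)
  if (sig > 0) h <- h + sig * stats::rnorm(1)
  h
}

#' Advance the body of one worm by one time step
#'
#' The head node advances `speed * dt` along the heading (when reversing,
#' the tail node leads, continuing backwards along the body axis); trailing
#' nodes follow their anterior neighbor; harmonic spring relaxation then
#' restores the adjacent-node spacing `L/(M-1)`.  Positions are wrapped
#' into the periodic arena.  An error is raised if relaxation leaves any
#' spacing more than 5% from rest.
#'
#' @param worm a worm state.
#' @param speed propulsion speed, mm/s.
#' @param params a [worm_params()] object.
#' @return the worm with updated `nodes`.
#' @export
advance_body <- function(worm, speed, params) {
  worm$nodes <- cpp_advance_body(worm$nodes, worm$heading, speed, params$dt,
                                 params$L / (params$M - 1),
                                 params$arena_side, isTRUE(worm$reversing), 10L)
  worm
}

end_contacts <- function(worm, others, params) {
  hn <- ceiling(0.1 * params$M)
  other_nodes <- do.call(rbind, lapply(others, `[[`, "nodes"))
  contact_at <- function(idx) {
    for (i in idx) {
      dx <- abs(other_nodes[, 1] - worm$nodes[i, 1])
      dy <- abs(other_nodes[, 2] - worm$nodes[i, 2])
      if (params$arena_side > 0) {
        dx <- pmin(dx, params$arena_side - dx)
        dy <- pmin(dy, params$arena_side - dy)
      }
      if (any(dx * dx + dy * dy <= params$r_contact^2)) return(TRUE)
    }
    FALSE
  }
  c(head = contact_at(seq_len(hn)),
    tail = contact_at(params$M - seq_len(hn) + 1))
}

#' Cluster-edge reversal update for one worm
#'
#' Contact is registered when any node of another worm lies within
#' `r_contact` of the first or last 10% of the focal worm's nodes.  If
#' exactly one end senses contact -- the signature of leaving a cluster --
#' a reversal starts with probability `1 - exp(-r_prime * rho * dt)`; at
#' zero density (or `r_prime = 0`) no reversals are initiated.  An ongoing
#' reversal swaps the propulsion direction head-to-tail and terminates
#' after an exponentially distributed duration with mean
#' `reversal_duration_mean`.
#'
#' @param worm a worm state.
#' @param others list of the other worms' states.
#' @param rho local neighbor density, mm^-2.
#' @param params a [worm_params()] object.
#' @return the worm with updated reversal state.
#' @export
reversal_update <- function(worm, others, rho, params) {
  stopifnot(rho >= 0)
  if (worm$reversing) {
    worm$reversal_time_left <- worm$reversal_time_left - params$dt
    if (worm$reversal_time_left <= 0) {
      worm$reversing <- FALSE
      b <- worm$nodes[1, ] - worm$nodes[2, ]
      if (any(b != 0)) worm$heading <- atan2(b[2], b[1])
    }
    return(worm)
  }
  ec <- end_contacts(worm, others, params)
  if (xor(ec[["head"]], ec[["tail"]]) && params$r_prime > 0 && rho > 0) {
    if (stats::runif(1) < 1 - exp(-params$r_prime * rho * params$dt)) {
      worm$reversing <- TRUE
      worm$reversal_time_left <- stats::rexp(1, 1 / params$reversal_duration_mean)
    }
  }
  worm
}

#' Stochastic switching between slow and fast crawling
#'
#' A fast worm slows with Poisson rate `k_slow = k_s0 + k_s_prime * rho`
#' (probability `1 - exp(-k_slow * dt)` per step); a slow worm speeds up
#' with rate `k_fast = k_f0 * exp(-k_f_prime * rho)`.  When food is absent
#' the slowing rate is set to zero -- worms keep (or regain) fast movement
#' on depleted patches -- while the speeding rate is unchanged.
#'
#' @param worm a worm state.
#' @param rho local neighbor density, mm^-2.
#' @param food_present logical; food at the worm's location.
#' @param params a [worm_params()] object.
#' @return the worm with updated `motility_state`.
#' @export
speed_state_update <- function(worm, rho, food_present, params) {
  stopifnot(rho >= 0)
  if (worm$motility_state == "fast") {
    k_slow <- if (food_present) params$k_s0 + params$k_s_prime * rho else 0
    if (k_slow > 0 && stats::runif(1) < 1 - exp(-k_slow * params$dt))
      worm$motility_state <- "slow"
  } else {
    k_fast <- params$k_f0 * exp(-params$k_f_prime * rho)
    if (k_fast > 0 && stats::runif(1) < 1 - exp(-k_fast * params$dt))
      worm$motility_state <- "fast"
  }
  worm
}

#' Run the agent-based aggregation/swarming simulation
#'
#' Iterates the full model: per step, local k-NN density sensing at the
#' worm head regions, neighbor taxis, heading diffusion, cluster-edge
#' reversals, slow/fast switching (suppressed slowing off food), body
#' advance with spring constraints, and (optionally) local food depletion
#' by feeding heads.  Head-region centroids -- the simulation analogue of
#' the tracked pharynx position -- are recorded every `record_every`
#' seconds.
#'
#' @param params a [worm_params()] object.
#' @param duration simulated time, s.
#' @param record_every sampling interval of recorded frames, s.
#' @param food_enabled enable the food field and its coupling to slowing.
#' @param record_skeletons also record full `M`-node skeletons.
#' @param n_food_snapshots number of evenly spaced food-grid snapshots to
#'   keep (0 for none; final grid is always returned when food is enabled).
#' @param seed RNG seed (defaults to `params$seed`); the same seed
#'   reproduces the run exactly.
#' @return a [worm_tracks] object with frame times, per-worm head-centroid
#'   coordinates, motility and reversal state per frame, and (if enabled)
#'   food grids.
#' @export
run_simulation <- function(params, duration, record_every = 1,
                           food_enabled = FALSE, record_skeletons = FALSE,
                           n_food_snapshots = 0, seed = params$seed) {
  stopifnot(inherits(params, "worm_params"),
            duration >= record_every, record_every > 0)
  if (!is.null(seed)) set.seed(seed)
  state <- initialize_state(params, seed = NULL)
  N <- params$N; M <- params$M
  X0 <- t(vapply(state$worms, function(w) w$nodes[, 1], numeric(M)))
  Y0 <- t(vapply(state$worms, function(w) w$nodes[, 2], numeric(M)))
  h0 <- vapply(state$worms, `[[`, numeric(1), "heading")
  f0 <- as.integer(vapply(state$worms, `[[`, character(1),
                          "motility_state") == "fast")
  if (food_enabled) {
    gn <- max(1L, round(params$arena_side / params$food_cell))
    food0 <- matrix(1, gn, gn)
    cell <- params$arena_side / gn
  } else {
    food0 <- matrix(0, 1, 1)
    cell <- params$food_cell
  }
  res <- cpp_run_simulation(X0, Y0, h0, f0, unclass(params), duration,
                            record_every, food_enabled, food0, cell,
                            record_skeletons, as.integer(n_food_snapshots))
  skel <- NULL
  if (record_skeletons) {
    nf <- length(res$times)
    skel <- array(c(res$skx, res$sky), dim = c(nf, M, N, 2))
    skel <- aperm(skel, c(1, 3, 2, 4))  # frames x worms x nodes x xy
  }
  worm_tracks(times = res$times, x = res$cx, y = res$cy,
              arena_side = params$arena_side, params = params,
              provenance = "simulated", seed = seed,
              state = res$state, reversing = res$reversing,
              skeletons = skel,
              food_final = res$food_final,
              food_snapshots = res$food_snapshots,
              food_snapshot_times = res$food_snapshot_times)
}
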