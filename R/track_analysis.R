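# centered moving average ignoring NA, partial windows at the edges
moving_average <- function(v, w) {
  if (w <= 1) return(v)
  n <- length(v)
  out <- numeric(n)
  half <- floor(w / 2)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i - half + w - 1)
    out[i] <- mean(v[lo:hi], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Signed crawling speed of one track
#'
#' The speed magnitude comes from the centroid displacement between
#' consecutive frames; its sign is the sign of the dot product of the
#' skeleton (head-direction) vector with the velocity, so forward crawling
#' is positive and reversing negative.  Missing frames are linearly
#' interpolated first, and the series is smoothed with a moving average
#' over half a second.
#'
#' @param centroid `F x 2` matrix of positions, mm (may contain `NA`).
#' @param skeleton `F x 2` matrix of head-direction vectors.
#' @param frame_rate frames per second.
#' @return signed speed series, um/s (length `F`; last value `NA`).
#' @export
signed_speed <- function(centroid, skeleton, frame_rate) {
  centroid <- matrix(as.numeric(centroid), ncol = 2)
  skeleton <- matrix(as.numeric(skeleton), ncol = 2)
  nf <- nrow(centroid)
  if (all(is.na(centroid[, 1]))) return(numeric(0))
  for (ax in 1:2) {
    v <- centroid[, ax]; ok <- !is.na(v)
    if (any(!ok) && sum(ok) >= 2)
      centroid[, ax] <- stats::approx(which(ok), v[ok], xout = seq_len(nf),
                                      rule = 1)$y
  }
  vel <- rbind(diff(centroid) * frame_rate * 1000, c(NA, NA))  # um/s
  sp <- sqrt(vel[, 1]^2 + vel[, 2]^2)
  sgn <- sign(rowSums(skeleton * vel))
  sgn[sgn == 0] <- 1
  moving_average(sp * sgn, max(1, round(0.5 * frame_rate)))
}

#' Detect reversal events in a signed-speed track
#'
#' Events are positive-to-negative sign changes of the signed speed.  An
#' event is kept only if the backward path length is at least
#' `min_length_um` and the mean per-frame displacement in the second
#' before and after the reversal is at least `min_disp_px_per_frame`
#' (calibrated via `um_per_px`).
#'
#' @param speed signed speed series from [signed_speed()], um/s.
#' @param positions `F x 2` matrix of positions, mm.
#' @param frame_rate frames per second.
#' @param min_length_um minimum backward path length, um.
#' @param min_disp_px_per_frame minimum mean displacement before/after,
#'   pixels per frame.
#' @param um_per_px pixel calibration, um per pixel (required).
#' @return data.frame of events: `start_frame`, `end_frame`,
#'   `path_length_um`, `pre_disp_px`, `post_disp_px`.
#' @export
detect_reversals <- function(speed, positions, frame_rate,
                             min_length_um = 50, min_disp_px_per_frame = 0.5,
                             um_per_px = 10) {
  if (is.null(um_per_px) || !is.finite(um_per_px))
    stop("missing um/pixel calibration")
  positions <- matrix(as.numeric(positions), ncol = 2)
  dxy <- diff(positions) * 1000                         # um per frame
  disp_um <- c(sqrt(rowSums(dxy^2)), NA)
  win <- max(1, round(frame_rate))
  ev <- list()
  n <- length(speed)
  t <- 1
  while (t < n) {
    nxt <- if (!is.na(speed[t]) && speed[t] > 0) {
      # next non-zero speed after t (sign changes may pass through 0)
      u <- t + 1
      while (u <= n && (is.na(speed[u]) || speed[u] == 0)) u <- u + 1
      if (u <= n && speed[u] < 0) u else 0L
    } else 0L
    if (nxt > 0) {
      e <- nxt
      while (e < n && !is.na(speed[e + 1]) && speed[e + 1] <= 0) e <- e + 1
      # forward direction just before the event
      pre_idx <- max(1, t - win + 1):t
      u_fwd <- colSums(dxy[pmin(pre_idx, n - 1), , drop = FALSE])
      u_fwd <- u_fwd / max(sqrt(sum(u_fwd^2)), 1e-12)
      # backward path: displacements opposing the forward direction inside
      # the (window-extended) event
      widx <- max(1, t - win + 1):min(n - 1, e + win)
      backward <- (dxy[widx, , drop = FALSE] %*% u_fwd) < 0
      path <- sum(disp_um[widx][backward], na.rm = TRUE)
      pre <- mean(disp_um[pre_idx], na.rm = TRUE) / um_per_px
      post <- if (e < n)
        mean(disp_um[(e + 1):min(n, e + win)], na.rm = TRUE) / um_per_px
      else NA_real_
      if (path >= min_length_um &&
          isTRUE(pre >= min_disp_px_per_frame) &&
          isTRUE(post >= min_disp_px_per_frame))
        ev[[length(ev) + 1]] <- data.frame(start_frame = nxt, end_frame = e,
                                           path_length_um = path,
                                           pre_disp_px = pre,
                                           post_disp_px = post)
      t <- e + 1
    } else t <- t + 1
  }
  if (!length(ev))
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      path_length_um = numeric(0), pre_disp_px = numeric(0),
                      post_disp_px = numeric(0)))
  do.call(rbind, ev)
}

#' Reversal rate as a function of local density
#'
#' Worm-frames are binned by their k-NN density; the rate in a bin is the
#' number of reversal events started there divided by the time spent in
#' forward motion in that bin.  Uncertainty is a subsampling bootstrap:
#' worm-frames are resampled with replacement `n_boot` times.
#'
#' @param densities per-worm-frame local densities, mm^-2.
#' @param forward logical per worm-frame: in forward motion.
#' @param event_start logical per worm-frame: a reversal event starts here.
#' @param frame_rate frames per second.
#' @param bins density bin edges, mm^-2.
#' @param n_boot bootstrap resamples.
#' @param relative normalize rates by the lowest-density bin.
#' @return data.frame per bin: `rate` (1/s), `boot_mean`, `boot_sd`,
#'   `n_events`, `forward_time`; bins without forward time are `NA`.
#' @export
reversal_rate_by_density <- function(densities, forward, event_start,
                                     frame_rate, bins, n_boot = 100,
                                     relative = FALSE) {
  stopifnot(length(densities) == length(forward),
            length(densities) == length(event_start))
  b <- findInterval(densities, bins, rightmost.closed = TRUE)
  nb <- length(bins) - 1
  rate_of <- function(idx) {
    bi <- b[idx]
    ev <- tapply(event_start[idx], factor(bi, levels = seq_len(nb)), sum)
    ft <- tapply(forward[idx], factor(bi, levels = seq_len(nb)), sum) / frame_rate
    ev[is.na(ev)] <- 0; ft[is.na(ft)] <- 0
    ifelse(ft > 0, ev / ft, NA_real_)
  }
  all_idx <- seq_along(densities)
  rate <- rate_of(all_idx)
  boot <- matrix(NA_real_, n_boot, nb)
  for (r in seq_len(n_boot))
    boot[r, ] <- rate_of(sample(all_idx, replace = TRUE))
  out <- data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1],
                    rate = as.numeric(rate),
                    boot_mean = colMeans(boot, na.rm = TRUE),
                    boot_sd = apply(boot, 2, stats::sd, na.rm = TRUE),
                    n_events = as.numeric(tapply(event_start,
                      factor(b, levels = seq_len(nb)), sum)),
                    forward_time = as.numeric(tapply(forward,
                      factor(b, levels = seq_len(nb)), sum)) / frame_rate)
  out$n_events[is.na(out$n_events)] <- 0
  out$forward_time[is.na(out$forward_time)] <- 0
  if (all(!event_start)) out$boot_sd[out$forward_time > 0] <- 0
  if (relative) {
    ref <- out$rate[which(is.finite(out$rate) & out$rate >= 0)[1]]
    out$relative_rate <- out$rate / ref
  }
  out
}

#' Speed histograms by local density
#'
#' Normalized histograms of absolute crawling speed, one per density bin,
#' after smoothing each track's speed over a one-second window.
#'
#' @param speeds `frames x worms` matrix (or vector) of absolute speeds,
#'   um/s.
#' @param densities matching local densities, mm^-2.
#' @param density_bins,speed_bins bin edges.
#' @param frame_rate frames per second; when given, speeds are smoothed
#'   over one second per worm before binning.
#' @return matrix `length(density_bins)-1` x `length(speed_bins)-1`; rows
#'   sum to 1 (all-`NA` rows mark empty density bins).
#' @export
speed_profiles_by_density <- function(speeds, densities, density_bins,
                                      speed_bins, frame_rate = NULL) {
  if (is.matrix(speeds) && !is.null(frame_rate)) {
    w <- max(1, round(frame_rate))
    speeds <- apply(speeds, 2, moving_average, w = w)
  }
  sp <- as.numeric(speeds); de <- as.numeric(densities)
  ok <- is.finite(sp) & is.finite(de)
  sp <- sp[ok]; de <- de[ok]
  db <- findInterval(de, density_bins, rightmost.closed = TRUE)
  ndb <- length(density_bins) - 1; nsb <- length(speed_bins) - 1
  out <- matrix(NA_real_, ndb, nsb)
  for (i in seq_len(ndb)) {
    s <- sp[db == i]
    s <- s[s >= min(speed_bins) & s <= max(speed_bins)]
    if (length(s))
      out[i, ] <- graphics::hist(s, breaks = speed_bins,
                                 plot = FALSE)$counts / length(s)
  }
  dimnames(out) <- list(density = paste0("[", density_bins[-length(density_bins)],
                                         ",", density_bins[-1], ")"),
                        speed = paste0("[", speed_bins[-nsb - 1], ",",
                                       speed_bins[-1], ")"))
  out
}

# 8-connected labeling of occupied cells on a (possibly periodic) grid
label_blobs <- function(occ, periodic) {
  gn <- nrow(occ); gm <- ncol(occ)
  lab <- matrix(0L, gn, gm)
  cur <- 0L
  idx <- which(occ > 0, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    if (lab[idx[s, 1], idx[s, 2]] != 0L) next
    cur <- cur + 1L
    queue <- list(idx[s, ])
    lab[idx[s, 1], idx[s, 2]] <- cur
    while (length(queue)) {
      c0 <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        i <- c0[1] + di; j <- c0[2] + dj
        if (periodic) {
          i <- ((i - 1) %% gn) + 1; j <- ((j - 1) %% gm) + 1
        } else if (i < 1 || i > gn || j < 1 || j > gm) next
        if (occ[i, j] > 0 && lab[i, j] == 0L) {
          lab[i, j] <- cur
          queue[[length(queue) + 1]] <- c(i, j)
        }
      }
    }
  }
  lab
}

# periodic-aware centroid of points on [0, side)
periodic_centroid <- function(p, side) {
  if (side <= 0) return(colMeans(p))
  vapply(1:2, function(ax) {
    th <- 2 * pi * p[, ax] / side
    (side * atan2(mean(sin(th)), mean(cos(th))) / (2 * pi)) %% side
  }, numeric(1))
}

#' Track worm clusters as super-threshold blobs
#'
#' Per sampled frame, worm positions (all skeleton nodes when available,
#' otherwise head centroids) are rasterized to an occupancy grid;
#' 8-connected blobs with area at or above the threshold are kept and
#' their centroids linked across frames by nearest centroid.  Centroid
#' positions are smoothed with a moving average over `smooth_window`
#' before differencing, giving the cluster speed in um/min.
#'
#' @param dataset a [worm_tracks] object spanning at least `smooth_window`.
#' @param sample_every sampling interval, s.
#' @param raster_cell occupancy grid resolution, mm.
#' @param area_threshold minimum blob area, mm^2; default the raster
#'   footprint of three worm lengths.
#' @param smooth_window centroid smoothing window, s.
#' @param link_max maximum centroid displacement for linking between
#'   consecutive samples, mm (scaled up proportionally across gaps).
#' @param max_gap number of consecutive samples a track may go unmatched
#'   (e.g. while a cluster transiently disperses) before it is closed.
#' @param min_blob_points,max_area generic blob pre-filter (minimum
#'   occupancy count and maximum area) for imported tracking tables.
#' @return list of cluster tracks (class `cluster_tracks`), each a
#'   data.frame with `time`, `x`, `y`, `area_mm2`, `speed_um_min`.
#' @export
cluster_tracks <- function(dataset, sample_every = 30, raster_cell = 0.1,
                           area_threshold = NULL, smooth_window = 600,
                           link_max = 1, max_gap = 4, min_blob_points = 1,
                           max_area = Inf) {
  stopifnot(inherits(dataset, "worm_tracks"))
  if (diff(range(dataset$times)) < smooth_window)
    stop("dataset shorter than the smoothing window")
  L <- if (!is.null(dataset$params)) dataset$params$L else 1
  # default: three worms' raster footprint -- ~L/raster_cell cells per worm
  # when full skeletons are rasterized, ~1 cell per worm for centroid-only
  if (is.null(area_threshold))
    area_threshold <- if (!is.null(dataset$skeletons)) 3 * L * raster_cell
      else 3 * raster_cell^2
  side <- dataset$arena_side
  periodic <- side > 0
  if (!periodic) {
    xr <- range(dataset$x, na.rm = TRUE); yr <- range(dataset$y, na.rm = TRUE)
    orig <- c(xr[1], yr[1])
    ext <- max(xr[2] - xr[1], yr[2] - yr[1]) + raster_cell
  } else { orig <- c(0, 0); ext <- side }
  gn <- ceiling(ext / raster_cell)

  sel <- which(!duplicated(floor(dataset$times / sample_every)))
  tracks <- list()       # each: times, x/y (unwrapped), x_raw/y_raw, area
  open <- integer(0)     # indices of tracks still eligible for linking
  md <- function(dv) if (periodic) dv - side * round(dv / side) else dv

  for (f in sel) {
    if (!is.null(dataset$skeletons)) {
      sk <- dataset$skeletons[f, , , , drop = FALSE]
      pts <- cbind(as.vector(sk[1, , , 1]), as.vector(sk[1, , , 2]))
    } else pts <- frame_positions(dataset, f)
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (!nrow(pts)) next
    ci <- floor((pts[, 1] - orig[1]) / raster_cell) + 1
    cj <- floor((pts[, 2] - orig[2]) / raster_cell) + 1
    ci <- pmin(pmax(ci, 1), gn); cj <- pmin(pmax(cj, 1), gn)
    occ <- matrix(0L, gn, gn)
    for (s in seq_along(ci)) occ[ci[s], cj[s]] <- occ[ci[s], cj[s]] + 1L
    lab <- label_blobs(occ, periodic)
    nblob <- max(lab)
    if (nblob == 0) next
    cent <- list(); areas <- numeric(0)
    for (bl in seq_len(nblob)) {
      cells <- lab == bl
      area <- sum(cells) * raster_cell^2
      npts <- sum(occ[cells])
      if (area < area_threshold || area > max_area ||
          npts < min_blob_points) next
      member <- lab[cbind(ci, cj)] == bl
      cent[[length(cent) + 1]] <- periodic_centroid(
        pts[member, , drop = FALSE], side)
      areas <- c(areas, area)
    }
    if (!length(cent)) next
    cent <- do.call(rbind, cent)
    tnow <- dataset$times[f]
    # prune tracks that have gone unmatched too long
    if (length(open)) {
      last_t <- vapply(open, function(ti)
        tracks[[ti]]$times[length(tracks[[ti]]$times)], 0)
      open <- open[tnow - last_t <= max_gap * sample_every]
    }
    # link blobs to open tracks: globally nearest pairs first, with the
    # linking radius scaled by the elapsed time
    nb2 <- nrow(cent); na2 <- length(open)
    assigned <- integer(nb2)
    if (na2 > 0) {
      dmat <- matrix(Inf, nb2, na2)
      lim <- numeric(na2)
      for (a in seq_len(na2)) {
        tr <- tracks[[open[a]]]
        lim[a] <- link_max *
          max(1, round((tnow - tr$times[length(tr$times)]) / sample_every))
        for (bl in seq_len(nb2)) {
          dx <- md(cent[bl, 1] - tr$x_raw[length(tr$x_raw)])
          dy <- md(cent[bl, 2] - tr$y_raw[length(tr$y_raw)])
          d <- sqrt(dx^2 + dy^2)
          dmat[bl, a] <- if (d <= lim[a]) d else Inf
        }
      }
      while (any(is.finite(dmat))) {
        m <- which.min(dmat)
        bl <- (m - 1) %% nb2 + 1; a <- (m - 1) %/% nb2 + 1
        assigned[bl] <- open[a]
        dmat[bl, ] <- Inf; dmat[, a] <- Inf
      }
    }
    for (bl in seq_len(nb2)) {
      if (assigned[bl] > 0) {
        ti <- assigned[bl]
        tr <- tracks[[ti]]
        dx <- md(cent[bl, 1] - tr$x_raw[length(tr$x_raw)])
        dy <- md(cent[bl, 2] - tr$y_raw[length(tr$y_raw)])
        tracks[[ti]]$x <- c(tr$x, tr$x[length(tr$x)] + dx)
        tracks[[ti]]$y <- c(tr$y, tr$y[length(tr$y)] + dy)
        tracks[[ti]]$x_raw <- c(tr$x_raw, cent[bl, 1])
        tracks[[ti]]$y_raw <- c(tr$y_raw, cent[bl, 2])
        tracks[[ti]]$times <- c(tr$times, tnow)
        tracks[[ti]]$area <- c(tr$area, areas[bl])
      } else {
        tracks[[length(tracks) + 1]] <-
          list(times = tnow, x = cent[bl, 1], y = cent[bl, 2],
               x_raw = cent[bl, 1], y_raw = cent[bl, 2], area = areas[bl])
        assigned[bl] <- length(tracks)
      }
    }
    open <- unique(c(assigned, open))
  }

  out <- lapply(tracks, function(tr) {
    nfr <- length(tr$times)
    w <- max(1, round(smooth_window / sample_every))
    xs <- moving_average(tr$x, w); ys <- moving_average(tr$y, w)
    sp <- c(NA, sqrt(diff(xs)^2 + diff(ys)^2) / diff(tr$times)) * 1000 * 60
    data.frame(time = tr$times, x = tr$x_raw, y = tr$y_raw,
               area_mm2 = tr$area, speed_um_min = sp)
  })
  structure(out, class = "cluster_tracks")
}

#' @export
print.cluster_tracks <- function(x, ...) {
  cat(sprintf("%d cluster track(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  track %d: %d samples, median speed %.0f um/min, mean area %.2f mm^2\n",
                i, nrow(x[[i]]), stats::median(x[[i]]$speed_um_min, na.rm = TRUE),
                mean(x[[i]]$area_mm2)))
  invisible(x)
}

#' Median smoothed speed of the dominant cluster
#'
#' Convenience readout: the median smoothed centroid speed of the longest
#' cluster track (um/min), the quantity compared against the
#' experimentally derived swarming speed.
#'
#' @param ct a [cluster_tracks()] result.
#' @return median speed, um/min (NA if no tracks).
#' @export
median_cluster_speed <- function(ct) {
  if (!length(ct)) return(NA_real_)
  main <- ct[[which.max(vapply(ct, nrow, 0L))]]
  stats::median(main$speed_um_min, na.rm = TRUE)
}
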