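#' Trajectory dataset container
#'
#' Frames-by-worms table of 2-D head positions (mm) with frame times,
#' arena metadata and provenance.  Missing observations are `NA`.
#' Simulated datasets additionally carry per-frame motility/reversal
#' states, optional skeletons (`frames x worms x nodes x 2`) and food
#' grids.
#'
#' @param times numeric vector of frame times, s (strictly increasing).
#' @param x,y numeric `frames x worms` matrices of coordinates, mm.
#' @param arena_side side of the periodic arena, mm; `0` marks a bounded,
#'   non-periodic domain (experimental-style data).
#' @param params optional [worm_params()] used to generate the data.
#' @param provenance one of `"simulated"`, `"fixture"`, `"imported"`.
#' @param seed RNG seed used, if any.
#' @param state,reversing optional integer matrices (1 = fast / reversing).
#' @param skeletons optional 4-d array of node positions.
#' @param food_final,food_snapshots,food_snapshot_times optional food grids.
#' @return an object of class `worm_tracks`.
#' @export
worm_tracks <- function(times, x, y, arena_side = 0, params = NULL,
                        provenance = c("simulated", "fixture", "imported"),
                        seed = NULL, state = NULL, reversing = NULL,
                        skeletons = NULL, food_final = NULL,
                        food_snapshots = NULL, food_snapshot_times = NULL) {
  provenance <- match.arg(provenance)
  x <- as.matrix(x); y <- as.matrix(y)
  if (length(times) != nrow(x) || !identical(dim(x), dim(y)))
    stop("times, x and y have inconsistent dimensions")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(times = as.numeric(times), x = x, y = y,
                 arena_side = arena_side, params = params,
                 provenance = provenance, seed = seed,
                 state = state, reversing = reversing,
                 skeletons = skeletons, food_final = food_final,
                 food_snapshots = food_snapshots,
                 food_snapshot_times = food_snapshot_times),
            class = "worm_tracks")
}

#' @export
print.worm_tracks <- function(x, ...) {
  cat(sprintf("worm_tracks: %d frames x %d worms (%s), %.1f s at %.3g s/frame\n",
              nrow(x$x), ncol(x$x), x$provenance,
              diff(range(x$times)), frame_interval(x)))
  if (x$arena_side > 0)
    cat(sprintf("  periodic arena %g mm\n", x$arena_side))
  invisible(x)
}

#' @export
plot.worm_tracks <- function(x, frame = nrow(x$x), ...) {
  lim <- if (x$arena_side > 0) c(0, x$arena_side) else
    range(c(x$x, x$y), na.rm = TRUE)
  graphics::plot(x$x[frame, ], x$y[frame, ], xlim = lim, ylim = lim,
                 asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("t = %.0f s", x$times[frame]), ...)
  invisible(x)
}

n_frames <- function(d) nrow(d$x)
n_worms <- function(d) ncol(d$x)
frame_interval <- function(d) stats::median(diff(d$times))

# positions of one frame as an n x 2 matrix, NA rows dropped
frame_positions <- function(d, frame) {
  p <- cbind(d$x[frame, ], d$y[frame, ])
  p[stats::complete.cases(p), , drop = FALSE]
}

#' Write / read trajectory datasets
#'
#' Flat CSV with columns `frame, time, worm, x, y` plus a JSON sidecar
#' (`<path>.json`) holding arena metadata, provenance, seed and the
#' generating parameters.  A write-then-read round trip reproduces the
#' dataset to within float formatting.
#'
#' @param dataset a [worm_tracks] object.
#' @param path CSV file path.
#' @return `write_trajectories` returns `path` invisibly.
#' @export
write_trajectories <- function(dataset, path) {
  stopifnot(inherits(dataset, "worm_tracks"))
  nf <- n_frames(dataset); nw <- n_worms(dataset)
  df <- data.frame(frame = rep(seq_len(nf), nw),
                   time = rep(dataset$times, nw),
                   worm = rep(seq_len(nw), each = nf),
                   x = as.vector(dataset$x), y = as.vector(dataset$y))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(arena_side = dataset$arena_side,
               provenance = dataset$provenance,
               seed = dataset$seed,
               params = if (!is.null(dataset$params)) unclass(dataset$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectories
#' @param interpolate_missing linearly interpolate interior missing frames
#'   per worm on read.
#' @export
read_trajectories <- function(path, interpolate_missing = FALSE) {
  df <- utils::read.csv(path)
  need <- c("frame", "time", "worm", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trajectory CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  frames <- sort(unique(df$frame))
  worms <- sort(unique(df$worm))
  nf <- length(frames); nw <- length(worms)
  x <- matrix(NA_real_, nf, nw); y <- matrix(NA_real_, nf, nw)
  fi <- match(df$frame, frames); wi <- match(df$worm, worms)
  x[cbind(fi, wi)] <- df$x
  y[cbind(fi, wi)] <- df$y
  times <- df$time[match(frames, df$frame)]
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  params <- if (!is.null(meta$params)) {
    p <- lapply(meta$params, function(v) if (is.null(v)) NULL else unlist(v))
    structure(p, class = "worm_params")
  }
  d <- worm_tracks(times, x, y,
                   arena_side = if (!is.null(meta$arena_side))
                     meta$arena_side else 0,
                   params = params, provenance = "imported",
                   seed = if (!is.null(meta$seed)) meta$seed)
  if (interpolate_missing) d <- interpolate_tracks(d)
  d
}

#' Linearly interpolate interior missing frames per worm
#'
#' @param dataset a [worm_tracks] object.
#' @return the dataset with interior `NA` runs filled linearly in time.
#' @export
interpolate_tracks <- function(dataset) {
  for (w in seq_len(n_worms(dataset))) {
    for (ax in c("x", "y")) {
      v <- dataset[[ax]][, w]
      ok <- !is.na(v)
      if (sum(ok) >= 2 && any(!ok))
        dataset[[ax]][, w] <- stats::approx(dataset$times[ok], v[ok],
                                            xout = dataset$times,
                                            rule = 1)$y
    }
  }
  dataset
}

#' Generate synthetic trajectory fixtures
#'
#' Deterministic (seeded) datasets emulating the statistical structure the
#' analyses assume, each carrying its ground truth in `attr(, "truth")`:
#'
#' * `uniform` -- independent uniform positions per frame (complete spatial
#'   randomness in a periodic box).
#' * `clustered` -- Gaussian clusters around random centers.
#' * `scripted_reversal` -- one worm crawling along +x with scripted
#'   backward excursions of given lengths; truth holds the skeleton
#'   vectors, the frame rate and the number of excursions at or above a
#'   given length.
#' * `rigid_blob` -- a disc of worms translating rigidly at a known speed
#'   (truth `speed_um_min`), plus optional far-away stragglers.
#' * `two_state_speed` -- a dense slow-moving group and sparse fast movers,
#'   mimicking density-dependent speed switching.
#'
#' @param kind fixture kind.
#' @param params named list of kind-specific settings (all have defaults).
#' @param seed RNG seed.
#' @return a [worm_tracks] object with a `truth` attribute.
#' @export
generate_fixtures <- function(kind = c("uniform", "clustered",
                                       "scripted_reversal", "rigid_blob",
                                       "two_state_speed"),
                              params = list(), seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  p <- function(nm, default) if (!is.null(params[[nm]])) params[[nm]] else default
  out <- switch(kind,
    uniform = {
      n <- p("n", 40); nf <- p("n_frames", 10); side <- p("arena_side", 8)
      x <- matrix(stats::runif(nf * n, 0, side), nf, n)
      y <- matrix(stats::runif(nf * n, 0, side), nf, n)
      d <- worm_tracks(seq_len(nf) - 1, x, y, arena_side = side,
                       provenance = "fixture", seed = seed)
      attr(d, "truth") <- list(csr = TRUE)
      d
    },
    clustered = {
      n <- p("n", 40); nf <- p("n_frames", 10); side <- p("arena_side", 8)
      ncl <- p("n_clusters", 2); sd_cl <- p("cluster_sd", 0.25)
      centers <- matrix(stats::runif(2 * ncl, 0.2 * side, 0.8 * side), ncl)
      assign_cl <- sample(ncl, n, replace = TRUE)
      x <- matrix(0, nf, n); y <- matrix(0, nf, n)
      for (f in seq_len(nf)) {
        x[f, ] <- (centers[assign_cl, 1] + stats::rnorm(n, 0, sd_cl)) %% side
        y[f, ] <- (centers[assign_cl, 2] + stats::rnorm(n, 0, sd_cl)) %% side
      }
      d <- worm_tracks(seq_len(nf) - 1, x, y, arena_side = side,
                       provenance = "fixture", seed = seed)
      attr(d, "truth") <- list(n_clusters = ncl, cluster_sd = sd_cl,
                               centers = centers)
      d
    },
    scripted_reversal = {
      lengths_um <- p("lengths_um", c(100, 60, 55))
      fr <- p("frame_rate", 9)
      speed <- p("speed_um_s", 100)   # crawl speed during segments
      fwd <- p("forward_um", 300)
      step <- speed / fr              # um per frame
      segs <- c(fwd, as.vector(rbind(lengths_um, fwd)))
      dirs <- c(1, as.vector(rbind(rep(-1, length(lengths_um)),
                                   rep(1, length(lengths_um)))))
      pos <- 0
      for (s in seq_along(segs)) {
        nfr <- max(2, round(segs[s] / step))
        pos <- c(pos, pos[length(pos)] + dirs[s] * seq_len(nfr) * segs[s] / nfr)
      }
      nf <- length(pos)
      x <- matrix(pos / 1000, nf, 1)          # mm
      y <- matrix(0, nf, 1)
      d <- worm_tracks((seq_len(nf) - 1) / fr, x, y, arena_side = 0,
                       provenance = "fixture", seed = seed)
      attr(d, "truth") <- list(lengths_um = lengths_um, frame_rate = fr,
                               skeleton = matrix(c(1, 0), nf, 2, byrow = TRUE),
                               n_events_50um = sum(lengths_um >= 50))
      d
    },
    rigid_blob = {
      nw <- p("n_worms", 40); radius <- p("radius", 0.35)
      v <- p("speed_um_min", 150); dur <- p("duration", 2400)
      dt <- p("frame_dt", 30); side <- p("arena_side", 20)
      th <- p("direction", pi / 7)
      rr <- radius * sqrt(stats::runif(nw)); ang <- stats::runif(nw, 0, 2 * pi)
      bx <- rr * cos(ang) + side / 2; by <- rr * sin(ang) + side / 2
      times <- seq(0, dur, by = dt)
      disp <- (v / 1000 / 60) * times          # mm
      x <- outer(disp * cos(th), bx, `+`)
      y <- outer(disp * sin(th), by, `+`)
      d <- worm_tracks(times, x %% side, y %% side, arena_side = side,
                       provenance = "fixture", seed = seed)
      attr(d, "truth") <- list(speed_um_min = v, n_worms = nw,
                               radius = radius)
      d
    },
    two_state_speed = {
      n_slow <- p("n_slow", 20); n_fast <- p("n_fast", 10)
      v_slow <- p("v_slow_um_s", 35); v_fast <- p("v_fast_um_s", 350)
      fr <- p("frame_rate", 9); dur <- p("duration", 60)
      side <- p("arena_side", 10)
      times <- seq(0, dur, by = 1 / fr); nf <- length(times)
      n <- n_slow + n_fast
      # dense cluster of slow worms, sparse fast worms
      x0 <- c(side / 2 + stats::rnorm(n_slow, 0, 0.25),
              stats::runif(n_fast, 0, side))
      y0 <- c(side / 2 + stats::rnorm(n_slow, 0, 0.25),
              stats::runif(n_fast, 0, side))
      sp <- c(rep(v_slow, n_slow), rep(v_fast, n_fast)) / 1000  # mm/s
      hd <- stats::runif(n, 0, 2 * pi)
      x <- (outer(times, sp * cos(hd)) + rep(x0, each = nf)) %% side
      y <- (outer(times, sp * sin(hd)) + rep(y0, each = nf)) %% side
      d <- worm_tracks(times, x, y, arena_side = side,
                       provenance = "fixture", seed = seed)
      attr(d, "truth") <- list(v_slow_um_s = v_slow, v_fast_um_s = v_fast,
                               slow_ids = seq_len(n_slow),
                               fast_ids = n_slow + seq_len(n_fast))
      d
    })
  out
}
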