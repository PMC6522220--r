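#' k-nearest-neighbor local density
#'
#' The areal density around a point is `k` divided by the area of the
#' circle through its `k`-th nearest neighbor, `k / (pi * d_k^2)`, with
#' the focal point excluded.  `k = 6` (about the square root of the worm
#' count) is the convention used throughout the package.
#'
#' @param points `n x 2` matrix of positions, mm.
#' @param k neighbor count.
#' @param focal_index index of the focal point; `NULL` returns densities
#'   for all points.
#' @param arena_side periodic arena side (0 = plain Euclidean distances).
#' @return density (mm^-2), scalar or length-`n` vector.
#' @export
knn_density <- function(points, k = 6, focal_index = NULL, arena_side = 0) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < k + 1)
    stop("insufficient data: k-NN density needs at least k+1 = ", k + 1,
         " points, got ", nrow(points))
  rho <- cpp_knn_density_all(points, as.integer(k), arena_side)
  if (is.null(focal_index)) rho else rho[focal_index]
}

# area of a minimum-image disc of radius r on an L x L torus
torus_disc_area <- function(r, L) {
  a <- pi * r^2
  over <- r > L / 2
  if (any(over)) {
    ro <- pmin(r[over], L / sqrt(2))
    a[over] <- pi * ro^2 -
      4 * (ro^2 * acos(L / (2 * ro)) - (L / 2) * sqrt(ro^2 - L^2 / 4))
  }
  pmin(a, L^2)
}

as_frame_list <- function(frames) {
  if (inherits(frames, "worm_tracks"))
    frames <- lapply(seq_len(n_frames(frames)),
                     function(f) frame_positions(frames, f))
  if (is.matrix(frames)) frames <- list(frames)
  lapply(frames, function(p) matrix(as.numeric(p), ncol = 2))
}

#' Pair-correlation function (S1)
#'
#' Counts neighbor pairs at distance `r`, normalized per bin by the
#' expected count for the same number of points distributed uniformly in
#' the same domain, averaged over frames.  For a periodic square domain
#' the expectation is analytic (minimum-image disc areas on the torus);
#' for bounded domains it is estimated from a seeded Monte-Carlo uniform
#' reference.
#'
#' @param frames a [worm_tracks] object, a list of `n x 2` position
#'   matrices, or a single matrix.
#' @param bin_edges distance bin edges, mm.
#' @param domain `list(type = "periodic", side = L)` or
#'   `list(type = "bounded", bbox = c(xmin, xmax, ymin, ymax))` with
#'   optional `mc_points` (default 10000) and `mc_seed` (default 1).
#' @return list with bin midpoints `r`, values `value`, and `edges`.
#' @export
pair_correlation <- function(frames, bin_edges = seq(0, 8, by = 0.1),
                             domain = list(type = "periodic", side = 8)) {
  frames <- as_frame_list(frames)
  nb <- length(bin_edges) - 1
  if (domain$type == "periodic") {
    side <- domain$side
    area <- torus_disc_area(bin_edges, side)
    p_bin <- diff(area) / side^2
  } else {
    bbox <- domain$bbox
    mc_n <- if (!is.null(domain$mc_points)) domain$mc_points else 10000
    mc_seed <- if (!is.null(domain$mc_seed)) domain$mc_seed else 1
    p_bin <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(mc_seed)
      pts <- cbind(stats::runif(mc_n, bbox[1], bbox[2]),
                   stats::runif(mc_n, bbox[3], bbox[4]))
      n_pairs <- min(2e6, mc_n * (mc_n - 1) / 2)
      i <- sample.int(mc_n, n_pairs, replace = TRUE)
      j <- sample.int(mc_n, n_pairs, replace = TRUE)
      keep <- i != j
      dmc <- sqrt((pts[i[keep], 1] - pts[j[keep], 1])^2 +
                  (pts[i[keep], 2] - pts[j[keep], 2])^2)
      graphics::hist(dmc[dmc <= max(bin_edges)], breaks = bin_edges,
                     plot = FALSE)$counts / length(dmc)
    })
    side <- 0
  }
  acc <- matrix(0, 0, nb)
  for (pts in frames) {
    n <- nrow(pts)
    if (n < 2) { warning("skipping frame with fewer than 2 points"); next }
    d <- cpp_pairwise_dist(pts, if (domain$type == "periodic") side else 0)
    if (any(d == 0)) warning("coincident points: small-r bins may diverge")
    obs <- graphics::hist(d[d <= max(bin_edges) & d >= min(bin_edges)],
                          breaks = bin_edges, plot = FALSE)$counts
    expd <- (n * (n - 1) / 2) * p_bin
    acc <- rbind(acc, ifelse(expd > 0, obs / expd, NA_real_))
  }
  if (nrow(acc) == 0) stop("no usable frames")
  list(r = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
       value = colMeans(acc), edges = bin_edges)
}

single_linkage_heights <- function(pts, arena_side = 0) {
  n <- nrow(pts)
  d <- cpp_pairwise_dist(pts, arena_side)
  dd <- structure(d, Size = n, class = "dist", Diag = FALSE, Upper = FALSE)
  stats::hclust(dd, method = "single")$height
}

#' Single-linkage branch-length distribution (S2)
#'
#' For each frame, the `n - 1` merge distances of agglomerative
#' hierarchical clustering with single linkage (the branch lengths of the
#' dendrogram), pooled over frames and returned as a relative-frequency
#' histogram over the given bins.
#'
#' @inheritParams pair_correlation
#' @param arena_side periodic side for minimum-image distances (0 = plain).
#' @return list with bin midpoints `r`, probabilities `value` (summing to
#'   1 over the bins), `edges`, and the pooled `heights`.
#' @export
branch_length_distribution <- function(frames, bin_edges = seq(0, 8, by = 0.2),
                                       arena_side = 0) {
  frames <- as_frame_list(frames)
  heights <- numeric(0)
  for (pts in frames) {
    if (nrow(pts) < 2) { warning("skipping single-point frame"); next }
    heights <- c(heights, single_linkage_heights(pts, arena_side))
  }
  if (!length(heights)) stop("no usable frames")
  counts <- graphics::hist(heights[heights <= max(bin_edges) &
                                     heights >= min(bin_edges)],
                           breaks = bin_edges, plot = FALSE)$counts
  if (sum(counts) == 0) stop("all merge distances fall outside the bins")
  list(r = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
       value = counts / sum(counts), edges = bin_edges, heights = heights)
}

axis_kurtosis <- function(v) {
  m <- mean(v); s2 <- mean((v - m)^2)
  mean((v - m)^4) / s2^2
}

#' Positional dispersion (S3) and kurtosis (S4)
#'
#' Per frame, the standard deviation and the (Pearson, non-excess)
#' kurtosis of the positions are computed per axis and averaged over the
#' two axes; S3 and S4 are the means over frames.  A Gaussian point cloud
#' gives S4 = 3, a uniform one 1.8; heavy-tailed (clustered) spatial
#' distributions give larger values.
#'
#' @inheritParams pair_correlation
#' @return list with scalars `S3` (mm) and `S4`, plus per-frame values.
#' @export
dispersion_and_kurtosis <- function(frames) {
  frames <- as_frame_list(frames)
  s3 <- s4 <- numeric(0)
  for (pts in frames) {
    if (nrow(pts) < 2) { warning("skipping frame with fewer than 2 points"); next }
    sds <- c(stats::sd(pts[, 1]), stats::sd(pts[, 2]))
    if (any(sds == 0)) { warning("skipping degenerate frame"); next }
    s3 <- c(s3, mean(sds))
    s4 <- c(s4, mean(c(axis_kurtosis(pts[, 1]), axis_kurtosis(pts[, 2]))))
  }
  if (!length(s3)) stop("no usable frames")
  list(S3 = mean(s3), S4 = mean(s4), per_frame_sd = s3, per_frame_kurt = s4)
}

#' Correlation between velocity and the direction towards neighbors
#'
#' For every worm-frame with non-zero velocity (finite-difference between
#' consecutive frames) and every neighbor, the cosine of the angle between
#' the velocity and the unit vector towards the neighbor is accumulated in
#' the distance bin of that neighbor.  Values near zero at all distances
#' indicate no detectable directed movement towards neighbors.
#'
#' @param dataset a [worm_tracks] object with at least 2 frames.
#' @param distance_bins bin edges, mm.
#' @return list with bin midpoints `r`, mean cosine `value`, and per-bin
#'   sample counts `n`.
#' @export
velocity_neighbor_correlation <- function(dataset,
                                          distance_bins = seq(0, 2, by = 0.25)) {
  stopifnot(inherits(dataset, "worm_tracks"), n_frames(dataset) >= 2)
  side <- dataset$arena_side
  nb <- length(distance_bins) - 1
  sums <- counts <- numeric(nb)
  md <- function(dv) if (side > 0) dv - side * round(dv / side) else dv
  for (f in seq_len(n_frames(dataset) - 1)) {
    vx <- md(dataset$x[f + 1, ] - dataset$x[f, ])
    vy <- md(dataset$y[f + 1, ] - dataset$y[f, ])
    for (i in seq_len(n_worms(dataset))) {
      sp <- sqrt(vx[i]^2 + vy[i]^2)
      if (!is.finite(sp) || sp == 0) next
      dx <- md(dataset$x[f, ] - dataset$x[f, i])
      dy <- md(dataset$y[f, ] - dataset$y[f, i])
      r <- sqrt(dx^2 + dy^2)
      ok <- which(r > 0 & is.finite(r))
      if (!length(ok)) next
      cosang <- (vx[i] * dx[ok] + vy[i] * dy[ok]) / (sp * r[ok])
      b <- findInterval(r[ok], distance_bins, rightmost.closed = TRUE)
      use <- b >= 1 & b <= nb
      for (k in which(use)) {
        sums[b[k]] <- sums[b[k]] + cosang[k]
        counts[b[k]] <- counts[b[k]] + 1
      }
    }
  }
  list(r = (distance_bins[-1] + distance_bins[-length(distance_bins)]) / 2,
       value = ifelse(counts > 0, sums / counts, NA_real_), n = counts)
}

#' Summary statistic set of a trajectory dataset
#'
#' Samples frames (for simulated data, evenly from the final fraction of
#' the run; for fixtures/imports, evenly across the whole recording, by
#' default one frame per 30 s) and computes the four spatial summary
#' statistics from head positions only: S1 pair correlation, S2
#' single-linkage branch-length distribution, S3 positional dispersion
#' and S4 positional kurtosis.
#'
#' @param dataset a [worm_tracks] object.
#' @param s1_edges,s2_edges distance bin edges, mm.
#' @param sample_every frame sampling interval, s.
#' @param last_fraction fraction of the run to sample from (default 0.1
#'   for simulated datasets, 1 otherwise).
#' @return an object of class `worm_sumstats`.
#' @export
summarize_dataset <- function(dataset,
                              s1_edges = seq(0, 8, by = 0.1),
                              s2_edges = seq(0, 8, by = 0.2),
                              sample_every = 30,
                              last_fraction = if (identical(dataset$provenance,
                                                            "simulated")) 0.1 else 1) {
  stopifnot(inherits(dataset, "worm_tracks"))
  tmax <- max(dataset$times)
  t0 <- tmax - last_fraction * diff(range(dataset$times))
  cand <- which(dataset$times >= t0)
  sel <- cand[c(TRUE, diff(dataset$times[cand]) >= 0) &
                !duplicated(floor((dataset$times[cand] - t0) / sample_every))]
  if (!length(sel)) sel <- cand[length(cand)]
  frames <- lapply(sel, function(f) frame_positions(dataset, f))
  frames <- frames[vapply(frames, nrow, 0L) >= 2]
  if (!length(frames)) stop("no frames with at least 2 tracked positions")
  domain <- if (dataset$arena_side > 0)
    list(type = "periodic", side = dataset$arena_side)
  else {
    all_x <- range(dataset$x, na.rm = TRUE); all_y <- range(dataset$y, na.rm = TRUE)
    list(type = "bounded", bbox = c(all_x, all_y))
  }
  s1 <- pair_correlation(frames, s1_edges, domain)
  s2 <- branch_length_distribution(frames, s2_edges,
                                   arena_side = max(dataset$arena_side, 0))
  dk <- dispersion_and_kurtosis(frames)
  structure(list(s1 = s1$value, s1_edges = s1_edges,
                 s2 = s2$value, s2_edges = s2_edges,
                 S3 = dk$S3, S4 = dk$S4,
                 frames_used = dataset$times[sel],
                 domain = domain),
            class = "worm_sumstats")
}

#' @export
print.worm_sumstats <- function(x, ...) {
  small <- x$s1_edges[-1] <= 0.5
  cat("Spatial summary statistics\n")
  cat(sprintf("  S1 (pair correlation): mean %.2f at r < 0.5 mm\n",
              mean(x$s1[small], na.rm = TRUE)))
  cat(sprintf("  S2 (branch lengths):   mass %.2f below 1 mm\n",
              sum(x$s2[x$s2_edges[-1] <= 1])))
  cat(sprintf("  S3 (dispersion):       %.3f mm\n", x$S3))
  cat(sprintf("  S4 (kurtosis):         %.3f\n", x$S4))
  cat(sprintf("  computed from %d sampled frames\n", length(x$frames_used)))
  invisible(x)
}

# mean S1 at distances below r_max (aggregation strength readout)
s1_small_r <- function(stats, r_max = 0.5) {
  mid <- (stats$s1_edges[-1] + stats$s1_edges[-length(stats$s1_edges)]) / 2
  mean(stats$s1[mid < r_max], na.rm = TRUE)
}
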