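# Independent brute-force oracles used to pin the optimized implementations.

# minimum-image distance between two points
oracle_mindist <- function(a, b, side = 0) {
  d <- a - b
  if (side > 0) d <- d - side * round(d / side)
  sqrt(sum(d^2))
}

# O(n^2) pair counting per bin, one frame
oracle_pair_counts <- function(pts, edges, side = 0) {
  n <- nrow(pts)
  d <- c()
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d <- c(d, oracle_mindist(pts[i, ], pts[j, ], side))
  counts <- numeric(length(edges) - 1)
  for (b in seq_along(counts))
    counts[b] <- sum(d > edges[b] & d <= edges[b + 1]) +
      if (b == 1) sum(d == edges[1]) else 0
  counts
}

# O(n^3) agglomerative single-linkage merge distances
oracle_single_linkage <- function(pts, side = 0) {
  n <- nrow(pts)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- oracle_mindist(pts[i, ], pts[j, ], side)
  groups <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(groups))
      for (b in seq_along(groups))
        if (a < b) {
          dmin <- min(D[groups[[a]], groups[[b]]])
          if (dmin < best[1]) best <- c(dmin, a, b)
        }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  sort(heights)
}

# reference npr-1-style aggregating parameter set used across suites
npr1_ref <- function(...) worm_params(strain = "npr1", ...)

s1_small <- function(st, r_max = 0.5) {
  mid <- (st$s1_edges[-1] + st$s1_edges[-length(st$s1_edges)]) / 2
  mean(st$s1[mid < r_max], na.rm = TRUE)
}
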