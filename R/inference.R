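#' Prior specification for the behavioral parameters
#'
#' Independent uniform priors over the four interaction parameters
#' (reversal density slope `r_prime`, slowing slope `k_s_prime`, speeding
#' decay `k_f_prime`, taxis strength `f_t`), restricted by a feasibility
#' constraint.  The default constraint caps the reversal rate attainable
#' at a reference dense-cluster density (`rho_ref`, 20 worms/mm^2 for the
#' default 40-worm arenas) at `rev_cap`, preventing unrealistically
#' reversal-dominated dynamics for a given worm count.
#'
#' @param lower,upper named numeric vectors of bounds.
#' @param constraint function of a named parameter vector returning
#'   `TRUE` for feasible draws.
#' @param rev_cap maximum reversal rate at `rho_ref`, 1/s.
#' @param rho_ref reference in-cluster density, mm^-2.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(lower = c(r_prime = 0, k_s_prime = 0,
                                 k_f_prime = 0, f_t = 0),
                       upper = c(r_prime = 1, k_s_prime = 1,
                                 k_f_prime = 2, f_t = 2),
                       constraint = NULL, rev_cap = 10, rho_ref = 20) {
  stopifnot(identical(names(lower), names(upper)), all(lower < upper))
  if (is.null(constraint)) {
    constraint <- function(theta) {
      !("r_prime" %in% names(theta)) || theta[["r_prime"]] * rho_ref <= rev_cap
    }
  }
  structure(list(lower = lower, upper = upper, constraint = constraint),
            class = "prior_spec")
}

#' Sample from the (feasibility-constrained) prior
#'
#' Uniform draws within the bounds; infeasible draws are rejected and
#' resampled.  Deterministic given the seed.
#'
#' @param spec a [prior_spec()].
#' @param n number of samples.
#' @param seed RNG seed.
#' @return `n x p` matrix of parameter vectors (columns named).
#' @export
sample_prior <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"))
  if (!is.null(seed)) set.seed(seed)
  p <- length(spec$lower)
  out <- matrix(NA_real_, n, p, dimnames = list(NULL, names(spec$lower)))
  filled <- 0
  tries <- 0
  while (filled < n) {
    tries <- tries + 1
    if (tries > 1000 * n) stop("feasible region appears to be empty")
    th <- stats::runif(p, spec$lower, spec$upper)
    names(th) <- names(spec$lower)
    if (isTRUE(spec$constraint(th))) {
      filled <- filled + 1
      out[filled, ] <- th
    }
  }
  out
}

component_distances <- function(a, b) {
  stopifnot(inherits(a, "worm_sumstats"), inherits(b, "worm_sumstats"))
  if (!isTRUE(all.equal(a$s1_edges, b$s1_edges)) ||
      !isTRUE(all.equal(a$s2_edges, b$s2_edges)))
    stop("summary statistic binning mismatch")
  c(sqrt(sum((a$s1 - b$s1)^2, na.rm = TRUE)),
    sqrt(sum((a$s2 - b$s2)^2, na.rm = TRUE)),
    abs(a$S3 - b$S3),
    abs(a$S4 - b$S4))
}

#' Distance between two summary statistic sets
#'
#' Sum of the four per-statistic distances (Euclidean for the binned S1
#' and S2 curves, absolute difference for the scalars S3 and S4), each
#' divided by its normalizer so all four statistics carry equal weight.
#'
#' @param a,b [summarize_dataset()] results with identical binning.
#' @param normalizers length-4 positive scale factors (one per statistic).
#' @return non-negative scalar; zero iff the component statistics agree.
#' @export
stat_distance <- function(a, b, normalizers = c(1, 1, 1, 1)) {
  stopifnot(length(normalizers) == 4, all(normalizers > 0))
  sum(component_distances(a, b) / normalizers)
}

#' Self-normalizing scale factors for [stat_distance()]
#'
#' Per-statistic root-mean-square component distance to the pooled mean
#' statistic across a set of (prior-predictive) summary statistic sets.
#'
#' @param stat_list list of `worm_sumstats`.
#' @return length-4 numeric.
#' @export
stat_normalizers <- function(stat_list) {
  ref <- stat_list[[1]]
  mstat <- ref
  mstat$s1 <- rowMeans(vapply(stat_list, `[[`, ref$s1, "s1"), na.rm = TRUE)
  mstat$s2 <- rowMeans(vapply(stat_list, `[[`, ref$s2, "s2"), na.rm = TRUE)
  mstat$S3 <- mean(vapply(stat_list, `[[`, 0, "S3"))
  mstat$S4 <- mean(vapply(stat_list, `[[`, 0, "S4"))
  d <- vapply(stat_list, component_distances, numeric(4), b = mstat)
  sig <- sqrt(rowMeans(d^2))
  ifelse(sig > 0, sig, 1)
}

#' Rejection ABC over simulated parameter/statistic pairs
#'
#' Accepts the fraction of simulations whose summary statistics lie
#' closest to the target, giving an approximate posterior sample over the
#' behavioral parameters.  Ties at the acceptance boundary are broken by
#' sample order.
#'
#' @param params `n x p` matrix of simulated parameter vectors.
#' @param stats list of `n` [summarize_dataset()] results.
#' @param target the target `worm_sumstats`.
#' @param accept_fraction fraction of samples to accept (0, 1].
#' @param normalizers per-statistic scales; `"auto"` computes
#'   [stat_normalizers()] from `stats` (the prior-predictive set).
#' @return object of class `worm_abc`: accepted parameters, distances,
#'   the closest-matching parameter set, and marginal summaries.
#' @export
abc_reject <- function(params, stats, target, accept_fraction = 0.01,
                       normalizers = "auto") {
  params <- as.matrix(params)
  stopifnot(nrow(params) == length(stats), length(stats) >= 1,
            accept_fraction > 0, accept_fraction <= 1)
  if (identical(normalizers, "auto")) normalizers <- stat_normalizers(stats)
  d <- vapply(stats, stat_distance, numeric(1), b = target,
              normalizers = normalizers)
  n_accept <- ceiling(accept_fraction * length(d))
  ord <- order(d)            # stable: ties broken by sample order
  acc <- ord[seq_len(n_accept)]
  marg <- apply(params[acc, , drop = FALSE], 2, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      q10 = unname(stats::quantile(v, 0.1)),
      q50 = unname(stats::quantile(v, 0.5)),
      q90 = unname(stats::quantile(v, 0.9))))
  structure(list(accepted = params[acc, , drop = FALSE],
                 distances = d[acc], all_distances = d,
                 accept_fraction = accept_fraction,
                 closest = params[ord[1], ],
                 marginals = marg, normalizers = normalizers),
            class = "worm_abc")
}

#' @export
print.worm_abc <- function(x, ...) {
  cat(sprintf("Rejection ABC posterior: %d accepted of %d simulations (%.1f%%)\n",
              nrow(x$accepted), length(x$all_distances),
              100 * x$accept_fraction))
  cat("Marginal summaries:\n")
  print(round(x$marginals, 4))
  cat("Closest match:\n")
  print(round(x$closest, 4))
  invisible(x)
}

#' @export
summary.worm_abc <- function(object, ...) object$marginals

#' @export
coef.worm_abc <- function(object, ...) object$marginals["mean", ]

#' @export
plot.worm_abc <- function(x, ...) {
  p <- ncol(x$accepted)
  op <- graphics::par(mfrow = c(1, p))
  on.exit(graphics::par(op))
  for (j in seq_len(p))
    graphics::hist(x$accepted[, j], main = colnames(x$accepted)[j],
                   xlab = "", col = "grey", border = NA, ...)
  invisible(x)
}

#' Two-parameter phase-portrait sweep
#'
#' Coarse exploration of the pre-taxis model: for each grid cell the
#' density-dependence of slowing and speeding is set equal
#' (`k_s_prime = k_f_prime = k_prime`), taxis is off, and the last
#' fraction of each run is summarized.
#'
#' @param r_prime_grid,k_prime_grid parameter grids.
#' @param base_params a [worm_params()] (its `f_t` is forced to 0).
#' @param replicates seeded replicates per cell.
#' @param duration simulated seconds per run.
#' @param record_every recording interval, s.
#' @param seed base seed; run seeds are derived deterministically.
#' @param sample_every,last_fraction frame sampling for the statistics.
#' @return list with the grids and `stats`, a `replicates`-column matrix
#'   of lists of `worm_sumstats` (cells in row-major r x k order).
#' @export
phase_sweep <- function(r_prime_grid, k_prime_grid, base_params,
                        replicates = 1, duration = 900, record_every = 5,
                        seed = 1, sample_every = 10, last_fraction = 0.1) {
  cells <- expand.grid(r_prime = r_prime_grid, k_prime = k_prime_grid,
                       KEEP.OUT.ATTRS = FALSE)
  stats <- vector("list", nrow(cells) * replicates)
  dim(stats) <- c(nrow(cells), replicates)
  for (ci in seq_len(nrow(cells))) {
    for (rep in seq_len(replicates)) {
      p <- base_params
      p$r_prime <- cells$r_prime[ci]
      p$k_s_prime <- cells$k_prime[ci]
      p$k_f_prime <- cells$k_prime[ci]
      p$f_t <- 0
      d <- run_simulation(p, duration, record_every,
                          seed = seed + 1000 * ci + rep)
      stats[[ci, rep]] <- summarize_dataset(d, sample_every = sample_every,
                                            last_fraction = last_fraction)
    }
  }
  list(cells = cells, stats = stats,
       r_prime_grid = r_prime_grid, k_prime_grid = k_prime_grid)
}
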