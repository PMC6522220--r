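#' Model parameters for the worm aggregation simulator
#'
#' Constructs and validates the full parameter set of the agent-based model:
#' worm-chain geometry, crawl speeds, persistent-random-walk noise, the
#' density-dependent behavioral rates (cluster-edge reversals, slow/fast
#' switching), neighbor taxis, arena, and food-depletion settings.
#'
#' The four interaction parameters `r_prime`, `k_s_prime`, `k_f_prime` and
#' `f_t` default to zero (non-interacting persistent random walkers).  The
#' `strain` presets install reference values that reproduce hyper-social
#' (aggregating, `"npr1"`) or hypo-social (`"n2"`) collective phenotypes;
#' these are package reference sets chosen to reproduce the respective
#' aggregation phenotypes, not experimentally measured constants.
#'
#' @param N number of worms.
#' @param M nodes per worm chain (>= 3).
#' @param L worm length, mm.
#' @param v_fast,v_slow fast and slow crawl speeds, mm/s.
#' @param dt integration time step, s.
#' @param D_theta angular diffusion coefficient of the head heading, rad^2/s.
#' @param r_prime slope of the reversal rate with local density, mm^2/s.
#'   The reversal rate is `r_prime * rho`; it is zero at zero density
#'   (no spontaneous reversals).
#' @param k_s0,k_f0 zero-density slowing and speeding rates, 1/s.
#' @param k_s_prime linear density slope of the slowing rate, mm^2/s
#'   (`k_slow = k_s0 + k_s_prime * rho`).
#' @param k_f_prime exponential density decay of the speeding rate, mm^2
#'   (`k_fast = k_f0 * exp(-k_f_prime * rho)`).
#' @param f_t taxis strength: dimensionless weight of the cumulative
#'   1/r-weighted attraction towards neighbors in the heading update.
#' @param r_contact contact-sensing radius of the chain end nodes, mm.
#' @param taxis_cutoff taxis interaction cutoff, mm (default one worm length).
#' @param arena_side side of the periodic square arena, mm.
#' @param reversal_duration_mean mean of the exponential reversal duration, s.
#' @param feed_rate food consumed per second by one worm head in its grid
#'   cell, in units of relative concentration (1/s).
#' @param food_threshold relative concentration below which food counts as
#'   absent and slowing is suppressed.
#' @param food_cell food grid resolution, mm per cell.
#' @param knn_k number of nearest neighbors for local density sensing.
#' @param seed optional RNG seed stored with the parameters and used by
#'   [run_simulation()] when no explicit seed is given.
#' @param strain optional preset: `"npr1"` or `"n2"` reference interaction
#'   parameters (overridden by explicitly supplied values).
#' @param ... override any field of a preset.
#'
#' @return an object of class `worm_params` (a named list).
#' @examples
#' p <- worm_params(strain = "npr1")
#' p$r_prime
#' @export
worm_params <- function(N = 40, M = 18, L = 1.0,
                        v_fast = 0.35, v_slow = 0.035,
                        dt = 0.05, D_theta = 0.1,
                        r_prime = 0, k_s0 = 1 / 240, k_f0 = 1 / 60,
                        k_s_prime = 0, k_f_prime = 0, f_t = 0,
                        r_contact = 0.1, taxis_cutoff = L,
                        arena_side = 8, reversal_duration_mean = 2,
                        feed_rate = 0.01, food_threshold = 0.05,
                        food_cell = 0.2, knn_k = 6, seed = NULL,
                        strain = NULL, ...) {
  p <- list(N = N, M = M, L = L, v_fast = v_fast, v_slow = v_slow, dt = dt,
            D_theta = D_theta, r_prime = r_prime, k_s0 = k_s0, k_f0 = k_f0,
            k_s_prime = k_s_prime, k_f_prime = k_f_prime, f_t = f_t,
            r_contact = r_contact, taxis_cutoff = taxis_cutoff,
            arena_side = arena_side,
            reversal_duration_mean = reversal_duration_mean,
            feed_rate = feed_rate, food_threshold = food_threshold,
            food_cell = food_cell, knn_k = knn_k, seed = seed)
  if (!is.null(strain)) {
    strain <- match.arg(strain, c("npr1", "n2"))
    preset <- strain_presets[[strain]]
    called <- names(match.call())[-1]
    for (nm in names(preset))
      if (!nm %in% called) p[[nm]] <- preset[[nm]]
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_worm_params(p)
  structure(p, class = "worm_params")
}

# Reference interaction parameter sets reproducing the two collective
# phenotypes: strong density-dependent reversals, speed switching and taxis
# for the aggregating strain; weak interactions for the solitary one.
strain_presets <- list(
  npr1 = list(r_prime = 0.5, k_s_prime = 0.03, k_f_prime = 1.0, f_t = 0.01),
  n2   = list(r_prime = 0.05, k_s_prime = 0.005, k_f_prime = 0.2, f_t = 0.002)
)

validate_worm_params <- function(p) {
  num1 <- function(nm) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar")
    v
  }
  nonneg <- c("L", "v_fast", "v_slow", "D_theta", "r_prime", "k_s0", "k_f0",
              "k_s_prime", "k_f_prime", "r_contact", "reversal_duration_mean",
              "feed_rate", "food_threshold")
  for (nm in nonneg)
    if (num1(nm) < 0) stop("parameter '", nm, "' must be >= 0")
  if (num1("M") < 3) stop("M must be >= 3")
  if (num1("N") < 1) stop("N must be >= 1")
  if (num1("dt") <= 0) stop("dt must be > 0")
  if (num1("taxis_cutoff") <= 0) stop("taxis_cutoff must be > 0")
  if (num1("food_cell") <= 0) stop("food_cell must be > 0")
  if (p$v_slow > p$v_fast) stop("v_slow must be <= v_fast")
  if (num1("arena_side") <= p$L)
    stop("arena too small: arena_side must exceed the worm length L")
  if (num1("knn_k") < 1) stop("knn_k must be >= 1")
  invisible(p)
}

#' @export
print.worm_params <- function(x, ...) {
  cat("Worm aggregation model parameters\n")
  cat(sprintf("  %d worms x %d nodes, L = %g mm, arena %g mm (periodic)\n",
              x$N, x$M, x$L, x$arena_side))
  cat(sprintf("  speeds: v_fast = %g, v_slow = %g mm/s; dt = %g s; D_theta = %g rad^2/s\n",
              x$v_fast, x$v_slow, x$dt, x$D_theta))
  cat(sprintf("  reversals: r' = %g mm^2/s, mean duration %g s\n",
              x$r_prime, x$reversal_duration_mean))
  cat(sprintf("  switching: k_s0 = %.4g, k_f0 = %.4g 1/s; k_s' = %g mm^2/s, k_f' = %g mm^2\n",
              x$k_s0, x$k_f0, x$k_s_prime, x$k_f_prime))
  cat(sprintf("  taxis: f_t = %g, cutoff %g mm; contact radius %g mm; k-NN k = %d\n",
              x$f_t, x$taxis_cutoff, x$r_contact, x$knn_k))
  invisible(x)
}
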