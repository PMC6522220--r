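#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Periodic helpers. arena <= 0 means a non-periodic (plain Euclidean) domain.
static inline double wrap0(double x, double L) {
  if (L <= 0) return x;
  double r = x - L * std::floor(x / L);
  if (r >= L) r -= L;
  if (r < 0) r = 0;
  return r;
}
static inline double mindel(double dx, double L) {
  if (L <= 0) return dx;
  return dx - L * std::nearbyint(dx / L);
}

// [[Rcpp::export]]
NumericVector cpp_taxis_drive(NumericVector head, NumericMatrix neighbors,
                              double f_t, double cutoff, double arena_side) {
  double tx = 0.0, ty = 0.0;
  int nskip = 0;
  if (f_t != 0.0) {
    for (int j = 0; j < neighbors.nrow(); j++) {
      double dx = mindel(neighbors(j, 0) - head[0], arena_side);
      double dy = mindel(neighbors(j, 1) - head[1], arena_side);
      double r = std::sqrt(dx * dx + dy * dy);
      if (r == 0.0) { nskip++; continue; }
      if (r > cutoff) continue;
      tx += dx / (r * r);  // unit vector / r  =  delta / r^2
      ty += dy / (r * r);
    }
  }
  NumericVector out = NumericVector::create(f_t * tx, f_t * ty);
  out.attr("n_skipped") = nskip;
  return out;
}

// One follow-the-leader body advance plus spring relaxation, shared between
// the exported single-worm operation and the full engine.
static void advance_chain(std::vector<double> &x, std::vector<double> &y,
                          int M, double heading, double speed, double dt,
                          double spacing, double arena, bool reversing,
                          int relax_iter) {
  if (speed != 0.0) {
    if (!reversing) {
      x[0] += speed * dt * std::cos(heading);
      y[0] += speed * dt * std::sin(heading);
      for (int i = 1; i < M; i++) {
        double dx = mindel(x[i - 1] - x[i], arena);
        double dy = mindel(y[i - 1] - y[i], arena);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d > 0) { x[i] += speed * dt * dx / d; y[i] += speed * dt * dy / d; }
      }
    } else {
      // tail leads, continuing backwards along the body axis
      double bx = mindel(x[M - 1] - x[M - 2], arena);
      double by = mindel(y[M - 1] - y[M - 2], arena);
      double b = std::sqrt(bx * bx + by * by);
      if (b > 0) { x[M - 1] += speed * dt * bx / b; y[M - 1] += speed * dt * by / b; }
      for (int i = M - 2; i >= 0; i--) {
        double dx = mindel(x[i + 1] - x[i], arena);
        double dy = mindel(y[i + 1] - y[i], arena);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d > 0) { x[i] += speed * dt * dx / d; y[i] += speed * dt * dy / d; }
      }
    }
  }
  // harmonic relaxation sweeps restoring adjacent spacing
  for (int it = 0; it < relax_iter; it++) {
    for (int i = 0; i < M - 1; i++) {
      double dx = mindel(x[i + 1] - x[i], arena);
      double dy = mindel(y[i + 1] - y[i], arena);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d == 0) continue;
      double c = 0.5 * (d - spacing) / d;
      x[i] += c * dx; y[i] += c * dy;
      x[i + 1] -= c * dx; y[i + 1] -= c * dy;
    }
  }
  for (int i = 0; i < M; i++) { x[i] = wrap0(x[i], arena); y[i] = wrap0(y[i], arena); }
}

// [[Rcpp::export]]
NumericMatrix cpp_advance_body(NumericMatrix nodes, double heading, double speed,
                               double dt, double spacing, double arena_side,
                               bool reversing, int relax_iter) {
  int M = nodes.nrow();
  std::vector<double> x(M), y(M);
  for (int i = 0; i < M; i++) { x[i] = nodes(i, 0); y[i] = nodes(i, 1); }
  advance_chain(x, y, M, heading, speed, dt, spacing, arena_side, reversing, relax_iter);
  double worst = 0.0;
  for (int i = 0; i < M - 1; i++) {
    double dx = mindel(x[i + 1] - x[i], arena_side);
    double dy = mindel(y[i + 1] - y[i], arena_side);
    double dev = std::fabs(std::sqrt(dx * dx + dy * dy) - spacing) / spacing;
    if (dev > worst) worst = dev;
  }
  if (worst > 0.05)
    stop("spring relaxation did not converge: max spacing deviation %f", worst);
  NumericMatrix out(M, 2);
  for (int i = 0; i < M; i++) { out(i, 0) = x[i]; out(i, 1) = y[i]; }
  return out;
}

// k-NN areal density  k / (pi d_k^2)  for every point, minimum-image metric.
// [[Rcpp::export]]
NumericVector cpp_knn_density_all(NumericMatrix pts, int k, double arena_side) {
  int n = pts.nrow();
  if (n < k + 1) stop("need at least k+1 points for k-NN density");
  NumericVector rho(n);
  std::vector<double> d2(n - 1);
  for (int i = 0; i < n; i++) {
    int m = 0;
    for (int j = 0; j < n; j++) {
      if (j == i) continue;
      double dx = mindel(pts(j, 0) - pts(i, 0), arena_side);
      double dy = mindel(pts(j, 1) - pts(i, 1), arena_side);
      d2[m++] = dx * dx + dy * dy;
    }
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    rho[i] = k / (M_PI * d2[k - 1]);
  }
  return rho;
}

// Full engine: per-step neighbor sensing, taxis, heading diffusion, reversal
// and speed-state switching, body advance, optional food depletion.
// All random draws use R's RNG in a fixed order (per phase, worms in index
// order) so runs are reproducible given set.seed().
// [[Rcpp::export]]
List cpp_run_simulation(NumericMatrix X0, NumericMatrix Y0,
                        NumericVector heading0, IntegerVector fast0,
                        List par, double duration, double record_every,
                        bool food_enabled, NumericMatrix food0,
                        double food_cell, bool record_skeletons,
                        int n_food_snapshots) {
  const int N = X0.nrow(), M = X0.ncol();
  const double L = as<double>(par["L"]);
  const double vf = as<double>(par["v_fast"]), vs = as<double>(par["v_slow"]);
  const double dt = as<double>(par["dt"]);
  const double Dth = as<double>(par["D_theta"]);
  const double rp = as<double>(par["r_prime"]);
  const double ks0 = as<double>(par["k_s0"]), kf0 = as<double>(par["k_f0"]);
  const double ksp = as<double>(par["k_s_prime"]), kfp = as<double>(par["k_f_prime"]);
  const double ft = as<double>(par["f_t"]);
  const double rc = as<double>(par["r_contact"]);
  const double cutoff = as<double>(par["taxis_cutoff"]);
  const double arena = as<double>(par["arena_side"]);
  const double revmean = as<double>(par["reversal_duration_mean"]);
  const double feed = as<double>(par["feed_rate"]);
  const double fthr = as<double>(par["food_threshold"]);
  const int knn = as<int>(par["knn_k"]);
  const int hn = (int)std::ceil(0.1 * M);  // contact-sensing nodes per end
  const double spacing = L / (M - 1);
  const double sig = std::sqrt(2.0 * Dth * dt);
  const double rc2 = rc * rc;
  const double prune = (L + rc) * (L + rc);

  if (N < knn + 1) stop("need more worms than knn_k for density sensing");

  const long nsteps = (long)std::llround(duration / dt);
  const long stride = std::max(1L, (long)std::llround(record_every / dt));
  const long nframes = nsteps / stride + 1;

  std::vector<double> x(N * M), y(N * M), h(N), revt(N, 0.0);
  std::vector<int> fast(N), rev(N, 0);
  for (int i = 0; i < N; i++) {
    h[i] = heading0[i]; fast[i] = fast0[i];
    for (int m = 0; m < M; m++) { x[i * M + m] = X0(i, m); y[i * M + m] = Y0(i, m); }
  }

  int gn = 0;
  std::vector<double> food;
  if (food_enabled) {
    gn = food0.nrow();
    food.assign(gn * gn, 0.0);
    for (int a = 0; a < gn; a++)
      for (int b = 0; b < gn; b++) food[a * gn + b] = food0(a, b);
  }

  NumericMatrix cx(nframes, N), cy(nframes, N);
  IntegerMatrix st(nframes, N), rv(nframes, N);
  NumericVector times(nframes);
  NumericMatrix skx, sky;
  if (record_skeletons) { skx = NumericMatrix(nframes, N * M); sky = NumericMatrix(nframes, N * M); }
  List food_snaps(n_food_snapshots);
  NumericVector food_snap_times(n_food_snapshots);
  long snap_stride = n_food_snapshots > 0 ? std::max(1L, nsteps / n_food_snapshots) : 0;
  int snap_i = 0;

  std::vector<double> hcx(N), hcy(N), rho(N), txv(N), tyv(N);
  std::vector<int> headC(N), tailC(N);
  std::vector<double> d2(N);

  long frame = 0;
  for (long step = 0; step <= nsteps; step++) {
    // head-region centroids (pharynx proxy): mean of first hn nodes,
    // unwrapped relative to the head node
    for (int i = 0; i < N; i++) {
      double ax = 0, ay = 0, x0 = x[i * M], y0 = y[i * M];
      for (int m = 0; m < hn; m++) {
        ax += mindel(x[i * M + m] - x0, arena);
        ay += mindel(y[i * M + m] - y0, arena);
      }
      hcx[i] = wrap0(x0 + ax / hn, arena);
      hcy[i] = wrap0(y0 + ay / hn, arena);
    }

    if (step % stride == 0) {
      times[frame] = step * dt;
      for (int i = 0; i < N; i++) {
        cx(frame, i) = hcx[i]; cy(frame, i) = hcy[i];
        st(frame, i) = fast[i]; rv(frame, i) = rev[i];
        if (record_skeletons)
          for (int m = 0; m < M; m++) {
            skx(frame, i * M + m) = x[i * M + m];
            sky(frame, i * M + m) = y[i * M + m];
          }
      }
      frame++;
    }
    if (food_enabled && n_food_snapshots > 0 && step % snap_stride == 0 &&
        snap_i < n_food_snapshots) {
      NumericMatrix g(gn, gn);
      for (int a = 0; a < gn; a++)
        for (int b = 0; b < gn; b++) g(a, b) = food[a * gn + b];
      food_snaps[snap_i] = g;
      food_snap_times[snap_i] = step * dt;
      snap_i++;
    }
    if (step == nsteps) break;

    // local density at head centroids
    for (int i = 0; i < N; i++) {
      int mcnt = 0;
      for (int j = 0; j < N; j++) {
        if (j == i) continue;
        double dx = mindel(hcx[j] - hcx[i], arena);
        double dy = mindel(hcy[j] - hcy[i], arena);
        d2[mcnt++] = dx * dx + dy * dy;
      }
      std::nth_element(d2.begin(), d2.begin() + (knn - 1), d2.begin() + mcnt);
      rho[i] = knn / (M_PI * d2[knn - 1]);
    }

    // taxis towards neighboring head centroids, 1/r weighted, cut off at L
    for (int i = 0; i < N; i++) {
      double tx = 0, ty = 0;
      if (ft != 0) {
        for (int j = 0; j < N; j++) {
          if (j == i) continue;
          double dx = mindel(hcx[j] - hcx[i], arena);
          double dy = mindel(hcy[j] - hcy[i], arena);
          double r2v = dx * dx + dy * dy;
          if (r2v == 0 || r2v > cutoff * cutoff) continue;
          tx += dx / r2v; ty += dy / r2v;
        }
      }
      txv[i] = ft * tx; tyv[i] = ft * ty;
    }

    // end contacts: any node of another worm within r_contact of the first /
    // last hn nodes; worm-pair pruning by mid-node distance.  Contacts only
    // matter for reversal initiation, so skip the scan when r' = 0.
    for (int i = 0; i < N; i++) { headC[i] = 0; tailC[i] = 0; }
    for (int i = 0; i < N && rp > 0; i++) {
      double mx = x[i * M + M / 2], my = y[i * M + M / 2];
      for (int j = 0; j < N && !(headC[i] && tailC[i]); j++) {
        if (j == i) continue;
        double pdx = mindel(x[j * M + M / 2] - mx, arena);
        double pdy = mindel(y[j * M + M / 2] - my, arena);
        if (pdx * pdx + pdy * pdy > prune) continue;
        for (int e = 0; e < 2 * hn && !(headC[i] && tailC[i]); e++) {
          int mi = (e < hn) ? e : (M - 1 - (e - hn));
          int *flag = (e < hn) ? &headC[i] : &tailC[i];
          if (*flag) continue;
          double ex = x[i * M + mi], ey = y[i * M + mi];
          for (int mj = 0; mj < M; mj++) {
            double dx = mindel(x[j * M + mj] - ex, arena);
            double dy = mindel(y[j * M + mj] - ey, arena);
            if (dx * dx + dy * dy <= rc2) { *flag = 1; break; }
          }
        }
      }
    }

    // heading: blend persistence with taxis, then rotational diffusion
    for (int i = 0; i < N; i++) {
      double vx = std::cos(h[i]) + txv[i];
      double vy = std::sin(h[i]) + tyv[i];
      if (vx != 0 || vy != 0) h[i] = std::atan2(vy, vx);
      if (sig > 0) h[i] += sig * norm_rand();
    }

    // cluster-edge reversals: one end in contact but not the other
    for (int i = 0; i < N; i++) {
      if (rev[i]) {
        revt[i] -= dt;
        if (revt[i] <= 0) {
          rev[i] = 0;
          // resume forward along the body axis
          double bx = mindel(x[i * M] - x[i * M + 1], arena);
          double by = mindel(y[i * M] - y[i * M + 1], arena);
          if (bx != 0 || by != 0) h[i] = std::atan2(by, bx);
        }
      } else if (headC[i] != tailC[i] && rp > 0 && rho[i] > 0) {
        if (unif_rand() < 1.0 - std::exp(-rp * rho[i] * dt)) {
          rev[i] = 1;
          revt[i] = exp_rand() * revmean;
        }
      }
    }

    // speed-state switching; absence of food suppresses slowing
    for (int i = 0; i < N; i++) {
      bool food_here = true;
      if (food_enabled) {
        int a = (int)(wrap0(hcx[i], arena) / food_cell); if (a >= gn) a = gn - 1;
        int b = (int)(wrap0(hcy[i], arena) / food_cell); if (b >= gn) b = gn - 1;
        food_here = food[a * gn + b] >= fthr;
      }
      if (fast[i]) {
        double kslow = food_here ? ks0 + ksp * rho[i] : 0.0;
        if (kslow > 0 && unif_rand() < 1.0 - std::exp(-kslow * dt)) fast[i] = 0;
      } else {
        double kfast = kf0 * std::exp(-kfp * rho[i]);
        if (kfast > 0 && unif_rand() < 1.0 - std::exp(-kfast * dt)) fast[i] = 1;
      }
    }

    // body advance
    for (int i = 0; i < N; i++) {
      double sp = fast[i] ? vf : vs;
      std::vector<double> wx(x.begin() + i * M, x.begin() + (i + 1) * M);
      std::vector<double> wy(y.begin() + i * M, y.begin() + (i + 1) * M);
      advance_chain(wx, wy, M, h[i], sp, dt, spacing, arena, rev[i] != 0, 3);
      std::copy(wx.begin(), wx.end(), x.begin() + i * M);
      std::copy(wy.begin(), wy.end(), y.begin() + i * M);
      if (!R_finite(wx[0]) || !R_finite(wy[0]))
        stop("non-finite coordinates at t=%f, worm %d", step * dt, i + 1);
    }

    // food depletion at the head cell (pharynx feeds)
    if (food_enabled && feed > 0) {
      for (int i = 0; i < N; i++) {
        double ax2 = 0, ay2 = 0, x0 = x[i * M], y0 = y[i * M];
        for (int m = 0; m < hn; m++) {
          ax2 += mindel(x[i * M + m] - x0, arena);
          ay2 += mindel(y[i * M + m] - y0, arena);
        }
        int a = (int)(wrap0(x0 + ax2 / hn, arena) / food_cell); if (a >= gn) a = gn - 1;
        int b = (int)(wrap0(y0 + ay2 / hn, arena) / food_cell); if (b >= gn) b = gn - 1;
        food[a * gn + b] = std::max(0.0, food[a * gn + b] - feed * dt);
      }
    }
  }

  List out = List::create(
    _["times"] = times, _["cx"] = cx, _["cy"] = cy,
    _["state"] = st, _["reversing"] = rv);
  if (record_skeletons) { out["skx"] = skx; out["sky"] = sky; }
  if (food_enabled) {
    NumericMatrix g(gn, gn);
    for (int a = 0; a < gn; a++)
      for (int b = 0; b < gn; b++) g(a, b) = food[a * gn + b];
    out["food_final"] = g;
    if (n_food_snapshots > 0) {
      out["food_snapshots"] = food_snaps;
      out["food_snapshot_times"] = food_snap_times;
    }
  }
  return out;
}

// Minimum-image pairwise distances of one frame (helper for the statistics).
// [[Rcpp::export]]
NumericVector cpp_pairwise_dist(NumericMatrix pts, double arena_side) {
  int n = pts.nrow();
  NumericVector out(n * (n - 1) / 2);
  int k = 0;
  for (int i = 0; i < n - 1; i++)
    for (int j = i + 1; j < n; j++) {
      double dx = mindel(pts(j, 0) - pts(i, 0), arena_side);
      double dy = mindel(pts(j, 1) - pts(i, 1), arena_side);
      out[k++] = std::sqrt(dx * dx + dy * dy);
    }
  return out;
}
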