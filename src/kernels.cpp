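#include <Rcpp.h>
using namespace Rcpp;

// Expected-error map: EE(c_j) = sum_i mass_i * |c_j - p_i|.
// [[Rcpp::export]]
NumericVector cq_ee_map_cpp(NumericVector cand_x, NumericVector cand_y,
                            NumericVector px, NumericVector py,
                            NumericVector mass) {
  const int nc = cand_x.size(), np = px.size();
  NumericVector ee(nc);
  for (int j = 0; j < nc; ++j) {
    const double cx = cand_x[j], cy = cand_y[j];
    double acc = 0.0;
    for (int i = 0; i < np; ++i) {
      const double dx = cx - px[i], dy = cy - py[i];
      acc += mass[i] * std::sqrt(dx * dx + dy * dy);
    }
    ee[j] = acc;
  }
  return ee;
}

// First (lexicographically smallest, given pre-sorted candidates) argmin of
// the EE map, without materialising the full map. Returns (index 1-based, min).
// [[Rcpp::export]]
List cq_ee_min_cpp(NumericVector cand_x, NumericVector cand_y,
                   NumericVector px, NumericVector py, NumericVector mass) {
  const int nc = cand_x.size(), np = px.size();
  int best = 0;
  double best_ee = R_PosInf;
  for (int j = 0; j < nc; ++j) {
    const double cx = cand_x[j], cy = cand_y[j];
    double acc = 0.0;
    for (int i = 0; i < np; ++i) {
      const double dx = cx - px[i], dy = cy - py[i];
      acc += mass[i] * std::sqrt(dx * dx + dy * dy);
    }
    if (acc < best_ee) { best_ee = acc; best = j; }
  }
  return List::create(_["index"] = best + 1, _["ee_opt"] = best_ee);
}

// ---- internal helpers for the trial simulator ----

// EE at the ideal placement for a uniform posterior over the feasible points,
// with point caps for tractability: the support is thinned to <= cap points
// and candidates are a stride-aligned lattice over the support bounding box
// coarsened so that its size stays <= cap.
static void ee_opt_capped(const std::vector<double> &fx,
                          const std::vector<double> &fy,
                          double stride, int cap,
                          double &ee_opt, double &lx, double &ly) {
  const int n = (int)fx.size();
  if (n == 0) { ee_opt = NA_REAL; lx = NA_REAL; ly = NA_REAL; return; }
  const int step = (n + cap - 1) / cap;   // support thinning
  std::vector<double> sx, sy;
  sx.reserve(n / step + 1); sy.reserve(n / step + 1);
  for (int i = 0; i < n; i += step) { sx.push_back(fx[i]); sy.push_back(fy[i]); }
  const int ns = (int)sx.size();
  const double w = 1.0 / ns;

  double x0 = fx[0], x1 = fx[0], y0 = fy[0], y1 = fy[0];
  for (int i = 1; i < n; ++i) {
    if (fx[i] < x0) x0 = fx[i]; if (fx[i] > x1) x1 = fx[i];
    if (fy[i] < y0) y0 = fy[i]; if (fy[i] > y1) y1 = fy[i];
  }
  // candidate lattice stride: integer multiple of the grid stride
  double cs = stride;
  for (;;) {
    const double ncx = std::floor((x1 - x0) / cs) + 1.0;
    const double ncy = std::floor((y1 - y0) / cs) + 1.0;
    if (ncx * ncy <= (double)cap) break;
    cs += stride;
  }
  double best_ee = R_PosInf, bx = sx[0], by = sy[0];
  for (double cx = x0; cx <= x1 + 1e-9; cx += cs) {
    for (double cy = y0; cy <= y1 + 1e-9; cy += cs) {
      double acc = 0.0;
      for (int i = 0; i < ns; ++i) {
        const double dx = cx - sx[i], dy = cy - sy[i];
        acc += std::sqrt(dx * dx + dy * dy);
      }
      acc *= w;
      if (acc < best_ee) { best_ee = acc; bx = cx; by = cy; }
    }
  }
  ee_opt = best_ee; lx = bx; ly = by;
}

// Myopic proposal score under the area-scaling approximation:
// E[EE'|touch at sigma] ~= EE * (p_in^{3/2} + p_out^{3/2}),
// where p_in is the posterior probability that the touch lands inside
// the hidden circle (fraction of feasible centres within r of sigma).
static double split_score(const std::vector<double> &fx,
                          const std::vector<double> &fy,
                          double sx, double sy, double r) {
  const int n = (int)fx.size();
  int nin = 0;
  const double r2 = r * r;
  for (int i = 0; i < n; ++i) {
    const double dx = fx[i] - sx, dy = fy[i] - sy;
    if (dx * dx + dy * dy <= r2) ++nin;
  }
  const double pin = (double)nin / n, pout = 1.0 - pin;
  return pin * std::sqrt(pin) + pout * std::sqrt(pout);
}

// Simulate one active trial of an information-sampling agent.
// Uses R's RNG (deterministic under set.seed()). grid_* is the prior support
// (stride lattice, lexicographically sorted); the hidden centre must be one
// of its points so the feasible set can never empty out.
// [[Rcpp::export]]
List cq_simulate_trial_cpp(NumericVector grid_x, NumericVector grid_y,
                           double hidden_x, double hidden_y,
                           double free_x, double free_y,
                           double r, double field_radius, double stride,
                           double R0, double eta_s, double eta_e,
                           double sampling_duration,
                           double isi_mu, double isi_sigma,
                           double q, double stop_threshold, double lapse,
                           int n_proposals, int cap,
                           double placement_jitter_sd) {
  RNGScope scope;
  const int ng = grid_x.size();
  const double r2 = r * r;

  std::vector<double> fx, fy;
  fx.reserve(ng); fy.reserve(ng);
  for (int i = 0; i < ng; ++i) {
    const double dx = grid_x[i] - free_x, dy = grid_y[i] - free_y;
    if (dx * dx + dy * dy <= r2) { fx.push_back(grid_x[i]); fy.push_back(grid_y[i]); }
  }
  if (fx.empty()) stop("free initial dot inconsistent with the prior support");

  double ee_now, lx, ly;
  ee_opt_capped(fx, fy, stride, cap, ee_now, lx, ly);

  std::vector<double> samp_t(1, 0.0), samp_x(1, free_x), samp_y(1, free_y);
  std::vector<int> samp_col(1, 1), samp_paid(1, 0);
  std::vector<double> traj(1, ee_now);

  double t = 0.0;
  for (;;) {
    const double isi = R::rlnorm(isi_mu, isi_sigma);
    if (t + isi > sampling_duration) break;

    // myopic proposal evaluation: probes are feasible centres displaced by
    // up to ~r, so the circle boundary can cut through small feasible sets
    const int nf = (int)fx.size();
    double best_score = R_PosInf, best_x = fx[0], best_y = fy[0];
    for (int k = 0; k < n_proposals; ++k) {
      int idx = (int)std::floor(R::unif_rand() * nf);
      if (idx >= nf) idx = nf - 1;
      const double d = R::unif_rand() * 1.05 * r;
      const double a = 2.0 * M_PI * R::unif_rand();
      double sxp = fx[idx] + d * std::cos(a);
      double syp = fy[idx] + d * std::sin(a);
      const double nrm = std::sqrt(sxp * sxp + syp * syp);
      if (nrm > field_radius) {  // keep the probe on the search field
        sxp *= field_radius / nrm; syp *= field_radius / nrm;
      }
      const double sc = split_score(fx, fy, sxp, syp, r);
      if (sc < best_score) { best_score = sc; best_x = sxp; best_y = syp; }
    }
    const double exp_ee_next = ee_now * best_score;
    const double gain = eta_e * (ee_now - exp_ee_next) - eta_s;
    if (gain < stop_threshold && R::unif_rand() >= lapse) break;

    double tx, ty;
    if (R::unif_rand() < q) {
      tx = best_x; ty = best_y;
    } else {
      const double rad = field_radius * std::sqrt(R::unif_rand());
      const double ang = 2.0 * M_PI * R::unif_rand();
      tx = rad * std::cos(ang); ty = rad * std::sin(ang);
    }

    t += isi;
    const double hdx = tx - hidden_x, hdy = ty - hidden_y;
    const int purple = (hdx * hdx + hdy * hdy <= r2) ? 1 : 0;

    std::vector<double> nfx, nfy;
    nfx.reserve(fx.size()); nfy.reserve(fy.size());
    for (size_t i = 0; i < fx.size(); ++i) {
      const double dx = fx[i] - tx, dy = fy[i] - ty;
      const bool inside = (dx * dx + dy * dy <= r2);
      if (inside == (purple == 1)) { nfx.push_back(fx[i]); nfy.push_back(fy[i]); }
    }
    fx.swap(nfx); fy.swap(nfy);
    if (fx.empty()) stop("feasible set emptied during simulation");

    ee_opt_capped(fx, fy, stride, cap, ee_now, lx, ly);
    samp_t.push_back(t); samp_x.push_back(tx); samp_y.push_back(ty);
    samp_col.push_back(purple); samp_paid.push_back(1);
    traj.push_back(ee_now);
  }

  double place_x = lx, place_y = ly;
  if (placement_jitter_sd > 0) {
    place_x += R::rnorm(0.0, placement_jitter_sd);
    place_y += R::rnorm(0.0, placement_jitter_sd);
  }
  const double edx = place_x - hidden_x, edy = place_y - hidden_y;
  const double err = std::sqrt(edx * edx + edy * edy);
  const int s_paid = (int)samp_t.size() - 1;
  const double score = R0 - s_paid * eta_s - err * eta_e;

  return List::create(
    _["t"] = samp_t, _["x"] = samp_x, _["y"] = samp_y,
    _["colour"] = samp_col, _["paid"] = samp_paid,
    _["ee_trajectory"] = traj,
    _["placement_x"] = place_x, _["placement_y"] = place_y,
    _["error_px"] = err, _["score"] = score, _["n_paid"] = s_paid);
}
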