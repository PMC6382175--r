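// Core time stepper for the growing-domain reaction-diffusion model.
//
// Operator order per step (matching the R reference step):
//   reaction -> mesenchymal forcing -> diffusion of a,i (IMEX or explicit)
//   -> cell density diffusion/chemotaxis (conservative explicit)
//   -> maturation (delayed activator) -> regime flags -> domain growth.
// No-flux (zero-gradient ghost node) boundaries throughout. All arrays are
// allocated at max_n and the active prefix has length n.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sstep(double z, double eps) {
  double u = z / eps;
  if (u > 50.0) u = 50.0;
  if (u < -50.0) u = -50.0;
  return 1.0 / (1.0 + std::exp(-u));
}

// Thomas solve of (I - r*L) u = rhs with no-flux Laplacian L*dx^2/r scaling
// folded in: diag 1+2r (1+r at ends), off-diagonals -r.
static void implicit_diffuse(std::vector<double>& u, int n, double r,
                             std::vector<double>& cp, std::vector<double>& dp) {
  if (n == 1 || r == 0.0) return;
  // forward sweep
  double b0 = 1.0 + r;
  cp[0] = -r / b0;
  dp[0] = u[0] / b0;
  for (int j = 1; j < n; ++j) {
    double bj = (j == n - 1) ? 1.0 + r : 1.0 + 2.0 * r;
    double m = bj + r * cp[j - 1];
    cp[j] = -r / m;
    dp[j] = (u[j] + r * dp[j - 1]) / m;
  }
  u[n - 1] = dp[n - 1];
  for (int j = n - 2; j >= 0; --j) u[j] = dp[j] - cp[j] * u[j + 1];
}

static void explicit_diffuse(std::vector<double>& u, std::vector<double>& tmp,
                             int n, double r) {
  if (n == 1 || r == 0.0) return;
  tmp[0] = u[0] + r * (u[1] - u[0]);
  for (int j = 1; j < n - 1; ++j)
    tmp[j] = u[j] + r * (u[j - 1] - 2.0 * u[j] + u[j + 1]);
  tmp[n - 1] = u[n - 1] + r * (u[n - 2] - u[n - 1]);
  for (int j = 0; j < n; ++j) u[j] = tmp[j];
}

// [[Rcpp::export]]
List engine_run(NumericVector a0, NumericVector i0, NumericVector m0,
                NumericVector rho0, IntegerVector flag0, double s0,
                List par, double t0, double acc0,
                int n_steps, int out_stride, int max_n) {
  const double dx = as<double>(par["dx"]);
  const double dt = as<double>(par["dt"]);
  const double D_a = as<double>(par["D_a"]);
  const double D_i = as<double>(par["D_i"]);
  const double Q_h = as<double>(par["Q_h"]);
  const double Q_l = as<double>(par["Q_l"]);
  const double theta0 = as<double>(par["theta0"]);
  const double gamma_ = as<double>(par["gamma"]);
  const double i_sat = as<double>(par["i_sat"]);
  const double a_switch = as<double>(par["a_switch"]);
  const double eps_Q = as<double>(par["eps_Q"]);
  const double bI = as<double>(par["b"]);
  const double p_i = as<double>(par["p_i"]);
  const double K_i = as<double>(par["K_i"]);
  const double Kp = std::pow(K_i, p_i);
  const double d_i = as<double>(par["d_i"]);
  const double q_b = as<double>(par["q_bistable"]);
  const double q_t = as<double>(par["q_turing"]);
  const double c_g = as<double>(par["growth_speed"]);
  const int growth_on = as<int>(par["growth_on"]);
  const int maturation_on = as<int>(par["maturation_on"]);
  const double mat_alpha = as<double>(par["mat_alpha"]);
  const double mat_beta = as<double>(par["mat_beta"]);
  const double mat_thresh = as<double>(par["mat_thresh"]);
  const double mat_tau = as<double>(par["mat_tau"]);
  const double m_star = as<double>(par["m_star"]);
  const double m_seed = as<double>(par["m_seed"]);
  const double m_cap = as<double>(par["m_cap"]);
  const double mat_eps = as<double>(par["mat_eps"]);
  const int mes_on = as<int>(par["mes_on"]);
  const double th_low = as<double>(par["th_low"]);
  const double th_high = as<double>(par["th_high"]);
  const double k_pos = as<double>(par["k_pos"]);
  const double k_neg = as<double>(par["k_neg"]);
  const double k_relax = as<double>(par["k_relax"]);
  const double window_frac = as<double>(par["window_frac"]);
  const double mes_eps = as<double>(par["mes_eps"]);
  const int chem_on = as<int>(par["chem_on"]);
  const double chi = as<double>(par["chi"]);
  const double D_rho = as<double>(par["D_rho"]);
  const double rho_ref = as<double>(par["rho_ref"]);
  const double fb = as<double>(par["fb_strength"]);
  const int imex = as<int>(par["imex"]);

  int n = a0.size();
  if (n > max_n) stop("initial state larger than max_n");

  std::vector<double> a(max_n, 0.0), ii(max_n, 0.0), m(max_n, 0.0),
      rho(max_n, rho_ref), srcbuf(max_n, 0.0), tmp(max_n, 0.0),
      cp(max_n, 0.0), dp(max_n, 0.0), adel(max_n, 0.0);
  std::vector<int> flag(max_n, 0);
  for (int j = 0; j < n; ++j) {
    a[j] = a0[j]; ii[j] = i0[j]; m[j] = m0[j]; rho[j] = rho0[j];
    flag[j] = flag0[j];
  }
  double s = s0, t = t0, acc = acc0;
  double clipped = 0.0;

  // delayed-activator ring buffer (linear interpolation between slots);
  // pre-history equals the initial condition.
  const bool use_delay = (maturation_on != 0) && (mat_tau > 0.0);
  int hist_stride = 1, n_slots = 2;
  std::vector<double> hist;
  std::vector<double> hist_t;
  int hist_head = 0;  // index of most recently written slot
  if (use_delay) {
    double hist_dt_target = mat_tau / 64.0;
    hist_stride = std::max(1, (int)std::floor(hist_dt_target / dt));
    double hist_dt = hist_stride * dt;
    n_slots = (int)std::ceil(mat_tau / hist_dt) + 3;
    hist.assign((size_t)n_slots * max_n, 0.0);
    hist_t.assign(n_slots, t0 - mat_tau * 2.0);
    for (int sIdx = 0; sIdx < n_slots; ++sIdx)
      for (int j = 0; j < n; ++j) hist[(size_t)sIdx * max_n + j] = a[j];
    hist_t[0] = t0;
    hist_head = 0;
  }

  const int n_frames = n_steps / out_stride + 1;
  NumericMatrix F_a(n_frames, max_n), F_i(n_frames, max_n),
      F_m(n_frames, max_n), F_rho(n_frames, max_n);
  IntegerMatrix F_flag(n_frames, max_n);
  std::fill(F_a.begin(), F_a.end(), NA_REAL);
  std::fill(F_i.begin(), F_i.end(), NA_REAL);
  std::fill(F_m.begin(), F_m.end(), NA_REAL);
  std::fill(F_rho.begin(), F_rho.end(), NA_REAL);
  std::fill(F_flag.begin(), F_flag.end(), NA_INTEGER);
  NumericVector F_t(n_frames), F_s(n_frames);
  IntegerVector F_n(n_frames);

  int frame = 0;
  auto save_frame = [&](void) {
    for (int j = 0; j < n; ++j) {
      F_a(frame, j) = a[j]; F_i(frame, j) = ii[j]; F_m(frame, j) = m[j];
      F_rho(frame, j) = rho[j]; F_flag(frame, j) = flag[j];
    }
    F_t[frame] = t; F_s[frame] = s; F_n[frame] = n;
    ++frame;
  };
  save_frame();

  const double r_a = imex ? D_a * dt / (dx * dx) : D_a * dt / (dx * dx);
  const double r_i = D_i * dt / (dx * dx);

  for (int step = 1; step <= n_steps; ++step) {
    // ---- reaction ----
    for (int j = 0; j < n; ++j) {
      double av = a[j], iv = ii[j];
      double Q = Q_l + (Q_h - Q_l) * sstep(av - a_switch, eps_Q);
      double q = flag[j] ? q_t : q_b;
      double phi = 1.0;
      if (chem_on) {
        double z = rho[j] / rho_ref - 1.0;
        phi = std::exp(-fb * (z >= 0.0 ? z : z / 10.0));
      }
      double fa = Q * av * (1.0 - av)
                  * (av - theta0 - gamma_ * iv / (1.0 + i_sat * iv));
      double ap = (p_i == 2.0) ? av * av : std::pow(std::max(av, 0.0), p_i);
      if (av < 0.0) ap = 0.0;
      double gi = phi * bI * ap / ((Kp + ap) * (1.0 + q * iv)) - d_i * iv;
      a[j] = av + dt * fa;
      ii[j] = iv + dt * gi;
    }

    // ---- mesenchymal forcing (posterior window) ----
    if (mes_on) {
      int wlen = (int)std::lround(window_frac * n);
      if (wlen < 1) wlen = 1;
      if (wlen > n) wlen = n;
      double abar = 0.0;
      for (int j = n - wlen; j < n; ++j) abar += a[j];
      abar /= wlen;
      for (int j = n - wlen; j < n; ++j) {
        double src = s * sstep(th_low - a[j], mes_eps)
                   - k_neg * a[j] * sstep(a[j] - th_high, mes_eps);
        a[j] += dt * src;
      }
      s += dt * (k_pos * sstep(th_low - abar, mes_eps) - k_relax * s);
      if (s < 0.0) s = 0.0;
    }

    // ---- diffusion of a and i ----
    if (imex) {
      implicit_diffuse(a, n, r_a, cp, dp);
      implicit_diffuse(ii, n, r_i, cp, dp);
    } else {
      explicit_diffuse(a, tmp, n, r_a);
      explicit_diffuse(ii, tmp, n, r_i);
    }

    // ---- cell density: conservative chemotactic advection + diffusion ----
    if (chem_on && n > 1) {
      // upwind advective flux at face j+1/2, F = 0 at ends; with the IMEX
      // scheme the diffusive part is folded into an implicit solve (which
      // also conserves mass exactly), otherwise both parts are explicit
      double Fprev = 0.0;
      double rho_left = rho[0];
      for (int j = 0; j < n - 1; ++j) {
        double grad = (a[j + 1] - a[j]) / dx;
        double v = chi * grad;
        double upw = (v > 0.0) ? rho_left : rho[j + 1];
        double Fface = v * upw;
        if (!imex) Fface += -D_rho * (rho[j + 1] - rho_left) / dx;
        double rj = rho_left;  // unmodified value of node j
        rho[j] = rj - dt / dx * (Fface - Fprev);
        Fprev = Fface;
        rho_left = rho[j + 1];
      }
      rho[n - 1] = rho_left - dt / dx * (0.0 - Fprev);
      if (imex) implicit_diffuse(rho, n, D_rho * dt / (dx * dx), cp, dp);
    }

    // ---- maturation ----
    if (maturation_on) {
      if (use_delay) {
        double t_del = t + dt - mat_tau;
        // locate bracketing slots (hist_t increasing with recency)
        int s1 = hist_head, s0_ = hist_head;
        for (int kIdx = 0; kIdx < n_slots; ++kIdx) {
          int idx = (hist_head - kIdx + n_slots * 4) % n_slots;
          if (hist_t[idx] <= t_del) { s0_ = idx; break; }
          s1 = idx;
        }
        double t0s = hist_t[s0_], t1s = hist_t[s1];
        double w = (s1 == s0_ || t1s <= t0s) ? 0.0
                   : std::min(1.0, std::max(0.0, (t_del - t0s) / (t1s - t0s)));
        for (int j = 0; j < n; ++j) {
          adel[j] = (1.0 - w) * hist[(size_t)s0_ * max_n + j]
                  + w * hist[(size_t)s1 * max_n + j];
        }
      } else {
        for (int j = 0; j < n; ++j) adel[j] = a[j];
      }
      double cap = m_cap * m_star;
      for (int j = 0; j < n; ++j) {
        double rate = mat_alpha + mat_beta * sstep(adel[j] - mat_thresh, mat_eps);
        m[j] += dt * rate * m[j];
        if (m[j] > cap) m[j] = cap;
      }
      // ---- regime flags (irreversible) ----
      for (int j = 0; j < n; ++j)
        if (m[j] >= m_star) flag[j] = 1;
    }

    // ---- domain growth ----
    if (growth_on) {
      acc += c_g * dt;
      while (acc >= dx && n < max_n) {
        acc -= dx;
        a[n] = 0.0; ii[n] = 0.0; m[n] = m_seed; rho[n] = rho_ref; flag[n] = 0;
        if (use_delay)
          for (int sIdx = 0; sIdx < n_slots; ++sIdx)
            hist[(size_t)sIdx * max_n + n] = 0.0;
        ++n;
      }
      if (acc >= dx) acc = dx;  // saturated at max_n
    }

    t = t0 + step * dt;

    // ---- history write ----
    if (use_delay && step % hist_stride == 0) {
      hist_head = (hist_head + 1) % n_slots;
      for (int j = 0; j < n; ++j) hist[(size_t)hist_head * max_n + j] = a[j];
      hist_t[hist_head] = t;
    }

    // ---- sanity: positivity and finiteness ----
    for (int j = 0; j < n; ++j) {
      if (!std::isfinite(a[j]) || !std::isfinite(ii[j]) ||
          !std::isfinite(m[j]) || !std::isfinite(rho[j])) {
        stop("non-finite field value at t = %f (node %d): numerical "
             "stability violated", t, j + 1);
      }
      if (a[j] < 0.0) {
        if (a[j] < -1e-12)
          stop("activator fell below -1e-12 at t = %f (node %d)", t, j + 1);
        a[j] = 0.0; clipped += 1.0;
      }
      if (ii[j] < 0.0) {
        if (ii[j] < -1e-12)
          stop("inhibitor fell below -1e-12 at t = %f (node %d)", t, j + 1);
        ii[j] = 0.0; clipped += 1.0;
      }
      if (rho[j] < 0.0) {
        if (rho[j] < -1e-12)
          stop("cell density fell below -1e-12 at t = %f (node %d)", t, j + 1);
        rho[j] = 0.0; clipped += 1.0;
      }
    }

    if (step % out_stride == 0) save_frame();
  }

  NumericVector a_fin(n), i_fin(n), m_fin(n), rho_fin(n);
  IntegerVector flag_fin(n);
  for (int j = 0; j < n; ++j) {
    a_fin[j] = a[j]; i_fin[j] = ii[j]; m_fin[j] = m[j]; rho_fin[j] = rho[j];
    flag_fin[j] = flag[j];
  }

  return List::create(
    _["times"] = F_t, _["lengths"] = F_n, _["s"] = F_s,
    _["activator"] = F_a, _["inhibitor"] = F_i, _["maturation"] = F_m,
    _["density"] = F_rho, _["regime"] = F_flag,
    _["final"] = List::create(
      _["a"] = a_fin, _["i"] = i_fin, _["m"] = m_fin, _["rho"] = rho_fin,
      _["flag"] = flag_fin, _["s"] = s, _["t"] = t, _["acc"] = acc),
    _["clipped"] = clipped);
}
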