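// Multi-pool Bloch-McConnell propagation for pulsed quasi-continuous CEST
// saturation. State vector: (Mx, My, Mz) per Lorentzian pool (water first),
// plus a longitudinal-only compartment for the semisolid (super-Lorentzian)
// MT pool, saturated at rate pi * w1^2 * g_SL(delta).
//
// Exchange topology is a star centred on water; back-rates follow detailed
// balance (k_water->i = f_i * k_i). Magnetization is normalized to water
// equilibrium (water Mz_eq = 1, pool i Mz_eq = f_i).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double GAMMA_HZ_PER_UT = 42.577; // gyromagnetic ratio / 2pi, Hz per uT

// ---------------------------------------------------------------------------
// Super-Lorentzian absorption lineshape (orientation-integrated), value in s.
// Gauss-Legendre quadrature over theta in [0, pi/2]; node set built once.
// ---------------------------------------------------------------------------
namespace {

struct GLNodes {
  vec x, w;
  GLNodes(int n, double a, double b) {
    // Golub-Welsch via symmetric tridiagonal eigen-decomposition
    vec d(n, fill::zeros), e(n - 1);
    for (int i = 1; i < n; ++i) {
      double ii = i;
      e(i - 1) = ii / std::sqrt(4.0 * ii * ii - 1.0);
    }
    mat J(n, n, fill::zeros);
    J.diag(1) = e; J.diag(-1) = e;
    vec eigval; mat eigvec;
    eig_sym(eigval, eigvec, J);
    x = 0.5 * (b - a) * eigval + 0.5 * (a + b);
    w = 0.5 * (b - a) * 2.0 * square(eigvec.row(0).t());
  }
};

// the integrand is sharply peaked around the magic angle (3cos^2 t = 1),
// so the quadrature is split there into two Gauss-Legendre panels
static const double MAGIC_ANGLE = 0.955316618124509; // acos(1/sqrt(3))

const GLNodes &sl_nodes_lo() {
  static GLNodes nodes(256, 0.0, MAGIC_ANGLE);
  return nodes;
}
const GLNodes &sl_nodes_hi() {
  static GLNodes nodes(256, MAGIC_ANGLE, M_PI / 2.0);
  return nodes;
}

// raw integrand evaluation (no interpolation window)
double sl_g_raw(double delta_hz, double t2_s) {
  double acc = 0.0;
  for (const GLNodes *n : {&sl_nodes_lo(), &sl_nodes_hi()}) {
    for (uword i = 0; i < n->x.n_elem; ++i) {
      double ct = std::cos(n->x(i));
      double u = 3.0 * ct * ct - 1.0;
      if (std::abs(u) < 1e-14) continue;
      double arg = 2.0 * M_PI * delta_hz * t2_s / u;
      acc += n->w(i) * std::sin(n->x(i)) * (t2_s / std::abs(u)) *
             std::exp(-2.0 * arg * arg);
    }
  }
  return std::sqrt(2.0 / M_PI) * acc;
}

// windowed lineshape: inside +/- window_hz the (divergent) lineshape is
// replaced by the cubic through four flanking samples at +/-W and +/-1.5W,
// which by evenness reduces to a polynomial in delta^2.
double sl_g_win(double delta_hz, double t2_s, double window_hz) {
  double ad = std::abs(delta_hz);
  if (window_hz <= 0.0 || ad >= window_hz) return sl_g_raw(ad, t2_s);
  double g1 = sl_g_raw(window_hz, t2_s);
  double g15 = sl_g_raw(1.5 * window_hz, t2_s);
  double b = (g15 - g1) / (1.25 * window_hz * window_hz);
  double a = g1 - b * window_hz * window_hz;
  return a + b * delta_hz * delta_hz;
}

// Lazily built lookup table of the windowed lineshape on a uniform |delta|
// grid, used inside the solver where g is evaluated ~50 times per spectrum
// and thousands of times per fit. Linear interpolation at 2 Hz spacing is
// accurate to ~1e-6 relative (g varies on the 1/T2 ~ kHz scale); offsets
// beyond the grid (only the far M0 reference) fall back to quadrature.
struct SLTable {
  double t2, window, step, dmax;
  std::vector<double> g;
};

double sl_g_cached(double delta_hz, double t2_s, double window_hz) {
  static std::vector<SLTable> tables;
  double ad = std::abs(delta_hz);
  SLTable *tab = nullptr;
  for (auto &t : tables)
    if (t.t2 == t2_s && t.window == window_hz) { tab = &t; break; }
  if (!tab) {
    SLTable t;
    t.t2 = t2_s; t.window = window_hz; t.step = 2.0; t.dmax = 64000.0;
    size_t n = (size_t)(t.dmax / t.step) + 2;
    t.g.resize(n);
    for (size_t i = 0; i < n; ++i)
      t.g[i] = sl_g_win(i * t.step, t2_s, window_hz);
    tables.push_back(std::move(t));
    tab = &tables.back();
  }
  if (ad >= tab->dmax) return sl_g_raw(ad, t2_s);
  double u = ad / tab->step;
  size_t i = (size_t)u;
  double w = u - i;
  return (1.0 - w) * tab->g[i] + w * tab->g[i + 1];
}

} // namespace

// [[Rcpp::export]]
arma::vec sl_lineshape_cpp(const arma::vec &delta_hz, double t2_s,
                           double window_hz) {
  vec out(delta_hz.n_elem);
  for (uword i = 0; i < delta_hz.n_elem; ++i)
    out(i) = sl_g_win(delta_hz(i), t2_s, window_hz);
  return out;
}

// ---------------------------------------------------------------------------
// Bloch-McConnell system assembly
// ---------------------------------------------------------------------------
namespace {

// pools: columns {delta_ppm, kex_hz, f_h, t1_s, t2_s, is_mt}; row 0 = water
struct BMSystem {
  mat A;   // homogeneous part
  vec b;   // constant (relaxation recovery) part
  uword nstate;
};

BMSystem build_system(const mat &pools, double offset_ppm, double w1_rad,
                      double larmor_mhz, double sl_window_hz) {
  const uword np = pools.n_rows;
  std::vector<int> zidx(np); // index of Mz row per pool
  uword n = 0;
  for (uword i = 0; i < np; ++i) {
    if (pools(i, 5) > 0.5) { zidx[i] = n; n += 1; }       // MT: z only
    else { zidx[i] = n + 2; n += 3; }                     // x, y, z
  }
  mat A(n, n, fill::zeros);
  vec b(n, fill::zeros);

  for (uword i = 0; i < np; ++i) {
    double f = pools(i, 2), k = pools(i, 1);
    double r1 = 1.0 / pools(i, 3), r2 = 1.0 / pools(i, 4);
    int zi = zidx[i];
    if (pools(i, 5) > 0.5) {
      // longitudinal-only MT pool with RF saturation rate pi*w1^2*g
      double d_hz = (pools(i, 0) - offset_ppm) * larmor_mhz;
      double rrf = (w1_rad > 0.0)
          ? M_PI * w1_rad * w1_rad * sl_g_cached(d_hz, pools(i, 4), sl_window_hz)
          : 0.0;
      A(zi, zi) += -r1 - rrf;
      b(zi) += r1 * f;
    } else {
      int xi = zi - 2, yi = zi - 1;
      double dw = 2.0 * M_PI * (pools(i, 0) - offset_ppm) * larmor_mhz;
      A(xi, xi) += -r2;  A(xi, yi) += dw;
      A(yi, xi) += -dw;  A(yi, yi) += -r2;  A(yi, zi) += w1_rad;
      A(zi, yi) += -w1_rad;  A(zi, zi) += -r1;
      b(zi) += r1 * f;
    }
    if (i > 0) {
      // exchange with water (row 0), all shared components
      int zw = zidx[0];
      double fk = f * k;
      if (pools(i, 5) > 0.5) {
        A(zi, zi) += -k;  A(zi, zw) += fk;
        A(zw, zi) += k;   A(zw, zw) += -fk;
      } else {
        for (int c = -2; c <= 0; ++c) {
          A(zi + c, zi + c) += -k;  A(zi + c, zw + c) += fk;
          A(zw + c, zi + c) += k;   A(zw + c, zw + c) += -fk;
        }
      }
    }
  }
  return BMSystem{A, b, n};
}

vec initial_state(const mat &pools, double recovery_s,
                  const std::vector<int> &zidx, uword n) {
  vec m0(n, fill::zeros);
  for (uword i = 0; i < pools.n_rows; ++i) {
    double rec = (recovery_s < 0) ? 1.0 : 1.0 - std::exp(-recovery_s / pools(i, 3));
    m0(zidx[i]) = pools(i, 2) * rec;
  }
  return m0;
}

std::vector<int> z_indices(const mat &pools) {
  std::vector<int> zidx(pools.n_rows);
  uword n = 0;
  for (uword i = 0; i < pools.n_rows; ++i) {
    if (pools(i, 5) > 0.5) { zidx[i] = n; n += 1; }
    else { zidx[i] = n + 2; n += 3; }
  }
  return zidx;
}

// exact solution of dM/dt = A M + b over a piecewise-constant segment,
// M(t) = Mss + expm(A t) (M0 - Mss) with Mss = -A^-1 b
vec evolve_expm(const mat &P, const vec &mss, const vec &m) {
  return mss + P * (m - mss);
}

} // namespace

// solver: 0 = analytic (single continuous block, eigendecomposition)
//         1 = numeric (exact pulsed propagation, matrix exponentials)
// returns unnormalized water Mz at each offset
// [[Rcpp::export]]
arma::vec bm_mz_cpp(const arma::vec &offsets_ppm, const arma::mat &pools,
                    double b1_ut, int n_pulses, double pulse_s, double delay_s,
                    double recovery_s, double larmor_mhz, int solver,
                    double sl_window_ppm) {
  double w1 = 2.0 * M_PI * GAMMA_HZ_PER_UT * b1_ut;
  double sl_window_hz = sl_window_ppm * larmor_mhz;
  std::vector<int> zidx = z_indices(pools);
  vec out(offsets_ppm.n_elem);

  for (uword j = 0; j < offsets_ppm.n_elem; ++j) {
    BMSystem on = build_system(pools, offsets_ppm(j), w1, larmor_mhz, sl_window_hz);
    vec m = initial_state(pools, recovery_s, zidx, on.nstate);
    if (solver == 0) {
      double t_total = n_pulses * pulse_s + (n_pulses - 1) * delay_s;
      m = evolve_expm(expmat(on.A * t_total), solve(on.A, -on.b), m);
    } else {
      BMSystem off = build_system(pools, offsets_ppm(j), 0.0, larmor_mhz, sl_window_hz);
      mat P_on = expmat(on.A * pulse_s);
      vec mss_on = solve(on.A, -on.b);
      mat P_off; vec mss_off;
      if (n_pulses > 1 && delay_s > 0) {
        P_off = expmat(off.A * delay_s);
        mss_off = solve(off.A, -off.b);
      }
      for (int p = 0; p < n_pulses; ++p) {
        m = evolve_expm(P_on, mss_on, m);
        if (p < n_pulses - 1 && delay_s > 0)
          m = evolve_expm(P_off, mss_off, m);
      }
    }
    out(j) = m(zidx[0]);
  }
  return out;
}
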