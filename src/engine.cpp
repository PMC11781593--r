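// Batched underdamped Langevin (BAOAB) with first-passage detection,
// stochastic resetting hooks and a per-walker well-tempered Metadynamics
// bias on a 1D (optionally rotated) collective variable.
//
// Internal units: length A, time fs, mass g/mol. Energies are expressed in
// multiples of k_BT; the single conversion constant below folds k_B into
// the internal unit system (1 internal energy unit = 1e4 kJ/mol).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KB_INTERNAL = 8.3144621e-7; // g/mol * A^2/fs^2 per K

// ---------------------------------------------------------------- surfaces

enum SurfaceType { SURF_MFE = 1, SURF_DWELL = 2, SURF_LINEAR = 3 };

struct Surface {
  int type;
  // mfe: U = A1*(x^6 + yc^6) + A2*exp(-x^2/s1^2)*(1 - B*exp(-ys^2/s2^2)),
  // yc = yscale*y (confinement), ys = saddle_yscale*y.  Units of U: k_BT.
  double A1, A2, B, s1sq, s2sq, yscale, syscale;
  // double well: U = h*((x/a)^2 - 1)^2 + 0.5*ky*y^2
  double h, a, ky;
  // linear: U = gx*x + 0.5*ky*y^2
  double gx;
};

Surface parse_surface(List s) {
  Surface out;
  std::string name = as<std::string>(s["name"]);
  List p = s["params"];
  if (name == "mfe") {
    out.type = SURF_MFE;
    out.A1 = as<double>(p["A1"]);
    out.A2 = as<double>(p["A2"]);
    out.B = as<double>(p["B"]);
    double s1 = as<double>(p["sigma1"]), s2 = as<double>(p["sigma2"]);
    out.s1sq = s1 * s1;
    out.s2sq = s2 * s2;
    out.yscale = as<double>(p["yscale"]);
    out.syscale = p.containsElementNamed("saddle_yscale")
        ? as<double>(p["saddle_yscale"]) : out.yscale;
  } else if (name == "double_well") {
    out.type = SURF_DWELL;
    out.h = as<double>(p["barrier"]);
    out.a = as<double>(p["xmin"]);
    out.ky = as<double>(p["ky"]);
  } else if (name == "linear") {
    out.type = SURF_LINEAR;
    out.gx = as<double>(p["slope"]);
    out.ky = as<double>(p["ky"]);
  } else {
    stop("unknown surface name: '%s'", name.c_str());
  }
  return out;
}

inline double surf_energy(const Surface& s, double x, double y) {
  switch (s.type) {
  case SURF_MFE: {
    double yc = s.yscale * y, ys = s.syscale * y;
    double ex = std::exp(-x * x / s.s1sq);
    double gy = std::exp(-ys * ys / s.s2sq);
    double x2 = x * x, yc2 = yc * yc;
    return s.A1 * (x2 * x2 * x2 + yc2 * yc2 * yc2) + s.A2 * ex * (1.0 - s.B * gy);
  }
  case SURF_DWELL: {
    double u = x / s.a, q = u * u - 1.0;
    return s.h * q * q + 0.5 * s.ky * y * y;
  }
  default:
    return s.gx * x + 0.5 * s.ky * y * y;
  }
}

// dU/dx, dU/dy in k_BT / A
inline void surf_grad(const Surface& s, double x, double y,
                      double& dx, double& dy) {
  switch (s.type) {
  case SURF_MFE: {
    double yc = s.yscale * y, ys = s.syscale * y;
    double ex = std::exp(-x * x / s.s1sq);
    double gy = std::exp(-ys * ys / s.s2sq);
    double x2 = x * x, yc2 = yc * yc;
    dx = 6.0 * s.A1 * x2 * x2 * x -
         s.A2 * (1.0 - s.B * gy) * ex * 2.0 * x / s.s1sq;
    dy = 6.0 * s.A1 * yc2 * yc2 * yc * s.yscale +
         s.A2 * ex * s.B * gy * 2.0 * ys / s.s2sq * s.syscale;
    break;
  }
  case SURF_DWELL: {
    double u = x / s.a, q = u * u - 1.0;
    dx = 4.0 * s.h * q * u / s.a;
    dy = s.ky * y;
    break;
  }
  default:
    dx = s.gx;
    dy = s.ky * y;
  }
}

// [[Rcpp::export]]
NumericVector cpp_surface_energy(List surface, NumericVector x, NumericVector y) {
  Surface s = parse_surface(surface);
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = surf_energy(s, x[i], y[i]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_surface_gradient(List surface, NumericVector x, NumericVector y) {
  Surface s = parse_surface(surface);
  R_xlen_t n = x.size();
  NumericMatrix out(n, 2);
  double dx, dy;
  for (R_xlen_t i = 0; i < n; ++i) {
    surf_grad(s, x[i], y[i], dx, dy);
    out(i, 0) = dx;
    out(i, 1) = dy;
  }
  return out;
}

// ------------------------------------------------------------- metadynamics

struct MetaDParams {
  bool enabled = false;
  int pace = 100;
  double height = 0.5;       // k_BT
  double sigma = 0.15;       // A
  double biasfactor = 10.0;
  double gmin = -8.0, gmax = 8.0, spacing = 0.01;
  double ct = 1.0, st = 0.0; // cos/sin of CV rotation angle
  int ng = 1601;
};

// linear interpolation on the grid, clamped to the boundary nodes
inline double grid_interp(const std::vector<double>& v, const MetaDParams& mp,
                          double cv) {
  double u = (cv - mp.gmin) / mp.spacing;
  if (u <= 0.0) return v.front();
  if (u >= mp.ng - 1) return v.back();
  int i = (int)u;
  double f = u - i;
  return v[i] * (1.0 - f) + v[i + 1] * f;
}

// deposit one well-tempered Gaussian; bias and its analytic derivative are
// accumulated on the grid nodes (PLUMED-style tabulated derivative)
void metad_deposit_kernel(std::vector<double>& bias, std::vector<double>& dbias,
                          const MetaDParams& mp, double cv) {
  double vc = grid_interp(bias, mp, cv);
  double w = mp.height * std::exp(-vc / (mp.biasfactor - 1.0));
  double cvc = cv < mp.gmin ? mp.gmin : (cv > mp.gmax ? mp.gmax : cv);
  double span = 6.0 * mp.sigma;
  int i0 = (int)std::floor((cvc - span - mp.gmin) / mp.spacing);
  int i1 = (int)std::ceil((cvc + span - mp.gmin) / mp.spacing);
  if (i0 < 0) i0 = 0;
  if (i1 > mp.ng - 1) i1 = mp.ng - 1;
  double s2 = mp.sigma * mp.sigma;
  for (int i = i0; i <= i1; ++i) {
    double g = mp.gmin + i * mp.spacing;
    double d = g - cvc;
    double e = w * std::exp(-0.5 * d * d / s2);
    bias[i] += e;
    dbias[i] += -e * d / s2;
  }
}

// R-facing kernels so the package exposes a single implementation
// [[Rcpp::export]]
List cpp_metad_deposit(NumericVector bias, NumericVector dbias, List params,
                       double cv) {
  MetaDParams mp;
  mp.height = as<double>(params["height"]);
  mp.sigma = as<double>(params["sigma"]);
  mp.biasfactor = as<double>(params["biasfactor"]);
  mp.gmin = as<double>(params["grid_min"]);
  mp.gmax = as<double>(params["grid_max"]);
  mp.spacing = as<double>(params["grid_spacing"]);
  mp.ng = bias.size();
  std::vector<double> b(bias.begin(), bias.end());
  std::vector<double> db(dbias.begin(), dbias.end());
  metad_deposit_kernel(b, db, mp, cv);
  return List::create(_["bias"] = NumericVector(b.begin(), b.end()),
                      _["dbias"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
NumericVector cpp_metad_interp(NumericVector table, List params, NumericVector cv) {
  MetaDParams mp;
  mp.gmin = as<double>(params["grid_min"]);
  mp.gmax = as<double>(params["grid_max"]);
  mp.spacing = as<double>(params["grid_spacing"]);
  mp.ng = table.size();
  std::vector<double> v(table.begin(), table.end());
  NumericVector out(cv.size());
  for (R_xlen_t i = 0; i < cv.size(); ++i) out[i] = grid_interp(v, mp, cv[i]);
  return out;
}

// ------------------------------------------------------------ batched runs

struct ResetParams {
  bool enabled = false;
  double rate_fs = 0.0;     // events per fs
  bool conditional = false; // false: standard SR (always reset)
  double threshold = 0.0;   // on the protocol CV
  bool greater = true;      // reset if cv > threshold
  double ct = 1.0, st = 0.0;
};

// [[Rcpp::export]]
List cpp_run_until_fpt(List surface, List config, List stop_cfg, List protocol,
                       List metad, int n_walkers, double init_x, double init_y,
                       int record_stride, double record_ct, double record_st,
                       int seed, int walker_offset) {
  Surface s = parse_surface(surface);

  const double dt = as<double>(config["timestep"]);
  const double gamma = as<double>(config["friction"]);
  const double mass = as<double>(config["mass"]);
  const double kT = KB_INTERNAL * as<double>(config["temperature"]);
  const double max_steps_d = as<double>(config["max_steps"]);
  const long long max_steps = (long long)max_steps_d;
  const int check_stride = as<int>(config["fpt_check_stride"]);

  const double stop_thr = as<double>(stop_cfg["threshold"]);
  const bool stop_below = as<bool>(stop_cfg["below"]);
  const double stop_ct = as<double>(stop_cfg["ct"]);
  const double stop_st = as<double>(stop_cfg["st"]);

  ResetParams rp;
  if (protocol.size() > 0) {
    double rate_ns = as<double>(protocol["rate_ns"]);
    if (rate_ns > 0) {
      rp.enabled = true;
      rp.rate_fs = rate_ns * 1e-6;
      rp.conditional = as<bool>(protocol["conditional"]);
      rp.threshold = as<double>(protocol["threshold"]);
      rp.greater = as<bool>(protocol["greater"]);
      rp.ct = as<double>(protocol["ct"]);
      rp.st = as<double>(protocol["st"]);
    }
  }

  MetaDParams mp;
  if (metad.size() > 0) {
    mp.enabled = true;
    mp.pace = as<int>(metad["pace"]);
    mp.height = as<double>(metad["height"]);
    mp.sigma = as<double>(metad["sigma"]);
    mp.biasfactor = as<double>(metad["biasfactor"]);
    mp.gmin = as<double>(metad["grid_min"]);
    mp.gmax = as<double>(metad["grid_max"]);
    mp.spacing = as<double>(metad["grid_spacing"]);
    mp.ct = as<double>(metad["ct"]);
    mp.st = as<double>(metad["st"]);
    mp.ng = (int)std::lround((mp.gmax - mp.gmin) / mp.spacing) + 1;
  }
  bool keep_bias = mp.enabled && metad.containsElementNamed("keep_bias") &&
                   as<bool>(metad["keep_bias"]);

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT / mass);
  const double vsd = std::sqrt(kT / mass);

  NumericVector fpt_fs(n_walkers, NA_REAL);
  NumericVector nsteps(n_walkers);
  IntegerVector nresets(n_walkers);
  LogicalVector censored(n_walkers);
  List cv_series(record_stride > 0 ? n_walkers : 0);
  List reset_steps(rp.enabled ? n_walkers : 0);
  List bias_tables(keep_bias ? n_walkers : 0);

  std::vector<double> bias, dbias;
  if (mp.enabled) {
    bias.resize(mp.ng);
    dbias.resize(mp.ng);
  }

  for (int w = 0; w < n_walkers; ++w) {
    std::seed_seq sq{seed, walker_offset + w};
    std::mt19937_64 rng(sq);
    std::normal_distribution<double> gauss(0.0, 1.0);
    std::exponential_distribution<double> rexp(rp.rate_fs > 0 ? rp.rate_fs : 1.0);

    double x = init_x, y = init_y;
    double vx = vsd * gauss(rng), vy = vsd * gauss(rng);
    double gx, gy;
    surf_grad(s, x, y, gx, gy);
    double fx = -kT * gx, fy = -kT * gy;
    if (mp.enabled) {
      std::fill(bias.begin(), bias.end(), 0.0);
      std::fill(dbias.begin(), dbias.end(), 0.0);
    }
    long long seg_step = 0;
    double next_reset = rp.enabled ? rexp(rng) : 0.0;
    std::vector<double> rec;
    std::vector<int> rsteps;
    if (record_stride > 0 && max_steps / record_stride < 50000000)
      rec.reserve((size_t)std::min<long long>(max_steps / record_stride + 1, 1 << 20));

    long long step = 0;
    bool done = false;
    while (step < max_steps && !done) {
      ++step;
      ++seg_step;
      // BAOAB
      vx += 0.5 * dt * fx / mass;
      vy += 0.5 * dt * fy / mass;
      x += 0.5 * dt * vx;
      y += 0.5 * dt * vy;
      vx = c1 * vx + c2 * gauss(rng);
      vy = c1 * vy + c2 * gauss(rng);
      x += 0.5 * dt * vx;
      y += 0.5 * dt * vy;
      surf_grad(s, x, y, gx, gy);
      fx = -kT * gx;
      fy = -kT * gy;
      if (mp.enabled) {
        double cv = mp.ct * x + mp.st * y;
        if (seg_step % mp.pace == 0) metad_deposit_kernel(bias, dbias, mp, cv);
        double dv = grid_interp(dbias, mp, cv) * kT;
        fx += -dv * mp.ct;
        fy += -dv * mp.st;
      }
      vx += 0.5 * dt * fx / mass;
      vy += 0.5 * dt * fy / mass;
      if (!std::isfinite(x) || !std::isfinite(y))
        stop("non-finite position encountered (walker %d, step %lld)",
             walker_offset + w, step);
      double t = step * dt;
      if (rp.enabled) {
        while (next_reset <= t) {
          bool fire = true;
          if (rp.conditional) {
            double cv = rp.ct * x + rp.st * y;
            fire = rp.greater ? (cv > rp.threshold) : (cv < rp.threshold);
          }
          if (fire) {
            x = init_x;
            y = init_y;
            vx = vsd * gauss(rng);
            vy = vsd * gauss(rng);
            surf_grad(s, x, y, gx, gy);
            fx = -kT * gx;
            fy = -kT * gy;
            if (mp.enabled) {
              std::fill(bias.begin(), bias.end(), 0.0);
              std::fill(dbias.begin(), dbias.end(), 0.0);
            }
            seg_step = 0;
            nresets[w] += 1;
            if (step <= INT_MAX) rsteps.push_back((int)step);
          }
          next_reset = t + rexp(rng);
        }
      }
      if (record_stride > 0 && step % record_stride == 0)
        rec.push_back(record_ct * x + record_st * y);
      if (step % check_stride == 0) {
        double cvs = stop_ct * x + stop_st * y;
        if (stop_below ? (cvs < stop_thr) : (cvs > stop_thr)) {
          fpt_fs[w] = t;
          done = true;
        }
      }
    }
    nsteps[w] = (double)step;
    censored[w] = !done;
    if (record_stride > 0)
      cv_series[w] = NumericVector(rec.begin(), rec.end());
    if (rp.enabled)
      reset_steps[w] = IntegerVector(rsteps.begin(), rsteps.end());
    if (keep_bias)
      bias_tables[w] = NumericVector(bias.begin(), bias.end());
    if (w % 8 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["fpt_fs"] = fpt_fs, _["n_steps"] = nsteps,
                      _["n_resets"] = nresets, _["censored"] = censored,
                      _["cv_series"] = cv_series, _["reset_steps"] = reset_steps,
                      _["bias_tables"] = bias_tables);
}

// Fixed-length sampling run recording positions and velocities; used for
// thermodynamic fidelity checks (equipartition, Boltzmann marginals) and
// for generating CV series without a stopping condition.
// [[Rcpp::export]]
List cpp_sample_trajectory(List surface, List config, double init_x,
                           double init_y, double n_steps_d, int record_stride,
                           int seed, int walker_id) {
  Surface s = parse_surface(surface);
  const double dt = as<double>(config["timestep"]);
  const double gamma = as<double>(config["friction"]);
  const double mass = as<double>(config["mass"]);
  const double kT = KB_INTERNAL * as<double>(config["temperature"]);
  long long n_steps = (long long)n_steps_d;

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT / mass);
  const double vsd = std::sqrt(kT / mass);

  std::seed_seq sq{seed, walker_id};
  std::mt19937_64 rng(sq);
  std::normal_distribution<double> gauss(0.0, 1.0);

  double x = init_x, y = init_y;
  double vx = vsd * gauss(rng), vy = vsd * gauss(rng);
  double gx, gy;
  surf_grad(s, x, y, gx, gy);
  double fx = -kT * gx, fy = -kT * gy;

  long long nrec = n_steps / record_stride;
  NumericVector ox(nrec), oy(nrec), ovx(nrec), ovy(nrec);
  long long k = 0;
  for (long long step = 1; step <= n_steps; ++step) {
    vx += 0.5 * dt * fx / mass;
    vy += 0.5 * dt * fy / mass;
    x += 0.5 * dt * vx;
    y += 0.5 * dt * vy;
    if (gamma > 0) {
      vx = c1 * vx + c2 * gauss(rng);
      vy = c1 * vy + c2 * gauss(rng);
    }
    x += 0.5 * dt * vx;
    y += 0.5 * dt * vy;
    surf_grad(s, x, y, gx, gy);
    fx = -kT * gx;
    fy = -kT * gy;
    vx += 0.5 * dt * fx / mass;
    vy += 0.5 * dt * fy / mass;
    if (step % record_stride == 0 && k < nrec) {
      ox[k] = x;
      oy[k] = y;
      ovx[k] = vx;
      ovy[k] = vy;
      ++k;
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["x"] = ox, _["y"] = oy, _["vx"] = ovx, _["vy"] = ovy);
}

// Survival-product accumulator for the reset-reweighting predictor.
// Given one strided CV series (reset trials at times j*stride_dt,
// j = 1..K, K excluding the first-passage step itself), the resetting
// probability per retained step p = (1 - exp(-r*stride_dt)) applied where
// indicator holds, returns the pieces of the per-trajectory sums.
// [[Rcpp::export]]
NumericVector cpp_survival_terms(NumericVector cv, double p, double threshold,
                                 bool greater, double stride_dt) {
  R_xlen_t n = cv.size();
  double psi = 1.0;       // survival up to (before) trial j
  double sum_jpsi = 0.0;  // sum over j of (j*stride_dt) * Psi(j) * p_j
  for (R_xlen_t j = 0; j < n; ++j) {
    bool ind = greater ? (cv[j] > threshold) : (cv[j] < threshold);
    if (ind) {
      double pj = p * psi;
      sum_jpsi += (j + 1) * stride_dt * pj;
      psi *= (1.0 - p);
      if (psi < 1e-300) { psi = 0.0; break; }
    }
  }
  return NumericVector::create(psi, sum_jpsi);
}
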