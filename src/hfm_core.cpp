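// Compiled kernels: fixed-step RK4 (deterministic and additive-noise),
// steady-state location (1-D bracketing + Newton polish; multi-start Newton
// for >= 2 states), trajectory observables, hybrid-fitness target weights and
// the Metropolis-Hastings loop.  All randomness uses R's RNG so set.seed()
// in R governs every draw.
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double STAB_BAND = 1e-8;   // |Re lambda| below this => marginal
static const double ROOT_TOL  = 1e-10;  // residual tolerance for a verified root
static const double DEDUP_R   = 1e-6;   // merge radius for duplicate roots

static inline double pow5(double y) { double t = y * y; return t * t * y; }

// ---- built-in models --------------------------------------------------------
// id 1: toy Hill-feedback model, 1 state, pars (k_d, k_p, K), Hill n = 5 fixed
//       dy/dt = input - k_d*y + k_p*y^5/(K^5 + y^5)
// id 2: two-variable bistable fixture, pars (alpha, beta)
//       du/dt = input + alpha*v^2/(1+v^2) - u ; dv/dt = beta*u - v

static inline int model_dim(int id) { return id == 2 ? 2 : 1; }

static inline void model_rhs(int id, const double* y, const double* p,
                             double input, double* dy) {
  if (id == 1) {
    double K5 = pow5(p[2]), y5 = pow5(y[0]);
    dy[0] = input - p[0] * y[0] + p[1] * y5 / (K5 + y5);
  } else {
    double v = y[1], h = v * v / (1.0 + v * v);
    dy[0] = input + p[0] * h - y[0];
    dy[1] = p[1] * y[0] - y[1];
  }
}

// column-major d x d Jacobian
static inline void model_jac(int id, const double* y, const double* p,
                             double input, double* J) {
  (void)input;
  if (id == 1) {
    double K5 = pow5(p[2]);
    double y2 = y[0] * y[0], y4 = y2 * y2, y5 = y4 * y[0];
    double den = K5 + y5;
    J[0] = -p[0] + p[1] * 5.0 * K5 * y4 / (den * den);
  } else {
    double v = y[1], den = 1.0 + v * v;
    J[0] = -1.0;  J[2] = p[0] * 2.0 * v / (den * den);
    J[1] = p[1];  J[3] = -1.0;
  }
}

// ---- RK4 --------------------------------------------------------------------

// out is (nsteps+1) x d column-major; returns index of first bad step or -1
static int rk4_fill(int id, const double* p, double input, const double* y0,
                    double dt, int nsteps, double* out, double noise_sd) {
  int d = model_dim(id);
  double y[2], k1[2], k2[2], k3[2], k4[2], tmp[2];
  for (int j = 0; j < d; ++j) { y[j] = y0[j]; out[j * (nsteps + 1)] = y[j]; }
  double sq = noise_sd * std::sqrt(dt);
  for (int i = 1; i <= nsteps; ++i) {
    model_rhs(id, y, p, input, k1);
    for (int j = 0; j < d; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    model_rhs(id, tmp, p, input, k2);
    for (int j = 0; j < d; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    model_rhs(id, tmp, p, input, k3);
    for (int j = 0; j < d; ++j) tmp[j] = y[j] + dt * k3[j];
    model_rhs(id, tmp, p, input, k4);
    for (int j = 0; j < d; ++j) {
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (noise_sd > 0.0) {
        y[j] += sq * norm_rand();
        if (y[j] < 0.0) y[j] = 0.0;  // concentrations stay non-negative
      }
      if (!std::isfinite(y[j])) return i;
      out[j * (nsteps + 1) + i] = y[j];
    }
  }
  return -1;
}

// [[Rcpp::export]]
NumericMatrix cpp_rk4(int model, NumericVector pars, double input,
                      NumericVector y0, double dt, int nsteps,
                      double noise_sd = 0.0) {
  int d = model_dim(model);
  if ((int)y0.size() != d) stop("y0 has wrong length for model");
  NumericMatrix out(nsteps + 1, d);
  int bad = rk4_fill(model, pars.begin(), input, y0.begin(), dt, nsteps,
                     out.begin(), noise_sd);
  if (bad >= 0) stop("non-finite state at integration step %d", bad);
  return out;
}

// ---- steady states ----------------------------------------------------------

struct Root1d { double y, fp; };

// bracket on a regular grid, refine by bisection, polish by Newton
static std::vector<Root1d> steady_1d(int id, const double* p, double input,
                                     double lo, double hi, int n_grid) {
  std::vector<double> raw;
  double step = (hi - lo) / n_grid;
  double fprev, fcur, yprev = lo, dy;
  model_rhs(id, &yprev, p, input, &fprev);
  if (fprev == 0.0) raw.push_back(yprev);
  for (int i = 1; i <= n_grid; ++i) {
    double yc = lo + step * i;
    model_rhs(id, &yc, p, input, &fcur);
    if (fcur == 0.0) {
      raw.push_back(yc);
    } else if (fprev != 0.0 && ((fprev > 0) != (fcur > 0))) {
      double a = yprev, b = yc, fa = fprev;
      for (int it = 0; it < 100 && (b - a) > 1e-14 * std::max(1.0, std::fabs(b)); ++it) {
        double m = 0.5 * (a + b), fm;
        model_rhs(id, &m, p, input, &fm);
        if (fm == 0.0) { a = b = m; break; }
        if ((fm > 0) == (fa > 0)) { a = m; fa = fm; } else { b = m; }
      }
      raw.push_back(0.5 * (a + b));
    }
    yprev = yc; fprev = fcur;
  }
  std::vector<Root1d> out;
  for (double r : raw) {
    for (int it = 0; it < 5; ++it) {       // Newton polish
      double f, fp;
      model_rhs(id, &r, p, input, &f);
      model_jac(id, &r, p, input, &fp);
      if (fp == 0.0) break;
      double rn = r - f / fp;
      if (!std::isfinite(rn) || rn < lo - step || rn > hi + step) break;
      r = rn;
    }
    double f, fp;
    model_rhs(id, &r, p, input, &f);
    if (std::fabs(f) > ROOT_TOL) continue;  // not a verified root
    model_jac(id, &r, p, input, &fp);
    bool dup = false;
    for (auto& q : out) if (std::fabs(q.y - r) < DEDUP_R) { dup = true; break; }
    if (!dup) out.push_back({r, fp});
  }
  std::sort(out.begin(), out.end(),
            [](const Root1d& a, const Root1d& b) { return a.y < b.y; });
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_steady_1d(int model, NumericVector pars, double input,
                            double lo, double hi, int n_grid) {
  auto r = steady_1d(model, pars.begin(), input, lo, hi, n_grid);
  NumericMatrix out(r.size(), 2);
  for (size_t i = 0; i < r.size(); ++i) { out(i, 0) = r[i].y; out(i, 1) = r[i].fp; }
  colnames(out) = CharacterVector::create("state", "jacobian");
  return out;
}

// multi-start Newton for d >= 1; starts on a regular grid of n_per_dim^d points
// [[Rcpp::export]]
List cpp_steady_nd(int model, NumericVector pars, double input,
                   NumericVector lo, NumericVector hi, int n_per_dim,
                   int max_iter = 100) {
  int d = model_dim(model);
  arma::vec y(d), f(d), dy_(d);
  arma::mat J(d, d);
  std::vector<arma::vec> roots;
  int nstart = 1;
  for (int j = 0; j < d; ++j) nstart *= n_per_dim;
  for (int s = 0; s < nstart; ++s) {
    int rem = s;
    for (int j = 0; j < d; ++j) {
      int ij = rem % n_per_dim; rem /= n_per_dim;
      y(j) = lo[j] + (hi[j] - lo[j]) *
             (n_per_dim == 1 ? 0.5 : (double)ij / (n_per_dim - 1));
    }
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      model_rhs(model, y.memptr(), pars.begin(), input, f.memptr());
      if (!f.is_finite()) break;
      if (arma::norm(f, "inf") <= ROOT_TOL) { ok = true; break; }
      model_jac(model, y.memptr(), pars.begin(), input, J.memptr());
      bool solved = arma::solve(dy_, J, -f, arma::solve_opts::no_approx);
      if (!solved || !dy_.is_finite()) break;   // singular Jacobian: abandon
      y += dy_;
    }
    if (!ok) continue;
    bool inbox = true;   // roots outside the bracket (e.g. negative
    for (int j = 0; j < d; ++j)          // concentrations) are discarded
      if (y(j) < lo[j] - 1e-9 || y(j) > hi[j] + 1e-9) inbox = false;
    if (!inbox) continue;
    bool dup = false;
    for (auto& r : roots) if (arma::norm(y - r, 2) < DEDUP_R) { dup = true; break; }
    if (!dup) roots.push_back(y);
  }
  std::sort(roots.begin(), roots.end(),
            [](const arma::vec& a, const arma::vec& b) { return a(0) < b(0); });
  NumericMatrix states(roots.size(), d);
  NumericMatrix eig_re(roots.size(), d), eig_im(roots.size(), d);
  NumericVector max_re(roots.size());
  for (size_t i = 0; i < roots.size(); ++i) {
    for (int j = 0; j < d; ++j) states(i, j) = roots[i](j);
    model_jac(model, roots[i].memptr(), pars.begin(), input, J.memptr());
    arma::cx_vec ev;
    arma::eig_gen(ev, J);
    double mr = -INFINITY;
    for (int j = 0; j < d; ++j) {
      eig_re(i, j) = ev(j).real(); eig_im(i, j) = ev(j).imag();
      mr = std::max(mr, ev(j).real());
    }
    max_re[i] = mr;
  }
  return List::create(_["states"] = states, _["max_re"] = max_re,
                      _["eig_re"] = eig_re, _["eig_im"] = eig_im);
}

// ---- observables ------------------------------------------------------------
// codes: 0 execution time (p1 = fraction), 1 endpoint value (p1 = time),
//        2 switching time (p1 = lo, p2 = hi); 3/4 (parameter observables)
//        are handled at the weight level, not here.

static double traj_observable(const double* y, int n1, double dt,
                              int code, double p1, double p2) {
  if (code == 1) {
    int idx = (int)std::lround(p1 / dt);
    if (idx < 0 || idx >= n1) return NA_REAL;
    return y[idx];
  }
  double m = y[0];
  for (int i = 1; i < n1; ++i) if (y[i] > m) m = y[i];
  auto first_cross = [&](double thr) {
    for (int i = 0; i < n1; ++i) if (y[i] >= thr) return i * dt;
    return NA_REAL;
  };
  if (code == 0) return first_cross(p1 * m);
  double tlo = first_cross(p1 * m), thi = first_cross(p2 * m);
  if (!std::isfinite(tlo) || !std::isfinite(thi)) return NA_REAL;
  return thi - tlo;
}

// [[Rcpp::export]]
NumericVector cpp_traj_observables(NumericMatrix traj, double dt,
                                   IntegerVector code, IntegerVector state,
                                   NumericVector p1, NumericVector p2) {
  int n1 = traj.nrow(), m = code.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k)
    out[k] = traj_observable(&traj(0, state[k]), n1, dt, code[k], p1[k], p2[k]);
  return out;
}

// observables over an ensemble of noisy replicates (trajectories discarded)
// [[Rcpp::export]]
NumericMatrix cpp_noisy_ensemble(int model, NumericVector pars, double input,
                                 NumericVector y0, double dt, int nsteps,
                                 double noise_sd, int n_rep,
                                 IntegerVector code, IntegerVector state,
                                 NumericVector p1, NumericVector p2) {
  int d = model_dim(model), m = code.size();
  std::vector<double> buf((nsteps + 1) * d);
  NumericMatrix out(n_rep, m);
  for (int r = 0; r < n_rep; ++r) {
    int bad = rk4_fill(model, pars.begin(), input, y0.begin(), dt, nsteps,
                       buf.data(), noise_sd);
    for (int k = 0; k < m; ++k)
      out(r, k) = bad >= 0 ? NA_REAL
        : traj_observable(buf.data() + state[k] * (nsteps + 1), nsteps + 1, dt,
                          code[k], p1[k], p2[k]);
  }
  return out;
}

// ---- hybrid-fitness target --------------------------------------------------

struct Fitness {
  int type;       // 0 histogram, 1 log-normal
  int obs_code;   // 0 T_e, 1 endpoint, 2 T_s, 3 param(log10), 4 param(linear)
  int state;      // trajectory column (obs 0-2)
  int par_idx;    // parameter index (obs 3-4)
  double p1, p2;  // observable parameters
  std::vector<double> edges, freq;
  double mu, sigma;
};

struct Problem {
  int model;                     // 0 = no dynamics/bifurcation (pure prior)
  int np;                        // sampled parameters
  std::vector<double> lower, upper;        // log10 prior box
  int grid_n;                              // 1-D steady-state grid resolution
  std::vector<double> cl_input;            // unique condition clauses
  std::vector<int> cl_ns, cl_nu;
  double sim_input, sim_dt; int sim_nsteps;
  std::vector<double> sim_y0;
  bool need_dyn;
  std::vector<Fitness> fit;
};

static Problem parse_problem(List P) {
  Problem pr;
  pr.model = as<int>(P["model"]);
  pr.lower = as<std::vector<double>>(P["lower"]);
  pr.upper = as<std::vector<double>>(P["upper"]);
  pr.np = pr.lower.size();
  if (pr.np > 16) stop("compiled engine supports at most 16 parameters");
  pr.grid_n = as<int>(P["grid_n"]);
  pr.cl_input = as<std::vector<double>>(P["clause_input"]);
  pr.cl_ns = as<std::vector<int>>(P["clause_ns"]);
  pr.cl_nu = as<std::vector<int>>(P["clause_nu"]);
  pr.sim_input = as<double>(P["sim_input"]);
  pr.sim_dt = as<double>(P["sim_dt"]);
  pr.sim_nsteps = as<int>(P["sim_nsteps"]);
  pr.sim_y0 = as<std::vector<double>>(P["sim_y0"]);
  List fl = P["fitness"];
  pr.need_dyn = false;
  for (int i = 0; i < fl.size(); ++i) {
    List f = fl[i];
    Fitness ft;
    ft.type = as<int>(f["type"]);
    ft.obs_code = as<int>(f["obs_code"]);
    ft.state = as<int>(f["state"]);
    ft.par_idx = as<int>(f["par_idx"]);
    ft.p1 = as<double>(f["p1"]); ft.p2 = as<double>(f["p2"]);
    if (ft.type == 0) {
      ft.edges = as<std::vector<double>>(f["edges"]);
      ft.freq = as<std::vector<double>>(f["freq"]);
      ft.mu = ft.sigma = 0.0;
    } else {
      ft.mu = as<double>(f["mu"]); ft.sigma = as<double>(f["sigma"]);
    }
    if (ft.obs_code <= 2) pr.need_dyn = true;
    pr.fit.push_back(ft);
  }
  return pr;
}

static double eval_hist(const std::vector<double>& e,
                        const std::vector<double>& fr, double z) {
  int n = fr.size();
  if (!(z >= e.front()) || z > e.back()) return 0.0;
  if (z == e.back()) return fr[n - 1];
  int i = std::upper_bound(e.begin(), e.end(), z) - e.begin() - 1;
  if (i < 0 || i >= n) return 0.0;
  return fr[i];
}

static double eval_lnorm(double mu, double sigma, double z) {
  if (z <= 0.0) return 0.0;
  double u = (std::log(z) - mu) / sigma;
  return std::exp(-0.5 * u * u) / (z * sigma * std::sqrt(2.0 * M_PI));
}

// target weight for a log10 parameter vector; qualitative conditions first,
// dynamics only when some fitness needs a trajectory.  Exact-count clause
// semantics; any marginal steady state fails the clause.
static double target_weight(const Problem& pr, const double* th,
                            std::vector<double>* buf) {
  for (int j = 0; j < pr.np; ++j)
    if (th[j] < pr.lower[j] || th[j] > pr.upper[j]) return 0.0;
  double lin[16];
  for (int j = 0; j < pr.np; ++j) lin[j] = std::pow(10.0, th[j]);
  if (pr.model == 1) {
    for (size_t c = 0; c < pr.cl_input.size(); ++c) {
      // all toy roots lie in [0, (input + k_p)/k_d]
      double hi = (pr.cl_input[c] + lin[1]) / lin[0] + 1.0;
      auto roots = steady_1d(1, lin, pr.cl_input[c], 0.0, hi, pr.grid_n);
      int ns = 0, nu = 0, nm = 0;
      for (auto& r : roots) {
        if (std::fabs(r.fp) <= STAB_BAND) ++nm;
        else if (r.fp < 0) ++ns;
        else ++nu;
      }
      if (nm > 0 || ns != pr.cl_ns[c] || nu != pr.cl_nu[c]) return 0.0;
    }
  }
  double w = 1.0;
  if (!pr.fit.empty()) {
    const double* traj = nullptr;
    int n1 = pr.sim_nsteps + 1;
    if (pr.need_dyn) {
      buf->assign(n1 * model_dim(pr.model), 0.0);
      int bad = rk4_fill(pr.model, lin, pr.sim_input, pr.sim_y0.data(),
                         pr.sim_dt, pr.sim_nsteps, buf->data(), 0.0);
      if (bad >= 0) return 0.0;  // integration failure => zero weight
      traj = buf->data();
    }
    for (auto& ft : pr.fit) {
      double z;
      if (ft.obs_code == 3) z = th[ft.par_idx];
      else if (ft.obs_code == 4) z = lin[ft.par_idx];
      else z = traj_observable(traj + ft.state * n1, n1, pr.sim_dt,
                               ft.obs_code, ft.p1, ft.p2);
      if (!std::isfinite(z)) return 0.0;
      w *= ft.type == 0 ? eval_hist(ft.edges, ft.freq, z)
                        : eval_lnorm(ft.mu, ft.sigma, z);
      if (w == 0.0) return 0.0;
    }
  }
  return w;
}

// [[Rcpp::export]]
double cpp_target_weight(List P, NumericVector theta_log10) {
  Problem pr = parse_problem(P);
  if ((int)theta_log10.size() != pr.np) stop("theta has wrong length");
  std::vector<double> buf;
  return target_weight(pr, theta_log10.begin(), &buf);
}

// ---- Metropolis-Hastings loop ----------------------------------------------

// [[Rcpp::export]]
List cpp_mcmc(List P, NumericVector theta0, double n_steps, double burn_in,
              int thin, double sigma_q, int proposal_kind) {
  Problem pr = parse_problem(P);
  int d = pr.np;
  std::vector<double> buf, cur(theta0.begin(), theta0.end()), cand(d);
  double wcur = target_weight(pr, cur.data(), &buf);
  if (!(wcur > 0.0)) stop("initial state has zero target weight");
  long long N = (long long)n_steps, B = (long long)burn_in;
  long long nrec = (N - B) / thin;
  NumericMatrix samples(nrec, d);
  NumericVector weights(nrec);
  IntegerVector acc(d), prop(d);
  long long r = 0;
  for (long long i = 1; i <= N; ++i) {
    int j = (int)(unif_rand() * d);
    if (j >= d) j = d - 1;
    double delta = proposal_kind == 0 ? sigma_q * (2.0 * unif_rand() - 1.0)
                                      : sigma_q * norm_rand();
    std::copy(cur.begin(), cur.end(), cand.begin());
    cand[j] += delta;
    ++prop[j];
    if (cand[j] >= pr.lower[j] && cand[j] <= pr.upper[j]) {
      double wc = target_weight(pr, cand.data(), &buf);
      if (wc > 0.0 && (wc >= wcur || unif_rand() < wc / wcur)) {
        cur[j] = cand[j]; wcur = wc; ++acc[j];
      }
    }
    if (i > B && (i - B) % thin == 0 && r < nrec) {
      for (int k = 0; k < d; ++k) samples(r, k) = cur[k];
      weights[r] = wcur;
      ++r;
    }
    if ((i & 0xFFFF) == 0) checkUserInterrupt();
  }
  return List::create(_["samples"] = samples, _["weights"] = weights,
                      _["accept"] = acc, _["propose"] = prop);
}

// deterministic observables for many parameter vectors (posterior predictive)
// [[Rcpp::export]]
NumericMatrix cpp_predict_observables(int model, NumericMatrix theta_log10,
                                      double input, NumericVector y0,
                                      double dt, int nsteps,
                                      IntegerVector code, IntegerVector state,
                                      NumericVector p1, NumericVector p2) {
  int d = model_dim(model), n = theta_log10.nrow(), m = code.size();
  std::vector<double> buf((nsteps + 1) * d), lin(theta_log10.ncol());
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < (int)lin.size(); ++j)
      lin[j] = std::pow(10.0, theta_log10(i, j));
    int bad = rk4_fill(model, lin.data(), input, y0.begin(), dt, nsteps,
                       buf.data(), 0.0);
    for (int k = 0; k < m; ++k)
      out(i, k) = bad >= 0 ? NA_REAL
        : traj_observable(buf.data() + state[k] * (nsteps + 1), nsteps + 1, dt,
                          code[k], p1[k], p2[k]);
  }
  return out;
}
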