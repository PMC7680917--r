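#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Illumination term phi_j(t) = amp * (offset + tanh(-steepness * (t - t_ilum))).
// tanh saturates to +/-1 well within double precision for |arg| > 19, so the
// hyperbolic tangent is only evaluated near the switch-off time.
static inline double phi_at(double t, double t_ilum, double amp, double offset,
                            double steep) {
  double z = -steep * (t - t_ilum);
  if (z > 19.0) return amp * (offset + 1.0);
  if (z < -19.0) return amp * (offset - 1.0);
  return amp * (offset + std::tanh(z));
}

struct NetRHS {
  int n;
  double inv_eps, q, f, alpha, beta;
  double amp, offset, steep;
  const double *t_ilum;      // length n; ignored when phi_const >= 0
  double phi_const;          // < 0 means "use the schedule"
  const int *adj;            // n x n column-major 0/1, empty diagonal
  std::vector<int> degree;

  void init_degree() {
    degree.assign(n, 0);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        if (i != j && adj[i + n * j]) degree[j]++;
  }

  void operator()(const double *u, const double *v, double t, double *du,
                  double *dv) const {
    for (int j = 0; j < n; ++j) {
      double ph = (phi_const >= 0.0)
                      ? phi_const
                      : phi_at(t, t_ilum[j], amp, offset, steep);
      double uj = u[j];
      double kin = inv_eps * (uj - uj * uj -
                              (f * v[j] + ph) * (uj - q) / (uj + q));
      double coup = 0.0;
      if (beta > 0.0) {
        double s = 0.0;
        for (int i = 0; i < n; ++i)
          if (i != j && adj[i + n * j]) s += u[i];
        coup = beta * (s - degree[j] * uj);
      }
      du[j] = kin - alpha * uj + coup;
      dv[j] = uj - v[j];
    }
  }
};

static inline void rk4_step(const NetRHS &rhs, std::vector<double> &u,
                            std::vector<double> &v, double t, double h,
                            std::vector<double> &k1u, std::vector<double> &k1v,
                            std::vector<double> &k2u, std::vector<double> &k2v,
                            std::vector<double> &k3u, std::vector<double> &k3v,
                            std::vector<double> &k4u, std::vector<double> &k4v,
                            std::vector<double> &tu, std::vector<double> &tv) {
  int n = rhs.n;
  rhs(u.data(), v.data(), t, k1u.data(), k1v.data());
  for (int j = 0; j < n; ++j) {
    tu[j] = u[j] + 0.5 * h * k1u[j];
    tv[j] = v[j] + 0.5 * h * k1v[j];
  }
  rhs(tu.data(), tv.data(), t + 0.5 * h, k2u.data(), k2v.data());
  for (int j = 0; j < n; ++j) {
    tu[j] = u[j] + 0.5 * h * k2u[j];
    tv[j] = v[j] + 0.5 * h * k2v[j];
  }
  rhs(tu.data(), tv.data(), t + 0.5 * h, k3u.data(), k3v.data());
  for (int j = 0; j < n; ++j) {
    tu[j] = u[j] + h * k3u[j];
    tv[j] = v[j] + h * k3v[j];
  }
  rhs(tu.data(), tv.data(), t + h, k4u.data(), k4v.data());
  for (int j = 0; j < n; ++j) {
    u[j] += h / 6.0 * (k1u[j] + 2.0 * (k2u[j] + k3u[j]) + k4u[j]);
    v[j] += h / 6.0 * (k1v[j] + 2.0 * (k2v[j] + k3v[j]) + k4v[j]);
  }
}

static inline bool state_bad(const std::vector<double> &u,
                             const std::vector<double> &v) {
  for (size_t j = 0; j < u.size(); ++j) {
    if (!std::isfinite(u[j]) || !std::isfinite(v[j])) return true;
    if (std::fabs(u[j]) > 1e3 || std::fabs(v[j]) > 1e3) return true;
    if (u[j] < -1e-6) return true;
  }
  return false;
}

// [[Rcpp::export]]
List rk4_trajectory_cpp(NumericVector u0, NumericVector v0,
                        NumericVector t_ilum, double amp, double offset,
                        double steep, double phi_const, double eps, double q,
                        double f, double alpha, double beta,
                        IntegerMatrix adjacency, double h, int nsteps,
                        int stride) {
  int n = u0.size();
  NetRHS rhs;
  rhs.n = n;
  rhs.inv_eps = 1.0 / eps;
  rhs.q = q;
  rhs.f = f;
  rhs.alpha = alpha;
  rhs.beta = beta;
  rhs.amp = amp;
  rhs.offset = offset;
  rhs.steep = steep;
  rhs.t_ilum = t_ilum.begin();
  rhs.phi_const = phi_const;
  rhs.adj = adjacency.begin();
  rhs.init_degree();

  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> k1u(n), k1v(n), k2u(n), k2v(n), k3u(n), k3v(n), k4u(n),
      k4v(n), tu(n), tv(n);

  int nstored = nsteps / stride + 1 + (nsteps % stride != 0 ? 1 : 0);
  NumericVector times(nstored);
  NumericMatrix um(nstored, n), vm(nstored, n);
  int row = 0;
  times[row] = 0.0;
  for (int j = 0; j < n; ++j) {
    um(row, j) = u[j];
    vm(row, j) = v[j];
  }
  ++row;

  for (int i = 0; i < nsteps; ++i) {
    double t = i * h;
    rk4_step(rhs, u, v, t, h, k1u, k1v, k2u, k2v, k3u, k3v, k4u, k4v, tu, tv);
    if ((i + 1) % stride == 0 || i + 1 == nsteps) {
      if (state_bad(u, v))
        stop("numerical instability at t = %g (state non-finite, |state| > 1e3, "
             "or activator below -1e-6)", (i + 1) * h);
      times[row] = (i + 1) * h;
      for (int j = 0; j < n; ++j) {
        um(row, j) = u[j];
        vm(row, j) = v[j];
      }
      ++row;
    }
  }
  return List::create(_["times"] = times[Range(0, row - 1)],
                      _["u"] = um(Range(0, row - 1), _),
                      _["v"] = vm(Range(0, row - 1), _));
}

// Integrate one record and count, per oscillator, the interior strict local
// maxima (prev < cur >= next) of the activator on the stored-sample grid that
// exceed `threshold`. Returns counts, or status 1 on numerical blow-up.
static int count_record(NetRHS &rhs, std::vector<double> &u,
                        std::vector<double> &v, double h, int nsteps,
                        int stride, double threshold, int *counts) {
  int n = rhs.n;
  std::vector<double> k1u(n), k1v(n), k2u(n), k2v(n), k3u(n), k3v(n), k4u(n),
      k4v(n), tu(n), tv(n);
  std::vector<double> prev1(u), prev2(n, 0.0);
  std::vector<int> nstored(1, 1);
  for (int j = 0; j < n; ++j) counts[j] = 0;
  int stored = 1;
  for (int i = 0; i < nsteps; ++i) {
    double t = i * h;
    rk4_step(rhs, u, v, t, h, k1u, k1v, k2u, k2v, k3u, k3v, k4u, k4v, tu, tv);
    if ((i + 1) % stride == 0 || i + 1 == nsteps) {
      if (state_bad(u, v)) return 1;
      for (int j = 0; j < n; ++j) {
        if (stored >= 2 && prev2[j] < prev1[j] && prev1[j] >= u[j] &&
            prev1[j] > threshold)
          counts[j]++;
        prev2[j] = prev1[j];
        prev1[j] = u[j];
      }
      ++stored;
    }
  }
  return 0;
}

// [[Rcpp::export]]
List rk4_count_batch_cpp(NumericMatrix t_ilum_mat, NumericMatrix u0_mat,
                         NumericMatrix v0_mat, double amp, double offset,
                         double steep, double eps, double q, double f,
                         double alpha, double beta, IntegerMatrix adjacency,
                         double h, int nsteps, int stride, double threshold) {
  int nrec = t_ilum_mat.nrow(), n = t_ilum_mat.ncol();
  IntegerMatrix counts(nrec, n);
  IntegerVector status(nrec);
  NetRHS rhs;
  rhs.n = n;
  rhs.inv_eps = 1.0 / eps;
  rhs.q = q;
  rhs.f = f;
  rhs.alpha = alpha;
  rhs.beta = beta;
  rhs.amp = amp;
  rhs.offset = offset;
  rhs.steep = steep;
  rhs.phi_const = -1.0;
  rhs.adj = adjacency.begin();
  rhs.init_degree();

  std::vector<double> ti(n), u(n), v(n);
  std::vector<int> cnt(n);
  for (int r = 0; r < nrec; ++r) {
    for (int j = 0; j < n; ++j) {
      ti[j] = t_ilum_mat(r, j);
      u[j] = u0_mat(r, j);
      v[j] = v0_mat(r, j);
    }
    rhs.t_ilum = ti.data();
    status[r] = count_record(rhs, u, v, h, nsteps, stride, threshold,
                             cnt.data());
    for (int j = 0; j < n; ++j)
      counts(r, j) = status[r] ? NA_INTEGER : cnt[j];
    if (r % 64 == 0) checkUserInterrupt();
  }
  return List::create(_["counts"] = counts, _["status"] = status);
}
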