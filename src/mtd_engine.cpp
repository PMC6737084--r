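// Langevin (BAOAB) metadynamics core for direct-CV toy potentials.
//
// The bias and its gradient are accumulated on a regular grid as hills are
// deposited (each hill touches only grid points within 6 sigma), and the bias
// force during integration is linearly interpolated from the gradient grid.
// This keeps the per-step cost independent of the number of hills, the same
// strategy production metadynamics codes use.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// toy potential kinds (must match make_toy_potential())
// 1 = harmonic: V = 0.5 * sum k_d x_d^2, params = (k_1 .. k_d)
// 2 = double_well_1d: V = h (x^2 - 1)^2, params = (h)
// 3 = two_channel_2d: V = q(x) (h1 G(y-1) + h2 G(y+1)) + kc (y^2-1)^2,
//     q(x) = (1 - x^2)^2, G gaussian with width sy; params = (h1, h2, kc, sy)
struct Potential {
  int kind;
  std::vector<double> p;
  int dim;

  double energy_grad(const double* x, double* g) const {
    if (kind == 1) {
      double v = 0.0;
      for (int d = 0; d < dim; ++d) {
        v += 0.5 * p[d] * x[d] * x[d];
        g[d] = p[d] * x[d];
      }
      return v;
    } else if (kind == 2) {
      double h = p[0];
      double a = x[0] * x[0] - 1.0;
      g[0] = 4.0 * h * x[0] * a;
      return h * a * a;
    } else {
      double h1 = p[0], h2 = p[1], kc = p[2], sy = p[3];
      double xx = x[0], yy = x[1];
      double q = (1.0 - xx * xx) * (1.0 - xx * xx);
      double dq = -4.0 * xx * (1.0 - xx * xx);
      double g1 = std::exp(-(yy - 1.0) * (yy - 1.0) / (2.0 * sy * sy));
      double g2 = std::exp(-(yy + 1.0) * (yy + 1.0) / (2.0 * sy * sy));
      double b = h1 * g1 + h2 * g2;
      double db = -h1 * g1 * (yy - 1.0) / (sy * sy)
                  - h2 * g2 * (yy + 1.0) / (sy * sy);
      double c = kc * (yy * yy - 1.0) * (yy * yy - 1.0);
      double dc = 4.0 * kc * yy * (yy * yy - 1.0);
      g[0] = dq * b;
      g[1] = q * db + dc;
      return q * b + c;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List mtd_engine_cpp(int kind, NumericVector params, NumericVector x0,
                    int nsteps, double dt, double friction, double mass,
                    double kT, int pace, double hill_height,
                    NumericVector hill_sigma, NumericVector grid_min,
                    NumericVector grid_max, IntegerVector grid_n,
                    int wall_idx, double wall_pos, double wall_kappa,
                    NumericMatrix noise, int cv_stride) {
  const int dim = x0.size();
  Potential pot;
  pot.kind = kind;
  pot.dim = dim;
  pot.p.assign(params.begin(), params.end());

  std::vector<double> step_sz(dim), ax_min(dim);
  std::vector<int> gn(dim);
  long total_cells = 1;
  for (int d = 0; d < dim; ++d) {
    gn[d] = grid_n[d];
    ax_min[d] = grid_min[d];
    step_sz[d] = (grid_max[d] - grid_min[d]) / (gn[d] - 1);
    total_cells *= gn[d];
  }
  std::vector<double> bias(total_cells, 0.0);
  std::vector<double> bgrad(total_cells * dim, 0.0);

  // add one Gaussian hill (analytic gradient) to the grid, within 6 sigma
  auto add_hill = [&](const double* c) {
    if (dim == 1) {
      int lo = std::max(0, (int)std::floor((c[0] - 6 * hill_sigma[0] - ax_min[0]) / step_sz[0]));
      int hi = std::min(gn[0] - 1, (int)std::ceil((c[0] + 6 * hill_sigma[0] - ax_min[0]) / step_sz[0]));
      for (int i = lo; i <= hi; ++i) {
        double dx = ax_min[0] + i * step_sz[0] - c[0];
        double e = hill_height * std::exp(-dx * dx / (2 * hill_sigma[0] * hill_sigma[0]));
        bias[i] += e;
        bgrad[i] += -e * dx / (hill_sigma[0] * hill_sigma[0]);
      }
    } else {
      int lo0 = std::max(0, (int)std::floor((c[0] - 6 * hill_sigma[0] - ax_min[0]) / step_sz[0]));
      int hi0 = std::min(gn[0] - 1, (int)std::ceil((c[0] + 6 * hill_sigma[0] - ax_min[0]) / step_sz[0]));
      int lo1 = std::max(0, (int)std::floor((c[1] - 6 * hill_sigma[1] - ax_min[1]) / step_sz[1]));
      int hi1 = std::min(gn[1] - 1, (int)std::ceil((c[1] + 6 * hill_sigma[1] - ax_min[1]) / step_sz[1]));
      for (int j = lo1; j <= hi1; ++j) {
        double dy = ax_min[1] + j * step_sz[1] - c[1];
        double ey = std::exp(-dy * dy / (2 * hill_sigma[1] * hill_sigma[1]));
        for (int i = lo0; i <= hi0; ++i) {
          double dx = ax_min[0] + i * step_sz[0] - c[0];
          double e = hill_height * ey *
                     std::exp(-dx * dx / (2 * hill_sigma[0] * hill_sigma[0]));
          long cell = (long)j * gn[0] + i;
          bias[cell] += e;
          bgrad[cell * dim + 0] += -e * dx / (hill_sigma[0] * hill_sigma[0]);
          bgrad[cell * dim + 1] += -e * dy / (hill_sigma[1] * hill_sigma[1]);
        }
      }
    }
  };

  // linear interpolation of the bias gradient at x (clamped to the grid)
  auto bias_grad_at = [&](const double* x, double* g) {
    if (dim == 1) {
      double u = (x[0] - ax_min[0]) / step_sz[0];
      int i = std::max(0, std::min(gn[0] - 2, (int)std::floor(u)));
      double f = std::max(0.0, std::min(1.0, u - i));
      g[0] = (1 - f) * bgrad[i] + f * bgrad[i + 1];
    } else {
      double u = (x[0] - ax_min[0]) / step_sz[0];
      double v = (x[1] - ax_min[1]) / step_sz[1];
      int i = std::max(0, std::min(gn[0] - 2, (int)std::floor(u)));
      int j = std::max(0, std::min(gn[1] - 2, (int)std::floor(v)));
      double fu = std::max(0.0, std::min(1.0, u - i));
      double fv = std::max(0.0, std::min(1.0, v - j));
      for (int d = 0; d < dim; ++d) {
        double g00 = bgrad[((long)j * gn[0] + i) * dim + d];
        double g10 = bgrad[((long)j * gn[0] + i + 1) * dim + d];
        double g01 = bgrad[((long)(j + 1) * gn[0] + i) * dim + d];
        double g11 = bgrad[((long)(j + 1) * gn[0] + i + 1) * dim + d];
        g[d] = (1 - fv) * ((1 - fu) * g00 + fu * g10) +
               fv * ((1 - fu) * g01 + fu * g11);
      }
    }
  };

  auto force = [&](const double* x, double* f) {
    double gpot[2], gbias[2];
    pot.energy_grad(x, gpot);
    bias_grad_at(x, gbias);
    for (int d = 0; d < dim; ++d) f[d] = -gpot[d] - gbias[d];
    if (wall_idx >= 1) {
      double over = x[wall_idx - 1] - wall_pos;
      if (over > 0) f[wall_idx - 1] -= 2.0 * wall_kappa * over;
    }
  };

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> pvec(dim, 0.0), fvec(dim);
  const double a = std::exp(-friction * dt);
  const double bnoise = std::sqrt(kT * mass * (1.0 - a * a));

  std::vector<double> hill_centers;
  std::vector<int> hill_steps;
  int n_saved = nsteps / cv_stride + 1;
  NumericMatrix cv_traj(n_saved, dim);
  IntegerVector cv_steps(n_saved);
  int saved = 0;
  for (int d = 0; d < dim; ++d) cv_traj(saved, d) = x[d];
  cv_steps[saved++] = 0;

  force(x.data(), fvec.data());
  for (int s = 0; s < nsteps; ++s) {
    for (int d = 0; d < dim; ++d) pvec[d] += 0.5 * dt * fvec[d];
    for (int d = 0; d < dim; ++d) x[d] += 0.5 * dt * pvec[d] / mass;
    for (int d = 0; d < dim; ++d) pvec[d] = a * pvec[d] + bnoise * noise(s, d);
    for (int d = 0; d < dim; ++d) x[d] += 0.5 * dt * pvec[d] / mass;
    for (int d = 0; d < dim; ++d) {
      if (!std::isfinite(x[d])) {
        stop("integration diverged at step %d", s + 1);
      }
    }
    if ((s + 1) % pace == 0) {
      add_hill(x.data());
      for (int d = 0; d < dim; ++d) hill_centers.push_back(x[d]);
      hill_steps.push_back(s + 1);
    }
    force(x.data(), fvec.data());
    for (int d = 0; d < dim; ++d) pvec[d] += 0.5 * dt * fvec[d];
    if ((s + 1) % cv_stride == 0 && saved < n_saved) {
      for (int d = 0; d < dim; ++d) cv_traj(saved, d) = x[d];
      cv_steps[saved++] = s + 1;
    }
  }

  int nh = hill_steps.size();
  NumericMatrix hc(nh, dim);
  for (int k = 0; k < nh; ++k) {
    for (int d = 0; d < dim; ++d) hc(k, d) = hill_centers[(long)k * dim + d];
  }
  NumericVector bias_out(bias.begin(), bias.end());
  if (dim == 2) bias_out.attr("dim") = IntegerVector::create(gn[0], gn[1]);

  return List::create(_["hill_centers"] = hc,
                      _["hill_steps"] = IntegerVector(hill_steps.begin(), hill_steps.end()),
                      _["cv_traj"] = cv_traj(Range(0, saved - 1), Range(0, dim - 1)),
                      _["cv_steps"] = cv_steps[Range(0, saved - 1)],
                      _["bias_grid"] = bias_out);
}
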