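#include <Rcpp.h>
#include <limits>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Lennard-Jones pair energy eps * ((r0/r)^12 - 2 (r0/r)^6) from the squared
// distance; multiplications only, no pow(), since this is the innermost loop.
static inline double lj_r2(double r2, double eps, double r02) {
  double s2 = r02 / r2;
  double s6 = s2 * s2 * s2;
  return eps * (s6 * s6 - 2.0 * s6);
}

// Grow one self-interacting random walk.
//
// dirs: m x 3 unit vectors (candidate moves, scaled by d0 at use).
// rule: 0 = categorical Boltzmann sampling over all candidates,
//       1 = uniform proposal + Metropolis accept/reject.
// rmin: hard-core cutoff; any candidate closer than rmin to a previous visit
//       gets +Inf energy (selection weight exactly 0).
//
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().
// [[Rcpp::export]]
List sirw_walk_cpp(NumericMatrix dirs, int n_steps, double temperature,
                   double epsilon, double r0, double d0, double rmin,
                   int rule, int max_attempts) {
  const int m = dirs.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  const double rmin2 = rmin * rmin;
  const double r02 = r0 * r0;

  NumericMatrix pos(n_steps + 1, 3);  // row 0 = origin
  NumericVector energy(n_steps + 1); // U_n at arrival; energy[0] = 0
  std::vector<double> cand_e(m), cand_w(m);
  // contiguous copies for the inner loops
  std::vector<double> ux(m), uy(m), uz(m);
  for (int j = 0; j < m; ++j) {
    ux[j] = d0 * dirs(j, 0);
    uy[j] = d0 * dirs(j, 1);
    uz[j] = d0 * dirs(j, 2);
  }
  std::vector<double> vx(n_steps + 1), vy(n_steps + 1), vz(n_steps + 1);
  vx[0] = vy[0] = vz[0] = 0.0;

  for (int n = 0; n < n_steps; ++n) {
    const double px = vx[n], py = vy[n], pz = vz[n];
    double emin = inf;
    for (int j = 0; j < m; ++j) {
      const double cx = px + ux[j];
      const double cy = py + uy[j];
      const double cz = pz + uz[j];
      double e = 0.0;
      for (int k = 0; k <= n; ++k) {
        const double dx = cx - vx[k];
        const double dy = cy - vy[k];
        const double dz = cz - vz[k];
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rmin2) { e = inf; break; }
        e += lj_r2(r2, epsilon, r02);
      }
      cand_e[j] = e;
      if (e < emin) emin = e;
    }
    if (!R_finite(emin))
      stop("trapped walker at step %d: all %d candidates inside the hard core",
           n + 1, m);

    int pick = -1;
    if (rule == 0) {
      // categorical sampling; max-shift by emin before exponentiation
      double total = 0.0;
      for (int j = 0; j < m; ++j) {
        const double w = R_finite(cand_e[j])
          ? std::exp(-(cand_e[j] - emin) / temperature) : 0.0;
        cand_w[j] = w;
        total += w;
      }
      const double u = unif_rand() * total;
      double acc = 0.0;
      int last_pos = -1;
      for (int j = 0; j < m; ++j) {
        if (cand_w[j] <= 0.0) continue;
        acc += cand_w[j];
        last_pos = j;
        if (u <= acc) { pick = j; break; }
      }
      if (pick < 0) pick = last_pos;  // fp guard: u == total
    } else {
      // uniform proposal accepted with the Boltzmann factor relative to the
      // minimum candidate energy: exact rejection sampling of the same
      // categorical distribution (a reference inside the candidate set is
      // required; the current-position energy differs by the large bonded
      // term u(d0) and would stall the chain)
      const double uref = emin;
      int attempts = 0;
      while (pick < 0) {
        if (++attempts > max_attempts)
          stop("trapped walker at step %d: no Metropolis acceptance in %d attempts",
               n + 1, max_attempts);
        int j = static_cast<int>(unif_rand() * m);
        if (j >= m) j = m - 1;
        const double e = cand_e[j];
        if (!R_finite(e)) continue;
        const double a = std::exp(-(e - uref) / temperature);
        if (a >= 1.0 || unif_rand() < a) pick = j;
      }
    }
    vx[n + 1] = px + ux[pick];
    vy[n + 1] = py + uy[pick];
    vz[n + 1] = pz + uz[pick];
    energy[n + 1] = cand_e[pick];
  }

  for (int k = 0; k <= n_steps; ++k) {
    pos(k, 0) = vx[k];
    pos(k, 1) = vy[k];
    pos(k, 2) = vz[k];
  }
  return List::create(_["positions"] = pos, _["energy"] = energy);
}

// Total LJ interaction energy over all unordered pairs of a configuration.
// [[Rcpp::export]]
double config_energy_cpp(NumericMatrix pos, double epsilon, double r0,
                         double rmin) {
  const int n = pos.nrow();
  const double rmin2 = rmin * rmin;
  const double r02 = r0 * r0;
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = pos(i, 0) - pos(j, 0);
      const double dy = pos(i, 1) - pos(j, 1);
      const double dz = pos(i, 2) - pos(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rmin2) return std::numeric_limits<double>::infinity();
      e += lj_r2(r2, epsilon, r02);
    }
  return e;
}
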