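#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum-image squared distance for an orthorhombic cell.
static inline double mi_r2(const double *a, const double *b, const double *cell) {
  double r2 = 0.0;
  for (int d = 0; d < 3; ++d) {
    double dx = a[d] - b[d];
    dx -= cell[d] * std::round(dx / cell[d]);
    r2 += dx * dx;
  }
  return r2;
}

// Flatten an N x 3 R matrix into xyz-contiguous storage.
static std::vector<double> flatten(const NumericMatrix &m) {
  const int n = m.nrow();
  std::vector<double> out(3 * n);
  for (int i = 0; i < n; ++i) {
    out[3 * i] = m(i, 0);
    out[3 * i + 1] = m(i, 1);
    out[3 * i + 2] = m(i, 2);
  }
  return out;
}

// Histogram of minimum-image pair distances.  Bins are centred on k * dr
// (k = 1..nbins), so a distance of exactly k * dr falls in bin k.  When
// same_set is true A and B are the same atoms and each unordered pair is
// counted once; otherwise every (i in A, j in B) pair is counted once.
// [[Rcpp::export]]
IntegerVector cpp_pair_hist(NumericMatrix A, NumericMatrix B, NumericVector cell,
                            double r_max, double dr, bool same_set) {
  const int na = A.nrow(), nb = B.nrow();
  const int nbins = (int)std::floor(r_max / dr + 0.5);
  IntegerVector counts(nbins);
  std::vector<double> a = flatten(A), b = flatten(B);
  double c[3] = {cell[0], cell[1], cell[2]};
  const double r2max = (r_max + 0.5 * dr) * (r_max + 0.5 * dr);
  for (int i = 0; i < na; ++i) {
    const int j0 = same_set ? i + 1 : 0;
    for (int j = j0; j < nb; ++j) {
      double r2 = mi_r2(&a[3 * i], &b[3 * j], c);
      if (r2 >= r2max) continue;
      double r = std::sqrt(r2);
      int k = (int)std::floor(r / dr + 0.5);
      if (k >= 1 && k <= nbins) counts[k - 1]++;
    }
  }
  return counts;
}

// Debye double sum: for each Q, sum of sin(Q r)/(Q r) over pairs with
// minimum-image distance <= r_cut.  Same pair-counting convention as
// cpp_pair_hist (unordered once when same_set).
// [[Rcpp::export]]
NumericVector cpp_debye_sum(NumericMatrix A, NumericMatrix B, NumericVector cell,
                            NumericVector Q, double r_cut, bool same_set) {
  const int na = A.nrow(), nb = B.nrow(), nq = Q.size();
  NumericVector S(nq);
  std::vector<double> a = flatten(A), b = flatten(B);
  double c[3] = {cell[0], cell[1], cell[2]};
  const double r2max = r_cut * r_cut;
  for (int i = 0; i < na; ++i) {
    const int j0 = same_set ? i + 1 : 0;
    for (int j = j0; j < nb; ++j) {
      double r2 = mi_r2(&a[3 * i], &b[3 * j], c);
      if (r2 > r2max || r2 < 1e-20) continue;
      double r = std::sqrt(r2);
      for (int q = 0; q < nq; ++q) {
        double x = Q[q] * r;
        S[q] += std::sin(x) / x;
      }
    }
  }
  return S;
}

// Angle histogram: for each central atom (1-based indices into pool), every
// unordered pair of pool neighbours within cutoff contributes the angle they
// subtend at the centre.  Bins centred on k * dtheta degrees, k = 1..nbins.
// [[Rcpp::export]]
IntegerVector cpp_angle_hist(NumericMatrix pool, NumericVector cell,
                             IntegerVector centres, double cutoff,
                             double dtheta, int nbins) {
  const int np = pool.nrow();
  IntegerVector counts(nbins);
  std::vector<double> p = flatten(pool);
  double c[3] = {cell[0], cell[1], cell[2]};
  const double cut2 = cutoff * cutoff;
  std::vector<double> vx, vy, vz, vr;
  for (int ci = 0; ci < centres.size(); ++ci) {
    const int cen = centres[ci] - 1;
    vx.clear(); vy.clear(); vz.clear(); vr.clear();
    for (int j = 0; j < np; ++j) {
      if (j == cen) continue;
      double d[3];
      double r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double dx = p[3 * j + k] - p[3 * cen + k];
        dx -= c[k] * std::round(dx / c[k]);
        d[k] = dx;
        r2 += dx * dx;
      }
      if (r2 > cut2 || r2 < 1e-20) continue;
      vx.push_back(d[0]); vy.push_back(d[1]); vz.push_back(d[2]);
      vr.push_back(std::sqrt(r2));
    }
    const int nn = (int)vr.size();
    for (int u = 0; u < nn; ++u) {
      for (int v = u + 1; v < nn; ++v) {
        double cosang = (vx[u] * vx[v] + vy[u] * vy[v] + vz[u] * vz[v]) /
                        (vr[u] * vr[v]);
        if (cosang > 1.0) cosang = 1.0;
        if (cosang < -1.0) cosang = -1.0;
        double theta = std::acos(cosang) * 180.0 / M_PI;
        int k = (int)std::floor(theta / dtheta + 0.5);
        if (k < 1) k = 1;
        if (k > nbins) k = nbins;
        counts[k - 1]++;
      }
    }
  }
  return counts;
}

static inline double pair_energy(double r2, double s) {
  double x = (s * s) / r2;   // (sigma/r)^2
  double x6 = x * x * x;
  return x6 * x6;            // (sigma/r)^12
}

// Metropolis single-particle-move Monte Carlo for additive purely repulsive
// soft spheres, pair energy (sigma_ij / r)^12 with sigma_ij = (s_i + s_j)/2,
// truncated at r_cut.  Uses R's RNG so set.seed() controls reproducibility.
// record_at: 1-based sweep numbers after which to store a frame (sorted).
// [[Rcpp::export]]
List cpp_mc_soft_sphere(NumericMatrix pos0, NumericVector sigma, NumericVector cell,
                        double tstar, double max_disp, int n_sweeps,
                        IntegerVector record_at, double r_cut) {
  RNGScope scope;
  const int n = pos0.nrow();
  std::vector<double> p = flatten(pos0);
  double c[3] = {cell[0], cell[1], cell[2]};
  const double cut2 = r_cut * r_cut;
  List frames(record_at.size());
  NumericVector energies(record_at.size());
  long accepted = 0, attempted = 0;
  int rec = 0;

  // store frames for n_sweeps == 0 handled by caller
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int m = 0; m < n; ++m) {
      int i = (int)std::floor(unif_rand() * n);
      if (i >= n) i = n - 1;
      double trial[3];
      for (int d = 0; d < 3; ++d) {
        double x = p[3 * i + d] + (unif_rand() * 2.0 - 1.0) * max_disp;
        x -= c[d] * std::floor(x / c[d]);   // wrap into box
        trial[d] = x;
      }
      double dE = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double s = 0.5 * (sigma[i] + sigma[j]);
        double r2new = mi_r2(trial, &p[3 * j], c);
        double r2old = mi_r2(&p[3 * i], &p[3 * j], c);
        if (r2new < cut2) dE += pair_energy(r2new, s);
        if (r2old < cut2) dE -= pair_energy(r2old, s);
      }
      ++attempted;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / tstar)) {
        for (int d = 0; d < 3; ++d) p[3 * i + d] = trial[d];
        ++accepted;
      }
    }
    if (rec < record_at.size() && sweep == record_at[rec]) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) fr(i, d) = p[3 * i + d];
      // total energy of the recorded frame (monitoring only)
      double E = 0.0;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double r2 = mi_r2(&p[3 * i], &p[3 * j], c);
          if (r2 < cut2) E += pair_energy(r2, 0.5 * (sigma[i] + sigma[j]));
        }
      energies[rec] = E;
      frames[rec] = fr;
      ++rec;
    }
  }
  double acc = attempted > 0 ? (double)accepted / (double)attempted : NA_REAL;
  return List::create(_["frames"] = frames, _["acceptance_rate"] = acc,
                      _["energies"] = energies);
}

static inline bool in_cavity(const double *q, const std::vector<double> &cen,
                             const NumericVector &radii, const double *c,
                             int nsph) {
  for (int s = 0; s < nsph; ++s) {
    double r2 = mi_r2(q, &cen[3 * s], c);
    double R = radii[s];
    if (r2 < R * R) return true;
  }
  return false;
}

// Monte-Carlo excluded-volume normalization: for uniformly random points in
// the retained region (box minus cavity spheres, minimum-image), estimate
// F(r) = P(a point at distance r in a random direction is also retained),
// i.e. the ratio of the retained-region pair-distance density to the free-box
// ideal-gas density.  Also returns the retained volume fraction.
// Uses R's RNG.
// [[Rcpp::export]]
List cpp_cavity_norm(NumericMatrix centers, NumericVector radii, NumericVector cell,
                     NumericVector rbins, int n_samples) {
  RNGScope scope;
  const int nsph = centers.nrow(), nb = rbins.size();
  std::vector<double> cen = flatten(centers);
  double c[3] = {cell[0], cell[1], cell[2]};
  std::vector<long> hits(nb, 0);
  long n_acc = 0;
  for (int s = 0; s < n_samples; ++s) {
    double p[3];
    for (int d = 0; d < 3; ++d) p[d] = unif_rand() * c[d];
    if (in_cavity(p, cen, radii, c, nsph)) continue;
    ++n_acc;
    // Marsaglia unit vector
    double u[3];
    double s1, s2, ss;
    do {
      s1 = 2.0 * unif_rand() - 1.0;
      s2 = 2.0 * unif_rand() - 1.0;
      ss = s1 * s1 + s2 * s2;
    } while (ss >= 1.0);
    double root = 2.0 * std::sqrt(1.0 - ss);
    u[0] = s1 * root;
    u[1] = s2 * root;
    u[2] = 1.0 - 2.0 * ss;
    for (int k = 0; k < nb; ++k) {
      double q[3];
      for (int d = 0; d < 3; ++d) {
        double x = p[d] + rbins[k] * u[d];
        x -= c[d] * std::floor(x / c[d]);
        q[d] = x;
      }
      if (!in_cavity(q, cen, radii, c, nsph)) hits[k]++;
    }
  }
  NumericVector ratio(nb);
  for (int k = 0; k < nb; ++k)
    ratio[k] = n_acc > 0 ? (double)hits[k] / (double)n_acc : NA_REAL;
  return List::create(_["ratio"] = ratio,
                      _["retained_fraction"] = (double)n_acc / (double)n_samples);
}
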