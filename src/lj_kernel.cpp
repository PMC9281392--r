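#include <Rcpp.h>
using namespace Rcpp;

// Lennard-Jones pair sums over the asymmetric unit and all explicit ghosts
// (symmetry mates and lattice images).
//
// asym:     n x D Cartesian positions of the asymmetric unit
// cellfrac: M x D wrapped fractional positions of the whole unit cell
//           (orbit-major)
// owner:    length M, 1-based asymmetric-unit particle owning each row
// offsets:  K x D integer lattice-image offsets (zero offset at zerorow)
// box:      D x D row-form box matrix
// weights:  length n orbit multiplicities (|G| for general positions)
//
// Returns per-cell potential energy
//   U = 1/2 * sum_i w_i * sum_{j != i} u(r_ij)
// (outer loop over the asymmetric unit, inner loop over every explicit
// particle) and the physical force on each asymmetric-unit particle.
// A ghost at numerically zero distance from the particle that OWNS it is
// that particle itself (its root copy, or a wrap-boundary duplicate of it)
// and is skipped; zero distance to anyone else's ghost is an overlap.
// [[Rcpp::export]]
List lj_eval_kernel(NumericMatrix asym, NumericMatrix cellfrac,
                    IntegerVector owner, NumericMatrix offsets,
                    NumericMatrix box, NumericVector weights,
                    double eps, double sigma, double rc, double ushift) {
  const int n = asym.nrow(), D = asym.ncol();
  const int M = cellfrac.nrow(), K = offsets.nrow();
  const double rc2 = rc * rc, s2 = sigma * sigma;
  const double tiny2 = 1e-16;

  // materialize ghost Cartesian positions, image-major within each cell row
  std::vector<double> ghost((size_t)M * K * D);
  for (int j = 0; j < M; ++j) {
    for (int k = 0; k < K; ++k) {
      size_t base = ((size_t)j * K + k) * D;
      for (int d = 0; d < D; ++d) {
        double x = 0.0;
        for (int e = 0; e < D; ++e)
          x += (cellfrac(j, e) + offsets(k, e)) * box(e, d);
        ghost[base + d] = x;
      }
    }
  }

  double energy = 0.0;
  NumericMatrix forces(n, D);
  bool overlap = false;
  for (int i = 0; i < n && !overlap; ++i) {
    const double wi = 0.5 * weights[i];
    double fx[3] = {0.0, 0.0, 0.0};
    double qi[3] = {0.0, 0.0, 0.0};
    for (int d = 0; d < D; ++d) qi[d] = asym(i, d);
    for (size_t jk = 0; jk < (size_t)M * K; ++jk) {
      const double *g = &ghost[jk * D];
      double r2 = 0.0;
      for (int d = 0; d < D; ++d) {
        double dx = qi[d] - g[d];
        r2 += dx * dx;
      }
      if (r2 >= rc2) continue;
      if (r2 < tiny2) {
        if (owner[jk / K] == i + 1) continue;   // the particle itself
        overlap = true;
        break;
      }
      double sr2 = s2 / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      energy += wi * (4.0 * eps * (sr12 - sr6) - ushift);
      double fmag = 24.0 * eps * (2.0 * sr12 - sr6) / r2; // -du/dr / r
      for (int d = 0; d < D; ++d) fx[d] += fmag * (qi[d] - g[d]);
    }
    for (int d = 0; d < D; ++d) forces(i, d) = fx[d];
  }
  return List::create(_["energy"] = energy, _["forces"] = forces,
                      _["overlap"] = overlap);
}

// Brute-force reference sum used by tests and cross-checks: per-cell energy
// from all unordered cell pairs plus half of every cell<->image interaction.
// [[Rcpp::export]]
double lj_cell_reference(NumericMatrix cellfrac, NumericMatrix offsets,
                         int zerorow, NumericMatrix box,
                         double eps, double sigma, double rc, double ushift) {
  const int M = cellfrac.nrow(), D = cellfrac.ncol(), K = offsets.nrow();
  const double rc2 = rc * rc, s2 = sigma * sigma;
  double energy = 0.0;
  for (int i = 0; i < M; ++i) {
    double qi[3] = {0.0, 0.0, 0.0};
    for (int d = 0; d < D; ++d)
      for (int e = 0; e < D; ++e) qi[d] += cellfrac(i, e) * box(e, d);
    for (int j = 0; j < M; ++j) {
      for (int k = 0; k < K; ++k) {
        if (j == i && k == zerorow - 1) continue;
        double r2 = 0.0;
        for (int d = 0; d < D; ++d) {
          double x = 0.0;
          for (int e = 0; e < D; ++e)
            x += (cellfrac(j, e) + offsets(k, e)) * box(e, d);
          double dx = qi[d] - x;
          r2 += dx * dx;
        }
        if (r2 >= rc2 || r2 <= 0.0) continue;
        double sr6 = (s2 / r2) * (s2 / r2) * (s2 / r2);
        energy += 0.5 * (4.0 * eps * (sr6 * sr6 - sr6) - ushift);
      }
    }
  }
  return energy;
}
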