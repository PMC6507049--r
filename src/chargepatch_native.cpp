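#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Cell-list key for a 3D integer grid cell.
static inline int64_t cell_key(int ix, int iy, int iz) {
  return (static_cast<int64_t>(ix) & 0x1FFFFF) |
         ((static_cast<int64_t>(iy) & 0x1FFFFF) << 21) |
         ((static_cast<int64_t>(iz) & 0x1FFFFF) << 42);
}

static void build_cells(const NumericMatrix& X, double h,
                        std::unordered_map<int64_t, std::vector<int> >& cells) {
  int n = X.nrow();
  cells.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(X(i, 0) / h);
    int iy = (int)std::floor(X(i, 1) / h);
    int iz = (int)std::floor(X(i, 2) / h);
    cells[cell_key(ix, iy, iz)].push_back(i);
  }
}

//' All point pairs within a distance cutoff (cell-list search).
//'
//' @param X numeric matrix, one 3D point per row.
//' @param cutoff pair distance cutoff in the units of X.
//' @return integer matrix with two columns (1-based indices, i < j).
//' @keywords internal
// [[Rcpp::export(name = ".cp_pairs_within")]]
IntegerMatrix cp_pairs_within(NumericMatrix X, double cutoff) {
  int n = X.nrow();
  double h = cutoff > 0 ? cutoff : 1.0;
  double c2 = cutoff * cutoff;
  std::unordered_map<int64_t, std::vector<int> > cells;
  build_cells(X, h, cells);
  std::vector<int> ai, aj;
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(X(i, 0) / h);
    int iy = (int)std::floor(X(i, 1) / h);
    int iz = (int)std::floor(X(i, 2) / h);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double ddx = X(i, 0) - X(j, 0);
            double ddy = X(i, 1) - X(j, 1);
            double ddz = X(i, 2) - X(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) {
              ai.push_back(i + 1);
              aj.push_back(j + 1);
            }
          }
        }
  }
  IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); ++k) {
    out(k, 0) = ai[k];
    out(k, 1) = aj[k];
  }
  return out;
}

//' Mark candidate surface dots buried inside any other atom's expanded sphere.
//'
//' @param atoms numeric matrix of atom centres (n x 3).
//' @param rexp expanded radii (radius + probe) per atom.
//' @param dots candidate dot coordinates (m x 3).
//' @param parent 1-based parent atom index per dot.
//' @return logical vector, TRUE where the dot is exposed (kept).
//' @keywords internal
// [[Rcpp::export(name = ".cp_exposed_dots")]]
LogicalVector cp_exposed_dots(NumericMatrix atoms, NumericVector rexp,
                              NumericMatrix dots, IntegerVector parent) {
  int na = atoms.nrow(), nd = dots.nrow();
  double rmax = 0;
  for (int i = 0; i < na; ++i) rmax = std::max(rmax, rexp[i]);
  double h = rmax > 0 ? rmax : 1.0;
  std::unordered_map<int64_t, std::vector<int> > cells;
  build_cells(atoms, h, cells);
  LogicalVector keep(nd, true);
  for (int d = 0; d < nd; ++d) {
    double x = dots(d, 0), y = dots(d, 1), z = dots(d, 2);
    int ix = (int)std::floor(x / h);
    int iy = (int)std::floor(y / h);
    int iz = (int)std::floor(z / h);
    bool exposed = true;
    for (int dx = -1; dx <= 1 && exposed; ++dx)
      for (int dy = -1; dy <= 1 && exposed; ++dy)
        for (int dz = -1; dz <= 1 && exposed; ++dz) {
          auto it = cells.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int a : it->second) {
            if (a == parent[d] - 1) continue;
            double ddx = x - atoms(a, 0);
            double ddy = y - atoms(a, 1);
            double ddz = z - atoms(a, 2);
            double r2 = rexp[a] * rexp[a];
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            // strict interior removes the dot; dots exactly on another
            // sphere's boundary (coincident/tangent shells) are kept only
            // for the lowest-index atom, so duplicated shells collapse
            if (d2 < r2 * (1.0 - 1e-9) ||
                (d2 < r2 * (1.0 + 1e-9) && a < parent[d] - 1)) {
              exposed = false;
              break;
            }
          }
        }
    keep[d] = exposed;
  }
  return keep;
}

//' Metropolis Monte Carlo over protonation states.
//'
//' Energy model: E(x, pH) = sum_i x_i * f_i(pH) + sum_{i<j} W_ij q_i q_j with
//' q_i = q0_i + x_i (acids q0 = -1, bases q0 = 0). Single-site flips, one
//' sweep = nsite proposals, sites visited in random order. Uses R's RNG so
//' set.seed() governs reproducibility.
//'
//' @param W symmetric interaction matrix (kJ/mol per unit-charge pair).
//' @param q0 deprotonated charge per site.
//' @param fmat field term f_i(pH) (nsite x npH), kJ/mol.
//' @param RT thermal energy, kJ/mol.
//' @param sweeps post-burn-in sweeps.
//' @param burnin discarded initial sweeps.
//' @return list with protonation-fraction matrix, mean protonated count and
//'   mean net charge per pH.
//' @keywords internal
// [[Rcpp::export(name = ".cp_titrate_mc")]]
List cp_titrate_mc(NumericMatrix W, NumericVector q0, NumericMatrix fmat,
                   double RT, int sweeps, int burnin) {
  int n = W.nrow(), nph = fmat.ncol();
  NumericMatrix frac(n, nph);
  NumericVector mean_nprot(nph), mean_q(nph);
  std::vector<int> x(n);
  std::vector<double> q(n);
  for (int p = 0; p < nph; ++p) {
    // start from the independent-site (Henderson-Hasselbalch) guess
    for (int i = 0; i < n; ++i) {
      double phh = 1.0 / (1.0 + std::exp(fmat(i, p) / RT));
      x[i] = (unif_rand() < phh) ? 1 : 0;
      q[i] = q0[i] + x[i];
    }
    std::vector<double> acc(n, 0.0);
    double accN = 0.0, accQ = 0.0;
    long nsamp = 0;
    for (int s = 0; s < burnin + sweeps; ++s) {
      for (int k = 0; k < n; ++k) {
        int i = (int)(unif_rand() * n);
        if (i >= n) i = n - 1;
        double wq = 0.0;
        for (int j = 0; j < n; ++j) if (j != i) wq += W(i, j) * q[j];
        double dq = 1.0 - 2.0 * x[i];
        double dE = dq * (fmat(i, p) + wq);
        if (dE <= 0 || unif_rand() < std::exp(-dE / RT)) {
          x[i] = 1 - x[i];
          q[i] = q0[i] + x[i];
        }
      }
      if (s >= burnin) {
        ++nsamp;
        // Rao-Blackwellised accumulation: the conditional protonation
        // probability of each site given the rest of the state has much
        // lower variance than the raw indicator x_i
        double nprot = 0, qt = 0;
        for (int i = 0; i < n; ++i) {
          double wq = 0.0;
          for (int j = 0; j < n; ++j) if (j != i) wq += W(i, j) * q[j];
          double pc = 1.0 / (1.0 + std::exp((fmat(i, p) + wq) / RT));
          acc[i] += pc;
          nprot += pc;
          qt += q0[i] + pc;
        }
        accN += nprot;
        accQ += qt;
      }
    }
    for (int i = 0; i < n; ++i) frac(i, p) = acc[i] / nsamp;
    mean_nprot[p] = accN / nsamp;
    mean_q[p] = accQ / nsamp;
  }
  return List::create(_["fraction"] = frac, _["mean_nprot"] = mean_nprot,
                      _["mean_charge"] = mean_q);
}
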