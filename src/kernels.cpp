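// Hot numerical loops: Shrake-Rupley point occlusion and the all-pairs
// superposed RMSD matrix used by conformational clustering.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-atom solvent-accessible surface area. xyz: n x 3, radii: n (already
// including no probe), sp: m x 3 unit-sphere points. Neighbour lists are
// radius-filtered all-pairs; occlusion testing exits at the first
// occluding neighbour.
// [[Rcpp::export]]
NumericVector cpp_sasa(const arma::mat& xyz, const arma::vec& radii,
                       const double probe, const arma::mat& sp) {
  const int n = xyz.n_rows;
  const int m = sp.n_rows;
  NumericVector area(n);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double Ri = radii[i] + probe;
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double Rj = radii[j] + probe;
      const double lim = Ri + Rj;
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < m; ++k) {
      const double px = xyz(i, 0) + Ri * sp(k, 0);
      const double py = xyz(i, 1) + Ri * sp(k, 1);
      const double pz = xyz(i, 2) + Ri * sp(k, 2);
      bool free_point = true;
      for (size_t q = 0; q < nbr.size(); ++q) {
        const int j = nbr[q];
        const double Rj = radii[j] + probe;
        const double dx = px - xyz(j, 0);
        const double dy = py - xyz(j, 1);
        const double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { free_point = false; break; }
      }
      if (free_point) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)m;
  }
  return area;
}

// Pairwise minimum (Kabsch-superposed) RMSD between all frames.
// coords: n_atoms x 3 x n_frames cube, in Angstrom; result in Angstrom.
// [[Rcpp::export]]
arma::mat cpp_pairwise_rmsd(const arma::cube& coords) {
  const int nf = coords.n_slices;
  const int na = coords.n_rows;
  arma::cube cent(coords);
  arma::vec ssd(nf);
  for (int f = 0; f < nf; ++f) {
    arma::mat X = cent.slice(f);
    arma::rowvec mu = arma::mean(X, 0);
    X.each_row() -= mu;
    cent.slice(f) = X;
    ssd[f] = arma::accu(X % X);
  }
  arma::mat out(nf, nf, arma::fill::zeros);
  arma::mat U, V;
  arma::vec s;
  for (int i = 0; i < nf; ++i) {
    for (int j = i + 1; j < nf; ++j) {
      arma::mat H = cent.slice(i).t() * cent.slice(j);  // 3x3
      if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed for frame pair");
      double d = arma::det(V * U.t());
      double tr = s[0] + s[1] + ((d < 0) ? -s[2] : s[2]);
      double msd = (ssd[i] + ssd[j] - 2.0 * tr) / (double)na;
      if (msd < 0) msd = 0;
      out(i, j) = out(j, i) = std::sqrt(msd);
    }
  }
  return out;
}
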