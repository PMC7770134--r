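#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Red-black successive over-relaxation for the finite-difference linearized
// Poisson-Boltzmann equation on a regular cubic grid with Dirichlet faces.
//
// Discretization at interior node c with the six neighbours d:
//   sum_d eps_cd (phi_d - phi_c) - kap2h2_c phi_c + src_c = 0
// where eps_cd lives on the edge between c and d (harmonic mean of node
// dielectrics), kap2h2 = eps_s * kappa^2 * h^2 in ion-accessible nodes and
// src = 4 pi k_e q_node / h.  phi holds the boundary condition on the six
// faces (never updated) and the initial guess elsewhere.
//
// [[Rcpp::export]]
List pb_sor(NumericVector phi_in, NumericVector epsx, NumericVector epsy,
            NumericVector epsz, NumericVector kap2h2, NumericVector src,
            int nx, int ny, int nz, double omega, double tol, int maxit) {
  NumericVector phi = clone(phi_in);
  auto idx = [nx, ny](int i, int j, int k) { return i + nx * (j + (R_xlen_t)ny * k); };
  // edge arrays: epsx[i,j,k] is the edge between (i,j,k) and (i+1,j,k), etc.
  auto ex = [nx, ny](int i, int j, int k) { return i + (nx - 1) * (j + (R_xlen_t)ny * k); };
  auto ey = [nx, ny](int i, int j, int k) { return i + nx * (j + (R_xlen_t)(ny - 1) * k); };
  auto ez = [nx, ny](int i, int j, int k) { return i + nx * (j + (R_xlen_t)ny * k); };

  double src_norm = 0.0;
  for (R_xlen_t t = 0; t < src.size(); ++t) src_norm += src[t] * src[t];
  src_norm = std::sqrt(src_norm);
  if (src_norm <= 0.0) src_norm = 1.0;

  double resid = NA_REAL;
  int iter = 0;
  for (iter = 1; iter <= maxit; ++iter) {
    double rsum = 0.0;
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          for (int i = 1; i < nx - 1; ++i) {
            if (((i + j + k) & 1) != color) continue;
            R_xlen_t c = idx(i, j, k);
            double exm = epsx[ex(i - 1, j, k)], exp_ = epsx[ex(i, j, k)];
            double eym = epsy[ey(i, j - 1, k)], eyp = epsy[ey(i, j, k)];
            double ezm = epsz[ez(i, j, k - 1)], ezp = epsz[ez(i, j, k)];
            double diag = exm + exp_ + eym + eyp + ezm + ezp + kap2h2[c];
            double nb = exm * phi[idx(i - 1, j, k)] + exp_ * phi[idx(i + 1, j, k)]
                      + eym * phi[idx(i, j - 1, k)] + eyp * phi[idx(i, j + 1, k)]
                      + ezm * phi[idx(i, j, k - 1)] + ezp * phi[idx(i, j, k + 1)];
            double res = nb + src[c] - diag * phi[c];
            phi[c] += omega * res / diag;
            rsum += res * res;
          }
        }
      }
    }
    resid = std::sqrt(rsum) / src_norm;
    if (resid < tol) break;
  }
  return List::create(_["phi"] = phi,
                      _["iterations"] = std::min(iter, maxit),
                      _["residual"] = resid);
}
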