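#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Structured voxel hexahedral FE kernels.
// Grid: nx*ny*nz elements, (nx+1)*(ny+1)*(nz+1) nodes, 3 dofs per node.
// Node id = ix + (nx+1)*(iy + (ny+1)*iz); dofs 3*id, 3*id+1, 3*id+2 (0-based).
// Local node order (must match the element matrices built on the R side):
// (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1).

static inline void element_dofs(int ex, int ey, int ez, int nx, int ny,
                                int *dofs) {
  static const int off[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  for (int a = 0; a < 8; ++a) {
    int nid = (ex + off[a][0]) +
              (nx + 1) * ((ey + off[a][1]) + (ny + 1) * (ez + off[a][2]));
    dofs[3 * a] = 3 * nid;
    dofs[3 * a + 1] = 3 * nid + 1;
    dofs[3 * a + 2] = 3 * nid + 2;
  }
}

// y += K(E) * u over all elements; Ke is the 24x24 unit-modulus element matrix
// (already scaled for voxel size), column-major.
static void fe_apply_raw(const double *u, double *y, const double *E, int nx,
                         int ny, int nz, const double *Ke) {
  int dofs[24];
  double ue[24];
  for (int ez = 0; ez < nz; ++ez)
    for (int ey = 0; ey < ny; ++ey)
      for (int ex = 0; ex < nx; ++ex) {
        int e = ex + nx * (ey + ny * ez);
        double Ee = E[e];
        if (Ee == 0.0) continue;
        element_dofs(ex, ey, ez, nx, ny, dofs);
        for (int a = 0; a < 24; ++a) ue[a] = u[dofs[a]];
        for (int a = 0; a < 24; ++a) {
          double acc = 0.0;
          const double *col = Ke + 24 * a; // symmetric: row a == col a
          for (int b = 0; b < 24; ++b) acc += col[b] * ue[b];
          y[dofs[a]] += Ee * acc;
        }
      }
}

// [[Rcpp::export]]
NumericVector fe_apply_cpp(NumericVector u, NumericVector E,
                           IntegerVector dims, NumericMatrix Ke) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ndof = 3 * (nx + 1) * (ny + 1) * (nz + 1);
  NumericVector y(ndof);
  fe_apply_raw(u.begin(), y.begin(), E.begin(), nx, ny, nz, Ke.begin());
  return y;
}

// Jacobi-preconditioned conjugate gradients with Dirichlet constraints
// enforced by projection. Solves K u = 0 subject to u[fixed] = val.
// [[Rcpp::export]]
List fe_pcg_cpp(NumericVector E, IntegerVector dims, NumericMatrix Ke,
                IntegerVector fixed_idx, NumericVector fixed_val,
                NumericVector u0, double tol, int maxit) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ndof = 3 * (nx + 1) * (ny + 1) * (nz + 1);
  std::vector<char> isfix(ndof, 0);
  for (int k = 0; k < fixed_idx.size(); ++k) isfix[fixed_idx[k]] = 1;

  // diagonal of K for the Jacobi preconditioner
  std::vector<double> diag(ndof, 0.0);
  {
    int dofs[24];
    for (int ez = 0; ez < nz; ++ez)
      for (int ey = 0; ey < ny; ++ey)
        for (int ex = 0; ex < nx; ++ex) {
          int e = ex + nx * (ey + ny * ez);
          double Ee = E[e];
          element_dofs(ex, ey, ez, nx, ny, dofs);
          for (int a = 0; a < 24; ++a) diag[dofs[a]] += Ee * Ke(a, a);
        }
    for (int i = 0; i < ndof; ++i)
      if (diag[i] <= 0.0) diag[i] = 1.0;
  }

  std::vector<double> u(ndof), r(ndof, 0.0), p(ndof, 0.0), z(ndof, 0.0),
      Ap(ndof, 0.0);
  for (int i = 0; i < ndof; ++i) u[i] = (u0.size() == ndof) ? u0[i] : 0.0;
  for (int k = 0; k < fixed_idx.size(); ++k) u[fixed_idx[k]] = fixed_val[k];

  // reference residual norm: load induced by the Dirichlet values alone
  double bnorm;
  {
    std::vector<double> ud(ndof, 0.0), t(ndof, 0.0);
    for (int k = 0; k < fixed_idx.size(); ++k) ud[fixed_idx[k]] = fixed_val[k];
    fe_apply_raw(ud.data(), t.data(), E.begin(), nx, ny, nz, Ke.begin());
    double s = 0.0;
    for (int i = 0; i < ndof; ++i)
      if (!isfix[i]) s += t[i] * t[i];
    bnorm = std::sqrt(s);
  }
  if (bnorm == 0.0) bnorm = 1.0;

  // r = -(K u) on free dofs
  std::fill(r.begin(), r.end(), 0.0);
  fe_apply_raw(u.data(), r.data(), E.begin(), nx, ny, nz, Ke.begin());
  for (int i = 0; i < ndof; ++i) r[i] = isfix[i] ? 0.0 : -r[i];

  double rz = 0.0;
  for (int i = 0; i < ndof; ++i) {
    z[i] = r[i] / diag[i];
    rz += r[i] * z[i];
    p[i] = z[i];
  }
  double rnorm = 0.0;
  for (int i = 0; i < ndof; ++i) rnorm += r[i] * r[i];
  rnorm = std::sqrt(rnorm);

  int it = 0;
  bool conv = (rnorm / bnorm) <= tol;
  while (!conv && it < maxit) {
    std::fill(Ap.begin(), Ap.end(), 0.0);
    fe_apply_raw(p.data(), Ap.data(), E.begin(), nx, ny, nz, Ke.begin());
    for (int i = 0; i < ndof; ++i)
      if (isfix[i]) Ap[i] = 0.0;
    double pAp = 0.0;
    for (int i = 0; i < ndof; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0.0) break; // singular / indefinite guard
    double alpha = rz / pAp;
    for (int i = 0; i < ndof; ++i) {
      u[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
    }
    double rznew = 0.0;
    for (int i = 0; i < ndof; ++i) {
      z[i] = r[i] / diag[i];
      rznew += r[i] * z[i];
    }
    double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < ndof; ++i) p[i] = z[i] + beta * p[i];
    rnorm = 0.0;
    for (int i = 0; i < ndof; ++i) rnorm += r[i] * r[i];
    rnorm = std::sqrt(rnorm);
    ++it;
    conv = (rnorm / bnorm) <= tol;
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector uout(ndof);
  std::copy(u.begin(), u.end(), uout.begin());
  return List::create(_["u"] = uout, _["iters"] = it,
                      _["relres"] = rnorm / bnorm, _["converged"] = conv);
}

// Per-element centroid strain and strain-energy density.
// B0: 6x24 strain-displacement matrix of the unit cube at its centroid
// (engineering shear convention); C0: 6x6 unit-modulus elasticity matrix.
// strain = (B0 u_e)/h, SED = 0.5 * E_e * strain' C0 strain.
// [[Rcpp::export]]
List fe_sed_cpp(NumericVector u, NumericVector E, IntegerVector dims,
                NumericMatrix B0, NumericMatrix C0, double h) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ne = nx * ny * nz;
  NumericVector sed(ne);
  NumericMatrix strain(6, ne);
  int dofs[24];
  double ue[24], eps[6], sig[6];
  for (int ez = 0; ez < nz; ++ez)
    for (int ey = 0; ey < ny; ++ey)
      for (int ex = 0; ex < nx; ++ex) {
        int e = ex + nx * (ey + ny * ez);
        element_dofs(ex, ey, ez, nx, ny, dofs);
        for (int a = 0; a < 24; ++a) ue[a] = u[dofs[a]];
        for (int i = 0; i < 6; ++i) {
          double acc = 0.0;
          for (int a = 0; a < 24; ++a) acc += B0(i, a) * ue[a];
          eps[i] = acc / h;
        }
        for (int i = 0; i < 6; ++i) {
          double acc = 0.0;
          for (int j = 0; j < 6; ++j) acc += C0(i, j) * eps[j];
          sig[i] = E[e] * acc;
        }
        double w = 0.0;
        for (int i = 0; i < 6; ++i) w += 0.5 * eps[i] * sig[i];
        sed[e] = w;
        for (int i = 0; i < 6; ++i) strain(i, e) = eps[i];
      }
  return List::create(_["sed"] = sed, _["strain"] = strain);
}
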