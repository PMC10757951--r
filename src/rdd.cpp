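#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Implicit (backward-time centred-space) step of
//   dc/dt = div(D grad c) - lambda c
// on a regular voxel grid with per-voxel isotropic diffusivity.
// Face conductances are harmonic means of the adjacent voxel diffusivities.
// Lateral (x/y) domain faces are zero-flux; Dirichlet voxels (typically the
// proximal/distal z-slabs and vessel oxygen sources) are held at fixed values
// and handled by projection (identity rows). The SPD system
//   (1/dt + lambda) c - div(D grad c) = c_old/dt
// is solved by conjugate gradients with a diagonal incomplete-Cholesky
// (DIC) preconditioner built on the 7-point stencil.

static inline double hmean(double a, double b) {
  double s = a + b;
  return (s > 0.0) ? (2.0 * a * b / s) : 0.0;
}

struct Stencil {
  int nx, ny, nz, n, nxy;
  // negative off-diagonal weights to the lower neighbours (0 across
  // Dirichlet links or domain faces) and the matrix diagonal
  std::vector<double> wx, wy, wz, diag;

  // a0[i] = 1/dt + lambda_i (per-voxel first-order loss: decay plus any
  // local consumption sink)
  Stencil(const double *D, const char *isfix, int nx_, int ny_, int nz_,
          double ih2, const double *a0)
      : nx(nx_), ny(ny_), nz(nz_), n(nx_ * ny_ * nz_), nxy(nx_ * ny_),
        wx(n, 0.0), wy(n, 0.0), wz(n, 0.0), diag(n, 0.0) {
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          int i = ix + nx * (iy + ny * iz);
          if (isfix[i]) {
            diag[i] = 1.0;
            continue;
          }
          double Di = D[i], d = a0[i];
          if (ix > 0) {
            double w = hmean(Di, D[i - 1]) * ih2;
            d += w;
            if (!isfix[i - 1]) wx[i] = -w;
          }
          if (ix < nx - 1) d += hmean(Di, D[i + 1]) * ih2;
          if (iy > 0) {
            double w = hmean(Di, D[i - nx]) * ih2;
            d += w;
            if (!isfix[i - nx]) wy[i] = -w;
          }
          if (iy < ny - 1) d += hmean(Di, D[i + nx]) * ih2;
          if (iz > 0) {
            double w = hmean(Di, D[i - nxy]) * ih2;
            d += w;
            if (!isfix[i - nxy]) wz[i] = -w;
          }
          if (iz < nz - 1) d += hmean(Di, D[i + nxy]) * ih2;
          diag[i] = d;
        }
  }

  // y = A x (projected: identity on Dirichlet voxels)
  void apply(const double *x, double *y) const {
    for (int i = 0; i < n; ++i) {
      double acc = diag[i] * x[i];
      if (wx[i] != 0.0) acc += wx[i] * x[i - 1];
      if (wy[i] != 0.0) acc += wy[i] * x[i - nx];
      if (wz[i] != 0.0) acc += wz[i] * x[i - nxy];
      y[i] = acc;
    }
    // symmetric upper contributions
    for (int i = 0; i < n; ++i) {
      if (wx[i] != 0.0) y[i - 1] += wx[i] * x[i];
      if (wy[i] != 0.0) y[i - nx] += wy[i] * x[i];
      if (wz[i] != 0.0) y[i - nxy] += wz[i] * x[i];
    }
  }
};

// [[Rcpp::export]]
List btcs_cg_cpp(NumericVector c0, NumericVector D, IntegerVector dims,
                 double h, double dt, NumericVector lambda,
                 IntegerVector fixed_idx, NumericVector fixed_val, double tol,
                 int maxit) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  double ih2 = 1.0 / (h * h);
  std::vector<double> a0(n);
  for (int i = 0; i < n; ++i) {
    double lam = (lambda.size() == 1) ? lambda[0] : lambda[i];
    a0[i] = 1.0 / dt + lam;
  }

  std::vector<char> isfix(n, 0);
  for (int k = 0; k < fixed_idx.size(); ++k) isfix[fixed_idx[k]] = 1;

  Stencil A(D.begin(), isfix.data(), nx, ny, nz, ih2, a0.data());

  // DIC factor: modified diagonal dpre with unchanged off-diagonals
  std::vector<double> dpre(A.diag);
  for (int i = 0; i < n; ++i) {
    if (A.wx[i] != 0.0) dpre[i] -= A.wx[i] * A.wx[i] / dpre[i - 1];
    if (A.wy[i] != 0.0) dpre[i] -= A.wy[i] * A.wy[i] / dpre[i - A.nx];
    if (A.wz[i] != 0.0) dpre[i] -= A.wz[i] * A.wz[i] / dpre[i - A.nxy];
    if (dpre[i] <= 0.0) dpre[i] = A.diag[i]; // safeguard
  }

  std::vector<double> c(n), r(n), p(n), z(n), Ap(n), b(n), tmp(n);
  for (int i = 0; i < n; ++i) {
    c[i] = c0[i];
    b[i] = isfix[i] ? 0.0 : c0[i] * (1.0 / dt);
  }
  for (int k = 0; k < fixed_idx.size(); ++k) c[fixed_idx[k]] = fixed_val[k];
  // fold Dirichlet values into the RHS of their free neighbours
  {
    std::vector<double> cd(n, 0.0), Ad(n);
    bool any = false;
    for (int k = 0; k < fixed_idx.size(); ++k) {
      cd[fixed_idx[k]] = fixed_val[k];
      any = true;
    }
    if (any) {
      // recompute full (unprojected) coupling of fixed values: use harmonic
      // weights directly
      int nxy = nx * ny;
      for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy)
          for (int ix = 0; ix < nx; ++ix) {
            int i = ix + nx * (iy + ny * iz);
            if (isfix[i]) continue;
            double Di = D[i], acc = 0.0;
            if (ix > 0 && isfix[i - 1])
              acc += hmean(Di, D[i - 1]) * ih2 * cd[i - 1];
            if (ix < nx - 1 && isfix[i + 1])
              acc += hmean(Di, D[i + 1]) * ih2 * cd[i + 1];
            if (iy > 0 && isfix[i - nx])
              acc += hmean(Di, D[i - nx]) * ih2 * cd[i - nx];
            if (iy < ny - 1 && isfix[i + nx])
              acc += hmean(Di, D[i + nx]) * ih2 * cd[i + nx];
            if (iz > 0 && isfix[i - nxy])
              acc += hmean(Di, D[i - nxy]) * ih2 * cd[i - nxy];
            if (iz < nz - 1 && isfix[i + nxy])
              acc += hmean(Di, D[i + nxy]) * ih2 * cd[i + nxy];
            b[i] += acc;
          }
    }
  }

  auto precond = [&](const double *rr, double *zz) {
    // forward solve (Dpre + L) y = r
    for (int i = 0; i < n; ++i) {
      double acc = rr[i];
      if (A.wx[i] != 0.0) acc -= A.wx[i] * tmp[i - 1];
      if (A.wy[i] != 0.0) acc -= A.wy[i] * tmp[i - A.nx];
      if (A.wz[i] != 0.0) acc -= A.wz[i] * tmp[i - A.nxy];
      tmp[i] = acc / dpre[i];
    }
    // backward solve (I + Dpre^{-1} U) z = y
    for (int i = n - 1; i >= 0; --i) {
      double acc = tmp[i] * dpre[i];
      // upper neighbours of i are j > i with w*[j] linking back to i
      if (i + 1 < n && A.wx[i + 1] != 0.0 && (i + 1) % A.nx != 0)
        acc -= A.wx[i + 1] * zz[i + 1];
      if (i + A.nx < n && A.wy[i + A.nx] != 0.0)
        acc -= A.wy[i + A.nx] * zz[i + A.nx];
      if (i + A.nxy < n && A.wz[i + A.nxy] != 0.0)
        acc -= A.wz[i + A.nxy] * zz[i + A.nxy];
      zz[i] = acc / dpre[i];
    }
  };

  // r = b - A c (c carries the Dirichlet values; A is projected, and b was
  // augmented with the Dirichlet coupling, so work on the free part only)
  std::vector<double> cfree(c);
  for (int k = 0; k < fixed_idx.size(); ++k) cfree[fixed_idx[k]] = 0.0;
  A.apply(cfree.data(), Ap.data());
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = isfix[i] ? 0.0 : (b[i] - Ap[i]);
    bnorm += b[i] * b[i];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;

  precond(r.data(), z.data());
  for (int i = 0; i < n; ++i)
    if (isfix[i]) z[i] = 0.0;
  double rz = 0.0;
  for (int i = 0; i < n; ++i) rz += r[i] * z[i];
  for (int i = 0; i < n; ++i) p[i] = z[i];
  double rnorm = 0.0;
  for (int i = 0; i < n; ++i) rnorm += r[i] * r[i];
  rnorm = std::sqrt(rnorm);

  int it = 0;
  bool conv = (rnorm / bnorm) <= tol;
  while (!conv && it < maxit) {
    A.apply(p.data(), Ap.data());
    for (int i = 0; i < n; ++i)
      if (isfix[i]) Ap[i] = 0.0;
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0.0) break;
    double alpha = rz / pAp;
    for (int i = 0; i < n; ++i) {
      cfree[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
    }
    precond(r.data(), z.data());
    for (int i = 0; i < n; ++i)
      if (isfix[i]) z[i] = 0.0;
    double rznew = 0.0;
    for (int i = 0; i < n; ++i) rznew += r[i] * z[i];
    double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    rnorm = 0.0;
    for (int i = 0; i < n; ++i) rnorm += r[i] * r[i];
    rnorm = std::sqrt(rnorm);
    ++it;
    conv = (rnorm / bnorm) <= tol;
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector cout(n);
  for (int i = 0; i < n; ++i) cout[i] = isfix[i] ? c[i] : cfree[i];
  return List::create(_["c"] = cout, _["iters"] = it,
                      _["relres"] = rnorm / bnorm, _["converged"] = conv);
}
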