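#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Lattice helpers for the agent layer: random-walk migration with swap
// rules and directed bias, connected-component labelling, and an exact
// Euclidean distance transform.

static const int FOFF[6][3] = {{-1, 0, 0}, {1, 0, 0},  {0, -1, 0},
                               {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};

// Cell type codes shared with the R side (see cell_type_codes()).
enum CellType {
  SSPC = 1,
  HSC = 2,
  IMMUNE = 3,
  OBL = 4,
  OCL = 5,
  LINING = 6,
  PREOCY = 7,
  OCY = 8,
  TIP = 9,
  STALK = 10
};

// One migration sweep. Agents are visited in the supplied order; each mobile
// agent takes one face-adjacent step within soft tissue (mineral < thresh).
// Occupied destinations trigger a position swap except for OBL<->OCL pairs
// and anchored residents (endothelial tip/stalk, (pre-)osteocytes).
// OCL drift up the RANKL field and OBL toward higher EFF with probability
// pbias (choosing the best admissible neighbour), otherwise uniformly.
// All randomness comes from the pre-drawn uniforms, so the sweep is fully
// reproducible from the R RNG stream.
// [[Rcpp::export]]
List migrate_cpp(IntegerMatrix pos, IntegerVector type, IntegerVector occ,
                 NumericVector mineral, NumericVector rankl,
                 NumericVector eff, IntegerVector dims, double thresh,
                 IntegerVector order, NumericVector u_move,
                 NumericVector u_bias, NumericVector u_dir,
                 NumericVector pmove, double pbias) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerMatrix P = clone(pos);
  IntegerVector O = clone(occ);
  int nmoved = 0;

  for (int k = 0; k < order.size(); ++k) {
    int a = order[k]; // 0-based agent index
    int ta = type[a];
    bool mobile = (ta >= SSPC && ta <= LINING);
    if (!mobile) continue;
    if (u_move[a] >= pmove[a]) continue;

    int x = P(a, 0), y = P(a, 1), z = P(a, 2);

    // admissible neighbours: in-domain soft tissue
    int cand[6];
    int ncand = 0;
    for (int d = 0; d < 6; ++d) {
      int tx = x + FOFF[d][0], ty = y + FOFF[d][1], tz = z + FOFF[d][2];
      if (tx < 0 || tx >= nx || ty < 0 || ty >= ny || tz < 0 || tz >= nz)
        continue;
      int ti = tx + nx * (ty + ny * tz);
      if (mineral[ti] >= thresh) continue;
      cand[ncand++] = ti;
    }
    if (ncand == 0) continue;

    int target;
    bool biased = (ta == OCL || ta == OBL) && (u_bias[a] < pbias);
    if (biased) {
      const NumericVector &f = (ta == OCL) ? rankl : eff;
      int best = cand[0];
      double bv = f[best];
      for (int q = 1; q < ncand; ++q)
        if (f[cand[q]] > bv) {
          bv = f[cand[q]];
          best = cand[q];
        }
      target = best;
    } else {
      int q = (int)(u_dir[a] * ncand);
      if (q >= ncand) q = ncand - 1;
      target = cand[q];
    }

    int src = x + nx * (y + ny * z);
    int res = O[target]; // 1-based agent id or 0
    if (res == 0) {
      O[target] = a + 1;
      O[src] = 0;
      P(a, 0) = target % nx;
      P(a, 1) = (target / nx) % ny;
      P(a, 2) = target / (nx * ny);
      ++nmoved;
    } else {
      int tb = type[res - 1];
      bool forbid = ((ta == OBL && tb == OCL) || (ta == OCL && tb == OBL) ||
                     tb == TIP || tb == STALK || tb == PREOCY || tb == OCY);
      if (!forbid) {
        // swap
        O[target] = a + 1;
        O[src] = res;
        int b = res - 1;
        P(b, 0) = x;
        P(b, 1) = y;
        P(b, 2) = z;
        P(a, 0) = target % nx;
        P(a, 1) = (target / nx) % ny;
        P(a, 2) = target / (nx * ny);
        ++nmoved;
      }
    }
  }
  return List::create(_["pos"] = P, _["occ"] = O, _["nmoved"] = nmoved);
}

// Connected components of a logical mask under face (6) or vertex (26)
// adjacency. Returns 0 for background, 1..k component labels.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      int ix = i % nx, iy = (i / nx) % ny, iz = i / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            int tx = ix + dx, ty = iy + dy, tz = iz + dz;
            if (tx < 0 || tx >= nx || ty < 0 || ty >= ny || tz < 0 || tz >= nz)
              continue;
            int t = tx + nx * (ty + ny * tz);
            if (mask[t] && lab[t] == 0) {
              lab[t] = next;
              stack.push_back(t);
            }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const double *f, double *d, int n, int *v, double *zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -INFINITY;
  zbuf[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) {
        --k;
      } else
        break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (voxel units) from each foreground voxel to the
// nearest background voxel. Background voxels get 0.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<double> g(n);
  const double INF = 1e30;
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      int base = nx * (iy + ny * iz);
      for (int ix = 0; ix < nx; ++ix) f[ix] = g[base + ix];
      dt1d(f.data(), d.data(), nx, v.data(), zbuf.data());
      for (int ix = 0; ix < nx; ++ix) g[base + ix] = d[ix];
    }
  // y pass
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) f[iy] = g[ix + nx * (iy + ny * iz)];
      dt1d(f.data(), d.data(), ny, v.data(), zbuf.data());
      for (int iy = 0; iy < ny; ++iy) g[ix + nx * (iy + ny * iz)] = d[iy];
    }
  // z pass
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iz = 0; iz < nz; ++iz) f[iz] = g[ix + nx * (iy + ny * iz)];
      dt1d(f.data(), d.data(), nz, v.data(), zbuf.data());
      for (int iz = 0; iz < nz; ++iz) g[ix + nx * (iy + ny * iz)] = d[iz];
    }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}
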