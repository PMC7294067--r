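#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = 1e30;

// ---------------------------------------------------------------------------
// 1D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher lower envelope of parabolas), with axis sample spacing w
// (distance between neighbouring samples in mm).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w, std::vector<int>& v, std::vector<double>& z) {
  double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (mm^2) from every voxel to the nearest
// voxel centre where `site` is TRUE. Voxels are anisotropic (spacing in mm).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector site, IntegerVector dim,
                         NumericVector spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; i++) out[i] = site[i] ? 0.0 : INF;
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; i++) f[i] = out[base + i];
      dt1d(f, d, n1, spacing[0], v, z);
      for (int i = 0; i < n1; i++) out[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; j++) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f, d, n2, spacing[1], v, z);
      for (int j = 0; j < n2; j++) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  // axis 3
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      for (int k = 0; k < n3; k++) f[k] = out[base + plane * k];
      dt1d(f, d, n3, spacing[2], v, z);
      for (int k = 0; k < n3; k++) out[base + plane * k] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary mask (6- or 26-connectivity).
// Components are numbered from 1 in decreasing ... (arbitrary) order; 0 is
// background. Label order follows first-encounter raster order.
// [[Rcpp::export]]
IntegerVector cpp_components(LogicalVector mask, IntegerVector dim,
                             int connectivity) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(N, 0);
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  int nn = (int)ox.size();
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < N; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    cur++;
    lab[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int x = (int)(p % n1);
      int y = (int)((p / n1) % n2);
      int z = (int)(p / ((R_xlen_t)n1 * n2));
      for (int t = 0; t < nn; t++) {
        int xx = x + ox[t], yy = y + oy[t], zz = z + oz[t];
        if (xx < 0 || xx >= n1 || yy < 0 || yy >= n2 || zz < 0 || zz >= n3)
          continue;
        R_xlen_t q = xx + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * zz);
        if (mask[q] && lab[q] == 0) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Resample a volume onto an output grid. M is the 4x4 matrix mapping 0-based
// OUTPUT voxel indices to continuous 0-based INPUT voxel indices.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dim,
                                  NumericMatrix M, IntegerVector outdim,
                                  double background, bool nearest) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int m1 = outdim[0], m2 = outdim[1], m3 = outdim[2];
  NumericVector out((R_xlen_t)m1 * m2 * m3);
  double a11 = M(0, 0), a12 = M(0, 1), a13 = M(0, 2), a14 = M(0, 3);
  double a21 = M(1, 0), a22 = M(1, 1), a23 = M(1, 2), a24 = M(1, 3);
  double a31 = M(2, 0), a32 = M(2, 1), a33 = M(2, 2), a34 = M(2, 3);
  R_xlen_t s = 0;
  for (int k = 0; k < m3; k++)
    for (int j = 0; j < m2; j++)
      for (int i = 0; i < m1; i++, s++) {
        double x = a11 * i + a12 * j + a13 * k + a14;
        double y = a21 * i + a22 * j + a23 * k + a24;
        double z = a31 * i + a32 * j + a33 * k + a34;
        if (nearest) {
          int xi = (int)std::lround(x), yi = (int)std::lround(y),
              zi = (int)std::lround(z);
          if (xi < 0 || xi >= n1 || yi < 0 || yi >= n2 || zi < 0 || zi >= n3)
            out[s] = background;
          else
            out[s] = vol[xi + (R_xlen_t)n1 * (yi + (R_xlen_t)n2 * zi)];
        } else {
          // exact upper-face samples are valid: clamp within a tolerance
          const double eps = 1e-9;
          if (x < -eps || x > n1 - 1 + eps || y < -eps || y > n2 - 1 + eps ||
              z < -eps || z > n3 - 1 + eps) {
            out[s] = background;
            continue;
          }
          x = std::min(std::max(x, 0.0), (double)(n1 - 1));
          y = std::min(std::max(y, 0.0), (double)(n2 - 1));
          z = std::min(std::max(z, 0.0), (double)(n3 - 1));
          int x0 = std::min((int)std::floor(x), n1 - 2);
          int y0 = std::min((int)std::floor(y), n2 - 2);
          int z0 = std::min((int)std::floor(z), n3 - 2);
          double fx = x - x0, fy = y - y0, fz = z - z0;
          R_xlen_t b = x0 + (R_xlen_t)n1 * (y0 + (R_xlen_t)n2 * z0);
          R_xlen_t dy = n1, dz = (R_xlen_t)n1 * n2;
          double c00 = vol[b] * (1 - fx) + vol[b + 1] * fx;
          double c10 = vol[b + dy] * (1 - fx) + vol[b + dy + 1] * fx;
          double c01 = vol[b + dz] * (1 - fx) + vol[b + dz + 1] * fx;
          double c11 = vol[b + dy + dz] * (1 - fx) + vol[b + dy + dz + 1] * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          out[s] = c0 * (1 - fz) + c1 * fz;
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Masked patch-SSD displacement search.
//
// For every voxel c inside a region of interest, consider the cubic patch of
// half-width `half` centred at c in the atlas image A. For every displacement
// d with |d_axis| <= radius, the patch is compared against the subject image
// B shifted by d: SSD is summed over voxel pairs (x, x+d) where x lies inside
// the (volume-clipped) patch window, x+d lies inside the volume, and neither
// maskA[x] nor maskB[x+d] is set (CSF masking). The SSD is normalised by the
// number of contributing pairs. The displacement minimising normalised SSD is
// retained; displacements are visited in order of increasing squared length,
// then lexicographically on (dx, dy, dz), and only strictly smaller SSD
// replaces the incumbent, so ties resolve to the smallest displacement.
//
// Only centres at least `half` voxels inside the ROI faces (or where the ROI
// face coincides with a volume face) receive correct window sums; callers
// must restrict consumption accordingly.
//
// lo: 0-based inclusive lower corner of the ROI; m: ROI dims.
// Returns ROI-shaped vectors: ssd (NA when no displacement had any valid
// pair), dx/dy/dz, npairs at the winning displacement.
// [[Rcpp::export]]
List cpp_patch_ssd(NumericVector A, NumericVector B, LogicalVector maskA,
                   LogicalVector maskB, IntegerVector dim, IntegerVector lo,
                   IntegerVector m, int half, int radius) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int l1 = lo[0], l2 = lo[1], l3 = lo[2];
  int m1 = m[0], m2 = m[1], m3 = m[2];
  R_xlen_t M = (R_xlen_t)m1 * m2 * m3;

  std::vector<double> E(M), V(M);
  NumericVector bssd(M, NA_REAL);
  IntegerVector bdx(M, NA_INTEGER), bdy(M, NA_INTEGER), bdz(M, NA_INTEGER);
  IntegerVector bnp(M, 0);
  std::vector<double> best(M, INF);

  // displacement visit order: squared norm, then lexicographic (dx, dy, dz)
  struct Disp { int dx, dy, dz, n2; };
  std::vector<Disp> disps;
  for (int dx = -radius; dx <= radius; dx++)
    for (int dy = -radius; dy <= radius; dy++)
      for (int dz = -radius; dz <= radius; dz++)
        disps.push_back({dx, dy, dz, dx * dx + dy * dy + dz * dz});
  std::stable_sort(disps.begin(), disps.end(),
                   [](const Disp& a, const Disp& b) {
                     if (a.n2 != b.n2) return a.n2 < b.n2;
                     if (a.dx != b.dx) return a.dx < b.dx;
                     if (a.dy != b.dy) return a.dy < b.dy;
                     return a.dz < b.dz;
                   });

  for (size_t di = 0; di < disps.size(); di++) {
    int dx = disps[di].dx, dy = disps[di].dy, dz = disps[di].dz;
    // per-voxel squared difference and validity over the ROI
    R_xlen_t s = 0;
    for (int k = 0; k < m3; k++) {
      int z = k + l3, zb = z + dz;
      for (int j = 0; j < m2; j++) {
        int y = j + l2, yb = y + dy;
        for (int i = 0; i < m1; i++, s++) {
          int x = i + l1, xb = x + dx;
          if (zb < 0 || zb >= n3 || yb < 0 || yb >= n2 || xb < 0 || xb >= n1) {
            E[s] = 0.0; V[s] = 0.0;
            continue;
          }
          R_xlen_t pa = x + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * z);
          R_xlen_t pb = xb + (R_xlen_t)n1 * (yb + (R_xlen_t)n2 * zb);
          if (maskA[pa] || maskB[pb]) {
            E[s] = 0.0; V[s] = 0.0;
          } else {
            double diff = A[pa] - B[pb];
            E[s] = diff * diff; V[s] = 1.0;
          }
        }
      }
    }
    // inclusive 3D prefix sums (separable in-place cumsums)
    for (R_xlen_t p = 0; p < M; p++)
      if (p % m1 != 0) { E[p] += E[p - 1]; V[p] += V[p - 1]; }
    R_xlen_t rowlen = m1, pl = (R_xlen_t)m1 * m2;
    for (R_xlen_t p = 0; p < M; p++)
      if ((p / rowlen) % m2 != 0) { E[p] += E[p - rowlen]; V[p] += V[p - rowlen]; }
    for (R_xlen_t p = pl; p < M; p++) { E[p] += E[p - pl]; V[p] += V[p - pl]; }

    // clipped box sums via inclusion-exclusion on the prefix arrays
    auto pref = [&](std::vector<double>& P, int a, int b, int c) -> double {
      if (a < 0 || b < 0 || c < 0) return 0.0;
      return P[a + (R_xlen_t)m1 * (b + (R_xlen_t)m2 * c)];
    };
    s = 0;
    for (int k = 0; k < m3; k++) {
      int c0 = std::max(0, k - half) - 1, c1 = std::min(m3 - 1, k + half);
      for (int j = 0; j < m2; j++) {
        int b0 = std::max(0, j - half) - 1, b1 = std::min(m2 - 1, j + half);
        for (int i = 0; i < m1; i++, s++) {
          int a0 = std::max(0, i - half) - 1, a1 = std::min(m1 - 1, i + half);
          double cnt =
              pref(V, a1, b1, c1) - pref(V, a0, b1, c1) - pref(V, a1, b0, c1) -
              pref(V, a1, b1, c0) + pref(V, a0, b0, c1) + pref(V, a0, b1, c0) +
              pref(V, a1, b0, c0) - pref(V, a0, b0, c0);
          if (cnt < 0.5) continue;
          double ssd =
              pref(E, a1, b1, c1) - pref(E, a0, b1, c1) - pref(E, a1, b0, c1) -
              pref(E, a1, b1, c0) + pref(E, a0, b0, c1) + pref(E, a0, b1, c0) +
              pref(E, a1, b0, c0) - pref(E, a0, b0, c0);
          double nssd = ssd / cnt;
          if (nssd < best[s]) {
            best[s] = nssd;
            bssd[s] = nssd;
            bdx[s] = dx; bdy[s] = dy; bdz[s] = dz;
            bnp[s] = (int)std::lround(cnt);
          }
        }
      }
    }
  }
  return List::create(_["ssd"] = bssd, _["dx"] = bdx, _["dy"] = bdy,
                      _["dz"] = bdz, _["npairs"] = bnp);
}
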