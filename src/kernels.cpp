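#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
using namespace Rcpp;

// Per-residue contact counts via a cell list. Two residues are neighbours when
// any heavy-atom pair lies within `cutoff` Angstrom. Returns, for each residue,
// the number of distinct other residues in contact.
// [[Rcpp::export]]
IntegerVector cpp_contact_counts(NumericMatrix coords, IntegerVector atom_res,
                                 int n_res, double cutoff) {
  const int n_atoms = coords.nrow();
  const double cut2 = cutoff * cutoff;
  // cell index per atom
  double minx = R_PosInf, miny = R_PosInf, minz = R_PosInf;
  for (int a = 0; a < n_atoms; ++a) {
    minx = std::min(minx, coords(a, 0));
    miny = std::min(miny, coords(a, 1));
    minz = std::min(minz, coords(a, 2));
  }
  std::map<long long, std::vector<int> > cells;
  std::vector<long long> key(n_atoms);
  for (int a = 0; a < n_atoms; ++a) {
    long long cx = (long long)std::floor((coords(a, 0) - minx) / cutoff);
    long long cy = (long long)std::floor((coords(a, 1) - miny) / cutoff);
    long long cz = (long long)std::floor((coords(a, 2) - minz) / cutoff);
    long long k = (cx * 1048576LL + cy) * 1048576LL + cz;
    key[a] = k;
    cells[k].push_back(a);
  }
  std::vector<std::vector<bool> > adj(n_res, std::vector<bool>(n_res, false));
  for (int a = 0; a < n_atoms; ++a) {
    long long cz0 = key[a] % 1048576LL;
    long long cy0 = (key[a] / 1048576LL) % 1048576LL;
    long long cx0 = key[a] / (1048576LL * 1048576LL);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          long long k = ((cx0 + dx) * 1048576LL + (cy0 + dy)) * 1048576LL + (cz0 + dz);
          std::map<long long, std::vector<int> >::iterator it = cells.find(k);
          if (it == cells.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t q = 0; q < v.size(); ++q) {
            int b = v[q];
            int ra = atom_res[a] - 1, rb = atom_res[b] - 1;
            if (ra == rb || adj[ra][rb]) continue;
            double d0 = coords(a, 0) - coords(b, 0);
            double d1 = coords(a, 1) - coords(b, 1);
            double d2 = coords(a, 2) - coords(b, 2);
            if (d0 * d0 + d1 * d1 + d2 * d2 <= cut2) {
              adj[ra][rb] = true;
              adj[rb][ra] = true;
            }
          }
        }
  }
  IntegerVector out(n_res);
  for (int i = 0; i < n_res; ++i) {
    int c = 0;
    for (int j = 0; j < n_res; ++j) if (adj[i][j]) ++c;
    out[i] = c;
  }
  return out;
}

// Grid-based solvent-excluded surface. The occupancy mask is the union of
// probe-inflated atoms, eroded back by the probe radius (morphological
// closing of the van der Waals solid). Volume is the voxel count; area is the
// integral of |grad| of the box-smoothed mask, a standard voxel surface
// estimator that avoids the staircase bias of face counting.
// [[Rcpp::export]]
List cpp_ses_grid(NumericMatrix coords, NumericVector radii, double probe,
                  double voxel) {
  const int n_atoms = coords.nrow();
  double maxr = 0.0;
  double minx = R_PosInf, miny = R_PosInf, minz = R_PosInf;
  double maxx = R_NegInf, maxy = R_NegInf, maxz = R_NegInf;
  for (int a = 0; a < n_atoms; ++a) {
    maxr = std::max(maxr, radii[a]);
    minx = std::min(minx, coords(a, 0)); maxx = std::max(maxx, coords(a, 0));
    miny = std::min(miny, coords(a, 1)); maxy = std::max(maxy, coords(a, 1));
    minz = std::min(minz, coords(a, 2)); maxz = std::max(maxz, coords(a, 2));
  }
  const double pad = maxr + probe + 3.0 * voxel;
  const double ox = minx - pad, oy = miny - pad, oz = minz - pad;
  const int nx = (int)std::ceil((maxx + pad - ox) / voxel) + 1;
  const int ny = (int)std::ceil((maxy + pad - oy) / voxel) + 1;
  const int nz = (int)std::ceil((maxz + pad - oz) / voxel) + 1;
  const long long nvox = (long long)nx * ny * nz;
  if (nvox > 60000000LL) stop("SES grid too large (%lld voxels); increase voxel size", nvox);
  std::vector<unsigned char> A(nvox, 0);
  // union of inflated atoms
  for (int a = 0; a < n_atoms; ++a) {
    const double r = radii[a] + probe;
    const double r2 = r * r;
    int ix0 = std::max(0, (int)std::floor((coords(a, 0) - r - ox) / voxel));
    int ix1 = std::min(nx - 1, (int)std::ceil((coords(a, 0) + r - ox) / voxel));
    int iy0 = std::max(0, (int)std::floor((coords(a, 1) - r - oy) / voxel));
    int iy1 = std::min(ny - 1, (int)std::ceil((coords(a, 1) + r - oy) / voxel));
    int iz0 = std::max(0, (int)std::floor((coords(a, 2) - r - oz) / voxel));
    int iz1 = std::min(nz - 1, (int)std::ceil((coords(a, 2) + r - oz) / voxel));
    for (int ix = ix0; ix <= ix1; ++ix) {
      double dx = ox + ix * voxel - coords(a, 0);
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = oy + iy * voxel - coords(a, 1);
        double dxy = dx * dx + dy * dy;
        if (dxy > r2) continue;
        for (int iz = iz0; iz <= iz1; ++iz) {
          double dz = oz + iz * voxel - coords(a, 2);
          if (dxy + dz * dz <= r2)
            A[((long long)ix * ny + iy) * nz + iz] = 1;
        }
      }
    }
  }
  // erosion by the probe: keep voxels whose probe-ball stays inside A
  std::vector<unsigned char> S = A;
  if (probe > 0.0) {
    // the complement is sampled at voxel centres only, which under-erodes by
    // about half a voxel; widen the erosion ball accordingly
    const double reff = probe / voxel + 0.5;
    const int m = (int)std::ceil(reff);
    std::vector<int> offx, offy, offz;
    const double p2 = reff * reff;
    for (int dx = -m; dx <= m; ++dx)
      for (int dy = -m; dy <= m; ++dy)
        for (int dz = -m; dz <= m; ++dz)
          if ((double)(dx * dx + dy * dy + dz * dz) <= p2 &&
              !(dx == 0 && dy == 0 && dz == 0)) {
            offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
          }
    const int noff = (int)offx.size();
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          long long idx = ((long long)ix * ny + iy) * nz + iz;
          if (!A[idx]) continue;
          for (int o = 0; o < noff; ++o) {
            int jx = ix + offx[o], jy = iy + offy[o], jz = iz + offz[o];
            if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz ||
                !A[((long long)jx * ny + jy) * nz + jz]) {
              S[idx] = 0;
              break;
            }
          }
        }
  }
  long long count = 0;
  for (long long i = 0; i < nvox; ++i) count += S[i];
  const double volume = (double)count * voxel * voxel * voxel;
  // one pass of 3x3x3 box smoothing, then central-difference gradient
  std::vector<float> f(nvox), g(nvox);
  for (long long i = 0; i < nvox; ++i) f[i] = (float)S[i];
  for (int pass = 0; pass < 1; ++pass) {
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          float s = 0.0f; int n = 0;
          for (int dx = -1; dx <= 1; ++dx) {
            int jx = ix + dx; if (jx < 0 || jx >= nx) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int jy = iy + dy; if (jy < 0 || jy >= ny) continue;
              for (int dz = -1; dz <= 1; ++dz) {
                int jz = iz + dz; if (jz < 0 || jz >= nz) continue;
                s += f[((long long)jx * ny + jy) * nz + jz];
                ++n;
              }
            }
          }
          g[((long long)ix * ny + iy) * nz + iz] = s / (float)n;
        }
    std::swap(f, g);
  }
  double area = 0.0;
  for (int ix = 1; ix < nx - 1; ++ix)
    for (int iy = 1; iy < ny - 1; ++iy)
      for (int iz = 1; iz < nz - 1; ++iz) {
        double gx = 0.5 * (f[((long long)(ix + 1) * ny + iy) * nz + iz] -
                           f[((long long)(ix - 1) * ny + iy) * nz + iz]);
        double gy = 0.5 * (f[((long long)ix * ny + iy + 1) * nz + iz] -
                           f[((long long)ix * ny + iy - 1) * nz + iz]);
        double gz = 0.5 * (f[((long long)ix * ny + iy) * nz + iz + 1] -
                           f[((long long)ix * ny + iy) * nz + iz - 1]);
        area += std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  area *= voxel * voxel;
  return List::create(_["area"] = area, _["volume"] = volume,
                      _["n_voxels"] = (double)count);
}

// Needleman-Wunsch with linear gap penalty and free end gaps (semi-global),
// on a precomputed similarity matrix. Returns 1-based aligned index pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_nw_align(NumericMatrix S, double gap) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix T(n + 1, m + 1); // 0 stop, 1 diag, 2 up (gap in target), 3 left
  for (int i = 0; i <= n; ++i) { H(i, 0) = 0.0; T(i, 0) = i ? 2 : 0; }
  for (int j = 0; j <= m; ++j) { H(0, j) = 0.0; T(0, j) = j ? 3 : 0; }
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double d = H(i - 1, j - 1) + S(i - 1, j - 1);
      double u = H(i - 1, j) - (j == m ? 0.0 : gap);
      double l = H(i, j - 1) - (i == n ? 0.0 : gap);
      if (d >= u && d >= l)      { H(i, j) = d; T(i, j) = 1; }
      else if (u >= l)           { H(i, j) = u; T(i, j) = 2; }
      else                       { H(i, j) = l; T(i, j) = 3; }
    }
  std::vector<int> ai, aj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int t = T(i, j);
    if (t == 1)      { ai.push_back(i); aj.push_back(j); --i; --j; }
    else if (t == 2) { --i; }
    else if (t == 3) { --j; }
    else break;
  }
  const int k = (int)ai.size();
  IntegerMatrix out(k, 2);
  for (int q = 0; q < k; ++q) {
    out(q, 0) = ai[k - 1 - q];
    out(q, 1) = aj[k - 1 - q];
  }
  return out;
}
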