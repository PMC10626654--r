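#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact ray/voxel-grid traversal (Siddon-Joseph style): each ray contributes
// to every voxel it crosses with a weight equal to the chord length of the
// intersection.  The same traversal drives the forward transform and its
// adjoint, so <T x, y> == <x, T' y> holds to machine precision.
//
// Volume: nx*ny*nz voxels of edge h, centred on the origin; voxel (ix,iy,iz)
// (0-based) occupies [(ix - nx/2) h, (ix + 1 - nx/2) h) along x, etc., with
// flat index ix + nx*(iy + ny*iz) (R array order).
//
// Rays: one per raster pixel (j,k) (0-based), through
//   p0 = oj*ej + ok*ek,  oj = (j - (nj-1)/2) h,  ok = (k - (nk-1)/2) h,
// with direction u; pixel flat index j + nj*k.

struct Hit {
  int idx;
  double len;
};

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Collect intersection lengths for one ray; returns number of hits.
static int trace_ray(const double p0[3], const double u[3],
                     const int dims[3], double h,
                     std::vector<Hit> &hits) {
  hits.clear();
  const double inf = std::numeric_limits<double>::infinity();
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = -0.5 * dims[a] * h;
    hi[a] = 0.5 * dims[a] * h;
  }
  // entry/exit parameters of the ray with the bounding box
  double tmin = -inf, tmax = inf;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(u[a]) > 1e-12) {
      double t1 = (lo[a] - p0[a]) / u[a];
      double t2 = (hi[a] - p0[a]) / u[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    } else if (p0[a] <= lo[a] || p0[a] >= hi[a]) {
      return 0; // parallel to axis a, outside the slab
    }
  }
  if (tmax <= tmin) return 0;

  // Amanatides-Woo style stepping with exact segment lengths
  double t = tmin;
  double entry[3];
  int iv[3];
  for (int a = 0; a < 3; ++a) {
    entry[a] = p0[a] + t * u[a];
    iv[a] = clampi((int)std::floor((entry[a] - lo[a]) / h), 0, dims[a] - 1);
  }
  double tnext[3], dt[3];
  int step[3];
  for (int a = 0; a < 3; ++a) {
    if (u[a] > 1e-12) {
      step[a] = 1;
      dt[a] = h / u[a];
      tnext[a] = ((lo[a] + (iv[a] + 1) * h) - p0[a]) / u[a];
    } else if (u[a] < -1e-12) {
      step[a] = -1;
      dt[a] = -h / u[a];
      tnext[a] = ((lo[a] + iv[a] * h) - p0[a]) / u[a];
    } else {
      step[a] = 0;
      dt[a] = inf;
      tnext[a] = inf;
    }
  }
  const double teps = 1e-12 * (1.0 + std::fabs(tmax));
  while (t < tmax - teps) {
    int a = 0;
    if (tnext[1] < tnext[a]) a = 1;
    if (tnext[2] < tnext[a]) a = 2;
    double tstop = tnext[a] < tmax ? tnext[a] : tmax;
    double len = tstop - t;
    if (len > 0) {
      Hit hh;
      hh.idx = iv[0] + dims[0] * (iv[1] + dims[1] * iv[2]);
      hh.len = len;
      hits.push_back(hh);
    }
    t = tstop;
    if (tnext[a] <= tmax) {
      iv[a] += step[a];
      if (iv[a] < 0 || iv[a] >= dims[a]) break;
      tnext[a] += dt[a];
    }
  }
  return (int)hits.size();
}

static void pixel_origin(int j, int k, int nj, int nk, double h,
                         const double ej[3], const double ek[3], double p0[3]) {
  double oj = (j - 0.5 * (nj - 1)) * h;
  double ok = (k - 0.5 * (nk - 1)) * h;
  for (int a = 0; a < 3; ++a) p0[a] = oj * ej[a] + ok * ek[a];
}

// [[Rcpp::export(name = ".cpp_john_forward")]]
NumericMatrix cpp_john_forward(NumericMatrix vol, IntegerVector dims_,
                               NumericVector u_, NumericVector ej_,
                               NumericVector ek_, int nj, int nk, double h) {
  int dims[3] = {dims_[0], dims_[1], dims_[2]};
  double u[3] = {u_[0], u_[1], u_[2]};
  double ej[3] = {ej_[0], ej_[1], ej_[2]};
  double ek[3] = {ek_[0], ek_[1], ek_[2]};
  int M = vol.ncol();
  NumericMatrix out(nj * nk, M);
  std::vector<Hit> hits;
  hits.reserve(4 * (dims[0] + dims[1] + dims[2]));
  double p0[3];
  for (int k = 0; k < nk; ++k) {
    for (int j = 0; j < nj; ++j) {
      pixel_origin(j, k, nj, nk, h, ej, ek, p0);
      int nh = trace_ray(p0, u, dims, h, hits);
      if (nh == 0) continue;
      int pix = j + nj * k;
      for (int m = 0; m < M; ++m) {
        double acc = 0.0;
        const double *col = &vol(0, m);
        for (int q = 0; q < nh; ++q) acc += hits[q].len * col[hits[q].idx];
        out(pix, m) = acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_john_adjoint")]]
NumericMatrix cpp_john_adjoint(NumericMatrix img, IntegerVector dims_,
                               NumericVector u_, NumericVector ej_,
                               NumericVector ek_, int nj, int nk, double h) {
  int dims[3] = {dims_[0], dims_[1], dims_[2]};
  double u[3] = {u_[0], u_[1], u_[2]};
  double ej[3] = {ej_[0], ej_[1], ej_[2]};
  double ek[3] = {ek_[0], ek_[1], ek_[2]};
  int M = img.ncol();
  int nvox = dims[0] * dims[1] * dims[2];
  NumericMatrix out(nvox, M);
  std::vector<Hit> hits;
  hits.reserve(4 * (dims[0] + dims[1] + dims[2]));
  double p0[3];
  for (int k = 0; k < nk; ++k) {
    for (int j = 0; j < nj; ++j) {
      pixel_origin(j, k, nj, nk, h, ej, ek, p0);
      int nh = trace_ray(p0, u, dims, h, hits);
      if (nh == 0) continue;
      int pix = j + nj * k;
      for (int m = 0; m < M; ++m) {
        double v = img(pix, m);
        if (v == 0.0) continue;
        double *col = &out(0, m);
        for (int q = 0; q < nh; ++q) col[hits[q].idx] += hits[q].len * v;
      }
    }
  }
  return out;
}

// Emit the sparse traversal weights of one projection as triplets
// (pixel, voxel, length); used to assemble the system matrix P once per
// geometry so solver iterations reduce to sparse matrix products.
// [[Rcpp::export(name = ".cpp_john_triplets")]]
List cpp_john_triplets(IntegerVector dims_, NumericVector u_,
                       NumericVector ej_, NumericVector ek_, int nj, int nk,
                       double h) {
  int dims[3] = {dims_[0], dims_[1], dims_[2]};
  double u[3] = {u_[0], u_[1], u_[2]};
  double ej[3] = {ej_[0], ej_[1], ej_[2]};
  double ek[3] = {ek_[0], ek_[1], ek_[2]};
  std::vector<int> pix_out, vox_out;
  std::vector<double> len_out;
  std::vector<Hit> hits;
  hits.reserve(4 * (dims[0] + dims[1] + dims[2]));
  double p0[3];
  for (int k = 0; k < nk; ++k) {
    for (int j = 0; j < nj; ++j) {
      pixel_origin(j, k, nj, nk, h, ej, ek, p0);
      int nh = trace_ray(p0, u, dims, h, hits);
      int pix = j + nj * k;
      for (int q = 0; q < nh; ++q) {
        pix_out.push_back(pix + 1);      // 1-based for R
        vox_out.push_back(hits[q].idx + 1);
        len_out.push_back(hits[q].len);
      }
    }
  }
  return List::create(Named("i") = wrap(pix_out), Named("j") = wrap(vox_out),
                      Named("x") = wrap(len_out));
}
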