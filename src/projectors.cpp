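#include <Rcpp.h>
#include <cmath>
#include <cstddef>

using namespace Rcpp;

// Joseph ray-driven projectors.
//
// A ray is traversed plane by plane along the principal axis p (the image
// axis most parallel to the ray).  At every plane the in-plane intersection
// point is bilinearly interpolated from its 4 nearest voxels; weights that
// fall outside the grid are dropped (zero padding).  The accumulated sum is
// scaled by vox[p] / |u_p|, the 3D incidence-angle correction (the distance
// between consecutive plane crossings along the ray).
//
// All accumulation is in double precision; forward and back projections use
// the identical weight computation, so the back projector is the exact
// transpose of the forward projector up to floating-point rounding.

struct Grid {
  int n[3];
  double vox[3];
  double org[3]; // world coordinates of the center of voxel (0,0,0)
};

static Grid makeGrid(const IntegerVector& shape, const NumericVector& voxel,
                     const NumericVector& origin) {
  if (shape.size() != 3 || voxel.size() != 3 || origin.size() != 3)
    stop("grid descriptors must have length 3");
  Grid g;
  for (int a = 0; a < 3; ++a) {
    g.n[a] = shape[a];
    g.vox[a] = voxel[a];
    g.org[a] = origin[a];
    if (g.n[a] < 1) stop("grid shape components must be >= 1");
    if (!(g.vox[a] > 0.0)) stop("voxel sizes must be > 0");
  }
  return g;
}

struct Ray {
  double S[3]; // start point
  double u[3]; // unit direction start -> end
  double L;    // Euclidean length
  double sf;   // step factor vox[p] / |u_p|
  int p, q, r; // principal axis and the two transverse axes (ascending)
};

static inline Ray setupRay(const double* xs, const double* xe, R_xlen_t i,
                           R_xlen_t N, const Grid& g) {
  Ray ray;
  double D[3];
  double L2 = 0.0;
  for (int a = 0; a < 3; ++a) {
    double s = xs[i + (R_xlen_t)a * N];
    double e = xe[i + (R_xlen_t)a * N];
    if (!std::isfinite(s) || !std::isfinite(e))
      stop("non-finite ray coordinates (ray %d)", (int)(i + 1));
    ray.S[a] = s;
    D[a] = e - s;
    L2 += D[a] * D[a];
  }
  ray.L = std::sqrt(L2);
  if (!(ray.L > 0.0))
    stop("degenerate (zero-length) ray %d", (int)(i + 1));
  // principal axis: argmax |u|, ties broken by the lowest axis index
  int p = 0;
  double m = -1.0;
  for (int a = 0; a < 3; ++a) {
    ray.u[a] = D[a] / ray.L;
    double au = std::fabs(ray.u[a]);
    if (au > m) { m = au; p = a; }
  }
  ray.p = p;
  ray.q = (p == 0) ? 1 : 0;
  ray.r = (p == 2) ? 1 : 2;
  ray.sf = g.vox[p] / m;
  return ray;
}

// Bilinear sample of the plane ip along the principal axis.  Returns the
// number of in-grid neighbours (0..4) and fills their linear indices and
// weights; returns -1 when the plane crossing lies outside the [start, end]
// segment.  tOut is the ray parameter (mm from the start point).
static inline int planeSample(const Ray& ray, const Grid& g, int ip,
                              double& tOut, R_xlen_t idx[4], double w[4]) {
  double xp = g.org[ray.p] + ip * g.vox[ray.p];
  double t = (xp - ray.S[ray.p]) / ray.u[ray.p];
  if (t < 0.0 || t > ray.L) return -1;
  tOut = t;
  const int q = ray.q, r = ray.r;
  double fq = (ray.S[q] + t * ray.u[q] - g.org[q]) / g.vox[q];
  double fr = (ray.S[r] + t * ray.u[r] - g.org[r]) / g.vox[r];
  int iq0 = (int)std::floor(fq);
  int ir0 = (int)std::floor(fr);
  double wq = fq - iq0;
  double wr = fr - ir0;
  int m = 0;
  int iv[3];
  iv[ray.p] = ip;
  for (int a = 0; a < 2; ++a) {
    int iq = iq0 + a;
    if (iq < 0 || iq >= g.n[q]) continue;
    double wa = a ? wq : 1.0 - wq;
    for (int b = 0; b < 2; ++b) {
      int ir = ir0 + b;
      if (ir < 0 || ir >= g.n[r]) continue;
      double wb = b ? wr : 1.0 - wr;
      iv[q] = iq;
      iv[r] = ir;
      idx[m] = (R_xlen_t)iv[0] +
               (R_xlen_t)g.n[0] * ((R_xlen_t)iv[1] + (R_xlen_t)g.n[1] * (R_xlen_t)iv[2]);
      w[m] = wa * wb;
      ++m;
    }
  }
  return m;
}

// TOF weight: Gaussian timing kernel convolved with the rectangular TOF bin,
// i.e. a difference of two error functions, truncated to exactly zero beyond
// n_sigmas * sigma + bin_width / 2.
static inline double tofWeight(double d, double binw, double sigma, double cutoff) {
  if (std::fabs(d) > cutoff) return 0.0;
  const double inv = 1.0 / (sigma * M_SQRT2);
  return 0.5 * (std::erf((d + 0.5 * binw) * inv) - std::erf((d - 0.5 * binw) * inv));
}

static void checkTof(int nbins, double binw, double sigma, double nsig) {
  if (nbins < 1 || nbins % 2 == 0) stop("number of TOF bins must be odd and >= 1");
  if (!(binw > 0.0)) stop("TOF bin width must be > 0");
  if (!(sigma > 0.0)) stop("TOF sigma must be > 0");
  if (!(nsig > 0.0)) stop("TOF truncation (n_sigmas) must be > 0");
}

// [[Rcpp::export]]
NumericVector cpp_joseph_fwd(NumericVector image, IntegerVector shape,
                             NumericVector voxel, NumericVector origin,
                             NumericMatrix xstart, NumericMatrix xend) {
  Grid g = makeGrid(shape, voxel, origin);
  if ((R_xlen_t)g.n[0] * g.n[1] * g.n[2] != image.size())
    stop("image length does not match grid shape");
  R_xlen_t N = xstart.nrow();
  if (xend.nrow() != N || xstart.ncol() != 3 || xend.ncol() != 3)
    stop("ray endpoint matrices must be N x 3 and of equal row count");
  NumericVector out(N);
  const double* xs = xstart.begin();
  const double* xe = xend.begin();
  for (R_xlen_t i = 0; i < N; ++i) {
    Ray ray = setupRay(xs, xe, i, N, g);
    double acc = 0.0, t;
    R_xlen_t idx[4];
    double w[4];
    for (int ip = 0; ip < g.n[ray.p]; ++ip) {
      int m = planeSample(ray, g, ip, t, idx, w);
      for (int k = 0; k < m; ++k) acc += w[k] * image[idx[k]];
    }
    out[i] = ray.sf * acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_joseph_back(NumericVector values, IntegerVector shape,
                              NumericVector voxel, NumericVector origin,
                              NumericMatrix xstart, NumericMatrix xend) {
  Grid g = makeGrid(shape, voxel, origin);
  R_xlen_t N = xstart.nrow();
  if (values.size() != N) stop("length of values must equal the number of rays");
  if (xend.nrow() != N || xstart.ncol() != 3 || xend.ncol() != 3)
    stop("ray endpoint matrices must be N x 3 and of equal row count");
  NumericVector img((R_xlen_t)g.n[0] * g.n[1] * g.n[2]);
  const double* xs = xstart.begin();
  const double* xe = xend.begin();
  for (R_xlen_t i = 0; i < N; ++i) {
    Ray ray = setupRay(xs, xe, i, N, g);
    double v = values[i];
    if (v == 0.0) continue; // adjoint of skipping nothing: zero contributes zero
    double t;
    R_xlen_t idx[4];
    double w[4];
    for (int ip = 0; ip < g.n[ray.p]; ++ip) {
      int m = planeSample(ray, g, ip, t, idx, w);
      for (int k = 0; k < m; ++k) img[idx[k]] += ray.sf * w[k] * v;
    }
  }
  return img;
}

// TOF sinogram mode: all bins per ray.  out(i, b), rays fastest (column-major).
// [[Rcpp::export]]
NumericMatrix cpp_joseph_fwd_tof_sino(NumericVector image, IntegerVector shape,
                                      NumericVector voxel, NumericVector origin,
                                      NumericMatrix xstart, NumericMatrix xend,
                                      int nbins, double binw, double sigma,
                                      double nsig) {
  Grid g = makeGrid(shape, voxel, origin);
  checkTof(nbins, binw, sigma, nsig);
  if ((R_xlen_t)g.n[0] * g.n[1] * g.n[2] != image.size())
    stop("image length does not match grid shape");
  R_xlen_t N = xstart.nrow();
  if (xend.nrow() != N) stop("endpoint row counts differ");
  NumericMatrix out(N, nbins);
  const double cutoff = nsig * sigma + 0.5 * binw;
  const double h = (nbins - 1) / 2.0; // integer-valued: nbins is odd
  const double* xs = xstart.begin();
  const double* xe = xend.begin();
  for (R_xlen_t i = 0; i < N; ++i) {
    Ray ray = setupRay(xs, xe, i, N, g);
    double t;
    R_xlen_t idx[4];
    double w[4];
    double tmid = 0.5 * ray.L;
    for (int ip = 0; ip < g.n[ray.p]; ++ip) {
      int m = planeSample(ray, g, ip, t, idx, w);
      if (m <= 0) continue;
      double bil = 0.0;
      for (int k = 0; k < m; ++k) bil += w[k] * image[idx[k]];
      if (bil == 0.0) continue;
      double dmid = t - tmid; // signed distance from LOR midpoint, + toward end
      int bmin = (int)std::ceil(h + (dmid - cutoff) / binw);
      int bmax = (int)std::floor(h + (dmid + cutoff) / binw);
      if (bmin < 0) bmin = 0;
      if (bmax > nbins - 1) bmax = nbins - 1;
      for (int b = bmin; b <= bmax; ++b) {
        double wt = tofWeight(dmid - (b - h) * binw, binw, sigma, cutoff);
        if (wt != 0.0) out(i, b) += ray.sf * bil * wt;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_joseph_back_tof_sino(NumericMatrix values, IntegerVector shape,
                                       NumericVector voxel, NumericVector origin,
                                       NumericMatrix xstart, NumericMatrix xend,
                                       int nbins, double binw, double sigma,
                                       double nsig) {
  Grid g = makeGrid(shape, voxel, origin);
  checkTof(nbins, binw, sigma, nsig);
  R_xlen_t N = xstart.nrow();
  if (values.nrow() != N || values.ncol() != nbins)
    stop("values must be an N x n_bins matrix");
  NumericVector img((R_xlen_t)g.n[0] * g.n[1] * g.n[2]);
  const double cutoff = nsig * sigma + 0.5 * binw;
  const double h = (nbins - 1) / 2.0;
  const double* xs = xstart.begin();
  const double* xe = xend.begin();
  for (R_xlen_t i = 0; i < N; ++i) {
    Ray ray = setupRay(xs, xe, i, N, g);
    double t;
    R_xlen_t idx[4];
    double w[4];
    double tmid = 0.5 * ray.L;
    for (int ip = 0; ip < g.n[ray.p]; ++ip) {
      int m = planeSample(ray, g, ip, t, idx, w);
      if (m <= 0) continue;
      double dmid = t - tmid;
      int bmin = (int)std::ceil(h + (dmid - cutoff) / binw);
      int bmax = (int)std::floor(h + (dmid + cutoff) / binw);
      if (bmin < 0) bmin = 0;
      if (bmax > nbins - 1) bmax = nbins - 1;
      double s = 0.0;
      for (int b = bmin; b <= bmax; ++b) {
        double wt = tofWeight(dmid - (b - h) * binw, binw, sigma, cutoff);
        if (wt != 0.0) s += wt * values(i, b);
      }
      if (s == 0.0) continue;
      for (int k = 0; k < m; ++k) img[idx[k]] += ray.sf * w[k] * s;
    }
  }
  return img;
}

// TOF listmode mode: one signed bin per event; bin center at sb * binw from
// the LOR midpoint (signed toward the end point), identical arithmetic to the
// sinogram column b = sb + (nbins-1)/2.
// [[Rcpp::export]]
NumericVector cpp_joseph_fwd_tof_lm(NumericVector image, IntegerVector shape,
                                    NumericVector voxel, NumericVector origin,
                                    NumericMatrix xstart, NumericMatrix xend,
                                    IntegerVector tofbin, int nbins, double binw,
                                    double sigma, double nsig) {
  Grid g = makeGrid(shape, voxel, origin);
  checkTof(nbins, binw, sigma, nsig);
  if ((R_xlen_t)g.n[0] * g.n[1] * g.n[2] != image.size())
    stop("image length does not match grid shape");
  R_xlen_t N = xstart.nrow();
  if (tofbin.size() != N) stop("one TOF bin per event required");
  NumericVector out(N);
  const double cutoff = nsig * sigma + 0.5 * binw;
  const int hb = (nbins - 1) / 2;
  const double h = (nbins - 1) / 2.0;
  const double* xs = xstart.begin();
  const double* xe = xend.begin();
  for (R_xlen_t i = 0; i < N; ++i) {
    int sb = tofbin[i];
    if (sb == NA_INTEGER || sb < -hb || sb > hb)
      stop("TOF bin index out of range (event %d)", (int)(i + 1));
    Ray ray = setupRay(xs, xe, i, N, g);
    double t;
    R_xlen_t idx[4];
    double w[4];
    double tmid = 0.5 * ray.L;
    double cb = ((sb + hb) - h) * binw; // == sb * binw, sinogram arithmetic
    double acc = 0.0;
    for (int ip = 0; ip < g.n[ray.p]; ++ip) {
      int m = planeSample(ray, g, ip, t, idx, w);
      if (m <= 0) continue;
      double wt = tofWeight((t - tmid) - cb, binw, sigma, cutoff);
      if (wt == 0.0) continue;
      double bil = 0.0;
      for (int k = 0; k < m; ++k) bil += w[k] * image[idx[k]];
      acc += bil * wt;
    }
    out[i] = ray.sf * acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_joseph_back_tof_lm(NumericVector values, IntegerVector shape,
                                     NumericVector voxel, NumericVector origin,
                                     NumericMatrix xstart, NumericMatrix xend,
                                     IntegerVector tofbin, int nbins, double binw,
                                     double sigma, double nsig) {
  Grid g = makeGrid(shape, voxel, origin);
  checkTof(nbins, binw, sigma, nsig);
  R_xlen_t N = xstart.nrow();
  if (values.size() != N) stop("length of values must equal the number of events");
  if (tofbin.size() != N) stop("one TOF bin per event required");
  NumericVector img((R_xlen_t)g.n[0] * g.n[1] * g.n[2]);
  const double cutoff = nsig * sigma + 0.5 * binw;
  const int hb = (nbins - 1) / 2;
  const double h = (nbins - 1) / 2.0;
  const double* xs = xstart.begin();
  const double* xe = xend.begin();
  for (R_xlen_t i = 0; i < N; ++i) {
    int sb = tofbin[i];
    if (sb == NA_INTEGER || sb < -hb || sb > hb)
      stop("TOF bin index out of range (event %d)", (int)(i + 1));
    double v = values[i];
    if (v == 0.0) continue;
    Ray ray = setupRay(xs, xe, i, N, g);
    double t;
    R_xlen_t idx[4];
    double w[4];
    double tmid = 0.5 * ray.L;
    double cb = ((sb + hb) - h) * binw;
    for (int ip = 0; ip < g.n[ray.p]; ++ip) {
      int m = planeSample(ray, g, ip, t, idx, w);
      if (m <= 0) continue;
      double wt = tofWeight((t - tmid) - cb, binw, sigma, cutoff);
      if (wt == 0.0) continue;
      for (int k = 0; k < m; ++k) img[idx[k]] += ray.sf * w[k] * wt * v;
    }
  }
  return img;
}

// [[Rcpp::export]]
NumericVector cpp_tof_bin_weight(NumericVector d, double binw, double sigma,
                                 double nsig) {
  checkTof(1, binw, sigma, nsig);
  const double cutoff = nsig * sigma + 0.5 * binw;
  R_xlen_t n = d.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = tofWeight(d[i], binw, sigma, cutoff);
  return out;
}
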