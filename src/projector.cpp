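#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fan-beam geometry conventions (2D, flat equidistant detector):
//  - isocenter at the origin; source on a circle of radius `sid`,
//    S(beta) = sid * (cos b, sin b), angles counter-clockwise (radians);
//  - central axis unit vector a = -(cos b, sin b) (source -> isocenter);
//  - detector axis unit vector u = (-sin b, cos b);
//  - detector element j (0-based) sits at S + sdd*a + u_j*u with
//    u_j = (j - (ndet-1)/2) * pitch + offset;
//  - image is an n x n matrix, row i / col j (0-based) centred at
//    x = (j - (n-1)/2) * px, y = ((n-1)/2 - i) * px  (row down, y up),
//    so the grid centre is the isocenter.
// Line integrals are evaluated by sampling the image with bilinear
// interpolation at steps of px/2 along each ray (Joseph-style), restricted
// to the circle circumscribing the grid.

static inline double bilin(const NumericMatrix& img, int n, double c, double r) {
  // c: fractional column, r: fractional row (0-based); zero outside.
  if (c < -1.0 || c > n || r < -1.0 || r > n) return 0.0;
  int c0 = (int)std::floor(c), r0 = (int)std::floor(r);
  double fc = c - c0, fr = r - r0;
  double v = 0.0;
  for (int dr = 0; dr <= 1; ++dr) {
    int rr = r0 + dr;
    if (rr < 0 || rr >= n) continue;
    double wr = dr ? fr : 1.0 - fr;
    for (int dc = 0; dc <= 1; ++dc) {
      int cc = c0 + dc;
      if (cc < 0 || cc >= n) continue;
      double wc = dc ? fc : 1.0 - fc;
      v += wr * wc * img(rr, cc);
    }
  }
  return v;
}

static inline bool ray_circle(double sx, double sy, double dx, double dy,
                              double R, double& t0, double& t1) {
  // |S + t d|^2 = R^2 with |d| = 1
  double b = sx * dx + sy * dy;
  double c = sx * sx + sy * sy - R * R;
  double disc = b * b - c;
  if (disc <= 0) return false;
  double s = std::sqrt(disc);
  t0 = -b - s; t1 = -b + s;
  return t1 > 0;
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(const NumericMatrix& img, double px,
                                  double sid, double sdd, int ndet,
                                  double pitch, double offset,
                                  const NumericVector& angles,
                                  double step_frac = 0.5) {
  const int n = img.nrow();
  const int nang = angles.size();
  NumericMatrix sino(nang, ndet);
  const double Rc = 0.5 * n * px * M_SQRT2 + px;
  const double h = step_frac * px;
  const double half = 0.5 * (ndet - 1);
  for (int ia = 0; ia < nang; ++ia) {
    double b = angles[ia];
    double cb = std::cos(b), sb = std::sin(b);
    double sx = sid * cb, sy = sid * sb;
    double ax = -cb, ay = -sb;       // central axis
    double ux = -sb, uy = cb;        // detector axis
    for (int j = 0; j < ndet; ++j) {
      double u = (j - half) * pitch + offset;
      double dx = sdd * ax + u * ux, dy = sdd * ay + u * uy;
      double norm = std::sqrt(dx * dx + dy * dy);
      dx /= norm; dy /= norm;
      double t0, t1;
      if (!ray_circle(sx, sy, dx, dy, Rc, t0, t1)) continue;
      if (t0 < 0) t0 = 0;
      int m = (int)std::ceil((t1 - t0) / h);
      if (m < 1) continue;
      double dt = (t1 - t0) / m;
      double acc = 0.0;
      for (int s = 0; s < m; ++s) {
        double t = t0 + (s + 0.5) * dt;
        double x = sx + t * dx, y = sy + t * dy;
        double c = x / px + 0.5 * (n - 1);
        double r = 0.5 * (n - 1) - y / px;
        acc += bilin(img, n, c, r);
      }
      sino(ia, j) = acc * dt;
    }
  }
  return sino;
}

// Exact adjoint of cpp_forward_project (ray-driven splatting).
// [[Rcpp::export]]
NumericMatrix cpp_back_project(const NumericMatrix& sino, double px,
                               double sid, double sdd, int ndet,
                               double pitch, double offset,
                               const NumericVector& angles, int n,
                               double step_frac = 0.5) {
  const int nang = angles.size();
  NumericMatrix img(n, n);
  const double Rc = 0.5 * n * px * M_SQRT2 + px;
  const double h = step_frac * px;
  const double half = 0.5 * (ndet - 1);
  for (int ia = 0; ia < nang; ++ia) {
    double b = angles[ia];
    double cb = std::cos(b), sb = std::sin(b);
    double sx = sid * cb, sy = sid * sb;
    double ax = -cb, ay = -sb, ux = -sb, uy = cb;
    for (int j = 0; j < ndet; ++j) {
      double v = sino(ia, j);
      if (v == 0.0) continue;
      double u = (j - half) * pitch + offset;
      double dx = sdd * ax + u * ux, dy = sdd * ay + u * uy;
      double norm = std::sqrt(dx * dx + dy * dy);
      dx /= norm; dy /= norm;
      double t0, t1;
      if (!ray_circle(sx, sy, dx, dy, Rc, t0, t1)) continue;
      if (t0 < 0) t0 = 0;
      int m = (int)std::ceil((t1 - t0) / h);
      if (m < 1) continue;
      double dt = (t1 - t0) / m;
      double w = v * dt;
      for (int s = 0; s < m; ++s) {
        double t = t0 + (s + 0.5) * dt;
        double x = sx + t * dx, y = sy + t * dy;
        double c = x / px + 0.5 * (n - 1);
        double r = 0.5 * (n - 1) - y / px;
        if (c < -1.0 || c > n || r < -1.0 || r > n) continue;
        int c0 = (int)std::floor(c), r0 = (int)std::floor(r);
        double fc = c - c0, fr = r - r0;
        for (int dr = 0; dr <= 1; ++dr) {
          int rr = r0 + dr;
          if (rr < 0 || rr >= n) continue;
          double wr = dr ? fr : 1.0 - fr;
          for (int dc = 0; dc <= 1; ++dc) {
            int cc = c0 + dc;
            if (cc < 0 || cc >= n) continue;
            double wc = dc ? fc : 1.0 - fc;
            img(rr, cc) += w * wr * wc;
          }
        }
      }
    }
  }
  return img;
}

// Pixel-driven weighted backprojection of a ramp-filtered sinogram given in
// isocenter-rescaled detector coordinates s (spacing ds, first sample s0).
// Accumulates q(beta, s*(x)) / U(x,beta)^2; view weights (dbeta, Parker,
// half-scan factor) are pre-applied per row by the caller.
// [[Rcpp::export]]
NumericMatrix cpp_fbp_backproject(const NumericMatrix& fsino, double px,
                                  int n, double sid, double s0, double ds,
                                  const NumericVector& angles) {
  const int nang = angles.size();
  const int ndet = fsino.ncol();
  NumericMatrix img(n, n);
  for (int ia = 0; ia < nang; ++ia) {
    double b = angles[ia];
    double cb = std::cos(b), sb = std::sin(b);
    for (int i = 0; i < n; ++i) {
      double y = (0.5 * (n - 1) - i) * px;
      for (int j = 0; j < n; ++j) {
        double x = (j - 0.5 * (n - 1)) * px;
        double va = sid - (x * cb + y * sb);   // (x - S) . a
        if (va <= 1e-6) continue;
        double vu = -x * sb + y * cb;          // (x - S) . u
        double U = va / sid;
        double s = sid * vu / va;
        double fs = (s - s0) / ds;
        if (fs < 0 || fs > ndet - 1) continue;
        int k = (int)std::floor(fs);
        if (k >= ndet - 1) k = ndet - 2;
        double f = fs - k;
        double q = (1.0 - f) * fsino(ia, k) + f * fsino(ia, k + 1);
        img(i, j) += q / (U * U);
      }
    }
  }
  return img;
}

// Harmonic inpainting: solve the 4-neighbour Laplace equation on the masked
// entries (mask != 0) with Dirichlet data from unmasked entries, via SOR.
// Grid edges use the available neighbours only (Neumann at the boundary).
// [[Rcpp::export]]
NumericMatrix cpp_harmonic_inpaint(const NumericMatrix& valsIn,
                                   const IntegerMatrix& mask,
                                   double tol = 1e-8, int maxit = 5000,
                                   double omega = 1.8) {
  int nr = valsIn.nrow(), nc = valsIn.ncol();
  NumericMatrix vals = clone(valsIn);
  // initialise masked entries with per-row linear interpolation for speed
  for (int i = 0; i < nr; ++i) {
    int j = 0;
    while (j < nc) {
      if (mask(i, j)) {
        int j0 = j;
        while (j < nc && mask(i, j)) ++j;
        int jl = j0 - 1, jr = j;
        double vl = (jl >= 0) ? vals(i, jl) : NA_REAL;
        double vr = (jr < nc) ? vals(i, jr) : NA_REAL;
        if (ISNA(vl) && ISNA(vr)) { vl = vr = 0.0; }
        else if (ISNA(vl)) vl = vr;
        else if (ISNA(vr)) vr = vl;
        for (int jj = j0; jj < jr; ++jj) {
          double f = (jr == j0 - 1) ? 0.0 :
            (double)(jj - j0 + 1) / (double)(jr - j0 + 1);
          vals(i, jj) = vl + f * (vr - vl);
        }
      } else ++j;
    }
  }
  for (int it = 0; it < maxit; ++it) {
    double maxd = 0.0;
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) {
        if (!mask(i, j)) continue;
        double s = 0.0; int m = 0;
        if (i > 0)      { s += vals(i - 1, j); ++m; }
        if (i < nr - 1) { s += vals(i + 1, j); ++m; }
        if (j > 0)      { s += vals(i, j - 1); ++m; }
        if (j < nc - 1) { s += vals(i, j + 1); ++m; }
        double nv = s / m;
        double d = nv - vals(i, j);
        vals(i, j) += omega * d;
        double ad = std::fabs(d);
        if (ad > maxd) maxd = ad;
      }
    }
    if (maxd < tol) break;
  }
  return vals;
}
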