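#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Ray-driven projection over a regular pixel grid using Amanatides-Woo
// traversal with exact intersection lengths (Siddon weights).  Forward and
// back projection share this single routine so the operator pair is an exact
// matrix transpose.
//
// Grid convention: pixel (row r, col c), 0-based, row 0 at the top.
// Pixel (r, c) center sits at
//   x = xmin + (c + 0.5) * h,   y = ymax - (r + 0.5) * h,
// with the rotation axis at the grid center.  Ray directions are unit
// vectors, so traversal parameters are lengths in mm and each weight is the
// exact chord length of the ray inside the pixel.

static inline void traverse_ray(
    double ox, double oy, double dx, double dy,
    double xmin, double ymax, double h, int nx, int ny,
    bool adjoint, double val,
    const double *img, double *out_img, double *acc) {

  const double xmax = xmin + nx * h;
  const double ymin = ymax - ny * h;
  const double inf = std::numeric_limits<double>::infinity();

  // clip ray to the grid bounding box (slab method)
  double tmin = -inf, tmax = inf;
  if (dx != 0.0) {
    double t1 = (xmin - ox) / dx, t2 = (xmax - ox) / dx;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  } else if (ox <= xmin || ox >= xmax) {
    return;
  }
  if (dy != 0.0) {
    double t1 = (ymin - oy) / dy, t2 = (ymax - oy) / dy;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  } else if (oy <= ymin || oy >= ymax) {
    return;
  }
  if (tmax <= tmin) return;

  // starting cell from the midpoint of the first segment
  double t = tmin;
  double xm = ox + (tmin + 1e-12) * dx;
  double ym = oy + (tmin + 1e-12) * dy;
  int c = (int)std::floor((xm - xmin) / h);
  int r = (int)std::floor((ymax - ym) / h);
  if (c < 0) c = 0;
  if (c >= nx) c = nx - 1;
  if (r < 0) r = 0;
  if (r >= ny) r = ny - 1;

  const int step_c = (dx > 0) ? 1 : -1;
  const int step_r = (dy > 0) ? -1 : 1;  // y decreasing => row increasing
  const double tDeltaX = (dx != 0.0) ? h / std::fabs(dx) : inf;
  const double tDeltaY = (dy != 0.0) ? h / std::fabs(dy) : inf;

  // parameter value at the next x / y grid-line crossing
  double tMaxX;
  if (dx > 0)      tMaxX = ((xmin + (c + 1) * h) - ox) / dx;
  else if (dx < 0) tMaxX = ((xmin + c * h) - ox) / dx;
  else             tMaxX = inf;
  double tMaxY;
  if (dy > 0)      tMaxY = ((ymax - r * h) - oy) / dy;
  else if (dy < 0) tMaxY = ((ymax - (r + 1) * h) - oy) / dy;
  else             tMaxY = inf;

  while (t < tmax - 1e-12) {
    double tnext = std::min(std::min(tMaxX, tMaxY), tmax);
    double w = tnext - t;
    if (w > 0 && r >= 0 && r < ny && c >= 0 && c < nx) {
      const R_xlen_t idx = (R_xlen_t)r + (R_xlen_t)c * ny;  // column-major
      if (adjoint) out_img[idx] += w * val;
      else         *acc += w * img[idx];
    }
    t = tnext;
    if (tMaxX <= tMaxY) {
      c += step_c;
      tMaxX += tDeltaX;
    } else {
      r += step_r;
      tMaxY += tDeltaY;
    }
    if (c < 0 || c >= nx || r < 0 || r >= ny) break;
  }
}

// [[Rcpp::export(name = ".cpp_forward_project")]]
NumericVector cpp_forward_project(NumericMatrix img,
                                  NumericVector sx, NumericVector sy,
                                  NumericVector dx, NumericVector dy,
                                  double xmin, double ymax, double h) {
  const int ny = img.nrow(), nx = img.ncol();
  const R_xlen_t nray = sx.size();
  NumericVector out(nray);
  const double *ip = img.begin();
  for (R_xlen_t i = 0; i < nray; ++i) {
    double acc = 0.0;
    traverse_ray(sx[i], sy[i], dx[i], dy[i], xmin, ymax, h, nx, ny,
                 false, 0.0, ip, nullptr, &acc);
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_back_project")]]
NumericMatrix cpp_back_project(NumericVector vals,
                               NumericVector sx, NumericVector sy,
                               NumericVector dx, NumericVector dy,
                               double xmin, double ymax, double h,
                               int nrow, int ncol) {
  NumericMatrix out(nrow, ncol);
  const R_xlen_t nray = sx.size();
  double *op = out.begin();
  for (R_xlen_t i = 0; i < nray; ++i) {
    if (vals[i] == 0.0) continue;
    traverse_ray(sx[i], sy[i], dx[i], dy[i], xmin, ymax, h, ncol, nrow,
                 true, vals[i], nullptr, op, nullptr);
  }
  return out;
}

// Pixel-driven weighted back projection for fan-beam FBP.
// q: filtered sinogram (n_views x n_bins), already ramp-filtered and
// multiplied by the detector sample spacing; betas: view angles (rad).
// Curved detector: bins equiangular in fan angle gamma, weight 1/L^2 with L
// the source-to-pixel distance.  Flat detector: bins equispaced in s on a
// detector at distance sdd from the source, weight (Dso/t)^2 with t the
// pixel's depth along the central ray.
// The caller multiplies the result by the view angular increment.
// [[Rcpp::export(name = ".cpp_fbp_backproject")]]
NumericMatrix cpp_fbp_backproject(NumericMatrix q, NumericVector betas,
                                  double dso, bool curved,
                                  double dstep, double sdd,
                                  double xmin, double ymax, double h,
                                  int nrow, int ncol) {
  const int nv = q.nrow(), nb = q.ncol();
  NumericMatrix out(nrow, ncol);
  const double kc = 0.5 * (nb - 1);
  for (int v = 0; v < nv; ++v) {
    const double cb = std::cos(betas[v]), sb = std::sin(betas[v]);
    const double sxv = dso * cb, syv = dso * sb;
    // u: unit from source toward isocenter; w: lateral (90 deg CCW from u)
    const double ux = -cb, uy = -sb;
    const double wx = -uy, wy = ux;
    for (int c = 0; c < ncol; ++c) {
      const double px = xmin + (c + 0.5) * h;
      for (int r = 0; r < nrow; ++r) {
        const double py = ymax - (r + 0.5) * h;
        const double rx = px - sxv, ry = py - syv;
        const double t = rx * ux + ry * uy;      // depth along central ray
        if (t <= 0) continue;
        const double l = rx * wx + ry * wy;      // lateral offset
        double kf, wgt;
        if (curved) {
          kf = std::atan2(l, t) / dstep + kc;
          wgt = 1.0 / (rx * rx + ry * ry);
        } else {
          kf = (sdd * l / t) / dstep + kc;
          const double u = t / dso;
          wgt = 1.0 / (u * u);
        }
        if (kf < 0 || kf > nb - 1) continue;
        const int k0 = (int)std::floor(kf);
        const int k1 = (k0 + 1 < nb) ? k0 + 1 : k0;
        const double fr = kf - k0;
        const double qv = (1.0 - fr) * q(v, k0) + fr * q(v, k1);
        out(r, c) += wgt * qv;
      }
    }
  }
  return out;
}
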