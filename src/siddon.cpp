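#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

// Ray-driven system-matrix assembly with exact ray-pixel intersection
// lengths (Siddon-style incremental traversal).
//
// Image convention: ny rows (y), nx columns (x), square pixels of side h,
// grid centred at the origin.  Pixel (i, j), 0-based with row 0 at the
// top, has centre x = (j - (nx-1)/2) * h, y = ((ny-1)/2 - i) * h and
// flattened index i + ny * j (column-major over the (ny, nx) plane).
//
// Ray index for angle a (0-based) and detector bin k: r = a + n_angles*k,
// matching the column-major flattening of an (n_angles, n_bins) sinogram
// plane.

namespace {

struct Tripletizer {
  std::vector<int> i, j;
  std::vector<double> x;
  void push(int r, int c, double v) {
    if (v > 0.0) { i.push_back(r + 1); j.push_back(c + 1); x.push_back(v); }
  }
};

// March one ray p(t) = o + t*u (u unit) through the grid, emitting
// per-pixel chord lengths.
void trace_ray(double ox, double oy, double ux, double uy,
               int ny, int nx, double h, int row, Tripletizer &out) {
  const double inf = std::numeric_limits<double>::infinity();
  const double xlo = -0.5 * nx * h, xhi = 0.5 * nx * h;
  const double ylo = -0.5 * ny * h, yhi = 0.5 * ny * h;

  double tmin = -inf, tmax = inf;
  if (ux != 0.0) {
    double t1 = (xlo - ox) / ux, t2 = (xhi - ox) / ux;
    tmin = std::max(tmin, std::min(t1, t2));
    tmax = std::min(tmax, std::max(t1, t2));
  } else if (ox <= xlo || ox >= xhi) return;
  if (uy != 0.0) {
    double t1 = (ylo - oy) / uy, t2 = (yhi - oy) / uy;
    tmin = std::max(tmin, std::min(t1, t2));
    tmax = std::min(tmax, std::max(t1, t2));
  } else if (oy <= ylo || oy >= yhi) return;
  if (!(tmax > tmin)) return;

  const double eps = 1e-12 * h;
  double t = tmin;
  double px = ox + t * ux, py = oy + t * uy;
  // current cell
  int jx = (int)std::floor((px - xlo) / h);
  int iyu = (int)std::floor((py - ylo) / h);  // y index measured upward
  if (jx < 0) jx = 0; if (jx > nx - 1) jx = nx - 1;
  if (iyu < 0) iyu = 0; if (iyu > ny - 1) iyu = ny - 1;

  int stepx = (ux > 0) ? 1 : (ux < 0 ? -1 : 0);
  int stepy = (uy > 0) ? 1 : (uy < 0 ? -1 : 0);
  double tdx = (ux != 0.0) ? h / std::fabs(ux) : inf;
  double tdy = (uy != 0.0) ? h / std::fabs(uy) : inf;

  double tmx = inf, tmy = inf;
  if (ux > 0)      tmx = ((xlo + (jx + 1) * h) - ox) / ux;
  else if (ux < 0) tmx = ((xlo + jx * h) - ox) / ux;
  if (uy > 0)      tmy = ((ylo + (iyu + 1) * h) - oy) / uy;
  else if (uy < 0) tmy = ((ylo + iyu * h) - oy) / uy;

  while (t < tmax - eps) {
    double tnext = std::min(std::min(tmx, tmy), tmax);
    double len = tnext - t;
    if (len > eps) {
      int irow = ny - 1 - iyu;            // row index counts downward
      out.push(row, irow + ny * jx, len);
    }
    if (tnext >= tmax - eps) break;
    if (tmx <= tmy) { jx += stepx; tmx += tdx; }
    else            { iyu += stepy; tmy += tdy; }
    t = tnext;
    if (jx < 0 || jx >= nx || iyu < 0 || iyu >= ny) break;
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List siddon_triplets(std::string beam, Rcpp::NumericVector angles_rad,
                           int nbins, double pitch, int ny, int nx, double h,
                           double dso, double dsd) {
  const int na = angles_rad.size();
  Tripletizer out;
  const bool fan = (beam == "fan2D");
  for (int a = 0; a < na; ++a) {
    const double th = angles_rad[a];
    const double c = std::cos(th), s = std::sin(th);
    // detector axis n = (-sin, cos); beam axis d = (cos, sin)
    for (int k = 0; k < nbins; ++k) {
      const double off = (k - 0.5 * (nbins - 1)) * pitch;
      const int row = a + na * k;
      if (!fan) {
        trace_ray(-s * off, c * off, c, s, ny, nx, h, row, out);
      } else {
        const double sx = -dso * c, sy = -dso * s;          // source
        const double px = sx + dsd * c - s * off;            // bin centre
        const double py = sy + dsd * s + c * off;
        double ux = px - sx, uy = py - sy;
        const double nrm = std::sqrt(ux * ux + uy * uy);
        ux /= nrm; uy /= nrm;
        trace_ray(sx, sy, ux, uy, ny, nx, h, row, out);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("i") = out.i,
                            Rcpp::Named("j") = out.j,
                            Rcpp::Named("x") = out.x,
                            Rcpp::Named("nrow") = na * nbins,
                            Rcpp::Named("ncol") = ny * nx);
}
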