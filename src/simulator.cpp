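#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Geometric tolerance for "on the boundary" tests, in metres. Vessel widths
// are O(1e-3) m so 1e-12 m is far below any feature size.
static const double EPS_ON = 1e-12;

static inline double sqr(double x) { return x * x; }

// Squared distance from point (px,py) to segment (ax,ay)-(bx,by).
static double pt_seg_dist2(double px, double py,
                           double ax, double ay, double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double len2 = dx * dx + dy * dy;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / len2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  return sqr(px - (ax + t * dx)) + sqr(py - (ay + t * dy));
}

// Even-odd point-in-polygon with a boundary-inclusive convention: points
// within EPS_ON of an edge count as inside (particles resting on a wall under
// friction must remain valid).
static bool pip(double x, double y, const NumericMatrix& poly) {
  int n = poly.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = poly(i, 0), yi = poly(i, 1);
    double xj = poly(j, 0), yj = poly(j, 1);
    if (pt_seg_dist2(x, y, xj, yj, xi, yi) <= EPS_ON * EPS_ON) return true;
    if ((yi > y) != (yj > y)) {
      double xint = xj + (y - yj) * (xi - xj) / (yi - yj);
      if (xint > x) inside = !inside;
    }
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector cpp_point_in_polygon(NumericVector px, NumericVector py,
                                   NumericMatrix poly) {
  int n = px.size();
  LogicalVector out(n);
  for (int i = 0; i < n; i++) out[i] = pip(px[i], py[i], poly);
  return out;
}

// Index of the boundary edge (i -> i+1, wrapping) closest to (x,y).
static int nearest_edge(double x, double y, const NumericMatrix& poly,
                        double* foot_x, double* foot_y) {
  int n = poly.nrow();
  double best = std::numeric_limits<double>::infinity();
  int ibest = 0;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double d2 = pt_seg_dist2(x, y, poly(j, 0), poly(j, 1), poly(i, 0), poly(i, 1));
    if (d2 < best) { best = d2; ibest = j; }
  }
  // recompute the foot on the winning edge
  int j = ibest, i = (ibest + 1) % n;
  double ax = poly(j, 0), ay = poly(j, 1), bx = poly(i, 0), by = poly(i, 1);
  double dx = bx - ax, dy = by - ay, len2 = dx * dx + dy * dy;
  double t = len2 > 0 ? ((x - ax) * dx + (y - ay) * dy) / len2 : 0.0;
  if (t < 0) t = 0; if (t > 1) t = 1;
  *foot_x = ax + t * dx;
  *foot_y = ay + t * dy;
  return ibest;
}

// [[Rcpp::export]]
List cpp_nearest_boundary(NumericVector px, NumericVector py,
                          NumericMatrix poly) {
  int n = px.size();
  NumericMatrix foot(n, 2), normal(n, 2);
  for (int k = 0; k < n; k++) {
    double fx, fy;
    int e = nearest_edge(px[k], py[k], poly, &fx, &fy);
    int e2 = (e + 1) % poly.nrow();
    double tx = poly(e2, 0) - poly(e, 0), ty = poly(e2, 1) - poly(e, 1);
    double L = std::sqrt(tx * tx + ty * ty);
    double nx = -ty / L, ny = tx / L;  // one of the two unit normals
    // orient the normal into the lumen: probe both sides
    double probe = 1e-9;
    if (!pip(fx + nx * probe, fy + ny * probe, poly)) { nx = -nx; ny = -ny; }
    foot(k, 0) = fx;  foot(k, 1) = fy;
    normal(k, 0) = nx; normal(k, 1) = ny;
  }
  return List::create(_["foot"] = foot, _["normal"] = normal);
}

// Proper/inclusive 2D segment intersection test (touching counts).
static bool seg_intersect(double p0x, double p0y, double p1x, double p1y,
                          double q0x, double q0y, double q1x, double q1y) {
  double d1 = (q1x - q0x) * (p0y - q0y) - (q1y - q0y) * (p0x - q0x);
  double d2 = (q1x - q0x) * (p1y - q0y) - (q1y - q0y) * (p1x - q0x);
  double d3 = (p1x - p0x) * (q0y - p0y) - (p1y - p0y) * (q0x - p0x);
  double d4 = (p1x - p0x) * (q1y - p0y) - (p1y - p0y) * (q1x - p0x);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
  // collinear / endpoint-touching cases
  auto on = [](double ax, double ay, double bx, double by, double cx, double cy) {
    return pt_seg_dist2(cx, cy, ax, ay, bx, by) <= EPS_ON * EPS_ON;
  };
  if (d1 == 0 && on(q0x, q0y, q1x, q1y, p0x, p0y)) return true;
  if (d2 == 0 && on(q0x, q0y, q1x, q1y, p1x, p1y)) return true;
  if (d3 == 0 && on(p0x, p0y, p1x, p1y, q0x, q0y)) return true;
  if (d4 == 0 && on(p0x, p0y, p1x, p1y, q1x, q1y)) return true;
  return false;
}

// [[Rcpp::export]]
IntegerVector cpp_gate_crossed(NumericVector p0x, NumericVector p0y,
                               NumericVector p1x, NumericVector p1y,
                               NumericMatrix gates) {
  // gates: one row per gate, columns (x0, y0, x1, y1).
  // Returns the 1-based index of the first gate crossed, or NA.
  int n = p0x.size();
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; i++) {
    for (int g = 0; g < gates.nrow(); g++) {
      if (seg_intersect(p0x[i], p0y[i], p1x[i], p1y[i],
                        gates(g, 0), gates(g, 1), gates(g, 2), gates(g, 3))) {
        out[i] = g + 1;
        break;
      }
    }
  }
  return out;
}

// ---- lookup-table sampling on a regular grid -------------------------------
//
// The table stores velocities at in-lumen nodes of a regular grid with origin
// (x0,y0) and spacing h. `cell` maps grid node (ix,iy) (column-major,
// ix + iy*nx) to a 0-based row of `vel`, or -1 for nodes outside the lumen.
// Because table points are exactly the in-lumen grid nodes, the snapped node
// (when in-lumen) is the exact Euclidean nearest neighbour; otherwise an
// expanding Chebyshev ring search recovers exactness: any node in ring m is
// at Euclidean distance >= (m - 0.5)*h from a query inside the snapped cell.
struct Grid {
  double x0, y0, h;
  int nx, ny;
  const int* cell;
  const double* vx;
  const double* vy;
  int npts;
};

static int grid_nearest(double x, double y, const Grid& g) {
  int ix = (int)std::lround((x - g.x0) / g.h);
  int iy = (int)std::lround((y - g.y0) / g.h);
  if (ix < 0) ix = 0; if (ix > g.nx - 1) ix = g.nx - 1;
  if (iy < 0) iy = 0; if (iy > g.ny - 1) iy = g.ny - 1;
  int best = -1;
  double bestd2 = std::numeric_limits<double>::infinity();
  int mmax = g.nx + g.ny;
  for (int m = 0; m <= mmax; m++) {
    if (best >= 0 && sqr((m - 0.5) * g.h) > bestd2) break;
    int lo_x = ix - m, hi_x = ix + m, lo_y = iy - m, hi_y = iy + m;
    for (int jx = lo_x; jx <= hi_x; jx++) {
      if (jx < 0 || jx >= g.nx) continue;
      for (int jy = lo_y; jy <= hi_y; jy++) {
        if (jy < 0 || jy >= g.ny) continue;
        if (m > 0 && jx != lo_x && jx != hi_x && jy != lo_y && jy != hi_y)
          continue;  // only the ring
        int id = g.cell[jx + jy * g.nx];
        if (id >= 0) {
          double d2 = sqr(x - (g.x0 + jx * g.h)) + sqr(y - (g.y0 + jy * g.h));
          if (d2 < bestd2) { bestd2 = d2; best = id; }
        }
      }
    }
  }
  return best;
}

static void sample_vel(double x, double y, const Grid& g,
                       const NumericMatrix& poly, double* u, double* v) {
  if (!pip(x, y, poly)) { *u = 0.0; *v = 0.0; return; }
  int id = grid_nearest(x, y, g);
  if (id < 0) { *u = 0.0; *v = 0.0; return; }
  *u = g.vx[id];
  *v = g.vy[id];
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_flow(NumericVector px, NumericVector py,
                              double x0, double y0, double h, int nx, int ny,
                              IntegerVector cell, NumericMatrix vel,
                              NumericMatrix poly) {
  Grid g{x0, y0, h, nx, ny, INTEGER(cell),
         REAL(vel), REAL(vel) + vel.nrow(), (int)vel.nrow()};
  int n = px.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; i++) {
    double u, v;
    sample_vel(px[i], py[i], g, poly, &u, &v);
    out(i, 0) = u;
    out(i, 1) = v;
  }
  return out;
}

// ---- collision resolution --------------------------------------------------
//
// A proposed move left the lumen. The crossing point is located by bisection
// (to 1e-9 m) between the last inside point and the outside proposal; the
// residual displacement and the velocity are reflected about the tangent of
// the boundary edge nearest the outside point (at corners this picks the
// nearer edge), and the tangential components are attenuated by (1 - mu)
// wall friction. Up to `max_reflect` reflections are chained; if the particle
// is still outside (corner trap), it is marked stuck on the boundary.
static const double BISECT_TOL = 1e-9;

static bool resolve_collision(double ax, double ay, double bx, double by,
                              double* vx, double* vy,
                              const NumericMatrix& poly, double mu,
                              int max_reflect,
                              double* out_x, double* out_y) {
  double cvx = *vx, cvy = *vy;
  for (int attempt = 0; attempt < max_reflect; attempt++) {
    // bisection: a inside, b outside
    double lox = ax, loy = ay, hix = bx, hiy = by;
    while (sqr(hix - lox) + sqr(hiy - loy) > BISECT_TOL * BISECT_TOL) {
      double mx = 0.5 * (lox + hix), my = 0.5 * (loy + hiy);
      if (pip(mx, my, poly)) { lox = mx; loy = my; }
      else { hix = mx; hiy = my; }
    }
    double cx = lox, cy = loy;  // inside, within 1e-9 of the wall
    // wall tangent/normal from the edge nearest the just-outside point
    double fx, fy;
    int e = nearest_edge(hix, hiy, poly, &fx, &fy);
    int e2 = (e + 1) % poly.nrow();
    double tx = poly(e2, 0) - poly(e, 0), ty = poly(e2, 1) - poly(e, 1);
    double L = std::sqrt(tx * tx + ty * ty);
    tx /= L; ty /= L;
    double nx = -ty, ny = tx;
    // residual displacement beyond the wall, reflected; friction on tangent
    double rx = bx - cx, ry = by - cy;
    double rt = rx * tx + ry * ty, rn = rx * nx + ry * ny;
    rx = (1.0 - mu) * rt * tx - rn * nx;
    ry = (1.0 - mu) * rt * ty - rn * ny;
    double vt = cvx * tx + cvy * ty, vn = cvx * nx + cvy * ny;
    cvx = (1.0 - mu) * vt * tx - vn * nx;
    cvy = (1.0 - mu) * vt * ty - vn * ny;
    double px = cx + rx, py = cy + ry;
    if (pip(px, py, poly)) {
      *out_x = px; *out_y = py; *vx = cvx; *vy = cvy;
      return true;
    }
    ax = cx; ay = cy; bx = px; by = py;
  }
  // corner trap: park the particle on the boundary (stuck)
  *out_x = ax; *out_y = ay; *vx = 0.0; *vy = 0.0;
  return false;
}

// [[Rcpp::export]]
List cpp_resolve_collision(NumericVector p_prev, NumericVector p_prop,
                           NumericVector v, NumericMatrix poly,
                           double mu, int max_reflect) {
  double vx = v[0], vy = v[1], ox, oy;
  bool ok = resolve_collision(p_prev[0], p_prev[1], p_prop[0], p_prop[1],
                              &vx, &vy, poly, mu, max_reflect, &ox, &oy);
  return List::create(_["position"] = NumericVector::create(ox, oy),
                      _["velocity"] = NumericVector::create(vx, vy),
                      _["resolved"] = ok);
}

// ---- the minor loop --------------------------------------------------------
//
// Runs n_steps minor-loop iterations with a fixed magnetic force (the force
// is commanded once per major loop). Per active particle and step:
//   v_p = v_f(p) + F / (3 pi eta d)   (semi-static Stokes balance; `vscale`
//                                      is the precomputed 1/(3 pi eta d))
//   p' = p + v_p * dt
// then outlet-gate crossing is checked first (an exit wins over a wall hit),
// and a proposal leaving the lumen is resolved by reflection.
// Status codes: 0 active, 1 exited, 2 stuck.
// [[Rcpp::export]]
List cpp_run_minors(NumericMatrix positions, IntegerVector status,
                    IntegerVector exit_gate, NumericVector exit_time,
                    double t0, int n_steps, double dt,
                    double fx, double fy, double vscale,
                    double mu, int max_reflect,
                    NumericMatrix poly, NumericMatrix gates,
                    double x0, double y0, double h, int nx, int ny,
                    IntegerVector cell, NumericMatrix vel) {
  NumericMatrix pos = clone(positions);
  IntegerVector st = clone(status);
  IntegerVector eg = clone(exit_gate);
  NumericVector et = clone(exit_time);
  int N = pos.nrow();
  NumericMatrix vout(N, 2);
  Grid g{x0, y0, h, nx, ny, INTEGER(cell),
         REAL(vel), REAL(vel) + vel.nrow(), (int)vel.nrow()};
  double dfx = fx * vscale, dfy = fy * vscale;  // magnetic drift velocity
  double t = t0;
  for (int s = 0; s < n_steps; s++) {
    t = t0 + (s + 1) * dt;  // no per-step accumulation error
    for (int i = 0; i < N; i++) {
      if (st[i] != 0) continue;
      double x = pos(i, 0), y = pos(i, 1);
      double u, v;
      sample_vel(x, y, g, poly, &u, &v);
      double vpx = u + dfx, vpy = v + dfy;
      double nxp = x + vpx * dt, nyp = y + vpy * dt;
      // exit check first: gates lie on the hull, so an exiting step would
      // otherwise be mistaken for a wall collision
      int hit = NA_INTEGER;
      for (int gg = 0; gg < gates.nrow(); gg++) {
        if (seg_intersect(x, y, nxp, nyp,
                          gates(gg, 0), gates(gg, 1),
                          gates(gg, 2), gates(gg, 3))) { hit = gg + 1; break; }
      }
      if (hit != NA_INTEGER) {
        st[i] = 1; eg[i] = hit; et[i] = t;
        pos(i, 0) = nxp; pos(i, 1) = nyp;
        vout(i, 0) = vpx; vout(i, 1) = vpy;
        continue;
      }
      if (!pip(nxp, nyp, poly)) {
        double ox, oy;
        bool ok = resolve_collision(x, y, nxp, nyp, &vpx, &vpy, poly, mu,
                                    max_reflect, &ox, &oy);
        pos(i, 0) = ox; pos(i, 1) = oy;
        if (!ok) st[i] = 2;
      } else {
        pos(i, 0) = nxp; pos(i, 1) = nyp;
      }
      vout(i, 0) = vpx; vout(i, 1) = vpy;
    }
  }
  return List::create(_["positions"] = pos, _["velocities"] = vout,
                      _["status"] = st, _["exit_gate"] = eg,
                      _["exit_time"] = et, _["t"] = t);
}
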