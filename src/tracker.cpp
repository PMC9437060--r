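// Particle advection-diffusion core.
//
// Deterministic displacement by Euler / midpoint RK2 / classical RK4 on the
// space-time interpolated velocity (currents + windage), then an
// Euler-Maruyama random-walk increment per axis with sd sqrt(2*K*dt).
// Stranding is resolved geometrically: whenever a sub-step ends inside the
// near-coast band, the displacement segment is intersected with every
// coastline edge and the earliest crossing in path order wins.
//
// Normal draws come from R's RNG so a single set.seed() governs runs.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Stencil {
  int i0, j0;
  double w00, w01, w10, w11, wsum;
};

struct FieldSpec {
  int type;  // 0 harmonic, 1 snapshots
  double x0, y0, dx, dy;
  int nx, ny;
  IntegerMatrix water;  // ny x nx, 1 = water
  NumericMatrix ur, vr, ua, va;
  double period;
  NumericVector times;  // snapshots
  NumericVector u, v;   // dim (nt, ny, nx), column-major
  int nt;
};

inline void make_stencil(const FieldSpec& f, double x, double y, Stencil& s) {
  double fx = (x - f.x0) / f.dx;
  double fy = (y - f.y0) / f.dy;
  int i0 = (int)std::floor(fx);
  int j0 = (int)std::floor(fy);
  if (i0 < 0) i0 = 0; if (i0 > f.nx - 2) i0 = f.nx - 2;
  if (j0 < 0) j0 = 0; if (j0 > f.ny - 2) j0 = f.ny - 2;
  double tx = fx - i0; if (tx < 0) tx = 0; if (tx > 1) tx = 1;
  double ty = fy - j0; if (ty < 0) ty = 0; if (ty > 1) ty = 1;
  s.i0 = i0; s.j0 = j0;
  s.w00 = (1 - tx) * (1 - ty) * f.water(j0, i0);
  s.w01 = tx * (1 - ty) * f.water(j0, i0 + 1);
  s.w10 = (1 - tx) * ty * f.water(j0 + 1, i0);
  s.w11 = tx * ty * f.water(j0 + 1, i0 + 1);
  s.wsum = s.w00 + s.w01 + s.w10 + s.w11;
}

inline double interp_mat(const NumericMatrix& m, const Stencil& s) {
  if (s.wsum <= 0) return 0.0;
  return (s.w00 * m(s.j0, s.i0) + s.w01 * m(s.j0, s.i0 + 1) +
          s.w10 * m(s.j0 + 1, s.i0) + s.w11 * m(s.j0 + 1, s.i0 + 1)) / s.wsum;
}

inline double interp_arr(const NumericVector& a, int nt, int ny, int k,
                         const Stencil& s) {
  if (s.wsum <= 0) return 0.0;
  auto at = [&](int j, int i) { return a[k + nt * (j + ny * i)]; };
  return (s.w00 * at(s.j0, s.i0) + s.w01 * at(s.j0, s.i0 + 1) +
          s.w10 * at(s.j0 + 1, s.i0) + s.w11 * at(s.j0 + 1, s.i0 + 1)) / s.wsum;
}

struct WindSpec {
  bool active;
  double t0, dt;
  NumericVector u, v;
};

inline void velocity(const FieldSpec& f, const WindSpec& w, double alpha,
                     double x, double y, double t, double& u, double& v) {
  Stencil s;
  make_stencil(f, x, y, s);
  if (f.type == 0) {
    double ph = (f.period > 0) ? std::cos(2.0 * M_PI * t / f.period) : 0.0;
    u = interp_mat(f.ur, s) + ph * interp_mat(f.ua, s);
    v = interp_mat(f.vr, s) + ph * interp_mat(f.va, s);
  } else {
    int k = (int)(std::upper_bound(f.times.begin(), f.times.end(), t) -
                  f.times.begin()) - 1;
    if (k < 0) k = 0; if (k > f.nt - 2) k = f.nt - 2;
    double fr = (t - f.times[k]) / (f.times[k + 1] - f.times[k]);
    if (fr < 0) fr = 0; if (fr > 1) fr = 1;
    double u0 = interp_arr(f.u, f.nt, f.ny, k, s);
    double u1 = interp_arr(f.u, f.nt, f.ny, k + 1, s);
    double v0 = interp_arr(f.v, f.nt, f.ny, k, s);
    double v1 = interp_arr(f.v, f.nt, f.ny, k + 1, s);
    u = (1 - fr) * u0 + fr * u1;
    v = (1 - fr) * v0 + fr * v1;
  }
  if (w.active) {
    int k = (int)std::floor((t - w.t0) / w.dt);
    if (k < 0) k = 0;
    if (k >= w.u.size()) k = w.u.size() - 1;
    u += alpha * w.u[k];
    v += alpha * w.v[k];
  }
  if (!std::isfinite(u) || !std::isfinite(v))
    stop("non-finite velocity at a water point");
}

inline void deterministic_step(const FieldSpec& f, const WindSpec& w,
                               double alpha, int integrator, double x,
                               double y, double t, double dt, double& nx,
                               double& ny) {
  double u1, v1, u2, v2, u3, v3, u4, v4;
  velocity(f, w, alpha, x, y, t, u1, v1);
  if (integrator == 0) {  // euler
    nx = x + dt * u1; ny = y + dt * v1;
    return;
  }
  if (integrator == 1) {  // midpoint RK2
    velocity(f, w, alpha, x + 0.5 * dt * u1, y + 0.5 * dt * v1, t + 0.5 * dt,
             u2, v2);
    nx = x + dt * u2; ny = y + dt * v2;
    return;
  }
  velocity(f, w, alpha, x + 0.5 * dt * u1, y + 0.5 * dt * v1, t + 0.5 * dt,
           u2, v2);
  velocity(f, w, alpha, x + 0.5 * dt * u2, y + 0.5 * dt * v2, t + 0.5 * dt,
           u3, v3);
  velocity(f, w, alpha, x + dt * u3, y + dt * v3, t + dt, u4, v4);
  nx = x + dt / 6.0 * (u1 + 2 * u2 + 2 * u3 + u4);
  ny = y + dt / 6.0 * (v1 + 2 * v2 + 2 * v3 + v4);
}

// Earliest crossing of path (ox,oy)->(ex,ey) with any edge; returns edge
// index (0-based) or -1, with path parameter in *ubest.
inline int first_crossing(const NumericMatrix& edges, double ox, double oy,
                          double ex, double ey, double* ubest) {
  double rx = ex - ox, ry = ey - oy;
  int best = -1;
  double ub = 2.0;
  int n = edges.nrow();
  for (int i = 0; i < n; ++i) {
    double ax = edges(i, 0), ay = edges(i, 1);
    double sx = edges(i, 2) - ax, sy = edges(i, 3) - ay;
    double denom = rx * sy - ry * sx;
    if (std::fabs(denom) < 1e-300) continue;
    double qx = ax - ox, qy = ay - oy;
    double u = (qx * sy - qy * sx) / denom;
    double vv = (qx * ry - qy * rx) / denom;
    if (u >= 0 && u <= 1 && vv >= -1e-12 && vv <= 1 + 1e-12 && u < ub) {
      ub = u;
      best = i;
    }
  }
  *ubest = ub;
  return best;
}

}  // namespace

// [[Rcpp::export]]
List advance_particles_cpp(NumericVector px, NumericVector py, double t0,
                           int nsub, double dt, List field_spec,
                           List wind_spec, double alpha, double K,
                           int integrator, NumericMatrix edges,
                           IntegerMatrix band, double bx0, double by0,
                           double bdx, NumericVector rect, int land_mode) {
  int n = px.size();
  FieldSpec f;
  f.type = as<int>(field_spec["type"]);
  f.x0 = as<double>(field_spec["x0"]);
  f.y0 = as<double>(field_spec["y0"]);
  f.dx = as<double>(field_spec["dx"]);
  f.dy = as<double>(field_spec["dy"]);
  f.nx = as<int>(field_spec["nx"]);
  f.ny = as<int>(field_spec["ny"]);
  f.water = as<IntegerMatrix>(field_spec["water"]);
  if (f.type == 0) {
    f.ur = as<NumericMatrix>(field_spec["u_res"]);
    f.vr = as<NumericMatrix>(field_spec["v_res"]);
    f.ua = as<NumericMatrix>(field_spec["u_amp"]);
    f.va = as<NumericMatrix>(field_spec["v_amp"]);
    f.period = as<double>(field_spec["period"]);
  } else {
    f.times = as<NumericVector>(field_spec["times"]);
    f.u = as<NumericVector>(field_spec["u"]);
    f.v = as<NumericVector>(field_spec["v"]);
    f.nt = f.times.size();
  }
  WindSpec w;
  w.active = as<bool>(wind_spec["active"]);
  if (w.active) {
    w.t0 = as<double>(wind_spec["t0"]);
    w.dt = as<double>(wind_spec["dt"]);
    w.u = as<NumericVector>(wind_spec["u"]);
    w.v = as<NumericVector>(wind_spec["v"]);
  }
  double sd = (K > 0) ? std::sqrt(2.0 * K * dt) : 0.0;
  int nxb = band.ncol(), nyb = band.nrow();
  auto flagged = [&](double x, double y) -> bool {
    int i = (int)std::floor((x - bx0) / bdx);
    int j = (int)std::floor((y - by0) / bdx);
    if (i < 0 || j < 0 || i >= nxb || j >= nyb) return true;
    return band(j, i) != 0;
  };

  NumericVector ox = clone(px), oy = clone(py);
  IntegerVector status(n, 0);
  NumericVector etime(n, t0 + nsub * dt);
  IntegerVector edge_hit(n, 0);

  for (int p = 0; p < n; ++p) {
    double x = ox[p], y = oy[p];
    double t = t0;
    for (int s = 0; s < nsub; ++s) {
      double xn, yn;
      deterministic_step(f, w, alpha, integrator, x, y, t, dt, xn, yn);
      if (sd > 0) {
        xn += R::rnorm(0.0, sd);
        yn += R::rnorm(0.0, sd);
      }
      if (flagged(x, y) || flagged(xn, yn)) {
        double u;
        int hit = first_crossing(edges, x, y, xn, yn, &u);
        if (hit >= 0) {
          if (land_mode == 0) {  // absorb
            double ub = u > 1e-9 ? u - 1e-9 : 0.0;
            ox[p] = x + ub * (xn - x);
            oy[p] = y + ub * (yn - y);
            status[p] = 1;
            etime[p] = t + u * dt;
            edge_hit[p] = hit + 1;
            break;
          } else {  // reflect across the crossed edge line
            double ax = edges(hit, 0), ay = edges(hit, 1);
            double dxx = edges(hit, 2) - ax, dyy = edges(hit, 3) - ay;
            double len2 = dxx * dxx + dyy * dyy;
            double tt = ((xn - ax) * dxx + (yn - ay) * dyy) / len2;
            double fx = ax + tt * dxx, fy = ay + tt * dyy;
            double mx = 2 * fx - xn, my = 2 * fy - yn;
            double u2;
            if (first_crossing(edges, x, y, mx, my, &u2) >= 0) {
              xn = x; yn = y;  // reflection blocked: hold position
            } else {
              xn = mx; yn = my;
            }
          }
        }
      }
      x = xn; y = yn;
      t = t0 + (s + 1) * dt;
      if (x < rect[0] || x > rect[1] || y < rect[2] || y > rect[3]) {
        ox[p] = x; oy[p] = y;
        status[p] = 2;
        etime[p] = t;
        break;
      }
    }
    if (status[p] == 0) {
      ox[p] = x;
      oy[p] = y;
    }
  }
  return List::create(_["x"] = ox, _["y"] = oy, _["status"] = status,
                      _["time"] = etime, _["edge"] = edge_hit);
}
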