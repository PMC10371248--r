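// Monte-Carlo forward ray tracer for canopy light distribution.
//
// Direct beam: stratified-jittered launch grid on the top plane, rays travel
// along the solar direction. Diffuse sky: cosine-weighted downward
// hemisphere (uniform overcast). On a facet hit a fraction 1-R-T of the ray
// power is scored as absorbed; survival is single-ray Russian roulette
// (reflect with probability R, transmit with probability T, terminate
// otherwise) with Lambertian redistribution about the facet normal. Lateral
// domain boundaries are periodic; the ground plane absorbs; rays leaving
// through the top escape. Deterministic for a fixed seed: each ray owns a
// counter-seeded RNG stream.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

struct RNG {
  uint64_t s0, s1;
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  RNG(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0xD1B54A32D192ED03ULL);
    s0 = splitmix(x); s1 = splitmix(x);
    if (!(s0 | s1)) s1 = 1;
  }
  uint64_t next() { // xorshift128+
    uint64_t a = s0, b = s1;
    s0 = b;
    a ^= a << 23;
    s1 = a ^ b ^ (a >> 17) ^ (b >> 26);
    return s1 + b;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Vec { double x, y, z; };
inline Vec vsub(Vec a, Vec b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
inline Vec cross(Vec a, Vec b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
inline double dot(Vec a, Vec b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
inline Vec vscale(Vec a, double s) { return {a.x*s, a.y*s, a.z*s}; }
inline Vec vnorm(Vec a) {
  double n = std::sqrt(dot(a, a));
  return (n > 0) ? vscale(a, 1.0/n) : a;
}

// Lambertian (cosine-weighted) direction about axis w
Vec cosine_dir(Vec w, RNG &rng) {
  double u1 = rng.unif(), u2 = rng.unif();
  double r = std::sqrt(u1), phi = 2.0 * M_PI * u2;
  double zl = std::sqrt(std::max(0.0, 1.0 - u1));
  Vec a = (std::fabs(w.x) < 0.9) ? Vec{1,0,0} : Vec{0,1,0};
  Vec u = vnorm(cross(a, w));
  Vec v = cross(w, u);
  return {u.x*r*std::cos(phi) + v.x*r*std::sin(phi) + w.x*zl,
          u.y*r*std::cos(phi) + v.y*r*std::sin(phi) + w.y*zl,
          u.z*r*std::cos(phi) + v.z*r*std::sin(phi) + w.z*zl};
}

struct Scene {
  std::vector<double> vx, vy, vz;      // triangle vertices, 3 per triangle
  std::vector<Vec> nrm;                // unit geometric normals
  std::vector<double> Rf, Tf;
  double lo[3], hi[3];                 // domain box
  int ng[3];
  double cell[3];
  std::vector<int> cstart, cidx;       // CSR triangle lists per grid cell

  int ntri() const { return (int)Rf.size(); }

  int clampc(int c, int d) const { return std::max(0, std::min(ng[d]-1, c)); }
  int ccoord(double v, int d) const {
    return clampc((int)std::floor((v - lo[d]) / cell[d]), d);
  }

  void build_grid() {
    const int nt = ntri();
    double ext[3];
    for (int d = 0; d < 3; ++d) ext[d] = std::max(hi[d] - lo[d], 1e-6);
    double target = std::cbrt((double)std::max(nt, 1) * 4.0 / (ext[0]*ext[1]*ext[2]));
    for (int d = 0; d < 3; ++d) {
      ng[d] = std::max(1, std::min(256, (int)std::floor(ext[d] * target)));
      cell[d] = ext[d] / ng[d];
    }
    long ncell = (long)ng[0] * ng[1] * ng[2];
    cstart.assign(ncell + 1, 0);
    std::vector<int> c0(nt), c1(nt), r0(nt), r1(nt), s0v(nt), s1v(nt);
    for (int t = 0; t < nt; ++t) {
      double bx0 = std::min(vx[3*t], std::min(vx[3*t+1], vx[3*t+2]));
      double bx1 = std::max(vx[3*t], std::max(vx[3*t+1], vx[3*t+2]));
      double by0 = std::min(vy[3*t], std::min(vy[3*t+1], vy[3*t+2]));
      double by1 = std::max(vy[3*t], std::max(vy[3*t+1], vy[3*t+2]));
      double bz0 = std::min(vz[3*t], std::min(vz[3*t+1], vz[3*t+2]));
      double bz1 = std::max(vz[3*t], std::max(vz[3*t+1], vz[3*t+2]));
      c0[t] = ccoord(bx0, 0); c1[t] = ccoord(bx1, 0);
      r0[t] = ccoord(by0, 1); r1[t] = ccoord(by1, 1);
      s0v[t] = ccoord(bz0, 2); s1v[t] = ccoord(bz1, 2);
      for (int z = s0v[t]; z <= s1v[t]; ++z)
        for (int y = r0[t]; y <= r1[t]; ++y)
          for (int x = c0[t]; x <= c1[t]; ++x)
            cstart[((long)z * ng[1] + y) * ng[0] + x + 1]++;
    }
    for (long c = 0; c < ncell; ++c) cstart[c+1] += cstart[c];
    cidx.resize(cstart[ncell]);
    std::vector<int> fill(cstart.begin(), cstart.end() - 1);
    for (int t = 0; t < nt; ++t)
      for (int z = s0v[t]; z <= s1v[t]; ++z)
        for (int y = r0[t]; y <= r1[t]; ++y)
          for (int x = c0[t]; x <= c1[t]; ++x)
            cidx[fill[((long)z * ng[1] + y) * ng[0] + x]++] = t;
  }

  // Moller-Trumbore; returns t or -1
  double intersect(int t, Vec o, Vec d) const {
    Vec p0{vx[3*t], vy[3*t], vz[3*t]};
    Vec p1{vx[3*t+1], vy[3*t+1], vz[3*t+1]};
    Vec p2{vx[3*t+2], vy[3*t+2], vz[3*t+2]};
    Vec e1 = vsub(p1, p0), e2 = vsub(p2, p0);
    Vec pv = cross(d, e2);
    double det = dot(e1, pv);
    if (std::fabs(det) < 1e-14) return -1;
    double inv = 1.0 / det;
    Vec tv = vsub(o, p0);
    double u = dot(tv, pv) * inv;
    if (u < -1e-9 || u > 1 + 1e-9) return -1;
    Vec qv = cross(tv, e1);
    double v = dot(d, qv) * inv;
    if (v < -1e-9 || u + v > 1 + 1e-9) return -1;
    return dot(e2, qv) * inv;
  }
};

// traversal event types
enum { EV_TRI = 0, EV_TOP, EV_GROUND, EV_SIDE_X0, EV_SIDE_X1, EV_SIDE_Y0, EV_SIDE_Y1, EV_NONE };

struct Event { int type; double t; int tri; };

// nearest event for a ray starting at o (inside the box) with direction d
Event traverse(const Scene &sc, Vec o, Vec d, int skip_tri, double eps) {
  int cx = sc.ccoord(o.x, 0), cy = sc.ccoord(o.y, 1), cz = sc.ccoord(o.z, 2);
  int stepx = (d.x > 0) - (d.x < 0), stepy = (d.y > 0) - (d.y < 0), stepz = (d.z > 0) - (d.z < 0);
  const double INF = 1e30;
  double tmaxx = INF, tmaxy = INF, tmaxz = INF;
  double tdx = INF, tdy = INF, tdz = INF;
  if (d.x != 0) {
    double nb = sc.lo[0] + (cx + (stepx > 0)) * sc.cell[0];
    tmaxx = (nb - o.x) / d.x; tdx = sc.cell[0] / std::fabs(d.x);
  }
  if (d.y != 0) {
    double nb = sc.lo[1] + (cy + (stepy > 0)) * sc.cell[1];
    tmaxy = (nb - o.y) / d.y; tdy = sc.cell[1] / std::fabs(d.y);
  }
  if (d.z != 0) {
    double nb = sc.lo[2] + (cz + (stepz > 0)) * sc.cell[2];
    tmaxz = (nb - o.z) / d.z; tdz = sc.cell[2] / std::fabs(d.z);
  }
  while (true) {
    double tcell = std::min(tmaxx, std::min(tmaxy, tmaxz));
    // test triangles in this cell
    long c = ((long)cz * sc.ng[1] + cy) * sc.ng[0] + cx;
    double best = INF; int btri = -1;
    for (int k = sc.cstart[c]; k < sc.cstart[c+1]; ++k) {
      int t = sc.cidx[k];
      if (t == skip_tri) continue;
      double th = sc.intersect(t, o, d);
      if (th > eps && th < best && th <= tcell + eps) { best = th; btri = t; }
    }
    if (btri >= 0) return {EV_TRI, best, btri};
    // advance to next cell
    if (tmaxx <= tmaxy && tmaxx <= tmaxz) {
      cx += stepx; tmaxx += tdx;
      if (cx < 0) return {EV_SIDE_X0, tcell, -1};
      if (cx >= sc.ng[0]) return {EV_SIDE_X1, tcell, -1};
    } else if (tmaxy <= tmaxz) {
      cy += stepy; tmaxy += tdy;
      if (cy < 0) return {EV_SIDE_Y0, tcell, -1};
      if (cy >= sc.ng[1]) return {EV_SIDE_Y1, tcell, -1};
    } else {
      cz += stepz; tmaxz += tdz;
      if (cz < 0) return {EV_GROUND, tcell, -1};
      if (cz >= sc.ng[2]) return {EV_TOP, tcell, -1};
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_trace")]]
List cpp_trace(NumericMatrix tri_xyz,      // nt x 9: p0,p1,p2 coords
               NumericVector Rf, NumericVector Tf,
               NumericVector box,          // x0,x1,y0,y1,z0,z1
               NumericVector sun_dir,      // unit, pointing down (travel dir)
               int n_direct, double p_direct,
               int n_diffuse, double p_diffuse,
               int max_bounces, double seed) {
  const int nt = tri_xyz.nrow();
  if (nt == 0) stop("empty scene");
  Scene sc;
  sc.vx.resize(3*nt); sc.vy.resize(3*nt); sc.vz.resize(3*nt);
  sc.nrm.resize(nt);
  sc.Rf.assign(Rf.begin(), Rf.end());
  sc.Tf.assign(Tf.begin(), Tf.end());
  for (int t = 0; t < nt; ++t) {
    for (int v = 0; v < 3; ++v) {
      sc.vx[3*t+v] = tri_xyz(t, 3*v);
      sc.vy[3*t+v] = tri_xyz(t, 3*v+1);
      sc.vz[3*t+v] = tri_xyz(t, 3*v+2);
    }
    Vec p0{sc.vx[3*t], sc.vy[3*t], sc.vz[3*t]};
    Vec p1{sc.vx[3*t+1], sc.vy[3*t+1], sc.vz[3*t+1]};
    Vec p2{sc.vx[3*t+2], sc.vy[3*t+2], sc.vz[3*t+2]};
    sc.nrm[t] = vnorm(cross(vsub(p1,p0), vsub(p2,p0)));
    if (sc.Rf[t] + sc.Tf[t] > 1.0 + 1e-12) stop("R + T > 1 for a facet");
  }
  for (int d = 0; d < 3; ++d) { sc.lo[d] = box[2*d]; sc.hi[d] = box[2*d+1]; }
  sc.build_grid();

  const double Lx = sc.hi[0] - sc.lo[0], Ly = sc.hi[1] - sc.lo[1];
  const double diag = std::sqrt(Lx*Lx + Ly*Ly + (sc.hi[2]-sc.lo[2])*(sc.hi[2]-sc.lo[2]));
  const double eps = diag * 1e-9;
  const double push = diag * 1e-7;

  std::vector<double> absorbed(nt, 0.0);
  double ground = 0, escaped = 0, lost = 0, emitted = 0;
  const double ztop = sc.hi[2] - push;

  const long n_total = (long)n_direct + n_diffuse;
  for (long ray = 0; ray < n_total; ++ray) {
    RNG rng((uint64_t)seed, (uint64_t)ray + 1);
    bool is_direct = ray < n_direct;
    double power = is_direct ? p_direct : p_diffuse;
    Vec o, d;
    if (is_direct) {
      // stratified-jittered grid over the tile
      long i = ray;
      long gx = (long)std::ceil(std::sqrt((double)n_direct));
      long gy = (gx > 0) ? (n_direct + gx - 1) / gx : 1;
      double fx = ((i % gx) + rng.unif()) / gx;
      double fy = ((i / gx) % gy + rng.unif()) / gy;
      o = {sc.lo[0] + fx * Lx, sc.lo[1] + fy * Ly, ztop};
      d = {sun_dir[0], sun_dir[1], sun_dir[2]};
    } else {
      o = {sc.lo[0] + rng.unif() * Lx, sc.lo[1] + rng.unif() * Ly, ztop};
      d = cosine_dir({0, 0, -1}, rng);
    }
    emitted += power;
    int skip = -1, bounces = 0, wraps = 0;
    bool alive = true;
    while (alive) {
      Event ev = traverse(sc, o, d, skip, eps);
      switch (ev.type) {
      case EV_TRI: {
        int t = ev.tri;
        o = {o.x + ev.t * d.x, o.y + ev.t * d.y, o.z + ev.t * d.z};
        double Rt = sc.Rf[t], Tt = sc.Tf[t];
        absorbed[t] += (1.0 - Rt - Tt) * power;
        if (++bounces > max_bounces) { lost += (Rt + Tt) * power; alive = false; break; }
        double u = rng.unif();
        Vec n_inc = (dot(d, sc.nrm[t]) < 0) ? sc.nrm[t] : vscale(sc.nrm[t], -1.0);
        if (u < Rt) {
          d = cosine_dir(n_inc, rng);
        } else if (u < Rt + Tt) {
          d = cosine_dir(vscale(n_inc, -1.0), rng);
        } else {
          alive = false; break;
        }
        skip = t;
        break;
      }
      case EV_TOP: escaped += power; alive = false; break;
      case EV_GROUND: ground += power; alive = false; break;
      case EV_SIDE_X0: case EV_SIDE_X1: case EV_SIDE_Y0: case EV_SIDE_Y1: {
        o = {o.x + ev.t * d.x, o.y + ev.t * d.y, o.z + ev.t * d.z};
        if (ev.type == EV_SIDE_X0) o.x += Lx;
        else if (ev.type == EV_SIDE_X1) o.x -= Lx;
        else if (ev.type == EV_SIDE_Y0) o.y += Ly;
        else o.y -= Ly;
        o.x = std::min(std::max(o.x, sc.lo[0]), sc.hi[0]);
        o.y = std::min(std::max(o.y, sc.lo[1]), sc.hi[1]);
        skip = -1;
        if (++wraps > 10000) { lost += power; alive = false; }
        break;
      }
      default: lost += power; alive = false; break;
      }
    }
  }
  return List::create(_["absorbed"] = NumericVector(absorbed.begin(), absorbed.end()),
                      _["ground"] = ground, _["escaped"] = escaped,
                      _["lost"] = lost, _["emitted"] = emitted,
                      _["n_rays"] = (double)n_total);
}
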