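// Spatial kernels for the reef community simulator.
//
// All geometry lives here: point-in-footprint tests for 24-axis star
// colonies (massive = polygon over the axis endpoints, branching = radial
// interpolation between adjacent axes), per-axis competitive growth
// modifiers, overgrowth fractions, branch shelter counts, macroalgal
// circle-overlap rules and settlement point location. Everything is
// deterministic; all random draws happen on the R side.
//
// Units: centimetres throughout. Axis k points in direction k * 15 degrees.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NAX = 24;
static const double SECTOR = M_PI / 12.0; // 15 degrees

static double DIRX[NAX], DIRY[NAX];
static bool dirs_ready = false;

static void init_dirs() {
  if (dirs_ready) return;
  for (int k = 0; k < NAX; ++k) {
    DIRX[k] = std::cos(k * SECTOR);
    DIRY[k] = std::sin(k * SECTOR);
  }
  dirs_ready = true;
}

// ---------------------------------------------------------------------------
// containment tests

// branching colony: radius limit interpolated linearly between the two
// axes bracketing the point's bearing
static inline bool in_star(double px, double py, double cx, double cy,
                           const double* ax) {
  double dx = px - cx, dy = py - cy;
  double d2 = dx * dx + dy * dy;
  if (d2 == 0.0) return true;
  double theta = std::atan2(dy, dx);
  if (theta < 0) theta += 2.0 * M_PI;
  double pos = theta / SECTOR;
  int k = (int)std::floor(pos);
  if (k >= NAX) k = NAX - 1;
  double f = pos - k;
  double rlim = ax[k] * (1.0 - f) + ax[(k + 1) % NAX] * f;
  return rlim > 0 && d2 <= rlim * rlim;
}

// massive colony: even-odd crossing test on the 24-gon of axis endpoints
static inline bool in_poly(double px, double py, double cx, double cy,
                           const double* ax) {
  bool inside = false;
  double x1 = cx + ax[NAX - 1] * DIRX[NAX - 1];
  double y1 = cy + ax[NAX - 1] * DIRY[NAX - 1];
  for (int k = 0; k < NAX; ++k) {
    double x2 = cx + ax[k] * DIRX[k];
    double y2 = cy + ax[k] * DIRY[k];
    if ((y2 > py) != (y1 > py)) {
      double xint = x2 + (py - y2) * (x1 - x2) / (y1 - y2);
      if (px < xint) inside = !inside;
    }
    x1 = x2; y1 = y2;
  }
  return inside;
}

static inline bool in_coral(double px, double py, double cx, double cy,
                            const double* ax, int morph) {
  return morph == 0 ? in_poly(px, py, cx, cy, ax)
                    : in_star(px, py, cx, cy, ax);
}

// O(1) short-cut containment: points within the inscribed circle are
// certainly inside, points beyond the bounding circle certainly outside;
// only the annulus between needs the full footprint test. For the massive
// 24-gon the inscribed radius is at least min(axis) * cos(7.5 deg); for the
// branching star the interpolated reach is at least min(axis).
static const double COS_HALF_SECTOR = 0.99144486137381; // cos(7.5 deg)

static inline bool in_coral_fast(double px, double py, double cx, double cy,
                                 const double* ax, int morph,
                                 double rin2, double rmax2) {
  double dx = px - cx, dy = py - cy;
  double d2 = dx * dx + dy * dy;
  if (d2 > rmax2) return false;
  if (d2 <= rin2) return true;
  return morph == 0 ? in_poly(px, py, cx, cy, ax)
                    : in_star(px, py, cx, cy, ax);
}

// ---------------------------------------------------------------------------
// uniform grid for neighbour candidate lookup

struct Grid {
  double x0, y0, cell;
  int nx, ny;
  std::vector< std::vector<int> > bins;

  Grid(const std::vector<double>& x, const std::vector<double>& y,
       const std::vector<double>& r, double cell_size) : cell(cell_size) {
    double xmin = 0, xmax = 1, ymin = 0, ymax = 1;
    size_t n = x.size();
    if (n > 0) {
      xmin = xmax = x[0]; ymin = ymax = y[0];
      for (size_t i = 1; i < n; ++i) {
        if (x[i] < xmin) xmin = x[i];
        if (x[i] > xmax) xmax = x[i];
        if (y[i] < ymin) ymin = y[i];
        if (y[i] > ymax) ymax = y[i];
      }
    }
    double rmax = 0;
    for (size_t i = 0; i < n; ++i) if (r[i] > rmax) rmax = r[i];
    x0 = xmin - rmax - cell; y0 = ymin - rmax - cell;
    nx = (int)std::floor((xmax + rmax + cell - x0) / cell) + 2;
    ny = (int)std::floor((ymax + rmax + cell - y0) / cell) + 2;
    bins.resize((size_t)nx * ny);
    for (size_t i = 0; i < n; ++i) insert((int)i, x[i], y[i], r[i]);
  }

  inline int clampx(int ix) const { return ix < 0 ? 0 : (ix >= nx ? nx - 1 : ix); }
  inline int clampy(int iy) const { return iy < 0 ? 0 : (iy >= ny ? ny - 1 : iy); }

  void insert(int id, double x, double y, double r) {
    int ix1 = clampx((int)std::floor((x - r - x0) / cell));
    int ix2 = clampx((int)std::floor((x + r - x0) / cell));
    int iy1 = clampy((int)std::floor((y - r - y0) / cell));
    int iy2 = clampy((int)std::floor((y + r - y0) / cell));
    for (int iy = iy1; iy <= iy2; ++iy)
      for (int ix = ix1; ix <= ix2; ++ix)
        bins[(size_t)iy * nx + ix].push_back(id);
  }

  // collect unique occupants of the cells overlapped by circle (x,y,r);
  // stamp[i] == tag marks already-seen ids
  void query(double x, double y, double r, std::vector<int>& out,
             std::vector<int>& stamp, int tag) const {
    out.clear();
    int ix1 = clampx((int)std::floor((x - r - x0) / cell));
    int ix2 = clampx((int)std::floor((x + r - x0) / cell));
    int iy1 = clampy((int)std::floor((y - r - y0) / cell));
    int iy2 = clampy((int)std::floor((y + r - y0) / cell));
    for (int iy = iy1; iy <= iy2; ++iy)
      for (int ix = ix1; ix <= ix2; ++ix) {
        const std::vector<int>& b = bins[(size_t)iy * nx + ix];
        for (size_t q = 0; q < b.size(); ++q) {
          int j = b[q];
          if (stamp[j] != tag) { stamp[j] = tag; out.push_back(j); }
        }
      }
  }
};

// ---------------------------------------------------------------------------
// Table-4 competitive growth multiplier (coral focal)
//
// morphology codes: 0 massive coral, 1 branching coral; competitor algae are
// handled separately. Sizes compared by mean diameter; ties count as F < C.
static inline double table4_coral(int fm, int cm, double fd, double cd,
                                  int fsp, int csp,
                                  int sp_f, int sp_c, double sp_ratio,
                                  double sp_mult) {
  if (fm == 0 && cm == 0) {
    if (fd > cd) return 0.9;
    if (fsp == sp_f && csp == sp_c && cd < sp_ratio * fd) return sp_mult;
    return 0.0;
  }
  if (fm == 0 && cm == 1) return (fd > cd) ? 1.0 : 0.3;
  if (fm == 1 && cm == 0) return 0.0;
  return (fd > cd) ? 0.7 : 0.3; // branching vs branching
}

// [[Rcpp::export]]
List interaction_kernel(NumericVector cx, NumericVector cy,
                        NumericMatrix A,        // 24 x n axis lengths (cm)
                        IntegerVector morph,    // 0 massive, 1 branching
                        IntegerVector sp,       // species index (1-based)
                        NumericVector perf,     // interaction strength 0..1
                        NumericVector step,     // base radial growth (cm)
                        NumericVector gx, NumericVector gy,
                        NumericVector gr,       // algal zone radius (cm)
                        int sp_focal, int sp_comp,
                        double sp_ratio, double sp_mult,
                        double shelter_buffer) {
  init_dirs();
  int n = cx.size(), na = gx.size();

  NumericMatrix M(NAX, n);
  NumericVector overfrac(n);
  IntegerVector shelter(n);
  std::fill(M.begin(), M.end(), 1.0);

  if (n == 0)
    return List::create(_["modifiers"] = M, _["overgrowth"] = overfrac,
                        _["shelter"] = shelter);

  std::vector<double> vx(cx.begin(), cx.end()), vy(cy.begin(), cy.end());
  std::vector<double> rmax(n), rbar(n), rmax2(n), rin2(n);
  for (int i = 0; i < n; ++i) {
    double mx = 0, mn = R_PosInf, s = 0;
    const double* ai = &A(0, i);
    for (int k = 0; k < NAX; ++k) {
      s += ai[k];
      if (ai[k] > mx) mx = ai[k];
      if (ai[k] < mn) mn = ai[k];
    }
    rmax[i] = mx; rbar[i] = s / NAX;
    rmax2[i] = mx * mx;
    double rin = (morph[i] == 0) ? mn * COS_HALF_SECTOR : mn;
    rin2[i] = rin * rin;
  }

  Grid cg(vx, vy, rmax, 150.0);
  std::vector<int> cstamp(n, -1), cand;

  bool has_algae = na > 0;
  std::vector<double> avx(gx.begin(), gx.end()), avy(gy.begin(), gy.end());
  std::vector<double> avr(gr.begin(), gr.end());
  std::vector<int> astamp(na, -1), acand;
  Grid* ag = has_algae ? new Grid(avx, avy, avr, 200.0) : (Grid*)0;

  for (int i = 0; i < n; ++i) {
    const double* ai = &A(0, i);
    double xi = vx[i], yi = vy[i];
    double reach = rmax[i] + step[i] + shelter_buffer;
    double fd = 2.0 * rbar[i];
    int fm = morph[i], fsp = sp[i];

    int nover = 0;
    // endpoint coordinates (current and grown)
    double ex[NAX], ey[NAX], gx_[NAX], gy_[NAX];
    bool covered[NAX];
    for (int k = 0; k < NAX; ++k) {
      ex[k] = xi + ai[k] * DIRX[k];
      ey[k] = yi + ai[k] * DIRY[k];
      gx_[k] = xi + (ai[k] + step[i]) * DIRX[k];
      gy_[k] = yi + (ai[k] + step[i]) * DIRY[k];
      covered[k] = false;
    }

    cg.query(xi, yi, reach, cand, cstamp, i);
    for (size_t q = 0; q < cand.size(); ++q) {
      int j = cand[q];
      if (j == i) continue;
      double dx = vx[j] - xi, dy = vy[j] - yi;
      double dist = std::sqrt(dx * dx + dy * dy);
      // shelter: neighbours in contact distance of at least focal size
      if (fm == 1 && dist <= rbar[i] + rbar[j] + shelter_buffer &&
          rbar[j] >= rbar[i])
        shelter[i]++;
      if (dist > rmax[i] + step[i] + rmax[j]) continue;
      const double* aj = &A(0, j);
      double m0 = table4_coral(fm, morph[j], fd, 2.0 * rbar[j], fsp, sp[j],
                               sp_focal, sp_comp, sp_ratio, sp_mult);
      // a recovering competitor exerts a weaker effect
      double meff = 1.0 - (1.0 - m0) * perf[j];
      bool need_mod = meff < 1.0;
      for (int k = 0; k < NAX; ++k) {
        if (need_mod && meff < M(k, i) &&
            in_coral_fast(gx_[k], gy_[k], vx[j], vy[j], aj, morph[j],
                          rin2[j], rmax2[j]))
          M(k, i) = meff;
        if (!covered[k] &&
            in_coral_fast(ex[k], ey[k], vx[j], vy[j], aj, morph[j],
                          rin2[j], rmax2[j]))
          covered[k] = true;
      }
    }

    if (has_algae) {
      ag->query(xi, yi, reach, acand, astamp, i);
      for (size_t q = 0; q < acand.size(); ++q) {
        int j = acand[q];
        double r2 = avr[j] * avr[j];
        double m0 = (fd > 2.0 * avr[j]) ? 1.0 : 0.7;
        for (int k = 0; k < NAX; ++k) {
          double pdx = gx_[k] - avx[j], pdy = gy_[k] - avy[j];
          if (pdx * pdx + pdy * pdy <= r2) {
            if (m0 < M(k, i)) M(k, i) = m0;
          }
          if (!covered[k]) {
            pdx = ex[k] - avx[j]; pdy = ey[k] - avy[j];
            if (pdx * pdx + pdy * pdy <= r2) covered[k] = true;
          }
        }
      }
    }

    for (int k = 0; k < NAX; ++k) if (covered[k]) nover++;
    overfrac[i] = (double)nover / NAX;
  }

  if (ag) delete ag;
  return List::create(_["modifiers"] = M, _["overgrowth"] = overfrac,
                      _["shelter"] = shelter);
}

// ---------------------------------------------------------------------------
// constrained radial growth: per-axis extension with species-maximum clamp
// and the arena-border rule (an axis whose endpoint would cross the border
// cannot exceed the colony's pre-growth mean radius); axes never shrink

// [[Rcpp::export]]
NumericMatrix grow_kernel(NumericMatrix A, NumericMatrix M,
                          NumericVector astep, NumericVector maxr,
                          NumericVector cx, NumericVector cy,
                          double W, double H) {
  init_dirs();
  int n = A.ncol();
  NumericMatrix out(NAX, n);
  for (int i = 0; i < n; ++i) {
    const double* ai = &A(0, i);
    const double* mi = &M(0, i);
    double rbar = 0;
    for (int k = 0; k < NAX; ++k) rbar += ai[k];
    rbar /= NAX;
    for (int k = 0; k < NAX; ++k) {
      double na = ai[k] + astep[i] * mi[k];
      if (na > maxr[i]) na = maxr[i];
      double ex = cx[i] + na * DIRX[k], ey = cy[i] + na * DIRY[k];
      if (ex < 0 || ex > W || ey < 0 || ey > H)
        na = std::min(na, rbar);
      if (na < ai[k]) na = ai[k];
      out(k, i) = na;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// settlement / placement: classify points against the living community

// [[Rcpp::export]]
List locate_points_kernel(NumericVector px, NumericVector py,
                          NumericVector cx, NumericVector cy,
                          NumericMatrix A, IntegerVector morph,
                          IntegerVector bleached,  // 0 healthy, 1 recovering
                          IntegerVector msb,       // months since bleaching
                          NumericVector gx, NumericVector gy,
                          NumericVector gr) {
  init_dirs();
  int np = px.size(), n = cx.size(), na = gx.size();
  LogicalVector in_healthy(np), in_alga(np);
  IntegerVector msb_max(np, -1); // max months-since-bleach among coverers

  std::vector<double> vx(cx.begin(), cx.end()), vy(cy.begin(), cy.end());
  std::vector<double> rmax(n), rmax2(n), rin2(n);
  for (int i = 0; i < n; ++i) {
    double mx = 0, mn = R_PosInf;
    const double* ai = &A(0, i);
    for (int k = 0; k < NAX; ++k) {
      if (ai[k] > mx) mx = ai[k];
      if (ai[k] < mn) mn = ai[k];
    }
    rmax[i] = mx; rmax2[i] = mx * mx;
    double rin = (morph[i] == 0) ? mn * COS_HALF_SECTOR : mn;
    rin2[i] = rin * rin;
  }
  Grid* cg = n > 0 ? new Grid(vx, vy, rmax, 150.0) : (Grid*)0;
  std::vector<int> cstamp(n, -1), cand;

  std::vector<double> avx(gx.begin(), gx.end()), avy(gy.begin(), gy.end());
  std::vector<double> avr(gr.begin(), gr.end());
  Grid* ag = na > 0 ? new Grid(avx, avy, avr, 200.0) : (Grid*)0;
  std::vector<int> astamp(na, -1), acand;

  for (int p = 0; p < np; ++p) {
    double x = px[p], y = py[p];
    if (cg) {
      cg->query(x, y, 0.0, cand, cstamp, p);
      for (size_t q = 0; q < cand.size(); ++q) {
        int j = cand[q];
        if (in_coral_fast(x, y, vx[j], vy[j], &A(0, j), morph[j],
                          rin2[j], rmax2[j])) {
          if (bleached[j]) {
            if (msb[j] > msb_max[p]) msb_max[p] = msb[j];
          } else in_healthy[p] = true;
        }
      }
    }
    if (ag) {
      ag->query(x, y, 0.0, acand, astamp, p);
      for (size_t q = 0; q < acand.size(); ++q) {
        int j = acand[q];
        double dx = x - avx[j], dy = y - avy[j];
        if (dx * dx + dy * dy <= avr[j] * avr[j]) { in_alga[p] = true; break; }
      }
    }
  }
  if (cg) delete cg;
  if (ag) delete ag;
  return List::create(_["in_healthy_coral"] = in_healthy,
                      _["in_alga"] = in_alga,
                      _["msb_max"] = msb_max);
}

// ---------------------------------------------------------------------------
// macroalgal conspecific competition: the smaller of two overlapping zones
// dies if at least half its circle area lies inside the larger one

static inline double lens_area(double d, double R, double r) {
  if (d >= R + r) return 0.0;
  if (d <= R - r) return M_PI * r * r; // small circle fully inside
  double a1 = (d * d + r * r - R * R) / (2.0 * d * r);
  double a2 = (d * d + R * R - r * r) / (2.0 * d * R);
  a1 = std::max(-1.0, std::min(1.0, a1));
  a2 = std::max(-1.0, std::min(1.0, a2));
  double t = (-d + r + R) * (d + r - R) * (d - r + R) * (d + r + R);
  if (t < 0) t = 0;
  return r * r * std::acos(a1) + R * R * std::acos(a2) - 0.5 * std::sqrt(t);
}

// [[Rcpp::export]]
LogicalVector alga_alga_kernel(NumericVector gx, NumericVector gy,
                               NumericVector gr) {
  int n = gx.size();
  LogicalVector removed(n);
  if (n < 2) return removed;
  std::vector<double> vx(gx.begin(), gx.end()), vy(gy.begin(), gy.end());
  std::vector<double> vr(gr.begin(), gr.end());
  Grid g(vx, vy, vr, 100.0);
  std::vector<int> stamp(n, -1), cand;
  for (int i = 0; i < n; ++i) {
    g.query(vx[i], vy[i], vr[i], cand, stamp, i);
    for (size_t q = 0; q < cand.size(); ++q) {
      int j = cand[q];
      if (j <= i) continue; // each pair once
      double dx = vx[i] - vx[j], dy = vy[i] - vy[j];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d >= vr[i] + vr[j]) continue;
      // smaller one (ties: the later index) is the candidate victim
      int small = (vr[i] < vr[j]) ? i : (vr[j] < vr[i] ? j : std::max(i, j));
      int big = (small == i) ? j : i;
      double lens = lens_area(d, vr[big], vr[small]);
      if (lens >= 0.5 * M_PI * vr[small] * vr[small]) removed[small] = true;
    }
  }
  return removed;
}

// ---------------------------------------------------------------------------
// alga vs coral displacement: the smaller individual is removed once it is
// actually overgrown, i.e. its centre lies inside the larger one's footprint
// (zone circle for the alga, mean-radius circle for the coral); mere touching
// of footprints has no lethal effect

// [[Rcpp::export]]
List alga_coral_kernel(NumericVector gx, NumericVector gy, NumericVector gr,
                       NumericVector cx, NumericVector cy,
                       NumericVector crbar) {
  int na = gx.size(), n = cx.size();
  LogicalVector alga_rm(na), coral_rm(n);
  if (na == 0 || n == 0)
    return List::create(_["alga_removed"] = alga_rm,
                        _["coral_removed"] = coral_rm);
  std::vector<double> vx(cx.begin(), cx.end()), vy(cy.begin(), cy.end());
  std::vector<double> vr(crbar.begin(), crbar.end());
  Grid g(vx, vy, vr, 200.0);
  std::vector<int> stamp(n, -1), cand;
  for (int a = 0; a < na; ++a) {
    g.query(gx[a], gy[a], gr[a], cand, stamp, a);
    for (size_t q = 0; q < cand.size(); ++q) {
      int j = cand[q];
      double dx = gx[a] - vx[j], dy = gy[a] - vy[j];
      double d2 = dx * dx + dy * dy;
      if (gr[a] > vr[j]) {
        if (d2 < gr[a] * gr[a]) coral_rm[j] = true;   // coral centre engulfed
      } else {
        if (d2 < vr[j] * vr[j]) alga_rm[a] = true;    // alga centre engulfed
      }
    }
  }
  return List::create(_["alga_removed"] = alga_rm,
                      _["coral_removed"] = coral_rm);
}

// ---------------------------------------------------------------------------
// single-shape containment used by the exported geometry helpers

// [[Rcpp::export]]
LogicalVector contains_point_kernel(double cx, double cy, NumericVector axes,
                                    int morph, NumericVector px,
                                    NumericVector py) {
  init_dirs();
  int np = px.size();
  LogicalVector out(np);
  std::vector<double> ax(axes.begin(), axes.end());
  for (int p = 0; p < np; ++p)
    out[p] = in_coral(px[p], py[p], cx, cy, &ax[0], morph);
  return out;
}
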