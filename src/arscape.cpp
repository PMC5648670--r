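#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Inside-ness is strict: distance < r is inside, a point exactly on the
// boundary is outside. All crossings are located by linear interpolation of
// position (and hence time) between consecutive fixes.

// Earliest s in (0, 1] at which the segment a + s*(b - a) crosses the circle
// of radius r about c, given the quadratic |a + s d - c|^2 = r^2. Which root
// is wanted depends on the endpoint states; helpers below pick it directly.

// Exit crossing for a segment with a strictly inside and b outside (>= r).
static double exit_frac(double ax, double ay, double bx, double by,
                        double cx, double cy, double r) {
  double ux = ax - cx, uy = ay - cy;
  double dx = bx - ax, dy = by - ay;
  double A = dx * dx + dy * dy;
  double B = ux * dx + uy * dy;
  double C = ux * ux + uy * uy - r * r;  // < 0
  if (A <= 0.0) return 1.0;              // no spatial motion; cannot happen with b outside
  double disc = B * B - A * C;
  if (disc < 0.0) disc = 0.0;
  double s = (-B + std::sqrt(disc)) / A; // larger root: the outward crossing
  if (s < 0.0) s = 0.0;
  if (s > 1.0) s = 1.0;
  return s;
}

// Entry crossing for a segment with a outside and b strictly inside.
static double entry_frac(double ax, double ay, double bx, double by,
                         double cx, double cy, double r) {
  double ux = ax - cx, uy = ay - cy;
  double dx = bx - ax, dy = by - ay;
  double A = dx * dx + dy * dy;
  double B = ux * dx + uy * dy;
  double C = ux * ux + uy * uy - r * r;  // > 0
  double disc = B * B - A * C;
  if (disc < 0.0) disc = 0.0;
  double s = (-B - std::sqrt(disc)) / A; // smaller root: the inward crossing
  if (s < 0.0) s = 0.0;
  if (s > 1.0) s = 1.0;
  return s;
}

// Chord: both endpoints outside but the segment dips inside. Returns true and
// fills s1 < s2 when the open interval (s1, s2) lies strictly within (0, 1).
static bool chord_frac(double ax, double ay, double bx, double by,
                       double cx, double cy, double r,
                       double& s1, double& s2) {
  double ux = ax - cx, uy = ay - cy;
  double dx = bx - ax, dy = by - ay;
  double A = dx * dx + dy * dy;
  if (A <= 0.0) return false;
  double B = ux * dx + uy * dy;
  double C = ux * ux + uy * uy - r * r;  // > 0
  double disc = B * B - A * C;
  if (disc <= 0.0) return false;         // misses (or touches tangentially)
  double sq = std::sqrt(disc);
  s1 = (-B - sq) / A;
  s2 = (-B + sq) / A;
  return (s1 > 0.0 && s2 < 1.0 && s2 > s1);
}

// First-passage scan from fix i in direction dir (+1 forward, -1 backward).
// interpolate = false counts time to the first fix at distance >= r instead.
static void fpt_scan(const double* t, const double* x, const double* y, int n,
                     int i, double r, int dir, bool interpolate,
                     double& dur, bool& cens) {
  double cx = x[i], cy = y[i], r2 = r * r;
  int j = i;
  for (;;) {
    int k = j + dir;
    if (k < 0 || k >= n) {               // ran off the path while still inside
      cens = true;
      dur = std::fabs(t[j] - t[i]);
      return;
    }
    double dxb = x[k] - cx, dyb = y[k] - cy;
    if (dxb * dxb + dyb * dyb >= r2) {
      cens = false;
      if (!interpolate) {
        dur = std::fabs(t[k] - t[i]);
      } else {
        double s = exit_frac(x[j], y[j], x[k], y[k], cx, cy, r);
        double tc = t[j] + s * (t[k] - t[j]);
        dur = std::fabs(tc - t[i]);
      }
      return;
    }
    j = k;
  }
}

// [[Rcpp::export]]
List cpp_fpt(NumericVector t, NumericVector x, NumericVector y,
             int i, double r, int dir, bool interpolate) {
  double dur;
  bool cens;
  fpt_scan(t.begin(), x.begin(), y.begin(), t.size(), i, r, dir, interpolate,
           dur, cens);
  return List::create(_["duration"] = dur, _["censored"] = cens);
}

// Residence time (backward FPT + forward FPT) for every fix over a radius
// grid. Returns an n x m matrix of durations and a matching censoring matrix.
// [[Rcpp::export]]
List cpp_rt_matrix(NumericVector t, NumericVector x, NumericVector y,
                   NumericVector radii, bool interpolate) {
  int n = t.size(), m = radii.size();
  NumericMatrix rt(n, m);
  LogicalMatrix cens(n, m);
  const double* tp = t.begin();
  const double* xp = x.begin();
  const double* yp = y.begin();
  for (int j = 0; j < m; ++j) {
    double r = radii[j];
    for (int i = 0; i < n; ++i) {
      double db, df;
      bool cb, cf;
      fpt_scan(tp, xp, yp, n, i, r, -1, interpolate, db, cb);
      fpt_scan(tp, xp, yp, n, i, r, +1, interpolate, df, cf);
      rt(i, j) = db + df;
      cens(i, j) = cb || cf;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["rt"] = rt, _["censored"] = cens);
}

// Raw (unmerged) inside intervals of the whole path for one circle.
// Columns: t_in, t_out, censored_start, censored_end.
// [[Rcpp::export]]
NumericMatrix cpp_visit_segments(NumericVector t, NumericVector x,
                                 NumericVector y, double cx, double cy,
                                 double r) {
  int n = t.size();
  double r2 = r * r;
  std::vector<double> tin, tout;
  std::vector<int> cstart, cend;
  double dx0 = x[0] - cx, dy0 = y[0] - cy;
  bool inside = (dx0 * dx0 + dy0 * dy0 < r2);
  double cur_in = t[0];
  bool cur_cens = inside;  // path begins inside the circle
  for (int j = 0; j + 1 < n; ++j) {
    int k = j + 1;
    double dxb = x[k] - cx, dyb = y[k] - cy;
    bool in_b = (dxb * dxb + dyb * dyb < r2);
    if (inside && in_b) {
      // segment fully inside (circle is convex)
    } else if (inside && !in_b) {
      double s = exit_frac(x[j], y[j], x[k], y[k], cx, cy, r);
      double tc = t[j] + s * (t[k] - t[j]);
      tin.push_back(cur_in);
      tout.push_back(tc);
      cstart.push_back(cur_cens ? 1 : 0);
      cend.push_back(0);
      inside = false;
    } else if (!inside && in_b) {
      double s = entry_frac(x[j], y[j], x[k], y[k], cx, cy, r);
      cur_in = t[j] + s * (t[k] - t[j]);
      cur_cens = false;
      inside = true;
    } else {
      double s1, s2;
      if (chord_frac(x[j], y[j], x[k], y[k], cx, cy, r, s1, s2)) {
        tin.push_back(t[j] + s1 * (t[k] - t[j]));
        tout.push_back(t[j] + s2 * (t[k] - t[j]));
        cstart.push_back(0);
        cend.push_back(0);
      }
    }
  }
  if (inside) {  // path ends inside the circle
    tin.push_back(cur_in);
    tout.push_back(t[n - 1]);
    cstart.push_back(cur_cens ? 1 : 0);
    cend.push_back(1);
  }
  int m = tin.size();
  NumericMatrix out(m, 4);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = tin[i];
    out(i, 1) = tout[i];
    out(i, 2) = cstart[i];
    out(i, 3) = cend[i];
  }
  colnames(out) = CharacterVector::create("t_in", "t_out",
                                          "censored_start", "censored_end");
  return out;
}

// Full revisit statistics for every focal fix at one radius. Consecutive
// inside intervals separated by a time-outside gap strictly shorter than
// max_time_outside are merged; a merged visit's duration is the sum of the
// inside durations only. Also reports the duration of the (merged) visit
// containing the focal time, and whether the whole-path trace touches either
// path end from inside.
// [[Rcpp::export]]
NumericMatrix cpp_revisit_stats(NumericVector t, NumericVector x,
                                NumericVector y, IntegerVector idx, double r,
                                double max_time_outside) {
  int n = t.size(), nf = idx.size();
  double r2 = r * r;
  NumericMatrix out(nf, 6);
  colnames(out) = CharacterVector::create(
      "n_visits", "mean_visit_duration", "total_time", "focal_duration",
      "focal_censored", "focal_n_visits_before");
  const double* tp = t.begin();
  const double* xp = x.begin();
  const double* yp = y.begin();
  std::vector<double> vin, vout, vdur;  // merged visits
  std::vector<int> vc0, vc1;            // merged-visit censor flags
  for (int f = 0; f < nf; ++f) {
    int i0 = idx[f];
    double cx = xp[i0], cy = yp[i0], tf = tp[i0];
    vin.clear(); vout.clear(); vdur.clear(); vc0.clear(); vc1.clear();
    // trace raw inside intervals and merge on the fly
    double dx0 = xp[0] - cx, dy0 = yp[0] - cy;
    bool inside = (dx0 * dx0 + dy0 * dy0 < r2);
    double cur_in = tp[0];
    bool cur_c0 = inside;  // current raw interval starts at path start
    bool have_open = false;
    double open_in = 0, open_out = 0, open_dur = 0;
    bool open_c0 = false, open_c1 = false;
    // lambda-free merge helper expanded inline below
    for (int j = 0; j + 1 < n; ++j) {
      int k = j + 1;
      double dxb = xp[k] - cx, dyb = yp[k] - cy;
      bool in_b = (dxb * dxb + dyb * dyb < r2);
      bool have_raw = false;
      double a_in = 0, a_out = 0;
      bool a_c0 = false;
      if (inside && !in_b) {
        double s = exit_frac(xp[j], yp[j], xp[k], yp[k], cx, cy, r);
        a_in = cur_in;
        a_out = tp[j] + s * (tp[k] - tp[j]);
        a_c0 = cur_c0;
        inside = false;
        have_raw = true;
      } else if (!inside && in_b) {
        double s = entry_frac(xp[j], yp[j], xp[k], yp[k], cx, cy, r);
        cur_in = tp[j] + s * (tp[k] - tp[j]);
        cur_c0 = false;
        inside = true;
      } else if (!inside && !in_b) {
        double s1, s2;
        if (chord_frac(xp[j], yp[j], xp[k], yp[k], cx, cy, r, s1, s2)) {
          a_in = tp[j] + s1 * (tp[k] - tp[j]);
          a_out = tp[j] + s2 * (tp[k] - tp[j]);
          have_raw = true;
        }
      }
      if (have_raw) {
        if (have_open && (a_in - open_out) < max_time_outside) {
          open_out = a_out;
          open_dur += (a_out - a_in);
        } else {
          if (have_open) {
            vin.push_back(open_in); vout.push_back(open_out);
            vdur.push_back(open_dur);
            vc0.push_back(open_c0 ? 1 : 0); vc1.push_back(open_c1 ? 1 : 0);
          }
          open_in = a_in; open_out = a_out; open_dur = a_out - a_in;
          open_c0 = a_c0; open_c1 = false;
          have_open = true;
        }
      }
    }
    if (inside) {  // path ends inside: close the trailing raw interval
      double a_in = cur_in, a_out = tp[n - 1];
      if (have_open && (a_in - open_out) < max_time_outside) {
        open_out = a_out;
        open_dur += (a_out - a_in);
        open_c1 = true;
      } else {
        if (have_open) {
          vin.push_back(open_in); vout.push_back(open_out);
          vdur.push_back(open_dur);
          vc0.push_back(open_c0 ? 1 : 0); vc1.push_back(open_c1 ? 1 : 0);
        }
        open_in = a_in; open_out = a_out; open_dur = a_out - a_in;
        open_c0 = cur_c0; open_c1 = true;
        have_open = true;
      }
    }
    if (have_open) {
      vin.push_back(open_in); vout.push_back(open_out);
      vdur.push_back(open_dur);
      vc0.push_back(open_c0 ? 1 : 0); vc1.push_back(open_c1 ? 1 : 0);
    }
    int nv = vin.size();
    double total = 0;
    for (int v = 0; v < nv; ++v) total += vdur[v];
    // locate the focal visit (the merged visit whose span contains tf)
    double focal_dur = NA_REAL;
    bool focal_cens = false;
    int before = 0;
    for (int v = 0; v < nv; ++v) {
      if (vin[v] <= tf && tf <= vout[v]) {
        focal_dur = vdur[v];
        focal_cens = (vc0[v] == 1) || (vc1[v] == 1);
        break;
      }
      before++;
    }
    out(f, 0) = nv;
    out(f, 1) = nv > 0 ? total / nv : NA_REAL;
    out(f, 2) = total;
    out(f, 3) = focal_dur;
    out(f, 4) = focal_cens ? 1.0 : 0.0;
    out(f, 5) = before;
    if (f % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// All-pairs proximity edges (distance strictly < r), 1-based indices.
// [[Rcpp::export]]
IntegerMatrix cpp_proximity_edges(NumericVector x, NumericVector y, double r) {
  int n = x.size();
  double r2 = r * r;
  std::vector<int> from, to;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy < r2) {
        from.push_back(i + 1);
        to.push_back(j + 1);
      }
    }
    if (n > 2000 && i % 512 == 0) Rcpp::checkUserInterrupt();
  }
  int m = from.size();
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = from[e];
    out(e, 1) = to[e];
  }
  return out;
}

static inline double wrap_angle(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a <= -M_PI) a += 2.0 * M_PI;
  return a;
}

// Biased correlated random walk forager. Heading at each step is drawn from
// N(previous heading, v) with v = v_b * (1 -/+ p * cos(heading - omega))
// (minus for attraction to the target bearing omega, plus for repulsion);
// step length is one cell; walls reflect. Modes: 0 explore, 1 ars,
// 2 foray_out, 3 foray_back. Uses R's RNG, so set.seed() governs everything.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix items, IntegerVector item_patch,
                  double grid_size, int n_steps, int strategy,
                  double v_b, double v_b_ars, double p_ars, double p_foray,
                  double perceptual_range, double gut_patch, double gut_clump,
                  double regeneration_delay, double foray_leg0,
                  double foray_growth, double rest_prob, double rest_mean) {
  int n_items = items.nrow();
  std::vector<int> avail(n_items, 1);
  std::vector<double> regrow_at(n_items, -1.0);
  double pr2 = perceptual_range * perceptual_range;

  NumericVector X(n_steps), Y(n_steps);
  IntegerVector M(n_steps);
  LogicalVector Rest(n_steps);
  std::vector<int> ev_t, ev_item;

  double px = R::runif(0.0, grid_size);
  double py = R::runif(0.0, grid_size);
  double theta = R::runif(-M_PI, M_PI);
  int mode = 0;  // explore
  double timer = 0;  // steps since last food encounter
  double tx = 0, ty = 0;          // ARS target (last consumed item)
  double ax = 0, ay = 0;          // foray anchor (departed patch centroid)
  double leg = foray_leg0;
  double ep_sx = 0, ep_sy = 0;    // episode consumption centroid accumulator
  int ep_n = 0;
  int rest_left = 0;              // remaining steps of the current rest bout

  for (int s = 1; s <= n_steps; ++s) {
    // regrowth
    for (int it = 0; it < n_items; ++it) {
      if (!avail[it] && regrow_at[it] >= 0 && regrow_at[it] <= s) {
        avail[it] = 1;
        regrow_at[it] = -1.0;
      }
    }
    // rest bouts punctuate exploration: the forager halts in place
    if (mode == 0 && rest_prob > 0.0) {
      if (rest_left == 0 && R::unif_rand() < rest_prob)
        rest_left = 1 + (int) R::rgeom(1.0 / rest_mean);
      if (rest_left > 0) {
        rest_left--;
        X[s - 1] = px;
        Y[s - 1] = py;
        M[s - 1] = mode;
        Rest[s - 1] = true;
        continue;
      }
    }
    // turning variance for this step
    double v;
    if (mode == 0) {
      v = v_b;
    } else if (mode == 1) {
      double omega = std::atan2(ty - py, tx - px);
      v = v_b_ars * (1.0 - p_ars * std::cos(theta - omega));  // attraction
    } else {
      double omega = std::atan2(ay - py, ax - px);
      double sign = (mode == 2) ? +1.0 : -1.0;  // repulsion out, attraction back
      v = v_b * (1.0 + sign * p_foray * std::cos(theta - omega));
    }
    if (v < 0.0) v = 0.0;
    theta = wrap_angle(v > 0.0 ? R::rnorm(theta, std::sqrt(v)) : theta);
    px += std::cos(theta);
    py += std::sin(theta);
    // reflecting walls
    if (px < 0.0) { px = -px; theta = M_PI - theta; }
    else if (px > grid_size) { px = 2.0 * grid_size - px; theta = M_PI - theta; }
    if (py < 0.0) { py = -py; theta = -theta; }
    else if (py > grid_size) { py = 2.0 * grid_size - py; theta = -theta; }
    theta = wrap_angle(theta);
    // consumption
    bool consumed = false;
    for (int it = 0; it < n_items; ++it) {
      if (!avail[it]) continue;
      double dx = items(it, 0) - px, dy = items(it, 1) - py;
      if (dx * dx + dy * dy <= pr2) {
        avail[it] = 0;
        regrow_at[it] = s + regeneration_delay;
        ev_t.push_back(s);
        ev_item.push_back(it + 1);
        tx = items(it, 0);
        ty = items(it, 1);
        consumed = true;
      }
    }
    // mode transitions
    if (strategy != 0) {
      if (consumed) {
        if (mode != 1) { ep_sx = 0; ep_sy = 0; ep_n = 0; }
        mode = 1;
        timer = 0;
        ep_sx += tx;
        ep_sy += ty;
        ep_n += 1;
        // search is anchored on the running centroid of this bout's finds
        // (the forager's patch-centre estimate), so successive loops sweep
        // the whole patch instead of pinning on the most recent item
        tx = ep_sx / ep_n;
        ty = ep_sy / ep_n;
      } else {
        timer += 1;
        if (mode == 1 && timer > gut_patch) {
          if (strategy == 1) {
            mode = 0;
          } else {
            mode = 2;  // foray_out
            if (ep_n > 0) { ax = ep_sx / ep_n; ay = ep_sy / ep_n; }
            else { ax = px; ay = py; }
            leg = foray_leg0;
          }
        } else if (mode == 2 || mode == 3) {
          if (timer > gut_clump) {
            mode = 0;
          } else {
            double dx = px - ax, dy = py - ay;
            double d2 = dx * dx + dy * dy;
            if (mode == 2 && d2 >= leg * leg) {
              mode = 3;
            } else if (mode == 3 && d2 <= pr2) {
              leg *= foray_growth;
              mode = 2;
            }
          }
        }
      }
    }
    X[s - 1] = px;
    Y[s - 1] = py;
    M[s - 1] = mode;
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  int ne = ev_t.size();
  IntegerVector et(ne), ei(ne);
  for (int e = 0; e < ne; ++e) {
    et[e] = ev_t[e];
    ei[e] = ev_item[e];
  }
  LogicalVector av(n_items);
  NumericVector rg(n_items);
  for (int it = 0; it < n_items; ++it) {
    av[it] = avail[it] == 1;
    rg[it] = avail[it] ? NA_REAL : regrow_at[it];
  }
  return List::create(_["x"] = X, _["y"] = Y, _["mode"] = M,
                      _["resting"] = Rest,
                      _["event_t"] = et, _["event_item"] = ei,
                      _["available"] = av, _["regrow_at"] = rg);
}
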