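// Fused C++ core: environment physics, dueling Q-network arithmetic,
// prioritized replay, the independent-learner training loop, and bulk
// episode rollout. The R sources hold reference implementations of the
// same operations; equivalence between the two routes is property-tested.
//
// All physics is double precision; network weights and activations are
// float (the training loop is the package's hot path). Every random draw
// goes through R's RNG so set.seed() controls the whole pipeline.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <algorithm>

using namespace Rcpp;

static const int NH1 = 64;   // trunk layer 1
static const int NH2 = 64;   // trunk layer 2
static const int NHS = 32;   // per-stream hidden
static const int NACT = 13;  // 12 directions + do-nothing

// ---------------------------------------------------------------- network

// Flat parameter block. Row-major weight layout: W[out][in].
struct NetF {
  int in = 0;
  int oW1, ob1, oW2, ob2, oWa1, oba1, oWa2, oba2, oWv1, obv1, oWv2, obv2;
  int total = 0;
  std::vector<float> p;

  void layout(int in_) {
    in = in_;
    int o = 0;
    oW1 = o;  o += NH1 * in;
    ob1 = o;  o += NH1;
    oW2 = o;  o += NH2 * NH1;
    ob2 = o;  o += NH2;
    oWa1 = o; o += NHS * NH2;
    oba1 = o; o += NHS;
    oWa2 = o; o += NACT * NHS;
    oba2 = o; o += NACT;
    oWv1 = o; o += NHS * NH2;
    obv1 = o; o += NHS;
    oWv2 = o; o += NHS;
    obv2 = o; o += 1;
    total = o;
    p.assign(total, 0.0f);
  }
};

static void copy_mat(std::vector<float>& dst, int off, const NumericMatrix& m) {
  // R column-major -> row-major
  for (int r = 0; r < m.nrow(); ++r)
    for (int c = 0; c < m.ncol(); ++c)
      dst[off + r * m.ncol() + c] = (float)m(r, c);
}

static void copy_vec(std::vector<float>& dst, int off, const NumericVector& v) {
  for (int i = 0; i < v.size(); ++i) dst[off + i] = (float)v[i];
}

static NetF net_from_list(const List& w) {
  NumericMatrix W1 = w["W1"];
  NetF n;
  n.layout(W1.ncol());
  copy_mat(n.p, n.oW1, W1);
  copy_vec(n.p, n.ob1, w["b1"]);
  copy_mat(n.p, n.oW2, as<NumericMatrix>(w["W2"]));
  copy_vec(n.p, n.ob2, w["b2"]);
  copy_mat(n.p, n.oWa1, as<NumericMatrix>(w["Wa1"]));
  copy_vec(n.p, n.oba1, w["ba1"]);
  copy_mat(n.p, n.oWa2, as<NumericMatrix>(w["Wa2"]));
  copy_vec(n.p, n.oba2, w["ba2"]);
  copy_mat(n.p, n.oWv1, as<NumericMatrix>(w["Wv1"]));
  copy_vec(n.p, n.obv1, w["bv1"]);
  copy_mat(n.p, n.oWv2, as<NumericMatrix>(w["Wv2"]));
  copy_vec(n.p, n.obv2, w["bv2"]);
  return n;
}

static NumericMatrix mat_to_R(const std::vector<float>& p, int off, int nr, int nc) {
  NumericMatrix m(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      m(r, c) = p[off + r * nc + c];
  return m;
}

static List net_to_list(const NetF& n) {
  NumericVector b1(NH1), b2(NH2), ba1(NHS), ba2(NACT), bv1(NHS), bv2(1);
  for (int i = 0; i < NH1; ++i) b1[i] = n.p[n.ob1 + i];
  for (int i = 0; i < NH2; ++i) b2[i] = n.p[n.ob2 + i];
  for (int i = 0; i < NHS; ++i) ba1[i] = n.p[n.oba1 + i];
  for (int i = 0; i < NACT; ++i) ba2[i] = n.p[n.oba2 + i];
  for (int i = 0; i < NHS; ++i) bv1[i] = n.p[n.obv1 + i];
  bv2[0] = n.p[n.obv2];
  List out = List::create(
    _["W1"] = mat_to_R(n.p, n.oW1, NH1, n.in), _["b1"] = b1,
    _["W2"] = mat_to_R(n.p, n.oW2, NH2, NH1), _["b2"] = b2,
    _["Wa1"] = mat_to_R(n.p, n.oWa1, NHS, NH2), _["ba1"] = ba1,
    _["Wa2"] = mat_to_R(n.p, n.oWa2, NACT, NHS), _["ba2"] = ba2,
    _["Wv1"] = mat_to_R(n.p, n.oWv1, NHS, NH2), _["bv1"] = bv1,
    _["Wv2"] = mat_to_R(n.p, n.oWv2, 1, NHS), _["bv2"] = bv2);
  out.attr("class") = "policy_params";
  out.attr("n_inputs") = n.in;
  return out;
}

struct Fwd {
  float h1[NH1], h2[NH2], ha[NHS], hv[NHS], A[NACT], Q[NACT];
  float V, meanA;
};

static inline void dense(const float* W, const float* b, const float* x,
                         float* y, int no, int ni, bool relu) {
  for (int o = 0; o < no; ++o) {
    float a = b[o];
    const float* w = W + (size_t)o * ni;
    for (int i = 0; i < ni; ++i) a += w[i] * x[i];
    y[o] = (relu && a < 0.0f) ? 0.0f : a;
  }
}

static void net_forward(const NetF& n, const float* s, Fwd& f) {
  const float* p = n.p.data();
  dense(p + n.oW1, p + n.ob1, s, f.h1, NH1, n.in, true);
  dense(p + n.oW2, p + n.ob2, f.h1, f.h2, NH2, NH1, true);
  dense(p + n.oWa1, p + n.oba1, f.h2, f.ha, NHS, NH2, true);
  dense(p + n.oWa2, p + n.oba2, f.ha, f.A, NACT, NHS, false);
  dense(p + n.oWv1, p + n.obv1, f.h2, f.hv, NHS, NH2, true);
  float v = p[n.obv2];
  for (int i = 0; i < NHS; ++i) v += p[n.oWv2 + i] * f.hv[i];
  f.V = v;
  float m = 0.0f;
  for (int a = 0; a < NACT; ++a) m += f.A[a];
  m /= (float)NACT;
  f.meanA = m;
  for (int a = 0; a < NACT; ++a) f.Q[a] = v + f.A[a] - m;
}

static inline int argmax_q(const float* Q) {  // ties -> lowest index
  int best = 0;
  for (int a = 1; a < NACT; ++a)
    if (Q[a] > Q[best]) best = a;
  return best;
}

// ------------------------------------------------------------------ Adam

struct Adam {
  std::vector<float> m, v;
  double t = 0.0;
  void init(int n) { m.assign(n, 0.0f); v.assign(n, 0.0f); t = 0.0; }
  void step(std::vector<float>& p, const std::vector<float>& g, double lr) {
    t += 1.0;
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    const double c1 = 1.0 - std::pow(b1, t);
    const double c2 = 1.0 - std::pow(b2, t);
    const int n = (int)p.size();
    for (int i = 0; i < n; ++i) {
      double gi = g[i];
      double mi = b1 * m[i] + (1.0 - b1) * gi;
      double vi = b2 * v[i] + (1.0 - b2) * gi * gi;
      m[i] = (float)mi;
      v[i] = (float)vi;
      p[i] -= (float)(lr * (mi / c1) / (std::sqrt(vi / c2) + eps));
    }
  }
};

// ----------------------------------------------------------- environment

struct EnvC {
  int np;            // predators
  double mob;        // predator acceleration scale
  int sharing;       // 1 shared, 0 individual
  double dt, damp, accel, diam, init_range, half;
  int tmax;          // step limit
};

struct WorldC {
  std::vector<double> px, py, vx, vy;
  int t = 0;
  void alloc(int na) {
    px.assign(na, 0); py.assign(na, 0); vx.assign(na, 0); vy.assign(na, 0);
    t = 0;
  }
};

// Relative-frame u axis: predators point at the prey, the prey points at
// its nearest predator (ties -> lowest index). Degenerate -> absolute x.
static void frame_of(const WorldC& w, int i, const EnvC& e,
                     double& ux, double& uy) {
  double tx, ty;
  if (i < e.np) {
    tx = w.px[e.np] - w.px[i];
    ty = w.py[e.np] - w.py[i];
  } else {
    int best = 0;
    double bd = R_PosInf;
    for (int j = 0; j < e.np; ++j) {
      double dx = w.px[j] - w.px[i], dy = w.py[j] - w.py[i];
      double d = dx * dx + dy * dy;
      if (d < bd) { bd = d; best = j; }
    }
    tx = w.px[best] - w.px[i];
    ty = w.py[best] - w.py[i];
  }
  double nrm = std::sqrt(tx * tx + ty * ty);
  if (nrm < 1e-12) { ux = 1.0; uy = 0.0; }
  else { ux = tx / nrm; uy = ty / nrm; }
}

static void accel_of(const WorldC& w, int i, int action, const EnvC& e,
                     double& ax, double& ay) {
  if (action == NACT) { ax = 0.0; ay = 0.0; return; }
  double ux, uy;
  frame_of(w, i, e, ux, uy);
  double th = (action - 1) * M_PI / 6.0;
  double c = std::cos(th), s = std::sin(th);
  double mag = e.accel * (i < e.np ? e.mob : 1.0);
  // v axis is u rotated 90 degrees clockwise: action angles are
  // measured clockwise, which is the convention under which the
  // rule-based edge turns point into the arena for both orientations.
  ax = mag * (c * ux + s * uy);
  ay = mag * (c * uy - s * ux);
}

static void integrate(WorldC& w, const std::vector<double>& ax,
                      const std::vector<double>& ay, const EnvC& e) {
  int na = e.np + 1;
  for (int i = 0; i < na; ++i) {
    w.vx[i] = e.damp * w.vx[i] + ax[i] * e.dt;
    w.vy[i] = e.damp * w.vy[i] + ay[i] * e.dt;
    w.px[i] += w.vx[i] * e.dt;
    w.py[i] += w.vy[i] * e.dt;
  }
  w.t += 1;
}

// events: 0 none, 1 capture, 2 predator_out, 3 prey_out, 4 timeout
static int detect(const WorldC& w, const EnvC& e, int& who) {
  who = -1;
  for (int j = 0; j < e.np; ++j) {
    double dx = w.px[j] - w.px[e.np], dy = w.py[j] - w.py[e.np];
    if (std::sqrt(dx * dx + dy * dy) <= e.diam) { who = j; return 1; }
  }
  for (int j = 0; j < e.np; ++j)
    if (std::fabs(w.px[j]) > e.half || std::fabs(w.py[j]) > e.half) {
      who = j;
      return 2;
    }
  if (std::fabs(w.px[e.np]) > e.half || std::fabs(w.py[e.np]) > e.half) {
    who = e.np;
    return 3;
  }
  if (w.t >= e.tmax) return 4;
  return 0;
}

static void rewards_of(int event, int who, const EnvC& e, double* r) {
  int na = e.np + 1;
  for (int i = 0; i < na; ++i) r[i] = 0.0;
  if (event == 1) {
    r[e.np] = -1.0;
    if (e.sharing) for (int j = 0; j < e.np; ++j) r[j] = 1.0;
    else r[who] = 1.0;
  } else if (event == 2) {
    r[who] = -1.0;
  } else if (event == 3) {
    r[e.np] = -1.0;
  }
}

static void reset_world(WorldC& w, const EnvC& e) {
  int na = e.np + 1;
  w.alloc(na);
  for (int i = 0; i < na; ++i) {
    w.px[i] = -e.init_range + unif_rand() * 2.0 * e.init_range;
    w.py[i] = -e.init_range + unif_rand() * 2.0 * e.init_range;
  }
}

static int detect(const WorldC& w, const EnvC& e, int& who);

// Initial draws that already satisfy a terminal predicate (overlapping
// disks) are redrawn, so every episode starts live.
static void reset_nonterminal(WorldC& w, const EnvC& e) {
  int who;
  do {
    reset_world(w, e);
  } while (detect(w, e, who) != 0);
}

// State vector: own absolute position; own velocity in own relative frame;
// then, per other agent in index order, relative position and relative
// velocity rotated into the same frame. Length 4 + 4*(n_agents-1).
static void state_of(const WorldC& w, int i, const EnvC& e, float* s) {
  double ux, uy;
  frame_of(w, i, e, ux, uy);
  s[0] = (float)w.px[i];
  s[1] = (float)w.py[i];
  s[2] = (float)(w.vx[i] * ux + w.vy[i] * uy);
  s[3] = (float)(w.vx[i] * uy - w.vy[i] * ux);
  int k = 4, na = e.np + 1;
  for (int j = 0; j < na; ++j) {
    if (j == i) continue;
    double dx = w.px[j] - w.px[i], dy = w.py[j] - w.py[i];
    double dvx = w.vx[j] - w.vx[i], dvy = w.vy[j] - w.vy[i];
    s[k++] = (float)(dx * ux + dy * uy);
    s[k++] = (float)(dx * uy - dy * ux);
    s[k++] = (float)(dvx * ux + dvy * uy);
    s[k++] = (float)(dvx * uy - dvy * ux);
  }
}

static EnvC env_from_list(const List& cfg) {
  EnvC e;
  e.np = as<int>(cfg["n_predators"]);
  e.mob = as<double>(cfg["mobility"]);
  std::string sh = as<std::string>(cfg["sharing"]);
  e.sharing = (sh == "shared") ? 1 : 0;
  e.dt = as<double>(cfg["dt"]);
  e.damp = as<double>(cfg["damping"]);
  e.accel = as<double>(cfg["prey_accel"]);
  e.diam = as<double>(cfg["agent_diameter"]);
  e.init_range = as<double>(cfg["init_range"]);
  e.half = as<double>(cfg["arena_half_width"]);
  e.tmax = (int)std::lround(as<double>(cfg["time_limit"]) / e.dt);
  return e;
}

// ------------------------------------------------------- rule-based agent

struct RuleC {
  double thr;                       // role-branch distance threshold
  double bot_x, bot_y, top_x, top_y;  // ambush reference points
};

static inline double sgn1(double x) { return x < 0 ? -1.0 : 1.0; }

// CW (true) / CCW: sign of cross(sign-quadrant of prey, dominant-axis
// direction of the closer-predator -> prey vector). Frozen against the
// printed worked example.
static bool is_cw(const WorldC& w, const EnvC& e) {
  int closer = 0;
  double bd = R_PosInf;
  for (int j = 0; j < e.np; ++j) {
    double dx = w.px[e.np] - w.px[j], dy = w.py[e.np] - w.py[j];
    double d = dx * dx + dy * dy;
    if (d < bd) { bd = d; closer = j; }
  }
  double rx = w.px[e.np] - w.px[closer], ry = w.py[e.np] - w.py[closer];
  double dx_, dy_;
  if (std::fabs(rx) >= std::fabs(ry)) { dx_ = sgn1(rx); dy_ = 0.0; }
  else { dx_ = 0.0; dy_ = sgn1(ry); }
  double cross = sgn1(w.px[e.np]) * dy_ - sgn1(w.py[e.np]) * dx_;
  return cross <= 0.0;
}

// Band tests use the max coordinate (square rings about the centre):
// the printed per-coordinate inequalities only cohere as rings.
static int edge_band_action(double x, double y, bool cw) {
  double m = std::max(std::fabs(x), std::fabs(y));
  if (m > 0.9) return cw ? 3 : 11;
  if (m > 0.8) return cw ? 2 : 12;
  return 0;
}

static int chase_act(const WorldC& w, int i, const EnvC& e) {
  bool cw = is_cw(w, e);
  int a = edge_band_action(w.px[i], w.py[i], cw);
  if (a) return a;
  double pm = std::max(std::fabs(w.px[e.np]), std::fabs(w.py[e.np]));
  if (pm <= 0.5) return cw ? 11 : 3;
  if (pm <= 0.6) return cw ? 12 : 2;
  double psi = std::atan2(w.vy[e.np], w.vx[e.np]) -
               std::atan2(w.vy[i], w.vx[i]);
  psi = psi * 180.0 / M_PI;
  while (psi > 180.0) psi -= 360.0;
  while (psi <= -180.0) psi += 360.0;
  if (psi <= -50.0) return 3;
  if (psi <= -15.0) return 2;
  if (psi <= 15.0) return 1;
  if (psi <= 50.0) return 2;
  return 3;
}

static int shortcut_act(const WorldC& w, int i, const EnvC& e) {
  bool cw = is_cw(w, e);
  int a = edge_band_action(w.px[i], w.py[i], cw);
  if (a) return a;
  return cw ? 2 : 12;
}

static int approach_act(const WorldC& w, int i, const EnvC& e) {
  bool cw = is_cw(w, e);
  int a = edge_band_action(w.px[i], w.py[i], cw);
  if (a) return a;
  return 1;
}

// One-step lookahead onto the ambush reference point, restricted to the
// 120-degree action set {3, 8, 12}; ties -> lowest action.
static int ambush_act(const WorldC& w, int i, const EnvC& e, const RuleC& rc) {
  double refx, refy;
  if (w.py[e.np] <= 0.0) { refx = rc.bot_x; refy = rc.bot_y; }
  else { refx = rc.top_x; refy = rc.top_y; }
  const int cand[3] = {3, 8, 12};
  int best = cand[0];
  double bd = R_PosInf;
  for (int k = 0; k < 3; ++k) {
    double ax, ay;
    accel_of(w, i, cand[k], e, ax, ay);
    double nvx = e.damp * w.vx[i] + ax * e.dt;
    double nvy = e.damp * w.vy[i] + ay * e.dt;
    double npx = w.px[i] + nvx * e.dt, npy = w.py[i] + nvy * e.dt;
    double d = (npx - refx) * (npx - refx) + (npy - refy) * (npy - refy);
    if (d < bd) { bd = d; best = cand[k]; }
  }
  return best;
}

// roles: 1 chase, 2 shortcut, 3 approach, 4 ambush (two-predator only)
static void assign_roles_c(const WorldC& w, const EnvC& e, const RuleC& rc,
                           int& rule1, int& rule2) {
  double d1 = std::sqrt((w.px[2] - w.px[0]) * (w.px[2] - w.px[0]) +
                        (w.py[2] - w.py[0]) * (w.py[2] - w.py[0]));
  double d2 = std::sqrt((w.px[2] - w.px[1]) * (w.px[2] - w.px[1]) +
                        (w.py[2] - w.py[1]) * (w.py[2] - w.py[1]));
  double dcloser = std::min(d1, d2);
  if (d1 <= d2) rule1 = 1;                       // ties: predator 1 closer
  else rule1 = (dcloser < rc.thr) ? 2 : 3;
  if (d2 < d1) rule2 = 1;
  else rule2 = (dcloser < rc.thr) ? 4 : 1;       // partner far -> both chase
}

static int rule_action(const WorldC& w, int i, const EnvC& e, const RuleC& rc) {
  int r1, r2;
  assign_roles_c(w, e, rc, r1, r2);
  int r = (i == 0) ? r1 : r2;
  switch (r) {
    case 1: return chase_act(w, i, e);
    case 2: return shortcut_act(w, i, e);
    case 3: return approach_act(w, i, e);
    default: return ambush_act(w, i, e, rc);
  }
}

// ------------------------------------------------------ scripted policies

// Closest-direction action (1..12) for a desired absolute direction.
static int action_toward(const WorldC& w, int i, const EnvC& e,
                         double dx, double dy) {
  double nrm = std::sqrt(dx * dx + dy * dy);
  if (nrm < 1e-12) return NACT;
  dx /= nrm; dy /= nrm;
  double ux, uy;
  frame_of(w, i, e, ux, uy);
  int best = 1;
  double bd = -R_PosInf;
  for (int a = 1; a <= 12; ++a) {
    double th = (a - 1) * M_PI / 6.0;
    double c = std::cos(th), s = std::sin(th);
    double ex = c * ux + s * uy, ey = c * uy - s * ux;
    double d = ex * dx + ey * dy;
    if (d > bd + 1e-12) { bd = d; best = a; }
  }
  return best;
}

struct ScriptC {
  int kind;          // 0 stationary, 1 pursuit, 2 flee, 3 straight,
                     // 4 random_walk, 5 evasive
  double dir_x = 1.0, dir_y = 0.0;   // straight
  double noise_sd = 0.0;             // evasive / straight angular noise
  double orbit_radius = 0.8;         // evasive idle/containment ring
  double radial_gain = 4.0;          // evasive radial correction
  double flight_dist = 0.45;         // evasive flight-initiation distance
};

static int script_action(const WorldC& w, int i, const EnvC& e,
                         const ScriptC& sc) {
  switch (sc.kind) {
    case 0: return NACT;
    case 1: return 1;
    case 2: return 7;
    case 3: {
      double dx = sc.dir_x, dy = sc.dir_y;
      if (sc.noise_sd > 0.0) {
        double a = norm_rand() * sc.noise_sd;
        double c = std::cos(a), s = std::sin(a);
        double rx = c * dx - s * dy, ry = s * dx + c * dy;
        dx = rx; dy = ry;
      }
      return action_toward(w, i, e, dx, dy);
    }
    case 4: return (int)std::floor(unif_rand() * 12.0) + 1;
    default: {
      // evasive: idle on an interior ring while no predator is within
      // the flight-initiation distance; when pressed, sprint along the
      // tangent that increases distance to the nearest predator, with
      // a radial correction that keeps the prey off the boundary.
      int best = 0;
      double bd = R_PosInf;
      for (int j = 0; j < e.np; ++j) {
        double ddx = w.px[j] - w.px[i], ddy = w.py[j] - w.py[i];
        double d = ddx * ddx + ddy * ddy;
        if (d < bd) { bd = d; best = j; }
      }
      double dn = std::sqrt(bd);
      double rho = std::sqrt(w.px[i] * w.px[i] + w.py[i] * w.py[i]);
      double dx, dy;
      if (dn > sc.flight_dist) {
        if (rho <= sc.orbit_radius) return NACT;
        dx = -w.px[i] / rho;
        dy = -w.py[i] / rho;
      } else {
        double ax = w.px[i] - w.px[best], ay = w.py[i] - w.py[best];
        double nrm = std::sqrt(ax * ax + ay * ay);
        if (nrm < 1e-12) { ax = 1.0; ay = 0.0; } else { ax /= nrm; ay /= nrm; }
        double ox, oy;
        if (rho < 1e-6) { ox = ax; oy = ay; }
        else { ox = w.px[i] / rho; oy = w.py[i] / rho; }
        double tx = -oy, ty = ox;               // CCW tangent
        if (tx * ax + ty * ay < 0) { tx = -tx; ty = -ty; }
        dx = tx + sc.radial_gain * (sc.orbit_radius - rho) * ox;
        dy = ty + sc.radial_gain * (sc.orbit_radius - rho) * oy;
        double nn = std::sqrt(dx * dx + dy * dy);
        if (nn < 1e-12) { dx = 1.0; dy = 0.0; } else { dx /= nn; dy /= nn; }
      }
      if (sc.noise_sd > 0.0) {
        double a = norm_rand() * sc.noise_sd;
        double c = std::cos(a), s = std::sin(a);
        double rx = c * dx - s * dy, ry = s * dx + c * dy;
        dx = rx; dy = ry;
      }
      return action_toward(w, i, e, dx, dy);
    }
  }
}

static int script_kind(const std::string& nm) {
  if (nm == "stationary") return 0;
  if (nm == "pursuit") return 1;
  if (nm == "flee") return 2;
  if (nm == "straight") return 3;
  if (nm == "random_walk") return 4;
  if (nm == "evasive") return 5;
  stop("unknown scripted policy '%s'", nm.c_str());
  return -1;
}

// --------------------------------------------------------------- replay

struct Replay {
  int cap, dim;
  int size = 0, head = 0;
  std::vector<float> s, s2;
  std::vector<int> a;
  std::vector<float> r;
  std::vector<char> done;
  std::vector<double> pr, pra;   // priority and cached priority^alpha
  double maxp = 1.0;
  std::vector<double> cums;      // scratch prefix sums

  void init(int cap_, int dim_) {
    cap = cap_; dim = dim_;
    s.assign((size_t)cap * dim, 0.0f);
    s2.assign((size_t)cap * dim, 0.0f);
    a.assign(cap, 0);
    r.assign(cap, 0.0f);
    done.assign(cap, 0);
    pr.assign(cap, 0.0);
    pra.assign(cap, 0.0);
    cums.assign(cap, 0.0);
  }

  void push(const float* st, int ac, float rw, const float* st2, bool dn,
            double alpha) {
    std::memcpy(&s[(size_t)head * dim], st, sizeof(float) * dim);
    std::memcpy(&s2[(size_t)head * dim], st2, sizeof(float) * dim);
    a[head] = ac;
    r[head] = rw;
    done[head] = dn ? 1 : 0;
    pr[head] = maxp;
    pra[head] = std::pow(maxp, alpha);
    head = (head + 1) % cap;
    if (size < cap) ++size;
  }
};

// -------------------------------------------------------------- learner

struct Learner {
  NetF online, target;
  Adam opt;
  Replay mem;
  std::vector<float> grad;
  double loss_sum = 0.0;
  long loss_n = 0;

  void init(const List& w, int cap) {
    online = net_from_list(w);
    target = online;
    opt.init(online.total);
    grad.assign(online.total, 0.0f);
    mem.init(cap, online.in);
  }
};

// One prioritized DDQN update (batch `B`) for a single agent.
static void dqn_update(Learner& L, int B, double gamma, double alpha,
                       double beta, double lr, double prio_eps,
                       double huber_delta) {
  Replay& M = L.mem;
  if (M.size < B) return;
  // prefix sums of cached p^alpha
  double tot = 0.0;
  for (int i = 0; i < M.size; ++i) { tot += M.pra[i]; M.cums[i] = tot; }
  std::vector<int> idx(B);
  std::vector<double> w(B);
  double wmax = 0.0;
  for (int b = 0; b < B; ++b) {
    double u = unif_rand() * tot;
    int lo = 0, hi = M.size - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (M.cums[mid] < u) lo = mid + 1; else hi = mid;
    }
    idx[b] = lo;
    double P = M.pra[lo] / tot;
    w[b] = std::pow((double)M.size * P, -beta);
    if (w[b] > wmax) wmax = w[b];
  }
  for (int b = 0; b < B; ++b) w[b] /= wmax;

  NetF& on = L.online;
  const NetF& tg = L.target;
  std::fill(L.grad.begin(), L.grad.end(), 0.0f);
  float* g = L.grad.data();
  const float* p = on.p.data();
  double loss = 0.0;
  Fwd f, f2;

  for (int b = 0; b < B; ++b) {
    int i = idx[b];
    const float* st = &M.s[(size_t)i * M.dim];
    const float* st2 = &M.s2[(size_t)i * M.dim];
    double y = M.r[i];
    if (!M.done[i]) {
      net_forward(on, st2, f2);
      int astar = argmax_q(f2.Q);
      net_forward(tg, st2, f2);
      y += gamma * f2.Q[astar];
    }
    net_forward(on, st, f);
    int ai = M.a[i] - 1;
    double delta = y - f.Q[ai];
    // Huber value and derivative w.r.t. the residual
    double hub, dpsi;
    if (std::fabs(delta) <= huber_delta) {
      hub = 0.5 * delta * delta;
      dpsi = delta;
    } else {
      hub = huber_delta * (std::fabs(delta) - 0.5 * huber_delta);
      dpsi = huber_delta * sgn1(delta);
    }
    loss += w[b] * hub;
    // d(mean loss)/dQ_sel
    float gq = (float)(-(w[b] * dpsi) / B);

    // backprop: Q = V + A[a] - mean(A)
    float gA[NACT], gha[NHS], ghv[NHS], gh2[NH2], gh1[NH1];
    for (int a2 = 0; a2 < NACT; ++a2)
      gA[a2] = gq * (((a2 == ai) ? 1.0f : 0.0f) - 1.0f / NACT);
    float gV = gq;
    // value head
    for (int k = 0; k < NHS; ++k) {
      g[on.oWv2 + k] += gV * f.hv[k];
      ghv[k] = (f.hv[k] > 0.0f) ? gV * p[on.oWv2 + k] : 0.0f;
    }
    g[on.obv2] += gV;
    // advantage head
    for (int k = 0; k < NHS; ++k) gha[k] = 0.0f;
    for (int a2 = 0; a2 < NACT; ++a2) {
      float ga = gA[a2];
      if (ga == 0.0f) continue;
      float* gw = g + on.oWa2 + (size_t)a2 * NHS;
      const float* wrow = p + on.oWa2 + (size_t)a2 * NHS;
      for (int k = 0; k < NHS; ++k) {
        gw[k] += ga * f.ha[k];
        gha[k] += ga * wrow[k];
      }
      g[on.oba2 + a2] += ga;
    }
    for (int k = 0; k < NHS; ++k)
      if (f.ha[k] <= 0.0f) gha[k] = 0.0f;
    // stream inputs -> trunk layer 2
    for (int j = 0; j < NH2; ++j) gh2[j] = 0.0f;
    for (int k = 0; k < NHS; ++k) {
      float gk = gha[k];
      if (gk != 0.0f) {
        float* gw = g + on.oWa1 + (size_t)k * NH2;
        const float* wrow = p + on.oWa1 + (size_t)k * NH2;
        for (int j = 0; j < NH2; ++j) {
          gw[j] += gk * f.h2[j];
          gh2[j] += gk * wrow[j];
        }
        g[on.oba1 + k] += gk;
      }
      gk = ghv[k];
      if (gk != 0.0f) {
        float* gw = g + on.oWv1 + (size_t)k * NH2;
        const float* wrow = p + on.oWv1 + (size_t)k * NH2;
        for (int j = 0; j < NH2; ++j) {
          gw[j] += gk * f.h2[j];
          gh2[j] += gk * wrow[j];
        }
        g[on.obv1 + k] += gk;
      }
    }
    for (int j = 0; j < NH2; ++j)
      if (f.h2[j] <= 0.0f) gh2[j] = 0.0f;
    // trunk layer 2 -> layer 1
    for (int j = 0; j < NH1; ++j) gh1[j] = 0.0f;
    for (int o = 0; o < NH2; ++o) {
      float go = gh2[o];
      if (go == 0.0f) continue;
      float* gw = g + on.oW2 + (size_t)o * NH1;
      const float* wrow = p + on.oW2 + (size_t)o * NH1;
      for (int j = 0; j < NH1; ++j) {
        gw[j] += go * f.h1[j];
        gh1[j] += go * wrow[j];
      }
      g[on.ob2 + o] += go;
    }
    for (int j = 0; j < NH1; ++j)
      if (f.h1[j] <= 0.0f) gh1[j] = 0.0f;
    // layer 1 -> input
    for (int o = 0; o < NH1; ++o) {
      float go = gh1[o];
      if (go == 0.0f) continue;
      float* gw = g + on.oW1 + (size_t)o * on.in;
      for (int j = 0; j < on.in; ++j) gw[j] += go * st[j];
      g[on.ob1 + o] += go;
    }

    // new priority
    double np = std::fabs(delta) + prio_eps;
    M.pr[i] = np;
    M.pra[i] = std::pow(np, alpha);
    if (np > M.maxp) M.maxp = np;
  }

  L.opt.step(on.p, L.grad, lr);
  L.loss_sum += loss / B;
  L.loss_n += 1;
}

// ------------------------------------------------------------- training

// [[Rcpp::export]]
List cpp_train(List condition, List init_weights, double gamma, double alpha,
               double beta, double lr, int batch, int capacity,
               int target_sync_every, int total_episodes, double eps_start,
               double eps_end, int eps_anneal_episodes, double priority_eps,
               double huber_delta, IntegerVector checkpoint_at) {
  EnvC e = env_from_list(condition);
  int na = e.np + 1;
  if (init_weights.size() != na) stop("need one weight set per agent");

  std::vector<Learner> L(na);
  for (int i = 0; i < na; ++i) L[i].init(init_weights[i], capacity);
  int dim = L[0].online.in;

  std::vector<int> cps(checkpoint_at.begin(), checkpoint_at.end());
  std::sort(cps.begin(), cps.end());
  List checkpoints;
  IntegerVector cp_eps;

  // per-episode log
  IntegerVector lg_ep(total_episodes), lg_steps(total_episodes),
      lg_event(total_episodes);
  NumericVector lg_eps(total_episodes);
  NumericMatrix lg_ret(total_episodes, na), lg_loss(total_episodes, na);

  WorldC w;
  std::vector<float> sv((size_t)na * dim), sv2((size_t)na * dim);
  std::vector<int> act(na);
  std::vector<double> axv(na), ayv(na), rw(na), ret(na);
  Fwd f;

  for (int ep = 0; ep < total_episodes; ++ep) {
    double eps = (ep < eps_anneal_episodes)
        ? eps_start + (eps_end - eps_start) * (double)ep / eps_anneal_episodes
        : eps_end;

    reset_nonterminal(w, e);
    std::fill(ret.begin(), ret.end(), 0.0);
    for (int i = 0; i < na; ++i) { L[i].loss_sum = 0.0; L[i].loss_n = 0; }
    int event = 0, who = -1;

    while (true) {
      for (int i = 0; i < na; ++i) {
        state_of(w, i, e, &sv[(size_t)i * dim]);
        if (eps > 0.0 && unif_rand() < eps) {
          act[i] = (int)std::floor(unif_rand() * NACT) + 1;
        } else {
          net_forward(L[i].online, &sv[(size_t)i * dim], f);
          act[i] = argmax_q(f.Q) + 1;
        }
      }
      for (int i = 0; i < na; ++i) accel_of(w, i, act[i], e, axv[i], ayv[i]);
      integrate(w, axv, ayv, e);
      event = detect(w, e, who);
      rewards_of(event, who, e, rw.data());
      bool terminal = (event != 0);
      for (int i = 0; i < na; ++i) {
        state_of(w, i, e, &sv2[(size_t)i * dim]);
        L[i].mem.push(&sv[(size_t)i * dim], act[i], (float)rw[i],
                      &sv2[(size_t)i * dim], terminal, alpha);
        ret[i] += rw[i];
      }
      for (int i = 0; i < na; ++i)
        dqn_update(L[i], batch, gamma, alpha, beta, lr, priority_eps,
                   huber_delta);
      if (terminal) break;
    }

    if (target_sync_every > 0 && (ep + 1) % target_sync_every == 0)
      for (int i = 0; i < na; ++i) L[i].target.p = L[i].online.p;

    lg_ep[ep] = ep + 1;
    lg_steps[ep] = w.t;
    lg_event[ep] = event;
    lg_eps[ep] = eps;
    for (int i = 0; i < na; ++i) {
      lg_ret(ep, i) = ret[i];
      lg_loss(ep, i) = L[i].loss_n ? L[i].loss_sum / L[i].loss_n : NA_REAL;
    }

    if (std::binary_search(cps.begin(), cps.end(), ep + 1)) {
      List snap(na);
      for (int i = 0; i < na; ++i) snap[i] = net_to_list(L[i].online);
      checkpoints.push_back(snap);
      cp_eps.push_back(ep + 1);
    }
    if ((ep + 1) % 500 == 0) Rcpp::checkUserInterrupt();
  }

  List final_w(na);
  for (int i = 0; i < na; ++i) final_w[i] = net_to_list(L[i].online);
  return List::create(
      _["params"] = final_w, _["checkpoints"] = checkpoints,
      _["checkpoint_episodes"] = cp_eps, _["log_episode"] = lg_ep,
      _["log_steps"] = lg_steps, _["log_event"] = lg_event,
      _["log_epsilon"] = lg_eps, _["log_return"] = lg_ret,
      _["log_loss"] = lg_loss);
}

// -------------------------------------------------------------- rollout

struct PolicyC {
  int type;  // 0 net, 1 rule, 2 script
  NetF net;
  double eps = 0.0;
  ScriptC sc;
};

// [[Rcpp::export]]
List cpp_rollout(List condition, List policies, List rule_cfg, int episodes,
                 bool record) {
  EnvC e = env_from_list(condition);
  int na = e.np + 1;
  if (policies.size() != na) stop("need one policy per agent slot");

  RuleC rc;
  rc.thr = as<double>(rule_cfg["distance_threshold"]);
  NumericVector bot = rule_cfg["ambush_bottom"], top = rule_cfg["ambush_top"];
  rc.bot_x = bot[0]; rc.bot_y = bot[1];
  rc.top_x = top[0]; rc.top_y = top[1];

  std::vector<PolicyC> P(na);
  for (int i = 0; i < na; ++i) {
    List pi = policies[i];
    std::string ty = as<std::string>(pi["type"]);
    if (ty == "net") {
      P[i].type = 0;
      P[i].net = net_from_list(pi["params"]);
      P[i].eps = pi.containsElementNamed("epsilon") ? as<double>(pi["epsilon"])
                                                    : 0.0;
    } else if (ty == "rule") {
      P[i].type = 1;
      if (e.np != 2) stop("rule-based policy requires exactly 2 predators");
    } else if (ty == "scripted") {
      P[i].type = 2;
      P[i].sc.kind = script_kind(as<std::string>(pi["name"]));
      if (pi.containsElementNamed("noise_sd"))
        P[i].sc.noise_sd = as<double>(pi["noise_sd"]);
      if (pi.containsElementNamed("orbit_radius"))
        P[i].sc.orbit_radius = as<double>(pi["orbit_radius"]);
      if (pi.containsElementNamed("radial_gain"))
        P[i].sc.radial_gain = as<double>(pi["radial_gain"]);
      if (pi.containsElementNamed("flight_distance"))
        P[i].sc.flight_dist = as<double>(pi["flight_distance"]);
      if (pi.containsElementNamed("direction")) {
        NumericVector d = pi["direction"];
        P[i].sc.dir_x = d[0]; P[i].sc.dir_y = d[1];
      }
    } else {
      stop("unknown policy type '%s'", ty.c_str());
    }
  }

  // outcome log
  IntegerVector oc_ep(episodes), oc_steps(episodes), oc_event(episodes),
      oc_catcher(episodes);
  NumericMatrix oc_ret(episodes, na);

  // trajectory records (one row per agent-step)
  std::vector<int> r_ep, r_step, r_agent, r_action, r_event;
  std::vector<double> r_x, r_y, r_vx, r_vy, r_rw;
  if (record) {
    size_t guess = (size_t)episodes * 64 * na;
    r_ep.reserve(guess); r_step.reserve(guess); r_agent.reserve(guess);
    r_action.reserve(guess); r_event.reserve(guess);
    r_x.reserve(guess); r_y.reserve(guess);
    r_vx.reserve(guess); r_vy.reserve(guess); r_rw.reserve(guess);
  }

  WorldC w;
  std::vector<int> act(na);
  std::vector<double> axv(na), ayv(na), rw(na), ret(na);
  std::vector<float> sv;
  Fwd f;

  for (int ep = 0; ep < episodes; ++ep) {
    reset_nonterminal(w, e);
    std::fill(ret.begin(), ret.end(), 0.0);
    int event = 0, who = -1;
    while (true) {
      for (int i = 0; i < na; ++i) {
        switch (P[i].type) {
          case 0: {
            if ((int)sv.size() < P[i].net.in) sv.resize(P[i].net.in);
            state_of(w, i, e, sv.data());
            if (P[i].eps > 0.0 && unif_rand() < P[i].eps)
              act[i] = (int)std::floor(unif_rand() * NACT) + 1;
            else {
              net_forward(P[i].net, sv.data(), f);
              act[i] = argmax_q(f.Q) + 1;
            }
            break;
          }
          case 1: act[i] = rule_action(w, i, e, rc); break;
          default: act[i] = script_action(w, i, e, P[i].sc); break;
        }
      }
      int t0 = w.t;
      if (record)
        for (int i = 0; i < na; ++i) {
          r_ep.push_back(ep + 1); r_step.push_back(t0); r_agent.push_back(i + 1);
          r_x.push_back(w.px[i]); r_y.push_back(w.py[i]);
          r_vx.push_back(w.vx[i]); r_vy.push_back(w.vy[i]);
          r_action.push_back(act[i]);
        }
      for (int i = 0; i < na; ++i) accel_of(w, i, act[i], e, axv[i], ayv[i]);
      integrate(w, axv, ayv, e);
      event = detect(w, e, who);
      rewards_of(event, who, e, rw.data());
      for (int i = 0; i < na; ++i) ret[i] += rw[i];
      if (record)
        for (int i = 0; i < na; ++i) {
          r_rw.push_back(rw[i]);
          r_event.push_back(event);
        }
      if (event != 0) break;
    }
    oc_ep[ep] = ep + 1;
    oc_steps[ep] = w.t;
    oc_event[ep] = event;
    oc_catcher[ep] = (event == 1) ? who + 1 : NA_INTEGER;
    for (int i = 0; i < na; ++i) oc_ret(ep, i) = ret[i];
    if ((ep + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["episode"] = oc_ep, _["steps"] = oc_steps, _["event"] = oc_event,
      _["catcher"] = oc_catcher, _["returns"] = oc_ret);
  if (record) {
    out["rec_episode"] = wrap(r_ep);
    out["rec_step"] = wrap(r_step);
    out["rec_agent"] = wrap(r_agent);
    out["rec_x"] = wrap(r_x);
    out["rec_y"] = wrap(r_y);
    out["rec_vx"] = wrap(r_vx);
    out["rec_vy"] = wrap(r_vy);
    out["rec_action"] = wrap(r_action);
    out["rec_reward"] = wrap(r_rw);
    out["rec_event"] = wrap(r_event);
  }
  return out;
}

// ------------------------------------------------- small exported helpers

// [[Rcpp::export]]
List cpp_forward(List weights, NumericVector state) {
  NetF n = net_from_list(weights);
  if ((int)state.size() != n.in) stop("state length mismatch");
  std::vector<float> s(n.in);
  for (int i = 0; i < n.in; ++i) s[i] = (float)state[i];
  Fwd f;
  net_forward(n, s.data(), f);
  NumericVector Q(NACT), A(NACT), ha(NHS), hv(NHS);
  for (int a = 0; a < NACT; ++a) { Q[a] = f.Q[a]; A[a] = f.A[a]; }
  for (int k = 0; k < NHS; ++k) { ha[k] = f.ha[k]; hv[k] = f.hv[k]; }
  return List::create(_["V"] = f.V, _["A"] = A, _["Q"] = Q,
                      _["hidden_advantage"] = ha, _["hidden_value"] = hv);
}
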