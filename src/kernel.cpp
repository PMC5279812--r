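// Monte-Carlo growth kernel for discrete semi-flexible self-avoiding chains
// with hard-sphere protrusions and optional spherical confinement.
//
// Chains are grown link by link; bend angles are drawn from the exact
// elastic Boltzmann density, so the Rosenbluth factor of a surviving chain
// carries only hard-wall survival information (single-trial scheme: weight 1
// if the chain never overlaps, discarded otherwise).  Conditions (on-chain
// protrusions, static protrusions, a confining sphere) may be "enforced"
// (violations discard the chain) or "virtual" (the first violating growth
// step is recorded, and ensembles are formed post hoc as the subset of
// chains with no violation -- exactly the ensemble that enforced growth
// with shared per-chain RNG streams would produce, since conditions consume
// no randomness).

#include <Rcpp.h>
#include <array>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm2(Vec3 a) { return dot(a, a); }

// splitmix64: small, fast, and good enough for Monte-Carlo; one independent
// stream per chain keyed by the chain's global index, so sub-ensembles merge
// deterministically regardless of partitioning.
static inline uint64_t sm64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// murmur3 finaliser: bijective scrambler used to key per-chain streams so
// that no two chains' state progressions (which advance by a fixed odd
// constant) can overlap in practice
static inline uint64_t fmix64(uint64_t z) {
  z ^= z >> 33;
  z *= 0xFF51AFD7ED558CCDULL;
  z ^= z >> 33;
  z *= 0xC4CEB9FE1A85EC53ULL;
  z ^= z >> 33;
  return z;
}

struct RNG {
  uint64_t s;
  // uniform on (0, 1]
  double unif() {
    uint64_t r = sm64(s);
    return ((r >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
};

struct Frame {
  Vec3 u, v, t;
};

// Draw a bend: zenith from density prop. to exp(-a(1-cos th)) sin th via the
// closed-form inverse CDF, azimuth uniform.
static inline void sample_bend(double a, RNG &rng, double &ct, double &st, double &phi) {
  double u = rng.unif();
  if (a <= 0.0) {
    ct = 2.0 * u - 1.0;
  } else {
    ct = 1.0 + std::log(u + (1.0 - u) * std::exp(-2.0 * a)) / a;
    if (ct < -1.0) ct = -1.0;
    if (ct > 1.0) ct = 1.0;
  }
  st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  phi = 2.0 * M_PI * rng.unif();
}

// New link direction with zenith/azimuth (ct,st,phi) in the previous local
// frame; u transported by the minimal rotation taking t to t' (no intrinsic
// twist about the polymer axis).
static inline Frame propagate(const Frame &f, double ct, double st, double phi) {
  Vec3 tn = (st * std::cos(phi)) * f.u + (st * std::sin(phi)) * f.v + ct * f.t;
  Vec3 n = cross(f.t, tn);
  double s2 = norm2(n);
  Frame out;
  out.t = tn;
  if (s2 < 1e-28) {
    out.u = (ct > 0.0) ? f.u : (-1.0 * f.u);  // straight (or exactly reversed)
  } else {
    double sa = std::sqrt(s2);
    Vec3 nh = (1.0 / sa) * n;
    double ca = ct;  // angle between t and t' equals the zenith angle
    out.u = ca * f.u + sa * cross(nh, f.u) + ((1.0 - ca) * dot(nh, f.u)) * nh;
  }
  // renormalise to stop drift over long chains
  out.t = (1.0 / std::sqrt(norm2(out.t))) * out.t;
  out.u = out.u - dot(out.u, out.t) * out.t;
  out.u = (1.0 / std::sqrt(norm2(out.u))) * out.u;
  out.v = cross(out.t, out.u);
  return out;
}

// right-handed rotation of u about unit axis t by angle g (t.u = 0)
static inline Vec3 rot_about(Vec3 u, Vec3 t, double g) {
  return std::cos(g) * u + std::sin(g) * cross(t, u);
}

struct Segment {
  int n;
  double l, a, excl;
};

struct Cond {
  int type;      // 0 on-chain protrusion, 1 static protrusion, 2 confinement
  int link;      // >0 forward link, <0 backward link (on-chain only)
  double radius; // protrusion radius R_o, or confining-sphere radius
  double gamma;  // phase about the chain axis (on-chain only)
  Vec3 spos;     // static position
  bool enforce;
};

struct Crit {
  int type;  // 0 end-anchored, 1 activator-anchored (cond index)
  Vec3 anchor, axis;
  int cond;
  double rlo2, rhi2, cosc;
  int sign;
};

// open-addressed cell list: buckets of joint ids, cleared between chains
struct Hash {
  int mask;
  double cell;
  std::vector<std::vector<int>> bucket;
  std::vector<int> used;
  void init(double cell_, int nbuckets) {
    cell = cell_;
    mask = nbuckets - 1;
    bucket.assign(nbuckets, {});
    used.clear();
    used.reserve(1024);
  }
  inline int key(int ix, int iy, int iz) const {
    uint32_t h = ((uint32_t)ix * 73856093u) ^ ((uint32_t)iy * 19349663u) ^
                 ((uint32_t)iz * 83492791u);
    return (int)(h & (uint32_t)mask);
  }
  inline void insert(const Vec3 &p, int id) {
    int ix = (int)std::floor(p.x / cell), iy = (int)std::floor(p.y / cell),
        iz = (int)std::floor(p.z / cell);
    int k = key(ix, iy, iz);
    if (bucket[k].empty()) used.push_back(k);
    bucket[k].push_back(id);
  }
  inline void clear() {
    for (int k : used) bucket[k].clear();
    used.clear();
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_run_ensemble(List cfg) {
  const double w = as<double>(cfg["w"]);
  const bool self_avoid = as<bool>(cfg["self_avoid"]);
  const double n_chains_d = as<double>(cfg["n_chains"]);
  const long long n_chains = (long long)n_chains_d;
  const double chain_offset = as<double>(cfg["chain_offset"]);
  const uint64_t seed = (uint64_t)as<double>(cfg["seed"]);
  const int eval_offset = as<int>(cfg["eval_offset"]);
  const bool collect_bend = as<bool>(cfg["collect_bend"]);
  const bool collect_r2 = as<bool>(cfg["collect_r2"]);
  const int return_chain = as<int>(cfg["return_chain"]);

  auto read_segments = [](NumericMatrix m, std::vector<Segment> &out, int &njoints) {
    njoints = 0;
    for (int i = 0; i < m.nrow(); ++i) {
      Segment s;
      s.n = (int)m(i, 0);
      s.l = m(i, 1);
      s.a = m(i, 2);
      s.excl = m(i, 3) * s.l;  // delta_i * link length: contour exclusion
      out.push_back(s);
      njoints += s.n;
    }
  };
  std::vector<Segment> fseg, bseg;
  int n_f = 0, n_b = 0;
  read_segments(as<NumericMatrix>(cfg["fwd_segments"]), fseg, n_f);
  if (!Rf_isNull(cfg["bwd_segments"]))
    read_segments(as<NumericMatrix>(cfg["bwd_segments"]), bseg, n_b);

  // conditions
  std::vector<Cond> conds;
  {
    List cl = as<List>(cfg["conditions"]);
    for (int i = 0; i < cl.size(); ++i) {
      List c = as<List>(cl[i]);
      Cond cc;
      std::string ty = as<std::string>(c["type"]);
      cc.type = (ty == "protrusion") ? 0 : (ty == "static") ? 1 : 2;
      cc.link = c.containsElementNamed("link") ? as<int>(c["link"]) : 0;
      cc.radius = as<double>(c["radius"]);
      cc.gamma = c.containsElementNamed("gamma") ? as<double>(c["gamma"]) : 0.0;
      if (cc.type == 1) {
        NumericVector p = as<NumericVector>(c["position"]);
        cc.spos = {p[0], p[1], p[2]};
      } else {
        cc.spos = {0, 0, 0};
      }
      cc.enforce = as<bool>(c["enforce"]);
      conds.push_back(cc);
    }
  }
  const int n_cond = (int)conds.size();

  // record grid (forward joint indices, ascending)
  IntegerVector rec = as<IntegerVector>(cfg["record_joints"]);
  const int n_grid = rec.size();

  // criteria
  std::vector<Crit> crits;
  {
    List cl = as<List>(cfg["criteria"]);
    for (int i = 0; i < cl.size(); ++i) {
      List c = as<List>(cl[i]);
      Crit cr;
      std::string ty = as<std::string>(c["type"]);
      cr.type = (ty == "end") ? 0 : 1;
      cr.cond = c.containsElementNamed("cond") ? as<int>(c["cond"]) - 1 : -1;
      if (cr.type == 0) {
        NumericVector an = as<NumericVector>(c["anchor"]);
        NumericVector ax = as<NumericVector>(c["axis"]);
        cr.anchor = {an[0], an[1], an[2]};
        cr.axis = {ax[0], ax[1], ax[2]};
      } else {
        cr.anchor = {0, 0, 0};
        cr.axis = {1, 0, 0};
      }
      double dmin = as<double>(c["d_min"]), eps = as<double>(c["eps"]);
      double dom = as<double>(c["domega"]);
      cr.rlo2 = dmin * dmin;
      cr.rhi2 = (dmin + eps) * (dmin + eps);
      cr.sign = (dom < 0) ? -1 : 1;
      double adom = std::fabs(dom);
      cr.cosc = 1.0 - adom / (2.0 * M_PI);
      if (adom >= 4.0 * M_PI - 1e-12) cr.cosc = -1.0 - 1e-9;  // accept everything
      crits.push_back(cr);
    }
  }
  const int n_crit = (int)crits.size();

  // criterion groups (1-based index vectors into criteria)
  std::vector<std::vector<int>> groups;
  {
    List gl = as<List>(cfg["criteria_groups"]);
    for (int i = 0; i < gl.size(); ++i) {
      IntegerVector g = as<IntegerVector>(gl[i]);
      std::vector<int> gg;
      for (int j = 0; j < g.size(); ++j) gg.push_back(g[j] - 1);
      groups.push_back(gg);
    }
  }
  const int n_grp = (int)groups.size();

  // ensembles: subsets of *virtual* condition indices (1-based)
  std::vector<std::vector<int>> ens;
  {
    List el = as<List>(cfg["ensembles"]);
    for (int i = 0; i < el.size(); ++i) {
      IntegerVector e = as<IntegerVector>(el[i]);
      std::vector<int> ee;
      for (int j = 0; j < e.size(); ++j) ee.push_back(e[j] - 1);
      ens.push_back(ee);
    }
  }
  const int n_ens = (int)ens.size();

  // windows: list of lists of items (ensemble, group, lo, hi), 1-based
  std::vector<std::vector<std::array<int, 4>>> wins;
  {
    List wl = as<List>(cfg["windows"]);
    for (int i = 0; i < wl.size(); ++i) {
      List items = as<List>(wl[i]);
      std::vector<std::array<int, 4>> v;
      for (int j = 0; j < items.size(); ++j) {
        IntegerVector it = as<IntegerVector>(items[j]);
        v.push_back({it[0] - 1, it[1] - 1, it[2] - 1, it[3] - 1});
      }
      wins.push_back(v);
    }
  }
  const int n_win = (int)wins.size();

  // accumulators
  std::vector<double> Zdiff((size_t)n_ens * (n_grid + 1), 0.0);
  std::vector<double> W((size_t)n_ens * n_grp * n_grid, 0.0);
  std::vector<double> DUP((size_t)n_ens * n_grp * n_grid, 0.0);
  std::vector<double> R2s(collect_r2 ? (size_t)n_ens * n_grid : 0, 0.0);
  std::vector<double> R4s(collect_r2 ? (size_t)n_ens * n_grid : 0, 0.0);
  double bend_sum = 0.0, bend_sumsq = 0.0;
  long long bend_n = 0;
  long long n_disc = 0, n_complete = 0;
  // per-window moment sums: k items -> 2k variables (sv_i, a_i)
  std::vector<std::vector<double>> winS(n_win), winM(n_win);
  std::vector<long long> winN(n_win, 0);
  for (int i = 0; i < n_win; ++i) {
    int k2 = 2 * (int)wins[i].size();
    winS[i].assign(k2, 0.0);
    winM[i].assign(k2 * k2, 0.0);
  }

  const int n_tot = n_b + n_f;                 // joints beyond the origin
  const int INF = std::numeric_limits<int>::max();

  // geometry scratch
  std::vector<Vec3> pos((size_t)n_tot + 1);    // idx 0 origin, 1..n_b backward, n_b+1.. forward
  std::vector<double> contour((size_t)n_tot + 1), excl((size_t)n_tot + 1);
  std::vector<Frame> fr_fwd((size_t)n_f + 1), fr_bwd((size_t)n_b + 1);
  std::vector<Vec3> pcenter(n_cond);
  std::vector<int> pstep(n_cond);              // placement step, INF if not placed
  std::vector<int> viol(n_cond);
  std::vector<int> pairv((size_t)n_cond * n_cond);
  std::vector<int> gmax(n_ens);
  std::vector<double> gval((size_t)n_grp * n_grid);
  std::vector<int> glooped_idx;                 // grid indices with any nonzero group value
  glooped_idx.reserve(64);

  double maxl = w;
  for (auto &s : fseg) maxl = std::max(maxl, s.l);
  for (auto &s : bseg) maxl = std::max(maxl, s.l);
  Hash hash;
  hash.init(maxl, 1 << 14);

  // map: forward/backward link index -> on-chain condition indices (several
  // protrusions may share a link, e.g. phase variants evaluated virtually)
  std::vector<std::vector<int>> cond_at_fwd((size_t)n_f + 1), cond_at_bwd((size_t)n_b + 1);
  for (int c = 0; c < n_cond; ++c) {
    if (conds[c].type == 0) {
      if (conds[c].link > 0 && conds[c].link <= n_f) cond_at_fwd[conds[c].link].push_back(c);
      if (conds[c].link < 0 && -conds[c].link <= n_b) cond_at_bwd[-conds[c].link].push_back(c);
    }
  }

  List chain_out = R_NilValue;

  // strict-inequality overlaps with a relative slack: exact tangency (e.g.
  // adjacent joints at link length equal to w) must never register
  const double TOL = 1.0 - 1e-9;
  const double w2 = w * w * TOL;
  const double half_w = 0.5 * w;

  for (long long ci = 0; ci < n_chains; ++ci) {
    if ((ci & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    RNG rng;
    {
      uint64_t idx = (uint64_t)(chain_offset + (double)ci + 1.0);
      uint64_t h = fmix64(idx * 0xD2B74407B1CE6E93ULL + seed * 0x9E3779B97F4A7C15ULL);
      rng.s = fmix64(h ^ 0x94D049BB133111EBULL);
    }
    hash.clear();
    int death = INF;
    for (int c = 0; c < n_cond; ++c) { viol[c] = INF; pstep[c] = INF; }
    std::fill(pairv.begin(), pairv.end(), INF);

    pos[0] = {0, 0, 0};
    contour[0] = 0.0;
    excl[0] = 0.0;
    hash.insert(pos[0], 0);

    // record a violation caused by condition c alone at step s
    auto hit_cond = [&](int c, int s) {
      if (conds[c].enforce) {
        if (s < death) death = s;
      } else if (s < viol[c]) {
        viol[c] = s;
      }
    };
    // violation requiring conditions c1 and c2 jointly
    auto hit_pair = [&](int c1, int c2, int s) {
      if (conds[c1].enforce && conds[c2].enforce) {
        if (s < death) death = s;
      } else if (conds[c1].enforce) {
        hit_cond(c2, s);
      } else if (conds[c2].enforce) {
        hit_cond(c1, s);
      } else {
        int a = std::min(c1, c2), b = std::max(c1, c2);
        int &pv = pairv[(size_t)a * n_cond + b];
        if (s < pv) pv = s;
      }
    };

    // place a protrusion with centre c, radius R, attached joint id (-1 static)
    auto place_prot = [&](int cond_i, Vec3 c, int attach_id, int s, int n_placed) {
      pcenter[cond_i] = c;
      pstep[cond_i] = s;
      double rr = conds[cond_i].radius + half_w;
      double rr2 = rr * rr * TOL;
      for (int id = 0; id <= n_placed; ++id) {
        if (id == attach_id) continue;
        if (norm2(pos[id] - c) < rr2) { hit_cond(cond_i, s); break; }
      }
      for (int q = 0; q < n_cond; ++q) {
        if (q == cond_i) continue;
        if (conds[q].type == 2) {  // confinement vs protrusion
          double lim = conds[q].radius - conds[cond_i].radius;
          if (lim < 0.0 || norm2(c) > lim * lim) hit_pair(cond_i, q, s);
        } else if (pstep[q] <= s) {  // other placed protrusion
          double rs = conds[cond_i].radius + conds[q].radius;
          if (norm2(c - pcenter[q]) < rs * rs * TOL) hit_pair(cond_i, q, s);
        }
      }
    };

    // static protrusions and confinement of the origin joint, step 0
    for (int c = 0; c < n_cond; ++c) {
      if (conds[c].type == 1) place_prot(c, conds[c].spos, -1, 0, 0);
      if (conds[c].type == 2) {
        double lim = conds[c].radius - half_w;
        if (lim < 0.0 || norm2(pos[0]) > lim * lim) hit_cond(c, 0);
      }
    }

    // per-joint hard-wall + condition checks; returns false if chain is dead
    auto check_joint = [&](int id, int s) {
      Vec3 p = pos[id];
      if (self_avoid) {
        int ix = (int)std::floor(p.x / hash.cell), iy = (int)std::floor(p.y / hash.cell),
            iz = (int)std::floor(p.z / hash.cell);
        for (int dx = -1; dx <= 1 && death > s; ++dx)
          for (int dy = -1; dy <= 1 && death > s; ++dy)
            for (int dz = -1; dz <= 1 && death > s; ++dz) {
              const std::vector<int> &b = hash.bucket[hash.key(ix + dx, iy + dy, iz + dz)];
              for (int id2 : b) {
                double dc = std::fabs(contour[id] - contour[id2]);
                if (dc + 1e-12 < std::max(excl[id], excl[id2])) continue;
                if (norm2(p - pos[id2]) < w2) { death = s; break; }
              }
            }
        if (death <= s) return false;
      }
      for (int c = 0; c < n_cond; ++c) {
        if (conds[c].type == 2) {
          double lim = conds[c].radius - half_w;
          if (lim < 0.0 || norm2(p) > lim * lim) hit_cond(c, s);
        } else if (pstep[c] <= s) {
          double rr = conds[c].radius + half_w;
          if (norm2(p - pcenter[c]) < rr * rr * TOL) hit_cond(c, s);
        }
      }
      return death > s;
    };

    Frame init;
    init.u = {1, 0, 0};
    init.v = {0, 1, 0};
    init.t = {0, 0, 1};

    int step = 0;
    bool alive = true;

    // ---- backward (leading / outside) segment ----
    if (n_b > 0) {
      Frame fb = init;
      int j = 0;
      for (size_t si = 0; si < bseg.size() && alive; ++si) {
        const Segment &sg = bseg[si];
        for (int m = 0; m < sg.n && alive; ++m) {
          ++j;
          double ct, st, phi;
          sample_bend(sg.a, rng, ct, st, phi);
          if (collect_bend) { bend_sum += ct; bend_sumsq += ct * ct; ++bend_n; }
          if (j == 1) {
            // bend at joint 0 between the first backward link and link 1
            Frame g = propagate(init, ct, st, phi);
            fb.t = -1.0 * g.t;
            fb.u = g.u;
            fb.v = cross(fb.t, fb.u);
          } else {
            fb = propagate(fb, ct, st, phi);
          }
          pos[j] = pos[j - 1] + sg.l * fb.t;
          contour[j] = contour[j - 1] - sg.l;
          excl[j] = sg.excl;
          fr_bwd[j] = fb;
          ++step;
          if (!check_joint(j, step)) { alive = false; break; }
          if (self_avoid) hash.insert(pos[j], j);
          for (int c : cond_at_bwd[j]) {
            Vec3 uh = rot_about(fb.u, fb.t, conds[c].gamma);
            Vec3 cc = pos[j] + (half_w + conds[c].radius) * uh;
            place_prot(c, cc, j, step, j);
          }
          if (death <= step) { alive = false; break; }
        }
      }
    }

    // ---- forward chain ----
    if (alive) {
      Frame ff = init;
      int j = 0;
      for (size_t si = 0; si < fseg.size() && alive; ++si) {
        const Segment &sg = fseg[si];
        for (int m = 0; m < sg.n && alive; ++m) {
          ++j;
          if (!(j == 1)) {
            double ct, st, phi;
            sample_bend(sg.a, rng, ct, st, phi);
            if (collect_bend) { bend_sum += ct; bend_sumsq += ct * ct; ++bend_n; }
            ff = propagate(ff, ct, st, phi);
          }  // link 1 lies along +z in the lab frame by convention
          int id = n_b + j;
          pos[id] = pos[id - 1] + sg.l * ff.t;
          contour[id] = contour[id - 1] + sg.l;
          excl[id] = sg.excl;
          fr_fwd[j] = ff;
          ++step;
          if (!check_joint(id, step)) { alive = false; break; }
          if (self_avoid) hash.insert(pos[id], id);
          for (int c : cond_at_fwd[j]) {
            Vec3 uh = rot_about(ff.u, ff.t, conds[c].gamma);
            Vec3 cc = pos[id] + (half_w + conds[c].radius) * uh;
            place_prot(c, cc, id, step, id);
          }
          if (death <= step) { alive = false; break; }
        }
      }
    }

    if (death < INF) ++n_disc; else ++n_complete;

    // ---- ensemble aliveness horizons ----
    int gmax_any = 0;
    for (int e = 0; e < n_ens; ++e) {
      int fe = death;
      for (int c : ens[e]) {
        if (viol[c] < fe) fe = viol[c];
        for (int c2 : ens[e])
          if (c < c2 && pairv[(size_t)c * n_cond + c2] < fe) fe = pairv[(size_t)c * n_cond + c2];
      }
      // alive at grid g iff step(joint rec[g] + eval_offset) < fe
      int g = 0;
      while (g < n_grid && n_b + rec[g] + eval_offset < fe) ++g;
      gmax[e] = g;  // number of alive grid points (prefix)
      if (g > gmax_any) gmax_any = g;
      Zdiff[(size_t)e * (n_grid + 1) + g] += 1.0;
    }

    // ---- criterion evaluation on the prefix that any ensemble still uses ----
    glooped_idx.clear();
    if (gmax_any > 0 && n_grp > 0) {
      for (int g = 0; g < gmax_any; ++g) {
        Vec3 rend = pos[(size_t)n_b + rec[g]];
        bool any = false;
        for (int gr = 0; gr < n_grp; ++gr) gval[(size_t)gr * n_grid + g] = 0.0;
        for (int k = 0; k < n_crit; ++k) {
          const Crit &cr = crits[k];
          Vec3 anchor = cr.anchor;
          Vec3 axis = cr.axis;
          if (cr.type == 1) {
            if (pstep[cr.cond] == INF) continue;
            anchor = pcenter[cr.cond];
            int lk = conds[cr.cond].link;
            Vec3 base = (lk > 0) ? pos[(size_t)n_b + lk] : pos[(size_t)(-lk)];
            Vec3 d = anchor - base;
            axis = (1.0 / std::sqrt(norm2(d))) * d;
          }
          Vec3 dr = rend - anchor;
          double r2 = norm2(dr);
          if (r2 < cr.rlo2 || r2 > cr.rhi2) continue;
          double cthr = dot(dr, axis) * cr.sign / std::sqrt(r2);
          if (cthr < cr.cosc) continue;
          for (int gr = 0; gr < n_grp; ++gr)
            for (int kk : groups[gr])
              if (kk == k) { gval[(size_t)gr * n_grid + g] += 1.0; any = true; }
        }
        if (any) glooped_idx.push_back(g);
      }
      // accumulate sparse looped events
      for (int g : glooped_idx) {
        for (int e = 0; e < n_ens; ++e) {
          if (g >= gmax[e]) continue;
          for (int gr = 0; gr < n_grp; ++gr) {
            double v = gval[(size_t)gr * n_grid + g];
            if (v > 0.0) {
              W[((size_t)e * n_grp + gr) * n_grid + g] += v;
              if (v >= 2.0) DUP[((size_t)e * n_grp + gr) * n_grid + g] += 1.0;
            }
          }
        }
      }
    }

    if (collect_r2) {
      for (int e = 0; e < n_ens; ++e)
        for (int g = 0; g < gmax[e]; ++g) {
          Vec3 dr = pos[(size_t)n_b + rec[g]] - pos[0];
          double r2 = norm2(dr);
          R2s[(size_t)e * n_grid + g] += r2;
          R4s[(size_t)e * n_grid + g] += r2 * r2;
        }
    }

    // ---- window moments ----
    for (int wi = 0; wi < n_win; ++wi) {
      const auto &items = wins[wi];
      int k = (int)items.size();
      double v[8];
      for (int it = 0; it < k; ++it) {
        int e = items[it][0], gr = items[it][1], lo = items[it][2], hi = items[it][3];
        int top = std::min(hi, gmax[e] - 1);
        double a = (top >= lo) ? (double)(top - lo + 1) : 0.0;
        double sv = 0.0;
        if (a > 0.0 && gr >= 0)
          for (int g : glooped_idx)
            if (g >= lo && g <= top) sv += gval[(size_t)gr * n_grid + g];
        v[2 * it] = sv;
        v[2 * it + 1] = a;
      }
      int k2 = 2 * k;
      ++winN[wi];
      for (int i1 = 0; i1 < k2; ++i1) {
        winS[wi][i1] += v[i1];
        for (int i2 = 0; i2 < k2; ++i2) winM[wi][(size_t)i1 * k2 + i2] += v[i1] * v[i2];
      }
    }

    // ---- optional single-chain trajectory return ----
    if (return_chain > 0 && ci == (long long)(return_chain - 1)) {
      int n_placed = (death == INF) ? n_tot : std::min(death - 1, n_tot);
      NumericMatrix jm(n_placed + 1, 3);
      NumericVector ctr(n_placed + 1);
      for (int id = 0; id <= n_placed; ++id) {
        jm(id, 0) = pos[id].x; jm(id, 1) = pos[id].y; jm(id, 2) = pos[id].z;
        ctr[id] = contour[id];
      }
      int nfw = std::max(0, std::min(n_f, n_placed - n_b));
      NumericMatrix um(nfw, 3), tm(nfw, 3);
      for (int j = 1; j <= nfw; ++j) {
        um(j - 1, 0) = fr_fwd[j].u.x; um(j - 1, 1) = fr_fwd[j].u.y; um(j - 1, 2) = fr_fwd[j].u.z;
        tm(j - 1, 0) = fr_fwd[j].t.x; tm(j - 1, 1) = fr_fwd[j].t.y; tm(j - 1, 2) = fr_fwd[j].t.z;
      }
      List pl(n_cond);
      for (int c = 0; c < n_cond; ++c) {
        if (pstep[c] < INF && conds[c].type != 2)
          pl[c] = NumericVector::create(pcenter[c].x, pcenter[c].y, pcenter[c].z);
        else
          pl[c] = R_NilValue;
      }
      chain_out = List::create(
          _["joints"] = jm, _["contour"] = ctr, _["u_fwd"] = um, _["t_fwd"] = tm,
          _["discarded"] = (death < INF), _["death_step"] = (death == INF) ? NA_INTEGER : death,
          _["n_backward"] = n_b, _["prot_centers"] = pl,
          _["viol_steps"] = IntegerVector(viol.begin(), viol.end()));
    }
  }

  // finalise Z from the difference representation: Z[e,g] = # chains with gmax > g
  NumericMatrix Z(n_ens, n_grid);
  for (int e = 0; e < n_ens; ++e) {
    double acc = 0.0;
    for (int g = n_grid; g >= 1; --g) {
      acc += Zdiff[(size_t)e * (n_grid + 1) + g];
      Z(e, g - 1) = acc;
    }
  }
  NumericVector Wv(W.begin(), W.end()), Dv(DUP.begin(), DUP.end());
  Wv.attr("dim") = IntegerVector::create(n_grid, n_grp, n_ens);
  Dv.attr("dim") = IntegerVector::create(n_grid, n_grp, n_ens);
  // note: stored flat as [(e*n_grp + gr)*n_grid + g]; reorder for R
  {
    NumericVector Wr((size_t)n_ens * n_grp * n_grid), Dr((size_t)n_ens * n_grp * n_grid);
    for (int e = 0; e < n_ens; ++e)
      for (int gr = 0; gr < n_grp; ++gr)
        for (int g = 0; g < n_grid; ++g) {
          size_t src = ((size_t)e * n_grp + gr) * n_grid + g;
          size_t dst = (size_t)e * n_grp * n_grid + (size_t)gr * n_grid + g;
          Wr[dst] = W[src];
          Dr[dst] = DUP[src];
        }
    Wv = Wr; Dv = Dr;
    Wv.attr("dim") = IntegerVector::create(n_grid, n_grp, n_ens);
    Dv.attr("dim") = IntegerVector::create(n_grid, n_grp, n_ens);
  }

  List winout(n_win);
  for (int i = 0; i < n_win; ++i) {
    int k2 = 2 * (int)wins[i].size();
    NumericMatrix M(k2, k2);
    for (int a = 0; a < k2; ++a)
      for (int b = 0; b < k2; ++b) M(a, b) = winM[i][(size_t)a * k2 + b];
    winout[i] = List::create(_["n"] = (double)winN[i],
                             _["S"] = NumericVector(winS[i].begin(), winS[i].end()),
                             _["M"] = M);
  }

  List out = List::create(
      _["Z"] = Z, _["W"] = Wv, _["dup"] = Dv,
      _["n_generated"] = (double)n_chains, _["n_discarded"] = (double)n_disc,
      _["n_complete"] = (double)n_complete,
      _["bend_sum"] = bend_sum, _["bend_sumsq"] = bend_sumsq, _["bend_n"] = (double)bend_n,
      _["windows"] = winout, _["chain"] = chain_out);
  if (collect_r2) {
    NumericMatrix R2m(n_ens, n_grid), R4m(n_ens, n_grid);
    for (int e = 0; e < n_ens; ++e)
      for (int g = 0; g < n_grid; ++g) {
        R2m(e, g) = R2s[(size_t)e * n_grid + g];
        R4m(e, g) = R4s[(size_t)e * n_grid + g];
      }
    out["R2"] = R2m;
    out["R4"] = R4m;
  }
  return out;
}
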