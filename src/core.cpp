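// Lattice-model compute core: chain projection onto the cubic lattice,
// reduced-model energy terms, and the replica-exchange Monte Carlo sampler.
// All randomness uses a self-contained xoshiro256** generator seeded from R
// so that runs are bit-reproducible independently of R's global RNG state.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
struct RNG {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
  double norm() {
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// --------------------------------------------------- vector-set index ----
struct VSet {
  std::vector<int> vx, vy, vz;
  std::vector<int> idx;   // (2*maxc+1)^3 lookup, 0 = not admissible, else 1-based id
  int maxc, dim, nv;
  explicit VSet(const IntegerMatrix &V) {
    nv = V.nrow();
    vx.resize(nv); vy.resize(nv); vz.resize(nv);
    maxc = 0;
    for (int i = 0; i < nv; ++i) {
      vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2);
      maxc = std::max(maxc, std::max(std::abs(vx[i]), std::max(std::abs(vy[i]), std::abs(vz[i]))));
    }
    dim = 2 * maxc + 1;
    idx.assign((size_t)dim * dim * dim, 0);
    for (int i = 0; i < nv; ++i)
      idx[key(vx[i], vy[i], vz[i])] = i + 1;
  }
  inline size_t key(int x, int y, int z) const {
    return ((size_t)(x + maxc) * dim + (y + maxc)) * dim + (z + maxc);
  }
  inline int id(int x, int y, int z) const {
    if (std::abs(x) > maxc || std::abs(y) > maxc || std::abs(z) > maxc) return 0;
    return idx[key(x, y, z)];
  }
  inline bool ok(int x, int y, int z) const { return id(x, y, z) != 0; }
};

// ------------------------------------------------------- force field -----
struct FF {
  double hardcore_ca, hardcore_cb;
  double r_rep, r_min, r_max, eps_rep;
  std::vector<double> eps;  // n_class x n_class, row-major
  int n_class;
  double hb_lo, hb_hi, hb_colin, e_hb, e_coop;
  double r13_lo, r13_step; std::vector<double> g13; std::vector<double> c13; // 3 x n13
  double r14_lo, r14_step; std::vector<double> g14; std::vector<double> c14; // 3 x n14
  int n13, n14;
  double w_contact, w_hbond, w_short, w_restraint;
};

static FF parse_ff(const List &par) {
  FF f;
  f.hardcore_ca = as<double>(par["hardcore_ca"]);
  f.hardcore_cb = as<double>(par["hardcore_cb"]);
  f.r_rep = as<double>(par["r_rep"]);
  f.r_min = as<double>(par["r_min"]);
  f.r_max = as<double>(par["r_max"]);
  f.eps_rep = as<double>(par["eps_rep"]);
  NumericMatrix e = par["eps"];
  f.n_class = e.nrow();
  f.eps.assign(f.n_class * f.n_class, 0.0);
  for (int i = 0; i < f.n_class; ++i)
    for (int j = 0; j < f.n_class; ++j) f.eps[i * f.n_class + j] = e(i, j);
  f.hb_lo = as<double>(par["hb_lo"]);
  f.hb_hi = as<double>(par["hb_hi"]);
  f.hb_colin = as<double>(par["hb_colin"]);
  f.e_hb = as<double>(par["e_hb"]);
  f.e_coop = as<double>(par["e_coop"]);
  f.r13_lo = as<double>(par["r13_lo"]);
  f.r13_step = as<double>(par["r13_step"]);
  f.g13 = as<std::vector<double> >(par["r13_gen"]);
  f.n13 = (int)f.g13.size();
  NumericMatrix c13 = par["r13_class"];  // 3 x n13 (H,E,C rows)
  f.c13.assign(3 * f.n13, 0.0);
  for (int r = 0; r < 3; ++r) for (int b = 0; b < f.n13; ++b) f.c13[r * f.n13 + b] = c13(r, b);
  f.r14_lo = as<double>(par["r14_lo"]);
  f.r14_step = as<double>(par["r14_step"]);
  f.g14 = as<std::vector<double> >(par["r14_gen"]);
  f.n14 = (int)f.g14.size();
  NumericMatrix c14 = par["r14_class"];
  f.c14.assign(3 * f.n14, 0.0);
  for (int r = 0; r < 3; ++r) for (int b = 0; b < f.n14; ++b) f.c14[r * f.n14 + b] = c14(r, b);
  NumericVector w = par["weights"];  // contact, hbond, short, restraint
  f.w_contact = w[0]; f.w_hbond = w[1]; f.w_short = w[2]; f.w_restraint = w[3];
  return f;
}

struct Restr { int i, j; double d0, tol, w; };

// Pseudo-atom construction: Cbeta 1.53 A from Calpha along the unit
// combination of the bond-bisector (outward) and out-of-plane directions;
// side-chain center at a per-residue-type distance along the same direction.
// Terminal residues copy the nearest interior residue's offsets.
static void pseudo_atoms(const std::vector<int> &ca, int N, double spacing,
                         const std::vector<double> &dsc,
                         std::vector<double> &cb, std::vector<double> &sc) {
  std::vector<double> dir(3 * N, 0.0);
  for (int i = 1; i < N - 1; ++i) {
    double b1[3], b2[3];
    for (int k = 0; k < 3; ++k) {
      b1[k] = (double)(ca[3 * i + k] - ca[3 * (i - 1) + k]);
      b2[k] = (double)(ca[3 * (i + 1) + k] - ca[3 * i + k]);
    }
    double n1 = std::sqrt(b1[0]*b1[0] + b1[1]*b1[1] + b1[2]*b1[2]);
    double n2 = std::sqrt(b2[0]*b2[0] + b2[1]*b2[1] + b2[2]*b2[2]);
    double u1[3], u2[3], nn[3], pp[3];
    for (int k = 0; k < 3; ++k) { u1[k] = b1[k] / n1; u2[k] = b2[k] / n2; }
    for (int k = 0; k < 3; ++k) nn[k] = u1[k] - u2[k];
    pp[0] = u1[1]*u2[2] - u1[2]*u2[1];
    pp[1] = u1[2]*u2[0] - u1[0]*u2[2];
    pp[2] = u1[0]*u2[1] - u1[1]*u2[0];
    double ln = std::sqrt(nn[0]*nn[0] + nn[1]*nn[1] + nn[2]*nn[2]);
    double lp = std::sqrt(pp[0]*pp[0] + pp[1]*pp[1] + pp[2]*pp[2]);
    double d[3];
    if (ln < 1e-9 && lp < 1e-9) {
      // collinear bonds: any perpendicular to u1
      d[0] = -u1[1]; d[1] = u1[0]; d[2] = 0.0;
      double l = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
      if (l < 1e-9) { d[0] = 0; d[1] = -u1[2]; d[2] = u1[1]; l = std::sqrt(d[1]*d[1] + d[2]*d[2]); }
      for (int k = 0; k < 3; ++k) d[k] /= l;
    } else {
      for (int k = 0; k < 3; ++k) {
        double a = ln > 1e-9 ? nn[k] / ln : 0.0;
        double b = lp > 1e-9 ? pp[k] / lp : 0.0;
        d[k] = 0.9 * a + 0.44 * b;   // out-of-plane component sets chirality
      }
      double l = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
      for (int k = 0; k < 3; ++k) d[k] /= l;
    }
    for (int k = 0; k < 3; ++k) dir[3 * i + k] = d[k];
  }
  if (N >= 2) {
    int src0 = (N > 2) ? 1 : -1, srcN = (N > 2) ? N - 2 : -1;
    if (src0 < 0) {
      // two-residue chain: perpendicular to the single bond
      double b[3];
      for (int k = 0; k < 3; ++k) b[k] = (double)(ca[3 + k] - ca[k]);
      double l = std::sqrt(b[0]*b[0] + b[1]*b[1] + b[2]*b[2]);
      double d[3] = { -b[1] / l, b[0] / l, 0.0 };
      double ld = std::sqrt(d[0]*d[0] + d[1]*d[1]);
      if (ld < 1e-9) { d[0] = 1; d[1] = 0; d[2] = 0; ld = 1; }
      for (int k = 0; k < 3; ++k) { dir[k] = d[k] / ld; dir[3 + k] = d[k] / ld; }
    } else {
      for (int k = 0; k < 3; ++k) {
        dir[k] = dir[3 * src0 + k];
        dir[3 * (N - 1) + k] = dir[3 * srcN + k];
      }
    }
  } else if (N == 1) {
    dir[2] = 1.0;
  }
  cb.assign(3 * N, 0.0); sc.assign(3 * N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) {
      double cak = ca[3 * i + k] * spacing;
      cb[3 * i + k] = cak + 1.53 * dir[3 * i + k];
      sc[3 * i + k] = cak + dsc[i] * dir[3 * i + k];
    }
}

static inline double dist3(const double *a, const double *b) {
  double dx = a[0]-b[0], dy = a[1]-b[1], dz = a[2]-b[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

static inline int clampi(int x, int lo, int hi) { return x < lo ? lo : (x > hi ? hi : x); }

// Full-energy evaluation. Returns +Inf total on hard-core violation.
// terms[0..5] = ev, contact, hbond, short_generic, short_seq, restraint (unweighted)
static double energy_eval(const std::vector<int> &ca, int N, double spacing,
                          const FF &f,
                          const std::vector<int> &cclass, const std::vector<int> &hec,
                          const std::vector<double> &dsc,
                          const std::vector<Restr> &restr,
                          double *terms) {
  const double INF = std::numeric_limits<double>::infinity();
  for (int t = 0; t < 6; ++t) terms[t] = 0.0;
  std::vector<double> cb, sc;
  pseudo_atoms(ca, N, spacing, dsc, cb, sc);
  std::vector<double> caA(3 * N);
  for (int i = 0; i < 3 * N; ++i) caA[i] = ca[i] * spacing;

  bool clash = false;
  double contact = 0.0;
  // pair scans: excluded volume (sep >= 2) and side-chain contacts (sep >= 3)
  for (int i = 0; i < N && !clash; ++i) {
    for (int j = i + 2; j < N; ++j) {
      double dca = dist3(&caA[3*i], &caA[3*j]);
      if (dca < f.hardcore_ca) { clash = true; break; }
      if (dist3(&cb[3*i], &cb[3*j]) < f.hardcore_cb) { clash = true; break; }
      if (j - i >= 3) {
        double r = dist3(&sc[3*i], &sc[3*j]);
        if (r < f.r_rep) contact += f.eps_rep;
        else if (r >= f.r_min && r <= f.r_max)
          contact -= f.eps[cclass[i] * f.n_class + cclass[j]];
      }
    }
  }
  if (clash) { terms[0] = INF; return INF; }
  terms[1] = contact;

  // hydrogen bonds: Calpha pairs, sep >= 3, distance window, bond direction
  // near-perpendicular to both local chain tangents; cooperativity for bond
  // pairs adjacent in both partners.
  std::vector<double> tang(3 * N, 0.0);
  for (int i = 0; i < N; ++i) {
    int a = i > 0 ? i - 1 : i, b = i < N - 1 ? i + 1 : i;
    double t[3], l = 0;
    for (int k = 0; k < 3; ++k) { t[k] = caA[3*b+k] - caA[3*a+k]; l += t[k]*t[k]; }
    l = std::sqrt(l);
    if (l > 1e-9) for (int k = 0; k < 3; ++k) tang[3*i+k] = t[k] / l;
  }
  std::vector<std::pair<int,int> > bonds;
  std::vector<unsigned char> isb((size_t)N * N, 0);
  for (int i = 0; i < N; ++i)
    for (int j = i + 3; j < N; ++j) {
      double d = dist3(&caA[3*i], &caA[3*j]);
      if (d < f.hb_lo || d > f.hb_hi) continue;
      double u[3];
      for (int k = 0; k < 3; ++k) u[k] = (caA[3*j+k] - caA[3*i+k]) / d;
      double ci = std::fabs(u[0]*tang[3*i] + u[1]*tang[3*i+1] + u[2]*tang[3*i+2]);
      double cj = std::fabs(u[0]*tang[3*j] + u[1]*tang[3*j+1] + u[2]*tang[3*j+2]);
      if (ci <= f.hb_colin && cj <= f.hb_colin) {
        bonds.push_back(std::make_pair(i, j));
        isb[(size_t)i * N + j] = 1;
      }
    }
  double ehb = -f.e_hb * (double)bonds.size();
  int ncoop = 0;
  for (size_t b = 0; b < bonds.size(); ++b) {
    int i = bonds[b].first, j = bonds[b].second;
    if (i + 1 < N && j + 1 < N && isb[(size_t)(i+1) * N + (j+1)]) ++ncoop;
    if (i + 1 < N && j - 1 >= 0 && i + 1 < j - 1 && isb[(size_t)(i+1) * N + (j-1)]) ++ncoop;
  }
  ehb -= f.e_coop * (double)ncoop;
  terms[2] = ehb;

  // short-range windows
  double sg = 0.0, ss = 0.0;
  for (int i = 0; i + 2 < N; ++i) {
    double r13 = dist3(&caA[3*i], &caA[3*(i+2)]);
    int b = clampi((int)std::floor((r13 - f.r13_lo) / f.r13_step), 0, f.n13 - 1);
    sg += f.g13[b];
    ss += f.c13[hec[i + 1] * f.n13 + b];
  }
  for (int i = 0; i + 3 < N; ++i) {
    double r14 = dist3(&caA[3*i], &caA[3*(i+3)]);
    double b1[3], b2[3], b3[3];
    for (int k = 0; k < 3; ++k) {
      b1[k] = caA[3*(i+1)+k] - caA[3*i+k];
      b2[k] = caA[3*(i+2)+k] - caA[3*(i+1)+k];
      b3[k] = caA[3*(i+3)+k] - caA[3*(i+2)+k];
    }
    double cx = b2[1]*b3[2] - b2[2]*b3[1];
    double cy = b2[2]*b3[0] - b2[0]*b3[2];
    double cz = b2[0]*b3[1] - b2[1]*b3[0];
    double trip = b1[0]*cx + b1[1]*cy + b1[2]*cz;
    double s14 = (trip >= 0 ? r14 : -r14);
    int b = clampi((int)std::floor((s14 - f.r14_lo) / f.r14_step), 0, f.n14 - 1);
    sg += f.g14[b];
    ss += f.c14[hec[i + 1] * f.n14 + b];
  }
  terms[3] = sg; terms[4] = ss;

  double er = 0.0;
  for (size_t r = 0; r < restr.size(); ++r) {
    double d = dist3(&caA[3 * restr[r].i], &caA[3 * restr[r].j]);
    double ex = std::fabs(d - restr[r].d0) - restr[r].tol;
    if (ex > 0) er += restr[r].w * ex * ex;
  }
  terms[5] = er;

  return f.w_contact * contact + f.w_hbond * ehb + f.w_short * (sg + ss) + f.w_restraint * er;
}

static std::vector<Restr> parse_restr(const NumericMatrix &R) {
  std::vector<Restr> v;
  for (int r = 0; r < R.nrow(); ++r) {
    Restr x;
    x.i = (int)R(r, 0) - 1; x.j = (int)R(r, 1) - 1;
    x.d0 = R(r, 2); x.tol = R(r, 3); x.w = R(r, 4);
    v.push_back(x);
  }
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_energy(IntegerMatrix ca, double spacing, List par,
                         IntegerVector cclass, IntegerVector hec,
                         NumericVector dsc, NumericMatrix restraints) {
  int N = ca.nrow();
  std::vector<int> c(3 * N);
  for (int i = 0; i < N; ++i) for (int k = 0; k < 3; ++k) c[3*i+k] = ca(i, k);
  FF f = parse_ff(par);
  std::vector<int> cc = as<std::vector<int> >(cclass);
  std::vector<int> hh = as<std::vector<int> >(hec);
  std::vector<double> ds = as<std::vector<double> >(dsc);
  std::vector<Restr> rr = parse_restr(restraints);
  double terms[6];
  double tot = energy_eval(c, N, spacing, f, cc, hh, ds, rr, terms);
  NumericVector out(7);
  out[0] = terms[0]; out[1] = terms[1]; out[2] = terms[2];
  out[3] = terms[3]; out[4] = terms[4]; out[5] = terms[5]; out[6] = tot;
  out.names() = CharacterVector::create("excluded_volume", "contact", "hbond",
                                        "short_generic", "short_seq", "restraint", "total");
  return out;
}

// [[Rcpp::export]]
List cpp_pseudoatoms(IntegerMatrix ca, double spacing, NumericVector dsc) {
  int N = ca.nrow();
  std::vector<int> c(3 * N);
  for (int i = 0; i < N; ++i) for (int k = 0; k < 3; ++k) c[3*i+k] = ca(i, k);
  std::vector<double> ds = as<std::vector<double> >(dsc);
  std::vector<double> cb, sc;
  pseudo_atoms(c, N, spacing, ds, cb, sc);
  NumericMatrix CB(N, 3), SC(N, 3);
  for (int i = 0; i < N; ++i) for (int k = 0; k < 3; ++k) {
    CB(i, k) = cb[3*i+k]; SC(i, k) = sc[3*i+k];
  }
  NumericMatrix MID(std::max(N - 1, 0), 3);
  for (int i = 0; i + 1 < N; ++i)
    for (int k = 0; k < 3; ++k)
      MID(i, k) = 0.5 * (c[3*i+k] + c[3*(i+1)+k]) * spacing;
  return List::create(_["cb"] = CB, _["sc"] = SC, _["mid"] = MID);
}

// ------------------------------------------------------- projection ------
// Greedy bond assignment with one-bond lookahead over the top-k candidates.
// targets are in lattice units; optional fixed previous anchor and next
// anchor (closure). Returns ok=false when the closure bond is inadmissible.
struct ProjResult { std::vector<int> pos; bool ok; double sumsq; };

static ProjResult project_greedy(const std::vector<double> &tgt, int N,
                                 const VSet &vs,
                                 const int *prev_anchor, const int *next_anchor,
                                 int topk) {
  ProjResult res; res.ok = true; res.sumsq = 0.0;
  res.pos.assign(3 * N, 0);
  int cur[3];
  int start = 0;
  if (prev_anchor) {
    cur[0] = prev_anchor[0]; cur[1] = prev_anchor[1]; cur[2] = prev_anchor[2];
  } else {
    for (int k = 0; k < 3; ++k) {
      cur[k] = (int)std::floor(tgt[k] + 0.5);
      res.pos[k] = cur[k];
      double d = cur[k] - tgt[k];
      res.sumsq += d * d;
    }
    start = 1;
  }
  int nv = vs.nv;
  std::vector<double> err(nv);
  std::vector<int> ord(topk);
  for (int i = start; i < N; ++i) {
    bool last = (i == N - 1);
    // candidate errors for this step
    for (int v = 0; v < nv; ++v) {
      double dx = cur[0] + vs.vx[v] - tgt[3*i];
      double dy = cur[1] + vs.vy[v] - tgt[3*i+1];
      double dz = cur[2] + vs.vz[v] - tgt[3*i+2];
      err[v] = dx*dx + dy*dy + dz*dz;
      if (last && next_anchor) {
        int gx = next_anchor[0] - (cur[0] + vs.vx[v]);
        int gy = next_anchor[1] - (cur[1] + vs.vy[v]);
        int gz = next_anchor[2] - (cur[2] + vs.vz[v]);
        if (!vs.ok(gx, gy, gz)) err[v] = std::numeric_limits<double>::infinity();
      }
    }
    int best = -1;
    if (last || topk <= 1) {
      double eb = std::numeric_limits<double>::infinity();
      for (int v = 0; v < nv; ++v) if (err[v] < eb) { eb = err[v]; best = v; }
      if (best < 0 || !std::isfinite(err[best])) { res.ok = false; return res; }
    } else {
      // top-k by immediate error (partial selection)
      double worst = -1.0; int nw = 0;
      for (int t = 0; t < topk; ++t) ord[t] = -1;
      for (int v = 0; v < nv; ++v) {
        if (nw < topk) {
          ord[nw++] = v;
          if (err[v] > worst) worst = err[v];
        } else if (err[v] < worst) {
          // replace current worst
          int wi = 0; double wv = -1;
          for (int t = 0; t < topk; ++t) if (err[ord[t]] > wv) { wv = err[ord[t]]; wi = t; }
          ord[wi] = v;
          wv = -1;
          for (int t = 0; t < topk; ++t) if (err[ord[t]] > wv) wv = err[ord[t]];
          worst = wv;
        }
      }
      double eb = std::numeric_limits<double>::infinity();
      for (int t = 0; t < nw; ++t) {
        int v = ord[t];
        double la = 0.0;
        // lookahead: best admissible continuation toward the next target
        double lb = std::numeric_limits<double>::infinity();
        double nx = cur[0] + vs.vx[v], ny = cur[1] + vs.vy[v], nz = cur[2] + vs.vz[v];
        for (int u = 0; u < nv; ++u) {
          double dx = nx + vs.vx[u] - tgt[3*(i+1)];
          double dy = ny + vs.vy[u] - tgt[3*(i+1)+1];
          double dz = nz + vs.vz[u] - tgt[3*(i+1)+2];
          double e2 = dx*dx + dy*dy + dz*dz;
          if (e2 < lb) lb = e2;
        }
        la = err[v] + lb;
        if (la < eb) { eb = la; best = v; }
      }
      if (best < 0) { res.ok = false; return res; }
    }
    cur[0] += vs.vx[best]; cur[1] += vs.vy[best]; cur[2] += vs.vz[best];
    res.pos[3*i] = cur[0]; res.pos[3*i+1] = cur[1]; res.pos[3*i+2] = cur[2];
    res.sumsq += err[best] >= std::numeric_limits<double>::infinity() ? 0 :
      ( (cur[0]-tgt[3*i])*(cur[0]-tgt[3*i]) + (cur[1]-tgt[3*i+1])*(cur[1]-tgt[3*i+1]) +
        (cur[2]-tgt[3*i+2])*(cur[2]-tgt[3*i+2]) );
  }
  return res;
}

// [[Rcpp::export]]
List cpp_project_segment(NumericMatrix target_lu, IntegerMatrix V,
                         IntegerVector prev_anchor, IntegerVector next_anchor,
                         int topk) {
  int N = target_lu.nrow();
  std::vector<double> t(3 * N);
  for (int i = 0; i < N; ++i) for (int k = 0; k < 3; ++k) t[3*i+k] = target_lu(i, k);
  VSet vs(V);
  int pa[3], na[3];
  const int *pp = 0, *np = 0;
  if (prev_anchor.size() == 3) { for (int k = 0; k < 3; ++k) pa[k] = prev_anchor[k]; pp = pa; }
  if (next_anchor.size() == 3) { for (int k = 0; k < 3; ++k) na[k] = next_anchor[k]; np = na; }
  ProjResult r = project_greedy(t, N, vs, pp, np, topk);
  IntegerMatrix P(N, 3);
  for (int i = 0; i < N; ++i) for (int k = 0; k < 3; ++k) P(i, k) = r.pos[3*i+k];
  return List::create(_["pos"] = P, _["ok"] = r.ok, _["sumsq"] = r.sumsq);
}

// ------------------------------------------------------------- REMC ------
struct MCSystem {
  int N;
  double spacing;
  FF f;
  std::vector<int> cclass, hec;
  std::vector<double> dsc;
  std::vector<Restr> restr;
  const VSet *vs;
};

static bool bond_ok(const MCSystem &S, const std::vector<int> &c, int a, int b) {
  return S.vs->ok(c[3*b] - c[3*a], c[3*b+1] - c[3*a+1], c[3*b+2] - c[3*a+2]);
}

// one attempted move; returns true if accepted, updates conf and E
static bool attempt_move(const MCSystem &S, std::vector<int> &conf, double &E,
                         double T, RNG &rng, const double *mw, double ls_sigma,
                         int topk) {
  int N = S.N;
  std::vector<int> prop = conf;
  double u = rng.unif();
  int kind;
  if (u < mw[0]) kind = 0;
  else if (u < mw[0] + mw[1]) kind = 1;
  else if (u < mw[0] + mw[1] + mw[2]) kind = 2;
  else if (u < mw[0] + mw[1] + mw[2] + mw[3]) kind = 3;
  else kind = 4;

  if (kind <= 3) {
    // rigid lattice shift of 1 (single CA) to 4 consecutive residues
    int len = (kind == 0) ? 1 : kind + 1;   // 1,2,3,4
    if (len > N) return false;
    int s = rng.below(N - len + 1);
    int d[3];
    do {
      d[0] = rng.below(3) - 1; d[1] = rng.below(3) - 1; d[2] = rng.below(3) - 1;
    } while (d[0] == 0 && d[1] == 0 && d[2] == 0);
    for (int i = s; i < s + len; ++i)
      for (int k = 0; k < 3; ++k) prop[3*i+k] += d[k];
    if (s > 0 && !bond_ok(S, prop, s - 1, s)) return false;
    if (s + len < N && !bond_ok(S, prop, s + len - 1, s + len)) return false;
  } else {
    // small rigid displacement of a 4-22 residue fragment, re-projected
    int maxlen = std::min(22, N);
    if (maxlen < 4) return false;
    int len = 4 + rng.below(maxlen - 4 + 1);
    int s = rng.below(N - len + 1);
    double t[3] = { rng.norm() * ls_sigma, rng.norm() * ls_sigma, rng.norm() * ls_sigma };
    std::vector<double> tgt(3 * len);
    for (int i = 0; i < len; ++i)
      for (int k = 0; k < 3; ++k)
        tgt[3*i+k] = conf[3*(s+i)+k] + t[k] / S.spacing;
    int pa[3], na[3];
    const int *pp = 0, *np = 0;
    if (s > 0) { for (int k = 0; k < 3; ++k) pa[k] = conf[3*(s-1)+k]; pp = pa; }
    if (s + len < N) { for (int k = 0; k < 3; ++k) na[k] = conf[3*(s+len)+k]; np = na; }
    ProjResult pr = project_greedy(tgt, len, *S.vs, pp, np, topk);
    if (!pr.ok) return false;
    for (int i = 0; i < len; ++i)
      for (int k = 0; k < 3; ++k) prop[3*(s+i)+k] = pr.pos[3*i+k];
    if (!pp && len < N && !bond_ok(S, prop, len - 1 + s, len + s)) return false;
  }

  double terms[6];
  double Enew = energy_eval(prop, N, S.spacing, S.f, S.cclass, S.hec, S.dsc, S.restr, terms);
  if (!std::isfinite(Enew)) return false;
  double dE = Enew - E;
  bool acc = (dE <= 0) || (!std::isfinite(E)) || (T > 0 && rng.unif() < std::exp(-dE / T));
  if (acc) { conf.swap(prop); E = Enew; }
  return acc;
}

// [[Rcpp::export]]
List cpp_run_remc(IntegerMatrix ca0, double spacing, List par,
                  IntegerVector cclass, IntegerVector hec, NumericVector dsc,
                  NumericMatrix restraints, IntegerMatrix V,
                  NumericVector temps0, double anneal_factor,
                  int n_macrocycles, int steps_per_cycle, int swap_interval,
                  NumericVector move_weights, double ls_sigma, int topk,
                  double seed) {
  int N = ca0.nrow();
  int R = temps0.size();
  MCSystem S;
  S.N = N; S.spacing = spacing; S.f = parse_ff(par);
  S.cclass = as<std::vector<int> >(cclass);
  S.hec = as<std::vector<int> >(hec);
  S.dsc = as<std::vector<double> >(dsc);
  S.restr = parse_restr(restraints);
  VSet vs(V);
  S.vs = &vs;
  double mw[5];
  for (int k = 0; k < 5; ++k) mw[k] = move_weights[k];

  std::vector<std::vector<int> > conf(R, std::vector<int>(3 * N));
  for (int r = 0; r < R; ++r)
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) conf[r][3*i+k] = ca0(i, k);
  std::vector<double> temps(R);
  for (int r = 0; r < R; ++r) temps[r] = temps0[r];
  std::vector<double> E(R);
  double terms[6];
  for (int r = 0; r < R; ++r)
    E[r] = energy_eval(conf[r], N, spacing, S.f, S.cclass, S.hec, S.dsc, S.restr, terms);

  std::vector<RNG> rng;
  for (int r = 0; r < R; ++r)
    rng.push_back(RNG((uint64_t)seed * 1000003ULL + 17ULL * (uint64_t)r + 1ULL));
  RNG swap_rng((uint64_t)seed * 1000003ULL + 999983ULL);

  List snaps(n_macrocycles);
  NumericVector snapE(n_macrocycles);
  IntegerVector snapC(n_macrocycles);
  long long n_att = 0, n_acc = 0, n_swap_att = 0, n_swap_acc = 0;
  int parity = 0;

  for (int mc = 0; mc < n_macrocycles; ++mc) {
    for (int sw = 0; sw < steps_per_cycle; ++sw) {
      for (int r = 0; r < R; ++r) {
        for (int m = 0; m < N; ++m) {
          ++n_att;
          if (attempt_move(S, conf[r], E[r], temps[r], rng[r], mw, ls_sigma, topk)) ++n_acc;
        }
      }
      if (swap_interval > 0 && ((sw + 1) % swap_interval == 0) && R > 1) {
        for (int p = parity; p + 1 < R; p += 2) {
          ++n_swap_att;
          double delta = (1.0 / temps[p] - 1.0 / temps[p + 1]) * (E[p] - E[p + 1]);
          if (delta >= 0 || swap_rng.unif() < std::exp(delta)) {
            conf[p].swap(conf[p + 1]);
            std::swap(E[p], E[p + 1]);
            ++n_swap_acc;
          }
        }
        parity = 1 - parity;
      }
    }
    // snapshot from the lowest-temperature replica (slot 0; ladder ascending)
    IntegerMatrix snap(N, 3);
    for (int i = 0; i < N; ++i) for (int k = 0; k < 3; ++k) snap(i, k) = conf[0][3*i+k];
    snaps[mc] = snap;
    snapE[mc] = E[0];
    snapC[mc] = mc + 1;
    for (int r = 0; r < R; ++r) temps[r] *= anneal_factor;
  }

  return List::create(
    _["snapshots"] = snaps, _["energies"] = snapE, _["cycles"] = snapC,
    _["acc_rate"] = n_att > 0 ? (double)n_acc / (double)n_att : NA_REAL,
    _["swap_rate"] = n_swap_att > 0 ? (double)n_swap_acc / (double)n_swap_att : NA_REAL,
    _["final_temps"] = NumericVector(temps.begin(), temps.end()));
}

// [[Rcpp::export]]
List cpp_mc_steps(IntegerMatrix ca0, double spacing, List par,
                  IntegerVector cclass, IntegerVector hec, NumericVector dsc,
                  NumericMatrix restraints, IntegerMatrix V,
                  double temperature, int n_steps,
                  NumericVector move_weights, double ls_sigma, int topk,
                  double seed) {
  int N = ca0.nrow();
  MCSystem S;
  S.N = N; S.spacing = spacing; S.f = parse_ff(par);
  S.cclass = as<std::vector<int> >(cclass);
  S.hec = as<std::vector<int> >(hec);
  S.dsc = as<std::vector<double> >(dsc);
  S.restr = parse_restr(restraints);
  VSet vs(V);
  S.vs = &vs;
  double mw[5];
  for (int k = 0; k < 5; ++k) mw[k] = move_weights[k];
  std::vector<int> conf(3 * N);
  for (int i = 0; i < N; ++i) for (int k = 0; k < 3; ++k) conf[3*i+k] = ca0(i, k);
  double terms[6];
  double E = energy_eval(conf, N, spacing, S.f, S.cclass, S.hec, S.dsc, S.restr, terms);
  RNG rng((uint64_t)seed);
  int n_acc = 0;
  bool last = false;
  for (int m = 0; m < n_steps; ++m) {
    last = attempt_move(S, conf, E, temperature, rng, mw, ls_sigma, topk);
    if (last) ++n_acc;
  }
  IntegerMatrix out(N, 3);
  for (int i = 0; i < N; ++i) for (int k = 0; k < 3; ++k) out(i, k) = conf[3*i+k];
  return List::create(_["ca"] = out, _["energy"] = E, _["n_accepted"] = n_acc,
                      _["last_accepted"] = last);
}
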