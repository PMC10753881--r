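// Kern-Frenkel patchy-particle Monte Carlo engine: NVT sampling with
// rototranslation + aggregation-volume-bias (AVB) moves, Gibbs-ensemble
// coexistence, energy/bond-graph evaluation.
//
// Reduced units: energy in epsilon, length in sigma, k_B = 1.
// Orientations are unit quaternions (w, x, y, z); body-frame patch vectors
// are rotated and cached per particle.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <functional>

using namespace Rcpp;

typedef std::array<double, 3> Vec3;
typedef std::array<double, 4> Quat;

static inline Vec3 rotate(const Quat &q, const Vec3 &v) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  Vec3 r;
  r[0] = (1 - 2 * (y * y + z * z)) * v[0] + 2 * (x * y - w * z) * v[1] +
         2 * (x * z + w * y) * v[2];
  r[1] = 2 * (x * y + w * z) * v[0] + (1 - 2 * (x * x + z * z)) * v[1] +
         2 * (y * z - w * x) * v[2];
  r[2] = 2 * (x * z - w * y) * v[0] + 2 * (y * z + w * x) * v[1] +
         (1 - 2 * (x * x + y * y)) * v[2];
  return r;
}

static inline Quat qmul(const Quat &a, const Quat &b) {
  Quat q;
  q[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  q[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  q[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  q[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
  return q;
}

static inline void qnormalize(Quat &q) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= n;
}

static inline Quat axis_angle(const Vec3 &axis, double ang) {
  double s = std::sin(ang / 2);
  Quat q = {std::cos(ang / 2), axis[0] * s, axis[1] * s, axis[2] * s};
  return q;
}

struct MixData {
  int nsp, np, ncol;
  double eps, delta, cosmax, sigma;
  std::vector<std::vector<Vec3>> patchv;   // species -> body patch vectors
  std::vector<std::vector<int>> patchc;    // species -> 0-based colors
  std::vector<std::vector<int>> ups;       // color compatibility
  std::vector<std::vector<int>> npairs;    // compatible pairs per sp pair
};

static MixData parse_mix(const List &mix) {
  MixData m;
  List pv = mix["patchv"], pc = mix["patchc"];
  m.nsp = pv.size();
  m.eps = as<double>(mix["eps"]);
  m.delta = as<double>(mix["delta"]);
  m.cosmax = as<double>(mix["cosmax"]);
  m.sigma = as<double>(mix["sigma"]);
  IntegerMatrix U = mix["ups"];
  m.ncol = U.nrow();
  m.ups.assign(m.ncol, std::vector<int>(m.ncol));
  for (int i = 0; i < m.ncol; ++i)
    for (int j = 0; j < m.ncol; ++j) m.ups[i][j] = U(i, j);
  for (int s = 0; s < m.nsp; ++s) {
    NumericMatrix V = pv[s];
    IntegerVector C = pc[s];
    m.np = V.nrow();
    std::vector<Vec3> vs(m.np);
    std::vector<int> cs(m.np);
    for (int a = 0; a < m.np; ++a) {
      vs[a] = {V(a, 0), V(a, 1), V(a, 2)};
      cs[a] = C[a] - 1;
    }
    m.patchv.push_back(vs);
    m.patchc.push_back(cs);
  }
  m.npairs.assign(m.nsp, std::vector<int>(m.nsp, 0));
  for (int s1 = 0; s1 < m.nsp; ++s1)
    for (int s2 = 0; s2 < m.nsp; ++s2) {
      int c = 0;
      for (int a = 0; a < m.np; ++a)
        for (int b = 0; b < m.np; ++b)
          if (m.ups[m.patchc[s1][a]][m.patchc[s2][b]]) ++c;
      m.npairs[s1][s2] = c;
    }
  return m;
}

// One simulation box with a linked-cell list (falls back to all pairs when
// the box holds fewer than 3 cells per dimension).
struct Box {
  const MixData *mix;
  double L;
  int N;
  std::vector<Vec3> pos;
  std::vector<Quat> quat;
  std::vector<int> sp;                    // 0-based species
  std::vector<std::vector<Vec3>> pw;      // world-frame patch vectors
  // cell list
  int nc;
  double cellw;
  std::vector<int> head, nxt, cellof;

  void init_pw() {
    pw.assign(N, std::vector<Vec3>(mix->np));
    for (int i = 0; i < N; ++i) update_pw(i);
  }
  void update_pw(int i) {
    for (int a = 0; a < mix->np; ++a)
      pw[i][a] = rotate(quat[i], mix->patchv[sp[i]][a]);
  }
  int cell_index(const Vec3 &p) const {
    int cx = (int)std::floor(p[0] / cellw); if (cx >= nc) cx = nc - 1; if (cx < 0) cx = 0;
    int cy = (int)std::floor(p[1] / cellw); if (cy >= nc) cy = nc - 1; if (cy < 0) cy = 0;
    int cz = (int)std::floor(p[2] / cellw); if (cz >= nc) cz = nc - 1; if (cz < 0) cz = 0;
    return (cx * nc + cy) * nc + cz;
  }
  void build_cells() {
    double rc = mix->sigma + mix->delta;
    nc = (int)std::floor(L / rc);
    if (nc < 3) { nc = 0; return; }
    cellw = L / nc;
    head.assign(nc * nc * nc, -1);
    nxt.assign(N, -1);
    cellof.assign(N, -1);
    for (int i = 0; i < N; ++i) cell_insert(i);
  }
  void cell_insert(int i) {
    if (nc == 0) return;
    int c = cell_index(pos[i]);
    cellof[i] = c;
    nxt[i] = head[c];
    head[c] = i;
  }
  void cell_remove(int i) {
    if (nc == 0) return;
    int c = cellof[i];
    int j = head[c];
    if (j == i) { head[c] = nxt[i]; return; }
    while (nxt[j] != i) j = nxt[j];
    nxt[j] = nxt[i];
  }
  void wrap(Vec3 &p) const {
    for (int k = 0; k < 3; ++k) {
      p[k] -= L * std::floor(p[k] / L);
      if (p[k] >= L) p[k] -= L;
    }
  }
  Vec3 minimage(const Vec3 &a, const Vec3 &b) const {
    Vec3 d;
    for (int k = 0; k < 3; ++k) {
      d[k] = b[k] - a[k];
      d[k] -= L * std::round(d[k] / L);
    }
    return d;
  }

  // Pair interaction: returns 0 none, 1 bond, 2 overlap; fills patches.
  int pair_state(int i, const Vec3 &pi, const std::vector<Vec3> &pwi,
                 int si, int j, int *pa, int *pb) const {
    Vec3 d = minimage(pi, pos[j]);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    double s = mix->sigma, rc = s + mix->delta;
    if (r2 < s * s) return 2;
    if (r2 > rc * rc) return 0;
    double r = std::sqrt(r2);
    Vec3 rh = {d[0] / r, d[1] / r, d[2] / r};
    double best = -1e9;
    int ba = -1, bb = -1;
    const std::vector<int> &ci = mix->patchc[si];
    const std::vector<int> &cj = mix->patchc[sp[j]];
    for (int a = 0; a < mix->np; ++a) {
      double c1 = pwi[a][0] * rh[0] + pwi[a][1] * rh[1] + pwi[a][2] * rh[2];
      if (c1 < mix->cosmax) continue;
      for (int b = 0; b < mix->np; ++b) {
        if (!mix->ups[ci[a]][cj[b]]) continue;
        double c2 = -(pw[j][b][0] * rh[0] + pw[j][b][1] * rh[1] +
                      pw[j][b][2] * rh[2]);
        if (c2 < mix->cosmax) continue;
        if (c1 + c2 > best) { best = c1 + c2; ba = a; bb = b; }
      }
    }
    if (ba < 0) return 0;
    *pa = ba; *pb = bb;
    return 1;
  }

  // Energy of particle i at trial pose; +inf (HUGE) when overlapping.
  double particle_energy(int i, const Vec3 &pi,
                         const std::vector<Vec3> &pwi, int si) const {
    double e = 0;
    int pa, pb;
    if (nc == 0) {
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        int st = pair_state(i, pi, pwi, si, j, &pa, &pb);
        if (st == 2) return 1e30;
        if (st == 1) e -= mix->eps;
      }
      return e;
    }
    int cx = (int)std::floor(pi[0] / cellw);
    int cy = (int)std::floor(pi[1] / cellw);
    int cz = (int)std::floor(pi[2] / cellw);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int c = (((cx + dx + nc) % nc) * nc + (cy + dy + nc) % nc) * nc +
                  (cz + dz + nc) % nc;
          for (int j = head[c]; j >= 0; j = nxt[j]) {
            if (j == i) continue;
            int st = pair_state(i, pi, pwi, si, j, &pa, &pb);
            if (st == 2) return 1e30;
            if (st == 1) e -= mix->eps;
          }
        }
    return e;
  }

  // Bonded neighbours of particle i (current pose).
  void bonded_neighbors(int i, std::vector<int> &out) const {
    out.clear();
    int pa, pb;
    if (nc == 0) {
      for (int j = 0; j < N; ++j)
        if (j != i && pair_state(i, pos[i], pw[i], sp[i], j, &pa, &pb) == 1)
          out.push_back(j);
      return;
    }
    int cx = (int)std::floor(pos[i][0] / cellw);
    int cy = (int)std::floor(pos[i][1] / cellw);
    int cz = (int)std::floor(pos[i][2] / cellw);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int c = (((cx + dx + nc) % nc) * nc + (cy + dy + nc) % nc) * nc +
                  (cz + dz + nc) % nc;
          for (int j = head[c]; j >= 0; j = nxt[j])
            if (j != i &&
                pair_state(i, pos[i], pw[i], sp[i], j, &pa, &pb) == 1)
              out.push_back(j);
        }
  }

  double total_energy(std::vector<std::array<int, 4>> *edges,
                      bool *overlap) const {
    double e = 0;
    *overlap = false;
    int pa, pb;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        int st = pair_state(i, pos[i], pw[i], sp[i], j, &pa, &pb);
        if (st == 2) { *overlap = true; return 1e30; }
        if (st == 1) {
          e -= mix->eps;
          if (edges) edges->push_back({i, pa, j, pb});
        }
      }
    return e;
  }
};

struct Rng {
  std::mt19937_64 gen;
  std::uniform_real_distribution<double> u01;
  Rng(uint64_t seed) : gen(seed), u01(0.0, 1.0) {}
  double u() { return u01(gen); }
  int ui(int n) { return (int)(u() * n) % n; }
  Vec3 unit_vec() {
    double z = 2 * u() - 1, phi = 2 * M_PI * u();
    double r = std::sqrt(1 - z * z);
    Vec3 v = {r * std::cos(phi), r * std::sin(phi), z};
    return v;
  }
  Quat random_quat() {
    double u1 = u(), u2 = u(), u3 = u();
    Quat q = {std::sqrt(1 - u1) * std::sin(2 * M_PI * u2),
              std::sqrt(1 - u1) * std::cos(2 * M_PI * u2),
              std::sqrt(u1) * std::sin(2 * M_PI * u3),
              std::sqrt(u1) * std::cos(2 * M_PI * u3)};
    return q;
  }
  // unit vector uniform in the cone of half-angle acos(cmin) about axis
  Vec3 cone_vec(const Vec3 &axis, double cmin) {
    double c = cmin + (1 - cmin) * u();
    double s = std::sqrt(1 - c * c), phi = 2 * M_PI * u();
    // build orthonormal frame around axis
    Vec3 a = axis, e1, e2;
    if (std::fabs(a[0]) < 0.9) e1 = {1, 0, 0}; else e1 = {0, 1, 0};
    // e1 = normalize(e1 - (e1.a) a)
    double d = e1[0] * a[0] + e1[1] * a[1] + e1[2] * a[2];
    for (int k = 0; k < 3; ++k) e1[k] -= d * a[k];
    double n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    for (int k = 0; k < 3; ++k) e1[k] /= n;
    e2 = {a[1] * e1[2] - a[2] * e1[1], a[2] * e1[0] - a[0] * e1[2],
          a[0] * e1[1] - a[1] * e1[0]};
    Vec3 v;
    for (int k = 0; k < 3; ++k)
      v[k] = c * a[k] + s * (std::cos(phi) * e1[k] + std::sin(phi) * e2[k]);
    return v;
  }
};

// Quaternion taking body vector u to world direction d, with spin angle psi
// about d.
static Quat orient_patch_to(const Vec3 &u, const Vec3 &d, double psi) {
  double dot = u[0] * d[0] + u[1] * d[1] + u[2] * d[2];
  Quat qa;
  if (dot > 1 - 1e-12) {
    qa = {1, 0, 0, 0};
  } else if (dot < -1 + 1e-12) {
    // 180 degrees about any axis orthogonal to u
    Vec3 ax;
    if (std::fabs(u[0]) < 0.9) ax = {1, 0, 0}; else ax = {0, 1, 0};
    double dd = ax[0] * u[0] + ax[1] * u[1] + ax[2] * u[2];
    for (int k = 0; k < 3; ++k) ax[k] -= dd * u[k];
    double n = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    for (int k = 0; k < 3; ++k) ax[k] /= n;
    qa = {0, ax[0], ax[1], ax[2]};
  } else {
    Vec3 ax = {u[1] * d[2] - u[2] * d[1], u[2] * d[0] - u[0] * d[2],
               u[0] * d[1] - u[1] * d[0]};
    double n = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    for (int k = 0; k < 3; ++k) ax[k] /= n;
    qa = axis_angle(ax, std::acos(dot));
  }
  Quat qs = axis_angle(d, psi);
  Quat q = qmul(qs, qa);
  qnormalize(q);
  return q;
}

static Box make_box(const NumericMatrix &pos, const NumericMatrix &quat,
                    const IntegerVector &sp, double L, const MixData *mix) {
  Box b;
  b.mix = mix;
  b.L = L;
  b.N = pos.nrow();
  b.pos.resize(b.N);
  b.quat.resize(b.N);
  b.sp.resize(b.N);
  for (int i = 0; i < b.N; ++i) {
    b.pos[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    b.wrap(b.pos[i]);
    b.quat[i] = {quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3)};
    b.sp[i] = sp[i] - 1;
  }
  b.init_pw();
  b.build_cells();
  return b;
}

// [[Rcpp::export(name = ".mc_total_energy")]]
List mc_total_energy(NumericMatrix pos, NumericMatrix quat,
                     IntegerVector sp, double L, List mixdata) {
  MixData mix = parse_mix(mixdata);
  Box b = make_box(pos, quat, sp, L, &mix);
  std::vector<std::array<int, 4>> edges;
  bool overlap;
  double e = b.total_energy(&edges, &overlap);
  IntegerMatrix E(edges.size(), 4);
  for (size_t k = 0; k < edges.size(); ++k) {
    E(k, 0) = edges[k][0] + 1; E(k, 1) = edges[k][1] + 1;
    E(k, 2) = edges[k][2] + 1; E(k, 3) = edges[k][3] + 1;
  }
  return List::create(_["energy"] = overlap ? R_PosInf : e,
                      _["overlap"] = overlap, _["edges"] = E);
}

// Single-box move engine shared by NVT and Gibbs.
struct MoveStats {
  long att_rt = 0, acc_rt = 0, att_b = 0, acc_b = 0, att_u = 0, acc_u = 0;
};

static bool move_rototrans(Box &b, Rng &rng, double T, double dmax,
                           double rmax, MoveStats &st, double *dU_out) {
  *dU_out = 0;
  st.att_rt++;
  if (b.N == 0) return false;
  int i = rng.ui(b.N);
  double e_old = b.particle_energy(i, b.pos[i], b.pw[i], b.sp[i]);
  Vec3 pnew = b.pos[i];
  for (int k = 0; k < 3; ++k) pnew[k] += dmax * (2 * rng.u() - 1);
  b.wrap(pnew);
  Quat qr = axis_angle(rng.unit_vec(), rmax * (2 * rng.u() - 1));
  Quat qnew = qmul(qr, b.quat[i]);
  qnormalize(qnew);
  std::vector<Vec3> pwnew(b.mix->np);
  for (int a = 0; a < b.mix->np; ++a)
    pwnew[a] = rotate(qnew, b.mix->patchv[b.sp[i]][a]);
  // remove from cells so the trial doesn't see its own old image
  b.cell_remove(i);
  double e_new = b.particle_energy(i, pnew, pwnew, b.sp[i]);
  double dU = e_new - e_old;
  if (e_new < 1e29 && (dU <= 0 || rng.u() < std::exp(-dU / T))) {
    b.pos[i] = pnew;
    b.quat[i] = qnew;
    b.pw[i] = pwnew;
    b.cell_insert(i);
    st.acc_rt++;
    *dU_out = dU;
    return true;
  }
  b.cell_insert(i);
  return false;
}

// AVB-B: bind a particle k (not bonded to j) into the bonding volume of a
// uniformly chosen compatible patch pair.  AVB-U: release a bonded
// neighbour to a uniform pose.  Acceptance carries the exact proposal
// densities:
//   acc_B = exp(-dU/T) * M_out(s) * n_pairs * V_b / (N_j(s') * V)
//   acc_U = exp(-dU/T) * N_j(s) * V / (M_out(s') * n_pairs * V_b)
static bool move_avb(Box &b, Rng &rng, double T, bool bind, MoveStats &st,
                     double *dU_out) {
  *dU_out = 0;
  const MixData *m = b.mix;
  if (b.N < 2) return false;
  double V = b.L * b.L * b.L;
  double s3 = m->sigma * m->sigma * m->sigma;
  double rc = m->sigma + m->delta;
  double shell = rc * rc * rc - s3;
  double pfrac = (1 - m->cosmax) / 2;
  double Vb1 = (4.0 * M_PI / 3.0) * shell * pfrac * pfrac;
  int j = rng.ui(b.N);
  std::vector<int> nb;
  b.bonded_neighbors(j, nb);
  int Nj = nb.size();
  if (bind) {
    st.att_b++;
    int Mout = b.N - 1 - Nj;
    if (Mout <= 0) return false;
    // uniform among particles not bonded to j (redraw on bonded)
    int k;
    for (;;) {
      k = rng.ui(b.N);
      if (k == j) continue;
      bool isb = false;
      for (int q : nb) if (q == k) { isb = true; break; }
      if (!isb) break;
    }
    int npair = m->npairs[b.sp[j]][b.sp[k]];
    if (npair == 0) return false;
    // choose a compatible (patch on j, patch on k) pair uniformly
    int pick = rng.ui(npair), pa = -1, pb = -1, cnt = 0;
    for (int a = 0; a < m->np && pa < 0; ++a)
      for (int bq = 0; bq < m->np; ++bq)
        if (m->ups[m->patchc[b.sp[j]][a]][m->patchc[b.sp[k]][bq]]) {
          if (cnt == pick) { pa = a; pb = bq; break; }
          ++cnt;
        }
    double e_old = b.particle_energy(k, b.pos[k], b.pw[k], b.sp[k]);
    // pose uniform in the bonding volume of patch pa of j
    Vec3 rhat = rng.cone_vec(b.pw[j][pa], m->cosmax);
    double r = std::cbrt(s3 + rng.u() * shell);
    Vec3 pnew;
    for (int kk = 0; kk < 3; ++kk) pnew[kk] = b.pos[j][kk] + r * rhat[kk];
    b.wrap(pnew);
    Vec3 back = {-rhat[0], -rhat[1], -rhat[2]};
    Vec3 d = rng.cone_vec(back, m->cosmax);
    Quat qnew = orient_patch_to(m->patchv[b.sp[k]][pb], d,
                                2 * M_PI * rng.u());
    std::vector<Vec3> pwnew(m->np);
    for (int a = 0; a < m->np; ++a)
      pwnew[a] = rotate(qnew, m->patchv[b.sp[k]][a]);
    b.cell_remove(k);
    double e_new = b.particle_energy(k, pnew, pwnew, b.sp[k]);
    if (e_new > 1e29) { b.cell_insert(k); return false; }
    double dU = e_new - e_old;
    // N_j after the move: place k provisionally
    Vec3 opos = b.pos[k]; Quat oq = b.quat[k];
    std::vector<Vec3> opw = b.pw[k];
    b.pos[k] = pnew; b.quat[k] = qnew; b.pw[k] = pwnew;
    b.cell_insert(k);
    std::vector<int> nb2;
    b.bonded_neighbors(j, nb2);
    int Nj_new = nb2.size();
    double ratio = std::exp(-dU / T) * (double)Mout * npair * Vb1 /
                   ((double)std::max(Nj_new, 1) * V);
    if (Nj_new > 0 && rng.u() < ratio) {
      st.acc_b++;
      *dU_out = dU;
      return true;
    }
    // revert
    b.cell_remove(k);
    b.pos[k] = opos; b.quat[k] = oq; b.pw[k] = opw;
    b.cell_insert(k);
    return false;
  } else {
    st.att_u++;
    if (Nj == 0) return false;
    int k = nb[rng.ui(Nj)];
    double e_old = b.particle_energy(k, b.pos[k], b.pw[k], b.sp[k]);
    Vec3 pnew = {rng.u() * b.L, rng.u() * b.L, rng.u() * b.L};
    Quat qnew = rng.random_quat();
    std::vector<Vec3> pwnew(m->np);
    for (int a = 0; a < m->np; ++a)
      pwnew[a] = rotate(qnew, m->patchv[b.sp[k]][a]);
    b.cell_remove(k);
    double e_new = b.particle_energy(k, pnew, pwnew, b.sp[k]);
    if (e_new > 1e29) { b.cell_insert(k); return false; }
    // provisional placement; reject if still bonded to j
    Vec3 opos = b.pos[k]; Quat oq = b.quat[k];
    std::vector<Vec3> opw = b.pw[k];
    b.pos[k] = pnew; b.quat[k] = qnew; b.pw[k] = pwnew;
    b.cell_insert(k);
    std::vector<int> nb2;
    b.bonded_neighbors(j, nb2);
    bool still = false;
    for (int q : nb2) if (q == k) { still = true; break; }
    int npair = m->npairs[b.sp[j]][b.sp[k]];
    int Mout_new = b.N - 1 - (int)nb2.size();
    double dU = e_new - e_old;
    double ratio = std::exp(-dU / T) * (double)Nj * V /
                   ((double)std::max(Mout_new, 1) * npair * Vb1);
    if (!still && npair > 0 && Mout_new > 0 && rng.u() < ratio) {
      st.acc_u++;
      *dU_out = dU;
      return true;
    }
    b.cell_remove(k);
    b.pos[k] = opos; b.quat[k] = oq; b.pw[k] = opw;
    b.cell_insert(k);
    return false;
  }
}

// Bond census: number of bonds and largest cluster via union-find.
static void bond_census(const Box &b, int *nbonds, int *largest,
                        int *maxdeg) {
  std::vector<int> parent(b.N), deg(b.N, 0);
  for (int i = 0; i < b.N; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int nb = 0;
  int pa, pb;
  for (int i = 0; i < b.N; ++i)
    for (int j = i + 1; j < b.N; ++j) {
      Vec3 d = b.minimage(b.pos[i], b.pos[j]);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      double rc = b.mix->sigma + b.mix->delta;
      if (r2 > rc * rc) continue;
      if (b.pair_state(i, b.pos[i], b.pw[i], b.sp[i], j, &pa, &pb) == 1) {
        ++nb; ++deg[i]; ++deg[j];
        int ri = find(i), rj = find(j);
        if (ri != rj) parent[ri] = rj;
      }
    }
  std::vector<int> csize(b.N, 0);
  int lg = 0;
  for (int i = 0; i < b.N; ++i) {
    int r = find(i);
    if (++csize[r] > lg) lg = csize[r];
  }
  int md = 0;
  for (int i = 0; i < b.N; ++i) if (deg[i] > md) md = deg[i];
  *nbonds = nb;
  *largest = b.N ? lg : 0;
  *maxdeg = md;
}

// [[Rcpp::export(name = ".mc_run_nvt")]]
List mc_run_nvt(NumericMatrix pos, NumericMatrix quat, IntegerVector sp,
                double L, List mixdata, double T, int sweeps, int seed,
                double p_rt, double p_avb_b, double p_avb_u,
                double dmax, double rmax, int cadence, int snap_every) {
  MixData mix = parse_mix(mixdata);
  Box b = make_box(pos, quat, sp, L, &mix);
  Rng rng((uint64_t)seed);
  MoveStats st;
  std::vector<double> ob_sweep, ob_energy;
  std::vector<int> ob_bonds, ob_cluster, ob_maxdeg;
  List snaps;
  for (int sw = 1; sw <= sweeps; ++sw) {
    for (int mv = 0; mv < b.N; ++mv) {
      double u = rng.u(), du;
      if (u < p_rt) move_rototrans(b, rng, T, dmax, rmax, st, &du);
      else if (u < p_rt + p_avb_b) move_avb(b, rng, T, true, st, &du);
      else move_avb(b, rng, T, false, st, &du);
    }
    if (sw % cadence == 0) {
      bool ov;
      double e = b.total_energy(nullptr, &ov);
      int nb, lg, md;
      bond_census(b, &nb, &lg, &md);
      ob_sweep.push_back(sw);
      ob_energy.push_back(e);
      ob_bonds.push_back(nb);
      ob_cluster.push_back(lg);
      ob_maxdeg.push_back(md);
    }
    if (snap_every > 0 && sw % snap_every == 0) {
      NumericMatrix P(b.N, 3), Q(b.N, 4);
      for (int i = 0; i < b.N; ++i) {
        for (int k = 0; k < 3; ++k) P(i, k) = b.pos[i][k];
        for (int k = 0; k < 4; ++k) Q(i, k) = b.quat[i][k];
      }
      snaps.push_back(List::create(_["sweep"] = sw, _["pos"] = P,
                                   _["quat"] = Q));
    }
    if (sw % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix P(b.N, 3), Q(b.N, 4);
  for (int i = 0; i < b.N; ++i) {
    for (int k = 0; k < 3; ++k) P(i, k) = b.pos[i][k];
    for (int k = 0; k < 4; ++k) Q(i, k) = b.quat[i][k];
  }
  return List::create(
      _["pos"] = P, _["quat"] = Q,
      _["observables"] = DataFrame::create(
          _["sweep"] = ob_sweep, _["energy"] = ob_energy,
          _["n_bonds"] = ob_bonds, _["largest_cluster"] = ob_cluster,
          _["max_bond_degree"] = ob_maxdeg),
      _["acceptance"] = DataFrame::create(
          _["move"] = CharacterVector::create("rototranslation", "avb_b",
                                              "avb_u"),
          _["attempted"] = NumericVector::create(st.att_rt, st.att_b,
                                                 st.att_u),
          _["accepted"] = NumericVector::create(st.acc_rt, st.acc_b,
                                                st.acc_u)),
      _["snapshots"] = snaps);
}

// [[Rcpp::export(name = ".mc_run_gibbs")]]
List mc_run_gibbs(NumericMatrix posA, NumericMatrix quatA, IntegerVector spA,
                  double LA, NumericMatrix posB, NumericMatrix quatB,
                  IntegerVector spB, double LB, List mixdata, double T,
                  int sweeps, int seed, double p_rt, double p_avb_b,
                  double p_avb_u, double dmax, double rmax, double dlnV,
                  int transfer_per_sweep, int cadence) {
  MixData mix = parse_mix(mixdata);
  Box A = make_box(posA, quatA, spA, LA, &mix);
  Box B = make_box(posB, quatB, spB, LB, &mix);
  Rng rng((uint64_t)seed);
  MoveStats stA, stB;
  long att_vol = 0, acc_vol = 0, att_tr = 0, acc_tr = 0;
  double Lmin = 2 * (mix.sigma + mix.delta);
  std::vector<double> ob_sweep, ob_rhoA, ob_rhoB, ob_xA, ob_xB, ob_eA, ob_eB;
  std::vector<int> ob_nA, ob_nB;
  bool ov;
  double eA = A.total_energy(nullptr, &ov);
  double eB = B.total_energy(nullptr, &ov);

  auto try_volume = [&]() {
    ++att_vol;
    double VA = A.L * A.L * A.L, VB = B.L * B.L * B.L, Vt = VA + VB;
    double lnVA = std::log(VA) + dlnV * (2 * rng.u() - 1);
    double VAn = std::exp(lnVA), VBn = Vt - VAn;
    if (VBn <= 0) return;
    double LAn = std::cbrt(VAn), LBn = std::cbrt(VBn);
    if (LAn < Lmin || LBn < Lmin) return;
    double sa = LAn / A.L, sb = LBn / B.L;
    Box An = A, Bn = B;
    An.L = LAn; Bn.L = LBn;
    for (int i = 0; i < An.N; ++i)
      for (int k = 0; k < 3; ++k) An.pos[i][k] *= sa;
    for (int i = 0; i < Bn.N; ++i)
      for (int k = 0; k < 3; ++k) Bn.pos[i][k] *= sb;
    An.build_cells(); Bn.build_cells();
    bool ovA, ovB;
    double eAn = An.total_energy(nullptr, &ovA);
    double eBn = Bn.total_energy(nullptr, &ovB);
    if (ovA || ovB) return;
    double arg = -(eAn - eA + eBn - eB) / T +
                 (A.N + 1) * std::log(VAn / VA) +
                 (B.N + 1) * std::log(VBn / VB);
    if (std::log(rng.u() + 1e-300) < arg) {
      A = An; B = Bn; eA = eAn; eB = eBn;
      ++acc_vol;
    }
  };

  auto try_transfer = [&]() {
    ++att_tr;
    bool a2b = rng.u() < 0.5;
    Box &S = a2b ? A : B;
    Box &D = a2b ? B : A;
    double &eS = a2b ? eA : eB;
    double &eD = a2b ? eB : eA;
    if (S.N == 0) return;
    int i = rng.ui(S.N);
    int spi = S.sp[i];
    double e_rem = S.particle_energy(i, S.pos[i], S.pw[i], spi);
    Vec3 pnew = {rng.u() * D.L, rng.u() * D.L, rng.u() * D.L};
    Quat qnew = rng.random_quat();
    std::vector<Vec3> pwnew(mix.np);
    for (int a = 0; a < mix.np; ++a)
      pwnew[a] = rotate(qnew, mix.patchv[spi][a]);
    // energy of the inserted particle in D (index D.N, not yet present)
    Box &Dref = D;
    double e_ins;
    {
      // temporary insertion probe: reuse particle_energy with i = -1 trick
      // by scanning all particles in D
      e_ins = 0;
      int pa, pb;
      bool bad = false;
      for (int j = 0; j < Dref.N && !bad; ++j) {
        Vec3 d = Dref.minimage(pnew, Dref.pos[j]);
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        double s = mix.sigma, rc = s + mix.delta;
        if (r2 < s * s) { bad = true; break; }
        if (r2 > rc * rc) continue;
        double r = std::sqrt(r2);
        Vec3 rh = {d[0] / r, d[1] / r, d[2] / r};
        double best = -1e9;
        for (int a = 0; a < mix.np; ++a) {
          double c1 = pwnew[a][0] * rh[0] + pwnew[a][1] * rh[1] +
                      pwnew[a][2] * rh[2];
          if (c1 < mix.cosmax) continue;
          for (int bq = 0; bq < mix.np; ++bq) {
            if (!mix.ups[mix.patchc[spi][a]][mix.patchc[Dref.sp[j]][bq]])
              continue;
            double c2 = -(Dref.pw[j][bq][0] * rh[0] +
                          Dref.pw[j][bq][1] * rh[1] +
                          Dref.pw[j][bq][2] * rh[2]);
            if (c2 < mix.cosmax) continue;
            if (c1 + c2 > best) best = c1 + c2;
          }
        }
        if (best > -1e8) e_ins -= mix.eps;
        (void)pa; (void)pb;
      }
      if (bad) return;
    }
    double VS = S.L * S.L * S.L, VD = D.L * D.L * D.L;
    double dU = e_ins - e_rem;  // removal removes e_rem, insertion adds e_ins
    double ratio = std::exp(-dU / T) * (double)S.N * VD /
                   ((double)(D.N + 1) * VS);
    if (rng.u() < ratio) {
      // commit: remove from S, append to D
      S.cell_remove(i);
      S.pos.erase(S.pos.begin() + i);
      S.quat.erase(S.quat.begin() + i);
      S.sp.erase(S.sp.begin() + i);
      S.pw.erase(S.pw.begin() + i);
      S.N--;
      S.build_cells();
      D.pos.push_back(pnew);
      D.quat.push_back(qnew);
      D.sp.push_back(spi);
      D.pw.push_back(pwnew);
      D.N++;
      D.build_cells();
      eS -= e_rem;
      eD += e_ins;
      ++acc_tr;
    }
  };

  for (int sw = 1; sw <= sweeps; ++sw) {
    int Ntot = A.N + B.N;
    for (int mv = 0; mv < Ntot; ++mv) {
      int pick = rng.ui(Ntot);
      bool inA = pick < A.N;
      Box &bx = inA ? A : B;
      double u = rng.u(), du = 0;
      MoveStats &stx = inA ? stA : stB;
      if (u < p_rt) move_rototrans(bx, rng, T, dmax, rmax, stx, &du);
      else if (u < p_rt + p_avb_b) move_avb(bx, rng, T, true, stx, &du);
      else move_avb(bx, rng, T, false, stx, &du);
      (inA ? eA : eB) += du;
    }
    try_volume();
    for (int t = 0; t < transfer_per_sweep; ++t) try_transfer();
    if (sw % cadence == 0) {
      eA = A.total_energy(nullptr, &ov);
      eB = B.total_energy(nullptr, &ov);
      double VA = A.L * A.L * A.L, VB = B.L * B.L * B.L;
      int n1A = 0, n1B = 0;
      for (int i = 0; i < A.N; ++i) if (A.sp[i] == 0) ++n1A;
      for (int i = 0; i < B.N; ++i) if (B.sp[i] == 0) ++n1B;
      ob_sweep.push_back(sw);
      ob_rhoA.push_back(A.N / VA);
      ob_rhoB.push_back(B.N / VB);
      ob_xA.push_back(A.N ? (double)n1A / A.N : NA_REAL);
      ob_xB.push_back(B.N ? (double)n1B / B.N : NA_REAL);
      ob_eA.push_back(eA);
      ob_eB.push_back(eB);
      ob_nA.push_back(A.N);
      ob_nB.push_back(B.N);
    }
    if (sw % 200 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix PA(A.N, 3), QA(A.N, 4), PB(B.N, 3), QB(B.N, 4);
  IntegerVector SA(A.N), SB(B.N);
  for (int i = 0; i < A.N; ++i) {
    for (int k = 0; k < 3; ++k) PA(i, k) = A.pos[i][k];
    for (int k = 0; k < 4; ++k) QA(i, k) = A.quat[i][k];
    SA[i] = A.sp[i] + 1;
  }
  for (int i = 0; i < B.N; ++i) {
    for (int k = 0; k < 3; ++k) PB(i, k) = B.pos[i][k];
    for (int k = 0; k < 4; ++k) QB(i, k) = B.quat[i][k];
    SB[i] = B.sp[i] + 1;
  }
  return List::create(
      _["observables"] = DataFrame::create(
          _["sweep"] = ob_sweep, _["rho_a"] = ob_rhoA, _["rho_b"] = ob_rhoB,
          _["x_a"] = ob_xA, _["x_b"] = ob_xB, _["energy_a"] = ob_eA,
          _["energy_b"] = ob_eB, _["n_a"] = ob_nA, _["n_b"] = ob_nB),
      _["box_a"] = List::create(_["pos"] = PA, _["quat"] = QA,
                                _["species"] = SA, _["L"] = A.L),
      _["box_b"] = List::create(_["pos"] = PB, _["quat"] = QB,
                                _["species"] = SB, _["L"] = B.L),
      _["acceptance"] = List::create(
          _["volume"] = NumericVector::create(att_vol, acc_vol),
          _["transfer"] = NumericVector::create(att_tr, acc_tr)));
}
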