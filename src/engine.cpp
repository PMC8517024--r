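// Core numerical kernels: bead-spring force field (FENE bonds, bend triples,
// LJ/WCA pair rules by bead type), BAOAB Langevin integrator with moving
// harmonic anchors, and the rolling-ball image background estimator.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
#include <random>
#include <cstdint>

using namespace Rcpp;

namespace {

struct PairRules {
  // indexed by (type_i, type_j), types 0..7
  double eps[8][8];
  double sig[8][8];
  double cut[8][8];
  double shift[8][8];  // energy shift so U(cutoff) = 0 for LJ
  int kind[8][8];      // 0 none, 1 LJ, 2 WCA
  double max_cut;
};

inline double lj_raw(double r, double eps, double sig) {
  double s6 = std::pow(sig / r, 6.0);
  return eps * (s6 * s6 - 2.0 * s6);
}

// dU/dr for the LJ form eps[(s/r)^12 - 2(s/r)^6]
inline double lj_dudr(double r, double eps, double sig) {
  double s6 = std::pow(sig / r, 6.0);
  return -12.0 * eps * (s6 * s6 - s6) / r;
}

PairRules make_rules(const NumericMatrix& eps, const NumericMatrix& sig,
                     const NumericMatrix& cut, const IntegerMatrix& kind) {
  PairRules pr;
  pr.max_cut = 0.0;
  for (int a = 0; a < 8; ++a) for (int b = 0; b < 8; ++b) {
    pr.eps[a][b] = eps(a, b);
    pr.sig[a][b] = sig(a, b);
    pr.cut[a][b] = cut(a, b);
    pr.kind[a][b] = kind(a, b);
    pr.shift[a][b] = 0.0;
    if (kind(a, b) == 1 && R_finite(cut(a, b)))
      pr.shift[a][b] = lj_raw(cut(a, b), eps(a, b), sig(a, b));
    if (kind(a, b) != 0 && R_finite(cut(a, b)) && cut(a, b) > pr.max_cut)
      pr.max_cut = cut(a, b);
  }
  return pr;
}

struct System {
  int n;
  std::vector<double> x, y;
  std::vector<int> type, cell;
  // bonds: i, j 0-based
  std::vector<int> bi, bj;
  std::vector<double> bkF, br0, bdrm;
  // angles: j is the center bead
  std::vector<int> ai, aj, ak;
  std::vector<double> akB, ac0;
  PairRules rules;        // pairs within the same cell
  PairRules rules_cross;  // pairs in different cells
  std::vector<std::vector<int>> excl;  // bonded partners per bead
  // anchors: bead, kx, ky, x0, y0, vx, vy (bead 0-based)
  NumericMatrix anchors;

  // scratch
  std::vector<double> fx, fy;
  // cell list
  std::vector<int> head, nxt;
  int nbx, nby;
  double bx0, by0, bin;

  bool excluded(int i, int j) const {
    for (int p : excl[i]) if (p == j) return true;
    return false;
  }

  void build_bins() {
    bin = std::max(rules.max_cut, rules_cross.max_cut);
    if (bin <= 0) bin = 1.0;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    bx0 = xmin; by0 = ymin;
    nbx = std::max(1, (int)((xmax - xmin) / bin) + 1);
    nby = std::max(1, (int)((ymax - ymin) / bin) + 1);
    head.assign((size_t)nbx * nby, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(nbx - 1, std::max(0, (int)((x[i] - bx0) / bin)));
      int cy = std::min(nby - 1, std::max(0, (int)((y[i] - by0) / bin)));
      int c = cy * nbx + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  // Accumulate forces; returns potential energy if want_energy.
  // anchor positions evaluated at time t; step index only for error messages.
  double forces(double t, bool want_energy, long step) {
    fx.assign(n, 0.0); fy.assign(n, 0.0);
    double pot = 0.0;

    // FENE bonds
    for (size_t b = 0; b < bi.size(); ++b) {
      int i = bi[b], j = bj[b];
      double kF = bkF[b], r0 = br0[b], drm = bdrm[b];
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double r = std::sqrt(dx * dx + dy * dy);
      double u = (r - r0) / drm;
      if (!R_finite(r) || std::fabs(u) >= 1.0)
        stop("FENE bond %d (beads %d-%d) overextended at step %ld (r=%g, r0=%g, drmax=%g)",
             b + 1, i + 1, j + 1, step, r, r0, drm);
      double fmag = -kF * (r - r0) / (1.0 - u * u);  // -dU/dr
      double inv = (r > 0) ? 1.0 / r : 0.0;
      fx[i] += fmag * dx * inv; fy[i] += fmag * dy * inv;
      fx[j] -= fmag * dx * inv; fy[j] -= fmag * dy * inv;
      if (want_energy) pot += -0.5 * kF * drm * drm * std::log(1.0 - u * u);
    }

    // bend triples: U = kB/2 (cos th - cos th0)^2, center bead is j
    for (size_t a = 0; a < ai.size(); ++a) {
      int i = ai[a], j = aj[a], k = ak[a];
      double kB = akB[a], c0 = ac0[a];
      double ax = x[i] - x[j], ay = y[i] - y[j];
      double bxv = x[k] - x[j], byv = y[k] - y[j];
      double la = std::sqrt(ax * ax + ay * ay), lb = std::sqrt(bxv * bxv + byv * byv);
      if (la <= 0 || lb <= 0) continue;
      double ct = (ax * bxv + ay * byv) / (la * lb);
      ct = std::max(-1.0, std::min(1.0, ct));
      double pref = -kB * (ct - c0);  // -dU/dcos
      // d(cos)/d r_i and d(cos)/d r_k
      double dix = (bxv / (la * lb)) - ct * ax / (la * la);
      double diy = (byv / (la * lb)) - ct * ay / (la * la);
      double dkx = (ax / (la * lb)) - ct * bxv / (lb * lb);
      double dky = (ay / (la * lb)) - ct * byv / (lb * lb);
      fx[i] += pref * dix; fy[i] += pref * diy;
      fx[k] += pref * dkx; fy[k] += pref * dky;
      fx[j] -= pref * (dix + dkx); fy[j] -= pref * (diy + dky);
      if (want_energy) pot += 0.5 * kB * (ct - c0) * (ct - c0);
    }

    // non-bonded pairs via cell list
    build_bins();
    for (int cy = 0; cy < nby; ++cy) for (int cx = 0; cx < nbx; ++cx) {
      for (int i = head[cy * nbx + cx]; i >= 0; i = nxt[i]) {
        for (int oy = -1; oy <= 1; ++oy) for (int ox = -1; ox <= 1; ++ox) {
          int ncx = cx + ox, ncy = cy + oy;
          if (ncx < 0 || ncx >= nbx || ncy < 0 || ncy >= nby) continue;
          for (int j = head[ncy * nbx + ncx]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;
            const PairRules& R = (cell[i] == cell[j]) ? rules : rules_cross;
            int ti = type[i], tj = type[j];
            int kd = R.kind[ti][tj];
            if (kd == 0) continue;
            double cutoff = R.cut[ti][tj];
            double dx = x[i] - x[j], dy = y[i] - y[j];
            double r2 = dx * dx + dy * dy;
            if (r2 >= cutoff * cutoff || r2 <= 0) continue;
            if (excluded(i, j)) continue;
            double e = R.eps[ti][tj], s = R.sig[ti][tj];
            double s2 = s * s / r2;
            double s6 = s2 * s2 * s2;
            // -(dU/dr)/r for U = e[(s/r)^12 - 2(s/r)^6]
            double fmag = 12.0 * e * (s6 * s6 - s6) / r2;
            fx[i] += fmag * dx; fy[i] += fmag * dy;
            fx[j] -= fmag * dx; fy[j] -= fmag * dy;
            if (want_energy) {
              double u = e * (s6 * s6 - 2.0 * s6);
              pot += (kd == 1) ? u - R.shift[ti][tj] : u + e;
            }
          }
        }
      }
    }

    // harmonic anchors (AFM tip springs, pull springs)
    for (int a = 0; a < anchors.nrow(); ++a) {
      int i = (int)anchors(a, 0);
      double kx = anchors(a, 1), ky = anchors(a, 2);
      double axp = anchors(a, 3) + anchors(a, 5) * t;
      double ayp = anchors(a, 4) + anchors(a, 6) * t;
      fx[i] += kx * (axp - x[i]);
      fy[i] += ky * (ayp - y[i]);
      if (want_energy)
        pot += 0.5 * kx * (axp - x[i]) * (axp - x[i]) +
               0.5 * ky * (ayp - y[i]) * (ayp - y[i]);
    }
    return pot;
  }
};

System make_system(const NumericMatrix& pos, const IntegerVector& type,
                   const IntegerVector& cell,
                   const NumericMatrix& bonds, const NumericMatrix& angles,
                   const List& rules_same, const List& rules_cross,
                   const NumericMatrix& anchors) {
  System sys;
  sys.n = pos.nrow();
  sys.x.resize(sys.n); sys.y.resize(sys.n);
  sys.type.resize(sys.n); sys.cell.resize(sys.n);
  for (int i = 0; i < sys.n; ++i) {
    sys.x[i] = pos(i, 0); sys.y[i] = pos(i, 1);
    sys.type[i] = type[i];
    sys.cell[i] = cell[i];
    if (sys.type[i] < 0 || sys.type[i] > 7) stop("bead type out of range 0..7");
  }
  // convert 1-based R indices to 0-based copies
  int nb = bonds.nrow();
  sys.bi.resize(nb); sys.bj.resize(nb);
  sys.bkF.resize(nb); sys.br0.resize(nb); sys.bdrm.resize(nb);
  sys.excl.assign(sys.n, {});
  for (int b = 0; b < nb; ++b) {
    sys.bi[b] = (int)bonds(b, 0) - 1; sys.bj[b] = (int)bonds(b, 1) - 1;
    sys.bkF[b] = bonds(b, 2); sys.br0[b] = bonds(b, 3); sys.bdrm[b] = bonds(b, 4);
    sys.excl[sys.bi[b]].push_back(sys.bj[b]);
    sys.excl[sys.bj[b]].push_back(sys.bi[b]);
  }
  int na = angles.nrow();
  sys.ai.resize(na); sys.aj.resize(na); sys.ak.resize(na);
  sys.akB.resize(na); sys.ac0.resize(na);
  for (int a = 0; a < na; ++a) {
    sys.ai[a] = (int)angles(a, 0) - 1;
    sys.aj[a] = (int)angles(a, 1) - 1;
    sys.ak[a] = (int)angles(a, 2) - 1;
    sys.akB[a] = angles(a, 3);
    sys.ac0[a] = std::cos(angles(a, 4));
  }
  sys.anchors = clone(anchors);
  for (int a = 0; a < sys.anchors.nrow(); ++a) sys.anchors(a,0) -= 1;
  sys.rules = make_rules(rules_same["eps"], rules_same["sig"],
                         rules_same["cut"], rules_same["kind"]);
  sys.rules_cross = make_rules(rules_cross["eps"], rules_cross["sig"],
                               rules_cross["cut"], rules_cross["kind"]);
  return sys;
}

// deterministic gaussians independent of R's RNG state
struct Gauss {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Gauss(std::uint64_t seed) : eng(seed) {}
  double uniform() {
    return (eng() >> 11) * (1.0 / 9007199254740992.0);  // [0,1)
  }
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u1, u2;
    do { u1 = uniform(); } while (u1 <= 1e-300);
    u2 = uniform();
    double m = std::sqrt(-2.0 * std::log(u1));
    spare = m * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return m * std::cos(2.0 * M_PI * u2);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_total_forces(NumericMatrix pos, IntegerVector type,
                      IntegerVector cell,
                      NumericMatrix bonds, NumericMatrix angles,
                      List rules_same, List rules_cross,
                      NumericMatrix anchors) {
  System sys = make_system(pos, type, cell, bonds, angles,
                           rules_same, rules_cross, anchors);
  double pot = sys.forces(0.0, true, 0);
  NumericMatrix f(sys.n, 2);
  for (int i = 0; i < sys.n; ++i) { f(i, 0) = sys.fx[i]; f(i, 1) = sys.fy[i]; }
  return List::create(_["forces"] = f, _["potential"] = pot);
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                IntegerVector cell,
                NumericMatrix bonds, NumericMatrix angles,
                List rules_same, List rules_cross,
                NumericMatrix anchors,
                double dt, double n_steps_d, double gamma_, double temp,
                double seed, int record_every, bool record_frames,
                double t0) {
  long n_steps = (long)n_steps_d;
  System sys = make_system(pos, type, cell, bonds, angles,
                           rules_same, rules_cross, anchors);
  int n = sys.n;
  std::vector<double> vx(n), vy(n);
  for (int i = 0; i < n; ++i) { vx[i] = vel(i, 0); vy[i] = vel(i, 1); }

  Gauss rng((std::uint64_t)seed + 0x9E3779B97F4A7C15ULL);
  double c1 = std::exp(-gamma_ * dt);
  double c2 = (temp > 0 && gamma_ > 0) ? std::sqrt(temp * (1.0 - c1 * c1)) : 0.0;
  // apparatus-driven beads (anchored) see no thermal noise; their friction
  // acts on the velocity relative to the moving anchor (clamp damping), so
  // steady co-motion with the apparatus is drag-free
  std::vector<char> thermo(n, 1);
  std::vector<double> avx(n, 0.0), avy(n, 0.0);
  for (int a = 0; a < sys.anchors.nrow(); ++a) {
    int ib = (int)sys.anchors(a, 0);
    thermo[ib] = 0;
    avx[ib] = sys.anchors(a, 5);
    avy[ib] = sys.anchors(a, 6);
  }

  long n_frames = n_steps / record_every + 1;
  NumericVector times(n_frames), ekin(n_frames), epot(n_frames);
  int na = sys.anchors.nrow();
  NumericMatrix afx(n_frames, std::max(1, na)), afy(n_frames, std::max(1, na));
  NumericMatrix aax(n_frames, std::max(1, na)), aay(n_frames, std::max(1, na));
  NumericVector frames;  // n * 2 * n_frames, filled only if record_frames
  if (record_frames) frames = NumericVector((R_xlen_t)n * 2 * n_frames);

  double t = t0;
  double pot = sys.forces(t, true, 0);

  long frame = 0;
  auto record = [&](long fr) {
    times[fr] = t;
    double ke = 0.0;
    for (int i = 0; i < n; ++i) ke += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i]);
    ekin[fr] = ke;
    epot[fr] = pot;
    for (int a = 0; a < na; ++a) {
      int ib = (int)sys.anchors(a, 0);
      double axp = sys.anchors(a, 3) + sys.anchors(a, 5) * t;
      double ayp = sys.anchors(a, 4) + sys.anchors(a, 6) * t;
      afx(fr, a) = sys.anchors(a, 1) * (axp - sys.x[ib]);
      afy(fr, a) = sys.anchors(a, 2) * (ayp - sys.y[ib]);
      aax(fr, a) = axp; aay(fr, a) = ayp;
    }
    if (record_frames) {
      R_xlen_t off = (R_xlen_t)fr * n * 2;
      for (int i = 0; i < n; ++i) {
        frames[off + i] = sys.x[i];
        frames[off + n + i] = sys.y[i];
      }
    }
  };
  record(frame++);

  for (long s = 1; s <= n_steps; ++s) {
    // BAOAB: B (half kick), A (half drift), O (friction+noise), A, B
    for (int i = 0; i < n; ++i) { vx[i] += 0.5 * dt * sys.fx[i]; vy[i] += 0.5 * dt * sys.fy[i]; }
    for (int i = 0; i < n; ++i) { sys.x[i] += 0.5 * dt * vx[i]; sys.y[i] += 0.5 * dt * vy[i]; }
    if (gamma_ > 0) {
      if (c2 > 0) {
        for (int i = 0; i < n; ++i) {
          if (!thermo[i]) continue;
          vx[i] = c1 * vx[i] + c2 * rng();
          vy[i] = c1 * vy[i] + c2 * rng();
        }
      } else {
        for (int i = 0; i < n; ++i) {
          if (!thermo[i]) continue;
          vx[i] *= c1; vy[i] *= c1;
        }
      }
      for (int i = 0; i < n; ++i) {
        if (thermo[i]) continue;
        vx[i] = avx[i] + c1 * (vx[i] - avx[i]);
        vy[i] = avy[i] + c1 * (vy[i] - avy[i]);
      }
    }
    for (int i = 0; i < n; ++i) { sys.x[i] += 0.5 * dt * vx[i]; sys.y[i] += 0.5 * dt * vy[i]; }
    t = t0 + s * dt;
    bool rec = (s % record_every == 0);
    pot = sys.forces(t, rec, s);
    for (int i = 0; i < n; ++i) { vx[i] += 0.5 * dt * sys.fx[i]; vy[i] += 0.5 * dt * sys.fy[i]; }
    if (rec) {
      for (int i = 0; i < n; ++i)
        if (!R_finite(sys.x[i]) || !R_finite(sys.y[i]))
          stop("simulation unstable: non-finite position at step %ld (bead %d)", s, i + 1);
      record(frame++);
    }
  }

  NumericMatrix outp(n, 2), outv(n, 2);
  for (int i = 0; i < n; ++i) {
    outp(i, 0) = sys.x[i]; outp(i, 1) = sys.y[i];
    outv(i, 0) = vx[i]; outv(i, 1) = vy[i];
  }
  List out = List::create(
    _["pos"] = outp, _["vel"] = outv, _["times"] = times,
    _["kinetic"] = ekin, _["potential"] = epot,
    _["anchor_fx"] = afx, _["anchor_fy"] = afy,
    _["anchor_x"] = aax, _["anchor_y"] = aay);
  if (record_frames) {
    frames.attr("dim") = IntegerVector::create(n, 2, (int)n_frames);
    out["frames"] = frames;
  }
  return out;
}

// Rolling-ball background: grey erosion then dilation with a ball-shaped
// (non-flat, height sqrt(r^2 - d^2)) structuring element, as in the classic
// background-subtraction method for uneven illumination.
// [[Rcpp::export]]
NumericMatrix cpp_rolling_ball(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  int w = radius;
  std::vector<double> ball((2 * w + 1) * (2 * w + 1));
  std::vector<int> ok((2 * w + 1) * (2 * w + 1));
  for (int dy = -w; dy <= w; ++dy) for (int dx = -w; dx <= w; ++dx) {
    int idx = (dy + w) * (2 * w + 1) + (dx + w);
    double d2 = (double)dx * dx + (double)dy * dy;
    if (d2 <= (double)radius * radius) {
      ball[idx] = std::sqrt((double)radius * radius - d2);
      ok[idx] = 1;
    } else ok[idx] = 0;
  }
  NumericMatrix ero(nr, nc), bg(nr, nc);
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) {
    double m = R_PosInf;
    for (int dy = -w; dy <= w; ++dy) {
      int jj = j + dy;
      if (jj < 0 || jj >= nc) continue;
      for (int dx = -w; dx <= w; ++dx) {
        int ii = i + dx;
        if (ii < 0 || ii >= nr) continue;
        int idx = (dy + w) * (2 * w + 1) + (dx + w);
        if (!ok[idx]) continue;
        double v = img(ii, jj) - ball[idx];
        if (v < m) m = v;
      }
    }
    ero(i, j) = m;
  }
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) {
    double m = R_NegInf;
    for (int dy = -w; dy <= w; ++dy) {
      int jj = j + dy;
      if (jj < 0 || jj >= nc) continue;
      for (int dx = -w; dx <= w; ++dx) {
        int ii = i + dx;
        if (ii < 0 || ii >= nr) continue;
        int idx = (dy + w) * (2 * w + 1) + (dx + w);
        if (!ok[idx]) continue;
        double v = ero(ii, jj) + ball[idx];
        if (v > m) m = v;
      }
    }
    bg(i, j) = m;
  }
  return bg;
}
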