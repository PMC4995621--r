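// Compiled time-stepping core: lattice fields (diffusion / deposit / pooled
// consumption) and the three agent behaviors, driven from R via an external
// pointer.  All randomness comes from one std::mt19937_64 stream seeded from
// R, with hand-rolled bounded draws so event traces are identical across
// platforms (std::uniform_int_distribution is not portable).
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <array>
#include <random>
#include <cmath>
#include <algorithm>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
static inline double rng_unif(std::mt19937_64 &g) {
  return (g() >> 11) * (1.0 / 9007199254740992.0); // 53-bit mantissa
}
static inline int rng_int(std::mt19937_64 &g, int n) { // uniform on [0, n)
  if (n <= 1) return 0;
  uint64_t un = (uint64_t)n, x, r;
  do { x = g(); r = x % un; } while (x - r > UINT64_MAX - un + 1);
  return (int)r;
}

// ----------------------------------------------------------- diffusion ----
// Separable random-walk expectation kernel: per axis each site keeps 1/3 and
// sends 1/3 to each in-bounds axis neighbor; the share that would cross the
// boundary stays put (reflecting).  Composition over x,y,z equals the uniform
// self+26-Moore-neighbor kernel (stay probability 1/27) at interior sites.
static void diffuse_axis(const std::vector<double> &in, std::vector<double> &out,
                         int n, int stride, int nlines, const int *line0) {
  const double w = 1.0 / 3.0;
  for (int l = 0; l < nlines; ++l) {
    int base = line0[l];
    if (n == 1) { out[base] = in[base]; continue; }
    for (int i = 0; i < n; ++i) {
      int idx = base + i * stride;
      double v = in[idx] * w;
      double acc = v; // stay share
      if (i > 0) acc += in[idx - stride] * w; else acc += v;     // reflect
      if (i < n - 1) acc += in[idx + stride] * w; else acc += v; // reflect
      out[idx] = acc;
    }
  }
}

static void diffuse_once(std::vector<double> &a, std::vector<double> &buf,
                         int nx, int ny, int nz,
                         const std::vector<int> &linesX,
                         const std::vector<int> &linesY,
                         const std::vector<int> &linesZ) {
  diffuse_axis(a, buf, nx, 1, (int)linesX.size(), linesX.data());
  diffuse_axis(buf, a, ny, nx, (int)linesY.size(), linesY.data());
  diffuse_axis(a, buf, nz, nx * ny, (int)linesZ.size(), linesZ.data());
  a.swap(buf);
}

static void make_lines(int nx, int ny, int nz,
                       std::vector<int> &lx, std::vector<int> &ly, std::vector<int> &lz) {
  lx.clear(); ly.clear(); lz.clear();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) lx.push_back(y * nx + z * nx * ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) ly.push_back(x + z * nx * ny);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) lz.push_back(x + y * nx);
}

// 26 Moore offsets ordered by distance class (faces, edges, corners) so the
// pooled-consumption rule can take nearest-first.
static const int OFF[26][3] = {
  {-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1},
  {-1,-1,0},{-1,1,0},{1,-1,0},{1,1,0},{-1,0,-1},{-1,0,1},{1,0,-1},{1,0,1},
  {0,-1,-1},{0,-1,1},{0,1,-1},{0,1,1},
  {-1,-1,-1},{-1,-1,1},{-1,1,-1},{-1,1,1},{1,-1,-1},{1,-1,1},{1,1,-1},{1,1,1}
};
static const int CLASS_END[3] = {6, 18, 26}; // offsets [0,6) faces, [6,18) edges, [18,26) corners

// Pooled nearest-first uptake: site itself, then face / edge / corner
// neighbors; within a distance class mass is taken proportionally.
static double consume_pooled(std::vector<double> &f, int nx, int ny, int nz,
                             int x, int y, int z, double req) {
  if (req <= 0) return 0.0;
  double need = req;
  long idx = x + (long)nx * (y + (long)ny * z);
  double here = f[idx];
  if (here > 0) {
    double take = std::min(here, need);
    f[idx] -= take; need -= take;
    if (need <= 1e-15) return req;
  }
  int start = 0;
  for (int c = 0; c < 3; ++c) {
    long ids[12]; int nid = 0; double avail = 0.0;
    for (int k = start; k < CLASS_END[c]; ++k) {
      int xx = x + OFF[k][0], yy = y + OFF[k][1], zz = z + OFF[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      long j = xx + (long)nx * (yy + (long)ny * zz);
      if (f[j] > 0) { ids[nid++] = j; avail += f[j]; }
    }
    start = CLASS_END[c];
    if (avail <= 0) continue;
    double take = std::min(avail, need);
    double frac = take / avail;
    for (int k = 0; k < nid; ++k) f[ids[k]] -= f[ids[k]] * frac;
    need -= take;
    if (need <= 1e-15) break;
  }
  return req - std::max(need, 0.0);
}

// ----------------------------------------------------------- parameters ---
struct Pars {
  double oxySec, vegfSec, switchThr, branchThr, oxyNeed, fibNeed, minVegf,
         fgfSec, hgfSec, hgfBoost, hgfThr, bindCap, bindFloor, cafProb,
         cafVegfFrac, ecmRate, baseMot, oxyBackground, decay[4];
  int dsteps[4];
  int hypoxia, anoxia, pulsePeriod, actWindow, branchWindow, starveLimit,
      prolifPeriod, cafRadius, vesselDistance, vegfDeficitLimit, matureAge,
      sproutPeriod;
  bool angiogenesis, proliferative, keepNecrotic;
};

enum Kind { TUMOR = 0, ENDO = 1, FIBRO = 2 };
// tumor state: 0 normal 1 hypoxic 2 necrotic
// endo role:   0 quiescent 1 stalk 2 tip
// fibro state: 0 resting 1 caf
enum EvType { EV_ACTIVATION = 0, EV_BRANCH = 1, EV_DIVISION = 2, EV_NECROSIS = 3,
              EV_ANASTOMOSIS = 4, EV_CAF = 5, EV_EC_DEATH = 6 };
static const char *EV_NAMES[] = {"activation", "branch", "division", "necrosis",
                                 "anastomosis", "caf_conversion", "ec_death"};

struct Event { int tick, type, cid, x, y, z; };

struct Sim {
  int nx, ny, nz;
  Pars P;
  std::mt19937_64 rng;
  long tick = 0;

  std::vector<double> ox, vegf, fgf, hgf, ecm, buf;
  std::vector<int> occ; // -1 empty, else cell index
  std::vector<int> linesX, linesY, linesZ;

  // cell arena (all kinds)
  std::vector<int> kind, x, y, z, state, deficit, clk, starve, vessel, pulseClk,
      birth;
  std::vector<uint8_t> alive, inhibited, newly;
  // endothelial VEGF-binding ring buffers
  std::vector<std::vector<double>> ring;
  std::vector<double> winSum, brSum;
  std::vector<int> ringPos;

  std::vector<std::vector<int>> vessels; // ordered member cell indices
  std::vector<int> vesselParent;
  std::vector<std::array<int,2>> junctions; // anastomosis (cell, other cell)

  std::vector<Event> events;
  std::vector<std::array<double, 12>> ts;

  // mass ledger per species (0 ox 1 vegf 2 fgf 3 hgf)
  double massInit[4] = {0, 0, 0, 0}, massDep[4] = {0, 0, 0, 0},
         massCons[4] = {0, 0, 0, 0}, massNow[4] = {0, 0, 0, 0},
         massDec[4] = {0, 0, 0, 0};

  long idx(int xx, int yy, int zz) const {
    return xx + (long)nx * (yy + (long)ny * zz);
  }
  bool inb(int xx, int yy, int zz) const {
    return xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz;
  }
  void log(int type, int cid) {
    events.push_back({(int)tick, type, cid, x[cid], y[cid], z[cid]});
  }

  int addCell(int k, int cx, int cy, int cz) {
    int id = (int)kind.size();
    kind.push_back(k); x.push_back(cx); y.push_back(cy); z.push_back(cz);
    state.push_back(0); deficit.push_back(0); clk.push_back(P.prolifPeriod);
    starve.push_back(0); vessel.push_back(-1); pulseClk.push_back(0);
    alive.push_back(1); inhibited.push_back(0); newly.push_back(0);
    birth.push_back((int)tick);
    ring.emplace_back(); winSum.push_back(0); brSum.push_back(0); ringPos.push_back(0);
    // quiescent founders integrate over the full activation window; cells
    // spawned later can only branch, so they carry the short branch ring
    if (k == ENDO) ring[id].assign(tick == 0 ? P.actWindow : P.branchWindow, 0.0);
    occ[idx(cx, cy, cz)] = id;
    return id;
  }

  void deposit(std::vector<double> &f, int s, long at, double amt) {
    f[at] += amt; massDep[s] += amt; massNow[s] += amt;
  }
  double consume(std::vector<double> &f, int s, int cx, int cy, int cz, double req) {
    double g = consume_pooled(f, nx, ny, nz, cx, cy, cz, req);
    massCons[s] += g; massNow[s] -= g;
    return g;
  }

  // uniformly random empty Moore neighbor, or -1
  int randomEmptyNeighbor(int cx, int cy, int cz, int *ox_, int *oy_, int *oz_) {
    int cand[26]; int nc = 0;
    for (int k = 0; k < 26; ++k) {
      int xx = cx + OFF[k][0], yy = cy + OFF[k][1], zz = cz + OFF[k][2];
      if (!inb(xx, yy, zz)) continue;
      if (occ[idx(xx, yy, zz)] < 0) cand[nc++] = k;
    }
    if (nc == 0) return -1;
    int k = cand[rng_int(rng, nc)];
    *ox_ = cx + OFF[k][0]; *oy_ = cy + OFF[k][1]; *oz_ = cz + OFF[k][2];
    return k;
  }

  // argmax-field empty neighbor (ties uniform; all-zero -> uniform empty), -1 if none
  int bestEmptyNeighbor(const std::vector<double> &f, int cx, int cy, int cz,
                        int *ox_, int *oy_, int *oz_) {
    int cand[26]; int nc = 0; double best = -1.0;
    for (int k = 0; k < 26; ++k) {
      int xx = cx + OFF[k][0], yy = cy + OFF[k][1], zz = cz + OFF[k][2];
      if (!inb(xx, yy, zz)) continue;
      long j = idx(xx, yy, zz);
      if (occ[j] >= 0) continue;
      double v = f[j];
      if (v > best + 1e-12) { best = v; nc = 0; cand[nc++] = k; }
      else if (v > best - 1e-12) cand[nc++] = k;
    }
    if (nc == 0) return -1;
    int k = cand[rng_int(rng, nc)];
    *ox_ = cx + OFF[k][0]; *oy_ = cy + OFF[k][1]; *oz_ = cz + OFF[k][2];
    return k;
  }

  // ------------------------------------------------------- agent steps ----
  void tumorStep(int i) {
    if (state[i] == 2) return; // necrotic: inert forever
    double g = consume(ox, 0, x[i], y[i], z[i], P.oxyNeed);
    bool enough = g + 1e-9 >= P.oxyNeed;
    if (enough) {
      deficit[i] = 0;
      if (state[i] == 1) { state[i] = 0; pulseClk[i] = 0; } // hypoxia is reversible
    } else {
      deficit[i] += 1;
      if (deficit[i] >= P.anoxia) { state[i] = 2; log(EV_NECROSIS, i); return; }
      if (state[i] == 0 && deficit[i] >= P.hypoxia) { state[i] = 1; pulseClk[i] = 0; }
    }
    long at = idx(x[i], y[i], z[i]);
    if (state[i] == 1 && deficit[i] < P.vegfDeficitLimit) {
      // hypoxic (but not yet moribund): pulsed VEGF
      if (pulseClk[i] % P.pulsePeriod == 0) deposit(vegf, 1, at, P.vegfSec);
      pulseClk[i] += 1;
    }
    if (P.fgfSec > 0) deposit(fgf, 2, at, P.fgfSec);
    // the division clock advances only on fed ticks: growth costs nutrients
    if (state[i] == 0 && P.proliferative && enough) {
      if (clk[i] > 0) clk[i] -= 1;
      if (clk[i] <= 0) {
        int tx, ty, tz;
        if (randomEmptyNeighbor(x[i], y[i], z[i], &tx, &ty, &tz) >= 0) {
          int child = addCell(TUMOR, tx, ty, tz);
          int period = P.prolifPeriod;
          if (P.hgfBoost > 1 && hgf[at] > P.hgfThr)
            period = std::max(1, (int)std::lround(period / P.hgfBoost));
          clk[i] = period; clk[child] = period;
          log(EV_DIVISION, child);
        }
      }
    }
    if (P.baseMot > 0) {
      double p = P.baseMot * (1.0 - ecm[at]);
      if (p > 0 && rng_unif(rng) < p) {
        int tx, ty, tz;
        if (randomEmptyNeighbor(x[i], y[i], z[i], &tx, &ty, &tz) >= 0) {
          occ[at] = -1; x[i] = tx; y[i] = ty; z[i] = tz;
          occ[idx(tx, ty, tz)] = i;
        }
      }
    }
  }

  void pushWindow(int i, double bound) {
    int W = (int)ring[i].size(), B = P.branchWindow;
    int p = ringPos[i];
    if (W > B) winSum[i] += bound - ring[i][p];
    int leaveB = p - B; if (leaveB < 0) leaveB += W;
    brSum[i] += bound - ring[i][leaveB];
    ring[i][p] = bound;
    ringPos[i] = (p + 1) % W;
  }

  void inhibitNeighbors(int i) {
    for (int k = 0; k < 26; ++k) {
      int xx = x[i] + OFF[k][0], yy = y[i] + OFF[k][1], zz = z[i] + OFF[k][2];
      if (!inb(xx, yy, zz)) continue;
      int j = occ[idx(xx, yy, zz)];
      if (j >= 0 && kind[j] == ENDO && alive[j]) inhibited[j] = 1;
    }
  }

  void spawnEndo(int parent, int tx, int ty, int tz, int ves, bool asTip) {
    int id = addCell(ENDO, tx, ty, tz);
    newly[id] = 1; vessel[id] = ves;
    state[id] = asTip ? 2 : 1;
    vessels[ves].push_back(id);
  }

  void killDistal(int i) {
    int v = vessel[i];
    if (v < 0) { // safety: lone cell
      occ[idx(x[i], y[i], z[i])] = -1; alive[i] = 0; log(EV_EC_DEATH, i); return;
    }
    std::vector<int> &mem = vessels[v];
    size_t from = 0;
    for (size_t k = 0; k < mem.size(); ++k) if (mem[k] == i) { from = k; break; }
    for (size_t k = from; k < mem.size(); ++k) {
      int j = mem[k];
      if (!alive[j] || !newly[j]) continue;
      occ[idx(x[j], y[j], z[j])] = -1; alive[j] = 0; log(EV_EC_DEATH, j);
    }
    mem.erase(std::remove_if(mem.begin(), mem.end(),
                             [&](int j) { return !alive[j]; }), mem.end());
  }

  double pooledAvail(const std::vector<double> &f, int cx, int cy, int cz) {
    double tot = f[idx(cx, cy, cz)];
    for (int k = 0; k < 26; ++k) {
      int xx = cx + OFF[k][0], yy = cy + OFF[k][1], zz = cz + OFF[k][2];
      if (inb(xx, yy, zz)) tot += f[idx(xx, yy, zz)];
    }
    return tot;
  }

  void endoStep(int i) {
    long at = idx(x[i], y[i], z[i]);
    // receptor floor: trace VEGF below the pooled floor is not bound at all
    double avail = pooledAvail(vegf, x[i], y[i], z[i]);
    double bound = 0.0;
    if (avail >= P.bindFloor)
      bound = consume(vegf, 1, x[i], y[i], z[i], P.bindCap);
    pushWindow(i, bound);
    if (P.oxySec > 0) deposit(ox, 0, at, P.oxySec);
    if (state[i] == 0 && P.angiogenesis && !inhibited[i] && winSum[i] >= P.switchThr) {
      state[i] = 2; // quiescent -> tip
      log(EV_ACTIVATION, i);
      inhibitNeighbors(i);
      // the sprout it will grow is a daughter vessel of the one it sits on
      int nv = (int)vessels.size();
      vessels.push_back({});
      vesselParent.push_back(vessel[i]);
      vessel[i] = nv;
    }
    if (state[i] == 2 &&
        (P.sproutPeriod <= 1 || rng_unif(rng) < 1.0 / P.sproutPeriod)) {
      // tip: elongate along the VEGF gradient (one site per ~SproutPeriod
      // ticks: endothelial proliferation is slower than tip migration)
      int cand[26]; int nc = 0; double best = -1.0;
      int par = vessel[i] >= 0 ? vesselParent[vessel[i]] : -1;
      for (int k = 0; k < 26; ++k) {
        int xx = x[i] + OFF[k][0], yy = y[i] + OFF[k][1], zz = z[i] + OFF[k][2];
        if (!inb(xx, yy, zz)) continue;
        long j = idx(xx, yy, zz);
        int o = occ[j];
        bool ok = (o < 0) ||
                  (kind[o] == ENDO && alive[o] && vessel[o] != vessel[i] &&
                   (par < 0 || vessel[o] != par));
        if (!ok) continue;
        if (vegf[j] > best + 1e-12) { best = vegf[j]; nc = 0; cand[nc++] = k; }
        else if (vegf[j] > best - 1e-12) cand[nc++] = k;
      }
      if (nc > 0) {
        int k = cand[rng_int(rng, nc)];
        int tx = x[i] + OFF[k][0], ty = y[i] + OFF[k][1], tz = z[i] + OFF[k][2];
        int o = occ[idx(tx, ty, tz)];
        if (o >= 0) { // met another vessel: anastomose, stop elongating
          state[i] = 1;
          junctions.push_back({i, o});
          log(EV_ANASTOMOSIS, i);
          if (kind[o] == ENDO && state[o] == 2) state[o] = 1;
        } else {
          spawnEndo(i, tx, ty, tz, vessel[i], true);
          state[i] = 1; // old tip becomes stalk
        }
      } // no target: skip elongation this tick
    }
    if (state[i] == 1 && P.angiogenesis && !inhibited[i] &&
        brSum[i] >= P.branchThr) {
      int tx, ty, tz; // branch: second tip starts a daughter vessel
      if (bestEmptyNeighbor(vegf, x[i], y[i], z[i], &tx, &ty, &tz) >= 0) {
        int nv = (int)vessels.size();
        vessels.push_back({});
        vesselParent.push_back(vessel[i]);
        spawnEndo(i, tx, ty, tz, nv, true);
        log(EV_BRANCH, i);
        std::fill(ring[i].begin(), ring[i].end(), 0.0); // refractory
        winSum[i] = 0; brSum[i] = 0;
        // delta-notch: a branch point suppresses sprouting around itself
        inhibited[i] = 1;
        inhibitNeighbors(i);
      }
    }
    if (newly[i] && tick - birth[i] > P.matureAge) newly[i] = 0; // matured
    if (newly[i]) { // young sprout cells need continued local VEGF
      if (avail + 1e-12 < P.minVegf) {
        starve[i] += 1;
        if (starve[i] >= P.starveLimit) { killDistal(i); return; }
      } else starve[i] = 0;
    }
  }

  // living-tumor bounding box, refreshed each tick for the CAF distance test
  int tbb[6] = {0, 0, 0, 0, 0, 0};
  bool anyTumor = false;

  bool tumorWithin(int cx, int cy, int cz, int r) {
    if (!anyTumor) return false;
    if (cx < tbb[0] - r || cx > tbb[1] + r || cy < tbb[2] - r ||
        cy > tbb[3] + r || cz < tbb[4] - r || cz > tbb[5] + r) return false;
    long r2 = (long)r * r;
    for (int zz = std::max(0, cz - r); zz <= std::min(nz - 1, cz + r); ++zz)
      for (int yy = std::max(0, cy - r); yy <= std::min(ny - 1, cy + r); ++yy)
        for (int xx = std::max(0, cx - r); xx <= std::min(nx - 1, cx + r); ++xx) {
          int o = occ[idx(xx, yy, zz)];
          if (o >= 0 && kind[o] == TUMOR && state[o] != 2) {
            long dx = xx - cx, dy = yy - cy, dz = zz - cz;
            if (dx * dx + dy * dy + dz * dz <= r2) return true;
          }
        }
    return false;
  }

  void fibroStep(int i) {
    double g = consume(ox, 0, x[i], y[i], z[i], P.fibNeed);
    bool enough = g + 1e-9 >= P.fibNeed;
    if (enough) deficit[i] = 0; else deficit[i] += 1;
    long at = idx(x[i], y[i], z[i]);
    if (state[i] == 0) {
      if (enough && P.cafProb > 0 && tumorWithin(x[i], y[i], z[i], P.cafRadius) &&
          rng_unif(rng) < P.cafProb) {
        state[i] = 1; pulseClk[i] = 0;
        log(EV_CAF, i);
      }
      return;
    }
    // CAF: pulsed VEGF scaled by own hypoxia counter, HGF, ECM degradation,
    // chemotaxis up the FGF gradient
    if (pulseClk[i] % P.pulsePeriod == 0) {
      double frac = std::min(1.0, (double)deficit[i] / (double)P.hypoxia);
      if (frac > 0) deposit(vegf, 1, at, frac * P.cafVegfFrac * P.vegfSec);
    }
    pulseClk[i] += 1;
    if (P.hgfSec > 0) deposit(hgf, 3, at, P.hgfSec);
    if (P.ecmRate > 0) {
      ecm[at] *= (1.0 - P.ecmRate);
      for (int k = 0; k < 26; ++k) {
        int xx = x[i] + OFF[k][0], yy = y[i] + OFF[k][1], zz = z[i] + OFF[k][2];
        if (inb(xx, yy, zz)) ecm[idx(xx, yy, zz)] *= (1.0 - P.ecmRate);
      }
    }
    int tx, ty, tz;
    if (bestEmptyNeighbor(fgf, x[i], y[i], z[i], &tx, &ty, &tz) >= 0) {
      // move only if it does not descend the gradient
      if (fgf[idx(tx, ty, tz)] + 1e-12 >= fgf[at]) {
        occ[at] = -1; x[i] = tx; y[i] = ty; z[i] = tz;
        occ[idx(tx, ty, tz)] = i;
      }
    }
  }

  void refreshTumorBB() {
    anyTumor = false;
    for (size_t i = 0; i < kind.size(); ++i) {
      if (!alive[i] || kind[i] != TUMOR || state[i] == 2) continue;
      if (!anyTumor) {
        tbb[0] = tbb[1] = x[i]; tbb[2] = tbb[3] = y[i]; tbb[4] = tbb[5] = z[i];
        anyTumor = true;
      } else {
        tbb[0] = std::min(tbb[0], x[i]); tbb[1] = std::max(tbb[1], x[i]);
        tbb[2] = std::min(tbb[2], y[i]); tbb[3] = std::max(tbb[3], y[i]);
        tbb[4] = std::min(tbb[4], z[i]); tbb[5] = std::max(tbb[5], z[i]);
      }
    }
  }

  void recordTs() {
    double living = 0, hyp = 0, nec = 0, endo = 0, act = 0, caf = 0, fib = 0;
    for (size_t i = 0; i < kind.size(); ++i) {
      if (!alive[i]) continue;
      switch (kind[i]) {
      case TUMOR:
        if (state[i] == 2) nec += 1;
        else { living += 1; if (state[i] == 1) hyp += 1; }
        break;
      case ENDO:
        endo += 1; if (state[i] != 0) act += 1; break;
      case FIBRO:
        fib += 1; if (state[i] == 1) caf += 1; break;
      }
    }
    double branches = 0;
    for (auto it = events.rbegin(); it != events.rend() && it->tick == (int)tick; ++it)
      if (it->type == EV_BRANCH) branches += 1;
    ts.push_back({(double)tick, living, hyp, nec, endo, act, caf, fib,
                  massNow[1], massNow[0], branches,
                  (double)events.size()});
  }

  void decayField(std::vector<double> &f, int s) {
    double lam = P.decay[s];
    if (lam <= 0) return;
    double lost = 0.0, keep = 1.0 - lam;
    for (double &v : f) { lost += v * lam; v *= keep; }
    massDec[s] += lost; massNow[s] -= lost;
  }

  void step() {
    tick += 1; // events and the time-series row of this step carry the new tick
    for (int k = 0; k < P.dsteps[0]; ++k) diffuse_once(ox, buf, nx, ny, nz, linesX, linesY, linesZ);
    for (int k = 0; k < P.dsteps[1]; ++k) diffuse_once(vegf, buf, nx, ny, nz, linesX, linesY, linesZ);
    for (int k = 0; k < P.dsteps[2]; ++k) diffuse_once(fgf, buf, nx, ny, nz, linesX, linesY, linesZ);
    for (int k = 0; k < P.dsteps[3]; ++k) diffuse_once(hgf, buf, nx, ny, nz, linesX, linesY, linesZ);
    decayField(ox, 0); decayField(vegf, 1);
    decayField(fgf, 2); decayField(hgf, 3);
    refreshTumorBB();
    int n0 = (int)kind.size();
    std::vector<int> order; order.reserve(n0);
    for (int i = 0; i < n0; ++i) if (alive[i]) order.push_back(i);
    for (int i = (int)order.size() - 1; i > 0; --i)
      std::swap(order[i], order[rng_int(rng, i + 1)]);
    for (int i : order) {
      if (!alive[i]) continue; // may have been pruned by a vessel death
      switch (kind[i]) {
      case TUMOR: tumorStep(i); break;
      case ENDO: endoStep(i); break;
      case FIBRO: fibroStep(i); break;
      }
    }
    recordTs();
  }
};

// ------------------------------------------------------------- builders ---
static Pars parsFromList(List p) {
  Pars P;
  P.oxySec = as<double>(p["OxygenSecretionAmount"]);
  P.vegfSec = as<double>(p["VEGFSecretionAmount"]);
  P.switchThr = as<double>(p["AngiogenicSwitchThreshold"]);
  P.branchThr = as<double>(p["BranchThreshold"]);
  P.oxyNeed = as<double>(p["OxygenNeedPerStep"]);
  P.fibNeed = as<double>(p["FibroblastOxygenNeed"]);
  P.minVegf = as<double>(p["EndothelialMinVEGF"]);
  P.fgfSec = as<double>(p["FGFSecretionAmount"]);
  P.hgfSec = as<double>(p["HGFSecretionAmount"]);
  P.hgfBoost = as<double>(p["HGFBoost"]);
  P.hgfThr = as<double>(p["HGFThreshold"]);
  P.bindCap = as<double>(p["VEGFBindingCapacity"]);
  P.bindFloor = as<double>(p["VEGFBindingFloor"]);
  P.vegfDeficitLimit = as<int>(p["VEGFSecretionDeficitLimit"]);
  P.matureAge = as<int>(p["EndothelialMaturationAge"]);
  P.sproutPeriod = as<int>(p["SproutPeriod"]);
  P.decay[0] = as<double>(p["OxygenDecayRate"]);
  P.decay[1] = as<double>(p["VEGFDecayRate"]);
  P.decay[2] = as<double>(p["FGFDecayRate"]);
  P.decay[3] = as<double>(p["HGFDecayRate"]);
  P.dsteps[0] = as<int>(p["OxygenDiffusionSteps"]);
  P.dsteps[1] = as<int>(p["VEGFDiffusionSteps"]);
  P.dsteps[2] = as<int>(p["FGFDiffusionSteps"]);
  P.dsteps[3] = as<int>(p["HGFDiffusionSteps"]);
  P.cafProb = as<double>(p["CAFBaseProb"]);
  P.cafVegfFrac = as<double>(p["CAFVEGFFraction"]);
  P.ecmRate = as<double>(p["ECMDegradationRate"]);
  P.baseMot = as<double>(p["BaseMotility"]);
  P.oxyBackground = as<double>(p["OxygenBackground"]);
  P.hypoxia = as<int>(p["HypoxiaLevel"]);
  P.anoxia = as<int>(p["AnoxiaLevel"]);
  P.pulsePeriod = as<int>(p["VEGFPulsePeriod"]);
  P.actWindow = as<int>(p["ActivationWindow"]);
  P.branchWindow = as<int>(p["BranchWindow"]);
  P.starveLimit = as<int>(p["StarvationLimit"]);
  P.prolifPeriod = as<int>(p["ProliferationPeriod"]);
  P.cafRadius = as<int>(p["CAFRadius"]);
  P.vesselDistance = as<int>(p["InitialVesselDistance"]);
  P.angiogenesis = true;
  P.proliferative = true;
  P.keepNecrotic = true;
  return P;
}

// [[Rcpp::export(name = ".sim_create_cpp")]]
SEXP sim_create_cpp(List params, List scen) {
  Sim *S = new Sim();
  S->P = parsFromList(params);
  IntegerVector dims = scen["dims"];
  S->nx = dims[0]; S->ny = dims[1]; S->nz = dims[2];
  long n = (long)S->nx * S->ny * S->nz;
  S->P.angiogenesis = as<bool>(scen["angiogenesis"]);
  S->P.proliferative = as<bool>(scen["proliferative"]);
  S->rng.seed((uint64_t)as<double>(scen["seed"]) * 2654435761u + 0x9e3779b97f4a7c15ull);
  S->ox.assign(n, S->P.oxyBackground);
  S->vegf.assign(n, 0.0); S->fgf.assign(n, 0.0); S->hgf.assign(n, 0.0);
  S->ecm.assign(n, 1.0); S->buf.assign(n, 0.0);
  S->occ.assign(n, -1);
  make_lines(S->nx, S->ny, S->nz, S->linesX, S->linesY, S->linesZ);
  S->massInit[0] = S->massNow[0] = S->P.oxyBackground * (double)n;

  int cx = S->nx / 2, cy = S->ny / 2, cz = S->nz / 2;
  if (as<bool>(scen["tumor"])) S->addCell(TUMOR, cx, cy, cz);

  // initial vasculature: straight chains of quiescent endothelial cells
  std::string mode = as<std::string>(scen["vessel_mode"]);
  int nv = as<int>(scen["n_vessels"]);
  std::vector<std::array<int,2>> cols; // (x, y) of vertical vessel columns
  if (mode == "distance") {
    int d = S->P.vesselDistance;
    if (cx - d < 0 || cx + d >= S->nx || cy - d < 0 || cy + d >= S->ny)
      stop("vessel distance %d does not fit in a %dx%dx%d world", d, S->nx, S->ny, S->nz);
    cols = {{cx - d, cy}, {cx + d, cy}, {cx, cy - d}, {cx, cy + d}};
  } else if (mode == "border") {
    cols = {{1, 1}, {S->nx - 2, 1}, {1, S->ny - 2}, {S->nx - 2, S->ny - 2}};
  } else { // random columns
    for (int k = 0; k < nv; ++k)
      cols.push_back({1 + rng_int(S->rng, S->nx - 2), 1 + rng_int(S->rng, S->ny - 2)});
  }
  int vlen = as<int>(scen["vessel_length"]);
  if (vlen <= 0 || vlen > S->nz) vlen = S->nz;
  int z0 = std::max(0, cz - vlen / 2);
  int z1 = std::min(S->nz - 1, z0 + vlen - 1);
  for (auto &c : cols) {
    int v = (int)S->vessels.size();
    S->vessels.push_back({});
    S->vesselParent.push_back(-1);
    for (int zz = z0; zz <= z1; ++zz) {
      if (S->occ[S->idx(c[0], c[1], zz)] >= 0) continue;
      int id = S->addCell(ENDO, c[0], c[1], zz);
      S->vessel[id] = v;
      S->vessels[v].push_back(id);
    }
  }

  // fibroblasts scattered in a shell around the tumor seed
  int nf = as<int>(scen["n_fibroblasts"]);
  NumericVector shell = scen["fibroblast_shell"];
  double r0 = shell[0], r1 = shell[1];
  int placed = 0, guard = 0;
  while (placed < nf && guard < nf * 1000) {
    ++guard;
    int fx = rng_int(S->rng, S->nx), fy = rng_int(S->rng, S->ny), fz = rng_int(S->rng, S->nz);
    double dx = fx - cx, dy = fy - cy, dz = fz - cz;
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < r0 || r > r1) continue;
    if (S->occ[S->idx(fx, fy, fz)] >= 0) continue;
    S->addCell(FIBRO, fx, fy, fz);
    ++placed;
  }
  S->recordTs(); // tick-0 row
  XPtr<Sim> ptr(S, true);
  return ptr;
}

// [[Rcpp::export(name = ".sim_step_cpp")]]
void sim_step_cpp(SEXP sp, int n) {
  XPtr<Sim> S(sp);
  for (int i = 0; i < n; ++i) S->step();
}

// [[Rcpp::export(name = ".sim_tick_cpp")]]
int sim_tick_cpp(SEXP sp) { XPtr<Sim> S(sp); return (int)S->tick; }

// [[Rcpp::export(name = ".sim_timeseries_cpp")]]
DataFrame sim_timeseries_cpp(SEXP sp) {
  XPtr<Sim> S(sp);
  size_t n = S->ts.size();
  IntegerVector tick(n); NumericVector liv(n), hyp(n), nec(n), endo(n), act(n),
      caf(n), fib(n), vm(n), om(n), br(n);
  for (size_t i = 0; i < n; ++i) {
    const auto &r = S->ts[i];
    tick[i] = (int)r[0]; liv[i] = r[1]; hyp[i] = r[2]; nec[i] = r[3];
    endo[i] = r[4]; act[i] = r[5]; caf[i] = r[6]; fib[i] = r[7];
    vm[i] = r[8]; om[i] = r[9]; br[i] = r[10];
  }
  return DataFrame::create(
      _["tick"] = tick, _["tumor_living"] = liv, _["tumor_hypoxic"] = hyp,
      _["tumor_necrotic"] = nec, _["endothelial"] = endo,
      _["endothelial_activated"] = act, _["caf"] = caf, _["fibroblast"] = fib,
      _["vegf_mass"] = vm, _["oxygen_mass"] = om, _["branch_events"] = br);
}

// [[Rcpp::export(name = ".sim_events_cpp")]]
DataFrame sim_events_cpp(SEXP sp) {
  XPtr<Sim> S(sp);
  size_t n = S->events.size();
  IntegerVector tick(n), cid(n), ex(n), ey(n), ez(n);
  CharacterVector type(n);
  for (size_t i = 0; i < n; ++i) {
    const Event &e = S->events[i];
    tick[i] = e.tick; type[i] = EV_NAMES[e.type]; cid[i] = e.cid;
    ex[i] = e.x; ey[i] = e.y; ez[i] = e.z;
  }
  return DataFrame::create(_["tick"] = tick, _["event"] = type, _["cell"] = cid,
                           _["x"] = ex, _["y"] = ey, _["z"] = ez);
}

// [[Rcpp::export(name = ".sim_cells_cpp")]]
DataFrame sim_cells_cpp(SEXP sp) {
  XPtr<Sim> S(sp);
  std::vector<int> keep;
  for (size_t i = 0; i < S->kind.size(); ++i) if (S->alive[i]) keep.push_back((int)i);
  size_t n = keep.size();
  IntegerVector id(n), cx(n), cy(n), cz(n), ves(n);
  CharacterVector kd(n), st(n);
  static const char *TS[] = {"normal", "hypoxic", "necrotic"};
  static const char *ES[] = {"quiescent", "stalk", "tip"};
  static const char *FS[] = {"resting", "caf"};
  static const char *KS[] = {"tumor", "endothelial", "fibroblast"};
  for (size_t i = 0; i < n; ++i) {
    int j = keep[i];
    id[i] = j; kd[i] = KS[S->kind[j]];
    st[i] = S->kind[j] == TUMOR ? TS[S->state[j]]
          : S->kind[j] == ENDO ? ES[S->state[j]] : FS[S->state[j]];
    cx[i] = S->x[j]; cy[i] = S->y[j]; cz[i] = S->z[j];
    ves[i] = S->kind[j] == ENDO ? S->vessel[j] : NA_INTEGER;
  }
  return DataFrame::create(_["id"] = id, _["kind"] = kd, _["state"] = st,
                           _["x"] = cx, _["y"] = cy, _["z"] = cz, _["vessel"] = ves);
}

// [[Rcpp::export(name = ".sim_fields_cpp")]]
List sim_fields_cpp(SEXP sp) {
  XPtr<Sim> S(sp);
  long n = (long)S->nx * S->ny * S->nz;
  IntegerVector dim = IntegerVector::create(S->nx, S->ny, S->nz);
  auto wrapf = [&](const std::vector<double> &v) {
    NumericVector out(v.begin(), v.end());
    out.attr("dim") = dim;
    return out;
  };
  (void)n;
  return List::create(_["oxygen"] = wrapf(S->ox), _["vegf"] = wrapf(S->vegf),
                      _["fgf"] = wrapf(S->fgf), _["hgf"] = wrapf(S->hgf),
                      _["ecm"] = wrapf(S->ecm));
}

// [[Rcpp::export(name = ".sim_vessels_cpp")]]
List sim_vessels_cpp(SEXP sp) {
  XPtr<Sim> S(sp);
  size_t nv = S->vessels.size();
  List mem(nv);
  IntegerVector parent(nv);
  for (size_t v = 0; v < nv; ++v) {
    mem[v] = IntegerVector(S->vessels[v].begin(), S->vessels[v].end());
    parent[v] = S->vesselParent[v] < 0 ? NA_INTEGER : S->vesselParent[v];
  }
  size_t nj = S->junctions.size();
  IntegerVector ja(nj), jb(nj);
  for (size_t j = 0; j < nj; ++j) { ja[j] = S->junctions[j][0]; jb[j] = S->junctions[j][1]; }
  return List::create(_["members"] = mem, _["parent"] = parent,
                      _["junction_a"] = ja, _["junction_b"] = jb);
}

// [[Rcpp::export(name = ".sim_ledger_cpp")]]
DataFrame sim_ledger_cpp(SEXP sp) {
  XPtr<Sim> S(sp);
  CharacterVector sa = CharacterVector::create("oxygen", "vegf", "fgf", "hgf");
  NumericVector ini(4), dep(4), con(4), dec(4), now(4), actual(4);
  const std::vector<double> *fs[4] = {&S->ox, &S->vegf, &S->fgf, &S->hgf};
  for (int s = 0; s < 4; ++s) {
    ini[s] = S->massInit[s]; dep[s] = S->massDep[s]; con[s] = S->massCons[s];
    dec[s] = S->massDec[s]; now[s] = S->massNow[s];
    double tot = 0; for (double v : *fs[s]) tot += v;
    actual[s] = tot;
  }
  return DataFrame::create(_["species"] = sa, _["initial"] = ini,
                           _["deposited"] = dep, _["consumed"] = con,
                           _["decayed"] = dec, _["tracked"] = now,
                           _["in_field"] = actual);
}

// ------------------------------------------------ standalone field ops ----
// These back the R-level field API so the interactive surface and the
// simulation share one diffusion/consumption implementation.

// [[Rcpp::export(name = ".field_diffuse_cpp")]]
NumericVector field_diffuse_cpp(NumericVector a, int steps) {
  IntegerVector dim = a.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(a.begin(), a.end()), buf(v.size());
  std::vector<int> lx, ly, lz;
  make_lines(nx, ny, nz, lx, ly, lz);
  for (int s = 0; s < steps; ++s) diffuse_once(v, buf, nx, ny, nz, lx, ly, lz);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export(name = ".field_consume_cpp")]]
List field_consume_cpp(NumericVector a, IntegerVector pos, double requested) {
  IntegerVector dim = a.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(a.begin(), a.end());
  double g = consume_pooled(v, nx, ny, nz, pos[0], pos[1], pos[2], requested);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return List::create(_["granted"] = g, _["amounts"] = out);
}
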