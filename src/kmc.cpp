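// Kinetic Monte Carlo core for the hexagonal lattice-gas composite model,
// plus the exact pair-count kernel used by the pair distribution functions.
//
// Geometry: triangular (hexagonally coordinated) lattice on a sheared torus.
// Axial coordinates (q, r) with q in [0, nq), r in [0, nr); site position
// x = a (q + r/2), y = a r sqrt(3)/2. Every site has 6 nearest neighbours at
// distance a; periodic wrap uses the minimum-image convention over candidate
// lattice translations.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double SQRT3_2 = 0.8660254037844386;

struct Off {
  int dq, dr;
  double dx, dy;    // minimum-image displacement
  double dist;
  double ux, uy;    // unit vector
};

// minimum-image displacement for a lattice offset (dq, dr)
static void min_image(int dq, int dr, int nq, int nr, double a,
                      double &dx, double &dy) {
  double best = 1e300, bx = 0, by = 0;
  for (int sq = -2; sq <= 2; ++sq) {
    for (int sr = -2; sr <= 2; ++sr) {
      double q = dq + (double)sq * nq;
      double r = dr + (double)sr * nr;
      double x = a * (q + 0.5 * r);
      double y = a * r * SQRT3_2;
      double d2 = x * x + y * y;
      if (d2 < best) { best = d2; bx = x; by = y; }
    }
  }
  dx = bx; dy = by;
}

// Enumerates every distinct lattice translation (one representative per
// residue class, so offsets are never double-counted on small tori) whose
// minimum-image distance is within rmax.
static std::vector<Off> build_offsets(int nq, int nr, double a, double rmax,
                                      bool exclude_origin = true) {
  std::vector<Off> out;
  for (int dq = 0; dq < nq; ++dq) {
    for (int dr = 0; dr < nr; ++dr) {
      if (exclude_origin && dq == 0 && dr == 0) continue;
      double dx, dy;
      min_image(dq, dr, nq, nr, a, dx, dy);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d <= rmax + 1e-9) {
        Off o;
        o.dq = dq; o.dr = dr; o.dx = dx; o.dy = dy; o.dist = d;
        o.ux = dx / d; o.uy = dy / d;
        out.push_back(o);
      }
    }
  }
  return out;
}

// Fenwick tree over per-filament total rates: O(log n) update and sampling
struct Fenwick {
  int n;
  std::vector<double> tree;
  std::vector<double> val;
  void init(int n_) {
    n = n_;
    tree.assign(n + 1, 0.0);
    val.assign(n, 0.0);
  }
  void set(int i, double v) {
    double d = v - val[i];
    val[i] = v;
    for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += d;
  }
  double total() const { return tree.empty() ? 0.0 : sum(n); }
  double sum(int i) const {  // sum of val[0..i-1]
    double s = 0;
    for (int j = i; j > 0; j -= j & (-j)) s += tree[j];
    return s;
  }
  // largest index such that prefix sum < u; returns index whose value covers u
  int sample(double u) const {
    int pos = 0;
    double acc = 0;
    int logn = 1;
    while ((1 << logn) <= n) ++logn;
    for (int k = logn; k >= 0; --k) {
      int nxt = pos + (1 << k);
      if (nxt <= n && acc + tree[nxt] < u) {
        pos = nxt;
        acc += tree[nxt];
      }
    }
    return pos;  // 0-based filament index
  }
};

struct Sim {
  int nq, nr, nsites, nfil;
  double a, kBT, zeta0, zeta_xl, F_m, p_eng, p_pull, orient_jitter,
      orient_thresh;
  std::vector<Off> nn;      // 6 nearest neighbours
  std::vector<Off> reach;   // interaction shell
  std::vector<int> occ;                 // site -> filament id or -1
  std::vector<int> fsite, fkind, fneng; // per filament
  std::vector<double> ftheta, ffx, ffy;
  std::vector<double> rate6;            // nfil * 6
  Fenwick fen;
  std::unordered_map<long long, signed char> eng;  // pair -> +1 pull / -1 push
  std::vector<int> stamp;
  int epoch = 0;

  long long key(int f, int g) const {
    int lo = f < g ? f : g, hi = f < g ? g : f;
    return (long long)lo * nfil + hi;
  }

  // Quenched motor polarity: whether an engaged motor pulls or pushes a
  // given pair is set by the pair's relative filament polarity, which does
  // not change during a run. Drawn from a salted hash of the pair id so it
  // is reproducible, uniform, and stable across re-encounters.
  unsigned long long salt = 0;
  signed char pair_sign(int f, int g) const {
    unsigned long long z = (unsigned long long)key(f, g) + salt +
                           0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z = z ^ (z >> 31);
    double u = (double)(z >> 11) / 9007199254740992.0;  // uniform in [0,1)
    return (u < p_pull) ? 1 : -1;
  }
  int shift_site(int s, int dq, int dr) const {
    int q = s % nq, r = s / nq;
    int q2 = q + dq; q2 %= nq; if (q2 < 0) q2 += nq;
    int r2 = r + dr; r2 %= nr; if (r2 < 0) r2 += nr;
    return r2 * nq + q2;
  }

  void sample_pair(int f, int g) {
    if (fkind[f] != 2 || fkind[g] != 2 || p_eng <= 0) return;
    if (unif_rand() < p_eng) eng[key(f, g)] = pair_sign(f, g);
  }

  void recompute_force(int f) {
    double fx = 0, fy = 0;
    int ne = 0;
    if (fkind[f] == 2 && !eng.empty()) {
      int s = fsite[f];
      for (size_t k = 0; k < reach.size(); ++k) {
        int t = shift_site(s, reach[k].dq, reach[k].dr);
        int g = occ[t];
        if (g < 0 || fkind[g] != 2) continue;
        std::unordered_map<long long, signed char>::const_iterator it =
            eng.find(key(f, g));
        if (it == eng.end()) continue;
        ++ne;
        // pull (+1): force on f toward g; push (-1): away
        fx += it->second * F_m * reach[k].ux;
        fy += it->second * F_m * reach[k].uy;
      }
    }
    ffx[f] = fx; ffy[f] = fy; fneng[f] = ne;
  }

  void update_orientation(int f) {
    double mag = std::sqrt(ffx[f] * ffx[f] + ffy[f] * ffy[f]);
    if (mag > orient_thresh) {
      ftheta[f] = std::atan2(ffy[f], ffx[f]);
      if (ftheta[f] < 0) ftheta[f] += 2 * M_PI;
    } else {
      double th = ftheta[f] + norm_rand() * orient_jitter;
      while (th >= 2 * M_PI) th -= 2 * M_PI;
      while (th < 0) th += 2 * M_PI;
      ftheta[f] = th;
    }
  }

  void recompute_rates(int f) {
    double zeta = zeta0 + zeta_xl * fneng[f];
    double D = kBT / zeta;
    double base = D / (a * a);
    double tot = 0;
    int s = fsite[f];
    for (int d = 0; d < 6; ++d) {
      int t = shift_site(s, nn[d].dq, nn[d].dr);
      double r = 0;
      if (occ[t] < 0) {
        double fpar = ffx[f] * nn[d].ux + ffy[f] * nn[d].uy;
        r = base + (fpar > 0 ? fpar / (zeta * a) : 0.0);
      }
      rate6[f * 6 + d] = r;
      tot += r;
    }
    fen.set(f, tot);
  }

  void full_refresh() {
    eng.clear();
    if (p_eng > 0) {
      for (int f = 0; f < nfil; ++f) {
        if (fkind[f] != 2) continue;
        int s = fsite[f];
        for (size_t k = 0; k < reach.size(); ++k) {
          int t = shift_site(s, reach[k].dq, reach[k].dr);
          int g = occ[t];
          if (g > f && fkind[g] == 2) sample_pair(f, g);
        }
      }
    }
    for (int f = 0; f < nfil; ++f) {
      recompute_force(f);
      update_orientation(f);
    }
    for (int f = 0; f < nfil; ++f) recompute_rates(f);
  }
};

// [[Rcpp::export]]
List kmc_run_cpp(IntegerVector kinds0, NumericVector theta0, int nq, int nr,
                 double a, double reach_um, double kBT, double zeta0,
                 double zeta_xl, double F_m, double p_eng, double p_pull,
                 double tau_m, NumericVector snap_times, double T_s,
                 double orient_thresh, double orient_jitter) {
  RNGScope scope;
  Sim sim;
  sim.nq = nq; sim.nr = nr; sim.nsites = nq * nr;
  sim.a = a; sim.kBT = kBT; sim.zeta0 = zeta0; sim.zeta_xl = zeta_xl;
  sim.F_m = F_m; sim.p_eng = p_eng; sim.p_pull = p_pull;
  sim.orient_thresh = orient_thresh; sim.orient_jitter = orient_jitter;
  sim.nn = build_offsets(nq, nr, a, a * 1.0001);
  if ((int)sim.nn.size() != 6) stop("lattice geometry error: expected 6 nearest neighbours, got %d", (int)sim.nn.size());
  sim.reach = build_offsets(nq, nr, a, reach_um);

  // filaments from initial occupancy
  sim.occ.assign(sim.nsites, -1);
  std::vector<int> fil_sites;
  for (int s = 0; s < sim.nsites; ++s)
    if (kinds0[s] > 0) fil_sites.push_back(s);
  sim.nfil = (int)fil_sites.size();
  sim.fsite.resize(sim.nfil); sim.fkind.resize(sim.nfil);
  sim.fneng.assign(sim.nfil, 0);
  sim.ftheta.resize(sim.nfil);
  sim.ffx.assign(sim.nfil, 0.0); sim.ffy.assign(sim.nfil, 0.0);
  sim.rate6.assign((size_t)sim.nfil * 6, 0.0);
  sim.fen.init(sim.nfil);
  for (int i = 0; i < sim.nfil; ++i) {
    int s = fil_sites[i];
    sim.fsite[i] = s; sim.fkind[i] = kinds0[s];
    sim.ftheta[i] = theta0[s];
    sim.occ[s] = i;
  }
  sim.stamp.assign(sim.nfil, -1);

  bool active = (p_eng > 0 && sim.F_m != 0);
  sim.salt = (unsigned long long)(unif_rand() * 4294967296.0) << 32 |
             (unsigned long long)(unif_rand() * 4294967296.0);
  sim.full_refresh();

  // snapshot bookkeeping
  int nsnap = snap_times.size();
  List snaps(nsnap);
  CharacterVector cn = CharacterVector::create("q", "r", "x", "y", "kind",
                                               "theta", "fx", "fy", "n_xl");
  int isnap = 0;
  double t = 0.0;
  long long n_events = 0, n_jammed = 0;

  std::vector<int> affected, dirty;
  affected.reserve(128); dirty.reserve(256);

  while (true) {
    // record any snapshots due at current time
    while (isnap < nsnap && snap_times[isnap] <= t + 1e-12) {
      NumericMatrix m(sim.nfil, 9);
      for (int f = 0; f < sim.nfil; ++f) {
        int s = sim.fsite[f];
        int q = s % nq, r = s / nq;
        m(f, 0) = q; m(f, 1) = r;
        m(f, 2) = a * (q + 0.5 * r);
        m(f, 3) = a * r * SQRT3_2;
        m(f, 4) = sim.fkind[f];
        m(f, 5) = sim.ftheta[f];
        m(f, 6) = sim.ffx[f]; m(f, 7) = sim.ffy[f];
        m(f, 8) = sim.fneng[f];
      }
      colnames(m) = cn;
      snaps[isnap] = List::create(_["time"] = snap_times[isnap],
                                  _["filaments"] = m);
      ++isnap;
    }
    if (t >= T_s - 1e-12) break;

    double next_boundary = T_s;
    double next_refresh = active ? (std::floor(t / tau_m + 1e-9) + 1) * tau_m
                                 : T_s + 1;
    if (next_refresh < next_boundary) next_boundary = next_refresh;
    if (isnap < nsnap && snap_times[isnap] < next_boundary)
      next_boundary = snap_times[isnap];

    double Rtot = sim.fen.total();
    double t_event = (Rtot > 1e-14) ? t + exp_rand() / Rtot : R_PosInf;
    if (t_event >= next_boundary) {
      if (Rtot <= 1e-14) ++n_jammed;
      t = next_boundary;
      if (active && std::abs(t - next_refresh) < 1e-9) sim.full_refresh();
      continue;
    }

    // execute one hop
    t = t_event;
    double u = unif_rand() * Rtot;
    int f = sim.fen.sample(u);
    // direction
    double resid = u - sim.fen.sum(f);
    int dir = 0;
    for (; dir < 5; ++dir) {
      if (resid < sim.rate6[f * 6 + dir]) break;
      resid -= sim.rate6[f * 6 + dir];
    }
    int s0 = sim.fsite[f];
    int s1 = sim.shift_site(s0, sim.nn[dir].dq, sim.nn[dir].dr);
    if (sim.occ[s1] >= 0) continue;  // stale rate guard (should not happen)

    affected.clear(); dirty.clear();
    ++sim.epoch;
    affected.push_back(f); sim.stamp[f] = sim.epoch;

    if (sim.fkind[f] == 2 && active) {
      for (size_t k = 0; k < sim.reach.size(); ++k) {
        int tsite = sim.shift_site(s0, sim.reach[k].dq, sim.reach[k].dr);
        int g = sim.occ[tsite];
        if (g >= 0 && sim.fkind[g] == 2) {
          sim.eng.erase(sim.key(f, g));
          if (sim.stamp[g] != sim.epoch) {
            sim.stamp[g] = sim.epoch;
            affected.push_back(g);
          }
        }
      }
    }
    sim.occ[s0] = -1; sim.occ[s1] = f; sim.fsite[f] = s1;
    if (sim.fkind[f] == 2 && active) {
      for (size_t k = 0; k < sim.reach.size(); ++k) {
        int tsite = sim.shift_site(s1, sim.reach[k].dq, sim.reach[k].dr);
        int g = sim.occ[tsite];
        if (g >= 0 && g != f && sim.fkind[g] == 2) {
          sim.sample_pair(f, g);
          if (sim.stamp[g] != sim.epoch) {
            sim.stamp[g] = sim.epoch;
            affected.push_back(g);
          }
        }
      }
    }
    for (size_t i = 0; i < affected.size(); ++i) {
      sim.recompute_force(affected[i]);
      sim.update_orientation(affected[i]);
      dirty.push_back(affected[i]);
    }
    // occupancy changed at s0/s1: neighbours' hop targets changed
    for (int d = 0; d < 6; ++d) {
      int ta = sim.shift_site(s0, sim.nn[d].dq, sim.nn[d].dr);
      int tb = sim.shift_site(s1, sim.nn[d].dq, sim.nn[d].dr);
      int ga = sim.occ[ta], gb = sim.occ[tb];
      if (ga >= 0 && sim.stamp[ga] != sim.epoch) {
        sim.stamp[ga] = sim.epoch; dirty.push_back(ga);
      }
      if (gb >= 0 && gb != f && sim.stamp[gb] != sim.epoch) {
        sim.stamp[gb] = sim.epoch; dirty.push_back(gb);
      }
    }
    for (size_t i = 0; i < dirty.size(); ++i) sim.recompute_rates(dirty[i]);
    ++n_events;
  }

  return List::create(_["snapshots"] = snaps,
                      _["n_events"] = (double)n_events,
                      _["n_jammed"] = (double)n_jammed,
                      _["n_filaments"] = sim.nfil);
}

// Exact pair counting on the periodic hexagonal lattice.
// kinds: nsites vector (0 empty / 1 actin / 2 microtubule), row-major over r.
// Bins are uniform with width `binw` centred at k*binw (k = 1..nbins).
// Returns per-bin counts N_i(r) summed over reference filaments of each kind,
// and the per-bin maximum neighbour count N(r) (sites per bin).
// [[Rcpp::export]]
List count_pairs_cpp(IntegerVector kinds, int nq, int nr, double a,
                     double rmax, double binw) {
  int nbins = (int)std::floor(rmax / binw + 0.5);
  std::vector<Off> offs = build_offsets(nq, nr, a, rmax + binw / 2);
  std::vector<int> obin(offs.size());
  NumericVector nmax(nbins);
  for (size_t k = 0; k < offs.size(); ++k) {
    int b = (int)std::floor(offs[k].dist / binw + 0.5);
    obin[k] = (b >= 1 && b <= nbins) ? b - 1 : -1;
    if (obin[k] >= 0) nmax[obin[k]] += 1;
  }
  // counts[bin + nbins*(ref-1) + 2*nbins*(neigh-1)]
  NumericVector counts(nbins * 4);
  int nsites = nq * nr;
  int nA = 0, nM = 0;
  for (int s = 0; s < nsites; ++s) {
    int rk = kinds[s];
    if (rk == 1) ++nA; else if (rk == 2) ++nM;
  }
  for (int s = 0; s < nsites; ++s) {
    int rk = kinds[s];
    if (rk == 0) continue;
    int q = s % nq, r = s / nq;
    for (size_t k = 0; k < offs.size(); ++k) {
      if (obin[k] < 0) continue;
      int q2 = q + offs[k].dq; q2 %= nq; if (q2 < 0) q2 += nq;
      int r2 = r + offs[k].dr; r2 %= nr; if (r2 < 0) r2 += nr;
      int nk = kinds[r2 * nq + q2];
      if (nk == 0) continue;
      counts[obin[k] + nbins * (rk - 1) + 2 * nbins * (nk - 1)] += 1;
    }
  }
  counts.attr("dim") = IntegerVector::create(nbins, 2, 2);
  return List::create(_["counts"] = counts, _["nmax"] = nmax,
                      _["n_actin"] = nA, _["n_mt"] = nM,
                      _["n_sites"] = nsites,
                      _["r"] = NumericVector(nbins));
}

// site positions and nearest-neighbour distances, used by lattice builders
// [[Rcpp::export]]
List hex_geometry_cpp(int nq, int nr, double a) {
  int nsites = nq * nr;
  NumericVector x(nsites), y(nsites);
  for (int s = 0; s < nsites; ++s) {
    int q = s % nq, r = s / nq;
    x[s] = a * (q + 0.5 * r);
    y[s] = a * r * SQRT3_2;
  }
  std::vector<Off> nn = build_offsets(nq, nr, a, a * 1.0001);
  NumericMatrix nnd((int)nn.size(), 3);
  for (size_t k = 0; k < nn.size(); ++k) {
    nnd(k, 0) = nn[k].dq; nnd(k, 1) = nn[k].dr; nnd(k, 2) = nn[k].dist;
  }
  return List::create(_["x"] = x, _["y"] = y, _["nn"] = nnd);
}

// minimum-image displacement between positions given in axial offsets
// [[Rcpp::export]]
NumericMatrix min_image_cpp(IntegerVector dq, IntegerVector dr, int nq, int nr,
                            double a) {
  int n = dq.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double dx, dy;
    min_image(dq[i], dr[i], nq, nr, a, dx, dy);
    out(i, 0) = dx; out(i, 1) = dy;
    out(i, 2) = std::sqrt(dx * dx + dy * dy);
  }
  return out;
}
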