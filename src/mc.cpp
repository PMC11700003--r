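#include "core.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// History-by-history accumulator: per-cell running sums with lazy per-history
// flushing via last-history tags.
// ---------------------------------------------------------------------------
struct HistTally {
  // cache-line-friendly cell: per-cell running sums flushed lazily when a
  // new history first touches the cell
  struct Cell { double sum, sumsq, cur; int last; };
  std::vector<Cell> cells;
  explicit HistTally(size_t n) : cells(n, Cell{0.0, 0.0, 0.0, -1}) {}
  inline void score(size_t i, double val, int hist) {
    Cell& c = cells[i];
    if (c.last != hist) {
      c.sum += c.cur;
      c.sumsq += c.cur * c.cur;
      c.cur = val;
      c.last = hist;
    } else {
      c.cur += val;
    }
  }
  void flush() {
    for (Cell& c : cells) {
      c.sum += c.cur;
      c.sumsq += c.cur * c.cur;
      c.cur = 0.0;
      c.last = -1;
    }
  }
  inline double sum(size_t i) const { return cells[i].sum; }
  inline double sumsq(size_t i) const { return cells[i].sumsq; }
};

struct Counters {
  double emitted = 0, absorbed = 0, escaped = 0, cutoff = 0, rrLost = 0;
};

// sample a spectral line index from cumulative weights
static inline int sampleLine(Rng& rng, const std::vector<double>& cdf) {
  double u = rng.u01();
  int lo = 0, hi = (int)cdf.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// ---------------------------------------------------------------------------
// Generation-resolved photon Monte Carlo in a voxel phantom with collision
// kerma scored by a track-length estimator.  Generation classes: prim
// (bkn = 0), 1sc (bkn = 1), msc (bkn >= 2).  With forcing enabled, every
// flight scores the expected track-length kerma along the whole ray to the
// phantom boundary and the collision point is sampled from the interaction
// density truncated to the phantom (weight times 1 - exp(-tau_max));
// photoelectric absorption is handled by survival weighting and low-weight
// photons are terminated by Russian roulette.  Without forcing the walk is
// analog.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_mc(IntegerVector dims, double v, NumericVector origin,
                IntegerVector med0, NumericVector rho, NumericVector src,
                NumericVector specE, NumericVector specW, int nhist,
                double seed, bool forcing, List physPack,
                IntegerVector region, int nregions, bool rayleigh,
                bool bknRayleigh, NumericVector specShell,
                NumericVector specEdges, bool voxelVariance) {
  Grid g;
  g.n[0] = dims[0]; g.n[1] = dims[1]; g.n[2] = dims[2];
  g.v = v;
  g.o[0] = origin[0]; g.o[1] = origin[1]; g.o[2] = origin[2];
  const Phys phys = physFromList(physPack);
  const int nv = g.nvox();
  const double vvol = v * v * v;
  const double ECUT = 1e-3;           // 1 keV photon cutoff
  const double WMIN = 0.1;            // Russian roulette threshold
  const bool haveRegion = region.size() == nv && nregions > 0;

  HistTally tal(voxelVariance ? (size_t)nv * 3 : 1);
  std::vector<double> plain(voxelVariance ? 1 : (size_t)nv * 3, 0.0);
  HistTally reg(haveRegion ? (size_t)nregions * 4 : 1);
  Counters cnt;
  Rng rng((uint64_t)seed * 2685821657736338717ULL + 1442695040888963407ULL);

  std::vector<double> cdf(specE.size());
  double acc = 0;
  for (int i = 0; i < specE.size(); ++i) { acc += specW[i]; cdf[i] = acc; }
  for (int i = 0; i < specE.size(); ++i) cdf[i] /= acc;

  std::vector<Crossing> cr;
  cr.reserve(g.n[0] + g.n[1] + g.n[2] + 3);
  std::vector<double> mulBuf;
  // packed per-voxel record: one cache line fetch per crossing
  struct VoxInfo { float rho; uint16_t med; uint16_t reg; };
  std::vector<VoxInfo> vinfo((size_t)nv);
  for (int i = 0; i < nv; ++i) {
    vinfo[i].rho = (float)rho[i];
    vinfo[i].med = (uint16_t)med0[i];
    vinfo[i].reg = (uint16_t)(haveRegion ? region[i] : 0);
  }
  // optional energy-fluence spectral tally of collisions in a radial shell
  const bool haveSpec = specShell.size() == 2 && specEdges.size() > 1;
  const int nsb = haveSpec ? specEdges.size() - 1 : 0;
  NumericMatrix specFl(std::max(nsb, 1), 3);
  std::vector<double> muM(phys.nmed), muenM(phys.nmed), fpM(phys.nmed),
      fiM(phys.nmed), fcM(phys.nmed);

  for (int h = 0; h < nhist; ++h) {
    int line = sampleLine(rng, cdf);
    double E = specE[line], w = 1.0;
    int bkn = 0;
    double p[3] = {src[0], src[1], src[2]};
    // isotropic emission
    double dz = 2.0 * rng.u01() - 1.0;
    double phi = 2.0 * M_PI * rng.u01();
    double st = std::sqrt(std::max(0.0, 1.0 - dz * dz));
    double d[3] = {st * std::cos(phi), st * std::sin(phi), dz};
    cnt.emitted += E;

    for (;;) {
      if (E < ECUT) {  // local deposit of sub-cutoff photon
        int ijk[3];
        if (g.locate(p, ijk)) {
          int vx = g.idx(ijk[0], ijk[1], ijk[2]);
          int cls = bkn > 2 ? 2 : bkn;
          double dep = w * E / (rho[vx] * vvol);
          if (voxelVariance) tal.score((size_t)vx * 3 + cls, dep, h);
          else plain[(size_t)vx * 3 + cls] += dep;
          if (haveRegion && region[vx] > 0) {
            reg.score((size_t)(region[vx] - 1) * 4 + cls, dep, h);
            reg.score((size_t)(region[vx] - 1) * 4 + 3, dep, h);
          }
        }
        cnt.cutoff += w * E;
        break;
      }
      const int cls = bkn > 2 ? 2 : bkn;
      // per-flight medium coefficient tables at the current energy
      for (int m = 0; m < phys.nmed; ++m)
        phys.lookup(E, m, muM[m], muenM[m], fpM[m], fiM[m], fcM[m]);

      int hitIdx = -1;
      double hitT = 0.0;
      // Expected-value scoring walks the whole ray and forces a collision:
      // used for primary flights, where it removes nearly all variance.
      // Scattered flights use analog free paths with literal track-length
      // scoring, which touches far fewer voxels per flight; photoelectric
      // survival weighting and Russian roulette still apply below.
      if (forcing && bkn == 0) {
        traceCrossings(g, p, d, 1e300, cr);  // ray to the phantom boundary
        if (cr.empty()) { cnt.escaped += w * E; break; }
        // expected-value scoring along the ray + forced collision; the
        // walk stops once the remaining transmission is negligible
        double t = 0.0, eprev = 1.0;
        size_t used = 0;
        mulBuf.resize(cr.size());
        for (const Crossing& c : cr) {
          const VoxInfo& vi = vinfo[c.idx];
          double mul = muM[vi.med] * vi.rho;
          mulBuf[used++] = mul;
          double dtau = mul * c.len;
          double enext = eprev * std::exp(-dtau);
          double fl = (mul > 1e-30) ? (eprev - enext) / mul : eprev * c.len;
          double dep = w * E * muenM[vi.med] * fl / vvol;
          if (voxelVariance) tal.score((size_t)c.idx * 3 + cls, dep, h);
          else plain[(size_t)c.idx * 3 + cls] += dep;
          if (vi.reg > 0) {
            reg.score((size_t)(vi.reg - 1) * 4 + cls, dep, h);
            reg.score((size_t)(vi.reg - 1) * 4 + 3, dep, h);
          }
          eprev = enext;
          t += c.len;
          if (eprev < 1e-5) break;  // transmission exhausted
        }
        double pInt = 1.0 - eprev;
        cnt.escaped += w * E * eprev;
        if (pInt < 1e-12) break;  // effectively transparent: all escaped
        // sample collision optical depth from the truncated distribution
        double tauStar = -std::log1p(-rng.u01() * pInt);
        w *= pInt;
        double tacc = 0.0;
        t = 0.0;
        for (size_t q = 0; q < used; ++q) {
          const Crossing& c = cr[q];
          double mul = mulBuf[q];
          double dtau = mul * c.len;
          if (tacc + dtau >= tauStar || q == used - 1) {
            hitIdx = c.idx;
            hitT = t + (mul > 1e-30 ?
              std::min((tauStar - tacc) / mul, c.len) : c.len);
            break;
          }
          tacc += dtau;
          t += c.len;
        }
      } else {
        // analog flight: incremental grid walk with actual track-length
        // scoring, terminated at the sampled optical depth or the boundary
        double tauStar = -std::log(rng.u01());
        double tacc = 0.0, t = 0.0;
        int ijk[3];
        if (!g.locate(p, ijk)) { cnt.escaped += w * E; break; }
        double tmax[3], tdel[3];
        int stp[3];
        for (int a = 0; a < 3; ++a) {
          if (std::fabs(d[a]) < 1e-14) {
            stp[a] = 0; tmax[a] = 1e300; tdel[a] = 1e300;
          } else if (d[a] > 0) {
            stp[a] = 1;
            tmax[a] = ((g.o[a] + (ijk[a] + 1) * g.v) - p[a]) / d[a];
            tdel[a] = g.v / d[a];
          } else {
            stp[a] = -1;
            tmax[a] = ((g.o[a] + ijk[a] * g.v) - p[a]) / d[a];
            tdel[a] = -g.v / d[a];
          }
        }
        for (;;) {
          int a = 0;
          if (tmax[1] < tmax[a]) a = 1;
          if (tmax[2] < tmax[a]) a = 2;
          double len = tmax[a] - t;
          const int idx = g.idx(ijk[0], ijk[1], ijk[2]);
          const VoxInfo& vi = vinfo[idx];
          double mul = muM[vi.med] * vi.rho;
          double dtau = mul * len;
          bool hit = tacc + dtau >= tauStar && mul > 1e-30;
          double seg = hit ? (tauStar - tacc) / mul : len;
          double dep = w * E * muenM[vi.med] * seg / vvol;
          if (voxelVariance) tal.score((size_t)idx * 3 + cls, dep, h);
          else plain[(size_t)idx * 3 + cls] += dep;
          if (vi.reg > 0) {
            reg.score((size_t)(vi.reg - 1) * 4 + cls, dep, h);
            reg.score((size_t)(vi.reg - 1) * 4 + 3, dep, h);
          }
          if (hit) {
            hitIdx = idx;
            hitT = t + seg;
            break;
          }
          tacc += dtau;
          t = tmax[a];
          ijk[a] += stp[a];
          if (ijk[a] < 0 || ijk[a] >= g.n[a]) break;  // escaped
          tmax[a] += tdel[a];
        }
        if (hitIdx < 0) { cnt.escaped += w * E; break; }
      }

      // move to the collision site
      p[0] += hitT * d[0]; p[1] += hitT * d[1]; p[2] += hitT * d[2];
      if (haveSpec) {
        double rx = p[0] - src[0], ry = p[1] - src[1], rz = p[2] - src[2];
        double rr = std::sqrt(rx * rx + ry * ry + rz * rz);
        if (rr >= specShell[0] && rr < specShell[1] &&
            E > specEdges[0] && E < specEdges[nsb]) {
          int lo = 0, hi = nsb;
          while (lo < hi - 1) {
            int mid = (lo + hi) / 2;
            if (specEdges[mid] <= E) lo = mid; else hi = mid;
          }
          specFl(lo, cls) += w * E / (muM[med0[hitIdx]] * rho[hitIdx]);
        }
      }
      double fp = fpM[med0[hitIdx]], fi = fiM[med0[hitIdx]],
             fc = fcM[med0[hitIdx]];
      if (!rayleigh) {  // renormalize with coherent scattering disabled
        double s = fp + fi;
        fp /= s; fi /= s; fc = 0.0;
      }
      if (forcing) {
        cnt.absorbed += w * E * fp;  // survival weighting of photoelectric
        w *= (1.0 - fp);
        if (w <= 0) break;
        double u = rng.u01() * (fi + fc);
        if (u < fi) {
          double eps = sampleKN(rng, E / MEC2);
          cnt.absorbed += w * E * (1.0 - eps);
          E *= eps;
          double ct = 1.0 - (1.0 / eps - 1.0) * MEC2 / (E / eps);
          rotateDirection(rng, d, ct);
          ++bkn;
        } else {
          rotateDirection(rng, d, sampleThomson(rng));
          if (bknRayleigh) ++bkn;
        }
      } else {
        double u = rng.u01();
        if (u < fp) { cnt.absorbed += w * E; break; }
        if (u < fp + fi) {
          double eps = sampleKN(rng, E / MEC2);
          cnt.absorbed += w * E * (1.0 - eps);
          E *= eps;
          double ct = 1.0 - (1.0 / eps - 1.0) * MEC2 / (E / eps);
          rotateDirection(rng, d, ct);
          ++bkn;
        } else {
          rotateDirection(rng, d, sampleThomson(rng));
          if (bknRayleigh) ++bkn;
        }
      }
      if (w < WMIN) {  // Russian roulette
        if (rng.u01() < w / WMIN) {
          w = WMIN;
        } else {
          cnt.rrLost += w * E;
          break;
        }
      }
    }
  }
  if (voxelVariance) tal.flush();
  if (haveRegion) reg.flush();

  NumericMatrix kerma(nv, 3), sumsq(nv, 3);
  for (int cls = 0; cls < 3; ++cls)
    for (int i = 0; i < nv; ++i) {
      if (voxelVariance) {
        kerma(i, cls) = tal.sum((size_t)i * 3 + cls);
        sumsq(i, cls) = tal.sumsq((size_t)i * 3 + cls);
      } else {
        kerma(i, cls) = plain[(size_t)i * 3 + cls];
      }
    }
  List regOut;
  if (haveRegion) {
    NumericMatrix rs(nregions, 4), rq(nregions, 4);
    for (int r = 0; r < nregions; ++r)
      for (int cls = 0; cls < 4; ++cls) {
        rs(r, cls) = reg.sum((size_t)r * 4 + cls);
        rq(r, cls) = reg.sumsq((size_t)r * 4 + cls);
      }
    regOut = List::create(_["sum"] = rs, _["sumsq"] = rq);
  }
  return List::create(
      _["kerma"] = kerma, _["sumsq"] = sumsq, _["regions"] = regOut,
      _["specFl"] = specFl,
      _["counters"] = NumericVector::create(
          _["emitted"] = cnt.emitted, _["absorbed"] = cnt.absorbed,
          _["escaped"] = cnt.escaped, _["cutoff"] = cnt.cutoff,
          _["rrLost"] = cnt.rrLost),
      _["nhist"] = (double)nhist);
}

// ---------------------------------------------------------------------------
// Forced-interaction kernel MC in infinite water.  An incident photon
// travelling along +z is forced to interact at the origin; the scattered
// photon(s) are tracked analogically and collision kerma deposits are
// tallied per unit released scatter energy in (radius, polar angle) bins.
//   mode 1 (1sc kernel): tally only the first-scatter photon's own deposit
//     at its next interaction site; record the 1sc emission spectrum at the
//     vertex and pass the remaining energy on as 'continued'.
//   mode 2 (msc kernel): the incident photon plays the role of a 1sc
//     photon; all deposits of the full descendant cascade (generations
//     >= 2) are tallied, and the fluence spectrum of those photons is
//     accumulated with collision-density weights w/mu(E).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_kernel_mc(int mode, NumericVector specE, NumericVector specW,
                   NumericVector specHW, int nhist, double seed,
                   List physPack, NumericVector rEdges, int ncones,
                   NumericVector specOutEdges, bool rayleigh) {
  const Phys phys = physFromList(physPack);
  const int nr = rEdges.size() - 1;
  const double rmax = rEdges[nr];
  NumericMatrix tally(nr, ncones);
  NumericVector escCone(ncones);
  const int nso = specOutEdges.size() - 1;
  NumericVector specOut(nso);
  double released = 0, deposited = 0, escaped = 0, cutoff = 0, continued = 0;
  const double ECUT = 1e-3;
  Rng rng((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 12345ULL);

  std::vector<double> cdf(specE.size());
  double acc = 0;
  for (int i = 0; i < specE.size(); ++i) { acc += specW[i]; cdf[i] = acc; }
  for (int i = 0; i < specE.size(); ++i) cdf[i] /= acc;

  // log-spaced radial bin lookup
  auto rbin = [&](double r) -> int {
    if (r >= rmax) return -1;
    int lo = 0, hi = nr;  // edges index
    while (lo < hi - 1) {
      int mid = (lo + hi) / 2;
      if (rEdges[mid] <= r) lo = mid; else hi = mid;
    }
    return lo;
  };
  auto sbin = [&](double E) -> int {
    if (E <= specOutEdges[0] || E >= specOutEdges[nso]) return -1;
    int lo = 0, hi = nso;
    while (lo < hi - 1) {
      int mid = (lo + hi) / 2;
      if (specOutEdges[mid] <= E) lo = mid; else hi = mid;
    }
    return lo;
  };
  auto coneOf = [&](const double pos[3]) -> int {
    double r = std::sqrt(pos[0] * pos[0] + pos[1] * pos[1] + pos[2] * pos[2]);
    double ct = r > 1e-12 ? pos[2] / r : 1.0;
    int ic = (int)((1.0 - ct) * 0.5 * ncones);
    if (ic < 0) ic = 0;
    if (ic >= ncones) ic = ncones - 1;
    return ic;
  };
  auto deposit = [&](const double pos[3], double e) {
    double r = std::sqrt(pos[0] * pos[0] + pos[1] * pos[1] + pos[2] * pos[2]);
    int ir = rbin(r);
    if (ir < 0) { escaped += e; return; }
    double ct = r > 1e-12 ? pos[2] / r : 1.0;
    int ic = (int)((1.0 - ct) * 0.5 * ncones);
    if (ic < 0) ic = 0;
    if (ic >= ncones) ic = ncones - 1;
    tally(ir, ic) += e;
    deposited += e;
  };

  for (int h = 0; h < nhist; ++h) {
    int line = sampleLine(rng, cdf);
    double E0 = specE[line];
    if (specHW[line] > 0) E0 += (rng.u01() - 0.5) * 2.0 * specHW[line];
    // forced vertex at the origin, incident along +z
    double murho, muenrho, fp, fi, fc;
    phys.lookup(E0, 0, murho, muenrho, fp, fi, fc);
    if (!rayleigh) { double s = fp + fi; fp /= s; fi /= s; fc = 0.0; }
    double u = rng.u01();
    if (u < fp) continue;  // photoelectric vertex: no scattered photon
    double d[3] = {0.0, 0.0, 1.0};
    double E1;
    if (u < fp + fi) {
      double eps = sampleKN(rng, E0 / MEC2);
      E1 = eps * E0;
      double ct = 1.0 - (1.0 / eps - 1.0) * MEC2 / E0;
      rotateDirection(rng, d, ct);
    } else {
      E1 = E0;
      rotateDirection(rng, d, sampleThomson(rng));
    }
    released += E1;
    if (mode == 1) {
      int is = sbin(E1);
      if (is >= 0) specOut[is] += E1;  // energy-weighted emission
      if (E1 < ECUT) { cutoff += E1; continue; }
      // fly to the next interaction; deposit the collision kerma there
      double s = -std::log(rng.u01()) / (phys.mu(E1, 0) * 1.0);
      double pos[3] = {s * d[0], s * d[1], s * d[2]};
      double r = std::sqrt(pos[0] * pos[0] + pos[1] * pos[1] +
                           pos[2] * pos[2]);
      bool out = r >= rmax;
      phys.lookup(E1, 0, murho, muenrho, fp, fi, fc);
      if (!rayleigh) { double ss = fp + fi; fp /= ss; fi /= ss; fc = 0.0; }
      double u2 = rng.u01();
      double dep = 0.0, cont = 0.0;
      if (u2 < fp) {
        dep = E1;
      } else if (u2 < fp + fi) {
        double eps = sampleKN(rng, E1 / MEC2);
        dep = E1 * (1.0 - eps);
        cont = E1 * eps;
      } else {
        cont = E1;  // coherent: all energy moves on as generation 2
      }
      continued += cont;
      if (out) {  // beyond the tally radius: book the deposit per cone
        escCone[coneOf(pos)] += dep;
        escaped += dep;
      } else if (dep > 0) {
        deposit(pos, dep);
      }
    } else {
      // full cascade of generations >= 2
      double E = E1, pos[3] = {0.0, 0.0, 0.0};
      for (;;) {
        if (E < ECUT) { deposit(pos, E); cutoff += 0.0; break; }
        double mul = phys.mu(E, 0) * 1.0;
        double s = -std::log(rng.u01()) / mul;
        pos[0] += s * d[0]; pos[1] += s * d[1]; pos[2] += s * d[2];
        double r = std::sqrt(pos[0] * pos[0] + pos[1] * pos[1] +
                             pos[2] * pos[2]);
        if (r >= rmax) { escCone[coneOf(pos)] += E; escaped += E; break; }
        int is = sbin(E);
        if (is >= 0) specOut[is] += E / mul;  // energy-fluence spectrum
        phys.lookup(E, 0, murho, muenrho, fp, fi, fc);
        if (!rayleigh) { double ss = fp + fi; fp /= ss; fi /= ss; fc = 0.0; }
        double u2 = rng.u01();
        if (u2 < fp) { deposit(pos, E); break; }
        if (u2 < fp + fi) {
          double eps = sampleKN(rng, E / MEC2);
          deposit(pos, E * (1.0 - eps));
          double ct = 1.0 - (1.0 / eps - 1.0) * MEC2 / (E / eps);
          E *= eps;
          rotateDirection(rng, d, ct);
        } else {
          rotateDirection(rng, d, sampleThomson(rng));
        }
      }
    }
  }
  return List::create(
      _["tally"] = tally, _["specOut"] = specOut, _["escCone"] = escCone,
      _["counters"] = NumericVector::create(
          _["released"] = released, _["deposited"] = deposited,
          _["escaped"] = escaped, _["continued"] = continued,
          _["cutoff"] = cutoff),
      _["nhist"] = (double)nhist);
}
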