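#ifndef CCBRACHY_CORE_H
#define CCBRACHY_CORE_H

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

// ---------------------------------------------------------------------------
// Deterministic RNG (xoshiro256**, splitmix64 seeding).  Hand-rolled uniform
// so that streams are bit-identical across platforms and compilers.
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double u01() {  // uniform in (0,1), never exactly 0
    return ((next() >> 11) + 0.5) * 1.1102230246251565e-16;
  }
};

// ---------------------------------------------------------------------------
// Uniform cubic voxel grid
// ---------------------------------------------------------------------------
struct Grid {
  int n[3];
  double v;
  double o[3];
  inline int nvox() const { return n[0] * n[1] * n[2]; }
  inline int idx(int i, int j, int k) const {
    return i + n[0] * (j + n[1] * k);
  }
  inline bool locate(const double p[3], int ijk[3]) const {
    for (int a = 0; a < 3; ++a) {
      ijk[a] = (int)std::floor((p[a] - o[a]) / v);
      if (ijk[a] < 0 || ijk[a] >= n[a]) return false;
    }
    return true;
  }
};

struct Crossing { int idx; double len; };

// Exact incremental grid-crossing walk from p along unit direction d for at
// most maxlen (use a large value to walk to the grid boundary).  Fills `out`
// with the traversed voxels and geometric segment lengths.
inline void traceCrossings(const Grid& g, const double p[3], const double d[3],
                           double maxlen, std::vector<Crossing>& out) {
  out.clear();
  int ijk[3];
  if (!g.locate(p, ijk)) return;  // callers keep start points inside
  double tmax[3], tdel[3];
  int step[3];
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-14) {
      step[a] = 0; tmax[a] = 1e300; tdel[a] = 1e300;
    } else if (d[a] > 0) {
      step[a] = 1;
      tmax[a] = ((g.o[a] + (ijk[a] + 1) * g.v) - p[a]) / d[a];
      tdel[a] = g.v / d[a];
    } else {
      step[a] = -1;
      tmax[a] = ((g.o[a] + ijk[a] * g.v) - p[a]) / d[a];
      tdel[a] = -g.v / d[a];
    }
  }
  double t = 0.0;
  while (true) {
    int a = 0;
    if (tmax[1] < tmax[a]) a = 1;
    if (tmax[2] < tmax[a]) a = 2;
    double tn = tmax[a];
    if (tn >= maxlen) {
      if (maxlen > t) out.push_back({g.idx(ijk[0], ijk[1], ijk[2]), maxlen - t});
      return;
    }
    if (tn > t) out.push_back({g.idx(ijk[0], ijk[1], ijk[2]), tn - t});
    t = tn;
    ijk[a] += step[a];
    if (ijk[a] < 0 || ijk[a] >= g.n[a]) return;  // left the grid
    tmax[a] += tdel[a];
  }
}

// ---------------------------------------------------------------------------
// Interaction coefficient pack: log-log tables on a uniform log-energy grid
// ---------------------------------------------------------------------------
struct Phys {
  int nE, nmed;
  double le0, dle;
  const double *lmu, *lmuen, *fpho, *finc, *fcoh;  // nE x nmed column-major
  inline void lookup(double E, int med, double& murho, double& muenrho,
                     double& fp, double& fi, double& fc) const {
    double t = (std::log(E) - le0) / dle;
    if (t < 0) t = 0;
    double tm = nE - 1.000001;
    if (t > tm) t = tm;
    int i = (int)t;
    double f = t - i;
    const int off = med * nE + i;
    murho = std::exp(lmu[off] + f * (lmu[off + 1] - lmu[off]));
    muenrho = std::exp(lmuen[off] + f * (lmuen[off + 1] - lmuen[off]));
    fp = fpho[off] + f * (fpho[off + 1] - fpho[off]);
    fi = finc[off] + f * (finc[off + 1] - finc[off]);
    fc = fcoh[off] + f * (fcoh[off + 1] - fcoh[off]);
  }
  inline double mu(double E, int med) const {
    double m, me, a, b, c;
    lookup(E, med, m, me, a, b, c);
    return m;
  }
};

inline Phys physFromList(const Rcpp::List& pk) {
  Phys ph;
  ph.nE = Rcpp::as<int>(pk["nE"]);
  ph.nmed = Rcpp::as<int>(pk["nmed"]);
  ph.le0 = Rcpp::as<double>(pk["le0"]);
  ph.dle = Rcpp::as<double>(pk["dle"]);
  ph.lmu = REAL(Rcpp::as<Rcpp::NumericMatrix>(pk["lmu"]));
  ph.lmuen = REAL(Rcpp::as<Rcpp::NumericMatrix>(pk["lmuen"]));
  ph.fpho = REAL(Rcpp::as<Rcpp::NumericMatrix>(pk["fpho"]));
  ph.finc = REAL(Rcpp::as<Rcpp::NumericMatrix>(pk["finc"]));
  ph.fcoh = REAL(Rcpp::as<Rcpp::NumericMatrix>(pk["fcoh"]));
  return ph;
}

// ---------------------------------------------------------------------------
// Sampling of photon interactions
// ---------------------------------------------------------------------------
const double MEC2 = 0.5109989;  // MeV

// Klein-Nishina scattered-energy fraction eps = E'/E (Messel-Crawford
// composition-rejection, free electron).
inline double sampleKN(Rng& rng, double k) {
  double emin = 1.0 / (1.0 + 2.0 * k);
  double a1 = std::log(1.0 / emin);
  double a2 = 0.5 * (1.0 - emin * emin);
  for (;;) {
    double eps;
    if (rng.u01() * (a1 + a2) < a1)
      eps = emin * std::exp(a1 * rng.u01());
    else
      eps = std::sqrt(emin * emin + (1.0 - emin * emin) * rng.u01());
    double t = (1.0 - eps) / (k * eps);
    double sin2 = t * (2.0 - t);
    double g = 1.0 - eps * sin2 / (1.0 + eps * eps);
    if (rng.u01() <= g) return eps;
  }
}

// Thomson angular sampling (form-factor-free coherent scattering)
inline double sampleThomson(Rng& rng) {
  for (;;) {
    double mu = 2.0 * rng.u01() - 1.0;
    if (rng.u01() <= 0.5 * (1.0 + mu * mu)) return mu;
  }
}

// rotate direction d by polar angle (cost) and uniform azimuth
inline void rotateDirection(Rng& rng, double d[3], double cost) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * rng.u01();
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double dz = d[2];
  if (std::fabs(dz) > 0.99999999) {
    double sgn = dz > 0 ? 1.0 : -1.0;
    d[0] = sint * cphi;
    d[1] = sgn * sint * sphi;
    d[2] = sgn * cost;
  } else {
    double sq = std::sqrt(1.0 - dz * dz);
    double dx = d[0], dy = d[1];
    d[0] = dx * cost + sint * (dx * dz * cphi - dy * sphi) / sq;
    d[1] = dy * cost + sint * (dy * dz * cphi + dx * sphi) / sq;
    d[2] = dz * cost - sq * sint * cphi;
  }
  double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
}

#endif
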