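#include "core.h"
using namespace Rcpp;

static Grid gridFromArgs(IntegerVector dims, double v, NumericVector origin) {
  Grid g;
  g.n[0] = dims[0]; g.n[1] = dims[1]; g.n[2] = dims[2];
  g.v = v;
  g.o[0] = origin[0]; g.o[1] = origin[1]; g.o[2] = origin[2];
  return g;
}

// Optical depth between two points given per-voxel linear attenuation.
// [[Rcpp::export]]
double cpp_radiological_path(IntegerVector dims, double v,
                             NumericVector origin, NumericVector muVox,
                             NumericVector p0, NumericVector p1) {
  Grid g = gridFromArgs(dims, v, origin);
  double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double len = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (len <= 0) return 0.0;
  for (int a = 0; a < 3; ++a) d[a] /= len;
  double p[3] = {p0[0], p0[1], p0[2]};
  // nudge a starting point on the boundary into the grid
  for (int a = 0; a < 3; ++a) {
    if (p[a] <= g.o[a]) p[a] = g.o[a] + 1e-9 * g.v;
    double hi = g.o[a] + g.n[a] * g.v;
    if (p[a] >= hi) p[a] = hi - 1e-9 * g.v;
  }
  std::vector<Crossing> cr;
  traceCrossings(g, p, d, len, cr);
  double tau = 0.0;
  for (const Crossing& c : cr) tau += muVox[c.idx] * c.len;
  return tau;
}

// Density-weighted path length per medium from the source to every voxel
// center: matrix nvox x nmed of sum(rho_j * dl_j) over traversed voxels of
// each medium.  Feeds the spectral primary attenuation.
// [[Rcpp::export]]
NumericMatrix cpp_path_per_medium(IntegerVector dims, double v,
                                  NumericVector origin, IntegerVector med0,
                                  NumericVector rho, NumericVector src,
                                  int nmed) {
  Grid g = gridFromArgs(dims, v, origin);
  const int nv = g.nvox();
  NumericMatrix out(nv, nmed);
  std::vector<Crossing> cr;
  cr.reserve(g.n[0] + g.n[1] + g.n[2] + 3);
  double p[3] = {src[0], src[1], src[2]};
  int vox = 0;
  for (int k = 0; k < g.n[2]; ++k)
    for (int j = 0; j < g.n[1]; ++j)
      for (int i = 0; i < g.n[0]; ++i, ++vox) {
        double c[3] = {g.o[0] + (i + 0.5) * g.v, g.o[1] + (j + 0.5) * g.v,
                       g.o[2] + (k + 0.5) * g.v};
        double d[3] = {c[0] - p[0], c[1] - p[1], c[2] - p[2]};
        double len = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        if (len <= 0) continue;
        for (int a = 0; a < 3; ++a) d[a] /= len;
        traceCrossings(g, p, d, len, cr);
        for (const Crossing& c2 : cr)
          out(vox, med0[c2.idx]) += rho[c2.idx] * c2.len;
      }
  return out;
}

// Primary dose and first-scatter scerma from the compact primary field.
// murho/muenrho: nmed x nlines mass coefficients at the line energies.
// [[Rcpp::export]]
List cpp_primary(NumericMatrix pathRho, NumericVector dist,
                 IntegerVector med0, NumericVector rho,
                 NumericMatrix murho, NumericMatrix muenrho,
                 NumericVector specE, NumericVector specW,
                 int sourceVoxel0, double geoSrc) {
  const int nv = pathRho.nrow(), nmed = pathRho.ncol(), nl = specE.size();
  NumericVector dprim(nv), s1sc(nv);
  const double fourpi = 4.0 * M_PI;
  for (int vx = 0; vx < nv; ++vx) {
    double geo = (vx == sourceVoxel0)
      ? geoSrc : 1.0 / (fourpi * dist[vx] * dist[vx]);
    const int m = med0[vx];
    double dp = 0.0, s1 = 0.0;
    for (int l = 0; l < nl; ++l) {
      double tau = 0.0;
      for (int mm = 0; mm < nmed; ++mm) tau += murho(mm, l) * pathRho(vx, mm);
      double psi = specW[l] * specE[l] * std::exp(-tau) * geo;
      dp += psi * muenrho(m, l);
      s1 += psi * (murho(m, l) - muenrho(m, l));
    }
    dprim[vx] = dp;
    s1sc[vx] = s1;
  }
  return List::create(_["dprim"] = dprim, _["s1sc"] = s1sc);
}

// ---------------------------------------------------------------------------
// Sheared transport line lattice: every voxel belongs to exactly one line
// per direction; constant step length dlmax = v / max|d|.
// ---------------------------------------------------------------------------

// Enumerate lattice steps for one direction (small grids; used for the
// TransportLineLattice class and its tests).
// [[Rcpp::export]]
List cpp_lattice_steps(IntegerVector dims, NumericVector dir) {
  int n[3] = {dims[0], dims[1], dims[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  int a = 0;
  if (std::fabs(d[1]) > std::fabs(d[a])) a = 1;
  if (std::fabs(d[2]) > std::fabs(d[a])) a = 2;
  const int b = (a + 1) % 3, c = (a + 2) % 3;
  const int sgn = d[a] > 0 ? 1 : -1;
  const double rb = d[b] / std::fabs(d[a]), rc = d[c] / std::fabs(d[a]);
  const int na = n[a], nb = n[b], nc = n[c];
  const int maxShB = (int)std::ceil(std::fabs(rb) * na) + 1;
  const int maxShC = (int)std::ceil(std::fabs(rc) * na) + 1;
  std::vector<int> lineId, order, voxel;
  int line = 0;
  int ijk[3];
  for (int b0 = -maxShB; b0 < nb + maxShB; ++b0)
    for (int c0 = -maxShC; c0 < nc + maxShC; ++c0) {
      bool any = false;
      int ord = 0;
      for (int m = 0; m < na; ++m) {
        int s = (sgn > 0) ? m : na - 1 - m;
        int bb = b0 + (int)std::llround(m * rb);
        int cc = c0 + (int)std::llround(m * rc);
        if (bb < 0 || bb >= nb || cc < 0 || cc >= nc) {
          if (any) break;  // monotone drift: once exited, gone
          continue;
        }
        any = true;
        ijk[a] = s; ijk[b] = bb; ijk[c] = cc;
        lineId.push_back(line);
        order.push_back(ord++);
        voxel.push_back(1 + ijk[0] + n[0] * (ijk[1] + n[1] * ijk[2]));
      }
      if (any) ++line;
    }
  return List::create(_["line"] = lineId, _["order"] = order,
                      _["voxel"] = voxel);
}

// ---------------------------------------------------------------------------
// Collapsed-cone line transport of a scerma grid with a (bi-)exponential
// kernel.  For each transport direction, lines sweep the grid; along each
// line and for each kernel term the effective energy fluence R is iterated
// as
//   bracket_j = (1 - eps_j) R_{j-1} + sigma_j dl - dR_j,
//   dose_j   += (1/dlmax)(1/rho_j) * [chi/eta]_j^(corrected) * bracket_j,
//   R_j       = R_{j-1} eps_j + dR_j [+ (1 - chi/eta)_j bracket_j],
// with eps_j = exp(-eta_j c_theta dl), sigma_j = S_j rho_j dOmega C/c and
// dR_j = sigma_j (1 - eps_j)/(eta_j c_theta) the self-absorption-corrected
// release.  The kernel parameters (C, c, F, f) are looked up per step from
// the angle between the transport direction and the source-to-voxel axis
// (kernel tilting).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_cc_transport(IntegerVector dims, double v, NumericVector origin,
                      IntegerVector med0, NumericVector rho,
                      NumericVector scerma, NumericVector src,
                      NumericMatrix dirs, NumericMatrix kern,
                      NumericVector eta, NumericVector chiOverEta,
                      bool corrected) {
  Grid g = gridFromArgs(dims, v, origin);
  const int nv = g.nvox(), M = dirs.nrow(), ncones = kern.nrow();
  const int nmed = eta.size();
  NumericVector dose(nv);
  double* pdose = REAL(dose);
  const double* pS = REAL(scerma);
  const double* prho = REAL(rho);
  const int* pmed = INTEGER(med0);
  const double* pchi = REAL(chiOverEta);
  std::vector<double> kC(ncones), kc(ncones), kF(ncones), kf(ncones);
  for (int t = 0; t < ncones; ++t) {
    kC[t] = kern(t, 0); kc[t] = kern(t, 1);
    kF[t] = kern(t, 2); kf[t] = kern(t, 3);
  }
  double released = 0.0, absorbed = 0.0, escaped = 0.0;
  long clamped = 0;
  const double dOmega = 4.0 * M_PI / M;

  std::vector<double> epsC(nmed * ncones), gC(nmed * ncones);
  std::vector<double> epsF(nmed * ncones), gF(nmed * ncones);

  for (int mdir = 0; mdir < M; ++mdir) {
    double d[3] = {dirs(mdir, 0), dirs(mdir, 1), dirs(mdir, 2)};
    double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    for (int q = 0; q < 3; ++q) d[q] /= nrm;
    int a = 0;
    if (std::fabs(d[1]) > std::fabs(d[a])) a = 1;
    if (std::fabs(d[2]) > std::fabs(d[a])) a = 2;
    const int b = (a + 1) % 3, c = (a + 2) % 3;
    const int sgn = d[a] > 0 ? 1 : -1;
    const double dl = v / std::fabs(d[a]);
    const double A = v * v * std::fabs(d[a]);  // tributary area per line
    const double rb = d[b] / std::fabs(d[a]), rc = d[c] / std::fabs(d[a]);
    const int na = g.n[a], nb = g.n[b], nc = g.n[c];
    const int maxShB = (int)std::ceil(std::fabs(rb) * na) + 1;
    const int maxShC = (int)std::ceil(std::fabs(rc) * na) + 1;

    // per-direction attenuation tables (step length is constant)
    for (int mm = 0; mm < nmed; ++mm)
      for (int t = 0; t < ncones; ++t) {
        double xc = eta[mm] * kc[t] * dl;
        double xf = eta[mm] * kf[t] * dl;
        epsC[mm * ncones + t] = std::exp(-xc);
        epsF[mm * ncones + t] = std::exp(-xf);
        gC[mm * ncones + t] = -std::expm1(-xc) / (eta[mm] * kc[t]);
        gF[mm * ncones + t] = -std::expm1(-xf) / (eta[mm] * kf[t]);
      }

    int ijk[3];
    for (int b0 = -maxShB; b0 < nb + maxShB; ++b0)
      for (int c0 = -maxShC; c0 < nc + maxShC; ++c0) {
        double RC = 0.0, RF = 0.0;
        bool any = false;
        for (int m = 0; m < na; ++m) {
          int s = (sgn > 0) ? m : na - 1 - m;
          int bb = b0 + (int)std::llround(m * rb);
          int cc = c0 + (int)std::llround(m * rc);
          if (bb < 0 || bb >= nb || cc < 0 || cc >= nc) {
            if (any) break;
            continue;
          }
          any = true;
          ijk[a] = s; ijk[b] = bb; ijk[c] = cc;
          const int vx = g.idx(ijk[0], ijk[1], ijk[2]);
          const int mv = pmed[vx];
          // kernel tilt: cone bin from angle to the source-voxel axis
          double rx = g.o[0] + (ijk[0] + 0.5) * v - src[0];
          double ry = g.o[1] + (ijk[1] + 0.5) * v - src[1];
          double rz = g.o[2] + (ijk[2] + 0.5) * v - src[2];
          double rr = std::sqrt(rx * rx + ry * ry + rz * rz);
          double ct = rr > 1e-12 ? (rx * d[0] + ry * d[1] + rz * d[2]) / rr
                                 : 1.0;
          int t = (int)((1.0 - ct) * 0.5 * ncones);
          if (t < 0) t = 0;
          if (t >= ncones) t = ncones - 1;
          const double S = pS[vx], rhov = prho[vx];
          const double cOe = pchi[mv];
          const double invDlRho = 1.0 / (dl * rhov);
          // C term
          {
            const double sig = S * rhov * dOmega * kC[t] / kc[t];
            const double eps = epsC[mv * ncones + t];
            const double dR = sig * gC[mv * ncones + t];
            double br = (1.0 - eps) * RC + sig * dl - dR;
            if (br < 0) { br = 0; ++clamped; }
            const double dep = corrected ? cOe * br : br;
            pdose[vx] += dep * invDlRho;
            RC = RC * eps + dR + (corrected ? (1.0 - cOe) * br : 0.0);
            released += sig * dl * A;
            absorbed += dep * A;
          }
          // F term
          {
            const double sig = S * rhov * dOmega * kF[t] / kf[t];
            const double eps = epsF[mv * ncones + t];
            const double dR = sig * gF[mv * ncones + t];
            double br = (1.0 - eps) * RF + sig * dl - dR;
            if (br < 0) { br = 0; ++clamped; }
            const double dep = corrected ? cOe * br : br;
            pdose[vx] += dep * invDlRho;
            RF = RF * eps + dR + (corrected ? (1.0 - cOe) * br : 0.0);
            released += sig * dl * A;
            absorbed += dep * A;
          }
        }
        escaped += (RC + RF) * A;
      }
  }
  return List::create(_["dose"] = dose, _["released"] = released,
                      _["absorbed"] = absorbed, _["escaped"] = escaped,
                      _["clamped"] = (double)clamped);
}
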