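// Pairwise kernels: group-group nonbonded energy (cell list with a
// brute-force fallback for boxes under three cells per edge) and the
// molecular radial distribution by minimum inter-bead distance.
// Distances use the minimum-image convention in an orthorhombic box.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double minImage(double d, double L) {
  return d - L * std::round(d / L);
}

static inline double wrap0(double x, double L) {
  double w = x - L * std::floor(x / L);
  if (w < 0) w += L;
  if (w >= L) w -= L;
  return w;
}

struct EnergyAcc {
  double lj = 0.0, coul = 0.0;
  bool singular = false;
};

static inline void pairEnergy(EnergyAcc &acc,
                              double dx, double dy, double dz,
                              int ti, int tj, double qi, double qj,
                              const NumericMatrix &sigma,
                              const NumericMatrix &eps,
                              double rc2, double rc, double epsR) {
  const double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 > rc2) return;
  if (r2 == 0.0) { acc.singular = true; return; }
  const double r = std::sqrt(r2);
  const double s = sigma(ti, tj), e = eps(ti, tj);
  if (e > 0.0) {
    const double sr6 = std::pow(s / r, 6), src6 = std::pow(s / rc, 6);
    acc.lj += 4.0 * e * (sr6 * sr6 - sr6) - 4.0 * e * (src6 * src6 - src6);
  }
  const double qq = qi * qj;
  if (qq != 0.0)
    acc.coul += 138.935 * qq / epsR * (1.0 / r - 1.0 / rc);
}

// [[Rcpp::export]]
List cppGroupEnergy(NumericMatrix coords, IntegerVector typeIdx,
                    NumericVector charge, IntegerVector molId,
                    IntegerVector idxA, IntegerVector idxB,
                    NumericVector box, double rc, double epsR,
                    NumericMatrix sigma, NumericMatrix eps,
                    bool sameGroup) {
  const int nA = idxA.size(), nB = idxB.size();
  const double rc2 = rc * rc;
  EnergyAcc acc;

  int nc[3];
  bool cells = true;
  for (int k = 0; k < 3; ++k) {
    nc[k] = (int)std::floor(box[k] / rc);
    if (nc[k] < 3) cells = false;
  }

  if (!cells) {
    for (int a = 0; a < nA; ++a) {
      const int i = idxA[a] - 1;
      for (int b = 0; b < nB; ++b) {
        const int j = idxB[b] - 1;
        if (sameGroup && j <= i) continue;
        if (molId[i] == molId[j]) continue;
        pairEnergy(acc,
                   minImage(coords(i, 0) - coords(j, 0), box[0]),
                   minImage(coords(i, 1) - coords(j, 1), box[1]),
                   minImage(coords(i, 2) - coords(j, 2), box[2]),
                   typeIdx[i] - 1, typeIdx[j] - 1, charge[i], charge[j],
                   sigma, eps, rc2, rc, epsR);
      }
    }
  } else {
    // cell list over the B beads
    const int ncTot = nc[0] * nc[1] * nc[2];
    std::vector<std::vector<int>> cell(ncTot);
    std::vector<int> cb(3);
    for (int b = 0; b < nB; ++b) {
      const int j = idxB[b] - 1;
      int cx = (int)(wrap0(coords(j, 0), box[0]) / box[0] * nc[0]);
      int cy = (int)(wrap0(coords(j, 1), box[1]) / box[1] * nc[1]);
      int cz = (int)(wrap0(coords(j, 2), box[2]) / box[2] * nc[2]);
      if (cx >= nc[0]) cx = nc[0] - 1;
      if (cy >= nc[1]) cy = nc[1] - 1;
      if (cz >= nc[2]) cz = nc[2] - 1;
      cell[(cz * nc[1] + cy) * nc[0] + cx].push_back(j);
    }
    for (int a = 0; a < nA; ++a) {
      const int i = idxA[a] - 1;
      int cx = (int)(wrap0(coords(i, 0), box[0]) / box[0] * nc[0]);
      int cy = (int)(wrap0(coords(i, 1), box[1]) / box[1] * nc[1]);
      int cz = (int)(wrap0(coords(i, 2), box[2]) / box[2] * nc[2]);
      if (cx >= nc[0]) cx = nc[0] - 1;
      if (cy >= nc[1]) cy = nc[1] - 1;
      if (cz >= nc[2]) cz = nc[2] - 1;
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            const int ccx = (cx + ox + nc[0]) % nc[0];
            const int ccy = (cy + oy + nc[1]) % nc[1];
            const int ccz = (cz + oz + nc[2]) % nc[2];
            const std::vector<int> &lst = cell[(ccz * nc[1] + ccy) * nc[0] + ccx];
            for (size_t t = 0; t < lst.size(); ++t) {
              const int j = lst[t];
              if (sameGroup && j <= i) continue;
              if (molId[i] == molId[j]) continue;
              pairEnergy(acc,
                         minImage(coords(i, 0) - coords(j, 0), box[0]),
                         minImage(coords(i, 1) - coords(j, 1), box[1]),
                         minImage(coords(i, 2) - coords(j, 2), box[2]),
                         typeIdx[i] - 1, typeIdx[j] - 1, charge[i], charge[j],
                         sigma, eps, rc2, rc, epsR);
            }
          }
    }
  }
  return List::create(_["lj"] = acc.lj, _["coulomb"] = acc.coul,
                      _["singular"] = acc.singular);
}

// Minimum inter-bead distance between two molecules (bead index
// vectors, 1-based), with an early exit once a distance under `stop`
// is found.
static double molMinDist(const NumericMatrix &coords,
                         const IntegerVector &mi, const IntegerVector &mj,
                         const NumericVector &box) {
  double best = R_PosInf;
  for (int a = 0; a < mi.size(); ++a) {
    const int i = mi[a] - 1;
    for (int b = 0; b < mj.size(); ++b) {
      const int j = mj[b] - 1;
      const double dx = minImage(coords(i, 0) - coords(j, 0), box[0]);
      const double dy = minImage(coords(i, 1) - coords(j, 1), box[1]);
      const double dz = minImage(coords(i, 2) - coords(j, 2), box[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  }
  return std::sqrt(best);
}

// [[Rcpp::export]]
IntegerVector cppMolRdf(NumericMatrix coords, NumericVector box,
                        List refMols, List tarMols,
                        IntegerVector refIds, IntegerVector tarIds,
                        double rMax, int nBins, double binWidth) {
  const int nr = refMols.size(), nt = tarMols.size();
  IntegerVector counts(nBins);

  // molecule centres of geometry and bounding radii for prefiltering
  std::vector<double> rcx(nt), rcy(nt), rcz(nt), rrad(nt);
  for (int t = 0; t < nt; ++t) {
    IntegerVector m = tarMols[t];
    double cx = 0, cy = 0, cz = 0;
    for (int b = 0; b < m.size(); ++b) {
      cx += coords(m[b] - 1, 0); cy += coords(m[b] - 1, 1); cz += coords(m[b] - 1, 2);
    }
    cx /= m.size(); cy /= m.size(); cz /= m.size();
    double rad = 0;
    for (int b = 0; b < m.size(); ++b) {
      const double dx = coords(m[b] - 1, 0) - cx;
      const double dy = coords(m[b] - 1, 1) - cy;
      const double dz = coords(m[b] - 1, 2) - cz;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > rad) rad = d;
    }
    rcx[t] = cx; rcy[t] = cy; rcz[t] = cz; rrad[t] = rad;
  }

  for (int r = 0; r < nr; ++r) {
    IntegerVector mr = refMols[r];
    double cx = 0, cy = 0, cz = 0;
    for (int b = 0; b < mr.size(); ++b) {
      cx += coords(mr[b] - 1, 0); cy += coords(mr[b] - 1, 1); cz += coords(mr[b] - 1, 2);
    }
    cx /= mr.size(); cy /= mr.size(); cz /= mr.size();
    double rad = 0;
    for (int b = 0; b < mr.size(); ++b) {
      const double dx = coords(mr[b] - 1, 0) - cx;
      const double dy = coords(mr[b] - 1, 1) - cy;
      const double dz = coords(mr[b] - 1, 2) - cz;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > rad) rad = d;
    }
    for (int t = 0; t < nt; ++t) {
      if (tarIds[t] == refIds[r]) continue;  // self-pair excluded
      const double dx = minImage(cx - rcx[t], box[0]);
      const double dy = minImage(cy - rcy[t], box[1]);
      const double dz = minImage(cz - rcz[t], box[2]);
      const double dCog = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dCog - rad - rrad[t] > rMax) continue;
      const double d = molMinDist(coords, mr, tarMols[t], box);
      if (d > rMax) continue;
      const int k = (int)std::floor(d / binWidth + 0.5);
      if (k >= 1 && k <= nBins) counts[k - 1] += 1;
    }
  }
  return counts;
}
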