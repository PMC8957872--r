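#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Natural-extension reference frame build: convert an internal-coordinate
// table (bond/angle/dihedral references, 1-based, 0 = undefined) into
// Cartesian coordinates.  Same semantics as nerf_embed_r() on the R side;
// this is the hot path called once per penalty evaluation in the torsion
// optimizer.  theta and phi are in degrees.
// [[Rcpp::export]]
NumericMatrix nerf_embed_cpp(IntegerVector ref1, IntegerVector ref2,
                             IntegerVector ref3, NumericVector r,
                             NumericVector theta, NumericVector phi) {
  const double D2R = M_PI / 180.0;
  int n = r.size();
  NumericMatrix X(n, 3);
  for (int i = 0; i < n; ++i) {
    double th = theta[i] * D2R, ph = phi[i] * D2R;
    if (ref1[i] == 0) {
      X(i, 0) = X(i, 1) = X(i, 2) = 0.0;
    } else if (ref2[i] == 0) {
      int j = ref1[i] - 1;
      X(i, 0) = X(j, 0) + r[i];
      X(i, 1) = X(j, 1);
      X(i, 2) = X(j, 2);
    } else if (ref3[i] == 0) {
      int j = ref1[i] - 1, k = ref2[i] - 1;
      double ux = X(k, 0) - X(j, 0), uy = X(k, 1) - X(j, 1),
             uz = X(k, 2) - X(j, 2);
      double un = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= un; uy /= un; uz /= un;
      // w = unit((0,0,1) x u), any perpendicular when u is along z
      double wx = -uy, wy = ux, wz = 0.0;
      double wn = std::sqrt(wx * wx + wy * wy);
      if (wn < 1e-8) { wx = 1.0; wy = 0.0; wz = 0.0; }
      else { wx /= wn; wy /= wn; }
      X(i, 0) = X(j, 0) + r[i] * (std::cos(th) * ux + std::sin(th) * wx);
      X(i, 1) = X(j, 1) + r[i] * (std::cos(th) * uy + std::sin(th) * wy);
      X(i, 2) = X(j, 2) + r[i] * (std::cos(th) * uz + std::sin(th) * wz);
    } else {
      int ia = ref3[i] - 1, ib = ref2[i] - 1, ic = ref1[i] - 1;
      double bcx = X(ic, 0) - X(ib, 0), bcy = X(ic, 1) - X(ib, 1),
             bcz = X(ic, 2) - X(ib, 2);
      double bcn = std::sqrt(bcx * bcx + bcy * bcy + bcz * bcz);
      bcx /= bcn; bcy /= bcn; bcz /= bcn;
      double abx = X(ib, 0) - X(ia, 0), aby = X(ib, 1) - X(ia, 1),
             abz = X(ib, 2) - X(ia, 2);
      double nx = aby * bcz - abz * bcy, ny = abz * bcx - abx * bcz,
             nz = abx * bcy - aby * bcx;
      double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
      nx /= nn; ny /= nn; nz /= nn;
      double mx = ny * bcz - nz * bcy, my = nz * bcx - nx * bcz,
             mz = nx * bcy - ny * bcx;
      // the realized signed dihedral (IUPAC convention, as measured by
      // dihedral_angle) equals ph
      double d0 = -r[i] * std::cos(th);
      double d1 = r[i] * std::sin(th) * std::cos(ph);
      double d2 = r[i] * std::sin(th) * std::sin(ph);
      X(i, 0) = X(ic, 0) + d0 * bcx + d1 * mx + d2 * nx;
      X(i, 1) = X(ic, 1) + d0 * bcy + d1 * my + d2 * ny;
      X(i, 2) = X(ic, 2) + d0 * bcz + d1 * mz + d2 * nz;
    }
  }
  return X;
}

// Flat-bottom distance-restraint + soft-sphere steric penalty.
// dist2_pairs: effective r^-6 group distances are computed in R; here we
// only need raw squared distances for the steric term over precomputed
// nonbonded heavy-atom index pairs (1-based).
// [[Rcpp::export]]
double steric_penalty_cpp(NumericMatrix X, IntegerVector pi1,
                          IntegerVector pi2, double cutoff) {
  double pen = 0.0;
  int m = pi1.size();
  for (int p = 0; p < m; ++p) {
    int i = pi1[p] - 1, j = pi2[p] - 1;
    double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
           dz = X(i, 2) - X(j, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < cutoff) pen += (cutoff - d) * (cutoff - d);
  }
  return pen;
}

// flat-bottom restraint penalty: groups are passed as flattened 1-based
// index vectors with 0-based offsets (restraint k uses ga_flat[ga_off[k]
// .. ga_off[k+1]-1]); distances use the arithmetic-mean convention
// [[Rcpp::export]]
double restraint_penalty_cpp(NumericMatrix X, IntegerVector ga_flat,
                             IntegerVector ga_off, IntegerVector gb_flat,
                             IntegerVector gb_off, NumericVector lower,
                             NumericVector upper) {
  double pen = 0.0;
  int nres = lower.size();
  for (int k = 0; k < nres; ++k) {
    double s = 0.0;
    int a0 = ga_off[k], a1 = ga_off[k + 1], b0 = gb_off[k],
        b1 = gb_off[k + 1];
    for (int p = a0; p < a1; ++p) {
      int i = ga_flat[p] - 1;
      for (int q = b0; q < b1; ++q) {
        int j = gb_flat[q] - 1;
        double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
               dz = X(i, 2) - X(j, 2);
        s += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
    }
    double d = s / (double)((a1 - a0) * (b1 - b0));
    double ex = 0.0;
    if (d < lower[k]) ex = lower[k] - d;
    else if (R_finite(upper[k]) && d > upper[k]) ex = d - upper[k];
    pen += ex * ex;
  }
  return pen;
}

// arithmetic-mean distance between two proton groups (1-based indices)
// [[Rcpp::export]]
double group_mean_cpp(NumericMatrix X, IntegerVector ia, IntegerVector ib) {
  double s = 0.0;
  int na = ia.size(), nb = ib.size();
  for (int p = 0; p < na; ++p) {
    int i = ia[p] - 1;
    for (int q = 0; q < nb; ++q) {
      int j = ib[q] - 1;
      double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
             dz = X(i, 2) - X(j, 2);
      s += std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return s / (double)(na * nb);
}

// r^-6 averaged effective distance between two proton groups:
// (mean over pairs of r^-6)^(-1/6).  idx vectors are 1-based atom indices.
// [[Rcpp::export]]
double group_r6_cpp(NumericMatrix X, IntegerVector ia, IntegerVector ib) {
  double s = 0.0;
  int na = ia.size(), nb = ib.size();
  for (int p = 0; p < na; ++p) {
    int i = ia[p] - 1;
    for (int q = 0; q < nb; ++q) {
      int j = ib[q] - 1;
      double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
             dz = X(i, 2) - X(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      s += 1.0 / (d2 * d2 * d2);
    }
  }
  s /= (double)(na * nb);
  return std::pow(s, -1.0 / 6.0);
}
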