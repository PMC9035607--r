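#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Draw a liability with mean eta and unit variance, truncated to (0, Inf)
// when positive, (-Inf, 0] otherwise.  Inverse-CDF sampling on the truncated
// region; |eta| is clamped at 8 to keep qnorm away from tail underflow (the
// truncated draw at |eta| = 8 is numerically indistinguishable beyond that).
static double draw_liability(double eta, bool positive) {
  double e = eta;
  if (e > 8.0) e = 8.0;
  else if (e < -8.0) e = -8.0;
  double u = unif_rand();
  double z;
  if (positive) {
    double p = R::pnorm(e, 0.0, 1.0, 1, 0);        // P(z > -e)
    z = R::qnorm(u * p, 0.0, 1.0, 0, 0);
  } else {
    double p = R::pnorm(-e, 0.0, 1.0, 1, 0);       // P(z <= -e)
    z = R::qnorm(u * p, 0.0, 1.0, 1, 0);
  }
  return e + z;
}

// [[Rcpp::export]]
NumericVector trunc_liability_cpp(NumericVector eta, LogicalVector positive) {
  int n = eta.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = draw_liability(eta[i], positive[i]);
  return out;
}

// Invert a symmetric 2x2 matrix given as (a11, a12, a22).
static inline void inv2(double a11, double a12, double a22,
                        double &b11, double &b12, double &b22) {
  double det = a11 * a22 - a12 * a12;
  b11 = a22 / det;
  b12 = -a12 / det;
  b22 = a11 / det;
}

// Sample G ~ InvWishart(df, Scale) for p = 2 via Bartlett on Scale^{-1}.
static void rinvwishart2(double df, double s11, double s12, double s22,
                         double &g11, double &g12, double &g22) {
  double v11, v12, v22;                        // Scale^{-1}
  inv2(s11, s12, s22, v11, v12, v22);
  // lower Cholesky of Scale^{-1}
  double l11 = std::sqrt(v11);
  double l21 = v12 / l11;
  double l22 = std::sqrt(v22 - l21 * l21);
  // Bartlett factor
  double a11 = std::sqrt(R::rchisq(df));
  double a21 = norm_rand();
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  // T = L * A (lower), W = T T'
  double t11 = l11 * a11;
  double t21 = l21 * a11 + l22 * a21;
  double t22 = l22 * a22;
  double w11 = t11 * t11;
  double w12 = t11 * t21;
  double w22 = t21 * t21 + t22 * t22;
  inv2(w11, w12, w22, g11, g12, g22);          // G = W^{-1}
}

struct LevelIndex {
  // records grouped by level: CSR layout
  std::vector<int> ptr;
  std::vector<int> recs;
  int nlev;
  void build(const IntegerVector &idx, int nl, int n) {
    nlev = nl;
    ptr.assign(nl + 1, 0);
    for (int r = 0; r < n; ++r) ptr[idx[r]]++;        // idx is 1-based
    for (int j = 0; j < nl; ++j) ptr[j + 1] += ptr[j];
    recs.assign(n, 0);
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int r = 0; r < n; ++r) recs[fill[idx[r] - 1]++] = r;
  }
};

// Gibbs sampler / Gauss-Seidel solver for the S-MGS threshold model.
//
// sb        : 1/2 stillbirth code per record (used when augment = TRUE)
// yGauss    : continuous working response (used when augment = FALSE)
// fidx      : list of 1-based level indices per record, one entry per factor
// nlev      : number of levels per factor
// estim     : list of logicals per factor; FALSE levels are clamped at 0
// lambdaFix : ridge (prior precision) per factor; ignored for hyFactor
// hyFactor  : 1-based position of the herd-year factor in fidx, or 0
// sire/mgs  : 1-based bull index per record
// Ap,Ai,Ax  : CSC arrays (0-based) of the full symmetric A-inverse pattern
// noise     : FALSE turns the sampler into deterministic Gauss-Seidel sweeps
// [[Rcpp::export]]
List gibbs_smgs_cpp(IntegerVector sb, NumericVector yGauss, bool augment,
                    List fidx, IntegerVector nlev, List estim,
                    NumericVector lambdaFix, int hyFactor,
                    IntegerVector sire, IntegerVector mgs, int nbull,
                    IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                    NumericMatrix g0Start, double hyVarStart,
                    double nu0G, NumericMatrix V0,
                    double nu0hy, double S0hy,
                    int niter, int burnin, int thin,
                    bool updateVar, bool noise) {
  const int n = augment ? sb.size() : yGauss.size();
  const int nf = fidx.size();

  std::vector<LevelIndex> flev(nf);
  std::vector<IntegerVector> fvec(nf);
  std::vector<LogicalVector> fest(nf);
  int neqFix = 0;
  for (int f = 0; f < nf; ++f) {
    fvec[f] = as<IntegerVector>(fidx[f]);
    fest[f] = as<LogicalVector>(estim[f]);
    flev[f].build(fvec[f], nlev[f], n);
    neqFix += nlev[f];
  }
  LevelIndex slev, mlev;
  slev.build(sire, nbull, n);
  mlev.build(mgs, nbull, n);
  std::vector<int> nboth(nbull, 0);
  for (int r = 0; r < n; ++r)
    if (sire[r] == mgs[r]) nboth[sire[r] - 1]++;

  // state
  std::vector<std::vector<double> > b(nf);
  for (int f = 0; f < nf; ++f) b[f].assign(nlev[f], 0.0);
  std::vector<double> us(nbull, 0.0), um(nbull, 0.0);
  std::vector<double> liab(n, 0.0), ycorr(n, 0.0);

  double g11 = g0Start(0, 0), g12 = g0Start(0, 1), g22 = g0Start(1, 1);
  double hyvar = hyVarStart;

  if (augment) {
    for (int r = 0; r < n; ++r) {
      liab[r] = noise ? draw_liability(0.0, sb[r] == 2)
                      : (sb[r] == 2 ? 0.5 : -0.5);
      ycorr[r] = liab[r];
    }
  } else {
    for (int r = 0; r < n; ++r) {
      liab[r] = yGauss[r];
      ycorr[r] = yGauss[r];
    }
  }

  const int neq = neqFix + 2 * nbull;
  const int nkeep = (niter > burnin) ? (niter - burnin + thin - 1) / thin : 0;
  NumericMatrix varSamples(std::max(nkeep, 1), 4);
  NumericMatrix solSamples(std::max(nkeep, 1), neq);
  int kept = 0;

  for (int it = 0; it < niter; ++it) {
    // (a) liabilities
    if (augment && noise) {
      for (int r = 0; r < n; ++r) {
        double eta = liab[r] - ycorr[r];
        if (!std::isfinite(eta))
          stop("non-finite liability mean at iteration %d", it + 1);
        double lnew = draw_liability(eta, sb[r] == 2);
        ycorr[r] += lnew - liab[r];
        liab[r] = lnew;
      }
    }

    // (b) factor effects
    for (int f = 0; f < nf; ++f) {
      double lambda = (f + 1 == hyFactor) ? 1.0 / hyvar : lambdaFix[f];
      for (int j = 0; j < nlev[f]; ++j) {
        if (!fest[f][j]) continue;
        double old = b[f][j];
        double rhs = 0.0;
        int lo = flev[f].ptr[j], hi = flev[f].ptr[j + 1];
        for (int k = lo; k < hi; ++k) {
          int r = flev[f].recs[k];
          ycorr[r] += old;
          rhs += ycorr[r];
        }
        double C = (hi - lo) + lambda;
        double bn = rhs / C;
        if (noise) bn += norm_rand() / std::sqrt(C);
        for (int k = lo; k < hi; ++k) ycorr[flev[f].recs[k]] -= bn;
        b[f][j] = bn;
      }
    }

    // (c) bull (sire, MGS) pairs, updated jointly
    double p11, p12, p22;                      // G0^{-1}
    inv2(g11, g12, g22, p11, p12, p22);
    for (int i = 0; i < nbull; ++i) {
      double osi = us[i], omi = um[i];
      double rs = 0.0, rm = 0.0;
      int slo = slev.ptr[i], shi = slev.ptr[i + 1];
      int mlo = mlev.ptr[i], mhi = mlev.ptr[i + 1];
      for (int k = slo; k < shi; ++k) { int r = slev.recs[k]; ycorr[r] += osi; }
      for (int k = mlo; k < mhi; ++k) { int r = mlev.recs[k]; ycorr[r] += omi; }
      for (int k = slo; k < shi; ++k) rs += ycorr[slev.recs[k]];
      for (int k = mlo; k < mhi; ++k) rm += ycorr[mlev.recs[k]];
      double aii = 0.0;
      for (int k = Ap[i]; k < Ap[i + 1]; ++k) {
        int j = Ai[k];
        double a = Ax[k];
        if (j == i) { aii = a; continue; }
        rs -= a * (p11 * us[j] + p12 * um[j]);
        rm -= a * (p12 * us[j] + p22 * um[j]);
      }
      int ns = shi - slo, nm = mhi - mlo, nb = nboth[i];
      double c11 = ns + aii * p11;
      double c12 = nb + aii * p12;
      double c22 = nm + aii * p22;
      double v11, v12, v22;                    // C^{-1}
      inv2(c11, c12, c22, v11, v12, v22);
      double m1 = v11 * rs + v12 * rm;
      double m2 = v12 * rs + v22 * rm;
      if (noise) {
        double l11 = std::sqrt(v11);
        double l21 = v12 / l11;
        double l22 = std::sqrt(v22 - l21 * l21);
        double z1 = norm_rand(), z2 = norm_rand();
        m1 += l11 * z1;
        m2 += l21 * z1 + l22 * z2;
      }
      us[i] = m1; um[i] = m2;
      for (int k = slo; k < shi; ++k) ycorr[slev.recs[k]] -= m1;
      for (int k = mlo; k < mhi; ++k) ycorr[mlev.recs[k]] -= m2;
    }

    // (d) variance components
    if (updateVar && noise) {
      if (hyFactor >= 1) {
        int f = hyFactor - 1;
        double ss = 0.0;
        for (int j = 0; j < nlev[f]; ++j) ss += b[f][j] * b[f][j];
        hyvar = (nu0hy * S0hy + ss) / R::rchisq(nu0hy + nlev[f]);
      }
      double s11 = V0(0, 0), s12 = V0(0, 1), s22 = V0(1, 1);
      for (int i = 0; i < nbull; ++i) {
        for (int k = Ap[i]; k < Ap[i + 1]; ++k) {
          int j = Ai[k];
          double a = Ax[k];
          s11 += a * us[i] * us[j];
          s12 += a * us[i] * um[j];
          s22 += a * um[i] * um[j];
        }
      }
      rinvwishart2(nu0G + nbull, s11, s12, s22, g11, g12, g22);
    }

    // (e) retain
    if (it >= burnin && (it - burnin) % thin == 0 && kept < nkeep) {
      varSamples(kept, 0) = g11;
      varSamples(kept, 1) = g22;
      varSamples(kept, 2) = g12;
      varSamples(kept, 3) = hyvar;
      int col = 0;
      for (int f = 0; f < nf; ++f)
        for (int j = 0; j < nlev[f]; ++j) solSamples(kept, col++) = b[f][j];
      for (int i = 0; i < nbull; ++i) solSamples(kept, col++) = us[i];
      for (int i = 0; i < nbull; ++i) solSamples(kept, col++) = um[i];
      kept++;
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // final state solution vector (Gauss-Seidel mode reads this)
  NumericVector finalSol(neq);
  {
    int col = 0;
    for (int f = 0; f < nf; ++f)
      for (int j = 0; j < nlev[f]; ++j) finalSol[col++] = b[f][j];
    for (int i = 0; i < nbull; ++i) finalSol[col++] = us[i];
    for (int i = 0; i < nbull; ++i) finalSol[col++] = um[i];
  }

  return List::create(_["variances"] = varSamples,
                      _["solutions"] = solSamples,
                      _["kept"] = kept,
                      _["finalSolution"] = finalSol);
}
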