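#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Multi-well toy potential: sum of inverted Gaussians plus optional harmonic
// confinement.  U(x) = -sum_k depth_k exp(-sum_d (x_d - c_kd)^2 / (2 s_kd^2))
//                      + 0.5 sum_d kconf_d (x_d - cc_d)^2
static void pot_eval(const NumericMatrix &centers, const NumericVector &depths,
                     const NumericMatrix &widths, const NumericVector &kconf,
                     const NumericVector &confCenter, const double *x, int D,
                     double &U, double *grad) {
  U = 0.0;
  for (int d = 0; d < D; ++d) grad[d] = 0.0;
  const int K = centers.nrow();
  for (int k = 0; k < K; ++k) {
    double e = 0.0;
    for (int d = 0; d < D; ++d) {
      const double z = (x[d] - centers(k, d)) / widths(k, d);
      e += 0.5 * z * z;
    }
    const double g = depths[k] * std::exp(-e);
    U -= g;
    for (int d = 0; d < D; ++d)
      grad[d] += g * (x[d] - centers(k, d)) / (widths(k, d) * widths(k, d));
  }
  for (int d = 0; d < D; ++d) {
    const double dx = x[d] - confCenter[d];
    U += 0.5 * kconf[d] * dx * dx;
    grad[d] += kconf[d] * dx;
  }
}

// Metadynamics bias from deposited hills.  hills has columns
// [c_1..c_m, s_1..s_m, height, time]; s = value of the m biased coordinates.
static void bias_eval(const NumericMatrix &hills, int nHills, int m,
                      const double *s, double &V, double *grad) {
  V = 0.0;
  for (int j = 0; j < m; ++j) grad[j] = 0.0;
  for (int h = 0; h < nHills; ++h) {
    double e = 0.0;
    for (int j = 0; j < m; ++j) {
      const double z = (s[j] - hills(h, j)) / hills(h, m + j);
      e += 0.5 * z * z;
    }
    if (e > 30.0) continue;  // exp(-30) ~ 1e-13: negligible
    const double g = hills(h, 2 * m) * std::exp(-e);
    V += g;
    for (int j = 0; j < m; ++j) {
      const double sig = hills(h, m + j);
      grad[j] -= g * (s[j] - hills(h, j)) / (sig * sig);
    }
  }
}

// [[Rcpp::export(name = ".cpp_eval_potential")]]
List cpp_eval_potential(NumericMatrix centers, NumericVector depths,
                        NumericMatrix widths, NumericVector kconf,
                        NumericVector confCenter, NumericMatrix points) {
  const int D = points.ncol(), n = points.nrow();
  NumericVector U(n);
  NumericMatrix grad(n, D);
  std::vector<double> x(D), g(D);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < D; ++d) x[d] = points(i, d);
    double u;
    pot_eval(centers, depths, widths, kconf, confCenter, x.data(), D, u, g.data());
    U[i] = u;
    for (int d = 0; d < D; ++d) grad(i, d) = g[d];
  }
  return List::create(_["energy"] = U, _["gradient"] = grad);
}

// [[Rcpp::export(name = ".cpp_eval_bias")]]
List cpp_eval_bias(NumericMatrix hills, NumericMatrix points) {
  const int m = points.ncol(), n = points.nrow();
  NumericVector V(n);
  NumericMatrix grad(n, m);
  std::vector<double> s(m), g(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) s[j] = points(i, j);
    double v;
    bias_eval(hills, hills.nrow(), m, s.data(), v, g.data());
    V[i] = v;
    for (int j = 0; j < m; ++j) grad(i, j) = g[j];
  }
  return List::create(_["bias"] = V, _["gradient"] = grad);
}

// One segment of overdamped Langevin dynamics with optional metadynamics.
//
// Update rule: x <- x - dt/friction * grad(U + V) + N(0, 2 kT dt / friction).
// Noise is drawn from R's RNG (norm_rand), so set.seed() on the R side makes
// trajectories bit-reproducible.  The bias acts on the coordinate subset
// `biased` (0-based); hills are deposited every `pace` global steps.
// Frames are recorded every `recordStride` global steps; each record carries
// the instantaneous bias potential V and the bias gradient dV/dxi for the
// biased coordinates.
// [[Rcpp::export(name = ".cpp_langevin_segment")]]
List cpp_langevin_segment(NumericMatrix centers, NumericVector depths,
                          NumericMatrix widths, NumericVector kconf,
                          NumericVector confCenter, NumericVector x0,
                          int nSteps, double dt, double friction, double kT,
                          IntegerVector biased, NumericMatrix hills,
                          double hillHeight, NumericVector hillSigma,
                          int pace, double wtBiasFactor, int recordStride,
                          int stepOffset) {
  const int D = x0.size();
  const int m = biased.size();
  std::vector<double> x(x0.begin(), x0.end()), gU(D), s(m), gV(m);
  const double noiseSd = (kT > 0.0) ? std::sqrt(2.0 * kT * dt / friction) : 0.0;

  const int maxNew = (pace > 0 && m > 0) ? nSteps / pace + 2 : 0;
  NumericMatrix newHills(std::max(maxNew, 1), m > 0 ? 2 * m + 2 : 1);
  int nNew = 0;
  const int nOld = hills.nrow();

  // count recorded frames
  int nRec = 0;
  for (int st = 1; st <= nSteps; ++st)
    if ((stepOffset + st) % recordStride == 0) ++nRec;
  NumericVector recTime(nRec);
  NumericMatrix recX(nRec, D), recGrad(nRec, std::max(m, 1));
  NumericVector recBias(nRec);
  int ir = 0;

  // scratch copy of old hills plus room for new ones (columns as in `hills`)
  // bias evaluation walks old hills then new ones
  for (int st = 1; st <= nSteps; ++st) {
    const int gstep = stepOffset + st;
    double U;
    pot_eval(centers, depths, widths, kconf, confCenter, x.data(), D, U, gU.data());
    double V = 0.0;
    if (m > 0) {
      for (int j = 0; j < m; ++j) s[j] = x[biased[j]];
      double v1 = 0.0, v2 = 0.0;
      std::vector<double> g1(m, 0.0), g2(m, 0.0);
      bias_eval(hills, nOld, m, s.data(), v1, g1.data());
      bias_eval(newHills, nNew, m, s.data(), v2, g2.data());
      V = v1 + v2;
      for (int j = 0; j < m; ++j) gV[j] = g1[j] + g2[j];
    }
    if (!std::isfinite(U) || !std::isfinite(V))
      stop("non-finite energy encountered: unstable timestep or parameters");

    // hill deposition before the move, PLUMED-style (at multiples of pace)
    if (m > 0 && pace > 0 && gstep % pace == 0) {
      double h = hillHeight;
      if (wtBiasFactor > 1.0)
        h *= std::exp(-V / (kT * (wtBiasFactor - 1.0)));
      if (nNew >= newHills.nrow()) stop("hill buffer overflow");
      for (int j = 0; j < m; ++j) {
        newHills(nNew, j) = s[j];
        newHills(nNew, m + j) = hillSigma[j];
      }
      newHills(nNew, 2 * m) = h;
      newHills(nNew, 2 * m + 1) = gstep * dt;
      // the new hill contributes to V and gV from the next step on
      ++nNew;
    }

    for (int d = 0; d < D; ++d) {
      double f = gU[d];
      if (m > 0)
        for (int j = 0; j < m; ++j)
          if (biased[j] == d) f += gV[j];
      x[d] += -dt / friction * f;
      if (noiseSd > 0.0) x[d] += noiseSd * norm_rand();
    }

    if (gstep % recordStride == 0) {
      recTime[ir] = gstep * dt;
      for (int d = 0; d < D; ++d) recX(ir, d) = x[d];
      // record bias at the *new* position so the stored gradient matches the
      // stored coordinates
      if (m > 0) {
        for (int j = 0; j < m; ++j) s[j] = x[biased[j]];
        double v1 = 0.0, v2 = 0.0;
        std::vector<double> g1(m, 0.0), g2(m, 0.0);
        bias_eval(hills, nOld, m, s.data(), v1, g1.data());
        bias_eval(newHills, nNew, m, s.data(), v2, g2.data());
        recBias[ir] = v1 + v2;
        for (int j = 0; j < m; ++j) recGrad(ir, j) = g1[j] + g2[j];
      } else {
        recBias[ir] = 0.0;
      }
      ++ir;
    }
  }

  NumericMatrix outHills;
  if (m > 0) {
    outHills = NumericMatrix(nOld + nNew, 2 * m + 2);
    for (int h = 0; h < nOld; ++h)
      for (int c = 0; c < 2 * m + 2; ++c) outHills(h, c) = hills(h, c);
    for (int h = 0; h < nNew; ++h)
      for (int c = 0; c < 2 * m + 2; ++c) outHills(nOld + h, c) = newHills(h, c);
  } else {
    outHills = NumericMatrix(0, 1);
  }

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["time"] = recTime, _["positions"] = recX,
                      _["bias"] = recBias, _["biasGradient"] = recGrad,
                      _["hills"] = outHills);
}
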