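#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One online update of the per-pixel Gaussian-mixture background model.
//
// w, mu, s2 are npx x K (pixel-major) and are updated IN PLACE: the model
// environment is their only owner. x is the new frame, pixel-major.
// Returns the binary foreground vector (1 = foreground), classified
// against the pre-update model.
//
// Rules (kept in lock-step with the scalar test oracle):
//  * component k is live iff w_k > 0; matching band is
//    max(thr, 2.5 * sd_k); the matched component is the matching one
//    with the highest fitness w/sd (first index on ties);
//  * a pixel is background iff the total weight of components ranked
//    strictly above its matched component is < T (so the component that
//    crosses T is part of the background set);
//  * matched: w_k += a*(hit - w_k); mean/variance move toward the sample
//    at rate rho = a, variance floored at s2_min;
//  * no match: the lowest-fitness component (dead slots first, first
//    index on ties) is replaced by (w_new, x, s2_init);
//  * weights renormalised to sum 1.
// [[Rcpp::export(name = ".mog_step")]]
NumericVector mog_step(NumericMatrix w, NumericMatrix mu, NumericMatrix s2,
                       NumericVector x, double thr, double alpha,
                       double T_bg, double s2_init, double s2_min,
                       double w_new) {
  const int npx = w.nrow(), K = w.ncol();
  NumericVector fg(npx);
  double *pw = REAL(w), *pmu = REAL(mu), *ps2 = REAL(s2);
  const double *px = REAL(x);
  double *pfg = REAL(fg);
  std::vector<double> wk(K), muk(K), s2k(K), score(K);

  for (int i = 0; i < npx; ++i) {
    const double xi = px[i];
    for (int k = 0; k < K; ++k) {
      const long o = (long)k * npx + i;
      wk[k] = pw[o]; muk[k] = pmu[o]; s2k[k] = ps2[o];
    }
    int matched = -1;
    double best = -1.0;
    for (int k = 0; k < K; ++k) {
      if (wk[k] > 0.0) {
        const double sd = std::sqrt(s2k[k]);
        score[k] = wk[k] / sd;
        double band = 2.5 * sd;
        if (band < thr) band = thr;
        if (std::fabs(xi - muk[k]) <= band && score[k] > best) {
          best = score[k];
          matched = k;
        }
      } else {
        score[k] = -1.0;
      }
    }
    bool background = false;
    if (matched >= 0) {
      double cumbefore = 0.0;
      for (int j = 0; j < K; ++j) {
        if (j == matched || wk[j] <= 0.0) continue;
        if (score[j] > score[matched] ||
            (score[j] == score[matched] && j < matched)) {
          cumbefore += wk[j];
        }
      }
      background = cumbefore < T_bg;
    }
    pfg[i] = background ? 0.0 : 1.0;

    // ---- update ----
    double wsum = 0.0;
    if (matched >= 0) {
      for (int k = 0; k < K; ++k) {
        wk[k] += alpha * ((k == matched ? 1.0 : 0.0) - wk[k]);
        wsum += wk[k];
      }
      const double rho = alpha;
      double m = muk[matched];
      m += rho * (xi - m);
      muk[matched] = m;
      double v = (1.0 - rho) * s2k[matched] + rho * (xi - m) * (xi - m);
      s2k[matched] = v < s2_min ? s2_min : v;
    } else {
      int weakest = 0;
      double worst = score[0];
      for (int k = 1; k < K; ++k) {
        if (score[k] < worst) { worst = score[k]; weakest = k; }
      }
      for (int k = 0; k < K; ++k) wk[k] *= (1.0 - alpha);
      wk[weakest] = w_new;
      muk[weakest] = xi;
      s2k[weakest] = s2_init;
      for (int k = 0; k < K; ++k) wsum += wk[k];
    }
    for (int k = 0; k < K; ++k) {
      const long o = (long)k * npx + i;
      pw[o] = wk[k] / wsum; pmu[o] = muk[k]; ps2[o] = s2k[k];
    }
  }
  return fg;
}
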