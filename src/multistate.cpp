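#include <Rcpp.h>
using namespace Rcpp;

// Forward pass over the hidden state space (S strata + absorbing dead state)
// for Arnason-Schwarz multistate encounter histories.
//
// Mass that dies is accumulated in a scalar per bird (dead birds are never
// resighted, so the remaining-unseen tail has probability 1); a detection
// zeroes that accumulator because dead mass is incompatible with it. This is
// the standard chi-recursion written as alive-vector + dead-scalar.
//
// Age is a time-varying state: juvenile rates apply only to the first
// interval after a juvenile's release (and juvenile p to the occasion that
// closes that interval); adult rates apply everywhere else.
//
// Individual covariates (hatch day, banding age) act on the logit of
// juvenile survival; they only ever matter at the release stratum in the
// release interval, where the alive mass is still a point mass.
//
// phi_ad:      S x (T-1) adult survival probabilities (fixes pre-applied)
// phi_juv_eta: S x (T-1) juvenile survival logits (NA where fixed)
// phi_juv_fix: S x (T-1) fixed juvenile survival values (NA where free)
// p_arr:       S x (T-1) x 2 resight probs for occasions 2..T (adult, juv)
// psi_arr:     S x S x (T-1) x 2 transition probs incl. stay (origin, dest)

// [[Rcpp::export]]
NumericVector ms_forward_logp_cpp(IntegerMatrix codes, IntegerVector first,
                                  LogicalVector juv, NumericVector hatch,
                                  NumericVector band, NumericVector phi_ad,
                                  NumericVector phi_juv_eta,
                                  NumericVector phi_juv_fix, double b_hatch,
                                  double b_band, NumericVector p_arr,
                                  NumericVector psi_arr, int S) {
  const int n = codes.nrow(), T = codes.ncol(), NI = T - 1;
  NumericVector logp(n);
  std::vector<double> alpha(S), anew(S);

  for (int i = 0; i < n; ++i) {
    const int f = first[i] - 1;  // 0-based release occasion
    std::fill(alpha.begin(), alpha.end(), 0.0);
    alpha[codes(i, f) - 1] = 1.0;
    double dead = 0.0;

    for (int t = f; t < NI; ++t) {
      const bool j = juv[i] && t == f;  // juvenile interval?
      // survival + transition
      std::fill(anew.begin(), anew.end(), 0.0);
      for (int r = 0; r < S; ++r) {
        if (alpha[r] <= 0.0) continue;
        double phi;
        if (j) {
          const double fx = phi_juv_fix[r + S * t];
          if (!ISNA(fx)) {
            phi = fx;
          } else {
            const double eta = phi_juv_eta[r + S * t] + b_hatch * hatch[i] +
                               b_band * band[i];
            phi = 1.0 / (1.0 + std::exp(-eta));
          }
        } else {
          phi = phi_ad[r + S * t];
        }
        dead += alpha[r] * (1.0 - phi);
        const double live = alpha[r] * phi;
        const int a = j ? 1 : 0;
        for (int s = 0; s < S; ++s)
          anew[s] += live * psi_arr[r + S * (s + S * (t + NI * a))];
      }
      // observation at occasion t + 1
      const int o = codes(i, t + 1);
      const int a = j ? 1 : 0;
      if (o > 0) {
        const double det =
            anew[o - 1] * p_arr[(o - 1) + S * (t + NI * a)];
        std::fill(anew.begin(), anew.end(), 0.0);
        anew[o - 1] = det;
        dead = 0.0;  // dead mass cannot be resighted
      } else {
        for (int s = 0; s < S; ++s)
          anew[s] *= 1.0 - p_arr[s + S * (t + NI * a)];
      }
      alpha.swap(anew);
    }
    double P = dead;
    for (int s = 0; s < S; ++s) P += alpha[s];
    logp[i] = std::log(P);
  }
  return logp;
}
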