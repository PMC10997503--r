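#include <Rcpp.h>
using namespace Rcpp;

// Pairwise kernels for the concordance measures. Both are O(n^2) over
// subject pairs, which is why they live in compiled code; the R-level
// wrappers do all validation.

// Harrell's C over usable pairs.
// Rules (documented in harrell_c()):
//  * t_i < t_j: usable iff the earlier subject had the event; credit 1 if
//    the earlier subject has the higher score, 0.5 on a score tie, else 0.
//  * t_i == t_j, both events: usable with 0.5 credit (no correct ordering).
//  * t_i == t_j, one event: the censored subject is taken to survive past
//    the tie, so the pair is usable with the event subject as "earlier".
// [[Rcpp::export]]
NumericVector harrell_c_pairs(NumericVector score, NumericVector time,
                              IntegerVector event) {
  const R_xlen_t n = score.size();
  double usable = 0.0, credit = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double ti = time[i], tj = time[j];
      double si = score[i], sj = score[j];
      int ei = event[i], ej = event[j];
      if (ti == tj) {
        if (ei == 1 && ej == 1) {
          usable += 1.0;
          credit += 0.5;
        } else if (ei != ej) {
          // event subject is the earlier one
          double se = (ei == 1) ? si : sj;
          double sc = (ei == 1) ? sj : si;
          usable += 1.0;
          credit += (se > sc) ? 1.0 : (se == sc ? 0.5 : 0.0);
        }
      } else {
        double tshort = (ti < tj) ? ti : tj;
        int eshort = (ti < tj) ? ei : ej;
        double sshort = (ti < tj) ? si : sj;
        double slong = (ti < tj) ? sj : si;
        (void)tshort;
        if (eshort == 1) {
          usable += 1.0;
          credit += (sshort > slong) ? 1.0 : (sshort == slong ? 0.5 : 0.0);
        }
      }
    }
  }
  return NumericVector::create(_["usable"] = usable, _["credit"] = credit);
}

// Goenen-Heller concordance probability kernel: mean over unordered pairs
// with distinct linear predictors of 1/(1 + exp(-|eta_i - eta_j|)).
// include_ties = true instead keeps tied pairs with 0.5 credit.
// [[Rcpp::export]]
NumericVector cpe_pairs(NumericVector eta, bool include_ties) {
  const R_xlen_t n = eta.size();
  double npair = 0.0, total = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double d = eta[i] - eta[j];
      if (d == 0.0) {
        if (include_ties) { npair += 1.0; total += 0.5; }
      } else {
        if (d < 0.0) d = -d;
        npair += 1.0;
        total += 1.0 / (1.0 + std::exp(-d));
      }
    }
  }
  return NumericVector::create(_["pairs"] = npair, _["total"] = total);
}

// Same estimate when the linear predictor takes few distinct values
// (e.g. fitted values of an ordered-group model): value[k] occurring
// count[k] times. Exact, O(K^2); used by the cutpoint search.
// [[Rcpp::export]]
NumericVector cpe_pairs_grouped(NumericVector value, NumericVector count,
                                bool include_ties) {
  const R_xlen_t K = value.size();
  double npair = 0.0, total = 0.0;
  for (R_xlen_t i = 0; i < K; ++i) {
    if (include_ties && count[i] > 1) {
      double w = count[i] * (count[i] - 1.0) / 2.0;
      npair += w;
      total += 0.5 * w;
    }
    for (R_xlen_t j = i + 1; j < K; ++j) {
      double d = value[i] - value[j];
      double w = count[i] * count[j];
      if (d == 0.0) {
        if (include_ties) { npair += w; total += 0.5 * w; }
      } else {
        if (d < 0.0) d = -d;
        npair += w;
        total += w / (1.0 + std::exp(-d));
      }
    }
  }
  return NumericVector::create(_["pairs"] = npair, _["total"] = total);
}
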