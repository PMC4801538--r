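#include <Rcpp.h>
using namespace Rcpp;

// OR-tree dead-time filter over events sorted by arrival time within
// contiguous runs of equal group id (one group = one sub-array in one laser
// period). An event is discarded iff it falls strictly less than tp after
// the reference event: the immediately preceding event in paralyzable mode
// (merged pulses keep the OR output high), the last accepted event in
// nonparalyzable mode. The first event of a group is always accepted.
// [[Rcpp::export]]
LogicalVector dead_time_keep(NumericVector t, IntegerVector grp, double tp,
                             bool paralyzable) {
  R_xlen_t n = t.size();
  if (grp.size() != n) stop("t and grp lengths differ");
  LogicalVector keep(n);
  double ref = 0.0, prev = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (i == 0 || grp[i] != grp[i - 1]) {
      keep[i] = true;
      ref = prev = t[i];
    } else {
      if (t[i] < prev) stop("events not sorted by time within group");
      double reft = paralyzable ? prev : ref;
      if (t[i] - reft < tp) {
        keep[i] = false;
      } else {
        keep[i] = true;
        ref = t[i];
      }
      prev = t[i];
    }
  }
  return keep;
}

// position of each element within its run of equal group ids (1-based);
// used to model TDC exhaustion (keep the first n_tdc arrivals per group)
// [[Rcpp::export]]
IntegerVector run_rank(IntegerVector grp) {
  R_xlen_t n = grp.size();
  IntegerVector r(n);
  int k = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    k = (i == 0 || grp[i] != grp[i - 1]) ? 1 : k + 1;
    r[i] = k;
  }
  return r;
}
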