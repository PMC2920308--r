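#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct-method inner loop for the fixed four-channel network.
//
// Channels (order fixed throughout the package):
//   A : x0 activates X3        a_A  = k_a  * x0  * x3
//   B1: x0 activates X1        a_B1 = k_b1 * x0  * x1
//   B2: X1* activates X2       a_B2 = k_b2 * x1a * x2
//   B3: X2* activates X3       a_B3 = k_b3 * x2a * x3
//
// The jump process is sampled onto `record_times` piecewise-constantly: the
// state reported at grid time tau is the state immediately after the last
// event with event time <= tau. Counts are carried in doubles (exact for
// integers far below 2^53). Uses R's RNG so set.seed() governs everything.
//
// Returns a matrix with one row per record time and columns
//   t, x1, x1a, x2, x2a, x3, x3a, fireA, fireB1, fireB2, fireB3

// [[Rcpp::export]]
NumericMatrix ssa_core(double x0,
                       double x1_total, double x2_total, double x3_total,
                       double k_a, double k_b1, double k_b2, double k_b3,
                       NumericVector record_times, double t_max) {
  const int n = record_times.size();
  NumericMatrix out(n, 11);

  double x1 = x1_total, x1a = 0, x2 = x2_total, x2a = 0, x3 = x3_total, x3a = 0;
  double fA = 0, fB1 = 0, fB2 = 0, fB3 = 0;
  double t = 0.0;
  int ri = 0;

  for (;;) {
    const double aA  = k_a  * x0  * x3;
    const double aB1 = k_b1 * x0  * x1;
    const double aB2 = k_b2 * x1a * x2;
    const double aB3 = k_b3 * x2a * x3;
    const double a0 = aA + aB1 + aB2 + aB3;

    // time of the next event (absorbing state => never)
    double tn;
    if (a0 > 0.0) {
      tn = t + R::exp_rand() / a0;
    } else {
      tn = R_PosInf;
    }

    while (ri < n && record_times[ri] < tn) {
      out(ri, 0) = record_times[ri];
      out(ri, 1) = x1;  out(ri, 2) = x1a;
      out(ri, 3) = x2;  out(ri, 4) = x2a;
      out(ri, 5) = x3;  out(ri, 6) = x3a;
      out(ri, 7) = fA;  out(ri, 8) = fB1;
      out(ri, 9) = fB2; out(ri, 10) = fB3;
      ++ri;
    }
    if (ri >= n || tn > t_max) break;

    t = tn;
    const double u = unif_rand() * a0;
    if (u < aA) {
      x3 -= 1; x3a += 1; fA += 1;
    } else if (u < aA + aB1) {
      x1 -= 1; x1a += 1; fB1 += 1;
    } else if (u < aA + aB1 + aB2) {
      x2 -= 1; x2a += 1; fB2 += 1;
    } else {
      x3 -= 1; x3a += 1; fB3 += 1;
    }
  }
  return out;
}
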