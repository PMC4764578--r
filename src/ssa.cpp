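#include <Rcpp.h>
using namespace Rcpp;

// Direct-method stochastic simulation of the four-stage chain.
// Reactions (propensities):
//   influx        -> DN3        K
//   DN3 -> DN4                  K1  * C1
//   DN3 -> loss                 Kd1 * C1
//   DN4 -> ISP                  K2  * C2
//   DN4 -> loss                 Kd2 * C2
//   ISP -> DP                   K3  * C3
//   ISP -> loss                 Kd3 * C3
//   DP  -> loss                 Kd4 * C4
// Uses R's RNG so trajectories are reproducible under set.seed().
// Records the state by piecewise-constant interpolation at record_times.
// [[Rcpp::export]]
NumericMatrix ssa_chain_cpp(NumericVector rates, NumericVector c0,
                            double t0, NumericVector record_times) {
  const double K = rates["K"], K1 = rates["K1"], Kd1 = rates["Kd1"],
               K2 = rates["K2"], Kd2 = rates["Kd2"], K3 = rates["K3"],
               Kd3 = rates["Kd3"], Kd4 = rates["Kd4"];
  double C[4] = {c0[0], c0[1], c0[2], c0[3]};
  const int nrec = record_times.size();
  NumericMatrix out(nrec, 4);
  RNGScope scope;
  double t = t0;
  int irec = 0;
  const double t_end = record_times[nrec - 1];
  for (;;) {
    double a[8];
    a[0] = K;
    a[1] = K1 * C[0];  a[2] = Kd1 * C[0];
    a[3] = K2 * C[1];  a[4] = Kd2 * C[1];
    a[5] = K3 * C[2];  a[6] = Kd3 * C[2];
    a[7] = Kd4 * C[3];
    double atot = 0.0;
    for (int k = 0; k < 8; ++k) atot += a[k];
    double t_next = (atot > 0.0) ? t + R::rexp(1.0 / atot) : R_PosInf;
    while (irec < nrec && record_times[irec] <= t_next) {
      for (int j = 0; j < 4; ++j) out(irec, j) = C[j];
      ++irec;
    }
    if (irec >= nrec || t_next > t_end) break;
    t = t_next;
    double u = R::unif_rand() * atot, cum = 0.0;
    int r = 7;
    for (int k = 0; k < 8; ++k) { cum += a[k]; if (u <= cum) { r = k; break; } }
    switch (r) {
      case 0: C[0] += 1; break;
      case 1: C[0] -= 1; C[1] += 1; break;
      case 2: C[0] -= 1; break;
      case 3: C[1] -= 1; C[2] += 1; break;
      case 4: C[1] -= 1; break;
      case 5: C[2] -= 1; C[3] += 1; break;
      case 6: C[2] -= 1; break;
      case 7: C[3] -= 1; break;
    }
  }
  return out;
}
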