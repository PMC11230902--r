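#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of the two-stage
// mass-action network, in integer molecule counts:
//   0: A_S + L   -> I_S   (c1S)     3: I_R + A_S -> P_RS (c2het)
//   1: A_R + L   -> I_R   (c1R)     4: I_S + A_S -> P_SS (c2hom)
//   2: I_S + A_R -> P_SR  (c2het)   5: I_R + A_R -> P_RR (c2hom)
// Species order: A_S, A_R, L, I_S, I_R, P_SR, P_RS, P_SS, P_RR.
// Stochastic rate constants c are the deterministic k divided by the
// system-size factor omega (computed by the R wrapper). Uses R's RNG, so
// set.seed() in R fixes the trajectory bit-for-bit.

// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(IntegerVector y0, NumericVector c, int n_snapshots) {
  if (y0.size() != 9) stop("y0 must have 9 species");
  if (c.size() != 4) stop("c must have 4 rate constants");
  long long y[9];
  for (int i = 0; i < 9; ++i) y[i] = y0[i];

  const double c1S = c[0], c1R = c[1], c2het = c[2], c2hom = c[3];

  // hard bound on event count: each event consumes one L or one I unit
  long long max_events = 2LL * y[2] + y[3] + y[4] + 1;
  int every = (int)std::max(1LL, max_events / std::max(1, n_snapshots));

  std::vector<double> times;
  std::vector<long long> snaps;
  times.reserve(n_snapshots + 2);
  snaps.reserve(9 * (n_snapshots + 2));

  double t = 0.0;
  long long ev = 0;
  auto record = [&]() {
    times.push_back(t);
    for (int i = 0; i < 9; ++i) snaps.push_back(y[i]);
  };
  record();

  double a[6];
  while (true) {
    a[0] = c1S * (double)y[0] * (double)y[2];
    a[1] = c1R * (double)y[1] * (double)y[2];
    a[2] = c2het * (double)y[3] * (double)y[1];
    a[3] = c2het * (double)y[4] * (double)y[0];
    a[4] = c2hom * (double)y[3] * (double)y[0];
    a[5] = c2hom * (double)y[4] * (double)y[1];
    double a0 = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
    if (a0 <= 0.0) break;
    t += R::exp_rand() / a0;
    double u = unif_rand() * a0;
    int j = 0;
    double acc = a[0];
    while (j < 5 && u > acc) acc += a[++j];
    switch (j) {
      case 0: --y[0]; --y[2]; ++y[3]; break;
      case 1: --y[1]; --y[2]; ++y[4]; break;
      case 2: --y[3]; --y[1]; ++y[5]; break;
      case 3: --y[4]; --y[0]; ++y[6]; break;
      case 4: --y[3]; --y[0]; ++y[7]; break;
      case 5: --y[4]; --y[1]; ++y[8]; break;
    }
    ++ev;
    if (ev % every == 0) record();
  }
  record();  // final state (exhausted network)

  int n = times.size();
  NumericMatrix states(n, 9);
  for (int r = 0; r < n; ++r)
    for (int i = 0; i < 9; ++i)
      states(r, i) = (double)snaps[(size_t)r * 9 + i];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = states,
                      _["n_events"] = (double)ev);
}
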