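#include <Rcpp.h>
using namespace Rcpp;

// Direct-method stochastic simulation of a mass-action network.
//
// Uses R's RNG stream (two uniforms per event: waiting time, reaction
// choice) so that trajectories are reproducible under set.seed().
//
// A step-change drug schedule is supported for a single target reaction:
// for t >= t_drug its rate constant is multiplied by post_factor. When a
// sampled waiting time would cross t_drug, the clock is advanced to
// t_drug, rates are switched and the waiting time is re-drawn, which is
// exact because exponential waiting times are memoryless.
//
// [[Rcpp::export]]
List ssa_run_cpp(IntegerMatrix stoich, NumericVector rates, IntegerMatrix orders,
                 IntegerVector x0, double t0, double tmax,
                 int drug_reaction, double t_drug, double post_factor,
                 int max_events) {
  const int N = stoich.nrow(), M = stoich.ncol();
  std::vector<double> times;
  std::vector<int> states_flat;
  times.reserve(1024);
  states_flat.reserve(1024 * N);
  std::vector<double> x(N), w(M);
  for (int i = 0; i < N; ++i) x[i] = x0[i];
  double t = t0;

  while (true) {
    double a0 = 0.0;
    for (int mu = 0; mu < M; ++mu) {
      double r = rates[mu];
      if (mu == drug_reaction && t >= t_drug) r *= post_factor;
      double ww = r;
      for (int i = 0; i < N; ++i) {
        const int o = orders(i, mu);
        if (o == 1) ww *= x[i];
        else if (o == 2) ww *= x[i] * (x[i] - 1.0) / 2.0;
        else if (o > 2) {
          double c = 1.0;
          for (int q = 0; q < o; ++q) c *= (x[i] - q) / (q + 1.0);
          ww *= c;
        }
      }
      if (ww < 0.0) ww = 0.0;
      w[mu] = ww;
      a0 += ww;
    }
    if (a0 <= 0.0) break;  // no further events possible

    const double u1 = unif_rand();
    const double tau = -std::log(u1) / a0;
    const double tnext = t + tau;
    if (drug_reaction >= 0 && t < t_drug && tnext >= t_drug) {
      t = t_drug;  // pause at the rate switch, re-draw the waiting time
      continue;
    }
    if (tnext > tmax) break;
    t = tnext;

    const double u2 = unif_rand();
    const double target = u2 * a0;
    double csum = 0.0;
    int k = M - 1;
    for (int mu = 0; mu < M; ++mu) {
      csum += w[mu];
      if (csum >= target) { k = mu; break; }
    }
    for (int i = 0; i < N; ++i) x[i] += stoich(i, k);

    times.push_back(t);
    for (int i = 0; i < N; ++i) states_flat.push_back(static_cast<int>(x[i]));
    if (static_cast<int>(times.size()) >= max_events)
      stop("SSA exceeded max_events (%d); raise the cap or shorten t_max", max_events);
  }

  const int E = static_cast<int>(times.size());
  IntegerMatrix states(E, N);
  for (int e = 0; e < E; ++e)
    for (int i = 0; i < N; ++i) states(e, i) = states_flat[e * N + i];
  IntegerVector xfinal(N);
  for (int i = 0; i < N; ++i) xfinal[i] = static_cast<int>(x[i]);
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = states, _["final"] = xfinal);
}
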