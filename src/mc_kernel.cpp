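#include <Rcpp.h>
using namespace Rcpp;

// Metropolis single-flip sampler for the saturated enantiomer lattice.
//
// Hamiltonian: H = -h * sum_i chi_i - jpair * sum_{unordered NN} chi_i chi_j
// on an n x n torus, chi = +/-1 (+1 = D). One sweep = n^2 flip attempts at
// uniformly random sites; a flip is accepted if dE <= 0, else with
// probability exp(-dE / (R T)). Draws come from R's RNG stream (RNGScope),
// so set.seed() in R gives bit-identical trajectories.
//
// dE for a flip takes only 10 values (chi = +/-1, neighbour sum in
// {-4,-2,0,2,4}), so acceptance probabilities are table lookups.
//
// Returns the final lattice plus one row per retained sample of
// (ees, energy per site, homochiral pair fraction), recorded every
// sample_interval sweeps during the measurement phase.
// [[Rcpp::export]]
List mc_run_cpp(IntegerMatrix chi_in, double h, double jpair, double rt,
                int burn_sweeps, int measure_sweeps, int sample_interval) {
  const int n = chi_in.nrow();
  if (chi_in.ncol() != n) stop("lattice must be square");
  const int n2 = n * n;
  IntegerMatrix chi = clone(chi_in);

  // Running sums: sum_chi = sum of labels, sum_pair = sum over unordered
  // periodic NN pairs of chi_i * chi_j (each site paired with its right
  // and down neighbour covers all 2 n^2 pairs once).
  long sum_chi = 0, sum_pair = 0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      const int c = chi(i, j);
      sum_chi += c;
      sum_pair += c * chi((i + 1) % n, j);
      sum_pair += c * chi(i, (j + 1) % n);
    }

  // acc[(c+1)/2][(s+4)/2] = min(1, exp(-dE/rt)), dE = 2 c (h + jpair s)
  double acc[2][5];
  for (int ci = 0; ci < 2; ++ci)
    for (int si = 0; si < 5; ++si) {
      const int c = 2 * ci - 1, s = 2 * si - 4;
      const double de = 2.0 * c * (h + jpair * s);
      acc[ci][si] = de <= 0.0 ? 1.0 : std::exp(-de / rt);
    }

  const int n_samples =
      measure_sweeps > 0 ? measure_sweeps / sample_interval : 0;
  NumericMatrix samples(n_samples, 3);
  int taken = 0;

  const int total_sweeps = burn_sweeps + measure_sweeps;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int att = 0; att < n2; ++att) {
      int i = (int)(n * unif_rand()); if (i == n) i = n - 1;
      int j = (int)(n * unif_rand()); if (j == n) j = n - 1;
      const int c = chi(i, j);
      const int s = chi(i == 0 ? n - 1 : i - 1, j)
                  + chi(i == n - 1 ? 0 : i + 1, j)
                  + chi(i, j == 0 ? n - 1 : j - 1)
                  + chi(i, j == n - 1 ? 0 : j + 1);
      const double p = acc[(c + 1) / 2][(s + 4) / 2];
      if (p >= 1.0 || unif_rand() < p) {
        chi(i, j) = -c;
        sum_chi -= 2L * c;
        sum_pair -= 2L * c * s;
      }
    }
    const int msweep = sweep - burn_sweeps + 1;  // 1-based measurement sweep
    if (msweep >= 1 && msweep % sample_interval == 0 && taken < n_samples) {
      samples(taken, 0) = (double)sum_chi / n2;
      samples(taken, 1) = (-h * sum_chi - jpair * sum_pair) / n2;
      samples(taken, 2) = (1.0 + (double)sum_pair / (2.0 * n2)) / 2.0;
      ++taken;
    }
  }

  return List::create(_["lattice"] = chi, _["samples"] = samples);
}
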