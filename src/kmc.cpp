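#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gillespie ("step by step") trajectories of one excitation on a frozen
// particle realization.  Donor rows of `transfer` hold Foerster rates to every
// other fluorophore (columns: the n_d donors first, then acceptors); acceptors
// are absorbing.  Waiting times are exponential in the current total exit rate
// W = decay_rate + sum_j w_ij; the event is chosen with probability
// proportional to its rate.  Uses R's RNG, so set.seed() gives bitwise
// reproducibility.
//
// termination codes: 1 = intrinsic donor decay, 2 = acceptor trapping.

// [[Rcpp::export]]
DataFrame run_kmc_cpp(NumericMatrix transfer, double decay_rate,
                      NumericMatrix chord2, int n_traj) {
  const int n_d = transfer.nrow();
  const int n_tot = transfer.ncol();
  if (n_d < 1) stop("at least one donor is required");
  if (!(decay_rate > 0)) stop("decay_rate must be positive");

  // per-donor cumulative transfer rates (row-major)
  std::vector<double> cum((size_t)n_d * n_tot);
  std::vector<double> wtot(n_d);
  for (int i = 0; i < n_d; ++i) {
    double s = 0.0;
    for (int j = 0; j < n_tot; ++j) {
      double w = transfer(i, j);
      if (w < 0) stop("negative transfer rate");
      s += w;
      cum[(size_t)i * n_tot + j] = s;
    }
    wtot[i] = s;
  }

  NumericVector time(n_traj), sqd(n_traj);
  IntegerVector term(n_traj), jumps(n_traj);

  for (int k = 0; k < n_traj; ++k) {
    if ((k & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    int start = (int)(unif_rand() * n_d);
    if (start >= n_d) start = n_d - 1;
    int cur = start, nj = 0, fin = start, tc = 1;
    double t = 0.0;
    for (;;) {
      double W = decay_rate + wtot[cur];
      t += exp_rand() / W;
      double u = unif_rand() * W;
      if (u <= decay_rate || wtot[cur] <= 0.0) { tc = 1; fin = cur; break; }
      double target = u - decay_rate;
      const double* row = &cum[(size_t)cur * n_tot];
      int lo = 0, hi = n_tot - 1;
      while (lo < hi) {
        int mid = (lo + hi) >> 1;
        if (row[mid] >= target) hi = mid; else lo = mid + 1;
      }
      if (lo < n_d) { cur = lo; ++nj; }
      else { tc = 2; fin = lo; break; }
    }
    time[k] = t;
    term[k] = tc;
    jumps[k] = nj;
    sqd[k] = chord2(start, fin);
  }

  return DataFrame::create(_["event_time"] = time, _["termination"] = term,
                           _["n_jumps"] = jumps, _["sq_displacement"] = sqd);
}
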