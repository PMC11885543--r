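#include <Rcpp.h>
using namespace Rcpp;

// Binomial draw with (possibly) huge n, chunked so R::rbinom never sees more
// than 1e9 trials at once.
static double rbinom_big(double n, double p) {
  double total = 0.0;
  while (n > 0.5) {
    double chunk = (n > 1e9) ? 1e9 : n;
    total += R::rbinom(chunk, p);
    n -= chunk;
  }
  return total;
}

// Moran-model ensemble, marginal representation.
//
// Each cell experiences K ~ Poisson(lambda_events) replication/death events
// over its lifetime (or exactly round(lambda_events) events when
// poisson_events is false).  Each event introduces m ~ Binomial(L, nu) novel
// mutations on the daughter molecule (infinite sites).  A mutation's copy
// count then performs, marginally, a birth-death walk on {0, ..., N}: per
// event it moves +1 or -1 each with probability p(1-p), p = k/N, else stays.
// Under neutrality each mutation's marginal law is exact; mutations are
// simulated independently (linkage between mutations on one molecule is not
// represented -- see simulate_cell_genomes() for the per-molecule version).
//
// obs_frac: sorted fractions of the lifetime (in (0, 1]) at which the state
// is recorded.  Observation event indices are drawn jointly (multinomial over
// the inter-observation intervals) so observations of one cell are nested.
//
// Returns, per observation point, parallel integer vectors (cell, count):
// one entry per mutation segregating (0 < count < N) or fixed (count == N)
// in that cell at that time.
// [[Rcpp::export]]
List cpp_moran_cells(int N, int n_cells, double lambda_events,
                     NumericVector obs_frac, double L, double nu,
                     bool poisson_events = true) {
  int n_obs = obs_frac.size();
  std::vector< std::vector<int> > out_cell(n_obs), out_count(n_obs);
  std::vector<double> o(n_obs);
  NumericVector events_per_cell(n_cells);

  for (int c = 0; c < n_cells; ++c) {
    double K = poisson_events ? R::rpois(lambda_events)
                              : std::floor(lambda_events + 0.5);
    events_per_cell[c] = K;
    // observation event indices: nested binomial splits
    double prev_f = 0.0, prev_o = 0.0, rem = K;
    for (int i = 0; i < n_obs; ++i) {
      double span = 1.0 - prev_f;
      double pi = (span <= 0.0) ? 1.0 : (obs_frac[i] - prev_f) / span;
      if (pi > 1.0) pi = 1.0;
      if (pi < 0.0) pi = 0.0;
      double ni = (pi >= 1.0) ? rem : R::rbinom(rem, pi);
      o[i] = prev_o + ni;
      rem -= ni;
      prev_f = obs_frac[i];
      prev_o = o[i];
    }

    double M = rbinom_big(K * L, nu);
    for (double m = 0; m < M; ++m) {
      double b = std::floor(unif_rand() * K) + 1.0; // birth event index
      if (b > K) b = K;
      int cur = 1;
      double seg_start = b;
      int j = 0;
      while (j < n_obs && o[j] < b) ++j; // first observation seeing it
      while (true) {
        if (cur == 0) break;
        if (cur == N) { // fixed: visible at every later observation
          for (; j < n_obs; ++j) {
            if (o[j] >= seg_start) {
              out_cell[j].push_back(c + 1);
              out_count[j].push_back(N);
            }
          }
          break;
        }
        double p = (double)cur / N;
        double pr = 2.0 * p * (1.0 - p);
        double gap = R::rgeom(pr) + 1.0;
        double seg_end = seg_start + gap - 1.0; // last event with this count
        while (j < n_obs && o[j] <= seg_end) {
          out_cell[j].push_back(c + 1);
          out_count[j].push_back(cur);
          ++j;
        }
        if (seg_end >= K) break;
        cur += (unif_rand() < 0.5) ? 1 : -1;
        seg_start = seg_end + 1.0;
        if (j >= n_obs && cur != 0) {
          // nothing left to record; still need absorption for correctness?
          // no: state beyond the last observation is irrelevant
          break;
        }
      }
    }
  }

  List res(n_obs);
  for (int i = 0; i < n_obs; ++i) {
    res[i] = List::create(_["cell"] = wrap(out_cell[i]),
                          _["count"] = wrap(out_count[i]));
  }
  res.attr("events_per_cell") = events_per_cell;
  return res;
}

// Track single new mutations (copy count 1) to absorption; returns the
// number out of n_trials that reach fixation (count N).  Used for the
// neutral fixation-probability check (expected fraction 1/N).
// [[Rcpp::export]]
int cpp_fixation_trials(int N, int n_trials) {
  int fixed = 0;
  for (int t = 0; t < n_trials; ++t) {
    int cur = 1;
    while (cur > 0 && cur < N) {
      cur += (unif_rand() < 0.5) ? 1 : -1;
    }
    if (cur == N) ++fixed;
  }
  return fixed;
}
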