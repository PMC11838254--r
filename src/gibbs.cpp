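#include <Rcpp.h>
using namespace Rcpp;

// Single-site heat-bath (Gibbs) sampler for the 1-D nearest-neighbor
// lattice in the grand-canonical ensemble.  One sweep = n_sites single-site
// updates in a freshly randomized site order.  The conditional probability
// of state s at a site is proportional to w[s] * pair(left, s) * pair(s,
// right); a missing neighbor (free boundary) contributes factor 1.  All
// randomness flows through R's RNG so a set.seed() in the caller makes the
// run fully reproducible.
//
// Returns, per recorded sweep, the per-state site counts and the ordered
// neighbor-pair counts (flattened k x k, column-major).
// [[Rcpp::export]]
List gibbs_lattice(NumericVector weights, NumericMatrix pairs, int n_sites,
                   bool periodic, int sweeps, int burn_in, int thinning) {
  const int k = weights.size();
  if (pairs.nrow() != k || pairs.ncol() != k)
    stop("pair matrix does not match the number of states");
  if (n_sites < 1) stop("n_sites must be >= 1");
  if (burn_in >= sweeps) stop("burn_in must be < sweeps");
  if (thinning < 1) stop("thinning must be >= 1");

  RNGScope scope;

  // initial configuration: independent draws from the site weights
  std::vector<int> state(n_sites);
  double wtot = 0.0;
  for (int s = 0; s < k; ++s) wtot += weights[s];
  if (wtot <= 0.0) stop("all site weights are zero");
  for (int i = 0; i < n_sites; ++i) {
    double u = unif_rand() * wtot, acc = 0.0;
    int s = k - 1;
    for (int j = 0; j < k; ++j) {
      acc += weights[j];
      if (u <= acc) { s = j; break; }
    }
    state[i] = s;
  }

  std::vector<int> order(n_sites);
  for (int i = 0; i < n_sites; ++i) order[i] = i;
  std::vector<double> cond(k);

  const int n_rec = (sweeps - burn_in + thinning - 1) / thinning;
  IntegerMatrix state_counts(n_rec, k);
  IntegerMatrix pair_counts(n_rec, k * k);
  IntegerVector rec_sweep(n_rec);
  int rec = 0;

  for (int sweep = 1; sweep <= sweeps; ++sweep) {
    // Fisher-Yates shuffle via R's RNG
    for (int i = n_sites - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int t = 0; t < n_sites; ++t) {
      const int i = order[t];
      const int left  = (i > 0) ? state[i - 1]
                        : (periodic && n_sites > 1 ? state[n_sites - 1] : -1);
      const int right = (i < n_sites - 1) ? state[i + 1]
                        : (periodic && n_sites > 1 ? state[0] : -1);
      double tot = 0.0;
      for (int s = 0; s < k; ++s) {
        double p = weights[s];
        if (left  >= 0) p *= pairs(left, s);
        if (right >= 0) p *= pairs(s, right);
        cond[s] = p;
        tot += p;
      }
      if (tot <= 0.0) stop("zero conditional probability encountered");
      double u = unif_rand() * tot, acc = 0.0;
      int s_new = k - 1;
      for (int s = 0; s < k; ++s) {
        acc += cond[s];
        if (u <= acc) { s_new = s; break; }
      }
      state[i] = s_new;
    }
    if (sweep > burn_in && ((sweep - burn_in - 1) % thinning == 0)) {
      for (int i = 0; i < n_sites; ++i) state_counts(rec, state[i])++;
      const int n_bonds = periodic ? n_sites : n_sites - 1;
      for (int b = 0; b < n_bonds; ++b) {
        const int s1 = state[b];
        const int s2 = state[(b + 1) % n_sites];
        pair_counts(rec, s1 + k * s2)++;
      }
      rec_sweep[rec] = sweep;
      ++rec;
    }
  }

  return List::create(_["sweep"] = rec_sweep,
                      _["state_counts"] = state_counts,
                      _["pair_counts"] = pair_counts);
}
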