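#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <set>

using namespace Rcpp;

// nearest integer, halves rounded away from zero
static inline int nint(double x) {
  return (int)(x >= 0 ? std::floor(x + 0.5) : std::ceil(x - 0.5));
}

// penalized objective Y = -sum(d) + mu*sum(max(0,g)^2) + lam*sum(h^2)
// d_k is the signed directional amplitude of step k: +(v_j - v_i) leaving a
// nadir, -(v_j - v_i) leaving a peak (the extreme kinds strictly alternate,
// so the direction of index i follows its parity given the first kind);
// g_k = thr - d_k, h_k = (-1)^(n_{k+1}-n_k) + 1
static double eval_Y(const int* sel, int K, const double* vals,
                     double thr, double mu, double lam,
                     bool first_kind_min) {
  double z = 0.0, pen = 0.0;
  for (int k = 0; k + 1 < K; ++k) {
    bool i_is_min = ((sel[k] & 1) == 1) == first_kind_min;  // 1-based index
    double d = vals[sel[k + 1] - 1] - vals[sel[k] - 1];
    if (!i_is_min) d = -d;
    z += d;
    double g = thr - d;
    if (g > 0) pen += mu * g * g;
    int dn = sel[k + 1] - sel[k];
    if ((dn & 1) == 0) pen += lam * 4.0;  // h = 2 when the gap is even
  }
  return -z + pen;
}

static inline int runif_int(int n) {  // uniform on 0..n-1
  int r;
  do {
    r = (int)(unif_rand() * n);
  } while (r >= n);  // guard the measure-zero unif_rand() == 1 edge
  return r;
}

// One K-slice of the integer DE search: NP sorted integer vectors of
// dimension K over {1..N}, G generations of difference mutation / binomial
// crossover / greedy selection on the penalized objective. `warm` rows (if
// any, at most NP/2 are used) are injected into the otherwise uniform
// initial population; after each generation, population members that
// duplicate an earlier member are re-drawn uniformly, which counters the
// stagnation that rounding to integers induces (the first copy of each
// vector, and hence the incumbent best, is always retained). Returns the
// best vector seen and its Y. Uses R's RNG, so results are reproducible
// under set.seed().
// [[Rcpp::export]]
List de_solve_k_cpp(NumericVector values, double threshold, int K,
                    int np, double f, double cr, int generations,
                    double mu, double lam, bool reinit_duplicates,
                    Nullable<IntegerMatrix> warm, bool first_kind_min) {
  const int N = values.size();
  const double* vals = REAL(values);
  if (N < 1 || K < 2 || np < 4) stop("invalid DE dimensions");

  std::vector<std::vector<int> > pop(np, std::vector<int>(K));
  std::vector<double> y(np);

  // (a) initialization: entry = 1 + NINT(rho * (N - 1)), rows sorted;
  // warm rows (clamped, sorted) come first
  int nw = 0;
  if (warm.isNotNull()) {
    IntegerMatrix wm(warm);
    if (wm.ncol() != K) stop("warm-start rows must have length K");
    nw = std::min((int)wm.nrow(), np / 2);
    for (int i = 0; i < nw; ++i) {
      for (int j = 0; j < K; ++j) {
        int v = wm(i, j);
        if (v < 1) v = 1;
        if (v > N) v = N;
        pop[i][j] = v;
      }
      std::sort(pop[i].begin(), pop[i].end());
    }
  }
  for (int i = nw; i < np; ++i) {
    for (int j = 0; j < K; ++j)
      pop[i][j] = 1 + nint(unif_rand() * (N - 1));
    std::sort(pop[i].begin(), pop[i].end());
  }
  for (int i = 0; i < np; ++i)
    y[i] = eval_Y(pop[i].data(), K, vals, threshold, mu, lam, first_kind_min);

  std::vector<int> bestv = pop[0];
  double besty = y[0];
  for (int i = 1; i < np; ++i)
    if (y[i] < besty) { besty = y[i]; bestv = pop[i]; }

  std::vector<std::vector<int> > newpop(pop);
  std::vector<int> trial(K);
  for (int g = 0; g < generations; ++g) {
    for (int i = 0; i < np; ++i) {
      // (b) mutation: three mutually distinct donors, all != i
      int r1, r2, r3;
      do { r1 = runif_int(np); } while (r1 == i);
      do { r2 = runif_int(np); } while (r2 == i || r2 == r1);
      do { r3 = runif_int(np); } while (r3 == i || r3 == r1 || r3 == r2);
      // (c) crossover with guaranteed mutant coordinate j_rand;
      // mutant entries are clamped into [1, N]
      int jrand = runif_int(K);
      for (int j = 0; j < K; ++j) {
        bool take = (unif_rand() <= cr) || (j == jrand);
        if (take) {
          int v = pop[r1][j] + nint(f * (pop[r2][j] - pop[r3][j]));
          if (v < 1) v = 1;
          if (v > N) v = N;
          trial[j] = v;
        } else {
          trial[j] = pop[i][j];
        }
      }
      std::sort(trial.begin(), trial.end());
      // (d) greedy selection
      double yt = eval_Y(trial.data(), K, vals, threshold, mu, lam, first_kind_min);
      if (yt < y[i]) {
        newpop[i] = trial;
        y[i] = yt;
      } else {
        newpop[i] = pop[i];
      }
      if (y[i] < besty) { besty = y[i]; bestv = newpop[i]; }
    }
    pop.swap(newpop);
    if (reinit_duplicates) {
      std::set<std::vector<int> > seen;
      for (int i = 0; i < np; ++i) {
        if (!seen.insert(pop[i]).second) {
          for (int j = 0; j < K; ++j)
            pop[i][j] = 1 + nint(unif_rand() * (N - 1));
          std::sort(pop[i].begin(), pop[i].end());
          y[i] = eval_Y(pop[i].data(), K, vals, threshold, mu, lam, first_kind_min);
          if (y[i] < besty) { besty = y[i]; bestv = pop[i]; }
        }
      }
    }
  }

  return List::create(_["indices"] = IntegerVector(bestv.begin(),
                                                   bestv.end()),
                      _["y"] = besty);
}
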