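#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// Systematic-scan Gibbs sweeps over a fixed-length simple path.
//
// One sweep resamples every interior position i = 2..L-1 in order from its
// exact full conditional: candidates are genes adjacent to both neighbours,
// inside the position's domain and not already elsewhere on the path (the
// incumbent gene is always a candidate), weighted by
// exp((wnode[g] + wedge(prev,g) + wedge(g,next) + dV3(g)) / T).
//
// All matrices are indexed over subnetwork genes (0-based here; the R side
// passes 1-based and we convert). Uses R's RNG stream, so results are
// bitwise reproducible under set.seed().
//
// locrank: 0 = unknown/other (matches anything), 1 = membrane,
// 2 = cytoplasm, 3 = nucleus. wlam = w3 * lambda / (L - 1).

static inline double conc(int ra, int rb) {
  return (ra == 0 || rb == 0 || rb >= ra) ? 1.0 : 0.0;
}

// [[Rcpp::export(name = ".gibbs_sweeps")]]
List gibbs_sweeps(IntegerVector init, List adj, LogicalMatrix adjmat,
                  NumericVector wnode, NumericMatrix wedge,
                  LogicalMatrix dom, IntegerVector locrank, double wlam,
                  double temperature, int iterations, int burnin) {
  const int L = init.size();
  const int S = wnode.size();
  std::vector<int> path(L);
  std::vector<bool> onpath(S, false);
  for (int i = 0; i < L; ++i) {
    path[i] = init[i] - 1;
    onpath[path[i]] = true;
  }
  std::vector<std::vector<int> > nbr(S);
  for (int g = 0; g < S; ++g) {
    IntegerVector v = adj[g];
    nbr[g].reserve(v.size());
    for (int k = 0; k < v.size(); ++k) nbr[g].push_back(v[k] - 1);
  }

  typedef std::map<std::vector<int>, std::pair<long, long> > PathMap;
  PathMap tally;
  const int recorded_total = iterations - burnin;
  const int half1 = recorded_total / 2;

  std::vector<int> cand;
  std::vector<double> score;
  cand.reserve(S);
  score.reserve(S);
  int recorded = 0;

  for (int sweep = 0; sweep < iterations; ++sweep) {
    for (int i = 1; i < L - 1; ++i) {
      const int prev = path[i - 1];
      const int next = path[i + 1];
      const int cur = path[i];
      cand.clear();
      score.clear();
      const std::vector<int>& pn = nbr[prev];
      double smax = R_NegInf;
      for (size_t k = 0; k < pn.size(); ++k) {
        const int g = pn[k];
        if (!adjmat(g, next)) continue;
        if (!dom(i, g)) continue;
        if (onpath[g] && g != cur) continue;
        double s = wnode[g] + wedge(prev, g) + wedge(g, next) +
          wlam * (conc(locrank[prev], locrank[g]) +
                  conc(locrank[g], locrank[next]));
        s /= temperature;
        cand.push_back(g);
        score.push_back(s);
        if (s > smax) smax = s;
      }
      // the incumbent always qualifies, so cand is never empty
      double total = 0.0;
      for (size_t k = 0; k < score.size(); ++k) {
        score[k] = std::exp(score[k] - smax);
        total += score[k];
      }
      double u = unif_rand() * total;
      int chosen = cand.back();
      for (size_t k = 0; k < score.size(); ++k) {
        u -= score[k];
        if (u <= 0.0) { chosen = cand[k]; break; }
      }
      if (chosen != cur) {
        onpath[cur] = false;
        onpath[chosen] = true;
        path[i] = chosen;
      }
    }
    if (sweep >= burnin) {
      std::pair<long, long>& cnt = tally[path];
      if (recorded < half1) cnt.first += 1; else cnt.second += 1;
      ++recorded;
    }
  }

  const int n = tally.size();
  IntegerMatrix paths(n, L);
  IntegerVector c1(n), c2(n);
  int r = 0;
  for (PathMap::const_iterator it = tally.begin(); it != tally.end();
       ++it, ++r) {
    for (int j = 0; j < L; ++j) paths(r, j) = it->first[j] + 1;
    c1[r] = (int) it->second.first;
    c2[r] = (int) it->second.second;
  }
  return List::create(_["paths"] = paths, _["count_half1"] = c1,
                      _["count_half2"] = c2);
}
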