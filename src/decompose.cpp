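// Monomer decomposition dynamic program: optimal tiling of a tandem-repeat
// sequence by a set of monomer templates (free transitions between template
// ends, per-base gap state), equivalent to minimising the edit distance
// between the sequence and the best concatenation of templates.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// [[Rcpp::export(name = ".decompose_dp")]]
List decompose_dp(std::string seq, CharacterVector templates,
                  double gap_cost) {
  const int n = (int)seq.size();
  const int K = templates.size();
  std::vector<std::string> T(K);
  std::vector<int> tlen(K), toff(K + 1, 0);
  for (int k = 0; k < K; ++k) {
    T[k] = as<std::string>(templates[k]);
    tlen[k] = (int)T[k].size();
    toff[k + 1] = toff[k] + tlen[k];
  }
  const int S = toff[K];
  const double INF = 1e18;

  std::vector<double> cur(S, INF), prev(S, INF);
  std::vector<int> curs(S, -1), prevs(S, -1);   // monomer start positions
  std::vector<double> best(n + 1, INF);
  std::vector<int> best_tpl(n + 1, -1), best_start(n + 1, -1);

  best[0] = 0.0;
  // column 0: only template-base deletions from the start state
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < tlen[k]; ++i) {
      prev[toff[k] + i] = best[0] + (i + 1);
      prevs[toff[k] + i] = 0;
    }

  for (int j = 1; j <= n; ++j) {
    const char c = seq[j - 1];
    for (int k = 0; k < K; ++k) {
      const std::string &tk = T[k];
      const int off = toff[k], m = tlen[k];
      for (int i = 0; i < m; ++i) {
        const int s = off + i;
        double diag = (i == 0) ? best[j - 1] : prev[s - 1];
        int diag_start = (i == 0) ? (j - 1) : prevs[s - 1];
        double dcost = diag + ((tk[i] == c) ? 0.0 : 1.0);
        double hcost = prev[s] + 1.0;            // consume sequence base
        double vcost = (i == 0) ? INF : cur[s - 1] + 1.0; // consume template
        double mbest = dcost; int st = diag_start;
        if (hcost < mbest) { mbest = hcost; st = prevs[s]; }
        if (vcost < mbest) { mbest = vcost; st = curs[s - 1]; }
        cur[s] = mbest; curs[s] = st;
      }
    }
    double bgap = best[j - 1] + gap_cost;
    double bcomp = INF; int bt = -1, bs = -1;
    for (int k = 0; k < K; ++k) {
      const int s = toff[k] + tlen[k] - 1;
      if (tlen[k] > 0 && cur[s] < bcomp) { bcomp = cur[s]; bt = k; bs = curs[s]; }
    }
    if (bcomp <= bgap && bs >= 0 && bs < j) {
      best[j] = bcomp; best_tpl[j] = bt; best_start[j] = bs;
    } else {
      best[j] = bgap;
    }
    std::swap(cur, prev);
    std::swap(curs, prevs);
  }

  // traceback at monomer granularity
  std::vector<int> seg_start, seg_end, seg_tpl;
  int j = n;
  while (j > 0) {
    if (best_tpl[j] >= 0 && best_start[j] >= 0 && best_start[j] < j) {
      seg_start.push_back(best_start[j]);
      seg_end.push_back(j);
      seg_tpl.push_back(best_tpl[j] + 1);  // 1-based template index for R
      j = best_start[j];
    } else {
      --j;
    }
  }
  std::reverse(seg_start.begin(), seg_start.end());
  std::reverse(seg_end.begin(), seg_end.end());
  std::reverse(seg_tpl.begin(), seg_tpl.end());

  return List::create(_["start"] = wrap(seg_start),
                      _["end"] = wrap(seg_end),
                      _["template_index"] = wrap(seg_tpl),
                      _["total_cost"] = best[n]);
}
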