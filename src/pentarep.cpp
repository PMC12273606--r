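#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstring>
#include <climits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Small-string edit distance (full global alignment, unit costs).
// Used for motif-vs-window comparisons where both strings are <= 6 bp.
// ---------------------------------------------------------------------------
static inline int edit_small(const char* a, int la, const char* b, int lb) {
  int prev[8], cur[8];
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int c = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int v = prev[j - 1] + c;
      if (prev[j] + 1 < v) v = prev[j] + 1;
      if (cur[j - 1] + 1 < v) v = cur[j - 1] + 1;
      cur[j] = v;
    }
    std::memcpy(prev, cur, (lb + 1) * sizeof(int));
  }
  return prev[lb];
}

// ---------------------------------------------------------------------------
// Semiglobal ("glocal") alignment: the pattern is aligned end-to-end against
// any substring of the subject; substitutions and indels cost 1.
// d_end[j] = min edit distance of pattern vs a subject substring ending at j
// (0-based, half-open ends, j in 0..n).
// ---------------------------------------------------------------------------
static std::vector<int> semiglobal_end_dists(const std::string& pat,
                                             const std::string& sub) {
  const int m = (int)pat.size(), n = (int)sub.size();
  std::vector<int> prev(m + 1), cur(m + 1), dend(n + 1);
  for (int i = 0; i <= m; ++i) prev[i] = i;
  dend[0] = prev[m];
  for (int j = 1; j <= n; ++j) {
    cur[0] = 0; // free start anywhere in the subject
    for (int i = 1; i <= m; ++i) {
      int c = (pat[i - 1] == sub[j - 1]) ? 0 : 1;
      int v = prev[i - 1] + c;
      if (cur[i - 1] + 1 < v) v = cur[i - 1] + 1;
      if (prev[i] + 1 < v) v = prev[i] + 1;
      cur[i] = v;
    }
    std::swap(prev, cur);
    dend[j] = prev[m];
  }
  return dend;
}

// d_start[s] = min edit distance of pattern vs a subject substring starting
// at s. Computed by reversing both strings.
static std::vector<int> semiglobal_start_dists(const std::string& pat,
                                               const std::string& sub) {
  std::string rp(pat.rbegin(), pat.rend()), rs(sub.rbegin(), sub.rend());
  std::vector<int> dend = semiglobal_end_dists(rp, rs);
  const int n = (int)sub.size();
  std::vector<int> dstart(n + 1);
  for (int s = 0; s <= n; ++s) dstart[s] = dend[n - s];
  return dstart;
}

// Minimal semiglobal edit distance of pattern against subject.
// [[Rcpp::export]]
int semiglobal_dist_cpp(std::string pattern, std::string subject) {
  std::vector<int> d = semiglobal_end_dists(pattern, subject);
  return *std::min_element(d.begin(), d.end());
}

// Best occurrence of `pattern` in `subject` under semiglobal alignment.
// leftmost = true  -> smallest start among minimal-distance occurrences,
//                     then smallest end (used for the 5' flank);
// leftmost = false -> largest start, then largest end (used for the 3' flank).
// Returns dist, start, end (0-based, half-open).
// [[Rcpp::export]]
List flank_hit_cpp(std::string pattern, std::string subject, bool leftmost) {
  const int n = (int)subject.size(), m = (int)pattern.size();
  std::vector<int> dstart = semiglobal_start_dists(pattern, subject);
  int best = *std::min_element(dstart.begin(), dstart.end());
  int s = 0;
  if (leftmost) {
    for (int i = 0; i <= n; ++i) if (dstart[i] == best) { s = i; break; }
  } else {
    for (int i = n; i >= 0; --i) if (dstart[i] == best) { s = i; break; }
  }
  // Find the matching end for this start: global-in-pattern alignment of the
  // pattern against growing prefixes of subject[s..n); take the first
  // (leftmost) or last (rightmost) end position achieving the best distance.
  std::vector<int> dp(m + 1);
  for (int i = 0; i <= m; ++i) dp[i] = i;
  int e = s;
  bool found = (dp[m] == best);
  for (int j = s + 1; j <= n; ++j) {
    if (found && leftmost) break;
    int prev_diag = dp[0];
    dp[0] = j - s;
    for (int i = 1; i <= m; ++i) {
      int old = dp[i];
      int c = (pattern[i - 1] == subject[j - 1]) ? 0 : 1;
      int v = prev_diag + c;
      if (dp[i - 1] + 1 < v) v = dp[i - 1] + 1;
      if (old + 1 < v) v = old + 1;
      prev_diag = old;
      dp[i] = v;
    }
    if (dp[m] == best) { e = j; found = true; }
  }
  return List::create(_["dist"] = best, _["start"] = s, _["end"] = e);
}

// ---------------------------------------------------------------------------
// Motif decomposition of a repeat tract.
//
// Minimum-cost tiling of the tract where a tile is either a window of
// length 3-7 (within max_edits of the unit length 5) matched to one motif
// with edit distance <= max_edits (cost = that distance), or a single base
// labeled OTHER (cost = other_cost). Among all minimum-cost tilings, one
// with the fewest label switches between adjacent tiles is chosen (maximum
// parsimony over runs: noise-induced ties inside a homogeneous run must not
// spawn spurious short runs), and among those one with the most tiles
// (shorter windows do not silently swallow repeat units when a same-cost
// two-unit explanation exists). Remaining ties prefer motif tiles over
// OTHER and earlier motifs in the supplied priority order.
// Adjacent tiles with the same label are merged into runs afterwards.
//
// Returns parallel vectors describing the runs (motif_idx is 1-based into
// `motifs`, 0 = OTHER; unit_count counts tiles for motif runs and bases for
// OTHER runs) plus the total cost.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List decompose_tract_cpp(std::string tract, CharacterVector motifs,
                         int max_edits, int other_cost) {
  const int n = (int)tract.size();
  const int K = motifs.size();
  std::vector<std::string> mot(K);
  for (int k = 0; k < K; ++k) mot[k] = as<std::string>(motifs[k]);

  const int INF = INT_MAX / 4;
  const int NL = 5;
  const int lens[NL] = {3, 4, 5, 6, 7};

  // Lazily cached per-(position, motif, length) edit distances.
  std::vector<signed char> ed_cache((size_t)(n + 1) * K * NL, -2);
  auto tile_ed = [&](int p, int k, int li) -> int {
    signed char& slot = ed_cache[((size_t)p * K + k) * NL + li];
    if (slot != -2) return slot;
    const int L = lens[li];
    const std::string& mo = mot[k];
    const int ml = (int)mo.size();
    int ed;
    if (p + L > n || std::abs(L - ml) > max_edits) {
      ed = -1;
    } else if (L == ml &&
               std::memcmp(tract.data() + p, mo.data(), L) == 0) {
      ed = 0;
    } else {
      ed = edit_small(tract.data() + p, L, mo.data(), ml);
      if (ed > max_edits) ed = -1;
    }
    slot = (signed char)ed;
    return ed;
  };

  // Forward DP over (position, label of the last tile). Objective is
  // lexicographic: minimal edit cost, then minimal number of switches,
  // then maximal number of tiles.
  // Labels: 0 = OTHER, 1..K = motifs; K+1 = virtual start state.
  const int S = K + 2;
  const int START = K + 1;
  std::vector<int> g_cost((size_t)(n + 1) * S, INF);
  std::vector<int> g_sw((size_t)(n + 1) * S, INF);
  std::vector<int> g_nt((size_t)(n + 1) * S, -1);
  std::vector<short> par_lab((size_t)(n + 1) * S, -1);
  std::vector<short> par_len((size_t)(n + 1) * S, 0);
  std::vector<short> par_ed((size_t)(n + 1) * S, 0);
  auto idx = [S](int p, int l) { return (size_t)p * S + l; };
  g_cost[idx(0, START)] = 0;
  g_sw[idx(0, START)] = 0;
  g_nt[idx(0, START)] = 0;

  // relaxation; on full ties prefer the parent that already carries the
  // target label, so an ambiguous window at a run junction joins the
  // 5'-side run instead of extending the 3' one
  auto relax = [&](int p2, int l2, int cost, int sw, int nt, int lp, int L,
                   int ed) {
    size_t i2 = idx(p2, l2);
    bool better = cost < g_cost[i2] ||
      (cost == g_cost[i2] &&
       (sw < g_sw[i2] || (sw == g_sw[i2] && nt > g_nt[i2])));
    bool tie_pref = cost == g_cost[i2] && sw == g_sw[i2] &&
      nt == g_nt[i2] && lp == l2 && par_lab[i2] != l2;
    if (better || tie_pref) {
      g_cost[i2] = cost;
      g_sw[i2] = sw;
      g_nt[i2] = nt;
      par_lab[i2] = (short)lp;
      par_len[i2] = (short)L;
      par_ed[i2] = (short)ed;
    }
  };

  for (int p = 0; p <= n; ++p) {
    for (int lp = 0; lp < S; ++lp) {
      size_t ip = idx(p, lp);
      int c0 = g_cost[ip];
      if (c0 >= INF) continue;
      int s0 = g_sw[ip];
      int t0 = g_nt[ip];
      if (p == n) continue;
      // motif tiles in priority order, shorter windows first
      for (int k = 0; k < K; ++k) {
        int l2 = k + 1;
        int sw = s0 + ((lp != l2 && lp != START) ? 1 : 0);
        for (int li = 0; li < NL; ++li) {
          int ed = tile_ed(p, k, li);
          if (ed < 0) continue;
          relax(p + lens[li], l2, c0 + ed, sw, t0 + 1, lp, lens[li], ed);
        }
      }
      // OTHER tile, least preferred on ties
      {
        int sw = s0 + ((lp != 0 && lp != START) ? 1 : 0);
        relax(p + 1, 0, c0 + other_cost, sw, t0 + 1, lp, 1, other_cost);
      }
    }
  }

  // final state: minimal (cost, switches); ties prefer motifs in priority
  // order, OTHER last
  int best_l = -1, best_cost = INF, best_sw = INF, best_nt = -1;
  if (n == 0) best_cost = 0;
  const int order_n = K + 1;
  for (int oi = 0; oi < order_n && n > 0; ++oi) {
    int l = (oi < K) ? oi + 1 : 0;
    size_t i2 = idx(n, l);
    if (g_cost[i2] < best_cost ||
        (g_cost[i2] == best_cost &&
         (g_sw[i2] < best_sw ||
          (g_sw[i2] == best_sw && g_nt[i2] > best_nt)))) {
      best_cost = g_cost[i2];
      best_sw = g_sw[i2];
      best_nt = g_nt[i2];
      best_l = l;
    }
  }

  // traceback into tiles
  std::vector<int> labs, lens_v, costs, starts;
  {
    int p = n, l = best_l;
    while (p > 0) {
      size_t i2 = idx(p, l);
      int L = par_len[i2];
      labs.push_back(l);
      lens_v.push_back(L);
      costs.push_back(par_ed[i2]);
      starts.push_back(p - L);
      l = par_lab[i2];
      p -= L;
    }
  }
  std::reverse(labs.begin(), labs.end());
  std::reverse(lens_v.begin(), lens_v.end());
  std::reverse(costs.begin(), costs.end());
  std::reverse(starts.begin(), starts.end());

  // merge adjacent same-label tiles into runs
  std::vector<int> r_lab, r_units, r_start, r_end, r_cost;
  for (size_t t = 0; t < labs.size(); ++t) {
    int lab = labs[t];
    if (!r_lab.empty() && r_lab.back() == lab) {
      r_units.back() += 1; // one tile = one unit (OTHER tile = one base)
      r_end.back() = starts[t] + lens_v[t];
      r_cost.back() += costs[t];
    } else {
      r_lab.push_back(lab);
      r_units.push_back(1);
      r_start.push_back(starts[t]);
      r_end.push_back(starts[t] + lens_v[t]);
      r_cost.push_back(costs[t]);
    }
  }

  return List::create(
      _["motif_idx"] = wrap(r_lab), _["unit_count"] = wrap(r_units),
      _["start"] = wrap(r_start), _["end"] = wrap(r_end),
      _["cost"] = wrap(r_cost), _["total_cost"] = best_cost);
}

// ---------------------------------------------------------------------------
// Per-base sequencing-error simulator (substitution / insertion / deletion,
// independent per base). Uses R's RNG so results are reproducible under
// set.seed().
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
std::string apply_errors_cpp(std::string seq, double sub_rate,
                             double ins_rate, double del_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string out;
  out.reserve(seq.size() + 16);
  for (size_t i = 0; i < seq.size(); ++i) {
    char c = seq[i];
    bool deleted = (del_rate > 0.0 && unif_rand() < del_rate);
    if (!deleted) {
      if (sub_rate > 0.0 && unif_rand() < sub_rate) {
        // substitute with one of the three other bases
        int k = (int)(unif_rand() * 3.0);
        if (k > 2) k = 2;
        int bi = 0;
        for (int b = 0; b < 4; ++b) {
          if (bases[b] == c) continue;
          if (bi == k) { c = bases[b]; break; }
          ++bi;
        }
        if (c == seq[i]) c = bases[k]; // original not in ACGT (e.g. N)
      }
      out.push_back(c);
    }
    if (ins_rate > 0.0 && unif_rand() < ins_rate) {
      int k = (int)(unif_rand() * 4.0);
      if (k > 3) k = 3;
      out.push_back(bases[k]);
    }
  }
  return out;
}

// Hamming mismatch counts of a probe against every offset of a template
// (substitution-only annealing model for repeat-primed PCR).
// [[Rcpp::export]]
IntegerVector hamming_scan_cpp(std::string tmpl, std::string probe) {
  const int n = (int)tmpl.size(), L = (int)probe.size();
  if (n < L) return IntegerVector(0);
  IntegerVector out(n - L + 1);
  for (int o = 0; o <= n - L; ++o) {
    int mm = 0;
    for (int j = 0; j < L; ++j) mm += (tmpl[o + j] != probe[j]);
    out[o] = mm;
  }
  return out;
}
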