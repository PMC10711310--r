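#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
// Sequences arrive as 1-based integer codes into the scoring matrix.
// A gap of length L costs gap_open + (L-1)*gap_extend, with gap_open <= gap_extend < 0.
// Traceback is fully deterministic: on ties prefer diagonal (M) > up (gap in b,
// consuming a) > left (gap in a, consuming b); for the local variant the best cell
// is the first (smallest i, then j) cell attaining the maximum, and continuing an
// alignment is preferred over restarting.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double gap_open, double gap_extend, bool local,
                 bool score_only) {
  const int m = a.size(), n = b.size();
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG_INF), X((m + 1) * W, NEG_INF),
      Y((m + 1) * W, NEG_INF);
  // traceback codes: ptrM: 0=from M, 1=from X, 2=from Y, 3=fresh start (local)
  //                  ptrX: 0=open (from M above), 1=extend (from X above)
  //                  ptrY: 0=open (from M left),  1=extend (from Y left)
  std::vector<uint8_t> pM, pX, pY;
  if (!score_only) {
    pM.assign((m + 1) * W, 0);
    pX.assign((m + 1) * W, 0);
    pY.assign((m + 1) * W, 0);
  }

  M[0] = 0.0;
  if (!local) {
    for (int i = 1; i <= m; ++i) X[i * W] = gap_open + (i - 1) * gap_extend;
    for (int j = 1; j <= n; ++j) Y[j] = gap_open + (j - 1) * gap_extend;
    if (!score_only) {
      for (int i = 2; i <= m; ++i) pX[i * W] = 1;
      for (int j = 2; j <= n; ++j) pY[j] = 1;
    }
  } else {
    for (int i = 1; i <= m; ++i) M[i * W] = 0.0;
    for (int j = 1; j <= n; ++j) M[j] = 0.0;
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= m; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j, dg = (i - 1) * W + (j - 1), up = (i - 1) * W + j,
                lf = i * W + (j - 1);
      // M state
      double bm = M[dg];
      uint8_t cm = 0;
      if (X[dg] > bm) { bm = X[dg]; cm = 1; }
      if (Y[dg] > bm) { bm = Y[dg]; cm = 2; }
      double s = sub(ai, b[j - 1] - 1);
      if (local && bm <= 0.0) { bm = 0.0; cm = 3; }
      double mv = (bm <= NEG_INF / 2) ? NEG_INF : bm + s;
      if (local && mv < 0.0) { mv = 0.0; cm = 3; }
      M[idx] = mv;
      // X state (gap in b, consume a; "up")
      double xo = (M[up] <= NEG_INF / 2) ? NEG_INF : M[up] + gap_open;
      double xe = (X[up] <= NEG_INF / 2) ? NEG_INF : X[up] + gap_extend;
      uint8_t cx = (xo >= xe) ? 0 : 1;
      X[idx] = (xo >= xe) ? xo : xe;
      // Y state (gap in a, consume b; "left")
      double yo = (M[lf] <= NEG_INF / 2) ? NEG_INF : M[lf] + gap_open;
      double ye = (Y[lf] <= NEG_INF / 2) ? NEG_INF : Y[lf] + gap_extend;
      uint8_t cy = (yo >= ye) ? 0 : 1;
      Y[idx] = (yo >= ye) ? yo : ye;
      if (!score_only) { pM[idx] = cm; pX[idx] = cx; pY[idx] = cy; }
      if (local && M[idx] > best) { best = M[idx]; best_i = i; best_j = j; }
    }
  }

  double score;
  int state; // 0=M, 1=X, 2=Y
  int ti, tj;
  if (local) {
    score = best;
    state = 0;
    ti = best_i; tj = best_j;
  } else {
    const int idx = m * W + n;
    score = M[idx]; state = 0;
    if (X[idx] > score) { score = X[idx]; state = 1; }
    if (Y[idx] > score) { score = Y[idx]; state = 2; }
    ti = m; tj = n;
  }

  if (score_only) return List::create(_["score"] = score);

  // traceback: ops 1 = M (consume both), 2 = X (consume a), 3 = Y (consume b)
  std::vector<int> ops;
  if (local && score <= 0.0) {
    ti = 0; tj = 0; // empty local alignment
  } else {
    while (ti > 0 || tj > 0) {
      if (!local && ti == 0) {
        ops.push_back(3); --tj; continue;
      }
      if (!local && tj == 0) {
        ops.push_back(2); --ti; continue;
      }
      const int idx = ti * W + tj;
      if (state == 0) {
        uint8_t c = pM[idx];
        ops.push_back(1);
        --ti; --tj;
        if (local && c == 3) break;
        state = c;
      } else if (state == 1) {
        ops.push_back(2);
        state = (pX[idx] == 0) ? 0 : 1;
        --ti;
      } else {
        ops.push_back(3);
        state = (pY[idx] == 0) ? 0 : 1;
        --tj;
      }
      if (local && ti == 0 && tj == 0) break;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // consumed spans (for local coverage): a spans [ti+1 .. ti+#(1,2)], etc.
  int na = 0, nb = 0;
  for (int o : ops) { if (o != 3) ++na; if (o != 2) ++nb; }
  return List::create(_["score"] = score, _["ops"] = wrap(ops),
                      _["a_start"] = ops.empty() ? 0 : ti + 1,
                      _["b_start"] = ops.empty() ? 0 : tj + 1,
                      _["a_len"] = na, _["b_len"] = nb);
}

// --- 16-mer seeding for fragment ANI ------------------------------------------

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// For each query fragment, vote over exact diagonals (subject_pos - query_pos)
// of shared k-mers against the subject contigs; report the best (contig, diagonal).
// K-mers occurring more than max_occ times in the subject are treated as
// low-complexity and skipped.
// [[Rcpp::export(name = ".map_fragments")]]
DataFrame map_fragments(CharacterVector fragments, CharacterVector contigs,
                        int k, int max_occ) {
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int ci = 0; ci < contigs.size(); ++ci) {
    std::string s = as<std::string>(contigs[ci]);
    uint64_t h = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int c = base_code(s[p]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto &v = index[h];
        if ((int)v.size() <= max_occ) v.push_back(std::make_pair(ci, p - k + 1));
      }
    }
  }
  const int nf = fragments.size();
  IntegerVector out_contig(nf), out_diag(nf), out_votes(nf);
  for (int f = 0; f < nf; ++f) {
    std::string q = as<std::string>(fragments[f]);
    std::unordered_map<int64_t, int> votes; // key = contig * 2^32 + (diag + 2^30)
    uint64_t h = 0; int run = 0;
    for (int p = 0; p < (int)q.size(); ++p) {
      int c = base_code(q[p]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto it = index.find(h);
        if (it == index.end() || (int)it->second.size() > max_occ) continue;
        for (auto &hit : it->second) {
          int diag = hit.second - (p - k + 1);
          int64_t key = ((int64_t)hit.first << 32) | (uint32_t)(diag + (1 << 30));
          ++votes[key];
        }
      }
    }
    int bestv = 0; int64_t bestk = 0;
    for (auto &kv : votes) {
      if (kv.second > bestv || (kv.second == bestv && kv.first < bestk)) {
        bestv = kv.second; bestk = kv.first;
      }
    }
    if (bestv == 0) {
      out_contig[f] = NA_INTEGER; out_diag[f] = NA_INTEGER; out_votes[f] = 0;
    } else {
      out_contig[f] = (int)(bestk >> 32) + 1;
      out_diag[f] = (int)((uint32_t)(bestk & 0xffffffffULL)) - (1 << 30);
      out_votes[f] = bestv;
    }
  }
  return DataFrame::create(_["contig"] = out_contig, _["diag"] = out_diag,
                           _["votes"] = out_votes);
}
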