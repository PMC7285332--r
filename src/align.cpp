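#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit base code; -1 for anything outside {A,C,G,T}
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// Exact k-mer seed matches between each query and one target.
// Returns, per query, an integer matrix with columns (qpos, tpos), 0-based.
// k-mers containing non-ACGT characters never match. k <= 31.
// Target k-mers occurring more than max_occ times are skipped
// (repeat masking of uninformative seeds).
// [[Rcpp::export]]
List seed_hits_batch_cpp(CharacterVector queries, std::string target,
                         int k, int max_occ = 200) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<uint64_t, std::vector<int> > index;
  const int tn = (int) target.size();
  {
    uint64_t v = 0;
    int valid = 0; // run length of valid bases ending here
    for (int i = 0; i < tn; ++i) {
      int c = base_code(target[i]);
      if (c < 0) { valid = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t) c) & mask;
      if (++valid >= k) {
        std::vector<int>& occ = index[v];
        if ((int) occ.size() <= max_occ) occ.push_back(i - k + 1);
      }
    }
  }
  const int nq = queries.size();
  List out(nq);
  for (int q = 0; q < nq; ++q) {
    std::string s = as<std::string>(queries[q]);
    std::vector<int> qp, tp;
    uint64_t v = 0;
    int valid = 0;
    const int sn = (int) s.size();
    for (int i = 0; i < sn; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t) c) & mask;
      if (++valid >= k) {
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
          index.find(v);
        if (it != index.end() && (int) it->second.size() <= max_occ) {
          for (size_t j = 0; j < it->second.size(); ++j) {
            qp.push_back(i - k + 1);
            tp.push_back(it->second[j]);
          }
        }
      }
    }
    IntegerMatrix m((int) qp.size(), 2);
    for (size_t j = 0; j < qp.size(); ++j) {
      m((int) j, 0) = qp[j];
      m((int) j, 1) = tp[j];
    }
    out[q] = m;
  }
  return out;
}

// Banded pairwise alignment of a against b; band of half-width `band`
// around the main diagonal (a and b are assumed to start together at 0).
// mode 0: global in both (path ends at (la, lb))
// mode 1: b fully consumed, free end in a (path ends at (i, lb), best i)
// mode 2: a fully consumed, free end in b (path ends at (la, j), best j)
// Scores: match +2, mismatch -2, gap -3 (linear). 'N' never matches.
// Returns score, matches, columns (alignment length incl. gap columns),
// a_used, b_used, and optionally the two gapped alignment strings.
// [[Rcpp::export]]
List band_align_cpp(std::string a, std::string b, int band, int mode = 0,
                    bool keep_alignment = false) {
  const int la = (int) a.size(), lb = (int) b.size();
  if (la == 0 || lb == 0) stop("empty sequence in band_align");
  if (band < 1) band = 1;
  const int W = 2 * band + 1;
  const int NEG = -1000000000;
  const int MATCH = 2, MISMATCH = -2, GAP = -3;
  std::vector<int> prev(W, NEG), cur(W, NEG);
  // traceback: 0 none, 1 diag, 2 up (gap in b), 3 left (gap in a)
  std::vector<unsigned char> tb((size_t)(la + 1) * W, 0);
  int best = NEG, end_i = -1, end_j = -1;
  // row i = 0: leading gaps in a; o = j - (i - band), so j = o - band here
  for (int o = 0; o < W; ++o) {
    int j = o - band;
    if (j < 0 || j > lb) continue;
    prev[o] = GAP * j;
    tb[o] = (j == 0) ? 0 : 3;
  }
  if (mode == 1 && lb <= band) {
    best = prev[lb + band]; end_i = 0; end_j = lb;
  }
  for (int i = 1; i <= la; ++i) {
    const int lo = std::max(0, i - band), hi = std::min(lb, i + band);
    for (int o = 0; o < W; ++o) cur[o] = NEG;
    for (int j = lo; j <= hi; ++j) {
      const int o = j - (i - band);
      int bst = NEG;
      unsigned char dir = 0;
      if (j >= 1) { // diagonal from (i-1, j-1)
        const int po = (j - 1) - ((i - 1) - band);
        if (po >= 0 && po < W && prev[po] > NEG) {
          char ca = a[i - 1], cb = b[j - 1];
          int sc = prev[po] + ((ca == cb && ca != 'N') ? MATCH : MISMATCH);
          if (sc > bst) { bst = sc; dir = 1; }
        }
      }
      { // up from (i-1, j): gap in b
        const int po = j - ((i - 1) - band);
        if (po >= 0 && po < W && prev[po] > NEG) {
          int sc = prev[po] + GAP;
          if (sc > bst) { bst = sc; dir = 2; }
        }
      }
      { // left from (i, j-1): gap in a
        const int co = (j - 1) - (i - band);
        if (co >= 0 && co < W && cur[co] > NEG) {
          int sc = cur[co] + GAP;
          if (sc > bst) { bst = sc; dir = 3; }
        }
      }
      cur[o] = bst;
      tb[(size_t) i * W + o] = dir;
    }
    if (mode == 1 && lb >= i - band && lb <= i + band) {
      const int o = lb - (i - band);
      if (cur[o] > best) { best = cur[o]; end_i = i; end_j = lb; }
    }
    std::swap(prev, cur);
  }
  if (mode == 0) {
    const int o = lb - (la - band);
    if (o >= 0 && o < W && prev[o] > NEG) {
      best = prev[o]; end_i = la; end_j = lb;
    }
  } else if (mode == 2) {
    for (int o = 0; o < W; ++o) {
      int j = o + (la - band);
      if (j < 0 || j > lb) continue;
      if (prev[o] > best) { best = prev[o]; end_i = la; end_j = j; }
    }
  }
  if (end_i < 0 || best <= NEG) {
    return List::create(_["feasible"] = false, _["score"] = NA_INTEGER,
                        _["matches"] = 0.0, _["columns"] = 0.0,
                        _["a_used"] = 0, _["b_used"] = 0);
  }
  // traceback
  int i = end_i, j = end_j;
  long matches = 0, columns = 0;
  std::string aa, bb;
  while (i > 0 || j > 0) {
    const int o = j - (i - band);
    unsigned char dir = (o >= 0 && o < W) ? tb[(size_t) i * W + o] : 0;
    if (dir == 1) {
      char ca = a[i - 1], cb = b[j - 1];
      if (ca == cb && ca != 'N') ++matches;
      ++columns;
      if (keep_alignment) { aa.push_back(ca); bb.push_back(cb); }
      --i; --j;
    } else if (dir == 2) {
      ++columns;
      if (keep_alignment) { aa.push_back(a[i - 1]); bb.push_back('-'); }
      --i;
    } else if (dir == 3) {
      ++columns;
      if (keep_alignment) { aa.push_back('-'); bb.push_back(b[j - 1]); }
      --j;
    } else {
      break;
    }
  }
  if (keep_alignment) {
    std::reverse(aa.begin(), aa.end());
    std::reverse(bb.begin(), bb.end());
  }
  List out = List::create(
    _["feasible"] = true, _["score"] = best,
    _["matches"] = (double) matches, _["columns"] = (double) columns,
    _["a_used"] = end_i, _["b_used"] = end_j);
  if (keep_alignment) {
    out["a_aln"] = aa;
    out["b_aln"] = bb;
  }
  return out;
}

// Gapless X-drop extension of an exact seed of length seedlen at
// (qpos, spos), 0-based. Extends left and right; trims back to the
// maximum-score endpoints. Score: match +1, mismatch -2; 'N' mismatches.
// Returns 0-based half-open intervals on query and subject plus the
// match count over the extended (gapless) span.
// [[Rcpp::export]]
List diag_extend_cpp(std::string q, std::string s, int qpos, int spos,
                     int seedlen, int xdrop = 40) {
  const int lq = (int) q.size(), ls = (int) s.size();
  const int MATCH = 1, MISMATCH = -2;
  int score = 0, best = 0, best_r = 0; // offset past seed end
  for (int off = 0; ; ++off) {
    int qi = qpos + seedlen + off, si = spos + seedlen + off;
    if (qi >= lq || si >= ls) break;
    char a = q[qi], b = s[si];
    score += (a == b && a != 'N') ? MATCH : MISMATCH;
    if (score > best) { best = score; best_r = off + 1; }
    if (best - score > xdrop) break;
  }
  score = 0;
  int bestl = 0, best_l = 0;
  for (int off = 1; ; ++off) {
    int qi = qpos - off, si = spos - off;
    if (qi < 0 || si < 0) break;
    char a = q[qi], b = s[si];
    score += (a == b && a != 'N') ? MATCH : MISMATCH;
    if (score > bestl) { bestl = score; best_l = off; }
    if (bestl - score > xdrop) break;
  }
  const int q0 = qpos - best_l, q1 = qpos + seedlen + best_r;
  const int s0 = spos - best_l;
  long matches = 0;
  for (int off = 0; off < q1 - q0; ++off) {
    char a = q[q0 + off], b = s[s0 + off];
    if (a == b && a != 'N') ++matches;
  }
  return List::create(_["q_start"] = q0, _["q_end"] = q1,
                      _["s_start"] = s0, _["s_end"] = s0 + (q1 - q0),
                      _["matches"] = (double) matches,
                      _["length"] = q1 - q0);
}
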