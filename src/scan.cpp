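#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// 32-bit FNV-1a hash of each string, returned as a double (fits exactly).
// [[Rcpp::export]]
NumericVector fnv1a_hash(CharacterVector x) {
  NumericVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) {
    const char *s = CHAR(STRING_ELT(x, k));
    uint32_t h = 2166136261u;
    for (; *s; ++s) {
      h ^= (uint32_t)(unsigned char)(*s);
      h *= 16777619u;
    }
    out[k] = (double)h;
  }
  return out;
}

// pair classification in duplex space: piRNA base vs target base.
// 2 = Watson-Crick, 1 = G:U wobble (G~T or T~G in DNA letters), 0 = mismatch.
static inline int pair_class(char p, char t) {
  if ((p == 'A' && t == 'T') || (p == 'T' && t == 'A') ||
      (p == 'C' && t == 'G') || (p == 'G' && t == 'C')) return 2;
  if ((p == 'G' && t == 'T') || (p == 'T' && t == 'G')) return 1;
  return 0;
}

// Banded antisense alignment of a piRNA against one transcript strand.
//
// For every anchor position e0 (exclusive site end on the transcript, the
// base pairing the piRNA 5' terminus), a small DP aligns the full piRNA
// (rows) against the transcript read 3'->5' from the anchor (columns),
// allowing at most max_gaps gaps in total. Penalties: mismatch / G:U / gap,
// doubled when the piRNA position lies in [core_lo, core_hi] (1-based from
// the piRNA 5' end). The best alignment per anchor is reported when its
// total penalty is <= max_score; ties prefer the leftmost site start.
// [[Rcpp::export]]
DataFrame scan_anchors_cpp(std::string pirna, std::string transcript,
                           double mismatch_penalty, double gu_penalty,
                           double gap_penalty, int core_lo, int core_hi,
                           double max_score, int max_gaps) {
  const int L = (int)pirna.size();
  const int n = (int)transcript.size();
  const int G = max_gaps;            // allowed gaps
  const double INF = std::numeric_limits<double>::infinity();
  const double EPS = 1e-9;

  std::vector<int> r_start, r_end, r_gaps;
  std::vector<double> r_score;
  std::vector<std::string> r_pair, r_a1, r_a2;

  if (L == 0 || n == 0)
    return DataFrame::create(_["start"] = IntegerVector(0),
                             _["end"] = IntegerVector(0),
                             _["score"] = NumericVector(0),
                             _["gaps"] = IntegerVector(0),
                             _["pairing"] = CharacterVector(0),
                             _["aln_pirna"] = CharacterVector(0),
                             _["aln_target"] = CharacterVector(0));

  const int W = L + G + 1;           // max columns + 1
  const int S = (L + 1) * W * (G + 1);
  std::vector<double> dp(S);
  std::vector<unsigned char> from(S); // 1 diag, 2 gap-in-target, 3 gap-in-piRNA
  auto idx = [&](int i, int j, int g) { return (i * W + j) * (G + 1) + g; };
  auto mult = [&](int pos) {
    int p = pos < 1 ? 1 : (pos > L ? L : pos);
    return (p >= core_lo && p <= core_hi) ? 2.0 : 1.0;
  };
  const double pc[3] = { mismatch_penalty, gu_penalty, 0.0 }; // by pair_class

  int e0_min = std::max(L - G, 1);
  for (int e0 = e0_min; e0 <= n; ++e0) {
    int qlen = std::min(e0, L + G);
    bool dead = false;
    // the dp array is reused across anchors; a source cell is trustworthy
    // only if it lies in the band computed for THIS anchor
    auto valid = [&](int i, int j) {
      return j >= std::max(0, i - G) && j <= std::min(qlen, i + G);
    };
    for (int i = 0; i <= L && !dead; ++i) {
      double rowmin = INF;
      int jlo = std::max(0, i - G), jhi = std::min(qlen, i + G);
      for (int j = jlo; j <= jhi; ++j) {
        for (int g = 0; g <= G; ++g) {
          double best = INF; unsigned char bf = 0;
          if (i == 0 && j == 0 && g == 0) best = 0.0;
          if (i > 0 && j > 0 && valid(i - 1, j - 1)) {
            double v = dp[idx(i - 1, j - 1, g)];
            if (v < INF) {
              int cls = pair_class(pirna[i - 1], transcript[e0 - 1 - (j - 1)]);
              v += pc[cls] * (cls == 2 ? 1.0 : mult(i));
              if (v < best) { best = v; bf = 1; }
            }
          }
          if (i > 0 && g > 0 && valid(i - 1, j)) {
            double v = dp[idx(i - 1, j, g - 1)];
            if (v < INF) {
              v += gap_penalty * mult(i);
              if (v < best) { best = v; bf = 2; }
            }
          }
          if (j > 0 && g > 0 && valid(i, j - 1)) {
            double v = dp[idx(i, j - 1, g - 1)];
            if (v < INF) {
              v += gap_penalty * mult(i + 1);
              if (v < best) { best = v; bf = 3; }
            }
          }
          dp[idx(i, j, g)] = best;
          from[idx(i, j, g)] = bf;
          if (best < rowmin) rowmin = best;
        }
      }
      if (rowmin > max_score + EPS) dead = true;
    }
    if (dead) continue;

    // best final state: iterate j descending so score ties pick the largest
    // consumed target span = leftmost site start
    double best = INF; int bj = -1, bg = -1;
    int jlo = std::max(0, L - G), jhi = std::min(qlen, L + G);
    for (int j = jhi; j >= jlo; --j)
      for (int g = 0; g <= G; ++g) {
        double v = dp[idx(L, j, g)];
        if (v < best - EPS) { best = v; bj = j; bg = g; }
      }
    if (bj < 0 || best > max_score + EPS) continue;

    // traceback
    std::string a1, a2, pr;
    int i = L, j = bj, g = bg;
    while (i > 0 || j > 0) {
      unsigned char f = from[idx(i, j, g)];
      if (f == 1) {
        char pb = pirna[i - 1], tb = transcript[e0 - 1 - (j - 1)];
        int cls = pair_class(pb, tb);
        a1 += pb; a2 += tb;
        pr += (cls == 2 ? '|' : (cls == 1 ? ':' : '.'));
        --i; --j;
      } else if (f == 2) {
        a1 += pirna[i - 1]; a2 += '-'; pr += '-';
        --i; --g;
      } else if (f == 3) {
        a1 += '-'; a2 += transcript[e0 - 1 - (j - 1)]; pr += '-';
        --j; --g;
      } else {
        break; // unreachable for valid tracebacks
      }
    }
    std::reverse(a1.begin(), a1.end());
    std::reverse(a2.begin(), a2.end());
    std::reverse(pr.begin(), pr.end());

    r_start.push_back(e0 - bj);
    r_end.push_back(e0);
    r_score.push_back(best);
    r_gaps.push_back(bg);
    r_pair.push_back(pr);
    r_a1.push_back(a1);
    r_a2.push_back(a2);
  }

  return DataFrame::create(_["start"] = wrap(r_start),
                           _["end"] = wrap(r_end),
                           _["score"] = wrap(r_score),
                           _["gaps"] = wrap(r_gaps),
                           _["pairing"] = wrap(r_pair),
                           _["aln_pirna"] = wrap(r_a1),
                           _["aln_target"] = wrap(r_a2),
                           _["stringsAsFactors"] = false);
}
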