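#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Canonical global affine alignment.
//
// Among all maximum-score end-to-end alignments the canonical one minimizes
// the number of indel events (gap opens), then the number of substitutions,
// then takes the lexicographically smallest forward op string under the
// ordering D < I < M (D: reference base deleted from the read, I: read base
// inserted, M: aligned pair). Preferring D/I over M places every gap at its
// lowest score-equivalent reference coordinate (left alignment); preferring
// the op order on ties makes event coordinates deterministic.
//
// Returned op string drives event extraction on the R side.

struct Val {
  double sc;
  int ev;
  int sb;
  bool ok;
};

static const double EPS = 1e-9;

// is a better than b?
static inline bool better(const Val& a, const Val& b) {
  if (!b.ok) return a.ok;
  if (!a.ok) return false;
  if (a.sc > b.sc + EPS) return true;
  if (a.sc < b.sc - EPS) return false;
  if (a.ev != b.ev) return a.ev < b.ev;
  return a.sb < b.sb;
}

static inline bool same(const Val& a, const Val& b) {
  return a.ok && b.ok && std::abs(a.sc - b.sc) < EPS && a.ev == b.ev &&
         a.sb == b.sb;
}

// [[Rcpp::export(name = ".canonical_align_ops")]]
std::string canonical_align_ops(std::string read, std::string ref,
                                double match, double mismatch,
                                double gap_open, double gap_extend) {
  const int n = (int)read.size();
  const int m = (int)ref.size();
  const int S = 3; // prev op: 0 = M/none, 1 = D, 2 = I
  // V[(i * (m + 1) + j) * S + s] = best (score, events, subs) for aligning
  // read[i..) vs ref[j..) given the previous column op s.
  std::vector<Val> V((size_t)(n + 1) * (m + 1) * S);
  auto at = [&](int i, int j, int s) -> Val& {
    return V[((size_t)i * (m + 1) + j) * S + s];
  };

  for (int i = n; i >= 0; --i) {
    for (int j = m; j >= 0; --j) {
      for (int s = 0; s < S; ++s) {
        Val best; best.ok = false; best.sc = 0; best.ev = 0; best.sb = 0;
        if (i == n && j == m) {
          best.ok = true;
          at(i, j, s) = best;
          continue;
        }
        if (j < m) { // D: consume ref[j]
          Val t = at(i, j + 1, 1);
          if (t.ok) {
            bool open = (s != 1);
            Val c { t.sc + gap_extend + (open ? gap_open : 0.0),
                    t.ev + (open ? 1 : 0), t.sb, true };
            if (better(c, best)) best = c;
          }
        }
        if (i < n) { // I: consume read[i]
          Val t = at(i + 1, j, 2);
          if (t.ok) {
            bool open = (s != 2);
            Val c { t.sc + gap_extend + (open ? gap_open : 0.0),
                    t.ev + (open ? 1 : 0), t.sb, true };
            if (better(c, best)) best = c;
          }
        }
        if (i < n && j < m) { // M: aligned pair
          Val t = at(i + 1, j + 1, 0);
          if (t.ok) {
            bool mis = (read[i] != ref[j]);
            Val c { t.sc + (mis ? mismatch : match), t.ev,
                    t.sb + (mis ? 1 : 0), true };
            if (better(c, best)) best = c;
          }
        }
        at(i, j, s) = best;
      }
    }
  }

  // forward greedy walk: at each step take the smallest op (D < I < M) whose
  // one-step cost plus cost-to-go equals the optimum from here.
  std::string ops;
  ops.reserve(n + m);
  int i = 0, j = 0, s = 0;
  while (i < n || j < m) {
    Val cur = at(i, j, s);
    bool stepped = false;
    if (j < m) {
      Val t = at(i, j + 1, 1);
      if (t.ok) {
        bool open = (s != 1);
        Val c { t.sc + gap_extend + (open ? gap_open : 0.0),
                t.ev + (open ? 1 : 0), t.sb, true };
        if (same(c, cur)) { ops.push_back('D'); j++; s = 1; stepped = true; }
      }
    }
    if (!stepped && i < n) {
      Val t = at(i + 1, j, 2);
      if (t.ok) {
        bool open = (s != 2);
        Val c { t.sc + gap_extend + (open ? gap_open : 0.0),
                t.ev + (open ? 1 : 0), t.sb, true };
        if (same(c, cur)) { ops.push_back('I'); i++; s = 2; stepped = true; }
      }
    }
    if (!stepped && i < n && j < m) {
      Val t = at(i + 1, j + 1, 0);
      bool mis = (read[i] != ref[j]);
      Val c { t.sc + (mis ? mismatch : match), t.ev + 0,
              t.sb + (mis ? 1 : 0), t.ok };
      if (same(c, cur)) { ops.push_back('M'); i++; j++; s = 0; stepped = true; }
    }
    if (!stepped) stop("canonical alignment traceback failed");
  }
  return ops;
}

// [[Rcpp::export(name = ".canonical_align_score")]]
double canonical_align_score(std::string read, std::string ref,
                             double match, double mismatch,
                             double gap_open, double gap_extend) {
  // score of the optimal alignment (same DP, entry value)
  const int n = (int)read.size();
  if (n == 0 && ref.size() == 0) return 0.0;
  std::string ops = canonical_align_ops(read, ref, match, mismatch,
                                        gap_open, gap_extend);
  double sc = 0.0;
  int i = 0, j = 0;
  char prev = 'M';
  for (char o : ops) {
    if (o == 'M') {
      sc += (read[i] == ref[j]) ? match : mismatch;
      i++; j++;
    } else if (o == 'D') {
      sc += gap_extend + (prev != 'D' ? gap_open : 0.0);
      j++;
    } else {
      sc += gap_extend + (prev != 'I' ? gap_open : 0.0);
      i++;
    }
    prev = o;
  }
  return sc;
}
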