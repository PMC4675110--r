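#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Affine-gap Needleman-Wunsch (Gotoh) with a fully deterministic traceback:
// ties are resolved diagonal > up (gap in b) > left (gap in a), both when
// choosing the end state and within every cell. A gap of length k costs
// gap_open + (k - 1) * gap_extend (gap_open covers the first gapped column).

static inline bool is_gap(char c) { return c == '-' || c == '.'; }

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct NWResult {
  std::string a_aln;
  std::string b_aln;
  double score;
};

static NWResult gotoh(const std::string& a, const std::string& b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  // state 0 = M (diagonal), 1 = Ix (up, gap in b), 2 = Iy (left, gap in a)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  // predecessor state for traceback, per state
  std::vector<signed char> pM((n + 1) * (m + 1), -1);
  std::vector<signed char> pIx((n + 1) * (m + 1), -1);
  std::vector<signed char> pIy((n + 1) * (m + 1), -1);
  const int W = m + 1;

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[i * W] = gap_open + (i - 1) * gap_extend;
    pIx[i * W] = (signed char) (i == 1 ? 0 : 1);
  }
  for (int j = 1; j <= m; ++j) {
    Iy[j] = gap_open + (j - 1) * gap_extend;
    pIy[j] = (signed char) (j == 1 ? 0 : 2);
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1);
      const int u = (i - 1) * W + j, l = i * W + (j - 1);
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: diagonal move from best of the three states (pref M > Ix > Iy)
      double best = M[d]; signed char from = 0;
      if (Ix[d] > best) { best = Ix[d]; from = 1; }
      if (Iy[d] > best) { best = Iy[d]; from = 2; }
      if (best > NEG_INF) { M[c] = best + s; pM[c] = from; }
      // Ix: up move (consume a[i], gap in b)
      best = M[u] + gap_open; from = 0;
      if (Ix[u] + gap_extend > best) { best = Ix[u] + gap_extend; from = 1; }
      if (Iy[u] + gap_open > best) { best = Iy[u] + gap_open; from = 2; }
      Ix[c] = best; pIx[c] = from;
      // Iy: left move (consume b[j], gap in a)
      best = M[l] + gap_open; from = 0;
      if (Ix[l] + gap_open > best) { best = Ix[l] + gap_open; from = 1; }
      if (Iy[l] + gap_extend > best) { best = Iy[l] + gap_extend; from = 2; }
      Iy[c] = best; pIy[c] = from;
    }
  }

  const int end = n * W + m;
  double score = M[end]; int state = 0;
  if (Ix[end] > score) { score = Ix[end]; state = 1; }
  if (Iy[end] > score) { score = Iy[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      const int prev = pM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      const int prev = pIx[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      const int prev = pIy[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  NWResult out; out.a_aln = ra; out.b_aln = rb; out.score = score;
  return out;
}

// Distance between two equal-length aligned strings: differences divided by
// compared length. Columns where both sequences are gapped are skipped; with
// one_gap = true a maximal run of gap columns contributes one difference and
// one unit of length; with count_ends = false, columns before the first and
// after the last position where both sequences have a base are ignored.
static double aligned_dist(const std::string& a, const std::string& b,
                           bool one_gap, bool count_ends) {
  if (a.size() != b.size())
    stop("aligned sequences have unequal lengths (%d vs %d)",
         (int) a.size(), (int) b.size());
  const int L = (int) a.size();
  int start = 0, end = L - 1;
  if (!count_ends) {
    while (start < L && (is_gap(a[start]) || is_gap(b[start]))) ++start;
    while (end >= 0 && (is_gap(a[end]) || is_gap(b[end]))) --end;
  }
  double diffs = 0.0, len = 0.0;
  bool in_gap_run = false;
  for (int k = start; k <= end; ++k) {
    const bool ga = is_gap(a[k]), gb = is_gap(b[k]);
    if (ga && gb) continue;           // shared gap column: transparent
    if (ga || gb) {
      if (one_gap) {
        if (!in_gap_run) { diffs += 1.0; len += 1.0; in_gap_run = true; }
      } else {
        diffs += 1.0; len += 1.0;
      }
    } else {
      in_gap_run = false;
      len += 1.0;
      if (a[k] != b[k]) diffs += 1.0;
    }
  }
  if (len <= 0.0) stop("zero compared length between aligned sequences");
  return diffs / len;
}

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  if (a.empty() || b.empty()) stop("cannot align an empty sequence");
  NWResult r = gotoh(a, b, match, mismatch, gap_open, gap_extend);
  return List::create(_["a"] = r.a_aln, _["b"] = r.b_aln,
                      _["score"] = r.score);
}

// [[Rcpp::export]]
double cpp_pair_dist(std::string a, std::string b, bool one_gap,
                     bool count_ends) {
  return aligned_dist(a, b, one_gap, count_ends);
}

// [[Rcpp::export]]
List cpp_sparse_dist(CharacterVector seqs, bool aligned, double cutoff,
                     double match, double mismatch, double gap_open,
                     double gap_extend, bool one_gap, bool count_ends) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  if (aligned) {
    for (int i = 1; i < n; ++i)
      if (s[i].size() != s[0].size())
        stop("sequences are not uniformly aligned");
  }
  std::vector<int> vi, vj;
  std::vector<double> vd;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d;
      if (aligned) {
        d = aligned_dist(s[i], s[j], one_gap, count_ends);
      } else {
        NWResult r = gotoh(s[i], s[j], match, mismatch, gap_open, gap_extend);
        d = aligned_dist(r.a_aln, r.b_aln, one_gap, count_ends);
      }
      if (d <= cutoff) {
        vi.push_back(i + 1); vj.push_back(j + 1); vd.push_back(d);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["d"] = wrap(vd));
}

// [[Rcpp::export]]
NumericMatrix cpp_cross_dist(CharacterVector q, CharacterVector r,
                             bool aligned, double match, double mismatch,
                             double gap_open, double gap_extend, bool one_gap,
                             bool count_ends) {
  const int nq = q.size(), nr = r.size();
  std::vector<std::string> qs(nq), rs(nr);
  for (int i = 0; i < nq; ++i) qs[i] = as<std::string>(q[i]);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(r[j]);
  NumericMatrix out(nq, nr);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j) {
      if (aligned) {
        out(i, j) = aligned_dist(qs[i], rs[j], one_gap, count_ends);
      } else {
        NWResult a = gotoh(qs[i], rs[j], match, mismatch, gap_open,
                           gap_extend);
        out(i, j) = aligned_dist(a.a_aln, a.b_aln, one_gap, count_ends);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
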