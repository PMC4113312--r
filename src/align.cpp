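#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap (Gotoh) local alignment over {A,C,G,T}; any other symbol
// (N, masked/lower-case) never matches.  A gap of length k costs
// gap_open + k * gap_extend.  Scores are integers internally.
//
// Banding: with band > 0 the recursion is restricted to diagonals
// |j - i| <= band.  Out-of-band cells are treated as score 0 in the
// score-only kernel (a fresh local start, never an accumulated path), so
// banded scores are a lower bound of the unbanded optimum and equal to it
// whenever the optimal path stays within the band.

static const int NEG = std::numeric_limits<int>::min() / 4;

static inline unsigned char base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return 4;  // never matches anything, not even itself
  }
}

static std::vector<unsigned char> encode(const std::string& s) {
  std::vector<unsigned char> v(s.size() + 1);
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  v[s.size()] = 5;
  return v;
}

// Score-only banded local alignment on encoded sequences.
static int sw_score(const unsigned char* a, int n, const unsigned char* b,
                    int m, int match, int mismatch, int go, int ge,
                    int band) {
  if (n == 0 || m == 0) return 0;
  std::vector<int> H0(m + 2, 0), H1(m + 2, 0), Fc(m + 2, NEG);
  int best = 0;
  const int goe = go + ge;
  for (int i = 1; i <= n; ++i) {
    int lo = 1, hi = m;
    if (band > 0) {
      lo = i - band; if (lo < 1) lo = 1;
      hi = i + band; if (hi > m) hi = m;
      if (lo > hi) break;
      H1[lo - 1] = 0;  // out-of-band left neighbour: fresh-start floor
    }
    int e = NEG;
    const unsigned char ai = a[i - 1];
    const int* __restrict h0 = H0.data();
    int* __restrict h1 = H1.data();
    int* __restrict fc = Fc.data();
    for (int j = lo; j <= hi; ++j) {
      int diag = h0[j - 1] + (ai == b[j - 1] && ai < 4 ? match : mismatch);
      int f = h0[j] + goe;
      const int fx = fc[j] + ge;
      if (fx > f) f = fx;
      fc[j] = f;
      int eo = h1[j - 1] + goe;
      e = e + ge;
      if (eo > e) e = eo;
      int h = diag;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      h1[j] = h;
      if (h > best) best = h;
    }
    std::swap(H0, H1);
  }
  return best;
}

struct AlnResult {
  int score, matches, cols, qstart, qend, sstart, send;
};

// Full-traceback banded local alignment (matrices allocated densely;
// out-of-band cells marked NEG so traced paths stay in band).
static AlnResult sw_align(const std::string& as, const std::string& bs,
                          int match, int mismatch, int go, int ge,
                          int band) {
  AlnResult res = {0, 0, 0, 0, 0, 0, 0};
  const int n = (int)as.size(), m = (int)bs.size();
  if (n == 0 || m == 0) return res;
  std::vector<unsigned char> a = encode(as), b = encode(bs);
  const int W = m + 1;
  std::vector<int> H((size_t)(n + 1) * W, 0), E((size_t)(n + 1) * W, NEG),
      F((size_t)(n + 1) * W, NEG);
  // traceback codes: tbH 0=stop 1=diag 2=E 3=F; tbE/tbF 0=open 1=extend
  std::vector<unsigned char> tbH((size_t)(n + 1) * W, 0),
      tbE((size_t)(n + 1) * W, 0), tbF((size_t)(n + 1) * W, 0);
  const int goe = go + ge;
  int best = 0, bi = 0, bj = 0;
  if (band > 0) {
    for (int i = 1; i <= n; ++i) {
      const int lo = std::max(1, i - band), hi = std::min(m, i + band);
      for (int j = 1; j < lo; ++j) H[(size_t)i * W + j] = NEG;
      for (int j = hi + 1; j <= m; ++j) H[(size_t)i * W + j] = NEG;
    }
  }
  for (int i = 1; i <= n; ++i) {
    int lo = 1, hi = m;
    if (band > 0) {
      lo = std::max(1, i - band);
      hi = std::min(m, i + band);
      if (lo > hi) break;
    }
    for (int j = lo; j <= hi; ++j) {
      const size_t k = (size_t)i * W + j;
      const size_t ku = k - W;       // (i-1, j)
      const size_t kl = k - 1;       // (i, j-1)
      const size_t kd = ku - 1;      // (i-1, j-1)
      int e_open = H[kl] + goe, e_ext = E[kl] + ge;
      E[k] = e_open >= e_ext ? e_open : e_ext;
      tbE[k] = e_open >= e_ext ? 0 : 1;
      int f_open = H[ku] + goe, f_ext = F[ku] + ge;
      F[k] = f_open >= f_ext ? f_open : f_ext;
      tbF[k] = f_open >= f_ext ? 0 : 1;
      int s = (a[i - 1] == b[j - 1] && a[i - 1] < 4) ? match : mismatch;
      int h = 0; unsigned char tb = 0;
      int d = H[kd] + s;
      if (d > h) { h = d; tb = 1; }
      if (E[k] > h) { h = E[k]; tb = 2; }
      if (F[k] > h) { h = F[k]; tb = 3; }
      H[k] = h; tbH[k] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  res.score = best;
  if (best <= 0) return res;
  int i = bi, j = bj, state = 0;  // 0 = H
  res.qend = bi; res.send = bj;
  while (true) {
    const size_t k = (size_t)i * W + j;
    if (state == 0) {
      unsigned char tb = tbH[k];
      if (tb == 0) break;
      if (tb == 1) {
        res.cols++;
        if (a[i - 1] == b[j - 1] && a[i - 1] < 4) res.matches++;
        --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      res.cols++;
      state = tbE[k] == 0 ? 0 : 2;
      --j;
    } else {
      res.cols++;
      state = tbF[k] == 0 ? 0 : 3;
      --i;
    }
  }
  res.qstart = i + 1; res.sstart = j + 1;
  return res;
}

static List aln_to_list(const AlnResult& r) {
  return List::create(
      _["score"] = (double)r.score, _["matches"] = r.matches,
      _["aligned_columns"] = r.cols, _["qstart"] = r.qstart,
      _["qend"] = r.qend, _["sstart"] = r.sstart, _["send"] = r.send);
}

// [[Rcpp::export(name = ".sw_pair_cpp")]]
List sw_pair_cpp(std::string a, std::string b, int match, int mismatch,
                 int gap_open, int gap_extend, int band) {
  AlnResult r = sw_align(a, b, match, mismatch, gap_open, gap_extend,
                         band);
  return aln_to_list(r);
}

// [[Rcpp::export(name = ".sw_score_all_cpp")]]
NumericMatrix sw_score_all_cpp(CharacterVector A, CharacterVector B,
                               int match, int mismatch, int gap_open,
                               int gap_extend, int band, bool self) {
  const int na = A.size(), nb = self ? na : B.size();
  NumericMatrix out(na, nb);
  std::vector<std::vector<unsigned char> > as(na), bs;
  std::vector<int> alen(na), blen;
  for (int i = 0; i < na; ++i) {
    std::string s = Rcpp::as<std::string>(A[i]);
    alen[i] = (int)s.size();
    as[i] = encode(s);
  }
  if (!self) {
    bs.resize(nb); blen.resize(nb);
    for (int j = 0; j < nb; ++j) {
      std::string s = Rcpp::as<std::string>(B[j]);
      blen[j] = (int)s.size();
      bs[j] = encode(s);
    }
  }
  const std::vector<std::vector<unsigned char> >& bref = self ? as : bs;
  const std::vector<int>& blref = self ? alen : blen;
  for (int i = 0; i < na; ++i) {
    Rcpp::checkUserInterrupt();
    int j0 = self ? i + 1 : 0;
    for (int j = j0; j < nb; ++j) {
      int s = sw_score(as[i].data(), alen[i], bref[j].data(), blref[j],
                       match, mismatch, gap_open, gap_extend, band);
      out(i, j) = s;
      if (self) out(j, i) = s;
    }
    if (self) out(i, i) = NA_REAL;
  }
  return out;
}

// Greedy best-first non-overlapping HSPs by iterative masking.
// [[Rcpp::export(name = ".sw_hsps_cpp")]]
NumericMatrix sw_hsps_cpp(std::string a, std::string b, int match,
                          int mismatch, int gap_open, int gap_extend,
                          int band, int max_hsps, int min_score) {
  std::vector<AlnResult> hsps;
  std::string am = a, bm = b;
  for (int k = 0; k < max_hsps; ++k) {
    AlnResult r = sw_align(am, bm, match, mismatch, gap_open, gap_extend,
                           band);
    if (r.score < min_score || r.cols == 0) break;
    hsps.push_back(r);
    for (int i = r.qstart - 1; i < r.qend; ++i) am[i] = '\1';
    for (int j = r.sstart - 1; j < r.send; ++j) bm[j] = '\2';
  }
  NumericMatrix out(hsps.size(), 7);
  colnames(out) = CharacterVector::create("score", "matches",
      "aligned_columns", "qstart", "qend", "sstart", "send");
  for (size_t k = 0; k < hsps.size(); ++k) {
    out(k, 0) = hsps[k].score;   out(k, 1) = hsps[k].matches;
    out(k, 2) = hsps[k].cols;    out(k, 3) = hsps[k].qstart;
    out(k, 4) = hsps[k].qend;    out(k, 5) = hsps[k].sstart;
    out(k, 6) = hsps[k].send;
  }
  return out;
}
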