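#include <Rcpp.h>
#include <climits>
#include <vector>
#include <cstdint>
#ifdef __SSE2__
#include <emmintrin.h>
#endif
using namespace Rcpp;

// Affine gaps follow the BLAST convention throughout: a gap of length L
// costs gap_open + L * gap_ext, so opening transition is -(go + ge).

static const int NEG = INT_MIN / 4;

// ---- Smith-Waterman, score only ------------------------------------------

static int sw_score_core(const int* a, int la, const int* b, int lb,
                         const int* sub, int ns, int go, int ge) {
  std::vector<int> H(lb + 1, 0), IX(lb + 1, NEG);
  int best = 0;
  const int open = go + ge;
  for (int i = 1; i <= la; ++i) {
    int diag = 0, iy = NEG, hleft = 0;
    const int* srow = sub + (size_t)a[i - 1] * ns;
    for (int j = 1; j <= lb; ++j) {
      int ix = IX[j] - ge;
      int t = H[j] - open;
      if (t > ix) ix = t;
      IX[j] = ix;
      iy -= ge;
      t = hleft - open;
      if (t > iy) iy = t;
      int h = diag + srow[b[j - 1]];
      if (ix > h) h = ix;
      if (iy > h) h = iy;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
int cpp_sw_score(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                 int gap_open, int gap_ext) {
  return sw_score_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                       INTEGER(sub), sub.nrow(), gap_open, gap_ext);
}

#ifdef __SSE2__
// ---- Striped SW (Farrar 2007 / SSW scheme), 16-bit, score only ----------
// Used for batch score matrices; exactness is cross-validated against the
// scalar kernel in the test suite.

struct StripedProfile {
  int lq, seglen, ns;
  std::vector<__m128i> prof; // ns * seglen vectors
};

static void build_profile(StripedProfile& P, const int* q, int lq,
                          const int* sub, int ns) {
  P.lq = lq;
  P.ns = ns;
  P.seglen = (lq + 7) / 8;
  P.prof.assign((size_t)ns * P.seglen, _mm_setzero_si128());
  int16_t* t = reinterpret_cast<int16_t*>(P.prof.data());
  for (int r = 0; r < ns; ++r) {
    for (int k = 0; k < P.seglen; ++k) {
      for (int l = 0; l < 8; ++l) {
        int idx = l * P.seglen + k;
        t[((size_t)r * P.seglen + k) * 8 + l] =
            (idx < lq) ? (int16_t)sub[(size_t)q[idx] * ns + r] : 0;
      }
    }
  }
}

static int sw_score_striped(const StripedProfile& P, const int* s, int ls,
                            int go, int ge) {
  int seglen = P.seglen;
  std::vector<__m128i> Hs(seglen, _mm_setzero_si128());
  std::vector<__m128i> Hl(seglen, _mm_setzero_si128());
  std::vector<__m128i> Ev(seglen, _mm_setzero_si128());
  __m128i vGapOE = _mm_set1_epi16((int16_t)(go + ge));
  __m128i vGapE = _mm_set1_epi16((int16_t)ge);
  __m128i vZero = _mm_setzero_si128();
  __m128i vMax = vZero;
  __m128i* pvHStore = Hs.data();
  __m128i* pvHLoad = Hl.data();
  for (int j = 0; j < ls; ++j) {
    const __m128i* prof = P.prof.data() + (size_t)s[j] * seglen;
    __m128i vF = vZero;
    __m128i vH = _mm_slli_si128(pvHStore[seglen - 1], 2);
    std::swap(pvHStore, pvHLoad);
    for (int k = 0; k < seglen; ++k) {
      vH = _mm_adds_epi16(vH, prof[k]);
      __m128i vE = Ev[k];
      vH = _mm_max_epi16(vH, vE);
      vH = _mm_max_epi16(vH, vF);
      vH = _mm_max_epi16(vH, vZero);
      pvHStore[k] = vH;
      vMax = _mm_max_epi16(vMax, vH);
      __m128i vHg = _mm_subs_epi16(vH, vGapOE);
      vE = _mm_subs_epi16(vE, vGapE);
      vE = _mm_max_epi16(vE, vHg);
      Ev[k] = vE;
      vF = _mm_subs_epi16(vF, vGapE);
      vF = _mm_max_epi16(vF, vHg);
      vH = pvHLoad[k];
    }
    // lazy F propagation
    for (int wrap = 0; wrap < 8; ++wrap) {
      vF = _mm_slli_si128(vF, 2);
      bool done = false;
      for (int k = 0; k < seglen; ++k) {
        __m128i vHk = pvHStore[k];
        vHk = _mm_max_epi16(vHk, vF);
        pvHStore[k] = vHk;
        vMax = _mm_max_epi16(vMax, vHk);
        __m128i vHg = _mm_subs_epi16(vHk, vGapOE);
        // F can also extend E-competitive paths; keep E in sync so the
        // next column sees the corrected H
        __m128i vE = _mm_max_epi16(Ev[k], vHg);
        Ev[k] = vE;
        vF = _mm_subs_epi16(vF, vGapE);
        if (!_mm_movemask_epi8(_mm_cmpgt_epi16(vF, vHg))) { done = true; break; }
      }
      if (done) break;
    }
  }
  // horizontal max of vMax
  int16_t buf[8];
  _mm_storeu_si128(reinterpret_cast<__m128i*>(buf), vMax);
  int best = 0;
  for (int l = 0; l < 8; ++l) if (buf[l] > best) best = buf[l];
  return best;
}
#endif

// safe for 16-bit striped arithmetic?
static bool fits_16bit(int la, int lb, const int* sub, int ns) {
  int mx = 0;
  for (int i = 0; i < ns * ns; ++i) if (sub[i] > mx) mx = sub[i];
  double bound = (double)std::min(la, lb) * mx;
  return bound < 30000.0;
}

// All-vs-all upper triangle (plus diagonal) of SW scores.
// [[Rcpp::export]]
IntegerMatrix cpp_sw_score_matrix(List seqs, IntegerMatrix sub,
                                  int gap_open, int gap_ext) {
  int n = seqs.size();
  std::vector<IntegerVector> sv(n);
  int maxlen = 0;
  for (int i = 0; i < n; ++i) {
    sv[i] = seqs[i];
    if (sv[i].size() > maxlen) maxlen = sv[i].size();
  }
  IntegerMatrix out(n, n);
#ifdef __SSE2__
  bool striped = fits_16bit(maxlen, maxlen, INTEGER(sub), sub.nrow());
  StripedProfile P;
#else
  bool striped = false;
#endif
  for (int i = 0; i < n; ++i) {
#ifdef __SSE2__
    if (striped)
      build_profile(P, INTEGER(sv[i]), sv[i].size(), INTEGER(sub),
                    sub.nrow());
#endif
    for (int j = i; j < n; ++j) {
      int s;
#ifdef __SSE2__
      if (striped)
        s = sw_score_striped(P, INTEGER(sv[j]), sv[j].size(), gap_open,
                             gap_ext);
      else
#endif
        s = sw_score_core(INTEGER(sv[i]), sv[i].size(),
                          INTEGER(sv[j]), sv[j].size(),
                          INTEGER(sub), sub.nrow(), gap_open, gap_ext);
      out(i, j) = s;
      out(j, i) = s;
    }
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Rectangular score matrix: queries x subjects.
// [[Rcpp::export]]
IntegerMatrix cpp_sw_score_cross(List qs, List ss, IntegerMatrix sub,
                                 int gap_open, int gap_ext) {
  int nq = qs.size(), nsub = ss.size();
  IntegerMatrix out(nq, nsub);
  int maxq = 0, maxs = 0;
  for (int i = 0; i < nq; ++i) {
    IntegerVector q = qs[i];
    if (q.size() > maxq) maxq = q.size();
  }
  for (int j = 0; j < nsub; ++j) {
    IntegerVector s = ss[j];
    if (s.size() > maxs) maxs = s.size();
  }
#ifdef __SSE2__
  bool striped = fits_16bit(maxq, maxs, INTEGER(sub), sub.nrow());
  StripedProfile P;
#else
  bool striped = false;
#endif
  for (int i = 0; i < nq; ++i) {
    IntegerVector q = qs[i];
#ifdef __SSE2__
    if (striped)
      build_profile(P, INTEGER(q), q.size(), INTEGER(sub), sub.nrow());
#endif
    for (int j = 0; j < nsub; ++j) {
      IntegerVector s = ss[j];
#ifdef __SSE2__
      if (striped) {
        out(i, j) = sw_score_striped(P, INTEGER(s), s.size(), gap_open,
                                     gap_ext);
        continue;
      }
#endif
      out(i, j) = sw_score_core(INTEGER(q), q.size(), INTEGER(s), s.size(),
                                INTEGER(sub), sub.nrow(), gap_open, gap_ext);
    }
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// exposed for cross-validation in the test suite
// [[Rcpp::export]]
int cpp_sw_score_striped_one(IntegerVector a, IntegerVector b,
                             IntegerMatrix sub, int gap_open, int gap_ext) {
#ifdef __SSE2__
  StripedProfile P;
  build_profile(P, INTEGER(a), a.size(), INTEGER(sub), sub.nrow());
  return sw_score_striped(P, INTEGER(b), b.size(), gap_open, gap_ext);
#else
  return sw_score_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                       INTEGER(sub), sub.nrow(), gap_open, gap_ext);
#endif
}

// ---- Full alignments with traceback --------------------------------------

// state codes for traceback
enum { ST_H = 0, ST_IX = 1, ST_IY = 2 };

// Shared traceback machinery for SW/NW. H/IX/IY matrices are fully stored.
static List align_full(const int* a, int la, const int* b, int lb,
                       const int* sub, int ns, int go, int ge, bool global) {
  const int open = go + ge;
  size_t w = lb + 1;
  std::vector<int> H((la + 1) * w, NEG), IX((la + 1) * w, NEG),
      IY((la + 1) * w, NEG);
  H[0] = 0;
  for (int j = 1; j <= lb; ++j) {
    if (global) {
      IY[j] = -(go + ge * j);
      H[j] = IY[j];
    } else {
      H[j] = 0;
    }
  }
  for (int i = 1; i <= la; ++i) {
    if (global) {
      IX[i * w] = -(go + ge * i);
      H[i * w] = IX[i * w];
    } else {
      H[i * w] = 0;
    }
  }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    const int* srow = sub + (size_t)a[i - 1] * ns;
    for (int j = 1; j <= lb; ++j) {
      size_t c = i * w + j, up = c - w, lf = c - 1, dg = up - 1;
      int ix = std::max(H[up] == NEG ? NEG : H[up] - open,
                        IX[up] == NEG ? NEG : IX[up] - ge);
      int iy = std::max(H[lf] == NEG ? NEG : H[lf] - open,
                        IY[lf] == NEG ? NEG : IY[lf] - ge);
      int dg_s = (H[dg] == NEG) ? NEG : H[dg] + srow[b[j - 1]];
      int h = dg_s;
      if (ix > h) h = ix;
      if (iy > h) h = iy;
      if (!global && h < 0) h = 0;
      IX[c] = ix;
      IY[c] = iy;
      H[c] = h;
      if (!global && h > best) { best = h; bi = i; bj = j; }
    }
  }
  int qe, se, score;
  int state = ST_H;
  if (global) {
    size_t c = la * w + lb;
    score = H[c];
    if (IX[c] > score && IX[c] >= IY[c]) { score = IX[c]; state = ST_IX; }
    else if (IY[c] > score) { score = IY[c]; state = ST_IY; }
    bi = la; bj = lb;
  } else {
    score = best;
  }
  qe = bi; se = bj;
  // traceback
  std::vector<int> ai, bjv;
  int i = bi, j = bj;
  while (true) {
    if (!global && state == ST_H && H[i * w + j] == 0) break;
    if (i == 0 && j == 0) break;
    size_t c = i * w + j, up = c - w, lf = c - 1;
    if (state == ST_H) {
      if (global && i == 0) { state = ST_IY; continue; }
      if (global && j == 0) { state = ST_IX; continue; }
      int h = H[c];
      const int* srow = sub + (size_t)a[i - 1] * ns;
      if (i > 0 && j > 0 && H[up - 1] != NEG &&
          h == H[up - 1] + srow[b[j - 1]]) {
        ai.push_back(i - 1); bjv.push_back(j - 1);
        --i; --j;
      } else if (h == IX[c]) {
        state = ST_IX;
      } else if (h == IY[c]) {
        state = ST_IY;
      } else {
        stop("traceback failure (H)");
      }
    } else if (state == ST_IX) {
      // gap in b: consume a[i-1]
      ai.push_back(i - 1); bjv.push_back(-1);
      int v = IX[c];
      if (IX[up] != NEG && v == IX[up] - ge && i > 1) {
        --i;
      } else {
        --i;
        state = ST_H;
      }
    } else { // ST_IY
      ai.push_back(-1); bjv.push_back(j - 1);
      int v = IY[c];
      if (IY[lf] != NEG && v == IY[lf] - ge && j > 1) {
        --j;
      } else {
        --j;
        state = ST_H;
      }
    }
  }
  int qs = i, ss = j; // 0-based start (half-open convention: starts here)
  std::reverse(ai.begin(), ai.end());
  std::reverse(bjv.begin(), bjv.end());
  int ncol = ai.size();
  int ident = 0, mism = 0, gaps = 0, gapopens = 0;
  bool ingap = false;
  for (int k = 0; k < ncol; ++k) {
    if (ai[k] < 0 || bjv[k] < 0) {
      ++gaps;
      if (!ingap) { ++gapopens; ingap = true; }
    } else {
      ingap = false;
      if (a[ai[k]] == b[bjv[k]]) ++ident; else ++mism;
    }
  }
  return List::create(_["score"] = score, _["ncol"] = ncol,
                      _["identities"] = ident, _["mismatches"] = mism,
                      _["gaps"] = gaps, _["gapopens"] = gapopens,
                      _["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se,
                      _["ai"] = IntegerVector(ai.begin(), ai.end()),
                      _["bj"] = IntegerVector(bjv.begin(), bjv.end()));
}

// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
  return align_full(INTEGER(a), a.size(), INTEGER(b), b.size(),
                    INTEGER(sub), sub.nrow(), gap_open, gap_ext, false);
}

// [[Rcpp::export]]
List cpp_nw_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
  return align_full(INTEGER(a), a.size(), INTEGER(b), b.size(),
                    INTEGER(sub), sub.nrow(), gap_open, gap_ext, true);
}

// ---- Longest common subsequence (for gene-order similarity) ---------------

// [[Rcpp::export]]
int cpp_lcs_length(IntegerVector x, IntegerVector y) {
  int n = x.size(), m = y.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    int xi = x[i - 1];
    for (int j = 1; j <= m; ++j) {
      cur[j] = (xi == y[j - 1]) ? prev[j - 1] + 1
                                : std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// ---- Longest direct repeat between two windows ----------------------------

// Finds the best pair of same-orientation substrings (one in `left`, one
// in `right`) with at most max_mismatch differences, ranked by the
// mismatch-penalized score len - penalty*mm (chance repeats are shorter
// than real attachment sites once mismatches are penalized). Candidate
// windows never start or end on a mismatch. Codes >= 4 (N) always count
// as mismatches. Ties: higher score, then longer, then the left copy
// ending closest to the end of `left` (the provirus boundary), then the
// right copy starting closest to the start of `right`. Returns
// c(len, i_start, j_start, mismatches) (0-based), or integer(0) when
// nothing >= min_len exists.
// [[Rcpp::export]]
IntegerVector cpp_longest_direct_repeat(IntegerVector left,
                                        IntegerVector right,
                                        int min_len, int max_mismatch,
                                        int penalty = 4) {
  int n = left.size(), m = right.size();
  int best_len = 0, best_i = -1, best_j = -1, best_mm = 0;
  int best_score = -1;
  std::vector<int> mmpos;
  for (int budget = 0; budget <= max_mismatch; ++budget) {
    for (int d = -(n - 1); d <= m - 1; ++d) {
      int i0 = std::max(0, -d);
      int len = std::min(n - i0, m - (i0 + d));
      if (len < min_len) continue;
      mmpos.clear();
      int lo = 0;
      size_t firstmm = 0;
      for (int k = 0; k < len; ++k) {
        int ai = left[i0 + k], bj = right[i0 + d + k];
        bool mismatch = (ai != bj) || ai >= 4;
        if (mismatch) mmpos.push_back(k);
        while ((int)(mmpos.size() - firstmm) > budget) {
          lo = mmpos[firstmm] + 1;
          ++firstmm;
        }
        if (mismatch) continue; // only consider windows ending on a match
        // trim leading mismatches
        int start = lo;
        size_t f = firstmm;
        while (f < mmpos.size() && mmpos[f] == start) { ++start; ++f; }
        int wlen = k - start + 1;
        if (wlen < min_len) continue;
        int mm = (int)(mmpos.size() - f);
        int score = wlen - penalty * mm;
        int i_start = i0 + start, j_start = i0 + d + start;
        int i_end = i_start + wlen;
        bool better = false;
        if (score > best_score) better = true;
        else if (score == best_score) {
          if (wlen > best_len) better = true;
          else if (wlen == best_len) {
            int cur_end = best_i + best_len;
            if (i_end > cur_end) better = true;
            else if (i_end == cur_end && j_start < best_j) better = true;
          }
        }
        if (better) {
          best_score = score;
          best_len = wlen;
          best_i = i_start;
          best_j = j_start;
          best_mm = mm;
        }
      }
    }
  }
  if (best_len < min_len) return IntegerVector(0);
  return IntegerVector::create(best_len, best_i, best_j, best_mm);
}
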