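// Exact affine-gap alignment kernels.
//
// Scoring conventions (shared with the R layer and the test oracles):
//   * a gap of length L costs  gap_open + L * gap_ext  (local and global);
//   * local (Smith-Waterman) scores are integers, cells floored at 0;
//   * global (Needleman-Wunsch) alignment leaves terminal gaps unpenalised
//     but counts them in the alignment length, as EMBOSS needle reports;
//   * traceback tie-break: diagonal, then gap-in-subject (up), then
//     gap-in-query (left).
//
// The all-vs-all score pass uses a striped SSE2 16-bit Smith-Waterman
// (Farrar 2007, Bioinformatics 23:156) with a scalar fallback; both paths
// return identical scores. 16-bit is exact here: max attainable score is
// max_len * max_diag (< 3000) << 32767.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
#ifdef __SSE2__
#include <emmintrin.h>
#endif
using namespace Rcpp;

static int sw_score_scalar(const uint8_t* a, int n, const uint8_t* b, int m,
                           const int* sm, int K, int gap_open, int gap_ext) {
  std::vector<int> H(m + 1, 0), E(m + 1, 0);
  const int go = gap_open + gap_ext, ge = gap_ext;
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int diag = 0, F = 0;
    const int* srow = sm + (size_t)a[i - 1] * K;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - ge, H[j] - go);
      F = std::max(F - ge, H[j - 1] - go);
      int h = diag + srow[b[j - 1]];
      if (h < E[j]) h = E[j];
      if (h < F) h = F;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

#ifdef __SSE2__

struct Profile16 {
  std::vector<int16_t> data;  // K * segLen * 8, striped layout
  int segLen = 0;
};

static void build_profile16(const uint8_t* q, int qlen, const int* sm, int K,
                            Profile16& p) {
  int segLen = (qlen + 7) / 8;
  p.segLen = segLen;
  p.data.assign((size_t)K * segLen * 8, 0);
  for (int a = 0; a < K; ++a) {
    int16_t* t = p.data.data() + (size_t)a * segLen * 8;
    int idx = 0;
    for (int i = 0; i < segLen; ++i)
      for (int seg = 0; seg < 8; ++seg) {
        int pos = i + seg * segLen;
        t[idx++] = (pos < qlen) ? (int16_t)sm[(size_t)q[pos] * K + a] : 0;
      }
  }
}

static int sw_score_striped(const Profile16& p, const uint8_t* db, int dblen,
                            int gap_open, int gap_ext,
                            std::vector<__m128i>& buf) {
  const int segLen = p.segLen;
  if ((int)buf.size() < 3 * segLen) buf.resize(3 * segLen);
  __m128i* pvHStore = buf.data();
  __m128i* pvHLoad = buf.data() + segLen;
  __m128i* pvE = buf.data() + 2 * segLen;
  const __m128i vZero = _mm_setzero_si128();
  for (int i = 0; i < segLen; ++i) { pvHStore[i] = vZero; pvE[i] = vZero; }
  const __m128i vGapO = _mm_set1_epi16((int16_t)(gap_open + gap_ext));
  const __m128i vGapE = _mm_set1_epi16((int16_t)gap_ext);
  __m128i vMax = vZero;
  const __m128i* vProfBase = (const __m128i*)p.data.data();
  for (int j = 0; j < dblen; ++j) {
    __m128i vF = vZero;
    __m128i vH = _mm_slli_si128(pvHStore[segLen - 1], 2);
    const __m128i* vP = vProfBase + (size_t)db[j] * segLen;
    std::swap(pvHStore, pvHLoad);
    for (int i = 0; i < segLen; ++i) {
      vH = _mm_adds_epi16(vH, vP[i]);
      __m128i vE = pvE[i];
      vH = _mm_max_epi16(vH, vE);
      vH = _mm_max_epi16(vH, vF);
      vH = _mm_max_epi16(vH, vZero);
      vMax = _mm_max_epi16(vMax, vH);
      pvHStore[i] = vH;
      __m128i vHg = _mm_subs_epi16(vH, vGapO);
      pvE[i] = _mm_max_epi16(_mm_subs_epi16(vE, vGapE), vHg);
      vF = _mm_max_epi16(_mm_subs_epi16(vF, vGapE), vHg);
      vH = pvHLoad[i];
    }
    // lazy-F correction (Farrar 2007), bounded as in the SSW library:
    // at most 8 lane shifts, early exit once F can no longer raise H
    for (int k = 0; k < 8; ++k) {
      vF = _mm_slli_si128(vF, 2);
      for (int i = 0; i < segLen; ++i) {
        __m128i vH2 = _mm_max_epi16(pvHStore[i], vF);
        pvHStore[i] = vH2;
        __m128i vHg = _mm_subs_epi16(vH2, vGapO);
        vF = _mm_subs_epi16(vF, vGapE);
        if (!_mm_movemask_epi8(_mm_cmpgt_epi16(vF, vHg))) goto col_done;
      }
    }
  col_done:;
  }
  int16_t tmp[8];
  _mm_storeu_si128((__m128i*)tmp, vMax);
  int best = 0;
  for (int k = 0; k < 8; ++k)
    if (tmp[k] > best) best = tmp[k];
  return best;
}

#endif  // __SSE2__

static std::vector<std::vector<uint8_t> > decode_seqs(const List& seqs) {
  int n = seqs.size();
  std::vector<std::vector<uint8_t> > S(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    S[i].resize(v.size());
    for (int k = 0; k < v.size(); ++k) S[i][k] = (uint8_t)v[k];
  }
  return S;
}

// All-vs-all optimal local alignment scores.
// seqs: list of integer vectors (0-based codes into the scoring alphabet);
// ia, ib: 1-based indices into seqs. If symmetric, all unordered pairs
// within ia are scored (ib ignored); otherwise all (ia x ib) pairs.
// Pairs scoring >= min_score are returned (scores are symmetric).
// [[Rcpp::export]]
DataFrame cpp_pair_scores(List seqs, IntegerVector ia, IntegerVector ib,
                          bool symmetric, IntegerMatrix sm, int gap_open,
                          int gap_ext, int min_score) {
  int K = sm.nrow();
  std::vector<int> smv((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) smv[(size_t)i * K + j] = sm(i, j);
  std::vector<std::vector<uint8_t> > S = decode_seqs(seqs);
  std::vector<int> outq, outs, outsc;
#ifdef __SSE2__
  std::vector<__m128i> buf;
  Profile16 prof;
#endif
  int na = ia.size(), nb = symmetric ? na : ib.size();
  for (int x = 0; x < na; ++x) {
    int qi = ia[x] - 1;
    const std::vector<uint8_t>& q = S[qi];
    if (q.empty()) continue;
#ifdef __SSE2__
    build_profile16(q.data(), q.size(), smv.data(), K, prof);
#endif
    if (x % 64 == 0) Rcpp::checkUserInterrupt();
    int ystart = symmetric ? x + 1 : 0;
    for (int y = ystart; y < nb; ++y) {
      int si = (symmetric ? ia[y] : ib[y]) - 1;
      const std::vector<uint8_t>& s = S[si];
      if (s.empty()) continue;
#ifdef __SSE2__
      int sc = sw_score_striped(prof, s.data(), s.size(), gap_open, gap_ext, buf);
#else
      int sc = sw_score_scalar(q.data(), q.size(), s.data(), s.size(),
                               smv.data(), K, gap_open, gap_ext);
#endif
      if (sc >= min_score) {
        outq.push_back(qi + 1);
        outs.push_back(si + 1);
        outsc.push_back(sc);
      }
    }
  }
  return DataFrame::create(_["qi"] = outq, _["si"] = outs, _["score"] = outsc);
}

// Single-pair optimal local score (used by tests and small searches).
// [[Rcpp::export]]
int cpp_sw_score(IntegerVector a, IntegerVector b, IntegerMatrix sm,
                 int gap_open, int gap_ext) {
  int K = sm.nrow();
  std::vector<int> smv((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) smv[(size_t)i * K + j] = sm(i, j);
  std::vector<uint8_t> av(a.size()), bv(b.size());
  for (int i = 0; i < a.size(); ++i) av[i] = (uint8_t)a[i];
  for (int i = 0; i < b.size(); ++i) bv[i] = (uint8_t)b[i];
  return sw_score_scalar(av.data(), av.size(), bv.data(), bv.size(),
                         smv.data(), K, gap_open, gap_ext);
}

struct SWBuffers {
  std::vector<int> H, E, F;
};

static void sw_stats_core(const uint8_t* a, int n, const uint8_t* b, int m,
                          const int* sm, int K, int gap_open, int gap_ext,
                          SWBuffers& buf, int* out7) {
  const int go = gap_open + gap_ext, ge = gap_ext;
  const int NEG = INT_MIN / 4;
  size_t sz = (size_t)(n + 1) * (m + 1);
  buf.H.assign(sz, 0);
  buf.E.assign(sz, NEG);
  buf.F.assign(sz, NEG);
  int* H = buf.H.data(); int* E = buf.E.data(); int* F = buf.F.data();
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int* srow = sm + (size_t)a[i - 1] * K;
    size_t c = (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      ++c;
      size_t up = c - (m + 1), left = c - 1, dg = up - 1;
      E[c] = std::max(E[left] - ge, H[left] - go);
      F[c] = std::max(F[up] - ge, H[up] - go);
      int h = H[dg] + srow[b[j - 1]];
      if (h < E[c]) h = E[c];
      if (h < F[c]) h = F[c];
      if (h < 0) h = 0;
      H[c] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best == 0) {
    for (int k = 0; k < 7; ++k) out7[k] = 0;
    return;
  }
  int i = bi, j = bj, nid = 0, cols = 0;
  int qe = bi, se = bj;
  int state = 0;  // 0 = H, 1 = F (up), 2 = E (left)
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * (m + 1) + j;
    size_t up = c - (m + 1), left = c - 1, dg = up - 1;
    if (state == 0) {
      if (H[c] == 0) break;
      int s = sm[(size_t)a[i - 1] * K + b[j - 1]];
      if (H[c] == H[dg] + s) {         // diagonal preferred
        if (a[i - 1] == b[j - 1]) ++nid;
        ++cols; --i; --j;
      } else if (H[c] == F[c]) {       // then gap in subject (up)
        state = 1;
      } else {                          // then gap in query (left)
        state = 2;
      }
    } else if (state == 1) {
      ++cols;
      if (F[c] == H[up] - go) { --i; state = 0; }
      else { --i; state = 1; }
    } else {
      ++cols;
      if (E[c] == H[left] - go) { --j; state = 0; }
      else { --j; state = 2; }
    }
  }
  out7[0] = best; out7[1] = nid; out7[2] = cols;
  out7[3] = i + 1; out7[4] = qe; out7[5] = j + 1; out7[6] = se;
}

// Full Smith-Waterman with traceback: alignment statistics for one pair.
// Returns score, n_ident, align_cols, q_start, q_end, s_start, s_end
// (1-based, inclusive; 0s if the optimal local score is 0).
// [[Rcpp::export]]
IntegerVector cpp_sw_stats(IntegerVector a, IntegerVector b, IntegerMatrix sm,
                           int gap_open, int gap_ext) {
  int K = sm.nrow();
  std::vector<int> smv((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) smv[(size_t)i * K + j] = sm(i, j);
  std::vector<uint8_t> av(a.size()), bv(b.size());
  for (int i = 0; i < a.size(); ++i) av[i] = (uint8_t)a[i];
  for (int i = 0; i < b.size(); ++i) bv[i] = (uint8_t)b[i];
  SWBuffers buf;
  IntegerVector out(7);
  sw_stats_core(av.data(), av.size(), bv.data(), bv.size(), smv.data(), K,
                gap_open, gap_ext, buf, INTEGER(out));
  return out;
}

// Batch Smith-Waterman traceback statistics over pairs of indices
// (1-based) into seqs. Returns one row per pair, columns as cpp_sw_stats.
// [[Rcpp::export]]
IntegerMatrix cpp_sw_stats_batch(List seqs, IntegerVector pa,
                                 IntegerVector pb, IntegerMatrix sm,
                                 int gap_open, int gap_ext) {
  int K = sm.nrow();
  std::vector<int> smv((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) smv[(size_t)i * K + j] = sm(i, j);
  std::vector<std::vector<uint8_t> > S = decode_seqs(seqs);
  int np = pa.size();
  IntegerMatrix out(np, 7);
  SWBuffers buf;
  int row[7];
  for (int k = 0; k < np; ++k) {
    if (k % 512 == 0) Rcpp::checkUserInterrupt();
    const std::vector<uint8_t>& a = S[pa[k] - 1];
    const std::vector<uint8_t>& b = S[pb[k] - 1];
    sw_stats_core(a.data(), a.size(), b.data(), b.size(), smv.data(), K,
                  gap_open, gap_ext, buf, row);
    for (int c = 0; c < 7; ++c) out(k, c) = row[c];
  }
  return out;
}

// Global (Needleman-Wunsch) alignment with free terminal gaps, needle-style.
// Gap of length L costs gap_open + L*gap_ext (doubles; needle uses 10/0.5).
// Terminal gaps are unpenalised but counted in the alignment length.
// Returns c(identity_pct, n_ident, align_cols, score).
struct NWBuffers {
  std::vector<double> M, X, Y, B;
};

static void nw_stats_core(const uint8_t* av, int n, const uint8_t* bv, int m,
                          const int* sm, int K, double gap_open,
                          double gap_ext, NWBuffers& buf, double* out4) {
  const double go = gap_open + gap_ext, ge = gap_ext;
  const double NEG = -1e30;
  size_t W = m + 1;
  size_t sz = (size_t)(n + 1) * W;
  buf.M.assign(sz, NEG); buf.X.assign(sz, NEG); buf.Y.assign(sz, NEG);
  buf.B.assign(sz, 0.0);
  double* M = buf.M.data(); double* X = buf.X.data();
  double* Y = buf.Y.data(); double* B = buf.B.data();
  // B(i,0) = B(0,j) = 0: free leading gaps.
  for (int i = 1; i <= n; ++i) {
    const int* srow = sm + (size_t)av[i - 1] * K;
    for (int j = 1; j <= m; ++j) {
      size_t c = (size_t)i * W + j;
      size_t up = c - W, left = c - 1, dg = up - 1;
      M[c] = B[dg] + srow[bv[j - 1]];
      X[c] = std::max(X[left] - ge, std::max(M[left], Y[left]) - go);
      Y[c] = std::max(Y[up] - ge, std::max(M[up], X[up]) - go);
      B[c] = std::max(M[c], std::max(X[c], Y[c]));
    }
  }
  // free trailing gaps: best over last row and last column
  double best = NEG;
  int bi = n, bj = m;
  for (int j = m; j >= 0; --j) {
    double v = (j == 0 && n == 0) ? 0.0 : B[(size_t)n * W + j];
    if (v > best) { best = v; bi = n; bj = j; }
  }
  for (int i = n; i >= 0; --i) {
    double v = B[(size_t)i * W + m];
    if (v > best) { best = v; bi = i; bj = m; }
  }
  long cols = (n - bi) + (m - bj);  // trailing overhang
  long nid = 0;
  int i = bi, j = bj;
  int state = -1;  // -1 = pick best, 0 = M, 1 = Y (up), 2 = X (left)
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * W + j;
    size_t up = c - W, left = c - 1;
    if (state == -1) {
      if (B[c] == M[c]) state = 0;
      else if (B[c] == Y[c]) state = 1;
      else state = 2;
    }
    if (state == 0) {
      if (av[i - 1] == bv[j - 1]) ++nid;
      ++cols; --i; --j;
      state = -1;
    } else if (state == 1) {
      ++cols;
      double v = Y[c];
      --i;
      if (v == Y[up] - ge) state = 1;
      else if (v == M[up] - go) state = 0;
      else state = 2;
      if (i == 0 || j == 0) state = -1;
    } else {
      ++cols;
      double v = X[c];
      --j;
      if (v == X[left] - ge) state = 2;
      else if (v == M[left] - go) state = 0;
      else state = 1;
      if (i == 0 || j == 0) state = -1;
    }
  }
  cols += i + j;  // leading overhang
  double pct = cols > 0 ? 100.0 * (double)nid / (double)cols : 0.0;
  out4[0] = pct; out4[1] = (double)nid; out4[2] = (double)cols;
  out4[3] = best;
}

// [[Rcpp::export]]
NumericVector cpp_nw_stats(IntegerVector a, IntegerVector b, IntegerMatrix sm,
                           double gap_open, double gap_ext) {
  int K = sm.nrow();
  std::vector<int> smv((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) smv[(size_t)i * K + j] = sm(i, j);
  std::vector<uint8_t> av(a.size()), bv(b.size());
  for (int i = 0; i < a.size(); ++i) av[i] = (uint8_t)a[i];
  for (int i = 0; i < b.size(); ++i) bv[i] = (uint8_t)b[i];
  NWBuffers buf;
  NumericVector out(4);
  nw_stats_core(av.data(), av.size(), bv.data(), bv.size(), smv.data(), K,
                gap_open, gap_ext, buf, REAL(out));
  return out;
}

// Batch global identity over pairs (1-based indices into seqs).
// [[Rcpp::export]]
NumericMatrix cpp_nw_identity_batch(List seqs, IntegerVector pa,
                                    IntegerVector pb, IntegerMatrix sm,
                                    double gap_open, double gap_ext) {
  int K = sm.nrow();
  std::vector<int> smv((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) smv[(size_t)i * K + j] = sm(i, j);
  std::vector<std::vector<uint8_t> > S = decode_seqs(seqs);
  int np = pa.size();
  NumericMatrix out(np, 4);
  colnames(out) = CharacterVector::create("identity", "n_ident",
                                          "align_cols", "score");
  NWBuffers buf;
  double row[4];
  for (int k = 0; k < np; ++k) {
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
    const std::vector<uint8_t>& a = S[pa[k] - 1];
    const std::vector<uint8_t>& b = S[pb[k] - 1];
    nw_stats_core(a.data(), a.size(), b.data(), b.size(), smv.data(), K,
                  gap_open, gap_ext, buf, row);
    for (int c = 0; c < 4; ++c) out(k, c) = row[c];
  }
  return out;
}
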