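// Dynamic-programming kernels for the similarity backend.
//
// One gap convention everywhere: a gap of length L costs gap_open + L * gap_ext
// (both positive costs). Substitution matrices arrive as integer matrices with
// a matching alphabet string; characters outside the alphabet score as 'X'.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int NEG = -(1 << 28);

struct SubLookup {
  int tab[256];
  std::vector<int> mat; // flat A x A
  int A;
  SubLookup(const IntegerMatrix& sub, const std::string& alphabet) {
    A = (int)alphabet.size();
    if (sub.nrow() != A || sub.ncol() != A)
      stop("substitution matrix does not match alphabet");
    int xi = 0;
    for (int i = 0; i < A; ++i) if (alphabet[i] == 'X') xi = i;
    for (int i = 0; i < 256; ++i) tab[i] = xi;
    for (int i = 0; i < A; ++i) tab[(unsigned char)alphabet[i]] = i;
    mat.resize(A * A);
    for (int i = 0; i < A; ++i)
      for (int j = 0; j < A; ++j)
        mat[i * A + j] = sub(i, j);
  }
  inline int score(unsigned char a, unsigned char b) const {
    return mat[tab[a] * A + tab[b]];
  }
  inline int idx(unsigned char a) const { return tab[a]; }
};

// ---------------------------------------------------------------------------
// Global (Needleman-Wunsch) affine alignment; propagates match and aligned-pair
// counts along the optimal path so percent identity needs no traceback.
// Tie-break: M > X (gap in b) > Y (gap in a), making results deterministic.
// ---------------------------------------------------------------------------

// Packed DP word: score in the high bits (signed), then match count, then a
// column/pair count in the low 20 bits. max() on packed words orders by
// score, then matches, then the low counter -- one deterministic tie-break,
// and count propagation costs no extra branches.
static const int PACK_CNT = 20;
static const int64_t PACK_ONE_SCORE = (int64_t)1 << (2 * PACK_CNT);
static const int64_t PACK_ONE_MATCH = (int64_t)1 << PACK_CNT;
static const int64_t PACK_MASK = ((int64_t)1 << PACK_CNT) - 1;
// very negative sentinel with headroom: subtracting gap costs must not wrap
static const int64_t PACK_NEG = -((int64_t)1 << 60);

static inline int64_t pack_score(int64_t p) { return p >> (2 * PACK_CNT); }
static inline int pack_matches(int64_t p) {
  return (int)((p >> PACK_CNT) & PACK_MASK);
}
static inline int pack_count(int64_t p) { return (int)(p & PACK_MASK); }

struct GlobalResult { int score; int matches; int pairs; };

// Global affine alignment (Gotoh); the packed word carries (score, matches,
// aligned pairs), so percent identity needs no traceback. Gap steps add no
// pair; match steps add one.
static GlobalResult global_align_core(const std::string& a, const std::string& b,
                                      const SubLookup& S, int go, int ge) {
  int n = (int)a.size(), m = (int)b.size();
  const int64_t OPEN = (int64_t)(go + ge) * PACK_ONE_SCORE;
  const int64_t EXT = (int64_t)ge * PACK_ONE_SCORE;
  std::vector<int64_t> H(m + 1), E(m + 1);
  H[0] = 0;
  E[0] = PACK_NEG;
  for (int j = 1; j <= m; ++j) {
    H[j] = -(int64_t)(go + ge * j) * PACK_ONE_SCORE;
    E[j] = PACK_NEG;
  }
  const int A = S.A;
  std::vector<int> bidx(m);
  for (int j = 0; j < m; ++j) bidx[j] = S.idx(b[j]);
  for (int i = 1; i <= n; ++i) {
    int64_t diag = H[0];
    H[0] = -(int64_t)(go + ge * i) * PACK_ONE_SCORE;
    int64_t F = PACK_NEG;
    const int* srow = &S.mat[(size_t)S.idx(a[i - 1]) * A];
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int64_t e = std::max(H[j] - OPEN, E[j] - EXT);   // gap in b (consumes a_i)
      int64_t f = std::max(H[j - 1] - OPEN, F - EXT);  // gap in a (consumes b_j)
      int64_t sc = (int64_t)srow[bidx[j - 1]] * PACK_ONE_SCORE +
                   ((ai == b[j - 1]) ? PACK_ONE_MATCH : 0) + 1;
      int64_t h = std::max(diag + sc, std::max(e, f));
      diag = H[j];
      H[j] = h; E[j] = e; F = f;
    }
  }
  GlobalResult r;
  int64_t fin = H[m];
  r.score = (int)pack_score(fin);
  r.matches = pack_matches(fin);
  r.pairs = pack_count(fin);
  return r;
}


// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, IntegerMatrix sub,
                      std::string alphabet, int gap_open, int gap_ext) {
  if (a.empty() || b.empty()) stop("empty sequence");
  SubLookup S(sub, alphabet);
  GlobalResult r = global_align_core(a, b, S, gap_open, gap_ext);
  int cols = (int)a.size() + (int)b.size() - r.pairs;
  return List::create(_["score"] = r.score, _["matches"] = r.matches,
                      _["pairs"] = r.pairs, _["columns"] = cols,
                      _["identity"] = (double)r.matches / (double)cols);
}

// ---------------------------------------------------------------------------
// Greedy incremental clustering with conservative prefilters.
// ---------------------------------------------------------------------------

// bit-parallel LCS length (Crochemore et al. formulation), upper bound on the
// number of identical aligned positions in any pairwise alignment
static int lcs_upper(const std::vector<uint64_t>& pm, int nw, int m,
                     const std::string& b, const SubLookup& S, int A) {
  std::vector<uint64_t> V(nw, ~0ULL);
  uint64_t topmask = (m % 64) ? ((1ULL << (m % 64)) - 1ULL) : ~0ULL;
  for (size_t j = 0; j < b.size(); ++j) {
    const uint64_t* Mc = &pm[(size_t)S.idx(b[j]) * nw];
    uint64_t carry = 0;
    for (int w = 0; w < nw; ++w) {
      uint64_t u = V[w] & Mc[w];
      uint64_t sum = V[w] + u + carry;
      carry = (sum < V[w] || (carry && sum == V[w])) ? 1 : 0;
      V[w] = sum | (V[w] & ~Mc[w]);
    }
    V[nw - 1] &= topmask;
  }
  int zeros = 0;
  for (int w = 0; w < nw; ++w) {
    uint64_t x = (w == nw - 1) ? (V[w] | ~topmask) : V[w];
    zeros += 64 - __builtin_popcountll(x);
  }
  return zeros;
}

static void kmer_codes(const std::string& s, int k, int A, const SubLookup& S,
                       std::vector<uint32_t>& out) {
  out.clear();
  int n = (int)s.size();
  if (n < k) return;
  for (int i = 0; i + k <= n; ++i) {
    uint32_t c = 0;
    for (int t = 0; t < k; ++t) c = c * (uint32_t)A + (uint32_t)S.idx(s[i + t]);
    out.push_back(c);
  }
  std::sort(out.begin(), out.end());
}

static int sorted_common(const std::vector<uint32_t>& x, const std::vector<uint32_t>& y) {
  size_t i = 0, j = 0; int c = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] < y[j]) ++i;
    else if (y[j] < x[i]) ++j;
    else { ++c; ++i; ++j; }
  }
  return c;
}

// seqs must already be in the caller's canonical order (length desc, id asc).
// Returns 1-based cluster assignment; cluster k's representative is the first
// sequence assigned k.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold,
                                 IntegerMatrix sub, std::string alphabet,
                                 int gap_open, int gap_ext, bool use_filters = true) {
  int n = seqs.size();
  SubLookup S(sub, alphabet);
  int A = S.A;
  std::vector<std::string> sq(n);
  for (int i = 0; i < n; ++i) sq[i] = as<std::string>(seqs[i]);

  // k-mer filter parameters: need coeff = t - (1-t)(k-1) > 0, i.e. k < 1/(1-t)
  int k = 1;
  if (threshold < 1.0) {
    while (k < 5 && (double)(k + 1) < 1.0 / (1.0 - threshold) - 1e-9) ++k;
  } else k = 5;
  double coeff = threshold - (1.0 - threshold) * (k - 1);

  std::vector<std::vector<uint32_t>> codes(n);
  if (use_filters)
    for (int i = 0; i < n; ++i) kmer_codes(sq[i], k, A, S, codes[i]);

  IntegerVector assign(n, 0);
  int nclust = 0;
  std::vector<uint64_t> pm; // letter masks of current representative
  const double eps = 1e-9;

  for (int i = 0; i < n; ++i) {
    if (assign[i] != 0) continue;
    ++nclust;
    assign[i] = nclust;
    int m = (int)sq[i].size();
    int nw = (m + 63) / 64;
    if (use_filters) {
      pm.assign((size_t)A * nw, 0ULL);
      for (int p = 0; p < m; ++p)
        pm[(size_t)S.idx(sq[i][p]) * nw + p / 64] |= (1ULL << (p % 64));
    }
    for (int j = i + 1; j < n; ++j) {
      if (assign[j] != 0) continue;
      int lj = (int)sq[j].size();
      int Lmax = std::max(m, lj), Lmin = std::min(m, lj);
      if ((double)Lmin / (double)Lmax < threshold - eps) continue;
      if (use_filters) {
        if (coeff > 0) {
          double bound = Lmax * coeff - (k - 1);
          if (bound > 0 && sorted_common(codes[i], codes[j]) < bound - eps) continue;
        }
        int ub = lcs_upper(pm, nw, m, sq[j], S, A);
        if ((double)ub / (double)Lmax < threshold - eps) continue;
      }
      GlobalResult r = global_align_core(sq[i], sq[j], S, gap_open, gap_ext);
      int cols = m + lj - r.pairs;
      if ((double)r.matches / (double)cols >= threshold - eps)
        assign[j] = nclust;
    }
  }
  return assign;
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment
// ---------------------------------------------------------------------------

// Single pair with traceback: trace[i] gives the b-position aligned to a_i
// (1-based; 0 = not aligned).
// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b, IntegerMatrix sub,
                     std::string alphabet, int gap_open, int gap_ext) {
  if (a.empty() || b.empty()) stop("empty sequence");
  SubLookup S(sub, alphabet);
  int n = (int)a.size(), m = (int)b.size();
  std::vector<int> M((n + 1) * (m + 1), 0), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  // pointers: 0 stop, 1 fromM, 2 fromX, 3 fromY
  std::vector<uint8_t> tM((n + 1) * (m + 1), 0), tX((n + 1) * (m + 1), 0),
      tY((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sc = S.score(a[i - 1], b[j - 1]);
      int dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)], dY = Y[at(i - 1, j - 1)];
      int pre = 0; uint8_t ptr = 0;
      if (dM > pre) { pre = dM; ptr = 1; }
      if (dX > pre) { pre = dX; ptr = 2; }
      if (dY > pre) { pre = dY; ptr = 3; }
      int v = pre + sc;
      if (v <= 0) { v = (v < 0) ? 0 : v; ptr = 0; }
      M[at(i, j)] = v; tM[at(i, j)] = ptr;
      int x1 = M[at(i - 1, j)] - (gap_open + gap_ext);
      int x2 = X[at(i - 1, j)] - gap_ext;
      int x3 = Y[at(i - 1, j)] - (gap_open + gap_ext);
      if (x1 >= x2 && x1 >= x3) { X[at(i, j)] = x1; tX[at(i, j)] = 1; }
      else if (x2 >= x3)        { X[at(i, j)] = x2; tX[at(i, j)] = 2; }
      else                      { X[at(i, j)] = x3; tX[at(i, j)] = 3; }
      int y1 = M[at(i, j - 1)] - (gap_open + gap_ext);
      int y2 = X[at(i, j - 1)] - (gap_open + gap_ext);
      int y3 = Y[at(i, j - 1)] - gap_ext;
      if (y1 >= y2 && y1 >= y3) { Y[at(i, j)] = y1; tY[at(i, j)] = 1; }
      else if (y2 >= y3)        { Y[at(i, j)] = y2; tY[at(i, j)] = 2; }
      else                      { Y[at(i, j)] = y3; tY[at(i, j)] = 3; }
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }
  IntegerVector trace(n, 0);
  int qs = 0, qe = 0, ts = 0, te = 0, matches = 0, cols = 0;
  if (best > 0) {
    int i = bi, j = bj, state = 1; // start in M at the max cell
    qe = bi; te = bj;
    while (state != 0 && i > 0 && j > 0) {
      if (state == 1) {
        trace[i - 1] = j;
        if (a[i - 1] == b[j - 1]) ++matches;
        ++cols; qs = i; ts = j;
        uint8_t p = tM[at(i, j)];
        --i; --j; state = p;
      } else if (state == 2) {
        uint8_t p = tX[at(i, j)]; ++cols; --i; state = p;
      } else {
        uint8_t p = tY[at(i, j)]; ++cols; --j; state = p;
      }
    }
  }
  return List::create(_["score"] = best, _["qstart"] = qs, _["qend"] = qe,
                      _["tstart"] = ts, _["tend"] = te, _["matches"] = matches,
                      _["columns"] = cols, _["trace"] = trace);
}

// All-vs-all local alignment scores (Gotoh, packed score/match/column word,
// no traceback). Returns parallel vectors over pairs i < j.
// [[Rcpp::export]]
List cpp_local_batch(CharacterVector seqs, IntegerMatrix sub, std::string alphabet,
                     int gap_open, int gap_ext) {
  int n = seqs.size();
  SubLookup S(sub, alphabet);
  const int A = S.A;
  std::vector<std::string> sq(n);
  for (int i = 0; i < n; ++i) sq[i] = as<std::string>(seqs[i]);
  std::vector<std::vector<int>> idxs(n);
  for (int i = 0; i < n; ++i) {
    idxs[i].resize(sq[i].size());
    for (size_t p = 0; p < sq[i].size(); ++p) idxs[i][p] = S.idx(sq[i][p]);
  }
  const int64_t OPEN = (int64_t)(gap_open + gap_ext) * PACK_ONE_SCORE;
  const int64_t EXT = (int64_t)gap_ext * PACK_ONE_SCORE;
  int np = n * (n - 1) / 2;
  IntegerVector pi(np), pj(np), score(np), matches(np), cols(np);
  std::vector<int64_t> H, E;
  int idx = 0;
  for (int i = 0; i < n; ++i) {
    const std::string& a = sq[i];
    int la = (int)a.size();
    for (int j = i + 1; j < n; ++j) {
      const std::string& b = sq[j];
      const int* bidx = idxs[j].data();
      int lb = (int)b.size();
      H.assign(lb + 1, 0);
      E.assign(lb + 1, PACK_NEG);
      int64_t best = 0;
      for (int r = 1; r <= la; ++r) {
        int64_t diag = 0;
        int64_t F = PACK_NEG;
        const int* srow = &S.mat[(size_t)idxs[i][r - 1] * A];
        const char ar = a[r - 1];
        for (int c = 1; c <= lb; ++c) {
          int64_t e = std::max(H[c] - OPEN, E[c] - EXT);
          int64_t f = std::max(H[c - 1] - OPEN, F - EXT);
          int64_t sc = (int64_t)srow[bidx[c - 1]] * PACK_ONE_SCORE +
                       ((ar == b[c - 1]) ? PACK_ONE_MATCH : 0) + 1;
          int64_t h = diag + sc;
          if (h < 0) h = 0;           // local restart
          h = std::max(h, std::max(e, f));
          if (h > best) best = h;
          diag = H[c];
          H[c] = h; E[c] = e; F = f;
        }
      }
      pi[idx] = i + 1; pj[idx] = j + 1;
      score[idx] = (int)pack_score(best);
      matches[idx] = pack_matches(best);
      cols[idx] = pack_count(best);
      ++idx;
    }
  }
  return List::create(_["i"] = pi, _["j"] = pj, _["score"] = score,
                      _["matches"] = matches, _["columns"] = cols);
}

// ---------------------------------------------------------------------------
// Glocal profile search: global in the profile (deleted columns are penalized),
// local in the target (free flanks). prof is W x A, columns in alphabet order.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_profile_search(IntegerMatrix prof, std::string seq, std::string alphabet,
                        int gap_open, int gap_ext) {
  if (seq.empty()) stop("empty sequence");
  int W = prof.nrow(), A = (int)alphabet.size();
  if (prof.ncol() != A) stop("profile does not match alphabet");
  int tab[256];
  int xi = 0;
  for (int i = 0; i < A; ++i) if (alphabet[i] == 'X') xi = i;
  for (int i = 0; i < 256; ++i) tab[i] = xi;
  for (int i = 0; i < A; ++i) tab[(unsigned char)alphabet[i]] = i;
  int L = (int)seq.size();
  // states over (i = profile column 1..W, j = target pos 0..L)
  std::vector<int> M((W + 1) * (L + 1), NEG), D((W + 1) * (L + 1), NEG),
      I((W + 1) * (L + 1), NEG);
  std::vector<uint8_t> tM((W + 1) * (L + 1), 0), tD((W + 1) * (L + 1), 0),
      tI((W + 1) * (L + 1), 0);
  auto at = [L](int i, int j) { return i * (L + 1) + j; };
  // virtual begin state: value 0 at row 0, any j (free target prefix)
  // pointer codes: 0 begin, 1 M, 2 D, 3 I
  for (int i = 1; i <= W; ++i) {
    for (int j = 0; j <= L; ++j) {
      // D: column i deleted
      int cand, ptr;
      cand = (i == 1) ? -(gap_open + gap_ext) : NEG; ptr = 0;
      if (M[at(i - 1, j)] - (gap_open + gap_ext) > cand) { cand = M[at(i - 1, j)] - (gap_open + gap_ext); ptr = 1; }
      if (D[at(i - 1, j)] - gap_ext > cand) { cand = D[at(i - 1, j)] - gap_ext; ptr = 2; }
      if (I[at(i - 1, j)] - (gap_open + gap_ext) > cand) { cand = I[at(i - 1, j)] - (gap_open + gap_ext); ptr = 3; }
      D[at(i, j)] = cand; tD[at(i, j)] = ptr;
      if (j >= 1) {
        int sc = prof(i - 1, tab[(unsigned char)seq[j - 1]]);
        cand = (i == 1) ? 0 : NEG; ptr = 0; // free start before column 1
        if (M[at(i - 1, j - 1)] > cand) { cand = M[at(i - 1, j - 1)]; ptr = 1; }
        if (D[at(i - 1, j - 1)] > cand) { cand = D[at(i - 1, j - 1)]; ptr = 2; }
        if (I[at(i - 1, j - 1)] > cand) { cand = I[at(i - 1, j - 1)]; ptr = 3; }
        M[at(i, j)] = cand + sc; tM[at(i, j)] = ptr;
        // I: target residue j inserted between columns i and i+1
        int i1 = M[at(i, j - 1)] - (gap_open + gap_ext);
        int i2 = I[at(i, j - 1)] - gap_ext;
        int i3 = D[at(i, j - 1)] - (gap_open + gap_ext);
        if (i1 >= i2 && i1 >= i3) { I[at(i, j)] = i1; tI[at(i, j)] = 1; }
        else if (i2 >= i3)        { I[at(i, j)] = i2; tI[at(i, j)] = 2; }
        else                      { I[at(i, j)] = i3; tI[at(i, j)] = 3; }
      }
    }
  }
  int best = NEG, bj = 0, bstate = 1;
  for (int j = 0; j <= L; ++j) {
    if (M[at(W, j)] > best) { best = M[at(W, j)]; bj = j; bstate = 1; }
    if (D[at(W, j)] > best) { best = D[at(W, j)]; bj = j; bstate = 2; }
  }
  IntegerVector trace(W, 0);
  int i = W, j = bj, state = bstate;
  int ts = 0, te = 0;
  while (i > 0) {
    if (state == 1) {
      trace[i - 1] = j;
      if (te == 0) te = j;
      ts = j;
      uint8_t p = tM[at(i, j)];
      --i; --j; state = p;
      if (state == 0) break;
    } else if (state == 2) {
      uint8_t p = tD[at(i, j)];
      --i; state = p;
      if (state == 0) break;
    } else {
      uint8_t p = tI[at(i, j)];
      --j; state = p;
    }
  }
  return List::create(_["score"] = best, _["tstart"] = ts, _["tend"] = te,
                      _["trace"] = trace);
}

// ---------------------------------------------------------------------------
// CRC-32 (IEEE) for the built-in zip writer
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int kbit = 0; kbit < 8; ++kbit)
        c = (c & 1) ? (0xEDB88320U ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFU;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFU] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFU);
}
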