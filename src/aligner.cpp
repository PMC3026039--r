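#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>

using namespace Rcpp;

// Alignment engine used by the genome scanner:
//  - exact k-mer seed index (2-bit encoded, k-mers containing non-ACGT are
//    never indexed, mirroring how unsequenced gap tracks are masked)
//  - gapped extension with x-drop termination, affine gaps
//  - banded end-to-end alignment for copy-vs-consensus comparison
// Scoring convention: a gap of length L costs gap_open + L * gap_ext
// (first gap character pays both terms). Columns containing N score 0.

static const int NEG_INF = INT_MIN / 4;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline bool is_n(char c) { return base_code(c) < 0; }

static inline int col_score(char a, char b, int match, int mismatch) {
  int ca = base_code(a), cb = base_code(b);
  if (ca < 0 || cb < 0) return 0;   // N columns are neutral
  return (ca == cb) ? match : mismatch;
}

struct KmerIndex {
  int k;
  int n;
  std::unordered_map<uint32_t, std::vector<int> > map; // 0-based start positions
};

// [[Rcpp::export]]
SEXP cpp_build_index(std::string seq, int k) {
  if (k < 8 || k > 15) stop("word size k must be in [8, 15]");
  KmerIndex *idx = new KmerIndex();
  idx->k = k;
  idx->n = (int)seq.size();
  uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  uint32_t code = 0;
  int run = 0; // valid bases accumulated
  for (int i = 0; i < (int)seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run >= k) idx->map[code].push_back(i - k + 1);
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP index, std::string kmer) {
  XPtr<KmerIndex> idx(index);
  if ((int)kmer.size() != idx->k) stop("k-mer length does not match index word size");
  uint32_t code = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int c = base_code(kmer[i]);
    if (c < 0) return IntegerVector(0); // k-mers with N are not indexed
    code = (code << 2) | (uint32_t)c;
  }
  std::unordered_map<uint32_t, std::vector<int> >::const_iterator it = idx->map.find(code);
  if (it == idx->map.end()) return IntegerVector(0);
  IntegerVector out(it->second.size());
  for (size_t i = 0; i < it->second.size(); ++i) out[i] = it->second[i] + 1; // 1-based
  return out;
}

// All exact k-mer matches between an indexed genome and a query.
// Returns a 2-column matrix (genome pos, query pos), 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_hits(SEXP index, std::string query) {
  XPtr<KmerIndex> idx(index);
  int k = idx->k;
  uint32_t mask = (1u << (2 * k)) - 1u;
  std::vector<int> gp, qp;
  uint32_t code = 0;
  int run = 0;
  for (int i = 0; i < (int)query.size(); ++i) {
    int c = base_code(query[i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run >= k) {
      std::unordered_map<uint32_t, std::vector<int> >::const_iterator it = idx->map.find(code);
      if (it != idx->map.end()) {
        int q = i - k + 1;
        for (size_t j = 0; j < it->second.size(); ++j) {
          gp.push_back(it->second[j] + 1);
          qp.push_back(q + 1);
        }
      }
    }
  }
  IntegerMatrix out(gp.size(), 2);
  for (size_t i = 0; i < gp.size(); ++i) { out(i, 0) = gp[i]; out(i, 1) = qp[i]; }
  return out;
}

// ---- gapped x-drop extension ------------------------------------------------

struct ExtResult {
  int score;     // best extension score (0 when no profitable extension)
  int ci, cj;    // characters of U (genome) and V (query) consumed
  std::string ua, va; // aligned strings of the extension (may be empty)
};

// One-direction extension of U vs V (both already oriented so that the
// extension proceeds left-to-right over the given strings).
static ExtResult extend_one(const std::string &U, const std::string &V,
                            int match, int mismatch, int gap_open, int gap_ext,
                            int xdrop) {
  const int nu = (int)U.size(), nv = (int)V.size();
  ExtResult res; res.score = 0; res.ci = 0; res.cj = 0;
  if (nu == 0 || nv == 0) return res;

  // per-row storage of packed traceback bytes:
  // bits 0-1: M-from (0=M,1=X,2=Y), bits 2-3: X-from, bits 4-5: Y-from
  std::vector< std::vector<uint8_t> > tb;
  std::vector<int> row_lo;

  std::vector<int> Mprev, Xprev, Yprev, Mcur, Xcur, Ycur;
  int lo = 0, hi = 0; // inclusive column range of row 0 (columns index j over V)
  // Row 0: i = 0 (no U consumed); Y state runs along j.
  int best = 0, bi = 0, bj = 0, bstate = 0;
  {
    int width = nv + 1;
    Mprev.assign(width, NEG_INF); Xprev.assign(width, NEG_INF); Yprev.assign(width, NEG_INF);
    Mprev[0] = 0;
    std::vector<uint8_t> trow;
    trow.push_back(0);
    int j = 1;
    for (; j <= nv; ++j) {
      int y = (j == 1) ? (gap_open + gap_ext) : (Yprev[j - 1] + gap_ext);
      if (y < -xdrop) break;
      Yprev[j] = y;
      trow.push_back((uint8_t)((j == 1 ? 0 : 2) << 4));
    }
    hi = j - 1;
    tb.push_back(trow);
    row_lo.push_back(0);
  }

  for (int i = 1; i <= nu; ++i) {
    int nlo = lo, nhi = std::min(hi + 1, nv);
    if (nlo > nhi) break;
    int width = nhi - nlo + 1;
    Mcur.assign(width, NEG_INF); Xcur.assign(width, NEG_INF); Ycur.assign(width, NEG_INF);
    std::vector<uint8_t> trow(width, 0);
    int thr = best - xdrop;
    int first_viable = -1, last_viable = -1;
    for (int j = nlo; j <= nhi; ++j) {
      int idx = j - nlo;
      // M from (i-1, j-1)
      int m = NEG_INF; uint8_t mf = 0;
      if (j >= 1 && j - 1 >= lo && j - 1 <= hi) {
        int pidx = j - 1 - lo;
        int v = Mprev[pidx]; mf = 0;
        if (Xprev[pidx] > v) { v = Xprev[pidx]; mf = 1; }
        if (Yprev[pidx] > v) { v = Yprev[pidx]; mf = 2; }
        if (v > NEG_INF / 2) m = v + col_score(U[i - 1], V[j - 1], match, mismatch);
      }
      // X from (i-1, j): gap in V (consume U)
      int x = NEG_INF; uint8_t xf = 0;
      if (j >= lo && j <= hi) {
        int pidx = j - lo;
        int vm = (Mprev[pidx] > NEG_INF / 2) ? Mprev[pidx] + gap_open + gap_ext : NEG_INF;
        int vx = (Xprev[pidx] > NEG_INF / 2) ? Xprev[pidx] + gap_ext : NEG_INF;
        int vy = (Yprev[pidx] > NEG_INF / 2) ? Yprev[pidx] + gap_open + gap_ext : NEG_INF;
        x = vm; xf = 0;
        if (vx > x) { x = vx; xf = 1; }
        if (vy > x) { x = vy; xf = 2; }
      }
      // Y from (i, j-1): gap in U (consume V)
      int y = NEG_INF; uint8_t yf = 0;
      if (idx >= 1) {
        int vm = (Mcur[idx - 1] > NEG_INF / 2) ? Mcur[idx - 1] + gap_open + gap_ext : NEG_INF;
        int vx = (Xcur[idx - 1] > NEG_INF / 2) ? Xcur[idx - 1] + gap_open + gap_ext : NEG_INF;
        int vy = (Ycur[idx - 1] > NEG_INF / 2) ? Ycur[idx - 1] + gap_ext : NEG_INF;
        y = vm; yf = 0;
        if (vx > y) { y = vx; yf = 1; }
        if (vy > y) { y = vy; yf = 2; }
      }
      int cellmax = std::max(m, std::max(x, y));
      if (cellmax < thr) { // pruned
        Mcur[idx] = Xcur[idx] = Ycur[idx] = NEG_INF;
        continue;
      }
      Mcur[idx] = m; Xcur[idx] = x; Ycur[idx] = y;
      trow[idx] = (uint8_t)(mf | (xf << 2) | (yf << 4));
      if (first_viable < 0) first_viable = j;
      last_viable = j;
      if (cellmax > best) {
        best = cellmax; bi = i; bj = j;
        bstate = (m >= x && m >= y) ? 0 : (x >= y ? 1 : 2);
      }
    }
    if (first_viable < 0) break;
    tb.push_back(std::vector<uint8_t>(trow.begin() + (first_viable - nlo),
                                      trow.begin() + (last_viable - nlo + 1)));
    row_lo.push_back(first_viable);
    // shift score rows to the viable window
    if (first_viable != nlo || last_viable != nhi) {
      std::vector<int> M2(Mcur.begin() + (first_viable - nlo), Mcur.begin() + (last_viable - nlo + 1));
      std::vector<int> X2(Xcur.begin() + (first_viable - nlo), Xcur.begin() + (last_viable - nlo + 1));
      std::vector<int> Y2(Ycur.begin() + (first_viable - nlo), Ycur.begin() + (last_viable - nlo + 1));
      Mprev.swap(M2); Xprev.swap(X2); Yprev.swap(Y2);
    } else {
      Mprev.swap(Mcur); Xprev.swap(Xcur); Yprev.swap(Ycur);
    }
    lo = first_viable; hi = last_viable;
    if ((int)tb.size() != i + 1) break; // row failed to record (should not happen)
  }

  res.score = best; res.ci = bi; res.cj = bj;
  if (best <= 0) { res.score = 0; res.ci = 0; res.cj = 0; return res; }

  // traceback from (bi, bj, bstate)
  std::string ua, va;
  int i = bi, j = bj, st = bstate;
  while (i > 0 || j > 0) {
    if (i >= (int)tb.size()) break;
    int idx = j - row_lo[i];
    if (idx < 0 || idx >= (int)tb[i].size()) break;
    uint8_t t = tb[i][idx];
    if (st == 0) {
      ua.push_back(U[i - 1]); va.push_back(V[j - 1]);
      st = t & 3; --i; --j;
    } else if (st == 1) {
      ua.push_back(U[i - 1]); va.push_back('-');
      st = (t >> 2) & 3; --i;
    } else {
      ua.push_back('-'); va.push_back(V[j - 1]);
      st = (t >> 4) & 3; --j;
    }
  }
  std::reverse(ua.begin(), ua.end());
  std::reverse(va.begin(), va.end());
  res.ua = ua; res.va = va;
  return res;
}

// Gapped x-drop extension around an exact seed of length k at
// genome[gpos..gpos+k-1] == query[qpos..qpos+k-1] (1-based).
// [[Rcpp::export]]
List cpp_xdrop_extend(std::string genome, std::string query,
                      int gpos, int qpos, int k,
                      int match, int mismatch, int gap_open, int gap_ext,
                      int xdrop) {
  int g0 = gpos - 1, q0 = qpos - 1;
  if (g0 < 0 || q0 < 0 || g0 + k > (int)genome.size() || q0 + k > (int)query.size())
    stop("seed out of range");
  std::string seed_g = genome.substr(g0, k);

  // right extension
  std::string Ur = genome.substr(g0 + k);
  std::string Vr = query.substr(q0 + k);
  ExtResult right = extend_one(Ur, Vr, match, mismatch, gap_open, gap_ext, xdrop);

  // left extension on reversed prefixes
  std::string Ul = genome.substr(0, g0);
  std::string Vl = query.substr(0, q0);
  std::reverse(Ul.begin(), Ul.end());
  std::reverse(Vl.begin(), Vl.end());
  ExtResult left = extend_one(Ul, Vl, match, mismatch, gap_open, gap_ext, xdrop);
  std::reverse(left.ua.begin(), left.ua.end());
  std::reverse(left.va.begin(), left.va.end());

  int seed_score = 0;
  for (int i = 0; i < k; ++i)
    seed_score += col_score(genome[g0 + i], query[q0 + i], match, mismatch);

  std::string ga = left.ua + seed_g + right.ua;
  std::string qa = left.va + query.substr(q0, k) + right.va;

  return List::create(
    _["gstart"] = gpos - left.ci,
    _["gend"]   = gpos + k - 1 + right.ci,
    _["qstart"] = qpos - left.cj,
    _["qend"]   = qpos + k - 1 + right.cj,
    _["score"]  = left.score + seed_score + right.score,
    _["g_aln"]  = ga,
    _["q_aln"]  = qa);
}

// ---- banded end-to-end alignment -------------------------------------------

// Global alignment of A (copy) vs B (consensus span), restricted to diagonals
// d = j - i in [dlo, dhi] (automatically widened to include both corners).
// [[Rcpp::export]]
List cpp_banded_global(std::string A, std::string B, int dlo, int dhi,
                       int match, int mismatch, int gap_open, int gap_ext) {
  const int na = (int)A.size(), nb = (int)B.size();
  if (na == 0 || nb == 0) stop("empty sequence in banded alignment");
  dlo = std::min(dlo, std::min(0, nb - na));
  dhi = std::max(dhi, std::max(0, nb - na));
  const int bw = dhi - dlo + 1;

  std::vector<int> Mprev(bw, NEG_INF), Xprev(bw, NEG_INF), Yprev(bw, NEG_INF);
  std::vector<int> Mcur(bw), Xcur(bw), Ycur(bw);
  // traceback: one byte per (row, band offset)
  std::vector<uint8_t> tb((size_t)(na + 1) * bw, 0);

  // band offset of column j in row i: off = j - (i + dlo), valid in [0, bw)
  // row 0
  for (int off = 0; off < bw; ++off) {
    int j = off + dlo; // i = 0
    if (j < 0 || j > nb) continue;
    if (j == 0) { Mprev[off] = 0; }
    else if (off > 0 && (Mprev[off - 1] > NEG_INF / 2 || Yprev[off - 1] > NEG_INF / 2)) {
      int prev = std::max(Mprev[off - 1], Yprev[off - 1]);
      Yprev[off] = prev + ((j == 1) ? gap_open + gap_ext
                                    : ((Yprev[off - 1] > Mprev[off - 1]) ? gap_ext : gap_open + gap_ext));
      // simple: from M at j-1==0 it's an opening, else extension of Y
      tb[(size_t)0 * bw + off] = (uint8_t)(((j == 1) ? 0 : 2) << 4);
    }
  }
  // fix row 0 Y chain properly (all-gap prefix): Y[j] = go + j*ge
  for (int off = 0; off < bw; ++off) {
    int j = off + dlo;
    if (j >= 1 && j <= nb) {
      Yprev[off] = gap_open + j * gap_ext;
      tb[(size_t)0 * bw + off] = (uint8_t)(((j == 1) ? 0 : 2) << 4);
    }
  }

  for (int i = 1; i <= na; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
    std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
    for (int off = 0; off < bw; ++off) {
      int j = i + dlo + off;
      if (j < 0 || j > nb) continue;
      uint8_t trace = 0;
      // M from (i-1, j-1): in row i-1, offset = (j-1) - (i-1+dlo) = off
      int m = NEG_INF; uint8_t mf = 0;
      if (j >= 1) {
        int v = Mprev[off]; mf = 0;
        if (Xprev[off] > v) { v = Xprev[off]; mf = 1; }
        if (Yprev[off] > v) { v = Yprev[off]; mf = 2; }
        if (v > NEG_INF / 2) m = v + col_score(A[i - 1], B[j - 1], match, mismatch);
      }
      // X from (i-1, j): offset in row i-1 = j - (i-1+dlo) = off + 1
      int x = NEG_INF; uint8_t xf = 0;
      if (off + 1 < bw) {
        int vm = (Mprev[off + 1] > NEG_INF / 2) ? Mprev[off + 1] + gap_open + gap_ext : NEG_INF;
        int vx = (Xprev[off + 1] > NEG_INF / 2) ? Xprev[off + 1] + gap_ext : NEG_INF;
        int vy = (Yprev[off + 1] > NEG_INF / 2) ? Yprev[off + 1] + gap_open + gap_ext : NEG_INF;
        x = vm; xf = 0;
        if (vx > x) { x = vx; xf = 1; }
        if (vy > x) { x = vy; xf = 2; }
      }
      // Y from (i, j-1): offset in row i = off - 1
      int y = NEG_INF; uint8_t yf = 0;
      if (off >= 1 && j >= 1) {
        int vm = (Mcur[off - 1] > NEG_INF / 2) ? Mcur[off - 1] + gap_open + gap_ext : NEG_INF;
        int vx = (Xcur[off - 1] > NEG_INF / 2) ? Xcur[off - 1] + gap_open + gap_ext : NEG_INF;
        int vy = (Ycur[off - 1] > NEG_INF / 2) ? Ycur[off - 1] + gap_ext : NEG_INF;
        y = vm; yf = 0;
        if (vx > y) { y = vx; yf = 1; }
        if (vy > y) { y = vy; yf = 2; }
      }
      Mcur[off] = m; Xcur[off] = x; Ycur[off] = y;
      trace = (uint8_t)(mf | (xf << 2) | (yf << 4));
      tb[(size_t)i * bw + off] = trace;
    }
    Mprev.swap(Mcur); Xprev.swap(Xcur); Yprev.swap(Ycur);
  }

  int end_off = nb - (na + dlo);
  if (end_off < 0 || end_off >= bw) stop("band does not contain the end corner");
  int score = Mprev[end_off]; int st = 0;
  if (Xprev[end_off] > score) { score = Xprev[end_off]; st = 1; }
  if (Yprev[end_off] > score) { score = Yprev[end_off]; st = 2; }
  if (score < NEG_INF / 2) stop("banded alignment band too narrow");

  // traceback
  std::string aa, ba;
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    int off = j - (i + dlo);
    uint8_t t = tb[(size_t)i * bw + off];
    if (i == 0) { // forced Y along row 0
      aa.push_back('-'); ba.push_back(B[j - 1]); --j; continue;
    }
    if (j == 0) { aa.push_back(A[i - 1]); ba.push_back('-'); --i; continue; }
    if (st == 0) {
      aa.push_back(A[i - 1]); ba.push_back(B[j - 1]);
      st = t & 3; --i; --j;
    } else if (st == 1) {
      aa.push_back(A[i - 1]); ba.push_back('-');
      st = (t >> 2) & 3; --i;
    } else {
      aa.push_back('-'); ba.push_back(B[j - 1]);
      st = (t >> 4) & 3; --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ba.begin(), ba.end());

  return List::create(_["score"] = score, _["a_aln"] = aa, _["b_aln"] = ba);
}

// ---- full seed-and-extend scan of one (genome arm, query) pair -------------

// Seeds every exact k-mer match, skips seeds inside already-explored
// alignment rectangles, extends the rest, and returns alignments scoring at
// least min_score.
// [[Rcpp::export]]
List cpp_scan_pair(SEXP index, std::string genome, std::string query,
                   int match, int mismatch, int gap_open, int gap_ext,
                   int xdrop, int min_score) {
  XPtr<KmerIndex> idx(index);
  int k = idx->k;
  uint32_t mask = (1u << (2 * k)) - 1u;

  struct Rect { int g1, g2, q1, q2; };
  std::vector<Rect> rects;
  List out;

  uint32_t code = 0;
  int run = 0;
  for (int qi = 0; qi < (int)query.size(); ++qi) {
    int c = base_code(query[qi]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run < k) continue;
    std::unordered_map<uint32_t, std::vector<int> >::const_iterator it = idx->map.find(code);
    if (it == idx->map.end()) continue;
    int q = qi - k + 2; // 1-based query start of this k-mer
    for (size_t h = 0; h < it->second.size(); ++h) {
      int g = it->second[h] + 1; // 1-based genome start
      bool skip = false;
      for (size_t r = 0; r < rects.size(); ++r) {
        if (g >= rects[r].g1 && g <= rects[r].g2 &&
            q >= rects[r].q1 && q <= rects[r].q2) { skip = true; break; }
      }
      if (skip) continue;

      int g0 = g - 1, q0 = q - 1;
      std::string Ur = genome.substr(g0 + k);
      std::string Vr = query.substr(q0 + k);
      ExtResult right = extend_one(Ur, Vr, match, mismatch, gap_open, gap_ext, xdrop);
      std::string Ul = genome.substr(0, g0);
      std::string Vl = query.substr(0, q0);
      std::reverse(Ul.begin(), Ul.end());
      std::reverse(Vl.begin(), Vl.end());
      ExtResult left = extend_one(Ul, Vl, match, mismatch, gap_open, gap_ext, xdrop);
      std::reverse(left.ua.begin(), left.ua.end());
      std::reverse(left.va.begin(), left.va.end());

      int seed_score = 0;
      for (int i = 0; i < k; ++i)
        seed_score += col_score(genome[g0 + i], query[q0 + i], match, mismatch);
      int score = left.score + seed_score + right.score;

      Rect rc;
      rc.g1 = g - left.ci; rc.g2 = g + k - 1 + right.ci;
      rc.q1 = q - left.cj; rc.q2 = q + k - 1 + right.cj;
      rects.push_back(rc);

      if (score >= min_score) {
        std::string ga = left.ua + genome.substr(g0, k) + right.ua;
        std::string qa = left.va + query.substr(q0, k) + right.va;
        out.push_back(List::create(
          _["gstart"] = rc.g1, _["gend"] = rc.g2,
          _["qstart"] = rc.q1, _["qend"] = rc.q2,
          _["score"] = score, _["g_aln"] = ga, _["q_aln"] = qa));
      }
    }
  }
  return out;
}
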