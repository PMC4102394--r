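// Core combinatorial kernels: 2-bit l-mer encoding, Hamming counting via
// XOR, mismatch-profile computation (all-pairs and k-mer tree DFS),
// near-neighbour counting for smoothed l-mer tables, and SVM-weight
// scattering over the l-mer space.
//
// l-mers are packed big-endian, 2 bits per base (A=0, C=1, G=2, T=3), into a
// 64-bit word and exchanged with R as doubles (exact for l <= 26).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <array>
#include <algorithm>
#include <unordered_map>
#include <string>

using namespace Rcpp;
typedef uint64_t u64;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BASES[5] = "ACGT";

// Hamming distance between two packed l-mers: XOR, collapse each 2-bit
// group to its low bit, popcount.
static inline int hamming(u64 x, u64 y) {
  u64 z = x ^ y;
  z = (z | (z >> 1)) & 0x5555555555555555ULL;
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(z);
#else
  int n = 0; while (z) { z &= z - 1; ++n; } return n;
#endif
}

static inline int base_at(u64 key, int pos, int l) {
  return (int)((key >> (2 * (l - 1 - pos))) & 3ULL);
}

// ---------------------------------------------------------------- encoding

// Unique l-mer keys (sorted) with multiplicities for one sequence.
// Windows containing a non-ACGT character are skipped; if revcomp is set the
// reverse-complement strand's windows are appended before deduplication.
// [[Rcpp::export]]
List cpp_extract_lmers(std::string seq, int l, bool revcomp) {
  int n = (int)seq.size();
  if (l < 1 || l > 26) stop("word length l must be in 1..26");
  if (l > n) stop("l (%d) exceeds sequence length (%d)", l, n);
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  std::vector<u64> keys;
  keys.reserve(2 * (n - l + 1));
  u64 mask = (l == 26) ? ((1ULL << 52) - 1) : ((1ULL << (2 * l)) - 1);

  for (int strand = 0; strand < (revcomp ? 2 : 1); ++strand) {
    u64 cur = 0;
    int valid = 0; // run length of valid bases ending at i
    for (int i = 0; i < n; ++i) {
      int c = strand == 0 ? code[i] : (code[n - 1 - i] < 0 ? -1 : 3 - code[n - 1 - i]);
      if (c < 0) { valid = 0; cur = 0; continue; }
      cur = ((cur << 2) | (u64)c) & mask;
      if (++valid >= l) keys.push_back(cur);
    }
  }
  int ntot = (int)keys.size();
  std::sort(keys.begin(), keys.end());
  std::vector<double> uk;
  std::vector<int> cnt;
  for (size_t i = 0; i < keys.size();) {
    size_t j = i;
    while (j < keys.size() && keys[j] == keys[i]) ++j;
    uk.push_back((double)keys[i]);
    cnt.push_back((int)(j - i));
    i = j;
  }
  return List::create(_["keys"] = NumericVector(uk.begin(), uk.end()),
                      _["counts"] = IntegerVector(cnt.begin(), cnt.end()),
                      _["n"] = ntot);
}

// [[Rcpp::export]]
CharacterVector cpp_keys_to_strings(NumericVector keys, int l) {
  CharacterVector out(keys.size());
  std::string s(l, 'A');
  for (int i = 0; i < keys.size(); ++i) {
    u64 k = (u64)keys[i];
    for (int p = 0; p < l; ++p) s[p] = BASES[base_at(k, p, l)];
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_strings_to_keys(CharacterVector lmers, int l) {
  NumericVector out(lmers.size());
  for (int i = 0; i < lmers.size(); ++i) {
    std::string s = as<std::string>(lmers[i]);
    if ((int)s.size() != l) stop("l-mer %d has length %d, expected %d", i + 1, (int)s.size(), l);
    u64 k = 0;
    for (int p = 0; p < l; ++p) {
      int c = base_code(s[p]);
      if (c < 0) stop("non-ACGT character in l-mer '%s'", s.c_str());
      k = (k << 2) | (u64)c;
    }
    out[i] = (double)k;
  }
  return out;
}

// Chunked encoding: ceil(l/t) integers, t bases each (big-endian; the last
// chunk holds the remainder).
// [[Rcpp::export]]
IntegerMatrix cpp_encode_chunks(CharacterVector lmers, int l, int t) {
  if (t < 1 || t > 15) stop("chunk width t must be in 1..15");
  int nc = (l + t - 1) / t;
  IntegerMatrix out(nc, lmers.size());
  for (int i = 0; i < lmers.size(); ++i) {
    std::string s = as<std::string>(lmers[i]);
    if ((int)s.size() != l) stop("l-mer %d has length %d, expected %d", i + 1, (int)s.size(), l);
    for (int j = 0; j < nc; ++j) {
      int v = 0;
      for (int p = j * t; p < std::min((j + 1) * t, l); ++p) {
        int c = base_code(s[p]);
        if (c < 0) stop("non-ACGT character in l-mer '%s'", s.c_str());
        v = (v << 2) | c;
      }
      out(j, i) = v;
    }
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_chunks(IntegerMatrix chunks, int l, int t) {
  int nc = (l + t - 1) / t;
  if (chunks.nrow() != nc) stop("chunk matrix has %d rows, expected %d", chunks.nrow(), nc);
  CharacterVector out(chunks.ncol());
  for (int i = 0; i < chunks.ncol(); ++i) {
    std::string s;
    for (int j = 0; j < nc; ++j) {
      int w = std::min((j + 1) * t, l) - j * t;
      int v = chunks(j, i);
      for (int p = w - 1; p >= 0; --p) s += BASES[(v >> (2 * p)) & 3];
    }
    out[i] = s;
  }
  return out;
}

// XOR + precomputed lookup table mapping a 2t-bit XOR pattern to the number
// of mismatched bases. Tables cached per chunk width.
static std::unordered_map<int, std::vector<uint8_t> > XOR_TABLES;

static const std::vector<uint8_t>& xor_table(int t) {
  auto it = XOR_TABLES.find(t);
  if (it != XOR_TABLES.end()) return it->second;
  if (t > 12) stop("lookup table unavailable for t > 12");
  size_t sz = (size_t)1 << (2 * t);
  std::vector<uint8_t> tab(sz);
  tab[0] = 0;
  for (size_t x = 1; x < sz; ++x) tab[x] = tab[x >> 2] + ((x & 3) != 0 ? 1 : 0);
  return XOR_TABLES.emplace(t, std::move(tab)).first->second;
}

// [[Rcpp::export]]
int cpp_count_mismatches_chunks(IntegerVector a, IntegerVector b, int t) {
  if (a.size() != b.size()) stop("l-mers have different chunk counts (%d vs %d)", (int)a.size(), (int)b.size());
  const std::vector<uint8_t>& tab = xor_table(t);
  int m = 0;
  for (int j = 0; j < a.size(); ++j) m += tab[a[j] ^ b[j]];
  return m;
}

// ---------------------------------------------------------- direct profiles

// All-pairs mismatch profiles between two collections of deduplicated l-mer
// lists. Output: nA x nB x (m_max+1) array of pair counts.
// [[Rcpp::export]]
NumericVector cpp_profiles_direct(List keysA, List cntA, List keysB, List cntB,
                                  int l, int m_max, bool symmetric) {
  int nA = keysA.size(), nB = keysB.size();
  int nm = m_max + 1;
  NumericVector out((double)nA * nB * nm);
  std::vector<std::vector<u64> > ka(nA), kb(nB);
  std::vector<std::vector<double> > ca(nA), cb(nB);
  for (int i = 0; i < nA; ++i) {
    NumericVector k = keysA[i]; IntegerVector c = cntA[i];
    ka[i].assign(k.begin(), k.end()); ca[i].assign(c.begin(), c.end());
  }
  for (int i = 0; i < nB; ++i) {
    NumericVector k = keysB[i]; IntegerVector c = cntB[i];
    kb[i].assign(k.begin(), k.end()); cb[i].assign(c.begin(), c.end());
  }
  for (int i = 0; i < nA; ++i) {
    for (int j = 0; j < nB; ++j) {
      if (symmetric && j > i) continue;
      std::vector<double> acc(nm, 0.0);
      const std::vector<u64>& ui = ka[i];
      const std::vector<u64>& uj = kb[j];
      for (size_t a = 0; a < ui.size(); ++a) {
        double caw = ca[i][a];
        for (size_t b = 0; b < uj.size(); ++b) {
          int m = hamming(ui[a], uj[b]);
          if (m <= m_max) acc[m] += caw * cb[j][b];
        }
      }
      for (int m = 0; m < nm; ++m) {
        out[i + (double)nA * (j + (double)nB * m)] = acc[m];
        if (symmetric) out[j + (double)nA * (i + (double)nB * m)] = acc[m];
      }
    }
    Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = IntegerVector::create(nA, nB, nm);
  return out;
}

// ------------------------------------------------------------- k-mer tree

// Tree built over the pooled unique l-mers of all sequences. A node at depth
// d is the set of stored l-mers sharing a length-d prefix; leaves (depth l)
// carry the (sequence, count) occurrence list. Profiles are accumulated by a
// depth-first traversal over node pairs, carrying the running prefix
// distance and pruning at m_max; unordered pair enumeration (child pairs
// b >= a under a shared node) computes every unordered sequence pair once,
// which is the role of the lower-triangle minID/maxID skip in the classical
// formulation.
struct KmerTree {
  std::vector<std::array<int, 4> > child;
  std::vector<int> leaf_lo, leaf_hi; // entry ranges for leaves
  std::vector<int> ent_seq;
  std::vector<double> ent_cnt;
  // compact child lists (filled after construction): bases and node ids of
  // the existing children only, so the traversal never probes empty slots
  std::vector<uint8_t> nkid;
  std::vector<std::array<uint8_t, 4> > kid_base;
  std::vector<std::array<int, 4> > kid_node;
  int l;

  int new_node() {
    child.push_back({-1, -1, -1, -1});
    leaf_lo.push_back(-1);
    leaf_hi.push_back(-1);
    return (int)child.size() - 1;
  }

  void compact() {
    size_t n = child.size();
    nkid.assign(n, 0);
    kid_base.resize(n);
    kid_node.resize(n);
    for (size_t i = 0; i < n; ++i) {
      for (int b = 0; b < 4; ++b) {
        if (child[i][b] >= 0) {
          kid_base[i][nkid[i]] = (uint8_t)b;
          kid_node[i][nkid[i]] = child[i][b];
          nkid[i]++;
        }
      }
    }
  }
};

static void build_tree(KmerTree& T, const std::vector<u64>& keys,
                       const std::vector<int>& seqs, const std::vector<double>& cnts) {
  // entries must be sorted by key
  T.new_node(); // root = 0
  size_t i = 0, N = keys.size();
  while (i < N) {
    size_t j = i;
    while (j < N && keys[j] == keys[i]) ++j;
    int node = 0;
    for (int d = 0; d < T.l; ++d) {
      int b = base_at(keys[i], d, T.l);
      if (T.child[node][b] < 0) T.child[node][b] = T.new_node();
      node = T.child[node][b];
    }
    T.leaf_lo[node] = (int)T.ent_seq.size();
    for (size_t q = i; q < j; ++q) {
      T.ent_seq.push_back(seqs[q]);
      T.ent_cnt.push_back(cnts[q]);
    }
    T.leaf_hi[node] = (int)T.ent_seq.size();
    i = j;
  }
}

struct TreeDFS {
  const KmerTree* T;
  double* N; // nseq x nseq x (m_max+1)
  int nseq, m_max, l;
  long long visits;

  void leaf_pair(int u, int v, int m) {
    double* Nm = N + (long long)m * nseq * nseq;
    int alo = T->leaf_lo[u], ahi = T->leaf_hi[u];
    int blo = T->leaf_lo[v], bhi = T->leaf_hi[v];
    if (u == v) {
      for (int a = alo; a < ahi; ++a)
        for (int b = blo; b < bhi; ++b)
          Nm[T->ent_seq[a] + (long long)nseq * T->ent_seq[b]] += T->ent_cnt[a] * T->ent_cnt[b];
    } else {
      for (int a = alo; a < ahi; ++a)
        for (int b = blo; b < bhi; ++b) {
          double w = T->ent_cnt[a] * T->ent_cnt[b];
          Nm[T->ent_seq[a] + (long long)nseq * T->ent_seq[b]] += w;
          Nm[T->ent_seq[b] + (long long)nseq * T->ent_seq[a]] += w;
        }
    }
  }

  void rec(int u, int v, int d, int depth) {
    if (depth == l) { leaf_pair(u, v, d); return; }
    if (++visits % 8388608 == 0) Rcpp::checkUserInterrupt();
    int nu = T->nkid[u], nv = T->nkid[v];
    const std::array<uint8_t, 4>& bu = T->kid_base[u];
    const std::array<uint8_t, 4>& bv = T->kid_base[v];
    const std::array<int, 4>& cu = T->kid_node[u];
    const std::array<int, 4>& cv = T->kid_node[v];
    bool same = (u == v);
    if (d == m_max) {
      // only matching-base child pairs can survive
      if (same) {
        for (int a = 0; a < nu; ++a) rec(cu[a], cu[a], d, depth + 1);
      } else {
        int a = 0, b = 0;
        while (a < nu && b < nv) {
          if (bu[a] == bv[b]) { rec(cu[a], cv[b], d, depth + 1); ++a; ++b; }
          else if (bu[a] < bv[b]) ++a;
          else ++b;
        }
      }
      return;
    }
    for (int a = 0; a < nu; ++a) {
      for (int b = same ? a : 0; b < nv; ++b) {
        int d2 = d + (bu[a] != bv[b] ? 1 : 0);
        if (d2 <= m_max) rec(cu[a], cv[b], d2, depth + 1);
      }
    }
  }
};

// [[Rcpp::export]]
NumericVector cpp_profiles_tree(List keysList, List cntList, int l, int m_max) {
  int nseq = keysList.size();
  std::vector<u64> keys;
  std::vector<int> seqs;
  std::vector<double> cnts;
  for (int i = 0; i < nseq; ++i) {
    NumericVector k = keysList[i];
    IntegerVector c = cntList[i];
    for (int j = 0; j < k.size(); ++j) {
      keys.push_back((u64)k[j]);
      seqs.push_back(i);
      cnts.push_back((double)c[j]);
    }
  }
  // sort entries by key (stable within key is irrelevant)
  std::vector<size_t> ord(keys.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) { return keys[a] < keys[b]; });
  std::vector<u64> ks(keys.size());
  std::vector<int> ss(keys.size());
  std::vector<double> cs(keys.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    ks[i] = keys[ord[i]]; ss[i] = seqs[ord[i]]; cs[i] = cnts[ord[i]];
  }
  KmerTree T;
  T.l = l;
  build_tree(T, ks, ss, cs);
  T.compact();

  int nm = m_max + 1;
  NumericVector out((double)nseq * nseq * nm);
  TreeDFS D;
  D.T = &T; D.N = REAL(out); D.nseq = nseq; D.m_max = m_max; D.l = l; D.visits = 0;
  if (!T.ent_seq.empty()) D.rec(0, 0, 0, 0);
  out.attr("dim") = IntegerVector::create(nseq, nseq, nm);
  return out;
}

// ------------------------------------------------- pooled l-mer count matrix

// Pool unique l-mers across sequences; triplets for a sparse lmer x sequence
// count matrix.
// [[Rcpp::export]]
List cpp_pool_lmers(List keysList, List cntList) {
  std::unordered_map<u64, int> id;
  std::vector<double> uk;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  for (int s = 0; s < keysList.size(); ++s) {
    NumericVector k = keysList[s];
    IntegerVector c = cntList[s];
    for (int j = 0; j < k.size(); ++j) {
      u64 key = (u64)k[j];
      auto it = id.find(key);
      int ix;
      if (it == id.end()) {
        ix = (int)uk.size();
        id.emplace(key, ix);
        uk.push_back((double)key);
      } else ix = it->second;
      ti.push_back(ix + 1);
      tj.push_back(s + 1);
      tx.push_back((double)c[j]);
    }
  }
  return List::create(_["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()),
                      _["keys"] = NumericVector(uk.begin(), uk.end()));
}

// --------------------------------------------------- near-neighbour counts

// For each query l-mer, the total training-table count at each Hamming
// distance m <= m_sup. Search uses m_sup+1 contiguous position blocks: two
// l-mers within m_sup mismatches agree exactly on at least one block
// (pigeonhole), so candidates are drawn from per-block buckets; a candidate
// is processed only in the first block where it matches the query.
// [[Rcpp::export]]
NumericMatrix cpp_neighbor_counts(NumericVector qkeys, NumericVector tkeys,
                                  NumericVector tcnts, int l, int m_sup) {
  int nq = qkeys.size(), nt = tkeys.size();
  int nb = m_sup + 1;
  if (nb > l) stop("m_sup must be < l");
  NumericMatrix out(nq, nb);
  if (nt == 0 || nq == 0) return out;

  std::vector<u64> tk(nt);
  for (int i = 0; i < nt; ++i) tk[i] = (u64)tkeys[i];

  // block p covers positions [starts[p], starts[p+1])
  std::vector<int> bl(nb, l / nb);
  for (int p = 0; p < l % nb; ++p) bl[p]++;
  std::vector<int> shift(nb), width(nb);
  int pos = 0;
  for (int p = 0; p < nb; ++p) {
    width[p] = bl[p];
    shift[p] = 2 * (l - pos - bl[p]); // right shift to bring block to low bits
    pos += bl[p];
  }
  auto blk = [&](u64 key, int p) -> u64 {
    return (key >> shift[p]) & ((1ULL << (2 * width[p])) - 1);
  };

  // counting sort of training indices per block
  std::vector<std::vector<int> > order(nb), offs(nb);
  for (int p = 0; p < nb; ++p) {
    int nbuck = 1 << (2 * width[p]);
    offs[p].assign(nbuck + 1, 0);
    for (int i = 0; i < nt; ++i) offs[p][blk(tk[i], p) + 1]++;
    for (int bkt = 0; bkt < nbuck; ++bkt) offs[p][bkt + 1] += offs[p][bkt];
    order[p].resize(nt);
    std::vector<int> cur(offs[p].begin(), offs[p].end() - 1);
    for (int i = 0; i < nt; ++i) order[p][cur[blk(tk[i], p)]++] = i;
  }

  for (int q = 0; q < nq; ++q) {
    u64 qk = (u64)qkeys[q];
    for (int p = 0; p < nb; ++p) {
      u64 qb = blk(qk, p);
      int lo = offs[p][qb], hi = offs[p][qb + 1];
      for (int ii = lo; ii < hi; ++ii) {
        int i = order[p][ii];
        u64 t = tk[i];
        bool seen = false;
        for (int p2 = 0; p2 < p; ++p2)
          if (blk(qk, p2) == blk(t, p2)) { seen = true; break; }
        if (seen) continue;
        int m = hamming(qk, t);
        if (m <= m_sup) out(q, m) += tcnts[i];
      }
    }
    if (q % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ----------------------------------------------------- SVM weight scatter

// Dense vector over all 4^l l-mers: W[u] = sum over weighted source l-mers v
// of coef(v) * h(d(u, v)) restricted to d <= m_max. Used to score every
// w-mer of a trained model when w equals the kernel word length.
// [[Rcpp::export]]
NumericVector cpp_scatter_lmer_weights(NumericVector keys, NumericVector coefs,
                                       int l, int m_max, NumericVector h) {
  if (l > 12) stop("dense l-mer weight vector limited to l <= 12");
  size_t sz = (size_t)1 << (2 * l);
  NumericVector out((R_xlen_t)sz);
  double* W = REAL(out);
  std::vector<double> hh(h.begin(), h.end());

  // recursive substitution enumeration
  struct Ctx {
    double* W; int l, m_max; const double* h; double c; u64 key;
    void rec(int p0, int m) {
      for (int p = p0; p < l; ++p) {
        int sh = 2 * (l - 1 - p);
        u64 orig = (key >> sh) & 3ULL;
        for (u64 nb = 0; nb < 4; ++nb) {
          if (nb == orig) continue;
          u64 saved = key;
          key = (key & ~(3ULL << sh)) | (nb << sh);
          W[key] += c * h[m];
          if (m < m_max) rec(p + 1, m + 1);
          key = saved;
        }
      }
    }
  } ctx;
  ctx.W = W; ctx.l = l; ctx.m_max = m_max; ctx.h = hh.data();

  for (int i = 0; i < keys.size(); ++i) {
    u64 key = (u64)keys[i];
    double c = coefs[i];
    W[key] += c * hh[0];
    if (m_max >= 1) { ctx.c = c; ctx.key = key; ctx.rec(0, 1); }
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Reverse-complement key and self-distance d(x, rc(x)) for every l-mer.
// [[Rcpp::export]]
List cpp_rc_info(int l) {
  if (l > 12) stop("limited to l <= 12");
  size_t sz = (size_t)1 << (2 * l);
  NumericVector rc((R_xlen_t)sz);
  IntegerVector dist((R_xlen_t)sz);
  for (size_t k = 0; k < sz; ++k) {
    u64 r = 0, x = (u64)k;
    for (int p = 0; p < l; ++p) {
      r = (r << 2) | (3ULL - (x & 3ULL));
      x >>= 2;
    }
    rc[k] = (double)r;
    dist[k] = hamming((u64)k, r);
  }
  return List::create(_["rc"] = rc, _["dist"] = dist);
}

// [[Rcpp::export]]
NumericVector cpp_hamming_keys(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("key vectors differ in length");
  NumericVector out(a.size());
  for (int i = 0; i < a.size(); ++i) out[i] = hamming((u64)a[i], (u64)b[i]);
  return out;
}
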