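#include "dbgvar.h"
#include <fstream>

using namespace Rcpp;

// ---- string-level primitives ------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp_str(s);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    std::string r = revcomp_str(s);
    out[i] = (s < r) ? s : r;
  }
  return out;
}

// ---- count table -------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_new_count_table(int k) {
  XPtr<CountTable> p(new CountTable(k), true);
  return p;
}

// [[Rcpp::export]]
void cpp_count_add(SEXP tab, CharacterVector reads) {
  XPtr<CountTable> p(tab);
  int k = p->k;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* cs = CHAR(STRING_ELT(reads, i));
    std::string s(cs);
    for_each_window(s, k, [&](size_t, uint64_t x) {
      uint64_t cn = canon_bits(x, k);
      uint32_t& v = p->counts[cn];
      if (v < 65535u) ++v;  // counts saturate at 2^16 - 1
      p->windows_scanned += 1.0;
    });
  }
}

// [[Rcpp::export]]
double cpp_count_size(SEXP tab) {
  XPtr<CountTable> p(tab);
  return (double)p->counts.size();
}

// [[Rcpp::export]]
double cpp_count_windows(SEXP tab) {
  XPtr<CountTable> p(tab);
  return p->windows_scanned;
}

// [[Rcpp::export]]
IntegerVector cpp_count_get(SEXP tab, CharacterVector kmers) {
  XPtr<CountTable> p(tab);
  int k = p->k;
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t x;
    if ((int)s.size() != k || !encode_kmer(s, &x)) {
      out[i] = 0;
      continue;
    }
    auto it = p->counts.find(canon_bits(x, k));
    out[i] = (it == p->counts.end()) ? 0 : (int)it->second;
  }
  return out;
}

// all (canonical kmer, count) pairs, kmers ascending; intended for
// small tables (tests, reports)
// [[Rcpp::export]]
DataFrame cpp_count_entries(SEXP tab) {
  XPtr<CountTable> p(tab);
  std::vector<uint64_t> keys;
  keys.reserve(p->counts.size());
  for (auto& kv : p->counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector km(keys.size());
  IntegerVector ct(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = decode_kmer(keys[i], p->k);
    ct[i] = (int)p->counts[keys[i]];
  }
  return DataFrame::create(_["kmer"] = km, _["count"] = ct,
                           _["stringsAsFactors"] = false);
}

// per-window canonical counts along a sequence; -1 for windows hit by
// a non-ACGT character
// [[Rcpp::export]]
IntegerVector cpp_window_counts(SEXP tab, std::string seq) {
  XPtr<CountTable> p(tab);
  int k = p->k;
  int n = (int)seq.size() - k + 1;
  if (n < 1) return IntegerVector(0);
  IntegerVector out(n, -1);
  for_each_window(seq, k, [&](size_t pos, uint64_t x) {
    auto it = p->counts.find(canon_bits(x, k));
    out[(int)pos] = (it == p->counts.end()) ? 0 : (int)it->second;
  });
  return out;
}

// ---- solid set ---------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_solid_build(SEXP tab, int c) {
  XPtr<CountTable> p(tab);
  XPtr<SolidSetC> s(new SolidSetC(p->k, c), true);
  std::vector<uint64_t> keep;
  for (auto& kv : p->counts)
    if ((int)kv.second >= c) keep.push_back(kv.first);
  s->finalize(std::move(keep));
  return s;
}

// [[Rcpp::export]]
SEXP cpp_solid_from_kmers(CharacterVector kmers, int k) {
  XPtr<SolidSetC> s(new SolidSetC(k, 1), true);
  std::vector<uint64_t> keep;
  keep.reserve(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string str = as<std::string>(kmers[i]);
    if ((int)str.size() != k) stop("k-mer %d has length != k", (int)i + 1);
    uint64_t x;
    if (!encode_kmer(str, &x)) stop("non-ACGT character in k-mer %d", (int)i + 1);
    keep.push_back(canon_bits(x, k));
  }
  s->finalize(std::move(keep));
  return s;
}

// [[Rcpp::export]]
double cpp_solid_size(SEXP solid) {
  XPtr<SolidSetC> s(solid);
  return (double)s->sorted.size();
}

// [[Rcpp::export]]
int cpp_solid_k(SEXP solid) {
  XPtr<SolidSetC> s(solid);
  return s->k;
}

// [[Rcpp::export]]
LogicalVector cpp_solid_contains(SEXP solid, CharacterVector kmers) {
  XPtr<SolidSetC> s(solid);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string str = as<std::string>(kmers[i]);
    uint64_t x;
    if ((int)str.size() != s->k || !encode_kmer(str, &x)) {
      out[i] = false;
      continue;
    }
    out[i] = s->contains_oriented(x);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_solid_members(SEXP solid) {
  XPtr<SolidSetC> s(solid);
  CharacterVector out(s->sorted.size());
  for (size_t i = 0; i < s->sorted.size(); ++i)
    out[i] = decode_kmer(s->sorted[i], s->k);
  return out;
}

// binary persistence: magic, k, c, count, packed k-mers ascending
// [[Rcpp::export]]
void cpp_solid_save(SEXP solid, std::string path) {
  XPtr<SolidSetC> s(solid);
  std::ofstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  f.write("DBGVSS1", 7);
  int32_t k = s->k, c = s->c;
  uint64_t n = s->sorted.size();
  f.write((char*)&k, 4);
  f.write((char*)&c, 4);
  f.write((char*)&n, 8);
  if (n) f.write((char*)s->sorted.data(), 8 * n);
  if (!f) stop("write failed for '%s'", path.c_str());
}

// [[Rcpp::export]]
SEXP cpp_solid_load(std::string path) {
  std::ifstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s'", path.c_str());
  char magic[7];
  f.read(magic, 7);
  if (!f || std::string(magic, 7) != "DBGVSS1")
    stop("'%s' is not a solid-set file", path.c_str());
  int32_t k, c;
  uint64_t n;
  f.read((char*)&k, 4);
  f.read((char*)&c, 4);
  f.read((char*)&n, 8);
  if (!f) stop("truncated solid-set file '%s'", path.c_str());
  std::vector<uint64_t> v(n);
  if (n) f.read((char*)v.data(), 8 * n);
  if (!f) stop("truncated solid-set file '%s'", path.c_str());
  XPtr<SolidSetC> s(new SolidSetC(k, c), true);
  s->finalize(std::move(v));
  return s;
}

// [[Rcpp::export]]
int cpp_solid_c(SEXP solid) {
  XPtr<SolidSetC> s(solid);
  return s->c;
}

// ---- bloom filter ------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_bloom_build(SEXP solid, int bits_per_elem, int h) {
  XPtr<SolidSetC> s(solid);
  uint64_t n = s->sorted.size();
  uint64_t m = (uint64_t)bits_per_elem * std::max((uint64_t)1, n);
  XPtr<BloomC> b(new BloomC(s->k, m, h), true);
  for (uint64_t km : s->sorted) b->insert(km);
  return b;
}

// [[Rcpp::export]]
LogicalVector cpp_bloom_contains(SEXP bloom, CharacterVector kmers) {
  XPtr<BloomC> b(bloom);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string str = as<std::string>(kmers[i]);
    uint64_t x;
    if ((int)str.size() != b->k || !encode_kmer(str, &x)) {
      out[i] = false;
      continue;
    }
    out[i] = b->query(canon_bits(x, b->k));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bloom_params(SEXP bloom) {
  XPtr<BloomC> b(bloom);
  return List::create(_["k"] = b->k, _["m"] = (double)b->m, _["h"] = b->h,
                      _["n_inserted"] = (double)b->n_inserted);
}

// ---- de Bruijn graph neighbor queries ---------------------------------

// [[Rcpp::export]]
CharacterVector cpp_successors(SEXP solid, std::string node) {
  XPtr<SolidSetC> s(solid);
  int k = s->k;
  uint64_t x;
  if ((int)node.size() != k || !encode_kmer(node, &x))
    stop("node must be an ACGT string of length k");
  std::vector<std::string> out;
  for (int b = 0; b < 4; ++b) {
    uint64_t cand = shift_right(x, b, k);
    if (s->contains_oriented(cand)) out.push_back(decode_kmer(cand, k));
  }
  return wrap(out);
}

// [[Rcpp::export]]
CharacterVector cpp_predecessors(SEXP solid, std::string node) {
  XPtr<SolidSetC> s(solid);
  int k = s->k;
  uint64_t x;
  if ((int)node.size() != k || !encode_kmer(node, &x))
    stop("node must be an ACGT string of length k");
  std::vector<std::string> out;
  for (int b = 0; b < 4; ++b) {
    uint64_t cand = shift_left(x, b, k);
    if (s->contains_oriented(cand)) out.push_back(decode_kmer(cand, k));
  }
  return wrap(out);
}

// unambiguous walk: advance while the current node has exactly one
// neighbor ahead and that neighbor has exactly one neighbor behind;
// stop on branch, dead end, revisit (loop guard) or max_len
std::string extend_unitig_impl(const SolidSetC& S, uint64_t start, bool right,
                               int max_len) {
  int k = S.k;
  std::unordered_set<uint64_t> visited;
  visited.insert(canon_bits(start, k));
  uint64_t cur = start;
  std::string ext;
  while ((int)ext.size() < max_len) {
    int nfwd = 0, base = -1;
    uint64_t next = 0;
    for (int b = 0; b < 4; ++b) {
      uint64_t cand = right ? shift_right(cur, b, k) : shift_left(cur, b, k);
      if (S.contains_oriented(cand)) {
        ++nfwd;
        next = cand;
        base = b;
      }
    }
    if (nfwd != 1) break;
    int nback = 0;
    for (int b = 0; b < 4; ++b) {
      uint64_t cand = right ? shift_left(next, b, k) : shift_right(next, b, k);
      if (S.contains_oriented(cand)) ++nback;
    }
    if (nback != 1) break;
    uint64_t cn = canon_bits(next, k);
    if (visited.count(cn)) break;
    visited.insert(cn);
    cur = next;
    ext.push_back(bits2base(base));
  }
  if (!right) std::reverse(ext.begin(), ext.end());
  return ext;
}

// [[Rcpp::export]]
std::string cpp_extend_unitig(SEXP solid, std::string start, bool right,
                              int max_len) {
  XPtr<SolidSetC> s(solid);
  uint64_t x;
  if ((int)start.size() != s->k || !encode_kmer(start, &x))
    stop("start must be an ACGT string of length k");
  if (!s->contains_oriented(x)) stop("start k-mer is not solid");
  return extend_unitig_impl(*s, x, right, max_len);
}

// ---- shared-read marking (set comparison) -----------------------------

// [[Rcpp::export]]
LogicalVector cpp_mark_shared_solid(SEXP solid, CharacterVector reads, int t) {
  XPtr<SolidSetC> s(solid);
  int k = s->k;
  LogicalVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    int hits = 0;
    for_each_window(r, k, [&](size_t, uint64_t x) {
      if (s->contains(canon_bits(x, k))) ++hits;
    });
    out[i] = (hits >= t);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_mark_shared_bloom(SEXP bloom, CharacterVector reads, int t) {
  XPtr<BloomC> b(bloom);
  int k = b->k;
  LogicalVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    int hits = 0;
    for_each_window(r, k, [&](size_t, uint64_t x) {
      if (b->query(canon_bits(x, k))) ++hits;
    });
    out[i] = (hits >= t);
  }
  return out;
}

// ---- read error simulation --------------------------------------------

// i.i.d. substitutions at rate err to a uniformly chosen different base;
// uses R's RNG so results are reproducible under set.seed()
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double err) {
  RNGScope scope;
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (R::unif_rand() < err) {
        int b = base2bits(s[j]);
        if (b < 0) continue;  // never touch N
        int shift = 1 + (int)(R::unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        s[j] = bits2base((b + shift) & 3);
      }
    }
    out[i] = s;
  }
  return out;
}
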