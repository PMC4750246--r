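#ifndef DBGVAR_H
#define DBGVAR_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>

// 2-bit base packing: A=0, C=1, G=2, T=3. k <= 31 so a k-mer fits in
// 62 bits of one uint64_t.

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char bits2base(int b) { return "ACGT"[b & 3]; }

static inline uint64_t kmer_mask(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

static inline uint64_t revcomp_bits(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

static inline uint64_t canon_bits(uint64_t x, int k) {
  uint64_t r = revcomp_bits(x, k);
  return x < r ? x : r;
}

// append base on the right, drop leftmost
static inline uint64_t shift_right(uint64_t x, int b, int k) {
  return ((x << 2) | (uint64_t)b) & kmer_mask(k);
}

// prepend base on the left, drop rightmost
static inline uint64_t shift_left(uint64_t x, int b, int k) {
  return (x >> 2) | ((uint64_t)b << (2 * (k - 1)));
}

static inline std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bits2base((int)(x & 3ULL));
    x >>= 2;
  }
  return s;
}

// false if any non-ACGT character
static inline bool encode_kmer(const std::string& s, uint64_t* out) {
  uint64_t x = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    x = (x << 2) | (uint64_t)b;
  }
  *out = x;
  return true;
}

static inline std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[s.size() - 1 - i]);
    if (b < 0) Rcpp::stop("non-ACGT character in sequence");
    r[i] = bits2base(3 - b);
  }
  return r;
}

// call f(start_position, packed_window) for every k-window free of
// non-ACGT characters; windows touching an N are skipped wholesale
template <typename F>
static inline void for_each_window(const std::string& s, int k, F f) {
  uint64_t mask = kmer_mask(k);
  uint64_t x = 0;
  int valid = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; x = 0; continue; }
    x = ((x << 2) | (uint64_t)b) & mask;
    if (++valid >= k) f(i + 1 - k, x);
  }
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct CountTable {
  int k;
  std::unordered_map<uint64_t, uint32_t> counts;
  double windows_scanned;
  CountTable(int k_) : k(k_), windows_scanned(0) {}
};

struct SolidSetC {
  int k;
  int c;
  std::vector<uint64_t> sorted;          // ascending, canonical
  std::unordered_set<uint64_t> members;  // same content, O(1) lookup
  SolidSetC(int k_, int c_) : k(k_), c(c_) {}
  bool contains(uint64_t canonical_km) const {
    return members.count(canonical_km) != 0;
  }
  bool contains_oriented(uint64_t x) const {
    return members.count(canon_bits(x, k)) != 0;
  }
  void finalize(std::vector<uint64_t> v) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
    members.insert(v.begin(), v.end());
    sorted = std::move(v);
  }
};

struct BloomC {
  int k;
  int h;
  uint64_t m;
  uint64_t n_inserted;
  std::vector<uint64_t> bits;
  BloomC(int k_, uint64_t m_, int h_)
      : k(k_), h(h_), m(m_), n_inserted(0), bits((m_ + 63) / 64, 0ULL) {}
  void setbit(uint64_t pos) { bits[pos >> 6] |= (1ULL << (pos & 63)); }
  bool getbit(uint64_t pos) const {
    return (bits[pos >> 6] >> (pos & 63)) & 1ULL;
  }
  void insert(uint64_t key) {
    uint64_t h1 = splitmix64(key);
    uint64_t h2 = splitmix64(key ^ 0xda942042e4dd58b5ULL) | 1ULL;
    for (int i = 0; i < h; ++i) setbit((h1 + (uint64_t)i * h2) % m);
    ++n_inserted;
  }
  bool query(uint64_t key) const {
    uint64_t h1 = splitmix64(key);
    uint64_t h2 = splitmix64(key ^ 0xda942042e4dd58b5ULL) | 1ULL;
    for (int i = 0; i < h; ++i)
      if (!getbit((h1 + (uint64_t)i * h2) % m)) return false;
    return true;
  }
};

std::string extend_unitig_impl(const SolidSetC& S, uint64_t start, bool right,
                               int max_len);

#endif
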