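#include "dbgvar.h"
#include <set>

using namespace Rcpp;

// ---- SNP bubbles -------------------------------------------------------
//
// A bubble is a pair of (2k-1)-length strings, every k-window of both
// canonical-solid, differing at exactly the center position k-1. It is
// seeded by two oriented solid k-mers identical except at their last
// base and grown by k-1 simultaneous right extensions. In strict mode
// every step must admit exactly one base keeping both paths solid.

namespace {

typedef std::pair<std::string, std::string> StrPair;

// representative of a path pair under {swap, reverse complement}
StrPair canon_pair(std::string p, std::string q) {
  if (q < p) std::swap(p, q);
  std::string rp = revcomp_str(p), rq = revcomp_str(q);
  if (rq < rp) std::swap(rp, rq);
  if (rp < p || (rp == p && rq < q)) return StrPair(rp, rq);
  return StrPair(p, q);
}

// The two paths of a bubble are vertex-disjoint simple paths, so an
// extension step is only admissible when its two new nodes are solid,
// distinct from each other and from every node already on either path
// (all compared canonically). Without the guard, tiny double-stranded
// graphs admit strand-crossing pseudo-paths and self-reverse-complement
// "bubbles" that are one molecule seen from both strands, not SNPs.
void bubble_dfs(const SolidSetC& S, uint64_t w1, uint64_t w2, std::string& ext,
                int remaining, bool strict, const std::string& s1,
                const std::string& s2, std::unordered_set<uint64_t>& visited,
                std::set<StrPair>& out) {
  int k = S.k;
  if (remaining == 0) {
    out.insert(canon_pair(s1 + ext, s2 + ext));
    return;
  }
  int adm[4], na = 0;
  for (int b = 0; b < 4; ++b) {
    uint64_t n1 = shift_right(w1, b, k), n2 = shift_right(w2, b, k);
    uint64_t c1 = canon_bits(n1, k), c2 = canon_bits(n2, k);
    if (c1 != c2 && S.contains(c1) && S.contains(c2) && !visited.count(c1) &&
        !visited.count(c2))
      adm[na++] = b;
  }
  if (strict && na != 1) return;
  for (int i = 0; i < na; ++i) {
    int b = adm[i];
    uint64_t n1 = shift_right(w1, b, k), n2 = shift_right(w2, b, k);
    uint64_t c1 = canon_bits(n1, k), c2 = canon_bits(n2, k);
    ext.push_back(bits2base(b));
    visited.insert(c1);
    visited.insert(c2);
    bubble_dfs(S, n1, n2, ext, remaining - 1, strict, s1, s2, visited, out);
    visited.erase(c1);
    visited.erase(c2);
    ext.pop_back();
  }
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_find_bubbles(SEXP solid, bool strict) {
  XPtr<SolidSetC> s(solid);
  int k = s->k;
  std::set<StrPair> found;
  for (uint64_t km : s->sorted) {
    uint64_t rc = revcomp_bits(km, k);
    for (int ori = 0; ori < 2; ++ori) {
      if (ori == 1 && rc == km) break;
      uint64_t w1 = ori ? rc : km;
      int last = (int)(w1 & 3ULL);
      for (int b = last + 1; b < 4; ++b) {
        uint64_t w2 = (w1 & ~3ULL) | (uint64_t)b;
        if (!s->contains_oriented(w2)) continue;
        uint64_t c1 = canon_bits(w1, k), c2 = canon_bits(w2, k);
        if (c1 == c2) continue;
        std::string ext;
        std::unordered_set<uint64_t> visited;
        visited.insert(c1);
        visited.insert(c2);
        bubble_dfs(*s, w1, w2, ext, k - 1, strict, decode_kmer(w1, k),
                   decode_kmer(w2, k), visited, found);
      }
    }
  }
  R_xlen_t n = (R_xlen_t)found.size();
  CharacterVector pa(n), pb(n);
  R_xlen_t i = 0;
  for (const StrPair& pr : found) {
    pa[i] = pr.first;
    pb[i] = pr.second;
    ++i;
  }
  return DataFrame::create(_["path_a"] = pa, _["path_b"] = pb,
                           _["stringsAsFactors"] = false);
}

// Flanking contigs shared by both bubble paths. On the left: if the
// shared (k-1)-prefix has exactly one solid predecessor p, the contig is
// the leftward unitig extension of p followed by p's leading base;
// otherwise "". Mirror logic on the right.
// [[Rcpp::export]]
List cpp_bubble_flanks(SEXP solid, CharacterVector path_a, int max_len) {
  XPtr<SolidSetC> s(solid);
  int k = s->k;
  R_xlen_t n = path_a.size();
  CharacterVector left(n), right(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string p = as<std::string>(path_a[i]);
    if ((int)p.size() != 2 * k - 1) stop("path %d has length != 2k-1", (int)i + 1);
    // left: unique x with (x + prefix) solid
    std::string lc, rc;
    {
      uint64_t pref;
      encode_kmer(p.substr(0, (size_t)(k - 1)), &pref);
      int nc = 0, base = -1;
      uint64_t node = 0;
      for (int b = 0; b < 4; ++b) {
        uint64_t cand = pref | ((uint64_t)b << (2 * (k - 1)));
        if (s->contains_oriented(cand)) {
          ++nc;
          node = cand;
          base = b;
        }
      }
      if (nc == 1)
        lc = extend_unitig_impl(*s, node, false, max_len) +
             std::string(1, bits2base(base));
    }
    {
      uint64_t suf;
      encode_kmer(p.substr((size_t)k, (size_t)(k - 1)), &suf);
      int nc = 0, base = -1;
      uint64_t node = 0;
      for (int b = 0; b < 4; ++b) {
        uint64_t cand = (suf << 2) | (uint64_t)b;
        if (s->contains_oriented(cand)) {
          ++nc;
          node = cand;
          base = b;
        }
      }
      if (nc == 1)
        rc = std::string(1, bits2base(base)) +
             extend_unitig_impl(*s, node, true, max_len);
    }
    left[i] = lc;
    right[i] = rc;
  }
  return List::create(_["left"] = left, _["right"] = right);
}

// ---- inversion breakpoints --------------------------------------------
//
// An inversion aIb -> aI'b leaves four 2k breakpoint words au, vb, av',
// u'b in the joint k-mer content (u, v the terminal k-mers of I). Each
// word is witnessed when all k+1 of its windows are canonical-solid.

namespace {

// all length-k extension strings e of 'start' such that every window of
// start+e is solid; false if the partial-path count ever exceeds cap
bool enum_ext(const SolidSetC& S, uint64_t start, int cap,
              std::vector<std::string>* out) {
  int k = S.k;
  std::vector<std::pair<uint64_t, std::string> > frontier;
  frontier.push_back(std::make_pair(start, std::string()));
  for (int step = 0; step < k; ++step) {
    std::vector<std::pair<uint64_t, std::string> > next;
    for (size_t i = 0; i < frontier.size(); ++i) {
      for (int b = 0; b < 4; ++b) {
        uint64_t cand = shift_right(frontier[i].first, b, k);
        if (S.contains_oriented(cand))
          next.push_back(std::make_pair(
              cand, frontier[i].second + std::string(1, bits2base(b))));
      }
    }
    if ((int)next.size() > cap) return false;
    frontier.swap(next);
  }
  out->clear();
  for (size_t i = 0; i < frontier.size(); ++i)
    out->push_back(frontier[i].second);
  return true;
}

int hamming(const std::string& a, const std::string& b) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) ++d;
  return d;
}

bool word_solid(const SolidSetC& S, const std::string& w) {
  int k = S.k;
  bool ok = true;
  int seen = 0;
  for_each_window(w, k, [&](size_t, uint64_t x) {
    ++seen;
    if (!S.contains(canon_bits(x, k))) ok = false;
  });
  return ok && seen == (int)w.size() - k + 1;
}

// Minimum over the eight equivalent tuple descriptions: the breakpoint
// word set {au, vb, av', u'b} (modulo reverse complement) is invariant
// under exchanging u <-> v' with u' <-> v, under reverse-complementing
// the whole event, and under swapping the two halves (a,u,v,b) ->
// (v,b,a,u); from k-mer content alone these all denote the same event.
std::vector<std::string> canon_event(const std::string& a, const std::string& u,
                                     const std::string& v,
                                     const std::string& b) {
  std::string ap = revcomp_str(a), up = revcomp_str(u), vp = revcomp_str(v),
              bp = revcomp_str(b);
  std::vector<std::vector<std::string> > forms;
  const std::string* base[4][4] = {
      {&a, &u, &v, &b}, {&a, &vp, &up, &b}, {&bp, &vp, &up, &ap},
      {&bp, &u, &v, &ap}};
  for (int i = 0; i < 4; ++i) {
    std::vector<std::string> f;
    for (int j = 0; j < 4; ++j) f.push_back(*base[i][j]);
    forms.push_back(f);
    // half-swap: (x1,x2,x3,x4) -> (x3,x4,x1,x2)
    std::vector<std::string> g;
    g.push_back(f[2]); g.push_back(f[3]); g.push_back(f[0]); g.push_back(f[1]);
    forms.push_back(g);
  }
  size_t best = 0;
  for (size_t i = 1; i < forms.size(); ++i)
    if (forms[i] < forms[best]) best = i;
  return forms[best];
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_find_inversions(SEXP solid, int max_paths, int min_fork_distance) {
  XPtr<SolidSetC> s(solid);
  int k = s->k;
  std::set<std::vector<std::string> > events;
  for (uint64_t km : s->sorted) {
    uint64_t rcb = revcomp_bits(km, k);
    for (int ori = 0; ori < 2; ++ori) {
      if (ori == 1 && rcb == km) break;
      uint64_t a64 = ori ? rcb : km;
      // a must be a k-fork root: >= 2 solid successors
      int nsucc = 0;
      for (int b = 0; b < 4; ++b)
        if (s->contains_oriented(shift_right(a64, b, k))) ++nsucc;
      if (nsucc < 2) continue;
      std::vector<std::string> exts;
      if (!enum_ext(*s, a64, max_paths, &exts)) continue;  // abandon repeat-dense fork
      std::string a = decode_kmer(a64, k);
      for (size_t j = 0; j < exts.size(); ++j) {
        const std::string& vprime = exts[j];  // word a + v'
        std::string v = revcomp_str(vprime);
        uint64_t v64;
        encode_kmer(v, &v64);
        std::vector<std::string> extsb;
        if (!enum_ext(*s, v64, max_paths, &extsb)) continue;
        for (size_t i = 0; i < exts.size(); ++i) {
          const std::string& u = exts[i];  // word a + u
          if (hamming(u, vprime) < min_fork_distance) continue;
          // part of the repeat guard: the motif is two k-forks, so each
          // junction must genuinely branch at its first base; folds
          // through chance palindromes fail this on one junction pair
          if (min_fork_distance > 0 && u[0] == vprime[0]) continue;
          std::string uprime = revcomp_str(u);
          char a_prime0 = bits2base(3 - base2bits(a[(size_t)(k - 1)]));
          for (size_t m = 0; m < extsb.size(); ++m) {
            const std::string& b = extsb[m];  // word v + b
            if (min_fork_distance > 0 && b[0] == a_prime0) continue;
            if (!word_solid(*s, uprime + b)) continue;
            // The pseudo-cycle joins FOUR k-mers: a, u, v, b must be
            // pairwise distinct canonically, else the candidate is a
            // degenerate closure of the pattern onto its own strands
            // (e.g. b = a', which is always word-consistent). The (u,v)
            // pair is exempt: a palindromic event (u = v') has
            // canonically equal u and v by definition and is handled by
            // the min_fork_distance guard instead.
            uint64_t q[4];
            encode_kmer(a, &q[0]);
            encode_kmer(u, &q[1]);
            encode_kmer(v, &q[2]);
            encode_kmer(b, &q[3]);
            bool distinct = true;
            for (int x = 0; x < 4 && distinct; ++x)
              for (int y = x + 1; y < 4; ++y) {
                if (x == 1 && y == 2) continue;
                if (canon_bits(q[x], k) == canon_bits(q[y], k)) {
                  distinct = false;
                  break;
                }
              }
            if (!distinct) continue;
            events.insert(canon_event(a, u, v, b));
          }
        }
      }
    }
  }
  R_xlen_t n = (R_xlen_t)events.size();
  CharacterVector A(n), U(n), V(n), B(n);
  LogicalVector pal(n);
  R_xlen_t i = 0;
  for (std::set<std::vector<std::string> >::const_iterator it = events.begin();
       it != events.end(); ++it, ++i) {
    A[i] = (*it)[0];
    U[i] = (*it)[1];
    V[i] = (*it)[2];
    B[i] = (*it)[3];
    pal[i] = ((*it)[1] == revcomp_str((*it)[2]));
  }
  return DataFrame::create(_["a"] = A, _["u"] = U, _["v"] = V, _["b"] = B,
                           _["palindromic"] = pal,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cpp_canonicalize_event(std::string a, std::string u,
                                       std::string v, std::string b) {
  std::vector<std::string> e = canon_event(a, u, v, b);
  return wrap(e);
}
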