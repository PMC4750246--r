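#include "dbgvar.h"
#include <climits>

using namespace Rcpp;

// Ungapped, k-mer-anchored read mapping onto predicted variant
// sequences. A placement is admissible when it is induced by at least
// one exact shared k-mer (read and target agree on k consecutive
// bases), its overlap covers the target's center position, and the
// number of mismatches over the overlap is <= max_mismatch.

namespace {

struct Anchor {
  int target;
  int pos;
};

// best (minimum) mismatch count over admissible placements of one
// oriented read on one target; INT_MAX if none
int best_placement(const std::string& read, const std::string& target,
                   int center, int k,
                   const std::unordered_map<uint64_t, std::vector<Anchor> >* idx,
                   int target_id) {
  int best = INT_MAX;
  std::unordered_set<long long> seen;
  int lr = (int)read.size(), lt = (int)target.size();
  for_each_window(read, k, [&](size_t rpos, uint64_t x) {
    std::unordered_map<uint64_t, std::vector<Anchor> >::const_iterator it =
        idx->find(x);
    if (it == idx->end()) return;
    for (size_t a = 0; a < it->second.size(); ++a) {
      if (it->second[a].target != target_id) continue;
      int off = it->second[a].pos - (int)rpos;  // read start on target
      if (!seen.insert((long long)off).second) continue;
      int lo = std::max(0, off), hi = std::min(lt, off + lr);
      if (center < lo || center >= hi) continue;
      int mm = 0;
      for (int t = lo; t < hi; ++t)
        if (target[(size_t)t] != read[(size_t)(t - off)]) ++mm;
      if (mm < best) best = mm;
    }
  });
  return best;
}

void build_index(const std::vector<std::string>& targets, int k,
                 std::unordered_map<uint64_t, std::vector<Anchor> >* idx) {
  for (size_t t = 0; t < targets.size(); ++t) {
    for_each_window(targets[t], k, [&](size_t pos, uint64_t x) {
      Anchor a;
      a.target = (int)t;
      a.pos = (int)pos;
      (*idx)[x].push_back(a);
    });
  }
}

}  // namespace

// [[Rcpp::export]]
bool cpp_map_read(std::string read, std::string target, int center, int k,
                  int max_mismatch) {
  if ((int)target.size() < k) stop("target shorter than k");
  std::unordered_map<uint64_t, std::vector<Anchor> > idx;
  std::vector<std::string> tv;
  tv.push_back(target);
  build_index(tv, k, &idx);
  int b1 = best_placement(read, target, center, k, &idx, 0);
  int b2 = best_placement(revcomp_str(read), target, center, k, &idx, 0);
  return std::min(b1, b2) <= max_mismatch;
}

// Per-allele per-set read counts for a batch of bubbles. seq_a/seq_b are
// the flanked allele sequences, center[i] the SNP position within them.
// A read whose best admissible placements tie between the two alleles of
// a bubble is ambiguous and counted for neither.
// [[Rcpp::export]]
List cpp_quantify(List readsets, CharacterVector seq_a, CharacterVector seq_b,
                  IntegerVector center, int k, int max_mismatch) {
  int nb = (int)seq_a.size();
  int ns = (int)readsets.size();
  std::vector<std::string> targets;  // 2*nb: allele A then allele B per bubble
  targets.reserve(2 * (size_t)nb);
  for (int i = 0; i < nb; ++i) targets.push_back(as<std::string>(seq_a[i]));
  for (int i = 0; i < nb; ++i) targets.push_back(as<std::string>(seq_b[i]));
  std::unordered_map<uint64_t, std::vector<Anchor> > idx;
  build_index(targets, k, &idx);

  IntegerMatrix countA(nb, ns), countB(nb, ns);
  for (int s = 0; s < ns; ++s) {
    CharacterVector reads = readsets[s];
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
      std::string fw = as<std::string>(reads[r]);
      std::string rv = revcomp_str(fw);
      // collect candidate targets once from anchors of both strands
      std::unordered_set<int> cand;
      for_each_window(fw, k, [&](size_t, uint64_t x) {
        std::unordered_map<uint64_t, std::vector<Anchor> >::const_iterator it =
            idx.find(x);
        if (it != idx.end())
          for (size_t a = 0; a < it->second.size(); ++a)
            cand.insert(it->second[a].target);
      });
      for_each_window(rv, k, [&](size_t, uint64_t x) {
        std::unordered_map<uint64_t, std::vector<Anchor> >::const_iterator it =
            idx.find(x);
        if (it != idx.end())
          for (size_t a = 0; a < it->second.size(); ++a)
            cand.insert(it->second[a].target);
      });
      if (cand.empty()) continue;
      // bubbles touched by any candidate target
      std::unordered_set<int> bubbles;
      for (std::unordered_set<int>::const_iterator it = cand.begin();
           it != cand.end(); ++it)
        bubbles.insert(*it % nb);
      for (std::unordered_set<int>::const_iterator it = bubbles.begin();
           it != bubbles.end(); ++it) {
        int i = *it;
        int bA = std::min(
            best_placement(fw, targets[(size_t)i], center[i], k, &idx, i),
            best_placement(rv, targets[(size_t)i], center[i], k, &idx, i));
        int bB = std::min(best_placement(fw, targets[(size_t)(i + nb)],
                                         center[i], k, &idx, i + nb),
                          best_placement(rv, targets[(size_t)(i + nb)],
                                         center[i], k, &idx, i + nb));
        bool okA = bA <= max_mismatch, okB = bB <= max_mismatch;
        if (okA && (!okB || bA < bB)) countA(i, s) += 1;
        else if (okB && (!okA || bB < bA)) countB(i, s) += 1;
        // tie or no admissible placement: counted for neither
      }
    }
  }
  return List::create(_["count_a"] = countA, _["count_b"] = countB);
}
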