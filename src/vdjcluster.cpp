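#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

// Semi-global alignment anchored at the left of seq: the aligned region of
// seq is a prefix of seq, the gene may start anywhere (free 5' gene end),
// both alignment ends are free. Linear gap penalties. Deterministic
// tie-break: among maximal cells, smallest end on seq, then on gene.
//
// Returns 0-based half-open coordinates: seq interval is [0, seq_end),
// gene interval is [gene_start, gene_end).
// [[Rcpp::export]]
List align_left_cpp(std::string gene, std::string seq,
                    int match, int mismatch, int gap) {
  int m = gene.size(), n = seq.size();
  // S: (m+1) x (n+1); origin O tracks the gene row where the path started
  std::vector<int> S((m + 1) * (n + 1));
  std::vector<int> O((m + 1) * (n + 1));
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };
  for (int i = 0; i <= m; ++i) { S[idx(i, 0)] = 0; O[idx(i, 0)] = i; }
  for (int j = 1; j <= n; ++j) { S[idx(0, j)] = gap * j; O[idx(0, j)] = 0; }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int sub = (gene[i - 1] == seq[j - 1]) ? match : mismatch;
      int d = S[idx(i - 1, j - 1)] + sub;
      int u = S[idx(i - 1, j)] + gap;
      int l = S[idx(i, j - 1)] + gap;
      int best = d, orig = O[idx(i - 1, j - 1)];
      if (u > best) { best = u; orig = O[idx(i - 1, j)]; }
      if (l > best) { best = l; orig = O[idx(i, j - 1)]; }
      S[idx(i, j)] = best;
      O[idx(i, j)] = orig;
    }
  }
  int bestScore = S[idx(0, 0)], bi = 0, bj = 0;
  for (int j = 0; j <= n; ++j)       // smallest seq end first
    for (int i = 0; i <= m; ++i)     // then smallest gene end
      if (S[idx(i, j)] > bestScore) { bestScore = S[idx(i, j)]; bi = i; bj = j; }
  return List::create(_["score"] = bestScore,
                      _["seq_end"] = bj,
                      _["gene_start"] = O[idx(bi, bj)],
                      _["gene_end"] = bi);
}

// Smith-Waterman local alignment with linear gaps, used for short D genes
// inside the junction. Tie-break: smallest seq end, then smallest gene end.
// [[Rcpp::export]]
List align_local_cpp(std::string gene, std::string seq,
                     int match, int mismatch, int gap) {
  int m = gene.size(), n = seq.size();
  std::vector<int> S((m + 1) * (n + 1), 0);
  std::vector<int> Og((m + 1) * (n + 1), 0);  // gene start of local path
  std::vector<int> Os((m + 1) * (n + 1), 0);  // seq start of local path
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };
  for (int i = 0; i <= m; ++i) { Og[idx(i, 0)] = i; }
  for (int j = 0; j <= n; ++j) { Os[idx(0, j)] = j; }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int sub = (gene[i - 1] == seq[j - 1]) ? match : mismatch;
      int d = S[idx(i - 1, j - 1)] + sub;
      int u = S[idx(i - 1, j)] + gap;
      int l = S[idx(i, j - 1)] + gap;
      int best = d, og = Og[idx(i - 1, j - 1)], os = Os[idx(i - 1, j - 1)];
      if (u > best) { best = u; og = Og[idx(i - 1, j)]; os = Os[idx(i - 1, j)]; }
      if (l > best) { best = l; og = Og[idx(i, j - 1)]; os = Os[idx(i, j - 1)]; }
      if (best < 0) { best = 0; og = i; os = j; }
      S[idx(i, j)] = best;
      Og[idx(i, j)] = og;
      Os[idx(i, j)] = os;
    }
  }
  int bestScore = 0, bi = 0, bj = 0;
  for (int j = 0; j <= n; ++j)
    for (int i = 0; i <= m; ++i)
      if (S[idx(i, j)] > bestScore) { bestScore = S[idx(i, j)]; bi = i; bj = j; }
  return List::create(_["score"] = bestScore,
                      _["seq_start"] = Os[idx(bi, bj)],
                      _["seq_end"] = bj,
                      _["gene_start"] = Og[idx(bi, bj)],
                      _["gene_end"] = bi);
}

static inline bool acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Extract the masked spaced k-mers of one sequence: at every position the
// characters under '#' are concatenated into the lookup key. Windows
// containing any non-ACGT character yield NA.
// [[Rcpp::export]]
CharacterVector masked_kmers_cpp(std::string s, std::string pattern) {
  int span = pattern.size();
  std::vector<int> hash_at;
  for (int k = 0; k < span; ++k) if (pattern[k] == '#') hash_at.push_back(k);
  int n = s.size();
  int npos = n - span + 1;
  if (npos < 1) return CharacterVector(0);
  CharacterVector out(npos);
  std::string key(hash_at.size(), 'A');
  for (int p = 0; p < npos; ++p) {
    bool ok = true;
    for (size_t q = 0; q < hash_at.size(); ++q) {
      char c = s[p + hash_at[q]];
      if (!acgt(c)) { ok = false; break; }
      key[q] = c;
    }
    if (ok) out[p] = key; else out[p] = NA_STRING;
  }
  return out;
}

// Batch affectation: label every seed position of every read against the
// index (keys -> integer labels; -1 encodes an ambiguous k-mer). Positions
// whose masked k-mer is absent from the index, or contains a non-ACGT
// character, get 0 (no affect).
// [[Rcpp::export]]
List affect_reads_cpp(CharacterVector reads, CharacterVector keys,
                      IntegerVector labels, std::string pattern) {
  std::unordered_map<std::string, int> index;
  index.reserve(keys.size() * 2);
  for (int i = 0; i < keys.size(); ++i)
    index[std::string(keys[i])] = labels[i];
  int span = pattern.size();
  std::vector<int> hash_at;
  for (int k = 0; k < span; ++k) if (pattern[k] == '#') hash_at.push_back(k);
  List out(reads.size());
  std::string key(hash_at.size(), 'A');
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = std::string(reads[r]);
    int npos = (int)s.size() - span + 1;
    if (npos < 1) { out[r] = IntegerVector(0); continue; }
    IntegerVector aff(npos);
    for (int p = 0; p < npos; ++p) {
      bool ok = true;
      for (size_t q = 0; q < hash_at.size(); ++q) {
        char c = s[p + hash_at[q]];
        if (!acgt(c)) { ok = false; break; }
        key[q] = c;
      }
      if (!ok) { aff[p] = 0; continue; }
      auto it = index.find(key);
      aff[p] = (it == index.end()) ? 0 : it->second;
    }
    out[r] = aff;
  }
  return out;
}
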