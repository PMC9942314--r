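// Test-grade ungapped seed-and-extend read mapper.
//
// Seeds are exact k-mer matches against a hash index of the reference;
// candidate loci are seed diagonals; each candidate is scored by ungapped
// extension over the full read (match +1, mismatch -4), with soft clipping
// only where the read overhangs a contig end. Substitution-only by design:
// indel-bearing reads score poorly and drop below the reporting threshold.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

struct MapIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<uint64_t>> tab; // kmer -> cid<<40|pos
};

// [[Rcpp::export]]
SEXP refix_index_build(CharacterVector contig_names, CharacterVector contig_seqs,
                       int k) {
  if (k < 11 || k > 31) stop("builtin mapper requires 11 <= k <= 31");
  MapIndex* idx = new MapIndex();
  idx->k = k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (int c = 0; c < contig_names.size(); ++c) {
    idx->names.push_back(as<std::string>(contig_names[c]));
    idx->seqs.push_back(as<std::string>(contig_seqs[c]));
    const std::string& s = idx->seqs.back();
    uint64_t key = 0;
    int run = 0; // number of consecutive valid bases ending at i
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        uint64_t pos = i + 1 - (size_t)k;
        idx->tab[key].push_back(((uint64_t)c << 40) | pos);
      }
    }
  }
  XPtr<MapIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
CharacterVector refix_index_contigs(SEXP xp) {
  XPtr<MapIndex> idx(xp);
  return wrap(idx->names);
}

struct Cand {
  int cid;
  long pos;      // 0-based start of the (unclipped) read on the contig
  int strand;    // 0 fwd, 1 rev
  int score;
  int nmis;
  int clip_left;
  int clip_right;
};

static void score_candidate(const MapIndex& idx, const std::string& oriented,
                            int cid, long start, int strand, int match,
                            int mismatch, int min_aln, std::vector<Cand>& out) {
  const std::string& ref = idx.seqs[cid];
  const long rlen = (long)ref.size();
  const long len = (long)oriented.size();
  long a = std::max(0L, start);
  long b = std::min(rlen, start + len);
  if (b - a < (long)min_aln) return;
  int nmis = 0, nmatch = 0;
  for (long p = a; p < b; ++p) {
    char rb = ref[p];
    char qb = oriented[p - start];
    if (rb == qb && base2bit(rb) >= 0) ++nmatch; else ++nmis;
  }
  Cand cd;
  cd.cid = cid;
  cd.pos = start;
  cd.strand = strand;
  cd.score = nmatch * match + nmis * mismatch;
  cd.nmis = nmis;
  cd.clip_left = (int)(a - start);
  cd.clip_right = (int)((start + len) - b);
  out.push_back(cd);
}

// [[Rcpp::export]]
DataFrame refix_map_batch(SEXP xp, CharacterVector reads, int seed_step,
                          int max_occ, int min_score, int max_cand,
                          int match, int mismatch) {
  XPtr<MapIndex> idx(xp);
  const int k = idx->k;
  std::vector<int> o_read, o_cid, o_strand, o_score, o_nmis, o_cl, o_cr;
  std::vector<double> o_pos;

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const long len = (long)fwd.size();
    if (len < k) continue; // unmapped: shorter than a seed
    std::string rev(fwd.rbegin(), fwd.rend());
    for (auto& ch : rev) ch = complement(ch);

    std::vector<Cand> cands;
    std::unordered_set<uint64_t> seen;
    const uint64_t mask = ((uint64_t)1 << (2 * k)) - 1ULL;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = (strand == 0) ? fwd : rev;
      for (long off = 0;; off += seed_step) {
        if (off > len - k) {
          if (off - seed_step < len - k) off = len - k; else break;
        }
        uint64_t key = 0;
        bool valid = true;
        for (int j = 0; j < k; ++j) {
          int b = base2bit(s[off + j]);
          if (b < 0) { valid = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        key &= mask;
        if (valid) {
          auto it = idx->tab.find(key);
          if (it != idx->tab.end() && (int)it->second.size() <= max_occ) {
            for (uint64_t packed : it->second) {
              int cid = (int)(packed >> 40);
              long pos = (long)(packed & ((1ULL << 40) - 1));
              long start = pos - off;
              // dedupe on (strand, cid, diagonal)
              uint64_t ckey = ((uint64_t)strand << 62) |
                              ((uint64_t)cid << 42) |
                              (uint64_t)(start + len);
              if (seen.insert(ckey).second) {
                score_candidate(*idx, s, cid, start, strand, match, mismatch,
                                k, cands);
              }
            }
          }
        }
        if (off == len - k) break;
      }
    }
    // drop sub-threshold candidates, canonical order, cap
    std::vector<Cand> keep;
    for (const Cand& c : cands) if (c.score >= min_score) keep.push_back(c);
    std::sort(keep.begin(), keep.end(), [](const Cand& a, const Cand& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.cid != b.cid) return a.cid < b.cid;
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.strand < b.strand;
    });
    if ((int)keep.size() > max_cand) keep.resize(max_cand);
    for (const Cand& c : keep) {
      o_read.push_back(r + 1);
      o_cid.push_back(c.cid + 1);
      o_pos.push_back((double)c.pos);
      o_strand.push_back(c.strand);
      o_score.push_back(c.score);
      o_nmis.push_back(c.nmis);
      o_cl.push_back(c.clip_left);
      o_cr.push_back(c.clip_right);
    }
  }
  return DataFrame::create(
    _["read"] = o_read, _["cid"] = o_cid, _["pos"] = o_pos,
    _["strand"] = o_strand, _["score"] = o_score, _["nmis"] = o_nmis,
    _["clip_left"] = o_cl, _["clip_right"] = o_cr);
}
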