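#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; anything outside ACGT (incl. N) is -1 and breaks k-mers
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

// ---------------------------------------------------------------------------
// k-mer index: hash table k-mer code -> sorted (chrom, 0-based pos) occurrences
// ---------------------------------------------------------------------------

class KmerIndex {
public:
  int k;
  std::vector<std::string> seqs;
  std::vector<std::string> names;
  std::unordered_map<uint64_t, std::vector<uint64_t> > table;

  KmerIndex(CharacterVector genome, int k_) : k(k_) {
    CharacterVector nm = genome.names();
    for (R_xlen_t i = 0; i < genome.size(); ++i) {
      seqs.push_back(as<std::string>(genome[i]));
      names.push_back(as<std::string>(nm[i]));
    }
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (size_t c = 0; c < seqs.size(); ++c) {
      const std::string& s = seqs[c];
      uint64_t code = 0;
      int run = 0;
      for (long i = 0; i < (long)s.size(); ++i) {
        int b = base_code(s[i]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
          long pos = i - k + 1;
          table[code].push_back(((uint64_t)c << 40) | (uint64_t)pos);
        }
      }
    }
  }

  bool encode(const std::string& s, size_t from, uint64_t& out) const {
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) {
      int b = base_code(s[from + j]);
      if (b < 0) return false;
      code = (code << 2) | (uint64_t)b;
    }
    out = code;
    return true;
  }
};

// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build(CharacterVector genome, int k) {
  XPtr<KmerIndex> p(new KmerIndex(genome, k), true);
  return p;
}

// [[Rcpp::export(name = ".kmer_index_k")]]
int kmer_index_k(SEXP xp) { return XPtr<KmerIndex>(xp)->k; }

// [[Rcpp::export(name = ".kmer_index_nkeys")]]
double kmer_index_nkeys(SEXP xp) { return (double)XPtr<KmerIndex>(xp)->table.size(); }

// [[Rcpp::export(name = ".kmer_index_chroms")]]
CharacterVector kmer_index_chroms(SEXP xp) {
  XPtr<KmerIndex> p(xp);
  return wrap(p->names);
}

// Occurrences of one k-mer; 1-based positions, chrom as 1-based index
// [[Rcpp::export(name = ".kmer_index_lookup")]]
DataFrame kmer_index_lookup(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> p(xp);
  std::vector<int> chrom, pos;
  if ((int)kmer.size() == p->k) {
    uint64_t code;
    if (p->encode(kmer, 0, code)) {
      std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
        p->table.find(code);
      if (it != p->table.end()) {
        for (size_t i = 0; i < it->second.size(); ++i) {
          uint64_t v = it->second[i];
          chrom.push_back((int)(v >> 40) + 1);
          pos.push_back((int)(v & ((1ULL << 40) - 1)) + 1);
        }
      }
    }
  }
  return DataFrame::create(_["chrom"] = chrom, _["pos"] = pos);
}

// ---------------------------------------------------------------------------
// seed-and-vote alignment
// ---------------------------------------------------------------------------

static std::vector<int> seed_offsets(int L, int k, int n) {
  std::vector<int> off;
  if (L < k) return off;
  if (n <= 1 || L == k) { off.push_back(0); return off; }
  int prev = -1;
  for (int i = 0; i < n; ++i) {
    int o = (int)std::floor((double)i * (double)(L - k) / (double)(n - 1) + 0.5);
    if (o != prev) off.push_back(o);
    prev = o;
  }
  return off;
}

// [[Rcpp::export(name = ".seed_offsets")]]
IntegerVector seed_offsets_cpp(int L, int k, int n) {
  return wrap(seed_offsets(L, k, n));
}

struct SeedHit {
  int chrom;
  long start;   // implied 0-based read-start
  int offset;   // seed offset within the read
  bool operator<(const SeedHit& o) const {
    if (chrom != o.chrom) return chrom < o.chrom;
    if (start != o.start) return start < o.start;
    return offset < o.offset;
  }
};

struct Candidate {
  int chrom;
  int strand;   // 0 = forward, 1 = reverse
  long s1;      // modal implied start
  long s2;      // second implied start (or s1 if none)
  int votes;    // distinct seed offsets in the pooled cluster
};

// collect seed hits for one oriented sequence and pool into candidates
static void vote_one_strand(const KmerIndex& idx, const std::string& seq,
                            int n_seeds, int max_indel, int strand,
                            std::vector<Candidate>& out) {
  int L = (int)seq.size();
  std::vector<int> offs = seed_offsets(L, idx.k, n_seeds);
  std::vector<SeedHit> hits;
  for (size_t i = 0; i < offs.size(); ++i) {
    uint64_t code;
    if (!idx.encode(seq, offs[i], code)) continue;
    std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
      idx.table.find(code);
    if (it == idx.table.end()) continue;
    for (size_t j = 0; j < it->second.size(); ++j) {
      uint64_t v = it->second[j];
      SeedHit h;
      h.chrom = (int)(v >> 40);
      h.start = (long)(v & ((1ULL << 40) - 1)) - offs[i];
      h.offset = offs[i];
      hits.push_back(h);
    }
  }
  if (hits.empty()) return;
  std::sort(hits.begin(), hits.end());
  size_t a = 0;
  while (a < hits.size()) {
    size_t b = a + 1;
    while (b < hits.size() && hits[b].chrom == hits[a].chrom &&
           hits[b].start - hits[b - 1].start <= max_indel) ++b;
    // cluster [a, b): support per distinct start = distinct offsets
    std::vector<std::pair<long, int> > support; // (start, n distinct offsets)
    std::vector<int> seen_offsets;
    size_t i = a;
    int cluster_votes = 0;
    std::vector<int> cluster_offsets;
    while (i < b) {
      size_t j = i;
      std::vector<int> offs_here;
      while (j < b && hits[j].start == hits[i].start) {
        if (offs_here.empty() || offs_here.back() != hits[j].offset)
          offs_here.push_back(hits[j].offset);
        ++j;
      }
      support.push_back(std::make_pair(hits[i].start, (int)offs_here.size()));
      for (size_t t = 0; t < offs_here.size(); ++t)
        cluster_offsets.push_back(offs_here[t]);
      i = j;
    }
    std::sort(cluster_offsets.begin(), cluster_offsets.end());
    cluster_offsets.erase(std::unique(cluster_offsets.begin(), cluster_offsets.end()),
                          cluster_offsets.end());
    cluster_votes = (int)cluster_offsets.size();
    // modal start: most distinct offsets, tie -> smallest coordinate
    size_t best = 0, second = support.size();
    for (size_t t = 1; t < support.size(); ++t)
      if (support[t].second > support[best].second) best = t;
    for (size_t t = 0; t < support.size(); ++t) {
      if (t == best) continue;
      if (second == support.size() || support[t].second > support[second].second)
        second = t;
    }
    Candidate c;
    c.chrom = hits[a].chrom;
    c.strand = strand;
    c.s1 = support[best].first;
    c.s2 = (second == support.size()) ? support[best].first : support[second].first;
    c.votes = cluster_votes;
    out.push_back(c);
    a = b;
  }
}

// [[Rcpp::export(name = ".vote_read")]]
DataFrame vote_read_cpp(SEXP xp, std::string read, int n_seeds, int max_indel) {
  XPtr<KmerIndex> p(xp);
  std::vector<Candidate> cands;
  vote_one_strand(*p, read, n_seeds, max_indel, 0, cands);
  vote_one_strand(*p, revcomp(read), n_seeds, max_indel, 1, cands);
  int n = (int)cands.size();
  IntegerVector chrom(n), pos(n), votes(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    chrom[i] = cands[i].chrom + 1;
    pos[i] = (int)cands[i].s1 + 1;
    votes[i] = cands[i].votes;
    strand[i] = cands[i].strand == 0 ? "+" : "-";
  }
  return DataFrame::create(_["chrom"] = chrom, _["pos"] = pos,
                           _["strand"] = strand, _["votes"] = votes);
}

struct Alignment {
  bool mapped;
  int chrom, strand;
  long pos;
  int matched, mismatched, votes, score;
  int indel_pos, indel_len;  // indel_len > 0 deletion, < 0 insertion, 0 none
  long ref_span;
  bool gene_overlap;
};

// extend one candidate: ungapped at s1 and s2 plus best single-indel split
static void extend_candidate(const std::string& seq, const std::string& chr,
                             const Candidate& c, Alignment& out) {
  int L = (int)seq.size();
  long n = (long)chr.size();
  long s1 = c.s1, s2 = c.s2;
  long d = s2 - s1;
  // prefix sums of in-bounds (b) and matched (m) flags at both offsets
  std::vector<int> P1m(L + 1, 0), P1b(L + 1, 0), P2m(L + 1, 0), P2b(L + 1, 0);
  for (int i = 0; i < L; ++i) {
    long g1 = s1 + i, g2 = s2 + i;
    int b1 = (g1 >= 0 && g1 < n) ? 1 : 0;
    int m1 = (b1 && chr[(size_t)g1] == seq[(size_t)i]) ? 1 : 0;
    int b2 = (g2 >= 0 && g2 < n) ? 1 : 0;
    int m2 = (b2 && chr[(size_t)g2] == seq[(size_t)i]) ? 1 : 0;
    P1m[i + 1] = P1m[i] + m1; P1b[i + 1] = P1b[i] + b1;
    P2m[i + 1] = P2m[i] + m2; P2b[i + 1] = P2b[i] + b2;
  }
  // ungapped at s1
  int best_matched = P1m[L], best_aligned = P1b[L];
  int best_score = 2 * best_matched - best_aligned;
  long best_pos = s1;
  int best_ipos = NA_INTEGER, best_ilen = 0;
  long best_span = L;
  if (d != 0) {
    // ungapped at s2
    int sc = 2 * P2m[L] - P2b[L];
    if (sc > best_score) {
      best_score = sc; best_matched = P2m[L]; best_aligned = P2b[L];
      best_pos = s2; best_ilen = 0; best_ipos = NA_INTEGER; best_span = L;
    }
    // one indel: read prefix anchored at sa, suffix at sb = sa + dd;
    // both arm assignments (s1->s2 and s2->s1) are tried because the
    // modal start may support either arm
    struct Arm { const std::vector<int>* Pm; const std::vector<int>* Pb;
                 const std::vector<int>* Sm; const std::vector<int>* Sb;
                 long sa; long dd; };
    Arm arms[2] = { { &P1m, &P1b, &P2m, &P2b, s1, d },
                    { &P2m, &P2b, &P1m, &P1b, s2, -d } };
    for (int t = 0; t < 2; ++t) {
      const Arm& A = arms[t];
      if (A.dd > 0) {
        // deletion of dd genome bases after read position j (interior)
        for (int j = 1; j < L; ++j) {
          int matched = (*A.Pm)[j] + ((*A.Sm)[L] - (*A.Sm)[j]);
          int aligned = (*A.Pb)[j] + ((*A.Sb)[L] - (*A.Sb)[j]);
          int s = 2 * matched - aligned;
          if (s > best_score) {
            best_score = s; best_matched = matched; best_aligned = aligned;
            best_pos = A.sa; best_ipos = j; best_ilen = (int)A.dd;
            best_span = L + A.dd;
          }
        }
      } else {
        int ins = (int)(-A.dd);
        // insertion: read bases j..j+ins-1 unaligned
        for (int j = 1; j + ins < L; ++j) {
          int matched = (*A.Pm)[j] + ((*A.Sm)[L] - (*A.Sm)[j + ins]);
          int aligned = (*A.Pb)[j] + ((*A.Sb)[L] - (*A.Sb)[j + ins]);
          int s = 2 * matched - aligned;
          if (s > best_score) {
            best_score = s; best_matched = matched; best_aligned = aligned;
            best_pos = A.sa; best_ipos = j; best_ilen = -ins;
            best_span = L - ins;
          }
        }
      }
    }
  }
  out.chrom = c.chrom; out.strand = c.strand;
  out.pos = best_pos;
  out.matched = best_matched;
  out.mismatched = best_aligned - best_matched;
  out.score = best_score;
  out.votes = c.votes;
  out.indel_pos = best_ipos;
  out.indel_len = best_ilen;
  out.ref_span = best_span;
  out.mapped = true;
}

static bool overlaps_gene(const std::vector<std::vector<long> >& starts,
                          const std::vector<std::vector<long> >& ends,
                          int chrom, long qs, long qe) {
  const std::vector<long>& en = ends[chrom];
  const std::vector<long>& st = starts[chrom];
  if (en.empty() || qe <= qs) return false;
  // first interval with end > qs
  std::vector<long>::const_iterator it = std::upper_bound(en.begin(), en.end(), qs);
  if (it == en.end()) return false;
  size_t i = (size_t)(it - en.begin());
  return st[i] < qe;
}

// [[Rcpp::export(name = ".align_reads")]]
DataFrame align_reads_cpp(SEXP xp, CharacterVector reads,
                          int n_seeds, int min_votes, int min_score,
                          int max_indel, int max_candidates,
                          List exon_starts, List exon_ends) {
  XPtr<KmerIndex> p(xp);
  int nchrom = (int)p->seqs.size();
  std::vector<std::vector<long> > est(nchrom), een(nchrom);
  for (int c = 0; c < nchrom; ++c) {
    IntegerVector s = exon_starts[c], e = exon_ends[c];
    for (R_xlen_t i = 0; i < s.size(); ++i) {
      est[c].push_back((long)s[i]);
      een[c].push_back((long)e[i]);
    }
  }
  R_xlen_t nr = reads.size();
  LogicalVector mapped(nr), gene_overlap(nr);
  IntegerVector chrom(nr), pos(nr), matched(nr), mismatched(nr),
                votes(nr), score(nr), indel_pos(nr), indel_len(nr), ref_span(nr);
  CharacterVector strand(nr);

  for (R_xlen_t r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);
    std::vector<Candidate> cands;
    vote_one_strand(*p, fwd, n_seeds, max_indel, 0, cands);
    vote_one_strand(*p, rev, n_seeds, max_indel, 1, cands);
    mapped[r] = false;
    chrom[r] = NA_INTEGER; pos[r] = NA_INTEGER; strand[r] = NA_STRING;
    matched[r] = NA_INTEGER; mismatched[r] = NA_INTEGER; votes[r] = NA_INTEGER;
    score[r] = NA_INTEGER; indel_pos[r] = NA_INTEGER; indel_len[r] = NA_INTEGER;
    ref_span[r] = NA_INTEGER; gene_overlap[r] = NA_LOGICAL;
    if (cands.empty()) continue;
    // keep candidates meeting the vote floor, capped at the best max_candidates
    std::vector<Candidate> keep;
    for (size_t i = 0; i < cands.size(); ++i)
      if (cands[i].votes >= min_votes) keep.push_back(cands[i]);
    if (keep.empty()) continue;
    std::stable_sort(keep.begin(), keep.end(),
      // votes desc, then genomic order for a deterministic cap
      [](const Candidate& a, const Candidate& b) {
        if (a.votes != b.votes) return a.votes > b.votes;
        if (a.chrom != b.chrom) return a.chrom < b.chrom;
        if (a.s1 != b.s1) return a.s1 < b.s1;
        return a.strand < b.strand;
      });
    if ((int)keep.size() > max_candidates) keep.resize(max_candidates);
    Alignment best; best.mapped = false;
    bool have = false;
    for (size_t i = 0; i < keep.size(); ++i) {
      Alignment a;
      const std::string& seq = keep[i].strand == 0 ? fwd : rev;
      extend_candidate(seq, p->seqs[keep[i].chrom], keep[i], a);
      a.gene_overlap = overlaps_gene(est, een, a.chrom, a.pos,
                                     a.pos + a.ref_span);
      bool better;
      if (!have) better = true;
      else if (a.score != best.score) better = a.score > best.score;
      else if (a.gene_overlap != best.gene_overlap) better = a.gene_overlap;
      else if (a.chrom != best.chrom) better = a.chrom < best.chrom;
      else if (a.pos != best.pos) better = a.pos < best.pos;
      else better = a.strand < best.strand;
      if (better) { best = a; have = true; }
    }
    if (!have || best.score < min_score) continue;
    mapped[r] = true;
    chrom[r] = best.chrom + 1;
    pos[r] = (int)best.pos + 1;
    strand[r] = best.strand == 0 ? "+" : "-";
    matched[r] = best.matched;
    mismatched[r] = best.mismatched;
    votes[r] = best.votes;
    score[r] = best.score;
    indel_pos[r] = best.indel_pos == NA_INTEGER ? NA_INTEGER : best.indel_pos + 1;
    indel_len[r] = best.indel_len;
    ref_span[r] = (int)best.ref_span;
    gene_overlap[r] = best.gene_overlap;
  }
  return DataFrame::create(
    _["mapped"] = mapped, _["chrom"] = chrom, _["pos"] = pos,
    _["strand"] = strand, _["matched"] = matched, _["mismatched"] = mismatched,
    _["votes"] = votes, _["score"] = score, _["indel_pos"] = indel_pos,
    _["indel_len"] = indel_len, _["ref_span"] = ref_span,
    _["gene_overlap"] = gene_overlap, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// UMI collapsing: connected components under Hamming distance <= 1
// ---------------------------------------------------------------------------

static inline bool umi_encode(const std::string& s, uint64_t& out) {
  uint64_t code = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_code(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  out = code;
  return true;
}

static inline bool ham_le1(uint64_t a, uint64_t b) {
  uint64_t x = a ^ b;
  if (!x) return true;
  int shift = (__builtin_ctzll(x) / 2) * 2;
  return (x >> shift) <= 3ULL;
}

static int uf_find(std::vector<int>& par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

// groups must arrive sorted by `group`; returns one row per UMI component
// [[Rcpp::export(name = ".collapse_umis_grouped")]]
DataFrame collapse_umis_grouped(IntegerVector group, CharacterVector umi,
                                IntegerVector nreads) {
  R_xlen_t n = group.size();
  std::vector<int> out_group;
  std::vector<std::string> out_rep;
  std::vector<int> out_reads;
  R_xlen_t a = 0;
  while (a < n) {
    R_xlen_t b = a + 1;
    while (b < n && group[b] == group[a]) ++b;
    int m = (int)(b - a);
    std::vector<uint64_t> codes(m);
    std::vector<std::string> strs(m);
    std::vector<bool> ok(m);
    for (int i = 0; i < m; ++i) {
      strs[i] = as<std::string>(umi[a + i]);
      ok[i] = umi_encode(strs[i], codes[i]);
    }
    std::vector<int> par(m);
    for (int i = 0; i < m; ++i) par[i] = i;
    for (int i = 0; i < m; ++i) {
      for (int j = i + 1; j < m; ++j) {
        bool link;
        if (ok[i] && ok[j]) {
          link = ham_le1(codes[i], codes[j]);
        } else {
          // UMIs containing N: fall back to direct comparison
          int d = 0;
          if (strs[i].size() != strs[j].size()) continue;
          for (size_t t = 0; t < strs[i].size() && d <= 1; ++t)
            if (strs[i][t] != strs[j][t]) ++d;
          link = d <= 1;
        }
        if (link) {
          int ri = uf_find(par, i), rj = uf_find(par, j);
          if (ri != rj) par[ri] = rj;
        }
      }
    }
    // component representative: max reads, tie -> lexicographically smallest
    std::unordered_map<int, int> rep;
    std::unordered_map<int, long> reads_sum;
    for (int i = 0; i < m; ++i) {
      int r = uf_find(par, i);
      std::unordered_map<int, int>::iterator it = rep.find(r);
      if (it == rep.end()) {
        rep[r] = i;
        reads_sum[r] = nreads[a + i];
      } else {
        reads_sum[r] += nreads[a + i];
        int cur = it->second;
        if (nreads[a + i] > nreads[a + cur] ||
            (nreads[a + i] == nreads[a + cur] && strs[i] < strs[cur]))
          it->second = i;
      }
    }
    std::vector<int> roots;
    for (std::unordered_map<int, int>::iterator it = rep.begin(); it != rep.end(); ++it)
      roots.push_back(it->first);
    std::sort(roots.begin(), roots.end());
    for (size_t t = 0; t < roots.size(); ++t) {
      out_group.push_back(group[a]);
      out_rep.push_back(strs[rep[roots[t]]]);
      out_reads.push_back((int)reads_sum[roots[t]]);
    }
    a = b;
  }
  return DataFrame::create(_["group"] = wrap(out_group),
                           _["umi"] = wrap(out_rep),
                           _["reads"] = wrap(out_reads),
                           _["stringsAsFactors"] = false);
}
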