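// Strand-aware exact k-mer voting index over a transcriptome.
//
// Only the sense-strand k-mers of the transcripts are stored; a query probes
// both the read's forward k-mers (sense votes) and their reverse complements
// (antisense votes).  K-mers are packed 2 bits/base into a 64-bit word, which
// caps k at 31 (kallisto's own cap; 31 is also the default).

#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <string>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or anything else: breaks the rolling window
  }
}

struct KmerIndex {
  int k;
  int n_transcripts;
  // k-mer -> sorted unique transcript indices (0-based)
  std::unordered_map<uint64_t, std::vector<int> > table;
};

static void add_seq_kmers(KmerIndex& idx, const char* s, int len, int tx) {
  const int k = idx.k;
  if (len < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0;
  int run = 0;  // length of current valid-base run
  for (int i = 0; i < len; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      std::vector<int>& v = idx.table[fwd];
      if (v.empty() || v.back() != tx) v.push_back(tx);
    }
  }
}

// [[Rcpp::export(name = ".build_index_cpp")]]
List build_index_cpp(CharacterVector seqs, int k) {
  if (k < 11 || k > 31 || k % 2 == 0)
    stop("k must be an odd integer in [11, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->n_transcripts = seqs.size();
  size_t total = 0;
  for (int t = 0; t < seqs.size(); ++t)
    total += (size_t) LENGTH(STRING_ELT(seqs, t));
  idx->table.reserve(total);
  std::vector<int> too_short;
  for (int t = 0; t < seqs.size(); ++t) {
    const char* s = CHAR(STRING_ELT(seqs, t));
    int len = (int) LENGTH(STRING_ELT(seqs, t));
    if (len < k) { too_short.push_back(t + 1); continue; }
    add_seq_kmers(*idx, s, len, t);
  }
  if (idx->table.empty()) {
    delete idx;
    stop("no transcript reaches length k = %d; cannot build index", k);
  }
  XPtr<KmerIndex> ptr(idx, true);
  return List::create(_["ptr"] = ptr,
                      _["n_kmers"] = (double) idx->table.size(),
                      _["too_short"] = wrap(too_short));
}

struct Assignment {
  int status;        // 0 UNMAPPED, 1 ASSIGNED, 2 AMBIGUOUS_STRAND
  int orientation;   // 0 none, 1 SENSE, 2 ANTISENSE
  int vs, va;
  bool multi;        // id-set intersection was empty; fell back to union
  std::vector<int> txs;  // sorted 0-based transcript indices (ASSIGNED only)
};

// per-thread scratch buffers, reused across reads to avoid heap churn
struct Workspace {
  std::vector<const std::vector<int>*> hits_s, hits_a;
  std::vector<int> tmp;
};

// out := out ∩ b (both sorted)
static void intersect_inplace(std::vector<int>& out,
                              const std::vector<int>& b,
                              std::vector<int>& tmp) {
  tmp.clear();
  std::set_intersection(out.begin(), out.end(), b.begin(), b.end(),
                        std::back_inserter(tmp));
  out.swap(tmp);
}

static void assign_one(const KmerIndex& idx, const char* s, int len,
                       double min_vote_frac, Workspace& ws,
                       Assignment& out) {
  const int k = idx.k;
  out.status = 0; out.orientation = 0; out.vs = 0; out.va = 0;
  out.multi = false; out.txs.clear();
  if (len < k) return;
  const int m = len - k + 1;  // k-mer positions in the read
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  ws.hits_s.clear(); ws.hits_a.clear();
  for (int i = 0; i < len; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run < k) continue;
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator it;
    it = idx.table.find(fwd);
    if (it != idx.table.end()) { out.vs++; ws.hits_s.push_back(&it->second); }
    it = idx.table.find(rc);
    if (it != idx.table.end()) { out.va++; ws.hits_a.push_back(&it->second); }
  }
  const double thr = min_vote_frac * m - 1e-9;
  const int v = std::max(out.vs, out.va);
  if (v == 0 || (double) v < thr) return;  // UNMAPPED
  bool s_pass = (double) out.vs >= thr, a_pass = (double) out.va >= thr;
  if (s_pass && a_pass && std::abs(out.vs - out.va) <= 1) {
    out.status = 2;  // AMBIGUOUS_STRAND: both orientations supported, near-tie
    return;
  }
  out.status = 1;
  out.orientation = (out.vs > out.va) ? 1 : 2;
  const std::vector<const std::vector<int>*>& hits =
      (out.orientation == 1) ? ws.hits_s : ws.hits_a;
  // intersection of id-sets over the winning orientation's matched k-mers;
  // empty intersection (junction-spanning read) falls back to the union
  out.txs = *hits[0];
  for (size_t i = 1; i < hits.size() && !out.txs.empty(); ++i)
    if (hits[i] != hits[i - 1])  // runs of identical id-sets are common
      intersect_inplace(out.txs, *hits[i], ws.tmp);
  if (out.txs.empty()) {
    out.multi = true;
    for (size_t i = 0; i < hits.size(); ++i)
      out.txs.insert(out.txs.end(), hits[i]->begin(), hits[i]->end());
    std::sort(out.txs.begin(), out.txs.end());
    out.txs.erase(std::unique(out.txs.begin(), out.txs.end()),
                  out.txs.end());
  }
}

// [[Rcpp::export(name = ".assign_read_cpp")]]
List assign_read_cpp(std::string seq, SEXP ptr, double min_vote_frac) {
  XPtr<KmerIndex> idx(ptr);
  Assignment a;
  Workspace ws;
  assign_one(*idx, seq.c_str(), (int) seq.size(), min_vote_frac, ws, a);
  IntegerVector txs(a.txs.size());
  for (size_t i = 0; i < a.txs.size(); ++i) txs[i] = a.txs[i] + 1;
  return List::create(_["status"] = a.status, _["orientation"] = a.orientation,
                      _["votes_sense"] = a.vs, _["votes_antisense"] = a.va,
                      _["multi"] = a.multi, _["transcripts"] = txs);
}

static bool disjoint_sorted(const std::vector<int>& a,
                            const std::vector<int>& b) {
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) return false;
    if (a[i] < b[j]) ++i; else ++j;
  }
  return true;
}

// Pair decision table.  Call codes: 1 FR, 2 RF, 3 FAILED, 4 UNMAPPED.
static int pair_call(const Assignment& a1, const Assignment& a2, int& tx_out) {
  tx_out = NA_INTEGER;
  if (a1.status == 2 || a2.status == 2) return 3;          // strand-ambiguous mate
  bool m1 = a1.status == 1, m2 = a2.status == 1;
  if (!m1 && !m2) return 4;                                 // UNMAPPED
  if (m1 && !m2) {                                          // mate 1 alone
    tx_out = a1.txs.empty() ? NA_INTEGER : a1.txs[0] + 1;
    return a1.orientation == 1 ? 1 : 2;
  }
  if (!m1 && m2) {                                          // mate 2 alone
    tx_out = a2.txs.empty() ? NA_INTEGER : a2.txs[0] + 1;
    return a2.orientation == 1 ? 2 : 1;
  }
  if (disjoint_sorted(a1.txs, a2.txs)) return 3;            // chimeric pair
  if (a1.orientation == a2.orientation) return 3;           // discordant
  // shared transcript: first element of the pairwise intersection
  for (size_t i = 0, j = 0; i < a1.txs.size() && j < a2.txs.size();) {
    if (a1.txs[i] == a2.txs[j]) { tx_out = a1.txs[i] + 1; break; }
    if (a1.txs[i] < a2.txs[j]) ++i; else ++j;
  }
  return a1.orientation == 1 ? 1 : 2;
}

// [[Rcpp::export(name = ".classify_pairs_cpp")]]
List classify_pairs_cpp(CharacterVector seq1, CharacterVector seq2,
                        SEXP ptr, double min_vote_frac) {
  XPtr<KmerIndex> idx(ptr);
  const int n = seq1.size();
  if (seq2.size() != n) stop("mate vectors differ in length");
  IntegerVector call(n), tx(n);
  IntegerVector s1(n), o1(n), vs1(n), va1(n);
  IntegerVector s2(n), o2(n), vs2(n), va2(n);
  Assignment a1, a2;
  Workspace ws;
  for (int i = 0; i < n; ++i) {
    assign_one(*idx, CHAR(STRING_ELT(seq1, i)),
               (int) LENGTH(STRING_ELT(seq1, i)), min_vote_frac, ws, a1);
    assign_one(*idx, CHAR(STRING_ELT(seq2, i)),
               (int) LENGTH(STRING_ELT(seq2, i)), min_vote_frac, ws, a2);
    int t;
    call[i] = pair_call(a1, a2, t);
    tx[i] = t;
    s1[i] = a1.status; o1[i] = a1.orientation; vs1[i] = a1.vs; va1[i] = a1.va;
    s2[i] = a2.status; o2[i] = a2.orientation; vs2[i] = a2.vs; va2[i] = a2.va;
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["call"] = call, _["tx"] = tx,
      _["m1_status"] = s1, _["m1_orientation"] = o1,
      _["m1_votes_sense"] = vs1, _["m1_votes_antisense"] = va1,
      _["m2_status"] = s2, _["m2_orientation"] = o2,
      _["m2_votes_sense"] = vs2, _["m2_votes_antisense"] = va2);
}

// [[Rcpp::export(name = ".index_kmers_cpp")]]
List index_kmers_cpp(SEXP ptr) {
  XPtr<KmerIndex> idx(ptr);
  const int k = idx->k;
  const size_t n = idx->table.size();
  CharacterVector kmers(n);
  List ids(n);
  static const char bases[] = "ACGT";
  std::string buf(k, 'A');
  size_t i = 0;
  for (std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
           idx->table.begin(); it != idx->table.end(); ++it, ++i) {
    uint64_t code = it->first;
    for (int p = k - 1; p >= 0; --p) { buf[p] = bases[code & 3]; code >>= 2; }
    kmers[i] = buf;
    IntegerVector v(it->second.size());
    for (size_t j = 0; j < it->second.size(); ++j) v[j] = it->second[j] + 1;
    ids[i] = v;
  }
  return List::create(_["kmer"] = kmers, _["ids"] = ids);
}

static const char INDEX_MAGIC[8] = {'S','C','K','I','D','X','0','1'};

// [[Rcpp::export(name = ".save_index_cpp")]]
void save_index_cpp(SEXP ptr, CharacterVector tx_ids, std::string path) {
  XPtr<KmerIndex> idx(ptr);
  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  std::fwrite(INDEX_MAGIC, 1, 8, f);
  int32_t k = idx->k, ntx = idx->n_transcripts;
  std::fwrite(&k, 4, 1, f);
  std::fwrite(&ntx, 4, 1, f);
  for (int t = 0; t < ntx; ++t) {
    const char* s = CHAR(STRING_ELT(tx_ids, t));
    uint32_t len = (uint32_t) LENGTH(STRING_ELT(tx_ids, t));
    std::fwrite(&len, 4, 1, f);
    std::fwrite(s, 1, len, f);
  }
  uint64_t nk = idx->table.size();
  std::fwrite(&nk, 8, 1, f);
  for (std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
           idx->table.begin(); it != idx->table.end(); ++it) {
    uint64_t key = it->first;
    uint32_t nids = (uint32_t) it->second.size();
    std::fwrite(&key, 8, 1, f);
    std::fwrite(&nids, 4, 1, f);
    std::fwrite(it->second.data(), 4, nids, f);
  }
  std::fclose(f);
}

// [[Rcpp::export(name = ".load_index_cpp")]]
List load_index_cpp(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open index file '%s'", path.c_str());
  char magic[8];
  if (std::fread(magic, 1, 8, f) != 8 ||
      !std::equal(magic, magic + 8, INDEX_MAGIC)) {
    std::fclose(f);
    stop("'%s' is not a strandcheck index (bad or missing header); rebuild it",
         path.c_str());
  }
  int32_t k = 0, ntx = 0;
  if (std::fread(&k, 4, 1, f) != 1 || std::fread(&ntx, 4, 1, f) != 1 ||
      k < 11 || k > 31 || ntx < 1) {
    std::fclose(f);
    stop("corrupt index file '%s'; rebuild it", path.c_str());
  }
  CharacterVector tx_ids(ntx);
  std::vector<char> buf;
  for (int t = 0; t < ntx; ++t) {
    uint32_t len;
    if (std::fread(&len, 4, 1, f) != 1 || len > (1u << 20)) {
      std::fclose(f); stop("corrupt index file '%s'; rebuild it", path.c_str());
    }
    buf.resize(len);
    if (len && std::fread(buf.data(), 1, len, f) != len) {
      std::fclose(f); stop("corrupt index file '%s'; rebuild it", path.c_str());
    }
    tx_ids[t] = std::string(buf.begin(), buf.end());
  }
  uint64_t nk = 0;
  if (std::fread(&nk, 8, 1, f) != 1) {
    std::fclose(f); stop("corrupt index file '%s'; rebuild it", path.c_str());
  }
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->n_transcripts = ntx;
  idx->table.reserve((size_t) nk);
  for (uint64_t i = 0; i < nk; ++i) {
    uint64_t key;
    uint32_t nids;
    if (std::fread(&key, 8, 1, f) != 1 || std::fread(&nids, 4, 1, f) != 1 ||
        nids == 0 || nids > (uint32_t) ntx) {
      std::fclose(f); delete idx;
      stop("corrupt index file '%s' (truncated at k-mer %u); rebuild it",
           path.c_str(), (unsigned) i);
    }
    std::vector<int> v(nids);
    if (std::fread(v.data(), 4, nids, f) != nids) {
      std::fclose(f); delete idx;
      stop("corrupt index file '%s' (truncated at k-mer %u); rebuild it",
           path.c_str(), (unsigned) i);
    }
    idx->table[key].swap(v);
  }
  std::fclose(f);
  XPtr<KmerIndex> xp(idx, true);
  return List::create(_["ptr"] = xp, _["k"] = (int) k, _["tx_ids"] = tx_ids,
                      _["n_kmers"] = (double) nk);
}
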