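// Alignment kernels: k-mer indexed maximal-exact-match (MEM) enumeration,
// max-weight collinear chaining, banded global alignment, SAM pileup tally,
// per-block mismatch extraction and a MEM-vote short-read mapper.
// Coordinates are 0-based half-open throughout.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}
static inline char compbase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = compbase(r[i]);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

struct KmerEntry {
  uint64_t kmer;
  uint32_t chrom;
  uint32_t pos;
};

struct RefIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<KmerEntry> tab;  // sorted by (kmer, chrom, pos)
};

// [[Rcpp::export]]
SEXP cpp_ref_index(CharacterVector seqs, int k) {
  if (k < 12 || k > 31) stop("seed length must be in [12, 31]");
  RefIndex* idx = new RefIndex();
  idx->k = k;
  CharacterVector nm = seqs.names();
  for (int c = 0; c < seqs.size(); ++c) {
    idx->names.push_back(nm.size() ? as<std::string>(nm[c]) : std::to_string(c + 1));
    idx->seqs.push_back(as<std::string>(seqs[c]));
  }
  size_t total = 0;
  for (auto& s : idx->seqs) if ((int)s.size() >= k) total += s.size() - k + 1;
  idx->tab.reserve(total);
  for (size_t c = 0; c < idx->seqs.size(); ++c) {
    const std::string& s = idx->seqs[c];
    if ((int)s.size() < k) continue;
    // rolling 2-bit encoding; restart after ambiguous bases
    uint64_t v = 0; int run = 0;
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)b) & mask;
      if (++run >= k) idx->tab.push_back({v, (uint32_t)c, (uint32_t)(i + 1 - k)});
    }
  }
  std::sort(idx->tab.begin(), idx->tab.end(), [](const KmerEntry& a, const KmerEntry& b) {
    if (a.kmer != b.kmer) return a.kmer < b.kmer;
    if (a.chrom != b.chrom) return a.chrom < b.chrom;
    return a.pos < b.pos;
  });
  XPtr<RefIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
CharacterVector cpp_index_names(SEXP xp) {
  XPtr<RefIndex> idx(xp);
  return wrap(idx->names);
}

struct Mem { int qs, qe; uint32_t chrom; long rs, re; };

// Enumerate all MEMs of length >= idx->k between Q (one orientation) and the
// reference. Seeds at every query offset; containment on the same diagonal is
// skipped via a per-diagonal high-water mark (seeds scanned left to right).
static void mems_one_strand(const RefIndex* idx, const std::string& Q,
                            int max_hits, std::vector<Mem>& out) {
  const int k = idx->k;
  const long qlen = (long)Q.size();
  if (qlen < k) return;
  std::unordered_map<uint64_t, long> diag_end;  // key -> q_end of last MEM
  diag_end.reserve(256);
  uint64_t v = 0; int run = 0;
  uint64_t mask = ((1ULL << (2 * k)) - 1);
  for (long i = 0; i + 1 <= qlen; ++i) {
    int b = base2bit(Q[i]);
    if (b < 0) { run = 0; v = 0; continue; }
    v = ((v << 2) | (uint64_t)b) & mask;
    if (++run < k) continue;
    long qpos = i + 1 - k;  // seed start
    KmerEntry probe{v, 0, 0};
    auto lo = std::lower_bound(idx->tab.begin(), idx->tab.end(), probe,
      [](const KmerEntry& a, const KmerEntry& b2) { return a.kmer < b2.kmer; });
    auto hi = lo;
    while (hi != idx->tab.end() && hi->kmer == v) ++hi;
    if (max_hits > 0 && (hi - lo) > max_hits) continue;
    for (auto it = lo; it != hi; ++it) {
      const std::string& R = idx->seqs[it->chrom];
      long rpos = (long)it->pos;
      long diag = rpos - qpos;
      uint64_t key = ((uint64_t)it->chrom << 42) | (uint64_t)(diag + qlen);
      auto de = diag_end.find(key);
      if (de != diag_end.end() && de->second >= qpos + k) continue;  // contained
      long qs = qpos, rs = rpos;
      while (qs > 0 && rs > 0 && base2bit(Q[qs - 1]) >= 0 && Q[qs - 1] == R[rs - 1]) { --qs; --rs; }
      long qe = qpos + k, re = rpos + k;
      long rlen = (long)R.size();
      while (qe < qlen && re < rlen && base2bit(Q[qe]) >= 0 && Q[qe] == R[re]) { ++qe; ++re; }
      diag_end[key] = qe;
      out.push_back({(int)qs, (int)qe, it->chrom, rs, re});
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_find_mems(SEXP xp, std::string query, int max_hits) {
  XPtr<RefIndex> idx(xp);
  std::vector<Mem> plus, minus;
  mems_one_strand(idx, query, max_hits, plus);
  std::string qrc = revcomp(query);
  mems_one_strand(idx, qrc, max_hits, minus);
  long qlen = (long)query.size();
  size_t n = plus.size() + minus.size();
  IntegerVector qs(n), qe(n), chrom(n);
  NumericVector rs(n), re(n);
  CharacterVector strand(n);
  size_t o = 0;
  for (auto& m : plus) {
    qs[o] = m.qs; qe[o] = m.qe; chrom[o] = m.chrom + 1;
    rs[o] = (double)m.rs; re[o] = (double)m.re; strand[o] = "+"; ++o;
  }
  for (auto& m : minus) {
    // convert rc-frame query coords back to the original frame
    qs[o] = (int)(qlen - m.qe); qe[o] = (int)(qlen - m.qs); chrom[o] = m.chrom + 1;
    rs[o] = (double)m.rs; re[o] = (double)m.re; strand[o] = "-"; ++o;
  }
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["chrom_i"] = chrom, _["r_start"] = rs,
                           _["r_end"] = re, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// Max-weight collinear chains over one anchor group (same contig, chrom,
// strand, coordinates already in a co-increasing frame). Weight = anchor
// length, no gap penalty. Chains extracted greedily (best first, members
// removed) until weight < min_weight or max_chains reached. Returns a list of
// 1-based index vectors into the input.
// [[Rcpp::export]]
List cpp_chain(IntegerVector qs, IntegerVector qe, NumericVector rs,
               NumericVector re, double min_weight, int max_chains) {
  int n = qs.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (qs[a] != qs[b]) return qs[a] < qs[b];
    if (rs[a] != rs[b]) return rs[a] < rs[b];
    if (qe[a] != qe[b]) return qe[a] < qe[b];
    return re[a] < re[b];
  });
  std::vector<bool> used(n, false);
  List chains;
  for (int iter = 0; iter < max_chains; ++iter) {
    std::vector<double> best(n, 0.0);
    std::vector<int> par(n, -1);
    double gbest = -1.0; int gidx = -1;
    for (int oi = 0; oi < n; ++oi) {
      int i = ord[oi];
      if (used[i]) continue;
      double w = (double)(qe[i] - qs[i]);
      best[i] = w; par[i] = -1;
      for (int oj = 0; oj < oi; ++oj) {
        int j = ord[oj];
        if (used[j]) continue;
        if (qs[j] < qs[i] && qe[j] < qe[i] && rs[j] < rs[i] && re[j] < re[i]) {
          if (best[j] + w > best[i]) { best[i] = best[j] + w; par[i] = j; }
        }
      }
      if (best[i] > gbest) { gbest = best[i]; gidx = i; }
    }
    if (gidx < 0 || gbest < min_weight) break;
    std::vector<int> members;
    for (int c = gidx; c >= 0; c = par[c]) { members.push_back(c + 1); used[c] = true; }
    std::reverse(members.begin(), members.end());
    chains.push_back(wrap(members));
    bool any = false;
    for (int i = 0; i < n; ++i) if (!used[i]) { any = true; break; }
    if (!any) break;
  }
  return chains;
}

// Banded global (Needleman-Wunsch) alignment of a (query rows) vs b (ref
// cols); linear gap penalty. CIGAR ops: M (both), I (consumes a), D
// (consumes b). Tie-break M > D > I. band_extra widens the band beyond the
// length difference on each side.
// [[Rcpp::export]]
List cpp_banded_global(std::string a, std::string b, int band_extra,
                       double match, double mismatch, double gap) {
  const long la = (long)a.size(), lb = (long)b.size();
  const long diff = lb - la;
  long dmin = std::min(0L, diff) - band_extra;
  long dmax = std::max(0L, diff) + band_extra;
  const long width = dmax - dmin + 1;
  const double NEG = -1e18;
  std::vector<double> S((la + 1) * width, NEG);
  std::vector<int8_t> D((la + 1) * width, 0);  // 1=M 2=D(left) 3=I(up)
  auto at = [&](long i, long j) -> long { return i * width + (j - (i + dmin)); };
  auto valid = [&](long i, long j) -> bool {
    return j >= 0 && j <= lb && j >= i + dmin && j <= i + dmax;
  };
  S[at(0, 0)] = 0.0;
  for (long j = 1; j <= lb && j <= dmax; ++j) { S[at(0, j)] = gap * j; D[at(0, j)] = 2; }
  for (long i = 1; i <= la && 0 >= i + dmin; ++i) { S[at(i, 0)] = gap * i; D[at(i, 0)] = 3; }
  for (long i = 1; i <= la; ++i) {
    long jlo = std::max(1L, i + dmin), jhi = std::min(lb, i + dmax);
    for (long j = jlo; j <= jhi; ++j) {
      double sm = NEG, sd = NEG, si = NEG;
      if (valid(i - 1, j - 1) && S[at(i - 1, j - 1)] > NEG / 2)
        sm = S[at(i - 1, j - 1)] + ((a[i - 1] == b[j - 1] && base2bit(a[i - 1]) >= 0) ? match : mismatch);
      if (valid(i, j - 1) && S[at(i, j - 1)] > NEG / 2) sd = S[at(i, j - 1)] + gap;
      if (valid(i - 1, j) && S[at(i - 1, j)] > NEG / 2) si = S[at(i - 1, j)] + gap;
      double bs = sm; int8_t bd = 1;
      if (sd > bs) { bs = sd; bd = 2; }
      if (si > bs) { bs = si; bd = 3; }
      S[at(i, j)] = bs; D[at(i, j)] = bd;
    }
  }
  // traceback
  long i = la, j = lb;
  if (!valid(i, j) || S[at(i, j)] <= NEG / 2)
    stop("banded alignment: end cell outside band");
  std::string ops;
  long matches = 0, columns = 0;
  bool band_hit = false;
  while (i > 0 || j > 0) {
    if (i > 0 && i < la && j > 0 && j < lb && (j == i + dmin || j == i + dmax))
      band_hit = true;
    int8_t d = D[at(i, j)];
    if (d == 1) {
      if (a[i - 1] == b[j - 1] && base2bit(a[i - 1]) >= 0) ++matches;
      ops.push_back('M'); --i; --j;
    } else if (d == 2) { ops.push_back('D'); --j; }
    else { ops.push_back('I'); --i; }
    ++columns;
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  for (size_t p = 0; p < ops.size();) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p); cig.push_back(ops[p]);
    p = q;
  }
  return List::create(_["score"] = S[at(la, lb)], _["cigar"] = cig,
                      _["matches"] = (double)matches, _["columns"] = (double)columns,
                      _["band_hit"] = band_hit);
}

// Walk a block CIGAR (M/I/D over oriented query segment qseq vs reference
// segment rseq) and report mismatching M columns plus match/M-column counts.
// Offsets are 0-based into qseq / rseq.
// [[Rcpp::export]]
List cpp_block_mismatches(std::string qseq, std::string rseq, std::string cigar) {
  std::vector<int> qoff, roff;
  long qi = 0, ri = 0, mcols = 0, matches = 0, columns = 0;
  size_t p = 0;
  while (p < cigar.size()) {
    long n = 0;
    while (p < cigar.size() && isdigit(cigar[p])) { n = n * 10 + (cigar[p] - '0'); ++p; }
    char op = cigar[p++];
    if (op == 'M') {
      for (long t = 0; t < n; ++t) {
        char qa = qseq[qi + t], ra = rseq[ri + t];
        bool ok = base2bit(qa) >= 0 && base2bit(ra) >= 0;
        if (ok && qa == ra) ++matches;
        else if (ok) { qoff.push_back((int)(qi + t)); roff.push_back((int)(ri + t)); }
        // ambiguous columns counted as columns but neither match nor SNP
      }
      qi += n; ri += n; mcols += n; columns += n;
    } else if (op == 'I') { qi += n; columns += n; }
    else if (op == 'D') { ri += n; columns += n; }
    else stop("unsupported CIGAR op in block");
  }
  if (qi != (long)qseq.size() || ri != (long)rseq.size())
    stop("block CIGAR does not span its sequences");
  return List::create(_["q_off"] = wrap(qoff), _["r_off"] = wrap(roff),
                      _["m_columns"] = (double)mcols, _["matches"] = (double)matches,
                      _["columns"] = (double)columns);
}

// Pileup over one contig from SAM-subset records (pos 0-based, CIGAR with
// M/I/D/S/H/=/X). Bases below min_base_qual are not tallied at all. Columns
// outside the contig are skipped. Allele order: A,C,G,T,del.
// [[Rcpp::export]]
List cpp_pileup(int contig_len, IntegerVector pos, CharacterVector cigar,
                CharacterVector seq, CharacterVector qual, int min_base_qual) {
  IntegerMatrix counts(contig_len, 5);
  NumericMatrix qsum(contig_len, 5);
  std::vector<int> ins_pos;
  std::vector<std::string> ins_seq;
  std::vector<double> ins_qual;
  int nreads = pos.size();
  for (int r = 0; r < nreads; ++r) {
    std::string cg = as<std::string>(cigar[r]);
    std::string sq = as<std::string>(seq[r]);
    std::string ql = as<std::string>(qual[r]);
    bool have_qual = ql.size() == sq.size();
    long ri = pos[r], qi = 0;
    int last_q = min_base_qual;  // qual carried onto deletion columns
    size_t p = 0;
    while (p < cg.size()) {
      long n = 0;
      while (p < cg.size() && isdigit(cg[p])) { n = n * 10 + (cg[p] - '0'); ++p; }
      char op = cg[p++];
      if (op == 'M' || op == '=' || op == 'X') {
        for (long t = 0; t < n; ++t) {
          int q = have_qual ? (ql[qi + t] - 33) : 40;
          if (ri + t >= 0 && ri + t < contig_len && q >= min_base_qual) {
            int b = base2bit(sq[qi + t]);
            if (b >= 0) { counts(ri + t, b)++; qsum(ri + t, b) += q; }
          }
          last_q = have_qual ? (ql[qi + t] - 33) : 40;
        }
        ri += n; qi += n;
      } else if (op == 'I') {
        double mq = 0;
        for (long t = 0; t < n; ++t) mq += have_qual ? (ql[qi + t] - 33) : 40;
        mq /= std::max(1L, n);
        long anchor = ri - 1;  // inserted after this contig position
        if (anchor >= 0 && anchor < contig_len && mq >= min_base_qual) {
          ins_pos.push_back((int)anchor);
          ins_seq.push_back(sq.substr(qi, n));
          ins_qual.push_back(mq);
        }
        qi += n;
      } else if (op == 'D') {
        for (long t = 0; t < n; ++t) {
          if (ri + t >= 0 && ri + t < contig_len && last_q >= min_base_qual) {
            counts(ri + t, 4)++; qsum(ri + t, 4) += last_q;
          }
        }
        ri += n;
      } else if (op == 'S') { qi += n; }
      else if (op == 'H') { /* consumes nothing */ }
      else stop("unsupported CIGAR op in SAM record");
    }
  }
  return List::create(_["counts"] = counts, _["qsum"] = qsum,
                      _["ins_pos"] = wrap(ins_pos), _["ins_seq"] = wrap(ins_seq),
                      _["ins_qual"] = wrap(ins_qual));
}

// MEM-vote read mapper: for each read, MEMs on both strands are grouped by
// (chrom, strand, diagonal bucket); the best-weight bucket gives the
// placement estimate, the best bucket >2 buckets away (or other chrom/strand)
// the runner-up weight used for uniqueness calls.
// [[Rcpp::export]]
List cpp_map_reads(SEXP xp, CharacterVector reads, int max_hits, int diag_bucket) {
  XPtr<RefIndex> idx(xp);
  int n = reads.size();
  IntegerVector chrom(n), strand(n);
  NumericVector pos(n), score(n), score2(n);
  std::vector<Mem> mems;
  for (int r = 0; r < n; ++r) {
    std::string rd = as<std::string>(reads[r]);
    std::unordered_map<uint64_t, double> wt;
    std::unordered_map<uint64_t, long> dg;
    for (int st = 0; st < 2; ++st) {
      mems.clear();
      std::string Q = st == 0 ? rd : revcomp(rd);
      mems_one_strand(idx, Q, max_hits, mems);
      for (auto& m : mems) {
        long diag = m.rs - m.qs;
        uint64_t key = ((uint64_t)m.chrom << 34) | ((uint64_t)st << 33) |
                       (uint64_t)((diag + (long)rd.size()) / diag_bucket);
        wt[key] += (double)(m.qe - m.qs);
        auto f = dg.find(key);
        if (f == dg.end() || diag < f->second) dg[key] = diag;
      }
    }
    double b1 = 0, b2 = 0; uint64_t k1 = 0;
    for (auto& kv : wt) if (kv.second > b1) { b1 = kv.second; k1 = kv.first; }
    for (auto& kv : wt) {
      if (kv.second > b2 && kv.first != k1) {
        // adjacent buckets on the same chrom/strand are the same locus
        if ((kv.first >> 33) == (k1 >> 33) &&
            std::llabs((long long)(kv.first & ((1ULL << 33) - 1)) -
                       (long long)(k1 & ((1ULL << 33) - 1))) <= 2) continue;
        b2 = kv.second;
      }
    }
    if (b1 <= 0) { chrom[r] = NA_INTEGER; strand[r] = NA_INTEGER; pos[r] = NA_REAL; score[r] = 0; score2[r] = 0; continue; }
    chrom[r] = (int)(k1 >> 34) + 1;
    strand[r] = (int)((k1 >> 33) & 1);  // 0 = +, 1 = -
    pos[r] = (double)dg[k1];
    score[r] = b1; score2[r] = b2;
  }
  return List::create(_["chrom_i"] = chrom, _["strand_i"] = strand,
                      _["diag"] = pos, _["score"] = score, _["score2"] = score2);
}
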