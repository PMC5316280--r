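#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit base encoding; -1 for anything but A/C/G/T
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// mismatches between read[r0, r0+n) and ctg[c0, c0+n); caller guarantees bounds
static inline int mm_count(const std::string& read, int r0,
                           const std::string& ctg, int c0, int n,
                           int stop_at) {
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    if (read[r0 + i] != ctg[c0 + i]) {
      if (++mm > stop_at) return mm;
    }
  }
  return mm;
}

struct Candidate {
  int contig;
  int start;
  int strand; // 0 = +, 1 = -
  bool operator<(const Candidate& o) const {
    if (contig != o.contig) return contig < o.contig;
    if (start != o.start) return start < o.start;
    return strand < o.strand;
  }
  bool operator==(const Candidate& o) const {
    return contig == o.contig && start == o.start && strand == o.strand;
  }
};

struct Placement {
  int mm = INT_MAX;
  int contig = -1;
  int start = -1;
  int strand = 0;
  int gap_j = -1;     // breakpoint within read for 1-nt indel, -1 = ungapped
  char gap_op = 'M';  // 'D' (consensus extra base) or 'I' (read extra base)
  bool better_than(const Placement& o) const {
    if (mm != o.mm) return mm < o.mm;
    if (contig != o.contig) return contig < o.contig;
    if (start != o.start) return start < o.start;
    if (strand != o.strand) return strand < o.strand;
    if (gap_op != o.gap_op) return gap_op < o.gap_op; // 'D' < 'I' < 'M'
    return gap_j < o.gap_j;
  }
};

// Try 1-nt-indel placements of read at left diagonal L on contig; update best.
static void indel_rescue(const std::string& read, const std::string& ctg,
                         int L, int contig, int strand, int max_mm,
                         Placement& best) {
  const int rlen = (int)read.size(), clen = (int)ctg.size();
  if (L < 0) return;
  std::vector<int> pref(rlen + 1, 0);
  int reach = std::min(rlen, clen - L);
  for (int j = 0; j < rlen; ++j) {
    pref[j + 1] = (j < reach) ? pref[j] + (read[j] != ctg[L + j]) : INT_MAX / 2;
  }
  // deletion in read (contig has one extra base): jM 1D (rlen-j)M
  if (L + rlen + 1 <= clen) {
    std::vector<int> sufD(rlen + 1, 0);
    for (int j = rlen - 1; j >= 0; --j)
      sufD[j] = sufD[j + 1] + (read[j] != ctg[L + j + 1]);
    for (int j = 1; j <= rlen - 1; ++j) {
      int cost = (pref[j] >= INT_MAX / 2) ? INT_MAX / 2 : pref[j] + sufD[j];
      if (cost <= max_mm) {
        Placement p; p.mm = cost; p.contig = contig; p.start = L;
        p.strand = strand; p.gap_j = j; p.gap_op = 'D';
        if (p.better_than(best)) best = p;
      }
    }
  }
  // insertion in read (read has one extra base): jM 1I (rlen-j-1)M
  if (L + rlen - 1 <= clen && rlen >= 3) {
    std::vector<int> sufI(rlen + 1, 0);
    sufI[rlen] = 0; sufI[rlen - 1] = 0; // read[rlen-1] inserted at j=rlen-1 not allowed (j<=rlen-2)
    for (int j = rlen - 2; j >= 0; --j)
      sufI[j] = sufI[j + 1] + (read[j + 1] != ctg[L + j]);
    for (int j = 1; j <= rlen - 2; ++j) {
      int cost = (pref[j] >= INT_MAX / 2) ? INT_MAX / 2 : pref[j] + sufI[j];
      if (cost <= max_mm) {
        Placement p; p.mm = cost; p.contig = contig; p.start = L;
        p.strand = strand; p.gap_j = j; p.gap_op = 'I';
        if (p.better_than(best)) best = p;
      }
    }
  }
}

// [[Rcpp::export]]
List map_reads_cpp(CharacterVector read_seqs,
                   CharacterVector contig_seqs,
                   int k, int max_mismatch, bool gap_rescue) {
  const int nc = contig_seqs.size(), nr = read_seqs.size();
  std::vector<std::string> ctg(nc);
  for (int i = 0; i < nc; ++i) ctg[i] = as<std::string>(contig_seqs[i]);

  // k-mer index over all contig positions
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
  index.reserve(1 << 20);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int c = 0; c < nc; ++c) {
    const std::string& s = ctg[c];
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[h].push_back(std::make_pair(c, i - k + 1));
    }
  }

  IntegerVector out_contig(nr, NA_INTEGER), out_start(nr, NA_INTEGER),
                out_mm(nr, NA_INTEGER);
  CharacterVector out_cigar(nr), out_strand(nr), out_seq(nr);
  LogicalVector out_mapped(nr);

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    const int rlen = (int)fwd.size();
    out_mapped[r] = false;
    out_cigar[r] = NA_STRING; out_strand[r] = NA_STRING; out_seq[r] = NA_STRING;
    if (rlen < k) continue;
    std::string rev = revcomp(fwd);

    std::vector<Candidate> cands;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& read = strand ? rev : fwd;
      // seeds at non-overlapping offsets plus the final window
      std::vector<int> offs;
      for (int o = 0; o + k <= rlen; o += k) offs.push_back(o);
      if (offs.empty() || offs.back() != rlen - k) offs.push_back(rlen - k);
      for (int o : offs) {
        uint64_t h = 0; bool ok = true;
        for (int i = 0; i < k; ++i) {
          int b = base_code(read[o + i]);
          if (b < 0) { ok = false; break; }
          h = ((h << 2) | (uint64_t)b) & mask;
        }
        if (!ok) continue;
        auto it = index.find(h);
        if (it == index.end()) continue;
        for (auto& hit : it->second) {
          int start = hit.second - o;
          if (start < 0 || start + rlen > (int)ctg[hit.first].size()) continue;
          Candidate cd; cd.contig = hit.first; cd.start = start; cd.strand = strand;
          cands.push_back(cd);
        }
      }
    }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    Placement best;
    for (auto& cd : cands) {
      const std::string& read = cd.strand ? rev : fwd;
      int mm = mm_count(read, 0, ctg[cd.contig], cd.start, rlen, max_mismatch);
      if (mm <= max_mismatch) {
        Placement p; p.mm = mm; p.contig = cd.contig; p.start = cd.start;
        p.strand = cd.strand; p.gap_j = -1; p.gap_op = 'M';
        if (p.better_than(best)) best = p;
      }
    }
    if (best.contig < 0 && gap_rescue) {
      size_t limit = std::min(cands.size(), (size_t)64);
      for (size_t ci = 0; ci < limit; ++ci) {
        const Candidate& cd = cands[ci];
        const std::string& read = cd.strand ? rev : fwd;
        for (int dL = -1; dL <= 1; ++dL)
          indel_rescue(read, ctg[cd.contig], cd.start + dL, cd.contig,
                       cd.strand, max_mismatch, best);
      }
    }
    if (best.contig >= 0) {
      out_mapped[r] = true;
      out_contig[r] = best.contig + 1;
      out_start[r] = best.start;
      out_mm[r] = best.mm;
      out_strand[r] = best.strand ? "-" : "+";
      out_seq[r] = best.strand ? rev : fwd;
      std::string cig;
      if (best.gap_j < 0) {
        cig = std::to_string(rlen) + "M";
      } else if (best.gap_op == 'D') {
        cig = std::to_string(best.gap_j) + "M1D" +
              std::to_string(rlen - best.gap_j) + "M";
      } else {
        cig = std::to_string(best.gap_j) + "M1I" +
              std::to_string(rlen - best.gap_j - 1) + "M";
      }
      out_cigar[r] = cig;
    }
  }
  return List::create(_["contig"] = out_contig, _["start"] = out_start,
                      _["cigar"] = out_cigar, _["strand"] = out_strand,
                      _["mapped"] = out_mapped, _["mismatches"] = out_mm,
                      _["seq"] = out_seq);
}

// [[Rcpp::export]]
List pileup_cpp(int contig_len, IntegerVector starts, CharacterVector cigars,
                CharacterVector seqs) {
  IntegerMatrix bases(5, contig_len); // rows A,C,G,T,N
  IntegerVector delcov(contig_len);   // reads deleting this position
  IntegerVector jcov(contig_len);     // junction after pos i spanned with no insertion
  std::map<std::pair<int, int>, int> dels;          // (pos, len) -> count
  std::map<std::pair<int, std::string>, int> ins;   // (pos anchored-after, seq) -> count

  const int n = starts.size();
  for (int a = 0; a < n; ++a) {
    if (cigars[a] == NA_STRING) continue;
    std::string cig = as<std::string>(cigars[a]);
    std::string seq = as<std::string>(seqs[a]);
    int rpos = starts[a]; // next reference position
    int qpos = 0;         // next query position
    int last_ref = -2;    // last reference position consumed by M/D
    bool ins_since = false;
    size_t i = 0;
    while (i < cig.size()) {
      long len = 0;
      while (i < cig.size() && isdigit(cig[i])) len = len * 10 + (cig[i++] - '0');
      if (i >= cig.size()) break;
      char op = cig[i++];
      if (op == '=' || op == 'X') op = 'M';
      if (op == 'M') {
        for (long j = 0; j < len; ++j) {
          int t = rpos + (int)j;
          if (t < 0 || t >= contig_len) stop("alignment overruns contig end");
          char b = seq[qpos + j];
          int bi = base_code(b);
          bases(bi < 0 ? 4 : bi, t) += 1;
          if (last_ref == t - 1 && !ins_since && t >= 1) jcov[t - 1] += 1;
          last_ref = t; ins_since = false;
        }
        rpos += len; qpos += len;
      } else if (op == 'D' || op == 'N') {
        if (rpos + len > contig_len) stop("alignment overruns contig end");
        if (op == 'D') {
          for (long j = 0; j < len; ++j) {
            int t = rpos + (int)j;
            delcov[t] += 1;
            if (last_ref == t - 1 && !ins_since && t >= 1) jcov[t - 1] += 1;
            last_ref = t; ins_since = false;
          }
          dels[std::make_pair(rpos, (int)len)] += 1;
        } else {
          last_ref = -2;
        }
        rpos += len;
      } else if (op == 'I') {
        int anchor = rpos - 1;
        if (anchor >= 0)
          ins[std::make_pair(anchor, seq.substr(qpos, len))] += 1;
        ins_since = true;
        qpos += len;
      } else if (op == 'S') {
        qpos += len;
      } // H, P: nothing
    }
  }

  int nd = dels.size();
  IntegerVector dpos(nd), dlen(nd), dcount(nd);
  int di = 0;
  for (auto& kv : dels) {
    dpos[di] = kv.first.first; dlen[di] = kv.first.second; dcount[di] = kv.second; ++di;
  }
  int ni = ins.size();
  IntegerVector ipos(ni), icount(ni);
  CharacterVector iseq(ni);
  int ii = 0;
  for (auto& kv : ins) {
    ipos[ii] = kv.first.first; iseq[ii] = kv.first.second; icount[ii] = kv.second; ++ii;
  }
  return List::create(_["bases"] = bases, _["delcov"] = delcov, _["jcov"] = jcov,
                      _["del_pos"] = dpos, _["del_len"] = dlen, _["del_count"] = dcount,
                      _["ins_pos"] = ipos, _["ins_seq"] = iseq, _["ins_count"] = icount);
}
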