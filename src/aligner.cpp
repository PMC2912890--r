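// k-mer seeded candidate detection and affine-gap local alignment.
// Replaces the all-to-all BLAST-style search stage: pairs sharing an exact
// w-mer (either strand) are aligned with full Smith-Waterman; identity and
// footprint statistics feed the edge-admission filter.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;  // N and anything else: never seeds, never matches
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// Enumerate valid (N-free) w-mers of s as 2-bit packed integers.
static void kmers_of(const std::string& s, int w,
                     std::vector<uint64_t>& out) {
  out.clear();
  const int n = (int) s.size();
  if (n < w) return;
  uint64_t kmer = 0, mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  int run = 0;  // valid bases accumulated
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) c) & mask;
    if (++run >= w) out.push_back(kmer);
  }
}

// Candidate read pairs sharing at least one exact w-mer, on the forward or
// reverse-complement strand. When same_set is true, seqs_a and seqs_b are the
// same collection and only unordered pairs i < j are reported.
// [[Rcpp::export(name = ".seed_candidates_cpp")]]
DataFrame seed_candidates_cpp(CharacterVector seqs_a, CharacterVector seqs_b,
                              int w, bool same_set) {
  if (w < 1 || w > 32) stop("word size must be between 1 and 32");
  const int nb = seqs_b.size();

  // index: w-mer -> target reads containing it (unique per kmer)
  std::unordered_map<uint64_t, std::vector<int>> index;
  {
    std::vector<uint64_t> buf;
    for (int j = 0; j < nb; ++j) {
      std::string s = as<std::string>(seqs_b[j]);
      kmers_of(s, w, buf);
      std::unordered_set<uint64_t> seen(buf.begin(), buf.end());
      for (uint64_t k : seen) index[k].push_back(j);
    }
  }

  std::vector<int> out_i, out_j, out_strand;
  std::unordered_set<uint64_t> emitted;
  const int na = seqs_a.size();
  std::vector<uint64_t> buf;
  for (int i = 0; i < na; ++i) {
    std::string fwd = as<std::string>(seqs_a[i]);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string s = (strand == 0) ? fwd : revcomp(fwd);
      kmers_of(s, w, buf);
      std::unordered_set<uint64_t> seen(buf.begin(), buf.end());
      for (uint64_t k : seen) {
        auto it = index.find(k);
        if (it == index.end()) continue;
        for (int j : it->second) {
          int a = i, b = j;
          if (same_set) {
            if (i == j) continue;
            if (strand == 1) { a = std::min(i, j); b = std::max(i, j); }
            else if (j > i) continue;  // forward pair found from other side
          }
          uint64_t key = (((uint64_t) a * (uint64_t) nb) + (uint64_t) b) * 2
                         + (uint64_t) strand;
          if (emitted.insert(key).second) {
            out_i.push_back(a + 1);
            out_j.push_back(b + 1);
            out_strand.push_back(strand);
          }
        }
      }
    }
  }
  return DataFrame::create(_["i"] = out_i, _["j"] = out_j,
                           _["strand"] = out_strand);
}

struct AlnResult {
  double score;
  int matches, columns;
  int a_start, a_end, b_start, b_end;  // 1-based, 0 if no alignment
};

// Smith-Waterman with affine gaps; a gap of length L costs open + L * ext.
// Traceback counts matches and alignment columns and records footprints.
static AlnResult sw_align(const std::string& a, const std::string& b,
                          double match, double mismatch,
                          double gap_open, double gap_ext) {
  const int n = (int) a.size(), m = (int) b.size();
  AlnResult res = {0.0, 0, 0, 0, 0, 0, 0};
  if (n == 0 || m == 0) return res;

  const double gap_first = gap_open + gap_ext;
  std::vector<double> H(m + 1, 0.0), E(m + 1, 0.0);
  // traceback: 2 bits H-source (0 stop, 1 diag, 2 E, 3 F),
  //            1 bit E-source (extend), 1 bit F-source (extend)
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);

  double best = 0.0; int bi = 0, bj = 0;
  std::vector<double> Fcol(m + 1, 0.0);  // F for current row, per column
  std::vector<int> acode(n), bcode(m);
  for (int i = 0; i < n; ++i) acode[i] = base_code(a[i]);
  for (int j = 0; j < m; ++j) bcode[j] = base_code(b[j]);

  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;  // H[i-1][j-1]
    double Hrow_prev = 0.0;  // H[i][j-1]
    double Erow = 0.0;       // E[i][j-1] band
    for (int j = 1; j <= m; ++j) {
      uint8_t cell = 0;
      // E: gap in a (consume b)
      double e_open = Hrow_prev - gap_first;
      double e_ext = Erow - gap_ext;
      double Eij = std::max(e_open, e_ext);
      if (e_ext > e_open) cell |= 0x04;
      // F: gap in b (consume a)
      double f_open = H[j] - gap_first;   // H[i-1][j]
      double f_ext = Fcol[j] - gap_ext;
      double Fij = std::max(f_open, f_ext);
      if (f_ext > f_open) cell |= 0x08;
      // H
      double s = (acode[i - 1] >= 0 && acode[i - 1] == bcode[j - 1])
                   ? match : mismatch;
      double h_diag = diag + s;
      double Hij = 0.0; uint8_t src = 0;
      if (h_diag > Hij) { Hij = h_diag; src = 1; }
      if (Eij > Hij) { Hij = Eij; src = 2; }
      if (Fij > Hij) { Hij = Fij; src = 3; }
      cell |= src;
      tb[(size_t) i * (m + 1) + j] = cell;
      diag = H[j];
      H[j] = Hij; Hrow_prev = Hij;
      Erow = Eij; Fcol[j] = Fij;
      if (Hij > best) { best = Hij; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) return res;

  // traceback from (bi, bj)
  int i = bi, j = bj, state = 0;  // 0 = H, 2 = E, 3 = F
  int matches = 0, cols = 0;
  int a_end = bi, b_end = bj, a_start = bi, b_start = bj;
  while (i > 0 && j > 0) {
    uint8_t cell = tb[(size_t) i * (m + 1) + j];
    if (state == 0) {
      uint8_t src = cell & 0x03;
      if (src == 0) break;
      if (src == 1) {
        ++cols;
        if (acode[i - 1] >= 0 && acode[i - 1] == bcode[j - 1]) ++matches;
        a_start = i; b_start = j;
        --i; --j;
      } else {
        state = src;  // enter E or F
      }
    } else if (state == 2) {  // E: gap in a, consume b
      ++cols;
      b_start = j;
      bool ext = (cell & 0x04) != 0;
      --j;
      if (!ext) state = 0;
    } else {  // F: gap in b, consume a
      ++cols;
      a_start = i;
      bool ext = (cell & 0x08) != 0;
      --i;
      if (!ext) state = 0;
    }
  }
  res.score = best;
  res.matches = matches;
  res.columns = cols;
  res.a_start = a_start; res.a_end = a_end;
  res.b_start = b_start; res.b_end = b_end;
  return res;
}

// Align the given candidate pairs. strand == 1 aligns a against the reverse
// complement of b; reported b footprints are in original b coordinates.
// [[Rcpp::export(name = ".align_pairs_cpp")]]
DataFrame align_pairs_cpp(CharacterVector seqs_a, CharacterVector seqs_b,
                          IntegerVector ii, IntegerVector jj,
                          IntegerVector strand,
                          double match, double mismatch,
                          double gap_open, double gap_ext) {
  const int np = ii.size();
  NumericVector score(np);
  IntegerVector matches(np), columns(np),
      a_start(np), a_end(np), b_start(np), b_end(np);
  for (int p = 0; p < np; ++p) {
    std::string a = as<std::string>(seqs_a[ii[p] - 1]);
    std::string b = as<std::string>(seqs_b[jj[p] - 1]);
    bool rc = strand[p] == 1;
    if (rc) b = revcomp(b);
    AlnResult r = sw_align(a, b, match, mismatch, gap_open, gap_ext);
    score[p] = r.score;
    matches[p] = r.matches; columns[p] = r.columns;
    a_start[p] = r.a_start; a_end[p] = r.a_end;
    if (rc && r.score > 0) {
      int lb = (int) b.size();
      b_start[p] = lb - r.b_end + 1;
      b_end[p] = lb - r.b_start + 1;
    } else {
      b_start[p] = r.b_start; b_end[p] = r.b_end;
    }
  }
  return DataFrame::create(
      _["i"] = ii, _["j"] = jj, _["strand"] = strand, _["score"] = score,
      _["matches"] = matches, _["columns"] = columns,
      _["a_start"] = a_start, _["a_end"] = a_end,
      _["b_start"] = b_start, _["b_end"] = b_end);
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  out.names() = seqs.names();
  return out;
}
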