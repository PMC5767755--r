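// Pairwise alignment kernels and k-mer candidate filtering.
//
// Scores use the BLAST gap convention: a gap of length L costs
// gap_open + L * gap_ext, i.e. the first gapped residue costs
// gap_open + gap_ext and each further residue gap_ext.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static const float NEG_INF = -1e30f;

// 256 x 256 lookup built from a dimnamed scoring matrix
struct ScoreTable {
  std::vector<float> tab;
  ScoreTable(const NumericMatrix& sub) : tab(256 * 256, NEG_INF) {
    CharacterVector rn = rownames(sub), cn = colnames(sub);
    for (int i = 0; i < sub.nrow(); ++i) {
      unsigned char a = (unsigned char) CHAR(STRING_ELT(rn, i))[0];
      for (int j = 0; j < sub.ncol(); ++j) {
        unsigned char b = (unsigned char) CHAR(STRING_ELT(cn, j))[0];
        tab[a * 256 + b] = (float) sub(i, j);
      }
    }
  }
  // residues outside the matrix score NEG_INF and are effectively
  // unalignable; alphabet validation happens upstream in R
  inline const float* row(unsigned char a) const { return &tab[a * 256]; }
};

struct AlnResult {
  double score;
  int qstart, qend, sstart, send; // 0-based half-open
  int n_ident, aln_len, n_gap_cols;
};

// Gotoh affine-gap alignment with full traceback.
// local = Smith-Waterman; otherwise global Needleman-Wunsch with
// penalised end gaps.
static AlnResult align_pair(const std::string& a, const std::string& b,
                            const ScoreTable& S, double go, double ge,
                            bool local) {
  const int n = (int) a.size(), m = (int) b.size();
  // scores are exact in single precision: all scoring schemes are
  // integer-valued and far below the float integer limit
  const float open = (float)(go + ge); // cost of first gapped residue
  const float gef = (float) ge;
  // rows: i over a (0..n), cols: j over b (0..m)
  std::vector<float> M((n + 1) * (m + 1), NEG_INF);
  std::vector<float> X((n + 1) * (m + 1), NEG_INF); // gap in b (a consumed)
  std::vector<float> Y((n + 1) * (m + 1), NEG_INF); // gap in a (b consumed)
  // traceback: which state each cell came from (0=M,1=X,2=Y,3=start)
  std::vector<uint8_t> tM((n + 1) * (m + 1), 3), tX((n + 1) * (m + 1), 3),
      tY((n + 1) * (m + 1), 3);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0f;
  for (int i = 1; i <= n; ++i) {
    if (local) { M[idx(i, 0)] = 0.0f; }
    else {
      X[idx(i, 0)] = (float) -(go + ge * i);
      tX[idx(i, 0)] = (i == 1) ? 0 : 1;
    }
  }
  for (int j = 1; j <= m; ++j) {
    if (local) { M[idx(0, j)] = 0.0f; }
    else {
      Y[idx(0, j)] = (float) -(go + ge * j);
      tY[idx(0, j)] = (j == 1) ? 0 : 2;
    }
  }
  float best = 0.0f;
  int bi = 0, bj = 0; uint8_t bstate = 0;
  for (int i = 1; i <= n; ++i) {
    const float* srow = S.row((unsigned char) a[i - 1]);
    float* Mi = &M[idx(i, 0)]; float* Xi = &X[idx(i, 0)];
    float* Yi = &Y[idx(i, 0)];
    const float* Mp = &M[idx(i - 1, 0)]; const float* Xp = &X[idx(i - 1, 0)];
    const float* Yp = &Y[idx(i - 1, 0)];
    uint8_t* tMi = &tM[idx(i, 0)]; uint8_t* tXi = &tX[idx(i, 0)];
    uint8_t* tYi = &tY[idx(i, 0)];
    for (int j = 1; j <= m; ++j) {
      // X: gap in b, consume a[i-1]
      float xv = Mp[j] - open; uint8_t xt = 0;
      if (Xp[j] - gef > xv) { xv = Xp[j] - gef; xt = 1; }
      if (Yp[j] - open > xv) { xv = Yp[j] - open; xt = 2; }
      Xi[j] = xv; tXi[j] = xt;
      // Y: gap in a, consume b[j-1]
      float yv = Mi[j - 1] - open; uint8_t yt = 0;
      if (Yi[j - 1] - gef > yv) { yv = Yi[j - 1] - gef; yt = 2; }
      if (Xi[j - 1] - open > yv) { yv = Xi[j - 1] - open; yt = 1; }
      Yi[j] = yv; tYi[j] = yt;
      // M: match/mismatch
      float mv = Mp[j - 1]; uint8_t mt = 0;
      if (Xp[j - 1] > mv) { mv = Xp[j - 1]; mt = 1; }
      if (Yp[j - 1] > mv) { mv = Yp[j - 1]; mt = 2; }
      mv += srow[(unsigned char) b[j - 1]];
      if (local && mv < 0.0f) { mv = 0.0f; mt = 3; }
      Mi[j] = mv; tMi[j] = mt;
      if (local && mv > best) { best = mv; bi = i; bj = j; bstate = 0; }
    }
  }
  AlnResult r{};
  int i, j; uint8_t st;
  if (local) {
    r.score = (double) best;
    if (best <= 0.0) { // empty alignment
      r.qstart = r.qend = r.sstart = r.send = 0;
      return r;
    }
    i = bi; j = bj; st = bstate;
    r.qend = bi; r.send = bj;
  } else {
    const int ij = idx(n, m);
    float v = M[ij]; st = 0;
    if (X[ij] > v) { v = X[ij]; st = 1; }
    if (Y[ij] > v) { v = Y[ij]; st = 2; }
    r.score = (double) v;
    i = n; j = m; r.qend = n; r.send = m;
  }
  // traceback (local paths stop at the first zero-valued match-state cell)
  while (true) {
    if (local && st == 0 && M[idx(i, j)] <= 0.0f) break;
    if (i == 0 && j == 0) break;
    if (st == 0) {
      uint8_t prev = tM[idx(i, j)];
      ++r.aln_len;
      if (a[i - 1] == b[j - 1]) ++r.n_ident;
      --i; --j;
      st = (prev == 3) ? 0 : prev;
    } else if (st == 1) {
      uint8_t prev = tX[idx(i, j)];
      ++r.aln_len; ++r.n_gap_cols;
      --i; st = prev;
    } else {
      uint8_t prev = tY[idx(i, j)];
      ++r.aln_len; ++r.n_gap_cols;
      --j; st = prev;
    }
  }
  r.qstart = i; r.sstart = j;
  return r;
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, NumericMatrix sub,
               double gap_open, double gap_ext, bool local) {
  if (a.empty() || b.empty()) stop("cannot align an empty sequence");
  ScoreTable S(sub);
  AlnResult r = align_pair(a, b, S, gap_open, gap_ext, local);
  return List::create(
      _["score"] = r.score, _["qstart"] = r.qstart, _["qend"] = r.qend,
      _["sstart"] = r.sstart, _["send"] = r.send, _["n_ident"] = r.n_ident,
      _["aln_len"] = r.aln_len, _["n_gap_cols"] = r.n_gap_cols);
}

// Batch alignment of index pairs (1-based into seqs_a / seqs_b).
// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector seqs_a, CharacterVector seqs_b,
                          IntegerVector ia, IntegerVector ib,
                          NumericMatrix sub, double gap_open, double gap_ext,
                          bool local) {
  ScoreTable S(sub);
  const int np = ia.size();
  NumericVector score(np);
  IntegerVector qstart(np), qend(np), sstart(np), send(np), n_ident(np),
      aln_len(np), n_gap(np);
  for (int p = 0; p < np; ++p) {
    std::string a = as<std::string>(seqs_a[ia[p] - 1]);
    std::string b = as<std::string>(seqs_b[ib[p] - 1]);
    AlnResult r = align_pair(a, b, S, gap_open, gap_ext, local);
    score[p] = r.score; qstart[p] = r.qstart; qend[p] = r.qend;
    sstart[p] = r.sstart; send[p] = r.send; n_ident[p] = r.n_ident;
    aln_len[p] = r.aln_len; n_gap[p] = r.n_gap_cols;
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
      _["score"] = score, _["qstart"] = qstart, _["qend"] = qend,
      _["sstart"] = sstart, _["send"] = send, _["n_ident"] = n_ident,
      _["aln_len"] = aln_len, _["n_gap_cols"] = n_gap);
}

// pack up to 12 characters into a 64-bit kmer code (5 bits per char)
static inline bool kmers_of(const std::string& s, int k,
                            std::vector<uint64_t>& out) {
  out.clear();
  const int n = (int) s.size();
  if (n < k) return false;
  for (int i = 0; i + k <= n; ++i) {
    uint64_t code = 0;
    for (int j = 0; j < k; ++j)
      code = (code << 5) | (uint64_t)((s[i + j] - 'A') & 31);
    out.push_back(code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return true;
}

// Candidate pairs within one sequence set: pairs (i < j) sharing at least
// min_shared distinct k-mers. 1-based indices in the output.
// [[Rcpp::export]]
DataFrame cpp_candidate_pairs(CharacterVector seqs, int k, int min_shared) {
  const int n = seqs.size();
  std::unordered_map<uint64_t, std::vector<int>> postings;
  std::vector<uint64_t> buf;
  for (int i = 0; i < n; ++i) {
    kmers_of(as<std::string>(seqs[i]), k, buf);
    for (uint64_t c : buf) postings[c].push_back(i);
  }
  std::unordered_map<uint64_t, int> counts;
  for (auto& kv : postings) {
    const std::vector<int>& v = kv.second;
    for (size_t x = 0; x < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y)
        ++counts[((uint64_t) v[x] << 32) | (uint64_t) v[y]];
  }
  std::vector<int> ii, jj, sh;
  for (auto& kv : counts)
    if (kv.second >= min_shared) {
      ii.push_back((int)(kv.first >> 32) + 1);
      jj.push_back((int)(kv.first & 0xffffffffu) + 1);
      sh.push_back(kv.second);
    }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["shared"] = sh);
}

// Candidate pairs between a query set and a subject set.
// [[Rcpp::export]]
DataFrame cpp_candidate_pairs_xy(CharacterVector qseqs, CharacterVector sseqs,
                                 int k, int min_shared) {
  std::unordered_map<uint64_t, std::vector<int>> postings;
  std::vector<uint64_t> buf;
  for (int j = 0; j < sseqs.size(); ++j) {
    kmers_of(as<std::string>(sseqs[j]), k, buf);
    for (uint64_t c : buf) postings[c].push_back(j);
  }
  std::vector<int> ii, jj, sh;
  std::unordered_map<int, int> counts;
  for (int i = 0; i < qseqs.size(); ++i) {
    counts.clear();
    kmers_of(as<std::string>(qseqs[i]), k, buf);
    for (uint64_t c : buf) {
      auto it = postings.find(c);
      if (it == postings.end()) continue;
      for (int j : it->second) ++counts[j];
    }
    for (auto& kv : counts)
      if (kv.second >= min_shared) {
        ii.push_back(i + 1); jj.push_back(kv.first + 1);
        sh.push_back(kv.second);
      }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["shared"] = sh);
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    default: return 'N';
  }
}

// Map each fragment onto the subject via shared k-mers (both strands),
// then locally align the fragment against the best-supported window.
// Returns per-fragment identity over aligned columns, alignment length
// and fraction of the fragment covered. Unmapped fragments get NA.
// [[Rcpp::export]]
DataFrame cpp_map_fragments(CharacterVector fragments, std::string subject,
                            int k, int margin, NumericMatrix sub,
                            double gap_open, double gap_ext) {
  ScoreTable S(sub);
  const int m = (int) subject.size();
  // index subject k-mer positions (forward orientation only; fragments are
  // tested forward and reverse-complemented)
  std::unordered_map<uint64_t, std::vector<int>> index;
  if (m >= k) {
    for (int i = 0; i + k <= m; ++i) {
      uint64_t code = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        char c = subject[i + j];
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
        code = (code << 5) | (uint64_t)((c - 'A') & 31);
      }
      if (ok) index[code].push_back(i);
    }
  }
  const int nf = fragments.size();
  NumericVector identity(nf), coverage(nf);
  IntegerVector alen(nf);
  LogicalVector mapped(nf);
  const int BIN = 64;
  for (int f = 0; f < nf; ++f) {
    std::string fr = as<std::string>(fragments[f]);
    std::string fr_rc(fr.rbegin(), fr.rend());
    for (auto& c : fr_rc) c = comp_base(c);
    int best_votes = 0, best_lo = 0, best_hi = 0;
    bool best_rc = false;
    for (int orient = 0; orient < 2; ++orient) {
      const std::string& q = orient ? fr_rc : fr;
      const int n = (int) q.size();
      if (n < k) continue;
      std::unordered_map<int, int> diag_votes;
      std::unordered_map<int, std::pair<int, int>> diag_span; // s range
      for (int i = 0; i + k <= n; ++i) {
        uint64_t code = 0; bool ok = true;
        for (int j = 0; j < k; ++j) {
          char c = q[i + j];
          if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
          code = (code << 5) | (uint64_t)((c - 'A') & 31);
        }
        if (!ok) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        for (int s : it->second) {
          int bin = (s - i) / BIN;
          int v = ++diag_votes[bin];
          auto& sp = diag_span[bin];
          if (v == 1) sp = {s, s};
          else { sp.first = std::min(sp.first, s); sp.second = std::max(sp.second, s); }
        }
      }
      for (auto& kv : diag_votes) {
        // pool with neighbouring bins so diagonals on a bin edge count once
        int v = kv.second;
        int lo = diag_span[kv.first].first, hi = diag_span[kv.first].second;
        for (int nb = -1; nb <= 1; nb += 2) {
          auto it2 = diag_votes.find(kv.first + nb);
          if (it2 != diag_votes.end()) {
            v += it2->second;
            lo = std::min(lo, diag_span[kv.first + nb].first);
            hi = std::max(hi, diag_span[kv.first + nb].second);
          }
        }
        if (v > best_votes) {
          best_votes = v; best_lo = lo; best_hi = hi; best_rc = orient == 1;
        }
      }
    }
    if (best_votes == 0) {
      identity[f] = NA_REAL; coverage[f] = NA_REAL; alen[f] = NA_INTEGER;
      mapped[f] = false;
      continue;
    }
    const std::string& q = best_rc ? fr_rc : fr;
    int lo = std::max(0, best_lo - margin);
    int hi = std::min(m, best_hi + (int) q.size() + margin);
    std::string window = subject.substr(lo, hi - lo);
    AlnResult r = align_pair(q, window, S, gap_open, gap_ext, true);
    mapped[f] = true;
    alen[f] = r.aln_len;
    identity[f] = r.aln_len > 0 ? 100.0 * r.n_ident / r.aln_len : 0.0;
    coverage[f] = (double)(r.qend - r.qstart) / (double) q.size();
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["mapped"] = mapped, _["identity"] = identity,
                           _["aln_len"] = alen, _["coverage"] = coverage);
}

// Fraction of identical positions between two equal-length strings.
// [[Rcpp::export]]
double cpp_hamming_identity(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences differ in length");
  if (a.empty()) stop("empty sequence");
  size_t n_same = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] == b[i]) ++n_same;
  return (double) n_same / (double) a.size();
}
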