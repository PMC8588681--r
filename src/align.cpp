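// Seed-and-extend local nucleotide alignment.
//
// Word hits are located on both strands, extended without gaps under an
// x-drop rule, then polished by a local (Smith-Waterman) gapped alignment
// restricted to a window around the ungapped segment: full-matrix when the
// window is small, banded around the seed diagonal otherwise.  Scores use
// an affine gap model where a gap of length k costs gap_open + k*gap_extend.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <random>
using namespace Rcpp;

static const int BASE_N = 4;

static std::vector<uint8_t> encode(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': case 'U': case 'u': v[i] = 3; break;
      default: v[i] = BASE_N;
    }
  }
  return v;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = (b == BASE_N) ? BASE_N : (uint8_t)(3 - b);
  }
  return r;
}

struct Hsp { int qs, qe, ss, se, score; };

struct Aln {
  int qs, qe, ss, se;      // 0-based half-open on the working strands
  int score, matches, len; // len = alignment columns
};

// ---- ungapped x-drop extension around a word hit -------------------------
static Hsp ungapped_extend(const std::vector<uint8_t>& q,
                           const std::vector<uint8_t>& s,
                           int qpos, int spos, int w,
                           int match, int mismatch, int xdrop) {
  int score = 0;
  for (int k = 0; k < w; ++k) score += match; // word is an exact match
  int best = score;
  int qe = qpos + w, se = spos + w;
  int run = score, bqe = qe;
  // right
  int i = qe, j = se;
  int n_q = (int)q.size(), n_s = (int)s.size();
  while (i < n_q && j < n_s) {
    run += (q[i] != BASE_N && q[i] == s[j]) ? match : mismatch;
    ++i; ++j;
    if (run > best) { best = run; bqe = i; }
    if (best - run > xdrop) break;
  }
  qe = bqe; se = spos + w + (bqe - (qpos + w));
  // left
  run = best;
  int bqs = qpos;
  i = qpos - 1; j = spos - 1;
  while (i >= 0 && j >= 0) {
    run += (q[i] != BASE_N && q[i] == s[j]) ? match : mismatch;
    if (run > best) { best = run; bqs = i; }
    if (best - run > xdrop) break;
    --i; --j;
  }
  Hsp h;
  h.qs = bqs; h.qe = qe;
  h.ss = spos - (qpos - bqs); h.se = se;
  h.score = best;
  return h;
}

// ---- local affine DP with traceback --------------------------------------
// tb byte layout: bits 0-1 = H source (0 stop, 1 diag, 2 from E, 3 from F);
// bit 2 = E extended; bit 3 = F extended.
static const int NEG = -1000000000;

static Aln window_sw(const std::vector<uint8_t>& q, int q0, int q1,
                     const std::vector<uint8_t>& s, int s0, int s1,
                     int match, int mismatch, int go, int ge) {
  int m = q1 - q0, n = s1 - s0;
  std::vector<int> Hp(n + 1, 0), Hc(n + 1, 0), Ep(n + 1, NEG), Ec(n + 1, NEG);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> Fc(n + 1, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hc[0] = 0; Ec[0] = NEG; Fc[0] = NEG;
    uint8_t qb = q[q0 + i - 1];
    uint8_t* tbrow = &tb[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (consumes subject)
      int e_open = Hc[j - 1] - go - ge, e_ext = Ec[j - 1] - ge;
      int E = std::max(e_open, e_ext);
      // F: gap in subject (consumes query)
      int f_open = Hp[j] - go - ge, f_ext = Fc[j] - ge;
      int F = std::max(f_open, f_ext);
      int sc = (qb != BASE_N && qb == s[s0 + j - 1]) ? match : mismatch;
      int diag = Hp[j - 1] + sc;
      int H = 0; uint8_t t = 0;
      if (diag > H) { H = diag; t = 1; }
      if (E > H) { H = E; t = 2; }
      if (F > H) { H = F; t = 3; }
      if (e_ext >= e_open) t |= 4;
      if (f_ext >= f_open) t |= 8;
      Ec[j] = E; Fc[j] = F; Hc[j] = H; tbrow[j] = t;
      if (H > best) { best = H; bi = i; bj = j; }
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec);
  }
  Aln a; a.score = best; a.matches = 0; a.len = 0;
  if (best <= 0) { a.qs = a.qe = a.ss = a.se = 0; return a; }
  // traceback
  int i = bi, j = bj, state = 0; // 0 = H
  while (true) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      int src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        a.len++;
        if (q[q0 + i - 1] != BASE_N && q[q0 + i - 1] == s[s0 + j - 1]) a.matches++;
        --i; --j;
      } else if (src == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // E: gap in query, consumed subject col j
      a.len++;
      bool ext = (t & 4) != 0;
      --j;
      state = ext ? 2 : 0;
    } else { // F: gap in subject, consumed query row i
      a.len++;
      bool ext = (t & 8) != 0;
      --i;
      state = ext ? 3 : 0;
    }
    if (i == 0 || j == 0) break;
  }
  a.qs = q0 + i; a.qe = q0 + bi;
  a.ss = s0 + j; a.se = s0 + bj;
  return a;
}

// banded variant; band of diagonals d = i - j in [dlo, dhi] (window coords)
static Aln banded_sw(const std::vector<uint8_t>& q, int q0, int q1,
                     const std::vector<uint8_t>& s, int s0, int s1,
                     int dlo, int dhi,
                     int match, int mismatch, int go, int ge) {
  int m = q1 - q0, n = s1 - s0;
  int width = dhi - dlo + 1;
  // cell (i, j) stored at row i, col k = j - (i - dhi)
  std::vector<int> Hp(width + 2, 0), Hc(width + 2, 0),
                   Ep(width + 2, NEG), Ec(width + 2, NEG),
                   Fp(width + 2, NEG), Fc(width + 2, NEG);
  std::vector<uint8_t> tb((size_t)(m + 1) * (width + 2), 0);
  int best = 0, bi = 0, bk = 0;
  // row 0: H = 0 along j where k valid
  for (int i = 1; i <= m; ++i) {
    std::fill(Hc.begin(), Hc.end(), 0);
    std::fill(Ec.begin(), Ec.end(), NEG);
    std::fill(Fc.begin(), Fc.end(), NEG);
    uint8_t qb = q[q0 + i - 1];
    int jlo = std::max(1, i - dhi), jhi = std::min(n, i - dlo);
    uint8_t* tbrow = &tb[(size_t)i * (width + 2)];
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - (i - dhi) + 1;         // 1..width+? within padded row
      // neighbours: (i, j-1) -> same row, k-1 ; (i-1, j) -> prev row, k+1 ;
      // (i-1, j-1) -> prev row, k
      int e_open = Hc[k - 1] - go - ge, e_ext = Ec[k - 1] - ge;
      int E = std::max(e_open, e_ext);
      int f_open = Hp[k + 1] - go - ge, f_ext = Fp[k + 1] - ge;
      int F = std::max(f_open, f_ext);
      int sc = (qb != BASE_N && qb == s[s0 + j - 1]) ? match : mismatch;
      int diag = Hp[k] + sc;
      int H = 0; uint8_t t = 0;
      if (diag > H) { H = diag; t = 1; }
      if (E > H) { H = E; t = 2; }
      if (F > H) { H = F; t = 3; }
      if (e_ext >= e_open) t |= 4;
      if (f_ext >= f_open) t |= 8;
      Ec[k] = E; Fc[k] = F; Hc[k] = H; tbrow[k] = t;
      if (H > best) { best = H; bi = i; bk = k; }
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }
  Aln a; a.score = best; a.matches = 0; a.len = 0;
  if (best <= 0) { a.qs = a.qe = a.ss = a.se = 0; return a; }
  int i = bi, k = bk, state = 0;
  int bj = bk - 1 + (bi - dhi);
  while (i > 0) {
    int j = k - 1 + (i - dhi);
    if (j <= 0) break;
    uint8_t t = tb[(size_t)i * (width + 2) + k];
    if (state == 0) {
      int src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        a.len++;
        if (q[q0 + i - 1] != BASE_N && q[q0 + i - 1] == s[s0 + j - 1]) a.matches++;
        --i;            // k stays (diag moves i-1, j-1)
      } else if (src == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // gap in query: j-1, same i -> k-1
      a.len++;
      bool ext = (t & 4) != 0;
      --k;
      state = ext ? 2 : 0;
    } else {                 // gap in subject: i-1, same j -> k+1
      a.len++;
      bool ext = (t & 8) != 0;
      --i; ++k;
      state = ext ? 3 : 0;
    }
  }
  int j_end = k - 1 + (i - dhi);
  a.qs = q0 + i; a.qe = q0 + bi;
  a.ss = s0 + j_end; a.se = s0 + bj;
  return a;
}

static bool redundant(const Aln& b, const std::vector<Aln>& kept,
                      const std::vector<char>& strands, char strand) {
  for (size_t k = 0; k < kept.size(); ++k) {
    if (strands[k] != strand) continue;
    const Aln& a = kept[k];
    int qov = std::min(a.qe, b.qe) - std::max(a.qs, b.qs);
    int sov = std::min(a.se, b.se) - std::max(a.ss, b.ss);
    if (qov <= 0 || sov <= 0) continue;
    double fq = (double)qov / (b.qe - b.qs);
    double fs = (double)sov / (b.se - b.ss);
    if (fq >= 0.9 && fs >= 0.9) return true;
  }
  return false;
}

// [[Rcpp::export(name = ".seed_extend_cpp")]]
DataFrame seed_extend_cpp(std::string query, std::string subject,
                          int word_size, int match, int mismatch,
                          int gap_open, int gap_extend, int xdrop,
                          int min_score, bool self_mode,
                          int band = 64, int pad = 60, int max_hsps = 2000,
                          double max_full_cells = 4000000.0) {
  std::vector<uint8_t> qv0 = encode(query), sv = encode(subject);
  int go = -gap_open, ge = -gap_extend;   // penalties as magnitudes
  std::vector<int> Rqs, Rqe, Rss, Rse, Rscore, Rmatch, Rlen;
  std::vector<std::string> Rstrand;
  int n_s = (int)sv.size();
  if (word_size > (int)qv0.size() || word_size > n_s || word_size < 2) {
    return DataFrame::create(_["q_start"] = Rqs, _["q_end"] = Rqe,
                             _["s_start"] = Rss, _["s_end"] = Rse,
                             _["strand"] = Rstrand, _["length_bp"] = Rlen,
                             _["n_matches"] = Rmatch, _["score"] = Rscore);
  }
  // subject word index
  std::unordered_map<uint64_t, std::vector<int>> index;
  {
    uint64_t h = 0, mask = (word_size >= 32) ? ~0ULL : ((1ULL << (2 * word_size)) - 1);
    int valid = 0;
    for (int j = 0; j < n_s; ++j) {
      if (sv[j] == BASE_N) { valid = 0; h = 0; continue; }
      h = ((h << 2) | sv[j]) & mask;
      if (++valid >= word_size) index[h].push_back(j - word_size + 1);
    }
  }
  for (int strand_i = 0; strand_i < 2; ++strand_i) {
    char strand = strand_i == 0 ? '+' : '-';
    std::vector<uint8_t> qv = (strand == '+') ? qv0 : revcomp(qv0);
    int n_q = (int)qv.size();
    std::unordered_map<long long, int> diag_end;
    std::vector<Hsp> hsps;
    uint64_t h = 0, mask = (word_size >= 32) ? ~0ULL : ((1ULL << (2 * word_size)) - 1);
    int valid = 0;
    int trigger = std::max(16, min_score / 2);
    for (int i = 0; i < n_q; ++i) {
      if (qv[i] == BASE_N) { valid = 0; h = 0; continue; }
      h = ((h << 2) | qv[i]) & mask;
      if (++valid < word_size) continue;
      auto it = index.find(h);
      if (it == index.end()) continue;
      int qpos = i - word_size + 1;
      for (int spos : it->second) {
        if (self_mode && strand == '+' && qpos == spos) continue;
        long long d = (long long)qpos - spos;
        auto de = diag_end.find(d);
        if (de != diag_end.end() && de->second >= qpos + word_size) continue;
        Hsp hs = ungapped_extend(qv, sv, qpos, spos, word_size,
                                 match, mismatch, xdrop);
        diag_end[d] = hs.qe;
        if (hs.score >= trigger) hsps.push_back(hs);
      }
    }
    std::sort(hsps.begin(), hsps.end(),
              [](const Hsp& a, const Hsp& b) { return a.score > b.score; });
    if ((int)hsps.size() > max_hsps) hsps.resize(max_hsps);
    std::vector<Aln> kept;
    std::vector<char> kept_strand;
    for (const Hsp& hs : hsps) {
      Aln probe; probe.qs = hs.qs; probe.qe = hs.qe; probe.ss = hs.ss;
      probe.se = hs.se; probe.score = hs.score; probe.matches = 0; probe.len = 0;
      if (redundant(probe, kept, kept_strand, strand)) continue;
      int q0 = std::max(0, hs.qs - pad), q1 = std::min(n_q, hs.qe + pad);
      int s0 = std::max(0, hs.ss - pad), s1 = std::min(n_s, hs.se + pad);
      Aln a;
      double cells = (double)(q1 - q0) * (s1 - s0);
      if (cells <= max_full_cells) {
        a = window_sw(qv, q0, q1, sv, s0, s1, match, mismatch, go, ge);
      } else {
        int d0 = (hs.qs - q0) - (hs.ss - s0); // hsp diagonal in window coords
        a = banded_sw(qv, q0, q1, sv, s0, s1, d0 - band, d0 + band,
                      match, mismatch, go, ge);
      }
      if (a.score < min_score || a.len == 0) continue;
      if (self_mode && strand == '+' && a.qs == a.ss && a.qe == a.se) continue;
      if (redundant(a, kept, kept_strand, strand)) continue;
      kept.push_back(a);
      kept_strand.push_back(strand);
    }
    for (const Aln& a : kept) {
      int qs = a.qs, qe = a.qe;
      if (strand == '-') { // map back to original query coordinates
        int L = (int)qv0.size();
        qs = L - a.qe; qe = L - a.qs;
      }
      Rqs.push_back(qs); Rqe.push_back(qe);
      Rss.push_back(a.ss); Rse.push_back(a.se);
      Rstrand.push_back(std::string(1, strand));
      Rlen.push_back(a.len); Rmatch.push_back(a.matches);
      Rscore.push_back(a.score);
    }
  }
  return DataFrame::create(_["q_start"] = Rqs, _["q_end"] = Rqe,
                           _["s_start"] = Rss, _["s_end"] = Rse,
                           _["strand"] = Rstrand, _["length_bp"] = Rlen,
                           _["n_matches"] = Rmatch, _["score"] = Rscore,
                           _["stringsAsFactors"] = false);
}

// ---- tandem array scan ----------------------------------------------------
// For every candidate period p, compare s[i] with s[i-p] along the sequence
// and keep maximal positively-scoring segments (Kadane-style local scan).
// [[Rcpp::export(name = ".tandem_scan_cpp")]]
DataFrame tandem_scan_cpp(std::string seq, int match, int mismatch_penalty,
                          int min_score, int max_period) {
  std::vector<uint8_t> x = encode(seq);
  int L = (int)x.size();
  std::vector<int> Pstart, Pend, Pperiod, Pscore, Pmatch, Pcols;
  for (int p = 1; p <= std::min(max_period, L - 1); ++p) {
    long long run = 0, best = 0;
    int seg_start = p, best_end = -1, best_start = p;
    int mrun = 0, crun = 0, mbest = 0, cbest = 0;
    for (int i = p; i <= L; ++i) {
      bool flush = (i == L);
      if (!flush) {
        bool eq = (x[i] != BASE_N && x[i] == x[i - p]);
        long long add = eq ? match : -mismatch_penalty;
        if (run + add <= 0) {
          // close current segment
          if (best >= min_score && best_end >= 0) {
            Pstart.push_back(seg_start - p); Pend.push_back(best_end + 1);
            Pperiod.push_back(p); Pscore.push_back((int)best);
            Pmatch.push_back(mbest); Pcols.push_back(cbest);
          }
          run = 0; best = 0; best_end = -1; seg_start = i + 1;
          mrun = 0; crun = 0; mbest = 0; cbest = 0;
        } else {
          run += add; crun += 1; if (eq) mrun += 1;
          if (run > best) { best = run; best_end = i; mbest = mrun; cbest = crun; }
        }
      } else {
        if (best >= min_score && best_end >= 0) {
          Pstart.push_back(seg_start - p); Pend.push_back(best_end + 1);
          Pperiod.push_back(p); Pscore.push_back((int)best);
          Pmatch.push_back(mbest); Pcols.push_back(cbest);
        }
      }
    }
  }
  return DataFrame::create(_["start"] = Pstart, _["end"] = Pend,
                           _["period"] = Pperiod, _["score"] = Pscore,
                           _["n_matches"] = Pmatch, _["n_compared"] = Pcols);
}

// ---- K2P site counting ----------------------------------------------------
// msa: integer matrix taxa x columns with codes 0=A,1=C,2=G,3=T, >=4 missing.
// Returns list of matrices P (transition prop.), Q (transversion prop.),
// N (valid sites per pair).
// [[Rcpp::export(name = ".k2p_counts_cpp")]]
List k2p_counts_cpp(IntegerMatrix msa) {
  int n = msa.nrow(), L = msa.ncol();
  NumericMatrix P(n, n), Q(n, n), N(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int nts = 0, ntv = 0, nv = 0;
      for (int j = 0; j < L; ++j) {
        int x = msa(a, j), y = msa(b, j);
        if (x > 3 || y > 3) continue;
        ++nv;
        if (x == y) continue;
        // transitions: A<->G (0,2), C<->T (1,3)
        if ((x + y == 2 && x != 1) || (x + y == 4 && x != 2)) ++nts; else ++ntv;
      }
      double p = nv > 0 ? (double)nts / nv : NA_REAL;
      double q = nv > 0 ? (double)ntv / nv : NA_REAL;
      P(a, b) = P(b, a) = p;
      Q(a, b) = Q(b, a) = q;
      N(a, b) = N(b, a) = nv;
    }
  }
  return List::create(_["P"] = P, _["Q"] = Q, _["N"] = N);
}

// ---- gene-conversion permutation scan -------------------------------------
// eq: npairs x ncols 0/1 matrix, equality of a taxon pair at polymorphic
// columns.  Observed statistic per pair = longest run of 1s.  Null: columns
// permuted jointly across pairs (global permutation), seeded internally.
// Returns observed runs, run locations and permutation p-values.
// [[Rcpp::export(name = ".geneconv_perm_cpp")]]
List geneconv_perm_cpp(IntegerMatrix eq, int n_perms, int seed) {
  int np = eq.nrow(), L = eq.ncol();
  std::vector<int> obs(np, 0), obs_start(np, -1), obs_end(np, -1);
  for (int p = 0; p < np; ++p) {
    int run = 0, start = 0;
    for (int j = 0; j < L; ++j) {
      if (eq(p, j) == 1) {
        if (run == 0) start = j;
        ++run;
        if (run > obs[p]) { obs[p] = run; obs_start[p] = start; obs_end[p] = j; }
      } else run = 0;
    }
  }
  std::vector<int> ge_count(np, 0);
  std::mt19937 rng((uint32_t)seed);
  std::vector<int> perm(L);
  for (int j = 0; j < L; ++j) perm[j] = j;
  for (int r = 0; r < n_perms; ++r) {
    for (int j = L - 1; j > 0; --j) {
      int k = (int)(rng() % (uint32_t)(j + 1));
      std::swap(perm[j], perm[k]);
    }
    for (int p = 0; p < np; ++p) {
      int run = 0, mx = 0;
      for (int j = 0; j < L; ++j) {
        if (eq(p, perm[j]) == 1) { ++run; if (run > mx) mx = run; }
        else run = 0;
      }
      if (mx >= obs[p]) ++ge_count[p];
    }
  }
  NumericVector pval(np);
  IntegerVector ob(np), os(np), oe(np);
  for (int p = 0; p < np; ++p) {
    pval[p] = (1.0 + ge_count[p]) / (1.0 + n_perms);
    ob[p] = obs[p]; os[p] = obs_start[p]; oe[p] = obs_end[p];
  }
  return List::create(_["max_run"] = ob, _["run_start"] = os,
                      _["run_end"] = oe, _["p_value"] = pval);
}
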