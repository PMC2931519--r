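#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dynamic-programming kernels for local/local profile-HMM scoring, plus the
// word-filter primitives.  All scores are log-odds in bits; transitions are
// log2 probabilities.  Sequences arrive as 0-based integer codes over the
// 20-letter amino-acid alphabet.  Windows are half-open [ws,we) on the
// sequence and [ms,me) on the model's match states.
//
// tsc columns: 0 M->M, 1 M->I, 2 M->D, 3 I->M, 4 I->I, 5 D->M, 6 D->D
// (row k holds transitions out of position k into k+1, 0-based).

static const double NEGINF = -std::numeric_limits<double>::infinity();

static inline double log2sum(double a, double b) {
  if (a == NEGINF) return b;
  if (b == NEGINF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log2(1.0 + std::exp2(b - a));
}

// [[Rcpp::export]]
List cpp_viterbi(NumericMatrix msc, NumericMatrix isc, NumericMatrix tsc,
                 NumericVector entry, NumericVector exitv, IntegerVector seq,
                 int ws, int we, int ms, int me, bool want_trace) {
  int L = we - ws, M = me - ms;
  std::vector<double> VM(L * M, NEGINF), VI(L * M, NEGINF), VD(L * M, NEGINF);
  std::vector<signed char> PM, PI, PD;
  if (want_trace) {
    PM.assign(L * M, -1); PI.assign(L * M, -1); PD.assign(L * M, -1);
  }
  // predecessor codes: 0 begin, 1 from M, 2 from I, 3 from D
  double best = NEGINF; int bi = -1, bk = -1;
  for (int i = 0; i < L; ++i) {
    int x = seq[ws + i];
    for (int k = 0; k < M; ++k) {
      int km = ms + k;           // absolute model index
      int c = i * M + k;
      // --- M state: tie-break priority M > D > I, begin last
      double sc = NEGINF; signed char ptr = -1;
      if (i > 0 && k > 0) {
        int p = (i - 1) * M + (k - 1);
        double v = VM[p] + tsc(km - 1, 0);
        if (v > sc) { sc = v; ptr = 1; }
        v = VD[p] + tsc(km - 1, 5);
        if (v > sc) { sc = v; ptr = 3; }
        v = VI[p] + tsc(km - 1, 3);
        if (v > sc) { sc = v; ptr = 2; }
      }
      if (entry[km] > sc) { sc = entry[km]; ptr = 0; }
      VM[c] = sc + msc(km, x);
      if (want_trace) PM[c] = ptr;
      // --- I state (insert after match km; needs M or I above at same k)
      if (i > 0) {
        int p = (i - 1) * M + k;
        double si = VM[p] + tsc(km, 1); signed char pi = 1;
        double v = VI[p] + tsc(km, 4);
        if (v > si) { si = v; pi = 2; }
        if (si > NEGINF) { VI[c] = si + isc(km, x); if (want_trace) PI[c] = pi; }
      }
      // --- D state (from M or D at k-1, same i)
      if (k > 0) {
        int p = i * M + (k - 1);
        double sd = VM[p] + tsc(km - 1, 2); signed char pd = 1;
        double v = VD[p] + tsc(km - 1, 6);
        if (v > sd) { sd = v; pd = 3; }
        if (sd > NEGINF) { VD[c] = sd; if (want_trace) PD[c] = pd; }
      }
      double end = VM[c] + exitv[km];
      if (end > best) { best = end; bi = i; bk = k; }
    }
  }
  if (!want_trace || bi < 0)
    return List::create(_["score"] = best, _["trace"] = R_NilValue);
  // traceback from (bi, bk) in state M
  std::vector<int> st, kk, ii;
  int i = bi, k = bk, state = 1; // 1 M, 2 I, 3 D
  while (true) {
    int c = i * M + k;
    if (state == 1) {
      st.push_back(1); kk.push_back(ms + k); ii.push_back(ws + i);
      signed char p = PM[c];
      if (p == 0) break;
      if (p == 1) { --i; --k; state = 1; }
      else if (p == 2) { --i; --k; state = 2; }
      else { --i; --k; state = 3; }
    } else if (state == 2) {
      st.push_back(2); kk.push_back(ms + k); ii.push_back(ws + i);
      signed char p = PI[c];
      --i; state = (p == 1) ? 1 : 2;
    } else {
      st.push_back(3); kk.push_back(ms + k); ii.push_back(ws + i);
      signed char p = PD[c];
      --k; state = (p == 1) ? 1 : 3;
    }
  }
  int n = st.size();
  IntegerMatrix tr(n + 2, 3);
  // row 0: B at entry point
  tr(0, 0) = 0; tr(0, 1) = kk[n - 1]; tr(0, 2) = ii[n - 1];
  for (int r = 0; r < n; ++r) {
    tr(r + 1, 0) = st[n - 1 - r];
    tr(r + 1, 1) = kk[n - 1 - r];
    // D consumes nothing: report next unconsumed position
    tr(r + 1, 2) = ii[n - 1 - r];
  }
  tr(n + 1, 0) = 4; tr(n + 1, 1) = ms + bk; tr(n + 1, 2) = ws + bi + 1;
  return List::create(_["score"] = best, _["trace"] = tr);
}

// [[Rcpp::export]]
double cpp_forward(NumericMatrix msc, NumericMatrix isc, NumericMatrix tsc,
                   NumericVector entry, NumericVector exitv, IntegerVector seq,
                   int ws, int we, int ms, int me) {
  int L = we - ws, M = me - ms;
  std::vector<double> FM(L * M, NEGINF), FI(L * M, NEGINF), FD(L * M, NEGINF);
  double total = NEGINF;
  for (int i = 0; i < L; ++i) {
    int x = seq[ws + i];
    for (int k = 0; k < M; ++k) {
      int km = ms + k;
      int c = i * M + k;
      double sc = entry[km];
      if (i > 0 && k > 0) {
        int p = (i - 1) * M + (k - 1);
        sc = log2sum(sc, FM[p] + tsc(km - 1, 0));
        sc = log2sum(sc, FI[p] + tsc(km - 1, 3));
        sc = log2sum(sc, FD[p] + tsc(km - 1, 5));
      }
      FM[c] = sc + msc(km, x);
      if (i > 0) {
        int p = (i - 1) * M + k;
        double si = log2sum(FM[p] + tsc(km, 1), FI[p] + tsc(km, 4));
        if (si > NEGINF) FI[c] = si + isc(km, x);
      }
      if (k > 0) {
        int p = i * M + (k - 1);
        FD[c] = log2sum(FM[p] + tsc(km - 1, 2), FD[p] + tsc(km - 1, 6));
      }
      total = log2sum(total, FM[c] + exitv[km]);
    }
  }
  return total;
}

// [[Rcpp::export]]
NumericVector cpp_score_many(NumericMatrix msc, NumericMatrix isc,
                             NumericMatrix tsc, NumericVector entry,
                             NumericVector exitv, List seqs, int algo) {
  int n = seqs.size();
  NumericVector out(n);
  int M = msc.nrow();
  for (int j = 0; j < n; ++j) {
    IntegerVector s = seqs[j];
    if (algo == 0) {
      List r = cpp_viterbi(msc, isc, tsc, entry, exitv, s, 0, s.size(), 0, M,
                           false);
      out[j] = as<double>(r["score"]);
    } else {
      out[j] = cpp_forward(msc, isc, tsc, entry, exitv, s, 0, s.size(), 0, M);
    }
  }
  return out;
}

// Enumerate all 4-mers with summed match emission score > theta, anchored at
// each model start.  DFS with suffix-max pruning keeps this fast at sane
// thresholds; theta = -Inf enumerates everything.
// [[Rcpp::export]]
List cpp_enum_words(NumericMatrix msc, double theta) {
  int M = msc.nrow();
  if (M < 4) stop("model has fewer than 4 match states; no words exist");
  std::vector<int> starts;
  std::vector<int> c0, c1, c2, c3;
  std::vector<double> scores;
  for (int k = 0; k + 4 <= M; ++k) {
    double mx1 = NEGINF, mx2 = NEGINF, mx3 = NEGINF;
    for (int a = 0; a < 20; ++a) {
      mx1 = std::max(mx1, msc(k + 1, a));
      mx2 = std::max(mx2, msc(k + 2, a));
      mx3 = std::max(mx3, msc(k + 3, a));
    }
    double rem1 = mx1 + mx2 + mx3, rem2 = mx2 + mx3, rem3 = mx3;
    for (int a = 0; a < 20; ++a) {
      double s0 = msc(k, a);
      if (!(s0 + rem1 > theta)) continue;
      for (int b = 0; b < 20; ++b) {
        double s1 = s0 + msc(k + 1, b);
        if (!(s1 + rem2 > theta)) continue;
        for (int cc = 0; cc < 20; ++cc) {
          double s2 = s1 + msc(k + 2, cc);
          if (!(s2 + rem3 > theta)) continue;
          for (int d = 0; d < 20; ++d) {
            double s3 = s2 + msc(k + 3, d);
            if (s3 > theta) {
              starts.push_back(k);
              c0.push_back(a); c1.push_back(b); c2.push_back(cc);
              c3.push_back(d);
              scores.push_back(s3);
            }
          }
        }
      }
    }
  }
  int n = starts.size();
  IntegerMatrix codes(n, 4);
  IntegerVector ks(n);
  NumericVector sc(n);
  for (int r = 0; r < n; ++r) {
    ks[r] = starts[r];
    codes(r, 0) = c0[r]; codes(r, 1) = c1[r];
    codes(r, 2) = c2[r]; codes(r, 3) = c3[r];
    sc[r] = scores[r];
  }
  return List::create(_["model_start"] = ks, _["codes"] = codes,
                      _["score"] = sc);
}

// The scanner is a table-driven DFA over 4-mer codes: state = the last three
// residues read, transition on the next residue, with an acceptance table
// mapping each complete 4-mer code to the model starts that emit it.
struct WordTable {
  std::vector<std::vector<int> > slots; // 20^4 entries
  WordTable() : slots(160000) {}
};

// [[Rcpp::export]]
SEXP cpp_build_automaton(IntegerVector starts, IntegerMatrix codes) {
  WordTable *wt = new WordTable();
  int n = starts.size();
  for (int r = 0; r < n; ++r) {
    int code = ((codes(r, 0) * 20 + codes(r, 1)) * 20 + codes(r, 2)) * 20 +
               codes(r, 3);
    wt->slots[code].push_back(starts[r]);
  }
  XPtr<WordTable> p(wt, true);
  return p;
}

// [[Rcpp::export]]
IntegerMatrix cpp_scan(SEXP aut, IntegerVector seq) {
  XPtr<WordTable> wt(aut);
  int L = seq.size();
  std::vector<int> ss, ks;
  if (L >= 4) {
    int code = ((seq[0] * 20 + seq[1]) * 20 + seq[2]) * 20 + seq[3];
    for (int i = 3; i < L; ++i) {
      if (i > 3) code = (code % 8000) * 20 + seq[i];
      const std::vector<int> &hits = wt->slots[code];
      for (size_t h = 0; h < hits.size(); ++h) {
        ss.push_back(i - 3);
        ks.push_back(hits[h]);
      }
    }
  }
  int n = ss.size();
  IntegerMatrix out(n, 2);
  for (int r = 0; r < n; ++r) { out(r, 0) = ss[r]; out(r, 1) = ks[r]; }
  return out;
}

// Ungapped diagonal extension of a 4-residue word seed with the delta/2
// drop-off rule: walk outward one (residue, match state) pair at a time,
// stop once the running score falls delta/2 or more below the best seen,
// keep the best-scoring endpoint.  Left end first, then right.
// [[Rcpp::export]]
NumericVector cpp_extend(NumericMatrix msc, IntegerVector seq, int seq_start,
                         int model_start, double delta) {
  int L = seq.size(), M = msc.nrow();
  double word = 0.0;
  for (int j = 0; j < 4; ++j) word += msc(model_start + j, seq[seq_start + j]);
  double drop = delta / 2.0;
  // leftward
  double run = 0.0, bestl = 0.0;
  int best_off = 0, off = 0;
  while (seq_start - off - 1 >= 0 && model_start - off - 1 >= 0) {
    ++off;
    run += msc(model_start - off, seq[seq_start - off]);
    if (run > bestl) { bestl = run; best_off = off; }
    if (run <= bestl - drop) break;
  }
  int ls = seq_start - best_off, lk = model_start - best_off;
  // rightward (word occupies [seq_start, seq_start+4))
  run = 0.0;
  double bestr = 0.0;
  int best_roff = 0;
  off = 0;
  while (seq_start + 4 + off < L && model_start + 4 + off < M) {
    run += msc(model_start + 4 + off, seq[seq_start + 4 + off]);
    ++off;
    if (run > bestr) { bestr = run; best_roff = off; }
    if (run <= bestr - drop) break;
  }
  int rs = seq_start + 4 + best_roff, rk = model_start + 4 + best_roff;
  return NumericVector::create(ls, rs, lk, rk, word + bestl + bestr);
}

struct ExtHit { int ss, se, ks, ke; double score; };

// Full filter cascade on one sequence: scan, extend, qualify (> mu),
// optional same-diagonal overlap merge, two-hit rule, windowed Viterbi
// gate (> eta; -Inf passes).  Mirrors the staged R-level operations.
// stage: 0 no_words, 1 one_hit, 2 window_fail, 3 passed
// [[Rcpp::export]]
List cpp_filter_cascade(NumericMatrix msc, NumericMatrix isc,
                        NumericMatrix tsc, NumericVector entry,
                        NumericVector exitv, SEXP aut, IntegerVector seq,
                        double delta, double mu, double eta,
                        bool merge_overlaps) {
  XPtr<WordTable> wt(aut);
  int L = seq.size();
  std::vector<ExtHit> qual;
  bool any_word = false;
  if (L >= 4) {
    int code = ((seq[0] * 20 + seq[1]) * 20 + seq[2]) * 20 + seq[3];
    for (int i = 3; i < L; ++i) {
      if (i > 3) code = (code % 8000) * 20 + seq[i];
      const std::vector<int> &anchors = wt->slots[code];
      for (size_t h = 0; h < anchors.size(); ++h) {
        any_word = true;
        NumericVector v = cpp_extend(msc, seq, i - 3, anchors[h], delta);
        if (v[4] > mu) {
          ExtHit e = {(int)v[0], (int)v[1], (int)v[2], (int)v[3], v[4]};
          qual.push_back(e);
        }
      }
    }
  }
  if (!any_word)
    return List::create(_["stage"] = 0, _["hits"] = R_NilValue,
                        _["window_score"] = NA_REAL);
  if (merge_overlaps && qual.size() > 1) {
    // sort by (diagonal, seq_start), then sweep clusters per diagonal
    std::sort(qual.begin(), qual.end(),
              [](const ExtHit &a, const ExtHit &b) {
                int da = a.ss - a.ks, db = b.ss - b.ks;
                if (da != db) return da < db;
                return a.ss < b.ss;
              });
    std::vector<ExtHit> merged;
    size_t i = 0;
    while (i < qual.size()) {
      int diag = qual[i].ss - qual[i].ks;
      ExtHit best = qual[i];
      int maxend = qual[i].se;
      size_t j = i + 1;
      while (j < qual.size() && qual[j].ss - qual[j].ks == diag &&
             qual[j].ss < maxend) {
        if (qual[j].score > best.score) best = qual[j];
        maxend = std::max(maxend, qual[j].se);
        ++j;
      }
      merged.push_back(best);
      i = j;
    }
    qual = merged;
  }
  int nq = qual.size();
  NumericMatrix hits(nq, 5);
  // report in (seq_start, model_start) order like the staged pipeline
  std::sort(qual.begin(), qual.end(),
            [](const ExtHit &a, const ExtHit &b) {
              if (a.ss != b.ss) return a.ss < b.ss;
              return a.ks < b.ks;
            });
  for (int r = 0; r < nq; ++r) {
    hits(r, 0) = qual[r].ss; hits(r, 1) = qual[r].se;
    hits(r, 2) = qual[r].ks; hits(r, 3) = qual[r].ke;
    hits(r, 4) = qual[r].score;
  }
  if (nq < 2)
    return List::create(_["stage"] = 1, _["hits"] = hits,
                        _["window_score"] = NA_REAL);
  int ws = qual[0].ss, we = 0, ms = qual[0].ks, me = 0;
  for (int r = 0; r < nq; ++r) {
    ws = std::min(ws, qual[r].ss); we = std::max(we, qual[r].se);
    ms = std::min(ms, qual[r].ks); me = std::max(me, qual[r].ke);
  }
  List vr = cpp_viterbi(msc, isc, tsc, entry, exitv, seq, ws, we, ms, me,
                        false);
  double wscore = as<double>(vr["score"]);
  bool pass = (eta == NEGINF) || (wscore > eta);
  return List::create(_["stage"] = pass ? 3 : 2, _["hits"] = hits,
                      _["window_score"] = wscore);
}
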