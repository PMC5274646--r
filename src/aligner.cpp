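// Alignment kernels: suffix array, adaptive seeding, Smith-Waterman
// (Gotoh affine), anchored X-drop extension, and the per-query
// seed-and-extend pipeline. Residues are 0-based integer codes into the
// substitution-matrix alphabet; concatenated library text uses per-sequence
// unique terminator codes >= alphabet size so suffix comparisons never
// cross sequence boundaries.
//
// Gap convention throughout: a gap of length L costs open + extend*(L-1),
// i.e. the first gapped residue is charged `open`.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// ---------------------------------------------------------------- suffix array

// [[Rcpp::export]]
IntegerVector cpp_build_sa(IntegerVector text, int n_letters) {
  const int n = text.size();
  const int* t = INTEGER(text);
  std::vector<int> pos;
  pos.reserve(n);
  for (int i = 0; i < n; ++i)
    if (t[i] >= 0 && t[i] < n_letters) pos.push_back(i);
  // Plain comparison sort; terminators are unique so comparisons terminate
  // before running past either suffix's own sequence.
  std::sort(pos.begin(), pos.end(), [t](int a, int b) {
    while (t[a] == t[b]) { ++a; ++b; }
    return t[a] < t[b];
  });
  return wrap(pos);
}

// Narrow the sa interval [lo,hi) of suffixes sharing a prefix of length
// `depth` down to those whose next character equals c. Within the interval
// the depth-th characters are non-decreasing, so binary search applies.
static inline void sa_narrow(const int* t, const int* sa, int depth, int c,
                             int& lo, int& hi) {
  int a = lo, b = hi;
  while (a < b) { int mid = a + (b - a) / 2; if (t[sa[mid] + depth] < c) a = mid + 1; else b = mid; }
  const int nlo = a;
  b = hi;
  while (a < b) { int mid = a + (b - a) / 2; if (t[sa[mid] + depth] <= c) a = mid + 1; else b = mid; }
  lo = nlo; hi = a;
}

// [[Rcpp::export]]
int cpp_sa_count(IntegerVector text, IntegerVector sa, IntegerVector pattern) {
  const int* t = INTEGER(text);
  const int* s = INTEGER(sa);
  int lo = 0, hi = sa.size();
  for (int d = 0; d < pattern.size() && lo < hi; ++d)
    sa_narrow(t, s, d, pattern[d], lo, hi);
  return hi - lo;
}

// One seed per library occurrence of, per query position, the shortest
// substring (>= min_len) occurring <= m times. Columns: qpos, tpos, len, freq
// (all 0-based positions).
// [[Rcpp::export]]
IntegerMatrix cpp_adaptive_seeds(IntegerVector text, IntegerVector sa,
                                 IntegerVector query, double m, int min_len) {
  const int* t = INTEGER(text);
  const int* s = INTEGER(sa);
  const int qlen = query.size(), nsa = sa.size();
  std::vector<int> qp, tp, ln, fq;
  for (int q0 = 0; q0 < qlen; ++q0) {
    int lo = 0, hi = nsa, d = 0;
    bool found = false;
    while (q0 + d < qlen) {
      sa_narrow(t, s, d, query[q0 + d], lo, hi);
      ++d;
      if (hi <= lo) break;
      if (d >= min_len && (double)(hi - lo) <= m) { found = true; break; }
    }
    if (found) {
      std::vector<int> occ(s + lo, s + hi);
      std::sort(occ.begin(), occ.end());
      for (int o : occ) {
        qp.push_back(q0); tp.push_back(o); ln.push_back(d); fq.push_back(hi - lo);
      }
    }
  }
  IntegerMatrix out(qp.size(), 4);
  for (int i = 0; i < (int)qp.size(); ++i) {
    out(i, 0) = qp[i]; out(i, 1) = tp[i]; out(i, 2) = ln[i]; out(i, 3) = fq[i];
  }
  colnames(out) = CharacterVector::create("qpos", "tpos", "len", "freq");
  return out;
}

// ---------------------------------------------------------------- Smith-Waterman

static int sw_score_core(const int* a, int la, const int* b, int lb,
                         const int* S, int A, int open, int extend) {
  std::vector<int> H(lb + 1, 0), Fv(lb + 1, NEG);
  int best = 0;
  for (int i = 0; i < la; ++i) {
    const int* Sa = S + a[i];
    int e = NEG;
    int hdiag = H[0];  // H(i-1, j-1)
    for (int j = 1; j <= lb; ++j) {
      const int hup = H[j];
      int f = hup - open;
      const int fe = Fv[j] - extend;
      if (fe > f) f = fe;
      Fv[j] = f;
      int eo = H[j - 1] - open;
      const int ee = e - extend;
      e = (eo >= ee) ? eo : ee;
      int h = hdiag + Sa[(size_t)b[j - 1] * A];
      hdiag = hup;
      if (f > h) h = f;
      if (e > h) h = e;
      if (h < 0) h = 0;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

static IntegerMatrix pairs_to_blocks(const std::vector<std::pair<int, int> >& pairs) {
  std::vector<int> qs, ts, ln;
  for (size_t k = 0; k < pairs.size(); ++k) {
    if (k > 0 && pairs[k].first == pairs[k - 1].first + 1 &&
        pairs[k].second == pairs[k - 1].second + 1) {
      ++ln.back();
    } else {
      qs.push_back(pairs[k].first);
      ts.push_back(pairs[k].second);
      ln.push_back(1);
    }
  }
  IntegerMatrix out(qs.size(), 3);
  for (int i = 0; i < (int)qs.size(); ++i) {
    out(i, 0) = qs[i]; out(i, 1) = ts[i]; out(i, 2) = ln[i];
  }
  colnames(out) = CharacterVector::create("qstart", "tstart", "len");
  return out;
}

// Full Smith-Waterman with traceback. Tie order: match > delete (gap in
// target, consumes query) > insert (gap in query, consumes target); best
// cell = earliest (i, j). Returns score 0 and no blocks when the optimum
// is empty.
// [[Rcpp::export]]
List cpp_sw(IntegerVector a, IntegerVector b, IntegerMatrix S, int open, int extend) {
  const int la = a.size(), lb = b.size(), A = S.nrow();
  const int* Sp = INTEGER(S);
  std::vector<int> H(lb + 1, 0), Fv(lb + 1, NEG);
  std::vector<unsigned char> dir((size_t)(la + 1) * (lb + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    const int* Sa = Sp + a[i - 1];
    unsigned char* dri = &dir[(size_t)i * (lb + 1)];
    int e = NEG;
    int hdiag = H[0];
    for (int j = 1; j <= lb; ++j) {
      const int hup = H[j];
      unsigned char fl = 0;
      int f = hup - open;
      const int fe = Fv[j] - extend;
      if (f >= fe) fl |= 0x10; else f = fe;
      Fv[j] = f;
      int eo = H[j - 1] - open;
      const int ee = e - extend;
      if (eo >= ee) { e = eo; fl |= 0x20; } else e = ee;
      int h = hdiag + Sa[(size_t)b[j - 1] * A];
      hdiag = hup;
      unsigned char c = 1;
      if (f > h) { h = f; c = 2; }
      if (e > h) { h = e; c = 3; }
      if (h <= 0) { h = 0; c = 0; }
      H[j] = h;
      dri[j] = (unsigned char)(c | fl);
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["blocks"] = IntegerMatrix(0, 3));
  std::vector<std::pair<int, int> > pairs;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = F(delete), 2 = E(insert)
  while (i > 0 && j > 0) {
    const unsigned char c = dir[(size_t)i * (lb + 1) + j];
    if (state == 0) {
      const int hc = c & 3;
      if (hc == 0) break;
      if (hc == 1) { pairs.push_back(std::make_pair(i - 1, j - 1)); --i; --j; }
      else if (hc == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      const bool opened = (c & 0x10) != 0;
      --i;
      if (opened) state = 0;
    } else {
      const bool opened = (c & 0x20) != 0;
      --j;
      if (opened) state = 0;
    }
  }
  std::reverse(pairs.begin(), pairs.end());
  return List::create(_["score"] = best, _["blocks"] = pairs_to_blocks(pairs));
}

// Score-only all-vs-all. With symmetric = true (queries and targets are the
// same collection) only the upper triangle is computed and mirrored.
// [[Rcpp::export]]
IntegerMatrix cpp_sw_scores(List queries, List targets, IntegerMatrix S,
                            int open, int extend, bool symmetric) {
  const int nq = queries.size(), nt = targets.size(), A = S.nrow();
  const int* Sp = INTEGER(S);
  IntegerMatrix out(nq, nt);
  std::vector<IntegerVector> qv(nq), tv(nt);
  for (int i = 0; i < nq; ++i) qv[i] = queries[i];
  for (int j = 0; j < nt; ++j) tv[j] = targets[j];
  for (int i = 0; i < nq; ++i) {
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
    const int jstart = symmetric ? i : 0;
    for (int j = jstart; j < nt; ++j) {
      const int sc = sw_score_core(INTEGER(qv[i]), qv[i].size(),
                                   INTEGER(tv[j]), tv[j].size(),
                                   Sp, A, open, extend);
      out(i, j) = sc;
      if (symmetric && j != i) out(j, i) = sc;
    }
  }
  return out;
}

// Paired score-only alignment (calibration workhorse).
// [[Rcpp::export]]
IntegerVector cpp_pair_scores(List as, List bs, IntegerMatrix S, int open, int extend) {
  const int n = as.size(), A = S.nrow();
  const int* Sp = INTEGER(S);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
    IntegerVector a = as[i], b = bs[i];
    out[i] = sw_score_core(INTEGER(a), a.size(), INTEGER(b), b.size(), Sp, A, open, extend);
  }
  return out;
}

// ---------------------------------------------------------------- gapless extension

// Greedy X-drop widening of a seed to its best-scoring gapless segment.
// Query and target are plain code vectors; returns (qs, qe, ts, te, score)
// with half-open 0-based intervals containing the seed.
// [[Rcpp::export]]
IntegerVector cpp_gapless_extend(IntegerVector q, IntegerVector t,
                                 int qpos, int tpos, int len,
                                 IntegerMatrix S, double xdrop) {
  const int A = S.nrow();
  const int* Sp = INTEGER(S);
  int score = 0;
  for (int k = 0; k < len; ++k)
    score += Sp[q[qpos + k] + (size_t)t[tpos + k] * A];
  // right of the seed
  int run = score, best = score, bqe = qpos + len;  // exclusive end
  for (int i = qpos + len, j = tpos + len; i < q.size() && j < t.size(); ++i, ++j) {
    run += Sp[q[i] + (size_t)t[j] * A];
    if (run > best) { best = run; bqe = i + 1; }
    if ((double)(best - run) > xdrop) break;
  }
  const int right_gain = best - score;
  // left of the seed
  run = score; best = score;
  int bqs = qpos;
  for (int i = qpos - 1, j = tpos - 1; i >= 0 && j >= 0; --i, --j) {
    run += Sp[q[i] + (size_t)t[j] * A];
    if (run > best) { best = run; bqs = i; }
    if ((double)(best - run) > xdrop) break;
  }
  const int left_gain = best - score;
  IntegerVector out = IntegerVector::create(
    _["qs"] = bqs, _["qe"] = bqe,
    _["ts"] = tpos - (qpos - bqs), _["te"] = tpos + len + (bqe - qpos - len),
    _["score"] = score + left_gain + right_gain);
  return out;
}

// ---------------------------------------------------------------- X-drop gapped extension

// Anchored extension: best-scoring alignment of prefixes of u and v starting
// at (0,0); scores may go negative, cells whose best state drops more than
// xdrop below the running best are pruned. Returns the score and the aligned
// index pairs of one optimal path (ties: match > delete > insert).
static void xdrop_extend(const int* u, int lu, const int* v, int lv,
                         const int* S, int A, int open, int extend, double xdrop,
                         int& out_score, std::vector<std::pair<int, int> >& out_pairs) {
  out_score = 0;
  out_pairs.clear();
  if (lu == 0 || lv == 0) {
    // pure-gap extensions never score > 0; empty extension is optimal
    return;
  }
  std::vector<int> H(lv + 1, NEG), Fv(lv + 1, NEG);
  // grow-only traceback buffer: stale bytes are never read because the
  // traceback only visits cells whose state was finite in this call
  static std::vector<unsigned char> dirbuf;
  const size_t need = (size_t)(lu + 1) * (lv + 1);
  if (dirbuf.size() < need) dirbuf.resize(need);
  unsigned char* dir = &dirbuf[0];
  int best = 0, bi = 0, bj = 0;
  H[0] = 0;
  int jlo = 0, jhi = 0;
  for (int j = 1; j <= lv; ++j) {
    const int h = -(open + (j - 1) * extend);
    if ((double)(0 - h) > xdrop) break;
    H[j] = h;
    dir[j] = (unsigned char)(3 | (j == 1 ? 0x20 : 0));
    jhi = j;
  }
  if (jhi + 1 <= lv) H[jhi + 1] = NEG;
  for (int i = 1; i <= lu; ++i) {
    unsigned char* dri = &dir[(size_t)i * (lv + 1)];
    const int* Su = S + u[i - 1];
    int e = NEG;
    int new_jlo = -1, new_jhi = -1;
    int hprev_jm1;   // H(i-1, j-1)
    int hleft = NEG; // H(i, j-1)
    int start_j;
    if (jlo == 0) {
      unsigned char fl = 0;
      int f = H[0] - open;
      const int fe = Fv[0] - extend;
      if (f >= fe) fl = 0x10; else f = fe;
      Fv[0] = f;
      hprev_jm1 = H[0];
      if ((double)(best - f) <= xdrop) {
        H[0] = f; dri[0] = (unsigned char)(2 | fl);
        new_jlo = new_jhi = 0;
        hleft = f;
      } else {
        H[0] = NEG; Fv[0] = NEG;
      }
      start_j = 1;
    } else {
      hprev_jm1 = H[jlo - 1];  // NEG by window invariant
      start_j = jlo;
    }
    for (int j = start_j; j <= lv; ++j) {
      int d, f;
      unsigned char fl = 0;
      if (j <= jhi + 1) {
        const int hup = H[j];
        d = hprev_jm1;
        hprev_jm1 = hup;
        f = hup - open;
        const int fe = Fv[j] - extend;
        if (f >= fe) fl |= 0x10; else f = fe;
      } else {
        d = NEG; f = NEG;
        hprev_jm1 = NEG;
      }
      Fv[j] = f;
      int eo = hleft - open;
      const int ee = e - extend;
      if (eo >= ee) { e = eo; fl |= 0x20; } else e = ee;
      int h = (d > NEG / 2) ? d + Su[(size_t)v[j - 1] * A] : NEG;
      unsigned char c = 1;
      if (f > h) { h = f; c = 2; }
      if (e > h) { h = e; c = 3; }
      const bool alive = h > NEG / 2 && (double)(best - h) <= xdrop;
      if (alive) {
        H[j] = h;
        dri[j] = (unsigned char)(c | fl);
        hleft = h;
        if (h > best) { best = h; bi = i; bj = j; }
        if (new_jlo < 0) new_jlo = j;
        new_jhi = j;
      } else {
        H[j] = NEG; Fv[j] = NEG;
        e = NEG;
        hleft = NEG;
        dri[j] = 0;
        if (j > jhi + 1) break;  // nothing right of here is reachable
      }
    }
    if (new_jlo < 0) break;  // whole row pruned
    jlo = new_jlo; jhi = new_jhi;
    if (jhi + 1 <= lv) { H[jhi + 1] = NEG; Fv[jhi + 1] = NEG; }
  }
  out_score = best;
  // traceback
  int i = bi, j = bj, state = 0;
  while (i > 0 || j > 0) {
    const unsigned char c = dir[(size_t)i * (lv + 1) + j];
    if (state == 0) {
      const int hc = c & 3;
      if (hc == 0) break;
      if (hc == 1) { out_pairs.push_back(std::make_pair(i - 1, j - 1)); --i; --j; }
      else if (hc == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      const bool opened = (c & 0x10) != 0;
      --i;
      if (opened) state = 0;
    } else {
      const bool opened = (c & 0x20) != 0;
      --j;
      if (opened) state = 0;
    }
  }
  std::reverse(out_pairs.begin(), out_pairs.end());
}

// Gapped X-drop extension outward from an anchor pair (qa, ta), which is
// kept as an aligned column. Returns total score and alignment blocks.
static void gapped_extend_core(const int* q, int lq, const int* t, int lt,
                               int qa, int ta, const int* S, int A,
                               int open, int extend, double xdrop,
                               int& out_score,
                               std::vector<std::pair<int, int> >& out_pairs) {
  out_pairs.clear();
  const int anchor = S[q[qa] + (size_t)t[ta] * A];
  // right side
  int rscore;
  std::vector<std::pair<int, int> > rpairs;
  xdrop_extend(q + qa + 1, lq - qa - 1, t + ta + 1, lt - ta - 1,
               S, A, open, extend, xdrop, rscore, rpairs);
  // left side on reversed prefixes
  std::vector<int> ur(qa), vr(ta);
  for (int k = 0; k < qa; ++k) ur[k] = q[qa - 1 - k];
  for (int k = 0; k < ta; ++k) vr[k] = t[ta - 1 - k];
  int lscore;
  std::vector<std::pair<int, int> > lpairs;
  xdrop_extend(ur.empty() ? q : &ur[0], qa, vr.empty() ? t : &vr[0], ta,
               S, A, open, extend, xdrop, lscore, lpairs);
  for (size_t k = lpairs.size(); k-- > 0;)
    out_pairs.push_back(std::make_pair(qa - 1 - lpairs[k].first, ta - 1 - lpairs[k].second));
  out_pairs.push_back(std::make_pair(qa, ta));
  for (size_t k = 0; k < rpairs.size(); ++k)
    out_pairs.push_back(std::make_pair(qa + 1 + rpairs[k].first, ta + 1 + rpairs[k].second));
  out_score = anchor + lscore + rscore;
}

// [[Rcpp::export]]
List cpp_gapped_extend(IntegerVector q, IntegerVector t, int qa, int ta,
                       IntegerMatrix S, int open, int extend, double xdrop) {
  int score;
  std::vector<std::pair<int, int> > pairs;
  gapped_extend_core(INTEGER(q), q.size(), INTEGER(t), t.size(), qa, ta,
                     INTEGER(S), S.nrow(), open, extend, xdrop, score, pairs);
  return List::create(_["score"] = score, _["blocks"] = pairs_to_blocks(pairs));
}

// ---------------------------------------------------------------- search pipeline

struct Candidate {
  int score, aq, at;  // anchor in (query pos, global text pos)
};

static bool cand_order(const Candidate& a, const Candidate& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.aq != b.aq) return a.aq < b.aq;
  return a.at < b.at;
}

// Per-query seed-and-extend search. Returns, per target with at least one
// computed alignment of score >= score_keep, the best-scoring alignment.
// Diagonal runs are segmented by a seed-independent positive-run scan, so
// detected pairs are monotone in the seed set (hence in m).
// [[Rcpp::export]]
List cpp_search_query(IntegerVector q, IntegerVector text, IntegerVector sa,
                      IntegerVector seq_of, IntegerVector seq_start,
                      IntegerVector seq_len, IntegerMatrix S,
                      double m, int min_len, int gapless_min,
                      int open, int extend, double gapped_xdrop) {
  const int* t = INTEGER(text);
  const int* s = INTEGER(sa);
  const int* Sp = INTEGER(S);
  const int A = S.nrow();
  const int qlen = q.size(), tlen = text.size(), nsa = sa.size();

  // 1. adaptive seeds, bucketed by global diagonal (tpos - qpos + qlen)
  //    with a counting sort; within a diagonal seed positions are ascending
  const int ndiag = tlen + qlen + 1;
  std::vector<int> dcount(ndiag, 0);
  std::vector<int> slo(qlen), shi(qlen);
  std::vector<char> sfound(qlen, 0);
  R_xlen_t total = 0;
  for (int q0 = 0; q0 < qlen; ++q0) {
    int lo = 0, hi = nsa, d = 0;
    while (q0 + d < qlen) {
      sa_narrow(t, s, d, q[q0 + d], lo, hi);
      ++d;
      if (hi <= lo) break;
      if (d >= min_len && (double)(hi - lo) <= m) {
        sfound[q0] = 1; slo[q0] = lo; shi[q0] = hi;
        break;
      }
    }
    if (sfound[q0]) {
      for (int i = slo[q0]; i < shi[q0]; ++i) ++dcount[s[i] - q0 + qlen];
      total += shi[q0] - slo[q0];
    }
  }
  if (total == 0)
    return List::create(_["target"] = IntegerVector(0),
                        _["score"] = IntegerVector(0),
                        _["blocks"] = List(0));
  std::vector<int> doff(ndiag + 1, 0);
  for (int i = 0; i < ndiag; ++i) doff[i + 1] = doff[i] + dcount[i];
  std::vector<int> bucket_q((size_t)total);
  {
    std::vector<int> fill(doff.begin(), doff.end() - 1);
    for (int q0 = 0; q0 < qlen; ++q0)
      if (sfound[q0])
        for (int i = slo[q0]; i < shi[q0]; ++i)
          bucket_q[fill[s[i] - q0 + qlen]++] = q0;
  }

  // 2. per-diagonal positive-run segmentation; keep runs holding a seed
  std::vector<Candidate> cands;
  for (int dg = 0; dg < ndiag; ++dg) {
    if (dcount[dg] == 0) continue;
    const int off = dg - qlen;
    const int q0 = std::max(0, -off);
    const int q1 = std::min(qlen - 1, tlen - 1 - off);
    int sp = doff[dg];
    const int spend = doff[dg + 1];
    int run_first = q0, runbest = 0, runbest_q = -1, runsum = 0;
    for (int qq = q0; qq <= q1 + 1; ++qq) {
      bool flush = false;
      int sc = 0;
      if (qq > q1) flush = true;
      else {
        const int tc = t[qq + off];
        if (tc >= A || tc < 0) flush = true;
        else sc = Sp[q[qq] + (size_t)tc * A];
      }
      if (!flush) {
        runsum += sc;
        if (runsum > runbest) { runbest = runsum; runbest_q = qq; }
        if (runsum < 0) flush = true;
      }
      if (flush) {
        if (runbest >= gapless_min && runbest_q >= 0) {
          while (sp < spend && bucket_q[sp] < run_first) ++sp;
          if (sp < spend && bucket_q[sp] <= qq) {
            Candidate c;
            c.score = runbest; c.aq = runbest_q; c.at = runbest_q + off;
            cands.push_back(c);
          }
        }
        run_first = qq + 1; runbest = 0; runbest_q = -1; runsum = 0;
      }
    }
  }
  std::sort(cands.begin(), cands.end(), cand_order);

  // 3. gapped extension of every candidate anchor, best-per-target kept.
  //    Candidates are processed in descending score order (deterministic
  //    tie-break), and each pair's result depends only on its own anchor
  //    set, which is monotone in the seed set -- so detected pairs are
  //    nested across increasing m.
  const int ntarg = seq_start.size();
  std::vector<int> best_score(ntarg, NEG);
  std::vector<std::vector<std::pair<int, int> > > best_pairs(ntarg);
  std::vector<int> tslice;
  int cnt = 0;
  for (size_t ci = 0; ci < cands.size(); ++ci) {
    if (++cnt % 256 == 0) Rcpp::checkUserInterrupt();
    const Candidate& c = cands[ci];
    const int tg = seq_of[c.at];
    const int ts0 = seq_start[tg], tl = seq_len[tg];
    const int at_local = c.at - ts0;
    tslice.assign(t + ts0, t + ts0 + tl);
    int score;
    std::vector<std::pair<int, int> > pairs;
    gapped_extend_core(INTEGER(q), qlen, &tslice[0], tl, c.aq, at_local,
                       Sp, A, open, extend, gapped_xdrop, score, pairs);
    if (score > best_score[tg]) {
      best_score[tg] = score;
      best_pairs[tg].swap(pairs);
    }
  }

  // 4. gather per-target best alignments
  std::vector<int> out_t, out_s;
  List out_blocks;
  for (int tg = 0; tg < ntarg; ++tg)
    if (best_score[tg] > NEG / 2) {
      out_t.push_back(tg);
      out_s.push_back(best_score[tg]);
      out_blocks.push_back(pairs_to_blocks(best_pairs[tg]));
    }
  return List::create(_["target"] = wrap(out_t),
                      _["score"] = wrap(out_s),
                      _["blocks"] = out_blocks);
}
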