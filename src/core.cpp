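#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---- scoring primitives -----------------------------------------------------
// Penalties are encoded as negative numbers throughout; the DP maximizes, so the
// least costly branch is always the max of the branch estimates.

static inline double ceil_frac(double x, int k) { return std::ceil(x / (double)k); }

// stage-1 chain extension cost for a signed query gap g (g = 1-k is a perfect
// k-1 overlap, negative g an overlap, positive g unanchored space)
static double p_cost(double g, int k, double M, double E, double W, double U) {
  if (g < 1.0 - k) return NEG_INF; // not chainable
  if (g == 1.0 - k) return (1.0 - k) * M;
  if (g < 0) return g * M + (std::fabs(g) - 1.0) * U + W;
  double c = ceil_frac(g, k);
  double mm = c * E + std::min(std::min(g - c, c), (double)k) * M;
  double gp = W + (g - 1.0) * U;
  return std::max(mm, gp);
}

// stage-1 chain opening cost, capped at L
static double o_cost(double ghat, double W, double U, double L) {
  if (ghat <= 0) return 0.0;
  return std::max(L, W + (ghat - 1.0) * U);
}

// stage-2 (mis)match join estimate
static double alpha_c(double m, int k, double M, double E) {
  if (m <= 0) return 0.0;
  double c = ceil_frac(m, k);
  return std::max(c, 2.0) * E + std::min(std::min(m - c, c), (double)k) * M;
}

// stage-2 gap join estimate
static double beta_c(double g, double M, double W, double U) {
  if (g == 0) return 0.0;
  if (g > 0) return W + (g - 1.0) * U;
  return W + (std::fabs(g) - 1.0) * U + g * M;
}

// stage-2 new-chain cost
static double gamma_c(double ghat, int k, double M, double E, double W, double U) {
  if (ghat <= 0) return 0.0;
  double c = ceil_frac(ghat, k);
  double mm = c * E + std::min(std::min(ghat - c, c), (double)k) * M;
  double gp = W + (ghat - 1.0) * U;
  return std::max(gp, mm);
}

// ---- sequence utilities -------------------------------------------------------

// reverse complement of DNA strings (non-ACGT characters become N)
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j];
      switch (c) {
        case 'A': r[j] = 'T'; break;
        case 'C': r[j] = 'G'; break;
        case 'G': r[j] = 'C'; break;
        case 'T': r[j] = 'A'; break;
        default: r[j] = 'N';
      }
    }
    out[i] = r;
  }
  return out;
}

// ---- minimizer selection ------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// 0-based start positions of the window minimizers of `s`: in every window of
// `w` consecutive m-mers the lexicographically smallest canonical m-mer (min of
// the m-mer and its reverse complement) is selected; ties go to the leftmost.
// m-mers containing N never win; positions are returned sorted and unique.
// [[Rcpp::export]]
IntegerVector cpp_minimizer_positions(std::string s, int m, int w) {
  int n = s.size();
  int np = n - m + 1; // number of m-mer positions
  if (np <= 0) return IntegerVector(0);
  if (w < 1) w = 1;
  // canonical m-mer per position (empty string marks N-containing m-mers)
  std::vector<std::string> can(np);
  for (int i = 0; i < np; ++i) {
    bool hasN = false;
    std::string fwd = s.substr(i, m), rc(m, 'N');
    for (int j = 0; j < m; ++j) {
      if (fwd[j] == 'N') { hasN = true; break; }
      rc[m - 1 - j] = comp_base(fwd[j]);
    }
    if (!hasN) can[i] = std::min(fwd, rc);
  }
  std::vector<int> pos;
  int nwin = std::max(np - w + 1, 1);
  for (int start = 0; start < nwin; ++start) {
    int stop = std::min(start + w, np);
    int best = -1;
    for (int i = start; i < stop; ++i) {
      if (can[i].empty()) continue;
      if (best < 0 || can[i] < can[best]) best = i;
    }
    if (best >= 0 && (pos.empty() || pos.back() != best)) pos.push_back(best);
  }
  std::sort(pos.begin(), pos.end());
  pos.erase(std::unique(pos.begin(), pos.end()), pos.end());
  return wrap(pos);
}

// ---- anchor handling --------------------------------------------------------

// Merge per-seed hits (qpos, tpos, 0-based) lying on one diagonal into maximal
// runs; overlapping or abutting hits on the same diagonal collapse to one anchor.
// [[Rcpp::export]]
IntegerMatrix cpp_merge_hits(IntegerVector qpos, IntegerVector tpos, int seedlen) {
  int n = qpos.size();
  if (n == 0) return IntegerMatrix(0, 3);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    long da = (long)tpos[a] - qpos[a], db = (long)tpos[b] - qpos[b];
    if (da != db) return da < db;
    return qpos[a] < qpos[b];
  });
  std::vector<int> qs, ts, len;
  int cq = qpos[idx[0]], ct = tpos[idx[0]], cend = cq + seedlen;
  long cdiag = (long)ct - cq;
  for (int r = 1; r < n; ++r) {
    int i = idx[r];
    long d = (long)tpos[i] - qpos[i];
    if (d == cdiag && qpos[i] <= cend) {
      cend = std::max(cend, qpos[i] + seedlen);
    } else {
      qs.push_back(cq); ts.push_back(ct); len.push_back(cend - cq);
      cq = qpos[i]; ct = tpos[i]; cend = cq + seedlen; cdiag = d;
    }
  }
  qs.push_back(cq); ts.push_back(ct); len.push_back(cend - cq);
  IntegerMatrix out(qs.size(), 3);
  for (size_t i = 0; i < qs.size(); ++i) {
    out(i, 0) = qs[i]; out(i, 1) = ts[i]; out(i, 2) = len[i];
  }
  colnames(out) = CharacterVector::create("q_start", "t_start", "length");
  return out;
}

// Greedy exact extension of anchors (needed when seeds are subsampled
// minimizers); merges duplicates afterwards.
// [[Rcpp::export]]
IntegerMatrix cpp_extend_anchors(IntegerMatrix anchors, std::string q, std::string t) {
  int n = anchors.nrow();
  std::vector<std::array<long, 3>> ext;
  ext.reserve(n);
  for (int i = 0; i < n; ++i) {
    long qs = anchors(i, 0), ts = anchors(i, 1), len = anchors(i, 2);
    while (qs > 0 && ts > 0 && q[qs - 1] == t[ts - 1] && q[qs - 1] != 'N') {
      --qs; --ts; ++len;
    }
    while (qs + len < (long)q.size() && ts + len < (long)t.size() &&
           q[qs + len] == t[ts + len] && q[qs + len] != 'N') {
      ++len;
    }
    ext.push_back({qs, ts, len});
  }
  std::sort(ext.begin(), ext.end());
  ext.erase(std::unique(ext.begin(), ext.end()), ext.end());
  IntegerMatrix out(ext.size(), 3);
  for (size_t i = 0; i < ext.size(); ++i) {
    out(i, 0) = ext[i][0]; out(i, 1) = ext[i][1]; out(i, 2) = ext[i][2];
  }
  colnames(out) = CharacterVector::create("q_start", "t_start", "length");
  return out;
}

// ---- chaining DPs -----------------------------------------------------------

static bool sets_intersect(const IntegerVector &a, const IntegerVector &b) {
  int i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) return true;
    if (a[i] < b[j]) ++i; else ++j;
  }
  return false;
}

// Stage-1 chaining over query coordinates. Anchors must be sorted by q_start.
// sets: per-anchor sorted template-ID sets; a link is feasible only between
// anchors whose signature sets share at least one template (empty set = wildcard).
// [[Rcpp::export]]
List cpp_chain_query(IntegerVector qs, IntegerVector len, NumericVector w, List sets,
                     int k, double M, double E, double W, double U, double L,
                     int qlen) {
  int n = qs.size();
  NumericVector f(n), total(n);
  IntegerVector prev(n);
  std::vector<IntegerVector> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = sets[i];
  for (int i = 0; i < n; ++i) {
    int qe_i = qs[i] + len[i];
    double best = o_cost(qs[i], W, U, L);
    int bp = -1;
    for (int j = 0; j < i; ++j) {
      if (qs[j] >= qs[i]) continue;
      int qe_j = qs[j] + len[j];
      if (qe_j >= qe_i) continue;
      double g = (double)qs[i] - qe_j;
      double pc = p_cost(g, k, M, E, W, U);
      if (pc == NEG_INF) continue;
      if (sv[i].size() && sv[j].size() && !sets_intersect(sv[i], sv[j])) continue;
      double cand = f[j] + pc;
      if (cand > best) { best = cand; bp = j; }
    }
    f[i] = w[i] + best;
    prev[i] = bp + 1; // 1-based, 0 = chain start
    total[i] = f[i] + o_cost((double)qlen - qe_i, W, U, L);
  }
  return List::create(_["f"] = f, _["prev"] = prev, _["total"] = total);
}

// Stage-2 chaining over (query, template) coordinates; anchors sorted by q_start.
// In global mode the opening cost is the new-chain estimate over the template
// prefix and `total` adds the mirror estimate over the template suffix; in free
// (dovetail) mode both ends are unpenalized.
// [[Rcpp::export]]
List cpp_chain_pair(IntegerVector qs, IntegerVector ts, IntegerVector len,
                    int k, double M, double E, double W, double U,
                    int tlen, bool global_ends) {
  int n = qs.size();
  NumericVector f(n), total(n);
  IntegerVector prev(n);
  for (int i = 0; i < n; ++i) {
    int te_i = ts[i] + len[i];
    double best = global_ends ? gamma_c(ts[i], k, M, E, W, U) : 0.0;
    int bp = -1;
    for (int j = 0; j < i; ++j) {
      if (qs[j] >= qs[i] || ts[j] >= ts[i]) continue;
      double dq = (double)qs[i] - (qs[j] + len[j]);
      double dt = (double)ts[i] - (ts[j] + len[j]);
      if (dq < 0 || dt < 0) continue;
      double cand = f[j] + alpha_c(std::min(dq, dt), k, M, E) + beta_c(dq - dt, M, W, U);
      if (cand > best) { best = cand; bp = j; }
    }
    f[i] = len[i] * M + best;
    prev[i] = bp + 1;
    double close = global_ends ? gamma_c((double)tlen - te_i, k, M, E, W, U) : 0.0;
    total[i] = f[i] + close;
  }
  return List::create(_["f"] = f, _["prev"] = prev, _["total"] = total);
}

// ---- affine-gap global alignment (Gotoh) ------------------------------------

struct NWResult {
  double score;
  std::vector<int> ops; // 1=match 2=mismatch 3=insertion(query) 4=deletion(template)
  int a_clip_begin, a_clip_end, b_clip_begin, b_clip_end;
};

// a = query, b = template. A gap of length n costs W + (n-1)U.
// free_*_begin / free_*_end make leading / trailing overhangs of that sequence
// free (soft-clipped); all four set gives dovetail semantics.
// band >= 0 restricts the DP to |i - j - d0| <= band around the diagonal
// through the anchored corner (d0 = m - n when the end is anchored at (m, n),
// 0 when anchored at (0, 0)); used only for free-end terminal segments, where
// paths far off that diagonal cannot pay for their gaps.
static NWResult nw_core(const std::string &a, const std::string &b,
                        double M, double E, double W, double U,
                        bool fa0, bool fb0, bool fa1, bool fb1,
                        int band = -1, int d0 = 0) {
  int m = a.size(), n = b.size();
  NWResult res;
  res.a_clip_begin = res.a_clip_end = res.b_clip_begin = res.b_clip_end = 0;
  res.score = 0.0;
  if (m == 0 && n == 0) return res;
  if (m == 0) { // pure template run
    if (fb0) { res.b_clip_begin = n; }
    else if (fb1) { res.b_clip_end = n; }
    else { res.score = W + (n - 1) * U; res.ops.assign(n, 4); }
    return res;
  }
  if (n == 0) {
    if (fa0) { res.a_clip_begin = m; }
    else if (fa1) { res.a_clip_end = m; }
    else { res.score = W + (m - 1) * U; res.ops.assign(m, 3); }
    return res;
  }
  int C = n + 1;
  std::vector<double> H((size_t)(m + 1) * C, NEG_INF), X((size_t)(m + 1) * C, NEG_INF),
      Y((size_t)(m + 1) * C, NEG_INF), B((size_t)(m + 1) * C, NEG_INF);
  auto at = [C](int i, int j) { return (size_t)i * C + j; };
  auto in_band = [band, d0](int i, int j) {
    return band < 0 || std::abs(i - j - d0) <= band;
  };
  if (in_band(0, 0)) B[at(0, 0)] = 0.0;
  for (int j = 1; j <= n; ++j) {
    if (!in_band(0, j)) continue;
    X[at(0, j)] = fb0 ? 0.0 : W + (j - 1) * U;
    B[at(0, j)] = X[at(0, j)];
  }
  for (int i = 1; i <= m; ++i) {
    if (!in_band(i, 0)) continue;
    Y[at(i, 0)] = fa0 ? 0.0 : W + (i - 1) * U;
    B[at(i, 0)] = Y[at(i, 0)];
  }
  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (band >= 0) {
      jlo = std::max(1, i - d0 - band);
      jhi = std::min(n, i - d0 + band);
      if (jlo > jhi) continue;
    }
    for (int j = jlo; j <= jhi; ++j) {
      double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? M : E;
      double h0 = B[at(i - 1, j - 1)];
      // with both leading overhangs free the alignment may start at any cell,
      // clipping a prefix of each sequence
      if (fa0 && fb0 && h0 < 0.0) h0 = 0.0;
      H[at(i, j)] = h0 + s;
      X[at(i, j)] = std::max(B[at(i, j - 1)] + W, X[at(i, j - 1)] + U);
      Y[at(i, j)] = std::max(B[at(i - 1, j)] + W, Y[at(i - 1, j)] + U);
      B[at(i, j)] = std::max(H[at(i, j)], std::max(X[at(i, j)], Y[at(i, j)]));
    }
  }
  // end cell: prefer the full corner; free ends may clip a suffix (of either
  // sequence, or of both when both trailing overhangs are free)
  int ei = m, ej = n;
  double best = B[at(m, n)];
  if (fa1 && fb1) {
    for (int i = m; i >= 0; --i)
      for (int j = n; j >= 0; --j)
        if (B[at(i, j)] > best) { best = B[at(i, j)]; ei = i; ej = j; }
  } else if (fa1) {
    for (int i = m - 1; i >= 0; --i)
      if (B[at(i, n)] > best) { best = B[at(i, n)]; ei = i; ej = n; }
  } else if (fb1) {
    for (int j = n - 1; j >= 0; --j)
      if (B[at(m, j)] > best) { best = B[at(m, j)]; ei = m; ej = j; }
  }
  res.score = best;
  res.a_clip_end = m - ei;
  res.b_clip_end = n - ej;

  // traceback; preference: diagonal (match/mismatch) > deletion > insertion,
  // and gap extension over gap opening within a gap state.
  auto pick = [&](int i, int j) -> int { // 1=H 2=X 3=Y
    double bij = B[at(i, j)];
    if (i > 0 && j > 0 && H[at(i, j)] == bij) return 1;
    if (j > 0 && X[at(i, j)] == bij) return 2;
    return 3;
  };
  std::vector<int> rops;
  int i = ei, j = ej;
  int state = (i == 0 && j == 0) ? 0 : pick(i, j);
  while (i > 0 || j > 0) {
    if (i == 0) { // leading template overhang
      if (fb0) res.b_clip_begin = j;
      else rops.insert(rops.end(), j, 4);
      break;
    }
    if (j == 0) { // leading query overhang
      if (fa0) res.a_clip_begin = i;
      else rops.insert(rops.end(), i, 3);
      break;
    }
    if (state == 1) {
      rops.push_back((a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? 1 : 2);
      bool fresh = fa0 && fb0 && B[at(i - 1, j - 1)] < 0.0;
      --i; --j;
      if (fresh) { // alignment started here; clip both leading overhangs
        res.a_clip_begin = i;
        res.b_clip_begin = j;
        break;
      }
      if (i > 0 || j > 0) state = pick(i, j);
    } else if (state == 2) {
      rops.push_back(4);
      bool ext = (j > 1) && (X[at(i, j)] == X[at(i, j - 1)] + U);
      --j;
      if (!ext && (i > 0 || j > 0)) state = pick(i, j);
    } else {
      rops.push_back(3);
      bool ext = (i > 1) && (Y[at(i, j)] == Y[at(i - 1, j)] + U);
      --i;
      if (ext) state = 3;
      else if (i > 0 || j > 0) state = pick(i, j);
    }
  }
  std::reverse(rops.begin(), rops.end());
  res.ops = rops;
  return res;
}

static IntegerMatrix ops_rle(const std::vector<int> &ops) {
  std::vector<int> op, len;
  for (size_t i = 0; i < ops.size(); ++i) {
    if (!op.empty() && op.back() == ops[i]) ++len.back();
    else { op.push_back(ops[i]); len.push_back(1); }
  }
  IntegerMatrix out(op.size(), 2);
  for (size_t i = 0; i < op.size(); ++i) { out(i, 0) = op[i]; out(i, 1) = len[i]; }
  colnames(out) = CharacterVector::create("op", "len");
  return out;
}

// [[Rcpp::export]]
List cpp_nw(std::string a, std::string b, double M, double E, double W, double U,
            bool free_a_begin, bool free_b_begin, bool free_a_end, bool free_b_end) {
  NWResult r = nw_core(a, b, M, E, W, U, free_a_begin, free_b_begin, free_a_end, free_b_end);
  return List::create(_["score"] = r.score, _["ops"] = ops_rle(r.ops),
                      _["a_clip_begin"] = r.a_clip_begin, _["a_clip_end"] = r.a_clip_end,
                      _["b_clip_begin"] = r.b_clip_begin, _["b_clip_end"] = r.b_clip_end);
}

// Join a collinear anchor chain into a full alignment. Anchors (q_start,
// t_start, length; 0-based, sorted, non-overlapping) are trimmed to cores that
// are kept as forced matches; every region between cores (and the two terminal
// regions) is aligned with the affine DP above. free_ends = dovetail.
// [[Rcpp::export]]
List cpp_join(std::string q, std::string t, IntegerMatrix anchors,
              double M, double E, double W, double U, int trim, bool free_ends) {
  int na = anchors.nrow();
  std::vector<int> cq(na), ct(na), cl(na);
  for (int i = 0; i < na; ++i) {
    int len = anchors(i, 2);
    int d = std::min(trim, (len - 1) / 2);
    cq[i] = anchors(i, 0) + d;
    ct[i] = anchors(i, 1) + d;
    cl[i] = len - 2 * d;
  }
  double score = 0.0;
  std::vector<int> ops;
  int q_clip0 = 0, t_clip0 = 0;
  int qcur = 0, tcur = 0;
  const int PAD = 48; // dovetail terminal window beyond the shorter overhang
  for (int i = 0; i <= na; ++i) {
    int qstop = (i < na) ? cq[i] : (int)q.size();
    int tstop = (i < na) ? ct[i] : (int)t.size();
    bool first = (i == 0), last = (i == na);
    int qdrop = 0, tdrop = 0; // free-end prefix/suffix skipped outright
    int qa = qcur, ta = tcur, qlen_seg = qstop - qcur, tlen_seg = tstop - tcur;
    if (free_ends && na > 0 && first) {
      // a leading overhang longer than the other side plus PAD cannot pay for
      // itself under free-end scoring; clip it before the DP
      int cap = std::min(qlen_seg, tlen_seg) + PAD;
      if (qlen_seg > cap) { qdrop = qlen_seg - cap; qa += qdrop; qlen_seg = cap; }
      if (tlen_seg > cap) { tdrop = tlen_seg - cap; ta += tdrop; tlen_seg = cap; }
    }
    if (free_ends && na > 0 && last) {
      int cap = std::min(qlen_seg, tlen_seg) + PAD;
      if (qlen_seg > cap) qlen_seg = cap;
      if (tlen_seg > cap) tlen_seg = cap;
    }
    int band = -1, d0 = 0;
    if (free_ends && na > 0 && first != last) {
      band = 64;
      d0 = first ? qlen_seg - tlen_seg : 0; // diagonal through anchored corner
    }
    NWResult r = nw_core(q.substr(qa, qlen_seg), t.substr(ta, tlen_seg),
                         M, E, W, U,
                         first && free_ends, first && free_ends,
                         last && free_ends, last && free_ends,
                         band, d0);
    score += r.score;
    if (first) { q_clip0 = qdrop + r.a_clip_begin; t_clip0 = tdrop + r.b_clip_begin; }
    ops.insert(ops.end(), r.ops.begin(), r.ops.end());
    if (i < na) {
      score += cl[i] * M;
      ops.insert(ops.end(), cl[i], 1);
      qcur = cq[i] + cl[i];
      tcur = ct[i] + cl[i];
    }
  }
  long matches = 0, qspan = 0, tspan = 0;
  for (int o : ops) {
    if (o == 1) ++matches;
    if (o == 1 || o == 2 || o == 3) ++qspan;
    if (o == 1 || o == 2 || o == 4) ++tspan;
  }
  return List::create(_["score"] = score, _["ops"] = ops_rle(ops),
                      _["matches"] = (double)matches,
                      _["q_begin"] = q_clip0, _["q_end"] = q_clip0 + (int)qspan,
                      _["t_begin"] = t_clip0, _["t_end"] = t_clip0 + (int)tspan);
}
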