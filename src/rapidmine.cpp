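// Compiled kernels: affine-gap identity alignment, k-word counting, greedy
// incremental clustering with an inverted word index, and profile-profile
// progressive alignment. All tie-breaks are deterministic (diagonal > gap in
// second sequence > gap in first; clusters scanned in creation order).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <cstdint>
#include <climits>

using namespace Rcpp;

static const int NAA = 20;

// alphabet order shared with the R side: ARNDCQEGHILKMFPSTWYV
static inline int aa_index(char c) {
  switch (c) {
    case 'A': return 0;  case 'R': return 1;  case 'N': return 2;  case 'D': return 3;
    case 'C': return 4;  case 'Q': return 5;  case 'E': return 6;  case 'G': return 7;
    case 'H': return 8;  case 'I': return 9;  case 'L': return 10; case 'K': return 11;
    case 'M': return 12; case 'F': return 13; case 'P': return 14; case 'S': return 15;
    case 'T': return 16; case 'W': return 17; case 'Y': return 18; case 'V': return 19;
    case 'y': return 18; // d-initiator: scored as Tyr, rendered as 'y'
    default: return -1;
  }
}

static std::vector<int> encode_pep(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int a = aa_index(s[i]);
    if (a < 0) stop("invalid residue '%c' in peptide '%s'", s[i], s.c_str());
    v[i] = a;
  }
  return v;
}

// ---------------------------------------------------------------------------
// Identity alignment (match 1 / mismatch 0, affine gaps). Returns the number
// of identical aligned positions on the optimal-score path (ties resolved
// toward more identities). A gap of length g costs go + (g - 1) * ge.
// ---------------------------------------------------------------------------
// Integer fast path for integral gap costs: scores and match counts are packed
// into one int (score * 64 + matches; matches < 64 for library-scale peptides)
// so the lexicographic (score, matches) maximisation is a plain max. Scratch
// buffers are reused across calls — the all-pairs distance stage runs millions
// of these DPs.
static int identity_matches_int(const std::vector<int>& a, const std::vector<int>& b,
                                int go, int ge) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la >= 60 || lb >= 60) return -1;      // packing headroom
  const int NEG = INT_MIN / 4;
  const int W = lb + 1;
  static std::vector<int> M, X, Y, Mp, Xp, Yp;
  if ((int)M.size() < W) {
    M.resize(W); X.resize(W); Y.resize(W);
    Mp.resize(W); Xp.resize(W); Yp.resize(W);
  }
  Mp[0] = 0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= lb; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = -(go + (j - 1) * ge) * 64;
  }
  for (int i = 1; i <= la; ++i) {
    M[0] = NEG; Y[0] = NEG;
    X[0] = -(go + (i - 1) * ge) * 64;
    const int ai = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      const int eq = (ai == b[j - 1]) ? 65 : 0;   // +1 score, +1 match
      int d = Mp[j - 1];
      if (Xp[j - 1] > d) d = Xp[j - 1];
      if (Yp[j - 1] > d) d = Yp[j - 1];
      M[j] = d + eq;
      int xo = Mp[j] > Yp[j] ? Mp[j] : Yp[j];
      xo -= go * 64;
      int xe = Xp[j] - ge * 64;
      X[j] = xe > xo ? xe : xo;
      int yo = M[j - 1] > X[j - 1] ? M[j - 1] : X[j - 1];
      yo -= go * 64;
      int ye = Y[j - 1] - ge * 64;
      Y[j] = ye > yo ? ye : yo;
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  int best = Mp[lb];
  if (Xp[lb] > best) best = Xp[lb];
  if (Yp[lb] > best) best = Yp[lb];
  return ((best % 64) + 64) % 64;
}

static int identity_matches(const std::vector<int>& a, const std::vector<int>& b,
                            double go, double ge) {
  if (go == std::floor(go) && ge == std::floor(ge) &&
      a.size() < 60 && b.size() < 60) {
    int m = identity_matches_int(a, b, (int)go, (int)ge);
    if (m >= 0) return m;
  }
  const int la = (int)a.size(), lb = (int)b.size();
  const double NEG = -1e18;
  const int W = lb + 1;

  std::vector<double> Ms(W), Xs(W), Ys(W), Mp(W), Xp(W), Yp(W);
  std::vector<int>    Mm(W), Xm(W), Ym(W), Mmp(W), Xmp(W), Ymp(W);

  Mp[0] = 0.0; Mmp[0] = 0;
  Xp[0] = NEG; Xmp[0] = 0;
  Yp[0] = NEG; Ymp[0] = 0;
  for (int j = 1; j <= lb; ++j) {
    Mp[j] = NEG; Mmp[j] = 0;
    Xp[j] = NEG; Xmp[j] = 0;
    Yp[j] = -(go + (j - 1) * ge); Ymp[j] = 0;
  }

  for (int i = 1; i <= la; ++i) {
    Ms[0] = NEG; Mm[0] = 0;
    Xs[0] = -(go + (i - 1) * ge); Xm[0] = 0;
    Ys[0] = NEG; Ym[0] = 0;
    for (int j = 1; j <= lb; ++j) {
      const int eq = (a[i - 1] == b[j - 1]) ? 1 : 0;
      // M from best of previous diagonal states
      double bs = Mp[j - 1]; int bm = Mmp[j - 1];
      if (Xp[j - 1] > bs + 1e-12 || (std::fabs(Xp[j - 1] - bs) <= 1e-12 && Xmp[j - 1] > bm)) { bs = Xp[j - 1]; bm = Xmp[j - 1]; }
      if (Yp[j - 1] > bs + 1e-12 || (std::fabs(Yp[j - 1] - bs) <= 1e-12 && Ymp[j - 1] > bm)) { bs = Yp[j - 1]; bm = Ymp[j - 1]; }
      Ms[j] = bs + eq; Mm[j] = bm + eq;
      // X: gap column in b (consume a)
      double xo = Mp[j] - go; int xom = Mmp[j];
      if (Yp[j] - go > xo + 1e-12 || (std::fabs(Yp[j] - go - xo) <= 1e-12 && Ymp[j] > xom)) { xo = Yp[j] - go; xom = Ymp[j]; }
      double xe = Xp[j] - ge; int xem = Xmp[j];
      if (xe > xo + 1e-12 || (std::fabs(xe - xo) <= 1e-12 && xem > xom)) { Xs[j] = xe; Xm[j] = xem; }
      else { Xs[j] = xo; Xm[j] = xom; }
      // Y: gap column in a (consume b)
      double yo = Ms[j - 1] - go; int yom = Mm[j - 1];
      if (Xs[j - 1] - go > yo + 1e-12 || (std::fabs(Xs[j - 1] - go - yo) <= 1e-12 && Xm[j - 1] > yom)) { yo = Xs[j - 1] - go; yom = Xm[j - 1]; }
      double ye = Yp[j - 1] - ge; int yem = Ymp[j - 1];
      if (ye > yo + 1e-12 || (std::fabs(ye - yo) <= 1e-12 && yem > yom)) { Ys[j] = ye; Ym[j] = yem; }
      else { Ys[j] = yo; Ym[j] = yom; }
    }
    std::swap(Ms, Mp); std::swap(Mm, Mmp);
    std::swap(Xs, Xp); std::swap(Xm, Xmp);
    std::swap(Ys, Yp); std::swap(Ym, Ymp);
  }
  double bs = Mp[lb]; int bm = Mmp[lb];
  if (Xp[lb] > bs + 1e-12 || (std::fabs(Xp[lb] - bs) <= 1e-12 && Xmp[lb] > bm)) { bs = Xp[lb]; bm = Xmp[lb]; }
  if (Yp[lb] > bs + 1e-12 || (std::fabs(Yp[lb] - bs) <= 1e-12 && Ymp[lb] > bm)) { bs = Yp[lb]; bm = Ymp[lb]; }
  return bm;
}

// [[Rcpp::export]]
double cpp_seq_identity(std::string a, std::string b, double go, double ge) {
  if (a.empty() || b.empty()) stop("empty sequence");
  std::vector<int> ea = encode_pep(a), eb = encode_pep(b);
  int m = identity_matches(ea, eb, go, ge);
  return (double)m / (double)std::min(ea.size(), eb.size());
}

// condensed lower-triangle distance vector (1 - identity), dist() ordering
// [[Rcpp::export]]
NumericVector cpp_identity_dist(CharacterVector seqs, double go, double ge) {
  const int n = seqs.size();
  std::vector<std::vector<int>> enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode_pep(as<std::string>(seqs[i]));
  NumericVector out((double)n * (n - 1) / 2);
  R_xlen_t idx = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int m = identity_matches(enc[i], enc[j], go, ge);
      double id = (double)m / (double)std::min(enc[i].size(), enc[j].size());
      out[idx++] = 1.0 - id;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-word machinery
// ---------------------------------------------------------------------------
static int word_space(int k) {
  int s = 1;
  for (int i = 0; i < k; ++i) s *= (NAA + 1);
  return s;
}

static void word_counts(const std::vector<int>& s, int k, std::vector<std::pair<int,int>>& out,
                        std::vector<int>& scratch) {
  out.clear();
  const int n = (int)s.size() - k + 1;
  for (int i = 0; i < n; ++i) {
    int w = 0;
    for (int t = 0; t < k; ++t) w = w * (NAA + 1) + s[i + t];
    if (scratch[w] == 0) out.push_back(std::make_pair(w, 0));
    scratch[w]++;
  }
  for (size_t i = 0; i < out.size(); ++i) {
    out[i].second = scratch[out[i].first];
    scratch[out[i].first] = 0;
  }
}

// multiset intersection of k-words
// [[Rcpp::export]]
int cpp_shared_words(std::string a, std::string b, int k) {
  if (k < 1 || k > 3) stop("word length k must be in 1..3");
  std::vector<int> ea = encode_pep(a), eb = encode_pep(b);
  if ((int)ea.size() < k || (int)eb.size() < k) return 0;
  std::vector<int> scratch(word_space(k), 0);
  std::vector<std::pair<int,int>> wa, wb;
  word_counts(ea, k, wa, scratch);
  word_counts(eb, k, wb, scratch);
  for (size_t i = 0; i < wb.size(); ++i) scratch[wb[i].first] = wb[i].second;
  int shared = 0;
  for (size_t i = 0; i < wa.size(); ++i)
    shared += std::min(wa[i].second, scratch[wa[i].first]);
  for (size_t i = 0; i < wb.size(); ++i) scratch[wb[i].first] = 0;
  return shared;
}

// Minimum number of shared k-words any pair with identity >= threshold must
// have. Deliberately slack: identity >= t guarantees m >= ceil(t * Ls) matched
// columns; the matched run structure can be broken by at most
// 2 * (Ls - m) + (Ll - Ls) non-match columns under the identity scoring
// (each gap column costs >= ge, so alignments this gappy are never optimal
// unless they buy matches back), and each break spoils at most k - 1 words.
// Length difference can additionally spoil k * (Ll - Ls) words.
// [[Rcpp::export]]
int cpp_word_bound(int ls, int ll, int k, double threshold) {
  if (ls > ll) std::swap(ls, ll);
  int m_min = (int)std::ceil(threshold * ls - 1e-9);
  int runs = 2 * (ls - m_min) + (ll - ls) + 1;
  int req = (m_min - k + 1) - (k - 1) * (runs - 1) - k * (ll - ls);
  // m_min - k + 1 words if all matches are one run; each extra run loses k - 1
  return req > 0 ? req : 0;
}

// ---------------------------------------------------------------------------
// Greedy incremental clustering (records pre-sorted by descending abundance).
// Each sequence joins the first existing cluster (creation order) whose
// representative passes the word prefilter and has identity >= threshold,
// else founds a new cluster.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_greedy_cluster(CharacterVector seqs, double threshold, int wordk,
                        bool prefilter, double go, double ge) {
  const int n = seqs.size();
  if (wordk < 1 || wordk > 3) stop("word length k must be in 1..3");
  std::vector<std::vector<int>> enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode_pep(as<std::string>(seqs[i]));

  IntegerVector cluster(n);
  NumericVector identity(n);
  std::vector<int> repIdx;                 // seq index of each representative
  const int WS = word_space(wordk);
  std::vector<std::vector<std::pair<int,int>>> postings(WS); // word -> (rep, count)
  std::vector<int> shared;                 // per-rep accumulated shared words
  std::vector<int> touched;
  std::vector<int> scratch(WS, 0);
  std::vector<std::pair<int,int>> qwords;

  for (int q = 0; q < n; ++q) {
    const int lq = (int)enc[q].size();
    bool usefilter = prefilter && lq >= wordk;
    if (usefilter) {
      word_counts(enc[q], wordk, qwords, scratch);
      for (size_t wi = 0; wi < qwords.size(); ++wi) {
        const std::vector<std::pair<int,int>>& pl = postings[qwords[wi].first];
        const int qc = qwords[wi].second;
        for (size_t pi = 0; pi < pl.size(); ++pi) {
          const int r = pl[pi].first;
          if (shared[r] == 0) touched.push_back(r);
          shared[r] += std::min(qc, pl[pi].second);
        }
      }
    }
    int hit = -1; double hitId = 0.0;
    for (size_t r = 0; r < repIdx.size(); ++r) {
      const int lr = (int)enc[repIdx[r]].size();
      const int ls = std::min(lq, lr), ll = std::max(lq, lr);
      if (usefilter) {
        int req = cpp_word_bound(ls, ll, wordk, threshold);
        if (req > 0 && shared[r] < req) continue;
      }
      int m = identity_matches(enc[q], enc[repIdx[r]], go, ge);
      double id = (double)m / (double)ls;
      if (id >= threshold - 1e-9) { hit = (int)r; hitId = id; break; }
    }
    for (size_t t = 0; t < touched.size(); ++t) shared[touched[t]] = 0;
    touched.clear();

    if (hit >= 0) {
      cluster[q] = hit + 1;
      identity[q] = hitId;
    } else {
      repIdx.push_back(q);
      shared.push_back(0);
      cluster[q] = (int)repIdx.size();
      identity[q] = 1.0;
      if (lq >= wordk) {
        word_counts(enc[q], wordk, qwords, scratch);
        for (size_t wi = 0; wi < qwords.size(); ++wi)
          postings[qwords[wi].first].push_back(
              std::make_pair((int)repIdx.size() - 1, qwords[wi].second));
      }
    }
    if ((q & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector reps(repIdx.size());
  for (size_t r = 0; r < repIdx.size(); ++r) reps[r] = repIdx[r] + 1;
  return List::create(_["cluster"] = cluster, _["identity"] = identity,
                      _["representatives"] = reps);
}

// ---------------------------------------------------------------------------
// Profile-profile Gotoh alignment with traceback. Profiles are residue
// frequency columns (gap frequency contributes score 0). Gap of length g
// costs go + (g - 1) * ge. Tie-break: diagonal > gap-in-B > gap-in-A.
// ---------------------------------------------------------------------------
struct ProfCol { std::vector<std::pair<int,double>> res; }; // residue, freq (non-gap only)

static void make_profile(const std::vector<std::vector<int>>& rows,
                         const std::vector<const std::string*>& src,
                         std::vector<ProfCol>& prof) {
  const int W = rows.empty() ? 0 : (int)rows[0].size();
  const int n = (int)rows.size();
  prof.assign(W, ProfCol());
  std::vector<double> cnt(NAA);
  for (int c = 0; c < W; ++c) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int m = 0; m < n; ++m) {
      int p = rows[m][c];
      if (p >= 0) cnt[aa_index((*src[m])[p])] += 1.0;
    }
    for (int a = 0; a < NAA; ++a)
      if (cnt[a] > 0) prof[c].res.push_back(std::make_pair(a, cnt[a] / n));
  }
}

static double col_score(const ProfCol& A, const ProfCol& B, const NumericMatrix& sub) {
  double s = 0.0;
  for (size_t i = 0; i < A.res.size(); ++i)
    for (size_t j = 0; j < B.res.size(); ++j)
      s += A.res[i].second * B.res[j].second * sub(A.res[i].first, B.res[j].first);
  return s;
}

// ops: 0 = consume both, 1 = consume A only (gap in B), 2 = consume B only
static double profile_dp(const std::vector<ProfCol>& A, const std::vector<ProfCol>& B,
                         const NumericMatrix& sub, double go, double ge,
                         std::vector<int>& ops) {
  const int la = (int)A.size(), lb = (int)B.size();
  const double NEG = -1e18;
  const int W = lb + 1;
  std::vector<double> M((la + 1) * W, NEG), X((la + 1) * W, NEG), Y((la + 1) * W, NEG);
  std::vector<uint8_t> tM((la + 1) * W, 0), tX((la + 1) * W, 0), tY((la + 1) * W, 0);
  // traceback codes: in tM, predecessor state 0=M 1=X 2=Y; in tX/tY, 0=open-from-M
  // 1=extend, 2=open-from-other-gap
  M[0] = 0.0;
  for (int i = 1; i <= la; ++i) { X[i * W] = -(go + (i - 1) * ge); tX[i * W] = 1; }
  for (int j = 1; j <= lb; ++j) { Y[j] = -(go + (j - 1) * ge); tY[j] = 1; }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const int id = i * W + j, dg = (i - 1) * W + (j - 1), up = (i - 1) * W + j, lf = i * W + (j - 1);
      const double s = col_score(A[i - 1], B[j - 1], sub);
      // M
      double bs = M[dg]; uint8_t bt = 0;
      if (X[dg] > bs + 1e-12) { bs = X[dg]; bt = 1; }
      if (Y[dg] > bs + 1e-12) { bs = Y[dg]; bt = 2; }
      M[id] = bs + s; tM[id] = bt;
      // X (gap in B, consume A)
      double xo = M[up] - go; uint8_t xt = 0;
      if (Y[up] - go > xo + 1e-12) { xo = Y[up] - go; xt = 2; }
      if (X[up] - ge > xo + 1e-12) { xo = X[up] - ge; xt = 1; }
      X[id] = xo; tX[id] = xt;
      // Y (gap in A, consume B)
      double yo = M[lf] - go; uint8_t yt = 0;
      if (X[lf] - go > yo + 1e-12) { yo = X[lf] - go; yt = 2; }
      if (Y[lf] - ge > yo + 1e-12) { yo = Y[lf] - ge; yt = 1; }
      Y[id] = yo; tY[id] = yt;
    }
  }

  int i = la, j = lb;
  int state = 0; double best = M[la * W + lb];
  if (X[la * W + lb] > best + 1e-12) { best = X[la * W + lb]; state = 1; }
  if (Y[la * W + lb] > best + 1e-12) { best = Y[la * W + lb]; state = 2; }
  ops.clear();
  while (i > 0 || j > 0) {
    const int id = i * W + j;
    if (state == 0) {
      ops.push_back(0); state = tM[id]; --i; --j;
    } else if (state == 1) {
      ops.push_back(1);
      state = (tX[id] == 1) ? 1 : (tX[id] == 0 ? 0 : 2);
      --i;
    } else {
      ops.push_back(2);
      state = (tY[id] == 1) ? 2 : (tY[id] == 0 ? 0 : 1);
      --j;
    }
    if (i == 0 && j > 0 && state != 2) state = 2;
    if (j == 0 && i > 0 && state != 1) state = 1;
  }
  std::reverse(ops.begin(), ops.end());
  return best;
}

static void apply_ops(std::vector<std::vector<int>>& rows, const std::vector<int>& ops,
                      int keepOp) {
  // keepOp: op code under which this side advances (plus 0); other op inserts gap
  for (size_t m = 0; m < rows.size(); ++m) {
    std::vector<int> nr;
    nr.reserve(ops.size());
    size_t p = 0;
    for (size_t o = 0; o < ops.size(); ++o) {
      if (ops[o] == 0 || ops[o] == keepOp) nr.push_back(rows[m][p++]);
      else nr.push_back(-1);
    }
    rows[m] = nr;
  }
}

// [[Rcpp::export]]
List cpp_pairwise_align(std::string a, std::string b, NumericMatrix sub,
                        double go, double ge) {
  if (a.empty() || b.empty()) stop("empty sequence");
  std::vector<int> ea = encode_pep(a), eb = encode_pep(b);
  std::vector<std::vector<int>> ra(1), rb(1);
  ra[0].resize(ea.size()); rb[0].resize(eb.size());
  for (size_t i = 0; i < ea.size(); ++i) ra[0][i] = (int)i;
  for (size_t i = 0; i < eb.size(); ++i) rb[0][i] = (int)i;
  std::vector<const std::string*> sa(1, &a), sb(1, &b);
  std::vector<ProfCol> pa, pb;
  make_profile(ra, sa, pa);
  make_profile(rb, sb, pb);
  std::vector<int> ops;
  double score = profile_dp(pa, pb, sub, go, ge, ops);
  apply_ops(ra, ops, 1);
  apply_ops(rb, ops, 2);
  std::string ga, gb;
  for (size_t c = 0; c < ra[0].size(); ++c) ga += (ra[0][c] < 0) ? '-' : a[ra[0][c]];
  for (size_t c = 0; c < rb[0].size(); ++c) gb += (rb[0][c] < 0) ? '-' : b[rb[0][c]];
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = score);
}

// Progressive alignment guided by an hclust merge matrix. Returns gapped
// sequences in input order.
// [[Rcpp::export]]
CharacterVector cpp_progressive_align(CharacterVector seqs, IntegerMatrix merge,
                                      NumericMatrix sub, double go, double ge) {
  const int n = seqs.size();
  std::vector<std::string> raw(n);
  for (int i = 0; i < n; ++i) raw[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) encode_pep(raw[i]); // validate

  struct Node { std::vector<int> ids; std::vector<std::vector<int>> rows; };
  const int nm = merge.nrow();
  std::vector<Node> nodes(nm);

  auto leaf = [&](int li) {
    Node nd;
    nd.ids.push_back(li);
    std::vector<int> r(raw[li].size());
    for (size_t p = 0; p < raw[li].size(); ++p) r[p] = (int)p;
    nd.rows.push_back(r);
    return nd;
  };

  for (int t = 0; t < nm; ++t) {
    int c1 = merge(t, 0), c2 = merge(t, 1);
    Node A = (c1 < 0) ? leaf(-c1 - 1) : std::move(nodes[c1 - 1]);
    Node B = (c2 < 0) ? leaf(-c2 - 1) : std::move(nodes[c2 - 1]);
    std::vector<const std::string*> sa, sb;
    for (size_t m = 0; m < A.ids.size(); ++m) sa.push_back(&raw[A.ids[m]]);
    for (size_t m = 0; m < B.ids.size(); ++m) sb.push_back(&raw[B.ids[m]]);
    std::vector<ProfCol> pa, pb;
    make_profile(A.rows, sa, pa);
    make_profile(B.rows, sb, pb);
    std::vector<int> ops;
    profile_dp(pa, pb, sub, go, ge, ops);
    apply_ops(A.rows, ops, 1);
    apply_ops(B.rows, ops, 2);
    Node out;
    out.ids = A.ids;
    out.ids.insert(out.ids.end(), B.ids.begin(), B.ids.end());
    out.rows = A.rows;
    out.rows.insert(out.rows.end(), B.rows.begin(), B.rows.end());
    nodes[t] = std::move(out);
    Rcpp::checkUserInterrupt();
  }

  const Node& fin = nodes[nm - 1];
  CharacterVector out(n);
  for (size_t m = 0; m < fin.ids.size(); ++m) {
    const std::string& src = raw[fin.ids[m]];
    std::string g;
    g.reserve(fin.rows[m].size());
    for (size_t c = 0; c < fin.rows[m].size(); ++c)
      g += (fin.rows[m][c] < 0) ? '-' : src[fin.rows[m][c]];
    out[fin.ids[m]] = g;
  }
  return out;
}

// Pairs of aligned rows with gapped identity >= threshold (identical residues
// in shared non-gap columns / shorter ungapped length). Returns 1-based edges.
// [[Rcpp::export]]
List cpp_aln_edges(CharacterVector aligned, double threshold) {
  const int n = aligned.size();
  int W = n ? (int)std::string(aligned[0]).size() : 0;
  std::vector<std::vector<int>> enc(n);
  std::vector<int> ulen(n, 0);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(aligned[i]);
    if ((int)s.size() != W) stop("aligned rows differ in length");
    enc[i].resize(W);
    for (int c = 0; c < W; ++c) {
      enc[i][c] = (s[c] == '-') ? -1 : aa_index(s[c]);
      if (s[c] != '-') ulen[i]++;
    }
  }
  std::vector<int> ei, ej;
  std::vector<double> ev;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int m = 0;
      for (int c = 0; c < W; ++c)
        if (enc[i][c] >= 0 && enc[i][c] == enc[j][c]) ++m;
      double id = (double)m / (double)std::min(ulen[i], ulen[j]);
      if (id >= threshold - 1e-9) { ei.push_back(i + 1); ej.push_back(j + 1); ev.push_back(id); }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["i"] = wrap(ei), _["j"] = wrap(ej), _["identity"] = wrap(ev));
}
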