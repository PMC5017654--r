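// Collapsed Gibbs samplers for the DP-MRF (single image) and HDP-MRF
// (Chinese restaurant franchise, multiple images) segmentation models.
//
// Observation model: univariate Gaussian with conjugate normal-inverse-gamma
// base measure, marginalized analytically (collapsed sampler); atoms carry
// only sufficient statistics (n, sum x, sum x^2).
//
// All randomness goes through R's RNG (unif_rand) so that set.seed() on the
// R side makes every run bit-reproducible. Pixel scan order is the fixed
// linear (column-major) order of the R matrix.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Hyp {
  double mu0, k0, a0, b0, alpha0, gam, lam;
};

static Hyp as_hyp(const NumericVector& h) {
  // order: mu0, kappa0, a0, b0, alpha0, gamma, lambda
  Hyp p;
  p.mu0 = h[0]; p.k0 = h[1]; p.a0 = h[2]; p.b0 = h[3];
  p.alpha0 = h[4]; p.gam = h[5]; p.lam = h[6];
  return p;
}

// log marginal likelihood of a set of observations with sufficient
// statistics (n, s, q) under the NIG base measure (closed form).
static inline double log_marg(const Hyp& h, double n, double s, double q) {
  if (n <= 0) return 0.0;
  double kn = h.k0 + n, an = h.a0 + 0.5 * n, xb = s / n;
  double ss = q - s * s / n;
  if (ss < 0) ss = 0;  // guard against cancellation
  double d = xb - h.mu0;
  double bn = h.b0 + 0.5 * ss + h.k0 * n * d * d / (2.0 * kn);
  return std::lgamma(an) - std::lgamma(h.a0) + h.a0 * std::log(h.b0) -
         an * std::log(bn) + 0.5 * (std::log(h.k0) - std::log(kn)) -
         0.5 * n * std::log(2.0 * M_PI);
}

// log posterior-predictive density of x given stats (n, s, q):
// a scaled shifted Student-t (prior predictive when n = 0).
static inline double log_pred(const Hyp& h, double x, double n, double s,
                              double q) {
  double kn = h.k0 + n, an = h.a0 + 0.5 * n;
  double mun = (h.k0 * h.mu0 + s) / kn;
  double bn = h.b0;
  if (n > 0) {
    double xb = s / n, ss = q - s * s / n;
    if (ss < 0) ss = 0;
    double d = xb - h.mu0;
    bn += 0.5 * ss + h.k0 * n * d * d / (2.0 * kn);
  }
  double nu = 2.0 * an;
  double s2 = bn * (kn + 1.0) / (an * kn);
  double z = x - mun;
  return std::lgamma(0.5 * (nu + 1.0)) - std::lgamma(0.5 * nu) -
         0.5 * std::log(nu * M_PI * s2) -
         0.5 * (nu + 1.0) * std::log1p(z * z / (nu * s2));
}

// inverse-CDF categorical draw from unnormalized log weights
static int sample_logw(const std::vector<double>& lw) {
  int K = (int)lw.size();
  double m = lw[0];
  for (int k = 1; k < K; ++k)
    if (lw[k] > m) m = lw[k];
  double tot = 0.0;
  std::vector<double> w(K);
  for (int k = 0; k < K; ++k) {
    w[k] = std::exp(lw[k] - m);
    tot += w[k];
  }
  double u = unif_rand() * tot, c = 0.0;
  for (int k = 0; k < K; ++k) {
    c += w[k];
    if (u <= c) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
double cppLogPred(NumericVector hp, double x, double n, double s, double q) {
  Hyp h = as_hyp(hp);
  return log_pred(h, x, n, s, q);
}

// [[Rcpp::export]]
double cppLogMarg(NumericVector hp, double n, double s, double q) {
  Hyp h = as_hyp(hp);
  return log_marg(h, n, s, q);
}

// ---------------------------------------------------------------------------
// Single-image DP-MRF sampler
// ---------------------------------------------------------------------------

struct SingleState {
  std::vector<int> lab;                  // pixel -> cluster (atom) index
  std::vector<int> pos;                  // pixel's index in its cluster's members
  std::vector<std::vector<int>> mem;     // cluster -> member pixels
  std::vector<double> cn, cs, cq;        // cluster sufficient statistics
};

static void single_remove(SingleState& st, int j, double x) {
  int c = st.lab[j];
  st.cn[c] -= 1.0;
  st.cs[c] -= x;
  st.cq[c] -= x * x;
  // swap-remove pixel j from member list
  std::vector<int>& m = st.mem[c];
  int p = st.pos[j], last = m.back();
  m[p] = last;
  st.pos[last] = p;
  m.pop_back();
  if (m.empty()) {
    // delete cluster c: move last cluster into slot c
    int L = (int)st.mem.size() - 1;
    if (c != L) {
      st.mem[c] = std::move(st.mem[L]);
      st.cn[c] = st.cn[L];
      st.cs[c] = st.cs[L];
      st.cq[c] = st.cq[L];
      for (int px : st.mem[c]) st.lab[px] = c;
    }
    st.mem.pop_back();
    st.cn.pop_back();
    st.cs.pop_back();
    st.cq.pop_back();
  }
  st.lab[j] = -1;
}

static void single_add(SingleState& st, int j, double x, int c) {
  if (c == (int)st.mem.size()) {  // new cluster
    st.mem.push_back(std::vector<int>());
    st.cn.push_back(0.0);
    st.cs.push_back(0.0);
    st.cq.push_back(0.0);
  }
  st.lab[j] = c;
  st.pos[j] = (int)st.mem[c].size();
  st.mem[c].push_back(j);
  st.cn[c] += 1.0;
  st.cs[c] += x;
  st.cq[c] += x * x;
}

// unnormalized log weights over {existing clusters} + {new}, pixel j removed
static void single_weights(const SingleState& st, const Hyp& h, double x,
                           int j, const int* nptr, const int* nidx,
                           const double* nw, std::vector<double>& lw) {
  int K = (int)st.mem.size();
  std::vector<double> agr(K, 0.0);
  for (int e = nptr[j]; e < nptr[j + 1]; ++e) {
    int l = nidx[e];
    if (st.lab[l] >= 0) agr[st.lab[l]] += nw[e];
  }
  lw.assign(K + 1, 0.0);
  for (int k = 0; k < K; ++k)
    lw[k] = std::log(st.cn[k]) + h.lam * agr[k] +
            log_pred(h, x, st.cn[k], st.cs[k], st.cq[k]);
  lw[K] = std::log(h.alpha0) + log_pred(h, x, 0.0, 0.0, 0.0);
}

static double single_logjoint(const SingleState& st, const Hyp& h,
                              const NumericVector& x, const int* nptr,
                              const int* nidx, const double* nw) {
  int N = (int)st.lab.size(), K = (int)st.mem.size();
  double lj = 0.0;
  for (int i = 0; i < N; ++i) lj -= std::log(h.alpha0 + i);
  for (int k = 0; k < K; ++k)
    lj += std::log(h.alpha0) + std::lgamma(st.cn[k]) +
          log_marg(h, st.cn[k], st.cs[k], st.cq[k]);
  double pot = 0.0;
  for (int j = 0; j < N; ++j)
    for (int e = nptr[j]; e < nptr[j + 1]; ++e)
      if (nidx[e] > j && st.lab[nidx[e]] == st.lab[j]) pot += nw[e];
  return lj + h.lam * pot;
}

static SingleState single_init(const IntegerVector& init, const NumericVector& x) {
  int N = x.size();
  SingleState st;
  st.lab.assign(N, -1);
  st.pos.assign(N, 0);
  int K = 0;
  for (int j = 0; j < N; ++j)
    if (init[j] + 1 > K) K = init[j] + 1;
  st.mem.resize(K);
  st.cn.assign(K, 0.0);
  st.cs.assign(K, 0.0);
  st.cq.assign(K, 0.0);
  for (int j = 0; j < N; ++j) {
    int c = init[j];
    st.lab[j] = c;
    st.pos[j] = (int)st.mem[c].size();
    st.mem[c].push_back(j);
    st.cn[c] += 1.0;
    st.cs[c] += x[j];
    st.cq[c] += x[j] * x[j];
  }
  // drop empty initial clusters (compact, preserving order)
  std::vector<int> map(K, -1);
  int kk = 0;
  for (int k = 0; k < K; ++k)
    if (!st.mem[k].empty()) {
      map[k] = kk;
      if (kk != k) {
        st.mem[kk] = std::move(st.mem[k]);
        st.cn[kk] = st.cn[k];
        st.cs[kk] = st.cs[k];
        st.cq[kk] = st.cq[k];
      }
      ++kk;
    }
  st.mem.resize(kk);
  st.cn.resize(kk);
  st.cs.resize(kk);
  st.cq.resize(kk);
  for (int j = 0; j < N; ++j) st.lab[j] = map[st.lab[j]];
  for (int k = 0; k < kk; ++k)
    for (int i = 0; i < (int)st.mem[k].size(); ++i) st.pos[st.mem[k][i]] = i;
  return st;
}

// [[Rcpp::export]]
List cppSingleRun(NumericVector x, IntegerVector nptr, IntegerVector nidx,
                  NumericVector nw, NumericVector hp, IntegerVector init,
                  int nSweeps, int burnIn, int thin, bool record) {
  Hyp h = as_hyp(hp);
  int N = x.size();
  SingleState st = single_init(init, x);
  const int* pp = INTEGER(nptr);
  const int* pi = INTEGER(nidx);
  const double* pw = REAL(nw);

  int nret = 0;
  if (record)
    for (int s = burnIn + 1; s <= nSweeps; ++s)
      if ((s - burnIn - 1) % thin == 0) ++nret;
  IntegerMatrix samples(record ? nret : 0, record ? N : 0);
  NumericVector trace(nSweeps);
  int r = 0;
  std::vector<double> lw;
  for (int s = 1; s <= nSweeps; ++s) {
    for (int j = 0; j < N; ++j) {
      single_remove(st, j, x[j]);
      single_weights(st, h, x[j], j, pp, pi, pw, lw);
      int c = sample_logw(lw);
      single_add(st, j, x[j], c);
    }
    trace[s - 1] = single_logjoint(st, h, x, pp, pi, pw);
    if (record && s > burnIn && (s - burnIn - 1) % thin == 0) {
      for (int j = 0; j < N; ++j) samples(r, j) = st.lab[j] + 1;
      ++r;
    }
  }
  IntegerVector lab(N);
  for (int j = 0; j < N; ++j) lab[j] = st.lab[j] + 1;
  int K = (int)st.mem.size();
  NumericMatrix stats(K, 3);
  for (int k = 0; k < K; ++k) {
    stats(k, 0) = st.cn[k];
    stats(k, 1) = st.cs[k];
    stats(k, 2) = st.cq[k];
  }
  return List::create(_["labels"] = lab, _["samples"] = samples,
                      _["trace"] = trace, _["atomStats"] = stats);
}

// Normalized full conditional for one pixel (single-image model); the pixel's
// own contribution is removed before weighting. Returns the surviving cluster
// labels (1-based, in the post-removal indexing of `labels`) and probabilities
// with the new-cluster option last.
// [[Rcpp::export]]
List cppSingleConditional(NumericVector x, IntegerVector nptr,
                          IntegerVector nidx, NumericVector nw,
                          NumericVector hp, IntegerVector labels, int pixel) {
  Hyp h = as_hyp(hp);
  int N = x.size();
  IntegerVector init(N);
  for (int j = 0; j < N; ++j) init[j] = labels[j] - 1;
  SingleState st = single_init(init, x);
  int j = pixel - 1;
  // remember which original label each current cluster slot carries
  std::vector<int> orig((int)st.mem.size());
  for (int k = 0; k < (int)orig.size(); ++k) orig[k] = labels[st.mem[k][0]];
  single_remove(st, j, x[j]);
  // rebuild slot -> original-label map after possible deletion/swap
  std::vector<int> lab_of((int)st.mem.size());
  for (int k = 0; k < (int)st.mem.size(); ++k) lab_of[k] = labels[st.mem[k][0]];
  std::vector<double> lw;
  single_weights(st, h, x[j], j, INTEGER(nptr), INTEGER(nidx), REAL(nw), lw);
  double m = lw[0];
  for (double v : lw)
    if (v > m) m = v;
  double tot = 0.0;
  NumericVector p(lw.size());
  for (int k = 0; k < (int)lw.size(); ++k) {
    p[k] = std::exp(lw[k] - m);
    tot += p[k];
  }
  for (int k = 0; k < (int)lw.size(); ++k) p[k] /= tot;
  IntegerVector cl(lab_of.size());
  for (int k = 0; k < (int)lab_of.size(); ++k) cl[k] = lab_of[k];
  return List::create(_["clusterLabels"] = cl, _["prob"] = p);
}

// ---------------------------------------------------------------------------
// Joint HDP-MRF sampler (Chinese restaurant franchise)
// ---------------------------------------------------------------------------

struct JointState {
  int nI;
  // per image
  std::vector<std::vector<int>> pixT, pixPos;       // pixel -> table, member pos
  std::vector<std::vector<std::vector<int>>> tMem;  // table member pixels
  std::vector<std::vector<int>> tAtom;              // table -> atom
  std::vector<std::vector<double>> tn, ts, tq;      // table stats
  // atoms (global)
  std::vector<int> aM;             // number of tables serving atom k
  std::vector<double> an, as, aq;  // atom stats (pooled over images)
  int mTot;                        // total table count
};

struct ImgView {
  int N;
  const double* x;
  const int* ptr;
  const int* idx;
  const double* w;
};

static void atom_delete(JointState& st, int k) {
  int L = (int)st.aM.size() - 1;
  if (k != L) {
    st.aM[k] = st.aM[L];
    st.an[k] = st.an[L];
    st.as[k] = st.as[L];
    st.aq[k] = st.aq[L];
    for (int i = 0; i < st.nI; ++i)
      for (int& a : st.tAtom[i])
        if (a == L) a = k;
  }
  st.aM.pop_back();
  st.an.pop_back();
  st.as.pop_back();
  st.aq.pop_back();
}

static void table_delete(JointState& st, int i, int t) {
  int L = (int)st.tMem[i].size() - 1;
  if (t != L) {
    st.tMem[i][t] = std::move(st.tMem[i][L]);
    st.tAtom[i][t] = st.tAtom[i][L];
    st.tn[i][t] = st.tn[i][L];
    st.ts[i][t] = st.ts[i][L];
    st.tq[i][t] = st.tq[i][L];
    for (int px : st.tMem[i][t]) st.pixT[i][px] = t;
  }
  st.tMem[i].pop_back();
  st.tAtom[i].pop_back();
  st.tn[i].pop_back();
  st.ts[i].pop_back();
  st.tq[i].pop_back();
  st.mTot -= 1;
}

// remove pixel j of image i from the state (may delete its table and atom)
static void joint_remove(JointState& st, int i, int j, double x) {
  int t = st.pixT[i][j];
  int k = st.tAtom[i][t];
  st.tn[i][t] -= 1.0;
  st.ts[i][t] -= x;
  st.tq[i][t] -= x * x;
  st.an[k] -= 1.0;
  st.as[k] -= x;
  st.aq[k] -= x * x;
  std::vector<int>& m = st.tMem[i][t];
  int p = st.pixPos[i][j], last = m.back();
  m[p] = last;
  st.pixPos[i][last] = p;
  m.pop_back();
  if (m.empty()) {
    table_delete(st, i, t);
    st.aM[k] -= 1;
    if (st.aM[k] == 0) atom_delete(st, k);
  }
  st.pixT[i][j] = -1;
}

// choice layout for the pixel conditional:
//   0 .. T-1          join existing table
//   T .. T+K-1        open a new table serving existing atom k
//   T+K               open a new table with a brand-new atom
static void joint_weights(const JointState& st, const Hyp& h, int i, int j,
                          double x, const ImgView& im, std::vector<double>& lw) {
  int T = (int)st.tMem[i].size();
  int K = (int)st.aM.size();
  std::vector<double> agr(K, 0.0);
  for (int e = im.ptr[j]; e < im.ptr[j + 1]; ++e) {
    int l = im.idx[e];
    int tl = st.pixT[i][l];
    if (tl >= 0) agr[st.tAtom[i][tl]] += im.w[e];
  }
  std::vector<double> pk(K);
  for (int k = 0; k < K; ++k)
    pk[k] = log_pred(h, x, st.an[k], st.as[k], st.aq[k]) + h.lam * agr[k];
  lw.assign(T + K + 1, 0.0);
  for (int t = 0; t < T; ++t)
    lw[t] = std::log(st.tn[i][t]) + pk[st.tAtom[i][t]];
  double la = std::log(h.alpha0), lden = std::log(st.mTot + h.gam);
  for (int k = 0; k < K; ++k)
    lw[T + k] = la + std::log((double)st.aM[k]) - lden + pk[k];
  lw[T + K] = la + std::log(h.gam) - lden + log_pred(h, x, 0.0, 0.0, 0.0);
}

static void joint_add_pixel(JointState& st, int i, int j, double x, int t) {
  st.pixT[i][j] = t;
  st.pixPos[i][j] = (int)st.tMem[i][t].size();
  st.tMem[i][t].push_back(j);
  st.tn[i][t] += 1.0;
  st.ts[i][t] += x;
  st.tq[i][t] += x * x;
  int k = st.tAtom[i][t];
  st.an[k] += 1.0;
  st.as[k] += x;
  st.aq[k] += x * x;
}

static int joint_new_table(JointState& st, int i, int k) {
  st.tMem[i].push_back(std::vector<int>());
  st.tAtom[i].push_back(k);
  st.tn[i].push_back(0.0);
  st.ts[i].push_back(0.0);
  st.tq[i].push_back(0.0);
  st.mTot += 1;
  st.aM[k] += 1;
  return (int)st.tMem[i].size() - 1;
}

static int joint_new_atom(JointState& st) {
  st.aM.push_back(0);
  st.an.push_back(0.0);
  st.as.push_back(0.0);
  st.aq.push_back(0.0);
  return (int)st.aM.size() - 1;
}

// resample the global atom of table t in image i (table-stage move)
static void joint_table_move(JointState& st, const Hyp& h, int i, int t,
                             const ImgView& im) {
  int k = st.tAtom[i][t];
  double n = st.tn[i][t], s = st.ts[i][t], q = st.tq[i][t];
  st.aM[k] -= 1;
  st.an[k] -= n;
  st.as[k] -= s;
  st.aq[k] -= q;
  int K = (int)st.aM.size();
  // Potts boundary agreement of the table's members with atoms outside it
  std::vector<double> agr(K, 0.0);
  if (h.lam > 0) {
    for (int px : st.tMem[i][t])
      for (int e = im.ptr[px]; e < im.ptr[px + 1]; ++e) {
        int l = im.idx[e];
        int tl = st.pixT[i][l];
        if (tl != t) agr[st.tAtom[i][tl]] += im.w[e];
      }
  }
  std::vector<double> lw;
  std::vector<int> choice;  // atom index, -1 = new
  for (int kk = 0; kk < K; ++kk)
    if (st.aM[kk] > 0) {
      double d = log_marg(h, st.an[kk] + n, st.as[kk] + s, st.aq[kk] + q) -
                 log_marg(h, st.an[kk], st.as[kk], st.aq[kk]);
      lw.push_back(std::log((double)st.aM[kk]) + d + h.lam * agr[kk]);
      choice.push_back(kk);
    }
  lw.push_back(std::log(h.gam) + log_marg(h, n, s, q));
  choice.push_back(-1);
  int c = choice[sample_logw(lw)];
  if (c == -1) {
    if (st.aM[k] == 0) {
      c = k;  // reuse the emptied slot as the fresh atom
    } else {
      c = joint_new_atom(st);
    }
  }
  st.tAtom[i][t] = c;
  st.aM[c] += 1;
  st.an[c] += n;
  st.as[c] += s;
  st.aq[c] += q;
  if (c != k && st.aM[k] == 0) atom_delete(st, k);
  // note: atom_delete may have renumbered atom c == last; tAtom already fixed
}

static double joint_logjoint(const JointState& st, const Hyp& h,
                             const std::vector<ImgView>& ims) {
  double lj = 0.0;
  for (int i = 0; i < st.nI; ++i) {
    int Ni = ims[i].N;
    for (int r = 0; r < Ni; ++r) lj -= std::log(h.alpha0 + r);
    for (int t = 0; t < (int)st.tn[i].size(); ++t)
      lj += std::log(h.alpha0) + std::lgamma(st.tn[i][t]);
  }
  for (int r = 0; r < st.mTot; ++r) lj -= std::log(h.gam + r);
  for (int k = 0; k < (int)st.aM.size(); ++k)
    lj += std::log(h.gam) + std::lgamma((double)st.aM[k]) +
          log_marg(h, st.an[k], st.as[k], st.aq[k]);
  double pot = 0.0;
  for (int i = 0; i < st.nI; ++i)
    for (int j = 0; j < ims[i].N; ++j)
      for (int e = ims[i].ptr[j]; e < ims[i].ptr[j + 1]; ++e) {
        int l = ims[i].idx[e];
        if (l > j &&
            st.tAtom[i][st.pixT[i][j]] == st.tAtom[i][st.pixT[i][l]])
          pot += ims[i].w[e];
      }
  return lj + h.lam * pot;
}

static JointState joint_init(const List& xs, const List& initT,
                             const List& initTA) {
  JointState st;
  st.nI = xs.size();
  st.mTot = 0;
  st.pixT.resize(st.nI);
  st.pixPos.resize(st.nI);
  st.tMem.resize(st.nI);
  st.tAtom.resize(st.nI);
  st.tn.resize(st.nI);
  st.ts.resize(st.nI);
  st.tq.resize(st.nI);
  int K = 0;
  for (int i = 0; i < st.nI; ++i) {
    IntegerVector ta = initTA[i];
    for (int t = 0; t < ta.size(); ++t)
      if (ta[t] > K) K = ta[t];
  }
  st.aM.assign(K, 0);
  st.an.assign(K, 0.0);
  st.as.assign(K, 0.0);
  st.aq.assign(K, 0.0);
  for (int i = 0; i < st.nI; ++i) {
    NumericVector x = xs[i];
    IntegerVector tv = initT[i];
    IntegerVector ta = initTA[i];
    int Ti = ta.size(), Ni = x.size();
    st.pixT[i].assign(Ni, -1);
    st.pixPos[i].assign(Ni, 0);
    st.tMem[i].resize(Ti);
    st.tAtom[i].resize(Ti);
    st.tn[i].assign(Ti, 0.0);
    st.ts[i].assign(Ti, 0.0);
    st.tq[i].assign(Ti, 0.0);
    for (int t = 0; t < Ti; ++t) st.tAtom[i][t] = ta[t] - 1;
    for (int j = 0; j < Ni; ++j) {
      int t = tv[j] - 1;
      st.pixT[i][j] = t;
      st.pixPos[i][j] = (int)st.tMem[i][t].size();
      st.tMem[i][t].push_back(j);
      st.tn[i][t] += 1.0;
      st.ts[i][t] += x[j];
      st.tq[i][t] += x[j] * x[j];
      int k = st.tAtom[i][t];
      st.an[k] += 1.0;
      st.as[k] += x[j];
      st.aq[k] += x[j] * x[j];
    }
    // drop empty tables
    for (int t = (int)st.tMem[i].size() - 1; t >= 0; --t)
      if (st.tMem[i][t].empty()) {
        st.tAtom[i].erase(st.tAtom[i].begin() + t);
        st.tMem[i].erase(st.tMem[i].begin() + t);
        st.tn[i].erase(st.tn[i].begin() + t);
        st.ts[i].erase(st.ts[i].begin() + t);
        st.tq[i].erase(st.tq[i].begin() + t);
      }
    for (int t = 0; t < (int)st.tMem[i].size(); ++t)
      for (int p = 0; p < (int)st.tMem[i][t].size(); ++p) {
        st.pixT[i][st.tMem[i][t][p]] = t;
        st.pixPos[i][st.tMem[i][t][p]] = p;
      }
    st.mTot += (int)st.tMem[i].size();
    for (int t = 0; t < (int)st.tMem[i].size(); ++t) st.aM[st.tAtom[i][t]] += 1;
  }
  // drop atoms no table serves (compact preserving order)
  for (int k = (int)st.aM.size() - 1; k >= 0; --k)
    if (st.aM[k] == 0) {
      int L = (int)st.aM.size() - 1;
      if (k != L) {
        st.aM[k] = st.aM[L];
        st.an[k] = st.an[L];
        st.as[k] = st.as[L];
        st.aq[k] = st.aq[L];
        for (int i = 0; i < st.nI; ++i)
          for (int& a : st.tAtom[i])
            if (a == L) a = k;
      }
      st.aM.pop_back();
      st.an.pop_back();
      st.as.pop_back();
      st.aq.pop_back();
    }
  return st;
}

static std::vector<ImgView> make_views(const List& xs, const List& nptrs,
                                       const List& nidxs, const List& nws) {
  int nI = xs.size();
  std::vector<ImgView> v(nI);
  for (int i = 0; i < nI; ++i) {
    NumericVector x = xs[i];
    IntegerVector p = nptrs[i], id = nidxs[i];
    NumericVector w = nws[i];
    v[i].N = x.size();
    v[i].x = REAL(x);
    v[i].ptr = INTEGER(p);
    v[i].idx = INTEGER(id);
    v[i].w = REAL(w);
  }
  return v;
}

// [[Rcpp::export]]
List cppJointRun(List xs, List nptrs, List nidxs, List nws, NumericVector hp,
                 List initT, List initTA, int nSweeps, int burnIn, int thin,
                 bool record, bool recordTables) {
  Hyp h = as_hyp(hp);
  JointState st = joint_init(xs, initT, initTA);
  std::vector<ImgView> ims = make_views(xs, nptrs, nidxs, nws);
  int nI = st.nI;
  int Ntot = 0;
  for (int i = 0; i < nI; ++i) Ntot += ims[i].N;

  int nret = 0;
  if (record)
    for (int s = burnIn + 1; s <= nSweeps; ++s)
      if ((s - burnIn - 1) % thin == 0) ++nret;
  IntegerMatrix sAtom(record ? nret : 0, record ? Ntot : 0);
  IntegerMatrix sTab((record && recordTables) ? nret : 0,
                     (record && recordTables) ? Ntot : 0);
  NumericVector trace(nSweeps);
  int r = 0;
  std::vector<double> lw;
  for (int s = 1; s <= nSweeps; ++s) {
    for (int i = 0; i < nI; ++i) {
      for (int j = 0; j < ims[i].N; ++j) {
        double x = ims[i].x[j];
        joint_remove(st, i, j, x);
        joint_weights(st, h, i, j, x, ims[i], lw);
        int T = (int)st.tMem[i].size(), K = (int)st.aM.size();
        int c = sample_logw(lw);
        int t;
        if (c < T) {
          t = c;
        } else if (c < T + K) {
          t = joint_new_table(st, i, c - T);
        } else {
          int k = joint_new_atom(st);
          t = joint_new_table(st, i, k);
        }
        joint_add_pixel(st, i, j, x, t);
      }
      // table-stage: resample each table's atom
      for (int t = 0; t < (int)st.tMem[i].size(); ++t)
        joint_table_move(st, h, i, t, ims[i]);
    }
    trace[s - 1] = joint_logjoint(st, h, ims);
    if (record && s > burnIn && (s - burnIn - 1) % thin == 0) {
      int off = 0;
      for (int i = 0; i < nI; ++i) {
        for (int j = 0; j < ims[i].N; ++j) {
          sAtom(r, off + j) = st.tAtom[i][st.pixT[i][j]] + 1;
          if (recordTables) sTab(r, off + j) = st.pixT[i][j] + 1;
        }
        off += ims[i].N;
      }
      ++r;
    }
  }
  List labAtom(nI), labTab(nI), tabAtom(nI);
  for (int i = 0; i < nI; ++i) {
    IntegerVector la(ims[i].N), lt(ims[i].N);
    for (int j = 0; j < ims[i].N; ++j) {
      lt[j] = st.pixT[i][j] + 1;
      la[j] = st.tAtom[i][st.pixT[i][j]] + 1;
    }
    labAtom[i] = la;
    labTab[i] = lt;
    IntegerVector ta((int)st.tAtom[i].size());
    for (int t = 0; t < ta.size(); ++t) ta[t] = st.tAtom[i][t] + 1;
    tabAtom[i] = ta;
  }
  int K = (int)st.aM.size();
  NumericMatrix stats(K, 3);
  IntegerVector mk(K);
  for (int k = 0; k < K; ++k) {
    stats(k, 0) = st.an[k];
    stats(k, 1) = st.as[k];
    stats(k, 2) = st.aq[k];
    mk[k] = st.aM[k];
  }
  return List::create(
      _["atomLabels"] = labAtom, _["tableLabels"] = labTab,
      _["tableAtom"] = tabAtom, _["samplesAtom"] = sAtom,
      _["samplesTable"] = sTab, _["trace"] = trace, _["atomStats"] = stats,
      _["atomTables"] = mk);
}

// Normalized full conditional for one pixel in the franchise model.
// Choices: existing tables of the image (by 1-based table index after the
// pixel's removal), then existing atoms (new table), then brand-new atom.
// [[Rcpp::export]]
List cppJointConditional(List xs, List nptrs, List nidxs, List nws,
                         NumericVector hp, List initT, List initTA, int image,
                         int pixel) {
  Hyp h = as_hyp(hp);
  JointState st = joint_init(xs, initT, initTA);
  std::vector<ImgView> ims = make_views(xs, nptrs, nidxs, nws);
  int i = image - 1, j = pixel - 1;
  double x = ims[i].x[j];
  joint_remove(st, i, j, x);
  std::vector<double> lw;
  joint_weights(st, h, i, j, x, ims[i], lw);
  int T = (int)st.tMem[i].size(), K = (int)st.aM.size();
  double m = lw[0];
  for (double v : lw)
    if (v > m) m = v;
  double tot = 0.0;
  NumericVector p(lw.size());
  for (int k = 0; k < (int)lw.size(); ++k) {
    p[k] = std::exp(lw[k] - m);
    tot += p[k];
  }
  for (int k = 0; k < (int)lw.size(); ++k) p[k] /= tot;
  // describe surviving tables by a representative member pixel (1-based) and
  // their atom; atoms by their 1-based index in the post-removal atom table
  IntegerVector tabRep(T), tabAtomV(T);
  for (int t = 0; t < T; ++t) {
    tabRep[t] = st.tMem[i][t][0] + 1;
    tabAtomV[t] = st.tAtom[i][t] + 1;
  }
  return List::create(_["prob"] = p, _["nTables"] = T, _["nAtoms"] = K,
                      _["tableRep"] = tabRep, _["tableAtom"] = tabAtomV);
}
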