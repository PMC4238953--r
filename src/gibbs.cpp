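#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs core for the three-level mixed-membership model.
//
// Layout conventions shared with the R side:
//  * labels z (metabosystem) and y (subnetwork) are 1-based on the R side,
//    0-based here;
//  * count matrices are R integer matrices in column-major order:
//    count_nk (N x K), count_kl (K x L), dcount_lc / gcount_lc (L x C);
//  * per-reaction substrate/product slots are concatenated into flat arrays
//    with slot_off (length R+1, 0-based) giving each reaction's range;
//    sub_rep / prod_rep hold, for each slot, the number of earlier slots of
//    the same reaction carrying the same compound (the ascending-factorial
//    offset of the Dirichlet-multinomial predictive);
//  * the conditional table is traversed in column-major order of the K x L
//    matrix (flattened index k + K*l) and one uniform deviate is consumed
//    per token per sweep (inverse CDF over the flattened table).

struct ModelDims {
  int N, K, L, C;
  double at, ap, ad, ag;
  int log_threshold;
};

// Unnormalized conditional table for a token of reaction r in sample n,
// given count tables with the token's contribution removed. Fills tab
// (size K*L, index k + K*l) and returns the table total.
// mode: 0 = auto (log space iff J > log_threshold), 1 = direct, 2 = log.
static double token_table(int n, int r, const int* soff, const int* sflat,
                          const int* srep, const int* pflat, const int* prep,
                          const int* cnk, const int* ckl, const int* ck,
                          const int* dlc, const int* dl, const int* glc,
                          const int* gl, const ModelDims& M,
                          std::vector<double>& W, std::vector<double>& tab,
                          int mode) {
  const int J = soff[r + 1] - soff[r];
  const int base = soff[r];
  const bool use_log = mode == 2 || (mode == 0 && J > M.log_threshold);

  for (int l = 0; l < M.L; ++l) {
    const double dden = dl[l] + M.C * M.ad;
    const double gden = gl[l] + M.C * M.ag;
    if (!use_log) {
      double w = 1.0;
      for (int j = 0; j < J; ++j) {
        const int c = sflat[base + j];
        w *= (dlc[l + M.L * c] + M.ad + srep[base + j]) / (dden + j);
      }
      for (int j = 0; j < J; ++j) {
        const int c = pflat[base + j];
        w *= (glc[l + M.L * c] + M.ag + prep[base + j]) / (gden + j);
      }
      W[l] = w;
    } else {
      double w = 0.0;
      for (int j = 0; j < J; ++j) {
        const int c = sflat[base + j];
        w += std::log(dlc[l + M.L * c] + M.ad + srep[base + j]) -
             std::log(dden + j);
      }
      for (int j = 0; j < J; ++j) {
        const int c = pflat[base + j];
        w += std::log(glc[l + M.L * c] + M.ag + prep[base + j]) -
             std::log(gden + j);
      }
      W[l] = w;
    }
  }

  double tot = 0.0;
  if (!use_log) {
    for (int l = 0; l < M.L; ++l) {
      for (int k = 0; k < M.K; ++k) {
        const double v = (cnk[n + M.N * k] + M.at) *
                         ((ckl[k + M.K * l] + M.ap) / (ck[k] + M.L * M.ap)) *
                         W[l];
        tab[k + M.K * l] = v;
        tot += v;
      }
    }
  } else {
    double mx = R_NegInf;
    for (int l = 0; l < M.L; ++l) {
      for (int k = 0; k < M.K; ++k) {
        const double lv = std::log(cnk[n + M.N * k] + M.at) +
                          std::log(ckl[k + M.K * l] + M.ap) -
                          std::log(ck[k] + M.L * M.ap) + W[l];
        tab[k + M.K * l] = lv;
        if (lv > mx) mx = lv;
      }
    }
    for (int i = 0; i < M.K * M.L; ++i) {
      tab[i] = std::exp(tab[i] - mx);
      tot += tab[i];
    }
  }
  return tot;
}

static void guard_nonneg(int v, const char* what) {
  if (v < 0) stop("internal consistency error: negative %s count", what);
}

// [[Rcpp::export]]
List cpp_sweeps(IntegerVector z, IntegerVector y, IntegerVector token_sample,
                IntegerVector token_reaction, IntegerVector slot_off,
                IntegerVector sub_flat, IntegerVector sub_rep,
                IntegerVector prod_flat, IntegerVector prod_rep,
                IntegerMatrix count_nk, IntegerMatrix count_kl,
                IntegerVector count_k, IntegerMatrix dcount_lc,
                IntegerVector dcount_l, IntegerMatrix gcount_lc,
                IntegerVector gcount_l, int C, double at, double ap,
                double ad, double ag, int n_sweeps, IntegerVector order,
                int log_threshold) {
  IntegerVector z2 = clone(z), y2 = clone(y);
  IntegerMatrix cnkM = clone(count_nk), cklM = clone(count_kl);
  IntegerMatrix dlcM = clone(dcount_lc), glcM = clone(gcount_lc);
  IntegerVector ckV = clone(count_k), dlV = clone(dcount_l),
                glV = clone(gcount_l);

  ModelDims M;
  M.N = cnkM.nrow(); M.K = cnkM.ncol(); M.L = cklM.ncol(); M.C = C;
  M.at = at; M.ap = ap; M.ad = ad; M.ag = ag;
  M.log_threshold = log_threshold;

  int* cnk = cnkM.begin(); int* ckl = cklM.begin(); int* ck = ckV.begin();
  int* dlc = dlcM.begin(); int* dl = dlV.begin();
  int* glc = glcM.begin(); int* gl = glV.begin();
  const int* soff = slot_off.begin();
  const int* sflat = sub_flat.begin(); const int* srep = sub_rep.begin();
  const int* pflat = prod_flat.begin(); const int* prep = prod_rep.begin();

  const int T = z2.size();
  std::vector<double> W(M.L), tab(M.K * M.L);

  for (int s = 0; s < n_sweeps; ++s) {
    for (int ti = 0; ti < T; ++ti) {
      const int t = order[ti] - 1;
      const int n = token_sample[t] - 1;
      const int r = token_reaction[t] - 1;
      const int zt = z2[t] - 1, yt = y2[t] - 1;
      const int J = soff[r + 1] - soff[r];

      // remove the token's whole contribution (exclude-self)
      guard_nonneg(--cnk[n + M.N * zt], "sample-metabosystem");
      guard_nonneg(--ckl[zt + M.K * yt], "metabosystem-subnetwork");
      --ck[zt];
      for (int j = soff[r]; j < soff[r + 1]; ++j) {
        guard_nonneg(--dlc[yt + M.L * sub_flat[j]], "substrate");
        guard_nonneg(--glc[yt + M.L * prod_flat[j]], "product");
      }
      dl[yt] -= J; gl[yt] -= J;

      const double tot = token_table(n, r, soff, sflat, srep, pflat, prep,
                                     cnk, ckl, ck, dlc, dl, glc, gl, M, W,
                                     tab, 0);
      const double u = unif_rand() * tot;
      int pick = M.K * M.L - 1;
      double cum = 0.0;
      for (int idx = 0; idx < M.K * M.L; ++idx) {
        cum += tab[idx];
        if (u <= cum) { pick = idx; break; }
      }
      const int k = pick % M.K, l = pick / M.K;

      ++cnk[n + M.N * k]; ++ckl[k + M.K * l]; ++ck[k];
      for (int j = soff[r]; j < soff[r + 1]; ++j) {
        ++dlc[l + M.L * sub_flat[j]];
        ++glc[l + M.L * prod_flat[j]];
      }
      dl[l] += J; gl[l] += J;
      z2[t] = k + 1; y2[t] = l + 1;
    }
  }

  return List::create(_["z"] = z2, _["y"] = y2, _["count_nk"] = cnkM,
                      _["count_kl"] = cklM, _["count_k"] = ckV,
                      _["dcount_lc"] = dlcM, _["dcount_l"] = dlV,
                      _["gcount_lc"] = glcM, _["gcount_l"] = glV);
}

// Normalized K x L conditional table for one token, computed from a full
// (consistent) state; the token's contribution is removed internally.
// mode: 0 auto, 1 direct, 2 log-space.
// [[Rcpp::export]]
NumericMatrix cpp_conditional_table(int token, IntegerVector z,
                                    IntegerVector y,
                                    IntegerVector token_sample,
                                    IntegerVector token_reaction,
                                    IntegerVector slot_off,
                                    IntegerVector sub_flat,
                                    IntegerVector sub_rep,
                                    IntegerVector prod_flat,
                                    IntegerVector prod_rep,
                                    IntegerMatrix count_nk,
                                    IntegerMatrix count_kl,
                                    IntegerVector count_k,
                                    IntegerMatrix dcount_lc,
                                    IntegerVector dcount_l,
                                    IntegerMatrix gcount_lc,
                                    IntegerVector gcount_l, int C, double at,
                                    double ap, double ad, double ag,
                                    int mode) {
  IntegerMatrix cnkM = clone(count_nk), cklM = clone(count_kl);
  IntegerMatrix dlcM = clone(dcount_lc), glcM = clone(gcount_lc);
  IntegerVector ckV = clone(count_k), dlV = clone(dcount_l),
                glV = clone(gcount_l);

  ModelDims M;
  M.N = cnkM.nrow(); M.K = cnkM.ncol(); M.L = cklM.ncol(); M.C = C;
  M.at = at; M.ap = ap; M.ad = ad; M.ag = ag;
  M.log_threshold = 32;

  int* cnk = cnkM.begin(); int* ckl = cklM.begin(); int* ck = ckV.begin();
  int* dlc = dlcM.begin(); int* dl = dlV.begin();
  int* glc = glcM.begin(); int* gl = glV.begin();
  const int* soff = slot_off.begin();

  const int t = token - 1;
  const int n = token_sample[t] - 1;
  const int r = token_reaction[t] - 1;
  const int zt = z[t] - 1, yt = y[t] - 1;
  const int J = soff[r + 1] - soff[r];

  guard_nonneg(--cnk[n + M.N * zt], "sample-metabosystem");
  guard_nonneg(--ckl[zt + M.K * yt], "metabosystem-subnetwork");
  --ck[zt];
  for (int j = soff[r]; j < soff[r + 1]; ++j) {
    guard_nonneg(--dlc[yt + M.L * sub_flat[j]], "substrate");
    guard_nonneg(--glc[yt + M.L * prod_flat[j]], "product");
  }
  dl[yt] -= J; gl[yt] -= J;

  std::vector<double> W(M.L), tab(M.K * M.L);
  const double tot = token_table(n, r, soff, sub_flat.begin(),
                                 sub_rep.begin(), prod_flat.begin(),
                                 prod_rep.begin(), cnk, ckl, ck, dlc, dl, glc,
                                 gl, M, W, tab, mode);

  NumericMatrix out(M.K, M.L);
  for (int i = 0; i < M.K * M.L; ++i) out[i] = tab[i] / tot;
  return out;
}

// Log of the collapsed joint probability P(Z, Y, pairs | alphas): product
// of Dirichlet-multinomial normalizing constants at the four levels.
// [[Rcpp::export]]
double cpp_log_joint(IntegerMatrix count_nk, IntegerMatrix count_kl,
                     IntegerMatrix dcount_lc, IntegerMatrix gcount_lc,
                     double at, double ap, double ad, double ag) {
  const int N = count_nk.nrow(), K = count_nk.ncol();
  const int L = count_kl.ncol(), C = dcount_lc.ncol();
  double lp = 0.0;

  for (int n = 0; n < N; ++n) {
    double tot = 0.0, s = 0.0;
    for (int k = 0; k < K; ++k) {
      const int v = count_nk(n, k);
      tot += v;
      s += lgamma(v + at);
    }
    lp += lgamma(K * at) - K * lgamma(at) + s - lgamma(tot + K * at);
  }
  for (int k = 0; k < K; ++k) {
    double tot = 0.0, s = 0.0;
    for (int l = 0; l < L; ++l) {
      const int v = count_kl(k, l);
      tot += v;
      s += lgamma(v + ap);
    }
    lp += lgamma(L * ap) - L * lgamma(ap) + s - lgamma(tot + L * ap);
  }
  for (int l = 0; l < L; ++l) {
    double dtot = 0.0, ds = 0.0, gtot = 0.0, gs = 0.0;
    for (int c = 0; c < C; ++c) {
      const int dv = dcount_lc(l, c), gv = gcount_lc(l, c);
      dtot += dv; ds += lgamma(dv + ad);
      gtot += gv; gs += lgamma(gv + ag);
    }
    lp += lgamma(C * ad) - C * lgamma(ad) + ds - lgamma(dtot + C * ad);
    lp += lgamma(C * ag) - C * lgamma(ag) + gs - lgamma(gtot + C * ag);
  }
  return lp;
}
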