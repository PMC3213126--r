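// Felsenstein pruning over site patterns with per-pattern scaling.
// One call evaluates all "mixture classes" (gamma categories x mixture
// components); the R side supplies, per class, the eigendecomposition of the
// scaled reversible rate matrix, the root frequencies and a rate multiplier.
// Transition matrices P(t) = U diag(exp(lambda * t * rate)) Uinv are built
// here so branch-length moves cost no R-level work.  The 4-state and 2-state
// propagation loops are unrolled: they dominate MCMC run time.  Tip partials
// are indexed through `tip_index` (tree tip number -> data row), so no
// reordering copy is needed per evaluation, and the weighted log-sum-exp
// over classes is folded into the same call.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void build_P(const double* U, const double* lam,
                           const double* Uinv, double t, int S, double* P) {
  double expd[8];
  for (int s = 0; s < S; ++s) expd[s] = std::exp(lam[s] * t);
  // column-major U (S x S), Uinv (S x S); P row-major (P[i*S+j])
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) {
      double acc = 0.0;
      for (int s = 0; s < S; ++s)
        acc += U[i + s * S] * expd[s] * Uinv[s + j * S];
      P[i * S + j] = acc > 0.0 ? acc : 0.0;
    }
}

// Core pruning for all classes; fills `cls_ll` (npat x nclass).
static void prune_all(IntegerMatrix& edge, NumericVector& el, int ntip,
                      IntegerVector& tip_index, NumericVector& tipp,
                      List& classes, std::vector<double>& cls_ll) {
  const int nedge = edge.nrow();
  const int nclass = classes.size();
  IntegerVector tdim = tipp.attr("dim");
  const int S = tdim[0];
  const int npat = tdim[1];

  int maxnode = ntip;
  const int* ep = INTEGER(edge);           // column-major: parent col 0
  for (int e = 0; e < nedge; ++e) {
    if (ep[e] > maxnode) maxnode = ep[e];
    if (ep[e + nedge] > maxnode) maxnode = ep[e + nedge];
  }
  const int root = ep[nedge - 1];

  std::vector<double> partial((size_t)(maxnode + 1) * S * npat);
  std::vector<double> scalelog(npat);
  std::vector<char> touched(maxnode + 1);
  std::vector<double> P(64);
  const double* tippp = REAL(tipp);
  const double* elp = REAL(el);
  const int* tidx = INTEGER(tip_index);

  for (int cl = 0; cl < nclass; ++cl) {
    List c = classes[cl];
    NumericMatrix U = c["U"], Uinv = c["Uinv"];
    NumericVector lam = c["lambda"], pi = c["pi"];
    const double rate = as<double>(c["rate"]);

    std::fill(scalelog.begin(), scalelog.end(), 0.0);
    std::fill(touched.begin(), touched.end(), 0);

    for (int e = 0; e < nedge; ++e) {
      const int par = ep[e], ch = ep[e + nedge];
      build_P(REAL(U), REAL(lam), REAL(Uinv), elp[e] * rate, S, P.data());

      const double* __restrict chp = (ch <= ntip)
        ? tippp + (size_t)(tidx[ch - 1] - 1) * S * npat
        : &partial[(size_t)ch * S * npat];
      double* __restrict pap = &partial[(size_t)par * S * npat];
      if (!touched[par]) {
        std::fill(pap, pap + (size_t)S * npat, 1.0);
        touched[par] = 1;
      }
      if (S == 4) {
        const double p00 = P[0], p01 = P[1], p02 = P[2], p03 = P[3];
        const double p10 = P[4], p11 = P[5], p12 = P[6], p13 = P[7];
        const double p20 = P[8], p21 = P[9], p22 = P[10], p23 = P[11];
        const double p30 = P[12], p31 = P[13], p32 = P[14], p33 = P[15];
        for (int p = 0; p < npat; ++p) {
          const double c0 = chp[4 * p], c1 = chp[4 * p + 1];
          const double c2 = chp[4 * p + 2], c3 = chp[4 * p + 3];
          pap[4 * p]     *= p00 * c0 + p01 * c1 + p02 * c2 + p03 * c3;
          pap[4 * p + 1] *= p10 * c0 + p11 * c1 + p12 * c2 + p13 * c3;
          pap[4 * p + 2] *= p20 * c0 + p21 * c1 + p22 * c2 + p23 * c3;
          pap[4 * p + 3] *= p30 * c0 + p31 * c1 + p32 * c2 + p33 * c3;
        }
      } else if (S == 2) {
        const double p00 = P[0], p01 = P[1], p10 = P[2], p11 = P[3];
        for (int p = 0; p < npat; ++p) {
          const double c0 = chp[2 * p], c1 = chp[2 * p + 1];
          pap[2 * p]     *= p00 * c0 + p01 * c1;
          pap[2 * p + 1] *= p10 * c0 + p11 * c1;
        }
      } else {
        for (int p = 0; p < npat; ++p) {
          const double* cv = chp + (size_t)p * S;
          double* pv = pap + (size_t)p * S;
          for (int i = 0; i < S; ++i) {
            double acc = 0.0;
            for (int j = 0; j < S; ++j) acc += P[i * S + j] * cv[j];
            pv[i] *= acc;
          }
        }
      }
      // rescale the completed parent block to avoid underflow; rescaling at
      // any point before the node is consumed is valid, so a conservative
      // check after the last postorder edge into `par` suffices
      const bool last_into_par = (e + 1 == nedge) || (ep[e + 1] != par);
      if (last_into_par) {
        for (int p = 0; p < npat; ++p) {
          double* pv = pap + (size_t)p * S;
          double mx = 0.0;
          for (int i = 0; i < S; ++i) if (pv[i] > mx) mx = pv[i];
          if (mx > 0.0 && mx < 1e-80) {
            const double inv = 1.0 / mx;
            for (int i = 0; i < S; ++i) pv[i] *= inv;
            scalelog[p] += std::log(mx);
          }
        }
      }
    }

    const double* rp = &partial[(size_t)root * S * npat];
    for (int p = 0; p < npat; ++p) {
      double acc = 0.0;
      for (int i = 0; i < S; ++i) acc += pi[i] * rp[p * S + i];
      cls_ll[(size_t)cl * npat + p] = std::log(acc) + scalelog[p];
    }
  }
}

// Per-pattern per-class log-likelihoods (npat x nclass); class weights are
// NOT applied.  edge: postorder, 1-based ids, tips 1..ntip; tip_index maps
// tree tip number -> slice of `tipp` (S x npat x ntaxa).
// [[Rcpp::export]]
NumericMatrix pruning_loglik_cpp(IntegerMatrix edge, NumericVector el,
                                 int ntip, IntegerVector tip_index,
                                 NumericVector tipp, List classes) {
  IntegerVector tdim = tipp.attr("dim");
  const int npat = tdim[1];
  const int nclass = classes.size();
  std::vector<double> cls_ll((size_t)nclass * npat);
  prune_all(edge, el, ntip, tip_index, tipp, classes, cls_ll);
  NumericMatrix out(npat, nclass);
  for (int cl = 0; cl < nclass; ++cl)
    for (int p = 0; p < npat; ++p) out(p, cl) = cls_ll[(size_t)cl * npat + p];
  return out;
}

// Per-pattern log-likelihood mixed over classes: log sum_c exp(logw_c + ll_pc).
// [[Rcpp::export]]
NumericVector pruning_mixture_loglik_cpp(IntegerMatrix edge, NumericVector el,
                                         int ntip, IntegerVector tip_index,
                                         NumericVector tipp, List classes,
                                         NumericVector logw) {
  IntegerVector tdim = tipp.attr("dim");
  const int npat = tdim[1];
  const int nclass = classes.size();
  std::vector<double> cls_ll((size_t)nclass * npat);
  prune_all(edge, el, ntip, tip_index, tipp, classes, cls_ll);
  NumericVector out(npat);
  for (int p = 0; p < npat; ++p) {
    double mx = R_NegInf;
    for (int cl = 0; cl < nclass; ++cl) {
      const double v = cls_ll[(size_t)cl * npat + p] + logw[cl];
      if (v > mx) mx = v;
    }
    if (!std::isfinite(mx)) { out[p] = R_NegInf; continue; }
    double acc = 0.0;
    for (int cl = 0; cl < nclass; ++cl)
      acc += std::exp(cls_ll[(size_t)cl * npat + p] + logw[cl] - mx);
    out[p] = mx + std::log(acc);
  }
  return out;
}
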