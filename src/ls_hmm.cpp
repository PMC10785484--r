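#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Diploid Li-Stephens haplotype-copying HMM over ordered reference-haplotype
// pairs (j,k). Transitions factorise per haplotype:
//   t(j'->j) = (1-rho) + rho/K  if j == j',  rho/K otherwise
// which lets each forward/backward/Viterbi step run in O(K^2) using row/column
// sums (or maxima) instead of O(K^4).
//
// Emission at site m for state (j,k):
//   e(j,k) = sum_g GL[m,g] * P(g | alleles copied from j,k with error theta)
// and depends on the copied alleles only through the ordered pair
// (a_j, a_k); P(g | a_j, a_k) treats the two copying errors independently.

static inline void emission_weights(double theta, int s, double w[3]) {
  // s = a_j + a_k (unordered is enough for the genotype distribution)
  double p1 = (s >= 1) ? 1.0 - theta : theta;   // first allele is 1
  double p2 = (s == 2) ? 1.0 - theta : theta;   // second allele is 1
  if (s == 1) { p1 = 1.0 - theta; p2 = theta; } // one match, one mismatch
  w[0] = (1.0 - p1) * (1.0 - p2);
  w[2] = p1 * p2;
  w[1] = 1.0 - w[0] - w[2];
}

// [[Rcpp::export(name = ".ls_forward_backward_cpp")]]
List ls_forward_backward_cpp(NumericMatrix gl, IntegerMatrix hap,
                             NumericVector rho, double theta,
                             bool return_states = false,
                             double max_workspace = 2e9) {
  const int M = gl.nrow();
  const int K = hap.nrow();
  if (hap.ncol() != M) stop("panel and GL site counts differ");
  if (rho.size() != M) stop("rho must have one entry per site");
  if (theta <= 0.0 || theta >= 0.5) stop("mismatch_theta must lie in (0, 0.5)");
  const size_t S = (size_t)K * (size_t)K;
  double need = (double)S * (double)M * 8.0;
  if (need > max_workspace)
    stop("K^2 x M workspace (%.0f bytes) exceeds the configured cap (%.0f); "
         "impute in smaller chunks (reduce chunk_bp)", need, max_workspace);

  // per-site emission values by s = a_j + a_k
  std::vector<double> es(3 * M), wst(9 * M);
  for (int m = 0; m < M; ++m) {
    for (int s = 0; s < 3; ++s) {
      double w[3];
      emission_weights(theta, s, w);
      double e = gl(m, 0) * w[0] + gl(m, 1) * w[1] + gl(m, 2) * w[2];
      es[3 * m + s] = e;
      for (int g = 0; g < 3; ++g) wst[9 * m + 3 * s + g] = w[g];
    }
  }

  // backward pass, stored
  std::vector<double> B((size_t)M * S);
  std::vector<double> G(S), rowG(K), colG(K);
  {
    double *Bm = &B[(size_t)(M - 1) * S];
    for (size_t i = 0; i < S; ++i) Bm[i] = 1.0;
    for (int m = M - 2; m >= 0; --m) {
      const double r = rho[m + 1], q = 1.0 - r, u = r / K;
      const double *Bn = &B[(size_t)(m + 1) * S];
      double totG = 0.0;
      std::fill(rowG.begin(), rowG.end(), 0.0);
      std::fill(colG.begin(), colG.end(), 0.0);
      const double *em = &es[3 * (m + 1)];
      for (int j = 0; j < K; ++j) {
        const int aj = hap(j, m + 1);
        for (int k = 0; k < K; ++k) {
          double g = em[aj + hap(k, m + 1)] * Bn[(size_t)j * K + k];
          G[(size_t)j * K + k] = g;
          rowG[j] += g; colG[k] += g; totG += g;
        }
      }
      double *Bm2 = &B[(size_t)m * S];
      double scale = 0.0;
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k) {
          double v = q * q * G[(size_t)j * K + k] +
                     q * u * (rowG[j] + colG[k]) + u * u * totG;
          Bm2[(size_t)j * K + k] = v;
          scale += v;
        }
      scale /= (double)S; // keep magnitudes O(1)
      for (size_t i = 0; i < S; ++i) Bm2[i] /= scale;
    }
  }

  // forward pass combined with posteriors on the fly
  NumericMatrix gp(M, 3);
  NumericVector or10(M), or01(M);
  NumericMatrix states;
  if (return_states) states = NumericMatrix(M, (int)S);
  std::vector<double> F(S), Fn(S), rowF(K), colF(K);
  double loglik = 0.0;
  for (int m = 0; m < M; ++m) {
    const double *em = &es[3 * m];
    if (m == 0) {
      double c = 0.0;
      for (int j = 0; j < K; ++j) {
        const int aj = hap(j, 0);
        for (int k = 0; k < K; ++k) {
          double v = em[aj + hap(k, 0)] / (double)S;
          Fn[(size_t)j * K + k] = v;
          c += v;
        }
      }
      loglik += std::log(c);
      for (size_t i = 0; i < S; ++i) Fn[i] /= c;
    } else {
      const double r = rho[m], q = 1.0 - r, u = r / K;
      std::fill(rowF.begin(), rowF.end(), 0.0);
      std::fill(colF.begin(), colF.end(), 0.0);
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k) {
          double f = F[(size_t)j * K + k];
          rowF[j] += f; colF[k] += f;
        }
      double c = 0.0;
      for (int j = 0; j < K; ++j) {
        const int aj = hap(j, m);
        for (int k = 0; k < K; ++k) {
          double pred = q * q * F[(size_t)j * K + k] +
                        q * u * (rowF[j] + colF[k]) + u * u;
          double v = pred * em[aj + hap(k, m)];
          Fn[(size_t)j * K + k] = v;
          c += v;
        }
      }
      loglik += std::log(c);
      for (size_t i = 0; i < S; ++i) Fn[i] /= c;
    }
    // posterior at m
    const double *Bm = &B[(size_t)m * S];
    double tot = 0.0;
    double mass4[4] = {0.0, 0.0, 0.0, 0.0};
    for (int j = 0; j < K; ++j) {
      const int aj = hap(j, m);
      for (int k = 0; k < K; ++k) {
        double p = Fn[(size_t)j * K + k] * Bm[(size_t)j * K + k];
        F[(size_t)j * K + k] = p; // reuse F as scratch posterior
        tot += p;
        mass4[2 * aj + hap(k, m)] += p;
      }
    }
    for (int t = 0; t < 4; ++t) mass4[t] /= tot;
    if (return_states)
      for (size_t i = 0; i < S; ++i) states(m, (int)i) = F[i] / tot;
    // genotype posterior: sum over states of P(state|data) P(g|state,data_m)
    double num[3] = {0.0, 0.0, 0.0};
    for (int t = 0; t < 4; ++t) {
      int s = (t >> 1) + (t & 1);
      double inv_e = 1.0 / em[s];
      for (int g = 0; g < 3; ++g)
        num[g] += mass4[t] * gl(m, g) * wst[9 * m + 3 * s + g] * inv_e;
    }
    double ng = num[0] + num[1] + num[2];
    for (int g = 0; g < 3; ++g) gp(m, g) = num[g] / ng;
    // ordered heterozygote orientation posteriors
    double o10 = 0.0, o01 = 0.0;
    for (int t = 0; t < 4; ++t) {
      int a1 = t >> 1, a2 = t & 1;
      int s = a1 + a2;
      double p1 = a1 ? 1.0 - theta : theta;
      double p2 = a2 ? 1.0 - theta : theta;
      o10 += mass4[t] * gl(m, 1) * p1 * (1.0 - p2) / em[s];
      o01 += mass4[t] * gl(m, 1) * (1.0 - p1) * p2 / em[s];
    }
    or10[m] = o10; or01[m] = o01;
    // Fn becomes F for the next step
    std::swap(F, Fn);
  }

  List out = List::create(_["gp"] = gp, _["or10"] = or10, _["or01"] = or01,
                          _["loglik"] = loglik);
  if (return_states) out["states"] = states;
  return out;
}

// [[Rcpp::export(name = ".ls_viterbi_cpp")]]
List ls_viterbi_cpp(NumericMatrix gl, IntegerMatrix hap, NumericVector rho,
                    double theta, double max_workspace = 2e9) {
  const int M = gl.nrow();
  const int K = hap.nrow();
  if (hap.ncol() != M) stop("panel and GL site counts differ");
  if (theta <= 0.0 || theta >= 0.5) stop("mismatch_theta must lie in (0, 0.5)");
  const size_t S = (size_t)K * (size_t)K;
  double need = (double)S * (double)M * 1.0 + (double)M * K * 8.0;
  if (need > max_workspace)
    stop("K^2 x M workspace (%.0f bytes) exceeds the configured cap (%.0f); "
         "impute in smaller chunks (reduce chunk_bp)", need, max_workspace);

  std::vector<double> les(3 * M);
  for (int m = 0; m < M; ++m)
    for (int s = 0; s < 3; ++s) {
      double w[3];
      emission_weights(theta, s, w);
      les[3 * m + s] =
          std::log(gl(m, 0) * w[0] + gl(m, 1) * w[1] + gl(m, 2) * w[2]);
    }

  std::vector<double> V(S), Vn(S), rowmax(K), colmax(K);
  std::vector<int> rowarg((size_t)M * K), colarg((size_t)M * K);
  std::vector<int> garg(2 * (size_t)M);
  std::vector<uint8_t> cat((size_t)M * S);

  const double l0 = std::log(1.0 / (double)S);
  for (int j = 0; j < K; ++j) {
    const int aj = hap(j, 0);
    for (int k = 0; k < K; ++k)
      V[(size_t)j * K + k] = l0 + les[aj + hap(k, 0)];
  }

  for (int m = 1; m < M; ++m) {
    const double r = rho[m], q = 1.0 - r, u = r / K;
    const double la = std::log(q + u);
    const double lb = (u > 0.0) ? std::log(u) : R_NegInf;
    double gmax = R_NegInf; int gj = 0, gk = 0;
    for (int j = 0; j < K; ++j) {
      double rm = R_NegInf; int ra = 0;
      for (int k = 0; k < K; ++k) {
        double v = V[(size_t)j * K + k];
        if (v > rm) { rm = v; ra = k; }
      }
      rowmax[j] = rm; rowarg[(size_t)m * K + j] = ra;
      if (rm > gmax) { gmax = rm; gj = j; gk = ra; }
    }
    for (int k = 0; k < K; ++k) {
      double cm = R_NegInf; int ca = 0;
      for (int j = 0; j < K; ++j) {
        double v = V[(size_t)j * K + k];
        if (v > cm) { cm = v; ca = j; }
      }
      colmax[k] = cm; colarg[(size_t)m * K + k] = ca;
    }
    garg[2 * (size_t)m] = gj; garg[2 * (size_t)m + 1] = gk;
    const double *lem = &les[3 * m];
    for (int j = 0; j < K; ++j) {
      const int aj = hap(j, m);
      for (int k = 0; k < K; ++k) {
        double c0 = V[(size_t)j * K + k] + la + la;
        double c1 = rowmax[j] + la + lb;
        double c2 = colmax[k] + lb + la;
        double c3 = gmax + lb + lb;
        // deterministic tie-break: prefer staying, then hap-B switch,
        // then hap-A switch, then double switch
        double best = c0; uint8_t cc = 0;
        if (c1 > best) { best = c1; cc = 1; }
        if (c2 > best) { best = c2; cc = 2; }
        if (c3 > best) { best = c3; cc = 3; }
        cat[(size_t)m * S + (size_t)j * K + k] = cc;
        Vn[(size_t)j * K + k] = best + lem[aj + hap(k, m)];
      }
    }
    std::swap(V, Vn);
  }

  // terminal argmax and traceback
  int bj = 0, bk = 0; double bv = R_NegInf;
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      if (V[(size_t)j * K + k] > bv) { bv = V[(size_t)j * K + k]; bj = j; bk = k; }
  IntegerVector pj(M), pk(M);
  pj[M - 1] = bj; pk[M - 1] = bk;
  for (int m = M - 1; m >= 1; --m) {
    int j = pj[m], k = pk[m];
    switch (cat[(size_t)m * S + (size_t)j * K + k]) {
    case 0: pj[m - 1] = j; pk[m - 1] = k; break;
    case 1: pj[m - 1] = j; pk[m - 1] = rowarg[(size_t)m * K + j]; break;
    case 2: pj[m - 1] = colarg[(size_t)m * K + k]; pk[m - 1] = k; break;
    default: pj[m - 1] = garg[2 * (size_t)m]; pk[m - 1] = garg[2 * (size_t)m + 1];
    }
  }
  return List::create(_["path_j"] = pj, _["path_k"] = pk, _["logmax"] = bv);
}
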