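#include <Rcpp.h>
using namespace Rcpp;

// One full CVB0 sweep over the records of the patients listed in `patients`
// (0-based), in patient order; within a patient: token records, then
// observed lab records, then unobserved lab pairs.  All assignment
// matrices and cached statistics are updated in place, incrementally:
// own contribution subtracted (clipped at 0), new value added back.
// Indices arriving from R are 0-based.
// [[Rcpp::export]]
void cvb0_sweep_cpp(int K,
                    IntegerVector patients,
                    IntegerVector tok_ptr, IntegerVector tt,
                    IntegerVector tw, NumericVector tc, NumericMatrix gamma,
                    IntegerVector obs_ptr, IntegerVector ol,
                    IntegerVector ov, NumericVector oy, NumericMatrix lambda,
                    IntegerVector miss_ptr, IntegerVector ml,
                    IntegerVector pi_off, NumericVector pi_flat,
                    IntegerVector Vl_all,
                    NumericMatrix n_jk, List n_wk, NumericMatrix nk,
                    NumericMatrix m_jk, List m_lkv,
                    NumericMatrix p, NumericMatrix q,
                    NumericVector alpha, List beta, NumericVector beta_sum,
                    List zeta, NumericVector zeta_sum,
                    NumericVector a, NumericVector b) {
  int T = n_wk.size();
  int L = m_lkv.size();
  std::vector<NumericMatrix> nw(T), mv(L);
  std::vector<NumericVector> bt(T), zl(L);
  for (int t = 0; t < T; ++t) { nw[t] = as<NumericMatrix>(n_wk[t]); bt[t] = as<NumericVector>(beta[t]); }
  for (int l = 0; l < L; ++l) { mv[l] = as<NumericMatrix>(m_lkv[l]); zl[l] = as<NumericVector>(zeta[l]); }
  std::vector<double> val(K), ex_nj(K), ex_nw(K), ex_nk(K), mass(K),
      ex_mj(K), ex_p(K), ex_q(K), ex_m(K);

  for (int pi_i = 0; pi_i < patients.size(); ++pi_i) {
    int j = patients[pi_i];

    // --- token records -------------------------------------------------
    for (int r = tok_ptr[j]; r < tok_ptr[j + 1]; ++r) {
      int t = tt[r], w = tw[r];
      double c = tc[r];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = c * gamma(r, k);
        ex_nj[k] = std::max(n_jk(j, k) - g, 0.0);
        ex_nw[k] = std::max(nw[t](w, k) - g, 0.0);
        ex_nk[k] = std::max(nk(t, k) - g, 0.0);
        val[k] = (alpha[k] + ex_nj[k] + m_jk(j, k)) *
                 (bt[t][w] + ex_nw[k]) / (beta_sum[t] + ex_nk[k]);
        tot += val[k];
      }
      for (int k = 0; k < K; ++k) {
        double gnew = val[k] / tot;
        gamma(r, k) = gnew;
        double add = c * gnew;
        n_jk(j, k) = ex_nj[k] + add;
        nw[t](w, k) = ex_nw[k] + add;
        nk(t, k) = ex_nk[k] + add;
      }
    }

    // --- observed lab records ------------------------------------------
    for (int r = obs_ptr[j]; r < obs_ptr[j + 1]; ++r) {
      int l = ol[r], v = ov[r];
      double y = oy[r];
      // current mass of the whole (l, j) group (all sibling states)
      for (int k = 0; k < K; ++k) mass[k] = 0.0;
      for (int s = obs_ptr[j]; s < obs_ptr[j + 1]; ++s) {
        if (ol[s] != l) continue;
        for (int k = 0; k < K; ++k) mass[k] += oy[s] * lambda(s, k);
      }
      double tot = 0.0;
      int Vl = Vl_all[l];
      for (int k = 0; k < K; ++k) {
        double own = y * lambda(r, k);
        ex_mj[k] = std::max(m_jk(j, k) - mass[k], 0.0);
        ex_p[k] = std::max(p(l, k) - mass[k], 0.0);
        ex_m[k] = std::max(mv[l](k, v) - own, 0.0);
        double rowrest = 0.0;
        for (int v2 = 0; v2 < Vl; ++v2) if (v2 != v) rowrest += mv[l](k, v2);
        double denom = zeta_sum[l] + rowrest + ex_m[k];
        val[k] = (alpha[k] + n_jk(j, k) + ex_mj[k]) *
                 (zl[l][v] + ex_m[k]) / denom *
                 (a[l] + ex_p[k]) / (a[l] + ex_p[k] + b[l] + q(l, k));
        tot += val[k];
      }
      for (int k = 0; k < K; ++k) {
        double lold = lambda(r, k);
        double lnew = val[k] / tot;
        lambda(r, k) = lnew;
        double groupnew = mass[k] - y * lold + y * lnew;
        m_jk(j, k) = ex_mj[k] + groupnew;
        p(l, k) = ex_p[k] + groupnew;
        mv[l](k, v) = ex_m[k] + y * lnew;
      }
    }

    // --- unobserved lab pairs ------------------------------------------
    for (int r = miss_ptr[j]; r < miss_ptr[j + 1]; ++r) {
      int l = ml[r];
      int Vl = Vl_all[l];
      int off = pi_off[r];
      for (int k = 0; k < K; ++k) {
        mass[k] = 0.0;
        for (int v = 0; v < Vl; ++v) mass[k] += pi_flat[off + v * K + k];
      }
      for (int k = 0; k < K; ++k) {
        ex_mj[k] = std::max(m_jk(j, k) - mass[k], 0.0);
        ex_q[k] = std::max(q(l, k) - mass[k], 0.0);
      }
      double tot = 0.0;
      std::vector<double> vv(K * Vl), exm(K * Vl);
      for (int v = 0; v < Vl; ++v) {
        for (int k = 0; k < K; ++k) {
          double own = pi_flat[off + v * K + k];
          double ex = std::max(mv[l](k, v) - own, 0.0);
          exm[v * K + k] = ex;
          double rowrest = 0.0;
          for (int v2 = 0; v2 < Vl; ++v2) if (v2 != v) rowrest += mv[l](k, v2);
          double denom = zeta_sum[l] + rowrest + ex;
          double x = (alpha[k] + n_jk(j, k) + ex_mj[k]) *
                     (zl[l][v] + ex) / denom *
                     (b[l] + ex_q[k]) / (a[l] + p(l, k) + b[l] + ex_q[k]);
          vv[v * K + k] = x;
          tot += x;
        }
      }
      for (int k = 0; k < K; ++k) {
        double newmass = 0.0;
        for (int v = 0; v < Vl; ++v) {
          double pnew = vv[v * K + k] / tot;
          pi_flat[off + v * K + k] = pnew;
          mv[l](k, v) = exm[v * K + k] + pnew;
          newmass += pnew;
        }
        m_jk(j, k) = ex_mj[k] + newmass;
        q(l, k) = ex_q[k] + newmass;
      }
    }
  }
}
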