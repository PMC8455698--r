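// Fused message-passing stack. One directed edge e carries a (d x d/2)
// edge state, stored row-major per edge in the embedding output (slot
// r*(d/2)+c of edge e); the message into the edge's head atom is
//   attn_e * rowSums( Conv(unfold(h_tail)) % e_state ).
// A forward call runs all T iterations of (bond pass, coupling pass) and
// caches only the small per-step node-state inputs; the backward call
// recomputes the large intermediates (unfold, Conv output) per step, which
// is cheaper than round-tripping them through R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// one message-passing step in place: H(head_e) += attn_e * message_e.
// ElinT: (d*k x E), column e = row-major slots of edge e's state.
static void step_forward(mat& H, const ivec& tail, const ivec& head,
                         const mat& ElinT, const mat& convA, const vec& convb,
                         const vec& attn, mat& U, mat& CU) {
  const uword d = H.n_cols, k = d / 2, E = tail.n_elem;
  for (uword e = 0; e < E; ++e) {
    const uword w = (uword)tail[e];
    for (uword r = 0; r < d; ++r) {
      double* uc = U.colptr(e * d + r);
      const uword cmax = std::min<uword>(k, d - r);
      for (uword c = 0; c < cmax; ++c) uc[c] = H(w, r + c);
      for (uword c = cmax; c < k; ++c) uc[c] = 0.0;
    }
  }
  CU = convA.t() * U;
  CU.each_col() += convb;
  for (uword e = 0; e < E; ++e) {
    const double* ecol = ElinT.colptr(e);
    const double a = attn[e];
    const uword v = (uword)head[e];
    for (uword r = 0; r < d; ++r) {
      const double* cu = CU.colptr(e * d + r);
      const double* es = ecol + r * k;
      double m = 0.0;
      for (uword c = 0; c < k; ++c) m += cu[c] * es[c];
      H(v, r) += a * m;
    }
  }
}

// [[Rcpp::export(name = ".cpp_mp_stack_forward")]]
Rcpp::List cpp_mp_stack_forward(const arma::mat& H0,
                                const arma::ivec& b_tail, const arma::ivec& b_head,
                                const arma::mat& EbT, const arma::mat& convA_b,
                                const arma::vec& convb_b, const arma::vec& attn_b,
                                const arma::ivec& c_tail, const arma::ivec& c_head,
                                const arma::mat& EcT, const arma::mat& convA_c,
                                const arma::vec& convb_c, int T) {
  const uword d = H0.n_cols, k = d / 2;
  mat H = H0;
  const uword Eb = b_tail.n_elem, Ec = c_tail.n_elem;
  mat Ub(k, Eb * d), CUb, Uc(k, Ec * d), CUc;
  Rcpp::List Hins(2 * T);
  for (int t = 0; t < T; ++t) {
    Hins[2 * t] = H;
    if (Eb) step_forward(H, b_tail, b_head, EbT, convA_b, convb_b, attn_b, Ub, CUb);
    Hins[2 * t + 1] = H;
    if (Ec) {
      vec ones_c(Ec, fill::ones);
      step_forward(H, c_tail, c_head, EcT, convA_c, convb_c, ones_c, Uc, CUc);
    }
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("Hins") = Hins);
}

// backward of one step. dH is the gradient at the step output; on exit it
// holds the gradient at the step input. dElinT, dconvA, dconvb, dattn
// accumulate across steps.
static void step_backward(mat& dH, const mat& Hin, const ivec& tail,
                          const ivec& head, const mat& ElinT, const mat& convA,
                          const vec& convb, const vec& attn, bool want_attn,
                          mat& dElinT, mat& dconvA, vec& dconvb, vec& dattn,
                          mat& U, mat& CU, mat& dCU) {
  const uword d = dH.n_cols, k = d / 2, E = tail.n_elem;
  // recompute the unfold and Conv output of this step
  for (uword e = 0; e < E; ++e) {
    const uword w = (uword)tail[e];
    for (uword r = 0; r < d; ++r) {
      double* uc = U.colptr(e * d + r);
      const uword cmax = std::min<uword>(k, d - r);
      for (uword c = 0; c < cmax; ++c) uc[c] = Hin(w, r + c);
      for (uword c = cmax; c < k; ++c) uc[c] = 0.0;
    }
  }
  CU = convA.t() * U;
  CU.each_col() += convb;

  for (uword e = 0; e < E; ++e) {
    const uword v = (uword)head[e];
    const double* ecol = ElinT.colptr(e);
    double* decol = dElinT.colptr(e);
    const double a = attn[e];
    double da = 0.0;
    for (uword r = 0; r < d; ++r) {
      const double g = dH(v, r);           // gradient at the aggregated state
      const double* cu = CU.colptr(e * d + r);
      const double* es = ecol + r * k;
      double* des = decol + r * k;
      double* dcu = dCU.colptr(e * d + r);
      if (want_attn) {
        double m = 0.0;
        for (uword c = 0; c < k; ++c) m += cu[c] * es[c];
        da += m * g;
      }
      const double ga = g * a;
      for (uword c = 0; c < k; ++c) {
        dcu[c] = ga * es[c];
        des[c] += ga * cu[c];
      }
    }
    if (want_attn) dattn[e] += da;
  }
  dconvA += U * dCU.t();
  dconvb += sum(dCU, 1);
  mat dU = convA * dCU;
  // adjoint of the unfold onto the tail atoms (the residual path leaves the
  // incoming dH in place)
  for (uword e = 0; e < E; ++e) {
    const uword w = (uword)tail[e];
    for (uword r = 0; r < d; ++r) {
      const double* uc = dU.colptr(e * d + r);
      const uword cmax = std::min<uword>(k, d - r);
      for (uword c = 0; c < cmax; ++c) dH(w, r + c) += uc[c];
    }
  }
}

// [[Rcpp::export(name = ".cpp_mp_stack_backward")]]
Rcpp::List cpp_mp_stack_backward(const arma::mat& dHtop, Rcpp::List Hins,
                                 const arma::ivec& b_tail, const arma::ivec& b_head,
                                 const arma::mat& EbT, const arma::mat& convA_b,
                                 const arma::vec& convb_b, const arma::vec& attn_b,
                                 const arma::ivec& c_tail, const arma::ivec& c_head,
                                 const arma::mat& EcT, const arma::mat& convA_c,
                                 const arma::vec& convb_c, int T, bool want_attn) {
  const uword d = dHtop.n_cols, k = d / 2;
  const uword Eb = b_tail.n_elem, Ec = c_tail.n_elem;
  mat dH = dHtop;
  mat dEbT(d * k, Eb, fill::zeros), dEcT(d * k, Ec, fill::zeros);
  mat dconvA_b(k, k, fill::zeros), dconvA_c(k, k, fill::zeros);
  vec dconvb_b(k, fill::zeros), dconvb_c(k, fill::zeros);
  vec dattn(Eb, fill::zeros), dattn_dummy(Ec, fill::zeros);
  vec ones_c(Ec, fill::ones);
  mat Ub(k, Eb * d), CUb, dCUb(k, Eb * d);
  mat Uc(k, Ec * d), CUc, dCUc(k, Ec * d);
  for (int t = T - 1; t >= 0; --t) {
    if (Ec) {
      mat Hin = Hins[2 * t + 1];
      step_backward(dH, Hin, c_tail, c_head, EcT, convA_c, convb_c, ones_c,
                    false, dEcT, dconvA_c, dconvb_c, dattn_dummy, Uc, CUc, dCUc);
    }
    if (Eb) {
      mat Hin = Hins[2 * t];
      step_backward(dH, Hin, b_tail, b_head, EbT, convA_b, convb_b, attn_b,
                    want_attn, dEbT, dconvA_b, dconvb_b, dattn, Ub, CUb, dCUb);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dH") = dH,
                            Rcpp::Named("dEbT") = dEbT,
                            Rcpp::Named("dEcT") = dEcT,
                            Rcpp::Named("dconvA_b") = dconvA_b,
                            Rcpp::Named("dconvb_b") = dconvb_b,
                            Rcpp::Named("dconvA_c") = dconvA_c,
                            Rcpp::Named("dconvb_c") = dconvb_c,
                            Rcpp::Named("dattn") = dattn);
}
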