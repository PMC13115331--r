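// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fused recurrent layers. Frame embeddings E are (d, T * B) with frame
// index fastest (column t + T * w is frame t of window w). Gate caches are
// stacked the same way so the backward weight gradients are single GEMMs.

static arma::mat step_cols(const arma::mat& E, int T, int B, int t) {
  arma::mat X(E.n_rows, B);
  for (int w = 0; w < B; ++w) X.col(w) = E.col((size_t)w * T + t);
  return X;
}

// [[Rcpp::export]]
List gru_forward_cpp(const arma::mat& E,
                     const arma::mat& Wz, const arma::mat& Uz,
                     const arma::vec& bz,
                     const arma::mat& Wr, const arma::mat& Ur,
                     const arma::vec& br,
                     const arma::mat& Wn, const arma::mat& Un,
                     const arma::vec& bn,
                     int T, int B, bool keep_cache) {
  const int h = Wz.n_rows;
  arma::mat H(h, B, arma::fill::zeros);
  arma::mat Z, R, N, RH, HP;
  if (keep_cache) {
    Z.set_size(h, (size_t)T * B); R.set_size(h, (size_t)T * B);
    N.set_size(h, (size_t)T * B); RH.set_size(h, (size_t)T * B);
    HP.set_size(h, (size_t)T * B);
  }
  for (int t = 0; t < T; ++t) {
    arma::mat Xt = step_cols(E, T, B, t);
    arma::mat z = 1.0 / (1.0 + arma::exp(-(Wz * Xt + Uz * H +
                                           arma::repmat(bz, 1, B))));
    arma::mat r = 1.0 / (1.0 + arma::exp(-(Wr * Xt + Ur * H +
                                           arma::repmat(br, 1, B))));
    arma::mat rh = r % H;
    arma::mat n = arma::tanh(Wn * Xt + Un * rh + arma::repmat(bn, 1, B));
    arma::mat Hn = (1.0 - z) % n + z % H;
    if (keep_cache) {
      for (int w = 0; w < B; ++w) {
        const size_t c = (size_t)w * T + t;
        Z.col(c) = z.col(w); R.col(c) = r.col(w); N.col(c) = n.col(w);
        RH.col(c) = rh.col(w); HP.col(c) = H.col(w);
      }
    }
    H = Hn;
  }
  if (keep_cache) {
    return List::create(_["H"] = H, _["Z"] = Z, _["R"] = R, _["N"] = N,
                        _["RH"] = RH, _["HP"] = HP);
  }
  return List::create(_["H"] = H);
}

// [[Rcpp::export]]
List gru_backward_cpp(const arma::mat& E, const List& cache,
                      const arma::mat& Uz, const arma::mat& Ur,
                      const arma::mat& Un,
                      const arma::mat& Wz, const arma::mat& Wr,
                      const arma::mat& Wn,
                      const arma::mat& dH_final, int T, int B) {
  const arma::mat& Z = cache["Z"];
  const arma::mat& R = cache["R"];
  const arma::mat& N = cache["N"];
  const arma::mat& RH = cache["RH"];
  const arma::mat& HP = cache["HP"];
  const int h = Uz.n_rows;
  arma::mat DAZ(h, (size_t)T * B), DAR(h, (size_t)T * B),
    DAN(h, (size_t)T * B);
  arma::mat dh = dH_final;
  for (int t = T - 1; t >= 0; --t) {
    arma::mat z(h, B), r(h, B), n(h, B), hp(h, B);
    for (int w = 0; w < B; ++w) {
      const size_t c = (size_t)w * T + t;
      z.col(w) = Z.col(c); r.col(w) = R.col(c); n.col(w) = N.col(c);
      hp.col(w) = HP.col(c);
    }
    arma::mat dn = dh % (1.0 - z);
    arma::mat dz = dh % (hp - n);
    arma::mat dh_prev = dh % z;
    arma::mat dan = dn % (1.0 - n % n);
    arma::mat drh = Un.t() * dan;
    arma::mat dr = drh % hp;
    dh_prev += drh % r;
    arma::mat daz = dz % z % (1.0 - z);
    arma::mat dar = dr % r % (1.0 - r);
    dh = dh_prev + Uz.t() * daz + Ur.t() * dar;
    for (int w = 0; w < B; ++w) {
      const size_t c = (size_t)w * T + t;
      DAZ.col(c) = daz.col(w); DAR.col(c) = dar.col(w);
      DAN.col(c) = dan.col(w);
    }
  }
  arma::mat gWz = DAZ * E.t(), gUz = DAZ * HP.t();
  arma::mat gWr = DAR * E.t(), gUr = DAR * HP.t();
  arma::mat gWn = DAN * E.t(), gUn = DAN * RH.t();
  arma::vec gbz = arma::sum(DAZ, 1), gbr = arma::sum(DAR, 1),
    gbn = arma::sum(DAN, 1);
  arma::mat dE = Wz.t() * DAZ + Wr.t() * DAR + Wn.t() * DAN;
  return List::create(
    _["W_z"] = gWz, _["U_z"] = gUz, _["b_z"] = gbz,
    _["W_r"] = gWr, _["U_r"] = gUr, _["b_r"] = gbr,
    _["W_n"] = gWn, _["U_n"] = gUn, _["b_n"] = gbn, _["dE"] = dE);
}

// [[Rcpp::export]]
List lstm_forward_cpp(const arma::mat& E,
                      const arma::mat& Wi, const arma::mat& Ui,
                      const arma::vec& bi,
                      const arma::mat& Wf, const arma::mat& Uf,
                      const arma::vec& bf,
                      const arma::mat& Wo, const arma::mat& Uo,
                      const arma::vec& bo,
                      const arma::mat& Wg, const arma::mat& Ug,
                      const arma::vec& bg,
                      int T, int B, bool keep_cache) {
  const int h = Wi.n_rows;
  arma::mat H(h, B, arma::fill::zeros), C(h, B, arma::fill::zeros);
  arma::mat I_, F_, O_, G_, TC, HP, CP;
  if (keep_cache) {
    const size_t n = (size_t)T * B;
    I_.set_size(h, n); F_.set_size(h, n); O_.set_size(h, n);
    G_.set_size(h, n); TC.set_size(h, n); HP.set_size(h, n);
    CP.set_size(h, n);
  }
  for (int t = 0; t < T; ++t) {
    arma::mat Xt = step_cols(E, T, B, t);
    arma::mat i = 1.0 / (1.0 + arma::exp(-(Wi * Xt + Ui * H +
                                           arma::repmat(bi, 1, B))));
    arma::mat f = 1.0 / (1.0 + arma::exp(-(Wf * Xt + Uf * H +
                                           arma::repmat(bf, 1, B))));
    arma::mat o = 1.0 / (1.0 + arma::exp(-(Wo * Xt + Uo * H +
                                           arma::repmat(bo, 1, B))));
    arma::mat g = arma::tanh(Wg * Xt + Ug * H + arma::repmat(bg, 1, B));
    arma::mat Cn = f % C + i % g;
    arma::mat tc = arma::tanh(Cn);
    if (keep_cache) {
      for (int w = 0; w < B; ++w) {
        const size_t c = (size_t)w * T + t;
        I_.col(c) = i.col(w); F_.col(c) = f.col(w); O_.col(c) = o.col(w);
        G_.col(c) = g.col(w); TC.col(c) = tc.col(w);
        HP.col(c) = H.col(w); CP.col(c) = C.col(w);
      }
    }
    C = Cn;
    H = o % tc;
  }
  if (keep_cache) {
    return List::create(_["H"] = H, _["I"] = I_, _["F"] = F_, _["O"] = O_,
                        _["G"] = G_, _["TC"] = TC, _["HP"] = HP,
                        _["CP"] = CP);
  }
  return List::create(_["H"] = H);
}

// [[Rcpp::export]]
List lstm_backward_cpp(const arma::mat& E, const List& cache,
                       const arma::mat& Ui, const arma::mat& Uf,
                       const arma::mat& Uo, const arma::mat& Ug,
                       const arma::mat& Wi, const arma::mat& Wf,
                       const arma::mat& Wo, const arma::mat& Wg,
                       const arma::mat& dH_final, int T, int B) {
  const arma::mat& I_ = cache["I"];
  const arma::mat& F_ = cache["F"];
  const arma::mat& O_ = cache["O"];
  const arma::mat& G_ = cache["G"];
  const arma::mat& TC = cache["TC"];
  const arma::mat& HP = cache["HP"];
  const arma::mat& CP = cache["CP"];
  const int h = Ui.n_rows;
  const size_t n = (size_t)T * B;
  arma::mat DAI(h, n), DAF(h, n), DAO(h, n), DAG(h, n);
  arma::mat dh = dH_final;
  arma::mat dc(h, B, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::mat i(h, B), f(h, B), o(h, B), g(h, B), tc(h, B), cp(h, B);
    for (int w = 0; w < B; ++w) {
      const size_t c = (size_t)w * T + t;
      i.col(w) = I_.col(c); f.col(w) = F_.col(c); o.col(w) = O_.col(c);
      g.col(w) = G_.col(c); tc.col(w) = TC.col(c); cp.col(w) = CP.col(c);
    }
    arma::mat do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    arma::mat di = dc % g, dg = dc % i, df = dc % cp;
    arma::mat dc_prev = dc % f;
    arma::mat dai = di % i % (1.0 - i);
    arma::mat daf = df % f % (1.0 - f);
    arma::mat dao = do_ % o % (1.0 - o);
    arma::mat dag = dg % (1.0 - g % g);
    dh = Ui.t() * dai + Uf.t() * daf + Uo.t() * dao + Ug.t() * dag;
    for (int w = 0; w < B; ++w) {
      const size_t c = (size_t)w * T + t;
      DAI.col(c) = dai.col(w); DAF.col(c) = daf.col(w);
      DAO.col(c) = dao.col(w); DAG.col(c) = dag.col(w);
    }
    dc = dc_prev;
  }
  arma::mat dE = Wi.t() * DAI + Wf.t() * DAF + Wo.t() * DAO + Wg.t() * DAG;
  return List::create(
    _["W_i"] = DAI * E.t(), _["U_i"] = DAI * HP.t(),
    _["b_i"] = arma::vec(arma::sum(DAI, 1)),
    _["W_f"] = DAF * E.t(), _["U_f"] = DAF * HP.t(),
    _["b_f"] = arma::vec(arma::sum(DAF, 1)),
    _["W_o"] = DAO * E.t(), _["U_o"] = DAO * HP.t(),
    _["b_o"] = arma::vec(arma::sum(DAO, 1)),
    _["W_g"] = DAG * E.t(), _["U_g"] = DAG * HP.t(),
    _["b_g"] = arma::vec(arma::sum(DAG, 1)), _["dE"] = dE);
}
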