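// Batched GRU forward pass and backpropagation through time.
// Sequences are processed as T x B matrices (B sequences of equal
// length T); hidden states are H x B. All state is passed in and out
// explicitly, so the functions are deterministic and thread-free.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// weights: list of layers, each with W_ir,W_iz,W_in (H x D),
// W_hr,W_hz,W_hn (H x H), b_ir,b_iz,b_in,b_hr,b_hz,b_hn (H).
// readout: w_out (H), optional w_res (D0) when residual.
// dropmasks: H x (n_layers-1) matrix of inverted-dropout scale factors
// applied to the output of each non-top layer (all ones when unused).

// [[Rcpp::export]]
Rcpp::List gru_forward_cpp(Rcpp::List layers, const arma::mat& X,
                           const arma::vec& w_out, const arma::vec& w_res,
                           bool residual, const arma::mat& dropmasks,
                           bool keep_cache) {
  const int T = X.n_rows, B = X.n_cols;
  const int L = layers.size();

  Rcpp::List caches(L);
  mat input_t;             // D x B input to current layer at time t
  mat Y(T, B, fill::zeros);

  // per-layer state
  std::vector<mat> h(L);
  std::vector<cube> R(L), Z(L), N(L), M(L), Hc(L);
  std::vector<cube> U(L);  // layer inputs over time (D x B x T)

  std::vector<mat> Wir(L), Wiz(L), Win(L), Whr(L), Whz(L), Whn(L);
  std::vector<vec> bir(L), biz(L), bin(L), bhr(L), bhz(L), bhn(L);
  for (int l = 0; l < L; ++l) {
    Rcpp::List ly = layers[l];
    Wir[l] = Rcpp::as<mat>(ly["W_ir"]); Wiz[l] = Rcpp::as<mat>(ly["W_iz"]);
    Win[l] = Rcpp::as<mat>(ly["W_in"]); Whr[l] = Rcpp::as<mat>(ly["W_hr"]);
    Whz[l] = Rcpp::as<mat>(ly["W_hz"]); Whn[l] = Rcpp::as<mat>(ly["W_hn"]);
    bir[l] = Rcpp::as<vec>(ly["b_ir"]); biz[l] = Rcpp::as<vec>(ly["b_iz"]);
    bin[l] = Rcpp::as<vec>(ly["b_in"]); bhr[l] = Rcpp::as<vec>(ly["b_hr"]);
    bhz[l] = Rcpp::as<vec>(ly["b_hz"]); bhn[l] = Rcpp::as<vec>(ly["b_hn"]);
    const int H = Wir[l].n_rows, D = Wir[l].n_cols;
    h[l] = mat(H, B, fill::zeros);
    R[l].set_size(H, B, T); Z[l].set_size(H, B, T);
    N[l].set_size(H, B, T); M[l].set_size(H, B, T);
    Hc[l].set_size(H, B, T);
    U[l].set_size(D, B, T);
  }

  for (int t = 0; t < T; ++t) {
    input_t = X.row(t);  // 1 x B
    for (int l = 0; l < L; ++l) {
      U[l].slice(t) = input_t;
      mat ar = Wir[l] * input_t + Whr[l] * h[l];
      ar.each_col() += bir[l] + bhr[l];
      mat az = Wiz[l] * input_t + Whz[l] * h[l];
      az.each_col() += biz[l] + bhz[l];
      mat m = Whn[l] * h[l];
      m.each_col() += bhn[l];
      mat r = sigmoid(ar), z = sigmoid(az);
      mat an = Win[l] * input_t + r % m;
      an.each_col() += bin[l];
      mat n = tanh(an);
      h[l] = (1.0 - z) % n + z % h[l];
      R[l].slice(t) = r; Z[l].slice(t) = z; N[l].slice(t) = n;
      M[l].slice(t) = m; Hc[l].slice(t) = h[l];
      input_t = h[l];
      if (l < L - 1) input_t.each_col() %= dropmasks.col(l);
    }
    rowvec y = w_out.t() * h[L - 1];
    if (residual) y += w_res.t() * X.row(t);  // scalar input path
    Y.row(t) = y;
  }

  if (!keep_cache) {
    return Rcpp::List::create(Rcpp::Named("Y") = Y,
                              Rcpp::Named("h_top") = Hc[L - 1]);
  }
  for (int l = 0; l < L; ++l) {
    caches[l] = Rcpp::List::create(
      Rcpp::Named("R") = R[l], Rcpp::Named("Z") = Z[l],
      Rcpp::Named("N") = N[l], Rcpp::Named("M") = M[l],
      Rcpp::Named("H") = Hc[l], Rcpp::Named("U") = U[l]);
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("h_top") = Hc[L - 1],
                            Rcpp::Named("cache") = caches);
}

// [[Rcpp::export]]
Rcpp::List gru_backward_cpp(Rcpp::List layers, Rcpp::List cache,
                            const arma::mat& X, const arma::mat& dY,
                            const arma::vec& w_out, const arma::vec& w_res,
                            bool residual, const arma::mat& dropmasks) {
  const int T = X.n_rows, B = X.n_cols;
  const int L = layers.size();

  std::vector<mat> Wir(L), Wiz(L), Win(L), Whr(L), Whz(L), Whn(L);
  std::vector<cube> R(L), Z(L), N(L), M(L), Hc(L), U(L);
  for (int l = 0; l < L; ++l) {
    Rcpp::List ly = layers[l];
    Wir[l] = Rcpp::as<mat>(ly["W_ir"]); Wiz[l] = Rcpp::as<mat>(ly["W_iz"]);
    Win[l] = Rcpp::as<mat>(ly["W_in"]); Whr[l] = Rcpp::as<mat>(ly["W_hr"]);
    Whz[l] = Rcpp::as<mat>(ly["W_hz"]); Whn[l] = Rcpp::as<mat>(ly["W_hn"]);
    Rcpp::List cl = cache[l];
    R[l] = Rcpp::as<cube>(cl["R"]); Z[l] = Rcpp::as<cube>(cl["Z"]);
    N[l] = Rcpp::as<cube>(cl["N"]); M[l] = Rcpp::as<cube>(cl["M"]);
    Hc[l] = Rcpp::as<cube>(cl["H"]); U[l] = Rcpp::as<cube>(cl["U"]);
  }

  vec dw_out(w_out.n_elem, fill::zeros);
  vec dw_res(w_res.n_elem, fill::zeros);

  // dOut[l]: gradient wrt layer l's output h_t (H x B x T)
  std::vector<cube> dOut(L);
  {
    const int Htop = Wir[L - 1].n_rows;
    dOut[L - 1].set_size(Htop, B, T);
    for (int t = 0; t < T; ++t) {
      dOut[L - 1].slice(t) = w_out * dY.row(t);  // H x 1 times 1 x B
      dw_out += Hc[L - 1].slice(t) * dY.row(t).t();
      if (residual) dw_res += X.row(t) * dY.row(t).t();
    }
  }

  Rcpp::List grads(L);
  for (int l = L - 1; l >= 0; --l) {
    const int H = Wir[l].n_rows, D = Wir[l].n_cols;
    mat dWir(H, D, fill::zeros), dWiz(H, D, fill::zeros),
        dWin(H, D, fill::zeros);
    mat dWhr(H, H, fill::zeros), dWhz(H, H, fill::zeros),
        dWhn(H, H, fill::zeros);
    vec dbir(H, fill::zeros), dbiz(H, fill::zeros), dbin(H, fill::zeros);
    vec dbhr(H, fill::zeros), dbhz(H, fill::zeros), dbhn(H, fill::zeros);
    cube dU(D, B, T, fill::zeros);
    mat dh_carry(H, B, fill::zeros);

    for (int t = T - 1; t >= 0; --t) {
      mat dh = dOut[l].slice(t) + dh_carry;
      mat h_prev = (t > 0) ? mat(Hc[l].slice(t - 1)) : mat(H, B, fill::zeros);
      const mat& r = R[l].slice(t); const mat& z = Z[l].slice(t);
      const mat& n = N[l].slice(t); const mat& m = M[l].slice(t);
      mat dz = dh % (h_prev - n);
      mat dn = dh % (1.0 - z);
      mat dan = dn % (1.0 - n % n);
      mat dr = dan % m;
      mat dm = dan % r;
      mat dar = dr % r % (1.0 - r);
      mat daz = dz % z % (1.0 - z);
      const mat& u = U[l].slice(t);

      dWin += dan * u.t(); dbin += sum(dan, 1);
      dWhn += dm * h_prev.t(); dbhn += sum(dm, 1);
      dWiz += daz * u.t(); dbiz += sum(daz, 1);
      dWhz += daz * h_prev.t(); dbhz += sum(daz, 1);
      dWir += dar * u.t(); dbir += sum(dar, 1);
      dWhr += dar * h_prev.t(); dbhr += sum(dar, 1);

      dh_carry = dh % z + Whn[l].t() * dm + Whz[l].t() * daz +
                 Whr[l].t() * dar;
      dU.slice(t) = Win[l].t() * dan + Wiz[l].t() * daz + Wir[l].t() * dar;
    }

    grads[l] = Rcpp::List::create(
      Rcpp::Named("W_ir") = dWir, Rcpp::Named("W_iz") = dWiz,
      Rcpp::Named("W_in") = dWin, Rcpp::Named("W_hr") = dWhr,
      Rcpp::Named("W_hz") = dWhz, Rcpp::Named("W_hn") = dWhn,
      Rcpp::Named("b_ir") = dbir, Rcpp::Named("b_iz") = dbiz,
      Rcpp::Named("b_in") = dbin, Rcpp::Named("b_hr") = dbhr,
      Rcpp::Named("b_hz") = dbhz, Rcpp::Named("b_hn") = dbhn);

    if (l > 0) {
      dOut[l - 1] = dU;
      for (int t = 0; t < T; ++t) {
        dOut[l - 1].slice(t).each_col() %= dropmasks.col(l - 1);
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("layers") = grads,
                            Rcpp::Named("w_out") = dw_out,
                            Rcpp::Named("w_res") = dw_res);
}
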