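// Hot numerical kernels: the LSTM recurrence (forward and
// backpropagation-through-time) and the 1-D convolution (im2col +
// GEMM) used by the multi-scale pyramid. Layouts match the R side:
// batch-first matrices, time-second cubes [B, L, C].

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat sigm(mat x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export(name = ".lstmForwardCpp")]]
Rcpp::List lstmForwardCpp(const arma::mat& Xh,
                          const arma::rowvec& Wf, const arma::rowvec& Wi,
                          const arma::rowvec& Wo, const arma::rowvec& Wc,
                          const arma::mat& Uf, const arma::mat& Ui,
                          const arma::mat& Uo, const arma::mat& Uc,
                          const arma::rowvec& bf, const arma::rowvec& bi,
                          const arma::rowvec& bo, const arma::rowvec& bc,
                          bool candTanh, bool cache) {
  const uword B = Xh.n_rows, W = Xh.n_cols, d = Uf.n_rows;
  mat h(B, d, fill::zeros), c(B, d, fill::zeros);
  cube F, I, O, G, C, Hprev;
  if (cache) {
    F.set_size(B, d, W); I.set_size(B, d, W); O.set_size(B, d, W);
    G.set_size(B, d, W); C.set_size(B, d, W); Hprev.set_size(B, d, W);
  }
  for (uword t = 0; t < W; ++t) {
    const vec x = Xh.col(t);
    mat f = x * Wf + h * Uf; f.each_row() += bf; f = sigm(f);
    mat i = x * Wi + h * Ui; i.each_row() += bi; i = sigm(i);
    mat o = x * Wo + h * Uo; o.each_row() += bo; o = sigm(o);
    mat g = x * Wc + h * Uc; g.each_row() += bc;
    g = candTanh ? mat(tanh(g)) : sigm(g);
    if (cache) Hprev.slice(t) = h;
    c = f % c + i % g;
    h = o % tanh(c);
    if (cache) {
      F.slice(t) = f; I.slice(t) = i; O.slice(t) = o;
      G.slice(t) = g; C.slice(t) = c;
    }
  }
  if (!cache) return Rcpp::List::create(Rcpp::Named("h") = h);
  return Rcpp::List::create(
      Rcpp::Named("h") = h, Rcpp::Named("f") = F, Rcpp::Named("i") = I,
      Rcpp::Named("o") = O, Rcpp::Named("g") = G, Rcpp::Named("c") = C,
      Rcpp::Named("hprev") = Hprev);
}

// [[Rcpp::export(name = ".lstmBackwardCpp")]]
Rcpp::List lstmBackwardCpp(const arma::mat& Xh, const arma::mat& dh,
                           const arma::cube& F, const arma::cube& I,
                           const arma::cube& O, const arma::cube& G,
                           const arma::cube& C, const arma::cube& Hprev,
                           const arma::mat& Uf, const arma::mat& Ui,
                           const arma::mat& Uo, const arma::mat& Uc,
                           bool candTanh) {
  const uword B = Xh.n_rows, W = Xh.n_cols, d = Uf.n_rows;
  rowvec gWf(d, fill::zeros), gWi(d, fill::zeros), gWo(d, fill::zeros),
      gWc(d, fill::zeros);
  mat gUf(d, d, fill::zeros), gUi(d, d, fill::zeros),
      gUo(d, d, fill::zeros), gUc(d, d, fill::zeros);
  rowvec gbf(d, fill::zeros), gbi(d, fill::zeros), gbo(d, fill::zeros),
      gbc(d, fill::zeros);
  mat dhCur = dh, dcNext(B, d, fill::zeros);
  for (uword tt = W; tt-- > 0;) {
    const mat& f = F.slice(tt);
    const mat& i = I.slice(tt);
    const mat& o = O.slice(tt);
    const mat& g = G.slice(tt);
    const mat tc = tanh(C.slice(tt));
    const mat cprev = (tt > 0) ? C.slice(tt - 1)
                               : mat(B, d, fill::zeros);
    mat dO = dhCur % tc;
    mat dC = dcNext + dhCur % o % (1.0 - tc % tc);
    mat dPreF = (dC % cprev) % f % (1.0 - f);
    mat dPreI = (dC % g) % i % (1.0 - i);
    mat dPreO = dO % o % (1.0 - o);
    mat dPreG = candTanh ? mat((dC % i) % (1.0 - g % g))
                         : mat((dC % i) % g % (1.0 - g));
    const rowvec xt = Xh.col(tt).t();
    gWf += xt * dPreF; gWi += xt * dPreI;
    gWo += xt * dPreO; gWc += xt * dPreG;
    const mat& hp = Hprev.slice(tt);
    gUf += hp.t() * dPreF; gUi += hp.t() * dPreI;
    gUo += hp.t() * dPreO; gUc += hp.t() * dPreG;
    gbf += sum(dPreF, 0); gbi += sum(dPreI, 0);
    gbo += sum(dPreO, 0); gbc += sum(dPreG, 0);
    dhCur = dPreF * Uf.t() + dPreI * Ui.t() + dPreO * Uo.t() +
            dPreG * Uc.t();
    dcNext = dC % f;
  }
  return Rcpp::List::create(
      Rcpp::Named("Wf") = gWf, Rcpp::Named("Wi") = gWi,
      Rcpp::Named("Wo") = gWo, Rcpp::Named("Wc") = gWc,
      Rcpp::Named("Uf") = gUf, Rcpp::Named("Ui") = gUi,
      Rcpp::Named("Uo") = gUo, Rcpp::Named("Uc") = gUc,
      Rcpp::Named("bf") = gbf, Rcpp::Named("bi") = gbi,
      Rcpp::Named("bo") = gbo, Rcpp::Named("bc") = gbc);
}

// im2col for [B, L, C] cubes: column (i*ks + j) holds Z[, j + l, i]
static mat im2col(const cube& Z, uword ks) {
  const uword B = Z.n_rows, L = Z.n_cols, Cin = Z.n_slices;
  const uword Lout = L - ks + 1;
  mat Zcol(B * Lout, ks * Cin);
  for (uword i = 0; i < Cin; ++i)
    for (uword j = 0; j < ks; ++j) {
      const mat& sl = Z.slice(i);
      Zcol.col(i * ks + j) =
          vectorise(sl.cols(j, j + Lout - 1));
    }
  return Zcol;
}

// [[Rcpp::export(name = ".convForwardCpp")]]
Rcpp::List convForwardCpp(const arma::cube& Z, const arma::mat& Kmat,
                          const arma::rowvec& b) {
  const uword B = Z.n_rows, L = Z.n_cols;
  const uword Cout = Kmat.n_cols;
  const uword ks = Kmat.n_rows / Z.n_slices;
  const uword Lout = L - ks + 1;
  mat Zcol = im2col(Z, ks);
  mat outMat = Zcol * Kmat;
  outMat.each_row() += b;
  cube out(outMat.memptr(), B, Lout, Cout);
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("Zcol") = Zcol);
}

// [[Rcpp::export(name = ".convBackwardCpp")]]
Rcpp::List convBackwardCpp(const arma::cube& dOut, const arma::mat& Zcol,
                           const arma::mat& Kmat, int Bdim, int Ldim,
                           int Cdim) {
  const uword B = (uword)Bdim, L = (uword)Ldim, Cin = (uword)Cdim;
  const uword Cout = Kmat.n_cols, ks = Kmat.n_rows / Cin;
  const uword Lout = L - ks + 1;
  mat dOutMat(const_cast<double*>(dOut.memptr()), B * Lout, Cout, false);
  mat dKmat = Zcol.t() * dOutMat;
  rowvec db = sum(dOutMat, 0);
  mat dZcol = dOutMat * Kmat.t();
  cube dZ(B, L, Cin, fill::zeros);
  for (uword i = 0; i < Cin; ++i)
    for (uword j = 0; j < ks; ++j) {
      mat blk(dZcol.colptr(i * ks + j), B, Lout, false);
      dZ.slice(i).cols(j, j + Lout - 1) += blk;
    }
  return Rcpp::List::create(Rcpp::Named("dKmat") = dKmat,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dZ") = dZ);
}

// window-2 stride-2 pooling along time (cube dim 2)
// [[Rcpp::export(name = ".poolForwardCpp")]]
Rcpp::List poolForwardCpp(const arma::cube& A, bool maxPool) {
  const uword B = A.n_rows, L = A.n_cols, C = A.n_slices;
  const uword P = (L + 1) / 2;
  cube out(B, P, C);
  cube first;                       // 1.0 where the first element wins
  if (maxPool) first.set_size(B, P, C);
  for (uword c = 0; c < C; ++c) {
    const mat& sl = A.slice(c);
    for (uword p = 0; p < P; ++p) {
      const uword j1 = 2 * p, j2 = 2 * p + 1;
      if (j2 >= L) {
        out.slice(c).col(p) = sl.col(j1);
        if (maxPool) first.slice(c).col(p).ones();
      } else if (maxPool) {
        for (uword b = 0; b < B; ++b) {
          const double a1 = sl(b, j1), a2 = sl(b, j2);
          out(b, p, c) = a1 >= a2 ? a1 : a2;
          first(b, p, c) = a1 >= a2 ? 1.0 : 0.0;
        }
      } else {
        out.slice(c).col(p) = 0.5 * (sl.col(j1) + sl.col(j2));
      }
    }
  }
  if (maxPool)
    return Rcpp::List::create(Rcpp::Named("out") = out,
                              Rcpp::Named("first") = first,
                              Rcpp::Named("L") = (int)L);
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("L") = (int)L);
}

// [[Rcpp::export(name = ".poolBackwardCpp")]]
arma::cube poolBackwardCpp(const arma::cube& dOut,
                           Rcpp::Nullable<Rcpp::NumericVector> firstR,
                           int Ldim, bool maxPool) {
  const uword B = dOut.n_rows, P = dOut.n_cols, C = dOut.n_slices;
  const uword L = (uword)Ldim;
  cube dA(B, L, C, fill::zeros);
  cube first;
  if (maxPool) {
    Rcpp::NumericVector fv(firstR);
    first = cube(fv.begin(), B, P, C);
  }
  for (uword c = 0; c < C; ++c) {
    for (uword p = 0; p < P; ++p) {
      const uword j1 = 2 * p, j2 = 2 * p + 1;
      if (j2 >= L) {
        dA.slice(c).col(j1) += dOut.slice(c).col(p);
      } else if (maxPool) {
        for (uword b = 0; b < B; ++b) {
          if (first(b, p, c) > 0.5)
            dA(b, j1, c) += dOut(b, p, c);
          else
            dA(b, j2, c) += dOut(b, p, c);
        }
      } else {
        dA.slice(c).col(j1) += 0.5 * dOut.slice(c).col(p);
        dA.slice(c).col(j2) += 0.5 * dOut.slice(c).col(p);
      }
    }
  }
  return dA;
}
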