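// Six-layer TSK fuzzy neural network: batch forward pass, analytic
// gradients of the half squared error, and the per-sample gradient
// descent loop with momentum and a bold-driver learning rate.
//
// Shapes: X (N x m), C/S/A (m x r: centres, widths, consequent
// coefficients), b (r), W (r x n mixing weights), targets T (N x n).
// Firing strengths are handled in log space and normalised with a
// softmax so that high-dimensional inputs cannot underflow the
// normaliser of the output layer.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// N x r matrix of log firing strengths, log mu_j = -sum_i ((x_i-c_ij)/s_ij)^2
static mat log_firing(const mat& X, const mat& C, const mat& S) {
  const uword r = C.n_cols;
  mat L(X.n_rows, r);
  for (uword j = 0; j < r; ++j) {
    mat D = X.each_row() - C.col(j).t();
    D.each_row() /= S.col(j).t();
    L.col(j) = -sum(square(D), 1);
  }
  return L;
}

// min t-norm variant: log mu_j = min_i of the per-input log memberships
static mat log_firing_min(const mat& X, const mat& C, const mat& S) {
  const uword r = C.n_cols;
  mat L(X.n_rows, r);
  for (uword j = 0; j < r; ++j) {
    mat D = X.each_row() - C.col(j).t();
    D.each_row() /= S.col(j).t();
    L.col(j) = -max(square(D), 1);
  }
  return L;
}

// row-wise softmax: nu_j = mu_j / sum_j mu_j, computed stably
static mat row_softmax(mat L) {
  L.each_col() -= max(L, 1);
  mat E = exp(L);
  E.each_col() /= sum(E, 1);
  return E;
}

// [[Rcpp::export]]
arma::mat fnn_forward_cpp(const arma::mat& X, const arma::mat& C,
                          const arma::mat& S, const arma::mat& A,
                          const arma::vec& b, const arma::mat& W,
                          const int tnorm_min) {
  mat L = tnorm_min ? log_firing_min(X, C, S) : log_firing(X, C, S);
  mat NU = row_softmax(L);
  mat Y = X * A;              // N x r
  Y.each_row() += b.t();
  return (NU % Y) * W;        // N x n
}

struct Grads { mat gW, gA, gC, gS; vec gb, u; };

// analytic gradients of E = 0.5 * sum_k (t_k - u_k)^2 for one sample,
// product t-norm
static Grads sample_grads(const vec& x, const vec& t, const mat& C,
                          const mat& S, const mat& A, const vec& b,
                          const mat& W) {
  mat XC = repmat(x, 1, C.n_cols) - C;          // m x r
  vec lmu = -sum(square(XC / S), 0).t();        // r
  vec nu = exp(lmu - lmu.max());
  nu /= accu(nu);
  vec y = A.t() * x + b;                        // r
  vec u = W.t() * (nu % y);                     // n
  vec e = u - t;                                // dE/du
  vec s = W * e;                                // r
  Grads g;
  g.u = u;
  g.gW = (nu % y) * e.t();                      // r x n
  g.gA = x * (s % nu).t();                      // m x r
  g.gb = s % nu;
  vec d = (y % s - dot(e, u)) % nu;             // r
  mat gc = 2.0 * (XC / square(S));
  gc.each_row() %= d.t();
  g.gC = gc;
  mat gs = 2.0 * (square(XC) / pow(S, 3));
  gs.each_row() %= d.t();
  g.gS = gs;
  return g;
}

// [[Rcpp::export]]
List fnn_gradients_cpp(const arma::vec& x, const arma::vec& t,
                       const arma::mat& C, const arma::mat& S,
                       const arma::mat& A, const arma::vec& b,
                       const arma::mat& W) {
  Grads g = sample_grads(x, t, C, S, A, b, W);
  return List::create(Named("w") = g.gW, Named("a") = g.gA,
                      Named("b") = g.gb, Named("centers") = g.gC,
                      Named("widths") = g.gS, Named("u") = g.u);
}

static double rmse_of(const mat& U, const mat& T) {
  return std::sqrt(accu(square(U - T)) / (double)(T.n_rows * T.n_cols));
}

// [[Rcpp::export]]
List fnn_train_cpp(const arma::mat& X, const arma::mat& T,
                   const arma::mat& Xev, const arma::mat& Tev,
                   arma::mat C, arma::mat S, arma::mat A, arma::vec b,
                   arma::mat W, const arma::imat& order, double gamma,
                   double lambda, double lr_up, double lr_down,
                   double width_floor, const bool batch) {
  const uword epochs = order.n_rows, N = X.n_rows;
  const bool has_eval = Xev.n_rows > 0;
  mat dC(size(C), fill::zeros), dS(size(S), fill::zeros),
      dA(size(A), fill::zeros), dW(size(W), fill::zeros);
  vec db(b.n_elem, fill::zeros);
  vec tr_rmse(epochs), ev_rmse(epochs), lr(epochs);
  double prev = rmse_of(fnn_forward_cpp(X, C, S, A, b, W, 0), T);
  if (!std::isfinite(prev))
    Rcpp::stop("training aborted: non-finite loss at epoch 0");
  double prev_ev = has_eval
    ? rmse_of(fnn_forward_cpp(Xev, C, S, A, b, W, 0), Tev) : NA_REAL;

  for (uword ep = 0; ep < epochs; ++ep) {
    // bold driver with epoch rollback: keep a restore point so a
    // worsening (or overflowing) epoch can be rejected outright
    mat bC = C, bS = S, bA = A, bW = W;
    vec bb = b;
    if (batch) {
      mat aC(size(C), fill::zeros), aS(size(S), fill::zeros),
          aA(size(A), fill::zeros), aW(size(W), fill::zeros);
      vec ab(b.n_elem, fill::zeros);
      for (uword i = 0; i < N; ++i) {
        Grads g = sample_grads(X.row(i).t(), T.row(i).t(), C, S, A, b, W);
        aC += g.gC; aS += g.gS; aA += g.gA; aW += g.gW; ab += g.gb;
      }
      const double inv = 1.0 / (double)N;   // mean gradient per epoch
      mat nC = C - gamma * inv * aC + lambda * dC;
      mat nS = clamp(S - gamma * inv * aS + lambda * dS,
                     width_floor, datum::inf);
      mat nA = A - gamma * inv * aA + lambda * dA;
      mat nW = W - gamma * inv * aW + lambda * dW;
      vec nb = b - gamma * inv * ab + lambda * db;
      dC = nC - C; dS = nS - S; dA = nA - A; dW = nW - W; db = nb - b;
      C = nC; S = nS; A = nA; W = nW; b = nb;
    } else {
      for (uword i = 0; i < N; ++i) {
        uword idx = (uword)order(ep, i) - 1;  // 1-based from R
        Grads g = sample_grads(X.row(idx).t(), T.row(idx).t(),
                               C, S, A, b, W);
        mat nC = C - gamma * g.gC + lambda * dC;
        mat nS = clamp(S - gamma * g.gS + lambda * dS,
                       width_floor, datum::inf);
        mat nA = A - gamma * g.gA + lambda * dA;
        mat nW = W - gamma * g.gW + lambda * dW;
        vec nb = b - gamma * g.gb + lambda * db;
        dC = nC - C; dS = nS - S; dA = nA - A; dW = nW - W; db = nb - b;
        C = nC; S = nS; A = nA; W = nW; b = nb;
      }
    }
    double tr = C.is_finite() && S.is_finite() && A.is_finite() &&
                b.is_finite() && W.is_finite()
      ? rmse_of(fnn_forward_cpp(X, C, S, A, b, W, 0), T)
      : datum::inf;
    lr(ep) = gamma;
    if (std::isfinite(tr) && tr <= prev + 1e-12) {   // accept the epoch
      prev = tr;
      if (has_eval)
        prev_ev = rmse_of(fnn_forward_cpp(Xev, C, S, A, b, W, 0), Tev);
      gamma *= lr_up;
    } else {                                  // reject: restore and shrink
      C = bC; S = bS; A = bA; W = bW; b = bb;
      dC.zeros(); dS.zeros(); dA.zeros(); dW.zeros(); db.zeros();
      gamma *= lr_down;
    }
    tr_rmse(ep) = prev;                       // RMSE of the retained model
    ev_rmse(ep) = prev_ev;
    if (gamma < 1e-12) {                      // every step rejected: converged
      for (uword e2 = ep + 1; e2 < epochs; ++e2) {
        tr_rmse(e2) = prev; ev_rmse(e2) = prev_ev; lr(e2) = gamma;
      }
      break;
    }
    if (ep % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    Named("centers") = C, Named("widths") = S, Named("a") = A,
    Named("b") = b, Named("w") = W, Named("train_rmse") = tr_rmse,
    Named("eval_rmse") = ev_rmse, Named("lr") = lr);
}
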