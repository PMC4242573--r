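// Likelihood engine for the FMutSel family of mutation-selection codon
// substitution models on a pairwise alignment.  The generator is reversible
// with respect to pi_j ~ pi*_{j1} pi*_{j2} pi*_{j3} exp(F_j), so the
// transition matrix is computed through the symmetrized eigendecomposition
// D^{1/2} Q D^{-1/2}.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// h(S) = S / (1 - exp(-S)), the relative fixation factor; h(0) = 1
static inline double hfix(double S) {
  if (std::fabs(S) < 1e-10) return 1.0 + S / 2.0;
  return S / (1.0 - std::exp(-S));
}

// nbr: one row per ordered single-nucleotide codon pair, columns
// (from, to, target_base, is_transition), all 0-based
static arma::mat build_Q(double kappa, const arma::vec& pi_star,
                         const arma::vec& F, const arma::imat& nbr) {
  const int n = F.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (arma::uword r = 0; r < nbr.n_rows; ++r) {
    const int a = nbr(r, 0), b = nbr(r, 1);
    const int tb = nbr(r, 2), ts = nbr(r, 3);
    const double mu = (ts ? kappa : 1.0) * pi_star(tb);
    Q(a, b) = mu * hfix(F(b) - F(a));
  }
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

static arma::vec stationary(const arma::vec& pi_star, const arma::vec& F,
                            const arma::imat& base_idx) {
  const int n = F.n_elem;
  arma::vec pi(n);
  for (int j = 0; j < n; ++j) {
    pi(j) = pi_star(base_idx(j, 0)) * pi_star(base_idx(j, 1)) *
            pi_star(base_idx(j, 2)) * std::exp(F(j));
  }
  return pi / arma::accu(pi);
}

static arma::mat transition(double kappa, const arma::vec& pi_star,
                            const arma::vec& F, double t,
                            const arma::imat& nbr,
                            const arma::imat& base_idx, arma::vec& pi) {
  pi = stationary(pi_star, F, base_idx);
  arma::mat Q = build_Q(kappa, pi_star, F, nbr);
  arma::vec sq = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= sq;        // B_ij = sqrt(pi_i) q_ij / sqrt(pi_j)
  B.each_row() /= sq.t();
  B = 0.5 * (B + B.t());     // enforce exact symmetry
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, B);
  arma::mat P = evec * arma::diagmat(arma::exp(eval * t)) * evec.t();
  P.each_col() /= sq;
  P.each_row() %= sq.t();
  return P;
}

// [[Rcpp::export]]
arma::mat cm_rate_matrix(double kappa, const arma::vec& pi_star,
                         const arma::vec& F, const arma::imat& nbr) {
  return build_Q(kappa, pi_star, F, nbr);
}

// [[Rcpp::export]]
arma::vec cm_stationary(const arma::vec& pi_star, const arma::vec& F,
                        const arma::imat& base_idx) {
  return stationary(pi_star, F, base_idx);
}

// [[Rcpp::export]]
arma::mat cm_transition_matrix(double kappa, const arma::vec& pi_star,
                               const arma::vec& F, double t,
                               const arma::imat& nbr,
                               const arma::imat& base_idx) {
  arma::vec pi;
  return transition(kappa, pi_star, F, t, nbr, base_idx, pi);
}

// log-likelihood of a 61x61 codon-pair count matrix N under the model:
// sum_ij N_ij log( pi_i P_ij(t) )
// [[Rcpp::export]]
double cm_loglik(const arma::mat& N, double kappa, const arma::vec& pi_star,
                 const arma::vec& F, double t, const arma::imat& nbr,
                 const arma::imat& base_idx) {
  arma::vec pi;
  arma::mat P = transition(kappa, pi_star, F, t, nbr, base_idx, pi);
  double ll = 0.0;
  for (arma::uword i = 0; i < N.n_rows; ++i) {
    for (arma::uword j = 0; j < N.n_cols; ++j) {
      if (N(i, j) > 0.0) {
        double pij = std::max(P(i, j), 1e-300);
        ll += N(i, j) * (std::log(pi(i)) + std::log(pij));
      }
    }
  }
  return ll;
}

// derivative of the fixation factor: h'(S)
static inline double hfix_d(double S) {
  if (std::fabs(S) < 1e-6) return 0.5 + S / 12.0;  // series about 0
  const double em = std::exp(-S);
  const double den = 1.0 - em;
  return (den - S * em) / (den * den);
}

// Log-likelihood and its analytic gradient with respect to the natural
// parameters (kappa, pi*_A..pi*_T, t, F_1..F_61), via the spectral
// (Daleckii-Krein) derivative of exp(Bt) for the symmetrized generator.
// The softmax / log reparameterizations are chained in R.
// [[Rcpp::export]]
List cm_loglik_grad(const arma::mat& N, double kappa,
                    const arma::vec& pi_star, const arma::vec& F, double t,
                    const arma::imat& nbr, const arma::imat& base_idx) {
  const int n = F.n_elem;
  arma::vec pi = stationary(pi_star, F, base_idx);
  arma::mat Q = build_Q(kappa, pi_star, F, nbr);
  arma::vec sq = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= sq;
  B.each_row() /= sq.t();
  B = 0.5 * (B + B.t());
  arma::vec eval;
  arma::mat V;
  arma::eig_sym(eval, V, B);
  arma::vec elt = arma::exp(eval * t);
  arma::mat E = V * arma::diagmat(elt) * V.t();
  arma::mat P = E;
  P.each_col() /= sq;
  P.each_row() %= sq.t();

  double ll = 0.0;
  arma::mat W(n, n, arma::fill::zeros);  // W_ij = N_ij / P_ij where N > 0
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (N(i, j) > 0.0) {
        double pij = std::max(P(i, j), 1e-300);
        ll += N(i, j) * (std::log(pi(i)) + std::log(pij));
        // clamp harder in the adjoint so extreme line-search corners
        // cannot overflow the gradient
        W(i, j) = N(i, j) / std::max(pij, 1e-100);
      }
    }
  }

  // adjoint of E: What = Dh W^T A (Dh = diag(sqrt pi), A = Dh^{-1})
  arma::mat What = W.t();
  What.each_col() %= sq;
  What.each_row() /= sq.t();
  arma::mat A1 = V.t() * What * V;

  // G: divided differences of exp(lambda t)
  arma::mat G(n, n);
  for (int k = 0; k < n; ++k) {
    for (int l = 0; l < n; ++l) {
      double d = eval(k) - eval(l);
      if (std::fabs(d) < 1e-9 * std::max(1.0, std::fabs(eval(k)))) {
        G(k, l) = t * std::exp(0.5 * (eval(k) + eval(l)) * t);
      } else {
        G(k, l) = (elt(k) - elt(l)) / d;
      }
    }
  }
  arma::mat H = A1.t() % G;
  arma::mat U = V * H * V.t();  // <U, dB> = tr(What dE)

  // per-state coefficient of d(log pi_i): the log pi_i data term plus the
  // diagonal scalings of dP (which contract with W to row/column sums of
  // N, since W_ij P_ij = N_ij) and of dB
  arma::mat UB = U % B;
  arma::vec g4 = arma::sum(UB, 1);
  arma::vec g5 = arma::sum(UB, 0).t();
  arma::vec cpi = 0.5 * arma::sum(N, 1) + 0.5 * arma::sum(N, 0).t() +
                  0.5 * g4 - 0.5 * g5;
  const double cpi_tot = arma::accu(cpi);

  // gradient accumulators over natural parameters
  double g_kappa = 0.0, g_t = 0.0;
  arma::vec g_pistar(4, arma::fill::zeros);
  arma::vec g_F(n, arma::fill::zeros);

  // t: tr(What dE/dt) = sum_k A1_kk lambda_k e^{lambda_k t}
  for (int k = 0; k < n; ++k) g_t += A1(k, k) * eval(k) * elt(k);

  // sparse dQ part: <U, Dh dQ A> with the diagonal row-sum correction
  for (arma::uword r = 0; r < nbr.n_rows; ++r) {
    const int a = nbr(r, 0), b = nbr(r, 1);
    const int tb = nbr(r, 2), ts = nbr(r, 3);
    const double mu = (ts ? kappa : 1.0) * pi_star(tb);
    const double S = F(b) - F(a);
    const double h = hfix(S), hd = hfix_d(S);
    const double q = mu * h;
    const double coef = U(a, b) * sq(a) / sq(b) - U(a, a);
    if (ts) g_kappa += coef * q / kappa;
    g_pistar(tb) += coef * q / pi_star(tb);
    g_F(b) += coef * mu * hd;
    g_F(a) -= coef * mu * hd;
  }

  // d(log pi) parts: for F_c, dlogpi_i = delta_ic - pi_c;
  // for pi*_m, dlogpi_i = (n_im - nbar_m)/pi*_m
  g_F += cpi - cpi_tot * pi;
  arma::mat ncount(n, 4, arma::fill::zeros);
  for (int j = 0; j < n; ++j) {
    for (int p = 0; p < 3; ++p) ncount(j, base_idx(j, p)) += 1.0;
  }
  arma::rowvec nbar = pi.t() * ncount;
  for (int m = 0; m < 4; ++m) {
    g_pistar(m) += arma::dot(cpi, ncount.col(m) - nbar(m)) / pi_star(m);
  }

  return List::create(_["value"] = ll, _["g_kappa"] = g_kappa,
                      _["g_pistar"] = g_pistar, _["g_t"] = g_t,
                      _["g_F"] = g_F);
}
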