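// Core numerics for photon-by-photon likelihoods and Viterbi decoding.
//
// The likelihood of one trajectory is
//   L = v_fin^T prod_{i=2}^{N} [ F(c_i) exp(K tau_i) ] F(c_1) v_ini
// with F(acceptor) = diag(E), F(donor) = I - diag(E).  exp(K tau) is applied
// through the eigendecomposition K = U diag(lambda) U^{-1}; the propagated
// vector is renormalized to unit sum after every photon and the log norms are
// accumulated, so trajectories with >1e6 photons do not underflow.
//
// All rate matrices used here (two-state binding, optionally Kronecker-summed
// with a two-state blinking chain, and the birth-death transient-complex
// chains) have real spectra; a complex code path is kept as a guard for
// near-defective or genuinely complex cases.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

namespace {

struct EigDecomp {
  bool real_ok;            // all eigenvalues/vectors numerically real
  arma::mat U, Uinv;       // real path
  arma::vec lambda;
  arma::cx_mat cU, cUinv;  // complex fallback
  arma::cx_vec clambda;
  bool valid;
};

EigDecomp decompose(const arma::mat& K) {
  EigDecomp d;
  d.valid = false;
  arma::cx_vec eval;
  arma::cx_mat evec;
  if (!arma::eig_gen(eval, evec, K)) return d;
  double scale = arma::abs(eval).max();
  if (scale == 0.0) scale = 1.0;
  double imag_max = arma::abs(arma::imag(eval)).max();
  double vimag_max = arma::abs(arma::imag(evec)).max();
  d.valid = true;
  if (imag_max < 1e-9 * scale && vimag_max < 1e-9) {
    arma::mat U = arma::real(evec);
    arma::mat Uinv;
    if (arma::inv(Uinv, U) && arma::rcond(U) > 1e-14) {
      d.real_ok = true;
      d.U = U;
      d.Uinv = Uinv;
      d.lambda = arma::real(eval);
      return d;
    }
  }
  d.real_ok = false;
  d.cU = evec;
  if (!arma::inv(d.cUinv, evec)) d.valid = false;
  d.clambda = eval;
  return d;
}

// Emission weights per state for one photon color (0 = donor, 1 = acceptor).
inline arma::vec emission(const arma::vec& E, int color) {
  return color == 1 ? E : arma::vec(1.0 - E);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".photon_loglik_cpp")]]
double photon_loglik_cpp(const arma::vec& tau, const arma::ivec& colors,
                         const arma::mat& K, const arma::vec& E,
                         const arma::vec& v_ini, const arma::vec& v_fin) {
  const arma::uword N = colors.n_elem;
  if (N == 0) return 0.0;
  if (tau.n_elem != N - 1) stop("tau must have length(colors) - 1 elements");
  const arma::uword n = K.n_rows;
  if (E.n_elem != n || v_ini.n_elem != n || v_fin.n_elem != n)
    stop("model dimension mismatch");

  double loglik = 0.0;
  arma::vec v = emission(E, colors[0]) % v_ini;
  double s = arma::accu(v);
  if (!(s > 0.0)) return R_NegInf;
  v /= s;
  loglik += std::log(s);

  if (N > 1) {
    EigDecomp d = decompose(K);
    if (!d.valid) stop("rate matrix eigendecomposition failed");
    if (d.real_ok) {
      arma::vec w(n);
      for (arma::uword i = 1; i < N; ++i) {
        w = d.Uinv * v;
        w %= arma::exp(d.lambda * tau[i - 1]);
        v = d.U * w;
        v %= emission(E, colors[i]);
        s = arma::accu(v);
        if (!(s > 0.0)) return R_NegInf;
        v /= s;
        loglik += std::log(s);
      }
    } else {
      arma::cx_vec cv = arma::conv_to<arma::cx_vec>::from(v);
      arma::cx_vec cw(n);
      for (arma::uword i = 1; i < N; ++i) {
        cw = d.cUinv * cv;
        cw %= arma::exp(d.clambda * tau[i - 1]);
        cv = d.cU * cw;
        arma::vec em = emission(E, colors[i]);
        cv %= arma::conv_to<arma::cx_vec>::from(em);
        s = arma::accu(arma::real(cv));
        if (!(s > 0.0)) return R_NegInf;
        cv /= s;
        loglik += std::log(s);
      }
      v = arma::real(cv);
    }
  }

  double fin = arma::dot(v_fin, v);
  if (!(fin > 0.0)) return R_NegInf;
  return loglik + std::log(fin);
}

//' @noRd
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(const arma::vec& tau, const arma::ivec& colors,
                          const arma::mat& K, const arma::vec& E,
                          const arma::vec& p_eq) {
  const arma::uword N = colors.n_elem;
  const arma::uword n = K.n_rows;
  if (N == 0) return IntegerVector(0);
  if (tau.n_elem != N - 1) stop("tau must have length(colors) - 1 elements");

  EigDecomp d = decompose(K);
  if (!d.valid) stop("rate matrix eigendecomposition failed");

  const double floor_p = 1e-300;
  arma::mat delta(n, N);
  arma::imat psi(n, N, arma::fill::zeros);

  arma::vec em = emission(E, colors[0]);
  for (arma::uword s = 0; s < n; ++s)
    delta(s, 0) = std::log(std::max(p_eq[s] * em[s], floor_p));

  arma::mat A(n, n);
  for (arma::uword i = 1; i < N; ++i) {
    // full propagator exp(K tau_i), clamped at a tiny positive floor
    if (d.real_ok) {
      A = d.U * arma::diagmat(arma::exp(d.lambda * tau[i - 1])) * d.Uinv;
    } else {
      arma::cx_mat cA =
          d.cU * arma::diagmat(arma::exp(d.clambda * tau[i - 1])) * d.cUinv;
      A = arma::real(cA);
    }
    em = emission(E, colors[i]);
    for (arma::uword s = 0; s < n; ++s) {
      double best = -arma::datum::inf;
      arma::uword arg = 0;
      for (arma::uword sp = 0; sp < n; ++sp) {
        double cand =
            delta(sp, i - 1) + std::log(std::max(A(s, sp), floor_p));
        if (cand > best) {  // strict: ties resolve to the lower prior index
          best = cand;
          arg = sp;
        }
      }
      delta(s, i) = best + std::log(std::max(em[s], floor_p));
      psi(s, i) = static_cast<int>(arg);
    }
  }

  IntegerVector path(N);
  arma::uword last = 0;
  double best = delta(0, N - 1);
  for (arma::uword s = 1; s < n; ++s)
    if (delta(s, N - 1) > best) {  // ties toward lower index
      best = delta(s, N - 1);
      last = s;
    }
  path[N - 1] = static_cast<int>(last) + 1;
  for (arma::uword i = N - 1; i >= 1; --i) {
    last = static_cast<arma::uword>(psi(last, i));
    path[i - 1] = static_cast<int>(last) + 1;
  }
  return path;
}
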