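#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Exact propagation of the linear compartment system
//   dx/dt = A x + u(t)
// where u(t) is piecewise constant: during an infusion window the dose enters
// the central compartment (state 0) at rate amount/duration; a dose with zero
// duration is an instantaneous bolus added to state 0. Between breakpoints the
// solution is advanced with the matrix exponential of the augmented system
//   d/dt [x; 1] = [[A, u], [0, 0]] [x; 1],
// which is robust to repeated eigenvalues and to zero rate constants.
//
// doses: matrix with columns (start, amount, duration), times in hours.
// times: sorted, non-negative output times.
// Returns a length(times) x n_state matrix of amounts (mg).
// [[Rcpp::export]]
arma::mat solve_amounts_cpp(const arma::mat& A,
                            const arma::mat& doses,
                            const arma::vec& times) {
  const arma::uword n = A.n_rows;
  const arma::uword n_t = times.n_elem;
  arma::mat out(n_t, n, arma::fill::zeros);
  if (n_t == 0) return out;

  const double tol = 1e-12;

  // breakpoints: 0, dose starts, infusion ends, output times
  std::vector<double> bp;
  bp.push_back(0.0);
  for (arma::uword d = 0; d < doses.n_rows; ++d) {
    bp.push_back(doses(d, 0));
    if (doses(d, 2) > 0.0) bp.push_back(doses(d, 0) + doses(d, 2));
  }
  for (arma::uword k = 0; k < n_t; ++k) bp.push_back(times(k));
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end(),
                       [tol](double a, double b) { return std::abs(a - b) < tol; }),
           bp.end());

  arma::vec x(n, arma::fill::zeros);
  arma::mat M(n + 1, n + 1, arma::fill::zeros);
  arma::uword next_out = 0;

  for (std::size_t k = 0; k < bp.size(); ++k) {
    const double t = bp[k];

    // instantaneous boluses at t (applied before recording: the solution is
    // taken right-continuous at a bolus instant)
    for (arma::uword d = 0; d < doses.n_rows; ++d) {
      if (doses(d, 2) <= 0.0 && std::abs(doses(d, 0) - t) < tol) {
        x(0) += doses(d, 1);
      }
    }

    while (next_out < n_t && times(next_out) <= t + tol) {
      out.row(next_out) = x.t();
      ++next_out;
    }
    if (next_out >= n_t) break;
    if (k + 1 == bp.size()) break;

    const double dt = bp[k + 1] - t;
    if (dt <= 0.0) continue;

    // summed input rate from all infusions active on (t, t + dt)
    double rate = 0.0;
    for (arma::uword d = 0; d < doses.n_rows; ++d) {
      if (doses(d, 2) > 0.0 &&
          doses(d, 0) <= t + tol &&
          doses(d, 0) + doses(d, 2) >= bp[k + 1] - tol) {
        rate += doses(d, 1) / doses(d, 2);
      }
    }

    if (rate == 0.0) {
      x = arma::expmat(A * dt) * x;
    } else {
      M.zeros();
      M.submat(0, 0, n - 1, n - 1) = A * dt;
      M(0, n) = rate * dt;
      arma::mat E = arma::expmat(M);
      x = E.submat(0, 0, n - 1, n - 1) * x + E.submat(0, n, n - 1, n);
    }
  }
  return out;
}
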