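#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Discrete-time transition matrix Gamma = exp(dt * Q) of a CTMC generator.
// Q in 1/ms, dt in ms (callers convert from 1/s). Armadillo's expmat uses
// scaling-and-squaring with Pade approximation.
// [[Rcpp::export(name = ".expm_generator")]]
arma::mat expm_generator(const arma::mat& Q, double dt) {
  return arma::expmat(dt * Q);
}

// Scaled forward pass for the grouped-Gaussian HMM likelihood.
//
// The forward vector is propagated through Gamma BEFORE every emission,
// including the first: alpha_t = alpha_{t-1} * Gamma * diag(dens[, t]),
// alpha_0 = delta (stationary row vector). Each step the vector is
// renormalized to sum one and the log of the normalizer accumulated, so the
// returned log-likelihood equals log(delta' (prod_t B_t) 1) without
// underflow.
//
// dens: n_states x T matrix of per-state emission densities.
// [[Rcpp::export(name = ".forward_filter")]]
List forward_filter(const arma::mat& Gamma, const arma::mat& dens,
                    const arma::rowvec& delta, bool keep_filtered = false) {
  const arma::uword T = dens.n_cols;
  const arma::uword n = dens.n_rows;
  std::vector<double> a(delta.begin(), delta.end());
  std::vector<double> b(n);
  double loglik = 0.0;
  arma::vec logscale(T);
  arma::mat filt;
  if (keep_filtered) filt.set_size(n, T);
  const double* G = Gamma.memptr();   // column-major
  const double* D = dens.memptr();
  for (arma::uword t = 0; t < T; ++t) {
    const double* dt_col = D + t * n;
    double s = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      const double* gcol = G + j * n;
      double acc = 0.0;
      for (arma::uword i = 0; i < n; ++i) acc += a[i] * gcol[i];
      acc *= dt_col[j];
      b[j] = acc;
      s += acc;
    }
    if (!std::isfinite(s) || s <= 0.0) {
      return List::create(_["loglik"] = R_NegInf,
                          _["logscale"] = NumericVector(0),
                          _["filtered"] = R_NilValue);
    }
    const double inv = 1.0 / s;
    for (arma::uword j = 0; j < n; ++j) a[j] = b[j] * inv;
    loglik += std::log(s);
    logscale(t) = std::log(s);
    if (keep_filtered)
      filt.col(t) = arma::vec(a.data(), n);
  }
  return List::create(_["loglik"] = loglik,
                      _["logscale"] = logscale,
                      _["filtered"] = keep_filtered ? wrap(filt) : R_NilValue);
}

// Exact CTMC simulation recording only transitions between groups:
// consecutive sojourns within the same group (per `gid`, 1-based) are
// merged on the fly, so memory scales with observable group switches, not
// microscopic jumps (fast intra-group equilibria stay cheap).
// [[Rcpp::export(name = ".sample_ctmc_grouped")]]
List sample_ctmc_grouped(const arma::mat& Q, double duration,
                         const arma::vec& p0, const IntegerVector& gid) {
  RNGScope scope;
  const int n = Q.n_rows;
  double u = unif_rand();
  int s = n - 1;
  double acc = 0.0;
  for (int j = 0; j < n; ++j) {
    acc += p0(j);
    if (u <= acc) { s = j; break; }
  }
  std::vector<int> groups;
  std::vector<double> dwell;
  double t = 0.0;
  int cur_g = gid[s];
  double cur_d = 0.0;
  while (t < duration) {
    const double exit_rate = -Q(s, s);
    double soj;
    bool done = false;
    if (exit_rate <= 0.0) {
      soj = duration - t;
      done = true;
    } else {
      soj = exp_rand() / exit_rate;
      if (t + soj >= duration) { soj = duration - t; done = true; }
    }
    cur_d += soj;
    t += soj;
    if (done) break;
    double u2 = unif_rand() * exit_rate;
    double a2 = 0.0;
    int nxt = -1;
    for (int j = 0; j < n; ++j) {
      if (j == s) continue;
      a2 += Q(s, j);
      if (u2 <= a2) { nxt = j; break; }
    }
    if (nxt < 0) {
      for (int j = n - 1; j >= 0; --j) {
        if (j != s && Q(s, j) > 0.0) { nxt = j; break; }
      }
    }
    s = nxt;
    if (gid[s] != cur_g) {
      groups.push_back(cur_g);
      dwell.push_back(cur_d);
      cur_g = gid[s];
      cur_d = 0.0;
    }
  }
  groups.push_back(cur_g);
  dwell.push_back(cur_d);
  return List::create(_["group"] = wrap(groups),
                      _["dwell_ms"] = wrap(dwell));
}

// Exact stochastic simulation of a CTMC sample path (jump chain +
// exponential sojourns). Q in 1/ms, duration in ms. Uses R's RNG so paths
// are reproducible under set.seed(). Returns 1-based state indices and
// sojourn durations; the final sojourn is truncated at `duration`.
// [[Rcpp::export(name = ".sample_ctmc")]]
List sample_ctmc(const arma::mat& Q, double duration, const arma::vec& p0) {
  RNGScope scope;
  const int n = Q.n_rows;

  // initial state from p0
  double u = unif_rand();
  int s = n - 1;
  double acc = 0.0;
  for (int j = 0; j < n; ++j) {
    acc += p0(j);
    if (u <= acc) { s = j; break; }
  }

  std::vector<int> states;
  std::vector<double> sojourn;
  double t = 0.0;
  while (t < duration) {
    const double exit_rate = -Q(s, s);
    if (exit_rate <= 0.0) {            // absorbing state
      states.push_back(s + 1);
      sojourn.push_back(duration - t);
      break;
    }
    const double dwell = exp_rand() / exit_rate;
    if (t + dwell >= duration) {
      states.push_back(s + 1);
      sojourn.push_back(duration - t);
      break;
    }
    states.push_back(s + 1);
    sojourn.push_back(dwell);
    t += dwell;
    // next state proportional to off-diagonal rates
    double u2 = unif_rand() * exit_rate;
    double a2 = 0.0;
    int nxt = -1;
    for (int j = 0; j < n; ++j) {
      if (j == s) continue;
      a2 += Q(s, j);
      if (u2 <= a2) { nxt = j; break; }
    }
    if (nxt < 0) {                      // guard against roundoff in the sum
      for (int j = n - 1; j >= 0; --j) {
        if (j != s && Q(s, j) > 0.0) { nxt = j; break; }
      }
    }
    s = nxt;
  }
  return List::create(_["state"] = wrap(states),
                      _["sojourn_ms"] = wrap(sojourn));
}
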