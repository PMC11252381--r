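// Core numerical kernels for the z-score event-based model.
// Sequences are passed as parallel vectors: ev_bio (1-based biomarker index
// per event position) and ev_z (threshold value per event position).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void expected_into(arma::mat& M, const int* ev_bio,
                          const double* ev_z, int E, int n_biomarkers,
                          const arma::vec& z_max) {
  // anchors per biomarker: (0,0), waypoint positions, (E, z_max) unless
  // the last waypoint already sits at stage E
  std::vector<double> xs, ys;
  xs.reserve(8); ys.reserve(8);
  for (int b = 1; b <= n_biomarkers; ++b) {
    xs.clear(); ys.clear();
    xs.push_back(0.0); ys.push_back(0.0);
    for (int j = 0; j < E; ++j) {
      if (ev_bio[j] == b) {
        xs.push_back(static_cast<double>(j + 1));
        ys.push_back(ev_z[j]);
      }
    }
    if (xs.back() < E) {
      xs.push_back(static_cast<double>(E));
      ys.push_back(z_max(b - 1));
    }
    int seg = 0;
    const int nseg = static_cast<int>(xs.size()) - 1;
    for (int k = 0; k <= E; ++k) {
      while (seg < nseg - 1 && k > xs[seg + 1]) ++seg;
      const double x0 = xs[seg], x1 = xs[seg + 1];
      const double y0 = ys[seg], y1 = ys[seg + 1];
      M(k, b - 1) = y0 + (y1 - y0) * (static_cast<double>(k) - x0) / (x1 - x0);
    }
  }
}

// Piecewise-linear expected z for every (stage, biomarker) pair.
// [[Rcpp::export]]
arma::mat cpp_expected_matrix(const IntegerVector& ev_bio,
                              const NumericVector& ev_z,
                              int n_biomarkers,
                              const arma::vec& z_max) {
  const int E = ev_bio.size();
  arma::mat M(E + 1, n_biomarkers);
  expected_into(M, ev_bio.begin(), ev_z.begin(), E, n_biomarkers, z_max);
  return M;
}

// Per-subject, per-stage Gaussian log-likelihood:
// L(i,k) = sum_b log Normal(Z(i,b); M(k,b), sigma_b^2)
// [[Rcpp::export]]
arma::mat cpp_stage_loglik(const arma::mat& Z,
                           const arma::mat& M,
                           const arma::vec& sigma) {
  const int B = Z.n_cols;
  arma::rowvec inv_sigma = 1.0 / sigma.t();
  arma::mat Zs = Z.each_row() % inv_sigma;
  arma::mat Ms = M.each_row() % inv_sigma;
  double cst = -0.5 * B * std::log(2.0 * M_PI) - arma::accu(arma::log(sigma));
  arma::vec zz = arma::sum(arma::square(Zs), 1);
  arma::vec mm = arma::sum(arma::square(Ms), 1);
  arma::mat L = Zs * Ms.t();
  L.each_col() += -0.5 * zz;
  L.each_row() += -0.5 * mm.t();
  L += cst;
  return L;
}

// Row-wise log-mean-exp over stages: stage-marginal subject log-likelihood
// under a uniform prior over stages 0..E.
// [[Rcpp::export]]
arma::vec cpp_row_logmeanexp(const arma::mat& L) {
  arma::vec mx = arma::max(L, 1);
  arma::vec out = mx + arma::log(arma::sum(arma::exp(L.each_col() - mx), 1));
  return out - std::log(static_cast<double>(L.n_cols));
}

// Row-wise log-sum-exp (used for mixture likelihoods)
// [[Rcpp::export]]
arma::vec cpp_row_logsumexp(const arma::mat& L) {
  arma::vec mx = arma::max(L, 1);
  return mx + arma::log(arma::sum(arma::exp(L.each_col() - mx), 1));
}

// Shared workspace for repeated marginal-likelihood evaluations against a
// fixed (scaled) data matrix.
struct MarginalEval {
  arma::mat Zs;        // n x B, columns scaled by 1/sigma
  arma::vec zz;        // row sums of Zs^2
  arma::rowvec inv_sigma;
  double cst;
  arma::vec z_max;
  int B, E;
  arma::mat M, Ms, L;  // scratch

  MarginalEval(const arma::mat& Z, const arma::vec& sigma,
               const arma::vec& z_max_, int E_)
      : inv_sigma(1.0 / sigma.t()), z_max(z_max_),
        B(Z.n_cols), E(E_) {
    Zs = Z.each_row() % inv_sigma;
    zz = arma::sum(arma::square(Zs), 1);
    cst = -0.5 * B * std::log(2.0 * M_PI) - arma::accu(arma::log(sigma));
    M.set_size(E + 1, B);
    Ms.set_size(E + 1, B);
    L.set_size(Z.n_rows, E + 1);
  }

  // stage-marginal log-likelihood per subject for the given sequence.
  // The row-wise log-sum-exp skips terms more than 34 log-units below the
  // row maximum (their exp is < 2e-15 of the sum).
  void marginal(const int* ev_bio, const double* ev_z, arma::vec& out) {
    expected_into(M, ev_bio, ev_z, E, B, z_max);
    Ms = M.each_row() % inv_sigma;
    arma::vec mm = arma::sum(arma::square(Ms), 1);
    L = Zs * Ms.t();
    const int n = L.n_rows;
    const int S = E + 1;
    arma::vec mx(n);
    for (int i = 0; i < n; ++i) mx(i) = -arma::datum::inf;
    for (int k = 0; k < S; ++k) {
      const double off = -0.5 * mm(k);
      double* col = L.colptr(k);
      for (int i = 0; i < n; ++i) {
        col[i] += off - 0.5 * zz(i);
        if (col[i] > mx(i)) mx(i) = col[i];
      }
    }
    out.zeros(n);
    for (int k = 0; k < S; ++k) {
      const double* col = L.colptr(k);
      for (int i = 0; i < n; ++i) {
        const double d = col[i] - mx(i);
        if (d > -34.0) out(i) += std::exp(d);
      }
    }
    const double c0 = cst - std::log(static_cast<double>(E + 1));
    for (int i = 0; i < n; ++i) out(i) = mx(i) + std::log(out(i)) + c0;
  }

  double weighted(const int* ev_bio, const double* ev_z,
                  const arma::vec& w, arma::vec& scratch) {
    marginal(ev_bio, ev_z, scratch);
    return arma::dot(w, scratch);
  }
};

// [[Rcpp::export]]
double cpp_weighted_seq_loglik(const arma::mat& Z, const arma::vec& w,
                               const IntegerVector& ev_bio,
                               const NumericVector& ev_z,
                               const arma::vec& z_max,
                               const arma::vec& sigma) {
  MarginalEval ev(Z, sigma, z_max, ev_bio.size());
  arma::vec scratch(Z.n_rows);
  return ev.weighted(ev_bio.begin(), ev_z.begin(), w, scratch);
}

// Greedy coordinate ascent over event positions: repeatedly remove one
// event and reinsert it at the position (among those preserving the
// within-biomarker threshold order) that maximizes the weighted
// stage-marginal log-likelihood. Sweeps until no move improves.
// [[Rcpp::export]]
List cpp_opt_sequence(const arma::mat& Z, const arma::vec& w,
                      const IntegerVector& ev_bio_in,
                      const NumericVector& ev_z_in,
                      const arma::vec& z_max, const arma::vec& sigma,
                      int max_sweeps = 100, double tol = 1e-6) {
  const int E = ev_bio_in.size();
  std::vector<int> bio(ev_bio_in.begin(), ev_bio_in.end());
  std::vector<double> z(ev_z_in.begin(), ev_z_in.end());
  MarginalEval ev(Z, sigma, z_max, E);
  arma::vec scratch(Z.n_rows);
  double cur = ev.weighted(bio.data(), z.data(), w, scratch);
  std::vector<int> cb(E);
  std::vector<double> cz(E);
  std::vector<int> rb(E - 1);
  std::vector<double> rz(E - 1);
  int sweeps = 0;
  bool improved = true;
  while (improved && sweeps < max_sweeps) {
    improved = false;
    ++sweeps;
    for (int e = 0; e < E; ++e) {
      const int b = bio[e];
      const double zval = z[e];
      // remaining list with event e removed
      int t = 0;
      for (int j = 0; j < E; ++j) {
        if (j == e) continue;
        rb[t] = bio[j]; rz[t] = z[j]; ++t;
      }
      int lo = 0, hi = E - 1;
      for (int j = 0; j < E - 1; ++j) {
        if (rb[j] == b) {
          if (rz[j] < zval) lo = j + 1;
          else { hi = j; break; }
        }
      }
      double best = cur;
      int best_pos = -1;
      for (int pos = lo; pos <= hi; ++pos) {
        for (int j = 0; j < pos; ++j) { cb[j] = rb[j]; cz[j] = rz[j]; }
        cb[pos] = b; cz[pos] = zval;
        for (int j = pos; j < E - 1; ++j) {
          cb[j + 1] = rb[j]; cz[j + 1] = rz[j];
        }
        const double ll = ev.weighted(cb.data(), cz.data(), w, scratch);
        if (ll > best + tol) { best = ll; best_pos = pos; }
      }
      if (best_pos >= 0) {
        for (int j = 0; j < best_pos; ++j) { bio[j] = rb[j]; z[j] = rz[j]; }
        bio[best_pos] = b; z[best_pos] = zval;
        for (int j = best_pos; j < E - 1; ++j) {
          bio[j + 1] = rb[j]; z[j + 1] = rz[j];
        }
        cur = best;
        improved = true;
      }
    }
  }
  return List::create(_["ev_bio"] = IntegerVector(bio.begin(), bio.end()),
                      _["ev_z"] = NumericVector(z.begin(), z.end()),
                      _["loglik"] = cur, _["sweeps"] = sweeps);
}

// Metropolis-Hastings over event orderings for a K-subtype mixture.
// State per subtype is an ordering of event ids 1..E (id -> (bio_of, z_of)).
// Each iteration removes one event of one subtype's ordering and reinserts
// it uniformly among the positions preserving within-biomarker threshold
// order; acceptance with min(1, exp(delta loglik)). Uses R's RNG, so runs
// are reproducible under set.seed(). Returns the full archive.
// [[Rcpp::export]]
List cpp_mcmc(const arma::mat& Z, const IntegerMatrix& init_orders,
              const IntegerVector& bio_of, const NumericVector& z_of,
              const arma::vec& fractions, const arma::vec& z_max,
              const arma::vec& sigma, int n_iter) {
  const int K = init_orders.nrow();
  const int E = init_orders.ncol();
  const int n = Z.n_rows;
  MarginalEval ev(Z, sigma, z_max, E);
  arma::vec logf = arma::log(fractions);

  std::vector<std::vector<int>> orders(K, std::vector<int>(E));
  for (int c = 0; c < K; ++c)
    for (int j = 0; j < E; ++j) orders[c][j] = init_orders(c, j);

  std::vector<int> bio(E); std::vector<double> z(E);
  auto decode = [&](const std::vector<int>& ord) {
    for (int j = 0; j < E; ++j) {
      bio[j] = bio_of[ord[j] - 1];
      z[j] = z_of[ord[j] - 1];
    }
  };

  arma::mat margs(n, K);
  arma::vec scratch(n);
  for (int c = 0; c < K; ++c) {
    decode(orders[c]);
    ev.marginal(bio.data(), z.data(), scratch);
    margs.col(c) = scratch;
  }
  auto total_ll = [&](const arma::mat& m) {
    arma::mat lf = m.each_row() + logf.t();
    arma::vec mx = arma::max(lf, 1);
    return arma::accu(mx +
      arma::log(arma::sum(arma::exp(lf.each_col() - mx), 1)));
  };
  double cur = total_ll(margs);

  std::vector<IntegerMatrix> arch;
  for (int c = 0; c < K; ++c) arch.push_back(IntegerMatrix(n_iter, E));
  NumericVector arch_ll(n_iter);
  int n_accept = 0;
  std::vector<int> cand(E);
  GetRNGstate();
  for (int it = 0; it < n_iter; ++it) {
    const int d = (K == 1) ? 0 : static_cast<int>(unif_rand() * K) % K;
    const int e = static_cast<int>(unif_rand() * E) % E;
    const std::vector<int>& ord = orders[d];
    const int id = ord[e];
    const int b = bio_of[id - 1];
    const double zval = z_of[id - 1];
    // valid insertion window in the list with position e removed
    int t = 0;
    int lo = 0, hi = E - 1;
    bool hi_set = false;
    for (int j = 0; j < E; ++j) {
      if (j == e) continue;
      const int jid = ord[j];
      if (bio_of[jid - 1] == b) {
        if (z_of[jid - 1] < zval) lo = t + 1;
        else if (!hi_set && z_of[jid - 1] > zval) { hi = t; hi_set = true; }
      }
      ++t;
    }
    const int span = hi - lo + 1;
    const int pos = lo + (static_cast<int>(unif_rand() * span) % span);
    t = 0;
    for (int j = 0; j < E; ++j) {
      if (j == e) continue;
      if (t == pos) ++t;
      cand[t] = ord[j];
      ++t;
    }
    cand[pos] = id;
    for (int j = 0; j < E; ++j) {
      bio[j] = bio_of[cand[j] - 1];
      z[j] = z_of[cand[j] - 1];
    }
    ev.marginal(bio.data(), z.data(), scratch);
    arma::mat m2 = margs;
    m2.col(d) = scratch;
    const double prop = total_ll(m2);
    if (std::log(unif_rand()) < prop - cur) {
      orders[d] = cand;
      margs = m2;
      cur = prop;
      ++n_accept;
    }
    for (int c = 0; c < K; ++c)
      for (int j = 0; j < E; ++j) arch[c](it, j) = orders[c][j];
    arch_ll[it] = cur;
  }
  PutRNGstate();
  List archL(K);
  for (int c = 0; c < K; ++c) archL[c] = arch[c];
  return List::create(_["ids"] = archL, _["loglik"] = arch_ll,
                      _["n_accept"] = n_accept);
}
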