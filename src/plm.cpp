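#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Conventions shared with the R side:
//  * sequences are 0-based integer codes into the alphabet
//  * h is a q x L matrix (residue x position)
//  * J is the (L*q) x (L*q) block matrix with J[(i*q+a), (j*q+b)] the
//    coupling between residue a at position i and residue b at position j;
//    it is stored symmetrically (both (i,j) and (j,i) blocks) with zero
//    diagonal blocks, so each unordered pair contributes once to the score
//    via 0.5 * sum over ordered pairs.

static inline double block_sum_row(const arma::mat& J, int q,
                                   const arma::ivec& seq, int i, int a) {
  // sum_j J[(i,a),(j, seq_j)]; diagonal block is zero so j == i is harmless
  const int L = seq.n_elem;
  double s = 0.0;
  const int row = i * q + a;
  for (int j = 0; j < L; ++j) s += J(row, j * q + seq[j]);
  return s;
}

// [[Rcpp::export]]
arma::vec cpp_score_sequences(const arma::imat& msa, const arma::mat& h,
                              const arma::mat& J) {
  const int n = msa.n_rows, L = msa.n_cols, q = h.n_rows;
  arma::vec out(n);
  for (int m = 0; m < n; ++m) {
    double s = 0.0, pair = 0.0;
    for (int i = 0; i < L; ++i) {
      const int a = msa(m, i);
      s += h(a, i);
      const int row = i * q + a;
      for (int j = i + 1; j < L; ++j) pair += J(row, j * q + msa(m, j));
    }
    out[m] = s + pair;
  }
  return out;
}

// Negative pseudolikelihood (data term only, weighted mean over sequences)
// and its gradient. Regularization is added on the R side so the exported
// objective matches the documented formula exactly.
// [[Rcpp::export]]
List cpp_plm_obj_grad(const arma::imat& msa, const arma::mat& h,
                      const arma::mat& J, const arma::vec& w,
                      const bool want_grad) {
  const int n = msa.n_rows, L = msa.n_cols, q = h.n_rows;
  const double meff = arma::accu(w);
  double f = 0.0;
  arma::mat gh(q, L, arma::fill::zeros);
  arma::mat gJ;
  if (want_grad) gJ.zeros(L * q, L * q);

  arma::vec logits(q), p(q);
  for (int m = 0; m < n; ++m) {
    const double wm = w[m];
    arma::ivec seq = msa.row(m).t();
    // field + coupling logits for every site, one site at a time
    for (int r = 0; r < L; ++r) {
      for (int a = 0; a < q; ++a)
        logits[a] = h(a, r) + block_sum_row(J, q, seq, r, a);
      const double mx = logits.max();
      p = arma::exp(logits - mx);
      const double Z = arma::accu(p);
      p /= Z;
      f += wm * (std::log(Z) + mx - logits[seq[r]]);
      if (want_grad) {
        for (int a = 0; a < q; ++a) gh(a, r) += wm * p[a];
        gh(seq[r], r) -= wm;
        for (int j = 0; j < L; ++j) {
          if (j == r) continue;
          const int col = j * q + seq[j];
          for (int a = 0; a < q; ++a) gJ(r * q + a, col) += wm * p[a];
          gJ(r * q + seq[r], col) -= wm;
        }
      }
    }
  }
  f /= meff;
  if (want_grad) { gh /= meff; gJ /= meff; }
  return List::create(_["f"] = f, _["grad_h"] = gh, _["grad_J"] = gJ);
}

// One Metropolis chain with single-site proposals restricted to variable
// positions, O(L) incremental score updates, and R's RNG (so set.seed on the
// R side fixes the trajectory). Records the current state every `thinning`
// steps once `burn_in` steps have been taken.
// [[Rcpp::export]]
List cpp_mc_chain(const arma::ivec& start, const arma::mat& h,
                  const arma::mat& J, const arma::uvec& variable_pos,
                  const int steps, const int burn_in, const int thinning,
                  const double temperature) {
  const int L = start.n_elem, q = h.n_rows, nv = variable_pos.n_elem;
  arma::ivec seq = start;
  double score = cpp_score_sequences(arma::imat(seq.t()), h, J)[0];

  const int n_rec = (steps - burn_in) / thinning;
  arma::imat rec(n_rec, L);
  arma::vec rec_score(n_rec);
  int accepted = 0, k = 0;

  for (int step = 1; step <= steps; ++step) {
    int ip = (int)(unif_rand() * nv); if (ip == nv) ip = nv - 1;
    const int i = variable_pos[ip];
    const int old = seq[i];
    int prop = (int)(unif_rand() * (q - 1)); if (prop == q - 1) prop = q - 2;
    if (prop >= old) ++prop;
    // delta score in O(L): field change + coupling row change
    double delta = h(prop, i) - h(old, i);
    const int row_new = i * q + prop, row_old = i * q + old;
    for (int j = 0; j < L; ++j) {
      if (j == i) continue;
      const int col = j * q + seq[j];
      delta += J(row_new, col) - J(row_old, col);
    }
    if (delta >= 0.0 || unif_rand() < std::exp(delta / temperature)) {
      seq[i] = prop;
      score += delta;
      ++accepted;
    }
    if (step > burn_in && ((step - burn_in) % thinning == 0) && k < n_rec) {
      rec.row(k) = seq.t();
      rec_score[k] = score;
      ++k;
    }
  }
  return List::create(_["states"] = rec, _["scores"] = rec_score,
                      _["n_proposed"] = steps, _["n_accepted"] = accepted);
}
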