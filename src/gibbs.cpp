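#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---- small dense kernels on stack buffers (t <= LACT_TMAX) ----------------
#define LACT_TMAX 8

// in-place lower Cholesky of symmetric A (t x t, column-major); A <- L
static inline void chol_lower(double* A, int t) {
  for (int j = 0; j < t; ++j) {
    double d = A[j + j * t];
    for (int k = 0; k < j; ++k) d -= A[j + k * t] * A[j + k * t];
    if (d <= 0.0) stop("non-positive-definite conditional precision");
    d = std::sqrt(d);
    A[j + j * t] = d;
    for (int i = j + 1; i < t; ++i) {
      double s = A[i + j * t];
      for (int k = 0; k < j; ++k) s -= A[i + k * t] * A[j + k * t];
      A[i + j * t] = s / d;
    }
  }
}

// solve L x = b (forward), L lower from chol_lower
static inline void solve_lower(const double* L, double* b, int t) {
  for (int i = 0; i < t; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i + k * t] * b[k];
    b[i] = s / L[i + i * t];
  }
}

// solve L' x = b (backward)
static inline void solve_lower_t(const double* L, double* b, int t) {
  for (int i = t - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < t; ++k) s -= L[k + i * t] * b[k];
    b[i] = s / L[i + i * t];
  }
}

// draw x ~ N(P^-1 rhs, P^-1); P (t x t) is destroyed, rhs overwritten by x
static inline void mvn_prec_inplace(double* P, double* rhs, int t) {
  chol_lower(P, t);
  solve_lower(P, rhs, t);
  solve_lower_t(P, rhs, t);
  double z[LACT_TMAX];
  for (int i = 0; i < t; ++i) z[i] = norm_rand();
  solve_lower_t(P, z, t);
  for (int i = 0; i < t; ++i) rhs[i] += z[i];
}

// Draw Sigma ~ inverse-Wishart(nu, S) by Bartlett decomposition.
static arma::mat riwish(double nu, const arma::mat& S) {
  int t = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(t, t, arma::fill::zeros);
  for (int i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t(); // ~ Wishart(Sinv, nu)
  return arma::inv_sympd(arma::symmatu(W));
}

// Multi-trait / recursive-SEM Gibbs sampler.
//
// Y (n x t): phenotypes in trait order (for the SEM, topological order
//   of the causal structure).
// X (n x p): fixed-effect design, full column rank.
// herd: 1-based herd-date level per record (ignored when n_herd == 0).
// animal: 1-based pedigree position per record.
// Hinv (q x q): sparse inverse relationship matrix.
// pattern (t x t): pattern[j][i] != 0 means trait i+1 is a parent of
//   trait j+1 (strictly lower triangular); all zero for the MTM.
// sem: per-trait location blocks with Y-parent covariates (requires a
//   diagonal residual mode); otherwise across-trait blocks per effect.
// resid_mode: 0 unstructured (inverse-Wishart), 1 diagonal
//   (per-trait scaled inverse chi-square), 2 identity (fixed).
// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(const arma::mat& Y, const arma::mat& X,
                const arma::ivec& herd, int n_herd,
                const arma::ivec& animal, const arma::sp_mat& Hinv,
                const arma::imat& pattern, bool sem, int resid_mode,
                int n_iter, int burn_in, int thin,
                double nu0, const arma::mat& Sg0, const arma::mat& Sh0,
                const arma::mat& Se0, double nu0_e, double s0_e,
                bool update_g, bool update_h, bool update_e,
                const arma::mat& Sg_init, const arma::mat& Sh_init,
                const arma::mat& Se_init, bool store_resid_draws) {
  const int n = Y.n_rows, t = Y.n_cols, p = X.n_cols;
  const int q = Hinv.n_rows;
  if (t > LACT_TMAX) stop("at most %d traits supported", LACT_TMAX);
  if (burn_in >= n_iter) stop("burn_in must be below n_iter");
  if (thin < 1) stop("thinning must be >= 1");
  const int n_keep = (n_iter - burn_in) / thin;

  // records per animal (CSR)
  std::vector<int> rec_ptr(q + 1, 0), rec_idx(n);
  for (int i = 0; i < n; ++i) rec_ptr[animal[i]]++;
  for (int i = 0; i < q; ++i) rec_ptr[i + 1] += rec_ptr[i];
  {
    // after the prefix sum, rec_ptr[a] is the start offset of animal a
    // (0-based) and rec_ptr[a + 1] its end
    std::vector<int> pos(q, 0);
    for (int i = 0; i < n; ++i) {
      int a = animal[i] - 1;
      rec_idx[rec_ptr[a] + pos[a]++] = i;
    }
  }
  // records per herd level
  std::vector<std::vector<int>> hrec(std::max(n_herd, 1));
  if (n_herd > 0)
    for (int i = 0; i < n; ++i) hrec[herd[i] - 1].push_back(i);

  // parent sets for the SEM
  std::vector<std::vector<int>> parents(t);
  int n_paths = 0;
  for (int j = 0; j < t; ++j)
    for (int i = 0; i < t; ++i)
      if (pattern(j, i) != 0) { parents[j].push_back(i); ++n_paths; }

  // state (Et, At transposed: traits in rows for contiguous access)
  arma::mat B(p, t, arma::fill::zeros);
  std::vector<arma::vec> lambda(t);
  for (int j = 0; j < t; ++j)
    lambda[j] = arma::vec(parents[j].size(), arma::fill::zeros);
  arma::mat Hd(std::max(n_herd, 1), t, arma::fill::zeros);
  arma::mat At(t, q, arma::fill::zeros);   // genetic values, traits x animals
  arma::mat Sg = Sg_init, Sh = Sh_init, Se = Se_init;
  arma::mat Et = Y.t();                    // residuals, traits x records

  // SEM: fixed location designs D_j = [X, Y[, parents(j)]] with
  // precomputed Gram matrices
  std::vector<arma::mat> Dg(t);
  if (sem) {
    for (int j = 0; j < t; ++j) {
      int pj = p + parents[j].size();
      arma::mat D(n, pj);
      D.cols(0, p - 1) = X;
      for (size_t k = 0; k < parents[j].size(); ++k)
        D.col(p + k) = Y.col(parents[j][k]);
      Dg[j] = D.t() * D;
    }
  }
  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx[j] = arma::dot(X.col(j), X.col(j));

  arma::vec hdiag(q);
  for (int i = 0; i < q; ++i) hdiag[i] = Hinv(i, i);

  // output storage
  arma::mat sg_draws(n_keep, t * t), sh_draws(n_keep, t * t),
      se_draws(n_keep, t * t), b_draws(n_keep, p * t),
      h_draws(n_keep, std::max(n_herd, 1) * t),
      l_draws(n_keep, std::max(n_paths, 1));
  arma::mat resid_mean(n, t, arma::fill::zeros),
      a_mean(q, t, arma::fill::zeros);
  arma::cube resid_draws;
  if (store_resid_draws) resid_draws.set_size(n, t, n_keep);

  double Pb[LACT_TMAX * LACT_TMAX], rb[LACT_TMAX], cb[LACT_TMAX];
  int keep = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    arma::mat Rinv(t, t);
    if (resid_mode == 0) Rinv = arma::inv_sympd(arma::symmatu(Se));
    else Rinv = arma::diagmat(1.0 / Se.diag());

    // ---- location effects ----
    if (!sem) {
      // per fixed-effect column, t-dimensional block across traits
      arma::mat L = (resid_mode == 0)
          ? arma::mat(arma::chol(Se, "lower"))
          : arma::mat(arma::diagmat(arma::sqrt(Se.diag())));
      arma::vec s(t), z(t), bnew(t);
      for (int j = 0; j < p; ++j) {
        s = Et * X.col(j);
        for (int k = 0; k < t; ++k) s[k] += xtx[j] * B(j, k);
        s /= xtx[j];
        for (int k = 0; k < t; ++k) z[k] = norm_rand();
        bnew = s + (L * z) / std::sqrt(xtx[j]);
        arma::vec d = bnew;
        for (int k = 0; k < t; ++k) d[k] -= B(j, k);
        // Et -= d * x_j'
        const double* xj = X.colptr(j);
        for (int r = 0; r < n; ++r) {
          if (xj[r] != 0.0) {
            double* e = Et.colptr(r);
            for (int k = 0; k < t; ++k) e[k] -= d[k] * xj[r];
          }
        }
        for (int k = 0; k < t; ++k) B(j, k) = bnew[k];
      }
    } else {
      // per trait: joint (b, lambda) block; diagonal residuals
      for (int j = 0; j < t; ++j) {
        int pj = p + (int)parents[j].size();
        double s2 = Se(j, j);
        arma::vec adj(n);
        for (int i = 0; i < n; ++i) {
          adj[i] = Y(i, j) - At(j, animal[i] - 1);
          if (n_herd > 0) adj[i] -= Hd(herd[i] - 1, j);
        }
        arma::vec rhs(pj);
        rhs.subvec(0, p - 1) = X.t() * adj;
        for (size_t k = 0; k < parents[j].size(); ++k)
          rhs[p + k] = arma::dot(Y.col(parents[j][k]), adj);
        arma::mat P = Dg[j] / s2;
        arma::vec bvec = rhs / s2;
        arma::mat U = arma::chol(P);
        arma::vec m = arma::solve(arma::trimatu(U),
                                  arma::solve(arma::trimatl(U.t()), bvec));
        arma::vec z(pj);
        for (int i = 0; i < pj; ++i) z[i] = norm_rand();
        arma::vec beta = m + arma::solve(arma::trimatu(U), z);
        B.col(j) = beta.subvec(0, p - 1);
        for (size_t k = 0; k < parents[j].size(); ++k)
          lambda[j][k] = beta[p + k];
        arma::vec fit = X * B.col(j);
        for (size_t k = 0; k < parents[j].size(); ++k)
          fit += Y.col(parents[j][k]) * lambda[j][k];
        for (int i = 0; i < n; ++i) Et(j, i) = adj[i] - fit[i];
      }
    }

    // ---- herd-date effects ----
    if (n_herd > 0) {
      arma::mat Shinv = arma::inv_sympd(arma::symmatu(Sh));
      for (int l = 0; l < n_herd; ++l) {
        const std::vector<int>& rows = hrec[l];
        arma::vec hold = Hd.row(l).t();
        arma::vec s(t, arma::fill::zeros);
        for (int r : rows) s += Et.col(r);
        s += (double)rows.size() * hold;
        arma::mat P = (double)rows.size() * Rinv + Shinv;
        arma::vec rhs = Rinv * s;
        for (int k = 0; k < t; ++k) {
          rb[k] = rhs[k];
          for (int k2 = 0; k2 < t; ++k2) Pb[k2 + k * t] = P(k2, k);
        }
        mvn_prec_inplace(Pb, rb, t);
        arma::vec d(t);
        for (int k = 0; k < t; ++k) d[k] = rb[k] - hold[k];
        for (int r : rows) Et.col(r) += -d;
        for (int k = 0; k < t; ++k) Hd(l, k) = rb[k];
      }
    }

    // ---- genetic values, single-site over the pedigree ----
    {
      arma::mat Sginv = arma::inv_sympd(arma::symmatu(Sg));
      arma::mat Lg = arma::chol(Sg, "lower"); // for record-less animals
      double Ri[LACT_TMAX * LACT_TMAX], Gi[LACT_TMAX * LACT_TMAX],
          Lgb[LACT_TMAX * LACT_TMAX];
      for (int k = 0; k < t; ++k)
        for (int m = 0; m < t; ++m) {
          Ri[m + k * t] = Rinv(m, k);
          Gi[m + k * t] = Sginv(m, k);
          Lgb[m + k * t] = Lg(m, k);
        }
      // raw CSC access into the symmetric H-inverse
      const double* hv = Hinv.values;
      const arma::uword* hri = Hinv.row_indices;
      const arma::uword* hcp = Hinv.col_ptrs;
      for (int i = 0; i < q; ++i) {
        // c = sum_{j != i} Hinv_ij a_j
        for (int k = 0; k < t; ++k) cb[k] = 0.0;
        for (arma::uword ptr = hcp[i]; ptr < hcp[i + 1]; ++ptr) {
          const int j = (int)hri[ptr];
          if (j == i) continue;
          const double v = hv[ptr];
          const double* aj = At.colptr(j);
          for (int k = 0; k < t; ++k) cb[k] += v * aj[k];
        }
        double* ai = At.colptr(i);
        const int r0 = rec_ptr[i], r1 = rec_ptr[i + 1];
        if (r0 == r1) {
          // no records: conditional is N(-c/h_ii, Sg/h_ii) directly
          const double hi = hdiag[i];
          const double sq = 1.0 / std::sqrt(hi);
          double z[LACT_TMAX];
          for (int k = 0; k < t; ++k) z[k] = norm_rand();
          for (int k = 0; k < t; ++k) {
            double s = 0.0;
            for (int m = 0; m <= k; ++m) s += Lgb[k + m * t] * z[m];
            ai[k] = -cb[k] / hi + s * sq;
          }
          continue;
        }
        // with records: P = w Rinv + h_ii Sginv
        const double w = (double)(r1 - r0);
        double sbuf[LACT_TMAX];
        for (int k = 0; k < t; ++k) sbuf[k] = w * ai[k];
        for (int r = r0; r < r1; ++r) {
          const double* e = Et.colptr(rec_idx[r]);
          for (int k = 0; k < t; ++k) sbuf[k] += e[k];
        }
        for (int k = 0; k < t; ++k) {
          double rv = 0.0, cv = 0.0;
          for (int m = 0; m < t; ++m) {
            rv += Ri[k + m * t] * sbuf[m];
            cv += Gi[k + m * t] * cb[m];
          }
          rb[k] = rv - cv;
          for (int m = 0; m < t; ++m)
            Pb[m + k * t] = w * Ri[m + k * t] + hdiag[i] * Gi[m + k * t];
        }
        mvn_prec_inplace(Pb, rb, t);
        double d[LACT_TMAX];
        for (int k = 0; k < t; ++k) { d[k] = rb[k] - ai[k]; ai[k] = rb[k]; }
        for (int r = r0; r < r1; ++r) {
          double* e = Et.colptr(rec_idx[r]);
          for (int k = 0; k < t; ++k) e[k] -= d[k];
        }
      }
    }

    // ---- covariance components ----
    if (update_g) {
      // scatter = A' Hinv A computed in one CSC pass: M = Hinv * A
      arma::mat M(t, q, arma::fill::zeros);
      const double* hv = Hinv.values;
      const arma::uword* hri = Hinv.row_indices;
      const arma::uword* hcp = Hinv.col_ptrs;
      for (int i = 0; i < q; ++i) {
        const double* ai = At.colptr(i);
        for (arma::uword ptr = hcp[i]; ptr < hcp[i + 1]; ++ptr) {
          const double v = hv[ptr];
          double* mj = M.colptr((int)hri[ptr]);
          for (int k = 0; k < t; ++k) mj[k] += v * ai[k];
        }
      }
      arma::mat scatter = At * M.t();
      Sg = riwish(nu0 + q, Sg0 + arma::symmatu(scatter));
    }
    if (update_h && n_herd > 0) {
      Sh = riwish(nu0 + n_herd, Sh0 + Hd.t() * Hd);
    }
    if (update_e) {
      if (resid_mode == 0) {
        Se = riwish(nu0 + n, Se0 + Et * Et.t());
      } else if (resid_mode == 1) {
        for (int j = 0; j < t; ++j) {
          double ss = s0_e + arma::dot(Et.row(j), Et.row(j));
          Se(j, j) = ss / R::rchisq(nu0_e + n);
        }
      } // resid_mode == 2: fixed identity
    }

    if (!Sg.is_finite() || !Se.is_finite() || !Et.is_finite())
      stop("divergent chain at iteration %d", iter);

    // ---- store ----
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      sg_draws.row(keep) = arma::vectorise(Sg).t();
      sh_draws.row(keep) = arma::vectorise(Sh).t();
      se_draws.row(keep) = arma::vectorise(Se).t();
      b_draws.row(keep) = arma::vectorise(B).t();
      h_draws.row(keep) = arma::vectorise(Hd).t();
      if (n_paths > 0) {
        int idx = 0;
        for (int j = 0; j < t; ++j)
          for (size_t k = 0; k < parents[j].size(); ++k)
            l_draws(keep, idx++) = lambda[j][k];
      }
      resid_mean += Et.t();
      a_mean += At.t();
      if (store_resid_draws) resid_draws.slice(keep) = Et.t();
      ++keep;
    }
  }
  if (keep > 0) {
    resid_mean /= keep;
    a_mean /= keep;
  }

  List out = List::create(
      Named("sigma_g") = sg_draws, Named("sigma_h") = sh_draws,
      Named("sigma_e") = se_draws, Named("b") = b_draws,
      Named("h") = h_draws, Named("lambda") = l_draws,
      Named("resid_mean") = resid_mean, Named("a_mean") = a_mean,
      Named("n_keep") = keep, Named("n_paths") = n_paths);
  if (store_resid_draws) out["resid_draws"] = resid_draws;
  return out;
}
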