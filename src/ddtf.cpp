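// Hot path of the spectral-causality stage: from accumulated regression
// cross-products to the DTF family, for every sliding window at once.
// Mirrors the R reference implementation (var_from_gram + spectral_transfer
// + ddtf_from_transfer); the two routes are cross-checked in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// gmat: (d*d + d*k + k*k) x W stacked vec(Sxx, Sxy, Syy) per window,
// already summed over the trial multiset. Fills [i, j, w, f] buffers.
static void ddtf_fill(const arma::mat& gmat, int k, int p, double n_obs,
                      const arma::vec& freqs, double fs,
                      double* out_ddtf, double* out_dtf, double* out_ff,
                      double* out_pc, bool all_measures) {
  const int d = k * p;
  const int W = gmat.n_cols;
  const int F = freqs.n_elem;
  const double eps = std::numeric_limits<double>::min();

  for (int w = 0; w < W; ++w) {
    const double* g = gmat.colptr(w);
    mat Sxx(const_cast<double*>(g), d, d, false, true);
    mat Sxy(const_cast<double*>(g + d * d), d, k, false, true);
    mat Syy(const_cast<double*>(g + d * d + d * k), k, k, false, true);

    mat Bhat;
    if (!solve(Bhat, Sxx, Sxy, solve_opts::no_approx)) {
      Rcpp::stop("singular regressor covariance in VAR fit (window %d)", w + 1);
    }
    mat sigma = (Syy - Sxy.t() * Bhat) / n_obs;
    sigma = 0.5 * (sigma + sigma.t());

    // lag coefficient matrices: A_m(i, j) = Bhat((m-1)k + j, i)
    std::vector<mat> A(p);
    for (int m = 0; m < p; ++m) {
      A[m] = Bhat.rows(m * k, (m + 1) * k - 1).t();
    }

    cx_cube H(k, k, F);
    cx_cube Afs(k, k, F);
    for (int fi = 0; fi < F; ++fi) {
      cx_mat Af(k, k, fill::eye);
      for (int m = 0; m < p; ++m) {
        std::complex<double> e =
          std::exp(std::complex<double>(0, -2.0 * M_PI * freqs(fi) * (m + 1) / fs));
        Af -= cx_mat(A[m] * e.real(), A[m] * e.imag());
      }
      cx_mat Hf;
      if (!inv(Hf, Af)) {
        Rcpp::stop("singular A(f) at %.3g Hz (window %d)", freqs(fi), w + 1);
      }
      Afs.slice(fi) = Af;
      H.slice(fi) = Hf;
    }

    // magnitude-squared transfer and its normalizations
    cube H2(k, k, F);
    for (int fi = 0; fi < F; ++fi) H2.slice(fi) = square(abs(H.slice(fi)));
    mat row_tot_f(k, F);        // per sink, per frequency
    for (int fi = 0; fi < F; ++fi) row_tot_f.col(fi) = sum(H2.slice(fi), 1);
    vec row_tot = sum(row_tot_f, 1); // per sink over sources and freqs

    mat sig_inv;
    if (!inv_sympd(sig_inv, sigma)) {
      if (!inv(sig_inv, sigma)) {
        Rcpp::stop("singular innovation covariance (window %d)", w + 1);
      }
    }
    cx_mat sig_inv_c(sig_inv, mat(k, k, fill::zeros));
    for (int fi = 0; fi < F; ++fi) {
      // inverse spectral matrix without inverting S(f):
      // P = S^-1 = (H Sigma H^H)^-1 = A(f)^H Sigma^-1 A(f)
      cx_mat P = Afs.slice(fi).t() * sig_inv_c * Afs.slice(fi);
      mat pm2 = square(abs(P));
      vec dd = pm2.diag();
      for (int i = 0; i < k; ++i) dd(i) = std::max(dd(i), eps);

      for (int j = 0; j < k; ++j) {
        for (int i = 0; i < k; ++i) {
          double dtf2 = H2(i, j, fi) / std::max(row_tot_f(i, fi), eps);
          double ff2 = H2(i, j, fi) / std::max(row_tot(i), eps);
          double pc2 = pm2(i, j) / std::sqrt(dd(i) * dd(j));
          if (pc2 > 1.0) pc2 = 1.0;
          double dd_val = std::sqrt(ff2) * std::sqrt(pc2);
          // layout [i, j, w, f]
          R_xlen_t idx = i + k * (j + k * ((R_xlen_t)w + (R_xlen_t)W * fi));
          out_ddtf[idx] = dd_val;
          if (all_measures) {
            out_dtf[idx] = std::sqrt(dtf2);
            out_ff[idx] = std::sqrt(ff2);
            out_pc[idx] = std::sqrt(pc2);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".ddtf_from_gram_cpp")]]
Rcpp::List ddtf_from_gram_cpp(const arma::mat& gmat, int k, int p,
                              double n_obs, const arma::vec& freqs,
                              double fs, bool all_measures) {
  const R_xlen_t n = (R_xlen_t)k * k * gmat.n_cols * freqs.n_elem;
  Rcpp::NumericVector out_ddtf(n);
  Rcpp::NumericVector out_dtf, out_ff, out_pc;
  if (all_measures) {
    out_dtf = Rcpp::NumericVector(n);
    out_ff = Rcpp::NumericVector(n);
    out_pc = Rcpp::NumericVector(n);
  }
  ddtf_fill(gmat, k, p, n_obs, freqs, fs, out_ddtf.begin(),
            all_measures ? out_dtf.begin() : nullptr,
            all_measures ? out_ff.begin() : nullptr,
            all_measures ? out_pc.begin() : nullptr, all_measures);
  if (all_measures) {
    return Rcpp::List::create(
      Rcpp::Named("ddtf") = out_ddtf, Rcpp::Named("dtf") = out_dtf,
      Rcpp::Named("ffdtf") = out_ff, Rcpp::Named("pcoh") = out_pc);
  }
  return Rcpp::List::create(Rcpp::Named("ddtf") = out_ddtf);
}

// dDTF then event-related causality in one pass: per (sink, source,
// frequency) the median over `baseline` windows (1-based indices)
// normalizes every window, in decibels, with values and medians
// floored at `eps_floor`.
// [[Rcpp::export(name = ".erc_from_gram_cpp")]]
Rcpp::NumericVector erc_from_gram_cpp(const arma::mat& gmat, int k, int p,
                                      double n_obs, const arma::vec& freqs,
                                      double fs,
                                      const Rcpp::IntegerVector& baseline,
                                      double eps_floor) {
  const int W = gmat.n_cols;
  const int F = freqs.n_elem;
  const R_xlen_t n = (R_xlen_t)k * k * W * F;
  Rcpp::NumericVector out(n);
  ddtf_fill(gmat, k, p, n_obs, freqs, fs, out.begin(), nullptr, nullptr,
            nullptr, false);
  const int nb = baseline.size();
  std::vector<double> buf(nb);
  for (int fi = 0; fi < F; ++fi) {
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        for (int b = 0; b < nb; ++b) {
          R_xlen_t idx = i + (R_xlen_t)k *
            (j + (R_xlen_t)k * ((baseline[b] - 1) + (R_xlen_t)W * fi));
          buf[b] = out[idx];
        }
        std::nth_element(buf.begin(), buf.begin() + nb / 2, buf.end());
        double med = buf[nb / 2];
        if (nb % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + nb / 2 - 1,
                           buf.begin() + nb / 2);
          med = 0.5 * (med + buf[nb / 2 - 1]);
        }
        med = std::max(med, eps_floor);
        for (int w = 0; w < W; ++w) {
          R_xlen_t idx = i + (R_xlen_t)k *
            (j + (R_xlen_t)k * ((R_xlen_t)w + (R_xlen_t)W * fi));
          out[idx] = 10.0 * std::log10(std::max(out[idx], eps_floor) / med);
        }
      }
    }
  }
  return out;
}
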