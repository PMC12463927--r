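// Numerical core of the DTF connectivity stage: MVAR least squares,
// band-averaged directed transfer function, and the phase-randomization
// surrogate loop. Kept in C++ because the surrogate null refits the MVAR
// model and re-inverts the spectral transfer matrix n_surrogates x
// n_epochs times per subject. Uses R's RNG so set.seed() governs the
// surrogates.

#include <RcppArmadillo.h>
#include <fftw3.h>
#include <memory>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// OLS fit of X(t) = sum_l A_l X(t-l) + e(t); X is k x n.
// Returns false on a singular normal system. A comes back k x (k*p).
static bool mvar_coef_fast(const mat& X, int p, mat& A) {
  const int k = X.n_rows, n = X.n_cols;
  const int N = n - p;
  if (N <= k * p) return false;
  mat Z(k * p, N);
  for (int lag = 1; lag <= p; ++lag)
    Z.rows((lag - 1) * k, lag * k - 1) = X.cols(p - lag, n - lag - 1);
  mat ZZ = Z * Z.t();
  mat ZY = Z * X.cols(p, n - 1).t();
  mat Bt;
  // exact solve first; on a rank-deficient system (e.g. average-referenced
  // data, whose channels sum to zero) fall back to the SVD-based
  // minimum-norm solution, the standard practice for MVAR on
  // common-average-referenced EEG
  if (!solve(Bt, ZZ, ZY, solve_opts::no_approx)) {
    if (!solve(Bt, ZZ, ZY, solve_opts::force_approx)) return false;
  }
  if (!Bt.is_finite()) return false;
  A = Bt.t();
  return true;
}

// Mean gamma^2 over each band's frequency list; out is k x k x nbands.
// gamma2_ij(f) = |H_ij|^2 / sum_m |H_im|^2 with H = Abar(f)^-1 and
// Abar(f) = I - sum_l A_l exp(-i 2 pi f l / fs).
static bool band_gamma(const mat& A, int p, double fs,
                       const std::vector<vec>& bandfreqs, cube& out) {
  const int k = A.n_rows;
  out.set_size(k, k, bandfreqs.size());
  // complex copies of the lag blocks, made once per fit
  std::vector<cx_mat> Ac(p);
  for (int lag = 1; lag <= p; ++lag)
    Ac[lag - 1] = cx_mat(A.cols((lag - 1) * k, lag * k - 1),
                         mat(k, k, fill::zeros));
  cx_mat eyek(k, k, fill::eye), Abar, H;
  for (size_t b = 0; b < bandfreqs.size(); ++b) {
    const vec& fr = bandfreqs[b];
    mat acc(k, k, fill::zeros);
    for (uword fi = 0; fi < fr.n_elem; ++fi) {
      Abar = eyek;
      for (int lag = 1; lag <= p; ++lag)
        Abar -= std::exp(std::complex<double>(0.0, -2.0 * M_PI * fr(fi) * lag / fs)) *
                Ac[lag - 1];
      if (!inv(H, Abar)) return false;
      mat g = square(abs(H));
      vec rs = sum(g, 1);
      if (rs.min() <= 0.0) return false;
      g.each_col() /= rs;
      acc += g;
    }
    out.slice(b) = acc / (double)fr.n_elem;
  }
  return out.is_finite();
}

static std::vector<mat> as_epoch_list(Rcpp::List epochs) {
  std::vector<mat> out;
  out.reserve(epochs.size());
  for (int i = 0; i < epochs.size(); ++i)
    out.push_back(Rcpp::as<mat>(epochs[i]));
  return out;
}

static std::vector<vec> as_freq_list(Rcpp::List bandFreqs) {
  std::vector<vec> out;
  out.reserve(bandFreqs.size());
  for (int i = 0; i < bandFreqs.size(); ++i)
    out.push_back(Rcpp::as<vec>(bandFreqs[i]));
  return out;
}

// Band-averaged DTF_Mean over epochs (observed statistic).
// [[Rcpp::export]]
arma::cube cpp_epoch_band_dtf(Rcpp::List epochs, int p, double fs,
                              Rcpp::List bandFreqs) {
  std::vector<mat> ep = as_epoch_list(epochs);
  std::vector<vec> bf = as_freq_list(bandFreqs);
  if (ep.empty()) Rcpp::stop("no epochs supplied");
  const int k = ep[0].n_rows;
  cube acc(k, k, bf.size(), fill::zeros);
  cube g;
  mat A;
  for (size_t e = 0; e < ep.size(); ++e) {
    if (!mvar_coef_fast(ep[e], p, A))
      Rcpp::stop("singular MVAR fit on epoch %d", (int)e + 1);
    if (!band_gamma(A, p, fs, bf, g))
      Rcpp::stop("non-finite DTF on epoch %d", (int)e + 1);
    acc += g;
  }
  return acc / (double)ep.size();
}

// Independent per-channel phase randomization preserving the amplitude
// spectrum (DC and Nyquist bins kept real). F0 holds the forward FFT of
// every channel (n x k, column-wise), computed once per epoch; phases are
// drawn from R's RNG and all channels are inverse-transformed in one
// batched call.
static mat phase_rand_from_spectrum(const cx_mat& F0, const mat& amp) {
  const int n = F0.n_rows, k = F0.n_cols;
  const int top = (n - 1) / 2;
  cx_mat F(n, k, fill::zeros);
  for (int c = 0; c < k; ++c) {
    F(0, c) = F0(0, c);
    if (n % 2 == 0) F(n / 2, c) = F0(n / 2, c);
    for (int j = 1; j <= top; ++j) {
      double ph = R::unif_rand() * 2.0 * M_PI;
      F(j, c) = std::polar(amp(j, c), ph);
      F(n - j, c) = std::conj(F(j, c));
    }
  }
  return real(ifft(F)).t();   // k x n
}

// [[Rcpp::export]]
arma::mat cpp_phase_randomize(const arma::mat& X) {
  cx_mat F0 = fft(X.t());
  mat amp = abs(F0);
  return phase_rand_from_spectrum(F0, amp);
}

// Half-spectrum (r2c) amplitudes and DC/Nyquist values of every channel of
// one epoch, plus a cached FFTW complex-to-real plan used to synthesize
// surrogates. Plans are created once per epoch set and reused across all
// surrogates; transforms run single-threaded.
struct SurrogateSynth {
  int k, n, nh;
  mat amp;                 // nh x k amplitude spectrum
  cx_vec dc, nyq;          // bin 0 and (even n) bin n/2 per channel
  std::vector<std::complex<double>> in;  // k * nh
  std::vector<double> out;               // k * n
  fftw_plan plan;

  SurrogateSynth(const mat& X) {
    k = X.n_rows; n = X.n_cols; nh = n / 2 + 1;
    cx_mat F0 = fft(X.t());              // n x k
    amp = abs(F0.rows(0, nh - 1));
    dc = F0.row(0).st();
    nyq = (n % 2 == 0) ? cx_vec(F0.row(n / 2).st()) : cx_vec(k, fill::zeros);
    in.resize((size_t)k * nh);
    out.resize((size_t)k * n);
    int nn = n;
    plan = fftw_plan_many_dft_c2r(1, &nn, k,
                                  reinterpret_cast<fftw_complex*>(in.data()),
                                  nullptr, 1, nh,
                                  out.data(), nullptr, 1, nn,
                                  FFTW_ESTIMATE);
  }
  ~SurrogateSynth() { fftw_destroy_plan(plan); }

  // draw phases from R's RNG and synthesize one surrogate epoch (k x n)
  mat draw() {
    const int top = (n - 1) / 2;
    for (int c = 0; c < k; ++c) {
      std::complex<double>* F = in.data() + (size_t)c * nh;
      F[0] = dc(c);
      if (n % 2 == 0) F[n / 2] = nyq(c);
      for (int j = 1; j <= top; ++j)
        F[j] = std::polar(amp(j, c), R::unif_rand() * 2.0 * M_PI);
    }
    fftw_execute(plan);
    mat Xs(k, n);
    const double sc = 1.0 / n;
    for (int c = 0; c < k; ++c)
      for (int t = 0; t < n; ++t) Xs(c, t) = out[(size_t)c * n + t] * sc;
    return Xs;
  }
};

// Surrogate null of the epoch-averaged band DTF_Mean: for every surrogate,
// phase-randomize each epoch, refit, recompute, average over epochs.
// Failed fits are redrawn; more than retryBudget failures abort.
// [[Rcpp::export]]
Rcpp::List cpp_surrogate_band_dtf(Rcpp::List epochs, int p, double fs,
                                  Rcpp::List bandFreqs, int nSurr,
                                  int retryBudget) {
  std::vector<mat> ep = as_epoch_list(epochs);
  std::vector<vec> bf = as_freq_list(bandFreqs);
  if (ep.empty()) Rcpp::stop("no epochs supplied");
  const int k = ep[0].n_rows;
  const int nb = bf.size();
  std::vector<std::unique_ptr<SurrogateSynth>> synth;
  for (size_t e = 0; e < ep.size(); ++e)
    synth.emplace_back(new SurrogateSynth(ep[e]));
  Rcpp::NumericVector values((R_xlen_t)k * k * nb * nSurr);
  values.attr("dim") = Rcpp::IntegerVector::create(k, k, nb, nSurr);
  int failures = 0;
  cube g;
  mat A;
  for (int s = 0; s < nSurr; ++s) {
    cube acc(k, k, nb, fill::zeros);
    for (size_t e = 0; e < ep.size(); ++e) {
      bool ok = false;
      while (!ok) {
        mat Xs = synth[e]->draw();
        ok = mvar_coef_fast(Xs, p, A) && band_gamma(A, p, fs, bf, g);
        if (!ok && ++failures > retryBudget)
          Rcpp::stop("surrogate failure: %d unstable/singular fits exceeded the retry budget",
                     failures);
      }
      acc += g;
    }
    acc /= (double)ep.size();
    std::copy(acc.begin(), acc.end(),
              values.begin() + (size_t)s * k * k * nb);
    if (s % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("values") = values,
                            Rcpp::Named("failures") = failures);
}

// Plain MVAR OLS coefficients (k x k*p) — used to cross-check the R fit.
// [[Rcpp::export]]
arma::mat cpp_mvar_coef(const arma::mat& X, int p) {
  mat A;
  if (!mvar_coef_fast(X, p, A)) Rcpp::stop("singular MVAR fit");
  return A;
}
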