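// Discrete smoothed pseudo-Wigner-Ville kernels.
//
// Conventions (shared with the pure-R WVD reference in R/timefreq.R):
//   - z is the analytic signal of one block, length N.
//   - frequency bin k has center k * fs / (2 * nfft): the lag variable of the
//     instantaneous autocorrelation advances in half-sample steps, so nfft
//     bins tile [0, fs/2).
//   - lag range at time n is min(n, N-1-n, Lh2, nfft/2 - 1); a length-1 lag
//     window means "no lag smoothing" and does not cap the range.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Accumulate the three smoothed instantaneous-autocorrelation kernels
// (h, tau_g*h, Dh) and FFT them over the lag axis.  Returns complex
// nfft x N matrices: spw (plain SPWVD, real up to rounding), spw_tg
// (time-reassignment numerator), spw_dh (frequency-reassignment numerator).
// [[Rcpp::export]]
List spwvd_block_cpp(arma::cx_vec z, arma::vec g, arma::vec h, arma::vec dh,
                     int nfft) {
  const int N = z.n_elem;
  const int Lg = g.n_elem, Lh = h.n_elem;
  const int Lg2 = (Lg - 1) / 2, Lh2 = (Lh - 1) / 2;
  const bool flat_h = (Lh == 1);

  arma::cx_mat Kh(nfft, N, arma::fill::zeros);
  arma::cx_mat Ktg(nfft, N, arma::fill::zeros);
  arma::cx_mat Kdh(nfft, N, arma::fill::zeros);

  for (int n = 0; n < N; ++n) {
    int taumax = std::min(n, N - 1 - n);
    taumax = std::min(taumax, nfft / 2 - 1);
    if (!flat_h) taumax = std::min(taumax, Lh2);
    for (int tau = 0; tau <= taumax; ++tau) {
      std::complex<double> acc(0.0, 0.0), acc_tg(0.0, 0.0);
      for (int s = -Lg2; s <= Lg2; ++s) {
        const int ip = n + s + tau, im = n + s - tau;
        if (ip < 0 || ip >= N || im < 0 || im >= N) continue;
        const std::complex<double> p = z[ip] * std::conj(z[im]);
        const double gw = g[s + Lg2];
        acc += gw * p;
        acc_tg += (double)s * gw * p;
      }
      const double hw = flat_h ? h[0] : h[tau + Lh2];
      const double dhw = flat_h ? 0.0 : dh[tau + Lh2];
      const int row_p = tau;                       // tau >= 0
      Kh(row_p, n) = hw * acc;
      Ktg(row_p, n) = hw * acc_tg;
      Kdh(row_p, n) = dhw * acc;
      if (tau > 0) {                               // tau < 0 rows
        const int row_m = nfft - tau;
        // A_n(-tau) = conj(A_n(tau)); h even, Dh odd in tau.
        Kh(row_m, n) = hw * std::conj(acc);
        Ktg(row_m, n) = hw * std::conj(acc_tg);
        Kdh(row_m, n) = -dhw * std::conj(acc);
      }
    }
  }
  return List::create(_["spw"] = arma::cx_mat(arma::fft(Kh)),
                      _["spw_tg"] = arma::cx_mat(arma::fft(Ktg)),
                      _["spw_dh"] = arma::cx_mat(arma::fft(Kdh)));
}

// Reassigned SPWVD of one block: every SPWVD value moves to the grid bin
// nearest its local centre of gravity (clamped to the block) and
// accumulates, so the block's total energy is conserved exactly.  Points
// where |SPWVD| < 1e-12 * max|SPWVD| stay in place.
// [[Rcpp::export]]
List rspwvd_block_cpp(arma::cx_vec z, arma::vec g, arma::vec h, arma::vec dh,
                      int nfft) {
  List kern = spwvd_block_cpp(z, g, h, dh, nfft);
  arma::cx_mat spw = kern["spw"], tg = kern["spw_tg"], dhm = kern["spw_dh"];
  const int N = z.n_elem;
  arma::mat den = arma::real(spw);
  arma::mat num_t = arma::real(tg);
  arma::mat num_k = arma::imag(dhm);
  const double eps = 1e-12 * den.max();
  const double kscale = nfft / (2.0 * M_PI);
  arma::mat rsp(nfft, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < nfft; ++k) {
      const double v = den(k, n);
      int th = n, kh = k;
      if (std::fabs(v) >= eps && v != 0.0) {
        th = (int)std::lround(n + num_t(k, n) / v);
        kh = (int)std::lround(k - kscale * num_k(k, n) / v);
        th = std::min(std::max(th, 0), N - 1);
        kh = std::min(std::max(kh, 0), nfft - 1);
      }
      rsp(kh, th) += v;
    }
  }
  return List::create(_["spw"] = den, _["rsp"] = rsp);
}
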