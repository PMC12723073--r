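// Numerical core: complex Morlet CWT filtering in the frequency domain,
// fused trial-wise PLV/ciPLV accumulation per scale, and spectral noise
// synthesis for the cohort generator. Kept in C++ because the pairwise
// phasor sums over (scale, time, trial) dominate pipeline runtime.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Frequency response of the L1-normalised analytic Morlet at scale a = fc/f0:
// H(nu) = exp(-pi^2 * fb * (a*nu - fc)^2) for nu >= 0, 0 for nu < 0.
// A unit cosine at f0 comes out with modulus 1/2 (analytic half).
static void morlet_support(double f0, double fb, double fc, double fs,
                           int nfft, int& k0, int& k1, vec& h) {
  const double a = fc / f0;
  // keep bins with exponent <= 30 (|H| >= ~9e-14)
  const double half = std::sqrt(30.0) / (datum::pi * std::sqrt(fb));
  const double nu_lo = (fc - half) / a;
  const double nu_hi = (fc + half) / a;
  const double dnu = fs / nfft;
  k0 = std::max(0, (int)std::ceil(nu_lo / dnu));
  k1 = std::min(nfft / 2 - 1, (int)std::floor(nu_hi / dnu));
  if (k1 < k0) { k1 = k0 - 1; h.reset(); return; }
  h.set_size(k1 - k0 + 1);
  for (int k = k0; k <= k1; ++k) {
    double d = a * (k * dnu) - fc;
    h(k - k0) = std::exp(-datum::pi * datum::pi * fb * d * d);
  }
}

static cx_mat forward_fft_padded(const mat& x, int nfft) {
  cx_mat xp(nfft, x.n_cols, fill::zeros);
  xp.rows(0, x.n_rows - 1) = conv_to<cx_mat>::from(x);
  return fft(xp);
}

// Real-packed forward FFT: pairs of real columns are packed into one
// complex column (even + i*odd) before the FFT; filtered_support() then
// unpacks the two spectra on a support row block via the conjugate-symmetry
// split. Halves the transform work for many-signal inputs.
struct PackedFFT {
  cx_mat F;
  int nsig;
  int nfft;
};

static PackedFFT forward_fft_packed(const mat& x, int nfft) {
  const int nsig = x.n_cols, npack = (nsig + 1) / 2;
  cx_mat xp(nfft, npack, fill::zeros);
  for (int p = 0; p < npack; ++p) {
    vec re = x.col(2 * p);
    vec im = (2 * p + 1 < nsig) ? vec(x.col(2 * p + 1))
                                : vec(x.n_rows, fill::zeros);
    xp.submat(0, p, x.n_rows - 1, p) = cx_vec(re, im);
  }
  return PackedFFT{fft(xp), nsig, nfft};
}

// spectrum rows k0..k1 (1 <= k0, k1 < nfft/2) of all original signals,
// multiplied by the real filter h; handles the k = 0 row separately
static cx_mat filtered_support(const PackedFFT& pf, int k0, int k1,
                               const vec& h) {
  const int nb = k1 - k0 + 1, npack = pf.F.n_cols, nsig = pf.nsig;
  const int kk0 = std::max(k0, 1);
  cx_mat S(nb, nsig);
  if (k1 >= kk0) {
    cx_mat B1 = pf.F.rows(kk0, k1);
    cx_mat B2 = flipud(pf.F.rows(pf.nfft - k1, pf.nfft - kk0));
    cx_mat A = 0.5 * (B1 + conj(B2));
    cx_mat B = std::complex<double>(0, -0.5) * (B1 - conj(B2));
    const int r0 = kk0 - k0;
    for (int p = 0; p < npack; ++p) {
      S.submat(r0, 2 * p, nb - 1, 2 * p) = A.col(p);
      if (2 * p + 1 < nsig)
        S.submat(r0, 2 * p + 1, nb - 1, 2 * p + 1) = B.col(p);
    }
  }
  if (k0 == 0) {
    for (int p = 0; p < npack; ++p) {
      S(0, 2 * p) = pf.F(0, p).real();
      if (2 * p + 1 < nsig) S(0, 2 * p + 1) = pf.F(0, p).imag();
    }
  }
  S.each_col() %= conv_to<cx_vec>::from(h);
  return S;
}

// Full-resolution CWT coefficients for one window segment.
// x: samples x signals; returns complex array (samples, signals, scales).
// [[Rcpp::export]]
Rcpp::ComplexVector cpp_cwt_morlet(const arma::mat& x, double fs,
                                   const arma::vec& freqs, double fb,
                                   double fc, int nfft) {
  const int n = x.n_rows, nsig = x.n_cols, ns = freqs.n_elem;
  cx_mat F = forward_fft_padded(x, nfft);
  Rcpp::ComplexVector out(Rcpp::Dimension(n, nsig, ns));
  std::complex<double>* po = reinterpret_cast<std::complex<double>*>(
      COMPLEX(out));
  for (int s = 0; s < ns; ++s) {
    int k0, k1; vec h;
    morlet_support(freqs(s), fb, fc, fs, nfft, k0, k1, h);
    cx_mat Y(nfft, nsig, fill::zeros);
    if (k1 >= k0) {
      Y.rows(k0, k1) = F.rows(k0, k1);
      Y.rows(k0, k1).each_col() %= conv_to<cx_vec>::from(h);
    }
    cx_mat y = ifft(Y);
    for (int j = 0; j < nsig; ++j)
      for (int i = 0; i < n; ++i)
        po[(size_t)s * n * nsig + (size_t)j * n + i] = y(i, j);
  }
  return out;
}

// Fused kernel: per-scale sums over COI-valid decimated cells of the
// pairwise PLV (modulus of trial-mean phasor) and signed ciPLV.
// x columns are ordered channel-fastest: col = trial * nch + ch.
// stride[s] must divide nfft; cells[[s]] holds 0-based decimated indices
// (cell m corresponds to window sample m * stride[s]).
// [[Rcpp::export]]
Rcpp::List cpp_plv_band_sums(const arma::mat& x, int nch, int ntr, double fs,
                             const arma::vec& freqs, double fb, double fc,
                             int nfft, const arma::ivec& stride,
                             Rcpp::List cells) {
  const int ns = freqs.n_elem;
  PackedFFT pf = forward_fft_packed(x, nfft);
  cube plv_sum(nch, nch, ns, fill::zeros);
  cube cip_sum(nch, nch, ns, fill::zeros);
  ivec ncell(ns, fill::zeros);

  for (int s = 0; s < ns; ++s) {
    Rcpp::IntegerVector cs = cells[s];
    const int nc = cs.size();
    ncell(s) = nc;
    if (nc == 0) continue;
    const int D = stride(s);
    const int L = nfft / D;
    int k0, k1; vec h;
    morlet_support(freqs(s), fb, fc, fs, nfft, k0, k1, h);
    // filtered support block, then alias-fold so an L-point ifft yields
    // the decimated samples y[m * D] exactly (up to the 1/D factor);
    // contiguous row-block operations keep this cache-friendly
    cx_mat S = filtered_support(pf, k0, k1, h);
    cx_mat Yd(L, x.n_cols, fill::zeros);
    {
      int j = 0, nb = k1 - k0 + 1;
      while (j < nb) {
        int dest = (k0 + j) % L;
        int len = std::min(L - dest, nb - j);
        Yd.rows(dest, dest + len - 1) += S.rows(j, j + len - 1);
        j += len;
      }
    }
    cx_mat y = ifft(Yd) / (double)D;

    // unit phasors at valid cells, gathered per channel
    uvec rows(nc);
    for (int m = 0; m < nc; ++m) rows(m) = cs[m];
    cx_mat Uc = y.rows(rows);                    // cell x signal
    mat a = abs(Uc);
    a.elem(find(a == 0)).ones();                 // zero stays zero
    Uc /= conv_to<cx_mat>::from(a);
    std::vector<cx_mat> bych(nch);
    for (int ch = 0; ch < nch; ++ch)
      bych[ch] = Uc.cols(regspace<uvec>(ch, nch, Uc.n_cols - 1)); // cell x trial
    for (int i = 0; i < nch; ++i) {
      cx_mat ci = conj(bych[i]);
      for (int j = i + 1; j < nch; ++j) {
        // mean phasor of exp(i*(phi_i - phi_j)) per cell
        cx_vec m = conj(sum(bych[j] % ci, 1)) / (double)ntr;
        double psum = accu(abs(m));
        double csum = 0.0;
        for (int c = 0; c < nc; ++c) {
          double re = m(c).real(), im = m(c).imag();
          double den2 = 1.0 - re * re;
          if (den2 > 1e-12) csum += im / std::sqrt(den2);
        }
        plv_sum(i, j, s) = psum;
        cip_sum(i, j, s) = csum;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("plv_sum") = plv_sum,
                            Rcpp::Named("ciplv_sum") = cip_sum,
                            Rcpp::Named("ncells") = ncell);
}

// Band-limited Gaussian noise synthesised in the frequency domain:
// positive-frequency bins bin0..bin0+nb-1 get amps .* (zre + i zim) and the
// mirrored negative-frequency bins get the independent amps .* (zre2 + i
// zim2). With both halves independent (a circularly symmetric spectrum),
// the real and imaginary parts of the ifft are two independent real noise
// signals with the same power spectrum. Returns nsamp x (2 * ncol) with
// columns (Re1, Im1, Re2, ...). Caller rescales.
// [[Rcpp::export]]
arma::mat cpp_spectral_synth(int nfft, int nsamp, int bin0,
                             const arma::vec& amps, const arma::mat& zre,
                             const arma::mat& zim, const arma::mat& zre2,
                             const arma::mat& zim2) {
  const int nb = amps.n_elem, ncx = zre.n_cols;
  cx_mat S(nfft, ncx, fill::zeros);
  cx_mat block(zre, zim);
  block.each_col() %= conv_to<cx_vec>::from(amps);
  S.rows(bin0, bin0 + nb - 1) = block;
  cx_mat block2(zre2, zim2);
  block2.each_col() %= conv_to<cx_vec>::from(amps);
  // negative frequencies: bin nfft - k for k = bin0..bin0+nb-1, reversed
  S.rows(nfft - (bin0 + nb - 1), nfft - bin0) = flipud(block2);
  cx_mat y = ifft(S);
  mat out(nsamp, 2 * ncx);
  for (int j = 0; j < ncx; ++j) {
    out.col(2 * j) = real(y.submat(0, j, nsamp - 1, j));
    out.col(2 * j + 1) = imag(y.submat(0, j, nsamp - 1, j));
  }
  return out;
}
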