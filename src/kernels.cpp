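// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <fftw3.h>

using namespace arma;

// Least-squares slope of y on t (closed form, two-pass).
static double ls_slope(const vec& t, const vec& y) {
  const double tb = mean(t), yb = mean(y);
  double sxx = 0.0, sxy = 0.0;
  for (uword i = 0; i < t.n_elem; ++i) {
    const double dt = t[i] - tb;
    sxx += dt * dt;
    sxy += dt * (y[i] - yb);
  }
  return sxy / sxx;
}

// One-sided periodogram excluding the DC bin: S[m-1] = |X(m)|^2, m = 1..floor(M/2).
static vec periodogram_onesided(const vec& w) {
  const cx_vec X = fft(w);
  const uword nb = w.n_elem / 2;
  vec S(nb);
  for (uword m = 1; m <= nb; ++m) {
    const double re = X[m].real(), im = X[m].imag();
    S[m - 1] = re * re + im * im;
  }
  return S;
}

static double shannon_entropy_bits(const vec& S) {
  const double tot = accu(S);
  if (!(tot > 0.0)) return datum::nan;
  double H = 0.0;
  for (uword i = 0; i < S.n_elem; ++i) {
    const double p = S[i] / tot;
    if (p > 0.0) H -= p * std::log2(p);
  }
  return H;
}

// Fraction of one-sided spectral energy in [f1, f2) intersected with the
// analysis band [lo, hi]; denominator is the energy in [lo, hi].
static double band_fraction(const vec& S, double fs, uword M,
                            double f1, double f2, double lo, double hi) {
  const double eps = 1e-6;
  double num = 0.0, den = 0.0;
  for (uword i = 0; i < S.n_elem; ++i) {
    const double f = (double)(i + 1) * fs / (double)M;
    const bool in_analysis = (f >= lo - eps) && (f <= hi + eps);
    if (!in_analysis) continue;
    den += S[i];
    if (f >= f1 - eps && f < f2 - eps) num += S[i];
  }
  if (!(den > 0.0)) return datum::nan;
  return num / den;
}

static double var_unbiased(const vec& x) {
  const double m = mean(x);
  double s = 0.0;
  for (uword i = 0; i < x.n_elem; ++i) { const double d = x[i] - m; s += d * d; }
  return s / (double)(x.n_elem - 1);
}

static double higuchi_fd(const vec& x, int kmax) {
  const int N = (int)x.n_elem;
  vec lt(kmax), ly(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    for (int m = 1; m <= k; ++m) {
      const int nm = (N - m) / k;
      if (nm < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= nm; ++i)
        s += std::fabs(x[m - 1 + i * k] - x[m - 1 + (i - 1) * k]);
      Lk += s * (double)(N - 1) / ((double)nm * (double)k * (double)k);
    }
    Lk /= (double)k;
    lt[k - 1] = std::log(1.0 / (double)k);
    ly[k - 1] = std::log(Lk);
  }
  return ls_slope(lt, ly);
}

static double dfa_exponent(const vec& x, const ivec& scales) {
  const uword N = x.n_elem;
  // mean-centered cumulative sum
  vec z(N);
  const double xb = mean(x);
  double acc = 0.0;
  for (uword i = 0; i < N; ++i) { acc += x[i] - xb; z[i] = acc; }
  vec lt(scales.n_elem), ly(scales.n_elem);
  for (uword si = 0; si < scales.n_elem; ++si) {
    const uword s = (uword)scales[si];
    const uword m = N / s;
    double sse = 0.0;
    const double tb = ((double)s - 1.0) / 2.0;
    const double sxx = (double)s * ((double)s * (double)s - 1.0) / 12.0;
    for (uword seg = 0; seg < m; ++seg) {
      const uword off = seg * s;
      double zb = 0.0;
      for (uword t = 0; t < s; ++t) zb += z[off + t];
      zb /= (double)s;
      double sxy = 0.0, syy = 0.0;
      for (uword t = 0; t < s; ++t) {
        const double dz = z[off + t] - zb;
        sxy += ((double)t - tb) * dz;
        syy += dz * dz;
      }
      const double ssres = syy - sxy * sxy / sxx;
      sse += ssres / (double)s;  // e_i^2 = mean squared deviation from trend
    }
    const double F = std::sqrt(sse / (double)m);
    lt[si] = std::log((double)s);
    ly[si] = std::log(F);
  }
  return ls_slope(lt, ly);
}

// Ten windowed features for every (window, channel).
// sig: samples x channels; returns cube n_win x n_ch x 10 in the fixed order
// [spectral_entropy, hjorth_mobility, hjorth_complexity, higuchi_fd,
//  delta, theta, alpha, beta, gamma, dfa].
// bands: 5 x 2 matrix of [f1, f2); analysis band [band_lo, band_hi].
// Degenerate (zero-variance) windows yield a full row of NaN.
// The window FFT uses one cached FFTW real-to-complex plan.
// [[Rcpp::export]]
arma::cube window_features_cpp(const Rcpp::NumericMatrix& sig_in, double fs,
                               int win_n, int hop_n, int kmax,
                               const arma::ivec& dfa_scales,
                               const arma::mat& bands,
                               double band_lo, double band_hi) {
  // no-copy view onto the R matrix (read-only use)
  const mat sig(const_cast<double*>(sig_in.begin()),
                (uword)sig_in.nrow(), (uword)sig_in.ncol(), false, true);
  const uword n = sig.n_rows, nch = sig.n_cols;
  const int n_win = (int)((n - (uword)win_n) / (uword)hop_n) + 1;
  cube out(n_win, nch, 10);
  out.fill(datum::nan);

  // bin membership (one-sided, DC excluded): bin i holds frequency
  // (i+1) * fs / win_n; same epsilon convention as the R reference ops
  const uword nb = (uword)win_n / 2;
  const double eps = 1e-6;
  std::vector<unsigned char> in_analysis(nb);
  std::vector<std::array<unsigned char, 5>> in_band(nb);
  for (uword i = 0; i < nb; ++i) {
    const double f = (double)(i + 1) * fs / (double)win_n;
    in_analysis[i] = (f >= band_lo - eps && f <= band_hi + eps) ? 1 : 0;
    for (int b = 0; b < 5; ++b)
      in_band[i][b] = (in_analysis[i] &&
                       f >= bands(b, 0) - eps && f < bands(b, 1) - eps) ? 1 : 0;
  }

  double* fft_in = ::fftw_alloc_real(win_n);
  ::fftw_complex* fft_out = ::fftw_alloc_complex(win_n / 2 + 1);
  ::fftw_plan plan = ::fftw_plan_dft_r2c_1d(win_n, fft_in, fft_out, FFTW_ESTIMATE);

  vec w(win_n), S(nb);
  for (uword ch = 0; ch < nch; ++ch) {
    for (int wi = 0; wi < n_win; ++wi) {
      const uword off = (uword)wi * (uword)hop_n;
      for (int t = 0; t < win_n; ++t) w[t] = sig(off + t, ch);
      const double v0 = var_unbiased(w);
      if (!(v0 > 0.0) || !w.is_finite()) continue;  // masked row
      const vec d1 = diff(w);
      const double v1 = var_unbiased(d1);
      std::memcpy(fft_in, w.memptr(), sizeof(double) * (size_t)win_n);
      ::fftw_execute(plan);
      for (uword i = 0; i < nb; ++i) {
        const double re = fft_out[i + 1][0], im = fft_out[i + 1][1];
        S[i] = re * re + im * im;
      }
      out(wi, ch, 0) = shannon_entropy_bits(S);
      const double mob = std::sqrt(v1 / v0);
      out(wi, ch, 1) = mob;
      if (v1 > 0.0) {
        const vec d2 = diff(d1);
        const double v2 = var_unbiased(d2);
        out(wi, ch, 2) = std::sqrt(v2 / v1) / mob;
      }
      out(wi, ch, 3) = higuchi_fd(w, kmax);
      double den = 0.0, num[5] = {0, 0, 0, 0, 0};
      for (uword i = 0; i < nb; ++i) {
        if (!in_analysis[i]) continue;
        den += S[i];
        for (int b = 0; b < 5; ++b) if (in_band[i][b]) num[b] += S[i];
      }
      if (den > 0.0)
        for (int b = 0; b < 5; ++b) out(wi, ch, 4 + b) = num[b] / den;
      out(wi, ch, 9) = dfa_exponent(w, dfa_scales);
    }
  }
  ::fftw_destroy_plan(plan);
  ::fftw_free(fft_in);
  ::fftw_free(fft_out);
  return out;
}

// Zero-phase FIR filtering by overlap-save FFT convolution.
// h must have odd length (linear-phase type I); the group delay is
// compensated and edges are handled by signal reflection, so the output has
// the same length as the input.
// [[Rcpp::export]]
arma::vec fir_filter_cpp(const arma::vec& x, const arma::vec& h) {
  const uword n = x.n_elem, L = h.n_elem;
  if (L % 2 == 0) Rcpp::stop("FIR length must be odd");
  const uword g = (L - 1) / 2;
  if (n < g + 2) Rcpp::stop("signal shorter than filter half-length");
  // reflect padding (no edge repetition)
  vec xp(n + 2 * g);
  for (uword i = 0; i < g; ++i) xp[i] = x[g - i];
  xp.subvec(g, g + n - 1) = x;
  for (uword i = 0; i < g; ++i) xp[g + n + i] = x[n - 2 - i];

  uword nfft = 8192;
  while (nfft < 4 * L) nfft *= 2;
  const uword step = nfft - (L - 1);
  cx_vec H = fft(cx_vec(h, vec(L, fill::zeros)), nfft);

  const uword np = xp.n_elem;
  const uword n_conv = np + L - 1;
  vec y(n, fill::zeros);
  cx_vec buf(nfft);
  // outputs needed: conv indices [2g, 2g + n - 1]
  for (uword o = 0; o < n_conv; o += step) {
    // block produces conv indices [o, o + step - 1] from inputs [o-(L-1), o+step-1]
    if (o + step <= 2 * g) continue;
    if (o > 2 * g + n - 1) break;
    for (uword j = 0; j < nfft; ++j) {
      const sword idx = (sword)o - (sword)(L - 1) + (sword)j;
      buf[j] = (idx >= 0 && idx < (sword)np) ? cx_double(xp[(uword)idx], 0.0)
                                             : cx_double(0.0, 0.0);
    }
    cx_vec Y = ifft(fft(buf) % H);
    const uword hi = std::min(o + step - 1, n_conv - 1);
    for (uword k = std::max(o, 2 * g); k <= hi; ++k) {
      const uword out_idx = k - 2 * g;
      if (out_idx < n) y[out_idx] = Y[k - o + (L - 1)].real();
    }
  }
  return y;
}

// Zero-phase FIR filtering of every column of a matrix, sharing the
// filter spectrum and FFTW plans across channels. Same contract as
// fir_filter_cpp (odd symmetric h, reflect padding, delay compensation).
// [[Rcpp::export]]
Rcpp::NumericMatrix fir_filter_mat_cpp(const Rcpp::NumericMatrix& x_in,
                                       const arma::vec& h) {
  const mat x(const_cast<double*>(x_in.begin()),
              (uword)x_in.nrow(), (uword)x_in.ncol(), false, true);
  const uword n = x.n_rows, nch = x.n_cols, L = h.n_elem;
  if (L % 2 == 0) Rcpp::stop("FIR length must be odd");
  const uword g = (L - 1) / 2;
  if (n < g + 2) Rcpp::stop("signal shorter than filter half-length");

  uword nfft = 8192;
  while (nfft < 4 * L) nfft *= 2;
  const uword step = nfft - (L - 1);
  const uword nc = nfft / 2 + 1;

  double* rbuf = ::fftw_alloc_real(nfft);
  ::fftw_complex* cbuf = ::fftw_alloc_complex(nc);
  ::fftw_plan fwd = ::fftw_plan_dft_r2c_1d((int)nfft, rbuf, cbuf,
                                           FFTW_ESTIMATE);
  ::fftw_plan bwd = ::fftw_plan_dft_c2r_1d((int)nfft, cbuf, rbuf,
                                           FFTW_ESTIMATE);
  // filter spectrum, pre-scaled by 1/nfft for the unnormalized inverse
  std::vector<double> Hre(nc), Him(nc);
  std::memset(rbuf, 0, sizeof(double) * nfft);
  std::memcpy(rbuf, h.memptr(), sizeof(double) * L);
  ::fftw_execute(fwd);
  for (uword i = 0; i < nc; ++i) {
    Hre[i] = cbuf[i][0] / (double)nfft;
    Him[i] = cbuf[i][1] / (double)nfft;
  }

  Rcpp::NumericMatrix out((int)n, (int)nch);
  vec xp(n + 2 * g);
  const uword np = n + 2 * g;
  const uword n_conv = np + L - 1;
  for (uword ch = 0; ch < nch; ++ch) {
    const double* xc = x.colptr(ch);
    for (uword i = 0; i < g; ++i) xp[i] = xc[g - i];
    std::memcpy(xp.memptr() + g, xc, sizeof(double) * n);
    for (uword i = 0; i < g; ++i) xp[g + n + i] = xc[n - 2 - i];
    double* yc = out.begin() + ch * n;
    for (uword o = 0; o < n_conv; o += step) {
      if (o + step <= 2 * g) continue;
      if (o > 2 * g + n - 1) break;
      for (uword j = 0; j < nfft; ++j) {
        const sword idx = (sword)o - (sword)(L - 1) + (sword)j;
        rbuf[j] = (idx >= 0 && idx < (sword)np) ? xp[(uword)idx] : 0.0;
      }
      ::fftw_execute(fwd);
      for (uword i = 0; i < nc; ++i) {
        const double re = cbuf[i][0], im = cbuf[i][1];
        cbuf[i][0] = re * Hre[i] - im * Him[i];
        cbuf[i][1] = re * Him[i] + im * Hre[i];
      }
      ::fftw_execute(bwd);
      const uword hi = std::min(o + step - 1, n_conv - 1);
      for (uword k = std::max(o, 2 * g); k <= hi; ++k) {
        const uword oi = k - 2 * g;
        if (oi < n) yc[oi] = rbuf[k - o + (L - 1)];
      }
    }
  }
  ::fftw_destroy_plan(fwd);
  ::fftw_destroy_plan(bwd);
  ::fftw_free(rbuf);
  ::fftw_free(cbuf);
  return out;
}

// Direct-form-II-transposed biquad cascade; coefs is nbq x 5 [b0 b1 b2 a1 a2].
// [[Rcpp::export]]
arma::vec biquad_filter_cpp(const arma::vec& x, const arma::mat& coefs) {
  vec y = x;
  for (uword q = 0; q < coefs.n_rows; ++q) {
    const double b0 = coefs(q, 0), b1 = coefs(q, 1), b2 = coefs(q, 2);
    const double a1 = coefs(q, 3), a2 = coefs(q, 4);
    double s1 = 0.0, s2 = 0.0;
    for (uword i = 0; i < y.n_elem; ++i) {
      const double xin = y[i];
      const double yo = b0 * xin + s1;
      s1 = b1 * xin - a1 * yo + s2;
      s2 = b2 * xin - a2 * yo;
      y[i] = yo;
    }
  }
  return y;
}

// Synthesize one EEG-like channel as a weighted sum of resonator-filtered
// white noise, with an optional anomaly segment during which an alternative
// resonator bank / weight vector is crossfaded in (raised-cosine ramps).
// white: driving noise; base_coefs/anom_coefs: one biquad row [b0 b1 b2 a1 a2]
// per band; anomaly sample span [anom_lo, anom_hi) (0-based), ramp_n
// crossfade samples, warmup_n samples of anomaly-filter warmup before the
// segment. Single pass over the samples; both banks share the driving noise.
// [[Rcpp::export]]
Rcpp::NumericVector synth_channel_cpp(const Rcpp::NumericVector& white_in,
                            const arma::mat& base_coefs, const arma::vec& base_w,
                            const arma::mat& anom_coefs, const arma::vec& anom_w,
                            double anom_lo, double anom_hi,
                            int ramp_n, int warmup_n, bool has_anom) {
  const vec white(const_cast<double*>(white_in.begin()),
                  (uword)white_in.size(), false, true);
  const sword n = (sword)white.n_elem;
  const uword nb = base_coefs.n_rows;
  Rcpp::NumericVector out_r((int)white.n_elem);
  vec out(out_r.begin(), white.n_elem, false, true);
  const sword lo = (sword)anom_lo, hi = (sword)anom_hi;
  const sword seg_lo = has_anom ? std::max((sword)0, lo - (sword)warmup_n) : n;
  const sword seg_hi = has_anom ? std::min(n, hi) : n;

  std::vector<double> bs1(nb, 0.0), bs2(nb, 0.0);  // base bank states
  std::vector<double> as1(nb, 0.0), as2(nb, 0.0);  // anomaly bank states
  for (sword i = 0; i < n; ++i) {
    const double xin = white[(uword)i];
    double base_mix = 0.0;
    for (uword b = 0; b < nb; ++b) {
      const double yo = base_coefs(b, 0) * xin + bs1[b];
      bs1[b] = base_coefs(b, 1) * xin - base_coefs(b, 3) * yo + bs2[b];
      bs2[b] = base_coefs(b, 2) * xin - base_coefs(b, 4) * yo;
      base_mix += base_w[b] * yo;
    }
    double y = base_mix;
    if (i >= seg_lo && i < seg_hi) {
      double anom_mix = 0.0;
      for (uword b = 0; b < nb; ++b) {
        const double yo = anom_coefs(b, 0) * xin + as1[b];
        as1[b] = anom_coefs(b, 1) * xin - anom_coefs(b, 3) * yo + as2[b];
        as2[b] = anom_coefs(b, 2) * xin - anom_coefs(b, 4) * yo;
        anom_mix += anom_w[b] * yo;
      }
      if (i >= lo) {
        double a = 1.0;
        if (i - lo < ramp_n)
          a = 0.5 * (1.0 - std::cos(M_PI * (double)(i - lo + 1) / (double)ramp_n));
        if (hi - 1 - i < ramp_n) {
          const double a2 = 0.5 * (1.0 - std::cos(M_PI * (double)(hi - i) / (double)ramp_n));
          a = std::min(a, a2);
        }
        y = (1.0 - a) * base_mix + a * anom_mix;
      }
    }
    out[(uword)i] = y;
  }
  return out_r;
}
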