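# Shared single-channel DSP primitives. All operate on plain numeric vectors;
# higher-level functions handle channel/trial bookkeeping.

#' Zero-phase spectral band-pass of a numeric vector
#'
#' Multiplies the FFT of the signal by a band mask with raised-cosine edges
#' (default half-width 1 Hz), giving a band-limited reconstruction with no
#' phase distortion. Used for band extraction (fatigue index, rhythm entropy)
#' and for narrowband filtering ahead of phase estimation.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz; `lo = 0` gives a low-pass.
#' @param transition raised-cosine edge half-width in Hz.
#' @return Filtered numeric vector of the same length.
#' @export
band_filter_fft <- function(x, fs, lo, hi, transition = 1) {
  n <- length(x)
  stopifnot(n > 1, hi > lo, hi <= fs / 2)
  f <- abs(seq(0, fs, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  mask <- raised_cosine_mask(f, lo, hi, transition)
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

raised_cosine_mask <- function(f, lo, hi, transition) {
  m <- numeric(length(f))
  m[f >= lo & f <= hi] <- 1
  if (transition > 0) {
    lo_ramp <- f > lo - transition & f < lo
    m[lo_ramp] <- 0.5 * (1 + cos(pi * (lo - f[lo_ramp]) / transition))
    hi_ramp <- f > hi & f < hi + transition
    m[hi_ramp] <- 0.5 * (1 + cos(pi * (f[hi_ramp] - hi) / transition))
  }
  m
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal (quadrature) of `x`: positive
#' frequencies doubled, negative zeroed, DC/Nyquist kept.
#'
#' @param x numeric vector.
#' @return Complex vector, `Re` equals `x` up to rounding.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n > 1)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Welch power spectral density estimate
#'
#' Hann-windowed averaged periodogram with 1 s segments and 50% overlap by
#' default; one-sided density scaled so that `sum(psd) * df` equals the
#' signal variance (Parseval).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param seg_s segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return A [tibble::tibble] with columns `freq` (Hz) and `psd` (power/Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 1, overlap = 0.5) {
  nseg <- round(seg_s * fs)
  stopifnot(length(x) >= nseg, nseg >= 8)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(w^2)
  nfreq <- nseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- abs(stats::fft(seg))^2 / (u * fs)
    half <- P[seq_len(nfreq)]
    # fold negative frequencies into the one-sided density
    if (nseg %% 2 == 0) half[2:(nfreq - 1L)] <- 2 * half[2:(nfreq - 1L)]
    else half[2:nfreq] <- 2 * half[2:nfreq]
    acc <- acc + half
  }
  tibble::tibble(freq = seq(0, by = fs / nseg, length.out = nfreq),
                 psd = acc / length(starts))
}

#' Integrated band power from a PSD table
#'
#' @param psd tibble from [welch_psd()].
#' @param band `c(lo, hi)` in Hz (inclusive).
#' @return Scalar power.
#' @export
psd_band_power <- function(psd, band) {
  df <- psd$freq[2] - psd$freq[1]
  sum(psd$psd[psd$freq >= band[1] & psd$freq <= band[2]]) * df
}

#' 1/f (pink) noise
#'
#' Spectral synthesis: white Gaussian spectrum shaped by f^(-1/2) amplitude
#' (1/f power), unit standard deviation.
#'
#' @param n samples.
#' @return Numeric vector, sd approximately 1.
#' @keywords internal
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  k <- pmin(k, n - k)                 # symmetric frequency index
  shape <- c(0, 1 / sqrt(k[-1]))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Unit-variance band-limited Gaussian noise
#' @keywords internal
band_noise <- function(n, fs, lo, hi) {
  x <- band_filter_fft(stats::rnorm(n), fs, lo, hi)
  x / stats::sd(x)
}
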