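#' Instantaneous phase of a narrowband signal
#'
#' Zero-phase spectral band-pass followed by the analytic signal; the phase
#' is the argument of the analytic signal. The first and last 10% of samples
#' (filter/Hilbert edge effects) are discarded by default.
#'
#' @param x numeric vector, at least 2 s long.
#' @param fs sampling rate (Hz).
#' @param band `c(lo, hi)` Hz, inside the Nyquist range.
#' @param trim fraction of samples dropped at each end.
#' @return A `phase_series`: list with `phi` (radians), `fs`, `band`, `trim`.
#' @export
instantaneous_phase <- function(x, fs, band = c(8, 13), trim = 0.1) {
  if (length(x) < 2 * fs) stop("signal must be at least 2 s long")
  if (band[2] >= fs / 2 || band[1] <= 0)
    stop("band must lie inside (0, Nyquist)")
  xb <- band_filter_fft(x, fs, band[1], band[2])
  if (stats::sd(xb) == 0)
    stop("degenerate input: zero narrowband signal, phase undefined")
  z <- analytic_signal(xb)
  n <- length(z)
  keep <- seq.int(floor(n * trim) + 1L, n - floor(n * trim))
  structure(list(phi = Arg(z[keep]), fs = fs, band = band, trim = trim),
            class = "phase_series")
}

#' Unwrap a phase sequence
#'
#' Removes 2*pi discontinuities so that the phase evolves continuously.
#'
#' @param phi numeric vector of phases (radians).
#' @return Unwrapped numeric vector.
#' @export
unwrap_phase <- function(phi) {
  d <- diff(phi)
  phi + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

#' Phase-locking value
#'
#' `PLV = |mean(exp(1i * (phi_x - phi_y)))|`, equivalently
#' `sqrt(mean(cos(dphi))^2 + mean(sin(dphi))^2)`. 1 means perfect phase
#' synchronization, 0 none; invariant to a constant phase offset.
#'
#' @param phi_x,phi_y `phase_series` objects or numeric phase vectors of
#'   equal length (radians).
#' @return Scalar in `[0, 1]`.
#' @export
plv <- function(phi_x, phi_y) {
  if (inherits(phi_x, "phase_series")) phi_x <- phi_x$phi
  if (inherits(phi_y, "phase_series")) phi_y <- phi_y$phi
  if (length(phi_x) != length(phi_y))
    stop("phase series lengths differ (", length(phi_x), " vs ",
         length(phi_y), ")")
  d <- phi_x - phi_y
  min(1, sqrt(mean(cos(d))^2 + mean(sin(d))^2))
}

#' PLV panel: one parietal channel against a frontal set
#'
#' Alpha-band (default) phase-locking value between the fatigue-sensitive
#' parietal channel and each frontal channel, computed per trial and
#' averaged over trials (avoiding phase jumps at trial boundaries).
#'
#' @param epochs an `eeg_epochs`.
#' @param parietal single parietal channel label.
#' @param frontal frontal channel labels, default [mi_frontal_set()].
#' @param band narrowband filter edges (Hz).
#' @param trim edge fraction discarded per trial, see
#'   [instantaneous_phase()].
#' @return A [tibble::tibble]: `parietal`, `frontal`, `plv`, `n_trials`,
#'   `n_samples` (per trial after trimming).
#' @export
plv_panel <- function(epochs, parietal, frontal = mi_frontal_set(),
                      band = c(8, 13), trim = 0.1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  miss <- setdiff(c(parietal, frontal), epochs$labels)
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  pi_ <- match(parietal, epochs$labels)
  n_trials <- dim(epochs$data)[3]
  vals <- matrix(0, nrow = n_trials, ncol = length(frontal))
  n_keep <- NA_integer_
  for (t in seq_len(n_trials)) {
    php <- instantaneous_phase(epochs$data[pi_, , t], epochs$fs, band, trim)
    n_keep <- length(php$phi)
    for (j in seq_along(frontal)) {
      fj <- match(frontal[j], epochs$labels)
      phf <- instantaneous_phase(epochs$data[fj, , t], epochs$fs, band, trim)
      vals[t, j] <- plv(php, phf)
    }
  }
  tibble::tibble(parietal = parietal, frontal = frontal,
                 plv = colMeans(vals), n_trials = n_trials,
                 n_samples = n_keep)
}
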