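#' Morlet time-frequency map of one channel
#'
#' Complex Morlet wavelet transform (default 5 cycles) of every trial of one
#' channel, power averaged across the trials of one class (or all trials).
#' Frequencies on a linear grid.
#'
#' @param epochs an `eeg_epochs`.
#' @param channel channel label.
#' @param freqs frequency grid (Hz), default 4-35 Hz in 1 Hz steps.
#' @param n_cycles wavelet width in cycles.
#' @param class `"left"`, `"right"` or `NULL` for all trials.
#' @return An `eeg_tfr`: list with `power` (freqs x times matrix, uV^2),
#'   `freqs`, `times` (s, epoch clock), `baseline`, `channel`, `normalized`.
#' @export
tf_morlet <- function(epochs, channel, freqs = 4:35, n_cycles = 5,
                      class = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  ci <- match(channel, epochs$labels)
  if (is.na(ci)) stop("unknown channel: ", channel)
  if (any(freqs <= 0 | freqs >= epochs$fs / 2))
    stop("freqs must lie inside (0, fs/2)")
  trials <- seq_along(epochs$classes)
  if (!is.null(class)) trials <- trials[epochs$classes == class]
  if (!length(trials)) stop("no trials of class ", class)

  n <- dim(epochs$data)[2]
  fs <- epochs$fs
  nfft <- stats::nextn(2L * n, 2)
  fax <- seq(0, fs, length.out = nfft + 1)[seq_len(nfft)]
  pow <- matrix(0, nrow = length(freqs), ncol = n)
  # frequency-domain Gaussian of each Morlet wavelet (analytic, unit gain at f0)
  kernels <- lapply(freqs, function(f0) {
    sigma_f <- f0 / n_cycles
    2 * exp(-0.5 * ((fax - f0) / sigma_f)^2)
  })
  for (t in trials) {
    X <- stats::fft(c(epochs$data[ci, , t], numeric(nfft - n)))
    for (k in seq_along(freqs)) {
      z <- stats::fft(X * kernels[[k]], inverse = TRUE)[seq_len(n)] / nfft
      pow[k, ] <- pow[k, ] + abs(z)^2
    }
  }
  structure(list(power = pow / length(trials), freqs = freqs,
                 times = epochs$window[1] + (seq_len(n) - 1) / fs,
                 baseline = epochs$baseline, channel = channel,
                 normalized = FALSE),
            class = "eeg_tfr")
}

#' @export
print.eeg_tfr <- function(x, ...) {
  cat(sprintf("<eeg_tfr> channel %s: %d freqs (%g-%g Hz) x %d times [%g, %g] s%s\n",
              x$channel, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times),
              if (x$normalized) " (baseline-normalized)" else ""))
  invisible(x)
}

#' Quantify ERD/ERS from a time-frequency map
#'
#' Relative power change `(P - P_base) / P_base`, where `P_base` is the mean
#' baseline-window power of each frequency row, averaged over the requested
#' band and time window. Negative values are desynchronization (ERD),
#' positive are synchronization (ERS); the relative-change definition is
#' bounded below by -1 and invariant to global amplitude scaling.
#'
#' @param tfr an `eeg_tfr` from [tf_morlet()].
#' @param band `c(lo, hi)` Hz, inside the map's frequency grid.
#' @param window `c(t0, t1)` s, inside the map's time axis.
#' @return A one-row [tibble::tibble]: `channel`, `band_lo`, `band_hi`,
#'   `t0`, `t1`, `erd`.
#' @export
erd_quantify <- function(tfr, band, window) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  fi <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  ti <- which(tfr$times >= window[1] & tfr$times < window[2])
  bi <- which(tfr$times >= tfr$baseline[1] & tfr$times < tfr$baseline[2])
  if (!length(fi)) stop("band outside the map's frequency grid")
  if (!length(ti)) stop("window outside the map's time axis")
  base <- rowMeans(tfr$power[fi, bi, drop = FALSE])
  if (any(base <= 0)) stop("degenerate input: zero baseline power")
  rel <- sweep(tfr$power[fi, ti, drop = FALSE], 1, base, "/") - 1
  tibble::tibble(channel = tfr$channel, band_lo = band[1], band_hi = band[2],
                 t0 = window[1], t1 = window[2], erd = mean(rel))
}

#' Two-sample pooled-variance t-test for ERD values
#'
#' Classical two-sided equal-variance t-test (df = n_a + n_b - 2) comparing
#' ERD values from two time windows or groups — e.g. the 0-1 s preparation
#' period against the 1-2.5 s imagery-execution period.
#'
#' @param group_a,group_b numeric vectors of ERD values (each length >= 2).
#' @return A one-row [tibble::tibble]: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
erd_ttest <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::var(group_a) + stats::var(group_b) == 0)
    stop("zero pooled variance")
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b))
}
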