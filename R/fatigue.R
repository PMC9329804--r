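#' Band-limited decomposition of one signal into theta/alpha/beta power
#'
#' Reconstructs the signal in each band by zero-phase spectral filtering and
#' returns the energy (sum of squared samples) per band.
#'
#' @param x numeric vector (one channel of one epoch).
#' @param fs sampling rate (Hz).
#' @param bands named list of band edges, see [mi_bands()].
#' @return A one-row [tibble::tibble] with one power column per band.
#' @export
band_decompose <- function(x, fs, bands = mi_bands()) {
  if (length(x) < fs) stop("signal shorter than 1 s")
  p <- vapply(bands, function(b) band_energy(band_filter_fft(x, fs, b[1], b[2])),
              numeric(1))
  tibble::as_tibble(as.list(p))
}

#' Fused fatigue index
#'
#' Average of the two classical band-ratio fatigue indicators,
#' `(theta + alpha) / beta` and `theta / beta`; both rise with fatigue, and
#' the unweighted mean preserves their monotonicity and units. A weight
#' `w` returns `w * (theta + alpha)/beta + (1 - w) * theta/beta`.
#'
#' @param theta,alpha,beta band powers (vectors of equal length), `beta > 0`.
#' @param w weight on the `(theta + alpha)/beta` component, default 0.5.
#' @return Numeric vector of fused index values.
#' @export
fatigue_index <- function(theta, alpha, beta, w = 0.5) {
  stopifnot(length(theta) == length(alpha), length(alpha) == length(beta),
            w >= 0, w <= 1)
  if (any(beta <= 0)) stop("beta power must be positive")
  if (any(theta < 0 | alpha < 0)) stop("band powers must be non-negative")
  w * (theta + alpha) / beta + (1 - w) * theta / beta
}

#' Per-trial fatigue time course
#'
#' For each requested channel and trial, band powers are estimated from a
#' Welch power spectral density (1 s Hann segments, 50% overlap) and fused
#' into the composite fatigue index. The `index` column of the returned
#' series is the mean over channels per trial; the per-channel values are
#' kept in the `by_channel` table.
#'
#' @param epochs an `eeg_epochs`.
#' @param channels channel labels (default: the parietal candidates present).
#' @param bands band edges, see [mi_bands()].
#' @param w fusion weight, see [fatigue_index()].
#' @return A `fatigue_series`: list with `index` (tibble: `trial`, `index`),
#'   `by_channel` (tibble: `channel`, `trial`, theta/alpha/beta, `index`),
#'   `session_mean`, `fs`, `threshold` fields filled by
#'   [select_sensitive_channels()].
#' @export
fatigue_timecourse <- function(epochs, channels = NULL, bands = mi_bands(),
                               w = 0.5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(channels))
    channels <- intersect(mi_parietal_candidates(), epochs$labels)
  if (!length(channels)) stop("empty channel set")
  miss <- setdiff(channels, epochs$labels)
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  n_trials <- dim(epochs$data)[3]
  rows <- vector("list", length(channels) * n_trials)
  k <- 0L
  for (ch in channels) {
    ci <- match(ch, epochs$labels)
    for (t in seq_len(n_trials)) {
      psd <- welch_psd(epochs$data[ci, , t], epochs$fs)
      p <- vapply(bands, function(b) psd_band_power(psd, b), numeric(1))
      k <- k + 1L
      rows[[k]] <- tibble::tibble(channel = ch, trial = epochs$trial_order[t],
                                  theta = p[["theta"]], alpha = p[["alpha"]],
                                  beta = p[["beta"]])
    }
  }
  by_channel <- dplyr::bind_rows(rows)
  by_channel$index <- fatigue_index(by_channel$theta, by_channel$alpha,
                                    by_channel$beta, w = w)
  index <- by_channel |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(index = mean(.data$index), .groups = "drop") |>
    dplyr::arrange(.data$trial)
  structure(list(index = index, by_channel = by_channel,
                 session_mean = mean(index$index),
                 channels = channels, selected = NULL, threshold = NULL),
            class = "fatigue_series")
}

#' @export
print.fatigue_series <- function(x, ...) {
  cat(sprintf("<fatigue_series> %d channels x %d trials; session mean %.3f\n",
              length(x$channels), nrow(x$index), x$session_mean))
  if (!is.null(x$selected))
    cat("  fatigue-sensitive (r > ", x$threshold, "): ",
        paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select fatigue-sensitive channels
#'
#' Pearson correlation between each channel's per-trial fatigue index and
#' the trial index ("experimental time"); channels with `r > threshold` are
#' fatigue-sensitive. The test is one-sided by construction (fatigue indices
#' are expected to rise); a constant index series is treated as `r = 0`.
#'
#' @param series a `fatigue_series` from [fatigue_timecourse()].
#' @param threshold correlation threshold, default 0.75.
#' @return The `fatigue_series` with `selected`, `threshold` and a
#'   `correlations` tibble (`channel`, `r`, `selected`) filled in.
#' @export
select_sensitive_channels <- function(series, threshold = 0.75) {
  stopifnot(inherits(series, "fatigue_series"))
  n_trials <- length(unique(series$by_channel$trial))
  if (n_trials < 3) stop("need at least 3 trials per channel")
  cors <- series$by_channel |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(r = if (stats::sd(.data$index) == 0) 0
                     else stats::cor(.data$index, .data$trial),
                     .groups = "drop") |>
    dplyr::mutate(selected = .data$r > threshold)
  series$correlations <- cors
  series$selected <- cors$channel[cors$selected]
  series$threshold <- threshold
  series
}
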