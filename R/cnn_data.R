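# Sample preparation for the compact motor-imagery CNN: channel
# rearrangement, sliding-window + decimation augmentation, per-sample
# standardization, and the trial-grouped train/test split.

#' Reorder epoch channels for the CNN
#'
#' Reorders the channel axis to `order` (default the fixed 32-channel layout
#' of [mi_channel_order32()], left hemisphere to right), so that spatially
#' adjacent electrodes are adjacent rows of the input tensor.
#'
#' @param epochs an `eeg_epochs` containing every label in `order`.
#' @param order character vector of channel labels.
#' @return An `eeg_epochs` restricted to `order`, in that order.
#' @export
rearrange_channels <- function(epochs, order = mi_channel_order32()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  miss <- setdiff(order, epochs$labels)
  if (length(miss))
    stop("channel(s) missing from epochs: ", paste(miss, collapse = ", "))
  idx <- match(order, epochs$labels)
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$labels <- order
  epochs
}

#' Globally standardize one sample
#'
#' Subtracts the mean of all values in the sample and divides by their
#' standard deviation, so the whole channels x time matrix has mean 0 and
#' standard deviation 1. Affine-invariant and idempotent.
#'
#' @param x numeric matrix (channels x time).
#' @return Standardized matrix.
#' @export
standardize_sample <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("constant sample: standard deviation is zero")
  (x - mean(x)) / s
}

#' Sliding-window + decimation augmentation
#'
#' Expands each trial epoch into `length(starts_s) * decim` samples: a
#' window of `window_pts` consecutive points is taken at each start offset,
#' and each window is split into `decim` interleaved sub-series (every
#' `decim`-th point, phases `0..decim-1`). With the defaults at 1,024 Hz —
#' 2,048-point (2 s) windows starting at 0, 1 and 2 s, decimation by 4 —
#' every 5 s trial yields 12 samples of `channels x window_pts/decim`
#' containing only original data points. Each sample is then standardized.
#'
#' @param epochs an `eeg_epochs` (typically after [rearrange_channels()]).
#' @param window_pts window length in points.
#' @param starts_s window start offsets in seconds from epoch start.
#' @param decim decimation factor (also the number of phases per window).
#' @return An `mi_samples`: list with `x` (channels x time x sample array),
#'   `meta` (tibble: `sample`, `trial`, `class`, `start_s`, `phase`) and
#'   `labels`.
#' @export
augment_sliding <- function(epochs, window_pts = 2048, starts_s = c(0, 1, 2),
                            decim = 4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  fs <- epochs$fs
  starts <- round(starts_s * fs)
  need <- max(starts) + window_pts
  if (need > d[2])
    stop("epoch too short: need ", need, " points, have ", d[2])
  out_len <- window_pts %/% decim
  n_per <- length(starts) * decim
  n_out <- n_per * d[3]
  x <- array(0, dim = c(d[1], out_len, n_out))
  meta <- vector("list", n_out)
  k <- 0L
  for (t in seq_len(d[3])) {
    for (s in seq_along(starts)) {
      for (ph in seq_len(decim) - 1L) {
        cols <- starts[s] + ph + seq(1L, window_pts, by = decim)
        k <- k + 1L
        x[, , k] <- standardize_sample(epochs$data[, cols, t])
        meta[[k]] <- tibble::tibble(sample = k, trial = epochs$trial_order[t],
                                    class = epochs$classes[t],
                                    start_s = starts_s[s], phase = ph)
      }
    }
  }
  structure(list(x = x, meta = dplyr::bind_rows(meta), labels = epochs$labels),
            class = "mi_samples")
}

#' @export
print.mi_samples <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<mi_samples> %d samples of %d x %d from %d trials\n",
              d[3], d[1], d[2], length(unique(x$meta$trial))))
  invisible(x)
}

subset_samples <- function(samples, keep) {
  structure(list(x = samples$x[, , keep, drop = FALSE],
                 meta = samples$meta[keep, ], labels = samples$labels),
            class = "mi_samples")
}

#' Trial-grouped train/test split
#'
#' Splits at the parent-trial level so that all augmented children of a
#' trial land on the same side — the test set never shares a trial with the
#' training set. With 160 trials and the default 80/20 ratio this gives
#' 1,536 training and 384 test samples.
#'
#' @param samples an `mi_samples` from [augment_sliding()].
#' @param ratio training fraction in (0, 1).
#' @param seed RNG seed for the trial shuffle.
#' @return List with elements `train` and `test` (`mi_samples`).
#' @export
split_train_test <- function(samples, ratio = 0.8, seed = 1) {
  stopifnot(inherits(samples, "mi_samples"), ratio > 0, ratio < 1)
  trials <- unique(samples$meta$trial)
  set.seed(seed)
  n_train <- floor(length(trials) * ratio)
  train_trials <- sample(trials, n_train)
  in_train <- samples$meta$trial %in% train_trials
  list(train = subset_samples(samples, which(in_train)),
       test = subset_samples(samples, which(!in_train)))
}
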