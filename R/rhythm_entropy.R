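#' Energy of a band-reconstructed signal
#'
#' Sum of squared samples, `Power = sum(S(x)^2)` over the trial.
#'
#' @param x numeric vector.
#' @return Scalar energy.
#' @export
band_energy <- function(x) {
  if (!length(x)) stop("empty signal")
  sum(x^2)
}

#' Normalize band energies to shares
#'
#' `p_j = Power_j / sum(Power_j)`; the shares sum to one.
#'
#' @param powers numeric vector of non-negative band energies.
#' @return Numeric vector of shares.
#' @export
normalize_powers <- function(powers) {
  if (any(powers < 0)) stop("band energies must be non-negative")
  s <- sum(powers)
  if (s == 0) stop("all band energies are zero")
  powers / s
}

#' Rhythm entropy (bits)
#'
#' Shannon entropy `En = -sum(p_j * log2(p_j))` of the normalized band-energy
#' shares, with `0 * log2(0) = 0`. Bounded in `[0, log2(k)]`; lower values
#' mean more ordered (band-concentrated) activity.
#'
#' @param p probability vector (non-negative, sums to 1 within 1e-6).
#' @return Entropy in bits.
#' @export
rhythm_entropy <- function(p) {
  if (any(p < 0)) stop("shares must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("shares must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz])) + 0   # + 0 avoids IEEE negative zero
}

#' Per-trial rhythm entropy of a set of channels
#'
#' For each channel and trial: band-limited reconstruction in theta, alpha
#' and beta, energies, shares, entropy.
#'
#' @param epochs an `eeg_epochs`.
#' @param channels channel labels, default the six frontal channels present.
#' @param bands band edges, see [mi_bands()].
#' @return Tibble: `channel`, `trial`, `entropy` plus the three share
#'   columns `p_theta`, `p_alpha`, `p_beta`.
#' @export
entropy_timecourse <- function(epochs, channels = NULL, bands = mi_bands()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(channels)) channels <- intersect(mi_frontal_set(), epochs$labels)
  miss <- setdiff(channels, epochs$labels)
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  if (!length(channels)) stop("empty channel set")
  n_trials <- dim(epochs$data)[3]
  out <- vector("list", length(channels) * n_trials)
  k <- 0L
  for (ch in channels) {
    ci <- match(ch, epochs$labels)
    for (t in seq_len(n_trials)) {
      bp <- band_decompose(epochs$data[ci, , t], epochs$fs, bands)
      p <- normalize_powers(unlist(bp))
      k <- k + 1L
      out[[k]] <- tibble::tibble(channel = ch, trial = epochs$trial_order[t],
                                 p_theta = p[[1]], p_alpha = p[[2]],
                                 p_beta = p[[3]],
                                 entropy = rhythm_entropy(p))
    }
  }
  dplyr::bind_rows(out)
}

#' Awake vs fatigue rhythm-entropy summary
#'
#' The first 20 trials (acquisition order) are treated as the awake state
#' and the last 20 as the fatigue state; per-trial rhythm entropy on the six
#' frontal channels is averaged within each state across channels.
#'
#' @param epochs an `eeg_epochs` with at least 40 trials.
#' @param channels frontal channels, default [mi_frontal_set()].
#' @param bands band edges.
#' @param n_state trials per state (default 20).
#' @return An `entropy_report`: list with `per_trial` (tibble from
#'   [entropy_timecourse()]), `awake_mean`, `fatigue_mean`, `delta`
#'   (fatigue - awake, bits) and per-state standard errors.
#' @export
awake_fatigue_summary <- function(epochs, channels = mi_frontal_set(),
                                  bands = mi_bands(), n_state = 20) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n_trials <- dim(epochs$data)[3]
  if (n_trials < 2 * n_state)
    stop("need at least ", 2 * n_state, " trials, got ", n_trials)
  tc <- entropy_timecourse(epochs, channels, bands)
  ord <- sort(unique(tc$trial))
  awake_ids <- ord[seq_len(n_state)]
  fatigue_ids <- ord[(length(ord) - n_state + 1):length(ord)]
  per_trial_mean <- tc |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(entropy = mean(.data$entropy), .groups = "drop")
  aw <- per_trial_mean$entropy[per_trial_mean$trial %in% awake_ids]
  fa <- per_trial_mean$entropy[per_trial_mean$trial %in% fatigue_ids]
  structure(list(per_trial = tc,
                 awake_mean = mean(aw), fatigue_mean = mean(fa),
                 awake_se = stats::sd(aw) / sqrt(length(aw)),
                 fatigue_se = stats::sd(fa) / sqrt(length(fa)),
                 delta = mean(fa) - mean(aw),
                 channels = channels, n_state = n_state),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("<entropy_report> awake %.3f +/- %.3f, fatigue %.3f +/- %.3f bits (delta %+.3f)\n",
              x$awake_mean, x$awake_se, x$fatigue_mean, x$fatigue_se, x$delta))
  invisible(x)
}
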