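#' Configuration for a synthetic motor-imagery EEG session
#'
#' Describes one recording session of cued left/right-hand motor imagery:
#' `n_runs` runs of `trials_per_run` trials, each trial a 3 s blank screen,
#' a 3 s video cue and 5 s of imagery, sampled at `fs` Hz. The generated
#' signal is pink (1/f) background noise plus band-limited theta/alpha/beta
#' oscillators per channel, with three planted effects that downstream
#' estimators are expected to recover:
#'
#' * **ERD** — alpha and beta power on the contralateral motor channel (C3
#'   for right-hand trials, C4 for left) is attenuated by `erd_attenuation`
#'   from `erd_onset` s after imagery onset to the end of imagery, so the
#'   0-1 s baseline keeps full power.
#' * **Fatigue drift** — band powers on `drift_channels` change linearly
#'   with trial index; `fatigue_drift[b]` is the fractional power change
#'   from the first to the last trial in band `b`.
#' * **Phase coupling** — each `(parietal, frontal)` pair in `coupled_pairs`
#'   shares a common alpha-band oscillator with weight `sqrt(strength)`,
#'   making the phase-locking value a monotone function of `strength`.
#'
#' @param n_runs,trials_per_run session size (defaults 4 x 40 = 160 trials).
#' @param fs sampling rate, Hz.
#' @param channels channel labels (10-20/10-10); default 64-channel montage.
#' @param blank_s,cue_s,imagery_s trial segment durations in seconds.
#' @param rest_every,rest_s a rest slot every `rest_every` trials lasting
#'   `rest_s` seconds (default 0 s: the slot exists in the schedule but is
#'   zero-length, keeping files small).
#' @param band_amp named numeric: oscillator amplitudes (uV) for theta,
#'   alpha, beta.
#' @param erd_attenuation fraction in `[0, 1)`: relative alpha/beta power
#'   reduction during imagery on the contralateral motor channel.
#' @param erd_channels named pair: which channel carries the ERD for each
#'   class (contralateral convention).
#' @param erd_onset seconds after imagery onset at which attenuation starts.
#' @param fatigue_drift named numeric: fractional power change per band
#'   across the session (e.g. `theta = 1` doubles theta power by the last
#'   trial) on `drift_channels`.
#' @param drift_channels channels carrying the fatigue drift; labels not in
#'   `channels` are ignored, so the default (all parietal candidates) works
#'   for reduced montages too.
#' @param coupled_pairs data frame with columns `parietal`, `frontal`,
#'   `strength` (each strength in `[0, 1]`).
#' @param noise_sd pink-background standard deviation (uV).
#' @param bands band edges, see [mi_bands()].
#' @param seed integer RNG seed.
#' @return A `session_config` list (validated).
#' @export
session_config <- function(n_runs = 4,
                           trials_per_run = 40,
                           fs = 1024,
                           channels = mi_montage64(),
                           blank_s = 3, cue_s = 3, imagery_s = 5,
                           rest_every = 10, rest_s = 0,
                           band_amp = c(theta = 4, alpha = 8, beta = 4),
                           erd_attenuation = 0.5,
                           erd_channels = c(right = "C3", left = "C4"),
                           erd_onset = 1,
                           fatigue_drift = c(theta = 1, alpha = 0.3, beta = -0.2),
                           drift_channels = mi_parietal_candidates(),
                           coupled_pairs = data.frame(
                             parietal = "P6",
                             frontal = mi_frontal_set(),
                             strength = 0.4),
                           noise_sd = 1,
                           bands = mi_bands(),
                           seed = 1L) {
  cfg <- list(n_runs = as.integer(n_runs),
              trials_per_run = as.integer(trials_per_run),
              fs = fs, channels = channels,
              blank_s = blank_s, cue_s = cue_s, imagery_s = imagery_s,
              rest_every = as.integer(rest_every), rest_s = rest_s,
              band_amp = band_amp,
              erd_attenuation = erd_attenuation,
              erd_channels = erd_channels, erd_onset = erd_onset,
              fatigue_drift = fatigue_drift,
              drift_channels = drift_channels,
              coupled_pairs = tibble::as_tibble(coupled_pairs),
              noise_sd = noise_sd, bands = bands,
              seed = as.integer(seed))
  class(cfg) <- "session_config"
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  stopifnot(cfg$n_runs >= 1, cfg$trials_per_run >= 1, cfg$fs > 0,
            cfg$blank_s >= 0, cfg$cue_s >= 0, cfg$imagery_s > 0,
            cfg$rest_s >= 0, cfg$noise_sd >= 0)
  if (cfg$erd_attenuation < 0 || cfg$erd_attenuation >= 1)
    stop("erd_attenuation must lie in [0, 1)")
  if (anyDuplicated(cfg$channels))
    stop("channel labels must be unique")
  bad <- setdiff(cfg$erd_channels, cfg$channels)
  if (length(bad))
    stop("unknown ERD channel label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(c(cfg$coupled_pairs$parietal, cfg$coupled_pairs$frontal),
                 cfg$channels)
  if (length(bad))
    stop("unknown channel label(s) in coupled_pairs: ",
         paste(bad, collapse = ", "))
  if (any(cfg$coupled_pairs$strength < 0 | cfg$coupled_pairs$strength > 1))
    stop("coupling strength must lie in [0, 1]")
  invisible(cfg)
}

#' Age-group generator presets
#'
#' Two qualitative spectral profiles observed in young vs elderly motor
#' imagery: the "young" preset has moderately even frontal band powers that
#' concentrate into theta over the session (rhythm entropy falls) and strong
#' parietal-frontal alpha coupling through P6; the "elderly" preset starts
#' theta-dominant and flattens towards even shares (rhythm entropy rises),
#' with weak coupling through P2. Further arguments override any
#' [session_config()] field.
#'
#' @param group `"young"` or `"elderly"`.
#' @param ... overrides passed to [session_config()].
#' @return A `session_config`.
#' @export
session_preset <- function(group = c("young", "elderly"), ...) {
  group <- match.arg(group)
  frontal <- mi_frontal_set()
  base <- if (group == "young") {
    list(band_amp = c(theta = 6, alpha = 7, beta = 5),
         fatigue_drift = c(theta = 2.5, alpha = -0.5, beta = -0.5),
         drift_channels = c(mi_parietal_candidates(), frontal),
         coupled_pairs = data.frame(parietal = "P6", frontal = frontal,
                                    strength = 0.7))
  } else {
    list(band_amp = c(theta = 10, alpha = 5, beta = 3.5),
         fatigue_drift = c(theta = -0.3, alpha = 1, beta = 4),
         drift_channels = c(mi_parietal_candidates(), frontal),
         coupled_pairs = data.frame(parietal = "P2", frontal = frontal,
                                    strength = 0.25))
  }
  args <- utils::modifyList(base, list(...))
  do.call(session_config, args)
}

#' Generate a synthetic motor-imagery EEG session
#'
#' Deterministic given `config$seed`. Left/right classes are balanced within
#' each run and shuffled; event markers are placed at every imagery onset.
#'
#' @param config a [session_config()].
#' @return An `eeg_recording`: list with `data` (channels x samples matrix,
#'   uV), `fs`, `labels`, and `events` (tibble: `sample`, `trial`, `class`).
#' @export
generate_session <- function(config) {
  validate_session_config(config)
  cfg <- config
  set.seed(cfg$seed)
  fs <- cfg$fs
  n_trials <- cfg$n_runs * cfg$trials_per_run

  # --- schedule -------------------------------------------------------------
  trial_len <- round((cfg$blank_s + cfg$cue_s + cfg$imagery_s) * fs)
  rest_len <- round(cfg$rest_s * fs)
  starts <- integer(n_trials)
  pos <- 0L
  for (t in seq_len(n_trials)) {
    starts[t] <- pos
    pos <- pos + trial_len
    if (cfg$rest_every > 0 && t %% cfg$rest_every == 0L) pos <- pos + rest_len
  }
  n_samp <- pos
  onset <- starts + round((cfg$blank_s + cfg$cue_s) * fs) + 1L  # 1-based

  classes <- unlist(lapply(seq_len(cfg$n_runs), function(r) {
    half <- cfg$trials_per_run %/% 2
    cls <- c(rep("left", half), rep("right", cfg$trials_per_run - half))
    sample(cls)
  }))

  events <- tibble::tibble(sample = onset, trial = seq_len(n_trials),
                           class = classes)

  # --- per-trial drift multipliers (power scale) ----------------------------
  denom <- max(1L, n_trials - 1L)
  drift_mult <- function(slope) 1 + slope * (seq_len(n_trials) - 1L) / denom
  band_names <- names(cfg$bands)
  # amplitude envelope value per sample given per-trial power multipliers
  trial_of_sample <- rep(NA_integer_, n_samp)
  for (t in seq_len(n_trials)) {
    span <- starts[t] + seq_len(trial_len)
    trial_of_sample[span] <- t
  }
  trial_of_sample[is.na(trial_of_sample)] <-
    findInterval(which(is.na(trial_of_sample)), starts + 1L)

  # ERD gate per class: samples attenuated on the contralateral channel
  erd_gate <- list()
  for (cl in c("left", "right")) {
    idx <- integer(0)
    sel <- which(classes == cl)
    for (t in sel) {
      a0 <- onset[t] + round(cfg$erd_onset * fs)
      a1 <- onset[t] + round(cfg$imagery_s * fs) - 1L
      idx <- c(idx, a0:a1)
    }
    erd_gate[[cl]] <- idx
  }

  # --- shared alpha oscillators for coupled hubs ----------------------------
  pairs <- cfg$coupled_pairs
  hub_common <- list()
  hub_strength <- list()
  if (nrow(pairs)) {
    for (hub in unique(pairs$parietal)) {
      s <- unique(pairs$strength[pairs$parietal == hub])
      if (length(s) > 1)
        stop("coupled_pairs: hub ", hub, " has differing strengths")
      hub_common[[hub]] <- band_noise(n_samp, fs, cfg$bands$alpha[1],
                                      cfg$bands$alpha[2])
      hub_strength[[hub]] <- s
    }
  }
  # channel -> (hub, strength) for the alpha component
  coupling_of <- function(ch) {
    if (!nrow(pairs)) return(NULL)
    if (ch %in% pairs$parietal)
      return(list(common = hub_common[[ch]], s = hub_strength[[ch]]))
    row <- which(pairs$frontal == ch)
    if (length(row) == 1) {
      hub <- pairs$parietal[row]
      return(list(common = hub_common[[hub]], s = pairs$strength[row]))
    }
    if (length(row) > 1)
      stop("coupled_pairs: frontal channel ", ch, " appears in several pairs")
    NULL
  }

  # --- synthesis ------------------------------------------------------------
  data <- matrix(0, nrow = length(cfg$channels), ncol = n_samp,
                 dimnames = list(cfg$channels, NULL))
  drifting <- cfg$channels %in% cfg$drift_channels
  per_trial_amp <- lapply(band_names, function(b) {
    slope <- if (b %in% names(cfg$fatigue_drift)) cfg$fatigue_drift[[b]] else 0
    sqrt(pmax(drift_mult(slope), 0))
  })
  names(per_trial_amp) <- band_names

  for (i in seq_along(cfg$channels)) {
    ch <- cfg$channels[i]
    x <- cfg$noise_sd * pink_noise(n_samp)
    cpl <- coupling_of(ch)
    for (b in band_names) {
      edges <- cfg$bands[[b]]
      osc <- if (b == "alpha" && !is.null(cpl)) {
        sqrt(cpl$s) * cpl$common +
          sqrt(1 - cpl$s) * band_noise(n_samp, fs, edges[1], edges[2])
      } else {
        band_noise(n_samp, fs, edges[1], edges[2])
      }
      env <- rep(cfg$band_amp[[b]], n_samp)
      if (drifting[i])
        env <- env * per_trial_amp[[b]][trial_of_sample]
      if (b %in% c("alpha", "beta") && ch %in% cfg$erd_channels) {
        cl <- names(cfg$erd_channels)[cfg$erd_channels == ch][1]
        env[erd_gate[[cl]]] <- env[erd_gate[[cl]]] * sqrt(1 - cfg$erd_attenuation)
      }
      x <- x + env * osc
    }
    data[i, ] <- x
  }

  new_eeg_recording(data, fs, cfg$channels, events,
                    meta = list(config_seed = cfg$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_eeg_recording <- function(data, fs, labels, events, meta = list()) {
  stopifnot(is.matrix(data), nrow(data) == length(labels),
            !anyDuplicated(labels))
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop("event sample index outside recording bounds")
  structure(list(data = data, fs = fs, labels = labels,
                 events = tibble::as_tibble(events), meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}
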