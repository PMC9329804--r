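#' Standard 10-20/10-10 channel sets
#'
#' `mi_channel_order32()` returns the fixed 32-channel order used by the CNN
#' classifier: channels are arranged so that electrodes on the same hemisphere
#' are contiguous (left lateral to midline to right lateral), which preserves
#' ipsilateral spatial structure along the "height" axis of the input tensor.
#' `mi_montage64()` returns a 64-label 10-10 montage containing that subset.
#'
#' @return Character vector of channel labels.
#' @export
mi_channel_order32 <- function() {
  c("F5", "FC5", "C5", "CP5", "P5", "P3", "CP3", "C3", "FC3", "F3",
    "F1", "FC1", "C1", "CP1", "P1", "Cz", "FCz", "F2", "FC2", "C2",
    "CP2", "P2", "P4", "CP4", "C4", "FC4", "F4", "F6", "FC6", "C6",
    "CP6", "P6")
}

#' @rdname mi_channel_order32
#' @export
mi_montage64 <- function() {
  c(mi_channel_order32(),
    "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "Fz", "F8", "FT7", "FT8", "T7", "T8", "TP7", "TP8",
    "CPz", "P7", "Pz", "P8", "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2", "M1", "M2", "Iz")
}

#' @rdname mi_channel_order32
#' @export
mi_parietal_candidates <- function() {
  paste0("P", 1:8)
}

#' @rdname mi_channel_order32
#' @export
mi_frontal_set <- function() {
  c("F3", "F4", "F5", "F1", "F2", "F6")
}

#' Default EEG band edges (Hz)
#'
#' Theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz. Band edges in the literature
#' vary by 1-2 Hz; every function taking `bands` accepts an edited copy.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
mi_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 13), beta = c(14, 30))
}
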