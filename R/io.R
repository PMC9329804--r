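# Recording I/O: European Data Format (EDF/EDF+) and a lossless internal
# container. EDF stores samples as 16-bit integers scaled to a per-channel
# physical range, so the round trip is exact only up to one quantization
# step; the internal container (R serialization, extension .mifl or .rds)
# is bit-exact. Events travel in an "EDF Annotations" channel (EDF+ TALs).

#' Write / read a recording
#'
#' Dispatch on file extension: `.edf` uses the 16-bit EDF+ format with an
#' annotation channel for events; anything else is the lossless internal
#' container.
#'
#' @param rec an `eeg_recording`.
#' @param path destination / source file.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) write_edf(rec, path)
  else saveRDS(unclass(rec), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("malformed container file '", path,
                                           "': ", conditionMessage(e)))
  need <- c("data", "fs", "labels", "events")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("malformed container file '", path, "': missing field(s) ",
         paste(miss, collapse = ", "))
  new_eeg_recording(obj$data, obj$fs, obj$labels, obj$events,
                    obj$meta %||% list())
}

pad_ascii <- function(s, width) {
  s <- substr(s, 1, width)
  sprintf("%-*s", width, s)
}

edf_num <- function(x, width) pad_ascii(format(x, trim = TRUE), width)

write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns_sig <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- as.integer(ceiling(n / fs))
  ann_spr <- 64L                                  # 128 bytes of TALs/record

  pmax_ <- apply(abs(rec$data), 1, max)
  pmax_[pmax_ == 0] <- 1
  # format to fit the 8-character header field (incl. the minus sign of the
  # physical minimum), then reparse so the writer quantizes with exactly the
  # range the reader will see; the fallback rounds the range up, never down
  pmax_txt <- vapply(pmax_, function(p) {
    s <- sprintf("%.5g", p)
    if (nchar(s) > 7) s <- sprintf("%.1e", p * 1.05)
    s
  }, "")
  pmax_ <- as.numeric(pmax_txt)
  if (any(pmax_ <= 0)) stop("physical range underflow in EDF header")
  # the reader maps digital d to pmin + (pmax - pmin)/(dmax - dmin)*(d - dmin);
  # quantize with exactly that affine so the error is at most gain/2
  gain <- 2 * pmax_ / 65535                       # uV per digital unit

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii("X X X X", 80),
    pad_ascii(sprintf("Startdate 01-JAN-2000 X X X NS=%d", n), 80),
    "01.01.00", "00.00.00",
    edf_num(256 * (1 + ns_sig + 1), 8),
    pad_ascii("EDF+C", 44),
    edf_num(n_rec, 8),
    edf_num(1, 8),
    edf_num(ns_sig + 1, 4))
  writeChar(hdr, con, eos = NULL)
  lab <- c(vapply(rec$labels, pad_ascii, "", width = 16),
           pad_ascii("EDF Annotations", 16))
  writeChar(paste(lab, collapse = ""), con, eos = NULL)
  writeChar(paste(rep(pad_ascii("", 80), ns_sig + 1), collapse = ""), con, eos = NULL)
  writeChar(paste(c(rep(pad_ascii("uV", 8), ns_sig), pad_ascii("", 8)),
                  collapse = ""), con, eos = NULL)
  writeChar(paste(c(vapply(paste0("-", pmax_txt), pad_ascii, "", width = 8),
                    edf_num(-1, 8)), collapse = ""), con, eos = NULL)
  writeChar(paste(c(vapply(pmax_txt, pad_ascii, "", width = 8),
                    edf_num(1, 8)), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_num(-32768, 8), ns_sig + 1), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_num(32767, 8), ns_sig + 1), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(pad_ascii("", 80), ns_sig + 1), collapse = ""), con, eos = NULL)
  writeChar(paste(c(rep(edf_num(fs, 8), ns_sig), edf_num(ann_spr, 8)),
                  collapse = ""), con, eos = NULL)
  writeChar(paste(rep(pad_ascii("", 32), ns_sig + 1), collapse = ""), con, eos = NULL)

  dig <- round(sweep(sweep(rec$data, 1, pmax_, "+"), 1, gain, "/")) - 32768
  dig[dig > 32767] <- 32767
  dig[dig < -32768] <- -32768
  onset_s <- (rec$events$sample - 1) / fs
  for (r in seq_len(n_rec) - 1L) {
    s0 <- r * fs + 1L
    s1 <- min(n, s0 + fs - 1L)
    block <- matrix(0L, nrow = fs, ncol = ns_sig)
    block[seq_len(s1 - s0 + 1L), ] <- t(dig[, s0:s1, drop = FALSE])
    writeBin(as.integer(block), con, size = 2, endian = "little")
    tal <- sprintf("+%g\x14\x14", r)
    in_rec <- which(onset_s >= r & onset_s < r + 1)
    for (k in in_rec)
      tal <- paste0(tal, sprintf("+%.6f\x14trial %d %s\x14",
                                 onset_s[k], rec$events$trial[k],
                                 rec$events$class[k]))
    bytes <- charToRaw(tal)
    if (length(bytes) > 2L * ann_spr)
      stop("annotation record overflow; too many events in one second")
    bytes <- c(bytes, raw(2L * ann_spr - length(bytes)))
    writeBin(bytes, con)
  }
  invisible(path)
}

read_edf <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    out <- readChar(con, w, useBytes = TRUE)
    if (nchar(out, type = "bytes") < w) stop("malformed EDF '", path,
                                             "': truncated header")
    out
  }
  rd(8)                                           # version
  rd(80)                                          # patient
  recfield <- rd(80)
  rd(8); rd(8)                                    # date, time
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns_all <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns_all)) || ns_all < 1)
    stop("malformed EDF '", path, "': bad field in fixed header")
  fld <- function(w) vapply(seq_len(ns_all), function(i) rd(w), "")
  labels <- trimws(fld(16))
  fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr)))
    stop("malformed EDF '", path, "': bad field in signal headers")
  is_ann <- labels == "EDF Annotations"
  expected <- hdr_bytes + n_rec * sum(spr) * 2
  if (sz < expected)
    stop("malformed EDF '", path, "': data records truncated (",
         sz, " < ", expected, " bytes)")

  sig_idx <- which(!is_ann)
  fs <- spr[sig_idx[1]] / rec_dur
  data <- matrix(0, nrow = length(sig_idx), ncol = n_rec * spr[sig_idx[1]])
  ann_text <- character(0)
  for (r in seq_len(n_rec) - 1L) {
    for (i in seq_len(ns_all)) {
      if (is_ann[i]) {
        bytes <- readBin(con, "raw", n = 2L * spr[i])
        ann_text <- c(ann_text, rawToChar(bytes[bytes != as.raw(0)]))
      } else {
        v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
        j <- match(i, sig_idx)
        gain <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
        data[j, r * spr[i] + seq_len(spr[i])] <- pmin_[i] + gain * (v - dmin_[i])
      }
    }
  }

  events <- parse_edf_events(paste(ann_text, collapse = ""), fs)
  nm <- regmatches(recfield, regexpr("NS=[0-9]+", recfield))
  if (length(nm) == 1) {
    true_n <- as.integer(sub("NS=", "", nm))
    if (true_n <= ncol(data)) data <- data[, seq_len(true_n), drop = FALSE]
  }
  rownames(data) <- labels[sig_idx]
  new_eeg_recording(data, fs, labels[sig_idx], events)
}

parse_edf_events <- function(txt, fs) {
  m <- gregexpr("\\+([0-9.]+)\x14trial ([0-9]+) ([a-z]+)\x14", txt)
  pieces <- regmatches(txt, m)[[1]]
  if (!length(pieces))
    return(tibble::tibble(sample = integer(0), trial = integer(0),
                          class = character(0)))
  onset <- as.numeric(sub("\\+([0-9.]+)\x14.*", "\\1", pieces))
  trial <- as.integer(sub(".*\x14trial ([0-9]+) .*", "\\1", pieces))
  cls <- sub(".*trial [0-9]+ ([a-z]+)\x14", "\\1", pieces)
  tibble::tibble(sample = as.integer(round(onset * fs)) + 1L,
                 trial = trial, class = cls)
}
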