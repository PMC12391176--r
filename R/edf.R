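## Minimal European Data Format (EDF) writer/reader for continuous recordings
## with one common sampling rate. Signals are stored as 16-bit integers with
## per-channel physical scaling, in 1-second data records; the true sample
## count is carried in the header's reserved field so that a recording whose
## length is not a whole number of records round-trips exactly.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Values are quantized to 16 bits over each channel's observed physical
#' range; the worst-case round-trip error is `(max - min) / 65535 / 2`
#' microvolts per channel. The event table, if present, is written alongside
#' as a tab-separated file (`*_events.tsv`).
#'
#' @param recording an [eeg_recording()].
#' @param path output path (conventionally `.edf`).
#' @return the path, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$data
  ns <- ncol(x)
  sfreq <- as.integer(round(recording$sfreq))
  n_samples <- nrow(x)
  n_rec <- ceiling(n_samples / sfreq)
  pmin_ <- apply(x, 2, min)
  pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad(paste0("NSAMP=", n_samples), 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(recording$channels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(pmin_, digits = 6, format = "g"), 8)
  field(formatC(pmax_, digits = 6, format = "g"), 8)
  field(rep(-32768L, ns), 8)
  field(rep(32767L, ns), 8)
  field(rep("", ns), 80)
  field(rep(sfreq, ns), 8)
  field(rep("", ns), 32)
  ## physical -> digital
  dig <- matrix(0L, n_rec * sfreq, ns)
  scale <- 65535 / (pmax_ - pmin_)
  for (j in seq_len(ns)) {
    d <- as.integer(round((x[, j] - pmin_[j]) * scale[j]) - 32768L)
    dig[seq_len(n_samples), j] <- pmin(32767L, pmax(-32768L, d))
  }
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * sfreq + 1L):(r * sfreq)
    writeBin(as.integer(dig[rows, ]), con, size = 2, endian = "little")
  }
  if (!is.null(recording$events)) {
    write_events(recording$events, events_path_for(path))
  }
  invisible(path)
}

events_path_for <- function(edf_path) {
  sub("\\.edf$", "_events.tsv", edf_path, ignore.case = TRUE)
}

#' Write / read a stimulus-event table
#'
#' Tab-separated with columns `onset_sample` (0-based), `onset_s`, `hand`,
#' `compartment`.
#'
#' @param events event `data.frame`.
#' @param path file path.
#' @return the path (write) or the event table (read).
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a recording from an EDF file
#'
#' Restores the continuous data in microvolts with channel labels and
#' sampling rate, validates that C3 and C4 are present, and attaches the
#' event table from the sibling `*_events.tsv` file.
#'
#' @param path EDF file path.
#' @param require_events error if the events file is absent (default `TRUE`).
#' @param require_central error if C3/C4 are missing (default `TRUE`).
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, require_events = TRUE,
                           require_central = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per_sig <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- per_sig(16)
  per_sig(80)
  per_sig(8) # units
  pmin_ <- as.numeric(per_sig(8))
  pmax_ <- as.numeric(per_sig(8))
  dmin_ <- as.numeric(per_sig(8))
  dmax_ <- as.numeric(per_sig(8))
  per_sig(80)
  spr <- as.integer(per_sig(8))
  per_sig(32)
  if (length(unique(spr)) != 1) {
    stop("mixed per-channel sampling rates are not supported", call. = FALSE)
  }
  sfreq <- spr[1] / rec_dur
  raw_vals <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                      endian = "little")
  x <- matrix(0, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    off <- (r - 1L) * sum(spr)
    block <- matrix(raw_vals[(off + 1L):(off + sum(spr))], spr[1], ns)
    x[((r - 1L) * spr[1] + 1L):(r * spr[1]), ] <- block
  }
  for (j in seq_len(ns)) {
    x[, j] <- (x[, j] - dmin_[j]) / (dmax_[j] - dmin_[j]) *
      (pmax_[j] - pmin_[j]) + pmin_[j]
  }
  if (grepl("^NSAMP=", reserved)) {
    n_true <- as.integer(sub("^NSAMP=", "", reserved))
    x <- x[seq_len(n_true), , drop = FALSE]
  }
  if (require_central && !all(c("C3", "C4") %in% labels)) {
    stop("recording lacks required central channels C3/C4", call. = FALSE)
  }
  ev_path <- events_path_for(path)
  events <- NULL
  if (file.exists(ev_path)) {
    events <- read_events(ev_path)
  } else if (require_events) {
    stop("events file not found at expected path: ", ev_path, call. = FALSE)
  }
  eeg_recording(x, sfreq, labels, events)
}
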