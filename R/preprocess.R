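#' Preprocessing configuration
#'
#' Parameters of the continuous-EEG cleaning chain: zero-phase FIR band-pass,
#' robust bad-channel detection, common-average re-referencing, and
#' peak-to-peak bad-segment rejection. The channel and segment criteria are
#' deterministic, documented stand-ins for black-box artifact-rejection tools:
#' channels are flagged on robust log-variance z-scores or on failing to
#' correlate with any other channel; segments on a sliding-window
#' peak-to-peak amplitude threshold.
#'
#' @param band band-pass edges in Hz (default 1-35).
#' @param bad_channel_zscore robust z threshold on log channel variance
#'   (default 3.5).
#' @param neighbor_corr_min minimum best absolute correlation with any other
#'   channel (default 0.4).
#' @param segment_ptp_max peak-to-peak rejection threshold in microvolts per
#'   sliding window (default 200).
#' @param segment_window sliding-window length in seconds (default 1).
#' @param filter_order FIR order; the default (`NULL`) chooses a Hamming
#'   windowed-sinc order giving a transition width of about 1 Hz at the low
#'   edge (3.3 / 1 Hz x sampling rate taps, rounded up to even).
#' @return an object of class `preproc_config`.
#' @export
preproc_config <- function(band = c(1, 35), bad_channel_zscore = 3.5,
                           neighbor_corr_min = 0.4, segment_ptp_max = 200,
                           segment_window = 1, filter_order = NULL) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  structure(
    list(band = band, bad_channel_zscore = bad_channel_zscore,
         neighbor_corr_min = neighbor_corr_min,
         segment_ptp_max = segment_ptp_max, segment_window = segment_window,
         filter_order = filter_order),
    class = "preproc_config"
  )
}

fir_coefficients <- function(config, sfreq) {
  if (config$band[2] >= sfreq / 2) {
    stop("band edge at or above Nyquist frequency", call. = FALSE)
  }
  order <- config$filter_order %||% {
    n <- ceiling(3.3 * sfreq / 1) # ~1 Hz transition for a Hamming window
    n + n %% 2
  }
  signal::fir1(order, config$band * 2 / sfreq, type = "pass")
}

#' Zero-phase FIR band-pass filter
#'
#' Applies a Hamming windowed-sinc band-pass FIR forward and backward (via
#' frequency-domain convolution), so the net filter has zero phase and the
#' squared magnitude response of the one-pass design. Attenuation at DC and
#' at the upper stopband exceeds 80 dB.
#'
#' @param recording an [eeg_recording()].
#' @param config a [preproc_config()].
#' @return the filtered recording.
#' @export
bandpass_filter <- function(recording, config = preproc_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!all(is.finite(recording$data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  h <- fir_coefficients(config, recording$sfreq)
  origin <- (length(h) + 1) / 2 # linear-phase kernel is symmetric
  for (j in seq_len(ncol(recording$data))) {
    y <- Re(fft_conv_same(recording$data[, j], h, origin))
    y <- rev(Re(fft_conv_same(rev(y), h, origin)))
    recording$data[, j] <- y
  }
  attr(recording, "filter") <- list(order = length(h) - 1L,
                                    band = config$band, passes = 2L)
  recording
}

#' Detect bad channels
#'
#' Flags channels whose robust z-score of log variance (median/MAD) exceeds
#' the threshold, or whose best absolute correlation with every other channel
#' falls below `neighbor_corr_min`. Flagging C3 or C4 raises a warning since
#' downstream analysis requires them.
#'
#' @param recording an [eeg_recording()] (at least 4 channels).
#' @param config a [preproc_config()].
#' @return character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(recording, config = preproc_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$data
  if (ncol(x) < 4) stop("need at least 4 channels", call. = FALSE)
  logvar <- log(apply(x, 2, stats::var))
  ## the MAD is floored at 0.15 log-units (~16% variance scale) so that a
  ## montage of near-identical channels does not make the z-score degenerate
  z <- (logvar - stats::median(logvar)) / max(stats::mad(logvar), 0.15)
  ## best correlation computed on a decimated copy for speed
  idx <- seq(1, nrow(x), by = max(1L, nrow(x) %/% 20000L))
  cm <- abs(stats::cor(x[idx, , drop = FALSE]))
  diag(cm) <- 0
  best_corr <- apply(cm, 2, max)
  bad <- abs(z) > config$bad_channel_zscore |
    best_corr < config$neighbor_corr_min
  flagged <- recording$channels[bad]
  if (length(flagged) == length(recording$channels)) {
    stop("all channels flagged as bad; check the recording", call. = FALSE)
  }
  if (any(c("C3", "C4") %in% flagged)) {
    warning("central channel(s) flagged as bad: ",
            paste(intersect(c("C3", "C4"), flagged), collapse = ", "),
            "; downstream analysis requires C3/C4", call. = FALSE)
  }
  flagged
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean across retained channels from each
#' retained channel; excluded (bad) channels are dropped from the output.
#'
#' @param recording an [eeg_recording()].
#' @param excluded channel labels to drop before averaging.
#' @return the re-referenced recording (excluded channels removed).
#' @export
rereference_car <- function(recording, excluded = character()) {
  stopifnot(inherits(recording, "eeg_recording"))
  keep <- setdiff(recording$channels, excluded)
  if (length(keep) < 2) stop("need at least 2 retained channels", call. = FALSE)
  x <- recording$data[, keep, drop = FALSE]
  x <- x - rowMeans(x)
  eeg_recording(x, recording$sfreq, keep, recording$events)
}

#' Reject high-amplitude segments
#'
#' Scans the recording with a sliding window and marks windows where any
#' channel's peak-to-peak amplitude exceeds the threshold; overlapping marked
#' windows are merged into spans, the spans are excised, events are re-indexed
#' to the excised timebase, and events whose full time-frequency epoch
#' (-1.5 to 2.2 s) intersects a marked span are dropped. Retained samples are
#' left untouched.
#'
#' @param recording an [eeg_recording()] (filtered).
#' @param config a [preproc_config()].
#' @param epoch_pad epoch extent `(pre, post)` in seconds used to decide which
#'   events a bad span invalidates (default `c(1.5, 2.2)`).
#' @return a list: `recording` (excised), `log` (data.frame of rejected spans
#'   in seconds of the original timebase), `dropped_events` (rows of the
#'   original event table).
#' @export
reject_bad_segments <- function(recording, config = preproc_config(),
                                epoch_pad = c(1.5, 2.2)) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$data
  n <- nrow(x)
  sfreq <- recording$sfreq
  win <- max(2L, as.integer(round(config$segment_window * sfreq)))
  hop <- max(1L, win %/% 2L)
  bad_sample <- rep(FALSE, n)
  if (is.finite(config$segment_ptp_max)) {
    starts <- seq(1L, max(1L, n - win + 1L), by = hop)
    for (s in starts) {
      idx <- s:min(n, s + win - 1L)
      ptp <- apply(x[idx, , drop = FALSE], 2,
                   function(v) max(v) - min(v))
      if (any(ptp > config$segment_ptp_max)) bad_sample[idx] <- TRUE
    }
  }
  if (mean(bad_sample) > 0.9) {
    stop(sprintf("%.0f%% of the data exceeds the %g uV peak-to-peak threshold;
  the recording is unusable at this setting", 100 * mean(bad_sample),
                 config$segment_ptp_max), call. = FALSE)
  }
  events <- recording$events
  dropped <- NULL
  if (!is.null(events) && any(bad_sample)) {
    bad_idx <- which(bad_sample)
    pre <- as.integer(round(epoch_pad[1] * sfreq))
    post <- as.integer(round(epoch_pad[2] * sfreq))
    hit <- vapply(events$onset_sample, function(s0) {
      lo <- max(1L, s0 + 1L - pre)
      hi <- min(n, s0 + 1L + post)
      any(bad_sample[lo:hi])
    }, logical(1))
    dropped <- events[hit, , drop = FALSE]
    events <- events[!hit, , drop = FALSE]
  }
  ## excise spans and re-index surviving events to the new timebase
  keep <- !bad_sample
  if (!is.null(events) && nrow(events)) {
    removed_before <- cumsum(!keep)
    events$onset_sample <- events$onset_sample -
      removed_before[events$onset_sample + 1L]
    events$onset_s <- events$onset_sample / sfreq
  }
  spans <- NULL
  if (any(bad_sample)) {
    r <- rle(bad_sample)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    spans <- data.frame(start_s = (starts[r$values] - 1L) / sfreq,
                        end_s = ends[r$values] / sfreq)
  } else {
    spans <- data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  out <- eeg_recording(x[keep, , drop = FALSE], sfreq, recording$channels,
                       events)
  list(recording = out, log = spans, dropped_events = dropped)
}

#' Run the full preprocessing chain
#'
#' Band-pass filter, bad-channel detection and removal, common-average
#' re-reference, and bad-segment rejection, in that order. The central
#' analysis electrodes are never removed (a flagged C3/C4 only warns, since
#' every downstream measurement needs them); set `keep_central = FALSE` to
#' drop them like any other channel.
#'
#' @param recording an [eeg_recording()] with events.
#' @param config a [preproc_config()].
#' @param keep_central retain C3/C4 even when flagged (default `TRUE`).
#' @return a list: `recording` (cleaned), `bad_channels` (channels removed),
#'   `flagged_central` (central channels that met a bad-channel criterion but
#'   were retained), `rejection_log`, `dropped_events`.
#' @export
preprocess <- function(recording, config = preproc_config(),
                       keep_central = TRUE) {
  filtered <- bandpass_filter(recording, config)
  bad <- detect_bad_channels(filtered, config)
  flagged_central <- intersect(bad, c("C3", "C4"))
  if (keep_central) bad <- setdiff(bad, c("C3", "C4"))
  reref <- rereference_car(filtered, bad)
  seg <- reject_bad_segments(reref, config)
  list(recording = seg$recording, bad_channels = bad,
       flagged_central = flagged_central,
       rejection_log = seg$log, dropped_events = seg$dropped_events)
}
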