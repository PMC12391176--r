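#' Continuous multi-channel EEG recording
#'
#' The in-memory container used by every stage of the pipeline: a samples x
#' channels matrix of microvolt values, the sampling rate, and an optional
#' stimulus-event table. Sample indices are 0-based (sample `k` is at time
#' `k / sfreq` seconds).
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param sfreq sampling rate in Hz.
#' @param channels character vector of channel labels (10-20 montage names);
#'   defaults to the column names of `data`.
#' @param events optional event table: a `data.frame` with columns
#'   `onset_sample` (0-based integer), `onset_s`, `hand` (`"left"`/`"right"`)
#'   and `compartment` (1-8).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channels = colnames(data),
                          events = NULL) {
  data <- as.matrix(data)
  if (is.null(channels)) {
    channels <- paste0("ch", seq_len(ncol(data)))
  }
  stopifnot(length(channels) == ncol(data), sfreq > 0)
  colnames(data) <- channels
  if (!is.null(events)) {
    events <- validate_events(events, nrow(data), sfreq)
  }
  structure(
    list(data = data, sfreq = sfreq, channels = channels, events = events),
    class = "eeg_recording"
  )
}

validate_events <- function(events, n_samples, sfreq) {
  stopifnot(is.data.frame(events))
  required <- c("onset_sample", "hand")
  missing <- setdiff(required, names(events))
  if (length(missing)) {
    stop("event table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(events$onset_sample < 0) || any(events$onset_sample >= n_samples)) {
    stop("event onsets fall outside the recording", call. = FALSE)
  }
  if (is.unsorted(events$onset_sample, strictly = TRUE)) {
    stop("event onsets must be strictly increasing", call. = FALSE)
  }
  events$onset_s <- events$onset_sample / sfreq
  events
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$sfreq, nrow(x$data) / x$sfreq))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  if (!is.null(x$events)) {
    cat(sprintf("  events: %d (%s)\n", nrow(x$events),
                paste(sprintf("%s=%d", names(table(x$events$hand)),
                              as.integer(table(x$events$hand))),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
duration.eeg_recording <- function(x) nrow(x$data) / x$sfreq

#' Recording duration in seconds
#' @param x an `eeg_recording`.
#' @export
duration <- function(x) UseMethod("duration")

#' Decimate a band-limited recording
#'
#' Keeps every `factor`-th sample and divides the sampling rate accordingly.
#' Intended for data already low-pass limited well below the new Nyquist
#' frequency (e.g. 1-35 Hz band-passed EEG decimated from 256 to 128 Hz
#' before wavelet decomposition); no additional anti-alias filter is applied,
#' so do not use it on broadband data.
#'
#' @param recording an [eeg_recording()].
#' @param factor integer decimation factor (default 2).
#' @return the decimated recording; event onsets are remapped to the nearest
#'   retained sample.
#' @export
decimate_recording <- function(recording, factor = 2L) {
  stopifnot(inherits(recording, "eeg_recording"))
  factor <- assert_positive_count(factor, "factor")
  if (factor == 1L) return(recording)
  idx <- seq(1L, nrow(recording$data), by = factor)
  events <- recording$events
  if (!is.null(events)) {
    events$onset_sample <- as.integer(round(events$onset_sample / factor))
    events$onset_s <- events$onset_sample * factor / recording$sfreq
  }
  eeg_recording(recording$data[idx, , drop = FALSE],
                recording$sfreq / factor, recording$channels, events)
}
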