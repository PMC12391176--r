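#' Extract stimulus-locked epochs
#'
#' Cuts trials from a continuous recording around each event, using 0-based
#' half-open sample windows `[round(start*sfreq), round(end*sfreq))` relative
#' to the event sample (the event is t = 0). Optionally subtracts each
#' epoch's mean over a baseline interval, per channel. Events too close to the
#' recording edge are skipped and logged.
#'
#' @param recording an [eeg_recording()].
#' @param events event table (defaults to `recording$events`).
#' @param start,end epoch window in seconds (time-domain default -0.5 to 1.5).
#' @param baseline baseline interval in seconds as `c(lo, hi)`, or `NULL` for
#'   no correction (default `c(-0.5, 0)`).
#' @param channels channels to keep (default all).
#' @return an object of class `epoch_set`: `data` (trial x channel x sample
#'   array), `times` (seconds), `sfreq`, `hand` (per-trial label), `skipped`
#'   (event rows that fell outside the recording).
#' @export
extract_epochs <- function(recording, events = recording$events,
                           start = -0.5, end = 1.5, baseline = c(-0.5, 0),
                           channels = recording$channels) {
  stopifnot(inherits(recording, "eeg_recording"), !is.null(events),
            start < 0, end > 0)
  sfreq <- recording$sfreq
  s_lo <- as.integer(round(start * sfreq))
  s_hi <- as.integer(round(end * sfreq)) # half-open
  n_samp <- s_hi - s_lo
  n_total <- nrow(recording$data)
  ch_idx <- match(channels, recording$channels)
  if (anyNA(ch_idx)) stop("unknown channel requested", call. = FALSE)
  ok <- events$onset_sample + s_lo >= 0 &
    events$onset_sample + s_hi <= n_total
  skipped <- events[!ok, , drop = FALSE]
  events <- events[ok, , drop = FALSE]
  if (!nrow(events)) stop("no events fit inside the recording", call. = FALSE)
  arr <- array(NA_real_, c(nrow(events), length(ch_idx), n_samp))
  times <- (s_lo:(s_hi - 1L)) / sfreq
  for (i in seq_len(nrow(events))) {
    rows <- events$onset_sample[i] + (s_lo:(s_hi - 1L)) + 1L
    arr[i, , ] <- t(recording$data[rows, ch_idx, drop = FALSE])
  }
  if (!is.null(baseline)) {
    stopifnot(baseline[1] >= start, baseline[2] <= 0)
    b_idx <- which(times >= baseline[1] & times < baseline[2])
    if (!length(b_idx)) stop("empty baseline interval", call. = FALSE)
    bl <- apply(arr[, , b_idx, drop = FALSE], c(1, 2), mean)
    arr <- arr - array(bl, dim(arr)) # recycles over the sample axis
  }
  structure(
    list(data = arr, times = times, sfreq = sfreq, channels = channels,
         hand = events$hand, skipped = skipped),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples (%g..%g s)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Average epochs into an event-related potential
#'
#' Pointwise mean across trials, optionally restricted to one hand's trials.
#'
#' @param epochs an [extract_epochs()] result.
#' @param hand optional hand label to subset trials.
#' @return a list: `erp` (channel x sample matrix), `times`, `channels`,
#'   `n_epochs`, `sfreq`.
#' @export
average_epochs <- function(epochs, hand = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- if (is.null(hand)) seq_along(epochs$hand) else which(epochs$hand == hand)
  if (!length(sel)) stop("no epochs to average", call. = FALSE)
  erp <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  rownames(erp) <- epochs$channels
  list(erp = erp, times = epochs$times, channels = epochs$channels,
       n_epochs = length(sel), sfreq = epochs$sfreq)
}
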