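#' Canonical time-frequency regions of interest
#'
#' The five stimulus-locked oscillatory phenomena that the masking procedure is
#' expected to recover, with their frequency bands (Hz) and post-stimulus time
#' windows (s): delta and theta band synchronization, alpha and beta band
#' desynchronization, and the late beta resynchronization (beta rebound).
#' These windows are also the targets of the synthetic generator's oscillatory
#' injections.
#'
#' @return a `data.frame` with columns `roi`, `f_lo`, `f_hi`, `t_lo`, `t_hi`,
#'   `direction` (+1 synchronization, -1 desynchronization).
#' @export
roi_windows <- function() {
  data.frame(
    roi = c("delta_sync", "theta_sync", "alpha_desync",
            "beta1_desync", "beta2_resync"),
    f_lo = c(1, 4, 5, 13, 11),
    f_hi = c(4, 6, 13, 27, 17),
    t_lo = c(0, 0, 0.047, 0.070, 0.820),
    t_hi = c(0.543, 0.262, 0.785, 0.566, 1.601),
    direction = c(1, 1, -1, -1, 1),
    stringsAsFactors = FALSE
  )
}

## Map a stimulated hand to the contralateral central electrode.
contralateral_channel <- function(hand) {
  switch(hand, left = "C4", right = "C3",
         stop("unknown hand label: ", hand, call. = FALSE))
}

#' Biphasic evoked-response template
#'
#' A smooth biphasic waveform (negative lobe followed by a positive lobe, each
#' a Gaussian), scaled so that in continuous time the negative-to-positive
#' excursion equals `np_amplitude` and the positive-lobe peak falls at
#' `pos_latency`. The negative lobe peaks at 60% of the positive latency.
#' Only these two peak metrics matter downstream; the lobe width is a shape
#' parameter.
#'
#' @param np_amplitude negative-to-positive excursion in microvolts (>= 0).
#' @param pos_latency positive-peak latency in seconds, in (0, 0.5].
#' @param sfreq sampling rate in Hz.
#' @param lobe_sd Gaussian SD of each lobe in seconds (default 0.02).
#' @return a list with `wave` (samples, starting at stimulus onset) and
#'   `onset_shift` (always 0; the template starts at t = 0).
#' @keywords internal
erp_template <- function(np_amplitude, pos_latency, sfreq, lobe_sd = 0.02) {
  stopifnot(np_amplitude >= 0)
  if (pos_latency <= 0 || pos_latency > 0.5) {
    stop("positive-peak latency must lie in (0, 500] ms", call. = FALSE)
  }
  neg_latency <- 0.6 * pos_latency
  span <- pos_latency + 6 * lobe_sd
  shape_fun <- function(t) {
    exp(-(t - pos_latency)^2 / (2 * lobe_sd^2)) -
      exp(-(t - neg_latency)^2 / (2 * lobe_sd^2))
  }
  ## calibrate the scale on a fine grid so the continuous-time excursion is exact
  t_fine <- seq(0, span, by = 1 / (sfreq * 16))
  s_fine <- shape_fun(t_fine)
  scale <- if (np_amplitude == 0) 0 else np_amplitude / (max(s_fine) - min(s_fine))
  t <- seq(0, span, by = 1 / sfreq)
  list(wave = scale * shape_fun(t), onset_shift = 0)
}

#' Add time-locked evoked responses to a recording
#'
#' At each stimulus event the biphasic template is added to the central
#' electrode contralateral to the stimulated hand. Injection is linear:
#' overlapping responses superpose.
#'
#' @param recording an [eeg_recording()].
#' @param events event table (defaults to `recording$events`).
#' @param np_amplitude,pos_latency,lobe_sd template parameters; see
#'   [erp_template()]. Latency in seconds.
#' @return the modified recording.
#' @export
inject_erp <- function(recording, events = recording$events,
                       np_amplitude, pos_latency, lobe_sd = 0.02) {
  stopifnot(inherits(recording, "eeg_recording"), !is.null(events))
  if (np_amplitude == 0) return(recording)
  tpl <- erp_template(np_amplitude, pos_latency, recording$sfreq, lobe_sd)
  n <- nrow(recording$data)
  for (hand in unique(events$hand)) {
    ch <- contralateral_channel(hand)
    j <- match(ch, recording$channels)
    if (is.na(j)) stop("target channel missing: ", ch, call. = FALSE)
    for (s0 in events$onset_sample[events$hand == hand]) {
      idx <- (s0 + 1L):min(n, s0 + length(tpl$wave))
      recording$data[idx, j] <- recording$data[idx, j] +
        tpl$wave[seq_along(idx)]
    }
  }
  recording
}

## Raised-cosine (Tukey) taper over [t_lo, t_hi], evaluated on sample grid
## offsets relative to the event, with ramps occupying `ramp_frac` of the
## window at each end.
roi_taper <- function(n_samp, sfreq, t_lo, t_hi, ramp_frac = 0.25) {
  t <- seq(0, by = 1 / sfreq, length.out = n_samp)
  w <- numeric(n_samp)
  len <- t_hi - t_lo
  ramp <- ramp_frac * len
  inside <- t >= t_lo & t <= t_hi
  w[inside] <- 1
  up <- inside & t < t_lo + ramp
  w[up] <- 0.5 * (1 - cos(pi * (t[up] - t_lo) / ramp))
  down <- inside & t > t_hi - ramp
  w[down] <- 0.5 * (1 - cos(pi * (t_hi - t[down]) / ramp))
  w
}

#' Modulate band-limited oscillatory power around stimulus events
#'
#' Multiplies the amplitude of the band-passed background, on the channel
#' contralateral to each stimulated hand and within each region of interest's
#' frequency band and post-stimulus time window (smoothly tapered), by the
#' configured gain. An amplitude gain `g > 1` injects event-related
#' synchronization, `g < 1` desynchronization; the ground-truth decibel effect
#' is `20*log10(g)` at the taper plateau.
#'
#' @param recording an [eeg_recording()].
#' @param events event table (defaults to `recording$events`).
#' @param gains named numeric vector of amplitude gains, keyed by the ROI
#'   labels of [roi_windows()]; all gains must be > 0. Missing ROIs default
#'   to 1 (no modulation).
#' @param windows ROI definition table (default [roi_windows()]).
#' @return the modified recording.
#' @export
inject_oscillations <- function(recording, events = recording$events, gains,
                                windows = roi_windows()) {
  stopifnot(inherits(recording, "eeg_recording"), !is.null(events))
  if (any(gains <= 0)) stop("oscillatory gains must be > 0", call. = FALSE)
  g <- stats::setNames(rep(1, nrow(windows)), windows$roi)
  unknown <- setdiff(names(gains), windows$roi)
  if (length(unknown)) {
    stop("unknown ROI label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  g[names(gains)] <- gains
  if (all(g == 1)) return(recording)
  n <- nrow(recording$data)
  sfreq <- recording$sfreq
  for (hand in unique(events$hand)) {
    ch <- contralateral_channel(hand)
    j <- match(ch, recording$channels)
    if (is.na(j)) stop("target channel missing: ", ch, call. = FALSE)
    onsets <- events$onset_sample[events$hand == hand]
    for (k in seq_len(nrow(windows))) {
      gain <- g[windows$roi[k]]
      if (gain == 1) next
      band <- fft_bandpass(recording$data[, j], sfreq,
                           windows$f_lo[k], windows$f_hi[k])
      n_tpl <- as.integer(ceiling(windows$t_hi[k] * sfreq)) + 1L
      tap <- roi_taper(n_tpl, sfreq, windows$t_lo[k], windows$t_hi[k])
      full_taper <- numeric(n)
      for (s0 in onsets) {
        idx <- (s0 + 1L):min(n, s0 + n_tpl)
        full_taper[idx] <- pmax(full_taper[idx], tap[seq_along(idx)])
      }
      recording$data[, j] <- recording$data[, j] +
        (gain - 1) * band * full_taper
    }
  }
  recording
}
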