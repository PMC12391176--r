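#' Simulate 1/f background EEG
#'
#' Generates Gaussian noise whose power spectral density follows
#' `P(f) ~ 1/f^exponent`, independently per channel, scaled to a target RMS
#' amplitude. This emulates the aperiodic broadband background of resting EEG;
#' it contains no oscillatory peaks, artifacts, or spatial correlation.
#'
#' @param duration recording length in seconds.
#' @param sfreq sampling rate in Hz (default 256).
#' @param channels channel labels (default a minimal central/frontal/parietal
#'   10-20 set including C3 and C4).
#' @param exponent 1/f power-spectral slope (0 = white noise; 1 = pink;
#'   default 1).
#' @param rms target per-channel RMS amplitude in microvolts (default 10).
#' @param spatial_corr pairwise inter-channel correlation, emulating volume
#'   conduction through a shared component (default 0.5; 0 gives independent
#'   channels).
#' @param rms_jitter_sd SD (log10 units) of a per-channel multiplicative RMS
#'   jitter, emulating electrode-gain heterogeneity (default 0 = all channels
#'   at exactly `rms`).
#' @param seed integer seed.
#' @param events optional event table attached to the returned recording.
#' @return an [eeg_recording()].
#' @export
simulate_background <- function(duration, sfreq = 256,
                                channels = c("F3", "F4", "C3", "C4", "P3", "P4"),
                                exponent = 1, rms = 10, spatial_corr = 0.5,
                                rms_jitter_sd = 0, seed = 1, events = NULL) {
  stopifnot(duration > 0, rms > 0, exponent >= 0,
            spatial_corr >= 0, spatial_corr < 1)
  if (!is.null(events)) {
    needed <- max(events$onset_sample) / sfreq + 2.2
    if (duration < needed) {
      stop(sprintf(paste0("duration %.1f s too short: protocol needs %.1f s ",
                          "(last event + 2.2 s epoch padding)"),
                   duration, needed), call. = FALSE)
    }
  }
  set.seed(seed)
  n <- as.integer(round(duration * sfreq))
  x <- matrix(0, n, length(channels))
  ## shape white noise in the frequency domain: amplitude ~ f^(-exponent/2);
  ## synthesis runs at a 5-smooth length (fast FFT) and is truncated to n
  n2 <- stats::nextn(n, c(2, 3, 5))
  f <- seq(0, sfreq, length.out = n2 + 1)[1:n2]
  f <- pmin(f, sfreq - f)
  shape <- c(0, f[-1]^(-exponent / 2)) # kill DC
  one_channel <- function() {
    w <- stats::rnorm(n2)
    y <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE) / n2)[seq_len(n)]
    y / sqrt(mean(y^2))
  }
  common <- if (spatial_corr > 0) one_channel() else 0
  gain <- rms * 10^stats::rnorm(length(channels), 0, rms_jitter_sd)
  for (j in seq_along(channels)) {
    x[, j] <- gain[j] * (sqrt(spatial_corr) * common +
                           sqrt(1 - spatial_corr) * one_channel())
  }
  eeg_recording(x, sfreq, channels, events)
}
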