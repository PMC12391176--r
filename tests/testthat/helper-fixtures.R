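## Shared fixture builders. Everything is generated in code; no data files.

## A silent recording (all zeros) with a small protocol attached.
zero_recording <- function(n_sets = 2, seed = 1, sfreq = 256,
                           channels = c("F3", "F4", "C3", "C4", "P3", "P4")) {
  ev <- generate_protocol(stimulus_protocol(n_sets = n_sets), seed = seed,
                          sfreq = sfreq)
  n <- max(ev$onset_sample) + 3 * sfreq
  eeg_recording(matrix(0, n, length(channels)), sfreq, channels, ev)
}

## A dB-scale "tfr" object built directly from a matrix (statistics-level
## fixture that bypasses the wavelet transform).
fake_db_tfr <- function(power, freqs, times, channel = "C3") {
  structure(
    list(power = power, freqs = freqs, times = times,
         sfreq = 1 / diff(times[1:2]), n_trials = 1, units = "dB",
         channel = channel),
    class = "tfr"
  )
}

## Stationary-noise participant stack on the standard 30-frequency grid.
noise_stack <- function(n_participants = 12, n_times = 80, sfreq_t = 64,
                        sd = 1, seed = 1) {
  set.seed(seed)
  freqs <- (35)^((0:29) / 29)
  times <- seq(-0.5, by = 1 / sfreq_t, length.out = n_times)
  tfrs <- lapply(seq_len(n_participants), function(i) {
    fake_db_tfr(matrix(rnorm(30 * n_times, 0, sd), 30), freqs, times)
  })
  grand_average_stack(tfrs)
}
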