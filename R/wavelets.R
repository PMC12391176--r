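#' Complex Morlet wavelet family
#'
#' Thirty logarithmically spaced frequencies from 1 to 35 Hz,
#' `f_k = 35^(k/29)` for `k = 0..29`, each paired with a Gaussian-windowed
#' complex sine wave `exp(i*2*pi*t*f) * exp(-t^2 / (2*sigma_t^2))` whose
#' temporal SD is `sigma_t(f) = 10 / (2*pi*f)` seconds (a fixed ~10-cycle
#' width). Kernels are truncated at `n_sd` standard deviations and scaled to
#' unit energy; the decibel baseline normalisation downstream cancels any
#' per-frequency scale factor, so the energy scaling matters only for
#' bit-reproducibility.
#'
#' @param f_min,f_max frequency endpoints in Hz (default 1 and 35).
#' @param n_freqs number of logarithmic steps (default 30).
#' @param sfreq sampling rate in Hz.
#' @param cycles_constant the constant in `sigma_t = cycles_constant/(2*pi*f)`
#'   (default 10).
#' @param n_sd kernel support half-width in units of `sigma_t` (default 3.5;
#'   values below 3 are refused because the Gaussian would be visibly
#'   truncated). At 3.5 SD the envelope has fallen to exp(-6.125) ~ 0.2% of
#'   its peak.
#' @return an object of class `wavelet_family`: `freqs`, `sigma_t`, `kernels`
#'   (list of complex vectors), `origins` (1-based index of t = 0 in each
#'   kernel), `sfreq`.
#' @export
wavelet_family <- function(f_min = 1, f_max = 35, n_freqs = 30, sfreq = 256,
                           cycles_constant = 10, n_sd = 3.5) {
  stopifnot(f_min > 0, f_max > f_min, n_freqs >= 2, sfreq > 2 * f_max)
  if (n_sd < 3) {
    stop("kernel support must cover at least +/- 3 sigma_t", call. = FALSE)
  }
  k <- seq(0, n_freqs - 1)
  freqs <- f_min * (f_max / f_min)^(k / (n_freqs - 1))
  sigma_t <- cycles_constant / (2 * pi * freqs)
  kernels <- vector("list", n_freqs)
  origins <- integer(n_freqs)
  for (i in seq_len(n_freqs)) {
    half <- ceiling(n_sd * sigma_t[i] * sfreq)
    t <- (-half:half) / sfreq
    w <- exp(1i * 2 * pi * t * freqs[i]) * exp(-t^2 / (2 * sigma_t[i]^2))
    kernels[[i]] <- w / sqrt(sum(Mod(w)^2)) # unit energy
    origins[i] <- half + 1L
  }
  structure(
    list(freqs = freqs, sigma_t = sigma_t, kernels = kernels,
         origins = origins, sfreq = sfreq, n_sd = n_sd),
    class = "wavelet_family"
  )
}

#' Trial-averaged wavelet power
#'
#' Convolves every trial of one channel with each wavelet kernel (in the
#' frequency domain, 'same'-length output aligned to the epoch), takes the
#' squared complex magnitude, and averages across trials. Near the epoch
#' edges the finite epoch truncates the kernel, which would bias power
#' downward by a deterministic, data-independent factor; each bin is
#' therefore divided by the fraction of kernel energy that overlaps the
#' epoch, making edge bins unbiased (at the cost of higher variance). The
#' earliest and latest time bins of the lowest frequencies are additionally
#' flagged edge-contaminated where the epoch is shorter than the kernel's
#' `+/- n_sd * sigma_t` support; flagged bins are reported in the result's
#' metadata, not removed.
#'
#' @param epochs an [extract_epochs()] result cut on the time-frequency window
#'   (-1.5 to 2.2 s, no baseline correction).
#' @param channel channel label to decompose.
#' @param family a [wavelet_family()].
#' @param edge_taper_s length (seconds) of the raised-cosine ramp applied to
#'   each end of every epoch before convolution (default 0.25 s). Tapering
#'   suppresses the spurious broadband power that the abrupt epoch edges
#'   would otherwise leak into the decomposition; the edge-bias correction
#'   accounts for the taper, so tapered bins stay unbiased in expectation.
#' @return an object of class `tfr`: `power` (frequency x time, raw),
#'   `freqs`, `times`, `sfreq`, `n_trials`, `units = "uV^2 (arbitrary scale)"`,
#'   `edge_flags` (logical frequency x time matrix).
#' @export
tfr_power <- function(epochs, channel,
                      family = wavelet_family(sfreq = epochs$sfreq),
                      edge_taper_s = 0.25) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(family, "wavelet_family"))
  if (!isTRUE(all.equal(family$sfreq, epochs$sfreq))) {
    stop("wavelet family sampling rate does not match the epochs", call. = FALSE)
  }
  ci <- match(channel, epochs$channels)
  if (is.na(ci)) stop("channel not present: ", channel, call. = FALSE)
  x <- t(epochs$data[, ci, , drop = TRUE]) # samples x trials
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n_samp <- nrow(x)
  n_trials <- ncol(x)
  ## raised-cosine ramps at both epoch ends
  taper <- rep(1, n_samp)
  n_ramp <- min(n_samp %/% 2L, as.integer(round(edge_taper_s * epochs$sfreq)))
  if (n_ramp > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / (n_ramp + 1)))
    taper[seq_len(n_ramp)] <- ramp
    taper[n_samp + 1L - seq_len(n_ramp)] <- ramp
  }
  x <- x * taper
  max_len <- max(lengths(family$kernels))
  nfft <- stats::nextn(n_samp + max_len - 1L, 2)
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n_samp, n_trials)))
  n_freqs <- length(family$freqs)
  power <- matrix(0, n_freqs, n_samp)
  taper2_pad <- c(taper^2, rep(0, nfft - n_samp))
  for (i in seq_len(n_freqs)) {
    kern <- family$kernels[[i]]
    K <- stats::fft(c(kern, rep(0, nfft - length(kern))))
    conv <- stats::mvfft(X * K, inverse = TRUE) / nfft
    seg <- Mod(conv[family$origins[i]:(family$origins[i] + n_samp - 1L), ,
                    drop = FALSE])^2
    ## unbiased edge correction: expected fraction of kernel energy captured
    ## at each output position given the finite, tapered epoch — the
    ## convolution of the squared taper with the kernel's energy profile
    e <- Mod(kern)^2
    E <- stats::fft(c(e, rep(0, nfft - length(e))))
    frac_full <- Re(stats::fft(stats::fft(taper2_pad) * E, inverse = TRUE)) /
      nfft / sum(e)
    frac <- frac_full[family$origins[i]:(family$origins[i] + n_samp - 1L)]
    frac <- pmax(frac, 1e-6)
    power[i, ] <- rowMeans(seg) / frac
  }
  ## flag bins closer to either epoch edge than the kernel half-support
  edge <- matrix(FALSE, n_freqs, n_samp)
  half_bins <- ceiling(family$n_sd * family$sigma_t * family$sfreq)
  for (i in seq_len(n_freqs)) {
    hb <- min(half_bins[i], n_samp)
    if (hb > 0) {
      edge[i, seq_len(hb)] <- TRUE
      edge[i, seq.int(n_samp - hb + 1L, n_samp)] <- TRUE
    }
  }
  structure(
    list(power = power, freqs = family$freqs, times = epochs$times,
         sfreq = epochs$sfreq, n_trials = n_trials,
         units = "uV^2 (arbitrary scale)", edge_flags = edge,
         channel = channel),
    class = "tfr"
  )
}

#' Decibel baseline normalisation
#'
#' `dB(f, t) = 10 * log10(power(f, t) / baseline(f))` where `baseline(f)` is
#' the mean raw power over the pre-stimulus baseline interval at frequency
#' `f`. By construction the mean of `power/baseline` over the baseline
#' interval is exactly 1 at each frequency.
#'
#' @param tfr a raw [tfr_power()] result.
#' @param baseline baseline interval in seconds (default `c(-0.4, -0.1)`).
#' @return the `tfr` with `power` replaced by decibel values and
#'   `units = "dB"`; the raw baseline spectrum is kept as `baseline_power`.
#' @export
db_normalize <- function(tfr, baseline = c(-0.4, -0.1)) {
  stopifnot(inherits(tfr, "tfr"))
  if (identical(tfr$units, "dB")) stop("already dB-normalized", call. = FALSE)
  b_idx <- which(tfr$times >= baseline[1] & tfr$times <= baseline[2])
  if (!length(b_idx)) stop("baseline interval outside epoch", call. = FALSE)
  base <- rowMeans(tfr$power[, b_idx, drop = FALSE])
  if (any(base <= 0)) {
    stop("zero baseline power at one or more frequencies", call. = FALSE)
  }
  tfr$power <- 10 * log10(tfr$power / base)
  tfr$units <- "dB"
  tfr$baseline_power <- base
  tfr$baseline_window <- baseline
  tfr
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("<tfr> %d freqs (%.3g-%.3g Hz) x %d times (%g..%g s), %s, %d trial(s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              min(x$times), max(x$times), x$units, x$n_trials))
  invisible(x)
}
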