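#' @keywords internal
"_PACKAGE"

## Conventions used throughout the package:
##   - sample indices are 0-based; sample k corresponds to time k / sfreq
##   - windows are half-open [start, end) in seconds
##   - amplitudes are in microvolts; times in seconds internally,
##     milliseconds only in printed reports

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from a single master seed; per-unit
#' substreams (one per participant, per iteration batch, ...) are derived with
#' a fixed affine map modulo a Mersenne prime so that any single unit can be
#' re-simulated in isolation.
#'
#' @param seed master seed (integer).
#' @param index non-negative integer identifying the substream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  as.integer((abs(seed) %% m + 104729 * (index + 1)) %% (m - 1) + 1)
}

## FFT-based linear convolution, returning the 'same' central part so that
## output[k] is aligned with input[k] for a kernel whose reference point is
## `origin` (1-based index into the kernel).
fft_conv_same <- function(x, kernel, origin = (length(kernel) + 1) / 2) {
  n <- length(x)
  nk <- length(kernel)
  nfft <- stats::nextn(n + nk - 1L, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  K <- stats::fft(c(kernel, rep(0, nfft - nk)))
  full <- stats::fft(X * K, inverse = TRUE) / nfft
  idx <- seq.int(from = round(origin), length.out = n)
  full[idx]
}

## Zero-phase brick-wall band-pass via FFT (used by the synthetic generator
## where an idealised band split is wanted; the preprocessing module uses a
## windowed-sinc FIR instead). The input is zero-padded to a 5-smooth length
## so the FFT stays O(n log n) for any input size.
fft_bandpass <- function(x, sfreq, f_lo, f_hi) {
  n <- length(x)
  n2 <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, n2 - n)))
  f <- seq(0, sfreq, length.out = n2 + 1)[1:n2]
  f <- pmin(f, sfreq - f) # two-sided frequency magnitude
  keep <- f >= f_lo & f <= f_hi
  Re(stats::fft(X * keep, inverse = TRUE) / n2)[seq_len(n)]
}

assert_positive_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("'%s' must be a positive integer (got %s)", name,
                 paste(x, collapse = ",")), call. = FALSE)
  }
  invisible(as.integer(x))
}
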