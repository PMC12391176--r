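#' Pinprick stimulation protocol description
#'
#' The stimulation schedule used during data collection: sets of one stimulus
#' per hand-dorsum compartment, applied to both hands in alternation, the whole
#' block repeated. At the defaults (10 sets x 8 compartments x 2 rounds) each
#' hand receives 160 pinpricks.
#'
#' @param n_sets sets per hand per round (default 10).
#' @param n_compartments compartments drawn on the hand dorsum (default 8);
#'   each appears exactly once per set, in random order.
#' @param n_rounds number of times the whole block is repeated (default 2).
#' @param isi_mean mean inter-stimulus interval in seconds (default 3 s).
#' @param isi_jitter half-width of the uniform jitter on the interval
#'   (default 0.5 s). The default spacing keeps adjacent time-frequency epochs
#'   (-1.5 to 2.2 s) from overlapping neighbouring responses.
#' @param hands ordered pair of hand labels, stimulated in set-by-set
#'   alternation.
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(n_sets = 10, n_compartments = 8, n_rounds = 2,
                              isi_mean = 3, isi_jitter = 0.5,
                              hands = c("left", "right")) {
  assert_positive_count(n_sets, "n_sets")
  assert_positive_count(n_compartments, "n_compartments")
  assert_positive_count(n_rounds, "n_rounds")
  stopifnot(isi_mean > 0, isi_jitter >= 0, isi_jitter < isi_mean,
            length(hands) == 2)
  structure(
    list(n_sets = as.integer(n_sets),
         n_compartments = as.integer(n_compartments),
         n_rounds = as.integer(n_rounds),
         isi_mean = isi_mean, isi_jitter = isi_jitter, hands = hands),
    class = "stimulus_protocol"
  )
}

#' Generate a stimulus-event table from a protocol
#'
#' Draws compartment orders (uniform permutation within each set) and
#' inter-stimulus intervals, and lays the stimuli out in time with hands
#' alternating set by set. Event times are strictly increasing and each hand
#' receives exactly `n_sets * n_compartments * n_rounds` stimuli.
#'
#' @param protocol a [stimulus_protocol()].
#' @param seed integer seed; the same seed reproduces the same table.
#' @param sfreq sampling rate used to snap onsets to samples (default 256 Hz).
#' @param t_start time of the first stimulus in seconds (default 5 s, leaving
#'   room for the pre-stimulus epoch window).
#' @return a `data.frame` with columns `onset_sample` (0-based), `onset_s`,
#'   `hand`, `compartment`, `set`, `round`.
#' @export
generate_protocol <- function(protocol = stimulus_protocol(), seed = 1,
                              sfreq = 256, t_start = 5) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  set.seed(seed)
  p <- protocol
  n_per_set <- p$n_compartments
  sets_per_round <- p$n_sets * 2L # both hands, alternating
  rows <- vector("list", p$n_rounds * sets_per_round)
  k <- 0L
  for (r in seq_len(p$n_rounds)) {
    for (s in seq_len(sets_per_round)) {
      hand <- p$hands[(s - 1L) %% 2L + 1L]
      k <- k + 1L
      rows[[k]] <- data.frame(
        hand = hand,
        compartment = sample.int(n_per_set),
        set = (s - 1L) %/% 2L + 1L,
        round = r
      )
    }
  }
  ev <- do.call(rbind, rows)
  n_ev <- nrow(ev)
  isi <- stats::runif(n_ev, p$isi_mean - p$isi_jitter, p$isi_mean + p$isi_jitter)
  t <- t_start + cumsum(isi) - isi[1]
  ev$onset_sample <- as.integer(round(t * sfreq))
  ev$onset_s <- ev$onset_sample / sfreq
  ev[, c("onset_sample", "onset_s", "hand", "compartment", "set", "round")]
}
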