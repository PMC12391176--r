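#' Measure the negative-positive SEP peak complex
#'
#' On a trial-averaged ERP: the negative peak is the minimum within the
#' negative search window; the positive peak is the maximum within the
#' positive window, constrained to follow the negative peak. The
#' peak-to-peak amplitude is positive-peak value minus negative-peak value;
#' the latency is the positive peak's time. A flat signal across the search
#' region is flagged invalid.
#'
#' @param erp an [average_epochs()] result.
#' @param channel channel label (`"C3"` or `"C4"` in practice).
#' @param neg_window negative-peak search window in seconds
#'   (default `c(0.05, 0.25)`; the reported healthy positive latency of
#'   202.69 +/- 70.62 ms falls inside the defaults).
#' @param pos_max upper bound of the positive-peak search in seconds
#'   (default 0.5); the search starts just after the negative peak.
#' @return a one-row `data.frame`: `channel`, `np_amplitude` (uV),
#'   `pos_latency` (ms), `neg_latency` (ms), `n_epochs`, `valid`.
#' @export
measure_sep <- function(erp, channel, neg_window = c(0.05, 0.25),
                        pos_max = 0.5) {
  stopifnot(channel %in% erp$channels)
  y <- erp$erp[channel, ]
  t <- erp$times
  neg_idx <- which(t >= neg_window[1] & t <= neg_window[2])
  if (!length(neg_idx)) stop("negative search window outside epoch", call. = FALSE)
  search_all <- which(t >= neg_window[1] & t <= pos_max)
  if (diff(range(y[search_all])) < .Machine$double.eps * 100) {
    return(data.frame(channel = channel, np_amplitude = NA_real_,
                      pos_latency = NA_real_, neg_latency = NA_real_,
                      n_epochs = erp$n_epochs, valid = FALSE))
  }
  i_neg <- neg_idx[which.min(y[neg_idx])]
  pos_idx <- which(t > t[i_neg] & t <= pos_max)
  if (!length(pos_idx)) {
    return(data.frame(channel = channel, np_amplitude = NA_real_,
                      pos_latency = NA_real_, neg_latency = NA_real_,
                      n_epochs = erp$n_epochs, valid = FALSE))
  }
  i_pos <- pos_idx[which.max(y[pos_idx])]
  data.frame(channel = channel,
             np_amplitude = y[i_pos] - y[i_neg],
             pos_latency = 1000 * t[i_pos],
             neg_latency = 1000 * t[i_neg],
             n_epochs = erp$n_epochs,
             valid = TRUE)
}

#' Select the analysis channel and condition for a participant
#'
#' Stroke participants are analysed at the ipsilesional central electrode
#' (C3 for a left-hemisphere lesion, C4 for right), for stimulation of the
#' impaired hand; healthy controls at the electrode contralateral to the
#' stimulated (dominant) hand.
#'
#' @param group `"healthy"`, `"motor"` or `"sensorimotor"`.
#' @param lesion_side `"left"`, `"right"` or `"none"`.
#' @param hand the stimulated hand entering the analysis (impaired hand for
#'   stroke; dominant hand for controls).
#' @return a list: `channel` (`"C3"`/`"C4"`), `hand`.
#' @export
select_analysis_channel <- function(group, lesion_side, hand) {
  if (is.na(group) || is.na(hand)) {
    stop("group and hand metadata are required", call. = FALSE)
  }
  if (group == "healthy") {
    return(list(channel = contralateral_channel(hand), hand = hand))
  }
  if (is.na(lesion_side) || lesion_side == "none") {
    stop("lesion side required for stroke participants", call. = FALSE)
  }
  channel <- switch(lesion_side, left = "C3", right = "C4",
                    stop("unknown lesion side: ", lesion_side, call. = FALSE))
  list(channel = channel, hand = hand)
}
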