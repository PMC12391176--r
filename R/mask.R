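#' Masking configuration
#'
#' Parameters of the circular-shift bootstrapping mask: number of surrogate
#' iterations (2000), the inclusion percentile (95), the post-stimulus
#' analysis window (0 to 1.6 s), sidedness, and the region-of-interest
#' labelling rules.
#'
#' @param n_iterations surrogate iterations (default 2000; at least 100).
#' @param percentile inclusion percentile (default 95).
#' @param analysis analysis window in seconds (default `c(0, 1.6)`).
#' @param baseline baseline interval in seconds (default `c(-0.4, -0.1)`).
#' @param two_sided if `TRUE` (default) the comparison uses `|t|` against the
#'   null `|t|` percentile, so desynchronizations (negative effects) can enter
#'   the mask; `FALSE` gives the literal one-sided rule on signed `t`.
#' @param min_roi_bins smallest component kept as a region of interest
#'   (default 10).
#' @param split_sign if `TRUE` (default) connected components are formed
#'   separately for positive-t and negative-t bins, so synchronization and
#'   desynchronization regions are never fused into one region.
#' @param split_bands frequency boundaries (Hz) at which components are split,
#'   defaulting to the standard EEG band taxonomy delta/theta/alpha-beta
#'   (4, 7, 13 Hz); band-adjacent same-sign phenomena are contiguous on the
#'   log-spaced grid and would otherwise merge. `NULL` disables splitting.
#' @return an object of class `mask_config`.
#' @export
mask_config <- function(n_iterations = 2000, percentile = 95,
                        analysis = c(0, 1.6), baseline = c(-0.4, -0.1),
                        two_sided = TRUE, min_roi_bins = 10,
                        split_sign = TRUE, split_bands = c(4, 7, 13)) {
  stopifnot(percentile > 0, percentile < 100, n_iterations >= 100)
  structure(
    list(n_iterations = as.integer(n_iterations), percentile = percentile,
         analysis = analysis, baseline = baseline, two_sided = two_sided,
         min_roi_bins = as.integer(min_roi_bins), split_sign = split_sign,
         split_bands = split_bands),
    class = "mask_config"
  )
}

#' Stack per-participant time-frequency matrices
#'
#' Collects dB-normalized matrices from all participants (all groups, all
#' pinprick conditions averaged per participant) into one participant x
#' frequency x time array, and computes the grand average. Pooling across
#' groups mitigates circularity between mask discovery and the group
#' statistics computed inside the mask.
#'
#' @param tfrs list of dB `tfr` objects, one per participant (a participant's
#'   conditions should be averaged into one matrix first, e.g. with
#'   [average_tfrs()]).
#' @return an object of class `tf_stack`: `x` (n x F x T array), `freqs`,
#'   `times`, `grand` (F x T matrix).
#' @export
grand_average_stack <- function(tfrs) {
  stopifnot(length(tfrs) >= 2)
  f0 <- tfrs[[1]]$freqs
  t0 <- tfrs[[1]]$times
  for (tf in tfrs) {
    if (!isTRUE(all.equal(tf$freqs, f0)) || !isTRUE(all.equal(tf$times, t0))) {
      stop("time-frequency axes differ across participants", call. = FALSE)
    }
    if (!identical(tf$units, "dB")) {
      stop("stack requires dB-normalized matrices", call. = FALSE)
    }
  }
  x <- array(0, c(length(tfrs), length(f0), length(t0)))
  for (i in seq_along(tfrs)) x[i, , ] <- tfrs[[i]]$power
  structure(
    list(x = x, freqs = f0, times = t0,
         grand = apply(x, c(2, 3), mean)),
    class = "tf_stack"
  )
}

#' Average several TFR matrices of one participant
#'
#' Element-wise mean over conditions (e.g. left- and right-hand pinpricks at
#' their contralateral electrodes); axes must match.
#'
#' @param tfrs list of `tfr` objects with identical axes and units.
#' @return a single `tfr`.
#' @export
average_tfrs <- function(tfrs) {
  out <- tfrs[[1]]
  if (length(tfrs) == 1) return(out)
  for (tf in tfrs[-1]) {
    stopifnot(isTRUE(all.equal(tf$freqs, out$freqs)),
              identical(tf$units, out$units))
    out$power <- out$power + tf$power
  }
  out$power <- out$power / length(tfrs)
  out$n_trials <- sum(vapply(tfrs, function(t) t$n_trials, numeric(1)))
  out$channel <- paste(unique(vapply(tfrs, function(t) t$channel %||% "?",
                                     character(1))), collapse = "+")
  out
}

## Core t-statistic engine. P: n x F x T array; fidx/tidx_a are the source
## rows/columns (already circularly remapped for a shifted surrogate). Each
## value is centred on the participant's mean baseline dB at the value's own
## (source) frequency; a one-sample t across participants is then computed
## per bin. The baseline reference is either recomputed from the remapped
## columns `tidx_b` (literal shifted-baseline variant) or taken from a
## precomputed n x F matrix `bm0` of unshifted pre-stimulus means (default
## surrogate behaviour; see [circular_shift_null()]). Returns a F x Ta
## matrix.
tstat_core <- function(P, fidx, tidx_a, tidx_b = NULL, bm0 = NULL,
                       warn_zero_var = FALSE) {
  n <- dim(P)[1]
  Fn <- length(fidx)
  Ta <- length(tidx_a)
  A <- matrix(P[, fidx, tidx_a, drop = FALSE], n, Fn * Ta)
  bm <- if (is.null(bm0)) {
    B <- P[, fidx, tidx_b, drop = FALSE]
    ## per-(participant, frequency) baseline mean, participant-fastest order
    rowMeans(matrix(B, n * Fn, length(tidx_b)))
  } else {
    as.vector(bm0[, fidx, drop = FALSE])
  }
  ## replicate the n*Fn reference across the Ta time columns
  D <- A - matrix(bm, n, Fn * Ta)
  mu <- colMeans(D)
  ss <- colSums(D * D)
  va <- (ss - n * mu^2) / (n - 1)
  va[va < 0] <- 0
  tt <- mu / sqrt(va / n)
  if (warn_zero_var && any(va == 0)) {
    warning("zero variance at ", sum(va == 0),
            " bin(s); t set to +/- Inf", call. = FALSE)
  }
  matrix(tt, Fn, Ta)
}

## Resolve analysis/baseline column indices on a stack's time axis.
mask_indices <- function(stack, config) {
  list(
    analysis = which(stack$times >= config$analysis[1] &
                       stack$times <= config$analysis[2]),
    baseline = which(stack$times >= config$baseline[1] &
                       stack$times <= config$baseline[2])
  )
}

#' Pointwise one-sample t-statistics against baseline
#'
#' At each time-frequency bin of the analysis window, the one-sample t across
#' participants of the dB value minus that participant's mean baseline dB at
#' the same frequency (`df = n - 1`). Bins with zero variance give
#' `t = +/- Inf` with a warning.
#'
#' @param stack a [grand_average_stack()] result (at least 3 participants).
#' @param config a [mask_config()].
#' @return a list: `t` (F x Ta matrix), `freqs`, `times` (analysis bins),
#'   `n`.
#' @export
pointwise_tstats <- function(stack, config = mask_config()) {
  stopifnot(inherits(stack, "tf_stack"))
  n <- dim(stack$x)[1]
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  ix <- mask_indices(stack, config)
  if (!length(ix$analysis) || !length(ix$baseline)) {
    stop("analysis or baseline window outside the stack's time axis",
         call. = FALSE)
  }
  Fn <- dim(stack$x)[2]
  t_mat <- tstat_core(stack$x, seq_len(Fn), ix$analysis, ix$baseline,
                      warn_zero_var = TRUE)
  list(t = t_mat, freqs = stack$freqs, times = stack$times[ix$analysis], n = n)
}

#' Circular-shift surrogate null distribution
#'
#' Per iteration a single shift `(df, dt)` is drawn uniformly over the grid
#' dimensions and applied, with wrap-around on both axes, to every
#' participant's matrix (the same shift for all, preserving the
#' between-participant structure); the t-matrix is then recomputed on the
#' analysis window. At the defaults this yields 2000 null t-values per
#' time-frequency bin.
#'
#' By default each shifted value keeps its own participant's unshifted
#' pre-stimulus baseline mean (at the value's source frequency) as the
#' reference: the surrogate destroys the event alignment of the tested
#' values while leaving the reference intact. Re-deriving the reference from
#' the wrapped matrix (`shift_baseline = TRUE`) lets post-stimulus effect
#' plateaus rotate under the baseline columns, which offsets whole frequency
#' rows coherently across participants and yields surrogate statistics that
#' match or exceed any aligned effect at every effect size — a null for a
#' different hypothesis, under which genuine responses can never reach the
#' inclusion percentile.
#'
#' @param stack a [grand_average_stack()] result.
#' @param config a [mask_config()].
#' @param seed integer seed for the shift draws.
#' @param exhaustive if `TRUE`, ignore `n_iterations` and enumerate all
#'   `F x T` distinct shifts once (for exact small-grid work).
#' @param shift_baseline if `TRUE`, recompute each iteration's baseline
#'   reference from the shifted matrix instead of keeping the unshifted
#'   reference (default `FALSE`; see above).
#' @return an object of class `tf_null`: `t` (iterations x bins matrix, bins
#'   in column-major F x Ta order), `shifts` (data.frame `df`, `dt`),
#'   `dim = c(F, Ta)`.
#' @export
circular_shift_null <- function(stack, config = mask_config(), seed = 1,
                                exhaustive = FALSE, shift_baseline = FALSE) {
  stopifnot(inherits(stack, "tf_stack"))
  Fn <- dim(stack$x)[2]
  Tn <- dim(stack$x)[3]
  ix <- mask_indices(stack, config)
  if (exhaustive) {
    shifts <- expand.grid(df = 0:(Fn - 1), dt = 0:(Tn - 1))
  } else {
    set.seed(seed)
    shifts <- data.frame(df = sample.int(Fn, config$n_iterations, replace = TRUE) - 1L,
                         dt = sample.int(Tn, config$n_iterations, replace = TRUE) - 1L)
  }
  n_iter <- nrow(shifts)
  n_bins <- Fn * length(ix$analysis)
  null_t <- matrix(NA_real_, n_iter, n_bins)
  f_base <- 0:(Fn - 1)
  bm0 <- NULL
  if (!shift_baseline) {
    ## unshifted per-participant baseline means, one per frequency row
    n <- dim(stack$x)[1]
    bm0 <- matrix(rowMeans(matrix(stack$x[, , ix$baseline], n * Fn,
                                  length(ix$baseline))), n, Fn)
  }
  for (it in seq_len(n_iter)) {
    fidx <- ((f_base - shifts$df[it]) %% Fn) + 1L
    tidx_a <- ((ix$analysis - 1L - shifts$dt[it]) %% Tn) + 1L
    if (shift_baseline) {
      tidx_b <- ((ix$baseline - 1L - shifts$dt[it]) %% Tn) + 1L
      null_t[it, ] <- as.vector(tstat_core(stack$x, fidx, tidx_a, tidx_b))
    } else {
      null_t[it, ] <- as.vector(tstat_core(stack$x, fidx, tidx_a, bm0 = bm0))
    }
  }
  structure(
    list(t = null_t, shifts = shifts, dim = c(Fn, length(ix$analysis)),
         freqs = stack$freqs, times = stack$times[ix$analysis]),
    class = "tf_null"
  )
}

#' Threshold the observed t-matrix against its surrogate null
#'
#' A bin enters the mask when its observed statistic reaches the configured
#' percentile of that bin's own null distribution: with `two_sided = TRUE`
#' (default) the comparison is `|t_obs| >= q95(|t_null|)`; one-sided uses
#' signed values. The percentile is the `ceiling(p/100 * n_iter)`-th smallest
#' null value, so the rule is exact under full enumeration.
#'
#' @param tstats a [pointwise_tstats()] result.
#' @param null a [circular_shift_null()] result computed on the same stack
#'   and config.
#' @param config the [mask_config()] used for both.
#' @return an object of class `tf_mask`: `mask` (logical F x Ta), `t`
#'   (observed), `threshold` (per-bin F x Ta), `freqs`, `times`, `config`.
#' @export
build_mask <- function(tstats, null, config = mask_config()) {
  Fn <- null$dim[1]
  Ta <- null$dim[2]
  stopifnot(nrow(tstats$t) == Fn, ncol(tstats$t) == Ta)
  n_iter <- nrow(null$t)
  k <- ceiling(config$percentile / 100 * n_iter)
  stat_null <- if (config$two_sided) abs(null$t) else null$t
  stat_obs <- if (config$two_sided) abs(tstats$t) else tstats$t
  thr <- apply(stat_null, 2, function(v) sort(v)[k])
  mask <- matrix(stat_obs >= matrix(thr, Fn, Ta), Fn, Ta)
  structure(
    list(mask = mask, t = tstats$t, threshold = matrix(thr, Fn, Ta),
         freqs = tstats$freqs, times = tstats$times, config = config),
    class = "tf_mask"
  )
}

## 4-connected component labelling by flood fill within cells of `cell_id`
## (bins with cell_id NA are background).
label_components <- function(cell_id) {
  Fn <- nrow(cell_id)
  Ta <- ncol(cell_id)
  comp <- matrix(0L, Fn, Ta)
  next_label <- 0L
  for (start in which(!is.na(cell_id))) {
    if (comp[start] != 0L) next
    next_label <- next_label + 1L
    queue <- start
    comp[start] <- next_label
    id <- cell_id[start]
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      fi <- (cur - 1L) %% Fn + 1L
      ti <- (cur - 1L) %/% Fn + 1L
      for (nb in c(if (fi > 1) cur - 1L, if (fi < Fn) cur + 1L,
                   if (ti > 1) cur - Fn, if (ti < Ta) cur + Fn)) {
        if (comp[nb] == 0L && !is.na(cell_id[nb]) && cell_id[nb] == id) {
          comp[nb] <- next_label
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

#' Label regions of interest in a time-frequency mask
#'
#' Finds 4-connected components of the mask, with components formed within
#' sign (synchronization vs desynchronization, from the observed t) and
#' within canonical frequency bands (see [mask_config()]); components smaller
#' than `min_roi_bins` are discarded. Each region is reported with its
#' frequency and time bounds, a band label derived from its centroid
#' frequency, and its member bins.
#'
#' @param mask a [build_mask()] result.
#' @param config a [mask_config()] (defaults to the mask's own).
#' @return an object of class `roi_set`: a list of regions, each with
#'   `label`, `f_lo`, `f_hi` (Hz), `t_lo`, `t_hi` (ms), `n_bins`, `mean_t`,
#'   `direction`, `bins` (logical F x Ta matrix). An empty mask yields an
#'   empty set.
#' @export
label_rois <- function(mask, config = mask$config) {
  stopifnot(inherits(mask, "tf_mask"))
  Fn <- nrow(mask$mask)
  Ta <- ncol(mask$mask)
  cell <- matrix(NA_real_, Fn, Ta)
  sign_part <- if (isTRUE(config$split_sign)) sign(mask$t) else 1
  band_of <- if (is.null(config$split_bands)) {
    rep(1, Fn)
  } else {
    findInterval(mask$freqs, config$split_bands)
  }
  cell[mask$mask] <- (matrix(band_of, Fn, Ta)[mask$mask]) * 10 +
    (if (is.matrix(sign_part)) sign_part[mask$mask] else sign_part)
  comp <- label_components(cell)
  rois <- list()
  for (lab in setdiff(unique(as.vector(comp)), 0L)) {
    bins <- comp == lab
    if (sum(bins) < config$min_roi_bins) next
    fi <- row(bins)[bins]
    ti <- col(bins)[bins]
    mean_t <- mean(mask$t[bins])
    centroid_f <- exp(mean(log(mask$freqs[fi])))
    band <- c("delta", "theta", "alpha", "beta")[
      findInterval(centroid_f, c(0, 4, 7, 13, Inf))]
    dir <- if (mean_t >= 0) "sync" else "desync"
    rois[[length(rois) + 1]] <- list(
      label = paste0(band, "_", dir),
      f_lo = min(mask$freqs[fi]), f_hi = max(mask$freqs[fi]),
      t_lo = 1000 * min(mask$times[ti]), t_hi = 1000 * max(mask$times[ti]),
      n_bins = sum(bins), mean_t = mean_t,
      direction = if (mean_t >= 0) 1 else -1,
      bins = bins
    )
  }
  ## disambiguate duplicate labels by descending size
  labels <- vapply(rois, `[[`, character(1), "label")
  for (lb in unique(labels[duplicated(labels)])) {
    idx <- which(labels == lb)
    idx <- idx[order(-vapply(rois[idx], `[[`, numeric(1), "n_bins"))]
    for (j in seq_along(idx)[-1]) {
      rois[[idx[j]]]$label <- paste0(lb, "_", j)
    }
  }
  structure(rois, class = "roi_set",
            freqs = mask$freqs, times = mask$times)
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d region(s)\n", length(x)))
  for (r in x) {
    cat(sprintf("  %-14s %5.2f-%5.2f Hz  %6.0f-%6.0f ms  %4d bins  mean t %6.2f\n",
                r$label, r$f_lo, r$f_hi, r$t_lo, r$t_hi, r$n_bins, r$mean_t))
  }
  invisible(x)
}

#' Mean dB power inside each region of interest
#'
#' For one participant/condition dB matrix, the mean over each region's
#' member bins.
#'
#' @param tfr a dB `tfr` whose axes cover the mask's analysis window.
#' @param rois a [label_rois()] result.
#' @return a `data.frame` with one row per region: `roi`, `mean_db`, `n_bins`.
#' @export
extract_roi_power <- function(tfr, rois) {
  stopifnot(inherits(tfr, "tfr"), inherits(rois, "roi_set"),
            identical(tfr$units, "dB"))
  roi_times <- attr(rois, "times")
  roi_freqs <- attr(rois, "freqs")
  t_map <- match(round(roi_times, 9), round(tfr$times, 9))
  f_map <- match(round(roi_freqs, 9), round(tfr$freqs, 9))
  if (anyNA(t_map) || anyNA(f_map)) {
    stop("ROI axes are not a subset of the TFR axes", call. = FALSE)
  }
  sub <- tfr$power[f_map, t_map, drop = FALSE]
  data.frame(
    roi = vapply(rois, `[[`, character(1), "label"),
    mean_db = vapply(rois, function(r) mean(sub[r$bins]), numeric(1)),
    n_bins = vapply(rois, `[[`, numeric(1), "n_bins"),
    stringsAsFactors = FALSE
  )
}

#' Jaccard overlap between a region and a rectangular window
#'
#' Bin-level Jaccard index between a labelled region's member bins and the
#' rectangle spanned by a frequency band and time window on the same grid.
#'
#' @param roi one element of a [label_rois()] result.
#' @param freqs,times the mask's axes.
#' @param f_lo,f_hi,t_lo,t_hi window bounds (Hz, seconds).
#' @return a number in `[0, 1]`.
#' @export
roi_jaccard <- function(roi, freqs, times, f_lo, f_hi, t_lo, t_hi) {
  rect <- outer(freqs >= f_lo & freqs <= f_hi,
                times >= t_lo & times <= t_hi, `&`)
  inter <- sum(roi$bins & rect)
  uni <- sum(roi$bins | rect)
  if (uni == 0) 0 else inter / uni
}
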