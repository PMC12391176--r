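#' Cohort specification for the synthetic pinprick-EEG generator
#'
#' Describes a synthetic study cohort: group sizes (healthy controls, motor
#' stroke, sensorimotor stroke), recording parameters, the 1/f background, and
#' the stimulus protocol. The defaults reproduce the study conditions: 10/6/10
#' participants, 256 Hz, 160 pinpricks per hand.
#'
#' @param n_healthy,n_motor,n_sensorimotor group sizes (default 10, 6, 10).
#' @param sfreq sampling rate in Hz (default 256); must exceed twice the
#'   highest analysis frequency (35 Hz).
#' @param channels channel labels; must include C3 and C4.
#' @param background_exponent 1/f slope of the background (default 1).
#' @param background_rms background RMS in microvolts (default 10).
#' @param background_rms_jitter per-channel log10 RMS jitter SD emulating
#'   electrode-gain heterogeneity (default 0.05, about +/- 12%).
#' @param protocol a [stimulus_protocol()].
#' @param seed master seed; every participant's data derives from it through
#'   named substreams (see [derive_seed()]).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 10, n_motor = 6, n_sensorimotor = 10,
                        sfreq = 256,
                        channels = c("F3", "F4", "C3", "C4", "P3", "P4"),
                        background_exponent = 1, background_rms = 10,
                        background_rms_jitter = 0.05,
                        protocol = stimulus_protocol(), seed = 1) {
  assert_positive_count(n_healthy, "n_healthy")
  assert_positive_count(n_motor, "n_motor")
  assert_positive_count(n_sensorimotor, "n_sensorimotor")
  if (sfreq <= 2 * 35) {
    stop("sampling rate must exceed twice the highest analysis frequency",
         call. = FALSE)
  }
  if (!all(c("C3", "C4") %in% channels)) {
    stop("channel set must include C3 and C4", call. = FALSE)
  }
  structure(
    list(n_healthy = n_healthy, n_motor = n_motor,
         n_sensorimotor = n_sensorimotor, sfreq = sfreq, channels = channels,
         background_exponent = background_exponent,
         background_rms = background_rms,
         background_rms_jitter = background_rms_jitter,
         protocol = protocol, seed = seed),
    class = "cohort_spec"
  )
}

#' Group-level generator defaults
#'
#' Per-group means and between-participant SDs of the evoked-response peak
#' metrics, and the per-group oscillatory amplitude gains for the five
#' canonical regions of interest. Amplitude and latency defaults are the
#' group-level values reported for pinprick stimulation (healthy
#' 2.81 uV / 202.69 ms; motor 3.22 uV / 169.09 ms; sensorimotor
#' 1.36 uV / 161.46 ms). Oscillatory gains correspond to about +/- 3 dB
#' power modulation at the taper plateau, the order of magnitude typical of
#' stimulus-locked ERD/ERS in sensorimotor cortex (tens of percent power
#' change, not orders of magnitude); the sensorimotor group's alpha
#' desynchronization is attenuated relative to the others, mirroring the
#' group difference the method is meant to detect.
#'
#' @return a nested list keyed by group.
#' @export
group_defaults <- function() {
  list(
    healthy = list(
      amp_mean = 2.81, amp_sd = 1.30, lat_mean = 0.20269, lat_sd = 0.07062,
      gains = c(delta_sync = 1.5, theta_sync = 1.4, alpha_desync = 0.68,
                beta1_desync = 0.70, beta2_resync = 1.45)
    ),
    motor = list(
      amp_mean = 3.22, amp_sd = 2.68, lat_mean = 0.16909, lat_sd = 0.07605,
      gains = c(delta_sync = 1.5, theta_sync = 1.4, alpha_desync = 0.71,
                beta1_desync = 0.70, beta2_resync = 1.45)
    ),
    sensorimotor = list(
      amp_mean = 1.36, amp_sd = 0.54, lat_mean = 0.16146, lat_sd = 0.06663,
      gains = c(delta_sync = 1.5, theta_sync = 1.4, alpha_desync = 0.80,
                beta1_desync = 0.70, beta2_resync = 1.45)
    )
  )
}

#' Default clinical-score linkage model
#'
#' Clinical scores are generated as linear functions of the injected EEG
#' effect magnitudes (evoked amplitude in microvolts; per-ROI decibel
#' modulation `20*log10(gain)`) plus Gaussian noise, then clipped to the
#' instrument range. Directions mirror the associations the statistical module
#' is meant to recover: motor impairment (FMA, 0-66) worsens with weaker beta
#' desynchronization; somatosensory scores (EmNSA exteroception 0-32) improve
#' with beta resynchronization, with a delta-power association confined to the
#' sensorimotor group; the touch threshold (PTT, mA) depends on evoked
#' amplitude in the sensorimotor group only. Change scores (T2 - T1) follow
#' the prognostic links: beta resynchronization at baseline predicts motor
#' change, amplitude predicts somatosensory change in sensorimotor stroke.
#'
#' Each entry gives an intercept, a named coefficient vector over the feature
#' columns of the ground-truth table (interaction features are products, e.g.
#' `amplitude:smr`), a noise SD, and the instrument range.
#'
#' @return a nested list keyed by outcome.
#' @export
default_clinical_model <- function() {
  list(
    fma_t1 = list(intercept = 12, coefs = c(beta1_db = -5), sd = 6,
                  range = c(0, 66)),
    emnsa_t1 = list(intercept = 20,
                    coefs = c(beta2_db = 2.5, smr = -18, `delta_db:smr` = 2.0),
                    sd = 2, range = c(0, 32)),
    emnsa_prop_t1 = list(intercept = 7.8, coefs = c(smr = -1.6), sd = 0.8,
                         range = c(0, 8)),
    ptt_t1 = list(intercept = 2.5,
                  coefs = c(smr = 7, `amplitude:smr` = -1.5), sd = 1,
                  range = c(0.1, 30)),
    sct_t1 = list(intercept = 54, coefs = c(smr = -12), sd = 4,
                  range = c(0, 54)),
    fma_change = list(intercept = 12, coefs = c(beta2_db = -1.5), sd = 3,
                      range = c(-66, 66)),
    emnsa_change = list(intercept = 0, coefs = c(`amplitude:smr` = 1.2),
                        sd = 1, range = c(-32, 32)),
    ptt_change = list(intercept = 0, coefs = c(smr = -3.4), sd = 1,
                      range = c(-30, 30))
  )
}

## Evaluate one clinical outcome for one participant's feature row.
eval_clinical <- function(spec, feats, noise_scale) {
  val <- spec$intercept
  for (nm in names(spec$coefs)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    x <- prod(vapply(parts, function(p) feats[[p]], numeric(1)))
    val <- val + spec$coefs[[nm]] * x
  }
  latent <- val + stats::rnorm(1, 0, spec$sd * noise_scale)
  list(latent = latent,
       clipped = min(max(latent, spec$range[1]), spec$range[2]))
}

#' Generate a full synthetic pinprick-EEG cohort
#'
#' For each participant: draws evoked-response and oscillatory-gain parameters
#' from the group distributions, generates a stimulus protocol, simulates 1/f
#' background EEG, applies the oscillatory modulations to the background and
#' then adds the evoked responses, and derives clinical scores at T1 and T2
#' from the injected effect magnitudes. The ground truth is returned alongside
#' the data so downstream recovery can be tested.
#'
#' @param spec a [cohort_spec()].
#' @param groups optional override of [group_defaults()].
#' @param clinical_model optional override of [default_clinical_model()].
#' @param clinical_noise_scale multiplier on all clinical noise SDs (0 gives
#'   noise-free scores).
#' @param gain_jitter_db between-participant SD of each ROI modulation in dB,
#'   independent across regions (default 0.75 dB).
#' @param responsiveness_sd SD of a per-participant multiplicative factor on
#'   the log gains, shared across all five regions (default 0.3). This models
#'   the observation that a person's modulation depths co-vary across bands:
#'   a responsive cortex desynchronises and rebounds more across the board.
#' @param keep_recordings if `FALSE`, recordings are dropped after generation
#'   (ground truth and clinical tables only).
#' @return a list with `participants` (per-participant list: `id`, `group`,
#'   `lesion_side`, `impaired_hand`, `recording`), `clinical` (data.frame,
#'   one row per stroke participant with T1/T2 scores; healthy rows carry NA),
#'   and `ground_truth` (one row per participant: injected amplitude, latency,
#'   per-ROI gains and dB magnitudes).
#' @export
generate_cohort <- function(spec = cohort_spec(), groups = group_defaults(),
                            clinical_model = default_clinical_model(),
                            clinical_noise_scale = 1, gain_jitter_db = 0.75,
                            responsiveness_sd = 0.3, keep_recordings = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  group_of <- rep(c("healthy", "motor", "sensorimotor"),
                  c(spec$n_healthy, spec$n_motor, spec$n_sensorimotor))
  n <- length(group_of)
  ## impaired side per stroke participant, following the reported 4:2 (motor)
  ## and 8:2 (sensorimotor) left:right ratios, assigned deterministically
  impaired_side <- function(group, k, n_group) {
    frac_left <- if (group == "motor") 4 / 6 else 8 / 10
    if (k <= round(frac_left * n_group)) "left" else "right"
  }
  participants <- vector("list", n)
  gt_rows <- vector("list", n)
  clin_rows <- vector("list", n)
  counters <- c(healthy = 0L, motor = 0L, sensorimotor = 0L)
  for (i in seq_len(n)) {
    grp <- group_of[i]
    counters[grp] <- counters[grp] + 1L
    g <- groups[[grp]]
    set.seed(derive_seed(spec$seed, i * 10L))
    amp <- max(0.2, stats::rnorm(1, g$amp_mean, g$amp_sd))
    lat <- min(0.35, max(0.09, stats::rnorm(1, g$lat_mean, g$lat_sd)))
    responsiveness <- max(0.1, stats::rnorm(1, 1, responsiveness_sd))
    gains <- exp(log(g$gains) * responsiveness) *
      10^(stats::rnorm(length(g$gains), 0, gain_jitter_db) / 20)
    names(gains) <- names(g$gains)
    if (grp == "healthy") {
      lesion <- "none"
      impaired <- "right" # dominant hand for controls
    } else {
      n_group <- if (grp == "motor") spec$n_motor else spec$n_sensorimotor
      impaired <- impaired_side(grp, counters[grp], n_group)
      lesion <- if (impaired == "left") "right" else "left"
    }
    events <- generate_protocol(spec$protocol, seed = derive_seed(spec$seed, i * 10L + 1L),
                                sfreq = spec$sfreq)
    dur <- max(events$onset_s) + 3
    rec <- simulate_background(dur, spec$sfreq, spec$channels,
                               spec$background_exponent, spec$background_rms,
                               rms_jitter_sd = spec$background_rms_jitter,
                               seed = derive_seed(spec$seed, i * 10L + 2L),
                               events = events)
    rec <- inject_oscillations(rec, events, gains)
    rec <- inject_erp(rec, events, amp, lat)
    dbs <- 20 * log10(gains)
    id <- sprintf("P%02d", i)
    participants[[i]] <- list(id = id, group = grp, lesion_side = lesion,
                              impaired_hand = impaired,
                              recording = if (keep_recordings) rec else NULL)
    gt_rows[[i]] <- data.frame(
      participant = id, group = grp, lesion_side = lesion,
      impaired_hand = impaired, amplitude = amp, latency_s = lat,
      delta_db = dbs[["delta_sync"]], theta_db = dbs[["theta_sync"]],
      alpha_db = dbs[["alpha_desync"]], beta1_db = dbs[["beta1_desync"]],
      beta2_db = dbs[["beta2_resync"]], stringsAsFactors = FALSE
    )
    feats <- as.list(gt_rows[[i]])
    feats$smr <- as.numeric(grp == "sensorimotor")
    set.seed(derive_seed(spec$seed, i * 10L + 3L))
    row <- list(participant = id, group = grp,
                stroke_type = if (grp == "healthy") NA_character_ else grp)
    for (nm in names(clinical_model)) {
      if (grp == "healthy") {
        row[[nm]] <- NA_real_
        row[[paste0(nm, "_latent")]] <- NA_real_
        next
      }
      v <- eval_clinical(clinical_model[[nm]], feats, clinical_noise_scale)
      row[[nm]] <- v$clipped
      row[[paste0(nm, "_latent")]] <- v$latent
    }
    clin_rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  clinical <- do.call(rbind, clin_rows)
  ## express T2 as T1 + change, clipped to the instrument range
  for (oc in c("fma", "emnsa", "ptt")) {
    t1_name <- paste0(oc, "_t1")
    ch_name <- paste0(oc, "_change")
    if (!all(c(t1_name, ch_name) %in% names(clinical))) next
    rng <- clinical_model[[t1_name]]$range
    clinical[[paste0(oc, "_t2")]] <-
      pmin(pmax(clinical[[t1_name]] + clinical[[ch_name]], rng[1]), rng[2])
  }
  list(participants = participants,
       clinical = clinical,
       ground_truth = do.call(rbind, gt_rows),
       spec = spec)
}
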