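test_that("protocol generation honours counts, balance, alternation and seed", {
  ev <- generate_protocol(seed = 7)
  expect_equal(sum(ev$hand == "left"), 160)
  expect_equal(sum(ev$hand == "right"), 160)
  ## each compartment exactly once within every (hand, round, set)
  balance <- tapply(ev$compartment, interaction(ev$hand, ev$round, ev$set),
                    function(x) length(unique(x)) == 8 && length(x) == 8)
  expect_true(all(balance))
  ## hands alternate set-by-set: collapsing consecutive runs of the same hand
  ## must give runs of exactly one set (8 stimuli)
  runs <- rle(ev$hand)
  expect_true(all(runs$lengths == 8))
  expect_true(!is.unsorted(ev$onset_s, strictly = TRUE))
  ## single-set case and determinism
  ev1 <- generate_protocol(stimulus_protocol(n_sets = 1, n_rounds = 1), seed = 2)
  expect_equal(as.integer(table(ev1$hand)), c(8L, 8L))
  expect_identical(generate_protocol(seed = 7), ev)
  expect_error(stimulus_protocol(n_sets = 0), "positive integer")
})

test_that("background noise has the configured spectral slope and RMS scaling", {
  bg0 <- simulate_background(60, exponent = 0, spatial_corr = 0, seed = 3)
  bg1 <- simulate_background(60, exponent = 1, spatial_corr = 0, seed = 3)
  slope_of <- function(x, sfreq = 256) {
    s <- stats::spec.pgram(stats::ts(x, frequency = sfreq), spans = 31,
                           plot = FALSE, taper = 0)
    sel <- s$freq > 2 & s$freq < 30
    unname(coef(lm(log10(s$spec[sel]) ~ log10(s$freq[sel])))[2])
  }
  expect_lt(abs(slope_of(bg0$data[, 1])), 0.15)
  expect_lt(abs(slope_of(bg1$data[, 1]) + 1), 0.15)
  ## RMS linearity
  a <- simulate_background(20, rms = 10, seed = 4)
  b <- simulate_background(20, rms = 20, seed = 4)
  expect_equal(b$data, 2 * a$data, tolerance = 1e-12)
  expect_equal(sqrt(mean(a$data[, 1]^2)), 10, tolerance = 0.2)
  ## too-short duration for an attached protocol errors
  ev <- generate_protocol(seed = 1)
  expect_error(simulate_background(10, events = ev), "too short")
})

test_that("evoked-response injection is null at zero amplitude and superposes", {
  rec <- zero_recording()
  expect_identical(inject_erp(rec, np_amplitude = 0, pos_latency = 0.2), rec)
  expect_error(inject_erp(rec, np_amplitude = 1, pos_latency = 0.6),
               "500")
  one <- inject_erp(rec, rec$events[1, ], np_amplitude = 2, pos_latency = 0.2)
  two <- inject_erp(one, rec$events[2, ], np_amplitude = 2, pos_latency = 0.2)
  ## non-overlapping events: injecting separately equals injecting jointly
  both <- inject_erp(rec, rec$events[1:2, ], np_amplitude = 2, pos_latency = 0.2)
  expect_equal(two$data, both$data, tolerance = 1e-12)
})

test_that("noise-free injected SEP is recovered at the configured peak metrics", {
  rec <- inject_erp(zero_recording(), np_amplitude = 2.81,
                    pos_latency = 0.20269)
  for (hand in c("left", "right")) {
    ch <- if (hand == "left") "C4" else "C3"
    ep <- extract_epochs(rec, rec$events[rec$events$hand == hand, ],
                         channels = ch)
    m <- measure_sep(average_epochs(ep), ch)
    expect_true(m$valid)
    expect_lt(abs(m$np_amplitude - 2.81) / 2.81, 0.01)
    expect_lt(abs(m$pos_latency - 202.69), 1000 / 256)
  }
})

test_that("oscillatory injection is identity at unit gain and directional in dB", {
  rec <- simulate_background(30, seed = 5,
                             events = generate_protocol(
                               stimulus_protocol(n_sets = 1, n_rounds = 1,
                                                 isi_mean = 1.2,
                                                 isi_jitter = 0.1),
                               seed = 5, t_start = 3))
  expect_equal(inject_oscillations(rec, gains = c(alpha_desync = 1))$data,
               rec$data)
  expect_error(inject_oscillations(rec, gains = c(alpha_desync = -1)), "> 0")
  expect_error(inject_oscillations(rec, gains = c(gamma = 2)), "unknown ROI")
})

test_that("cohort generation matches group sizes, clips scores, is deterministic", {
  spec <- cohort_spec(n_healthy = 2, n_motor = 2, n_sensorimotor = 2,
                      protocol = stimulus_protocol(n_sets = 1, n_rounds = 1),
                      seed = 9)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$ground_truth), 6)
  expect_equal(as.vector(table(co$ground_truth$group)[c("healthy", "motor",
                                                        "sensorimotor")]),
               c(2L, 2L, 2L))
  stroke <- co$clinical[co$clinical$group != "healthy", ]
  expect_true(all(stroke$fma_t1 >= 0 & stroke$fma_t1 <= 66))
  expect_true(all(stroke$emnsa_t1 >= 0 & stroke$emnsa_t1 <= 32))
  expect_true(all(stroke$emnsa_prop_t1 >= 0 & stroke$emnsa_prop_t1 <= 8))
  expect_true(all(stroke$sct_t1 >= 0 & stroke$sct_t1 <= 54))
  co2 <- generate_cohort(spec)
  expect_identical(co$clinical, co2$clinical)
  expect_identical(co$ground_truth, co2$ground_truth)
})

test_that("noise-free identity clinical model reproduces injected magnitudes", {
  spec <- cohort_spec(n_healthy = 1, n_motor = 2, n_sensorimotor = 2,
                      protocol = stimulus_protocol(n_sets = 1, n_rounds = 1),
                      seed = 4)
  model <- list(fma_t1 = list(intercept = 0, coefs = c(amplitude = 1),
                              sd = 1, range = c(0, 66)))
  co <- generate_cohort(spec, clinical_model = model,
                        clinical_noise_scale = 0, keep_recordings = FALSE)
  stroke <- co$clinical$group != "healthy"
  expect_equal(co$clinical$fma_t1_latent[stroke],
               co$ground_truth$amplitude[stroke], tolerance = 1e-12)
})

test_that("default cohort totals 26 participants in a 10/6/10 split", {
  spec <- cohort_spec(protocol = stimulus_protocol(n_sets = 1, n_rounds = 1))
  expect_equal(spec$n_healthy + spec$n_motor + spec$n_sensorimotor, 26)
  co <- generate_cohort(spec, keep_recordings = FALSE)
  expect_equal(as.vector(table(co$ground_truth$group)[c("healthy", "motor",
                                                        "sensorimotor")]),
               c(10L, 6L, 10L))
})
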