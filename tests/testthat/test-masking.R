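test_that("grand average stacking: trivial cases and permutation invariance", {
  freqs <- 35^((0:29) / 29)
  times <- seq(-0.5, 1.6, by = 1 / 32)
  mk <- function(v) fake_db_tfr(matrix(v, 30, length(times)), freqs, times)
  same <- grand_average_stack(list(mk(2), mk(2), mk(2)))
  expect_equal(same$grand, matrix(2, 30, length(times)))
  pm <- grand_average_stack(list(mk(1), mk(-1)))
  expect_equal(pm$grand, matrix(0, 30, length(times)))
  set.seed(1)
  tfrs <- lapply(1:4, function(i)
    fake_db_tfr(matrix(rnorm(30 * length(times)), 30), freqs, times))
  g1 <- grand_average_stack(tfrs)$grand
  g2 <- grand_average_stack(tfrs[c(3, 1, 4, 2)])$grand
  expect_equal(g1, g2, tolerance = 1e-12)
  bad <- fake_db_tfr(matrix(0, 30, 10), freqs, times[1:10])
  expect_error(grand_average_stack(list(tfrs[[1]], bad)), "axes differ")
})

test_that("pointwise t-statistics match the closed form and flag degeneracies", {
  freqs <- 35^((0:29) / 29)
  times <- seq(-0.5, 1.6, by = 1 / 32)
  base <- matrix(0, 30, length(times))
  analysis_bin <- which(times >= 0)[1]
  mk <- function(v) {
    p <- base
    p[1, analysis_bin] <- v
    fake_db_tfr(p, freqs, times)
  }
  ## values 1, 2, 3 dB against a zero baseline: t = 2 / (1/sqrt(3)) = 3.464
  st <- grand_average_stack(list(mk(1), mk(2), mk(3)))
  ts <- suppressWarnings(pointwise_tstats(st, mask_config()))
  expect_equal(ts$t[1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-9)
  ## symmetric values about baseline: t = 0
  st0 <- grand_average_stack(list(mk(-1), mk(0), mk(1)))
  expect_equal(suppressWarnings(pointwise_tstats(st0, mask_config()))$t[1, 1], 0)
  ## identical nonzero offsets: zero variance, |t| = Inf with a warning
  stinf <- grand_average_stack(list(mk(2), mk(2), mk(2)))
  expect_warning(tsi <- pointwise_tstats(stinf, mask_config()),
                 "zero variance")
  expect_true(is.infinite(tsi$t[1, 1]))
})

test_that("circular shifts preserve each matrix's value multiset and the
           identity shift reproduces the observed t", {
  st <- noise_stack(n_participants = 5, n_times = 40, seed = 11)
  cfg <- mask_config(n_iterations = 100, analysis = c(0, 0.55),
                     baseline = c(-0.4, -0.1))
  nl <- circular_shift_null(st, cfg, seed = 2)
  expect_equal(dim(nl$t), c(100, 30 * sum(st$times >= 0 & st$times <= 0.55)))
  ## manual shifted extraction preserves the multiset of any participant matrix
  df <- 7; dt <- 13
  Fn <- 30; Tn <- length(st$times)
  shifted <- st$x[1, ((0:(Fn - 1) - df) %% Fn) + 1, ((0:(Tn - 1) - dt) %% Tn) + 1]
  expect_equal(sort(as.vector(shifted)), sort(as.vector(st$x[1, , ])))
  ## exhaustive enumeration contains the identity, matching observed t
  nl_all <- circular_shift_null(st, cfg, exhaustive = TRUE)
  ts <- pointwise_tstats(st, cfg)
  id_row <- which(nl_all$shifts$df == 0 & nl_all$shifts$dt == 0)
  expect_equal(nl_all$t[id_row, ], as.vector(ts$t), tolerance = 1e-12)
})

test_that("percentile mask under full enumeration matches a brute-force oracle
           on a small grid", {
  ## toy 4-frequency x 8-time stack, 6 participants; baseline = first 2 bins,
  ## analysis = last 5
  set.seed(23)
  freqs <- c(2, 4, 8, 16)
  times <- seq(-0.2, 0.5, by = 0.1) # 8 bins; baseline -0.2/-0.1, analysis 0..0.5
  n <- 6
  tfrs <- lapply(1:n, function(i)
    fake_db_tfr(matrix(rnorm(4 * 8), 4, 8) +
                  outer(c(0, 0, 2, 0), c(0, 0, 0, 1, 1, 1, 0, 0)),
                freqs, times))
  st <- grand_average_stack(tfrs)
  cfg <- mask_config(n_iterations = 100, percentile = 95,
                     analysis = c(0, 0.5), baseline = c(-0.2, -0.1),
                     two_sided = TRUE)
  ts <- pointwise_tstats(st, cfg)
  nl <- circular_shift_null(st, cfg, exhaustive = TRUE)
  expect_equal(nrow(nl$t), 4 * 8)
  got <- build_mask(ts, nl, cfg)

  ## ---- independent brute-force oracle ----
  b_idx <- which(times >= -0.2 & times <= -0.1)
  a_idx <- which(times >= 0 & times <= 0.5)
  tmat_oracle <- function(arrs) {
    t_out <- matrix(0, 4, length(a_idx))
    for (fi in 1:4) {
      for (aj in seq_along(a_idx)) {
        d <- vapply(arrs, function(m) {
          m[fi, a_idx[aj]] - mean(m[fi, b_idx])
        }, numeric(1))
        t_out[fi, aj] <- mean(d) / (sd(d) / sqrt(n))
      }
    }
    t_out
  }
  arrs <- lapply(tfrs, `[[`, "power")
  t_obs <- tmat_oracle(arrs)
  ## surrogate oracle: shifted values keep their own (source-row, unshifted)
  ## baseline reference
  nulls <- array(NA_real_, c(4 * 8, 4, length(a_idx)))
  it <- 0
  for (dt in 0:7) {
    for (df in 0:3) {
      it <- it + 1
      for (fi in 1:4) {
        sf <- ((fi - 1 - df) %% 4) + 1
        for (aj in seq_along(a_idx)) {
          sc <- ((a_idx[aj] - 1 - dt) %% 8) + 1
          d <- vapply(arrs, function(m) m[sf, sc] - mean(m[sf, b_idx]),
                      numeric(1))
          nulls[it, fi, aj] <- mean(d) / (sd(d) / sqrt(n))
        }
      }
    }
  }
  k <- ceiling(0.95 * 32)
  oracle_mask <- matrix(FALSE, 4, length(a_idx))
  for (fi in 1:4) {
    for (aj in seq_along(a_idx)) {
      thr <- sort(abs(nulls[, fi, aj]))[k]
      oracle_mask[fi, aj] <- abs(t_obs[fi, aj]) >= thr
    }
  }
  expect_equal(t_obs, ts$t, tolerance = 1e-12)
  expect_identical(got$mask, oracle_mask)
  expect_true(any(got$mask)) # the planted effect row is found
})

test_that("mask inclusion: dominance for huge effects, exclusion below null", {
  st <- noise_stack(n_participants = 8, n_times = 60, seed = 5)
  cfg <- mask_config(n_iterations = 200, analysis = c(0, 0.4),
                     baseline = c(-0.4, -0.1))
  ## plant an overwhelming effect at one bin for every participant
  a_first <- which(st$times >= 0)[1]
  st$x[, 15, a_first:(a_first + 5)] <- st$x[, 15, a_first:(a_first + 5)] + 50
  ts <- pointwise_tstats(st, cfg)
  nl <- circular_shift_null(st, cfg, seed = 3)
  m <- build_mask(ts, nl, cfg)
  expect_true(all(m$mask[15, 1:6]))
  ## a bin whose |t| is below every null value is excluded
  low <- which.min(abs(ts$t))
  expect_false(m$mask[low])
})

test_that("ROI labelling: rectangles, size filter, sign separation", {
  freqs <- 35^((0:29) / 29)
  times <- seq(0, 1.6, by = 1 / 32)
  mask <- matrix(FALSE, 30, length(times))
  tmat <- matrix(0, 30, length(times))
  ## two disjoint rectangles with opposite signs + a single-bin speckle
  ## (each rectangle sits inside one canonical band)
  mask[2:6, 5:20] <- TRUE;  tmat[2:6, 5:20] <- 5
  mask[18:21, 30:45] <- TRUE; tmat[18:21, 30:45] <- -4
  mask[15, 50] <- TRUE; tmat[15, 50] <- 3
  m <- structure(list(mask = mask, t = tmat, threshold = mask * 0,
                      freqs = freqs, times = times,
                      config = mask_config(min_roi_bins = 10)),
                 class = "tf_mask")
  rois <- label_rois(m)
  expect_equal(length(rois), 2) # speckle dropped
  expect_setequal(vapply(rois, `[[`, numeric(1), "direction"), c(1, -1))
  r_pos <- rois[[which(vapply(rois, `[[`, numeric(1), "direction") == 1)]]
  expect_equal(r_pos$f_lo, freqs[2])
  expect_equal(r_pos$f_hi, freqs[6])
  expect_equal(r_pos$t_lo, 1000 * times[5])
  expect_equal(r_pos$t_hi, 1000 * times[20])
  ## touching rectangles with opposite signs stay separate ROIs
  mask2 <- matrix(FALSE, 30, length(times))
  tmat2 <- matrix(0, 30, length(times))
  mask2[8:10, 10:20] <- TRUE; tmat2[8:10, 10:20] <- 4
  mask2[8:10, 21:30] <- TRUE; tmat2[8:10, 21:30] <- -4
  m2 <- m; m2$mask <- mask2; m2$t <- tmat2
  expect_equal(length(label_rois(m2)), 2)
  ## empty mask gives an empty set, not an error
  m3 <- m; m3$mask <- matrix(FALSE, 30, length(times))
  expect_equal(length(label_rois(m3)), 0)
})

test_that("ROI power extraction averages member bins", {
  freqs <- 35^((0:29) / 29)
  times <- seq(0, 1.6, by = 1 / 32)
  mask <- matrix(FALSE, 30, length(times))
  tmat <- matrix(0, 30, length(times))
  mask[5:8, 10:19] <- TRUE; tmat[5:8, 10:19] <- 2
  m <- structure(list(mask = mask, t = tmat, threshold = mask * 0,
                      freqs = freqs, times = times,
                      config = mask_config(min_roi_bins = 10)),
                 class = "tf_mask")
  rois <- label_rois(m)
  const <- fake_db_tfr(matrix(3, 30, length(times)), freqs, times)
  rp <- extract_roi_power(const, rois)
  expect_equal(rp$mean_db, 3)
  ## values equal to bin indices: mean of the rectangle
  grid <- fake_db_tfr(matrix(seq_len(30 * length(times)), 30), freqs, times)
  rp2 <- extract_roi_power(grid, rois)
  expect_equal(rp2$mean_db, mean(grid$power[5:8, 10:19]))
  ## axis mismatch errors
  short <- fake_db_tfr(matrix(1, 30, 10), freqs, times[1:10])
  expect_error(extract_roi_power(short, rois), "axes")
})

test_that("type-I inclusion rate on stationary stacks is near the nominal 5%", {
  ## a reduced-size version of the calibration study (the acceptance test
  ## runs the full 200-stack version)
  rates <- vapply(1:20, function(s) {
    st <- noise_stack(n_participants = 10, n_times = 60, seed = 100 + s)
    cfg <- mask_config(n_iterations = 200, analysis = c(0, 0.7),
                       baseline = c(-0.4, -0.1))
    ts <- pointwise_tstats(st, cfg)
    nl <- circular_shift_null(st, cfg, seed = 200 + s)
    mean(build_mask(ts, nl, cfg)$mask)
  }, numeric(1))
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.09)
})
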