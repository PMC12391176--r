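## textbook-style 3-group fixture with a hand-computed F statistic
anova_fixture <- function() {
  data.frame(
    np_amplitude = c(2.1, 2.9, 3.2, 2.5, 2.8,
                     1.1, 1.6, 1.4, 0.9, 1.3,
                     3.6, 4.1, 3.3, 3.9, 4.4),
    group = rep(c("healthy", "sensorimotor", "motor"), each = 5)
  )
}

## independent sums-of-squares oracle
anova_oracle_F <- function(tab) {
  groups <- split(tab$np_amplitude, tab$group)
  gm <- mean(tab$np_amplitude)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- length(groups) - 1
  df2 <- nrow(tab) - length(groups)
  (ss_between / df1) / (ss_within / df2)
}

test_that("one-way ANOVA matches the sums-of-squares oracle and the t^2
           identity for two groups", {
  tab <- anova_fixture()
  res <- anova_amplitude(tab)
  expect_equal(res$F, anova_oracle_F(tab), tolerance = 1e-12)
  expect_equal(res$df, c(2, 12))
  ## two-group ANOVA F equals the squared pooled-variance t
  tab2 <- tab[tab$group != "motor", ]
  res2 <- anova_amplitude(tab2)
  tt <- t.test(np_amplitude ~ group, data = tab2, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  ## degenerate inputs
  expect_error(anova_amplitude(data.frame(np_amplitude = 1:3,
                                          group = c("a", "a", "b"))),
               "fewer than 2")
  flat <- data.frame(np_amplitude = rep(1, 6),
                     group = rep(c("a", "b"), each = 3))
  w <- capture_warnings(anova_amplitude(flat))
  expect_true(any(grepl("equal", w)))
})

test_that("Tukey post-hocs: identical means give p ~ 1 and d = 0; the pooled-SD
           convention reproduces the hand-computed example", {
  set.seed(4)
  same <- data.frame(np_amplitude = rnorm(30), group = rep(c("a", "b", "c"), 10))
  same$np_amplitude <- same$np_amplitude - ave(same$np_amplitude, same$group)
  ph <- tukey_posthoc(anova_amplitude(same))
  expect_true(all(ph$p_tukey > 0.999))
  expect_true(all(abs(ph$cohens_d) < 1e-9))
  ## hand-computed pooled-SD example: means 2.73 vs 1.44, SDs 1.36 vs 0.59,
  ## n = 10 each -> d = 1.29 / sqrt((9*1.36^2 + 9*0.59^2)/18) = 1.2306
  sp <- sqrt((9 * 1.36^2 + 9 * 0.59^2) / 18)
  expect_equal(1.29 / sp, 1.2306, tolerance = 1e-4)
  x <- scale(rnorm(10)) * 1.36 + 2.73
  y <- scale(rnorm(10)) * 0.59 + 1.44
  expect_equal(cohens_d(as.vector(x), as.vector(y)), 1.2306, tolerance = 1e-4)
})

test_that("group separation yields directionally correct Tukey contrasts", {
  set.seed(77)
  tab <- data.frame(
    np_amplitude = c(rnorm(10, 2.81, 1.0), rnorm(6, 3.22, 1.0),
                     rnorm(10, 1.36, 0.5)),
    group = rep(c("healthy", "motor", "sensorimotor"), c(10, 6, 10))
  )
  ph <- tukey_posthoc(anova_amplitude(tab))
  hs <- ph[ph$contrast == "healthy - sensorimotor", ]
  expect_gt(hs$estimate, 0)
  expect_gt(hs$cohens_d, 0)
  expect_true(all(ph$p_tukey >= 0 & ph$p_tukey <= 1))
})

test_that("mixed model of ROI power: zero random variance degenerates to OLS
           and interactions are recovered when present", {
  ## no participant effect, no interaction: backward selection should not
  ## invent one, and fixed estimates match OLS on the same data
  set.seed(31)
  n_sub <- 40
  grid <- expand.grid(participant = sprintf("p%02d", 1:n_sub),
                      feature = c("delta", "theta", "alpha", "beta1", "beta2"))
  grid$group <- rep(rep(c("healthy", "motor", "sensorimotor"),
                        length.out = n_sub), 5)
  feat_eff <- c(delta = 5, theta = 4, alpha = -5, beta1 = -5, beta2 = 5)
  grid$power <- feat_eff[as.character(grid$feature)] + rnorm(nrow(grid), 0, 1)
  res <- suppressWarnings(mixed_model_power(grid))
  expect_true("feature" %in% res$final_terms)
  expect_false("group:feature" %in% res$final_terms)
  ## with a genuine group x feature interaction it is retained
  grid2 <- grid
  boost <- grid2$group == "sensorimotor" & grid2$feature == "alpha"
  grid2$power[boost] <- grid2$power[boost] + 4
  res2 <- suppressWarnings(mixed_model_power(grid2))
  expect_true("group:feature" %in% res2$final_terms)
  expect_true(!is.null(res2$contrasts))
})

test_that("backward elimination respects marginality and is deterministic", {
  set.seed(8)
  tab <- simulate_feature_table(60, coefs = list(
    y = c(`beta1:sensorimotor` = 4)
  ), noise_sd = 1, seed = 8)
  fit <- lm(y ~ beta1 * stroke_type, data = tab)
  final <- pinprickEEG:::backward_eliminate(fit, tab)
  terms_final <- attr(terms(final), "term.labels")
  ## the interaction is retained, so both mains must still be present
  expect_true("beta1:stroke_type" %in% terms_final)
  expect_true(all(c("beta1", "stroke_type") %in% terms_final))
  final2 <- pinprickEEG:::backward_eliminate(lm(y ~ beta1 * stroke_type,
                                                data = tab), tab)
  expect_identical(attr(terms(final2), "term.labels"), terms_final)
})

test_that("clinical regression recovers a single generating feature with the
           right sign", {
  tab <- simulate_feature_table(50, coefs = list(fma = c(beta1 = -6)),
                                intercepts = list(fma = 10),
                                noise_sd = 5, seed = 21)
  res <- clinical_regression(tab, "fma")
  expect_true("beta1" %in% res$final_terms)
  expect_lt(res$estimates["beta1", "Estimate"], 0)
  expect_gt(res$adj_r2, 0.3)
  ## sample-size guard
  expect_error(clinical_regression(tab[1:10, ], "fma"), "cannot support")
})

test_that("coefficient estimates are unbiased at large n", {
  ests <- vapply(1:20, function(s) {
    tab <- simulate_feature_table(200, coefs = list(fma = c(beta1 = -6)),
                                  noise_sd = 4, seed = 300 + s)
    fit <- lm(fma ~ amplitude + delta + theta + alpha + beta1 + beta2 +
                stroke_type, data = tab)
    coef(fit)[["beta1"]]
  }, numeric(1))
  expect_lt(abs(mean(ests) - (-6)), 3 * sd(ests) / sqrt(20))
  expect_lt(abs(mean(ests) - (-6)), 0.2)
})

test_that("feature-level simulation is deterministic given a seed", {
  a <- simulate_feature_table(30, coefs = list(y = c(delta = 2)), seed = 5)
  b <- simulate_feature_table(30, coefs = list(y = c(delta = 2)), seed = 5)
  expect_identical(a, b)
})
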