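#' Cohen's d with (n-1)-weighted pooled SD
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled = sqrt(((nx-1)*sx^2 + (ny-1)*sy^2) / (nx+ny-2))`. The pooled-SD
#' convention is stated here because published effect sizes do not always say
#' which convention they use.
#'
#' @param x,y numeric vectors.
#' @return a number.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

## Flag observations whose standardised model residual exceeds `z`.
## Documented stand-in for normal-quantile-plot outlier screening.
residual_outliers <- function(fit, z = 3) {
  r <- stats::rstandard(fit)
  which(abs(r) > z)
}

#' One-way ANOVA of SEP amplitude on group
#'
#' Fixed-effect one-way ANOVA of the negative-positive peak-to-peak amplitude
#' on GROUP, with optional residual-based outlier removal (|standardised
#' residual| > 3, the package's documented replacement for quantile-plot
#' screening). Post-hoc contrasts are available regardless of the omnibus
#' p-value via [tukey_posthoc()].
#'
#' @param table a data.frame with columns `np_amplitude` and `group`.
#' @param remove_outliers apply the residual rule before the final fit
#'   (default `FALSE`).
#' @return a list of class `amplitude_anova`: `F`, `df`, `p`, `fit`, `table`
#'   (the analysed rows), `outliers_removed`.
#' @export
anova_amplitude <- function(table, remove_outliers = FALSE) {
  stopifnot(all(c("np_amplitude", "group") %in% names(table)))
  table$group <- factor(table$group)
  counts <- table(table$group)
  if (length(counts) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  removed <- integer(0)
  fit <- stats::aov(np_amplitude ~ group, data = table)
  if (remove_outliers) {
    removed <- residual_outliers(stats::lm(np_amplitude ~ group, data = table))
    if (length(removed)) {
      table <- table[-removed, , drop = FALSE]
      fit <- stats::aov(np_amplitude ~ group, data = table)
    }
  }
  an <- stats::anova(fit)
  if (an[1, "Sum Sq"] < .Machine$double.eps * 100 &&
      an[2, "Sum Sq"] < .Machine$double.eps * 100) {
    warning("all observations equal; F undefined", call. = FALSE)
  }
  structure(
    list(F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
         p = an[1, "Pr(>F)"], fit = fit, table = table,
         outliers_removed = removed),
    class = "amplitude_anova"
  )
}

#' Tukey-corrected pairwise group contrasts with Cohen's d
#'
#' All pairwise group contrasts of a fitted group model, adjusted with the
#' studentized-range (Tukey) method via \pkg{emmeans}, plus the raw-data
#' Cohen's d for each pair.
#'
#' @param model an [anova_amplitude()] result, or any model `emmeans`
#'   understands with a `group` factor.
#' @param table the analysed data (defaults to the model's own).
#' @param response response column name (default `"np_amplitude"`).
#' @return a `data.frame`: `contrast`, `estimate`, `SE`, `df`, `t`,
#'   `p_tukey`, `cohens_d`.
#' @export
tukey_posthoc <- function(model, table = NULL, response = "np_amplitude") {
  if (inherits(model, "amplitude_anova")) {
    table <- table %||% model$table
    fit <- model$fit
  } else {
    fit <- model
    stopifnot(!is.null(table))
  }
  emm <- emmeans::emmeans(fit, "group")
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  d <- vapply(strsplit(as.character(ctr$contrast), " - "), function(pair) {
    g1 <- table[[response]][table$group == pair[1]]
    g2 <- table[[response]][table$group == pair[2]]
    cohens_d(g1, g2)
  }, numeric(1))
  data.frame(contrast = as.character(ctr$contrast), estimate = ctr$estimate,
             SE = ctr$SE, df = ctr$df, t = ctr$t.ratio, p_tukey = ctr$p.value,
             cohens_d = d, stringsAsFactors = FALSE)
}

## Backward elimination on an lm/lmer fit: repeatedly drop the
## highest-p eliminable term (marginality respected: a main effect is never
## dropped while its interaction remains) until every eliminable term has
## p < alpha. Aliased or otherwise untestable terms (zero degrees of
## freedom, e.g. an interaction block larger than a subgroup can support)
## count as p = 1 and are removed first. Ties broken by term order in the
## formula. Deterministic.
backward_eliminate <- function(fit, data, alpha = 0.05) {
  is_mixed <- inherits(fit, "merMod")
  repeat {
    if (is_mixed) {
      dr <- stats::drop1(fit, ddf = "Satterthwaite") # lmerTest method
      pcol <- "Pr(>F)"
    } else {
      dr <- stats::drop1(fit, test = "F")
      pcol <- "Pr(>F)"
    }
    terms_tbl <- dr[rownames(dr) != "<none>", , drop = FALSE]
    if (!nrow(terms_tbl)) break
    p <- terms_tbl[[pcol]]
    p[is.na(p)] <- 1 # aliased / untestable
    if (all(p < alpha)) break
    worst <- rownames(terms_tbl)[which.max(p)]
    new_formula <- stats::update.formula(stats::formula(fit),
                                         paste(". ~ . -", worst))
    fit <- if (is_mixed) {
      lmerTest::lmer(new_formula, data = data, REML = FALSE)
    } else {
      stats::lm(new_formula, data = data)
    }
    ## stop when only the intercept (and any random effects) remain
    if (!length(attr(stats::terms(new_formula), "term.labels"))) break
    fe <- attr(stats::terms(fit), "term.labels")
    fe <- fe[!grepl("\\|", fe)]
    if (!length(fe)) break
  }
  fit
}

#' Linear mixed model of ROI power
#'
#' `POWER ~ GROUP * FEATURE + (1 | participant)` on the long-form feature
#' table, fitted with \pkg{lmerTest} (Satterthwaite denominator degrees of
#' freedom). Fixed effects are reduced by backward elimination (p-based at
#' `alpha`, marginality respected); Tukey-corrected cell contrasts are
#' computed on the final model. A singular random-intercept fit triggers a
#' prominent warning and a fixed-effects-only refit.
#'
#' @param table long-form data.frame with columns `participant`, `group`,
#'   `feature` (the five ROI labels), `power` (dB).
#' @param alpha stay-threshold for backward elimination (default 0.05).
#' @param reduce perform backward elimination (default `TRUE`).
#' @return a list of class `power_mixed_model`: `fit` (final model), `anova`
#'   (Satterthwaite F-table of the full model), `final_terms`, `contrasts`
#'   (Tukey group contrasts within each feature), `singular`.
#' @export
mixed_model_power <- function(table, alpha = 0.05, reduce = TRUE) {
  stopifnot(all(c("participant", "group", "feature", "power") %in% names(table)))
  table$group <- factor(table$group)
  table$feature <- factor(table$feature)
  table$participant <- factor(table$participant)
  fit <- lmerTest::lmer(power ~ group * feature + (1 | participant),
                        data = table, REML = FALSE)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("random-intercept variance is (near) zero; refitting without ",
            "the random intercept", call. = FALSE)
    fit_fixed <- stats::lm(power ~ group * feature, data = table)
    an <- stats::anova(fit_fixed)
    final <- if (reduce) backward_eliminate(fit_fixed, table, alpha) else fit_fixed
  } else {
    an <- stats::anova(fit) # lmerTest: Satterthwaite ddf
    final <- if (reduce) backward_eliminate(fit, table, alpha) else fit
  }
  fe <- tryCatch(attr(stats::terms(final), "term.labels"),
                 error = function(e) character(0))
  fe <- fe[!grepl("\\|", fe)]
  ctr <- NULL
  if (all(c("group", "feature") %in% all.vars(stats::formula(final)))) {
    emm <- emmeans::emmeans(final, ~ group | feature)
    ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "tukey"))
  }
  structure(
    list(fit = final, anova = an, final_terms = fe, contrasts = ctr,
         singular = singular),
    class = "power_mixed_model"
  )
}

#' Clinical-association regression with backward-stepwise reduction
#'
#' For the stroke subset only: a linear model of a clinical outcome (at T1,
#' or the T2 - T1 change) on the EEG features (peak-to-peak amplitude and the
#' five ROI powers), stroke type, and every EEG-feature-by-stroke-type
#' interaction, reduced by backward elimination (drop the highest-p
#' eliminable term, marginality respected, until all retained terms have
#' p < `alpha`).
#'
#' @param table wide feature table with columns `amplitude`, `delta`, `theta`,
#'   `alpha`, `beta1`, `beta2`, `stroke_type`, and the outcome column.
#' @param outcome outcome column name (e.g. `"fma"`, `"emnsa"`, `"ptt"`, or
#'   any column present).
#' @param alpha stay-threshold (default 0.05).
#' @param features EEG feature columns entering the model.
#' @return a list of class `clinical_regression`: `fit` (final model),
#'   `final_terms`, `estimates` (coefficient table), `adj_r2`, `outcome`.
#' @export
clinical_regression <- function(table, outcome, alpha = 0.05,
                                features = c("amplitude", "delta", "theta",
                                             "alpha", "beta1", "beta2")) {
  stopifnot(outcome %in% names(table),
            all(features %in% names(table)),
            "stroke_type" %in% names(table))
  table <- table[!is.na(table[[outcome]]), , drop = FALSE]
  table$stroke_type <- factor(table$stroke_type)
  rhs <- paste(c(features, "stroke_type",
                 paste0(features, ":stroke_type")), collapse = " + ")
  n_terms <- 2 * length(features) + 2 # mains + interactions + type + intercept
  if (nrow(table) <= n_terms) {
    stop(sprintf(paste0("n = %d observations cannot support %d model terms; ",
                        "reduce the starting model or add data"),
                 nrow(table), n_terms), call. = FALSE)
  }
  fit <- stats::lm(stats::as.formula(paste(outcome, "~", rhs)), data = table)
  final <- backward_eliminate(fit, table, alpha)
  sm <- summary(final)
  structure(
    list(fit = final,
         final_terms = attr(stats::terms(final), "term.labels"),
         estimates = stats::coef(sm),
         adj_r2 = sm$adj.r.squared,
         outcome = outcome),
    class = "clinical_regression"
  )
}

#' @export
print.clinical_regression <- function(x, ...) {
  cat(sprintf("<clinical_regression> outcome: %s\n", x$outcome))
  if (length(x$final_terms)) {
    cat("  retained terms:", paste(x$final_terms, collapse = ", "), "\n")
  } else {
    cat("  retained terms: (intercept only)\n")
  }
  cat(sprintf("  adjusted R^2 = %.3f\n", x$adj_r2))
  invisible(x)
}

#' Simulate a feature table at the statistics level
#'
#' Generates per-participant EEG features (amplitude and the five ROI dB
#' powers) and clinical outcomes as linear functions of chosen features plus
#' Gaussian noise, bypassing the signal-level pipeline. Used for estimator
#' and model-selection recovery studies at arbitrary n.
#'
#' @param n participants (stroke only unless `groups` given).
#' @param coefs named list: for each outcome, a named coefficient vector over
#'   features; interaction terms as `"feature:sensorimotor"` (active in the
#'   sensorimotor subgroup).
#' @param intercepts named numeric (default 0 for each outcome).
#' @param noise_sd residual SD per outcome (default 1).
#' @param prop_sensorimotor proportion of sensorimotor stroke (default 0.6).
#' @param seed integer seed.
#' @return a data.frame with features, `stroke_type`, and outcome columns.
#' @export
simulate_feature_table <- function(n = 50, coefs = list(),
                                   intercepts = NULL, noise_sd = 1,
                                   prop_sensorimotor = 0.6, seed = 1) {
  set.seed(seed)
  n_smr <- round(prop_sensorimotor * n)
  tab <- data.frame(
    participant = sprintf("S%03d", seq_len(n)),
    stroke_type = rep(c("sensorimotor", "motor"), c(n_smr, n - n_smr)),
    amplitude = pmax(0.2, stats::rnorm(n, 2.3, 1.3)),
    delta = stats::rnorm(n, 5, 1.5),
    theta = stats::rnorm(n, 4.5, 1.5),
    alpha = stats::rnorm(n, -5, 1.5),
    beta1 = stats::rnorm(n, -5, 1.5),
    beta2 = stats::rnorm(n, 5, 1.5),
    stringsAsFactors = FALSE
  )
  smr <- as.numeric(tab$stroke_type == "sensorimotor")
  for (oc in names(coefs)) {
    y <- rep(intercepts[[oc]] %||% 0, n)
    for (nm in names(coefs[[oc]])) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      x <- rep(1, n)
      for (p in parts) {
        x <- x * if (p == "sensorimotor") smr else tab[[p]]
      }
      y <- y + coefs[[oc]][[nm]] * x
    }
    sd_oc <- if (length(noise_sd) > 1) noise_sd[[oc]] else noise_sd
    tab[[oc]] <- y + stats::rnorm(n, 0, sd_oc)
  }
  tab
}
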