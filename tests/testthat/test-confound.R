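make_intact_cohort <- function(seed, n = 80, beta_age = 0.05) {
  set.seed(seed)
  subjects <- do.call(rbind, lapply(c("left", "right"), function(s)
    data.frame(subject_id = sprintf("s%03d", 1:n), group = "intact",
               age = runif(n, 25, 75), sex = sample(c("male", "female"), n, TRUE),
               side = s,
               dominant_side_tested = (s == "right") == (runif(n) < 0.9),
               stereo_deficit = runif(n) < 0.1,
               fma_ue = NA, arat = NA, nhpt = NA)))
  X <- covariate_matrix <- cbind(subjects$age,
                                 subjects$sex == "female",
                                 subjects$side == "right",
                                 subjects$dominant_side_tested,
                                 subjects$stereo_deficit)
  u <- rnorm(n, 0, 0.8)
  names(u) <- sprintf("s%03d", 1:n)
  z <- 10 + beta_age * subjects$age + 0.4 * X[, 2] +
    u[subjects$subject_id] + rnorm(nrow(subjects), 0, 0.5)
  values <- data.frame(subject_id = subjects$subject_id, side = subjects$side,
                       value = z)
  list(subjects = subjects, values = values, z = z)
}

test_that("confound model fit matches lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  co <- make_intact_cohort(1)
  fit <- fit_confound_model(co$values, co$subjects, "m",
                            boxcox = fixed_boxcox(1))
  d <- merge(co$values, co$subjects, by = c("subject_id", "side"))
  d$z <- boxcox_transform(fixed_boxcox(1), d$value)
  m <- lme4::lmer(z ~ age + I(sex == "female") + I(side == "right") +
                    dominant_side_tested + stereo_deficit + (1 | subject_id),
                  data = d, REML = FALSE)
  expect_equal(unname(fit$betas),
               unname(lme4::fixef(m)[c(1, 2, 3, 4, 5, 6)]), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-7)
  expect_equal(fit$random_intercept_sd,
               unname(attr(lme4::VarCorr(m)$subject_id, "stddev")),
               tolerance = 1e-4)
  expect_equal(fit$residual_sd, stats::sigma(m), tolerance = 1e-4)
})

test_that("planted age effect is recovered and removed", {
  covered <- 0L
  nrep <- 20L
  for (s in seq_len(nrep)) {
    co <- make_intact_cohort(100 + s)
    fit <- fit_confound_model(co$values, co$subjects, "m",
                              boxcox = fixed_boxcox(1))
    se <- fit$se[match("age", names(fit$lmm$beta))]
    if (abs(fit$betas[["age"]] - 0.05) <= 2 * se) covered <- covered + 1L
  }
  expect_gte(covered, round(0.8 * nrep))  # ~95% nominal
  # correction equalizes planted old vs young groups
  co <- make_intact_cohort(7, n = 150)
  fit <- fit_confound_model(co$values, co$subjects, "m",
                            boxcox = fixed_boxcox(1))
  d <- merge(co$values, co$subjects, by = c("subject_id", "side"))
  corr <- remove_confounds(d$value, d, fit)
  old <- corr[d$age > 60]; young <- corr[d$age < 40]
  pooled_sd <- sd(corr)
  expect_lt(abs(mean(old) - mean(young)), 0.15 * pooled_sd)
  # with zero covariates coded 0 the value passes through unchanged
  d0 <- data.frame(age = 0, sex = "male", side = "left",
                   dominant_side_tested = FALSE, stereo_deficit = FALSE)
  expect_equal(remove_confounds(5, d0, fit),
               boxcox_transform(fit$boxcox, 5))
  # the correction subtracts exactly the covariate term (no intercept, no
  # random effect), so a repeated subtraction would shift by the same
  # amount again - linear, not idempotent
  d1 <- d[5, , drop = FALSE]
  z1 <- boxcox_transform(fit$boxcox, d1$value)
  shift <- z1 - remove_confounds(d1$value, d1, fit)
  xc <- c(d1$age, d1$sex == "female", d1$side == "right",
          d1$dominant_side_tested, d1$stereo_deficit)
  expect_equal(shift, sum(xc * fit$betas[-1]))
  expect_false(isTRUE(all.equal(shift, 0)))
})

test_that("single-side data falls back to a fixed-effects-only fit", {
  co <- make_intact_cohort(3)
  one_side <- co$values[co$values$side == "right", ]
  w <- testthat::capture_warnings(
    fit <- fit_confound_model(one_side, co$subjects, "m",
                              boxcox = fixed_boxcox(1)))
  expect_true(any(grepl("random intercept", w)))
  expect_true(any(grepl("side", w)))   # single-side => constant covariate
  expect_true(fit$no_random_effect)
  expect_true("side" %in% fit$dropped)
})

test_that("constant covariates are dropped with a warning flag", {
  co <- make_intact_cohort(4)
  co$subjects$stereo_deficit <- FALSE
  expect_warning(
    fit <- fit_confound_model(co$values, co$subjects, "m",
                              boxcox = fixed_boxcox(1)),
    "stereo")
  expect_identical(fit$dropped, "stereo")
  expect_equal(fit$betas[["stereo"]], 0)
  expect_equal(bootstrap_lrt(fit, "stereo", 10, seed = 1), 1)
})

test_that("bootstrap LRT is deterministic under a seed and detects effects", {
  co <- make_intact_cohort(5)
  fit <- fit_confound_model(co$values, co$subjects, "m",
                            boxcox = fixed_boxcox(1))
  p1 <- bootstrap_lrt(fit, "sex", iterations = 60, seed = 42)
  p2 <- bootstrap_lrt(fit, "sex", iterations = 60, seed = 42)
  expect_identical(p1, p2)
  expect_error(bootstrap_lrt(fit, "sex", iterations = 0), "iterations")
  # large planted effect -> smallest attainable p
  co2 <- make_intact_cohort(6)
  co2$values$value <- co2$values$value + 6 * (co2$subjects$sex == "female")
  fit2 <- fit_confound_model(co2$values, co2$subjects, "m",
                             boxcox = fixed_boxcox(1))
  expect_lte(bootstrap_lrt(fit2, "sex", iterations = 99, seed = 1), 0.01)
})

test_that("model quality criteria implement the MAE arithmetic", {
  values <- seq(0, 20, length.out = 40)
  q <- model_quality(NULL, values, values)       # perfect predictions
  expect_equal(q$mae, 0); expect_equal(q$c1, 0); expect_equal(q$c2, 0)
  expect_true(q$pass)
  q2 <- model_quality(NULL, values, values - 3)  # MAE 3, sigma 0, range 20
  expect_equal(q2$c1, 15); expect_equal(q2$c2, 15)
  expect_true(q2$pass)                           # pass boundary inclusive
  # independent arithmetic check on noisy residuals
  set.seed(9)
  preds <- values + rnorm(40, 0, 2)
  q3 <- model_quality(NULL, values, preds)
  ar <- abs(values - preds); keep <- ar <= quantile(ar, 0.95)
  expect_equal(q3$c1, 100 * mean(ar[keep]) / 20)
  expect_equal(q3$c2, 100 * (mean(ar[keep]) + 3 * sd(ar[keep])) / 20)
  expect_error(model_quality(NULL, rep(1, 40), rep(1, 40)), "zero range")
})

test_that("normalization centers on intact median and scales by MAD", {
  desc <- metric_descriptor("m", "overall", "whole_trial", "higher_is_worse")
  intact <- c(1, 2, 3, 4, 100)
  params <- normalization_params(intact, affected_corrected = c(6, 10), desc)
  expect_equal(params$intact_median, 3)
  expect_equal(params$mad, 1)
  # value 5 -> (5 - 3)/1 = 2 before worst-case scaling; worst affected = 100%
  expect_equal(normalize_metric(5, params) * params$worst_scale / 100, 2)
  expect_equal(normalize_metric(10, params), 100)
  expect_equal(normalize_metric(3, params), 0)
  # lower-is-worse metrics are sign-aligned so higher normalized = worse
  desc_lo <- metric_descriptor("m", "speed", "transport", "lower_is_worse")
  p_lo <- normalization_params(intact, c(0, -5), desc_lo)
  expect_equal(normalize_metric(-5, p_lo), 100)
  expect_error(normalization_params(rep(2, 30), c(3, 4), desc), "MAD")
})

test_that("abnormality cutoff leaves at most 5% of intact above it", {
  x <- 1:100
  cut <- abnormality_cutoff(x)
  expect_lte(mean(x > cut), 0.05)
  expect_equal(abnormality_cutoff(rep(7, 25)), 7)
  set.seed(15)
  z <- rnorm(1e4)
  expect_gt(abnormality_cutoff(z), 1.55)
  expect_lt(abnormality_cutoff(z), 1.75)
  expect_error(abnormality_cutoff(rnorm(10)), "at least 20")
})

test_that("step-1 filter fires on model quality and stereo significance", {
  pass_q <- structure(list(c1 = 10, c2 = 20, pass = TRUE),
                      class = "model_quality")
  bad_c1 <- structure(list(c1 = 16, c2 = 20, pass = FALSE),
                      class = "model_quality")
  expect_false(step1_filter(bad_c1, 0.5)$keep)
  expect_match(step1_filter(bad_c1, 0.5)$reason, "C1")
  d <- step1_filter(pass_q, 0.03)
  expect_false(d$keep)
  expect_match(d$reason, "stereo")
  expect_true(step1_filter(pass_q, 0.2)$keep)
})
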