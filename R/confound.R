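CONFOUNDS <- c("age", "sex", "side", "handedness", "stereo")

# Fixed-effect design columns for the confound model. Reference levels:
# sex male = 0 / female = 1, tested side left = 0 / right = 1,
# handedness: dominant side tested TRUE = 1, stereo deficit TRUE = 1.
covariate_matrix <- function(demo) {
  cbind(age = as.numeric(demo$age),
        sex = as.numeric(demo$sex == "female"),
        side = as.numeric(demo$side == "right"),
        handedness = as.numeric(demo$dominant_side_tested),
        stereo = as.numeric(demo$stereo_deficit))
}

#' Fit the demographic confound model for one metric
#'
#' Fits, in Box-Cox-transformed space and on neurologically intact data only,
#' a linear mixed model of the metric on age, sex, tested body side,
#' handedness (dominant side tested) and stereo-vision deficits, with one
#' random intercept per subject to absorb the correlation between the two
#' tested sides. Fitting is by maximum likelihood. Constant covariates
#' (singular design) are dropped with a warning flag; if every subject
#' contributes a single row the random intercept is unidentifiable and the
#' fit falls back to fixed effects only (flagged `no_random_effect`).
#'
#' @param values Data frame with columns `subject_id, side, value`: aggregated
#'   test-session values of one metric for intact subjects.
#' @param subjects Subjects table (see [read_cohort()]); matched on
#'   `subject_id` and `side`.
#' @param metric_name Metric identifier stored in the fit.
#' @param boxcox Optional pre-fitted [fit_boxcox()] transform; fitted from
#'   `values$value` when `NULL`.
#' @return Object of class `confound_model_fit`: coefficient vector
#'   `betas` (intercept + 5 confounds, dropped ones zero), `random_intercept_sd`,
#'   `residual_sd`, Wald `confound_p`, the `boxcox` transform, flags, and the
#'   internal design kept for bootstrap refits.
#' @export
fit_confound_model <- function(values, subjects, metric_name = "metric",
                               boxcox = NULL) {
  demo <- merge(values, subjects, by = c("subject_id", "side"), sort = FALSE)
  if (nrow(demo) != nrow(values))
    stop("missing demographics for some subject x side rows", call. = FALSE)
  if (is.null(boxcox)) boxcox <- fit_boxcox(demo$value)
  z <- boxcox_transform(boxcox, demo$value)
  Xc <- covariate_matrix(demo)
  dropped <- colnames(Xc)[apply(Xc, 2, function(x) stats::var(x) == 0)]
  if (length(dropped))
    warning("constant covariate(s) dropped from confound model: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  keep <- setdiff(colnames(Xc), dropped)
  X <- cbind(intercept = 1, Xc[, keep, drop = FALSE])
  fit <- fit_lmm(X, z, demo$subject_id)
  if (fit$no_random_effect && anyDuplicated(demo$subject_id) == 0L)
    warning("each subject contributes one row; random intercept unidentifiable, ",
            "fixed-effects-only fit", call. = FALSE)
  betas <- stats::setNames(numeric(6), c("intercept", CONFOUNDS))
  betas[names(fit$beta)] <- fit$beta
  wald_p <- stats::setNames(rep(NA_real_, 5), CONFOUNDS)
  for (cv in intersect(CONFOUNDS, names(fit$beta))) {
    se <- fit$se[match(cv, names(fit$beta))]
    if (is.finite(se) && se > 0)
      wald_p[cv] <- 2 * stats::pnorm(-abs(fit$beta[cv] / se))
  }
  structure(list(metric_name = metric_name,
                 betas = betas,
                 se = fit$se,
                 random_intercept_sd = fit$sigma_u,
                 residual_sd = fit$sigma_e,
                 confound_p = wald_p,
                 boxcox = boxcox,
                 dropped = dropped,
                 no_random_effect = fit$no_random_effect,
                 loglik = fit$loglik,
                 lmm = fit,
                 data = demo),
            class = "confound_model_fit")
}

#' Parametric-bootstrap likelihood-ratio test for one confound
#'
#' Simulated LRT between the full confound model and the model without the
#' confound of interest: response data are simulated under the fitted reduced
#' model, both models are refitted per replicate, and the p-value is the
#' exceedance rate of the simulated likelihood-ratio statistics,
#' `p = (1 + #\{LR* >= LR_obs\}) / (1 + iterations)`.
#'
#' @param fit A `confound_model_fit`.
#' @param covariate One of `"age", "sex", "side", "handedness", "stereo"`.
#' @param iterations Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the same seed reproduces the same p-value.
#' @return Numeric p-value in (0, 1].
#' @export
bootstrap_lrt <- function(fit, covariate, iterations = 1000L, seed = 1L) {
  covariate <- match.arg(covariate, CONFOUNDS)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (covariate %in% fit$dropped) return(1)
  full <- fit$lmm
  j <- match(covariate, colnames(full$X))
  Xr <- full$X[, -j, drop = FALSE]
  reduced <- fit_lmm(Xr, full$y, full$group)
  lr_obs <- max(0, 2 * (full$loglik - reduced$loglik))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(iterations)) {
    ystar <- simulate_lmm(reduced)
    f1 <- fit_lmm(full$X, ystar, full$group)
    f0 <- fit_lmm(Xr, ystar, full$group)
    lr <- max(0, 2 * (f1$loglik - f0$loglik))
    if (lr >= lr_obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + iterations)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Confound-model quality criteria
#'
#' Residuals are computed in original metric units (model predictions -
#' conditional on the estimated subject random intercepts, the default
#' residual type of mixed-model tooling - are back-transformed through the
#' inverse Box-Cox), the 5 percent largest absolute residuals are discarded,
#' and the criteria are `C1 = 100 * MAE / range` and
#' `C2 = 100 * (MAE + 3 * sigma) / range`, with `sigma` the standard
#' deviation of the absolute residuals and `range` the range of the intact
#' raw values. A model passes with `C1 <= 15` and `C2 <= 25`
#' (moderate-or-good quality).
#'
#' @param fit A `confound_model_fit`.
#' @param values Intact raw metric values (original units). Defaults to the
#'   fitting data.
#' @param predictions Model predictions in original units, aligned with
#'   `values`. Defaults to the back-transformed conditional predictions.
#' @return Object of class `model_quality` with `mae`, `sigma`, `c1`, `c2`,
#'   `pass`.
#' @export
model_quality <- function(fit, values = NULL, predictions = NULL) {
  if (is.null(values)) values <- fit$data$value
  if (is.null(predictions)) {
    zhat <- drop(fit$lmm$X %*% fit$lmm$beta) + blup_lmm(fit$lmm)[fit$lmm$group]
    predictions <- boxcox_inverse(fit$boxcox, zhat)
  }
  if (length(values) != length(predictions))
    stop("values and predictions must be aligned", call. = FALSE)
  if (length(values) < 20L) stop("need at least 20 data points", call. = FALSE)
  rng <- diff(range(values))
  if (rng == 0) stop("degenerate metric: zero range", call. = FALSE)
  ar <- abs(values - predictions)
  keep <- ar <= stats::quantile(ar, 0.95)
  mae <- mean(ar[keep])
  sigma <- stats::sd(ar[keep])
  c1 <- 100 * mae / rng
  c2 <- 100 * (mae + 3 * sigma) / rng
  structure(list(mae = mae, sigma = sigma, c1 = c1, c2 = c2,
                 pass = c1 <= 15 && c2 <= 25),
            class = "model_quality")
}

#' Remove demographic confound effects from metric values
#'
#' Subtracts, in Box-Cox space, the fitted confound terms
#' (age, sex, tested side, handedness, stereo deficits) from each value.
#' Neither the intercept nor the subject random effect is subtracted, so the
#' corrected values stay on the transformed scale of the intact cohort. The
#' intact-fitted transform is applied verbatim to affected subjects.
#'
#' @param values Raw metric values (original units).
#' @param demo Data frame with the covariate columns
#'   (`age, sex, side, dominant_side_tested, stereo_deficit`), aligned with
#'   `values`.
#' @param fit A `confound_model_fit`.
#' @return Corrected values in Box-Cox space.
#' @export
remove_confounds <- function(values, demo, fit) {
  z <- boxcox_transform(fit$boxcox, values)
  Xc <- covariate_matrix(demo)
  z - drop(Xc %*% fit$betas[CONFOUNDS])
}

#' Normalization parameters from the intact reference cohort
#'
#' Centers on the intact median, scales by the intact median absolute
#' deviation (unscaled MAD, Eq.-style `d_i`), sign-aligns so higher = worse,
#' and rescales so the worst-performing affected observation scores 100
#' percent.
#'
#' @param intact_corrected Confound-corrected intact values (Box-Cox space).
#' @param affected_corrected Confound-corrected affected values.
#' @param descriptor [metric_descriptor()] declaring `worse_direction`.
#' @return Object of class `normalization_params`
#'   (`intact_median`, `mad`, `sign`, `worst_scale`, `abnormal_cutoff`).
#' @export
normalization_params <- function(intact_corrected, affected_corrected,
                                 descriptor) {
  med <- stats::median(intact_corrected)
  d <- stats::median(abs(intact_corrected - med))
  if (d == 0) stop("degenerate metric: intact MAD is zero", call. = FALSE)
  s <- if (descriptor$worse_direction == "higher_is_worse") 1 else -1
  yhat_aff <- s * (affected_corrected - med) / d
  worst <- max(yhat_aff)
  if (worst <= 0)
    stop("no affected observation worse than the intact median; ",
         "worst-case scaling undefined", call. = FALSE)
  p <- structure(list(intact_median = med, mad = d, sign = s,
                      worst_scale = worst, abnormal_cutoff = NA_real_),
                 class = "normalization_params")
  if (length(intact_corrected) >= 20L)
    p$abnormal_cutoff <- abnormality_cutoff(normalize_metric(intact_corrected, p))
  p
}

#' Normalize corrected values to the percent impairment scale
#'
#' @param corrected Confound-corrected values (Box-Cox space).
#' @param params [normalization_params()].
#' @return Values in percent of the currently worst affected performance
#'   (intact median maps to 0, worst affected to 100).
#' @export
normalize_metric <- function(corrected, params) {
  100 * params$sign * (corrected - params$intact_median) /
    (params$mad * params$worst_scale)
}

#' Abnormal-behavior cutoff
#'
#' 95th percentile of the normalized intact values: at most 5 percent of the
#' reference cohort lies strictly above the cutoff (imposed false-positive
#' rate of 5 percent).
#'
#' @param normalized_intact Normalized intact values (>= 20).
#' @param probs Percentile, default 0.95.
#' @return Scalar cutoff.
#' @export
abnormality_cutoff <- function(normalized_intact, probs = 0.95) {
  if (length(normalized_intact) < 20L)
    stop("need at least 20 intact values", call. = FALSE)
  unname(stats::quantile(normalized_intact, probs))
}

#' Selection step 1: confound-model gate
#'
#' A metric is dropped when its confound model has insufficient quality
#' (`C1 > 15` or `C2 > 25`) or when it is significantly influenced by
#' stereo-vision deficits (`p < 0.05`), which cannot reliably be compensated
#' outside screened settings.
#'
#' @param quality [model_quality()] result.
#' @param stereo_p Stereo-deficit LRT p-value.
#' @param alpha Significance level (default 0.05).
#' @return List `keep` (logical) and `reason` (character, `""` when kept).
#' @export
step1_filter <- function(quality, stereo_p, alpha = 0.05) {
  reasons <- character()
  if (quality$c1 > 15) reasons <- c(reasons, "C1 > 15%")
  if (quality$c2 > 25) reasons <- c(reasons, "C2 > 25%")
  if (is.finite(stereo_p) && stereo_p < alpha)
    reasons <- c(reasons, sprintf("stereo vision deficit effect (p = %.3g)", stereo_p))
  list(keep = length(reasons) == 0L, reason = paste(reasons, collapse = "; "))
}
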