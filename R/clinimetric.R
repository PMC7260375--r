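#' Discriminant validity: area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the fraction of
#' (affected, intact) pairs in which the affected value is worse, ties
#' counted half. `orientation` makes "worse" explicit so AUC >= 0.5 means the
#' metric separates groups in the declared direction.
#'
#' @param intact,affected Numeric vectors (non-empty).
#' @param orientation `"higher_is_worse"` (default) or `"lower_is_worse"`.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(intact, affected,
                        orientation = c("higher_is_worse", "lower_is_worse")) {
  orientation <- match.arg(orientation)
  if (!length(intact) || !length(affected))
    stop("both groups must be non-empty", call. = FALSE)
  if (orientation == "lower_is_worse") {
    intact <- -intact
    affected <- -affected
  }
  r <- rank(c(affected, intact))
  na <- length(affected)
  ni <- length(intact)
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * ni)
}

#' Test-retest reliability: agreement ICC, ICC(A,k)
#'
#' Two-way ANOVA agreement intraclass correlation for the average of k = 2
#' sessions: `(MS_rows - MS_err) / (MS_rows + (MS_cols - MS_err) / n)`, where
#' rows are subject x side units and columns are sessions. Sensitive to
#' systematic session differences through the column mean square.
#'
#' @param paired n x 2 numeric matrix (test, retest), complete pairs only,
#'   n >= 3.
#' @return ICC in `(-Inf, 1]`.
#' @export
compute_icc_agreement <- function(paired) {
  paired <- as.matrix(paired)
  if (ncol(paired) != 2L) stop("paired must have two columns", call. = FALSE)
  paired <- paired[stats::complete.cases(paired), , drop = FALSE]
  n <- nrow(paired)
  if (n < 3L) stop("need at least 3 complete test-retest pairs", call. = FALSE)
  k <- 2L
  grand <- mean(paired)
  row_m <- rowMeans(paired)
  col_m <- colMeans(paired)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((paired - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  (ms_rows - ms_err) / (ms_rows + (ms_cols - ms_err) / n)
}

#' Measurement error: smallest real difference
#'
#' `SRD = 1.96 * sqrt(2) * Sigma * sqrt(1 - ICC)`, with `Sigma` the standard
#' deviation of all aggregated test-retest values (pooled over subjects,
#' sides and sessions). `SRD%` expresses it relative to the range of the
#' normalized intact values.
#'
#' @param paired n x 2 matrix of test/retest values.
#' @param icc Agreement ICC for the metric (<= 1).
#' @param normalized_range Range of the intact normalized values (> 0).
#' @return List `srd`, `srd_pct`.
#' @export
compute_srd <- function(paired, icc, normalized_range) {
  if (icc > 1) stop("ICC cannot exceed 1", call. = FALSE)
  if (normalized_range <= 0) stop("normalized_range must be positive", call. = FALSE)
  sigma <- stats::sd(as.vector(as.matrix(paired)))
  srd <- 1.96 * sqrt(2) * sigma * sqrt(max(0, 1 - icc))
  list(srd = srd, srd_pct = 100 * srd / normalized_range)
}

#' Learning effects: slope eta and paired t-test
#'
#' `eta = 100 * mean(retest - test) / range`: the mean session-to-session
#' change as a percentage of the normative range (negative = improved
#' performance at retest). A two-sided paired t-test accompanies it.
#'
#' @param paired n x 2 matrix (test, retest), n >= 3.
#' @param normalized_range Range of the intact normalized values (> 0).
#' @return List `eta`, `paired_t_p`.
#' @export
compute_eta <- function(paired, normalized_range) {
  paired <- as.matrix(paired)
  if (nrow(paired) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (normalized_range <= 0) stop("degenerate metric: zero range", call. = FALSE)
  d <- paired[, 2] - paired[, 1]
  eta <- 100 * mean(d) / normalized_range
  p <- if (stats::sd(d) == 0) {
    if (mean(d) == 0) 1 else 0
  } else {
    stats::t.test(paired[, 2], paired[, 1], paired = TRUE)$p.value
  }
  list(eta = eta, paired_t_p = p)
}

#' Nearest-rank percentile
#'
#' The k-th order statistic with `k = ceiling(p * n / 100)`; the convention
#' under which the published learning-effect cutoff (-6.35 at the 20th
#' percentile) is reproduced from the printed score table. A
#' linear-interpolation variant is available via `type = "linear"`.
#'
#' @param x Numeric vector.
#' @param p Percentile in (0, 100).
#' @param type `"nearest_rank"` (default) or `"linear"` (type-7 quantile).
#' @return Scalar percentile value.
#' @export
percentile <- function(x, p, type = c("nearest_rank", "linear")) {
  type <- match.arg(type)
  if (type == "linear") return(unname(stats::quantile(x, p / 100)))
  sort(x)[ceiling(p * length(x) / 100)]
}

#' Data-driven SRD% and eta cutoffs
#'
#' The measurement-error cutoff is the 80th percentile of all evaluated SRD%
#' values (the 20 percent worst are removed); the learning-effect cutoff is
#' the 20th percentile of all eta values. Both vectors must cover the full
#' evaluated metric set, controls included.
#'
#' @param all_srd_pct,all_eta Vectors over every evaluated metric.
#' @param srd_percentile,eta_percentile Cut percentiles (defaults 80 / 20).
#' @param type Percentile convention, see [percentile()].
#' @return List `srd_cutoff`, `eta_cutoff`.
#' @export
percentile_cutoffs <- function(all_srd_pct, all_eta, srd_percentile = 80,
                               eta_percentile = 20, type = "nearest_rank") {
  list(srd_cutoff = percentile(all_srd_pct, srd_percentile, type),
       eta_cutoff = percentile(all_eta, eta_percentile, type))
}

#' Selection step 2: clinimetric pass/fail filter
#'
#' A metric survives when all four hold: `AUC >= 0.7` (acceptable
#' discriminant ability), `ICC >= 0.7` (acceptable reliability; inclusive
#' boundary), `SRD% < srd_cutoff`, and `eta > eta_cutoff` (strict: a metric
#' exactly at the learning cutoff fails). Every failed criterion is recorded.
#'
#' @param scores Data frame with columns `metric, auc, icc, srd_pct, eta`.
#' @param cutoffs List from [percentile_cutoffs()].
#' @param auc_min,icc_min Fixed thresholds (defaults 0.7).
#' @param step1_keep Optional logical vector (or character vector of step-1
#'   survivor names) used to report the intersection with step 1.
#' @return `scores` augmented with `pass_step2`, `reason`, and (when
#'   `step1_keep` is given) `pass_steps_1_2`.
#' @export
step2_filter <- function(scores, cutoffs, auc_min = 0.7, icc_min = 0.7,
                         step1_keep = NULL) {
  reason <- character(nrow(scores))
  fails <- function(cond, msg) ifelse(cond, msg, NA_character_)
  parts <- cbind(
    fails(scores$auc < auc_min, sprintf("AUC < %.2g", auc_min)),
    fails(scores$icc < icc_min, sprintf("ICC < %.2g", icc_min)),
    fails(scores$srd_pct >= cutoffs$srd_cutoff,
          sprintf("SRD%% >= %.4g", cutoffs$srd_cutoff)),
    fails(scores$eta <= cutoffs$eta_cutoff,
          sprintf("eta <= %.4g", cutoffs$eta_cutoff)))
  scores$pass_step2 <- apply(parts, 1, function(r) all(is.na(r)))
  scores$reason <- apply(parts, 1, function(r)
    paste(r[!is.na(r)], collapse = "; "))
  if (!is.null(step1_keep)) {
    if (is.character(step1_keep)) step1_keep <- scores$metric %in% step1_keep
    scores$pass_steps_1_2 <- scores$pass_step2 & step1_keep
  }
  scores
}

#' Write a clinimetric scores table
#'
#' One row per metric with AUC, ICC, SRD%, eta and pass flags, as delimited
#' text and/or JSON.
#'
#' @param scores Scores data frame (see [step2_filter()]).
#' @param path Output path; `.json` selects JSON, anything else CSV.
#' @export
write_scores <- function(scores, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(scores, path, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(scores, path, row.names = FALSE)
  }
  invisible(path)
}
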