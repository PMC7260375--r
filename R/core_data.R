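#' @keywords internal
"_PACKAGE"

GROUPS <- c("intact", "stroke", "ms", "arsacs")
SIDES <- c("left", "right")
SESSIONS <- c("test", "retest")
FAMILIES <- c("smoothness", "efficiency", "curvature", "speed", "endpoint_error",
              "haptic", "counts", "drops", "gf_scaling", "gf_coordination",
              "overall", "control")
PHASES <- c("transport", "return", "peg_approach", "hole_approach", "buildup",
            "release", "whole_trial")

#' Construct a metric descriptor
#'
#' Registers a metric's family, task phase, support and - crucially - the
#' direction in which values worsen. Every metric entering the selection
#' pipeline must declare `worse_direction` so that the ROC orientation and the
#' sign alignment of the normalized scale are well defined.
#'
#' @param metric_name Metric identifier.
#' @param family One of the movement-characteristic families
#'   (smoothness, efficiency, curvature, speed, endpoint_error, haptic,
#'   counts, drops, gf_scaling, gf_coordination, overall, control).
#' @param phase Task phase the metric is computed on.
#' @param worse_direction `"higher_is_worse"` or `"lower_is_worse"`.
#' @param support Numeric length-2 support interval (may be infinite).
#' @return A `metric_descriptor` object (named list).
#' @export
metric_descriptor <- function(metric_name, family, phase,
                              worse_direction = c("higher_is_worse", "lower_is_worse"),
                              support = c(-Inf, Inf)) {
  worse_direction <- match.arg(worse_direction)
  family <- match.arg(family, FAMILIES)
  phase <- match.arg(phase, PHASES)
  stopifnot(is.character(metric_name), length(metric_name) == 1L,
            length(support) == 2L, support[1] < support[2])
  structure(list(metric_name = metric_name, family = family, phase = phase,
                 worse_direction = worse_direction, support = support),
            class = "metric_descriptor")
}

#' Read a metric registry from YAML
#'
#' The registry file is a YAML list of entries with fields `metric_name`,
#' `family`, `phase`, `worse_direction` and optionally `support`.
#'
#' @param path Path to the YAML registry.
#' @return Named list of [metric_descriptor()] objects.
#' @export
read_metric_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(e) {
    metric_descriptor(e$metric_name, e$family, e$phase, e$worse_direction,
                      support = if (is.null(e$support)) c(-Inf, Inf) else
                        as.numeric(e$support))
  })
  names(out) <- vapply(out, `[[`, "", "metric_name")
  out
}

subjects_columns <- c("subject_id", "group", "age", "sex", "side",
                      "dominant_side_tested", "stereo_deficit",
                      "fma_ue", "arat", "nhpt")
metrics_columns <- c("subject_id", "side", "session", "repetition", "peg",
                     "metric_name", "value")

validate_subjects <- function(subjects) {
  miss <- setdiff(subjects_columns, names(subjects))
  if (length(miss))
    stop("subjects table: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(subjects$group %in% GROUPS))
    stop("subjects table: unknown group value(s): ",
         paste(setdiff(subjects$group, GROUPS), collapse = ", "), call. = FALSE)
  if (!all(subjects$sex %in% c("male", "female")))
    stop("subjects table: sex must be 'male' or 'female'", call. = FALSE)
  if (!all(subjects$side %in% SIDES))
    stop("subjects table: side must be 'left' or 'right'", call. = FALSE)
  if (any(!is.finite(subjects$age) | subjects$age <= 0))
    stop("subjects table: age must be a positive number", call. = FALSE)
  ok_rng <- function(x, lo, hi) all(is.na(x) | (x >= lo & x <= hi))
  if (!ok_rng(subjects$fma_ue, 0, 66)) stop("fma_ue outside [0, 66]", call. = FALSE)
  if (!ok_rng(subjects$arat, 0, 57)) stop("arat outside [0, 57]", call. = FALSE)
  if (!all(is.na(subjects$nhpt) | subjects$nhpt > 0))
    stop("nhpt must be > 0 when present", call. = FALSE)
  dup <- duplicated(subjects[c("subject_id", "side")])
  if (any(dup))
    stop("subjects table: duplicate subject_id x side rows", call. = FALSE)
  invisible(subjects)
}

validate_observations <- function(obs, subjects = NULL) {
  miss <- setdiff(metrics_columns, names(obs))
  if (length(miss))
    stop("metrics table: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(obs$value))
  if (length(bad))
    stop("metrics table: non-finite value in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (!all(obs$session %in% SESSIONS))
    stop("metrics table: session must be 'test' or 'retest'", call. = FALSE)
  if (!all(obs$side %in% SIDES))
    stop("metrics table: side must be 'left' or 'right'", call. = FALSE)
  key <- do.call(paste, c(obs[c("subject_id", "side", "session", "repetition",
                                "peg", "metric_name")], sep = "\r"))
  if (anyDuplicated(key))
    stop("metrics table: duplicate (subject, side, session, repetition, peg, metric) rows",
         call. = FALSE)
  if (!is.null(subjects)) {
    unknown <- setdiff(obs$subject_id, subjects$subject_id)
    if (length(unknown))
      stop("metrics table: subject_id not present in subjects table: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(obs)
}

read_delim_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a cohort (subjects + per-trial metric observations)
#'
#' Both files are comma-delimited with the documented headers. Referential
#' integrity (every observation's subject appears in the subjects table) and
#' value finiteness are enforced; an informative error names the offending
#' column or row.
#'
#' @param subjects_path CSV with columns
#'   `subject_id,group,age,sex,side,dominant_side_tested,stereo_deficit,fma_ue,arat,nhpt`
#'   (clinical columns may be empty).
#' @param metrics_path CSV with columns
#'   `subject_id,side,session,repetition,peg,metric_name,value`.
#' @return List with elements `subjects` and `observations` (data frames).
#' @export
read_cohort <- function(subjects_path, metrics_path) {
  subjects <- read_delim_checked(subjects_path)
  for (col in c("fma_ue", "arat", "nhpt"))
    if (col %in% names(subjects)) subjects[[col]] <- as.numeric(subjects[[col]])
  for (col in c("dominant_side_tested", "stereo_deficit"))
    if (col %in% names(subjects)) subjects[[col]] <- as.logical(subjects[[col]])
  validate_subjects(subjects)
  obs <- read_delim_checked(metrics_path)
  if ("value" %in% names(obs) && !is.numeric(obs$value)) {
    suppressWarnings(v <- as.numeric(obs$value))
    bad <- which(is.na(v) | is.nan(v))
    if (length(bad))
      stop("metrics table: non-numeric value in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    obs$value <- v
  }
  validate_observations(obs, subjects)
  list(subjects = subjects, observations = obs)
}

#' Write cohort tables
#'
#' Inverse of [read_cohort()]; values round-trip exactly at full double
#' precision (written with 17 significant digits).
#'
#' @param subjects,observations Data frames as returned by [read_cohort()].
#' @param subjects_path,metrics_path Output paths.
#' @export
write_cohort <- function(subjects, observations, subjects_path, metrics_path) {
  w <- function(df, path) {
    df2 <- df
    num <- vapply(df2, is.double, TRUE)
    df2[num] <- lapply(df2[num], function(x) sprintf("%.17g", x))
    utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  }
  w(subjects, subjects_path)
  w(observations, metrics_path)
  invisible(c(subjects_path, metrics_path))
}

#' Aggregate per-trial observations to a subject-level metric table
#'
#' Collapses repetitions and pegs with the grand median so that downstream
#' analyses operate on one value per subject, tested side, session and metric.
#' Missing trials are simply absent; the median runs over available trials.
#' Even-length medians are the mean of the two middle order statistics.
#'
#' @param observations Data frame of per-trial observations
#'   (see [read_cohort()]).
#' @return Data frame in long aggregated form with columns
#'   `subject_id, side, session, metric_name, value` - one row per
#'   subject x side x session x metric.
#' @export
aggregate_trials <- function(observations) {
  if (nrow(observations) == 0L) stop("no observations to aggregate", call. = FALSE)
  validate_observations(observations)
  key <- interaction(observations$subject_id, observations$side,
                     observations$session, observations$metric_name,
                     drop = TRUE, sep = "\r")
  med <- tapply(observations$value, key, stats::median)
  parts <- strsplit(names(med), "\r", fixed = TRUE)
  out <- data.frame(
    subject_id = vapply(parts, `[[`, "", 1L),
    side = vapply(parts, `[[`, "", 2L),
    session = vapply(parts, `[[`, "", 3L),
    metric_name = vapply(parts, `[[`, "", 4L),
    value = as.numeric(med),
    stringsAsFactors = FALSE
  )
  out[order(out$subject_id, out$side, out$session, out$metric_name), ,
      drop = FALSE]
}

#' Pivot an aggregated metric table to wide (one column per metric)
#'
#' @param agg Output of [aggregate_trials()].
#' @param session Optional session filter (`"test"` or `"retest"`).
#' @return Data frame with key columns `subject_id, side, session` and one
#'   numeric column per metric.
#' @export
metric_table <- function(agg, session = NULL) {
  if (!is.null(session)) agg <- agg[agg$session %in% session, , drop = FALSE]
  wide <- stats::reshape(agg, idvar = c("subject_id", "side", "session"),
                         timevar = "metric_name", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
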