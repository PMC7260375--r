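#' Packaged reference clinimetric score table
#'
#' The published clinimetric scores (AUC, ICC, SRD%, learning slope eta) of
#' the 77 candidate pick-and-place metrics of the validation cohort,
#' including the simulated-noise control, the step-1 model-quality outcome
#' and the all-criteria flag. Distributed so that the selection arithmetic
#' can be exercised and checked offline without any raw subject data.
#'
#' @return Data frame with one row per metric.
#' @export
reference_scores <- function() {
  path <- system.file("extdata", "vpit_reference_scores.csv",
                      package = "metricsieve", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Step-3 removals documented for the reference core set
#'
#' Encodes the two literature-preference removals applied to the reference
#' survivor set: the grip-force-rate peak count during hole approach is
#' dropped in favour of the force-rate spectral arc length of the same phase
#' (distance-independent), and the hole-approach speed-profile spectral arc
#' length is dropped in favour of the force-rate version (more directly
#' hand-function related).
#'
#' @return Named character vector usable as `overrides` in
#'   [iterative_reduction()].
#' @export
reference_step3_overrides <- function() {
  c("gf_rate_num_peaks_hole_approach|gf_rate_sparc_hole_approach" =
      "gf_rate_num_peaks_hole_approach",
    "gf_rate_sparc_hole_approach|sparc_hole_approach" =
      "sparc_hole_approach")
}

#' Apply the selection arithmetic to a precomputed score table
#'
#' Recomputes the data-driven cutoffs from the table (80th percentile of
#' SRD%, 20th percentile of eta, nearest-rank), applies the step-2 filter,
#' intersects with the step-1 survivors, and applies a list of documented
#' step-3 removals. This is the score-table route through the pipeline: it
#' needs no raw data and reproduces the published survivor counts from
#' [reference_scores()].
#'
#' @param scores Data frame with columns
#'   `metric, auc, icc, srd_pct, eta, model_quality_pass`.
#' @param step3_removals Character vector of metrics removed in step 3
#'   (default: the documented reference removals present in the table).
#' @param percentile_type Percentile convention (see [percentile()]).
#' @return List: `cutoffs`, `scores` (augmented), `step2_survivors`,
#'   `steps12_survivors`, `core`, `medians` (AUC/ICC/SRD%/eta over the
#'   steps-1-2 survivors).
#' @export
apply_selection <- function(scores,
                            step3_removals = intersect(
                              c("gf_rate_num_peaks_hole_approach",
                                "sparc_hole_approach"), scores$metric),
                            percentile_type = "nearest_rank") {
  cutoffs <- percentile_cutoffs(scores$srd_pct, scores$eta,
                                type = percentile_type)
  scored <- step2_filter(scores, cutoffs,
                         step1_keep = scores$metric[scores$model_quality_pass])
  s2 <- scored$metric[scored$pass_step2]
  s12 <- scored$metric[scored$pass_steps_1_2]
  core <- setdiff(s12, step3_removals)
  sel <- scored[scored$pass_steps_1_2, ]
  medians <- c(auc = stats::median(sel$auc), icc = stats::median(sel$icc),
               srd_pct = stats::median(sel$srd_pct),
               eta = stats::median(sel$eta))
  list(cutoffs = cutoffs, scores = scored, step2_survivors = s2,
       steps12_survivors = s12, core = core, medians = medians)
}

#' Run the full selection and validation pipeline on a cohort
#'
#' End-to-end orchestration on metric-level data: trial aggregation, per
#' metric Box-Cox + mixed-effects confound model + bootstrap stereo LRT +
#' model-quality gate (step 1), confound removal, normalization to the
#' percent impairment scale, AUC / ICC(A,k) / SRD% / eta scoring with
#' data-driven cutoffs (step 2), iterative partial-Spearman redundancy
#' reduction (step 3), then exploratory factor analysis with parallel
#' analysis + KMO and disability-subgroup Kruskal-Wallis tests on the core
#' set. Deterministic given `seed`. The returned ledger records survivors
#' and the reason for every removal at every step.
#'
#' @param subjects,observations Cohort tables ([read_cohort()] /
#'   [gen_cohort()]).
#' @param descriptors Named list of [metric_descriptor()] covering every
#'   metric in `observations`.
#' @param lrt_iterations Parametric-bootstrap iterations for the stereo LRT
#'   (default 200).
#' @param seed Integer seed.
#' @param percentile_type Percentile convention for the cutoffs.
#' @param step3_overrides Manual pair overrides for [iterative_reduction()].
#' @param run_validation Run EFA + subgroup tests on the core set (default
#'   `TRUE`; needs >= 3 core metrics for the EFA).
#' @return Object of class `selection_ledger`.
#' @export
run_pipeline <- function(subjects, observations, descriptors,
                         lrt_iterations = 200L, seed = 1L,
                         percentile_type = "nearest_rank",
                         step3_overrides = NULL, run_validation = TRUE) {
  agg <- aggregate_trials(observations)
  metrics <- sort(unique(agg$metric_name))
  missing_desc <- setdiff(metrics, names(descriptors))
  if (length(missing_desc))
    stop("stage core_data: no descriptor for metric(s): ",
         paste(missing_desc, collapse = ", "), call. = FALSE)
  intact_ids <- subjects$subject_id[subjects$group == "intact"]
  step1 <- list()
  normalized <- list()   # per metric: data frame subject_id, side, session, norm
  scores_rows <- list()
  for (m in metrics) {
    am <- agg[agg$metric_name == m, , drop = FALSE]
    a_test <- am[am$session == "test", c("subject_id", "side", "value")]
    intact_test <- a_test[a_test$subject_id %in% intact_ids, , drop = FALSE]
    fit <- tryCatch(
      fit_confound_model(intact_test, subjects, metric_name = m),
      error = function(e) stop("stage confound_normalization [", m, "]: ",
                               conditionMessage(e), call. = FALSE))
    qual <- model_quality(fit)
    stereo_p <- if ("stereo" %in% fit$dropped) NA_real_ else
      bootstrap_lrt(fit, "stereo", iterations = lrt_iterations,
                    seed = seed + match(m, metrics))
    dec <- step1_filter(qual, stereo_p)
    step1[[m]] <- list(fit = fit, quality = qual, stereo_p = stereo_p,
                       keep = dec$keep, reason = dec$reason)
    demo_all <- merge(am[, c("subject_id", "side", "session", "value")],
                      subjects, by = c("subject_id", "side"), sort = FALSE)
    corrected <- remove_confounds(demo_all$value, demo_all, fit)
    is_int <- demo_all$subject_id %in% intact_ids
    is_test <- demo_all$session == "test"
    params <- tryCatch(
      normalization_params(corrected[is_int & is_test],
                           corrected[!is_int & is_test], descriptors[[m]]),
      error = function(e) NULL)
    if (is.null(params)) {
      step1[[m]]$keep <- FALSE
      step1[[m]]$reason <- paste0(step1[[m]]$reason,
                                  "; degenerate normalization")
      next
    }
    nv <- normalize_metric(corrected, params)
    normalized[[m]] <- data.frame(subject_id = demo_all$subject_id,
                                  side = demo_all$side,
                                  session = demo_all$session, norm = nv,
                                  intact = is_int, stringsAsFactors = FALSE)
    ni_test <- nv[is_int & is_test]
    rng <- diff(range(nv[is_int]))
    pairs <- merge(normalized[[m]][normalized[[m]]$session == "test" &
                                     normalized[[m]]$intact,
                                   c("subject_id", "side", "norm")],
                   normalized[[m]][normalized[[m]]$session == "retest",
                                   c("subject_id", "side", "norm")],
                   by = c("subject_id", "side"))
    paired <- as.matrix(pairs[, c("norm.x", "norm.y")])
    auc <- compute_auc(ni_test, nv[!is_int & is_test], "higher_is_worse")
    icc <- if (nrow(paired) >= 3L) compute_icc_agreement(paired) else NA_real_
    srd <- if (is.finite(icc) && icc <= 1)
      compute_srd(paired, icc, rng) else list(srd = NA_real_, srd_pct = NA_real_)
    eta <- if (nrow(paired) >= 3L) compute_eta(paired, rng) else
      list(eta = NA_real_, paired_t_p = NA_real_)
    scores_rows[[m]] <- data.frame(
      metric = m, auc = auc, icc = icc, srd = srd$srd, srd_pct = srd$srd_pct,
      eta = eta$eta, paired_t_p = eta$paired_t_p,
      abnormal_cutoff = params$abnormal_cutoff,
      model_quality_pass = step1[[m]]$keep, stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, scores_rows)
  rownames(scores) <- NULL
  cutoffs <- percentile_cutoffs(scores$srd_pct, scores$eta,
                                type = percentile_type)
  scores <- step2_filter(scores, cutoffs,
                         step1_keep = scores$metric[scores$model_quality_pass])
  s12 <- scores$metric[scores$pass_steps_1_2]
  norm_wide <- NULL
  reduction <- list(core = s12,
                    decisions = data.frame(metric_a = character(),
                                           metric_b = character(),
                                           removed = character(),
                                           kept = character(),
                                           rho_p = numeric(),
                                           rationale = character()))
  if (length(s12) >= 2L) {
    norm_long <- do.call(rbind, lapply(s12, function(m) {
      d <- normalized[[m]]
      d <- d[d$session == "test", ]
      data.frame(subject_id = d$subject_id, side = d$side, metric_name = m,
                 value = d$norm, stringsAsFactors = FALSE)
    }))
    norm_long$session <- "test"
    norm_wide <- metric_table(norm_long)
    reduction <- iterative_reduction(
      norm_wide[, s12, drop = FALSE],
      scores[scores$metric %in% s12, c("metric", "auc", "icc", "srd_pct")],
      overrides = step3_overrides)
  }
  core <- reduction$core
  validation <- NULL
  if (run_validation && length(core) >= 3L && !is.null(norm_wide)) {
    Xcore <- norm_wide[, core, drop = FALSE]
    pa <- parallel_analysis(Xcore, seed = seed)
    fm <- if (pa$k >= 1L && ncol(Xcore) >= pa$k + 2L)
      tryCatch(efa_promax(Xcore, pa$k), error = function(e) NULL) else NULL
    key <- subjects[match(paste(norm_wide$subject_id, norm_wide$side),
                          paste(subjects$subject_id, subjects$side)), ]
    sev <- suppressWarnings(assign_severity_groups(key))
    subgroups <- lapply(core, function(m) {
      lapply(c("stroke", "ms", "arsacs"), function(g) {
        sel <- key$group %in% c("intact", g)
        tryCatch(suppressWarnings(
          subgroup_tests(Xcore[sel, m], ifelse(key$group[sel] == "intact",
                                               "intact", sev[sel]),
                         n_metrics = length(core))),
          error = function(e) NULL)
      }) |> stats::setNames(c("stroke", "ms", "arsacs"))
    })
    names(subgroups) <- core
    validation <- list(kmo = kmo(Xcore), parallel = pa, factors = fm,
                       subgroups = subgroups)
  }
  structure(list(
    metrics_evaluated = metrics,
    step1 = data.frame(
      metric = names(step1),
      c1 = vapply(step1, function(s) s$quality$c1, 0),
      c2 = vapply(step1, function(s) s$quality$c2, 0),
      stereo_p = vapply(step1, function(s) s$stereo_p, 0),
      keep = vapply(step1, function(s) s$keep, TRUE),
      reason = vapply(step1, function(s) s$reason, ""),
      row.names = NULL, stringsAsFactors = FALSE),
    fits = lapply(step1, function(s) s$fit),
    scores = scores, cutoffs = cutoffs,
    step2_survivors = scores$metric[scores$pass_step2],
    steps12_survivors = s12,
    reduction = reduction, core = core,
    normalized = normalized, validation = validation,
    seed = seed), class = "selection_ledger")
}

#' @export
print.selection_ledger <- function(x, ...) {
  cat("metric selection ledger\n")
  cat("  evaluated:        ", length(x$metrics_evaluated), "metrics\n")
  cat("  step 1 survivors: ", sum(x$step1$keep), "\n")
  cat("  step 2 survivors: ", length(x$step2_survivors), "\n")
  cat("  steps 1+2:        ", length(x$steps12_survivors), "\n")
  cat("  core set:         ", length(x$core), "->",
      paste(x$core, collapse = ", "), "\n")
  invisible(x)
}

#' Write pipeline reports
#'
#' Emits the scores table (CSV + JSON), the step-1 model report, the step-3
#' decision log (JSON) and, when present, factor loadings and subgroup
#' statistics, into `out_dir`.
#'
#' @param ledger A `selection_ledger` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(ledger, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(out_dir, "scores.csv")
  write_scores(ledger$scores, p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "scores.json")
  write_scores(ledger$scores, p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "step1_models.csv")
  utils::write.csv(ledger$step1, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "selection.json")
  jsonlite::write_json(list(
    cutoffs = ledger$cutoffs,
    step2_survivors = ledger$step2_survivors,
    steps12_survivors = ledger$steps12_survivors,
    core = ledger$core,
    decisions = ledger$reduction$decisions), p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  if (!is.null(ledger$validation)) {
    v <- ledger$validation
    p <- file.path(out_dir, "validation.json")
    jsonlite::write_json(list(
      kmo = v$kmo, k = v$parallel$k,
      loadings = if (!is.null(v$factors)) as.data.frame(v$factors$loadings),
      heywood = if (!is.null(v$factors)) v$factors$heywood), p,
      auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
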