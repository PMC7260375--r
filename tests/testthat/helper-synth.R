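# shared helpers for the test suite

fixed_boxcox <- function(lambda, shift = 0)
  structure(list(lambda = lambda, shift = shift), class = "boxcox_transform")

# tiny two-subject cohort files for reader tests
write_tiny_cohort <- function(dir) {
  subjects <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 2),
    group = "intact", age = rep(c(40, 55), each = 2), sex = "male",
    side = rep(c("left", "right"), 2),
    dominant_side_tested = c(FALSE, TRUE, FALSE, TRUE),
    stereo_deficit = FALSE, fma_ue = NA, arat = NA, nhpt = NA)
  obs <- data.frame(subject_id = c("s1", "s1", "s2"),
                    side = c("left", "left", "right"),
                    session = "test", repetition = c(1, 2, 1), peg = 1,
                    metric_name = "m1", value = c(7, 9, 4.25))
  sp <- file.path(dir, "subjects.csv"); mp <- file.path(dir, "metrics.csv")
  write_cohort(subjects, obs, sp, mp)
  list(subjects = sp, metrics = mp)
}

# maximal absolute boundary error (s) between segmentation and script truth
seg_worst_err <- function(gen, pre, seg) {
  worst <- 0
  for (i in seq_len(nrow(seg))) {
    tt <- gen$truth[gen$truth$peg == seg$peg[i] &
                      gen$truth$phase == seg$phase[i], ]
    if (nrow(tt)) {
      worst <- max(worst,
                   abs((seg$start[i] - 1) / pre$fs + pre$time[1] - tt$start_time),
                   abs((seg$end[i] - 1) / pre$fs + pre$time[1] - tt$end_time))
    }
  }
  worst
}

# confound-corrected ICC / AUC for one metric of a generated cohort,
# using the generative transform (recovery route used by the acceptance
# checks; lambda re-estimation is exercised elsewhere)
cohort_metric_scores <- function(cohort, metric, lambda) {
  agg <- aggregate_trials(
    cohort$observations[cohort$observations$metric_name == metric, ])
  intact <- unique(cohort$subjects$subject_id[cohort$subjects$group == "intact"])
  a_test <- agg[agg$session == "test", c("subject_id", "side", "value")]
  fit <- fit_confound_model(a_test[a_test$subject_id %in% intact, ],
                            cohort$subjects, metric,
                            boxcox = fixed_boxcox(lambda))
  demo <- merge(agg, cohort$subjects, by = c("subject_id", "side"), sort = FALSE)
  z <- remove_confounds(demo$value, demo, fit)
  dd <- data.frame(sid = demo$subject_id, side = demo$side,
                   sess = demo$session, z = z)
  pr <- merge(dd[dd$sess == "test" & dd$sid %in% intact, ],
              dd[dd$sess == "retest", ], by = c("sid", "side"))
  icc <- if (nrow(pr) >= 3) compute_icc_agreement(cbind(pr$z.x, pr$z.y)) else NA
  it <- dd$sess == "test" & dd$sid %in% intact
  af <- dd$sess == "test" & !(dd$sid %in% intact)
  wd <- cohort$ground_truth[[metric]]$worse_direction
  auc <- if (any(af)) compute_auc(dd$z[it], dd$z[af], wd) else NA
  list(icc = icc, auc = auc, fit = fit,
       beta_age = fit$betas[["age"]],
       se_age = fit$se[match("age", names(fit$lmm$beta))])
}

planted_loadings <- function(m_per_factor = 4, k = 3, loading = 0.8) {
  L <- matrix(0, m_per_factor * k, k)
  for (j in seq_len(k)) L[(j - 1) * m_per_factor + seq_len(m_per_factor), j] <- loading
  rownames(L) <- paste0("m", seq_len(nrow(L)))
  L
}

auc_bruteforce <- function(intact, affected) {
  # concordant-pair counting oracle, ties half credit
  s <- 0
  for (a in affected) for (i in intact)
    s <- s + (a > i) + 0.5 * (a == i)
  s / (length(affected) * length(intact))
}

icc_aov_oracle <- function(paired) {
  # two-way ANOVA mean squares via aov()
  n <- nrow(paired)
  d <- data.frame(y = c(paired[, 1], paired[, 2]),
                  subj = factor(rep(seq_len(n), 2)),
                  sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / n)
}
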