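#' Default synthetic metric specifications
#'
#' A small panel of generative metric specifications mirroring the
#' statistical structure of the confound model: fixed demographic effects,
#' a subject random intercept shared across sides, a stable subject-x-side
#' component, session noise sized to a planted agreement ICC, a planted
#' retest shift (learning), and a planted affected-group separation
#' expressed as a target AUC. `lambda` is the Box-Cox exponent used to map
#' the Gaussian model space back to the raw metric scale.
#'
#' @param true_icc,true_auc Planted agreement ICC and AUC shared by the
#'   default panel.
#' @return Named list of metric spec lists.
#' @export
default_metric_specs <- function(true_icc = 0.8, true_auc = 0.85) {
  spec <- function(name, lambda, betas, worse = "higher_is_worse",
                   session_shift = -0.15) {
    list(name = name, lambda = lambda, betas = betas,
         worse_direction = worse,
         sigma_subject = 0.95, sigma_unit = sqrt(1 - 0.95^2),
         true_icc = true_icc, true_auc = true_auc,
         session_shift = session_shift, trial_sd = 0.3)
  }
  b <- function(intercept, age = 0, sex = 0, side = 0, handedness = 0,
                stereo = 0)
    c(intercept = intercept, age = age, sex = sex, side = side,
      handedness = handedness, stereo = stereo)
  list(
    log_jerk_tp = spec("log_jerk_tp", 0, b(8, age = 0.05, sex = 0.5)),
    path_length_ratio_tp = spec("path_length_ratio_tp", 1,
                                b(10, age = 0.05, handedness = -0.6),
                                worse = "lower_is_worse"),
    velocity_max_rt = spec("velocity_max_rt", 1,
                           b(9, age = 0.06, side = 0.4, sex = 0.5),
                           worse = "lower_is_worse"),
    gf_rate_sparc_tp = spec("gf_rate_sparc_tp", 1,
                            b(9, age = 0.05, sex = 0.6)),
    task_completion_time = spec("task_completion_time", 0,
                                b(3.6, age = 0.015, sex = 0.15))
  )
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults are the study conditions of the validation cohort: 120
#' neurologically intact subjects (60 of them with a retest session), 53
#' stroke, 28 MS and 8 ARSACS subjects, both body sides tested, five
#' repetitions of nine pegs per side, plus a pure-noise control metric drawn
#' log-normal with mean 46.0 and standard deviation 32.2 (the raw-scale
#' moments of the reference completion-time distribution).
#'
#' @param n_intact,n_retest,n_affected Cohort sizes.
#' @param metrics Metric specs, see [default_metric_specs()].
#' @param n_repetitions,n_pegs Trial grid collapsed by the grand median.
#' @param noise_metric `list(mean, sd)` of the log-normal control, or `NULL`
#'   to omit it.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_intact = 120L, n_retest = 60L,
                          n_affected = c(stroke = 53L, ms = 28L, arsacs = 8L),
                          metrics = default_metric_specs(),
                          n_repetitions = 5L, n_pegs = 9L,
                          noise_metric = list(mean = 46.0, sd = 32.2),
                          seed = 1L) {
  stopifnot(n_intact >= 0, n_retest >= 0, n_retest <= n_intact,
            all(n_affected >= 0))
  for (m in metrics)
    if (!is.null(m$true_icc) && (m$true_icc < 0 || m$true_icc > 1))
      stop("true_icc must be in [0, 1]", call. = FALSE)
  structure(list(n_intact = as.integer(n_intact), n_retest = as.integer(n_retest),
                 n_affected = n_affected, metrics = metrics,
                 n_repetitions = as.integer(n_repetitions),
                 n_pegs = as.integer(n_pegs), noise_metric = noise_metric,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

sample_skewed_score <- function(n, lo, hi, q50) {
  # integer clinical scores with median near q50, right-concentrated
  raw <- round(q50 + (hi - lo) * 0.18 * stats::rnorm(n) - abs(stats::rnorm(n)) * (hi - lo) * 0.08)
  pmin(hi, pmax(lo, raw))
}

gen_subjects <- function(config) {
  n_int <- config$n_intact
  na <- config$n_affected
  ids <- c(sprintf("HC%03d", seq_len(n_int)),
           sprintf("ST%03d", seq_len(na[["stroke"]])),
           sprintf("MS%03d", seq_len(na[["ms"]])),
           sprintf("AR%03d", seq_len(na[["arsacs"]])))
  group <- rep(c("intact", "stroke", "ms", "arsacs"),
               times = c(n_int, na[["stroke"]], na[["ms"]], na[["arsacs"]]))
  n <- length(ids)
  age <- numeric(n)
  age[group == "intact"] <- round(stats::runif(n_int, 25, 75), 1)
  age[group == "stroke"] <- round(stats::runif(sum(group == "stroke"), 40, 80), 1)
  age[group == "ms"] <- round(stats::runif(sum(group == "ms"), 30, 65), 1)
  age[group == "arsacs"] <- round(stats::runif(sum(group == "arsacs"), 26, 58))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  dominant <- sample(c("right", "left"), n, replace = TRUE, prob = c(0.88, 0.12))
  stereo <- stats::runif(n) < 0.10
  fma <- ifelse(group == "stroke", sample_skewed_score(n, 35, 66, 57), NA)
  arat <- ifelse(group == "ms", sample_skewed_score(n, 22, 57, 52), NA)
  nhpt <- ifelse(group == "arsacs",
                 round(stats::rlnorm(n, log(43.5), 0.3), 1), NA)
  per_side <- do.call(rbind, lapply(c("left", "right"), function(s)
    data.frame(subject_id = ids, group = group, age = age, sex = sex,
               side = s, dominant_side_tested = dominant == s,
               stereo_deficit = stereo, fma_ue = fma, arat = arat,
               nhpt = nhpt, stringsAsFactors = FALSE)))
  per_side[order(per_side$subject_id, per_side$side), ]
}

#' Generate a synthetic cohort with known ground truth
#'
#' Intact metric values are drawn from the confound model's generative form
#' in transformed space (fixed demographic effects + subject random
#' intercept + stable subject-x-side component + session noise), the retest
#' session adds the planted mean shift (learning) and noise sized so the
#' agreement ICC of the aggregated test-retest values equals `true_icc`,
#' affected subjects are shifted in the "worse" direction by the amount that
#' yields `true_auc` under the binormal identity `AUC = Phi(delta / (sqrt(2)
#' sigma))`, values are mapped to the raw scale through the inverse Box-Cox
#' exponent of each spec, and the pure-noise control metric is drawn
#' log-normal independently per subject, side and session.
#'
#' @param config A [cohort_config()].
#' @return List `subjects`, `observations` (per-trial rows), `ground_truth`
#'   (per metric: planted parameters), `config`.
#' @export
gen_cohort <- function(config = cohort_config()) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  subjects <- gen_subjects(config)
  units <- subjects  # one row per subject x side
  subj_ids <- unique(subjects$subject_id)
  retest_ids <- subjects$subject_id %in%
    sprintf("HC%03d", seq_len(config$n_retest))
  n_units <- nrow(units)
  obs <- list()
  truth <- list()
  reps <- config$n_repetitions
  pegs <- config$n_pegs
  n_trials <- reps * pegs
  trial_grid <- expand.grid(repetition = seq_len(reps), peg = seq_len(pegs))
  for (ms in config$metrics) {
    Xc <- covariate_matrix(units)
    fixed <- ms$betas[["intercept"]] + drop(Xc %*% ms$betas[-1])
    W <- stats::rnorm(length(subj_ids), 0, ms$sigma_subject)
    names(W) <- subj_ids
    U <- stats::rnorm(n_units, 0, ms$sigma_unit)
    sigma_b2 <- ms$sigma_subject^2 + ms$sigma_unit^2
    delta <- ms$session_shift
    sigma_e2 <- if (!is.null(ms$true_icc) && ms$true_icc > 0)
      max(0.01, 2 * sigma_b2 * (1 - ms$true_icc) / ms$true_icc - delta^2 / 2)
    else 1
    sgn <- if (ms$worse_direction == "higher_is_worse") 1 else -1
    shift_aff <- if (!is.null(ms$true_auc))
      sgn * sqrt(2 * (sigma_b2 + sigma_e2)) * stats::qnorm(ms$true_auc) else 0
    base <- fixed + W[units$subject_id] + U
    aff <- units$group != "intact"
    cell_test <- base + (aff * shift_aff) + stats::rnorm(n_units, 0, sqrt(sigma_e2))
    cell_retest <- base + delta + stats::rnorm(n_units, 0, sqrt(sigma_e2))
    sessions <- list(test = cell_test)
    for (k in names(sessions)) {
      take <- rep(TRUE, n_units)
      vals <- sessions[[k]]
      trial <- rep(vals[take], each = n_trials) +
        stats::rnorm(sum(take) * n_trials, 0, ms$trial_sd)
      raw <- boxcox_unapply(trial, ms$lambda)
      obs[[length(obs) + 1L]] <- data.frame(
        subject_id = rep(units$subject_id[take], each = n_trials),
        side = rep(units$side[take], each = n_trials),
        session = k,
        repetition = rep(trial_grid$repetition, sum(take)),
        peg = rep(trial_grid$peg, sum(take)),
        metric_name = ms$name, value = raw, stringsAsFactors = FALSE)
    }
    if (any(retest_ids)) {
      take <- retest_ids
      trial <- rep(cell_retest[take], each = n_trials) +
        stats::rnorm(sum(take) * n_trials, 0, ms$trial_sd)
      raw <- boxcox_unapply(trial, ms$lambda)
      obs[[length(obs) + 1L]] <- data.frame(
        subject_id = rep(units$subject_id[take], each = n_trials),
        side = rep(units$side[take], each = n_trials),
        session = "retest",
        repetition = rep(trial_grid$repetition, sum(take)),
        peg = rep(trial_grid$peg, sum(take)),
        metric_name = ms$name, value = raw, stringsAsFactors = FALSE)
    }
    truth[[ms$name]] <- list(lambda = ms$lambda, betas = ms$betas,
                             sigma_subject = ms$sigma_subject,
                             sigma_unit = ms$sigma_unit,
                             sigma_session = sqrt(sigma_e2),
                             session_shift = delta,
                             affected_shift = shift_aff,
                             true_icc = ms$true_icc, true_auc = ms$true_auc,
                             worse_direction = ms$worse_direction)
  }
  if (!is.null(config$noise_metric)) {
    nm <- config$noise_metric
    s2 <- log(1 + (nm$sd / nm$mean)^2)
    mu <- log(nm$mean) - s2 / 2
    draw_sessions <- list(test = rep(TRUE, n_units), retest = retest_ids)
    for (k in names(draw_sessions)) {
      take <- draw_sessions[[k]]
      if (!any(take)) next
      vals <- stats::rlnorm(sum(take), mu, sqrt(s2))
      obs[[length(obs) + 1L]] <- data.frame(
        subject_id = rep(units$subject_id[take], each = n_trials),
        side = rep(units$side[take], each = n_trials),
        session = k,
        repetition = rep(trial_grid$repetition, sum(take)),
        peg = rep(trial_grid$peg, sum(take)),
        metric_name = "simulated_noise",
        value = rep(vals, each = n_trials), stringsAsFactors = FALSE)
    }
    truth[["simulated_noise"]] <- list(meanlog = mu, sdlog = sqrt(s2),
                                       mean = nm$mean, sd = nm$sd,
                                       worse_direction = "higher_is_worse")
  }
  observations <- do.call(rbind, obs)
  rownames(observations) <- NULL
  list(subjects = subjects, observations = observations,
       ground_truth = truth, config = config)
}

#' Metric descriptors for a generated cohort
#'
#' @param cohort Output of [gen_cohort()].
#' @return Named list of [metric_descriptor()] for every generated metric.
#' @export
cohort_descriptors <- function(cohort) {
  out <- lapply(names(cohort$ground_truth), function(nm) {
    wd <- cohort$ground_truth[[nm]]$worse_direction
    fam <- if (nm == "simulated_noise") "control" else "overall"
    metric_descriptor(nm, family = fam, phase = "whole_trial",
                      worse_direction = wd)
  })
  names(out) <- names(cohort$ground_truth)
  out
}

# ---- scripted recordings ---------------------------------------------------

minjerk_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# 10%-of-peak speed crossings of a minimum-jerk segment, as fractions of its
# duration: 16 tau^2 (1-tau)^2 = 0.1.
MJ_BALLISTIC <- {
  tau0 <- (1 - sqrt(1 - 4 * sqrt(0.1 / 16))) / 2
  c(tau0, 1 - tau0)
}

# logistic force profile: 10%-of-peak force-rate half-width in units of the
# sigmoid scale s (solve 4q/(1+q)^2 = 0.1)
LOGISTIC_RATE10 <- log(19 + sqrt(360))

#' Default nine-peg board geometry
#'
#' A 3 x 3 peg matrix and its corresponding holes on a horizontal board,
#' with the 3 mm alignment tolerance and the 2 N grasp threshold.
#'
#' @return Geometry list for [recording()].
#' @export
default_board <- function() {
  gx <- c(-0.08, 0, 0.08)
  gy <- c(0.02, 0.06, 0.10)
  pegs <- as.matrix(expand.grid(x = gx - 0.05, y = gy, z = 0.02))
  holes <- as.matrix(expand.grid(x = gx + 0.05, y = gy, z = 0.02))
  dimnames(pegs) <- dimnames(holes) <- NULL
  list(pegs = pegs, holes = holes, tolerance = 0.003, force_threshold = 2)
}

#' Generate a scripted synthetic recording with ground-truth phases
#'
#' Builds a pick-and-place trial from minimum-jerk segments between
#' waypoints, logistic grip-force profiles crossing the 2 N threshold at
#' analytically known times, optional superimposed submovements (to degrade
#' smoothness), optional mid-transport force dips below 2 N (scripted peg
#' drops), and optional measurement noise. The exact phase intervals implied
#' by the same definitions the segmentation uses (10 percent-of-peak speed
#' crossings for ballistic phases, 10 percent-of-peak force-rate intervals
#' for buildup/release) are returned as ground truth.
#'
#' @param pegs Which pegs to transfer (default `1:9`).
#' @param geometry Board geometry (default [default_board()]).
#' @param t_reach,t_transport,t_dwell Segment durations (s).
#' @param fmax Peak grasp force (N); baseline is 0.3 N.
#' @param sigmoid_scale Force sigmoid time scale (s).
#' @param submovement `NULL`, or `list(peg, amplitude, at)`: an extra
#'   minimum-jerk displacement bump (m) superimposed mid-transport.
#' @param drops `NULL`, or integer vector of pegs that suffer one
#'   mid-transport force dip below the threshold.
#' @param pos_noise_sd,force_noise_sd Gaussian measurement noise (m, N).
#' @param fs Sample rate (Hz).
#' @param seed Seed for the noise.
#' @return List `recording` and `truth` (data frame `peg, phase, start_time,
#'   end_time` in seconds).
#' @export
gen_recording <- function(pegs = 1:9, geometry = default_board(),
                          t_reach = 0.8, t_transport = 1.0, t_dwell = 0.5,
                          fmax = 5, sigmoid_scale = 0.03,
                          submovement = NULL, drops = NULL,
                          pos_noise_sd = 0, force_noise_sd = 0,
                          fs = 1000, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  fb <- 0.3
  fthr <- geometry$force_threshold
  u_cross <- -log((fmax - fthr) / (fthr - fb))   # pickup: c + u_cross * s
  lead <- 0.3
  tail <- 0.8
  total <- lead + length(pegs) * (t_reach + t_dwell + t_transport + t_dwell) + tail
  n <- round(total * fs) + 1L
  t <- (0:(n - 1)) / fs
  start_pos <- c(0, -0.06, 0.05)
  pos <- matrix(rep(start_pos, each = n), n, 3)
  force <- rep(fb, n)
  active <- integer(n)
  truth <- list()
  cursor <- start_pos
  tcur <- lead
  mj_segment <- function(from, to, t0, dur) {
    idx <- which(t >= t0 & t <= t0 + dur)
    tau <- (t[idx] - t0) / dur
    s <- minjerk_pos(tau)
    for (d in 1:3) pos[idx, d] <<- from[d] + (to[d] - from[d]) * s
    after <- t > t0 + dur
    for (d in 1:3) pos[after, d] <<- to[d]
  }
  add_logistic <- function(center, scale, rising) {
    u <- (t - center) / scale
    if (rising) force <<- pmax(force, fb + (fmax - fb) / (1 + exp(-u)))
    else {
      idx <- t >= center - 10 * scale
      force[idx] <<- pmin(force[idx], fb + (fmax - fb) / (1 + exp(u[idx])))
    }
  }
  for (p in pegs) {
    peg_xyz <- geometry$pegs[p, ]
    hole_xyz <- geometry$holes[p, ]
    # reach (return + peg approach)
    mj_segment(cursor, peg_xyz, tcur, t_reach)
    ret <- tcur + MJ_BALLISTIC * t_reach
    t_arrive <- tcur + t_reach
    c_up <- t_arrive + t_dwell / 2
    pickup <- c_up + u_cross * sigmoid_scale
    add_logistic(c_up, sigmoid_scale, rising = TRUE)
    truth[[length(truth) + 1L]] <- data.frame(
      peg = p, phase = c("return", "peg_approach", "buildup"),
      start_time = c(ret[1], ret[2], c_up - LOGISTIC_RATE10 * sigmoid_scale),
      end_time = c(ret[2], pickup, c_up + LOGISTIC_RATE10 * sigmoid_scale))
    # transport
    t_move <- t_arrive + t_dwell
    mj_segment(peg_xyz, hole_xyz, t_move, t_transport)
    tp <- t_move + MJ_BALLISTIC * t_transport
    t_hole <- t_move + t_transport
    c_dn <- t_hole + t_dwell / 2
    insertion <- c_dn + (-u_cross) * sigmoid_scale
    add_logistic(c_dn, sigmoid_scale, rising = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      peg = p, phase = c("transport", "hole_approach", "release"),
      start_time = c(tp[1], tp[2], c_dn - LOGISTIC_RATE10 * sigmoid_scale),
      end_time = c(tp[2], insertion, c_dn + LOGISTIC_RATE10 * sigmoid_scale))
    active[t >= pickup & t <= insertion] <- p
    if (p %in% drops) {
      dip_c <- t_move + 0.5 * t_transport
      force <- force - (fmax - 0.5) * exp(-((t - dip_c) / 0.06)^2)
      force <- pmax(force, 0)
    }
    if (!is.null(submovement) && submovement$peg == p) {
      at <- submovement$at %||% 0.55
      amp <- submovement$amplitude
      dur <- 0.25 * t_transport
      idx <- which(t >= t_move + at * t_transport &
                     t <= t_move + at * t_transport + dur)
      tau <- (t[idx] - t[idx[1]]) / dur
      dirv <- (hole_xyz - peg_xyz) / sqrt(sum((hole_xyz - peg_xyz)^2))
      bump <- amp * minjerk_pos(tau)
      for (d in 1:3) pos[idx, d] <- pos[idx, d] + dirv[d] * bump
    }
    cursor <- hole_xyz
    tcur <- t_hole + t_dwell
  }
  if (pos_noise_sd > 0) pos <- pos + stats::rnorm(length(pos), 0, pos_noise_sd)
  if (force_noise_sd > 0) force <- force + stats::rnorm(n, 0, force_noise_sd)
  rec <- recording(t, pos, force, active, geometry)
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  list(recording = rec, truth = truth_df)
}

#' Generate a units-x-metrics table with planted common-factor structure
#'
#' Draws orthogonal standard-normal factor scores and builds each metric as
#' `Lambda_j f + sqrt(1 - h_j^2) e`, so the population correlation matrix is
#' `Lambda Lambda' + Psi`. Used to validate the structural-analysis stage
#' (parallel analysis, KMO, promax factor recovery) against known truth.
#'
#' @param n Number of rows (subject x side units).
#' @param loadings metrics x k loading matrix (rownames become metric
#'   names); communalities must not exceed 1.
#' @param seed Integer seed.
#' @return Numeric matrix n x metrics.
#' @export
gen_factor_table <- function(n, loadings, seed = 1L) {
  loadings <- as.matrix(loadings)
  if (any(rowSums(loadings^2) > 1))
    stop("communalities exceed 1", call. = FALSE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  k <- ncol(loadings)
  m <- nrow(loadings)
  FS <- matrix(stats::rnorm(n * k), n, k)
  E <- matrix(stats::rnorm(n * m), n, m)
  X <- FS %*% t(loadings) + E %*% diag(sqrt(1 - rowSums(loadings^2)), m)
  colnames(X) <- rownames(loadings) %||% paste0("metric_", seq_len(m))
  X
}
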