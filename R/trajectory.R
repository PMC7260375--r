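#' Construct a raw pick-and-place recording
#'
#' Container for the raw signals of one trial: time (nominally 1 kHz),
#' 3-D cursor position in metres, grip force in newtons, the active-peg
#' indicator (0 = no peg lifted), and optionally a vertical interaction-force
#' channel for haptic-collision metrics. Board geometry carries the peg and
#' hole coordinates, the alignment tolerance radius (3 mm) and the 2 N grasp
#' force threshold.
#'
#' @param time Seconds, strictly increasing.
#' @param position n x 3 matrix (metres); board plane is horizontal x-y,
#'   vertical is z.
#' @param grip_force Newtons.
#' @param active_peg Integer peg indicator (0 = none).
#' @param geometry List with `pegs` (9 x 3), `holes` (9 x 3), `tolerance`
#'   (default 0.003 m), `force_threshold` (default 2 N).
#' @param vert_force Optional vertical interaction force (N).
#' @return Object of class `recording`.
#' @export
recording <- function(time, position, grip_force, active_peg, geometry,
                      vert_force = NULL) {
  position <- as.matrix(position)
  n <- length(time)
  stopifnot(nrow(position) == n, length(grip_force) == n,
            length(active_peg) == n, ncol(position) == 3L)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  fs <- 1 / stats::median(diff(time))
  if (fs < 100 || fs > 2000)
    stop("sample rate outside [100, 2000] Hz", call. = FALSE)
  if (is.null(geometry$tolerance)) geometry$tolerance <- 0.003
  if (is.null(geometry$force_threshold)) geometry$force_threshold <- 2
  structure(list(time = time, position = position, grip_force = grip_force,
                 active_peg = as.integer(active_peg), vert_force = vert_force,
                 geometry = geometry, fs = fs),
            class = "recording")
}

#' Read / write a recording as delimited text
#'
#' Signal file columns: `t,x,y,z,grip_force,active_peg` (optional
#' `vert_force`). The geometry sidecar is YAML with `pegs`, `holes`
#' (lists of xyz triples), `tolerance`, `force_threshold`.
#'
#' @param signal_path CSV of the sampled signals.
#' @param geometry_path YAML geometry sidecar.
#' @return A `recording`.
#' @export
read_recording <- function(signal_path, geometry_path) {
  d <- utils::read.csv(signal_path)
  g <- yaml::read_yaml(geometry_path)
  geometry <- list(pegs = do.call(rbind, lapply(g$pegs, as.numeric)),
                   holes = do.call(rbind, lapply(g$holes, as.numeric)),
                   tolerance = g$tolerance %||% 0.003,
                   force_threshold = g$force_threshold %||% 2)
  recording(d$t, cbind(d$x, d$y, d$z), d$grip_force, d$active_peg, geometry,
            vert_force = d$vert_force)
}

#' @rdname read_recording
#' @param rec A `recording`.
#' @export
write_recording <- function(rec, signal_path, geometry_path) {
  df <- data.frame(t = rec$time, x = rec$position[, 1], y = rec$position[, 2],
                   z = rec$position[, 3], grip_force = rec$grip_force,
                   active_peg = rec$active_peg)
  if (!is.null(rec$vert_force)) df$vert_force <- rec$vert_force
  utils::write.csv(df, signal_path, row.names = FALSE)
  g <- rec$geometry
  yaml::write_yaml(list(pegs = lapply(seq_len(nrow(g$pegs)), function(i) as.numeric(g$pegs[i, ])),
                        holes = lapply(seq_len(nrow(g$holes)), function(i) as.numeric(g$holes[i, ])),
                        tolerance = g$tolerance, force_threshold = g$force_threshold),
                   geometry_path)
  invisible(c(signal_path, geometry_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lowpass8 <- function(x, fs, fc = 8, order = 4) {
  bf <- signal::butter(order, fc / (fs / 2))
  n <- length(x)
  # odd-reflection padding suppresses the zero-state startup transient
  pad <- min(n - 1L, ceiling(3 * fs / fc))
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  # filter deviations from the edge value so a constant signal is exact
  y <- as.numeric(signal::filtfilt(bf, xp - xp[1])) + xp[1]
  y[(pad + 1L):(pad + n)]
}

num_gradient <- function(x, dt) {
  n <- length(x)
  g <- numeric(n)
  if (n < 2L) return(g)
  g[1] <- (x[2] - x[1]) / dt
  g[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2L) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  g
}

interp_gaps <- function(time, x, fs, max_gap_samples = 50L) {
  # temporal gaps larger than max_gap_samples are bridged by linear
  # interpolation onto the uniform grid
  t0 <- seq(time[1], time[length(time)], by = 1 / fs)
  stats::approx(time, x, xout = t0, rule = 2)$y
}

#' Preprocess a recording: filtering and kinematic derivatives
#'
#' Temporal gaps are linearly interpolated onto a uniform grid, positions are
#' zero-phase low-pass filtered (4th-order Butterworth, 8 Hz cut-off), a 1-D
#' distance trajectory d(t) (cumulative path length) is built, and velocity,
#' acceleration and jerk are obtained by successive differentiation with the
#' same low-pass filter re-applied after every derivative. Grip force and its
#' rate receive the same treatment.
#'
#' @param rec A `recording` with at least 1 s of data.
#' @return List with `time`, filtered `position`, `d` (cumulative distance),
#'   `v` (speed), `a`, `j` (jerk), `force`, `force_rate`, `vert_force`, `fs`.
#' @export
preprocess <- function(rec) {
  fs <- rec$fs
  if (diff(range(rec$time)) < 1) stop("need at least 1 s of data", call. = FALSE)
  tgrid <- seq(rec$time[1], rec$time[length(rec$time)], by = 1 / fs)
  pos <- apply(rec$position, 2, function(col)
    lowpass8(interp_gaps(rec$time, col, fs), fs))
  step <- sqrt(rowSums(rbind(0, diff(pos))^2))
  d <- cumsum(step)
  dt <- 1 / fs
  v <- lowpass8(num_gradient(d, dt), fs)
  a <- lowpass8(num_gradient(v, dt), fs)
  j <- lowpass8(num_gradient(a, dt), fs)
  f <- lowpass8(interp_gaps(rec$time, rec$grip_force, fs), fs)
  fr <- lowpass8(num_gradient(f, dt), fs)
  vf <- if (!is.null(rec$vert_force))
    lowpass8(interp_gaps(rec$time, rec$vert_force, fs), fs) else NULL
  peg <- as.integer(round(stats::approx(rec$time, rec$active_peg, xout = tgrid,
                                        method = "constant", rule = 2)$y))
  list(time = tgrid, position = pos, d = d, v = v, a = a, j = j,
       force = f, force_rate = fr, vert_force = vf, active_peg = peg, fs = fs)
}

ballistic_bounds <- function(speed, idx, frac = 0.1) {
  # ballistic start/end: crossings of `frac` of the segment's peak speed
  s <- speed[idx]
  pk <- which.max(s)
  thr <- frac * s[pk]
  lo <- pk
  while (lo > 1L && s[lo - 1L] >= thr) lo <- lo - 1L
  hi <- pk
  while (hi < length(s) && s[hi + 1L] >= thr) hi <- hi + 1L
  c(idx[lo], idx[hi])
}

rate_extreme_interval <- function(rate, idx, sign = 1, frac = 0.1) {
  r <- sign * rate[idx]
  pk <- which.max(r)
  thr <- frac * r[pk]
  lo <- pk
  while (lo > 1L && r[lo - 1L] >= thr) lo <- lo - 1L
  hi <- pk
  while (hi < length(r) && r[hi + 1L] >= thr) hi <- hi + 1L
  c(idx[lo], idx[hi])
}

#' Segment a recording into task phases
#'
#' Per transported peg: `transport` (ballistic carry, bounded by crossings of
#' 10 percent of the carry's peak speed), `hole_approach` (end of transport
#' until insertion), `return` (ballistic move towards the next peg),
#' `peg_approach` (end of return until pickup), and the `buildup` / `release`
#' intervals around the maximum / minimum grip-force rate between approaching
#' and inserting the peg. Pickup and insertion are taken from the active-peg
#' indicator (grasp force crossing the 2 N threshold while aligned). Pegs
#' never picked up contribute no phases (they still count for the
#' number-of-movements metrics).
#'
#' @param rec A `recording`.
#' @param pre Optional [preprocess()] output (recomputed when `NULL`).
#' @return Data frame `peg, phase, start, end` (1-based sample indices,
#'   inclusive) of class `phase_segmentation`, with attribute `fs`.
#' @export
segment_phases <- function(rec, pre = NULL) {
  if (is.null(pre)) pre <- preprocess(rec)
  peg_sig <- pre$active_peg
  n <- length(peg_sig)
  pegs <- unique(peg_sig[peg_sig > 0L])
  rows <- list()
  prev_insert <- 1L
  for (p in pegs) {
    span <- range(which(peg_sig == p))
    pickup <- span[1]
    insert <- span[2]
    carry <- pickup:insert
    if (length(carry) >= 10L && max(pre$v[carry]) > 0) {
      tb <- ballistic_bounds(pre$v, carry)
      rows[[length(rows) + 1L]] <- data.frame(peg = p, phase = "transport",
                                              start = tb[1], end = tb[2])
      rows[[length(rows) + 1L]] <- data.frame(peg = p, phase = "hole_approach",
                                              start = tb[2], end = insert)
    }
    appr <- prev_insert:pickup
    if (length(appr) >= 10L && max(pre$v[appr]) > 0) {
      rb <- ballistic_bounds(pre$v, appr)
      rows[[length(rows) + 1L]] <- data.frame(peg = p, phase = "return",
                                              start = rb[1], end = rb[2])
      rows[[length(rows) + 1L]] <- data.frame(peg = p, phase = "peg_approach",
                                              start = rb[2], end = pickup)
    }
    bu_win <- max(prev_insert, pickup - as.integer(2 * pre$fs)):
      min(insert, pickup + as.integer(0.5 * pre$fs))
    bu <- rate_extreme_interval(pre$force_rate, bu_win, sign = 1)
    rows[[length(rows) + 1L]] <- data.frame(peg = p, phase = "buildup",
                                            start = bu[1], end = bu[2])
    rel_win <- max(pickup, insert - as.integer(0.5 * pre$fs)):
      min(n, insert + as.integer(1 * pre$fs))
    rel <- rate_extreme_interval(pre$force_rate, rel_win, sign = -1)
    rows[[length(rows) + 1L]] <- data.frame(peg = p, phase = "release",
                                            start = rel[1], end = rel[2])
    prev_insert <- insert
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peg = integer(), phase = character(), start = integer(),
               end = integer())
  class(out) <- c("phase_segmentation", "data.frame")
  attr(out, "fs") <- pre$fs
  out
}

#' Spectral arc length (SPARC) smoothness of a signal
#'
#' Negated arc length of the normalized magnitude spectrum of the signal
#' (typically the speed profile), restricted to the adaptive frequency band
#' below `fc` where the normalized magnitude exceeds `amp_threshold`. Always
#' <= 0; more submovements make it strictly more negative.
#'
#' @param x Signal segment (e.g. speed).
#' @param fs Sample rate (Hz).
#' @param fc Maximum frequency (default 20 Hz).
#' @param amp_threshold Normalized amplitude threshold (default 0.05).
#' @param padlevel Zero-padding exponent (default 4).
#' @return SPARC value (<= 0).
#' @export
sparc <- function(x, fs, fc = 20, amp_threshold = 0.05, padlevel = 4) {
  nfft <- 2^(ceiling(log2(length(x))) + padlevel)
  f <- (0:(nfft - 1)) * fs / nfft
  Mf <- abs(stats::fft(c(x, rep(0, nfft - length(x)))))
  sel <- f <= fc
  f_sel <- f[sel]
  M_sel <- Mf[sel] / max(Mf[sel])
  inx <- which(M_sel >= amp_threshold)
  band <- seq_len(max(inx))
  f_b <- f_sel[band]
  M_b <- M_sel[band]
  -sum(sqrt((diff(f_b) / (f_b[length(f_b)] - f_b[1]))^2 + diff(M_b)^2))
}

#' Dimensionless jerk and log jerk of a movement segment
#'
#' Time-integrated squared jerk normalized by movement duration and length:
#' `DJ = int j(t)^2 dt * T^5 / L^2`. An ideal minimum-jerk point-to-point
#' movement attains the minimum value 720 regardless of duration or
#' amplitude; submovements strictly increase it. `log_jerk` is its natural
#' logarithm.
#'
#' @param jerk Jerk signal over the segment (third derivative of the 1-D
#'   distance trajectory).
#' @param fs Sample rate (Hz).
#' @param length_covered Distance covered in the segment (m).
#' @return Dimensionless jerk (positive, higher = less smooth).
#' @export
dimensionless_jerk <- function(jerk, fs, length_covered) {
  if (length_covered <= 0) return(NA_real_)
  n <- length(jerk)
  duration <- (n - 1) / fs
  integral <- sum((jerk[-1]^2 + jerk[-n]^2) / 2) / fs
  integral * duration^5 / length_covered^2
}

#' @rdname dimensionless_jerk
#' @export
log_jerk <- function(jerk, fs, length_covered)
  log(dimensionless_jerk(jerk, fs, length_covered))

# Local maxima with a minimum topographic prominence.
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- x[i]
    lm <- h
    jx <- i
    while (jx > 1L && x[jx] <= h) { jx <- jx - 1L; lm <- min(lm, x[jx]) }
    rm <- h
    jx <- i
    while (jx < n && x[jx] <= h) { jx <- jx + 1L; rm <- min(rm, x[jx]) }
    keep[k] <- (h - max(lm, rm)) >= min_prominence
  }
  cand[keep]
}

count_velocity_peaks <- function(speed, prominence_frac = 0.05) {
  length(find_peaks(speed, prominence_frac * max(speed)))
}

count_rate_extrema <- function(rate, prominence_frac = 0.05) {
  pr <- prominence_frac * max(abs(rate))
  length(find_peaks(rate, pr)) + length(find_peaks(-rate, pr))
}

dist_xy <- function(p, q) sqrt(sum((p[1:2] - q[1:2])^2))

point_line_dist_xy <- function(pts, a, b) {
  # distance of each row of pts to segment-line a->b, horizontal plane
  ab <- b[1:2] - a[1:2]
  L2 <- sum(ab^2)
  if (L2 == 0) return(sqrt(rowSums(sweep(pts[, 1:2, drop = FALSE], 2, a[1:2])^2)))
  rel <- sweep(pts[, 1:2, drop = FALSE], 2, a[1:2])
  cross <- rel[, 1] * ab[2] - rel[, 2] * ab[1]
  abs(cross) / sqrt(L2)
}

angle_deg_xy <- function(u, w) {
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) return(NA_real_)
  acos(pmin(1, pmax(-1, sum(u * w) / (nu * nw)))) * 180 / pi
}

seg_idx <- function(seg, p, ph) {
  r <- seg[seg$peg == p & seg$phase == ph, , drop = FALSE]
  if (nrow(r) == 0L) return(NULL)
  r$start[1]:r$end[1]
}

#' Kinematic metrics for one peg transfer
#'
#' Computes, from the preprocessed signals and the phase segmentation, the
#' smoothness (dimensionless jerk, log jerk, SPARC, velocity-peak count,
#' time/distance-to-peak-speed fractions), efficiency (path length ratio =
#' shortest / covered distance, throughput (D/W)/T), curvature (mean/max
#' trajectory error and initial movement angles theta1-3 in the horizontal
#' plane), speed (mean/max), endpoint error (summed horizontal position
#' error, approach-phase jerk metrics) and, when a vertical interaction-force
#' channel is present, haptic-collision metrics.
#'
#' @param pre [preprocess()] output.
#' @param seg [segment_phases()] output.
#' @param geometry Board geometry (see [recording()]).
#' @param peg Peg number.
#' @param shannon_throughput Use the Shannon formulation `log2(D/W + 1) / T`
#'   instead of the literal `(D/W) / T` (default `FALSE`).
#' @return Named list of metric values for that transfer (units: s, m/s, N,
#'   N/s, dimensionless); metrics whose phase is missing are `NA`.
#' @export
kinematic_metrics <- function(pre, seg, geometry, peg,
                              shannon_throughput = FALSE) {
  out <- list()
  fs <- pre$fs
  W <- 2 * geometry$tolerance
  smooth_block <- function(idx, suffix) {
    res <- list()
    if (is.null(idx) || length(idx) < 10L) {
      nm <- paste0(c("jerk_", "log_jerk_", "sparc_", "num_velocity_peaks_",
                     "dist_to_max_velocity_", "time_to_max_velocity_",
                     "velocity_mean_", "velocity_max_"), suffix)
      res[nm] <- NA_real_
      return(res)
    }
    L <- pre$d[idx[length(idx)]] - pre$d[idx[1]]
    res[[paste0("jerk_", suffix)]] <- dimensionless_jerk(pre$j[idx], fs, L)
    res[[paste0("log_jerk_", suffix)]] <- log_jerk(pre$j[idx], fs, L)
    res[[paste0("sparc_", suffix)]] <- sparc(pre$v[idx], fs)
    res[[paste0("num_velocity_peaks_", suffix)]] <- count_velocity_peaks(pre$v[idx])
    pk <- which.max(pre$v[idx])
    res[[paste0("dist_to_max_velocity_", suffix)]] <-
      if (L > 0) (pre$d[idx[pk]] - pre$d[idx[1]]) / L else NA_real_
    res[[paste0("time_to_max_velocity_", suffix)]] <- (pk - 1) / (length(idx) - 1)
    res[[paste0("velocity_mean_", suffix)]] <- mean(pre$v[idx])
    res[[paste0("velocity_max_", suffix)]] <- max(pre$v[idx])
    res
  }
  curv_block <- function(idx, target, suffix) {
    res <- list()
    nm <- paste0(c("trajectory_error_mean_", "trajectory_error_max_",
                   "initial_mov_angle_t1_", "initial_mov_angle_t2_",
                   "initial_mov_angle_t3_"), suffix)
    if (is.null(idx) || length(idx) < 10L) { res[nm] <- NA_real_; return(res) }
    P <- pre$position[idx, , drop = FALSE]
    a <- P[1, ]; b <- P[nrow(P), ]
    errs <- point_line_dist_xy(P, a, b)
    res[[nm[1]]] <- mean(errs)
    res[[nm[2]]] <- max(errs)
    Ds <- dist_xy(a, target)
    w <- target[1:2] - a[1:2]
    disp <- sqrt(rowSums(sweep(P[, 1:2, drop = FALSE], 2, a[1:2])^2))
    i1 <- which(disp >= 0.2 * Ds)[1]
    covered <- pre$d[idx] - pre$d[idx[1]]
    i2 <- which(covered >= 0.2 * covered[length(covered)])[1]
    i3 <- which.max(pre$v[idx])
    ang <- function(i) if (is.na(i)) NA_real_ else
      angle_deg_xy(P[i, 1:2] - a[1:2], w)
    res[[nm[3]]] <- ang(i1)
    res[[nm[4]]] <- ang(i2)
    res[[nm[5]]] <- ang(i3)
    res
  }
  eff_block <- function(idx, suffix) {
    res <- list()
    nm <- paste0(c("path_length_ratio_", "throughput_"), suffix)
    if (is.null(idx) || length(idx) < 10L) { res[nm] <- NA_real_; return(res) }
    P <- pre$position[idx, , drop = FALSE]
    shortest <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
    covered <- pre$d[idx[length(idx)]] - pre$d[idx[1]]
    res[[nm[1]]] <- if (covered > 0) shortest / covered else NA_real_
    Tdur <- (length(idx) - 1) / fs
    ratio <- shortest / W
    res[[nm[2]]] <- if (shannon_throughput) log2(ratio + 1) / Tdur else ratio / Tdur
    res
  }
  haptic_block <- function(idx, suffix) {
    res <- list()
    nm <- paste0(c("haptic_collisions_mean_", "haptic_collisions_max_"), suffix)
    if (is.null(pre$vert_force) || is.null(idx)) { res[nm] <- NA_real_; return(res) }
    res[[nm[1]]] <- mean(abs(pre$vert_force[idx]))
    res[[nm[2]]] <- max(abs(pre$vert_force[idx]))
    res
  }
  endpoint_block <- function(idx, target, suffix) {
    res <- list()
    nm <- paste0(c("position_error_", "jerk_", "log_jerk_", "sparc_"), suffix)
    if (is.null(idx) || length(idx) < 10L) { res[nm] <- NA_real_; return(res) }
    P <- pre$position[idx, , drop = FALSE]
    res[[nm[1]]] <- sum(sqrt((P[, 1] - target[1])^2 + (P[, 2] - target[2])^2))
    L <- pre$d[idx[length(idx)]] - pre$d[idx[1]]
    res[[nm[2]]] <- dimensionless_jerk(pre$j[idx], fs, L)
    res[[nm[3]]] <- log_jerk(pre$j[idx], fs, L)
    res[[nm[4]]] <- sparc(pre$v[idx], fs)
    res
  }
  i_tp <- seg_idx(seg, peg, "transport")
  i_rt <- seg_idx(seg, peg, "return")
  i_pa <- seg_idx(seg, peg, "peg_approach")
  i_ha <- seg_idx(seg, peg, "hole_approach")
  hole <- geometry$holes[peg, ]
  pegpos <- geometry$pegs[peg, ]
  out <- c(out, smooth_block(i_tp, "tp"), smooth_block(i_rt, "rt"))
  out <- c(out, curv_block(i_tp, hole, "tp"), curv_block(i_rt, pegpos, "rt"))
  # efficiency spans ballistic movement plus the endpoint correction
  i_tp_full <- if (!is.null(i_tp) && !is.null(i_ha)) i_tp[1]:i_ha[length(i_ha)] else i_tp
  i_rt_full <- if (!is.null(i_rt) && !is.null(i_pa)) i_rt[1]:i_pa[length(i_pa)] else i_rt
  out <- c(out, eff_block(i_tp_full, "tp"), eff_block(i_rt_full, "rt"))
  out <- c(out, endpoint_block(i_pa, pegpos, "peg_approach"),
           endpoint_block(i_ha, hole, "hole_approach"))
  out <- c(out, haptic_block(i_tp, "tp"), haptic_block(i_rt, "rt"))
  out
}

#' Kinetic (grip force) metrics for one peg transfer
#'
#' Grip-force scaling (mean/max force, mean-absolute/max-absolute force
#' rate) on transport, return and the two approach phases; grip-force
#' coordination (signed force-rate extrema count, force-rate SPARC) on those
#' phases plus buildup and release; buildup/release durations; and the
#' dropped-peg count (downward 2 N crossings while the peg is lifted,
#' excluding the final insertion release).
#'
#' @inheritParams kinematic_metrics
#' @return Named list of metric values.
#' @export
kinetic_metrics <- function(pre, seg, geometry, peg) {
  out <- list()
  fs <- pre$fs
  scaling_block <- function(idx, suffix) {
    res <- list()
    nm <- paste0(c("gf_mean_", "gf_max_", "gf_rate_mean_", "gf_rate_max_"), suffix)
    if (is.null(idx)) { res[nm] <- NA_real_; return(res) }
    res[[nm[1]]] <- mean(pre$force[idx])
    res[[nm[2]]] <- max(pre$force[idx])
    res[[nm[3]]] <- mean(abs(pre$force_rate[idx]))
    res[[nm[4]]] <- max(abs(pre$force_rate[idx]))
    res
  }
  coord_block <- function(idx, suffix) {
    res <- list()
    nm <- paste0(c("gf_rate_num_peaks_", "gf_rate_sparc_"), suffix)
    if (is.null(idx) || length(idx) < 10L) { res[nm] <- NA_real_; return(res) }
    res[[nm[1]]] <- count_rate_extrema(pre$force_rate[idx])
    res[[nm[2]]] <- sparc(abs(pre$force_rate[idx]), fs)
    res
  }
  i_tp <- seg_idx(seg, peg, "transport")
  i_rt <- seg_idx(seg, peg, "return")
  i_pa <- seg_idx(seg, peg, "peg_approach")
  i_ha <- seg_idx(seg, peg, "hole_approach")
  i_bu <- seg_idx(seg, peg, "buildup")
  i_re <- seg_idx(seg, peg, "release")
  out <- c(out,
           scaling_block(i_tp, "tp"), scaling_block(i_rt, "rt"),
           scaling_block(i_pa, "peg_approach"), scaling_block(i_ha, "hole_approach"),
           coord_block(i_tp, "tp"), coord_block(i_rt, "rt"),
           coord_block(i_pa, "peg_approach"), coord_block(i_ha, "hole_approach"),
           coord_block(i_bu, "buildup"), coord_block(i_re, "release"))
  out$gf_buildup_duration <- if (is.null(i_bu)) NA_real_ else
    (length(i_bu) - 1) / fs
  out$gf_release_duration <- if (is.null(i_re)) NA_real_ else
    (length(i_re) - 1) / fs
  # dropped pegs: grasp force dips below threshold while the peg is lifted
  lift <- which(pre$active_peg == peg)
  out$dropped_pegs <- if (length(lift) < 2L) 0L else {
    f <- pre$force[lift]
    thr <- geometry$force_threshold
    below <- f < thr
    # a drop is a dip below threshold that recovers while still lifting;
    # the final release at insertion never recovers and is not counted
    down <- which(!below[-length(f)] & below[-1])
    sum(vapply(down, function(k) any(!below[(k + 1):length(f)]), TRUE))
  }
  out
}

#' Extract per-trial metric observations from a recording
#'
#' Runs [preprocess()], [segment_phases()], [kinematic_metrics()] and
#' [kinetic_metrics()] for every transported peg and emits long-format rows
#' compatible with [aggregate_trials()]. Trial-level metrics (movement
#' onset/end counts, task completion time, dropped pegs summed over pegs)
#' are attached to peg 0.
#'
#' @param rec A `recording`.
#' @param subject_id,side,session,repetition Observation key fields.
#' @return Data frame of metric observations.
#' @export
extract_observations <- function(rec, subject_id = "s1", side = "right",
                                 session = "test", repetition = 1L) {
  pre <- preprocess(rec)
  seg <- segment_phases(rec, pre)
  pegs <- sort(unique(seg$peg))
  rows <- list()
  add <- function(metric, value, peg) {
    if (is.null(value) || is.na(value)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject_id, side = side, session = session,
      repetition = repetition, peg = peg, metric_name = metric,
      value = as.numeric(value), stringsAsFactors = FALSE)
  }
  dropped_total <- 0L
  for (p in pegs) {
    km <- kinematic_metrics(pre, seg, rec$geometry, p)
    kn <- kinetic_metrics(pre, seg, rec$geometry, p)
    dropped_total <- dropped_total + (kn$dropped_pegs %||% 0L)
    kn$dropped_pegs <- NULL
    for (m in names(km)) add(m, km[[m]], p)
    for (m in names(kn)) add(m, kn[[m]], p)
  }
  add("number_of_mov_onsets",
      sum(seg$phase %in% c("transport", "return")), 0L)
  add("number_of_mov_ends",
      sum(seg$phase %in% c("transport", "return")), 0L)
  add("number_of_dropped_pegs", dropped_total, 0L)
  tp_rows <- seg[seg$phase == "transport", , drop = FALSE]
  ha_rows <- seg[seg$phase == "hole_approach", , drop = FALSE]
  if (nrow(tp_rows) && nrow(ha_rows))
    add("task_completion_time",
        (max(ha_rows$end) - min(tp_rows$start)) / pre$fs, 0L)
  do.call(rbind, rows)
}
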