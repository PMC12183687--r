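# Stream synchronization and event-aligned trial averaging.

#' Synchronize two acquisition clocks via shared event codes
#'
#' The FSCV and EPhys systems each timestamp the same trial-start event
#' codes on their own clocks. Matching the k-th occurrence of each code
#' across streams gives paired timestamps; a least-squares linear map
#' (slope and offset) from clock A to clock B is fit over the pairs.
#'
#' @param codes_a,codes_b `data.frame`s with `time_s` and `code` columns
#'   (or numeric timestamp vectors, matched in order).
#' @param rms_tol residual RMS (s) above which a warning is raised.
#' @return An object of class `clock_map`: `slope`, `offset` (s),
#'   `residual_rms` (s), `n_matched`.
#' @export
sync_streams <- function(codes_a, codes_b, rms_tol = 0.005) {
  pair <- function(a, b) {
    if (is.numeric(a) && is.numeric(b)) {
      n <- min(length(a), length(b))
      return(cbind(a[seq_len(n)], b[seq_len(n)]))
    }
    out <- NULL
    for (code in intersect(unique(a$code), unique(b$code))) {
      ta <- sort(a$time_s[a$code == code])
      tb <- sort(b$time_s[b$code == code])
      n <- min(length(ta), length(tb))
      out <- rbind(out, cbind(ta[seq_len(n)], tb[seq_len(n)]))
    }
    out
  }
  m <- pair(codes_a, codes_b)
  if (is.null(m) || nrow(m) < 2) {
    stop_with("validation_error", "need at least 2 matching event codes")
  }
  fit <- stats::lm.fit(cbind(1, m[, 1]), m[, 2])
  rms <- sqrt(mean(fit$residuals^2))
  if (rms > rms_tol) {
    warning(sprintf("clock-map residual RMS %.4g s exceeds %.4g s",
                    rms, rms_tol))
  }
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope <= 0) {
    stop_with("validation_error", "degenerate clock map (slope <= 0)")
  }
  structure(list(slope = slope, offset = unname(fit$coefficients[1]),
                 residual_rms = rms, n_matched = nrow(m)),
            class = "clock_map")
}

#' Map times through (or back through) a clock map
#'
#' @param map a `clock_map`.
#' @param t times on clock A (s).
#' @param inverse map from clock B back to clock A.
#' @return Mapped times (s).
#' @export
map_time <- function(map, t, inverse = FALSE) {
  if (inverse) (t - map$offset) / map$slope else map$offset + map$slope * t
}

#' @export
print.clock_map <- function(x, ...) {
  cat(sprintf(
    "Clock map: b = %.8g * a + %.6g s (%d codes, residual RMS %.3g s)\n",
    x$slope, x$offset, x$n_matched, x$residual_rms))
  invisible(x)
}

# Pull (time, values) out of the containers that can be epoch-averaged.
series_values <- function(series, analyte = "dopamine") {
  if (inherits(series, "chem_trace")) {
    list(time_s = series$time_s, values = series$conc[, analyte])
  } else if (inherits(series, "beta_envelope")) {
    list(time_s = series$time_s, values = series$power)
  } else if (is.list(series) && !is.null(series$time_s)) {
    list(time_s = series$time_s,
         values = series$values %||% series$power)
  } else {
    stop_with("validation_error",
              "series must be a chem_trace, beta_envelope, or time/values list")
  }
}

#' Event-aligned, condition-split trial average
#'
#' Extracts an epoch around every event on the series' native time grid
#' (10 Hz frames for chemistry, 1 kHz for beta envelopes; no
#' cross-interpolation between modalities) and averages across trials per
#' condition. Null-masked (NA) points are excluded pointwise from both the
#' mean and the standard error; the standard error is sample SD / sqrt(n)
#' with n the non-null trial count at that point (reported as 0, flagged,
#' for single-trial conditions). Epochs extending beyond the recording are
#' dropped and counted.
#'
#' @param series a `chem_trace`, `beta_envelope`, or list with `time_s`
#'   and `values`.
#' @param event_times alignment event times (s) on the series clock.
#' @param window epoch window (s) relative to the event, spanning it.
#' @param condition_labels optional per-event labels; `NULL` pools into
#'   `"all"`.
#' @param analyte which `chem_trace` column to average (default dopamine).
#' @param baseline per-trial baseline handling: `"none"`, `"subtract"`
#'   (e.g. re-reference each chemistry epoch to its own value-cue frame) or
#'   `"divide"` (e.g. normalize beta power to the pre-cue level). Trials
#'   whose baseline is entirely null are dropped.
#' @param baseline_window window (s, relative to the event) averaged for
#'   the baseline; defaults to the event frame `c(0, 0)` for `"subtract"`
#'   and the pre-event half of `window` for `"divide"`.
#' @return An object of class `trial_average`: `time_s` (aligned grid),
#'   `mean` and `se` (condition x time), `n_trials`, `n_points` (non-null
#'   trial count per point), `n_dropped`, `null_fraction` per condition.
#' @export
epoch_and_average <- function(series, event_times, window = c(-2, 4),
                              condition_labels = NULL,
                              analyte = "dopamine",
                              baseline = c("none", "subtract", "divide"),
                              baseline_window = NULL) {
  baseline <- match.arg(baseline)
  sv <- series_values(series, analyte)
  tt <- sv$time_s
  vv <- sv$values
  dt <- stats::median(diff(tt))
  k0 <- as.integer(round(window[1] / dt))
  k1 <- as.integer(round(window[2] / dt))
  if (k0 > 0 || k1 < 0) {
    stop_with("validation_error", "window must span the event")
  }
  grid <- (k0:k1) * dt
  labels <- condition_labels %||% rep("all", length(event_times))
  conds <- unique(labels)
  n <- length(tt)
  idx_of <- function(e) as.integer(round((e - tt[1]) / dt)) + 1L

  epochs <- matrix(NA_real_, length(event_times), length(grid))
  usable <- logical(length(event_times))
  for (j in seq_along(event_times)) {
    i <- idx_of(event_times[j])
    rows <- i + (k0:k1)
    if (rows[1] < 1L || rows[length(rows)] > n) next
    epochs[j, ] <- vv[rows]
    usable[j] <- TRUE
  }
  if (baseline != "none") {
    bw <- baseline_window %||%
      if (baseline == "subtract") c(0, 0) else c(window[1], 0)
    bcols <- which(grid >= bw[1] - dt / 2 & grid <= bw[2] + dt / 2)
    b <- rowMeans(epochs[, bcols, drop = FALSE], na.rm = TRUE)
    usable <- usable & is.finite(b)
    if (baseline == "divide") usable <- usable & b > 0
    epochs <- if (baseline == "subtract") epochs - b else epochs / b
  }
  n_dropped <- sum(!usable)

  mk <- function(f) matrix(NA_real_, length(conds), length(grid),
                           dimnames = list(conds, NULL))
  avg <- mk(); se <- mk(); npts <- mk()
  n_trials <- stats::setNames(integer(length(conds)), conds)
  null_fraction <- stats::setNames(numeric(length(conds)), conds)
  single_flag <- stats::setNames(logical(length(conds)), conds)
  for (cc in conds) {
    rows <- which(labels == cc & usable)
    n_trials[cc] <- length(rows)
    if (!length(rows)) {
      warning(sprintf("condition '%s' has no usable trials", cc))
      next
    }
    E <- epochs[rows, , drop = FALSE]
    null_fraction[cc] <- mean(is.na(E))
    m <- colSums(!is.na(E))
    avg[cc, ] <- colMeans(E, na.rm = TRUE)
    s <- apply(E, 2, stats::sd, na.rm = TRUE)
    se[cc, ] <- ifelse(m > 1, s / sqrt(m), 0)
    npts[cc, ] <- m
    single_flag[cc] <- length(rows) == 1L
  }
  structure(list(time_s = grid, mean = avg, se = se, n_trials = n_trials,
                 n_points = npts, n_dropped = n_dropped,
                 null_fraction = null_fraction,
                 single_trial = single_flag),
            class = "trial_average")
}

#' @export
print.trial_average <- function(x, ...) {
  cat(sprintf("Trial average: %d conditions on [%.2f, %.2f] s grid\n",
              nrow(x$mean), min(x$time_s), max(x$time_s)))
  for (cc in rownames(x$mean)) {
    cat(sprintf("  %s: n = %d trials\n", cc, x$n_trials[cc]))
  }
  invisible(x)
}

#' @export
as.data.frame.trial_average <- function(x, ...) {
  do.call(rbind, lapply(rownames(x$mean), function(cc) {
    data.frame(time_s = x$time_s, condition = cc, mean = x$mean[cc, ],
               se = x$se[cc, ], n = x$n_points[cc, ])
  }))
}

#' Select trials for averaging
#'
#' Standard inclusion filter: for the shape task the condition-split
#' averages use successful forced-choice trials only; for the direction
#' task all successful trials (every trial is forced).
#'
#' @param trials a trial table.
#' @param successful_only keep only completed trials.
#' @param forced_only keep only forced trials; `NULL` (default) means
#'   forced-only for the shape task, all for the direction task.
#' @return The filtered trial table.
#' @export
filter_trials <- function(trials, successful_only = TRUE,
                          forced_only = NULL) {
  forced_only <- forced_only %||%
    identical(attr(trials, "task"), "shape")
  keep <- rep(TRUE, nrow(trials))
  if (successful_only) keep <- keep & trials$success
  if (forced_only) keep <- keep & trials$type == "forced"
  trials[keep, , drop = FALSE]
}
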