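# Electrophysiology: referencing, FSCV-artifact removal (spectral and
# time-domain), beta-band power envelopes, spike detection, PSTH and ISI.

#' Bipolar re-reference two traces
#'
#' Sample-wise difference of two simultaneously recorded channels.
#' Common-mode components (shared artifacts, volume-conducted far-field
#' signals) cancel exactly; the result localizes differential LFP sources
#' between the two contacts.
#'
#' @param trace_a,trace_b `ephys_trace` objects with equal `fs` and length.
#' @return An `ephys_trace` of `a - b` with a bipolar reference descriptor
#'   recording both parent channel ids.
#' @export
bipolar_reference <- function(trace_a, trace_b) {
  if (trace_a$fs != trace_b$fs) {
    stop_with("validation_error", "sampling rates differ")
  }
  if (length(trace_a$samples) != length(trace_b$samples)) {
    stop_with("validation_error", "trace lengths differ")
  }
  new_ephys_trace(trace_a$samples - trace_b$samples, trace_a$fs,
                  channel = paste0(trace_a$channel, "-", trace_b$channel),
                  reference = c(trace_a$channel, trace_b$channel),
                  events = trace_a$events %||% trace_b$events)
}

#' Remove periodic FSCV scan artifacts by spectral interpolation
#'
#' The scan artifact repeats at the scan rate (10 Hz) and concentrates its
#' energy at that frequency and its integer harmonics. Each contaminated
#' discrete-spectrum bin (the harmonic bin plus `halfwidth` bins each side)
#' is replaced by interpolating magnitude (linearly) and phase (along the
#' shortest circular arc) from `neighbor_bins` flanking clean bins on each
#' side; conjugate symmetry is preserved so the inverse transform is real.
#' Power at all untouched bins is unchanged.
#'
#' @param trace an `ephys_trace`.
#' @param scan_rate_hz artifact repetition rate (Hz), default 10.
#' @param n_harmonics number of harmonics to clean; `Inf` (default) means
#'   all below Nyquist. Harmonics at or above Nyquist are clipped with a
#'   warning when a finite request exceeds it.
#' @param neighbor_bins clean flanking bins per side used for
#'   interpolation.
#' @param halfwidth contaminated bins each side of the harmonic bin.
#' @return The cleaned `ephys_trace` (same length, real-valued).
#' @export
remove_artifacts_spectral <- function(trace, scan_rate_hz = 10,
                                      n_harmonics = Inf, neighbor_bins = 2,
                                      halfwidth = 1) {
  x <- trace$samples
  n <- length(x)
  fs <- trace$fs
  df <- fs / n
  nyq_bin <- floor(n / 2)
  h_max <- floor((fs / 2 - df) / scan_rate_hz)
  if (is.finite(n_harmonics) && n_harmonics > h_max) {
    warning("harmonics at or above Nyquist clipped")
  }
  H <- min(n_harmonics, h_max)
  X <- stats::fft(x)
  for (h in seq_len(H)) {
    k0 <- round(h * scan_rate_hz / df)          # 0-based bin of harmonic
    lo <- k0 - halfwidth
    hi <- k0 + halfwidth
    fl <- (lo - neighbor_bins):(lo - 1)
    fr <- (hi + 1):(hi + neighbor_bins)
    if (lo < 2 || max(fr) >= nyq_bin) next
    magL <- mean(Mod(X[fl + 1])); magR <- mean(Mod(X[fr + 1]))
    phL <- Arg(sum(X[fl + 1]));  phR <- Arg(sum(X[fr + 1]))
    dph <- Arg(exp(1i * (phR - phL)))           # shortest arc
    for (k in lo:hi) {
      w <- (k - (lo - 1)) / (hi - lo + 2)
      mag <- (1 - w) * magL + w * magR
      ph <- phL + w * dph
      X[k + 1] <- mag * exp(1i * ph)
      X[n - k + 1] <- Conj(X[k + 1])            # mirror bin
    }
  }
  trace$samples <- Re(stats::fft(X, inverse = TRUE)) / n
  trace
}

#' Remove FSCV scan artifacts by time-domain interpolation
#'
#' Excises a window around every scan artifact (`window_pre` before onset
#' through artifact duration plus `window_post` after) and replaces it with
#' a least-squares cubic polynomial fit to `anchor_s` seconds of clean
#' signal flanking each side (a smoothing fit, not an interpolant through
#' individual noisy samples, so the fill does not overshoot across the
#' gap). Samples outside the excision windows are untouched sample-exactly,
#' which preserves the high-frequency content (spike waveforms) between
#' scans.
#'
#' @param trace an `ephys_trace`.
#' @param artifact_times sorted artifact onset times (s).
#' @param window_pre,window_post guard intervals (s) before onset / after
#'   artifact end.
#' @param artifact_duration artifact length (s), default the 8.5 ms scan.
#' @param anchor_s clean-signal span per side anchoring the fit (s).
#' @param degree polynomial degree of the fill (default cubic).
#' @return The cleaned `ephys_trace`.
#' @export
remove_artifacts_time <- function(trace, artifact_times,
                                  window_pre = 0.001, window_post = 0.002,
                                  artifact_duration = 0.0085,
                                  anchor_s = 0.002, degree = 3) {
  if (!length(artifact_times)) return(trace)
  if (is.unsorted(artifact_times)) {
    stop_with("validation_error", "artifact_times must be sorted")
  }
  fs <- trace$fs
  x <- trace$samples
  n <- length(x)
  n_anchor <- max(as.integer(round(anchor_s * fs)), degree + 1L)
  i0 <- pmax(1L, as.integer(floor((artifact_times - window_pre) * fs)) + 1L)
  i1 <- pmin(n, as.integer(ceiling(
    (artifact_times + artifact_duration + window_post) * fs)) + 1L)
  if (any(i0[-1] <= i1[-length(i1)] + n_anchor)) {
    stop_with("validation_error", "excision windows overlap")
  }
  for (j in seq_along(i0)) {
    la <- max(1L, i0[j] - n_anchor):(i0[j] - 1L)
    ra <- (i1[j] + 1L):min(n, i1[j] + n_anchor)
    la <- la[la >= 1]; ra <- ra[ra <= n]
    if (length(la) < degree + 1 || length(ra) < degree + 1) next  # edge
    ia <- c(la, ra)
    mid <- (i0[j] + i1[j]) / 2
    hw <- (i1[j] - i0[j]) / 2 + n_anchor        # normalized time axis
    u <- (ia - mid) / hw
    Xd <- outer(u, 0:degree, `^`)
    beta <- stats::lm.fit(Xd, x[ia])$coefficients
    gap <- i0[j]:i1[j]
    x[gap] <- outer((gap - mid) / hw, 0:degree, `^`) %*% beta
  }
  trace$samples <- x
  trace
}

#' Beta-band LFP power envelope
#'
#' Downsamples to 1 kHz (polyphase anti-aliased), zero-phase band-pass
#' filters (default 13-28 Hz, 4th-order Butterworth forward-backward),
#' computes instantaneous power as the squared magnitude of the analytic
#' signal, and smooths with a unit-area Hanning window (default 0.25 s).
#' A unit-amplitude in-band tone yields a steady-state power of 1.
#'
#' @param trace an `ephys_trace`.
#' @param band band edges (Hz), default `c(13, 28)`.
#' @param smooth_window_s Hanning smoothing window (s).
#' @param target_fs envelope sampling rate (Hz), default 1000.
#' @param method `"analytic"` (default; squared analytic-signal magnitude)
#'   or `"rectify"` (squared trace low-pass filtered before smoothing).
#' @return An object of class `beta_envelope`: `power` (uV^2, nonnegative)
#'   at `fs = target_fs`, with `time_s`, `band` and `smooth_window_s`.
#' @export
beta_power <- function(trace, band = c(13, 28), smooth_window_s = 0.25,
                       target_fs = 1000, method = c("analytic", "rectify")) {
  method <- match.arg(method)
  if (band[1] >= band[2]) {
    stop_with("validation_error", "band edges inverted")
  }
  x <- resample_to(trace$samples, trace$fs, target_fs)
  if (band[2] >= target_fs / 2) {
    stop_with("validation_error", "band upper edge at or above Nyquist")
  }
  xb <- bandpass_filtfilt(x, band, target_fs)
  p <- if (method == "analytic") {
    Mod(analytic_signal(xb))^2
  } else {
    lp <- signal::butter(4, min(0.9, 2 * band[1] / target_fs), type = "low")
    pmax(0, signal::filtfilt(lp, xb^2)) * 2   # x2 restores tone power to A^2
  }
  p <- pmax(0, hanning_smooth(p, smooth_window_s * target_fs))
  structure(list(power = p, fs = target_fs,
                 time_s = (seq_along(p) - 1) / target_fs,
                 band = band, smooth_window_s = smooth_window_s,
                 events = trace$events),
            class = "beta_envelope")
}

#' @export
print.beta_envelope <- function(x, ...) {
  cat(sprintf("Beta envelope: %g-%g Hz, %d samples at %g Hz (%.2f s smooth)\n",
              x$band[1], x$band[2], length(x$power), x$fs,
              x$smooth_window_s))
  invisible(x)
}

#' Threshold spike detection
#'
#' A deliberately simple single-threshold detector standing in for offline
#' spike sorting (no cluster separation): band-pass filter (default
#' 300-6000 Hz), estimate the noise level robustly as
#' `sigma = median(|x|) / 0.6745`, detect negative threshold crossings at
#' `-threshold_k * sigma`, align each event to its local trough, enforce a
#' lockout, and cut fixed-window waveform snippets.
#'
#' @param trace an artifact-cleaned `ephys_trace`.
#' @param band spike band (Hz); the upper edge is clipped below Nyquist.
#' @param threshold_k threshold in robust noise SDs (default 4).
#' @param lockout_s minimum inter-event interval (s).
#' @param snippet_window snippet extent around the trough (s, c(pre, post)).
#' @param exclude_times optional onset times (s) of excised artifact
#'   windows: these stretches (onset to onset + `exclude_dur_s`) hold
#'   interpolated, artificially smooth signal, and including them biases
#'   the noise estimate low. They are skipped when estimating sigma.
#' @param exclude_dur_s length of each excluded stretch (s).
#' @return An object of class `spike_set`: sorted `times` (s), `snippets`
#'   (events x samples, uV), `mean_waveform`, `sd_waveform`, `threshold`
#'   (uV), `sigma`, and `n_dropped` (events lost to trace bounds).
#' @export
detect_spikes <- function(trace, band = c(300, 6000), threshold_k = 4,
                          lockout_s = 0.001,
                          snippet_window = c(-4e-4, 8e-4),
                          exclude_times = NULL, exclude_dur_s = 0.0125) {
  fs <- trace$fs
  hi <- min(band[2], 0.45 * fs)
  if (band[1] >= hi) {
    stop_with("validation_error", "sampling rate too low for the spike band")
  }
  xb <- bandpass_filtfilt(trace$samples, c(band[1], hi), fs)
  noise_mask <- rep(TRUE, length(xb))
  for (t0 in exclude_times) {
    i <- max(1L, as.integer(floor(t0 * fs))):
      min(length(xb), as.integer(ceiling((t0 + exclude_dur_s) * fs)))
    noise_mask[i] <- FALSE
  }
  sigma <- stats::median(abs(xb[noise_mask])) / 0.6745
  thr <- -threshold_k * sigma
  below <- xb < thr
  onsets <- which(below & !c(FALSE, below[-length(below)]))
  search <- max(1L, as.integer(5e-4 * fs))
  troughs <- vapply(onsets, function(i) {
    j <- i:min(length(xb), i + search)
    j[which.min(xb[j])]
  }, integer(1))
  troughs <- troughs[order(troughs)]
  keep <- integer(0)
  last <- -Inf
  for (i in troughs) {
    if ((i - last) / fs > lockout_s) {
      keep <- c(keep, i)
      last <- i
    }
  }
  pre <- as.integer(round(-snippet_window[1] * fs))
  post <- as.integer(round(snippet_window[2] * fs))
  in_bounds <- keep - pre >= 1 & keep + post <= length(xb)
  n_dropped <- sum(!in_bounds)
  keep <- keep[in_bounds]
  snippets <- if (length(keep)) {
    t(vapply(keep, function(i) xb[(i - pre):(i + post)],
             numeric(pre + post + 1L)))
  } else {
    matrix(numeric(0), 0, pre + post + 1L)
  }
  structure(list(
    times = (keep - 1L) / fs,
    snippets = snippets,
    mean_waveform = if (nrow(snippets)) colMeans(snippets) else numeric(0),
    sd_waveform = if (nrow(snippets) > 1) apply(snippets, 2, stats::sd) else numeric(0),
    snippet_time_s = seq(-pre, post) / fs,
    threshold = thr, sigma = sigma, band = c(band[1], hi),
    lockout_s = lockout_s, n_dropped = n_dropped, fs = fs
  ), class = "spike_set")
}

#' @export
print.spike_set <- function(x, ...) {
  cat(sprintf("Spike set: %d events (threshold %.1f uV, sigma %.2f uV)\n",
              length(x$times), x$threshold, x$sigma))
  invisible(x)
}

#' Peristimulus time histogram
#'
#' Trial-averaged firing rate aligned to events, split by condition.
#'
#' @param spike_times sorted spike times (s).
#' @param event_times alignment event times (s).
#' @param window aligned window (s), e.g. `c(-1, 2)`.
#' @param bin_width bin width (s).
#' @param condition_labels optional per-event condition labels (a factor's
#'   unused levels yield empty rows with a warning); `NULL` pools all
#'   events as `"all"`.
#' @return An object of class `psth`: `time_s` (bin centers), `rate`
#'   (conditions x bins, spikes/s), `n_trials` per condition.
#' @export
psth <- function(spike_times, event_times, window = c(-1, 2),
                 bin_width = 0.05, condition_labels = NULL) {
  if (bin_width <= 0) stop_with("validation_error", "bin_width must be > 0")
  labels <- condition_labels %||% rep("all", length(event_times))
  conds <- if (is.factor(labels)) levels(labels) else unique(labels)
  breaks <- seq(window[1], window[2], by = bin_width)
  centers <- breaks[-length(breaks)] + bin_width / 2
  rate <- matrix(0, length(conds), length(centers),
                 dimnames = list(conds, NULL))
  n_trials <- stats::setNames(integer(length(conds)), conds)
  for (cc in conds) {
    ev <- event_times[labels == cc]
    n_trials[cc] <- length(ev)
    if (!length(ev)) {
      warning(sprintf("condition '%s' has no events", cc))
      next
    }
    counts <- numeric(length(centers))
    for (e in ev) {
      rel <- spike_times - e
      rel <- rel[rel >= window[1] & rel < window[2]]
      if (length(rel)) {
        idx <- pmin(length(centers),
                    1L + as.integer(floor((rel - window[1]) / bin_width)))
        tab <- tabulate(idx, nbins = length(centers))
        counts <- counts + tab
      }
    }
    rate[cc, ] <- counts / (length(ev) * bin_width)
  }
  structure(list(time_s = centers, rate = rate, n_trials = n_trials,
                 bin_width = bin_width, window = window),
            class = "psth")
}

#' Interspike interval histogram
#'
#' Histogram of successive spike-time differences, default 1 ms bins.
#'
#' @param spike_times sorted spike times (s).
#' @param bin_width_s bin width (s), default 0.001.
#' @param max_isi_s upper edge (s); defaults to the largest observed ISI.
#' @return `data.frame` with `isi_s` (bin centers) and `count`; empty (zero
#'   rows) when fewer than 2 spikes are supplied.
#' @export
isi_histogram <- function(spike_times, bin_width_s = 0.001,
                          max_isi_s = NULL) {
  if (length(spike_times) < 2) {
    return(data.frame(isi_s = numeric(0), count = integer(0)))
  }
  isi <- diff(sort(spike_times))
  top <- max_isi_s %||% max(isi)
  breaks <- seq(0, top + bin_width_s, by = bin_width_s)
  idx <- pmin(length(breaks) - 1L, 1L + as.integer(floor(isi / bin_width_s)))
  data.frame(isi_s = breaks[-length(breaks)] + bin_width_s / 2,
             count = tabulate(idx, nbins = length(breaks) - 1L))
}
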