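#' Simulate a behavioral trial table
#'
#' Generates the event schedule of the reward-biased eye-movement tasks:
#' each trial presents a central fixation cue, a value cue 2 s later (after
#' fixation), and delivers the reward after a 4 s hold. In the "direction"
#' task every trial is a forced single-cue trial whose location signals the
#' reward size; in the "shape" task a configurable fraction of trials
#' (default 25%) are forced-choice, the rest free choices between two
#' shapes.
#'
#' @param task `"shape"` or `"direction"`.
#' @param n_trials number of trials (>= 1).
#' @param forced_fraction fraction of forced trials for the shape task
#'   (exact count, rounded); the direction task is all forced.
#' @param fixation_s central-cue fixation interval before the value cue (s).
#' @param hold_s hold interval between value cue and reward (s).
#' @param iti_s inter-trial interval after reward (s).
#' @param success_rate per-trial probability the monkey completes the trial.
#' @param seed RNG seed; identical seeds give identical tables.
#' @return A `data.frame` with one row per trial: `trial`, `t_central`,
#'   `t_value`, `t_reward` (s), `reward` ("large"/"small"), `laterality`
#'   ("contra"/"ipsi"), `type` ("forced"/"choice"), `success`, `block`.
#' @export
simulate_trials <- function(task = c("shape", "direction"), n_trials,
                            forced_fraction = 0.25, fixation_s = 2,
                            hold_s = 4, iti_s = 3, success_rate = 0.9,
                            seed = NULL) {
  task <- match.arg(task)
  if (n_trials < 1) stop_with("config_error", "n_trials must be >= 1")
  with_seed(seed, {
    period <- fixation_s + hold_s + iti_s
    t_central <- iti_s + period * (seq_len(n_trials) - 1)
    t_value <- t_central + fixation_s
    t_reward <- t_value + hold_s
    reward <- sample(c("large", "small"), n_trials, replace = TRUE)
    laterality <- sample(c("contra", "ipsi"), n_trials, replace = TRUE)
    if (task == "direction") {
      type <- rep("forced", n_trials)
    } else {
      n_forced <- as.integer(round(forced_fraction * n_trials))
      type <- rep("choice", n_trials)
      type[sample.int(n_trials, n_forced)] <- "forced"
    }
    success <- stats::runif(n_trials) < success_rate
    block <- 1L + (seq_len(n_trials) - 1L) %/% 50L
    out <- data.frame(
      trial = seq_len(n_trials),
      t_central = t_central, t_value = t_value, t_reward = t_reward,
      reward = reward, laterality = laterality, type = type,
      success = success, block = block,
      stringsAsFactors = FALSE
    )
    attr(out, "task") <- task
    out
  })
}

# Event-code table shared by both acquisition streams (8-bit codes).
EVENT_CODES <- c(central_cue = 1L, value_cue = 2L, reward = 3L)

#' Event table for a trial schedule
#'
#' Expands a trial table into the timestamped 8-bit event-code stream the
#' acquisition systems would log (central cue doubles as the trial-start
#' synchronization code).
#'
#' @param trials a trial table from [simulate_trials()].
#' @return `data.frame` with `time_s`, `code` (integer 0-255), `label`.
#' @export
trial_events <- function(trials) {
  ev <- rbind(
    data.frame(time_s = trials$t_central, code = EVENT_CODES[["central_cue"]],
               label = "central_cue"),
    data.frame(time_s = trials$t_value, code = EVENT_CODES[["value_cue"]],
               label = "value_cue"),
    data.frame(time_s = trials$t_reward, code = EVENT_CODES[["reward"]],
               label = "reward")
  )
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Gamma-shaped transient kernel, normalized to unit peak. Models the rise
# and decay of a cue-evoked dopamine release event.
transient_kernel <- function(t, shape = 2, tau = 0.7) {
  k <- ifelse(t <= 0, 0, (t / tau)^(shape - 1) * exp(-(t / tau)))
  pk <- max(k)
  if (pk > 0) k / pk else k
}

#' Simulate an FSCV recording session
#'
#' Renders a synthetic color plot (scans x in-scan samples) for a trial
#' schedule: a large stable capacitive background current, slow drift
#' (linear trend plus random walk), dopamine transients after each value
#' cue with amplitude scaled by reward size (large > small), a slow pH
#' oscillation, sporadic movement-artifact frames, and white measurement
#' noise. Ground truth (the exact concentration series multiplied into the
#' templates) is returned alongside.
#'
#' @param trials trial table from [simulate_trials()].
#' @param templates `analyte_templates` from [make_templates()].
#' @param da_large,da_small peak dopamine transient amplitude (nM) for
#'   large/small reward trials.
#' @param kinetics list with `shape` and `tau` (s) of the gamma transient
#'   kernel.
#' @param ph_amp,ph_period_s amplitude (pH units) and period of the slow pH
#'   oscillation.
#' @param background_current background CV peak amplitude (nA).
#' @param drift_rate linear drift (nA/s at the background peak).
#' @param drift_rw_sd per-frame random-walk drift step (nA).
#' @param artifact_rate per-frame probability of a movement-artifact frame.
#' @param artifact_amp movement artifact amplitude (units of the movement
#'   template; current is amplitude x movement gain).
#' @param noise_sd white noise sd per sample (nA).
#' @param post_s recording continued after the last reward (s).
#' @param seed session seed; all randomness derives from it.
#' @return list with `colorplot` (a `color_plot`) and `truth` (list:
#'   `da_nM`, `ph`, `movement` per frame; `artifact_frames`; effect sizes).
#' @export
simulate_fscv_session <- function(trials, templates,
                                  da_large = 100, da_small = 50,
                                  kinetics = list(shape = 2, tau = 0.7),
                                  ph_amp = 0.05, ph_period_s = 60,
                                  background_current = 400,
                                  drift_rate = 0.05, drift_rw_sd = 0.02,
                                  artifact_rate = 0.005, artifact_amp = 1,
                                  noise_sd = 0.1, post_s = 5,
                                  seed = NULL) {
  wf <- templates$waveform
  with_seed(seed, {
    dt <- wf$repetition_interval
    duration <- max(trials$t_reward) + post_s
    n_frames <- as.integer(floor(duration / dt))
    frame_times <- (seq_len(n_frames) - 1) * dt

    # True concentration series on the frame grid.
    da <- numeric(n_frames)
    for (i in seq_len(nrow(trials))) {
      amp <- if (trials$reward[i] == "large") da_large else da_small
      da <- da + amp * transient_kernel(frame_times - trials$t_value[i],
                                        kinetics$shape, kinetics$tau)
    }
    ph <- ph_amp * sin(2 * pi * frame_times / ph_period_s)
    mv <- numeric(n_frames)
    art <- which(stats::runif(n_frames) < artifact_rate)
    mv[art] <- artifact_amp

    # Background CV: smoothed capacitive (dV/dt-shaped) curve.
    n <- wf$n_samples
    bg_unit <- background_cv(wf)
    bg <- background_current * bg_unit

    drift <- drift_rate * frame_times +
      cumsum(stats::rnorm(n_frames, 0, drift_rw_sd))

    g <- templates$gains
    tm <- templates$templates
    conc <- cbind(da * g[["dopamine"]], ph * g[["ph"]], mv * g[["movement"]])
    currents <- conc %*% tm[c("dopamine", "ph", "movement"), , drop = FALSE]
    currents <- currents +
      rep(1, n_frames) %o% bg +
      drift %o% bg_unit
    if (noise_sd > 0) {
      currents <- currents + matrix(stats::rnorm(n_frames * n, 0, noise_sd),
                                    n_frames, n)
    }

    cp <- new_color_plot(currents, frame_times, wf, trial_events(trials),
                         meta = list(seed = seed,
                                     background_current = background_current))
    truth <- list(da_nM = da, ph = ph, movement = mv, artifact_frames = art,
                  effects = list(da_large = da_large, da_small = da_small))
    list(colorplot = cp, truth = truth)
  })
}

#' Simulate a concurrent electrophysiology session
#'
#' Renders a wide-band extracellular voltage trace for a trial schedule:
#' 1/f (pink) background noise, stochastic beta-band bursts (center
#' frequency within 13-28 Hz, one to a few cycles long) whose amplitude is
#' suppressed after the value cue by a reward-size- and laterality-dependent
#' event-related desynchronization (ERD) factor, an inhomogeneous-Poisson
#' spike train with reward-modulated rate and a fixed biphasic waveform,
#' and a stereotyped damped-oscillation artifact at every FSCV scan onset
#' (every 100 ms). Output is quantized to the int16 ADC grid of a +-1 mV
#' input range, as acquired by the recording headstage.
#'
#' @param trials trial table from [simulate_trials()].
#' @param fs sampling rate (Hz); 30 or 32 kHz in the recording rig, lower
#'   rates are accepted for LFP-only renders.
#' @param beta_params list: `freq_range` (Hz), `burst_rate` (bursts/s),
#'   `cycles`, `amp` (uV), `erd_large`, `erd_small` (fractional suppression
#'   depths, large > small by default), `erd_contra` (additional depth for
#'   contralateral cues), `erd_window` (s after value cue).
#' @param spike_params list: `rate_base` (Hz), `gain_large`, `gain_small`
#'   (rate multipliers in `window` s after value cue), `refractory` (s),
#'   `amp` (trough uV; 0 disables spikes).
#' @param artifact_params list: `amp` (uV; 0 disables), `freq` (Hz),
#'   `tau` (s), `duration` (s), `interval` (s).
#' @param pink_sd 1/f background noise sd (uV; 0 disables).
#' @param white_sd broadband (thermal/amplifier) noise floor sd (uV); sets
#'   the in-band noise level for spike detection.
#' @param post_s recording continued after the last reward (s).
#' @param quantize quantize to the int16 ADC grid (default TRUE).
#' @param seed session seed.
#' @return list with `trace` (an `ephys_trace`) and `truth` (list:
#'   `spike_times`, `artifact_times`, `bursts` table, per-trial `erd_depth`,
#'   effect sizes).
#' @export
simulate_ephys_session <- function(trials, fs = 30000,
                                   beta_params = list(), spike_params = list(),
                                   artifact_params = list(),
                                   pink_sd = 15, white_sd = 3, post_s = 5,
                                   quantize = TRUE, seed = NULL) {
  bp <- utils::modifyList(list(freq_range = c(16, 24), burst_rate = 2,
                               cycles = 3, amp = 25, erd_large = 0.6,
                               erd_small = 0.25, erd_contra = 0.1,
                               erd_window = c(0, 1.5)), beta_params)
  sp <- utils::modifyList(list(rate_base = 15, gain_large = 2,
                               gain_small = 1.3, window = c(0, 1),
                               refractory = 0.002, amp = -80), spike_params)
  ap <- utils::modifyList(list(amp = 300, freq = 600, tau = 0.002,
                               duration = 0.0085, interval = 0.1),
                          artifact_params)
  if (ap$duration >= ap$interval) {
    stop_with("config_error",
              "artifact duration must be below the scan repetition interval")
  }
  with_seed(seed, {
    duration <- max(trials$t_reward) + post_s
    n <- as.integer(floor(duration * fs))
    t_end <- n / fs
    x <- numeric(n)

    # 1/f background via spectral shaping of white noise.
    if (pink_sd > 0) {
      w <- stats::rnorm(n)
      W <- stats::fft(w)
      f <- c(1, seq_len(n - 1))
      f <- pmin(f, n - f + 1)           # two-sided frequency index
      W <- W / sqrt(f)
      p <- Re(stats::fft(W, inverse = TRUE)) / n
      x <- x + pink_sd * p / stats::sd(p)
    }
    if (white_sd > 0) x <- x + stats::rnorm(n, 0, white_sd)

    # ERD depth per trial (ground truth for the reward/laterality effects).
    depth <- ifelse(trials$reward == "large", bp$erd_large, bp$erd_small) +
      ifelse(trials$laterality == "contra", bp$erd_contra, 0)
    depth <- pmin(depth, 0.95)

    erd_scale <- function(tb) {
      # suppression factor applying to a burst at time tb
      i <- which(trials$t_value + bp$erd_window[1] <= tb &
                   tb <= trials$t_value + bp$erd_window[2])
      if (length(i)) 1 - depth[i[1]] else 1
    }

    bursts <- NULL
    if (bp$amp > 0 && bp$burst_rate > 0) {
      n_burst <- stats::rpois(1, bp$burst_rate * t_end)
      onset <- sort(stats::runif(n_burst, 0, t_end))
      freq <- stats::runif(n_burst, bp$freq_range[1], bp$freq_range[2])
      scale <- vapply(onset, erd_scale, numeric(1))
      for (b in seq_len(n_burst)) {
        len <- bp$cycles / freq[b]
        i0 <- as.integer(floor(onset[b] * fs)) + 1L
        i1 <- min(n, i0 + as.integer(len * fs))
        if (i1 - i0 < 4) next
        tt <- (seq(i0, i1) - i0) / fs
        env <- 0.5 * (1 - cos(2 * pi * tt / len))
        x[i0:i1] <- x[i0:i1] +
          bp$amp * scale[b] * env * sin(2 * pi * freq[b] * tt)
      }
      bursts <- data.frame(onset = onset, freq = freq, amp_scale = scale)
    }

    # Spikes: thinned inhomogeneous Poisson with absolute refractory period.
    spike_times <- numeric(0)
    if (sp$amp != 0 && sp$rate_base > 0) {
      gain_of <- function(tt) {
        i <- which(trials$t_value + sp$window[1] <= tt &
                     tt <= trials$t_value + sp$window[2])
        if (length(i) == 0) return(1)
        if (trials$reward[i[1]] == "large") sp$gain_large else sp$gain_small
      }
      rmax <- sp$rate_base * max(sp$gain_large, sp$gain_small, 1)
      cand <- cumsum(stats::rexp(as.integer(2.5 * rmax * t_end) + 20L,
                                 rate = rmax))
      cand <- cand[cand < t_end - 0.002]
      keep <- stats::runif(length(cand)) <
        vapply(cand, gain_of, numeric(1)) * sp$rate_base / rmax
      st <- cand[keep]
      if (length(st) > 1) {
        ok <- c(TRUE, diff(st) > sp$refractory)
        while (!all(ok)) {        # sequential refractory enforcement
          st <- st[ok]
          ok <- c(TRUE, diff(st) > sp$refractory)
        }
      }
      spike_times <- st
      if (length(st)) {
        tt <- seq(0, 0.0012, by = 1 / fs)
        wfm <- sp$amp * (exp(-((tt - 3e-4) / 1.2e-4)^2) -
                           0.35 * exp(-((tt - 6.5e-4) / 2.5e-4)^2))
        for (s in st) {
          i0 <- as.integer(round(s * fs)) + 1L
          i1 <- min(n, i0 + length(wfm) - 1L)
          x[i0:i1] <- x[i0:i1] + wfm[seq_len(i1 - i0 + 1L)]
        }
      }
    }

    # FSCV scan artifact: damped oscillation at every scan onset.
    artifact_times <- seq(0, t_end - ap$duration, by = ap$interval)
    if (ap$amp != 0) {
      tt <- seq(0, ap$duration, by = 1 / fs)
      awf <- ap$amp * exp(-tt / ap$tau) * sin(2 * pi * ap$freq * tt)
      for (s in artifact_times) {
        i0 <- as.integer(round(s * fs)) + 1L
        i1 <- min(n, i0 + length(awf) - 1L)
        x[i0:i1] <- x[i0:i1] + awf[seq_len(i1 - i0 + 1L)]
      }
    }

    tr <- new_ephys_trace(x, fs, channel = "sim01", reference = "ground",
                          events = trial_events(trials))
    if (quantize) tr <- quantize_trace(tr)
    truth <- list(spike_times = spike_times, artifact_times = artifact_times,
                  bursts = bursts, erd_depth = depth,
                  effects = list(erd_large = bp$erd_large,
                                 erd_small = bp$erd_small,
                                 spike_gain_large = sp$gain_large,
                                 spike_gain_small = sp$gain_small))
    list(trace = tr, truth = truth)
  })
}
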