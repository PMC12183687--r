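# End-to-end pipeline driver: simulate -> FSCV chemometrics -> ephys ->
# event-aligned averages -> recovery metrics.

#' Match detected spikes against reference times
#'
#' Greedy one-to-one matching within a tolerance; standard detection
#' scoring.
#'
#' @param detected,reference sorted spike times (s).
#' @param tol match tolerance (s), default 0.5 ms.
#' @return list with `precision`, `recall`, `f1`, `n_matched`.
#' @export
match_spikes <- function(detected, reference, tol = 5e-4) {
  used <- logical(length(reference))
  matched <- 0L
  for (t in detected) {
    d <- abs(reference - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  precision <- if (length(detected)) matched / length(detected) else NA_real_
  recall <- if (length(reference)) matched / length(reference) else NA_real_
  f1 <- if (is.finite(precision) && is.finite(recall) &&
            precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1, n_matched = matched)
}

#' Default pipeline configuration
#'
#' @param seed master session seed; every random stage derives a
#'   documented substream from it.
#' @param ... overrides for any top-level field.
#' @return A config list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    task = "shape", n_trials = 60,
    waveform = list(v_start = -0.4, v_peak = 1.3, scan_rate = 400,
                    repetition_interval = 0.1, adc_rate = 1e4),
    fscv = list(noise_sd = 0.1, artifact_rate = 0.005, artifact_amp = 1,
                alpha = 0.05, r_threshold = 0.8, n_standards_per = 40,
                standards_noise_sd = 0.1, k = 4, n_ref_frames = 30),
    ephys = list(fs = 1000, pink_sd = 15,
                 spikes = FALSE, spike_fs = 30000,
                 band = c(13, 28), smooth_s = 0.25),
    window = c(-2, 4)
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full simulate-analyze-align pipeline
#'
#' Executes the analysis chain on a synthetic session with known ground
#' truth: simulate the task and both recording streams; background-subtract
#' the color plot at the value cue, fit principal component regression on
#' a synthetic standards bank, predict and gate concentrations; clean FSCV
#' artifacts from the ephys trace spectrally and compute the beta-band
#' envelope; build condition-split value-cue-aligned averages (per-trial
#' value-cue re-referencing for chemistry); and score recovery against the
#' ground truth. Deterministic: identical config (including seed) gives
#' identical metrics.
#'
#' @param config a config list from [pipeline_config()].
#' @param out_dir optional directory; when given, the session bundle,
#'   trial-average tables and `metrics.json` are written there.
#' @return list with `trials`, `chem`, `beta`, `averages`, `metrics`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  seed <- config$seed
  wfp <- config$waveform
  wf <- generate_waveform(wfp$v_start, wfp$v_peak, wfp$scan_rate,
                          wfp$repetition_interval, wfp$adc_rate)
  tpl <- make_templates(wf)
  trials <- simulate_trials(config$task, config$n_trials,
                            seed = substream(seed, 1))

  fscv_sim <- simulate_fscv_session(
    trials, tpl, noise_sd = config$fscv$noise_sd,
    artifact_rate = config$fscv$artifact_rate,
    artifact_amp = config$fscv$artifact_amp,
    seed = substream(seed, 2))
  ephys_sim <- simulate_ephys_session(
    trials, fs = config$ephys$fs, pink_sd = config$ephys$pink_sd,
    spike_params = if (isTRUE(config$ephys$spikes)) list()
                   else list(amp = 0),
    seed = substream(seed, 3))

  # --- FSCV chain ---------------------------------------------------------
  std <- make_standards(tpl, n_per = config$fscv$n_standards_per,
                        noise_sd = config$fscv$standards_noise_sd,
                        seed = substream(seed, 4))
  model <- fit_pcr(std$standards, std$concentrations,
                   k = config$fscv$k, alpha = config$fscv$alpha)
  chem <- analyze_fscv_trials(fscv_sim$colorplot, model, trials$t_value,
                              window = c(-2, 7),
                              n_ref_frames = config$fscv$n_ref_frames,
                              r_threshold = config$fscv$r_threshold)

  # --- EPhys chain --------------------------------------------------------
  clean <- remove_artifacts_spectral(ephys_sim$trace)
  beta <- beta_power(clean, band = config$ephys$band,
                     smooth_window_s = config$ephys$smooth_s)

  spikes <- NULL
  spike_truth <- NULL
  if (isTRUE(config$ephys$spikes)) {
    sp_sim <- simulate_ephys_session(
      trials, fs = config$ephys$spike_fs, pink_sd = 5,
      beta_params = list(amp = 0),
      seed = substream(seed, 5))
    sp_clean <- remove_artifacts_time(sp_sim$trace,
                                      sp_sim$truth$artifact_times)
    spikes <- detect_spikes(sp_clean)
    spike_truth <- sp_sim$truth$spike_times
  }

  # --- Alignment / condition averages ------------------------------------
  inc <- filter_trials(trials)
  avg_da <- epoch_and_average(chem, inc$t_value, config$window,
                              condition_labels = inc$reward)
  avg_beta <- epoch_and_average(beta, inc$t_value, config$window,
                                condition_labels = inc$reward)

  # --- Recovery metrics vs ground truth -----------------------------------
  truth <- fscv_sim$truth
  # reference the ground truth exactly as each frame was referenced
  cs <- cumsum(c(0, truth$da_nM))
  m <- config$fscv$n_ref_frames
  ref_mean <- function(i) {
    lo <- pmax(1L, i - m + 1L)
    (cs[i + 1L] - cs[lo]) / (i - lo + 1L)
  }
  ok <- chem$valid
  da_true_ref <- truth$da_nM[ok] - ref_mean(chem$ref_frame[ok])
  da_rmse <- sqrt(mean((chem$conc[ok, "dopamine"] - da_true_ref)^2))

  post <- function(ta, cond) {
    cols <- ta$time_s > 0 & ta$time_s <= 2
    mean(ta$mean[cond, cols], na.rm = TRUE)
  }
  da_effect <- post(avg_da, "large") - post(avg_da, "small")
  beta_effect <- post(avg_beta, "large") - post(avg_beta, "small")
  metrics <- list(
    n_trials = nrow(trials), n_included = nrow(inc),
    da_rmse_nM = da_rmse,
    null_fraction = mean(!chem$valid[chem$reason != "not-analyzed"]),
    da_reward_effect_nM = da_effect,
    da_sign_correct = da_effect > 0,
    beta_reward_effect_uV2 = beta_effect,
    beta_erd_sign_correct = beta_effect < 0
  )
  if (!is.null(spikes)) {
    sc <- match_spikes(spikes$times, spike_truth)
    metrics$spike_f1 <- sc$f1
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("fscvephys")),
    seed = seed,
    config_hash = jsonlite_hash(config),
    config = config)

  if (!is.null(out_dir)) {
    write_session(list(colorplot = fscv_sim$colorplot,
                       trace = ephys_sim$trace,
                       truth = list(da_nM = truth$da_nM, ph = truth$ph,
                                    artifact_frames = truth$artifact_frames),
                       seed = seed, config = config), out_dir)
    utils::write.table(as.data.frame(avg_da),
                       file.path(out_dir, "avg_dopamine.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(avg_beta),
                       file.path(out_dir, "avg_beta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(c(metrics, provenance["config_hash"]),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(trials = trials, chem = chem, beta = beta, spikes = spikes,
       averages = list(dopamine = avg_da, beta = avg_beta),
       metrics = metrics, provenance = provenance)
}

# Stable hash of a config list for provenance logging.
jsonlite_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
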