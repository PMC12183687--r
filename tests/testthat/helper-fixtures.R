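# Shared desk-scale fixtures. The 10 kHz ADC variant of the standard
# waveform (85 samples/scan) keeps matrices small; geometry tests use the
# full-rate default.
wf10k <- generate_waveform(adc_rate = 1e4)
tpl10k <- make_templates(wf10k)

# Small noiseless session: 6 trials, no drift/noise/artifacts.
clean_session <- function(n_trials = 6, seed = 11, ...) {
  tr <- simulate_trials("shape", n_trials, success_rate = 1, seed = seed)
  sim <- simulate_fscv_session(tr, tpl10k, noise_sd = 0, drift_rate = 0,
                               drift_rw_sd = 0, ph_amp = 0,
                               artifact_rate = 0, seed = seed + 1, ...)
  list(trials = tr, sim = sim)
}

# Matched-noise PCR model for gating tests.
fit_session_model <- function(seed = 21, n_per = 40, noise_sd = 0.1) {
  std <- make_standards(tpl10k, n_per = n_per, noise_sd = noise_sd,
                        seed = seed)
  fit_pcr(std$standards, std$concentrations, k = 4)
}
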