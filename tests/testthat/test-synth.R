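# Synthetic-data generator: waveform geometry, templates, trials, sessions.

test_that("scan waveform has the standard triangular geometry", {
  wf <- generate_waveform()
  expect_equal(wf$duration, 2 * (1.3 - (-0.4)) / 400)   # 8.5 ms
  expect_equal(wf$n_samples, 850L)
  expect_equal(wf$frame_rate, 10)
  expect_identical(wf$potentials[1], -0.4)
  expect_equal(max(wf$potentials), 1.3)
  # apex at the midpoint sample, closing sample within one ADC step of start
  expect_lte(abs(which.max(wf$potentials) - wf$n_samples / 2), 1)
  expect_lt(abs(wf$potentials[wf$n_samples] - wf$v_start),
            wf$scan_rate / wf$adc_rate + 1e-12)
  # slope magnitude equals the scan rate everywhere off the apex
  dv <- diff(wf$potentials) * wf$adc_rate
  expect_true(all(abs(abs(dv) - 400) < 1e-6))
})

test_that("waveform configuration errors are caught", {
  expect_error(generate_waveform(v_start = 1.3, v_peak = -0.4), "v_peak")
  expect_error(generate_waveform(repetition_interval = 0.008),
               class = "config_error")
})

test_that("dopamine template peaks at the printed redox potentials", {
  da <- tpl10k$templates["dopamine", ]
  expect_equal(peak_potential(da, wf10k, "anodic", "max"), 0.6,
               tolerance = 0.021)
  expect_equal(peak_potential(da, wf10k, "cathodic", "min"), -0.2,
               tolerance = 0.021)
  # full-rate waveform puts them exactly on the grid
  tpl <- make_templates(generate_waveform())
  expect_equal(peak_potential(tpl$templates["dopamine", ],
                              tpl$waveform, "anodic", "max"), 0.6)
  expect_equal(peak_potential(tpl$templates["dopamine", ],
                              tpl$waveform, "cathodic", "min"), -0.2)
})

test_that("movement template is uncorrelated with dopamine and peaks are validated", {
  r <- cor(tpl10k$templates["movement", ], tpl10k$templates["dopamine", ])
  expect_lt(abs(r), 0.3)
  expect_equal(ncol(tpl10k$templates), wf10k$n_samples)
  expect_error(make_templates(wf10k, da_ox_v = 2), class = "config_error")
})

test_that("trial simulation honors forced fraction, ordering and determinism", {
  tr <- simulate_trials("shape", 100, seed = 1)
  expect_equal(sum(tr$type == "forced"), 25L)
  expect_true(all(tr$t_central < tr$t_value & tr$t_value < tr$t_reward))
  expect_equal(tr$t_value - tr$t_central, rep(2, 100))
  expect_equal(tr$t_reward - tr$t_value, rep(4, 100))
  expect_identical(tr, simulate_trials("shape", 100, seed = 1))
  expect_true(all(simulate_trials("direction", 20, seed = 2)$type ==
                    "forced"))
  expect_error(simulate_trials("saccade", 10), "arg")
})

test_that("fscv session ground truth is exact by construction", {
  cs <- clean_session()
  sim <- cs$sim
  # no analytes, no drift, no noise: every frame equals the background
  flat <- simulate_fscv_session(cs$trials, tpl10k, da_large = 0,
                                da_small = 0, ph_amp = 0, noise_sd = 0,
                                drift_rate = 0, drift_rw_sd = 0,
                                artifact_rate = 0, seed = 3)
  expect_equal(max(apply(flat$colorplot$currents, 2, function(z)
    diff(range(z)))), 0)
  # a single injected transient peaks exactly at the configured amplitude
  tr1 <- simulate_trials("shape", 1, success_rate = 1, seed = 13)
  sim1 <- simulate_fscv_session(tr1, tpl10k, noise_sd = 0, drift_rate = 0,
                                drift_rw_sd = 0, ph_amp = 0,
                                artifact_rate = 0,
                                da_large = 100, da_small = 100, seed = 14)
  expect_equal(max(sim1$truth$da_nM), 100)
  # reward ordering holds in the ground truth post-cue windows
  post_mean <- function(rw) {
    rows <- cs$trials$reward == rw
    mean(sapply(cs$trials$t_value[rows], function(tv) {
      i <- findInterval(tv, sim$colorplot$frame_times)
      mean(sim$truth$da_nM[i:(i + 20)])
    }))
  }
  expect_gt(post_mean("large"), post_mean("small"))
  # determinism
  sim2 <- simulate_fscv_session(cs$trials, tpl10k, noise_sd = 0,
                                drift_rate = 0, drift_rw_sd = 0,
                                ph_amp = 0, artifact_rate = 0, seed = 12)
  expect_identical(sim$colorplot$currents, sim2$colorplot$currents)
})

test_that("ephys session honors its switches and repeats under a seed", {
  tr <- simulate_trials("direction", 4, success_rate = 1, seed = 5)
  nospikes <- simulate_ephys_session(tr, fs = 2000,
                                     spike_params = list(amp = 0), seed = 6)
  expect_length(nospikes$truth$spike_times, 0)
  again <- simulate_ephys_session(tr, fs = 2000,
                                  spike_params = list(amp = 0), seed = 6)
  expect_identical(nospikes$trace$samples, again$trace$samples)
  expect_error(
    simulate_ephys_session(tr, fs = 2000,
                           artifact_params = list(duration = 0.2)),
    class = "config_error")
})

test_that("artifact train concentrates power at 10 Hz harmonics", {
  tr <- simulate_trials("direction", 4, success_rate = 1, seed = 5)
  pure <- simulate_ephys_session(tr, fs = 2000, pink_sd = 0, white_sd = 0,
                                 beta_params = list(amp = 0),
                                 spike_params = list(amp = 0),
                                 quantize = FALSE, seed = 7)
  x <- pure$trace$samples
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * 2000 / n
  harm <- sapply(seq(10, 90, by = 10), function(h) which.min(abs(f - h)))
  offh <- sapply(seq(15, 95, by = 10), function(h) which.min(abs(f - h)))
  expect_gt(sum(P[harm]), 1e3 * sum(P[offh]))
  # amplitude 0 leaves no 10 Hz-locked component
  none <- simulate_ephys_session(tr, fs = 2000, pink_sd = 0, white_sd = 1,
                                 beta_params = list(amp = 0),
                                 spike_params = list(amp = 0),
                                 artifact_params = list(amp = 0),
                                 quantize = FALSE, seed = 8)
  Pn <- Mod(stats::fft(none$trace$samples))^2 / n
  expect_lt(mean(Pn[harm]), 10 * mean(Pn[offh]))
})
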