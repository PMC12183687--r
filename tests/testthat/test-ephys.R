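# Electrophysiology: referencing, artifact removal, beta power, spikes,
# PSTH, ISI.

test_that("bipolar referencing cancels common-mode signal exactly", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  shared <- 50 * sin(2 * pi * 7 * t)
  a <- new_ephys_trace(shared + sin(2 * pi * 20 * t), fs, channel = "a")
  b <- new_ephys_trace(shared + cos(2 * pi * 22 * t), fs, channel = "b")
  d <- bipolar_reference(a, b)
  expect_equal(d$samples, sin(2 * pi * 20 * t) - cos(2 * pi * 22 * t))
  expect_identical(d$reference, c("a", "b"))
  expect_equal(bipolar_reference(a, a)$samples, rep(0, length(t)))
  bad <- new_ephys_trace(shared, 1000)
  expect_error(bipolar_reference(a, bad), class = "validation_error")
})

test_that("spectral interpolation touches only the targeted bins", {
  set.seed(31)
  fs <- 1000
  x <- rnorm(20 * fs)
  tr <- new_ephys_trace(x, fs)
  out <- remove_artifacts_spectral(tr, scan_rate_hz = 10, n_harmonics = 5)
  X0 <- stats::fft(x)
  X1 <- stats::fft(out$samples)
  n <- length(x)
  db <- Mod(X1 - X0)
  changed <- which(db > 1e-6 * sqrt(n))
  k_expect <- unlist(lapply(1:5, function(h) {
    k0 <- round(h * 10 * n / fs)
    c(k0 - 1, k0, k0 + 1)
  }))
  k_expect <- sort(c(k_expect + 1, n - k_expect + 1))   # + mirrors
  expect_true(all(changed %in% k_expect))
})

test_that("scan-frequency harmonics are flattened to the flanking floor", {
  tr <- simulate_trials("direction", 8, success_rate = 1, seed = 41)
  sim <- simulate_ephys_session(tr, fs = 1000,
                                spike_params = list(amp = 0), seed = 42)
  clean <- remove_artifacts_spectral(sim$trace)
  n <- length(clean$samples)
  P <- Mod(stats::fft(clean$samples))^2 / n
  f <- (seq_len(n) - 1) * 1000 / n
  for (h in c(10, 20, 30)) {
    k <- which.min(abs(f - h))
    flank <- c(k - (3:5), k + (3:5))
    expect_lt(P[k], 2 * median(P[flank]))
  }
})

test_that("beta envelope survives artifact removal within 10% RMS", {
  tr <- simulate_trials("direction", 8, success_rate = 1, seed = 51)
  with_art <- simulate_ephys_session(tr, fs = 1000,
                                     spike_params = list(amp = 0),
                                     seed = 52)
  no_art <- simulate_ephys_session(tr, fs = 1000,
                                   spike_params = list(amp = 0),
                                   artifact_params = list(amp = 0),
                                   seed = 52)
  env_clean <- beta_power(no_art$trace)
  env_fixed <- beta_power(remove_artifacts_spectral(with_art$trace))
  mid <- seq(2000, length(env_clean$power) - 2000)
  rms <- function(z) sqrt(mean(z^2))
  expect_lt(rms(env_fixed$power[mid] - env_clean$power[mid]),
            0.1 * rms(env_clean$power[mid]))
})

test_that("time-domain interpolation is a no-op off the excision windows", {
  set.seed(61)
  fs <- 30000
  x <- rnorm(fs)                      # 1 s
  tr <- new_ephys_trace(x, fs)
  expect_identical(remove_artifacts_time(tr, numeric(0))$samples, x)
  at <- c(0.2, 0.5, 0.8)
  out <- remove_artifacts_time(tr, at)
  gap <- rep(FALSE, fs)
  for (t0 in at) {
    gap[floor((t0 - 0.001) * fs):ceiling((t0 + 0.0105) * fs) + 1] <- TRUE
  }
  expect_identical(out$samples[!gap], x[!gap])
  expect_false(identical(out$samples[gap], x[gap]))
  expect_error(remove_artifacts_time(tr, c(0.2, 0.205)),
               class = "validation_error")
})

test_that("a spike between artifacts is preserved sample-exactly", {
  fs <- 30000
  x <- numeric(fs)
  spike_idx <- round(0.25 * fs) + (0:30)
  x[spike_idx] <- -80 * exp(-((0:30) - 10)^2 / 20)
  tr <- new_ephys_trace(x, fs)
  out <- remove_artifacts_time(tr, c(0.1, 0.4))
  expect_identical(out$samples[spike_idx], x[spike_idx])
})

test_that("beta power reproduces the analytic response of pure tones", {
  fs <- 1000
  t <- (0:(30 * fs - 1)) / fs
  env0 <- beta_power(new_ephys_trace(numeric(length(t)), fs))
  expect_equal(max(env0$power), 0)
  env20 <- beta_power(new_ephys_trace(sin(2 * pi * 20 * t), fs))
  mid <- (5 * fs):(25 * fs)
  expect_equal(mean(env20$power[mid]), 1, tolerance = 0.05)
  env50 <- beta_power(new_ephys_trace(sin(2 * pi * 50 * t), fs))
  expect_lt(max(env50$power[mid]), 0.01)       # >= 20 dB rejection
  expect_true(all(env20$power >= 0))
  expect_error(beta_power(new_ephys_trace(t, fs), band = c(28, 13)),
               class = "validation_error")
})

test_that("beta power is insensitive to trace padding", {
  set.seed(71)
  fs <- 1000
  x <- rnorm(10 * fs)
  tr <- new_ephys_trace(x, fs)
  padded <- new_ephys_trace(c(numeric(fs), x, numeric(fs)), fs)
  a <- beta_power(tr)$power
  b <- beta_power(padded)$power[(fs + 1):(11 * fs)]
  mid <- (2 * fs):(8 * fs)
  expect_lt(max(abs(a[mid] - b[mid])) / max(a[mid]), 0.01)
})

test_that("spike detection is quiet on silence and calibrated on noise", {
  fs <- 30000
  expect_length(detect_spikes(new_ephys_trace(numeric(fs), fs))$times, 0)
  set.seed(81)
  noise <- new_ephys_trace(rnorm(20 * fs), fs)
  sp <- detect_spikes(noise)
  # Monte-Carlo-derived bound for -4 sigma crossings of band-limited
  # Gaussian noise (Rice rate ~1/s); well below any physiological rate
  expect_lt(length(sp$times) / 20, 2)
  # sigma estimates the in-band noise: sqrt(band width / Nyquist)
  expect_equal(sp$sigma, sqrt((6000 - 300) / 15000), tolerance = 0.1)
})

test_that("spikes at high SNR are recovered nearly perfectly", {
  tr <- simulate_trials("direction", 4, success_rate = 1, seed = 91)
  sim <- simulate_ephys_session(tr, fs = 30000,
                                beta_params = list(amp = 0),
                                artifact_params = list(amp = 0),
                                pink_sd = 4, white_sd = 8, seed = 92)
  sp <- detect_spikes(sim$trace)
  sc <- match_spikes(sp$times, sim$truth$spike_times)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
  expect_equal(nrow(sp$snippets), length(sp$times))
  expect_true(all(diff(sp$times) > sp$lockout_s))
})

test_that("PSTH matches Poisson theory and handles empty input", {
  set.seed(101)
  lambda <- 20
  events <- seq(10, 10 * 200, by = 10)
  spikes <- sort(runif(rpois(1, lambda * 2010), 0, 2010))
  ps <- psth(spikes, events, window = c(-1, 2), bin_width = 0.1)
  se <- sqrt(lambda / (length(events) * 0.1))
  expect_true(all(abs(ps$rate["all", ] - lambda) < 3 * se + 1e-9))
  ps0 <- psth(numeric(0), events, window = c(-1, 2), bin_width = 0.1)
  expect_true(all(ps0$rate == 0))
  expect_warning(
    ps2 <- psth(spikes, events,
                condition_labels = factor(rep("a", length(events)),
                                          levels = c("a", "b"))),
    "no events")
  expect_true(all(ps2$rate["b", ] == 0))
  expect_error(psth(spikes, events, bin_width = 0),
               class = "validation_error")
})

test_that("PSTH resolves a rate step scaled by condition", {
  set.seed(111)
  events <- seq(10, 10 * 200, by = 10)
  base <- 15
  spikes <- sort(unlist(lapply(events, function(e) {
    pre <- runif(rpois(1, base), e - 1, e)
    post <- runif(rpois(1, 2 * base), e, e + 1)
    c(pre, post)
  })))
  ps <- psth(spikes, events, window = c(-1, 1), bin_width = 0.25)
  pre_rate <- mean(ps$rate["all", ps$time_s < 0])
  post_rate <- mean(ps$rate["all", ps$time_s > 0])
  expect_equal(post_rate / pre_rate, 2, tolerance = 0.1)
})

test_that("ISI histogram conserves counts and respects refractoriness", {
  regular <- seq(0, 5, by = 0.1)
  h <- isi_histogram(regular)
  expect_equal(sum(h$count), length(regular) - 1)
  # all mass within one bin of the 100 ms interval (fp jitter straddles)
  expect_equal(sum(h$count[abs(h$isi_s - 0.1) < 0.0015]),
               length(regular) - 1)
  expect_equal(nrow(isi_histogram(c(1))), 0)
  set.seed(121)
  # refractory Poisson train: exponential gaps floored at 2 ms
  gaps <- pmax(rexp(3000, 50), 0) + 0.002
  spk <- cumsum(gaps)
  hr <- isi_histogram(spk)
  expect_equal(sum(hr$count), length(spk) - 1)
  expect_true(all(hr$count[hr$isi_s < 0.002] == 0))
})
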