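# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic substream seeds derived from a session seed. Kept below
# 2^31 - 1 so they remain valid R integers.
substream <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1009 * k) %% 2147483563L)
}

# Analytic signal via FFT: x + i * H(x). Standard construction; the
# magnitude is the instantaneous amplitude envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase Butterworth bandpass (applied forward-backward).
bandpass_filtfilt <- function(x, band, fs, order = 4) {
  nyq <- fs / 2
  if (band[1] >= band[2]) stop("band edges inverted: low >= high")
  if (band[2] >= nyq) stop("band upper edge at or above Nyquist")
  bf <- signal::butter(order, band / nyq, type = "pass")
  signal::filtfilt(bf, x)
}

# Smooth with a unit-area Hanning window; reflective padding keeps edge
# effects contained so the output is insensitive to how the trace was
# padded upstream.
hanning_smooth <- function(x, window_samples) {
  m <- max(3L, as.integer(window_samples))
  w <- signal::hanning(m)
  w <- w / sum(w)
  n <- length(x)
  pad <- min(m, n - 1L)
  xe <- c(x[pad:1], x, x[n:(n - pad + 1L)])
  y <- stats::filter(xe, w, sides = 2)
  as.numeric(y[(pad + 1L):(pad + n)])
}

# Polyphase-style integer-factor downsampling chain; falls back to an
# anti-aliased linear interpolation for non-integer ratios.
resample_to <- function(x, fs, target_fs) {
  if (isTRUE(all.equal(fs, target_fs))) return(x)
  if (fs < target_fs) stop("upsampling not supported; fs below target rate")
  ratio <- fs / target_fs
  if (isTRUE(all.equal(ratio, round(ratio)))) {
    q <- as.integer(round(ratio))
    for (f in factor_chain(q)) x <- signal::decimate(x, f, ftype = "iir")
    return(x)
  }
  bf <- signal::butter(8, (0.45 * target_fs) / (fs / 2), type = "low")
  xl <- signal::filtfilt(bf, x)
  t_old <- seq_along(x) / fs
  t_new <- seq(t_old[1], t_old[length(t_old)], by = 1 / target_fs)
  stats::approx(t_old, xl, xout = t_new)$y
}

# Decompose an integer downsampling factor into stages <= 10.
factor_chain <- function(q) {
  stages <- integer(0)
  for (f in c(10L, 8L, 7L, 6L, 5L, 4L, 3L, 2L)) {
    while (q %% f == 0L && q > 10L) {
      stages <- c(stages, f)
      q <- q %/% f
    }
  }
  c(stages, q)
}

stop_with <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "fscvephys_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
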