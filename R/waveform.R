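#' Build the applied FSCV scan waveform
#'
#' Constructs the triangular potential ramp applied to the carbon-fiber
#' electrode on every scan: a linear sweep from `v_start` up to `v_peak` and
#' symmetrically back, sampled at the acquisition ADC rate. The standard
#' dopamine waveform sweeps -0.4 to 1.3 V at 400 V/s, repeated every 100 ms
#' (10 Hz effective frame rate).
#'
#' The ramp is sampled on the uniform grid `t = (0:(n-1))/adc_rate` with
#' `n = 2 (v_peak - v_start) / scan_rate * adc_rate` samples, so the first
#' sample sits exactly at `v_start`, the apex exactly at `v_peak` at the
#' midpoint sample, and the final sample one ADC step above `v_start` (the
#' scan closes at `v_start` on the first sample of the inter-scan holding
#' period).
#'
#' @param v_start holding/start potential (V).
#' @param v_peak apex potential (V); must exceed `v_start`.
#' @param scan_rate sweep rate (V/s).
#' @param repetition_interval time between scan onsets (s); the effective
#'   frame rate is its reciprocal.
#' @param adc_rate ADC sampling rate within a scan (samples/s).
#' @return An object of class `scan_waveform`: list with the per-sample
#'   applied `potentials`, the scan `duration` (s), `n_samples`,
#'   `frame_rate` (Hz) and the generating parameters.
#' @examples
#' wf <- generate_waveform()
#' wf$duration      # 0.0085 s
#' wf$n_samples     # 850
#' wf$frame_rate    # 10 Hz
#' @export
generate_waveform <- function(v_start = -0.4, v_peak = 1.3, scan_rate = 400,
                              repetition_interval = 0.1, adc_rate = 1e5) {
  if (v_peak <= v_start) stop_with("config_error", "v_peak must exceed v_start")
  if (scan_rate <= 0) stop_with("config_error", "scan_rate must be positive")
  duration <- 2 * (v_peak - v_start) / scan_rate
  if (duration >= repetition_interval) {
    stop_with("config_error",
              "scan duration must be shorter than the repetition interval")
  }
  n <- as.integer(round(duration * adc_rate))
  if (n < 4L) stop_with("config_error", "adc_rate too low to sample the scan")
  t <- (seq_len(n) - 1L) / adc_rate
  half <- duration / 2
  pot <- ifelse(t <= half, v_start + scan_rate * t,
                v_peak - scan_rate * (t - half))
  structure(list(
    potentials = pot,
    v_start = v_start, v_peak = v_peak,
    scan_rate = scan_rate,
    repetition_interval = repetition_interval,
    adc_rate = adc_rate,
    duration = duration,
    n_samples = n,
    frame_rate = 1 / repetition_interval
  ), class = "scan_waveform")
}

#' @export
print.scan_waveform <- function(x, ...) {
  cat(sprintf(
    "FSCV scan waveform: %.2g to %.2g V at %g V/s, every %g ms (%g Hz)\n",
    x$v_start, x$v_peak, x$scan_rate, 1000 * x$repetition_interval,
    x$frame_rate))
  cat(sprintf("  %d samples/scan at %g kHz ADC (%.2f ms scan)\n",
              x$n_samples, x$adc_rate / 1000, 1000 * x$duration))
  invisible(x)
}

# Index of the sample on the anodic (rising) sweep closest to `v`, and the
# same for the cathodic (falling) sweep. Used to place analyte peaks.
sweep_index <- function(waveform, v, sweep = c("anodic", "cathodic")) {
  sweep <- match.arg(sweep)
  apex <- which.max(waveform$potentials)
  idx <- if (sweep == "anodic") seq_len(apex) else apex:waveform$n_samples
  idx[which.min(abs(waveform$potentials[idx] - v))]
}
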