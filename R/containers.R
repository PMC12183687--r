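# Core data containers: color plots (FSCV) and wide-band ephys traces.

#' Construct an FSCV color plot
#'
#' The central FSCV object: per-scan voltammograms stacked into a
#' frames x samples current matrix on the 10 Hz (or configured) frame grid,
#' with the generating waveform and the timestamped event-code stream.
#'
#' @param currents numeric matrix, frames x samples-per-scan (nA).
#' @param frame_times scan onset times (s), strictly increasing, uniform.
#' @param waveform the `scan_waveform` applied on every scan.
#' @param events `data.frame` with `time_s`, `code`, `label`.
#' @param meta optional named list of provenance metadata.
#' @return An object of class `color_plot`.
#' @export
new_color_plot <- function(currents, frame_times, waveform, events,
                           meta = list()) {
  currents <- as.matrix(currents)
  if (nrow(currents) != length(frame_times)) {
    stop_with("dimension_error", "frame_times length must match frame count")
  }
  if (ncol(currents) != waveform$n_samples) {
    stop_with("dimension_error",
              "sample dimension must equal waveform samples-per-scan")
  }
  d <- diff(frame_times)
  if (length(d) && (any(d <= 0) ||
                    max(abs(d - waveform$repetition_interval)) >
                    1 / waveform$adc_rate)) {
    stop_with("validation_error",
              "frame_times must increase uniformly at the repetition interval")
  }
  structure(list(currents = currents, frame_times = frame_times,
                 waveform = waveform, events = events, meta = meta),
            class = "color_plot")
}

#' @export
print.color_plot <- function(x, ...) {
  cat(sprintf("FSCV color plot: %d frames x %d samples (%.1f s at %g Hz)\n",
              nrow(x$currents), ncol(x$currents),
              diff(range(x$frame_times)), x$waveform$frame_rate))
  if (!is.null(x$meta$background_ref_index)) {
    cat(sprintf("  background-subtracted (reference frame %d)\n",
                x$meta$background_ref_index))
  }
  invisible(x)
}

#' @export
dim.color_plot <- function(x) dim(x$currents)

#' Construct a wide-band electrophysiology trace
#'
#' @param samples voltage samples (uV).
#' @param fs sampling rate (samples/s).
#' @param channel channel identifier.
#' @param reference `"ground"` or a bipolar descriptor (set by
#'   [bipolar_reference()]).
#' @param events `data.frame` with `time_s`, `code`, `label` (8-bit codes).
#' @param adc_gain_uV ADC step size if the trace is quantized (uV/count).
#' @return An object of class `ephys_trace`.
#' @export
new_ephys_trace <- function(samples, fs, channel = "ch1",
                            reference = "ground", events = NULL,
                            adc_gain_uV = NULL) {
  if (fs <= 0) stop_with("validation_error", "fs must be positive")
  if (any(!is.finite(samples))) {
    stop_with("validation_error", "samples must be finite")
  }
  structure(list(samples = as.numeric(samples), fs = fs, channel = channel,
                 reference = reference, events = events,
                 adc_gain_uV = adc_gain_uV),
            class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("EPhys trace %s [%s]: %d samples at %g kHz (%.1f s)\n",
              x$channel, paste(x$reference, collapse = "-"),
              length(x$samples), x$fs / 1000, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.ephys_trace <- function(x) length(x$samples)

# Quantize a trace to the int16 grid of a +-1 mV headstage input range.
quantize_trace <- function(trace, range_uV = 1000) {
  gain <- 2 * range_uV / 65536
  counts <- pmin(32767, pmax(-32768, round(trace$samples / gain)))
  trace$samples <- counts * gain
  trace$adc_gain_uV <- gain
  trace
}

# Nearest frame at or before a time point (ties toward earlier).
frame_at <- function(frame_times, time_s) {
  i <- findInterval(time_s, frame_times)
  if (i < 1L || time_s > frame_times[length(frame_times)] +
      diff(frame_times[1:2])) {
    stop_with("validation_error", "reference time outside the recording")
  }
  i
}
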