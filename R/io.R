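# Session bundle I/O: flat binaries with structured-text sidecars and
# checksums. Color plots are stored as little-endian float64, ephys traces
# as little-endian int16 counts with a gain sidecar, events as TSV,
# metadata and ground truth as JSON.

#' Write a recording session to a directory
#'
#' Persists a (typically synthetic) session as plain files: the color-plot
#' current matrix as flat little-endian float64 (`colorplot.f64`,
#' frame-major), the ephys trace as little-endian int16 counts
#' (`ephys.i16`) with its ADC gain in the sidecar, events as a TSV table
#' (`events.tsv`: `time_s`, `code`, `label`), optional ground truth as
#' JSON, and a `metadata.json` sidecar holding dimensions, waveform and
#' acquisition parameters, the seed/config snapshot and MD5 checksums of
#' every data file.
#'
#' @param session list with any of `colorplot` (a `color_plot`), `trace`
#'   (an `ephys_trace`), `truth`, plus optional `seed` and `config`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the bundle manifest (paths + checksums).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = 1L,
               package_version = as.character(utils::packageVersion("fscvephys")),
               seed = session$seed, config = session$config)
  files <- character(0)

  if (!is.null(session$colorplot)) {
    cp <- session$colorplot
    path <- file.path(dir, "colorplot.f64")
    con <- file(path, "wb")
    writeBin(as.numeric(t(cp$currents)), con, size = 8, endian = "little")
    close(con)
    files <- c(files, "colorplot.f64")
    wf <- cp$waveform
    meta$colorplot <- list(
      n_frames = nrow(cp$currents), n_samples = ncol(cp$currents),
      t0 = cp$frame_times[1],
      waveform = list(v_start = wf$v_start, v_peak = wf$v_peak,
                      scan_rate = wf$scan_rate,
                      repetition_interval = wf$repetition_interval,
                      adc_rate = wf$adc_rate),
      frame_rate = wf$frame_rate,
      meta = cp$meta)
    ev <- cp$events
    if (!is.null(ev)) {
      evp <- file.path(dir, "events.tsv")
      utils::write.table(
        data.frame(timestamp_s = sprintf("%.17g", ev$time_s),
                   code = ev$code, label = ev$label),
        evp, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, "events.tsv")
    }
  }

  if (!is.null(session$trace)) {
    tr <- session$trace
    gain <- tr$adc_gain_uV %||% (2000 / 65536)
    counts <- as.integer(round(tr$samples / gain))
    path <- file.path(dir, "ephys.i16")
    con <- file(path, "wb")
    writeBin(counts, con, size = 2, endian = "little")
    close(con)
    files <- c(files, "ephys.i16")
    meta$ephys <- list(n_samples = length(tr$samples), fs = tr$fs,
                       adc_gain_uV = gain, channel = tr$channel,
                       reference = tr$reference)
  }

  if (!is.null(session$truth)) {
    jsonlite::write_json(session$truth, file.path(dir, "groundtruth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, "groundtruth.json")
  }

  meta$checksums <- as.list(tools::md5sum(file.path(dir, files)))
  names(meta$checksums) <- files
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(dir = dir, files = files, checksums = meta$checksums))
}

#' Read a session bundle
#'
#' Loads a directory written by [write_session()], verifying the MD5
#' checksum of every data file against the sidecar, the file sizes against
#' the declared dimensions, and the waveform/frame-rate consistency.
#' Failures raise distinct error classes (`checksum_error`,
#' `missing_sidecar_error`, `dimension_error`, `validation_error`).
#'
#' @param dir the bundle directory.
#' @return list with `colorplot`, `trace`, `truth`, `meta` (those present).
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "metadata.json")
  if (!file.exists(mpath)) {
    stop_with("missing_sidecar_error", "metadata.json sidecar is missing")
  }
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  for (f in names(meta$checksums)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      stop_with("missing_sidecar_error", sprintf("file '%s' is missing", f))
    }
    if (unname(tools::md5sum(p)) != meta$checksums[[f]]) {
      stop_with("checksum_error",
                sprintf("checksum mismatch for '%s'", f))
    }
  }
  out <- list(meta = meta)

  if (!is.null(meta$colorplot)) {
    cpm <- meta$colorplot
    nf <- cpm$n_frames; ns <- cpm$n_samples
    p <- file.path(dir, "colorplot.f64")
    expected <- 8 * nf * ns
    if (file.info(p)$size != expected) {
      stop_with("dimension_error", sprintf(
        "colorplot.f64 is %d bytes; metadata declares %d frames x %d samples (%d bytes)",
        file.info(p)$size, nf, ns, expected))
    }
    con <- file(p, "rb")
    vals <- readBin(con, "numeric", n = nf * ns, size = 8, endian = "little")
    close(con)
    wfp <- cpm$waveform
    wf <- generate_waveform(wfp$v_start, wfp$v_peak, wfp$scan_rate,
                            wfp$repetition_interval, wfp$adc_rate)
    if (wf$n_samples != ns) {
      stop_with("validation_error", sprintf(
        "field 'waveform' inconsistent: implies %d samples/scan, data has %d",
        wf$n_samples, ns))
    }
    if (!isTRUE(all.equal(wf$frame_rate, cpm$frame_rate))) {
      stop_with("validation_error", sprintf(
        "field 'frame_rate' (%g) disagrees with waveform repetition interval (%g Hz)",
        cpm$frame_rate, wf$frame_rate))
    }
    ev <- NULL
    evp <- file.path(dir, "events.tsv")
    if (file.exists(evp)) {
      raw <- utils::read.table(evp, header = TRUE, sep = "\t",
                               colClasses = c("character", "integer",
                                              "character"))
      ev <- data.frame(time_s = as.numeric(raw$timestamp_s),
                       code = raw$code, label = raw$label)
    }
    frame_times <- cpm$t0 +
      (seq_len(nf) - 1) * wfp$repetition_interval
    cpmeta <- as.list(cpm$meta)
    out$colorplot <- new_color_plot(
      matrix(vals, nf, ns, byrow = TRUE), frame_times, wf, ev, meta = cpmeta)
  }

  if (!is.null(meta$ephys)) {
    em <- meta$ephys
    p <- file.path(dir, "ephys.i16")
    expected <- 2 * em$n_samples
    if (file.info(p)$size != expected) {
      stop_with("dimension_error", sprintf(
        "ephys.i16 is %d bytes; metadata declares %d samples (%d bytes)",
        file.info(p)$size, em$n_samples, expected))
    }
    con <- file(p, "rb")
    counts <- readBin(con, "integer", n = em$n_samples, size = 2,
                      endian = "little", signed = TRUE)
    close(con)
    ev <- out$colorplot$events
    out$trace <- new_ephys_trace(counts * em$adc_gain_uV, em$fs,
                                 channel = em$channel,
                                 reference = unlist(em$reference),
                                 events = ev, adc_gain_uV = em$adc_gain_uV)
  }

  gtp <- file.path(dir, "groundtruth.json")
  if (file.exists(gtp)) {
    out$truth <- jsonlite::read_json(gtp, simplifyVector = TRUE)
  }
  out
}
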