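# Preprocessing: Butterworth band-pass (zero-phase by default), head
# truncation to a fixed analysis duration, and channel exclusion.

#' Band-pass filter specification
#'
#' @param low_hz lower cutoff (Hz).
#' @param high_hz upper cutoff (Hz); must satisfy
#'   `0 < low_hz < high_hz < fs/2` for any signal it is applied to.
#' @param order filter order (default 4).
#' @param zero_phase apply forward-backward (`filtfilt`) so the net phase
#'   response is zero (default `TRUE`).  Zero-phase application squares the
#'   magnitude response, doubling stopband attenuation in dB.
#' @return object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz, high_hz, order = 4L, zero_phase = TRUE) {
  if (!(is.numeric(low_hz) && is.numeric(high_hz) &&
        low_hz > 0 && high_hz > low_hz)) {
    stop("need 0 < low_hz < high_hz")
  }
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("order must be a positive integer")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = isTRUE(zero_phase)),
            class = "bandpass_spec")
}

#' Butterworth band-pass filtering of a recording
#'
#' Removes drift and out-of-band noise ahead of fractal-dimension
#' estimation.  Conventional bands are 1-40 Hz for EEG at 128 Hz and
#' 25-125 Hz for facial EMG at 256 Hz.
#'
#' @param record a [ts_record()].
#' @param spec a [bandpass_spec()].
#' @return a [ts_record()] of identical length and metadata.
#' @export
butterworth_bandpass <- function(record, spec) {
  stopifnot(inherits(record, "ts_record"), inherits(spec, "bandpass_spec"))
  nyq <- record$fs / 2
  if (spec$high_hz >= nyq) {
    stop(sprintf("invalid band: high_hz = %g >= Nyquist %g Hz",
                 spec$high_hz, nyq))
  }
  n <- length(record$samples)
  if (n <= 3L * spec$order) {
    stop(sprintf("signal too short to filter: %d samples, order %d",
                 n, spec$order))
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  x <- record$samples
  # odd-reflection padding: continues the signal without a level jump, so
  # filter edge transients decay inside the pads instead of contaminating
  # (and, via min-max normalization, dwarfing) the record
  pad <- min(n - 1L, max(512L, as.integer(round(3 * record$fs / spec$low_hz))))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  yp <- if (spec$zero_phase) {
    signal::filtfilt(bf, xp)
  } else {
    as.numeric(signal::filter(bf, xp))
  }
  y <- yp[(pad + 1L):(pad + n)]
  out <- record
  out$samples <- y
  out
}

#' Truncate a recording to its first `duration_s` seconds
#'
#' Recording devices with drifting sample clocks deliver slightly short
#' recordings; analyzing a fixed head segment (118.2 s by convention here)
#' keeps every record the same analytic length.
#'
#' @param record a [ts_record()].
#' @param duration_s target duration in seconds; the output keeps
#'   `floor(duration_s * fs)` samples from the start.
#' @return a truncated [ts_record()].
#' @export
truncate_record <- function(record, duration_s) {
  stopifnot(inherits(record, "ts_record"))
  n_keep <- floor(duration_s * record$fs)
  n <- length(record$samples)
  if (n < n_keep) {
    stop(sprintf(
      "insufficient data: need %d samples (%.4g s at %g Hz), have %d (short by %d)",
      n_keep, duration_s, record$fs, n, n_keep - n))
  }
  out <- record
  out$samples <- record$samples[seq_len(n_keep)]
  out
}

#' Drop channels by label
#'
#' @param records list of [ts_record()].
#' @param labels channel labels to remove.  Labels not present trigger a
#'   warning, not an error (a channel may be absent from some sessions).
#' @return surviving records, original order preserved.
#' @export
exclude_channels <- function(records, labels) {
  if (length(labels) == 0L) return(records)
  present <- vapply(records, function(r) r$channel, character(1))
  missing <- setdiff(labels, present)
  if (length(missing) > 0L) {
    warning("exclude_channels: label(s) not present: ",
            paste(missing, collapse = ", "))
  }
  kept <- records[!(present %in% labels)]
  if (length(kept) == 0L) warning("exclude_channels: all channels excluded")
  kept
}
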