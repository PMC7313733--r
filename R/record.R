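#' @keywords internal
"_PACKAGE"

STIMULUS_LEVELS <- c("first", "second", "third", "fourth", "fifth", "sixth")

#' Viewing condition implied by a stimulus label
#'
#' The six stimuli are three content-matched pairs: the first, third and
#' fifth stimuli are presented flat (2D), the second, fourth and sixth
#' stereoscopically (3D).
#'
#' @param stimulus_id character vector of stimulus labels
#'   (`"first"` ... `"sixth"`).
#' @return character vector of `"2D"` / `"3D"`.
#' @export
#' @examples
#' stimulus_condition(c("first", "second"))
stimulus_condition <- function(stimulus_id) {
  idx <- match(stimulus_id, STIMULUS_LEVELS)
  if (anyNA(idx)) {
    stop("unknown stimulus_id: ",
         paste(unique(stimulus_id[is.na(idx)]), collapse = ", "))
  }
  ifelse(idx %% 2L == 1L, "2D", "3D")
}

#' Single-channel recording with study metadata
#'
#' Container for one channel's samples together with its sampling rate and
#' the study coordinates (subject, stimulus, viewing condition, session,
#' modality) needed by the analysis pipeline.
#'
#' @param samples numeric vector of amplitude values (arbitrary units,
#'   typically microvolts); must be nonempty and finite.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel channel label.
#' @param subject_id subject identifier.
#' @param stimulus_id one of `"first"` ... `"sixth"`.
#' @param condition `"2D"` or `"3D"`; must agree with `stimulus_id`
#'   (defaults to the condition the stimulus implies).
#' @param session session number (integer >= 1).
#' @param modality `"EEG"` or `"EMG"`.
#' @return an object of class `ts_record`.
#' @export
ts_record <- function(samples, fs, channel = "ch1",
                      subject_id = "S1", stimulus_id = "first",
                      condition = stimulus_condition(stimulus_id),
                      session = 1L, modality = "EEG") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be nonempty")
  if (!all(is.finite(samples))) stop("samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar (Hz)")
  }
  stimulus_id <- match.arg(stimulus_id, STIMULUS_LEVELS)
  implied <- stimulus_condition(stimulus_id)
  condition <- match.arg(condition, c("2D", "3D"))
  if (condition != implied) {
    stop(sprintf("condition '%s' disagrees with stimulus '%s' (implies '%s')",
                 condition, stimulus_id, implied))
  }
  session <- as.integer(session)
  if (is.na(session) || session < 1L) stop("session must be an integer >= 1")
  modality <- match.arg(modality, c("EEG", "EMG"))
  structure(
    list(samples = samples, fs = fs, channel = as.character(channel),
         subject_id = as.character(subject_id), stimulus_id = stimulus_id,
         condition = condition, session = session, modality = modality),
    class = "ts_record")
}

#' @export
print.ts_record <- function(x, ...) {
  cat(sprintf("<ts_record> %s %s | subject %s, stimulus %s (%s), session %d\n",
              x$modality, x$channel, x$subject_id, x$stimulus_id,
              x$condition, x$session))
  cat(sprintf("  %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param record a [ts_record()].
#' @return duration in seconds.
#' @export
record_duration <- function(record) {
  stopifnot(inherits(record, "ts_record"))
  length(record$samples) / record$fs
}
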