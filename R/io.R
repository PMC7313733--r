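# Plain-text I/O: wide CSV (one column per channel) plus a YAML/JSON
# manifest carrying the metadata a bare CSV cannot.

#' Read a multi-channel signal CSV
#'
#' The CSV is expected in wide form: a header row of channel labels and one
#' row per sample, comma-separated, '.' decimal separator.  Metadata
#' (sampling rate, subject, stimulus, session, modality) comes from the
#' accompanying manifest entry, not the file.
#'
#' @param path CSV file path.
#' @param manifest_entry named list with at least `fs`; optionally
#'   `subject_id`, `stimulus_id`, `condition`, `session`, `modality`.
#' @return list of [ts_record()], one per column, in column order.
#' @export
read_signal_csv <- function(path, manifest_entry) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("empty signal file (header only): ", path)
  cols <- lapply(seq_along(df), function(j) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(x) & !is.na(df[[j]]) & df[[j]] != "")
    if (length(bad) > 0L || anyNA(x)) {
      row <- if (length(bad)) bad[1] else which(is.na(x))[1]
      stop(sprintf("non-numeric cell in %s at row %d, column '%s'",
                   path, row, names(df)[j]))
    }
    x
  })
  me <- manifest_entry
  lapply(seq_along(cols), function(j) {
    ts_record(cols[[j]], fs = me$fs, channel = names(df)[j],
              subject_id = me$subject_id %||% "S1",
              stimulus_id = me$stimulus_id %||% "first",
              session = me$session %||% 1L,
              modality = me$modality %||% "EEG")
  })
}

#' Write records sharing a recording to a wide CSV
#'
#' @param records list of [ts_record()] with identical length and `fs`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(records, path) {
  if (length(records) == 0L) stop("no records to write")
  lens <- vapply(records, function(r) length(r$samples), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("records have mismatched lengths: ",
         paste(unique(lens), collapse = ", "))
  }
  fss <- vapply(records, function(r) r$fs, numeric(1))
  if (length(unique(fss)) != 1L) stop("records have mismatched sampling rates")
  mat <- vapply(records, function(r) r$samples, numeric(lens[1]))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = lens[1])
  colnames(mat) <- vapply(records, function(r) r$channel, character(1))
  # %.12g keeps round-trips faithful well past 9 significant digits
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(colnames(mat), collapse = ","), con)
  body <- apply(mat, 1L, function(row)
    paste(sprintf("%.12g", row), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a study manifest (YAML or JSON)
#'
#' A manifest lists the recording files and their metadata. Required keys
#' per entry: `path`, `subject_id`, `stimulus_id`, `session`, `modality`,
#' `fs`; `condition` is optional (derived from the stimulus when absent).
#'
#' @param path manifest file (`.yaml`/`.yml` or `.json`).
#' @return list with elements `records` (list of entries),
#'   `fs_by_modality`, and `analysis_duration_s`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(m$records)) stop("manifest has no 'records' key: ", path)
  req <- c("path", "subject_id", "stimulus_id", "session", "modality", "fs")
  base <- dirname(path)
  m$records <- lapply(m$records, function(e) {
    miss <- setdiff(req, names(e))
    if (length(miss) > 0L) {
      stop("manifest entry missing keys: ", paste(miss, collapse = ", "))
    }
    if (!file.exists(e$path) && file.exists(file.path(base, e$path))) {
      e$path <- file.path(base, e$path)
    }
    if (!file.exists(e$path)) stop("manifest references missing file: ", e$path)
    e
  })
  m$fs_by_modality <- m$fs_by_modality %||% list(EEG = 128, EMG = 256)
  m$analysis_duration_s <- m$analysis_duration_s %||% 118.2
  m
}

#' Load every record a manifest references
#' @param manifest a manifest as returned by [read_manifest()].
#' @return flat list of [ts_record()].
#' @export
read_manifest_records <- function(manifest) {
  out <- lapply(manifest$records, function(e) read_signal_csv(e$path, e))
  do.call(c, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
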