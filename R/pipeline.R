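# End-to-end study pipeline: preprocess -> per-channel fractal dimension
# -> aggregate -> repeated-measures inference -> questionnaire scoring.
#
# Aggregation hierarchy: FD per channel, mean over channels, mean over
# sessions, one value per subject x stimulus x modality.  Stage order is
# fixed as filter -> truncate -> exclude channels.

#' Analysis configuration
#'
#' @param eeg_band,emg_band band-pass edges in Hz (defaults 1-40 for EEG,
#'   25-125 for EMG).
#' @param filter apply the band-pass stage (default `TRUE`).  Disabling it
#'   is useful when analyzing surrogate signals whose fractal structure
#'   spans all frequencies, since a band-pass removes the out-of-band part
#'   of that structure.
#' @param filter_order Butterworth order (default 4).
#' @param zero_phase forward-backward filtering (default `TRUE`).
#' @param analysis_duration_s head segment analyzed per recording
#'   (default 118.2 s).
#' @param exclude list of channel labels to drop, per modality, e.g.
#'   `list(EEG = c("EEG13", "EEG14"))`.
#' @param scales_cap maximum dyadic depth for box counting (default 8).
#' @param m amplitude intervals for the occupancy measure (default 100).
#' @param orders Renyi orders reported alongside the box-counting D.
#' @param alpha significance level (default 0.05).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(eeg_band = c(1, 40), emg_band = c(25, 125),
                            filter = TRUE,
                            filter_order = 4L, zero_phase = TRUE,
                            analysis_duration_s = 118.2,
                            exclude = list(),
                            scales_cap = 8L, m = 100L,
                            orders = c(0, 1, 2), alpha = 0.05) {
  structure(list(eeg_band = eeg_band, emg_band = emg_band,
                 filter = isTRUE(filter),
                 filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase),
                 analysis_duration_s = analysis_duration_s,
                 exclude = exclude, scales_cap = as.integer(scales_cap),
                 m = as.integer(m), orders = orders, alpha = alpha),
            class = "analysis_config")
}

#' Preprocess and estimate the fractal dimension of every record
#'
#' Applies the modality-specific Butterworth band-pass, truncates to the
#' analysis duration, drops excluded channels, and estimates the
#' box-counting dimension of each surviving record.
#'
#' @param records list of [ts_record()].
#' @param config an [analysis_config()].
#' @return data frame with one row per record: subject, stimulus,
#'   condition, session, modality, channel, `D`, `r_squared`.
#' @export
compute_fd_table <- function(records, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  labels_excl <- unlist(config$exclude, use.names = FALSE)
  if (length(labels_excl) > 0L) {
    records <- exclude_channels(records, labels_excl)
  }
  if (length(records) == 0L) stop("no records left to analyze")
  rows <- lapply(records, function(r) {
    band <- if (r$modality == "EEG") config$eeg_band else config$emg_band
    spec <- bandpass_spec(band[1], band[2], order = config$filter_order,
                          zero_phase = config$zero_phase)
    r <- tryCatch({
      if (config$filter) r <- butterworth_bandpass(r, spec)
      truncate_record(r, config$analysis_duration_s)
    },
      error = function(e) stop(sprintf(
        "preprocess failed for %s/%s/%s session %d channel %s: %s",
        r$subject_id, r$stimulus_id, r$modality, r$session, r$channel,
        conditionMessage(e)), call. = FALSE))
    poly <- normalize_graph(r)
    fd <- estimate_fd(box_count_curve(
      poly, dyadic_scales(nrow(poly), cap = config$scales_cap)))
    data.frame(subject_id = r$subject_id, stimulus_id = r$stimulus_id,
               condition = r$condition, session = r$session,
               modality = r$modality, channel = r$channel,
               D = fd$D, r_squared = fd$r_squared)
  })
  do.call(rbind, rows)
}

#' Aggregate per-channel dimensions to a subjects-by-stimuli table
#'
#' Mean over channels within subject/stimulus/session, then mean over
#' sessions.
#'
#' @param fd per-record data frame from [compute_fd_table()].
#' @param modality `"EEG"` or `"EMG"`.
#' @return numeric matrix, rows = subjects, columns = `first` ... `sixth`.
#' @export
aggregate_fd <- function(fd, modality) {
  fd <- fd[fd$modality == modality, , drop = FALSE]
  if (nrow(fd) == 0L) stop("no records for modality ", modality)
  by_sess <- stats::aggregate(D ~ subject_id + stimulus_id + session,
                              data = fd, FUN = mean)
  by_subj <- stats::aggregate(D ~ subject_id + stimulus_id,
                              data = by_sess, FUN = mean)
  subjects <- sort(unique(by_subj$subject_id))
  tab <- matrix(NA_real_, nrow = length(subjects), ncol = 6L,
                dimnames = list(subjects, STIMULUS_LEVELS))
  for (r in seq_len(nrow(by_subj))) {
    tab[by_subj$subject_id[r], by_subj$stimulus_id[r]] <- by_subj$D[r]
  }
  if (anyNA(tab)) {
    miss <- which(is.na(tab), arr.ind = TRUE)
    stop("incomplete design: missing ",
         paste(sprintf("%s/%s", rownames(tab)[miss[, 1]],
                       colnames(tab)[miss[, 2]]), collapse = ", "))
  }
  tab
}

#' Score a questionnaire answer sheet
#'
#' Percent-correct per viewing condition, pooled over subjects, stimuli
#' and questions.
#'
#' @param answers data frame with columns `subject_id`, `stimulus_id`,
#'   `question_index`, `correct` (0/1); a `condition` column is derived
#'   from the stimulus if absent.
#' @return named numeric vector `c(rate_2d, rate_3d)` in percent.
#' @export
score_questionnaire <- function(answers) {
  req <- c("subject_id", "stimulus_id", "question_index", "correct")
  miss <- setdiff(req, names(answers))
  if (length(miss) > 0L) {
    stop("answer sheet missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyNA(answers$correct)) {
    gaps <- answers[is.na(answers$correct),
                    c("subject_id", "stimulus_id", "question_index")]
    stop("missing answers for: ",
         paste(utils::head(apply(gaps, 1L, paste, collapse = "/"), 10L),
               collapse = ", "))
  }
  cond <- answers$condition
  if (is.null(cond)) cond <- stimulus_condition(answers$stimulus_id)
  rate <- function(k) 100 * mean(answers$correct[cond == k])
  c(rate_2d = rate("2D"), rate_3d = rate("3D"))
}

#' Run the full study analysis
#'
#' Executes the complete pipeline on a synthetic [gen_study()] dataset or
#' a manifest read with [read_manifest()]: band-pass filter (modality
#' band), truncate to the analysis duration, exclude channels, estimate a
#' box-counting dimension per channel, aggregate to subject-by-stimulus
#' tables, run the repeated-measures tests per modality, and score the
#' questionnaire.  Deterministic given dataset and configuration.
#'
#' @param dataset a `study_dataset`, or a manifest list (its records are
#'   then loaded from disk; answers come from `dataset$answers` if
#'   present).
#' @param config an [analysis_config()].
#' @return object of class `study_report`: per-stimulus mean FD tables
#'   (rows `first` ... `sixth`), per-modality `stats_report`s,
#'   subject-level tables, learning rates (percent), and a provenance
#'   block (config hash, package version).
#' @export
run_study <- function(dataset, config = analysis_config()) {
  if (inherits(dataset, "study_dataset")) {
    records <- dataset$records
    answers <- dataset$answers
  } else if (is.list(dataset) && !is.null(dataset$records)) {
    records <- read_manifest_records(dataset)
    answers <- dataset$answers
  } else {
    stop("dataset must be a study_dataset or a manifest list")
  }
  fd <- compute_fd_table(records, config)
  modalities <- intersect(c("EEG", "EMG"), unique(fd$modality))
  tables <- lapply(modalities, function(mod) aggregate_fd(fd, mod))
  names(tables) <- modalities
  stats <- lapply(tables, stats_report, alpha = config$alpha)
  fd_means <- lapply(tables, function(tab) {
    data.frame(stimulus = STIMULUS_LEVELS,
               condition = stimulus_condition(STIMULUS_LEVELS),
               mean_fd = unname(colMeans(tab)))
  })
  rates <- if (!is.null(answers)) score_questionnaire(answers) else NULL
  structure(list(
    fd_table = fd_means,
    stats = stats,
    subject_tables = tables,
    learning_rate_2d = unname(rates["rate_2d"]),
    learning_rate_3d = unname(rates["rate_3d"]),
    per_record = fd,
    provenance = list(
      config = unclass(config),
      config_hash = config_hash(config),
      generator_seed = if (inherits(dataset, "study_dataset"))
        dataset$config$seed,
      package_version = as.character(utils::packageVersion("boxfd")))),
    class = "study_report")
}

# FNV-1a hash of the canonical JSON rendering of the configuration
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (code in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), code) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Serialize a study report to JSON
#'
#' Full precision; re-running the same pipeline on the same inputs yields
#' a byte-identical file.
#'
#' @param report a [run_study()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  out <- report
  out$per_record <- NULL   # bulky; tables and stats carry the results
  out$subject_tables <- lapply(out$subject_tables, function(m)
    as.data.frame(m))
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.study_report <- function(x, ...) {
  for (mod in names(x$fd_table)) {
    cat(sprintf("Mean fractal dimension (%s):\n", mod))
    tab <- x$fd_table[[mod]]
    for (r in seq_len(nrow(tab))) {
      cat(sprintf("  %-7s (%s)  %.4f\n", tab$stimulus[r], tab$condition[r],
                  tab$mean_fd[r]))
    }
    a <- x$stats[[mod]]$anova_stimulus
    cat(sprintf("  ANOVA (stimulus): F(%d, %d) = %.4f, p = %.4g\n",
                a$df1, a$df2, a$F, a$p))
  }
  if (!is.null(x$learning_rate_2d)) {
    cat(sprintf("Learning rate: 2D %.2f%%, 3D %.2f%%\n",
                x$learning_rate_2d, x$learning_rate_3d))
  }
  invisible(x)
}
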