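# Synthetic signals and studies.
#
# Fractional Brownian motion is the signal model: its graph has
# box-counting dimension 2 - H, so the whole pipeline can be exercised
# against analytic ground truth.  A full synthetic study mirrors the
# within-subject viewing design: 9 subjects x 6 stimuli (three
# content-matched 2D/3D pairs) x 2 sessions, EEG at 128 Hz (12 channels)
# and facial EMG at 256 Hz (5 channels), ~120 s per stimulus, plus a
# three-question multiple-choice score sheet per stimulus.

#' Fractional Brownian motion path
#'
#' Exact synthesis: Davies-Harte circulant embedding of the fractional
#' Gaussian noise covariance, followed by a cumulative sum.  The graph of
#' the returned path has theoretical box-counting dimension `2 - H`.
#'
#' @param H Hurst exponent in (0, 1).
#' @param n number of samples (>= 2).
#' @param seed optional integer seed; identical `(H, n, seed)` give
#'   identical paths.
#' @return numeric vector of length `n`.
#' @export
gen_fbm <- function(H, n, seed = NULL) {
  if (!is.numeric(H) || length(H) != 1L || H <= 0 || H >= 1) {
    stop("H must lie strictly inside (0, 1)")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- 2L * n
  k <- 0:n
  g <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  lam <- Re(stats::fft(c(g, rev(g[2:n]))))
  lam[lam < 0] <- 0    # tiny negative eigenvalues from roundoff
  a <- complex(length.out = m)
  a[1] <- sqrt(lam[1] / m) * stats::rnorm(1)
  a[n + 1] <- sqrt(lam[n + 1] / m) * stats::rnorm(1)
  idx <- 2:n
  re <- stats::rnorm(n - 1); im <- stats::rnorm(n - 1)
  a[idx] <- sqrt(lam[idx] / (2 * m)) * complex(real = re, imaginary = im)
  a[m + 2 - idx] <- Conj(a[idx])
  cumsum(Re(stats::fft(a))[1:n])
}

#' Weierstrass cosine function
#'
#' `W(t) = sum_k a^k cos(b^k pi t)` on `t` in \[0, 1\]: a deterministic
#' fractal fixture whose graph has box-counting dimension
#' `D = 2 + ln(a) / ln(b)` when `0 < a < 1 < b` and `a b > 1`.
#'
#' @param a amplitude ratio in (0, 1).
#' @param b frequency ratio (> 1, with `a * b > 1` for a fractal graph;
#'   `n_terms = 1` gives a plain cosine).
#' @param n_terms number of series terms.
#' @param n number of samples on \[0, 1\].
#' @return numeric vector of length `n`.
#' @export
gen_weierstrass <- function(a, b, n_terms = 30L, n = 2^14) {
  if (!(a > 0 && a < 1)) stop("a must lie in (0, 1)")
  if (!(b > 1)) stop("b must exceed 1")
  if (n_terms > 1L && a * b <= 1) stop("need a * b > 1 for a fractal graph")
  t <- seq(0, 1, length.out = n)
  w <- numeric(n)
  for (k in seq_len(n_terms) - 1L) w <- w + a^k * cos(b^k * pi * t)
  w
}

#' Configuration of a synthetic viewing study
#'
#' Defaults emulate the study design: 9 subjects, 6 stimuli in three
#' content-matched 2D/3D pairs, 2 sessions, 12 EEG channels at 128 Hz and
#' 5 EMG channels at 256 Hz, 120 s per stimulus.  Per-condition Hurst
#' exponents are chosen so the true graph dimensions `2 - H` match the
#' reported per-condition mean fractal dimensions (EEG about 1.705 in 2D
#' vs 1.725 in 3D; EMG about 1.247 vs 1.262), and questionnaire success
#' probabilities match the reported learning rates (80.87% in 2D, 92.60%
#' in 3D).
#'
#' @param n_subjects number of subjects.
#' @param sessions number of repeated sessions.
#' @param fs_eeg,fs_emg sampling rates (Hz).
#' @param duration_s recording length per stimulus (seconds).
#' @param n_channels_eeg,n_channels_emg channel counts.
#' @param h_eeg_2d,h_eeg_3d,h_emg_2d,h_emg_3d per-condition Hurst
#'   exponents in (0, 1); lower H means a rougher, higher-dimension signal.
#' @param subject_sd between-subject standard deviation of H.
#' @param p_correct_2d,p_correct_3d per-question success probabilities.
#' @param n_questions_per_stimulus questions asked after each stimulus.
#' @param seed master seed; per-record substreams are derived from it by
#'   stable hashing of (subject, stimulus, session, channel).
#' @return object of class `study_config`.
#' @export
study_config <- function(n_subjects = 9L, sessions = 2L,
                         fs_eeg = 128, fs_emg = 256, duration_s = 120,
                         n_channels_eeg = 12L, n_channels_emg = 5L,
                         h_eeg_2d = 0.2950, h_eeg_3d = 0.2747,
                         h_emg_2d = 0.7532, h_emg_3d = 0.7384,
                         subject_sd = 0.02,
                         p_correct_2d = 0.8087, p_correct_3d = 0.9260,
                         n_questions_per_stimulus = 3L, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              sessions = as.integer(sessions),
              fs_eeg = fs_eeg, fs_emg = fs_emg, duration_s = duration_s,
              n_channels_eeg = as.integer(n_channels_eeg),
              n_channels_emg = as.integer(n_channels_emg),
              h_eeg_2d = h_eeg_2d, h_eeg_3d = h_eeg_3d,
              h_emg_2d = h_emg_2d, h_emg_3d = h_emg_3d,
              subject_sd = subject_sd,
              p_correct_2d = p_correct_2d, p_correct_3d = p_correct_3d,
              n_questions_per_stimulus = as.integer(n_questions_per_stimulus),
              seed = as.integer(seed))
  hs <- unlist(cfg[c("h_eeg_2d", "h_eeg_3d", "h_emg_2d", "h_emg_3d")])
  if (any(hs <= 0 | hs >= 1)) stop("Hurst exponents must lie in (0, 1)")
  ps <- unlist(cfg[c("p_correct_2d", "p_correct_3d")])
  if (any(ps < 0 | ps > 1)) stop("success probabilities must lie in [0, 1]")
  cnt <- unlist(cfg[c("n_subjects", "sessions", "n_questions_per_stimulus")])
  if (any(is.na(cnt) | cnt < 1)) stop("counts must be positive integers")
  ch <- c(cfg$n_channels_eeg, cfg$n_channels_emg)
  if (any(is.na(ch) | ch < 0) || sum(ch) < 1L) {
    stop("channel counts must be nonnegative with at least one channel")
  }
  if (!(cfg$subject_sd >= 0)) stop("subject_sd must be nonnegative")
  if (!(cfg$duration_s > 0 && cfg$fs_eeg > 0 && cfg$fs_emg > 0)) {
    stop("duration and sampling rates must be positive")
  }
  structure(cfg, class = "study_config")
}

# Deterministic substream seed from a master seed and string tokens
# (polynomial rolling hash mod 2^31 - 1; exact in double arithmetic).
derive_seed <- function(master, ...) {
  p <- 2147483647
  h <- (as.numeric(master) %% p + p) %% p
  for (tok in as.character(c(...))) {
    for (code in utf8ToInt(tok)) h <- (h * 31 + code) %% p
  }
  as.integer(h)
}

#' Generate a full synthetic viewing study
#'
#' For each subject and condition, a subject-specific Hurst exponent
#' `H_[s,k] = clip(H_k + N(0, subject_sd), 0.05, 0.95)` is drawn per
#' modality; every channel of that subject/condition is an independent
#' fBm path with that exponent.  Questionnaire answers are independent
#' Bernoulli draws with the per-condition success probability.  The whole
#' dataset is reproducible from the master seed, with per-record
#' substreams insulated from generation order.
#'
#' @param config a [study_config()].
#' @return object of class `study_dataset`: list with `records` (list of
#'   [ts_record()]), `answers` (data frame: `subject_id`, `stimulus_id`,
#'   `condition`, `question_index`, `correct`), and `config`.
#' @export
gen_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  n_eeg <- as.integer(floor(cfg$duration_s * cfg$fs_eeg))
  n_emg <- as.integer(floor(cfg$duration_s * cfg$fs_emg))
  eeg_ch <- sprintf("EEG%02d", seq_len(cfg$n_channels_eeg))
  emg_ch <- sprintf("EMG%02d", seq_len(cfg$n_channels_emg))

  h_base <- list(
    EEG = c("2D" = cfg$h_eeg_2d, "3D" = cfg$h_eeg_3d),
    EMG = c("2D" = cfg$h_emg_2d, "3D" = cfg$h_emg_3d))
  # subject-by-condition-by-modality Hurst draws, each from its own substream
  h_subj <- list()
  for (s in subjects) {
    for (mod in c("EEG", "EMG")) {
      for (k in c("2D", "3D")) {
        set.seed(derive_seed(cfg$seed, "hurst", s, mod, k))
        h <- h_base[[mod]][[k]] + stats::rnorm(1, 0, cfg$subject_sd)
        h_subj[[paste(s, mod, k)]] <- min(max(h, 0.05), 0.95)
      }
    }
  }

  records <- vector("list",
                    cfg$n_subjects * 6L * cfg$sessions *
                      (cfg$n_channels_eeg + cfg$n_channels_emg))
  i <- 0L
  for (s in subjects) {
    for (stim in STIMULUS_LEVELS) {
      k <- stimulus_condition(stim)
      for (sess in seq_len(cfg$sessions)) {
        for (mod in c("EEG", "EMG")) {
          fs <- if (mod == "EEG") cfg$fs_eeg else cfg$fs_emg
          nn <- if (mod == "EEG") n_eeg else n_emg
          chans <- if (mod == "EEG") eeg_ch else emg_ch
          h <- h_subj[[paste(s, mod, k)]]
          for (ch in chans) {
            i <- i + 1L
            records[[i]] <- ts_record(
              gen_fbm(h, nn, seed = derive_seed(cfg$seed, s, stim, sess, ch)),
              fs = fs, channel = ch, subject_id = s, stimulus_id = stim,
              session = sess, modality = mod)
          }
        }
      }
    }
  }

  grid <- expand.grid(question_index = seq_len(cfg$n_questions_per_stimulus),
                      stimulus_id = STIMULUS_LEVELS, subject_id = subjects,
                      stringsAsFactors = FALSE)[, 3:1]
  grid$condition <- stimulus_condition(grid$stimulus_id)
  grid$correct <- NA_integer_
  for (s in subjects) {
    for (stim in STIMULUS_LEVELS) {
      p <- if (stimulus_condition(stim) == "2D") cfg$p_correct_2d else cfg$p_correct_3d
      set.seed(derive_seed(cfg$seed, "answers", s, stim))
      rows <- grid$subject_id == s & grid$stimulus_id == stim
      grid$correct[rows] <- stats::rbinom(sum(rows), 1L, p)
    }
  }
  structure(list(records = records, answers = grid, config = cfg),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "<study_dataset> %d records (%d subjects x 6 stimuli x %d sessions), %d answers\n",
    length(x$records), x$config$n_subjects, x$config$sessions,
    nrow(x$answers)))
  invisible(x)
}

#' Write a study dataset to disk as CSVs plus a manifest
#'
#' One wide CSV per subject/stimulus/session/modality, an `answers.csv`
#' score sheet, and a YAML manifest readable by [read_manifest()].
#'
#' @param dataset a [gen_study()] result.
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
write_study <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  key <- vapply(dataset$records, function(r)
    paste(r$subject_id, r$stimulus_id, r$session, r$modality, sep = "_"),
    character(1))
  entries <- list()
  for (k in unique(key)) {
    recs <- dataset$records[key == k]
    fn <- paste0(k, ".csv")
    write_signal_csv(recs, file.path(dir, fn))
    r1 <- recs[[1]]
    entries[[length(entries) + 1L]] <- list(
      path = fn, subject_id = r1$subject_id, stimulus_id = r1$stimulus_id,
      condition = r1$condition, session = r1$session,
      modality = r1$modality, fs = r1$fs)
  }
  utils::write.csv(dataset$answers, file.path(dir, "answers.csv"),
                   row.names = FALSE)
  manifest <- list(records = entries,
                   fs_by_modality = list(EEG = dataset$config$fs_eeg,
                                         EMG = dataset$config$fs_emg),
                   analysis_duration_s = 118.2)
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(mp)
}
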