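# Shared fixtures, built in code.

# random polyline in the unit square; graphs (monotone x) exercise the fast
# column counter, general polylines the segment traversal
random_polyline <- function(n = 50, graph = FALSE) {
  if (graph) {
    cbind(x = sort(stats::runif(n)), y = stats::runif(n))
  } else {
    cbind(x = stats::runif(n), y = stats::runif(n))
  }
}

# miniature synthetic study: quick to generate and analyze
tiny_study_config <- function(seed = 42, ...) {
  args <- list(n_subjects = 3, sessions = 2, duration_s = 16,
               n_channels_eeg = 2, n_channels_emg = 1, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(study_config, args)
}

tiny_analysis_config <- function(...) {
  args <- list(analysis_duration_s = 15.5)
  args[names(list(...))] <- list(...)
  do.call(analysis_config, args)
}

# independent repeated-measures ANOVA oracle: hand-expanded sums of squares
rm_anova_by_hand <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_treat <- n * sum((colMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_subj - ss_treat
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  F <- (ss_treat / df1) / (ss_err / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       ss_treat = ss_treat, ss_error = ss_err)
}
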