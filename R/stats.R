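# Inference across stimuli: Shapiro-Wilk normality screening, one-way
# repeated-measures ANOVA (subjects as the blocking factor), and paired
# Student t tests between condition-matched stimuli.

#' Shapiro-Wilk normality p-value
#'
#' @param values numeric sample, 3 <= n <= 5000.  A constant sample has no
#'   defined W statistic; this is raised as an error (documented contract).
#' @return the Shapiro-Wilk p-value.
#' @export
normality_check <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("normality check needs at least 3 values")
  if (stats::sd(values) == 0) {
    stop("normality check undefined for a constant sample")
  }
  stats::shapiro.test(values)$p.value
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA of a complete subjects-by-conditions table:
#' `F = MS_treatment / MS_error` where the error term is the
#' subject-by-treatment interaction, with degrees of freedom `(k - 1,
#' (n - 1)(k - 1))`.  No sphericity correction is applied.  Fitted via
#' `stats::aov` with an `Error(subject)` stratum; sums of squares are
#' extracted and the F ratio recomputed so degenerate tables (zero
#' treatment or zero error variance) are handled explicitly.
#'
#' @param values numeric matrix, rows = subjects, columns = treatment
#'   levels (e.g. the six stimuli); complete and finite.
#' @return list with `F`, `p`, `df1`, `df2`, `ss_treat`, `ss_error`,
#'   `partial_eta_sq`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 levels")
  if (any(!is.finite(values))) stop("table must be complete and finite")
  df <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    treat = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ treat + Error(subject), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_treat <- tab["treat", "Sum Sq"]
  ss_error <- tab["Residuals", "Sum Sq"]
  df1 <- tab["treat", "Df"]
  df2 <- tab["Residuals", "Df"]
  # degeneracy detected relative to the table's total variance: aov's sums
  # of squares are never exactly zero in floating point
  scale <- sum((values - mean(values))^2)
  if (scale == 0 || ss_treat <= 1e-10 * scale) {
    # no treatment variance: F = 0, p = 1 (covers the all-equal table too)
    return(list(F = 0, p = 1, df1 = df1, df2 = df2, ss_treat = 0,
                ss_error = ss_error, partial_eta_sq = 0))
  }
  if (ss_error <= 1e-10 * scale) {
    warning("zero error variance: treatment effect is exact; F = Inf, p = 0")
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2, ss_treat = ss_treat,
                ss_error = 0, partial_eta_sq = 1))
  }
  F <- (ss_treat / df1) / (ss_error / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, ss_treat = ss_treat, ss_error = ss_error,
       partial_eta_sq = ss_treat / (ss_treat + ss_error))
}

#' Paired Student t test
#'
#' Two-sided paired t on the differences, `df = n - 1`.  Zero-variance
#' differences leave t undefined and raise an error.
#'
#' @param a,b numeric vectors of equal length (n >= 2), paired by position.
#' @param paired compare within pairs (default); `FALSE` gives the
#'   two-sample Student t with pooled variance.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t <- function(a, b, paired = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (paired && length(a) != length(b)) stop("paired vectors differ in length")
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 observations")
  if (paired && stats::sd(a - b) == 0) {
    stop("zero-variance differences: paired t statistic undefined")
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = !paired)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_diff = if (paired) mean(a - b) else mean(a) - mean(b))
}

#' Full inferential report for a subjects-by-stimuli table
#'
#' Computes (i) the stimulus-factor repeated-measures ANOVA over all six
#' stimuli, (ii) the condition-factor ANOVA on per-subject 2D/3D means
#' (two levels, so `F = t^2` of the paired t), (iii) paired t tests for
#' the three content-matched stimulus pairs with Holm-adjusted p-values
#' logged alongside the raw ones, and (iv) per-stimulus Shapiro-Wilk
#' normality p-values (a warning, not an abort, below `alpha`).
#'
#' @param table numeric matrix, rows = subjects, columns named
#'   `first` ... `sixth`.
#' @param alpha significance level (default 0.05).
#' @return object of class `stats_report`.
#' @export
stats_report <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  if (is.null(colnames(table))) colnames(table) <- STIMULUS_LEVELS[seq_len(ncol(table))]
  stopifnot(identical(colnames(table), STIMULUS_LEVELS))
  cond <- stimulus_condition(colnames(table))
  mean_2d <- rowMeans(table[, cond == "2D", drop = FALSE])
  mean_3d <- rowMeans(table[, cond == "3D", drop = FALSE])

  normality_p <- apply(table, 2L, function(col) {
    tryCatch(normality_check(col), error = function(e) NA_real_)
  })
  if (any(normality_p < alpha, na.rm = TRUE)) {
    warning("normality rejected (p < ", alpha, ") for: ",
            paste(names(normality_p)[which(normality_p < alpha)],
                  collapse = ", "))
  }

  pairs <- list(c("first", "second"), c("third", "fourth"),
                c("fifth", "sixth"))
  pw <- lapply(pairs, function(pr) {
    res <- paired_t(table[, pr[1]], table[, pr[2]])
    data.frame(pair = paste(pr, collapse = "-"), t = res$t, p = res$p,
               df = res$df, mean_diff = res$mean_diff)
  })
  pw <- do.call(rbind, pw)
  pw$p_holm <- stats::p.adjust(pw$p, method = "holm")

  structure(list(
    anova_stimulus = rm_anova(table),
    anova_condition = rm_anova(cbind(`2D` = mean_2d, `3D` = mean_3d)),
    condition_t = paired_t(mean_3d, mean_2d),
    pairwise = pw,
    normality_p = normality_p,
    alpha = alpha), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  a <- x$anova_stimulus
  cat(sprintf("RM-ANOVA (stimulus, %d levels): F(%d, %d) = %.4f, p = %.4g\n",
              a$df1 + 1, a$df1, a$df2, a$F, a$p))
  b <- x$anova_condition
  cat(sprintf("RM-ANOVA (condition, 2 levels): F(%d, %d) = %.4f, p = %.4g\n",
              b$df1, b$df2, b$F, b$p))
  cat("Pairwise paired t (2D vs 3D pairs):\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
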