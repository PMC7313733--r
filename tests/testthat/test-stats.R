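test_that("normality check is calibrated and has power", {
  set.seed(15)
  p_null <- replicate(500, normality_check(rnorm(100)))
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.025)
  p_alt <- replicate(100, normality_check(exp(rnorm(100))))
  expect_gte(mean(p_alt < 0.05), 0.8)
  expect_error(normality_check(c(1, 2)), "at least 3")
  expect_error(normality_check(rep(1, 10)), "constant")
})

test_that("rm_anova agrees with hand-expanded sums of squares", {
  set.seed(25)
  for (i in 1:20) {
    m <- matrix(rnorm(9 * 6, mean = 1.7, sd = 0.05), 9, 6)
    got <- rm_anova(m)
    ref <- rm_anova_by_hand(m)
    expect_equal(got$F, ref$F, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
    expect_equal(got$ss_treat, ref$ss_treat, tolerance = 1e-10)
  }
})

test_that("rm_anova handles degenerate tables explicitly", {
  # subjects differ, no treatment effect: F = 0, p = 1
  m0 <- matrix(rep(c(1, 2, 3), 6), nrow = 3)
  res0 <- rm_anova(m0)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  # additive toy table {(1,2),(2,3),(3,4)}: zero interaction variance
  expect_warning(res <- rm_anova(cbind(c(1, 2, 3), c(2, 3, 4))),
                 "zero error variance")
  expect_equal(res$F, Inf)
  expect_equal(res$p, 0)
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
  expect_error(rm_anova(matrix(1:4, 1)), "at least 2")
})

test_that("paired t matches closed forms and flags degenerate input", {
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))   # differences 1, 2, 3
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)

  zero <- paired_t(c(1, 2, 3, 4), c(2, 1, 4, 3))  # differences -1,+1,-1,+1
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)

  expect_error(paired_t(c(6, 7, 8), c(1, 2, 3)), "zero-variance")
  expect_error(paired_t(1:3, 1:4), "differ in length")
})

test_that("two-level repeated measures satisfies F = t squared", {
  set.seed(35)
  for (i in 1:20) {
    a <- rnorm(8, 1.7, 0.05); b <- rnorm(8, 1.72, 0.05)
    F <- rm_anova(cbind(a, b))$F
    t <- paired_t(a, b)$t
    expect_equal(F, t^2, tolerance = 1e-9)
  }
})

test_that("stats_report assembles all inferential pieces", {
  set.seed(45)
  tab <- matrix(rnorm(9 * 6, 1.7, 0.02), 9, 6,
                dimnames = list(NULL, c("first", "second", "third",
                                        "fourth", "fifth", "sixth")))
  rep <- suppressWarnings(stats_report(tab))
  expect_s3_class(rep, "stats_report")
  expect_equal(nrow(rep$pairwise), 3)
  expect_equal(rep$pairwise$pair,
               c("first-second", "third-fourth", "fifth-sixth"))
  expect_true(all(rep$pairwise$p >= 0 & rep$pairwise$p <= 1))
  expect_true(all(rep$pairwise$p_holm >= rep$pairwise$p))
  expect_length(rep$normality_p, 6)
  # condition-level ANOVA on 2 levels must square the condition t
  expect_equal(rep$anova_condition$F, rep$condition_t$t^2, tolerance = 1e-9)
})
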